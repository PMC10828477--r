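# internal helpers shared across modules

.clip01 <- function(x) pmin(pmax(x, 0), 1)  # first-arg order keeps dims

# deterministic per-stage seed derived from one run seed; stays < 2^31
.deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629 + 1)
}

.stopIf <- function(cond, ...) if (cond) stop(..., call. = FALSE)

# fixed-format TSV writer so that repeated runs are byte-identical
.writeTsv <- function(df, path, digits = 10) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = digits,
                                                 format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
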