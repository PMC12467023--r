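# Round half away from zero (matches the printed shares/excess figures;
# base round() is banker's rounding).
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Fixed-format numeric printing so report files are byte-stable across runs.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    formatC(v, format = "g", digits = 10)
  }, character(1))
  out
}

write_tsv_stable <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) {
    # keep integers as integers, format reals stably
    if (!is.integer(df[[j]])) out[[j]] <- fmt_num(df[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
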