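# Internal helpers shared across modules.

.stop_param <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("proteodeg_parameter_error", "error")))
}

.stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("proteodeg_input_error", "error")))
}

# round() in R rounds half to even; published tables round half away from
# zero, so summaries use this variant.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == trunc(x)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path, required = character()) {
  if (!file.exists(path)) .stop_input("file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    .stop_input("%s: missing required column(s): %s",
                path, paste(miss, collapse = ", "))
  }
  df
}
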