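#' @keywords internal
"_PACKAGE"

# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1))
    stopf("%s must lie in [0, 1]", name)
  invisible(x)
}

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || x <= 0 || x != round(x))
    stopf("%s must be a positive integer", name)
  invisible(as.integer(x))
}

#' Haldane mapping function
#'
#' Convert a recombination fraction to a map distance in centimorgans
#' (`haldane_cm`) or back (`haldane_rf`), assuming crossovers occur as a
#' Poisson process with no interference.
#'
#' @param r recombination fraction in `[0, 0.5)`.
#' @param d map distance in centimorgans.
#' @return `haldane_cm`: distance in cM; `haldane_rf`: recombination fraction.
#' @examples
#' haldane_cm(0.25)        # 34.657 cM
#' haldane_rf(haldane_cm(0.1))
#' @export
haldane_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) stopf("recombination fraction must be in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' @rdname haldane_cm
#' @export
haldane_rf <- function(d) {
  if (any(d < 0)) stopf("map distance must be non-negative")
  (1 - exp(-2 * d / 100)) / 2
}

#' Kosambi mapping function
#'
#' @inheritParams haldane_cm
#' @return distance in cM, or recombination fraction for the inverse.
#' @export
kosambi_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) stopf("recombination fraction must be in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cm
#' @export
kosambi_rf <- function(d) {
  if (any(d < 0)) stopf("map distance must be non-negative")
  0.5 * tanh(2 * d / 100)
}

# write a data.frame as plain TSV (the interchange format used throughout)
write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}
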