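#' Derive a stage seed from a master seed
#'
#' One master seed governs all randomness in a run; per-stage (or per-fold)
#' seeds are derived deterministically so that partial re-runs reproduce the
#' same streams. The hash is a plain base-31 polynomial over the UTF-8 bytes
#' of \code{master/label1/label2/...}, reduced modulo 2^31 - 1 so the result
#' is always a valid 32-bit R integer.
#'
#' @param master integer master seed.
#' @param ... further labels (stage name, repeat index, fold index, ...).
#' @return an integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  tok <- paste(c(format(master, scientific = FALSE), ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tok)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' @keywords internal
check_binary <- function(x, what) {
  if (!all(x == 0 | x == 1)) {
    bad <- x[!(x == 0 | x == 1)][1]
    stop(sprintf("%s must contain only 0/1 values (found %s)", what,
                 format(bad)), call. = FALSE)
  }
  invisible(TRUE)
}

#' @keywords internal
check_no_duplicates <- function(ids, what) {
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate %s: %s", what,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}
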