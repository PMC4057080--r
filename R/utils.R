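#' Round half away from zero
#'
#' Commercial rounding used for all integer-percent reporting: 0.5 rounds to
#' 1 and -0.5 to -1, unlike [base::round()]'s round-half-even. This is the
#' rule that reproduces the printed accuracies and change percentages in the
#' reference tables from their own counts.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_away(c(0.5, -0.5, 7.5, 67.42))
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Derive named RNG substream seeds from a top-level seed
#'
#' All randomness in the synthetic-data generator flows from one top-level
#' seed through named substreams, so any single stage (landscape, climate,
#' survey, ...) can be re-run independently yet reproducibly.
#'
#' @param seed integer top-level seed.
#' @param streams character vector of substream names.
#' @return named integer vector of derived seeds.
#' @export
substream_seeds <- function(seed,
                            streams = c("landscape", "climate", "survey",
                                        "routes", "forest", "design")) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  s <- sample.int(.Machine$integer.max - 1L, length(streams))
  names(s) <- streams
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
warn_ <- function(...) warning(sprintf(...), call. = FALSE)
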