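#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code under a temporary RNG state; restores .Random.seed afterwards so
## simulators are reproducible without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1), matching the fixed-point
#' display convention of published coalescence-age tables rather than R's
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_purine <- function(b) b %in% c("A", "G")

## transition partner of a base (A<->G, C<->T)
transition_partner <- function(b) {
  unname(c(A = "G", G = "A", C = "T", T = "C")[b])
}
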