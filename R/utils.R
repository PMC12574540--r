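#' Round half away from zero
#'
#' Fixed-point rounding with ties going up (0.5 -> 1), unlike [round()]'s
#' round-half-even. Used for all printed percentages so that reported figures
#' are reproducible integers/decimals.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage share with two-decimal rounding
#'
#' Gene-share percentages are conventionally printed with two decimals
#' (e.g. 72.53%); group frequencies with none (e.g. 62%). Both use
#' round-half-up.
#'
#' @param count numerator count.
#' @param total denominator count (> 0).
#' @param digits decimal places (default 2).
#' @return numeric percentage.
#' @examples
#' gene_share_percent(7811, 10769)  # 72.53
#' @export
gene_share_percent <- function(count, total, digits = 2) {
  stopifnot(total > 0, count >= 0)
  round_half_up(100 * count / total, digits)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

stop_input <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

#' @noRd
is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min && x == floor(x)
}

# run expr with a private RNG stream seeded from `seed`, restoring the
# caller's .Random.seed afterwards so simulations never perturb user code
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
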