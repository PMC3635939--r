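#' Kosambi mapping function and its inverse
#'
#' Converts a recombination fraction `r` to a map distance in centimorgans
#' under the Kosambi mapping function, `d = 25 * ln((1 + 2r) / (1 - 2r))`,
#' which allows for partial crossover interference, and back.
#'
#' `kosambi_cM()` is strictly increasing on `[0, 0.5)`, zero at `r = 0`, and
#' diverges as `r` approaches 0.5. `kosambi_r()` is its exact inverse,
#' `r = tanh(d / 50) / 2`.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @param d Map distance(s) in centimorgans, `>= 0`.
#' @return Numeric vector of map distances (cM) or recombination fractions.
#' @examples
#' kosambi_cM(0.2)        # 21.18 cM
#' kosambi_r(kosambi_cM(0.35))
#' @export
kosambi_cM <- function(r) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE))
    stop_input("recombination fractions must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cM
#' @export
kosambi_r <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop_input("map distances must be >= 0")
  tanh(d / 50) / 2
}
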