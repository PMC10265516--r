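# delta-notation bookkeeping for the 6Li/7Li pair.
#
# All delta values are carried in permil against a reporting standard and are
# never stored internally as raw ratios; at the permil scale the (1 + d/1000)
# algebra is exact in double precision whereas repeated ratio round trips are
# not.

#' The 7Li/6Li ratio of the LSVEC reporting standard
#'
#' LSVEC (lithium carbonate, NIST RM 8545) defines delta-7Li = 0. The absolute
#' ratio does not appear in any fractionation difference, so it is exposed as
#' a configurable constant rather than hard-wired into results.
#'
#' @param r_ref Optional replacement ratio; must be a positive scalar.
#' @return The 7Li/6Li ratio of the standard (dimensionless).
#' @export
#' @examples
#' lsvec_ratio()
lsvec_ratio <- function(r_ref = 12.0192) {
  if (!is.numeric(r_ref) || length(r_ref) != 1L || !is.finite(r_ref) || r_ref <= 0)
    stop("'r_ref' must be a single positive number", call. = FALSE)
  r_ref
}

#' Convert a 7Li/6Li ratio to a delta-7Li value
#'
#' delta-7Li (permil) = (r_sample / r_ref - 1) * 1000.
#'
#' @param r_sample 7Li/6Li ratio(s) of the sample; must be positive.
#' @param r_ref Ratio of the reporting standard (default LSVEC).
#' @return delta-7Li in permil.
#' @seealso [delta_to_ratio()] for the exact inverse.
#' @export
ratio_to_delta <- function(r_sample, r_ref = lsvec_ratio()) {
  if (any(!is.finite(r_sample)) || any(r_sample <= 0))
    stop("'r_sample' must be positive and finite: a 7Li/6Li ratio of ",
         paste(r_sample[!is.finite(r_sample) | r_sample <= 0], collapse = ", "),
         " has no delta representation", call. = FALSE)
  1000 * (r_sample / lsvec_ratio(r_ref) - 1)
}

#' Convert a delta-7Li value to a 7Li/6Li ratio
#'
#' @param delta delta-7Li in permil; must exceed -1000.
#' @param r_ref Ratio of the reporting standard.
#' @return 7Li/6Li ratio(s).
#' @export
delta_to_ratio <- function(delta, r_ref = lsvec_ratio()) {
  if (any(!is.finite(delta)) || any(delta <= -1000))
    stop("'delta' must be finite and > -1000 permil", call. = FALSE)
  lsvec_ratio(r_ref) * (1 + delta / 1000)
}

#' delta-7Li of a pool given its isotope amounts
#'
#' Invariant under uniform scaling of the two amounts.
#'
#' @param n6,n7 Amounts of 6Li and 7Li (mol, or any common unit); both
#'   non-negative, `n6` strictly positive.
#' @param r_ref Ratio of the reporting standard.
#' @return delta-7Li in permil.
#' @export
amounts_to_delta <- function(n6, n7, r_ref = lsvec_ratio()) {
  if (any(n6 < 0) || any(n7 < 0))
    stop("isotope amounts must be non-negative", call. = FALSE)
  if (any(n6 == 0))
    stop("n6 = 0: the 7Li/6Li ratio is infinite and delta is undefined",
         call. = FALSE)
  ratio_to_delta(n7 / n6, r_ref)
}

#' Split a delta value into isotope mole fractions
#'
#' Returns the unique (x6, x7) with x6 + x7 = 1 and
#' x7/x6 = r_ref * (1 + delta/1000).
#'
#' @inheritParams delta_to_ratio
#' @return A list with components `x6` and `x7`.
#' @export
delta_to_fractions <- function(delta, r_ref = lsvec_ratio()) {
  r <- delta_to_ratio(delta, r_ref)
  list(x6 = 1 / (1 + r), x7 = r / (1 + r))
}

#' Split a bulk Li concentration into isotope-specific concentrations
#'
#' Convenience wrapper around [delta_to_fractions()] used to set up media.
#'
#' @param conc Total Li concentration (any unit).
#' @param delta delta-7Li of the pool in permil.
#' @param r_ref Ratio of the reporting standard.
#' @return A list with components `C6` and `C7` in the unit of `conc`.
#' @export
split_li <- function(conc, delta, r_ref = lsvec_ratio()) {
  x <- delta_to_fractions(delta, r_ref)
  list(C6 = conc * x$x6, C7 = conc * x$x7)
}

#' Fractionation between two reservoirs
#'
#' Delta-7Li between reservoirs a and b (for cells against medium, a = cell,
#' b = medium). The default is the plain difference of the two delta values,
#' which is how cell-medium fractionations such as -13.8 permil (cell at
#' 1.2 permil, medium at 15 permil) are reported. `method = "ratio"` gives
#' the multiplicative alternative 1000 * (Ra/Rb - 1); the two agree to first
#' order in delta/1000.
#'
#' @param delta_a,delta_b delta-7Li of the two reservoirs, permil, on the
#'   same standard.
#' @param method `"difference"` (default) or `"ratio"`.
#' @return Fractionation in permil.
#' @export
#' @examples
#' fractionation(1.2, 15) # -13.8
fractionation <- function(delta_a, delta_b,
                          method = c("difference", "ratio")) {
  method <- match.arg(method)
  if (any(!is.finite(delta_a)) || any(!is.finite(delta_b)))
    stop("delta values must be finite", call. = FALSE)
  if (method == "difference") {
    delta_a - delta_b
  } else {
    1000 * ((1 + delta_a / 1000) / (1 + delta_b / 1000) - 1)
  }
}
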