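# Goldman-Hodgkin-Katz electrodiffusion and the membrane-potential balance.
#
# Conventions used throughout the package:
#   * V_m = inside minus outside, reported in mV;
#   * fluxes are molar and inward-positive (mol m^-2 s^-1 with P in m/s and
#     concentrations in mM = mol m^-3), so cation entry depolarises.

FARADAY <- 96485.33212      # C / mol
GAS_R   <- 8.31446261815324 # J / mol / K

#' Goldman-Hodgkin-Katz flux equation
#'
#' Net inward molar flux of one ion species across a constant-field membrane,
#' `J = P w (C_out - C_in e^w) / (e^w - 1)` with `w = z F V_m / (R T)`.
#' The removable singularity at `w = 0` is handled by a first-order expansion,
#' and `|w|` beyond ~700 by the exact saturating limits, so the function is
#' continuous over the whole voltage axis.
#'
#' @param P Permeability (m/s), non-negative.
#' @param z Signed valence (+1 or -1 for the species used here).
#' @param Vm_mV Membrane potential, inside minus outside, in mV.
#' @param C_in,C_out Concentrations (mM) on each side.
#' @param temp_K Absolute temperature (K).
#' @return Net inward flux in mol m^-2 s^-1; positive means entry.
#' @export
#' @examples
#' ghk_flux(1e-9, +1, -60, 0.1, 15, 310)
ghk_flux <- function(P, z, Vm_mV, C_in, C_out, temp_K = 310) {
  if (any(P < 0)) stop("permeability must be non-negative", call. = FALSE)
  if (temp_K <= 0) stop("temperature must be positive", call. = FALSE)
  w <- z * FARADAY * (Vm_mV / 1000) / (GAS_R * temp_K)
  out <- numeric(length(w <- rep_len(w, max(length(w), length(P), length(C_in), length(C_out)))))
  P <- rep_len(P, length(w)); C_in <- rep_len(C_in, length(w))
  C_out <- rep_len(C_out, length(w))
  small <- abs(w) < 1e-6
  big_pos <- w > 700
  big_neg <- w < -700
  mid <- !small & !big_pos & !big_neg
  # Fick limit plus first-order correction in w
  out[small] <- P[small] * ((C_out[small] - C_in[small]) -
                              w[small] * (C_out[small] + C_in[small]) / 2)
  out[mid] <- P[mid] * w[mid] * (C_out[mid] - C_in[mid] * exp(w[mid])) /
    expm1(w[mid])
  # e^w dominates: J -> -P w C_in (w>0), J -> P |w| C_out (w<0)
  out[big_pos] <- -P[big_pos] * w[big_pos] * C_in[big_pos]
  out[big_neg] <- -P[big_neg] * w[big_neg] * C_out[big_neg]
  out
}

# minimal GHK kernel for the ODE hot path: no validation, no recycling of
# argument lengths; wfac = F/(R T)/1000 premultiplied so Vm arrives in mV
.ghk_fast <- function(P, z, Vm_mV, C_in, C_out, wfac) {
  w <- z * Vm_mV * wfac
  J <- P * w * (C_out - C_in * exp(w)) / expm1(w)
  bad <- !is.finite(J)
  if (any(bad)) J[bad] <- P[bad] * (C_out[bad] - C_in[bad])  # w -> 0 limit
  J
}

#' Zero-current (reversal) membrane potential of a set of GHK fluxes
#'
#' Solves sum_s z_s J_s(V) = 0 by bracketed root finding. With monovalent
#' species only this net-current function is monotone in V and the root is
#' unique; it coincides with the closed-form GHK voltage equation when all
#' permeant species are monovalent.
#'
#' @param species A data frame with columns `z`, `P`, `C_in`, `C_out`
#'   (see [membrane_species()]).
#' @param temp_K Temperature (K).
#' @param interval Search bracket in mV.
#' @return Zero-current potential in mV.
#' @export
ghk_voltage <- function(species, temp_K = 310, interval = c(-500, 500)) {
  net <- function(v) {
    sum(species$z * ghk_flux(species$P, species$z, v,
                             species$C_in, species$C_out, temp_K))
  }
  lo <- net(interval[1]); hi <- net(interval[2])
  if (!is.finite(lo) || !is.finite(hi) || sign(lo) == sign(hi))
    stop("no sign change of the net current in the bracket [",
         interval[1], ", ", interval[2], "] mV; check permeabilities ",
         "and concentrations", call. = FALSE)
  stats::uniroot(net, interval = interval, tol = 1e-10)$root
}

#' Channel fluxes and the membrane-potential derivative
#'
#' Evaluates the per-species inward GHK fluxes and the capacitive charging
#' rate `dV_m/dt = (F / c_m) sum_s z_s J_s` (per-area form; the membrane
#' area cancels).
#'
#' @param species Data frame as in [ghk_voltage()].
#' @param Vm_mV Membrane potential (mV).
#' @param c_m Specific membrane capacitance (F/m^2); 0.01 F/m^2 is the
#'   textbook 1 uF/cm^2.
#' @param temp_K Temperature (K).
#' @return List with `J` (named fluxes, mol m^-2 s^-1, inward positive) and
#'   `dVm_dt_mV` (mV/s).
#' @export
channel_rhs <- function(species, Vm_mV, c_m = 0.01, temp_K = 310) {
  J <- ghk_flux(species$P, species$z, Vm_mV, species$C_in, species$C_out,
                temp_K)
  names(J) <- species$name
  list(J = J, dVm_dt_mV = 1000 * (FARADAY / c_m) * sum(species$z * J))
}
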