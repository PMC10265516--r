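# Whole-cell uptake: channels + exchanger coupled to intracellular isotope
# pools, pH and membrane potential.

#' Simulate whole-cell Li uptake
#'
#' Integrates the coupled system
#' \itemize{
#'   \item d(ion)_in/dt = (A/V) * J_channel + (n_scale/V) * J_NHE,
#'   \item dV_m/dt = (F/c_m) * sum z_s J_channel,s (the exchanger is
#'     electroneutral and carries no current),
#'   \item d pH_in/dt = + J_H,NHE / (V * beta_buffer) (proton extrusion
#'     alkalinises),
#' }
#' with GHK channel fluxes for Li6, Li7, Na, K, Cl and the dimeric-exchanger
#' master-equation fluxes for Li6, Li7, Na. Integration uses an adaptive
#' embedded Runge-Kutta scheme of order 4(5) (Dormand-Prince) by default.
#'
#' For an infinite medium the exchanger fluxes depend only on pH_in, and are
#' evaluated through a tabulated pH spline (`exchanger_mode = "spline"`);
#' `"exact"` solves the 50-state stationary system at every evaluation and
#' is used automatically when the medium is finite.
#'
#' @param cell A [cell_config()] object.
#' @param mem A [membrane_params()] object.
#' @param exch An [exchanger_params()] object, or `NULL` for a channel-only
#'   (exchanger-null) cell.
#' @param times Increasing vector of output times (s).
#' @param method Integration method: `"ode45"` (default) or any
#'   \pkg{deSolve} method name such as `"lsoda"`.
#' @param rtol,atol Solver tolerances.
#' @param exchanger_mode `"spline"` or `"exact"`.
#' @param r_ref Reporting-standard ratio for the delta columns.
#' @return A data frame of class `li_trajectory` with columns `t_s`,
#'   `Li_cell_mM`, `delta7Li_permil`, `pH_in`, `Vm_mV`, `n6_mol`, `n7_mol`
#'   (plus medium columns in finite-medium mode).
#' @export
#' @examples
#' tr <- simulate_uptake(cell_config(), membrane_params(), NULL,
#'                       times = seq(0, 10, 1))
#' tail(tr, 3)
simulate_uptake <- function(cell, mem, exch = NULL,
                            times = seq(0, 60, by = 1),
                            method = c("ode45", "lsoda"),
                            rtol = 1e-8, atol = 1e-12,
                            exchanger_mode = c("spline", "exact"),
                            r_ref = lsvec_ratio()) {
  stopifnot(inherits(cell, "cell_config"), inherits(mem, "membrane_params"))
  if (!is.null(exch)) stopifnot(inherits(exch, "exchanger_params"))
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing", call. = FALSE)
  method <- match.arg(method)
  exchanger_mode <- match.arg(exchanger_mode)
  if (!cell$medium_infinite) exchanger_mode <- "exact"

  V <- cell$V_cell_um3 * 1e-18    # m^3
  A <- cell$A_um2 * 1e-12         # m^2
  AoV <- A / V                    # 1/m
  Vb <- cell$bath_volume_um3 * 1e-18
  sp <- split_li(cell$Li_out, cell$delta_out, r_ref)
  li0 <- split_li(max(cell$Li_in0, 0), cell$delta_out, r_ref)
  out0 <- c(Li6 = sp$C6, Li7 = sp$C7, Na = cell$Na_out, K = cell$K_out,
            Cl = cell$Cl_out)
  y0 <- c(Li6 = li0$C6, Li7 = li0$C7, Na = cell$Na_in0, K = cell$K_in0,
          Cl = cell$Cl_in0, pH = cell$pH_in0, Vm = cell$Vm0_mV)
  finite <- !cell$medium_infinite
  if (finite) y0 <- c(y0, out0_Li6 = sp$C6, out0_Li7 = sp$C7,
                      out0_Na = cell$Na_out, out0_K = cell$K_out,
                      out0_Cl = cell$Cl_out)

  nhe_spline <- NULL
  if (!is.null(exch) && exchanger_mode == "spline") {
    env0 <- exchanger_env(sp$C6, sp$C7, cell$Na_out,
                          H_in = 10^-cell$pH_in0, H_out = 10^-cell$pH_out)
    nhe_spline <- exchanger_flux_spline(exch, env0)
  }

  # hot path: plain vectors, no data-frame construction per evaluation
  Pvec <- c(mem$rho_ch * mem$P7, mem$P7, mem$P_Na, mem$P_K, mem$P_Cl)
  zvec <- c(1, 1, 1, 1, -1)
  FoverC <- 1000 * FARADAY / mem$c_m
  wfac <- FARADAY / (GAS_R * cell$temp_K) / 1000
  rhs <- function(t, y, parms) {
    cin <- pmax(y[1:5], 0)
    cout <- if (finite) pmax(y[8:12], 0) else out0
    J <- .ghk_fast(Pvec, zvec, y[[7L]], cin, cout, wfac)
    dcin <- J * AoV                          # mM/s from channels
    dJH_nhe <- 0
    if (!is.null(exch)) {
      Jn <- if (!is.null(nhe_spline)) {
        nhe_spline(y[[6L]])
      } else {
        e <- exchanger_env(cout[[1L]], cout[[2L]], cout[[3L]],
                           H_in = 10^-y[[6L]], H_out = 10^-cell$pH_out)
        r <- steady_state_flux(exch, e)
        c(r$J6, r$J7, r$J_Na)
      }
      # steady_state_flux already applies the inhibited fraction
      nhe_mM <- exch$n_scale * Jn / V
      dcin[1:3] <- dcin[1:3] + nhe_mM
      dJH_nhe <- sum(nhe_mM)
    }
    dpH <- dJH_nhe / cell$beta_buffer
    dVm <- FoverC * sum(zvec * J)
    dy <- c(dcin, dpH, dVm)
    if (finite) dy <- c(dy, -dcin * V / Vb)
    list(dy)
  }
  desolve_method <- if (method == "ode45") deSolve::rkMethod("ode45") else method
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = desolve_method, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed; solver diagnostics: ",
         paste(utils::capture.output(deSolve::diagnostics(sol)),
               collapse = "\n"), call. = FALSE)
  sol <- as.data.frame(sol)
  n6 <- sol$Li6 * V               # mM = mol/m^3, so conc * volume = mol
  n7 <- sol$Li7 * V
  delta <- rep(NA_real_, nrow(sol))
  ok <- sol$Li6 > 0 & sol$Li7 > 0
  delta[ok] <- 1000 * (sol$Li7[ok] / sol$Li6[ok] / lsvec_ratio(r_ref) - 1)
  out <- data.frame(t_s = sol$time,
                    Li_cell_mM = sol$Li6 + sol$Li7,
                    delta7Li_permil = delta,
                    pH_in = sol$pH,
                    Vm_mV = sol$Vm,
                    n6_mol = n6, n7_mol = n7,
                    K_in_mM = sol$K, Na_in_mM = sol$Na, Cl_in_mM = sol$Cl)
  if (finite) {
    out$Li6_out_mM <- sol$out0_Li6
    out$Li7_out_mM <- sol$out0_Li7
  }
  class(out) <- c("li_trajectory", "data.frame")
  out
}

#' Dose response over external Li concentration
#'
#' One uptake simulation per concentration; the medium Li is split into
#' isotopes by the medium delta-7Li. Cell Li at `t_end` saturates with
#' concentration (Michaelis-Menten-like) while the cell delta falls when the
#' exchanger expresses its cooperative isotope selection.
#'
#' @inheritParams simulate_uptake
#' @param conc Vector of external Li concentrations (mM), within 0.1-200.
#' @param t_end Uptake duration (s).
#' @param ... Passed on to [simulate_uptake()].
#' @return Data frame with `Li_out_mM`, `Li_cell_mM`, `delta7Li_permil`.
#' @export
dose_response <- function(cell, mem, exch, conc = c(0.3, 1, 3, 10, 15, 30, 60, 120),
                          t_end = 60, ...) {
  if (any(conc < 0.1) || any(conc > 200))
    stop("'conc' outside the supported 0.1-200 mM range", call. = FALSE)
  rows <- lapply(conc, function(C) {
    cl <- cell; cl$Li_out <- C
    tr <- simulate_uptake(cl, mem, exch, times = c(0, t_end), ...)
    n <- nrow(tr)
    data.frame(Li_out_mM = C, Li_cell_mM = tr$Li_cell_mM[n],
               delta7Li_permil = tr$delta7Li_permil[n])
  })
  do.call(rbind, rows)
}

#' Scan over initial intracellular pH
#'
#' Uptake and fractionation are maximal at the most acidic pH, where the
#' proton-activated exchanger runs fastest; at alkaline pH the cell delta
#' approaches the channel-only value.
#'
#' @inheritParams dose_response
#' @param pH_list Initial intracellular pH values, within 5.5-7.8.
#' @return Data frame with `pH_in0`, `Li_cell_mM`, `delta7Li_permil`.
#' @export
ph_scan <- function(cell, mem, exch, pH_list = seq(5.8, 7.4, by = 0.2),
                    t_end = 60, ...) {
  if (any(pH_list < 5.5) || any(pH_list > 7.8))
    stop("'pH_list' outside the supported 5.5-7.8 range", call. = FALSE)
  rows <- lapply(pH_list, function(p) {
    cl <- cell; cl$pH_in0 <- p
    tr <- simulate_uptake(cl, mem, exch, times = c(0, t_end), ...)
    n <- nrow(tr)
    data.frame(pH_in0 = p, Li_cell_mM = tr$Li_cell_mM[n],
               delta7Li_permil = tr$delta7Li_permil[n])
  })
  do.call(rbind, rows)
}

#' Scan over external Na (competition with Li for the exchanger)
#'
#' @inheritParams dose_response
#' @param Na_list External Na concentrations (mM), non-negative.
#' @return Data frame with `Na_out_mM`, `Li_cell_mM`, `delta7Li_permil`.
#' @export
na_scan <- function(cell, mem, exch, Na_list = c(0, 10, 35, 70, 105, 140),
                    t_end = 60, ...) {
  if (any(Na_list < 0)) stop("'Na_list' must be non-negative", call. = FALSE)
  rows <- lapply(Na_list, function(Na) {
    cl <- cell; cl$Na_out <- Na
    tr <- simulate_uptake(cl, mem, exch, times = c(0, t_end), ...)
    n <- nrow(tr)
    data.frame(Na_out_mM = Na, Li_cell_mM = tr$Li_cell_mM[n],
               delta7Li_permil = tr$delta7Li_permil[n])
  })
  do.call(rbind, rows)
}
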