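# Whole-cell configuration: geometry, membrane electrical properties,
# buffering, medium composition.

#' Channel permeability set
#'
#' Permeabilities of the passive (channel) pathway. The two Li isotopes
#' carry distinct permeabilities, `P6 = rho_ch * P7`; the ratio `rho_ch` is
#' the channel-scale kinetic isotope effect and is a calibrated quantity
#' (see [calibrate_defaults()]), far below the gas-kinetic sqrt(m7/m6).
#' K+, Na+ and Cl- defaults are textbook resting-membrane values for a
#' fibroblast-like cell; only their ratios shape the potential dynamics.
#'
#' @param P7 7Li+ permeability (m/s).
#' @param rho_ch Isotope permeability ratio `P6/P7` (dimensionless, >= 1).
#' @param P_Na,P_K,P_Cl Permeabilities of the electrogenic background ions
#'   (m/s).
#' @param c_m Specific membrane capacitance (F/m^2).
#' @return A list of class `membrane_params`.
#' @export
membrane_params <- function(P7 = 5e-11, rho_ch = 1.004354, P_Na = 4e-10,
                            P_K = 1e-8, P_Cl = 4.5e-9, c_m = 0.01) {
  if (any(c(P7, P_Na, P_K, P_Cl) < 0) || c_m <= 0 || rho_ch <= 0)
    stop("permeabilities must be non-negative and c_m, rho_ch positive",
         call. = FALSE)
  structure(list(P7 = P7, rho_ch = rho_ch, P_Na = P_Na, P_K = P_K,
                 P_Cl = P_Cl, c_m = c_m), class = "membrane_params")
}

#' Whole-cell geometry, buffering and medium composition
#'
#' The default geometry is a sphere with the measured cell volume of
#' 2.6e3 um^3; the membrane area follows from the sphere unless given.
#' The acid-loaded initial state (ammonium-prepulse protocol) is represented
#' by `pH_in0 = 6`. The uptake medium is Li (split into isotopes by
#' `delta_out`) plus K and Cl with impermeant choline as the osmotic filler;
#' Na is zero unless a competition experiment adds it.
#'
#' @param V_cell_um3 Cell volume in cubic micrometres.
#' @param A_um2 Membrane area in square micrometres; default spherical.
#' @param beta_buffer Intrinsic buffering power (mM per pH unit).
#' @param pH_in0 Initial intracellular pH.
#' @param Vm0_mV Initial membrane potential (mV).
#' @param Li_out Total medium Li (mM).
#' @param delta_out delta-7Li of the medium (permil).
#' @param Na_out,K_out,Cl_out Medium concentrations (mM).
#' @param pH_out Medium pH.
#' @param K_in0,Na_in0,Cl_in0,Li_in0 Initial intracellular concentrations
#'   (mM).
#' @param medium_infinite If `TRUE` (default) the bath composition is held
#'   fixed; otherwise a finite bath of `bath_volume_um3` is depleted.
#' @param bath_volume_um3 Bath volume for the finite-medium mode.
#' @param temp_K Temperature (K).
#' @return A list of class `cell_config`.
#' @export
cell_config <- function(V_cell_um3 = 2.6e3, A_um2 = NULL, beta_buffer = 20,
                        pH_in0 = 6, Vm0_mV = -60, Li_out = 15,
                        delta_out = 15, Na_out = 0, K_out = 5, Cl_out = 150,
                        pH_out = 7.4, K_in0 = 140, Na_in0 = 10, Cl_in0 = 10,
                        Li_in0 = 0, medium_infinite = TRUE,
                        bath_volume_um3 = 1e12, temp_K = 310) {
  if (V_cell_um3 <= 0 || beta_buffer <= 0)
    stop("V_cell and beta_buffer must be positive", call. = FALSE)
  if (pH_in0 < 5 || pH_in0 > 8)
    stop("pH_in0 outside the supported 5-8 range", call. = FALSE)
  if (is.null(A_um2)) {
    r_um <- (3 * V_cell_um3 / (4 * pi))^(1 / 3)
    A_um2 <- 4 * pi * r_um^2
  }
  structure(list(V_cell_um3 = V_cell_um3, A_um2 = A_um2,
                 beta_buffer = beta_buffer, pH_in0 = pH_in0,
                 Vm0_mV = Vm0_mV, Li_out = Li_out, delta_out = delta_out,
                 Na_out = Na_out, K_out = K_out, Cl_out = Cl_out,
                 pH_out = pH_out, K_in0 = K_in0, Na_in0 = Na_in0,
                 Cl_in0 = Cl_in0, Li_in0 = Li_in0,
                 medium_infinite = medium_infinite,
                 bath_volume_um3 = bath_volume_um3, temp_K = temp_K),
            class = "cell_config")
}

#' Species table of the passive pathway for a given cell state
#'
#' @param mem A [membrane_params()] object.
#' @param C_in Named vector of intracellular concentrations (mM) with
#'   entries Li6, Li7, Na, K, Cl.
#' @param C_out Named vector of medium concentrations, same names.
#' @return Data frame with columns `name`, `z`, `P`, `C_in`, `C_out`.
#' @export
membrane_species <- function(mem, C_in, C_out) {
  data.frame(
    name = c("Li6", "Li7", "Na", "K", "Cl"),
    z = c(1, 1, 1, 1, -1),
    P = c(mem$rho_ch * mem$P7, mem$P7, mem$P_Na, mem$P_K, mem$P_Cl),
    C_in = as.numeric(C_in[c("Li6", "Li7", "Na", "K", "Cl")]),
    C_out = as.numeric(C_out[c("Li6", "Li7", "Na", "K", "Cl")])
  )
}

#' Read a run configuration from JSON or YAML
#'
#' Recognised top-level blocks: `cell`, `membrane`, `exchanger`; each holds
#' arguments for [cell_config()], [membrane_params()], [exchanger_params()].
#' Missing blocks fall back to defaults; `exchanger: null` (or an absent
#' block with `exchanger_null: true`) requests a channel-only run.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return List with `cell`, `membrane`, `exchanger` (possibly `NULL`).
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.(yaml|yml)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configurations",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cl <- do.call(cell_config, as.list(raw$cell %||% list()))
  mm <- do.call(membrane_params, as.list(raw$membrane %||% list()))
  ex <- if (isTRUE(raw$exchanger_null) ||
            (is.null(raw$exchanger) && "exchanger" %in% names(raw))) {
    NULL
  } else {
    args <- as.list(raw$exchanger %||% list())
    if (!is.null(args$mwc)) args$mwc <- as.list(args$mwc)
    do.call(exchanger_params, args)
  }
  list(cell = cl, membrane = mm, exchanger = ex)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
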