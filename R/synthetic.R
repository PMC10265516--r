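# Seeded generators of measurement-shaped tables: uptake time courses,
# dose responses and pH scans with replicate Gaussian noise at the magnitudes
# reported for the real measurements (SEM ~0.3 permil on delta, a few
# percent relative on Li content). Noise is applied to the observables only,
# never to the latent state.

#' Observation-noise specification
#'
#' @param sigma_delta Additive noise on delta-7Li (permil).
#' @param sigma_li_rel Multiplicative (relative) noise on Li content.
#' @param n_replicates Replicates per design point.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(sigma_delta = 0.3, sigma_li_rel = 0.03,
                       n_replicates = 3, seed = 1L) {
  if (sigma_delta < 0 || sigma_li_rel < 0)
    stop("noise magnitudes must be non-negative", call. = FALSE)
  if (n_replicates < 1)
    stop("need at least one replicate", call. = FALSE)
  structure(list(sigma_delta = sigma_delta, sigma_li_rel = sigma_li_rel,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "noise_spec")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.noisify <- function(truth, noise) {
  # truth: data frame with Li_cell_mM and delta7Li_permil plus design cols
  n <- nrow(truth)
  out <- do.call(rbind, lapply(seq_len(noise$n_replicates), function(r) {
    d <- truth
    d$replicate <- r
    d$Li_cell_mM <- d$Li_cell_mM *
      (1 + stats::rnorm(n, 0, noise$sigma_li_rel))
    d$delta7Li_permil <- d$delta7Li_permil +
      stats::rnorm(n, 0, noise$sigma_delta)
    d
  }))
  rownames(out) <- NULL
  out
}

#' Generate a noisy uptake time-course table
#'
#' Truth from [simulate_uptake()]; independent Gaussian noise per replicate
#' (additive in permil for delta, relative for Li), reproducible for a
#' given seed.
#'
#' @param cell,mem,exch Model configuration (see [simulate_uptake()]).
#' @param times Sampling times (s).
#' @param noise A [noise_spec()].
#' @param ... Passed to [simulate_uptake()].
#' @return Data frame with `t_s`, `replicate`, `Li_cell_mM`,
#'   `delta7Li_permil`.
#' @export
generate_kinetics <- function(cell = cell_config(), mem = membrane_params(),
                              exch = exchanger_params(),
                              times = c(5, 10, 20, 30, 60),
                              noise = noise_spec(), ...) {
  tr <- simulate_uptake(cell, mem, exch, times = c(0, times), ...)
  truth <- data.frame(t_s = times,
                      Li_cell_mM = tr$Li_cell_mM[-1],
                      delta7Li_permil = tr$delta7Li_permil[-1])
  .with_seed(noise$seed, .noisify(truth, noise))
}

#' Generate a noisy dose-response table
#'
#' @inheritParams generate_kinetics
#' @param conc External Li concentrations (mM).
#' @param t_end Uptake duration (s).
#' @return Data frame with `Li_out_mM`, `replicate`, `Li_cell_mM`,
#'   `delta7Li_permil`.
#' @export
generate_dose_response <- function(cell = cell_config(),
                                   mem = membrane_params(),
                                   exch = exchanger_params(),
                                   conc = c(0.3, 1, 3, 10, 15, 30, 60, 120),
                                   t_end = 60, noise = noise_spec(), ...) {
  truth <- dose_response(cell, mem, exch, conc = conc, t_end = t_end, ...)
  .with_seed(noise$seed, .noisify(truth, noise))
}

#' Generate a noisy pH-scan table
#'
#' @inheritParams generate_dose_response
#' @param pH_list Initial intracellular pH values.
#' @return Data frame with `pH_in0`, `replicate`, `Li_cell_mM`,
#'   `delta7Li_permil`.
#' @export
generate_ph_scan <- function(cell = cell_config(), mem = membrane_params(),
                             exch = exchanger_params(),
                             pH_list = seq(5.8, 7.4, by = 0.2),
                             t_end = 60, noise = noise_spec(), ...) {
  truth <- ph_scan(cell, mem, exch, pH_list = pH_list, t_end = t_end, ...)
  .with_seed(noise$seed, .noisify(truth, noise))
}
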