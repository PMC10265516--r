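# Shared fixtures: the shipped (calibrated) defaults and a few cheap
# configurations reused across test files.

default_cell <- function(...) cell_config(...)
default_mem <- function(...) membrane_params(...)
default_exch <- function(...) exchanger_params(...)

# exchanger with every isotope dial switched off
null_kie_exch <- function(...) {
  exchanger_params(alpha_kie = 1, gamma_on = 1, gamma_off = 1, ...)
}

# per-dimer flux delta at a given medium composition and intracellular pH
flux_delta_at <- function(exch, C_mM, pH_in, delta_out = 15, Na = 0) {
  s <- split_li(C_mM, delta_out)
  env <- exchanger_env(s$C6, s$C7, C_Na = Na, H_in = 10^-pH_in)
  r <- steady_state_flux(exch, env)
  flux_delta(r$J6, r$J7)
}
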