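# Dimeric exchanger master equation: MWC activation, state space, generator
# structure, stationary fluxes, isotope selection, inhibition, and the
# stochastic cross-check.

test_that("MWC activation has the closed-form limits and midpoint of the printed constants", {
  m <- mwc_constants()
  expect_equal(mwc_activation(0), 1 / (1 + m$L0), tolerance = 1e-12)
  expect_equal(mwc_activation(1), 1 / (1 + m$L0 * (m$K_h / m$K_l)^2),
               tolerance = 1e-6)  # x >> K_l is effectively the acid limit
  expect_equal(1 / (1 + m$L0), 1.137e-3, tolerance = 1e-3)
  expect_equal(1 / (1 + m$L0 * (m$K_h / m$K_l)^2), 0.981, tolerance = 1e-3)

  H <- 10^seq(-8.5, -4.5, length.out = 60)
  expect_true(all(diff(mwc_activation(H)) > 0))

  # half-activation between the two bounds sits near pH 6.2-6.3
  mid <- mwc_midpoint_ph()
  expect_gt(mid, 6.2)
  expect_lt(mid, 6.3)
})

test_that("the dimer state space enumerates 50 states with label-swap symmetry", {
  st <- enumerate_dimer_states()
  expect_identical(nrow(st), 50L)
  expect_identical(anyDuplicated(st[, c("a", "b", "senior")]), 0L)
  # swapping protomer labels and the seniority flag maps the set onto itself
  swapped <- data.frame(a = st$b, b = st$a,
                        senior = ifelse(st$senior == "A", "B", "A"))
  key <- function(d) sort(paste(d$a, d$b, d$senior))
  expect_identical(key(swapped), key(st[, 1:3]))
})

test_that("the generator is a proper rate matrix and matches a hand-built reduced scheme", {
  ex <- default_exch()
  env <- exchanger_env(1.1, 13.9, 20, H_in = 1e-6)
  Q <- build_generator(ex, env)
  expect_equal(max(abs(colSums(Q))), 0, tolerance = 1e-10)
  off <- Q; diag(off) <- 0
  expect_true(all(off >= 0))

  # independent hand construction for the single-isotope, Na-free case:
  # protomer states E/H/L7 only, seniority rules written out directly
  env7 <- exchanger_env(0, 14, 0, H_in = 1e-6)
  Q2 <- build_generator(ex, env7)
  f <- mwc_activation(1e-6, ex$mwc)
  g <- 1e-6 / (1e-6 + ex$K_prot)
  kon <- ex$k_bind * 14 / ex$K_Li
  koff <- ex$k_bind
  kt <- ex$k_t7 * f
  krec <- ex$k_rec * g * f
  code <- c(E = 1L, H = 2L, L = 4L)  # L7 is the 4th protomer state
  idx <- function(a, b, s) (code[[a]] - 1L) * 10L + (code[[b]] - 1L) * 2L +
    (if (s == "A") 1L else 2L)
  states <- expand.grid(a = names(code), b = names(code), s = c("A", "B"),
                        stringsAsFactors = FALSE)
  H2 <- matrix(0, 50, 50)
  for (k in seq_len(nrow(states))) {
    a <- states$a[k]; b <- states$b[k]; s <- states$s[k]
    i <- idx(a, b, s)
    pst <- c(a, b); names(pst) <- c("A", "B")
    for (p in c("A", "B")) {
      q <- setdiff(c("A", "B"), p)
      set <- function(pp, v) { x <- pst; x[[pp]] <- v; x }
      if (pst[[p]] == "E") {
        x <- set(p, "H"); H2[idx(x[["A"]], x[["B"]], s), i] <-
          H2[idx(x[["A"]], x[["B"]], s), i] + krec
      } else if (pst[[p]] == "H") {
        x <- set(p, "L")
        s2 <- if (pst[[q]] != "L") p else s
        H2[idx(x[["A"]], x[["B"]], s2), i] <-
          H2[idx(x[["A"]], x[["B"]], s2), i] + kon
      } else {
        x <- set(p, "H")
        s2 <- if (s == p) q else s
        H2[idx(x[["A"]], x[["B"]], s2), i] <-
          H2[idx(x[["A"]], x[["B"]], s2), i] + koff
        if (s == p && pst[[q]] == "L") {
          x <- set(p, "E")
          H2[idx(x[["A"]], x[["B"]], q), i] <-
            H2[idx(x[["A"]], x[["B"]], q), i] + kt
        }
      }
    }
  }
  diag(H2) <- diag(H2) - colSums(H2)
  live <- sort(unique(unlist(lapply(seq_len(nrow(states)), function(k)
    idx(states$a[k], states$b[k], states$s[k])))))
  expect_equal(Q2[live, live], H2[live, live], tolerance = 1e-12)
})

test_that("the generator is symmetric under isotope-label swap when all KIEs are off", {
  ex <- null_kie_exch()
  env <- exchanger_env(7, 7, 0, H_in = 1e-6)  # equal abundances
  Q <- build_generator(ex, env)
  # permutation exchanging L6 and L7 on both protomers
  st <- expand.grid(s = 1:2, b = 1:5, a = 1:5)
  swap <- function(x) ifelse(x == 3L, 4L, ifelse(x == 4L, 3L, x))
  perm <- (swap(st$a) - 1L) * 10L + (swap(st$b) - 1L) * 2L + st$s
  orig <- (st$a - 1L) * 10L + (st$b - 1L) * 2L + st$s
  P <- matrix(0, 50, 50); P[cbind(perm, orig)] <- 1
  expect_equal(P %*% Q %*% t(P), Q, tolerance = 1e-12)
})

test_that("stationary fluxes solve the master equation and respect the null cases", {
  ex <- default_exch()
  env <- exchanger_env(1.1, 13.9, 30, H_in = 1e-6)
  r <- steady_state_flux(ex, env)
  expect_lt(r$residual, 1e-12 * ex$k_bind * 50)
  expect_true(all(r$pi >= 0))
  expect_equal(sum(r$pi), 1, tolerance = 1e-12)
  expect_equal(r$J_H, r$J6 + r$J7 + r$J_Na, tolerance = 1e-12)

  # no sodium outside -> Na-loaded states carry no stationary mass
  env0 <- exchanger_env(1.1, 13.9, 0, H_in = 1e-6)
  r0 <- steady_state_flux(ex, env0)
  st <- enumerate_dimer_states()
  expect_equal(sum(r0$pi[st$a == "Na" | st$b == "Na"]), 0, tolerance = 1e-14)
  expect_identical(r0$J_Na, 0)

  # no-KIE null: transported flux carries exactly the medium composition
  exn <- null_kie_exch()
  for (C in c(0.5, 15, 120)) {
    d <- flux_delta_at(exn, C, pH_in = 6)
    expect_lt(abs(d - 15), 1e-9)
  }

  # saturation: flux flattens in [Li] and increases with acidity
  sat1 <- steady_state_flux(ex, exchanger_env(7.5e3, 9.25e4, 0, 1e-6))
  sat2 <- steady_state_flux(ex, exchanger_env(1.5e4, 1.85e5, 0, 1e-6))
  expect_equal(sat1$J6 + sat1$J7, sat2$J6 + sat2$J7, tolerance = 5e-3)
  acid <- steady_state_flux(ex, exchanger_env(7.5e3, 9.25e4, 0, 1e-5))
  expect_gt(acid$J6 + acid$J7, sat1$J6 + sat1$J7)
})

test_that("flux delta decreases with external Li (cooperative selection) at the calibrated dials", {
  ex <- default_exch()
  lad <- vapply(c(0.3, 1, 3, 10, 30, 60, 120), function(C)
    flux_delta_at(ex, C, pH_in = 6), numeric(1))
  expect_true(all(diff(lad) < 0))
  expect_lt(lad[7], lad[1] - 1)
})

test_that("sodium competes with lithium without reversing the isotope preference", {
  ex <- default_exch()
  Na <- c(0, 35, 70, 140)
  res <- vapply(Na, function(nn) {
    s <- split_li(15, 15)
    r <- steady_state_flux(ex, exchanger_env(s$C6, s$C7, nn, 1e-6))
    c(J = r$J6 + r$J7, d = flux_delta(r$J6, r$J7))
  }, numeric(2))
  expect_true(all(diff(res["J", ]) < 0))          # Li flux falls with Na
  # the isotope composition of the residual Li flux "evolves little"
  expect_lt(abs(res["d", 4] - res["d", 1]), 2)
})

test_that("a specific inhibitor scales the flux and leaves the flux delta untouched", {
  ex <- default_exch()
  env <- exchanger_env(1.1, 13.9, 10, H_in = 1e-6)
  r0 <- steady_state_flux(ex, env)
  r5 <- steady_state_flux(apply_inhibitor(ex, 0.5), env)
  r1 <- steady_state_flux(apply_inhibitor(ex, 1), env)
  expect_equal(r5$J6, r0$J6 / 2, tolerance = 1e-12)
  expect_equal(r5$J7, r0$J7 / 2, tolerance = 1e-12)
  expect_lt(abs(flux_delta(r5$J6, r5$J7) - flux_delta(r0$J6, r0$J7)), 1e-9)
  expect_identical(r1$J6 + r1$J7 + r1$J_Na, 0)
  expect_identical(steady_state_flux(apply_inhibitor(ex, 0), env)$J6, r0$J6)
  expect_error(apply_inhibitor(ex, 1.2), "0, 1")
  expect_error(apply_inhibitor(ex, -0.1), "0, 1")
})

test_that("the stochastic simulation reproduces the stationary fluxes", {
  ex <- default_exch()
  s <- split_li(15, 15)
  env <- exchanger_env(s$C6, s$C7, 0, H_in = 1e-6)
  det <- steady_state_flux(ex, env)
  ssa <- gillespie_flux(ex, env, n_events = 2e5, seed = 99)
  expect_lt(abs(ssa$J6 - det$J6), 3 * ssa$se6)
  expect_lt(abs(ssa$J7 - det$J7), 3 * ssa$se7)
})
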