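test_that("speciation with no complexes returns free totals", {
  m <- eq_model("Cu", complexes = list())
  s <- solve_speciation(m, c(Cu = 10e-6))
  expect_equal(s$free_Cu, 10e-6)
})

test_that("Cu/BCS speciation matches the brute-force oracle", {
  m <- eq_model(c("Cu", "BCS"),
                list(CuBCS2 = list(stoich = c(Cu = 1, BCS = 2),
                                   log_beta = 19.8)))
  tot <- c(Cu = 22e-6, BCS = 60e-6)
  s <- solve_speciation(m, tot)
  ref <- oracle_speciation_2comp(m$stoich, m$log_beta, tot)
  expect_equal(s$free_Cu, ref$free[1], tolerance = 1e-8)
  expect_equal(s$free_BCS, ref$free[2], tolerance = 1e-8)
  # essentially all Cu is chelated and ~16 uM BCS remains free
  expect_gt(s$CuBCS2 / tot["Cu"], 0.999)
  expect_equal(s$free_BCS, 16e-6, tolerance = 1e-3)
})

test_that("protein site competes with the chelator per mass action", {
  m <- eq_model(c("Cu", "BCS", "P"),
                list(CuBCS2 = list(stoich = c(Cu = 1, BCS = 2), log_beta = 19.8),
                     CuP    = list(stoich = c(Cu = 1, P = 1),   log_beta = 16.6)))
  s <- solve_speciation(m, c(Cu = 22e-6, BCS = 60e-6, P = 30e-6))
  lhs <- s$CuP / s$CuBCS2
  rhs <- 10^16.6 * s$free_P / (10^19.8 * s$free_BCS^2)
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("mass is conserved on randomized models and 2-component systems match the oracle", {
  withr::with_seed(7, {
    for (rep in 1:25) {
      ncomp <- sample(1:3, 1)
      ncplx <- sample(1:4, 1)
      comps <- paste0("X", seq_len(ncomp))
      cplxs <- list()
      for (i in seq_len(ncplx)) {
        st <- stats::setNames(sample(0:2, ncomp, replace = TRUE), comps)
        if (all(st == 0)) st[sample(ncomp, 1)] <- 1
        cplxs[[paste0("C", i)]] <-
          list(stoich = st, log_beta = sum(st) * stats::runif(1, 2, 6))
      }
      m <- eq_model(comps, cplxs)
      totals <- stats::setNames(10^stats::runif(ncomp, -6, -3), comps)
      s <- solve_speciation(m, totals)
      # reconstruct totals: free + stoichiometry-weighted complexes
      for (j in seq_len(ncomp)) {
        recon <- s[[paste0("free_", comps[j])]] +
          sum(m$stoich[, j] * as.numeric(s[1, ncomp + seq_len(ncplx)]))
        expect_lt(abs(recon - totals[j]) / totals[j], 1e-9)
      }
      if (ncomp == 2) {
        ref <- oracle_speciation_2comp(m$stoich, m$log_beta, totals)
        expect_equal(s$free_X1, ref$free[1], tolerance = 1e-7)
        expect_equal(s$free_X2, ref$free[2], tolerance = 1e-7)
      }
    }
  })
})

test_that("speciation is invariant under a concentration unit change", {
  m <- eq_model(c("Cu", "BCS"),
                list(CuBCS2 = list(stoich = c(Cu = 1, BCS = 2),
                                   log_beta = 19.8)))
  s1 <- solve_speciation(m, c(Cu = 22e-6, BCS = 60e-6))
  # M -> mM: numbers x1e3, beta scaled by f^(1 - sum(stoich))
  f <- 1e3
  m2 <- eq_model(c("Cu", "BCS"),
                 list(CuBCS2 = list(stoich = c(Cu = 1, BCS = 2),
                                    log_beta = 19.8 + (1 - 3) * log10(f))))
  s2 <- solve_speciation(m2, c(Cu = 22e-6 * f, BCS = 60e-6 * f))
  expect_equal(s2$free_Cu / (22e-6 * f), s1$free_Cu / 22e-6, tolerance = 1e-9)
  expect_equal(s2$CuBCS2 / (22e-6 * f), s1$CuBCS2 / 22e-6, tolerance = 1e-9)
})

test_that("simulated competition signal is monotone in the competing protein", {
  m <- eq_model(c("Cu", "BCS", "P"),
                list(CuBCS2 = list(stoich = c(Cu = 1, BCS = 2), log_beta = 19.8),
                     CuP    = list(stoich = c(Cu = 1, P = 1),   log_beta = 16.6)))
  tot <- tibble::tibble(Cu = 22e-6, BCS = 60e-6,
                        P = seq(0, 55e-6, length.out = 12))
  sim <- simulate_titration(m, tot, c(CuBCS2 = 13000), baseline = 0.01)
  expect_true(all(diff(sim$signal) <= 0))
  # zero response -> flat baseline
  flat <- simulate_titration(m, tot, c(CuBCS2 = 0), baseline = 0.25)
  expect_equal(flat$signal, rep(0.25, 12))
  # unknown species in the response map errors
  expect_error(simulate_titration(m, tot, c(Nope = 1)), "not species")
})

test_that("Zn/mf2 simulated signal is non-decreasing in Zn", {
  zn <- gen_competition_titration(12, preset = "zn_mf2", noise = noise_spec(0))
  expect_true(all(diff(zn$signal) >= -1e-12))
})

test_that("global fit recovers the constant exactly from noiseless data", {
  tit <- gen_competition_titration(16.6, noise = noise_spec(0))
  m <- attr(tit, "model")
  m$log_beta[2] <- 15.5  # start away from the truth
  fit <- fit_global_affinity(tit, m, free = "CuP", observed = "CuBCS2",
                             bound_check = FALSE)
  expect_equal(unname(fit$par), 16.6, tolerance = 1e-6)
  expect_false(fit$lower_bound_only)
  expect_length(fit$residuals, nrow(tit))
})

test_that("global fit errors when underdetermined", {
  tit <- gen_competition_titration(16.6, n_points = 2, noise = noise_spec(0))
  m <- attr(tit, "model")
  expect_error(fit_global_affinity(tit, m, free = "CuP", observed = "CuBCS2"),
               "underdetermined")
})

test_that("stoichiometric Zn binding yields a lower bound, not an estimate", {
  zn <- gen_competition_titration(12, preset = "zn_mf2",
                                  noise = noise_spec(0.01, seed = 11))
  m <- attr(zn, "model")
  m$log_beta[2] <- 10
  fit <- fit_global_affinity(zn, m, free = "ZnP", observed = "Znmf2",
                             scan_width = 8)
  expect_true(fit$lower_bound_only)
  expect_gte(fit$bound_log10, 9)
})

test_that("tidy/glance on affinity fits are well-formed", {
  tit <- gen_competition_titration(16.6, noise = noise_spec(0.01, seed = 2))
  fit <- fit_global_affinity(tit, attr(tit, "model"), free = "CuP",
                             observed = "CuBCS2", bound_check = FALSE)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "conf.low", "conf.high",
                     "lower_bound_only", "bound_log10"))
  expect_true(td$conf.low <= td$estimate && td$estimate <= td$conf.high)
  expect_equal(glance(fit)$n_experiments, 3)
})

test_that("breakpoint detection finds ideal and noisy equivalence points", {
  # ideal bilinear break at 1.0 equivalent
  x <- seq(0, 60e-6, length.out = 13)
  ideal <- tibble::tibble(titrant = x, signal = pmin(x, 30e-6) * 2e4 + 0.01)
  fit <- detect_stoichiometry_breakpoint(ideal, protein_conc = 30e-6)
  expect_equal(fit$equivalence, 1.0, tolerance = 1e-6)

  # tight-binding Cu titration, 2% noise: 1 Cu per protomer recovered
  withr::with_seed(5, {
    y <- pmin(x, 30e-6) * 2e4 + 0.01
    noisy <- tibble::tibble(titrant = x,
                            signal = y + stats::rnorm(13, 0, 0.02 * max(y)))
  })
  fitn <- detect_stoichiometry_breakpoint(noisy, protein_conc = 30e-6)
  expect_equal(fitn$equivalence, 1.0, tolerance = 0.1)
  expect_true(fitn$ci_lower <= fitn$equivalence &&
                fitn$equivalence <= fitn$ci_upper)

  # 1 Zn per dimer at 12 uM dimer
  xz <- seq(0, 25e-6, length.out = 11)
  zn <- tibble::tibble(titrant = xz, signal = pmin(xz, 12e-6) * 1.5e4)
  fz <- detect_stoichiometry_breakpoint(zn, protein_conc = 12e-6)
  expect_equal(fz$equivalence, 1.0, tolerance = 1e-6)

  # monotone ramp with no plateau is rejected
  ramp <- tibble::tibble(titrant = x, signal = x * 2e4)
  expect_error(detect_stoichiometry_breakpoint(ramp, protein_conc = 30e-6),
               "plateau")
})
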