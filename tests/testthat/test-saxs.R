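test_that("Guinier fit is exact on ideal Guinier data", {
  q <- seq(0.002, 0.08, by = 0.001)
  prof <- tibble::tibble(q = q, I = 100 * exp(-q^2 * 24.3^2 / 3))
  g <- guinier_fit(prof)
  expect_equal(g$rg, 24.3, tolerance = 1e-6)
  expect_equal(g$i0, 100, tolerance = 1e-6)
})

test_that("Guinier Rg of a sphere equals sqrt(3/5) R within 1%", {
  prof <- gen_saxs_profile(radius = 31.4, noise = noise_spec(0))
  g <- guinier_fit(prof)
  expect_equal(g$rg, sqrt(3 / 5) * 31.4, tolerance = 0.01)
  expect_false(g$nonlinearity_warning)
})

test_that("a monomer/tetramer mixture triggers the heterogeneity warning", {
  # tetramer of 4x the monomer volume: radius x 4^(1/3)
  mix <- gen_saxs_profile(
    mixture = tibble::tibble(radius = c(25, 25 * 4^(1 / 3)),
                             fraction = c(0.7, 0.3)),
    noise = noise_spec(0))
  expect_warning(g <- guinier_fit(mix), "heterogeneous")
  expect_true(g$nonlinearity_warning)
})

test_that("Kratky transform shows the expected limiting shapes", {
  sph <- gen_saxs_profile(radius = 25, noise = noise_spec(0))
  k <- kratky_transform(sph)
  expect_named(k, c("q", "q2I"))
  peak <- which.max(k$q2I)
  expect_gt(peak, 5)                     # rises to a maximum ...
  expect_lt(peak, nrow(k))               # ... inside the range
  expect_lt(mean(k$q2I[k$q > 0.4]), 0.2 * max(k$q2I))  # then decays

  # I ~ 1/q^2 gives a plateau
  q <- seq(0.01, 0.5, by = 0.005)
  chain <- tibble::tibble(q = q, I = 1 / q^2)
  kc <- kratky_transform(chain)
  expect_equal(stats::sd(kc$q2I), 0, tolerance = 1e-12)

  # flat I gives a monotone increase
  flat <- kratky_transform(tibble::tibble(q = q, I = 1))
  expect_true(all(diff(flat$q2I) > 0))
})

test_that("IFT round trip recovers the sphere p(r) and its Rg", {
  prof <- gen_saxs_profile(radius = 38, noise = noise_spec(0))
  pd <- ift_pr(prof, dmax = 76)
  expect_equal(pd$pr$p[1], 0)
  expect_equal(pd$pr$p[nrow(pd$pr)], 0)
  truth <- sphere_pr(38, n = nrow(pd$pr))
  sc <- trapz(pd$pr$r, pd$pr$p)  # compare shapes at unit area
  nrms <- sqrt(mean((pd$pr$p / sc - truth$p)^2)) / max(truth$p)
  expect_lt(nrms, 0.02)
  expect_equal(pd$rg, sqrt(3 / 5) * 38, tolerance = 0.01)
  expect_lt(pd$negativity, 0.01)

  # 2% noise: round trip still within 5%
  profn <- gen_saxs_profile(radius = 38, noise = noise_spec(0.02, seed = 9))
  pdn <- ift_pr(profn, dmax = 76)
  scn <- trapz(pdn$pr$r, pdn$pr$p)
  nrmsn <- sqrt(mean((pdn$pr$p / scn - truth$p)^2)) / max(truth$p)
  expect_lt(nrmsn, 0.05)
})

test_that("overestimated Dmax leaves a negligible p(r) tail", {
  prof <- gen_saxs_profile(radius = 38, noise = noise_spec(0))
  pd <- ift_pr(prof, dmax = 76 * 1.2)
  tail_area <- trapz(pd$pr$r[pd$pr$r > 76], abs(pd$pr$p[pd$pr$r > 76]))
  expect_lt(tail_area / trapz(pd$pr$r, abs(pd$pr$p)), 0.03)
})

test_that("real-space and Guinier Rg agree on globular bodies", {
  for (R in c(20, 30, 38)) {
    prof <- gen_saxs_profile(radius = R, noise = noise_spec(0))
    g <- guinier_fit(prof)
    pd <- ift_pr(prof, dmax = 2 * R)
    expect_lt(abs(pd$rg - g$rg) / g$rg, 0.05)
  }
})

test_that("an implausibly small Dmax warns", {
  prof <- gen_saxs_profile(radius = 38, noise = noise_spec(0))
  expect_warning(ift_pr(prof, dmax = 40, rg_guinier = 29.4), "implausibly")
})

test_that("Dmax is estimated at twice the sphere radius", {
  p38 <- gen_saxs_profile(radius = 38, noise = noise_spec(0))
  expect_equal(estimate_dmax(p38)$dmax, 76, tolerance = 4 / 76)
  p20 <- gen_saxs_profile(radius = 20, noise = noise_spec(0))
  expect_equal(estimate_dmax(p20)$dmax, 40, tolerance = 2 / 40)
})

test_that("featureless input is flagged low-confidence", {
  withr::with_seed(7, {
    wn <- tibble::tibble(q = seq(0.005, 0.5, by = 0.0025),
                         I = abs(stats::rnorm(199, 1, 0.3)))
  })
  expect_true(estimate_dmax(wn)$low_confidence)
})

test_that("Porod molecular weight matches the sphere volume", {
  prof <- gen_saxs_profile(radius = 20, noise = noise_spec(0))
  pm <- porod_mw(prof)
  v_sphere <- 4 / 3 * pi * 20^3
  expect_equal(pm$porod_volume_A3, v_sphere, tolerance = 0.1)
  expect_equal(pm$mw_kda, v_sphere / 1.66 / 1000, tolerance = 0.1)

  # intensity scale invariance
  prof2 <- prof
  prof2$I <- prof2$I * 2
  prof2$sigma <- prof2$sigma * 2
  pm2 <- porod_mw(prof2)
  expect_equal(pm2$mw_kda, pm$mw_kda, tolerance = 1e-6)

  # insufficient reach errors with the required coverage named
  short <- prof[prof$q * pm$rg <= 3, ]
  expect_error(porod_mw(short), "q_max \\* Rg")
})

test_that("MW discrepancy is simple percent arithmetic", {
  expect_equal(mw_discrepancy(26.0, 30.9), 15.9)
  expect_equal(mw_discrepancy(24.7, 30.9), 20.1)
  expect_equal(mw_discrepancy(30.9, 30.9), 0.0)
  expect_error(mw_discrepancy(-1, 2), "positive")
})

test_that("SAXS dat files round-trip through the reader", {
  prof <- gen_saxs_profile(radius = 20, noise = noise_spec(0))
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# synthetic sphere profile",
               sprintf("%.12g %.12g %.12g", prof$q, prof$I, prof$sigma)), f)
  back <- read_saxs_dat(f)
  expect_equal(back$q, prof$q)
  expect_equal(back$I, prof$I)
  # nm^-1 data are auto-converted
  f2 <- withr::local_tempfile(fileext = ".dat")
  writeLines(sprintf("%.12g %.12g", prof$q * 10, prof$I), f2)
  expect_message(back2 <- read_saxs_dat(f2), "1/nm")
  expect_equal(back2$q, prof$q, tolerance = 1e-9)
})
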