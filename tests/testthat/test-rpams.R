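# Reference [M+H]+ values cross-checked against an independent proteomics
# mass calculator before freezing.
test_that("peptide [M+H]+ masses reproduce the reference digest table", {
  expect_equal(round(peptide_mh_mass("DKVCSRRIRNLLA"), 2), 1543.88)
  expect_equal(round(peptide_mh_mass("SSAVTEVRCNCM"), 2), 1299.55)
  expect_equal(peptide_mh_mass("G"), 76.039, tolerance = 1e-5)
  expect_error(peptide_mh_mass("ABZ"), "unknown residue")
})

test_that("NEM-modified peptide masses reproduce the reference table", {
  # protiated species are exact at two decimals
  expect_equal(round(modified_peptide_masses("DKVCSRRIRNLLA", "h5")$mass, 2),
               1668.93)
  expect_equal(round(modified_peptide_masses("SSAVTEVRCNCM",
                                             c("h5", "h5"))$mass, 2),
               1549.64)
  # deuterated species agree within 0.02 Da (mass-convention gap for d5)
  expect_lt(abs(modified_peptide_masses("DKVCSRRIRNLLA", "d5")$mass - 1673.97),
            0.02)
  expect_lt(abs(modified_peptide_masses("SSAVTEVRCNCM",
                                        c("d5", "h5"))$mass - 1554.69), 0.02)
  expect_lt(abs(modified_peptide_masses("SSAVTEVRCNCM",
                                        c("d5", "d5"))$mass - 1559.73), 0.03)
  expect_error(modified_peptide_masses("SSAVTEVRCNCM", "d5"), "cysteines")
})

test_that("the isotope-coded adduct pair differs by a nominal 5 Da", {
  ad <- adduct_library()
  shift <- ad$mass[ad$adduct == "d5_nem"] - ad$mass[ad$adduct == "h5_nem"]
  expect_equal(shift, 5.03138, tolerance = 1e-5)
  expect_equal(round(shift, 1), 5.0)
})

test_that("adducts are rejected on non-cysteine residues", {
  expect_error(
    peptide_mh_mass("DKVCSRRIRNLLA",
                    tibble::tibble(position = 1, adduct = "h5_nem")),
    "non-cysteine")
})

test_that("fragment ions match residue-sum references and carry modifications", {
  f <- fragment_ion_masses("SSAVTEVRCNCM")
  y1 <- f$mz[f$series == "y" & f$index == 1]
  b2 <- f$mz[f$series == "b" & f$index == 2]
  expect_equal(y1, 150.058, tolerance = 1e-4)
  expect_equal(b2, 175.071, tolerance = 1e-4)
  expect_error(fragment_ion_masses("SSAV", max_charge = 0), "charge")

  # a C-terminal-side adduct appears in y ions covering the site, not b2
  mods <- tibble::tibble(position = 11, adduct = "d5_nem")
  fm <- fragment_ion_masses("SSAVTEVRCNCM", modifications = mods)
  expect_equal(fm$mz[fm$series == "y" & fm$index == 2] -
                 f$mz[f$series == "y" & f$index == 2],
               adduct_library()$mass[2], tolerance = 1e-9)
  expect_equal(fm$mz[fm$series == "b" & fm$index == 2], b2)
})

test_that("b/y complementarity holds for 1000 random peptides", {
  seqs <- random_peptides(1000, seed = 42)
  for (s in seqs) {
    n <- nchar(s)
    i <- max(1, n %/% 2)
    f <- fragment_ion_masses(s)
    bi <- f$mz[f$series == "b" & f$index == i]
    yni <- f$mz[f$series == "y" & f$index == n - i]
    expect_equal(bi + yni, peptide_mh_mass(s) + 1.007276, tolerance = 1e-9)
  }
})

test_that("alkylation forward model fractions are coherent", {
  m <- alkylation_forward_model(c(0, 15, 60, 600), k = c(0.005, 0.02))
  expect_equal(m$f_h5h5[1], 1)  # t = 0: nothing deuterated
  expect_equal(rowSums(m[-1]), rep(1, 4), tolerance = 1e-12)
  m_inf <- alkylation_forward_model(1e6, k = c(0.005, 0.02))
  expect_equal(m_inf$f_d5d5, 1, tolerance = 1e-8)
  # the faster site always carries at least as much deuterium
  tt <- seq(0, 600, by = 5)
  p128 <- 1 - exp(-0.005 * tt)
  p130 <- 1 - exp(-0.02 * tt)
  expect_true(all(p130 >= p128))
  expect_error(alkylation_forward_model(-1, 0.1), "non-negative")
})

test_that("alkylation rates are recovered from time courses", {
  # zero noise: exact
  tc0 <- gen_alkylation_timecourse(k = c(0.005, 0.02), noise = noise_spec(0))
  f0 <- fit_alkylation_rates(tc0)
  expect_equal(f0$k, c(0.005, 0.02), tolerance = 1e-6)

  # 3% intensity noise: both rates within 20%
  tc <- gen_alkylation_timecourse(k = c(0.005, 0.02),
                                  noise = noise_spec(0.03, seed = 8))
  f1 <- fit_alkylation_rates(tc)
  expect_lt(max(abs(f1$k / c(0.005, 0.02) - 1)), 0.2)

  # identical apo/holo data give unit protection factors
  expect_equal(protection_factor(f0$k, f0$k), c(1, 1))
  expect_equal(protection_factor(0.01, 0), Inf)

  # fully quenched site: k = 0 with a finite upper bound
  tq <- tibble::tibble(t_s = c(15, 30, 60, 240, 600), I_d5 = 0, I_h5 = 1)
  fq <- fit_alkylation_rates(tq)
  expect_equal(fq$k, 0)
  expect_true(is.finite(fq$k_upper_bound))
  expect_gt(fq$k_upper_bound, 0)

  # an all-zero time point is excluded with a warning
  tcz <- tc0
  tcz[3, c("I_d5d5", "I_d5h5", "I_h5h5")] <- 0
  expect_warning(fz <- fit_alkylation_rates(tcz), "all-zero")
  expect_equal(nrow(fz$data), nrow(tc0) - 1)
})

test_that("site occupancy is partitioned from diagnostic fragments", {
  dmap <- tibble::tibble(ion = c("y2", "y3", "b9", "b10"),
                         site = c("C130", "C130", "C128", "C128"))
  # all d5 intensity on the C130 diagnostics
  all130 <- tibble::tibble(
    ion = c("y2", "y3", "b9", "b10"), label = "d5",
    intensity = c(50, 50, 0, 0))
  occ <- site_occupancy_from_fragments(all130, dmap)
  expect_equal(occ$partition[occ$site == "C130"], 1.0)

  # equal partition
  eq <- tidyr::crossing(ion = dmap$ion, label = c("d5", "h5")) |>
    dplyr::mutate(intensity = 25)
  occ_eq <- site_occupancy_from_fragments(eq, dmap)
  expect_equal(occ_eq$partition, c(0.5, 0.5))

  # 70/30 partition with 5% noise recovered within 5 points
  withr::with_seed(21, {
    part <- c(C128 = 0.3, C130 = 0.7)
    tab <- tidyr::crossing(ion = dmap$ion, label = c("d5", "h5")) |>
      dplyr::left_join(dmap, by = "ion") |>
      dplyr::mutate(
        frac = ifelse(label == "d5", part[site], 1 - part[site]),
        intensity = pmax(100 * frac * (1 + stats::rnorm(8, 0, 0.05)), 0)) |>
      dplyr::select(ion, label, intensity)
  })
  occ_n <- site_occupancy_from_fragments(tab, dmap)
  expect_lt(abs(occ_n$partition[occ_n$site == "C130"] - 0.7), 0.05)

  expect_error(
    site_occupancy_from_fragments(
      tibble::tibble(ion = "y9", label = "d5", intensity = 1), dmap),
    "undefined")
})
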