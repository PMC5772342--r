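#' Synthetic chelator-competition titrations
#'
#' Generates competition titrations with the package's forward model
#' ([simulate_titration()]) plus Gaussian noise. Two presets reproduce the
#' canonical experimental designs for a dimeric Cu(i)/Zn(ii) sensor:
#'
#' * `"cu_bcs"`: apo protein titrated into three Cu(i)/BCS mixtures
#'   (22/60, 25/75 and 29/90 uM Cu/BCS; BCS log10 beta2 = 19.8), signal
#'   proportional to the Cu(BCS)2 absorbance at 483 nm. The protein binds Cu
#'   at two identical independent per-protomer sites (site total = protomer
#'   total), per-site constant `10^log_k`.
#' * `"zn_mf2"`: Zn(ii) titrated into 12 uM protein dimer (one Zn site per
#'   dimer) plus 16 uM mag-fura-2 (log10 K = 7.7, i.e. 5.0e7 M^-1), signal
#'   proportional to the Zn-mf2 complex.
#'
#' @param log_k Ground-truth log10 association constant of the protein site.
#' @param preset `"cu_bcs"` or `"zn_mf2"`.
#' @param n_points Points per experiment (including the zero-titrant point).
#' @param noise A [noise_spec()]; default 1% relative.
#' @param response Molar response of the observed complex (AU/M); absorbance
#'   scale only, profiled out by the fitter.
#' @param baseline Signal offset.
#' @return A tibble of points across experiments with columns `experiment`,
#'   `total_*`, `signal`. Attributes `truth` (generator parameters), `model`
#'   (the [eq_model()] used, with the truth constant), and `observed` (the
#'   signal-carrying species) record the ground truth.
#' @examples
#' tit <- gen_competition_titration(16.6, noise = noise_spec(0.01, seed = 1))
#' @export
gen_competition_titration <- function(log_k,
                                      preset = c("cu_bcs", "zn_mf2"),
                                      n_points = 15L,
                                      noise = noise_spec(0.01),
                                      response = 13000, baseline = 0) {
  preset <- match.arg(preset)
  if (preset == "cu_bcs") {
    model <- eq_model(
      c("Cu", "BCS", "P"),
      list(CuBCS2 = list(stoich = c(Cu = 1, BCS = 2), log_beta = 19.8),
           CuP    = list(stoich = c(Cu = 1, P = 1),   log_beta = log_k)))
    designs <- list(c(Cu = 22e-6, BCS = 60e-6),
                    c(Cu = 25e-6, BCS = 75e-6),
                    c(Cu = 29e-6, BCS = 90e-6))
    observed <- "CuBCS2"
    sims <- purrr::imap_dfr(designs, function(dd, i) {
      # protomer = per-site totals; titrate to ~2.5 Cu equivalents
      totals <- tibble::tibble(
        total_Cu = dd[["Cu"]], total_BCS = dd[["BCS"]],
        total_P = seq(0, 2.5 * dd[["Cu"]], length.out = n_points))
      names(totals) <- c("total_Cu", "total_BCS", "total_P")
      sim <- simulate_titration(model, stats::setNames(totals,
                                                       c("Cu", "BCS", "P")),
                                c(CuBCS2 = response), baseline)
      names(sim) <- c("total_Cu", "total_BCS", "total_P", "signal")
      dplyr::mutate(sim, experiment = paste0("exp", i), .before = 1)
    })
  } else {
    model <- eq_model(
      c("Zn", "mf2", "P"),
      list(Znmf2 = list(stoich = c(Zn = 1, mf2 = 1), log_beta = log10(5.0e7)),
           ZnP   = list(stoich = c(Zn = 1, P = 1),   log_beta = log_k)))
    totals <- tibble::tibble(
      Zn = seq(0, 30e-6, length.out = n_points),
      mf2 = 16e-6, P = 12e-6)  # one Zn site per dimer
    sim <- simulate_titration(model, totals, c(Znmf2 = response), baseline)
    names(sim) <- c("total_Zn", "total_mf2", "total_P", "signal")
    observed <- "Znmf2"
    sims <- dplyr::mutate(sim, experiment = "exp1", .before = 1)
  }
  sims$signal <- apply_noise(sims$signal, noise)
  structure(sims,
            truth = list(log_k = log_k, preset = preset, response = response,
                         baseline = baseline, noise = noise),
            model = model, observed = observed)
}

#' Synthetic fluorescence-anisotropy DNA-binding isotherm
#'
#' Points on the 1:1 non-dissociable dimer-DNA isotherm
#' `r = r_free + delta_r * fb` with additive Gaussian anisotropy noise.
#' Presets carry the parameter pairs of the two reference metallostates of
#' the Zn-activated repressor: `"zn1"` (Ka = 1.0e7 M^-1, delta_r = 0.014)
#' and `"apo"` (Ka = 2.8e6 M^-1, delta_r = 0.017).
#'
#' @param preset `"zn1"`, `"apo"` or `"custom"`.
#' @param ka Association constant, M^-1 (used when `preset = "custom"`).
#' @param dna_total DNA duplex total, M.
#' @param protein_grid Dimer totals, M.
#' @param r_free Free-DNA anisotropy.
#' @param delta_r Anisotropy change on saturation.
#' @param noise A [noise_spec()]; default absolute sigma 0.001.
#' @return Tibble with `protein_dimer_M`, `anisotropy`; attribute `truth`.
#' @export
gen_fa_isotherm <- function(preset = c("custom", "zn1", "apo"),
                            ka = 1e7, dna_total = 10e-9,
                            protein_grid = 10^seq(-9, -5, length.out = 20),
                            r_free = 0.05, delta_r = 0.014,
                            noise = noise_spec(0.001, relative = FALSE)) {
  preset <- match.arg(preset)
  if (preset == "zn1") { ka <- 1.0e7; delta_r <- 0.014 }
  if (preset == "apo") { ka <- 2.8e6; delta_r <- 0.017 }
  r <- r_free + delta_r * fraction_bound_1to1(ka, protein_grid, dna_total)
  out <- tibble::tibble(protein_dimer_M = protein_grid,
                        anisotropy = apply_noise(r, noise))
  structure(out, truth = list(ka = ka, dna_total = dna_total,
                              r_free = r_free, delta_r = delta_r,
                              preset = preset, noise = noise))
}

#' Synthetic EMSA lanes from the 1:1 dimer-DNA model
#'
#' Bound/free band intensity pairs at the given dimer totals, with relative
#' Gaussian intensity noise per band.
#'
#' @param ka Association constant, M^-1.
#' @param protein_grid Dimer totals per lane, M.
#' @param dna_total DNA duplex total, M.
#' @param total_intensity Summed band intensity per lane before noise.
#' @param noise A [noise_spec()]; default 5% relative.
#' @return Tibble with `protein_dimer_M`, `bound`, `free`; attribute `truth`.
#' @export
gen_emsa_lanes <- function(ka = 2e7,
                           protein_grid = 10^seq(-8.5, -5.5, length.out = 8),
                           dna_total = 1e-9, total_intensity = 1000,
                           noise = noise_spec(0.05)) {
  fb <- fraction_bound_1to1(ka, protein_grid, dna_total)
  raw <- cbind(bound = fb, free = 1 - fb) * total_intensity
  noisy <- matrix(apply_noise(as.vector(raw), noise), ncol = 2,
                  dimnames = list(NULL, c("bound", "free")))
  noisy <- pmax(noisy, 0)
  structure(tibble::tibble(protein_dimer_M = protein_grid,
                           bound = noisy[, "bound"], free = noisy[, "free"]),
            truth = list(ka = ka, dna_total = dna_total, noise = noise))
}

#' Synthetic isotope-coded alkylation time course
#'
#' Species fractions from [alkylation_forward_model()] (which sum to one at
#' every time before noise) with relative Gaussian intensity noise, clipped
#' at zero. The default two-site rates make the second site four-fold more
#' reactive than the first, the qualitative ordering seen for the
#' C-terminal cysteine pair of the Zn-bound repressor.
#'
#' @param k Per-site rates, s^-1 (length 1 or 2).
#' @param times Pulse times, s.
#' @param noise A [noise_spec()]; default 3% relative.
#' @return Tibble with `t_s` and intensity columns (`I_*`); attribute
#'   `truth`.
#' @export
gen_alkylation_timecourse <- function(k = c(0.005, 0.02),
                                      times = c(15, 30, 60, 240, 600),
                                      noise = noise_spec(0.03)) {
  m <- alkylation_forward_model(times, k)
  frac <- as.matrix(m[-1])
  noisy <- pmax(matrix(apply_noise(as.vector(frac), noise),
                       ncol = ncol(frac)), 0)
  colnames(noisy) <- sub("^f_", "I_", names(m)[-1])
  out <- tibble::as_tibble(noisy)
  out <- dplyr::bind_cols(tibble::tibble(t_s = times), out)
  structure(out, truth = list(k = k, noise = noise))
}

# sphere form-factor amplitude squared (normalised to 1 at q = 0)
sphere_intensity <- function(q, radius) {
  x <- q * radius
  a <- ifelse(x == 0, 1, 3 * (sin(x) - x * cos(x)) / pmax(x, .Machine$double.eps)^3)
  a^2
}

#' Synthetic SAXS profile of a sphere or sphere mixture
#'
#' Scattering of a homogeneous sphere of radius R,
#' \eqn{I(q) = I_0 [3(\sin qR - qR\cos qR)/(qR)^3]^2}, or an intensity-
#' weighted mixture of spheres (for aggregation/heterogeneity tests), with
#' Poisson-like noise \eqn{\sigma_i = scale\sqrt{I_0 I_i}} (so the relative
#' error at zero angle equals `scale`). The reported `sigma` column always
#' reflects this noise model, also at `scale = 0` where a nominal 1%
#' floor is used for weighting.
#'
#' @param radius Sphere radius, Angstrom (Dmax truth = 2R).
#' @param q Scattering-vector grid, 1/Angstrom.
#' @param i0 Zero-angle intensity.
#' @param mixture Optional data frame (`radius`, `fraction`) replacing the
#'   single sphere with a weighted mixture (fractions of I0).
#' @param noise A [noise_spec()]; `scale` is the relative error at q = 0.
#' @return Tibble `q`, `I`, `sigma`; attribute `truth` including
#'   `dmax = 2 * radius`.
#' @export
gen_saxs_profile <- function(radius = 38,
                             q = seq(0.005, 0.5, by = 0.0025),
                             i0 = 100, mixture = NULL,
                             noise = noise_spec(0.01)) {
  if (is.null(mixture)) {
    I <- i0 * sphere_intensity(q, radius)
    truth_r <- radius
  } else {
    stopifnot(all(c("radius", "fraction") %in% names(mixture)))
    I <- i0 * rowSums(vapply(seq_len(nrow(mixture)), function(i)
      mixture$fraction[i] * sphere_intensity(q, mixture$radius[i]),
      numeric(length(q))))
    truth_r <- mixture$radius
  }
  scale <- max(noise$scale, 0.01)
  sigma <- scale * sqrt(pmax(I, 0) * i0)
  I_noisy <- if (noise$scale > 0)
    with_local_seed(noise$seed, I + stats::rnorm(length(I), 0, noise$scale * sqrt(pmax(I, 0) * i0)))
  else I
  structure(tibble::tibble(q = q, I = I_noisy, sigma = sigma),
            truth = list(radius = truth_r, dmax = 2 * max(truth_r),
                         i0 = i0, mixture = mixture, noise = noise))
}

#' Synthetic SAXS profile from an arbitrary p(r)
#'
#' Forward transform \eqn{I(q) = 4\pi\int p(r)\sin(qr)/(qr)\,dr} of a given
#' pair-distance distribution, for round-trip tests of [ift_pr()].
#'
#' @param pr Data frame with columns `r` and `p`.
#' @param q Scattering-vector grid.
#' @param noise A [noise_spec()].
#' @return Tibble `q`, `I`, `sigma`.
#' @export
gen_saxs_from_pr <- function(pr, q = seq(0.005, 0.5, by = 0.0025),
                             noise = noise_spec(0)) {
  stopifnot(all(c("r", "p") %in% names(pr)))
  QR <- outer(q, pr$r)
  Kn <- 4 * pi * ifelse(QR == 0, 1, sin(QR) / pmax(QR, .Machine$double.eps))
  I <- drop(Kn %*% (trapezoid_weights(pr$r) * pr$p))
  i0 <- 4 * pi * trapz(pr$r, pr$p)
  scale <- max(noise$scale, 0.01)
  sigma <- scale * sqrt(pmax(I, 0) * i0)
  I_noisy <- if (noise$scale > 0)
    with_local_seed(noise$seed, I + stats::rnorm(length(I), 0, noise$scale * sqrt(pmax(I, 0) * i0)))
  else I
  structure(tibble::tibble(q = q, I = I_noisy, sigma = sigma),
            truth = list(pr = tibble::as_tibble(pr), i0 = i0, noise = noise))
}

#' Analytic pair-distance distribution of a homogeneous sphere
#'
#' \eqn{p(r) \propto r^2\,(1 - \frac{3r}{4R} + \frac{r^3}{16R^3})} on
#' `[0, 2R]`; the reference shape for IFT round-trip tests.
#'
#' @param radius Sphere radius, Angstrom.
#' @param n Number of grid points.
#' @return Tibble `r`, `p` (normalised to unit area).
#' @export
sphere_pr <- function(radius, n = 201L) {
  r <- seq(0, 2 * radius, length.out = n)
  x <- r / radius
  p <- r^2 * (1 - 0.75 * x + x^3 / 16)
  p <- pmax(p, 0)
  tibble::tibble(r = r, p = p / trapz(r, p))
}

#' Synthetic mobility (CCS) distribution
#'
#' Sum of Gaussian conformer components on a CCS grid plus Gaussian noise
#' relative to the peak intensity. The default bimodal preset places the
#' compact and extended dimer conformations at 2500 and 3200 square
#' Angstrom (areas 0.6/0.4, widths 120).
#'
#' @param components Data frame (`mean`, `width`, `fraction`).
#' @param grid CCS grid, square Angstrom.
#' @param noise A [noise_spec()]; scale is relative to the maximum of the
#'   noiseless envelope.
#' @return Tibble `ccs`, `intensity`; attribute `truth`.
#' @export
gen_mobility_distribution <- function(components = tibble::tibble(
                                        mean = c(2500, 3200),
                                        width = c(120, 120),
                                        fraction = c(0.6, 0.4)),
                                      grid = seq(2000, 4000, by = 10),
                                      noise = noise_spec(0.02)) {
  stopifnot(all(c("mean", "width", "fraction") %in% names(components)))
  I <- rowSums(vapply(seq_len(nrow(components)), function(i)
    components$fraction[i] *
      stats::dnorm(grid, components$mean[i], components$width[i]),
    numeric(length(grid))))
  I <- I / max(I)
  noisy <- if (noise$scale > 0)
    with_local_seed(noise$seed, I + stats::rnorm(length(I), 0, noise$scale))
  else I
  structure(tibble::tibble(ccs = grid, intensity = pmax(noisy, 0)),
            truth = list(components = tibble::as_tibble(components),
                         noise = noise))
}

#' Synthetic centroided MALDI peak list of labelled peptide species
#'
#' One centroid per labelling pattern at its [modified_peptide_masses()]
#' mass, intensity proportional to the species fraction, with relative
#' Gaussian intensity noise.
#'
#' @param sequence Peptide sequence.
#' @param patterns List of labelling patterns (see
#'   [modified_peptide_masses()]).
#' @param fractions Species abundances (normalised internally).
#' @param total_intensity Summed intensity before noise.
#' @param noise A [noise_spec()].
#' @return Tibble `mz`, `intensity`, `species`; attribute `truth`.
#' @export
gen_maldi_peaklist <- function(sequence,
                               patterns = list(c("d5", "d5"), c("d5", "h5"),
                                               c("h5", "h5")),
                               fractions = c(0.25, 0.5, 0.25),
                               total_intensity = 1000,
                               noise = noise_spec(0.03)) {
  stopifnot(length(patterns) == length(fractions), all(fractions >= 0))
  fr <- fractions / sum(fractions)
  sp <- purrr::map_dfr(patterns, ~modified_peptide_masses(sequence, .x))
  out <- tibble::tibble(mz = sp$mass,
                        intensity = pmax(apply_noise(fr * total_intensity,
                                                     noise), 0),
                        species = sp$species)
  structure(dplyr::arrange(out, .data$mz),
            truth = list(sequence = sequence, fractions = fr, noise = noise))
}
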