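#' Forward model of an isotope-coded alkylation pulse
#'
#' During a pulse of deuterated alkylating agent each cysteine is labelled
#' with pseudo-first-order probability \eqn{f_i(t) = 1 - e^{-k_i t}}; the
#' chase converts every remaining free thiol to the protiated adduct. Sites
#' label independently, so the isotopologue fractions are products of the
#' per-site probabilities and sum to one at every time.
#'
#' @param times Pulse times, s (non-negative).
#' @param k Per-site rate constants, s^-1 (length 1 or 2, >= 0).
#' @return A tibble with column `t_s` and species-fraction columns: `f_d5`,
#'   `f_h5` for one site; `f_d5d5`, `f_d5h5`, `f_h5h5` for two sites.
#' @examples
#' alkylation_forward_model(c(0, 30, 600), k = c(0.005, 0.02))
#' @export
alkylation_forward_model <- function(times, k) {
  if (any(times < 0)) stop("pulse times must be non-negative", call. = FALSE)
  if (any(k < 0)) stop("rate constants must be non-negative", call. = FALSE)
  if (!length(k) %in% 1:2)
    stop("k must have length 1 or 2", call. = FALSE)
  p <- outer(times, k, function(t, kk) 1 - exp(-kk * t))
  if (length(k) == 1) {
    tibble::tibble(t_s = times, f_d5 = p[, 1], f_h5 = 1 - p[, 1])
  } else {
    tibble::tibble(t_s = times,
                   f_d5d5 = p[, 1] * p[, 2],
                   f_d5h5 = p[, 1] * (1 - p[, 2]) + (1 - p[, 1]) * p[, 2],
                   f_h5h5 = (1 - p[, 1]) * (1 - p[, 2]))
  }
}

#' Fit per-cysteine alkylation rate constants from a time course
#'
#' Least squares of the observed isotopologue fractions (intensities are
#' normalised within each time point) against [alkylation_forward_model()].
#' For a two-cysteine peptide the species fractions are symmetric under
#' exchange of the two sites (d5/d5 and h5/h5 depend on \eqn{p_1p_2} and
#' \eqn{(1-p_1)(1-p_2)}), so peptide-level data identify the rates only up
#' to permutation: they are reported sorted ascending. Attributing a rate to
#' a specific cysteine requires the MS/MS partition
#' ([site_occupancy_from_fragments()]).
#'
#' A rate that refines to zero (no detectable labelling, fully protected
#' site) is reported as 0 together with a finite upper bound: the rate at
#' which the residual sum of squares rises by four times the residual
#' variance above its minimum (floored, for noise-free input, at the rate
#' giving 1% labelling at the last time point).
#'
#' @param data Tibble with column `t_s` and intensity columns `I_d5`, `I_h5`
#'   (one site) or `I_d5d5`, `I_d5h5`, `I_h5h5` (two sites).
#' @return Object of class `alkylation_fit`: `k` (sorted, s^-1), `se`,
#'   `ci_lower`/`ci_upper`, `k_upper_bound` (finite where k = 0), residuals.
#' @export
fit_alkylation_rates <- function(data) {
  d <- tibble::as_tibble(data)
  stopifnot("t_s" %in% names(d))
  two <- all(c("I_d5d5", "I_d5h5", "I_h5h5") %in% names(d))
  one <- all(c("I_d5", "I_h5") %in% names(d))
  if (!two && !one)
    stop("need intensity columns I_d5/I_h5 or I_d5d5/I_d5h5/I_h5h5",
         call. = FALSE)
  icols <- if (two) c("I_d5d5", "I_d5h5", "I_h5h5") else c("I_d5", "I_h5")
  if (nrow(d) < 3) stop("need at least 3 time points", call. = FALSE)
  if (any(as.matrix(d[icols]) < 0))
    stop("intensities must be non-negative", call. = FALSE)
  tot <- rowSums(d[icols])
  if (any(tot == 0)) {
    warning("excluding ", sum(tot == 0), " time point(s) with all-zero intensities")
    d <- d[tot > 0, ]
    tot <- tot[tot > 0]
  }
  frac <- as.matrix(d[icols]) / tot
  nsite <- if (two) 2L else 1L

  resid_fun <- function(k) {
    m <- alkylation_forward_model(d$t_s, k)
    as.vector(frac - as.matrix(m[-1]))
  }
  # crude start from the d5-appearance half-time
  fd5 <- if (two) frac[, 1] + frac[, 2] / 2 else frac[, 1]
  t_half <- d$t_s[which(fd5 >= 0.5)[1]]
  k0 <- if (!is.na(t_half) && t_half > 0) log(2) / t_half else
    1 / max(d$t_s)
  start <- if (two) c(k0 / 2, k0 * 2) else k0
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fun,
                            lower = rep(0, nsite),
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  k_hat <- fit$par
  ord <- order(k_hat)
  k_hat <- k_hat[ord]
  rss <- sum(fit$fvec^2)
  dof <- max(length(fit$fvec) - nsite, 1)
  sigma2 <- rss / dof
  se <- tryCatch(unname(summary(fit)$coefficients[, "Std. Error"])[ord],
                 error = function(e) rep(NA_real_, nsite))

  # finite upper bound for rates indistinguishable from zero
  ub <- rep(NA_real_, nsite)
  floor_k <- -log(0.99) / max(d$t_s)
  for (i in seq_len(nsite)) {
    if (k_hat[i] > floor_k) next
    thr <- rss + max(4 * sigma2, 1e-12)
    f <- function(ki) {
      kk <- k_hat; kk[i] <- ki
      sum(resid_fun(kk)^2) - thr
    }
    hi <- 1 / min(d$t_s[d$t_s > 0])
    ub[i] <- tryCatch(stats::uniroot(f, c(k_hat[i], hi))$root,
                      error = function(e) floor_k)
    ub[i] <- max(ub[i], floor_k)
    k_hat[i] <- 0
  }

  structure(list(k = k_hat, se = se,
                 ci_lower = pmax(k_hat - 1.96 * se, 0),
                 ci_upper = k_hat + 1.96 * se,
                 k_upper_bound = ub, rss = rss, sigma2 = sigma2,
                 n_sites = nsite, data = d, fractions = frac),
            class = "alkylation_fit")
}

#' @export
print.alkylation_fit <- function(x, ...) {
  cat("<alkylation_fit>", x$n_sites, "site(s)\n")
  for (i in seq_len(x$n_sites)) {
    cat(sprintf("  k[%d] = %.4g s^-1 (se %.2g)", i, x$k[i], x$se[i]))
    if (is.finite(x$k_upper_bound[i]))
      cat(sprintf("  [no labelling detected; k < %.3g]", x$k_upper_bound[i]))
    cat("\n")
  }
  invisible(x)
}

#' @export
tidy.alkylation_fit <- function(x, ...) {
  tibble::tibble(term = paste0("k", seq_len(x$n_sites)), estimate = x$k,
                 std.error = x$se, conf.low = x$ci_lower,
                 conf.high = x$ci_upper, upper_bound = x$k_upper_bound)
}

#' @export
glance.alkylation_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, sigma = sqrt(x$sigma2),
                 nobs = nrow(x$data) * (x$n_sites + 1), n_sites = x$n_sites)
}

#' @export
autoplot.alkylation_fit <- function(object, ...) {
  d <- object$data
  obs <- tibble::as_tibble(object$fractions)
  obs$t_s <- d$t_s
  obs_long <- tidyr::pivot_longer(obs, -"t_s", names_to = "species",
                                  values_to = "fraction")
  tt <- seq(0, max(d$t_s), length.out = 200)
  mod <- alkylation_forward_model(tt, pmax(object$k, 0))
  names(mod) <- sub("^f_", "I_", names(mod))
  mod_long <- tidyr::pivot_longer(mod, -"t_s", names_to = "species",
                                  values_to = "fraction")
  ggplot2::ggplot(obs_long, ggplot2::aes(.data$t_s, .data$fraction,
                                         colour = .data$species)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = mod_long) +
    ggplot2::labs(x = "pulse time (s)", y = "species fraction") +
    ggplot2::theme_minimal()
}

#' Protection factor between two metallostates
#'
#' Ratio of a site's alkylation rate in a reference state (typically apo) to
#' the rate in the metallated state; values above 1 indicate protection by
#' metal coordination or burial. A fully quenched site (k_state = 0) gives an
#' infinite protection factor.
#'
#' @param k_ref,k_state Rate constants, s^-1 (vectorised, matched sites).
#' @return Numeric protection factor(s), >= 0.
#' @export
protection_factor <- function(k_ref, k_state) {
  if (any(k_ref < 0) || any(k_state < 0))
    stop("rates must be non-negative", call. = FALSE)
  ifelse(k_state == 0, ifelse(k_ref == 0, 1, Inf), k_ref / k_state)
}

#' Per-cysteine d5 occupancy from diagnostic fragment ions
#'
#' For a singly-deuterated two-cysteine peptide, fragment ions covering only
#' one of the sites are diagnostic of where the deuterated adduct sits. The
#' raw occupancy of a site is its summed d5-diagnostic intensity divided by
#' the summed (d5 + h5) diagnostic intensity; the partition between the two
#' sites is the normalisation of the raw occupancies to unit sum.
#'
#' @param data Tibble of fragment observations: columns `ion` (e.g. `"y2"`),
#'   `label` (`"d5"` or `"h5"`), `intensity` (>= 0).
#' @param diagnostic_map Tibble mapping `ion` to the `site` it covers
#'   exclusively (e.g. y2/y3 -> "C130", b9/b10 -> "C128").
#' @return Tibble with one row per site: `site`, `occupancy` (raw d5 share
#'   among that site's ions), `partition` (normalised across sites).
#' @export
site_occupancy_from_fragments <- function(data, diagnostic_map) {
  stopifnot(all(c("ion", "label", "intensity") %in% names(data)),
            all(c("ion", "site") %in% names(diagnostic_map)))
  d <- dplyr::inner_join(tibble::as_tibble(data),
                         tibble::as_tibble(diagnostic_map), by = "ion")
  if (!nrow(d) || all(d$intensity == 0))
    stop("occupancy undefined: no diagnostic ions observed", call. = FALSE)
  occ <- d |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(
      occupancy = sum(.data$intensity[.data$label == "d5"]) /
        sum(.data$intensity),
      .groups = "drop")
  # a site whose diagnostic ions carry no intensity at all contributes zero
  occ$occupancy[is.nan(occ$occupancy)] <- 0
  occ$partition <- occ$occupancy / sum(occ$occupancy)
  occ
}
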