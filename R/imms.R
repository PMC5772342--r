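#' Assign oligomer order and charge state to native MS peaks
#'
#' For each centroided peak the candidate `(n, z)` minimising
#' `|observed - (n*M + z*1.00728)/z|` is selected; peaks with no candidate
#' within tolerance are left unassigned. Ties are broken toward the smaller
#' oligomer order.
#'
#' @param peaks Data frame with columns `mz` (> 0) and optionally
#'   `intensity` (>= 0).
#' @param monomer_mass Neutral monomer mass, Da.
#' @param max_n,max_z Largest oligomer order and charge considered.
#' @param tolerance Assignment tolerance.
#' @param tolerance_unit `"ppm"` or `"Th"` (absolute m/z).
#' @return The input tibble with columns `n`, `z`, `mz_calc`, `error_ppm`
#'   appended (`NA` where unassigned).
#' @examples
#' assign_oligomer_charges(data.frame(mz = 2810.1), monomer_mass = 15450)
#' @export
assign_oligomer_charges <- function(peaks, monomer_mass, max_n = 4L,
                                    max_z = 20L, tolerance = 50,
                                    tolerance_unit = c("ppm", "Th")) {
  stopifnot("mz" %in% names(peaks), monomer_mass > 0)
  tolerance_unit <- match.arg(tolerance_unit)
  d <- tibble::as_tibble(peaks)
  if (any(d$mz <= 0)) stop("m/z must be positive", call. = FALSE)
  if ("intensity" %in% names(d) && any(d$intensity < 0))
    stop("intensities must be non-negative", call. = FALSE)
  cand <- tidyr::crossing(n = seq_len(max_n), z = seq_len(max_z)) |>
    dplyr::mutate(mz_calc = (.data$n * monomer_mass + .data$z * 1.00728) /
                    .data$z)
  assign_one <- function(mz) {
    err <- abs(mz - cand$mz_calc)
    tol_th <- if (tolerance_unit == "ppm") tolerance * 1e-6 * mz else tolerance
    ok <- which(err <= tol_th)
    if (!length(ok)) return(c(NA_real_, NA_real_, NA_real_))
    ok <- ok[order(err[ok], cand$n[ok])]
    i <- ok[1]
    c(cand$n[i], cand$z[i], cand$mz_calc[i])
  }
  res <- t(vapply(d$mz, assign_one, numeric(3)))
  d$n <- as.integer(res[, 1])
  d$z <- as.integer(res[, 2])
  d$mz_calc <- res[, 3]
  d$error_ppm <- (d$mz - d$mz_calc) / d$mz_calc * 1e6
  d
}

# par = (amp_1..k, mu_1..k, width_1..k, baseline)
gaussian_mixture_curve <- function(x, par) {
  k <- (length(par) - 1) / 3
  amp <- par[seq_len(k)]
  mu <- par[k + seq_len(k)]
  wd <- par[2 * k + seq_len(k)]
  par[3 * k + 1] + rowSums(vapply(seq_len(k), function(i)
    amp[i] * exp(-(x - mu[i])^2 / (2 * wd[i]^2)), numeric(length(x))))
}

#' Decompose a mobility (CCS) distribution into Gaussian conformer components
#'
#' Fits Gaussian mixtures with k = 1..`max_components` components to the
#' intensity envelope by Levenberg-Marquardt least squares and selects the
#' minimum number of components that satisfactorily describes it: the
#' smallest k for which adding one more component reduces the residual sum
#' of squares by less than `rss_threshold` (default 5%). A constant
#' baseline is fitted alongside the Gaussians so that an imperfect
#' background subtraction is not soaked up by a spurious wide component.
#' Initialisation is deterministic (intensity-weighted quantiles of the
#' grid), so repeated calls give identical results.
#'
#' @param data Data frame with columns `ccs` (strictly increasing grid,
#'   square Angstrom) and `intensity` (>= 0), at least 20 points.
#' @param max_components Largest mixture size tried.
#' @param rss_threshold Fractional RSS improvement below which an extra
#'   component is deemed unnecessary.
#' @return Object of class `conformer_components`: tibble `components`
#'   (`mean`, `width`, `area_fraction`), `k`, `rss`, `r_squared`.
#' @export
fit_mobility_components <- function(data, max_components = 3L,
                                    rss_threshold = 0.05) {
  stopifnot(all(c("ccs", "intensity") %in% names(data)))
  d <- tibble::as_tibble(data)
  if (nrow(d) < 20) stop("need at least 20 grid points", call. = FALSE)
  if (is.unsorted(d$ccs, strictly = TRUE))
    stop("ccs grid must be strictly increasing", call. = FALSE)
  if (any(d$intensity < 0)) stop("intensities must be non-negative", call. = FALSE)
  x <- d$ccs; y <- d$intensity
  wts <- y / sum(y)
  sd_all <- sqrt(sum(wts * (x - sum(wts * x))^2))

  # initial means from the k tallest local maxima of the lightly smoothed
  # envelope (falling back to intensity-weighted quantiles); deterministic
  ys <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  is_peak <- c(FALSE, diff(sign(diff(ys))) < 0, FALSE) & ys > 0.1 * max(ys)
  peak_x <- x[is_peak][order(ys[is_peak], decreasing = TRUE)]
  fit_k <- function(k) {
    mu0 <- peak_x[seq_len(min(k, length(peak_x)))]
    if (length(mu0) < k) {
      qs <- (seq_len(k - length(mu0)) - 0.5) / (k - length(mu0) + 1)
      cw <- cumsum(wts)
      mu0 <- c(mu0, vapply(qs, function(p) x[which(cw >= p)[1]], numeric(1)))
    }
    wd0 <- rep(max(sd_all / k, diff(range(x)) / 50), k)
    amp0 <- vapply(mu0, function(m) max(y[which.min(abs(x - m))], 0.1 * max(y)),
                   numeric(1))
    lower <- c(rep(0, k), rep(min(x), k), rep(diff(range(x)) / 200, k), 0)
    upper <- c(rep(Inf, k), rep(max(x), k), rep(diff(range(x)) / 2, k),
               0.2 * max(y))  # residual pedestal only: data are background subtracted
    tryCatch({
      fit <- minpack.lm::nls.lm(
        par = c(amp0, mu0, wd0, 0),
        fn = function(par) y - gaussian_mixture_curve(x, par),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 1000))
      list(par = fit$par, rss = sum(fit$fvec^2))
    }, error = function(e) NULL)
  }

  fits <- vector("list", max_components)
  chosen <- NA_integer_
  rss_floor <- 1e-12 * sum(y^2)  # numerically perfect fit: stop growing k
  for (k in seq_len(max_components)) {
    fits[[k]] <- fit_k(k)
    if (is.null(fits[[k]])) next
    if (k > 1 && !is.null(fits[[k - 1]])) {
      impr <- (fits[[k - 1]]$rss - fits[[k]]$rss) /
        max(fits[[k - 1]]$rss, rss_floor)
      if (impr < rss_threshold) { chosen <- k - 1L; break }
    }
    chosen <- k
    if (fits[[k]]$rss < rss_floor) break
  }
  if (is.na(chosen) || is.null(fits[[chosen]]))
    stop("mixture fit failed to converge for every component count",
         call. = FALSE)
  best <- fits[[chosen]]
  kk <- chosen
  amp <- best$par[seq_len(kk)]
  mu <- best$par[kk + seq_len(kk)]
  wd <- best$par[2 * kk + seq_len(kk)]
  area <- amp * wd * sqrt(2 * pi)
  ord <- order(mu)
  comps <- tibble::tibble(component = seq_len(kk), mean = mu[ord],
                          width = wd[ord],
                          area_fraction = (area / sum(area))[ord])
  baseline <- best$par[3 * kk + 1]
  if (kk == 1L && max_components > 1L && best$rss > 1e-10 * sum(y^2)) {
    # systematic single-Gaussian misfit (strongly autocorrelated residuals)
    # flags structure that extra Gaussians could not resolve
    resid <- y - gaussian_mixture_curve(x, best$par)
    ac <- stats::cor(resid[-1], resid[-length(resid)])
    if (is.finite(ac) && ac > 0.5)
      warning("the envelope deviates systematically from a single Gaussian; ",
              "additional components may be present but are not resolvable")
  }
  r2 <- 1 - best$rss / sum((y - mean(y))^2)
  structure(list(components = comps, k = kk, rss = best$rss,
                 r_squared = r2, baseline = baseline, data = d),
            class = "conformer_components")
}

#' @export
print.conformer_components <- function(x, ...) {
  cat("<conformer_components>", x$k, "component(s), R2 =",
      format(x$r_squared, digits = 4), "\n")
  print(x$components)
  invisible(x)
}

#' @export
tidy.conformer_components <- function(x, ...) x$components

#' @export
glance.conformer_components <- function(x, ...) {
  tibble::tibble(k = x$k, rss = x$rss, r_squared = x$r_squared)
}

#' @export
autoplot.conformer_components <- function(object, ...) {
  d <- object$data
  comp_curves <- purrr::map_dfr(seq_len(object$k), function(i) {
    cc <- object$components[i, ]
    tibble::tibble(component = factor(i), ccs = d$ccs,
                   intensity = stats::dnorm(d$ccs, cc$mean, cc$width) *
                     cc$area_fraction)
  })
  tot_area <- trapz(d$ccs, d$intensity)
  comp_curves$intensity <- comp_curves$intensity * tot_area
  ggplot2::ggplot(d, ggplot2::aes(.data$ccs, .data$intensity)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_line(data = comp_curves,
                       ggplot2::aes(colour = .data$component)) +
    ggplot2::labs(x = expression("CCS ("*ring(A)^2*")"), y = "intensity") +
    ggplot2::theme_minimal()
}

#' Compact and extended conformer fractions
#'
#' Sums Gaussian component area fractions on either side of a CCS boundary.
#' A component mean exactly on the boundary counts as compact, with a
#' warning.
#'
#' @param components A `conformer_components` object or its `components`
#'   tibble (`mean`, `area_fraction`).
#' @param boundary CCS boundary (square Angstrom) separating compact (below)
#'   from extended (above) conformations.
#' @return Tibble with rows `compact` and `extended` and their `fraction`
#'   (summing to 1).
#' @export
conformer_fractions <- function(components, boundary) {
  comps <- if (inherits(components, "conformer_components"))
    components$components else tibble::as_tibble(components)
  stopifnot(all(c("mean", "area_fraction") %in% names(comps)))
  if (any(comps$mean == boundary))
    warning("component mean exactly on the boundary: counted as compact")
  compact <- sum(comps$area_fraction[comps$mean <= boundary])
  total <- sum(comps$area_fraction)
  tibble::tibble(conformation = c("compact", "extended"),
                 fraction = c(compact, total - compact) / total)
}
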