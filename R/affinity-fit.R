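#' Globally fit binding constants to one or more titrations
#'
#' Fits shared thermodynamic parameters (log10 formation constants of named
#' complexes) across several titration experiments by least squares. Each
#' experiment carries its own nuisance baseline and response scale for the
#' observed species; these are profiled out analytically (they enter the
#' signal linearly), so the numerical optimisation runs only over the
#' thermodynamic parameters.
#'
#' When the binding is stoichiometric the objective is flat above some
#' affinity and only a lower bound is resolvable. The fit detects this by
#' profiling the objective over the fitted constant: if the profile at the
#' upper end of the scan stays within the threshold (an objective increase of
#' four times the residual variance, roughly a 2-sigma rise) of the minimum,
#' `lower_bound_only` is set and the reported bound is the value at which the
#' profile crosses the threshold from below.
#'
#' @param data Tibble of observed points: one column `total_<component>` per
#'   model component (M), a `signal` column, and optionally an `experiment`
#'   column grouping points into experiments (each with its own baseline and
#'   scale). A single experiment is assumed when absent.
#' @param model An [eq_model()] whose `log_beta` entries provide starting
#'   values for the free parameters and fixed values for the rest.
#' @param free Character vector of complex names whose log10 constants are
#'   fitted (currently the profile lower-bound scan requires exactly one).
#' @param observed Name of the species whose concentration carries the
#'   signal (e.g. `"CuBCS2"`).
#' @param scan_width Half-width (log10 units) of the profile scan around the
#'   optimum used for the lower-bound diagnosis.
#' @param bound_check Logical; run the profile scan? Skipping it saves time
#'   in large simulation studies where the affinity is known to be resolvable.
#' @return An object of class `affinity_fit`; see [tidy.affinity_fit()] and
#'   [glance.affinity_fit()].
#' @export
fit_global_affinity <- function(data, model, free, observed,
                                scan_width = 6, bound_check = TRUE) {
  stopifnot(inherits(model, "eq_model"), length(free) >= 1)
  if (!all(free %in% rownames(model$stoich)))
    stop("`free` names complexes absent from the model", call. = FALSE)
  data <- tibble::as_tibble(data)
  if (!"experiment" %in% names(data)) data$experiment <- "exp1"
  tot_cols <- paste0("total_", model$components)
  miss <- setdiff(c(tot_cols, "signal"), names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  exps <- split(data, data$experiment)
  n_obs <- nrow(data)
  n_par <- length(free) + 2L * length(exps)
  if (n_obs <= n_par)
    stop("underdetermined: ", n_obs, " points for ", n_par, " parameters",
         call. = FALSE)

  totals_of <- function(e) stats::setNames(e[tot_cols], model$components)

  # Profiled objective: nuisance baseline + scale solved by linear LS.
  rss_at <- function(theta) {
    m <- set_log_beta(model, stats::setNames(theta, free))
    tot <- 0
    for (e in exps) {
      conc <- solve_speciation(m, totals_of(e))[[observed]]
      fit <- stats::lm.fit(cbind(1, conc), e$signal)
      tot <- tot + sum(fit$residuals^2)
    }
    tot
  }

  theta0 <- model$log_beta[match(free, rownames(model$stoich))]
  if (length(free) == 1L) {
    opt <- stats::optimize(rss_at, c(theta0 - scan_width, theta0 + scan_width),
                           tol = 1e-7)
    theta_hat <- opt$minimum
    rss_min <- opt$objective
  } else {
    opt <- stats::optim(theta0, rss_at, method = "BFGS",
                        control = list(reltol = 1e-12))
    theta_hat <- opt$par
    rss_min <- opt$value
  }

  sigma2 <- rss_min / (n_obs - n_par)
  # curvature-based standard errors on the profiled objective
  h <- 1e-3
  se <- vapply(seq_along(theta_hat), function(i) {
    ei <- replace(numeric(length(theta_hat)), i, h)
    d2 <- (rss_at(theta_hat + ei) - 2 * rss_min + rss_at(theta_hat - ei)) / h^2
    if (d2 > 0) sqrt(2 * sigma2 / d2) else NA_real_
  }, numeric(1))

  lower_bound_only <- FALSE
  bound <- NA_real_
  profile <- NULL
  if (bound_check && length(free) == 1L) {
    grid <- seq(theta_hat - scan_width, theta_hat + scan_width, length.out = 61)
    prof <- vapply(grid, rss_at, numeric(1))
    thr <- rss_min + max(4 * sigma2, 1e-12 * max(rss_min, 1e-300))
    profile <- tibble::tibble(log10_k = grid, rss = prof)
    if (prof[length(prof)] <= thr) {
      lower_bound_only <- TRUE
      below <- which(prof > thr & grid < theta_hat)
      if (length(below)) {
        i <- max(below)  # last grid point (from the left) above threshold
        # linear interpolation of the downward crossing
        bound <- grid[i] + (thr - prof[i]) * (grid[i + 1] - grid[i]) /
          (prof[i + 1] - prof[i])
      } else {
        bound <- grid[1]
      }
      se[1] <- NA_real_
    }
  }

  # nuisance parameters and residuals at the optimum
  m_hat <- set_log_beta(model, stats::setNames(theta_hat, free))
  nuisance <- purrr::map_dfr(names(exps), function(lbl) {
    e <- exps[[lbl]]
    conc <- solve_speciation(m_hat, totals_of(e))[[observed]]
    fit <- stats::lm.fit(cbind(1, conc), e$signal)
    tibble::tibble(experiment = lbl, baseline = fit$coefficients[1],
                   response_scale = fit$coefficients[2])
  })
  resid <- numeric(n_obs)
  idx <- split(seq_len(n_obs), data$experiment)
  for (lbl in names(exps)) {
    e <- exps[[lbl]]
    conc <- solve_speciation(m_hat, totals_of(e))[[observed]]
    resid[idx[[lbl]]] <- stats::lm.fit(cbind(1, conc), e$signal)$residuals
  }

  structure(list(
    par = stats::setNames(theta_hat, free), se = stats::setNames(se, free),
    ci_lower = theta_hat - 1.96 * se, ci_upper = theta_hat + 1.96 * se,
    lower_bound_only = lower_bound_only, bound_log10 = bound,
    nuisance = nuisance, residuals = resid, sigma2 = sigma2,
    rss = rss_min, n_obs = n_obs, n_par = n_par,
    observed = observed, model = m_hat, data = data, profile = profile
  ), class = "affinity_fit")
}

#' @export
print.affinity_fit <- function(x, ...) {
  cat("<affinity_fit> global fit of", length(x$par), "constant(s) over",
      nrow(x$nuisance), "experiment(s),", x$n_obs, "points\n")
  for (nm in names(x$par))
    cat(sprintf("  log10 K[%s] = %.3f (se %.3f)\n", nm, x$par[nm], x$se[nm]))
  if (x$lower_bound_only)
    cat(sprintf("  objective flat above the optimum: lower bound only, log10 K >= %.2f\n",
                x$bound_log10))
  invisible(x)
}

#' Tidy an affinity fit
#'
#' @param x An `affinity_fit`.
#' @param ... Unused.
#' @return One row per fitted constant: estimate (log10), standard error,
#'   Wald 95% interval, and the lower-bound diagnosis.
#' @export
tidy.affinity_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par),
                 std.error = unname(x$se),
                 conf.low = unname(x$ci_lower), conf.high = unname(x$ci_upper),
                 lower_bound_only = x$lower_bound_only,
                 bound_log10 = x$bound_log10)
}

#' @rdname tidy.affinity_fit
#' @export
glance.affinity_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, sigma = sqrt(x$sigma2), nobs = x$n_obs,
                 n_par = x$n_par, n_experiments = nrow(x$nuisance),
                 lower_bound_only = x$lower_bound_only)
}

#' @export
autoplot.affinity_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- d$signal - object$residuals
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[grep("^total_", names(d), value = TRUE)[1]]])) +
    ggplot2::geom_point(ggplot2::aes(y = .data$signal, colour = .data$experiment)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted, colour = .data$experiment)) +
    ggplot2::labs(x = "titrant total (M)", y = "signal") +
    ggplot2::theme_minimal()
}
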