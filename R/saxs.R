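check_profile <- function(profile) {
  stopifnot(all(c("q", "I") %in% names(profile)))
  d <- tibble::as_tibble(profile)
  if (any(d$q <= 0) || is.unsorted(d$q, strictly = TRUE))
    stop("q must be positive and strictly increasing", call. = FALSE)
  if (any(!is.finite(d$I))) stop("I must be finite", call. = FALSE)
  if ("sigma" %in% names(d) && any(d$sigma <= 0, na.rm = TRUE))
    stop("sigma must be positive where present", call. = FALSE)
  d
}

#' Guinier analysis of a SAXS profile
#'
#' Weighted fit of \eqn{\ln I = \ln I_0 - q^2R_g^2/3 + cq^4} over the low-q
#' region; \eqn{R_g} is read from the \eqn{q^2} coefficient. The quartic
#' term absorbs the leading systematic deviation of real form factors from
#' the Guinier law inside the fitting window (for a sphere fitted to
#' \eqn{qR_g = 1.3} a pure two-parameter fit overestimates \eqn{R_g} by
#' about 2%; the corrected fit is accurate to ~0.1%) and leaves exact
#' Gaussian input untouched. The q-range is chosen self-consistently:
#' starting from the lowest-q points, the fit is iterated so that every
#' point used satisfies \eqn{qR_g \le} `qrg_limit` with the fitted
#' \eqn{R_g}.
#'
#' A significant *positive* quartic coefficient (upturn of \eqn{\ln I} vs
#' \eqn{q^2} at low q) indicates interparticle aggregation or a
#' heterogeneous mixture; the fit then carries a nonlinearity warning flag
#' and raises an R warning. Compact single-species particles give a
#' negative coefficient.
#'
#' @param profile Data frame with columns `q` (1/Angstrom, strictly
#'   increasing), `I`, and optionally `sigma`.
#' @param qrg_limit Upper limit of \eqn{qR_g} for points entering the fit.
#' @param min_points Minimum number of points required in the fitted range.
#' @return Object of class `guinier_fit`: `rg`, `i0`, `q_range`, `n_points`,
#'   `r_squared`, `nonlinearity_warning`.
#' @examples
#' prof <- gen_saxs_profile(radius = 31.4, noise = noise_spec(0))
#' guinier_fit(prof)$rg  # ~ sqrt(3/5) * 31.4
#' @export
guinier_fit <- function(profile, qrg_limit = 1.3, min_points = 5L) {
  d <- check_profile(profile)
  d <- d[d$I > 0, ]
  w <- if ("sigma" %in% names(d)) (d$I / d$sigma)^2 else rep(1, nrow(d))
  lnI <- log(d$I); q2 <- d$q^2

  fit_window <- function(sel) {
    if (length(sel) >= 6)
      stats::lm(lnI[sel] ~ q2[sel] + I(q2[sel]^2), weights = w[sel])
    else
      stats::lm(lnI[sel] ~ q2[sel], weights = w[sel])
  }
  sel <- seq_len(min(max(min_points, 10L), nrow(d)))
  rg <- NA_real_
  for (it in 1:50) {
    slope <- unname(stats::coef(fit_window(sel))[2])
    rg_new <- if (slope < 0) sqrt(-3 * slope) else NA_real_
    if (is.na(rg_new)) break
    sel_new <- which(d$q * rg_new <= qrg_limit)
    if (length(sel_new) < min_points) sel_new <- seq_len(min_points)
    if (identical(sel_new, sel)) { rg <- rg_new; break }
    sel <- sel_new
    rg <- rg_new
  }
  if (is.na(rg))
    stop("Guinier fit failed: no negative slope at low q", call. = FALSE)
  if (length(sel) < min_points)
    stop("fewer than ", min_points, " points satisfy q*Rg <= ", qrg_limit,
         call. = FALSE)
  f <- fit_window(sel)
  rg <- unname(sqrt(-3 * stats::coef(f)[[2]]))
  i0 <- exp(stats::coef(f)[[1]])
  smry <- suppressWarnings(summary(f))  # degenerate-fit warnings on exact data
  r2 <- smry$r.squared

  # upturn diagnostic from the quartic coefficient
  nonlin <- FALSE
  if (length(sel) >= 6) {
    cf <- smry$coefficients
    if (nrow(cf) == 3 && cf[3, "Estimate"] > 0 && cf[3, "t value"] > 4) {
      nonlin <- TRUE
      warning("Guinier region shows significant positive curvature: ",
              "heterogeneous/aggregating sample suspected")
    }
  }
  structure(list(rg = rg, i0 = i0, q_range = range(d$q[sel]),
                 n_points = length(sel), r_squared = r2,
                 qrg_limit = qrg_limit, nonlinearity_warning = nonlin,
                 used = d[sel, ], profile = d),
            class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("<guinier_fit> Rg = %.2f A, I0 = %.4g, %d pts (q %.4f-%.4f), R2 = %.4f\n",
              x$rg, x$i0, x$n_points, x$q_range[1], x$q_range[2], x$r_squared))
  if (x$nonlinearity_warning)
    cat("  WARNING: positive curvature (heterogeneous sample?)\n")
  invisible(x)
}

#' @export
tidy.guinier_fit <- function(x, ...) {
  tibble::tibble(term = c("rg", "i0"), estimate = c(x$rg, x$i0))
}

#' @export
glance.guinier_fit <- function(x, ...) {
  tibble::tibble(rg = x$rg, i0 = x$i0, n_points = x$n_points,
                 r_squared = x$r_squared, q_min = x$q_range[1],
                 q_max = x$q_range[2],
                 nonlinearity_warning = x$nonlinearity_warning)
}

#' @export
autoplot.guinier_fit <- function(object, ...) {
  d <- object$profile
  d$in_fit <- d$q >= object$q_range[1] & d$q <= object$q_range[2]
  d <- d[d$q * object$rg <= 2.5, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$q^2, y = log(.data$I))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_fit)) +
    ggplot2::geom_abline(intercept = log(object$i0),
                         slope = -object$rg^2 / 3, colour = "firebrick") +
    ggplot2::labs(x = expression(q^2), y = "ln I") +
    ggplot2::theme_minimal()
}

#' Kratky transform
#'
#' Pointwise transform to \eqn{(q, q^2 I(q))}; globular particles show a
#' peak followed by decay, unfolded chains a plateau. No smoothing is
#' applied.
#'
#' @param profile SAXS profile data frame (`q`, `I`).
#' @return Tibble with columns `q` and `q2I`.
#' @export
kratky_transform <- function(profile) {
  d <- check_profile(profile)
  tibble::tibble(q = d$q, q2I = d$q^2 * d$I)
}

#' Percent discrepancy between an estimated and a sequence molecular weight
#'
#' @param mw_estimated,mw_sequence Molecular weights (kDa), both positive.
#' @return `100 * |mw_estimated - mw_sequence| / mw_sequence`, rounded to one
#'   decimal.
#' @examples
#' mw_discrepancy(26.0, 30.9)  # 15.9
#' @export
mw_discrepancy <- function(mw_estimated, mw_sequence) {
  if (any(mw_estimated <= 0) || any(mw_sequence <= 0))
    stop("molecular weights must be positive", call. = FALSE)
  round(100 * abs(mw_estimated - mw_sequence) / mw_sequence, 1)
}

#' Porod-volume molecular weight estimate
#'
#' The Porod invariant \eqn{Q = \int_0^\infty q^2 I(q)\,dq} is evaluated by
#' trapezoidal quadrature over the measured range, extended analytically at
#' both ends: below `q_min` by the Guinier form with the fitted
#' \eqn{(I_0, R_g)}, and above `q_max` by the Porod law \eqn{I = K/q^4} with
#' K estimated from the high-q tail. The Porod volume is
#' \eqn{V_p = 2\pi^2 I_0/Q} and the molecular weight \eqn{V_p / 1.66} Da
#' (the packing divisor is overridable).
#'
#' @param profile SAXS profile (`q`, `I`, optional `sigma`).
#' @param i0,rg Zero-angle intensity and radius of gyration; computed by
#'   [guinier_fit()] when omitted.
#' @param divisor Volume-to-mass divisor, cubic Angstrom per Da.
#' @param min_qrg_reach Required reach of the data, `q_max * Rg`; shorter
#'   profiles cannot anchor the Porod tail and raise an error.
#' @return A list with `mw_kda`, `porod_volume_A3`, `invariant_q`, `i0`, `rg`.
#' @export
porod_mw <- function(profile, i0 = NULL, rg = NULL, divisor = 1.66,
                     min_qrg_reach = 5) {
  d <- check_profile(profile)
  if (is.null(i0) || is.null(rg)) {
    g <- guinier_fit(d)
    if (is.null(i0)) i0 <- g$i0
    if (is.null(rg)) rg <- g$rg
  }
  qmax <- max(d$q)
  if (qmax * rg < min_qrg_reach)
    stop("insufficient high-q coverage: q_max * Rg = ",
         format(qmax * rg, digits = 3), " but >= ", min_qrg_reach,
         " is required for the Porod tail", call. = FALSE)
  # measured part
  Q_mid <- trapz(d$q, d$q^2 * d$I)
  # q -> 0 by the Guinier form
  q_lo <- seq(0, min(d$q), length.out = 50)
  Q_lo <- trapz(q_lo, q_lo^2 * i0 * exp(-q_lo^2 * rg^2 / 3))
  # q -> Inf by the Porod law; K averaged over the top 30% of the q-range so
  # that form-factor oscillations of q^4*I average out over full periods
  tail_idx <- which(d$q >= 0.7 * qmax)
  K <- mean(d$q[tail_idx]^4 * d$I[tail_idx])
  Q_hi <- K / qmax  # integral of K/q^2 from qmax to Inf
  Q <- Q_lo + Q_mid + Q_hi
  vp <- 2 * pi^2 * i0 / Q
  list(mw_kda = vp / divisor / 1000, porod_volume_A3 = vp,
       invariant_q = Q, i0 = i0, rg = rg)
}
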