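#' Define a mass-action equilibrium model
#'
#' An equilibrium model lists free components (metal ion, chelator, protein
#' site, ...) and the complexes they form, each with an overall (cumulative)
#' formation constant. Concentrations are in molar throughout; a formation
#' constant for a complex of total stoichiometry \eqn{\Sigma s} has units
#' \eqn{M^{1-\Sigma s}} and is supplied as \eqn{\log_{10}\beta}.
#'
#' @param components Character vector of unique component names.
#' @param complexes Named list; each element is a list with fields `stoich`
#'   (named non-negative integer vector over the components, at least one
#'   positive entry) and `log_beta` (finite `log10` cumulative formation
#'   constant).
#' @param temperature Temperature in kelvin (metadata; speciation itself is
#'   isothermal).
#' @return An object of class `eq_model` with the stoichiometry matrix laid
#'   out complexes-by-components.
#' @examples
#' # Cu(i) partitioned between a bis-chelator complex and a protein site
#' eq_model(
#'   components = c("Cu", "BCS", "P"),
#'   complexes = list(
#'     CuBCS2 = list(stoich = c(Cu = 1, BCS = 2), log_beta = 19.8),
#'     CuP    = list(stoich = c(Cu = 1, P = 1),   log_beta = 16.6)
#'   )
#' )
#' @export
eq_model <- function(components, complexes, temperature = 298.15) {
  stopifnot(is.character(components), length(components) >= 1,
            !anyDuplicated(components))
  if (length(complexes) && is.null(names(complexes)))
    stop("`complexes` must be a named list", call. = FALSE)
  S <- matrix(0, nrow = length(complexes), ncol = length(components),
              dimnames = list(names(complexes), components))
  log_beta <- numeric(length(complexes))
  for (i in seq_along(complexes)) {
    cp <- complexes[[i]]
    st <- cp$stoich
    if (is.null(names(st)) || !all(names(st) %in% components))
      stop("complex '", names(complexes)[i],
           "' has stoichiometry over unknown components", call. = FALSE)
    if (any(st < 0) || any(st != round(st)) || !any(st > 0))
      stop("stoichiometry must be non-negative integers with at least one ",
           "positive entry (complex '", names(complexes)[i], "')",
           call. = FALSE)
    if (!is.finite(cp$log_beta))
      stop("log_beta must be finite (complex '", names(complexes)[i], "')",
           call. = FALSE)
    S[i, names(st)] <- st
    log_beta[i] <- cp$log_beta
  }
  structure(list(components = components, stoich = S, log_beta = log_beta,
                 temperature = temperature),
            class = "eq_model")
}

#' @export
print.eq_model <- function(x, ...) {
  cat("<eq_model> ", length(x$components), " components, ",
      nrow(x$stoich), " complexes, T = ", x$temperature, " K\n", sep = "")
  for (i in seq_len(nrow(x$stoich))) {
    st <- x$stoich[i, ]
    cat("  ", rownames(x$stoich)[i], ": ",
        paste(paste0(st[st > 0], " ", names(st)[st > 0]), collapse = " + "),
        "  log10(beta) = ", x$log_beta[i], "\n", sep = "")
  }
  invisible(x)
}

# Replace the formation constants of named complexes; used by the fitter.
set_log_beta <- function(model, values) {
  idx <- match(names(values), rownames(model$stoich))
  if (anyNA(idx)) stop("unknown complex name in `values`", call. = FALSE)
  model$log_beta[idx] <- as.numeric(values)
  model
}

# Damped Newton solve of the mass-balance system for a single point, in log
# free-concentration space (guarantees positivity even with beta ~ 1e20).
# S: complexes x components; returns c(free..., complex...).
solve_point <- function(S, log_beta, totals, tol = 1e-11, maxit = 200L) {
  ncomp <- ncol(S)
  active <- totals > 0
  # components with zero total carry zero free conc and kill their complexes
  keep_cplx <- if (nrow(S)) apply(S, 1, function(s) all(s[!active] == 0)) else logical(0)
  Sa <- S[keep_cplx, active, drop = FALSE]
  lb <- log_beta[keep_cplx] * log(10)
  Ta <- totals[active]
  na <- length(Ta)
  out_free <- numeric(ncomp)
  out_cplx <- numeric(nrow(S))
  if (na > 0) {
    sol <- NULL
    starts <- list(fixed_point_start(Sa, lb, Ta), log(Ta * 0.5),
                   log(Ta * 1e-6), log(Ta) - 25, log(Ta) - 60)
    for (start in starts) {
      sol <- newton_speciation(Sa, lb, Ta, start, tol, maxit)
      if (sol$converged) break
    }
    if (!sol$converged)
      stop("speciation solver failed to converge (max residual ",
           format(sol$err, digits = 3), ") for totals [",
           paste(format(totals, digits = 4), collapse = ", "), "]",
           call. = FALSE)
    out_free[active] <- exp(sol$u)
    out_cplx[keep_cplx] <- sol$cplx
  }
  c(out_free, out_cplx)
}

# Damped multiplicative mass-balance iteration; slow but globally stable,
# used only to produce a starting point for the Newton iteration.
fixed_point_start <- function(S, lb, Tt, n_iter = 200L, omega = 0.5) {
  u <- log(Tt * 0.5)
  nc <- nrow(S)
  for (i in seq_len(n_iter)) {
    cc <- if (nc) exp(lb + drop(S %*% u)) else numeric(0)
    tot <- exp(u) + (if (nc) drop(crossprod(S, cc)) else 0)
    u <- u + omega * (log(Tt) - log(tot))
    if (max(abs(log(Tt) - log(tot))) < 1e-3) break
  }
  u
}

newton_speciation <- function(S, lb, Tt, u, tol, maxit) {
  nc <- nrow(S)
  resid <- function(u) {
    x <- exp(u)
    cc <- if (nc) exp(lb + drop(S %*% u)) else numeric(0)
    f <- x + (if (nc) drop(crossprod(S, cc)) else 0) - Tt
    list(f = f, x = x, cc = cc, err = max(abs(f) / Tt))
  }
  r <- resid(u)
  for (it in seq_len(maxit)) {
    if (r$err <= tol) return(list(u = u, cplx = r$cc, converged = TRUE, err = r$err))
    J <- diag(r$x, length(u))
    if (nc) J <- J + t(S) %*% (S * r$cc)
    du <- tryCatch(solve(J, -r$f), error = function(e) NULL)
    if (is.null(du)) return(list(u = u, converged = FALSE, err = r$err))
    du <- pmin(pmax(du, -10), 10)
    lam <- 1
    repeat {
      r_new <- resid(u + lam * du)
      if (all(is.finite(r_new$f)) && r_new$err < r$err) break
      lam <- lam / 2
      if (lam < 1e-12) return(list(u = u, converged = r$err <= tol * 10, err = r$err))
    }
    u <- u + lam * du
    r <- r_new
  }
  list(u = u, cplx = r$cc, converged = r$err <= tol, err = r$err)
}

#' Solve mass-action speciation
#'
#' Computes free and complex concentrations satisfying every mass balance and
#' every mass-action law simultaneously, by damped Newton iteration on the
#' log free concentrations with an analytic Jacobian. Log-space iteration
#' keeps all concentrations strictly positive even for formation constants
#' spanning twenty orders of magnitude.
#'
#' @param model An [eq_model()].
#' @param totals Either a named numeric vector of total concentrations (M),
#'   or a data frame with one column per component (one speciation problem
#'   per row).
#' @param tol Relative mass-balance tolerance.
#' @return A tibble with one row per input point: columns `free_<component>`
#'   and one column per complex, all in M.
#' @examples
#' m <- eq_model(c("Cu", "BCS"),
#'               list(CuBCS2 = list(stoich = c(Cu = 1, BCS = 2), log_beta = 19.8)))
#' solve_speciation(m, c(Cu = 22e-6, BCS = 60e-6))
#' @export
solve_speciation <- function(model, totals, tol = 1e-11) {
  stopifnot(inherits(model, "eq_model"))
  if (is.data.frame(totals)) {
    miss <- setdiff(model$components, names(totals))
    if (length(miss)) stop("missing total column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    M <- as.matrix(totals[model$components])
  } else {
    if (!all(model$components %in% names(totals)))
      stop("`totals` must name every component", call. = FALSE)
    M <- matrix(totals[model$components], nrow = 1,
                dimnames = list(NULL, model$components))
  }
  if (any(M < 0)) stop("total concentrations must be non-negative", call. = FALSE)
  nsp <- length(model$components) + nrow(model$stoich)
  res <- t(vapply(seq_len(nrow(M)), function(i) {
    solve_point(model$stoich, model$log_beta,
                stats::setNames(M[i, ], model$components), tol = tol)
  }, numeric(nsp)))
  colnames(res) <- c(paste0("free_", model$components), rownames(model$stoich))
  tibble::as_tibble(res)
}

#' Simulate a titration signal from an equilibrium model
#'
#' Forward model of a spectroscopic titration: at each point the speciation
#' is solved and the signal is `baseline + sum(response[s] * conc[s])` over
#' the species named in `response` (molar response = extinction coefficient
#' times pathlength).
#'
#' @param model An [eq_model()].
#' @param totals Data frame of per-point total concentrations (M), one column
#'   per component. Extra columns are carried through.
#' @param response Named numeric vector of molar responses; names must be
#'   species of the model (`free_<component>` or complex names).
#' @param baseline Signal offset.
#' @return The input totals as a tibble with a `signal` column appended.
#' @export
simulate_titration <- function(model, totals, response, baseline = 0) {
  sp <- solve_speciation(model, totals)
  bad <- setdiff(names(response), names(sp))
  if (length(bad))
    stop("response names not species of the model: ",
         paste(bad, collapse = ", "), call. = FALSE)
  sig <- baseline + as.matrix(sp[names(response)]) %*% response
  dplyr::mutate(tibble::as_tibble(totals), signal = drop(sig))
}
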