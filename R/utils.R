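#' Gaussian noise specification for the synthetic-data generators
#'
#' Every generator in the package takes a `noise_spec` so that synthetic data
#' are reproducible: the same seed and parameters always yield the same data.
#'
#' @param scale Noise scale. Interpreted as a relative fraction of the signal
#'   when `relative = TRUE`, otherwise as an absolute standard deviation in
#'   signal units.
#' @param relative Logical; is `scale` relative to the signal magnitude?
#' @param seed Integer seed, or `NULL` to draw from the current RNG state.
#' @return A list of class `noise_spec`.
#' @examples
#' noise_spec(0.01, seed = 1)
#' @export
noise_spec <- function(scale = 0, relative = TRUE, seed = NULL) {
  stopifnot(is.numeric(scale), length(scale) == 1, scale >= 0)
  structure(list(scale = scale, relative = relative, seed = seed),
            class = "noise_spec")
}

# Add Gaussian noise to `x` under a noise_spec; restores the caller's RNG
# state when the spec carries a seed.
apply_noise <- function(x, spec) {
  if (is.null(spec)) return(x)
  stopifnot(inherits(spec, "noise_spec"))
  if (spec$scale == 0) return(x)
  sd <- if (spec$relative) spec$scale * abs(x) else rep(spec$scale, length(x))
  with_local_seed(spec$seed, x + stats::rnorm(length(x), 0, sd))
}

# Evaluate `expr` under `seed` without disturbing the global RNG stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Trapezoid-rule quadrature weights for an arbitrary strictly increasing grid.
trapezoid_weights <- function(x) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  dx <- diff(x)
  c(dx[1], dx[-1] + dx[-(n - 1)], dx[n - 1]) / 2
}

trapz <- function(x, y) sum(trapezoid_weights(x) * y)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
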