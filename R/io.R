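#' Read a titration CSV
#'
#' Expects a header row with one `total_<component>` column per component
#' and a `signal` column; an optional `experiment` column groups points.
#' Concentrations are molar unless `units = "uM"`, in which case all
#' `total_*` columns are converted from micromolar.
#'
#' @param path File path.
#' @param units `"M"` or `"uM"`.
#' @return A tibble.
#' @export
read_titration_csv <- function(path, units = c("M", "uM")) {
  units <- match.arg(units)
  d <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  if (!"signal" %in% names(d)) stop("no `signal` column in ", path, call. = FALSE)
  tot <- grep("^total_", names(d), value = TRUE)
  if (!length(tot)) stop("no `total_*` columns in ", path, call. = FALSE)
  if (units == "uM") d[tot] <- d[tot] * 1e-6
  d
}

#' Read a 3-column SAXS profile (.dat)
#'
#' Whitespace-separated `q I sigma` (sigma optional), `#` comment lines
#' skipped. q is assumed to be in 1/Angstrom; profiles whose q-range looks
#' like 1/nm (maximum above `nm_threshold`) are converted, unless `q_unit`
#' overrides the heuristic.
#'
#' @param path File path.
#' @param q_unit `"auto"`, `"A"` (1/Angstrom) or `"nm"` (1/nm).
#' @param nm_threshold Heuristic: a maximum q above this value (1/Angstrom
#'   would be unusually wide-angle) is taken to indicate 1/nm data.
#' @return A tibble with columns `q`, `I` and, when present, `sigma`.
#' @export
read_saxs_dat <- function(path, q_unit = c("auto", "A", "nm"),
                          nm_threshold = 2.0) {
  q_unit <- match.arg(q_unit)
  d <- utils::read.table(path, comment.char = "#", header = FALSE,
                         fill = TRUE)
  d <- d[stats::complete.cases(d[, 1:2]), , drop = FALSE]
  out <- tibble::tibble(q = as.numeric(d[[1]]), I = as.numeric(d[[2]]))
  if (ncol(d) >= 3 && !all(is.na(d[[3]]))) out$sigma <- as.numeric(d[[3]])
  is_nm <- switch(q_unit, nm = TRUE, A = FALSE,
                  auto = max(out$q) > nm_threshold)
  if (is_nm) {
    out$q <- out$q / 10
    message("q interpreted as 1/nm and converted to 1/Angstrom")
  }
  out
}

#' Read a 2-column peak list or distribution
#'
#' Whitespace- or comma-separated `x intensity` pairs with optional `#`
#' comments; used for centroided m/z peak lists and CCS distributions.
#'
#' @param path File path.
#' @param col_names Names for the two columns.
#' @return A tibble.
#' @export
read_peaklist <- function(path, col_names = c("mz", "intensity")) {
  d <- utils::read.table(path, comment.char = "#", header = FALSE,
                         sep = "", dec = ".")
  if (ncol(d) == 1)
    d <- utils::read.table(path, comment.char = "#", header = FALSE, sep = ",")
  stopifnot(ncol(d) >= 2)
  out <- tibble::tibble(a = as.numeric(d[[1]]), b = as.numeric(d[[2]]))
  names(out) <- col_names[1:2]
  out
}
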