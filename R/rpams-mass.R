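# Monoisotopic residue masses of the 20 standard amino acids (Da), i.e. the
# mass of the residue as incorporated in a peptide chain (minus water).
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

MASS_WATER  <- 18.010565
MASS_PROTON <- 1.007276
MASS_H      <- 1.0078250319
MASS_D      <- 2.014102  # deuterium; d5 - h5 adduct shift = 5 * (2H - 1H)

#' Cysteine-alkylation adduct library
#'
#' Monoisotopic masses added to a cysteine on Michael addition of
#' N-ethylmaleimide (NEM, C6H7NO2) and its pentadeuterated form (d5-NEM,
#' C6H2D5NO2). The isotope-coded pair differs by 5 x (2H - 1H) = 5.03138 Da,
#' read out as a nominal 5 Da shift in the mass spectrum.
#'
#' @return A tibble with columns `adduct` and `mass` (Da).
#' @examples
#' adduct_library()
#' @export
adduct_library <- function() {
  tibble::tibble(
    adduct = c("h5_nem", "d5_nem"),
    mass = c(125.04768, 125.04768 + 5 * (MASS_D - MASS_H))
  )
}

split_residues <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(aa, names(RESIDUE_MASS))
  if (length(bad))
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  aa
}

#' Monoisotopic [M+H]+ mass of a peptide
#'
#' Sum of the monoisotopic residue masses plus one water (free N- and
#' C-termini) plus one proton. Optional modifications add the adduct mass at
#' the stated residue; alkylation adducts are only accepted on cysteine.
#'
#' @param sequence One-letter amino-acid string (20 standard residues).
#' @param modifications Optional data frame with columns `position` (1-based
#'   residue index) and `adduct` (a name in [adduct_library()]).
#' @param adducts Adduct mass table, by default [adduct_library()].
#' @return Monoisotopic `[M+H]+` in Da.
#' @examples
#' peptide_mh_mass("DKVCSRRIRNLLA")
#' @export
peptide_mh_mass <- function(sequence, modifications = NULL,
                            adducts = adduct_library()) {
  aa <- split_residues(sequence)
  m <- sum(RESIDUE_MASS[aa]) + MASS_WATER + MASS_PROTON
  if (!is.null(modifications) && nrow(modifications)) {
    stopifnot(all(c("position", "adduct") %in% names(modifications)))
    for (i in seq_len(nrow(modifications))) {
      pos <- modifications$position[i]
      if (pos < 1 || pos > length(aa))
        stop("modification position out of range", call. = FALSE)
      if (aa[pos] != "C")
        stop("alkylation adduct on non-cysteine residue at position ", pos,
             call. = FALSE)
      j <- match(modifications$adduct[i], adducts$adduct)
      if (is.na(j)) stop("unknown adduct '", modifications$adduct[i], "'",
                         call. = FALSE)
      m <- m + adducts$mass[j]
    }
  }
  m
}

#' Masses of the isotope-labelled forms of a cysteine-containing peptide
#'
#' Applies a labelling pattern over the peptide's cysteines (in sequence
#' order) and returns the `[M+H]+` of the resulting isotopologue. A peptide
#' with n cysteines yields n + 1 ratio-distinguishable mass classes spaced by
#' the d5/h5 adduct difference.
#'
#' @param sequence Peptide sequence.
#' @param pattern Character vector over the cysteines, each one of `"d5"`,
#'   `"h5"`, `"none"`.
#' @return A one-row tibble: `species` (e.g. `"d5/h5"`), `mass` (Da),
#'   `n_d5`.
#' @examples
#' modified_peptide_masses("SSAVTEVRCNCM", c("d5", "h5"))
#' @export
modified_peptide_masses <- function(sequence, pattern) {
  aa <- split_residues(sequence)
  cys <- which(aa == "C")
  if (length(pattern) != length(cys))
    stop("pattern length (", length(pattern), ") != number of cysteines (",
         length(cys), ")", call. = FALSE)
  if (!all(pattern %in% c("d5", "h5", "none")))
    stop("pattern entries must be 'd5', 'h5' or 'none'", call. = FALSE)
  keep <- pattern != "none"
  mods <- tibble::tibble(position = cys[keep],
                         adduct = paste0(pattern[keep], "_nem"))
  tibble::tibble(
    species = paste(pattern, collapse = "/"),
    mass = peptide_mh_mass(sequence, mods),
    n_d5 = sum(pattern == "d5"))
}

#' b- and y-series fragment-ion m/z values
#'
#' Singly-protonated b ions are the N-terminal residue sums plus a proton;
#' y ions are C-terminal sums plus water and a proton. Modifications are
#' carried by whichever fragment contains the modified residue. For charge z
#' the m/z is `(neutral + z * proton)/z`. The complementarity identity
#' `b_i + y_(n-i) = [M+H]+ + proton` holds exactly at charge 1.
#'
#' @param sequence Peptide sequence.
#' @param series Which series to return, subset of `c("b", "y")`.
#' @param max_charge Highest charge state (>= 1).
#' @param modifications As in [peptide_mh_mass()].
#' @return Tibble with columns `series`, `index`, `charge`, `mz`.
#' @export
fragment_ion_masses <- function(sequence, series = c("b", "y"),
                                max_charge = 1L, modifications = NULL) {
  if (max_charge < 1) stop("charge must be >= 1", call. = FALSE)
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  aa <- split_residues(sequence)
  n <- length(aa)
  res <- RESIDUE_MASS[aa]
  mod_mass <- numeric(n)
  if (!is.null(modifications) && nrow(modifications)) {
    ad <- adduct_library()
    for (i in seq_len(nrow(modifications))) {
      pos <- modifications$position[i]
      mod_mass[pos] <- mod_mass[pos] +
        ad$mass[match(modifications$adduct[i], ad$adduct)]
    }
  }
  res <- res + mod_mass
  out <- list()
  if ("b" %in% series) {
    neutral <- unname(cumsum(res)[-n])  # b_n is not a fragment
    out$b <- tibble::tibble(series = "b", index = seq_len(n - 1),
                            neutral = neutral)
  }
  if ("y" %in% series) {
    neutral <- unname(rev(cumsum(rev(res)))[-1]) + MASS_WATER
    out$y <- tibble::tibble(series = "y", index = rev(seq_len(n - 1)),
                            neutral = neutral)
  }
  frags <- dplyr::bind_rows(out)
  tidyr::crossing(frags, charge = seq_len(max_charge)) |>
    dplyr::mutate(mz = (.data$neutral + .data$charge * MASS_PROTON) /
                    .data$charge) |>
    dplyr::select("series", "index", "charge", "mz") |>
    dplyr::arrange(.data$series, .data$index, .data$charge)
}
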