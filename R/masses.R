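# Monoisotopic mass arithmetic for peptides and b/y fragment ions.
# All masses in Da, m/z in Thomson. Values are the standard monoisotopic
# constants; the SILAC shifts correspond to [13C6,15N2]-Lys and
# [13C6,15N4]-Arg.

.MASS_PROTON <- 1.00727646688
.MASS_WATER <- 18.0105646863
.MASS_CAM <- 57.021464     # carbamidomethyl on Cys
.MASS_HEAVY_K <- 8.014199  # 13C6 15N2 lysine
.MASS_HEAVY_R <- 10.008269 # 13C6 15N4 arginine

.RESIDUE_MASS <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

.AA_REGEX <- "^[ACDEFGHIKLMNPQRSTVWY]+$"

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("'sequence' must be a single non-empty string", call. = FALSE)
  }
  if (!grepl(.AA_REGEX, sequence)) {
    bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWY]", sequence)
    stop(sprintf("invalid residue '%s' at position %d in sequence '%s'",
                 substr(sequence, bad, bad), bad, sequence), call. = FALSE)
  }
  invisible(sequence)
}

.residues <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1L]]

# neutral monoisotopic mass of the residue chain (no water)
.chain_mass <- function(residues, fixed_cys_cam) {
  m <- sum(.RESIDUE_MASS[residues])
  if (fixed_cys_cam) m <- m + .MASS_CAM * sum(residues == "C")
  m
}

.heavy_shift <- function(cterm) {
  switch(cterm, K = .MASS_HEAVY_K, R = .MASS_HEAVY_R,
         stop("heavy label requires a C-terminal K or R residue",
              call. = FALSE))
}

#' Monoisotopic precursor m/z of a peptide
#'
#' Computes the monoisotopic m/z of a protonated peptide, optionally with
#' fixed carbamidomethylation on cysteine and a SILAC heavy label
#' (+8.014199 Da for C-terminal Lys, +10.008269 Da for C-terminal Arg).
#'
#' @param sequence Peptide sequence (uppercase one-letter codes).
#' @param charge Positive integer charge state.
#' @param label `"light"` or `"heavy"`. Heavy is only valid for peptides
#'   ending in K or R.
#' @param fixed_cys_cam Apply +57.021464 Da to every cysteine (default TRUE,
#'   matching chloroacetamide alkylation).
#' @return Precursor m/z in Thomson.
#' @examples
#' peptide_mz("INIPFDELK", 2)
#' peptide_mz("INIPFDELK", 2, label = "heavy") - peptide_mz("INIPFDELK", 2)
#' @export
peptide_mz <- function(sequence, charge, label = c("light", "heavy"),
                       fixed_cys_cam = TRUE) {
  label <- match.arg(label)
  .check_sequence(sequence)
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != as.integer(charge)) {
    stop("'charge' must be a positive integer", call. = FALSE)
  }
  res <- .residues(sequence)
  m <- .chain_mass(res, fixed_cys_cam) + .MASS_WATER
  if (label == "heavy") m <- m + .heavy_shift(res[length(res)])
  (m + charge * .MASS_PROTON) / charge
}

#' Monoisotopic m/z of a b- or y-series fragment ion
#'
#' Standard singly-to-multiply protonated b/y fragment masses. The SILAC
#' heavy shift is carried by y-ions only (they contain the C-terminal K/R);
#' b-ions are label-invariant.
#'
#' @inheritParams peptide_mz
#' @param series `"b"` or `"y"`.
#' @param ordinal Fragment ordinal, `1 <= ordinal <= nchar(sequence) - 1`.
#' @param product_charge Positive integer product ion charge.
#' @return Fragment m/z in Thomson.
#' @examples
#' fragment_mz("INIPFDELK", "y", 7, 1)
#' @export
fragment_mz <- function(sequence, series = c("b", "y"), ordinal,
                        product_charge = 1L, label = c("light", "heavy"),
                        fixed_cys_cam = TRUE) {
  series <- match.arg(series)
  label <- match.arg(label)
  .check_sequence(sequence)
  n <- nchar(sequence)
  if (!is.numeric(ordinal) || length(ordinal) != 1L || ordinal < 1L ||
      ordinal > n - 1L) {
    stop(sprintf("fragment ordinal must be in [1, %d] for '%s'", n - 1L,
                 sequence), call. = FALSE)
  }
  if (product_charge < 1L) stop("'product_charge' must be >= 1", call. = FALSE)
  res <- .residues(sequence)
  if (series == "b") {
    m <- .chain_mass(res[seq_len(ordinal)], fixed_cys_cam)
  } else {
    frag <- res[seq.int(n - ordinal + 1L, n)]
    m <- .chain_mass(frag, fixed_cys_cam) + .MASS_WATER
    if (label == "heavy") m <- m + .heavy_shift(res[n])
  }
  if (series == "b" && label == "heavy") {
    # b-ions never contain the C-terminal residue: validate the peptide can
    # carry the label but add no shift
    .heavy_shift(res[n])
  }
  (m + product_charge * .MASS_PROTON) / product_charge
}
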