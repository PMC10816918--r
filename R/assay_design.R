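# In silico assay design: tryptic digestion, proteotypic candidate
# selection, iRT calibration and scheduled retention-time windows,
# top-transition picking, transition-list export.

#' Tryptic digestion without missed cleavages
#'
#' Cleaves C-terminal to K or R, suppressed when the following residue is
#' proline (Keil rule). The returned peptides tile the protein: their
#' concatenation reconstructs the input sequence.
#'
#' @param sequence Protein sequence, uppercase one-letter codes.
#' @param protein_id Optional protein identifier carried into the output.
#' @return A data.frame with columns `protein_id`, `sequence`, `start`,
#'   `end`, `length` (1-based inclusive residue coordinates).
#' @examples
#' digest_tryptic("AKRPKW")$sequence  # "AK" "RPK" "W"
#' @export
digest_tryptic <- function(sequence, protein_id = NA_character_) {
  .check_sequence(sequence)
  res <- .residues(sequence)
  n <- length(res)
  # cut after position i when res[i] is K/R and res[i+1] is not P
  cuts <- which(res %in% c("K", "R"))
  cuts <- cuts[cuts < n & res[cuts + 1L] != "P"]
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  data.frame(
    protein_id = protein_id,
    sequence = substring(sequence, starts, ends),
    start = starts,
    end = ends,
    length = ends - starts + 1L,
    stringsAsFactors = FALSE
  )
}

#' Select proteotypic candidate peptides
#'
#' Keeps tryptic peptides 7-21 residues long, free of methionine, and whose
#' sequence occurs in exactly one protein of the supplied background set
#' (exact full-sequence uniqueness). Output order follows position in the
#' protein.
#'
#' @param peptides data.frame as returned by [digest_tryptic()] for one
#'   protein.
#' @param background data.frame of peptides from the whole reference set
#'   (columns `protein_id`, `sequence`), which must include the target
#'   protein's own peptides.
#' @param min_length,max_length Length window (defaults 7 and 21).
#' @return The filtered subset of `peptides`.
#' @export
select_candidate_peptides <- function(peptides, background,
                                      min_length = 7L, max_length = 21L) {
  if (is.null(background) || nrow(background) == 0L) {
    stop("'background' peptide set must be non-empty", call. = FALSE)
  }
  stopifnot(all(c("protein_id", "sequence") %in% names(background)))
  keep <- peptides$length >= min_length & peptides$length <= max_length &
    !grepl("M", peptides$sequence, fixed = TRUE)
  # uniqueness: sequence maps to exactly one background protein
  prot_per_seq <- tapply(background$protein_id, background$sequence,
                         function(p) length(unique(p)))
  n_prot <- prot_per_seq[peptides$sequence]
  n_prot[is.na(n_prot)] <- 0L
  keep <- keep & n_prot == 1L
  out <- peptides[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Fit an iRT calibration line
#'
#' Ordinary least squares of measured retention time (minutes) on reference
#' iRT for a set of standard peptides. The calibration is rejected when the
#' fit quality falls below `min_r_squared`.
#'
#' @param reference_irt Numeric vector of reference iRT values.
#' @param measured_rt Numeric vector of measured retention times (minutes).
#' @param min_r_squared Minimum acceptable r-squared (default 0.99).
#' @return An object of class `irt_calibration` with elements `slope`
#'   (min/iRT), `intercept` (min), `r_squared` and `n_standards`.
#' @examples
#' fit_irt_calibration(c(0, 50, 100), c(5, 10, 15))
#' @export
fit_irt_calibration <- function(reference_irt, measured_rt,
                                min_r_squared = 0.99) {
  if (length(reference_irt) != length(measured_rt)) {
    stop("reference and measured vectors must have equal length",
         call. = FALSE)
  }
  ok <- is.finite(reference_irt) & is.finite(measured_rt)
  x <- reference_irt[ok]; y <- measured_rt[ok]
  if (length(x) < 2L) stop("need at least 2 iRT standards", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("iRT standards have zero variance in reference iRT", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2L])
  intercept <- unname(fit$coefficients[1L])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  if (r2 < min_r_squared) {
    stop(sprintf("iRT calibration rejected: r^2 = %.4f < %.4f",
                 r2, min_r_squared), call. = FALSE)
  }
  if (slope <= 0) stop("iRT calibration slope must be positive", call. = FALSE)
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         n_standards = length(x)),
    class = "irt_calibration"
  )
}

#' @export
print.irt_calibration <- function(x, ...) {
  cat(sprintf(
    "iRT calibration: rt = %.4f * irt + %.4f (r^2 = %.5f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n_standards))
  invisible(x)
}

.check_cal <- function(cal) {
  if (!inherits(cal, "irt_calibration")) {
    stop("'cal' must be an 'irt_calibration' object", call. = FALSE)
  }
  invisible(cal)
}

#' Convert measured retention time to iRT
#' @param rt Retention time in minutes.
#' @param cal An [fit_irt_calibration()] result.
#' @return iRT units.
#' @export
rt_to_irt <- function(rt, cal) {
  .check_cal(cal)
  (rt - cal$intercept) / cal$slope
}

#' Predict retention time from iRT
#' @param irt iRT value(s).
#' @param cal An [fit_irt_calibration()] result.
#' @return Retention time in minutes.
#' @export
irt_to_rt <- function(irt, cal) {
  .check_cal(cal)
  cal$slope * irt + cal$intercept
}

#' Scheduled acquisition window for a peptide
#'
#' Centers a window of `2 * half_width` minutes on the predicted retention
#' time; the start is clipped at zero.
#'
#' @inheritParams irt_to_rt
#' @param half_width Half window width in minutes (default 2.5).
#' @return A two-column matrix with `start` and `end` in minutes.
#' @export
predict_rt_window <- function(irt, cal, half_width = 2.5) {
  .check_cal(cal)
  if (!is.numeric(half_width) || half_width <= 0) {
    stop("'half_width' must be > 0", call. = FALSE)
  }
  center <- irt_to_rt(irt, cal)
  cbind(start = pmax(0, center - half_width), end = center + half_width)
}

#' Pick the most intense transitions of a precursor
#'
#' Returns the `k` fragment ions with the largest intensity. Ties are broken
#' by series letter then ordinal (lexicographic) so the selection is
#' deterministic. With fewer than `k` candidates all are returned.
#'
#' @param intensities Named numeric vector, names like `"y7"` or `"b4"`.
#' @param k Number of transitions to keep (the assay default is 3-4).
#' @return Character vector of selected fragment names, most intense first.
#' @examples
#' select_top_transitions(c(y3 = 10, y5 = 50, y7 = 40, b4 = 5), 3)
#' @export
select_top_transitions <- function(intensities, k = 3L) {
  if (length(intensities) == 0L) {
    stop("candidate transition set is empty", call. = FALSE)
  }
  if (is.null(names(intensities)) || any(!nzchar(names(intensities)))) {
    stop("'intensities' must be named by fragment ion", call. = FALSE)
  }
  if (k < 1L) stop("'k' must be >= 1", call. = FALSE)
  if (any(intensities < 0)) stop("intensities must be non-negative",
                                 call. = FALSE)
  series <- substr(names(intensities), 1L, 1L)
  ordinal <- as.integer(sub("^[by]", "", names(intensities)))
  ord <- order(-intensities, series, ordinal)
  names(intensities)[ord][seq_len(min(k, length(intensities)))]
}

#' Design a transition list from protein sequences
#'
#' Runs the full in silico design chain for each protein: tryptic digestion,
#' proteotypic candidate filtering against the supplied background (the
#' input set itself by default), and light/heavy transition enumeration for
#' charge-2 precursors with y-ions of ordinal >= `min_ordinal`.
#'
#' @param sequences Named character vector or list of protein sequences
#'   (names are protein ids), or a path to a FASTA file.
#' @param background Optional background peptide data.frame for the
#'   uniqueness filter; defaults to the digest of `sequences` itself.
#' @param transitions_per_peptide Number of y-ion transitions to enumerate
#'   per precursor (default 3).
#' @param min_ordinal Smallest fragment ordinal considered (default 3).
#' @param irt Optional named numeric vector of iRT values per peptide
#'   sequence; peptides without a value get NA.
#' @return data.frame of assay transitions (one row per fragment x label)
#'   with precursor and product m/z.
#' @export
design_assay <- function(sequences, background = NULL,
                         transitions_per_peptide = 3L, min_ordinal = 3L,
                         irt = NULL) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    sequences <- read_fasta(sequences)
  }
  sequences <- unlist(as.list(sequences))
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("protein sequences must be named", call. = FALSE)
  }
  digests <- do.call(rbind, lapply(names(sequences), function(id) {
    digest_tryptic(sequences[[id]], protein_id = id)
  }))
  if (is.null(background)) background <- digests
  rows <- list()
  for (id in names(sequences)) {
    cand <- select_candidate_peptides(
      digests[digests$protein_id == id, , drop = FALSE], background)
    for (pep in cand$sequence) {
      n <- nchar(pep)
      # spike-in SILAC needs a labeled C-terminal K/R; the protein C-terminal
      # peptide may lack one and is then unusable
      if (!substr(pep, n, n) %in% c("K", "R")) next
      ords <- seq.int(min_ordinal, n - 1L)
      ords <- utils::tail(ords, transitions_per_peptide)
      if (length(ords) == 0L) next
      for (lab in c("light", "heavy")) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein = id,
          peptide_sequence = pep,
          precursor_charge = 2L,
          precursor_mz = peptide_mz(pep, 2L, lab),
          fragment_ion = paste0("y", ords),
          product_charge = 1L,
          product_mz = vapply(ords, function(o)
            fragment_mz(pep, "y", o, 1L, lab), numeric(1)),
          isotope_label = lab,
          irt = if (is.null(irt)) NA_real_ else unname(irt[pep]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    stop("no candidate peptides survived the design filters", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
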