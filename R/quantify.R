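# Sum-then-ratio quantification: quantitative transition areas are summed
# per sample and protein (or peptide), log2 light/heavy ratios computed,
# and every sample normalized to its SEC63 ratio as a general ER membrane
# reference. A transition contributes to a sum only when both isotope
# channels are present (paired inclusion) so that censoring of one channel
# cannot bias the ratio.

.sum_group <- function(rows, by_cols) {
  # paired inclusion: a transition contributes only if both labels present;
  # the pairing key is the full transition identity regardless of the
  # summary grouping
  wide_key <- do.call(paste, c(rows[c("sample_id", .TRANSITION_KEY)],
                               sep = "\r"))
  light <- rows$isotope_label == "light"
  la <- stats::setNames(rows$area[light], wide_key[light])
  ha <- stats::setNames(rows$area[!light], wide_key[!light])
  frag <- unique(wide_key)
  l <- la[frag]; h <- ha[frag]
  ok <- !is.na(l) & !is.na(h)
  list(light_sum = sum(l[ok]), heavy_sum = sum(h[ok]),
       n_used = sum(ok))
}

.ratio_table <- function(report, qc = NULL, level = c("protein", "peptide")) {
  level <- match.arg(level)
  validate_transition_report(report)
  if (!is.null(qc)) {
    # per-sample peptide exclusion for precursors failing the rdotp filter
    rec <- qc$records
    fail <- rec[!rec$pass_rdotp, , drop = FALSE]
    if (nrow(fail) > 0L) {
      failkey <- paste(fail$sample_id, fail$protein, fail$peptide_sequence,
                       fail$precursor_charge, sep = "\r")
      report <- report[!(.pep_key(report) %in% failkey), , drop = FALSE]
    }
  }
  if (nrow(report) == 0L) {
    return(data.frame(sample_id = character(0), protein = character(0),
                      light_sum = numeric(0), heavy_sum = numeric(0),
                      log2_ratio = numeric(0),
                      n_transitions_used = integer(0),
                      stringsAsFactors = FALSE))
  }
  by_cols <- if (level == "protein") {
    c("sample_id", "protein")
  } else {
    c("sample_id", "protein", "peptide_sequence", "precursor_charge")
  }
  # paired inclusion, vectorized: align light/heavy per (sample, fragment)
  light <- report[report$isotope_label == "light", , drop = FALSE]
  heavy <- report[report$isotope_label == "heavy", , drop = FALSE]
  u <- unique(report[c("sample_id", .TRANSITION_KEY)])
  ukey <- paste(u$sample_id, .trans_id(u), sep = "\r")
  la <- light$area[match(ukey, paste(light$sample_id, .trans_id(light),
                                     sep = "\r"))]
  ha <- heavy$area[match(ukey, paste(heavy$sample_id, .trans_id(heavy),
                                     sep = "\r"))]
  ok <- !is.na(la) & !is.na(ha)
  gkey <- do.call(paste, c(u[by_cols], sep = "\r"))
  g <- factor(gkey, levels = unique(gkey))
  light_sum <- as.vector(rowsum(ifelse(ok, la, 0), g))
  heavy_sum <- as.vector(rowsum(ifelse(ok, ha, 0), g))
  n_used <- as.vector(rowsum(ok + 0L, g))
  first <- !duplicated(g)
  out <- u[first, by_cols, drop = FALSE]
  out$light_sum <- light_sum
  out$heavy_sum <- heavy_sum
  out$log2_ratio <- ifelse(light_sum > 0 & heavy_sum > 0,
                           log2(light_sum / heavy_sum), NA_real_)
  out$n_transitions_used <- n_used
  rownames(out) <- NULL
  out[out$n_transitions_used > 0L, , drop = FALSE]
}

#' Summarize one sample x protein (or peptide) group
#'
#' Reference implementations of the sum-then-ratio rule for a single
#' group of QC-passed rows: transition areas are summed per label under
#' paired inclusion and the log2 light/heavy ratio computed. The
#' table-level equivalents are [protein_ratios()] and [peptide_ratios()].
#'
#' @param rows Transition report rows for exactly one sample x protein
#'   (`summarize_protein`) or sample x peptide x precursor charge
#'   (`summarize_peptide`).
#' @return One-row data.frame with sums, `log2_ratio` (NA when either
#'   channel sum is zero) and `n_transitions_used`.
#' @export
summarize_protein <- function(rows) {
  stopifnot(nrow(rows) > 0L,
            length(unique(paste(rows$sample_id, rows$protein))) == 1L)
  s <- .sum_group(rows, c("sample_id", "protein"))
  data.frame(sample_id = rows$sample_id[1L], protein = rows$protein[1L],
             light_sum = s$light_sum, heavy_sum = s$heavy_sum,
             log2_ratio = if (s$light_sum > 0 && s$heavy_sum > 0) {
               log2(s$light_sum / s$heavy_sum)
             } else NA_real_,
             n_transitions_used = s$n_used, stringsAsFactors = FALSE)
}

#' @rdname summarize_protein
#' @export
summarize_peptide <- function(rows) {
  stopifnot(nrow(rows) > 0L, length(unique(.pep_key(rows))) == 1L)
  s <- .sum_group(rows, c("sample_id", "protein", "peptide_sequence",
                          "precursor_charge"))
  data.frame(sample_id = rows$sample_id[1L], protein = rows$protein[1L],
             peptide_sequence = rows$peptide_sequence[1L],
             precursor_charge = rows$precursor_charge[1L],
             light_sum = s$light_sum, heavy_sum = s$heavy_sum,
             log2_ratio = if (s$light_sum > 0 && s$heavy_sum > 0) {
               log2(s$light_sum / s$heavy_sum)
             } else NA_real_,
             n_transitions_used = s$n_used, stringsAsFactors = FALSE)
}

#' Per-sample per-protein light/heavy ratios
#'
#' Sums quantitative transition areas across all retained peptides of each
#' protein within each sample and computes the log2 light/heavy ratio.
#' Precursors failing the rdotp filter (per sample) are excluded when a QC
#' result is supplied.
#'
#' @param report Transition report data.frame (after masking).
#' @param qc Optional [qc_report()] result for per-sample rdotp exclusion.
#' @return data.frame with `sample_id`, `protein`, `light_sum`,
#'   `heavy_sum`, `log2_ratio`, `n_transitions_used`. Ratios with a zero
#'   or fully-censored channel are `NA` (below-LOD signals propagate as
#'   missing, never as an imputed floor).
#' @export
protein_ratios <- function(report, qc = NULL) {
  .ratio_table(report, qc, "protein")
}

#' Per-sample per-peptide light/heavy ratios
#'
#' As [protein_ratios()] but grouped at (protein, peptide, precursor
#' charge). Peptide-level views are what reveal single-peptide effects such
#' as a heterozygous variant falling inside one target peptide.
#'
#' @inheritParams protein_ratios
#' @return data.frame with `sample_id`, `protein`, `peptide_sequence`,
#'   `precursor_charge`, sums, `log2_ratio`, `n_transitions_used`.
#' @export
peptide_ratios <- function(report, qc = NULL) {
  .ratio_table(report, qc, "peptide")
}

#' Normalize log2 ratios to a reference protein
#'
#' Subtracts each sample's reference-protein (default SEC63) log2 ratio
#' from every ratio in that sample, absorbing shared loading/biological
#' variation. The reference's own normalized value is exactly 0.
#'
#' @param table Ratio table from [protein_ratios()] or [peptide_ratios()].
#' @param reference_protein Reference protein name (default `"SEC63"`).
#' @param reference_table Table to take the reference ratios from; defaults
#'   to `table` itself. Pass the protein-level table here when normalizing
#'   a peptide-level table.
#' @return `table` with an added `log2_ratio_normalized` column.
#' @export
normalize_to_reference <- function(table, reference_protein = "SEC63",
                                   reference_table = NULL) {
  if (is.null(reference_table)) reference_table <- table
  ref <- reference_table[reference_table$protein == reference_protein, ,
                         drop = FALSE]
  if (!is.null(ref$peptide_sequence)) {
    stop("'reference_table' must be a protein-level ratio table",
         call. = FALSE)
  }
  samples <- unique(table$sample_id)
  ref_val <- ref$log2_ratio[match(samples, ref$sample_id)]
  bad <- is.na(ref_val)
  if (any(bad)) {
    stop("reference protein '", reference_protein,
         "' is not quantified in sample '", samples[bad][1L], "'",
         call. = FALSE)
  }
  table$log2_ratio_normalized <-
    table$log2_ratio - ref_val[match(table$sample_id, samples)]
  table
}

#' Write a ratio table CSV
#' @param table Ratio table (protein- or peptide-level, normalized or not).
#' @param path Output path.
#' @export
write_ratio_csv <- function(table, path) {
  out <- table
  ren <- c(sample_id = "Sample", protein = "Protein",
           peptide_sequence = "Peptide", precursor_charge = "PrecursorCharge",
           light_sum = "LightSum", heavy_sum = "HeavySum",
           log2_ratio = "Log2Ratio", log2_ratio_normalized = "Log2RatioNorm",
           n_transitions_used = "NTransitions")
  names(out) <- ifelse(names(out) %in% names(ren), ren[names(out)],
                       names(out))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a ratio table CSV written by [write_ratio_csv()]
#' @param path Path to the CSV file.
#' @return Ratio table data.frame with internal snake_case columns.
#' @export
read_ratio_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  ren <- c(Sample = "sample_id", Protein = "protein",
           Peptide = "peptide_sequence", PrecursorCharge = "precursor_charge",
           LightSum = "light_sum", HeavySum = "heavy_sum",
           Log2Ratio = "log2_ratio", Log2RatioNorm = "log2_ratio_normalized",
           NTransitions = "n_transitions_used")
  names(raw) <- ifelse(names(raw) %in% names(ren), ren[names(raw)],
                       names(raw))
  raw
}
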