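# Readers and writers for every table the pipeline touches. CSV dialect is
# RFC 4180 with a required header; missing values are written as empty
# cells and additionally accepted as "#N/A" on read (the Skyline token).

.REPORT_COLS <- c("Sample", "Protein", "Peptide", "PrecursorCharge",
                  "FragmentIon", "ProductCharge", "IsotopeLabel", "Area",
                  "ApexRT", "Truncated", "FwhmDegenerate", "Coeluting")

.REPORT_INTERNAL <- c("sample_id", "protein", "peptide_sequence",
                      "precursor_charge", "fragment_ion", "product_charge",
                      "isotope_label", "area", "apex_rt", "truncated",
                      "fwhm_degenerate", "coeluting")

.TRANSITION_KEY <- c("protein", "peptide_sequence", "precursor_charge",
                     "fragment_ion", "product_charge")

.parse_num <- function(x) {
  x[x %in% c("", "#N/A", "NA")] <- NA_character_
  suppressWarnings(as.numeric(x))
}

.parse_bool <- function(x, column) {
  v <- toupper(trimws(x))
  out <- rep(NA, length(v))
  out[v %in% c("TRUE", "T", "1")] <- TRUE
  out[v %in% c("FALSE", "F", "0")] <- FALSE
  if (anyNA(out)) {
    stop(sprintf("column '%s' contains a value that is not a boolean: '%s'",
                 column, x[which(is.na(out))[1L]]), call. = FALSE)
  }
  out
}

#' Read a Skyline-style transition-level report
#'
#' Reads the long-format CSV exported from a document-grid custom report:
#' one row per (sample, protein, peptide, precursor charge, fragment ion,
#' product charge, isotope label) with peak area, apex retention time and
#' the chromatographic QC flags Truncated, FwhmDegenerate and Coeluting.
#'
#' @param path Path to the CSV file.
#' @return A validated data.frame with snake_case columns (`sample_id`,
#'   `protein`, `peptide_sequence`, `precursor_charge`, `fragment_ion`,
#'   `product_charge`, `isotope_label`, `area`, `apex_rt`, `truncated`,
#'   `fwhm_degenerate`, `coeluting`). Missing areas (`""` or `"#N/A"`)
#'   become `NA`.
#' @export
read_transition_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  unknown <- setdiff(names(raw), .REPORT_COLS)
  if (length(unknown) > 0L) {
    stop("unknown column in transition report: '", unknown[1L], "'",
         call. = FALSE)
  }
  missing_cols <- setdiff(.REPORT_COLS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("transition report is missing column '", missing_cols[1L], "'",
         call. = FALSE)
  }
  df <- data.frame(
    sample_id = raw$Sample,
    protein = raw$Protein,
    peptide_sequence = raw$Peptide,
    precursor_charge = as.integer(raw$PrecursorCharge),
    fragment_ion = raw$FragmentIon,
    product_charge = as.integer(raw$ProductCharge),
    isotope_label = tolower(raw$IsotopeLabel),
    area = .parse_num(raw$Area),
    apex_rt = .parse_num(raw$ApexRT),
    truncated = .parse_bool(raw$Truncated, "Truncated"),
    fwhm_degenerate = .parse_bool(raw$FwhmDegenerate, "FwhmDegenerate"),
    coeluting = .parse_bool(raw$Coeluting, "Coeluting"),
    stringsAsFactors = FALSE
  )
  validate_transition_report(df)
}

#' Validate a transition-report data.frame
#'
#' Enforces the report invariants: known isotope labels, valid peptide
#' sequences, non-negative areas, missing area implies missing apex RT, and
#' uniqueness of the full transition key within each sample.
#'
#' @param df Transition report data.frame (internal snake_case columns).
#' @return `df` invisibly-validated (returned unchanged).
#' @export
validate_transition_report <- function(df) {
  stopifnot(all(.REPORT_INTERNAL %in% names(df)))
  if (!all(df$isotope_label %in% c("light", "heavy"))) {
    stop("isotope_label must be 'light' or 'heavy'", call. = FALSE)
  }
  bad_seq <- !grepl(.AA_REGEX, df$peptide_sequence)
  if (any(bad_seq)) {
    stop("invalid peptide sequence: '", df$peptide_sequence[bad_seq][1L],
         "'", call. = FALSE)
  }
  if (any(!is.na(df$area) & df$area < 0)) {
    stop("negative peak area in transition report", call. = FALSE)
  }
  orphan_rt <- is.na(df$area) & !is.na(df$apex_rt)
  if (any(orphan_rt)) {
    stop("apex RT present for a missing area (row ",
         which(orphan_rt)[1L], ")", call. = FALSE)
  }
  key <- do.call(paste, c(df[c("sample_id", .TRANSITION_KEY,
                               "isotope_label")], sep = "\r"))
  if (anyDuplicated(key)) {
    d <- df[which(duplicated(key))[1L], ]
    stop(sprintf(
      "duplicate transition in sample '%s': %s %s %s/%d %s",
      d$sample_id, d$protein, d$peptide_sequence, d$fragment_ion,
      d$product_charge, d$isotope_label), call. = FALSE)
  }
  if (any(!df$precursor_charge >= 1L) || any(!df$product_charge >= 1L)) {
    stop("charges must be positive integers", call. = FALSE)
  }
  df
}

#' Write a transition report CSV
#'
#' Inverse of [read_transition_report()]; missing values are written as
#' empty cells.
#'
#' @param df Transition report data.frame.
#' @param path Output path.
#' @export
write_transition_report <- function(df, path) {
  validate_transition_report(df)
  out <- data.frame(
    Sample = df$sample_id, Protein = df$protein,
    Peptide = df$peptide_sequence, PrecursorCharge = df$precursor_charge,
    FragmentIon = df$fragment_ion, ProductCharge = df$product_charge,
    IsotopeLabel = df$isotope_label, Area = df$area, ApexRT = df$apex_rt,
    Truncated = df$truncated, FwhmDegenerate = df$fwhm_degenerate,
    Coeluting = df$coeluting, stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' The header token up to the first whitespace is the protein id. Sequences
#' are uppercased and validated against the 20 standard amino acids.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, protein id to sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: '", ids[which(duplicated(ids))[1L]], "'",
         call. = FALSE)
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for FASTA id '", ids[!nzchar(seqs)][1L], "'",
         call. = FALSE)
  }
  for (i in seq_along(seqs)) {
    if (!grepl(.AA_REGEX, seqs[[i]])) {
      bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWY]", seqs[[i]])
      stop(sprintf("invalid residue '%s' at position %d of '%s'",
                   substr(seqs[[i]], bad, bad), bad, ids[[i]]),
           call. = FALSE)
    }
  }
  stats::setNames(unname(seqs), ids)
}

#' Read a sample annotation table
#'
#' CSV with columns Sample, Group, Replicate mapping each sample to its
#' comparison group.
#'
#' @param path Path to the CSV file.
#' @return data.frame with `sample_id`, `group`, `replicate_index`.
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("Sample", "Group", "Replicate")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("annotation is missing column '", missing_cols[1L], "'",
         call. = FALSE)
  }
  ann <- data.frame(sample_id = raw$Sample, group = raw$Group,
                    replicate_index = as.integer(raw$Replicate),
                    stringsAsFactors = FALSE)
  validate_annotation(ann)
}

#' @rdname read_sample_annotation
#' @param ann Annotation data.frame to validate.
#' @export
validate_annotation <- function(ann) {
  stopifnot(all(c("sample_id", "group", "replicate_index") %in% names(ann)))
  if (anyDuplicated(ann$sample_id)) {
    stop("duplicate sample_id in annotation: '",
         ann$sample_id[which(duplicated(ann$sample_id))[1L]], "'",
         call. = FALSE)
  }
  if (any(is.na(ann$replicate_index) | ann$replicate_index < 1L)) {
    stop("replicate indices must be positive integers", call. = FALSE)
  }
  ann
}

#' Write a sample annotation CSV
#' @param ann Annotation data.frame (`sample_id`, `group`,
#'   `replicate_index`).
#' @param path Output path.
#' @export
write_sample_annotation <- function(ann, path) {
  validate_annotation(ann)
  utils::write.csv(
    data.frame(Sample = ann$sample_id, Group = ann$group,
               Replicate = ann$replicate_index),
    path, row.names = FALSE)
  invisible(path)
}

#' Read an nCounter-style count table
#'
#' CSV whose first column is `Gene` and remaining columns are samples.
#' Rows whose gene name starts with `"POS_"` are treated as positive-control
#' probes and separated from the endogenous genes.
#'
#' @param path Path to the CSV file.
#' @param housekeeping_genes Character vector of housekeeping gene names
#'   (default `c("C1orf43", "SNRPD3")`).
#' @return An object of class `ncounter_table`: list with `counts`
#'   (gene x sample integer matrix), `positive_controls` (probe x sample
#'   matrix) and `housekeeping_genes`.
#' @export
read_ncounter <- function(path, housekeeping_genes = c("C1orf43", "SNRPD3")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  if (names(raw)[1L] != "Gene") {
    stop("first column of an nCounter table must be 'Gene'", call. = FALSE)
  }
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- raw$Gene
  is_pos <- startsWith(raw$Gene, "POS_")
  ncounter_table(counts = mat[!is_pos, , drop = FALSE],
                 positive_controls = mat[is_pos, , drop = FALSE],
                 housekeeping_genes = housekeeping_genes)
}

#' Construct and validate an nCounter table object
#'
#' @param counts Gene x sample matrix of non-negative counts with gene row
#'   names and sample column names.
#' @param positive_controls Probe x sample matrix of positive counts.
#' @param housekeeping_genes Subset of `rownames(counts)` used for the
#'   housekeeping normalization step.
#' @return `ncounter_table` object.
#' @export
ncounter_table <- function(counts, positive_controls, housekeeping_genes) {
  stopifnot(is.matrix(counts), is.matrix(positive_controls))
  if (ncol(counts) != ncol(positive_controls) ||
      !identical(colnames(counts), colnames(positive_controls))) {
    stop("counts and positive controls must share identical sample columns",
         call. = FALSE)
  }
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (nrow(positive_controls) == 0L || any(positive_controls <= 0)) {
    stop("all positive-control counts must be > 0", call. = FALSE)
  }
  missing_hk <- setdiff(housekeeping_genes, rownames(counts))
  if (length(missing_hk) > 0L) {
    stop("housekeeping gene not present in count table: '",
         missing_hk[1L], "'", call. = FALSE)
  }
  structure(list(counts = counts, positive_controls = positive_controls,
                 housekeeping_genes = housekeeping_genes),
            class = "ncounter_table")
}

#' Write an nCounter table to CSV
#' @param tab An `ncounter_table`.
#' @param path Output path.
#' @export
write_ncounter <- function(tab, path) {
  stopifnot(inherits(tab, "ncounter_table"))
  all_mat <- rbind(tab$positive_controls, tab$counts)
  out <- data.frame(Gene = rownames(all_mat), all_mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a comparison result TSV
#'
#' Tab-separated with fixed column order (protein, log2fc, fold_change,
#' ci_low, ci_high, p_value, adj_p_value, n_condition, n_control); real
#' values are rendered with 6 significant digits. Peptide-level tables gain
#' `peptide` and `precursor_charge` columns after `protein`.
#'
#' @param rows Comparison data.frame from [run_comparison()].
#' @param path Output path.
#' @export
write_comparison_tsv <- function(rows, path) {
  if (is.null(rows) || nrow(rows) == 0L) {
    stop("comparison table is empty; nothing to write", call. = FALSE)
  }
  cols <- c("protein",
            intersect(c("peptide", "precursor_charge"), names(rows)),
            "log2fc", "fold_change", "ci_low", "ci_high", "p_value",
            "adj_p_value", "n_condition", "n_control")
  stopifnot(all(cols %in% names(rows)))
  out <- rows[, cols, drop = FALSE]
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a vendor-agnostic scheduled transition list
#'
#' Columns: Protein, Peptide, PrecursorMz, PrecursorCharge, FragmentIon,
#' ProductMz, ProductCharge, IsotopeLabel, iRT, CollisionEnergy (left
#' empty: collision-energy optimization is delegated to the instrument
#' software).
#'
#' @param assay Assay data.frame from [design_assay()].
#' @param path Output path.
#' @export
write_transition_list <- function(assay, path) {
  need <- c("protein", "peptide_sequence", "precursor_mz",
            "precursor_charge", "fragment_ion", "product_mz",
            "product_charge", "isotope_label", "irt")
  stopifnot(all(need %in% names(assay)))
  out <- data.frame(
    Protein = assay$protein, Peptide = assay$peptide_sequence,
    PrecursorMz = round(assay$precursor_mz, 5),
    PrecursorCharge = assay$precursor_charge,
    FragmentIon = assay$fragment_ion,
    ProductMz = round(assay$product_mz, 5),
    ProductCharge = assay$product_charge,
    IsotopeLabel = assay$isotope_label,
    iRT = assay$irt, CollisionEnergy = "",
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
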