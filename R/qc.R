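# Transition-level quality control: reference dot-product (rdotp) between
# the light and heavy fragment intensity patterns of each peptide,
# chromatographic flag triage, and study-wide masking of non-quantitative
# transitions. The manual-inspection step of the original workflow is
# replaced by a deterministic, auditable proposal rule; proposals are meant
# to be reviewed (and possibly edited) before being applied.

#' Reference dot-product of a light/heavy fragment pattern
#'
#' Normalized dot product between the light and heavy peak-area vectors of
#' one precursor, ordered by the same fragment list. 1 means identical
#' relative fragment intensities (an interference-free, correctly picked
#' peak); values drop when one channel's pattern is distorted. Missing
#' areas count as 0 — a fragment absent in one label is genuine pattern
#' disagreement.
#'
#' @param light_areas,heavy_areas Numeric vectors of equal length >= 2,
#'   ordered by the same fragments.
#' @return Value in `[0, 1]`, or `NA` when either vector has zero norm.
#' @examples
#' rdotp(c(1, 2, 3), c(2, 4, 6)) # 1
#' rdotp(c(3, 4), c(4, 3))       # 0.96
#' @export
rdotp <- function(light_areas, heavy_areas) {
  if (length(light_areas) != length(heavy_areas)) {
    stop("light and heavy vectors must have equal length", call. = FALSE)
  }
  if (length(light_areas) < 2L) {
    stop("rdotp needs at least 2 transitions", call. = FALSE)
  }
  l <- ifelse(is.na(light_areas), 0, light_areas)
  h <- ifelse(is.na(heavy_areas), 0, heavy_areas)
  if (any(l < 0) || any(h < 0)) {
    stop("areas must be non-negative", call. = FALSE)
  }
  nl <- sqrt(sum(l^2)); nh <- sqrt(sum(h^2))
  if (nl == 0 || nh == 0) return(NA_real_)
  min(1, sum(l * h) / (nl * nh))
}

# split-key helpers shared across QC and quantification
.pep_key <- function(df) {
  paste(df$sample_id, df$protein, df$peptide_sequence, df$precursor_charge,
        sep = "\r")
}
.trans_id <- function(df) {
  do.call(paste, c(df[.TRANSITION_KEY], sep = "\r"))
}

#' QC one precursor in one sample
#'
#' Computes the rdotp over the fragment set, applies the strict
#' `rdotp > threshold` rule, and collects per-fragment flag reasons:
#' `truncated`, `fwhm_degenerate`, and `not_coeluting` (either channel not
#' coeluting, or |apex RT(light) - apex RT(heavy)| exceeding
#' `coelution_tol`).
#'
#' @param rows Transition report rows for one sample x protein x peptide x
#'   precursor charge, both labels.
#' @param threshold rdotp acceptance threshold; the comparison is strictly
#'   greater (default 0.9).
#' @param coelution_tol Apex retention-time tolerance in minutes
#'   (default 0.1).
#' @return List of class `peptide_qc`: identifiers, `rdotp`, `pass_rdotp`
#'   and a data.frame `flagged_transitions` (`fragment_ion`,
#'   `product_charge`, `reason`).
#' @export
evaluate_peptide <- function(rows, threshold = 0.9, coelution_tol = 0.1) {
  stopifnot(nrow(rows) > 0L)
  if (length(unique(.pep_key(rows))) != 1L) {
    stop("'rows' must cover exactly one sample x precursor", call. = FALSE)
  }
  light <- rows[rows$isotope_label == "light", , drop = FALSE]
  heavy <- rows[rows$isotope_label == "heavy", , drop = FALSE]
  frag <- unique(rows[c("fragment_ion", "product_charge")])
  frag_id <- paste(frag$fragment_ion, frag$product_charge)
  la <- light$area[match(frag_id,
                         paste(light$fragment_ion, light$product_charge))]
  ha <- heavy$area[match(frag_id,
                         paste(heavy$fragment_ion, heavy$product_charge))]
  rd <- if (nrow(heavy) == 0L || nrow(light) == 0L || length(frag_id) < 2L) {
    NA_real_
  } else {
    rdotp(la, ha)
  }
  # per-fragment flag collection
  reasons <- list()
  add_flag <- function(sel, reason) {
    if (any(sel)) {
      reasons[[length(reasons) + 1L]] <<- data.frame(
        fragment_ion = frag$fragment_ion[sel],
        product_charge = frag$product_charge[sel],
        reason = reason, stringsAsFactors = FALSE)
    }
  }
  has_flag <- function(df, col) {
    idx <- match(frag_id, paste(df$fragment_ion, df$product_charge))
    out <- df[[col]][idx]
    !is.na(out) & out
  }
  add_flag(has_flag(light, "truncated") | has_flag(heavy, "truncated"),
           "truncated")
  add_flag(has_flag(light, "fwhm_degenerate") |
             has_flag(heavy, "fwhm_degenerate"), "fwhm_degenerate")
  lrt <- light$apex_rt[match(frag_id,
                             paste(light$fragment_ion,
                                   light$product_charge))]
  hrt <- heavy$apex_rt[match(frag_id,
                             paste(heavy$fragment_ion,
                                   heavy$product_charge))]
  coel_ok <- function(df) {
    idx <- match(frag_id, paste(df$fragment_ion, df$product_charge))
    out <- df$coeluting[idx]
    out[is.na(out)] <- TRUE # absent channel: coelution unassessable
    out
  }
  not_coel <- !(coel_ok(light) & coel_ok(heavy))
  rt_off <- !is.na(lrt) & !is.na(hrt) & abs(lrt - hrt) > coelution_tol
  add_flag(not_coel | rt_off, "not_coeluting")
  flagged <- if (length(reasons)) {
    do.call(rbind, reasons)
  } else {
    data.frame(fragment_ion = character(0), product_charge = integer(0),
               reason = character(0), stringsAsFactors = FALSE)
  }
  structure(list(
    sample_id = rows$sample_id[1L], protein = rows$protein[1L],
    peptide_sequence = rows$peptide_sequence[1L],
    precursor_charge = rows$precursor_charge[1L],
    rdotp = rd, pass_rdotp = !is.na(rd) && rd > threshold,
    flagged_transitions = flagged
  ), class = "peptide_qc")
}

#' QC every precursor in a report
#'
#' Applies [evaluate_peptide()] to each (sample, protein, peptide,
#' precursor charge) group.
#'
#' @param report Transition report data.frame.
#' @inheritParams evaluate_peptide
#' @return List with `records` (one data.frame row per precursor per
#'   sample: `sample_id`, `protein`, `peptide_sequence`,
#'   `precursor_charge`, `rdotp`, `pass_rdotp`, `n_flagged`) and `flags`
#'   (long data.frame of per-fragment flag reasons).
#' @export
qc_report <- function(report, threshold = 0.9, coelution_tol = 0.1) {
  validate_transition_report(report)
  # vectorized over all (sample, fragment) pairs; evaluate_peptide() is the
  # single-group reference implementation and agrees by property test
  light <- report[report$isotope_label == "light", , drop = FALSE]
  heavy <- report[report$isotope_label == "heavy", , drop = FALSE]
  u <- unique(report[c("sample_id", .TRANSITION_KEY)])
  ukey <- paste(u$sample_id, .trans_id(u), sep = "\r")
  li <- match(ukey, paste(light$sample_id, .trans_id(light), sep = "\r"))
  hi <- match(ukey, paste(heavy$sample_id, .trans_id(heavy), sep = "\r"))
  la <- light$area[li]; ha <- heavy$area[hi]
  la0 <- ifelse(is.na(la), 0, la); ha0 <- ifelse(is.na(ha), 0, ha)

  pkey <- .pep_key(u)
  g <- factor(pkey, levels = unique(pkey))
  dot <- rowsum(la0 * ha0, g)
  nl2 <- rowsum(la0^2, g)
  nh2 <- rowsum(ha0^2, g)
  nfrag <- as.vector(rowsum(rep(1L, nrow(u)), g))
  rd <- as.vector(dot) / sqrt(as.vector(nl2) * as.vector(nh2))
  rd[as.vector(nl2) == 0 | as.vector(nh2) == 0 | nfrag < 2L] <- NA_real_
  rd <- pmin(rd, 1)

  flag_of <- function(df, idx, col, na_val = FALSE) {
    out <- df[[col]][idx]
    out[is.na(out)] <- na_val
    out
  }
  f_trunc <- flag_of(light, li, "truncated") | flag_of(heavy, hi,
                                                       "truncated")
  f_fwhm <- flag_of(light, li, "fwhm_degenerate") |
    flag_of(heavy, hi, "fwhm_degenerate")
  coel <- flag_of(light, li, "coeluting", TRUE) &
    flag_of(heavy, hi, "coeluting", TRUE)
  lrt <- light$apex_rt[li]; hrt <- heavy$apex_rt[hi]
  rt_off <- !is.na(lrt) & !is.na(hrt) & abs(lrt - hrt) > coelution_tol
  f_coel <- !coel | rt_off

  mk_flags <- function(sel, reason) {
    if (!any(sel)) return(NULL)
    data.frame(u[sel, c("sample_id", "protein", "peptide_sequence",
                        "precursor_charge", "fragment_ion",
                        "product_charge")],
               reason = reason, stringsAsFactors = FALSE)
  }
  flags <- do.call(rbind, c(list(
    data.frame(sample_id = character(0), protein = character(0),
               peptide_sequence = character(0),
               precursor_charge = integer(0), fragment_ion = character(0),
               product_charge = integer(0), reason = character(0),
               stringsAsFactors = FALSE)),
    Filter(Negate(is.null), list(mk_flags(f_trunc, "truncated"),
                                 mk_flags(f_fwhm, "fwhm_degenerate"),
                                 mk_flags(f_coel, "not_coeluting")))))
  rownames(flags) <- NULL

  first <- !duplicated(g)
  records <- data.frame(
    sample_id = u$sample_id[first], protein = u$protein[first],
    peptide_sequence = u$peptide_sequence[first],
    precursor_charge = u$precursor_charge[first],
    rdotp = rd, pass_rdotp = !is.na(rd) & rd > threshold,
    n_flagged = as.vector(rowsum(f_trunc + f_fwhm + f_coel, g)),
    stringsAsFactors = FALSE)
  rownames(records) <- NULL
  list(records = records, flags = flags,
       threshold = threshold, coelution_tol = coelution_tol)
}

#' Propose non-quantitative transitions
#'
#' Deterministic, auditable surrogate for manual interference inspection.
#' A transition is proposed when (a) it is flagged (any reason) in at least
#' `min_flag_fraction` of the samples in which its peptide was measured,
#' or (b) its peptide currently fails the rdotp filter on the
#' across-sample median and removing the transition lifts that median
#' above the threshold.
#'
#' @param report Transition report data.frame.
#' @param qc Result of [qc_report()] on the same report.
#' @param min_flag_fraction Flag-fraction trigger (default 0.5).
#' @return data.frame mask of proposed transitions (`protein`,
#'   `peptide_sequence`, `precursor_charge`, `fragment_ion`,
#'   `product_charge`, `reason`). Never applied silently — pass it to
#'   [apply_mask()] after review.
#' @export
propose_nonquantitative <- function(report, qc, min_flag_fraction = 0.5) {
  validate_transition_report(report)
  threshold <- qc$threshold
  n_samples <- length(unique(report$sample_id))
  proposals <- list()

  # rule (a): flag fraction across samples
  if (nrow(qc$flags) > 0L) {
    f <- unique(qc$flags[c("sample_id", "protein", "peptide_sequence",
                           "precursor_charge", "fragment_ion",
                           "product_charge")])
    tkey <- paste(f$protein, f$peptide_sequence, f$precursor_charge,
                  f$fragment_ion, f$product_charge, sep = "\r")
    tab <- table(tkey)
    hit <- names(tab)[tab / n_samples >= min_flag_fraction]
    if (length(hit) > 0L) {
      parts <- do.call(rbind, strsplit(hit, "\r", fixed = TRUE))
      proposals[[1L]] <- data.frame(
        protein = parts[, 1L], peptide_sequence = parts[, 2L],
        precursor_charge = as.integer(parts[, 3L]),
        fragment_ion = parts[, 4L],
        product_charge = as.integer(parts[, 5L]),
        reason = "flag_fraction", stringsAsFactors = FALSE)
    }
  }

  # rule (b): leave-one-out rdotp rescue for failing peptides
  rec <- qc$records
  pepkey <- paste(rec$protein, rec$peptide_sequence, rec$precursor_charge,
                  sep = "\r")
  med <- tapply(rec$rdotp, pepkey, stats::median, na.rm = TRUE)
  failing <- names(med)[!is.na(med) & med <= threshold]
  for (pk in failing) {
    parts <- strsplit(pk, "\r", fixed = TRUE)[[1L]]
    sel <- report$protein == parts[1L] &
      report$peptide_sequence == parts[2L] &
      report$precursor_charge == as.integer(parts[3L])
    sub <- report[sel, , drop = FALSE]
    frags <- unique(sub[c("fragment_ion", "product_charge")])
    if (nrow(frags) <= 2L) next  # removal would leave < 2 transitions
    for (fi in seq_len(nrow(frags))) {
      keep <- !(sub$fragment_ion == frags$fragment_ion[fi] &
                  sub$product_charge == frags$product_charge[fi])
      loo <- sub[keep, , drop = FALSE]
      rds <- vapply(split(seq_len(nrow(loo)), loo$sample_id), function(ix) {
        q <- evaluate_peptide(loo[ix, , drop = FALSE],
                              threshold = threshold)
        q$rdotp
      }, numeric(1))
      if (stats::median(rds, na.rm = TRUE) > threshold) {
        proposals[[length(proposals) + 1L]] <- data.frame(
          protein = parts[1L], peptide_sequence = parts[2L],
          precursor_charge = as.integer(parts[3L]),
          fragment_ion = frags$fragment_ion[fi],
          product_charge = frags$product_charge[fi],
          reason = "rdotp_rescue", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(proposals) == 0L) {
    return(data.frame(protein = character(0),
                      peptide_sequence = character(0),
                      precursor_charge = integer(0),
                      fragment_ion = character(0),
                      product_charge = integer(0),
                      reason = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, proposals)
  out[!duplicated(out[.TRANSITION_KEY]), , drop = FALSE]
}

#' Apply a non-quantitative transition mask
#'
#' Removes every masked transition from every sample, both isotope labels
#' — masking is global, mirroring the removal of a transition's signal
#' from the whole study.
#'
#' @param report Transition report data.frame.
#' @param mask data.frame with the five transition key columns (extra
#'   columns such as `reason` are ignored). An empty mask is the identity.
#' @return The filtered report; the removed rows are attached as
#'   `attr(x, "removed")` for auditing.
#' @export
apply_mask <- function(report, mask) {
  validate_transition_report(report)
  if (is.null(mask) || nrow(mask) == 0L) {
    attr(report, "removed") <- report[0L, , drop = FALSE]
    return(report)
  }
  stopifnot(all(.TRANSITION_KEY %in% names(mask)))
  mkey <- do.call(paste, c(mask[.TRANSITION_KEY], sep = "\r"))
  rkey <- .trans_id(report)
  unknown <- setdiff(mkey, rkey)
  if (length(unknown) > 0L) {
    stop("mask references a transition absent from the report: ",
         gsub("\r", " ", unknown[1L], fixed = TRUE), call. = FALSE)
  }
  drop <- rkey %in% mkey
  out <- report[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- report[drop, , drop = FALSE]
  out
}
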