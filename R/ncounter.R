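# NanoString nCounter two-step normalization: (1) positive-control scale
# factors from the geometric mean of the spiked positive-control probes,
# (2) housekeeping-gene factors (C1orf43, SNRPD3) with the same
# construction, then per-gene patient-to-control fold changes. The factor
# reference is the arithmetic mean of per-sample geometric means, the
# vendor's documented convention.

.geomean <- function(x) exp(mean(log(x)))

#' Positive-control normalization factors
#'
#' For each sample (lane), the geometric mean of its positive-control
#' probe counts is computed; the factor is the across-sample arithmetic
#' mean of those geometric means divided by the sample's own.
#'
#' @param tab An [ncounter_table()].
#' @return Named numeric vector of per-sample factors.
#' @export
positive_control_factors <- function(tab) {
  stopifnot(inherits(tab, "ncounter_table"))
  if (any(tab$positive_controls <= 0)) {
    stop("zero or negative positive-control count", call. = FALSE)
  }
  g <- apply(tab$positive_controls, 2L, .geomean)
  mean(g) / g
}

#' Housekeeping-gene normalization factors
#'
#' Same geometric-mean factor construction as
#' [positive_control_factors()], computed over the housekeeping genes of a
#' (typically positive-control-normalized) count matrix.
#'
#' @param counts Gene x sample matrix after the positive-control step.
#' @param housekeeping_genes Character vector of housekeeping gene names
#'   present in `rownames(counts)`.
#' @return Named numeric vector of per-sample factors.
#' @export
housekeeping_factors <- function(counts,
                                 housekeeping_genes = c("C1orf43",
                                                        "SNRPD3")) {
  missing_hk <- setdiff(housekeeping_genes, rownames(counts))
  if (length(missing_hk) > 0L) {
    stop("housekeeping gene missing from counts: '", missing_hk[1L], "'",
         call. = FALSE)
  }
  hk <- counts[housekeeping_genes, , drop = FALSE]
  if (any(hk <= 0)) {
    stop("zero housekeeping-gene count; cannot normalize", call. = FALSE)
  }
  g <- apply(hk, 2L, .geomean)
  mean(g) / g
}

#' Two-step nCounter normalization
#'
#' Applies the positive-control factors, then the housekeeping factors.
#' After both steps the geometric mean of housekeeping-gene values is
#' identical across samples.
#'
#' @param tab An [ncounter_table()].
#' @return List of class `ncounter_normalized`: `normalized` (gene x
#'   sample matrix), `positive_control_factors`, `housekeeping_factors`.
#' @export
normalize_ncounter <- function(tab) {
  stopifnot(inherits(tab, "ncounter_table"))
  pcf <- positive_control_factors(tab)
  step1 <- sweep(tab$counts, 2L, pcf, `*`)
  hkf <- housekeeping_factors(step1, tab$housekeeping_genes)
  norm <- sweep(step1, 2L, hkf, `*`)
  structure(list(normalized = norm,
                 positive_control_factors = pcf,
                 housekeeping_factors = hkf,
                 housekeeping_genes = tab$housekeeping_genes),
            class = "ncounter_normalized")
}

#' Per-gene transcript fold changes between two groups
#'
#' Fold change is the ratio of group means on the normalized linear scale
#' (the descriptive quantity); confidence intervals and p-values come from
#' the same two-group regression machinery as the protein statistics,
#' applied to log2 normalized counts, with Benjamini-Hochberg adjustment
#' across genes. Housekeeping genes are excluded from testing.
#'
#' @param normalized An `ncounter_normalized` object (or a plain gene x
#'   sample matrix of normalized counts).
#' @param annotation Sample annotation data.frame.
#' @param condition,control Group labels to contrast.
#' @param alpha Significance threshold on adjusted p (default 0.05).
#' @return data.frame: `gene`, `fold_change` (ratio of linear-scale
#'   means), `log2fc_regression`, `ci_low`, `ci_high` (linear),
#'   `p_value`, `adj_p_value`, `significant`.
#' @export
transcript_fold_changes <- function(normalized, annotation, condition,
                                    control, alpha = 0.05) {
  hk <- character(0)
  if (inherits(normalized, "ncounter_normalized")) {
    hk <- normalized$housekeeping_genes
    normalized <- normalized$normalized
  }
  validate_annotation(annotation)
  for (g in c(condition, control)) {
    if (!g %in% annotation$group) {
      stop("unknown group '", g, "'", call. = FALSE)
    }
  }
  samples <- colnames(normalized)
  grp <- annotation$group[match(samples, annotation$sample_id)]
  if (anyNA(grp)) {
    stop("sample '", samples[is.na(grp)][1L], "' is not annotated",
         call. = FALSE)
  }
  cond_ix <- grp == condition
  ctrl_ix <- grp == control
  if (!any(cond_ix) || !any(ctrl_ix)) {
    stop("both groups need at least one sample", call. = FALSE)
  }
  genes <- setdiff(rownames(normalized), hk)
  rows <- lapply(genes, function(g) {
    x1 <- normalized[g, cond_ix]
    x0 <- normalized[g, ctrl_ix]
    m0 <- mean(x0)
    if (m0 <= 0) {
      stop("zero control mean for gene '", g, "'", call. = FALSE)
    }
    cmp <- compare_two_groups(log2(pmax(x1, 0.5)), log2(pmax(x0, 0.5)))
    data.frame(gene = g, fold_change = mean(x1) / m0,
               log2fc_regression = cmp$log2fc,
               ci_low = 2^cmp$ci_low, ci_high = 2^cmp$ci_high,
               p_value = cmp$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p_value <- adjust_bh(out$p_value)
  out$significant <- !is.na(out$adj_p_value) & out$adj_p_value <= alpha
  rownames(out) <- NULL
  out
}
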