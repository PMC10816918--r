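# Two-group differential abundance on normalized log2 ratios: ordinary
# least squares on a 0/1 group indicator (the slope is the log2 fold
# change and equals the difference of group means), t-based p-values and
# 95% confidence intervals from the slope's standard error (df = n - 2),
# and Benjamini-Hochberg adjustment across the proteins of one contrast.

#' Two-group comparison by linear regression
#'
#' OLS of the response on an intercept and a 0/1 condition indicator. The
#' slope equals `mean(condition) - mean(control)`; its standard error
#' yields a two-sided p-value and a 95% CI from the t distribution with
#' `n - 2` degrees of freedom. With `n = 2` (df = 0) the fold change is
#' still returned but p and CI are `NA`.
#'
#' @param values_condition,values_control Numeric vectors of normalized
#'   log2 ratios (at least one value per group).
#' @return List: `log2fc`, `se`, `p_value`, `ci_low`, `ci_high` (log2
#'   scale), `df`, `n_condition`, `n_control`.
#' @export
compare_two_groups <- function(values_condition, values_control) {
  vc <- values_condition[is.finite(values_condition)]
  v0 <- values_control[is.finite(values_control)]
  n1 <- length(vc); n0 <- length(v0)
  if (n1 == 0L || n0 == 0L) {
    stop("both groups need at least one finite value", call. = FALSE)
  }
  n <- n0 + n1
  slope <- mean(vc) - mean(v0)
  df <- n - 2L
  if (df < 1L) {
    return(list(log2fc = slope, se = NA_real_, p_value = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, df = df,
                n_condition = n1, n_control = n0))
  }
  sse <- sum((vc - mean(vc))^2) + sum((v0 - mean(v0))^2)
  s2 <- sse / df
  se <- sqrt(s2 * (1 / n1 + 1 / n0))
  if (se == 0) {
    p <- if (slope == 0) 1 else 0
    ci <- c(slope, slope)
  } else {
    tval <- slope / se
    p <- 2 * stats::pt(-abs(tval), df)
    tq <- stats::qt(0.975, df)
    ci <- c(slope - tq * se, slope + tq * se)
  }
  list(log2fc = slope, se = se, p_value = p, ci_low = ci[1L],
       ci_high = ci[2L], df = df, n_condition = n1, n_control = n0)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR control: with p-values sorted ascending,
#' `adj_i = min_{j >= i} m * p_j / j`, capped at 1. `NA` p-values are
#' excluded from the family size `m` and returned as `NA`; input order is
#' preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values in the input order.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03)) # all 0.03
#' @export
adjust_bh <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  pv <- p[ok]
  ord <- order(pv)
  ranked <- pv[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  tmp <- rep(NA_real_, m)
  tmp[ord] <- adj
  out[ok] <- tmp
  out
}

#' Run a pairwise group comparison over a ratio table
#'
#' One regression per protein (or peptide) comparing the condition group
#' against the control group on SEC63-normalized log2 ratios,
#' complete-case, followed by Benjamini-Hochberg adjustment across all
#' tested entities of the contrast. The reference protein is excluded
#' (its normalized values are identically zero). Entities lacking at
#' least one observation per group, or with fewer than `min_obs` total,
#' are excluded and listed in `attr(x, "excluded")`.
#'
#' @param ratio_table Normalized ratio table (needs
#'   `log2_ratio_normalized`).
#' @param annotation Sample annotation data.frame.
#' @param condition,control Group labels to contrast.
#' @param level `"protein"` or `"peptide"`.
#' @param alpha Significance level on adjusted p-values (default 0.05,
#'   inclusive).
#' @param min_obs Minimum total observations per entity (default 3, the
#'   smallest n giving a finite p).
#' @param reference_protein Excluded from testing (default `"SEC63"`).
#' @return data.frame of class `comparison_table`: `protein`
#'   (and `peptide`, `precursor_charge` at peptide level), `log2fc`,
#'   `fold_change`, `ci_low`, `ci_high` (linear scale), `p_value`,
#'   `adj_p_value`, `significant`, `n_condition`, `n_control`.
#' @export
run_comparison <- function(ratio_table, annotation, condition, control,
                           level = c("protein", "peptide"), alpha = 0.05,
                           min_obs = 3L, reference_protein = "SEC63") {
  level <- match.arg(level)
  validate_annotation(annotation)
  if (!condition %in% annotation$group) {
    stop("unknown condition group '", condition, "'", call. = FALSE)
  }
  if (!control %in% annotation$group) {
    stop("unknown control group '", control, "'", call. = FALSE)
  }
  if (!"log2_ratio_normalized" %in% names(ratio_table)) {
    stop("ratio table is not normalized; run normalize_to_reference()",
         call. = FALSE)
  }
  missing_ann <- setdiff(ratio_table$sample_id, annotation$sample_id)
  if (length(missing_ann) > 0L) {
    stop("sample '", missing_ann[1L], "' is not annotated", call. = FALSE)
  }
  tab <- ratio_table[ratio_table$protein != reference_protein, ,
                     drop = FALSE]
  grp <- annotation$group[match(tab$sample_id, annotation$sample_id)]
  tab <- tab[grp %in% c(condition, control), , drop = FALSE]
  grp <- annotation$group[match(tab$sample_id, annotation$sample_id)]

  ekey <- if (level == "protein") {
    tab$protein
  } else {
    paste(tab$protein, tab$peptide_sequence, tab$precursor_charge,
          sep = "\r")
  }
  groups <- split(seq_len(nrow(tab)), ekey)
  rows <- list()
  excluded <- list()
  for (ent in names(groups)) {
    ix <- groups[[ent]]
    y <- tab$log2_ratio_normalized[ix]
    g <- grp[ix]
    ok <- is.finite(y)
    y <- y[ok]; g <- g[ok]
    vc <- y[g == condition]; v0 <- y[g == control]
    if (length(vc) == 0L || length(v0) == 0L ||
        length(vc) + length(v0) < min_obs) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        entity = gsub("\r", "|", ent, fixed = TRUE),
        reason = sprintf("insufficient observations (%d condition, %d control)",
                         length(vc), length(v0)),
        stringsAsFactors = FALSE)
      next
    }
    cmp <- compare_two_groups(vc, v0)
    id <- if (level == "protein") {
      data.frame(protein = ent, stringsAsFactors = FALSE)
    } else {
      parts <- strsplit(ent, "\r", fixed = TRUE)[[1L]]
      data.frame(protein = parts[1L], peptide = parts[2L],
                 precursor_charge = as.integer(parts[3L]),
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- cbind(id, data.frame(
      log2fc = cmp$log2fc, fold_change = 2^cmp$log2fc,
      ci_low = 2^cmp$ci_low, ci_high = 2^cmp$ci_high,
      p_value = cmp$p_value, n_condition = cmp$n_condition,
      n_control = cmp$n_control, stringsAsFactors = FALSE))
  }
  if (length(rows) == 0L) {
    stop("no entity had enough observations for the contrast",
         call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out$adj_p_value <- adjust_bh(out$p_value)
  out$significant <- !is.na(out$adj_p_value) & out$adj_p_value <= alpha
  ord <- c("protein", intersect(c("peptide", "precursor_charge"),
                                names(out)),
           "log2fc", "fold_change", "ci_low", "ci_high", "p_value",
           "adj_p_value", "significant", "n_condition", "n_control")
  out <- out[, ord]
  rownames(out) <- NULL
  attr(out, "excluded") <- if (length(excluded)) {
    do.call(rbind, excluded)
  } else {
    data.frame(entity = character(0), reason = character(0))
  }
  attr(out, "contrast") <- c(condition = condition, control = control)
  class(out) <- c("comparison_table", "data.frame")
  out
}
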