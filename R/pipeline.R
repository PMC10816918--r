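# End-to-end orchestration: simulate (or read) a transition report, run
# QC, propose and apply the non-quantitative mask, quantify, normalize and
# compare, writing a deterministic artifact set plus a reproducibility log
# (package version, seed, effective configuration and its hash).

.DEFAULT_CONFIG <- list(
  scenario = NULL,            # preset name for simulation runs
  seed = 1L,
  report = NULL,              # input transition report CSV (if no scenario)
  annotation = NULL,          # input annotation CSV (if no scenario)
  out_dir = ".",
  condition = "condition",
  control = "control",
  rdotp_threshold = 0.9,
  coelution_tol = 0.1,
  min_flag_fraction = 0.5,
  reference_protein = "SEC63",
  significance_alpha = 0.05,
  half_width = 2.5,
  mask_file = NULL,           # reviewed mask CSV overriding the proposal
  level = "protein"
)

#' Build a run configuration
#'
#' Merges user settings over the documented defaults and validates ranges.
#' Settings may come from a flat YAML file, a list, or both (explicit
#' arguments take precedence over the file).
#'
#' @param config Path to a YAML file or a named list (optional).
#' @param ... Individual settings overriding the file and the defaults.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(config = NULL, ...) {
  cfg <- .DEFAULT_CONFIG
  if (!is.null(config)) {
    if (is.character(config)) {
      if (!file.exists(config)) {
        stop("config file not found: ", config, call. = FALSE)
      }
      config <- yaml::read_yaml(config)
    }
    stopifnot(is.list(config))
    unknown <- setdiff(names(config), names(cfg))
    if (length(unknown) > 0L) {
      stop("unknown config key '", unknown[1L], "'", call. = FALSE)
    }
    cfg[names(config)] <- config
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config key '", unknown[1L], "'", call. = FALSE)
  }
  cfg[names(dots)] <- dots
  if (cfg$rdotp_threshold < 0 || cfg$rdotp_threshold > 1) {
    stop("rdotp_threshold must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$significance_alpha <= 0 || cfg$significance_alpha >= 1) {
    stop("significance_alpha must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$coelution_tol <= 0 || cfg$half_width <= 0) {
    stop("coelution_tol and half_width must be > 0", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

.config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(unclass(cfg)), tf)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline
#'
#' Stages: simulate (when `scenario` is set) or read inputs, QC, mask
#' proposal (or a reviewed mask file), mask application, protein- and
#' peptide-level quantification with reference normalization, and the
#' two-group comparison. All artifacts are written under `out_dir`:
#' `report.csv`, `annotation.csv`, `qc_records.csv`, `qc_flags.csv`,
#' `proposed_mask.csv`, `mask_audit.csv`, `protein_ratios.csv`,
#' `peptide_ratios.csv`, `comparison_protein.tsv`,
#' `comparison_peptide.tsv`, `run_log.yaml`.
#'
#' @param config A [run_config()], a config list, or a YAML path.
#' @param ... Settings overriding `config`.
#' @return Invisibly, a list with the in-memory results (`report`,
#'   `annotation`, `qc`, `mask`, `protein_ratios`, `peptide_ratios`,
#'   `comparison_protein`, `comparison_peptide`, `paths`).
#' @export
run_pipeline <- function(config = NULL, ...) {
  cfg <- if (inherits(config, "run_config") && length(list(...)) == 0L) {
    config
  } else {
    run_config(config, ...)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  stage <- "input"
  result <- tryCatch({
    if (!is.null(cfg$scenario)) {
      scen <- scenario_preset(cfg$scenario, seed = cfg$seed)
      sim <- generate_study(scen)
      report <- sim$report
      annotation <- sim$annotation
    } else {
      if (is.null(cfg$report) || !file.exists(cfg$report %||% "")) {
        stop("input report not found: ", cfg$report %||% "<unset>",
             call. = FALSE)
      }
      if (is.null(cfg$annotation) || !file.exists(cfg$annotation %||% "")) {
        stop("annotation file not found: ", cfg$annotation %||% "<unset>",
             call. = FALSE)
      }
      report <- read_transition_report(cfg$report)
      annotation <- read_sample_annotation(cfg$annotation)
    }
    write_transition_report(report, out("report.csv"))
    write_sample_annotation(annotation, out("annotation.csv"))

    stage <- "qc"
    qc <- qc_report(report, threshold = cfg$rdotp_threshold,
                    coelution_tol = cfg$coelution_tol)
    utils::write.csv(qc$records, out("qc_records.csv"), row.names = FALSE,
                     na = "")
    utils::write.csv(qc$flags, out("qc_flags.csv"), row.names = FALSE)

    stage <- "mask"
    proposed <- propose_nonquantitative(report, qc,
                                        min_flag_fraction =
                                          cfg$min_flag_fraction)
    utils::write.csv(proposed, out("proposed_mask.csv"), row.names = FALSE)
    mask <- if (!is.null(cfg$mask_file)) {
      utils::read.csv(cfg$mask_file, stringsAsFactors = FALSE)
    } else {
      proposed
    }
    masked <- apply_mask(report, mask)
    utils::write.csv(attr(masked, "removed"), out("mask_audit.csv"),
                     row.names = FALSE, na = "")
    # QC must be recomputed on the masked data: rdotp changes when a
    # contaminated transition disappears
    qc2 <- qc_report(masked, threshold = cfg$rdotp_threshold,
                     coelution_tol = cfg$coelution_tol)

    stage <- "quantify"
    prot <- protein_ratios(masked, qc2)
    prot <- normalize_to_reference(prot, cfg$reference_protein)
    write_ratio_csv(prot, out("protein_ratios.csv"))
    pep <- peptide_ratios(masked, qc2)
    pep <- normalize_to_reference(pep, cfg$reference_protein,
                                  reference_table =
                                    prot[setdiff(names(prot),
                                                 "log2_ratio_normalized")])
    write_ratio_csv(pep, out("peptide_ratios.csv"))

    stage <- "compare"
    cmp_prot <- run_comparison(prot, annotation, cfg$condition,
                               cfg$control, level = "protein",
                               alpha = cfg$significance_alpha,
                               reference_protein = cfg$reference_protein)
    write_comparison_tsv(cmp_prot, out("comparison_protein.tsv"))
    cmp_pep <- run_comparison(pep, annotation, cfg$condition,
                              cfg$control, level = "peptide",
                              alpha = cfg$significance_alpha,
                              reference_protein = cfg$reference_protein)
    write_comparison_tsv(cmp_pep, out("comparison_peptide.tsv"))

    log <- list(
      package = "glycoMRM",
      version = as.character(utils::packageVersion("glycoMRM")),
      seed = cfg$seed,
      config = unclass(cfg),
      config_hash = .config_hash(cfg),
      n_samples = length(unique(report$sample_id)),
      n_proteins = length(unique(report$protein)),
      n_masked_transitions = nrow(mask)
    )
    yaml::write_yaml(log, out("run_log.yaml"))

    list(report = report, annotation = annotation, qc = qc2, mask = mask,
         protein_ratios = prot, peptide_ratios = pep,
         comparison_protein = cmp_prot, comparison_peptide = cmp_pep,
         paths = vapply(c("report.csv", "annotation.csv", "qc_records.csv",
                          "proposed_mask.csv", "protein_ratios.csv",
                          "peptide_ratios.csv", "comparison_protein.tsv",
                          "comparison_peptide.tsv", "run_log.yaml"),
                        out, character(1)))
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
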