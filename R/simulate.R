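# Synthetic transition-level MRM data and nCounter count tables with known
# ground truth, emulating a spike-in SILAC patient-versus-control study.
#
# Generative model per transition t, sample s:
#   heavy area = base(t) * spike(s)            * 2^N(0, noise_sigma)
#   light area = base(t) * loading(s) * ratio  * 2^N(0, noise_sigma)
# where spike(s) is the per-sample internal-standard amount (log-normal,
# CV = spike_cv), loading(s) a shared biological loading factor
# (2^N(0, loading_sigma)) carried by every light channel including the
# reference protein SEC63, and ratio the condition/control abundance ratio
# of the peptide's protein (control samples: 1). Light transitions can
# receive additive interference; areas below the limit of detection are
# censored to missing.

# the 21 panel proteins routinely quantified from whole-cell lysate
.PANEL_21 <- c("ALG7", "ALG13", "ALG14", "ALG1", "ALG2", "ALG11", "RFT1",
               "ALG9", "ALG12", "ALG5", "ALG6", "ALG8", "ALG10", "RPN1",
               "STT3A", "STT3B", "TMTC2", "TMTC3", "DPY19L1", "DPM1",
               "SEC63")

# the full 30-protein assay panel
.PANEL_30 <- c("ALG7", "ALG13", "ALG14", "ALG1", "ALG2", "ALG11", "RFT1",
               "ALG3", "ALG9", "ALG12", "ALG5", "ALG6", "ALG8", "ALG10",
               "RPN1", "STT3A", "STT3B",
               "POMT1", "POMT2", "TMTC1", "TMTC2", "TMTC3", "TMTC4",
               "DPY19L1", "DPY19L3", "DPY19L4",
               "DPM1", "DPM3", "PMM2", "SEC63")

# 18 glycosyltransferase genes monitored at the transcript level
.NCOUNTER_GENES <- c("ALG7", "ALG13", "ALG14", "ALG1", "ALG2", "ALG11",
                     "RFT1", "ALG3", "ALG9", "ALG12", "ALG5", "ALG6",
                     "ALG8", "ALG10", "RPN1", "STT3A", "STT3B", "DPM1")

#' MRM panel protein names
#'
#' @param full If `TRUE`, the complete 30-protein assay panel (including
#'   proteins often below detection in whole-cell lysate and the PMM2
#'   enrichment control); otherwise the 21 proteins routinely quantified,
#'   including the SEC63 normalization reference.
#' @return Character vector of gene-style protein names.
#' @export
mrm_panel_proteins <- function(full = FALSE) {
  if (full) .PANEL_30 else .PANEL_21
}

#' Define a simulation scenario
#'
#' Captures the complete stated world of one synthetic study: panel layout,
#' group sizes, true condition/control abundance ratios, noise magnitudes
#' and artifact rates. All randomness downstream flows from `seed`.
#'
#' @param proteins Character vector of panel protein names; must contain
#'   the reference protein `"SEC63"`.
#' @param peptides_per_protein,transitions_per_peptide Assay layout
#'   (defaults 4 peptides and 3 transitions, the assay's typical density).
#' @param n_condition,n_control Number of condition and control samples.
#' @param true_protein_ratio Named positive vector of condition/control
#'   abundance ratios; unnamed proteins default to 1. SEC63 must stay at 1.
#' @param true_peptide_ratio_override Named positive vector keyed as
#'   `"PROTEIN|PEPTIDESEQ"` overriding the protein ratio for single
#'   peptides (heterozygous-variant emulation).
#' @param noise_sigma SD of log2 multiplicative measurement noise per
#'   transition (default 0.15).
#' @param spike_cv Coefficient of variation of the per-sample
#'   internal-standard amount (default 0.1).
#' @param loading_sigma SD (log2) of the shared per-sample biological
#'   loading factor absorbed by SEC63 normalization (default 0.2).
#' @param interference_rate Probability that a light measurement receives
#'   additive contamination (default 0).
#' @param interference_scale Contamination magnitude as a multiple of the
#'   true area (default 5).
#' @param lod Absolute area below which a measurement is censored to
#'   missing (default 0 = no censoring).
#' @param truncation_rate Probability a measurement is flagged truncated
#'   (default 0).
#' @param seed Integer seed.
#' @return `sim_scenario` object (a validated list).
#' @export
sim_scenario <- function(proteins = mrm_panel_proteins(),
                         peptides_per_protein = 4L,
                         transitions_per_peptide = 3L,
                         n_condition = 3L, n_control = 4L,
                         true_protein_ratio = NULL,
                         true_peptide_ratio_override = NULL,
                         noise_sigma = 0.15, spike_cv = 0.1,
                         loading_sigma = 0.2, interference_rate = 0,
                         interference_scale = 5, lod = 0,
                         truncation_rate = 0, seed = 1L) {
  if (!"SEC63" %in% proteins) {
    stop("the panel must include the reference protein SEC63", call. = FALSE)
  }
  ratio <- stats::setNames(rep(1, length(proteins)), proteins)
  if (!is.null(true_protein_ratio)) {
    if (is.null(names(true_protein_ratio))) {
      stop("'true_protein_ratio' must be named", call. = FALSE)
    }
    unknown <- setdiff(names(true_protein_ratio), proteins)
    if (length(unknown) > 0L) {
      stop("ratio given for unknown protein '", unknown[1L], "'",
           call. = FALSE)
    }
    ratio[names(true_protein_ratio)] <- true_protein_ratio
  }
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("all true ratios must be positive", call. = FALSE)
  }
  if (ratio[["SEC63"]] != 1) {
    stop("SEC63 must keep a true ratio of 1 (it is the normalization
 reference)", call. = FALSE)
  }
  if (!is.null(true_peptide_ratio_override)) {
    if (is.null(names(true_peptide_ratio_override)) ||
        any(!grepl("|", names(true_peptide_ratio_override), fixed = TRUE))) {
      stop("peptide overrides must be named 'PROTEIN|PEPTIDE'",
           call. = FALSE)
    }
    if (any(true_peptide_ratio_override <= 0)) {
      stop("peptide override ratios must be positive", call. = FALSE)
    }
  }
  rates <- c(interference_rate, truncation_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (n_condition < 1L || n_control < 1L) {
    stop("both groups need at least one sample", call. = FALSE)
  }
  stopifnot(noise_sigma >= 0, spike_cv >= 0, loading_sigma >= 0, lod >= 0)
  structure(list(
    proteins = proteins,
    peptides_per_protein = as.integer(peptides_per_protein),
    transitions_per_peptide = as.integer(transitions_per_peptide),
    n_condition = as.integer(n_condition),
    n_control = as.integer(n_control),
    true_protein_ratio = ratio,
    true_peptide_ratio_override = true_peptide_ratio_override,
    noise_sigma = noise_sigma, spike_cv = spike_cv,
    loading_sigma = loading_sigma,
    interference_rate = interference_rate,
    interference_scale = interference_scale,
    lod = lod, truncation_rate = truncation_rate,
    seed = as.integer(seed)
  ), class = "sim_scenario")
}

#' Named scenario presets for the study's findings
#'
#' * `alg1_cdg`: the affected protein reduced to 10% of control
#'   (3 patients vs 4 controls).
#' * `alg2_cdg`: the affected protein's light signal pushed below the limit
#'   of detection in condition samples (3 culture replicates vs 4 controls).
#' * `alg11_loss`: the affected protein at 20% of control (3 vs 4).
#' * `alg11_variant`: all protein ratios 1, but the single variant-bearing
#'   ALG11 peptide INIPFDELK at 35% of control (3 replicate injections of
#'   one patient vs 4 controls).
#' * `null_two_celltypes`: all ratios 1, 3 vs 3 — a cross-cell-type null
#'   comparison.
#'
#' @param name Preset name.
#' @param seed Seed stored in the scenario (default 1).
#' @return A [sim_scenario()].
#' @export
scenario_preset <- function(name = c("alg1_cdg", "alg2_cdg", "alg11_loss",
                                     "alg11_variant", "null_two_celltypes"),
                            seed = 1L) {
  name <- match.arg(name)
  switch(name,
    alg1_cdg = sim_scenario(
      n_condition = 3L, n_control = 4L,
      true_protein_ratio = c(ALG1 = 0.1), seed = seed),
    alg2_cdg = sim_scenario(
      n_condition = 3L, n_control = 4L,
      true_protein_ratio = c(ALG2 = 0.001), lod = 2500, seed = seed),
    alg11_loss = sim_scenario(
      n_condition = 3L, n_control = 4L,
      true_protein_ratio = c(ALG11 = 0.2), seed = seed),
    alg11_variant = sim_scenario(
      n_condition = 3L, n_control = 4L,
      true_peptide_ratio_override = c("ALG11|INIPFDELK" = 0.35),
      seed = seed),
    null_two_celltypes = sim_scenario(
      n_condition = 3L, n_control = 3L, seed = seed)
  )
}

# deterministic synthetic tryptic-like peptide for panel position (i, j);
# built from a seeded RNG inside generate_assay
.random_peptide <- function(len) {
  body <- sample(setdiff(names(.RESIDUE_MASS), c("K", "R", "M", "P")),
                 len - 1L, replace = TRUE)
  paste0(paste(body, collapse = ""), sample(c("K", "R"), 1L))
}

#' Generate the synthetic assay layout for a scenario
#'
#' Lays out peptides (with synthetic tryptic-like sequences; ALG11's first
#' peptide is fixed to INIPFDELK so the variant preset targets a real
#' peptide), y-ion transitions, iRTs and per-transition base intensities
#' drawn log-uniformly over two decades. Both isotope labels are present
#' for every transition. Deterministic given the scenario seed.
#'
#' @param scenario A [sim_scenario()].
#' @return data.frame of assay transitions with columns `protein`,
#'   `peptide_sequence`, `precursor_charge`, `precursor_mz`,
#'   `fragment_ion`, `product_charge`, `product_mz`, `isotope_label`,
#'   `irt`, `rt`, `base_intensity`.
#' @export
generate_assay <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  rng <- .scenario_rng(scenario)
  on.exit(rng$restore())
  npep <- scenario$peptides_per_protein
  ntr <- scenario$transitions_per_peptide
  rows <- vector("list", length(scenario$proteins))
  used_peptides <- character(0)
  for (pi in seq_along(scenario$proteins)) {
    prot <- scenario$proteins[[pi]]
    peps <- character(npep)
    for (j in seq_len(npep)) {
      if (prot == "ALG11" && j == 1L) {
        peps[j] <- "INIPFDELK"
      } else {
        repeat {
          p <- .random_peptide(sample(8:15, 1L))
          if (!p %in% used_peptides && !p %in% peps) break
        }
        peps[j] <- p
      }
    }
    used_peptides <- c(used_peptides, peps)
    irt <- stats::runif(npep, -10, 110)
    per_pep <- lapply(seq_len(npep), function(j) {
      pep <- peps[j]
      ords <- seq.int(3L, 2L + ntr)
      ords <- pmin(ords, nchar(pep) - 1L)
      ords <- unique(ords)
      base <- 10^stats::runif(length(ords), 4, 6)
      light <- data.frame(
        protein = prot, peptide_sequence = pep, precursor_charge = 2L,
        precursor_mz = peptide_mz(pep, 2L, "light"),
        fragment_ion = paste0("y", ords), product_charge = 1L,
        product_mz = vapply(ords, function(o)
          fragment_mz(pep, "y", o, 1L, "light"), numeric(1)),
        isotope_label = "light", irt = irt[j],
        rt = 20 + 0.25 * irt[j], base_intensity = base,
        stringsAsFactors = FALSE
      )
      heavy <- light
      heavy$isotope_label <- "heavy"
      heavy$precursor_mz <- peptide_mz(pep, 2L, "heavy")
      heavy$product_mz <- vapply(ords, function(o)
        fragment_mz(pep, "y", o, 1L, "heavy"), numeric(1))
      rbind(light, heavy)
    })
    rows[[pi]] <- do.call(rbind, per_pep)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# isolated RNG stream for a scenario; draw order is documented as
# assay layout -> sample factors -> noise -> artifacts
.scenario_rng <- function(scenario, offset = 0L) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(scenario$seed + offset)
  list(restore = function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}

#' Generate a full synthetic study
#'
#' Draws the assay layout, per-sample spike-in and loading factors,
#' measurement noise, interference and truncation artifacts, and
#' limit-of-detection censoring, producing a transition report plus the
#' ground truth needed for parameter-recovery tests.
#'
#' @param scenario A [sim_scenario()].
#' @return List with elements `report` (transition report data.frame, see
#'   [read_transition_report()]), `annotation` (sample annotation
#'   data.frame with groups `"condition"` and `"control"`), and `truth`
#'   (list: `scenario`, `assay`, `spike_factors`, `loading_factors`,
#'   `contaminated` data.frame, `censored` data.frame).
#' @export
generate_study <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  assay <- generate_assay(scenario)
  rng <- .scenario_rng(scenario, offset = 1L)
  on.exit(rng$restore())

  samples <- c(sprintf("COND_%02d", seq_len(scenario$n_condition)),
               sprintf("CTRL_%02d", seq_len(scenario$n_control)))
  groups <- rep(c("condition", "control"),
                c(scenario$n_condition, scenario$n_control))
  ann <- data.frame(
    sample_id = samples, group = groups,
    replicate_index = c(seq_len(scenario$n_condition),
                        seq_len(scenario$n_control)),
    stringsAsFactors = FALSE)

  ns <- length(samples)
  # spike factors: log-normal with CV spike_cv, expectation-preserving
  sdlog <- sqrt(log(1 + scenario$spike_cv^2))
  spike <- stats::setNames(
    stats::rlnorm(ns, meanlog = -sdlog^2 / 2, sdlog = sdlog), samples)
  loading <- stats::setNames(
    2^stats::rnorm(ns, 0, scenario$loading_sigma), samples)

  nt <- nrow(assay)
  is_light <- assay$isotope_label == "light"
  ratio <- scenario$true_protein_ratio[assay$protein]
  ov <- scenario$true_peptide_ratio_override
  if (!is.null(ov)) {
    key <- paste(assay$protein, assay$peptide_sequence, sep = "|")
    hit <- match(key, names(ov))
    ratio[!is.na(hit)] <- ov[hit[!is.na(hit)]]
  }

  rep_rows <- vector("list", ns)
  contaminated <- list()
  for (si in seq_len(ns)) {
    s <- samples[si]
    cond <- groups[si] == "condition"
    true_area <- ifelse(
      is_light,
      assay$base_intensity * loading[[s]] * (if (cond) ratio else 1),
      assay$base_intensity * spike[[s]])
    noise <- 2^stats::rnorm(nt, 0, scenario$noise_sigma)
    area <- true_area * noise
    apex <- assay$rt + stats::rnorm(nt, 0, 0.02)
    coeluting <- rep(TRUE, nt)
    # additive light-only interference
    hit <- is_light & stats::runif(nt) < scenario$interference_rate
    if (any(hit)) {
      area[hit] <- area[hit] + scenario$interference_scale * true_area[hit]
      shift <- stats::runif(sum(hit)) < 0.5
      coeluting[hit][shift] <- FALSE
      apex[hit][shift] <- apex[hit][shift] + 0.3
      contaminated[[length(contaminated) + 1L]] <- data.frame(
        sample_id = s, assay[hit, .TRANSITION_KEY],
        stringsAsFactors = FALSE)
    }
    truncated <- stats::runif(nt) < scenario$truncation_rate
    censor <- area < scenario$lod
    area[censor] <- NA_real_
    apex[censor] <- NA_real_
    rep_rows[[si]] <- data.frame(
      sample_id = s,
      assay[, c("protein", "peptide_sequence", "precursor_charge",
                "fragment_ion", "product_charge", "isotope_label")],
      area = area, apex_rt = apex, truncated = truncated,
      fwhm_degenerate = FALSE, coeluting = coeluting,
      censored = censor,
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rep_rows)
  censored <- report[report$censored,
                     c("sample_id", .TRANSITION_KEY, "isotope_label")]
  rownames(censored) <- NULL
  report$censored <- NULL
  rownames(report) <- NULL
  list(
    report = validate_transition_report(report),
    annotation = ann,
    truth = list(
      scenario = scenario, assay = assay,
      spike_factors = spike, loading_factors = loading,
      contaminated = if (length(contaminated)) {
        do.call(rbind, contaminated)
      } else {
        data.frame(sample_id = character(0))
      },
      censored = censored)
  )
}

#' Generate a synthetic nCounter count table
#'
#' Counts are negative-binomial around gene mean x lane factor x group
#' ratio; positive-control probes (a four-fold concentration ladder) and
#' housekeeping genes carry the lane factor but a ratio of 1.
#'
#' @param genes Endogenous gene names (default: the 18-gene GT panel).
#' @param n_condition,n_control Replicates per group (defaults 4 and 4).
#' @param true_ratio Named positive vector of condition/control ratios
#'   (unnamed genes default to 1).
#' @param lane_factor_sigma SD (log2) of per-sample lane factors
#'   (default 0.2).
#' @param dispersion Negative-binomial dispersion (1/size); 0 gives
#'   deterministic rounded means (default 0.05).
#' @param housekeeping_genes Housekeeping gene names appended to the table
#'   (default C1orf43 and SNRPD3).
#' @param n_pos Number of positive-control probes (default 6).
#' @param seed Integer seed.
#' @return List with `table` (an [ncounter_table()]), `annotation`, and
#'   `truth` (lane factors, gene means, ratios).
#' @export
generate_ncounter <- function(genes = .NCOUNTER_GENES, n_condition = 4L,
                              n_control = 4L, true_ratio = NULL,
                              lane_factor_sigma = 0.2, dispersion = 0.05,
                              housekeeping_genes = c("C1orf43", "SNRPD3"),
                              n_pos = 6L, seed = 1L) {
  if (length(housekeeping_genes) < 2L) {
    stop("need at least 2 housekeeping genes", call. = FALSE)
  }
  if (n_pos < 6L) stop("need at least 6 positive-control probes",
                       call. = FALSE)
  all_genes <- c(genes, housekeeping_genes)
  ratio <- stats::setNames(rep(1, length(all_genes)), all_genes)
  if (!is.null(true_ratio)) {
    unknown <- setdiff(names(true_ratio), genes)
    if (length(unknown) > 0L) {
      stop("ratio for unknown gene '", unknown[1L], "'", call. = FALSE)
    }
    ratio[names(true_ratio)] <- true_ratio
  }
  if (any(ratio <= 0)) stop("ratios must be positive", call. = FALSE)

  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  samples <- c(sprintf("COND_%02d", seq_len(n_condition)),
               sprintf("CTRL_%02d", seq_len(n_control)))
  groups <- rep(c("condition", "control"), c(n_condition, n_control))
  ns <- length(samples)
  lane <- stats::setNames(2^stats::rnorm(ns, 0, lane_factor_sigma), samples)
  gene_mean <- stats::setNames(10^stats::runif(length(all_genes), 2.5, 4.5),
                               all_genes)
  pos_mean <- stats::setNames(32000 / 4^(seq_len(n_pos) - 1L),
                              paste0("POS_", LETTERS[seq_len(n_pos)]))

  draw <- function(mu) {
    if (dispersion <= 0) round(mu) else {
      stats::rnbinom(length(mu), size = 1 / dispersion, mu = mu)
    }
  }
  counts <- matrix(0, length(all_genes), ns,
                   dimnames = list(all_genes, samples))
  pos <- matrix(0, n_pos, ns, dimnames = list(names(pos_mean), samples))
  for (si in seq_len(ns)) {
    r <- if (groups[si] == "condition") ratio else rep(1, length(ratio))
    counts[, si] <- draw(gene_mean * lane[si] * r)
    pos[, si] <- pmax(1, draw(pos_mean * lane[si]))
  }
  list(
    table = ncounter_table(counts, pos, housekeeping_genes),
    annotation = data.frame(
      sample_id = samples, group = groups,
      replicate_index = c(seq_len(n_condition), seq_len(n_control)),
      stringsAsFactors = FALSE),
    truth = list(lane_factors = lane, gene_means = gene_mean,
                 true_ratio = ratio, dispersion = dispersion, seed = seed)
  )
}
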