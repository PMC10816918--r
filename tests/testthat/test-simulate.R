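test_that("scenario validation enforces the stated world", {
  expect_error(sim_scenario(proteins = c("ALG1", "ALG2")), "SEC63")
  expect_error(sim_scenario(true_protein_ratio = c(ALG1 = -1)), "positive")
  expect_error(sim_scenario(true_protein_ratio = c(SEC63 = 2)), "SEC63")
  expect_error(sim_scenario(true_protein_ratio = c(NOPE = 0.5)),
               "unknown protein")
  expect_error(sim_scenario(interference_rate = 1.5), "rates")
  expect_error(sim_scenario(n_condition = 0), "at least one sample")
})

test_that("assay layout counts and determinism", {
  sc <- sim_scenario(peptides_per_protein = 4L,
                     transitions_per_peptide = 3L)
  a1 <- generate_assay(sc)
  # 21 proteins x 4 peptides x 3 transitions x 2 labels
  expect_equal(nrow(a1), 21L * 4L * 3L * 2L)
  expect_identical(a1, generate_assay(sc))
  # base intensities within the two stated decades
  expect_true(all(a1$base_intensity >= 1e4 & a1$base_intensity <= 1e6))
  # both labels everywhere, ALG11 carries the variant peptide
  expect_true("INIPFDELK" %in%
                a1$peptide_sequence[a1$protein == "ALG11"])
  counts <- table(a1$protein, a1$isotope_label)
  expect_true(all(counts == 12L))
})

test_that("full 30-protein panel mirrors the assay overview", {
  p30 <- mrm_panel_proteins(full = TRUE)
  expect_length(p30, 30L)
  expect_true(all(c("ALG1", "ALG2", "ALG11", "SEC63", "PMM2", "POMT1",
                    "DPY19L3", "DPM3", "STT3A", "RFT1") %in% p30))
  expect_true(all(mrm_panel_proteins() %in% c(p30)))
})

test_that("study generation is reproducible and obeys the noise model", {
  sc <- scenario_preset("alg1_cdg", seed = 3L)
  s1 <- generate_study(sc)
  s2 <- generate_study(sc)
  expect_identical(s1$report, s2$report)
  expect_identical(s1$truth$spike_factors, s2$truth$spike_factors)
  # noiseless propagation: every ALG1 light/heavy ratio in condition is
  # exactly ratio x the control value
  sc0 <- noiseless_scenario(true_protein_ratio = c(ALG1 = 0.25))
  s0 <- generate_study(sc0)
  rep0 <- s0$report
  r <- rep0[rep0$protein == "ALG1", ]
  key <- paste(r$peptide_sequence, r$fragment_ion, r$product_charge)
  lh <- tapply(r$area, paste(r$sample_id, key, r$isotope_label), identity)
  for (k in unique(key)) {
    cond_ratio <- lh[[paste("COND_01", k, "light")]] /
      lh[[paste("COND_01", k, "heavy")]]
    ctrl_ratio <- lh[[paste("CTRL_01", k, "light")]] /
      lh[[paste("CTRL_01", k, "heavy")]]
    expect_equal(cond_ratio / ctrl_ratio, 0.25, tolerance = 1e-12)
  }
})

test_that("loading factors are absorbed by SEC63 normalization", {
  sc <- noiseless_scenario(loading_sigma = 0.5, seed = 9L)
  s <- generate_study(sc)
  pr <- normalize_to_reference(protein_ratios(s$report))
  # raw ratios differ between samples, normalized values are exactly 0
  expect_gt(stats::sd(pr$log2_ratio[pr$protein == "ALG5"]), 0.01)
  expect_equal(max(abs(pr$log2_ratio_normalized)), 0, tolerance = 1e-9)
})

test_that("censoring is monotone in the detection limit", {
  base <- scenario_preset("alg2_cdg", seed = 4L)
  lo <- generate_study(base)
  hi_sc <- base; hi_sc$lod <- base$lod * 4
  hi <- generate_study(hi_sc)
  cen_key <- function(s) do.call(paste, s$truth$censored)
  expect_true(all(cen_key(lo) %in% cen_key(hi)))
  # censored measurements are missing, not zero
  expect_true(all(is.na(
    merge(lo$report, lo$truth$censored)[, "area"])))
})

test_that("nCounter generator honors its closed form", {
  # dispersion 0 and lane sigma 0: counts equal rounded expected means
  d0 <- generate_ncounter(dispersion = 0, lane_factor_sigma = 0,
                          true_ratio = c(ALG2 = 0.6), seed = 2L)
  mu <- d0$truth$gene_means
  cond <- d0$annotation$sample_id[d0$annotation$group == "condition"]
  expect_equal(d0$table$counts["ALG2", cond[1L]],
               round(mu[["ALG2"]] * 0.6))
  expect_equal(d0$table$counts["C1orf43", ],
               rep(round(mu[["C1orf43"]]), 8L), ignore_attr = TRUE)
  # positive-control geometric mean per lane proportional to lane factor
  dl <- generate_ncounter(dispersion = 0, lane_factor_sigma = 0.4,
                          seed = 6L)
  g <- apply(dl$table$positive_controls, 2L, function(x) exp(mean(log(x))))
  ratio <- g / dl$truth$lane_factors
  expect_lt(diff(range(ratio)) / mean(ratio), 0.01)
  expect_error(generate_ncounter(true_ratio = c(NOPE = 2)), "unknown gene")
  expect_error(generate_ncounter(housekeeping_genes = "C1orf43"),
               "housekeeping")
})

test_that("presets encode the study findings", {
  p <- scenario_preset("alg1_cdg")
  expect_equal(p$n_condition, 3L)
  expect_equal(p$n_control, 4L)
  expect_equal(unname(p$true_protein_ratio[["ALG1"]]), 0.1)
  v <- scenario_preset("alg11_variant")
  expect_equal(max(v$true_protein_ratio), 1)
  expect_equal(min(v$true_protein_ratio), 1)
  expect_length(v$true_peptide_ratio_override, 1L)
  expect_equal(unname(v$true_peptide_ratio_override), 0.35)
  n <- scenario_preset("null_two_celltypes")
  expect_true(all(n$true_protein_ratio == 1))
  expect_error(scenario_preset("nope"))
})
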