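test_that("sum-then-ratio on a single peptide and protein", {
  r <- tiny_report(light = c(10, 20, 30), heavy = c(20, 40, 60))
  p <- summarize_protein(r)
  expect_equal(p$light_sum, 60)
  expect_equal(p$heavy_sum, 120)
  expect_equal(p$log2_ratio, -1)
  pep <- summarize_peptide(r)
  expect_equal(pep$log2_ratio, -1)
  # two peptides with equal ratios but different intensities preserve the
  # ratio under summation
  r2 <- rbind(tiny_report(peptide = "INIPFDELK",
                          light = c(10, 20, 30), heavy = c(10, 20, 30)),
              tiny_report(peptide = "AAAAGGGGK",
                          light = c(500, 100, 80), heavy = c(500, 100, 80)))
  expect_equal(summarize_protein(r2)$log2_ratio, 0)
})

test_that("paired inclusion keeps censored channels out of the sums", {
  r <- tiny_report(light = c(10, NA, 30), heavy = c(20, 40, 60))
  r$apex_rt[2L] <- NA
  p <- summarize_protein(r)
  expect_equal(p$light_sum, 40)   # y4 light missing drops heavy y4 too
  expect_equal(p$heavy_sum, 80)
  expect_equal(p$n_transitions_used, 2L)
  # fully censored light channel: ratio missing, not zero
  r0 <- tiny_report(light = c(NA, NA, NA), heavy = c(20, 40, 60))
  r0$apex_rt[1:3] <- NA
  expect_equal(nrow(protein_ratios(r0)), 0L)
})

test_that("peptide-level view resolves what the protein sum masks", {
  # one of four peptides at 0.35, equal base intensities: protein ratio
  # (0.35 + 3) / 4
  peps <- c("AAAGGGFFK", "CCDDEEFFK", "GGHHIIFFK", "INIPFDELK")
  mk <- function(pep, ratio) tiny_report(
    peptide = pep, light = ratio * c(100, 100, 100),
    heavy = c(100, 100, 100))
  r <- do.call(rbind, Map(mk, peps, c(1, 1, 1, 0.35)))
  expect_equal(summarize_protein(r)$log2_ratio, log2((0.35 + 3) / 4))
  pr <- peptide_ratios(r)
  expect_equal(sort(2^pr$log2_ratio), sort(c(1, 1, 1, 0.35)))
})

test_that("reference normalization is exact and shift-invariant", {
  s <- generate_study(noiseless_scenario(
    true_protein_ratio = c(ALG1 = 0.25), loading_sigma = 0.3, seed = 2L))
  pr <- normalize_to_reference(protein_ratios(s$report))
  expect_equal(pr$log2_ratio_normalized[pr$protein == "SEC63"],
               rep(0, 7L))
  alg1 <- pr[pr$protein == "ALG1" & grepl("COND", pr$sample_id), ]
  expect_equal(alg1$log2_ratio_normalized, rep(log2(0.25), 3L),
               tolerance = 1e-9)
  # adding a constant per sample to all log2 ratios leaves normalized
  # values unchanged
  shifted <- pr
  shift <- stats::setNames(stats::runif(7, -2, 2),
                           unique(pr$sample_id))
  shifted$log2_ratio <- shifted$log2_ratio + shift[shifted$sample_id]
  renorm <- normalize_to_reference(
    shifted[setdiff(names(shifted), "log2_ratio_normalized")])
  expect_equal(renorm$log2_ratio_normalized, pr$log2_ratio_normalized,
               tolerance = 1e-12)
})

test_that("missing reference is a hard, named error", {
  s <- generate_study(noiseless_scenario(seed = 3L))
  pr <- protein_ratios(s$report)
  pr <- pr[!(pr$protein == "SEC63" & pr$sample_id == "CTRL_02"), ]
  expect_error(normalize_to_reference(pr), "CTRL_02")
})

test_that("heavy-channel rescaling shifts raw but not normalized ratios", {
  s <- generate_study(sim_scenario(seed = 17L))
  rep0 <- s$report
  pr0 <- normalize_to_reference(protein_ratios(rep0))
  c_fac <- 3.7
  rep1 <- rep0
  sel <- rep1$sample_id == "COND_01" & rep1$isotope_label == "heavy"
  rep1$area[sel] <- rep1$area[sel] * c_fac
  pr1 <- normalize_to_reference(protein_ratios(rep1))
  raw_shift <- pr1$log2_ratio[pr1$sample_id == "COND_01"] -
    pr0$log2_ratio[pr0$sample_id == "COND_01"]
  expect_equal(raw_shift, rep(-log2(c_fac), length(raw_shift)),
               tolerance = 1e-9)
  expect_equal(pr1$log2_ratio_normalized, pr0$log2_ratio_normalized,
               tolerance = 1e-9)
})

test_that("row order never affects ratio tables", {
  s <- generate_study(sim_scenario(seed = 19L))
  rep0 <- s$report
  set.seed(1)
  shuf <- rep0[sample(nrow(rep0)), ]
  a <- protein_ratios(rep0)
  b <- protein_ratios(shuf)
  b <- b[match(paste(a$sample_id, a$protein),
               paste(b$sample_id, b$protein)), ]
  rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("noiseless recovery is exact for every protein", {
  truth <- c(ALG1 = 0.1, ALG11 = 0.2, ALG9 = 2.5)
  s <- generate_study(noiseless_scenario(true_protein_ratio = truth,
                                         loading_sigma = 0.25,
                                         seed = 23L))
  pr <- normalize_to_reference(protein_ratios(s$report))
  cond <- grepl("COND", pr$sample_id)
  for (p in names(truth)) {
    expect_equal(pr$log2_ratio_normalized[cond & pr$protein == p],
                 rep(log2(truth[[p]]), 3L), tolerance = 1e-9)
  }
  ctrl <- grepl("CTRL", pr$sample_id)
  expect_equal(max(abs(pr$log2_ratio_normalized[ctrl])), 0,
               tolerance = 1e-9)
})

test_that("ratio CSV round-trips", {
  s <- generate_study(sim_scenario(seed = 29L))
  pr <- normalize_to_reference(protein_ratios(s$report))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratio_csv(pr, path)
  back <- read_ratio_csv(path)
  expect_equal(back$log2_ratio_normalized, pr$log2_ratio_normalized,
               tolerance = 1e-12)
  expect_equal(names(back), names(pr))
})
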