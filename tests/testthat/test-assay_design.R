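test_that("tryptic digestion follows the Keil rule and tiles the protein", {
  expect_equal(digest_tryptic("AKRPKW")$sequence, c("AK", "RPK", "W"))
  d <- digest_tryptic("KINIPFDELKR")
  expect_equal(d$sequence, c("K", "INIPFDELK", "R"))
  expect_equal(d$start[2L], 2L)
  expect_equal(d$end[2L], 10L)
  expect_equal(digest_tryptic("ACDEFG")$sequence, "ACDEFG")
  expect_error(digest_tryptic("AXK"), "invalid residue")
})

test_that("digestion partition property holds for random sequences", {
  set.seed(11)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  for (i in 1:25) {
    s <- paste(sample(aas, sample(5:120, 1L), replace = TRUE),
               collapse = "")
    d <- digest_tryptic(s)
    expect_identical(paste(d$sequence, collapse = ""), s)
    expect_equal(d$length, d$end - d$start + 1L)
  }
})

test_that("candidate selection applies length, Met and uniqueness rules", {
  peps <- digest_tryptic("LATKINIPFDELKMLLDVTTKAAAAAAAAK", "P1")
  bg <- rbind(peps[c("protein_id", "sequence")],
              data.frame(protein_id = "P2", sequence = "AAAAAAAAK"))
  out <- select_candidate_peptides(peps, bg)
  expect_equal(out$sequence, "INIPFDELK")   # kept: 9-mer, no M, unique
  # LATK too short, MLLDVTTK has Met, AAAAAAAAK shared with P2
  expect_error(select_candidate_peptides(peps, bg[0L, ]), "non-empty")
  # idempotence
  expect_equal(select_candidate_peptides(out, bg), out)
})

test_that("peptide m/z matches the independent mass oracle", {
  # frozen from an independent residue-mass summation (biopython)
  expect_equal(peptide_mz("INIPFDELK", 2L), 544.80296, tolerance = 1e-5)
  expect_equal(fragment_mz("INIPFDELK", "y", 7L, 1L), 861.47165,
               tolerance = 1e-5)
  # heavy - light = +8.01420/charge for K-terminated peptides
  expect_equal(peptide_mz("INIPFDELK", 2L, "heavy") -
                 peptide_mz("INIPFDELK", 2L), 8.014199 / 2,
               tolerance = 1e-9)
  # charge identity: m1 = 2*m2 - proton
  m1 <- peptide_mz("INIPFDELK", 1L); m2 <- peptide_mz("INIPFDELK", 2L)
  expect_equal(m1, 2 * m2 - 1.00727646688, tolerance = 1e-9)
  expect_error(peptide_mz("INIPFDELA", 2L, "heavy"), "C-terminal K or R")
})

test_that("b/y fragments are complementary and label-aware", {
  proton <- 1.00727646688
  for (pep in c("INIPFDELK", "SAMPLECR", "GAVLIWK")) {
    n <- nchar(pep)
    for (k in seq_len(n - 1L)) {
      expect_equal(
        fragment_mz(pep, "b", k, 1L) + fragment_mz(pep, "y", n - k, 1L),
        peptide_mz(pep, 1L) + proton, tolerance = 1e-9)
    }
    # heavy shift on y-ions only
    expect_equal(fragment_mz(pep, "y", 1L, 1L, "heavy") -
                   fragment_mz(pep, "y", 1L, 1L, "light"),
                 if (substr(pep, n, n) == "K") 8.014199 else 10.008269,
                 tolerance = 1e-9)
    expect_equal(fragment_mz(pep, "b", 2L, 1L, "heavy"),
                 fragment_mz(pep, "b", 2L, 1L, "light"))
  }
  expect_error(fragment_mz("INIPFDELK", "y", 9L, 1L), "ordinal")
})

test_that("iRT calibration fits, rejects and round-trips", {
  cal <- fit_irt_calibration(c(0, 100), c(5, 15))
  expect_equal(cal$slope, 0.1)
  expect_equal(cal$intercept, 5)
  expect_equal(cal$r_squared, 1)
  expect_equal(rt_to_irt(15, cal), 100)
  # noiseless line with 10 standards
  irt <- seq(-10, 110, length.out = 10L)
  cal2 <- fit_irt_calibration(irt, 0.1 * irt + 5)
  expect_equal(cal2$slope, 0.1, tolerance = 1e-12)
  expect_equal(cal2$r_squared, 1, tolerance = 1e-12)
  # round trip to 1e-9 minutes
  x <- c(-5, 0, 42.42, 99.9)
  expect_equal(rt_to_irt(irt_to_rt(x, cal2), cal2), x, tolerance = 1e-9)
  expect_error(fit_irt_calibration(c(50, 50), c(5, 6)), "zero variance")
  expect_error(fit_irt_calibration(c(1), c(5)), "at least 2")
  set.seed(2)
  expect_error(fit_irt_calibration(1:10, rnorm(10)), "rejected")
})

test_that("scheduling windows center, clip and separate", {
  cal <- fit_irt_calibration(c(0, 100), c(5, 15))
  w <- predict_rt_window(150, cal, half_width = 2.5)
  expect_equal(unname(w), cbind(17.5, 22.5), ignore_attr = TRUE)
  ident <- fit_irt_calibration(c(0, 100), c(0, 100))
  w0 <- predict_rt_window(0, ident, half_width = 2.5)
  expect_equal(unname(w0[1L, "start"]), 0)  # clipped at zero
  expect_equal(unname(w0[1L, "end"]), 2.5)
  # iRT gap > 2*half_width/slope implies disjoint windows
  gap <- 2 * 2.5 / cal$slope + 1
  w1 <- predict_rt_window(c(40, 40 + gap), cal, half_width = 2.5)
  expect_gt(w1[2L, "start"], w1[1L, "end"])
})

test_that("top-transition selection ranks and breaks ties deterministically", {
  expect_equal(select_top_transitions(c(y3 = 10, y5 = 50, y7 = 40, b4 = 5),
                                      3L), c("y5", "y7", "y3"))
  expect_equal(select_top_transitions(c(y3 = 1, y5 = 2), 10L),
               c("y5", "y3"))
  # tie at rank k: lower ordinal kept
  expect_equal(select_top_transitions(c(y6 = 5, y4 = 5, y9 = 9), 2L),
               c("y9", "y4"))
  expect_error(select_top_transitions(numeric(0), 3L), "empty")
})

test_that("design_assay produces a coherent transition list from FASTA", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "GGGKINIPFDELKAAAGGGWWR", ">P2", "VVVVVVVKTTTTTTTR"),
             path)
  assay <- design_assay(path)
  expect_true(all(c("INIPFDELK") %in% assay$peptide_sequence))
  expect_setequal(unique(assay$isotope_label), c("light", "heavy"))
  # heavy precursor above light for every peptide
  sp <- split(assay$precursor_mz, paste(assay$peptide_sequence,
                                        assay$isotope_label))
  for (pep in unique(assay$peptide_sequence)) {
    expect_gt(sp[[paste(pep, "heavy")]][1L], sp[[paste(pep, "light")]][1L])
  }
  tl <- withr::local_tempfile(fileext = ".csv")
  write_transition_list(assay, tl)
  got <- utils::read.csv(tl)
  expect_equal(nrow(got), nrow(assay))
  expect_equal(names(got)[1:4],
               c("Protein", "Peptide", "PrecursorMz", "PrecursorCharge"))
})
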