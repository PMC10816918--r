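# In-code fixtures: a tiny hand-built transition report and convenience
# builders used across the suite. Everything is generated at test time;
# nothing is stored on disk.

# one sample, one peptide, `frags` fragment ions x 2 labels
tiny_report <- function(sample_id = "S1", protein = "ALG1",
                        peptide = "INIPFDELK", frags = c("y3", "y4", "y5"),
                        light = c(10, 20, 30), heavy = c(20, 40, 60),
                        rt = 25) {
  n <- length(frags)
  data.frame(
    sample_id = sample_id, protein = protein, peptide_sequence = peptide,
    precursor_charge = 2L,
    fragment_ion = rep(frags, 2L), product_charge = 1L,
    isotope_label = rep(c("light", "heavy"), each = n),
    area = c(light, heavy), apex_rt = ifelse(is.na(c(light, heavy)), NA,
                                             rt),
    truncated = FALSE, fwhm_degenerate = FALSE, coeluting = TRUE,
    stringsAsFactors = FALSE
  )
}

# noiseless scenario: every stochastic knob off unless overridden
noiseless_scenario <- function(..., seed = 1L) {
  args <- list(noise_sigma = 0, spike_cv = 0, loading_sigma = 0,
               interference_rate = 0, truncation_rate = 0, lod = 0,
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_scenario, args)
}

# independent normal-equations OLS oracle for y ~ 1 + x
ols_oracle <- function(y, x) {
  X <- cbind(1, x)
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  df <- length(y) - 2L
  s2 <- sum(resid^2) / df
  se <- sqrt(s2 * xtx_inv[2L, 2L])
  tval <- beta[2L] / se
  list(slope = beta[2L], se = se,
       p = 2 * stats::pt(-abs(tval), df))
}

# brute-force BH definition: adj_i = min_{j: p_j >= p_i} m * p_j / rank_j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  r <- integer(m); r[ord] <- seq_len(m)
  vapply(seq_len(m), function(i) {
    min(1, min(m * p[ord][r[ord] >= r[i]] / r[ord][r[ord] >= r[i]]))
  }, numeric(1))
}
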