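# Shared fixture builders for the suite. All randomness is seeded by callers.

# Harmonized set straight from a simulated pair (bypasses allele matching,
# which has its own tests).
sim_hset <- function(...) {
  p <- simulate_mr_pair(...)
  harmonized_set(p$exposure$SNP, p$exposure$beta, p$exposure$se,
                 p$outcome$beta, p$outcome$se)
}

# Add horizontal-pleiotropy offsets (in units of the outcome SE) to chosen
# SNPs of a harmonized set.
plant_outliers <- function(hset, idx, mult) {
  hset$data$beta_out[idx] <- hset$data$beta_out[idx] +
    mult * hset$data$se_out[idx]
  hset
}

# Canonical toy summary-statistics table.
toy_sumstats <- function(n = 5, seed = 1) {
  set.seed(seed)
  data.frame(
    SNP = sprintf("rs%03d", seq_len(n)),
    effect_allele = rep(c("A", "C", "G", "T", "A"), length.out = n),
    other_allele = rep(c("G", "T", "A", "C", "C"), length.out = n),
    beta = round(rnorm(n, 0.1, 0.05), 4),
    se = round(runif(n, 0.01, 0.05), 4),
    pval = signif(runif(n), 3),
    eaf = round(runif(n, 0.1, 0.5), 3),
    samplesize = 18340L,
    chr = "1",
    pos = seq_len(n) * 1e6,
    stringsAsFactors = FALSE
  )
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
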