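# Synthetic two-sample GWAS summary statistics with known ground truth.
# Effects are simulated directly on the summary-statistic scale (no
# individual-level genotypes): two-sample MR consumes only per-SNP effect
# estimates and their standard errors, so this is the level at which the
# data-generating process needs to be faithful.

#' Simulate one exposure/outcome summary-statistics pair
#'
#' For each of L instruments: a minor allele frequency is drawn uniformly on
#' \code{maf_range}; the true exposure effect gamma is drawn from
#' N(0.08, 0.03^2) truncated positive (effects reported for the
#' trait-increasing allele); the exposure standard error is
#' 1/sqrt(2 n_exp maf (1-maf)) and the observed effect is drawn about the
#' truth. A fraction \code{prop_invalid} of SNPs carries a horizontal
#' pleiotropic effect alpha, drawn from N(0, alpha_sd^2) (balanced) or
#' N(alpha_sd, alpha_sd^2) (directional); with \code{inside_violated} alpha
#' is given correlation 0.5 with instrument strength. The true outcome
#' effect is theta * gamma + alpha, observed with standard error scaled by
#' \code{n_out}. Alleles are drawn with a given fraction of palindromic
#' (A/T, C/G) pairs; p-values are two-sided normal Wald tests.
#'
#' @param theta True causal effect of exposure on outcome (log-odds scale).
#' @param L Number of instruments.
#' @param prop_invalid Fraction of instruments with horizontal pleiotropy.
#' @param pleiotropy_mode \code{"balanced"} or \code{"directional"}.
#' @param alpha_sd Pleiotropy effect scale.
#' @param inside_violated Correlate pleiotropy with instrument strength
#'   (violating the InSIDE assumption).
#' @param n_exp,n_out Sample sizes controlling the exposure/outcome standard
#'   errors; defaults match a large microbiome GWAS meta-analysis (18340)
#'   and a case-control outcome GWAS totalling 24510.
#' @param maf_range Minor-allele-frequency range, default c(0.05, 0.5)
#'   (common variants only).
#' @param frac_palindromic Expected fraction of palindromic allele pairs.
#' @param seed Integer seed; identical seeds give identical tables.
#' @param label SNP id prefix and pair label.
#' @return list(exposure, outcome, truth): two canonical summary-statistics
#'   data.frames over the same SNPs and a truth data.frame (snp_id,
#'   gamma_true, alpha, valid) with attributes theta, seed.
#' @export
simulate_mr_pair <- function(theta = 0.3, L = 100, prop_invalid = 0,
                             pleiotropy_mode = c("balanced", "directional"),
                             alpha_sd = 0.1, inside_violated = FALSE,
                             n_exp = 18340, n_out = 24510,
                             maf_range = c(0.05, 0.5), frac_palindromic = 0.2,
                             seed = 1, label = "snp") {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(L >= 1, prop_invalid >= 0, prop_invalid <= 1,
            n_exp > 0, n_out > 0, alpha_sd >= 0,
            maf_range[1] > 0, maf_range[2] < 1, maf_range[1] <= maf_range[2],
            frac_palindromic >= 0, frac_palindromic <= 1)
  withr_seed(seed, {
    maf <- stats::runif(L, maf_range[1], maf_range[2])
    gamma <- abs(stats::rnorm(L, 0.08, 0.03))  # truncated-positive true effects
    se_x <- 1 / sqrt(2 * n_exp * maf * (1 - maf))
    gx <- stats::rnorm(L, gamma, se_x)

    n_invalid <- round(prop_invalid * L)
    invalid <- sample.int(L, n_invalid)
    m <- if (pleiotropy_mode == "directional") alpha_sd else 0
    alpha <- numeric(L)
    if (n_invalid > 0) {
      eps <- stats::rnorm(n_invalid)
      if (inside_violated) {
        zg <- (gamma[invalid] - 0.08) / 0.03
        alpha[invalid] <- m + alpha_sd * (0.5 * zg + sqrt(0.75) * eps)
      } else {
        alpha[invalid] <- m + alpha_sd * eps
      }
    }
    Gamma <- theta * gamma + alpha
    se_y <- 1 / sqrt(2 * n_out * maf * (1 - maf))
    gy <- stats::rnorm(L, Gamma, se_y)

    pal <- stats::runif(L) < frac_palindromic
    pal_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                        ncol = 2, byrow = TRUE)
    npal_pairs <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                           "G", "A", "G", "T", "T", "C", "T", "G"),
                         ncol = 2, byrow = TRUE)
    alleles <- matrix(NA_character_, L, 2)
    alleles[pal, ] <- pal_pairs[sample.int(4, sum(pal), replace = TRUE), , drop = FALSE]
    alleles[!pal, ] <- npal_pairs[sample.int(8, sum(!pal), replace = TRUE), , drop = FALSE]

    snp_id <- sprintf("%s%05d", label, seq_len(L))
    mk <- function(beta, se, n) data.frame(
      SNP = snp_id, effect_allele = alleles[, 1], other_allele = alleles[, 2],
      beta = beta, se = se, pval = 2 * stats::pnorm(-abs(beta / se)),
      eaf = maf, samplesize = n, chr = "1", pos = seq_len(L) * 2e6,
      stringsAsFactors = FALSE)
    truth <- data.frame(snp_id = snp_id, gamma_true = gamma, alpha = alpha,
                        valid = !(seq_len(L) %in% invalid),
                        stringsAsFactors = FALSE)
    attr(truth, "theta") <- theta
    attr(truth, "seed") <- seed
    list(exposure = mk(gx, se_x, n_exp), outcome = mk(gy, se_y, n_out),
         truth = truth)
  })
}

#' Simulate a multi-taxon exposure panel with a shared outcome
#'
#' One exposure table per taxon at the requested taxonomic ranks, plus a
#' single outcome table covering every instrument. Taxa named in
#' \code{signal_spec} are generated with the stated causal effect; all
#' others are null (theta = 0). Instrument sets are disjoint across taxa.
#'
#' With \code{n_disease_snps > 0} the outcome table additionally carries
#' SNPs with direct (taxon-independent) effects on the disease — the
#' outcome's own GWAS hits — and every taxon table carries matching
#' null-effect rows for those SNPs. These are the instruments a
#' reverse-direction analysis selects; under forward-only causation the
#' reverse estimate through them is null.
#'
#' @param n_per_rank Named integer vector of taxa counts per rank, e.g.
#'   \code{c(genus = 10, family = 5)}.
#' @param signal_spec Named numeric vector mapping taxon names (of the form
#'   \code{rank_i}) to nonzero causal effects; NULL for an all-null panel.
#' @param L Instruments per taxon.
#' @param seed Integer seed.
#' @param n_disease_snps Direct disease-associated SNPs added to the
#'   outcome table (genome-wide significant scale).
#' @param disease_effect_mean,disease_effect_sd Distribution of the direct
#'   disease effects.
#' @param n_exp,n_out,maf_range,frac_palindromic As in
#'   \code{\link{simulate_mr_pair}}.
#' @param ... Further arguments passed to \code{\link{simulate_mr_pair}}.
#' @return list(exposures: named list of tables, ranks: named character
#'   vector, outcome: single table, truth: data.frame (taxon, rank, theta)).
#' @export
simulate_multitaxon <- function(n_per_rank, signal_spec = NULL, L = 30,
                                seed = 1, n_disease_snps = 0,
                                disease_effect_mean = 0.1,
                                disease_effect_sd = 0.03,
                                n_exp = 18340, n_out = 24510,
                                maf_range = c(0.05, 0.5),
                                frac_palindromic = 0.2, ...) {
  stopifnot(all(n_per_rank >= 1), !is.null(names(n_per_rank)))
  taxa <- unlist(lapply(names(n_per_rank), function(r) {
    paste0(r, "_", seq_len(n_per_rank[[r]]))
  }))
  ranks <- rep(names(n_per_rank), times = n_per_rank)
  names(ranks) <- taxa
  if (!is.null(signal_spec)) {
    unknown <- setdiff(names(signal_spec), taxa)
    if (length(unknown)) {
      stop("signal_spec references unknown taxa: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  exposures <- list()
  outcomes <- list()
  truth <- data.frame(taxon = taxa, rank = unname(ranks),
                      theta = 0, stringsAsFactors = FALSE)
  for (i in seq_along(taxa)) {
    tx <- taxa[i]
    th <- if (!is.null(signal_spec) && tx %in% names(signal_spec)) {
      signal_spec[[tx]]
    } else 0
    truth$theta[i] <- th
    pair <- simulate_mr_pair(theta = th, L = L, seed = seed + i,
                             n_exp = n_exp, n_out = n_out,
                             maf_range = maf_range,
                             frac_palindromic = frac_palindromic,
                             label = sprintf("rs%02d_", i), ...)
    exposures[[tx]] <- pair$exposure
    outcomes[[i]] <- pair$outcome
  }
  outcome <- do.call(rbind, outcomes)

  if (n_disease_snps > 0) {
    dis <- withr_seed(seed + 90000L, {
      maf <- stats::runif(n_disease_snps, maf_range[1], maf_range[2])
      delta <- stats::rnorm(n_disease_snps, disease_effect_mean,
                            disease_effect_sd)
      se_y <- 1 / sqrt(2 * n_out * maf * (1 - maf))
      pal <- stats::runif(n_disease_snps) < frac_palindromic
      pal_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                          ncol = 2, byrow = TRUE)
      npal_pairs <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                             "G", "A", "G", "T", "T", "C", "T", "G"),
                           ncol = 2, byrow = TRUE)
      alleles <- matrix(NA_character_, n_disease_snps, 2)
      alleles[pal, ] <- pal_pairs[sample.int(4, sum(pal), replace = TRUE), , drop = FALSE]
      alleles[!pal, ] <- npal_pairs[sample.int(8, sum(!pal), replace = TRUE), , drop = FALSE]
      gy <- stats::rnorm(n_disease_snps, delta, se_y)
      se_x <- 1 / sqrt(2 * n_exp * maf * (1 - maf))
      # per-taxon null associations at the disease SNPs
      taxon_beta <- lapply(seq_along(taxa), function(i) {
        stats::rnorm(n_disease_snps, 0, se_x)
      })
      list(maf = maf, se_y = se_y, se_x = se_x, alleles = alleles, gy = gy,
           taxon_beta = taxon_beta)
    })
    snp_id <- sprintf("rsdis%05d", seq_len(n_disease_snps))
    mk <- function(beta, se, n) data.frame(
      SNP = snp_id, effect_allele = dis$alleles[, 1],
      other_allele = dis$alleles[, 2], beta = beta, se = se,
      pval = 2 * stats::pnorm(-abs(beta / se)), eaf = dis$maf,
      samplesize = n, chr = "2", pos = seq_len(n_disease_snps) * 2e6,
      stringsAsFactors = FALSE)
    outcome <- rbind(outcome, mk(dis$gy, dis$se_y, n_out))
    for (i in seq_along(taxa)) {
      exposures[[taxa[i]]] <- rbind(exposures[[taxa[i]]],
                                    mk(dis$taxon_beta[[i]], dis$se_x, n_exp))
    }
  }
  list(exposures = exposures, ranks = ranks, outcome = outcome, truth = truth)
}

#' Write allele-flipped copies of a summary-statistics table
#'
#' Test fixture generator for harmonization: returns a copy with the allele
#' columns swapped and beta/eaf adjusted accordingly
#' (\code{mode = "swap"}), with both alleles replaced by their strand
#' complements (\code{mode = "strand"}), or both (\code{mode = "both"}).
#' Harmonizing the original against any of these should recover the
#' original effects for all non-palindromic SNPs.
#'
#' @param records Canonical summary-statistics data.frame.
#' @param mode One of \code{"swap"}, \code{"strand"}, \code{"both"}.
#' @return The transformed data.frame.
#' @export
flip_fixture <- function(records, mode = c("swap", "strand", "both")) {
  mode <- match.arg(mode)
  out <- records
  if (mode %in% c("swap", "both")) {
    ea <- out$other_allele
    out$other_allele <- out$effect_allele
    out$effect_allele <- ea
    out$beta <- -out$beta
    out$eaf <- 1 - out$eaf
  }
  if (mode %in% c("strand", "both")) {
    out$effect_allele <- unname(complement_base(out$effect_allele))
    out$other_allele <- unname(complement_base(out$other_allele))
  }
  out
}
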