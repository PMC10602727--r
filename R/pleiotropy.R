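# Heterogeneity and horizontal-pleiotropy diagnostics: Cochran's Q, the
# Egger intercept test, the residual-sum-of-squares (PRESSO-style) global,
# outlier and distortion tests with sequential outlier removal, and
# leave-one-out sensitivity analysis.

#' Cochran's Q heterogeneity test
#'
#' Q is the inverse-variance weighted sum of squared deviations of the
#' per-SNP outcome effects from the fixed-effect IVW fit, referred to a
#' chi-square distribution with L-1 degrees of freedom. A p-value below
#' 0.05 flags heterogeneity (possible invalid instruments).
#'
#' @param hset A \code{harmonized_set} with at least 2 SNPs.
#' @return list(Q, df, p, flag) of class \code{heterogeneity_report}.
#' @export
cochran_q <- function(hset) {
  d <- hset$data
  L <- nrow(d)
  if (L < 2) stop("Cochran's Q needs at least 2 instruments", call. = FALSE)
  fit <- ivw_slope(d$beta_exp, d$beta_out, d$se_out)
  Q <- sum((d$beta_out - fit$beta * d$beta_exp)^2 / d$se_out^2)
  df <- L - 1
  p <- stats::pchisq(Q, df = df, lower.tail = FALSE)
  structure(list(Q = Q, df = df, p = p, flag = p < 0.05),
            class = "heterogeneity_report")
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4g on %d df, p = %.3g%s\n", x$Q, x$df, x$p,
              if (x$flag) "  [heterogeneity]" else ""))
  invisible(x)
}

#' Egger intercept test for directional pleiotropy
#'
#' The intercept of the MR-Egger regression estimates the average
#' directional pleiotropic effect; a two-sided t-test with L-2 degrees of
#' freedom against zero.
#'
#' @param hset A \code{harmonized_set} with at least 3 SNPs.
#' @return list(intercept, se, p).
#' @export
egger_intercept_test <- function(hset) {
  e <- mr_egger(hset)
  list(intercept = e$egger_intercept, se = e$egger_intercept_se,
       p = e$egger_intercept_p)
}

# Leave-one-out fixed-effect IVW slopes and weighted squared residuals for
# observed or simulated effect matrices. gx, gy: n_set x L matrices (rows =
# datasets); w: length-L weights 1/sy^2. Returns list(resid: n_set x L,
# rss: n_set).
loo_residuals <- function(gx, gy, w) {
  wr <- matrix(w, nrow = nrow(gx), ncol = length(w), byrow = TRUE)
  sxy <- rowSums(wr * gx * gy)
  sxx <- rowSums(wr * gx^2)
  beta_loo <- (sxy - wr * gx * gy) / (sxx - wr * gx^2)
  resid <- wr * (gy - beta_loo * gx)^2
  list(resid = resid, rss = rowSums(resid), beta_loo = beta_loo)
}

# One simulated null ensemble shared by the global and outlier tests.
presso_ensemble <- function(d, n_distribution, seed) {
  L <- nrow(d)
  w <- 1 / d$se_out^2
  obs <- loo_residuals(matrix(d$beta_exp, 1), matrix(d$beta_out, 1), w)
  exp_out <- obs$beta_loo[1, ] * d$beta_exp  # expected outcome effects under the LOO fits
  # simulated normals are attached to SNP identity (columns drawn in sorted
  # id order), so results are exactly equivariant under input reordering
  rk <- rank(d$snp_id, ties.method = "first")
  sims <- withr_seed(seed, {
    z1 <- matrix(stats::rnorm(n_distribution * L), nrow = n_distribution)[, rk, drop = FALSE]
    z2 <- matrix(stats::rnorm(n_distribution * L), nrow = n_distribution)[, rk, drop = FALSE]
    gx <- sweep(sweep(z1, 2, d$se_exp, "*"), 2, d$beta_exp, "+")
    gy <- sweep(sweep(z2, 2, d$se_out, "*"), 2, exp_out, "+")
    loo_residuals(gx, gy, w)
  })
  list(obs_resid = obs$resid[1, ], obs_rss = obs$rss[1],
       sim_resid = sims$resid, sim_rss = sims$rss, n = n_distribution)
}

#' Global pleiotropy test (residual-sum-of-squares)
#'
#' The observed statistic is the inverse-variance weighted residual sum of
#' squares of each SNP's outcome effect about the leave-one-out IVW fit.
#' Its null distribution is simulated parametrically: exposure effects are
#' redrawn from their sampling distributions and outcome effects from the
#' leave-one-out fitted values, and the statistic recomputed. The empirical
#' p-value uses the (1+k)/(1+N) estimator and is therefore never zero.
#'
#' @param hset A \code{harmonized_set} with at least 4 SNPs (the
#'   leave-one-out fit needs at least 3 remaining).
#' @param n_distribution Number of null simulations (default 10000).
#' @param seed Integer seed.
#' @return list(global_rss, global_p, n_distribution).
#' @export
presso_global <- function(hset, n_distribution = 10000, seed = 1) {
  d <- hset$data
  if (nrow(d) < 4) stop("insufficient instruments for PRESSO", call. = FALSE)
  ens <- presso_ensemble(d, n_distribution, seed)
  list(global_rss = ens$obs_rss,
       global_p = (1 + sum(ens$sim_rss >= ens$obs_rss)) / (n_distribution + 1),
       n_distribution = n_distribution)
}

#' Per-SNP outlier test
#'
#' Each SNP's observed weighted squared residual is compared with its own
#' simulated residual distribution from the global-test ensemble; empirical
#' p-values are Bonferroni-adjusted by the instrument count.
#'
#' @inheritParams presso_global
#' @return data.frame (snp_id, raw_p, adj_p).
#' @export
presso_outlier_test <- function(hset, n_distribution = 10000, seed = 1) {
  d <- hset$data
  if (nrow(d) < 4) stop("insufficient instruments for PRESSO", call. = FALSE)
  ens <- presso_ensemble(d, n_distribution, seed)
  raw <- vapply(seq_len(nrow(d)), function(j) {
    (1 + sum(ens$sim_resid[, j] >= ens$obs_resid[j])) / (n_distribution + 1)
  }, numeric(1))
  data.frame(snp_id = d$snp_id, raw_p = raw,
             adj_p = pmin(1, raw * nrow(d)), stringsAsFactors = FALSE)
}

#' Sequential outlier removal
#'
#' Runs the global pleiotropy test; while it is significant (p <= alpha) the
#' SNP with the smallest outlier-test p-value on the current set (ties
#' broken lexicographically by SNP id) is removed and the global test rerun
#' on the remainder. Outlier p-values are re-ranked on each iteration's
#' remaining set (\code{freeze_ranking = TRUE} instead ranks once on the
#' initial set). The loop hard-stops, with a note, when fewer than 4 SNPs
#' would remain. A distortion test compares the IVW estimate before and
#' after removal: the difference is scaled by a parametric-bootstrap
#' standard error of the difference and referred to the normal.
#'
#' @inheritParams presso_global
#' @param alpha Significance level for the global test (default 0.05).
#' @param freeze_ranking Rank outliers once on the initial set.
#' @param n_boot_distortion Bootstrap resamples for the distortion test.
#' @return A \code{presso_report}: list with global_rss, global_p (final),
#'   initial_global_p, outlier_p (initial set), removed (ordered snp_ids),
#'   trace (per-iteration data.frame), distortion_p, beta_before,
#'   beta_after, n_distribution, seed, exhausted (TRUE when the hard stop
#'   triggered).
#' @export
sequential_outlier_removal <- function(hset, n_distribution = 10000, seed = 1,
                                       alpha = 0.05, freeze_ranking = FALSE,
                                       n_boot_distortion = 500) {
  if (n_snps(hset) < 4) stop("insufficient instruments for PRESSO", call. = FALSE)
  current <- hset
  removed <- character()
  trace <- list()
  initial_outlier <- NULL
  initial_global <- NULL
  frozen_rank <- NULL
  exhausted <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    g <- presso_global(current, n_distribution, seed + iter)
    out_p <- presso_outlier_test(current, n_distribution, seed + iter)
    if (iter == 1L) {
      initial_outlier <- out_p
      initial_global <- g
      frozen_rank <- out_p
    }
    if (g$global_p > alpha) {
      trace[[iter]] <- data.frame(iteration = iter, snp_id = NA_character_,
                                  outlier_p = NA_real_, global_p = g$global_p,
                                  stringsAsFactors = FALSE)
      break
    }
    if (n_snps(current) - 1L < 4L) {
      exhausted <- TRUE
      trace[[iter]] <- data.frame(iteration = iter, snp_id = NA_character_,
                                  outlier_p = NA_real_, global_p = g$global_p,
                                  stringsAsFactors = FALSE)
      break
    }
    rank_tab <- if (freeze_ranking) {
      frozen_rank[frozen_rank$snp_id %in% current$data$snp_id, , drop = FALSE]
    } else out_p
    ord <- order(rank_tab$raw_p, rank_tab$snp_id)
    victim <- rank_tab$snp_id[ord[1]]
    removed <- c(removed, victim)
    trace[[iter]] <- data.frame(iteration = iter, snp_id = victim,
                                outlier_p = rank_tab$raw_p[ord[1]],
                                global_p = g$global_p, stringsAsFactors = FALSE)
    current <- subset_hset(current, current$data$snp_id != victim)
  }
  beta_before <- mr_ivw(hset)$beta
  beta_after <- mr_ivw(current)$beta
  distortion_p <- NA_real_
  if (length(removed)) {
    d <- hset$data
    keep <- !(d$snp_id %in% removed)
    diffs <- withr_seed(seed + 10000L, {
      vapply(seq_len(n_boot_distortion), function(i) {
        gx <- stats::rnorm(nrow(d), d$beta_exp, d$se_exp)
        gy <- stats::rnorm(nrow(d), d$beta_out, d$se_out)
        b_full <- ivw_slope(gx, gy, d$se_out)$beta
        b_sub <- ivw_slope(gx[keep], gy[keep], d$se_out[keep])$beta
        b_sub - b_full
      }, numeric(1))
    })
    z <- (beta_after - beta_before) / stats::sd(diffs)
    distortion_p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(
    global_rss = initial_global$global_rss,
    initial_global_p = initial_global$global_p,
    global_p = trace[[length(trace)]]$global_p,
    outlier_p = initial_outlier,
    removed = removed,
    trace = do.call(rbind, trace),
    distortion_p = distortion_p,
    beta_before = beta_before, beta_after = beta_after,
    n_distribution = n_distribution, seed = seed, exhausted = exhausted
  ), class = "presso_report")
}

#' @export
print.presso_report <- function(x, ...) {
  cat(sprintf("Global pleiotropy test: RSS = %.4g, initial p = %.3g, final p = %.3g\n",
              x$global_rss, x$initial_global_p, x$global_p))
  if (length(x$removed)) {
    cat("  removed:", paste(x$removed, collapse = ", "),
        sprintf(" (distortion p = %.3g)\n", x$distortion_p))
  } else {
    cat("  no outliers removed\n")
  }
  if (x$exhausted) cat("  note: stopped with global test still significant (too few SNPs)\n")
  invisible(x)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate excluding each SNP in turn, plus the full-set
#' estimate (row \code{"All"}). The result carries a \code{driver}
#' attribute, TRUE when any single exclusion changes the sign of the
#' estimate or moves its 95\% confidence interval across zero relative to
#' the full set.
#'
#' @param hset A \code{harmonized_set} with at least 4 SNPs.
#' @param model IVW variance model.
#' @return data.frame (snp_id, beta, se, ci_low, ci_high, pval), one row per
#'   excluded SNP plus the full-set row.
#' @export
leave_one_out <- function(hset, model = "re") {
  L <- n_snps(hset)
  if (L < 4) stop("leave-one-out needs at least 4 instruments", call. = FALSE)
  rows <- lapply(seq_len(L), function(j) {
    e <- mr_ivw(subset_hset(hset, -j), model = model)
    data.frame(snp_id = hset$data$snp_id[j], beta = e$beta, se = e$se,
               ci_low = e$beta - 1.96 * e$se, ci_high = e$beta + 1.96 * e$se,
               pval = e$pval, stringsAsFactors = FALSE)
  })
  full <- mr_ivw(hset, model = model)
  rows[[L + 1]] <- data.frame(snp_id = "All", beta = full$beta, se = full$se,
                              ci_low = full$beta - 1.96 * full$se,
                              ci_high = full$beta + 1.96 * full$se,
                              pval = full$pval, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  loo <- out[out$snp_id != "All", ]
  full_excl0 <- full$beta - 1.96 * full$se > 0 || full$beta + 1.96 * full$se < 0
  driver <- any(sign(loo$beta) != sign(full$beta)) ||
    (full_excl0 && any(loo$ci_low <= 0 & loo$ci_high >= 0))
  attr(out, "driver") <- driver
  out
}
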