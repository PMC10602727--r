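# Five summary-data MR estimators. All operate on a harmonized_set whose
# per-SNP vectors are the exposure effects (beta_exp, se_exp) and outcome
# effects (beta_out, se_out) aligned to a common effect allele.

mr_estimate <- function(method, beta, se, pval, n_snp, ...) {
  structure(c(list(method = method, beta = beta, se = se, pval = pval,
                   n_snp = n_snp), list(...)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (se %.4g), p = %.3g, L = %d\n",
              x$method, x$beta, x$se, x$pval, x$n_snp))
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  intercept = %.4g (se %.4g), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  }
  invisible(x)
}

#' Per-SNP Wald ratio estimates
#'
#' The ratio beta_out / beta_exp with first-order delta-method standard
#' error se_out / |beta_exp| (exposure sampling error ignored, the usual
#' no-measurement-error simplification). SNPs with a zero exposure effect
#' are excluded with a warning.
#'
#' @param hset A \code{harmonized_set}.
#' @return data.frame (snp_id, ratio, se, weight) where weight = 1/se^2.
#' @export
ratio_estimates <- function(hset) {
  d <- hset$data
  zero <- d$beta_exp == 0
  if (any(zero)) {
    warning(sum(zero), " SNP(s) with zero exposure effect excluded from ratio estimates",
            call. = FALSE)
    d <- d[!zero, , drop = FALSE]
  }
  ratio <- d$beta_out / d$beta_exp
  se <- d$se_out / abs(d$beta_exp)
  data.frame(snp_id = d$snp_id, ratio = ratio, se = se, weight = 1 / se^2,
             stringsAsFactors = FALSE)
}

# Fixed-effect IVW slope and its building blocks; shared by estimators and
# diagnostics.
ivw_slope <- function(gx, gy, sy) {
  w <- 1 / sy^2
  sw <- sum(w * gx^2)
  if (sw == 0) stop("all exposure effects are zero", call. = FALSE)
  list(beta = sum(w * gx * gy) / sw, sum_wx2 = sw, w = w)
}

#' Inverse-variance weighted estimate
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights 1/se_out^2. Under the multiplicative random-effects
#' model (default) the standard error is inflated by
#' sqrt(max(1, Q/(L-1))) where Q is Cochran's heterogeneity statistic;
#' \code{model = "fe"} gives the fixed-effect standard error. The p-value is
#' two-sided normal.
#'
#' @param hset A \code{harmonized_set} with at least 2 SNPs.
#' @param model \code{"re"} (multiplicative random effects, default) or
#'   \code{"fe"}.
#' @return An \code{mr_estimate}.
#' @export
mr_ivw <- function(hset, model = c("re", "fe")) {
  model <- match.arg(model)
  d <- hset$data
  L <- nrow(d)
  if (L < 2) stop("IVW needs at least 2 instruments", call. = FALSE)
  fit <- ivw_slope(d$beta_exp, d$beta_out, d$se_out)
  Q <- sum((d$beta_out - fit$beta * d$beta_exp)^2 / d$se_out^2)
  phi <- if (model == "re") max(1, Q / (L - 1)) else 1
  se <- sqrt(phi / fit$sum_wx2)
  p <- 2 * stats::pnorm(-abs(fit$beta) / se)
  mr_estimate("ivw", fit$beta, se, p, L, Q = Q, model = model)
}

#' MR-Egger regression
#'
#' Each SNP is oriented so its exposure effect is non-negative (both effects
#' sign-flipped otherwise), then outcome effects are regressed on exposure
#' effects with an intercept, weights 1/se_out^2. The slope is the
#' pleiotropy-adjusted causal estimate; the intercept estimates average
#' directional pleiotropy. Standard errors are the unscaled weighted
#' least-squares errors inflated by max(1, sqrt(RSS/(L-2))); p-values are
#' two-sided t with L-2 degrees of freedom.
#'
#' @param hset A \code{harmonized_set} with at least 3 SNPs.
#' @return An \code{mr_estimate} carrying \code{egger_intercept},
#'   \code{egger_intercept_se}, \code{egger_intercept_p}.
#' @export
mr_egger <- function(hset) {
  d <- hset$data
  L <- nrow(d)
  if (L < 3) stop("MR-Egger needs at least 3 instruments", call. = FALSE)
  flip <- d$beta_exp < 0
  gx <- ifelse(flip, -d$beta_exp, d$beta_exp)
  gy <- ifelse(flip, -d$beta_out, d$beta_out)
  w <- 1 / d$se_out^2
  X <- cbind(1, gx)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * gy)
  coef <- solve(XtWX, XtWy)
  resid <- gy - X %*% coef
  rss <- sum(w * resid^2)
  scale <- max(1, sqrt(rss / (L - 2)))
  se <- sqrt(diag(solve(XtWX))) * scale
  coef <- unname(drop(coef))
  se <- unname(se)
  tval <- coef / se
  p <- 2 * stats::pt(-abs(tval), df = L - 2)
  mr_estimate("egger", coef[2], se[2], p[2], L,
              egger_intercept = coef[1], egger_intercept_se = se[1],
              egger_intercept_p = p[1], rss = rss)
}

# Weighted median of values b with positive weights w: order b ascending,
# form normalized cumulative weights s_j = cumsum(w') - w'/2, and linearly
# interpolate b across s at s = 0.5.
weighted_median_point <- function(b, w) {
  ord <- order(b)
  b <- b[ord]; w <- w[ord]
  wn <- w / sum(w)
  s <- cumsum(wn) - wn / 2
  if (0.5 <= s[1]) return(b[1])
  n <- length(b)
  if (0.5 >= s[n]) return(b[n])
  k <- max(which(s < 0.5))
  b[k] + (b[k + 1] - b[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

# Parametric bootstrap over the summary statistics: redraw each effect from
# its sampling distribution and recompute a point estimator.
boot_se <- function(d, point_fun, n_boot, seed) {
  if (n_boot <= 0) return(NA_real_)
  L <- nrow(d)
  est <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      gx <- stats::rnorm(L, d$beta_exp, d$se_exp)
      gy <- stats::rnorm(L, d$beta_out, d$se_out)
      point_fun(gx, gy)
    }, numeric(1))
  })
  stats::sd(est)
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Weighted-median estimate
#'
#' The inverse-variance weighted median of the per-SNP ratio estimates:
#' consistent when instruments carrying at least half the weight are valid.
#' The standard error comes from a seeded parametric bootstrap that redraws
#' both exposure and outcome effects from their sampling distributions.
#'
#' @param hset A \code{harmonized_set} with at least 3 SNPs.
#' @param n_boot Bootstrap resamples for the standard error (default 1000;
#'   0 skips the bootstrap and returns \code{se = NA}).
#' @param seed Integer seed for the bootstrap.
#' @return An \code{mr_estimate}.
#' @export
mr_weighted_median <- function(hset, n_boot = 1000, seed = 1) {
  d <- hset$data
  L <- nrow(d)
  if (L < 3) stop("weighted median needs at least 3 instruments", call. = FALSE)
  r <- ratio_estimates(hset)
  beta <- weighted_median_point(r$ratio, r$weight)
  point <- function(gx, gy) {
    ok <- gx != 0
    weighted_median_point(gy[ok] / gx[ok], gx[ok]^2 / d$se_out[ok]^2)
  }
  se <- boot_se(d, point, n_boot, seed)
  p <- if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(beta) / se)
  mr_estimate("weighted_median", beta, se, p, L)
}

# Kernel-density argmax of ratio estimates on a fixed grid. Bandwidth is
# phi * 0.9 * min(sd, IQR/1.349) * L^(-1/5); zero bandwidth (all ratios
# identical) collapses to the common ratio.
mode_point <- function(b, w, phi = 1, n_grid = 512) {
  L <- length(b)
  s <- stats::sd(b)
  iqr <- stats::IQR(b) / 1.349
  h <- phi * 0.9 * min(s, iqr) * L^(-1 / 5)
  if (!is.finite(h) || h <= 0) {
    h <- phi * 0.9 * s * L^(-1 / 5)  # IQR can be 0 with sd > 0
  }
  if (!is.finite(h) || h <= 0) return(b[1])
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = n_grid)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm(x, mean = b, sd = h)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Mode-based estimate (simple or weighted)
#'
#' The argmax of a Gaussian kernel density over the per-SNP ratio estimates,
#' evaluated on a 512-point grid spanning the ratio range plus three
#' bandwidths; consistent when the largest cluster of instruments is valid.
#' Weights are uniform (simple mode) or normalized inverse-variance
#' (weighted mode). Standard error by the same parametric bootstrap as the
#' weighted median; p-value two-sided t with L-1 degrees of freedom.
#'
#' @param hset A \code{harmonized_set} with at least 3 SNPs.
#' @param weighted Use inverse-variance weights (TRUE) or uniform (FALSE).
#' @param phi Bandwidth inflation factor (default 1).
#' @param n_boot Bootstrap resamples (default 1000; 0 skips).
#' @param seed Integer seed.
#' @return An \code{mr_estimate}.
#' @export
mr_mode <- function(hset, weighted = FALSE, phi = 1, n_boot = 1000, seed = 1) {
  d <- hset$data
  L <- nrow(d)
  if (L < 3) stop("mode estimator needs at least 3 instruments", call. = FALSE)
  r <- ratio_estimates(hset)
  wts <- if (weighted) r$weight / sum(r$weight) else rep(1 / L, L)
  beta <- mode_point(r$ratio, wts, phi = phi)
  point <- function(gx, gy) {
    ok <- gx != 0
    b <- gy[ok] / gx[ok]
    w <- if (weighted) {
      wv <- gx[ok]^2 / d$se_out[ok]^2
      wv / sum(wv)
    } else rep(1 / sum(ok), sum(ok))
    mode_point(b, w, phi = phi)
  }
  se <- boot_se(d, point, n_boot, seed)
  p <- if (is.na(se)) NA_real_ else 2 * stats::pt(-abs(beta) / se, df = L - 1)
  mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
              beta, se, p, L)
}

#' Odds ratio with 95\% confidence interval from a log-odds estimate
#'
#' @param beta Log-odds causal estimate.
#' @param se Standard error, positive.
#' @param z Normal quantile for the interval (default 1.96, two-sided 95\%).
#' @return list(or, ci_low, ci_high).
#' @export
or_from_beta <- function(beta, se, z = 1.96) {
  stopifnot(all(se > 0))
  list(or = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se))
}

#' Run all five estimators on one harmonized set
#'
#' @param hset A \code{harmonized_set} with at least 3 SNPs.
#' @param n_boot Bootstrap resamples for median/mode standard errors.
#' @param seed Integer seed.
#' @param ivw_model IVW variance model, \code{"re"} or \code{"fe"}.
#' @return data.frame with one row per method: method, n_snp, beta, se,
#'   pval, or, ci_low, ci_high.
#' @export
mr_all <- function(hset, n_boot = 1000, seed = 1, ivw_model = "re") {
  ests <- list(
    mr_ivw(hset, model = ivw_model),
    mr_egger(hset),
    mr_weighted_median(hset, n_boot = n_boot, seed = seed),
    mr_mode(hset, weighted = FALSE, n_boot = n_boot, seed = seed + 1L),
    mr_mode(hset, weighted = TRUE, n_boot = n_boot, seed = seed + 2L)
  )
  do.call(rbind, lapply(ests, function(e) {
    or <- if (is.na(e$se)) list(or = exp(e$beta), ci_low = NA, ci_high = NA)
          else or_from_beta(e$beta, e$se)
    data.frame(method = e$method, n_snp = e$n_snp, beta = e$beta, se = e$se,
               pval = e$pval, or = or$or, ci_low = or$ci_low,
               ci_high = or$ci_high, stringsAsFactors = FALSE)
  }))
}
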