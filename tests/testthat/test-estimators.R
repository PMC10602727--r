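# Independent oracles used below: origin-constrained WLS via stats::lm for
# IVW, a cumulative-weight walk for the weighted median, and a direct
# kernel-sum grid scan for the mode estimators.

oracle_wm <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  stats::approx(s, b, xout = 0.5, rule = 2)$y
}

oracle_mode <- function(b, w, phi = 1) {
  h <- phi * 0.9 * min(stats::sd(b), stats::IQR(b) / 1.349) * length(b)^(-0.2)
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = 512)
  dens <- sapply(grid, function(x) sum(w * exp(-(x - b)^2 / (2 * h^2))))
  grid[which.max(dens)]
}

test_that("ratio estimates are element-wise Wald ratios", {
  h <- harmonized_set(c("a", "b"), c(2, -1), c(0.1, 0.1), c(1, 0.3), c(0.2, 0.1))
  r <- ratio_estimates(h)
  expect_equal(r$ratio, c(0.5, -0.3))
  expect_equal(r$se, c(0.1, 0.1))
  p <- simulate_mr_pair(theta = 0.4, L = 10, seed = 21)
  h2 <- harmonized_set(p$exposure$SNP, p$exposure$beta, p$exposure$se,
                       p$outcome$beta, p$outcome$se)
  r2 <- ratio_estimates(h2)
  expect_equal(r2$ratio, p$outcome$beta / p$exposure$beta)
  expect_equal(r2$se, p$outcome$se / abs(p$exposure$beta))
  h3 <- h
  h3$data$beta_exp[1] <- 0
  expect_warning(r3 <- ratio_estimates(h3), "zero exposure effect")
  expect_equal(nrow(r3), 1)
})

test_that("IVW reproduces closed-form weighted sums and scales linearly", {
  h0 <- harmonized_set(c("a", "b"), c(1, 2), c(0.1, 0.1), c(0.5, 1), c(0.1, 0.1))
  e0 <- mr_ivw(h0)
  expect_equal(e0$beta, 0.5)
  expect_equal(e0$Q, 0)
  h <- harmonized_set(c("a", "b", "c"), c(1, 2, 3), c(0.1, 0.1, 0.1),
                      c(0.4, 1.0, 1.5), c(0.1, 0.2, 0.3))
  e <- mr_ivw(h)
  expect_equal(e$beta, 140 / 300)
  h2 <- h
  h2$data$beta_out <- 3 * h2$data$beta_out
  expect_equal(mr_ivw(h2)$beta, 3 * e$beta)
  expect_error(mr_ivw(harmonized_set("a", 1, 0.1, 0.5, 0.1)), "at least 2")
})

test_that("IVW equals origin-constrained WLS fitted independently", {
  for (s in 1:5) {
    h <- sim_hset(theta = 0.25, L = 30, seed = 300 + s)
    d <- h$data
    fit <- stats::lm(beta_out ~ beta_exp - 1, data = d,
                     weights = 1 / d$se_out^2)
    mine <- mr_ivw(h)
    expect_equal(mine$beta, unname(coef(fit)), tolerance = 1e-12)
    # random-effects SE equals the lm SE when the scale exceeds 1
    phi <- max(1, mine$Q / (nrow(d) - 1))
    lm_se <- summary(fit)$coefficients[1, 2]
    expect_equal(mine$se, lm_se * sqrt(phi) / summary(fit)$sigma,
                 tolerance = 1e-10)
  }
})

test_that("Egger recovers an exact affine relationship", {
  gx <- c(1, 2, 3)
  h <- harmonized_set(c("a", "b", "c"), gx, rep(0.05, 3),
                      0.1 + 0.5 * gx, c(0.1, 0.2, 0.3))
  e <- mr_egger(h)
  expect_equal(e$beta, 0.5, tolerance = 1e-12)
  expect_equal(e$egger_intercept, 0.1, tolerance = 1e-12)
  expect_error(mr_egger(harmonized_set(c("a", "b"), 1:2, c(1, 1) * 0.1,
                                       1:2 * 0.5, c(1, 1) * 0.1)),
               "at least 3")
})

test_that("Egger matches an independent weighted lm with oriented effects", {
  for (s in 1:5) {
    h <- sim_hset(theta = 0.25, L = 25, seed = 400 + s)
    d <- h$data
    flip <- sign(d$beta_exp)
    gx <- d$beta_exp * flip
    gy <- d$beta_out * flip
    fit <- stats::lm(gy ~ gx, weights = 1 / d$se_out^2)
    sm <- summary(fit)
    mine <- mr_egger(h)
    expect_equal(mine$beta, unname(coef(fit)[2]), tolerance = 1e-12)
    scale <- max(1, sm$sigma)
    expect_equal(mine$se, sm$coefficients[2, 2] / sm$sigma * scale,
                 tolerance = 1e-10)
    expect_equal(mine$pval,
                 2 * pt(-abs(mine$beta / mine$se), df = nrow(d) - 2))
  }
})

test_that("weighted median interpolates cumulative weights to one half", {
  h <- harmonized_set(letters[1:3], c(1, 1, 1), rep(0.1, 3),
                      c(0.2, 0.5, 0.9), rep(0.1, 3))
  expect_equal(mr_weighted_median(h, n_boot = 0)$beta, 0.5)
  expect_equal(microMR:::weighted_median_point(c(0, 1), c(0.5, 0.5)), 0.5)
  set.seed(31)
  for (i in 1:10) {
    b <- rnorm(5)
    w <- runif(5, 0.2, 2)
    expect_equal(microMR:::weighted_median_point(b, w), oracle_wm(b, w),
                 tolerance = 1e-12)
  }
})

test_that("weighted-median bootstrap SE is seeded and reproducible", {
  h <- sim_hset(theta = 0.3, L = 20, seed = 8)
  a <- mr_weighted_median(h, n_boot = 200, seed = 99)
  b <- mr_weighted_median(h, n_boot = 200, seed = 99)
  c <- mr_weighted_median(h, n_boot = 200, seed = 100)
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, c$se))
  expect_gt(a$se, 0)
})

test_that("mode estimators collapse on degenerate input and resist outliers", {
  h <- harmonized_set(letters[1:3], c(1, 2, 4), rep(0.1, 3),
                      0.7 * c(1, 2, 4), rep(0.1, 3))
  expect_equal(mr_mode(h, n_boot = 0)$beta, 0.7)
  h2 <- harmonized_set(letters[1:4], rep(1, 4), rep(0.1, 4),
                       c(0.5, 0.5, 0.5, 5), rep(0.1, 4))
  est <- mr_mode(h2, weighted = FALSE, n_boot = 0)$beta
  expect_lt(abs(est - 0.5), abs(est - 1.625))
})

test_that("mode argmax equals a direct kernel-sum grid evaluation", {
  b <- c(-0.2, 0.1, 0.12, 0.15, 0.4, 0.45, 1.1)
  h <- harmonized_set(paste0("s", 1:7), rep(1, 7), rep(0.1, 7), b, rep(0.1, 7))
  expect_equal(mr_mode(h, weighted = FALSE, n_boot = 0)$beta,
               oracle_mode(b, rep(1 / 7, 7)), tolerance = 1e-12)
  w <- (1:7) / sum(1:7)
  hw <- harmonized_set(paste0("s", 1:7), rep(1, 7), rep(0.1, 7), b,
                       1 / sqrt(1:7))
  expect_equal(mr_mode(hw, weighted = TRUE, n_boot = 0)$beta,
               oracle_mode(b, w), tolerance = 1e-12)
})

test_that("all estimators collapse to the common ratio on exact-fit data", {
  gx <- c(0.5, 1, 2, 3)
  h <- harmonized_set(paste0("s", 1:4), gx, rep(0.05, 4), 0.3 * gx,
                      rep(0.1, 4))
  expect_equal(mr_ivw(h)$beta, 0.3)
  expect_equal(mr_weighted_median(h, n_boot = 0)$beta, 0.3)
  expect_equal(mr_mode(h, n_boot = 0)$beta, 0.3, tolerance = 1e-9)
  expect_equal(mr_mode(h, weighted = TRUE, n_boot = 0)$beta, 0.3,
               tolerance = 1e-9)
  # egger: slope through the points with zero intercept
  expect_equal(mr_egger(h)$beta, 0.3, tolerance = 1e-10)
})

test_that("negating outcome effects negates every point estimate", {
  h <- sim_hset(theta = 0.3, L = 15, seed = 17)
  hneg <- h
  hneg$data$beta_out <- -hneg$data$beta_out
  expect_equal(mr_ivw(hneg)$beta, -mr_ivw(h)$beta)
  expect_equal(mr_ivw(hneg)$se, mr_ivw(h)$se)
  expect_equal(mr_egger(hneg)$beta, -mr_egger(h)$beta)
  expect_equal(mr_weighted_median(hneg, n_boot = 0)$beta,
               -mr_weighted_median(h, n_boot = 0)$beta)
  expect_equal(mr_mode(hneg, n_boot = 0)$beta, -mr_mode(h, n_boot = 0)$beta)
})

test_that("odds-ratio transformation exponentiates the estimate and interval", {
  o <- or_from_beta(0, 0.1)
  expect_equal(o$or, 1)
  expect_equal(o$ci_low, exp(-1.96 * 0.1))
  expect_equal(o$ci_high, exp(1.96 * 0.1))
  expect_error(or_from_beta(0.5, 0), "se > 0")
  o2 <- or_from_beta(0.778, 0.265)
  expect_true(o2$ci_low < o2$or && o2$or < o2$ci_high)
})

test_that("estimators recover the causal effect up to attenuation bias", {
  # With instrument noise, IVW converges to theta * sum(w g^2) /
  # sum(w (g^2 + sx^2)) rather than theta; the other estimators carry
  # comparable or larger dilution (Egger the largest). Checked against the
  # closed-form attenuated expectation computed from the generating truth.
  reps <- 100
  theta <- 0.3
  est <- matrix(NA_real_, reps, 5,
                dimnames = list(NULL, c("ivw", "egger", "wm", "sm", "wmod")))
  lambda <- numeric(reps)
  for (s in seq_len(reps)) {
    p <- simulate_mr_pair(theta = theta, L = 100, seed = 6000 + s)
    h <- harmonized_set(p$exposure$SNP, p$exposure$beta, p$exposure$se,
                        p$outcome$beta, p$outcome$se)
    w <- 1 / p$outcome$se^2
    g <- p$truth$gamma_true
    lambda[s] <- sum(w * g^2) / sum(w * (g^2 + p$exposure$se^2))
    est[s, ] <- c(mr_ivw(h)$beta, mr_egger(h)$beta,
                  mr_weighted_median(h, n_boot = 0)$beta,
                  mr_mode(h, n_boot = 0)$beta,
                  mr_mode(h, weighted = TRUE, n_boot = 0)$beta)
  }
  mcse_ivw <- sd(est[, "ivw"]) / sqrt(reps)
  expect_lt(abs(mean(est[, "ivw"]) - theta * mean(lambda)), 3 * mcse_ivw)
  for (m in c("ivw", "wm")) {
    expect_lt(abs(mean(est[, m]) - theta), 0.05 * theta)
  }
  # the mode estimators carry somewhat larger finite-sample dilution than
  # the ratio-mean estimators; Egger the largest (attenuation on var(gamma))
  for (m in c("sm", "wmod")) {
    expect_lt(abs(mean(est[, m]) - theta), 0.075 * theta)
  }
  expect_lt(abs(mean(est[, "egger"]) - theta), 0.15 * theta)
})

test_that("mr_all tabulates five methods with odds ratios", {
  h <- sim_hset(theta = 0.3, L = 12, seed = 23)
  tab <- mr_all(h, n_boot = 100, seed = 4)
  expect_equal(nrow(tab), 5)
  expect_setequal(tab$method, c("ivw", "egger", "weighted_median",
                                "simple_mode", "weighted_mode"))
  expect_equal(tab$or, exp(tab$beta))
  expect_true(all(tab$ci_low < tab$or & tab$or < tab$ci_high))
  expect_true(all(tab$n_snp == 12))
})
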