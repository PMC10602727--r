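# Orchestration of the full bidirectional screen: per-taxon instrument
# selection and QC, outlier removal, the five estimators, diagnostics,
# rank-level multiple-testing thresholds, and the reverse-direction pass.

#' Analysis configuration
#'
#' Collects every threshold and seed used by the pipeline. Defaults are the
#' conventional two-sample MR filter stack for microbiome exposures:
#' instrument p-value ceiling 1e-5 forward and genome-wide 5e-8 reverse, LD
#' r-squared ceiling 0.001 in a 10000 kb window, F-statistic floor 10,
#' 10000 pleiotropy-test simulations, and per-rank Bonferroni correction at
#' overall alpha 0.05.
#'
#' @param seed Integer seed (mandatory).
#' @param p_select Forward instrument p-value ceiling.
#' @param p_select_reverse Reverse-direction ceiling.
#' @param r2_threshold,window_kb LD clumping parameters.
#' @param f_min F-statistic retention floor.
#' @param f_method F-statistic variant, \code{"wald"} or \code{"r2"}.
#' @param n_distribution Pleiotropy-test simulation count.
#' @param n_boot Bootstrap resamples for median/mode standard errors.
#' @param alpha Overall significance level.
#' @param ivw_model IVW variance model, \code{"re"} or \code{"fe"}.
#' @param freeze_outlier_ranking Rank pleiotropy outliers once on the
#'   initial set rather than re-ranking per iteration.
#' @return A named list of class \code{mr_config}.
#' @export
mr_config <- function(seed, p_select = 1e-5, p_select_reverse = 5e-8,
                      r2_threshold = 0.001, window_kb = 10000, f_min = 10,
                      f_method = "wald", n_distribution = 10000,
                      n_boot = 1000, alpha = 0.05, ivw_model = "re",
                      freeze_outlier_ranking = FALSE) {
  if (missing(seed) || !is.numeric(seed)) stop("an integer seed is mandatory", call. = FALSE)
  stopifnot(p_select > 0, p_select <= 1, p_select_reverse > 0,
            p_select_reverse <= 1, r2_threshold > 0, r2_threshold <= 1,
            window_kb > 0, f_min >= 0, n_distribution >= 1, n_boot >= 0,
            alpha > 0, alpha < 1)
  structure(list(seed = as.integer(seed), p_select = p_select,
                 p_select_reverse = p_select_reverse,
                 r2_threshold = r2_threshold, window_kb = window_kb,
                 f_min = f_min, f_method = f_method,
                 n_distribution = n_distribution, n_boot = n_boot,
                 alpha = alpha, ivw_model = ivw_model,
                 freeze_outlier_ranking = freeze_outlier_ranking),
            class = "mr_config")
}

#' Rank-level Bonferroni threshold
#'
#' The per-rank significance threshold alpha / n, where n is the number of
#' independent taxa with a reported result at that taxonomic rank.
#'
#' @param n_taxa_at_rank Positive integer count of reported taxa.
#' @param alpha Overall level (default 0.05).
#' @return The threshold alpha / n.
#' @export
rank_threshold <- function(n_taxa_at_rank, alpha = 0.05) {
  if (any(n_taxa_at_rank < 1)) stop("taxa count must be at least 1", call. = FALSE)
  alpha / n_taxa_at_rank
}

# One taxon through the QC + estimation stack. Returns either a result
# record or an exclusion record.
analyse_one <- function(taxon, rank, exposure, outcome, config, ld,
                        exclusion_list, p_select, seed) {
  counts <- c(input = nrow(exposure))
  cand <- select_candidates(exposure, p_select)
  counts["p_selected"] <- nrow(cand)
  cand <- suppressWarnings(clump(cand, ld, config$r2_threshold, config$window_kb))
  counts["clumped"] <- nrow(cand)
  cand <- exclude_confounder_snps(cand, exclusion_list)
  excluded_snps <- attr(cand, "excluded")
  counts["confounder_filtered"] <- nrow(cand)
  cand <- filter_weak_instruments(cand, config$f_min, method = config$f_method)
  counts["strong"] <- nrow(cand)
  hset <- harmonize(cand, outcome, pair_label = taxon)
  counts["harmonized"] <- n_snps(hset)

  presso <- NULL
  if (n_snps(hset) >= 4) {
    presso <- sequential_outlier_removal(
      hset, n_distribution = config$n_distribution, seed = seed,
      alpha = config$alpha, freeze_ranking = config$freeze_outlier_ranking)
    if (length(presso$removed)) {
      hset <- subset_hset(hset, !(hset$data$snp_id %in% presso$removed))
    }
  }
  counts["final"] <- n_snps(hset)
  if (n_snps(hset) < 3) {
    return(list(excluded = TRUE, taxon = taxon, rank = rank,
                reason = "fewer than three shared SNPs", counts = counts))
  }
  estimates <- mr_all(hset, n_boot = config$n_boot, seed = seed,
                      ivw_model = config$ivw_model)
  diagnostics <- list(
    heterogeneity = cochran_q(hset),
    egger_intercept = egger_intercept_test(hset),
    presso = presso,
    loo = if (n_snps(hset) >= 4) leave_one_out(hset, model = config$ivw_model) else NULL
  )
  list(excluded = FALSE, taxon = taxon, rank = rank, estimates = estimates,
       diagnostics = diagnostics, n_snp_final = n_snps(hset),
       counts = counts, confounder_exclusions = excluded_snps,
       harmonization_dropped = hset$dropped)
}

screen_direction <- function(exposures, ranks, outcome, config, ld,
                             exclusion_list, p_select) {
  if (nrow(outcome) == 0) stop("empty outcome table", call. = FALSE)
  results <- list()
  excluded <- list()
  for (i in seq_along(exposures)) {
    taxon <- names(exposures)[i]
    rank <- unname(ranks[taxon])
    res <- tryCatch(
      analyse_one(taxon, rank, exposures[[i]], outcome, config, ld,
                  exclusion_list, p_select, seed = config$seed + i),
      error = function(e) list(excluded = TRUE, taxon = taxon, rank = rank,
                               reason = conditionMessage(e), counts = NULL)
    )
    if (isTRUE(res$excluded)) excluded[[length(excluded) + 1L]] <- res
    else results[[taxon]] <- res
  }
  list(results = results, excluded = excluded)
}

#' Forward screen: every taxon as exposure against one outcome
#'
#' Runs the full per-taxon stack — p-value selection, LD clumping,
#' confounder exclusion, weak-instrument filtering, harmonization,
#' sequential pleiotropy-outlier removal — then the five estimators and
#' diagnostics for every taxon retaining at least three instruments. The
#' rank-level threshold is alpha divided by the count of taxa with a
#' reported result at that rank; the significance flag applies it to the
#' IVW p-value. Per-taxon failures are quarantined with a reason rather
#' than aborting the screen.
#'
#' @param exposures Named list of exposure summary-statistics tables.
#' @param ranks Named character vector mapping taxon name to taxonomic rank.
#' @param outcome Outcome summary-statistics table.
#' @param config An \code{\link{mr_config}}.
#' @param ld Optional \code{ld_matrix} for clumping.
#' @param exclusion_list Optional confounder-SNP exclusion data.frame
#'   (snp_id, trait).
#' @return An object of class \code{mr_screen}: list(results, excluded,
#'   thresholds, config, direction).
#' @export
run_forward <- function(exposures, ranks, outcome, config, ld = NULL,
                        exclusion_list = NULL) {
  sc <- screen_direction(exposures, ranks, outcome, config, ld,
                         exclusion_list, config$p_select)
  reported_ranks <- vapply(sc$results, function(r) r$rank, character(1))
  thresholds <- if (length(reported_ranks)) {
    tab <- table(reported_ranks)
    data.frame(rank = names(tab), n_taxa = as.integer(tab),
               threshold = rank_threshold(as.integer(tab), config$alpha),
               stringsAsFactors = FALSE)
  } else {
    data.frame(rank = character(), n_taxa = integer(), threshold = numeric(),
               stringsAsFactors = FALSE)
  }
  for (taxon in names(sc$results)) {
    r <- sc$results[[taxon]]
    ivw_p <- r$estimates$pval[r$estimates$method == "ivw"]
    thr <- thresholds$threshold[thresholds$rank == r$rank]
    sc$results[[taxon]]$nominal <- ivw_p < 0.05
    sc$results[[taxon]]$significant <- ivw_p < thr
    sc$results[[taxon]]$rank_threshold <- thr
  }
  structure(list(results = sc$results, excluded = sc$excluded,
                 thresholds = thresholds, config = config,
                 direction = "forward"),
            class = "mr_screen")
}

#' Reverse screen: the outcome as exposure against identified taxa
#'
#' Re-runs the same stage sequence with the disease as exposure (instrument
#' ceiling \code{p_select_reverse}, genome-wide significance) and each
#' identified taxon as outcome. A taxon's no-reverse-causality flag is set
#' when the reverse IVW p-value is at or above 0.05.
#'
#' @param outcome_as_exposure The disease summary-statistics table.
#' @param identified_taxa Named list of taxon summary-statistics tables to
#'   use as outcomes.
#' @param ranks Named character vector of taxonomic ranks.
#' @param config An \code{\link{mr_config}}.
#' @param ld,exclusion_list As in \code{\link{run_forward}}.
#' @return An \code{mr_screen} with direction \code{"reverse"}; each result
#'   carries \code{no_reverse_causality}.
#' @export
run_reverse <- function(outcome_as_exposure, identified_taxa, ranks, config,
                        ld = NULL, exclusion_list = NULL) {
  if (length(identified_taxa) == 0) stop("no identified taxa supplied", call. = FALSE)
  results <- list()
  excluded <- list()
  for (i in seq_along(identified_taxa)) {
    taxon <- names(identified_taxa)[i]
    rank <- unname(ranks[taxon])
    res <- tryCatch(
      analyse_one(taxon, rank, outcome_as_exposure, identified_taxa[[i]],
                  config, ld, exclusion_list, config$p_select_reverse,
                  seed = config$seed + i),
      error = function(e) list(excluded = TRUE, taxon = taxon, rank = rank,
                               reason = conditionMessage(e), counts = NULL)
    )
    if (isTRUE(res$excluded)) {
      excluded[[length(excluded) + 1L]] <- res
    } else {
      ivw_p <- res$estimates$pval[res$estimates$method == "ivw"]
      res$no_reverse_causality <- ivw_p >= 0.05
      results[[taxon]] <- res
    }
  }
  structure(list(results = results, excluded = excluded,
                 thresholds = data.frame(), config = config,
                 direction = "reverse"),
            class = "mr_screen")
}

#' @export
print.mr_screen <- function(x, ...) {
  cat(sprintf("%s MR screen: %d taxa reported, %d excluded\n",
              x$direction, length(x$results), length(x$excluded)))
  if (x$direction == "forward") {
    sig <- Filter(function(r) isTRUE(r$significant), x$results)
    cat("  significant at rank threshold:",
        if (length(sig)) paste(names(sig), collapse = ", ") else "none", "\n")
  }
  invisible(x)
}

#' Tabulate all estimates of a screen
#'
#' @param screen An \code{mr_screen}.
#' @return data.frame with one row per taxon and method.
#' @export
screen_estimates <- function(screen) {
  rows <- lapply(screen$results, function(r) {
    cbind(data.frame(taxon = r$taxon, rank = r$rank, stringsAsFactors = FALSE),
          r$estimates)
  })
  if (!length(rows)) {
    return(data.frame(taxon = character(), rank = character(),
                      method = character(), n_snp = integer(),
                      beta = numeric(), se = numeric(), pval = numeric(),
                      or = numeric(), ci_low = numeric(), ci_high = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write screen reports
#'
#' Writes a machine-readable estimates table (one row per taxon and method),
#' a diagnostics table, and a run manifest echoing the configuration, seeds
#' and per-stage SNP accounting.
#'
#' @param screen An \code{mr_screen}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(screen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(estimates = file.path(dir, "estimates.tsv"),
             diagnostics = file.path(dir, "diagnostics.tsv"),
             manifest = file.path(dir, "manifest.tsv"))
  est <- screen_estimates(screen)
  utils::write.table(format(est, digits = 10, trim = TRUE, scientific = NA),
                     paths["estimates"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  diag_rows <- lapply(screen$results, function(r) {
    d <- r$diagnostics
    rows <- data.frame(
      taxon = r$taxon,
      test = c("cochran_q", "egger_intercept"),
      statistic = c(d$heterogeneity$Q, d$egger_intercept$intercept),
      p = c(d$heterogeneity$p, d$egger_intercept$p),
      flag = c(d$heterogeneity$flag, d$egger_intercept$p < 0.05),
      stringsAsFactors = FALSE)
    if (!is.null(d$presso)) {
      rows <- rbind(rows, data.frame(
        taxon = r$taxon, test = "presso_global",
        statistic = d$presso$global_rss, p = d$presso$initial_global_p,
        flag = length(d$presso$removed) > 0, stringsAsFactors = FALSE))
    }
    if (!is.null(d$loo)) {
      rows <- rbind(rows, data.frame(
        taxon = r$taxon, test = "leave_one_out_driver",
        statistic = NA_real_, p = NA_real_,
        flag = attr(d$loo, "driver"), stringsAsFactors = FALSE))
    }
    rows
  })
  diag_df <- if (length(diag_rows)) do.call(rbind, diag_rows) else
    data.frame(taxon = character(), test = character(), statistic = numeric(),
               p = numeric(), flag = logical(), stringsAsFactors = FALSE)
  utils::write.table(format(diag_df, digits = 10, trim = TRUE, scientific = NA),
                     paths["diagnostics"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  cfg <- screen$config
  man <- c(
    sprintf("direction\t%s", screen$direction),
    sprintf("package_version\t%s", as.character(utils::packageVersion("microMR"))),
    vapply(names(unclass(cfg)), function(k) {
      sprintf("config.%s\t%s", k, format(cfg[[k]], digits = 15))
    }, character(1)),
    unlist(lapply(screen$results, function(r) {
      vapply(names(r$counts), function(st) {
        sprintf("counts.%s.%s\t%d", r$taxon, st, r$counts[[st]])
      }, character(1))
    })),
    vapply(screen$excluded, function(r) {
      sprintf("excluded.%s\t%s", r$taxon, r$reason)
    }, character(1)),
    if (nrow(screen$thresholds)) {
      vapply(seq_len(nrow(screen$thresholds)), function(i) {
        sprintf("threshold.%s\t%d\t%.10g", screen$thresholds$rank[i],
                screen$thresholds$n_taxa[i], screen$thresholds$threshold[i])
      }, character(1))
    }
  )
  writeLines(man, paths["manifest"])
  invisible(paths)
}
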