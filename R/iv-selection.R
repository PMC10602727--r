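#' Select candidate instruments by association p-value
#'
#' Keeps exactly the records with \code{pval < p_select}, preserving order.
#' The comparison is strict, matching the convention that an instrument must
#' fall below the stated ceiling.
#'
#' @param records Validated summary-statistics data.frame.
#' @param p_select Instrument p-value ceiling (default 1e-5, the relaxed
#'   microbiome-GWAS choice; genome-wide 5e-8 is used in the reverse
#'   direction).
#' @return The filtered data.frame.
#' @export
select_candidates <- function(records, p_select = 1e-5) {
  stopifnot(p_select > 0, p_select <= 1)
  out <- records[records$pval < p_select, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a pairwise LD matrix
#'
#' Accepts either long form (columns snp_a, snp_b, r2) or a square matrix
#' with SNP ids as header row and first column.
#'
#' @param path TSV path.
#' @return An \code{ld_matrix}: list with \code{snp_ids} and symmetric
#'   \code{r2} matrix (unit diagonal).
#' @export
read_ld_matrix <- function(path) {
  first <- utils::read.delim(path, nrows = 1, header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
  if (all(c("snp_a", "snp_b", "r2") %in% names(first))) {
    long <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    ids <- sort(unique(c(long$snp_a, long$snp_b)))
    r2 <- diag(1, length(ids))
    dimnames(r2) <- list(ids, ids)
    r2[cbind(match(long$snp_a, ids), match(long$snp_b, ids))] <- long$r2
    r2[cbind(match(long$snp_b, ids), match(long$snp_a, ids))] <- long$r2
  } else {
    m <- utils::read.delim(path, header = TRUE, row.names = 1,
                           check.names = FALSE)
    r2 <- as.matrix(m)
    ids <- rownames(r2)
    colnames(r2) <- ids
  }
  ld_matrix(ids, r2)
}

#' Construct an LD matrix object
#'
#' @param snp_ids Ordered identifiers.
#' @param r2 Symmetric matrix of pairwise r-squared values in [0,1], unit
#'   diagonal, dimensions matching \code{snp_ids}.
#' @export
ld_matrix <- function(snp_ids, r2) {
  r2 <- as.matrix(r2)
  stopifnot(nrow(r2) == length(snp_ids), ncol(r2) == length(snp_ids))
  if (any(abs(r2 - t(r2)) > 1e-8)) stop("LD matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(r2) - 1) > 1e-8)) stop("LD matrix diagonal must be 1", call. = FALSE)
  if (any(r2 < 0 | r2 > 1 + 1e-12)) stop("r2 values must lie in [0,1]", call. = FALSE)
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, r2 = r2), class = "ld_matrix")
}

#' Greedy LD clumping
#'
#' Sorts records by p-value ascending (ties broken lexicographically on SNP
#' id), then repeatedly promotes the best remaining SNP to index SNP and
#' discards every remaining SNP in LD with it (r-squared at or above
#' \code{r2_threshold}) within \code{window_kb} of its position. When
#' positions are unavailable the window condition is treated as satisfied;
#' SNPs absent from the LD matrix are treated as unlinked. With no LD matrix
#' at all, clumping degenerates to the distance/identity rule and a warning
#' is raised.
#'
#' @param records p-filtered summary-statistics data.frame.
#' @param ld An \code{ld_matrix} or NULL.
#' @param r2_threshold LD ceiling between retained instruments (default 0.001).
#' @param window_kb Clumping window in kilobases (default 10000).
#' @return Index SNPs sorted by p-value.
#' @export
clump <- function(records, ld = NULL, r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1, window_kb > 0)
  if (nrow(records) == 0) return(records)
  if (is.null(ld)) {
    warning("no LD matrix supplied; clumping treats all SNPs as unlinked",
            call. = FALSE)
  }
  ord <- order(records$pval, records$SNP)
  rec <- records[ord, , drop = FALSE]
  n <- nrow(rec)
  alive <- rep(TRUE, n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    if (i == n) break
    rest <- which(alive)
    r2v <- rep(0, length(rest))
    if (!is.null(ld)) {
      ii <- match(rec$SNP[i], ld$snp_ids)
      jj <- match(rec$SNP[rest], ld$snp_ids)
      ok <- !is.na(ii) & !is.na(jj)
      if (any(ok)) r2v[ok] <- ld$r2[ii, jj[ok]]
    }
    in_window <- rep(TRUE, length(rest))
    if (!is.null(rec$pos) && !is.na(rec$pos[i])) {
      pos_ok <- !is.na(rec$pos[rest])
      same_chr <- if (!is.null(rec$chr)) {
        !is.na(rec$chr[rest]) & !is.na(rec$chr[i]) & rec$chr[rest] == rec$chr[i]
      } else rep(TRUE, length(rest))
      # a SNP with known position on the same chromosome outside the window
      # cannot be clumped away by this index
      dist_ok <- abs(rec$pos[rest] - rec$pos[i]) <= window_kb * 1000
      in_window[pos_ok] <- (same_chr & dist_ok)[pos_ok]
    }
    alive[rest[r2v >= r2_threshold & in_window]] <- FALSE
  }
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude instruments associated with known confounders
#'
#' Removes records whose SNP id appears in a user-supplied exclusion list
#' (a static replacement for an interactive phenotype-lookup service), and
#' records the annotated trait for each removal.
#'
#' @param records Summary-statistics data.frame.
#' @param exclusion_list data.frame with columns \code{snp_id} and
#'   \code{trait}, or NULL for no exclusions.
#' @return Filtered data.frame with attribute \code{"excluded"}: data.frame
#'   (snp_id, trait) of removals.
#' @export
exclude_confounder_snps <- function(records, exclusion_list = NULL) {
  if (is.null(exclusion_list) || nrow(exclusion_list) == 0) {
    attr(records, "excluded") <- data.frame(snp_id = character(),
                                            trait = character(),
                                            stringsAsFactors = FALSE)
    return(records)
  }
  hit <- records$SNP %in% exclusion_list$snp_id
  excluded <- data.frame(
    snp_id = records$SNP[hit],
    trait = exclusion_list$trait[match(records$SNP[hit], exclusion_list$snp_id)],
    stringsAsFactors = FALSE
  )
  out <- records[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Per-instrument F-statistic
#'
#' Instrument-strength statistic for a single SNP. The default is the Wald
#' form F = (beta/se)^2; the variance-explained form
#' F = R2 (N - 2) / (1 - R2) with R2 = 2 maf (1 - maf) beta^2 is available
#' when allele frequency and sample size are known. At GWAS scales the two
#' agree closely.
#'
#' @param beta,se Effect and standard error (vectorized); \code{se > 0}.
#' @param method \code{"wald"} (default) or \code{"r2"}.
#' @param maf,n Minor allele frequency and sample size, required for
#'   \code{method = "r2"}.
#' @return Non-negative F values.
#' @export
f_statistic <- function(beta, se, method = c("wald", "r2"), maf = NULL, n = NULL) {
  method <- match.arg(method)
  if (method == "wald") {
    if (any(se <= 0)) stop("se must be positive", call. = FALSE)
    (beta / se)^2
  } else {
    if (is.null(maf) || is.null(n)) stop("r2 method needs maf and n", call. = FALSE)
    r2 <- 2 * maf * (1 - maf) * beta^2
    r2 * (n - 2) / (1 - r2)
  }
}

#' Drop weak instruments
#'
#' Retains exactly the records whose F-statistic is at least \code{f_min};
#' the conventional cutoff 10 flags weak instruments below it.
#'
#' @param records Summary-statistics data.frame.
#' @param f_min Retention threshold (default 10), inclusive.
#' @param method F-statistic variant, see \code{\link{f_statistic}}.
#' @return Filtered data.frame.
#' @export
filter_weak_instruments <- function(records, f_min = 10,
                                    method = c("wald", "r2")) {
  method <- match.arg(method)
  f <- if (method == "wald") {
    f_statistic(records$beta, records$se)
  } else {
    maf <- pmin(records$eaf, 1 - records$eaf)
    f_statistic(records$beta, records$se, method = "r2",
                maf = maf, n = records$samplesize)
  }
  out <- records[f >= f_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}
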