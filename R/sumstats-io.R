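# Canonical column set for a summary-statistics table. beta is the per-allele
# effect on the trait (log-odds for binary traits), se its standard error.
SUMSTATS_COLS <- c("SNP", "effect_allele", "other_allele", "beta", "se",
                   "pval", "eaf", "samplesize", "chr", "pos")
MANDATORY_COLS <- c("SNP", "effect_allele", "other_allele", "beta", "se", "pval")

VALID_BASES <- c("A", "C", "G", "T")

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated table with a header row, one row per SNP, and
#' validates each row. Rows failing validation (non-positive SE, p-value
#' outside (0,1], invalid or identical alleles, non-numeric effect fields)
#' are rejected and reported with their row numbers; valid rows are returned
#' in file order. Missing optional fields may be encoded as "." or left empty.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping canonical names
#'   (\code{SNP}, \code{effect_allele}, \code{other_allele}, \code{beta},
#'   \code{se}, \code{pval}, \code{eaf}, \code{samplesize}, \code{chr},
#'   \code{pos}) to the file's header names. Unmapped canonical names are
#'   looked up verbatim.
#' @param sep Field separator, tab by default.
#' @return A data.frame with canonical columns plus attribute
#'   \code{"rejected"}: a data.frame of (row, snp_id, reason) for rows that
#'   failed validation.
#' @export
read_sumstats <- function(path, column_map = NULL, sep = "\t") {
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, na.strings = c("NA", "."),
                           check.names = FALSE)
  resolve <- function(canon) {
    nm <- if (!is.null(column_map) && canon %in% names(column_map)) column_map[[canon]] else canon
    if (nm %in% names(raw)) raw[[nm]] else NULL
  }
  for (canon in MANDATORY_COLS) {
    if (is.null(resolve(canon))) {
      stop("missing mandatory column '", canon, "' in ", path, call. = FALSE)
    }
  }
  df <- data.frame(
    SNP = as.character(resolve("SNP")),
    effect_allele = toupper(as.character(resolve("effect_allele"))),
    other_allele = toupper(as.character(resolve("other_allele"))),
    beta = suppressWarnings(as.numeric(resolve("beta"))),
    se = suppressWarnings(as.numeric(resolve("se"))),
    pval = suppressWarnings(as.numeric(resolve("pval"))),
    stringsAsFactors = FALSE
  )
  opt_num <- function(canon) {
    v <- resolve(canon)
    if (is.null(v)) rep(NA_real_, nrow(df)) else suppressWarnings(as.numeric(v))
  }
  df$eaf <- opt_num("eaf")
  df$samplesize <- opt_num("samplesize")
  df$chr <- {
    v <- resolve("chr")
    if (is.null(v)) rep(NA_character_, nrow(df)) else as.character(v)
  }
  df$pos <- opt_num("pos")

  reason <- rep(NA_character_, nrow(df))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[cond & is.na(reason)] <<- why
  }
  bad(is.na(df$beta), "non-numeric beta")
  bad(is.na(df$se), "non-numeric se")
  bad(df$se <= 0, "nonpositive SE")
  bad(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "p-value outside (0,1]")
  bad(!(df$effect_allele %in% VALID_BASES) | !(df$other_allele %in% VALID_BASES),
      "invalid allele")
  bad(df$effect_allele == df$other_allele, "identical alleles")
  bad(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "eaf outside (0,1)")

  keep <- is.na(reason)
  rejected <- data.frame(row = which(!keep), snp_id = df$SNP[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write a summary-statistics table in the canonical TSV dialect
#'
#' @param records data.frame of validated records.
#' @param path Output path.
#' @export
write_sumstats <- function(records, path) {
  cols <- intersect(SUMSTATS_COLS, names(records))
  utils::write.table(records[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = ".")
  invisible(path)
}

#' Is an allele pair palindromic?
#'
#' A/T and C/G pairs read the same on both strands, so the effect allele
#' cannot be resolved from the alleles alone during harmonization.
#'
#' @param effect_allele,other_allele Single-base alleles (vectorized).
#' @return Logical vector, \code{TRUE} iff the pair is \{A,T\} or \{C,G\}.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  ea <- toupper(effect_allele); oa <- toupper(other_allele)
  if (!all(ea %in% VALID_BASES) || !all(oa %in% VALID_BASES)) {
    stop("invalid allele base", call. = FALSE)
  }
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

complement_base <- function(x) {
  c(A = "T", C = "G", G = "C", T = "A")[x]
}

#' Harmonize exposure and outcome summary statistics
#'
#' Joins the two tables on SNP identifier and aligns the outcome effects to
#' the exposure's effect allele. Alleles already matching are kept as-is;
#' swapped alleles (outcome effect allele equals the exposure other allele)
#' have the outcome beta sign-flipped and eaf replaced by 1-eaf; for
#' non-palindromic pairs a strand flip (base complement) is attempted before
#' declaring the alleles incompatible. All palindromic SNPs are dropped
#' unconditionally — no allele-frequency rescue. Every input SNP not retained
#' is accounted for in the audit list.
#'
#' @param exposure,outcome Validated record data.frames (see
#'   \code{\link{read_sumstats}}).
#' @param pair_label Character label for the exposure/outcome pair.
#' @return An object of class \code{harmonized_set}: a list with
#'   \itemize{
#'     \item \code{data}: data.frame with per-SNP columns \code{snp_id},
#'       \code{effect_allele}, \code{other_allele}, \code{beta_exp},
#'       \code{se_exp}, \code{pval_exp}, \code{eaf_exp}, \code{beta_out},
#'       \code{se_out}, \code{pval_out}, \code{eaf_out}, \code{action}
#'       (\code{"kept"}, \code{"flipped"}, \code{"strand_flipped"},
#'       \code{"strand_flipped_swapped"});
#'     \item \code{dropped}: data.frame (snp_id, reason);
#'     \item \code{pair_label}.
#'   }
#' @export
harmonize <- function(exposure, outcome, pair_label = "exposure~outcome") {
  if (anyDuplicated(exposure$SNP)) {
    stop("duplicate snp_id in exposure table: ambiguous join", call. = FALSE)
  }
  if (anyDuplicated(outcome$SNP)) {
    stop("duplicate snp_id in outcome table: ambiguous join", call. = FALSE)
  }
  dropped <- list()
  drop <- function(ids, reason) {
    if (length(ids)) {
      dropped[[length(dropped) + 1L]] <<- data.frame(
        snp_id = ids, reason = reason, stringsAsFactors = FALSE)
    }
  }
  only_exp <- setdiff(exposure$SNP, outcome$SNP)
  only_out <- setdiff(outcome$SNP, exposure$SNP)
  drop(only_exp, "unmatched")
  drop(only_out, "unmatched")

  shared <- intersect(exposure$SNP, outcome$SNP)
  ei <- match(shared, exposure$SNP)
  oi <- match(shared, outcome$SNP)
  e <- exposure[ei, , drop = FALSE]
  o <- outcome[oi, , drop = FALSE]

  pal <- is_palindromic(e$effect_allele, e$other_allele) |
    is_palindromic(o$effect_allele, o$other_allele)
  drop(shared[pal], "palindromic")
  keep <- !pal
  e <- e[keep, , drop = FALSE]; o <- o[keep, , drop = FALSE]
  shared <- shared[keep]

  action <- rep(NA_character_, length(shared))
  same <- o$effect_allele == e$effect_allele & o$other_allele == e$other_allele
  swap <- o$effect_allele == e$other_allele & o$other_allele == e$effect_allele
  oc_e <- complement_base(o$effect_allele)
  oc_o <- complement_base(o$other_allele)
  str_same <- !same & !swap & oc_e == e$effect_allele & oc_o == e$other_allele
  str_swap <- !same & !swap & oc_e == e$other_allele & oc_o == e$effect_allele
  action[same] <- "kept"
  action[swap] <- "flipped"
  action[str_same] <- "strand_flipped"
  action[str_swap] <- "strand_flipped_swapped"

  incompatible <- is.na(action)
  drop(shared[incompatible], "incompatible alleles")
  keep <- !incompatible
  e <- e[keep, , drop = FALSE]; o <- o[keep, , drop = FALSE]
  shared <- shared[keep]; action <- action[keep]

  flip <- action %in% c("flipped", "strand_flipped_swapped")
  beta_out <- ifelse(flip, -o$beta, o$beta)
  eaf_out <- ifelse(flip, 1 - o$eaf, o$eaf)

  data <- data.frame(
    snp_id = shared,
    effect_allele = e$effect_allele,
    other_allele = e$other_allele,
    beta_exp = e$beta, se_exp = e$se, pval_exp = e$pval, eaf_exp = e$eaf,
    beta_out = beta_out, se_out = o$se, pval_out = o$pval, eaf_out = eaf_out,
    action = action,
    stringsAsFactors = FALSE
  )
  rownames(data) <- NULL
  dropped_df <- if (length(dropped)) {
    do.call(rbind, dropped)
  } else {
    data.frame(snp_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(data = data, dropped = dropped_df, pair_label = pair_label),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized set:", x$pair_label, "\n")
  cat("  retained SNPs:", nrow(x$data), "\n")
  if (nrow(x$dropped)) {
    tab <- table(x$dropped$reason)
    cat("  dropped:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of instruments in a harmonized set
#' @param hset A \code{harmonized_set}.
#' @export
n_snps <- function(hset) nrow(hset$data)

# Build a harmonized_set directly from effect vectors; used by estimators'
# callers and throughout the tests.
#' Construct a harmonized set from per-SNP effect vectors
#'
#' Convenience constructor when harmonization has already happened (or for
#' simulated data): supplies the aligned exposure/outcome effect vectors
#' directly.
#'
#' @param snp_id Character identifiers.
#' @param beta_exp,se_exp Exposure per-SNP effects and standard errors.
#' @param beta_out,se_out Outcome per-SNP effects and standard errors.
#' @param pair_label Label for the pair.
#' @export
harmonized_set <- function(snp_id, beta_exp, se_exp, beta_out, se_out,
                           pair_label = "pair") {
  stopifnot(length(beta_exp) == length(snp_id),
            length(se_exp) == length(snp_id),
            length(beta_out) == length(snp_id),
            length(se_out) == length(snp_id),
            all(se_exp > 0), all(se_out > 0))
  data <- data.frame(
    snp_id = as.character(snp_id),
    effect_allele = NA_character_, other_allele = NA_character_,
    beta_exp = beta_exp, se_exp = se_exp, pval_exp = NA_real_, eaf_exp = NA_real_,
    beta_out = beta_out, se_out = se_out, pval_out = NA_real_, eaf_out = NA_real_,
    action = "kept", stringsAsFactors = FALSE
  )
  structure(list(data = data,
                 dropped = data.frame(snp_id = character(), reason = character(),
                                      stringsAsFactors = FALSE),
                 pair_label = pair_label),
            class = "harmonized_set")
}

# Subset a harmonized set by logical/index vector, preserving audit fields.
subset_hset <- function(hset, idx) {
  hset$data <- hset$data[idx, , drop = FALSE]
  rownames(hset$data) <- NULL
  hset
}

#' Write a harmonization audit trail
#'
#' @param hset A \code{harmonized_set}.
#' @param path Output TSV path; columns snp_id, action, reason.
#' @export
write_audit <- function(hset, path) {
  kept <- data.frame(snp_id = hset$data$snp_id, action = hset$data$action,
                     reason = "", stringsAsFactors = FALSE)
  drp <- data.frame(snp_id = hset$dropped$snp_id, action = "dropped",
                    reason = hset$dropped$reason, stringsAsFactors = FALSE)
  utils::write.table(rbind(kept, drp), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
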