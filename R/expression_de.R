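# FPKM quantification and differential-expression calling.
#
# The DE test is a pooled-replicate conditional exact binomial
# (Audic-Claverie style): replicates of a condition are summed, and under the
# null the pooled count of condition A given the pair total n follows
# Binomial(n, La / (La + Lb)) where La, Lb are the summed library sizes.  The
# two-sided p-value sums the probabilities of all outcomes whose probability
# does not exceed that of the observed outcome (minimum-likelihood rule, with
# a 1e-7 relative guard against floating-point ties).  This model ignores
# biological replicate variability; see the methods vignette for what that
# implies.

#' Compute FPKM from an expression matrix
#'
#' `FPKM(t, s) = 1e9 * counts(t, s) / (library_size(s) * length_nt(t))`.
#'
#' @param expr An [expression_matrix()] with `lengths` set.
#' @return Numeric matrix, same shape as `expr$counts`.
#' @export
compute_fpkm <- function(expr) {
  if (is.null(expr$lengths)) .tl_fail("expression matrix lacks spliced lengths")
  len <- expr$lengths[rownames(expr$counts)]
  if (any(len <= 0)) .tl_fail("zero or negative spliced length")
  if (any(expr$library_size <= 0)) .tl_fail("zero library size")
  1e9 * sweep(expr$counts, 2L, expr$library_size, "/") / len
}

#' Two-sided conditional exact binomial test on pooled counts
#'
#' @param a,b Pooled fragment counts for conditions A and B.
#' @param La,Lb Summed library sizes (> 0).
#' @return Two-sided p-value in `[0, 1]`; 1 by convention when `a + b = 0`.
#' @export
de_exact_test <- function(a, b, La, Lb) {
  if (a < 0 || b < 0 || La <= 0 || Lb <= 0) .tl_fail("de_exact_test: bad input")
  n <- a + b
  if (n == 0) return(1)
  pr <- La / (La + Lb)
  d_obs <- dbinom(a, n, pr)
  d <- dbinom(0:n, n, pr)
  p <- sum(d[d <= d_obs * (1 + 1e-7)])
  min(max(p, 0), 1)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values (same order as input), each >= its p-value,
#'   clipped at 1, monotone with p-rank.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    .tl_fail("bh_adjust: p-values must be in [0, 1]")
  }
  m <- length(pvals)
  o <- order(pvals)
  q <- pvals[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

#' Call differential expression between two conditions
#'
#' Mean FPKM per condition, fold change on pseudocounted means, pooled exact
#' binomial p-values, BH FDR, and a status call.  Thresholds are strict:
#' `up` iff `fdr < fdr_threshold` and `log2fc > min_abs_log2fc`; `down`
#' symmetric; otherwise `ns`.
#'
#' @param expr An [expression_matrix()] with two conditions and lengths.
#' @param ref_level Condition treated as the baseline (default `"control"`;
#'   fold changes are the other condition over this one).
#' @param fdr_threshold,min_abs_log2fc,pseudocount Calling parameters
#'   (defaults 0.001, 1, 0.01 FPKM).
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `mean_fpkm_control`, `mean_fpkm_heat`, `log2fc`, `p_value`, `fdr`,
#'   `status`; attribute `"summary"` carries `n_up`, `n_down`, `n_de`,
#'   `n_tested`.
#' @export
call_de <- function(expr, ref_level = "control", fdr_threshold = 0.001,
                    min_abs_log2fc = 1, pseudocount = 0.01) {
  conds <- unique(expr$condition)
  if (length(conds) != 2L) .tl_fail("call_de needs exactly two conditions")
  if (!ref_level %in% conds) .tl_fail("ref_level '%s' not a condition", ref_level)
  alt_level <- setdiff(conds, ref_level)
  fpkm <- compute_fpkm(expr)
  sa <- names(expr$condition)[expr$condition == ref_level]
  sb <- names(expr$condition)[expr$condition == alt_level]
  mean_ctrl <- rowMeans(fpkm[, sa, drop = FALSE])
  mean_heat <- rowMeans(fpkm[, sb, drop = FALSE])
  log2fc <- log2((mean_heat + pseudocount) / (mean_ctrl + pseudocount))
  pooled_a <- rowSums(expr$counts[, sb, drop = FALSE])  # heat
  pooled_b <- rowSums(expr$counts[, sa, drop = FALSE])  # control
  La <- sum(expr$library_size[sb])
  Lb <- sum(expr$library_size[sa])
  p <- vapply(seq_along(pooled_a), function(i) {
    de_exact_test(pooled_a[i], pooled_b[i], La, Lb)
  }, 0)
  fdr <- bh_adjust(p)
  status <- rep("ns", length(p))
  status[fdr < fdr_threshold & log2fc > min_abs_log2fc] <- "up"
  status[fdr < fdr_threshold & log2fc < -min_abs_log2fc] <- "down"
  out <- data.frame(transcript_id = rownames(expr$counts),
                    mean_fpkm_control = unname(mean_ctrl),
                    mean_fpkm_heat = unname(mean_heat),
                    log2fc = unname(log2fc), p_value = p, fdr = fdr,
                    status = status, stringsAsFactors = FALSE)
  stopifnot(sum(status == "up") + sum(status == "down") + sum(status == "ns")
            == nrow(out))
  attr(out, "summary") <- list(n_up = sum(status == "up"),
                               n_down = sum(status == "down"),
                               n_de = sum(status != "ns"),
                               n_tested = nrow(out))
  out
}
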