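# Hypergeometric pathway enrichment of DE target genes.
#
# Universe: genes carrying at least one pathway annotation (configurable to
# all supplied genes).  One row per pathway with at least one DE target;
# BH adjustment across tested pathways; a pathway is significant iff
# p_adj < 0.05 AND it has at least `min_genes` (4) DE target genes.

#' Upper hypergeometric tail probability
#'
#' `p = sum_{i = k}^{min(K, n)} C(K, i) C(N-K, n-i) / C(N, n)`, computed by
#' log-space summation of the exact terms (smallest first).
#'
#' @param N Background size; `K` annotated genes in the pathway; `n` drawn
#'   genes; `k` observed overlap.
#' @return Tail probability in `[0, 1]`; exactly 1 when `k = 0`.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n)) {
    .tl_fail("hypergeom_tail: bound violation (N=%s K=%s n=%s k=%s)", N, K, n, k)
  }
  if (k == 0) return(1)
  i <- k:min(K, n)
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  mx <- max(lt)
  p <- exp(mx) * sum(exp(sort(lt - mx)))
  min(max(p, 0), 1)
}

#' Hypergeometric pathway enrichment of DE target genes
#'
#' @param de_targets Character vector of DE target gene ids.
#' @param pathway_map data.frame with `gene_id`, `pathway_id`, `pathway_name`
#'   (one row per membership; genes may belong to several pathways).
#' @param p_adj_threshold,min_genes Significance rule: adjusted p below the
#'   threshold (strict) and at least `min_genes` DE target genes.
#' @param background `"annotated"` (default: genes with >= 1 annotation) or
#'   `"all"` (requires `all_genes`).
#' @param all_genes Character vector of the full gene universe when
#'   `background = "all"`.
#' @return data.frame sorted by `p_adj` then `pathway_id`: `pathway_id`,
#'   `pathway_name`, `k`, `K`, `n`, `N`, `p_raw`, `p_adj`, `significant`.
#'   DE targets absent from the map are excluded from `n` and reported via a
#'   message.
#' @export
enrich_pathways <- function(de_targets, pathway_map, p_adj_threshold = 0.05,
                            min_genes = 4L, background = c("annotated", "all"),
                            all_genes = NULL) {
  background <- match.arg(background)
  if (nrow(pathway_map) == 0L) .tl_fail("empty pathway map")
  de_targets <- unique(de_targets)
  annotated <- unique(pathway_map$gene_id)
  universe <- if (background == "annotated") annotated else {
    if (is.null(all_genes)) .tl_fail("background='all' requires all_genes")
    unique(c(all_genes, annotated))
  }
  N <- length(universe)
  unmapped <- setdiff(de_targets, annotated)
  if (length(unmapped)) {
    message(sprintf("enrich_pathways: %d DE target gene(s) without annotation excluded from n",
                    length(unmapped)))
  }
  de_in <- intersect(de_targets, universe)
  if (background == "annotated") de_in <- intersect(de_in, annotated)
  n <- length(de_in)
  rows <- lapply(split(pathway_map, pathway_map$pathway_id), function(pm) {
    genes <- unique(pm$gene_id)
    k <- length(intersect(genes, de_in))
    if (k < 1L) return(NULL)
    data.frame(pathway_id = pm$pathway_id[1L], pathway_name = pm$pathway_name[1L],
               k = k, K = length(genes), n = n, N = N,
               p_raw = hypergeom_tail(N, length(genes), n, k),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(data.frame(pathway_id = character(0), pathway_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_raw = numeric(0), p_adj = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  rows$p_adj <- bh_adjust(rows$p_raw)
  rows$significant <- rows$p_adj < p_adj_threshold & rows$k >= min_genes
  rows <- rows[order(rows$p_adj, rows$pathway_id), ]
  rownames(rows) <- NULL
  rows
}
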