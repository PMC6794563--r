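# Independent oracles and small fixture builders shared across the suite.
# Every oracle re-implements the documented rule text by a different route
# (naive walk, quadratic scan, direct pmf summation, exhaustive enumeration)
# than the package code it checks.

# ---- naive ORF oracle: enumerate every AUG, walk codons to the next stop
oracle_longest_orf <- function(seq) {
  s <- toupper(chartr("Tt", "Uu", seq))
  n <- nchar(s)
  best <- 0L
  for (start in seq_len(max(n - 2L, 0L))) {
    if (substr(s, start, start + 2L) != "AUG") next
    pos <- start
    while (pos + 5L <= n) {
      pos <- pos + 3L
      cod <- substr(s, pos, pos + 2L)
      if (cod %in% c("UAA", "UAG", "UGA")) {
        best <- max(best, (pos - start) %/% 3L)
        break
      }
    }
  }
  best
}

# ---- quadratic interval helpers over transcript_model lists
iv_overlap <- function(a1, a2, b1, b2) a1 < b2 && b1 < a2

# all-pairs classification oracle applying the rule text directly
oracle_classify <- function(lnc, reference, intronic_strand = "any") {
  same <- opp <- FALSE
  for (m in reference) {
    if (m$seq_name != lnc$seq_name) next
    for (i in seq_len(nrow(m$exons))) for (j in seq_len(nrow(lnc$exons))) {
      if (iv_overlap(lnc$exons[j, 1], lnc$exons[j, 2], m$exons[i, 1], m$exons[i, 2])) {
        if (m$strand == lnc$strand) same <- TRUE else opp <- TRUE
      }
    }
  }
  if (same) return("sense")
  if (opp) return("antisense")
  sp <- transcript_span(lnc)
  for (m in reference) {
    if (m$seq_name != lnc$seq_name) next
    if (intronic_strand == "sense" && m$strand != lnc$strand) next
    k <- nrow(m$exons)
    if (k < 2L) next
    for (i in seq_len(k - 1L)) {
      if (m$exons[i, 2] <= sp[1] && sp[2] <= m$exons[i + 1L, 1]) return("intronic")
    }
  }
  "intergenic"
}

# all-pairs cis-window oracle applying the window sentence directly
oracle_cis_pairs <- function(de_lnc, de_mrna, up_bp = 10000, down_bp = 20000) {
  out <- character(0)
  for (l in de_lnc) for (m in de_mrna) {
    if (l$seq_name != m$seq_name) next
    a <- transcript_span(l); b <- transcript_span(m)
    if (iv_overlap(a[1], a[2], b[1], b[2])) {
      out <- c(out, paste(l$transcript_id, m$transcript_id, "cis_overlap"))
      next
    }
    gap <- max(b[1] - a[2], a[1] - b[2])
    if (gap == 0) {  # book-ended counts as overlap
      out <- c(out, paste(l$transcript_id, m$transcript_id, "cis_overlap"))
      next
    }
    lnc_left <- a[2] <= b[1]
    upstream <- if (m$strand == "+") lnc_left else !lnc_left
    if ((upstream && gap <= up_bp) || (!upstream && gap <= down_bp)) {
      out <- c(out, paste(l$transcript_id, m$transcript_id, "cis_window"))
    }
  }
  sort(out)
}

# direct-summation hypergeometric oracle (stats::dhyper route)
oracle_hypergeom <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(dhyper(i, K, N - K, n))
}

# full-pmf enumeration oracle for the two-sided exact binomial, computed via
# lchoose (not dbinom)
oracle_exact_p <- function(a, b, La, Lb) {
  n <- a + b
  if (n == 0) return(1)
  pr <- La / (La + Lb)
  lp <- lchoose(n, 0:n) + (0:n) * log(pr) + (n - (0:n)) * log1p(-pr)
  p <- exp(lp)
  min(1, sum(p[p <= p[a + 1L] * (1 + 1e-7)]))
}

# duplex enumeration oracle (DFS over every monotone pairing, compiled)
oracle_duplex <- function(x, y, params = duplex_params()) {
  code <- c(A = 0L, C = 1L, G = 2L, U = 3L)
  xi <- unname(code[strsplit(x, "")[[1]]])
  yi <- rev(unname(code[strsplit(y, "")[[1]]]))
  thermolnc:::duplex_enum_cpp(xi, yi, params$stack, unname(params$terminal),
                              params$init, params$loop_base, params$loop_slope,
                              params$max_loop)
}

dp_duplex <- function(x, y, params = duplex_params()) {
  code <- c(A = 0L, C = 1L, G = 2L, U = 3L)
  xi <- unname(code[strsplit(x, "")[[1]]])
  yi <- rev(unname(code[strsplit(y, "")[[1]]]))
  thermolnc:::duplex_mfe_cpp(xi, yi, params$stack, unname(params$terminal),
                             params$init, params$loop_base, params$loop_slope,
                             params$max_loop)
}

# ---- fixture builders
rand_seq <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# single-exon transcript at a random spot
rand_model <- function(id, seq_name = "chr1", max_pos = 50000, len = NULL,
                       n_exons = 1L) {
  if (is.null(len)) len <- sample(100:800, 1L)
  start <- sample.int(max_pos, 1L)
  if (n_exons == 2L) {
    e1 <- max(20L, len %/% 2L)
    gap <- sample(30:200, 1L)
    exons <- cbind(c(start, start + e1 + gap), c(start + e1, start + e1 + gap + (len - e1)))
  } else {
    exons <- cbind(start, start + len)
  }
  transcript_model(id, paste0("g_", id), seq_name, sample(c("+", "-"), 1L), exons)
}

# minimal expression matrix over given models
toy_expr <- function(models, counts = NULL) {
  ids <- vapply(models, `[[`, "", "transcript_id")
  if (is.null(counts)) {
    counts <- matrix(50L, nrow = length(ids), ncol = 6L,
                     dimnames = list(ids, c(paste0("c", 1:3), paste0("h", 1:3))))
  }
  expression_matrix(counts, rep(c("control", "heat"), each = 3L),
                    library_size = colSums(counts) + 1000L,
                    lengths = setNames(vapply(models, spliced_length, 0), ids))
}
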