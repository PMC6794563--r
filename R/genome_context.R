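# Strand-aware genomic-context classification of lncRNAs against a reference
# annotation: intergenic / antisense / sense / intronic.
#
# Decision order (first match wins):
#   1. sense      -- >= 1 bp overlap between lnc exons and reference exons on
#                    the SAME strand;
#   2. antisense  -- >= 1 bp overlap with reference exons on the OPPOSITE
#                    strand;
#   3. intronic   -- the entire lnc genomic span inside a single intron of one
#                    reference transcript (either strand by default);
#   4. intergenic -- otherwise.
# Exonic evidence outranks containment; an intron-contained antisense-strand
# transcript with no exon overlap is intronic, not antisense.

#' Build an interval index over a reference annotation
#'
#' Collects per-(seq_name, strand) exon intervals and per-transcript introns
#' (gaps between consecutive exons of multi-exon transcripts), backed by
#' IRanges overlap queries.
#'
#' @param reference Non-empty list of [transcript_model()] objects.
#' @return An object of class `gene_index`.
#' @export
build_gene_index <- function(reference) {
  if (length(reference) == 0L) .tl_fail("empty reference annotation")
  ex <- do.call(rbind, lapply(reference, function(m) {
    data.frame(seq_name = m$seq_name, strand = m$strand,
               start = m$exons[, 1L], end = m$exons[, 2L],
               gene_id = m$gene_id, transcript_id = m$transcript_id,
               stringsAsFactors = FALSE)
  }))
  intr <- do.call(rbind, lapply(reference, function(m) {
    n <- nrow(m$exons)
    if (n < 2L) return(NULL)
    data.frame(seq_name = m$seq_name, strand = m$strand,
               start = m$exons[-n, 2L], end = m$exons[-1L, 1L],
               gene_id = m$gene_id, transcript_id = m$transcript_id,
               stringsAsFactors = FALSE)
  }))
  if (is.null(intr)) {
    intr <- ex[0L, ]
  } else {
    intr <- intr[intr$end > intr$start, , drop = FALSE]  # guard abutting exons
  }
  spans <- do.call(rbind, lapply(reference, function(m) {
    sp <- transcript_span(m)
    data.frame(seq_name = m$seq_name, strand = m$strand, start = sp[1L],
               end = sp[2L], gene_id = m$gene_id, stringsAsFactors = FALSE)
  }))
  structure(list(exons = ex, introns = intr, spans = spans), class = "gene_index")
}

# internal: indices of `tab` rows ([start,end) on tab$seq_name) overlapping
# any of the query intervals `iv` on sequence `seq_name` by >= 1 bp
.index_hits <- function(tab, seq_name, iv) {
  rows <- which(tab$seq_name == seq_name)
  if (length(rows) == 0L || nrow(iv) == 0L) return(integer(0))
  hits <- findOverlaps(IRanges(iv[, 1L] + 1L, iv[, 2L]),
                       IRanges(tab$start[rows] + 1L, tab$end[rows]))
  rows[unique(subjectHits(hits))]
}

#' Classify one lncRNA by genomic context
#'
#' @param lnc A [transcript_model()].
#' @param index A [build_gene_index()] result over the reference annotation.
#' @param intronic_strand `"any"` (default) or `"sense"`: whether intronic
#'   containment may use host transcripts of either strand.
#' @return List with `model`, `category` (one of intergenic / antisense /
#'   sense / intronic) and `evidence` (an overlapping/host `gene_id`, or
#'   `"none"` iff intergenic); class `lncrna_record`.
#' @export
classify_lncrna <- function(lnc, index, intronic_strand = c("any", "sense")) {
  intronic_strand <- match.arg(intronic_strand)
  iv <- lnc$exons
  ex_hits <- .index_hits(index$exons, lnc$seq_name, iv)
  same <- ex_hits[index$exons$strand[ex_hits] == lnc$strand]
  opp <- ex_hits[index$exons$strand[ex_hits] != lnc$strand]
  pick <- function(rows, tab) {  # deterministic evidence: leftmost, then id
    o <- order(tab$start[rows], tab$gene_id[rows])
    tab$gene_id[rows[o[1L]]]
  }
  if (length(same)) {
    cat <- "sense"; ev <- pick(same, index$exons)
  } else if (length(opp)) {
    cat <- "antisense"; ev <- pick(opp, index$exons)
  } else {
    sp <- transcript_span(lnc)
    ir <- index$introns
    rows <- which(ir$seq_name == lnc$seq_name &
                    ir$start <= sp[1L] & sp[2L] <= ir$end)
    if (intronic_strand == "sense") rows <- rows[ir$strand[rows] == lnc$strand]
    if (length(rows)) {
      cat <- "intronic"; ev <- pick(rows, ir)
    } else {
      cat <- "intergenic"; ev <- "none"
    }
  }
  structure(list(model = lnc, category = cat, evidence = ev),
            class = "lncrna_record")
}

#' Classify a list of lncRNAs
#'
#' @inheritParams classify_lncrna
#' @param lncs List of [transcript_model()] objects.
#' @return List of `lncrna_record` objects (same order as input).
#' @export
classify_lncrnas <- function(lncs, index, intronic_strand = c("any", "sense")) {
  intronic_strand <- match.arg(intronic_strand)
  lapply(lncs, classify_lncrna, index = index, intronic_strand = intronic_strand)
}

#' Category counts and percentages
#'
#' @param records List of `lncrna_record` objects, or a character vector of
#'   categories.
#' @return data.frame with `category`, `count`, `percent` (2 decimals); the
#'   four categories always appear, in fixed order.  Empty input yields zero
#'   counts and a warning.
#' @export
category_summary <- function(records) {
  cats <- c("intergenic", "antisense", "sense", "intronic")
  x <- if (is.character(records)) records
       else vapply(records, `[[`, "", "category")
  counts <- vapply(cats, function(k) sum(x == k), 0L)
  if (length(x) == 0L) {
    warning("category_summary: empty input; percentages reported as 0")
    pct <- rep(0, 4L)
  } else {
    pct <- round(100 * counts / length(x), 2L)
  }
  data.frame(category = cats, count = as.integer(counts), percent = pct,
             stringsAsFactors = FALSE)
}

#' Percentage share, rounded the way the report prints it
#' @param num,den Numerator and denominator counts.
#' @param digits Decimal places.
#' @return `round(100 * num / den, digits)`.
#' @export
percent_share <- function(num, den, digits = 2L) {
  if (den <= 0) .tl_fail("percent_share: non-positive denominator")
  round(100 * num / den, digits)
}
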