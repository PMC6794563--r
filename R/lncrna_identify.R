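# Candidate-filter cascade with per-step provenance.
#
# Fixed step order: novel_locus, length_ge_200, orf_le_100aa,
# coding_potential_pass, no_domain_hit, expressed_fpkm_gt_1.  A transcript is
# a lncRNA iff every evaluated step passes; steps after the first failure are
# marked "skipped", as are steps whose inputs are absent (no reference
# annotation, no domain table).
#
# Boundary conventions (documented, configurable through `thresholds`):
#   * length: spliced length >= 200 nt passes ("length < 200 ... excluded");
#   * ORF: longest ORF of exactly 100 aa passes ("> 100 aa ... excluded");
#   * surrogate coding score of exactly 0 passes (no-ORF transcripts score 0
#     and must not be rejected);
#   * expression: max FPKM over the libraries must exceed 1 (strict).

#' Novelty filter: same-strand exonic overlap with the reference
#'
#' A transcript fails iff at least one of its exons overlaps (>= 1 bp) an
#' exon of a reference transcript on the same strand.  Antisense and intronic
#' overlap do not disqualify -- otherwise the antisense/intronic context
#' classes could not exist downstream.
#'
#' @param assembled,reference Lists of [transcript_model()] objects on the
#'   same genome.
#' @return Named logical vector: `TRUE` = pass (novel locus).
#' @export
novel_locus_filter <- function(assembled, reference) {
  index <- build_gene_index(reference)
  vapply(assembled, function(m) {
    hits <- .index_hits(index$exons, m$seq_name, m$exons)
    !any(index$exons$strand[hits] == m$strand)
  }, TRUE, USE.NAMES = FALSE) |>
    setNames(vapply(assembled, `[[`, "", "transcript_id"))
}

#' Longest AUG-initiated, stop-terminated ORF
#'
#' Scans the three forward frames of the spliced sense sequence (the library
#' is strand-specific, so only the sense strand is read).  An ORF is
#' AUG..stop; the stop codon is required and not counted in the amino-acid
#' length.
#'
#' @param seq RNA (or DNA; T is folded to U) character scalar.
#' @return List with `length_aa` (0 if no complete ORF), and `start`/`end`:
#'   0-based half-open spliced coordinates of the ORF including its stop
#'   codon (`NA` when no ORF).
#' @export
longest_orf_aa <- function(seq) {
  s <- toupper(dna_to_rna(seq))
  n <- nchar(s)
  best <- list(length_aa = 0L, start = NA_integer_, end = NA_integer_)
  for (f in 1:3) {
    if (n - f + 1L < 3L) next
    starts <- seq.int(f, n - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    augs <- which(codons == "AUG")
    stops <- which(codons %in% c("UAA", "UAG", "UGA"))
    if (length(augs) == 0L || length(stops) == 0L) next
    # next stop at or after each AUG
    idx <- findInterval(augs - 1L, stops) + 1L
    ok <- idx <= length(stops)
    if (!any(ok)) next
    aa <- stops[idx[ok]] - augs[ok]
    ok2 <- aa >= 1L
    if (!any(ok2)) next
    aa <- aa[ok2]; a <- augs[ok][ok2]; st <- stops[idx[ok]][ok2]
    i <- which.max(aa)
    if (aa[i] > best$length_aa) {
      best <- list(length_aa = as.integer(aa[i]),
                   start = as.integer(starts[a[i]] - 1L),
                   end = as.integer(starts[st[i]] + 2L))
    }
  }
  best
}

# all 4096 hexamers over the RNA alphabet, fixed order
.hexamer_keys <- function() {
  b <- c("A", "C", "G", "U")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)
  apply(g[, 6:1], 1L, paste, collapse = "")
}

.count_hexamers <- function(seqs, step) {
  keys <- .hexamer_keys()
  counts <- setNames(numeric(4096L), keys)
  for (s in seqs) {
    s <- toupper(dna_to_rna(s))
    n <- nchar(s)
    if (n < 6L) next
    starts <- seq.int(1L, n - 5L, by = step)
    w <- substring(s, starts, starts + 5L)
    t <- table(w[w %in% keys])  # windows containing N are dropped
    counts[names(t)] <- counts[names(t)] + as.numeric(t)
  }
  counts
}

#' Train the surrogate hexamer log-ratio table
#'
#' A built-in stand-in for external coding-potential programs: in-frame
#' hexamer frequencies from reference CDS sequences against all-frame
#' frequencies from a background set (mononucleotide-shuffled copies of the
#' coding set when no background is supplied).  The table holds
#' `log2((f_coding + eps) / (f_background + eps))` for all 4096 hexamers,
#' with pseudocount `eps = 1/4096`.
#'
#' Note: the default shuffled background consumes random draws from the
#' current RNG stream; seed the session for reproducible tables.
#'
#' @param coding_seqs Character vector of in-frame CDS sequences (each
#'   starting at its AUG); >= 10 sequences and >= 20 kb in total.
#' @param background_seqs Optional character vector of background sequences.
#' @return Named numeric vector of length 4096, class `hexamer_table`.
#' @export
train_hexamer_table <- function(coding_seqs, background_seqs = NULL) {
  if (length(coding_seqs) < 10L || sum(nchar(coding_seqs)) < 20000L) {
    .tl_fail(paste0("insufficient training mass for the hexamer table ",
                    "(need >= 10 coding sequences, >= 20 kb total); ",
                    "consider the synthetic-data defaults"))
  }
  if (is.null(background_seqs)) {
    background_seqs <- vapply(coding_seqs, function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  eps <- 1 / 4096
  fc <- .count_hexamers(coding_seqs, step = 3L)
  fb <- .count_hexamers(background_seqs, step = 1L)
  fc <- fc / max(sum(fc), 1)
  fb <- fb / max(sum(fb), 1)
  structure(log2((fc + eps) / (fb + eps)), class = "hexamer_table")
}

#' Surrogate coding-potential score
#'
#' Mean hexamer log-ratio over the longest ORF, sliding in-frame windows of
#' width 6 at step 3 (the window may extend into the stop codon).  Returns 0
#' when the transcript has no complete ORF; higher = more coding-like.  The
#' cascade passes a transcript iff its score is < 0, with the tie at exactly
#' 0 passing.
#'
#' @param seq RNA character scalar.
#' @param table A [train_hexamer_table()] result.
#' @return Numeric score.
#' @export
surrogate_coding_score <- function(seq, table) {
  orf <- longest_orf_aa(seq)
  if (orf$length_aa == 0L) return(0)
  s <- toupper(dna_to_rna(seq))
  starts <- seq.int(orf$start + 1L, orf$end - 5L, by = 3L)
  w <- substring(s, starts, starts + 5L)
  v <- unname(table[w])
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(0)
  mean(v)
}

.cascade_steps <- c("novel_locus", "length_ge_200", "orf_le_100aa",
                    "coding_potential_pass", "no_domain_hit",
                    "expressed_fpkm_gt_1")

#' Apply the lncRNA filter cascade
#'
#' Runs the six filters in fixed order over assembled transcripts, recording
#' a per-transcript, per-step trace (pass / fail / skipped) and emitting a
#' per-step survivor table.
#'
#' When an external score table is supplied, the coding-potential rule is the
#' published one (`cpc < 0 AND txcds < 500 AND cnci < 0`; a missing
#' individual score is treated as vacuously satisfied); otherwise the
#' built-in hexamer surrogate is used (`score < 0` passes, tie at 0 passes),
#' trained on the reference CDS against a shuffled background.
#'
#' @param assembled List of [transcript_model()] objects to filter.
#' @param reference List of reference [transcript_model()] objects, or `NULL`
#'   to skip the novelty step.
#' @param genome Named character vector of chromosome sequences.
#' @param expr An [expression_matrix()] covering every assembled transcript.
#' @param scores Optional data.frame from [read_scores_table()].
#' @param domain_hits Optional data.frame from [read_domain_hits()]; when
#'   absent the domain step is skipped.
#' @param thresholds List overriding `min_length` (200), `max_orf_aa` (100),
#'   `min_fpkm` (1).
#' @param hexamer Optional pre-trained [train_hexamer_table()]; by default
#'   trained from the reference CDS when the surrogate is needed.
#' @return List with `lncrna` (surviving models), `trace` (data.frame, one
#'   row per assembled transcript with per-step verdicts and `final`), and
#'   `step_counts` (survivors after each step).
#' @export
apply_filter_cascade <- function(assembled, reference, genome, expr,
                                 scores = NULL, domain_hits = NULL,
                                 thresholds = list(), hexamer = NULL) {
  th <- modifyList(list(min_length = 200, max_orf_aa = 100, min_fpkm = 1),
                   thresholds)
  ids <- vapply(assembled, `[[`, "", "transcript_id")
  missing <- setdiff(ids, rownames(expr$counts))
  if (length(missing)) {
    .tl_fail("transcript %s present in assembled but absent from counts",
             missing[1L])
  }
  seqs <- vapply(assembled, spliced_sequence, "", genome = genome, rna = TRUE)
  lens <- vapply(assembled, spliced_length, 0)
  orf_aa <- vapply(seqs, function(s) longest_orf_aa(s)$length_aa, 0L,
                   USE.NAMES = FALSE)

  use_external <- !is.null(scores)
  if (!use_external && is.null(hexamer)) {
    if (is.null(reference)) {
      .tl_fail("coding-potential step needs external scores, a hexamer table, or a reference with CDS")
    }
    cds_seqs <- unlist(lapply(reference, function(m) {
      if (is.null(m$cds)) return(NULL)
      cds_model <- transcript_model(m$transcript_id, m$gene_id, m$seq_name,
                                    m$strand, m$cds, biotype = "coding")
      spliced_sequence(cds_model, genome, rna = TRUE)
    }))
    hexamer <- train_hexamer_table(cds_seqs)
  }

  novelty <- if (is.null(reference)) NULL else novel_locus_filter(assembled, reference)
  fpkm <- compute_fpkm(expression_matrix(expr$counts[ids, , drop = FALSE],
                                         expr$condition, expr$library_size,
                                         lengths = setNames(lens, ids)))
  max_fpkm <- apply(fpkm, 1L, max)

  coding_pass <- function(i) {
    id <- ids[i]
    if (use_external && id %in% scores$transcript_id) {
      r <- scores[match(id, scores$transcript_id), ]
      ok <- c(is.na(r$cpc) || r$cpc < 0,
              is.na(r$txcds) || r$txcds < 500,
              is.na(r$cnci) || r$cnci < 0)
      all(ok)
    } else {
      surrogate_coding_score(seqs[i], hexamer) <= 0  # tie at 0 passes
    }
  }
  domain_pos <- if (is.null(domain_hits)) character(0) else
    unique(domain_hits$transcript_id[domain_hits$hit])

  n <- length(assembled)
  trace <- matrix("skipped", nrow = n, ncol = length(.cascade_steps),
                  dimnames = list(ids, .cascade_steps))
  final <- character(n)
  for (i in seq_len(n)) {
    alive <- TRUE
    for (step in .cascade_steps) {
      if (!alive) break
      verdict <- switch(step,
        novel_locus = if (is.null(novelty)) NA else unname(novelty[ids[i]]),
        length_ge_200 = lens[i] >= th$min_length,
        orf_le_100aa = orf_aa[i] <= th$max_orf_aa,
        coding_potential_pass = coding_pass(i),
        no_domain_hit = if (is.null(domain_hits)) NA else !(ids[i] %in% domain_pos),
        expressed_fpkm_gt_1 = max_fpkm[i] > th$min_fpkm)
      if (is.na(verdict)) next  # step skipped (input absent); trace stays "skipped"
      trace[i, step] <- if (verdict) "pass" else "fail"
      if (!verdict) alive <- FALSE
    }
    final[i] <- if (alive) "lncRNA" else "rejected"
  }
  trace_df <- data.frame(transcript_id = ids, trace, final = final,
                         stringsAsFactors = FALSE, row.names = NULL)

  # survivors after each step (monotone by construction; asserted anyway)
  surv <- integer(length(.cascade_steps))
  alive_mask <- rep(TRUE, n)
  for (k in seq_along(.cascade_steps)) {
    alive_mask <- alive_mask & trace[, k] != "fail"
    surv[k] <- sum(alive_mask)
  }
  if (any(diff(surv) > 0)) .tl_fail("internal: filter cascade not monotone")
  step_counts <- data.frame(step = c("input", .cascade_steps),
                            survivors = c(n, surv), stringsAsFactors = FALSE)

  list(lncrna = assembled[final == "lncRNA"], trace = trace_df,
       step_counts = step_counts)
}
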