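# Target prediction for DE lncRNAs.
#
# cis: genomic proximity -- span overlap (distance 0) or a gap of at most
# 10 kb on the mRNA's upstream side / 20 kb on its downstream side, sides
# taken on the mRNA's strand.
#
# trans: all remaining DE lnc x DE mRNA pairs are screened with an
# intermolecular-only RNA-RNA duplex minimum-free-energy dynamic program
# (nearest-neighbor stacks, affine loop penalties, duplex initiation,
# terminal AU/GU penalties); a pair is kept iff MFE < -30 kcal/mol (strict).
# The embedded stack table is Turner-2004-like; we claim the decision rule,
# not numeric identity with any external tool.

.DUPLEX_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")

# 6x6 stack table, kcal/mol.  Entry [t1, t2] is the energy of the dinucleotide
# stack 5'-a b-3' / 3'-c d-5' with left pair t1 = (a, c) and right pair
# t2 = (b, d).  Physical strand-flip symmetry requires
# M[t1, t2] == M[rev(t2), rev(t1)] with rev swapping AU<->UA, CG<->GC,
# GU<->UG; asserted in duplex_params().
.duplex_stack_matrix <- function() {
  M <- matrix(NA_real_, 6L, 6L, dimnames = list(.DUPLEX_PAIRS, .DUPLEX_PAIRS))
  M["AU", ] <- c(-0.93, -1.10, -2.24, -2.08, -0.55, -1.36)
  M["UA", ] <- c(-1.33, -0.93, -2.35, -2.11, -1.00, -1.30)
  M["CG", ] <- c(-2.11, -2.08, -3.26, -2.36, -1.41, -2.11)
  M["GC", ] <- c(-2.35, -2.24, -3.42, -3.26, -1.80, -2.20)
  M["GU", ] <- c(-1.30, -1.36, -2.20, -2.11, -0.50, 0.47)
  M["UG", ] <- c(-1.00, -0.55, -1.80, -1.41, -0.30, -0.50)
  M
}

#' Duplex energy parameters
#'
#' Nearest-neighbor-style parameter set for the intermolecular duplex model:
#' 36 stack energies over the pair alphabet AU, UA, CG, GC, GU, UG; duplex
#' initiation +4.09 kcal/mol; terminal AU/GU penalty +0.45 per helix end;
#' affine loop cost `loop_base + loop_slope * (k + l)` for k, l unpaired
#' bases (k + l >= 1), capped at `max_loop = 15` unpaired bases per side.
#'
#' The default loop cost (base 4.0, slope 0.9 kcal/mol per unpaired base) is
#' deliberately bulge-like and harsher than Turner interior loops: it keeps
#' helix chaining subcritical on unrelated sequence, so the -30 kcal/mol
#' trans rule stays selective (random 1 kb pairs score around -20 to -28,
#' a planted 40-nt perfect complement around -80).
#'
#' @param loop_base,loop_slope,max_loop,init,terminal_au_gu Overridable
#'   scalars.
#' @return List of class `duplex_params`.
#' @export
duplex_params <- function(loop_base = 4.0, loop_slope = 0.9, max_loop = 15L,
                          init = 4.09, terminal_au_gu = 0.45) {
  stopifnot(loop_slope > 0, init > 0, max_loop >= 1)
  M <- .duplex_stack_matrix()
  stopifnot(all(is.finite(M)))
  rev_pair <- c(AU = "UA", UA = "AU", CG = "GC", GC = "CG", GU = "UG", UG = "GU")
  for (t1 in .DUPLEX_PAIRS) for (t2 in .DUPLEX_PAIRS) {
    stopifnot(isTRUE(all.equal(M[t1, t2], M[rev_pair[t2], rev_pair[t1]])))
  }
  term <- setNames(c(terminal_au_gu, terminal_au_gu, 0, 0,
                     terminal_au_gu, terminal_au_gu), .DUPLEX_PAIRS)
  structure(list(stack = M, init = init, terminal = term,
                 loop_base = loop_base, loop_slope = loop_slope,
                 max_loop = as.integer(max_loop)),
            class = "duplex_params")
}

.encode_rna <- function(seq, what) {
  s <- strsplit(toupper(dna_to_rna(seq)), "")[[1]]
  code <- c(A = 0L, C = 1L, G = 2L, U = 3L)
  v <- code[s]
  if (anyNA(v)) .tl_fail("%s: illegal character '%s' (alphabet A,C,G,U)",
                         what, s[which(is.na(v))[1L]])
  unname(v)
}

#' Minimum free energy of an intermolecular RNA-RNA duplex
#'
#' Dynamic program over hybridising positions, intermolecular pairs only (no
#' intramolecular structure): pairs are monotone with the lncRNA read 5'->3'
#' against the mRNA read 3'->5'; Watson-Crick and GU wobble pairs are
#' admissible; consecutive pairs are scored by the stack table when adjacent
#' and by the affine loop cost otherwise; the duplex pays one initiation term
#' and a terminal AU/GU penalty at each helix end.
#'
#' @param lnc_seq,mrna_seq RNA strings (>= 2 nt over A,C,G,U; T tolerated).
#' @param params A [duplex_params()] object.
#' @return List with `mfe` (kcal/mol; `NA` when no admissible pair exists),
#'   `pairing` (two-column matrix of 1-based positions, lnc index vs mRNA
#'   index in the original 5'->3' orientation), and `no_duplex` flag.
#' @export
duplex_mfe <- function(lnc_seq, mrna_seq, params = duplex_params()) {
  x <- .encode_rna(lnc_seq, "lnc_seq")
  y <- .encode_rna(mrna_seq, "mrna_seq")
  if (length(x) < 2L || length(y) < 2L) .tl_fail("sequences must be >= 2 nt")
  res <- duplex_mfe_cpp(x, rev(y), params$stack, unname(params$terminal),
                        params$init, params$loop_base, params$loop_slope,
                        params$max_loop)
  if (res$no_duplex) {
    return(list(mfe = NA_real_, pairing = matrix(0L, 0L, 2L), no_duplex = TRUE))
  }
  pairing <- cbind(lnc = res$pair_i, mrna = length(y) - res$pair_j + 1L)
  list(mfe = res$mfe, pairing = pairing, no_duplex = FALSE)
}

.model_ids <- function(models) vapply(models, `[[`, "", "transcript_id")

#' Find cis lncRNA-mRNA pairs by genomic proximity
#'
#' A pair is emitted iff both transcripts sit on the same sequence and their
#' genomic spans overlap (mode `cis_overlap`, signed distance 0; book-ended
#' spans with a zero-base gap count as overlap) or the gap between nearest
#' span edges is at most `up_kb` kb with the lncRNA on the mRNA's upstream
#' side, or at most `down_kb` kb on its downstream side (mode `cis_window`;
#' signed distance negative upstream, positive downstream, on the mRNA's
#' strand).
#'
#' @param de_lnc,de_mrna Lists of [transcript_model()] objects, both already
#'   restricted to DE members.
#' @param up_kb,down_kb Window sizes in kb (defaults 10 and 20).
#' @return data.frame of target pairs: `lnc_id`, `mrna_id`, `mode`,
#'   `signed_distance`, `mfe` (NA for cis modes).
#' @export
find_cis_pairs <- function(de_lnc, de_mrna, up_kb = 10, down_kb = 20) {
  up_bp <- up_kb * 1000
  down_bp <- down_kb * 1000
  if (length(de_lnc) == 0L || length(de_mrna) == 0L) {
    return(data.frame(lnc_id = character(0), mrna_id = character(0),
                      mode = character(0), signed_distance = numeric(0),
                      mfe = numeric(0), stringsAsFactors = FALSE))
  }
  lspan <- t(vapply(de_lnc, transcript_span, numeric(2)))
  mspan <- t(vapply(de_mrna, transcript_span, numeric(2)))
  lseq <- vapply(de_lnc, `[[`, "", "seq_name")
  mseq <- vapply(de_mrna, `[[`, "", "seq_name")
  mstrand <- vapply(de_mrna, `[[`, "", "strand")
  lids <- .model_ids(de_lnc); mids <- .model_ids(de_mrna)
  out <- vector("list", length(de_lnc))
  for (i in seq_along(de_lnc)) {
    j <- which(mseq == lseq[i])
    if (length(j) == 0L) next
    a <- lspan[i, 1L]; b <- lspan[i, 2L]
    c_ <- mspan[j, 1L]; d <- mspan[j, 2L]
    overlap <- a < d & c_ < b
    # gap between nearest span edges (0 when book-ended)
    gap <- pmax(c_ - b, a - d)
    lnc_left <- b <= c_
    upstream <- ifelse(mstrand[j] == "+", lnc_left, !lnc_left)
    win <- !overlap & ((upstream & gap <= up_bp) | (!upstream & gap <= down_bp))
    win <- win & gap > 0  # zero-gap book-ended pairs are cis_overlap
    overlap <- overlap | (!overlap & gap == 0)
    keep <- overlap | win
    if (!any(keep)) next
    out[[i]] <- data.frame(
      lnc_id = lids[i], mrna_id = mids[j[keep]],
      mode = ifelse(overlap[keep], "cis_overlap", "cis_window"),
      signed_distance = ifelse(overlap[keep], 0,
                               ifelse(upstream[keep], -gap[keep], gap[keep])),
      mfe = NA_real_, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(lnc_id = character(0), mrna_id = character(0),
                                      mode = character(0),
                                      signed_distance = numeric(0),
                                      mfe = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# 8-mer seed-and-extend prefilter: a candidate pair enters the DP only if the
# lncRNA's reverse complement shares an exact 8-mer with the mRNA
.kmer_set <- function(seq, k = 8L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

#' Find trans lncRNA-mRNA pairs by duplex energy
#'
#' Screens every DE lnc x DE mRNA pair that is not already cis with
#' [duplex_mfe()]; a pair is reported iff its MFE is strictly below
#' `energy_threshold`.  An optional exact 8-mer reverse-complement seed match
#' prunes hopeless pairs before the quadratic DP.
#'
#' @param de_lnc,de_mrna Lists of DE [transcript_model()] objects.
#' @param genome Named character vector of chromosome sequences.
#' @param params A [duplex_params()] object.
#' @param energy_threshold MFE cutoff in kcal/mol (default -30, strict `<`).
#' @param cis_pairs data.frame from [find_cis_pairs()]; those pairs are
#'   excluded from the scan.
#' @param prefilter Use the 8-mer seed prefilter (default `TRUE`).
#' @return data.frame of trans target pairs (`mode = "trans"`, `mfe` filled,
#'   `signed_distance` NA), disjoint from `cis_pairs` by construction.
#' @export
find_trans_pairs <- function(de_lnc, de_mrna, genome, params = duplex_params(),
                             energy_threshold = -30, cis_pairs = NULL,
                             prefilter = TRUE) {
  lids <- .model_ids(de_lnc); mids <- .model_ids(de_mrna)
  cis_key <- if (is.null(cis_pairs) || nrow(cis_pairs) == 0L) character(0)
             else paste(cis_pairs$lnc_id, cis_pairs$mrna_id)
  lseqs <- vapply(de_lnc, spliced_sequence, "", genome = genome, rna = TRUE)
  mseqs <- vapply(de_mrna, spliced_sequence, "", genome = genome, rna = TRUE)
  m8 <- lapply(mseqs, .kmer_set)
  rows <- list()
  for (i in seq_along(de_lnc)) {
    rc8 <- .kmer_set(revcomp(lseqs[i]))
    for (j in seq_along(de_mrna)) {
      if (paste(lids[i], mids[j]) %in% cis_key) next
      if (prefilter && !any(rc8 %in% m8[[j]])) next
      d <- duplex_mfe(lseqs[i], mseqs[j], params)
      if (!d$no_duplex && d$mfe < energy_threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          lnc_id = lids[i], mrna_id = mids[j], mode = "trans",
          signed_distance = NA_real_, mfe = d$mfe, stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lnc_id = character(0), mrna_id = character(0),
               mode = character(0), signed_distance = numeric(0),
               mfe = numeric(0), stringsAsFactors = FALSE)
  if (any(paste(res$lnc_id, res$mrna_id) %in% cis_key)) {
    .tl_fail("internal: cis and trans pair sets overlap")
  }
  res
}
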