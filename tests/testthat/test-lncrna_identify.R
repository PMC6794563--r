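test_that("novel_locus_filter is strand-aware and matches the exhaustive oracle", {
  ref <- list(transcript_model("r", "g", "chr1", "+", cbind(150, 250)))
  asm <- list(transcript_model("a1", "g", "chr1", "+", cbind(100, 200)),
              transcript_model("a2", "g", "chr1", "-", cbind(100, 200)))
  verdict <- novel_locus_filter(asm, ref)
  expect_false(verdict[["a1"]])  # same-strand exonic overlap
  expect_true(verdict[["a2"]])   # antisense retained

  set.seed(5)
  ref <- lapply(1:30, function(i) rand_model(paste0("r", i), max_pos = 8000,
                                             n_exons = sample(1:2, 1)))
  asm <- lapply(1:50, function(i) rand_model(paste0("a", i), max_pos = 8500))
  got <- novel_locus_filter(asm, ref)
  want <- vapply(asm, function(m) {
    !any(vapply(ref, function(r) {
      r$seq_name == m$seq_name && r$strand == m$strand &&
        any(vapply(seq_len(nrow(r$exons)), function(i) {
          any(vapply(seq_len(nrow(m$exons)), function(j) {
            iv_overlap(m$exons[j, 1], m$exons[j, 2], r$exons[i, 1], r$exons[i, 2])
          }, TRUE))
        }, TRUE))
    }, TRUE))
  }, TRUE)
  expect_identical(unname(got), want)
})

test_that("longest_orf_aa matches examples and the AUG-walk oracle", {
  expect_equal(longest_orf_aa("AUGAAAUAA")$length_aa, 2L)
  expect_equal(longest_orf_aa("CCCCCC")$length_aa, 0L)
  expect_equal(longest_orf_aa("AUGUAA")$length_aa, 1L)     # Met only
  expect_equal(longest_orf_aa("AUGAAA")$length_aa, 0L)     # stop required
  o <- longest_orf_aa("GGAUGAAAUAAGG")  # frame 3, coords include the stop
  expect_equal(o$length_aa, 2L)
  expect_equal(c(o$start, o$end), c(2L, 11L))

  set.seed(21)
  for (i in 1:150) {
    s <- rand_seq(sample(60:600, 1))
    expect_equal(longest_orf_aa(s)$length_aa, oracle_longest_orf(s))
  }
})

test_that("hexamer table is complete and scores behave as specified", {
  set.seed(31)
  usage <- thermolnc:::.codon_usage()
  cds <- replicate(20, paste0("AUG", paste(chartr("T", "U",
    sample(names(usage), 400, TRUE, usage)), collapse = ""), "UAA"))
  tab <- train_hexamer_table(cds)
  expect_length(tab, 4096L)
  expect_true(all(is.finite(tab)))
  expect_setequal(substr(names(tab), 1, 1), c("A", "C", "G", "U"))

  # hand-summation oracle: 12-nt ORF has exactly 3 in-frame hexamer windows
  orf12 <- "AUGGCUAAAUAA"
  wins <- substring(orf12, c(1, 4, 7), c(6, 9, 12))
  expect_equal(surrogate_coding_score(orf12, tab), mean(tab[wins]))
  # no ORF scores exactly 0
  expect_identical(surrogate_coding_score("CCCCCCCCC", tab), 0)

  # separation: biased CDS score positive in >= 95% of draws; planted-style
  # uniform sequence scores lower on average
  cod_sc <- replicate(40, surrogate_coding_score(paste0("AUG", paste(chartr("T", "U",
    sample(names(usage), 200, TRUE, usage)), collapse = ""), "UAA"), tab))
  unif_sc <- replicate(40, surrogate_coding_score(rand_seq(600), tab))
  expect_gte(mean(cod_sc > 0), 0.95)
  expect_gt(mean(cod_sc), mean(unif_sc))

  expect_error(train_hexamer_table(c("AUGAAA")), "insufficient training mass")
})

test_that("filter cascade applies steps in order with provenance", {
  genome <- list()
  set.seed(41)
  chr <- rand_seq(4000, c("A", "C", "G", "T"))
  genome <- c(chr1 = chr)
  short <- transcript_model("short", "g", "chr1", "+", cbind(0, 150))
  ok <- transcript_model("ok", "g", "chr1", "+", cbind(500, 900))
  silent <- transcript_model("silent", "g", "chr1", "+", cbind(1200, 1700))
  models <- list(short, ok, silent)
  counts <- matrix(60L, 3, 6, dimnames = list(c("short", "ok", "silent"),
                                              c(paste0("c", 1:3), paste0("h", 1:3))))
  counts["silent", ] <- 0L
  expr <- expression_matrix(counts, rep(c("control", "heat"), each = 3),
                            library_size = colSums(counts) + 5000)
  scores <- data.frame(transcript_id = c("short", "ok", "silent"),
                       cpc = -0.5, txcds = 499, cnci = -0.1)
  res <- apply_filter_cascade(models, reference = NULL, genome, expr,
                              scores = scores)
  tr <- res$trace
  # short fails at length; later steps skipped
  expect_equal(tr$length_ge_200[tr$transcript_id == "short"], "fail")
  expect_equal(tr$orf_le_100aa[tr$transcript_id == "short"], "skipped")
  expect_equal(tr$final[tr$transcript_id == "short"], "rejected")
  # the published external-score rule passes (cpc<0, txcds<500, cnci<0)
  expect_equal(tr$coding_potential_pass[tr$transcript_id == "ok"], "pass")
  expect_equal(tr$final[tr$transcript_id == "ok"], "lncRNA")
  # no expression: max FPKM = 0 fails the last step
  expect_equal(tr$expressed_fpkm_gt_1[tr$transcript_id == "silent"], "fail")
  # novelty and domain steps were skipped (inputs absent)
  expect_true(all(tr$novel_locus == "skipped"))
  expect_true(all(tr$no_domain_hit == "skipped"))
  # trace completeness and monotone step counts
  expect_equal(nrow(tr), length(models))
  expect_true(all(diff(res$step_counts$survivors) <= 0))

  # domain-hit table flips a survivor
  hits <- data.frame(transcript_id = "ok", hit = TRUE)
  res2 <- apply_filter_cascade(models, NULL, genome, expr, scores = scores,
                               domain_hits = hits)
  expect_equal(res2$trace$no_domain_hit[res2$trace$transcript_id == "ok"], "fail")

  # a transcript absent from the counts is an error
  expr_bad <- expression_matrix(counts[1:2, ], rep(c("control", "heat"), each = 3),
                                library_size = colSums(counts) + 5000)
  expect_error(apply_filter_cascade(models, NULL, genome, expr_bad, scores = scores),
               "absent from counts")
})

test_that("boundary conventions: 200 nt and 100 aa pass; score 0 passes", {
  set.seed(43)
  genome <- c(chr1 = paste(rep("C", 1000), collapse = ""))
  m200 <- transcript_model("t200", "g", "chr1", "+", cbind(0, 200))
  counts <- matrix(60L, 1, 6, dimnames = list("t200", c(paste0("c", 1:3), paste0("h", 1:3))))
  expr <- expression_matrix(counts, rep(c("control", "heat"), each = 3),
                            library_size = colSums(counts) + 5000)
  usage <- thermolnc:::.codon_usage()
  cds <- replicate(15, paste0("AUG", paste(chartr("T", "U",
    sample(names(usage), 500, TRUE, usage)), collapse = ""), "UAA"))
  tab <- train_hexamer_table(cds)
  res <- apply_filter_cascade(list(m200), NULL, genome, expr, hexamer = tab)
  tr <- res$trace
  expect_equal(tr$length_ge_200, "pass")      # exactly 200 nt kept
  expect_equal(tr$orf_le_100aa, "pass")       # poly-C: no ORF
  expect_equal(tr$coding_potential_pass, "pass")  # score 0 ties pass
  expect_equal(tr$final, "lncRNA")
})
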