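test_that("read_fasta parses, normalises and validates", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT"), f)
  expect_equal(read_fasta(f), c(a = "ACGT"))

  writeLines(c(">a", "acg", "t"), f)
  expect_equal(unname(read_fasta(f)["a"]), "ACGT")

  writeLines(c(">a", "AC", ">a", "GG"), f)
  expect_error(read_fasta(f), "duplicate id")

  writeLines(c(">a", "AC", ">b", "XY"), f)
  expect_error(read_fasta(f), "line 4.*illegal")

  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
})

test_that("FASTA round-trips through write_fasta at 60 columns", {
  f <- withr::local_tempfile(fileext = ".fa")
  set.seed(1)
  seqs <- c(x = rand_seq(150, c("A", "C", "G", "T")), y = rand_seq(60, c("A", "C", "G", "T")))
  write_fasta(seqs, f)
  expect_equal(read_fasta(f), seqs)
  expect_true(all(nchar(readLines(f)) <= 60))
})

test_that("read_gtf converts coordinates and groups exons", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste("chr1", ".", "exon", 101, 200, ".", "+", ".",
                   'gene_id "g1"; transcript_id "t1";', sep = "\t"), f)
  m <- read_gtf(f)[[1]]
  expect_equal(m$exons, cbind(100, 200))
  expect_equal(m$strand, "+")
  expect_equal(spliced_length(m), 100)

  writeLines(c(paste("chr1", ".", "exon", 101, 200, ".", "+", ".",
                     'gene_id "g1"; transcript_id "t1";', sep = "\t"),
               paste("chr1", ".", "exon", 301, 400, ".", "+", ".",
                     'gene_id "g1"; transcript_id "t1";', sep = "\t")), f)
  expect_equal(spliced_length(read_gtf(f)[[1]]), 200)
})

test_that("read_gtf rejects malformed annotation", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(paste("chr1", ".", "exon", 101, 200, ".", "+", ".",
                     'gene_id "g1"; transcript_id "t1";', sep = "\t"),
               paste("chr1", ".", "exon", 301, 400, ".", "-", ".",
                     'gene_id "g1"; transcript_id "t1";', sep = "\t")), f)
  expect_error(read_gtf(f), "mixed strand")

  writeLines(paste("chr1", ".", "exon", 101, 200, ".", "+", ".",
                   'gene_id "g1";', sep = "\t"), f)
  expect_error(read_gtf(f), "transcript_id")

  writeLines(paste("chr1", ".", "exon", 201, 101, ".", "+", ".",
                   'gene_id "g1"; transcript_id "t1";', sep = "\t"), f)
  expect_error(read_gtf(f), "zero-length")
})

test_that("write_gtf o read_gtf is the identity on canonical files", {
  set.seed(42)
  models <- c(
    lapply(1:6, function(i) rand_model(sprintf("t%02d", i), n_exons = sample(1:2, 1))),
    list(transcript_model("tc", "gc", "chr1", "-", cbind(c(1000, 1400), c(1200, 1600)),
                          cds = cbind(1050, 1200), biotype = "coding",
                          attributes = 'note "kept verbatim";')))
  f1 <- withr::local_tempfile(fileext = ".gtf")
  f2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(models, f1)
  write_gtf(read_gtf(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
  # coordinate round-trip is exact
  back <- read_gtf(f1)
  for (i in seq_along(models)) expect_equal(back[[i]]$exons, models[[i]]$exons)
  # unknown attributes preserved
  expect_match(grep("tc", readLines(f1), value = TRUE)[1], 'note "kept verbatim";')
  # coding_only filter
  expect_length(read_gtf(f1, coding_only = TRUE), 1L)
})

test_that("transcript_model enforces its invariants", {
  expect_error(transcript_model("t", "g", "c", "+", cbind(10, 10)), "zero-length")
  expect_error(transcript_model("t", "g", "c", "+", cbind(c(0, 50), c(60, 100))),
               "overlapping")
  expect_error(transcript_model("t", "g", "c", "*", cbind(0, 10)), "strand")
  expect_error(transcript_model("t", "g", "c", "+", cbind(0, 100), cds = cbind(90, 150)),
               "CDS outside")
})

test_that("spliced_sequence applies strand and RNA view at extraction", {
  genome <- c(chr1 = "AAACCCGGGTTT")
  m_plus <- transcript_model("p", "g", "chr1", "+", cbind(c(0, 9), c(3, 12)))
  m_minus <- transcript_model("m", "g", "chr1", "-", cbind(c(0, 9), c(3, 12)))
  expect_equal(spliced_sequence(m_plus, genome), "AAATTT")
  expect_equal(spliced_sequence(m_minus, genome), "AAATTT")  # revcomp of AAATTT
  expect_equal(spliced_sequence(m_minus, genome, rna = TRUE), "AAAUUU")
})

test_that("typed TSV readers validate columns and values", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tc1\tc2\tc3\th1\th2\th3",
               "t1\t10\t12\t9\t55\t60\t51"), f)
  m <- read_counts_table(f)
  expect_identical(unname(m["t1", ]), c(10L, 12L, 9L, 55L, 60L, 51L))

  writeLines(c("transcript_id\tc1", "t1\t-3"), f)
  expect_error(read_counts_table(f), "negative count")
  writeLines(c("transcript_id\tc1", "t1\tfoo"), f)
  expect_error(read_counts_table(f), "non-numeric")
  writeLines(c("id\tc1", "t1\t3"), f)
  expect_error(read_counts_table(f), "missing column")

  writeLines(c("transcript_id\tcpc\ttxcds\tcnci", "t1\t-0.4\t320\t-1.1"), f)
  sc <- read_scores_table(f)
  expect_equal(sc$cpc, -0.4)
  expect_equal(sc$txcds, 320)
  expect_equal(sc$cnci, -1.1)
})

test_that("expression_matrix enforces its invariants", {
  cm <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  expect_error(expression_matrix(cm, c("x", "y")), "condition length")
  expect_error(expression_matrix(cm, c("x", "x", "y"), library_size = c(1, 1, 1)),
               "below column sum")
  e <- expression_matrix(cm, c("x", "x", "y"))
  expect_equal(unname(e$library_size), unname(colSums(cm)))
})
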