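test_that("duplex parameters are complete, finite and strand-flip symmetric", {
  p <- duplex_params()
  expect_equal(dim(p$stack), c(6L, 6L))
  expect_true(all(is.finite(p$stack)))
  expect_gt(p$init, 0)
  expect_gt(p$loop_slope, 0)
  # most stacks are stabilizing; tandem GU wobbles may not be
  expect_gt(sum(p$stack < 0), 30)
  expect_equal(unname(p$terminal[c("CG", "GC")]), c(0, 0))
})

test_that("duplex_mfe matches hand summation and handles degenerate input", {
  expect_true(duplex_mfe("AAAA", "AAAA")$no_duplex)
  p <- duplex_params()
  d <- duplex_mfe("GGGGG", "CCCCC", p)
  expect_equal(d$mfe, p$init + 4 * p$stack["GC", "GC"], ignore_attr = TRUE)
  expect_equal(nrow(d$pairing), 5L)
  # single pair: initiation + both terminal penalties
  d1 <- duplex_mfe("GA", "CA", p)  # only G-C admissible
  expect_equal(d1$mfe, p$init, ignore_attr = TRUE)
  d2 <- duplex_mfe("AA", "UC", p)  # only A-U admissible
  expect_equal(d2$mfe, p$init + 2 * 0.45, ignore_attr = TRUE)
  expect_error(duplex_mfe("ACGX", "ACGU"), "illegal character")
  expect_error(duplex_mfe("A", "ACGU"), ">= 2 nt")
})

test_that("duplex_mfe equals exhaustive pairing enumeration (pilot sweep)", {
  p <- duplex_params()
  # complete sweep over the 2-letter pilot alphabet up to length 4
  gc <- unlist(lapply(2:4, function(L) {
    apply(expand.grid(rep(list(c("G", "C")), L)), 1, paste, collapse = "")
  }))
  for (x in gc) for (y in gc) {
    a <- dp_duplex(x, y, p); b <- oracle_duplex(x, y, p)
    expect_identical(a$no_duplex, b$no_duplex)
    if (!a$no_duplex) expect_equal(a$mfe, b$mfe, tolerance = 1e-9)
  }
  # random 4-letter pairs incl. GU wobbles
  set.seed(29)
  for (i in 1:80) {
    x <- rand_seq(sample(2:6, 1)); y <- rand_seq(sample(2:6, 1))
    a <- dp_duplex(x, y, p); b <- oracle_duplex(x, y, p)
    expect_identical(a$no_duplex, b$no_duplex)
    if (!a$no_duplex) expect_equal(a$mfe, b$mfe, tolerance = 1e-9)
  }
})

test_that("duplex model symmetry and extension (superset) properties", {
  set.seed(31)
  for (i in 1:25) {
    x <- rand_seq(sample(5:25, 1)); y <- rand_seq(sample(5:25, 1))
    a <- duplex_mfe(x, y); b <- duplex_mfe(y, x)
    expect_identical(a$no_duplex, b$no_duplex)
    if (!a$no_duplex) expect_equal(a$mfe, b$mfe, tolerance = 1e-9)
    # flanking bases can only add admissible options
    ax <- paste0(rand_seq(1), x); by <- paste0(rand_seq(1), y)
    e <- duplex_mfe(ax, by)
    if (!a$no_duplex) expect_lte(e$mfe, a$mfe + 1e-9)
  }
})

test_that("find_cis_pairs applies the window sentence", {
  lnc <- function(id, s, e, chr = "chr1")
    transcript_model(id, id, chr, "+", cbind(s, e))
  mrna <- function(id, s, e, strand, chr = "chr1")
    transcript_model(id, id, chr, strand, cbind(s, e))
  m <- mrna("m1", 12000, 15000, "+")

  # gap 6 kb on the upstream side of a + mRNA
  p <- find_cis_pairs(list(lnc("l1", 5000, 6000)), list(m))
  expect_equal(p$mode, "cis_window")
  expect_equal(p$signed_distance, -6000)
  # 25 kb downstream exceeds the 20 kb window
  expect_equal(nrow(find_cis_pairs(list(lnc("l2", 40000, 41000)), list(m))), 0L)
  # 15 kb downstream is within it
  p <- find_cis_pairs(list(lnc("l3", 30000, 31000)), list(m))
  expect_equal(p$signed_distance, 15000)
  # minus-strand mRNA flips the sides: same geometry becomes downstream
  m2 <- mrna("m2", 12000, 15000, "-")
  p <- find_cis_pairs(list(lnc("l4", 5000, 6000)), list(m2))
  expect_equal(p$signed_distance, 6000)
  # overlap and different chromosome
  p <- find_cis_pairs(list(lnc("l5", 14000, 14500)), list(m))
  expect_equal(p$mode, "cis_overlap")
  expect_equal(p$signed_distance, 0)
  expect_equal(nrow(find_cis_pairs(list(lnc("l6", 12000, 13000, "chr2")), list(m))), 0L)
})

test_that("find_cis_pairs matches the quadratic oracle on random placements", {
  set.seed(37)
  lncs <- lapply(1:80, function(i) {
    rand_model(paste0("l", i), seq_name = sample(c("chr1", "chr2"), 1),
               max_pos = 100000, len = sample(200:2000, 1))
  })
  mrnas <- lapply(1:40, function(i) {
    rand_model(paste0("m", i), seq_name = sample(c("chr1", "chr2"), 1),
               max_pos = 100000, len = sample(500:3000, 1))
  })
  got <- find_cis_pairs(lncs, mrnas)
  got_keys <- sort(paste(got$lnc_id, got$mrna_id, got$mode))
  expect_identical(got_keys, oracle_cis_pairs(lncs, mrnas))
})

test_that("find_trans_pairs screens non-cis pairs with the -30 rule", {
  set.seed(41)
  # two chromosomes; lnc carries an exact 40-nt reverse complement of an
  # mRNA segment -> guaranteed deep duplex
  mrna_seq <- rand_seq(600, c("A", "C", "G", "T"))
  lnc_seq <- paste0(rand_seq(150, c("A", "C", "G", "T")),
                    revcomp(substr(mrna_seq, 200, 239)),
                    rand_seq(150, c("A", "C", "G", "T")))
  genome <- c(chr1 = mrna_seq, chr2 = lnc_seq)
  m <- transcript_model("m1", "gm", "chr1", "+", cbind(0, 600), biotype = "coding")
  l <- transcript_model("l1", "gl", "chr2", "+", cbind(0, nchar(lnc_seq)))
  cis <- find_cis_pairs(list(l), list(m))
  expect_equal(nrow(cis), 0L)
  tr <- find_trans_pairs(list(l), list(m), genome, cis_pairs = cis)
  expect_equal(nrow(tr), 1L)
  expect_lt(tr$mfe, -30)

  # a pair already cis is excluded from the trans scan
  l2 <- transcript_model("l2", "gl2", "chr1", "+", cbind(700, 900))
  genome2 <- c(chr1 = paste0(mrna_seq, lnc_seq))
  cis2 <- find_cis_pairs(list(l2), list(m))
  expect_equal(nrow(cis2), 1L)
  tr2 <- find_trans_pairs(list(l2), list(m), genome2, cis_pairs = cis2)
  expect_equal(nrow(tr2), 0L)
})
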