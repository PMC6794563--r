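test_that("compute_fpkm is definitional and scales correctly", {
  counts <- matrix(c(10L, 0L), 1, 2, dimnames = list("t", c("a", "b")))
  e <- expression_matrix(counts, c("control", "heat"),
                         library_size = c(1e6, 1e6), lengths = c(t = 1000))
  f <- compute_fpkm(e)
  expect_equal(unname(f["t", "a"]), 10)  # 1e9 * 10 / (1e6 * 1000)
  expect_equal(unname(f["t", "b"]), 0)

  set.seed(3)
  counts <- matrix(rpois(40, 50), 10, 4,
                   dimnames = list(paste0("t", 1:10), paste0("s", 1:4)))
  lens <- setNames(sample(200:2000, 10), paste0("t", 1:10))
  libs <- colSums(counts) + 1000
  e1 <- expression_matrix(counts, c("control", "control", "heat", "heat"),
                          library_size = libs, lengths = lens)
  e2 <- expression_matrix(counts, c("control", "control", "heat", "heat"),
                          library_size = 2 * libs, lengths = lens)
  expect_equal(compute_fpkm(e2), compute_fpkm(e1) / 2)
  # linear in counts (per-sample library ratios applied columnwise)
  libs3 <- libs + colSums(counts)
  e3 <- expression_matrix(2L * counts, c("control", "control", "heat", "heat"),
                          library_size = libs3, lengths = lens)
  expect_equal(compute_fpkm(e3),
               sweep(compute_fpkm(e1) * 2, 2, libs3 / libs, "/"),
               tolerance = 1e-12)
})

test_that("de_exact_test matches closed forms and the pmf-enumeration oracle", {
  expect_equal(de_exact_test(0, 0, 100, 100), 1)
  expect_equal(de_exact_test(5, 5, 100, 100), 1)
  expect_equal(de_exact_test(20, 0, 100, 100), 2 * 0.5^20, tolerance = 1e-12)

  set.seed(13)
  for (i in 1:200) {
    a <- rpois(1, 40); b <- rpois(1, 40)
    La <- sample(5e4:2e5, 1); Lb <- sample(5e4:2e5, 1)
    expect_equal(de_exact_test(a, b, La, Lb), oracle_exact_p(a, b, La, Lb),
                 tolerance = 1e-12)
    # symmetry
    expect_equal(de_exact_test(a, b, La, Lb), de_exact_test(b, a, Lb, La),
                 tolerance = 1e-12)
  }
})

test_that("bh_adjust reproduces the step-up rule and matches p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(17)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, method = "BH"))
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone with p-rank
  }
})

test_that("call_de computes fold changes, statuses and the partition", {
  # mean FPKM 40 vs 10 => log2fc = 2 (pseudocount negligible)
  counts <- rbind(t1 = c(100L, 100L, 100L, 400L, 400L, 400L),
                  t2 = c(200L, 200L, 200L, 200L, 200L, 200L))
  colnames(counts) <- c(paste0("c", 1:3), paste0("h", 1:3))
  e <- expression_matrix(counts, rep(c("control", "heat"), each = 3),
                         library_size = rep(1e6, 6),
                         lengths = c(t1 = 1000, t2 = 1000))
  de <- call_de(e)
  expect_equal(de$log2fc[de$transcript_id == "t1"], 2, tolerance = 1e-3)
  expect_equal(de$status[de$transcript_id == "t1"], "up")
  expect_equal(de$status[de$transcript_id == "t2"], "ns")
  s <- attr(de, "summary")
  expect_equal(s$n_up + s$n_down + (s$n_tested - s$n_de), s$n_tested)
})

test_that("null calibration: Poisson-limit counts give calibrated p-values", {
  # de_fraction = 0, dispersion at the Poisson limit: the pooled conditional
  # binomial is the true null, so p < 0.05 for at most ~5% of transcripts
  cfg <- sim_config(seed = 19, de_fraction = 0, nb_dispersion = 1e-6)
  n <- 600
  truth <- data.frame(transcript_id = paste0("t", 1:n),
                      gene_id = paste0("g", 1:n), ref_gene_id = "none",
                      true_class = "coding", true_de_status = "null",
                      true_log2fc = 0, true_mean = 300)
  models <- lapply(1:n, function(i) {
    transcript_model(paste0("t", i), paste0("g", i), "chr1", "+",
                     cbind((i - 1) * 1000, (i - 1) * 1000 + 500))
  })
  expr <- simulate_counts(models, truth, cfg)
  de <- call_de(expr)
  frac <- mean(de$p_value < 0.05)
  expect_lte(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / n))
  expect_equal(attr(de, "summary")$n_de, 0)
})

test_that("power: planted |log2FC| = 3 is recovered with correct signs", {
  # mass-balanced direction split keeps the library composition fixed, so
  # "null" keeps its meaning under FPKM (relative) semantics
  alpha <- (1 - 2^-3) / (2^3 - 2^-3)
  set.seed(23)
  n <- 500
  de_status <- ifelse(runif(n) < 0.3, ifelse(runif(n) < alpha, "up", "down"), "null")
  truth <- data.frame(transcript_id = paste0("t", 1:n),
                      gene_id = paste0("g", 1:n), ref_gene_id = "none",
                      true_class = "coding", true_de_status = de_status,
                      true_log2fc = ifelse(de_status == "up", 3,
                                           ifelse(de_status == "down", -3, 0)),
                      true_mean = 500)
  models <- lapply(1:n, function(i) {
    transcript_model(paste0("t", i), paste0("g", i), "chr1", "+",
                     cbind((i - 1) * 1000, (i - 1) * 1000 + 500))
  })
  cfg <- sim_config(seed = 23, de_log2fc = 3, nb_dispersion = 0.05)
  expr <- simulate_counts(models, truth, cfg)
  de <- call_de(expr)
  planted <- de_status != "null"
  sens <- mean(de$status[planted] != "ns")
  expect_gte(sens, 0.9)
  hit <- planted & de$status != "ns"
  expect_gte(mean(ifelse(de$status[hit] == "up", 1, -1) ==
                  ifelse(de_status[hit] == "up", 1, -1)), 0.99)
})
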