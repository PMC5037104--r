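test_that("size factors equal the step-by-step median-of-ratios", {
  m <- matrix(c(10, 20, 30, 10, 20, 30, 10, 20, 30, 10, 20, 30), ncol = 4)
  expect_equal(unname(compute_size_factors(m)), rep(1, 4))
  m2 <- cbind(c(10, 20, 40), c(20, 40, 80))
  expect_equal(unname(compute_size_factors(m2)), c(1 / sqrt(2), sqrt(2)))
  set.seed(81)
  m3 <- matrix(rpois(200, 40), ncol = 4)
  m3[sample(200, 12)] <- 0
  expect_equal(unname(compute_size_factors(m3)),
               unname(oracle_size_factors(m3)), tolerance = 1e-12)
  allzero <- matrix(c(0, 5, 5, 0, 0, 5, 5, 0), ncol = 4)
  expect_error(compute_size_factors(allzero), "filter")
  # cross-check against the reference implementation (which interpolates
  # even medians in log space, hence the loose tolerance)
  expect_equal(unname(compute_size_factors(m3)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m3)),
               tolerance = 1e-4)
})

test_that("normalization divides by factors and combining sums replicates", {
  m <- rbind(g1 = c(10, 20, 5, 5), g2 = c(4, 4, 4, 4))
  nc <- normalize_and_combine(m, c(1, 1, 1, 1))
  expect_equal(nc$apo_combined, c(30, 8))
  nc2 <- normalize_and_combine(m, c(1, 2, 1, 1))
  expect_equal(nc2$apo_combined[1], 10 + 10)
  # conservation: the combined totals equal the normalized totals
  expect_equal(sum(nc2$apo_combined) + sum(nc2$ir64_combined),
               sum(attr(nc2, "normalized")))
  expect_error(normalize_and_combine(m, c(1, -1, 1, 1)), "positive")
})

test_that("the exact binomial AI p-value matches closed forms and binom.test", {
  expect_equal(binomial_ai_test(5, 5), 1)
  expect_equal(binomial_ai_test(0, 10), 2 / 1024)
  # large asymmetric case against the independent implementation
  expect_equal(binomial_ai_test(201, 5),
               stats::binom.test(201, 206, 0.5)$p.value, tolerance = 1e-12)
  set.seed(82)
  for (i in 1:25) {
    n <- sample(1:400, 1)
    x <- sample(0:n, 1)
    expect_equal(binomial_ai_test(x, n - x),
                 stats::binom.test(x, n, 0.5)$p.value, tolerance = 1e-10)
  }
  # fractional normalized counts are rounded before testing
  expect_equal(binomial_ai_test(4.6, 5.4), binomial_ai_test(5, 5))
  expect_message(p0 <- binomial_ai_test(0, 0), "zero combined")
  expect_true(is.na(p0))
})

test_that("the chi-square AI test uses 1 df without correction and filters expected < 5", {
  expect_equal(chisq_ai_test(5, 5), 1)
  expect_true(is.na(chisq_ai_test(4, 4)))     # expected 4 < 5: removed
  # (30, 10): statistic 10, checked against the stock implementation
  expect_equal(chisq_ai_test(30, 10),
               stats::chisq.test(c(30, 10), correct = FALSE)$p.value,
               tolerance = 1e-12)
  expect_equal(chisq_ai_test(30, 10), 0.001565402, tolerance = 1e-6)
})

test_that("fold changes give the published extreme-case magnitude and handle zeros", {
  fc <- fold_change(4.75, 201.08)
  expect_equal(round(fc$magnitude, 1), 42.3)
  expect_identical(fc$direction, "IR64")
  fc2 <- fold_change(10, 10)
  expect_equal(fc2$fc, 1)
  expect_equal(fc2$magnitude, 1)
  expect_identical(fc2$direction, "none")
  fc3 <- fold_change(10, 0)
  expect_true(fc3$monoallelic)
  expect_identical(fc3$magnitude, Inf)
})

test_that("ASE classification respects the fold and significance boundaries", {
  rec <- data.frame(p = c(0.01, 0.01, 0.2, 0.01, 0.01),
                    magnitude = c(1.25, 1.24, 3.0, 2.0, Inf),
                    direction = c("Apo", "Apo", "Apo", "IR64", "Apo"),
                    apo_combined = c(5, 5, 6, 2, 8),
                    ir64_combined = c(4, 4, 2, 4, 0))
  cls <- classify_ase(rec, threshold = 1.25, alpha = 0.05)
  expect_identical(cls, c("apo_favoring", "biallelic", "not_significant",
                          "ir64_favoring", "monoallelic_apo"))
})

test_that("AI summaries reproduce the published table arithmetic", {
  s1 <- ai_summary_counts(179, 183, 560)
  expect_identical(s1$n_total_ai, 362)
  expect_identical(s1$pct_ai_over_significant, 64.6)
  s2 <- ai_summary_counts(179, 255, 676)
  expect_identical(s2$n_total_ai, 434)
  expect_identical(s2$pct_ai_over_significant, 64.2)
  s0 <- ai_summary_counts(0, 0, 0)
  expect_identical(s0$n_total_ai, 0)
  expect_true(is.na(s0$pct_ai_over_significant))
})

test_that("swapping the alleles mirrors classes and preserves p-values", {
  set.seed(83)
  apo <- rpois(40, 30)
  ir64 <- rpois(40, 30)
  p1 <- binomial_ai_test(apo, ir64)
  p2 <- binomial_ai_test(ir64, apo)
  expect_equal(p1, p2)
  f1 <- fold_change(apo, ir64)
  f2 <- fold_change(ir64, apo)
  expect_equal(f1$magnitude, f2$magnitude)
  expect_equal(f1$fc, 1 / f2$fc)
  r1 <- data.frame(p = p1, magnitude = f1$magnitude,
                   direction = f1$direction, apo_combined = apo,
                   ir64_combined = ir64)
  r2 <- data.frame(p = p2, magnitude = f2$magnitude,
                   direction = f2$direction, apo_combined = ir64,
                   ir64_combined = apo)
  mirror <- c(apo_favoring = "ir64_favoring", ir64_favoring = "apo_favoring",
              monoallelic_apo = "monoallelic_ir64",
              monoallelic_ir64 = "monoallelic_apo",
              biallelic = "biallelic", not_significant = "not_significant")
  expect_identical(unname(mirror[classify_ase(r1)]), classify_ase(r2))
})

test_that("the binomial test holds its size and detects 70:30 imbalance", {
  set.seed(84)
  # type-I error at depth 40 under a 1:1 truth, 5000 genes
  x <- rbinom(5000, 40, 0.5)
  p <- binomial_ai_test(x, 40 - x)
  rej <- mean(p < 0.05)
  expect_lte(rej, 0.05 + 3 * sqrt(0.05 * 0.95 / 5000))
  # power: >= 90 % of 70:30 genes with 100 informative reads are called
  # asymmetric at the 1.25x threshold
  x7 <- rbinom(1000, 100, 0.7)
  rec <- data.frame(p = binomial_ai_test(x7, 100 - x7),
                    magnitude = pmax(x7, 100 - x7) / pmin(x7, 100 - x7),
                    direction = ifelse(x7 >= 50, "Apo", "IR64"),
                    apo_combined = x7, ir64_combined = 100 - x7)
  cls <- classify_ase(rec, threshold = 1.25)
  expect_gte(mean(cls %in% c("apo_favoring", "monoallelic_apo")), 0.90)
})

test_that("binomial and chi-square agree on reject/accept for well-covered genes", {
  set.seed(85)
  n <- sample(50:400, 600, replace = TRUE)
  frac <- runif(600, 0.35, 0.65)
  x <- rbinom(600, n, frac)
  pb <- binomial_ai_test(x, n - x)
  pc <- chisq_ai_test(x, n - x)
  agree <- (pb < 0.05) == (pc < 0.05)
  expect_gte(mean(agree), 0.95)
})

test_that("ai_test assembles a coherent per-gene table", {
  set.seed(86)
  m <- matrix(rpois(80, 25), ncol = 4,
              dimnames = list(sprintf("g%02d", 1:20),
                              c("apo_rep1", "apo_rep2", "ir64_rep1",
                                "ir64_rep2")))
  m[3, ] <- c(40, 44, 0, 0)                    # a monoallelic gene
  res <- ai_test(m, condition = "control")
  expect_s3_class(res, "ai_result")
  expect_true(all(c("p_binomial", "p_chisq", "padj_binomial", "class_125",
                    "class_200") %in% names(res)))
  expect_identical(nrow(res), 20L)
  expect_length(attr(res, "size_factors"), 4L)
  g3 <- res[res$gene_id == "g03", ]
  expect_true(g3$monoallelic)
  expect_identical(g3$class_125, "monoallelic_apo")
  # summary matches a hand count
  sm <- summary(res, threshold = 1.25)
  cls <- res$class_125
  expect_identical(sm$n_total_ai,
                   sum(cls %in% c("apo_favoring", "monoallelic_apo",
                                  "ir64_favoring", "monoallelic_ir64")))
  expect_identical(sm$n_significant, sum(res$p_binomial < 0.05))
})
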