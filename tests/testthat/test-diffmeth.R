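# Per-site t-test machinery and the promoter DMC caller.

test_that("degenerate sites are defined, not NA", {
  # both groups constant and equal
  expect_equal(t_test_site(c(0.2, 0.2, 0.2), c(0.2, 0.2, 0.2)), 1)
  # both groups constant, unequal means: below any threshold
  expect_equal(t_test_site(c(0.2, 0.2, 0.2), c(0.5, 0.5, 0.5)), 0)
  expect_equal(t_test_site(c(0, 0, 0), c(0, 0, 0), var_equal = FALSE), 1)
  expect_error(t_test_site(c(0.2, 1.2, 0.1), c(0.3, 0.2, 0.1)), "\\[0, 1\\]")
  expect_error(t_test_site(c(0.2), c(0.3, 0.2)), "2 samples")
})

test_that("both test variants agree with stats::t.test site by site", {
  set.seed(5)
  for (i in 1:30) {
    a <- runif(3)
    b <- runif(sample(3:5, 1))
    p_pool <- t_test_site(matrix(a, 1), matrix(b, 1), var_equal = TRUE)
    p_welch <- t_test_site(matrix(a, 1), matrix(b, 1), var_equal = FALSE)
    expect_equal(p_pool, t.test(a, b, var.equal = TRUE)$p.value)
    expect_equal(p_welch, t.test(a, b)$p.value)
  }
  # vectorised path equals the per-site path
  rc <- matrix(runif(30), 10, 3)
  rt <- matrix(runif(30), 10, 3)
  pv <- t_test_site(rc, rt)
  p1 <- vapply(1:10, function(i) t.test(rc[i, ], rt[i, ],
                                        var.equal = TRUE)$p.value, 0)
  expect_equal(pv, p1)
})

test_that("a clear separation is significant and matches a Monte-Carlo null", {
  a <- c(0.10, 0.12, 0.11)
  b <- c(0.45, 0.50, 0.47)
  p <- t_test_site(a, b)
  expect_lt(p, 0.05)
  expect_equal(p, t.test(a, b, var.equal = TRUE)$p.value)

  # Monte-Carlo reference on a borderline case: simulate the null
  # distribution of the pooled t statistic for normal data with the
  # observed group variances and compare tail masses.
  a2 <- c(0.20, 0.30, 0.25)
  b2 <- c(0.36, 0.46, 0.41)
  p2 <- t_test_site(a2, b2)
  t_obs <- abs(diff(c(mean(a2), mean(b2)))) /
    sqrt((var(a2) + var(b2)) / 3)
  set.seed(123)
  B <- 1e5
  sd_pool <- sqrt((var(a2) + var(b2)) / 2)
  t_null <- replicate(B, {
    x <- rnorm(3, 0, sd_pool); y <- rnorm(3, 0, sd_pool)
    (mean(y) - mean(x)) / sqrt((var(x) + var(y)) / 3)
  })
  p_mc <- mean(abs(t_null) >= t_obs)
  expect_lt(abs(p_mc - p2), 3 * sqrt(p2 * (1 - p2) / B) + 1e-3)
})

test_that("two-sided p is symmetric in the group order", {
  set.seed(8)
  for (i in 1:10) {
    a <- runif(3); b <- runif(3)
    expect_equal(t_test_site(a, b), t_test_site(b, a))
    expect_equal(t_test_site(a, b, var_equal = FALSE),
                 t_test_site(b, a, var_equal = FALSE))
  }
})

dmc_fixture <- function() {
  # sites: 1 clear hyper DMC, 1 big-but-sub-threshold diff, 1 null,
  # 1 huge diff outside any promoter
  rates <- rbind(c(0.10, 0.12, 0.11, 0.45, 0.50, 0.47),   # pos 100, DMC
                 c(0.10, 0.11, 0.09, 0.25, 0.26, 0.24),   # pos 200, diff .15
                 c(0.50, 0.52, 0.48, 0.49, 0.51, 0.50),   # pos 300, null
                 c(0.05, 0.06, 0.04, 0.95, 0.96, 0.94))   # pos 5000, no prom
  make_matrix(pos = c(100L, 200L, 300L, 5000L), rates, cov = 100L)
}

test_that("DMC rule: p below threshold AND 20-point difference, promoters only", {
  mat <- dmc_fixture()
  prom <- data.frame(chrom = "chr1", start = 1L, end = 400L,
                     strand = "+", gene_id = "gA")
  ps <- promoter_sites(mat, prom)
  dmcs <- call_dmcs(mat, ps)
  expect_equal(nrow(dmcs), 1L)
  expect_equal(dmcs$pos, 100L)
  expect_equal(dmcs$direction, "hyper")
  expect_equal(dmcs$diff, mean(c(0.45, 0.50, 0.47)) - mean(c(0.10, 0.12, 0.11)))
  expect_equal(attr(dmcs, "n_tested"), 3L)
  # the 15-point site is excluded regardless of p
  expect_false(200L %in% dmcs$pos)
  # the huge-effect site outside promoters is neither tested nor reported
  expect_false(5000L %in% dmcs$pos)
  # promoters = NULL tests everything
  all_dmcs <- call_dmcs(mat, NULL)
  expect_true(5000L %in% all_dmcs$pos)
})

test_that("DMC calls are monotone in both thresholds and stable to sample order", {
  set.seed(21)
  n <- 300
  rates <- matrix(runif(n * 6), n, 6)
  mat <- make_matrix(seq(10L, by = 20L, length.out = n), rates, cov = 1000L)
  base <- call_dmcs(mat, NULL, p_threshold = 0.10, diff_threshold = 0.10)
  stricter_p <- call_dmcs(mat, NULL, p_threshold = 0.01, diff_threshold = 0.10)
  stricter_d <- call_dmcs(mat, NULL, p_threshold = 0.10, diff_threshold = 0.30)
  key <- function(x) paste(x$chrom, x$pos)
  expect_true(all(key(stricter_p) %in% key(base)))
  expect_true(all(key(stricter_d) %in% key(base)))

  perm <- c(3, 1, 2, 5, 6, 4)  # permutes within groups
  mat2 <- mat
  mat2$rate <- mat$rate[, perm]
  mat2$cov <- mat$cov[, perm]
  mat2$meth <- mat$meth[, perm]
  mat2$samples <- mat$samples[perm]
  mat2$groups <- mat$groups[perm]
  expect_equal(key(call_dmcs(mat2, NULL)), key(call_dmcs(mat, NULL)))
})

test_that("optional BH correction only removes calls", {
  set.seed(31)
  n <- 500
  rates <- matrix(runif(n * 6), n, 6)
  mat <- make_matrix(seq(10L, by = 20L, length.out = n), rates, cov = 1000L)
  raw <- call_dmcs(mat, NULL, diff_threshold = 0.10)
  adj <- call_dmcs(mat, NULL, diff_threshold = 0.10, fdr = TRUE)
  expect_true(all(paste(adj$chrom, adj$pos) %in% paste(raw$chrom, raw$pos)))
  expect_lte(nrow(adj), nrow(raw))
})

test_that("DMC tables round-trip with their summary line", {
  mat <- dmc_fixture()
  dmcs <- call_dmcs(mat, NULL)
  f <- tempfile(fileext = ".tsv")
  write_dmc_table(dmcs, f)
  expect_match(readLines(f, n = 1L), "^# hyper=")
  back <- read_dmc_table(f)
  expect_equal(back$pos, dmcs$pos)
  expect_equal(back$direction, dmcs$direction)
  expect_equal(attr(back, "n_tested"), attr(dmcs, "n_tested"))
})
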