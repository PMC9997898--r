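# Windowed DMR extraction against an exhaustive oracle, plus merging.

test_that("boundary configurations pin the window conventions", {
  # 10 CpGs at 1000,1030,...,1270: span 271, all diffs +0.25 -> one window
  pos <- seq(1000L, by = 30L, length.out = 10L)
  mat <- make_diff_matrix(pos, rep(0.25, 10))
  w <- enumerate_windows(mat)
  expect_equal(nrow(w), 1L)
  expect_equal(w$n_cpgs, 10L)
  expect_equal(w$mean_diff, 0.25)
  expect_equal(w$start, 1000L)
  expect_equal(w$end, 1270L)
  expect_equal(w$direction, "hyper")

  # 9 CpGs with huge diffs: below the count threshold
  mat9 <- make_diff_matrix(seq(1000L, by = 30L, length.out = 9L), rep(0.5, 9))
  expect_equal(nrow(enumerate_windows(mat9)), 0L)

  # span exactly 300 qualifies, 301 does not
  pos300 <- c(seq(1000L, by = 33L, length.out = 9L), 1299L)  # span 300
  expect_equal(nrow(enumerate_windows(make_diff_matrix(pos300, rep(0.3, 10)))), 1L)
  pos301 <- c(seq(1000L, by = 33L, length.out = 9L), 1300L)  # span 301
  expect_equal(nrow(enumerate_windows(make_diff_matrix(pos301, rep(0.3, 10)))), 0L)

  # regional average >= 0.20 can hold with individual diffs below 0.20
  mixed <- rep(c(0.15, 0.27), 5)
  wm <- enumerate_windows(make_diff_matrix(seq(1000L, by = 30L,
                                               length.out = 10L), mixed))
  expect_equal(nrow(wm), 1L)
  expect_equal(wm$mean_diff, mean(mixed))

  # mean below 0.20 fails even though every site is near the cutoff
  low <- rep(0.19, 10)
  expect_equal(nrow(enumerate_windows(make_diff_matrix(
    seq(1000L, by = 30L, length.out = 10L), low))), 0L)
})

test_that("scanner equals the exhaustive O(n^2) oracle on random chromosomes", {
  set.seed(2024)
  for (rep in 1:12) {
    n <- 200
    pos <- sort(sample(seq(2L, 12000L, by = 2L), n))
    # blocky diffs so qualifying runs actually arise
    d <- rep(0, n)
    for (b in 1:6) {
      i <- sample(n - 15, 1)
      d[i:(i + sample(8:15, 1))] <- runif(1, -0.45, 0.45)
    }
    d <- d + rnorm(n, 0, 0.03)
    d <- pmin(pmax(d, -0.59), 0.59)
    mat <- make_diff_matrix(pos, round(d, 3))
    gm <- group_means(mat)
    w <- enumerate_windows(mat)
    bf <- bf_windows(gm$pos, gm$diff)
    expect_equal(nrow(w), nrow(bf))
    if (nrow(bf)) {
      expect_equal(w$first_idx, bf$first)
      expect_equal(w$last_idx, bf$last)
    }
  }
})

test_that("windows merge by direction and overlap only", {
  # two overlapping hyper windows -> one DMR over the union of sites
  pos <- seq(1000L, by = 28L, length.out = 16L)
  d <- c(rep(0.30, 5), rep(0.22, 6), rep(0.30, 5))
  mat <- make_diff_matrix(pos, d)
  w <- enumerate_windows(mat)
  expect_gte(nrow(w), 2L)
  dmrs <- merge_windows(w, mat)
  expect_equal(nrow(dmrs), 1L)
  expect_equal(dmrs$start, min(w$start))
  expect_equal(dmrs$end, max(w$end))
  expect_equal(dmrs$n_cpgs, max(w$last_idx) - min(w$first_idx) + 1L)
  gm <- group_means(mat)
  expect_equal(dmrs$mean_diff,
               mean(gm$diff[min(w$first_idx):max(w$last_idx)]))

  # non-overlapping windows stay separate
  pos2 <- c(seq(1000L, by = 30L, length.out = 10L),
            seq(2000L, by = 30L, length.out = 10L))
  mat2 <- make_diff_matrix(pos2, rep(0.3, 20))
  w2 <- enumerate_windows(mat2)
  dmr2 <- merge_windows(w2, mat2)
  expect_equal(nrow(dmr2), 2L)

  # opposite directions never merge even when spans overlap
  pos3 <- seq(1000L, by = 10L, length.out = 40L)
  d3 <- c(rep(0.35, 20), rep(-0.35, 20))
  mat3 <- make_diff_matrix(pos3, d3)
  w3 <- enumerate_windows(mat3)
  dmr3 <- merge_windows(w3, mat3)
  expect_setequal(unique(dmr3$direction), c("hyper", "hypo"))
  expect_equal(nrow(dmr3), 2L)
})

test_that("merging neither gains nor loses covered window bases", {
  set.seed(77)
  for (rep in 1:8) {
    n <- 150
    pos <- sort(sample(seq(2L, 9000L, by = 2L), n))
    d <- rep(0, n)
    for (b in 1:5) {
      i <- sample(n - 14, 1)
      d[i:(i + 13)] <- runif(1, -0.4, 0.4)
    }
    mat <- make_diff_matrix(pos, round(d, 3))
    w <- enumerate_windows(mat)
    dmrs <- merge_windows(w, mat)
    for (dir in c("hyper", "hypo")) {
      cover <- function(df) {
        df <- df[df$direction == dir, , drop = FALSE]
        if (!nrow(df)) return(integer(0))
        sort(unique(unlist(Map(seq, df$start, df$end))))
      }
      expect_identical(cover(dmrs), cover(w))
    }
  }
})

test_that("the scanner is deterministic and chromosome-order invariant", {
  set.seed(13)
  n <- 120
  build <- function(chroms) {
    pos <- sort(sample(seq(2L, 6000L, by = 2L), n))
    d <- c(rep(0.3, 12), runif(n - 24, -0.1, 0.1), rep(-0.3, 12))
    rates <- cbind(0.4, 0.4, 0.4, 0.4 + d, 0.4 + d, 0.4 + d)
    list(pos = pos, rates = rates)
  }
  a <- build()
  mat_ab <- make_matrix(rep(a$pos, 2), rbind(a$rates, a$rates),
                        chrom = rep(c("chrA", "chrB"), each = n), cov = 1000L)
  mat_ba <- make_matrix(rep(a$pos, 2), rbind(a$rates, a$rates),
                        chrom = rep(c("chrB", "chrA"), each = n), cov = 1000L)
  wa <- enumerate_windows(mat_ab)
  wb <- enumerate_windows(mat_ba)
  expect_equal(wa[order(wa$chrom, wa$start), -1],
               wb[order(wb$chrom, wb$start), -1],
               ignore_attr = TRUE)
  expect_identical(enumerate_windows(mat_ab), enumerate_windows(mat_ab))
})
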