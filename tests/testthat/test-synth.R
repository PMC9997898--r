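# The synthetic generator: determinism, format closure, truth
# invariants and baseline calibration.

small_cfg <- function(...) {
  args <- utils::modifyList(list(n_chroms = 1L, chrom_length = 2e5,
                                 n_genes_per_chrom = 10L, n_dmrs = 6L,
                                 n_dmcs = 8L, n_background_peaks = 10L),
                            list(...))
  do.call(synth_config, args)
}

test_that("identical seeds give byte-identical files, different seeds differ", {
  d1 <- file.path(tempdir(), "sim_a")
  d3 <- file.path(tempdir(), "sim_c")
  sim1 <- simulate_wgbs(small_cfg(seed = 5L), dir = d1)
  h1 <- tools::md5sum(unlist(sim1$files))
  sim2 <- simulate_wgbs(small_cfg(seed = 5L), dir = d1)   # same destination
  h2 <- tools::md5sum(unlist(sim2$files))
  expect_identical(unname(h1), unname(h2))
  sim3 <- simulate_wgbs(small_cfg(seed = 6L), dir = d3)
  expect_false(identical(tools::md5sum(sim1$files$truth_rates)[[1]],
                         tools::md5sum(sim3$files$truth_rates)[[1]]))
})

test_that("generated files parse through the io module without error", {
  d <- file.path(tempdir(), "sim_parse")
  sim <- simulate_wgbs(small_cfg(seed = 2L), dir = d)
  sheet <- read.table(sim$files$sample_sheet, header = TRUE, sep = "\t")
  expect_equal(nrow(sheet), 6L)
  m <- read_cpg_report(sheet$path[1], sheet$sample_id[1], sheet$group[1])
  expect_gt(nrow(m), 0)
  # stranded dyads: equal numbers of plus and minus calls
  expect_equal(sum(m$strand == "+"), sum(m$strand == "-"))
  tss <- read_tss_table(sim$files$tss)
  expect_equal(nrow(tss), 10L)
  expect_silent(p <- suppressMessages(read_peaks(sim$files$peaks, 50)))
  expect_true(all(p$score >= 50))
})

test_that("planted DMRs qualify as windows on the true rates", {
  sim <- simulate_wgbs(small_cfg(seed = 3L))
  tr <- sim$truth
  expect_equal(nrow(tr$dmrs), 6L)
  for (i in seq_len(nrow(tr$dmrs))) {
    ii <- which(tr$rates$chrom == tr$dmrs$chrom[i] &
                  tr$rates$pos >= tr$dmrs$start[i] &
                  tr$rates$pos <= tr$dmrs$end[i])
    expect_gte(length(ii), 12L)
    span <- max(tr$rates$pos[ii]) - min(tr$rates$pos[ii]) + 1L
    expect_lte(span, 300L)
    d <- tr$rates$rate_treated[ii] - tr$rates$rate_control[ii]
    expect_gte(abs(mean(d)), 0.20)
    expect_equal(unique(sign(d)), if (tr$dmrs$direction[i] == "hyper") 1 else -1)
  }
  # planted DMCs carry the full configured shift inside promoters
  expect_equal(nrow(tr$dmcs), 8L)
  key <- paste(tr$rates$chrom, tr$rates$pos)
  ii <- match(paste(tr$dmcs$chrom, tr$dmcs$pos), key)
  expect_false(anyNA(ii))
  expect_equal(tr$rates$rate_treated[ii] - tr$rates$rate_control[ii],
               tr$dmcs$delta)
})

test_that("sperm-like baselines hit their configured grand mean", {
  cfg <- synth_config(seed = 8L, n_dmrs = 0L, n_dmcs = 0L,
                      n_background_peaks = 0L)
  sim <- simulate_wgbs(cfg)
  expect_gt(nrow(sim$truth$rates), 1e4)
  # expected mixture mean: promoter islands low, background bimodal
  meths <- lapply(sim$methylomes, destrand)
  mat <- unify(meths, 10)
  gl_mean <- mean(mat$rate)
  true_mean <- mean((sim$truth$rates$rate_control +
                       sim$truth$rates$rate_treated) / 2)
  expect_lt(abs(gl_mean - true_mean), 0.02)
})

test_that("morula mode targets the configured low grand mean", {
  cfg <- synth_config(profile = "morula_like", seed = 12L, n_dmrs = 0L,
                      n_dmcs = 0L, n_background_peaks = 0L)
  sim <- simulate_wgbs(cfg)
  mat <- unify(lapply(sim$methylomes, destrand), 10)
  expect_gt(nrow(mat$sites), 1e4)
  ctrl_mean <- mean(mat$rate[, mat$groups == "control"])
  expect_lt(abs(ctrl_mean - 0.19), 0.01)
})

test_that("truth_eval scores recovery and flags undefined sensitivity", {
  sim <- simulate_wgbs(small_cfg(seed = 4L))
  # calling the truth intervals back yields sensitivity 1 and no false calls
  called <- structure(data.frame(chrom = sim$truth$dmrs$chrom,
                                 start = sim$truth$dmrs$start,
                                 end = sim$truth$dmrs$end,
                                 n_cpgs = 12L,
                                 mean_diff = sim$truth$dmrs$delta,
                                 direction = sim$truth$dmrs$direction),
                      class = c("dmr_table", "data.frame"))
  ev <- truth_eval(called, NULL, sim$truth)
  expect_equal(ev$dmr_sensitivity, 1)
  expect_equal(sum(ev$false_dmrs), 0L)
  # direction mismatches do not count as recovery
  flipped <- called
  flipped$direction <- ifelse(called$direction == "hyper", "hypo", "hyper")
  expect_equal(truth_eval(flipped, NULL, sim$truth)$dmr_sensitivity, 0)

  # nothing planted: sensitivity undefined, false calls counted
  cfg0 <- small_cfg(seed = 4L, n_dmrs = 0L, n_dmcs = 0L)
  sim0 <- simulate_wgbs(cfg0)
  ev0 <- truth_eval(called, NULL, sim0$truth)
  expect_true(is.na(ev0$dmr_sensitivity))
  expect_equal(sum(ev0$false_dmrs), nrow(called))
})

test_that("impossible planting configurations fail loudly", {
  expect_error(synth_config(dmr_n_cpgs = 200L, dmr_span = 250),
               "too small")
  expect_error(simulate_wgbs(synth_config(n_chroms = 1L, chrom_length = 3e4,
                                          n_genes_per_chrom = 5L,
                                          n_dmrs = 40L)),
               "cannot place")
})
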