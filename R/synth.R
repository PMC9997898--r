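# Synthetic WGBS generator: clustered CpG placement, sperm- or
# morula-like baselines, beta-binomial count noise, and planted DMCs,
# DMRs and histone peaks with recorded truth, plus the recovery scorer.

#' Configuration for the synthetic WGBS generator
#'
#' Defaults describe the standard benchmark scenario: a 3-vs-3 design,
#' negative-binomial coverage around 30x, mild sample-level
#' beta-overdispersion, 50 planted DMRs of 12 CpGs within 250 bp at a
#' 0.30 rate shift, and 60 planted promoter DMCs at a 0.35 shift.
#'
#' @param profile `"sperm_like"` (bimodal: mostly high methylation with
#'   a low-methylation island component; promoter CpG islands largely
#'   unmethylated) or `"morula_like"` (unimodal low, target grand mean
#'   `morula_mean`).
#' @param n_chroms,chrom_length genome shape.
#' @param cpg_spacing mean distance (bp) between background CpGs.
#' @param island_spacing mean CpG distance inside promoter islands.
#' @param n_genes_per_chrom genes (hence promoters/islands) per
#'   chromosome.
#' @param promoter_upstream promoter length used for island placement.
#' @param sperm_high_mean,sperm_low_mean,sperm_high_weight,baseline_conc
#'   sperm-profile baseline beta-mixture parameters.
#' @param promoter_low_mean,promoter_high_mean,promoter_low_weight
#'   promoter-island baseline mixture (mostly unmethylated).
#' @param morula_mean,morula_conc morula-profile beta baseline; the
#'   generated grand mean is unbiased for `morula_mean` (default 0.19).
#' @param phi sample-level beta overdispersion of the methylation
#'   probability around the group's true rate (variance
#'   `phi * mu * (1 - mu)`); 0 means pure binomial sampling.
#' @param coverage_mean,coverage_size negative-binomial coverage per
#'   site and sample (mean 30, size 30 by default), split binomially
#'   between the two strands of each dyad.
#' @param n_control,n_treated replicates per group (3 and 3).
#' @param n_dmrs,dmr_n_cpgs,dmr_span,dmr_delta planted-DMR spec: count,
#'   member CpGs, exact span (bp), and rate shift (alternating
#'   hyper/hypo).
#' @param n_dmcs,dmc_delta planted promoter DMCs: count (one per
#'   distinct promoter, alternating direction) and rate shift.
#' @param peak_fraction fraction of planted DMRs that receive a nearby
#'   (within 1 kb) high-scoring peak.
#' @param n_background_peaks unplanted peaks at random positions with
#'   scores spanning the significance threshold.
#' @param peak_score_range,peak_width_range uniform ranges for
#'   background peak scores and all peak widths.
#' @param group_shift uniform rate shift added to the treated group's
#'   true rate at every site (clamped to `[0, 1]`; default 0). Used for
#'   sample-separation scenarios rather than locus-level effects.
#' @param effect_scale `"rate"` (additive shift, clamped) or `"logit"`
#'   (shift on the log-odds scale).
#' @param seed integer; fully determines the output.
#' @return object of class `synth_config` (a validated list).
#' @export
synth_config <- function(profile = c("sperm_like", "morula_like"),
                         n_chroms = 2L, chrom_length = 1e6,
                         cpg_spacing = 150, island_spacing = 25,
                         n_genes_per_chrom = 40L, promoter_upstream = 2000,
                         sperm_high_mean = 0.80, sperm_low_mean = 0.10,
                         sperm_high_weight = 0.75, baseline_conc = 15,
                         promoter_low_mean = 0.08, promoter_high_mean = 0.65,
                         promoter_low_weight = 0.7,
                         morula_mean = 0.19, morula_conc = 10,
                         phi = 0.005, coverage_mean = 30, coverage_size = 30,
                         n_control = 3L, n_treated = 3L,
                         n_dmrs = 50L, dmr_n_cpgs = 12L, dmr_span = 250,
                         dmr_delta = 0.30, n_dmcs = 60L, dmc_delta = 0.35,
                         peak_fraction = 0.6, n_background_peaks = 40L,
                         peak_score_range = c(10, 400),
                         peak_width_range = c(300, 800),
                         group_shift = 0,
                         effect_scale = c("rate", "logit"), seed = 1L) {
  cfg <- list(profile = match.arg(profile), n_chroms = as.integer(n_chroms),
              chrom_length = chrom_length, cpg_spacing = cpg_spacing,
              island_spacing = island_spacing,
              n_genes_per_chrom = as.integer(n_genes_per_chrom),
              promoter_upstream = promoter_upstream,
              sperm_high_mean = sperm_high_mean,
              sperm_low_mean = sperm_low_mean,
              sperm_high_weight = sperm_high_weight,
              baseline_conc = baseline_conc,
              promoter_low_mean = promoter_low_mean,
              promoter_high_mean = promoter_high_mean,
              promoter_low_weight = promoter_low_weight,
              morula_mean = morula_mean, morula_conc = morula_conc,
              phi = phi, coverage_mean = coverage_mean,
              coverage_size = coverage_size,
              n_control = as.integer(n_control),
              n_treated = as.integer(n_treated),
              n_dmrs = as.integer(n_dmrs), dmr_n_cpgs = as.integer(dmr_n_cpgs),
              dmr_span = dmr_span, dmr_delta = dmr_delta,
              n_dmcs = as.integer(n_dmcs), dmc_delta = dmc_delta,
              peak_fraction = peak_fraction,
              n_background_peaks = as.integer(n_background_peaks),
              peak_score_range = peak_score_range,
              peak_width_range = peak_width_range,
              group_shift = group_shift,
              effect_scale = match.arg(effect_scale),
              seed = as.integer(seed))
  stopifnot(cfg$dmr_delta >= 0, cfg$dmr_delta <= 1,
            cfg$dmc_delta >= 0, cfg$dmc_delta <= 1,
            cfg$phi >= 0, cfg$phi < 1,
            cfg$n_control >= 2L, cfg$n_treated >= 2L)
  if (cfg$n_dmrs > 0 && cfg$dmr_n_cpgs * 2 > cfg$dmr_span)
    stopf("dmr_span %s too small for %d CpGs (dyads need 2 bp each)",
          format(cfg$dmr_span), cfg$dmr_n_cpgs)
  class(cfg) <- "synth_config"
  cfg
}

# beta draw with mean mu and variance phi*mu*(1-mu)
rbeta_mean <- function(n, mu, phi) {
  mu <- pmin(pmax(mu, 1e-3), 1 - 1e-3)
  a <- mu * (1 - phi) / phi
  b <- (1 - mu) * (1 - phi) / phi
  rbeta(n, a, b)
}

# clustered positions with a minimum gap of 2 bp (dyads must not abut)
rpositions <- function(from, to, mean_spacing) {
  if (to < from) return(integer(0))
  n_max <- ceiling((to - from + 1) / 2)
  gaps <- 2L + stats::rgeom(min(n_max, ceiling((to - from) / mean_spacing * 2) + 10L),
                            prob = 1 / max(mean_spacing - 1, 1))
  pos <- from + cumsum(c(stats::rgeom(1L, prob = 2 / mean_spacing), gaps))
  pos[pos <= to]
}

#' Generate a synthetic WGBS experiment with known truth
#'
#' Draws a clustered CpG map (background CpGs plus dense promoter
#' islands), assigns per-site true methylation rates for the two
#' groups, plants the configured DMCs, DMRs and histone peaks, then
#' samples stranded per-sample read counts: per-strand coverage is
#' negative binomial, the per-sample methylation probability is beta
#' around the group rate (overdispersion `phi`), and methylated counts
#' are binomial. The same seed always reproduces the same experiment,
#' byte for byte when written.
#'
#' @param config a [synth_config()].
#' @param dir optional directory; when given, per-sample cytosine
#'   reports, a sample sheet, TSS BED, peak BED and truth tables are
#'   written there.
#' @return list with `methylomes` (stranded [methylome()] objects),
#'   `tss`, `promoters`, `peaks` (raw, unfiltered, 1-based), `truth`
#'   (class `synthetic_truth`: `dmrs`, `dmcs`, `peaks`, `rates`),
#'   `config`, and `files` (paths, when `dir` was given).
#' @export
simulate_wgbs <- function(config = synth_config(), dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, simulate_wgbs_impl(config, dir))
}

simulate_wgbs_impl <- function(cfg, dir) {
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  L <- cfg$chrom_length

  ## gene map: TSS at jittered segment centres, random strand
  tss <- do.call(rbind, lapply(chroms, function(ch) {
    k <- cfg$n_genes_per_chrom
    centre <- (seq_len(k) - 0.5) * (L / k)
    t0 <- as.integer(round(centre + runif(k, -L / k / 8, L / k / 8)))
    t0 <- pmin(pmax(t0, cfg$promoter_upstream + 2L), as.integer(L) - cfg$promoter_upstream - 2L)
    data.frame(chrom = ch, tss = t0,
               strand = sample(c("+", "-"), k, replace = TRUE),
               gene_id = sprintf("%s_g%03d", ch, seq_len(k)))
  }))
  promoters <- build_promoters(tss, cfg$promoter_upstream)

  ## planted DMR anchors: intergenic, clear of promoters and each other
  dmr_truth <- NULL
  if (cfg$n_dmrs > 0) {
    per_chrom <- diff(round(seq(0, cfg$n_dmrs, length.out = cfg$n_chroms + 1)))
    slots <- list()
    for (ci in seq_along(chroms)) {
      ch <- chroms[ci]
      pr <- promoters[promoters$chrom == ch, ]
      placed <- integer(0)
      for (r in seq_len(per_chrom[ci])) {
        ok <- FALSE
        for (try in 1:500) {
          s <- as.integer(round(runif(1, 1000, L - cfg$dmr_span - 1000)))
          e <- s + as.integer(cfg$dmr_span) - 1L
          clash_p <- any(pr$start - 500 <= e & pr$end + 500 >= s)
          clash_d <- length(placed) &&
            any(abs(placed - s) < cfg$dmr_span + 2000)
          if (!clash_p && !clash_d) { ok <- TRUE; break }
        }
        if (!ok)
          stopf("cannot place planted DMR %d on %s: genome too crowded", r, ch)
        placed <- c(placed, s)
        slots[[length(slots) + 1L]] <- data.frame(chrom = ch, start = s, end = e)
      }
    }
    dmr_truth <- do.call(rbind, slots)
    dmr_truth$direction <- rep_len(c("hyper", "hypo"), nrow(dmr_truth))
    dmr_truth$delta <- ifelse(dmr_truth$direction == "hyper", 1, -1) * cfg$dmr_delta
    dmr_truth$n_cpgs <- cfg$dmr_n_cpgs
  }

  ## site map per chromosome
  site_list <- lapply(chroms, function(ch) {
    bg <- rpositions(2L, as.integer(L) - 1L, cfg$cpg_spacing)
    pr <- promoters[promoters$chrom == ch, ]
    isl <- unlist(lapply(seq_len(nrow(pr)), function(i)
      rpositions(pr$start[i], pr$end[i], cfg$island_spacing)))
    planted <- integer(0)
    if (!is.null(dmr_truth)) {
      dt <- dmr_truth[dmr_truth$chrom == ch, ]
      planted <- unlist(lapply(seq_len(nrow(dt)), function(i) {
        s <- dt$start[i]; e <- dt$end[i]; k <- cfg$dmr_n_cpgs
        grid <- seq(s + 2L, e - 2L, by = 2L)
        mid <- sort(sample(grid, k - 2L))
        c(s, mid, e)
      }))
    }
    df <- data.frame(pos = c(bg, isl, planted),
                     planted = rep(c(FALSE, FALSE, TRUE),
                                   c(length(bg), length(isl), length(planted))))
    df <- df[order(df$pos, !df$planted), , drop = FALSE]
    df <- df[!duplicated(df$pos), , drop = FALSE]
    # enforce dyad separation, never dropping a planted site
    keep <- logical(nrow(df)); last <- -10L
    for (i in seq_len(nrow(df))) {
      if (df$pos[i] - last >= 2L || df$planted[i]) {
        keep[i] <- TRUE; last <- df$pos[i]
      }
    }
    df <- df[keep, , drop = FALSE]
    df$chrom <- ch
    df
  })
  sites <- do.call(rbind, site_list)
  sites <- sites[order_sites(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  ns <- nrow(sites)

  ## baseline (control) rates
  mix_beta <- function(n, mean_hi, mean_lo, w_hi, conc) {
    hi <- runif(n) < w_hi
    mu <- ifelse(hi, mean_hi, mean_lo)
    rbeta(n, mu * conc, (1 - mu) * conc)
  }
  in_promoter <- rep(FALSE, ns)
  pidx <- promoter_hits(sites, promoters)
  in_promoter[pidx] <- TRUE
  if (cfg$profile == "sperm_like") {
    base <- mix_beta(ns, cfg$sperm_high_mean, cfg$sperm_low_mean,
                     cfg$sperm_high_weight, cfg$baseline_conc)
    np <- sum(in_promoter)
    base[in_promoter] <- mix_beta(np, cfg$promoter_high_mean,
                                  cfg$promoter_low_mean,
                                  1 - cfg$promoter_low_weight,
                                  cfg$baseline_conc)
  } else {
    base <- rbeta(ns, cfg$morula_mean * cfg$morula_conc,
                  (1 - cfg$morula_mean) * cfg$morula_conc)
  }
  rate_control <- base
  rate_treated <- if (cfg$group_shift != 0)
    pmin(pmax(base + cfg$group_shift, 0), 1) else base

  apply_shift <- function(mu, delta) {
    if (cfg$effect_scale == "rate") pmin(pmax(mu + delta, 0), 1)
    else stats::plogis(stats::qlogis(pmin(pmax(mu, 1e-6), 1 - 1e-6)) +
                         delta * 8)   # logit shift scaled to the rate delta
  }

  ## plant DMR effects: redraw baselines so the full shift survives
  if (!is.null(dmr_truth)) {
    for (i in seq_len(nrow(dmr_truth))) {
      ii <- which(sites$chrom == dmr_truth$chrom[i] &
                    sites$pos >= dmr_truth$start[i] &
                    sites$pos <= dmr_truth$end[i])
      d <- dmr_truth$delta[i]
      lo <- if (d > 0) 0.05 else abs(d) + 0.02
      hi <- if (d > 0) 1 - d - 0.02 else 0.95
      rate_control[ii] <- runif(length(ii), lo, hi)
      rate_treated[ii] <- apply_shift(rate_control[ii], d)
    }
  }

  ## plant promoter DMCs: one per distinct promoter
  dmc_truth <- NULL
  if (cfg$n_dmcs > 0) {
    # promoters holding at least one non-planted site
    cand <- setdiff(pidx, which(sites$planted))
    prom_of <- promoter_of(sites[cand, , drop = FALSE], promoters)
    first_site <- !duplicated(prom_of)
    avail <- which(first_site & !is.na(prom_of))
    if (length(avail) < cfg$n_dmcs)
      stopf("only %d promoters with CpGs available for %d planted DMCs",
            length(avail), cfg$n_dmcs)
    pick <- sort(sample(avail, cfg$n_dmcs))
    ii <- cand[pick]
    dir_ <- rep_len(c("hyper", "hypo"), cfg$n_dmcs)
    delta <- ifelse(dir_ == "hyper", 1, -1) * cfg$dmc_delta
    rate_control[ii] <- ifelse(dir_ == "hyper",
                               runif(cfg$n_dmcs, 0.05, 0.25),
                               runif(cfg$n_dmcs, 0.60, 0.85))
    rate_treated[ii] <- apply_shift(rate_control[ii], delta)
    dmc_truth <- data.frame(chrom = sites$chrom[ii], pos = sites$pos[ii],
                            gene_id = promoters$gene_id[prom_of[pick]],
                            delta = delta, direction = dir_)
    dmc_truth <- dmc_truth[order_sites(dmc_truth$chrom, dmc_truth$pos), ]
    rownames(dmc_truth) <- NULL
  }

  ## peaks
  peak_truth <- NULL
  peak_rows <- list()
  if (!is.null(dmr_truth) && cfg$peak_fraction > 0) {
    k <- round(cfg$peak_fraction * nrow(dmr_truth))
    if (k > 0) {
      near <- sort(sample(nrow(dmr_truth), k))
      w <- as.integer(round(runif(k, cfg$peak_width_range[1L],
                                  cfg$peak_width_range[2L])))
      off <- as.integer(round(runif(k, -500, 900)))
      s <- pmax(dmr_truth$end[near] + off, 1L)
      peak_rows$planted <- data.frame(chrom = dmr_truth$chrom[near],
                                      start = s, end = s + w - 1L,
                                      score = round(runif(k, 60, 400), 1),
                                      near_dmr = near)
    }
  }
  if (cfg$n_background_peaks > 0) {
    k <- cfg$n_background_peaks
    ch <- sample(chroms, k, replace = TRUE)
    w <- as.integer(round(runif(k, cfg$peak_width_range[1L],
                                cfg$peak_width_range[2L])))
    s <- as.integer(round(runif(k, 1, L - max(w) - 1)))
    peak_rows$background <- data.frame(chrom = ch, start = s, end = s + w - 1L,
                                       score = round(runif(k,
                                                           cfg$peak_score_range[1L],
                                                           cfg$peak_score_range[2L]), 1),
                                       near_dmr = NA_integer_)
  }
  if (length(peak_rows)) {
    peak_truth <- do.call(rbind, peak_rows)
    peak_truth <- peak_truth[order_sites(peak_truth$chrom, peak_truth$start), ]
    rownames(peak_truth) <- NULL
  }

  ## per-sample stranded counts
  ids <- c(sprintf("ctrl_%d", seq_len(cfg$n_control)),
           sprintf("trt_%d", seq_len(cfg$n_treated)))
  grp <- rep(c("control", "treated"), c(cfg$n_control, cfg$n_treated))
  methylomes <- vector("list", length(ids))
  names(methylomes) <- ids
  for (j in seq_along(ids)) {
    mu <- if (grp[j] == "control") rate_control else rate_treated
    p <- if (cfg$phi > 0) rbeta_mean(ns, mu, cfg$phi) else mu
    cov_p <- rnbinom(ns, size = cfg$coverage_size / 2, mu = cfg$coverage_mean / 2)
    cov_m <- rnbinom(ns, size = cfg$coverage_size / 2, mu = cfg$coverage_mean / 2)
    meth_p <- rbinom(ns, cov_p, p)
    meth_m <- rbinom(ns, cov_m, p)
    calls <- data.frame(
      chrom = rep(sites$chrom, 2L),
      pos = c(sites$pos, sites$pos + 1L),
      strand = rep(c("+", "-"), each = ns),
      n_meth = c(meth_p, meth_m),
      n_unmeth = c(cov_p - meth_p, cov_m - meth_m))
    methylomes[[j]] <- methylome(calls, ids[j], grp[j])
  }

  truth <- structure(list(dmrs = dmr_truth, dmcs = dmc_truth,
                          peaks = peak_truth,
                          rates = data.frame(chrom = sites$chrom,
                                             pos = sites$pos,
                                             rate_control = rate_control,
                                             rate_treated = rate_treated)),
                     class = "synthetic_truth")

  out <- list(methylomes = methylomes, tss = tss, promoters = promoters,
              peaks = peak_truth, truth = truth, config = cfg, files = NULL)
  if (!is.null(dir)) out$files <- write_simulation(out, dir)
  out
}

# which sites (rows of `sites`) fall in >= 1 promoter / which promoter
promoter_hits <- function(sites, promoters) {
  if (!nrow(sites) || !nrow(promoters)) return(integer(0))
  sgr <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L))
  pgr <- GRanges(promoters$chrom, IRanges(promoters$start, promoters$end))
  sort(unique(queryHits(findOverlaps(sgr, pgr))))
}

promoter_of <- function(sites, promoters) {
  if (!nrow(sites)) return(integer(0))
  sgr <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L))
  pgr <- GRanges(promoters$chrom, IRanges(promoters$start, promoters$end))
  ov <- findOverlaps(sgr, pgr, select = "first")
  as.integer(ov)
}

# write every artefact of a simulation to `dir`; returns named paths
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  sheet <- data.frame(path = character(), sample_id = character(),
                      group = character())
  for (id in names(sim$methylomes)) {
    p <- file.path(dir, paste0(id, ".CpG_report.txt"))
    write_cpg_report(sim$methylomes[[id]], p)
    sheet <- rbind(sheet, data.frame(path = p, sample_id = id,
                                     group = attr(sim$methylomes[[id]], "group")))
  }
  files$sample_sheet <- file.path(dir, "samples.tsv")
  write_result_table(sheet, files$sample_sheet)
  files$tss <- file.path(dir, "tss.bed")
  tssbed <- data.table(chrom = sim$tss$chrom,
                       start = ifelse(sim$tss$strand == "+",
                                      sim$tss$tss - 1L, sim$tss$tss - 1L),
                       end = ifelse(sim$tss$strand == "+",
                                    sim$tss$tss, sim$tss$tss),
                       name = sim$tss$gene_id, score = 0L,
                       strand = sim$tss$strand)
  fwrite(tssbed, files$tss, sep = "\t", col.names = FALSE, quote = FALSE)
  files$peaks <- file.path(dir, "peaks.bed")
  if (!is.null(sim$peaks)) {
    write_bed(sim$peaks, files$peaks, name = "peak", score = sim$peaks$score)
  } else file.create(files$peaks)
  files$truth_dmrs <- file.path(dir, "truth_dmrs.tsv")
  write_result_table(if (is.null(sim$truth$dmrs))
    data.frame(chrom = character(), start = integer(), end = integer(),
               direction = character(), delta = numeric(), n_cpgs = integer())
    else sim$truth$dmrs, files$truth_dmrs)
  files$truth_dmcs <- file.path(dir, "truth_dmcs.tsv")
  write_result_table(if (is.null(sim$truth$dmcs))
    data.frame(chrom = character(), pos = integer(), gene_id = character(),
               delta = numeric(), direction = character())
    else sim$truth$dmcs, files$truth_dmcs)
  files$truth_rates <- file.path(dir, "truth_rates.tsv")
  write_result_table(sim$truth$rates, files$truth_rates)
  files
}

#' Score pipeline output against planted truth
#'
#' Sensitivity is the fraction of planted DMRs overlapped (>= 1 bp, same
#' chromosome) by a called DMR of matching direction; DMC sensitivity is
#' the fraction of planted DMC positions present in the called table
#' with matching direction. False calls are called records overlapping
#' no planted interval at all, counted per direction.
#'
#' @param dmrs a `dmr_table` (may be empty), or NULL to skip.
#' @param dmcs a `dmc_table`, or NULL to skip.
#' @param truth a `synthetic_truth` from [simulate_wgbs()].
#' @return `truth_eval` list: `dmr_sensitivity`, `dmc_sensitivity`
#'   (NA when nothing was planted), `false_dmrs` and `false_dmcs`
#'   (named per-direction counts), `n_planted_dmrs`, `n_planted_dmcs`.
#' @export
truth_eval <- function(dmrs = NULL, dmcs = NULL, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  res <- list(dmr_sensitivity = NA_real_, dmc_sensitivity = NA_real_,
              false_dmrs = c(hyper = 0L, hypo = 0L),
              false_dmcs = c(hyper = 0L, hypo = 0L),
              n_planted_dmrs = if (is.null(truth$dmrs)) 0L else nrow(truth$dmrs),
              n_planted_dmcs = if (is.null(truth$dmcs)) 0L else nrow(truth$dmcs))
  overlaps <- function(a, b)   # data.frames with chrom/start/end
    outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j)
      a$chrom[i] == b$chrom[j] & a$start[i] <= b$end[j] & a$end[i] >= b$start[j])
  if (!is.null(dmrs)) {
    td <- truth$dmrs
    if (!is.null(td) && nrow(td)) {
      if (nrow(dmrs)) {
        ov <- overlaps(td, as.data.frame(dmrs))
        dirmatch <- outer(td$direction, dmrs$direction, `==`)
        res$dmr_sensitivity <- mean(rowSums(ov & dirmatch) > 0)
        fc <- colSums(ov) == 0
        res$false_dmrs <- c(hyper = sum(fc & dmrs$direction == "hyper"),
                            hypo = sum(fc & dmrs$direction == "hypo"))
      } else res$dmr_sensitivity <- 0
    } else if (nrow(dmrs)) {
      res$false_dmrs <- c(hyper = sum(dmrs$direction == "hyper"),
                          hypo = sum(dmrs$direction == "hypo"))
    }
  }
  if (!is.null(dmcs)) {
    tc <- truth$dmcs
    if (!is.null(tc) && nrow(tc)) {
      if (nrow(dmcs)) {
        key <- paste(dmcs$chrom, dmcs$pos, dmcs$direction)
        res$dmc_sensitivity <- mean(paste(tc$chrom, tc$pos, tc$direction) %in% key)
        fp <- !paste(dmcs$chrom, dmcs$pos) %in% paste(tc$chrom, tc$pos)
        res$false_dmcs <- c(hyper = sum(fp & dmcs$direction == "hyper"),
                            hypo = sum(fp & dmcs$direction == "hypo"))
      } else res$dmc_sensitivity <- 0
    } else if (nrow(dmcs)) {
      res$false_dmcs <- c(hyper = sum(dmcs$direction == "hyper"),
                          hypo = sum(dmcs$direction == "hypo"))
    }
  }
  structure(res, class = "truth_eval")
}

#' @export
print.truth_eval <- function(x, ...) {
  cat(sprintf(paste0("truth_eval: DMR sensitivity %s (%d planted), ",
                     "DMC sensitivity %s (%d planted)\n"),
              format(x$dmr_sensitivity), x$n_planted_dmrs,
              format(x$dmc_sensitivity), x$n_planted_dmcs))
  cat(sprintf("false DMRs hyper/hypo: %d/%d; false DMCs: %d/%d\n",
              x$false_dmrs["hyper"], x$false_dmrs["hypo"],
              x$false_dmcs["hyper"], x$false_dmcs["hypo"]))
  invisible(x)
}
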