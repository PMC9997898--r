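# Brute-force reference implementations and small fixture builders.
# The oracles deliberately share no code with the package internals:
# exhaustive loops over index ranges and all-pairs interval checks.

# Exhaustive window oracle: every contiguous index range satisfying the
# three criteria, reduced to ranges not contained in a qualifying range.
bf_windows <- function(pos, diff, min_cpgs = 10, max_span = 300,
                       diff_threshold = 0.20) {
  n <- length(pos)
  qual <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 < min_cpgs) next
      if (pos[j] - pos[i] + 1 > max_span) break
      if (abs(mean(diff[i:j])) >= diff_threshold)
        qual[[length(qual) + 1L]] <- c(i, j)
    }
  }
  if (!length(qual)) return(data.frame(first = integer(), last = integer()))
  q <- do.call(rbind, qual)
  contained <- vapply(seq_len(nrow(q)), function(k)
    any(q[, 1] <= q[k, 1] & q[, 2] >= q[k, 2] &
          (q[, 1] != q[k, 1] | q[, 2] != q[k, 2])), logical(1))
  q <- q[!contained, , drop = FALSE]
  q <- q[order(q[, 1], q[, 2]), , drop = FALSE]
  data.frame(first = q[, 1], last = q[, 2])
}

# All-pairs promoter containment oracle.
bf_promoter_sites <- function(sites, promoters) {
  hit <- vapply(seq_len(nrow(sites)), function(i)
    any(promoters$chrom == sites$chrom[i] &
          promoters$start <= sites$pos[i] &
          promoters$end >= sites$pos[i]), logical(1))
  which(hit)
}

# All-pairs flanked-overlap oracle (1-based inclusive intervals).
bf_proximity <- function(dmrs, peaks, flank = 1000) {
  vapply(seq_len(nrow(dmrs)), function(i)
    sum(peaks$chrom == dmrs$chrom[i] &
          peaks$start <= dmrs$end[i] + flank &
          peaks$end >= dmrs$start[i] - flank), integer(1))
}

# Build a cpg_matrix directly from a rate specification (one chromosome
# unless `chrom` given): rates is a sites x samples matrix.
make_matrix <- function(pos, rates, groups = rep(c("control", "treated"),
                                                 each = ncol(rates) / 2),
                        chrom = "chr1", cov = 50L) {
  rates <- as.matrix(rates)
  ns <- nrow(rates)
  covm <- matrix(as.integer(cov), ns, ncol(rates))
  methm <- matrix(as.integer(round(rates * cov)), ns, ncol(rates))
  samples <- sprintf("s%d", seq_len(ncol(rates)))
  colnames(covm) <- colnames(methm) <- samples
  ord <- order(rep_len(chrom, ns), pos)
  structure(list(sites = data.frame(chrom = rep_len(chrom, ns)[ord],
                                    pos = as.integer(pos)[ord]),
                 cov = covm[ord, , drop = FALSE],
                 meth = methm[ord, , drop = FALSE],
                 rate = (methm / covm)[ord, , drop = FALSE],
                 samples = samples, groups = groups, min_cov = 1),
            class = "cpg_matrix")
}

# A matrix with explicit per-site group diffs (control rate 0.4).
make_diff_matrix <- function(pos, diff, chrom = "chr1") {
  base <- 0.4
  rates <- cbind(base, base, base, base + diff, base + diff, base + diff)
  make_matrix(pos, rates, chrom = chrom, cov = 1000L)
}

# Small stranded methylome from vectors.
make_methylome <- function(chrom, pos, strand, n_meth, n_unmeth,
                           sample_id = "s1", group = "control") {
  methylome(data.frame(chrom = chrom, pos = pos, strand = strand,
                       n_meth = n_meth, n_unmeth = n_unmeth),
            sample_id, group)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
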