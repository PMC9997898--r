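# Promoter construction from TSS records, assignment of unified CpG
# sites to promoters, and DMR-to-peak proximity. Interval overlap is
# delegated to GenomicRanges; brute-force equivalents back the tests.

#' Build strand-aware promoter intervals
#'
#' A promoter is the `upstream` bases immediately 5' of the TSS,
#' excluding the TSS base itself: for a "+" gene at t it is
#' `[t - upstream, t - 1]`, for a "-" gene `[t + 1, t + upstream]`,
#' clipped at position 1.
#'
#' @param tss data.frame from [read_tss_table()] (chrom, tss, strand,
#'   gene_id).
#' @param upstream promoter length in bp (default 2000).
#' @return data.frame with chrom, start, end (1-based inclusive),
#'   strand, gene_id. Overlapping promoters are kept separate.
#' @export
build_promoters <- function(tss, upstream = 2000) {
  stopifnot(is.data.frame(tss), upstream >= 1)
  if (!all(tss$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  plus <- tss$strand == "+"
  start <- ifelse(plus, tss$tss - as.integer(upstream), tss$tss + 1L)
  end <- ifelse(plus, tss$tss - 1L, tss$tss + as.integer(upstream))
  start <- pmax(start, 1L)
  keep <- start <= end   # a "+" TSS at position 1 has no upstream left
  data.frame(chrom = tss$chrom[keep], start = as.integer(start[keep]),
             end = as.integer(end[keep]), strand = tss$strand[keep],
             gene_id = tss$gene_id[keep])
}

#' Assign unified CpG sites to promoters
#'
#' @param mat a [unify()] matrix.
#' @param promoters data.frame from [build_promoters()].
#' @return data.frame with one row per unique site falling in at least
#'   one promoter: site_idx (row in `mat$sites`), chrom, pos, and
#'   gene_ids (all containing promoters' genes, ";"-collapsed). Ends
#'   are inclusive; a site at the promoter end belongs, one past it
#'   does not. Result is independent of promoter input order.
#' @export
promoter_sites <- function(mat, promoters) {
  stopifnot(inherits(mat, "cpg_matrix"), is.data.frame(promoters))
  empty <- data.frame(site_idx = integer(), chrom = character(),
                      pos = integer(), gene_ids = character())
  if (!nrow(mat$sites) || !nrow(promoters)) return(empty)
  sgr <- GRanges(mat$sites$chrom, IRanges(mat$sites$pos, width = 1L))
  pgr <- GRanges(promoters$chrom, IRanges(promoters$start, promoters$end))
  ov <- findOverlaps(sgr, pgr)
  if (!length(ov)) return(empty)
  qh <- queryHits(ov); sh <- subjectHits(ov)
  o <- order(qh, promoters$gene_id[sh])
  qh <- qh[o]; sh <- sh[o]
  genes <- vapply(split(promoters$gene_id[sh], qh),
                  function(g) paste(unique(g), collapse = ";"), character(1))
  idx <- as.integer(names(genes))
  ord <- order(idx)
  idx <- idx[ord]
  data.frame(site_idx = idx, chrom = mat$sites$chrom[idx],
             pos = mat$sites$pos[idx], gene_ids = unname(genes[ord]))
}

#' DMR-to-peak proximity within a flank
#'
#' A DMR `[s, e]` is proximal to a peak when the peak interval overlaps
#' the flanked interval `[s - flank, e + flank]` by at least one base
#' (with `flank = 0` this is plain overlap). Peaks are expected already
#' score-filtered by [read_peaks()].
#'
#' @param dmrs a `dmr_table` (or any data.frame with chrom, start, end,
#'   and optionally direction), 1-based inclusive.
#' @param peaks a `peak_set` from [read_peaks()].
#' @param flank vicinity in bp on each side (default 1000).
#' @return `proximity_report`: list with `per_dmr` (one row per DMR:
#'   chrom, start, end, direction, n_proximal_peaks,
#'   nearest_peak_distance — 0 when overlapping, NA when the
#'   chromosome has no peak), `pairs` (dmr_idx, peak_idx for every
#'   proximal pair), and `summary` (n_dmrs, n_proximal, fraction).
#' @export
peak_proximity <- function(dmrs, peaks, flank = 1000) {
  stopifnot(is.data.frame(dmrs), is.data.frame(peaks), flank >= 0)
  n <- nrow(dmrs)
  direction <- if ("direction" %in% names(dmrs)) dmrs$direction
               else rep(NA_character_, n)
  per <- data.frame(chrom = as.character(dmrs$chrom), start = dmrs$start,
                    end = dmrs$end, direction = direction,
                    n_proximal_peaks = integer(n),
                    nearest_peak_distance = rep(NA_integer_, n))
  pairs <- data.frame(dmr_idx = integer(), peak_idx = integer())
  if (n && nrow(peaks)) {
    dgr <- GRanges(dmrs$chrom,
                   IRanges(pmax(dmrs$start - as.integer(flank), 1L),
                           dmrs$end + as.integer(flank)))
    pgr <- GRanges(peaks$chrom, IRanges(peaks$start, peaks$end))
    ov <- findOverlaps(dgr, pgr)
    if (length(ov)) {
      cnt <- table(factor(queryHits(ov), levels = seq_len(n)))
      per$n_proximal_peaks <- as.integer(cnt)
      pairs <- data.frame(dmr_idx = queryHits(ov), peak_idx = subjectHits(ov))
      pairs <- pairs[order(pairs$dmr_idx, pairs$peak_idx), , drop = FALSE]
      rownames(pairs) <- NULL
    }
    # nearest distance from the *unflanked* DMR to any same-chromosome peak
    ugr <- GRanges(dmrs$chrom, IRanges(dmrs$start, dmrs$end))
    near <- GenomicRanges::distanceToNearest(ugr, pgr)
    per$nearest_peak_distance[queryHits(near)] <-
      as.integer(S4Vectors::mcols(near)$distance)
  }
  structure(list(per_dmr = per, pairs = pairs,
                 summary = list(n_dmrs = n,
                                n_proximal = sum(per$n_proximal_peaks > 0L),
                                fraction = if (n) sum(per$n_proximal_peaks > 0L) / n
                                           else NA_real_)),
            class = "proximity_report")
}

#' @export
print.proximity_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("proximity_report: %d/%d DMRs with >= 1 proximal peak (%.1f%%)\n",
              s$n_proximal, s$n_dmrs,
              if (is.na(s$fraction)) NA else 100 * s$fraction))
  invisible(x)
}

#' Write promoter intervals as BED
#' @param promoters data.frame from [build_promoters()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_promoter_bed <- function(promoters, path) {
  if (!nrow(promoters)) {
    file.create(path)
    return(invisible(path))
  }
  dt <- data.table(chrom = promoters$chrom,
                   start = to_bed_start(promoters$start),
                   end = as.integer(promoters$end),
                   name = promoters$gene_id, score = 0L,
                   strand = promoters$strand)
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a proximity report as TSV
#' @param report a `proximity_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_proximity_table <- function(report, path) {
  stopifnot(inherits(report, "proximity_report"))
  write_result_table(report$per_dmr, path)
}
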