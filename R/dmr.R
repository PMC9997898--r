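# Windowed DMR extraction: maximal contiguous runs of unified CpGs with
# >= min_cpgs sites inside max_span bp and |average group difference|
# >= diff_threshold, then same-direction overlap merging.

#' Enumerate maximal qualifying DMR windows
#'
#' Scans each chromosome's sorted unified sites for contiguous runs of
#' at least `min_cpgs` CpGs whose genomic span (last - first + 1) is at
#' most `max_span` bp and whose mean signed per-site rate difference
#' (treated - control) is at least `diff_threshold` in absolute value.
#' Every qualifying run not contained in a larger qualifying run is
#' emitted.
#'
#' @param mat a [unify()] matrix.
#' @param min_cpgs minimum member CpGs (default 10).
#' @param max_span maximum span in bp, 1-based inclusive (default 300).
#' @param diff_threshold minimum |mean difference| (default 0.20).
#' @param control control group label.
#' @return data.frame with chrom, start, end (positions of the first and
#'   last member CpG), first_idx, last_idx (row indices into
#'   `mat$sites`), n_cpgs, mean_diff, direction.
#' @export
enumerate_windows <- function(mat, min_cpgs = 10, max_span = 300,
                              diff_threshold = 0.20, control = NULL) {
  stopifnot(inherits(mat, "cpg_matrix"), min_cpgs >= 2, max_span >= 1)
  gm <- group_means(mat, control)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      first_idx = integer(), last_idx = integer(),
                      n_cpgs = integer(), mean_diff = numeric(),
                      direction = character())
  if (!nrow(gm)) return(empty)
  res <- list()
  for (ch in unique(gm$chrom)) {
    rows <- which(gm$chrom == ch)
    pos <- gm$pos[rows]
    d <- gm$diff[rows]
    n <- length(pos)
    if (n < min_cpgs) next
    cs <- c(0, cumsum(d))
    # for each start i, the largest j with span <= max_span
    jmax <- findInterval(pos + max_span - 1L, pos)
    cand_i <- integer(0); cand_j <- integer(0); cand_m <- numeric(0)
    for (i in seq_len(n - min_cpgs + 1L)) {
      hi <- jmax[i]
      lo <- i + min_cpgs - 1L
      if (hi < lo) next
      js <- lo:hi
      mu <- (cs[js + 1L] - cs[i]) / (js - i + 1L)
      ok <- abs(mu) >= diff_threshold
      if (any(ok)) {
        cand_i <- c(cand_i, rep.int(i, sum(ok)))
        cand_j <- c(cand_j, js[ok])
        cand_m <- c(cand_m, mu[ok])
      }
    }
    if (!length(cand_i)) next
    # keep maximal ranges: drop [i,j] contained in another qualifying range
    o <- order(cand_i, -cand_j)
    keep <- logical(length(o)); best_j <- -1L
    for (k in o) {
      if (cand_j[k] > best_j) {
        keep[k] <- TRUE
        best_j <- cand_j[k]
      }
    }
    res[[ch]] <- data.frame(chrom = ch,
                            start = pos[cand_i[keep]],
                            end = pos[cand_j[keep]],
                            first_idx = rows[cand_i[keep]],
                            last_idx = rows[cand_j[keep]],
                            n_cpgs = cand_j[keep] - cand_i[keep] + 1L,
                            mean_diff = cand_m[keep],
                            direction = ifelse(cand_m[keep] > 0,
                                               "hyper", "hypo"))
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res[order(names(res))])
  rownames(out) <- NULL
  out
}

#' Merge overlapping same-direction windows into DMRs
#'
#' Qualifying windows of the same direction whose genomic spans share at
#' least one base are joined into connected components; each component
#' is reported once with its statistics recomputed over the union of
#' member sites. Windows of opposite direction never merge, and windows
#' separated by any gap stay separate.
#'
#' @param windows output of [enumerate_windows()].
#' @param mat the same matrix the windows were derived from (needed to
#'   recompute per-region means over the merged site span).
#' @param control control group label.
#' @return `dmr_table`: data.frame with chrom, start, end, n_cpgs,
#'   mean_diff, direction.
#' @export
merge_windows <- function(windows, mat, control = NULL) {
  stopifnot(inherits(mat, "cpg_matrix"))
  empty <- structure(
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_cpgs = integer(), mean_diff = numeric(),
               direction = character()),
    class = c("dmr_table", "data.frame"))
  if (!nrow(windows)) return(empty)
  gm <- group_means(mat, control)
  parts <- split(windows, paste(windows$chrom, windows$direction))
  out <- lapply(parts, function(w) {
    w <- w[order(w$start, w$end), , drop = FALSE]
    grp <- cumsum(c(TRUE, w$start[-1L] > cummax(w$end)[-nrow(w)]))
    mrg <- lapply(split(seq_len(nrow(w)), grp), function(ii) {
      fi <- min(w$first_idx[ii]); li <- max(w$last_idx[ii])
      md <- mean(gm$diff[fi:li])
      data.frame(chrom = w$chrom[1L], start = min(w$start[ii]),
                 end = max(w$end[ii]), n_cpgs = li - fi + 1L,
                 mean_diff = md,
                 direction = w$direction[1L])
    })
    do.call(rbind, mrg)
  })
  out <- do.call(rbind, out)
  out <- out[order_sites(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("dmr_table", "data.frame"))
}

#' Call DMRs from a unified matrix
#'
#' Convenience wrapper: [enumerate_windows()] then [merge_windows()].
#'
#' @inheritParams enumerate_windows
#' @return a `dmr_table` (see [merge_windows()]).
#' @export
call_dmrs <- function(mat, min_cpgs = 10, max_span = 300,
                      diff_threshold = 0.20, control = NULL) {
  w <- enumerate_windows(mat, min_cpgs = min_cpgs, max_span = max_span,
                         diff_threshold = diff_threshold, control = control)
  merge_windows(w, mat, control = control)
}

#' @export
print.dmr_table <- function(x, ...) {
  cat(sprintf("dmr_table: %d DMRs (%d hyper / %d hypo)\n", nrow(x),
              sum(x$direction == "hyper"), sum(x$direction == "hypo")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Write DMRs as BED
#'
#' 0-based half-open intervals with `name` = direction and `score` =
#' `round(|mean_diff| * 1000)`.
#'
#' @param dmrs a `dmr_table`.
#' @param path output BED path; an empty table writes an empty file.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  write_bed(dmrs, path, name = dmrs$direction,
            score = as.integer(round(abs(dmrs$mean_diff) * 1000)))
}

#' Read a DMR BED written by [write_dmr_bed()]
#'
#' @param path BED path.
#' @return data.frame with chrom, start, end (1-based inclusive),
#'   direction, score.
#' @export
read_dmr_bed <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), direction = character(),
                      score = integer()))
  dt <- fread(path, header = FALSE, sep = "\t", data.table = TRUE,
              showProgress = FALSE)
  iv <- from_bed(dt[[2L]], dt[[3L]])
  data.frame(chrom = as.character(dt[[1L]]), start = iv$start, end = iv$end,
             direction = as.character(dt[[4L]]), score = as.integer(dt[[5L]]))
}
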