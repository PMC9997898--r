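# Readers and writers for the on-disk formats: Bismark-style cytosine
# reports, TSS tables (BED6 or 4-column TSV), scored peak BEDs, and the
# package's own result tables. Point coordinates are 1-based inclusive
# internally; all BED I/O is 0-based half-open.

#' Construct a per-sample methylome
#'
#' A `methylome` is a data.frame of per-cytosine calls (`chrom`, `pos`,
#' `strand`, `n_meth`, `n_unmeth`) sorted by chromosome and position,
#' carrying the sample id and group label as attributes.
#'
#' @param calls data.frame with columns chrom, pos, strand, n_meth, n_unmeth.
#' @param sample_id single string identifying the sample.
#' @param group single string, the sample's group label (e.g. "control").
#' @param destranded logical; TRUE once CpG dyads have been merged.
#' @return object of class `methylome`.
#' @export
methylome <- function(calls, sample_id, group, destranded = FALSE) {
  stopifnot(is.data.frame(calls), length(sample_id) == 1L, length(group) == 1L)
  need <- c("chrom", "pos", "strand", "n_meth", "n_unmeth")
  if (!all(need %in% names(calls)))
    stopf("methylome calls need columns: %s", paste(need, collapse = ", "))
  calls <- as.data.frame(calls)[need]
  if (nrow(calls)) {
    if (any(calls$pos < 1L)) stopf("positions must be >= 1")
    if (any(calls$n_meth < 0L) || any(calls$n_unmeth < 0L))
      stopf("read counts must be non-negative")
    if (!all(calls$strand %in% c("+", "-")))
      stopf("strand must be '+' or '-'")
    calls <- calls[order_sites(calls$chrom, calls$pos), , drop = FALSE]
    rownames(calls) <- NULL
  }
  structure(calls,
            sample_id = as.character(sample_id),
            group = as.character(group),
            destranded = isTRUE(destranded),
            class = c("methylome", "data.frame"))
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf("methylome '%s' (group %s): %d calls on %d chromosome(s)%s\n",
              attr(x, "sample_id"), attr(x, "group"), nrow(x),
              length(unique(x$chrom)),
              if (attr(x, "destranded")) ", destranded" else ""))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Read a per-cytosine bisulfite call report
#'
#' Parses the tab-separated per-CpG output of a bisulfite caller. Two
#' dialects are supported: `"cytosine"` (chrom, 1-based position, strand,
#' methylated count, unmethylated count, then optional context columns,
#' which are ignored) and `"coverage"` (chrom, start, end, methylation
#' percentage, methylated count, unmethylated count; strand is recorded
#' as "+").
#'
#' @param path file path; an empty file yields an empty methylome.
#' @param sample_id sample identifier stored on the result.
#' @param group group label stored on the result.
#' @param format `"cytosine"` (default) or `"coverage"`.
#' @return a [methylome()].
#' @export
read_cpg_report <- function(path, sample_id, group,
                            format = c("cytosine", "coverage")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  empty <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), n_meth = integer(),
                      n_unmeth = integer())
  if (file.size(path) == 0L)
    return(methylome(empty, sample_id, group))
  min_cols <- if (format == "cytosine") 5L else 6L
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = "character",
              fill = TRUE, data.table = TRUE, showProgress = FALSE)
  if (ncol(dt) < min_cols)
    stopf("%s: expected >= %d tab-separated columns, found %d",
          path, min_cols, ncol(dt))
  check_int <- function(x, what) {
    bad <- which(!grepl("^[0-9]+$", x))
    if (length(bad))
      stopf("%s: malformed %s '%s' at line %d", path, what, x[bad[1L]], bad[1L])
    as.integer(x)
  }
  if (format == "cytosine") {
    strand <- dt[[3L]]
    bad <- which(!strand %in% c("+", "-"))
    if (length(bad))
      stopf("%s: bad strand '%s' at line %d", path, strand[bad[1L]], bad[1L])
    calls <- data.frame(
      chrom = dt[[1L]],
      pos = check_int(dt[[2L]], "position"),
      strand = strand,
      n_meth = check_int(dt[[4L]], "methylated count"),
      n_unmeth = check_int(dt[[5L]], "unmethylated count"))
  } else {
    calls <- data.frame(
      chrom = dt[[1L]],
      pos = check_int(dt[[2L]], "position"),
      strand = "+",
      n_meth = check_int(dt[[5L]], "methylated count"),
      n_unmeth = check_int(dt[[6L]], "unmethylated count"))
  }
  bad <- which(calls$pos < 1L)
  if (length(bad)) stopf("%s: position < 1 at line %d", path, bad[1L])
  methylome(calls, sample_id, group)
}

#' Write a methylome as a cytosine report
#'
#' Emits the 7-column tab-separated dialect (chrom, pos, strand,
#' methylated count, unmethylated count, context, trinucleotide) that
#' [read_cpg_report()] parses, closing the round trip.
#'
#' @param x a [methylome()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cpg_report <- function(x, path) {
  stopifnot(inherits(x, "methylome"))
  dt <- data.table(chrom = x$chrom, pos = x$pos, strand = x$strand,
                   n_meth = x$n_meth, n_unmeth = x$n_unmeth,
                   context = "CG", tri = "CGN")
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Accepts BED6 (`chrom start end name score strand`; the TSS is `start`
#' converted to 1-based for "+" genes and `end` for "-" genes) or a
#' 4-column TSV (`chrom tss_1based strand gene_id`). The dialect is
#' auto-detected from the column count and can be forced.
#'
#' @param path file path.
#' @param format `"auto"` (default), `"bed"`, or `"tsv"`.
#' @return data.frame with columns chrom, tss, strand, gene_id.
#' @export
read_tss_table <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = "character",
              fill = TRUE, data.table = TRUE, showProgress = FALSE)
  if (format == "auto") format <- if (ncol(dt) >= 6L) "bed" else "tsv"
  if (format == "bed") {
    if (ncol(dt) < 6L) stopf("%s: BED6 needs 6 columns, found %d", path, ncol(dt))
    strand <- dt[[6L]]
    tss <- ifelse(strand == "+", as.integer(dt[[2L]]) + 1L, as.integer(dt[[3L]]))
    out <- data.frame(chrom = dt[[1L]], tss = tss, strand = strand,
                      gene_id = dt[[4L]])
  } else {
    if (ncol(dt) < 4L) stopf("%s: TSS TSV needs 4 columns, found %d", path, ncol(dt))
    out <- data.frame(chrom = dt[[1L]], tss = as.integer(dt[[2L]]),
                      strand = dt[[3L]], gene_id = dt[[4L]])
  }
  bad <- which(!out$strand %in% c("+", "-"))
  if (length(bad))
    stopf("%s: unknown strand '%s' at line %d", path, out$strand[bad[1L]], bad[1L])
  if (anyNA(out$tss) || any(out$tss < 1L)) stopf("%s: invalid TSS position", path)
  out
}

#' Read a scored peak BED and filter by score
#'
#' Reads a BED file whose fifth column is a numeric significance score
#' (as exported from ChIP peak browsers) and keeps peaks with
#' `score >= min_score`. The default threshold of 50 matches the usual
#' "significant peak" cutoff on the -10*log10(q) score scale.
#'
#' @param path BED file path (0-based half-open intervals).
#' @param min_score minimum score to retain (default 50).
#' @return `peak_set`: data.frame with chrom, start, end (1-based
#'   inclusive), score; the number retained is reported via `message()`.
#' @export
read_peaks <- function(path, min_score = 50) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (file.size(path) == 0L) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), score = numeric())
    class(out) <- c("peak_set", "data.frame")
    return(out)
  }
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = "character",
              fill = TRUE, data.table = TRUE, showProgress = FALSE)
  if (ncol(dt) < 5L) stopf("%s: scored BED needs 5 columns, found %d", path, ncol(dt))
  score <- suppressWarnings(as.numeric(dt[[5L]]))
  bad <- which(is.na(score))
  if (length(bad))
    stopf("%s: non-numeric score '%s' at line %d", path, dt[[5L]][bad[1L]], bad[1L])
  iv <- from_bed(dt[[2L]], dt[[3L]])
  out <- data.frame(chrom = dt[[1L]], start = iv$start, end = iv$end,
                    score = score)
  if (any(out$start > out$end)) stopf("%s: empty or inverted interval", path)
  keep <- out$score >= min_score
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("read_peaks: retained %d of %d peaks at score >= %s",
                  nrow(out), length(keep), format(min_score)))
  class(out) <- c("peak_set", "data.frame")
  out
}

# Generic BED writer for internal 1-based inclusive intervals.
write_bed <- function(df, path, name = ".", score = 0L) {
  if (!nrow(df)) {
    file.create(path)
    return(invisible(path))
  }
  dt <- data.table(chrom = df$chrom, start = to_bed_start(df$start),
                   end = as.integer(df$end), name = name, score = score)
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Plain tab-separated export with a header row; used for DMC, DMR,
#' proximity, site-class and PCA tables.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path) {
  fwrite(as.data.table(as.data.frame(df)), path, sep = "\t", quote = FALSE,
         na = "NA")
  invisible(path)
}
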