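# CpG dyad destranding, all-sample site unification, and the unified
# site-by-sample matrix that every downstream caller consumes.

#' Merge CpG dyads onto the plus-strand cytosine
#'
#' CpG methylation is symmetric: the cytosines at position p (+ strand)
#' and p+1 (- strand) report the same dyad. Destranding remaps each
#' minus-strand call at p to p-1 and sums its read counts with any
#' plus-strand call there, increasing effective coverage. Total
#' methylated and unmethylated counts are conserved.
#'
#' @param x a [methylome()].
#' @return a plus-strand-only `methylome` with `destranded = TRUE`.
#' @export
destrand <- function(x) {
  stopifnot(inherits(x, "methylome"))
  if (!nrow(x)) return(methylome(as.data.frame(x), attr(x, "sample_id"),
                                 attr(x, "group"), destranded = TRUE))
  dt <- data.table(chrom = x$chrom,
                   pos = ifelse(x$strand == "-", x$pos - 1L, x$pos),
                   n_meth = x$n_meth, n_unmeth = x$n_unmeth)
  if (any(dt$pos < 1L))
    stopf("minus-strand call at position 1 cannot be remapped")
  dt <- dt[, list(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)),
           by = list(chrom, pos)]
  calls <- data.frame(chrom = dt$chrom, pos = dt$pos, strand = "+",
                      n_meth = dt$n_meth, n_unmeth = dt$n_unmeth)
  methylome(calls, attr(x, "sample_id"), attr(x, "group"), destranded = TRUE)
}

#' Unify methylomes into a site-by-sample matrix
#'
#' Retains exactly the CpG sites with coverage (methylated plus
#' unmethylated reads) of at least `min_cov` in every sample — the
#' "data existed in all samples" rule — and computes per-site,
#' per-sample methylation rates. No imputation is performed.
#'
#' @param methylomes list of [methylome()] objects (>= 2), normally
#'   destranded; sample ids must be unique.
#' @param min_cov minimum per-sample coverage for a site to be kept
#'   (default 10).
#' @return object of class `cpg_matrix`: a list with `sites`
#'   (data.frame chrom, pos, sorted), `cov` and `meth` integer matrices
#'   (sites x samples), `rate` numeric matrix, `samples`, `groups`, and
#'   `min_cov`.
#' @export
unify <- function(methylomes, min_cov = 10) {
  stopifnot(is.list(methylomes), length(methylomes) >= 2L, min_cov >= 1)
  ids <- vapply(methylomes, function(m) attr(m, "sample_id"), character(1))
  if (anyDuplicated(ids)) stopf("duplicate sample ids: %s",
                                paste(ids[duplicated(ids)], collapse = ", "))
  groups <- vapply(methylomes, function(m) attr(m, "group"), character(1))
  tabs <- lapply(seq_along(methylomes), function(i) {
    m <- methylomes[[i]]
    data.table(chrom = m$chrom, pos = m$pos,
               cov = m$n_meth + m$n_unmeth, meth = m$n_meth, s = i)
  })
  long <- data.table::rbindlist(tabs)
  long <- long[long$cov >= min_cov]
  n <- length(methylomes)
  counts <- long[, list(k = .N), by = list(chrom, pos)]
  keep <- counts[counts$k == n, c("chrom", "pos")]
  data.table::setorder(keep, chrom, pos)
  if (!nrow(keep))
    warnf("unify: no site passed coverage >= %s in all %d samples", min_cov, n)
  sites <- data.frame(chrom = keep$chrom, pos = keep$pos)
  covm <- matrix(0L, nrow(sites), n, dimnames = list(NULL, ids))
  methm <- covm
  if (nrow(sites)) {
    key <- paste(sites$chrom, sites$pos)
    long <- long[paste(long$chrom, long$pos) %in% key]
    idx <- match(paste(long$chrom, long$pos), key)
    covm[cbind(idx, long$s)] <- long$cov
    methm[cbind(idx, long$s)] <- long$meth
  }
  ratem <- methm / ifelse(covm > 0L, covm, NA_integer_)
  structure(list(sites = sites, cov = covm, meth = methm, rate = ratem,
                 samples = ids, groups = groups, min_cov = min_cov),
            class = "cpg_matrix")
}

#' @export
print.cpg_matrix <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf("cpg_matrix: %d sites x %d samples (%s); min_cov = %s\n",
              nrow(x$sites), length(x$samples),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "),
              format(x$min_cov)))
  invisible(x)
}

#' @export
summary.cpg_matrix <- function(object, ...) {
  gl <- resolve_groups(object$groups)
  gm <- group_means(object)
  cat(sprintf(paste0("cpg_matrix: %d sites, %d samples\n",
                     "grand mean rate  %s: %.4f   %s: %.4f\n"),
              nrow(object$sites), length(object$samples),
              gl["control"], mean(object$rate[, object$groups == gl["control"]]),
              gl["treated"], mean(object$rate[, object$groups == gl["treated"]])))
  cat(sprintf("per-site |diff| quartiles: %s\n",
              paste(format(round(stats::quantile(abs(gm$diff),
                                                 c(.25, .5, .75)), 4)),
                    collapse = " / ")))
  invisible(object)
}

#' Per-site group means and signed difference
#'
#' @param mat a [unify()] matrix.
#' @param control control group label; defaults to `"control"` when
#'   present, otherwise the alphabetically first label.
#' @return data.frame with chrom, pos, mean_control, mean_treated and
#'   `diff = mean_treated - mean_control` (in `[-1, 1]`).
#' @export
group_means <- function(mat, control = NULL) {
  stopifnot(inherits(mat, "cpg_matrix"))
  gl <- resolve_groups(mat$groups, control)
  ic <- which(mat$groups == gl["control"])
  it <- which(mat$groups == gl["treated"])
  if (!length(ic) || !length(it)) stopf("both groups must be non-empty")
  mc <- rowMeans(mat$rate[, ic, drop = FALSE])
  mt <- rowMeans(mat$rate[, it, drop = FALSE])
  data.frame(chrom = mat$sites$chrom, pos = mat$sites$pos,
             mean_control = mc, mean_treated = mt, diff = mt - mc)
}

#' Write / read a unified matrix checkpoint
#'
#' The checkpoint is a TSV with one row per site (`chrom`, `pos`, then
#' `cov_<sample>` and `meth_<sample>` column pairs) preceded by a single
#' header comment line recording sample ids, group labels and `min_cov`,
#' so a pipeline stage can resume from disk.
#'
#' @param mat a `cpg_matrix`.
#' @param path TSV path.
#' @return `path` (writer) or the restored `cpg_matrix` (reader).
#' @export
write_cpg_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "cpg_matrix"))
  hdr <- sprintf("#methdmr_matrix\tv1\tmin_cov=%s\t%s", format(mat$min_cov),
                 paste(sprintf("%s=%s", mat$samples, mat$groups),
                       collapse = ";"))
  dt <- data.table(chrom = mat$sites$chrom, pos = mat$sites$pos)
  for (j in seq_along(mat$samples)) {
    dt[[paste0("cov_", mat$samples[j])]] <- mat$cov[, j]
    dt[[paste0("meth_", mat$samples[j])]] <- mat$meth[, j]
  }
  writeLines(hdr, path)
  fwrite(dt, path, sep = "\t", quote = FALSE, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_cpg_matrix
#' @export
read_cpg_matrix <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#methdmr_matrix"))
    stopf("%s is not a methdmr matrix checkpoint", path)
  parts <- strsplit(hdr, "\t", fixed = TRUE)[[1L]]
  min_cov <- as.numeric(sub("min_cov=", "", parts[3L]))
  pairs <- strsplit(strsplit(parts[4L], ";", fixed = TRUE)[[1L]], "=")
  samples <- vapply(pairs, `[`, character(1), 1L)
  groups <- vapply(pairs, `[`, character(1), 2L)
  dt <- fread(path, sep = "\t", skip = 1L, header = TRUE,
              data.table = TRUE, showProgress = FALSE)
  sites <- data.frame(chrom = as.character(dt$chrom), pos = as.integer(dt$pos))
  covm <- as.matrix(dt[, paste0("cov_", samples), with = FALSE])
  methm <- as.matrix(dt[, paste0("meth_", samples), with = FALSE])
  colnames(covm) <- colnames(methm) <- samples
  ratem <- methm / ifelse(covm > 0L, covm, NA_integer_)
  structure(list(sites = sites, cov = covm, meth = methm, rate = ratem,
                 samples = samples, groups = groups, min_cov = min_cov),
            class = "cpg_matrix")
}
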