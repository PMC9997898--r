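# Per-site two-sample t-tests on methylation rates and the promoter DMC
# caller: p < 0.05 AND |treated - control| >= 20 percentage points.

#' Vectorised two-sample t-test on per-site rates
#'
#' Tests, at each site (row), whether mean methylation rate differs
#' between groups. The default is the pooled-variance (Student) test;
#' `var_equal = FALSE` gives Welch with Satterthwaite degrees of
#' freedom. With three replicates per group the pooled test is the
#' calibrated choice when group variances match (as in a two-arm design
#' measured on one platform); Welch at n = 3 is noticeably conservative.
#'
#' Degenerate sites are defined rather than NA: when both groups have
#' zero variance, p = 1 if the group means are equal and p = 0 (i.e.
#' below any threshold) if they are not.
#'
#' @param rates_control,rates_treated numeric matrices (sites x samples)
#'   of rates in `[0, 1]`; vectors are treated as a single site.
#' @param var_equal pool the group variances (default TRUE).
#' @return numeric vector of two-sided p-values, one per site.
#' @export
t_test_site <- function(rates_control, rates_treated, var_equal = TRUE) {
  if (is.null(dim(rates_control))) rates_control <- matrix(rates_control, 1L)
  if (is.null(dim(rates_treated))) rates_treated <- matrix(rates_treated, 1L)
  if (nrow(rates_control) != nrow(rates_treated))
    stopf("site counts differ between groups")
  n1 <- ncol(rates_control); n2 <- ncol(rates_treated)
  if (n1 < 2L || n2 < 2L) stopf("need >= 2 samples per group")
  rng <- range(rates_control, rates_treated)
  if (is.na(rng[1L]) || rng[1L] < 0 || rng[2L] > 1)
    stopf("rates must lie in [0, 1] and be non-missing")
  m1 <- rowMeans(rates_control); m2 <- rowMeans(rates_treated)
  v1 <- apply(rates_control, 1L, var); v2 <- apply(rates_treated, 1L, var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2, length(se))
  } else {
    a <- v1 / n1; b <- v2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  tt <- (m2 - m1) / se
  p <- 2 * pt(-abs(tt), df)
  zero <- se == 0
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  p
}

#' Call differentially methylated cytosines in promoters
#'
#' A site is a DMC when its two-sided t-test p-value is below
#' `p_threshold` and the absolute difference in mean methylation rate
#' between groups is at least `diff_threshold` (default: p < 0.05 and
#' a 20-percentage-point difference). Only sites belonging to a
#' promoter are tested; pass `promoters = NULL` to test every site.
#'
#' @param mat a [unify()] matrix.
#' @param promoters result of [promoter_sites()] (the promoter subset of
#'   `mat`'s sites, with gene annotations), or NULL for all sites.
#' @param p_threshold p-value cutoff, exclusive (default 0.05).
#' @param diff_threshold minimum |rate difference|, inclusive (default 0.20).
#' @param var_equal passed to [t_test_site()].
#' @param fdr also compute Benjamini-Hochberg adjusted p-values over the
#'   tested sites and require `q < p_threshold` (default FALSE: the
#'   classic raw-p workflow).
#' @param control control group label (see [group_means()]).
#' @return `dmc_table`: data.frame with chrom, pos, mean_control,
#'   mean_treated, diff, p_value, direction ("hyper" when treated >
#'   control), and gene_ids (";"-collapsed, NA without annotation),
#'   sorted by (chrom, pos). The number of sites tested is kept in
#'   attribute `n_tested`.
#' @export
call_dmcs <- function(mat, promoters = NULL, p_threshold = 0.05,
                      diff_threshold = 0.20, var_equal = TRUE,
                      fdr = FALSE, control = NULL) {
  stopifnot(inherits(mat, "cpg_matrix"))
  gl <- resolve_groups(mat$groups, control)
  if (is.null(promoters)) {
    idx <- seq_len(nrow(mat$sites))
    genes <- rep(NA_character_, length(idx))
  } else {
    idx <- promoters$site_idx
    genes <- promoters$gene_ids
    if (length(idx) && (min(idx) < 1L || max(idx) > nrow(mat$sites)))
      stopf("promoter site indices out of range for this matrix")
  }
  empty <- data.frame(chrom = character(), pos = integer(),
                      mean_control = numeric(), mean_treated = numeric(),
                      diff = numeric(), p_value = numeric(),
                      direction = character(), gene_ids = character())
  if (!length(idx)) {
    return(structure(empty, n_tested = 0L,
                     class = c("dmc_table", "data.frame")))
  }
  rc <- mat$rate[idx, mat$groups == gl["control"], drop = FALSE]
  rt <- mat$rate[idx, mat$groups == gl["treated"], drop = FALSE]
  p <- t_test_site(rc, rt, var_equal = var_equal)
  if (fdr) p_sel <- stats::p.adjust(p, "BH") else p_sel <- p
  d <- rowMeans(rt) - rowMeans(rc)
  hit <- p_sel < p_threshold & abs(d) >= diff_threshold
  out <- data.frame(chrom = mat$sites$chrom[idx][hit],
                    pos = mat$sites$pos[idx][hit],
                    mean_control = rowMeans(rc)[hit],
                    mean_treated = rowMeans(rt)[hit],
                    diff = d[hit],
                    p_value = p[hit],
                    direction = ifelse(d[hit] > 0, "hyper", "hypo"),
                    gene_ids = genes[hit])
  out <- out[order_sites(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_tested = length(idx),
            class = c("dmc_table", "data.frame"))
}

#' @export
print.dmc_table <- function(x, ...) {
  cat(sprintf("dmc_table: %d DMCs (%d hyper / %d hypo) from %d tested sites\n",
              nrow(x), sum(x$direction == "hyper"),
              sum(x$direction == "hypo"), attr(x, "n_tested")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Write / read a DMC table as TSV
#'
#' The file opens with a `# hyper=<n> hypo=<n> tested=<n>` summary
#' comment (the hyper/hypo split usually quoted next to DMC counts),
#' followed by the header and data rows.
#'
#' @param dmcs a `dmc_table`.
#' @param path TSV path.
#' @return `path` (writer) or the restored `dmc_table` (reader).
#' @export
write_dmc_table <- function(dmcs, path) {
  writeLines(sprintf("# hyper=%d hypo=%d tested=%d",
                     sum(dmcs$direction == "hyper"),
                     sum(dmcs$direction == "hypo"),
                     attr(dmcs, "n_tested")), path)
  fwrite(as.data.table(as.data.frame(dmcs)), path, sep = "\t", quote = FALSE,
         na = "NA", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_dmc_table
#' @export
read_dmc_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  hdr <- readLines(path, n = 1L)
  n_tested <- if (grepl("tested=", hdr))
    as.integer(sub(".*tested=(\\d+).*", "\\1", hdr)) else NA_integer_
  dt <- fread(path, sep = "\t", skip = 1L, header = TRUE,
              showProgress = FALSE,
              colClasses = list(character = c("chrom", "direction",
                                              "gene_ids")))
  out <- as.data.frame(dt)
  structure(out, n_tested = n_tested, class = c("dmc_table", "data.frame"))
}
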