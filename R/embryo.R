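# Low-coverage embryo (morula) comparison: classification bins over the
# CpGs covered in all samples, per-group grand means, and sample PCA.

#' Classify common CpGs by group difference
#'
#' Bins each unified site by its treated-minus-control rate difference,
#' using the strict thresholds of the scatter-plot convention:
#' `hyper20` (diff > 0.20), `hyper10` (0.10 < diff <= 0.20), `hypo10`
#' (diff < -0.10) and `neutral` otherwise. The bins are mutually
#' exclusive and cover every site. Per-group grand means (over all
#' sites and samples) are reported alongside.
#'
#' @param mat a [unify()] matrix built under the all-samples coverage
#'   rule.
#' @param control control group label.
#' @return `site_classes`: list with `classes` (data.frame chrom, pos,
#'   diff, label) and `group_means` (named numeric: control, treated;
#'   NA with a flag when the matrix is empty).
#' @export
classify_sites <- function(mat, control = NULL) {
  stopifnot(inherits(mat, "cpg_matrix"))
  gl <- resolve_groups(mat$groups, control)
  if (!nrow(mat$sites)) {
    return(structure(list(classes = data.frame(chrom = character(),
                                               pos = integer(),
                                               diff = numeric(),
                                               label = character()),
                          group_means = c(control = NA_real_,
                                          treated = NA_real_),
                          empty = TRUE),
                     class = "site_classes"))
  }
  gm <- group_means(mat, control)
  label <- ifelse(gm$diff > 0.20, "hyper20",
           ifelse(gm$diff > 0.10, "hyper10",
           ifelse(gm$diff < -0.10, "hypo10", "neutral")))
  means <- c(control = mean(mat$rate[, mat$groups == gl["control"]]),
             treated = mean(mat$rate[, mat$groups == gl["treated"]]))
  structure(list(classes = data.frame(chrom = gm$chrom, pos = gm$pos,
                                      diff = gm$diff,
                                      label = factor(label,
                                                     levels = c("hyper20",
                                                                "hyper10",
                                                                "neutral",
                                                                "hypo10"))),
                 group_means = means, empty = FALSE),
            class = "site_classes")
}

#' @export
print.site_classes <- function(x, ...) {
  cat(sprintf("site_classes: %d common CpGs\n", nrow(x$classes)))
  if (!x$empty) {
    print(table(x$classes$label))
    cat(sprintf("grand mean rate  control: %.3f  treated: %.3f\n",
                x$group_means["control"], x$group_means["treated"]))
  } else cat("empty matrix: group means undefined\n")
  invisible(x)
}

#' Sample-level PCA of methylation rates
#'
#' Principal component analysis with samples as observations and sites
#' as variables, on per-site mean-centred (optionally scaled) rates.
#' For determinism, each axis' sign is fixed so that its
#' largest-magnitude site loading is positive.
#'
#' @param mat a [unify()] matrix with >= 2 samples and >= 2 sites.
#' @param center,scale. passed to [stats::prcomp()] (defaults: centred,
#'   unscaled).
#' @return `meth_pca`: list with `scores` (samples x axes), `loadings`
#'   (sites x axes), `var_explained` (fraction per axis; sums to 1 over
#'   the retained axes), `samples`, `groups`.
#' @export
pca_samples <- function(mat, center = TRUE, scale. = FALSE) {
  stopifnot(inherits(mat, "cpg_matrix"))
  if (length(mat$samples) < 2L) stopf("PCA needs >= 2 samples")
  if (nrow(mat$sites) < 2L) stopf("PCA needs >= 2 sites")
  x <- t(mat$rate)
  if (scale. && any(apply(x, 2L, var) == 0))
    stopf("cannot scale: some sites have zero variance")
  pc <- prcomp(x, center = center, scale. = scale.)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(k) {
    l <- pc$rotation[, k]
    sign(l[which.max(abs(l))]) < 0
  }, logical(1))
  pc$rotation[, flip] <- -pc$rotation[, flip]
  pc$x[, flip] <- -pc$x[, flip]
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 var_explained = ve, samples = mat$samples,
                 groups = mat$groups),
            class = "meth_pca")
}

#' @export
print.meth_pca <- function(x, ...) {
  cat(sprintf("meth_pca: %d samples, %d axes\n", length(x$samples),
              ncol(x$scores)))
  cat("variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_along(x$var_explained),
                    100 * x$var_explained), collapse = "  "), "\n")
  invisible(x)
}

#' Scatter plot of the first two principal axes
#'
#' @param x a `meth_pca`.
#' @param axes length-2 integer vector of axes to draw (default 1:2).
#' @param ... further arguments to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.meth_pca <- function(x, axes = c(1L, 2L), ...) {
  grp <- factor(x$groups)
  graphics::plot(x$scores[, axes[1L]], x$scores[, axes[2L]],
                 col = as.integer(grp) + 1L, pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", axes[1L],
                                100 * x$var_explained[axes[1L]]),
                 ylab = sprintf("PC%d (%.1f%%)", axes[2L],
                                100 * x$var_explained[axes[2L]]), ...)
  graphics::text(x$scores[, axes[1L]], x$scores[, axes[2L]],
                 labels = x$samples, pos = 3, cex = 0.7)
  graphics::legend("topright", legend = levels(grp), pch = 19,
                   col = seq_along(levels(grp)) + 1L)
  invisible(x)
}
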