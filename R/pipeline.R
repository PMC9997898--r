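# End-to-end orchestration with checkpointed intermediates: every stage
# reads the previous stage's files from the output directory, so the
# monolithic run and chained stage calls produce identical tables.

#' Build a validated pipeline run configuration
#'
#' @param sample_sheet data.frame with columns path, sample_id, group
#'   (exactly two distinct labels), or the path of such a TSV.
#' @param out_dir output directory (created if needed).
#' @param mode `"sperm"` (promoter DMCs, DMRs, peak proximity) or
#'   `"embryo"` (site classes, group means, PCA).
#' @param tss_path TSS annotation (BED6 or 4-column TSV); required in
#'   sperm mode.
#' @param peaks_path scored peak BED; optional (proximity is skipped
#'   without it).
#' @param min_cov,p_threshold,diff_threshold,dmr_min_cpgs,dmr_max_span,
#'   promoter_upstream,peak_flank,peak_min_score analysis thresholds;
#'   defaults are the package's standard workflow values.
#' @param destrand merge CpG dyads before unification (default TRUE).
#' @param var_equal pooled-variance t-test (default TRUE).
#' @param report_format cytosine-report dialect, see [read_cpg_report()].
#' @return object of class `run_config`.
#' @export
run_config <- function(sample_sheet, out_dir, mode = c("sperm", "embryo"),
                       tss_path = NULL, peaks_path = NULL,
                       min_cov = 10, p_threshold = 0.05,
                       diff_threshold = 0.20, dmr_min_cpgs = 10,
                       dmr_max_span = 300, promoter_upstream = 2000,
                       peak_flank = 1000, peak_min_score = 50,
                       destrand = TRUE, var_equal = TRUE,
                       report_format = "cytosine") {
  mode <- match.arg(mode)
  if (is.character(sample_sheet)) {
    if (!file.exists(sample_sheet)) stopf("sample sheet not found: %s",
                                          sample_sheet)
    sample_sheet <- as.data.frame(fread(sample_sheet, sep = "\t",
                                        header = TRUE, showProgress = FALSE,
                                        colClasses = "character"))
  }
  need <- c("path", "sample_id", "group")
  if (!all(need %in% names(sample_sheet)))
    stopf("sample sheet needs columns: %s", paste(need, collapse = ", "))
  if (length(unique(sample_sheet$group)) != 2L)
    stopf("sample sheet must contain exactly two group labels, found: %s",
          paste(unique(sample_sheet$group), collapse = ", "))
  missing <- sample_sheet$path[!file.exists(sample_sheet$path)]
  if (length(missing)) stopf("input file(s) not found: %s",
                             paste(missing, collapse = ", "))
  if (mode == "sperm" && is.null(tss_path))
    stopf("sperm mode requires tss_path")
  for (p in c(tss_path, peaks_path))
    if (!file.exists(p)) stopf("input file not found: %s", p)
  thr <- c(min_cov = min_cov, p_threshold = p_threshold,
           diff_threshold = diff_threshold, dmr_min_cpgs = dmr_min_cpgs,
           dmr_max_span = dmr_max_span, promoter_upstream = promoter_upstream,
           peak_flank = peak_flank, peak_min_score = peak_min_score)
  if (any(thr[setdiff(names(thr), "peak_min_score")] <= 0))
    stopf("all thresholds must be positive")
  structure(list(sample_sheet = sample_sheet, out_dir = out_dir, mode = mode,
                 tss_path = tss_path, peaks_path = peaks_path,
                 thresholds = as.list(thr), destrand = isTRUE(destrand),
                 var_equal = isTRUE(var_equal),
                 report_format = report_format),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `samples` is a
#' list of `{path, sample_id, group}` records.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stopf("the 'yaml' package is required to read YAML configs")
  y <- yaml::read_yaml(path)
  sheet <- do.call(rbind, lapply(y$samples, function(s)
    data.frame(path = s$path, sample_id = s$sample_id, group = s$group)))
  args <- y[setdiff(names(y), "samples")]
  do.call(run_config, c(list(sample_sheet = sheet), args))
}

ckpt <- function(cfg, name) file.path(cfg$out_dir, name)

#' Individual pipeline stages
#'
#' Each stage reads its inputs (raw files or the previous stage's
#' checkpoint in `out_dir`), writes its result table(s) there and
#' returns the in-memory object. Chaining
#' `stage_unify()` -> `stage_dmc()` -> `stage_dmr()` ->
#' `stage_proximity()` (or `stage_embryo()`) reproduces
#' [run_pipeline()] exactly.
#'
#' @param cfg a [run_config()].
#' @return the stage's result object, invisibly where it is file-first.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_unify <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  sheet <- cfg$sample_sheet
  meths <- lapply(seq_len(nrow(sheet)), function(i) {
    m <- read_cpg_report(sheet$path[i], sheet$sample_id[i], sheet$group[i],
                         format = cfg$report_format)
    if (cfg$destrand) destrand(m) else m
  })
  mat <- unify(meths, min_cov = cfg$thresholds$min_cov)
  if (!nrow(mat$sites))
    stopf("stage unify: zero sites passed coverage >= %s in all samples",
          format(cfg$thresholds$min_cov))
  write_cpg_matrix(mat, ckpt(cfg, "matrix.tsv"))
  mat
}

#' @rdname pipeline_stages
#' @export
stage_dmc <- function(cfg) {
  mat <- read_cpg_matrix(ckpt_require(cfg, "matrix.tsv", "unify"))
  tss <- read_tss_table(cfg$tss_path)
  prom <- build_promoters(tss, cfg$thresholds$promoter_upstream)
  write_promoter_bed(prom, ckpt(cfg, "promoters.bed"))
  psites <- promoter_sites(mat, prom)
  dmcs <- call_dmcs(mat, psites,
                    p_threshold = cfg$thresholds$p_threshold,
                    diff_threshold = cfg$thresholds$diff_threshold,
                    var_equal = cfg$var_equal)
  write_dmc_table(dmcs, ckpt(cfg, "dmc.tsv"))
  dmcs
}

#' @rdname pipeline_stages
#' @export
stage_dmr <- function(cfg) {
  mat <- read_cpg_matrix(ckpt_require(cfg, "matrix.tsv", "unify"))
  dmrs <- call_dmrs(mat, min_cpgs = cfg$thresholds$dmr_min_cpgs,
                    max_span = cfg$thresholds$dmr_max_span,
                    diff_threshold = cfg$thresholds$diff_threshold)
  write_result_table(as.data.frame(dmrs), ckpt(cfg, "dmr.tsv"))
  write_dmr_bed(dmrs, ckpt(cfg, "dmr.bed"))
  dmrs
}

#' @rdname pipeline_stages
#' @export
stage_proximity <- function(cfg) {
  if (is.null(cfg$peaks_path)) stopf("stage proximity: no peaks_path configured")
  dmr_path <- ckpt_require(cfg, "dmr.tsv", "dmr")
  dmrs <- as.data.frame(fread(dmr_path, sep = "\t", header = TRUE,
                              showProgress = FALSE))
  peaks <- suppressMessages(
    read_peaks(cfg$peaks_path, min_score = cfg$thresholds$peak_min_score))
  rep_ <- peak_proximity(dmrs, peaks, flank = cfg$thresholds$peak_flank)
  write_proximity_table(rep_, ckpt(cfg, "proximity.tsv"))
  rep_
}

#' @rdname pipeline_stages
#' @export
stage_embryo <- function(cfg) {
  mat <- read_cpg_matrix(ckpt_require(cfg, "matrix.tsv", "unify"))
  cls <- classify_sites(mat)
  write_result_table(cls$classes, ckpt(cfg, "site_classes.tsv"))
  pca <- pca_samples(mat)
  sc <- data.frame(sample_id = pca$samples, group = pca$groups,
                   pca$scores, check.names = FALSE)
  write_result_table(sc, ckpt(cfg, "pca.tsv"))
  write_result_table(
    data.frame(axis = seq_along(pca$var_explained),
               var_explained = pca$var_explained),
    ckpt(cfg, "pca_variance.tsv"))
  list(classes = cls, pca = pca)
}

ckpt_require <- function(cfg, name, stage) {
  p <- ckpt(cfg, name)
  if (!file.exists(p))
    stopf("checkpoint '%s' missing: run stage '%s' first", name, stage)
  p
}

#' Run the whole pipeline
#'
#' Sperm mode: unify -> promoter DMCs -> DMRs -> peak proximity (when a
#' peak file is configured). Embryo mode: unify -> site classes and
#' group means -> PCA. All tables land in `cfg$out_dir` together with a
#' machine-readable `manifest.json` recording the package version,
#' thresholds, input hashes and outputs. Reruns with identical inputs
#' and configuration are byte-identical.
#'
#' @param cfg a [run_config()].
#' @return list with the in-memory stage results and `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  res <- list(matrix = stage_unify(cfg))
  if (cfg$mode == "sperm") {
    res$dmcs <- stage_dmc(cfg)
    res$dmrs <- stage_dmr(cfg)
    if (!is.null(cfg$peaks_path)) res$proximity <- stage_proximity(cfg)
  } else {
    emb <- stage_embryo(cfg)
    res$classes <- emb$classes
    res$pca <- emb$pca
  }
  inputs <- c(cfg$sample_sheet$path, cfg$tss_path, cfg$peaks_path)
  manifest <- list(
    package = "methdmr",
    version = as.character(packageVersion("methdmr")),
    schema = "methdmr-run/1",
    mode = cfg$mode,
    thresholds = cfg$thresholds,
    destrand = cfg$destrand,
    var_equal = cfg$var_equal,
    inputs = data.frame(path = inputs,
                        md5 = unname(tools::md5sum(inputs))),
    outputs = list.files(cfg$out_dir, pattern = "\\.(tsv|bed)$"))
  jsonlite::write_json(manifest, ckpt(cfg, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  res
}
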