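# Internal helpers shared across modules.

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x) && x >= 0

# 1-based inclusive interval -> BED 0-based half-open and back.
to_bed_start <- function(start_1based) as.integer(start_1based) - 1L
from_bed <- function(bed_start, bed_end) {
  list(start = as.integer(bed_start) + 1L, end = as.integer(bed_end))
}

# Natural-ish deterministic chromosome order: plain lexicographic.
# Exact string identity everywhere; see `normalize_chrom` for prefix fixes.
order_sites <- function(chrom, pos) order(chrom, pos, method = "radix")

#' Add or strip the "chr" prefix on chromosome names
#'
#' Chromosome matching in methdmr is exact string equality; mixed "chr1" /
#' "1" inputs are a user error this helper repairs explicitly rather than
#' silently.
#'
#' @param x character vector of chromosome names.
#' @param style `"chr"` to ensure the prefix, `"plain"` to remove it.
#' @return character vector of renamed chromosomes.
#' @export
#' @examples
#' normalize_chrom(c("1", "chr2"), "chr")
normalize_chrom <- function(x, style = c("chr", "plain")) {
  style <- match.arg(style)
  bare <- sub("^chr", "", x)
  if (style == "chr") paste0("chr", bare) else bare
}

# Two-group label resolution for a cpg_matrix: returns
# c(control = <label>, treated = <label>).
resolve_groups <- function(groups, control = NULL) {
  lev <- unique(groups)
  if (length(lev) != 2L)
    stopf("expected exactly 2 group labels, found %d (%s)",
          length(lev), paste(lev, collapse = ", "))
  if (is.null(control)) {
    control <- if ("control" %in% lev) "control" else sort(lev)[1L]
  }
  if (!control %in% lev)
    stopf("control label '%s' not among group labels (%s)",
          control, paste(lev, collapse = ", "))
  c(control = control, treated = setdiff(lev, control))
}
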