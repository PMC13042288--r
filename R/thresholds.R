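#' Hard-filter thresholds for variant candidacy and callable-site accounting
#'
#' Bundles every numeric cutoff used by the filtering stack. The defaults are
#' the GATK-recommended hard filters for germline short-variant calls plus the
#' depth-window, proximity, clustering and merge distances used throughout the
#' pipeline. All comparisons are inclusive: a site sitting exactly on a bound
#' passes.
#'
#' @param min_alt_reads Minimum reads supporting the variant allele
#'   (variant mode only).
#' @param min_MQ Minimum RMS mapping quality.
#' @param min_QD Minimum quality by depth.
#' @param max_FS Maximum Fisher strand bias (phred).
#' @param max_SOR Maximum strand odds ratio.
#' @param max_abs_MQRankSum Maximum absolute mapping-quality rank sum.
#' @param max_abs_ReadPosRankSum Maximum absolute read-position rank sum.
#' @param depth_lo_frac,depth_hi_frac Acceptable depth window as fractions of
#'   the line's median chromosome-wide depth (`depth_lo_frac * median <= DP <=
#'   depth_hi_frac * median`).
#' @param proximity_bp Exclusion distance (bp) around structural variants and
#'   TE insertions; point variants at distance `<= proximity_bp` are removed.
#' @param cluster_bp Single-linkage gap (bp) for grouping variants of one line
#'   into multinucleotide / complex events.
#' @param te_merge_bp Single-linkage gap (bp) for merging TE calls of the same
#'   family across lines into one event.
#' @param sv_min_support Minimum spanning OR split read support for a
#'   structural variant.
#' @return A named list with class `"filter_thresholds"`.
#' @export
filter_thresholds <- function(min_alt_reads = 10,
                              min_MQ = 50,
                              min_QD = 2,
                              max_FS = 60,
                              max_SOR = 3,
                              max_abs_MQRankSum = 8,
                              max_abs_ReadPosRankSum = 4,
                              depth_lo_frac = 0.5,
                              depth_hi_frac = 2,
                              proximity_bp = 1000,
                              cluster_bp = 1000,
                              te_merge_bp = 50,
                              sv_min_support = 10) {
  th <- list(min_alt_reads = min_alt_reads, min_MQ = min_MQ, min_QD = min_QD,
             max_FS = max_FS, max_SOR = max_SOR,
             max_abs_MQRankSum = max_abs_MQRankSum,
             max_abs_ReadPosRankSum = max_abs_ReadPosRankSum,
             depth_lo_frac = depth_lo_frac, depth_hi_frac = depth_hi_frac,
             proximity_bp = proximity_bp, cluster_bp = cluster_bp,
             te_merge_bp = te_merge_bp, sv_min_support = sv_min_support)
  if (!all(vapply(th, function(x) is.numeric(x) && length(x) == 1 && x > 0,
                  logical(1))))
    stop("all thresholds must be single positive numbers")
  if (th$depth_lo_frac >= th$depth_hi_frac)
    stop("depth_lo_frac must be < depth_hi_frac")
  structure(th, class = "filter_thresholds")
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat("Filter thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
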