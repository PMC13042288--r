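#' Evaluate a site (or many sites) against the hard-filter stack
#'
#' Applies the symmetric filter rules to site annotations and depth. In
#' `variant` mode the alt-read-support rule is additionally required; in
#' `nonvariant` mode (callable-site accounting) only the site-level rules and
#' the depth window apply. Every comparison is inclusive, rank-sum rules use
#' the absolute value, and the depth window is
#' `depth_lo_frac * median <= DP <= depth_hi_frac * median`.
#'
#' Missing annotations fail closed in variant mode (a candidate without the
#' evidence to pass cannot pass). For callable-site evaluation the
#' `strict_callable` flag chooses between the same fail-closed behaviour
#' (default) and pass-open, since joint callers leave some annotations
#' undefined at invariant sites.
#'
#' @param annotations Named list / one-row data frame with any of `MQ`, `QD`,
#'   `FS`, `SOR`, `MQRankSum`, `ReadPosRankSum` (NA = absent).
#' @param depth Total read depth at the site (non-negative).
#' @param median_depth The line's median chromosome-wide depth (> 0).
#' @param thresholds A [filter_thresholds()] object.
#' @param mode `"variant"` or `"nonvariant"`.
#' @param alt_reads Reads supporting the variant allele (variant mode).
#' @param strict_callable Logical; how missing annotations are treated in
#'   nonvariant mode (see Details).
#' @return A list with `pass` (logical) and `reason` (label of the first
#'   failed rule, NA when passing). Rules are checked in the order min_MQ,
#'   min_QD, max_FS, max_SOR, max_abs_MQRankSum, max_abs_ReadPosRankSum,
#'   depth_window, then (variant mode) min_alt_reads.
#' @export
site_passes_filters <- function(annotations, depth, median_depth,
                                thresholds = filter_thresholds(),
                                mode = c("variant", "nonvariant"),
                                alt_reads = NULL, strict_callable = TRUE) {
  mode <- match.arg(mode)
  if (any(depth < 0, na.rm = TRUE)) stop("input error: negative depth")
  if (any(median_depth <= 0)) stop("input error: median depth must be positive")
  ann <- as.list(annotations)
  df <- data.frame(MQ = ann_or_na(ann, "MQ"), QD = ann_or_na(ann, "QD"),
                   FS = ann_or_na(ann, "FS"), SOR = ann_or_na(ann, "SOR"),
                   MQRankSum = ann_or_na(ann, "MQRankSum"),
                   ReadPosRankSum = ann_or_na(ann, "ReadPosRankSum"))
  reason <- eval_filter_reasons(df, depth, median_depth,
                                alt_reads = alt_reads, thresholds = thresholds,
                                mode = mode, strict_callable = strict_callable)
  list(pass = is.na(reason), reason = reason)
}

ann_or_na <- function(ann, key) {
  v <- ann[[key]]
  if (is.null(v)) NA_real_ else as.numeric(v)
}

# Vectorised core: one reason (or NA) per site. `df` holds annotation columns.
eval_filter_reasons <- function(df, depth, median_depth, alt_reads,
                                thresholds, mode, strict_callable = TRUE) {
  n <- max(nrow(df), length(depth))
  reason <- rep(NA_character_, n)
  miss_fails <- mode == "variant" || strict_callable
  check <- function(reason, val, fails, label) {
    hit <- is.na(reason) & ((!is.na(val) & fails) | (is.na(val) & miss_fails))
    reason[hit] <- ifelse(is.na(val[hit]), paste0("missing_", label), label)
    reason
  }
  th <- thresholds
  reason <- check(reason, df$MQ, df$MQ < th$min_MQ, "min_MQ")
  reason <- check(reason, df$QD, df$QD < th$min_QD, "min_QD")
  reason <- check(reason, df$FS, df$FS > th$max_FS, "max_FS")
  reason <- check(reason, df$SOR, df$SOR > th$max_SOR, "max_SOR")
  reason <- check(reason, df$MQRankSum, abs(df$MQRankSum) > th$max_abs_MQRankSum,
                  "max_abs_MQRankSum")
  reason <- check(reason, df$ReadPosRankSum,
                  abs(df$ReadPosRankSum) > th$max_abs_ReadPosRankSum,
                  "max_abs_ReadPosRankSum")
  lo <- th$depth_lo_frac * median_depth
  hi <- th$depth_hi_frac * median_depth
  bad_dp <- is.na(depth) | depth < lo | depth > hi
  reason[is.na(reason) & bad_dp] <- "depth_window"
  if (mode == "variant") {
    if (is.null(alt_reads)) stop("variant mode requires alt_reads")
    bad_ar <- is.na(alt_reads) | alt_reads < th$min_alt_reads
    reason[is.na(reason) & bad_ar] <- "min_alt_reads"
  }
  reason
}

#' Per-line site evaluation table to a failed-site interval track
#'
#' Evaluates a per-site statistics table (columns `contig`, `pos`, the six
#' annotation columns, `DP`) for one line in nonvariant mode and returns the
#' failing positions as an [interval_track()] (maximal runs of consecutive
#' failing positions).
#'
#' @param site_stats Data frame of per-site statistics for one line.
#' @param median_depth Named per-contig median depth for the line (or single
#'   number).
#' @param thresholds A [filter_thresholds()].
#' @param strict_callable See [site_passes_filters()].
#' @return An [interval_track()] of failed regions (0-based half-open).
#' @export
evaluate_line_sites <- function(site_stats, median_depth,
                                thresholds = filter_thresholds(),
                                strict_callable = TRUE) {
  med <- if (length(median_depth) > 1 || !is.null(names(median_depth)))
    unname(median_depth[site_stats$contig]) else median_depth
  reason <- eval_filter_reasons(site_stats, site_stats$DP, med,
                                alt_reads = NULL, thresholds = thresholds,
                                mode = "nonvariant",
                                strict_callable = strict_callable)
  fail <- !is.na(reason)
  if (!any(fail)) return(interval_track(character(), integer(), integer()))
  pos <- site_stats$pos[fail]
  ctg <- site_stats$contig[fail]
  out <- lapply(split(pos, ctg), function(p) {
    p <- sort(unique(p))
    brk <- c(0, which(diff(p) > 1), length(p))
    data.frame(start = p[brk[-length(brk)] + 1] - 1, end = p[brk[-1]])
  })
  interval_track(rep(names(out), vapply(out, nrow, 0L)),
                 unlist(lapply(out, `[[`, "start")),
                 unlist(lapply(out, `[[`, "end")))
}

#' Compute the panel-wide callable mask
#'
#' A site is callable iff it is not repeat-masked and passes the nonvariant
#' filter evaluation in every line. Per-line failures are supplied as interval
#' tracks of failing regions (from [evaluate_line_sites()] or from the
#' synthetic generator's site tables). The summary identity
#' `total = repeat_masked + filter_failed + callable` holds exactly by
#' construction and is asserted.
#'
#' @param genome Named vector of contig lengths (bp).
#' @param repeat_mask [interval_track()] of repeat-masked regions.
#' @param fail_tracks List (one per line) of [interval_track()]s of regions
#'   failing the nonvariant filters in that line.
#' @param gc_track Optional [interval_track()] marking reference G/C regions;
#'   enables callable G/C accounting.
#' @return Object of class `"callable_mask"`: per-contig logical vectors
#'   (`mask`), optional per-contig G/C logicals (`gc`), and a `summary` data
#'   frame with per-contig and total site accounting.
#' @export
compute_callable_mask <- function(genome, repeat_mask,
                                  fail_tracks = list(), gc_track = NULL) {
  contigs <- names(genome)
  if (is.null(contigs)) stop("genome must be a named vector of contig lengths")
  all_tracks <- c(list(repeat_mask), fail_tracks,
                  if (!is.null(gc_track)) list(gc_track))
  for (tr in all_tracks) {
    extra <- setdiff(unique(tr$contig), contigs)
    if (length(extra))
      stop("contig(s) absent from genome definition: ",
           paste(extra, collapse = ", "))
  }
  flag <- function(track, ctg, L) {
    v <- logical(L)
    sub <- track[track$contig == ctg, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      s <- max(0, sub$start[i]); e <- min(L, sub$end[i])
      if (e > s) v[(s + 1):e] <- TRUE
    }
    v
  }
  mask <- list(); gc <- list()
  rows <- list()
  for (ctg in contigs) {
    L <- as.integer(genome[[ctg]])
    masked <- flag(repeat_mask, ctg, L)
    failed <- logical(L)
    for (tr in fail_tracks) failed <- failed | flag(tr, ctg, L)
    callable <- !masked & !failed
    mask[[ctg]] <- callable
    is_gc <- if (!is.null(gc_track)) flag(gc_track, ctg, L) else NULL
    if (!is.null(is_gc)) gc[[ctg]] <- is_gc
    rows[[ctg]] <- data.frame(
      contig = ctg, total = L, repeat_masked = sum(masked),
      filter_failed = sum(!masked & failed), callable = sum(callable),
      callable_gc = if (is.null(is_gc)) NA_integer_ else sum(callable & is_gc))
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  tot <- data.frame(contig = "total", t(colSums(summary[, -1])))
  names(tot) <- names(summary)
  summary <- rbind(summary, tot)
  stopifnot(all(summary$total ==
                  summary$repeat_masked + summary$filter_failed + summary$callable))
  structure(list(genome = genome, mask = mask,
                 gc = if (length(gc)) gc else NULL, summary = summary),
            class = "callable_mask")
}

#' @export
print.callable_mask <- function(x, ...) {
  cat("Callable mask:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Callable-site bookkeeping from summary totals
#'
#' Pure arithmetic on the three published totals: splits non-callable sites
#' into the repeat-masked and filter-failed components and reports the
#' callable count and percentage. `total = repeat_masked + filter_failed +
#' callable` holds exactly.
#'
#' @param total_sites Reference sites on the analyzed contigs.
#' @param noncallable_sites Sites excluded for any reason.
#' @param repeat_masked_sites Sites excluded because repeat-masked.
#' @return List with `filter_failed`, `callable`, `callable_percent`.
#' @examples
#' callability_bookkeeping(133880608, 34422478, 20052895)
#' @export
callability_bookkeeping <- function(total_sites, noncallable_sites,
                                    repeat_masked_sites) {
  stopifnot(noncallable_sites <= total_sites,
            repeat_masked_sites <= noncallable_sites)
  filter_failed <- noncallable_sites - repeat_masked_sites
  callable <- total_sites - noncallable_sites
  list(filter_failed = filter_failed, callable = callable,
       callable_percent = 100 * callable / total_sites)
}

#' Count callable (and callable G/C) sites overlapping a track or window
#'
#' @param mask A `"callable_mask"`.
#' @param track An [interval_track()]; counts callable sites inside it.
#' @return Named list with `callable` and (if the mask carries G/C state)
#'   `callable_gc` counts inside the track.
#' @export
count_callable_in <- function(mask, track) {
  tot <- 0; tot_gc <- if (is.null(mask$gc)) NA else 0
  for (ctg in unique(track$contig)) {
    v <- mask$mask[[ctg]]
    if (is.null(v)) next
    sub <- track[track$contig == ctg, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      s <- max(0, sub$start[i]); e <- min(length(v), sub$end[i])
      if (e <= s) next
      idx <- (s + 1):e
      tot <- tot + sum(v[idx])
      if (!is.null(mask$gc))
        tot_gc <- tot_gc + sum(v[idx] & mask$gc[[ctg]][idx])
    }
  }
  list(callable = tot, callable_gc = tot_gc)
}

#' Screen per-contig coverage for aneuploidy
#'
#' Flags (line, contig) pairs whose mean depth is elevated relative to the
#' line-wide autosomal median, the signature of a trisomic chromosome. The
#' default ratio threshold of 1.4 sits between the euploid expectation (1.0)
#' and the trisomic expectation (1.5).
#'
#' @param depth Numeric matrix (lines x contigs) of mean sequencing depth.
#' @param autosomes Contigs used for the line-wide baseline.
#' @param ratio_threshold Flag when `depth / baseline >= ratio_threshold`.
#' @return Data frame with `line_id`, `contig`, `ratio`, `flagged`.
#' @export
detect_aneuploidy <- function(depth, autosomes = c("2L", "2R", "3L", "3R"),
                              ratio_threshold = 1.4) {
  depth <- as.matrix(depth)
  if (ncol(depth) < 2) stop("need depth on at least two contigs")
  base_cols <- intersect(autosomes, colnames(depth))
  if (!length(base_cols)) base_cols <- colnames(depth)
  out <- list()
  for (i in seq_len(nrow(depth))) {
    med <- stats::median(depth[i, base_cols])
    if (!is.finite(med) || med == 0)
      stop("zero line-wide median depth for line ", rownames(depth)[i])
    ratio <- depth[i, ] / med
    out[[i]] <- data.frame(line_id = rownames(depth)[i] %||% as.character(i),
                           contig = colnames(depth),
                           ratio = as.numeric(ratio),
                           flagged = as.numeric(ratio) >= ratio_threshold,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
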