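#' Read and write transposable-element call tables
#'
#' TE calls are a TSV with header columns `line_id`, `family`, `contig`,
#' `breakpoint` (1-based), `event_type` (`insertion` or `excision`), and
#' `support` (read count).
#'
#' @param path Path to a TSV file.
#' @return A data frame of TE calls.
#' @export
read_te_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(line_id = "character",
                                         family = "character",
                                         contig = "character"))
  need <- c("line_id", "family", "contig", "breakpoint", "event_type", "support")
  if (!all(need %in% names(df)))
    stop("TE table parse error: expected columns ", paste(need, collapse = ", "))
  df <- df[, need, drop = FALSE]
  bad <- !df$event_type %in% c("insertion", "excision")
  if (any(bad))
    stop("TE table parse error: unknown event_type '",
         df$event_type[which(bad)[1]], "' at data row ", which(bad)[1])
  if (nrow(df) && (any(df$breakpoint < 1) || any(!nzchar(df$family))))
    stop("TE table parse error: breakpoint must be >= 1 and family non-empty")
  df$breakpoint <- as.integer(df$breakpoint)
  df$support <- as.integer(df$support)
  df
}

#' @rdname read_te_calls
#' @param calls TE call data frame.
#' @export
write_te_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write structural-variant call tables
#'
#' SV calls are a TSV with header columns `contig`, `start`, `end` (1-based
#' inclusive span), `sv_type` (`deletion`, `insertion`, `tandem_duplication`),
#' `length` (bp), `quality`, `spanning_reads`, `split_reads`, `carriers`
#' (comma-separated line ids carrying the variant) and `genotyped`
#' (comma-separated line ids with a called genotype at the locus).
#'
#' @param path Path to a TSV file.
#' @return A data frame of SV records; `carriers` and `genotyped` are
#'   list-columns of character vectors.
#' @export
read_sv_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(contig = "character"))
  need <- c("contig", "start", "end", "sv_type", "length", "quality",
            "spanning_reads", "split_reads", "carriers", "genotyped")
  if (!all(need %in% names(df)))
    stop("SV table parse error: expected columns ", paste(need, collapse = ", "))
  df <- df[, need, drop = FALSE]
  bad <- !df$sv_type %in% c("deletion", "insertion", "tandem_duplication")
  if (any(bad))
    stop("SV table parse error: unknown sv_type '",
         df$sv_type[which(bad)[1]], "'")
  if (nrow(df) && (any(df$length <= 0) ||
                   any(df$spanning_reads < 0) || any(df$split_reads < 0)))
    stop("SV table parse error: length must be positive, supports non-negative")
  df$carriers <- strsplit(as.character(df$carriers), ",", fixed = TRUE)
  df$genotyped <- strsplit(as.character(df$genotyped), ",", fixed = TRUE)
  df
}

#' @rdname read_sv_table
#' @param sv SV data frame (as returned by [read_sv_table()]).
#' @export
write_sv_table <- function(sv, path) {
  out <- sv
  out$carriers <- vapply(sv$carriers, paste, "", collapse = ",")
  out$genotyped <- vapply(sv$genotyped, paste, "", collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Line metadata: treatment, generations and per-contig median depth
#'
#' @param line_id Character vector of line ids.
#' @param treatment Factor-like vector with levels `dsb_plus` / `dsb_minus`.
#' @param generations Nominal MA generations per line (default 30).
#' @param adjusted_generations Effective generations used for per-site rate
#'   denominators (accounts for the extra chromosome copies sampled per line);
#'   defaults to `generations`, i.e. an adjustment factor of 1. The adjustment
#'   rescales absolute rates but cancels from treatment contrasts.
#' @param median_depth Numeric matrix (lines x contigs) of median
#'   chromosome-wide sequencing depth.
#' @return A data frame of class `"line_meta"` with the depth matrix attached
#'   as attribute `"median_depth"`.
#' @export
line_metadata <- function(line_id, treatment, generations = 30,
                          adjusted_generations = generations,
                          median_depth = NULL) {
  treatment <- as.character(treatment)
  if (!all(treatment %in% c("dsb_plus", "dsb_minus")))
    stop("treatment must be dsb_plus or dsb_minus")
  if (any(adjusted_generations <= 0))
    stop("adjusted_generations must be positive")
  df <- data.frame(line_id = as.character(line_id), treatment = treatment,
                   generations = generations,
                   adjusted_generations = adjusted_generations,
                   stringsAsFactors = FALSE)
  if (!is.null(median_depth)) {
    median_depth <- as.matrix(median_depth)
    if (nrow(median_depth) != nrow(df))
      stop("median_depth must have one row per line")
    if (any(median_depth <= 0))
      stop("median depth must be positive on every analyzed contig")
    rownames(median_depth) <- df$line_id
  }
  attr(df, "median_depth") <- median_depth
  class(df) <- c("line_meta", "data.frame")
  df
}

#' @rdname line_metadata
#' @param path Path of the metadata TSV (depth columns are prefixed `depth_`).
#' @export
read_line_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(line_id = "character"))
  depth_cols <- grep("^depth_", names(df), value = TRUE)
  md <- NULL
  if (length(depth_cols)) {
    md <- as.matrix(df[, depth_cols, drop = FALSE])
    colnames(md) <- sub("^depth_", "", depth_cols)
  }
  line_metadata(df$line_id, df$treatment, df$generations,
                df$adjusted_generations, md)
}

#' @rdname line_metadata
#' @param meta A `"line_meta"` object.
#' @export
write_line_metadata <- function(meta, path) {
  out <- as.data.frame(meta)
  md <- attr(meta, "median_depth")
  if (!is.null(md)) {
    depth_df <- as.data.frame(md)
    names(depth_df) <- paste0("depth_", colnames(md))
    out <- cbind(out, depth_df)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# median depth of one line on one contig, with a clear error
line_median_depth <- function(meta, line, contig) {
  md <- attr(meta, "median_depth")
  if (is.null(md)) stop("line metadata carries no median_depth matrix")
  if (!line %in% rownames(md)) stop("no depth for line ", line)
  if (!contig %in% colnames(md)) stop("no depth for contig ", contig)
  md[line, contig]
}
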