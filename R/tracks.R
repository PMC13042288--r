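#' Interval tracks (BED-style, 0-based half-open)
#'
#' An interval track is a data frame with columns `contig`, `start`, `end`
#' (0-based half-open) and optionally `value` (numeric or character). Intervals
#' on one contig must not overlap within a track.
#'
#' @param contig Character vector of contig names.
#' @param start,end Integer interval bounds, 0-based half-open (`start < end`).
#' @param value Optional per-interval value (numeric or label).
#' @return A `data.frame` with class `c("interval_track", "data.frame")`,
#'   sorted by contig then start.
#' @export
interval_track <- function(contig, start, end, value = NULL) {
  df <- data.frame(contig = as.character(contig),
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (!is.null(value)) df$value <- value
  validate_track(df)
}

validate_track <- function(df) {
  if (nrow(df)) {
    if (any(!is.finite(df$start)) || any(!is.finite(df$end)))
      stop("interval track: non-finite coordinates")
    bad <- which(df$start >= df$end)
    if (length(bad))
      stop("interval track: start >= end at row(s) ", paste(bad, collapse = ", "))
    if (any(df$start < 0)) stop("interval track: negative start")
    df <- df[order(df$contig, df$start), , drop = FALSE]
    rownames(df) <- NULL
    for (ctg in unique(df$contig)) {
      sub <- df[df$contig == ctg, , drop = FALSE]
      if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
        stop("interval track: overlapping intervals on contig ", ctg)
    }
  }
  class(df) <- c("interval_track", "data.frame")
  df
}

#' Read a BED3+1 interval track
#'
#' Reads whitespace-separated BED lines (`contig start end [value]`), 0-based
#' half-open. Lines starting with `#` or `track` are skipped. Overlapping
#' intervals on one contig are rejected.
#'
#' @param path Path to a BED-style file.
#' @param value_type One of `"auto"` (numeric if all values parse as numbers),
#'   `"numeric"`, `"label"`, or `"none"` (ignore a 4th column).
#' @return An [interval_track()].
#' @export
read_intervals <- function(path, value_type = c("auto", "numeric", "label", "none")) {
  value_type <- match.arg(value_type)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines)]
  if (!length(lines))
    return(interval_track(character(), integer(), integer()))
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED parse error: fewer than 3 fields at line ", which(nf < 3)[1])
  contig <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end))
    stop("BED parse error: non-numeric coordinate at line ",
         which(is.na(start) | is.na(end))[1])
  value <- NULL
  if (value_type != "none" && all(nf >= 4)) {
    raw <- vapply(fields, `[[`, "", 4)
    if (value_type == "label") {
      value <- raw
    } else {
      num <- suppressWarnings(as.numeric(raw))
      if (value_type == "numeric" && anyNA(num))
        stop("BED parse error: non-numeric value column at line ",
             which(is.na(num))[1])
      value <- if (anyNA(num)) raw else num
    }
  }
  interval_track(contig, start, end, value)
}

#' Write an interval track as BED3+1
#'
#' @param track An [interval_track()].
#' @param path Output path.
#' @export
write_intervals <- function(track, path) {
  lines <- if (is.null(track$value)) {
    paste(track$contig, format_num(track$start), format_num(track$end), sep = "\t")
  } else {
    paste(track$contig, format_num(track$start), format_num(track$end),
          format_num(track$value), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

# plain decimal formatting that round-trips through as.character
format_num <- function(x) {
  if (is.numeric(x)) {
    out <- vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE,
                                        digits = 15), "")
    out
  } else as.character(x)
}

# IRanges view of one contig's intervals (1-based closed, for overlap work)
track_ranges <- function(track, ctg) {
  sub <- track[track$contig == ctg, , drop = FALSE]
  list(ir = IRanges::IRanges(start = sub$start + 1L, end = sub$end),
       value = sub$value, df = sub)
}

# total bases of a track on each contig
track_coverage <- function(track) {
  if (!nrow(track)) return(numeric(0))
  tapply(track$end - track$start, track$contig, sum)
}

# membership of 1-based points in a track (logical)
points_in_track <- function(track, contig, pos) {
  out <- logical(length(pos))
  for (ctg in unique(contig)) {
    sel <- contig == ctg
    sub <- track[track$contig == ctg, , drop = FALSE]
    if (!nrow(sub)) next
    ir <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    q <- IRanges::IRanges(start = pos[sel], width = 1L)
    out[sel] <- IRanges::overlapsAny(q, ir)
  }
  out
}
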