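#' Select line-unique variant candidates
#'
#' A record is a candidate de novo mutation iff exactly one line carries a
#' non-reference genotype and no line is missing a genotype at the site.
#' Everything else is logged: `uncalled_site` (any missing genotype),
#' `shared` (two or more carrier lines), `no_carrier` (no non-reference
#' genotype).
#'
#' @param panel A [variant_panel()].
#' @return List with `candidates` (data frame: record index, owner line,
#'   owner genotype/AD/DP plus the variant columns) and `rejections`
#'   (record index, reason).
#' @export
select_line_unique <- function(panel) {
  gt <- panel$gt
  non_ref <- gt == "het" | gt == "hom_alt"
  n_carrier <- rowSums(non_ref)
  any_missing <- rowSums(gt == "missing") > 0
  reason <- rep(NA_character_, nrow(gt))
  reason[any_missing] <- "uncalled_site"
  reason[is.na(reason) & n_carrier == 0] <- "no_carrier"
  reason[is.na(reason) & n_carrier > 1] <- "shared"
  keep <- is.na(reason)
  owner_idx <- max.col(non_ref, ties.method = "first")
  v <- panel$variants
  idx <- which(keep)
  owner <- panel$lines[owner_idx[idx]]
  cand <- cbind(data.frame(record = idx, line_id = owner,
                           stringsAsFactors = FALSE),
                v[idx, , drop = FALSE])
  cand$genotype <- gt[cbind(idx, owner_idx[idx])]
  cand$alt_reads <- panel$ad[cbind(idx, owner_idx[idx])]
  cand$depth <- panel$dp[cbind(idx, owner_idx[idx])]
  rownames(cand) <- NULL
  rej <- data.frame(record = which(!keep), reason = reason[!keep],
                    contig = v$contig[!keep], pos = v$pos[!keep],
                    alt = v$alt[!keep], stringsAsFactors = FALSE)
  list(candidates = cand, rejections = rej)
}

#' Apply the variant-mode filter stack to line-unique candidates
#'
#' Each candidate is evaluated with [site_passes_filters()] in variant mode
#' against its owner line's median chromosome-wide depth. The rejection log
#' records the first failed rule per candidate.
#'
#' @param candidates Candidate data frame from [select_line_unique()].
#' @param thresholds A [filter_thresholds()].
#' @param meta [line_metadata()] carrying the per-line per-contig median
#'   depths.
#' @return List with `pass` (surviving candidates) and `rejections`
#'   (candidate rows plus `reason`).
#' @export
apply_variant_filters <- function(candidates, thresholds = filter_thresholds(),
                                  meta = NULL) {
  if (!nrow(candidates))
    return(list(pass = candidates,
                rejections = cbind(candidates, reason = character(0))))
  md <- attr(meta, "median_depth")
  if (is.null(md)) stop("line metadata must carry median depths")
  med <- md[cbind(match(candidates$line_id, rownames(md)),
                  match(candidates$contig, colnames(md)))]
  if (anyNA(med)) stop("missing median depth for some (line, contig)")
  reason <- eval_filter_reasons(candidates, candidates$depth, med,
                                alt_reads = candidates$alt_reads,
                                thresholds = thresholds, mode = "variant")
  keep <- is.na(reason)
  rej <- candidates[!keep, , drop = FALSE]
  if (nrow(rej)) rej$reason <- reason[!keep]
  else rej$reason <- character(0)
  list(pass = candidates[keep, , drop = FALSE], rejections = rej)
}

#' Remove point variants near structural variants or TE insertions
#'
#' A variant is excluded when its position is within `proximity_bp`
#' (inclusive) of the nearest SV interval edge (distance 0 inside the
#' interval) or TE insertion breakpoint on the same contig. By default only TE
#' insertions are used, not excisions.
#'
#' @param variants Candidate data frame (columns `contig`, `pos`).
#' @param sv Filtered SV data frame (columns `contig`, `start`, `end`;
#'   1-based inclusive), or NULL.
#' @param te TE event/call data frame (columns `contig`, `breakpoint`,
#'   `event_type`), or NULL.
#' @param proximity_bp Inclusive exclusion distance.
#' @param include_excisions Also exclude near TE excisions.
#' @return List with `pass` and `rejections` (reason `near_sv_te`).
#' @export
exclude_near_sv_te <- function(variants, sv = NULL, te = NULL,
                               proximity_bp = 1000,
                               include_excisions = FALSE) {
  if (!nrow(variants)) return(list(pass = variants,
                                   rejections = cbind(variants,
                                                      reason = character(0))))
  near <- logical(nrow(variants))
  if (!is.null(te) && nrow(te)) {
    tesub <- te[te$event_type == "insertion" |
                  (include_excisions & te$event_type == "excision"), ,
                drop = FALSE]
    for (ctg in unique(variants$contig)) {
      bp <- tesub$breakpoint[tesub$contig == ctg]
      if (!length(bp)) next
      sel <- variants$contig == ctg
      d <- vapply(variants$pos[sel], function(p) min(abs(p - bp)), 0)
      near[sel] <- near[sel] | d <= proximity_bp
    }
  }
  if (!is.null(sv) && nrow(sv)) {
    for (ctg in unique(variants$contig)) {
      ss <- sv[sv$contig == ctg, , drop = FALSE]
      if (!nrow(ss)) next
      sel <- which(variants$contig == ctg)
      for (i in sel) {
        p <- variants$pos[i]
        inside <- any(p >= ss$start & p <= ss$end)
        d <- if (inside) 0 else min(pmin(abs(p - ss$start), abs(p - ss$end)))
        near[i] <- near[i] || d <= proximity_bp
      }
    }
  }
  rej <- variants[near, , drop = FALSE]
  if (nrow(rej)) rej$reason <- "near_sv_te" else rej$reason <- character(0)
  list(pass = variants[!near, , drop = FALSE], rejections = rej)
}

#' Filter structural-variant records
#'
#' A record survives iff it is carried by exactly one line, every line of its
#' analysis block is genotyped at the locus, it has at least
#' `sv_min_support` spanning OR split reads, and its quality equals the
#' caller's maximum possible score.
#'
#' @param sv SV data frame (see [read_sv_table()]).
#' @param thresholds A [filter_thresholds()] (uses `sv_min_support`).
#' @param quality_max The dialect's maximum quality score; defaults to the
#'   maximum observed in the table.
#' @param blocks Optional named vector mapping line id to analysis-block id;
#'   `genotyped` completeness is assessed within the carrier's block
#'   (default: one block containing all genotyped lines of the panel).
#' @param panel_lines All panel line ids (needed for the default block).
#' @return List with `pass` and `rejections` (reason one of `shared`,
#'   `not_genotyped_all`, `low_support`, `not_max_quality`).
#' @export
filter_sv_records <- function(sv, thresholds = filter_thresholds(),
                              quality_max = NULL, blocks = NULL,
                              panel_lines = NULL) {
  if (!nrow(sv)) return(list(pass = sv, rejections = cbind(sv, reason = character(0))))
  if (is.null(quality_max)) quality_max <- max(sv$quality)
  reason <- rep(NA_character_, nrow(sv))
  n_carr <- lengths(sv$carriers)
  reason[n_carr != 1] <- "shared"
  block_of <- function(line) if (is.null(blocks)) "all" else blocks[[line]]
  for (i in which(is.na(reason))) {
    carrier <- sv$carriers[[i]][1]
    expected <- if (is.null(blocks)) {
      if (is.null(panel_lines)) sv$genotyped[[i]] else panel_lines
    } else names(blocks)[blocks == block_of(carrier)]
    if (!all(expected %in% sv$genotyped[[i]])) reason[i] <- "not_genotyped_all"
  }
  low <- is.na(reason) & !(sv$spanning_reads >= thresholds$sv_min_support |
                             sv$split_reads >= thresholds$sv_min_support)
  reason[low] <- "low_support"
  reason[is.na(reason) & sv$quality != quality_max] <- "not_max_quality"
  keep <- is.na(reason)
  rej <- sv[!keep, , drop = FALSE]
  if (nrow(rej)) rej$reason <- reason[!keep] else rej$reason <- character(0)
  list(pass = sv[keep, , drop = FALSE], rejections = rej)
}

variant_is_snv <- function(ref, alt) nchar(ref) == 1 & nchar(alt) == 1

#' Cluster surviving variants of one line into mutation events
#'
#' Per (line, contig), variants sorted by position are chained by single
#' linkage: consecutive positions at gap `<= cluster_bp` (inclusive) join one
#' chain, so a chain may span more than `cluster_bp` end to end. Chains of
#' one variant become SNV or INDEL events; larger chains become MNV (all
#' members SNVs) or COMPLEX (at least one INDEL). Each chain contributes
#' exactly one event and every variant belongs to exactly one event. Output
#' is independent of input row order.
#'
#' @param variants Surviving candidate data frame (columns `line_id`,
#'   `contig`, `pos`, `ref`, `alt`, `genotype`).
#' @param cluster_bp Inclusive chaining gap.
#' @param pairwise With `pairwise = TRUE`, chains additionally break so that
#'   all members of an event are pairwise within `cluster_bp` (the stricter
#'   reading of "within 1 kb"); default is plain single linkage.
#' @return Data frame of mutation events: `line_id`, `category`, `contig`,
#'   `start`, `end`, `n_members`, `zygosity`, plus list-columns
#'   `member_pos` and `member_rows` (row indices into `variants`).
#' @export
cluster_variants <- function(variants, cluster_bp = 1000, pairwise = FALSE) {
  if (!nrow(variants)) {
    return(data.frame(line_id = character(), category = character(),
                      contig = character(), start = integer(),
                      end = integer(), n_members = integer(),
                      zygosity = character()))
  }
  ord <- order(variants$line_id, variants$contig, variants$pos, variants$alt)
  v <- variants[ord, , drop = FALSE]
  v$.row <- ord
  key <- paste(v$line_id, v$contig, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    s <- v[key == k, , drop = FALSE]
    gap_break <- c(FALSE, diff(s$pos) > cluster_bp)
    chain <- cumsum(gap_break)
    if (pairwise) {
      # additionally break when the span from the chain anchor exceeds the gap
      anchor <- s$pos[1]; cid <- 0; chain2 <- integer(nrow(s))
      for (i in seq_len(nrow(s))) {
        if (i > 1 && (gap_break[i] || s$pos[i] - anchor > cluster_bp)) {
          cid <- cid + 1; anchor <- s$pos[i]
        }
        chain2[i] <- cid
      }
      chain <- chain2
    }
    for (cid in unique(chain)) {
      m <- s[chain == cid, , drop = FALSE]
      snv <- variant_is_snv(m$ref, m$alt)
      category <- if (nrow(m) == 1) {
        if (snv[1]) "SNV" else "INDEL"
      } else if (all(snv)) "MNV" else "COMPLEX"
      out[[length(out) + 1]] <- data.frame(
        line_id = m$line_id[1], category = category, contig = m$contig[1],
        start = min(m$pos), end = max(m$pos), n_members = nrow(m),
        zygosity = classify_zygosity(m$genotype), stringsAsFactors = FALSE)
      out[[length(out)]]$member_pos <- I(list(m$pos))
      out[[length(out)]]$member_rows <- I(list(m$.row))
    }
  }
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$line_id, ev$contig, ev$start), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Classify the zygosity of a mutation event
#'
#' Homozygous iff every member genotype is `hom_alt`, heterozygous iff every
#' member is `het`, otherwise mixed.
#'
#' @param genotypes Character vector of member genotypes.
#' @return One of `"homozygous"`, `"heterozygous"`, `"mixed"`.
#' @export
classify_zygosity <- function(genotypes) {
  if (all(genotypes == "hom_alt")) "homozygous"
  else if (all(genotypes == "het")) "heterozygous"
  else "mixed"
}

#' Run the full small-variant calling pipeline on a panel
#'
#' Chains line-unique selection, the variant filter stack, SV filtering, TE
#' merging, SV/TE proximity exclusion and event clustering, and appends the
#' surviving SVs as single-member events. Rejections from every stage are
#' concatenated with a `stage` column.
#'
#' @param panel A [variant_panel()].
#' @param sv SV call table (see [read_sv_table()]), or NULL.
#' @param te_calls TE call table (see [read_te_calls()]), or NULL.
#' @param meta [line_metadata()].
#' @param thresholds A [filter_thresholds()].
#' @param sv_quality_max Maximum possible SV quality score (see
#'   [filter_sv_records()]).
#' @param genes Optional gene [interval_track()]; adds a `genic` flag.
#' @param consequences Optional data frame (`contig`, `pos`, `consequence`)
#'   of input consequence annotations, joined onto events by first member.
#' @return List with `events`, `sv_events`, `te_events`, `te_de_novo`,
#'   `rejections`.
#' @export
call_mutations <- function(panel, sv = NULL, te_calls = NULL, meta,
                           thresholds = filter_thresholds(),
                           sv_quality_max = NULL, genes = NULL,
                           consequences = NULL) {
  uniq <- select_line_unique(panel)
  filt <- apply_variant_filters(uniq$candidates, thresholds, meta)
  sv_res <- if (!is.null(sv) && nrow(sv))
    filter_sv_records(sv, thresholds, quality_max = sv_quality_max,
                      panel_lines = meta$line_id)
  else list(pass = NULL, rejections = NULL)
  te_events <- if (!is.null(te_calls) && nrow(te_calls))
    merge_te_calls(te_calls, thresholds$te_merge_bp)
  else NULL
  prox <- exclude_near_sv_te(filt$pass, sv_res$pass, te_events,
                             thresholds$proximity_bp)
  events <- cluster_variants(prox$pass, thresholds$cluster_bp)
  if (!is.null(sv_res$pass) && nrow(sv_res$pass)) {
    svp <- sv_res$pass
    sv_ev <- data.frame(line_id = vapply(svp$carriers, `[[`, "", 1),
                        category = "SV", contig = svp$contig,
                        start = svp$start, end = svp$end, n_members = 1L,
                        zygosity = NA_character_, stringsAsFactors = FALSE)
    sv_ev$member_pos <- I(as.list(svp$start))
    sv_ev$member_rows <- I(as.list(rep(NA_integer_, nrow(svp))))
    events <- rbind(events, sv_ev)
  }
  if (!is.null(genes) && nrow(events))
    events$genic <- points_in_track(genes, events$contig, events$start)
  if (!is.null(consequences) && nrow(events)) {
    key <- paste(consequences$contig, consequences$pos)
    events$consequence <- consequences$consequence[
      match(paste(events$contig, events$start), key)]
  }
  stage_rej <- function(df, stage) {
    if (is.null(df) || !nrow(df)) return(NULL)
    data.frame(stage = stage, contig = df$contig, pos = df$pos %||% df$start,
               alt = if ("alt" %in% names(df)) df$alt else NA_character_,
               reason = df$reason, stringsAsFactors = FALSE)
  }
  rejections <- rbind(stage_rej(uniq$rejections, "line_unique"),
                      stage_rej(filt$rejections, "hard_filters"),
                      stage_rej(prox$rejections, "proximity"))
  list(events = events, sv_events = sv_res$pass, te_events = te_events,
       te_de_novo = if (!is.null(te_events)) select_de_novo(te_events)$events,
       rejections = rejections, sv_rejections = sv_res$rejections)
}
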