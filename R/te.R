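#' Merge TE calls across lines into events
#'
#' Calls of the same family, contig and event type whose breakpoints chain by
#' single linkage at gap `<= te_merge_bp` (inclusive) are treated as one
#' event; different families never merge. Merging is order-invariant and
#' idempotent, and the total member count over events equals the input call
#' count.
#'
#' @param calls TE call data frame (see [read_te_calls()]).
#' @param te_merge_bp Inclusive single-linkage gap (bp).
#' @return Data frame of TE events: `family`, `contig`, `event_type`,
#'   `breakpoint` (median of member breakpoints), `n_members`, `n_lines`,
#'   plus list-columns `lines` and `member_rows`. Events carry a
#'   `de_novo` flag (carrier-set size 1). The excision caveat applies: an
#'   apparent excision cannot be distinguished from a deletion spanning the
#'   TE.
#' @export
merge_te_calls <- function(calls, te_merge_bp = 50) {
  if (!nrow(calls)) {
    out <- data.frame(family = character(), contig = character(),
                      event_type = character(), breakpoint = numeric(),
                      n_members = integer(), n_lines = integer(),
                      de_novo = logical())
    return(out)
  }
  ord <- order(calls$family, calls$contig, calls$event_type, calls$breakpoint)
  s <- calls[ord, , drop = FALSE]
  s$.row <- ord
  key <- paste(s$family, s$contig, s$event_type, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    g <- s[key == k, , drop = FALSE]
    chain <- cumsum(c(FALSE, diff(g$breakpoint) > te_merge_bp))
    for (cid in unique(chain)) {
      m <- g[chain == cid, , drop = FALSE]
      lines <- unique(m$line_id)
      row <- data.frame(family = m$family[1], contig = m$contig[1],
                        event_type = m$event_type[1],
                        breakpoint = stats::median(m$breakpoint),
                        n_members = nrow(m), n_lines = length(lines),
                        de_novo = length(lines) == 1,
                        stringsAsFactors = FALSE)
      row$lines <- I(list(lines))
      row$member_rows <- I(list(m$.row))
      out[[length(out) + 1]] <- row
    }
  }
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$family, ev$contig, ev$event_type, ev$breakpoint), ,
           drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Keep only de novo TE events
#'
#' De novo events are carried by exactly one line; events present in two or
#' more lines are logged as `segregating_or_recurrent` (detection error,
#' recurrent insertion, or variation segregating in the ancestral stock).
#'
#' @param events Merged TE events from [merge_te_calls()].
#' @return List with `events` (de novo only) and `rejections`.
#' @export
select_de_novo <- function(events) {
  keep <- events$n_lines == 1
  rej <- events[!keep, , drop = FALSE]
  if (nrow(rej)) rej$reason <- "segregating_or_recurrent"
  else rej$reason <- character(0)
  list(events = events[keep, , drop = FALSE], rejections = rej)
}

#' Per-genome TE mutation rates
#'
#' Rates are events per genome per generation: count divided by the summed
#' nominal line generations (TE rates are per line-generation, so the
#' chromosome-copy generation adjustment used for per-site rates does not
#' apply). Confidence intervals are a percentile bootstrap over lines.
#'
#' @param events De novo TE events (see [select_de_novo()]).
#' @param meta [line_metadata()].
#' @param by `"overall"`, `"group"`, `"event_type"`, `"family"`, or
#'   `"group_event_type"`.
#' @param boot,seed,conf Bootstrap replicates, RNG seed, CI level.
#' @return Data frame with one [estimate_rate()] row per stratum.
#' @export
te_rates <- function(events, meta, by = c("group", "overall", "event_type",
                                          "family", "group_event_type"),
                     boot = 10000, seed = 1, conf = 0.95) {
  by <- match.arg(by)
  carrier <- vapply(events$lines, `[[`, "", 1)
  strata <- switch(by,
    overall = list(all = rep(TRUE, nrow(events))),
    group = split_flags(events, meta$treatment[match(carrier, meta$line_id)]),
    event_type = split_flags(events, events$event_type),
    family = split_flags(events, events$family),
    group_event_type = split_flags(
      events, paste(meta$treatment[match(carrier, meta$line_id)],
                    events$event_type, sep = ".")))
  out <- list()
  for (nm in names(strata)) {
    sel <- strata[[nm]]
    lines_in <- if (by %in% c("group", "group_event_type")) {
      grp <- sub("\\..*$", "", nm)
      meta$line_id[meta$treatment == grp]
    } else meta$line_id
    counts <- table(factor(carrier[sel], levels = lines_in))
    opp <- meta$generations[match(lines_in, meta$line_id)]
    est <- estimate_rate(as.numeric(counts), opp,
                         scope = "per_genome_per_generation",
                         boot = boot, seed = seed, conf = conf)
    out[[nm]] <- data.frame(stratum = nm, rate = est$estimate,
                            lower = est$lower, upper = est$upper,
                            count = est$count, opportunity = est$opportunity,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

split_flags <- function(events, fac) {
  fac <- as.character(fac)
  sapply(unique(fac), function(l) fac == l, simplify = FALSE)
}

#' Are TE families mobilising independently?
#'
#' Two diagnostics on the per-line per-family de novo insertion counts:
#' (1) a Monte-Carlo chi-square test of the per-line number of active
#' families against a Poisson distribution with matched mean (parametric
#' bootstrap p with the +1/+1 correction), and (2) the pairwise Spearman
#' rank-correlation matrix of insertion counts for the `top_k` most active
#' families.
#'
#' @param counts Integer matrix (lines x families) of de novo insertion
#'   counts.
#' @param n_sims Monte-Carlo replicates for the dispersion test.
#' @param seed RNG seed.
#' @param top_k Number of most-active families for the correlation matrix.
#' @return List with `dispersion` (an `ma_test`) and `spearman` (list of
#'   `rho` matrix and `p` matrix).
#' @export
family_activity_tests <- function(counts, n_sims = 10000, seed = 1, top_k = 5) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("need at least two lines")
  active <- rowSums(counts > 0)
  stat_fun <- function(x) {
    lam <- mean(x)
    kmax <- max(x, 1)
    e <- length(x) * c(stats::dpois(0:(kmax - 1), lam),
                       1 - stats::ppois(kmax - 1, lam))
    o <- tabulate(x + 1L, nbins = kmax + 1L)
    sum((o - e)^2 / e)
  }
  obs <- stat_fun(active)
  lam_hat <- mean(active)
  sims <- withr::with_seed(seed, replicate(n_sims, {
    stat_fun(stats::rpois(length(active), lam_hat))
  }))
  p <- (1 + sum(sims >= obs)) / (n_sims + 1)
  disp <- ma_test("poisson_dispersion_mc", statistic = obs, p_value = p,
                  n = length(active),
                  options = list(n_sims = n_sims, seed = seed,
                                 lambda_hat = lam_hat))
  k <- min(top_k, ncol(counts))
  top <- order(colSums(counts), decreasing = TRUE)[seq_len(k)]
  sub <- counts[, top, drop = FALSE]
  rho <- suppressWarnings(stats::cor(sub, method = "spearman"))
  pm <- matrix(NA_real_, k, k, dimnames = dimnames(rho))
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j) {
    ct <- suppressWarnings(stats::cor.test(sub[, i], sub[, j],
                                           method = "spearman"))
    pm[i, j] <- pm[j, i] <- ct$p.value
  }
  list(dispersion = disp, spearman = list(rho = rho, p = pm))
}

#' X-chromosome enrichment of TE insertions
#'
#' Exact two-sided binomial test of the number of events on the X against the
#' null success probability expected from chromosome size
#' (X length / total analyzed length).
#'
#' @param events TE events (or any data frame with a `contig` column).
#' @param contig_lengths Named vector of analyzed contig lengths.
#' @param x_contig Name of the X chromosome contig.
#' @return An `ma_test`.
#' @export
x_enrichment <- function(events, contig_lengths, x_contig = "X") {
  if (!x_contig %in% names(contig_lengths))
    stop("x_contig not in contig_lengths")
  p0 <- contig_lengths[[x_contig]] / sum(contig_lengths)
  n <- nrow(events)
  x_n <- sum(events$contig == x_contig)
  bt <- stats::binom.test(x_n, n, p = p0)
  ma_test("x_enrichment_binomial", statistic = x_n / n, p_value = bt$p.value,
          n = n, options = list(null_prob = p0, x_count = x_n))
}
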