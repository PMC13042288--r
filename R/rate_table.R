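#' Per-type mutation rates by treatment group, with group differences
#'
#' Builds the headline rate table of an MA analysis: for each point-mutation
#' category (per callable site per adjusted generation) and each TE event
#' type (per genome per nominal generation), the per-group rate with a
#' bootstrap CI and the absolute group difference as a percent of the group
#' mean.
#'
#' @param events Point-mutation event data frame from [call_mutations()]
#'   (each MNV/COMPLEX group counts once).
#' @param te_de_novo De novo TE events, or NULL.
#' @param mask A `"callable_mask"` (for the per-site opportunity).
#' @param meta [line_metadata()].
#' @param boot,seed,conf Bootstrap settings passed to [estimate_rate()].
#' @return Data frame with one row per (type, comparison): per-group rates,
#'   CIs, and `difference_percent`.
#' @export
rate_table <- function(events, te_de_novo = NULL, mask, meta,
                       boot = 10000, seed = 1, conf = 0.95) {
  callable <- mask$summary$callable[mask$summary$contig == "total"]
  groups <- c("dsb_plus", "dsb_minus")
  one <- function(type, line_counts, per_site) {
    ests <- lapply(groups, function(g) {
      lines <- meta$line_id[meta$treatment == g]
      cnt <- line_counts[lines]
      opp <- if (per_site)
        callable * meta$adjusted_generations[match(lines, meta$line_id)]
      else meta$generations[match(lines, meta$line_id)]
      estimate_rate(cnt, opp,
                    scope = if (per_site) "per_site_per_generation"
                    else "per_genome_per_generation",
                    boot = boot, seed = seed, conf = conf)
    })
    data.frame(type = type,
               rate_dsb_plus = ests[[1]]$estimate,
               lower_dsb_plus = ests[[1]]$lower,
               upper_dsb_plus = ests[[1]]$upper,
               rate_dsb_minus = ests[[2]]$estimate,
               lower_dsb_minus = ests[[2]]$lower,
               upper_dsb_minus = ests[[2]]$upper,
               difference_percent = group_difference_percent(
                 ests[[1]]$estimate, ests[[2]]$estimate),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (cat in c("SNV", "INDEL", "MNV", "COMPLEX", "SV")) {
    cnt <- table(factor(events$line_id[events$category == cat],
                        levels = meta$line_id))
    rows[[cat]] <- one(cat, stats::setNames(as.numeric(cnt), meta$line_id),
                       per_site = TRUE)
  }
  if (!is.null(te_de_novo) && nrow(te_de_novo)) {
    carrier <- vapply(te_de_novo$lines, `[[`, "", 1)
    for (ty in c("insertion", "excision")) {
      cnt <- table(factor(carrier[te_de_novo$event_type == ty],
                          levels = meta$line_id))
      rows[[paste0("TE_", ty)]] <- one(paste0("TE_", ty),
                                       stats::setNames(as.numeric(cnt),
                                                       meta$line_id),
                                       per_site = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
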