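#' Configuration for a synthetic MA experiment
#'
#' Defines a miniature two-treatment mutation-accumulation panel with planted
#' ground truth. Defaults emulate the design this package targets: 16 lines
#' with programmed meiotic DSBs and 19 without, 30 generations of single-pair
#' bottlenecks, five recombining contigs, per-site point-mutation rates of a
#' few 1e-9 and per-genome TE rates differing between groups. All
#' probabilities are validated; every stochastic quantity is driven by a
#' single seed.
#'
#' @param seed Integer RNG seed.
#' @param n_lines Named pair: lines per treatment group.
#' @param generations MA generations.
#' @param contig_lengths Named contig lengths (bp); the X must be named "X".
#' @param snv_rate,indel_rate,mnv_rate,complex_rate,sv_rate Per callable site
#'   per generation event rates.
#' @param te_insertion_rate,te_excision_rate Per genome per generation, named
#'   by treatment group.
#' @param spectrum Named six-class SNV probabilities (sum 1); classes whose
#'   origin pair is G:C control the planted G/C-site bias.
#' @param indel_del_frac Probability an indel is a deletion.
#' @param del_size_mean,ins_size_mean Mean indel sizes (sizes are
#'   `1 + Poisson(mean - 1)`).
#' @param hom_frac_autosome,hom_frac_x Probability a planted mutation is
#'   homozygous on autosomes / the X (full-sib MA fixes most mutations; the X
#'   fixes faster).
#' @param median_depth,depth_theta Sequencing depth model: per-line median and
#'   negative-binomial dispersion for per-site depths.
#' @param repeat_frac Fraction of each contig that is repeat-masked.
#' @param fail_frac Fraction of each line's genome failing the nonvariant
#'   filters (depth anomalies).
#' @param gc_frac Reference G/C composition; `gc_block_mean` the mean length
#'   of uniform-composition blocks.
#' @param gc_block_mean See `gc_frac`.
#' @param genic_frac Fraction of the genome covered by gene intervals.
#' @param coding_frac Probability a genic SNV is coding (gets a consequence
#'   label); `nonsyn_frac` the probability a coding SNV is nonsynonymous.
#' @param nonsyn_frac See `coding_frac`.
#' @param artifacts_per_filter Planted filter-failing artifacts per named
#'   rule; `artifact_margin` the minimum margin by which the one violated
#'   threshold is exceeded.
#' @param artifact_margin See `artifacts_per_filter`.
#' @param n_shared_artifacts,n_uncalled_artifacts,n_proximity_artifacts
#'   Planted multi-line, missing-genotype and near-SV/TE artifacts.
#' @param sv_artifacts_per_reason Planted failing SV records per rejection
#'   reason.
#' @param sv_quality_max Maximum possible SV quality score in the dialect.
#' @param te_families Named sampling weights for TE families.
#' @param te_jitter_bp Breakpoint jitter: calls are reported within this many
#'   bp (uniform) of the true insertion site, below the 50 bp merge window.
#' @param n_segregating_te Multi-line (pre-existing) TE insertions planted to
#'   exercise merging and the de novo rule.
#' @param te_bad_jitter_frac Fraction of segregating TE events where one call
#'   is jittered beyond the merge window, planting a deliberate merge
#'   failure (0 by default).
#' @param n_windows Approximate number of chromatin-state windows.
#' @param state_freq Chromatin-state frequencies over RE/YE/BL/GR/BK.
#' @param beta Named regression coefficients of the window count model
#'   (intercept, gc, recomb, timing, RE, YE, BL, GR; BK is baseline).
#' @param theta nbinom2 dispersion of the window count model.
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              n_lines = c(dsb_plus = 16L, dsb_minus = 19L),
                              generations = 30L,
                              contig_lengths = c(`2L` = 1100000, `2R` = 1050000,
                                                 `3L` = 1100000, `3R` = 1150000,
                                                 X = 900000),
                              snv_rate = 5.85e-9,
                              indel_rate = 1.7e-9,
                              mnv_rate = 5e-10,
                              complex_rate = 6e-10,
                              sv_rate = 2.2e-10,
                              te_insertion_rate = c(dsb_plus = 0.482,
                                                    dsb_minus = 0.681),
                              te_excision_rate = c(dsb_plus = 0.119,
                                                   dsb_minus = 0.136),
                              spectrum = c(`A:T>C:G` = 0.09, `A:T>G:C` = 0.17,
                                           `A:T>T:A` = 0.08, `G:C>A:T` = 0.38,
                                           `G:C>C:G` = 0.11, `G:C>T:A` = 0.17),
                              indel_del_frac = 0.62,
                              del_size_mean = 7, ins_size_mean = 16,
                              hom_frac_autosome = 0.55, hom_frac_x = 0.70,
                              median_depth = 99, depth_theta = 25,
                              repeat_frac = 0.15, fail_frac = 0.003,
                              gc_frac = 0.43, gc_block_mean = 2000,
                              genic_frac = 0.75,
                              coding_frac = 0.6, nonsyn_frac = 0.71,
                              artifacts_per_filter = 3, artifact_margin = 0.5,
                              n_shared_artifacts = 15,
                              n_uncalled_artifacts = 8,
                              n_proximity_artifacts = 8,
                              sv_artifacts_per_reason = 2,
                              sv_quality_max = 999,
                              te_families = c(roo = 0.20, Doc = 0.15, S = 0.12,
                                              H = 0.10, I = 0.09, F = 0.08,
                                              Rt1a = 0.07, jockey = 0.07,
                                              copia = 0.06, `412` = 0.06),
                              te_jitter_bp = 20,
                              n_segregating_te = 25,
                              te_bad_jitter_frac = 0,
                              n_windows = 1000,
                              state_freq = c(RE = 0.12, YE = 0.18, BL = 0.08,
                                             GR = 0.07, BK = 0.55),
                              beta = c(intercept = -11.4, gc = -0.3,
                                       recomb = 0.2, timing = -0.1,
                                       RE = 0.3, YE = 0.2, BL = -0.1,
                                       GR = 0.1),
                              theta = 2) {
  cfg <- as.list(environment())
  probs <- c(cfg$spectrum, cfg$indel_del_frac, cfg$hom_frac_autosome,
             cfg$hom_frac_x, cfg$repeat_frac, cfg$fail_frac, cfg$gc_frac,
             cfg$genic_frac, cfg$te_bad_jitter_frac, cfg$state_freq)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$spectrum) - 1) > 1e-9) stop("spectrum must sum to 1")
  rates <- c(cfg$snv_rate, cfg$indel_rate, cfg$mnv_rate, cfg$complex_rate,
             cfg$sv_rate, cfg$te_insertion_rate, cfg$te_excision_rate)
  if (any(rates < 0)) stop("rates must be non-negative")
  if (cfg$theta <= 0) stop("theta must be positive")
  if (any(cfg$contig_lengths < 10000)) stop("contigs must be >= 10 kb")
  class(cfg) <- "simulation_config"
  cfg
}

# random disjoint cover of each contig at approximately `frac` of its length,
# built by alternating uncovered gaps and covered blocks
random_cover_track <- function(contig_lengths, frac, mean_len, value = NULL) {
  if (frac <= 0)
    return(interval_track(character(), integer(), integer()))
  ctg_v <- character(); s_v <- numeric(); e_v <- numeric()
  gap_mean <- mean_len * (1 - frac) / frac
  for (ctg in names(contig_lengths)) {
    L <- contig_lengths[[ctg]]
    pos <- 0
    repeat {
      pos <- pos + stats::rexp(1, 1 / gap_mean)
      if (pos >= L) break
      len <- max(1, round(stats::rexp(1, 1 / mean_len)))
      s <- floor(pos); e <- min(L, s + len)
      ctg_v <- c(ctg_v, ctg); s_v <- c(s_v, s); e_v <- c(e_v, e)
      pos <- e + 1
    }
  }
  interval_track(ctg_v, s_v, e_v,
                 if (!is.null(value)) rep(value, length(s_v)) else NULL)
}

# piecewise-constant covariate track covering (almost) the whole genome
random_value_track <- function(contig_lengths, mean_seg, rvalue,
                               drop_prob = 0) {
  ctg_v <- character(); s_v <- numeric(); e_v <- numeric(); val <- numeric()
  for (ctg in names(contig_lengths)) {
    L <- contig_lengths[[ctg]]
    pos <- 0
    while (pos < L) {
      len <- max(500, round(stats::rexp(1, 1 / mean_seg)))
      e <- min(L, pos + len)
      if (stats::runif(1) >= drop_prob) {
        ctg_v <- c(ctg_v, ctg); s_v <- c(s_v, pos); e_v <- c(e_v, e)
        val <- c(val, rvalue(1))
      }
      pos <- e
    }
  }
  interval_track(ctg_v, s_v, e_v, val)
}

#' Generate a synthetic MA experiment with planted ground truth
#'
#' Builds, deterministically from the config seed, every input the pipeline
#' consumes — a joint variant panel, SV and TE call tables, repeat mask, gene
#' and G/C interval tracks, recombination and replication-timing covariate
#' tracks, chromatin-state windows and line metadata — plus the planted truth
#' (`$truth`) recording every event, artifact and model parameter.
#'
#' Planted event counts are Poisson draws with mean `rate x callable sites x
#' generations` per line (per-site rates) or `rate x generations` (per-genome
#' TE rates). Point-mutation events are placed on callable sites, more than
#' 1 kb from any planted SV or TE insertion and from other events of the same
#' line, so that on this noise-free signal the filter stack is transparent.
#' Planted artifacts violate exactly one named rule each, by at least
#' `artifact_margin`, and carry their expected rejection reason.
#'
#' @param config A [simulation_config()].
#' @return List of class `"ma_experiment"` with elements `panel`, `sv`,
#'   `te_calls`, `repeat_mask`, `gc_track`, `genes`, `recomb`, `timing`,
#'   `windows`, `mask`, `meta`, `consequences`, `truth`, `config`.
#' @export
generate_experiment <- function(config = simulation_config()) {
  cfg <- config
  withr::with_seed(cfg$seed, generate_experiment_impl(cfg))
}

generate_experiment_impl <- function(cfg) {
  genome <- cfg$contig_lengths
  contigs <- names(genome)

  repeat_mask <- random_cover_track(genome, cfg$repeat_frac, 5000)
  gc_track <- random_cover_track(genome, cfg$gc_frac, cfg$gc_block_mean)
  genes <- random_cover_track(genome, cfg$genic_frac, 10000)

  line_ids <- c(sprintf("P%02d", seq_len(cfg$n_lines[["dsb_plus"]])),
                sprintf("M%02d", seq_len(cfg$n_lines[["dsb_minus"]])))
  treatment <- rep(c("dsb_plus", "dsb_minus"), cfg$n_lines)
  n_line <- length(line_ids)

  fail_tracks <- lapply(seq_len(n_line), function(i)
    random_cover_track(genome, cfg$fail_frac, 1000))
  mask <- compute_callable_mask(genome, repeat_mask, fail_tracks, gc_track)
  callable_total <- mask$summary$callable[mask$summary$contig == "total"]
  if (callable_total == 0) stop("configuration error: zero callable genome")

  md <- matrix(pmax(10, round(stats::rnorm(n_line * length(contigs),
                                           cfg$median_depth, 2))),
               n_line, length(contigs), dimnames = list(line_ids, contigs))
  meta <- line_metadata(line_ids, treatment, cfg$generations,
                        median_depth = md)

  # --- position sampling machinery -----------------------------------------
  zones <- stats::setNames(vector("list", length(contigs)), contigs)
  used <- stats::setNames(vector("list", length(contigs)), contigs)
  line_pos <- lapply(stats::setNames(seq_len(n_line), line_ids),
                     function(i) stats::setNames(vector("list",
                                                        length(contigs)),
                                                 contigs))
  margin <- 1100       # > proximity_bp + max breakpoint jitter
  line_margin <- 2100  # keeps clustered members of distinct events > 1 kb apart
  ctg_prob <- genome / sum(genome)
  clear_of <- function(v, p, m) is.null(v) || !length(v) || all(abs(v - p) > m)
  sample_site <- function(line = NULL, want_gc = NA, span = 1) {
    for (try in 1:4000) {
      ctg <- sample(contigs, 1, prob = ctg_prob)
      p <- sample.int(genome[[ctg]] - span, 1)
      if (!all(mask$mask[[ctg]][p:(p + span)])) next
      if (!is.na(want_gc) && mask$gc[[ctg]][p] != want_gc) next
      if (!clear_of(zones[[ctg]], p, margin)) next
      if (!clear_of(used[[ctg]], p, 2)) next
      if (!is.null(line) &&
          !clear_of(line_pos[[line]][[ctg]], p, line_margin)) next
      return(list(contig = ctg, pos = p))
    }
    stop("could not place an event; genome too constrained")
  }
  register <- function(site, line = NULL, zone = FALSE, span = 1) {
    ctg <- site$contig; p <- site$pos
    used[[ctg]] <<- c(used[[ctg]], p + seq_len(span) - 1)
    if (zone) zones[[ctg]] <<- c(zones[[ctg]], p)
    if (!is.null(line))
      line_pos[[line]][[ctg]] <<- c(line_pos[[line]][[ctg]], p)
    invisible(site)
  }

  # --- structural variants --------------------------------------------------
  sv_rows <- list(); sv_truth <- list()
  sv_id <- 0
  add_sv <- function(line, reason = NA_character_, carriers = line) {
    len <- sample(300:7800, 1)
    site <- sample_site(span = 1)
    start <- site$pos; end <- start + len - 1
    zones[[site$contig]] <<- c(zones[[site$contig]], start, end)
    used[[site$contig]] <<- c(used[[site$contig]], start)
    sv_id <<- sv_id + 1
    ok <- is.na(reason)
    spanning <- if (!is.na(reason) && reason == "low_support")
      sample(0:9, 1) else 10 + stats::rpois(1, 15)
    split <- if (!is.na(reason) && reason == "low_support")
      sample(0:9, 1) else stats::rpois(1, 15)
    quality <- if (!is.na(reason) && reason == "not_max_quality")
      cfg$sv_quality_max - sample(1:100, 1) else cfg$sv_quality_max
    row <- data.frame(contig = site$contig, start = start, end = end,
                      sv_type = sample(c("deletion", "insertion",
                                         "tandem_duplication"), 1,
                                       prob = c(0.45, 0.45, 0.1)),
                      length = len, quality = quality,
                      spanning_reads = spanning, split_reads = split,
                      stringsAsFactors = FALSE)
    row$carriers <- I(list(carriers))
    row$genotyped <- I(list(line_ids))
    sv_rows[[length(sv_rows) + 1]] <<- row
    if (ok) sv_truth[[length(sv_truth) + 1]] <<- data.frame(
      line_id = line, contig = site$contig, start = start, end = end,
      sv_type = row$sv_type, stringsAsFactors = FALSE)
    else sv_truth[[length(sv_truth) + 1]] <<- NULL
    invisible(row)
  }
  sv_art <- list()
  for (i in seq_len(n_line)) {
    lam <- cfg$sv_rate * callable_total * cfg$generations
    for (k in seq_len(stats::rpois(1, lam))) add_sv(line_ids[i])
  }
  for (reason in c("low_support", "not_max_quality", "shared")) {
    for (k in seq_len(cfg$sv_artifacts_per_reason)) {
      line <- sample(line_ids, 1)
      carriers <- if (reason == "shared") sample(line_ids, 2) else line
      row <- add_sv(line, reason = reason, carriers = carriers)
      sv_art[[length(sv_art) + 1]] <- data.frame(
        contig = row$contig, start = row$start, expected_reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  sv <- if (length(sv_rows)) do.call(rbind, sv_rows) else
    data.frame(contig = character(), start = integer(), end = integer(),
               sv_type = character(), length = integer(), quality = integer(),
               spanning_reads = integer(), split_reads = integer(),
               carriers = I(list()), genotyped = I(list()))

  # --- transposable elements ------------------------------------------------
  te_rows <- list(); te_truth <- list()
  jit <- function() sample(seq(-cfg$te_jitter_bp, cfg$te_jitter_bp), 1)
  add_te <- function(lines, type, planted = "de_novo") {
    fam <- sample(names(cfg$te_families), 1, prob = cfg$te_families)
    site <- sample_site()
    register(site, zone = (type == "insertion"))
    bad <- planted == "segregating" && length(lines) > 1 &&
      stats::runif(1) < cfg$te_bad_jitter_frac
    for (i in seq_along(lines)) {
      off <- if (bad && i == 1) sample(c(-1, 1), 1) * sample(60:120, 1)
        else jit()
      te_rows[[length(te_rows) + 1]] <<- data.frame(
        line_id = lines[i], family = fam, contig = site$contig,
        breakpoint = max(1, site$pos + off), event_type = type,
        support = 5 + stats::rpois(1, 10), stringsAsFactors = FALSE)
    }
    te_truth[[length(te_truth) + 1]] <<- data.frame(
      line_id = if (length(lines) == 1) lines else NA_character_,
      family = fam, contig = site$contig, breakpoint = site$pos,
      event_type = type, planted = if (bad) "segregating_bad_jitter"
        else planted, n_lines = length(lines), stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_line)) {
    grp <- treatment[i]
    n_ins <- stats::rpois(1, cfg$te_insertion_rate[[grp]] * cfg$generations)
    n_exc <- stats::rpois(1, cfg$te_excision_rate[[grp]] * cfg$generations)
    for (k in seq_len(n_ins)) add_te(line_ids[i], "insertion")
    for (k in seq_len(n_exc)) add_te(line_ids[i], "excision")
  }
  for (k in seq_len(cfg$n_segregating_te)) {
    lines <- sample(line_ids, sample(2:5, 1))
    add_te(lines, "insertion", planted = "segregating")
  }
  te_calls <- if (length(te_rows)) do.call(rbind, te_rows) else
    data.frame(line_id = character(), family = character(),
               contig = character(), breakpoint = integer(),
               event_type = character(), support = integer())

  # --- point mutations ------------------------------------------------------
  gc_classes <- startsWith(names(cfg$spectrum), "G:C")
  p_gc_origin <- sum(cfg$spectrum[gc_classes])
  draw_class <- function() {
    at_gc <- stats::runif(1) < p_gc_origin
    pool <- cfg$spectrum[gc_classes == at_gc]
    sample(names(pool), 1, prob = pool)
  }
  bases_of <- function(cls) {
    # concrete ref/alt on a random strand, consistent with the class
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    from <- if (startsWith(cls, "G:C")) sample(c("G", "C"), 1)
      else sample(c("A", "T"), 1)
    alt_purine <- substr(sub(".*>", "", cls), 1, 1)
    alt <- if (from %in% c("A", "G")) alt_purine else comp[[alt_purine]]
    c(ref = from, alt = alt)
  }
  zyg_draw <- function(ctg) {
    p <- if (ctg == "X") cfg$hom_frac_x else cfg$hom_frac_autosome
    if (stats::runif(1) < p) "homozygous" else "heterozygous"
  }
  var_rows <- list(); ev_truth <- list(); cons_rows <- list()
  add_members <- function(line, members, category, zyg, sites) {
    ctg <- sites[[1]]$contig
    pos <- vapply(sites, `[[`, 0L, "pos")
    genic <- points_in_track(genes, rep(ctg, length(pos)), pos)
    for (j in seq_along(members)) {
      m <- members[[j]]
      var_rows[[length(var_rows) + 1]] <<- data.frame(
        contig = ctg, pos = pos[j], ref = m$ref, alt = m$alt,
        line_id = line,
        genotype = if (zyg == "homozygous") "hom_alt" else "het",
        kind = m$kind, stringsAsFactors = FALSE)
      if (m$kind == "SNV" && genic[j] && stats::runif(1) < cfg$coding_frac)
        cons_rows[[length(cons_rows) + 1]] <<- data.frame(
          contig = ctg, pos = pos[j],
          consequence = if (stats::runif(1) < cfg$nonsyn_frac)
            "nonsynonymous" else "synonymous", stringsAsFactors = FALSE)
    }
    ev_truth[[length(ev_truth) + 1]] <<- data.frame(
      line_id = line, category = category, contig = ctg,
      start = min(pos), end = max(pos), n_members = length(pos),
      zygosity = zyg, genic = genic[which.min(pos)],
      class = if (category == "SNV") members[[1]]$class else NA_character_,
      size = if (category == "INDEL") members[[1]]$size else NA_real_,
      stringsAsFactors = FALSE)
  }
  make_snv <- function(line) {
    cls <- draw_class()
    want_gc <- startsWith(cls, "G:C")
    site <- sample_site(line, want_gc = want_gc)
    b <- bases_of(cls)
    register(site, line)
    list(site = site, member = list(ref = b[["ref"]], alt = b[["alt"]],
                                    kind = "SNV", class = cls, size = NA))
  }
  make_indel <- function(line, site = NULL) {
    if (is.null(site)) site <- sample_site(line, span = 45)
    del <- stats::runif(1) < cfg$indel_del_frac
    size <- 1 + stats::rpois(1, (if (del) cfg$del_size_mean else
                                   cfg$ins_size_mean) - 1)
    anchor <- sample(c("A", "C", "G", "T"), 1)
    extra <- paste(sample(c("A", "C", "G", "T"), size, replace = TRUE),
                   collapse = "")
    ref <- if (del) paste0(anchor, extra) else anchor
    alt <- if (del) anchor else paste0(anchor, extra)
    register(site, line, span = if (del) size + 1 else 1)
    list(site = site, member = list(ref = ref, alt = alt, kind = "INDEL",
                                    class = NA, size = if (del) -size else size))
  }
  nearby_site <- function(line, anchor, want_gc = NA, span = 1) {
    ctg <- anchor$contig
    for (try in 1:400) {
      off <- sample(30:900, 1)
      p <- anchor$pos + off
      if (p + span > genome[[ctg]]) next
      if (!all(mask$mask[[ctg]][p:(p + span)])) next
      if (!is.na(want_gc) && mask$gc[[ctg]][p] != want_gc) next
      if (!clear_of(zones[[ctg]], p, margin)) next
      if (!clear_of(used[[ctg]], p, 2)) next
      return(list(contig = ctg, pos = p))
    }
    NULL
  }
  for (i in seq_len(n_line)) {
    line <- line_ids[i]
    opp <- callable_total * cfg$generations
    n_snv <- stats::rpois(1, cfg$snv_rate * opp)
    n_indel <- stats::rpois(1, cfg$indel_rate * opp)
    n_mnv <- stats::rpois(1, cfg$mnv_rate * opp)
    n_cpx <- stats::rpois(1, cfg$complex_rate * opp)
    for (k in seq_len(n_snv)) {
      s <- make_snv(line)
      add_members(line, list(s$member), "SNV", zyg_draw(s$site$contig),
                  list(s$site))
    }
    for (k in seq_len(n_indel)) {
      d <- make_indel(line)
      add_members(line, list(d$member), "INDEL", zyg_draw(d$site$contig),
                  list(d$site))
    }
    for (k in seq_len(n_mnv)) {
      repeat {
        s1 <- make_snv(line)
        cls2 <- draw_class()
        s2site <- nearby_site(line, s1$site,
                              want_gc = startsWith(cls2, "G:C"))
        if (!is.null(s2site)) break
      }
      b2 <- bases_of(cls2)
      register(s2site, line)
      m2 <- list(ref = b2[["ref"]], alt = b2[["alt"]], kind = "SNV",
                 class = cls2, size = NA)
      add_members(line, list(s1$member, m2), "MNV",
                  zyg_draw(s1$site$contig), list(s1$site, s2site))
    }
    for (k in seq_len(n_cpx)) {
      repeat {
        s1 <- make_snv(line)
        d2site <- nearby_site(line, s1$site, span = 45)
        if (!is.null(d2site)) break
      }
      d2 <- make_indel(line, site = d2site)
      add_members(line, list(s1$member, d2$member), "COMPLEX",
                  zyg_draw(s1$site$contig), list(s1$site, d2site))
    }
  }

  # --- planted artifacts ----------------------------------------------------
  art_rows <- list(); art_truth <- list()
  passing_ann <- function() list(
    MQ = round(stats::runif(1, 55, 60), 3),
    QD = round(stats::runif(1, 5, 30), 3),
    FS = round(stats::runif(1, 0, 20), 3),
    SOR = round(stats::runif(1, 0.3, 2), 3),
    MQRankSum = round(stats::runif(1, -2, 2), 3),
    ReadPosRankSum = round(stats::runif(1, -2, 2), 3))
  # coordinates the pipeline will actually exclude around: surviving SVs'
  # interval edges plus every reported insertion-call breakpoint
  live_zones <- stats::setNames(vector("list", length(contigs)), contigs)
  for (s in sv_truth) if (!is.null(s))
    live_zones[[s$contig]] <- c(live_zones[[s$contig]], s$start, s$end)
  for (r in te_rows) if (r$event_type == "insertion")
    live_zones[[r$contig]] <- c(live_zones[[r$contig]], r$breakpoint)
  add_artifact <- function(reason) {
    line <- sample(line_ids, 1)
    site <- if (reason == "near_sv_te") {
      # drop a filter-passing variant inside an exclusion zone
      repeat {
        ctg <- sample(contigs, 1, prob = ctg_prob)
        if (!length(live_zones[[ctg]])) next
        z <- sample(live_zones[[ctg]], 1)
        p <- z + sample(c(-1, 1), 1) * sample(10:900, 1)
        if (p < 1 || p > genome[[ctg]]) next
        if (!mask$mask[[ctg]][p]) next
        if (!clear_of(used[[ctg]], p, 2)) next
        break
      }
      list(contig = ctg, pos = p)
    } else sample_site()
    register(site)
    ann <- passing_ann()
    m <- cfg$artifact_margin
    med <- md[line, site$contig]
    depth <- NA; alt_reads <- NA; carriers <- line; miss <- character(0)
    if (reason == "min_MQ") ann$MQ <- round(50 - m - stats::runif(1, 0, 10), 3)
    if (reason == "min_QD") ann$QD <- round(2 - m - stats::runif(1, 0, 1), 3)
    if (reason == "max_FS") ann$FS <- round(60 + m + stats::runif(1, 0, 40), 3)
    if (reason == "max_SOR") ann$SOR <- round(3 + m + stats::runif(1, 0, 3), 3)
    if (reason == "max_abs_MQRankSum")
      ann$MQRankSum <- sample(c(-1, 1), 1) * round(8 + m + stats::runif(1, 0, 4), 3)
    if (reason == "max_abs_ReadPosRankSum")
      ann$ReadPosRankSum <- sample(c(-1, 1), 1) * round(4 + m + stats::runif(1, 0, 4), 3)
    if (reason == "depth_window")
      depth <- round(med * (2 + 0.5 + stats::runif(1, 0, 1)))
    if (reason == "min_alt_reads") alt_reads <- sample(1:9, 1)
    if (reason == "shared") carriers <- sample(line_ids, sample(2:4, 1))
    if (reason == "uncalled_site")
      miss <- sample(setdiff(line_ids, carriers), 1)
    b <- bases_of(draw_class())
    art_rows[[length(art_rows) + 1]] <<- list(
      contig = site$contig, pos = site$pos, ref = b[["ref"]],
      alt = b[["alt"]], ann = ann, carriers = carriers, missing = miss,
      depth = depth, alt_reads = alt_reads)
    art_truth[[length(art_truth) + 1]] <<- data.frame(
      contig = site$contig, pos = site$pos,
      expected_reason = reason, stringsAsFactors = FALSE)
  }
  filter_reasons <- c("min_MQ", "min_QD", "max_FS", "max_SOR",
                      "max_abs_MQRankSum", "max_abs_ReadPosRankSum",
                      "depth_window", "min_alt_reads")
  for (r in filter_reasons)
    for (k in seq_len(cfg$artifacts_per_filter)) add_artifact(r)
  for (k in seq_len(cfg$n_shared_artifacts)) add_artifact("shared")
  for (k in seq_len(cfg$n_uncalled_artifacts)) add_artifact("uncalled_site")
  if (length(zones) && any(lengths(zones) > 0))
    for (k in seq_len(cfg$n_proximity_artifacts)) add_artifact("near_sv_te")

  # --- assemble the variant panel ------------------------------------------
  panel <- build_panel(var_rows, art_rows, line_ids, md, cfg)

  # --- windows and covariate tracks ----------------------------------------
  recomb <- random_value_track(genome, 20000,
                               function(n) round(stats::rgamma(n, 4, 2), 4),
                               drop_prob = 0.02)
  timing <- random_value_track(genome, 30000,
                               function(n) round(stats::runif(n, -1, 1), 4),
                               drop_prob = 0.02)
  windows <- make_windows(genome, cfg$n_windows, cfg$state_freq)

  ev_df <- if (length(ev_truth)) do.call(rbind, ev_truth) else
    data.frame(line_id = character(), category = character(),
               contig = character(), start = integer(), end = integer(),
               n_members = integer(), zygosity = character(),
               genic = logical(), class = character(), size = numeric())
  te_df <- if (length(te_truth)) do.call(rbind, te_truth) else
    data.frame(line_id = character(), family = character(),
               contig = character(), breakpoint = integer(),
               event_type = character(), planted = character(),
               n_lines = integer())
  sv_df <- if (length(sv_truth)) do.call(rbind, sv_truth) else
    data.frame(line_id = character(), contig = character(),
               start = integer(), end = integer(), sv_type = character())
  art_df <- if (length(art_truth)) do.call(rbind, art_truth) else
    data.frame(contig = character(), pos = integer(),
               expected_reason = character())
  sv_art_df <- if (length(sv_art)) do.call(rbind, sv_art) else
    data.frame(contig = character(), start = integer(),
               expected_reason = character())

  # truth window counts, computed by direct interval lookup
  windows$n_point_true <- count_in_windows(windows, ev_df$contig, ev_df$start)
  consequences <- if (length(cons_rows)) do.call(rbind, cons_rows) else
    data.frame(contig = character(), pos = integer(),
               consequence = character())

  truth <- list(
    events = ev_df, te = te_df, sv = sv_df, artifacts = art_df,
    sv_artifacts = sv_art_df,
    rates = list(snv = cfg$snv_rate, indel = cfg$indel_rate,
                 mnv = cfg$mnv_rate, complex = cfg$complex_rate,
                 sv = cfg$sv_rate, te_insertion = cfg$te_insertion_rate,
                 te_excision = cfg$te_excision_rate),
    spectrum = cfg$spectrum,
    transition_fraction = sum(cfg$spectrum[.transition_classes]),
    gc_origin_fraction = sum(cfg$spectrum[startsWith(names(cfg$spectrum),
                                                     "G:C")]),
    beta = cfg$beta, theta = cfg$theta,
    callable_total = callable_total, seed = cfg$seed)

  structure(list(panel = panel, sv = sv, te_calls = te_calls,
                 repeat_mask = repeat_mask, gc_track = gc_track,
                 genes = genes, recomb = recomb, timing = timing,
                 windows = windows, mask = mask, meta = meta,
                 consequences = consequences, truth = truth, config = cfg),
            class = "ma_experiment")
}

count_in_windows <- function(windows, contig, pos1) {
  n <- integer(nrow(windows))
  for (ctg in unique(contig)) {
    sel <- which(windows$contig == ctg)
    if (!length(sel)) next
    p <- pos1[contig == ctg]
    starts <- windows$start[sel]
    idx <- findInterval(p - 1, starts)   # contiguous ascending windows
    idx <- idx[idx >= 1 & (p - 1) < windows$end[sel][idx]]
    tb <- table(idx)
    n[sel[as.integer(names(tb))]] <- n[sel[as.integer(names(tb))]] +
      as.integer(tb)
  }
  n
}

make_windows <- function(genome, n_windows, state_freq) {
  mean_len <- sum(genome) / n_windows
  ctg_v <- character(); s_v <- numeric(); e_v <- numeric()
  for (ctg in names(genome)) {
    L <- genome[[ctg]]
    pos <- 0
    while (pos < L) {
      len <- max(200, round(stats::rexp(1, 1 / mean_len)))
      e <- min(L, pos + len)
      ctg_v <- c(ctg_v, ctg); s_v <- c(s_v, pos); e_v <- c(e_v, e)
      pos <- e
    }
  }
  w <- data.frame(contig = ctg_v, start = s_v, end = e_v,
                  stringsAsFactors = FALSE)
  w$state <- sample(names(state_freq), nrow(w), replace = TRUE,
                    prob = state_freq)
  w
}

build_panel <- function(var_rows, art_rows, line_ids, md, cfg) {
  n_true <- length(var_rows)
  n_art <- length(art_rows)
  n <- n_true + n_art
  ann_cols <- c("MQ", "QD", "FS", "SOR", "MQRankSum", "ReadPosRankSum")
  variants <- data.frame(contig = character(n), pos = integer(n),
                         ref = character(n), alt = character(n),
                         stringsAsFactors = FALSE)
  for (k in ann_cols) variants[[k]] <- NA_real_
  n_line <- length(line_ids)
  gt <- matrix("hom_ref", n, n_line, dimnames = list(NULL, line_ids))
  ad <- matrix(0L, n, n_line, dimnames = list(NULL, line_ids))
  dp <- matrix(0L, n, n_line, dimnames = list(NULL, line_ids))

  draw_dp <- function(line, contig) {
    med <- md[line, contig]
    d <- stats::rnbinom(1, mu = med, size = cfg$depth_theta)
    min(max(d, ceiling(0.6 * med)), floor(1.8 * med))
  }
  fill_row <- function(i, contig, pos, ref, alt, ann, carriers, genotype,
                       missing_lines = character(0), depth = NA,
                       alt_reads = NA) {
    variants$contig[i] <<- contig; variants$pos[i] <<- as.integer(pos)
    variants$ref[i] <<- ref; variants$alt[i] <<- alt
    for (k in ann_cols) variants[[k]][i] <<- ann[[k]]
    for (l in line_ids) {
      if (l %in% missing_lines) {
        gt[i, l] <<- "missing"; ad[i, l] <<- NA_integer_; dp[i, l] <<- NA_integer_
      } else if (l %in% carriers) {
        d <- if (!is.na(depth)) depth else draw_dp(l, contig)
        a <- if (!is.na(alt_reads)) alt_reads
          else if (genotype == "hom_alt") d
          else {
            # het support: binomial split, redrawn into the passing range so
            # planted signal is transparent to the alt-read filter
            aa <- stats::rbinom(1, d, 0.5)
            while (aa < 10) aa <- stats::rbinom(1, d, 0.5)
            aa
          }
        gt[i, l] <<- genotype; ad[i, l] <<- as.integer(a)
        dp[i, l] <<- as.integer(d)
      } else {
        dp[i, l] <<- as.integer(draw_dp(l, contig))
        ad[i, l] <<- 0L
      }
    }
  }
  i <- 0
  ann_pass <- function() list(
    MQ = round(stats::runif(1, 55, 60), 3),
    QD = round(stats::runif(1, 5, 30), 3),
    FS = round(stats::runif(1, 0, 20), 3),
    SOR = round(stats::runif(1, 0.3, 2), 3),
    MQRankSum = round(stats::runif(1, -2, 2), 3),
    ReadPosRankSum = round(stats::runif(1, -2, 2), 3))
  for (vr in var_rows) {
    i <- i + 1
    fill_row(i, vr$contig, vr$pos, vr$ref, vr$alt, ann_pass(), vr$line_id,
             vr$genotype)
  }
  for (ar in art_rows) {
    i <- i + 1
    fill_row(i, ar$contig, ar$pos, ar$ref, ar$alt, ar$ann, ar$carriers,
             "het", missing_lines = ar$missing, depth = ar$depth,
             alt_reads = ar$alt_reads)
  }
  ord <- order(variants$contig, variants$pos, variants$alt)
  variant_panel(variants[ord, , drop = FALSE], gt[ord, , drop = FALSE],
                ad[ord, , drop = FALSE], dp[ord, , drop = FALSE], line_ids)
}

#' Simulate per-window counts from the nbinom2 regression model
#'
#' Draws counts with mean `exp(X beta) * power` and nbinom2 dispersion
#' `theta` on an annotated window table (covariates are divided by their
#' mean over included windows, exactly as [fit_nb()] does). Optionally plants
#' treatment-interaction effects for the stacked two-treatment design.
#'
#' @param windows Annotated window data frame (needs `gc_frac`, `recomb`,
#'   `timing`, `state`, `power`, `excluded`).
#' @param beta Named coefficients: `intercept`, `gc`, `recomb`, `timing`,
#'   and state offsets `RE`, `YE`, `BL`, `GR` (baseline BK).
#' @param theta nbinom2 dispersion.
#' @param seed RNG seed.
#' @return Integer counts for the non-excluded windows, NA elsewhere.
#' @export
simulate_window_counts <- function(windows, beta, theta, seed = 1) {
  d <- windows[!windows$excluded, , drop = FALSE]
  eta <- window_linear_predictor(d, beta)
  mu <- exp(eta) * d$power
  counts <- withr::with_seed(seed,
                             stats::rnbinom(nrow(d), mu = mu, size = theta))
  out <- rep(NA_integer_, nrow(windows))
  out[!windows$excluded] <- counts
  out
}

window_linear_predictor <- function(d, beta) {
  gc_s <- d$gc_frac / mean(d$gc_frac)
  rec_s <- d$recomb / mean(d$recomb)
  eta <- beta[["intercept"]] + beta[["gc"]] * gc_s +
    beta[["recomb"]] * rec_s + beta[["timing"]] * d$timing
  for (st in c("RE", "YE", "BL", "GR"))
    eta <- eta + ifelse(d$state == st, beta[[st]], 0)
  eta
}

#' Score pipeline output against the planted truth
#'
#' Matches recovered events to planted events — exactly by (line, category,
#' contig, start) for point mutations and SVs, and within the TE merge window
#' by (line, family, type) for TE events — and reports per-category true
#' positives, false positives and false negatives, precision and recall,
#' the rate-estimation error for SNVs, and the fate of every planted
#' artifact.
#'
#' @param pipeline Output of [call_mutations()].
#' @param truth The `$truth` element of an [generate_experiment()] result.
#' @param mask,meta Optional; when supplied, the SNV rate is re-estimated and
#'   compared to the planted rate.
#' @param te_merge_bp Breakpoint tolerance for TE matching.
#' @return List of class `"recovery_report"`.
#' @export
score_recovery <- function(pipeline, truth, mask = NULL, meta = NULL,
                           te_merge_bp = 50) {
  ev <- pipeline$events
  tr <- truth$events
  if (nrow(ev) && length(setdiff(unique(ev$contig), unique(c(tr$contig,
                                                             truth$te$contig,
                                                             truth$sv$contig)))) &&
      nrow(tr) == 0)
    stop("mismatched contig sets between pipeline output and truth")
  cats <- c("SNV", "INDEL", "MNV", "COMPLEX", "SV")
  per_cat <- lapply(cats, function(cat) {
    if (cat == "SV") {
      got <- ev[ev$category == "SV", c("line_id", "contig", "start"),
                drop = FALSE]
      want <- truth$sv[, c("line_id", "contig", "start"), drop = FALSE]
    } else {
      got <- ev[ev$category == cat, c("line_id", "contig", "start"),
                drop = FALSE]
      want <- tr[tr$category == cat, c("line_id", "contig", "start"),
                 drop = FALSE]
    }
    gk <- do.call(paste, got); wk <- do.call(paste, want)
    tp <- sum(gk %in% wk)
    data.frame(category = cat, tp = tp, fp = nrow(got) - tp,
               fn = nrow(want) - tp,
               precision = if (nrow(got)) tp / nrow(got) else NA_real_,
               recall = if (nrow(want)) tp / nrow(want) else NA_real_,
               stringsAsFactors = FALSE)
  })
  per_cat <- do.call(rbind, per_cat)

  te_truth <- truth$te[truth$te$planted == "de_novo", , drop = FALSE]
  tep <- pipeline$te_de_novo
  te_tp <- 0
  if (!is.null(tep) && nrow(tep) && nrow(te_truth)) {
    taken <- logical(nrow(tep))
    carrier <- vapply(tep$lines, `[[`, "", 1)
    for (i in seq_len(nrow(te_truth))) {
      cand <- which(!taken & carrier == te_truth$line_id[i] &
                      tep$family == te_truth$family[i] &
                      tep$contig == te_truth$contig[i] &
                      tep$event_type == te_truth$event_type[i] &
                      abs(tep$breakpoint - te_truth$breakpoint[i]) <=
                        te_merge_bp)
      if (length(cand)) { taken[cand[1]] <- TRUE; te_tp <- te_tp + 1 }
    }
  }
  n_tep <- if (is.null(tep)) 0 else nrow(tep)
  te_row <- data.frame(category = "TE", tp = te_tp, fp = n_tep - te_tp,
                       fn = nrow(te_truth) - te_tp,
                       precision = if (n_tep) te_tp / n_tep else NA_real_,
                       recall = if (nrow(te_truth)) te_tp / nrow(te_truth)
                         else NA_real_, stringsAsFactors = FALSE)
  per_cat <- rbind(per_cat, te_row)

  # artifact bookkeeping: every planted should-fail candidate must be absent
  # from the final events and logged with its expected reason
  art <- truth$artifacts
  art_report <- NULL
  if (nrow(art)) {
    rej <- pipeline$rejections
    ev_keys <- if (nrow(ev))
      unlist(mapply(function(ctg, mp) paste(ctg, mp), ev$contig,
                    ev$member_pos, SIMPLIFY = FALSE))
    else character(0)
    obs_reason <- rej$reason[match(paste(art$contig, art$pos),
                                   paste(rej$contig, rej$pos))]
    art_report <- data.frame(art,
                             observed_reason = obs_reason,
                             leaked = paste(art$contig, art$pos) %in% ev_keys,
                             stringsAsFactors = FALSE)
  }
  rate_check <- NULL
  if (!is.null(mask) && !is.null(meta)) {
    callable <- mask$summary$callable[mask$summary$contig == "total"]
    counts <- table(factor(ev$line_id[ev$category == "SNV"],
                           levels = meta$line_id))
    est <- estimate_rate(as.numeric(counts),
                         callable * meta$adjusted_generations)
    rate_check <- list(estimate = est, truth = truth$rates$snv,
                      relative_error = est$estimate / truth$rates$snv - 1,
                      covered = est$lower <= truth$rates$snv &
                        truth$rates$snv <= est$upper)
  }
  structure(list(per_category = per_cat, artifacts = art_report,
                 rate_check = rate_check),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery vs planted truth:\n")
  print(x$per_category, row.names = FALSE, digits = 3)
  if (!is.null(x$artifacts)) {
    ok <- sum(x$artifacts$observed_reason == x$artifacts$expected_reason,
              na.rm = TRUE)
    cat(sprintf("Artifacts: %d/%d rejected with expected reason; %d leaked\n",
                ok, nrow(x$artifacts), sum(x$artifacts$leaked)))
  }
  if (!is.null(x$rate_check))
    cat(sprintf("SNV rate: est %.3e vs planted %.3e (CI covers: %s)\n",
                x$rate_check$estimate$estimate, x$rate_check$truth,
                x$rate_check$covered))
  invisible(x)
}

#' Write a synthetic experiment to disk in its exchange formats
#'
#' Emits the multi-sample VCF, TE and SV TSVs, BED tracks, window and line
#' metadata tables and `truth.json` into a directory. Two runs with the same
#' config produce byte-identical files.
#'
#' @param exp An [generate_experiment()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_vcf(exp$panel, fp("panel.vcf"), exp$config$contig_lengths)
  write_te_calls(exp$te_calls, fp("te_calls.tsv"))
  write_sv_table(exp$sv, fp("sv_calls.tsv"))
  write_intervals(exp$repeat_mask, fp("repeats.bed"))
  write_intervals(exp$gc_track, fp("gc.bed"))
  write_intervals(exp$genes, fp("genes.bed"))
  write_intervals(exp$recomb, fp("recomb.bed"))
  write_intervals(exp$timing, fp("timing.bed"))
  utils::write.table(exp$windows, fp("windows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_line_metadata(exp$meta, fp("lines.tsv"))
  jsonlite::write_json(exp$truth, fp("truth.json"), dataframe = "columns",
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
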