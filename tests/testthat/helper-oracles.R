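# Independent naive reimplementations used as oracles. These deliberately
# share no code with the package internals.

# --- minimal VCF parser ------------------------------------------------------
naive_read_vcf <- function(path, lines) {
  raw <- readLines(path)
  body <- raw[!startsWith(raw, "#")]
  header <- raw[startsWith(raw, "#CHROM")]
  samples <- strsplit(header, "\t")[[1]][-(1:9)]
  ann_keys <- c("MQ", "QD", "FS", "SOR", "MQRankSum", "ReadPosRankSum")
  rows <- list(); gt <- list(); ad <- list(); dp <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t")[[1]]
    info <- strsplit(f[8], ";")[[1]]
    ann <- rep(NA_real_, 6); names(ann) <- ann_keys
    if (f[8] != ".") {
      for (kv in info) {
        p <- strsplit(kv, "=")[[1]]
        if (p[1] %in% ann_keys) ann[p[1]] <- as.numeric(p[2])
      }
    }
    alts <- strsplit(f[5], ",")[[1]]
    for (k in seq_along(alts)) {
      g <- character(length(samples)); a <- integer(length(samples))
      d <- integer(length(samples))
      for (j in seq_along(samples)) {
        cell <- strsplit(f[9 + j], ":")[[1]]
        als <- strsplit(cell[1], "[/|]")[[1]]
        if (any(als == ".")) {
          g[j] <- "missing"; a[j] <- NA; d[j] <- NA
        } else {
          cp <- sum(als == as.character(k))
          g[j] <- c("hom_ref", "het", "hom_alt")[cp + 1]
          a[j] <- as.integer(strsplit(cell[2], ",")[[1]][k + 1])
          d[j] <- as.integer(cell[3])
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        contig = f[1], pos = as.integer(f[2]), ref = f[4], alt = alts[k],
        MQ = ann[["MQ"]], QD = ann[["QD"]], FS = ann[["FS"]],
        SOR = ann[["SOR"]], MQRankSum = ann[["MQRankSum"]],
        ReadPosRankSum = ann[["ReadPosRankSum"]], stringsAsFactors = FALSE)
      gt[[length(gt) + 1]] <- g
      ad[[length(ad) + 1]] <- a
      dp[[length(dp) + 1]] <- d
    }
  }
  list(variants = do.call(rbind, rows),
       gt = do.call(rbind, gt), ad = do.call(rbind, ad),
       dp = do.call(rbind, dp), samples = samples)
}

# --- random fixtures ---------------------------------------------------------
random_panel <- function(n = 200, line_ids = paste0("L", 1:5), seed = 1) {
  withr::with_seed(seed, {
    contigs <- c("2L", "2R", "X")
    ctg <- sort(sample(contigs, n, replace = TRUE))
    pos <- unlist(lapply(split(seq_len(n), ctg), function(ix)
      sort(sample.int(5e5, length(ix)))))
    ctg <- sort(ctg)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    maybe <- function(v) ifelse(runif(n) < 0.1, NA_real_, round(v, 3))
    variants <- data.frame(contig = ctg, pos = pos, ref = ref, alt = alt,
                           MQ = maybe(runif(n, 20, 60)),
                           QD = maybe(runif(n, 0, 35)),
                           FS = maybe(runif(n, 0, 100)),
                           SOR = maybe(runif(n, 0, 6)),
                           MQRankSum = maybe(runif(n, -12, 12)),
                           ReadPosRankSum = maybe(runif(n, -8, 8)),
                           stringsAsFactors = FALSE)
    L <- length(line_ids)
    gt <- matrix(sample(c("hom_ref", "het", "hom_alt", "missing"), n * L,
                        replace = TRUE, prob = c(0.7, 0.12, 0.12, 0.06)),
                 n, L)
    dp <- matrix(rpois(n * L, 80), n, L)
    frac <- matrix(runif(n * L), n, L)
    ad <- round(dp * frac * (gt != "hom_ref"))
    ad[gt == "hom_alt"] <- dp[gt == "hom_alt"]
    miss <- gt == "missing"
    ad[miss] <- NA; dp[miss] <- NA
    variant_panel(variants, gt, matrix(as.integer(ad), n, L),
                  matrix(as.integer(dp), n, L), line_ids)
  })
}

random_track <- function(n = 100, contigs = c("2L", "2R"), L = 1e5,
                         seed = 1, values = TRUE) {
  withr::with_seed(seed, {
    ctg <- character(); s <- numeric(); e <- numeric()
    per <- ceiling(n / length(contigs))
    for (c0 in contigs) {
      cuts <- sort(sample.int(L, 2 * per))
      st <- cuts[seq(1, length(cuts), 2)]
      en <- cuts[seq(2, length(cuts), 2)]
      ok <- st < en
      ctg <- c(ctg, rep(c0, sum(ok))); s <- c(s, st[ok]); e <- c(e, en[ok])
    }
    interval_track(ctg, s, e, if (values) round(runif(length(s), 0, 5), 3))
  })
}

# --- naive filter stack ------------------------------------------------------
naive_filter_reason <- function(row, depth, med, alt_reads, th) {
  num <- function(x) if (is.null(x) || is.na(x)) NA_real_ else x
  if (is.na(num(row$MQ)) || row$MQ < th$min_MQ)
    return(if (is.na(num(row$MQ))) "missing_min_MQ" else "min_MQ")
  if (is.na(num(row$QD)) || row$QD < th$min_QD)
    return(if (is.na(num(row$QD))) "missing_min_QD" else "min_QD")
  if (is.na(num(row$FS)) || row$FS > th$max_FS)
    return(if (is.na(num(row$FS))) "missing_max_FS" else "max_FS")
  if (is.na(num(row$SOR)) || row$SOR > th$max_SOR)
    return(if (is.na(num(row$SOR))) "missing_max_SOR" else "max_SOR")
  if (is.na(num(row$MQRankSum)) || abs(row$MQRankSum) > th$max_abs_MQRankSum)
    return(if (is.na(num(row$MQRankSum))) "missing_max_abs_MQRankSum"
           else "max_abs_MQRankSum")
  if (is.na(num(row$ReadPosRankSum)) ||
      abs(row$ReadPosRankSum) > th$max_abs_ReadPosRankSum)
    return(if (is.na(num(row$ReadPosRankSum)))
      "missing_max_abs_ReadPosRankSum" else "max_abs_ReadPosRankSum")
  if (depth < th$depth_lo_frac * med || depth > th$depth_hi_frac * med)
    return("depth_window")
  if (!is.null(alt_reads) && alt_reads < th$min_alt_reads)
    return("min_alt_reads")
  NA_character_
}

# --- naive proximity ---------------------------------------------------------
naive_near <- function(variants, sv, te, prox) {
  vapply(seq_len(nrow(variants)), function(i) {
    p <- variants$pos[i]; ctg <- variants$contig[i]
    near <- FALSE
    if (!is.null(te))
      for (j in seq_len(nrow(te)))
        if (te$contig[j] == ctg && te$event_type[j] == "insertion" &&
            abs(te$breakpoint[j] - p) <= prox) near <- TRUE
    if (!is.null(sv))
      for (j in seq_len(nrow(sv)))
        if (sv$contig[j] == ctg) {
          d <- if (p >= sv$start[j] && p <= sv$end[j]) 0
          else min(abs(p - sv$start[j]), abs(p - sv$end[j]))
          if (d <= prox) near <- TRUE
        }
    near
  }, logical(1))
}

# --- naive single-linkage clustering (union-find over all pairs) -------------
naive_cluster <- function(pos, gap) {
  n <- length(pos)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && abs(pos[i] - pos[j]) <= gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, 0L)
}

# --- naive per-bp covariate projection --------------------------------------
naive_project <- function(track, windows) {
  vapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    bp <- seq(w$start, w$end - 1)        # 0-based positions in the window
    vals <- rep(NA_real_, length(bp))
    sub <- track[track$contig == w$contig, , drop = FALSE]
    for (j in seq_len(nrow(sub)))
      vals[bp >= sub$start[j] & bp < sub$end[j]] <- sub$value[j]
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1))
}

# --- small fast simulation config -------------------------------------------
small_config <- function(seed = 1, ...) {
  args <- list(
    seed = seed,
    n_lines = c(dsb_plus = 4L, dsb_minus = 5L),
    contig_lengths = c(`2L` = 200000, `2R` = 150000, X = 120000),
    snv_rate = 2e-7, indel_rate = 6e-8, mnv_rate = 2e-8, complex_rate = 2e-8,
    sv_rate = 4e-9,
    te_insertion_rate = c(dsb_plus = 0.08, dsb_minus = 0.12),
    te_excision_rate = c(dsb_plus = 0.03, dsb_minus = 0.03),
    artifacts_per_filter = 1, n_shared_artifacts = 4,
    n_uncalled_artifacts = 3, n_proximity_artifacts = 3,
    sv_artifacts_per_reason = 1, n_segregating_te = 5,
    n_windows = 120)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_config, args)
}

# thin aliases for package internals exercised directly in tests
points_covered <- function(track, contig, pos)
  mamut:::points_in_track(track, contig, pos)
line_median_depth_public <- function(meta, line, contig)
  mamut:::line_median_depth(meta, line, contig)

# synthetic annotated window table (already projected covariates)
sim_windows <- function(n, seed = 1) {
  w <- withr::with_seed(seed, {
    data.frame(contig = "2L", start = (0:(n - 1)) * 1000,
               end = (1:n) * 1000,
               state = sample(c("RE", "YE", "BL", "GR", "BK"), n,
                              replace = TRUE,
                              prob = c(0.12, 0.18, 0.08, 0.07, 0.55)),
               gc_frac = runif(n, 0.3, 0.55),
               recomb = rgamma(n, 4, 2),
               timing = runif(n, -1, 1),
               callable = round(runif(n, 2000, 8000)),
               excluded = FALSE, stringsAsFactors = FALSE)
  })
  w$power <- w$callable * 35
  w
}
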