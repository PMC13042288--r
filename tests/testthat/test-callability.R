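th <- filter_thresholds()

test_that("all printed filter bounds are inclusive", {
  ann <- list(MQ = 50, QD = 2, FS = 60, SOR = 3, MQRankSum = -8,
              ReadPosRankSum = 4)
  res <- site_passes_filters(ann, depth = 50, median_depth = 100, th,
                             mode = "variant", alt_reads = 10)
  expect_true(res$pass)
  # depth window bounds are inclusive too
  for (d in c(50, 200)) {
    r <- site_passes_filters(ann, d, 100, th, "variant", alt_reads = 10)
    expect_true(r$pass)
  }
})

test_that("failures are labelled with the first violated rule", {
  ann <- list(MQ = 50, QD = 2, FS = 60, SOR = 3, MQRankSum = -8,
              ReadPosRankSum = 4)
  r <- site_passes_filters(ann, 50, 100, th, "variant", alt_reads = 9)
  expect_false(r$pass)
  expect_equal(r$reason, "min_alt_reads")
  r <- site_passes_filters(ann, 201, 100, th, "variant", alt_reads = 10)
  expect_equal(r$reason, "depth_window")
  r <- site_passes_filters(ann, 49, 100, th, "nonvariant")
  expect_equal(r$reason, "depth_window")
  ann$QD <- 1.9
  r <- site_passes_filters(ann, 50, 100, th, "variant", alt_reads = 10)
  expect_equal(r$reason, "min_QD")
  expect_error(site_passes_filters(ann, -1, 100, th, "nonvariant"),
               "negative depth")
})

test_that("missing annotations fail closed unless strict_callable is off", {
  ann <- list(MQ = 60, QD = 20, FS = 1, SOR = 1, MQRankSum = NA,
              ReadPosRankSum = 0)
  expect_false(site_passes_filters(ann, 100, 100, th, "variant",
                                   alt_reads = 20)$pass)
  expect_false(site_passes_filters(ann, 100, 100, th, "nonvariant")$pass)
  expect_true(site_passes_filters(ann, 100, 100, th, "nonvariant",
                                  strict_callable = FALSE)$pass)
})

test_that("variant mode is strictly stricter than nonvariant mode", {
  set.seed(31)
  for (i in 1:300) {
    ann <- list(MQ = runif(1, 40, 60), QD = runif(1, 0, 10),
                FS = runif(1, 0, 90), SOR = runif(1, 0, 5),
                MQRankSum = runif(1, -10, 10),
                ReadPosRankSum = runif(1, -6, 6))
    d <- rpois(1, 100)
    v <- site_passes_filters(ann, d, 100, th, "variant",
                             alt_reads = rpois(1, 20))
    if (v$pass)
      expect_true(site_passes_filters(ann, d, 100, th, "nonvariant")$pass)
  }
})

test_that("callable-site bookkeeping identities hold on the printed totals", {
  # toy genome: disjoint masked and failing sets
  bk <- callability_bookkeeping(1000, 150, 100)
  expect_equal(bk$filter_failed, 50)
  expect_equal(bk$callable, 850)
  bk <- callability_bookkeeping(133880608, 34422478, 20052895)
  expect_equal(bk$filter_failed, 14369583)
  expect_equal(bk$callable, 99458130)
  expect_equal(round(bk$callable_percent), 74)
})

test_that("mask computation matches a brute-force site-by-site loop", {
  L <- 10000
  genome <- c(chrA = L)
  set.seed(5)
  lines <- paste0("L", 1:3)
  stats_by_line <- lapply(lines, function(l) {
    data.frame(contig = "chrA", pos = 1:L,
               MQ = runif(L, 45, 60), QD = runif(L, 0, 10),
               FS = runif(L, 0, 80), SOR = runif(L, 0, 4),
               MQRankSum = runif(L, -10, 10), ReadPosRankSum = runif(L, -5, 5),
               DP = rpois(L, 100), stringsAsFactors = FALSE)
  })
  meds <- c(L1 = 100, L2 = 95, L3 = 105)
  rmask <- interval_track("chrA", c(100, 5000), c(200, 5500))
  fails <- lapply(seq_along(lines), function(i)
    evaluate_line_sites(stats_by_line[[i]], meds[i], th))
  mask <- compute_callable_mask(genome, rmask, fails)

  # independent loop over every site and line
  masked <- logical(L); masked[101:200] <- TRUE; masked[5001:5500] <- TRUE
  brute <- vapply(1:L, function(p) {
    if (masked[p]) return(FALSE)
    for (i in seq_along(lines)) {
      row <- stats_by_line[[i]][p, ]
      if (!is.na(naive_filter_reason(row, row$DP, meds[i], NULL, th)))
        return(FALSE)
    }
    TRUE
  }, logical(1))
  expect_equal(mask$mask$chrA, brute)
  s <- mask$summary[mask$summary$contig == "total", ]
  expect_equal(s$callable, sum(brute))
  expect_equal(s$total, s$repeat_masked + s$filter_failed + s$callable)
})

test_that("tightening any threshold never increases the callable count", {
  L <- 4000
  genome <- c(chrA = L)
  set.seed(8)
  stats1 <- data.frame(contig = "chrA", pos = 1:L,
                       MQ = runif(L, 45, 60), QD = runif(L, 0, 10),
                       FS = runif(L, 0, 80), SOR = runif(L, 0, 4),
                       MQRankSum = runif(L, -10, 10),
                       ReadPosRankSum = runif(L, -5, 5),
                       DP = rpois(L, 100), stringsAsFactors = FALSE)
  rmask <- interval_track("chrA", 0, 50)
  base <- compute_callable_mask(genome, rmask,
                                list(evaluate_line_sites(stats1, 100, th)))
  n_base <- base$summary$callable[2]
  tighter <- list(filter_thresholds(min_MQ = 55),
                  filter_thresholds(min_QD = 5),
                  filter_thresholds(max_FS = 30),
                  filter_thresholds(max_SOR = 2),
                  filter_thresholds(max_abs_MQRankSum = 4),
                  filter_thresholds(max_abs_ReadPosRankSum = 2),
                  filter_thresholds(depth_lo_frac = 0.8,
                                    depth_hi_frac = 1.2))
  for (t2 in tighter) {
    m <- compute_callable_mask(genome, rmask,
                               list(evaluate_line_sites(stats1, 100, t2)))
    expect_lte(m$summary$callable[2], n_base)
  }
})

test_that("coverage screening flags trisomy-like depth ratios", {
  depth <- rbind(A = c(`2L` = 100, `2R` = 101, `3L` = 99, `3R` = 100, X = 98),
                 B = c(`2L` = 100, `2R` = 100, `3L` = 100, `3R` = 100,
                       X = 150))
  flags <- detect_aneuploidy(depth)
  expect_false(any(flags$flagged[flags$line_id == "A"]))
  hit <- flags[flags$line_id == "B" & flags$contig == "X", ]
  expect_true(hit$flagged)
  expect_equal(hit$ratio, 1.5)
  expect_error(detect_aneuploidy(depth[, 1, drop = FALSE]), "two contigs")

  # noisy simulation: per-contig mean depth over 5 kb of NB per-site noise,
  # one contig at 1.5x, should be flagged nearly always
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    mus <- c(`2L` = 100, `2R` = 100, `3L` = 100, `3R` = 100, X = 100,
             `4` = 150)
    d <- matrix(vapply(mus, function(m)
      mean(rnbinom(5000, mu = m, size = 5)), 0), 1, 6,
      dimnames = list("L", names(mus)))
    f <- detect_aneuploidy(d)
    if (f$flagged[f$contig == "4"]) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("callable counting within tracks matches direct indexing", {
  genome <- c(chrA = 1000)
  rmask <- interval_track("chrA", 100, 300)
  gc <- interval_track("chrA", c(0, 500), c(250, 700))
  mask <- compute_callable_mask(genome, rmask, list(), gc_track = gc)
  inside <- count_callable_in(mask, interval_track("chrA", 0, 600))
  expect_equal(inside$callable, 400)        # 600 - 200 masked
  expect_equal(inside$callable_gc, 200)     # 0..99 and 500..599
})
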