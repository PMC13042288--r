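test_that("the generator is deterministic given the seed", {
  e1 <- generate_experiment(small_config(seed = 11))
  e2 <- generate_experiment(small_config(seed = 11))
  expect_equal(e1$panel$variants, e2$panel$variants)
  expect_equal(e1$te_calls, e2$te_calls)
  expect_equal(e1$truth$events, e2$truth$events)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_experiment(e1, d1); write_experiment(e2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  e3 <- generate_experiment(small_config(seed = 12))
  expect_false(identical(e1$panel$variants, e3$panel$variants))
})

test_that("zero rates plant no events, only labelled artifacts", {
  cfg <- small_config(seed = 3, snv_rate = 0, indel_rate = 0, mnv_rate = 0,
                      complex_rate = 0, sv_rate = 0,
                      te_insertion_rate = c(dsb_plus = 0, dsb_minus = 0),
                      te_excision_rate = c(dsb_plus = 0, dsb_minus = 0),
                      n_segregating_te = 0, sv_artifacts_per_reason = 0,
                      n_proximity_artifacts = 0)
  e <- generate_experiment(cfg)
  expect_equal(nrow(e$truth$events), 0L)
  expect_equal(nrow(e$truth$te[e$truth$te$planted == "de_novo", ]), 0L)
  # every variant record is a planted artifact
  expect_equal(nrow(e$panel$variants), nrow(e$truth$artifacts))
  res <- call_mutations(e$panel, e$sv, e$te_calls, e$meta,
                        sv_quality_max = cfg$sv_quality_max)
  expect_equal(nrow(res$events), 0L)
  rep <- score_recovery(res, e$truth, e$mask, e$meta)
  expect_equal(sum(rep$per_category$fp), 0)
  # defined (zero) rates, not NaN
  expect_equal(rep$rate_check$estimate$estimate, 0)
})

test_that("planted event counts follow the Poisson opportunity model", {
  lambdas <- numeric(0); counts <- numeric(0)
  for (s in 1:20) {
    cfg <- small_config(seed = 100 + s, snv_rate = 1e-7,
                        n_lines = c(dsb_plus = 5L, dsb_minus = 5L))
    e <- generate_experiment(cfg)
    callable <- e$mask$summary$callable[e$mask$summary$contig == "total"]
    lambdas <- c(lambdas, 1e-7 * callable * 30 * 10)
    counts <- c(counts, sum(e$truth$events$category == "SNV"))
  }
  lam <- mean(lambdas)
  expect_lt(abs(mean(counts) - lam), 3 * sqrt(lam))
})

test_that("noise-free pipeline output equals the planted truth exactly", {
  cfg <- small_config(seed = 21)
  e <- generate_experiment(cfg)
  res <- call_mutations(e$panel, e$sv, e$te_calls, e$meta,
                        sv_quality_max = cfg$sv_quality_max, genes = e$genes,
                        consequences = e$consequences)
  rep <- score_recovery(res, e$truth, e$mask, e$meta)
  pc <- rep$per_category
  nonempty <- pc[pc$tp + pc$fn > 0, ]
  expect_true(all(nonempty$precision == 1))
  expect_true(all(nonempty$recall == 1))
  expect_equal(sum(pc$fp), 0)
  # zygosity recovered event-by-event
  key <- function(d) paste(d$line_id, d$contig, d$start)
  tr <- e$truth$events
  m <- match(key(res$events[res$events$category != "SV", ]), key(tr))
  expect_false(anyNA(m))
  expect_equal(res$events$zygosity[res$events$category != "SV"],
               tr$zygosity[m])
  # every planted artifact is logged with its expected reason
  expect_true(all(!rep$artifacts$leaked))
  expect_equal(rep$artifacts$observed_reason, rep$artifacts$expected_reason)
})

test_that("window counts in the annotated table equal the planted truth", {
  cfg <- small_config(seed = 31)
  e <- generate_experiment(cfg)
  res <- call_mutations(e$panel, e$sv, e$te_calls, e$meta,
                        sv_quality_max = cfg$sv_quality_max)
  point <- res$events[res$events$category != "SV", , drop = FALSE]
  w <- annotate_windows(e$windows, e$mask, e$recomb, e$timing, point,
                        meta = e$meta)
  expect_equal(w$n_point, e$windows$n_point_true)
  expect_equal(w$n_point_dsb_plus + w$n_point_dsb_minus, w$n_point)
})

test_that("deliberate oversized jitter splits a segregating TE event", {
  cfg <- small_config(seed = 41, te_bad_jitter_frac = 1,
                      n_segregating_te = 10)
  e <- generate_experiment(cfg)
  ev <- merge_te_calls(e$te_calls)
  seg_truth <- e$truth$te[grepl("segregating", e$truth$te$planted), ]
  bad <- seg_truth[seg_truth$planted == "segregating_bad_jitter", ]
  expect_gt(nrow(bad), 0)
  # at least one planted multi-line event fragments into > 1 merged event
  frag <- vapply(seq_len(nrow(bad)), function(i) {
    hits <- ev$family == bad$family[i] & ev$contig == bad$contig[i] &
      abs(ev$breakpoint - bad$breakpoint[i]) <= 200
    sum(hits)
  }, 0)
  expect_gt(sum(frag > 1), 0)
})

test_that("planted spectrum parameters are recovered at scale", {
  cfg <- small_config(seed = 51, snv_rate = 3e-6,
                      contig_lengths = c(`2L` = 400000, `2R` = 300000,
                                         X = 200000))
  e <- generate_experiment(cfg)
  snv <- e$truth$events[e$truth$events$category == "SNV", ]
  expect_gt(nrow(snv), 500)
  res <- call_mutations(e$panel, e$sv, e$te_calls, e$meta,
                        sv_quality_max = cfg$sv_quality_max)
  got <- res$events[res$events$category == "SNV", ]
  # look the alleles back up in the panel by coordinate
  m <- match(paste(got$contig, got$start),
             paste(e$panel$variants$contig, e$panel$variants$pos))
  sp <- snv_spectrum(e$panel$variants$ref[m], e$panel$variants$alt[m],
                     boot = 200)
  ts_frac <- sp$ts / sp$n
  expect_lt(abs(ts_frac - e$truth$transition_fraction), 0.05)
})

test_that("recovery scoring flags contig mismatches", {
  e <- generate_experiment(small_config(seed = 61))
  res <- call_mutations(e$panel, e$sv, e$te_calls, e$meta,
                        sv_quality_max = 999)
  truth2 <- e$truth
  truth2$events <- truth2$events[0, ]
  truth2$te <- truth2$te[0, ]
  truth2$sv <- truth2$sv[0, ]
  expect_error(score_recovery(res, truth2), "mismatched contig")
})
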