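mk_calls <- function(line, family, bp, type = "insertion", contig = "2L") {
  data.frame(line_id = line, family = family, contig = contig,
             breakpoint = as.integer(bp), event_type = type,
             support = 10L, stringsAsFactors = FALSE)
}

test_that("TE merging is inclusive at 50 bp and family-aware", {
  calls <- rbind(mk_calls("A", "roo", 1000), mk_calls("B", "roo", 1050))
  ev <- merge_te_calls(calls)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_lines, 2L)
  expect_equal(ev$breakpoint, 1025)

  calls2 <- rbind(mk_calls("A", "roo", 1000), mk_calls("B", "roo", 1051))
  expect_equal(nrow(merge_te_calls(calls2)), 2L)

  calls3 <- rbind(mk_calls("A", "roo", 1000), mk_calls("B", "Doc", 1000))
  expect_equal(nrow(merge_te_calls(calls3)), 2L)

  # insertions and excisions never merge with each other
  calls4 <- rbind(mk_calls("A", "roo", 1000),
                  mk_calls("B", "roo", 1010, type = "excision"))
  expect_equal(nrow(merge_te_calls(calls4)), 2L)
})

test_that("TE merging is order-invariant, idempotent and conserves calls", {
  set.seed(55)
  calls <- do.call(rbind, lapply(1:300, function(i)
    mk_calls(sample(paste0("L", 1:8), 1),
             sample(c("roo", "Doc", "S"), 1),
             sample.int(2e5, 1),
             sample(c("insertion", "excision"), 1),
             sample(c("2L", "X"), 1))))
  ev <- merge_te_calls(calls)
  expect_equal(sum(ev$n_members), nrow(calls))
  shuf <- calls[sample.int(nrow(calls)), ]
  ev2 <- merge_te_calls(shuf)
  cols <- c("family", "contig", "event_type", "breakpoint", "n_members",
            "n_lines")
  expect_equal(ev[, cols], ev2[, cols])
  # re-merging representative breakpoints changes nothing
  rep_calls <- data.frame(line_id = vapply(ev$lines, `[[`, "", 1),
                          family = ev$family, contig = ev$contig,
                          breakpoint = ev$breakpoint,
                          event_type = ev$event_type, support = 10L,
                          stringsAsFactors = FALSE)
  expect_equal(nrow(merge_te_calls(rep_calls)), nrow(ev))
  # member sets match a naive union-find per (family, contig, type)
  for (f in unique(calls$family)) for (ctg in unique(calls$contig))
    for (ty in c("insertion", "excision")) {
      bp <- sort(calls$breakpoint[calls$family == f & calls$contig == ctg &
                                    calls$event_type == ty])
      if (!length(bp)) next
      sizes <- sort(as.integer(table(naive_cluster(bp, 50))))
      got <- sort(ev$n_members[ev$family == f & ev$contig == ctg &
                                 ev$event_type == ty])
      expect_equal(got, sizes)
    }
})

test_that("de novo selection keeps single-line events only", {
  calls <- rbind(mk_calls("A", "roo", 1000),
                 mk_calls("A", "Doc", 5000), mk_calls("B", "Doc", 5010))
  ev <- merge_te_calls(calls)
  dn <- select_de_novo(ev)
  expect_equal(nrow(dn$events), 1L)
  expect_equal(dn$events$family, "roo")
  expect_equal(dn$rejections$reason, "segregating_or_recurrent")
})

test_that("TE rates use per-genome generations as the denominator", {
  lines <- sprintf("P%02d", 1:16)
  meta <- line_metadata(lines, rep("dsb_plus", 16))
  calls <- do.call(rbind, lapply(1:290, function(i)
    mk_calls(sample(lines, 1), "roo", i * 500L)))
  ev <- select_de_novo(merge_te_calls(calls))$events
  r <- te_rates(ev, meta, by = "group", boot = 200)
  expect_equal(r$opportunity, 16 * 30)
  expect_equal(r$rate, sum(ev$n_members >= 1) / (16 * 30))
  expect_equal(r$rate, 0.604, tolerance = 1e-3)
})

test_that("family activity diagnostics behave at the extremes", {
  counts <- matrix(rpois(10 * 6, 1.2), 10, 6,
                   dimnames = list(NULL, paste0("f", 1:6)))
  res <- family_activity_tests(counts, n_sims = 500, seed = 2)
  expect_true(res$dispersion$p_value > 0 && res$dispersion$p_value <= 1)
  expect_equal(dim(res$spearman$rho), c(5, 5))

  # perfectly rank-correlated families
  a <- 1:8
  m <- cbind(f1 = a, f2 = 2 * a, f3 = rev(a), f4 = a, f5 = a)
  r2 <- family_activity_tests(m, n_sims = 100, seed = 1)
  expect_equal(r2$spearman$rho["f1", "f2"], 1)
  expect_equal(r2$spearman$rho["f1", "f3"], -1)

  # identical per-line activity counts are underdispersed relative to Poisson
  flat <- matrix(1L, 60, 4)
  r3 <- suppressWarnings(family_activity_tests(flat, n_sims = 2000, seed = 3))
  expect_lt(r3$dispersion$p_value, 0.05)
})

test_that("dispersion test has nominal type-I error under the Poisson null", {
  rej <- 0
  n_data <- 200
  for (s in seq_len(n_data)) {
    set.seed(1000 + s)
    counts <- matrix(rpois(20 * 5, 0.8), 20, 5)
    p <- family_activity_tests(counts, n_sims = 399, seed = s)$dispersion$p_value
    if (p <= 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_data, 0.01)
  expect_lte(rej / n_data, 0.09)
})

test_that("X enrichment uses chromosome-size null probabilities", {
  lens <- c(`2L` = 4e5, `2R` = 4e5, X = 2e5)
  ev <- data.frame(contig = rep("X", 20), stringsAsFactors = FALSE)
  r <- x_enrichment(ev, lens)
  expect_equal(r$options$null_prob, 0.2)
  expect_equal(r$p_value, binom.test(20, 20, 0.2)$p.value)
  # observed at the null: large p
  ev2 <- data.frame(contig = c(rep("X", 2), rep("2L", 4), rep("2R", 4)),
                    stringsAsFactors = FALSE)
  expect_gt(x_enrichment(ev2, lens)$p_value, 0.5)
})
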