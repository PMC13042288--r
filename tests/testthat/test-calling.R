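make_test_panel <- function(gt_rows, pos = NULL, contig = "2L",
                            ref = "A", alt = "G") {
  # gt_rows: list of named genotype vectors (one per record)
  lines <- names(gt_rows[[1]])
  n <- length(gt_rows)
  if (is.null(pos)) pos <- seq(1000, by = 5000, length.out = n)
  variants <- data.frame(contig = rep(contig, n), pos = as.integer(pos),
                         ref = rep(ref, n), alt = rep(alt, n),
                         MQ = 60, QD = 20, FS = 1, SOR = 1,
                         MQRankSum = 0, ReadPosRankSum = 0,
                         stringsAsFactors = FALSE)
  gt <- do.call(rbind, gt_rows)
  dp <- matrix(100L, n, length(lines))
  ad <- matrix(0L, n, length(lines))
  ad[gt == "het"] <- 50L
  ad[gt == "hom_alt"] <- 100L
  ad[gt == "missing"] <- NA_integer_
  dp[gt == "missing"] <- NA_integer_
  variant_panel(variants, gt, ad, dp, lines)
}

meta3 <- line_metadata(c("A", "B", "C"),
                       c("dsb_plus", "dsb_plus", "dsb_minus"),
                       median_depth = matrix(100, 3, 1,
                                             dimnames = list(NULL, "2L")))

test_that("line-unique selection keeps singletons and logs the rest", {
  panel <- make_test_panel(list(
    c(A = "het", B = "hom_ref", C = "hom_ref"),     # candidate owned by A
    c(A = "het", B = "het", C = "hom_ref"),         # shared
    c(A = "het", B = "hom_ref", C = "missing"),     # uncalled site
    c(A = "hom_ref", B = "hom_ref", C = "hom_ref")  # no carrier
  ))
  res <- select_line_unique(panel)
  expect_equal(nrow(res$candidates), 1L)
  expect_equal(res$candidates$line_id, "A")
  expect_equal(res$candidates$genotype, "het")
  expect_setequal(res$rejections$reason,
                  c("shared", "uncalled_site", "no_carrier"))
  # empty input gives empty output
  empty <- make_test_panel(list(c(A = "het", B = "hom_ref", C = "hom_ref")))
  empty$gt[1, ] <- "hom_ref"
  expect_equal(nrow(select_line_unique(empty)$candidates), 0L)
})

test_that("variant filters match a naive per-candidate loop on random input", {
  set.seed(21)
  n <- 1000
  th <- filter_thresholds()
  cand <- data.frame(record = 1:n, line_id = "A", contig = "2L",
                     pos = seq_len(n) * 3000L,
                     ref = "A", alt = "G",
                     MQ = round(runif(n, 40, 60), 2),
                     QD = round(runif(n, 0, 6), 2),
                     FS = round(runif(n, 0, 90), 2),
                     SOR = round(runif(n, 0, 5), 2),
                     MQRankSum = round(runif(n, -10, 10), 2),
                     ReadPosRankSum = round(runif(n, -6, 6), 2),
                     genotype = "het",
                     alt_reads = rpois(n, 12),
                     depth = rpois(n, 100), stringsAsFactors = FALSE)
  # sprinkle missing annotations
  for (k in c("MQ", "SOR")) cand[[k]][runif(n) < 0.05] <- NA
  meta1 <- line_metadata("A", "dsb_plus",
                         median_depth = matrix(100, 1, 1,
                                               dimnames = list(NULL, "2L")))
  res <- apply_variant_filters(cand, th, meta1)
  naive <- vapply(seq_len(n), function(i)
    naive_filter_reason(cand[i, ], cand$depth[i], 100, cand$alt_reads[i], th),
    "")
  expect_equal(sort(res$pass$record), which(is.na(naive)))
  expect_equal(res$rejections$reason,
               naive[!is.na(naive)])
  # planted QD artifact just under the printed threshold
  cand2 <- cand[1, ]; cand2$QD <- 1.9
  cand2$MQ <- 60; cand2$SOR <- 1
  r2 <- apply_variant_filters(cand2, th, meta1)
  expect_equal(r2$rejections$reason, "min_QD")
})

test_that("SV/TE proximity exclusion is inclusive at exactly 1 kb", {
  v <- data.frame(contig = "2L", pos = c(5000L, 5000L),
                  stringsAsFactors = FALSE)
  sv <- data.frame(contig = "2L", start = 6000L, end = 6500L,
                   stringsAsFactors = FALSE)
  te <- data.frame(contig = "2L", breakpoint = 6001L,
                   event_type = "insertion", stringsAsFactors = FALSE)
  expect_equal(nrow(exclude_near_sv_te(v[1, ], sv = sv)$pass), 0L)
  expect_equal(nrow(exclude_near_sv_te(v[1, ], te = te)$pass), 1L)
  # inside an SV interval counts as distance zero
  v2 <- data.frame(contig = "2L", pos = 6200L)
  expect_equal(nrow(exclude_near_sv_te(v2, sv = sv)$pass), 0L)
  # excisions are ignored unless asked for
  te2 <- te; te2$event_type <- "excision"; te2$breakpoint <- 5100L
  expect_equal(nrow(exclude_near_sv_te(v[1, ], te = te2)$pass), 1L)
  expect_equal(nrow(exclude_near_sv_te(v[1, ], te = te2,
                                       include_excisions = TRUE)$pass), 0L)
})

test_that("proximity exclusion matches all-pairs distances on random input", {
  set.seed(14)
  v <- data.frame(contig = sample(c("2L", "2R"), 1000, replace = TRUE),
                  pos = sample.int(1e5, 1000, replace = TRUE),
                  stringsAsFactors = FALSE)
  sv <- data.frame(contig = sample(c("2L", "2R"), 15, replace = TRUE),
                   start = sample.int(9e4, 15))
  sv$end <- sv$start + sample.int(5000, 15)
  te <- data.frame(contig = sample(c("2L", "2R"), 25, replace = TRUE),
                   breakpoint = sample.int(1e5, 25),
                   event_type = sample(c("insertion", "excision"), 25,
                                       replace = TRUE),
                   stringsAsFactors = FALSE)
  res <- exclude_near_sv_te(v, sv, te)
  expect_equal(nrow(res$pass) + nrow(res$rejections), nrow(v))
  near <- naive_near(v, sv, te, 1000)
  expect_equal(res$pass, v[!near, , drop = FALSE])
})

test_that("SV filtering applies the or-rule, uniqueness and quality ceiling", {
  mk <- function(span, split, qual, carriers = "A",
                 genotyped = c("A", "B", "C")) {
    s <- data.frame(contig = "2L", start = 1000L, end = 2000L,
                    sv_type = "deletion", length = 1001L, quality = qual,
                    spanning_reads = span, split_reads = split,
                    stringsAsFactors = FALSE)
    s$carriers <- I(list(carriers)); s$genotyped <- I(list(genotyped))
    s
  }
  sv <- rbind(mk(10, 0, 999),                 # spanning alone suffices
              mk(0, 10, 999),                 # split alone suffices
              mk(9, 9, 999),                  # neither support reaches 10
              mk(30, 30, 998),                # below the quality ceiling
              mk(30, 30, 999, carriers = c("A", "B")),   # shared
              mk(30, 30, 999, genotyped = c("A", "B")))  # incomplete block
  res <- filter_sv_records(sv, quality_max = 999,
                           panel_lines = c("A", "B", "C"))
  expect_equal(nrow(res$pass), 2L)
  expect_equal(res$rejections$reason,
               c("low_support", "not_max_quality", "shared",
                 "not_genotyped_all"))
})

test_that("clustering follows the single-linkage definitions", {
  v <- data.frame(line_id = "A", contig = "2L",
                  pos = c(100L, 900L), ref = c("A", "C"), alt = c("G", "T"),
                  genotype = c("het", "het"), stringsAsFactors = FALSE)
  ev <- cluster_variants(v)
  expect_equal(ev$category, "MNV")
  expect_equal(ev$n_members, 2L)

  v2 <- data.frame(line_id = "A", contig = "2L", pos = c(100L, 600L),
                   ref = c("A", "CTTT"), alt = c("G", "C"),
                   genotype = c("hom_alt", "hom_alt"),
                   stringsAsFactors = FALSE)
  expect_equal(cluster_variants(v2)$category, "COMPLEX")

  # consecutive gaps of 900 chain even though the ends are 1800 apart
  v3 <- data.frame(line_id = "A", contig = "2L",
                   pos = c(100L, 1000L, 1900L), ref = "A", alt = "G",
                   genotype = "het", stringsAsFactors = FALSE)
  ev3 <- cluster_variants(v3)
  expect_equal(ev3$category, "MNV")
  expect_equal(ev3$n_members, 3L)
  # the stricter pairwise reading splits that chain
  ev3p <- cluster_variants(v3, pairwise = TRUE)
  expect_equal(sort(ev3p$n_members), c(1L, 2L))

  # events never span lines or contigs
  v4 <- v3; v4$line_id <- c("A", "B", "A")
  expect_equal(nrow(cluster_variants(v4)), 3L)
})

test_that("clustering partitions all variants and ignores input order", {
  set.seed(77)
  v <- data.frame(line_id = sample(c("A", "B"), 400, replace = TRUE),
                  contig = sample(c("2L", "2R"), 400, replace = TRUE),
                  pos = sample.int(2e5, 400),
                  ref = "A", alt = "G", genotype = "het",
                  stringsAsFactors = FALSE)
  ev <- cluster_variants(v)
  expect_equal(sum(ev$n_members), nrow(v))
  shuf <- v[sample.int(nrow(v)), ]
  ev2 <- cluster_variants(shuf)
  expect_equal(ev[, c("line_id", "contig", "start", "end", "n_members")],
               ev2[, c("line_id", "contig", "start", "end", "n_members")])
  # member sets equal a naive union-find single linkage per (line, contig)
  for (l in c("A", "B")) for (ctg in c("2L", "2R")) {
    pos <- sort(v$pos[v$line_id == l & v$contig == ctg])
    comp <- naive_cluster(pos, 1000)
    sizes <- sort(as.integer(table(comp)))
    got <- sort(ev$n_members[ev$line_id == l & ev$contig == ctg])
    expect_equal(got, sizes)
  }
})

test_that("zygosity classification distinguishes pure and mixed events", {
  expect_equal(classify_zygosity("hom_alt"), "homozygous")
  expect_equal(classify_zygosity(c("het", "het")), "heterozygous")
  expect_equal(classify_zygosity(c("het", "hom_alt")), "mixed")
})
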