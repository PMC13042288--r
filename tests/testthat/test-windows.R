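test_that("covariate projection is overlap-weighted and mass-conserving", {
  w <- data.frame(contig = "2L", start = 0, end = 100)
  tr <- interval_track("2L", c(0, 50), c(50, 150), c(2, 4))
  expect_equal(project_covariate(tr, w), 3)
  # constant track projects to the constant
  tr2 <- interval_track("2L", c(0, 500), c(500, 1500), c(7, 7))
  w2 <- data.frame(contig = "2L", start = c(0, 200, 900), end = c(100, 800, 1400))
  expect_equal(project_covariate(tr2, w2), c(7, 7, 7))
  # no overlap gives NA
  w3 <- data.frame(contig = "2R", start = 0, end = 100)
  expect_true(is.na(project_covariate(tr, w3)))
})

test_that("projection matches per-bp averaging on random tracks", {
  tr <- random_track(n = 60, contigs = c("2L", "2R"), L = 2e4, seed = 13)
  set.seed(13)
  w <- data.frame(contig = sample(c("2L", "2R"), 40, replace = TRUE),
                  start = sample.int(18000, 40))
  w$end <- w$start + sample.int(1500, 40)
  got <- project_covariate(tr, w)
  oracle <- naive_project(tr, w)
  expect_equal(got, oracle, tolerance = 1e-12)
  # projected values lie within the range of overlapping track values
  rng <- range(tr$value)
  expect_true(all(is.na(got) | (got >= rng[1] & got <= rng[2])))
})

test_that("covariate scaling modes behave as documented", {
  s <- scale_covariates(c(1, 2, 3))
  expect_equal(as.numeric(s), c(0.5, 1, 1.5))
  expect_equal(as.numeric(scale_covariates(c(4, 4, 4))), c(1, 1, 1))
  z <- scale_covariates(c(1, 2, 3), mode = "z_score")
  expect_equal(mean(z), 0)
  expect_equal(sd(as.numeric(z)), 1)
})

test_that("window annotation counts callable sites, G/C and events", {
  genome <- c(chrA = 3000)
  rmask <- interval_track("chrA", 1000, 1200)
  gc <- interval_track("chrA", 0, 1500)
  mask <- compute_callable_mask(genome, rmask, list(), gc_track = gc)
  windows <- data.frame(contig = "chrA", start = c(0, 1000, 2000),
                        end = c(1000, 2000, 3000),
                        state = c("BK", "RE", "BK"), stringsAsFactors = FALSE)
  recomb <- interval_track("chrA", 0, 3000, 2)
  timing <- interval_track("chrA", 0, 2000, 0.5)   # missing on last window
  events <- data.frame(contig = "chrA", start = c(1000, 1001, 2500),
                       line_id = "A", stringsAsFactors = FALSE)
  w <- annotate_windows(windows, mask, recomb, timing, events,
                        n_lines = 10)
  expect_equal(w$callable, c(1000, 800, 1000))
  expect_equal(w$gc_sites, c(1000, 300, 0))
  expect_equal(w$power, w$callable * 10)
  # boundary event at position 1000 belongs to [0, 1000), 1001 to [1000, 2000)
  expect_equal(w$n_point, c(1L, 1L, 1L))
  expect_equal(w$excluded, c(FALSE, FALSE, TRUE))
  # a fully masked window is excluded via zero callable sites
  rmask2 <- interval_track("chrA", 0, 1000)
  mask2 <- compute_callable_mask(genome, rmask2, list(), gc_track = gc)
  w2 <- annotate_windows(windows, mask2, recomb,
                         interval_track("chrA", 0, 3000, 0.5), events)
  expect_true(w2$excluded[1])
})

test_that("intercept-only NB fit recovers log mean; huge theta matches Poisson", {
  w <- sim_windows(400, seed = 5)
  w$power <- 1   # null exposure: offset log(1) = 0
  w$n <- withr::with_seed(6, rpois(400, 3))
  fit <- fit_nb(w, response = "n", covariates = character(0), unscaled = NULL,
                state_col = NULL, power = "offset")
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["(Intercept)"]), log(mean(w$n)),
               tolerance = 1e-6)

  # theta pinned very large reproduces the Poisson GLM
  w2 <- sim_windows(500, seed = 8)
  w2$n <- withr::with_seed(9, rpois(500, exp(1 + 0.3 * w2$timing)))
  w2$power <- 1
  fit_nb2 <- fit_nb(w2, response = "n", covariates = character(0),
                    unscaled = "timing", state_col = NULL,
                    theta_fix = 1e8)
  pois <- glm(n ~ timing, data = w2, family = poisson())
  expect_equal(unname(coef(fit_nb2)[c("(Intercept)", "timing")]),
               unname(coef(pois)), tolerance = 1e-6)
})

test_that("power offset scaling shifts only the intercept", {
  w <- sim_windows(600, seed = 10)
  w$n <- simulate_window_counts(w, beta = c(intercept = -8, gc = -0.3,
                                            recomb = 0.2, timing = -0.1,
                                            RE = 0.3, YE = 0.2, BL = -0.1,
                                            GR = 0.1), theta = 2, seed = 11)
  f1 <- fit_nb(w, response = "n")
  w2 <- w; w2$power <- w$power * 10
  f2 <- fit_nb(w2, response = "n")
  c1 <- coef(f1); c2 <- coef(f2)
  expect_equal(unname(c2["(Intercept)"] - c1["(Intercept)"]), -log(10),
               tolerance = 1e-4)
  other <- setdiff(names(c1), "(Intercept)")
  expect_equal(c1[other], c2[other], tolerance = 1e-3)
})

test_that("duplicating every window leaves coefficients unchanged", {
  w <- sim_windows(300, seed = 12)
  w$n <- simulate_window_counts(w, beta = c(intercept = -8, gc = -0.2,
                                            recomb = 0.1, timing = 0,
                                            RE = 0, YE = 0, BL = 0, GR = 0),
                                theta = 3, seed = 13)
  f1 <- fit_nb(w, response = "n")
  f2 <- fit_nb(rbind(w, w), response = "n")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-5)
  # doubled information: standard errors shrink by about sqrt(2)
  expect_equal(f2$coefficients$se, f1$coefficients$se / sqrt(2),
               tolerance = 0.05)
})

test_that("likelihood-ratio test is zero on identical fits and calibrated", {
  w <- sim_windows(300, seed = 14)
  w$n <- simulate_window_counts(w, beta = c(intercept = -8, gc = 0,
                                            recomb = 0, timing = 0, RE = 0,
                                            YE = 0, BL = 0, GR = 0),
                                theta = 2, seed = 15)
  f <- fit_nb(w, response = "n")
  same <- likelihood_ratio_test(f, f)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  red <- fit_nb(w, response = "n", state_col = NULL)
  lrt <- likelihood_ratio_test(f, red)
  expect_equal(lrt$options$df, 4)
  expect_true(lrt$p_value > 0 && lrt$p_value <= 1)
})

test_that("treatment interaction model reports nothing on duplicated counts", {
  w <- sim_windows(250, seed = 16)
  w$n_point_dsb_plus <- simulate_window_counts(
    w, beta = c(intercept = -8, gc = -0.3, recomb = 0.2, timing = 0,
                RE = 0, YE = 0, BL = 0, GR = 0), theta = 2, seed = 17)
  w$n_point_dsb_minus <- w$n_point_dsb_plus
  meta <- line_metadata(sprintf("L%02d", 1:20),
                        rep(c("dsb_plus", "dsb_minus"), each = 10))
  res <- fit_treatment_interaction(w, meta)
  inter <- res$full$coefficients[grepl(":", res$full$coefficients$term), ]
  expect_true(all(abs(inter$estimate) < 2 * pmax(inter$se, 1e-6) + 1e-6))
  expect_gt(res$lrt$p_value, 0.5)
})

test_that("nbinom2 fit agrees with an independent NB-GLM implementation", {
  w <- sim_windows(800, seed = 18)
  w$n <- simulate_window_counts(w, beta = c(intercept = -8, gc = -0.3,
                                            recomb = 0.2, timing = -0.1,
                                            RE = 0, YE = 0, BL = 0, GR = 0),
                                theta = 2, seed = 19)
  fit <- fit_nb(w, response = "n", state_col = NULL)
  w$gc_s <- w$gc_frac / mean(w$gc_frac)
  w$rec_s <- w$recomb / mean(w$recomb)
  oracle <- MASS::glm.nb(n ~ gc_s + rec_s + timing + offset(log(power)),
                         data = w)
  expect_equal(unname(coef(fit)), unname(coef(oracle)), tolerance = 1e-4)
  expect_equal(fit$theta, oracle$theta, tolerance = 1e-3)
})
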