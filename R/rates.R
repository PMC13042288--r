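#' Estimate a mutation rate with a bootstrap confidence interval
#'
#' The point estimate is total events over total opportunity. For per-site
#' rates the per-line opportunity is callable sites times adjusted
#' generations; for per-genome rates (TE events) it is the line's
#' generations. The default CI is a seeded percentile bootstrap over lines;
#' an exact Poisson (Garwood) interval is available as an alternative. With
#' zero events the point estimate is 0 with a one-sided exact Poisson upper
#' bound.
#'
#' @param counts Per-line event counts.
#' @param opportunity Per-line opportunity (same length/order as `counts`).
#' @param scope `"per_site_per_generation"` or `"per_genome_per_generation"`
#'   (a label; the arithmetic is `sum(counts) / sum(opportunity)` either
#'   way).
#' @param ci_method `"bootstrap"` (percentile over lines) or `"poisson"`
#'   (exact, conditioning on total opportunity).
#' @param boot Bootstrap replicates.
#' @param conf Confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `"rate_estimate"`.
#' @examples
#' estimate_rate(c(3, 3), c(3e7, 3e7))  # 1e-7 per site per generation
#' @export
estimate_rate <- function(counts, opportunity,
                          scope = c("per_site_per_generation",
                                    "per_genome_per_generation"),
                          ci_method = c("bootstrap", "poisson"),
                          boot = 10000, conf = 0.95, seed = 1) {
  scope <- match.arg(scope)
  ci_method <- match.arg(ci_method)
  if (length(counts) != length(opportunity))
    stop("counts and opportunity must align per line")
  if (length(counts) < 1) stop("need at least one line")
  if (sum(opportunity) <= 0) stop("zero opportunity")
  total <- sum(counts)
  opp <- sum(opportunity)
  rate <- total / opp
  alpha <- 1 - conf
  if (total == 0) {
    lower <- 0
    upper <- stats::qgamma(conf, 1) / opp
    method <- "poisson_one_sided"
  } else if (ci_method == "poisson") {
    lower <- stats::qgamma(alpha / 2, total) / opp
    upper <- stats::qgamma(1 - alpha / 2, total + 1) / opp
    method <- "poisson_exact"
  } else {
    n <- length(counts)
    rates_b <- withr::with_seed(seed, {
      idx <- matrix(sample.int(n, n * boot, replace = TRUE), nrow = boot)
      num <- matrix(counts[idx], nrow = boot)
      den <- matrix(opportunity[idx], nrow = boot)
      rowSums(num) / rowSums(den)
    })
    qs <- stats::quantile(rates_b, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    lower <- qs[1]; upper <- qs[2]
    method <- "percentile_bootstrap"
  }
  structure(list(estimate = rate, lower = lower, upper = upper,
                 count = total, opportunity = opp, scope = scope,
                 conf = conf, ci_method = method, boot = boot, seed = seed,
                 n_lines = length(counts)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Rate: %.3e %s (%d events / %.4g opportunity)\n",
              x$estimate, gsub("_", " ", x$scope), x$count, x$opportunity))
  cat(sprintf("%d%% CI [%.3e, %.3e] (%s)\n", round(100 * x$conf),
              x$lower, x$upper, x$ci_method))
  invisible(x)
}

#' Absolute between-group rate difference, percent of the group mean
#'
#' `100 * |a - b| / ((a + b) / 2)`, reported to two decimals. Undefined
#' (NA) when both rates are zero.
#'
#' @param rate_a,rate_b Per-group rate estimates.
#' @return Percent difference rounded to 2 decimals.
#' @examples
#' group_difference_percent(5.87e-9, 5.82e-9)  # 0.86
#' @export
group_difference_percent <- function(rate_a, rate_b) {
  if (rate_a == 0 && rate_b == 0) return(NA_real_)
  round(100 * abs(rate_a - rate_b) / ((rate_a + rate_b) / 2), 2)
}

#' Relative increase of a rate over a reference rate, percent
#'
#' `100 * (rate_alt - rate_ref) / rate_ref`; negative when the alternative
#' rate is lower.
#'
#' @param rate_ref Reference (baseline) rate, must be positive.
#' @param rate_alt Alternative rate.
#' @return Percent change (unrounded).
#' @examples
#' relative_increase_percent(4.82e-1, 6.81e-1)  # 41.29
#' @export
relative_increase_percent <- function(rate_ref, rate_alt) {
  if (rate_ref <= 0) stop("rate_ref must be positive")
  100 * (rate_alt - rate_ref) / rate_ref
}

#' Fold excess of mutation within DSB repair tracts
#'
#' Under the model that the entire between-group excess of point mutations is
#' confined to the DNA synthesised while repairing programmed meiotic DSBs
#' (`n_dsb` breaks per genome per generation, each with a repair tract of
#' `tract_length_bp`), the implied within-tract rate elevation is
#' `1 + (rate_plus - rate_minus) * genome_sites / (n_dsb * tract_length_bp *
#' rate_minus)`.
#'
#' @param rate_plus Rate in the group with programmed DSBs.
#' @param rate_minus Rate in the group without (must be positive and not
#'   exceed `rate_plus`).
#' @param n_dsb Meiotic DSBs per genome per generation (default 24).
#' @param tract_length_bp Repair-tract synthesis length in bp (default 5000).
#' @param genome_sites Callable genome size the rates refer to.
#' @return The fold elevation (1 = no excess).
#' @export
tract_fold_excess <- function(rate_plus, rate_minus, n_dsb = 24,
                              tract_length_bp = 5000,
                              genome_sites = 99458130) {
  stopifnot(n_dsb > 0, tract_length_bp > 0, genome_sites > 0)
  if (rate_minus <= 0) stop("rate_minus must be positive")
  if (rate_plus < rate_minus)
    stop("model undefined: rate_plus < rate_minus")
  1 + (rate_plus - rate_minus) * genome_sites /
    (n_dsb * tract_length_bp * rate_minus)
}

ma_test <- function(method, statistic, p_value, n = NA, options = list()) {
  structure(list(method = method, statistic = unname(statistic),
                 p_value = unname(p_value), n = n, options = options),
            class = "ma_test")
}

#' @export
print.ma_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$method, x$statistic,
              x$p_value))
  invisible(x)
}

#' Compare treatment groups with the standard test battery
#'
#' A uniform front end over the two-group and goodness-of-fit tests used in
#' MA analyses. All tests are two-sided unless the underlying test offers no
#' choice.
#'
#' \describe{
#'   \item{welch_t}{Welch's unequal-variance t test on per-line values.}
#'   \item{wilcoxon_rank_sum}{Wilcoxon rank-sum test on per-line values.}
#'   \item{levene}{Levene's test of equal variance (via \pkg{car};
#'     `center = "median"` by default, i.e. the Brown-Forsythe variant).}
#'   \item{fisher_exact}{Fisher's exact test on a contingency `table`.}
#'   \item{chi_square_contingency}{Pearson chi-square (no continuity
#'     correction) on a contingency `table`.}
#'   \item{chi_square_gof}{Goodness of fit of counts `x` against expected
#'     proportions `expected` (e.g. per-arm callable sites for point
#'     mutations, raw contig lengths for TE placement).}
#'   \item{binomial}{Exact binomial test of `x` successes in `n` trials
#'     against null probability `p`.}
#'   \item{bootstrap_cv}{Permutation test of the absolute difference in
#'     coefficients of variation between groups; group labels are permuted
#'     `reps` times and p is the (+1/+1 corrected) fraction of permuted
#'     `|dCV|` at least the observed.}
#' }
#'
#' @param x,y Per-line values for the two groups (two-sample methods), or the
#'   observed counts (`chi_square_gof`), or successes (`binomial`).
#' @param method Test name (see Details).
#' @param table Contingency table for `fisher_exact` /
#'   `chi_square_contingency`.
#' @param expected Expected proportions (or weights) for `chi_square_gof`.
#' @param n,p Trials and null probability for `binomial`.
#' @param reps,seed Permutation count and RNG seed for `bootstrap_cv`.
#' @param center Centring for `levene` (`"median"` or `"mean"`).
#' @return An `ma_test` (method, statistic, p value, group sizes, options).
#' @export
compare_groups <- function(x = NULL, y = NULL,
                           method = c("welch_t", "wilcoxon_rank_sum", "levene",
                                      "fisher_exact",
                                      "chi_square_contingency",
                                      "chi_square_gof", "binomial",
                                      "bootstrap_cv"),
                           table = NULL, expected = NULL, n = NULL, p = NULL,
                           reps = 10000, seed = 1,
                           center = c("median", "mean")) {
  method <- match.arg(method)
  center <- match.arg(center)
  switch(method,
    welch_t = {
      tt <- stats::t.test(x, y)
      ma_test("welch_t", tt$statistic, tt$p.value, n = c(length(x), length(y)))
    },
    wilcoxon_rank_sum = {
      wt <- suppressWarnings(stats::wilcox.test(x, y))
      ma_test("wilcoxon_rank_sum", wt$statistic, wt$p.value,
              n = c(length(x), length(y)))
    },
    levene = {
      if (length(x) < 2 || length(y) < 2)
        stop("variance tests need at least 2 values per group")
      grp <- factor(rep(c("a", "b"), c(length(x), length(y))))
      lt <- car::leveneTest(c(x, y) ~ grp, center = if (center == "median")
        stats::median else mean)
      ma_test("levene", lt[1, "F value"], lt[1, "Pr(>F)"],
              n = c(length(x), length(y)), options = list(center = center))
    },
    fisher_exact = {
      ft <- stats::fisher.test(table)
      ma_test("fisher_exact", if (!is.null(ft$estimate)) ft$estimate else NA,
              ft$p.value, n = sum(table))
    },
    chi_square_contingency = {
      ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
      ma_test("chi_square_contingency", ct$statistic, ct$p.value,
              n = sum(table))
    },
    chi_square_gof = {
      stopifnot(!is.null(expected), length(expected) == length(x))
      ct <- suppressWarnings(stats::chisq.test(x, p = expected / sum(expected)))
      ma_test("chi_square_gof", ct$statistic, ct$p.value, n = sum(x))
    },
    binomial = {
      bt <- stats::binom.test(x, n, p = p)
      ma_test("binomial", x / n, bt$p.value, n = n,
              options = list(null_prob = p))
    },
    bootstrap_cv = {
      if (length(x) < 2 || length(y) < 2)
        stop("variance tests need at least 2 values per group")
      cv <- function(v) stats::sd(v) / mean(v)
      obs <- abs(cv(x) - cv(y))
      all_v <- c(x, y)
      nx <- length(x)
      perm <- withr::with_seed(seed, replicate(reps, {
        idx <- sample.int(length(all_v))
        abs(cv(all_v[idx[seq_len(nx)]]) - cv(all_v[idx[-seq_len(nx)]]))
      }))
      pv <- (1 + sum(perm >= obs)) / (reps + 1)
      ma_test("bootstrap_cv", obs, pv, n = c(length(x), length(y)),
              options = list(reps = reps, seed = seed))
    })
}
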