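.spectrum_classes <- c("A:T>C:G", "A:T>G:C", "A:T>T:A",
                       "G:C>A:T", "G:C>C:G", "G:C>T:A")
.transition_classes <- c("A:T>G:C", "G:C>A:T")

#' Strand-collapsed substitution class of an SNV
#'
#' Collapses a ref>alt substitution to its base-pair-symmetric class
#' (e.g. C>T and G>A are both `G:C>A:T`). Classes whose origin pair is G:C
#' identify mutations at G/C reference sites; the two transition classes are
#' `A:T>G:C` and `G:C>A:T`.
#'
#' @param ref,alt Single-base reference and alternate alleles.
#' @return Factor with the six class levels.
#' @export
snv_class <- function(ref, alt) {
  if (any(ref == alt)) stop("ref must differ from alt")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # represent each substitution on its purine reference strand; complementing
  # both alleles (reading the other strand) then maps to the same class
  pyr <- ref %in% c("C", "T")
  r <- ifelse(pyr, comp[ref], ref)
  a <- ifelse(pyr, comp[alt], alt)
  factor(paste0(r, ":", comp[r], ">", a, ":", comp[a]),
         levels = .spectrum_classes)
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Successes.
#' @param n Trials.
#' @param conf Confidence level.
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' wilson_interval(10, 100)  # (0.0552, 0.1744)
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(lower = centre - half, upper = centre + half)
}

#' Six-class SNV spectrum with Wilson intervals and Ts/Tv
#'
#' Counts and proportions of the strand-collapsed substitution classes, a
#' 95% Wilson score interval per class, and the transition/transversion ratio
#' with a seeded percentile bootstrap CI over events.
#'
#' @param ref,alt Vectors of single-base ref and alt alleles, one per SNV.
#' @param conf Confidence level.
#' @param boot Bootstrap replicates for the Ts/Tv CI.
#' @param seed RNG seed.
#' @return List of class `"spectrum_summary"`: `classes` data frame (class,
#'   count, proportion, Wilson bounds, transition flag), `ts`, `tv`,
#'   `ts_tv`, `ts_tv_ci`.
#' @export
snv_spectrum <- function(ref, alt, conf = 0.95, boot = 10000, seed = 1) {
  cls <- snv_class(ref, alt)
  n <- length(cls)
  counts <- table(cls)
  wi <- t(vapply(as.integer(counts), function(x) wilson_interval(x, n, conf),
                 c(lower = 0, upper = 0)))
  classes <- data.frame(class = names(counts), count = as.integer(counts),
                        proportion = as.integer(counts) / n,
                        lower = wi[, "lower"], upper = wi[, "upper"],
                        transition = names(counts) %in% .transition_classes,
                        stringsAsFactors = FALSE)
  rownames(classes) <- NULL
  is_ts <- cls %in% .transition_classes
  ts <- sum(is_ts); tv <- n - ts
  ts_tv <- ts / tv
  ci <- withr::with_seed(seed, {
    ratios <- replicate(boot, {
      b <- sample(is_ts, n, replace = TRUE)
      sum(b) / sum(!b)
    })
    stats::quantile(ratios[is.finite(ratios)],
                    c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  })
  structure(list(classes = classes, n = n, ts = ts, tv = tv, ts_tv = ts_tv,
                 ts_tv_ci = ci, conf = conf),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("SNV spectrum (n = %d):\n", x$n))
  print(x$classes, row.names = FALSE, digits = 4)
  cat(sprintf("Ts/Tv = %.3f (%d/%d), %d%% CI [%.3f, %.3f]\n", x$ts_tv,
              x$ts, x$tv, round(100 * x$conf), x$ts_tv_ci[1], x$ts_tv_ci[2]))
  invisible(x)
}

#' G/C-site mutational bias
#'
#' Tests whether SNVs arise at G/C reference sites more often than expected.
#' The null success probability defaults to the callable-site G/C fraction
#' (the composition-based null under which the test is about per-site rates);
#' pass 0.5 for a raw count comparison.
#'
#' @param ref Reference base per SNV (or a spectrum class factor).
#' @param gc_null Null probability that a mutation sits at a G/C site.
#' @return List with `n_gc`, `n`, `percent_gc` and `test` (`ma_test`, exact
#'   two-sided binomial).
#' @export
gc_at_bias <- function(ref, gc_null) {
  stopifnot(gc_null > 0, gc_null < 1)
  at_gc <- if (is.factor(ref) || all(grepl(">", ref)))
    grepl("^G:C", as.character(ref)) else ref %in% c("G", "C")
  n <- length(at_gc); n_gc <- sum(at_gc)
  bt <- stats::binom.test(n_gc, n, p = gc_null)
  list(n_gc = n_gc, n = n, percent_gc = 100 * n_gc / n,
       test = ma_test("gc_at_binomial", n_gc / n, bt$p.value, n = n,
                      options = list(null_prob = gc_null)))
}

# lower median: for an even count, the smaller of the two central values
median_low <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

#' Indel deletion bias and size summaries
#'
#' Exact binomial test of deletions vs insertions against equal probability,
#' and the median size per sign (lower median on even counts).
#'
#' @param sizes Signed indel lengths (negative = deletion).
#' @return List with counts, medians, and `test` (`ma_test`).
#' @export
indel_stats <- function(sizes) {
  stopifnot(all(sizes != 0))
  n_del <- sum(sizes < 0); n_ins <- sum(sizes > 0)
  bt <- stats::binom.test(n_del, n_del + n_ins, p = 0.5)
  list(n_deletions = n_del, n_insertions = n_ins,
       median_deletion = if (n_del) median_low(abs(sizes[sizes < 0])) else NA,
       median_insertion = if (n_ins) median_low(sizes[sizes > 0]) else NA,
       test = ma_test("deletion_bias_binomial", n_del / (n_del + n_ins),
                      bt$p.value, n = n_del + n_ins))
}

#' Genic and nonsynonymous fractions against selection-free nulls
#'
#' The genic null is the fraction of callable sites inside gene intervals;
#' SNV and INDEL genic fractions are tested against it with exact binomial
#' tests. The nonsynonymous fraction among coding SNVs is tested against a
#' configurable null (default 0.744, the expected fraction in the absence of
#' selection for the fly genome).
#'
#' @param events Event data frame with columns `category`, `genic`, and
#'   optionally `consequence` (values containing `"nonsynonymous"` /
#'   `"synonymous"` for coding SNVs).
#' @param genes Gene [interval_track()].
#' @param mask A `"callable_mask"`.
#' @param nonsyn_null Null nonsynonymous fraction among coding SNVs.
#' @return List with `genic_null`, per-category fractions and tests, and the
#'   nonsynonymous fraction and test (NA when no consequence annotations are
#'   present).
#' @export
genic_fractions <- function(events, genes, mask, nonsyn_null = 0.744) {
  inside <- count_callable_in(mask, genes)$callable
  total <- mask$summary$callable[mask$summary$contig == "total"]
  genic_null <- inside / total
  one <- function(cat) {
    sel <- events$category == cat
    k <- sum(events$genic[sel], na.rm = TRUE); n <- sum(sel)
    if (!n) return(list(fraction = NA, n = 0, test = NULL))
    bt <- stats::binom.test(k, n, p = genic_null)
    list(fraction = k / n, n = n,
         test = ma_test(paste0("genic_", cat, "_binomial"), k / n,
                        bt$p.value, n = n,
                        options = list(null_prob = genic_null)))
  }
  nonsyn <- list(fraction = NA, n = 0, test = NULL)
  if ("consequence" %in% names(events)) {
    coding <- events$category == "SNV" &
      events$consequence %in% c("nonsynonymous", "synonymous")
    k <- sum(events$consequence[coding] == "nonsynonymous")
    n <- sum(coding)
    if (n) {
      bt <- stats::binom.test(k, n, p = nonsyn_null)
      nonsyn <- list(fraction = k / n, n = n,
                     test = ma_test("nonsynonymous_binomial", k / n,
                                    bt$p.value, n = n,
                                    options = list(null_prob = nonsyn_null)))
    }
  }
  list(genic_null = genic_null, snv = one("SNV"), indel = one("INDEL"),
       nonsynonymous = nonsyn)
}
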