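#' Project an interval-track covariate onto windows by overlap weighting
#'
#' Each window receives the overlap-weighted average of the track values it
#' intersects: `sum(overlap_bp * value) / sum(overlap_bp)`. Windows with no
#' overlapping track interval get NA. The projected value always lies within
#' the range of the overlapping track values.
#'
#' @param track [interval_track()] with a numeric `value` column.
#' @param windows Data frame with `contig`, `start`, `end` (0-based
#'   half-open).
#' @return Numeric vector, one value per window.
#' @export
project_covariate <- function(track, windows) {
  if (is.null(track$value) || !is.numeric(track$value))
    stop("track must carry a numeric value column")
  out <- rep(NA_real_, nrow(windows))
  for (ctg in unique(windows$contig)) {
    wsel <- which(windows$contig == ctg)
    tsub <- track[track$contig == ctg, , drop = FALSE]
    if (!nrow(tsub)) next
    wir <- IRanges::IRanges(start = windows$start[wsel] + 1L,
                            end = windows$end[wsel])
    tir <- IRanges::IRanges(start = tsub$start + 1L, end = tsub$end)
    hits <- IRanges::findOverlaps(wir, tir)
    if (!length(hits)) next
    ovl <- IRanges::width(IRanges::pintersect(wir[S4Vectors::queryHits(hits)],
                                              tir[S4Vectors::subjectHits(hits)]))
    val <- tsub$value[S4Vectors::subjectHits(hits)]
    num <- tapply(ovl * val, S4Vectors::queryHits(hits), sum)
    den <- tapply(ovl, S4Vectors::queryHits(hits), sum)
    out[wsel[as.integer(names(num))]] <- as.numeric(num / den)
  }
  out
}

#' Scale a covariate for regression
#'
#' `divide_by_mean` (default) divides by the mean of the supplied values;
#' `z_score` centres and scales. Means are taken over the windows actually
#' entering the model fit.
#'
#' @param values Numeric vector.
#' @param mode `"divide_by_mean"` or `"z_score"`.
#' @return Scaled vector with attribute `"scaling"` recording mode and
#'   parameters.
#' @export
scale_covariates <- function(values, mode = c("divide_by_mean", "z_score")) {
  mode <- match.arg(mode)
  m <- mean(values, na.rm = TRUE)
  out <- if (mode == "divide_by_mean") values / m
  else (values - m) / stats::sd(values, na.rm = TRUE)
  attr(out, "scaling") <- list(mode = mode, mean = m,
                               sd = if (mode == "z_score")
                                 stats::sd(values, na.rm = TRUE) else NULL)
  out
}

#' Annotate chromatin-state windows with covariates and event counts
#'
#' Fills each window with callable and G/C site counts from the mask,
#' overlap-weighted recombination rate and replication timing, the power
#' covariate (callable sites x number of lines), and event counts (an event
#' is assigned to the window whose half-open interval contains its start
#' position). Windows missing recombination or timing data, or with zero
#' callable sites, are flagged `excluded`.
#'
#' @param windows Data frame with `contig`, `start`, `end`, `state`.
#' @param mask A `"callable_mask"` carrying G/C state.
#' @param recomb,timing Numeric-valued [interval_track()]s.
#' @param events Point-mutation event data frame (`contig`, `start`,
#'   optionally `line_id`), or NULL.
#' @param te_events TE event data frame (`contig`, `breakpoint`), or NULL.
#' @param meta Optional [line_metadata()]; splits event counts by treatment
#'   (columns `n_point_dsb_plus` etc.) in addition to totals.
#' @param n_lines Number of lines for the power covariate (defaults to
#'   `nrow(meta)`).
#' @return The windows data frame with columns `callable`, `gc_sites`,
#'   `gc_frac`, `recomb`, `timing`, `power`, `n_point`, `n_te`, `excluded`
#'   (and per-treatment counts when `meta` is given).
#' @export
annotate_windows <- function(windows, mask, recomb, timing, events = NULL,
                             te_events = NULL, meta = NULL, n_lines = NULL) {
  w <- as.data.frame(windows)
  if (is.null(n_lines)) n_lines <- if (!is.null(meta)) nrow(meta) else 1L
  w$callable <- NA_real_; w$gc_sites <- NA_real_
  for (ctg in unique(w$contig)) {
    v <- mask$mask[[ctg]]
    g <- if (!is.null(mask$gc)) mask$gc[[ctg]] else NULL
    if (is.null(v)) stop("mask lacks contig ", ctg)
    cs <- c(0, cumsum(v))
    cg <- if (!is.null(g)) c(0, cumsum(v & g)) else NULL
    sel <- w$contig == ctg
    s <- pmax(0, w$start[sel]); e <- pmin(length(v), w$end[sel])
    w$callable[sel] <- cs[e + 1] - cs[s + 1]
    if (!is.null(cg)) w$gc_sites[sel] <- cg[e + 1] - cg[s + 1]
  }
  w$gc_frac <- ifelse(w$callable > 0, w$gc_sites / w$callable, NA)
  w$recomb <- project_covariate(recomb, w)
  w$timing <- project_covariate(timing, w)
  w$power <- w$callable * n_lines

  assign_counts <- function(contig, pos1) {
    # 1-based point pos1 lies in window [start, end) iff start < pos1 <= end
    n <- integer(nrow(w))
    for (ctg in unique(contig)) {
      sel <- which(w$contig == ctg)
      p <- pos1[contig == ctg]
      if (!length(p) || !length(sel)) next
      ir <- IRanges::IRanges(start = w$start[sel] + 1L, end = w$end[sel])
      q <- IRanges::IRanges(start = p, width = 1L)
      hits <- IRanges::findOverlaps(q, ir)
      tb <- table(S4Vectors::subjectHits(hits))
      n[sel[as.integer(names(tb))]] <- as.integer(tb)
    }
    n
  }
  w$n_point <- if (!is.null(events) && nrow(events))
    assign_counts(events$contig, events$start) else 0L
  w$n_te <- if (!is.null(te_events) && nrow(te_events))
    assign_counts(te_events$contig, round(te_events$breakpoint)) else 0L
  if (!is.null(meta) && !is.null(events) && "line_id" %in% names(events)) {
    for (grp in c("dsb_plus", "dsb_minus")) {
      lines <- meta$line_id[meta$treatment == grp]
      sub <- events[events$line_id %in% lines, , drop = FALSE]
      w[[paste0("n_point_", grp)]] <- if (nrow(sub))
        assign_counts(sub$contig, sub$start) else 0L
    }
  }
  w$excluded <- is.na(w$recomb) | is.na(w$timing) | w$callable == 0
  w
}

#' Fit a negative-binomial regression of window counts on genomic covariates
#'
#' Fits an nbinom2 (variance `mu + mu^2 / theta`) log-link regression via
#' maximum likelihood, with the power covariate either as a log offset
#' (exposure model, default) or as a linearly scaled predictor. Excluded
#' windows are dropped before fitting. The fit is deterministic given the
#' data.
#'
#' @param windows Annotated window data frame (see [annotate_windows()]).
#' @param response Name of the count column.
#' @param covariates Character vector of numeric covariate column names that
#'   are divided by their mean before fitting.
#' @param unscaled Covariate columns entered as-is (e.g. replication timing).
#' @param state_col Name of the chromatin-state factor column (NULL to omit);
#'   the baseline level is `BK`, the largest class.
#' @param power `"offset"` or `"predictor"`.
#' @param theta_fix Optionally fix the dispersion parameter at this value
#'   (used for Poisson-limit checks).
#' @return Object of class `"nb_fit"`: coefficient table (estimate, SE, z,
#'   p), `theta`, `logLik`, `converged`, the model frame and options, and the
#'   underlying \pkg{glmmTMB} fit.
#' @export
fit_nb <- function(windows, response = "n_point",
                   covariates = c("gc_frac", "recomb"),
                   unscaled = "timing", state_col = "state",
                   power = c("offset", "predictor"), theta_fix = NULL) {
  power <- match.arg(power)
  d <- windows[!windows$excluded, , drop = FALSE]
  if (nrow(d) < 10) stop("need at least 10 usable windows")
  if (any(d[[response]] < 0) || any(d[[response]] != round(d[[response]])))
    stop("counts must be non-negative integers")
  terms <- character(0)
  for (cv in covariates) {
    d[[paste0(cv, "_scaled")]] <- as.numeric(scale_covariates(d[[cv]]))
    terms <- c(terms, paste0(cv, "_scaled"))
  }
  terms <- c(terms, unscaled)
  if (!is.null(state_col) && state_col %in% names(d)) {
    lev <- unique(as.character(d[[state_col]]))
    lev <- c(intersect("BK", lev), sort(setdiff(lev, "BK")))
    d[[state_col]] <- factor(d[[state_col]], levels = lev)
    if (nlevels(d[[state_col]]) > 1) terms <- c(terms, state_col)
  }
  if (power == "offset") {
    if (any(d$power <= 0)) stop("offset requires positive power")
    terms <- c(terms, "offset(log(power))")
  } else {
    d$power_scaled <- as.numeric(scale_covariates(d$power))
    terms <- c(terms, "power_scaled")
  }
  fml <- stats::reformulate(terms, response = response)
  args <- list(formula = fml, data = d, family = glmmTMB::nbinom2())
  if (!is.null(theta_fix)) {
    args$start <- list(betad = log(theta_fix))
    args$map <- list(betad = factor(NA))
  }
  fit <- do.call(glmmTMB::glmmTMB, args)
  nb_fit_from_glmmTMB(fit, data = d, response = response, power = power,
                      theta_fix = theta_fix)
}

nb_fit_from_glmmTMB <- function(fit, data, response, power,
                                theta_fix = NULL, label = "nb_fit") {
  sm <- summary(fit)$coefficients$cond
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"],
                      z = sm[, "Estimate"] / sm[, "Std. Error"],
                      p = 2 * stats::pnorm(-abs(sm[, "Estimate"] /
                                                  sm[, "Std. Error"])),
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  conv <- isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
  # maximised log-likelihood straight from the objective: logLik() would be
  # NA on boundary fits even though the maximum is valid
  ll <- -fit$fit$objective
  df <- sum(!names(fit$fit$parfull) %in% c("b", "bzi"))
  structure(list(coefficients = coefs,
                 theta = glmmTMB::sigma(fit),
                 logLik = ll,
                 df = df,
                 converged = conv, n = nrow(data), response = response,
                 power = power, theta_fix = theta_fix, fit = fit,
                 label = label),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("Negative-binomial fit (%s; power as %s; n = %d windows)\n",
              x$label, x$power, x$n))
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("theta = %.4g, logLik = %.2f, converged = %s\n", x$theta,
              x$logLik, x$converged))
  invisible(x)
}

#' @export
coef.nb_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
logLik.nb_fit <- function(object, ...) {
  structure(object$logLik, df = object$df, class = "logLik")
}

#' Likelihood-ratio test between nested count-regression fits
#'
#' `2 * (logLik(full) - logLik(reduced))` against a chi-square reference with
#' degrees of freedom equal to the parameter-count difference. Both fits
#' must be on the same data rows.
#'
#' @param full,reduced `"nb_fit"` objects (reduced nested in full).
#' @return An `ma_test`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  if (full$n != reduced$n)
    stop("fits must use the same data rows")
  df <- full$df - reduced$df
  if (df < 0) stop("reduced model has more parameters than full")
  stat <- max(0, 2 * (full$logLik - reduced$logLik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  ma_test("likelihood_ratio", stat, p, n = full$n,
          options = list(df = df))
}

#' Test treatment-by-covariate interactions with a window random intercept
#'
#' Stacks the window table into two rows per window (one per treatment group,
#' each with its own count and its own power = callable sites x group size),
#' and fits nbinom2 mixed models with a per-window random intercept by
#' Laplace approximation: a full model with treatment main effect and all
#' treatment x covariate interactions, and a reduced model without the
#' interactions. When the mixed fit fails to converge, a fixed-effect
#' per-window paired model is fitted instead and the output labelled
#' accordingly.
#'
#' @param windows Annotated windows carrying per-treatment counts
#'   (`n_point_dsb_plus`, `n_point_dsb_minus` for `response = "n_point"`).
#' @param meta [line_metadata()] (for group sizes).
#' @param response Base name of the count columns.
#' @param covariates,unscaled,state_col As in [fit_nb()].
#' @param power `"offset"` or `"predictor"`.
#' @return List of class `"nb_interaction"`: `full`, `reduced` (`nb_fit`s),
#'   `lrt` (`ma_test` of all interactions jointly), `stacked` data, and
#'   `method` (`"laplace_random_intercept"` or `"fixed_effect_fallback"`).
#' @export
fit_treatment_interaction <- function(windows, meta, response = "n_point",
                                      covariates = c("gc_frac", "recomb"),
                                      unscaled = "timing", state_col = "state",
                                      power = c("offset", "predictor")) {
  power <- match.arg(power)
  d <- windows[!windows$excluded, , drop = FALSE]
  d$window_id <- factor(seq_len(nrow(d)))
  n_grp <- table(meta$treatment)
  stack <- function(grp) {
    s <- d
    s$treatment <- grp
    s$count <- d[[paste0(response, "_", grp)]]
    s$power <- d$callable * as.integer(n_grp[[grp]])
    s
  }
  dd <- rbind(stack("dsb_plus"), stack("dsb_minus"))
  dd$treatment <- factor(dd$treatment, levels = c("dsb_plus", "dsb_minus"))
  terms <- character(0)
  for (cv in covariates) {
    dd[[paste0(cv, "_scaled")]] <- as.numeric(scale_covariates(dd[[cv]]))
    terms <- c(terms, paste0(cv, "_scaled"))
  }
  terms <- c(terms, unscaled)
  if (!is.null(state_col) && state_col %in% names(dd)) {
    lev <- unique(as.character(dd[[state_col]]))
    lev <- c(intersect("BK", lev), sort(setdiff(lev, "BK")))
    dd[[state_col]] <- factor(dd[[state_col]], levels = lev)
    if (nlevels(dd[[state_col]]) > 1) terms <- c(terms, state_col)
  }
  off <- if (power == "offset") "offset(log(power))" else NULL
  if (power == "predictor") {
    dd$power_scaled <- as.numeric(scale_covariates(dd$power))
  }
  pw <- if (power == "predictor") "power_scaled" else NULL
  main <- paste(c(terms, "treatment", pw, off), collapse = " + ")
  inter <- paste(paste0("treatment:", terms), collapse = " + ")
  f_full <- stats::as.formula(paste("count ~", main, "+", inter,
                                    "+ (1 | window_id)"))
  f_red <- stats::as.formula(paste("count ~", main, "+ (1 | window_id)"))
  fit_one <- function(f) {
    suppressWarnings(glmmTMB::glmmTMB(f, data = dd,
                                      family = glmmTMB::nbinom2()))
  }
  full_raw <- fit_one(f_full)
  red_raw <- fit_one(f_red)
  # a random-intercept variance on the zero boundary often trips the
  # optimiser's "false convergence" flag without invalidating the maximised
  # likelihood; accept the fit when the likelihood is finite and the fixed-
  # effect gradient is essentially zero, else fall back to fixed effects
  ok <- function(ft) {
    gr <- ft$sdr$gradient.fixed
    is.finite(ft$fit$objective) &&
      !is.null(gr) && all(is.finite(gr)) && max(abs(gr)) < 1e-2
  }
  method <- "laplace_random_intercept"
  if (!ok(full_raw) || !ok(red_raw)) {
    method <- "fixed_effect_fallback"
    f_full <- stats::as.formula(paste("count ~", main, "+", inter,
                                      "+ window_id"))
    f_red <- stats::as.formula(paste("count ~", main, "+ window_id"))
    full_raw <- fit_one(f_full)
    red_raw <- fit_one(f_red)
  }
  full <- nb_fit_from_glmmTMB(full_raw, dd, "count", power,
                              label = paste0("interaction_full_", method))
  reduced <- nb_fit_from_glmmTMB(red_raw, dd, "count", power,
                                 label = paste0("interaction_reduced_", method))
  lrt <- likelihood_ratio_test(full, reduced)
  structure(list(full = full, reduced = reduced, lrt = lrt, method = method,
                 stacked = dd),
            class = "nb_interaction")
}

#' @export
print.nb_interaction <- function(x, ...) {
  cat("Treatment-interaction model (", x$method, ")\n", sep = "")
  print(x$full)
  cat("LRT dropping all interactions: ")
  print(x$lrt)
  invisible(x)
}
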