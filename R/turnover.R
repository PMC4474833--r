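# 15N pulse-labeling turnover kinetics: Y transform, per-protein synthesis
# rate fits, half-life censoring, and proteome-level summaries.

#' Linearizing transform of the light/heavy ratio
#'
#' Under a steady-state proteome the light/heavy ratio R at labeling time t
#' satisfies 1 + 1/R = exp(k_syn t), so Y = ln(1 + 1/R) grows linearly in
#' time with slope k_syn.
#'
#' @param R Positive 14N/15N area ratio(s).
#' @return Y = ln(1 + 1/R), same length as `R`.
#' @examples
#' y_transform(1)            # ln 2: half the pool replaced
#' y_transform(1 / (exp(1) - 1))  # exactly 1
#' @export
y_transform <- function(R) {
  if (!is.numeric(R) || any(!is.finite(R)) || any(R <= 0))
    stop("R must be positive and finite")
  log1p(1 / R)
}

.fit_one <- function(t, R, min_points, through_origin, censor_halflife,
                     censor_p) {
  keep <- is.finite(t) & is.finite(R) & R > 0 & t > 0
  t <- t[keep]; R <- R[keep]
  n <- length(t)
  if (n < min_points) {
    return(data.frame(k_syn = NA_real_, intercept = NA_real_,
                      pearson_r = NA_real_, p_value = NA_real_,
                      half_life = NA_real_, censored = NA,
                      n_points = n, reason = "fewer than min_points",
                      stringsAsFactors = FALSE))
  }
  Y <- y_transform(R)
  if (through_origin) {
    fit <- lm(Y ~ 0 + t)
    slope <- unname(coef(fit)[1L]); intercept <- 0
  } else {
    fit <- lm(Y ~ t)
    slope <- unname(coef(fit)[2L]); intercept <- unname(coef(fit)[1L])
  }
  if (sd(Y) == 0) {
    r <- 0; p <- 1
  } else {
    r <- cor(t, Y)
    # two-sided test of the Pearson correlation, t-distributed on n - 2 df
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
  }
  half_life <- if (slope > 0) log(2) / slope else Inf
  censored <- half_life > censor_halflife | p > censor_p
  data.frame(k_syn = slope, intercept = intercept, pearson_r = r,
             p_value = p, half_life = half_life, censored = censored,
             n_points = n, reason = NA_character_, stringsAsFactors = FALSE)
}

#' Fit the synthesis rate constant for one protein
#'
#' Ordinary least squares of Y = ln(1 + 1/R) on labeling time; the slope is
#' the synthesis rate constant k_syn and the half-life is ln(2)/k_syn.
#' Estimates with half-life above `censor_halflife` minutes or fit P above
#' `censor_p` are flagged censored: such slow turnover cannot be resolved
#' within the labeling window.
#'
#' @param series A data.frame with columns `time_min` and `ratio` (one
#'   protein), or a two-column data.frame `(t, R)`.
#' @param min_points Minimum usable timepoints (default 3); below this the
#'   estimate is withheld with a reason.
#' @param through_origin Force the strict zero-intercept form of the model
#'   (default `FALSE`: a free intercept absorbs labeling lag).
#' @param censor_halflife Half-life censoring threshold in minutes
#'   (default 500).
#' @param censor_p Fit P-value above which the estimate is censored
#'   (default 0.05).
#' @return One-row data.frame: `k_syn` (per minute), `intercept`,
#'   `pearson_r`, `p_value`, `half_life` (minutes, `Inf` when the slope is
#'   non-positive), `censored`, `n_points`, `reason`.
#' @export
fit_ksyn <- function(series, min_points = 3, through_origin = FALSE,
                     censor_halflife = 500, censor_p = 0.05) {
  nm <- names(series)
  if (all(c("time_min", "ratio") %in% nm)) {
    t <- series$time_min; R <- series$ratio
  } else if (ncol(series) >= 2L) {
    t <- series[[1L]]; R <- series[[2L]]
  } else stop("series must have columns time_min and ratio")
  .fit_one(t, R, min_points, through_origin, censor_halflife, censor_p)
}

#' Fit turnover kinetics across a cohort of proteins
#'
#' The central model of the package: for every protein in a long-format
#' ratio table, fits Y = ln(1 + 1/R) against labeling time by ordinary
#' least squares, yielding the synthesis rate constant k_syn (slope),
#' Pearson correlation, fit P-value and half-life ln(2)/k_syn, with
#' censoring of unreliable long half-lives.
#'
#' @param data data.frame with columns `protein_id`, `time_min`, `ratio`.
#'   Rows with missing ratios are dropped, not imputed.
#' @inheritParams fit_ksyn
#' @return An object of class `"turnover_fit"` with components `estimates`
#'   (one row per protein), `data`, `settings` and `call`. Supports
#'   `print`, `summary`, `coef`, `predict`, `residuals`, `plot` and
#'   `simulate` methods.
#' @seealso [fit_ksyn()] for a single series, [half_life_stats()],
#'   [proteome_trend()], [compare_half_life_distributions()].
#' @export
turnover_fit <- function(data, min_points = 3, through_origin = FALSE,
                         censor_halflife = 500, censor_p = 0.05) {
  stopifnot(is.data.frame(data),
            all(c("protein_id", "time_min", "ratio") %in% names(data)))
  data <- data[!is.na(data$ratio), , drop = FALSE]
  est <- do.call(rbind, lapply(split(data, data$protein_id), function(d) {
    cbind(protein_id = d$protein_id[1L],
          .fit_one(d$time_min, d$ratio, min_points, through_origin,
                   censor_halflife, censor_p))
  }))
  rownames(est) <- NULL
  structure(list(estimates = est, data = data,
                 settings = list(min_points = min_points,
                                 through_origin = through_origin,
                                 censor_halflife = censor_halflife,
                                 censor_p = censor_p),
                 call = match.call()),
            class = "turnover_fit")
}

#' @export
print.turnover_fit <- function(x, ...) {
  e <- x$estimates
  ok <- !is.na(e$k_syn)
  cat("15N pulse-labeling turnover fit\n")
  cat(sprintf("  proteins: %d fitted, %d withheld (<%d points)\n",
              sum(ok), sum(!ok), x$settings$min_points))
  if (any(ok)) {
    cat(sprintf("  median k_syn: %.3g /min; median half-life: %.1f min\n",
                median(e$k_syn[ok]), median(e$half_life[ok])))
    cat(sprintf("  censored (half-life > %g min or P > %g): %d (%.1f%%)\n",
                x$settings$censor_halflife, x$settings$censor_p,
                sum(e$censored[ok]), 100 * mean(e$censored[ok])))
  }
  invisible(x)
}

#' @export
summary.turnover_fit <- function(object, ...) {
  e <- object$estimates
  ok <- !is.na(e$k_syn)
  s <- list(
    n_proteins = nrow(e),
    n_fitted = sum(ok),
    n_withheld = sum(!ok),
    settings = object$settings,
    half_life = half_life_stats(object),
    median_k_syn = if (any(ok)) median(e$k_syn[ok]) else NA_real_,
    fraction_censored = if (any(ok)) mean(e$censored[ok]) else NA_real_)
  class(s) <- "summary.turnover_fit"
  s
}

#' @export
print.summary.turnover_fit <- function(x, ...) {
  cat("Turnover kinetics summary\n")
  cat(sprintf("  %d proteins (%d fitted, %d withheld)\n",
              x$n_proteins, x$n_fitted, x$n_withheld))
  cat(sprintf("  median k_syn: %.4g /min\n", x$median_k_syn))
  hs <- x$half_life
  cat(sprintf("  mean half-life (uncensored): %.2f min\n", hs$mean_half_life))
  cat(sprintf("  fraction below %g min: %.3f; fraction censored above %g min: %.3f\n",
              hs$thresholds[1L], hs$fraction_below,
              hs$thresholds[2L], hs$fraction_above))
  invisible(x)
}

#' @export
coef.turnover_fit <- function(object, ...) {
  setNames(object$estimates$k_syn, object$estimates$protein_id)
}

#' @export
predict.turnover_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  e <- object$estimates
  i <- match(newdata$protein_id, e$protein_id)
  e$intercept[i] + e$k_syn[i] * newdata$time_min
}

#' @export
residuals.turnover_fit <- function(object, ...) {
  d <- object$data
  y_transform(d$ratio) - predict(object, d)
}

#' @export
plot.turnover_fit <- function(x, type = c("fits", "half_life"),
                              proteins = NULL, ...) {
  type <- match.arg(type)
  e <- x$estimates
  if (type == "half_life") {
    hl <- pmin(e$half_life[!is.na(e$half_life)], x$settings$censor_halflife)
    hist(hl, breaks = 25, col = "steelblue", border = "white",
         main = "Protein half-lives",
         xlab = sprintf("half-life (min, censored at %g)",
                        x$settings$censor_halflife), ...)
    return(invisible(x))
  }
  if (is.null(proteins))
    proteins <- head(e$protein_id[!is.na(e$k_syn)], 4L)
  op <- par(mfrow = c(ceiling(length(proteins) / 2), min(2, length(proteins))))
  on.exit(par(op))
  for (p in proteins) {
    d <- x$data[x$data$protein_id == p, ]
    plot(d$time_min, y_transform(d$ratio), pch = 19,
         xlab = "t (min)", ylab = "Y = ln(1 + 1/R)", main = p, ...)
    ei <- e[e$protein_id == p, ]
    abline(ei$intercept, ei$k_syn, col = "firebrick")
  }
  invisible(x)
}

#' Simulate replicate ratio tables from a fitted turnover model
#'
#' Draws new light/heavy ratios at the observed timepoints from each
#' protein's fitted line, perturbed by Gaussian noise on the Y scale at the
#' pooled residual standard deviation (multiplicative on 1 + 1/R).
#'
#' @param object A `"turnover_fit"`.
#' @param nsim Number of replicate datasets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return List of `nsim` data.frames shaped like the input data.
#' @export
simulate.turnover_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$data
  mu <- predict(object, d)
  sdres <- sd(residuals(object))
  lapply(seq_len(nsim), function(i) {
    y <- mu + rnorm(length(mu), sd = sdres)
    y <- pmax(y, 1e-12)
    data.frame(protein_id = d$protein_id, time_min = d$time_min,
               ratio = 1 / expm1(y), stringsAsFactors = FALSE)
  })
}

#' Proteome-wide ratio trend over labeling time
#'
#' Aggregates the per-protein light/heavy ratio at each timepoint (median
#' by default) and fits the aggregate against time; a significantly
#' negative slope is the proteome-level signature of ongoing synthesis.
#'
#' @param data Long ratio table (`protein_id`, `time_min`, `ratio`), or a
#'   `"turnover_fit"`.
#' @param aggregate `"median"` (robust default) or `"mean"`.
#' @return List with `per_time` (data.frame of `time_min` and aggregated
#'   `ratio`), `slope`, `pearson_r` and `p_value`.
#' @export
proteome_trend <- function(data, aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  if (inherits(data, "turnover_fit")) data <- data$data
  data <- data[!is.na(data$ratio), , drop = FALSE]
  agg <- vapply(split(data$ratio, data$time_min),
                if (aggregate == "median") median else mean, 0)
  tt <- as.numeric(names(agg))
  if (length(tt) < 3L) stop("need at least 3 timepoints")
  fit <- lm(agg ~ tt)
  ct <- cor.test(tt, agg)
  list(per_time = data.frame(time_min = tt, ratio = unname(agg)),
       slope = unname(coef(fit)[2L]),
       pearson_r = unname(ct$estimate), p_value = ct$p.value)
}

#' Summary statistics of a half-life distribution
#'
#' @param estimates A `"turnover_fit"` or its `estimates` data.frame.
#' @param thresholds `c(lower, upper)` minutes; the summary reports the
#'   fraction of proteins below the lower threshold and at/above the upper
#'   (censoring) threshold (default `c(100, 500)`).
#' @param exclude_censored_from_mean Compute the mean half-life over
#'   uncensored proteins only (default `TRUE`; under strong stress, where
#'   most proteins are censored, the fractions are the meaningful summary).
#' @param breaks Histogram bin width in minutes (default 25).
#' @return List with `mean_half_life`, `fraction_below`, `fraction_above`,
#'   `thresholds`, `n` and `histogram` (counts per bin with censored
#'   half-lives stacked in the top bin).
#' @export
half_life_stats <- function(estimates, thresholds = c(100, 500),
                            exclude_censored_from_mean = TRUE,
                            breaks = 25) {
  if (inherits(estimates, "turnover_fit")) estimates <- estimates$estimates
  e <- estimates[!is.na(estimates$k_syn), , drop = FALSE]
  if (!nrow(e)) stop("no fitted estimates")
  cap <- thresholds[2L]
  hl_capped <- pmin(e$half_life, cap)
  censored <- e$censored | e$half_life > cap
  mean_hl <- if (exclude_censored_from_mean) {
    if (any(!censored)) mean(e$half_life[!censored]) else NA_real_
  } else mean(hl_capped)
  bins <- seq(0, cap, by = breaks)
  hist_counts <- table(cut(hl_capped, breaks = c(bins, Inf),
                           include.lowest = TRUE, right = TRUE))
  list(mean_half_life = mean_hl,
       fraction_below = mean(hl_capped < thresholds[1L] & !censored),
       fraction_above = mean(censored),
       thresholds = thresholds, n = nrow(e),
       histogram = hist_counts)
}

#' Compare two half-life distributions
#'
#' Two-sample Kolmogorov-Smirnov test on half-life values, with censored
#' half-lives entered at the censoring cap (the same convention used for
#' plotting: values above the cap are shown at the cap).
#'
#' @param a,b `"turnover_fit"` objects or numeric half-life vectors.
#' @param cap Censoring cap in minutes (default 500).
#' @return List with `D` (KS statistic) and `p_value`.
#' @export
compare_half_life_distributions <- function(a, b, cap = 500) {
  to_hl <- function(x) {
    if (inherits(x, "turnover_fit")) {
      e <- x$estimates[!is.na(x$estimates$k_syn), ]
      x <- e$half_life
    }
    x <- x[!is.na(x)]
    if (!length(x)) stop("empty half-life sample")
    pmin(x, cap)
  }
  ha <- to_hl(a); hb <- to_hl(b)
  kt <- suppressWarnings(ks.test(ha, hb))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}

#' Read a long-format ratio table
#'
#' @param path TSV with columns `protein_id`, `time_min`, `ratio`.
#' @return data.frame ready for [turnover_fit()].
#' @export
read_ratio_tsv <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "time_min", "ratio") %in% names(x)))
  x
}
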