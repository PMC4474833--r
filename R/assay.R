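# Growth-curve and qPCR arithmetic: Beer-Lambert OD, moving averages,
# exponential growth-rate fits, group comparisons and delta-delta-Ct.

#' Optical density from transmitted light intensity
#'
#' Beer-Lambert: OD = log10(I_blank / I), with the blank (cell-free)
#' intensity as the reference.
#'
#' @param intensity Transmitted intensity (> 0).
#' @param blank Blank intensity (> 0).
#' @return OD values.
#' @export
od_from_intensity <- function(intensity, blank) {
  if (any(intensity <= 0) || any(blank <= 0))
    stop("intensities must be positive")
  log10(blank / intensity)
}

#' Centered moving average over a time window
#'
#' Each point is replaced by the mean of all observations within
#' `window / 2` minutes on either side; edges use whatever points are
#' available (shrinking window).
#'
#' @param times Observation times in minutes (increasing).
#' @param values Observed values.
#' @param window Window width in minutes (default 5).
#' @return Smoothed values, same length as the input.
#' @export
moving_average <- function(times, values, window = 5) {
  if (window <= 0) stop("window must be positive")
  stopifnot(length(times) == length(values))
  half <- window / 2
  vapply(seq_along(times), function(i) {
    sel <- abs(times - times[i]) <= half
    mean(values[sel])
  }, 0)
}

#' Exponential growth rate from an OD time series
#'
#' Slope of the ordinary least-squares fit of ln(OD) against time inside
#' the fit window; a negative rate constant indicates net cell death.
#' Non-positive OD readings inside the window are dropped with a warning.
#'
#' @param curve data.frame with `time_min` and `od` (e.g. from
#'   [simulate_growth()]).
#' @param fit_window Optional `c(start, end)` minutes; default uses the
#'   whole curve.  `"auto"` slides a window of `auto_width` minutes and
#'   keeps the one maximizing R-squared.
#' @param auto_width Width of the automatic window in minutes
#'   (default 60).
#' @return List with `k` (per minute), `se`, `r_squared`, `n` and
#'   `window`.
#' @export
growth_rate <- function(curve, fit_window = NULL, auto_width = 60) {
  stopifnot(all(c("time_min", "od") %in% names(curve)))
  pick <- function(win) {
    d <- curve[curve$time_min >= win[1L] & curve$time_min <= win[2L], ]
    bad <- d$od <= 0
    if (any(bad)) {
      warning(sprintf("dropping %d non-positive OD readings", sum(bad)))
      d <- d[!bad, , drop = FALSE]
    }
    d
  }
  fit_in <- function(d) {
    fit <- lm(log(d$od) ~ d$time_min)
    s <- summary(fit)
    list(k = unname(coef(fit)[2L]), se = s$coefficients[2L, 2L],
         r_squared = s$r.squared, n = nrow(d))
  }
  if (identical(fit_window, "auto")) {
    starts <- curve$time_min[curve$time_min + auto_width <=
                               max(curve$time_min)]
    best <- NULL; best_win <- NULL
    for (s0 in starts) {
      d <- pick(c(s0, s0 + auto_width))
      if (nrow(d) < 3L) next
      f <- suppressWarnings(fit_in(d))
      if (is.null(best) || f$r_squared > best$r_squared) {
        best <- f; best_win <- c(s0, s0 + auto_width)
      }
    }
    if (is.null(best)) stop("no window with 3 positive OD points")
    return(c(best, list(window = best_win)))
  }
  if (is.null(fit_window))
    fit_window <- range(curve$time_min)
  d <- pick(fit_window)
  if (nrow(d) < 3L) stop("need at least 3 points with positive OD")
  c(fit_in(d), list(window = fit_window))
}

#' Compare growth rates between two groups of replicates
#'
#' Two-tailed Student t-test (equal variance by default; set
#' `var_equal = FALSE` for Welch).  Degenerate input (zero variance in
#' both groups) yields `p_value = NaN` with a reason instead of an error.
#'
#' @param rates_a,rates_b Numeric vectors of per-replicate rate constants
#'   (each of length >= 2).
#' @param var_equal Pool the variance (default `TRUE`).
#' @return List with `statistic`, `p_value`, `mean_a`, `mean_b`, `reason`.
#' @export
compare_rates <- function(rates_a, rates_b, var_equal = TRUE) {
  if (length(rates_a) < 2L || length(rates_b) < 2L)
    stop("each group needs at least 2 replicates")
  res <- tryCatch(
    t.test(rates_a, rates_b, var.equal = var_equal),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$statistic)) {
    return(list(statistic = NaN, p_value = NaN,
                mean_a = mean(rates_a), mean_b = mean(rates_b),
                reason = "degenerate variance"))
  }
  list(statistic = unname(res$statistic), p_value = res$p.value,
       mean_a = mean(rates_a), mean_b = mean(rates_b),
       reason = NA_character_)
}

#' Reference-normalized delta-delta-Ct
#'
#' Per condition, dCt = Ct(reference) - Ct(target) (so larger dCt means
#' more target — note this is the reverse of the more common
#' target-minus-reference convention); ddCt = dCt(stress) - dCt(normal);
#' fold change = 2^ddCt.  Negative ddCt therefore means the target
#' decreased under stress.
#'
#' @param table data.frame with columns `target_id`, `condition`, `ct`
#'   (replicate rows are averaged).
#' @param target,reference Target and normalizer ids.
#' @param cond_stress,cond_normal Condition labels (defaults `"oxidative"`
#'   and `"normal"`).
#' @return List with `ddct`, `fold_change`, `dct_stress`, `dct_normal`.
#' @export
ddct <- function(table, target, reference, cond_stress = "oxidative",
                 cond_normal = "normal") {
  stopifnot(all(c("target_id", "condition", "ct") %in% names(table)))
  if (any(table$ct <= 0)) stop("CT values must be positive")
  cell <- function(id, cond) {
    v <- table$ct[table$target_id == id & table$condition == cond]
    if (!length(v))
      stop(sprintf("missing CT for target '%s' in condition '%s'", id, cond))
    mean(v)
  }
  dct_s <- cell(reference, cond_stress) - cell(target, cond_stress)
  dct_n <- cell(reference, cond_normal) - cell(target, cond_normal)
  dd <- dct_s - dct_n
  list(ddct = dd, fold_change = 2^dd, dct_stress = dct_s, dct_normal = dct_n)
}

#' Read a growth-curve TSV
#'
#' @param path TSV with columns `time_min`, `od` and optionally
#'   `replicate`.
#' @return data.frame.
#' @export
read_growth_tsv <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_min", "od") %in% names(x)))
  x
}

#' Read a CT table TSV
#'
#' @param path TSV with columns `target_id`, `condition`, `ct`.
#' @return data.frame usable with [ddct()].
#' @export
read_ct_tsv <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("target_id", "condition", "ct") %in% names(x)))
  x
}
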