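# First-order decay fitting for protein (cycloheximide chase) and mRNA
# (actinomycin-D chase) stability, plus the relative-expression arithmetic
# that feeds it. The kinetic model is A(t) = A0 * exp(-k t): ordinary least
# squares of ln(abundance) on time, k = -slope, half-life = ln(2)/k.

#' Fit a first-order decay curve
#'
#' Pools all supplied observations (replicates included) into one ordinary
#' least-squares regression of `ln(abundance)` on `time`. A non-negative
#' slope is reported as a stable species (`half_life = Inf`). The
#' half-life confidence interval comes from residual-resampling bootstrap.
#'
#' @param times Time points in hours (replicated observations allowed; at
#'   least 3 observations over at least 2 distinct times).
#' @param abundance Positive normalized abundances (e.g. densitometry
#'   ratios rescaled to 1 at t = 0).
#' @param n_boot Bootstrap replicates for the half-life CI (default 1000;
#'   0 skips the CI).
#' @param seed Optional seed for the bootstrap.
#' @param level CI level (default 0.95).
#' @return An object of class `decay_fit` with components `rate` (per
#'   hour), `half_life` (hours), `intercept` (ln abundance at t = 0),
#'   `r_squared`, `ci_half_life`, `n_points`, `stable`, and the underlying
#'   `lm` fit. Supports `print`, `summary`, `coef`, `predict`, `plot`,
#'   `residuals`, `simulate` and `confint`.
#' @export
#' @examples
#' fit <- fit_decay(c(0, 2, 4), c(1, 0.5, 0.25), n_boot = 0)
#' fit$half_life  # exactly 2 hours
fit_decay <- function(times, abundance, n_boot = 1000L, seed = NULL,
                      level = 0.95) {
  if (length(times) != length(abundance)) {
    stop("'times' and 'abundance' must have equal length", call. = FALSE)
  }
  if (length(times) < 3L) stop("need >= 3 data points", call. = FALSE)
  if (length(unique(times)) < 2L) {
    stop("need >= 2 distinct time points", call. = FALSE)
  }
  if (any(!is.finite(abundance)) || any(abundance <= 0)) {
    stop("abundance values must be positive and finite", call. = FALSE)
  }
  y <- log(abundance)
  fit <- stats::lm(y ~ times)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  k <- -slope
  stable <- k <= 0
  half_life <- if (stable) Inf else log(2) / k
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  r_squared <- if (ss_tot == 0) {
    if (ss_res < 1e-12) 1 else 0
  } else {
    max(0, min(1, 1 - ss_res / ss_tot))
  }
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    res <- stats::residuals(fit)
    fitted_y <- stats::fitted(fit)
    hl_boot <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      yb <- fitted_y + sample(res, length(res), replace = TRUE)
      cb <- stats::coef(stats::lm.fit(cbind(1, times), yb))
      kb <- -cb[2L]
      if (kb <= 0) Inf else log(2) / kb
    }, numeric(1)))
    alpha <- (1 - level) / 2
    ci <- unname(stats::quantile(hl_boot, c(alpha, 1 - alpha),
                                 names = FALSE, type = 7))
  }
  structure(list(rate = k, half_life = half_life, intercept = intercept,
                 r_squared = r_squared, ci_half_life = ci,
                 ci_level = level, n_points = length(times),
                 stable = stable, lm = fit, times = times,
                 abundance = abundance),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$stable) {
    cat("First-order decay fit: no decay detected (stable; half-life = Inf)\n")
  } else {
    cat(sprintf("First-order decay fit: half-life %.3g h (k = %.3g /h)\n",
                x$half_life, x$rate))
  }
  if (!anyNA(x$ci_half_life)) {
    cat(sprintf("  %d%% bootstrap CI [%.3g, %.3g] h\n",
                round(100 * x$ci_level), x$ci_half_life[1],
                x$ci_half_life[2]))
  }
  cat(sprintf("  R^2 = %.3f over %d points\n", x$r_squared, x$n_points))
  invisible(x)
}

#' @method summary decay_fit
#' @export
summary.decay_fit <- function(object, ...) {
  structure(list(fit = object, lm_summary = summary(object$lm)),
            class = "summary.decay_fit")
}

#' @method print summary.decay_fit
#' @export
print.summary.decay_fit <- function(x, ...) {
  print(x$fit)
  cat("\nUnderlying log-linear regression:\n")
  stats::printCoefmat(x$lm_summary$coefficients)
  invisible(x)
}

#' @method coef decay_fit
#' @export
coef.decay_fit <- function(object, ...) {
  c(rate = object$rate, log_intercept = object$intercept,
    half_life = object$half_life)
}

#' @export
predict.decay_fit <- function(object, times = NULL, ...) {
  times <- times %||% object$times
  exp(object$intercept - object$rate * times)
}

#' @method residuals decay_fit
#' @export
residuals.decay_fit <- function(object, ...) stats::residuals(object$lm)

#' @method confint decay_fit
#' @export
confint.decay_fit <- function(object, parm = "half_life", level = NULL,
                              ...) {
  object$ci_half_life
}

#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sigma <- summary(object$lm)$sigma
  if (!is.finite(sigma)) sigma <- 0
  mu <- predict(object)
  with_seed(seed, {
    out <- as.data.frame(replicate(nsim, mu *
      exp(stats::rnorm(length(mu), 0, sigma))))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' @method plot decay_fit
#' @export
plot.decay_fit <- function(x, ...) {
  graphics::plot(x$times, x$abundance, log = "y", xlab = "time (h)",
                 ylab = "relative abundance",
                 main = if (x$stable) "decay fit (stable)" else
                   sprintf("decay fit: t1/2 = %.2g h", x$half_life), ...)
  tt <- seq(min(x$times), max(x$times), length.out = 100)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' Densitometry ratio of a target band to its loading control
#'
#' @param target_signal,loading_signal Band signal intensities;
#'   `loading_signal` must be positive.
#' @param rescale_t0 If `TRUE`, divide the ratios by the first element so
#'   the series starts at 1 (for decay-fit input).
#' @return Numeric vector of normalized abundances.
#' @export
#' @examples
#' densitometry_ratio(c(100, 50), c(100, 100))           # 1.0 0.5
#' densitometry_ratio(c(2, 1, 0.5), rep(1, 3), TRUE)     # 1.0 0.5 0.25
densitometry_ratio <- function(target_signal, loading_signal,
                               rescale_t0 = FALSE) {
  if (length(target_signal) != length(loading_signal)) {
    stop("signal vectors must have equal length", call. = FALSE)
  }
  if (any(!is.finite(loading_signal)) || any(loading_signal <= 0)) {
    stop("loading signal must be positive", call. = FALSE)
  }
  ratio <- target_signal / loading_signal
  if (rescale_t0) ratio <- ratio / ratio[1L]
  ratio
}

#' Relative expression from Ct values (delta-Ct)
#'
#' Fold expression of a target relative to a reference gene:
#' `efficiency^(Ct_reference - Ct_target)`. The delta-delta-Ct comparison
#' between two conditions is the ratio of two such folds, see
#' [ddct_ratio()].
#'
#' @param ct_target,ct_reference Ct values (finite).
#' @param efficiency Amplification efficiency per cycle (default 2).
#' @return Fold expression.
#' @export
#' @examples
#' relative_expression(23, 25)            # 4: target 2 cycles earlier
#' relative_expression(23, 25, 1.9)       # 1.9^2 = 3.61
relative_expression <- function(ct_target, ct_reference, efficiency = 2) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  efficiency^(ct_reference - ct_target)
}

#' Delta-delta-Ct fold ratio between two conditions
#'
#' @param ct_target_a,ct_reference_a Cts in condition A.
#' @param ct_target_b,ct_reference_b Cts in condition B.
#' @inheritParams relative_expression
#' @return Fold change of condition A relative to condition B.
#' @export
ddct_ratio <- function(ct_target_a, ct_reference_a, ct_target_b,
                       ct_reference_b, efficiency = 2) {
  relative_expression(ct_target_a, ct_reference_a, efficiency) /
    relative_expression(ct_target_b, ct_reference_b, efficiency)
}

#' Read a decay time-course table from TSV
#'
#' Accepts either a pre-normalized `abundance` column or raw
#' `target_signal` + `loading_signal` columns (converted with
#' [densitometry_ratio()] per replicate and rescaled to the mean t = 0
#' value). A `time_min` column is converted to hours.
#'
#' @param path TSV with columns `time_h` (or `time_min`), `replicate`, and
#'   either `abundance` or `target_signal` + `loading_signal`.
#' @return Data frame with columns `time_h`, `replicate`, `abundance`.
#' @export
read_time_course <- function(path) {
  df <- read_tsv(path)
  if ("time_min" %in% names(df) && !"time_h" %in% names(df)) {
    df$time_h <- df$time_min / 60
    df$time_min <- NULL
  }
  if (!"time_h" %in% names(df)) {
    stop("time-course table needs a 'time_h' (or 'time_min') column",
         call. = FALSE)
  }
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  if (!"abundance" %in% names(df)) {
    need <- c("target_signal", "loading_signal")
    if (!all(need %in% names(df))) {
      stop("need 'abundance' or 'target_signal' + 'loading_signal' columns",
           call. = FALSE)
    }
    df <- do.call(rbind, lapply(split(df, df$replicate), function(d) {
      d <- d[order(d$time_h), ]
      d$abundance <- densitometry_ratio(d$target_signal, d$loading_signal,
                                        rescale_t0 = TRUE)
      d
    }))
    rownames(df) <- NULL
  }
  df[, c("time_h", "replicate", "abundance")]
}
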