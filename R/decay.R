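#' Fit a one-phase exponential decay
#'
#' Least-squares fit of first-order decay after transcription shutoff,
#' `N(t) = n0 * exp(-k * t)`, on the natural scale (set
#' `log_scale = TRUE` for log-scale least squares, which is robust to
#' multiplicative noise). The half-life is `log(2) / k`.
#'
#' @param series data frame with columns `time_min` and `value`
#'   (replicates are simply pooled), e.g. from [simulate_decay_series()].
#' @param log_scale fit `log(value)` instead of `value` (default FALSE).
#' @return list of class `decay_fit`: `model = "one_phase"`, `n0`, `k`
#'   (1/min), `t0 = 0`, `half_life_min`, `rss`, `aicc`, `n_obs`,
#'   `converged`, and `flagged` (`TRUE` when `k` collapsed to its lower
#'   bound, e.g. for a non-decaying series).
#' @export
fit_one_phase <- function(series, log_scale = FALSE) {
  .check_series(series, 3)
  t <- series$time_min; y <- series$value
  ## log-linear initialization
  k0 <- .init_k(t, y)
  st <- c(n0 = max(y), k = k0)
  fn <- if (log_scale)
    function(p) log(pmax(p[1] * exp(-p[2] * t), 1e-12)) - log(pmax(y, 1e-12))
  else function(p) p[1] * exp(-p[2] * t) - y
  fit <- minpack.lm::nls.lm(par = st, lower = c(1e-12, 1e-9),
                            upper = c(Inf, Inf), fn = fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-10))
  p <- coef(fit)
  rss <- sum((p[1] * exp(-p[2] * t) - y)^2)
  flagged <- p[2] <= 1e-8
  .decay_fit("one_phase", n0 = p[1], k = p[2], t0 = 0, rss = rss,
             n_obs = length(y), n_par = 2,
             converged = fit$info %in% 1:4, flagged = flagged)
}

#' Fit a plateau followed by one-phase decay
#'
#' Least-squares fit of
#' `N(t) = n0` for `t <= t0` and `N(t) = n0 * exp(-k * (t - t0))` after,
#' the model describing delayed-onset decay. The breakpoint
#' `t0` makes the objective non-smooth, so it is profiled over a grid
#' spanning the observed time range and then refined by golden-section
#' search; `n0` and `k` are fitted conditionally at each candidate.
#'
#' @inheritParams fit_one_phase
#' @param n_grid number of `t0` grid points (default 60).
#' @return a `decay_fit` with `model = "plateau_one_phase"` and the
#'   fitted `t0` (min). The fit is flagged when `t0` reaches the last
#'   observed timepoint (plateau unidentifiable).
#' @export
fit_plateau_one_phase <- function(series, log_scale = FALSE, n_grid = 60) {
  .check_series(series, 4)
  t <- series$time_min; y <- series$value
  t_max <- max(t)
  fit_at <- function(t0) {
    td <- pmax(t - t0, 0)
    k0 <- .init_k(td[td > 0] + 1e-9, y[td > 0])
    st <- c(n0 = max(y), k = max(k0, 1e-6))
    fn <- if (log_scale)
      function(p) log(pmax(p[1] * exp(-p[2] * td), 1e-12)) -
        log(pmax(y, 1e-12))
    else function(p) p[1] * exp(-p[2] * td) - y
    f <- minpack.lm::nls.lm(par = st, lower = c(1e-12, 1e-9),
                            upper = c(Inf, Inf), fn = fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-10))
    p <- coef(f)
    list(par = p, rss = sum((p[1] * exp(-p[2] * td) - y)^2),
         converged = f$info %in% 1:4)
  }
  grid <- seq(0, max(t[t < t_max]), length.out = n_grid)
  rss_grid <- vapply(grid, function(g) fit_at(g)$rss, 0)
  ib <- which.min(rss_grid)
  lo <- grid[max(1, ib - 1)]; hi <- grid[min(length(grid), ib + 1)]
  t0 <- if (hi > lo)
    optimize(function(g) fit_at(g)$rss, c(lo, hi))$minimum else grid[ib]
  best <- fit_at(t0)
  flagged <- best$par[2] <= 1e-8 || t0 >= max(t[t < t_max]) - 1e-9
  .decay_fit("plateau_one_phase", n0 = best$par[1], k = best$par[2],
             t0 = t0, rss = best$rss, n_obs = length(y), n_par = 3,
             converged = best$converged, flagged = flagged)
}

.check_series <- function(series, min_pts) {
  stopifnot(all(c("time_min", "value") %in% names(series)))
  if (any(series$time_min < 0)) stop("timepoints must be non-negative")
  if (length(unique(series$time_min)) < min_pts)
    stop("at least ", min_pts, " distinct timepoints are required")
  if (any(series$value <= 0)) stop("abundances must be > 0")
}

.init_k <- function(t, y) {
  if (length(t) < 2 || sd(t) == 0) return(0.01)
  sl <- -coef(stats::lm(log(pmax(y, 1e-12)) ~ t))[2]
  max(as.numeric(sl), 1e-6)
}

.decay_fit <- function(model, n0, k, t0, rss, n_obs, n_par, converged,
                       flagged) {
  ## AICc with Gaussian errors; n_par + 1 counts the error variance
  p <- n_par + 1
  aicc <- n_obs * log(rss / n_obs) + 2 * p +
    if (n_obs - p - 1 > 0) 2 * p * (p + 1) / (n_obs - p - 1) else Inf
  structure(list(model = model, n0 = unname(n0), k = unname(k),
                 t0 = unname(t0), half_life_min = log(2) / unname(k),
                 rss = rss, aicc = aicc, n_obs = n_obs,
                 converged = converged, flagged = flagged),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "decay_fit [%s]: n0 %.3g, k %.4g /min, t0 %.1f min, half-life %.1f min (AICc %.1f%s)\n",
    x$model, x$n0, x$k, x$t0, x$half_life_min, x$aicc,
    if (x$flagged) ", FLAGGED" else ""))
  invisible(x)
}

#' Select between decay models by AICc
#'
#' Compares two fits of the same series by the small-sample-corrected
#' Akaike criterion; the lower AICc wins and ties (within `tie_margin`)
#' go to the model with fewer parameters.
#'
#' @param fit1,fit2 `decay_fit` objects for the same data.
#' @param tie_margin AICc difference treated as a tie (default 1e-6).
#' @return the winning `decay_fit`, with attributes `aicc_margin` (AICc
#'   of the loser minus the winner) and `selected` (model name).
#' @export
select_model <- function(fit1, fit2, tie_margin = 1e-6) {
  stopifnot(inherits(fit1, "decay_fit"), inherits(fit2, "decay_fit"))
  if (fit1$n_obs != fit2$n_obs)
    stop("fits must be on the same data")
  d <- fit2$aicc - fit1$aicc
  npar <- function(f) if (f$model == "one_phase") 2 else 3
  win <- if (abs(d) <= tie_margin) {
    if (npar(fit1) <= npar(fit2)) fit1 else fit2
  } else if (d > 0) fit1 else fit2
  attr(win, "aicc_margin") <- abs(d)
  attr(win, "selected") <- win$model
  win
}
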