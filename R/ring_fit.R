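#' Detect ring-shaped particles by circle Hough transform
#'
#' Votes intensity-weighted circle centers over a range of radii, one
#' accumulator per radius, normalized by circumference so radii compete
#' fairly. Candidates are accumulator peaks above a sensitivity-mapped
#' threshold, `(1 - sensitivity) * max(accumulator)` -- higher sensitivity
#' admits weaker rings, matching the convention of common Hough
#' implementations. Peaks are non-maximum-suppressed: within one center
#' neighborhood only radii separated by more than `radius_merge_nm`
#' survive, so concentric rings of clearly distinct radii are both
#' reported.
#'
#' @param img an [sr_image].
#' @param sensitivity in `(0, 1]`, default 0.85.
#' @param radius_range numeric length-2 `(min, max)` radius in nm.
#' @param n_theta angular samples per vote (default 72).
#' @param min_separation_nm minimum center distance between detections
#'   (default: the larger radius bound).
#' @param radius_merge_nm radii closer than this at one center are merged
#'   (default 60 nm).
#' @param min_coverage minimum fraction of angular sectors around a
#'   candidate that contain signal at its radius (default 0.6); rejects
#'   partial-arc artifacts so only mostly closed rings are reported.
#' @param vote_threshold pixels with intensity above this fraction of the
#'   image maximum cast votes (default 0.1).
#' @return data frame `x_nm, y_nm, radius_nm, score`, strongest first.
#' @export
detect_rings <- function(img, sensitivity = 0.85, radius_range,
                         n_theta = 72, min_separation_nm = NULL,
                         radius_merge_nm = 60, min_coverage = 0.6,
                         vote_threshold = 0.1) {
  stopifnot(inherits(img, "sr_image"))
  if (sensitivity <= 0 || sensitivity > 1)
    stop("sensitivity must be in (0, 1]")
  if (radius_range[1] <= 0 || radius_range[1] >= radius_range[2])
    stop("radius_range must be positive and ordered")
  px <- img$pixel_size
  m <- img$data
  m[is.na(m)] <- 0
  nx <- nrow(m); ny <- ncol(m)
  empty <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      radius_nm = numeric(0), score = numeric(0))
  if (max(m) <= 0) return(empty)
  if (is.null(min_separation_nm)) min_separation_nm <- radius_range[2]
  ## voting pixels: a low fraction-of-maximum floor keeps dim but genuine
  ## rings voting while excluding near-empty background
  sel <- which(m > vote_threshold * max(m))
  if (!length(sel)) return(empty)
  sx <- (sel - 1) %% nx; sy <- (sel - 1) %/% nx       # 0-based pixel idx
  w <- m[sel]
  radii_px <- seq(max(1, floor(radius_range[1] / px)),
                  ceiling(radius_range[2] / px), by = 1)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  accs <- vector("list", length(radii_px))
  for (k in seq_along(radii_px)) {
    r <- radii_px[k]
    cx <- round(rep(sx, times = n_theta) -
                  rep(r * cos(theta), each = length(sx)))
    cy <- round(rep(sy, times = n_theta) -
                  rep(r * sin(theta), each = length(sx)))
    ok <- cx >= 0 & cx < nx & cy >= 0 & cy < ny
    idx <- cx[ok] + nx * cy[ok] + 1
    acc <- numeric(nx * ny)
    sums <- rowsum(rep(w, times = n_theta)[ok], idx)
    acc[as.integer(rownames(sums))] <- sums
    acc <- matrix(acc, nx, ny) / r
    accs[[k]] <- blur_matrix(acc, 1)
  }
  global_max <- max(vapply(accs, max, 0))
  thr_acc <- (1 - sensitivity) * global_max
  ## collect local maxima above threshold
  cand <- NULL
  for (k in seq_along(radii_px)) {
    a <- accs[[k]]
    mx <- EBImage::filter2(a, matrix(1 / 9, 3, 3), boundary = "replicate")
    is_pk <- a >= thr_acc & a >= mx &
      a == .local_max3(a)
    if (any(is_pk)) {
      ij <- which(is_pk, arr.ind = TRUE)
      cand <- rbind(cand, data.frame(
        ix = ij[, 1], iy = ij[, 2], r_px = radii_px[k],
        score = a[is_pk]))
    }
  }
  if (is.null(cand) || !nrow(cand)) return(empty)
  ## angular-coverage verification: a genuine ring is supported by signal
  ## all the way around its circumference
  sectors <- 24L
  coverage <- vapply(seq_len(nrow(cand)), function(i) {
    dx <- sx - (cand$ix[i] - 1); dy <- sy - (cand$iy[i] - 1)
    dd <- sqrt(dx^2 + dy^2)
    on_ring <- dd >= 0.7 * cand$r_px[i] & dd <= 1.3 * cand$r_px[i]
    if (!any(on_ring)) return(0)
    ang <- atan2(dy[on_ring], dx[on_ring])
    length(unique(floor((ang + pi) / (2 * pi) * sectors))) / sectors
  }, 0)
  cand <- cand[coverage >= min_coverage, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand <- cand[order(-cand$score), , drop = FALSE]
  concentric_tol_px <- 3
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (any(keep)) {
      kd <- cand[keep, , drop = FALSE]
      cdist <- sqrt((kd$ix - cand$ix[i])^2 + (kd$iy - cand$iy[i])^2)
      same_center <- cdist <= concentric_tol_px
      close_xy <- cdist * px < min_separation_nm
      close_r <- abs(kd$r_px - cand$r_px[i]) * px < radius_merge_nm
      if (any(same_center & close_r)) next
      if (any(same_center & !close_r)) {
        keep[i] <- TRUE            # concentric ring at a distinct radius
        next
      }
      if (any(close_xy)) next
    }
    keep[i] <- TRUE
  }
  out <- cand[keep, , drop = FALSE]
  data.frame(x_nm = (out$ix - 0.5) * px, y_nm = (out$iy - 0.5) * px,
             radius_nm = out$r_px * px, score = out$score)
}

## 3x3 neighborhood maximum (replicate boundary)
.local_max3 <- function(a) {
  nx <- nrow(a); ny <- ncol(a)
  out <- a
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    shifted <- a[pmin(pmax(seq_len(nx) + dx, 1), nx),
                 pmin(pmax(seq_len(ny) + dy, 1), ny)]
    out <- pmax(out, shifted)
  }
  out
}

#' Match 5' and 3' channel detections into particle pairs
#'
#' Pairs detections across channels by mutual nearest neighbors subject
#' to a maximum center distance. Each 5' detection is paired with its
#' nearest 3' detection only if that 3' detection's nearest 5' detection
#' is the same one.
#'
#' @param detections_5,detections_3 data frames from [detect_rings()].
#' @param max_dist maximum pairing distance in nm, `> 0` (default 300).
#' @return list: `pairs` (data frame with indices `i5, i3`, the paired
#'   coordinates and center distance) and `unmatched_5`, `unmatched_3`
#'   (integer indices).
#' @export
match_channels <- function(detections_5, detections_3, max_dist = 300) {
  if (max_dist <= 0) stop("max_dist must be > 0")
  n5 <- nrow(detections_5); n3 <- nrow(detections_3)
  if (n5 == 0 || n3 == 0)
    return(list(pairs = data.frame(i5 = integer(0), i3 = integer(0),
                                   x5_nm = numeric(0), y5_nm = numeric(0),
                                   x3_nm = numeric(0), y3_nm = numeric(0),
                                   dist_nm = numeric(0)),
                unmatched_5 = seq_len(n5), unmatched_3 = seq_len(n3)))
  d <- outer(detections_5$x_nm, detections_3$x_nm, "-")^2 +
    outer(detections_5$y_nm, detections_3$y_nm, "-")^2
  nn5 <- apply(d, 1, which.min)           # nearest 3' for each 5'
  nn3 <- apply(d, 2, which.min)           # nearest 5' for each 3'
  i5 <- which(nn3[nn5] == seq_len(n5) &
                d[cbind(seq_len(n5), nn5)] <= max_dist^2)
  pairs <- data.frame(i5 = i5, i3 = nn5[i5],
                      x5_nm = detections_5$x_nm[i5],
                      y5_nm = detections_5$y_nm[i5],
                      x3_nm = detections_3$x_nm[nn5[i5]],
                      y3_nm = detections_3$y_nm[nn5[i5]],
                      dist_nm = sqrt(d[cbind(i5, nn5[i5])]))
  list(pairs = pairs,
       unmatched_5 = setdiff(seq_len(n5), pairs$i5),
       unmatched_3 = setdiff(seq_len(n3), pairs$i3))
}

#' Ring-model intensity function
#'
#' The two-Gaussian ring model fitted to segmented ring-shaped signals:
#' an offset `C1`, a broad positive Gaussian (amplitude `C2`, widths
#' `u1`, `v1`) and a second Gaussian (amplitude `C3`, typically negative)
#' that carves out the ring's central dip. The default `"printed"`
#' variant reproduces the published form of the model, whose third term
#' contains the y offset twice:
#' \deqn{C_1 + C_2 e^{-\left(((x-a)/u_1)^2 + ((y-b)/v_1)^2\right)}
#'   + C_3 e^{-\left(((x-a)/u_2)^2 + ((y-b)/u_2)^2 +
#'     ((y-b)/(v_1 u_2/u_1))^2\right)}}
#' The `"symmetric"` variant is the plausible intended form in which the
#' second Gaussian scales x by `u2` and y by `v1*u2/u1`.
#'
#' @param x,y coordinates in nm (vectors of equal length).
#' @param par named numeric vector `C1, C2, C3, a, b, u1, v1, u2`.
#' @param variant `"printed"` (default) or `"symmetric"`.
#' @return intensity values.
#' @export
ring_model <- function(x, y, par, variant = c("printed", "symmetric")) {
  variant <- match.arg(variant)
  dx <- x - par[["a"]]; dy <- y - par[["b"]]
  g1 <- exp(-((dx / par[["u1"]])^2 + (dy / par[["v1"]])^2))
  w2y <- par[["v1"]] * par[["u2"]] / par[["u1"]]
  g2 <- if (variant == "printed")
    exp(-((dx / par[["u2"]])^2 + (dy / par[["u2"]])^2 + (dy / w2y)^2))
  else
    exp(-((dx / par[["u2"]])^2 + (dy / w2y)^2))
  par[["C1"]] + par[["C2"]] * g1 + par[["C3"]] * g2
}

#' Fit the ring model to an image patch
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of [ring_model()]
#' against a patch around a detected candidate. Optimization runs from
#' two starting shapes (broad-positive/narrow-negative and the reverse
#' width ordering) and keeps the lower-residual solution; convergence
#' requires a relative cost change below `1e-8` within `maxit`
#' iterations. Constraints: `C2 >= 0`, all widths `> 0`.
#'
#' @param img an [sr_image] (a full frame or an already cut patch).
#' @param center numeric `(x, y)` nm, candidate center (e.g. from
#'   [detect_rings()]).
#' @param radius candidate radius in nm.
#' @param half_size patch half-width in nm (default `2.5 * radius`).
#' @param variant model variant, see [ring_model()].
#' @param maxit maximum iterations (default 500).
#' @return list of class `ring_fit`: `par` (named vector), `converged`,
#'   `rss`, `variant`, `radius_nm` (center-to-outer-FWHM radius, `NA` if
#'   undefined), `radius_defined`, `flat` (`TRUE` when the fit degenerates
#'   to a non-ring, i.e. no positive structure).
#' @export
fit_ring <- function(img, center, radius, half_size = NULL,
                     variant = c("printed", "symmetric"), maxit = 500) {
  stopifnot(inherits(img, "sr_image"))
  variant <- match.arg(variant)
  px <- img$pixel_size
  if (is.null(half_size)) half_size <- 2.5 * radius
  i0 <- max(1, floor((center[1] - half_size) / px) + 1)
  i1 <- min(nrow(img$data), ceiling((center[1] + half_size) / px))
  j0 <- max(1, floor((center[2] - half_size) / px) + 1)
  j1 <- min(ncol(img$data), ceiling((center[2] + half_size) / px))
  patch <- img$data[i0:i1, j0:j1, drop = FALSE]
  xs <- ((i0:i1) - 0.5) * px
  ys <- ((j0:j1) - 0.5) * px
  xg <- rep(xs, times = length(ys))
  yg <- rep(ys, each = length(xs))
  z <- as.numeric(patch)
  ok <- is.finite(z)
  xg <- xg[ok]; yg <- yg[ok]; z <- z[ok]
  if (length(z) < 10)
    stop("patch too small for a ring fit")
  amp <- max(z) - min(z)
  base <- min(z)
  mk_start <- function(wide, narrow)
    c(C1 = base, C2 = amp, C3 = -0.8 * amp, a = center[1], b = center[2],
      u1 = wide, v1 = wide, u2 = narrow)
  starts <- list(mk_start(radius, radius / 2),      # hole narrower than ring
                 mk_start(radius / 2, radius))      # alternative ordering
  lower <- c(C1 = 0, C2 = 0, C3 = -Inf, a = center[1] - 2 * radius,
             b = center[2] - 2 * radius, u1 = px / 2, v1 = px / 2,
             u2 = px / 2)
  upper <- c(C1 = Inf, C2 = Inf, C3 = Inf, a = center[1] + 2 * radius,
             b = center[2] + 2 * radius, u1 = 10 * radius, v1 = 10 * radius,
             u2 = 10 * radius)
  resid_fun <- function(p) {
    names(p) <- names(starts[[1]])
    ring_model(xg, yg, p, variant) - z
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxit, ftol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(structure(list(par = NULL, converged = FALSE, rss = NA_real_,
                          variant = variant, radius_nm = NA_real_,
                          radius_defined = FALSE, flat = TRUE),
                     class = "ring_fit"))
  par <- coef(best$fit)
  names(par) <- names(starts[[1]])
  converged <- best$fit$info %in% 1:4
  out <- structure(list(par = par, converged = converged, rss = best$rss,
                        variant = variant, radius_nm = NA_real_,
                        radius_defined = FALSE, flat = FALSE),
                   class = "ring_fit")
  ## degenerate / non-ring detection: no positive structure above offset
  prof_max <- .ring_profile_max(out)
  if (!is.finite(prof_max) || prof_max <= 1e-6 * max(1, abs(par[["C1"]]))) {
    out$flat <- TRUE
    return(out)
  }
  rr <- ring_radius(out)
  out$radius_nm <- rr
  out$radius_defined <- is.finite(rr)
  out
}

#' @export
print.ring_fit <- function(x, ...) {
  if (is.null(x$par)) {
    cat("ring_fit: failed\n"); return(invisible(x))
  }
  cat(sprintf(
    "ring_fit (%s): center (%.1f, %.1f) nm, radius %s nm, %s, rss %.3g\n",
    x$variant, x$par[["a"]], x$par[["b"]],
    if (x$radius_defined) sprintf("%.1f", x$radius_nm) else "undefined",
    if (x$converged) "converged" else "NOT converged", x$rss))
  invisible(x)
}

## angularly averaged, offset-subtracted model profile f(r)
.ring_profile_fun <- function(fit, n_angle = 90) {
  par <- fit$par
  theta <- seq(0, 2 * pi, length.out = n_angle + 1)[-(n_angle + 1)]
  function(r) {
    vapply(r, function(ri) {
      mean(ring_model(par[["a"]] + ri * cos(theta),
                      par[["b"]] + ri * sin(theta), par, fit$variant)) -
        par[["C1"]]
    }, 0)
  }
}

.ring_profile_max <- function(fit, r_max = NULL) {
  if (is.null(fit$par)) return(NA_real_)
  if (is.null(r_max)) r_max <- 4 * max(fit$par[c("u1", "v1", "u2")])
  f <- .ring_profile_fun(fit)
  max(f(seq(0, r_max, length.out = 200)))
}

#' Outer half-maximum radius of a radial profile
#'
#' Finds the outermost distance at which a radial profile function falls
#' to half of its maximum, by dense evaluation and linear interpolation
#' of the last downward half-maximum crossing. For a Gaussian ridge
#' centered at radius `r0` with radial standard deviation `s`, this is
#' `r0 + sqrt(2 * log(2)) * s`.
#'
#' @param profile_fun vectorized function of radius (nm), already
#'   background-subtracted.
#' @param r_max outermost radius searched (nm).
#' @param n grid resolution (default 2000).
#' @return radius in nm, or `NA` if the profile has no positive maximum
#'   or never falls to half of it within `r_max`.
#' @export
outer_fwhm_radius <- function(profile_fun, r_max, n = 2000) {
  r <- seq(0, r_max, length.out = n)
  y <- profile_fun(r)
  ymax <- max(y)
  if (!is.finite(ymax) || ymax <= 0) return(NA_real_)
  half <- ymax / 2
  below <- which(y < half)
  ipk <- which.max(y)
  below <- below[below > ipk]
  if (!length(below)) return(NA_real_)
  i2 <- below[1]; i1 <- i2 - 1
  r[i1] + (half - y[i1]) * (r[i2] - r[i1]) / (y[i2] - y[i1])
}

#' Radius of a fitted ring
#'
#' The particle radius is the distance from the fitted center to the
#' outer half-maximum of the background-subtracted, angularly averaged
#' radial profile of the fitted model, found numerically on the model
#' function.
#'
#' @param fit a `ring_fit` from [fit_ring()].
#' @param r_max outermost radius searched (default
#'   `4 * max(u1, v1, u2)`).
#' @return radius in nm, or `NA` when undefined (no ring structure, e.g.
#'   `C2 = 0` with no positive profile).
#' @export
ring_radius <- function(fit, r_max = NULL) {
  stopifnot(inherits(fit, "ring_fit"))
  if (is.null(fit$par)) return(NA_real_)
  if (is.null(r_max)) r_max <- 4 * max(fit$par[c("u1", "v1", "u2")])
  outer_fwhm_radius(.ring_profile_fun(fit), r_max)
}

#' Classify a particle as small or large by its 5' radius
#'
#' Applies the fixed cutoff on the fitted 5' ring radius: radius strictly
#' below `cutoff` is `"small"`, at or above is `"large"`.
#'
#' @param fit a converged `ring_fit` of the 5' channel, or a numeric
#'   radius in nm.
#' @param cutoff nm (default 280).
#' @return `"small"` or `"large"`.
#' @export
classify_particle <- function(fit, cutoff = 280) {
  r <- if (inherits(fit, "ring_fit")) fit$radius_nm else fit
  ifelse(r < cutoff, "small", "large")
}

#' 5'/3' radius ratio of a particle pair
#'
#' Ratio of the fitted 5' shell radius to the 3' shell radius; a ratio
#' below 1 indicates 5' ends internalized relative to the 3' shell.
#'
#' @param fit_5,fit_3 `ring_fit` objects (or numeric radii in nm).
#' @return the ratio, or `NA` when either fit is unconverged/undefined or
#'   the 3' radius is zero.
#' @export
five_three_ratio <- function(fit_5, fit_3) {
  r5 <- if (inherits(fit_5, "ring_fit")) {
    if (!fit_5$converged || !fit_5$radius_defined) return(NA_real_)
    fit_5$radius_nm
  } else fit_5
  r3 <- if (inherits(fit_3, "ring_fit")) {
    if (!fit_3$converged || !fit_3$radius_defined) return(NA_real_)
    fit_3$radius_nm
  } else fit_3
  if (!is.finite(r3) || r3 == 0) return(NA_real_)
  r5 / r3
}
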