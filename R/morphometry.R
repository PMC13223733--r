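#' Segment a super-resolution image into labeled particles
#'
#' Smooths the image with a Gaussian blur (default 10 nm), thresholds it
#' to a binary mask, and labels connected components (8-connectivity).
#' The threshold defaults to Otsu's method computed on the blurred image;
#' pass a number to reproduce a manually chosen fixed threshold. The
#' threshold actually applied is recorded in the result so every
#' measurement is traceable.
#'
#' @param img an [sr_image].
#' @param blur_sigma Gaussian blur sigma in nm, `>= 0` (0 = no blur).
#' @param threshold `"auto"` (Otsu) or a numeric intensity; pixels with
#'   blurred intensity strictly above the threshold are foreground.
#' @return list of class `ps_segmentation`: `labels` (integer matrix,
#'   0 = background), `threshold` (value used), `pixel_size`.
#' @export
segment_image <- function(img, blur_sigma = 10, threshold = "auto") {
  stopifnot(inherits(img, "sr_image"))
  if (blur_sigma < 0) stop("blur_sigma must be >= 0")
  m <- img$data
  m[is.na(m)] <- 0
  b <- blur_matrix(m, blur_sigma / img$pixel_size)
  thr <- if (identical(threshold, "auto")) {
    mx <- max(b)
    if (mx <= 0) Inf else EBImage::otsu(b / mx, levels = 256) * mx
  } else as.numeric(threshold)
  mask <- (b > thr) * 1
  labels <- if (any(mask > 0)) label_components(mask) else
    matrix(0L, nrow(m), ncol(m))
  structure(list(labels = labels, threshold = thr,
                 pixel_size = img$pixel_size),
            class = "ps_segmentation")
}

#' @export
print.ps_segmentation <- function(x, ...) {
  cat(sprintf("ps_segmentation: %d objects, threshold %.4g, %.3g nm/px\n",
              max(x$labels), x$threshold, x$pixel_size))
  invisible(x)
}

#' Measure segmented particles
#'
#' Computes per-object morphometric descriptors from a labeled mask:
#' area (pixel count times pixel area, reported in um^2), centroid (nm),
#' the major axis of the second-moment (image-moment) fitted ellipse
#' (nm), roundness and the equivalent-disk radius.
#'
#' Roundness follows the particle-analyzer definition
#' \deqn{Round = 4 \cdot Area / (\pi \cdot major\_axis^2),}
#' which equals 1 for a circle and minor/major for an ellipse.
#' The equivalent radius is \eqn{\sqrt{Area/\pi}}, the radius of the disk
#' with the same area, and is the quantity the small/large size rule
#' operates on.
#'
#' @param seg a `ps_segmentation` from [segment_image()], or an integer
#'   label matrix (then `pixel_size` must be given).
#' @param pixel_size pixel size in nm (taken from `seg` if absent).
#' @return data frame with one row per particle: `label, area_um2,
#'   centroid_x_nm, centroid_y_nm, major_axis_nm, roundness,
#'   equiv_radius_nm`.
#' @export
measure_particles <- function(seg, pixel_size = NULL) {
  if (inherits(seg, "ps_segmentation")) {
    labels <- seg$labels
    pixel_size <- seg$pixel_size
  } else {
    labels <- seg
    if (is.null(pixel_size)) stop("pixel_size required for a bare matrix")
  }
  n <- max(labels)
  empty <- data.frame(label = integer(0), area_um2 = numeric(0),
                      centroid_x_nm = numeric(0), centroid_y_nm = numeric(0),
                      major_axis_nm = numeric(0), roundness = numeric(0),
                      equiv_radius_nm = numeric(0))
  if (n == 0) return(empty)
  px <- pixel_size
  mom <- EBImage::computeFeatures.moment(labels)
  if (is.null(dim(mom))) mom <- matrix(mom, nrow = 1,
                                       dimnames = list(NULL, names(mom)))
  areas_px <- tabulate(labels[labels > 0], nbins = n)
  area_um2 <- areas_px * (px / 1000)^2
  major_px <- mom[, "m.majoraxis"]
  roundness <- 4 * areas_px / (pi * major_px^2)
  data.frame(label = seq_len(n),
             area_um2 = area_um2,
             ## m.cx/m.cy are 1-based pixel-center coordinates
             centroid_x_nm = (mom[, "m.cx"] - 0.5) * px,
             centroid_y_nm = (mom[, "m.cy"] - 0.5) * px,
             major_axis_nm = major_px * px,
             roundness = roundness,
             equiv_radius_nm = sqrt(area_um2 / pi) * 1000)
}

#' Filter particles by size and roundness
#'
#' Keeps particles that pass both strict thresholds, the standard filter
#' for individual paraspeckle spheres: area strictly greater than
#' `min_area` um^2 and roundness strictly greater than `min_roundness`.
#'
#' @param records data frame from [measure_particles()].
#' @param min_area area threshold in um^2 (default 0.025).
#' @param min_roundness roundness threshold (default 0.8).
#' @return filtered data frame.
#' @export
filter_particles <- function(records, min_area = 0.025, min_roundness = 0.8) {
  if (min_area < 0 || min_roundness < 0) stop("thresholds must be >= 0")
  records[records$area_um2 > min_area & records$roundness > min_roundness, ,
          drop = FALSE]
}

#' Classify particles as small or large
#'
#' Applies the fixed size threshold on the equivalent-disk radius:
#' radius `<= cutoff_radius` is `"small"`, above is `"large"`. The
#' boundary value itself classifies as small.
#'
#' @param records data frame with an `equiv_radius_nm` column (or a bare
#'   numeric vector of radii in nm).
#' @param cutoff_radius nm (default 140).
#' @return character vector `"small"`/`"large"`, one per record.
#' @export
classify_size <- function(records, cutoff_radius = 140) {
  r <- if (is.data.frame(records)) records$equiv_radius_nm else records
  ifelse(r <= cutoff_radius, "small", "large")
}

#' Quantify paraspeckle clusters
#'
#' Objects larger than `min_area` um^2 are reported as clusters (fused
#' groups of individual spheres). Returns the cluster rows plus per-field
#' summary statistics, including a crude member estimate obtained by
#' dividing each cluster area by the area of a reference sphere.
#'
#' @param records data frame from [measure_particles()].
#' @param min_area cluster area threshold in um^2 (default 0.2).
#' @param sphere_radius_nm reference single-sphere radius for the member
#'   estimate (default 180 nm).
#' @return list: `clusters` (data frame with `members_est`), `n_clusters`,
#'   `mean_area_um2`.
#' @export
quantify_clusters <- function(records, min_area = 0.2,
                              sphere_radius_nm = 180) {
  cl <- records[records$area_um2 > min_area, , drop = FALSE]
  sphere_area <- pi * (sphere_radius_nm / 1000)^2
  cl$members_est <- if (nrow(cl)) pmax(1, round(cl$area_um2 / sphere_area))
    else numeric(0)
  list(clusters = cl, n_clusters = nrow(cl),
       mean_area_um2 = if (nrow(cl)) mean(cl$area_um2) else NA_real_)
}

#' Radial distribution of signal around a point
#'
#' Averages image intensity over concentric annuli around `center` and
#' normalizes the profile to its peak, describing how signal (e.g. the
#' NEAT1_2 5' end) is distributed with distance from a particle center.
#' The full width at half maximum (FWHM) is obtained by linear
#' interpolation of the half-maximum crossings flanking the peak; when
#' the peak sits at zero distance (a filled, center-peaked object) the
#' profile is treated as the positive half of a symmetric peak and the
#' FWHM is twice the outer crossing distance.
#'
#' @param img an [sr_image].
#' @param center numeric length-2 `(x, y)` in nm; must lie inside the
#'   image.
#' @param max_radius outermost annulus edge in nm.
#' @param bin_width annulus width in nm.
#' @return list of class `radial_distribution`: `distance_nm` (bin
#'   centers), `signal` (peak-normalized mean intensity per annulus),
#'   `fwhm_nm` (`NA` with `fwhm_defined = FALSE` when no half-maximum
#'   crossing exists, e.g. a uniform image).
#' @export
radial_signal_distribution <- function(img, center, max_radius,
                                       bin_width = 10) {
  stopifnot(inherits(img, "sr_image"))
  px <- img$pixel_size
  ext <- dim(img$data) * px
  if (center[1] < 0 || center[1] >= ext[1] ||
      center[2] < 0 || center[2] >= ext[2])
    stop("center lies outside the image")
  prof <- .annulus_means(img$data, px, center, max_radius, bin_width)
  sig <- prof$mean_intensity
  if (all(!is.finite(sig)) || max(sig, na.rm = TRUE) <= 0)
    return(structure(list(distance_nm = prof$distance_nm,
                          signal = rep(NA_real_, length(sig)),
                          fwhm_nm = NA_real_, fwhm_defined = FALSE),
                     class = "radial_distribution"))
  sig <- sig / max(sig, na.rm = TRUE)
  fw <- .profile_fwhm(prof$distance_nm, sig)
  structure(list(distance_nm = prof$distance_nm, signal = sig,
                 fwhm_nm = fw$fwhm, fwhm_defined = fw$defined),
            class = "radial_distribution")
}

## mean intensity per annulus; distances measured from pixel centers
.annulus_means <- function(m, px, center, max_radius, bin_width) {
  nx <- nrow(m); ny <- ncol(m)
  xc <- (seq_len(nx) - 0.5) * px
  yc <- (seq_len(ny) - 0.5) * px
  d <- sqrt(outer((xc - center[1])^2, (yc - center[2])^2, "+"))
  bins <- seq(0, max_radius, by = bin_width)
  idx <- findInterval(d, bins, rightmost.closed = FALSE)
  keep <- idx >= 1 & idx <= length(bins) - 1 & !is.na(m)
  means <- rep(NA_real_, length(bins) - 1)
  if (any(keep)) {
    s <- tapply(m[keep], idx[keep], mean)
    means[as.integer(names(s))] <- s
  }
  list(distance_nm = bins[-length(bins)] + bin_width / 2,
       mean_intensity = means)
}

## FWHM of a sampled profile by linear interpolation around its peak
.profile_fwhm <- function(x, y) {
  ok <- is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(y) < 3) return(list(fwhm = NA_real_, defined = FALSE))
  ipk <- which.max(y)
  half <- y[ipk] / 2
  if (min(y) > half) return(list(fwhm = NA_real_, defined = FALSE))
  cross <- function(side) {
    idxs <- if (side == "right") seq(ipk, length(y)) else seq(ipk, 1)
    for (j in seq_len(length(idxs) - 1)) {
      i1 <- idxs[j]; i2 <- idxs[j + 1]
      if ((y[i1] - half) * (y[i2] - half) <= 0 && y[i1] != y[i2])
        return(x[i1] + (half - y[i1]) * (x[i2] - x[i1]) / (y[i2] - y[i1]))
    }
    NA_real_
  }
  r_right <- cross("right")
  r_left <- cross("left")
  if (is.na(r_right)) return(list(fwhm = NA_real_, defined = FALSE))
  if (is.na(r_left)) {
    ## peak at (or adjacent to) zero distance: symmetric-half convention
    return(list(fwhm = 2 * r_right, defined = TRUE))
  }
  list(fwhm = r_right - r_left, defined = TRUE)
}
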