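#' Restrict an image to a nucleus mask
#'
#' Marks pixels outside the mask as `NA` so every downstream statistic
#' (Pearson correlation, overlap counting, radial profiles) is computed
#' on nuclear pixels only.
#'
#' @param img an [sr_image].
#' @param mask logical or 0/1 matrix of the same dimensions.
#' @return an [sr_image] with `NA` outside the mask.
#' @export
crop_to_nucleus <- function(img, mask) {
  stopifnot(inherits(img, "sr_image"))
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(img$data)))
    stop("mask extent does not match the image")
  if (!any(mask > 0)) stop("empty nucleus mask")
  out <- img$data
  out[!(mask > 0)] <- NA_real_
  res <- img
  res$data <- out
  res
}

#' Pearson correlation between two image channels
#'
#' Standard Pearson correlation coefficient over the pixels shared by
#' both channels (and an optional mask), the usual pixel-based
#' colocalization statistic. Compare against the mirrored null from
#' [mirror_randomize()] to judge significance.
#'
#' @param img_a,img_b [sr_image]s (or matrices) of equal dimensions.
#' @param mask optional logical matrix restricting the pixel set.
#' @return the correlation coefficient in `[-1, 1]`, or `NA` (with a
#'   warning) if fewer than 2 pixels remain or either channel has zero
#'   variance.
#' @export
pearson_coloc <- function(img_a, img_b, mask = NULL) {
  a <- if (inherits(img_a, "sr_image")) img_a$data else as.matrix(img_a)
  b <- if (inherits(img_b, "sr_image")) img_b$data else as.matrix(img_b)
  if (!all(dim(a) == dim(b))) stop("channel extents differ")
  keep <- is.finite(a) & is.finite(b)
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == dim(a))) stop("mask extent does not match")
    keep <- keep & (mask > 0)
  }
  av <- a[keep]; bv <- b[keep]
  if (length(av) < 2 || sd(av) == 0 || sd(bv) == 0) {
    warning("PCC undefined: fewer than 2 pixels or zero variance")
    return(NA_real_)
  }
  cor(av, bv)
}

#' Mirror an image for the randomized colocalization control
#'
#' Flips the image along the vertical axis (column order reversed, rows
#' unchanged), producing the "randomized" channel pair used as the
#' colocalization null: mirroring preserves every first- and
#' second-order intensity statistic of the channel while destroying its
#' spatial registration with the partner channel. The operation is an
#' involution.
#'
#' @param img an [sr_image] (or matrix).
#' @return object of the same type, mirrored.
#' @export
mirror_randomize <- function(img) {
  if (inherits(img, "sr_image")) {
    img$data <- img$data[rev(seq_len(nrow(img$data))), , drop = FALSE]
    img
  } else {
    m <- as.matrix(img)
    m[rev(seq_len(nrow(m))), , drop = FALSE]
  }
}

#' Count particle overlaps between two segmented channels
#'
#' Counts the connected objects of `mask_a` (8-connectivity) and how many
#' of them overlap objects of `mask_b` by at least `min_shared_px` shared
#' pixels (default 1, i.e. any contact counts).
#'
#' @param mask_a,mask_b binary matrices (or `ps_segmentation` label
#'   matrices / [sr_image]s, thresholded at 0) of equal dimensions.
#' @param min_shared_px minimum number of shared pixels for an object to
#'   count as overlapping (default 1).
#' @return list: `n_overlap`, `n_total` (objects in `mask_a`),
#'   `percent_overlap` (`100 * n_overlap / n_total`, `NA` with a warning
#'   when `n_total = 0`).
#' @export
count_overlaps <- function(mask_a, mask_b, min_shared_px = 1) {
  bin <- function(x) {
    m <- if (inherits(x, "ps_segmentation")) x$labels
    else if (inherits(x, "sr_image")) x$data else as.matrix(x)
    m[is.na(m)] <- 0
    (m > 0) * 1
  }
  a <- bin(mask_a); b <- bin(mask_b)
  if (!all(dim(a) == dim(b))) stop("mask extents differ")
  lab <- label_components(a)
  n_total <- max(lab)
  if (n_total == 0) {
    warning("no objects in reference mask; percent undefined")
    return(list(n_overlap = 0L, n_total = 0L, percent_overlap = NA_real_))
  }
  shared <- tabulate(lab[lab > 0 & b > 0], nbins = n_total)
  n_overlap <- sum(shared >= min_shared_px)
  list(n_overlap = as.integer(n_overlap), n_total = as.integer(n_total),
       percent_overlap = overlap_percent(n_overlap, n_total))
}

#' Overlap percentage from counts
#'
#' @param n_overlap,n_total non-negative counts, `n_overlap <= n_total`.
#' @return `100 * n_overlap / n_total`.
#' @export
overlap_percent <- function(n_overlap, n_total) {
  stopifnot(all(n_overlap >= 0), all(n_total > 0), all(n_overlap <= n_total))
  100 * n_overlap / n_total
}

#' Averaged radial profile of one channel around the other's particles
#'
#' For each reference center (e.g. segmented paraspeckle centers),
#' computes the mean intensity of the signal channel in concentric
#' annuli, normalizes each particle's profile to its own peak, and
#' averages across particles per distance bin. Per-annulus averaging
#' (rather than integration) makes a spatially uniform signal give a
#' flat profile.
#'
#' @param img_signal an [sr_image], the channel profiled (e.g. SRSF5).
#' @param centers 2-column matrix / data frame of `(x, y)` centers in nm,
#'   e.g. `centroid_x_nm`/`centroid_y_nm` from [measure_particles()].
#' @param max_radius outermost distance in nm.
#' @param step bin width in nm (default 20).
#' @return list of class `radial_profile`: `distance_nm`, `mean_signal`
#'   (averaged peak-normalized intensity), `n_particles`.
#' @export
radial_profile_around <- function(img_signal, centers, max_radius,
                                  step = 20) {
  stopifnot(inherits(img_signal, "sr_image"))
  centers <- as.matrix(as.data.frame(centers)[, 1:2])
  if (!nrow(centers)) stop("at least one center is required")
  profs <- apply(centers, 1, function(ctr) {
    p <- .annulus_means(img_signal$data, img_signal$pixel_size, ctr,
                        max_radius, step)
    v <- p$mean_intensity
    pk <- suppressWarnings(max(v, na.rm = TRUE))
    if (is.finite(pk) && pk > 0) v / pk else v
  })
  profs <- matrix(profs, ncol = nrow(centers))
  dist_nm <- seq(0, max_radius - step, by = step) + step / 2
  list(distance_nm = dist_nm,
       mean_signal = rowMeans(profs, na.rm = TRUE),
       n_particles = nrow(centers))
}

#' Intensity profile along a line
#'
#' Bilinearly interpolated intensities at evenly spaced points between
#' two endpoints, the classic line-scan display of confocal colocal-
#' ization figures.
#'
#' @param img an [sr_image].
#' @param p0,p1 numeric `(x, y)` endpoints in nm, inside the image.
#' @param n_samples number of samples (>= 2).
#' @return data frame `distance_nm, intensity`.
#' @export
line_scan <- function(img, p0, p1, n_samples = 100) {
  stopifnot(inherits(img, "sr_image"), n_samples >= 2)
  px <- img$pixel_size
  ext <- dim(img$data) * px
  for (p in list(p0, p1))
    if (p[1] < 0 || p[1] >= ext[1] || p[2] < 0 || p[2] >= ext[2])
      stop("line endpoints must lie inside the image")
  t <- seq(0, 1, length.out = n_samples)
  xs <- p0[1] + t * (p1[1] - p0[1])
  ys <- p0[2] + t * (p1[2] - p0[2])
  data.frame(distance_nm = t * sqrt(sum((p1 - p0)^2)),
             intensity = .bilinear(img$data, px, xs, ys))
}

## bilinear interpolation at physical coordinates (nm); pixel centers at
## (i - 0.5) * px. Coordinates beyond the outermost centers clamp.
.bilinear <- function(m, px, xs, ys) {
  nx <- nrow(m); ny <- ncol(m)
  fx <- pmin(pmax(xs / px - 0.5, 0), nx - 1)
  fy <- pmin(pmax(ys / px - 0.5, 0), ny - 1)
  i0 <- pmin(floor(fx) + 1, nx); i1 <- pmin(i0 + 1, nx)
  j0 <- pmin(floor(fy) + 1, ny); j1 <- pmin(j0 + 1, ny)
  wx <- fx - (i0 - 1); wy <- fy - (j0 - 1)
  m[cbind(i0, j0)] * (1 - wx) * (1 - wy) +
    m[cbind(i1, j0)] * wx * (1 - wy) +
    m[cbind(i0, j1)] * (1 - wx) * wy +
    m[cbind(i1, j1)] * wx * wy
}

#' Full two-channel colocalization analysis with mirrored null
#'
#' Convenience wrapper combining [pearson_coloc()] and [count_overlaps()]
#' on the real channel pair and on the mirrored-reference null pair.
#'
#' @param img_ref reference channel [sr_image] (e.g. NEAT1), the channel
#'   that is mirrored for the null.
#' @param img_other second channel [sr_image].
#' @param mask optional nucleus mask.
#' @param threshold_ref,threshold_other segmentation thresholds
#'   (`"auto"` = Otsu) used for overlap counting.
#' @param blur_sigma blur before segmentation, nm.
#' @return list of class `coloc_result` with `pcc`, `pcc_randomized`,
#'   `n_overlap`, `n_total`, `percent_overlap`,
#'   `n_overlap_randomized`, `percent_overlap_randomized`.
#' @export
coloc_analysis <- function(img_ref, img_other, mask = NULL,
                           threshold_ref = "auto", threshold_other = "auto",
                           blur_sigma = 10) {
  ref <- if (!is.null(mask)) crop_to_nucleus(img_ref, mask) else img_ref
  oth <- if (!is.null(mask)) crop_to_nucleus(img_other, mask) else img_other
  ref_m <- mirror_randomize(ref)
  seg_ref <- segment_image(ref, blur_sigma, threshold_ref)
  seg_ref_m <- segment_image(ref_m, blur_sigma, threshold_ref)
  seg_oth <- segment_image(oth, blur_sigma, threshold_other)
  ov <- count_overlaps(seg_ref$labels, seg_oth$labels)
  ov_m <- count_overlaps(seg_ref_m$labels, seg_oth$labels)
  structure(list(pcc = pearson_coloc(ref, oth),
                 pcc_randomized = pearson_coloc(ref_m, oth),
                 n_overlap = ov$n_overlap, n_total = ov$n_total,
                 percent_overlap = ov$percent_overlap,
                 n_overlap_randomized = ov_m$n_overlap,
                 percent_overlap_randomized = ov_m$percent_overlap),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result: PCC %.3f (randomized %.3f); overlap %d/%d = %.1f%% (randomized %.1f%%)\n",
              x$pcc, x$pcc_randomized, x$n_overlap, x$n_total,
              x$percent_overlap, x$percent_overlap_randomized))
  invisible(x)
}
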