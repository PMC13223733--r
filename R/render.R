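#' Quality-filter a localization table
#'
#' Retains localizations whose PSF ellipticity and width fall inside
#' closed ranges, the standard post-processing step before rendering.
#' Typical settings are ellipticity 0-0.15 and PSF width 0.8-1.15 px for
#' NEAT1 FISH channels, and 0-0.2 / 0.7-1.3 px for protein channels.
#' Row order is preserved and the operation is idempotent.
#'
#' @param table localization data frame (see [read_localizations()]).
#' @param ellipticity_range,psf_width_range numeric length-2, closed
#'   `[lo, hi]` ranges.
#' @return the filtered data frame.
#' @export
filter_localizations <- function(table, ellipticity_range = c(0, 0.15),
                                 psf_width_range = c(0.8, 1.15)) {
  if (ellipticity_range[1] > ellipticity_range[2] ||
      psf_width_range[1] > psf_width_range[2])
    stop("range limits must be ordered (lo <= hi)")
  if (!nrow(table)) return(table)
  keep <- table$ellipticity >= ellipticity_range[1] &
    table$ellipticity <= ellipticity_range[2] &
    table$psf_width_px >= psf_width_range[1] &
    table$psf_width_px <= psf_width_range[2]
  table[keep, , drop = FALSE]
}

#' Link repeated localizations across frames
#'
#' Merges localizations that re-appear within `link_radius` nm in
#' consecutive frames, tolerating up to `max_dark_frames` frames of
#' blinking gap, into a single record at the photon-weighted mean
#' position with summed photons -- the standard treatment of multi-frame
#' emission events. The linking radius is a plain nm parameter (in
#' acquisition pipelines it is commonly set to a multiple of the
#' localization precision).
#'
#' Linking is transitive: a chain in frames 3, 5, 7 with gap tolerance 2
#' collapses to one record. The merged record keeps the first frame and
#' the photon-weighted mean of the quality metrics.
#'
#' @param table localization data frame.
#' @param link_radius maximum displacement in nm between linked
#'   localizations, `> 0`.
#' @param max_dark_frames maximum number of empty frames inside a chain,
#'   `>= 0` (frame gap of `max_dark_frames + 1` still links).
#' @return data frame with one row per linked event.
#' @export
link_localizations <- function(table, link_radius, max_dark_frames = 2) {
  if (link_radius <= 0) stop("link_radius must be > 0")
  if (max_dark_frames < 0) stop("max_dark_frames must be >= 0")
  n <- nrow(table)
  if (n <= 1) return(table)
  ord <- order(table$frame)
  tab <- table[ord, , drop = FALSE]
  chain <- integer(n)            # chain id per row
  ## open chains: last position, last frame, chain id
  open_x <- numeric(0); open_y <- numeric(0); open_f <- integer(0)
  open_id <- integer(0); next_id <- 0L
  max_gap <- max_dark_frames + 1L
  for (i in seq_len(n)) {
    alive <- open_f >= tab$frame[i] - max_gap
    open_x <- open_x[alive]; open_y <- open_y[alive]
    open_f <- open_f[alive]; open_id <- open_id[alive]
    d2 <- (open_x - tab$x_nm[i])^2 + (open_y - tab$y_nm[i])^2
    cand <- which(d2 <= link_radius^2 & open_f < tab$frame[i])
    if (length(cand)) {
      j <- cand[which.min(d2[cand])]
      chain[i] <- open_id[j]
      open_x[j] <- tab$x_nm[i]; open_y[j] <- tab$y_nm[i]
      open_f[j] <- tab$frame[i]
    } else {
      next_id <- next_id + 1L
      chain[i] <- next_id
      open_x <- c(open_x, tab$x_nm[i]); open_y <- c(open_y, tab$y_nm[i])
      open_f <- c(open_f, tab$frame[i]); open_id <- c(open_id, next_id)
    }
  }
  merged <- lapply(split(seq_len(n), chain), function(idx) {
    w <- tab$photons[idx]
    if (sum(w) <= 0) w <- rep(1, length(idx))
    data.frame(x_nm = sum(tab$x_nm[idx] * w) / sum(w),
               y_nm = sum(tab$y_nm[idx] * w) / sum(w),
               frame = min(tab$frame[idx]),
               photons = sum(tab$photons[idx]),
               ellipticity = sum(tab$ellipticity[idx] * w) / sum(w),
               psf_width_px = sum(tab$psf_width_px[idx] * w) / sum(w))
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$frame, out$x_nm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render a localization table to a super-resolution image
#'
#' Bins localizations into a 2-D count histogram at the requested pixel
#' size (pixel `i` covers `[i * px, (i + 1) * px)` nm) and optionally
#' applies a Gaussian blur with a normalized kernel, so that the
#' unblurred image sum equals the number of in-field localizations.
#'
#' @param table localization data frame.
#' @param pixel_size pixel size in nm, `> 0` (default 10).
#' @param blur_sigma optional Gaussian blur sigma in nm (`NULL` or 0 for
#'   none).
#' @param extent optional numeric length-2 field extent `(x, y)` in nm;
#'   defaults to the smallest grid covering all localizations. An empty
#'   table with no extent yields a 1x1 zero image.
#' @return an [sr_image].
#' @export
render_histogram <- function(table, pixel_size = 10, blur_sigma = NULL,
                             extent = NULL) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (is.null(extent)) {
    extent <- if (nrow(table))
      c(max(table$x_nm), max(table$y_nm)) + pixel_size else
        c(pixel_size, pixel_size)
  }
  nx <- max(1L, ceiling(extent[1] / pixel_size))
  ny <- max(1L, ceiling(extent[2] / pixel_size))
  m <- matrix(0, nx, ny)
  if (nrow(table)) {
    ix <- floor(table$x_nm / pixel_size)
    iy <- floor(table$y_nm / pixel_size)
    keep <- ix >= 0 & ix < nx & iy >= 0 & iy < ny
    if (any(keep)) {
      idx <- ix[keep] + nx * iy[keep] + 1
      counts <- tabulate(idx, nbins = nx * ny)
      m <- matrix(counts, nx, ny)
    }
  }
  if (!is.null(blur_sigma) && blur_sigma > 0)
    m <- blur_matrix(m, blur_sigma / pixel_size)
  sr_image(pmax(m, 0), pixel_size)
}
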