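#' Super-resolution intensity image
#'
#' Container for a 2-D non-negative intensity grid with a physical pixel
#' size. The pixel convention is half-open: zero-based pixel `i` covers the
#' physical interval `[i * pixel_size, (i + 1) * pixel_size)` nanometres,
#' with the origin at the top-left corner and y increasing downward. The
#' intensity matrix is stored x-first (`data[ix + 1, iy + 1]`), matching
#' the EBImage convention so that images interoperate with its filters.
#'
#' Pixels may be `NA` to mark regions excluded from analysis (e.g. outside
#' a nucleus mask, see [crop_to_nucleus()]); all statistics in the package
#' skip `NA` pixels.
#'
#' @param data numeric matrix of intensities, `dim = c(nx, ny)`; values
#'   must be non-negative (or `NA`).
#' @param pixel_size physical pixel size in nm, `> 0`.
#' @return An object of class `sr_image`: a list with elements `data` and
#'   `pixel_size`.
#' @examples
#' img <- sr_image(matrix(0, 64, 64), pixel_size = 10)
#' dim(img$data)
#' @export
sr_image <- function(data, pixel_size) {
  stopifnot(is.matrix(data), is.numeric(pixel_size), length(pixel_size) == 1)
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (any(data < 0, na.rm = TRUE)) stop("intensities must be non-negative")
  structure(list(data = data, pixel_size = as.numeric(pixel_size)),
            class = "sr_image")
}

#' @export
print.sr_image <- function(x, ...) {
  cat(sprintf("sr_image: %d x %d px, %.3g nm/px, intensity range [%g, %g]\n",
              nrow(x$data), ncol(x$data), x$pixel_size,
              suppressWarnings(min(x$data, na.rm = TRUE)),
              suppressWarnings(max(x$data, na.rm = TRUE))))
  invisible(x)
}

#' @export
dim.sr_image <- function(x) dim(x$data)

as_sr_image <- function(x, pixel_size) {
  if (inherits(x, "sr_image")) return(x)
  sr_image(as.matrix(x), pixel_size)
}

#' Write / read a super-resolution image as TIFF with a JSON sidecar
#'
#' The intensity grid is stored as a 32-bit float single-channel TIFF;
#' the physical pixel size (nm) is recorded in a JSON sidecar file
#' (`<path>.json`) so that the physical calibration survives round trips
#' through tools that drop TIFF resolution tags.
#'
#' @param img an [sr_image].
#' @param path output TIFF path.
#' @return `write_sr_tiff` returns `path` invisibly; `read_sr_tiff`
#'   returns an [sr_image].
#' @export
write_sr_tiff <- function(img, path) {
  stopifnot(inherits(img, "sr_image"))
  m <- img$data
  m[is.na(m)] <- 0
  ## tiff::writeTIFF takes row-major (y, x) matrices; transpose from the
  ## internal x-first layout
  tiff::writeTIFF(t(m) / max(1, max(m)), path, bits.per.sample = 32L,
                  reduce = TRUE)
  meta <- list(pixel_size_nm = img$pixel_size, intensity_scale = max(1, max(m)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sr_tiff
#' @export
read_sr_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  sr_image(t(m) * scale, pixel_size = meta$pixel_size_nm)
}

## Gaussian blur with a sum-conserving normalized kernel (circular
## boundary); sigma in pixels. sigma = 0 is the identity.
blur_matrix <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  size <- 2L * max(1L, ceiling(3 * sigma_px)) + 1L
  size <- min(size, 2L * (min(dim(m)) %/% 2L) - 1L)
  if (size < 3L) return(m)
  brush <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma_px)
  brush <- brush / sum(brush)
  EBImage::filter2(m, brush, boundary = "circular")
}

## 8-connectivity labeling. EBImage::bwlabel is 4-connected; diagonal
## contacts between 4-connected labels are merged through the label
## adjacency graph.
label_components <- function(mask) {
  storage.mode(mask) <- "double"
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n <= 1) return(lab)
  nx <- nrow(lab); ny <- ncol(lab)
  edges <- NULL
  ## diagonal neighbor pairs: offsets (+1,+1) and (+1,-1)
  a1 <- lab[-nx, -ny]; b1 <- lab[-1, -1]
  a2 <- lab[-nx, -1];  b2 <- lab[-1, -ny]
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  edges <- cbind(c(a1[keep1], a2[keep2]), c(b1[keep1], b2[keep2]))
  if (nrow(edges) == 0L) return(lab)
  g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  ## relabel consecutively
  relab <- match(comp, sort(unique(comp)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}
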