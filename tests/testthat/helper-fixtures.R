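# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk.

# minimal localization table from coordinates
loc_table <- function(x, y, frame = 0L, photons = 1000,
                      ellipticity = 0.1, psf_width_px = 1.0) {
  data.frame(x_nm = x, y_nm = y,
             frame = rep_len(frame, length(x)),
             photons = rep_len(photons, length(x)),
             ellipticity = rep_len(ellipticity, length(x)),
             psf_width_px = rep_len(psf_width_px, length(x)))
}

# image whose intensity is fun(distance from center in nm)
radial_image <- function(n_px, pixel_size, center, fun) {
  xc <- (seq_len(n_px) - 0.5) * pixel_size
  d <- sqrt(outer((xc - center[1])^2, (xc - center[2])^2, "+"))
  sr_image(fun(d), pixel_size)
}

disk_image <- function(n_px, pixel_size, center, radius)
  radial_image(n_px, pixel_size, center, function(d) (d <= radius) * 1)

# solid ellipse with semi-axes (a, b) nm
ellipse_image <- function(n_px, pixel_size, center, a, b) {
  xc <- (seq_len(n_px) - 0.5) * pixel_size
  m <- (outer(((xc - center[1]) / a)^2, ((xc - center[2]) / b)^2,
              "+") <= 1) * 1
  sr_image(m, pixel_size)
}

# image evaluated from the ring model on a pixel grid
ring_model_image <- function(n_px, pixel_size, par, variant = "printed",
                             noise_sd = 0) {
  xc <- (seq_len(n_px) - 0.5) * pixel_size
  xg <- rep(xc, times = n_px); yg <- rep(xc, each = n_px)
  z <- matrix(ring_model(xg, yg, par, variant), n_px, n_px)
  if (noise_sd > 0) z <- z + matrix(rnorm(n_px^2, 0, noise_sd), n_px)
  sr_image(pmax(z, 0), pixel_size)
}

# localization table tracing a ring of given radius
ring_points_table <- function(n, center, radius, radial_sd = 4, seed = NULL) {
  gen <- function() {
    th <- runif(n, 0, 2 * pi)
    r <- rnorm(n, radius, radial_sd)
    loc_table(center[1] + r * cos(th), center[2] + r * sin(th))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# hand-constructed source/target LSV pair for a cassette exon:
# donor D, skipped exon [e1, e2], acceptor A
cassette_pair <- function(D = 100, e1 = 200, e2 = 300, A = 500,
                          prob = 0.9, dpsi = c(10, -10)) {
  src <- lsv_record("src", "source", dpsi = dpsi, probability = prob,
                    junctions = data.frame(start = c(D, D),
                                           end = c(A, e1 - 1)))
  tgt <- lsv_record("tgt", "target", dpsi = dpsi, probability = prob,
                    junctions = data.frame(start = c(D, e2 + 1),
                                           end = c(A, A)))
  list(source = src, target = tgt, exon = c(e1, e2))
}

# independent brute-force oracle for binarize_lsv: scan all ordered
# junction pairs, take the pair maximizing (|d_i|, |d_j|) lexicographically
# with i as the strongest junction, then apply the retention rule
binarize_oracle <- function(d) {
  n <- length(d)
  best <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (abs(d[i]) < max(abs(d))) next          # i must be a strongest junction
    cand <- c(i, j)
    if (is.null(best) ||
        abs(d[j]) > abs(d[best[2]]) + 1e-12) best <- cand
  }
  i1 <- best[1]; i2 <- best[2]
  retained <- abs(d[i2]) >= 0.5 * abs(d[i1]) && sign(d[i1]) * sign(d[i2]) < 0
  list(retained = retained,
       dpsi_main = d[i1], dpsi_second = d[i2])
}
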