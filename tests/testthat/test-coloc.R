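test_that("nucleus cropping restricts statistics to the masked pixel set", {
  withr::with_seed(2, {
    a <- sr_image(matrix(runif(400), 20, 20), 10)
    b <- sr_image(matrix(runif(400), 20, 20), 10)
  })
  full <- matrix(1, 20, 20)
  expect_equal(pearson_coloc(crop_to_nucleus(a, full), b),
               pearson_coloc(a, b))

  half <- matrix(0, 20, 20); half[1:10, ] <- 1
  pcc <- pearson_coloc(crop_to_nucleus(a, half), b)
  expect_equal(pcc, cor(as.numeric(a$data[1:10, ]),
                        as.numeric(b$data[1:10, ])))

  expect_error(crop_to_nucleus(a, matrix(1, 5, 5)), "extent")
  expect_error(crop_to_nucleus(a, matrix(0, 20, 20)), "empty")
})

test_that("PCC hits its algebraic anchors and its independence null", {
  withr::with_seed(3, a <- sr_image(matrix(runif(10000), 100, 100), 10))
  expect_equal(pearson_coloc(a, a), 1.0)
  neg <- sr_image(max(a$data) - a$data, 10)
  expect_equal(pearson_coloc(a, neg), -1.0)

  withr::with_seed(4, b <- sr_image(matrix(runif(10000), 100, 100), 10))
  expect_lt(abs(pearson_coloc(a, b)), 0.05)

  ## affine gain invariance
  expect_equal(pearson_coloc(sr_image(3 * a$data + 2, 10), b),
               pearson_coloc(a, b))

  expect_warning(p <- pearson_coloc(sr_image(matrix(1, 5, 5), 10), a$data[1:5, 1:5]),
                 "undefined")
  expect_true(is.na(p))
})

test_that("mirror randomization is an involution along the vertical axis", {
  withr::with_seed(5, img <- sr_image(matrix(runif(60), 10, 6), 10))
  m <- mirror_randomize(img)
  expect_equal(mirror_randomize(m)$data, img$data)
  expect_equal(sum(m$data), sum(img$data))

  sym <- sr_image(matrix(c(1, 2, 3, 3, 2, 1), 6, 1), 10)
  expect_equal(mirror_randomize(sym)$data, sym$data)

  ## a point at x-pixel c moves to W - 1 - c (zero-based)
  pt <- matrix(0, 8, 4); pt[3, 2] <- 1     # zero-based x = 2
  mm <- mirror_randomize(sr_image(pt, 10))
  expect_equal(unname(which(mm$data == 1, arr.ind = TRUE)[1, 1]),
               8 - 2)                    # zero-based x = 5, 1-based row 6
})

test_that("overlap counting uses object-level contact", {
  a <- matrix(0, 30, 30)
  a[2:4, 2:4] <- 1; a[10:12, 10:12] <- 1; a[20:22, 20:22] <- 1
  b <- matrix(0, 30, 30)
  b[4:6, 4:6] <- 1                        # touches object 1 only
  ov <- count_overlaps(a, b)
  expect_equal(ov$n_overlap, 1)
  expect_equal(ov$n_total, 3)
  expect_equal(ov$percent_overlap, 100 / 3)

  empty <- count_overlaps(a, matrix(0, 30, 30))
  expect_equal(empty$n_overlap, 0)
  expect_equal(empty$percent_overlap, 0)

  expect_warning(none <- count_overlaps(matrix(0, 30, 30), b), "undefined")
  expect_true(is.na(none$percent_overlap))

  ## minimum-shared-pixel variant
  strict <- count_overlaps(a, b, min_shared_px = 2)
  expect_equal(strict$n_overlap, 0)       # only one shared pixel at (4,4)
})

test_that("radial profiles localize ring signal and flatten uniform fields", {
  centers <- data.frame(x = c(300, 700), y = c(300, 700))
  xc <- (seq_len(101) - 0.5) * 10
  sig <- matrix(0, 101, 101)
  for (i in 1:2) {
    d <- sqrt(outer((xc - centers$x[i])^2, (xc - centers$y[i])^2, "+"))
    sig <- sig + exp(-(d - 150)^2 / (2 * 20^2))
  }
  prof <- radial_profile_around(sr_image(sig, 10), centers, 300, 20)
  pk <- prof$distance_nm[which.max(prof$mean_signal)]
  expect_true(pk >= 140 && pk <= 160)
  expect_equal(prof$n_particles, 2)

  flat <- radial_profile_around(sr_image(matrix(5, 101, 101), 10),
                                centers, 300, 20)
  expect_lt(diff(range(flat$mean_signal)), 1e-9)

  ## structured signal beats its mirrored null at shell distances
  mirrored <- radial_profile_around(mirror_randomize(sr_image(sig, 10)),
                                    centers, 300, 20)
  shell_bin <- which.min(abs(prof$distance_nm - 150))
  expect_gt(prof$mean_signal[shell_bin], mirrored$mean_signal[shell_bin])

  expect_error(radial_profile_around(sr_image(sig, 10),
                                     centers[0, ], 300), "center")
})

test_that("line scans interpolate between endpoints", {
  const <- sr_image(matrix(4, 30, 30), 10)
  ls <- line_scan(const, c(20, 20), c(280, 250), 50)
  expect_true(all(abs(ls$intensity - 4) < 1e-12))

  disk <- disk_image(41, 10, c(205, 205), 100)
  prof <- line_scan(disk, c(25, 205), c(385, 205), 101)
  expect_equal(prof$intensity[51], max(prof$intensity))  # center on plateau
  expect_equal(prof$intensity, rev(prof$intensity), tolerance = 1e-9)

  two <- line_scan(const, c(15, 15), c(275, 275), 2)
  expect_equal(nrow(two), 2)
  expect_error(line_scan(const, c(-5, 10), c(100, 100)), "inside")
})

test_that("the full coloc analysis beats its mirrored null on structured scenes", {
  p <- scene_params(n_particles = 6, field_size = c(4000, 4000),
                    channels = c("five_prime", "srsf5"),
                    srsf5 = list(n_speckles = 2, speckle_sigma = 150,
                                 points_per_speckle = 300,
                                 decorated_fraction = 1,
                                 shell_enrichment = 6, ring_radius = 140),
                    background_density = 1, seed = 12)
  sc <- simulate_scene(p)
  ref <- render_histogram(sc$localizations$five_prime, 20, blur_sigma = 30,
                          extent = c(4000, 4000))
  oth <- render_histogram(sc$localizations$srsf5, 20, blur_sigma = 30,
                          extent = c(4000, 4000))
  res <- coloc_analysis(ref, oth)
  expect_gt(res$pcc, res$pcc_randomized)
  expect_true(res$n_overlap >= res$n_overlap_randomized)
  expect_equal(res$percent_overlap,
               100 * res$n_overlap / res$n_total)
})
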