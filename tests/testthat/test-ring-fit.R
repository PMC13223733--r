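test_that("Hough detection finds disjoint rings near their true centers", {
  p <- scene_params(n_particles = 3, field_size = c(3000, 3000),
                    shell_radius_sd = 0, channels = "five_prime",
                    background_density = 0, seed = 3)
  sc <- simulate_scene(p)
  img <- render_histogram(sc$localizations$five_prime, 10, blur_sigma = 20,
                          extent = c(3000, 3000))
  det <- detect_rings(img, 0.85, c(120, 250))
  expect_equal(nrow(det), 3)
  d <- sapply(seq_len(3), function(i)
    min(sqrt((det$x_nm - sc$truth$x_nm[i])^2 +
               (det$y_nm - sc$truth$y_nm[i])^2)))
  expect_true(all(d < 20))

  blank <- sr_image(matrix(0, 50, 50), 10)
  expect_equal(nrow(detect_rings(blank, 0.85, c(100, 200))), 0)
})

test_that("concentric rings are reported at distinct radii", {
  withr::with_seed(1, {
    th <- runif(2000, 0, 2 * pi)
    tab <- loc_table(c(500 + 150 * cos(th), 500 + 250 * cos(th[1:1000])),
                     c(500 + 150 * sin(th), 500 + 250 * sin(th[1:1000])))
  })
  img <- render_histogram(tab, 10, blur_sigma = 15, extent = c(1000, 1000))
  det <- detect_rings(img, 0.85, c(100, 300))
  expect_equal(nrow(det), 2)
  expect_gt(abs(diff(det$radius_nm)), 60)
  expect_true(all(sqrt((det$x_nm - 500)^2 + (det$y_nm - 500)^2) < 30))
})

test_that("channel matching is mutual nearest neighbor within range", {
  one5 <- data.frame(x_nm = 100, y_nm = 100)
  one3 <- data.frame(x_nm = 150, y_nm = 100)
  m <- match_channels(one5, one3, max_dist = 200)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$dist_nm, 50)

  far3 <- data.frame(x_nm = 400, y_nm = 100)
  expect_equal(nrow(match_channels(one5, far3, 200)$pairs), 0)

  ## crossed 2 vs 2 geometry: mutual NN resolves to the two closest pairs,
  ## checked against brute force over the two possible assignments
  d5 <- data.frame(x_nm = c(0, 1000), y_nm = c(0, 0))
  d3 <- data.frame(x_nm = c(80, 920), y_nm = c(0, 0))
  mm <- match_channels(d5, d3, 300)
  cost <- function(assig) sum(sqrt((d5$x_nm - d3$x_nm[assig])^2 +
                                     (d5$y_nm - d3$y_nm[assig])^2))
  best <- if (cost(c(1, 2)) <= cost(c(2, 1))) c(1, 2) else c(2, 1)
  expect_equal(nrow(mm$pairs), 2)
  expect_equal(mm$pairs$i3[order(mm$pairs$i5)], best)
})

test_that("fitting data generated from the model recovers its parameters", {
  truth <- c(C1 = 5, C2 = 80, C3 = -70, a = 500, b = 510,
             u1 = 260, v1 = 250, u2 = 120)
  for (variant in c("printed", "symmetric")) {
    img <- ring_model_image(101, 10, truth, variant)
    fit <- fit_ring(img, center = c(495, 505), radius = 180,
                    variant = variant)
    expect_true(fit$converged)
    expect_true(all(abs((fit$par - truth) / truth) < 0.01))
  }
})

test_that("a flat image degenerates to a flagged non-ring fit", {
  flat <- sr_image(matrix(7, 41, 41), 10)
  fit <- fit_ring(flat, center = c(200, 200), radius = 100)
  expect_true(fit$flat)
  expect_false(fit$radius_defined)
})

test_that("shell-ring radii are defined, centered and monotone in ring size", {
  ## the model-based outer-FWHM radius carries a positive offset relative
  ## to the annulus peak radius (the centered two-Gaussian model cannot
  ## decay faster than its own tails); what must hold is that the fit
  ## converges, centers correctly, and orders ring sizes faithfully
  radii <- c(140, 180, 220)
  fits <- lapply(radii, function(r0) {
    tab <- ring_points_table(2000, c(500, 500), r0, radial_sd = 20,
                             seed = 21 + r0)
    img <- render_histogram(tab, 10, blur_sigma = 15, extent = c(1000, 1000))
    fit_ring(img, center = c(500, 500), radius = r0)
  })
  expect_true(all(vapply(fits, function(f) f$converged && f$radius_defined,
                         TRUE)))
  centers <- t(vapply(fits, function(f) f$par[c("a", "b")], c(0, 0)))
  expect_true(all(abs(centers - 500) < 15))
  rfit <- vapply(fits, function(f) f$radius_nm, 0)
  expect_true(all(diff(rfit) > 0))
  ## equally sized 5' and 3' rings share the offset: the ratio stays ~1
  tab3 <- ring_points_table(2000, c(500, 500), 180, radial_sd = 20,
                            seed = 77)
  img3 <- render_histogram(tab3, 10, blur_sigma = 15, extent = c(1000, 1000))
  f3 <- fit_ring(img3, center = c(500, 500), radius = 180)
  expect_equal(five_three_ratio(fits[[2]], f3), 1, tolerance = 0.1)
})

test_that("translation moves the fitted center and leaves the radius", {
  truth <- c(C1 = 2, C2 = 60, C3 = -50, a = 400, b = 400,
             u1 = 220, v1 = 220, u2 = 110)
  imgA <- ring_model_image(101, 10, truth)
  truthB <- truth; truthB["a"] <- 500; truthB["b"] <- 460
  imgB <- ring_model_image(101, 10, truthB)
  fa <- fit_ring(imgA, c(400, 400), 150)
  fb <- fit_ring(imgB, c(500, 460), 150)
  expect_equal(fb$par[["a"]] - fa$par[["a"]], 100, tolerance = 1e-3)
  expect_equal(fb$par[["b"]] - fa$par[["b"]], 60, tolerance = 1e-3)
  expect_equal(fa$radius_nm, fb$radius_nm, tolerance = 1e-3)
})

test_that("outer-FWHM radius matches the Gaussian-ridge closed form", {
  for (r0 in c(120, 180)) for (s in c(20, 40)) {
    f <- function(r) exp(-(r - r0)^2 / (2 * s^2))
    expect_equal(outer_fwhm_radius(f, 600), r0 + sqrt(2 * log(2)) * s,
                 tolerance = 1e-3)
  }
  ## no positive structure -> undefined
  expect_true(is.na(outer_fwhm_radius(function(r) rep(0, length(r)), 500)))
})

test_that("ring radius is invariant to intensity rescaling", {
  base <- c(C1 = 0, C2 = 60, C3 = -50, a = 400, b = 400,
            u1 = 220, v1 = 220, u2 = 110)
  doubled <- base; doubled[c("C2", "C3")] <- 2 * doubled[c("C2", "C3")]
  fit1 <- structure(list(par = base, converged = TRUE, variant = "printed"),
                    class = "ring_fit")
  fit2 <- structure(list(par = doubled, converged = TRUE,
                         variant = "printed"), class = "ring_fit")
  expect_equal(ring_radius(fit1), ring_radius(fit2), tolerance = 1e-9)
})

test_that("size classes and 5'/3' ratios follow their definitions", {
  expect_equal(classify_particle(180), "small")
  expect_equal(classify_particle(300), "large")
  expect_equal(classify_particle(280), "large")   # boundary -> large

  expect_equal(five_three_ratio(180, 180), 1.0)
  expect_equal(five_three_ratio(90, 180), 0.5)
  expect_true(is.na(five_three_ratio(90, 0)))

  ## an "internalized 5'" population has a smaller mean ratio than control
  withr::with_seed(17, {
    r3 <- rnorm(50, 180, 10)
    ratio_ctrl <- rnorm(50, 180, 10) / r3
    ratio_int <- (0.7 * rnorm(50, 180, 10)) / r3
  })
  expect_lt(wilcox.test(ratio_int, ratio_ctrl,
                        alternative = "less")$p.value, 0.01)
})
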