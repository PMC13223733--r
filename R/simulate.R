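#' Parameters for a synthetic two-channel paraspeckle scene
#'
#' Describes the generative model for a field of core-shell paraspeckles
#' imaged by single-molecule localization microscopy. Each particle is a
#' sphere whose 5' and 3' NEAT1_2 ends occupy a shell ring around the
#' center and whose middle region fills the core. The shell is modeled as
#' points at radius `Normal(shell_radius, shell_thickness / 2.355)` around
#' the particle center, i.e. `shell_thickness` is the FWHM of the radial
#' label distribution. Localization uncertainty adds isotropic Gaussian
#' jitter of `loc_noise_sd` nm to every point.
#'
#' Cluster morphologies mirror the two architectures seen for paraspeckle
#' clusters: `rod` places `k` sphere centers on a line at spacing
#' `2 * shell_radius` (a cylinder-like chain), `aggregate` packs `k`
#' centers by hard-sphere rejection sampling around a common origin.
#'
#' The SRSF5 channel models a nuclear-speckle protein: uniform
#' nucleoplasmic background, Gaussian speckle blobs, and optionally a
#' shell-enrichment ring at 100-180 nm from a decorated fraction of
#' particle centers.
#'
#' @param field_size numeric length-2, field extent in nm (x, y).
#' @param pixel_size rendering pixel size in nm (default 10).
#' @param n_particles number of singleton particles.
#' @param shell_radius_mean,shell_radius_sd shell radius distribution (nm).
#'   The defaults emulate untreated cells, where paraspeckles are ~360 nm
#'   diameter spheres.
#' @param shell_thickness FWHM of the radial shell label distribution (nm).
#' @param core_fraction fraction of each shell channel's points that are
#'   mislocalized into the core disk (0 for intact shell architecture).
#' @param points_per_particle localizations per particle per channel.
#' @param cluster list describing clusters: `list(type = "none")`,
#'   `list(type = "rod", k = 4, n = 1)` or
#'   `list(type = "aggregate", k = 5, n = 1)`.
#' @param channels character vector among `"five_prime"`, `"three_prime"`
#'   (shell rings), `"core"` (disk over the particle middle region),
#'   `"sphere"` (uniform disk over the whole particle, as for a label
#'   covering the full transcript), `"srsf5"`.
#' @param srsf5 list of SRSF5 channel parameters: `n_speckles`,
#'   `speckle_sigma` (nm), `points_per_speckle`, `decorated_fraction`
#'   (fraction of particles carrying a shell-enrichment ring),
#'   `shell_enrichment` (ring points as a multiple of background density
#'   over the ring area), `ring_radius` (nm, within 100-180).
#' @param background_density uniform background localizations per um^2.
#' @param loc_noise_sd localization noise sd in nm.
#' @param n_frames number of acquisition frames localizations are spread
#'   over.
#' @param seed integer seed fixing every stream of randomness.
#' @return A validated list of class `scene_params`.
#' @export
scene_params <- function(field_size = c(5000, 5000),
                         pixel_size = 10,
                         n_particles = 10,
                         shell_radius_mean = 180,
                         shell_radius_sd = 10,
                         shell_thickness = 50,
                         core_fraction = 0,
                         points_per_particle = 400,
                         cluster = list(type = "none"),
                         channels = c("five_prime", "three_prime"),
                         srsf5 = list(n_speckles = 5, speckle_sigma = 150,
                                      points_per_speckle = 400,
                                      decorated_fraction = 0,
                                      shell_enrichment = 3,
                                      ring_radius = 140),
                         background_density = 1,
                         loc_noise_sd = 5,
                         n_frames = 1000,
                         seed = 1L) {
  p <- list(field_size = field_size, pixel_size = pixel_size,
            n_particles = n_particles,
            shell_radius_mean = shell_radius_mean,
            shell_radius_sd = shell_radius_sd,
            shell_thickness = shell_thickness,
            core_fraction = core_fraction,
            points_per_particle = points_per_particle,
            cluster = cluster, channels = channels, srsf5 = srsf5,
            background_density = background_density,
            loc_noise_sd = loc_noise_sd, n_frames = n_frames,
            seed = as.integer(seed))
  if (any(p$field_size <= 0) || p$pixel_size <= 0 ||
      p$shell_radius_mean <= 0 || p$shell_thickness <= 0)
    stop("all lengths must be > 0")
  if (p$n_particles < 0) stop("n_particles must be >= 0")
  if (p$shell_radius_sd < 0 || p$loc_noise_sd < 0)
    stop("standard deviations must be >= 0")
  if (p$core_fraction < 0 || p$core_fraction > 1)
    stop("core_fraction must be in [0, 1]")
  if (!p$cluster$type %in% c("none", "rod", "aggregate"))
    stop("unknown cluster type")
  cls <- setdiff(p$channels,
                 c("five_prime", "three_prime", "core", "sphere", "srsf5"))
  if (length(cls)) stop("unknown channels: ", paste(cls, collapse = ", "))
  structure(p, class = "scene_params")
}

## attach acquisition metadata columns to a coordinate table
.loc_table <- function(x, y, n_frames) {
  n <- length(x)
  data.frame(
    x_nm = x, y_nm = y,
    frame = if (n) sample.int(n_frames, n, replace = TRUE) - 1L else integer(0),
    photons = if (n) round(rlnorm(n, log(1000), 0.3)) else numeric(0),
    ellipticity = runif(n, 0, 0.15),
    psf_width_px = pmax(0.5, rnorm(n, 1.0, 0.08))
  )
}

## points on a shell ring: radius ~ Normal(R, fwhm/2.355), angle uniform
.ring_points <- function(n, cx, cy, radius, thickness_fwhm, noise_sd) {
  theta <- runif(n, 0, 2 * pi)
  r <- rnorm(n, radius, thickness_fwhm / (2 * sqrt(2 * log(2))))
  list(x = cx + r * cos(theta) + rnorm(n, 0, noise_sd),
       y = cy + r * sin(theta) + rnorm(n, 0, noise_sd))
}

## uniform points on a disk of given radius
.disk_points <- function(n, cx, cy, radius, noise_sd) {
  theta <- runif(n, 0, 2 * pi)
  r <- radius * sqrt(runif(n))
  list(x = cx + r * cos(theta) + rnorm(n, 0, noise_sd),
       y = cy + r * sin(theta) + rnorm(n, 0, noise_sd))
}

## place m centers uniformly with minimum pairwise separation
.place_centers <- function(m, field, min_sep, margin) {
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < m && tries < 20000L) {
    x <- runif(1, margin, field[1] - margin)
    y <- runif(1, margin, field[2] - margin)
    if (!length(xs) || all((xs - x)^2 + (ys - y)^2 >= min_sep^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
    tries <- tries + 1L
  }
  if (length(xs) < m)
    stop("could not place ", m, " particles at separation ", min_sep,
         " in the field; enlarge the field or reduce n_particles")
  cbind(xs, ys)
}

#' Simulate a two-channel paraspeckle scene
#'
#' Draws per-channel localization tables from the generative model in
#' [scene_params()] and returns them together with the ground truth
#' (particle centers, true shell radii, cluster membership).
#'
#' Two calls with identical parameters (including `seed`) return identical
#' tables.
#'
#' @param params a [scene_params()] object.
#' @return A list with elements
#'   \describe{
#'     \item{localizations}{named list of per-channel data frames with
#'       columns `x_nm, y_nm, frame, photons, ellipticity, psf_width_px`.}
#'     \item{truth}{data frame with one row per simulated particle:
#'       `particle, x_nm, y_nm, radius_nm, cluster_id` (`0` = singleton).}
#'     \item{params}{the input parameters.}
#'   }
#' @examples
#' sc <- simulate_scene(scene_params(n_particles = 3, seed = 7))
#' nrow(sc$truth)
#' @export
simulate_scene <- function(params) {
  if (!inherits(params, "scene_params")) params <- do.call(scene_params, params)
  p <- params
  withr::with_seed(p$seed, {
    ## ---- particle centers -------------------------------------------------
    margin <- p$shell_radius_mean * 2 + 100
    truth <- data.frame(particle = integer(0), x_nm = numeric(0),
                        y_nm = numeric(0), radius_nm = numeric(0),
                        cluster_id = integer(0))
    n_clusters <- if (p$cluster$type == "none") 0L else
      as.integer(if (is.null(p$cluster$n)) 1L else p$cluster$n)
    n_anchor <- p$n_particles + n_clusters
    if (n_anchor > 0) {
      sep <- 4 * p$shell_radius_mean +
        if (n_clusters > 0) 2 * p$shell_radius_mean *
          max(0, (if (is.null(p$cluster$k)) 0 else p$cluster$k)) else 0
      anchors <- .place_centers(n_anchor, p$field_size, sep, margin)
      pid <- 0L
      add_particle <- function(x, y, cl) {
        pid <<- pid + 1L
        r <- max(20, rnorm(1, p$shell_radius_mean, p$shell_radius_sd))
        truth <<- rbind(truth, data.frame(particle = pid, x_nm = x, y_nm = y,
                                          radius_nm = r, cluster_id = cl))
      }
      if (p$n_particles > 0)
        for (i in seq_len(p$n_particles))
          add_particle(anchors[i, 1], anchors[i, 2], 0L)
      if (n_clusters > 0) {
        k <- p$cluster$k
        for (ci in seq_len(n_clusters)) {
          ax <- anchors[p$n_particles + ci, 1]
          ay <- anchors[p$n_particles + ci, 2]
          if (p$cluster$type == "rod") {
            phi <- runif(1, 0, pi)
            for (j in seq_len(k))
              add_particle(ax + (j - (k + 1) / 2) * 2 * p$shell_radius_mean *
                             cos(phi),
                           ay + (j - (k + 1) / 2) * 2 * p$shell_radius_mean *
                             sin(phi), ci)
          } else {                      # aggregate: hard-sphere packing
            cxs <- ax; cys <- ay
            add_particle(ax, ay, ci)
            while (length(cxs) < k) {
              host <- sample.int(length(cxs), 1)
              phi <- runif(1, 0, 2 * pi)
              nx <- cxs[host] + 2 * p$shell_radius_mean * cos(phi)
              ny <- cys[host] + 2 * p$shell_radius_mean * sin(phi)
              if (all((cxs - nx)^2 + (cys - ny)^2 >=
                      (1.99 * p$shell_radius_mean)^2)) {
                cxs <- c(cxs, nx); cys <- c(cys, ny)
                add_particle(nx, ny, ci)
              }
            }
          }
        }
      }
    }
    ## ---- per-channel localizations ---------------------------------------
    area_um2 <- prod(p$field_size) / 1e6
    n_bg <- if (p$background_density > 0)
      stats::rpois(1, p$background_density * area_um2) else 0L
    shell_channel <- function() {
      xs <- numeric(0); ys <- numeric(0)
      for (i in seq_len(nrow(truth))) {
        n_core <- rbinom(1, p$points_per_particle, p$core_fraction)
        n_ring <- p$points_per_particle - n_core
        rp <- .ring_points(n_ring, truth$x_nm[i], truth$y_nm[i],
                           truth$radius_nm[i], p$shell_thickness,
                           p$loc_noise_sd)
        cp <- .disk_points(n_core, truth$x_nm[i], truth$y_nm[i],
                           0.6 * truth$radius_nm[i], p$loc_noise_sd)
        xs <- c(xs, rp$x, cp$x); ys <- c(ys, rp$y, cp$y)
      }
      if (n_bg > 0) {
        xs <- c(xs, runif(n_bg, 0, p$field_size[1]))
        ys <- c(ys, runif(n_bg, 0, p$field_size[2]))
      }
      .loc_table(xs, ys, p$n_frames)
    }
    core_channel <- function(radius_scale = 0.6) {
      xs <- numeric(0); ys <- numeric(0)
      for (i in seq_len(nrow(truth))) {
        cp <- .disk_points(p$points_per_particle, truth$x_nm[i],
                           truth$y_nm[i], radius_scale * truth$radius_nm[i],
                           p$loc_noise_sd)
        xs <- c(xs, cp$x); ys <- c(ys, cp$y)
      }
      if (n_bg > 0) {
        xs <- c(xs, runif(n_bg, 0, p$field_size[1]))
        ys <- c(ys, runif(n_bg, 0, p$field_size[2]))
      }
      .loc_table(xs, ys, p$n_frames)
    }
    srsf5_channel <- function() {
      s <- p$srsf5
      n_np <- stats::rpois(1, max(p$background_density, 20) * area_um2)
      xs <- runif(n_np, 0, p$field_size[1])
      ys <- runif(n_np, 0, p$field_size[2])
      for (i in seq_len(s$n_speckles)) {
        cx <- runif(1, 0, p$field_size[1]); cy <- runif(1, 0, p$field_size[2])
        xs <- c(xs, rnorm(s$points_per_speckle, cx, s$speckle_sigma))
        ys <- c(ys, rnorm(s$points_per_speckle, cy, s$speckle_sigma))
      }
      if (s$decorated_fraction > 0 && nrow(truth) > 0) {
        dec <- runif(nrow(truth)) < s$decorated_fraction
        for (i in which(dec)) {
          n_ring <- max(1, round(s$shell_enrichment * 50))
          rp <- .ring_points(n_ring, truth$x_nm[i], truth$y_nm[i],
                             s$ring_radius, 40, p$loc_noise_sd)
          xs <- c(xs, rp$x); ys <- c(ys, rp$y)
        }
        attr(xs, "decorated") <- dec
      }
      tab <- .loc_table(as.numeric(xs), as.numeric(ys), p$n_frames)
      attr(tab, "decorated") <- attr(xs, "decorated")
      tab
    }
    locs <- lapply(setNames(p$channels, p$channels), function(ch)
      switch(ch,
             five_prime = shell_channel(),
             three_prime = shell_channel(),
             core = core_channel(0.6),
             sphere = core_channel(1),
             srsf5 = srsf5_channel()))
    list(localizations = locs, truth = truth, params = p)
  })
}

#' Construct a mask pair realizing given overlap counts
#'
#' Builds two binary masks such that the reference mask contains exactly
#' `n_total` well-separated square objects of which exactly `n_overlap`
#' share at least one pixel with an object of the second mask. Used to
#' exercise object-overlap counting against known contingency counts.
#'
#' @param n_overlap,n_total counts with `0 <= n_overlap <= n_total`,
#'   `n_total >= 1`.
#' @return list of two 0/1 matrices `mask_a`, `mask_b`.
#' @seealso [count_overlaps()]
#' @export
simulate_overlap_masks <- function(n_overlap, n_total) {
  stopifnot(n_overlap >= 0, n_total >= 1, n_overlap <= n_total)
  side <- ceiling(sqrt(n_total))
  pitch <- 7L
  n_px <- side * pitch + pitch
  a <- matrix(0, n_px, n_px)
  b <- matrix(0, n_px, n_px)
  for (i in seq_len(n_total)) {
    r <- (i - 1) %/% side
    c <- (i - 1) %% side
    x <- 2L + c * pitch
    y <- 2L + r * pitch
    a[x:(x + 1), y:(y + 1)] <- 1
    if (i <= n_overlap)
      b[(x + 1):(x + 2), (y + 1):(y + 2)] <- 1
  }
  list(mask_a = a, mask_b = b)
}

#' Simulate an RNA decay time course
#'
#' Models transcript abundance after transcription shutoff as a plateau
#' followed by first-order decay:
#' `N(t) = n0` for `t <= plateau`, then
#' `N(t) = n0 * exp(-log(2) * (t - plateau) / half_life)`, with
#' multiplicative lognormal noise of coefficient of variation `noise_cv`.
#' `plateau = 0` gives a pure one-phase exponential.
#'
#' @param n0 abundance at `t = 0` (typically 1 for normalized data).
#' @param half_life half-life in minutes, `> 0`.
#' @param plateau delay in minutes before decay starts, `>= 0`.
#' @param timepoints minutes, non-negative.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 = noiseless).
#' @param n_replicates replicates per timepoint.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return data frame `time_min, value, replicate`.
#' @examples
#' simulate_decay_series(1, half_life = 44, plateau = 0,
#'                       timepoints = c(0, 60, 120, 240, 480),
#'                       noise_cv = 0, seed = 1)
#' @export
simulate_decay_series <- function(n0 = 1, half_life, plateau = 0,
                                  timepoints = c(0, 60, 120, 240, 480),
                                  noise_cv = 0.1, n_replicates = 1,
                                  seed = NULL) {
  if (half_life <= 0) stop("half_life must be > 0")
  if (plateau < 0) stop("plateau must be >= 0")
  if (any(timepoints < 0)) stop("timepoints must be non-negative")
  gen <- function() {
    t <- rep(sort(timepoints), times = n_replicates)
    rep_id <- rep(seq_len(n_replicates), each = length(timepoints))
    mu <- ifelse(t <= plateau, n0,
                 n0 * exp(-log(2) * (t - plateau) / half_life))
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      mu <- mu * rlnorm(length(mu), -sdlog^2 / 2, sdlog)
    }
    data.frame(time_min = t, value = mu, replicate = rep_id)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate aligned reads with and without non-templated polyA tails
#'
#' Constructs SAM-style alignment records over a genomic region. `n_pa`
#' reads carry a 3' soft-clipped adenosine run of `tail_len` nt (the
#' signature of a polyadenylated transcript end); `n_plain` reads end
#' flush with the template. Reverse-strand reads carry the tail as a 5'
#' soft-clipped thymidine run, as a reverse-complemented alignment would.
#'
#' @param region list `(chrom, start, end)`, 1-based closed coordinates.
#' @param n_pa,n_plain read counts, `>= 0`.
#' @param tail_len soft-clipped tail length in nt (`> 0` when `n_pa > 0`).
#' @param read_len aligned read length in nt.
#' @param frac_reverse fraction of reads simulated on the reverse strand.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return data frame of SAM fields
#'   (`qname, flag, rname, pos, mapq, cigar, seq`) with an attribute
#'   `truth` marking which rows are polyA-evidence reads.
#' @seealso [write_sam()], [count_pa_reads()]
#' @export
simulate_reads <- function(region, n_pa, n_plain, tail_len = 8,
                           read_len = 50, frac_reverse = 0, seed = NULL) {
  if (n_pa < 0 || n_plain < 0) stop("read counts must be >= 0")
  if (n_pa > 0 && tail_len <= 0)
    stop("tail_len must be > 0 when polyA reads are requested")
  stopifnot(all(c("chrom", "start", "end") %in% names(region)))
  if (region$end - region$start + 1 < read_len)
    stop("region shorter than read_len")
  gen <- function() {
    n <- n_pa + n_plain
    if (n == 0)
      return(structure(data.frame(qname = character(0), flag = integer(0),
                                  rname = character(0), pos = integer(0),
                                  mapq = integer(0), cigar = character(0),
                                  seq = character(0)),
                       truth = logical(0)))
    is_pa <- rep(c(TRUE, FALSE), c(n_pa, n_plain))
    rev <- runif(n) < frac_reverse
    ## aligned segment start so the whole alignment fits in the region
    pos <- sample(seq(region$start, region$end - read_len + 1), n,
                  replace = TRUE)
    bases <- c("A", "C", "G", "T")
    rows <- lapply(seq_len(n), function(i) {
      body <- paste(sample(bases, read_len, replace = TRUE,
                           prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
      if (is_pa[i]) {
        if (rev[i]) {
          cigar <- sprintf("%dS%dM", tail_len, read_len)
          seqs <- paste0(strrep("T", tail_len), body)
        } else {
          cigar <- sprintf("%dM%dS", read_len, tail_len)
          seqs <- paste0(body, strrep("A", tail_len))
        }
      } else {
        cigar <- sprintf("%dM", read_len)
        seqs <- body
      }
      data.frame(qname = sprintf("read_%04d", i),
                 flag = if (rev[i]) 16L else 0L,
                 rname = region$chrom, pos = pos[i], mapq = 60L,
                 cigar = cigar, seq = seqs)
    })
    structure(do.call(rbind, rows), truth = is_pa)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a table of local splicing variations with known labels
#'
#' Builds a MAJIQ-style LSV table in which each row's junction deltaPSI
#' values (percent) and change probability are drawn so that the row is,
#' by construction, `regulated` (max |deltaPSI| > 5 and probability >
#' 0.5), `non_regulated` (max |deltaPSI| < 2 and probability exactly 0) or
#' `ambiguous` (neither rule). Junction deltaPSIs within an LSV sum to
#' zero (closure).
#'
#' @param n_regulated,n_nonregulated,n_ambiguous row counts, `>= 0`.
#' @param n_junctions junctions per LSV (>= 2).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return data frame with columns `gene_id, lsv_id, orientation,
#'   dpsi` (list column, percent), `probability` and `truth`.
#' @export
simulate_lsv_table <- function(n_regulated = 0, n_nonregulated = 0,
                               n_ambiguous = 0, n_junctions = 2,
                               seed = NULL) {
  if (min(n_regulated, n_nonregulated, n_ambiguous) < 0)
    stop("counts must be >= 0")
  if (n_junctions < 2) stop("n_junctions must be >= 2")
  gen <- function() {
    mk_dpsi <- function(lead) {
      ## lead junction carries +lead, the rest share -lead (closure)
      rest <- -lead * diff(c(0, sort(runif(n_junctions - 2)), 1))
      c(lead, rest)
    }
    one <- function(i, kind) {
      if (kind == "regulated") {
        lead <- runif(1, 5.5, 40) * sample(c(-1, 1), 1)
        prob <- runif(1, 0.55, 1)
      } else if (kind == "non_regulated") {
        lead <- runif(1, 0, 1.8) * sample(c(-1, 1), 1)
        prob <- 0
      } else {
        ## sits in the gap: strong dPSI but weak probability, or the
        ## 2-5% deltaPSI band
        if (runif(1) < 0.5) {
          lead <- runif(1, 5.5, 40) * sample(c(-1, 1), 1)
          prob <- runif(1, 0, 0.45)
        } else {
          lead <- runif(1, 2.2, 4.8) * sample(c(-1, 1), 1)
          prob <- runif(1, 0.1, 1)
        }
      }
      data.frame(gene_id = sprintf("gene_%s_%03d", kind, i),
                 lsv_id = sprintf("lsv_%s_%03d", kind, i),
                 orientation = sample(c("source", "target"), 1),
                 dpsi = I(list(mk_dpsi(lead))),
                 probability = prob, truth = kind)
    }
    rows <- c(lapply(seq_len(n_regulated), one, kind = "regulated"),
              lapply(seq_len(n_nonregulated), one, kind = "non_regulated"),
              lapply(seq_len(n_ambiguous), one, kind = "ambiguous"))
    if (!length(rows))
      return(data.frame(gene_id = character(0), lsv_id = character(0),
                        orientation = character(0), dpsi = I(list()),
                        probability = numeric(0), truth = character(0)))
    do.call(rbind, rows)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
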