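#' Synthetic en-face OCT-A phantom specification
#'
#' Describes a synthetic angiogram: a dark contiguous avascular region
#' (optic-nerve head analogue) of configurable shape, a bright curvilinear
#' vessel network grown as seeded biased random walks with branching, per-
#' region Gaussian intensity models on the 8-bit scale, multiplicative
#' speckle, and a global brightness/contrast "device profile". Defaults
#' emulate a 3 x 3 mm optic-nerve scan on a 304 x 304 grid with whole-image
#' mean gray near 100.
#'
#' @param size_px image side length in pixels.
#' @param field_of_view_mm lateral field of view (isotropic pixels).
#' @param avascular_shape `"disc"`, `"ellipse"` or `"irregular"`.
#' @param avascular_radius_um nominal radius of the avascular region.
#' @param ellipse_ratio minor/major axis ratio for the ellipse shape.
#' @param irregularity relative amplitude of the low-frequency radial
#'   perturbation for the irregular shape.
#' @param n_vessels number of vessel seeds.
#' @param branch_prob per-step branching probability.
#' @param vessel_diameter_range_um vessel diameter range, micrometres.
#' @param vessel_mean,vessel_sd,background_mean,background_sd,avascular_mean,avascular_sd
#'   per-region intensity model (8-bit gray levels).
#' @param speckle_sd standard deviation of the multiplicative speckle factor.
#' @param brightness,contrast global device profile applied last.
#' @param seed master seed; the phantom is a deterministic function of the
#'   spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size_px = 304L, field_of_view_mm = 3,
                         avascular_shape = c("disc", "ellipse", "irregular"),
                         avascular_radius_um = 600, ellipse_ratio = 0.65,
                         irregularity = 0.25, n_vessels = 14L,
                         branch_prob = 0.04,
                         vessel_diameter_range_um = c(12, 80),
                         vessel_mean = 180, vessel_sd = 20,
                         background_mean = 90, background_sd = 15,
                         avascular_mean = 25, avascular_sd = 8,
                         speckle_sd = 0.10, brightness = 1, contrast = 1,
                         seed = 1L) {
  avascular_shape <- match.arg(avascular_shape)
  if (!(vessel_mean > background_mean && background_mean > avascular_mean))
    stop("intensity model must satisfy vessel mean > background mean > avascular mean")
  pixel_size_um <- 1000 * field_of_view_mm / size_px
  if (avascular_radius_um / pixel_size_um >= size_px / 2)
    stop("avascular region larger than image")
  structure(as.list(environment()), class = "phantom_spec")
}

# splitmix-style derived stream, always < 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 104729) %% 2147483647)
}

#' Generate a synthetic phantom with ground truth
#'
#' @param spec a [phantom_spec].
#' @return list with `image` (an [octa_image]) and `truth` (class
#'   `phantom_truth`: vessel mask, avascular mask, true per-region means and
#'   the generating spec).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec)
  img <- render_phantom(spec, geo, noise_seed = derive_seed(spec$seed, 5),
                        brightness_factor = 1)
  list(image = img, truth = geo)
}

# deterministic geometry: avascular region + vessel network masks
phantom_geometry <- function(spec) {
  n <- spec$size_px
  px_um <- spec$pixel_size_um
  av <- with_seed(derive_seed(spec$seed, 1), avascular_region_mask(spec))
  vessels <- matrix(FALSE, n, n)
  dmin_px <- spec$vessel_diameter_range_um[1] / px_um
  for (v in seq_len(spec$n_vessels)) {
    vessels <- vessels | with_seed(derive_seed(spec$seed, 100 + v),
                                   grow_vessel(spec, dmin_px))
  }
  vessels[av] <- FALSE  # avascular region carries no flow signal
  structure(list(vessel_mask = vessels, avascular_mask = av,
                 true_means = c(vessel = spec$vessel_mean,
                                background = spec$background_mean,
                                avascular = spec$avascular_mean),
                 spec = spec),
            class = "phantom_truth")
}

avascular_region_mask <- function(spec) {
  n <- spec$size_px
  r_px <- spec$avascular_radius_um / spec$pixel_size_um
  ctr <- n / 2 + stats::runif(2, -0.05, 0.05) * n
  xs <- matrix(rep(seq_len(n), each = n), n) - ctr[1]   # columns
  ys <- matrix(rep(seq_len(n), times = n), n) - ctr[2]  # rows
  switch(spec$avascular_shape,
    disc = xs^2 + ys^2 <= r_px^2,
    ellipse = {
      th <- stats::runif(1, 0, pi)
      u <- xs * cos(th) + ys * sin(th)
      v <- -xs * sin(th) + ys * cos(th)
      (u / r_px)^2 + (v / (r_px * spec$ellipse_ratio))^2 <= 1
    },
    irregular = {
      nh <- 5L
      amp <- stats::rnorm(nh, 0, spec$irregularity / sqrt(nh))
      phase <- stats::runif(nh, 0, 2 * pi)
      ang <- atan2(ys, xs)
      rb <- r_px * (1 + Reduce(`+`, lapply(seq_len(nh), function(k)
        amp[k] * cos(k * ang + phase[k]))))
      xs^2 + ys^2 <= pmax(rb, 0.3 * r_px)^2
    })
}

# one vessel tree as a biased random walk with branching, rasterised as
# discs of the local diameter
grow_vessel <- function(spec, dmin_px) {
  n <- spec$size_px
  px_um <- spec$pixel_size_um
  mask <- matrix(FALSE, n, n)
  dr <- spec$vessel_diameter_range_um
  d0_um <- exp(stats::runif(1, log(dr[1] * 1.5), log(dr[2])))
  # start on a random border point heading inward
  side <- sample.int(4, 1)
  pos <- switch(side,
                c(1, stats::runif(1, 1, n)), c(n, stats::runif(1, 1, n)),
                c(stats::runif(1, 1, n), 1), c(stats::runif(1, 1, n), n))
  theta <- atan2(n / 2 - pos[2], n / 2 - pos[1]) + stats::rnorm(1, 0, 0.4)
  todo <- list(list(pos = pos, theta = theta, d_um = d0_um))
  step <- 2
  total_steps <- 0L
  while (length(todo) > 0 && total_steps < 4000L) {
    cur <- todo[[1]]; todo <- todo[-1]
    pos <- cur$pos; theta <- cur$theta; d_um <- cur$d_um
    for (s in seq_len(600L)) {
      total_steps <- total_steps + 1L
      rad <- max(d_um / px_um / 2, 0.5)
      mask <- stamp_disc(mask, pos[1], pos[2], rad)
      theta <- theta + stats::rnorm(1, 0, 0.25)
      pos <- pos + step * c(cos(theta), sin(theta))
      d_um <- d_um * 0.999
      if (pos[1] < 1 || pos[1] > n || pos[2] < 1 || pos[2] > n) break
      if (d_um < dr[1]) break
      if (stats::runif(1) < spec$branch_prob && d_um > 2 * dr[1]) {
        sgn <- if (stats::runif(1) < 0.5) 1 else -1
        todo[[length(todo) + 1L]] <-
          list(pos = pos, theta = theta + sgn * stats::runif(1, 0.4, 0.9),
               d_um = d_um * 0.7)
        d_um <- d_um * 0.85
      }
    }
  }
  mask
}

stamp_disc <- function(mask, x, y, r) {
  n <- nrow(mask)
  i0 <- max(1L, floor(y - r)); i1 <- min(n, ceiling(y + r))
  j0 <- max(1L, floor(x - r)); j1 <- min(n, ceiling(x + r))
  if (i0 > i1 || j0 > j1) return(mask)
  ii <- i0:i1; jj <- j0:j1
  sub <- outer((ii - y)^2, (jj - x)^2, `+`) <= r^2
  mask[ii, jj] <- mask[ii, jj] | sub
  mask
}

# per-region intensities + multiplicative speckle + device profile
render_phantom <- function(spec, geo, noise_seed, brightness_factor) {
  n <- spec$size_px
  img <- with_seed(noise_seed, {
    img <- matrix(stats::rnorm(n * n, spec$background_mean,
                               spec$background_sd), n, n)
    n_av <- sum(geo$avascular_mask)
    n_ve <- sum(geo$vessel_mask)
    if (n_av > 0)
      img[geo$avascular_mask] <- stats::rnorm(n_av, spec$avascular_mean,
                                              spec$avascular_sd)
    if (n_ve > 0)
      img[geo$vessel_mask] <- stats::rnorm(n_ve, spec$vessel_mean,
                                           spec$vessel_sd)
    if (spec$speckle_sd > 0)
      img <- img * (1 + matrix(stats::rnorm(n * n, 0, spec$speckle_sd), n, n))
    img
  })
  img <- (img - 127.5) * spec$contrast + 127.5
  img <- img * spec$brightness * brightness_factor
  img <- pmin(pmax(img, 0), 255)
  octa_image(img, pixel_size_um = spec$pixel_size_um, layer = "other",
             device_label = "phantom")
}

#' Simulate a repeat-acquisition series of the same phantom eye
#'
#' The geometry (vessels and avascular region) is fixed by the spec's seed —
#' the same eye — while each repeat gets fresh speckle/intensity noise and a
#' multiplicative brightness factor drawn from
#' `Normal(1, brightness_jitter_pct / 100)`, emulating acquisition-to-
#' acquisition device fluctuation.
#'
#' @param spec a [phantom_spec].
#' @param n number of repeats, `>= 2`.
#' @param brightness_jitter_pct standard deviation of the brightness factor,
#'   in percent.
#' @param seeds one integer seed per repeat (`length(seeds) == n`).
#' @return list of `n` [octa_image]s; the shared geometry is attached as
#'   attribute `"truth"`.
#' @export
simulate_repeat_series <- function(spec, n, brightness_jitter_pct, seeds) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n < 2) stop("need n >= 2 repeats")
  if (length(seeds) != n)
    stop("need exactly one seed per repeat (", n, " != ", length(seeds), ")")
  geo <- phantom_geometry(spec)
  imgs <- lapply(seq_len(n), function(i) {
    b <- with_seed(derive_seed(seeds[i], 7),
                   stats::rnorm(1, 1, brightness_jitter_pct / 100))
    img <- render_phantom(spec, geo, noise_seed = derive_seed(seeds[i], 9),
                          brightness_factor = max(b, 0))
    img$acquisition_index <- i
    img
  })
  attr(imgs, "truth") <- geo
  imgs
}

#' Sample scribble annotations from phantom ground truth
#'
#' Emulates an annotator's sparse scribbles: avascular-class pixels are drawn
#' from the interior of the true avascular region (at least `margin_px` from
#' its boundary), vascular-class pixels half from the vessel network and half
#' from the inter-vessel background, both away from the avascular region.
#' Different seeds place the scribbles at different locations within the same
#' true regions.
#'
#' @param truth a `phantom_truth` from [generate_phantom()].
#' @param n_avascular,n_vascular pixels to draw per class.
#' @param margin_px standoff from the avascular boundary.
#' @param seed sampling seed.
#' @return An [annotation_set].
#' @export
phantom_scribbles <- function(truth, n_avascular = 300L, n_vascular = 600L,
                              margin_px = 4, seed = 1L) {
  stopifnot(inherits(truth, "phantom_truth"))
  av <- truth$avascular_mask
  interior <- .edt_squared(!av) > margin_px^2
  outside <- .edt_squared(av) > margin_px^2
  vess <- truth$vessel_mask & outside
  bg <- !truth$vessel_mask & outside
  lab <- with_seed(derive_seed(seed, 3), {
    lab <- matrix(0, nrow(av), ncol(av))
    lab[sample(which(interior), min(n_avascular, sum(interior)))] <- 1
    lab[sample(which(vess), min(ceiling(n_vascular / 2), sum(vess)))] <- 2
    lab[sample(which(bg), min(floor(n_vascular / 2), sum(bg)))] <- 2
    lab
  })
  annotation_set(lab, annotation_id = sprintf("phantom_scribbles_seed%d", seed))
}
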