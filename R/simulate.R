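# Synthetic synapse / movie generator.
#
# Every downstream stage is testable against this module's known ground
# truth.  Geometry model: each synapse has a 3D center and a transsynaptic
# axis u (unit vector).  Population A sits at center - u*d/2, population B
# at center + u*d/2, so their center-of-mass separation along u is exactly
# `separation_nm`.  Axes are drawn uniformly on the upper hemisphere
# (z >= 0, z being the optical axis) unless a fixed axis is supplied.

#' Population shape specifications
#'
#' A population shape describes the support from which label positions are
#' drawn, expressed in the synapse's local frame: `thickness` extends along
#' the transsynaptic axis, the remaining dimensions span the cleft plane.
#'
#' Defaults used by [synapse_config()] mimic scaffold-type markers as flat
#' bars (300 x 300 nm plane, 40-60 nm thick) and vesicle-associated
#' populations as an isotropic Gaussian cloud (sd 120 nm).
#'
#' @param length,width,thickness bar extents in nm (uniform box).
#' @param radius disc radius in nm (uniform disc x uniform thickness).
#' @param sd isotropic Gaussian standard deviation in nm.
#' @return A `synapse_shape` object.
#' @export
shape_bar <- function(length = 300, width = 300, thickness = 40) {
  stopifnot(length > 0, width > 0, thickness > 0)
  structure(list(type = "bar", length = length, width = width,
                 thickness = thickness), class = "synapse_shape")
}

#' @rdname shape_bar
#' @export
shape_disc <- function(radius = 150, thickness = 40) {
  stopifnot(radius > 0, thickness > 0)
  structure(list(type = "disc", radius = radius, thickness = thickness),
            class = "synapse_shape")
}

#' @rdname shape_bar
#' @export
shape_cloud <- function(sd = 120) {
  stopifnot(sd >= 0)  # sd 0 = idealized point population (tests/oracles)
  structure(list(type = "cloud", sd = sd), class = "synapse_shape")
}

shape_max_dim <- function(shape) {
  switch(shape$type,
    bar = max(shape$length, shape$width, shape$thickness),
    disc = max(2 * shape$radius, shape$thickness),
    cloud = 4 * shape$sd,
    stop("unknown shape type: ", shape$type))
}

#' Camera / acquisition model
#'
#' Defaults follow a typical dSTORM acquisition: EMCCD with an effective
#' pixel size of 132 nm, 30000 frames per channel at 46 Hz.
#'
#' @param pixel_size_nm effective camera pixel size (nm).
#' @param frame_rate_hz acquisition frequency (Hz); metadata only.
#' @param n_frames_per_channel frames acquired per color channel.
#' @param em_gain electron-multiplying gain (kept at 1: counts are photons).
#' @param read_noise_e Gaussian read noise, electrons rms per pixel.
#' @param background_rate mean background photons per pixel per frame.
#' @param psf_sd_nm Gaussian PSF standard deviation (nm).
#' @param fov_px field of view, pixels per side (square sensor region).
#' @return A `camera_model` object.
#' @export
camera_model <- function(pixel_size_nm = 132, frame_rate_hz = 46,
                         n_frames_per_channel = 30000, em_gain = 1,
                         read_noise_e = 0, background_rate = 2,
                         psf_sd_nm = 150, fov_px = 64) {
  stopifnot(pixel_size_nm > 0, n_frames_per_channel >= 1, psf_sd_nm > 0,
            background_rate >= 0, fov_px >= 8)
  structure(list(pixel_size_nm = pixel_size_nm, frame_rate_hz = frame_rate_hz,
                 n_frames_per_channel = as.integer(n_frames_per_channel),
                 em_gain = em_gain, read_noise_e = read_noise_e,
                 background_rate = background_rate, psf_sd_nm = psf_sd_nm,
                 fov_px = as.integer(fov_px)),
            class = "camera_model")
}

#' Drift program
#'
#' Deterministic xy drift applied during movie rendering, either a linear
#' slope (nm per frame) or a piecewise-linear table of knots.  Drift at
#' frame 1 is always (0, 0).
#'
#' @param slope_nm_per_frame length-2 numeric, xy slope in nm/frame.
#' @param knots optional data.frame(frame, dx_nm, dy_nm) overriding the
#'   linear form; interpolated linearly between knots.
#' @return A `drift_program` object with a `$shift(frames)` accessor
#'   returning an n x 2 matrix of shifts in nm.
#' @export
drift_program <- function(slope_nm_per_frame = c(0, 0), knots = NULL) {
  if (is.null(knots)) {
    stopifnot(length(slope_nm_per_frame) == 2)
    slope <- as.numeric(slope_nm_per_frame)
    shift <- function(frames) {
      cbind(dx_nm = slope[1] * (frames - 1), dy_nm = slope[2] * (frames - 1))
    }
  } else {
    stopifnot(all(c("frame", "dx_nm", "dy_nm") %in% names(knots)))
    if (knots$dx_nm[1] != 0 || knots$dy_nm[1] != 0 || knots$frame[1] != 1)
      stop("drift knots must start at frame 1 with shift (0,0)")
    shift <- function(frames) {
      cbind(dx_nm = lin_interp_extrap(knots$frame, knots$dx_nm, frames),
            dy_nm = lin_interp_extrap(knots$frame, knots$dy_nm, frames))
    }
  }
  structure(list(shift = shift), class = "drift_program")
}

#' Blinking emitter set
#'
#' Positions plus a two-state (on/off) Markov photoswitching model with
#' optional irreversible bleaching, used by [render_movie()].
#'
#' @param positions_nm n x 2 matrix of emitter xy positions (nm).
#' @param photon_rate photons emitted per frame while ON.
#' @param k_on,k_off per-frame OFF->ON and ON->OFF transition probabilities.
#' @param bleach_prob per-frame irreversible bleaching probability while ON.
#' @return An `emitter_set` object.
#' @export
emitter_set <- function(positions_nm, photon_rate = 2000,
                        k_on = 0.002, k_off = 0.5, bleach_prob = 0) {
  positions_nm <- as.matrix(positions_nm)
  stopifnot(ncol(positions_nm) == 2, photon_rate > 0,
            k_on >= 0, k_on <= 1, k_off >= 0, k_off <= 1,
            bleach_prob >= 0, bleach_prob <= 1)
  structure(list(positions_nm = positions_nm, photon_rate = photon_rate,
                 k_on = k_on, k_off = k_off, bleach_prob = bleach_prob),
            class = "emitter_set")
}

#' Ground-truth synapse configuration
#'
#' @param separation_nm true center-of-mass offset between population A and
#'   B along the transsynaptic axis (nm).
#' @param axis optional fixed 3D axis (will be normalized); `NULL` draws
#'   axes uniformly on the upper hemisphere per synapse.
#' @param shape_a,shape_b population shapes (see [shape_bar()]).
#' @param n_labels_a,n_labels_b label (antibody) counts per population.
#' @param linkage_sd_nm isotropic Gaussian antibody-linkage displacement (nm).
#' @param field_size_nm square field edge length for synapse placement (nm).
#' @return A `synapse_config` list.
#' @export
synapse_config <- function(separation_nm = 100, axis = NULL,
                           shape_a = shape_bar(300, 300, 40),
                           shape_b = shape_bar(300, 300, 60),
                           n_labels_a = 40, n_labels_b = 40,
                           linkage_sd_nm = 10, field_size_nm = 20000) {
  stopifnot(separation_nm >= 0, n_labels_a >= 1, n_labels_b >= 1,
            linkage_sd_nm >= 0, field_size_nm > 0)
  if (!is.null(axis)) axis <- unitize(as.numeric(axis))
  structure(list(separation_nm = separation_nm, axis = axis,
                 shape_a = shape_a, shape_b = shape_b,
                 n_labels_a = as.integer(n_labels_a),
                 n_labels_b = as.integer(n_labels_b),
                 linkage_sd_nm = linkage_sd_nm,
                 field_size_nm = field_size_nm),
            class = "synapse_config")
}

new_synapse_truth <- function(id, center, axis, config) {
  stopifnot(abs(vec_norm(axis) - 1) < 1e-9)
  structure(list(id = id, center = center, axis = axis,
                 separation_nm = config$separation_nm,
                 shape_a = config$shape_a, shape_b = config$shape_b,
                 n_labels_a = config$n_labels_a,
                 n_labels_b = config$n_labels_b,
                 linkage_sd_nm = config$linkage_sd_nm),
            class = "synapse_truth")
}

#' Per-population true 3D centers of mass
#' @param truth a `synapse_truth`.
#' @return list with 3-vectors `a` and `b`.
#' @export
true_population_centers <- function(truth) {
  half <- truth$axis * truth$separation_nm / 2
  list(a = truth$center - half, b = truth$center + half)
}

#' True separation as seen after projecting onto the image plane
#'
#' Dropping the optical-axis (z) coordinate turns a 3D separation d along
#' axis u into an apparent 2D separation d * sqrt(ux^2 + uy^2) = d sin(theta).
#' @param truth a `synapse_truth`.
#' @return projected separation in nm.
#' @export
true_projected_separation <- function(truth) {
  truth$separation_nm * sqrt(sum(truth$axis[1:2]^2))
}

#' Generate a field of ground-truth synapses
#'
#' Centers are placed on a jittered square grid in the focal (z = 0) plane
#' with minimum spacing at least 4x the largest population shape dimension;
#' axes are uniform on the upper hemisphere unless `config$axis` is fixed.
#'
#' @param config a [synapse_config()].
#' @param n_synapses number of synapses.
#' @param rng_seed mandatory integer seed.
#' @return list of `synapse_truth` objects.
#' @export
make_synapse_population <- function(config, n_synapses, rng_seed) {
  stopifnot(inherits(config, "synapse_config"), n_synapses >= 1)
  set.seed(rng_seed)
  maxdim <- max(shape_max_dim(config$shape_a), shape_max_dim(config$shape_b),
                config$separation_nm)
  k <- ceiling(sqrt(n_synapses))
  spacing <- config$field_size_nm / k
  min_spacing <- 4 * maxdim
  if (spacing < min_spacing)
    stop(sprintf(paste0("synapse spacing infeasible: %d synapses need a field ",
                        "of at least %.0f nm (got %.0f nm)"),
                 n_synapses, k * min_spacing, config$field_size_nm))
  jitter_amp <- min(spacing / 8, (spacing - min_spacing) / 2)
  jitter_amp <- max(jitter_amp, 0)
  idx <- seq_len(n_synapses) - 1L
  gx <- (idx %% k) + 0.5
  gy <- (idx %/% k) + 0.5
  cx <- gx * spacing + runif(n_synapses, -jitter_amp, jitter_amp)
  cy <- gy * spacing + runif(n_synapses, -jitter_amp, jitter_amp)

  axes <- if (is.null(config$axis)) {
    # uniform on the upper hemisphere: normalize a 3D Gaussian, fold z >= 0
    m <- matrix(rnorm(3 * n_synapses), ncol = 3)
    m <- m / sqrt(rowSums(m^2))
    m[, 3] <- abs(m[, 3])
    m
  } else {
    matrix(config$axis, nrow = n_synapses, ncol = 3, byrow = TRUE)
  }

  lapply(seq_len(n_synapses), function(i) {
    new_synapse_truth(i, c(cx[i], cy[i], 0), axes[i, ], config)
  })
}

sample_in_shape <- function(shape, n) {
  # local coordinates: columns (in-plane 1, in-plane 2, along-axis)
  switch(shape$type,
    bar = cbind(runif(n, -shape$length / 2, shape$length / 2),
                runif(n, -shape$width / 2, shape$width / 2),
                runif(n, -shape$thickness / 2, shape$thickness / 2)),
    disc = {
      r <- shape$radius * sqrt(runif(n))
      phi <- runif(n, 0, 2 * pi)
      cbind(r * cos(phi), r * sin(phi),
            runif(n, -shape$thickness / 2, shape$thickness / 2))
    },
    cloud = matrix(rnorm(3 * n, sd = shape$sd), ncol = 3),
    stop("unknown shape type"))
}

#' Sample immunolabel positions for one synapse
#'
#' Draws `n_labels` positions inside each population's shape (in the
#' synapse local frame), maps them to lab coordinates, and displaces each
#' by an isotropic Gaussian of sd `linkage_sd_nm` (antibody linkage error).
#'
#' @param truth a `synapse_truth`.
#' @param rng_seed integer seed.
#' @return list of two n x 3 matrices `a` and `b` (lab-frame nm).
#' @export
sample_labels <- function(truth, rng_seed) {
  stopifnot(inherits(truth, "synapse_truth"))
  set.seed(rng_seed)
  basis <- axis_basis(truth$axis)
  ctr <- true_population_centers(truth)
  one <- function(shape, n, center) {
    loc <- sample_in_shape(shape, n)
    lab <- loc[, 1, drop = FALSE] %*% t(basis$e1) +
           loc[, 2, drop = FALSE] %*% t(basis$e2) +
           loc[, 3, drop = FALSE] %*% t(basis$u)
    lab <- sweep(lab, 2, center, "+")
    if (truth$linkage_sd_nm > 0)
      lab <- lab + matrix(rnorm(3 * n, sd = truth$linkage_sd_nm), ncol = 3)
    colnames(lab) <- c("x_nm", "y_nm", "z_nm")
    lab
  }
  list(a = one(truth$shape_a, truth$n_labels_a, ctr$a),
       b = one(truth$shape_b, truth$n_labels_b, ctr$b))
}

plausible_qc_fields <- function(n) {
  # width / asymmetry values that pass the default QC filter
  list(width_nm = runif(n, 110, 200), asymmetry = runif(n, 1, 1.2))
}

#' Fast-path localization table from label positions
#'
#' Bypasses movie rendering: projects 3D label positions to 2D by dropping
#' the optical-axis (z) coordinate, draws a Poisson number of localization
#' records per label, jitters each by the localization precision, and fills
#' intensity (lognormal photon counts), width and asymmetry with plausible
#' in-filter values.  Records carry a `label_id` column tying every record
#' back to its generating label (ground-truth sidecar round-trip).
#'
#' @param labels per-channel list of n x 3 matrices as from [sample_labels()]
#'   (channel 1 = `a`, channel 2 = `b`), or a single matrix (channel 1).
#' @param loc_precision_sd localization precision sd per axis (nm).
#' @param mean_locs_per_label Poisson mean localization count per label.
#' @param n_frames frames to spread records over (uniformly).
#' @param intensity_meanlog,intensity_sdlog lognormal photon-count model.
#' @param count_model `"poisson"` (default) draws Poisson(mean) records per
#'   label; `"fixed"` emits exactly `mean_locs_per_label` (deterministic
#'   bookkeeping for oracle tests).
#' @param rng_seed integer seed.
#' @return a localization `data.frame` with columns
#'   `frame, x_nm, y_nm, intensity, width_nm, asymmetry, channel, label_id`.
#' @export
emit_localization_table <- function(labels, loc_precision_sd = 10,
                                    mean_locs_per_label = 20,
                                    n_frames = 30000,
                                    intensity_meanlog = 6,
                                    intensity_sdlog = 0.5,
                                    count_model = c("poisson", "fixed"),
                                    rng_seed = 1) {
  stopifnot(loc_precision_sd >= 0, mean_locs_per_label > 0)
  count_model <- match.arg(count_model)
  if (is.matrix(labels)) labels <- list(labels)
  set.seed(rng_seed)
  out <- vector("list", length(labels))
  label_offset <- 0L
  for (ch in seq_along(labels)) {
    pos <- as.matrix(labels[[ch]])
    n_lab <- nrow(pos)
    counts <- if (count_model == "poisson") rpois(n_lab, mean_locs_per_label)
              else rep.int(as.integer(mean_locs_per_label), n_lab)
    idx <- rep.int(seq_len(n_lab), counts)
    n <- length(idx)
    if (n == 0) {
      out[[ch]] <- empty_loc_table()
      label_offset <- label_offset + n_lab
      next
    }
    x <- pos[idx, 1] + rnorm(n, sd = loc_precision_sd)
    y <- pos[idx, 2] + rnorm(n, sd = loc_precision_sd)
    qc <- plausible_qc_fields(n)
    out[[ch]] <- data.frame(
      frame = sample.int(n_frames, n, replace = TRUE),
      x_nm = x, y_nm = y,
      intensity = rlnorm(n, intensity_meanlog, intensity_sdlog),
      width_nm = qc$width_nm, asymmetry = qc$asymmetry,
      channel = ch, label_id = label_offset + idx)
    label_offset <- label_offset + n_lab
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$frame), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

empty_loc_table <- function() {
  data.frame(frame = integer(), x_nm = numeric(), y_nm = numeric(),
             intensity = numeric(), width_nm = numeric(),
             asymmetry = numeric(), channel = integer(),
             label_id = integer())
}

# integrated 2D Gaussian PSF: add `photons` at (x_nm, y_nm) into frame
# `img` (matrix rows = y pixels, 0-based pixel i spans [i, i+1) px units)
add_psf <- function(img, x_nm, y_nm, photons, pixel_size, psf_sd) {
  ny <- nrow(img); nx <- ncol(img)
  xpx <- x_nm / pixel_size; ypx <- y_nm / pixel_size
  spx <- psf_sd / pixel_size
  r <- ceiling(6 * spx)
  ix <- floor(xpx); iy <- floor(ypx)
  xs <- max(0, ix - r):min(nx - 1, ix + r)
  ys <- max(0, iy - r):min(ny - 1, iy + r)
  if (length(xs) == 0 || length(ys) == 0) return(img)
  fx <- pnorm((xs + 1 - xpx) / spx) - pnorm((xs - xpx) / spx)
  fy <- pnorm((ys + 1 - ypx) / spx) - pnorm((ys - ypx) / spx)
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + photons * outer(fy, fx)
  img
}

#' Render a blinking-emitter movie
#'
#' Forward model of a dSTORM acquisition for one channel: each emitter
#' follows an on/off Markov chain (with optional bleaching); active emitters
#' are rendered as integrated 2D Gaussians (sd = `camera$psf_sd_nm`) at
#' their drifted positions; fiducial beads are rendered in every frame;
#' Poisson photon noise is applied to signal + uniform background, plus
#' optional Gaussian read noise.
#'
#' @param emitters an [emitter_set()] (positions in nm).
#' @param camera a [camera_model()]; `fov_px` and `n_frames_per_channel`
#'   set the stack dimensions.
#' @param drift a [drift_program()] (default: none).
#' @param beads optional m x 2 matrix of bead positions (nm); beads emit
#'   `bead_photons` every frame and drift with the sample.
#' @param bead_photons photons per bead per frame.
#' @param noise logical; `FALSE` renders the noiseless expectation.
#' @param rng_seed integer seed.
#' @return list with `stack` (ny x nx x nt array, photons) and `sidecar`
#'   data.frame (frame, emitter, x_nm, y_nm drifted true positions of
#'   active emitters).
#' @export
render_movie <- function(emitters, camera, drift = drift_program(),
                         beads = NULL, bead_photons = 5000,
                         noise = TRUE, rng_seed = 1) {
  stopifnot(inherits(emitters, "emitter_set"), inherits(camera, "camera_model"))
  set.seed(rng_seed)
  px <- camera$pixel_size_nm
  n_px <- camera$fov_px
  fov_nm <- n_px * px
  pos <- emitters$positions_nm
  margin <- 3 * camera$psf_sd_nm
  if (any(pos[, 1] < margin | pos[, 1] > fov_nm - margin |
          pos[, 2] < margin | pos[, 2] > fov_nm - margin))
    stop("emitter outside field of view (need >= 3 psf_sd from the border)")
  nt <- camera$n_frames_per_channel
  ne <- nrow(pos)
  shifts <- drift$shift(seq_len(nt))

  # on/off Markov chain, vectorized over emitters frame by frame
  state <- rbinom(ne, 1, emitters$k_on / max(emitters$k_on + emitters$k_off, 1e-12))
  bleached <- rep(FALSE, ne)
  stack <- array(0, dim = c(n_px, n_px, nt))
  side <- vector("list", nt)
  for (t in seq_len(nt)) {
    turn_on <- state == 0 & !bleached & runif(ne) < emitters$k_on
    turn_off <- state == 1 & runif(ne) < emitters$k_off
    state[turn_on] <- 1L
    state[turn_off] <- 0L
    if (emitters$bleach_prob > 0) {
      zap <- state == 1 & runif(ne) < emitters$bleach_prob
      state[zap] <- 0L
      bleached[zap] <- TRUE
    }
    img <- matrix(0, n_px, n_px)
    act <- which(state == 1)
    for (i in act) {
      img <- add_psf(img, pos[i, 1] + shifts[t, 1], pos[i, 2] + shifts[t, 2],
                     emitters$photon_rate, px, camera$psf_sd_nm)
    }
    if (!is.null(beads)) {
      for (b in seq_len(nrow(beads))) {
        img <- add_psf(img, beads[b, 1] + shifts[t, 1],
                       beads[b, 2] + shifts[t, 2],
                       bead_photons, px, camera$psf_sd_nm)
      }
    }
    img <- img + camera$background_rate
    if (noise) {
      img <- matrix(rpois(length(img), img), n_px, n_px)
      if (camera$read_noise_e > 0)
        img <- img + matrix(rnorm(length(img), sd = camera$read_noise_e),
                            n_px, n_px)
    }
    stack[, , t] <- img
    if (length(act))
      side[[t]] <- data.frame(frame = t, emitter = act,
                              x_nm = pos[act, 1] + shifts[t, 1],
                              y_nm = pos[act, 2] + shifts[t, 2])
  }
  sidecar <- do.call(rbind, side[!vapply(side, is.null, logical(1))])
  if (is.null(sidecar))
    sidecar <- data.frame(frame = integer(), emitter = integer(),
                          x_nm = numeric(), y_nm = numeric())
  rownames(sidecar) <- NULL
  list(stack = stack, sidecar = sidecar)
}
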