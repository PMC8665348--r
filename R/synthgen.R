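#' Parameters for a synthetic phase-contrast scene
#'
#' The renderer emulates the statistical appearance of phase-contrast cell
#' images: dark elliptical cell bodies surrounded by bright halo rings,
#' darker nuclei, substrate-dependent background texture, and sensor noise.
#' PDMS substrates additionally carry blob artifacts emulating material
#' background noise such as micro air bubbles.
#'
#' @param side image side in px
#' @param n_cells number of cells to place
#' @param cell_radius_range min/max cell radius in px
#' @param halo_amplitude peak halo brightness above background
#' @param nucleus_contrast nucleus darkening below the cell body
#' @param substrate one of "glass", "tcps", "pdms"
#' @param noise_sd Gaussian sensor noise s.d. (intensity units)
#' @param seed integer seed; rendering is bit-reproducible for a fixed seed
#' @return a `scene_params` list
#' @export
scene_params <- function(side = 134L, n_cells = 8L,
                         cell_radius_range = c(8, 16),
                         halo_amplitude = 0.25, nucleus_contrast = 0.12,
                         substrate = c("tcps", "glass", "pdms"),
                         noise_sd = 0.02, seed = 1L) {
  substrate <- match.arg(substrate)
  stopifnot(n_cells >= 0, all(cell_radius_range > 0), noise_sd >= 0)
  structure(list(side = as.integer(side), n_cells = as.integer(n_cells),
                 cell_radius_range = cell_radius_range,
                 halo_amplitude = halo_amplitude,
                 nucleus_contrast = nucleus_contrast, substrate = substrate,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_params")
}

#' Render a focused synthetic cell scene
#'
#' Deterministic for a fixed seed. Cells are placed with rejection sampling
#' to limit overlap; each contributes a soft dark elliptical body, a bright
#' Gaussian halo ring at its rim, and a darker nucleus. Values are clipped
#' to `[0, 1]` and the three channels share the cell structure with small
#' per-channel gain differences, as in real phase-contrast acquisitions.
#'
#' @param params a [scene_params()] list
#' @return side x side x 3 array in `[0, 1]`
#' @export
render_focused_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  side <- params$side
  rmax <- max(params$cell_radius_range)
  if (side < 4 * rmax) stop("scene side too small for the requested cell radii")
  with_seed(params$seed, {
    bg_level <- switch(params$substrate, glass = 0.55, tcps = 0.50, pdms = 0.50)
    xs <- matrix(rep(seq_len(side), each = side), side, side)  # col coord
    ys <- matrix(rep(seq_len(side), times = side), side, side) # row coord
    base <- matrix(bg_level, side, side)
    # low-frequency substrate texture
    tex_amp <- switch(params$substrate, glass = 0.005, tcps = 0.012, pdms = 0.02)
    for (k in 1:3) {
      fx <- stats::runif(1, 0.5, 2) * 2 * pi / side
      fy <- stats::runif(1, 0.5, 2) * 2 * pi / side
      ph <- stats::runif(2, 0, 2 * pi)
      base <- base + tex_amp * sin(fx * xs + ph[1]) * cos(fy * ys + ph[2])
    }
    # cell placement with limited overlap
    centers <- matrix(0, 0, 2)
    radii <- numeric(0)
    tries <- 0L
    while (nrow(centers) < params$n_cells && tries < 200L * max(params$n_cells, 1L)) {
      tries <- tries + 1L
      r <- stats::runif(1, params$cell_radius_range[1], params$cell_radius_range[2])
      cx <- stats::runif(1, 1.6 * r, side - 1.6 * r)
      cy <- stats::runif(1, 1.6 * r, side - 1.6 * r)
      if (nrow(centers) > 0) {
        dmin <- min(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) - radii)
        if (dmin < 1.9 * r) next
      }
      centers <- rbind(centers, c(cx, cy))
      radii <- c(radii, r)
    }
    if (nrow(centers) < params$n_cells) {
      warning("placed only ", nrow(centers), " of ", params$n_cells, " cells")
    }
    for (i in seq_len(nrow(centers))) {
      r <- radii[i]
      ecc <- stats::runif(1, 0.6, 1)       # ellipse axis ratio
      th <- stats::runif(1, 0, pi)          # orientation
      dx <- xs - centers[i, 1]
      dy <- ys - centers[i, 2]
      u <- (cos(th) * dx + sin(th) * dy) / r
      v <- (-sin(th) * dx + cos(th) * dy) / (r * ecc)
      rr <- sqrt(u^2 + v^2)
      body <- exp(-rr^4)                    # soft dark cell body
      halo <- exp(-((rr - 1.15) / 0.25)^2)  # bright rim just outside the body
      nuc <- exp(-(rr / 0.35)^2)            # darker nucleus
      base <- base - 0.18 * body + params$halo_amplitude * halo -
        params$nucleus_contrast * nuc
    }
    if (params$substrate == "pdms") {
      n_blob <- stats::rpois(1, 4)
      for (b in seq_len(n_blob)) {
        br <- stats::runif(1, 2, 5)
        bx <- stats::runif(1, br + 1, side - br - 1)
        by <- stats::runif(1, br + 1, side - br - 1)
        rr <- sqrt((xs - bx)^2 + (ys - by)^2) / br
        base <- base + 0.1 * exp(-((rr - 1) / 0.3)^2) - 0.05 * exp(-rr^2)
      }
    }
    gains <- c(0.985, 1, 1.015)  # slight channel imbalance of a color camera
    img <- array(0, dim = c(side, side, 3L))
    for (ch in 1:3) {
      chn <- base * gains[ch]
      if (params$noise_sd > 0) {
        chn <- chn + stats::rnorm(side * side, sd = params$noise_sd)
      }
      img[, , ch] <- chn
    }
    clamp01(img)
  })
}

#' Parameters of the synthetic defocus model
#'
#' Defocus is modeled as a Gaussian point-spread function whose width grows
#' linearly with the axial defocus distance, `sigma_px =
#' sigma_per_um * |distance_um| * (magnification / 100)`, combined with a
#' contrast attenuation `exp(-contrast_decay * |distance_um|)` toward the
#' image mean and optional sensor noise. The doubling of blur per unit
#' distance at 200x reflects that the same axial displacement defocuses a
#' higher-magnification image more strongly.
#'
#' @param distance_um signed defocus distance in micrometers (0 = in focus)
#' @param magnification 100 or 200
#' @param sigma_per_um blur growth rate in px/um at 100x. The default 0.4
#'   follows from the geometric defocus cone of a 0.30-NA 10x objective
#'   sampled at 2.7 px/um: blur radius ~ NA * distance, Gaussian-equivalent
#'   sigma about half of it
#' @param contrast_decay contrast attenuation rate in 1/um; the default
#'   0.04 leaves ~45% of contrast at 20 um, where subcellular structure is
#'   essentially invisible
#' @param noise_sd sensor noise s.d. added after blurring
#' @return a `defocus_params` list
#' @export
defocus_params <- function(distance_um, magnification = 100,
                           sigma_per_um = 0.4, contrast_decay = 0.04,
                           noise_sd = 0) {
  stopifnot(magnification %in% c(100, 200), sigma_per_um > 0,
            contrast_decay >= 0, noise_sd >= 0)
  structure(list(distance_um = distance_um, magnification = magnification,
                 sigma_per_um = sigma_per_um, contrast_decay = contrast_decay,
                 noise_sd = noise_sd),
            class = "defocus_params")
}

gaussian_kernel_1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  k <- exp(-0.5 * ((-radius):radius / sigma)^2)
  k / sum(k)
}

pad_symmetric_edge <- function(img, pad) {
  # half-sample symmetric extension (edge pixel repeated); conserves the
  # image sum under normalized symmetric filtering
  d <- dim(img)
  ext <- function(n) {
    idx <- c(rev(seq_len(pad)), seq_len(n), n + 1 - seq_len(pad))
    pmin(pmax(idx, 1L), n)
  }
  img[ext(d[1]), ext(d[2]), , drop = FALSE]
}

#' Gaussian blur with symmetric boundary
#'
#' Separable Gaussian filtering; the half-sample symmetric boundary
#' extension conserves the image mean exactly.
#' @param img H x W x C array
#' @param sigma blur s.d. in px (0 returns the input)
#' @return blurred array of the same shape
#' @export
gaussian_blur <- function(img, sigma) {
  img <- as_image(img)
  if (sigma <= 0) return(img)
  k <- gaussian_kernel_1d(sigma)
  pad <- (length(k) - 1L) %/% 2L
  xp <- pad_symmetric_edge(img, pad)
  cpp_sepfilter(xp, k, k, 0L)
}

#' Blur magnitude (px) implied by a defocus parameter set
#' @param dp a [defocus_params()] list
#' @export
defocus_sigma <- function(dp) {
  dp$sigma_per_um * abs(dp$distance_um) * (dp$magnification / 100)
}

#' Apply synthetic defocus to a focused image
#'
#' Convolves with the Gaussian defocus PSF, attenuates contrast toward the
#' image mean, and optionally adds sensor noise. Zero distance returns the
#' input unchanged; with noise off, the mean intensity is preserved exactly.
#'
#' @param img focused H x W x C array
#' @param dp a [defocus_params()] list
#' @return defocused array of the same shape
#' @export
apply_defocus <- function(img, dp) {
  stopifnot(inherits(dp, "defocus_params"))
  img <- as_image(img)
  if (dp$distance_um == 0) return(img)
  out <- gaussian_blur(img, defocus_sigma(dp))
  att <- exp(-dp$contrast_decay * abs(dp$distance_um))
  m <- mean(out)
  out <- m + (out - m) * att
  if (dp$noise_sd > 0) {
    out <- clamp01(out + stats::rnorm(length(out), sd = dp$noise_sd))
  }
  out
}

#' Generate a balanced focused/defocused training set for the sorter
#'
#' Produces `n` labeled scenes: exactly n/2 focused and n/2 defocused, with
#' the two magnifications balanced 1:1 inside each class. Each image is
#' acquired the way the sorting workflow sees real data: the scene is
#' rendered, defocused, and noised at native camera pitch
#' (`render_scale` times the delivered side, matching the chip generator's
#' pitch) and then downsampled to `side` by bilinear resize. Defocus
#' distances default to the regime where the delivered-scale Gaussian PSF
#' width is 6 px (15 um at 100x, 7.5 um at 200x), jittered by
#' `jitter_sd_um` to emulate mechanical imprecision, with a random sign.
#'
#' @param n total number of images (even)
#' @param side delivered image side in px
#' @param render_scale native-pitch oversampling factor (default 4, the
#'   536 -> 134 crop-and-resize of the workflow)
#' @param distance_by_mag named vector of nominal defocus distances (um) for
#'   magnifications "100" and "200"
#' @param jitter_sd_um s.d. of the mechanical jitter on distances (um)
#' @param noise_sd sensor noise for both rendering and defocusing
#' @param substrates substrates to cycle through
#' @param seed master seed
#' @param out_dir optional directory: writes PNGs plus `manifest.csv`
#' @return list with `images` (list of H x W x 3 arrays), `labels`
#'   (character), `onehot` (n x 2 matrix, `[1,0]` = focused), and
#'   `manifest` (data.frame: path, label, defocus_um, magnification,
#'   cell_type, substrate)
#' @export
generate_sorting_dataset <- function(n, side = 134L, render_scale = 4L,
                                     distance_by_mag = c("100" = 15, "200" = 7.5),
                                     jitter_sd_um = 1, noise_sd = 0.02,
                                     substrates = c("tcps", "glass", "pdms"),
                                     seed = 1L, out_dir = NULL) {
  stopifnot(n %% 2L == 0L, render_scale >= 1)
  with_seed(seed, {
    half <- n %/% 2L
    labels <- rep(c("focused", "defocused"), each = half)
    mags <- rep(rep(c(100, 200), length.out = half), times = 2L)
    cell_types <- rep_len(c("EC", "EC", "SMC", "3T3"), n)  # 2:1:1 mix
    subs <- rep_len(substrates, n)
    scene_seeds <- sample.int(.Machine$integer.max, n)
    images <- vector("list", n)
    dist_um <- numeric(n)
    native_side <- as.integer(side * render_scale)
    for (i in seq_len(n)) {
      sp <- scene_params(side = native_side,
                         n_cells = max(2L, round(8 * (side / 134)^2)),
                         cell_radius_range = c(8, 16) * render_scale *
                           min(1, side / 134),
                         substrate = subs[i],
                         noise_sd = noise_sd, seed = scene_seeds[i])
      img <- render_focused_scene(sp)
      if (labels[i] == "defocused") {
        d0 <- distance_by_mag[[as.character(mags[i])]]
        d <- (d0 + stats::rnorm(1, sd = jitter_sd_um)) * sample(c(-1, 1), 1)
        dist_um[i] <- d
        # blur applies at native pitch: sigma scales with the oversampling
        img <- apply_defocus(img, defocus_params(
          d, mags[i], sigma_per_um = 0.4 * render_scale,
          noise_sd = noise_sd))
      }
      if (native_side != side) img <- resize_bilinear(img, side)
      images[[i]] <- img
    }
    onehot <- cbind(as.numeric(labels == "focused"),
                    as.numeric(labels == "defocused"))
    manifest <- data.frame(
      path = sprintf("scene_%04d.png", seq_len(n)), label = labels,
      defocus_um = ifelse(labels == "focused", NA_real_, dist_um),
      magnification = mags, cell_type = cell_types, substrate = subs,
      stringsAsFactors = FALSE)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      for (i in seq_len(n)) {
        write_image(images[[i]], file.path(out_dir, manifest$path[i]))
      }
      utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                       row.names = FALSE)
    }
    list(images = images, labels = labels, onehot = onehot, manifest = manifest)
  })
}

#' Generate focused/defocused image pairs for reconstruction training
#'
#' Mirrors the acquisition protocol for the reconstruction task: per scene,
#' one focused image plus one defocused counterpart per signed defocus
#' distance, with mechanical jitter on the realized distances.
#'
#' @param n_scenes number of distinct scenes
#' @param distances signed nominal defocus distances in um
#'   (default +/-10 and +/-20, the 100x protocol)
#' @param magnification 100 or 200
#' @param side scene side in px
#' @param jitter_sd_um s.d. of distance jitter (um)
#' @param noise_sd sensor noise
#' @param seed master seed
#' @return list of pairs; each has `defocused`, `focused`, `distance_um`
#'   (realized), `magnification`
#' @export
generate_reconstruction_dataset <- function(n_scenes,
                                            distances = c(-20, -10, 10, 20),
                                            magnification = 100, side = 388L,
                                            jitter_sd_um = 1, noise_sd = 0.02,
                                            seed = 1L) {
  stopifnot(length(distances) > 0, all(distances != 0))
  with_seed(seed, {
    scene_seeds <- sample.int(.Machine$integer.max, n_scenes)
    pairs <- list()
    for (s in seq_len(n_scenes)) {
      sp <- scene_params(side = side,
                         n_cells = max(4L, round(8 * (side / 134)^2)),
                         noise_sd = noise_sd, seed = scene_seeds[s])
      focused <- render_focused_scene(sp)
      for (d0 in distances) {
        d <- d0 + stats::rnorm(1, sd = jitter_sd_um)
        if (sign(d) != sign(d0)) d <- d0  # jitter never flips the side
        defoc <- apply_defocus(focused,
                               defocus_params(d, magnification,
                                              noise_sd = noise_sd))
        pairs[[length(pairs) + 1L]] <-
          list(defocused = defoc, focused = focused, distance_um = d,
               magnification = magnification)
      }
    }
    pairs
  })
}

#' Generate a synthetic high-throughput chip acquisition
#'
#' Emulates an autofocused microarray scan: `n_images` frames of which
#' `n_defocused` suffered an autofocus failure and are heavily blurred.
#' Chip frames are native-resolution acquisitions, so cells span about four
#' times as many pixels as in the classifier-resolution training scenes;
#' radii and counts are scaled accordingly. `blur_sigma` is expressed in
#' native pixels of the frame; the default 24 corresponds to a 6 px blur
#' after the workflow's 4x central-crop + resize to the classifier
#' resolution.
#'
#' @param n_images total frames (default 120)
#' @param n_defocused number of defocused frames (default 8)
#' @param side frame side in px
#' @param blur_sigma Gaussian PSF sigma (native px) of the defocused frames
#' @param noise_sd sensor noise
#' @param seed master seed
#' @return list with `images`, `labels`, and `manifest`
#' @export
generate_chip_dataset <- function(n_images = 120L, n_defocused = 8L,
                                  side = 600L, blur_sigma = 24,
                                  noise_sd = 0.02, seed = 1L) {
  with_seed(seed, {
    labels <- rep("focused", n_images)
    labels[sample.int(n_images, n_defocused)] <- "defocused"
    scene_seeds <- sample.int(.Machine$integer.max, n_images)
    images <- vector("list", n_images)
    for (i in seq_len(n_images)) {
      sp <- scene_params(side = side, n_cells = max(4L, round(10 * (side / 600)^2)),
                         cell_radius_range = c(8, 16) * side / 150,
                         substrate = "pdms", noise_sd = noise_sd,
                         seed = scene_seeds[i])
      img <- render_focused_scene(sp)
      if (labels[i] == "defocused") {
        img <- gaussian_blur(img, blur_sigma)
        m <- mean(img)
        img <- clamp01(m + (img - m) * 0.8 +
                         stats::rnorm(length(img), sd = noise_sd))
      }
      images[[i]] <- img
    }
    manifest <- data.frame(path = sprintf("spot_%03d.png", seq_len(n_images)),
                           label = labels, stringsAsFactors = FALSE)
    list(images = images, labels = labels, manifest = manifest)
  })
}
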