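#' Texture, shape and motion specifications for synthetic scenes
#'
#' `texture_spec()` describes a band-limited noise texture: a white-noise
#' field bandpassed by a difference of Gaussians (pass band centred near 8 px
#' wavelength with the defaults, inside the Gabor bank's range), scaled to a
#' given amplitude around a mean luminance, and clipped.  `blob_shape()`
#' describes a closed star-shaped region by a base radius and low-order
#' radial harmonics \eqn{r(\phi) = R (1 + \sum_m c_m \cos(m\phi + \psi_m))}.
#'
#' @param mean Mean luminance in `[0, 1]`.
#' @param amplitude Noise standard deviation in luminance units.
#' @param sigma_lo,sigma_hi Difference-of-Gaussian smoothing sds (pixels)
#'   defining the pass band.
#' @param clip Clip the noise at `clip` standard deviations.
#' @param seed Integer seed making the texture reproducible.
#' @return A `texture_spec` / `blob_shape` list.
#' @export
texture_spec <- function(mean, amplitude = 0.022, sigma_lo = 1.2,
                         sigma_hi = 2.5, clip = 2.2, seed = 0L) {
  stopifnot(mean >= 0, mean <= 1, amplitude >= 0, sigma_hi > sigma_lo)
  structure(list(mean = mean, amplitude = amplitude, sigma_lo = sigma_lo,
                 sigma_hi = sigma_hi, clip = clip, seed = as.integer(seed)),
            class = "texture_spec")
}

#' @rdname texture_spec
#' @param base_radius Base radius `R` in pixels.
#' @param harm_amp,harm_phase Amplitudes and phases of radial harmonics
#'   `m = 2, 3, ...` (same length).
#' @export
blob_shape <- function(base_radius, harm_amp = numeric(0),
                       harm_phase = numeric(0)) {
  stopifnot(base_radius > 0, length(harm_amp) == length(harm_phase))
  structure(list(base_radius = base_radius, harm_amp = as.numeric(harm_amp),
                 harm_phase = as.numeric(harm_phase)),
            class = "blob_shape")
}

# Realise a band-limited noise field of given size (deterministic per spec).
noise_field <- function(spec, nrow, ncol) {
  with_seed(spec$seed, {
    w <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
    b <- EBImage::gblur(w, spec$sigma_lo) - EBImage::gblur(w, spec$sigma_hi)
    b <- b / stats::sd(b) * spec$amplitude
    lim <- spec$clip * spec$amplitude
    pmin(pmax(spec$mean + pmin(pmax(b, -lim), lim), 0), 1)
  })
}

# Rasterise a blob_shape as a binary mask on a square canvas centred at
# (half, half) (0-based), optionally offset by (dx, dy).
blob_mask <- function(shape, side, offset = c(0, 0)) {
  half <- (side - 1) / 2
  dx <- matrix(rep(seq_len(side) - 1 - half - offset[1], each = side),
               side, side)
  dy <- matrix(rep(seq_len(side) - 1 - half - offset[2], times = side),
               side, side)
  r <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  bound <- rep(1, length(phi))
  for (m in seq_along(shape$harm_amp)) {
    bound <- bound + shape$harm_amp[m] * cos((m + 1) * phi + shape$harm_phase[m])
  }
  r <= shape$base_radius * matrix(bound, side, side)
}

# Largest boundary radius a blob_shape can reach.
blob_max_radius <- function(shape) {
  shape$base_radius * (1 + sum(abs(shape$harm_amp)))
}

#' Specify one moving textured object
#'
#' An object is a flat textured layer: a closed silhouette filled with a
#' surface texture, one strictly interior texture contour bounding a
#' differently textured sub-region, a depth rank (lower = nearer the
#' observer), and a per-frame motion.  `motion[[f]]` is the cumulative
#' affine transform taking the object from its frame-1 placement to frame
#' `f`, acting about the object's `home` position, so warped frames never
#' accumulate resampling error.
#'
#' @param home `(x, y)` frame position of the object centre at frame 1.
#' @param depth_rank Positive integer; lower ranks occlude higher ones.
#' @param silhouette A [blob_shape()].
#' @param surface_texture,internal_texture [texture_spec()]s for the surface
#'   and the interior sub-region.
#' @param internal_shape A [blob_shape()] for the internal texture contour.
#' @param internal_offset `(x, y)` offset of the internal region from the
#'   object centre, in object coordinates.
#' @param motion List of [affine_params()], one per frame (cumulative).
#' @return An `object_spec`.
#' @export
object_spec <- function(home, depth_rank, silhouette, surface_texture,
                        internal_texture, internal_shape,
                        internal_offset = c(0, 0), motion) {
  stopifnot(length(home) == 2L, depth_rank >= 1L,
            inherits(silhouette, "blob_shape"),
            inherits(surface_texture, "texture_spec"),
            inherits(internal_texture, "texture_spec"),
            inherits(internal_shape, "blob_shape"),
            length(internal_offset) == 2L, is.list(motion))
  if (blob_max_radius(internal_shape) + sqrt(sum(internal_offset^2)) >=
      silhouette$base_radius * (1 - sum(abs(silhouette$harm_amp)))) {
    stop("internal texture contour is not strictly inside the silhouette")
  }
  structure(list(home = as.numeric(home), depth_rank = as.integer(depth_rank),
                 silhouette = silhouette, surface_texture = surface_texture,
                 internal_texture = internal_texture,
                 internal_shape = internal_shape,
                 internal_offset = as.numeric(internal_offset),
                 motion = lapply(motion, as_affine_params)),
            class = "object_spec")
}

#' Assemble a scene configuration
#'
#' @param frame_count Number of frames (at least 2).
#' @param frame_size `(height, width)` in pixels.
#' @param background_texture A [texture_spec()] for the static background.
#' @param objects List of [object_spec()]s with unique depth ranks.
#' @param rng_seed Integer seed recorded for provenance.
#' @return A `scene_config`.
#' @export
scene_config <- function(frame_count, frame_size, background_texture, objects,
                         rng_seed = 0L) {
  frame_count <- as.integer(frame_count)
  stopifnot(frame_count >= 2L, length(frame_size) == 2L, all(frame_size > 0),
            inherits(background_texture, "texture_spec"),
            length(objects) >= 1L,
            all(vapply(objects, inherits, TRUE, "object_spec")))
  ranks <- vapply(objects, `[[`, 1L, "depth_rank")
  if (anyDuplicated(ranks)) stop("depth_rank must be unique per object")
  for (k in seq_along(objects)) {
    ob <- objects[[k]]
    if (length(ob$motion) != frame_count) {
      stop("object ", k, " motion length ", length(ob$motion),
           " does not match frame_count ", frame_count)
    }
    rmax <- blob_max_radius(ob$silhouette)
    if (ob$home[1] - rmax < 0 || ob$home[2] - rmax < 0 ||
        ob$home[1] + rmax > frame_size[2] - 1 ||
        ob$home[2] + rmax > frame_size[1] - 1) {
      stop("object ", k, " does not fit inside the frame at frame 1")
    }
  }
  structure(list(frame_count = frame_count,
                 frame_size = as.integer(frame_size),
                 background_texture = background_texture,
                 objects = objects, rng_seed = as.integer(rng_seed)),
            class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat("scene_config:", x$frame_count, "frames of",
      x$frame_size[1], "x", x$frame_size[2], "px,",
      length(x$objects), "objects (seed", x$rng_seed, ")\n")
  invisible(x)
}

#' Motion helpers
#'
#' `motion_identity()` holds an object still; `motion_translation()` moves
#' it at constant velocity `v` pixels per frame.  Both return cumulative
#' per-frame transforms suitable for [object_spec()].
#'
#' @param frame_count Number of frames.
#' @param v `(vx, vy)` velocity in pixels per frame.
#' @return List of [affine_params()] of length `frame_count`.
#' @export
motion_identity <- function(frame_count) {
  replicate(frame_count, affine_identity(), simplify = FALSE)
}

#' @rdname motion_identity
#' @export
motion_translation <- function(frame_count, v) {
  lapply(seq_len(frame_count) - 1L,
         function(f) affine_params(tx = v[1] * f, ty = v[2] * f))
}

#' Default four-object test scene
#'
#' Builds the standard validation scene: 160 frames of four independently
#' deforming textured objects on a static textured background, each object
#' carrying one internal texture contour.  Objects sit on a 2 x 2 grid and
#' follow constant-speed elliptical orbits choreographed so that each
#' vertical pair periodically overlaps (guaranteeing mutual partial
#' occlusion under unique depth ranks) while no internal texture region can
#' ever be fully hidden; rotation, scale and shear oscillate independently
#' per object, so every object undergoes deformation and scale change.
#' Region mean luminances are spaced so that every contour (object
#' boundaries and internal texture contours) carries an intensity step well
#' above the within-region texture contrast.
#'
#' @param seed Integer seed; every random choice (shapes, texture seeds,
#'   motion phases and magnitudes) derives from it.
#' @param frame_count Number of frames (default 160).
#' @param n_objects Number of objects (default 4; the 2 x 2 layout supports
#'   at most 4).
#' @return A [scene_config()].
#' @export
make_default_config <- function(seed = 0L, frame_count = 160L,
                                n_objects = 4L) {
  stopifnot(n_objects >= 1L, n_objects <= 4L)
  frame_size <- c(272L, 336L)
  homes <- list(c(104, 88), c(232, 88), c(104, 184), c(232, 184))
  ysign <- c(1, 1, -1, -1)    # top row oscillates down as bottom row rises
  # luminance levels: only vertically adjacent objects can ever touch, so
  # distinctness is required within vertical pairs and against the
  # background; this spacing keeps every realisable contour step >= 0.13
  surface_means <- c(0.26, 0.48, 0.70, 0.92)
  base_radius <- 44
  orbit_period <- 40   # constant orbital speed ~2.2 px/frame
  with_seed(seed, {
    phi0 <- stats::runif(1, 0, 2 * pi)   # shared orbit phase
    objects <- vector("list", n_objects)
    for (k in seq_len(n_objects)) {
      harm <- stats::runif(4, -0.005, 0.005)
      sil <- blob_shape(base_radius, harm, stats::runif(4, 0, 2 * pi))
      # the internal contour sits at ~1/3 of the silhouette radius; with the
      # 10 px side shift this keeps the inward-shifted patch centre well
      # inside the internal region while the outward-shifted patch is still
      # separated from the silhouette (and whatever moves beyond it) by more
      # than the receptive fields' effective support -- the locality the
      # side-wise diffeomorphism test needs
      int_frac <- stats::runif(1, 0.32, 0.35)
      int_shape <- blob_shape(base_radius * int_frac,
                              stats::runif(3, -0.005, 0.005),
                              stats::runif(3, 0, 2 * pi))
      ang <- stats::runif(1, 0, 2 * pi)
      int_off <- stats::runif(1, 0, 0.034) * base_radius * c(cos(ang), sin(ang))
      # constant-speed elliptical orbit around the grid position; vertical
      # pairs mirror their y motion so they approach by up to 2 * amp_y
      # while the x offset stays small, guaranteeing partial (never total)
      # occlusion; the frame-1 home is the initial point on the orbit
      amp <- stats::runif(2, 13, 15)
      jit <- stats::runif(1, -0.3, 0.3)
      th0 <- phi0 + jit
      home <- homes[[k]] + c(amp[1] * cos(th0), ysign[k] * amp[2] * sin(th0))
      # independent oscillating linear parts: rotation, scale, shear
      rho <- stats::runif(1, 5, 9) * pi / 180 * sample(c(-1, 1), 1)
      p_rot <- stats::runif(1, 80, 120)
      beta <- stats::runif(1, 0.03, 0.045) * sample(c(-1, 1), 1)
      p_scl <- stats::runif(1, 90, 130)
      eta <- stats::runif(1, 0.03, 0.05) * sample(c(-1, 1), 1)
      p_shr <- stats::runif(1, 70, 110)
      motion <- lapply(seq_len(frame_count) - 1L, function(f) {
        th <- th0 + 2 * pi * f / orbit_period
        tx <- amp[1] * (cos(th) - cos(th0))
        ty <- ysign[k] * amp[2] * (sin(th) - sin(th0))
        rot <- rho * sin(2 * pi * f / p_rot)
        scl <- 1 + beta * sin(2 * pi * f / p_scl)
        shr <- eta * sin(2 * pi * f / p_shr)
        A <- scl * matrix(c(cos(rot), -sin(rot), sin(rot), cos(rot)),
                          2, 2, byrow = TRUE) %*%
          matrix(c(1, shr, 0, 1), 2, 2, byrow = TRUE)
        affine_params(A[1, 1], A[1, 2], A[2, 1], A[2, 2], tx, ty)
      })
      objects[[k]] <- object_spec(
        home = home, depth_rank = k, silhouette = sil,
        surface_texture = texture_spec(surface_means[k],
                                       seed = seed * 101L + k * 7L),
        internal_texture = texture_spec(surface_means[k] - 0.13,
                                        seed = seed * 101L + k * 7L + 3L),
        internal_shape = int_shape, internal_offset = int_off,
        motion = motion)
    }
    scene_config(frame_count, frame_size,
                 texture_spec(0.08, seed = seed * 101L + 997L),
                 objects, rng_seed = seed)
  })
}

#' Render a scene configuration into frames and ground truth
#'
#' Frames are composited back-to-front (painter's algorithm): the static
#' background first, then objects in decreasing depth rank, each warped by
#' its cumulative affine motion (bicubic for textures, bilinear for masks).
#' Pixel values are quantised to 8-bit grey levels.  Ground truth is derived
#' from the same warped masks, so it is consistent with the composite by
#' construction.
#'
#' @param config A [scene_config()].
#' @return A list with components `frames` (a `frame_sequence`: list of
#'   numeric matrices in `[0, 1]`) and `gt` (a `ground_truth` with per-frame
#'   `label_maps` (0 = background), `edge_type_maps` (0 none / 1 texture
#'   edge / 2 occluding edge), `owner_maps` (owning object id on occluding
#'   edge pixels) and `texture_maps` (object id on visible internal texture
#'   region pixels)).
#' @export
render_sequence <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  h <- config$frame_size[1]; w <- config$frame_size[2]
  bg <- noise_field(config$background_texture, h, w)
  ord <- order(vapply(config$objects, `[[`, 1L, "depth_rank"),
               decreasing = TRUE)
  # per-object canvases: silhouette mask, internal mask, combined texture
  canv <- lapply(config$objects, function(ob) {
    side <- 2L * ceiling(blob_max_radius(ob$silhouette) + 3) + 1L
    mask <- blob_mask(ob$silhouette, side)
    imask <- blob_mask(ob$internal_shape, side, ob$internal_offset)
    tex <- noise_field(ob$surface_texture, side, side)
    itex <- noise_field(ob$internal_texture, side, side)
    tex[imask] <- itex[imask]
    list(side = side, half = (side - 1) / 2, mask = mask * 1,
         imask = imask * 1, tex = tex)
  })
  frames <- vector("list", config$frame_count)
  label_maps <- vector("list", config$frame_count)
  texture_maps <- vector("list", config$frame_count)
  for (f in seq_len(config$frame_count)) {
    img <- bg
    lab <- matrix(0L, h, w)
    tmap <- matrix(0L, h, w)
    for (k in ord) {
      ob <- config$objects[[k]]
      cv <- canv[[k]]
      a <- unclass(ob$motion[[f]])
      A <- matrix(a[1:4], 2, 2, byrow = TRUE)
      if (abs(a[1] * a[4] - a[2] * a[3]) < 1e-10) {
        stop("object ", k, " has a singular motion at frame ", f)
      }
      ctr <- ob$home + a[5:6]
      corners <- A %*% rbind(c(-1, 1, -1, 1), c(-1, -1, 1, 1)) * cv$half
      x0 <- max(0L, floor(ctr[1] + min(corners[1, ])) - 1L)
      x1 <- min(w - 1L, ceiling(ctr[1] + max(corners[1, ])) + 1L)
      y0 <- max(0L, floor(ctr[2] + min(corners[2, ])) - 1L)
      y1 <- min(h - 1L, ceiling(ctr[2] + max(corners[2, ])) + 1L)
      if (x0 > x1 || y0 > y1) {
        stop("object ", k, " is entirely outside the frame at frame ", f)
      }
      nx <- x1 - x0 + 1L; ny <- y1 - y0 + 1L
      px <- rep(x0:x1, each = ny) - ctr[1]
      py <- rep(y0:y1, times = nx) - ctr[2]
      B <- solve(A)
      qx <- B[1, 1] * px + B[1, 2] * py + cv$half
      qy <- B[2, 1] * px + B[2, 2] * py + cv$half
      m <- sample_image(cv$mask, qx, qy, method = "linear") >= 0.5
      if (!any(m)) {
        stop("object ", k, " is entirely outside the frame at frame ", f)
      }
      rows <- (rep(y0:y1, times = nx) + 1L)[m]
      cols <- (rep(x0:x1, each = ny) + 1L)[m]
      pix <- cbind(rows, cols)
      img[pix] <- sample_image(cv$tex, qx[m], qy[m], clamp = TRUE)
      lab[pix] <- k
      im <- sample_image(cv$imask, qx[m], qy[m], method = "linear") >= 0.5
      tmap[pix] <- k * im
    }
    frames[[f]] <- pmin(pmax(round(img * 255) / 255, 0), 1)
    label_maps[[f]] <- lab
    texture_maps[[f]] <- tmap
  }
  depth <- vapply(config$objects, `[[`, 1L, "depth_rank")
  gt_edges <- lapply(seq_len(config$frame_count), function(f) {
    edge_and_owner_maps(label_maps[[f]], texture_maps[[f]], depth)
  })
  structure(
    list(frames = structure(frames, class = "frame_sequence",
                            height = h, width = w),
         gt = structure(list(label_maps = label_maps,
                             edge_type_maps = lapply(gt_edges, `[[`, "type"),
                             owner_maps = lapply(gt_edges, `[[`, "owner"),
                             texture_maps = texture_maps,
                             depth_rank = depth),
                        class = "ground_truth")),
    class = "rendered_scene")
}

# Classify ground-truth pixels into edge types and assign occluding-edge
# owners (the adjacent label of minimum depth rank; background never owns).
edge_and_owner_maps <- function(lab, tmap, depth_rank) {
  h <- nrow(lab); w <- ncol(lab)
  dep <- matrix(999L, h, w)
  pos <- lab > 0L
  dep[pos] <- depth_rank[lab[pos]]
  occ <- matrix(FALSE, h, w)
  tex <- matrix(FALSE, h, w)
  own_lab <- lab
  own_dep <- dep
  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  for (s in shifts) {
    nl <- shift_mat(lab, s[1], s[2], pad = -1L)
    nd <- shift_mat(dep, s[1], s[2], pad = 999L)
    nt <- shift_mat(tmap, s[1], s[2], pad = -1L)
    valid <- nl >= 0L
    differs <- valid & (nl != lab)
    occ <- occ | differs
    tex <- tex | (valid & nl == lab & nt >= 0L & nt != tmap)
    take <- differs & nd < own_dep
    own_lab[take] <- nl[take]
    own_dep[take] <- nd[take]
  }
  type <- matrix(0L, h, w)
  type[tex] <- 1L
  type[occ] <- 2L   # occluding wins where both apply
  owner <- matrix(0L, h, w)
  owner[occ] <- own_lab[occ]
  list(type = type, owner = owner)
}

#' @export
print.rendered_scene <- function(x, ...) {
  cat("rendered scene:", length(x$frames), "frames",
      attr(x$frames, "height"), "x", attr(x$frames, "width"), "px\n")
  invisible(x)
}
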