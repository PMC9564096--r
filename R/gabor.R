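#' Configure a Gabor receptive-field bank
#'
#' The bank holds `n_orientations * n_frequencies` even (cosine-phase) Gabor
#' filters with orientations evenly spaced over `[0, pi)` and one filter per
#' wavelength.  Projections of an image patch onto the bank form its *place
#' token*, the n-vector descriptor on which diffeomorphism detection
#' operates.  All filters are DC-corrected (zero mean) so constant patches
#' project to the zero token.
#'
#' @param n_orientations Number of evenly spaced orientations (default 6).
#' @param n_frequencies Number of spatial frequencies (default 3).
#' @param wavelengths Pixel wavelengths, one per frequency.
#' @param envelope_sigma_factor Ratio of the Gaussian envelope sd to the
#'   wavelength.
#' @param patch_radius Patch half-side in pixels; the nominal patch side is
#'   `2 * patch_radius + 1` and must cover the largest wavelength.
#' @param margin Extra pixels read around the patch so warped filter
#'   supports stay inside the data; defaults to `ceiling(1.5 * patch_radius)`.
#' @param phase `"even"` for cosine-phase filters only (18 filters with the
#'   defaults), `"quadrature"` to add sine-phase partners (doubles the token
#'   length).
#' @param token_floor Additive floor on the squared token norm used when
#'   normalising residuals, so the existence test is contrast-invariant but
#'   near-blank patches are not declared matches by 0/0.
#' @param rel_tol Relative residual `E / (|gamma|^2 + token_floor)` at or
#'   below which a solved transform is declared a diffeomorphism.
#' @return A `gabor_bank_config` object.
#' @export
gabor_bank_config <- function(n_orientations = 6L, n_frequencies = 3L,
                              wavelengths = c(4, 6, 9),
                              envelope_sigma_factor = 0.5,
                              patch_radius = 10L, margin = NULL,
                              phase = c("even", "quadrature"),
                              token_floor = 1e-5, rel_tol = 0.05) {
  phase <- match.arg(phase)
  n_orientations <- as.integer(n_orientations)
  n_frequencies <- as.integer(n_frequencies)
  stopifnot(n_orientations >= 1L, n_frequencies >= 1L,
            length(wavelengths) == n_frequencies, all(wavelengths > 0),
            envelope_sigma_factor > 0, patch_radius >= 1L,
            token_floor > 0, rel_tol > 0)
  if (2L * patch_radius + 1L < max(wavelengths)) {
    stop("patch side ", 2L * patch_radius + 1L,
         " is smaller than the largest wavelength ", max(wavelengths))
  }
  if (is.null(margin)) margin <- ceiling(1.5 * patch_radius)
  structure(list(n_orientations = n_orientations,
                 n_frequencies = n_frequencies,
                 wavelengths = as.numeric(wavelengths),
                 envelope_sigma_factor = envelope_sigma_factor,
                 patch_radius = as.integer(patch_radius),
                 margin = as.integer(margin),
                 phase = phase,
                 token_floor = token_floor,
                 rel_tol = rel_tol),
            class = "gabor_bank_config")
}

#' Build a Gabor receptive-field bank
#'
#' Filters are defined analytically,
#' \deqn{F_i(u) = s_i\, e^{-|u|^2 / 2\sigma_i^2}\,(\cos(k_i \cdot u - \phi_i) - d_i),}
#' with \eqn{d_i} the DC correction making each even filter zero-mean and
#' \eqn{s_i} a normalisation giving each filter unit discrete L2 norm on the
#' patch support.  Because the filters are analytic they can be evaluated at
#' affine-warped coordinates exactly, which is how the conjugate transform
#' of [warped_token()] and the Lie-germ Jacobian of [solve_affine()] are
#' computed without resampling the filters.
#'
#' @param config A [gabor_bank_config()].
#' @return A `gabor_bank` object.
#' @export
make_gabor_bank <- function(config = gabor_bank_config()) {
  stopifnot(inherits(config, "gabor_bank_config"))
  th <- (seq_len(config$n_orientations) - 1) * pi / config$n_orientations
  tab <- expand.grid(orientation = th, wavelength = config$wavelengths,
                     KEEP.OUT.ATTRS = FALSE)
  if (config$phase == "quadrature") {
    tab <- rbind(cbind(tab, phase = 0), cbind(tab, phase = pi / 2))
  } else {
    tab$phase <- 0
  }
  k <- 2 * pi / tab$wavelength
  tab$kx <- k * cos(tab$orientation)
  tab$ky <- k * sin(tab$orientation)
  tab$sigma <- config$envelope_sigma_factor * tab$wavelength
  # DC of an even Gabor under its Gaussian envelope; sine filters are
  # naturally zero-mean.
  tab$dc <- ifelse(tab$phase == 0,
                   exp(-(2 * pi * config$envelope_sigma_factor)^2 / 2), 0)
  tab$scale <- 1
  half <- config$patch_radius + config$margin
  side <- 2L * half + 1L
  xs <- seq(-half, half)
  grid_x <- rep(xs, each = side)
  grid_y <- rep(xs, times = side)
  bank <- structure(list(config = config, filters = tab, n = nrow(tab),
                         half = half, side = side,
                         grid_x = grid_x, grid_y = grid_y),
                    class = "gabor_bank")
  # unit discrete L2 norm on the support
  for (i in seq_len(bank$n)) {
    v <- gabor_filter_values(bank, i, grid_x, grid_y)$f
    bank$filters$scale[i] <- 1 / sqrt(sum(v^2))
  }
  # plain-vector copies of the filter parameters for the hot path
  bank$par <- lapply(bank$filters[c("kx", "ky", "sigma", "dc", "phase",
                                    "scale")], as.numeric)
  bank
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat("Gabor bank:", x$n, "filters (", x$config$n_orientations,
      "orientations x", x$config$n_frequencies, "frequencies,",
      x$config$phase, "phase )\n")
  cat("  wavelengths:", paste(x$config$wavelengths, collapse = ", "),
      "px; envelope sigma =", x$config$envelope_sigma_factor, "* wavelength\n")
  cat("  patch radius:", x$config$patch_radius, "px, margin:",
      x$config$margin, "px (support side", x$side, ")\n")
  invisible(x)
}

# Evaluate filter i (and optionally its spatial gradient) at arbitrary
# filter-domain coordinates.  Pure-R reference twin of the C++ kernel.
gabor_filter_values <- function(bank, i, wx, wy, derivs = FALSE) {
  p <- bank$filters[i, ]
  g <- exp(-(wx^2 + wy^2) / (2 * p$sigma^2))
  arg <- p$kx * wx + p$ky * wy - p$phase
  cc <- cos(arg) - p$dc
  f <- p$scale * g * cc
  if (!derivs) return(list(f = f))
  sn <- sin(arg)
  list(f = f,
       fx = p$scale * g * (-wx / p$sigma^2 * cc - p$kx * sn),
       fy = p$scale * g * (-wy / p$sigma^2 * cc - p$ky * sn))
}

#' Materialise bank filters or conjugate-warped filters as kernels
#'
#' `gabor_kernels()` samples every filter on the patch support;
#' `warped_gabor_kernel()` samples a single filter after the conjugate
#' affine transform `T*(g)`, i.e. \eqn{F_i(g^{-1} u) / \det A}, which is the
#' receptive field whose projection implements [warped_token()].
#'
#' @param bank A [make_gabor_bank()] bank.
#' @param i Filter index.
#' @param a An [affine_params()] transform.
#' @return A list of matrices, or a single matrix.
#' @export
gabor_kernels <- function(bank) {
  lapply(seq_len(bank$n), function(i) {
    matrix(gabor_filter_values(bank, i, bank$grid_x, bank$grid_y)$f,
           bank$side, bank$side)
  })
}

#' @rdname gabor_kernels
#' @export
warped_gabor_kernel <- function(bank, i, a) {
  a <- unclass(as_affine_params(a))
  A <- matrix(a[1:4], 2, 2, byrow = TRUE)
  dt <- a[1] * a[4] - a[2] * a[3]
  if (abs(dt) < 1e-10) stop("affine transform is singular (det ~ 0)")
  B <- solve(A)
  wx <- B[1, 1] * (bank$grid_x - a[5]) + B[1, 2] * (bank$grid_y - a[6])
  wy <- B[2, 1] * (bank$grid_x - a[5]) + B[2, 2] * (bank$grid_y - a[6])
  matrix(gabor_filter_values(bank, i, wx, wy)$f / dt, bank$side, bank$side)
}

#' Lie germ receptive fields
#'
#' The Lie germ of filter `i` with respect to affine parameter `k` is the
#' derivative of the conjugate-warped filter with respect to that parameter
#' at the identity transform.  The germs supply the Jacobian for the Newton
#' iteration in [solve_affine()]; this function materialises them as kernels
#' on the patch support (an `side x side x n x 6` array), mainly for
#' inspection and finite-difference validation.
#'
#' @param bank A [make_gabor_bank()] bank.
#' @return A `lie_germ_bank` array with parameter order
#'   `(a11, a12, a21, a22, tx, ty)` on the fourth dimension.
#' @export
lie_germ_bank <- function(bank) {
  out <- array(0, dim = c(bank$side, bank$side, bank$n, 6L),
               dimnames = list(NULL, NULL, NULL,
                               c("a11", "a12", "a21", "a22", "tx", "ty")))
  vx <- bank$grid_x; vy <- bank$grid_y
  for (i in seq_len(bank$n)) {
    gv <- gabor_filter_values(bank, i, vx, vy, derivs = TRUE)
    # d/da_k [F(A^{-1}(v - t)) / det A] at the identity; the -F terms on the
    # diagonal parameters come from the determinant (L2-conjugacy) factor.
    out[, , i, 1] <- matrix(-gv$fx * vx - gv$f, bank$side, bank$side)
    out[, , i, 2] <- matrix(-gv$fx * vy, bank$side, bank$side)
    out[, , i, 3] <- matrix(-gv$fy * vx, bank$side, bank$side)
    out[, , i, 4] <- matrix(-gv$fy * vy - gv$f, bank$side, bank$side)
    out[, , i, 5] <- matrix(-gv$fx, bank$side, bank$side)
    out[, , i, 6] <- matrix(-gv$fy, bank$side, bank$side)
  }
  structure(out, class = "lie_germ_bank")
}

#' Extract an image patch with margin
#'
#' A patch is the square of pixels of half-side `radius + margin` centred at
#' an integer pixel location; the margin ensures affine-warped filter
#' supports stay inside the data.
#'
#' @param img Numeric matrix (a frame).
#' @param center Integer `(x, y)` pixel location, 0-based.
#' @param radius,margin Patch half-side and margin in pixels (defaults from
#'   `bank` when supplied).
#' @param bank Optional [make_gabor_bank()] bank supplying radius and margin.
#' @param frame Optional frame index carried for bookkeeping.
#' @return An `image_patch` object.
#' @export
image_patch <- function(img, center, radius = NULL, margin = NULL,
                        bank = NULL, frame = NA_integer_) {
  if (!is.null(bank)) {
    radius <- bank$config$patch_radius
    margin <- bank$config$margin
  }
  stopifnot(is.matrix(img), length(center) == 2L, !is.null(radius),
            !is.null(margin))
  cx <- as.integer(round(center[1])); cy <- as.integer(round(center[2]))
  half <- radius + margin
  if (cx - half < 0L || cy - half < 0L ||
      cx + half > ncol(img) - 1L || cy + half > nrow(img) - 1L) {
    stop("patch at (", cx, ", ", cy, ") with half-side ", half,
         " exceeds frame bounds ", nrow(img), "x", ncol(img))
  }
  structure(list(values = img[(cy - half):(cy + half) + 1L,
                              (cx - half):(cx + half) + 1L],
                 center = c(x = cx, y = cy),
                 radius = as.integer(radius), margin = as.integer(margin),
                 half = as.integer(half), frame = frame),
            class = "image_patch")
}

check_patch_bank <- function(patch, bank) {
  if (patch$half != bank$half) {
    stop("patch support (half-side ", patch$half,
         ") does not match bank support (half-side ", bank$half, ")")
  }
}

#' Gabor place token of an image patch
#'
#' The place token is the vector of inner products of the patch with every
#' filter in the bank.  It is linear in the patch values and zero for
#' constant patches.
#'
#' @param patch An [image_patch()].
#' @param bank A [make_gabor_bank()] bank with matching support.
#' @return Numeric vector of length `bank$n`.
#' @export
place_token <- function(patch, bank) {
  check_patch_bank(patch, bank)
  p <- bank$par
  pr <- .gabor_project_cpp(as.numeric(patch$values), bank$side,
                           c(1, 0, 0, 1), 0, 0,
                           p$kx, p$ky, p$sigma, p$dc, p$phase, p$scale, FALSE)
  as.numeric(pr$s)
}

# Shared engine: token of a patch seen through conjugate affine-warped
# receptive fields, plus (optionally) the Jacobian wrt the six parameters.
# `idx` restricts the projection to a (sigma-contiguous) filter subset.
warped_projection <- function(patch, bank, a, derivs = FALSE, idx = NULL) {
  check_patch_bank(patch, bank)
  a <- unclass(as_affine_params(a))
  A <- matrix(a[1:4], 2, 2, byrow = TRUE)
  dt <- a[1] * a[4] - a[2] * a[3]
  if (abs(dt) < 1e-10) stop("affine transform is singular (det ~ 0)")
  p <- bank$par
  if (!is.null(idx)) p <- lapply(p, `[`, idx)
  # the 3-sigma ball of the widest envelope, pushed forward by A plus the
  # translation, must stay inside the patch support
  reach <- norm(A, "2") * 3 * max(p$sigma) + sqrt(a[5]^2 + a[6]^2)
  if (reach > patch$half + 0.5) {
    stop("warped filter support (reach ", round(reach, 1),
         " px) exceeds the patch margin (half-side ", patch$half, ")")
  }
  B <- solve(A)
  pr <- .gabor_project_cpp(as.numeric(patch$values), bank$side,
                           c(B[1, 1], B[1, 2], B[2, 1], B[2, 2]), a[5], a[6],
                           p$kx, p$ky, p$sigma, p$dc, p$phase, p$scale, derivs)
  gamma <- as.numeric(pr$s) / dt
  if (!derivs) return(list(gamma = gamma))
  J <- cbind(-(B[1, 1] * pr$P + B[2, 1] * pr$R),
             -(B[1, 1] * pr$Q + B[2, 1] * pr$S),
             -(B[1, 2] * pr$P + B[2, 2] * pr$R),
             -(B[1, 2] * pr$Q + B[2, 2] * pr$S),
             -(B[1, 1] * pr$T + B[2, 1] * pr$U),
             -(B[1, 2] * pr$T + B[2, 2] * pr$U)) / dt
  ddet <- c(a[4], -a[3], -a[2], a[1], 0, 0)
  J <- J - outer(gamma / dt, ddet)
  list(gamma = gamma, J = J)
}

#' Place token through conjugate affine-warped receptive fields
#'
#' Computes \eqn{\gamma'_i(p, a) = \langle F_i(g_a^* \circ U), f \rangle}:
#' each receptive field is carried through the conjugate transform of
#' `a` (evaluated analytically at the inverse-warped coordinates, with the
#' Jacobian determinant of the L2 adjoint) before projection.  The defining
#' contract is affine invariance: if `patch2 = apply_affine(patch1, a)` then
#' `warped_token(patch2, bank, a)` equals `place_token(patch1, bank)` up to
#' interpolation error.
#'
#' @inheritParams place_token
#' @param a An [affine_params()] transform.
#' @return Numeric vector of length `bank$n`.
#' @export
warped_token <- function(patch, bank, a) {
  warped_projection(patch, bank, a)$gamma
}

#' Token-matching energy of an affine transform
#'
#' \eqn{E(a) = \|\gamma'(p, a) - \gamma(p)\|^2} where \eqn{\gamma} is the
#' place token of `patch1` and \eqn{\gamma'} the conjugate-warped token of
#' `patch2`.  `E` vanishes exactly when the warped receptive fields cancel
#' the transform relating the two patches.
#'
#' @param a An [affine_params()] transform.
#' @param patch1,patch2 [image_patch()]es from successive frames at
#'   corresponding centres.
#' @inheritParams place_token
#' @return Non-negative scalar.
#' @export
energy <- function(a, patch1, patch2, bank) {
  d <- warped_token(patch2, bank, a) - place_token(patch1, bank)
  sum(d^2)
}

diffeo_result <- function(params, residual, rel_residual, converged,
                          n_iterations, token_norm) {
  structure(list(params = as_affine_params(params), residual = residual,
                 rel_residual = rel_residual, converged = converged,
                 n_iterations = n_iterations, token_norm = token_norm),
            class = "diffeo_result")
}

#' @export
print.diffeo_result <- function(x, ...) {
  cat("diffeo solve:", if (x$converged) "converged" else "NOT converged",
      "in", x$n_iterations, "iterations; E =", signif(x$residual, 4),
      "( relative", signif(x$rel_residual, 4), ")\n")
  print(x$params)
  invisible(x)
}

#' @export
format.diffeo_result <- function(x, ...) {
  sprintf("diffeo(%s, E_rel=%.3g, conv=%s)",
          paste(signif(unclass(x$params), 4), collapse = ","),
          x$rel_residual, x$converged)
}

#' Solve for the affine transform relating two patches
#'
#' Newton (Gauss-Newton) iteration on the n-dimensional token residual
#' \eqn{E_i(a) = \gamma'_i(p, a) - \gamma_i(p)}.  Each step solves the
#' `n x 6` least-squares system whose Jacobian is assembled from Lie-germ
#' receptive-field projections (the analytic derivative of the warped token
#' with respect to each affine parameter, evaluated at the current
#' transform; at the identity these are exactly the kernels of
#' [lie_germ_bank()]).  Normal equations are Tikhonov-damped relative to the
#' Jacobian scale, so rank-deficient Jacobians yield a damped pseudo-inverse
#' step instead of an error.
#'
#' Convergence is declared when the relative residual
#' `E / (|gamma|^2 + token_floor)` falls at or below `rel_tol` and the
#' iteration did not diverge; a residual increase beyond `diverge_factor`
#' times the best seen stops the iteration with `converged = FALSE`.
#'
#' @param patch1,patch2 [image_patch()]es from successive frames at
#'   corresponding centres.
#' @param bank A [make_gabor_bank()] bank.
#' @param germs Optional [lie_germ_bank()]; accepted for completeness (the
#'   solver evaluates the same germs analytically at the current transform,
#'   which at the identity coincides with projecting these kernels).
#' @param init Initial transform (default identity).
#' @param max_iter Newton iteration cap (default 10).
#' @param damping Tikhonov damping relative to `mean(diag(J'J))`.
#' @param step_tol Early exit when the step norm falls below this.
#' @param rel_tol Convergence tolerance on the relative residual; defaults
#'   to the bank's `rel_tol`.
#' @param diverge_factor Residual growth factor that triggers a divergence
#'   stop.
#' @param stage1_iters Number of initial iterations fitted against the two
#'   coarsest-frequency blocks only; their wide envelopes smooth the energy
#'   landscape while large translations are pulled into range.
#' @param seed_step Spacing in pixels of the 3 x 3 translation seed grid
#'   used when the identity-seeded attempt fails: remaining seeds are ranked
#'   by coarse-band energy and retried in order.  `0` disables retries.
#' @param max_seeds Maximum number of Newton attempts (identity seed
#'   included); the first attempt whose relative residual reaches `rel_tol`
#'   is accepted.
#' @return A `diffeo_result`: `params`, `residual` (final energy),
#'   `rel_residual`, `converged`, `n_iterations`, `token_norm`.
#' @export
solve_affine <- function(patch1, patch2, bank, germs = NULL,
                         init = affine_identity(), max_iter = 10L,
                         damping = 1e-3, step_tol = 3e-4, rel_tol = NULL,
                         diverge_factor = 25, stage1_iters = 3L,
                         seed_step = 2.4, max_seeds = 3L) {
  if (is.null(rel_tol)) rel_tol <- bank$config$rel_tol
  gamma <- place_token(patch1, bank)
  denom <- sum(gamma^2) + bank$config$token_floor
  a0 <- unclass(as_affine_params(init))

  # the two coarsest-frequency blocks, whose wide envelopes give the
  # translation landscape its basin, drive the early iterations and the
  # fallback seed ranking
  wl <- sort(unique(bank$filters$wavelength), decreasing = TRUE)
  coarse_idx <- which(bank$filters$wavelength %in% wl[seq_len(min(2L, length(wl)))])
  full_idx <- seq_len(bank$n)

  # one damped Gauss-Newton attempt of at most max_iter iterations; the
  # first stage1_iters steps fit all six parameters against the coarse
  # blocks only, the rest against the full bank
  attempt <- function(a) {
    best_E <- Inf; best_a <- a
    diverged <- FALSE; n_done <- 0L
    for (it in seq_len(max_iter)) {
      coarse <- it <= stage1_iters
      idx <- if (coarse) coarse_idx else full_idx
      pr <- tryCatch(warped_projection(patch2, bank, a, derivs = TRUE,
                                       idx = idx),
                     error = function(e) NULL)
      if (is.null(pr)) { diverged <- TRUE; break }  # support left the margin
      r <- pr$gamma - gamma[idx]
      n_done <- it
      if (!coarse) {
        E <- sum(r^2)
        if (E < best_E) { best_E <- E; best_a <- a }
        if (E > diverge_factor * best_E + 1e-12) { diverged <- TRUE; break }
      }
      JtJ <- crossprod(pr$J)
      lam <- damping * mean(diag(JtJ)) + 1e-12
      step <- tryCatch(-solve(JtJ + diag(lam, 6L), crossprod(pr$J, r)),
                       error = function(e) NULL)
      if (is.null(step)) { diverged <- TRUE; break }
      a <- a + as.numeric(step)
      if (a[1] * a[4] - a[2] * a[3] <= 0.05) { diverged <- TRUE; break }
      if (!coarse && sqrt(sum(step^2)) < step_tol) break
    }
    if (!diverged) {
      E_fin <- tryCatch(sum((warped_projection(patch2, bank, a)$gamma - gamma)^2),
                        error = function(e) Inf)
      if (E_fin < best_E) { best_E <- E_fin; best_a <- a }
    }
    list(E = best_E, a = best_a, n = n_done, diverged = diverged)
  }
  accepted <- function(res) {
    !res$diverged && is.finite(res$E) && res$E / denom <= rel_tol
  }
  # a marginal pass can be a spurious shallow minimum (texture self-similar
  # along a strong edge); only a decisively small residual ends the seed
  # search early, otherwise all seeds compete on energy
  strong <- function(res) {
    !res$diverged && is.finite(res$E) && res$E / denom <= rel_tol / 10
  }

  best <- attempt(a0)
  if (!strong(best) && max_seeds > 1L && seed_step > 0) {
    # the identity-seeded attempt missed: rank translation seeds by the
    # coarse-band energy and retry from the most promising ones
    g_co <- gamma[coarse_idx]
    offs <- as.matrix(expand.grid(dx = c(-seed_step, 0, seed_step),
                                  dy = c(-seed_step, 0, seed_step)))
    offs <- offs[offs[, 1] != 0 | offs[, 2] != 0, , drop = FALSE]
    Es <- apply(offs, 1L, function(o) {
      pr <- tryCatch(warped_projection(patch2, bank, a0 + c(0, 0, 0, 0, o),
                                       idx = coarse_idx),
                     error = function(e) NULL)
      if (is.null(pr)) Inf else sum((pr$gamma - g_co)^2)
    })
    ord <- order(Es)[seq_len(min(max_seeds - 1L, sum(is.finite(Es))))]
    for (k in ord) {
      res <- attempt(a0 + c(0, 0, 0, 0, as.numeric(offs[k, ])))
      # lowest energy wins; an accepted attempt always beats a rejected one
      if ((accepted(res) && !accepted(best)) ||
          (accepted(res) == accepted(best) && res$E < best$E)) {
        best <- res
      }
      if (strong(res)) break
    }
  }
  rel <- best$E / denom
  diffeo_result(best$a, best$E, rel, accepted(best), best$n, denom)
}

#' Decide existence of a local diffeomorphism
#'
#' True exactly when the solve converged and its residual, normalised by the
#' squared token norm plus the contrast floor, is at or below `tol`.
#'
#' @param result A [solve_affine()] result.
#' @param tol Relative residual tolerance (default: the tolerance the solve
#'   was run with, via its stored relative residual and convergence flag).
#' @return Logical.
#' @export
diffeo_exists <- function(result, tol = NULL) {
  stopifnot(inherits(result, "diffeo_result"))
  if (is.null(tol)) return(isTRUE(result$converged))
  isTRUE(result$converged) && result$rel_residual <= tol
}
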