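#' Six-parameter affine transforms
#'
#' An `affine_params` object holds the six parameters
#' \eqn{(a_{11}, a_{12}, a_{21}, a_{22}, t_x, t_y)} of a planar affine
#' transform acting about a stated center \eqn{c}:
#' \deqn{p \mapsto A (p - c) + c + t,\qquad
#'       A = \begin{pmatrix} a_{11} & a_{12} \\ a_{21} & a_{22} \end{pmatrix}.}
#' The linear part is dimensionless; translations are in pixels.  This is the
#' local first-order (Taylor) approximation of a diffeomorphism between two
#' views of the same surface patch, and the parameter vector the Newton
#' solver in [solve_affine()] estimates.
#'
#' @param a11,a12,a21,a22 Entries of the linear part `A`.
#' @param tx,ty Translation in pixels.
#' @return An `affine_params` object (named numeric vector of length 6).
#' @seealso [apply_affine()], [affine_compose()], [affine_invert()]
#' @export
affine_params <- function(a11 = 1, a12 = 0, a21 = 0, a22 = 1, tx = 0, ty = 0) {
  a <- c(a11 = a11, a12 = a12, a21 = a21, a22 = a22, tx = tx, ty = ty)
  stopifnot(is.numeric(a), length(a) == 6L, all(is.finite(a)))
  structure(a, class = "affine_params")
}

#' @rdname affine_params
#' @export
affine_identity <- function() affine_params()

# Coerce a length-6 numeric vector (ordered a11, a12, a21, a22, tx, ty).
as_affine_params <- function(a) {
  if (inherits(a, "affine_params")) return(a)
  stopifnot(is.numeric(a), length(a) == 6L)
  affine_params(a[[1]], a[[2]], a[[3]], a[[4]], a[[5]], a[[6]])
}

#' @export
print.affine_params <- function(x, ...) {
  cat("affine transform: A = [",
      sprintf("%.4f %.4f; %.4f %.4f", x[1], x[2], x[3], x[4]),
      "], t = (", sprintf("%.3f, %.3f", x[5], x[6]), ") px\n", sep = "")
  invisible(x)
}

# 2x2 linear part.
affine_linear <- function(a) matrix(unclass(a)[1:4], 2, 2, byrow = TRUE)

affine_det <- function(a) a[[1]] * a[[4]] - a[[2]] * a[[3]]

#' Compose and invert affine transforms
#'
#' Composition is about a common center: `affine_compose(a, b)` is the
#' transform that first applies `b`, then `a`.
#'
#' @param a,b `affine_params` objects.
#' @return An `affine_params` object.
#' @export
affine_compose <- function(a, b) {
  a <- as_affine_params(a); b <- as_affine_params(b)
  A <- affine_linear(a) %*% affine_linear(b)
  t_new <- affine_linear(a) %*% c(b[["tx"]], b[["ty"]]) + c(a[["tx"]], a[["ty"]])
  affine_params(A[1, 1], A[1, 2], A[2, 1], A[2, 2], t_new[1], t_new[2])
}

#' @rdname affine_compose
#' @export
affine_invert <- function(a) {
  a <- as_affine_params(a)
  d <- affine_det(a)
  if (abs(d) < 1e-10) stop("affine transform is singular (det ~ 0)")
  B <- solve(affine_linear(a))
  t_new <- -B %*% c(a[["tx"]], a[["ty"]])
  affine_params(B[1, 1], B[1, 2], B[2, 1], B[2, 2], t_new[1], t_new[2])
}

#' Apply an affine transform to an image or to point coordinates
#'
#' For a coordinate set (a data frame or list with components `x` and `y`,
#' 0-based), returns the forward-mapped coordinates
#' \eqn{A(p - c) + c + t}.  For an image (numeric matrix), returns the
#' warped image computed by the inverse map with bilinear interpolation, so
#' that image content moves forward under the transform:
#' `out(g(p)) == img(p)`.
#'
#' @param x Numeric matrix (image) or data frame / list with `x`, `y`
#'   components (points, 0-based pixel coordinates).
#' @param a An [affine_params()] transform.
#' @param center Length-2 numeric `(x, y)` fixed point of the linear part.
#'   Defaults to the image center for images and `(0, 0)` for points.
#' @param fill Fill value for pixels mapping outside the source image.
#' @param clamp If `TRUE`, clamp source coordinates to the image border
#'   instead of filling (replicates edge rows/columns).
#' @param interp Interpolation method for image warping, see [sample_image()].
#' @return Warped image matrix, or data frame of transformed coordinates.
#' @export
apply_affine <- function(x, a, center = NULL, fill = 0, clamp = FALSE,
                         interp = c("cubic", "linear")) {
  a <- as_affine_params(a)
  if (abs(affine_det(a)) < 1e-10) stop("affine transform is singular (det ~ 0)")
  A <- affine_linear(a)
  tv <- c(a[["tx"]], a[["ty"]])
  if (is.data.frame(x) || (is.list(x) && !is.matrix(x))) {
    stopifnot(!is.null(x$x), !is.null(x$y))
    if (is.null(center)) center <- c(0, 0)
    P <- rbind(x$x - center[1], x$y - center[2])
    Q <- A %*% P
    return(data.frame(x = Q[1, ] + center[1] + tv[1],
                      y = Q[2, ] + center[2] + tv[2]))
  }
  stopifnot(is.matrix(x))
  nr <- nrow(x); nc <- ncol(x)
  if (is.null(center)) center <- c((nc - 1) / 2, (nr - 1) / 2)
  B <- solve(A)
  # inverse map: src = B (q - c - t) + c for every output pixel q
  qx <- rep(seq_len(nc) - 1, each = nr) - center[1] - tv[1]
  qy <- rep(seq_len(nr) - 1, times = nc) - center[2] - tv[2]
  sx <- B[1, 1] * qx + B[1, 2] * qy + center[1]
  sy <- B[2, 1] * qx + B[2, 2] * qy + center[2]
  matrix(sample_image(x, sx, sy, fill = fill, clamp = clamp, method = interp),
         nr, nc)
}
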