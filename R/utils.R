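#' @useDynLib surftrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Sample an image at fractional coordinates
#'
#' Coordinates follow the package-wide convention: 0-based, `x` rightward
#' (columns), `y` downward (rows), so `sample_image(img, 0, 0)` is
#' `img[1, 1]`.  Interpolation is bicubic (Catmull-Rom) by default, which
#' attenuates the fine spatial frequencies the Gabor bank measures far less
#' than bilinear does; bilinear is available for masks and other piecewise
#' data where overshoot is unwanted.
#'
#' @param img Numeric matrix.
#' @param x,y Numeric vectors of 0-based coordinates.
#' @param fill Value returned for out-of-range coordinates.
#' @param clamp If `TRUE`, clamp out-of-range coordinates to the border
#'   instead of filling.
#' @param method `"cubic"` or `"linear"`.
#' @return Numeric vector of sampled values.
#' @export
sample_image <- function(img, x, y, fill = 0, clamp = FALSE,
                         method = c("cubic", "linear")) {
  method <- match.arg(method)
  stopifnot(is.matrix(img), length(x) == length(y))
  if (method == "cubic") {
    .bicubic_sample_cpp(img, as.numeric(x), as.numeric(y), fill, clamp)
  } else {
    .bilinear_sample_cpp(img, as.numeric(x), as.numeric(y), fill, clamp)
  }
}

# Majority (modal) value of an integer vector, NA if empty; ties broken by
# the smaller value so results are deterministic.
majority_label <- function(x) {
  if (length(x) == 0L) return(NA_integer_)
  tab <- tabulate(x + 1L)
  which.max(tab) - 1L
}

# Shift a matrix by (dy, dx), padding with `pad`.
shift_mat <- function(m, dy, dx, pad = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(pad, nr, nc)
  ys <- seq_len(nr) - dy; xs <- seq_len(nc) - dx
  ok_y <- ys >= 1L & ys <= nr; ok_x <- xs >= 1L & xs <= nc
  out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
  out
}
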