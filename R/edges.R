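#' Edge detection parameters
#'
#' Canny-style detection: Gaussian smoothing, central-difference gradients,
#' non-maximum suppression along the gradient direction, and hysteresis
#' thresholding on the gradient magnitude.  The defaults are calibrated for
#' the synthetic generator's contrast structure (region mean steps of about
#' 0.1 against within-region texture of sd about 0.03) and are exposed here
#' for other material.
#'
#' @param sigma Gaussian smoothing sd in pixels.
#' @param low,high Hysteresis thresholds on gradient magnitude (luminance
#'   units per pixel).
#' @return An `edge_params` list.
#' @export
edge_params <- function(sigma = 1.2, low = 0.012, high = 0.025) {
  stopifnot(sigma > 0, low > 0, high >= low)
  structure(list(sigma = sigma, low = low, high = high),
            class = "edge_params")
}

#' Detect intensity edges
#'
#' @param frame Numeric matrix (grayscale, `[0, 1]`).
#' @param params An [edge_params()].
#' @return An `edge_map`: `edges` (logical matrix), `orientation` (local
#'   edge *tangent* direction in radians mod pi) and `magnitude` (smoothed
#'   gradient magnitude).
#' @export
detect_edges <- function(frame, params = edge_params()) {
  stopifnot(is.matrix(frame))
  h <- nrow(frame); w <- ncol(frame)
  sm <- EBImage::gblur(frame, params$sigma)
  # central differences; one-sided at the border
  gx <- (shift_mat(sm, 0, -1, NA) - shift_mat(sm, 0, 1, NA)) / 2
  gy <- (shift_mat(sm, -1, 0, NA) - shift_mat(sm, 1, 0, NA)) / 2
  gx[is.na(gx)] <- 0; gy[is.na(gy)] <- 0
  mag <- sqrt(gx^2 + gy^2)
  # non-maximum suppression in one of four quantised gradient directions
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4L)
  n1 <- matrix(0, h, w); n2 <- matrix(0, h, w)
  pick <- function(dy, dx) shift_mat(mag, dy, dx, 0)
  s0 <- sector == 0L  # gradient ~ horizontal: compare left/right
  s1 <- sector == 1L  # diagonal
  s2 <- sector == 2L  # vertical
  s3 <- sector == 3L
  n1[s0] <- pick(0, 1)[s0];  n2[s0] <- pick(0, -1)[s0]
  n1[s1] <- pick(1, 1)[s1];  n2[s1] <- pick(-1, -1)[s1]
  n1[s2] <- pick(1, 0)[s2];  n2[s2] <- pick(-1, 0)[s2]
  n1[s3] <- pick(1, -1)[s3]; n2[s3] <- pick(-1, 1)[s3]
  nms <- mag >= n1 & mag >= n2 & mag > 0
  weak <- nms & mag >= params$low
  strong <- nms & mag >= params$high
  edges <- hysteresis_link(weak, strong)
  orientation <- (ang + pi / 2) %% pi
  structure(list(edges = edges, orientation = orientation, magnitude = mag),
            class = "edge_map")
}

# Keep weak-edge chains (8-connected) that contain at least one strong
# pixel.  bwlabel is 4-connected, so diagonally adjacent components are
# unioned through a graph of diagonal label adjacencies.
hysteresis_link <- function(weak, strong) {
  if (!any(strong)) return(strong)
  lab <- EBImage::bwlabel(weak * 1)
  pairs <- NULL
  for (s in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab; b <- shift_mat(lab, s[1], s[2], 0L)
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  }
  nlab <- max(lab)
  comp <- seq_len(nlab)
  if (!is.null(pairs)) {
    g <- igraph::graph_from_edgelist(unique(pairs), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nlab - igraph::vcount(g)))
    comp <- igraph::components(g)$membership[seq_len(nlab)]
  }
  strong_comp <- unique(comp[lab[strong]])
  keep <- matrix(FALSE, nrow(weak), ncol(weak))
  pos <- lab > 0L
  keep[pos] <- comp[lab[pos]] %in% strong_comp
  keep
}

#' Super segmentation parameters
#'
#' @param closing_radius Radius (pixels) of the morphological closing that
#'   bridges small contour gaps before labeling.
#' @param min_area Components smaller than this (pixels) are merged into
#'   their largest neighbor.
#' @return A `superseg_params` list.
#' @export
superseg_params <- function(closing_radius = 2L, min_area = 20L) {
  stopifnot(closing_radius >= 0L, min_area >= 0L)
  structure(list(closing_radius = as.integer(closing_radius),
                 min_area = as.integer(min_area)),
            class = "superseg_params")
}

#' Super segmentation: label every contour-bounded component
#'
#' Closes small gaps in the edge map, then labels the 4-connected components
#' of the edge complement, giving every contour-bounded region its own
#' label; texture and occluding edges are treated alike at this stage.
#' Components below `min_area` are merged into their largest neighbor.
#' Contour pixels keep label 0.
#'
#' @param edge_map A [detect_edges()] result (or logical matrix).
#' @param params A [superseg_params()].
#' @return A `superseg_map`: `labels` (integer matrix, 0 on contours),
#'   `n_components`, and `adjacency` (two-column matrix of label pairs that
#'   share a contour segment).
#' @export
super_segmentation <- function(edge_map, params = superseg_params()) {
  edges <- if (inherits(edge_map, "edge_map")) edge_map$edges else edge_map
  stopifnot(is.matrix(edges))
  closed <- edges
  if (params$closing_radius > 0L) {
    brush <- EBImage::makeBrush(2L * params$closing_radius + 1L, "box")
    closed <- EBImage::closing(edges * 1, brush) > 0.5
    # a one-pixel dilation seals chain breaks (e.g. non-maximum-suppression
    # dropouts at contour elbows) that closing alone cannot bridge; the
    # contour band simply becomes one pixel wider on each side
    closed <- EBImage::dilate(closed * 1, EBImage::makeBrush(3L, "box")) > 0.5
  }
  lab <- EBImage::bwlabel((!closed) * 1)
  lab <- merge_small_components(lab, params$min_area,
                                gap = 2L * params$closing_radius + 3L)
  # compact labels to 1..n in raster order of first appearance
  u <- unique(as.integer(lab[lab > 0L]))
  remap <- integer(max(u)); remap[u] <- seq_along(u)
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  structure(list(labels = lab, n_components = length(u),
                 adjacency = label_adjacency(lab, gap = 2L * params$closing_radius + 3L)),
            class = "superseg_map")
}

# Label pairs that face each other across a contour: scan rows and columns
# for distinct labels separated by at most `gap` zero pixels.
label_adjacency <- function(lab, gap = 7L) {
  pairs <- NULL
  for (d in seq_len(gap)) {
    for (s in list(c(0L, d), c(d, 0L))) {
      b <- shift_mat(lab, s[1], s[2], 0L)
      sel <- lab > 0L & b > 0L & lab != b
      if (any(sel)) {
        p <- cbind(pmin(lab[sel], b[sel]), pmax(lab[sel], b[sel]))
        pairs <- rbind(pairs, unique(p))
      }
    }
  }
  if (is.null(pairs)) matrix(integer(0), 0, 2) else unique(pairs)
}

merge_small_components <- function(lab, min_area, gap = 7L) {
  repeat {
    areas <- tabulate(lab[lab > 0L])
    small <- which(areas > 0L & areas < min_area)
    if (length(small) == 0L) return(lab)
    adj <- label_adjacency(lab, gap = gap)
    changed <- FALSE
    for (s in small) {
      nb <- c(adj[adj[, 1] == s, 2], adj[adj[, 2] == s, 1])
      nb <- setdiff(nb, s)
      if (length(nb) == 0L) next
      target <- nb[which.max(areas[nb])]
      lab[lab == s] <- target
      changed <- TRUE
    }
    if (!changed) return(lab)
  }
}

#' Sample edge neighborhoods for diffeomorphism testing
#'
#' Draws up to `n` edge pixels without replacement, stratified across the
#' distinct pairs of super-segmentation labels facing each other at the
#' edge, so that every component boundary receives samples.  For each
#' sampled edge pixel the patch centres are shifted off the edge
#' perpendicular to the local edge tangent ("left" lies at tangent + pi/2
#' under the x-right / y-down convention); candidates whose shifted centres
#' fall on equal labels, on contour pixels, or out of bounds are rejected.
#'
#' @param edge_map A [detect_edges()] result.
#' @param superseg A [super_segmentation()] map.
#' @param n Number of neighborhoods requested (default 100).
#' @param seed Integer seed; the sample is fully reproducible.
#' @param shift_distance Perpendicular shift of the side patch centres in
#'   pixels (default: the bank patch radius convention, 10).
#' @param bound_margin Minimum distance of side centres from the frame
#'   border (use the bank half-support so patches stay in bounds).
#' @return A data frame (class `edge_neighborhoods`) with the edge pixel
#'   (`x`, `y`), `orientation`, side centres (`lx`, `ly`, `rx`, `ry`) and
#'   side labels (`left_label`, `right_label`).  If fewer than `n` valid
#'   candidates exist, all are returned and the shortfall is recorded in
#'   `attr(, "shortfall")`.
#' @export
sample_edge_neighborhoods <- function(edge_map, superseg, n = 100L, seed = 0L,
                                      shift_distance = 10L,
                                      bound_margin = 26L) {
  stopifnot(inherits(edge_map, "edge_map"), inherits(superseg, "superseg_map"),
            n >= 1L)
  lab <- superseg$labels
  h <- nrow(lab); w <- ncol(lab)
  idx <- which(edge_map$edges)
  if (length(idx) == 0L) {
    out <- empty_neighborhoods()
    attr(out, "shortfall") <- n
    return(out)
  }
  y <- (idx - 1L) %% h
  x <- (idx - 1L) %/% h
  ori <- edge_map$orientation[idx]
  nx <- cos(ori + pi / 2); ny <- sin(ori + pi / 2)
  lx <- as.integer(round(x + shift_distance * nx))
  ly <- as.integer(round(y + shift_distance * ny))
  rx <- as.integer(round(x - shift_distance * nx))
  ry <- as.integer(round(y - shift_distance * ny))
  ok <- lx >= bound_margin & lx <= w - 1L - bound_margin &
        rx >= bound_margin & rx <= w - 1L - bound_margin &
        ly >= bound_margin & ly <= h - 1L - bound_margin &
        ry >= bound_margin & ry <= h - 1L - bound_margin
  ll <- rl <- integer(length(idx))
  ll[ok] <- lab[cbind(ly[ok] + 1L, lx[ok] + 1L)]
  rl[ok] <- lab[cbind(ry[ok] + 1L, rx[ok] + 1L)]
  ok <- ok & ll > 0L & rl > 0L & ll != rl
  if (!any(ok)) {
    out <- empty_neighborhoods()
    attr(out, "shortfall") <- n
    return(out)
  }
  cand <- data.frame(x = x[ok], y = y[ok], orientation = ori[ok],
                     lx = lx[ok], ly = ly[ok], rx = rx[ok], ry = ry[ok],
                     left_label = ll[ok], right_label = rl[ok])
  cand$pair <- paste0(pmin(cand$left_label, cand$right_label), ":",
                      pmax(cand$left_label, cand$right_label))
  sel <- with_seed(seed, {
    # shuffle within pair, then deal one candidate per pair round-robin
    ord <- sample.int(nrow(cand))
    byp <- split(ord, cand$pair[ord])
    byp <- byp[sample.int(length(byp))]
    take <- integer(0)
    k <- 1L
    while (length(take) < n && any(lengths(byp) >= k)) {
      nxt <- unlist(lapply(byp, function(v) if (length(v) >= k) v[k]),
                    use.names = FALSE)
      room <- n - length(take)
      take <- c(take, nxt[seq_len(min(room, length(nxt)))])
      k <- k + 1L
    }
    take
  })
  out <- cand[sel, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("edge_neighborhoods", "data.frame")
  attr(out, "shortfall") <- max(0L, n - nrow(out))
  if (nrow(out) < n) {
    warning("only ", nrow(out), " of ", n,
            " requested edge neighborhoods are valid")
  }
  out
}

empty_neighborhoods <- function() {
  out <- data.frame(x = integer(0), y = integer(0), orientation = numeric(0),
                    lx = integer(0), ly = integer(0), rx = integer(0),
                    ry = integer(0), left_label = integer(0),
                    right_label = integer(0), pair = character(0))
  class(out) <- c("edge_neighborhoods", "data.frame")
  out
}

#' Extract a same-centre patch pair from successive frames
#'
#' The two patches share the centre; the affine solver then estimates the
#' transform carrying the frame-`i` content to frame `i + 1` at that place.
#'
#' @param frame_a,frame_b Numeric frame matrices.
#' @param center Integer `(x, y)` centre, 0-based.
#' @param bank The [make_gabor_bank()] bank defining patch radius and margin.
#' @param frames Optional length-2 frame indices for bookkeeping.
#' @return List of two [image_patch()]es.
#' @export
extract_patch_pair <- function(frame_a, frame_b, center, bank,
                               frames = c(NA_integer_, NA_integer_)) {
  list(a = image_patch(frame_a, center, bank = bank, frame = frames[1]),
       b = image_patch(frame_b, center, bank = bank, frame = frames[2]))
}
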