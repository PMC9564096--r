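#' Classification parameters
#'
#' @param param_tol Tolerance on the dimensionless transform distance below
#'   which the two side transforms are considered equal (texture edge).  The
#'   distance is the maximum over linear-part component differences and
#'   translation differences divided by `shift_distance`.
#' @param shift_distance Side-patch shift in pixels (normalises translation
#'   differences).
#' @param ratio_threshold Minimum ratio of the larger to the smaller
#'   accretion score required to decide border ownership.
#' @param score_floor Additive floor in the accretion-score normalisation.
#' @param min_normal_disp Minimum relative displacement (pixels) of the two
#'   side transforms along the edge normal for an ownership decision:
#'   without motion across the edge there is no accretion to perceive, so
#'   ownership is deferred.
#' @param mask_softness Width (pixels) of the soft half-plane mask that
#'   restricts the accretion difference to one side of the contour.
#' @param accretion_band Gaussian half-width (pixels) of the band along the
#'   contour within which the accretion difference is evaluated; accretion
#'   physically appears right at the contour, so structure farther away
#'   (e.g. another object's nearby edge) is excluded from the score.
#' @param accretion_min Minimum larger accretion score required to decide
#'   ownership when the normal-displacement gate cannot be evaluated
#'   (only one side converged).
#' @return A `classify_params` list.
#' @export
classify_params <- function(param_tol = 0.1, shift_distance = 10,
                            ratio_threshold = 2, score_floor = 1e-3,
                            min_normal_disp = 0.8, mask_softness = 1.5,
                            accretion_band = 4, accretion_min = 0.25) {
  stopifnot(param_tol > 0, shift_distance > 0, ratio_threshold >= 1,
            score_floor > 0, min_normal_disp >= 0, mask_softness > 0,
            accretion_band > 0, accretion_min >= 0)
  structure(list(param_tol = param_tol, shift_distance = shift_distance,
                 ratio_threshold = ratio_threshold, score_floor = score_floor,
                 min_normal_disp = min_normal_disp,
                 mask_softness = mask_softness,
                 accretion_band = accretion_band,
                 accretion_min = accretion_min),
            class = "classify_params")
}

# Dimensionless distance between two side transforms: max over linear-part
# differences and translation differences per shift_distance.
transform_distance <- function(a_left, a_right, shift_distance) {
  d <- abs(unclass(as_affine_params(a_left)) -
             unclass(as_affine_params(a_right)))
  max(d[1:4], d[5:6] / shift_distance)
}

#' Classify an edge as texture or occluding from its two side transforms
#'
#' A texture edge is interior to one surface, so the affine transforms
#' recovered on its two sides agree; an occluding edge separates surfaces
#' with different motions, so the transforms differ, or the occluded side
#' fails to admit any diffeomorphism at all.  The primary criterion is the
#' parameter distance between two converged solutions; one-sided
#' non-convergence is the fallback.  If neither side admits a
#' diffeomorphism the sample is ambiguous.
#'
#' @param T_left,T_right [solve_affine()] results for the two side patches.
#' @param params A [classify_params()].
#' @return One of `"texture"`, `"occluding"`, `"ambiguous"`.
#' @export
classify_edge <- function(T_left, T_right, params = classify_params()) {
  okL <- diffeo_exists(T_left); okR <- diffeo_exists(T_right)
  if (okL && okR) {
    d <- transform_distance(T_left$params, T_right$params,
                            params$shift_distance)
    if (d <= params$param_tol) "texture" else "occluding"
  } else if (okL || okR) {
    "occluding"
  } else {
    "ambiguous"
  }
}

#' Accretion score of one edge side across a frame transition
#'
#' Warps the contour-centred patch from frame `i` by the side's computed
#' transform, subtracts the frame `i + 1` patch, restricts the difference to
#' the side's half of the contour with a soft half-plane mask, and projects
#' it onto the Gabor bank (whose envelopes further discount the patch
#' borders); the result is the norm of that difference token, normalised by
#' the norm of the equally masked frame `i + 1` token plus a floor.  On the
#' owner side the warp cancels the motion, contour included, and the score
#' is small; on the occluded side a strip of texture right at the contour
#' accretes or is deleted, landing at the centre of the receptive fields,
#' and the score is large.  Texture edges score small on both sides.
#'
#' @param side_patch_i,side_patch_i1 Contour-centred [image_patch()]es from
#'   the two frames (extracted at the sampled edge pixel).
#' @param T_side The transform to test (the side's own solution, or the
#'   cross side's when the side's own solve failed).
#' @param bank A [make_gabor_bank()] bank.
#' @param params A [classify_params()].
#' @param side_normal Optional unit `(x, y)` vector pointing from the
#'   contour towards the scored side; when supplied the difference is
#'   masked to that half.  `NULL` scores the whole patch.
#' @return Non-negative scalar.
#' @export
accretion_score <- function(side_patch_i, side_patch_i1, T_side, bank,
                            params = classify_params(), side_normal = NULL) {
  a <- if (inherits(T_side, "diffeo_result")) T_side$params else
    as_affine_params(T_side)
  ctr <- side_patch_i$half  # patch-local centre index (0-based)
  warped <- apply_affine(side_patch_i$values, a, center = c(ctr, ctr),
                         clamp = TRUE)
  mask <- 1
  if (!is.null(side_normal)) {
    # one-sided band along the contour: the half-plane of the scored side,
    # narrowed to where accretion physically appears
    d <- bank$grid_x * side_normal[1] + bank$grid_y * side_normal[2]
    mask <- matrix(stats::pnorm(d / params$mask_softness) *
                     exp(-0.5 * (d / params$accretion_band)^2),
                   bank$side, bank$side)
  }
  dpatch <- side_patch_i1
  dpatch$values <- (warped - side_patch_i1$values) * mask
  rpatch <- side_patch_i1
  rpatch$values <- side_patch_i1$values * mask
  dtok <- place_token(dpatch, bank)
  ref <- sqrt(sum(place_token(rpatch, bank)^2))
  sqrt(sum(dtok^2)) / (ref + params$score_floor)
}

#' Assign border ownership from the two accretion scores
#'
#' The owner is the side *opposite* the perceivable accretion, i.e. the side
#' with the smaller score, provided the score ratio is decisive and the two
#' side transforms actually displace material across the edge (without
#' normal relative motion nothing accretes, so nothing can be perceived);
#' otherwise no owner is assigned and the decision is deferred to
#' aggregation.
#'
#' @param score_left,score_right Non-negative accretion scores.
#' @param params A [classify_params()] (uses `ratio_threshold` and
#'   `min_normal_disp`).
#' @param normal_disp Relative displacement of the two side transforms along
#'   the edge normal, in pixels (`NA` when only one side converged, in which
#'   case the gate is waived and the score ratio alone decides).
#' @return `"left"`, `"right"` or `"none"`.
#' @export
assign_owner <- function(score_left, score_right,
                         params = classify_params(), normal_disp = NA) {
  lo <- min(score_left, score_right); hi <- max(score_left, score_right)
  if (is.na(normal_disp)) {
    # one-sided convergence: no displacement estimate, so require clearly
    # perceivable accretion on the losing side instead
    if (hi < params$accretion_min) return("none")
  } else if (abs(normal_disp) < params$min_normal_disp) {
    return("none")
  }
  if (hi < params$ratio_threshold * max(lo, 1e-12)) return("none")
  if (score_left <= score_right) "left" else "right"
}

#' Classify all sampled neighborhoods across one frame transition
#'
#' For every neighborhood, solves for the side transforms between the two
#' frames at the shifted side centres, classifies the edge, and for
#' occluding edges computes both accretion scores and the owner side.
#'
#' @param frame_a,frame_b Successive frames (numeric matrices).
#' @param nbh A [sample_edge_neighborhoods()] data frame for `frame_a`.
#' @param bank A [make_gabor_bank()] bank.
#' @param params A [classify_params()].
#' @param solver Optional list of [solve_affine()] arguments
#'   (e.g. `max_iter`, `damping`).
#' @return `nbh` extended with `kind`, `owner`, per-side convergence flags,
#'   relative residuals, accretion scores, and the six transform parameters
#'   per side (`l_a11` ... `r_ty`); class `edge_classifications`.
#' @export
classify_neighborhoods <- function(frame_a, frame_b, nbh, bank,
                                   params = classify_params(),
                                   solver = list()) {
  n <- nrow(nbh)
  kind <- character(n); owner <- character(n)
  convL <- logical(n); convR <- logical(n)
  relL <- numeric(n); relR <- numeric(n)
  accL <- rep(NA_real_, n); accR <- rep(NA_real_, n)
  TL <- matrix(NA_real_, n, 6); TR <- matrix(NA_real_, n, 6)
  for (i in seq_len(n)) {
    pl <- extract_patch_pair(frame_a, frame_b, c(nbh$lx[i], nbh$ly[i]), bank)
    pr <- extract_patch_pair(frame_a, frame_b, c(nbh$rx[i], nbh$ry[i]), bank)
    T_left <- do.call(solve_affine, c(list(pl$a, pl$b, bank), solver))
    T_right <- do.call(solve_affine, c(list(pr$a, pr$b, bank), solver))
    kind[i] <- classify_edge(T_left, T_right, params)
    convL[i] <- T_left$converged; convR[i] <- T_right$converged
    relL[i] <- T_left$rel_residual; relR[i] <- T_right$rel_residual
    TL[i, ] <- unclass(T_left$params); TR[i, ] <- unclass(T_right$params)
    owner[i] <- "none"
    if (kind[i] == "occluding") {
      # accretion test on the contour-centred patch: each side's half is
      # compared under its own transform (or the cross side's when the
      # side's own solve failed)
      pe <- tryCatch(extract_patch_pair(frame_a, frame_b,
                                        c(nbh$x[i], nbh$y[i]), bank),
                     error = function(e) NULL)
      if (!is.null(pe)) {
        nxv <- cos(nbh$orientation[i] + pi / 2)
        nyv <- sin(nbh$orientation[i] + pi / 2)
        ndisp <- if (T_left$converged && T_right$converged) {
          (T_left$params[["tx"]] - T_right$params[["tx"]]) * nxv +
            (T_left$params[["ty"]] - T_right$params[["ty"]]) * nyv
        } else NA
        aL <- if (T_left$converged) T_left$params else T_right$params
        aR <- if (T_right$converged) T_right$params else T_left$params
        accL[i] <- accretion_score(pe$a, pe$b, aL, bank, params,
                                   side_normal = c(nxv, nyv))
        accR[i] <- accretion_score(pe$a, pe$b, aR, bank, params,
                                   side_normal = -c(nxv, nyv))
        owner[i] <- assign_owner(accL[i], accR[i], params, ndisp)
      }
    }
  }
  out <- nbh
  out$kind <- kind; out$owner <- owner
  out$conv_left <- convL; out$conv_right <- convR
  out$rel_left <- relL; out$rel_right <- relR
  out$acc_left <- accL; out$acc_right <- accR
  colnames(TL) <- paste0("l_", c("a11", "a12", "a21", "a22", "tx", "ty"))
  colnames(TR) <- paste0("r_", c("a11", "a12", "a21", "a22", "tx", "ty"))
  out <- cbind(out, TL, TR)
  class(out) <- c("edge_classifications", "data.frame")
  out
}

#' Aggregate per-neighborhood classifications into per-region votes
#'
#' Because one boundary between two components is a single contour of a
#' single physical type, the samples of each adjacent-label pair are first
#' consolidated by majority: on a majority-texture boundary the minority
#' occluding samples (and their owner decisions) are discarded, and vice
#' versa; ties keep everything.  A region is then *pure texture* exactly
#' when at least one texture edge lies on its boundary and it is never the
#' owner side of any occluding edge; its texture partner is the adjacent
#' region across its majority-texture boundary.  Regions with no samples are
#' flagged unsampled and left untouched downstream.
#'
#' @param classifications An [classify_neighborhoods()] result for one frame.
#' @param superseg The frame's [super_segmentation()] map.
#' @return Data frame with one row per super-segmentation label:
#'   `texture_count`, `owner_count`, `sampled`, `is_pure_texture`,
#'   `texture_partner` (NA when none).
#' @export
aggregate_region_votes <- function(classifications, superseg) {
  nlab <- superseg$n_components
  tex_count <- integer(nlab); own_count <- integer(nlab)
  sampled <- logical(nlab)
  partner_votes <- vector("list", nlab)
  # per-boundary majority over the redundant samples of each label pair
  pairkey <- paste0(pmin(classifications$left_label,
                         classifications$right_label), ":",
                    pmax(classifications$left_label,
                         classifications$right_label))
  n_tex <- tapply(classifications$kind == "texture", pairkey, sum)
  n_occ <- tapply(classifications$kind == "occluding", pairkey, sum)
  for (i in seq_len(nrow(classifications))) {
    cl <- classifications[i, ]
    l <- cl$left_label; r <- cl$right_label
    if (l < 1L || l > nlab || r < 1L || r > nlab) next
    sampled[c(l, r)] <- TRUE
    key <- pairkey[i]
    if (cl$kind == "texture" && n_tex[[key]] >= n_occ[[key]]) {
      tex_count[l] <- tex_count[l] + 1L
      tex_count[r] <- tex_count[r] + 1L
      partner_votes[[l]] <- c(partner_votes[[l]], r)
      partner_votes[[r]] <- c(partner_votes[[r]], l)
    } else if (cl$kind == "occluding" && cl$owner != "none" &&
               n_occ[[key]] >= n_tex[[key]]) {
      side <- if (cl$owner == "left") l else r
      own_count[side] <- own_count[side] + 1L
    }
  }
  partner <- vapply(seq_len(nlab), function(k) {
    v <- partner_votes[[k]]
    if (length(v) == 0L) NA_integer_ else {
      tab <- table(v)
      as.integer(names(tab)[which.max(tab)])
    }
  }, integer(1))
  data.frame(label = seq_len(nlab),
             texture_count = tex_count,
             owner_count = own_count,
             sampled = sampled,
             is_pure_texture = tex_count >= 1L & own_count == 0L,
             texture_partner = partner)
}
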