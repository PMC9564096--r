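#' Erase texture edges: build the object segmentation map
#'
#' Every pure-texture region's label is replaced by its texture partner's
#' label, iterated to a fixpoint so nested texture regions collapse
#' outward.  Labels are only ever replaced by existing labels, never
#' invented.  Regions in `protect` (typically the frame-border/background
#' component) are never merged; a pure-texture region whose partner is
#' missing is left unmerged.
#'
#' @param superseg A [super_segmentation()] map.
#' @param votes An [aggregate_region_votes()] data frame.
#' @param protect Integer labels exempt from merging.
#' @return A `seg_map`: `labels` (integer matrix), `merges` (two-column
#'   matrix of (from, into) label pairs applied), `mapping` (final label of
#'   every super-segmentation label).
#' @export
build_seg_map <- function(superseg, votes, protect = integer(0)) {
  nlab <- superseg$n_components
  mapping <- seq_len(nlab)
  mergeable <- votes$is_pure_texture & !is.na(votes$texture_partner) &
    !(votes$label %in% protect)
  step <- ifelse(mergeable, votes$texture_partner, mapping)
  # resolve chains; a cycle (two texture regions pointing at each other)
  # leaves its members unmerged
  for (k in which(mergeable)) {
    cur <- k; seen <- k
    while (step[cur] != cur) {
      nxt <- step[cur]
      if (nxt %in% seen) { cur <- k; break }  # cycle: keep own label
      seen <- c(seen, nxt)
      cur <- nxt
    }
    mapping[k] <- cur
  }
  lab <- superseg$labels
  pos <- lab > 0L
  lab[pos] <- mapping[lab[pos]]
  merges <- cbind(from = which(mapping != seq_len(nlab)),
                  into = mapping[mapping != seq_len(nlab)])
  structure(list(labels = lab, merges = merges, mapping = mapping),
            class = "seg_map")
}

#' Propagate diffeomorphic samples into cross-frame component links
#'
#' Each usable side of a classified neighborhood (both sides of a texture
#' edge, the owner side of an occluding edge, in either case only when that
#' side's solve converged) maps its side centre through its transform into
#' the next frame; a link is emitted between the frame-`i` component at the
#' side centre and the frame-`i+1` component containing the mapped point.
#' Samples mapping out of bounds or onto contour pixels are ignored.
#'
#' @param classifications A [classify_neighborhoods()] result for frame `i`.
#' @param superseg_next The next frame's [super_segmentation()] map.
#' @return Data frame of links `from` (frame-i label), `to` (frame-i+1
#'   label) and `votes` (supporting sample count), one row per pair.
#' @export
link_frames <- function(classifications, superseg_next) {
  lab2 <- superseg_next$labels
  h <- nrow(lab2); w <- ncol(lab2)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(nrow(classifications))) {
    cl <- classifications[i, ]
    sides <- character(0)
    if (cl$kind == "texture") {
      sides <- c(if (cl$conv_left) "l", if (cl$conv_right) "r")
    } else if (cl$kind == "occluding" && cl$owner != "none") {
      s <- substr(cl$owner, 1, 1)
      if ((s == "l" && cl$conv_left) || (s == "r" && cl$conv_right)) sides <- s
    }
    for (s in sides) {
      cx <- cl[[paste0(s, "x")]] + cl[[paste0(s, "_tx")]]
      cy <- cl[[paste0(s, "y")]] + cl[[paste0(s, "_ty")]]
      xi <- as.integer(round(cx)); yi <- as.integer(round(cy))
      if (xi < 0L || yi < 0L || xi > w - 1L || yi > h - 1L) next
      l2 <- lab2[yi + 1L, xi + 1L]
      if (l2 == 0L) next
      from <- c(from, cl[[if (s == "l") "left_label" else "right_label"]])
      to <- c(to, l2)
    }
  }
  if (length(from) == 0L) {
    return(data.frame(from = integer(0), to = integer(0), votes = integer(0)))
  }
  agg <- stats::aggregate(list(votes = rep(1L, length(from))),
                          by = list(from = from, to = to), FUN = sum)
  agg
}

#' Build the scene graph over all frames
#'
#' Vertices are (frame, super-segmentation component) pairs; edges are
#' same-frame texture merges and cross-frame diffeomorphic links supported
#' by at least `min_votes` samples.  Components containing any frame-border
#' pixel are marked background.
#'
#' @param supersegs List of per-frame [super_segmentation()] maps.
#' @param links List of per-transition [link_frames()] data frames (entry
#'   `f` links frame `f` to frame `f + 1`).
#' @param merges List of per-frame merge matrices from [build_seg_map()].
#' @param min_votes Minimum supporting samples for a cross-frame link.
#' @return A `scene_graph`: an igraph with vertex attributes `frame`,
#'   `comp`, `background`, and edge attribute `tag` (`"merge"` or
#'   `"diffeo"`).
#' @export
build_scene_graph <- function(supersegs, links, merges, min_votes = 2L) {
  n_frames <- length(supersegs)
  vname <- function(f, l) paste0("f", f, ":", l)
  verts <- do.call(rbind, lapply(seq_len(n_frames), function(f) {
    data.frame(name = vname(f, seq_len(supersegs[[f]]$n_components)),
               frame = f, comp = seq_len(supersegs[[f]]$n_components))
  }))
  verts$background <- FALSE
  for (f in seq_len(n_frames)) {
    lab <- supersegs[[f]]$labels
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border <- border[border > 0L]
    verts$background[verts$frame == f & verts$comp %in% border] <- TRUE
  }
  edges <- character(0); tags <- character(0)
  for (f in seq_len(n_frames)) {
    mg <- merges[[f]]
    if (!is.null(mg) && nrow(mg) > 0L) {
      edges <- c(edges, rbind(vname(f, mg[, 1]), vname(f, mg[, 2])))
      tags <- c(tags, rep("merge", nrow(mg)))
    }
  }
  for (f in seq_along(links)) {
    lk <- links[[f]]
    if (is.null(lk) || nrow(lk) == 0L) next
    lk <- lk[lk$votes >= min_votes, , drop = FALSE]
    if (nrow(lk) == 0L) next
    edges <- c(edges, rbind(vname(f, lk$from), vname(f + 1L, lk$to)))
    tags <- c(tags, rep("diffeo", nrow(lk)))
  }
  g <- igraph::graph_from_data_frame(
    if (length(edges)) data.frame(from = edges[c(TRUE, FALSE)],
                                  to = edges[c(FALSE, TRUE)], tag = tags)
    else data.frame(from = character(0), to = character(0),
                    tag = character(0)),
    directed = FALSE, vertices = verts)
  g <- igraph::simplify(g, edge.attr.comb = "first")
  class(g) <- c("scene_graph", class(g))
  g
}

#' Count the scene graph's non-background connected components
#'
#' These are the invariant objects the tracker reports.
#'
#' @param graph A [build_scene_graph()] result.
#' @return Integer count.
#' @export
count_objects <- function(graph) {
  memb <- igraph::components(graph)$membership
  bg_comps <- unique(memb[igraph::V(graph)$background])
  length(setdiff(unique(memb), bg_comps))
}

#' Assign stable object ids to scene-graph vertices
#'
#' Every connected component containing a background (frame-border) vertex
#' gets id 0; the remaining components get ids 1, 2, ... ordered by their
#' smallest (frame, component) key, a deterministic tie-break invariant to
#' vertex insertion order.
#'
#' @param graph A [build_scene_graph()] result.
#' @return Named integer vector: object id per vertex name.
#' @export
assign_object_ids <- function(graph) {
  memb <- igraph::components(graph)$membership
  frame <- igraph::V(graph)$frame
  comp <- igraph::V(graph)$comp
  bg <- unique(memb[igraph::V(graph)$background])
  obj_comps <- setdiff(unique(memb), bg)
  if (length(obj_comps)) {
    key <- vapply(obj_comps, function(m) {
      sel <- memb == m
      min(frame[sel] * 1e6 + comp[sel])
    }, numeric(1))
    obj_comps <- obj_comps[order(key)]
  }
  ids <- integer(length(memb))
  for (i in seq_along(obj_comps)) ids[memb == obj_comps[i]] <- i
  names(ids) <- igraph::V(graph)$name
  ids
}

#' Relabel all frames with invariant object ids (backward sweep)
#'
#' After the whole sequence has been linked, every pixel's
#' super-segmentation label is replaced by its component's object id in
#' every frame, so pieces separated by dynamic occlusion share one id
#' across all frames.  Contour pixels and background keep id 0.
#'
#' @param supersegs List of per-frame [super_segmentation()] maps.
#' @param ids An [assign_object_ids()] vector.
#' @return List of integer matrices (the track maps).
#' @export
backward_relabel <- function(supersegs, ids) {
  lapply(seq_along(supersegs), function(f) {
    lab <- supersegs[[f]]$labels
    lut <- ids[paste0("f", f, ":", seq_len(supersegs[[f]]$n_components))]
    lut[is.na(lut)] <- 0L
    out <- matrix(0L, nrow(lab), ncol(lab))
    pos <- lab > 0L
    out[pos] <- as.integer(lut[lab[pos]])
    out
  })
}

# Majority predicted label over a pixel subset, ignoring unlabelled (0)
# pixels; NA when fewer than min_px labelled pixels remain.
region_majority <- function(pred, sel, min_px = 8L) {
  v <- pred[sel]
  v <- v[v > 0L]
  if (length(v) < min_px) return(NA_integer_)
  majority_label(v)  # ties broken deterministically
}

# Count per-frame per-object segmentation errors of a predicted label map
# against ground truth: an object is in error when its internal texture
# region carries a different majority label than its surface (unmerged
# texture region), or when the object's majority label coincides with
# another ground-truth region's majority label (wrongly merged).  At most
# one error is counted per object per frame.
frame_seg_errors <- function(pred, lab, tmap, n_objects) {
  whole <- vapply(seq_len(n_objects), function(k)
    region_majority(pred, lab == k), integer(1))
  bg_maj <- region_majority(pred, lab == 0L)
  errs <- 0L
  for (k in seq_len(n_objects)) {
    internal <- region_majority(pred, tmap == k)
    surface <- region_majority(pred, lab == k & tmap == 0L)
    unmerged <- !is.na(internal) && !is.na(surface) && internal != surface
    others <- c(whole[-k], bg_maj)
    wrongly <- !is.na(whole[k]) && whole[k] %in% others[!is.na(others)]
    if (unmerged || wrongly) errs <- errs + 1L
  }
  errs
}

#' Score segmentation and tracking maps against ground truth
#'
#' Segmentation errors are counted per frame per ground-truth object under
#' majority-overlap matching: one error when the object's internal texture
#' region remains unmerged from its surface, or when the object is wrongly
#' merged with another region.  `baseline_errors` applies the same count to
#' the raw super segmentation used verbatim as the segmentation.  Tracking
#' errors count (frame, object) pairs whose track-map majority id is
#' inconsistent with the object's global id.  `error_rate` is
#' `segmentation_errors / baseline_errors`.
#'
#' @param seg_labels List of per-frame segmentation label matrices.
#' @param superseg_labels List of per-frame super-segmentation label
#'   matrices (the baseline).
#' @param track_labels List of per-frame track maps (object ids), or `NULL`
#'   to skip tracking metrics.
#' @param gt A `ground_truth` from [render_sequence()].
#' @return List with `segmentation_errors`, `baseline_errors`,
#'   `tracking_errors`, `error_rate`, and `error_rate_pct`.
#' @export
evaluate_sequence <- function(seg_labels, superseg_labels, track_labels, gt) {
  n_frames <- length(gt$label_maps)
  stopifnot(length(seg_labels) == n_frames,
            length(superseg_labels) == n_frames)
  if (!all(dim(seg_labels[[1]]) == dim(gt$label_maps[[1]]))) {
    stop("prediction and ground-truth shapes differ")
  }
  n_objects <- length(gt$depth_rank)
  seg_err <- 0L; base_err <- 0L
  for (f in seq_len(n_frames)) {
    lab <- gt$label_maps[[f]]; tm <- gt$texture_maps[[f]]
    seg_err <- seg_err + frame_seg_errors(seg_labels[[f]], lab, tm, n_objects)
    base_err <- base_err + frame_seg_errors(superseg_labels[[f]], lab, tm,
                                            n_objects)
  }
  track_err <- NA_integer_
  if (!is.null(track_labels)) {
    stopifnot(length(track_labels) == n_frames)
    # global id of each object: majority track id over all frames
    global <- vapply(seq_len(n_objects), function(k) {
      v <- unlist(lapply(seq_len(n_frames), function(f) {
        x <- track_labels[[f]][gt$label_maps[[f]] == k]
        x[x > 0L]
      }))
      if (length(v) == 0L) NA_integer_ else majority_label(v)
    }, integer(1))
    track_err <- 0L
    for (f in seq_len(n_frames)) {
      lab <- gt$label_maps[[f]]; tm <- gt$texture_maps[[f]]
      for (k in seq_len(n_objects)) {
        surface <- region_majority(track_labels[[f]], lab == k & tm == 0L)
        internal <- region_majority(track_labels[[f]], tm == k)
        bad <- (!is.na(surface) && surface != global[k]) ||
          (!is.na(internal) && internal != global[k])
        if (is.na(global[k]) || bad) track_err <- track_err + 1L
      }
    }
  }
  rate <- if (base_err > 0L) seg_err / base_err else NA_real_
  list(segmentation_errors = seg_err,
       baseline_errors = base_err,
       tracking_errors = track_err,
       error_rate = rate,
       error_rate_pct = 100 * rate)
}
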