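#' Pipeline configuration
#'
#' Gathers every setting that affects pipeline results: the Gabor bank, edge
#' detection, super segmentation, classification thresholds, the sampling
#' budget and seed, solver options, and the cross-frame link vote threshold.
#'
#' @param bank A [gabor_bank_config()].
#' @param edges An [edge_params()].
#' @param superseg A [superseg_params()].
#' @param classify A [classify_params()].
#' @param n_neighborhoods Edge neighborhoods sampled per frame (default 100).
#' @param sampling_seed Integer seed for neighborhood sampling; frame `f`
#'   uses `sampling_seed + f`.
#' @param min_votes Minimum samples supporting a cross-frame link.
#' @param solver Named list of [solve_affine()] options.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(bank = gabor_bank_config(),
                            edges = edge_params(),
                            superseg = superseg_params(),
                            classify = classify_params(),
                            n_neighborhoods = 100L,
                            sampling_seed = 0L,
                            min_votes = 2L,
                            solver = list()) {
  stopifnot(inherits(bank, "gabor_bank_config"),
            inherits(edges, "edge_params"),
            inherits(superseg, "superseg_params"),
            inherits(classify, "classify_params"),
            n_neighborhoods >= 1L)
  structure(list(bank = bank, edges = edges, superseg = superseg,
                 classify = classify,
                 n_neighborhoods = as.integer(n_neighborhoods),
                 sampling_seed = as.integer(sampling_seed),
                 min_votes = as.integer(min_votes), solver = solver),
            class = "pipeline_config")
}

#' Run the full segmentation and tracking pipeline
#'
#' Executes, for every frame: edge detection, super segmentation, stratified
#' neighborhood sampling, side-wise diffeomorphism solving and edge
#' classification against the next frame (the last frame is classified
#' against its predecessor), texture-region merging into object segmentation
#' maps, cross-frame linking, scene-graph construction, and the backward
#' relabeling sweep that yields invariant track maps.  When ground truth is
#' supplied the run is scored with [evaluate_sequence()].
#'
#' @param frames A `frame_sequence` (list of numeric matrices) from
#'   [render_sequence()] or [read_frames()].
#' @param config A [pipeline_config()].
#' @param gt Optional `ground_truth` for evaluation.
#' @param verbose Print progress every 20 frames.
#' @return A `surftrack_run`: per-frame super segmentations, segmentation
#'   maps, track maps, the scene graph, object ids, the number of recovered
#'   objects, per-frame classifications, and (with `gt`) metrics.
#' @export
run_pipeline <- function(frames, config = pipeline_config(), gt = NULL,
                         verbose = FALSE) {
  n <- length(frames)
  stopifnot(n >= 2L)
  bank <- make_gabor_bank(config$bank)
  margin <- bank$half + 1L
  shift <- config$classify$shift_distance

  supersegs <- vector("list", n)
  edge_maps <- vector("list", n)
  for (f in seq_len(n)) {
    edge_maps[[f]] <- detect_edges(frames[[f]], config$edges)
    supersegs[[f]] <- super_segmentation(edge_maps[[f]], config$superseg)
  }

  classifications <- vector("list", n)
  votes <- vector("list", n)
  seg_maps <- vector("list", n)
  merges <- vector("list", n)
  border_labels <- vector("list", n)
  for (f in seq_len(n)) {
    lab <- supersegs[[f]]$labels
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border_labels[[f]] <- border[border > 0L]
    nbh <- sample_edge_neighborhoods(edge_maps[[f]], supersegs[[f]],
                                     n = config$n_neighborhoods,
                                     seed = config$sampling_seed + f,
                                     shift_distance = shift,
                                     bound_margin = margin)
    nxt <- if (f < n) f + 1L else f - 1L
    classifications[[f]] <- classify_neighborhoods(frames[[f]], frames[[nxt]],
                                                   nbh, bank,
                                                   config$classify,
                                                   config$solver)
    votes[[f]] <- aggregate_region_votes(classifications[[f]], supersegs[[f]])
    sm <- build_seg_map(supersegs[[f]], votes[[f]],
                        protect = border_labels[[f]])
    seg_maps[[f]] <- sm$labels
    merges[[f]] <- sm$merges
    if (verbose && f %% 20L == 0L) {
      message("frame ", f, "/", n, ": ", supersegs[[f]]$n_components,
              " components, ", nrow(sm$merges), " texture merges")
    }
  }

  # cross-frame links; the last frame was classified backward, so its links
  # support the final transition with roles swapped
  links <- vector("list", n - 1L)
  for (f in seq_len(n - 1L)) {
    links[[f]] <- link_frames(classifications[[f]], supersegs[[f + 1L]])
  }
  back <- link_frames(classifications[[n]], supersegs[[n - 1L]])
  if (nrow(back) > 0L) {
    swapped <- data.frame(from = back$to, to = back$from, votes = back$votes)
    pooled <- rbind(links[[n - 1L]], swapped)
    links[[n - 1L]] <- stats::aggregate(votes ~ from + to, pooled, sum)
  }

  graph <- build_scene_graph(supersegs, links, merges,
                             min_votes = config$min_votes)
  ids <- assign_object_ids(graph)
  track_maps <- backward_relabel(supersegs, ids)

  metrics <- NULL
  if (!is.null(gt)) {
    metrics <- evaluate_sequence(seg_maps,
                                 lapply(supersegs, `[[`, "labels"),
                                 track_maps, gt)
  }
  structure(list(config = config,
                 supersegs = supersegs,
                 seg_maps = seg_maps,
                 track_maps = track_maps,
                 graph = graph,
                 object_ids = ids,
                 n_objects = count_objects(graph),
                 classifications = classifications,
                 votes = votes,
                 metrics = metrics),
            class = "surftrack_run")
}

#' @export
print.surftrack_run <- function(x, ...) {
  cat("surftrack run:", length(x$seg_maps), "frames,",
      x$n_objects, "invariant objects recovered\n")
  if (!is.null(x$metrics)) {
    cat(sprintf("  segmentation errors %d / baseline %d (%.2f%%), tracking errors %d\n",
                x$metrics$segmentation_errors, x$metrics$baseline_errors,
                x$metrics$error_rate_pct, x$metrics$tracking_errors))
  }
  invisible(x)
}
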