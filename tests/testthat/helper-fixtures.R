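# Shared fixtures: band-limited textures, small scenes, and a cached run of
# the default four-object sequence (rendered and tracked once per session).

.cache <- new.env(parent = emptyenv())

# Band-limited noise texture matching the generator's contrast structure.
textured_image <- function(n = 201, seed = 1, amp = 0.035, mean = 0.5,
                           s1 = 1.2, s2 = 2.5) {
  spec <- texture_spec(mean, amplitude = amp, sigma_lo = s1, sigma_hi = s2,
                       seed = seed)
  surftrack:::noise_field(spec, n, n)
}

test_bank <- function() {
  if (is.null(.cache$bank)) .cache$bank <- make_gabor_bank()
  .cache$bank
}

# A single textured object translating at constant velocity.
translating_scene <- function(v = c(5, 0), n_frames = 8, seed = 3,
                              motion = NULL) {
  if (is.null(motion)) motion <- motion_translation(n_frames, v)
  scene_config(
    n_frames, c(160, 220),
    texture_spec(0.1, seed = seed),
    list(object_spec(home = c(80, 80), depth_rank = 1,
                     silhouette = blob_shape(30, c(0.01, -0.008), c(0.3, 1.1)),
                     surface_texture = texture_spec(0.55, seed = seed + 1),
                     internal_texture = texture_spec(0.42, seed = seed + 2),
                     internal_shape = blob_shape(10),
                     motion = motion)),
    rng_seed = seed)
}

# First frames of the default scene (same random draws as the full config).
demo_scene <- function(n_frames = 6) {
  key <- paste0("demo", n_frames)
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- render_sequence(make_default_config(0,
                                                         frame_count = n_frames))
  }
  .cache[[key]]
}

# The full default 160-frame sequence, rendered and run through the whole
# pipeline once; shared across the acceptance checks.
default_run <- function() {
  if (is.null(.cache$run)) {
    sc <- render_sequence(make_default_config(0))
    run <- run_pipeline(sc$frames, pipeline_config(sampling_seed = 1),
                        gt = sc$gt)
    .cache$scene <- sc
    .cache$run <- run
  }
  list(scene = .cache$scene, run = .cache$run)
}

# Ground-truth edge type near a sampled edge pixel (0-based coordinates).
gt_kind_at <- function(edge_type_map, x, y) {
  rows <- max(1, y):min(nrow(edge_type_map), y + 3)
  cols <- max(1, x):min(ncol(edge_type_map), x + 3)
  win <- edge_type_map[rows, cols]
  if (any(win == 2)) "occluding" else if (any(win == 1)) "texture"
  else NA_character_
}

# Ground-truth owner id near a sampled edge pixel.
gt_owner_at <- function(owner_map, x, y) {
  rows <- max(1, y):min(nrow(owner_map), y + 3)
  cols <- max(1, x):min(ncol(owner_map), x + 3)
  o <- owner_map[rows, cols]
  o <- o[o > 0]
  if (length(o) == 0) return(NA_integer_)
  as.integer(names(which.max(table(o))))
}

# Per-sample classification accuracy of a pipeline run against ground truth.
classification_accuracy <- function(run, gt) {
  kind_ok <- 0L; kind_n <- 0L; own_ok <- 0L; own_n <- 0L
  for (f in seq_along(run$classifications)) {
    cl <- run$classifications[[f]]
    et <- gt$edge_type_maps[[f]]
    ow <- gt$owner_maps[[f]]
    lab <- gt$label_maps[[f]]
    for (i in seq_len(nrow(cl))) {
      gtk <- gt_kind_at(et, cl$x[i], cl$y[i])
      if (is.na(gtk) || cl$kind[i] == "ambiguous") next
      kind_n <- kind_n + 1L
      if (cl$kind[i] == gtk) kind_ok <- kind_ok + 1L
      if (cl$kind[i] == "occluding" && gtk == "occluding" &&
          cl$owner[i] != "none") {
        gown <- gt_owner_at(ow, cl$x[i], cl$y[i])
        if (is.na(gown)) next
        side_lab <- if (cl$owner[i] == "left") {
          lab[cl$ly[i] + 1, cl$lx[i] + 1]
        } else {
          lab[cl$ry[i] + 1, cl$rx[i] + 1]
        }
        own_n <- own_n + 1L
        if (side_lab == gown) own_ok <- own_ok + 1L
      }
    }
  }
  list(kind = kind_ok / kind_n, kind_n = kind_n,
       owner = own_ok / own_n, owner_n = own_n)
}
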