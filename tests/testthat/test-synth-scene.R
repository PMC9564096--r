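test_that("the default configuration reproduces the study conditions deterministically", {
  cfg <- make_default_config(0)
  expect_equal(cfg$frame_count, 160L)
  expect_length(cfg$objects, 4L)
  for (ob in cfg$objects) {
    expect_s3_class(ob$internal_shape, "blob_shape")  # one internal contour each
  }
  expect_identical(cfg, make_default_config(0))
  expect_false(identical(make_default_config(1), cfg))
  # motion sequences differ across seeds
  m0 <- unclass(cfg$objects[[1]]$motion[[50]])
  m1 <- unclass(make_default_config(1)$objects[[1]]$motion[[50]])
  expect_false(isTRUE(all.equal(m0, m1)))
})

test_that("identity motions render every frame identical to the first", {
  cfg <- translating_scene(motion = motion_identity(4), n_frames = 4)
  sc <- render_sequence(cfg)
  expect_identical(sc$frames[[2]], sc$frames[[1]])
  expect_identical(sc$frames[[4]], sc$frames[[1]])
  expect_identical(sc$gt$label_maps[[3]], sc$gt$label_maps[[1]])
})

test_that("a pure translation advances the object-mask centroid accordingly", {
  sc <- render_sequence(translating_scene(v = c(5, 0), n_frames = 6))
  cents <- sapply(sc$gt$label_maps, function(m) {
    idx <- which(m == 1L, arr.ind = TRUE)
    c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)  # (x, y), 0-based
  })
  dx <- diff(cents[1, ])
  dy <- diff(cents[2, ])
  expect_equal(unname(dx), rep(5, 5), tolerance = 0.05)
  expect_lt(max(abs(dy)), 0.25)
})

test_that("rendering is bit-identical for identical configurations", {
  sc1 <- render_sequence(translating_scene(n_frames = 3))
  sc2 <- render_sequence(translating_scene(n_frames = 3))
  expect_identical(sc1$frames, sc2$frames)
  expect_identical(sc1$gt$label_maps, sc2$gt$label_maps)
  expect_identical(sc1$gt$edge_type_maps, sc2$gt$edge_type_maps)
})

test_that("an object transformed outside the frame raises a named error", {
  cfg <- translating_scene(v = c(40, 0), n_frames = 8)
  expect_error(render_sequence(cfg), "object 1.*outside the frame at frame")
})

test_that("painter consistency: labels equal the nearest covering object", {
  # render the two-object prefix of the default scene and compare against
  # each object's solo rendering
  cfg <- make_default_config(2, frame_count = 4)
  sc <- render_sequence(cfg)
  masks <- lapply(1:4, function(k) {
    solo <- cfg
    solo$objects <- cfg$objects[k]
    render_sequence(solo)$gt$label_maps
  })
  for (f in c(1, 4)) {
    lab <- sc$gt$label_maps[[f]]
    expect_true(all(dim(lab) == dim(masks[[1]][[f]])))
    nearest <- matrix(0L, nrow(lab), ncol(lab))
    for (k in 4:1) nearest[masks[[k]][[f]] > 0L] <- k  # lower rank painted last
    expect_identical(lab, nearest)
  }
})

test_that("ground-truth edge types are consistent with the label maps", {
  sc <- demo_scene(4)
  for (f in c(1, 3)) {
    lab <- sc$gt$label_maps[[f]]
    et <- sc$gt$edge_type_maps[[f]]
    ow <- sc$gt$owner_maps[[f]]
    occ <- which(et == 2L, arr.ind = TRUE)
    # occluding pixels touch two different labels; owners are the nearer side
    differs <- mapply(function(r, c) {
      nb <- c(if (r > 1) lab[r - 1, c], if (r < nrow(lab)) lab[r + 1, c],
              if (c > 1) lab[r, c - 1], if (c < ncol(lab)) lab[r, c + 1])
      any(nb != lab[r, c])
    }, occ[, 1], occ[, 2])
    expect_true(all(differs))
    expect_true(all(ow[et == 2L] > 0L))
    expect_true(all(ow[et != 2L] == 0L))
    # texture-edge pixels are strictly interior to one label
    tex <- which(et == 1L, arr.ind = TRUE)
    interior <- mapply(function(r, c) {
      nb <- c(lab[r - 1, c], lab[r + 1, c], lab[r, c - 1], lab[r, c + 1])
      all(nb == lab[r, c])
    }, tex[, 1], tex[, 2])
    expect_true(all(interior))
  }
})

test_that("configurations fail fast on invalid inputs", {
  expect_error(make_default_config(0, frame_count = 1), "frame_count >= 2")
  expect_error(translating_scene(motion = motion_identity(3), n_frames = 5),
               "motion length")
  expect_error(
    object_spec(home = c(50, 50), depth_rank = 1,
                silhouette = blob_shape(20),
                surface_texture = texture_spec(0.5),
                internal_texture = texture_spec(0.3),
                internal_shape = blob_shape(25),
                motion = motion_identity(2)),
    "strictly inside")
})
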