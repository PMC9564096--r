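toy_superseg <- function(labels) {
  structure(list(labels = labels, n_components = max(labels),
                 adjacency = matrix(integer(0), 0, 2)),
            class = "superseg_map")
}

test_that("segmentation maps equal the super segmentation when nothing is texture", {
  lab <- matrix(rep(1:2, each = 50), 10, 10)
  ss <- toy_superseg(lab)
  votes <- data.frame(label = 1:2, texture_count = 0L, owner_count = c(1L, 2L),
                      sampled = TRUE, is_pure_texture = FALSE,
                      texture_partner = NA_integer_)
  sm <- build_seg_map(ss, votes)
  expect_identical(sm$labels, lab)
  expect_equal(nrow(sm$merges), 0L)
})

test_that("nested texture regions collapse outward to a fixpoint", {
  lab <- matrix(3L, 20, 20)
  lab[5:16, 5:16] <- 2L
  lab[9:12, 9:12] <- 1L
  ss <- toy_superseg(lab)
  votes <- data.frame(label = 1:3, texture_count = c(3L, 4L, 2L),
                      owner_count = c(0L, 0L, 1L), sampled = TRUE,
                      is_pure_texture = c(TRUE, TRUE, FALSE),
                      texture_partner = c(2L, 3L, NA))
  sm <- build_seg_map(ss, votes)
  expect_true(all(sm$labels == 3L))
  expect_setequal(sm$mapping, c(3L, 3L, 3L))
  # labels are conserved: nothing outside the input label set appears
  expect_true(all(sm$labels %in% lab))
})

test_that("a pure-texture region without a partner or under protection stays unmerged", {
  lab <- matrix(2L, 12, 12); lab[4:9, 4:9] <- 1L
  ss <- toy_superseg(lab)
  votes <- data.frame(label = 1:2, texture_count = c(2L, 0L),
                      owner_count = 0L, sampled = c(TRUE, FALSE),
                      is_pure_texture = c(TRUE, FALSE),
                      texture_partner = c(NA_integer_, NA_integer_))
  expect_identical(build_seg_map(ss, votes)$labels, lab)
  votes$texture_partner[1] <- 2L
  expect_true(all(build_seg_map(ss, votes)$labels == 2L))
  expect_identical(build_seg_map(ss, votes, protect = 1L)$labels, lab)
})

test_that("cross-frame links follow converged transforms and respect vote thresholds", {
  lab2 <- matrix(1L, 40, 60); lab2[, 31:60] <- 2L
  ss2 <- toy_superseg(lab2)
  cl <- data.frame(kind = c("texture", "texture", "occluding", "occluding"),
                   owner = c("none", "none", "left", "none"),
                   conv_left = TRUE, conv_right = c(TRUE, TRUE, TRUE, FALSE),
                   lx = c(10, 12, 40, 40), ly = c(10, 12, 20, 22),
                   rx = c(40, 42, 10, 12), ry = c(10, 12, 20, 22),
                   left_label = c(1L, 1L, 2L, 2L), right_label = c(2L, 2L, 1L, 1L),
                   l_tx = 0, l_ty = 0, r_tx = 0, r_ty = 0)
  links <- link_frames(cl, ss2)
  # texture rows link both sides; the owned occluding row links its owner side
  expect_setequal(paste(links$from, links$to),
                  c("1 1", "2 2"))
  expect_equal(links$votes[links$from == 1L], 2L)
  expect_equal(links$votes[links$from == 2L], 3L)
  # undecided or unconverged sides emit nothing extra
  cl_none <- cl[4, ]
  expect_equal(nrow(link_frames(cl_none, ss2)), 0L)
})

test_that("the scene graph of a static object links it across frames", {
  lab <- matrix(1L, 30, 40); lab[10:20, 15:25] <- 2L
  ss <- toy_superseg(lab)
  links <- list(data.frame(from = 2L, to = 2L, votes = 5L))
  merges <- list(NULL, NULL)
  g <- build_scene_graph(list(ss, ss), links, merges)
  expect_equal(count_objects(g), 1L)
  ids <- assign_object_ids(g)
  expect_equal(unname(ids[c("f1:2", "f2:2")]), c(1L, 1L))
  expect_equal(unname(ids[c("f1:1", "f2:1")]), c(0L, 0L))  # border component
  # dropping the cross-frame link splits the object into per-frame components
  g0 <- build_scene_graph(list(ss, ss), list(data.frame(from = integer(0),
                                                        to = integer(0),
                                                        votes = integer(0))),
                          merges)
  expect_equal(count_objects(g0), 2L)
  # graph monotonicity: adding a link never increases the component count
  expect_lte(igraph::count_components(g), igraph::count_components(g0))
})

test_that("links below the vote threshold are ignored", {
  lab <- matrix(1L, 30, 40); lab[10:20, 5:15] <- 2L; lab[10:20, 25:35] <- 3L
  ss <- toy_superseg(lab)
  links <- list(data.frame(from = c(2L, 3L), to = c(2L, 3L), votes = c(5L, 1L)))
  g <- build_scene_graph(list(ss, ss), links, list(NULL, NULL), min_votes = 2L)
  expect_equal(count_objects(g), 3L)  # object 3 unlinked -> two components
})

test_that("object ids are deterministic and the backward sweep applies them everywhere", {
  lab1 <- matrix(1L, 30, 40); lab1[5:15, 5:15] <- 2L; lab1[18:28, 20:30] <- 3L
  lab2 <- matrix(1L, 30, 40); lab2[6:16, 6:16] <- 3L; lab2[17:27, 19:29] <- 2L
  ss1 <- toy_superseg(lab1); ss2 <- toy_superseg(lab2)
  links <- list(data.frame(from = c(2L, 3L), to = c(3L, 2L), votes = 5L))
  g <- build_scene_graph(list(ss1, ss2), links, list(NULL, NULL))
  ids <- assign_object_ids(g)
  expect_equal(unname(ids["f1:2"]), unname(ids["f2:3"]))
  expect_equal(unname(ids["f1:3"]), unname(ids["f2:2"]))
  expect_setequal(unname(ids[c("f1:2", "f1:3")]), c(1L, 2L))
  tm <- backward_relabel(list(ss1, ss2), ids)
  expect_equal(tm[[1]][10, 10], ids[["f1:2"]])
  expect_equal(tm[[2]][10, 10], ids[["f2:3"]])
  expect_equal(tm[[1]][1, 1], 0L)
  # static scene: identical track maps in both frames
  gs <- build_scene_graph(list(ss1, ss1),
                          list(data.frame(from = c(2L, 3L), to = c(2L, 3L),
                                          votes = 5L)),
                          list(NULL, NULL))
  tms <- backward_relabel(list(ss1, ss1), assign_object_ids(gs))
  expect_identical(tms[[1]], tms[[2]])
})

test_that("evaluation scores perfect maps as error-free and is id-permutation invariant", {
  sc <- demo_scene(3)
  gt <- sc$gt
  gt3 <- list(label_maps = gt$label_maps[1:3],
              texture_maps = gt$texture_maps[1:3],
              depth_rank = gt$depth_rank)
  class(gt3) <- "ground_truth"
  perfect_seg <- gt3$label_maps
  m <- evaluate_sequence(perfect_seg, perfect_seg, perfect_seg, gt3)
  expect_equal(m$segmentation_errors, 0L)
  expect_equal(m$tracking_errors, 0L)
  permuted <- lapply(perfect_seg, function(x) {
    y <- x; y[x == 1L] <- 4L; y[x == 4L] <- 1L; y
  })
  m2 <- evaluate_sequence(perfect_seg, perfect_seg, permuted, gt3)
  expect_equal(m2$tracking_errors, 0L)
  expect_error(
    evaluate_sequence(list(matrix(0L, 2, 2)), list(matrix(0L, 2, 2)), NULL,
                      gt3),
    "length|shapes")
})

test_that("an unmerged internal texture region counts as exactly one error per frame", {
  sc <- demo_scene(3)
  gt <- sc$gt
  gt1 <- list(label_maps = gt$label_maps[1], texture_maps = gt$texture_maps[1],
              depth_rank = gt$depth_rank)
  class(gt1) <- "ground_truth"
  # super segmentation verbatim: internal regions split from their surfaces
  ss <- super_segmentation(detect_edges(sc$frames[[1]]))
  m <- evaluate_sequence(list(ss$labels), list(ss$labels), NULL, gt1)
  expect_equal(m$baseline_errors, 4L)
  expect_equal(m$segmentation_errors, 4L)
})
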