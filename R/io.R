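#' Write and read frame sequences
#'
#' Frames are written as zero-padded 8-bit grayscale PNGs plus a JSON
#' manifest.  `read_frames()` accepts 8-bit gray or RGB PNGs; RGB is
#' converted to luminance with the Rec. 601 weights (0.299, 0.587, 0.114).
#'
#' @param frames A `frame_sequence` or list of numeric matrices in `[0, 1]`.
#' @param dir Output directory (created if missing).
#' @return `write_frames()` returns the manifest path invisibly;
#'   `read_frames()` returns a `frame_sequence`.
#' @export
write_frames <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("frame_%04d.png", seq_along(frames))
  for (i in seq_along(frames)) {
    png::writePNG(frames[[i]], file.path(dir, files[i]))
  }
  manifest <- list(n_frames = length(frames),
                   height = nrow(frames[[1]]), width = ncol(frames[[1]]),
                   files = files)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  files <- if (file.exists(mpath)) {
    unlist(jsonlite::read_json(mpath)$files)
  } else {
    sort(list.files(dir, pattern = "\\.png$"))
  }
  if (length(files) == 0L) stop("no frames found in ", dir)
  missing <- files[!file.exists(file.path(dir, files))]
  if (length(missing)) {
    stop("missing frames: ", paste(missing, collapse = ", "))
  }
  frames <- lapply(files, function(f) {
    img <- png::readPNG(file.path(dir, f))
    if (length(dim(img)) == 3L) {
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    }
    img
  })
  structure(frames, class = "frame_sequence",
            height = nrow(frames[[1]]), width = ncol(frames[[1]]))
}

#' Write and read integer label maps
#'
#' Label maps (ground truth, super segmentation, segmentation, tracking) are
#' stored as 16-bit grayscale TIFFs.
#'
#' @param maps List of integer matrices (values in `[0, 65535]`).
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return `write_label_maps()` returns the file names invisibly;
#'   `read_label_maps()` returns a list of integer matrices.
#' @export
write_label_maps <- function(maps, dir, prefix = "labels") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s_%04d.tif", prefix, seq_along(maps))
  for (i in seq_along(maps)) {
    tiff::writeTIFF(maps[[i]] / 65535, file.path(dir, files[i]),
                    bits.per.sample = 16L)
  }
  invisible(files)
}

#' @rdname write_label_maps
#' @export
read_label_maps <- function(dir, prefix = "labels") {
  files <- sort(list.files(dir, pattern = paste0("^", prefix,
                                                 "_[0-9]+\\.tif$")))
  lapply(files, function(f) {
    m <- tiff::readTIFF(file.path(dir, f))
    matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  })
}

#' Write and read ground truth
#'
#' @param gt A `ground_truth` from [render_sequence()].
#' @param dir Output directory.
#' @return `read_ground_truth()` returns a `ground_truth`.
#' @export
write_ground_truth <- function(gt, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_label_maps(gt$label_maps, dir, "label")
  write_label_maps(gt$edge_type_maps, dir, "edgetype")
  write_label_maps(gt$owner_maps, dir, "owner")
  write_label_maps(gt$texture_maps, dir, "texture")
  jsonlite::write_json(list(depth_rank = gt$depth_rank),
                       file.path(dir, "gt.json"), auto_unbox = FALSE)
  invisible(dir)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "gt.json"),
                              simplifyVector = TRUE)
  structure(list(label_maps = read_label_maps(dir, "label"),
                 edge_type_maps = read_label_maps(dir, "edgetype"),
                 owner_maps = read_label_maps(dir, "owner"),
                 texture_maps = read_label_maps(dir, "texture"),
                 depth_rank = as.integer(meta$depth_rank)),
            class = "ground_truth")
}

#' Round-trip configurations through YAML
#'
#' Both [scene_config()] and [pipeline_config()] objects serialise to plain
#' YAML and back without loss.
#'
#' @param config A `scene_config` or `pipeline_config`.
#' @param path YAML file path.
#' @return `read_config()` returns the restored object.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path, precision = 12L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  config_from_list(yaml::read_yaml(path))
}

config_to_list <- function(x) {
  if (inherits(x, "affine_params")) {
    return(list(.class = "affine_params", values = as.numeric(x)))
  }
  if (is.list(x)) {
    out <- lapply(x, config_to_list)
    cls <- class(x)[1]
    if (cls != "list") out$.class <- cls
    return(out)
  }
  x
}

config_from_list <- function(x) {
  if (!is.list(x)) return(x)
  cls <- x$.class
  x$.class <- NULL
  if (!is.null(cls) && cls == "affine_params") {
    v <- as.numeric(unlist(x$values))
    return(affine_params(v[1], v[2], v[3], v[4], v[5], v[6]))
  }
  out <- lapply(x, config_from_list)
  # restore vectors flattened by YAML
  out <- lapply(out, function(e) {
    if (is.list(e) && length(e) > 0L && is.null(names(e)) &&
        all(vapply(e, function(z) is.numeric(z) && length(z) == 1L, TRUE))) {
      unlist(e)
    } else e
  })
  if (!is.null(cls)) {
    class(out) <- cls
    if (cls == "scene_config") {
      out$frame_count <- as.integer(out$frame_count)
      out$frame_size <- as.integer(out$frame_size)
      out$rng_seed <- as.integer(out$rng_seed)
    }
    if (cls == "blob_shape") {
      # empty harmonic vectors come back from YAML as empty lists
      out$harm_amp <- as.numeric(unlist(out$harm_amp))
      out$harm_phase <- as.numeric(unlist(out$harm_phase))
    }
  }
  out
}

#' Export a scene graph
#'
#' Writes the graph as JSON (nodes with frame/component/background flags,
#' edges with their tag) and, optionally, GraphML.
#'
#' @param graph A [build_scene_graph()] result.
#' @param json_path Output JSON path.
#' @param graphml_path Optional GraphML path.
#' @return The JSON path, invisibly.
#' @export
write_scene_graph <- function(graph, json_path, graphml_path = NULL) {
  nodes <- data.frame(name = igraph::V(graph)$name,
                      frame = igraph::V(graph)$frame,
                      comp = igraph::V(graph)$comp,
                      background = igraph::V(graph)$background)
  el <- igraph::as_edgelist(graph)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      tag = igraph::E(graph)$tag)
  jsonlite::write_json(list(nodes = nodes, edges = edges), json_path,
                       auto_unbox = TRUE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(graph, graphml_path, format = "graphml")
  }
  invisible(json_path)
}

#' Write run metrics as JSON
#'
#' @param metrics An [evaluate_sequence()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
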