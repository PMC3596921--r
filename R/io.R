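# File interchange: Wavefront OBJ and binary little-endian PLY meshes,
# 8-bit PNG masks, JSON key points / senescence specs / schedules, CSV
# population histories. Writers and readers round-trip exactly.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write a mesh to OBJ or binary PLY
#'
#' OBJ uses 1-based indices with one `v x y z` line per vertex, one `vt u v`
#' line per vertex and `f a/a b/b c/c` faces; coordinates are printed with
#' 17 significant digits so the round trip through [read_mesh()] is
#' bit-exact. PLY is binary little-endian with double-precision vertex
#' positions and texture coordinates.
#'
#' @param mesh A [tri_mesh()].
#' @param path Output file path.
#' @param format `"obj"` or `"ply"`; defaults to the file extension.
#' @param positions Optional n x 3 matrix overriding vertex positions (e.g.
#'   a deformation snapshot); by default the mesh's 2D vertices are written
#'   with z = 0.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, positions = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (!format %in% c("obj", "ply")) {
    stop(sprintf("unknown mesh format '%s' (use obj or ply)", format),
         call. = FALSE)
  }
  P <- if (is.null(positions)) cbind(mesh$vertices, 0) else as.matrix(positions)
  if (ncol(P) == 2) P <- cbind(P, 0)
  if (nrow(P) != nrow(mesh$vertices) || ncol(P) != 3) {
    stop("positions must be an n x 3 matrix matching the mesh", call. = FALSE)
  }
  uv <- mesh$uv
  tris <- mesh$triangles
  if (format == "obj") {
    lines <- c(
      "# leafcycle mesh",
      sprintf("v %s %s %s", fmt_num(P[, 1]), fmt_num(P[, 2]), fmt_num(P[, 3])),
      sprintf("vt %s %s", fmt_num(uv[, 1]), fmt_num(uv[, 2])),
      sprintf("f %d/%d %d/%d %d/%d",
              tris[, 1], tris[, 1], tris[, 2], tris[, 2], tris[, 3], tris[, 3])
    )
    writeLines(lines, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- c(
      "ply",
      "format binary_little_endian 1.0",
      sprintf("element vertex %d", nrow(P)),
      "property double x", "property double y", "property double z",
      "property double s", "property double t",
      sprintf("element face %d", nrow(tris)),
      "property list uchar int vertex_indices",
      "end_header"
    )
    writeChar(paste0(paste(header, collapse = "\n"), "\n"), con, eos = NULL)
    writeBin(as.vector(t(cbind(P, uv))), con, size = 8, endian = "little")
    for (r in seq_len(nrow(tris))) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(tris[r, ] - 1L), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' Read a mesh written by [write_mesh()]
#'
#' @param path OBJ or PLY file path.
#' @param format `"obj"` or `"ply"`; defaults to the file extension.
#' @return A [tri_mesh()]. When the file stores deformed 3D positions the
#'   returned mesh carries the x/y coordinates and the full n x 3 positions
#'   in the attribute `positions`.
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (format == "obj") {
    lines <- readLines(path)
    vs <- strsplit(grep("^v ", lines, value = TRUE), " +")
    vts <- strsplit(grep("^vt ", lines, value = TRUE), " +")
    fs <- strsplit(grep("^f ", lines, value = TRUE), "[ /]+")
    P <- do.call(rbind, lapply(vs, function(x) as.numeric(x[2:4])))
    uv <- do.call(rbind, lapply(vts, function(x) as.numeric(x[2:3])))
    tris <- do.call(rbind, lapply(fs, function(x) as.integer(x[c(2, 4, 6)])))
  } else if (format == "ply") {
    raw <- readBin(path, "raw", n = file.size(path))
    marker <- charToRaw("end_header\n")
    hit <- NULL
    limit <- min(length(raw) - length(marker) + 1L, 4096L)
    for (off in seq_len(limit)) {
      if (all(raw[off:(off + length(marker) - 1L)] == marker)) {
        hit <- off
        break
      }
    }
    if (is.null(hit)) stop("malformed PLY header", call. = FALSE)
    header <- strsplit(rawToChar(raw[seq_len(hit - 1L)]), "\n")[[1]]
    con <- rawConnection(raw[(hit + length(marker)):length(raw)])
    on.exit(close(con))
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                     header, value = TRUE)))
    nf <- as.integer(sub("element face ", "", grep("^element face",
                                                   header, value = TRUE)))
    vals <- matrix(readBin(con, "double", n = nv * 5L, size = 8,
                           endian = "little"),
                   nrow = nv, byrow = TRUE)
    P <- vals[, 1:3, drop = FALSE]
    uv <- vals[, 4:5, drop = FALSE]
    tris <- matrix(0L, nf, 3)
    for (r in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", n = 1))
      if (cnt != 3L) stop("only triangle faces are supported", call. = FALSE)
      tris[r, ] <- readBin(con, "integer", n = 3, size = 4,
                           endian = "little") + 1L
    }
  } else {
    stop(sprintf("unknown mesh format '%s' (use obj or ply)", format),
         call. = FALSE)
  }
  mesh <- tri_mesh(P[, 1:2, drop = FALSE], tris, uv = uv)
  if (any(P[, 3] != 0)) attr(mesh, "positions") <- P
  mesh
}

#' Read a grayscale mask map from a PNG file
#'
#' Multi-channel images are converted to 8-bit grayscale by integer luma:
#' `round(0.299 R + 0.587 G + 0.114 B)` on the 0..255 channel values; an
#' alpha channel, if present, is ignored.
#'
#' @param path PNG file path.
#' @return A [mask_map()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  img <- tryCatch(png::readPNG(path),
                  error = function(e) {
                    stop(sprintf("cannot read PNG '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  if (length(dim(img)) == 2) {
    gray <- round(img * 255)
  } else {
    ch <- dim(img)[3]
    if (ch == 2) {            # gray + alpha
      gray <- round(img[, , 1] * 255)
    } else {
      r <- round(img[, , 1] * 255)
      g <- round(img[, , 2] * 255)
      b <- round(img[, , 3] * 255)
      gray <- round(0.299 * r + 0.587 * g + 0.114 * b)
    }
  }
  mask_map(gray)
}

#' Write a mask map as an 8-bit grayscale PNG
#'
#' @param mask A [mask_map()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask_map"))
  png::writePNG(mask$pixels / 255, path)
  invisible(path)
}

#' Read key points from JSON or two-column text
#'
#' Accepts either the JSON dialect `{"points": [[x, y], ...]}` or
#' whitespace-delimited two-column text.
#'
#' @param path Input file path.
#' @return A [key_point_set()].
#' @export
read_key_points <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  first <- readLines(path, n = 1)
  if (grepl("^\\s*\\{", first)) {
    obj <- jsonlite::fromJSON(path)
    key_point_set(obj$points)
  } else {
    key_point_set(as.matrix(utils::read.table(path)))
  }
}

#' Write key points as JSON
#'
#' @param key_points A [key_point_set()] or coordinate matrix.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_key_points <- function(key_points, path) {
  pts <- if (inherits(key_points, "key_point_set")) key_points$points else {
    as.matrix(key_points)
  }
  jsonlite::write_json(list(points = pts), path, digits = NA)
  invisible(path)
}

#' Read a senescence specification from JSON
#'
#' Expects `{"states": [{"name", "texture_label", "snapshot"}, ...],
#' "tau_corners": {state: [4 numbers]}, "X_corners": {"i->j": [4 numbers]},
#' "absorbing": [names]}` with corner order dry-cold, dry-warm, wet-cold,
#' wet-warm.
#'
#' @param path JSON file path.
#' @return A [senescence_spec()].
#' @export
read_senescence_spec <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  states <- obj$states
  names_ <- if (is.data.frame(states)) states$name else as.character(states)
  n <- length(names_)
  tau <- matrix(0, n, 4)
  for (i in seq_len(n)) tau[i, ] <- as.numeric(obj$tau_corners[[names_[i]]])
  X <- array(0, dim = c(n, n, 4))
  for (key in names(obj$X_corners)) {
    ij <- strsplit(key, "->", fixed = TRUE)[[1]]
    i <- match(trimws(ij[1]), names_)
    j <- match(trimws(ij[2]), names_)
    if (is.na(i) || is.na(j)) {
      stop(sprintf("X_corners key '%s' names unknown states", key),
           call. = FALSE)
    }
    X[i, j, ] <- as.numeric(obj$X_corners[[key]])
  }
  absorbing <- if (is.null(obj$absorbing)) character(0) else {
    as.character(obj$absorbing)
  }
  senescence_spec(states, tau, X, absorbing = absorbing)
}

#' Write a senescence specification as JSON
#'
#' @param spec A [senescence_spec()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_senescence_spec <- function(spec, path) {
  stopifnot(inherits(spec, "senescence_spec"))
  n <- length(spec$states)
  tau <- stats::setNames(
    lapply(seq_len(n), function(i) spec$tau_corners[i, ]), spec$states)
  X <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && any(spec$X_corners[i, j, ] > 0)) {
        X[[paste0(spec$states[i], "->", spec$states[j])]] <- spec$X_corners[i, j, ]
      }
    }
  }
  states <- lapply(seq_len(n), function(i) {
    s <- list(name = spec$states[i], texture_label = spec$texture_labels[i])
    if (!is.na(spec$snapshots[i])) s$snapshot <- spec$snapshots[i]
    s
  })
  jsonlite::write_json(
    list(states = states, tau_corners = tau, X_corners = X,
         absorbing = spec$states[spec$absorbing]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an environment schedule from JSON
#'
#' Expects a JSON list of `{"temperature", "humidness", "duration"}` epochs.
#'
#' @param path JSON file path.
#' @return A list of epochs usable by [evolve_population()].
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- jsonlite::fromJSON(path)
  lapply(seq_len(nrow(df)), function(k) {
    list(env = leaf_env(df$temperature[k], df$humidness[k]),
         duration = df$duration[k])
  })
}

#' Write a population history as CSV
#'
#' Long format with header `epoch,state,count`; epoch 0 is the initial
#' distribution.
#'
#' @param pop An evolved [leaf_population()] (with non-null history).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(pop, path) {
  stopifnot(inherits(pop, "leaf_population"))
  if (is.null(pop$history)) stop("population has no history yet", call. = FALSE)
  h <- pop$history
  df <- data.frame(
    epoch = rep(seq_len(nrow(h)) - 1L, each = ncol(h)),
    state = rep(colnames(h), nrow(h)),
    count = as.vector(t(h))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
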