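# File interfaces. Meshes travel as PLY (ascii written; ascii and
# binary-little-endian read) or OBJ, with region labels, landmark indices
# and pedicle axes in a sidecar JSON keyed by vertex index. Shape models
# serialize to a single versioned JSON archive.

#' Write a mesh as ascii PLY
#'
#' @param mesh a [labeled_mesh].
#' @param path output `.ply` path.
#' @param sidecar write `<path>.json` with labels/landmarks/axes when the
#'   mesh carries them.
#' @return the path, invisibly.
#' @export
write_ply <- function(mesh, path, sidecar = TRUE) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", n),
               "property double x", "property double y", "property double z",
               paste("element face", m),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(mesh$vertices, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  if (sidecar) write_mesh_sidecar(mesh, paste0(path, ".json"))
  invisible(path)
}

write_mesh_sidecar <- function(mesh, path) {
  meta <- list(region_labels = mesh$region_labels,
               landmark_indices = as.list(mesh$landmark_indices),
               pedicle_axes = mesh$pedicle_axes)
  jsonlite::write_json(meta, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

read_mesh_sidecar <- function(path) {
  if (!file.exists(path)) return(NULL)
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(meta$landmark_indices))
    meta$landmark_indices <- unlist(meta$landmark_indices)
  if (!is.null(meta$pedicle_axes))
    meta$pedicle_axes <- lapply(meta$pedicle_axes, function(ax)
      list(p0 = as.numeric(ax$p0), p1 = as.numeric(ax$p1)))
  meta
}

#' Read a PLY mesh (ascii or binary little-endian)
#'
#' @param path `.ply` path; a sidecar `<path>.json` is picked up when
#'   present.
#' @param validate run [validate_mesh].
#' @return a [labeled_mesh].
#' @export
read_ply <- function(path, validate = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ln <- readBinLine(con)
    header <- c(header, ln)
    if (ln == "end_header") break
    if (length(header) > 200) stop("PLY header not terminated")
  }
  fmt <- grep("^format", header, value = TRUE)[1]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", header, value = TRUE)[1]))
  vprops <- grep("^property (float|double)", header, value = TRUE)
  nprop <- length(vprops)
  dbl <- grepl("double", vprops[1])
  if (grepl("ascii", fmt)) {
    txt <- readLines(con)
    vl <- strsplit(trimws(txt[seq_len(nv)]), "\\s+")
    V <- t(vapply(vl, function(x) as.numeric(x[1:3]), numeric(3)))
    fl <- strsplit(trimws(txt[nv + seq_len(nf)]), "\\s+")
    F <- t(vapply(fl, function(x) as.integer(x[2:4]), integer(3))) + 1L
  } else if (grepl("binary_little_endian", fmt)) {
    sz <- if (dbl) 8L else 4L
    raw_v <- readBin(con, "double", n = nv * nprop, size = sz, endian = "little")
    V <- matrix(raw_v, ncol = nprop, byrow = TRUE)[, 1:3, drop = FALSE]
    F <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", n = 1L))
      idx <- readBin(con, "integer", n = cnt, size = 4L, endian = "little")
      if (cnt != 3L) stop("only triangular PLY faces are supported")
      F[i, ] <- idx + 1L
    }
  } else stop("unsupported PLY format: ", fmt)
  meta <- read_mesh_sidecar(paste0(path, ".json"))
  labeled_mesh(V, F, region_labels = meta$region_labels,
               landmark_indices = meta$landmark_indices,
               pedicle_axes = meta$pedicle_axes, validate = validate)
}

readBinLine <- function(con) {
  out <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0 || b == as.raw(10)) break
    out <- c(out, b)
  }
  sub("\r$", "", rawToChar(out))
}

#' Write / read a mesh as Wavefront OBJ
#' @param mesh a [labeled_mesh]; `path` the `.obj` path.
#' @param sidecar write/read `<path>.json` metadata.
#' @param validate run [validate_mesh] on read.
#' @return `read_obj` returns a [labeled_mesh].
#' @export
write_obj <- function(mesh, path, sidecar = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("v",
                   format(mesh$vertices[, 1], digits = 17, trim = TRUE),
                   format(mesh$vertices[, 2], digits = 17, trim = TRUE),
                   format(mesh$vertices[, 3], digits = 17, trim = TRUE)), con)
  writeLines(paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  if (sidecar) write_mesh_sidecar(mesh, paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path, validate = TRUE) {
  txt <- readLines(path)
  vl <- txt[startsWith(txt, "v ")]
  fl <- txt[startsWith(txt, "f ")]
  V <- t(vapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                function(x) as.numeric(x[x != ""][1:3]), numeric(3)))
  F <- t(vapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"), function(x) {
    x <- x[x != ""]
    as.integer(vapply(strsplit(x, "/"), `[[`, character(1), 1))[1:3]
  }, integer(3)))
  meta <- read_mesh_sidecar(paste0(path, ".json"))
  labeled_mesh(V, F, region_labels = meta$region_labels,
               landmark_indices = meta$landmark_indices,
               pedicle_axes = meta$pedicle_axes, validate = validate)
}

SSM_FORMAT_VERSION <- "spinefit-ssm-1"

#' Serialize / load a shape model
#'
#' Single JSON archive with a versioned header carrying the mean shape,
#' basis, eigenvalues, template mesh (with labels/landmarks/axes) and
#' path annotations at full floating-point precision.
#' @param model a `vertebra_ssm`; `path` the archive path.
#' @return `read_ssm` returns the `vertebra_ssm`.
#' @export
write_ssm <- function(model, path) {
  tpl <- model$template
  obj <- list(
    format_version = SSM_FORMAT_VERSION,
    mean_shape = model$mean_shape,
    basis = model$basis,
    eigenvalues = model$eigenvalues,
    full_eigenvalues = model$full_eigenvalues,
    n_training = model$n_training,
    template = list(vertices = tpl$vertices, faces = tpl$faces,
                    region_labels = tpl$region_labels,
                    landmark_indices = as.list(tpl$landmark_indices),
                    pedicle_axes = tpl$pedicle_axes),
    path_annotations = lapply(model$path_annotations, unclass)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname write_ssm
#' @export
read_ssm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format_version, SSM_FORMAT_VERSION))
    stop("unsupported shape-model archive version: ", obj$format_version)
  tpl <- labeled_mesh(obj$template$vertices, obj$template$faces,
                      region_labels = obj$template$region_labels,
                      landmark_indices = unlist(obj$template$landmark_indices),
                      pedicle_axes = if (is.null(obj$template$pedicle_axes)) NULL
                        else lapply(obj$template$pedicle_axes, function(ax)
                          list(p0 = as.numeric(ax$p0), p1 = as.numeric(ax$p1))),
                      validate = FALSE)
  pa <- NULL
  if (!is.null(obj$path_annotations) && length(obj$path_annotations))
    pa <- lapply(obj$path_annotations, function(p)
      path_template(p$side, p$entry_face, as.numeric(p$entry_bary),
                    p$exit_face, as.numeric(p$exit_bary)))
  basis <- obj$basis
  if (is.null(dim(basis))) basis <- matrix(basis, ncol = 1)
  structure(list(template = tpl,
                 mean_shape = as.numeric(obj$mean_shape),
                 basis = basis,
                 eigenvalues = as.numeric(obj$eigenvalues),
                 full_eigenvalues = as.numeric(obj$full_eigenvalues),
                 n_training = obj$n_training,
                 path_annotations = pa),
            class = "vertebra_ssm")
}

#' Write / read pose-shape parameters as JSON
#' @param params a [pose_shape_params]; `path` the file path.
#' @return `read_params` returns the [pose_shape_params].
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  pose_shape_params(rotation = p$rotation, translation = p$translation,
                    coeffs = p$coeffs, scale = p$scale,
                    coeff_bound = p$coeff_bound)
}

#' Write a path plan as JSON
#' @param plan a [path_plan]; `path` the file path.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(list(side = plan$side, entry_mm = plan$entry,
                            exit_mm = plan$exit, diameter_mm = plan$diameter,
                            min_wall_distance_mm = plan$min_wall_distance_mm,
                            breach = plan$breach),
                       path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Write an image matrix to disk
#'
#' Float TIFF (lossless) when the `tiff` package is available, else
#' 8-bit PNG via `png`; values are expected in [0, 1].
#' @param img numeric matrix in [0, 1].
#' @param path output path (`.tif`/`.tiff` or `.png`).
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF output")
    tiff::writeTIFF(img, path, bits.per.sample = 32L)
  } else {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the 'png' package is required for PNG output")
    png::writePNG(pmin(1, pmax(0, img)), path)
  }
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF input")
    img <- tiff::readTIFF(path)
  } else {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the 'png' package is required for PNG input")
    img <- png::readPNG(path)
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
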