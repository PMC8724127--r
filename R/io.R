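# Readers and writers for on-disk formats: connectivity matrices (TSV or
# Matrix Market + node-index sidecar), streamline endpoint tables (TSV),
# atlas label volumes (NIfTI + label metadata TSV), and population exports.
# Delimited outputs are tab-separated UTF-8 with '#'-prefixed metadata lines.

matrix_sidecar_path <- function(path) paste0(path, ".nodes.tsv")

#' Write a connectivity matrix
#'
#' Two dialects: `"tsv"` writes a dense tab-separated matrix with node ids in
#' the header and first column; `"matrixmarket"` writes a sparse symmetric
#' Matrix Market file plus a node-index sidecar (`<path>.nodes.tsv`), since
#' the MTX format itself carries no node ids. Both round-trip through
#' [read_matrix()].
#'
#' @param matrix A connectivity matrix (validated before writing).
#' @param path Output path.
#' @param format `"tsv"` (default) or `"matrixmarket"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, format = c("tsv", "matrixmarket")) {
  format <- match.arg(format)
  validate_matrix(matrix)
  ids <- node_ids(matrix)
  if (format == "tsv") {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(c(
      "# connectivity matrix: symmetric, hollow, non-negative weights",
      paste(c("node", ids), collapse = "\t")
    ), con)
    utils::write.table(
      cbind(ids, format(matrix, digits = 17, trim = TRUE, scientific = TRUE)),
      con,
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  } else {
    M <- Matrix::forceSymmetric(Matrix::Matrix(matrix, sparse = TRUE))
    Matrix::writeMM(M, path)
    utils::write.table(
      data.frame(index = seq_along(ids), node = ids),
      matrix_sidecar_path(path),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}

#' Read a connectivity matrix
#'
#' Reads either dialect written by [write_matrix()], restores node ids, and
#' validates symmetry, hollowness and non-negativity (reporting offending
#' indices on failure).
#'
#' @param path Input path.
#' @param format `"tsv"` or `"matrixmarket"`; guessed from the file extension
#'   (`.mtx` = Matrix Market) when omitted.
#' @return A connectivity matrix with node ids as dimnames.
#' @export
read_matrix <- function(path, format = NULL) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path), class = "hubrank_error_io")
  }
  if (is.null(format)) {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "matrixmarket" else "tsv"
  }
  if (format == "tsv") {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[!startsWith(lines, "#")]
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
    body <- utils::read.table(
      text = lines[-1], sep = "\t",
      colClasses = c("character", rep("numeric", length(header)))
    )
    W <- as.matrix(body[, -1, drop = FALSE])
    dimnames(W) <- list(body[[1]], header)
  } else {
    M <- Matrix::readMM(path)
    W <- as.matrix(M)
    sidecar <- matrix_sidecar_path(path)
    ids <- if (file.exists(sidecar)) {
      utils::read.table(sidecar, sep = "\t", header = TRUE, colClasses = "character")$node
    } else {
      paste0("roi_", seq_len(nrow(W)))
    }
    dimnames(W) <- list(ids, ids)
  }
  validate_matrix(W, arg = path)
  W
}

#' Write / read a streamline endpoint table
#'
#' One row per streamline: `roi_a`, `roi_b`, `length_mm`. Lengths must be
#' strictly positive; reading validates this and reports offending rows.
#'
#' @param streamlines Data frame with columns `roi_a`, `roi_b`, `length_mm`.
#' @param path File path.
#' @return `write_streamlines()`: `path`, invisibly. `read_streamlines()`: a
#'   tibble.
#' @export
write_streamlines <- function(streamlines, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# streamline endpoints: one row per streamline; length in mm", con)
  utils::write.table(
    streamlines[, c("roi_a", "roi_b", "length_mm")], con,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_streamlines
#' @export
read_streamlines <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path), class = "hubrank_error_io")
  }
  df <- utils::read.table(path,
    sep = "\t", header = TRUE, comment.char = "#",
    colClasses = c("character", "character", "numeric")
  )
  out <- tibble::as_tibble(df)
  if (nrow(out) > 0 && (anyNA(out$length_mm) || any(out$length_mm <= 0))) {
    bad <- which(is.na(out$length_mm) | out$length_mm <= 0)[1]
    rlang::abort(
      sprintf("Non-positive streamline length at row %d.", bad),
      class = "hubrank_error_validation"
    )
  }
  out
}

label_metadata_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".labels.tsv", path)
}

#' Write / read an atlas label volume (NIfTI)
#'
#' The 3D integer label grid is stored as NIfTI (via RNifti) with the voxel
#' size in the header; the parcel metadata table (label, name, hemisphere,
#' homolog) is stored alongside as `<path minus .nii[.gz]>.labels.tsv`.
#' Reading validates that every non-background label in the grid appears in
#' the metadata table.
#'
#' @param volume A `label_volume`.
#' @param path NIfTI path (`.nii` or `.nii.gz`).
#' @return `write_label_volume()`: `path`, invisibly. `read_label_volume()`:
#'   a `label_volume`.
#' @export
write_label_volume <- function(volume, path) {
  if (!inherits(volume, "label_volume")) {
    abort_bad_arg("volume", "be a label_volume")
  }
  img <- RNifti::asNifti(volume$grid, internal = FALSE)
  RNifti::pixdim(img) <- volume$voxel_size
  RNifti::writeNifti(img, path, datatype = "int32")
  utils::write.table(
    volume$labels, label_metadata_path(path),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_label_volume
#' @param metadata_path Optional explicit path of the label metadata TSV.
#' @export
read_label_volume <- function(path, metadata_path = NULL) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path), class = "hubrank_error_io")
  }
  img <- RNifti::readNifti(path)
  grid <- array(as.integer(round(as.array(img))), dim = dim(img))
  vsz <- RNifti::pixdim(img)[seq_len(3)]
  metadata_path <- metadata_path %||% label_metadata_path(path)
  labels <- if (file.exists(metadata_path)) {
    tibble::as_tibble(utils::read.table(metadata_path,
      sep = "\t", header = TRUE,
      colClasses = c("integer", "character", "character", "integer")
    ))
  } else {
    present <- sort(unique(grid[grid > 0]))
    tibble::tibble(
      label = present, name = sprintf("parcel_%03d", present),
      hemisphere = NA_character_, homolog = NA_integer_
    )
  }
  present <- sort(unique(grid[grid > 0]))
  missing_lab <- setdiff(present, labels$label)
  if (length(missing_lab) > 0) {
    rlang::abort(
      sprintf(
        "Label(s) %s present in the volume but absent from the metadata table.",
        paste(missing_lab, collapse = ", ")
      ),
      class = "hubrank_error_validation"
    )
  }
  new_label_volume(grid, as.numeric(vsz), labels)
}

#' Export a generated population to disk
#'
#' Writes one matrix file per subject (TSV or Matrix Market), the base
#' matrix, the node metadata as TSV, and a JSON ground-truth sidecar (hub
#' ids, asymmetric parcels, the generating parameters).
#'
#' @param pop A `connectome_population` (or `subject_population`).
#' @param dir Output directory (created if needed).
#' @param format Matrix format, `"tsv"` or `"matrixmarket"`.
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir, format = c("tsv", "matrixmarket")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "tsv") "tsv" else "mtx"
  subjects <- as_subject_list(pop)
  for (s in seq_along(subjects)) {
    write_matrix(
      subjects[[s]],
      file.path(dir, sprintf("subject_%04d.%s", s, ext)), format
    )
  }
  if (!is.null(pop$base_matrix)) {
    write_matrix(pop$base_matrix, file.path(dir, paste0("base_matrix.", ext)), format)
  }
  utils::write.table(pop_node_info(pop), file.path(dir, "node_info.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(pop$ground_truth)) {
    gt <- pop$ground_truth
    gt$spec <- unclass(gt$spec)
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  invisible(dir)
}

#' Read a population directory written by [write_population()]
#'
#' @param dir Directory containing `subject_*.tsv` / `subject_*.mtx` files
#'   and optionally `node_info.tsv`.
#' @return A `subject_population`.
#' @export
read_population <- function(dir) {
  files <- sort(list.files(dir, pattern = "^subject_\\d+\\.(tsv|mtx)$", full.names = TRUE))
  if (length(files) == 0) {
    rlang::abort(sprintf("No subject matrices found in %s.", dir), class = "hubrank_error_io")
  }
  subjects <- lapply(files, read_matrix)
  info_path <- file.path(dir, "node_info.tsv")
  node_info <- if (file.exists(info_path)) {
    tibble::as_tibble(utils::read.table(info_path, sep = "\t", header = TRUE))
  } else {
    NULL
  }
  if (!is.null(node_info)) node_info$node <- as.character(node_info$node)
  subject_population(subjects, node_info)
}
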