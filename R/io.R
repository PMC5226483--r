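# Reading the delimited-text exchange formats (connectivity matrices,
# volume tables, subject tables) and writing BrainNet-style .node/.edge files.

#' Read a square connectivity matrix from delimited text
#'
#' Accepts comma- or tab-delimited numeric matrices, by default without a
#' header. A header row matching the atlas labels is tolerated when
#' `atlas` is supplied. Small numeric asymmetry (within 1e-8 relative) is
#' averaged away; anything larger is an error, since tractography matrices
#' are nominally symmetric.
#'
#' @param path File path.
#' @param atlas Optional [region_atlas()] used to check dimension and an
#'   optional header row.
#' @return A numeric matrix.
#' @export
read_connectivity_matrix <- function(path, atlas = NULL) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- suppressWarnings(any(is.na(as.numeric(fields))))
  tbl <- utils::read.table(path, sep = sep, header = has_header,
                           check.names = FALSE)
  m <- as.matrix(tbl)
  dimnames(m) <- NULL
  if (!is_square_matrix(m)) {
    abort(sprintf("matrix in '%s' is %d x %d, not square", path, nrow(m), ncol(m)),
          class = "wmnet_dimension_error")
  }
  if (!is.null(atlas)) {
    if (nrow(m) != nrow(atlas)) {
      abort(sprintf("matrix in '%s' has %d rows; atlas has %d regions",
                    path, nrow(m), nrow(atlas)), class = "wmnet_dimension_error")
    }
    if (has_header && !identical(names(tbl), atlas$label)) {
      abort(sprintf("header of '%s' does not match atlas labels", path),
            class = "wmnet_validation_error")
    }
  }
  symmetrize(m, what = sprintf("matrix in '%s'", path))
}

#' Read per-region volumes
#'
#' Two-column delimited text: region label and volume in mm^3. Rows are
#' reordered to the atlas order when an atlas is given.
#'
#' @inheritParams read_connectivity_matrix
#' @return A named numeric vector of volumes.
#' @export
read_region_volumes <- function(path, atlas = NULL) {
  tbl <- as.data.frame(readr::read_delim(
    path, col_names = c("label", "volume_mm3"), show_col_types = FALSE
  ))
  if (suppressWarnings(is.na(as.numeric(tbl$volume_mm3[1])))) tbl <- tbl[-1, ] # header row
  vols <- setNames(as.numeric(tbl$volume_mm3), tbl$label)
  if (!is.null(atlas)) {
    missing <- setdiff(atlas$label, names(vols))
    if (length(missing)) {
      abort(sprintf("volume file '%s' lacks regions: %s", path,
                    paste(head(missing, 5), collapse = ", ")),
            class = "wmnet_validation_error")
    }
    vols <- vols[atlas$label]
  }
  vols
}

#' Read a subject table
#'
#' Delimited text with columns `subject_id, group, age, sex, education,
#' MMSE, MoCA, AVLT_I, AVLT_D, AVLT_R, fn_path, fa_path, vol_path`. Paths
#' are resolved relative to the table's directory unless absolute.
#'
#' @param path File path.
#' @return A tibble, one row per subject.
#' @export
read_subject_table <- function(path) {
  tbl <- readr::read_delim(path, show_col_types = FALSE)
  required <- c("subject_id", "group", "fn_path", "fa_path", "vol_path")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    abort(sprintf("subject table lacks columns: %s", paste(missing, collapse = ", ")),
          class = "wmnet_validation_error")
  }
  base <- dirname(path)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  dplyr::mutate(tbl, dplyr::across(dplyr::ends_with("_path"), resolve))
}

#' Load one subject's matrices from a subject-table row
#'
#' @param row One-row data frame from [read_subject_table()].
#' @param atlas A [region_atlas()]; by default inferred from the matrix
#'   dimension (AAL-90 for 90 x 90 inputs, generic labels otherwise).
#' @return A [subject_connectivity()] object.
#' @export
load_subject <- function(row, atlas = NULL) {
  score_cols <- intersect(c("MMSE", "MoCA", "AVLT_I", "AVLT_D", "AVLT_R"), names(row))
  if (is.null(atlas)) {
    fn0 <- read_connectivity_matrix(row$fn_path)
    atlas <- if (nrow(fn0) == 90) aal90_atlas() else
      region_atlas(sprintf("R%02d", seq_len(nrow(fn0))))
  }
  subject_connectivity(
    subject_id = row$subject_id, group = row$group,
    fn = read_connectivity_matrix(row$fn_path, atlas),
    fa = read_connectivity_matrix(row$fa_path, atlas),
    volumes = read_region_volumes(row$vol_path, atlas),
    age = row$age %||% NA_real_, sex = row$sex %||% NA_character_,
    education = row$education %||% NA_real_,
    scores = setNames(as.numeric(row[score_cols]), score_cols),
    atlas = atlas
  )
}

#' Write BrainNet-style .node and .edge files
#'
#' The `.node` format has six whitespace-delimited columns: x, y, z
#' coordinates, a color group code, a node size, and the label. Here size is
#' the nodal betweenness and color distinguishes hubs (2) from non-hubs (1).
#' The `.edge` file is the tab-delimited weight matrix. Coordinates come from
#' the atlas; the bundled AAL-90 coordinates are approximate centroids meant
#' for display only.
#'
#' @param nodal Tibble from [nodal_metrics()] (columns `label`,
#'   `betweenness`), or a group-averaged equivalent.
#' @param atlas A [region_atlas()] with coordinates.
#' @param path Output path for the `.node` file.
#' @param hubs Optional character vector of hub labels colored differently.
#' @return The path, invisibly.
#' @export
write_node_file <- function(nodal, atlas, path, hubs = character()) {
  stopifnot(all(c("label", "betweenness") %in% names(nodal)))
  b <- setNames(nodal$betweenness, nodal$label)[atlas$label]
  out <- data.frame(
    x = atlas$x, y = atlas$y, z = atlas$z,
    color = ifelse(atlas$label %in% hubs, 2L, 1L),
    size = round(as.numeric(b), 6),
    label = atlas$label
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_node_file
#' @param net A [weighted_network()] whose weight matrix becomes the `.edge`
#'   file.
#' @export
write_edge_file <- function(net, path) {
  utils::write.table(net$weights, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
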