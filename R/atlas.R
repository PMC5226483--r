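#' Region atlases
#'
#' A region atlas fixes the node order, labels, and (optionally) display
#' coordinates of the network. The default is the 90-region cortical +
#' subcortical anatomical parcellation (AAL-90) commonly used for
#' tractography-derived structural connectomes. Bundled coordinates are
#' approximate MNI centroids intended only for visualization output (see
#' [write_node_file()]); they carry no analytic weight.
#'
#' @param labels Character vector of unique region labels.
#' @param names Optional long-form region names (defaults to `labels`).
#' @param x,y,z Optional numeric display coordinates per region.
#'
#' @return A tibble of class `region_atlas` with columns `index`, `label`,
#'   `name`, `x`, `y`, `z`.
#' @export
#' @examples
#' atlas <- aal90_atlas()
#' nrow(atlas) # 90
region_atlas <- function(labels, names = labels, x = NA_real_, y = NA_real_,
                         z = NA_real_) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    abort("atlas labels must be unique", class = "wmnet_validation_error")
  }
  if (length(labels) < 2) {
    abort("an atlas needs at least 2 regions", class = "wmnet_validation_error")
  }
  out <- tibble::tibble(
    index = seq_along(labels),
    label = labels,
    name = as.character(names),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)
  )
  class(out) <- c("region_atlas", class(out))
  out
}

#' @rdname region_atlas
#' @export
aal90_atlas <- function() {
  path <- system.file("extdata", "aal90_nodes_approx.tsv", package = "wmnet")
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  region_atlas(tbl$label, names = tbl$name, x = tbl$x, y = tbl$y, z = tbl$z)
}

#' Read an atlas from a delimited label file
#'
#' Expects a header with at least a `label` column; optional `name`, `x`,
#' `y`, `z` columns are carried through.
#'
#' @param path Path to a tab- or comma-delimited text file.
#' @return A `region_atlas` tibble.
#' @export
read_atlas <- function(path) {
  tbl <- as.data.frame(readr::read_delim(path, show_col_types = FALSE))
  if (!"label" %in% names(tbl)) {
    abort("atlas file must contain a 'label' column", class = "wmnet_validation_error")
  }
  region_atlas(
    tbl$label,
    names = tbl$name %||% tbl$label,
    x = tbl$x %||% NA_real_, y = tbl$y %||% NA_real_, z = tbl$z %||% NA_real_
  )
}
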