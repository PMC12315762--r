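# Atlas tables: parcel id -> name -> large-scale network.

#' Canonical 7-network labels
#'
#' The seven large-scale cortical networks of the 200-parcel scheme the
#' pipeline assumes: visual (VIS), somatomotor (SOM), dorsal attention (DAN),
#' ventral attention (VAN), limbic (LIM), frontoparietal (FPN), and default
#' mode (DMN).
#' @export
atlas_networks <- c("VIS", "SOM", "DAN", "VAN", "LIM", "FPN", "DMN")

validate_atlas <- function(atlas) {
  need <- c("roi_id", "roi_name", "network")
  miss <- setdiff(need, names(atlas))
  if (length(miss) > 0)
    abort(paste0("atlas is missing column(s): ", paste(miss, collapse = ", ")),
          class = "decodr_format_error")
  if (anyDuplicated(atlas$roi_id))
    abort("atlas has duplicate roi_id values", class = "decodr_validation_error")
  ids <- sort(atlas$roi_id)
  if (!identical(as.integer(ids), seq_len(nrow(atlas))))
    abort("atlas roi_id values are non-contiguous (must be 1..n_rois)",
          class = "decodr_validation_error")
  bad <- setdiff(unique(atlas$network), atlas_networks)
  if (length(bad) > 0)
    abort(paste0("unknown network label(s): ", paste(bad, collapse = ", ")),
          class = "decodr_validation_error")
  invisible(atlas)
}

#' Read an atlas table
#'
#' Reads a tab-separated table with columns `roi_id`, `roi_name`, `network`.
#' Parcel ids must form a contiguous 1-based range and every network label
#' must be one of [atlas_networks].
#'
#' @param path path to a TSV file.
#' @return A tibble with one row per parcel, ordered by `roi_id`.
#' @export
read_atlas <- function(path) {
  atlas <- readr::read_tsv(path, col_types = readr::cols(
    roi_id = readr::col_integer(),
    roi_name = readr::col_character(),
    network = readr::col_character()
  ))
  validate_atlas(atlas)
  arrange(atlas, .data$roi_id)
}

#' Write an atlas table
#'
#' @param atlas tibble with `roi_id`, `roi_name`, `network`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  validate_atlas(atlas)
  readr::write_tsv(atlas, path, na = "")
  invisible(path)
}

#' Build a synthetic atlas
#'
#' Assigns parcels to the seven canonical networks in contiguous blocks of
#' roughly equal size, mimicking how atlas parcels are grouped into
#' large-scale networks. Intended as the companion atlas for simulated
#' cohorts; label it synthetic in any serious reporting.
#'
#' @param n_rois number of parcels.
#' @return An atlas tibble.
#' @export
#' @examples
#' synthetic_atlas(14)
synthetic_atlas <- function(n_rois) {
  stopifnot(n_rois >= 1)
  net <- atlas_networks[ceiling(seq_len(n_rois) / n_rois * length(atlas_networks))]
  tibble(
    roi_id = seq_len(n_rois),
    roi_name = sprintf("ROI_%03d", seq_len(n_rois)),
    network = net
  )
}
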