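# Per-subject trial tables: one row per trial, behavioral columns plus one
# activation column per parcel.

new_subject_data <- function(df, subject_id, mean_fd = NA_real_) {
  out <- as_tibble(df)
  attr(out, "subject_id") <- as.character(subject_id)
  attr(out, "mean_fd") <- as.numeric(mean_fd)
  class(out) <- c("subject_data", class(out))
  out
}

#' Subject identifier of a trial table
#' @param x a `subject_data` tibble.
#' @return Character scalar.
#' @export
subject_id <- function(x) attr(x, "subject_id", exact = TRUE)

#' Mean frame displacement of a subject
#' @param x a `subject_data` tibble.
#' @return Numeric scalar (mm); `NA` if unknown.
#' @export
mean_fd <- function(x) attr(x, "mean_fd", exact = TRUE)

roi_columns <- function(x) grep("^roi_[0-9]+$", names(x), value = TRUE)

#' Activation matrix of a subject
#'
#' @param x a `subject_data` tibble.
#' @return A numeric matrix, trials by parcels, columns ordered by roi id.
#' @export
beta_matrix <- function(x) {
  cols <- roi_columns(x)
  cols <- cols[order(as.integer(sub("^roi_", "", cols)))]
  m <- as.matrix(x[cols])
  rownames(m) <- NULL
  m
}

validate_subject_data <- function(x, atlas = NULL) {
  need <- c("trial", "run", "rt", "confidence")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    abort(paste0("subject table is missing column(s): ",
                 paste(miss, collapse = ", ")), class = "decodr_format_error")
  if (!is.null(atlas)) {
    want <- paste0("roi_", atlas$roi_id)
    miss <- setdiff(want, names(x))
    if (length(miss) > 0)
      abort(paste0("subject table is missing ROI column(s): ",
                   paste(miss, collapse = ", ")),
            class = "decodr_format_error")
  }
  bad <- which(!is.na(x$rt) & x$rt <= 0)
  if (length(bad) > 0)
    abort(paste0("non-positive rt at row(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "decodr_validation_error")
  invisible(x)
}

#' Read one subject's trial table
#'
#' Reads a tab-separated trial table with header columns `trial`, `run`,
#' `rt` (seconds), `confidence` (ordinal integer; empty where the rating was
#' not collected), and one `roi_<id>` activation column per atlas parcel.
#' ROI columns are matched by name against the atlas, not by position, and
#' trial order is preserved exactly as in the file.
#'
#' @param path path to a TSV file.
#' @param atlas atlas tibble (see [read_atlas()]); every `roi_<id>` for its
#'   parcels must be present in the file.
#' @param subject_id subject identifier; defaults to the file name without
#'   extension.
#' @param mean_fd per-subject mean frame displacement (mm), if known.
#' @return A `subject_data` tibble.
#' @export
read_subject_table <- function(path, atlas, subject_id = NULL, mean_fd = NA_real_) {
  # doubles come in as text and through as.numeric, which (unlike the fast
  # multi-threaded parser) is exact on full-precision decimal strings
  df <- readr::read_tsv(path, col_types = readr::cols(
    trial = readr::col_integer(),
    run = readr::col_integer(),
    confidence = readr::col_integer(),
    .default = readr::col_character()
  ))
  chr <- names(df)[vapply(df, is.character, logical(1))]
  df[chr] <- lapply(df[chr], as.numeric)
  sid <- subject_id %||% sub("\\.[^.]*$", "", basename(path))
  x <- new_subject_data(df, sid, mean_fd)
  validate_subject_data(x, atlas)
  x
}

#' Write one subject's trial table
#'
#' Inverse of [read_subject_table()]; missing values are written as empty
#' fields and numeric columns round-trip at full precision.
#'
#' @param x a `subject_data` tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(x, path) {
  df <- as_tibble(x)
  dbl <- vapply(df, is.double, logical(1))
  df[dbl] <- lapply(df[dbl], function(v)
    ifelse(is.na(v), NA_character_, sprintf("%.17g", v)))
  readr::write_tsv(df, path, na = "")
  invisible(path)
}

#' @export
print.subject_data <- function(x, ...) {
  cat(sprintf("<subject_data> %s: %d trials x %d ROIs, mean FD %.3g mm\n",
              subject_id(x), nrow(x), length(roi_columns(x)), mean_fd(x)))
  NextMethod()
}

# Behavioral target vector (raw scale).
target_vector <- function(x, target, log_rt = FALSE) {
  target <- match.arg(target, c("rt", "confidence"))
  y <- x[[target]]
  if (target == "rt" && log_rt) y <- log(y)
  as.numeric(y)
}
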