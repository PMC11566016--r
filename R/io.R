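# File I/O contracts: BIDS-style events TSV, delimited pattern matrices,
# hypnogram text, spindle CSV, NIfTI volumes, and results JSON/CSV.

EVENTS_COLUMNS <- c("onset", "duration", "trial_type", "item_id",
                    "pair_id", "condition", "run")

#' Write / read BIDS-style events tables
#'
#' Tab-separated with columns onset, duration, trial_type, item_id,
#' pair_id, condition, run. One file per run is the convention; pass a
#' pre-filtered events data.frame.
#'
#' @param events Events data.frame (extra columns are dropped on write).
#' @param path File path.
#' @return \code{read_events_tsv} returns the events data.frame.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events[, EVENTS_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", na.strings = "n/a",
                    stringsAsFactors = FALSE)
}

#' Write / read a snapshot pattern matrix as delimited text
#'
#' Tab-separated; first column \code{item_id} carries the rownames, the
#' remaining columns are voxel amplitudes.
#'
#' @param mat Item-by-voxel numeric matrix with item_id rownames.
#' @param path File path.
#' @return \code{read_pattern_matrix} returns the matrix with rownames.
#' @export
write_pattern_matrix <- function(mat, path) {
  df <- data.frame(item_id = rownames(mat), mat, stringsAsFactors = FALSE)
  colnames(df) <- c("item_id", sprintf("v%04d", seq_len(ncol(mat))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pattern_matrix
#' @export
read_pattern_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$item_id
  colnames(m) <- NULL
  m
}

#' Write / read a hypnogram as plain text
#'
#' Header comment lines carry the in-bed interval and artifact epochs;
#' each subsequent line is one 30-s epoch's stage code.
#'
#' @param h A \code{remdiff_hypnogram}.
#' @param path File path.
#' @return \code{read_hypnogram} returns the \code{remdiff_hypnogram}.
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "remdiff_hypnogram"))
  header <- c(paste("# lights_off", h$lights_off),
              paste("# lights_on", h$lights_on),
              paste("# artifact", paste(h$artifact, collapse = ",")))
  writeLines(c(header, h$stages), path)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  stages <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get_field <- function(name) {
    ln <- hdr[grepl(paste0("^# ", name, "\\b"), hdr)]
    if (length(ln) == 0L) return(NULL)
    sub(paste0("^# ", name, " *"), "", ln[1L])
  }
  lo <- get_field("lights_off")
  on <- get_field("lights_on")
  art <- get_field("artifact")
  hypnogram(stages,
            lights_off = if (is.null(lo)) 1L else as.integer(lo),
            lights_on = if (is.null(on)) length(stages) + 1L else as.integer(on),
            artifact = if (is.null(art) || !nzchar(art)) integer()
              else as.integer(strsplit(art, ",")[[1L]]))
}

#' Write / read spindle-event tables
#'
#' CSV with columns start_s, duration_s, stage, channel.
#'
#' @param spindles Spindle data.frame.
#' @param path File path.
#' @return \code{read_spindles} returns the data.frame.
#' @export
write_spindles <- function(spindles, path) {
  utils::write.csv(spindles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spindles
#' @export
read_spindles <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read / write 4D functional volumes and 3D masks as NIfTI
#'
#' Thin wrappers over RNifti. Masks are returned as logical arrays
#' (nonzero voxels TRUE).
#'
#' @param path NIfTI file path.
#' @param arr Numeric array to write.
#' @return \code{read_bold_nifti} returns a plain numeric array;
#'   \code{read_mask_nifti} a logical array.
#' @export
read_bold_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img))
}

#' @rdname read_bold_nifti
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) != 0, dim = dim(img))
}

#' @rdname read_bold_nifti
#' @export
write_bold_nifti <- function(arr, path) {
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Write per-subject analysis results as JSON
#'
#' Serializes the per-ROI results of \code{\link{analyze_subject}} (pairwise
#' records, differentiation score, randomization test, coupling analyses)
#' with full numeric precision.
#'
#' @param results Result of \code{\link{analyze_subject}}.
#' @param path File path.
#' @export
write_subject_results <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
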