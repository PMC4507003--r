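# Delimited-text I/O ---------------------------------------------------------

#' Read and write trajectory tables
#'
#' Trajectories are exchanged as delimited text with a header and columns
#' `track_id, frame, t_s, x_um, y_um[, bound_truth]`; the frame index is
#' 0-based.
#'
#' @param path File path.
#' @param traj Trajectory tibble.
#' @return `read_trajectories()` returns a trajectory tibble;
#'   `write_trajectories()` returns `path` invisibly.
#' @export
read_trajectories <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("track_id", "frame", "t_s", "x_um", "y_um")
  if (!all(need %in% names(out))) {
    stop(
      "trajectory file must have columns ",
      paste(need, collapse = ", "), ".",
      call. = FALSE
    )
  }
  out
}

#' @rdname read_trajectories
#' @export
write_trajectories <- function(traj, path) {
  stopifnot(is.data.frame(traj))
  readr::write_csv(traj, path)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' Parses lines of the form `key = value` (or `key: value`); blank lines and
#' `#` comments are ignored. Values that parse as numbers are returned
#' numeric.
#'
#' @param path File path.
#' @return A named list.
#' @export
read_config_kv <- function(path) {
  lines <- readr::read_lines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  lines <- lines[grepl("[=:]", lines)]
  keys <- trimws(sub("[=:].*$", "", lines))
  vals <- trimws(sub("^[^=:]*[=:]", "", lines))
  out <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(out, keys)
}

#' Write an event or survival table as delimited text
#'
#' @param x A tibble (events, survival curves, kinetics summaries, ...).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
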