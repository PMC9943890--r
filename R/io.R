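# CSV readers and writers for the analysis surfaces.  Dialect: comma
# separated, UTF-8, '.' decimal, header mandatory.  Units are enforced by
# the column names (t_h hours, x_um / y_um micrometres).

#' Read a trajectory table from CSV
#'
#' Required columns: `track_id`, `cluster_id`, `t_h`, `x_um`, `y_um`.
#' Validation rejects missing columns, non-numeric or non-finite
#' coordinates and duplicated `(track_id, t)` pairs, naming the offending
#' row.  Image-convention files (y increasing downward, as pixel
#' coordinates do) are flipped on load so that angles are
#' counterclockwise-positive.
#'
#' @param path CSV file.
#' @param convention `"cartesian"` (default, y up) or `"image"` (y down;
#'   the y coordinate is negated on load).
#' @return validated trajectory data frame.
#' @export
read_trajectories <- function(path, convention = c("cartesian", "image")) {
  convention <- match.arg(convention)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_trajectories(df)
  if (convention == "image") df$y_um <- -df$y_um
  df
}

#' Write a trajectory table to CSV
#'
#' @param tracks trajectory data frame.
#' @param path output file.
#' @export
write_trajectories <- function(tracks, path) {
  validate_trajectories(tracks)
  write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' Read growth records / confluence series from CSV
#'
#' `read_growth_records` expects `cluster_id`, `t_h`, `n_cells`,
#' `area_um2`; `read_confluence_series` expects `sample_id`, `t_h`, `a_s`.
#'
#' @param path CSV file.
#' @return validated data frame.
#' @export
read_growth_records <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cluster_id", "t_h", "n_cells", "area_um2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$n_cells) | df$n_cells < 1))
    stop("n_cells must be finite and >= 1")
  if (any(!is.finite(df$area_um2) | df$area_um2 <= 0))
    stop("area_um2 must be finite and positive")
  df
}

#' @rdname read_growth_records
#' @export
read_confluence_series <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "t_h", "a_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$a_s) | df$a_s <= 0 | df$a_s > 1))
    stop("a_s must lie in (0, 1]")
  df
}
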