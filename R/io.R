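#' Read and write canal curve tables
#'
#' Curves travel as delimited text with the header
#' `subject_id,scan_id,side,point_index,x_mm,y_mm,z_mm`; points are sorted
#' by `point_index` within each canal.
#'
#' @param path file path of the curve table.
#' @return `read_curves()` returns a named list of [canal_curve()]
#'   objects, keyed by `subject_id/scan_id/side`.
#' @export
read_curves <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "scan_id", "side", "point_index",
              "x_mm", "y_mm", "z_mm")
  if (!all(needed %in% names(tab)))
    stop("curve table must have columns: ", paste(needed, collapse = ", "))
  curves_from_table(tab)
}

curves_from_table <- function(tab) {
  key <- paste(tab$subject_id, tab$scan_id, tab$side, sep = "/")
  out <- lapply(split(tab, key), function(d) {
    d <- d[order(d$point_index), , drop = FALSE]
    canal_curve(cbind(d$x_mm, d$y_mm, d$z_mm),
                d$subject_id[1L], d$scan_id[1L], d$side[1L])
  })
  out
}

#' @rdname read_curves
#' @param curves a curve table data frame (as produced by
#'   [simulate_cohort()]) or a list of `canal_curve` objects.
#' @export
write_curves <- function(curves, path) {
  if (!is.data.frame(curves)) {
    if (inherits(curves, "canal_curve")) curves <- list(curves)
    curves <- do.call(rbind, lapply(curves, function(cv)
      curve_to_rows(cv, cv$subject_id, cv$scan_id, cv$side)))
  }
  utils::write.csv(curves, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write Likert rating tables
#'
#' Ratings travel as delimited text with the header
#' `canal_id,rater,session,marker,score,error_types`; `error_types` is a
#' semicolon-joined subset of the fixed vocabulary (empty for none).
#'
#' @param path file path.
#' @return `read_ratings()` returns a validated ratings data frame.
#' @export
read_ratings <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(error_types = "character"))
  tab$error_types[is.na(tab$error_types)] <- ""
  validate_ratings(tab)
}

#' @rdname read_ratings
#' @param ratings a ratings data frame.
#' @export
write_ratings <- function(ratings, path) {
  validate_ratings(ratings)
  utils::write.csv(ratings, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a metric record table
#'
#' One row per canal-scan with `smcd`, `assd`, `dsc` and the validity
#' flag; invalid records keep the distance columns empty.
#'
#' @param records metric record data frame from [run_metrics()].
#' @param path file path.
#' @export
write_metrics <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$valid <- as.logical(tab$valid)
  tab
}
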