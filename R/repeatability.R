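#' Group metric records into repeatability input
#'
#' Collects the SMCD values of valid records into per-canal replicate
#' groups.  Each canal (subject x side) is treated as an independent
#' subject of interest; sides are never pooled.  Groups with a single
#' valid measurement are retained for descriptive summaries but flagged
#' as excluded from the within-subject mean square.
#'
#' @param records a data frame of metric records with at least columns
#'   `canal_id`, `smcd` and `valid` (see [run_metrics()]); an optional
#'   grouping column named by `by` restricts records to one stratum.
#' @param by optional name of a column in `records` to stratify on.
#' @param group when `by` is given, the stratum value to keep.
#' @param measure name of the measurement column (default `"smcd"`).
#' @return An object of class `repeatability_input`: a list with `groups`
#'   (named list of numeric replicate vectors), `n` (canals with >= 2
#'   measurements), `k_i`, `N`, and `singletons`.
#' @export
group_measurements <- function(records, by = NULL, group = NULL,
                               measure = "smcd") {
  stopifnot(is.data.frame(records))
  needed <- c("canal_id", measure, "valid")
  if (!all(needed %in% names(records)))
    stop("records must have columns: ", paste(needed, collapse = ", "))
  if (!is.null(by)) {
    if (!by %in% names(records))
      stop(sprintf("unknown grouping key '%s'", by))
    records <- records[records[[by]] %in% group, , drop = FALSE]
  }
  ok <- records$valid & !is.na(records[[measure]])
  records <- records[ok, , drop = FALSE]
  y <- records[[measure]]
  if (any(y < 0)) stop("distance measurements cannot be negative")
  groups <- split(y, as.character(records$canal_id))
  k_all <- lengths(groups)
  rep_groups <- groups[k_all >= 2L]
  structure(
    list(groups = rep_groups,
         singletons = groups[k_all == 1L],
         n = length(rep_groups),
         k_i = lengths(rep_groups),
         N = sum(lengths(rep_groups))),
    class = "repeatability_input")
}

#' @export
print.repeatability_input <- function(x, ...) {
  cat(sprintf(
    "<repeatability_input> %d canals with replicates (N = %d, K in {%s}); %d singleton(s) excluded from WMS\n",
    x$n, x$N, paste(sort(unique(x$k_i)), collapse = ", "),
    length(x$singletons)))
  invisible(x)
}

as_repeatability_input <- function(x) {
  if (inherits(x, "repeatability_input")) return(x)
  if (is.list(x) && all(vapply(x, is.numeric, TRUE))) {
    k <- lengths(x)
    if (is.null(names(x))) names(x) <- paste0("canal", seq_along(x))
    if (any(unlist(x) < 0)) stop("distance measurements cannot be negative")
    return(structure(
      list(groups = x[k >= 2L], singletons = x[k == 1L],
           n = sum(k >= 2L), k_i = lengths(x[k >= 2L]),
           N = sum(k[k >= 2L])),
      class = "repeatability_input"))
  }
  stop("cannot interpret input as replicate groups")
}

#' Effective replicate count for unbalanced designs
#'
#' For `n` subjects with replicate counts `K_i` and `N` total
#' measurements, the effective count is
#' `K = (N - sum(K_i^2)/N) / (n - 1)`,
#' a downward correction that prevents subjects with few replicates from
#' inflating the within-subject variance.  For a balanced design with
#' `K_i = k` it collapses to `k`.
#'
#' @param input a `repeatability_input` (or a list of replicate vectors).
#' @return Numeric scalar `K`.
#' @export
effective_k <- function(input) {
  input <- as_repeatability_input(input)
  if (input$n < 2L)
    stop("effective K needs at least 2 canals with replicates")
  (input$N - sum(input$k_i^2) / input$N) / (input$n - 1L)
}

#' Within-subject repeatability of repeated measurements
#'
#' Fits the within-subject variance model for repeated distance
#' measurements: the within-subject mean square
#' `WMS = sum_i sum_k (Y_ik - Ybar_i)^2 / (n (K - 1))`
#' with the effective replicate count `K` from [effective_k()], the
#' within-subject standard deviation `wSD = sqrt(WMS)`, and the
#' repeatability coefficient `RC = 1.96 sqrt(2) wSD`, the 95% bound on the
#' difference between two repeated measurements of the same canal.
#'
#' @param input a `repeatability_input` from [group_measurements()], or a
#'   plain list of per-canal replicate vectors (mm).
#' @return An object of class `repeatability` with components `wms`,
#'   `wsd`, `rc` (mm), `k_eff`, `mean`, `range`, `n`, `N` and `k_set`.
#' @examples
#' fit <- repeatability(list(a = c(0.6, 0.8), b = c(0.5, 0.7, 0.9)))
#' fit$rc / fit$wsd  # always 1.96 * sqrt(2)
#' @export
repeatability <- function(input) {
  input <- as_repeatability_input(input)
  if (input$n < 2L)
    stop("repeatability needs at least 2 canals with >= 2 measurements")
  k_eff <- effective_k(input)
  ss <- sum(vapply(input$groups,
                   function(y) sum((y - mean(y))^2), numeric(1)))
  wms <- ss / (input$n * (k_eff - 1))
  wsd <- sqrt(wms)
  all_y <- unlist(input$groups, use.names = FALSE)
  structure(
    list(wms = wms, wsd = wsd, rc = 1.96 * sqrt(2) * wsd,
         k_eff = k_eff, mean = mean(all_y),
         range = range(all_y), n = input$n, N = input$N,
         k_set = sort(unique(input$k_i))),
    class = "repeatability")
}

#' @export
print.repeatability <- function(x, digits = 3, ...) {
  cat("Within-subject repeatability of repeated measurements\n")
  cat(sprintf("  n = %d canals, N = %d measurements, K in {%s} (effective K %.3f)\n",
              x$n, x$N, paste(x$k_set, collapse = ", "), x$k_eff))
  cat(sprintf("  mean %.*f, range [%.*f, %.*f]\n",
              digits, x$mean, digits, x$range[1L], digits, x$range[2L]))
  cat(sprintf("  wSD %.*f, RC %.*f\n", digits, x$wsd, digits, x$rc))
  invisible(x)
}

#' @export
summary.repeatability <- function(object, ...) {
  out <- data.frame(
    n = object$n, N = object$N,
    K = paste0("{", paste(object$k_set, collapse = ", "), "}"),
    mean = object$mean, wSD = object$wsd, RC = object$rc,
    min = object$range[1L], max = object$range[2L],
    stringsAsFactors = FALSE)
  class(out) <- c("summary.repeatability", "data.frame")
  out
}

#' @export
coef.repeatability <- function(object, ...) {
  c(wSD = object$wsd, RC = object$rc)
}

#' Descriptive summary of a distribution
#'
#' Median with interquartile range (linear-interpolation quantiles,
#' `stats::quantile()` type 7) or mean with sample standard deviation
#' (denominator `n - 1`).
#'
#' @param values non-empty numeric vector.
#' @param style `"median_iqr"` or `"mean_sd"`.
#' @return Named numeric vector of length 2: `c(median, iqr)` or
#'   `c(mean, sd)`.
#' @export
summarize_distribution <- function(values, style = c("median_iqr", "mean_sd")) {
  style <- match.arg(style)
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values to summarize")
  if (style == "median_iqr") {
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    c(median = q[2L], iqr = q[3L] - q[1L])
  } else {
    c(mean = mean(values),
      sd = if (length(values) > 1L) stats::sd(values) else 0)
  }
}
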