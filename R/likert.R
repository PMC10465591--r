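#' @name likert
#' @title Likert rating tables
#'
#' @description Ratings are stored as plain data frames with columns
#' `canal_id`, `rater`, `session` (1 or 2), `marker` (`"radiologist"` or
#' `"dls"`), `score` (0-4) and `error_types` (semicolon-joined tokens from
#' the fixed vocabulary, empty string for none).  The five error types
#' are: `fully_missing`, `major_parts_missing`, `off_centre`,
#' `short_mandibular`, `short_mental`; the first two are clinically
#' relevant and only co-occur with scores 0-2.  For model fitting, scores
#' are mapped internally from the reported 0-4 scale to 1-5.
NULL

error_type_vocabulary <- c("fully_missing", "major_parts_missing",
                           "off_centre", "short_mandibular", "short_mental")
severe_error_types <- error_type_vocabulary[1:2]

#' Validate a Likert rating table
#'
#' Checks column presence, score range, session values and the rule that
#' the two clinically relevant error types only occur with scores 0-2.
#'
#' @param ratings data frame as described in [likert].
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_ratings <- function(ratings) {
  needed <- c("canal_id", "rater", "session", "marker", "score", "error_types")
  if (!all(needed %in% names(ratings)))
    stop("ratings must have columns: ", paste(needed, collapse = ", "))
  if (!all(ratings$score %in% 0:4))
    stop("scores must be integers in 0..4")
  if (!all(ratings$session %in% c(1L, 2L)))
    stop("session must be 1 or 2")
  toks <- strsplit(as.character(ratings$error_types), ";", fixed = TRUE)
  bad <- setdiff(unlist(toks), c(error_type_vocabulary, ""))
  if (length(bad))
    stop("unknown error types: ", paste(bad, collapse = ", "))
  severe <- vapply(toks, function(t) any(t %in% severe_error_types), TRUE)
  if (any(severe & ratings$score > 2))
    stop("clinically relevant error types require a score of 0-2")
  ratings
}

#' Binarize a Likert score into diagnostic suitability
#'
#' Scores 3 and 4 are fully suitable for diagnosis; 0-2 are not.
#'
#' @param y integer score(s) in 0..4.
#' @return Factor with levels `fully_usable`, `not_fully_usable`.
#' @export
binarize_score <- function(y) {
  if (any(!(y %in% 0:4))) stop("scores must be in 0..4")
  factor(ifelse(y >= 3, "fully_usable", "not_fully_usable"),
         levels = c("fully_usable", "not_fully_usable"))
}

#' Median expert rating of one canal
#'
#' The median of all ratings of one canal (midpoint convention for even
#' counts) classified three ways: median >= 3 is fully suitable,
#' median <= 2 not fully suitable, and a fractional median strictly
#' between 2 and 3 is uncertain.
#'
#' @param scores numeric vector of the ratings of one canal (0..4).
#' @return List with `median` and `class` (one of `"fully"`,
#'   `"uncertain"`, `"not_fully"`).
#' @export
median_rating <- function(scores) {
  if (length(scores) == 0L) stop("no scores")
  if (any(!(scores %in% 0:4))) stop("scores must be in 0..4")
  med <- stats::median(scores)
  cls <- if (med >= 3) "fully" else if (med <= 2) "not_fully" else "uncertain"
  list(median = med, class = cls)
}

#' Majority vote over per-expert error-type reports
#'
#' An error type enters the aggregate set iff strictly more than half of
#' the experts reported it; an exact tie is excluded.
#'
#' @param reports list of character vectors, one per expert, each a subset
#'   of the error-type vocabulary.
#' @return Character vector of majority error types (possibly empty).
#' @export
majority_error_types <- function(reports) {
  if (length(reports) == 0L) stop("no reports")
  counts <- table(factor(unlist(reports), levels = error_type_vocabulary))
  names(counts)[counts > length(reports) / 2]
}

#' Percent agreement between two aligned rating vectors
#'
#' The inter-observer variant compares two experts on the same canals and
#' session; the intra-observer variant compares one expert's session 1
#' against session 2.
#'
#' @param a,b equal-length vectors of scores aligned by canal.
#' @return Percentage of identical scores, in \[0, 100\].
#' @export
agreement_accuracy <- function(a, b) {
  if (length(a) != length(b)) stop("rating vectors differ in length")
  if (length(a) == 0L) stop("empty rating vectors")
  100 * mean(a == b)
}

#' Descriptive summary of Likert ratings
#'
#' Counts per category over all supplied ratings (all sessions and
#' experts) plus mean and standard deviation (denominator `n - 1`) on the
#' 0-4 scale.
#'
#' @param scores integer vector of ratings in 0..4, or a ratings data
#'   frame (its `score` column is used).
#' @return List with `counts` (named N_0..N_4), `mean` and `sd`.
#' @export
likert_summary <- function(scores) {
  if (is.data.frame(scores)) scores <- scores$score
  if (length(scores) == 0L) stop("empty rating group")
  if (any(!(scores %in% 0:4))) stop("scores must be in 0..4")
  counts <- table(factor(scores, levels = 0:4))
  names(counts) <- paste0("N_", 0:4)
  list(counts = counts,
       mean = mean(scores),
       sd = if (length(scores) > 1L) stats::sd(scores) else 0)
}
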