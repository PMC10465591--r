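#' @name synthetic-cohorts
#' @title Synthetic repeated-scan cohorts
#'
#' @description The clinical CBCT data behind this analysis is
#' access-restricted, so the package ships a generator that reproduces the
#' statistical structure the pipeline assumes: patients with 2-5 repeated
#' scans, two canals per scan treated as independent subjects, smooth
#' within-subject perturbation of the automated localisation with a
#' controllable SMCD scale, occasional canal truncation and dropout, and
#' Likert ratings drawn from a partial credit model with known rater
#' parameters.  Every stage is seed-deterministic; named substreams keep
#' cohort geometry, rescan perturbation and ratings independently
#' re-runnable under one master seed.
NULL

# deterministic substream seed derived from a master seed and a name
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * (seq_len(nchar(name)) * 131L))
  (as.integer(seed) * 2654435L + h) %% 2147483647L
}

# canonical right-side canal knots (mm): mental foramen first, then along
# the mandibular body, ascending the ramus to the mandibular foramen
canal_knots <- rbind(
  c(24, 28, 2),
  c(26, 12, -4),
  c(27, -8, -2),
  c(25, -22, 12))

#' Generate an anatomy-shaped template canal curve
#'
#' A smooth spline-interpolated 3D arc running from the mental foramen
#' opening to the mandibular foramen opening, with control points at 3 mm
#' arc-length spacing and total length inside `length_band`.  Left and
#' right sides are mirror images across the sagittal plane up to the
#' per-patient jitter.
#'
#' @param side `"left"` or `"right"`.
#' @param jitter_sd standard deviation (mm) of Gaussian jitter applied to
#'   the shape knots; 0 gives the canonical shape.
#' @param length_band allowed total arc length range, mm.
#' @param step control point spacing along the arc, mm.
#' @param seed optional integer seed (the current RNG stream is used when
#'   `NULL`).
#' @return A [canal_curve()].
#' @export
make_template_canal <- function(side = c("right", "left"), jitter_sd = 1.5,
                                length_band = c(55, 75), step = 3,
                                seed = NULL) {
  side <- match.arg(side)
  if (!is.null(seed)) set.seed(seed)
  if (length(length_band) != 2L || diff(length_band) <= 0 ||
      length_band[1L] <= 0)
    stop("degenerate length band")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  knots <- canal_knots +
    matrix(stats::rnorm(length(canal_knots), 0, jitter_sd),
           nrow(canal_knots), 3L)
  margin <- 0.1 * diff(length_band)
  target <- stats::runif(1L, length_band[1L] + margin,
                         length_band[2L] - margin)
  # chord-length parameterised natural splines, densely sampled
  tpar <- c(0, cumsum(sqrt(rowSums(diff(knots)^2))))
  tt <- seq(0, max(tpar), length.out = 200L)
  dense <- vapply(1:3, function(ax)
    stats::spline(tpar, knots[, ax], xout = tt, method = "natural")$y,
    numeric(length(tt)))
  cv <- canal_curve(dense, side = side)
  ctr <- colMeans(cv$points)
  pts <- sweep(cv$points, 2L, ctr) * (target / arc_length(cv))
  pts <- sweep(pts, 2L, ctr, `+`)
  if (side == "left") pts[, 1L] <- -pts[, 1L]
  resample_curve(canal_curve(pts, side = side), step)
}

# calibration cache: expected SMCD per unit field amplitude, keyed by
# correlation length (Monte-Carlo estimated once per session)
.calib_env <- new.env(parent = emptyenv())

smcd_per_unit_amp <- function(corr_length, n_draws = 30L) {
  key <- sprintf("cl_%.2f", corr_length)
  if (!is.null(.calib_env[[key]])) return(.calib_env[[key]])
  state <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(state)) assign(".Random.seed", state,
                                      envir = globalenv()))
  set.seed(20260401L)
  ref <- make_template_canal("right", jitter_sd = 0)
  amp0 <- 0.5
  vals <- replicate(n_draws, {
    disp <- correlated_field(ref, corr_length) * amp0
    smcd(ref, canal_curve(ref$points + disp, side = ref$side))
  })
  .calib_env[[key]] <- mean(vals) / amp0
  .calib_env[[key]]
}

# smooth zero-mean displacement field (unit marginal SD per axis) sampled
# at the curve's control points, squared-exponential correlation along arc
correlated_field <- function(curve, corr_length) {
  s <- cum_arc_length(curve$points)
  K <- exp(-0.5 * (outer(s, s, `-`) / corr_length)^2)
  diag(K) <- diag(K) + 1e-8
  L <- chol(K)
  crossprod(L, matrix(stats::rnorm(3L * length(s)), length(s), 3L))
}

#' Perturb a canal curve to emulate a repeated scan
#'
#' Adds a smooth correlated displacement field scaled so that the expected
#' SMCD between the original and the perturbed curve is approximately
#' `sigma_w` (the scale factor comes from a cached Monte-Carlo calibration
#' per correlation length; with `exact = TRUE` the realised field is
#' additionally rescaled by a secant step so the achieved SMCD matches
#' `sigma_w` to within about 1%).  The curve can be truncated at either
#' foramen, and the canal can drop out entirely, emulating scans where the
#' automated system fails to find it.
#'
#' @param curve a [canal_curve()].
#' @param sigma_w target SMCD between input and output, mm (>= 0).
#' @param corr_length correlation length of the displacement field along
#'   the arc, mm.
#' @param truncate_prob probability of truncating one end.
#' @param truncate_len length-2 range (mm) of the truncated piece.
#' @param dropout_prob probability of returning a dropout (`NULL`).
#' @param exact rescale the realised field to hit `sigma_w` exactly.
#' @param scan_id scan id for the returned curve.
#' @return A `canal_curve`, or `NULL` on dropout.  The attributes
#'   `truncated` (`"none"`, `"anterior"` or `"posterior"`) and
#'   `trunc_len` record what was done.
#' @export
perturb_for_rescan <- function(curve, sigma_w, corr_length = 10,
                               truncate_prob = 0, truncate_len = c(2, 8),
                               dropout_prob = 0, exact = FALSE,
                               scan_id = curve$scan_id) {
  stopifnot(inherits(curve, "canal_curve"), sigma_w >= 0)
  if (dropout_prob > 0 && stats::runif(1L) < dropout_prob) return(NULL)
  pts <- curve$points
  if (sigma_w > 0) {
    field <- correlated_field(curve, corr_length)
    amp <- sigma_w / smcd_per_unit_amp(corr_length)
    if (exact) {
      cand <- canal_curve(pts + amp * field, curve$subject_id, scan_id,
                          curve$side)
      got <- smcd(curve, cand)
      if (got > 0) amp <- amp * sigma_w / got
    }
    pts <- pts + amp * field
  }
  out <- canal_curve(pts, curve$subject_id, scan_id, curve$side)
  trunc_end <- "none"; trunc_len <- 0
  if (truncate_prob > 0 && stats::runif(1L) < truncate_prob) {
    trunc_len <- stats::runif(1L, truncate_len[1L], truncate_len[2L])
    trunc_end <- sample(c("anterior", "posterior"), 1L)
    total <- arc_length(out)
    keep <- if (trunc_end == "anterior") c(trunc_len, total)
            else c(0, total - trunc_len)
    s <- seq(keep[1L], keep[2L], by = 3)
    if (s[length(s)] < keep[2L] - 1e-9) s <- c(s, keep[2L])
    out <- canal_curve(interp_at_arc(out$points, s),
                       curve$subject_id, scan_id, curve$side)
  }
  attr(out, "truncated") <- trunc_end
  attr(out, "trunc_len") <- trunc_len
  out
}

#' Cohort generator configuration
#'
#' Defaults emulate the structure of the study cohort the pipeline is
#' designed for: 72 patients with 2-5 repeated scans each (a small
#' majority with exactly two), two canals per scan, four heterogeneity
#' groups, within-canal SMCD variability and mean DLS-vs-radiologist
#' distances on the scale reported for such cohorts, voxel spacings drawn
#' from the common CBCT values, and three simulated experts whose partial
#' credit model parameters put the repeatability measure in the 0.85-0.96
#' range with a top-heavy score distribution.
#'
#' @param n_patients number of patients.
#' @param k_probs probability of 2, 3, 4 or 5 repeated scans per patient.
#' @param group_probs named probabilities of the heterogeneity groups.
#' @param sigma_w named per-group within-canal standard deviation of the
#'   SMCD measurements, mm (a single unnamed value recycles to all
#'   groups).
#' @param mu_dls named per-group mean DLS-vs-radiologist SMCD, mm.
#' @param sigma_between SD of per-canal mean distance around the group
#'   mean, mm.
#' @param annotation_sd scale of the radiologist's independent
#'   re-annotation noise per scan, mm (expected SMCD to the template).
#' @param corr_length displacement-field correlation length, mm.
#' @param truncate_prob,truncate_len,dropout_prob rescan artefact rates,
#'   see [perturb_for_rescan()].
#' @param spacing_choices,spacing_probs voxel spacings (mm) sampled per
#'   scan and their probabilities.
#' @param rater_truth per-marker list of expert parameters: `alpha`
#'   (length 3) and `delta` (3 x 4 matrix); see the defaults.
#' @param sigma_x SD of the latent per-segmentation quality effect.
#' @param jitter_sd per-patient anatomy jitter, mm.
#' @param seed master seed for the whole cohort.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_patients = 72L,
    k_probs = c(`2` = 0.54, `3` = 0.20, `4` = 0.15, `5` = 0.11),
    group_probs = c(normal = 23, tmj_prosthetic = 13,
                    orthognathic = 22, pathological = 14) / 72,
    sigma_w = c(normal = 0.12, tmj_prosthetic = 0.21,
                orthognathic = 0.62, pathological = 0.23),
    mu_dls = c(normal = 0.74, tmj_prosthetic = 0.76,
               orthognathic = 0.81, pathological = 0.72),
    sigma_between = 0.08,
    annotation_sd = 0.05,
    corr_length = 10,
    truncate_prob = 0.05,
    truncate_len = c(2, 8),
    dropout_prob = 0.03,
    spacing_choices = c(0.2, 0.3, 0.4),
    spacing_probs = c(0.61, 0.31, 0.08),
    rater_truth = list(
      radiologist = list(
        alpha = c(expert1 = 3.0, expert2 = 2.2, expert3 = 1.8),
        delta = matrix(rep(c(-4.0, -3.4, -2.9, -2.3), each = 3L), 3L, 4L)),
      dls = list(
        alpha = c(expert1 = 2.2, expert2 = 1.8, expert3 = 1.5),
        delta = matrix(rep(c(-3.6, -3.0, -2.4, -1.8), each = 3L), 3L, 4L))),
    sigma_x = 1,
    jitter_sd = 1.5,
    seed = 1L) {
  groups <- names(group_probs)
  expand <- function(v) {
    if (is.null(names(v)) && length(v) == 1L)
      v <- stats::setNames(rep(v, length(groups)), groups)
    if (!all(groups %in% names(v)))
      stop("per-group parameter must name every heterogeneity group")
    v[groups]
  }
  cfg <- list(n_patients = as.integer(n_patients), k_probs = k_probs,
              group_probs = group_probs, sigma_w = expand(sigma_w),
              mu_dls = expand(mu_dls), sigma_between = sigma_between,
              annotation_sd = annotation_sd, corr_length = corr_length,
              truncate_prob = truncate_prob, truncate_len = truncate_len,
              dropout_prob = dropout_prob,
              spacing_choices = spacing_choices,
              spacing_probs = spacing_probs,
              rater_truth = rater_truth, sigma_x = sigma_x,
              jitter_sd = jitter_sd, seed = as.integer(seed))
  stopifnot(abs(sum(cfg$group_probs) - 1) < 1e-8,
            abs(sum(cfg$k_probs) - 1) < 1e-8,
            all(cfg$sigma_w >= 0), cfg$dropout_prob >= 0,
            cfg$dropout_prob <= 1, cfg$truncate_prob >= 0,
            cfg$truncate_prob <= 1)
  class(cfg) <- "cohort_config"
  cfg
}

#' Simulate a repeated-scan cohort with known ground truth
#'
#' Generates, for every patient, scan and side: a radiologist-role curve
#' (the patient's template canal plus small independent annotation noise)
#' and a DLS-role curve (the template perturbed by a smooth within-subject
#' field whose SMCD target is drawn per scan around the canal's mean
#' distance), with the configured truncation and dropout rates.  The
#' manifest records the group label, spacing, dropout/truncation events
#' and the true target distances, so downstream estimates can be checked
#' against the generating values.
#'
#' @param config a [cohort_config()].
#' @return List with `curves_radiologist` and `curves_dls` (curve tables
#'   in the interchange format, see [write_curves()]), `manifest` (one row
#'   per canal-scan) and the `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(substream_seed(config$seed, "cohort"))
  np <- config$n_patients
  groups <- names(config$group_probs)
  pat_group <- groups[sample.int(length(groups), np, replace = TRUE,
                                 prob = config$group_probs)]
  k_vals <- as.integer(names(config$k_probs))
  pat_k <- k_vals[sample.int(length(k_vals), np, replace = TRUE,
                             prob = config$k_probs)]

  rad_rows <- list(); dls_rows <- list(); man_rows <- list()
  set.seed(substream_seed(config$seed, "perturbation"))
  for (p in seq_len(np)) {
    pid <- sprintf("P%03d", p)
    g <- pat_group[p]
    for (side in c("left", "right")) {
      template <- make_template_canal(side, jitter_sd = config$jitter_sd)
      canal_id <- paste(pid, side, sep = "_")
      mu_i <- max(stats::rnorm(1L, config$mu_dls[g], config$sigma_between),
                  0.1)
      for (k in seq_len(pat_k[p])) {
        sid <- sprintf("%s_scan%d", pid, k)
        spacing <- config$spacing_choices[
          sample.int(length(config$spacing_choices), 1L,
                     prob = config$spacing_probs)]
        rad <- perturb_for_rescan(template, config$annotation_sd,
                                  config$corr_length, scan_id = sid)
        target <- -1
        while (target <= 0.01)
          target <- stats::rnorm(1L, mu_i, config$sigma_w[g])
        dls <- perturb_for_rescan(template, target, config$corr_length,
                                  truncate_prob = config$truncate_prob,
                                  truncate_len = config$truncate_len,
                                  dropout_prob = config$dropout_prob,
                                  exact = TRUE, scan_id = sid)
        dropped <- is.null(dls)
        rad_rows[[length(rad_rows) + 1L]] <- curve_to_rows(rad, pid, sid, side)
        if (!dropped)
          dls_rows[[length(dls_rows) + 1L]] <- curve_to_rows(dls, pid, sid, side)
        man_rows[[length(man_rows) + 1L]] <- data.frame(
          subject_id = pid, scan_id = sid, side = side,
          canal_id = canal_id, group = g, spacing = spacing,
          k_planned = pat_k[p], target_smcd = if (dropped) NA_real_ else target,
          dropout = dropped,
          truncated = if (dropped) "none" else attr(dls, "truncated"),
          trunc_len = if (dropped) 0 else attr(dls, "trunc_len"),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(curves_radiologist = do.call(rbind, rad_rows),
       curves_dls = do.call(rbind, dls_rows),
       manifest = do.call(rbind, man_rows),
       config = config)
}

curve_to_rows <- function(curve, subject_id, scan_id, side) {
  p <- curve$points
  data.frame(subject_id = subject_id, scan_id = scan_id, side = side,
             point_index = seq_len(nrow(p)) - 1L,
             x_mm = p[, 1L], y_mm = p[, 2L], z_mm = p[, 3L],
             stringsAsFactors = FALSE)
}

#' Simulate Likert ratings from known rater parameters
#'
#' Draws, for every canal-scan segmentation in the manifest and both
#' markers, a latent quality effect `x ~ Normal(0, sigma_x^2)` and then
#' ordinal scores from the partial credit model for each simulated expert
#' and session.  Segmentations the automated system dropped are scored 0
#' with the `fully_missing` error type; truncated ones attract the
#' matching `short_*` type; other error types are attached to low scores
#' consistently with the rule that the two clinically relevant types imply
#' scores 0-2.
#'
#' @param manifest manifest from [simulate_cohort()] (or any data frame
#'   with `scan_id`, `side`, `dropout`, `truncated` columns).
#' @param rater_truth per-marker expert parameters, see [cohort_config()].
#' @param sigma_x latent effect SD.
#' @param seed integer seed.
#' @return A ratings data frame in the format of [likert], plus a
#'   `truth` attribute with the latent effects per segmentation.
#' @export
simulate_likert <- function(manifest,
                            rater_truth = cohort_config()$rater_truth,
                            sigma_x = 1, seed = 1L) {
  set.seed(substream_seed(seed, "ratings"))
  for (mk in names(rater_truth))
    if (any(rater_truth[[mk]]$alpha <= 0))
      stop("rater discriminations must be positive")
  seg_id <- paste(manifest$scan_id, manifest$side, sep = "_")
  rows <- list(); truth <- list()
  for (mk in names(rater_truth)) {
    tr <- rater_truth[[mk]]
    experts <- names(tr$alpha)
    if (is.null(experts)) experts <- paste0("expert", seq_along(tr$alpha))
    x <- stats::rnorm(length(seg_id), 0, sigma_x)
    truth[[mk]] <- stats::setNames(x, seg_id)
    for (j in seq_along(experts)) for (ses in 1:2) {
      score <- rpcm(x, tr$alpha[j], tr$delta[j, ]) - 1L
      err <- character(length(score))
      if (mk == "dls") {
        score[manifest$dropout] <- 0L
        err[manifest$dropout] <- "fully_missing"
        tr_ant <- manifest$truncated == "anterior" & !manifest$dropout
        tr_post <- manifest$truncated == "posterior" & !manifest$dropout
        err[tr_ant] <- paste0(err[tr_ant], ";short_mental")
        err[tr_post] <- paste0(err[tr_post], ";short_mandibular")
      }
      low <- score <= 2L & !startsWith(err, "fully_missing")
      add_major <- low & stats::runif(length(score)) < 0.5
      err[add_major] <- paste0(err[add_major], ";major_parts_missing")
      off <- score == 3L & stats::runif(length(score)) < 0.3
      err[off] <- paste0(err[off], ";off_centre")
      err <- sub("^;", "", err)
      rows[[length(rows) + 1L]] <- data.frame(
        canal_id = seg_id, rater = experts[j], session = ses, marker = mk,
        score = score, error_types = err, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- truth
  validate_ratings(out)
  out
}
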