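#' Compute agreement metrics for every canal-scan
#'
#' Joins radiologist-role and DLS-role curves on (subject, scan, side) and
#' computes, per canal-scan: the SMCD between the two centerlines, and
#' optionally the Dice coefficient and ASSD between tube masks voxelized
#' from them at the scan's spacing.  Canals with no DLS output become
#' invalid records with empty distance columns (the default validity
#' policy is output-exists; `smcd_max` optionally also invalidates canals
#' whose SMCD exceeds a threshold).
#'
#' @param rad_curves,dls_curves curve tables (data frames) or named lists
#'   of [canal_curve()] objects for the radiologist and DLS roles.
#' @param manifest optional manifest with per-scan `spacing`, `group` and
#'   (optionally) `immediate_postop` columns, joined on
#'   (`scan_id`, `side`).
#' @param step SMCD resampling interval, mm.
#' @param radius tube radius for voxelized masks, mm.
#' @param spacing fallback isotropic voxel spacing (mm) when the manifest
#'   does not supply one.
#' @param masks compute DSC/ASSD on voxelized tube masks (slower).
#' @param smcd_max validity threshold on SMCD, default `Inf` (disabled).
#' @param exclude_immediate_postop drop scans flagged `immediate_postop`
#'   in the manifest before computing anything.
#' @return Data frame of metric records: `subject_id`, `canal_id`,
#'   `scan_id`, `side`, `group`, `smcd`, `assd`, `dsc`, `valid`.
#' @export
run_metrics <- function(rad_curves, dls_curves, manifest = NULL,
                        step = 0.5, radius = 0.75, spacing = 0.4,
                        masks = TRUE, smcd_max = Inf,
                        exclude_immediate_postop = FALSE) {
  if (is.data.frame(rad_curves)) rad_curves <- curves_from_table(rad_curves)
  if (is.data.frame(dls_curves)) dls_curves <- curves_from_table(dls_curves)
  if (length(rad_curves) == 0L) stop("no radiologist curves to compare")
  meta <- function(scan_id, side, col, default) {
    if (is.null(manifest) || !col %in% names(manifest)) return(default)
    hit <- manifest[[col]][manifest$scan_id == scan_id &
                             manifest$side == side]
    if (length(hit) == 0L) default else hit[1L]
  }
  rows <- lapply(names(rad_curves), function(key) {
    rc <- rad_curves[[key]]
    if (exclude_immediate_postop &&
        isTRUE(meta(rc$scan_id, rc$side, "immediate_postop", FALSE)))
      return(NULL)
    rec <- data.frame(
      subject_id = rc$subject_id,
      canal_id = paste(rc$subject_id, rc$side, sep = "_"),
      scan_id = rc$scan_id, side = rc$side,
      group = as.character(meta(rc$scan_id, rc$side, "group", NA_character_)),
      smcd = NA_real_, assd = NA_real_, dsc = NA_real_, valid = FALSE,
      stringsAsFactors = FALSE)
    dc <- dls_curves[[key]]
    if (is.null(dc)) return(rec)  # DLS did not find this canal
    rec$smcd <- smcd(rc, dc, step = step)
    if (masks) {
      sp <- as.numeric(meta(rc$scan_id, rc$side, "spacing", spacing))
      grid <- grid_for_curves(list(rc, dc), spacing = sp,
                              margin = radius + 2 * sp)
      ma <- voxelize_tube(rc, grid, radius)
      mb <- voxelize_tube(dc, grid, radius)
      rec$dsc <- dsc(ma, mb)
      rec$assd <- assd(ma, mb)
    }
    rec$valid <- rec$smcd <= smcd_max
    if (!rec$valid) rec[c("smcd", "assd", "dsc")] <- NA_real_
    rec
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Repeatability table over the full dataset and each group
#'
#' Assembles the quantitative reproducibility report: one row for the
#' full dataset and one per heterogeneity group, each with the number of
#' canals `n`, measurements `N`, the set of replicate counts, the mean,
#' wSD, RC and range of the valid SMCD values.  Groups with fewer than
#' two replicated canals are skipped with a warning.
#'
#' @param records metric record table from [run_metrics()].
#' @param by name of the grouping column (default `"group"`); `NULL`
#'   reports the full dataset only.
#' @return Data frame in the shape of the quantitative results table.
#' @export
run_repeatability <- function(records, by = "group") {
  strata <- list(`Full dataset` = NULL)
  if (!is.null(by) && by %in% names(records)) {
    lv <- sort(unique(stats::na.omit(records[[by]])))
    for (g in lv) strata[[g]] <- g
  }
  rows <- lapply(names(strata), function(nm) {
    inp <- group_measurements(records, by = if (is.null(strata[[nm]])) NULL
                              else by, group = strata[[nm]])
    if (inp$n < 2L) {
      warning(sprintf("group '%s' has fewer than 2 replicated canals; skipped", nm))
      return(NULL)
    }
    fit <- repeatability(inp)
    data.frame(group = nm, n = fit$n, N = fit$N,
               K = paste0("{", paste(fit$k_set, collapse = ", "), "}"),
               mean = fit$mean, wSD = fit$wsd, RC = fit$rc,
               min = fit$range[1L], max = fit$range[2L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Qualitative reproducibility and rating summary reports
#'
#' For each marker (radiologist annotations and DLS outputs are modelled
#' in separate fits): the posterior repeatability measure with 95%
#' credibility intervals per expert and for the across-expert average,
#' fitted on session-1 scores; optionally the companion binary-scale RM
#' (the model refitted with H = 2 on binarized scores); the descriptive
#' Likert summary (counts, mean, SD over all sessions and experts); and
#' the intra- and inter-observer accuracy matrices.
#'
#' @param ratings Likert ratings table (see [likert]).
#' @param markers markers to analyse.
#' @param binary also fit the binary diagnostic-suitability scale.
#' @param mcmc list of MCMC settings passed to [fit_pcm()] (`chains`,
#'   `adapt`, `warmup`, `iter`, `rhat_max`, `min_ess`).
#' @param seed integer seed for the samplers.
#' @return List with `rm_table`, `rm_binary_table` (or `NULL`),
#'   `likert_table`, `intraobserver` and `interobserver` data frames.
#' @export
run_likert <- function(ratings, markers = c("radiologist", "dls"),
                       binary = TRUE, mcmc = list(), seed = 1L) {
  ratings <- validate_ratings(ratings)
  fit_one <- function(marker, H) {
    args <- c(list(ratings = ratings, H = H, marker = marker,
                   seed = substream_seed(seed, paste0("rm_", marker, H))),
              mcmc)
    rm_posterior(do.call(fit_pcm, args))
  }
  rm_rows <- function(H) {
    do.call(rbind, lapply(markers, function(mk) {
      res <- fit_one(mk, H)
      data.frame(marker = mk, as.data.frame(res),
                 stringsAsFactors = FALSE)
    }))
  }
  rm_table <- rm_rows(5L)
  rm_binary_table <- if (binary) rm_rows(2L) else NULL

  likert_table <- do.call(rbind, lapply(markers, function(mk) {
    ls <- likert_summary(ratings[ratings$marker == mk, ])
    data.frame(marker = mk, mean = ls$mean, sd = ls$sd,
               t(as.integer(ls$counts)), stringsAsFactors = FALSE) |>
      stats::setNames(c("marker", "mean", "sd", paste0("N_", 0:4)))
  }))

  experts <- sort(unique(as.character(ratings$rater)))
  align <- function(mk, ses, rater) {
    d <- ratings[ratings$marker == mk & ratings$session == ses &
                   ratings$rater == rater, ]
    stats::setNames(d$score, d$canal_id)
  }
  intra <- do.call(rbind, lapply(markers, function(mk)
    do.call(rbind, lapply(experts, function(ex) {
      s1 <- align(mk, 1L, ex); s2 <- align(mk, 2L, ex)
      ids <- intersect(names(s1), names(s2))
      data.frame(marker = mk, rater = ex,
                 accuracy = agreement_accuracy(s1[ids], s2[ids]),
                 n = length(ids), stringsAsFactors = FALSE)
    }))))
  pairs <- if (length(experts) >= 2L) utils::combn(experts, 2L) else NULL
  inter <- if (is.null(pairs)) NULL else
    do.call(rbind, lapply(markers, function(mk)
      do.call(rbind, lapply(seq_len(ncol(pairs)), function(pi) {
        a <- align(mk, 1L, pairs[1L, pi]); b <- align(mk, 1L, pairs[2L, pi])
        ids <- intersect(names(a), names(b))
        data.frame(marker = mk, rater_a = pairs[1L, pi],
                   rater_b = pairs[2L, pi],
                   accuracy = agreement_accuracy(a[ids], b[ids]),
                   n = length(ids), stringsAsFactors = FALSE)
      }))))
  list(rm_table = rm_table, rm_binary_table = rm_binary_table,
       likert_table = likert_table, intraobserver = intra,
       interobserver = inter)
}

#' Provenance block for report outputs
#'
#' A stable fingerprint of a run: the MD5 hash of the serialized
#' configuration, the package and R versions, and the seed.  Re-running
#' with the same configuration and seed reproduces outputs bit-identically;
#' changing any configuration field changes the hash.
#'
#' @param config any serialisable configuration object.
#' @param seed the master seed of the run.
#' @return Named list.
#' @export
provenance <- function(config, seed = NULL) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  list(config_hash = unname(tools::md5sum(tmp)),
       package = as.character(utils::packageVersion("canalrepro")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       seed = seed)
}

#' Run the full reproducibility pipeline on a synthetic cohort
#'
#' Convenience wrapper chaining [simulate_cohort()], [simulate_likert()],
#' [run_metrics()], [run_repeatability()] and [run_likert()], writing all
#' report tables (delimited text) plus a JSON provenance block to
#' `out_dir` when given.
#'
#' @param config a [cohort_config()].
#' @param out_dir optional output directory.
#' @param masks compute DSC/ASSD masks (slower).
#' @param mcmc MCMC settings forwarded to [run_likert()].
#' @param binary also compute the binary-scale RM.
#' @return List with `metrics`, `repeatability`, `likert` and
#'   `provenance` components.
#' @export
run_report <- function(config = cohort_config(), out_dir = NULL,
                       masks = TRUE, mcmc = list(), binary = TRUE) {
  cohort <- simulate_cohort(config)
  ratings <- simulate_likert(cohort$manifest, config$rater_truth,
                             config$sigma_x, seed = config$seed)
  records <- run_metrics(cohort$curves_radiologist, cohort$curves_dls,
                         manifest = cohort$manifest, masks = masks)
  rep_table <- run_repeatability(records)
  likert <- run_likert(ratings, mcmc = mcmc, binary = binary,
                       seed = config$seed)
  prov <- provenance(config, seed = config$seed)
  out <- list(metrics = records, repeatability = rep_table,
              likert = likert, provenance = prov)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics(records, file.path(out_dir, "metric_records.csv"))
    utils::write.csv(rep_table, file.path(out_dir, "repeatability.csv"),
                     row.names = FALSE)
    utils::write.csv(likert$rm_table, file.path(out_dir, "rm_table.csv"),
                     row.names = FALSE)
    if (!is.null(likert$rm_binary_table))
      utils::write.csv(likert$rm_binary_table,
                       file.path(out_dir, "rm_binary_table.csv"),
                       row.names = FALSE)
    utils::write.csv(likert$likert_table,
                     file.path(out_dir, "likert_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(likert$intraobserver,
                     file.path(out_dir, "intraobserver.csv"),
                     row.names = FALSE)
    utils::write.csv(likert$interobserver,
                     file.path(out_dir, "interobserver.csv"),
                     row.names = FALSE)
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  out
}
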