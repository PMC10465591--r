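pcm_jags_model <- "
model {
  for (i in 1:Nsub) { x[i] ~ dnorm(0, 1) }
  for (j in 1:Nrater) {
    alpha[j] ~ dlnorm(0, 1)
    for (m in 1:(H - 1)) { delta[j, m] ~ dnorm(0, 0.25) }
  }
  for (o in 1:Nobs) {
    eta[o, 1] <- 0
    for (h in 2:H) {
      eta[o, h] <- eta[o, h - 1] + alpha[r[o]] * (x[s[o]] - delta[r[o], h - 1])
    }
    for (h in 1:H) { p[o, h] <- exp(eta[o, h] - max(eta[o, 1:H])) }
    y[o] ~ dcat(p[o, 1:H])
  }
}"

#' Fit a Bayesian partial credit model to Likert ratings
#'
#' Joint posterior over per-canal latent effects `x_i`, per-rater
#' discriminations `alpha_j` and step thresholds `delta_jm` via MCMC
#' (JAGS).  The latent scale is anchored by `x_i ~ Normal(0, 1)`; the
#' weakly informative priors are `alpha_j ~ LogNormal(0, 1)` and
#' `delta_jm ~ Normal(0, 2^2)`.  Scores on the reported 0-4 scale are
#' mapped to the internal 1..H scale before fitting; with `H = 2` the
#' scores are first binarized with [binarize_score()] so the model reduces
#' to a logistic rater model on diagnostic suitability.
#'
#' A rater whose (selected) scores all fall in one category carries no
#' information about its discrimination; such raters are excluded from the
#' MCMC with a warning and reported as degenerate, with their
#' repeatability measure fixed at the deterministic limit 1 in
#' [rm_posterior()].
#'
#' @param ratings Likert rating table (see [likert]); only `session`
#'   ratings of `marker` are used.
#' @param H number of ordinal categories: 5 (default) or 2 (binary scale).
#' @param session rating session used for the fit (default 1).
#' @param marker `"radiologist"`, `"dls"`, or `NULL` to use all rows.
#' @param chains,adapt,warmup,iter MCMC size: number of chains, adaptation
#'   steps, burn-in steps and retained iterations per chain.
#' @param seed integer seed controlling all chains.
#' @param rhat_max convergence gate: the fit fails loudly when any rater
#'   parameter (`alpha`, `delta`) has split-chain R-hat above this
#'   (default 1.01).
#' @param min_ess minimum effective sample size (across chains) required
#'   for `alpha` and `delta` parameters.
#' @param check_convergence set `FALSE` to keep a non-converged fit (it is
#'   still flagged and refused by [rm_posterior()] unless overridden).
#' @return An object of class `pcm_fit`.
#' @seealso [rm_posterior()] for the repeatability measure.
#' @export
fit_pcm <- function(ratings, H = 5L, session = 1L, marker = NULL,
                    chains = 4L, adapt = 500L, warmup = 1000L, iter = 1000L,
                    seed = NULL, rhat_max = 1.01, min_ess = 100,
                    check_convergence = TRUE) {
  ratings <- validate_ratings(ratings)
  if (!H %in% c(2L, 5L)) stop("H must be 5 (Likert) or 2 (binary scale)")
  keep <- ratings$session == session
  if (!is.null(marker)) keep <- keep & ratings$marker == marker
  ratings <- ratings[keep, , drop = FALSE]
  if (nrow(ratings) == 0L) stop("no ratings selected for the fit")

  # 0-4 -> 1..5; binary scale: not fully usable -> 1, fully usable -> 2
  y <- if (H == 2L) ifelse(ratings$score >= 3, 2L, 1L) else ratings$score + 1L

  rater_levels <- sort(unique(as.character(ratings$rater)))
  subj_levels <- sort(unique(as.character(ratings$canal_id)))
  r <- match(as.character(ratings$rater), rater_levels)
  s <- match(as.character(ratings$canal_id), subj_levels)

  per_rater_cats <- tapply(y, factor(r, levels = seq_along(rater_levels)),
                           function(v) length(unique(v)))
  degenerate <- rater_levels[which(per_rater_cats < 2L)]
  if (length(degenerate)) {
    warning("rater(s) with all scores in one category excluded from MCMC: ",
            paste(degenerate, collapse = ", "),
            " (repeatability measure fixed at the deterministic limit)")
    ok <- !(rater_levels[r] %in% degenerate)
    y <- y[ok]; s <- s[ok]
    r <- match(rater_levels[r][ok], setdiff(rater_levels, degenerate))
    active <- setdiff(rater_levels, degenerate)
    used <- sort(unique(s))
    s <- match(s, used)
    subj_levels <- subj_levels[used]
  } else active <- rater_levels
  if (length(active) == 0L)
    stop("no rater with score variation: the model is unidentifiable")
  n_sub <- length(subj_levels)
  if (length(active) < 2L && n_sub < 10L)
    stop("need >= 2 raters or >= 10 subjects to fit the model")

  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  # explicit overdispersed-but-moderate starting points: JAGS's default of
  # drawing inits from the priors can start alpha deep in the LogNormal
  # tail, where slice updates become extremely expensive
  rng_state <- get0(".Random.seed", envir = globalenv())
  inits <- lapply(seq_len(chains), function(ch) {
    chseed <- (as.integer(seed) + 7919L * ch) %% 2147483562L + 1L
    set.seed(chseed)
    list(alpha = stats::runif(length(active), 0.5, 2),
         delta = matrix(stats::rnorm(length(active) * (H - 1L), 0, 0.5),
                        length(active), H - 1L),
         x = stats::rnorm(n_sub, 0, 0.5),
         .RNG.name = "base::Mersenne-Twister", .RNG.seed = chseed)
  })
  if (!is.null(rng_state)) assign(".Random.seed", rng_state,
                                  envir = globalenv())

  dat <- list(y = y, s = s, r = r, Nsub = n_sub,
              Nrater = length(active), Nobs = length(y), H = H)
  jm <- rjags::jags.model(textConnection(pcm_jags_model), data = dat,
                          inits = inits, n.chains = chains,
                          n.adapt = adapt, quiet = TRUE)
  if (warmup > 0) stats::update(jm, n.iter = warmup, progress.bar = "none")
  draws <- rjags::coda.samples(jm, c("alpha", "delta", "x"),
                               n.iter = iter, progress.bar = "none")

  # the gate applies to the structural rater parameters; the per-subject
  # effects are nuisance parameters entering only through averages
  core <- grep("^(alpha|delta)", coda::varnames(draws), value = TRUE)
  rhat <- split_rhat(draws)
  core_rhat <- max(rhat[core], na.rm = TRUE)
  ess <- coda::effectiveSize(draws[, core, drop = FALSE])
  converged <- core_rhat <= rhat_max && min(ess) >= min_ess
  if (!converged && check_convergence)
    stop(sprintf(paste0(
      "MCMC did not converge: max split R-hat %.3f (gate %.2f), ",
      "min ESS %.0f (gate %.0f); increase warmup/iter"),
      core_rhat, rhat_max, min(ess), min_ess))

  structure(
    list(draws = draws, raters = active, degenerate = degenerate,
         subjects = subj_levels, H = H, session = session, marker = marker,
         chains = chains, iter = iter, seed = seed,
         diagnostics = list(split_rhat = rhat, ess = ess,
                            max_rhat = core_rhat,
                            min_ess = min(ess), converged = converged)),
    class = "pcm_fit")
}

#' Split-chain R-hat convergence statistic
#'
#' Each chain is split in half and the potential scale reduction factor is
#' computed over the resulting half-chains, per parameter.
#'
#' @param draws a `coda::mcmc.list`.
#' @return Named numeric vector of R-hat values.
#' @export
split_rhat <- function(draws) {
  mats <- lapply(draws, as.matrix)
  n <- nrow(mats[[1L]])
  h <- n %/% 2L
  halves <- unlist(lapply(mats, function(m)
    list(m[seq_len(h), , drop = FALSE],
         m[seq_len(h) + (n - h), , drop = FALSE])), recursive = FALSE)
  vapply(colnames(mats[[1L]]), function(p) {
    ch <- vapply(halves, function(m) c(mean(m[, p]), stats::var(m[, p])),
                 numeric(2))
    W <- mean(ch[2L, ])
    B <- h * stats::var(ch[1L, ])
    if (W == 0) return(1)
    sqrt(((h - 1) / h * W + B / h) / W)
  }, numeric(1))
}

# JAGS drops indices from singleton nodes ("alpha" rather than "alpha[1]");
# resolve a parameter column regardless
par_col <- function(M, base, i, j = NULL) {
  cand <- c(if (!is.null(j)) sprintf("%s[%d,%d]", base, i, j),
            sprintf("%s[%d]", base, i), base)
  hit <- cand[cand %in% colnames(M)][1L]
  if (is.na(hit)) stop("parameter not found in draws: ", cand[1L])
  M[, hit]
}

#' @export
print.pcm_fit <- function(x, ...) {
  cat(sprintf("Partial credit model fit (H = %d), %d rater(s), %d subjects\n",
              x$H, length(x$raters), length(x$subjects)))
  cat(sprintf("  %d chains x %d iterations; max split R-hat %.3f, min ESS %.0f%s\n",
              x$chains, x$iter, x$diagnostics$max_rhat, x$diagnostics$min_ess,
              if (x$diagnostics$converged) "" else " [NOT CONVERGED]"))
  if (length(x$degenerate))
    cat("  degenerate rater(s):", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.pcm_fit <- function(object, ...) {
  M <- as.matrix(object$draws)
  alpha <- vapply(seq_along(object$raters),
                  function(j) mean(par_col(M, "alpha", j)), numeric(1))
  names(alpha) <- object$raters
  delta <- t(vapply(seq_along(object$raters), function(j)
    vapply(seq_len(object$H - 1L),
           function(m) mean(par_col(M, "delta", j, m)), numeric(1)),
    numeric(object$H - 1L)))
  dimnames(delta) <- list(object$raters, paste0("delta", seq_len(object$H - 1L)))
  list(alpha = alpha, delta = delta)
}

#' @export
summary.pcm_fit <- function(object, ...) {
  co <- coef(object)
  data.frame(rater = object$raters, alpha = co$alpha, co$delta,
             row.names = NULL, check.names = FALSE)
}

#' Posterior repeatability measure from a PCM fit
#'
#' Evaluates [rm_hat()] at every posterior draw (using that draw's subject
#' effects and rater parameters) and summarises the draws by their mean
#' and a central credibility interval, per rater and for the across-rater
#' average (the mean of the per-rater values within each draw).  Raters
#' excluded from the fit as degenerate enter with the deterministic limit
#' RM = 1.
#'
#' @param fit a converged [fit_pcm()] object.
#' @param prob credibility level of the interval (default 0.95).
#' @param allow_nonconverged set `TRUE` to summarise a flagged fit anyway.
#' @return An object of class `rm_result`: a data frame with columns
#'   `rater`, `mean`, `lower`, `upper` (the `"average"` row last), with
#'   the RM draws and fit diagnostics attached as attributes.
#' @export
rm_posterior <- function(fit, prob = 0.95, allow_nonconverged = FALSE) {
  stopifnot(inherits(fit, "pcm_fit"))
  if (!fit$diagnostics$converged && !allow_nonconverged)
    stop("refusing to summarise a non-converged fit (see diagnostics)")
  M <- as.matrix(fit$draws)
  n_sub <- length(fit$subjects)
  xs <- vapply(seq_len(n_sub), function(i) par_col(M, "x", i),
               numeric(nrow(M)))
  per_rater <- vapply(seq_along(fit$raters), function(j) {
    a <- par_col(M, "alpha", j)
    dd <- vapply(seq_len(fit$H - 1L),
                 function(m) par_col(M, "delta", j, m), numeric(nrow(M)))
    vapply(seq_len(nrow(M)), function(t)
      rm_hat(xs[t, ], a[t], dd[t, ]), numeric(1))
  }, numeric(nrow(M)))
  colnames(per_rater) <- fit$raters
  if (length(fit$degenerate)) {
    ones <- matrix(1, nrow(per_rater), length(fit$degenerate),
                   dimnames = list(NULL, fit$degenerate))
    per_rater <- cbind(per_rater, ones)
    per_rater <- per_rater[, order(colnames(per_rater)), drop = FALSE]
  }
  draws <- cbind(per_rater, average = rowMeans(per_rater))
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  out <- data.frame(
    rater = colnames(draws),
    mean = colMeans(draws),
    lower = apply(draws, 2L, stats::quantile, qs[1L]),
    upper = apply(draws, 2L, stats::quantile, qs[2L]),
    row.names = NULL)
  structure(out, class = c("rm_result", "data.frame"),
            rm_draws = draws, prob = prob, H = fit$H,
            marker = fit$marker, diagnostics = fit$diagnostics)
}

#' @export
print.rm_result <- function(x, digits = 3, ...) {
  cat(sprintf("Repeatability measure (posterior mean and %.0f%% CrI)%s\n",
              100 * attr(x, "prob"),
              if (is.null(attr(x, "marker"))) ""
              else paste0(", marker: ", attr(x, "marker"))))
  df <- as.data.frame(x)
  df$mean <- round(df$mean, digits)
  df$lower <- round(df$lower, digits)
  df$upper <- round(df$upper, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
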