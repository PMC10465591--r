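# independent term-by-term evaluation of the partial credit model
oracle_pcm <- function(x, alpha, delta) {
  H <- length(delta) + 1
  num <- numeric(H)
  for (h in 1:H) {
    e <- 0
    if (h > 1) for (m in 1:(h - 1)) e <- e + alpha * (x - delta[m])
    num[h] <- exp(e)
  }
  num / sum(num)
}

test_that("pcm probabilities follow the step-sum formula", {
  p <- pcm_probabilities(0.3, 1.5, c(-1, -0.2, 0.4, 1.1))
  expect_equal(p, oracle_pcm(0.3, 1.5, c(-1, -0.2, 0.4, 1.1)),
               tolerance = 1e-12)
  expect_equal(pcm_probabilities(1.7, 0, c(-1, 0, 1, 2)), rep(0.2, 5))
  # two categories collapse to a logistic
  for (x in c(-1, 0.4, 2)) {
    p2 <- pcm_probabilities(x, 1.3, -0.5)
    expect_equal(p2[2], plogis(1.3 * (x + 0.5)), tolerance = 1e-12)
  }
  expect_error(pcm_probabilities(0, Inf, c(0, 1)), "finite")
})

test_that("pcm probabilities are a proper distribution for random draws", {
  set.seed(17)
  for (rep in 1:1000) {
    p <- pcm_probabilities(stats::rnorm(1, 0, 2), stats::rlnorm(1),
                           stats::rnorm(4, 0, 2))
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_true(all(p > 0))
  }
})

test_that("rm_hat matches the explicit double sum and its limits", {
  # alpha = 0: uniform probabilities, the 1/H lower bound
  expect_equal(rm_hat(c(-1, 0, 1), 0, c(-1, 0, 1, 2)), 0.2)
  # near-deterministic rater
  expect_gt(rm_hat(c(2, 3), 50, c(-1, -0.5, 0, 0.5)), 0.999)
  # three subjects, hand-computed double sum
  x <- c(-0.5, 0.2, 1.1); alpha <- 1.4; delta <- c(-1, -0.1, 0.6, 1.3)
  want <- mean(sapply(x, function(xi) sum(oracle_pcm(xi, alpha, delta)^2)))
  expect_equal(rm_hat(x, alpha, delta), want, tolerance = 1e-12)
  expect_error(rm_hat(numeric(0), 1, c(0, 1)), "empty")
})

test_that("rm_hat stays in [1/H, 1] and is non-decreasing in alpha", {
  set.seed(29)
  for (rep in 1:50) {
    x <- stats::rnorm(10)
    delta <- sort(stats::rnorm(4, 0, 1.5))
    vals <- sapply(c(0, 0.5, 1, 2, 4, 8), function(a) rm_hat(x, a, delta))
    expect_true(all(vals >= 0.2 - 1e-12 & vals <= 1))
    expect_true(all(diff(vals) >= -1e-9))
  }
})

test_that("binarization maps 3-4 to fully usable and 0-2 to not", {
  expect_equal(as.character(binarize_score(c(3, 4))),
               rep("fully_usable", 2))
  expect_equal(as.character(binarize_score(0:2)),
               rep("not_fully_usable", 3))
  expect_error(binarize_score(5), "0..4")
})

test_that("median rating classifies fully / uncertain / not fully", {
  expect_equal(median_rating(c(4, 4, 4, 4, 4, 3)),
               list(median = 4, class = "fully"))
  expect_equal(median_rating(c(2, 2, 3, 3, 1, 4))$median, 2.5)
  expect_equal(median_rating(c(2, 2, 3, 3, 1, 4))$class, "uncertain")
  expect_equal(median_rating(c(0, 0, 1, 1, 2, 2)),
               list(median = 1, class = "not_fully"))
  expect_error(median_rating(numeric(0)), "no scores")
})

test_that("error-type majority voting is strict with ties excluded", {
  r3 <- list(c("off_centre"), c("off_centre"), character(0))
  expect_equal(majority_error_types(r3), "off_centre")
  expect_equal(majority_error_types(list("short_mental", character(0),
                                         character(0))), character(0))
  tie <- list("off_centre", "off_centre", character(0), character(0))
  expect_equal(majority_error_types(tie), character(0))
})

test_that("agreement accuracy counts identical scores", {
  expect_equal(agreement_accuracy(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(agreement_accuracy(c(rep(4, 9), 0), rep(4, 10)), 90)
  set.seed(3)
  a <- sample(0:4, 50, TRUE); b <- sample(0:4, 50, TRUE)
  n_same <- 0
  for (i in 1:50) if (a[i] == b[i]) n_same <- n_same + 1
  expect_equal(agreement_accuracy(a, b), 100 * n_same / 50)
  expect_error(agreement_accuracy(1:3, 1:4), "length")
})

test_that("likert summary reproduces the reported full-dataset statistics", {
  scores <- rep(0:4, times = c(0, 3, 12, 72, 1821))
  s <- likert_summary(scores)
  expect_equal(round(s$mean, 2), 3.94)
  expect_equal(round(s$sd, 2), 0.27)
  expect_equal(unname(as.integer(s$counts)), c(0, 3, 12, 72, 1821))
  expect_equal(sum(s$counts), length(scores))
  # binarized counts reconcile with the category counts
  bins <- table(binarize_score(scores))
  expect_equal(unname(bins["fully_usable"]), sum(s$counts[4:5]),
               ignore_attr = TRUE)
  one <- likert_summary(4L)
  expect_equal(one$mean, 4); expect_equal(one$sd, 0)
})

test_that("rating tables are validated against the error-type rules", {
  good <- data.frame(canal_id = "c1", rater = "e1", session = 1L,
                     marker = "dls", score = 1L,
                     error_types = "major_parts_missing")
  expect_silent(validate_ratings(good))
  bad <- good; bad$score <- 3L
  expect_error(validate_ratings(bad), "clinically relevant")
  bad2 <- good; bad2$error_types <- "melted"
  expect_error(validate_ratings(bad2), "unknown error types")
})
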