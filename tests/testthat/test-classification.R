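test_that("empirical density estimation is exact on small count tables", {
  d <- estimate_density(rep("h1", 7))
  expect_equal(nrow(d), 1)
  expect_equal(d$p, 1)
  d2 <- estimate_density(c("a", "a", "a", "b"))
  expect_equal(d2$p[match(c("a", "b"), d2$hash)], c(0.75, 0.25))
  expect_equal(attr(d2, "n"), 4)
  expect_error(estimate_density(character(0)), "empty")
})

test_that("density estimates are unbiased with Bernoulli variance", {
  # two-atom distribution with p = 0.3 / 0.7, n = 200 draws, 100 replicates
  set.seed(101)
  p_true <- 0.3; n <- 200; reps <- 100
  est <- replicate(reps, {
    x <- ifelse(runif(n) < p_true, "u", "v")
    d <- estimate_density(x)
    d$p[d$hash == "u"]
  })
  se <- sqrt(p_true * (1 - p_true) / n) / sqrt(reps)
  expect_lt(abs(mean(est) - p_true), 3 * se)
})

test_that("the Bayes rule reproduces closed-form posteriors", {
  # class 1 saw hash h in 2/10 profiles, class 2 in 1/10
  train <- tibble::tibble(
    class_label = c(rep(1, 10), rep(2, 10)),
    hash = c("h", "h", paste0("x", 1:8), "h", paste0("y", 1:9)))
  fit <- fit_bayes(train)
  res <- bayes_classify(fit, "h")
  expect_equal(res$class, 1)
  expect_equal(unname(res$posterior), c(2 / 3, 1 / 3))
  # profile seen in exactly one class
  res2 <- bayes_classify(fit, "x1")
  expect_equal(res2$class, 1)
  expect_equal(unname(res2$posterior), c(1, 0))
  # never-seen profile: abstention
  res3 <- bayes_classify(fit, "zzz")
  expect_true(is.na(res3$class))
  expect_true(all(res3$posterior == 0))
  expect_true(is.na(predict(fit, "zzz")))
  expect_error(fit_bayes(train, prior = c(`1` = 0.7, `2` = 0.7)), "sum to 1")
})

test_that("posteriors normalize and ties break to the lowest class", {
  train <- tibble::tibble(class_label = c(2, 1), hash = c("t", "t"))
  fit <- fit_bayes(train)
  res <- bayes_classify(fit, "t")
  expect_equal(sum(res$posterior), 1)
  expect_equal(res$class, 1)
})

test_that("discriminative training separates separable classes", {
  # two classes, clearly separated profiles, two points each (LDA needs >= 2)
  x <- matrix(0L, 4, 231)
  x[1:2, 1:3] <- 5L
  x[3:4, 1:3] <- 50L
  x[, 4] <- c(1L, 2L, 1L, 2L)  # within-class noise
  x[, 5] <- c(1L, 3L, 2L, 4L)
  y <- c("a", "a", "b", "b")
  for (m in c("svm", "lda")) {
    fit <- train_discriminative(x, y, method = m)
    expect_equal(predict(fit, x), y, info = m)
  }
  expect_error(train_discriminative(x, c("a", "b", "c", "d"), method = "lda"),
               "two training points")
  expect_error(train_discriminative(x[, 1:10], y, method = "svm"))
})

test_that("evaluation summarizes perfect and degenerate classifiers", {
  truth <- rep(1:3, each = 10)
  ev <- evaluate_predictions(truth, truth)
  expect_equal(ev$per_class$m, c(0, 0, 0))
  expect_equal(ev$overall_error, 0)
  diag_n <- ev$confusion$n[ev$confusion$truth == ev$confusion$pred]
  expect_equal(diag_n, c(10, 10, 10))
  expect_equal(ev$mean_ppv, 1)

  always1 <- rep(1, 30)
  ev2 <- evaluate_predictions(always1, truth)
  expect_equal(ev2$per_class$m, c(0, 1, 1))
  # abstentions count as errors
  ev3 <- evaluate_predictions(rep(NA, 30), truth)
  expect_equal(ev3$overall_error, 1)
})

test_that("regret of the Bayes classifier against itself is zero", {
  truth <- rep(1:2, each = 5)
  pred <- c(1, 1, 1, 2, 1, 2, 2, 2, 2, 1)
  ev <- evaluate_predictions(pred, truth)
  r <- regret(ev, ev)
  expect_true(all(r$regret == 0))
})

test_that("match probability counts prediction agreement across levels", {
  pb <- data.frame(p10 = c(1, 2, 3, 4), p20 = c(1, 2, 3, 5),
                   p30 = c(1, 1, 1, 1))
  mp <- match_probability(pb)
  expect_equal(mp$match_prob[mp$t == "p10" & mp$s == "p20"], 0.75)
  expect_equal(mp$match_prob[mp$t == "p10" & mp$s == "p30"], 0.25)
})

test_that("family confusion mass is computed from the confusion table", {
  truth <- c(1, 1, 1, 1, 2, 2)
  pred <- c(1, 1, 3, 3, 2, 2)
  ev <- evaluate_predictions(pred, truth)
  fam <- c(`1` = "Platonic", `2` = "Johnson", `3` = "Johnson")
  expect_equal(family_confusion(ev, fam, "Platonic", "Johnson"), 0.5)
  expect_equal(family_confusion(ev, fam, "Johnson", "Platonic"), 0)
})

test_that("feature subsets index the documented blocks", {
  expect_equal(profile_subset("all"), 1:231)
  expect_equal(profile_subset("global"), 1:3)
  expect_length(profile_subset("local"), 228)
  expect_length(profile_subset("complete"), 212)
  expect_length(profile_subset("incomplete"), 19)
  expect_setequal(c(profile_subset("global"), profile_subset("local")), 1:231)
  expect_setequal(c(profile_subset("complete"), profile_subset("incomplete")),
                  1:231)
  expect_error(profile_subset("weird"))
})

test_that("subset regret is zero for the full feature set by definition", {
  set.seed(5)
  lib <- test_library()
  tet <- test_solid("tetrahedron")
  oct <- test_solid("octahedron")
  train <- dplyr::bind_rows(
    dplyr::mutate(generate_ttps(tet, 40, 20, seed = 1), class_label = 1),
    dplyr::mutate(generate_ttps(oct, 40, 20, seed = 2), class_label = 2))
  test <- dplyr::bind_rows(
    dplyr::mutate(generate_ttps(tet, 15, 20, seed = 3), class_label = 1),
    dplyr::mutate(generate_ttps(oct, 15, 20, seed = 4), class_label = 2))
  r <- feature_subset_regret(train, test, "all", method = "svm")
  expect_true(all(r$regret == 0))
  r2 <- feature_subset_regret(train, test, "local", method = "svm")
  expect_equal(nrow(r2), 2)
  expect_error(feature_subset_regret(train, test, "bogus"), "unknown subset")
})
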