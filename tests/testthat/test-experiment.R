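test_that("configs validate their fields and round-trip through JSON", {
  cfg <- experiment_config(truncation_percents = c(10, 20), n_train = 50,
                           n_test = 10, seed = 3, method = "bayes")
  path <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$truncation_percents, cfg$truncation_percents)
  expect_equal(back$n_train, cfg$n_train)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$method, cfg$method)
  expect_equal(back$perturb, cfg$perturb)
  expect_error(experiment_config(truncation_percents = 120), "percent")
  expect_error(experiment_config(n_train = 0), "positive")
  expect_error(experiment_config(method = "forest"))
})

test_that("a small experiment runs, is seed-stable, and is exact at 0 %", {
  lib <- test_library()
  cm <- test_class_map()
  platonic <- lib[vapply(lib, function(p) p$family == "Platonic", logical(1))]
  class(platonic) <- "poly_library"
  cmp <- find_duplicate_profiles(platonic)
  cfg <- experiment_config(truncation_percents = 0, n_train = 40, n_test = 10,
                           seed = 11, method = "bayes")
  res <- run_experiment(cfg, library = platonic, class_map = cmp)
  expect_equal(res$overall_error, 0)
  res2 <- run_experiment(cfg, library = platonic, class_map = cmp)
  expect_equal(res$evaluations[["0"]]$confusion,
               res2$evaluations[["0"]]$confusion)
})

test_that("experiments write confusion and summary artifacts", {
  lib <- test_library()
  platonic <- lib[vapply(lib, function(p) p$family == "Platonic", logical(1))]
  class(platonic) <- "poly_library"
  cmp <- find_duplicate_profiles(platonic)
  out <- withr::local_tempdir()
  cfg <- experiment_config(truncation_percents = 20, n_train = 30, n_test = 5,
                           seed = 2, method = "bayes")
  run_experiment(cfg, library = platonic, class_map = cmp, out_dir = out)
  expect_true(file.exists(file.path(out, "confusion_p20.csv")))
  expect_true(file.exists(file.path(out, "summary_p20.json")))
  js <- jsonlite::fromJSON(file.path(out, "summary_p20.json"))
  expect_equal(js$config$seed, 2)
})

test_that("vertex caps restrict the class space", {
  lib <- test_library()
  cm <- test_class_map()
  cfg <- experiment_config(truncation_percents = 20, n_train = 20, n_test = 5,
                           seed = 4, method = "bayes", vertex_cap = 8)
  res <- run_experiment(cfg, library = lib, class_map = cm)
  caps <- ids_with_cap(8)
  expect_lte(nrow(res$evaluations[["20"]]$per_class), length(caps))
})

test_that("plot helpers return ggplot objects", {
  truth <- rep(1:2, each = 5)
  ev <- evaluate_predictions(truth, truth)
  expect_s3_class(autoplot(ev), "ggplot")
  sat <- tibble::tibble(n = c(10, 20), unique_ttps = c(3, 4))
  expect_s3_class(plot_saturation(sat), "ggplot")
})
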