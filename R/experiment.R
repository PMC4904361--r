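#' Experiment configuration
#'
#' Bundles the settings of a simulate-train-evaluate experiment.  Defaults
#' follow the reference study conditions: truncation percentages 10-30 in
#' steps of 5, 4500 training orientations per solid, 500 test profiles per
#' class, uniform prior.
#'
#' @param truncation_percents Numeric vector in `[0, 100)`.
#' @param n_train Training orientations per solid and percent.
#' @param n_test Test profiles per class and percent.
#' @param seed Base integer seed; per-stage substreams are derived from it.
#' @param method `"bayes"`, `"svm"` or `"lda"`.
#' @param features Feature subset (see [profile_subset()]).
#' @param vertex_cap Restrict to solids with at most this many vertices
#'   (`NA` = no restriction; discriminative methods conventionally use 20).
#' @param perturb Test-set mis-specification: `"none"` or `"delete-vertex"`.
#' @param deletion How a deleted vertex affects its incident edges: `"stub"`
#'   (edges remain visible as incomplete stubs, as when an annotator fails to
#'   mark a vertex) or `"remove"` (edges vanish entirely).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(truncation_percents = c(10, 15, 20, 25, 30),
                              n_train = 4500, n_test = 500, seed = 1,
                              method = c("bayes", "svm", "lda"),
                              features = "all", vertex_cap = NA,
                              perturb = c("none", "delete-vertex"),
                              deletion = c("stub", "remove")) {
  method <- match.arg(method)
  perturb <- match.arg(perturb)
  deletion <- match.arg(deletion)
  if (any(truncation_percents < 0 | truncation_percents >= 100))
    stop("truncation percents must lie in [0, 100)")
  if (n_train < 1 || n_test < 1) stop("counts must be positive")
  structure(list(truncation_percents = truncation_percents,
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 seed = as.integer(seed), method = method,
                 features = features, vertex_cap = vertex_cap,
                 perturb = perturb, deletion = deletion),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(paste0("<experiment_config> %s (features %s), percents %s, ",
                     "n_train %d, n_test %d, cap %s, perturb %s, seed %d\n"),
              x$method, x$features,
              paste(x$truncation_percents, collapse = "/"),
              x$n_train, x$n_test, as.character(x$vertex_cap), x$perturb,
              x$seed))
  invisible(x)
}

#' @rdname experiment_config
#' @param path JSON file path.
#' @export
write_config <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_config <- function(path) {
  j <- jsonlite::fromJSON(path)
  do.call(experiment_config, j)
}

# deterministic substream seeds below 2^31
seed_stream <- function(base, i) {
  (as.double(base) * 48271 + i * 1000003) %% 2147483629
}

#' Run a simulate-train-evaluate experiment
#'
#' For each truncation percentage: generates training TTPs for every library
#' solid (pooling duplicate-profile solids into their canonical class),
#' fits the configured classifier, generates an independent test set from the
#' canonical representative of each class (optionally mis-specified by random
#' vertex deletion), and evaluates.
#'
#' @param config An `experiment_config`.
#' @param library Optional pre-built `poly_library`.
#' @param class_map Optional pre-computed [find_duplicate_profiles()] result.
#' @param out_dir Optional directory; when given, a confusion CSV and a
#'   summary JSON (with the config and per-stage seeds) are written per
#'   percent.
#' @param progress Print progress lines.
#' @return A list of class `experiment_result`: per-percent
#'   `ttp_evaluation`s, per-class error table, and the overall mean error.
#' @export
run_experiment <- function(config, library = NULL, class_map = NULL,
                           out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  lib <- library %||% poly_library()
  cm <- class_map %||% find_duplicate_profiles(lib)
  classes <- cm$classes
  if (!is.na(config$vertex_cap)) {
    nv <- vapply(lib, function(p) nrow(p$vertices), integer(1))
    keep_ids <- vapply(lib, function(p) p$id, integer(1))[nv <= config$vertex_cap]
    lib <- lib[vapply(lib, function(p) p$id %in% keep_ids, logical(1))]
    classes <- classes[classes$id %in% keep_ids, ]
  }
  solid_by_id <- setNames(lib, vapply(lib, function(p) p$id, integer(1)))
  evals <- list()
  for (pct in config$truncation_percents) {
    train <- dplyr::bind_rows(purrr::map(seq_len(nrow(classes)), function(i) {
      p <- solid_by_id[[as.character(classes$id[i])]]
      tt <- generate_ttps(p, config$n_train, pct,
                          seed = seed_stream(config$seed, p$id * 10 + 1))
      tt$class_label <- classes$class_id[i]
      tt[, c("class_label", "hash",
             if (config$method != "bayes") profile_names())]
    }))
    reps <- classes[classes$id == classes$class_id, ]
    test <- dplyr::bind_rows(purrr::map(seq_len(nrow(reps)), function(i) {
      p <- solid_by_id[[as.character(reps$id[i])]]
      tt <- generate_ttps(p, config$n_test, pct,
                          seed = seed_stream(config$seed, p$id * 10 + 2),
                          perturb = config$perturb,
                          deletion = config$deletion %||% "stub")
      tt$class_label <- reps$class_id[i]
      tt[, c("class_label", "hash", profile_names())]
    }))
    if (config$method == "bayes") {
      fit <- fit_bayes(train)
      pred <- predict(fit, test$hash)
    } else {
      fit <- train_discriminative(ttp_matrix(train), train$class_label,
                                  method = config$method,
                                  features = config$features)
      pred <- as.integer(predict(fit, ttp_matrix(test)))
    }
    ev <- evaluate_predictions(pred, test$class_label,
                               classes = sort(unique(classes$class_id)))
    evals[[as.character(pct)]] <- ev
    if (progress)
      message(sprintf("percent %g: error %.4f", pct, ev$overall_error))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(ev$confusion,
                       file.path(out_dir, sprintf("confusion_p%g.csv", pct)),
                       row.names = FALSE)
      jsonlite::write_json(
        list(config = unclass(config), percent = pct,
             overall_error = ev$overall_error, mean_ppv = ev$mean_ppv),
        file.path(out_dir, sprintf("summary_p%g.json", pct)),
        auto_unbox = TRUE, digits = NA)
    }
  }
  per_class <- dplyr::bind_rows(purrr::imap(evals, function(ev, pct)
    dplyr::mutate(ev$per_class, percent = as.numeric(pct))))
  structure(list(evaluations = evals, per_class = per_class,
                 overall_error = mean(per_class$m), config = config,
                 class_map = cm),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s, overall error %.4f over %d percents\n",
              x$config$method, x$overall_error, length(x$evaluations)))
  invisible(x)
}

#' Feature-subset regret experiment
#'
#' Trains the configured discriminative classifier on a named feature subset
#' and reports the per-class regret relative to the same classifier trained
#' on all features, under the same train/test data.
#'
#' @param train,test TTP tibbles with `class_label` columns.
#' @param subset Feature subset name.
#' @param method `"svm"` or `"lda"`.
#' @return Tibble `class`, `m_subset`, `m_all`, `regret`.
#' @export
feature_subset_regret <- function(train, test, subset, method = "svm") {
  if (!subset %in% c("all", "global", "local", "complete", "incomplete"))
    stop("unknown subset name: ", subset)
  fit_all <- train_discriminative(ttp_matrix(train), train$class_label,
                                  method = method, features = "all")
  ev_all <- evaluate_predictions(predict(fit_all, ttp_matrix(test)),
                                 test$class_label)
  if (subset == "all") {
    out <- ev_all$per_class[, c("class", "m")]
    names(out)[2] <- "m_subset"
    out$m_all <- out$m_subset
    out$regret <- 0
    return(out)
  }
  fit_sub <- train_discriminative(ttp_matrix(train), train$class_label,
                                  method = method, features = subset)
  ev_sub <- evaluate_predictions(predict(fit_sub, ttp_matrix(test)),
                                 test$class_label)
  a <- ev_sub$per_class[, c("class", "m")]; names(a)[2] <- "m_subset"
  b <- ev_all$per_class[, c("class", "m")]; names(b)[2] <- "m_all"
  out <- dplyr::inner_join(a, b, by = "class")
  dplyr::mutate(out, regret = .data$m_subset - .data$m_all)
}
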