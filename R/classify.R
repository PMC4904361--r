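#' Empirical TTP density of one class
#'
#' The distribution of truncated topological profiles for a class is discrete
#' with limited support, so it is estimated by the empirical density
#' `p_hat(T | class) = count(T) / n`; the estimate is unbiased with variance
#' `p (1 - p) / n` per atom.
#'
#' @param hashes Character vector of profile hashes observed for the class.
#' @return Object of class `ttp_density`: tibble of `hash`, `count`, `p`,
#'   with attribute `n`.
#' @examples
#' d <- estimate_density(c("a", "a", "a", "b"))
#' d$p  # 0.75, 0.25
#' @export
estimate_density <- function(hashes) {
  if (length(hashes) < 1) stop("empty training set")
  tab <- sort(table(hashes), decreasing = TRUE)
  out <- tibble::tibble(hash = names(tab), count = as.integer(tab),
                        p = as.integer(tab) / length(hashes))
  attr(out, "n") <- length(hashes)
  class(out) <- c("ttp_density", class(out))
  out
}

#' Fit the empirical-density Bayes classifier
#'
#' Estimates one empirical TTP density per class from a training tibble and
#' precomputes the maximum-posterior class for every training hash.
#'
#' @param train Tibble with columns `class_label` and `hash` (e.g. pooled
#'   output of [generate_ttps()] joined with a class map).
#' @param prior Optional named prior over classes (default uniform over the
#'   classes present).  Must sum to 1 within 1e-9.
#' @return Object of class `bayes_ttp`.
#' @export
fit_bayes <- function(train, prior = NULL) {
  stopifnot(all(c("class_label", "hash") %in% names(train)))
  classes <- sort(unique(train$class_label))
  if (is.null(prior)) {
    prior <- setNames(rep(1 / length(classes), length(classes)),
                      as.character(classes))
  } else {
    if (abs(sum(prior) - 1) > 1e-9) stop("prior must sum to 1")
    prior <- prior[as.character(classes)]
  }
  n_class <- table(factor(train$class_label, levels = classes))
  counts <- dplyr::count(train, .data$class_label, .data$hash, name = "count")
  counts$p <- counts$count / as.integer(n_class[as.character(counts$class_label)])
  counts$w <- counts$p * prior[as.character(counts$class_label)]
  # per-hash argmax (ties broken by lowest class label)
  ord <- order(counts$hash, -counts$w, counts$class_label)
  cs <- counts[ord, ]
  first <- !duplicated(cs$hash)
  pred <- setNames(cs$class_label[first], cs$hash[first])
  structure(list(counts = counts, classes = classes, prior = prior,
                 n_class = as.integer(n_class), pred = pred),
            class = "bayes_ttp")
}

#' @export
print.bayes_ttp <- function(x, ...) {
  cat(sprintf("<bayes_ttp> %d classes, %d distinct training profiles\n",
              length(x$classes), length(x$pred)))
  invisible(x)
}

#' Posterior over classes for one profile
#'
#' Bayes rule on the empirical densities: the posterior of a class given a
#' profile `T` is proportional to `p_hat(T | class) * prior(class)`.  If no
#' class has positive likelihood the classifier abstains (`class = NA`), a
#' no-match that evaluation counts as an error.
#'
#' @param fit A `bayes_ttp`.
#' @param hash A single profile hash (or a `topological_profile`).
#' @return List with `class` (NA on no-match) and `posterior` (named vector
#'   over classes, all zero on no-match).
#' @export
bayes_classify <- function(fit, hash) {
  stopifnot(inherits(fit, "bayes_ttp"))
  if (inherits(hash, "topological_profile")) hash <- profile_hash(hash)
  sub <- fit$counts[fit$counts$hash == hash, ]
  post <- setNames(numeric(length(fit$classes)), as.character(fit$classes))
  if (nrow(sub) == 0)
    return(list(class = NA_integer_, posterior = post))
  w <- sub$w / sum(sub$w)
  post[as.character(sub$class_label)] <- w
  cl <- sub$class_label[order(-w, sub$class_label)][1]
  list(class = cl, posterior = post)
}

#' @export
predict.bayes_ttp <- function(object, hashes, ...) {
  unname(object$pred[hashes])
}

#' Train a discriminative classifier on profile vectors
#'
#' Wraps a support vector machine (radial kernel, one-vs-one multiclass,
#' training-column standardization, `e1071` defaults for cost and gamma) or
#' linear discriminant analysis on the 231-dimensional profile vectors.  The
#' profile matrix is rank-deficient (constant and collinear columns), so
#' features are first projected onto the principal components of the training
#' matrix with non-negligible variance; LDA is fitted in that subspace.
#'
#' @param x Training matrix (rows = profiles) or TTP tibble.
#' @param labels Class labels (coerced to factor).
#' @param method `"svm"` or `"lda"`.
#' @param features Feature subset name (see [profile_subset()]).
#' @return Object of class `ttp_classifier`.
#' @export
train_discriminative <- function(x, labels, method = c("svm", "lda"),
                                 features = "all") {
  method <- match.arg(method)
  if (is.data.frame(x)) x <- ttp_matrix(x)
  sel <- profile_subset(features)
  x <- x[, sel, drop = FALSE]
  y <- factor(labels)
  if (nrow(x) != length(y)) stop("feature/label dimension mismatch")
  if (method == "lda" && any(table(y) < 2))
    stop("LDA needs at least two training points per class")
  keep <- which(apply(x, 2, stats::var) > 1e-12)
  x <- x[, keep, drop = FALSE]
  if (method == "svm") {
    fit <- e1071::svm(x = x, y = y, kernel = "radial", scale = TRUE)
    proj <- NULL
  } else {
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    r <- sum(pc$sdev > 1e-8)
    proj <- list(center = pc$center, rot = pc$rotation[, seq_len(r), drop = FALSE])
    z <- scale(x, center = proj$center, scale = FALSE) %*% proj$rot
    # lda() rejects directions with zero within-group variance even though
    # they separate perfectly; nudge such columns deterministically
    wvar <- Reduce(`+`, lapply(split(seq_along(y), y), function(i) {
      zc <- scale(z[i, , drop = FALSE], scale = FALSE)
      colSums(zc^2)
    })) / length(y)
    flat <- wvar < 1e-10 * pmax(apply(z, 2, stats::var), 1e-300)
    if (any(flat)) {
      eps <- 1e-6 * pmax(apply(z, 2, stats::sd), 1e-6)
      z[, flat] <- z[, flat, drop = FALSE] +
        outer((-1)^seq_along(y), eps[flat])
    }
    fit <- suppressWarnings(MASS::lda(z, grouping = y))
  }
  structure(list(method = method, fit = fit, features = features,
                 keep = keep, proj = proj, levels = levels(y)),
            class = "ttp_classifier")
}

#' @export
print.ttp_classifier <- function(x, ...) {
  cat(sprintf("<ttp_classifier> %s on %d classes (features: %s, %d columns)\n",
              toupper(x$method), length(x$levels), x$features, length(x$keep)))
  invisible(x)
}

#' @export
predict.ttp_classifier <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- ttp_matrix(newdata)
  newdata <- newdata[, profile_subset(object$features), drop = FALSE]
  newdata <- newdata[, object$keep, drop = FALSE]
  if (object$method == "svm") {
    as.character(predict(object$fit, newdata))
  } else {
    z <- scale(newdata, center = object$proj$center, scale = FALSE) %*%
      object$proj$rot
    as.character(predict(object$fit, z)$class)
  }
}

#' Evaluate a classifier on labelled test profiles
#'
#' Builds the confusion matrix `M[pred, truth]`, the per-class
#' misclassification rate `m(class)` (abstentions count as errors), the
#' unweighted mean error over classes, and the per-predicted-class positive
#' predictive value (diagonal mass over predicted-column mass).
#'
#' @param pred Predicted class labels (NA = abstain).
#' @param truth True class labels.
#' @param classes Optional full class set (default: classes present in
#'   `truth`).
#' @return Object of class `ttp_evaluation` with elements `confusion`
#'   (tibble `truth`, `pred`, `n`), `per_class` (tibble `class`, `n_test`,
#'   `errors`, `m`), `overall_error`, `ppv` (tibble `pred`, `ppv`),
#'   `mean_ppv`.
#' @export
evaluate_predictions <- function(pred, truth, classes = NULL) {
  classes <- classes %||% sort(unique(truth))
  pred_chr <- ifelse(is.na(pred), "(abstain)", as.character(pred))
  conf <- dplyr::count(
    tibble::tibble(truth = as.character(truth), pred = pred_chr),
    .data$truth, .data$pred, name = "n")
  per_class <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(truth = as.character(truth),
                                   err = pred_chr != as.character(truth)),
                    .data$truth),
    n_test = dplyr::n(), errors = sum(.data$err), .groups = "drop")
  per_class <- dplyr::mutate(per_class, m = .data$errors / .data$n_test)
  names(per_class)[1] <- "class"
  ppv_tab <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(conf, .data$pred != "(abstain)"), .data$pred),
    ppv = sum(.data$n[.data$truth == .data$pred[1]]) / sum(.data$n),
    .groups = "drop")
  structure(list(confusion = conf, per_class = per_class,
                 overall_error = mean(per_class$m),
                 ppv = ppv_tab, mean_ppv = mean(ppv_tab$ppv),
                 classes = classes),
            class = "ttp_evaluation")
}

#' @export
print.ttp_evaluation <- function(x, ...) {
  cat(sprintf("<ttp_evaluation> %d classes, overall error %.4f, mean PPV %.3f\n",
              nrow(x$per_class), x$overall_error, x$mean_ppv))
  invisible(x)
}

#' @export
tidy.ttp_evaluation <- function(x, ...) x$per_class

#' @export
glance.ttp_evaluation <- function(x, ...) {
  tibble::tibble(n_classes = nrow(x$per_class),
                 n_test = sum(x$per_class$n_test),
                 overall_error = x$overall_error,
                 mean_ppv = x$mean_ppv)
}

#' Per-class regret of a classifier relative to the Bayes classifier
#'
#' @param eval_clf,eval_bayes `ttp_evaluation` objects on the same test sets.
#' @return Tibble `class`, `m_clf`, `m_bayes`, `regret`.
#' @export
regret <- function(eval_clf, eval_bayes) {
  a <- eval_clf$per_class[, c("class", "m")]
  names(a)[2] <- "m_clf"
  b <- eval_bayes$per_class[, c("class", "m")]
  names(b)[2] <- "m_bayes"
  out <- dplyr::inner_join(a, b, by = "class")
  dplyr::mutate(out, regret = .data$m_clf - .data$m_bayes)
}

#' Cross-truncation match probability
#'
#' Agreement of predictions for the same objects when the classifier assumes
#' different truncation levels: for each ordered pair of levels `t != s`, the
#' fraction of objects with identical predicted classes.
#'
#' @param pred_by_level Matrix or data frame: rows = objects, columns =
#'   truncation levels, entries = predicted classes.
#' @return Tibble `t`, `s`, `match_prob` for all unordered pairs.
#' @export
match_probability <- function(pred_by_level) {
  pred_by_level <- as.data.frame(pred_by_level)
  lev <- colnames(pred_by_level)
  cmb <- utils::combn(length(lev), 2)
  rows <- lapply(seq_len(ncol(cmb)), function(k) {
    i <- cmb[1, k]; j <- cmb[2, k]
    tibble::tibble(t = lev[i], s = lev[j],
                   match_prob = mean(pred_by_level[[i]] == pred_by_level[[j]]))
  })
  dplyr::bind_rows(rows)
}

#' Confusion mass from one family into another
#'
#' Probability that a test profile whose true class is in `from_family` is
#' predicted as a class in `to_family`, computed from a confusion tibble and
#' a class-to-family map.
#'
#' @param evaluation A `ttp_evaluation`.
#' @param class_family Named character vector mapping class label to family.
#' @param from_family,to_family Family names.
#' @return A single probability.
#' @export
family_confusion <- function(evaluation, class_family, from_family, to_family) {
  conf <- evaluation$confusion
  conf <- conf[conf$pred != "(abstain)", ]
  tf <- class_family[conf$truth]
  pf <- class_family[conf$pred]
  denom <- sum(conf$n[tf == from_family])
  if (denom == 0) return(NA_real_)
  sum(conf$n[tf == from_family & pf == to_family]) / denom
}
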