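# Random-forest classification/regression of Vk gene activity and
# rearrangement frequency, with cross-validated performance, variable
# importance, and recursive feature elimination.

feature_frame <- function(features) {
  abort_if(!"v_gene" %in% names(features), "features need a v_gene column")
  x <- as.data.frame(features[, setdiff(names(features), "v_gene")])
  rownames(x) <- features$v_gene
  abort_if(!all(vapply(x, is.numeric, logical(1))),
           "all feature columns must be numeric")
  x
}

make_folds <- function(n, n_folds) {
  sample(rep(seq_len(n_folds), length.out = n))
}

# OOB grid search for the per-split candidate count, on the training fold
# only; grid {sqrt(p)/2, sqrt(p), 2 sqrt(p)} for classification.
tune_mtry <- function(x, y, n_trees) {
  p <- ncol(x)
  s <- max(1L, floor(sqrt(p)))
  grid <- unique(pmin(p, pmax(1L, c(s %/% 2L, s, 2L * s))))
  oob <- vapply(grid, function(m) {
    fit <- randomForest::randomForest(x, y, ntree = min(500L, n_trees),
                                      mtry = m)
    fit$err.rate[nrow(fit$err.rate), "OOB"]
  }, numeric(1))
  grid[which.min(oob)]
}

rf_cv <- function(x, y, task, n_trees, n_folds, mtry, tune) {
  folds <- make_folds(nrow(x), n_folds)
  imp <- matrix(0, nrow = ncol(x), ncol = n_folds,
                dimnames = list(colnames(x), NULL))
  pred <- if (task == "classification") {
    factor(rep(NA_character_, nrow(x)), levels = levels(y))
  } else rep(NA_real_, nrow(x))
  mtry_used <- integer(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    m <- if (!is.null(mtry)) {
      mtry
    } else if (task == "classification" && tune) {
      tune_mtry(x[tr, , drop = FALSE], y[tr], n_trees)
    } else if (task == "classification") {
      max(1L, floor(sqrt(ncol(x))))
    } else {
      max(1L, floor(ncol(x) / 3))
    }
    fit <- randomForest::randomForest(x[tr, , drop = FALSE], y[tr],
                                      ntree = n_trees, mtry = m)
    pred[!tr] <- stats::predict(fit, x[!tr, , drop = FALSE])
    imp[, f] <- fit$importance[, 1]
    mtry_used[f] <- m
  }
  list(folds = folds, pred = pred, importance = rowMeans(imp),
       mtry = mtry_used)
}

new_kappa_rf <- function(task, cv, importance, performance, metric,
                         n_trees, mtry, seed) {
  structure(list(task = task, cv = cv,
                 importance = importance, performance = performance,
                 metric = metric, n_trees = n_trees, mtry = mtry,
                 seed = seed),
            class = "kappa_rf")
}

#' Random-forest classification of Vk gene activity
#'
#' 10-fold cross-validation with every gene in a test set exactly once;
#' 5,000 trees per fold by default; the per-split candidate count is tuned
#' on the training folds only via out-of-bag error. Accuracy is the
#' fraction of correct predictions across all test sets; variable
#' importance is the mean decrease in Gini index averaged over folds.
#'
#' @param features tibble from [assemble_feature_matrix()].
#' @param labels tibble with `v_gene` and logical `active` (e.g. from
#'   [classify_active()]).
#' @param n_trees trees per fold.
#' @param n_folds cross-validation folds.
#' @param mtry fixed per-split candidate count (disables tuning).
#' @param tune tune mtry by OOB grid search (default).
#' @param seed RNG seed.
#' @return A `kappa_rf` object; see [tidy.kappa_rf()], [glance.kappa_rf()],
#'   [autoplot.kappa_rf()].
#' @export
rf_classify <- function(features, labels, n_trees = 5000L, n_folds = 10L,
                        mtry = NULL, tune = TRUE, seed = 1L) {
  set.seed(seed)
  x <- feature_frame(features)
  lab <- labels[match(rownames(x), labels$v_gene), ]
  abort_if(anyNA(lab$active), "labels missing for some genes")
  y <- factor(ifelse(lab$active, "active", "inactive"),
              levels = c("inactive", "active"))
  abort_if(length(unique(y)) < 2, "labels are single-class")
  res <- rf_cv(x, y, "classification", n_trees, n_folds, mtry, tune)
  cv <- tibble::tibble(v_gene = rownames(x), fold = res$folds,
                       obs = as.character(y), pred = as.character(res$pred))
  new_kappa_rf(
    "classification", cv,
    tibble::tibble(feature = names(res$importance),
                   importance = unname(res$importance),
                   metric = "mean_decrease_gini"),
    performance = mean(cv$obs == cv$pred), metric = "accuracy",
    n_trees = n_trees, mtry = res$mtry, seed = seed
  )
}

#' Random-forest regression of rearrangement frequency
#'
#' Same cross-validation scheme as [rf_classify()], with the default
#' regression per-split candidate count (p/3). Performance is the root mean
#' squared error over all test predictions; variable importance is the mean
#' decrease in node purity averaged over folds. Intended for responses
#' defined over active genes only (and functional genes only for RNA/gDNA
#' ratio responses).
#'
#' @param features tibble from [assemble_feature_matrix()]; rows are matched
#'   to `response$v_gene`, so pass the active-gene subset.
#' @param response tibble with `v_gene` and `value`.
#' @inheritParams rf_classify
#' @param min_obs refuse to fit below this many observations.
#' @return A `kappa_rf` object.
#' @export
rf_regress <- function(features, response, n_trees = 5000L, n_folds = 10L,
                       mtry = NULL, seed = 1L, min_obs = 20L) {
  set.seed(seed)
  features <- features[features$v_gene %in% response$v_gene, ]
  abort_if(nrow(features) < min_obs,
           paste0("fewer than ", min_obs, " observations; refusing to fit"))
  x <- feature_frame(features)
  y <- response$value[match(rownames(x), response$v_gene)]
  abort_if(anyNA(y), "response missing for some genes")
  res <- rf_cv(x, y, "regression", n_trees, n_folds, mtry, tune = FALSE)
  cv <- tibble::tibble(v_gene = rownames(x), fold = res$folds,
                       obs = y, pred = res$pred)
  new_kappa_rf(
    "regression", cv,
    tibble::tibble(feature = names(res$importance),
                   importance = unname(res$importance),
                   metric = "mean_decrease_node_purity"),
    performance = sqrt(mean((cv$obs - cv$pred)^2)), metric = "rmse",
    n_trees = n_trees, mtry = res$mtry, seed = seed
  )
}

#' Recursive feature elimination over the top-ranked features
#'
#' Restricts to the `top_k` most important features of a fitted model, then
#' evaluates cross-validated models over nested subsets ranked by variable
#' importance (sizes `top_k` down to 1). Reports performance per subset
#' size and selects the smallest subset whose performance is within one
#' standard error of the best.
#'
#' @param features tibble from [assemble_feature_matrix()].
#' @param outcome labels tibble (`v_gene`, `active`) for classification or
#'   response tibble (`v_gene`, `value`) for regression.
#' @param model a fitted `kappa_rf` providing the importance ranking.
#' @param top_k number of top features to consider.
#' @param n_trees trees per fold during the elimination.
#' @param n_folds cross-validation folds.
#' @param seed RNG seed.
#' @return A `kappa_rfe` object with elements `curve` (size, performance,
#'   se), `selected` (feature names), `best_size`, `ranking`.
#' @export
rfe_select <- function(features, outcome, model, top_k = 20L,
                       n_trees = 1000L, n_folds = 10L, seed = 1L) {
  set.seed(seed)
  task <- model$task
  ranking <- dplyr::arrange(model$importance, dplyr::desc(.data$importance))
  p_avail <- nrow(ranking)
  if (top_k > p_avail) {
    rlang::warn("top_k exceeds the feature count; clamping")
    top_k <- p_avail
  }
  top <- ranking$feature[seq_len(top_k)]

  if (task == "classification") {
    lab <- outcome[match(features$v_gene, outcome$v_gene), ]
    y <- factor(ifelse(lab$active, "active", "inactive"),
                levels = c("inactive", "active"))
  } else {
    features <- features[features$v_gene %in% outcome$v_gene, ]
    y <- outcome$value[match(features$v_gene, outcome$v_gene)]
  }
  x_all <- feature_frame(features)
  folds <- make_folds(nrow(x_all), n_folds)

  curve <- purrr::map_dfr(seq.int(top_k, 1L), function(k) {
    x <- x_all[, top[seq_len(k)], drop = FALSE]
    perf_f <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      m <- if (task == "classification") {
        max(1L, floor(sqrt(k)))
      } else max(1L, floor(k / 3))
      fit <- randomForest::randomForest(x[tr, , drop = FALSE], y[tr],
                                        ntree = n_trees, mtry = m)
      pr <- stats::predict(fit, x[!tr, , drop = FALSE])
      if (task == "classification") {
        mean(pr == y[!tr])
      } else sqrt(mean((pr - y[!tr])^2))
    }, numeric(1))
    tibble::tibble(size = k, performance = mean(perf_f),
                   se = stats::sd(perf_f) / sqrt(n_folds))
  })

  better <- if (task == "classification") `>=` else `<=`
  best_i <- if (task == "classification") {
    which.max(curve$performance)
  } else which.min(curve$performance)
  margin <- if (task == "classification") {
    curve$performance[best_i] - curve$se[best_i]
  } else curve$performance[best_i] + curve$se[best_i]
  ok_sizes <- curve$size[better(curve$performance, margin)]
  best_size <- min(ok_sizes)
  structure(list(curve = dplyr::arrange(curve, .data$size),
                 selected = top[seq_len(best_size)],
                 best_size = best_size,
                 ranking = ranking[seq_len(top_k), ],
                 task = task, seed = seed),
            class = "kappa_rfe")
}

#' Pearson correlation between one feature and a response
#'
#' @param features tibble from [assemble_feature_matrix()].
#' @param response tibble with `v_gene`, `value`.
#' @param feature feature column name.
#' @param log_response correlate against `log(value)`.
#' @return One-row tibble with `feature`, `estimate`, `p.value`,
#'   `conf.low`, `conf.high`, `n`.
#' @export
correlate_feature <- function(features, response, feature,
                              log_response = FALSE) {
  abort_if(!feature %in% names(features), "unknown feature")
  merged <- dplyr::inner_join(features[, c("v_gene", feature)], response,
                              by = "v_gene")
  x <- merged[[feature]]
  y <- if (log_response) log(merged$value) else merged$value
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::warn("zero variance; correlation undefined")
    return(tibble::tibble(feature = feature, estimate = NA_real_,
                          p.value = NA_real_, conf.low = NA_real_,
                          conf.high = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y)
  tibble::tibble(feature = feature, estimate = unname(ct$estimate),
                 p.value = ct$p.value, conf.low = ct$conf.int[1],
                 conf.high = ct$conf.int[2], n = length(x))
}

# ---- broom-style and plot methods -------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Variable importance of a fitted repertoire model
#'
#' @param x a `kappa_rf`.
#' @param ... unused.
#' @return Tibble of per-feature importance, descending.
#' @method tidy kappa_rf
#' @export
tidy.kappa_rf <- function(x, ...) {
  dplyr::arrange(x$importance, dplyr::desc(.data$importance))
}

#' One-row model summary
#'
#' @param x a `kappa_rf`.
#' @param ... unused.
#' @method glance kappa_rf
#' @export
glance.kappa_rf <- function(x, ...) {
  tibble::tibble(task = x$task, metric = x$metric,
                 performance = x$performance,
                 n_obs = nrow(x$cv), n_features = nrow(x$importance),
                 n_trees = x$n_trees, seed = x$seed)
}

#' @export
print.kappa_rf <- function(x, ...) {
  cat(sprintf("<kappa_rf> %s, %d genes, %d features\n", x$task,
              nrow(x$cv), nrow(x$importance)))
  cat(sprintf("  10-fold CV %s: %.4g (%d trees/fold)\n", x$metric,
              x$performance, x$n_trees))
  top <- tidy(x)
  cat("  top features:", paste(utils::head(top$feature, 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' Variable-importance barplot
#'
#' @param object a `kappa_rf`.
#' @param top_n number of features to display.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot kappa_rf
#' @export
autoplot.kappa_rf <- function(object, top_n = 10L, ...) {
  d <- utils::head(tidy(object), top_n)
  lab <- if (object$task == "classification") {
    "Mean decrease in Gini index"
  } else "Mean decrease in node purity"
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$importance),
    y = .data$importance
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = lab) +
    ggplot2::theme_minimal()
}

#' @export
print.kappa_rfe <- function(x, ...) {
  cat(sprintf("<kappa_rfe> %s, sizes %d..1\n", x$task, max(x$curve$size)))
  cat(sprintf("  selected %d feature(s): %s\n", x$best_size,
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Recursive-feature-elimination performance curve
#'
#' @param object a `kappa_rfe`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot kappa_rf
#' @export
autoplot.kappa_rfe <- function(object, ...) {
  ylab <- if (object$task == "classification") "CV accuracy" else "CV RMSE"
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$size, .data$performance)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$performance - .data$se,
      ymax = .data$performance + .data$se
    )) +
    ggplot2::geom_vline(xintercept = object$best_size, linetype = 2) +
    ggplot2::labs(x = "Number of features", y = ylab) +
    ggplot2::theme_minimal()
}

#' Repertoire frequency barplot
#'
#' @param freq tibble from [repertoire_frequencies()].
#' @param ref optional `kappa_ref` to order genes along the locus and colour
#'   by orientation.
#' @return A ggplot object.
#' @export
plot_repertoire <- function(freq, ref = NULL) {
  d <- freq
  if (!is.null(ref)) {
    d <- dplyr::left_join(
      d, ref$v_genes[, c("name", "orientation")],
      by = c(v_gene = "name")
    )
    d$v_gene <- factor(d$v_gene, levels = ref$v_genes$name)
    p <- ggplot2::ggplot(d, ggplot2::aes(.data$v_gene, 100 * .data$freq,
                                         fill = .data$orientation))
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(.data$v_gene, 100 * .data$freq))
  }
  p + ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Rearrangement frequency (%)") +
    ggplot2::theme_minimal()
}
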