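# Latent-space QSAR: activity labeling from Ki, nested cross-validated
# classifier suite, and the SCAvg cosine distance-to-model applicability
# domain.

#' Label activity classes from Ki measurements
#'
#' Compounds with Ki of at most 100 nM are `active`; compounds with Ki below
#' 10 uM (10000 nM) but above 100 nM are `inactive`; measurements of 10 uM
#' or more are `excluded` from classifier training.
#'
#' @param ki_nm positive numeric vector of Ki values in nM.
#' @return factor with levels `active`, `inactive`, `excluded`.
#' @export
label_activity <- function(ki_nm) {
  if (any(!is.finite(ki_nm) | ki_nm <= 0)) {
    profis_abort("Ki must be positive and finite", "profis_invalid_measurement")
  }
  out <- ifelse(ki_nm >= 10000, "excluded",
         ifelse(ki_nm <= 100, "active", "inactive"))
  factor(out, levels = c("active", "inactive", "excluded"))
}

#' Compact default hyperparameter grids for the classifier suite
#'
#' @return named list of data frames, one grid per model family.
#' @export
default_hyper_grids <- function() {
  list(
    svm = expand.grid(cost = c(1, 10), gamma_scale = c(1, 0.25)),
    rf = expand.grid(num_trees = 300, mtry_frac = c(0.25, 0.6)),
    xgb = expand.grid(max_depth = c(2, 4), nrounds = c(60, 150), eta = 0.1),
    mlp = expand.grid(size = c(8, 24), decay = c(1e-3, 1e-1), maxit = 300)
  )
}

# grouped k-fold assignment: groups shuffled, then dealt to folds to balance
# fold sizes; all members of a group share a fold
grouped_folds <- function(groups, k, seed) {
  gl <- split(seq_along(groups), groups)
  with_seed(seed, {
    ord <- sample.int(length(gl))
    fold_sizes <- numeric(k)
    fold_of <- integer(length(groups))
    for (gi in ord) {
      f <- which.min(fold_sizes)
      fold_of[gl[[gi]]] <- f
      fold_sizes[f] <- fold_sizes[f] + length(gl[[gi]])
    }
    fold_of
  })
}

fit_classifier <- function(model, x, y01, par, seed) {
  seed <- as.integer(seed %% .Machine$integer.max)
  set.seed(seed)
  if (model == "svm") {
    yf <- factor(ifelse(y01 == 1, "active", "inactive"),
                 levels = c("active", "inactive"))
    fit <- e1071::svm(x, yf, kernel = "radial", cost = par$cost,
                      gamma = par$gamma_scale / ncol(x), probability = TRUE)
    list(model = "svm", fit = fit)
  } else if (model == "rf") {
    df <- as.data.frame(x)
    df$.y <- factor(ifelse(y01 == 1, "active", "inactive"),
                    levels = c("active", "inactive"))
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = df, probability = TRUE,
      num.trees = par$num_trees,
      mtry = max(1, floor(par$mtry_frac * ncol(x))),
      seed = seed, num.threads = 1
    )
    list(model = "rf", fit = fit)
  } else if (model == "xgb") {
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = par$max_depth,
                    eta = par$eta, nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y01),
      nrounds = par$nrounds, verbose = 0
    )
    list(model = "xgb", fit = fit)
  } else if (model == "mlp") {
    fit <- nnet::nnet(x, y01, size = par$size, decay = par$decay,
                      maxit = par$maxit, entropy = TRUE, trace = FALSE,
                      MaxNWts = 100000)
    list(model = "mlp", fit = fit)
  } else {
    profis_abort(paste0("unknown model: ", model), "profis_bad_config")
  }
}

predict_classifier <- function(cl, x) {
  if (cl$model == "svm") {
    pr <- predict(cl$fit, x, probability = TRUE)
    as.numeric(attr(pr, "probabilities")[, "active"])
  } else if (cl$model == "rf") {
    as.numeric(predict(cl$fit, data = as.data.frame(x),
                       num.threads = 1)$predictions[, "active"])
  } else if (cl$model == "xgb") {
    as.numeric(predict(cl$fit, xgboost::xgb.DMatrix(x)))
  } else {
    as.numeric(predict(cl$fit, x))
  }
}

safe_auc <- function(y01, p) {
  if (length(unique(y01)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(y01, p, quiet = TRUE, direction = "<",
                                 levels = c(0, 1))))
}

#' Nested cross-validated latent activity classifiers
#'
#' Outer scaffold-grouped k-fold for evaluation; inner k-fold grid search on
#' each outer-training split selects hyperparameters, which are refit on the
#' full outer-training split. ROC-AUC and accuracy are reported as mean and
#' standard deviation over outer folds. Runs are reproducible by seed.
#'
#' @param features numeric matrix (rows = compounds).
#' @param labels factor or character with levels `active`/`inactive`
#'   (`excluded` rows must be removed beforehand).
#' @param scaffolds optional grouping vector for fold assignment (compounds
#'   sharing a scaffold never straddle a fold boundary); default ungrouped.
#' @param models subset of `c("svm", "rf", "xgb", "mlp")`.
#' @param grids hyperparameter grids, see [default_hyper_grids()].
#' @param outer_k,inner_k fold counts.
#' @param seed integer seed.
#' @return an object of class `profis_cv`: `summary` tibble (per model:
#'   ROC-AUC and accuracy mean +- sd), `folds` tibble with per-fold metrics
#'   and selected hyperparameters.
#' @export
nested_cv <- function(features, labels, scaffolds = NULL,
                      models = c("svm", "rf", "xgb", "mlp"),
                      grids = default_hyper_grids(),
                      outer_k = 5, inner_k = 5, seed = 1) {
  x <- as.matrix(features)
  y01 <- as.integer(as.character(labels) == "active")
  stopifnot(nrow(x) == length(y01))
  if (is.null(scaffolds)) scaffolds <- seq_len(nrow(x))
  outer <- grouped_folds(scaffolds, outer_k, seed)
  fold_rows <- list()
  for (model in models) {
    grid <- grids[[model]]
    for (of in seq_len(outer_k)) {
      tr <- which(outer != of)
      te <- which(outer == of)
      if (length(unique(y01[tr])) < 2) {
        profis_abort("outer training fold has a single class",
                     "profis_degenerate_fold")
      }
      # inner grid search
      inner <- grouped_folds(scaffolds[tr], inner_k, seed + 17 * of)
      inner_auc <- vapply(seq_len(nrow(grid)), function(gi) {
        aucs <- vapply(seq_len(inner_k), function(inf) {
          itr <- tr[inner != inf]
          ite <- tr[inner == inf]
          if (length(unique(y01[itr])) < 2 || length(unique(y01[ite])) < 2) {
            return(NA_real_)
          }
          cl <- fit_classifier(model, x[itr, , drop = FALSE], y01[itr],
                               grid[gi, , drop = FALSE],
                               seed + 1000 * of + 10 * inf + gi)
          safe_auc(y01[ite], predict_classifier(cl, x[ite, , drop = FALSE]))
        }, numeric(1))
        mean(aucs, na.rm = TRUE)
      }, numeric(1))
      best <- which.max(inner_auc)
      cl <- fit_classifier(model, x[tr, , drop = FALSE], y01[tr],
                           grid[best, , drop = FALSE], seed + 99991 * of)
      p <- predict_classifier(cl, x[te, , drop = FALSE])
      fold_rows[[length(fold_rows) + 1]] <- tibble::tibble(
        model = model, fold = of,
        roc_auc = safe_auc(y01[te], p),
        accuracy = mean((p > 0.5) == y01[te]),
        params = list(as.list(grid[best, , drop = FALSE]))
      )
    }
  }
  folds <- dplyr::bind_rows(fold_rows)
  summary <- folds |>
    dplyr::group_by(model) |>
    dplyr::summarise(
      roc_auc_mean = mean(roc_auc, na.rm = TRUE),
      roc_auc_sd = stats::sd(roc_auc, na.rm = TRUE),
      accuracy_mean = mean(accuracy),
      accuracy_sd = stats::sd(accuracy),
      .groups = "drop"
    )
  structure(list(summary = summary, folds = folds, seed = seed),
            class = "profis_cv")
}

#' @export
print.profis_cv <- function(x, ...) {
  cat("Nested cross-validation report\n")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.profis_cv <- function(x, ...) x$folds

#' @exportS3Method generics::glance
glance.profis_cv <- function(x, ...) x$summary

#' Train one classifier on a full dataset
#'
#' Convenience fit (no cross-validation) used to drive latent search and
#' applicability-domain analyses; returns a predictor closure mapping a
#' latent matrix to p(active).
#'
#' @param features numeric matrix.
#' @param labels `active`/`inactive` labels.
#' @param model one of `"svm"`, `"rf"`, `"xgb"`, `"mlp"`.
#' @param params single-row data frame of hyperparameters (defaults: first
#'   row of the model's default grid).
#' @param seed integer seed.
#' @return function `(matrix) -> numeric` of activity probabilities, with the
#'   fitted object in attribute `fit`.
#' @export
train_latent_classifier <- function(features, labels, model = "mlp",
                                    params = NULL, seed = 1) {
  x <- as.matrix(features)
  y01 <- as.integer(as.character(labels) == "active")
  params <- params %||% default_hyper_grids()[[model]][1, , drop = FALSE]
  cl <- fit_classifier(model, x, y01, params, seed)
  f <- function(z) {
    if (is.null(dim(z))) z <- matrix(z, nrow = 1)
    predict_classifier(cl, z)
  }
  attr(f, "fit") <- cl
  f
}

#' SCAvg distance-to-model
#'
#' The mean cosine similarity of a query latent vector to its `n_neighbors`
#' nearest training vectors (neighbors ranked by cosine similarity) defines
#' the SCAvg score; the distance-to-model reported here is `1 - SCAvg`, so
#' small values mean the query sits inside the training distribution.
#'
#' @param z query vector or matrix (rows = queries).
#' @param train_z training latent matrix.
#' @param n_neighbors number of neighbors (default 3).
#' @return numeric vector of distances in \[0, 2\].
#' @export
distance_to_model <- function(z, train_z, n_neighbors = 3) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  train_z <- as.matrix(train_z)
  stopifnot(nrow(train_z) >= n_neighbors)
  tn <- sqrt(rowSums(train_z^2))
  qn <- sqrt(rowSums(z^2))
  if (any(tn == 0) || any(qn == 0)) {
    profis_abort("zero-norm latent vector has no direction",
                 "profis_undefined_direction")
  }
  sims <- (z %*% t(train_z)) / outer(qn, tn)
  apply(sims, 1, function(s) {
    1 - mean(sort(s, decreasing = TRUE)[seq_len(n_neighbors)])
  })
}

#' Prediction-error profile across distance-to-model bins
#'
#' Bins queries into half-open DM ranges (`[0, b1)`, `[b1, b2)`, ..., last
#' bin open-ended) and summarizes the absolute classification error
#' `|p(active) - y|` and the F1 score per bin. Empty bins are reported with
#' `n = 0`, not as errors.
#'
#' @param p_active predicted activity probabilities.
#' @param labels true `active`/`inactive` labels.
#' @param dm distance-to-model values from [distance_to_model()].
#' @param bins increasing breakpoints (default `c(0.05, 0.10, 0.15)`).
#' @return tibble: `bin`, `n`, `median_abs_error`, `mean_abs_error`, `f1`.
#' @export
dm_error_profile <- function(p_active, labels, dm, bins = c(0.05, 0.10, 0.15)) {
  y01 <- as.integer(as.character(labels) == "active")
  breaks <- c(0, bins, Inf)
  lab <- c(
    paste0("<", bins[1]),
    paste0("[", bins[-length(bins)], ",", bins[-1], ")"),
    paste0(">=", bins[length(bins)])
  )
  bin_id <- cut(dm, breaks = breaks, labels = lab, right = FALSE,
                include.lowest = TRUE)
  err <- abs(p_active - y01)
  pred <- as.integer(p_active > 0.5)
  out <- lapply(seq_along(lab), function(k) {
    idx <- which(bin_id == lab[k])
    if (length(idx) == 0) {
      return(tibble::tibble(bin = lab[k], n = 0L,
                            median_abs_error = NA_real_,
                            mean_abs_error = NA_real_, f1 = NA_real_))
    }
    tp <- sum(pred[idx] == 1 & y01[idx] == 1)
    fp <- sum(pred[idx] == 1 & y01[idx] == 0)
    fn <- sum(pred[idx] == 0 & y01[idx] == 1)
    f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
    tibble::tibble(
      bin = lab[k], n = length(idx),
      median_abs_error = stats::median(err[idx]),
      mean_abs_error = mean(err[idx]),
      f1 = f1
    )
  })
  dplyr::bind_rows(out)
}
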