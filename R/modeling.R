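#' Pseudoabsence design, model fitting and evaluation
#'
#' Presence-only data are contrasted with randomly placed pseudoabsences
#' drawn from the study area. Each pseudoabsence set crossed with each
#' replicate split yields one fitted model; model skill is measured on the
#' held-out partition with the ROC AUC (rank statistic) and the maximized
#' sensitivity + specificity (MTSS) threshold.
#'
#' @name modeling
NULL

#' Draw pseudoabsence sets from a study area
#'
#' Uniform draws without replacement from the study-area cells, excluding
#' every cell that contains a presence; the sets are mutually independent
#' and jointly seeded.
#'
#' @param area A `study_area`.
#' @param occ Occurrence tibble (presences).
#' @param n Pseudoabsences per set.
#' @param n_sets Number of sets.
#' @param seed Integer seed.
#' @return List of `n_sets` tibbles (`set_id`, `row`, `col`, `lon`, `lat`).
#' @export
sample_pseudoabsences <- function(area, occ, n = 5000, n_sets = 5,
                                  seed = 1L) {
  cells <- study_area_cells(area)
  pres <- cell_from_lonlat(area$mask, occ$lon, occ$lat)
  pres_key <- unique(paste(pres$row, pres$col))
  pool <- cells[!(paste(cells$row, cells$col) %in% pres_key), , drop = FALSE]
  if (n > nrow(pool))
    stop("study area has only ", nrow(pool),
         " candidate cells; cannot draw ", n, " pseudoabsences")
  withr::with_seed(seed, {
    lapply(seq_len(n_sets), function(s) {
      picked <- pool[sample.int(nrow(pool), n), , drop = FALSE]
      dplyr::bind_cols(tibble::tibble(set_id = s), picked)
    })
  })
}

#' Assemble a weighted, partitioned training table
#'
#' Presences become response 1, pseudoabsences response 0. Rows whose
#' predictors contain nodata are dropped (count reported). Per-row weights
#' rescale the minority class so the summed weight of each class is equal
#' (prevalence 0.5). The 70/30 split is stratified by class so both
#' partitions contain both classes.
#'
#' @param stack `predictor_stack` restricted to the selected predictors.
#' @param occ Occurrence tibble.
#' @param pa One pseudoabsence tibble from [sample_pseudoabsences()].
#' @param split Training fraction in (0, 1).
#' @param seed Integer seed for the split.
#' @return Tibble with `response`, `weight`, `partition` and one column per
#'   predictor; attributes `pa_set_id`, `split_seed`, `n_dropped`.
#' @export
assemble_training <- function(stack, occ, pa, split = 0.7, seed = 1L) {
  stopifnot(split > 0, split < 1)
  pres_cells <- cell_from_lonlat(stack[[1]], occ$lon, occ$lat)
  pres_tb <- dplyr::bind_cols(
    tibble::tibble(response = 1),
    stack_extract(stack, pres_cells$row, pres_cells$col))
  abs_tb <- dplyr::bind_cols(
    tibble::tibble(response = 0),
    stack_extract(stack, pa$row, pa$col))
  tb <- dplyr::bind_rows(pres_tb, abs_tb)
  ok <- stats::complete.cases(tb)
  n_dropped <- sum(!ok)
  if (n_dropped)
    message("assemble_training: dropped ", n_dropped,
            " row(s) with nodata predictors")
  tb <- tb[ok, , drop = FALSE]
  n1 <- sum(tb$response == 1); n0 <- sum(tb$response == 0)
  if (n1 == 0 || n0 == 0) stop("training table must contain both classes")
  # prevalence 0.5: each class contributes equal summed weight
  tb$weight <- ifelse(tb$response == 1, n0 / n1, 1)

  withr::with_seed(seed, {
    part <- rep("test", nrow(tb))
    for (cls in c(0, 1)) {
      idx <- which(tb$response == cls)
      n_train <- round(split * length(idx))
      n_train <- max(1, min(n_train, length(idx) - 1))
      part[sample(idx, n_train)] <- "train"
    }
    tb$partition <- part
  })
  out <- tb[, c("response", "weight", "partition",
                setdiff(names(tb), c("response", "weight", "partition")))]
  attr(out, "pa_set_id") <- pa$set_id[1]
  attr(out, "split_seed") <- as.integer(seed)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Default hyperparameters per algorithm
#'
#' GBM defaults mirror the boosted-regression-tree settings common in SDM
#' ensemble platforms (2500 trees, interaction depth 7, learning rate 0.001,
#' bag fraction 0.5); RF uses 500 trees. Reduce tree counts for quick runs.
#'
#' @param algorithm One of `"GLM"`, `"GBM"`, `"RF"`, `"ANN"`.
#' @return Named list.
#' @export
default_hyperparameters <- function(algorithm) {
  switch(algorithm,
    GLM = list(),
    GBM = list(n_trees = 2500, max_depth = 7, learning_rate = 0.001,
               bag_fraction = 0.5),
    RF = list(n_trees = 500, mtry = NULL),
    ANN = list(size = 8, decay = 0.01, maxit = 200),
    stop("unknown algorithm: ", algorithm))
}

#' Fit one model run
#'
#' Fits the requested algorithm on the training partition with the row
#' weights; predictions are suitability values in `[0, 1]`. Supported
#' algorithms: `GLM` (weighted binomial regression), `GBM` (gradient-boosted
#' trees via xgboost), `RF` (probability random forest via ranger), `ANN`
#' (single-hidden-layer network via nnet).
#'
#' @param table Training table from [assemble_training()].
#' @param algorithm Algorithm id.
#' @param hyperparameters Overrides merged onto [default_hyperparameters()].
#' @param seed Integer seed for stochastic learners.
#' @param replicate_id Replicate index recorded on the run.
#' @return An `sdm_run` object.
#' @export
fit_model <- function(table, algorithm = "RF", hyperparameters = list(),
                      seed = 1L, replicate_id = 1L) {
  predictors <- setdiff(names(table), c("response", "weight", "partition"))
  train <- table[table$partition == "train", , drop = FALSE]
  if (length(unique(train$response)) < 2)
    stop("training partition contains a single class")
  hp <- utils::modifyList(default_hyperparameters(algorithm),
                          hyperparameters)
  x <- as.matrix(train[predictors])
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (all(const)) warning("all predictors are constant on the training data")

  fit <- switch(algorithm,
    GLM = {
      df <- as.data.frame(train[c("response", predictors)])
      stats::glm(response ~ ., family = stats::quasibinomial(),
                 weights = train$weight, data = df)
    },
    GBM = {
      dtrain <- xgboost::xgb.DMatrix(x, label = train$response,
                                     weight = train$weight)
      withr::with_seed(seed,
        xgboost::xgb.train(
          params = list(objective = "binary:logistic",
                        max_depth = hp$max_depth, eta = hp$learning_rate,
                        subsample = hp$bag_fraction, nthread = 1),
          data = dtrain, nrounds = hp$n_trees, verbose = 0))
    },
    RF = {
      df <- as.data.frame(train[c("response", predictors)])
      df$response <- factor(df$response, levels = c(0, 1))
      ranger::ranger(response ~ ., data = df, probability = TRUE,
                     num.trees = hp$n_trees,
                     mtry = hp$mtry,
                     case.weights = train$weight,
                     num.threads = 1, seed = seed)
    },
    ANN = {
      df <- as.data.frame(train[predictors])
      ctr <- colMeans(df); scl <- apply(df, 2, stats::sd); scl[scl == 0] <- 1
      xs <- scale(df, ctr, scl)
      net <- withr::with_seed(seed,
        nnet::nnet(xs, train$response, weights = train$weight,
                   size = hp$size, decay = hp$decay, maxit = hp$maxit,
                   entropy = TRUE, trace = FALSE))
      list(net = net, center = ctr, scale = scl)
    },
    stop("unknown algorithm: ", algorithm))

  structure(
    list(algorithm = algorithm, fit = fit, predictors = predictors,
         hyperparameters = hp,
         pa_set_id = attr(table, "pa_set_id"),
         replicate_id = as.integer(replicate_id),
         seed = as.integer(seed),
         evaluation = NULL, importance = NULL),
    class = "sdm_run")
}

#' @export
print.sdm_run <- function(x, ...) {
  cat(sprintf("<sdm_run> %s (PA set %s, replicate %d)\n", x$algorithm,
              x$pa_set_id %||% "?", x$replicate_id))
  if (!is.null(x$evaluation))
    cat(sprintf("  AUC %.3f, TSS %.3f at threshold %.3f\n",
                x$evaluation$auc, x$evaluation$tss,
                x$evaluation$mtss_threshold))
  invisible(x)
}

#' Predict suitability for new predictor rows
#'
#' @param object An `sdm_run`.
#' @param newdata Data frame / tibble holding the run's predictor columns.
#' @param ... Unused.
#' @return Numeric vector of suitabilities in `[0, 1]`.
#' @export
predict.sdm_run <- function(object, newdata, ...) {
  nd <- newdata[object$predictors]
  p <- switch(object$algorithm,
    GLM = as.numeric(stats::predict(object$fit,
                                    newdata = as.data.frame(nd),
                                    type = "response")),
    GBM = as.numeric(stats::predict(object$fit,
                                    xgboost::xgb.DMatrix(as.matrix(nd)))),
    RF = {
      pr <- stats::predict(object$fit, data = as.data.frame(nd),
                           num.threads = 1)$predictions
      as.numeric(pr[, "1"])
    },
    ANN = {
      xs <- scale(as.data.frame(nd), object$fit$center, object$fit$scale)
      as.numeric(stats::predict(object$fit$net, xs))
    })
  pmin(1, pmax(0, p))
}

#' ROC AUC by the rank statistic
#'
#' Equivalent to the fraction of presence/absence score pairs that are
#' concordant, counting ties as one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 class labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Maximized sensitivity + specificity threshold
#'
#' Scans the midpoints of consecutive sorted unique scores (plus 0 and 1);
#' a prediction counts positive when `score >= threshold`. Returns the
#' threshold maximizing sensitivity + specificity (the max-TSS rule); on
#' ties the lowest such threshold is taken.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 class labels.
#' @return List: `threshold`, `sensitivity`, `specificity`, `tss`.
#' @export
mtss_threshold <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- unique(c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, 1))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  best <- NULL
  for (t in cand) {
    pos <- scores >= t
    sens <- sum(pos & labels == 1) / n1
    spec <- sum(!pos & labels == 0) / n0
    if (is.null(best) || sens + spec > best$sensitivity + best$specificity +
        1e-12) {
      best <- list(threshold = t, sensitivity = sens, specificity = spec,
                   tss = sens + spec - 1)
    }
  }
  best
}

#' Evaluate a model run on its held-out partition
#'
#' @param run An `sdm_run`.
#' @param table The training table the run was fitted on.
#' @return The run with an `evaluation` list (`auc`, `mtss_threshold`,
#'   `sensitivity`, `specificity`, `tss`) attached.
#' @export
evaluate_model <- function(run, table) {
  test <- table[table$partition == "test", , drop = FALSE]
  if (!nrow(test)) stop("test partition is empty")
  if (length(unique(test$response)) < 2)
    stop("test partition contains a single class")
  scores <- predict(run, test)
  mt <- mtss_threshold(scores, test$response)
  run$evaluation <- list(
    auc = roc_auc(scores, test$response),
    mtss_threshold = mt$threshold,
    sensitivity = mt$sensitivity,
    specificity = mt$specificity,
    tss = mt$tss)
  run
}

#' Pre-select the modeling algorithm by mean test AUC
#'
#' Fits `runs` replicates per candidate algorithm (cycling over the
#' pseudoabsence sets) and ranks algorithms by mean held-out AUC; the
#' top-ranked algorithm is the one to carry into the final ensemble.
#'
#' @param stack Selected-predictor `predictor_stack`.
#' @param occ Occurrence tibble.
#' @param pa_sets List from [sample_pseudoabsences()].
#' @param algorithms Candidate algorithm ids.
#' @param runs Replicates per algorithm.
#' @param split Training fraction.
#' @param hyperparameters Named list of per-algorithm overrides.
#' @param seed Integer seed.
#' @return Tibble (`algorithm`, `mean_auc`, `n_runs`), best first; attribute
#'   `evaluations` holds the per-run AUCs.
#' @export
preselect_algorithms <- function(stack, occ, pa_sets,
                                 algorithms = c("GLM", "GBM", "RF"),
                                 runs = 5, split = 0.7,
                                 hyperparameters = list(), seed = 1L) {
  stopifnot(length(algorithms) >= 1)
  evals <- list()
  for (alg in algorithms) {
    aucs <- rep(NA_real_, runs)
    for (r in seq_len(runs)) {
      res <- tryCatch({
        pa <- pa_sets[[(r - 1) %% length(pa_sets) + 1]]
        tb <- assemble_training(stack, occ, pa, split = split,
                                seed = child_seed(seed, paste0(alg, r)))
        run <- fit_model(tb, alg,
                         hyperparameters = hyperparameters[[alg]] %||% list(),
                         seed = child_seed(seed, paste0(alg, r, "fit")),
                         replicate_id = r)
        evaluate_model(run, tb)$evaluation$auc
      }, error = function(e) {
        message("preselect: ", alg, " run ", r, " failed: ",
                conditionMessage(e))
        NA_real_
      })
      aucs[r] <- res
    }
    evals[[alg]] <- aucs
  }
  out <- tibble::tibble(
    algorithm = algorithms,
    mean_auc = unname(vapply(evals, function(a) mean(a, na.rm = TRUE),
                             numeric(1))),
    n_runs = unname(vapply(evals, function(a) sum(!is.na(a)), integer(1)))
  ) |> dplyr::arrange(dplyr::desc(.data$mean_auc))
  attr(out, "evaluations") <- evals
  out
}

#' Permutation variable importance
#'
#' For each predictor the column is shuffled, the model re-predicts, and the
#' importance is `1 - max(0, r)` where `r` is the Pearson correlation
#' between original and shuffled-input predictions, averaged over `n_perm`
#' shuffles. A variable the model ignores scores 0; a variable the model
#' depends on entirely scores near 1.
#'
#' @param run Fitted `sdm_run`.
#' @param table Training table.
#' @param n_perm Number of shuffles per variable.
#' @param seed Integer seed.
#' @return Named numeric vector of importance scores in `[0, 1]`.
#' @export
permutation_importance <- function(run, table, n_perm = 1, seed = 1L) {
  stopifnot(n_perm >= 1)
  base_pred <- predict(run, table)
  if (stats::sd(base_pred) == 0) {
    warning("model predictions have zero variance; importances set to 0")
    return(stats::setNames(rep(0, length(run$predictors)), run$predictors))
  }
  withr::with_seed(seed, {
    scores <- vapply(run$predictors, function(v) {
      mean(vapply(seq_len(n_perm), function(k) {
        shuf <- table
        shuf[[v]] <- sample(shuf[[v]])
        p <- predict(run, shuf)
        r <- if (stats::sd(p) == 0) 0 else stats::cor(base_pred, p)
        1 - max(0, r)
      }, numeric(1)))
    }, numeric(1))
  })
  scores
}

`%||%` <- function(a, b) if (is.null(a)) b else a
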