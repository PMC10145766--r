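# A tiny separable two-predictor world used across the modeling tests.
separable_table <- function(n = 120, seed = 1) {
  withr::with_seed(seed, {
    response <- rep(c(1, 0), each = n / 2)
    x1 <- ifelse(response == 1, rnorm(n, 3), rnorm(n, -3))
    x2 <- rnorm(n)
    tb <- tibble::tibble(response = response, weight = 1,
                         partition = sample(rep(c("train", "test"),
                                                length.out = n)),
                         x1 = x1, x2 = x2)
    # ensure both classes in both partitions
    tb$partition[1] <- "train"; tb$partition[n] <- "train"
    tb$partition[2] <- "test"; tb$partition[n - 1] <- "test"
    tb
  })
}

test_that("pseudoabsence sets exclude presences and are reproducible", {
  tmpl <- const_grid(0, nr = 12, nc = 12, origin_lon = 0, origin_lat = 1.2)
  area <- full_area(tmpl)
  cc <- cell_centers(tmpl)
  occ <- occ_tbl(lon = cc$lon[1:10], lat = cc$lat[1:10])
  sets <- sample_pseudoabsences(area, occ, n = 50, n_sets = 3, seed = 5)
  expect_length(sets, 3)
  occ_cells <- cell_from_lonlat(tmpl, occ$lon, occ$lat)
  for (s in sets) {
    expect_equal(nrow(s), 50)
    expect_equal(length(intersect(paste(s$row, s$col),
                                  paste(occ_cells$row, occ_cells$col))), 0)
  }
  expect_false(identical(sets[[1]]$row, sets[[2]]$row))
  expect_identical(sets, sample_pseudoabsences(area, occ, 50, 3, seed = 5))
})

test_that("a fully constrained pool forces the unique complement", {
  tmpl <- const_grid(0, nr = 3, nc = 3)
  area <- full_area(tmpl)
  cc <- cell_centers(tmpl)
  occ <- occ_tbl(lon = cc$lon[1:4], lat = cc$lat[1:4])
  sets <- sample_pseudoabsences(area, occ, n = 5, n_sets = 2, seed = 1)
  for (s in sets)
    expect_setequal(paste(s$row, s$col), paste(cc$row, cc$col)[5:9])
  expect_error(sample_pseudoabsences(area, occ, n = 6, n_sets = 1, seed = 1),
               "candidate cells")
})

test_that("training tables balance class weight and split reproducibly", {
  st <- gen_landscape(demo_landscape_config(seed = 2, n_rows = 30,
                                            n_cols = 30))
  sp <- demo_species_config(seed = 2, n_presences = 60)
  suit <- true_suitability(st, sp)
  occ <- sample_occurrences(suit, sp)
  area <- full_area(st[[1]])
  pa <- sample_pseudoabsences(area, occ, n = 300, n_sets = 1, seed = 3)[[1]]
  tb <- assemble_training(st, occ, pa, split = 0.7, seed = 4)

  w1 <- sum(tb$weight[tb$response == 1])
  w0 <- sum(tb$weight[tb$response == 0])
  expect_lt(abs(w1 - w0), 1e-9)

  n_train <- sum(tb$partition == "train")
  expect_lt(abs(n_train - 0.7 * nrow(tb)), 2)
  for (p in c("train", "test"))
    expect_setequal(unique(tb$response[tb$partition == p]), c(0, 1))

  tb2 <- assemble_training(st, occ, pa, split = 0.7, seed = 4)
  expect_identical(tb$partition, tb2$partition)
  tb3 <- assemble_training(st, occ, pa, split = 0.7, seed = 5)
  expect_false(identical(tb$partition, tb3$partition))
})

test_that("rows with nodata predictors are dropped with a report", {
  st <- const_stack(list(a = 1), nr = 5, nc = 5)
  st$a$values[1, 1] <- NA
  cc <- cell_centers(st$a)
  occ <- occ_tbl(lon = cc$lon[c(1, 7, 8)], lat = cc$lat[c(1, 7, 8)])
  pa <- tibble::tibble(set_id = 1, row = c(3, 4, 5), col = c(3, 4, 5),
                       lon = NA, lat = NA)
  expect_message(tb <- assemble_training(st, occ, pa, seed = 1),
                 "dropped 1")
  expect_equal(sum(tb$response == 1), 2)
})

test_that("every core algorithm separates a separable world perfectly", {
  tb <- separable_table()
  train <- tb[tb$partition == "train", ]
  for (alg in c("GLM", "GBM", "RF", "ANN")) {
    hp <- switch(alg, GBM = list(n_trees = 50, learning_rate = 0.3),
                 RF = list(n_trees = 50), ANN = list(size = 4, maxit = 100),
                 list())
    run <- suppressWarnings(fit_model(tb, alg, hp, seed = 1))
    p_train <- predict(run, train)
    expect_equal(roc_auc(p_train, train$response), 1,
                 info = alg)
    expect_true(all(p_train >= 0 & p_train <= 1))
  }
})

test_that("constant predictors are flagged and one-class training errors", {
  tb <- separable_table()
  tb$x1 <- 1; tb$x2 <- 2
  expect_warning(fit_model(tb, "GLM"), "constant")
  tb2 <- separable_table()
  tb2$response <- 1
  expect_error(fit_model(tb2, "RF"), "single class")
  expect_error(fit_model(separable_table(), "SVM"), "unknown algorithm")
})

test_that("AUC equals the concordant-pair fraction", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3, 0.5, 0.1),
                       c(1, 1, 1, 0, 0, 0)), 8 / 9)
  for (seed in 1:6) {
    withr::with_seed(seed, {
      n <- sample(5:50, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
      scores <- round(runif(n), 2)  # rounding forces ties
    })
    expect_equal(roc_auc(scores, labels), auc_bruteforce(scores, labels))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(10, {
    labels <- rbinom(80, 1, 0.4)
    labels[1:2] <- c(0, 1)
    scores <- runif(80)
  })
  expect_equal(roc_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE))))
})

test_that("the MTSS threshold maximizes sensitivity + specificity", {
  scores <- c(0.9, 0.8, 0.4, 0.3, 0.5, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  mt <- mtss_threshold(scores, labels)
  expect_equal(mt$tss, 2 / 3, tolerance = 1e-12)
  expect_gt(mt$threshold, 0.3)
  expect_lte(mt$threshold, 0.4)
  expect_equal(mt$sensitivity, 1)
  expect_equal(mt$specificity, 2 / 3, tolerance = 1e-12)

  for (seed in 1:6) {
    withr::with_seed(seed, {
      n <- sample(6:40, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
      scores <- round(runif(n), 1)
    })
    expect_equal(mtss_threshold(scores, labels)$tss,
                 mtss_bruteforce(scores, labels), tolerance = 1e-9)
  }
})

test_that("evaluation on separated classes gives AUC 1 and a gap threshold", {
  tb <- separable_table()
  run <- evaluate_model(suppressWarnings(fit_model(tb, "GLM")), tb)
  e <- run$evaluation
  expect_equal(e$auc, 1)
  expect_equal(e$tss, 1)
  test <- tb[tb$partition == "test", ]
  p <- predict(run, test)
  expect_gt(e$mtss_threshold, max(p[test$response == 0]))
  expect_lte(e$mtss_threshold, min(p[test$response == 1]))
  expect_equal(e$tss, e$sensitivity + e$specificity - 1)
})

test_that("algorithm pre-selection ranks by recomputed mean AUC", {
  st <- gen_landscape(demo_landscape_config(seed = 3, n_rows = 30,
                                            n_cols = 30))
  sp <- demo_species_config(seed = 3, n_presences = 80)
  occ <- sample_occurrences(true_suitability(st, sp), sp)
  area <- full_area(st[[1]])
  pa_sets <- sample_pseudoabsences(area, occ, n = 300, n_sets = 2, seed = 1)
  rank <- preselect_algorithms(
    st, occ, pa_sets, algorithms = c("GLM", "RF"), runs = 3,
    hyperparameters = list(RF = list(n_trees = 60)), seed = 2)
  evals <- attr(rank, "evaluations")
  means <- sort(vapply(evals, mean, numeric(1)), decreasing = TRUE)
  expect_equal(rank$mean_auc, unname(means), tolerance = 1e-12)
  expect_equal(rank$algorithm, names(means))

  single <- preselect_algorithms(st, occ, pa_sets, algorithms = "GLM",
                                 runs = 2, seed = 2)
  expect_equal(single$algorithm, "GLM")
})

test_that("permutation importance separates used from ignored variables", {
  tb <- separable_table(n = 200, seed = 2)
  run <- suppressWarnings(fit_model(tb, "GLM"))
  # provably ignore x2 by zeroing its coefficient
  run$fit$coefficients["x2"] <- 0
  imp <- permutation_importance(run, tb, n_perm = 3, seed = 1)
  expect_equal(unname(imp["x2"]), 0, tolerance = 1e-12)
  expect_gt(imp["x1"], 0.5)
  expect_true(all(imp >= 0 & imp <= 1))
})

test_that("a model that is a pure function of one variable scores near 1", {
  withr::with_seed(3, {
    tb <- tibble::tibble(response = rep(c(0, 1), 100), weight = 1,
                         partition = "train",
                         x1 = rnorm(200))
  })
  tb$response <- as.numeric(tb$x1 > 0)
  tb$partition[c(1, 2)] <- "test"
  run <- suppressWarnings(fit_model(tb, "GLM"))
  imp <- permutation_importance(run, tb, n_perm = 5, seed = 4)
  expect_gt(imp["x1"], 0.85)

  run_const <- run
  run_const$fit$coefficients[] <- 0
  expect_warning(imp0 <- permutation_importance(run_const, tb, seed = 1),
                 "zero variance")
  expect_true(all(imp0 == 0))
})

test_that("tidiers expose evaluations and importances as tibbles", {
  tb <- separable_table()
  run <- evaluate_model(suppressWarnings(fit_model(tb, "GLM")), tb)
  run$importance <- permutation_importance(run, tb, seed = 1)
  g <- glance(run)
  expect_equal(g$auc, 1)
  expect_equal(g$algorithm, "GLM")
  td <- tidy(run)
  expect_setequal(td$variable, c("x1", "x2"))
  expect_true(all(diff(td$importance) <= 0))
})
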