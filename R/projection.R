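#' Map projection, ensembling, binarization and range-change accounting
#'
#' @name projection
NULL

#' Project a fitted run onto a predictor stack
#'
#' @param run Fitted `sdm_run`.
#' @param stack `predictor_stack` holding all the run's predictor layers.
#' @return Suitability `sdm_grid` in `[0, 1]`; nodata wherever any predictor
#'   is nodata.
#' @export
predict_map <- function(run, stack) {
  missing <- setdiff(run$predictors, names(stack))
  if (length(missing))
    stop("stack lacks predictor layer(s): ", paste(missing, collapse = ", "))
  g <- stack[[1]]
  d <- dim(g$values)
  tb <- tibble::as_tibble(lapply(stack[run$predictors],
                                 function(x) as.vector(x$values)))
  ok <- stats::complete.cases(tb)
  vals <- rep(NA_real_, nrow(tb))
  if (any(ok)) vals[ok] <- predict(run, tb[ok, , drop = FALSE])
  grid_new(matrix(vals, d[1], d[2]), g$origin_lon, g$origin_lat,
           g$cell_size, g$crs)
}

#' AUC-gated ensemble of suitability maps
#'
#' Unweighted per-cell mean over the maps whose evaluation AUC exceeds the
#' gate. The number of contributing models is recorded as the attribute
#' `n_contributing` and reported with a message.
#'
#' @param maps List of aligned suitability `sdm_grid`s.
#' @param evals List of evaluation lists (one per map, each with `$auc`).
#' @param auc_min AUC gate; a map contributes only if `auc > auc_min`.
#' @return Ensemble suitability `sdm_grid` with attribute `n_contributing`.
#' @export
ensemble_maps <- function(maps, evals, auc_min = 0.8) {
  stopifnot(length(maps) == length(evals), length(maps) >= 1)
  aucs <- vapply(evals, function(e) e$auc, numeric(1))
  pass <- which(aucs > auc_min)
  if (!length(pass))
    stop("no model passed the AUC gate (max AUC ",
         sprintf("%.3f", max(aucs)), " <= ", auc_min, ")")
  g <- maps[[pass[1]]]
  acc <- matrix(0, nrow(g$values), ncol(g$values))
  for (i in pass) acc <- acc + maps[[i]]$values
  out <- grid_new(acc / length(pass), g$origin_lon, g$origin_lat,
                  g$cell_size, g$crs)
  attr(out, "n_contributing") <- length(pass)
  message("ensemble_maps: ", length(pass), " of ", length(maps),
          " models passed the AUC gate")
  out
}

#' Binarize a suitability map at a threshold
#'
#' Cell value 1 when suitability `>= threshold`, else 0; nodata preserved.
#'
#' @param map Suitability `sdm_grid`.
#' @param threshold Threshold in `[0, 1]` (typically the ensemble's MTSS).
#' @return Binary `sdm_grid`.
#' @export
mtss_binarize <- function(map, threshold) {
  v <- ifelse(map$values >= threshold, 1, 0)
  v[is.na(map$values)] <- NA_real_
  grid_new(v, map$origin_lon, map$origin_lat, map$cell_size, map$crs)
}

#' Combine binary maps by averaging and majority
#'
#' Per-cell mean of the member maps, re-binarized at 0.5 (ties count as
#' suitable); with three members this is the majority rule. Used to merge
#' the per-GCM futures within one RCP.
#'
#' @param maps Non-empty list of aligned binary `sdm_grid`s.
#' @return Binary `sdm_grid`.
#' @export
combine_binary <- function(maps) {
  if (!length(maps)) stop("no maps to combine")
  g <- maps[[1]]
  acc <- matrix(0, nrow(g$values), ncol(g$values))
  for (m in maps) acc <- acc + m$values
  mean_map <- acc / length(maps)
  v <- ifelse(mean_map >= 0.5, 1, 0)
  grid_new(v, g$origin_lon, g$origin_lat, g$cell_size, g$crs)
}

# round half away from zero to `digits` decimals (table formatting)
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Loss / stable / gain range change between two binary maps
#'
#' Transition classes between the present and future binary maps: loss
#' (1 to 0), stable (1 to 1), gain (0 to 1), never (0 to 0). Percentages use
#' the present range as denominator: `pct_loss = 100 * loss / (loss +
#' stable)`, `pct_gain = 100 * gain / (loss + stable)`, `pct_change =
#' pct_gain - pct_loss`, each reported to one decimal (half away from zero).
#'
#' @param present,future Aligned binary `sdm_grid`s with identical valid
#'   masks.
#' @return One-row tibble: `loss_cells`, `stable_cells`, `gain_cells`,
#'   `never_cells`, `pct_loss`, `pct_gain`, `pct_change`.
#' @export
range_change <- function(present, future) {
  if (!grid_aligned(present, future))
    stop("present and future maps are not aligned")
  pv <- present$values; fv <- future$values
  if (!identical(is.na(pv), is.na(fv)))
    stop("present and future maps have different valid masks")
  ok <- !is.na(pv)
  loss <- sum(pv[ok] == 1 & fv[ok] == 0)
  stable <- sum(pv[ok] == 1 & fv[ok] == 1)
  gain <- sum(pv[ok] == 0 & fv[ok] == 1)
  never <- sum(pv[ok] == 0 & fv[ok] == 0)
  stopifnot(loss + stable + gain + never == sum(ok))
  denom <- loss + stable
  if (denom == 0) stop("present map has no suitable cells")
  pct_loss <- 100 * loss / denom
  pct_gain <- 100 * gain / denom
  tibble::tibble(
    loss_cells = loss, stable_cells = stable, gain_cells = gain,
    never_cells = never,
    pct_loss = round_half_up(pct_loss),
    pct_gain = round_half_up(pct_gain),
    pct_change = round_half_up(pct_gain - pct_loss))
}

#' Elevational distribution of the suitable range, present vs future
#'
#' Summarizes the elevation of cells suitable in the present map against
#' those suitable in the future map (the union of stable and gain cells);
#' the shift is the difference of means.
#'
#' @param present,future Aligned binary `sdm_grid`s.
#' @param elevation Aligned elevation `sdm_grid` (meters).
#' @return One-row tibble: present/future mean, Q1, median, Q3 (m) and
#'   `shift` (m).
#' @export
elevation_shift <- function(present, future, elevation) {
  if (!grid_aligned(present, elevation) || !grid_aligned(future, elevation))
    stop("maps and elevation are not aligned")
  ep <- elevation$values[!is.na(present$values) & present$values == 1]
  ef <- elevation$values[!is.na(future$values) & future$values == 1]
  ep <- ep[!is.na(ep)]; ef <- ef[!is.na(ef)]
  if (!length(ep)) stop("present map has no suitable cells")
  if (!length(ef)) stop("future map has no suitable cells")
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  qp <- qs(ep); qf <- qs(ef)
  tibble::tibble(
    present_mean = mean(ep), future_mean = mean(ef),
    present_q1 = qp[1], present_median = qp[2], present_q3 = qp[3],
    future_q1 = qf[1], future_median = qf[2], future_q3 = qf[3],
    shift = mean(ef) - mean(ep))
}

#' MTSS threshold for an ensemble from pooled test partitions
#'
#' Pools the held-out rows of every contributing run's training table,
#' scores them with the gated ensemble (mean prediction of the contributing
#' models), and derives one MTSS threshold from the pooled scores.
#'
#' @param runs List of evaluated `sdm_run`s.
#' @param tables List of their training tables (same order).
#' @param auc_min AUC gate.
#' @return List from [mtss_threshold()].
#' @export
ensemble_threshold <- function(runs, tables, auc_min = 0.8) {
  pass <- which(vapply(runs, function(r) r$evaluation$auc, numeric(1)) >
                  auc_min)
  if (!length(pass)) stop("no model passed the AUC gate")
  scores <- numeric(0); labels <- numeric(0)
  for (i in pass) {
    test <- tables[[i]][tables[[i]]$partition == "test", , drop = FALSE]
    p <- rowMeans(vapply(pass, function(j) predict(runs[[j]], test),
                         numeric(nrow(test))))
    scores <- c(scores, p)
    labels <- c(labels, test$response)
  }
  mtss_threshold(scores, labels)
}
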