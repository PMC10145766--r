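#' Predictor preparation, collinearity filtering, GCM selection
#'
#' @name predictors
NULL

# Bilinear interpolation of one grid at arbitrary lon/lat points. Any NA
# among the four surrounding cell centers, or a point outside the span of
# cell centers, yields NA.
bilinear_at <- function(grid, lon, lat) {
  d <- dim(grid$values)
  # fractional column/row position in cell-center coordinates
  fc <- (lon - grid$origin_lon) / grid$cell_size + 0.5
  fr <- (grid$origin_lat - lat) / grid$cell_size + 0.5
  c0 <- floor(fc); r0 <- floor(fr)
  wx <- fc - c0; wy <- fr - r0
  out <- rep(NA_real_, length(lon))
  ok <- c0 >= 1 & c0 + 1 <= d[2] & r0 >= 1 & r0 + 1 <= d[1]
  if (any(ok)) {
    v <- grid$values
    i00 <- cbind(r0[ok], c0[ok]);     i01 <- cbind(r0[ok], c0[ok] + 1)
    i10 <- cbind(r0[ok] + 1, c0[ok]); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
    out[ok] <- v[i00] * (1 - wx[ok]) * (1 - wy[ok]) +
      v[i01] * wx[ok] * (1 - wy[ok]) +
      v[i10] * (1 - wx[ok]) * wy[ok] +
      v[i11] * wx[ok] * wy[ok]
  }
  out
}

#' Align layers onto a common template grid
#'
#' Layers already on the template geometry pass through unchanged; others
#' are resampled bilinearly (continuous values) at the template's cell
#' centers. Nodata propagates; template cells outside a layer's interior
#' span become nodata.
#'
#' @param layers Named list of `sdm_grid` objects (each with a defined CRS).
#' @param template `sdm_grid` defining the target geometry.
#' @return A `predictor_stack` on the template geometry.
#' @export
align_stack <- function(layers, template) {
  out <- lapply(names(layers), function(nm) {
    g <- layers[[nm]]
    if (is.null(g$crs) || is.na(g$crs)) stop("layer '", nm, "' has no CRS")
    if (grid_aligned(g, template)) return(g)
    cc <- cell_centers(template)
    vals <- bilinear_at(g, cc$lon, cc$lat)
    if (all(is.na(vals)))
      stop("layer '", nm, "' does not overlap the template")
    grid_new(matrix(vals, nrow(template$values), ncol(template$values)),
             template$origin_lon, template$origin_lat, template$cell_size,
             template$crs)
  })
  names(out) <- names(layers)
  predictor_stack(out)
}

#' Terrain slope from elevation (Horn's method)
#'
#' Computes slope in degrees on a geographic grid using Horn's 3x3 weighted
#' finite differences. Degree spacing is converted to meters with 111,320 m
#' per degree of latitude and `111,320 * cos(lat)` per degree of longitude
#' at each row. Edge cells and cells whose 3x3 window touches nodata are
#' nodata.
#'
#' @param elevation `sdm_grid` of elevation in meters.
#' @return `sdm_grid` of slope in degrees.
#' @export
compute_slope <- function(elevation) {
  z <- elevation$values
  d <- dim(z)
  if (d[1] < 3 || d[2] < 3) stop("elevation grid must be at least 3 x 3")
  ri <- 2:(d[1] - 1); ci <- 2:(d[2] - 1)
  # 3x3 neighborhood blocks: letters follow Horn's stencil
  #   a b c
  #   d e f
  #   g h i
  a <- z[ri - 1, ci - 1]; b <- z[ri - 1, ci]; cc_ <- z[ri - 1, ci + 1]
  dd <- z[ri, ci - 1];                         f <- z[ri, ci + 1]
  g <- z[ri + 1, ci - 1]; h <- z[ri + 1, ci]; i2 <- z[ri + 1, ci + 1]

  m_per_deg <- 111320
  lat_rows <- elevation$origin_lat - (ri - 0.5) * elevation$cell_size
  xres <- elevation$cell_size * m_per_deg * cos(lat_rows * pi / 180)
  yres <- elevation$cell_size * m_per_deg

  dzdx <- ((cc_ + 2 * f + i2) - (a + 2 * dd + g)) / (8 * xres)  # recycled by row
  dzdy <- ((g + 2 * h + i2) - (a + 2 * b + cc_)) / (8 * yres)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi

  out <- matrix(NA_real_, d[1], d[2])
  out[ri, ci] <- slope
  out[is.na(z)] <- NA_real_  # the nodata cell itself is nodata too
  grid_new(out, elevation$origin_lon, elevation$origin_lat,
           elevation$cell_size, elevation$crs)
}

#' Crop and mask a stack to a study area
#'
#' Cells outside the mask become nodata and the grid extent is trimmed to
#' the bounding box of the mask's true cells.
#'
#' @param stack A `predictor_stack`.
#' @param area A `study_area` aligned to the stack.
#' @return A cropped, masked `predictor_stack`.
#' @export
crop_mask <- function(stack, area) {
  if (!grid_aligned(stack[[1]], area$mask))
    stop("study area mask is not aligned to the stack")
  inside <- area$mask$values == 1 & !is.na(area$mask$values)
  if (!any(inside)) stop("study area mask has no cells inside")
  rr <- range(which(apply(inside, 1, any)))
  cr <- range(which(apply(inside, 2, any)))
  g0 <- stack[[1]]
  new_origin_lon <- g0$origin_lon + (cr[1] - 1) * g0$cell_size
  new_origin_lat <- g0$origin_lat - (rr[1] - 1) * g0$cell_size
  out <- lapply(stack, function(g) {
    v <- g$values
    v[!inside] <- NA_real_
    grid_new(v[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE],
             new_origin_lon, new_origin_lat, g$cell_size, g$crs)
  })
  predictor_stack(out)
}

#' Seeded sample of valid cells from a stack
#'
#' Draws up to `max_cells` cells where every layer has data; used to keep
#' collinearity diagnostics tractable on large grids.
#'
#' @param stack A `predictor_stack`.
#' @param max_cells Sample-size cap.
#' @param seed Integer seed.
#' @return Tibble of predictor values, one column per layer.
#' @export
sample_stack_cells <- function(stack, max_cells = 10000, seed = 1L) {
  tb <- stack_as_tibble(stack, drop_na = TRUE)
  if (nrow(tb) > max_cells) {
    tb <- withr::with_seed(seed,
                           tb[sample.int(nrow(tb), max_cells), , drop = FALSE])
  }
  tb[names(stack)]
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from an ordinary least-squares regression of
#' each variable on all the others. Perfectly collinear variables are
#' reported as `Inf` (with a warning), never silently dropped.
#'
#' @param table Data frame / tibble of numeric variables (cell sample).
#' @return Named numeric vector of VIF scores.
#' @export
multicollinearity_vif <- function(table) {
  table <- as.data.frame(table)
  p <- ncol(table)
  if (p < 2) stop("need at least two variables")
  if (nrow(table) <= p) stop("sample size must exceed the number of variables")
  out <- stats::setNames(numeric(p), names(table))
  for (j in seq_len(p)) {
    fit <- stats::lm(table[[j]] ~ ., data = table[-j])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  if (any(is.infinite(out)))
    warning("perfect collinearity: ",
            paste(names(out)[is.infinite(out)], collapse = ", "))
  out
}

#' Pairwise-correlation variable selection
#'
#' While any pair of variables has `|r| >= threshold`, the member of the
#' worst (highest `|r|`) offending pair with the larger mean absolute
#' correlation against all remaining variables is dropped; variables in
#' `keep_list` are protected. Reports the selection and the maximum
#' remaining pairwise `|r|`.
#'
#' @param table Data frame / tibble of numeric variables (cell sample).
#' @param threshold Pearson correlation threshold in (0, 1].
#' @param keep_list Variables that must be kept (expert override).
#' @return List: `selected` (names kept), `dropped` (tibble `variable`,
#'   `reason`), `max_remaining_r` (max `|r|` among kept), `report` (tibble,
#'   one row per input variable).
#' @export
cor_select <- function(table, threshold = 0.8, keep_list = character(0)) {
  stopifnot(threshold > 0, threshold <= 1)
  table <- as.data.frame(table)
  vars <- names(table)
  cm <- abs(stats::cor(table))
  diag(cm) <- 0
  keep_cm <- cm[keep_list, keep_list, drop = FALSE]
  if (length(keep_list) > 1 && any(keep_cm >= threshold))
    stop("keep_list variables are themselves correlated above the threshold")

  alive <- vars
  dropped <- tibble::tibble(variable = character(), reason = character())
  repeat {
    sub <- cm[alive, alive, drop = FALSE]
    worst <- max(sub)
    if (worst < threshold || length(alive) < 2) break
    idx <- which(sub == worst, arr.ind = TRUE)[1, ]
    pair <- c(alive[idx[1]], alive[idx[2]])
    protected <- pair %in% keep_list
    victim <- if (all(protected)) {
      stop("keep_list variables are themselves correlated above the threshold")
    } else if (any(protected)) {
      pair[!protected][1]
    } else {
      mean_abs <- vapply(pair, function(v)
        mean(sub[v, setdiff(alive, v)]), numeric(1))
      pair[which.max(mean_abs)]
    }
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      variable = victim,
      reason = sprintf("|r| = %.3f with %s", worst,
                       setdiff(pair, victim))))
    alive <- setdiff(alive, victim)
  }
  max_rem <- if (length(alive) > 1) max(cm[alive, alive]) else 0
  report <- tibble::tibble(
    variable = vars,
    kept = vars %in% alive,
    reason = dplyr::if_else(
      vars %in% alive, "kept",
      dropped$reason[match(vars, dropped$variable)])
  )
  list(selected = alive, dropped = dropped,
       max_remaining_r = max_rem, report = report)
}

#' Rank candidate GCMs by distance to the candidate ensemble
#'
#' For each candidate future stack, the mean change (future minus present)
#' of two indicator variables is computed over the study area; candidates
#' are ranked by Euclidean distance (raw units by default) from the
#' across-candidate mean of those changes, and the `k` closest are selected.
#'
#' @param candidates Named list of future `predictor_stack`s (one per GCM).
#' @param present Present-day `predictor_stack`.
#' @param vars Two layer names used for the comparison.
#' @param area A `study_area` aligned to the stacks.
#' @param k Number of GCMs to select.
#' @param standardize Z-score the per-variable deltas across candidates
#'   before computing distances (off by default).
#' @return Tibble with one row per candidate (`gcm`, per-variable mean
#'   deltas, `distance`, `rank`, `selected`), ordered by rank.
#' @export
select_gcms <- function(candidates, present, vars, area, k = 3,
                        standardize = FALSE) {
  stopifnot(length(vars) == 2, k <= length(candidates))
  cells <- study_area_cells(area)
  if (!nrow(cells)) stop("empty study area")
  idx <- cbind(cells$row, cells$col)
  mean_delta <- function(stack, v) {
    d <- stack[[v]]$values[idx] - present[[v]]$values[idx]
    mean(d, na.rm = TRUE)
  }
  nm <- names(candidates)
  if (is.null(nm)) nm <- sprintf("gcm_%02d", seq_along(candidates))
  deltas <- t(vapply(candidates, function(st)
    c(mean_delta(st, vars[1]), mean_delta(st, vars[2])), numeric(2)))
  colnames(deltas) <- vars
  work <- deltas
  if (standardize) work <- scale(work)
  centre <- colMeans(work)
  dist <- sqrt(rowSums(sweep(work, 2, centre)^2))
  ord <- order(dist)
  tibble::tibble(
    gcm = nm,
    !!vars[1] := deltas[, 1],
    !!vars[2] := deltas[, 2],
    distance = as.numeric(dist),
    rank = match(seq_along(nm), ord),
    selected = rank <= k
  ) |> dplyr::arrange(.data$rank)
}
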