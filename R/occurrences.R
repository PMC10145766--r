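#' Occurrence ingestion, accuracy filtering, spatial thinning, study area
#'
#' Occurrence records travel as tibbles with columns `species`, `lon`, `lat`,
#' `uncertainty_km`, `source`. Distances between records are great-circle
#' (haversine) kilometers; study-area buffers are planar decimal degrees,
#' mirroring the common buffer-on-unprojected-coordinates workflow.
#'
#' @name occurrences
NULL

occ_columns <- c("species", "lon", "lat", "uncertainty_km", "source")

#' Read occurrence records from CSV
#'
#' Expects the header `species,lon,lat,uncertainty_km,source`. Rows whose
#' lon/lat fail to parse or fall outside valid coordinate ranges are dropped
#' with a message reporting the count.
#'
#' @param path CSV file path.
#' @return Occurrence tibble.
#' @export
read_occurrences <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(occ_columns, names(raw))
  if (length(missing))
    stop("occurrence file lacks required columns: ",
         paste(missing, collapse = ", "))
  out <- raw |>
    dplyr::mutate(
      lon = suppressWarnings(as.numeric(.data$lon)),
      lat = suppressWarnings(as.numeric(.data$lat)),
      uncertainty_km = suppressWarnings(as.numeric(.data$uncertainty_km))
    )
  bad <- is.na(out$lon) | is.na(out$lat) |
    out$lon < -180 | out$lon > 180 | out$lat < -90 | out$lat > 90
  if (any(bad))
    message("read_occurrences: dropped ", sum(bad),
            " row(s) with unparseable or out-of-range coordinates")
  out[!bad, occ_columns]
}

#' Write occurrence records to CSV
#' @param occ Occurrence tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  readr::write_csv(occ[occ_columns], path)
  invisible(path)
}

#' Filter records by positional accuracy
#'
#' Keeps records whose positional uncertainty is strictly below the bound.
#' In strict mode (default) records with unknown uncertainty are omitted —
#' only georeferenced or highly accurate data survive. In non-strict mode
#' every record is kept and a logical `flagged` column marks those that
#' failed the accuracy requirement.
#'
#' @param occ Occurrence tibble.
#' @param max_uncertainty_km Accuracy bound in km (> 0).
#' @param strict Drop failing records (`TRUE`) or keep and flag (`FALSE`).
#' @return Occurrence tibble (with `flagged` column when `strict = FALSE`).
#' @export
filter_accuracy <- function(occ, max_uncertainty_km = 5, strict = TRUE) {
  stopifnot(max_uncertainty_km > 0)
  ok <- !is.na(occ$uncertainty_km) & occ$uncertainty_km < max_uncertainty_km
  if (strict) occ[ok, , drop = FALSE]
  else dplyr::mutate(occ, flagged = !ok)
}

# Pairwise great-circle distance matrix in km.
haversine_matrix_km <- function(occ) {
  p <- cbind(occ$lon, occ$lat)
  geosphere::distm(p, fun = geosphere::distHaversine) / 1000
}

#' Spatially thin occurrence records
#'
#' Subsamples records so that all pairwise great-circle distances are at
#' least `min_dist_km`, repeating a randomized greedy pass `iterations`
#' times and keeping the largest subset found (first attained on ties), so
#' as many records as possible are retained. Records are canonically ordered
#' internally, making the result invariant to input row order for a given
#' seed; the returned rows keep their input order.
#'
#' @param occ Occurrence tibble.
#' @param min_dist_km Minimum nearest-neighbor distance in km (> 0).
#' @param iterations Number of randomized passes (>= 1).
#' @param seed Integer seed.
#' @return Thinned occurrence tibble (a subset of `occ`).
#' @export
thin_spatial <- function(occ, min_dist_km = 10, iterations = 1000,
                         seed = 1L) {
  stopifnot(min_dist_km > 0, iterations >= 1)
  n <- nrow(occ)
  if (n <= 1) return(occ)
  canon <- order(occ$lon, occ$lat, occ$uncertainty_km, occ$source)
  dmat <- haversine_matrix_km(occ[canon, , drop = FALSE])
  conflict <- dmat < min_dist_km
  diag(conflict) <- FALSE
  if (!any(conflict)) return(occ)

  best <- integer(0)
  withr::with_seed(seed, {
    for (it in seq_len(iterations)) {
      ord <- sample.int(n)
      accepted <- logical(n)
      for (i in ord) {
        if (!any(conflict[i, accepted])) accepted[i] <- TRUE
      }
      if (sum(accepted) > length(best)) best <- which(accepted)
    }
  })
  keep_input_idx <- sort(canon[best])
  occ[keep_input_idx, , drop = FALSE]
}

#' Build a buffered study area around presences
#'
#' Marks every template cell whose center lies within `buffer_deg` planar
#' decimal degrees of any presence point. Contiguity of the buffered patches
#' is emergent, not enforced.
#'
#' @param occ Non-empty occurrence tibble.
#' @param buffer_deg Buffer radius in decimal degrees.
#' @param template `sdm_grid` defining the analysis grid.
#' @return A `study_area`: list with `mask` (logical-valued `sdm_grid`, 1 =
#'   inside) and `buffer_deg`.
#' @export
build_study_area <- function(occ, buffer_deg = 2.5, template) {
  if (!nrow(occ)) stop("cannot build a study area from zero occurrences")
  cc <- cell_centers(template)
  inside <- rep(FALSE, nrow(cc))
  r2 <- buffer_deg^2
  for (i in seq_len(nrow(occ))) {
    d2 <- (cc$lon - occ$lon[i])^2 + (cc$lat - occ$lat[i])^2
    inside <- inside | d2 <= r2
  }
  mask_vals <- matrix(as.numeric(inside), nrow(template$values),
                      ncol(template$values))
  mask_vals[is.na(template$values)] <- NA_real_
  structure(
    list(mask = grid_new(mask_vals, template$origin_lon,
                         template$origin_lat, template$cell_size,
                         template$crs),
         buffer_deg = buffer_deg),
    class = "study_area")
}

#' @export
print.study_area <- function(x, ...) {
  cat(sprintf("<study_area> %d cells inside (buffer %.3g deg)\n",
              sum(x$mask$values == 1, na.rm = TRUE), x$buffer_deg))
  invisible(x)
}

#' Cells of a study area that are inside the mask
#' @param area A `study_area`.
#' @return Tibble with `row`, `col`, `lon`, `lat`.
#' @export
study_area_cells <- function(area) {
  tb <- as_tibble.sdm_grid(area$mask)
  tb[tb$value == 1, c("row", "col", "lon", "lat")]
}
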