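#' Synthetic landscapes and virtual species
#'
#' Seeded generators for spatially autocorrelated, mutually correlated
#' bioclim-like predictor layers, an elevation surface, a virtual species
#' with unimodal (Gaussian) responses, presence sampling proportional to
#' suitability, and future-climate scenario sets built from additive deltas
#' plus smooth per-GCM deviations. Every generator is a pure function of its
#' configuration, so the full modeling workflow can be exercised end-to-end
#' with no external data.
#'
#' @name synthetic
NULL

# Row-stochastic Gaussian smoothing matrix; applied on both margins it
# implements separable kernel smoothing with edge renormalization.
smoothing_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  i <- seq_len(n)
  W <- exp(-outer(i, i, "-")^2 / (2 * sigma^2))
  W[abs(outer(i, i, "-")) > ceiling(3 * sigma)] <- 0
  W / rowSums(W)
}

# One smooth standardized (mean 0, sd 1) random field. Assumes RNG state set
# by the caller.
smooth_field <- function(n_rows, n_cols, range_cells) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  f <- smoothing_matrix(n_rows, range_cells) %*% z %*%
    t(smoothing_matrix(n_cols, range_cells))
  f <- f - mean(f)
  s <- stats::sd(as.vector(f))
  if (s > 0) f <- f / s
  f
}

#' Landscape generator configuration
#'
#' Layers are linear mixes of shared smooth latent fields (orthonormalized,
#' so the loading geometry fixes the inter-layer correlations exactly) plus
#' an optional coupling to the standardized elevation pattern, then rescaled
#' to the requested per-layer mean and standard deviation. Elevation is a
#' deterministic planar gradient plus a smooth random roughness component.
#'
#' @param n_rows,n_cols Grid dimensions (>= 8).
#' @param cell_size_deg Cell size in decimal degrees.
#' @param origin_lon,origin_lat Upper-left corner of the grid (degrees).
#' @param n_latent_fields Number of shared latent fields.
#' @param autocorrelation_range Gaussian smoothing kernel width, in cells.
#' @param layer_loadings Numeric matrix (layers x latent fields) with row
#'   names naming the generated climate layers.
#' @param layer_means,layer_sds Per-layer location and scale, in layer units.
#' @param elevation_coupling Named per-layer weight on the standardized
#'   elevation pattern (e.g. a negative weight makes a temperature-like layer
#'   decrease with altitude). Defaults to 0 for unnamed layers.
#' @param elevation_params List: `base` (m), `gradient_east` and
#'   `gradient_north` (m per cell), `roughness_sd` (m), `roughness_range`
#'   (cells).
#' @param seed Integer seed.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(n_rows = 100, n_cols = 100,
                             cell_size_deg = 0.05,
                             origin_lon = 10, origin_lat = 48,
                             n_latent_fields = 4,
                             autocorrelation_range = 6,
                             layer_loadings,
                             layer_means, layer_sds,
                             elevation_coupling = numeric(0),
                             elevation_params = list(
                               base = 200, gradient_east = 8,
                               gradient_north = 4, roughness_sd = 350,
                               roughness_range = 8),
                             seed = 1L) {
  if (n_rows < 8 || n_cols < 8) stop("grid must be at least 8 x 8")
  if (cell_size_deg <= 0) stop("cell_size_deg must be positive")
  if (!is.matrix(layer_loadings) || is.null(rownames(layer_loadings)))
    stop("layer_loadings must be a matrix with layer names as row names")
  if (ncol(layer_loadings) != n_latent_fields)
    stop("layer_loadings must have one column per latent field")
  nm <- rownames(layer_loadings)
  if (length(layer_means) != length(nm) || length(layer_sds) != length(nm))
    stop("layer_means and layer_sds must have one value per layer")
  cpl <- stats::setNames(rep(0, length(nm)), nm)
  cpl[names(elevation_coupling)] <- elevation_coupling
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size_deg = cell_size_deg,
         origin_lon = origin_lon, origin_lat = origin_lat,
         n_latent_fields = n_latent_fields,
         autocorrelation_range = autocorrelation_range,
         layer_loadings = layer_loadings,
         layer_means = stats::setNames(layer_means, nm),
         layer_sds = stats::setNames(layer_sds, nm),
         elevation_coupling = cpl,
         elevation_params = elevation_params,
         seed = as.integer(seed)),
    class = "landscape_config")
}

#' Generate a synthetic predictor stack
#'
#' Produces one grid per configured climate layer plus an `altitude` layer.
#' Identical configuration (including seed) yields bit-identical output.
#'
#' @param config A [landscape_config()].
#' @return A `predictor_stack`.
#' @export
gen_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  withr::with_seed(config$seed, {
    nr <- config$n_rows; nc <- config$n_cols
    ep <- config$elevation_params

    rough <- smooth_field(nr, nc, ep$roughness_range)
    east <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
    north <- matrix(rep(nr - seq_len(nr), times = nc), nr, nc)
    elev <- ep$base + ep$gradient_east * east + ep$gradient_north * north +
      ep$roughness_sd * rough

    # orthonormal basis: first component spans the elevation pattern, the
    # rest are smooth latent fields orthogonal to it and to each other
    raw <- vapply(seq_len(config$n_latent_fields),
                  function(k) as.vector(
                    smooth_field(nr, nc, config$autocorrelation_range)),
                  numeric(nr * nc))
    ev <- as.vector(elev) - mean(elev)
    qr_basis <- qr.Q(qr(cbind(ev, raw)))
    ncell <- nr * nc
    elev_u <- qr_basis[, 1] * sqrt(ncell - 1)        # unit-sd elevation axis
    fields <- qr_basis[, -1, drop = FALSE] * sqrt(ncell - 1)
    if (sum(ev^2) > 0 && stats::cor(elev_u, ev) < 0) elev_u <- -elev_u

    layers <- list()
    for (j in seq_len(nrow(config$layer_loadings))) {
      nm <- rownames(config$layer_loadings)[j]
      mix <- fields %*% config$layer_loadings[j, ] +
        config$elevation_coupling[[nm]] * elev_u
      s <- stats::sd(mix)
      vals <- if (s > 0) {
        config$layer_means[[nm]] +
          config$layer_sds[[nm]] * (mix - mean(mix)) / s
      } else {
        rep(config$layer_means[[nm]], length(mix))
      }
      layers[[nm]] <- grid_new(matrix(vals, nr, nc),
                               config$origin_lon, config$origin_lat,
                               config$cell_size_deg)
    }
    layers[["altitude"]] <- grid_new(elev, config$origin_lon,
                                     config$origin_lat, config$cell_size_deg)
    predictor_stack(layers)
  })
}

#' Virtual species configuration
#'
#' The species' suitability is a product of independent Gaussian responses,
#' `S(x) = prod_v exp(-(E_v(x) - mu_v)^2 / (2 sigma_v^2))`, emulating the
#' realized niche a correlative model approximates.
#'
#' @param response_vars Layer names the species responds to.
#' @param mu Named optimum per response variable (layer units).
#' @param sigma Named niche breadth per response variable (> 0, layer units).
#' @param n_presences Number of presences to sample.
#' @param sampling `"weighted"` (draw cells with probability proportional to
#'   suitability) or `"bernoulli"` (accept cells with probability equal to
#'   suitability).
#' @param species Label attached to sampled records.
#' @param seed Integer seed for presence sampling.
#' @return A `virtual_species_config` list.
#' @export
virtual_species_config <- function(response_vars, mu, sigma,
                                   n_presences = 300,
                                   sampling = c("weighted", "bernoulli"),
                                   species = "virtualis", seed = 1L) {
  sampling <- match.arg(sampling)
  mu <- mu[response_vars]; sigma <- sigma[response_vars]
  if (anyNA(mu) || anyNA(sigma))
    stop("mu and sigma must be named for every response variable")
  if (any(sigma <= 0)) stop("all niche breadths must be positive")
  structure(
    list(response_vars = response_vars, mu = mu, sigma = sigma,
         n_presences = as.integer(n_presences), sampling = sampling,
         species = species, seed = as.integer(seed)),
    class = "virtual_species_config")
}

#' True suitability surface of a virtual species
#'
#' @param stack A `predictor_stack` containing all response variables.
#' @param sp A [virtual_species_config()].
#' @return An `sdm_grid` with values in `[0, 1]`; nodata propagated.
#' @export
true_suitability <- function(stack, sp) {
  missing <- setdiff(sp$response_vars, names(stack))
  if (length(missing))
    stop("response variables not in stack: ", paste(missing, collapse = ", "))
  g <- stack[[1]]
  s <- matrix(1, nrow(g$values), ncol(g$values))
  for (v in sp$response_vars) {
    e <- stack[[v]]$values
    s <- s * exp(-(e - sp$mu[[v]])^2 / (2 * sp$sigma[[v]]^2))
  }
  grid_new(s, g$origin_lon, g$origin_lat, g$cell_size, g$crs)
}

#' Sample virtual presences from a suitability surface
#'
#' Coordinates are cell centers; records carry zero positional uncertainty
#' and source `"virtual"`.
#'
#' @param suit Suitability `sdm_grid` (values in `[0, 1]`).
#' @param sp A [virtual_species_config()].
#' @return Occurrence tibble (`species`, `lon`, `lat`, `uncertainty_km`,
#'   `source`).
#' @export
sample_occurrences <- function(suit, sp) {
  cells <- as_tibble.sdm_grid(suit)
  n <- sp$n_presences
  empty <- tibble::tibble(species = character(), lon = numeric(),
                          lat = numeric(), uncertainty_km = numeric(),
                          source = character())
  if (n == 0) return(empty)
  if (!nrow(cells) || sum(cells$value) <= 0)
    stop("cannot sample presences: suitability is zero everywhere")
  withr::with_seed(sp$seed, {
    if (sp$sampling == "weighted") {
      pos <- cells[cells$value > 0, , drop = FALSE]
      if (n > nrow(pos))
        stop("n_presences exceeds the number of cells with positive ",
             "suitability")
      picked <- pos[sample.int(nrow(pos), n, prob = pos$value), , drop = FALSE]
    } else {
      picked <- cells[0, ]
      guard <- 0
      while (nrow(picked) < n) {
        guard <- guard + 1
        if (guard > 10000) stop("bernoulli sampling failed to reach n")
        ord <- cells[sample.int(nrow(cells)), , drop = FALSE]
        acc <- ord[stats::runif(nrow(ord)) < ord$value, , drop = FALSE]
        picked <- utils::head(dplyr::bind_rows(picked, acc), n)
      }
    }
    tibble::tibble(species = sp$species, lon = picked$lon, lat = picked$lat,
                   uncertainty_km = 0, source = "virtual")
  })
}

#' Future climate scenario configuration
#'
#' @param rcp_label Scenario label, e.g. `"RCP45"`.
#' @param deltas Named additive shift per climate layer (layer units).
#'   Topographic layers (`altitude`, `slope`) must not appear.
#' @param gcm_noise_sd Scale of the smooth per-GCM deviation field applied to
#'   every shifted layer (single value or named per layer).
#' @param n_gcms Number of candidate general circulation models (>= 1).
#' @param noise_range Autocorrelation range of the deviation fields (cells).
#' @param seed Integer seed.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(rcp_label, deltas, gcm_noise_sd = 0,
                            n_gcms = 3, noise_range = 8, seed = 1L) {
  if (n_gcms < 1) stop("n_gcms must be at least 1")
  topo <- intersect(names(deltas), c("altitude", "slope"))
  if (length(topo))
    stop("deltas may not target topographic layers: ",
         paste(topo, collapse = ", "))
  structure(
    list(rcp_label = rcp_label, deltas = deltas,
         gcm_noise_sd = gcm_noise_sd, n_gcms = as.integer(n_gcms),
         noise_range = noise_range, seed = as.integer(seed)),
    class = "scenario_config")
}

#' Build per-GCM future predictor stacks
#'
#' Each candidate GCM stack is `present + delta + smooth deviation field` on
#' the climate layers; `altitude` and `slope` are copied unchanged (topography
#' is static over the projection horizon).
#'
#' @param stack Present-day `predictor_stack`.
#' @param sc A [scenario_config()].
#' @return A `scenario_set`: list with `rcp_label` and `gcms`, a named list
#'   of `predictor_stack`s.
#' @export
make_future_scenarios <- function(stack, sc) {
  stopifnot(inherits(sc, "scenario_config"))
  unknown <- setdiff(names(sc$deltas), names(stack))
  if (length(unknown))
    stop("delta for unknown layer: ", paste(unknown, collapse = ", "))
  climate <- setdiff(names(stack), c("altitude", "slope"))
  noise_sd <- sc$gcm_noise_sd
  if (is.null(names(noise_sd)))
    noise_sd <- stats::setNames(rep(noise_sd[1], length(climate)), climate)
  nr <- nrow(stack[[1]]$values); ncg <- ncol(stack[[1]]$values)
  gcms <- withr::with_seed(sc$seed, {
    lapply(seq_len(sc$n_gcms), function(g) {
      out <- stack
      for (nm in climate) {
        delta <- if (nm %in% names(sc$deltas)) sc$deltas[[nm]] else 0
        sdv <- if (nm %in% names(noise_sd)) noise_sd[[nm]] else 0
        dev <- if (sdv > 0) sdv * smooth_field(nr, ncg, sc$noise_range) else 0
        out[[nm]]$values <- out[[nm]]$values + delta + dev
      }
      structure(out, class = "predictor_stack")
    })
  })
  names(gcms) <- sprintf("gcm_%02d", seq_len(sc$n_gcms))
  structure(list(rcp_label = sc$rcp_label, gcms = gcms),
            class = "scenario_set")
}

# ---- bundled demonstration fixture -----------------------------------------

#' Demonstration landscape and virtual species
#'
#' A 100 x 100 cell landscape with six bioclim-like layers (three of which
#' the demo species responds to, three pure decoys), a temperature layer
#' strongly coupled to elevation (lapse-rate style), one deliberately
#' collinear layer pair (r = 0.9, exercising correlation filtering), and an
#' elevation surface with an eastward/northward gradient plus smooth relief.
#'
#' @param seed Integer seed.
#' @param n_rows,n_cols Grid dimensions.
#' @return `demo_landscape_config()` a [landscape_config()];
#'   `demo_species_config()` a [virtual_species_config()].
#' @export
demo_landscape_config <- function(seed = 1L, n_rows = 100, n_cols = 100) {
  loadings <- rbind(
    bio_4  = c(0.8,  0,    0,   0,    0.2,  0),
    bio_10 = c(0.45, 0.1,  0,   0,    0,    0.15),  # + strong lapse-rate term
    bio_12 = c(0,    0,    1,   0,    0.2,  0),
    bio_2  = c(0,    0.95, 0,   0.3,  0,    0.2),
    bio_17 = c(0,    0,    0.3, 0.95, 0,    0.15),
    bio_18 = c(0.2,  0.3,  0.2, 0.4,  0.65, 0)
  )
  landscape_config(
    n_rows = n_rows, n_cols = n_cols,
    cell_size_deg = 0.05, origin_lon = 10, origin_lat = 48,
    n_latent_fields = 6, autocorrelation_range = 6,
    layer_loadings = loadings,
    layer_means = c(bio_4 = 700, bio_10 = 18, bio_12 = 900,
                    bio_2 = 10, bio_17 = 120, bio_18 = 220),
    layer_sds = c(bio_4 = 150, bio_10 = 4, bio_12 = 250,
                  bio_2 = 2, bio_17 = 50, bio_18 = 80),
    elevation_coupling = c(bio_4 = 0.45, bio_10 = -0.85, bio_12 = 0.35),
    seed = seed)
}

#' @rdname demo_landscape_config
#' @export
demo_scenarios <- function(seed = 1L) {
  list(
    # warming pushes the thermal optimum upslope and contracts the envelope
    contract = scenario_config(
      "RCP_contract", deltas = c(bio_10 = 2, bio_4 = 40),
      gcm_noise_sd = 0.3, n_gcms = 3, seed = child_seed(seed, "contract")),
    # mild cooling plus wetting moves climate toward the optimum everywhere
    expand = scenario_config(
      "RCP_expand", deltas = c(bio_10 = -0.5, bio_4 = -30, bio_12 = 80),
      gcm_noise_sd = 0.3, n_gcms = 3, seed = child_seed(seed, "expand"))
  )
}

#' @rdname demo_landscape_config
#' @param n_presences Presences to sample.
#' @export
demo_species_config <- function(seed = 1L, n_presences = 300) {
  virtual_species_config(
    response_vars = c("bio_4", "bio_10", "bio_12"),
    mu = c(bio_4 = 650, bio_10 = 16, bio_12 = 1000),
    sigma = c(bio_4 = 75, bio_10 = 1.6, bio_12 = 140),
    n_presences = n_presences, sampling = "weighted",
    species = "virtualis", seed = seed)
}
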