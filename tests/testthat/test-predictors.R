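test_that("aligned layers pass through bit-identical", {
  g <- const_grid(7, nr = 8, nc = 8)
  st <- align_stack(list(x = g), template = g)
  expect_identical(st$x, g)
})

test_that("bilinear resampling reproduces constants and linear ramps", {
  # fine constant layer onto a coarser template: still constant
  fine <- const_grid(3.5, nr = 20, nc = 20, cell = 0.05)
  coarse_tmpl <- const_grid(0, nr = 9, nc = 9, cell = 0.1,
                            origin_lon = 0.05, origin_lat = 9.95)
  out <- align_stack(list(x = fine), coarse_tmpl)$x
  expect_true(all(abs(out$values[!is.na(out$values)] - 3.5) < 1e-12))

  # linear ramp in longitude: interior values match the closed form
  nr <- 20; nc <- 20
  lon_centers <- 0 + (seq_len(nc) - 0.5) * 0.05
  ramp <- grid_new(matrix(rep(10 * lon_centers, each = nr), nr, nc),
                   0, 10, 0.05)
  tmpl <- grid_new(matrix(0, 12, 12), 0.1, 9.9, 0.07)
  res <- align_stack(list(x = ramp), tmpl)$x
  cc <- cell_centers(res)
  ok <- !is.na(as.vector(res$values))
  expect_lt(max(abs(as.vector(res$values)[ok] - 10 * cc$lon[ok])), 1e-6)
})

test_that("misaligned layers without overlap or CRS are rejected", {
  g <- const_grid(1)
  far <- grid_new(matrix(1, 5, 5), 100, -60, 0.1)
  expect_error(align_stack(list(x = far), g), "overlap")
  nocrs <- g; nocrs$crs <- NA
  expect_error(align_stack(list(x = nocrs), far), "CRS")
})

test_that("slope is zero on flat terrain and atan(g) on a tilted plane", {
  flat <- const_grid(500, nr = 10, nc = 10)
  s <- compute_slope(flat)
  inner <- s$values[2:9, 2:9]
  expect_true(all(inner == 0))
  expect_true(all(is.na(s$values[1, ])))  # edge cells are nodata

  # plane rising g meters per meter eastward at the equator
  gpm <- 0.05
  nr <- 12; nc <- 12; cell <- 0.01
  m_per_deg <- 111320
  lonm <- (seq_len(nc) - 0.5) * cell * m_per_deg
  plane <- grid_new(matrix(rep(gpm * lonm, each = nr), nr, nc),
                    0, 0.06, cell)  # rows straddle the equator
  sp <- compute_slope(plane)
  inner <- sp$values[2:(nr - 1), 2:(nc - 1)]
  expected <- atan(gpm) * 180 / pi
  expect_lt(max(abs(inner - expected)), expected * 0.001)
})

test_that("slope agrees with a central-difference gradient on smooth relief", {
  st <- gen_landscape(demo_landscape_config(seed = 8, n_rows = 30,
                                            n_cols = 30))
  elev <- st$altitude
  s <- compute_slope(elev)
  # independent oracle: central differences, same metric conversion
  z <- elev$values
  m_per_deg <- 111320
  for (cell_idx in list(c(10, 10), c(15, 20), c(22, 7))) {
    i <- cell_idx[1]; j <- cell_idx[2]
    lat <- elev$origin_lat - (i - 0.5) * elev$cell_size
    dx <- (z[i, j + 1] - z[i, j - 1]) /
      (2 * elev$cell_size * m_per_deg * cos(lat * pi / 180))
    dy <- (z[i + 1, j] - z[i - 1, j]) / (2 * elev$cell_size * m_per_deg)
    oracle <- atan(sqrt(dx^2 + dy^2)) * 180 / pi
    expect_lt(abs(s$values[i, j] - oracle), max(0.15, 0.1 * oracle))
  }
})

test_that("nodata in elevation blanks the full 3x3 neighborhood of slopes", {
  elev <- const_grid(100, nr = 9, nc = 9)
  elev$values[5, 5] <- NA
  s <- compute_slope(elev)
  expect_true(all(is.na(s$values[4:6, 4:6])))
  expect_false(is.na(s$values[2, 2]))
  expect_error(compute_slope(const_grid(1, nr = 2, nc = 2)), "3 x 3")
})

test_that("crop_mask masks outside cells and trims to the mask extent", {
  st <- const_stack(list(a = 1, b = 2), nr = 10, nc = 10)
  area_all <- full_area(st$a)
  full <- crop_mask(st, area_all)
  expect_equal(full$a$values, st$a$values)

  # checkerboard: half the cells nodata, extent unchanged
  mk <- st$a
  mk$values <- matrix(as.numeric((outer(1:10, 1:10, "+")) %% 2 == 0), 10, 10)
  area_cb <- structure(list(mask = mk, buffer_deg = 1), class = "study_area")
  cb <- crop_mask(st, area_cb)
  expect_equal(sum(is.na(cb$a$values)), 50)
  expect_equal(sum(!is.na(cb$a$values)),
               sum(mk$values == 1))

  # interior block: bounding box trimmed, accounting identity holds
  mk2 <- st$a
  mk2$values <- matrix(0, 10, 10)
  mk2$values[3:6, 4:8] <- 1
  area_in <- structure(list(mask = mk2, buffer_deg = 1),
                       class = "study_area")
  crp <- crop_mask(st, area_in)
  expect_equal(dim(crp$a$values), c(4, 5))
  expect_equal(sum(!is.na(crp$a$values)), sum(mk2$values == 1))
  # geotransform shifted to the trimmed window
  expect_equal(crp$a$origin_lon, st$a$origin_lon + 3 * 0.1)
  expect_equal(crp$a$origin_lat, st$a$origin_lat - 2 * 0.1)
})

test_that("VIF matches its closed form and flags degeneracy", {
  n <- 4000
  tab <- withr::with_seed(1, tibble::tibble(
    a = rnorm(n), b = rnorm(n), c = rnorm(n)))
  v <- multicollinearity_vif(tab)
  expect_true(all(abs(v - 1) < 0.1))

  x1 <- withr::with_seed(2, rnorm(n))
  x2 <- 0.8 * x1 + sqrt(1 - 0.64) * withr::with_seed(3, rnorm(n))
  tab2 <- tibble::tibble(x1 = x1, x2 = x2)
  r <- cor(x1, x2)
  v2 <- multicollinearity_vif(tab2)
  expect_equal(unname(v2["x1"]), 1 / (1 - r^2), tolerance = 1e-8)
  expect_equal(unname(v2["x2"]), 1 / (1 - r^2), tolerance = 1e-8)

  dup <- tibble::tibble(x = x1, y = x1)
  expect_warning(v3 <- multicollinearity_vif(dup), "collinearity")
  expect_true(all(is.infinite(v3)))
})

test_that("correlation selection drops by the mean-|r| rule with keep_list", {
  n <- 2000
  base <- withr::with_seed(4, rnorm(n))
  tab <- tibble::tibble(
    A = base,
    B = 0.9 * base + sqrt(1 - 0.81) * withr::with_seed(5, rnorm(n)),
    C = withr::with_seed(6, rnorm(n)))

  # nothing above threshold: all kept
  low <- cor_select(tab, threshold = 0.95)
  expect_setequal(low$selected, c("A", "B", "C"))
  expect_equal(nrow(low$dropped), 0)

  # protected A: its partner B is the victim
  sel <- cor_select(tab, threshold = 0.8, keep_list = "A")
  expect_setequal(sel$selected, c("A", "C"))
  expect_equal(sel$dropped$variable, "B")
  expect_lt(sel$max_remaining_r, 0.8)

  expect_error(cor_select(tab, threshold = 0.8, keep_list = c("A", "B")),
               "keep_list")
})

test_that("selection always leaves max pairwise |r| below the threshold", {
  for (seed in 1:4) {
    tab <- withr::with_seed(seed, {
      z <- matrix(rnorm(500 * 3), 500, 3)
      tibble::as_tibble(as.data.frame(
        z %*% matrix(runif(3 * 6, -1, 1), 3, 6) +
          0.4 * matrix(rnorm(500 * 6), 500, 6)))
    })
    sel <- cor_select(tab, threshold = 0.7)
    if (length(sel$selected) > 1) {
      cm <- abs(cor(tab[sel$selected])); diag(cm) <- 0
      expect_lt(max(cm), 0.7)
    }
  }
})

test_that("GCM selection ranks candidates by distance to their ensemble", {
  present <- const_stack(list(v1 = 0, v2 = 0), nr = 6, nc = 6)
  mk_future <- function(d1, d2)
    const_stack(list(v1 = d1, v2 = d2), nr = 6, nc = 6)
  cands <- list(A = mk_future(1, 1), B = mk_future(1.1, 0.9),
                C = mk_future(5, 5), D = mk_future(0.9, 1.1))
  area <- full_area(present$v1)
  sel <- select_gcms(cands, present, c("v1", "v2"), area, k = 3)
  expect_setequal(sel$gcm[sel$selected], c("A", "B", "D"))
  expect_equal(sel$distance[sel$gcm == "A"], sqrt(2), tolerance = 1e-9)
  expect_equal(sel$distance[sel$gcm == "C"], sqrt(18), tolerance = 1e-9)
  expect_equal(sel$gcm[1], "A")

  # permutation invariance of the selection
  sel2 <- select_gcms(cands[c("C", "D", "A", "B")], present,
                      c("v1", "v2"), area, k = 3)
  expect_setequal(sel2$gcm[sel2$selected], c("A", "B", "D"))

  one <- select_gcms(cands["A"], present, c("v1", "v2"), area, k = 1)
  expect_equal(one$distance, 0)
  expect_true(one$selected)
})
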