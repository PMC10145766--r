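# Independent brute-force oracles used to check the package's statistics.

# AUC as the concordant-pair fraction over all presence x absence pairs,
# ties counting one half.
auc_bruteforce <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(s1) * length(s0))
}

# Max sensitivity + specificity by scanning a dense lattice of thresholds
# bracketing every observed score (rule: score >= threshold is positive).
mtss_bruteforce <- function(scores, labels) {
  cand <- sort(unique(c(0, 1, scores, scores - 1e-9, scores + 1e-9)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  best <- -Inf
  for (t in cand) {
    pos <- scores >= t
    tss <- sum(pos & labels == 1) / n1 + sum(!pos & labels == 0) / n0 - 1
    if (tss > best) best <- tss
  }
  best
}

# Largest subset with all pairwise haversine distances >= min_dist_km, by
# exhaustive search over all 2^n subsets (n <= 12).
thin_optimum_size <- function(occ, min_dist_km) {
  n <- nrow(occ)
  d <- geosphere::distm(cbind(occ$lon, occ$lat),
                        fun = geosphere::distHaversine) / 1000
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) <= best) next
    ok <- TRUE
    if (length(idx) > 1) {
      sub <- d[idx, idx]
      ok <- min(sub[upper.tri(sub)]) >= min_dist_km
    }
    if (ok) best <- length(idx)
  }
  best
}

# Occurrence tibble shorthand.
occ_tbl <- function(lon, lat, uncertainty_km = 0, species = "sp",
                    source = "test") {
  tibble::tibble(species = species, lon = lon, lat = lat,
                 uncertainty_km = uncertainty_km, source = source)
}

# Constant-valued grid/stack shorthands.
const_grid <- function(value, nr = 10, nc = 10, origin_lon = 0,
                       origin_lat = 10, cell = 0.1) {
  grid_new(matrix(value, nr, nc), origin_lon, origin_lat, cell)
}

const_stack <- function(values, nr = 10, nc = 10, ...) {
  predictor_stack(lapply(values, const_grid, nr = nr, nc = nc, ...))
}

full_area <- function(template, buffer = 1e6) {
  mk <- template
  mk$values <- matrix(ifelse(is.na(template$values), NA_real_, 1),
                      nrow(template$values), ncol(template$values))
  structure(list(mask = mk, buffer_deg = buffer), class = "study_area")
}
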