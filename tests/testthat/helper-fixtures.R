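# shared fixtures built in code

default_calib <- calibration_model()

# tiny 3x3 grid with values 1..9 (column-major), no missing cells
tiny_grid <- function() {
  isoscape_grid(lat = c(10, 20, 30), lon = c(-30, -20, -10),
                values = matrix(1:9, nrow = 3))
}

# random grid with missing cells, for oracle comparisons
random_grid <- function(n_lat = 6, n_lon = 7, miss = 0.2) {
  vals <- matrix(stats::rnorm(n_lat * n_lon, 0, 2), n_lat, n_lon)
  vals[stats::runif(n_lat * n_lon) < miss] <- NA
  if (all(is.na(vals))) vals[1, 1] <- 0
  isoscape_grid(lat = seq(0, 70, length.out = n_lat),
                lon = seq(-80, -10, length.out = n_lon), vals)
}

# brute-force per-cell interval scan (independent of assign_interval)
brute_mask <- function(grid, lo, hi) {
  out <- matrix(FALSE, length(grid$lat), length(grid$lon))
  for (i in seq_along(grid$lat)) {
    for (j in seq_along(grid$lon)) {
      v <- grid$values[i, j]
      if (!is.na(v) && v >= lo && v <= hi) out[i, j] <- TRUE
    }
  }
  out
}

# independent tie-corrected Kruskal-Wallis from first principles
kw_oracle <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  splits <- split(r, rep(seq_along(groups), lengths(groups)))
  s <- sum(vapply(splits, function(ri) sum(ri)^2 / length(ri), numeric(1)))
  tie <- sum(vapply(unique(pooled), function(v) {
    t <- sum(pooled == v); t^3 - t
  }, numeric(1)))
  ((12 / (N * (N + 1))) * s - 3 * (N + 1)) / (1 - tie / (N^3 - N))
}

# independent Dunn z for one pair (i, j)
dunn_z_oracle <- function(groups, i, j) {
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  splits <- split(r, rep(seq_along(groups), lengths(groups)))
  tie <- sum(vapply(unique(pooled), function(v) {
    t <- sum(pooled == v); t^3 - t
  }, numeric(1)))
  sigma2 <- (N * (N + 1) / 12 - tie / (12 * (N - 1))) *
    (1 / length(splits[[i]]) + 1 / length(splits[[j]]))
  (mean(splits[[i]]) - mean(splits[[j]])) / sqrt(sigma2)
}

# brute-force O(n^3) average-linkage: recompute every cross-pair mean
upgma_oracle_heights <- function(values) {
  clusters <- as.list(seq_along(values))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        d <- mean(abs(outer(values[clusters[[a]]], values[clusters[[b]]], "-")))
        if (d < best_d - 1e-12) { best_d <- d; best <- c(a, b) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}
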