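# Independent oracles and small fixture builders. These deliberately avoid
# the package's own code paths (explicit loops, dense solves) so they can
# serve as cross-checks.

# brute-force voxel counter: explicit triple loop over the grid
brute_force_volumes <- function(mask, labels, label_table, voxel_size_mm) {
  k <- max(label_table$merged_id)
  counts <- numeric(k)
  total <- 0
  merged_of <- integer(max(label_table$raw_id))
  merged_of[label_table$raw_id] <- label_table$merged_id
  d <- dim(mask)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
    if (mask[i, j, l] == 1) {
      total <- total + 1
      lab <- labels[i, j, l]
      if (lab > 0) counts[merged_of[lab]] <- counts[merged_of[lab]] + 1
    }
  }
  vox_ml <- prod(rep_len(voxel_size_mm, 3)) / 1000
  list(volumes_ml = counts * vox_ml, total_ml = total * vox_ml)
}

# brute-force recount of the compound score for one length-6 pattern
brute_force_vrcs <- function(ind) {
  a <- 0L
  p <- 0L
  for (v in ind) {
    if (!is.na(v)) {
      a <- a + 1L
      if (v == 1) p <- p + 1L
    }
  }
  if (a >= 3L) p / a else NA_real_
}

# closed-form GLS with the true covariance, built element by element
gls_oracle <- function(X, y, site, tau2, sigma2) {
  n <- nrow(X)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) V[i, j] <- sigma2 + tau2
    else if (site[i] == site[j]) V[i, j] <- tau2
  }
  Vi <- solve(V)
  cov_b <- solve(t(X) %*% Vi %*% X)
  drop(cov_b %*% t(X) %*% Vi %*% y)
}

# small atlas: two bilateral pairs + one midline ROI on a 16^3 grid
tiny_atlas <- function(vox = 1) {
  tab <- data.frame(
    raw_id = 1:5,
    name = c("pair A", "pair A", "pair B", "pair B", "mid C"),
    laterality = c("left", "right", "left", "right", "midline"),
    stringsAsFactors = FALSE)
  labels <- array(0L, c(16, 16, 16))
  labels[2:5, 2:7, 2:7] <- 1L
  labels[12:15, 2:7, 2:7] <- 2L
  labels[2:5, 9:14, 2:7] <- 3L
  labels[12:15, 9:14, 2:7] <- 4L
  labels[7:10, 2:7, 9:14] <- 5L
  label_atlas(labels, vox, tab)
}

random_lesion <- function(dims = c(16, 16, 16), p = 0.2, vox = 1,
                          subject_id = "S1") {
  lesion_mask(array(stats::rbinom(prod(dims), 1, p), dims), vox, subject_id)
}

# a valid custom layout: one bilateral pair + one midline block on a small grid
small_layout <- function() {
  structure(data.frame(
    name = c("pair A", "pair A", "mid B"),
    laterality = c("left", "right", "midline"),
    zone = c("anterior", "anterior", "posterior"),
    x0 = c(2L, 14L, 8L), x1 = c(5L, 17L, 11L),
    y0 = c(2L, 2L, 8L), y1 = c(6L, 6L, 12L),
    z0 = c(2L, 2L, 2L), z1 = c(6L, 6L, 6L),
    stringsAsFactors = FALSE), grid_shape = c(18L, 16L, 10L))
}

# derive the analysis covariate table from a simulated subject table
sim_covariates <- function(subjects) prepare_covariates(subjects)
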