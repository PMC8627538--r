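# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive quantities from first principles with
# naive loops, so they stay independent of the package's vectorized paths.

# O(n^2) silhouette: naive per-point loops over the distance matrix
oracle_silhouette <- function(X, labels) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- Inf
    for (g in unique(labels[!own])) {
      b <- min(b, mean(D[i, labels == g]))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  s
}

# exhaustive GLCM: loop every voxel and every signed offset
oracle_glcm <- function(levels, n_bins, directions = radiohet:::DIRECTIONS_13) {
  d <- dim(levels)
  counts <- matrix(0, n_bins, n_bins)
  dirs <- rbind(directions, -directions)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (is.na(levels[x, y, z])) next
    for (k in seq_len(nrow(dirs))) {
      p <- c(x, y, z) + dirs[k, ]
      if (any(p < 1) || any(p > d)) next
      v <- levels[p[1], p[2], p[3]]
      if (is.na(v)) next
      counts[levels[x, y, z], v] <- counts[levels[x, y, z], v] + 1
    }
  }
  counts / sum(counts)
}

# build a discretized VOI directly from a level array (NA = outside mask)
toy_voi <- function(levels, n_bins = max(levels, na.rm = TRUE),
                    spacing = c(1, 1, 1)) {
  if (is.matrix(levels)) levels <- array(levels, dim = c(dim(levels), 1))
  if (is.null(dim(levels))) levels <- array(levels, dim = c(length(levels), 1, 1))
  mask <- array(as.integer(!is.na(levels)), dim = dim(levels))
  structure(list(levels = levels, mask = mask, spacing_mm = spacing,
                 raw_suv = as.numeric(levels[!is.na(levels)]),
                 n_bins = as.integer(n_bins)),
            class = "discretized_voi")
}

# digitized ball mask of the given voxel radius
ball_mask <- function(r, margin = 2) {
  d <- 2 * r + 1 + 2 * margin
  cen <- r + 1 + margin
  g <- expand.grid(x = 1:d, y = 1:d, z = 1:d)
  arr <- array(as.integer((g$x - cen)^2 + (g$y - cen)^2 + (g$z - cen)^2
                          <= r^2), dim = c(d, d, d))
  arr
}

# random small VOI (volume + mask) for property tests
random_voi <- function(seed, dim_max = 7) {
  set.seed(seed)
  d <- sample(3:dim_max, 3, replace = TRUE)
  vol <- array(runif(prod(d), 1, 10), dim = d)
  mask <- array(as.integer(runif(prod(d)) > 0.3), dim = d)
  if (sum(mask) < 4) mask[sample(prod(d), 4)] <- 1L
  list(volume = vol, mask = mask)
}

# small feature table: g patients x m lesions in 2-D space, coords given
toy_features <- function(coords, patient_ids, site = NULL, suv = NULL) {
  n <- nrow(coords)
  df <- data.frame(lesion_id = sprintf("L%02d", 1:n),
                   patient_id = patient_ids,
                   stringsAsFactors = FALSE)
  if (!is.null(site)) df$site_class <- site
  if (!is.null(suv)) df$suv_max <- suv
  cbind(df, as.data.frame(coords))
}
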