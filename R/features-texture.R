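# The 13 unique 3-D neighbour directions (each with its negation covers all
# 26 neighbours).
DIRECTIONS_13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

# index pairs (i -> i+dir) of in-mask voxels for one direction
shift_pairs <- function(levels, dir) {
  d <- dim(levels)
  rx <- seq_len(d[1]); ry <- seq_len(d[2]); rz <- seq_len(d[3])
  sx <- rx + dir[1]; sy <- ry + dir[2]; sz <- rz + dir[3]
  okx <- sx >= 1 & sx <= d[1]; oky <- sy >= 1 & sy <= d[2]
  okz <- sz >= 1 & sz <= d[3]
  a <- levels[rx[okx], ry[oky], rz[okz], drop = FALSE]
  b <- levels[sx[okx], sy[oky], sz[okz], drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  cbind(from = a[keep], to = b[keep])
}

#' Grey-level co-occurrence matrix
#'
#' Co-occurrences of grey levels at the given voxel distance are accumulated
#' over all 13 unique 3-D directions and both orientations into a single
#' symmetric matrix, normalized to sum 1 (the LIFEx-style aggregation: one
#' matrix, not 13 averaged feature sets).
#'
#' @param voi a `discretized_voi`.
#' @param distance neighbour distance in voxels (Chebyshev), default 1.
#' @param directions matrix of direction offsets (rows), default the 13
#'   unique 3-D neighbour directions.
#' @return `n_bins x n_bins` normalized symmetric matrix.
#' @export
glcm_matrix <- function(voi, distance = 1, directions = DIRECTIONS_13) {
  nb <- voi$n_bins
  counts <- matrix(0, nb, nb)
  for (k in seq_len(nrow(directions))) {
    pr <- shift_pairs(voi$levels, directions[k, ] * distance)
    if (nrow(pr) == 0) next
    tab <- table(factor(pr[, 1], levels = 1:nb),
                 factor(pr[, 2], levels = 1:nb))
    counts <- counts + tab + t(tab)  # both orientations -> symmetric
  }
  if (sum(counts) == 0)
    rh_stop("texture_undefined", "no valid voxel pair for GLCM")
  counts / sum(counts)
}

#' GLCM features
#'
#' Six descriptors of the normalized co-occurrence matrix `p(i,j)`:
#' Homogeneity `sum p/(1+|i-j|)`, Energy `sum p^2`, Contrast
#' `sum (i-j)^2 p`, Dissimilarity `sum |i-j| p`, Entropy `-sum p log2 p`
#' (with `0 log 0 := 0`), and Correlation
#' `sum (i-mu_i)(j-mu_j) p / (sigma_i sigma_j)` (0 if a marginal sd is 0).
#'
#' @param p normalized GLCM from [glcm_matrix()].
#' @return named numeric vector of 6 values.
#' @export
glcm_features <- function(p) {
  nb <- nrow(p)
  i <- row(p); j <- col(p)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  var_i <- sum((i - mu_i)^2 * p); var_j <- sum((j - mu_j)^2 * p)
  pe <- p[p > 0]
  corr <- if (var_i > 0 && var_j > 0)
    sum((i - mu_i) * (j - mu_j) * p) / sqrt(var_i * var_j) else 0
  c(GLCM_Homogeneity = sum(p / (1 + abs(i - j))),
    GLCM_Energy = sum(p^2),
    GLCM_Contrast = sum((i - j)^2 * p),
    GLCM_Correlation = corr,
    GLCM_Entropy = -sum(pe * log2(pe)),
    GLCM_Dissimilarity = sum(abs(i - j) * p))
}

# run-length matrix: rows = grey level, cols = run length, accumulated over
# the given directions; runs are maximal same-level straight segments of
# in-mask voxels.
glrlm_matrix <- function(voi, directions = DIRECTIONS_13) {
  lv <- voi$levels
  d <- dim(lv)
  nb <- voi$n_bins
  idx <- which(!is.na(lv), arr.ind = TRUE)
  res <- list()
  maxlen <- max(d)
  rl <- matrix(0, nb, maxlen)
  for (k in seq_len(nrow(directions))) {
    dir <- directions[k, ]
    # line key: project each voxel onto the line it belongs to
    t_par <- idx %*% dir  # monotone along the line
    perp <- idx - (as.numeric(t_par) %o% (dir / sum(dir^2)))
    key <- apply(round(perp, 6), 1, paste, collapse = ",")
    ord <- order(key, t_par)
    lev_ord <- lv[idx][ord]
    key_ord <- key[ord]
    t_ord <- t_par[ord]
    # breaks: new line, or a gap along the line (non-adjacent), or new level
    step <- sum(dir^2)  # t increases by |dir|^2 between adjacent voxels
    n <- length(lev_ord)
    if (n == 0) next
    new_run <- c(TRUE, key_ord[-1] != key_ord[-n] |
                   (t_ord[-1] - t_ord[-n]) != step |
                   lev_ord[-1] != lev_ord[-n])
    run_id <- cumsum(new_run)
    lens <- tabulate(run_id)
    run_lev <- lev_ord[new_run]
    for (u in seq_along(lens))
      rl[run_lev[u], lens[u]] <- rl[run_lev[u], lens[u]] + 1
  }
  rl
}

#' GLRLM (run-length) features
#'
#' Eleven standard run-length statistics of the matrix `r(i,l)` (grey level
#' `i`, run length `l`), accumulated over the 13 unique 3-D directions:
#' SRE, LRE, LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE, GLNU, RLNU and run
#' percentage `RP = n_runs / (n_voxels * n_directions)`.
#'
#' @param voi a `discretized_voi`.
#' @param directions direction set (rows); default all 13.
#' @return named numeric vector of 11 values.
#' @export
glrlm_features <- function(voi, directions = DIRECTIONS_13) {
  rl <- glrlm_matrix(voi, directions)
  nr <- sum(rl)
  if (nr == 0) rh_stop("texture_undefined", "no runs in VOI")
  i <- row(rl); l <- col(rl)
  nvox <- sum(voi$mask > 0)
  c(GLRLM_SRE = sum(rl / l^2) / nr,
    GLRLM_LRE = sum(rl * l^2) / nr,
    GLRLM_LGRE = sum(rl / i^2) / nr,
    GLRLM_HGRE = sum(rl * i^2) / nr,
    GLRLM_SRLGE = sum(rl / (i^2 * l^2)) / nr,
    GLRLM_SRHGE = sum(rl * i^2 / l^2) / nr,
    GLRLM_LRLGE = sum(rl * l^2 / i^2) / nr,
    GLRLM_LRHGE = sum(rl * i^2 * l^2) / nr,
    GLRLM_GLNU = sum(rowSums(rl)^2) / nr,
    GLRLM_RLNU = sum(colSums(rl)^2) / nr,
    GLRLM_RP = nr / (nvox * nrow(directions)))
}

#' NGLDM features
#'
#' Neighbourhood grey-level difference statistics on the masked
#' 26-neighbourhood: for each voxel with at least one in-mask neighbour the
#' absolute difference between its level and the mean level of its in-mask
#' neighbours is accumulated per grey level (`s_i`), with `p_i` the level's
#' share of contributing voxels. Coarseness `1 / sum(p_i s_i)` (capped at
#' 1e6 when the denominator vanishes, e.g. on a constant VOI), Contrast
#' `[sum_{i,j} p_i p_j (i-j)^2 / (Ng(Ng-1))] * [sum s_i / Nv]` (0 when a
#' single level is present), Busyness `sum(p_i s_i) / sum_{i!=j} |i p_i -
#' j p_j|` with the 0-denominator convention Busyness := 0.
#'
#' @param voi a `discretized_voi`.
#' @return named numeric vector of 3 values.
#' @export
ngldm_features <- function(voi) {
  lv <- voi$levels
  nb <- voi$n_bins
  d <- dim(lv)
  nsum <- array(0, dim = d)   # sum of neighbour levels
  ncnt <- array(0L, dim = d)  # number of in-mask neighbours
  for (k in seq_len(nrow(DIRECTIONS_13))) {
    for (sgn in c(1, -1)) {
      dir <- DIRECTIONS_13[k, ] * sgn
      sh <- shift_level_sum(lv, dir)
      nsum <- nsum + sh$sum
      ncnt <- ncnt + sh$cnt
    }
  }
  ok <- !is.na(lv) & ncnt > 0
  if (!any(ok))
    rh_stop("texture_undefined", "mask contains only isolated voxels")
  lev <- lv[ok]
  diffs <- abs(lev - nsum[ok] / ncnt[ok])
  nv <- sum(ok)
  n_i <- tabulate(lev, nbins = nb)
  s_i <- vapply(1:nb, function(g) sum(diffs[lev == g]), numeric(1))
  p_i <- n_i / nv
  present <- which(n_i > 0)
  ng <- length(present)
  den_coarse <- sum(p_i * s_i)
  coarseness <- if (den_coarse > 0) min(1 / den_coarse, 1e6) else 1e6
  contrast <- if (ng > 1) {
    pij <- outer(p_i[present], p_i[present])
    iij <- outer(present, present, function(a, b) (a - b)^2)
    (sum(pij * iij) / (ng * (ng - 1))) * (sum(s_i) / nv)
  } else 0
  busy_den <- {
    ip <- present * p_i[present]
    sum(abs(outer(ip, ip, `-`)))
  }
  busyness <- if (busy_den > 0) den_coarse / busy_den else 0
  c(NGLDM_Coarseness = coarseness, NGLDM_Contrast = contrast,
    NGLDM_Busyness = busyness)
}

# neighbour level sums/counts for one offset (NA-aware)
shift_level_sum <- function(lv, dir) {
  d <- dim(lv)
  s <- array(0, dim = d); cnt <- array(0L, dim = d)
  rx <- seq_len(d[1]) + dir[1]; ry <- seq_len(d[2]) + dir[2]
  rz <- seq_len(d[3]) + dir[3]
  okx <- rx >= 1 & rx <= d[1]; oky <- ry >= 1 & ry <= d[2]
  okz <- rz >= 1 & rz <= d[3]
  src <- lv[rx[okx], ry[oky], rz[okz], drop = FALSE]
  val <- ifelse(is.na(src), 0, src)
  has <- !is.na(src)
  s[okx, oky, okz] <- val
  cnt[okx, oky, okz] <- has
  list(sum = s, cnt = cnt)
}

# size-zone matrix: zones are 26-connected components of constant grey level
glzlm_matrix <- function(voi) {
  lv <- voi$levels
  nb <- voi$n_bins
  d <- dim(lv)
  nvox <- sum(!is.na(lv))
  offs <- rbind(DIRECTIONS_13, -DIRECTIONS_13)
  visited <- array(FALSE, dim = d)
  zones <- list()
  in_idx <- which(!is.na(lv))
  coord <- arrayInd(in_idx, d)
  lin <- function(cc) (cc[, 3] - 1L) * d[1] * d[2] + (cc[, 2] - 1L) * d[1] + cc[, 1]
  zl <- integer(0); zs <- integer(0)
  for (p in seq_along(in_idx)) {
    start <- in_idx[p]
    if (visited[start]) next
    g <- lv[start]
    visited[start] <- TRUE
    queue <- matrix(coord[p, ], ncol = 3)
    size <- 0L
    while (nrow(queue) > 0) {
      size <- size + nrow(queue)
      nxt <- NULL
      for (k in seq_len(nrow(offs))) {
        cand <- sweep(queue, 2, offs[k, ], `+`)
        ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
          cand[, 2] >= 1 & cand[, 2] <= d[2] &
          cand[, 3] >= 1 & cand[, 3] <= d[3]
        cand <- cand[ok, , drop = FALSE]
        if (nrow(cand) == 0) next
        li <- lin(cand)
        keep <- !visited[li] & !is.na(lv[li]) & lv[li] == g
        if (any(keep)) {
          visited[li[keep]] <- TRUE
          nxt <- rbind(nxt, cand[keep, , drop = FALSE])
        }
      }
      queue <- if (is.null(nxt)) matrix(numeric(0), ncol = 3) else unique(nxt)
    }
    zl <- c(zl, g); zs <- c(zs, size)
  }
  maxz <- max(zs)
  zm <- matrix(0, nb, maxz)
  for (u in seq_along(zl)) zm[zl[u], zs[u]] <- zm[zl[u], zs[u]] + 1
  list(matrix = zm, n_voxels = nvox)
}

#' GLZLM (size-zone) features
#'
#' Zones are 26-connected components of constant grey level. Eleven standard
#' size-zone statistics plus zone percentage `ZP = n_zones / n_voxels`.
#'
#' @param voi a `discretized_voi`.
#' @return named numeric vector of 11 values.
#' @export
glzlm_features <- function(voi) {
  z <- glzlm_matrix(voi)
  zm <- z$matrix
  nz <- sum(zm)
  i <- row(zm); s <- col(zm)
  c(GLZLM_SZE = sum(zm / s^2) / nz,
    GLZLM_LZE = sum(zm * s^2) / nz,
    GLZLM_LGZE = sum(zm / i^2) / nz,
    GLZLM_HGZE = sum(zm * i^2) / nz,
    GLZLM_SZLGE = sum(zm / (i^2 * s^2)) / nz,
    GLZLM_SZHGE = sum(zm * i^2 / s^2) / nz,
    GLZLM_LZLGE = sum(zm * s^2 / i^2) / nz,
    GLZLM_LZHGE = sum(zm * i^2 * s^2) / nz,
    GLZLM_GLNU = sum(rowSums(zm)^2) / nz,
    GLZLM_ZLNU = sum(colSums(zm)^2) / nz,
    GLZLM_ZP = nz / z$n_voxels)
}
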