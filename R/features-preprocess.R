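#' Extraction configuration
#'
#' Settings for the radiomic extraction pipeline: isotropic resampling
#' spacing, grey-level discretization, and the ordered 42-feature roster.
#'
#' @param target_spacing_mm isotropic voxel size for resampling (mm);
#'   2 mm is typical PET radiomics practice.
#' @param n_bins number of grey levels for discretization (>= 2).
#' @param discretization_mode `"RELATIVE_MINMAX"` (bins between the VOI's own
#'   min and max) or `"ABSOLUTE_BOUNDS"` (fixed SUV bounds).
#' @param absolute_bounds `c(low, high)` SUV, used only in absolute mode.
#' @param feature_roster ordered feature names; the default 42-name roster is
#'   Shape (2) + first-order (9) + GLCM (6) + GLRLM (11) + NGLDM (3) +
#'   GLZLM (11).
#' @return object of class `extraction_config`.
#' @export
extraction_config <- function(target_spacing_mm = 2,
                              n_bins = 64,
                              discretization_mode = c("RELATIVE_MINMAX",
                                                      "ABSOLUTE_BOUNDS"),
                              absolute_bounds = c(0, 25),
                              feature_roster = default_feature_roster()) {
  discretization_mode <- match.arg(discretization_mode)
  if (!is.numeric(n_bins) || n_bins < 2)
    rh_stop("config_error", "invalid 'n_bins': must be >= 2")
  if (!is.numeric(target_spacing_mm) || target_spacing_mm <= 0)
    rh_stop("config_error", "invalid 'target_spacing_mm': must be > 0")
  if (discretization_mode == "ABSOLUTE_BOUNDS" &&
      !(absolute_bounds[1] < absolute_bounds[2]))
    rh_stop("config_error", "invalid 'absolute_bounds': low must be < high")
  structure(list(target_spacing_mm = target_spacing_mm,
                 n_bins = as.integer(n_bins),
                 discretization_mode = discretization_mode,
                 absolute_bounds = absolute_bounds,
                 feature_roster = feature_roster),
            class = "extraction_config")
}

#' Default 42-feature roster
#'
#' Shape (2) + first-order (9) + GLCM (6) + GLRLM (11) + NGLDM (3) +
#' GLZLM (11) = 42, following the LIFEx family structure. The roster is
#' configurable so users can reorder or substitute names.
#'
#' @return character vector of length 42.
#' @export
default_feature_roster <- function() {
  c("Volume_mL", "Sphericity",
    "SUV_min", "SUV_mean", "SUV_std", "SUV_max", "Skewness", "Kurtosis",
    "Energy", "Entropy", "Uniformity",
    "GLCM_Homogeneity", "GLCM_Energy", "GLCM_Contrast", "GLCM_Correlation",
    "GLCM_Entropy", "GLCM_Dissimilarity",
    "GLRLM_SRE", "GLRLM_LRE", "GLRLM_LGRE", "GLRLM_HGRE", "GLRLM_SRLGE",
    "GLRLM_SRHGE", "GLRLM_LRLGE", "GLRLM_LRHGE", "GLRLM_GLNU", "GLRLM_RLNU",
    "GLRLM_RP",
    "NGLDM_Coarseness", "NGLDM_Contrast", "NGLDM_Busyness",
    "GLZLM_SZE", "GLZLM_LZE", "GLZLM_LGZE", "GLZLM_HGZE", "GLZLM_SZLGE",
    "GLZLM_SZHGE", "GLZLM_LZLGE", "GLZLM_LZHGE", "GLZLM_GLNU", "GLZLM_ZLNU",
    "GLZLM_ZP")
}

#' Resample a volume and mask to an isotropic grid
#'
#' Volume by trilinear interpolation, mask by nearest neighbour, both onto a
#' grid of `target_spacing_mm` isotropic voxels covering the input extent.
#' An input already isotropic at the target spacing is returned unchanged.
#'
#' @param volume 3-D numeric array.
#' @param mask 3-D 0/1 array on the same grid.
#' @param spacing_mm input voxel spacing (length 3 or scalar).
#' @param config an [extraction_config()].
#' @return list with `volume`, `mask`, `spacing_mm`.
#' @export
resample_voi <- function(volume, mask, spacing_mm, config = extraction_config()) {
  spacing_mm <- rep_len(spacing_mm, 3L)
  if (!identical(dim(volume), dim(mask)))
    rh_stop("input_error", "volume and mask must share a grid")
  if (sum(mask) == 0) rh_stop("degenerate_voi", "mask is empty")
  t <- config$target_spacing_mm
  if (all(abs(spacing_mm - t) < 1e-9))
    return(list(volume = volume, mask = mask, spacing_mm = rep(t, 3)))
  d <- dim(volume)
  extent <- d * spacing_mm
  nd <- pmax(as.integer(round(extent / t)), 1L)
  # target voxel centres in input voxel (continuous index) coordinates
  coords <- lapply(1:3, function(k) {
    cen <- (seq_len(nd[k]) - 0.5) * t          # mm, from grid origin
    cen / spacing_mm[k] + 0.5                  # continuous input index
  })
  vol2 <- trilinear_sample(volume, coords[[1]], coords[[2]], coords[[3]])
  msk2 <- nearest_sample(mask, coords[[1]], coords[[2]], coords[[3]])
  if (sum(msk2) == 0)
    rh_stop("degenerate_voi", "mask empty after resampling to %g mm", t)
  list(volume = vol2, mask = msk2, spacing_mm = rep(t, 3))
}

# trilinear interpolation of arr at the grid outer(xi, yi, zi) of continuous
# 1-based indices; out-of-range coordinates are clamped to the edge.
trilinear_sample <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  clamp <- function(v, n) pmin(pmax(v, 1), n)
  xi <- clamp(xi, d[1]); yi <- clamp(yi, d[2]); zi <- clamp(zi, d[3])
  x0 <- pmin(floor(xi), d[1] - 1L); x0[d[1] == 1] <- 1
  y0 <- pmin(floor(yi), d[2] - 1L); y0[d[2] == 1] <- 1
  z0 <- pmin(floor(zi), d[3] - 1L); z0[d[3] == 1] <- 1
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  nx <- length(xi); ny <- length(yi); nz <- length(zi)
  out <- array(0, dim = c(nx, ny, nz))
  X0 <- rep(x0, times = ny * nz); FX <- rep(fx, times = ny * nz)
  Y0 <- rep(rep(y0, each = nx), times = nz)
  FY <- rep(rep(fy, each = nx), times = nz)
  Z0 <- rep(z0, each = nx * ny); FZ <- rep(fz, each = nx * ny)
  x1 <- pmin(X0 + 1, d[1]); y1 <- pmin(Y0 + 1, d[2]); z1 <- pmin(Z0 + 1, d[3])
  at <- function(ix, iy, iz) arr[cbind(ix, iy, iz)]
  v <- at(X0, Y0, Z0) * (1 - FX) * (1 - FY) * (1 - FZ) +
    at(x1, Y0, Z0) * FX * (1 - FY) * (1 - FZ) +
    at(X0, y1, Z0) * (1 - FX) * FY * (1 - FZ) +
    at(x1, y1, Z0) * FX * FY * (1 - FZ) +
    at(X0, Y0, z1) * (1 - FX) * (1 - FY) * FZ +
    at(x1, Y0, z1) * FX * (1 - FY) * FZ +
    at(X0, y1, z1) * (1 - FX) * FY * FZ +
    at(x1, y1, z1) * FX * FY * FZ
  array(v, dim = c(nx, ny, nz))
}

nearest_sample <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  rx <- pmin(pmax(round(xi), 1), d[1])
  ry <- pmin(pmax(round(yi), 1), d[2])
  rz <- pmin(pmax(round(zi), 1), d[3])
  array(arr[cbind(rep(rx, times = length(ry) * length(rz)),
                  rep(rep(ry, each = length(rx)), times = length(rz)),
                  rep(rz, each = length(rx) * length(ry)))],
        dim = c(length(rx), length(ry), length(rz)))
}

#' Discretize a VOI's intensities to grey levels
#'
#' Relative min-max mode assigns
#' `level = 1 + floor(n_bins * (x - min) / (max - min))`, clamped to
#' `n_bins` at the maximum; a constant VOI maps wholly to level 1. Absolute
#' mode uses the configured fixed bounds, clamping values outside.
#'
#' @param volume,mask 3-D arrays on a shared grid.
#' @param spacing_mm voxel spacing of the (already resampled) grid.
#' @param config an [extraction_config()].
#' @return object of class `discretized_voi`: list with `levels` (integer
#'   array, NA outside mask), `mask`, `spacing_mm`, `raw_suv` (in-mask
#'   intensities), `n_bins`.
#' @export
discretize_voi <- function(volume, mask, spacing_mm,
                           config = extraction_config()) {
  if (sum(mask) == 0) rh_stop("degenerate_voi", "mask is empty")
  inm <- mask > 0
  x <- volume[inm]
  nb <- config$n_bins
  if (config$discretization_mode == "RELATIVE_MINMAX") {
    lo <- min(x); hi <- max(x)
  } else {
    lo <- config$absolute_bounds[1]; hi <- config$absolute_bounds[2]
    x <- pmin(pmax(x, lo), hi)
  }
  if (hi > lo) {
    lev <- 1L + as.integer(floor(nb * (x - lo) / (hi - lo)))
    lev[lev > nb] <- nb
  } else {
    lev <- rep(1L, length(x))
  }
  levels <- array(NA_integer_, dim = dim(volume))
  levels[inm] <- lev
  structure(list(levels = levels, mask = mask,
                 spacing_mm = rep_len(spacing_mm, 3L),
                 raw_suv = volume[inm], n_bins = nb),
            class = "discretized_voi")
}
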