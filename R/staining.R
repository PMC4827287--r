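# Alcian-blue quantification: optical-density transform, automatic stain
# vector estimation (SVD / extreme angular percentiles), per-pixel least
# squares colour deconvolution, whole-image Otsu thresholding and
# ROI-restricted coverage / mean-intensity metrics.

#' RGB image to optical density
#'
#' Beer-Lambert preprocessing: stains absorb multiplicatively in intensity
#' and therefore add linearly in optical density,
#' \eqn{OD = -\log_{10}((I + 1) / I_0)}. The +1 offset keeps saturated black
#' pixels finite; with the default \eqn{I_0 = 256} a pure white pixel
#' (255, 255, 255) maps to OD 0 exactly.
#'
#' @param image Numeric array `H x W x 3` with values in `[0, 255]`.
#' @param I0 Incident intensity (default 256).
#' @return Array `H x W x 3` of optical densities (>= 0).
#' @export
to_od <- function(image, I0 = 256) {
  assert_scalar_pos(I0, "I0")
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop_quant("image must be an H x W x 3 array", class = "invalid_image")
  -log10((image + 1) / I0)
}

od_to_rgb <- function(od, I0 = 256) I0 * 10^(-od) - 1

#' Automatic stain-vector estimation by SVD
#'
#' Estimates the two dominant stain vectors of an OD image: background
#' pixels (OD norm below `beta`) are discarded, the remaining pixel ODs are
#' projected onto the plane of the two leading singular vectors, and the
#' `alpha`-th and (100 - `alpha`)-th percentiles of the angular distribution
#' in that plane are taken as the extreme (pure-stain) directions. Vectors
#' are unit-normalised with non-negative components and returned bluest
#' first, where "bluest" means the stain that appears blue, i.e. the vector
#' absorbing most in the red channel relative to the blue channel.
#'
#' @param od OD array from [to_od()].
#' @param alpha Angular percentile (default 1).
#' @param beta OD-norm threshold below which pixels count as background
#'   (default 0.15).
#' @param names Stain labels for the (bluest, other) vectors.
#' @return A `stain_basis`: 3 x 2 matrix of unit column vectors with stain
#'   names as column names.
#' @export
estimate_stain_basis <- function(od, alpha = 1, beta = 0.15,
                                 names = c("alcian_blue", "counterstain")) {
  M <- matrix(od, ncol = 3L)
  keep <- sqrt(rowSums(M^2)) > beta
  if (sum(keep) < 100L)
    stop_quant("insufficient stained tissue", class = "insufficient_tissue")
  M <- M[keep, , drop = FALSE]
  ev <- eigen(crossprod(M), symmetric = TRUE)
  V <- ev$vectors[, 1:2, drop = FALSE]
  if (sum(V[, 1]) < 0) V[, 1] <- -V[, 1]
  j <- which.max(abs(V[, 2]))
  if (V[j, 2] < 0) V[, 2] <- -V[, 2]
  proj <- M %*% V
  phi <- atan2(proj[, 2], proj[, 1])
  q <- stats::quantile(phi, c(alpha / 100, 1 - alpha / 100), names = FALSE)
  if ((q[2] - q[1]) < pi / 180)
    stop_quant("degenerate basis", class = "degenerate_basis")
  mk <- function(a) {
    v <- as.numeric(V %*% c(cos(a), sin(a)))
    if (sum(v) < 0) v <- -v
    v <- pmax(v, 0)
    v / sqrt(sum(v^2))
  }
  v1 <- mk(q[1])
  v2 <- mk(q[2])
  blueness <- function(v) v[1] - v[3]  # red OD minus blue OD
  S <- if (blueness(v1) >= blueness(v2)) cbind(v1, v2) else cbind(v2, v1)
  colnames(S) <- names
  rownames(S) <- c("red", "green", "blue")
  structure(S, class = "stain_basis")
}

#' Colour deconvolution by per-pixel least squares
#'
#' Solves \eqn{od = S c} for each pixel in the least-squares sense, where
#' `S` holds the stain vectors as columns. Negative coefficients are clipped
#' to zero *after* the reconstruction residual is computed, so the residual
#' reflects the true fit quality.
#'
#' @param od OD array from [to_od()].
#' @param basis A `stain_basis` (or plain 3 x k matrix with column names).
#' @return A `stain_maps` list: `concentrations` (`H x W x k` array, stain
#'   names in the third dimension), `residual` (`H x W` L2 reconstruction
#'   residual), `basis`.
#' @export
deconvolve <- function(od, basis) {
  S <- unclass(basis)
  if (!is.matrix(S) || nrow(S) != 3L)
    stop_quant("basis must be a 3 x k matrix", class = "invalid_basis")
  sv <- svd(S, nu = 0, nv = 0)$d
  if (min(sv) < 1e-8 * max(sv))
    stop_quant("singular stain matrix", class = "singular_basis")
  dm <- dim(od)
  M <- matrix(od, ncol = 3L)
  C <- M %*% S %*% solve(crossprod(S))
  res <- sqrt(rowSums((M - C %*% t(S))^2))
  C[C < 0] <- 0
  k <- ncol(S)
  conc <- array(C, dim = c(dm[1], dm[2], k),
                dimnames = list(NULL, NULL, colnames(S)))
  structure(list(concentrations = conc,
                 residual = matrix(res, dm[1], dm[2]),
                 basis = basis),
            class = "stain_maps")
}

#' Otsu threshold on a concentration histogram
#'
#' Builds an `n_bins` histogram over `[0, max(values)]` and returns the bin
#' edge maximising the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2}; ties (within floating-point
#' tolerance) are broken by the lowest qualifying threshold. Per the
#' whole-slide rule, callers should pass *all* image pixels, not the
#' ROI-restricted subset.
#'
#' @param values Numeric vector (or array) of stain concentrations (>= 0).
#' @param n_bins Histogram bins (default 256).
#' @return The threshold (a bin edge, same units as `values`).
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2L)
    stop_quant("no separation", class = "no_separation")
  vmax <- max(v)
  if (vmax <= 0)
    stop_quant("no separation", class = "no_separation")
  bin <- pmin(pmax(ceiling(v / vmax * n_bins), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  centers <- (seq_len(n_bins) - 0.5) * vmax / n_bins
  n <- length(v)
  w0 <- cumsum(counts) / n
  mu_cum <- cumsum(counts * centers) / n
  mu_tot <- mu_cum[n_bins]
  k <- seq_len(n_bins - 1L)
  w0k <- w0[k]
  valid <- w0k > 0 & w0k < 1
  sigma_b <- rep(-Inf, n_bins - 1L)
  sigma_b[valid] <- (mu_tot * w0k[valid] - mu_cum[k][valid])^2 /
    (w0k[valid] * (1 - w0k[valid]))
  best <- which(sigma_b >= max(sigma_b) * (1 - 1e-12))[1L]
  best * vmax / n_bins
}

#' Load a region-of-interest mask
#'
#' Accepts either a polygon JSON file
#' (`{"polygons": [[[x, y], ...], ...]}`, pixel coordinates, 0-based,
#' x = column) rasterised with the even-odd rule at pixel centres
#' (`(col + 0.5, row + 0.5)` in 0-based coordinates), or a mask image
#' (PNG/TIFF) whose non-zero pixels are inside.
#'
#' @param path Path to the polygon JSON or mask image.
#' @param image_shape Integer vector `c(H, W)` of the target image.
#' @return Logical `H x W` matrix with at least one `TRUE` pixel.
#' @export
load_roi <- function(path, image_shape) {
  stopifnot(length(image_shape) >= 2L)
  h <- as.integer(image_shape[1])
  w <- as.integer(image_shape[2])
  ext <- tolower(tools::file_ext(path))
  mask <- if (ext == "json") {
    spec <- jsonlite::read_json(path, simplifyVector = TRUE)
    polys <- normalize_polygons(spec$polygons)
    rasterize_polygons(polys, h, w)
  } else {
    img <- read_image(path)
    m <- if (length(dim(img)) == 3L) apply(img, c(1, 2), max) else img
    if (!all(dim(m)[1:2] == c(h, w)))
      stop_quant("ROI mask shape %dx%d does not match image %dx%d",
                 dim(m)[1], dim(m)[2], h, w, class = "invalid_roi")
    m > 0
  }
  if (!any(mask))
    stop_quant("empty ROI", class = "empty_roi")
  mask
}

# JSON simplification can return the polygon set as a list of matrices, a
# single matrix, or an n_poly x n_pts x 2 array; normalize to a list of
# (x, y) vertex matrices.
normalize_polygons <- function(polys) {
  if (is.null(polys) || length(polys) == 0L)
    stop_quant("ROI file has no polygons", class = "invalid_roi")
  as_matrix <- function(p) {
    if (is.array(p) && length(dim(p)) == 3L) p <- p[1, , , drop = TRUE]
    if (is.matrix(p)) return(p)
    do.call(rbind, lapply(p, as.numeric))
  }
  if (is.array(polys) && length(dim(polys)) == 3L)
    return(lapply(seq_len(dim(polys)[1]), function(i) polys[i, , ]))
  if (is.matrix(polys)) return(list(polys))
  lapply(polys, as_matrix)
}

# Even-odd rasterisation of polygons at pixel centres. Polygons are
# matrices of (x, y) vertices in 0-based pixel coordinates; pixel (r, c)
# (1-based in R) has centre (c - 0.5, r - 0.5).
rasterize_polygons <- function(polys, h, w) {
  mask <- matrix(FALSE, h, w)
  xc <- seq_len(w) - 0.5
  yc <- seq_len(h) - 0.5
  for (P in polys) {
    if (!is.matrix(P) || ncol(P) != 2L || nrow(P) < 3L)
      stop_quant("polygon needs at least 3 vertices", class = "invalid_roi")
    nv <- nrow(P)
    for (e in seq_len(nv)) {
      x1 <- P[e, 1]; y1 <- P[e, 2]
      x2 <- P[e %% nv + 1L, 1]; y2 <- P[e %% nv + 1L, 2]
      if (y1 == y2) next
      rows <- which((yc >= min(y1, y2)) & (yc < max(y1, y2)))
      if (length(rows) == 0L) next
      xint <- x1 + (yc[rows] - y1) * (x2 - x1) / (y2 - y1)
      for (i in seq_along(rows)) {
        cols <- xc < xint[i]
        mask[rows[i], cols] <- !mask[rows[i], cols]
      }
    }
  }
  mask
}

#' Coverage and mean staining intensity within an ROI
#'
#' Positive pixels are ROI pixels whose target-stain concentration exceeds
#' the threshold. Coverage is the percentage of ROI pixels that are
#' positive; mean intensity averages the target concentration over the
#' positive pixels only (the all-ROI variant is available via
#' `positive_only = FALSE`). The threshold is typically computed on the
#' whole image with [otsu_threshold()] and applied here within the ROI.
#'
#' @param maps A `stain_maps` from [deconvolve()].
#' @param target Stain name to quantify (default `"alcian_blue"`).
#' @param roi Logical mask from [load_roi()] (same H, W as the image).
#' @param threshold Concentration threshold (e.g. the Otsu value).
#' @param positive_only Average intensity over positive pixels (default)
#'   or over the whole ROI.
#' @return A `stain_metrics` list: `coverage_pct`, `mean_intensity`,
#'   `threshold`, `n_roi`, `n_positive`, `target`.
#' @export
quantify_stain <- function(maps, target = "alcian_blue", roi, threshold,
                           positive_only = TRUE) {
  stopifnot(inherits(maps, "stain_maps"))
  stains <- dimnames(maps$concentrations)[[3]]
  if (!target %in% stains)
    stop_quant("stain '%s' not present in maps (%s)", target,
               paste(stains, collapse = ", "), class = "invalid_argument")
  conc <- maps$concentrations[, , target]
  if (!is.logical(roi) || !all(dim(roi) == dim(conc)))
    stop_quant("ROI mask does not match image shape", class = "invalid_roi")
  n_roi <- sum(roi)
  if (n_roi == 0L)
    stop_quant("empty ROI", class = "empty_roi")
  pos <- roi & (conc > threshold)
  n_pos <- sum(pos)
  mean_int <- if (positive_only) {
    if (n_pos > 0L) mean(conc[pos]) else 0
  } else {
    mean(conc[roi])
  }
  structure(list(coverage_pct = 100 * n_pos / n_roi,
                 mean_intensity = mean_int,
                 threshold = threshold,
                 n_roi = n_roi, n_positive = n_pos, target = target),
            class = "stain_metrics")
}

#' @export
print.stain_metrics <- function(x, ...) {
  cat(sprintf("<stain_metrics> %s: coverage %.2f%% (%d/%d px), mean intensity %.4g (threshold %.4g)\n",
              x$target, x$coverage_pct, x$n_positive, x$n_roi,
              x$mean_intensity, x$threshold))
  invisible(x)
}
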