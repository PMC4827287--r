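# Seeded synthetic-data generators. Every generator is deterministic given
# its seed and returns its ground truth alongside its output, so pipeline
# recovery can be measured against a known answer.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L)
    stop_quant("seed must be a single integer", class = "invalid_argument")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a cyclic compression trace with known ground truth
#'
#' Forward model of the compression test: a constant-speed approach down to
#' the tare-load contact, then `n_cycles` sinusoidal strain cycles. Strain
#' is referenced to the tare-contact gap -- the same frame the measurement
#' protocol defines -- and the cyclic force is
#' \eqn{F(\epsilon) = F_{tare} + A_{face} A (e^{B\epsilon} - 1)}, so the
#' generator truth and the pipeline estimate share one frame and the
#' noiseless round trip is exact. Gaussian force noise with SD
#' `noise_sd * max(F)` is added to the cyclic phase; the quasi-static
#' approach gets an absolute load-cell noise floor instead
#' (`approach_noise_sd_N`, default 0.002 N, 0 in the ideal
#' `noise_sd = 0` case), since a tare threshold of 0.02 N is only
#' measurable when approach noise is well below it.
#'
#' @param A_MPa,B True coefficients of the exponential stress-strain law.
#' @param thickness_um True (tare-referenced) thickness in micrometres.
#' @param diameter_mm Construct diameter in millimetres.
#' @param frequency Loading frequency in Hz (default 1).
#' @param n_cycles Number of strain cycles (default 10).
#' @param peak_strain Peak engineering strain (default 0.20).
#' @param noise_sd Cyclic force noise SD as a fraction of the peak force.
#' @param seed Integer seed; identical seeds give bit-identical traces.
#' @param sample_rate Sampling rate in Hz (default 100).
#' @param tare_N Tare threshold in newtons.
#' @param approach_speed Platen approach speed in micrometres/second.
#' @param start_clearance_um Initial platen clearance above the specimen.
#' @param approach_noise_sd_N Absolute force noise SD (N) for the approach
#'   phase; `NULL` picks 0.002 N when `noise_sd > 0`, else 0.
#' @return A [cyclic_trace()] whose `truth` field records the generating
#'   parameters.
#' @export
gen_mech_trace <- function(A_MPa = 0.01, B = 20, thickness_um = 1180,
                           diameter_mm = 5, frequency = 1, n_cycles = 10L,
                           peak_strain = 0.2, noise_sd = 0, seed = NULL,
                           sample_rate = 100, tare_N = 0.02,
                           approach_speed = 50, start_clearance_um = 200,
                           approach_noise_sd_N = NULL) {
  assert_scalar_pos(A_MPa, "A_MPa")
  assert_scalar_pos(B, "B")
  assert_scalar_pos(peak_strain, "peak_strain")
  if (peak_strain > 0.25)
    stop_quant("peak_strain must be <= 0.25", class = "invalid_argument")
  area <- face_area_mm2(diameter_mm)
  if (tare_N >= area * A_MPa)
    stop_quant("tare load exceeds the construct's force scale; law cannot reach zero",
               class = "invalid_argument")
  if (is.null(approach_noise_sd_N))
    approach_noise_sd_N <- if (noise_sd > 0) 0.002 else 0
  n_app <- round(start_clearance_um / approach_speed * sample_rate)
  clearance <- n_app * approach_speed / sample_rate
  t_app <- (0:n_app) / sample_rate
  disp_app <- approach_speed * t_app
  eps_app <- (disp_app - clearance) / thickness_um  # <= 0 until contact
  f_app <- pmax(0, tare_N + area * A_MPa * expm1(B * eps_app))
  n_cyc <- round(n_cycles / frequency * sample_rate)
  t_cyc <- (1:n_cyc) / sample_rate
  eps_cyc <- peak_strain * (1 - cos(2 * pi * frequency * t_cyc)) / 2
  disp_cyc <- clearance + eps_cyc * thickness_um
  f_cyc <- tare_N + area * A_MPa * expm1(B * eps_cyc)
  with_seed(seed, {
    if (approach_noise_sd_N > 0)
      f_app <- f_app + stats::rnorm(length(f_app), 0, approach_noise_sd_N)
    if (noise_sd > 0)
      f_cyc <- f_cyc + stats::rnorm(n_cyc, 0, noise_sd * max(abs(f_cyc)))
  })
  cyclic_trace(time_s = c(t_app, t_app[n_app + 1L] + t_cyc),
               force_N = c(f_app, f_cyc),
               displacement_um = c(disp_app, disp_cyc),
               sample_rate = sample_rate,
               specimen_id = sprintf("sim_A%g_B%g", A_MPa, B),
               start_gap_um = thickness_um + clearance,
               truth = list(A_MPa = A_MPa, B = B, thickness_um = thickness_um,
                            diameter_mm = diameter_mm, peak_strain = peak_strain,
                            frequency = frequency, n_cycles = n_cycles,
                            noise_sd = noise_sd, tare_N = tare_N))
}

default_stain_vectors <- function() {
  v1 <- c(0.80, 0.55, 0.22)  # appears blue: absorbs red, transmits blue
  v2 <- c(0.19, 0.65, 0.73)  # counterstain: absorbs green/blue
  S <- cbind(alcian_blue = v1 / sqrt(sum(v1^2)),
             counterstain = v2 / sqrt(sum(v2^2)))
  rownames(S) <- c("red", "green", "blue")
  S
}

#' Generate a stained-section image with known ground truth
#'
#' Beer-Lambert forward model of a two-stain histology tile. A
#' notched-ellipse silhouette plays the tissue section (and the ROI); the
#' target stain is painted on a spatially coherent subset of ROI pixels
#' occupying exactly `coverage_pct` percent of the ROI, the counterstain is
#' spread over the whole section, optical densities are composed as
#' `S %*% c` (optionally with Gaussian OD noise) and exponentiated back to
#' RGB. Because the image is built in OD space, the deconvolution model is
#' exactly the data-generating model in the noiseless limit. Pixel values
#' are continuous in `[0, 255]`; quantise (e.g. via [write_image()]) to
#' emulate an 8-bit camera.
#'
#' @param width,height Image size in pixels.
#' @param coverage_pct True target-stain coverage, percent of ROI pixels.
#' @param intensity_mean,intensity_sd Normal parameters of the target-stain
#'   concentration in positive pixels (OD units).
#' @param intensity_floor Lower truncation of positive concentrations.
#' @param counterstain_max Counterstain concentration is uniform on
#'   `[0, counterstain_max]` over the section.
#' @param od_noise_sd Gaussian noise SD added per channel in OD space.
#' @param stain_vectors 3 x 2 matrix of unit stain OD vectors (columns);
#'   defaults to a blue target stain plus counterstain.
#' @param seed Integer seed.
#' @param I0 Incident intensity for the OD transform.
#' @return List with `image` (H x W x 3, values in `[0, 255]`), `roi`
#'   (logical mask) and `truth` (coverage, mean intensity over positive
#'   pixels, stain vectors, per-pixel concentration array).
#' @export
gen_histology <- function(width = 256L, height = 256L, coverage_pct = 40,
                          intensity_mean = 0.7, intensity_sd = 0.12,
                          intensity_floor = 0.2, counterstain_max = 0.3,
                          od_noise_sd = 0, stain_vectors = NULL, seed = NULL,
                          I0 = 256) {
  if (coverage_pct < 0 || coverage_pct > 100)
    stop_quant("coverage_pct must be in [0, 100]", class = "invalid_argument")
  S <- stain_vectors %||% default_stain_vectors()
  h <- as.integer(height)
  w <- as.integer(width)
  # notched-ellipse section silhouette (deterministic)
  yc <- matrix(seq_len(h) - 0.5, h, w)
  xc <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  cx <- w / 2
  cy <- h / 2
  rx <- 0.42 * w
  ry <- 0.35 * h
  roi <- ((xc - cx) / rx)^2 + ((yc - cy) / ry)^2 <= 1
  roi <- roi & ((xc - cx)^2 + (yc - (cy - ry))^2 > (0.10 * h)^2)
  roi <- roi & ((xc - (cx + rx))^2 + (yc - cy)^2 > (0.08 * w)^2)
  roi_idx <- which(roi)
  n_roi <- length(roi_idx)
  k <- as.integer(round(coverage_pct / 100 * n_roi))
  res <- with_seed(seed, {
    # coherent positive region: top-k pixels of a random smooth blob field
    nb <- 40L
    bx <- stats::runif(nb, 0, w)
    by <- stats::runif(nb, 0, h)
    bs <- stats::runif(nb, 0.05, 0.15) * min(h, w)
    field <- numeric(n_roi)
    px <- xc[roi_idx]
    py <- yc[roi_idx]
    for (b in seq_len(nb))
      field <- field + exp(-((px - bx[b])^2 + (py - by[b])^2) / (2 * bs[b]^2))
    pos_idx <- roi_idx[order(field, decreasing = TRUE)[seq_len(k)]]
    c1 <- if (k > 0) pmax(stats::rnorm(k, intensity_mean, intensity_sd),
                          intensity_floor) else numeric(0)
    c2 <- stats::runif(n_roi, 0, counterstain_max)
    Cfull <- matrix(0, h * w, 2L)
    Cfull[roi_idx, 2L] <- c2
    Cfull[pos_idx, 1L] <- c1
    od <- Cfull %*% t(S)
    if (od_noise_sd > 0)
      od <- od + stats::rnorm(length(od), 0, od_noise_sd)
    od <- pmax(od, 0)
    list(od = od, Cfull = Cfull, c1 = c1, k = k)
  })
  img <- array(od_to_rgb(res$od, I0), dim = c(h, w, 3L))
  conc <- array(res$Cfull, dim = c(h, w, 2L),
                dimnames = list(NULL, NULL, colnames(S)))
  list(image = img, roi = roi,
       truth = list(coverage_pct = 100 * res$k / n_roi,
                    mean_intensity = if (res$k > 0) mean(res$c1) else 0,
                    stain_vectors = S, concentrations = conc,
                    n_roi = n_roi, n_positive = res$k))
}

#' Generate a construct cohort with calibrated metric-modulus correlation
#'
#' Draws \eqn{\log_{10}} moduli uniformly over the observed range of the
#' study cohort (about -0.9 to 1.3 log10 MPa at 18 percent strain) and sets each
#' staining metric to a linear function of log modulus plus Gaussian noise
#' whose variance is chosen so the population \eqn{R^2} equals the target:
#' \eqn{\sigma^2 = slope^2 \sigma_x^2 (1 - R^2) / R^2}.
#'
#' @param n Number of records.
#' @param r2_target Population R^2 between `mean_intensity` and log10
#'   modulus (default 0.84).
#' @param seed Integer seed.
#' @param slope,intercept Linear law for `mean_intensity` (OD units per
#'   log10 MPa).
#' @param coverage_r2,coverage_slope,coverage_intercept Same for
#'   `coverage_pct` (percent per log10 MPa; default R^2 0.64).
#' @param log10_range Range of log10 modulus (MPa).
#' @param days Culture days cycled over records.
#' @return Data frame of construct records (see [read_records()] for the
#'   column dialect) with attribute `truth`.
#' @export
gen_cohort <- function(n, r2_target = 0.84, seed = NULL,
                       slope = 0.25, intercept = 0.45,
                       coverage_r2 = 0.64, coverage_slope = 18,
                       coverage_intercept = 40,
                       log10_range = c(-0.9, 1.3),
                       days = c(0, 28, 56, 84)) {
  if (!(r2_target > 0 && r2_target < 1) || !(coverage_r2 > 0 && coverage_r2 < 1))
    stop_quant("r2 targets must lie in (0, 1)", class = "invalid_argument")
  sd_x <- diff(log10_range) / sqrt(12)
  sd_int <- abs(slope) * sd_x * sqrt((1 - r2_target) / r2_target)
  sd_cov <- abs(coverage_slope) * sd_x * sqrt((1 - coverage_r2) / coverage_r2)
  with_seed(seed, {
    x <- stats::runif(n, log10_range[1], log10_range[2])
    mi <- intercept + slope * x + stats::rnorm(n, 0, sd_int)
    cov <- pmin(100, pmax(0, coverage_intercept + coverage_slope * x +
                            stats::rnorm(n, 0, sd_cov)))
    rec <- data.frame(
      specimen_id = sprintf("S%04d", seq_len(n)),
      group = rep_len(c("loaded", "nonloaded"), n),
      day = rep_len(rep(days, each = 2L), n),
      modulus_18pct_MPa = 10^x,
      coverage_pct = cov,
      mean_intensity = mi,
      dna_ng = NA_real_,
      protein_ug = NA_real_,
      thickness_um = stats::runif(n, 900, 1400),
      diameter_mm = stats::runif(n, 4.8, 5.6))
    attr(rec, "truth") <- list(r2_intensity = r2_target, r2_coverage = coverage_r2,
                               slope = slope, intercept = intercept,
                               noise_sd = sd_int)
    rec
  })
}

#' Generate a dip-then-rise construct growth trajectory
#'
#' Emits construct states whose thickness dips at the second time point and
#' then rises, while stiffness grows monotonically -- the phenomenology of
#' a loaded cohort compacting before matrix deposition thickens and
#' stiffens it. The default stiffness path is anchored to the study's
#' tangent-moduli tables: `B` from the modulus ratio between 18 and 10 percent
#' strain (\eqn{M_{18}/M_{10} = e^{0.08B}}) and `A` from
#' \eqn{M_{10} = A B e^{0.1 B}}. Feeding the defaults to
#' [strain_trajectory()] reproduces the decrease-then-increase pattern of
#' the estimated applied strain.
#'
#' @param days Time points (days).
#' @param thickness_path Thickness per day, micrometres (dip then rise).
#' @param A_path,B_path Exponential-law coefficients per day.
#' @param diameter_path Construct diameter per day, millimetres.
#' @return List of [construct_state()] objects.
#' @export
gen_trajectory <- function(days = c(0, 28, 56, 84),
                           thickness_path = c(1180, 1050, 1250, 1300),
                           A_path = c(1.59e-4, 1.05e-5, 7.8e-6, 1.87e-5),
                           B_path = c(20.4, 45.8, 56.8, 53.5),
                           diameter_path = rep(5, length(days))) {
  n <- length(days)
  if (length(thickness_path) != n || length(A_path) != n ||
      length(B_path) != n || length(diameter_path) != n)
    stop_quant("all trajectory paths must match length(days)",
               class = "invalid_argument")
  lapply(seq_len(n), function(i)
    construct_state(thickness_um = thickness_path[i],
                    diameter_mm = diameter_path[i],
                    A_MPa = A_path[i], B = B_path[i], day = days[i]))
}
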