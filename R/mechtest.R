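# Cyclic unconfined-compression analysis: thickness by tare load, cycle
# segmentation, exponential stress-strain fit, tangent instantaneous moduli.

#' Construct a cyclic compression test trace
#'
#' Container for one specimen's raw test record: time, force and platen
#' travel sampled simultaneously. Force is stored positive-in-compression;
#' use [read_trace()] to normalise instrument sign conventions on import.
#'
#' @param time_s Sample times in seconds, strictly increasing.
#' @param force_N Compressive force in newtons (positive in compression).
#' @param displacement_um Platen travel in micrometres, measured downward
#'   from the starting position.
#' @param sample_rate Sampling rate in Hz; inferred from `time_s` if `NULL`.
#' @param specimen_id Specimen label.
#' @param start_gap_um Platen gap (micrometres) at `displacement_um = 0`.
#'   Required for thickness detection: the gap at any sample is
#'   `start_gap_um - displacement_um`.
#' @param truth Optional list of generator ground truth (see
#'   [gen_mech_trace()]); carried along for validation work.
#' @return An object of class `cyclic_trace`.
#' @export
cyclic_trace <- function(time_s, force_N, displacement_um, sample_rate = NULL,
                         specimen_id = "specimen", start_gap_um = NA_real_,
                         truth = NULL) {
  n <- length(time_s)
  if (n < 2L || length(force_N) != n || length(displacement_um) != n)
    stop_quant("time, force and displacement must have equal length >= 2",
               class = "invalid_trace")
  if (any(diff(time_s) <= 0))
    stop_quant("time must be strictly increasing", class = "invalid_trace")
  if (is.null(sample_rate)) sample_rate <- 1 / stats::median(diff(time_s))
  assert_scalar_pos(sample_rate, "sample_rate")
  structure(
    list(data = data.frame(time_s = as.numeric(time_s),
                           force_N = as.numeric(force_N),
                           displacement_um = as.numeric(displacement_um)),
         sample_rate = sample_rate,
         specimen_id = specimen_id,
         start_gap_um = start_gap_um,
         truth = truth),
    class = "cyclic_trace")
}

#' @export
print.cyclic_trace <- function(x, ...) {
  cat(sprintf("<cyclic_trace> %s: %d samples @ %.6g Hz, force %.4g..%.4g N\n",
              x$specimen_id, nrow(x$data), x$sample_rate,
              min(x$data$force_N), max(x$data$force_N)))
  invisible(x)
}

#' Detect construct thickness from the tare-load crossing
#'
#' The platen approaches the specimen at constant speed and stops once the
#' tare load is read; thickness is the platen gap at which the compressive
#' force first reaches the tare threshold, with linear interpolation
#' between the bracketing samples. Two measures make this robust on
#' records where the (noisier) cyclic test follows immediately: the
#' crossing is searched only within the constant-velocity approach prefix,
#' identified from the machine-controlled displacement channel, and the
#' force is median-smoothed so single noisy samples cannot trigger a false
#' contact. If the approach record stops marginally short of the threshold
#' (it ends the instant the tare is read), the last few micrometres are
#' extrapolated from the local force-displacement slope. On a monotone
#' noise-free approach every step is exact.
#'
#' @param trace A [cyclic_trace()] with `start_gap_um` set.
#' @param tare_N Tare threshold in newtons (default 0.02, positive
#'   compression).
#' @param smooth_window Odd window length (samples) for the running median.
#' @return Thickness in micrometres.
#' @export
detect_thickness <- function(trace, tare_N = 0.02, smooth_window = 9L) {
  stopifnot(inherits(trace, "cyclic_trace"))
  assert_scalar_pos(tare_N, "tare_N")
  if (!is.finite(trace$start_gap_um))
    stop_quant("trace has no start_gap_um; thickness cannot be referenced",
               class = "invalid_trace")
  f <- trace$data$force_N
  d <- trace$data$displacement_um
  # constant-velocity approach prefix (displacement is machine-controlled)
  v <- diff(d)
  v0 <- stats::median(v[seq_len(min(10L, length(v)))])
  approach_end <- if (is.finite(v0) && v0 > 0) {
    dev <- which(abs(v - v0) > 0.5 * v0)
    if (length(dev) > 0L) dev[1L] else length(f)
  } else {
    length(f)
  }
  fa <- f[seq_len(approach_end)]
  k <- min(as.integer(smooth_window), length(fa))
  if (k %% 2L == 0L) k <- k - 1L
  fs <- if (k >= 3L) stats::runmed(fa, k, endrule = "median") else fa
  if (fs[1L] >= tare_N)
    stop_quant("pre-loaded specimen", class = "preloaded")
  idx <- which(fs >= tare_N)[1L]
  disp_cross <- if (!is.na(idx)) {
    df <- fs[idx] - fs[idx - 1L]
    frac <- if (df > 0) (tare_N - fs[idx - 1L]) / df else 1
    d[idx - 1L] + frac * (d[idx] - d[idx - 1L])
  } else {
    # approach stopped at the tare reading: extrapolate the remaining
    # fraction of a sample from the local slope near the record end
    w <- min(8L, approach_end - 1L)
    slope <- (fs[approach_end] - fs[approach_end - w]) /
      (d[approach_end] - d[approach_end - w])
    extra <- if (is.finite(slope) && slope > 0)
      (tare_N - fs[approach_end]) / slope else Inf
    if (!is.finite(extra) || extra > 25)
      stop_quant("no contact detected", class = "no_contact")
    d[approach_end] + extra
  }
  trace$start_gap_um - disp_cross
}

# Local extrema of a (clean) displacement signal. Plateau-safe: zero slopes
# inherit the previous non-zero sign. Enforces a minimum index distance.
find_extrema <- function(x, min_dist = 1L) {
  s <- sign(diff(x))
  nz <- s != 0
  if (!any(nz)) return(list(peaks = integer(), troughs = integer()))
  carry <- cummax(seq_along(s) * nz)  # carry last non-zero sign forward
  carry[carry == 0L] <- which(nz)[1L]
  s <- s[carry]
  ds <- diff(s)
  peaks <- which(ds < 0) + 1L
  troughs <- which(ds > 0) + 1L
  thin <- function(idx) {
    if (length(idx) < 2L) return(idx)
    keep <- idx[1L]
    for (i in idx[-1L]) if (i - keep[length(keep)] >= min_dist) keep <- c(keep, i)
    keep
  }
  list(peaks = thin(peaks), troughs = thin(troughs))
}

#' Segment cycles and build an engineering stress-strain curve
#'
#' Segments the post-contact record into loading cycles by peak detection on
#' displacement, converts displacement to engineering strain using the
#' detected thickness and force to engineering stress using the initial
#' circular face area, and returns the loading limbs (trough to peak) of the
#' last `keep_last` cycles, concatenated. The zero-load stress reading is
#' subtracted before the curve is returned (see `offset_rule`).
#'
#' @param trace A [cyclic_trace()].
#' @param diameter_mm Specimen diameter in millimetres.
#' @param frequency Loading frequency in Hz.
#' @param n_cycles Number of cycles the protocol applied.
#' @param keep_last How many final (steady-state) cycles to keep.
#' @param thickness_um Specimen thickness; detected via [detect_thickness()]
#'   when `NULL`.
#' @param tare_N Tare threshold forwarded to [detect_thickness()].
#' @param zero_offset Subtract the zero-load stress reading? Default `TRUE`.
#' @param offset_rule How the zero-load reading is obtained. `"tare"`
#'   (default) subtracts the known tare stress `tare_N / area`: thickness is
#'   *defined* as the gap at which the platen reads the tare load, so in the
#'   thickness-referenced strain frame the stress at zero strain equals the
#'   tare stress exactly, with no estimation noise. `"trough"` uses the
#'   median stress at the detected cycle troughs (robust under baseline
#'   drift); `"low_strain"` uses the median stress of the samples in the
#'   lowest 2 percent of the strain range.
#' @return A `stress_strain_curve`: data frame with columns `strain`,
#'   `stress` (MPa) and attributes `cycles_used`, `thickness_um`,
#'   `area_mm2`, `offset_MPa`, `index` (original sample indices).
#' @export
extract_cycles <- function(trace, diameter_mm, frequency = 1, n_cycles = 10L,
                           keep_last = 4L, thickness_um = NULL, tare_N = 0.02,
                           zero_offset = TRUE,
                           offset_rule = c("tare", "trough", "low_strain")) {
  stopifnot(inherits(trace, "cyclic_trace"))
  assert_scalar_pos(diameter_mm, "diameter_mm")
  assert_scalar_pos(frequency, "frequency")
  offset_rule <- match.arg(offset_rule)
  if (keep_last > n_cycles)
    stop_quant("keep_last exceeds n_cycles", class = "invalid_argument")
  thickness <- thickness_um %||% detect_thickness(trace, tare_N = tare_N)
  d <- trace$data$displacement_um
  f <- trace$data$force_N
  contact_disp <- trace$start_gap_um - thickness
  i0 <- which(d >= contact_disp - 1e-9)[1L]
  if (is.na(i0))
    stop_quant("cycle segmentation failed", class = "segmentation_failed")
  seg <- i0:length(d)
  ds <- d[seg]
  min_dist <- max(1L, floor(0.5 / frequency * trace$sample_rate))
  ext <- find_extrema(ds, min_dist)
  peaks <- ext$peaks
  troughs <- ext$troughs
  # the record enters the cyclic phase at a trough (the contact point)
  if (length(peaks) > 0L && (length(troughs) == 0L || troughs[1L] > peaks[1L]))
    troughs <- c(1L, troughs)
  if (length(peaks) < n_cycles)
    stop_quant("incomplete test", class = "incomplete_test")
  # sanity: peaks must be nearly periodic and each preceded by a trough
  if (length(peaks) >= 3L) {
    sp <- diff(peaks)
    if (max(abs(sp - stats::median(sp))) > 0.35 * stats::median(sp))
      stop_quant("cycle segmentation failed", class = "segmentation_failed")
  }
  area <- face_area_mm2(diameter_mm)
  strain_all <- (d - contact_disp) / thickness
  stress_all <- f / area
  offset <- 0
  if (zero_offset) {
    offset <- switch(offset_rule,
      tare = tare_N / area,
      trough = stats::median(stress_all[seg][troughs]),
      low_strain = {
        st <- strain_all[seg]
        lo <- min(st) + 0.02 * (max(st) - min(st))
        stats::median(stress_all[seg][st <= lo])
      })
  }
  use <- seq.int(length(peaks) - keep_last + 1L, length(peaks))
  idx <- integer()
  for (p in use) {
    tr <- troughs[troughs < peaks[p]]
    if (length(tr) == 0L)
      stop_quant("cycle segmentation failed", class = "segmentation_failed")
    idx <- c(idx, seg[max(tr):peaks[p]])
  }
  curve <- data.frame(strain = strain_all[idx], stress = stress_all[idx] - offset)
  structure(curve, class = c("stress_strain_curve", "data.frame"),
            cycles_used = use, thickness_um = thickness, area_mm2 = area,
            offset_MPa = offset, index = idx)
}

#' Fit the exponential stress-strain law
#'
#' Nonlinear least squares fit of \eqn{\sigma(\epsilon) = A(e^{B\epsilon}-1)}
#' over a strain window, with the deterministic initialisation
#' \eqn{B_0 = 15}, \eqn{A_0 = \sigma_{max}/(e^{B_0 \epsilon_{max}}-1)} so
#' repeated runs are bit-reproducible. The law is forced through the origin,
#' which keeps the tangent moduli identifiable.
#'
#' @param curve A `stress_strain_curve` (zero-offset already applied).
#' @param fit_lo,fit_hi Strain window for the fit (defaults 0 and 0.2).
#' @return An `exp_fit` list: `A` (MPa), `B` (dimensionless), `fit_range`,
#'   `rss` (MPa^2), `n_points`.
#' @export
fit_exponential <- function(curve, fit_lo = 0, fit_hi = 0.2) {
  if (!(fit_lo >= 0 && fit_hi <= 0.25 && fit_lo < fit_hi))
    stop_quant("fit range must satisfy 0 <= lo < hi <= 0.25",
               class = "invalid_argument")
  sel <- curve$strain >= fit_lo & curve$strain <= fit_hi &
    is.finite(curve$stress)
  eps <- curve$strain[sel]
  sig <- curve$stress[sel]
  if (length(eps) < 10L)
    stop_quant("fit failed: fewer than 10 samples in fit range",
               class = "fit_failed")
  if (max(sig) <= 0)
    stop_quant("fit failed: no positive stress in fit range",
               class = "fit_failed")
  B0 <- 15
  A0 <- max(sig) / (exp(B0 * max(eps)) - 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(sig ~ A * (exp(B * eps) - 1),
                      start = list(A = A0, B = B0),
                      lower = c(A = 1e-12, B = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop_quant("fit failed: %s", conditionMessage(e), class = "fit_failed"))
  co <- stats::coef(fit)
  if (!all(is.finite(co)) || co[["A"]] <= 0 || co[["B"]] <= 0)
    stop_quant("fit failed: non-positive coefficients", class = "fit_failed")
  structure(list(A = unname(co[["A"]]), B = unname(co[["B"]]),
                 fit_range = c(fit_lo, fit_hi),
                 rss = sum(stats::resid(fit)^2), n_points = length(eps)),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> sigma = %.6g (exp(%.6g e) - 1) MPa on [%.3g, %.3g], rss %.3g, n %d\n",
              x$A, x$B, x$fit_range[1], x$fit_range[2], x$rss, x$n_points))
  invisible(x)
}

#' Tangent instantaneous moduli from a fitted exponential law
#'
#' The tangent modulus at strain \eqn{\epsilon} is the analytic derivative
#' \eqn{d\sigma/d\epsilon = A B e^{B\epsilon}} of the fitted law; strictly
#' increasing in strain whenever \eqn{B > 0}.
#'
#' @param fit An `exp_fit`.
#' @param strains Strains at which moduli are evaluated (defaults: the
#'   protocol's 10, 12, 15 and 18 percent).
#' @return Data frame with columns `strain` and `modulus_MPa`.
#' @export
tangent_moduli <- function(fit, strains = c(0.10, 0.12, 0.15, 0.18)) {
  stopifnot(inherits(fit, "exp_fit"))
  if (any(strains < 0 | strains > 0.25))
    stop_quant("strains must lie in [0, 0.25]", class = "invalid_argument")
  data.frame(strain = strains, modulus_MPa = fit$A * fit$B * exp(fit$B * strains))
}

#' Select specimens by thickness window
#'
#' Inclusive window selection mirroring the protocol's preselection of
#' constructs whose thickness produces the intended strain under the ring
#' limiter; default bounds 1110-1250 um.
#'
#' @param thicknesses Thicknesses in micrometres.
#' @param lo,hi Window bounds in micrometres (inclusive).
#' @return List with `selected` (indices) and `discard_fraction`.
#' @export
select_by_thickness <- function(thicknesses, lo = 1110, hi = 1250) {
  if (length(thicknesses) == 0L)
    stop_quant("no thicknesses supplied", class = "invalid_argument")
  if (!(lo < hi))
    stop_quant("lo must be < hi", class = "invalid_argument")
  idx <- which(thicknesses >= lo & thicknesses <= hi)
  list(selected = idx,
       discard_fraction = 1 - length(idx) / length(thicknesses))
}
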