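# Force-balance model of the loading station: a force-controlled plunger
# bearing on a construct and a surrounding silicone ring in parallel. The
# ring is linear elastic; the construct follows the exponential law fitted
# from its own compression test. The plunger settles at the height where the
# two reaction forces balance the applied force, so the strain delivered to
# the construct depends on its thickness and stiffness at that time point.

#' Silicone ring specification
#'
#' @param thickness_um Ring thickness in micrometres (default 1000).
#' @param modulus_MPa Ring compressive modulus in MPa (default 2.64,
#'   Sylgard 184).
#' @param contact_area_mm2 Plunger/ring contact area in mm^2. Default: the
#'   annulus between the 7 mm plunger and the 5 mm construct footprint,
#'   \eqn{\pi(3.5^2-2.5^2) \approx 18.85} mm^2.
#' @param plunger_diameter_mm,footprint_diameter_mm Geometry used for the
#'   default annulus area.
#' @return A `ring_spec` object.
#' @export
ring_spec <- function(thickness_um = 1000, modulus_MPa = 2.64,
                      contact_area_mm2 = NULL, plunger_diameter_mm = 7,
                      footprint_diameter_mm = 5) {
  assert_scalar_pos(thickness_um, "thickness_um")
  assert_scalar_pos(modulus_MPa, "modulus_MPa")
  if (is.null(contact_area_mm2))
    contact_area_mm2 <- pi / 4 * (plunger_diameter_mm^2 - footprint_diameter_mm^2)
  assert_scalar_pos(contact_area_mm2, "contact_area_mm2")
  structure(list(thickness_um = thickness_um, modulus_MPa = modulus_MPa,
                 contact_area_mm2 = contact_area_mm2),
            class = "ring_spec")
}

#' Construct state entering the force-balance strain estimate
#'
#' @param thickness_um Construct thickness in micrometres.
#' @param diameter_mm Construct diameter in millimetres.
#' @param A_MPa,B Coefficients of the construct's exponential stress-strain
#'   law \eqn{\sigma = A(e^{B\epsilon}-1)}; an `exp_fit` may be given as
#'   `fit` instead.
#' @param fit Optional `exp_fit` supplying `A_MPa` and `B`.
#' @param day Optional culture day label.
#' @return A `construct_state` object.
#' @export
construct_state <- function(thickness_um, diameter_mm = 5, A_MPa = NULL,
                            B = NULL, fit = NULL, day = NA_real_) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "exp_fit"))
    A_MPa <- fit$A
    B <- fit$B
  }
  assert_scalar_pos(thickness_um, "thickness_um")
  assert_scalar_pos(diameter_mm, "diameter_mm")
  assert_scalar_pos(A_MPa, "A_MPa")
  assert_scalar_pos(B, "B")
  structure(list(thickness_um = thickness_um, diameter_mm = diameter_mm,
                 A_MPa = A_MPa, B = B, day = day),
            class = "construct_state")
}

ring_force_at <- function(h, ring) {
  if (h >= ring$thickness_um) return(0)
  ring$contact_area_mm2 * ring$modulus_MPa *
    (ring$thickness_um - h) / ring$thickness_um
}

construct_force_at <- function(h, construct) {
  if (h >= construct$thickness_um) return(0)
  eps <- (construct$thickness_um - h) / construct$thickness_um
  face_area_mm2(construct$diameter_mm) * construct$A_MPa *
    (exp(construct$B * eps) - 1)
}

#' Plunger settling height with the ring carrying all the load
#'
#' Closed form for the linear ring spring when the construct's contribution
#' is negligible: \eqn{h = t_r (1 - F / (A_r E_r))}.
#'
#' @param force_N Applied force in newtons.
#' @param ring A [ring_spec()].
#' @return Plunger height (gap under the plunger) in micrometres.
#' @export
ring_only_height <- function(force_N, ring) {
  stopifnot(inherits(ring, "ring_spec"))
  if (!is.numeric(force_N) || length(force_N) != 1L || force_N < 0)
    stop_quant("force_N must be a single non-negative number",
               class = "invalid_argument")
  s <- force_N / (ring$contact_area_mm2 * ring$modulus_MPa)
  if (s >= 1)
    stop_quant("ring overload", class = "ring_overload")
  ring$thickness_um * (1 - s)
}

#' Solve the plunger/ring/construct load sharing
#'
#' Finds the unique plunger height at which the linear ring force plus the
#' construct's exponential-law force equals the applied force. The combined
#' reaction is strictly decreasing in plunger height, so bisection over
#' \eqn{(0, \max(t_r, t_c))} brackets the root; the interval is halved to
#' machine precision, leaving a force residual far below `tol_N`. Constructs
#' shorter than the settled ring carry no load and receive exactly zero
#' strain.
#'
#' @param force_N Applied force in newtons (> 0).
#' @param ring A [ring_spec()].
#' @param construct A [construct_state()].
#' @param tol_N Force-balance tolerance in newtons (default 1e-6).
#' @return A `loading_estimate`: `plunger_height_um`, `construct_strain`,
#'   `construct_force_N`, `ring_force_N`.
#' @export
solve_load_sharing <- function(force_N, ring, construct, tol_N = 1e-6) {
  stopifnot(inherits(ring, "ring_spec"), inherits(construct, "construct_state"))
  assert_scalar_pos(force_N, "force_N")
  resid <- function(h)
    ring_force_at(h, ring) + construct_force_at(h, construct) - force_N
  lo <- 0
  hi <- max(ring$thickness_um, construct$thickness_um)
  if (resid(lo) <= 0)
    stop_quant("no equilibrium", class = "no_equilibrium")
  for (i in 1:120) {
    mid <- (lo + hi) / 2
    if (resid(mid) > 0) lo <- mid else hi <- mid
  }
  h <- (lo + hi) / 2
  if (abs(resid(h)) > tol_N)
    stop_quant("no equilibrium", class = "no_equilibrium")
  strain <- max(0, (construct$thickness_um - h) / construct$thickness_um)
  structure(list(plunger_height_um = h,
                 construct_strain = strain,
                 construct_force_N = construct_force_at(h, construct),
                 ring_force_N = ring_force_at(h, ring)),
            class = "loading_estimate")
}

#' Estimated strain trajectory across a culture time course
#'
#' Applies [solve_load_sharing()] independently at each time point (a pure
#' map; no state is carried between days). Per-time-point failures are
#' flagged in the `error` column rather than aborting the whole trajectory.
#'
#' @param force_N Applied force in newtons.
#' @param ring A [ring_spec()].
#' @param states List of [construct_state()] objects, or a data frame with
#'   columns `day`, `thickness_um`, `diameter_mm`, `A_MPa`, `B`.
#' @return Data frame: `day`, `strain`, `plunger_height_um`,
#'   `construct_force_N`, `ring_force_N`, `error`.
#' @export
strain_trajectory <- function(force_N, ring, states) {
  if (is.data.frame(states)) {
    states <- lapply(seq_len(nrow(states)), function(i)
      construct_state(states$thickness_um[i], states$diameter_mm[i],
                      states$A_MPa[i], states$B[i],
                      day = if ("day" %in% names(states)) states$day[i] else NA_real_))
  }
  if (length(states) < 1L)
    stop_quant("at least one construct state is required",
               class = "invalid_argument")
  rows <- lapply(states, function(st) {
    est <- tryCatch(solve_load_sharing(force_N, ring, st), error = function(e) e)
    if (inherits(est, "error")) {
      data.frame(day = st$day, strain = NA_real_, plunger_height_um = NA_real_,
                 construct_force_N = NA_real_, ring_force_N = NA_real_,
                 error = conditionMessage(est))
    } else {
      data.frame(day = st$day, strain = est$construct_strain,
                 plunger_height_um = est$plunger_height_um,
                 construct_force_N = est$construct_force_N,
                 ring_force_N = est$ring_force_N, error = NA_character_)
    }
  })
  do.call(rbind, rows)
}
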