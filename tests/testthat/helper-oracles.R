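# Independent oracles used across tests. These deliberately re-derive the
# quantities by brute force (exhaustive scans, full enumeration, closed
# forms) so they stay independent of the implementation paths they check.

# Exhaustive between-class-variance maximization over every candidate bin
# edge, lowest-threshold tie-break.
otsu_brute <- function(v, n_bins = 256L) {
  v <- as.numeric(v)
  vmax <- max(v)
  bin <- pmin(pmax(ceiling(v / vmax * n_bins), 1L), n_bins)
  centers <- (seq_len(n_bins) - 0.5) * vmax / n_bins
  x <- centers[bin]
  best_t <- NA_real_
  best_s <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    in0 <- bin <= k
    n0 <- sum(in0)
    if (n0 == 0L || n0 == length(v)) next
    w0 <- n0 / length(v)
    s <- w0 * (1 - w0) * (mean(x[in0]) - mean(x[!in0]))^2
    if (s > best_s * (1 + 1e-12)) {
      best_s <- s
      best_t <- k * vmax / n_bins
    }
  }
  best_t
}

# Exact two-sided rank-sum p-value by full enumeration of rank assignments
# (midranks under ties), defined as 2 * min(P(W <= w), P(W >= w)) capped
# at 1.
ranksum_enum_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(r), n1)
  wd <- colSums(matrix(r[combos], nrow = n1))
  min(1, 2 * min(mean(wd <= w + 1e-9), mean(wd >= w - 1e-9)))
}

# Angle in degrees between two unit vectors.
angle_deg <- function(u, v) acos(min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))) * 180 / pi

# Constant-speed approach onto a linear spring: gap from start_gap down at
# `speed`, force k * (contact_gap - gap) once below the contact gap.
spring_trace <- function(start_gap = 1250, contact_gap = 1200, k = 0.004,
                         speed = 50, rate = 10) {
  tt <- seq(0, (start_gap - contact_gap + 40) / speed, by = 1 / rate)
  disp <- speed * tt
  gap <- start_gap - disp
  force <- pmax(0, k * (contact_gap - gap))
  cyclic_trace(tt, force, disp, start_gap_um = start_gap,
               specimen_id = "spring")
}

# Point-in-polygon (even-odd ray casting) at a single point; used to
# rasterize small ROIs pixel by pixel as an oracle.
point_in_polygon <- function(px, py, P) {
  n <- nrow(P)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((P[i, 2] > py) != (P[j, 2] > py) &&
        px < (P[j, 1] - P[i, 1]) * (py - P[i, 2]) / (P[j, 2] - P[i, 2]) + P[i, 1])
      inside <- !inside
    j <- i
  }
  inside
}
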