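# Stain quantification: OD transform, stain-vector estimation,
# deconvolution, Otsu thresholding, ROI handling and metrics.

test_that("optical density transform matches the Beer-Lambert definition", {
  white <- array(255, c(2, 2, 3))
  expect_lt(max(abs(to_od(white))), 0.002)
  # decade pixel: I + 1 = I0 / 10 gives OD exactly 1
  dec <- array(25.6 - 1, c(1, 1, 3))
  expect_equal(as.numeric(to_od(dec)), rep(1, 3))
  # forward/backward round trip at 1e-9
  S <- chondroquant:::default_stain_vectors()
  od_true <- array(as.numeric(S %*% c(0.6, 0.2)), c(1, 1, 3))
  img <- 256 * 10^(-od_true) - 1
  expect_equal(to_od(img), od_true, tolerance = 1e-9)
})

test_that("stain vectors are recovered within 2 degrees from synthetic slides", {
  g <- gen_histology(seed = 101)
  basis <- estimate_stain_basis(to_od(g$image))
  truth <- g$truth$stain_vectors
  expect_lt(angle_deg(basis[, "alcian_blue"], truth[, "alcian_blue"]), 2)
  expect_lt(angle_deg(basis[, "counterstain"], truth[, "counterstain"]), 2)
  expect_equal(colSums(basis^2), c(alcian_blue = 1, counterstain = 1),
               tolerance = 1e-12)
  expect_true(all(basis >= 0))
})

test_that("single-stain images yield a degenerate basis error", {
  S <- chondroquant:::default_stain_vectors()
  conc <- matrix(runif(64 * 64, 0.3, 1))
  od <- array(conc %*% t(S[, 1, drop = FALSE]), c(64, 64, 3))
  img <- 256 * 10^(-od) - 1
  expect_error(estimate_stain_basis(to_od(img)), "degenerate basis")
  blank <- array(255, c(64, 64, 3))
  expect_error(estimate_stain_basis(to_od(blank)), "insufficient stained tissue")
})

test_that("deconvolution inverts the forward model", {
  g <- gen_histology(seed = 102)
  maps <- deconvolve(to_od(g$image), g$truth$stain_vectors)
  expect_lt(max(abs(maps$concentrations - g$truth$concentrations)), 1e-6)
  expect_lt(max(maps$residual), 1e-6)

  white <- deconvolve(to_od(array(255, c(4, 4, 3))),
                      g$truth$stain_vectors)
  expect_lt(max(white$concentrations), 0.002)

  # an orthonormal 3-stain basis makes deconvolution an exact projection
  I3 <- diag(3)
  colnames(I3) <- c("r", "g", "b")
  any_od <- array(runif(4 * 4 * 3), c(4, 4, 3))
  m3 <- deconvolve(any_od, I3)
  expect_lt(max(m3$residual), 1e-12)
  expect_equal(as.numeric(m3$concentrations), as.numeric(any_od))

  sing <- cbind(a = c(1, 0, 0), b = c(1, 0, 0))
  expect_error(deconvolve(any_od, sing), "singular stain matrix")
})

test_that("Otsu threshold equals the exhaustive scan and honours tie-breaks", {
  # two-delta histogram with equal mass at bins 10 and 200 of 256:
  # every edge between them ties, so the lowest qualifying edge (bin 10) wins
  v <- c(rep(9.5, 100), rep(199.5, 100), 255.9)  # last sample pins the range
  vmax <- max(v)
  expect_equal(otsu_threshold(v, 256L), 10 / 256 * vmax)
  expect_equal(otsu_threshold(v, 256L), otsu_brute(v, 256L))

  set.seed(41)
  for (r in 1:25) {
    v <- c(abs(rnorm(300, 0.05, 0.03)), abs(rnorm(sample(50:400, 1), 0.6, 0.2)))
    expect_identical(otsu_threshold(v), otsu_brute(v))
  }

  # two-point input separates the points
  thr <- otsu_threshold(c(0, 1))
  expect_true(thr > 0 && thr < 1)
  expect_error(otsu_threshold(rep(0.5, 10)), "no separation")
})

test_that("threshold and metrics are invariant to pixel order", {
  set.seed(42)
  v <- c(rep(0.05, 400), runif(300, 0.4, 1))
  p <- sample(length(v))
  expect_identical(otsu_threshold(v), otsu_threshold(v[p]))
})

test_that("coverage is invariant under joint monotone rescaling", {
  g <- gen_histology(width = 96L, height = 96L, seed = 103)
  maps <- deconvolve(to_od(g$image), g$truth$stain_vectors)
  thr <- otsu_threshold(maps$concentrations[, , "alcian_blue"])
  q1 <- quantify_stain(maps, roi = g$roi, threshold = thr)
  scaled <- maps
  scaled$concentrations <- maps$concentrations * 7.3
  q2 <- quantify_stain(scaled, roi = g$roi, threshold = thr * 7.3)
  expect_identical(q1$coverage_pct, q2$coverage_pct)
  expect_identical(q1$n_positive, q2$n_positive)
})

test_that("quantification counts positive pixels within the ROI", {
  conc <- array(0, c(10, 10, 1), dimnames = list(NULL, NULL, "alcian_blue"))
  roi <- matrix(FALSE, 10, 10)
  roi[3:8, 3:8] <- TRUE
  maps <- structure(list(concentrations = conc,
                         residual = matrix(0, 10, 10)),
                    class = "stain_maps")
  # uniform concentration at twice the threshold: full coverage, mean = c
  maps$concentrations[, , 1] <- 0.8
  q <- quantify_stain(maps, roi = roi, threshold = 0.4)
  expect_equal(q$coverage_pct, 100)
  expect_equal(q$mean_intensity, 0.8)
  expect_equal(q$n_roi, 36L)
  # everything below threshold: zero coverage and zero mean intensity
  maps$concentrations[, , 1] <- 0.1
  q0 <- quantify_stain(maps, roi = roi, threshold = 0.4)
  expect_equal(q0$coverage_pct, 0)
  expect_equal(q0$mean_intensity, 0)
  expect_error(quantify_stain(maps, roi = matrix(FALSE, 10, 10), threshold = 0.4),
               "empty ROI")
  expect_error(quantify_stain(maps, target = "sirius_red", roi = roi,
                              threshold = 0.4), "not present")
})

test_that("generated coverage is recovered within a point end to end", {
  g <- gen_histology(coverage_pct = 40, seed = 104)
  od <- to_od(g$image)
  maps <- deconvolve(od, estimate_stain_basis(od))
  thr <- otsu_threshold(maps$concentrations[, , "alcian_blue"])
  q <- quantify_stain(maps, roi = g$roi, threshold = thr)
  expect_lt(abs(q$coverage_pct - g$truth$coverage_pct), 1)
})

test_that("polygon ROIs rasterize with the even-odd rule at pixel centres", {
  tmp <- tempfile(fileext = ".json")
  # full-frame rectangle -> everything inside
  jsonlite::write_json(list(polygons = list(list(c(0, 0), c(30, 0),
                                                 c(30, 20), c(0, 20)))),
                       tmp)
  expect_true(all(load_roi(tmp, c(20, 30))))
  # 10x10 axis-aligned square on 100x100 -> exactly 100 pixels
  jsonlite::write_json(list(polygons = list(list(c(10, 10), c(20, 10),
                                                 c(20, 20), c(10, 20)))),
                       tmp)
  m <- load_roi(tmp, c(100, 100))
  expect_identical(sum(m), 100L)
  # matches a per-pixel point-in-polygon oracle on an irregular polygon
  P <- cbind(c(2.2, 17.5, 14.1, 8.3, 3.7), c(3.1, 5.2, 16.8, 9.9, 14.4))
  jsonlite::write_json(list(polygons = list(asplit(P, 1))), tmp)
  m2 <- load_roi(tmp, c(20, 20))
  oracle <- matrix(FALSE, 20, 20)
  for (r in 1:20) for (cc in 1:20)
    oracle[r, cc] <- point_in_polygon(cc - 0.5, r - 0.5, P)
  expect_identical(m2, oracle)
  # polygon fully outside the frame -> empty ROI
  jsonlite::write_json(list(polygons = list(list(c(500, 500), c(600, 500),
                                                 c(600, 600)))), tmp)
  expect_error(load_roi(tmp, c(100, 100)), "empty ROI")
})

test_that("mask images convert non-zero pixels to ROI membership", {
  tmp <- tempfile(fileext = ".png")
  m <- matrix(0, 16, 16)
  m[4:9, 6:12] <- c(0.2, 0.5, 1)  # mixed non-zero values
  png::writePNG(m, tmp)
  roi <- load_roi(tmp, c(16, 16))
  expect_identical(roi, m > 0)
  expect_error(load_roi(tmp, c(32, 32)), "does not match")
})
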