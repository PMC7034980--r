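straight_record <- function(row, cols) {
  path <- cbind(rep(row, length(cols)), cols)
  list(id = 1L, corner_a = 1L, corner_b = 2L,
       path = matrix(as.integer(path), ncol = 2L),
       cell_pair = c(1L, 2L), junction_class = "untyped", flag = "")
}

test_that("path length sums weighted steps and rejects broken paths", {
  expect_equal(path_length(cbind(5L, 10:20)), 10)
  diag6 <- cbind(1:6, 1:6)
  expect_equal(path_length(diag6), 5 * sqrt(2))
  # L-path: 30 steps right then 40 steps down
  L <- rbind(cbind(1L, 1:31), cbind(2:41, 31L))
  expect_equal(path_length(L), 70)
  euclid <- sqrt(sum((L[1, ] - L[nrow(L), ])^2))
  expect_equal(euclid, 50)
  expect_equal(path_length(L) / euclid, 1.4)
  expect_equal(path_length(matrix(c(3L, 3L), 1L)), 0)
  expect_error(path_length(rbind(c(1L, 1L), c(1L, 3L))), "8-neighbours")
  expect_error(path_length(rbind(c(1L, 1L), c(1L, 1L))), "8-neighbours")
})

test_that("dilation bands equal the Chebyshev ball around the path", {
  rec <- straight_record(60L, 10:110)          # 101 px, far from borders
  band <- dilate_interface(rec, 2L, c(120L, 130L))
  expect_equal(sum(band$pixels), 525)          # (101 + 4) x 5
  expect_true(all(band$pixels[rec$path] == 1L))

  single <- straight_record(20L, 20L)
  single$path <- matrix(c(20L, 20L), 1L)
  b1 <- dilate_interface(single, 1L, c(40L, 40L))
  expect_equal(sum(b1$pixels), 9)

  b2 <- dilate_interface(rec, 3L, c(120L, 130L))
  expect_true(all(b2$pixels >= band$pixels))   # nesting
  expect_error(dilate_interface(rec, 0L, c(120L, 130L)))
  expect_error(dilate_interface(rec, 10L, c(120L, 130L)))

  # random small paths against the brute-force pixel scan
  set.seed(11)
  for (i in 1:5) {
    p <- random_path(c(48L, 48L), 20L)
    r <- list(id = 1L, path = p)
    d <- sample(1:4, 1)
    band <- dilate_interface(r, d, c(48L, 48L))
    expect_identical(band$pixels, oracle_band(p, d, c(48L, 48L)))
  }
})

test_that("covered runs follow the marker with zero gap tolerance", {
  rec <- straight_record(30L, 10:110)
  shape <- c(60L, 130L)
  band <- dilate_interface(rec, 2L, shape)

  full <- matrix(1L, shape[1L], shape[2L])
  r <- covered_runs(rec, band, full)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(1, 101))

  # marker strips over path indices 10..39 and 60..79 only
  marker <- matrix(0L, shape[1L], shape[2L])
  marker[28:32, (10:39) + 9L] <- 1L
  marker[28:32, (60:79) + 9L] <- 1L
  r2 <- covered_runs(rec, band, marker)
  expect_equal(r2$start, c(10, 60))
  expect_equal(r2$end, c(39, 79))

  expect_equal(nrow(covered_runs(rec, band, 0 * full)), 0)

  # a single uncovered pixel splits runs unless gap tolerance bridges it
  gap1 <- marker
  gap1[28:32, (40:59) + 9L] <- 1L
  gap1[28:32, 50 + 9L] <- 0L
  r3 <- covered_runs(rec, band, gap1)
  expect_equal(nrow(r3), 2)
  r4 <- covered_runs(rec, band, gap1, gap_tolerance = 1L)
  expect_equal(nrow(r4), 1)
})

test_that("primary measures handle full, fragmented, and empty coverage", {
  rec <- straight_record(30L, 10:110)
  shape <- c(60L, 130L)
  band <- dilate_interface(rec, 2L, shape)

  img <- matrix(0, shape[1L], shape[2L])
  img[28:32, (10:39) + 9L] <- 180
  img[28:32, (60:79) + 9L] <- 180
  p <- measure_primary(rec, band, raster_image(img), 50)
  expect_equal(p$fragmented_junction_contour, 29 + 19)
  expect_equal(p$junction_contour, 69)          # indices 10 -> 79
  expect_equal(p$straight_junction_length, 69)
  expect_equal(p$interface_contour, 100)
  expect_equal(p$straight_interface_length, 100)
  expect_equal(p$marker_area, sum(band$pixels == 1L & img > 50))
  expect_equal(p$marker_intensity, 180 * p$marker_area)

  # full coverage: junction == fragmented == interface contour
  imgf <- matrix(200, shape[1L], shape[2L])
  pf <- measure_primary(rec, band, raster_image(imgf), 50)
  expect_equal(pf$junction_contour, pf$interface_contour)
  expect_equal(pf$fragmented_junction_contour, pf$interface_contour)
  expect_equal(pf$straight_junction_length, pf$straight_interface_length)
  expect_equal(pf$marker_area, pf$interface_area)
  expect_equal(pf$junction_area, pf$interface_area)

  # empty marker: junction fields zero, interface fields intact
  p0 <- measure_primary(rec, band, raster_image(0 * img), 50)
  expect_equal(p0$fragmented_junction_contour, 0)
  expect_equal(p0$junction_contour, 0)
  expect_equal(p0$junction_area, 0)
  expect_equal(p0$marker_area, 0)
  expect_equal(p0$interface_contour, 100)
  expect_equal(p0$interface_area, 525)
})

test_that("secondary parameters are the documented ratios", {
  p <- structure(list(interface_contour = 100,
                      straight_interface_length = 100,
                      interface_area = 400, junction_contour = 69,
                      straight_junction_length = 69, junction_area = 350,
                      fragmented_junction_contour = 50,
                      marker_area = 100, marker_intensity = 1000),
                 class = "primary_measures")
  s <- derive_secondary(p)
  expect_equal(s$interface_linearity_index, 1)
  expect_equal(s$junction_linearity_index, 1)
  expect_equal(s$coverage_index, 50)
  expect_equal(s$interface_occupancy, 25)
  expect_equal(s$intensity_per_interface_area, 2.5)
  expect_equal(s$cluster_density, 10)

  s2 <- derive_secondary(p, cluster_denominator = "junction_area")
  expect_equal(s2$cluster_density, 1000 / 350)

  p$marker_area <- 0
  expect_true(is.na(derive_secondary(p)$cluster_density))
  p$interface_contour <- 0
  expect_error(derive_secondary(p), "degenerate")
})

test_that("a second marker is measured inside marker 1's band", {
  rec <- straight_record(30L, 10:90)
  shape <- c(60L, 110L)
  band <- dilate_interface(rec, 2L, shape)
  img <- matrix(0, shape[1L], shape[2L])
  img[29:31, 19:99] <- 100
  m1 <- raster_image(img)

  same <- measure_second_marker(rec, band, m1, 50)
  ref <- measure_primary(rec, band, m1, 50)
  expect_equal(unclass(same$primary), unclass(ref))

  none <- measure_second_marker(rec, band, raster_image(0 * img), 50)
  expect_equal(none$primary$marker_area, 0)
  expect_equal(none$primary$interface_area, ref$interface_area)

  # doubling intensities (no new above-threshold pixels) doubles intensity
  dbl <- raster_image(pmin(img * 2, 255))
  d <- measure_second_marker(rec, band, dbl, 50)
  expect_equal(d$primary$marker_intensity, 2 * ref$marker_intensity)
  expect_equal(d$primary$marker_area, ref$marker_area)
  expect_equal(d$primary$fragmented_junction_contour,
               ref$fragmented_junction_contour)

  expect_error(measure_second_marker(rec, band, raster_image(matrix(0, 5, 5)), 1),
               "shape")
})

test_that("primary measures agree with brute-force enumeration on random cases", {
  set.seed(99)
  for (i in 1:25) {
    shape <- c(sample(40:64, 1), sample(40:64, 1))
    p <- random_path(shape, sample(12:30, 1))
    rec <- list(id = 1L, path = p)
    d <- sample(1:4, 1)
    img <- random_image(shape)
    thr <- sample(40:220, 1)
    band <- dilate_interface(rec, d, shape)
    got <- measure_primary(rec, band, img, thr)
    want <- oracle_primary(p, d, unclass(img), thr)
    for (f in names(want)) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-9,
                   info = paste("field", f, "case", i))
    }
  }
})
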