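# A 2x2 grid of square cells: frame at rows/cols 5 and 35, cross at 20.
grid_skeleton <- function() {
  m <- matrix(0L, 40, 40)
  m[5, 5:35] <- 1L; m[35, 5:35] <- 1L
  m[5:35, 5] <- 1L; m[5:35, 35] <- 1L
  m[20, 5:35] <- 1L
  m[5:35, 20] <- 1L
  skeleton_map(m)
}

test_that("cell labelling counts regions and flags border cells", {
  sq <- matrix(0L, 30, 30)
  sq[10, 10:20] <- 1L; sq[20, 10:20] <- 1L
  sq[10:20, 10] <- 1L; sq[10:20, 20] <- 1L
  lab <- label_cells(skeleton_map(sq))
  expect_equal(lab$n_cells, 2)       # inside + outside
  expect_equal(sum(lab$border), 1)   # only the outside touches the border

  lab2 <- label_cells(grid_skeleton())
  expect_equal(lab2$n_cells, 5)      # 4 cells + exterior
  expect_equal(sum(lab2$border), 1)

  empty <- label_cells(skeleton_map(matrix(0L, 20, 20)))
  expect_equal(empty$n_cells, 1)
})

test_that("corner detection finds tricellular meeting points only", {
  # four quadrants meeting at the centre: one corner with 4 cells
  cross <- matrix(0L, 41, 41)
  cross[21, ] <- 1L
  cross[, 21] <- 1L
  sk <- skeleton_map(cross)
  lab <- label_cells(sk)
  corners <- detect_corners(sk, lab, radius = 2L)
  expect_equal(nrow(corners), 1)
  expect_equal(corners$n_cells, 4)
  expect_equal(c(corners$row, corners$col), c(21, 21))

  # two cells and one straight boundary: no corner can exist
  line <- matrix(0L, 30, 30)
  line[15, ] <- 1L
  skl <- skeleton_map(line)
  expect_equal(nrow(detect_corners(skl, label_cells(skl))), 0)
})

test_that("manual corner adjustment appends, removes, and validates", {
  sk <- grid_skeleton()
  lab <- label_cells(sk)
  corners <- detect_corners(sk, lab)
  n0 <- nrow(corners)
  same <- adjust_corners(corners, sk, lab)
  expect_equal(nrow(same), n0)

  added <- adjust_corners(corners, sk, lab,
                          additions = rbind(c(20L, 12L)))
  expect_equal(nrow(added), n0 + 1)
  expect_true("manual" %in% added$source)
  expect_error(adjust_corners(corners, sk, lab,
                              additions = rbind(c(2L, 2L))),
               "off the skeleton")
  expect_error(adjust_corners(corners, sk, lab, removals = 999L),
               "unknown corner id")

  # adding a mid-path corner splits that interface into two (on a larger
  # grid so both halves stay above the corner-zone footprint)
  big <- matrix(0L, 60, 60)
  big[5, 5:55] <- 1L; big[55, 5:55] <- 1L
  big[5:55, 5] <- 1L; big[5:55, 55] <- 1L
  big[30, 5:55] <- 1L; big[5:55, 30] <- 1L
  bsk <- skeleton_map(big)
  blab <- label_cells(bsk)
  bc <- detect_corners(bsk, blab)
  badd <- adjust_corners(bc, bsk, blab, additions = rbind(c(30L, 15L)))
  n_meas <- function(x) sum(vapply(x, function(r) r$flag == "", logical(1)))
  before <- extract_interfaces(bsk, bc, blab)
  after <- extract_interfaces(bsk, badd, blab)
  expect_equal(n_meas(after), n_meas(before) + 1)
})

test_that("interface extraction recovers the grid topology and is deterministic", {
  sk <- grid_skeleton()
  lab <- label_cells(sk)
  corners <- detect_corners(sk, lab)
  recs <- extract_interfaces(sk, corners, lab)
  meas <- Filter(function(r) r$flag == "", recs)
  expect_equal(length(meas), 4)      # the four arms of the centre cross
  for (r in meas) {
    expect_equal(length(r$cell_pair), 2)
    expect_lt(r$corner_a, r$corner_b)
    steps <- abs(diff(r$path))
    expect_true(all(pmax(steps[, 1L], steps[, 2L]) == 1L))
    # path runs corner to corner
    expect_true(all(r$path[1L, ] ==
                      c(corners$row[r$corner_a], corners$col[r$corner_a])))
    expect_true(all(r$path[nrow(r$path), ] ==
                      c(corners$row[r$corner_b], corners$col[r$corner_b])))
  }
  keys <- vapply(meas, function(r)
    paste(r$corner_a, r$corner_b, paste(r$cell_pair, collapse = "-")),
    character(1))
  expect_false(any(duplicated(keys)))

  recs2 <- extract_interfaces(sk, corners, lab)
  expect_identical(recs, recs2)
})

test_that("one straight path between two manual corners yields one interface", {
  m <- matrix(0L, 30, 60)
  m[15, 10:50] <- 1L
  sk <- skeleton_map(m)
  lab <- label_cells(sk)
  corners <- adjust_corners(detect_corners(sk, lab), sk, lab,
                            additions = rbind(c(15L, 10L), c(15L, 50L)))
  recs <- extract_interfaces(sk, corners, lab, exclude_border = FALSE)
  meas <- Filter(function(r) r$flag %in% c("", "no_cell_pair"), recs)
  expect_equal(length(meas), 1)
  expect_equal(nrow(meas[[1]]$path), 41)
})

test_that("junction classification follows the expression mask and >= rule", {
  sk <- grid_skeleton()
  lab <- label_cells(sk)
  corners <- detect_corners(sk, lab)
  recs <- extract_interfaces(sk, corners, lab)

  zero <- classify_junctions(recs, lab, matrix(0L, 40, 40))
  for (r in Filter(function(r) r$flag == "", zero))
    expect_equal(r$junction_class, "control")

  # mark the two upper cells as expressing
  upper <- lab$labels[12, 12]
  upper2 <- lab$labels[12, 28]
  mask <- matrix(0L, 40, 40)
  mask[lab$labels %in% c(upper, upper2)] <- 1L
  cls <- classify_junctions(recs, lab, mask, min_fraction = 0.5)
  for (r in Filter(function(r) r$flag == "", cls)) {
    n_exp <- sum(r$cell_pair %in% c(upper, upper2))
    expect_equal(r$junction_class, c("control", "en", "ee")[n_exp + 1])
  }

  # coverage exactly at min_fraction counts as expressing
  half <- matrix(0L, 40, 40)
  cellpx <- which(lab$labels == upper)
  half[cellpx[seq_len(ceiling(length(cellpx) / 2))]] <- 1L
  frac <- sum(half[lab$labels == upper]) / length(cellpx)
  cls2 <- classify_junctions(recs, lab, half, min_fraction = frac)
  touched <- Filter(function(r) r$flag == "" & upper %in% r$cell_pair, cls2)
  expect_true(all(vapply(touched, function(r) r$junction_class, "") == "en"))

  expect_error(classify_junctions(recs, lab, matrix(0L, 10, 10)), "shape")
})

test_that("Voronoi scene topology is recovered exactly at small scale", {
  sc <- cached_scene("clean16", scene_spec(n_cells = 16, seed = 5,
                                           width = 320L, height = 320L))
  jm <- junction_map(sc$image, threshold = 50, dilation = 2)
  intr <- Filter(function(e) e$interior, sc$truth$edges)
  meas <- Filter(function(r) r$flag == "", jm$interfaces)
  expect_equal(length(meas), length(intr))
  # handshake: every measured interface has two corners; incidence sums
  inc <- table(unlist(lapply(meas, function(r) c(r$corner_a, r$corner_b))))
  expect_equal(sum(inc), 2 * length(meas))
})
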