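test_that("edge detection finds a bright line and ignores flat images", {
  flat <- raster_image(matrix(77, 64, 64))
  expect_true(all(detect_edges(flat) == 0L))

  img <- matrix(10, 80, 80)
  img[39:41, 10:70] <- 200           # 3-px horizontal line
  em <- detect_edges(raster_image(img))
  line <- matrix(0L, 80, 80)
  line[40, 10:70] <- 1L
  near <- junctmorph:::dilate_chebyshev(em, 1L)
  expect_gte(mean(near[line == 1L]), 0.95)
  bg <- em
  bg[35:45, ] <- 0L
  expect_lt(mean(bg), 0.01)
  expect_error(detect_edges(raster_image(img), local_window = 20L))
})

test_that("skeletonization thins to one pixel width and prunes artifacts", {
  band <- matrix(0L, 40, 80)
  band[18:22, 10:59] <- 1L           # 5-px wide band, length 50
  sk <- skeletonize(band, prune_len = 0L)
  # open band ends retract by about half the band width under thinning
  expect_true(sum(sk$pixels) >= 42 && sum(sk$pixels) <= 52)
  rowsused <- unique(which(sk$pixels == 1L, arr.ind = TRUE)[, 1L])
  expect_lte(length(rowsused), 2)    # essentially one horizontal path
  m <- sk$pixels
  blocks <- m[-nrow(m), -ncol(m)] & m[-1, -ncol(m)] &
    m[-nrow(m), -1] & m[-1, -1]
  expect_false(any(blocks))

  # idempotence on an already-thin path (up to pruning)
  path <- matrix(0L, 30, 30)
  path[15, 5:25] <- 1L
  expect_identical(skeletonize(path, prune_len = 0L)$pixels, path)

  # filled '+' cross: exactly one branch pixel (>= 3 separated arms)
  cross <- matrix(0L, 41, 41)
  cross[20:22, 5:37] <- 1L
  cross[5:37, 20:22] <- 1L
  skc <- skeletonize(cross, prune_len = 0L)
  branch <- junctmorph:::crossing_number(skc$pixels) >= 3 &
    skc$pixels == 1L
  expect_equal(sum(branch), 1)
})

test_that("no produced skeleton contains a fully set 2x2 block", {
  set.seed(31)
  for (i in 1:12) {
    blob <- matrix(0L, 48, 48)
    for (j in 1:4) {
      r <- sample(8:40, 1); c <- sample(8:40, 1)
      blob[max(1, r - sample(2:6, 1)):min(48, r + sample(2:6, 1)),
           max(1, c - sample(2:6, 1)):min(48, c + sample(2:6, 1))] <- 1L
    }
    m <- skeletonize(blob)$pixels
    blocks <- m[-nrow(m), -ncol(m)] & m[-1, -ncol(m)] &
      m[-nrow(m), -1] & m[-1, -1]
    expect_false(any(blocks))
  }
})

test_that("edit scripts add and remove skeleton segments reproducibly", {
  m <- matrix(0L, 40, 40)
  m[20, 5:15] <- 1L
  m[20, 26:35] <- 1L
  sk <- skeleton_map(m)
  expect_identical(apply_edits(sk, edit_script())$pixels, sk$pixels)

  bridge <- edit_script(list(action = "add",
                             polyline = rbind(c(20L, 15L), c(20L, 26L))))
  bridged <- apply_edits(sk, bridge)
  expect_equal(max(junctmorph:::label8(bridged$pixels)), 1)
  expect_equal(max(junctmorph:::label8(sk$pixels)), 2)

  rm_script <- edit_script(list(action = "remove",
                                polyline = rbind(c(20L, 26L), c(20L, 35L))))
  removed <- apply_edits(sk, rm_script)
  expect_true(all(removed$pixels[, 25:40] == 0L))
  expect_identical(removed$pixels[20, 5:15], sk$pixels[20, 5:15])

  bad <- edit_script(list(action = "add",
                          polyline = rbind(c(1L, 1L), c(50L, 50L))))
  expect_error(apply_edits(sk, bad), "edit 1")

  # inverse edit restores the component count
  again <- apply_edits(bridged, rm_script)
  expect_equal(max(junctmorph:::label8(again$pixels)),
               max(junctmorph:::label8(removed$pixels)))

  path <- tempfile(fileext = ".txt")
  write_edit_script(bridge, path)
  back <- read_edit_script(path)
  expect_equal(back[[1]]$action, "add")
  expect_equal(back[[1]]$polyline, bridge[[1]]$polyline)
  unlink(path)
})

test_that("ridge refinement snaps to bright ridges and fixes ties", {
  img <- matrix(10, 40, 60)
  img[20, 5:55] <- 200               # bright 1-px ridge
  sk <- matrix(0L, 40, 60)
  sk[22, 5:55] <- 1L                 # skeleton offset 2 px below
  ref <- refine_skeleton(skeleton_map(sk), raster_image(img),
                         search_radius = 3L)
  pts <- which(ref$pixels == 1L, arr.ind = TRUE)
  on_ridge <- mean(abs(pts[, 1L] - 20) <= 0)
  expect_gte(on_ridge, 0.9)

  # already on the ridge: fixed point
  sk2 <- matrix(0L, 40, 60)
  sk2[20, 5:55] <- 1L
  ref2 <- refine_skeleton(skeleton_map(sk2), raster_image(img), 3L)
  expect_identical(ref2$pixels, sk2)

  # constant image: all ties, skeleton unchanged
  flat <- raster_image(matrix(50, 40, 60))
  ref3 <- refine_skeleton(skeleton_map(sk2), flat, 2L)
  expect_identical(ref3$pixels, sk2)
})
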