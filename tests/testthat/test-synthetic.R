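test_that("scene generation is byte-deterministic for a fixed seed", {
  sp <- scene_spec(n_cells = 12, seed = 21, width = 256L, height = 256L,
                   coverage_fraction = 0.7, noise_sigma = 8)
  a <- generate_monolayer(sp)
  b <- generate_monolayer(sp)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$truth$seeds, b$truth$seeds)
  expect_identical(a$truth$edges, b$truth$edges)
})

test_that("covered intervals realize the programmed coverage with resolvable gaps", {
  set.seed(2)
  for (cov in c(0.25, 0.5, 0.9)) {
    for (L in c(30, 80, 150)) {
      iv <- junctmorph:::covered_intervals(L, cov, 10)
      expect_equal(sum(iv[, 2] - iv[, 1]), cov * L, tolerance = 1e-9)
      if (nrow(iv) > 1) {
        gaps <- iv[-1, 1] - iv[-nrow(iv), 2]
        expect_true(all(gaps >= 2))
      }
    }
  }
  expect_equal(junctmorph:::covered_intervals(50, 1, 10), matrix(c(0, 50), 1))
  expect_equal(nrow(junctmorph:::covered_intervals(50, 0, 10)), 0)
})

test_that("full coverage with no undulation yields straight, covered truth", {
  sc <- cached_scene("clean16", scene_spec(n_cells = 16, seed = 5,
                                           width = 320L, height = 320L))
  for (e in sc$truth$edges) {
    expect_equal(e$coverage, 1)
    # continuous arc length equals the Euclidean endpoint distance
    expect_equal(e$arc_length, sqrt(sum((e$to - e$from)^2)),
                 tolerance = 1e-6)
  }
})

test_that("a 2x2 seed lattice dualizes to one interior corner and four edges", {
  # a slight asymmetry resolves the cocircular degeneracy; the two dual
  # vertices it creates are sub-pixel apart, i.e. one 4-way corner
  seeds <- rbind(c(30, 30), c(30, 70), c(70, 30), c(70, 71))
  geo <- junctmorph:::voronoi_geometry(seeds, 100, 100)
  v <- geo$vertices
  inside <- v[, 1] > 1 & v[, 1] < 100 & v[, 2] > 1 & v[, 2] < 100
  v <- v[inside, , drop = FALSE]
  expect_true(nrow(v) >= 1)
  expect_lt(max(dist(v)), 1.5)
  expect_equal(length(geo$edges), 4)
})

test_that("scene degradation hits the target PSNR and scales monotonically", {
  sc <- cached_scene("clean16", scene_spec(n_cells = 16, seed = 5,
                                           width = 320L, height = 320L))
  deg40 <- degrade_scene(sc$image, 40, seed = 2)
  expect_lt(abs(compute_psnr(sc$image, deg40) - 40), 0.5)
  deg22 <- degrade_scene(sc$image, 22, seed = 2)
  expect_lt(abs(compute_psnr(sc$image, deg22) - 22), 0.5)
  expect_gt(attr(deg22, "sigma"), attr(deg40, "sigma"))
  expect_error(degrade_scene(sc$image, 3, seed = 2), "unreachable")
})

test_that("expression masks mark whole cells and drive truth classes", {
  sc <- generate_monolayer(scene_spec(n_cells = 16, seed = 8, width = 320L,
                                      height = 320L,
                                      expressing_fraction = 0.4))
  expect_false(is.null(sc$expression_mask))
  expr <- sc$truth$expressing
  expect_equal(sum(expr), round(0.4 * 16))
  # the mask is exactly the union of expressing cells' pixels
  expect_identical(sc$expression_mask,
                   matrix(as.integer(expr[sc$truth$labels]), 320, 320))
  ti <- truth_interfaces(sc)
  for (r in ti) {
    n_exp <- sum(expr[r$cell_pair])
    expect_equal(r$junction_class, c("control", "en", "ee")[n_exp + 1])
  }
})

test_that("a second marker channel renders with its own photometry", {
  sc <- generate_monolayer(scene_spec(n_cells = 12, seed = 3, width = 256L,
                                      height = 256L,
                                      marker2 = list(staining_intensity = 120,
                                                     coverage_fraction = 0.5)))
  expect_false(is.null(sc$marker2))
  expect_equal(max(sc$marker2), 120)
  expect_identical(dim(sc$marker2), dim(sc$image))
})
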