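test_that("surface extraction counts boundary faces with exact areas", {
  g <- make_grid(c(3, 3, 3), c(1, 1, 1))
  occ <- array(FALSE, g$dims); occ[2, 2, 2] <- TRUE
  s <- extract_surface(structure_mask("v", g, occ))
  expect_equal(nrow(s$fine_index), 6)
  expect_equal(s$total_area_mm2, 6)

  occ2 <- array(FALSE, c(4, 3, 3)); occ2[2:3, 2, 2] <- TRUE
  g2 <- make_grid(c(4, 3, 3), c(1, 1, 1))
  s2 <- extract_surface(structure_mask("bar", g2, occ2))
  expect_equal(nrow(s2$fine_index), 10)
  expect_equal(s2$total_area_mm2, 10)

  # 10x10x10 voxels at (1,1,2) mm is a 10x10x20 mm box
  g3 <- make_grid(c(12, 12, 12), c(1, 1, 2))
  s3 <- extract_surface(box_mask(g3, c(2, 2, 2), c(11, 11, 11)))
  expect_equal(s3$total_area_mm2, 2 * (10 * 10 + 10 * 20 + 10 * 20))
  expect_error(extract_surface(structure_mask("e", g3)), "empty")
})

test_that("masks touching the grid boundary contribute grid-edge faces", {
  g <- make_grid(c(4, 4, 4), c(1, 1, 1))
  s <- extract_surface(box_mask(g, c(1, 1, 1), c(4, 4, 4)))
  expect_equal(s$total_area_mm2, 6 * 16)
})

test_that("surface dice boundary values: identity gives 1, far apart gives 0", {
  g <- make_grid(c(50, 50, 50), c(1, 1, 1))
  s <- sphere_mask(g, c(0, 0, 0), 20)
  for (tol in c(0, 3, 5))
    expect_identical(surface_dice(s, s, tol)$value, 1)
  g2 <- voxel_grid(c(120, 14, 14), c(1, 1, 1), origin = c(-8, -6.5, -6.5))
  a <- sphere_mask(g2, c(0, 0, 0), 5, "a")
  b <- sphere_mask(g2, c(100, 0, 0), 5, "b")
  expect_identical(surface_dice(a, b, 3)$value, 0)
})

test_that("surface dice validates its inputs", {
  g <- make_grid(c(10, 10, 10))
  m <- sphere_mask(g, c(0, 0, 0), 3)
  expect_error(surface_dice(m, structure_mask("e", g), 3), "empty")
  expect_error(surface_dice(m, m, -1), "nonnegative")
  g2 <- make_grid(c(10, 10, 10), c(2, 2, 2))
  expect_error(surface_dice(m, sphere_mask(g2, c(0, 0, 0), 3), 3), "grid")
})

test_that("surface dice equals the O(n^2) pairwise oracle on random masks", {
  for (seed in 1:12) {
    sp <- list(c(1, 1, 1), c(1, 1, 2), c(0.8, 1.2, 1.5))[[seed %% 3 + 1]]
    g <- make_grid(c(14, 12, 10), sp)
    a <- random_blob(g, 100 + seed, "a")
    b <- random_blob(g, 200 + seed, "b")
    for (tol in c(1, 2.5, 4)) {
      expect_equal(surface_dice(a, b, tol)$value,
                   bf_surface_dice(a, b, tol), tolerance = 1e-12)
    }
  }
})

test_that("surface dice is symmetric, tolerance-monotone and shift-invariant", {
  g <- make_grid(c(16, 14, 12), c(1, 1.5, 2))
  for (seed in 1:6) {
    a <- random_blob(g, 300 + seed, "a")
    b <- random_blob(g, 400 + seed, "b")
    vals <- vapply(c(0, 1, 2, 4, 8), function(tol) {
      f <- surface_dice(a, b, tol)
      r <- surface_dice(b, a, tol)
      expect_equal(f$value, r$value, tolerance = 1e-12)
      expect_gte(f$value, 0); expect_lte(f$value, 1)
      f$value
    }, 0)
    expect_true(all(diff(vals) >= 0))
  }
  # common integer-voxel translation leaves the value unchanged
  g2 <- make_grid(c(20, 18, 16), c(1, 1, 2))
  a <- random_blob(make_grid(c(12, 10, 8), c(1, 1, 2)), 7, "a")
  b <- random_blob(make_grid(c(12, 10, 8), c(1, 1, 2)), 8, "b")
  embed <- function(m, off) {
    occ <- array(FALSE, g2$dims)
    occ[off[1] + 1:12, off[2] + 1:10, off[3] + 1:8] <- m$occupancy
    structure_mask(m$label, g2, occ)
  }
  v0 <- surface_dice(embed(a, c(0, 0, 0)), embed(b, c(0, 0, 0)), 3)$value
  v1 <- surface_dice(embed(a, c(5, 4, 6)), embed(b, c(5, 4, 6)), 3)$value
  expect_equal(v0, v1, tolerance = 1e-12)
})

test_that("sdsc_table layout, summary rows and missing-label handling", {
  g <- make_grid(c(14, 14, 14))
  ref <- structure_set("ref", list(random_blob(g, 1, "CTV"),
                                   random_blob(g, 2, "CTVN")))
  obs <- list(
    structure_set("A", list(random_blob(g, 1, "CTV"),
                            random_blob(g, 2, "CTVN"))),
    structure_set("B", list(random_blob(g, 3, "CTV"),
                            random_blob(g, 4, "CTVN"))))
  tab <- sdsc_table(obs, ref, c("CTV", "CTVN"), tolerances_mm = c(3, 5))
  # identical observer scores 1 everywhere
  expect_true(all(tab$sdsc[tab$observer == "A"] == 1))
  # summary rows recompute from the individual entries
  for (lab in c("CTV", "CTVN")) for (tol in c(3, 5)) {
    ind <- tab$sdsc[tab$structure == lab & tab$tolerance_mm == tol &
                      !tab$observer %in% c("Mean value", "Median value")]
    expect_equal(tab$sdsc[tab$structure == lab & tab$tolerance_mm == tol &
                            tab$observer == "Mean value"], mean(ind))
    expect_equal(tab$sdsc[tab$structure == lab & tab$tolerance_mm == tol &
                            tab$observer == "Median value"], median(ind))
    expect_equal(median(ind), mean(ind[order(ind)][1:2]))  # n = 2 median
  }
  # missing label: NA row plus warning; reference must be complete
  obs2 <- c(obs, list(structure_set("C", list(random_blob(g, 5, "CTV")))))
  expect_warning(tab2 <- sdsc_table(obs2, ref, c("CTVN"), 3), "no structure")
  expect_true(is.na(tab2$sdsc[tab2$observer == "C"]))
  expect_error(sdsc_table(obs, ref, c("CTV", "missing"), 3), "lacks")
})
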