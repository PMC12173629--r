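test_that("volume_cc counts whole voxels", {
  g <- make_grid(c(20, 20, 20), c(2, 2, 2))
  empty <- structure_mask("e", g)
  expect_equal(volume_cc(empty), 0)
  m <- box_mask(g, c(1, 1, 1), c(10, 10, 10))  # 1000 voxels at 8 mm^3
  expect_equal(volume_cc(m), 8)
})

test_that("rasterized sphere volume is within 2% of the closed form", {
  g <- make_grid(c(60, 60, 60), c(1, 1, 1))
  s <- sphere_mask(g, c(0, 0, 0), 20)
  expect_lt(abs(volume_cc(s) - 4 / 3 * pi * 20^3 / 1000) /
              (4 / 3 * pi * 20^3 / 1000), 0.02)
})

test_that("expand_mask handles trivial margins and rejects negatives", {
  g <- make_grid(c(20, 20, 20))
  m <- sphere_mask(g, c(0, 0, 0), 5)
  expect_identical(expand_mask(m, 0)$occupancy, m$occupancy)
  e <- structure_mask("e", g)
  expect_true(all(!expand_mask(e, 7)$occupancy))
  expect_error(expand_mask(m, -1), "nonnegative")
})

test_that("expand_mask is monotone, a superset, and matches the analytic ball", {
  g <- make_grid(c(60, 60, 60), c(1, 1, 1))
  s <- sphere_mask(g, c(0, 0, 0), 20)
  prev <- s
  for (margin in c(1, 2.5, 5)) {
    cur <- expand_mask(s, margin)
    expect_true(all(cur$occupancy[prev$occupancy]))  # superset of smaller margin
    prev <- cur
  }
  e5 <- expand_mask(s, 5)
  expect_lt(abs(volume_cc(e5) - 4 / 3 * pi * 25^3 / 1000) /
              (4 / 3 * pi * 25^3 / 1000), 0.02)
})

test_that("expand_mask honours anisotropic spacing", {
  g <- make_grid(c(21, 21, 11), c(1, 1, 2))
  occ <- array(FALSE, g$dims); occ[11, 11, 6] <- TRUE
  m <- structure_mask("pt", g, occ)
  e <- expand_mask(m, 4)
  # voxel 2 slices away in z is 4 mm away: included; 3 slices = 6 mm: not
  expect_true(e$occupancy[11, 11, 8])
  expect_false(e$occupancy[11, 11, 9])
  expect_true(e$occupancy[15, 11, 6])  # 4 mm in x
  expect_false(e$occupancy[16, 11, 6])
})

test_that("union matches inclusion-exclusion voxel counting", {
  g <- make_grid(c(40, 40, 40), c(1, 1, 1))
  a <- sphere_mask(g, c(-5, 0, 0), 10, "a")
  b <- sphere_mask(g, c(5, 0, 0), 10, "b")
  u <- union_masks(list(a, b))
  inter <- sum(a$occupancy & b$occupancy)
  expect_equal(sum(u$occupancy), sum(a$occupancy) + sum(b$occupancy) - inter)
  expect_identical(union_masks(list(a, a))$occupancy, a$occupancy)
  g2 <- make_grid(c(40, 40, 40), c(2, 2, 2))
  expect_error(union_masks(list(a, sphere_mask(g2, c(0, 0, 0), 10))),
               "grid")
})

test_that("border extents match an exhaustive scan and resolve laterality", {
  g <- make_grid(c(30, 30, 30), c(1, 1, 1), origin = c(0, 0, 40))
  occ <- array(FALSE, g$dims); occ[11, 1, 11] <- TRUE
  m <- structure_mask("pt", g, occ)
  b <- border_extents(m, "left")
  expect_equal(b$cranial_mm, 50); expect_equal(b$caudal_mm, 50)
  expect_equal(b$medial_mm, 10); expect_equal(b$lateral_mm, 10)

  for (seed in 1:5) {
    blob <- random_blob(make_grid(c(18, 15, 12), c(1, 2, 2.5)), seed)
    be <- border_extents(blob, "left")
    w <- index_to_world(blob$grid, which(blob$occupancy, arr.ind = TRUE))
    expect_equal(be$cranial_mm, max(w[, 3]))
    expect_equal(be$caudal_mm, min(w[, 3]))
    expect_equal(be$lateral_mm, max(w[, 1]))
    expect_equal(be$medial_mm, min(w[, 1]))
    br <- border_extents(blob, "right")
    expect_equal(br$lateral_mm, min(w[, 1]))
    expect_equal(br$medial_mm, max(w[, 1]))
  }
  expect_error(border_extents(structure_mask("e", g), "left"), "empty")
})

test_that("a 27 mm cranial offset between observers reads as 2.70 cm", {
  g <- make_grid(c(40, 40, 70), c(1, 1, 1))
  a <- sphere_mask(g, c(0, 0, -14), 10, "CTV")
  b <- sphere_mask(g, c(0, 0, 13), 10, "CTV")
  sets <- list(structure_set("A", list(a)), structure_set("B", list(b)))
  tab <- border_difference_table(sets, "CTV", borders = "cranial")
  expect_equal(tab$max_difference_cm, 2.70)
})

test_that("border differences equal the pairwise brute-force scan", {
  g <- make_grid(c(20, 16, 14), c(1.5, 2, 2.5))
  sets <- lapply(1:5, function(i)
    structure_set(paste0("o", i), list(random_blob(g, 50 + i, "CTV"))))
  tab <- border_difference_table(sets, "CTV")
  for (bi in seq_len(nrow(tab))) {
    fld <- paste0(tab$border[bi], "_mm")
    vals <- vapply(sets, function(s)
      border_extents(s$masks[["CTV"]], "left")[[fld]], 0)
    bf <- max(vapply(seq_along(vals), function(i)
      max(abs(vals[i] - vals)), 0)) / 10
    expect_equal(tab$max_difference_cm[bi], bf)
  }
})

test_that("observers missing the structure are skipped with a warning", {
  g <- make_grid(c(20, 20, 20))
  a <- sphere_mask(g, c(0, 0, 0), 6, "CTV")
  sets <- list(structure_set("A", list(a)),
               structure_set("B", list(a)),
               structure_set("C", list(sphere_mask(g, c(0, 0, 0), 6, "other"))))
  expect_warning(tab <- border_difference_table(sets, "CTV"), "skipped")
  expect_true(all(tab$max_difference_cm == 0))
})

test_that("nearest-neighbour resampling is identity on the same grid and maps centres", {
  g <- make_grid(c(20, 20, 20), c(2, 2, 2))
  m <- sphere_mask(g, c(0, 0, 0), 12)
  expect_identical(resample_mask(m, g), m)
  fine <- make_grid(c(40, 40, 40), c(1, 1, 1),
                    origin = g$origin)
  r <- resample_mask(m, fine)
  idx <- which(r$occupancy, arr.ind = TRUE)
  w <- index_to_world(fine, idx)
  src_idx <- round(sweep(sweep(w, 2, g$origin, `-`), 2, g$spacing, `/`)) + 1
  keep <- apply(src_idx >= 1 & sweep(src_idx, 2, g$dims, `<=`), 1, all)
  expect_true(all(m$occupancy[src_idx[keep, , drop = FALSE]]))
})
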