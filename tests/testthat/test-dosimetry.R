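rx <- 40.05

test_that("trilinear dose resampling is exact on affine fields", {
  g <- make_grid(c(12, 10, 8), c(2, 2, 3))
  ramp <- function(gr) {
    co <- expand.grid(x = axis_coords(gr, 1), y = axis_coords(gr, 2),
                      z = axis_coords(gr, 3))
    array(2 + 0.1 * co$x + 0.05 * co$y + 0.2 * co$z + 30, gr$dims)
  }
  d <- dose_grid(g, ramp(g), prescription_gy = rx)
  expect_identical(resample_dose(d, g), d)
  tgt <- voxel_grid(c(15, 10, 8), c(1.3, 1.7, 2.1),
                    origin = g$origin + c(1, 1, 1))
  r <- resample_dose(d, tgt)
  expect_equal(r$dose, ramp(tgt), tolerance = 1e-10)
  const <- dose_grid(g, array(7, g$dims), prescription_gy = rx)
  expect_true(all(abs(resample_dose(const, tgt)$dose - 7) < 1e-12))
  far <- voxel_grid(c(5, 5, 5), c(1, 1, 1), origin = g$origin + 1000)
  expect_error(resample_dose(d, far), "disjoint")
})

test_that("resampling outside the dose extent yields 0 Gy with a warning", {
  g <- make_grid(c(8, 8, 8), c(2, 2, 2))
  d <- dose_grid(g, array(5, g$dims), prescription_gy = rx)
  big <- voxel_grid(c(12, 8, 8), c(2, 2, 2), origin = g$origin - c(6, 0, 0))
  expect_warning(r <- resample_dose(d, big), "outside")
  expect_true(all(r$dose[1:3, , ] == 0))
  expect_true(all(r$dose[4:11, , ] == 5))
})

test_that("DVH curves are cumulative at-or-above and match direct counting", {
  g <- make_grid(c(10, 10, 10))
  m <- box_mask(g, c(1, 1, 1), c(10, 10, 10))
  u <- dose_grid(g, array(rx, g$dims), prescription_gy = rx)
  dvh <- compute_dvh(u, m, bin_gy = 0.5)
  expect_true(all(dvh$percent[dvh$dose_gy <= rx] == 100))
  expect_true(all(dvh$percent[dvh$dose_gy > rx] == 0))
  expect_equal(dvh$volume_cc, volume_cc(m))

  occ <- array(FALSE, g$dims); occ[1:2, 1, 1] <- TRUE
  two <- structure_mask("two", g, occ)
  dd <- array(0, g$dims); dd[1, 1, 1] <- 10; dd[2, 1, 1] <- 30
  d2 <- dose_grid(g, dd, prescription_gy = rx)
  dvh2 <- compute_dvh(d2, two, bin_gy = 1)
  expect_equal(dvh2$percent[dvh2$dose_gy == 20], 50)

  rdose <- random_dose(g, 42)
  dvh3 <- compute_dvh(rdose, m, bin_gy = 0.37)
  dv <- rdose$dose[m$occupancy]
  for (k in seq(1, length(dvh3$dose_gy), by = 7)) {
    expect_equal(dvh3$percent[k], 100 * mean(dv >= dvh3$dose_gy[k]))
    expect_equal(dvh3$cc[k],
                 sum(dv >= dvh3$dose_gy[k]) * voxel_volume_mm3(g) / 1000)
  }
  expect_true(all(diff(dvh3$percent) <= 0))
  expect_error(compute_dvh(u, structure_mask("e", g)), "empty")
})

test_that("Dmean, VxGy and Dp% match voxel-level oracles exactly", {
  g <- make_grid(c(9, 9, 9), c(2, 2, 2))
  m <- sphere_mask(g, c(0, 0, 0), 7)
  d <- random_dose(g, 7)
  dv <- d$dose[m$occupancy]

  expect_equal(d_mean(d, m), sum(dv) / length(dv))

  half <- array(0, g$dims); half[5:8, , ] <- 4  # half 0 Gy, half 4 Gy
  dh <- dose_grid(g, half, prescription_gy = rx)
  mfull <- box_mask(g, c(1, 1, 1), c(8, 9, 9))
  expect_equal(d_mean(dh, mfull), 2)

  expect_equal(v_dose(d, m, threshold_gy = 0), 100)
  expect_equal(v_dose(d, m, threshold_gy = 17),
               100 * sum(dv >= 17) / length(dv))
  expect_equal(v_dose(d, m, threshold_gy = 17, output = "cc"),
               sum(dv >= 17) * 8 / 1000)
  expect_equal(v_dose(d, m, threshold_pct = 105),
               100 * sum(dv >= 1.05 * rx) / length(dv))
  expect_equal(v_dose(d, m, threshold_gy = 17, strict = TRUE, output = "cc"),
               sum(dv > 17) * 8 / 1000)
  low <- dose_grid(g, array(3, g$dims), prescription_gy = rx)
  expect_equal(v_dose(low, m, threshold_gy = 5), 0)
  expect_error(v_dose(d, structure_mask("e", g), threshold_gy = 5), "empty")
  expect_error(v_dose(d, m), "exactly one")

  u <- dose_grid(g, array(rx, g$dims), prescription_gy = rx)
  expect_equal(d_percent_coverage(u, m, 98), 100)
  u95 <- dose_grid(g, array(0.95 * rx, g$dims), prescription_gy = rx)
  expect_equal(d_percent_coverage(u95, m, 98), 95)
  # independent oracle: largest dose with at-or-above fraction >= p
  for (p in c(2, 50, 98)) {
    cand <- sort(unique(dv))
    ok <- cand[vapply(cand, function(t) mean(dv >= t) >= p / 100, TRUE)]
    expect_equal(d_percent_coverage(d, m, p), 100 * max(ok) / rx)
  }
  expect_gte(d_percent_coverage(d, m, 2), d_percent_coverage(d, m, 50))
  expect_gte(d_percent_coverage(d, m, 50), d_percent_coverage(d, m, 98))
  expect_error(d_percent_coverage(d, m, 0), "0, 100")
})

test_that("dose scaling maps every metric linearly", {
  g <- make_grid(c(8, 8, 8))
  m <- random_blob(g, 9)
  d <- random_dose(g, 10)
  c_ <- 0.6
  ds <- dose_grid(g, c_ * d$dose, prescription_gy = rx)
  expect_equal(d_mean(ds, m), c_ * d_mean(d, m))
  expect_equal(d_percent_coverage(ds, m, 98),
               c_ * d_percent_coverage(d, m, 98))
  expect_equal(v_dose(ds, m, threshold_gy = c_ * 12),
               v_dose(d, m, threshold_gy = 12))
})

test_that("ICRU treated/irradiated volumes behave and match counting", {
  g <- make_grid(c(10, 10, 10), c(2, 2, 2))
  body <- sphere_mask(g, c(0, 0, 0), 9, "Body")
  zero <- dose_grid(g, array(0, g$dims), prescription_gy = rx)
  expect_equal(icru_volumes(zero, body), list(treated_cc = 0,
                                              irradiated_cc = 0))
  u <- dose_grid(g, array(rx, g$dims), prescription_gy = rx)
  iu <- icru_volumes(u, body)
  expect_equal(iu$treated_cc, volume_cc(body))
  expect_equal(iu$irradiated_cc, volume_cc(body))
  d <- random_dose(g, 21)
  i <- icru_volumes(d, body)
  dv <- d$dose[body$occupancy]
  expect_equal(i$treated_cc, sum(dv >= 0.9 * rx) * 8 / 1000)
  expect_equal(i$irradiated_cc, sum(dv >= 0.5 * rx) * 8 / 1000)
  expect_lte(i$treated_cc, i$irradiated_cc)
  expect_lte(i$irradiated_cc, volume_cc(body))
})

test_that("irradiated volume outside the PTV uses a strict 90% threshold", {
  g <- make_grid(c(10, 10, 10), c(2, 2, 2))
  body <- box_mask(g, c(1, 1, 1), c(10, 10, 10), "Body")
  ptv <- box_mask(g, c(1, 1, 1), c(5, 10, 10), "PTV")
  u <- dose_grid(g, array(rx, g$dims), prescription_gy = rx)
  expect_equal(irradiated_outside_ptv(u, ptv, body), volume_cc(body) / 2)
  confined <- array(0, g$dims); confined[1:5, , ] <- rx
  expect_equal(irradiated_outside_ptv(dose_grid(g, confined, prescription_gy = rx),
                                      ptv, body), 0)
  # exactly 90% of prescription does NOT count (strict >)
  at90 <- dose_grid(g, array(0.9 * rx, g$dims), prescription_gy = rx)
  expect_equal(irradiated_outside_ptv(at90, ptv, body), 0)
  expect_equal(irradiated_outside_ptv(at90, ptv, body, strict = FALSE),
               volume_cc(body) / 2)
  d <- random_dose(g, 33)
  outside <- body$occupancy & !ptv$occupancy
  expect_equal(irradiated_outside_ptv(d, ptv, body),
               sum(d$dose[outside] > 0.9 * rx) * 8 / 1000)
})

test_that("coverage verdicts pass at or above threshold and flag missing structures", {
  g <- make_grid(c(12, 12, 12), c(2, 2, 2))
  ptv <- sphere_mask(g, c(0, 0, 0), 8, "PTV-breast+PTVN")
  masks <- list("CTV-breast+CTVN" = sphere_mask(g, c(0, 0, 0), 6,
                                                "CTV-breast+CTVN"),
                "PTV-breast+PTVN" = ptv)
  exact <- array(0, g$dims); exact[ptv$occupancy] <- rx
  d <- dose_grid(g, exact, prescription_gy = rx)
  rep1 <- coverage_report(d, masks)
  expect_true(all(rep1$pass[rep1$structure %in% names(masks)]))
  expect_true(is.na(rep1$pass[rep1$structure == "CTV-IMN"]))
  expect_equal(rep1$achieved_pct[rep1$structure == "CTV-breast+CTVN"], 100)

  dhalf <- dose_grid(g, 0.5 * exact, prescription_gy = rx)
  rep2 <- coverage_report(dhalf, masks)
  expect_false(any(rep2$pass[rep2$structure %in% names(masks)]))

  # exact equality with the threshold counts as a pass (38 Gy is exactly
  # 95% of a 40 Gy prescription in floating point)
  d95 <- dose_grid(g, array(38, g$dims), prescription_gy = 40)
  rep3 <- coverage_report(d95, masks)
  expect_true(rep3$pass[rep3$structure == "CTV-breast+CTVN"])
  expect_equal(rep3$achieved_pct[rep3$structure == "CTV-breast+CTVN"], 95)
})
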