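# Uptake scans, carbon-nitrogen coordination, and growth-bound scans.

test_that("two-stage coordination reproduces the hand LP answers", {
  t3 <- make_toy("two_substrate")
  cc0 <- coordinate_carbon_nitrogen(t3, v_nh4 = 0,
                                    n_exchange = "EX_N", c_exchange = "EX_C")
  expect_equal(cc0$v_gro_max, 0)
  expect_equal(cc0$v_glc_min, 0)
  cc5 <- coordinate_carbon_nitrogen(t3, v_nh4 = 5,
                                    n_exchange = "EX_N", c_exchange = "EX_C")
  expect_equal(cc5$v_gro_max, 5)
  expect_equal(cc5$v_glc_min, 5)
  # nitrogen in excess: carbon becomes limiting
  cc20 <- coordinate_carbon_nitrogen(t3, v_nh4 = 20,
                                     n_exchange = "EX_N", c_exchange = "EX_C")
  expect_equal(cc20$v_gro_max, 10)
  expect_equal(cc20$v_glc_min, 10)
  expect_error(coordinate_carbon_nitrogen(t3, v_nh4 = -1,
                                          n_exchange = "EX_N",
                                          c_exchange = "EX_C"),
               "non-negative")
})

test_that("coordinated glucose minimum rises with nitrogen, then saturates", {
  t3 <- make_toy("two_substrate")
  grid <- c(1, 3, 5, 8, 10, 12, 15, 20)
  vmin <- vapply(grid, function(n)
    coordinate_carbon_nitrogen(t3, v_nh4 = n, n_exchange = "EX_N",
                               c_exchange = "EX_C")$v_glc_min, numeric(1))
  expect_true(all(diff(vmin) >= -1e-9))
  expect_equal(vmin[grid >= 10], rep(10, sum(grid >= 10)))
})

test_that("uptake scans return one components row per feasible grid point", {
  t3 <- make_toy("two_substrate")
  ref <- compute_reference_ranges(t3)
  sc <- scan_uptake(t3, exchange_id = "EX_N", grid = c(2, 5, 15),
                    reference = ref)
  expect_identical(nrow(sc), 3L)
  expect_true(all(sc$feasible))
  expect_equal(sc$delta_tot,
               sc$delta_int + sc$delta_ext + sc$delta_gro, tolerance = 1e-9)
  # a maintenance demand makes very low uptake infeasible: flagged row
  t1m <- make_toy("chain", maintenance = 1)
  ref1 <- compute_reference_ranges(t1m)
  sc1 <- scan_uptake(t1m, exchange_id = "EX_A", grid = c(0.5, 2, 5),
                     reference = ref1)
  expect_identical(sc1$feasible, c(FALSE, TRUE, TRUE))
  expect_true(is.na(sc1$delta_tot[1]))
  expect_error(scan_uptake(t1m, exchange_id = "EX_A", grid = c(0.2, 0.5),
                           reference = ref1), "every grid point")
  expect_error(scan_uptake(t3, exchange_id = "EX_N", grid = c(5, 2)),
               "strictly increasing")
  expect_warning(scan_uptake(t3, exchange_id = "EX_C", grid = c(5, 12),
                             reference = ref),
                 "beyond the medium uptake limit")
})

test_that("carbon-nitrogen coordination collapses internal and external variability", {
  t3 <- make_toy("two_substrate")
  ref <- compute_reference_ranges(t3)
  grid <- c(2, 5, 8)                      # below nitrogen saturation
  free <- scan_uptake(t3, exchange_id = "EX_N", grid = grid, reference = ref)
  coord <- scan_uptake(t3, exchange_id = "EX_N", grid = grid,
                       coordinate_cn = TRUE, c_exchange = "EX_C",
                       reference = ref)
  expect_true(all(free$delta_int + free$delta_ext > 0))
  expect_true(all(coord$delta_int <= 1e-6))
  expect_true(all(coord$delta_ext <= 1e-6))
  # growth variability survives coordination
  expect_true(all(coord$delta_gro > 0))
})

test_that("growth-bound scans reproduce the branched-toy goldens", {
  t2 <- make_toy("branched")
  ref <- compute_reference_ranges(t2)
  both <- scan_growth_bounds(t2, mode = "both_bounds", fractions = 0.5,
                             reference = ref)
  expect_equal(both$delta_tot, 0.375, tolerance = 1e-6)
  lower <- scan_growth_bounds(t2, mode = "lower_bound",
                              fractions = c(0, 0.5), reference = ref)
  expect_equal(lower$delta_tot, c(1, 0.875), tolerance = 1e-6)
  upper <- scan_growth_bounds(t2, mode = "upper_bound", fractions = 1,
                              reference = ref)
  expect_equal(upper$delta_tot, 1, tolerance = 1e-6)
})

test_that("variability falls as the growth lower bound rises, and rises with uptake", {
  t2 <- make_toy("branched")
  ref <- compute_reference_ranges(t2)
  lower <- scan_growth_bounds(t2, mode = "lower_bound",
                              fractions = c(0, 0.5, 1), reference = ref)
  expect_true(all(diff(lower$delta_tot) <= 1e-9))
  glc <- scan_growth_bounds(t2, mode = "glucose_limited",
                            glucose_exchange = "EX_A",
                            glucose_grid = c(2, 6, 10), reference = ref)
  expect_true(all(diff(glc$delta_tot) >= -1e-9))
  expect_equal(glc$fraction, c(0.2, 0.6, 1))
})
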