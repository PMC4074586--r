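# Delta and Sigma measures and the internal/external/growth decomposition.

test_that("reference state records ranges and the admissible set", {
  t2 <- make_toy("branched")
  ref <- compute_reference_ranges(t2)
  internal <- ref$internal
  expect_setequal(internal, c("R1", "R2", "R3", "R4"))
  expect_equal(unname(ref$widths[internal]), rep(10, 4))
  expect_setequal(ref$admissible, internal)
  # closing the only source blocks everything; Delta must refuse
  t2c <- t2; t2c$upper_bounds[["EX_A"]] <- 0
  refc <- compute_reference_ranges(t2c)
  expect_length(refc$admissible, 0)
  expect_error(delta_measure(compute_reference_ranges(t2)$ranges, refc),
               "no variable internal reactions")
})

test_that("Delta is the average ratio of condition to reference widths", {
  t2 <- make_toy("branched")
  ref <- compute_reference_ranges(t2)
  expect_equal(delta_measure(ref$ranges, ref), 1)
  allfix <- solve_fva(t2, fixes = c(EX_A = 6, R1 = 6, R2 = 6, R3 = 0,
                                    R4 = 0, GRO = 6))
  expect_equal(delta_measure(allfix, ref), 0)
  # direct formula arithmetic on a fabricated reference
  fake_ref <- structure(list(admissible = c("a", "b"),
                             widths = c(a = 2, b = 4),
                             internal = c("a", "b")),
                        class = "reference_state")
  q <- structure(data.frame(reaction = c("a", "b"),
                            min = c(0, 0), max = c(1, 1)),
                 class = c("flux_ranges", "data.frame"))
  expect_equal(delta_measure(q, fake_ref), (1/2 + 1/4) / 2)
  expect_error(delta_measure(q[q$reaction == "a", ], fake_ref),
               "do not cover")
})

test_that("the admissible-set divisor switch changes only the denominator", {
  t2 <- make_toy("branched")
  t2$upper_bounds[["R3"]] <- 0      # blocks R3 and R4: admissible = {R1, R2}
  ref <- compute_reference_ranges(t2)
  expect_setequal(ref$admissible, c("R1", "R2"))
  d_adm <- delta_measure(ref$ranges, ref)
  d_all <- delta_measure(ref$ranges, ref, include_pinned = TRUE)
  expect_equal(d_adm, 1)
  expect_equal(d_all, length(ref$admissible) / length(ref$internal))
})

test_that("Sigma is the spread of the summed internal flux vs reference", {
  t2 <- make_toy("branched")
  ref <- compute_reference_ranges(t2)
  expect_equal(sigma_measure(t2, ref), 1)
  # growth and uptake pinned at 10: internal sum is 20 + t, t in [0, 10],
  # against a reference spread of 30 (hand LP, confirmed by the oracle)
  expect_equal(sigma_measure(t2, ref, fixes = c(GRO = 10, EX_A = 10)), 1/3)
  # total fixing: spread 0
  expect_equal(sigma_measure(t2, ref, fixes = c(EX_A = 6, R1 = 6, R2 = 6,
                                                R3 = 0, R4 = 0, GRO = 6)), 0)
  # zero reference spread errors
  t2c <- t2; t2c$upper_bounds[["EX_A"]] <- 0
  refc <- compute_reference_ranges(t2c)
  expect_error(sigma_measure(t2c, refc), "spread .* is zero")
})

test_that("decomposition reproduces the branched-toy golden answer", {
  t2 <- make_toy("branched")
  ref <- compute_reference_ranges(t2)
  vc <- decompose_variability(t2, ref, sigma = TRUE)
  expect_equal(vc$delta_int, 0.75, tolerance = 1e-6)
  expect_equal(vc$delta_ext, 0, tolerance = 1e-6)
  expect_equal(vc$delta_gro, 0.25, tolerance = 1e-6)
  expect_equal(vc$delta_tot, 1, tolerance = 1e-6)
  expect_equal(vc$vgro_max, 10)
  expect_equal(vc$sigma_tot, 1, tolerance = 1e-6)
  expect_identical(vc$delta_tot,
                   vc$delta_int + vc$delta_ext + vc$delta_gro)
})

test_that("components are non-negative and sum exactly across conditions", {
  t3 <- make_toy("two_substrate")
  ref <- compute_reference_ranges(t3)
  for (fx in list(NULL, c(EX_N = 5), c(EX_N = 12), c(EX_C = 6),
                  c(EX_C = 6, EX_N = 4))) {
    vc <- decompose_variability(t3, ref, fixes = fx)
    expect_identical(vc$delta_tot,
                     vc$delta_int + vc$delta_ext + vc$delta_gro)
    expect_gte(vc$delta_int, 0)
    expect_gte(vc$delta_ext, -1e-9)
    expect_gte(vc$delta_gro, -1e-9)
    # conditions only tighten the reference set: 0 <= Delta <= 1
    expect_gte(vc$delta_tot, 0)
    expect_lte(vc$delta_tot, 1 + 1e-9)
  }
})

test_that("fixing external rates alone pins growth too (steady-state redundancy)", {
  for (preset in c("chain", "branched")) {
    m <- make_toy(preset)
    ref <- compute_reference_ranges(m)
    fba <- solve_fba(m)
    exch <- names(m$reaction_class)[m$reaction_class == "exchange"]
    vext <- fba$flux[exch]
    d_ext_only <- delta_measure(solve_fva(m, ref$admissible, fixes = vext), ref)
    d_both <- delta_measure(
      solve_fva(m, ref$admissible,
                fixes = c(vext, stats::setNames(fba$value, m$biomass))), ref)
    expect_equal(d_ext_only, d_both, tolerance = 1e-9)
  }
})

test_that("degenerate external optima shift delta_int/ext but not their sum", {
  tw <- twin_route_model()
  ref <- compute_reference_ranges(tw)
  # feeding through A keeps the twin-route split free; feeding B directly
  # pins both internal routes at zero
  v1 <- decompose_variability(tw, ref,
                              vext_override = c(EX_A = 10, EX_B = 0))
  v2 <- decompose_variability(tw, ref,
                              vext_override = c(EX_A = 0, EX_B = 10))
  expect_equal(v1$delta_int, 1, tolerance = 1e-6)
  expect_equal(v2$delta_int, 0, tolerance = 1e-6)
  expect_equal(v1$delta_int + v1$delta_ext, v2$delta_int + v2$delta_ext,
               tolerance = 1e-6)
  expect_equal(v1$delta_gro, v2$delta_gro, tolerance = 1e-6)
  expect_equal(v1$delta_tot, v2$delta_tot, tolerance = 1e-6)
})

test_that("growth-fix slack gamma relaxes the pin without breaking the sum", {
  t2 <- make_toy("branched")
  ref <- compute_reference_ranges(t2)
  vc <- decompose_variability(t2, ref, gamma = 0.01)
  expect_identical(vc$delta_tot,
                   vc$delta_int + vc$delta_ext + vc$delta_gro)
  expect_gte(vc$delta_int, 0.75 - 1e-9)   # slack can only widen ranges
})
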