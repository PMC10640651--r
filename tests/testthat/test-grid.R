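test_that("hydraulic-geometry river width matches the worked values", {
  expect_equal(round(river_width_from_discharge(18), 1), 30.5)
  expect_equal(river_width_from_discharge(0), 0)
  expect_equal(river_width_from_discharge(100), 72)
  expect_error(river_width_from_discharge(-1), "non-negative")
})

test_that("grid layout honours the domain footprint at any resolution", {
  cfg60 <- mm_config()
  g60 <- build_grid(cfg60)
  basin60 <- sum(g60$role %in% c("basin", "river_inflow"))
  # 4000 x 2000 m basin at 60 m cells
  expect_equal(basin60, round(4000 / 60) * round(2000 / 60))

  g120 <- build_grid(mm_config(domain = list(resolution = 120)))
  basin120 <- sum(g120$role %in% c("basin", "river_inflow"))
  # footprint is resolution-independent to within one cell ring
  ring60 <- 2 * (round(4000 / 60) + round(2000 / 60)) * 60^2
  expect_lt(abs(basin60 * 60^2 - basin120 * 120^2), ring60)

  # reference resolution: river segments span twice the 15 m cell
  g15 <- build_grid(mm_config(domain = list(resolution = 15)))
  expect_equal(nrow(g15$rivers$head), 2)
  expect_equal(nrow(g15$rivers$north), 2)

  # the inlet must resolve into at least two cells
  expect_error(build_grid(mm_config(domain = list(resolution = 200))),
               "inlet")
})

test_that("grid roles partition the domain as designed", {
  g <- build_grid(mm_config())
  expect_setequal(unique(as.vector(g$role)),
                  c("offshore", "basin", "barrier", "river_inflow",
                    "open_sea_boundary"))
  # barriers flank a central inlet on one column
  barrier_cols <- unique(which(g$role == "barrier", arr.ind = TRUE)[, 1])
  expect_equal(length(barrier_cols), 1)
  expect_equal(nrow(g$inlet), round(mm_config()$domain$inlet_width / g$dx))
})

test_that("initial bathymetry matches the idealized setting", {
  cfg <- mm_config()
  g <- build_grid(cfg)
  bed <- init_bathymetry(g, cfg)
  basin <- g$role %in% c("basin", "river_inflow")
  expect_true(all(bed$elevation[basin] == -1.5))
  expect_true(all(bed$elevation[1, ] == -100))      # open boundary column
  expect_true(all(mud_fraction_top1m(bed) == 0))    # all-sand substrate
  expect_false(any(bed$erodible[g$role == "barrier"]))

  # non-erodible contract: barrier elevation unchanged under erosive fluxes
  z0 <- bed$elevation
  bed2 <- update_bed(bed, mud_flux = matrix(-1, g$nx, g$ny),
                     sand_flux = matrix(-1, g$nx, g$ny),
                     morfac = 90, dt = 60, cfg = cfg)
  barrier <- g$role == "barrier"
  expect_equal(bed2$elevation[barrier], z0[barrier])
  expect_true(all(bed2$elevation >= bed2$floor - 1e-12))
})

test_that("scenario catalogue encodes the management phases", {
  cfg <- mm_config()
  hf <- make_scenario("high_forever", cfg)
  expect_equal(plan_mud_conc(hf, 100), 0)            # spin-up, no mud
  expect_equal(plan_mud_conc(hf, 300), 0.005)        # pre-disturbance 5 mg/L
  expect_equal(plan_mud_conc(hf, 450), 0.015)        # disturbance 15 mg/L
  expect_equal(plan_mud_conc(hf, 599), 0.015)        # maintained to the end

  r100 <- make_scenario("remove_100", cfg)
  expect_equal(r100$events$year, 500)
  expect_equal(r100$events$fraction, 1)

  r450 <- make_scenario("reduce_at_450", cfg)
  expect_equal(plan_mud_conc(r450, 449), 0.015)
  expect_equal(plan_mud_conc(r450, 450.5), 0.005)

  ri <- make_scenario("reduce_intermediate", cfg)
  expect_equal(plan_mud_conc(ri, 550), 0.010)

  nv <- make_scenario("no_vegetation_control", cfg)
  expect_false(any(nv$phases$vegetation))

  # phases tile the horizon exactly
  for (nm in scenario_catalogue()) {
    p <- make_scenario(nm, cfg)$phases
    expect_equal(p$from[-1], p$to[-nrow(p)])
    expect_equal(p$to[nrow(p)], cfg$scenario$horizon)
  }
  expect_error(make_scenario("not_a_plan", cfg), "unknown")
})
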