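cfg <- mm_config()

test_that("mud exchange honours the Partheniades-Krone thresholds", {
  sed <- cfg$sediment
  ex <- mud_exchange(tau = sed$tau_ce, c_mud = 0.1, cfg = cfg)
  expect_equal(ex$erosion, 0)
  ex <- mud_exchange(tau = 2 * sed$tau_ce, c_mud = 0, cfg = cfg)
  expect_equal(ex$erosion, sed$erosion_rate)
  ex <- mud_exchange(tau = 0, c_mud = 0.02, cfg = cfg)
  expect_equal(ex$deposition, sed$ws_mud * 0.02)
  # erosion is scaled by the mud actually present at the surface
  ex <- mud_exchange(tau = 2 * sed$tau_ce, c_mud = 0, mud_avail = 0,
                     cfg = cfg)
  expect_equal(ex$erosion, 0)
})

test_that("sand capacity is thresholded and monotone in velocity", {
  s0 <- sand_transport(u = 0.1, h = 2, cfg = cfg)
  expect_equal(s0$q_total, 0)
  expect_equal(s0$c_eq, 0)
  u <- seq(0.3, 2, by = 0.1)
  qt <- sand_transport(u = u, h = 2, cfg = cfg)$q_total
  expect_true(all(diff(qt) > 0))
  # doubling the velocity strictly increases capacity
  expect_gt(sand_transport(u = 1.6, h = 2, cfg = cfg)$q_total,
            sand_transport(u = 0.8, h = 2, cfg = cfg)$q_total)
})

test_that("transverse slope correction damps upslope transport", {
  flat <- slope_correction(qb_x = 1e-4, qb_y = 0, dzdx = 0, dzdy = 0,
                           cfg = cfg)
  expect_equal(flat$qb_x, 1e-4)
  expect_equal(flat$qb_y, 0)
  # along-slope flow over a lateral gradient gains a downslope component
  lat <- slope_correction(qb_x = 1e-4, qb_y = 0, dzdx = 0, dzdy = 0.01,
                          cfg = cfg)
  expect_lt(lat$qb_y, 0)
  # reversing the slope reverses the transverse flux exactly
  lat2 <- slope_correction(qb_x = 1e-4, qb_y = 0, dzdx = 0, dzdy = -0.01,
                           cfg = cfg)
  expect_equal(lat2$qb_y, -lat$qb_y)
})

test_that("tracer transport conserves mass and advects at the flow speed", {
  nx <- 50; ny <- 5
  h <- matrix(2, nx, ny)
  conc <- matrix(0, nx, ny); conc[10, ] <- 1
  # no velocity, no diffusion: unchanged
  still <- advect_diffuse(conc, h, u = matrix(0, nx, ny),
                          v = matrix(0, nx, ny), dx = 60, dt = 60)
  expect_equal(still, conc)
  # uniform flow: the centroid moves at the flow speed (closed in y)
  u <- matrix(0.5, nx, ny); u[nx, ] <- 0
  cc <- conc
  nstep <- 40
  for (k in seq_len(nstep)) {
    cc <- advect_diffuse(cc, h, u, v = matrix(0, nx, ny), dx = 60, dt = 60)
  }
  centroid0 <- sum(seq_len(nx) * rowSums(conc)) / sum(conc)
  centroid1 <- sum(seq_len(nx) * rowSums(cc)) / sum(cc)
  shift_m <- (centroid1 - centroid0) * 60
  expect_equal(shift_m, 0.5 * nstep * 60, tolerance = 0.02)
  # mass conserved on the closed domain
  expect_equal(sum(cc * h), sum(conc * h), tolerance = 1e-10)
})

test_that("suspended mass in the coupled solver is conserved when closed", {
  nx <- 30; ny <- 6
  z <- matrix(-2, nx, ny)
  ct <- matrix(1L, nx, ny)
  c0 <- matrix(0, nx, ny); c0[10:12, 2:4] <- 0.05
  m0 <- sum(c0 * 2) * 3600
  out <- step_flow(z, ct, dx = 60, dt = 240, nsteps = 200, eta = 0,
                   c_mud = c0, transport = TRUE, morpho = FALSE)
  expect_lt(abs(out$susp_mass[1] - m0) / m0, 1e-8)
})

test_that("bed updating converts fluxes with morphological acceleration", {
  cfg2 <- mm_config(domain = list(resolution = 120))
  g <- build_grid(cfg2)
  bed <- init_bathymetry(g, cfg2)
  # pure mud deposition: dz = morfac * F * dt / rho_dry_mud, top layer mud
  flux <- matrix(0, g$nx, g$ny); flux[40, 8] <- 1e-4
  bed2 <- update_bed(bed, mud_flux = flux, sand_flux = 0 * flux,
                     morfac = 90, dt = 3600, cfg = cfg2)
  dz <- bed2$elevation[40, 8] - bed$elevation[40, 8]
  expect_equal(dz, 90 * 1e-4 * 3600 / cfg2$sediment$rho_dry_mud)
  cell <- 40 + (8 - 1) * g$nx
  expect_equal(surface_mud_fraction(bed2)[cell], 1)
  # zero flux: bed identical
  bed3 <- update_bed(bed, mud_flux = 0 * flux, sand_flux = 0 * flux,
                     morfac = 90, dt = 3600, cfg = cfg2)
  expect_identical(bed3$elevation, bed$elevation)
})

test_that("top-1 m mud fraction is the thickness-weighted stack mean", {
  s <- new_stratigraphy(3)
  # cell 1: a single 1 m layer at fraction 0.4
  s <- strat_deposit(s, 1L, t_mud = 0.4, t_sand = 0.6, nominal = 2)
  # cell 2: 0.5 m pure mud over 0.5 m pure sand
  s <- strat_deposit(s, 2L, t_mud = 0, t_sand = 0.5, nominal = 0.1)
  s <- strat_deposit(s, 2L, t_mud = 0.5, t_sand = 0, nominal = 0.1)
  # cell 3: 0.2 m pure mud over 0.9 m at fraction 0.1
  s <- strat_deposit(s, 3L, t_mud = 0.09, t_sand = 0.81, nominal = 0.1)
  s <- strat_deposit(s, 3L, t_mud = 0.2, t_sand = 0, nominal = 0.1)
  frac <- mud_fraction_top1m(s)
  expect_equal(frac[1], 0.4)
  expect_equal(frac[2], 0.5)
  expect_equal(frac[3], 0.2 * 1.0 + 0.8 * 0.1)
  # erosion exposes the older layer
  s2 <- strat_erode(s, 2L, 0.5)
  expect_equal(surface_mud_fraction(s2)[2], 0)
})

test_that("deep erosion falls through to the implicit sand base", {
  s <- new_stratigraphy(1)
  s <- strat_deposit(s, 1L, t_mud = 0.3, t_sand = 0, nominal = 0.1)
  s <- strat_erode(s, 1L, 5)
  expect_equal(s$nlay[1], 0L)
  expect_equal(mud_fraction_top1m(s)[1], 0)
})

test_that("uniform flow at equilibrium sand concentration leaves the bed alone", {
  S <- 1e-4; h0 <- 2; nx <- 60
  z <- matrix(-h0 - S * 60 * (nx:1), nx, 1)
  ct <- matrix(1L, nx, 1); ct[1, 1] <- 2L; ct[nx, 1] <- 2L
  off <- z + h0
  # spin the channel to its steady Chezy balance
  spin <- step_flow(z, ct, dx = 60, dt = 60, nsteps = 1500,
                    eta = as.numeric(off), eta_offset = off)
  u0 <- abs(spin$u[30, 1])
  ceq <- sand_transport(u = u0, h = h0, cfg = mm_config())$c_eq
  out <- step_flow(z, ct, dx = 60, dt = 60, nsteps = 200,
                   eta = spin$eta, u = spin$u, v = spin$v,
                   eta_offset = off, c_sand = ceq,
                   transport = TRUE, morpho = TRUE, morfac = 50)
  # interior fluxes are uniform, so divergence and net exchange vanish
  dz_int <- (out$z - z)[5:(nx - 5), 1]
  expect_lt(max(abs(dz_int)), 1e-3)
})
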