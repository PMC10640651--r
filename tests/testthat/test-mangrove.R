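cfg <- mm_config()
v <- cfg$vegetation

test_that("height allometry anchors at 137 cm and saturates at the maxima", {
  expect_equal(tree_height(0, cfg), 137)
  d <- seq(0, v$b2 / (2 * v$b3), length.out = 50)
  expect_true(all(diff(tree_height(d, cfg)) >= 0))
  expect_equal(tree_height(v$d_max, cfg), v$h_max, tolerance = 1e-10)
})

test_that("diameter growth vanishes at the size ceiling and under full stress", {
  # D*H = Dmax*Hmax at D = Dmax (by the allometry closure): rate is zero
  expect_equal(growth_rate(v$d_max, fc = 1, cfg), 0, tolerance = 1e-12)
  expect_equal(growth_rate(5, fc = 0, cfg), 0)
  veg <- init_vegetation()
  veg$cohorts <- data.frame(cell = 1L, age = 0, d = 5, stems = 100, supp = 0L)
  grown <- grow_cohorts(veg, stress = list(fc = c(0)), cfg)
  expect_equal(grown$cohorts$d, 5)
})

test_that("one optimal season matches an independent ODE integration", {
  skip_if_not_installed("deSolve")
  rate <- function(t, y, p) list(growth_rate(y, fc = 1, cfg))
  oracle <- unname(deSolve::lsoda(y = v$seedling_d0, times = c(0, 0.25),
                                  func = rate, rtol = 1e-10,
                                  atol = 1e-12)[2, 2])
  veg <- init_vegetation()
  veg$cohorts <- data.frame(cell = 1L, age = 0, d = v$seedling_d0,
                            stems = 100, supp = 0L)
  grown <- grow_cohorts(veg, stress = list(fc = 1), cfg)
  # a single Euler season against the adaptive integrator
  expect_equal(grown$cohorts$d, oracle, tolerance = 0.02)
  expect_equal(grown$cohorts$age, 0.25)
})

test_that("a cohort saturates monotonically toward the ceiling", {
  veg <- init_vegetation()
  veg$cohorts <- data.frame(cell = 1L, age = 0, d = v$seedling_d0,
                            stems = 100, supp = 0L)
  d_hist <- numeric(200)
  for (k in 1:200) {
    veg <- grow_cohorts(veg, stress = list(fc = 1), cfg)
    d_hist[k] <- veg$cohorts$d
  }
  expect_true(all(diff(d_hist) >= -1e-12))
  expect_lte(max(d_hist), v$d_max)
  expect_gt(d_hist[200], 0.95 * v$d_max)  # approaches the ceiling
})

test_that("stress factors respect their bounds and asymptotes", {
  expect_equal(fitness_hydroperiod(v$hp_opt, cfg), 1)
  expect_equal(fitness_hydroperiod(0, cfg), v$f_dry)
  expect_equal(fitness_hydroperiod(0.5, cfg), 0)
  expect_equal(fitness_hydroperiod(0.7, cfg), 0)
  expect_equal(competition_biomass(0, cfg), 1)
  expect_equal(competition_biomass(v$b_half, cfg), 0.5)
  expect_lt(competition_biomass(1e6, cfg), 1e-3)
  # empty cell at optimal hydroperiod: f = 1, C = 1
  g <- build_grid(mm_config(domain = list(resolution = 120)))
  st <- compute_stress(init_vegetation(), rep(v$hp_opt, g$nx * g$ny), g, cfg)
  expect_equal(max(st$f), 1)
  expect_true(all(st$C == 1))
})

test_that("colonization applies the hydroperiod, shear and viability gates", {
  cfg2 <- mm_config(domain = list(resolution = 120))
  g <- build_grid(cfg2)
  ncell <- g$nx * g$ny
  basin_cells <- which(as.vector(basin_mask(g)))
  hp <- rep(1, ncell); tau <- rep(1, ncell)
  pick <- basin_cells[1:4]
  hp[pick] <- c(0.3, 0.6, 0.3, 0.3)     # cell 2 outside the window
  tau[pick] <- c(0.1, 0.1, 0.25, 0.1)   # cell 3 above the shear threshold
  veg <- init_vegetation()
  veg <- attempt_colonization(veg, hp, tau, g, cfg2)
  expect_setequal(veg$cohorts$cell, pick[c(1, 4)])
  # 3000 stems/ha scaled to the cell area
  expect_equal(unique(veg$cohorts$stems),
               3000 / 1e4 * g$area)
  # an already-vegetated cell is not recolonized
  n0 <- nrow(veg$cohorts)
  veg2 <- attempt_colonization(veg, hp, tau, g, cfg2)
  expect_equal(nrow(veg2$cohorts), n0)
})

test_that("five consecutive suppressed years trigger thinning, a broken streak does not", {
  g <- build_grid(mm_config(domain = list(resolution = 120)))
  mk_veg <- function() {
    veg <- init_vegetation()
    veg$cohorts <- data.frame(cell = 500L, age = 10, d = 10,
                              stems = 400, supp = 0L)
    veg
  }
  run_years <- function(veg, fc_seq, hp_of_fc) {
    for (fcv in fc_seq) {
      hp <- rep(hp_of_fc(fcv), g$nx * g$ny)
      stress <- compute_stress(veg, hp, g, cfg)
      veg <- apply_mortality(veg, stress, g, bed = NULL, cfg)
    }
    veg
  }
  # choose hydroperiods whose fitness brackets the suppression threshold:
  # f*C < 0.5 every year for five years -> thinning
  hp_bad <- 0.45   # low fitness
  hp_good <- v$hp_opt
  veg <- mk_veg()
  stems0 <- veg$cohorts$stems
  veg <- run_years(veg, 1:5, function(k) hp_bad)
  expect_true(nrow(veg$cohorts) == 0 || veg$cohorts$stems < stems0)
  # broken streak: suppression counter resets, no thinning
  veg2 <- mk_veg()
  hps <- c(hp_bad, hp_bad, hp_good, hp_bad, hp_bad)
  for (h in hps) {
    stress <- compute_stress(veg2, rep(h, g$nx * g$ny), g, cfg)
    veg2 <- apply_mortality(veg2, stress, g, bed = NULL, cfg)
  }
  expect_equal(veg2$cohorts$stems, stems0)
})

test_that("thinning removes exactly the stems needed to lift suppression", {
  g <- build_grid(mm_config(domain = list(resolution = 120)))
  veg <- init_vegetation()
  d0 <- 8; stems0 <- 6000
  veg$cohorts <- data.frame(cell = 500L, age = 10, d = d0,
                            stems = stems0, supp = 4L)
  hp <- rep(0.38, g$nx * g$ny)  # moderate fitness, f in (0.5, 1)
  stress <- compute_stress(veg, hp, g, cfg)
  expect_lt(stress$fc[500], 0.5) # suppressed: year 5 triggers thinning
  veg2 <- apply_mortality(veg, stress, g, bed = NULL, cfg)
  # brute force: smallest k with f * C(stems - k) >= 0.5
  f <- stress$f[500]
  per_tree <- tree_biomass(d0, cfg)
  k <- 0
  while (k <= stems0) {
    B <- (stems0 - k) * per_tree / g$area
    if (f * competition_biomass(B, cfg) >= 0.5) break
    k <- k + 1
  }
  expect_equal(veg2$cohorts$stems, stems0 - k, tolerance = 1 / stems0)
  # suppression lifted
  stress2 <- compute_stress(veg2, hp, g, cfg)
  expect_gte(stress2$fc[500] + 1e-9, 0.5)
})

test_that("removal clears the requested share of vegetated area", {
  cfg2 <- mm_config(domain = list(resolution = 120))
  g <- build_grid(cfg2)
  veg <- init_vegetation()
  cells <- which(as.vector(basin_mask(g)))[1:40]
  veg$cohorts <- data.frame(cell = cells, age = 10, d = 8,
                            stems = 400, supp = 0L)
  r100 <- remove_mangroves(veg, 1, g, cfg2)
  expect_equal(nrow(r100$cohorts), 0)
  r25 <- remove_mangroves(veg, 0.25, g, cfg2)
  expect_equal(length(unique(r25$cohorts$cell)), 30)
  # seaward-first: the removed cells are the most seaward ones
  kept_i <- (r25$cohorts$cell - 1) %% g$nx + 1
  gone <- setdiff(cells, r25$cohorts$cell)
  gone_i <- (gone - 1) %% g$nx + 1
  expect_lte(max(gone_i), min(kept_i))
  expect_error(remove_mangroves(veg, 0, g, cfg2), "fraction")
})

test_that("root persistence keeps pneumatophore roughness after clearing stems", {
  cfg2 <- mm_config(domain = list(resolution = 120))
  g <- build_grid(cfg2)
  veg <- init_vegetation()
  cells <- which(as.vector(basin_mask(g)))[1:10]
  veg$cohorts <- data.frame(cell = cells, age = 10, d = 8,
                            stems = 400, supp = 0L)
  veg <- remove_mangroves(veg, 1, g, cfg2, root_persistence_years = 2)
  summ <- to_roughness_summary(veg, g, cfg2)
  expect_equal(max(summ$stem$n), 0)        # stems gone at once
  expect_gt(max(summ$pneu$n), 0)           # roots persist
  # two annual ticks later the roots are gone too
  stress <- list(f = rep(1, g$nx * g$ny), C = rep(1, g$nx * g$ny),
                 fc = rep(1, g$nx * g$ny))
  veg <- apply_mortality(veg, stress, g, bed = NULL, cfg2)
  veg <- apply_mortality(veg, stress, g, bed = NULL, cfg2)
  summ2 <- to_roughness_summary(veg, g, cfg2)
  expect_equal(max(summ2$pneu$n), 0)
})

test_that("roughness summary implements n = m D per object class", {
  cfg15 <- mm_config(domain = list(resolution = 15))
  g <- build_grid(cfg15)   # 225 m2 cells
  veg <- init_vegetation()
  cell <- which(as.vector(basin_mask(g)))[100]
  veg$cohorts <- data.frame(cell = cell, age = 5, d = 5, stems = 100,
                            supp = 0L)
  summ <- to_roughness_summary(veg, g, cfg15)
  expect_equal(summ$stem$n[cell], 100 / 225 * 0.05, tolerance = 1e-10)
  # doubling the stem count doubles the density
  veg2 <- veg; veg2$cohorts$stems <- 200
  summ2 <- to_roughness_summary(veg2, g, cfg15)
  expect_equal(summ2$stem$n[cell], 2 * summ$stem$n[cell])
  # empty cells carry no roughness objects
  empty <- to_roughness_summary(init_vegetation(), g, cfg15)
  expect_equal(max(empty$stem$n), 0)
  expect_equal(max(empty$pneu$n), 0)
})
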