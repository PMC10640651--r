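cfg <- mm_config()

# a minimal grid whose basin is fully controllable
toy_grid <- function(nx, ny, dx = 60) {
  structure(list(nx = nx, ny = ny, dx = dx, area = dx^2,
                 role = matrix("basin", nx, ny)), class = "mm_grid")
}

test_that("accommodation space sums the volume below high tide", {
  g <- toy_grid(10, 10)
  z <- matrix(-1, 10, 10)
  expect_equal(accommodation_space(z, g, hw = 0.75), 1.75 * 100 * 3600)
  z_high <- matrix(2, 10, 10)
  expect_equal(accommodation_space(z_high, g, hw = 0.75), 0)
  # two-cell hand sum: (-1.5, +1.0) under HW 0.75 at 60 m cells
  g2 <- toy_grid(2, 1)
  z2 <- matrix(c(-1.5, 1.0), 2, 1)
  expect_equal(accommodation_space(z2, g2, hw = 0.75), 2.25 * 3600)
  # hypsometry invariance: permuting elevations leaves the volume unchanged
  z3 <- matrix(runif(100, -3, 1), 10, 10)
  zp <- matrix(sample(z3), 10, 10)
  expect_equal(accommodation_space(z3, g, hw = 0.75),
               accommodation_space(zp, g, hw = 0.75))
})

test_that("muddy region applies a strict 30 % threshold", {
  g <- toy_grid(3, 1)
  bed <- list(strat = new_stratigraphy(3))
  bed$strat <- strat_deposit(bed$strat, 1:3,
                             t_mud = c(0.2, 0.4, 0.30),
                             t_sand = c(0.8, 0.6, 0.70), nominal = 2)
  class(bed) <- "mm_bed"
  # exactly 0.30 is excluded (strict); 0.4 included; 0.2 excluded -> 1/3
  expect_equal(muddy_region_fraction(bed, g, cfg = cfg), 1 / 3)
  bed0 <- structure(list(strat = new_stratigraphy(3)), class = "mm_bed")
  expect_equal(muddy_region_fraction(bed0, g, cfg = cfg), 0)
})

test_that("mangrove coverage counts vegetated basin cells", {
  g <- toy_grid(10, 10)
  expect_equal(mangrove_coverage(init_vegetation(), g), 0)
  veg <- init_vegetation()
  veg$cohorts <- data.frame(cell = 1:27, age = 1, d = 1, stems = 10, supp = 0L)
  expect_equal(mangrove_coverage(veg, g), 0.27)
  veg$cohorts <- data.frame(cell = 1:100, age = 1, d = 1, stems = 10,
                            supp = 0L)
  expect_equal(mangrove_coverage(veg, g), 1)
})

test_that("relative area above MSL counts the high-tide-wetted basin", {
  g <- toy_grid(10, 1)
  expect_equal(relative_area_amsl(matrix(-1.5, 10, 1), g, hw = 0.75), 0)
  z <- matrix(c(rep(0.2, 3), rep(-0.5, 7)), 10, 1)
  expect_equal(relative_area_amsl(z, g, hw = 0.75), 0.3)
  # supratidal cells leave the wetted denominator
  z2 <- matrix(c(rep(2, 5), rep(0.2, 5)), 10, 1)
  expect_equal(relative_area_amsl(z2, g, hw = 0.75), 1)
})

test_that("channel classification recovers a constructed incision", {
  g <- toy_grid(40, 21)
  z <- matrix(0, 40, 21)
  z[, 11] <- -1        # straight incised channel through a flat platform
  cl <- classify_channels(z, g, cfg)
  in_channel <- cl$j == 11
  expect_true(all(cl$channel[in_channel]))
  expect_false(any(cl$channel[!in_channel]))
  expect_equal(cl$distance_m[cl$j == 11][1], 0)
  # 5 cells from the channel at 60 m -> 300 m, in the far class
  row5 <- cl[cl$j == 16, ]
  expect_equal(unique(row5$distance_m), 300)
  expect_equal(unique(row5$class), "far")
  row1 <- cl[cl$j == 12, ]
  expect_equal(unique(row1$class), "near")
  # flat platform: empty mask with a warning
  expect_warning(cl0 <- classify_channels(matrix(0, 40, 21), g, cfg),
                 "no channels")
  expect_false(any(cl0$channel))
})

test_that("sedimentation rates and class summaries are exact on fixtures", {
  g <- toy_grid(4, 1)
  z0 <- matrix(0, 4, 1)
  z1 <- matrix(c(0.05, -0.1, 0.05, -0.1), 4, 1)
  expect_equal(sedimentation_rate(z0, z0 + 0.05, 50)[1, 1], 1)
  expect_equal(sedimentation_rate(z0, z0 - 0.1, 100)[1, 1], -1)
  cl <- tibble::tibble(cell = 1:4, i = 1:4, j = 1,
                       channel = c(TRUE, TRUE, FALSE, FALSE),
                       distance_m = c(0, 0, 60, 60),
                       class = c("channel", "channel", "near", "near"))
  out <- sedimentation_rate(z0, z1, 50, classification = cl)
  summ <- attr(out, "summary")
  expect_equal(summ$mean_rate[summ$class == "channel"],
               mean(c(0.05, -0.1)) * 1000 / 50)
  expect_equal(summ$mean_rate[summ$class == "near"],
               mean(c(0.05, -0.1)) * 1000 / 50)
  expect_error(sedimentation_rate(z0, z1, 0), "year")
})

test_that("sediment yield scales linearly and matches the source arithmetic", {
  omega <- 2 * pi / 43200
  tt <- seq(0, 43200, by = 60)[-1]
  q <- 500 * sin(omega * tt)
  out15 <- sediment_yield_and_prism(0.015, q, 60, cfg)
  # 3 rivers x 18 m3/s x 15 mg/L over a year
  expect_equal(out15$SY_kg, 3 * 18 * 0.015 * 86400 * 365.25)
  expect_equal(out15$SY_kg / 1e7, 2.56, tolerance = 2e-3)
  out5 <- sediment_yield_and_prism(0.005, q, 60, cfg)
  expect_equal(out15$SY_kg, 3 * out5$SY_kg)
  out0 <- sediment_yield_and_prism(0, q, 60, cfg)
  expect_equal(out0$SY_kg, 0)
  expect_gt(out15$TP_m3, 0)
  expect_equal(out15$SY_TP, out15$SY_m3 / out15$TP_m3)
})
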