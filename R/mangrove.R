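#' Create an empty vegetation state
#'
#' Mangrove vegetation (*Avicennia marina*) is tracked per cell as cohorts
#' with a stem diameter, stem count and a suppression counter, plus
#' "ghost" pneumatophore records that keep root roughness in place for a
#' configurable number of years after above-ground removal.
#'
#' @return an `mm_veg` object
#' @export
init_vegetation <- function() {
  structure(list(
    cohorts = data.frame(cell = integer(), age = numeric(), d = numeric(),
                         stems = numeric(), supp = integer()),
    ghost_roots = data.frame(cell = integer(), m_pneu = numeric(),
                             years_left = numeric()),
    blocked = integer() # cells cleared this year; recolonizable next year
  ), class = "mm_veg")
}

#' @export
print.mm_veg <- function(x, ...) {
  cat("<mm_veg> ", nrow(x$cohorts), " cohorts in ",
      length(unique(x$cohorts$cell)), " cells\n", sep = "")
  invisible(x)
}

#' Cohort table
#' @param veg an `mm_veg`
#' @param cfg an [mm_config()] (for the height allometry)
#' @return tibble of cohorts (cell, age, stem diameter cm, height cm, stems,
#'   suppression counter)
#' @export
cohort_table <- function(veg, cfg = mm_config()) {
  co <- veg$cohorts
  tibble(cell = co$cell, age = co$age, diameter_cm = co$d,
         height_cm = tree_height(co$d, cfg), stems = co$stems,
         suppressed_years = co$supp)
}

#' Tree height from stem diameter
#'
#' Quadratic allometry \eqn{H = 137 + b_2 D - b_3 D^2} (cm), the classic
#' JABOWA form; the defaults pin \eqn{H(D_{max}) = H_{max}} with zero slope at
#' the size ceiling, so height saturates as the diameter approaches its
#' maximum.
#'
#' @param d stem diameter (cm), vectorized
#' @param cfg an [mm_config()]
#' @return tree height (cm)
#' @export
tree_height <- function(d, cfg = mm_config()) {
  v <- cfg$vegetation
  137 + v$b2 * d - v$b3 * d^2
}

#' Above-ground biomass of a tree
#'
#' Power-law allometry on stem diameter (kg per tree, D in cm).
#' @inheritParams tree_height
#' @return biomass (kg)
#' @export
tree_biomass <- function(d, cfg = mm_config()) {
  v <- cfg$vegetation
  v$biomass_a * d^v$biomass_b
}

#' Seasonal stem-diameter growth rate
#'
#' The diameter increment equation
#' \deqn{dD/dt = \frac{G D (1 - D H/(D_{max} H_{max}))}{274 + 3 b_2 D -
#'   4 b_3 D^2} f C}
#' (cm per year, D and H in cm): logistic-like saturation toward the size
#' ceiling \eqn{D H = D_{max} H_{max}}, modulated by the hydroperiod fitness
#' `f` and biomass competition `C`.
#'
#' @param d stem diameter (cm)
#' @param fc product of fitness and competition factors in `[0, 1]`
#' @param cfg an [mm_config()]
#' @return growth rate dD/dt (cm/yr)
#' @export
growth_rate <- function(d, fc = 1, cfg = mm_config()) {
  v <- cfg$vegetation
  h <- tree_height(d, cfg)
  v$growth_g * d * (1 - d * h / (v$d_max * v$h_max)) /
    (274 + 3 * v$b2 * d - 4 * v$b3 * d^2) * fc
}

#' Hydroperiod fitness curve
#'
#' Smooth unimodal response of mangrove growth to relative hydroperiod:
#' optimal at `hp_opt`, dropping to the configured dry-end minimum at
#' hydroperiod 0 and to zero at the wet edge of the colonization window
#' (`hp_max`, default 0.5); zero beyond it. The shape follows the
#' inundation-stress curves of one-dimensional mangrove models; it is
#' config-exposed rather than observation-fitted.
#'
#' @param hp relative hydroperiod in `[0, 1]`
#' @param cfg an [mm_config()]
#' @return fitness f in `[0, 1]`
#' @export
fitness_hydroperiod <- function(hp, cfg = mm_config()) {
  v <- cfg$vegetation
  f <- numeric(length(hp))
  left <- hp >= 0 & hp < v$hp_opt
  right <- hp >= v$hp_opt & hp <= v$hp_max
  f[left] <- v$f_dry + (1 - v$f_dry) *
    (1 - ((hp[left] - v$hp_opt) / v$hp_opt)^2)
  f[right] <- 1 - ((hp[right] - v$hp_opt) / (v$hp_max - v$hp_opt))^2
  pmin(pmax(f, 0), 1)
}

#' Biomass competition factor
#'
#' Decreasing saturating response to standing biomass per unit area:
#' C = 1 with no biomass, C = 1/2 at `b_half`, and C tends to 0 as biomass
#' grows without bound (resource limitation).
#'
#' @param biomass standing biomass (kg/m2)
#' @param cfg an [mm_config()]
#' @return competition factor C in `[0, 1]`
#' @export
competition_biomass <- function(biomass, cfg = mm_config()) {
  1 / (1 + pmax(biomass, 0) / cfg$vegetation$b_half)
}

#' Stress factors for every cell
#'
#' Computes the hydroperiod fitness `f`, the biomass competition `C` and
#' their product per grid cell. Both range between 0 (no growth) and 1
#' (optimal growth).
#'
#' @param veg an `mm_veg`
#' @param hp relative hydroperiod per cell (vector of length ncell)
#' @param grid an `mm_grid`
#' @param cfg an [mm_config()]
#' @return list of vectors `f`, `C`, `fc` (length ncell)
#' @export
compute_stress <- function(veg, hp, grid, cfg = mm_config()) {
  ncell <- grid$nx * grid$ny
  f <- fitness_hydroperiod(hp, cfg)
  bio <- numeric(ncell)
  co <- veg$cohorts
  if (nrow(co) > 0) {
    b <- co$stems * tree_biomass(co$d, cfg) / grid$area
    agg <- rowsum(b, co$cell)
    bio[as.integer(rownames(agg))] <- agg[, 1]
  }
  C <- competition_biomass(bio, cfg)
  list(f = f, C = C, fc = f * C)
}

#' Seedling colonization
#'
#' At the first season of each ecological year, every unvegetated basin cell
#' whose inundation and flow climate permit seedling establishment (relative
#' hydroperiod within the window, cycle bed shear stress below the
#' threshold, viable growth f*C above the suppression threshold) receives a
#' new cohort at the initial seedling density (3000 stems/ha scaled by cell
#' area).
#'
#' @param veg an `mm_veg`
#' @param hp relative hydroperiod per cell
#' @param tau colonization shear-stress statistic per cell (N/m2; the cycle
#'   maximum by default configuration)
#' @param grid an `mm_grid`
#' @param cfg an [mm_config()]
#' @return updated `mm_veg`
#' @export
attempt_colonization <- function(veg, hp, tau, grid, cfg = mm_config()) {
  v <- cfg$vegetation
  ncell <- grid$nx * grid$ny
  stress <- compute_stress(veg, hp, grid, cfg)
  vegetated <- rep(FALSE, ncell)
  vegetated[veg$cohorts$cell] <- TRUE
  basin <- as.vector(basin_mask(grid))
  ok <- basin & !vegetated &
    hp > v$hp_min & hp <= v$hp_max &
    tau < v$tau_crit &
    stress$fc > v$suppression_threshold
  ok[veg$blocked] <- FALSE # cleared cells wait until the next year
  cells <- which(ok)
  if (length(cells) > 0) {
    stems0 <- v$seed_density_ha / 1e4 * grid$area
    veg$cohorts <- rbind(veg$cohorts,
                         data.frame(cell = cells, age = 0, d = v$seedling_d0,
                                    stems = stems0, supp = 0L))
  }
  veg
}

#' Seasonal cohort growth
#'
#' Advances every cohort's stem diameter by one season of the growth-rate
#' equation (explicit Euler with capping at the size ceiling) and its age by
#' one season.
#'
#' @param veg an `mm_veg`
#' @param stress list from [compute_stress()]
#' @param cfg an [mm_config()]
#' @return updated `mm_veg`
#' @export
grow_cohorts <- function(veg, stress, cfg = mm_config()) {
  co <- veg$cohorts
  if (nrow(co) == 0) return(veg)
  v <- cfg$vegetation
  dt <- 1 / v$seasons_per_year
  fc <- stress$fc[co$cell]
  dnew <- co$d + growth_rate(co$d, fc, cfg) * dt
  co$d <- pmin(dnew, v$d_max)
  co$age <- co$age + dt
  veg$cohorts <- co
  veg
}

#' Annual mortality and self-thinning
#'
#' At the end of each ecological year, cohorts whose growth was suppressed
#' (f*C below the threshold) advance their suppression counter; a viable
#' year resets it. After the configured number of consecutive suppressed
#' years (default 5) self-thinning removes stems until the suppression lifts
#' (competition relaxes as biomass drops) or no vegetation is left. Cells
#' whose bed has accreted above the upper mangrove elevation (mean high
#' water) lose stem density along a linear taper.
#'
#' @param veg an `mm_veg`
#' @param stress list from [compute_stress()]
#' @param grid the `mm_grid` the vegetation lives on
#' @param bed an `mm_bed` (for the upper-elevation taper)
#' @param cfg an [mm_config()]
#' @param hw_level high-water level (m MSL) marking the hydroperiod-0
#'   elevation
#' @return updated `mm_veg`
#' @export
apply_mortality <- function(veg, stress, grid, bed = NULL,
                            cfg = mm_config(),
                            hw_level = cfg$metrics$hw_level) {
  co <- veg$cohorts
  if (nrow(co) > 0) {
    v <- cfg$vegetation
    fc <- stress$fc[co$cell]
    suppressed <- fc < v$suppression_threshold
    co$supp <- ifelse(suppressed, co$supp + 1L, 0L)
    thin <- co$supp >= v$suppression_years
    if (any(thin)) {
      # thin stems until f*C recovers: C >= thr/f  <=>  B <= b_half*(f/thr - 1)
      f <- stress$f[co$cell[thin]]
      thr <- v$suppression_threshold
      per_tree <- tree_biomass(co$d[thin], cfg) # kg/tree
      # target biomass per m2; with f <= thr no stem count can lift suppression
      b_target <- ifelse(f > thr, v$b_half * (f / thr - 1), 0)
      stems_max <- floor(b_target * grid$area / per_tree)
      co$stems[thin] <- pmin(co$stems[thin], pmax(stems_max, 0))
      co$supp[thin] <- ifelse(co$stems[thin] > 0, 0L, co$supp[thin])
    }
    # upper-elevation taper: accretion beyond the tidal frame kills stems
    if (!is.null(bed)) {
      z <- as.vector(bed$elevation)[co$cell]
      over <- z > hw_level
      if (any(over)) {
        keep <- pmax(0, 1 - (z[over] - hw_level) / v$taper_width)
        co$stems[over] <- floor(co$stems[over] * keep)
      }
    }
    veg$cohorts <- co[co$stems > 0, , drop = FALSE]
  }
  # ghost pneumatophores decay on the annual clock
  if (nrow(veg$ghost_roots) > 0) {
    veg$ghost_roots$years_left <- veg$ghost_roots$years_left - 1
    veg$ghost_roots <- veg$ghost_roots[veg$ghost_roots$years_left > 0, ,
                                       drop = FALSE]
  }
  veg$blocked <- integer() # cleared cells become recolonizable
  veg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mangrove removal intervention
#'
#' Clears the requested fraction of the vegetated area. Selection is
#' seaward-first by default (mimicking mapped clearance campaigns) or
#' uniform-random under a seed. Stems disappear immediately; with a positive
#' root persistence the pneumatophore roughness of the cleared cells remains
#' for that many years before vanishing. Cleared cells are recolonizable
#' from the next ecological year.
#'
#' @param veg an `mm_veg`
#' @param fraction fraction of vegetated area to clear, in (0, 1]
#' @param grid an `mm_grid`
#' @param cfg an [mm_config()]
#' @param mode `"seaward"` or `"random"`
#' @param root_persistence_years years pneumatophores persist after removal
#' @return updated `mm_veg`
#' @export
remove_mangroves <- function(veg, fraction, grid, cfg = mm_config(),
                             mode = cfg$vegetation$removal_mode,
                             root_persistence_years = 0) {
  if (fraction <= 0 || fraction > 1) abort("removal fraction must be in (0, 1]")
  cells <- unique(veg$cohorts$cell)
  if (length(cells) == 0) return(veg)
  n_rm <- round(fraction * length(cells))
  if (fraction == 1) n_rm <- length(cells)
  sel <- switch(mode,
    seaward = {
      i <- (cells - 1L) %% grid$nx + 1L
      cells[order(i)][seq_len(n_rm)]
    },
    random = sample(cells, n_rm),
    abort(paste0("unknown removal mode: ", mode))
  )
  if (root_persistence_years > 0) {
    co <- veg$cohorts[veg$cohorts$cell %in% sel, , drop = FALSE]
    v <- cfg$vegetation
    n_per_tree <- pmin(v$pneu_coef * co$d^2, v$pneu_max)
    m_pneu <- co$stems * n_per_tree / grid$area
    agg <- rowsum(m_pneu, co$cell)
    veg$ghost_roots <- rbind(
      veg$ghost_roots,
      data.frame(cell = as.integer(rownames(agg)), m_pneu = agg[, 1],
                 years_left = root_persistence_years)
    )
  }
  veg$cohorts <- veg$cohorts[!(veg$cohorts$cell %in% sel), , drop = FALSE]
  veg$blocked <- unique(c(veg$blocked, as.integer(sel)))
  veg
}

#' Roughness-object summary of the vegetation
#'
#' Maps each cell's cohorts onto the two roughness-object classes consumed by
#' the flow solver: stems (height = tree height, diameter = stem diameter)
#' and pneumatophores (fixed 10 cm height, count growing with tree size),
#' including ghost roots left by removal. Densities follow n = m D with m the
#' object count per unit area and D the object diameter in metres.
#'
#' @param veg an `mm_veg`
#' @param grid an `mm_grid`
#' @param cfg an [mm_config()]
#' @return list of classes `stem` and `pneu`, each with per-cell matrices
#'   `h_v` (m), `n` (1/m) and `m` (1/m2)
#' @export
to_roughness_summary <- function(veg, grid, cfg = mm_config()) {
  v <- cfg$vegetation
  ncell <- grid$nx * grid$ny
  m_stem <- n_stem <- hv_stem <- numeric(ncell)
  m_pneu <- numeric(ncell)
  co <- veg$cohorts
  if (nrow(co) > 0) {
    m <- co$stems / grid$area                 # stems per m2
    d_m <- co$d / 100                         # stem diameter in m
    h_m <- tree_height(co$d, cfg) / 100       # height in m
    agg_m <- rowsum(m, co$cell)
    agg_n <- rowsum(m * d_m, co$cell)
    agg_h <- rowsum(m * h_m, co$cell)         # stem-weighted height
    idx <- as.integer(rownames(agg_m))
    m_stem[idx] <- agg_m[, 1]
    n_stem[idx] <- agg_n[, 1]
    hv_stem[idx] <- agg_h[, 1] / pmax(agg_m[, 1], 1e-12)
    pneu_per_tree <- pmin(v$pneu_coef * co$d^2, v$pneu_max)
    agg_p <- rowsum(co$stems * pneu_per_tree / grid$area, co$cell)
    m_pneu[as.integer(rownames(agg_p))] <- agg_p[, 1]
  }
  if (nrow(veg$ghost_roots) > 0) {
    m_pneu[veg$ghost_roots$cell] <- m_pneu[veg$ghost_roots$cell] +
      veg$ghost_roots$m_pneu
  }
  dims <- c(grid$nx, grid$ny)
  list(
    stem = list(h_v = matrix(pmax(hv_stem, 0.01), dims[1], dims[2]),
                n = matrix(n_stem, dims[1], dims[2]),
                m = matrix(m_stem, dims[1], dims[2])),
    pneu = list(h_v = matrix(v$pneu_height, dims[1], dims[2]),
                n = matrix(m_pneu * v$pneu_diameter, dims[1], dims[2]),
                m = matrix(m_pneu, dims[1], dims[2]))
  )
}
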