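#' Initialize a run state
#'
#' Builds the grid, initial bathymetry and substrate, a resting flow field,
#' clear water and an empty vegetation state.
#'
#' @param cfg an [mm_config()]
#' @return an `mm_state`
#' @export
new_run_state <- function(cfg = mm_config()) {
  grid <- build_grid(cfg)
  bed <- init_bathymetry(grid, cfg)
  ctype <- matrix(1L, grid$nx, grid$ny)
  ctype[grid$role == "barrier"] <- 0L
  ctype[grid$role == "open_sea_boundary"] <- 2L
  riv <- do.call(rbind, grid$rivers)
  zero <- matrix(0, grid$nx, grid$ny)
  structure(list(
    grid = grid, cfg = cfg, ctype = ctype,
    river_cells = riv[, 1] + (riv[, 2] - 1L) * grid$nx,
    river_q_cell = rep(cfg$rivers$discharge / nrow(grid$rivers$head),
                       nrow(riv)),
    inlet_faces = grid$inlet[, 1] + (grid$inlet[, 2] - 1L) * grid$nx,
    bed = bed,
    eta = pmax(zero, bed$elevation), u = zero, v = zero,
    c_mud = zero, c_sand = zero, m_mud = zero, m_sand = zero,
    c_return = 0,
    susp_mass = c(mud = 0, sand = 0),
    t_phase = 0, year = 0, season = 1L,
    veg = init_vegetation(),
    diag = NULL,
    ledger = list(river_mud = 0, boundary_mud = 0, exch_mud = 0,
                  river_sand = 0, boundary_sand = 0, exch_sand = 0,
                  water_clip = 0),
    closure = c(max_susp_resid = 0, max_bed_resid = 0),
    config_hash = config_hash(cfg)
  ), class = "mm_state")
}

#' @export
print.mm_state <- function(x, ...) {
  cat("<mm_state> year", x$year, "season", x$season, "\n")
  invisible(x)
}

#' Advance one ecological season
#'
#' Simulates the configured number of representative M2 cycles with the
#' current vegetation roughness field (the morphological acceleration factor
#' is chosen so the simulated hydrodynamic time maps onto exactly one
#' season), applies the resulting erosion/deposition to the stratigraphy,
#' and then performs the season's vegetation step: colonization at the first
#' season of the ecological year, growth every season, mortality and
#' self-thinning at the last.
#'
#' @param state an `mm_state`
#' @param mud_conc river mud concentration for this season (kg/m3)
#' @param veg_on whether the vegetation life cycle is active
#' @return updated `mm_state`
#' @export
run_season <- function(state, mud_conc, veg_on = TRUE) {
  cfg <- state$cfg
  grid <- state$grid
  tp <- tide_parameters(cfg)
  season_s <- 365.25 * 86400 / cfg$vegetation$seasons_per_year
  cycles <- cfg$scenario$cycles_per_season
  spc <- round(tp$period / cfg$hydro$dt)
  dt <- tp$period / spc                     # integer steps per cycle
  morfac_eff <- season_s / (cycles * tp$period)

  # vegetation -> roughness at the representative (high-tide) depth
  summary <- to_roughness_summary(state$veg, grid, cfg)
  h_rep <- pmax(cfg$metrics$hw_level - state$bed$elevation,
                2 * cfg$hydro$dry_depth)
  rf <- roughness_fields(summary, h_rep, cfg)

  # tidal-frame reference: always-connected subtidal basin cells
  basin <- as.vector(basin_mask(grid))
  ref_cells <- which(basin & as.vector(state$bed$elevation) <
                       cfg$metrics$mlw_level)
  if (length(ref_cells) == 0) {
    ref_cells <- state$inlet_faces
  }
  out <- step_flow(
    z = state$bed$elevation, ctype = state$ctype, dx = grid$dx, dt = dt,
    nsteps = cycles * spc, eta = state$eta, u = state$u, v = state$v,
    cr = rf$cr, lambda = rf$lambda,
    amp = tp$amplitude, omega = tp$omega, t0 = state$t_phase,
    river_cells = state$river_cells, river_q = state$river_q_cell,
    c_river_mud = mud_conc, m_mud = state$m_mud, m_sand = state$m_sand,
    p_surf = surface_mud_fraction(state$bed),
    stack_mud = stack_mud_mass(state$bed, cfg$sediment$rho_dry_mud),
    floor_z = state$bed$floor, erodible = state$bed$erodible,
    transport = TRUE, morpho = TRUE, morfac = morfac_eff,
    diag_start = (cycles - 1L) * spc, inlet_faces = state$inlet_faces,
    ref_cells = ref_cells, c_return0 = state$c_return, cfg = cfg)

  # --- stratigraphy bookkeeping -----------------------------------------
  sed <- cfg$sediment
  dz_kernel <- out$z - state$bed$elevation
  ero_mud <- as.vector(out$parent_mud) / sed$rho_dry_mud
  ero_sand <- as.vector(out$parent_sand) / sed$rho_dry_sand
  dep_mud <- as.vector(out$new_mud) / sed$rho_dry_mud
  dep_sand <- as.vector(out$new_sand) / sed$rho_dry_sand
  cells <- which(ero_mud + ero_sand > 0 | dep_mud + dep_sand > 0)
  state$bed$strat <- strat_remove(state$bed$strat, cells, ero_mud[cells],
                                  ero_sand[cells])
  state$bed$strat <- strat_deposit(state$bed$strat, cells, dep_mud[cells],
                                   dep_sand[cells],
                                   nominal = sed$layer_thickness)
  # bed bookkeeping must agree with the kernel's elevation change
  bed_resid <- max(abs(as.vector(dz_kernel) -
                         (dep_mud + dep_sand - ero_mud - ero_sand)))
  state$bed$elevation <- out$z

  # --- mass-closure diagnostics -----------------------------------------
  led <- out$ledger
  susp_new <- c(mud = led_num(out$susp_mass[1]), sand = led_num(out$susp_mass[2]))
  rhs_mud <- led$river_mud + led$boundary_mud + led$exch_mud + led$clip_mud
  rhs_sand <- led$boundary_sand + led$exch_sand + led$clip_sand
  scale_mud <- max(abs(susp_new[1]), abs(led$river_mud), abs(led$exch_mud), 1)
  scale_sand <- max(abs(susp_new[2]), abs(led$exch_sand), 1)
  susp_resid <- max(
    abs(susp_new[1] - state$susp_mass[1] - rhs_mud) / scale_mud,
    abs(susp_new[2] - state$susp_mass[2] - rhs_sand) / scale_sand)
  state$closure["max_susp_resid"] <- max(state$closure["max_susp_resid"],
                                         susp_resid)
  state$closure["max_bed_resid"] <- max(state$closure["max_bed_resid"],
                                        bed_resid)
  state$susp_mass <- susp_new
  for (nm in c("river_mud", "boundary_mud", "exch_mud", "boundary_sand",
               "exch_sand")) {
    state$ledger[[nm]] <- state$ledger[[nm]] + led[[nm]]
  }
  state$ledger$water_clip <- state$ledger$water_clip + led$clip_water

  # --- carry flow state --------------------------------------------------
  state$eta <- out$eta; state$u <- out$u; state$v <- out$v
  state$c_mud <- out$c_mud; state$c_sand <- out$c_sand
  state$m_mud <- out$m_mud; state$m_sand <- out$m_sand
  state$c_return <- out$c_return
  state$t_phase <- out$t_end
  # habitat hydroperiod: inundation by the connected tide (the raw wet
  # fraction counts water ponded on the flats after ebb, an artifact of
  # unresolved creek drainage at coarse resolution)
  hp_tidal <- hydroperiod(out$ref_eta, as.vector(state$bed$elevation))
  state$diag <- list(hydroperiod = matrix(hp_tidal, grid$nx, grid$ny),
                     wet_fraction = out$hydroperiod,
                     tau_max = out$tau_max,
                     tau_mean = out$tau_mean, inlet_q = out$inlet_q, dt = dt)

  # --- seasonal vegetation step ------------------------------------------
  if (veg_on && cfg$vegetation$enabled) {
    hp <- hp_tidal
    tau_stat <- if (identical(cfg$vegetation$tau_stat, "mean")) {
      as.vector(out$tau_mean)
    } else {
      as.vector(out$tau_max)
    }
    if (state$season == 1L) {
      state$veg <- attempt_colonization(state$veg, hp, tau_stat, grid, cfg)
    }
    stress <- compute_stress(state$veg, hp, grid, cfg)
    state$veg <- grow_cohorts(state$veg, stress, cfg)
    if (state$season == cfg$vegetation$seasons_per_year) {
      stress <- compute_stress(state$veg, hp, grid, cfg)
      state$veg <- apply_mortality(state$veg, stress, grid, state$bed, cfg)
    }
  }

  # --- clock -------------------------------------------------------------
  if (state$season == cfg$vegetation$seasons_per_year) {
    state$season <- 1L
    state$year <- state$year + 1
  } else {
    state$season <- state$season + 1L
  }
  state
}

led_num <- function(x) as.numeric(x)

#' Run a management scenario
#'
#' Executes a scenario plan: spin-up without vegetation, the pre-disturbance
#' and disturbance phases, and the management branch, firing removal events
#' and recording landscape metrics annually and grid snapshots at the
#' configured epoch years. A run can resume from the final state of another
#' run whose configuration and earlier phases match, so management branches
#' share one spin-up/disturbance trajectory.
#'
#' @param plan an `mm_plan` from [make_scenario()] (or a catalogue name)
#' @param cfg an [mm_config()]
#' @param resume_from an `mm_run` (or `mm_state`) to continue from
#' @param until final year (defaults to the plan horizon)
#' @param seed RNG seed (only the random removal mode draws random numbers)
#' @param quiet suppress progress messages
#' @return an `mm_run`: list with `plan`, `cfg`, final `state`, annual
#'   `metrics` tibble, and `snapshots`
#' @export
run_scenario <- function(plan, cfg = mm_config(), resume_from = NULL,
                         until = NULL, seed = 1L, quiet = TRUE) {
  if (is.character(plan)) plan <- make_scenario(plan, cfg)
  set.seed(seed)
  metrics <- list()
  snapshots <- list()
  if (is.null(resume_from)) {
    state <- new_run_state(cfg)
  } else {
    prior <- if (inherits(resume_from, "mm_run")) resume_from else
      list(state = resume_from, metrics = NULL, snapshots = list())
    state <- prior$state
    if (!identical(state$config_hash, config_hash(cfg))) {
      abort("cannot resume: configuration differs from the checkpoint")
    }
    if (!is.null(prior$metrics)) metrics <- list(prior$metrics)
    snapshots <- prior$snapshots
  }
  until <- until %||% plan$horizon
  if (until <= state$year) abort("nothing to simulate: already past 'until'")

  t_start <- Sys.time()
  while (state$year < until) {
    y <- state$year
    # snapshot of the state entering this year
    ylab <- as.character(round(y))
    if (round(y) %in% cfg$scenario$snapshot_years &&
        is.null(snapshots[[ylab]])) {
      snapshots[[ylab]] <- take_snapshot(state, plan)
    }
    # events fire when their year begins
    ev <- plan$events[plan$events$year == round(y), , drop = FALSE]
    if (nrow(ev) > 0) {
      for (k in seq_len(nrow(ev))) {
        if (ev$kind[k] == "remove_vegetation") {
          state$veg <- remove_mangroves(
            state$veg, ev$fraction[k], state$grid, cfg,
            root_persistence_years = ev$persistence[k])
        }
      }
    }
    mud <- plan_mud_conc(plan, y + 1e-6)
    veg_on <- plan_vegetation_on(plan, y + 1e-6)
    for (s in seq_len(cfg$vegetation$seasons_per_year)) {
      state <- run_season(state, mud, veg_on)
    }
    metrics[[length(metrics) + 1]] <- annual_metrics(state, plan, mud)
    if (!quiet && round(state$year) %% 50 == 0) {
      message(sprintf("[%s] year %d (%.1f min elapsed)", plan$name,
                      round(state$year),
                      as.numeric(Sys.time() - t_start, units = "mins")))
    }
  }
  ylab <- as.character(round(state$year))
  if (round(state$year) %in% cfg$scenario$snapshot_years &&
      is.null(snapshots[[ylab]])) {
    snapshots[[ylab]] <- take_snapshot(state, plan)
  }
  structure(list(plan = plan, cfg = cfg, state = state,
                 metrics = bind_rows(metrics), snapshots = snapshots,
                 runtime_s = as.numeric(Sys.time() - t_start,
                                        units = "secs")),
            class = "mm_run")
}

annual_metrics <- function(state, plan, mud_conc) {
  cfg <- state$cfg
  syp <- sediment_yield_and_prism(mud_conc, state$diag$inlet_q,
                                  state$diag$dt, cfg)
  tibble(
    scenario = plan$name,
    year = round(state$year),
    accommodation_m3 = accommodation_space(state$bed, state$grid, cfg = cfg),
    muddy_fraction = muddy_region_fraction(state$bed, state$grid, cfg = cfg),
    coverage = mangrove_coverage(state$veg, state$grid),
    amsl = relative_area_amsl(state$bed, state$grid, cfg = cfg),
    SY_kg = syp$SY_kg, TP_m3 = syp$TP_m3, SY_TP = syp$SY_TP,
    susp_resid = state$closure[["max_susp_resid"]],
    bed_resid = state$closure[["max_bed_resid"]]
  )
}

take_snapshot <- function(state, plan) {
  grid <- state$grid
  cover <- rep(FALSE, grid$nx * grid$ny)
  cover[state$veg$cohorts$cell] <- TRUE
  mean_d <- rep(NA_real_, grid$nx * grid$ny)
  if (nrow(state$veg$cohorts) > 0) {
    agg <- rowsum(state$veg$cohorts$d * state$veg$cohorts$stems,
                  state$veg$cohorts$cell)
    aggn <- rowsum(state$veg$cohorts$stems, state$veg$cohorts$cell)
    mean_d[as.integer(rownames(agg))] <- agg[, 1] / aggn[, 1]
  }
  list(
    year = round(state$year),
    scenario = plan$name,
    elevation = state$bed$elevation,
    mud_top1m = matrix(mud_fraction_top1m(state$bed), grid$nx, grid$ny),
    vegetated = matrix(cover, grid$nx, grid$ny),
    mean_diameter_cm = matrix(mean_d, grid$nx, grid$ny),
    hydroperiod = state$diag$hydroperiod,
    tau_max = state$diag$tau_max
  )
}

#' @export
print.mm_run <- function(x, ...) {
  m <- tail(x$metrics, 1)
  cat("<mm_run> ", x$plan$name, ": ", nrow(x$metrics), " years simulated\n",
      sep = "")
  if (nrow(m) > 0) {
    cat(sprintf(
      "  year %d: accommodation %.3g m3, muddy %.3f, coverage %.3f, aMSL %.3f\n",
      m$year, m$accommodation_m3, m$muddy_fraction, m$coverage, m$amsl))
  }
  invisible(x)
}
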