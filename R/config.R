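#' Build a run configuration
#'
#' Assembles the full set of physical and numerical parameters governing a
#' simulation, with defaults describing an idealized back-barrier estuary on
#' the North Island of New Zealand: a 4 km x 2 km basin behind two
#' non-erodible barriers, connected through a central inlet to a 2 km x 2 km
#' offshore area, forced by an M2 tide of 1.5 m range (30 deg/hr) and three
#' rivers of 18 m3/s each whose mud concentration is the management lever.
#'
#' Every parameter can be overridden by name using nested lists, e.g.
#' `mm_config(hydro = list(dt = 120))`. Unknown keys are rejected so typos
#' cannot silently fall back to defaults.
#'
#' @param ... named overrides for the top-level groups `domain`, `tide`,
#'   `rivers`, `hydro`, `sediment`, `vegetation`, `scenario`, `metrics`.
#'   Each must be a named list; entries replace the corresponding defaults.
#' @return An object of class `mm_config`: a named nested list.
#' @examples
#' cfg <- mm_config()
#' cfg$tide$range
#' cfg <- mm_config(domain = list(resolution = 120))
#' @export
mm_config <- function(...) {
  defaults <- mm_default_config()
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad) > 0) {
    abort(paste0("Unknown config group(s): ", paste(bad, collapse = ", ")))
  }
  cfg <- defaults
  for (grp in names(overrides)) {
    ov <- overrides[[grp]]
    if (!is.list(ov) || is.null(names(ov)) || any(names(ov) == "")) {
      abort(paste0("Override for group '", grp, "' must be a named list"))
    }
    unknown <- setdiff(names(ov), names(defaults[[grp]]))
    if (length(unknown) > 0) {
      abort(paste0("Unknown key(s) in group '", grp, "': ",
                   paste(unknown, collapse = ", ")))
    }
    cfg[[grp]] <- modifyList(cfg[[grp]], ov)
  }
  validate_config(cfg)
  structure(cfg, class = "mm_config")
}

mm_default_config <- function() {
  list(
    domain = list(
      basin_length    = 4000,   # m, along-estuary
      basin_width     = 2000,   # m
      offshore_length = 2000,   # m
      resolution      = 60,     # m cell size (desk-scale default; 15 m is the
                                # reference resolution of the full-scale study)
      inlet_width     = 300,    # m opening between the two barrier strips
      basin_z0        = -1.5,   # m MSL initial basin platform elevation
      offshore_zmax   = -100,   # m MSL depth at the open boundary
      substrate_depth = 10      # m of erodible sand above the non-erodible floor
    ),
    tide = list(
      range     = 1.5,          # m, single M2 constituent
      freq_deg_hr = 30,         # deg/hr -> 12 h period
      phase     = 0
    ),
    rivers = list(
      n          = 3,
      discharge  = 18,          # m3/s each (north, head, south)
      width      = 30,          # m (about twice the 15-m reference cell)
      mud_low    = 5,           # mg/L pre-disturbance concentration
      mud_high   = 15,          # mg/L post-deforestation concentration
      mud_mid    = 10           # mg/L 'intermediate' management level
    ),
    hydro = list(
      dt           = 240,       # s, ADI solver step (tide is quasi-static at
                                # basin scale so large Courant numbers are fine)
      dry_depth    = 0.05,      # m wetting/drying threshold
      chezy_bed    = 65,        # m^(1/2)/s unvegetated Chezy coefficient
      kappa        = 0.41,      # von Karman constant
      g            = 9.81,      # m/s2
      rho_water    = 1025,      # kg/m3
      u_max        = 3.0,       # m/s velocity cap damping drying-front spikes
      drag_cd      = 1.0,       # vegetation drag coefficient
      multi_class  = TRUE       # combine stem+pneumatophore roughness classes
    ),
    sediment = list(
      d50_sand        = 250e-6, # m median sand grain size
      erosion_rate    = 5e-5,   # kg/m2/s Partheniades-Krone M
      tau_ce          = 0.5,    # N/m2 critical erosion stress for mud
      tau_cd          = 0.5,    # N/m2 critical deposition stress (Krone):
                                # mud settles onto the bed only where currents
                                # are weak enough, which lets vegetation-
                                # damped flats trap mud preferentially
      ws_mud          = 2e-3,   # m/s mud settling velocity (flocculated)
      ws_sand         = 0.03,   # m/s sand settling velocity
      u_crit_sand     = 0.28,   # m/s critical depth-averaged velocity (Shields)
      eh_coef         = 0.02,   # Engelund-Hansen-type capacity coefficient
      bedload_frac    = 0.7,    # share of sand capacity carried as bedload
      alpha_bn        = 1.5,    # transverse bed-slope coefficient
      alpha_bs        = 1.0,    # longitudinal slope damping coefficient
      diffusivity     = 0.2,    # m2/s explicit horizontal dispersion, kept
                                # small: upwind transport already mixes at
                                # ~u*dx/2 where flow is active, and large
                                # values drain the basin through the deep
                                # offshore column (conductance scales with h)
      morfac          = 90,     # morphological acceleration factor
      rho_dry_mud     = 500,    # kg/m3 dry bulk density of mud deposits
      rho_dry_sand    = 1600,   # kg/m3 dry bulk density of sand
      max_dz_step     = 0.05,   # m bed-change limiter per solver step
      layer_thickness = 0.1,    # m nominal stratigraphy layer thickness
      sea_mud_conc    = 0,      # kg/m3 ambient mud in inflowing sea water
      boundary_return = 0,      # fraction of the recently exported mud
                                # concentration returned on inflow
                                # (Thatcher-Harleman-style plume memory;
                                # 0 = every crossing is lost to the ocean)
      dep_ceiling     = 0.75,   # m MSL intertidal accretion ceiling: settling
                                # requires tidal inundation, so deposition
                                # fades as a cell aggrades toward mean high
                                # water and stops there
      dep_taper       = 0.5,    # m taper width below the ceiling over which
                                # the deposition rate ramps down linearly
      morpho_min_z    = -15     # m MSL: morphology is frozen on the deep
                                # offshore slope (no shoaling seaward of the
                                # inlet; only the upper slope is active)
    ),
    vegetation = list(
      enabled          = TRUE,
      d_max            = 18,    # cm maximum stem diameter
      h_max            = 320,   # cm maximum tree height
      growth_g         = 162,   # cm/yr JABOWA-type growth constant
      b2               = 2 * (320 - 137) / 18,      # cm/cm allometry slope
      b3               = (320 - 137) / 18^2,        # cm/cm2 allometry curvature
      seedling_d0      = 0.5,   # cm initial stem diameter
      seed_density_ha  = 3000,  # seedlings per hectare at colonization
      hp_min           = 0,     # colonization hydroperiod window (exclusive)
      hp_max           = 0.5,   # (inclusive)
      tau_crit         = 0.2,   # N/m2 max bed shear stress for settlement
      tau_stat         = "mean", # cycle statistic gating colonization; the
                                # cycle maximum is config-switchable but is
                                # contaminated by drying-front velocity spikes
                                # on emergent flats at coarse resolution
      hp_opt           = 0.25,  # optimum of the hydroperiod fitness curve
      f_dry            = 0,     # fitness at hydroperiod 0 (never flooded)
      biomass_a        = 0.308, # kg per tree = a * D[cm]^b (A. marina)
      biomass_b        = 2.11,
      b_half           = 15,    # kg/m2 biomass at which competition C = 0.5
      suppression_threshold = 0.5,  # f*C below this counts as suppression
      suppression_years = 5,    # consecutive years before self-thinning
      pneu_height      = 0.10,  # m pneumatophore height
      pneu_diameter    = 0.01,  # m pneumatophore diameter
      pneu_coef        = 25,    # pneumatophores per tree = coef * D[cm]^2
      pneu_max         = 10000, # cap per tree
      seasons_per_year = 4,
      removal_mode     = "seaward", # or "random"
      taper_width      = 0.5    # m elevation band above MHW over which stem
                                # density is linearly reduced to zero
    ),
    scenario = list(
      spinup_years      = 200,
      predisturb_years  = 200,  # low mud supply, year 200-400
      disturb_years     = 100,  # high mud supply, year 400-500
      horizon           = 600,
      cycles_per_season = 1,    # representative M2 cycles simulated per
                                # season; the effective acceleration factor is
                                # season_seconds/(cycles * tidal period)
      snapshot_years    = c(200, 400, 430, 450, 500, 600)
    ),
    metrics = list(
      hw_level          = 0.75, # m MSL high-tide level (tidal amplitude)
      mlw_level         = -0.75,
      muddy_threshold   = 0.30, # top-1 m mud fraction defining 'muddy'
      relief_threshold  = 0.3,  # m residual relief defining channels
      relief_window     = 9,    # cells, moving-median window (at 60 m)
      near_channel_max  = 100,  # m
      far_channel_range = c(300, 400) # m
    )
  )
}

validate_config <- function(cfg) {
  d <- cfg$domain
  if (d$resolution <= 0) abort("resolution must be positive")
  if (d$resolution > d$inlet_width / 2) {
    abort("resolution too coarse: the inlet must span at least 2 cells")
  }
  if (cfg$tide$range <= 0) abort("tidal range must be positive")
  if (cfg$rivers$discharge < 0) abort("river discharge must be non-negative")
  with(cfg$sediment, {
    stopifnot(morfac >= 1, erosion_rate > 0, tau_ce > 0, ws_mud > 0,
              rho_dry_mud > 0, rho_dry_sand > 0)
  })
  v <- cfg$vegetation
  if (v$d_max <= 0 || v$h_max <= 137) abort("vegetation size limits invalid")
  invisible(cfg)
}

#' Tidal angular frequency and period
#' @param cfg an [mm_config()] object
#' @return list with `omega` (rad/s), `period` (s), `amplitude` (m)
#' @export
tide_parameters <- function(cfg) {
  omega <- cfg$tide$freq_deg_hr * pi / 180 / 3600
  list(omega = omega, period = 2 * pi / omega, amplitude = cfg$tide$range / 2)
}

#' Read / write a configuration as YAML
#'
#' Round-trips the full parameter set so a run is reproducible from the file
#' alone. Unknown keys in the file are rejected on read.
#'
#' @param cfg an `mm_config` object
#' @param path file path
#' @return `write_config` returns `path` invisibly; `read_config` returns an
#'   `mm_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "mm_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(mm_config, raw)
}

#' Hash of a configuration
#'
#' Stable content hash used to guard checkpoint/resume against mismatched
#' parameter sets.
#' @param cfg an `mm_config` object
#' @return a character scalar
#' @export
config_hash <- function(cfg) {
  norm <- rapply(unclass(cfg), function(x) {
    if (is.numeric(x)) signif(x, 12) else x
  }, how = "replace")
  s <- paste(deparse(norm, control = "exact"), collapse = "")
  # small polynomial rolling hash; no external digest dependency
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
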