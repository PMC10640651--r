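#' Vegetation-modified bed roughness (Baptist formulation)
#'
#' Representative Chezy coefficient of a vegetated bed. For emergent
#' vegetation (`h < h_v`) the bed value `C_b` applies; for submerged
#' vegetation the canopy adds a logarithmic overflow correction:
#' \deqn{C_r = C_b + \frac{\sqrt{g}}{\kappa}\ln(h/h_v)
#'   \sqrt{1 + C_D n h_v C_b^2 / (2g)}}
#' with vegetation density `n = m D` (frontal area per unit bed area, 1/m).
#'
#' @param h water depth (m), > 0; vectorized
#' @param h_v vegetation object height (m)
#' @param n vegetation density m*D (1/m)
#' @param cb bed Chezy coefficient (m^(1/2)/s)
#' @param cd drag coefficient
#' @param g gravity (m/s2)
#' @param kappa von Karman constant
#' @return representative Chezy coefficient (same shape as `h`)
#' @export
baptist_roughness <- function(h, h_v, n, cb = 65, cd = 1, g = 9.81,
                              kappa = 0.41) {
  if (any(h <= 0)) abort("water depth must be positive")
  sub <- h >= h_v & n > 0
  cr <- rep_len(cb, length(h)) + 0 * h
  if (any(sub)) {
    hs <- h[sub]
    hvs <- rep_len(h_v, length(h))[sub]
    ns <- rep_len(n, length(h))[sub]
    cr[sub] <- cb + sqrt(g) / kappa * log(hs / hvs) *
      sqrt(1 + cd * ns * hvs * cb^2 / (2 * g))
  }
  cr
}

#' Vegetation momentum-resistance coefficient
#'
#' The coefficient of the additional momentum sink \eqn{-(\lambda/2) u |u|}
#' that corrects the shear-stress partitioning over a vegetated bed:
#' \eqn{\lambda = C_D n (h_v/h) C_b^2/C_r^2} when the canopy is submerged and
#' \eqn{\lambda = C_D n} when emergent.
#'
#' @inheritParams baptist_roughness
#' @param cr representative Chezy value from [baptist_roughness()]
#' @return lambda (1/m), same shape as `h`
#' @export
vegetation_lambda <- function(h, h_v, n, cr, cb = 65, cd = 1) {
  if (any(h <= 0)) abort("water depth must be positive")
  n <- rep_len(n, length(h)) + 0 * h
  h_v <- rep_len(h_v, length(h))
  cr <- rep_len(cr, length(h))
  lam <- cd * n
  sub <- h >= h_v
  lam[sub] <- cd * n[sub] * (h_v[sub] / h[sub]) * (cb^2 / cr[sub]^2)
  lam
}

#' Combined roughness fields from a vegetation summary
#'
#' Combines multiple roughness-object classes in one cell (pneumatophores and
#' stems) into a single representative Chezy field and total resistance
#' coefficient. Classes are applied in order of increasing object height,
#' each taking the previously accumulated Chezy value as its bed roughness;
#' lambda contributions are additive (each evaluated against the final
#' combined Chezy value).
#'
#' @param summary a vegetation summary as returned by
#'   [to_roughness_summary()]: list of classes, each with matrices/vectors
#'   `h_v` (m) and `n` (1/m)
#' @param h water depth (m), matrix or vector
#' @param cfg an [mm_config()]
#' @return list with `cr` and `lambda` fields shaped like `h`
#' @export
roughness_fields <- function(summary, h, cfg = mm_config()) {
  hy <- cfg$hydro
  hpos <- pmax(h, 1e-3)
  classes <- summary[order(vapply(summary, function(cl) mean(cl$h_v),
                                  numeric(1)))]
  if (!isTRUE(hy$multi_class) && length(classes) > 1) {
    # single-class mode: keep the dominant (tallest) class only
    classes <- classes[length(classes)]
  }
  cr <- hpos * 0 + hy$chezy_bed
  for (cl in classes) {
    sub <- hpos >= cl$h_v & cl$n > 0
    if (any(sub)) {
      cr[sub] <- cr[sub] + sqrt(hy$g) / hy$kappa *
        log(hpos[sub] / cl$h_v[sub]) *
        sqrt(1 + hy$drag_cd * cl$n[sub] * cl$h_v[sub] * cr[sub]^2 /
               (2 * hy$g))
    }
  }
  lam <- hpos * 0
  for (cl in classes) {
    lam <- lam + vegetation_lambda(hpos, cl$h_v, cl$n, cr,
                                   cb = hy$chezy_bed, cd = hy$drag_cd)
  }
  lam[lam < 0] <- 0
  list(cr = cr, lambda = lam)
}

#' Bed shear stress from depth-averaged flow
#'
#' Chezy relation \eqn{\tau = \rho_w g (u^2 + v^2) / C_r^2}; dry cells carry
#' zero stress.
#'
#' @param u,v depth-averaged velocity components (m/s)
#' @param cr representative Chezy coefficient
#' @param wet logical mask (optional); dry cells are zeroed
#' @param rho_w water density (kg/m3)
#' @param g gravity
#' @return shear stress (N/m2), same shape as `u`
#' @export
bed_shear_stress <- function(u, v = 0, cr = 65, wet = NULL, rho_w = 1025,
                             g = 9.81) {
  tau <- rho_w * g * (u^2 + v^2) / cr^2
  if (!is.null(wet)) tau[!wet] <- 0
  tau
}

#' Relative hydroperiod
#'
#' Fraction of a tidal cycle a location is inundated. Under the single M2
#' constituent used here, a cell at mean sea level is flooded half the time
#' (hydroperiod 0.5) and a cell at or above mean high water never is.
#'
#' @param eta water-level series (m MSL): a vector (uniform over cells) or a
#'   matrix `[time, cell]`
#' @param bed_elev bed elevation (m MSL), one value per cell
#' @param dt sampling interval of `eta` (s); together with `period` used to
#'   check that at least one full cycle is covered
#' @param period tidal period (s)
#' @return hydroperiod in `[0, 1]` per cell
#' @export
hydroperiod <- function(eta, bed_elev, dt = NULL, period = NULL) {
  if (!is.null(dt) && !is.null(period)) {
    nt <- if (is.matrix(eta)) nrow(eta) else length(eta)
    if (nt * dt < period - 1e-9) {
      abort("water-level series must span at least one full tidal cycle")
    }
  }
  if (is.matrix(eta)) {
    colMeans(eta > matrix(bed_elev, nrow(eta), ncol(eta), byrow = TRUE))
  } else {
    vapply(bed_elev, function(z) mean(eta > z), numeric(1))
  }
}

#' Tidal prism from an inlet discharge series
#'
#' Volume of water carried through the inlet in the flood direction over one
#' tidal cycle. The flood side is identified as the larger of the two
#' directional integrals, so the result does not depend on the sign
#' convention of the series.
#'
#' @param q discharge series through the inlet section (m3/s)
#' @param dt sampling interval (s)
#' @return tidal prism (m3)
#' @export
tidal_prism <- function(q, dt) {
  max(sum(pmax(q, 0)), sum(pmax(-q, 0))) * dt
}

#' Advance the shallow-water solver
#'
#' Thin wrapper over the compiled ADI solver used both by the scenario engine
#' and directly in analyses/tests. Solves the depth-averaged continuity and
#' momentum balance (pressure gradient, Chezy bed friction, vegetation
#' momentum sink, wetting/drying) with water level clamped at open-boundary
#' cells and river discharge injected at inflow cells; optionally transports
#' suspended mud/sand and updates the bed with morphological acceleration.
#'
#' @param z bed elevation matrix (m MSL)
#' @param ctype integer matrix: 0 inactive, 1 active, 2 clamped water level
#' @param dx cell size (m)
#' @param dt solver step (s)
#' @param nsteps number of steps
#' @param eta,u,v initial fields (matrices or scalars; `u`, `v` live on the
#'   right/top faces of each cell)
#' @param cr,lambda roughness fields (matrices or scalars)
#' @param eta_offset per-cell offset of the clamped water level (m)
#' @param amp,omega,phase tidal amplitude (m), angular frequency (rad/s) and
#'   phase of the clamped level
#' @param t0 start time (s)
#' @param river_cells integer vector of flattened cell indices (1-based)
#' @param river_q discharge per river cell (m3/s)
#' @param c_river_mud river mud concentration (kg/m3)
#' @param c_mud,c_sand initial suspended concentrations (kg/m3)
#' @param m_mud,m_sand initial suspended mass per cell (kg); when supplied
#'   they take precedence over the concentrations, which lets chained bursts
#'   hand the mass state over exactly
#' @param p_surf surface mud fraction per cell
#' @param stack_mud column-integrated parent-bed mud inventory (kg/m2),
#'   capping mud erosion (see [stack_mud_mass()])
#' @param floor_z non-erodible floor elevation
#' @param erodible logical matrix
#' @param transport,morpho switch suspended transport / bed updating on or off
#' @param morfac morphological acceleration factor for this call
#' @param diag_start step index (0-based) from which diagnostics accumulate
#' @param inlet_faces 1-based flattened indices of cells whose right x-face
#'   crosses the inlet section (for the discharge series)
#' @param ref_cells 1-based flattened indices of always-connected (subtidal)
#'   cells whose mean water level defines the tidal frame used for
#'   hydroperiod (returned as the `ref_eta` series)
#' @param c_return0 initial returned-plume mud concentration (kg/m3) carried
#'   over from the previous burst (see `sediment$boundary_return`)
#' @param cfg an [mm_config()] supplying the physical constants
#' @return list of final fields (`eta`, `u`, `v`, `z`, `c_mud`, `c_sand`, all
#'   matrices), per-burst deposits and parent-bed erosion (`new_mud`,
#'   `new_sand`, `parent_mud`, `parent_sand`, all kg/m2),
#'   cycle diagnostics (`hydroperiod`, `tau_max`,
#'   `tau_mean`, `inlet_q`), the mass `ledger`, and `t_end`
#' @export
step_flow <- function(z, ctype, dx, dt, nsteps,
                      eta = 0, u = 0, v = 0, cr = NULL, lambda = 0,
                      eta_offset = 0, amp = 0, omega = 0, phase = 0, t0 = 0,
                      river_cells = integer(0), river_q = numeric(0),
                      c_river_mud = 0, c_mud = 0, c_sand = 0,
                      m_mud = NULL, m_sand = NULL, p_surf = 0,
                      stack_mud = NULL,
                      floor_z = NULL, erodible = NULL,
                      transport = FALSE, morpho = FALSE, morfac = 1,
                      diag_start = 0, inlet_faces = integer(0),
                      ref_cells = integer(0), c_return0 = 0,
                      cfg = mm_config()) {
  nx <- nrow(z); ny <- ncol(z)
  full <- function(x) {
    m <- matrix(0, nx, ny); m[] <- x; m
  }
  if (is.null(cr)) cr <- cfg$hydro$chezy_bed
  if (is.null(floor_z)) floor_z <- z - 1000
  if (is.null(erodible)) erodible <- matrix(TRUE, nx, ny)
  eta <- pmax(full(eta), z) # a level below the bed means a dry cell
  par <- c(cfg$hydro[c("dt", "dry_depth", "g", "rho_water", "u_max")],
           cfg$sediment[c("diffusivity", "erosion_rate", "tau_ce", "tau_cd",
                          "ws_mud", "ws_sand", "u_crit_sand", "eh_coef",
                          "d50_sand", "bedload_frac", "alpha_bn",
                          "rho_dry_mud", "rho_dry_sand", "max_dz_step",
                          "sea_mud_conc", "boundary_return", "dep_ceiling",
                          "dep_taper", "morpho_min_z")])
  par$dt <- dt
  par$nsteps <- as.integer(nsteps)
  par$morfac <- morfac
  par$morpho_on <- isTRUE(morpho)
  par$transport_on <- isTRUE(transport)
  par$diag_start <- as.integer(diag_start)
  par$mass_input <- !is.null(m_mud)
  par$c_return0 <- c_return0
  if (par$mass_input) {
    if (is.null(m_sand)) m_sand <- 0
    c_mud <- m_mud
    c_sand <- m_sand
  }

  out <- .mm_burst_cpp(nx, ny, dx,
                       as.numeric(z), as.numeric(full(floor_z)),
                       as.integer(ctype), as.logical(full(erodible) > 0),
                       as.numeric(full(cr)), as.numeric(full(lambda)),
                       as.numeric(eta), as.numeric(full(u)),
                       as.numeric(full(v)), as.numeric(full(c_mud)),
                       as.numeric(full(c_sand)), as.numeric(full(p_surf)),
                       as.numeric(full(stack_mud %||% (full(p_surf) * 1e9))),
                       as.numeric(full(eta_offset)), amp, omega, phase, t0,
                       as.integer(river_cells) - 1L, as.numeric(river_q),
                       c_river_mud, as.integer(inlet_faces) - 1L,
                       as.integer(ref_cells) - 1L, par)
  for (f in c("eta", "u", "v", "z", "c_mud", "c_sand", "m_mud", "m_sand",
              "new_mud", "new_sand",
              "parent_mud", "parent_sand", "hydroperiod", "tau_max",
              "tau_mean")) {
    out[[f]] <- matrix(out[[f]], nx, ny)
  }
  out$wet <- out$eta - out$z > cfg$hydro$dry_depth
  out
}
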