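#' Partheniades-Krone mud exchange fluxes
#'
#' Threshold-based erosion and deposition of cohesive sediment:
#' erosion \eqn{E = M \max(\tau/\tau_{ce} - 1, 0)} scaled by the mud
#' availability of the surface layer, and deposition
#' \eqn{D = w_s c \max(1 - \tau/\tau_{cd}, 0)}. With the default (very large)
#' \eqn{\tau_{cd}} deposition is never shut off.
#'
#' @param tau bed shear stress (N/m2), vectorized
#' @param c_mud suspended mud concentration (kg/m3)
#' @param mud_avail surface-layer mud fraction in `[0, 1]` scaling erosion
#' @param cfg an [mm_config()] supplying `erosion_rate` (M), `tau_ce`,
#'   `tau_cd` and `ws_mud`
#' @return list with `erosion` and `deposition` fluxes (kg/m2/s)
#' @export
mud_exchange <- function(tau, c_mud, mud_avail = 1, cfg = mm_config()) {
  sed <- cfg$sediment
  stopifnot(all(tau >= 0), all(c_mud >= 0))
  list(
    erosion = sed$erosion_rate * pmax(tau / sed$tau_ce - 1, 0) * mud_avail,
    deposition = sed$ws_mud * c_mud * pmax(1 - tau / sed$tau_cd, 0)
  )
}

#' Capacity-based sand transport
#'
#' Reduced-complexity total-load capacity (Engelund-Hansen type,
#' \eqn{q_t \propto |u|^5 / C_r^3}) with a critical-mobility cutoff, split
#' into a bedload share carried with the flow and a suspended share expressed
#' as an equilibrium concentration toward which suspended sand relaxes at the
#' sand settling velocity.
#'
#' @param u,v depth-averaged velocity components (m/s)
#' @param h water depth (m)
#' @param cr representative Chezy coefficient
#' @param cfg an [mm_config()]
#' @return list with `q_total` (m2/s of deposited-bed volume), `qb_x`, `qb_y`
#'   (bedload vector), and `c_eq` (kg/m3 suspended equilibrium concentration)
#' @export
sand_transport <- function(u, v = 0, h = 1, cr = 65, cfg = mm_config()) {
  sed <- cfg$sediment
  g <- cfg$hydro$g
  um <- sqrt(u^2 + v^2)
  mob <- pmax(1 - (sed$u_crit_sand / pmax(um, 1e-12))^2, 0)
  qt <- sed$eh_coef * um^5 / (1.65^2 * sqrt(g) * sed$d50_sand * cr^3) * mob
  qb <- sed$bedload_frac * qt
  safe_um <- pmax(um, 1e-12)
  list(
    q_total = qt,
    qb_x = qb * u / safe_um,
    qb_y = qb * v / safe_um,
    c_eq = ifelse(um > 1e-6 & h > 0,
                  (1 - sed$bedload_frac) * qt * sed$rho_dry_sand /
                    (safe_um * pmax(h, 1e-6)),
                  0)
  )
}

#' Transverse bed-slope correction of bedload
#'
#' Adds a down-slope component proportional to the local bed gradient and the
#' bedload magnitude (Koch-Flokstra type), which damps upslope transport and
#' feeds the lateral spreading that keeps channel banks realistic.
#'
#' @param qb_x,qb_y bedload flux components (m2/s)
#' @param dzdx,dzdy bed slope components (m/m)
#' @param cfg an [mm_config()] supplying `alpha_bn`
#' @return list with corrected `qb_x`, `qb_y`
#' @export
slope_correction <- function(qb_x, qb_y, dzdx, dzdy, cfg = mm_config()) {
  a <- cfg$sediment$alpha_bn
  qmag <- sqrt(qb_x^2 + qb_y^2)
  list(qb_x = qb_x - a * qmag * dzdx,
       qb_y = qb_y - a * qmag * dzdy)
}

#' Explicit advection-diffusion of a depth-averaged tracer
#'
#' Conservative first-order upwind transport on the model grid, the same
#' scheme the compiled burst kernel applies to suspended mud and sand. Exposed
#' for analyses and as an independently testable building block; closed
#' domains conserve tracer mass to round-off.
#'
#' @param conc tracer concentration matrix (kg/m3)
#' @param h water depth matrix (m)
#' @param u,v face velocities (m/s; `u[i,j]` sits between cells `i` and `i+1`)
#' @param dx cell size (m)
#' @param dt time step (s); must satisfy the advective CFL bound
#' @param kdiff horizontal diffusivity (m2/s)
#' @param active logical matrix of transporting cells
#' @param sources matrix of mass source rates (kg/s per cell)
#' @return updated concentration matrix
#' @export
advect_diffuse <- function(conc, h, u, v, dx, dt, kdiff = 0, active = NULL,
                           sources = NULL) {
  nx <- nrow(conc); ny <- ncol(conc)
  if (is.null(active)) active <- matrix(TRUE, nx, ny)
  cfl <- max(abs(u), abs(v)) * dt / dx
  if (cfl > 1 + 1e-9) abort(sprintf("advective CFL %.2f exceeds 1", cfl))
  area <- dx^2
  hpos <- pmax(h, 0)
  mass <- conc * hpos * area
  dm <- matrix(0, nx, ny)
  # x faces
  for (i in seq_len(nx - 1)) {
    hf <- pmin(hpos[i, ], hpos[i + 1, ])
    open <- active[i, ] & active[i + 1, ] & hf > 0
    q <- hf * u[i, ] * dx
    cup <- ifelse(q >= 0, conc[i, ], conc[i + 1, ])
    f <- (q * cup + kdiff * hf * (conc[i, ] - conc[i + 1, ])) * dt
    f[!open] <- 0
    dm[i, ] <- dm[i, ] - f
    dm[i + 1, ] <- dm[i + 1, ] + f
  }
  # y faces
  for (j in seq_len(ny - 1)) {
    hf <- pmin(hpos[, j], hpos[, j + 1])
    open <- active[, j] & active[, j + 1] & hf > 0
    q <- hf * v[, j] * dx
    cup <- ifelse(q >= 0, conc[, j], conc[, j + 1])
    f <- (q * cup + kdiff * hf * (conc[, j] - conc[, j + 1])) * dt
    f[!open] <- 0
    dm[, j] <- dm[, j] - f
    dm[, j + 1] <- dm[, j + 1] + f
  }
  if (!is.null(sources)) dm <- dm + sources * dt
  out <- (mass + dm) / pmax(hpos * area, 1e-9)
  out[!active] <- conc[!active]
  out
}
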