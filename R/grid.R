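#' River width from discharge (hydraulic geometry)
#'
#' Empirical hydraulic-geometry relation between bankfull river width and mean
#' discharge, W = 7.2 * Q^0.5, used to check that the prescribed 30 m river
#' width is consistent with the 18 m3/s discharge typical of small North
#' Island (NZ) catchments.
#'
#' @param Q discharge in m3/s (vectorized, must be >= 0)
#' @return river width in metres
#' @examples
#' river_width_from_discharge(18) # about 30.5 m
#' @export
river_width_from_discharge <- function(Q) {
  if (any(Q < 0)) abort("discharge must be non-negative")
  7.2 * sqrt(Q)
}

#' Build the idealized model grid
#'
#' Lays out the rectangular back-barrier domain on a regular grid: a 2 km
#' offshore strip (x increasing landward from the open-sea boundary), a
#' one-cell barrier column pierced by a central inlet, and the 4 km basin with
#' three river-inflow segments on its north, head (landward) and south edges.
#'
#' @param cfg an [mm_config()] object; `cfg$domain$resolution` sets the cell
#'   size in metres.
#' @return An `mm_grid` object: list with `nx`, `ny`, `dx`, `role` (character
#'   matrix with values `"offshore"`, `"basin"`, `"barrier"`, `"river_inflow"`,
#'   `"open_sea_boundary"`), `active` (logical matrix), index vectors for the
#'   inlet, rivers and boundary, and the per-river discharge.
#' @export
build_grid <- function(cfg = mm_config()) {
  d <- cfg$domain
  dx <- d$resolution
  nx_off <- round(d$offshore_length / dx)
  nx_bas <- round(d$basin_length / dx)
  ny <- round(d$basin_width / dx)
  n_inlet <- round(d$inlet_width / dx)
  if (n_inlet < 2) abort("inlet must span at least 2 cells; refine the grid")
  nx <- nx_off + 1 + nx_bas           # barrier occupies one column
  ib <- nx_off + 1                    # barrier column index

  role <- matrix("basin", nx, ny)
  role[seq_len(nx_off), ] <- "offshore"
  role[1, ] <- "open_sea_boundary"
  role[ib, ] <- "barrier"
  j_in <- inlet_rows(ny, n_inlet)
  role[ib, j_in] <- "offshore"        # the inlet throat

  # river inflow segments: width in cells (at least one)
  nw <- max(1L, round(cfg$rivers$width / dx))
  j_mid <- mid_span(ny, nw)
  i_mid <- ib + mid_span(nx_bas, nw)  # halfway along the basin
  rivers <- list(
    head  = cbind(i = rep(nx, nw), j = j_mid),
    north = cbind(i = i_mid, j = rep(ny, nw)),
    south = cbind(i = i_mid, j = rep(1L, nw))
  )
  for (r in rivers) role[r] <- "river_inflow"

  active <- role != "barrier"
  structure(list(
    nx = nx, ny = ny, dx = dx, area = dx^2,
    nx_offshore = nx_off, barrier_col = ib,
    role = role, active = active,
    inlet = cbind(i = rep(ib, length(j_in)), j = j_in),
    rivers = rivers,
    river_q = cfg$rivers$discharge,
    sea_col = 1L
  ), class = "mm_grid")
}

# rows of a centred span of length n within 1..ny
inlet_rows <- function(ny, n) mid_span(ny, n)
mid_span <- function(ny, n) {
  start <- floor((ny - n) / 2) + 1L
  seq.int(start, start + n - 1L)
}

#' @export
print.mm_grid <- function(x, ...) {
  cat("<mm_grid> ", x$nx, "x", x$ny, " cells at ", x$dx, " m\n", sep = "")
  cat("  basin cells:", sum(x$role %in% c("basin", "river_inflow")),
      " offshore:", sum(x$role == "offshore"),
      " barrier:", sum(x$role == "barrier"), "\n")
  invisible(x)
}

#' Logical mask of basin cells
#'
#' Basin cells (including river-inflow cells) form the denominator of all
#' areal landscape metrics.
#' @param grid an `mm_grid`
#' @return logical matrix
#' @export
basin_mask <- function(grid) {
  matrix(grid$role %in% c("basin", "river_inflow"), grid$nx, grid$ny)
}

#' Initial bathymetry and substrate
#'
#' Sets the basin platform at its initial elevation (default -1.5 m MSL), a
#' linear offshore slope from the inlet depth down to the open-boundary depth
#' (default -100 m, deep enough that no shoaling occurs seaward of the inlet),
#' raises the barrier above the tide and flags it non-erodible, and installs
#' an all-sand substrate of configured thickness above a non-erodible floor.
#'
#' @param grid an `mm_grid`
#' @param cfg the matching [mm_config()]
#' @return An `mm_bed` object: list with `elevation`, `floor` (m MSL
#'   matrices), `erodible` (logical matrix) and `strat` (see
#'   [new_stratigraphy()]).
#' @export
init_bathymetry <- function(grid, cfg = mm_config()) {
  d <- cfg$domain
  z <- matrix(d$basin_z0, grid$nx, grid$ny)
  nx_off <- grid$nx_offshore
  # linear slope: column 1 (open boundary) at zmax, column ib at basin_z0
  slope_z <- seq(d$offshore_zmax, d$basin_z0, length.out = nx_off + 1)
  for (i in seq_len(nx_off)) z[i, ] <- slope_z[i]
  z[grid$barrier_col, ] <- slope_z[nx_off + 1]   # inlet cells at basin depth
  z[grid$role == "barrier"] <- 3.0               # dry crest, inactive
  erodible <- grid$role != "barrier"
  floor_z <- z - ifelse(grid$role %in% c("offshore", "open_sea_boundary"),
                        50, d$substrate_depth)
  floor_z[!erodible] <- z[!erodible]
  structure(list(
    elevation = z, floor = floor_z, erodible = erodible,
    strat = new_stratigraphy(grid$nx * grid$ny)
  ), class = "mm_bed")
}

#' @export
print.mm_bed <- function(x, ...) {
  cat("<mm_bed> elevation range:",
      sprintf("%.2f .. %.2f m MSL", min(x$elevation), max(x$elevation)), "\n")
  invisible(x)
}
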