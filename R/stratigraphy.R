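#' Create an empty stratigraphy store
#'
#' The substrate memory of the bed: each cell carries an ordered stack of
#' layers (thickness in m, mud fraction by volume in 0..1), top layer first.
#' Below the explicit stack sits an implicit pure-sand base extending to the
#' non-erodible floor, so a freshly initialized bed is 100 % sand everywhere.
#'
#' @param ncell number of grid cells
#' @param capacity initial number of preallocated layers
#' @return an `mm_strat` object (list of `thick`, `mud` matrices `[layer, cell]`
#'   and integer vector `nlay`)
#' @export
new_stratigraphy <- function(ncell, capacity = 8L) {
  structure(list(
    thick = matrix(0, capacity, ncell),
    mud   = matrix(0, capacity, ncell),
    nlay  = integer(ncell)
  ), class = "mm_strat")
}

strat_capacity <- function(strat) nrow(strat$thick)

strat_grow <- function(strat, extra = 8L) {
  ncell <- ncol(strat$thick)
  strat$thick <- rbind(strat$thick, matrix(0, extra, ncell))
  strat$mud   <- rbind(strat$mud,   matrix(0, extra, ncell))
  strat
}

# merge the two bottom-most explicit layers of the given cells
strat_merge_bottom <- function(strat, cells) {
  for (c in cells) {
    n <- strat$nlay[c]
    if (n < 2) next
    t1 <- strat$thick[n - 1, c]; t2 <- strat$thick[n, c]
    strat$mud[n - 1, c] <- (strat$mud[n - 1, c] * t1 + strat$mud[n, c] * t2) /
      (t1 + t2)
    strat$thick[n - 1, c] <- t1 + t2
    strat$thick[n, c] <- 0; strat$mud[n, c] <- 0
    strat$nlay[c] <- n - 1L
  }
  strat
}

#' Deposit mixed sediment on top of the stack
#'
#' Thin seasonal deposits are blended into the existing top layer until it
#' reaches the nominal layer thickness; thicker deposits start a new layer.
#'
#' @param strat an `mm_strat`
#' @param cells integer cell indices
#' @param t_mud,t_sand deposited thickness (m) per cell (same length as cells)
#' @param nominal nominal layer thickness (m) controlling merge/split
#' @return updated `mm_strat`
#' @export
strat_deposit <- function(strat, cells, t_mud, t_sand, nominal = 0.1) {
  tot <- t_mud + t_sand
  keep <- tot > 1e-12
  cells <- cells[keep]; t_mud <- t_mud[keep]; tot <- tot[keep]
  if (length(cells) == 0) return(strat)
  frac <- t_mud / tot

  top <- strat$nlay[cells] > 0L
  top_thick <- rep(0, length(cells))
  if (any(top)) top_thick[top] <- strat$thick[cbind(1L, cells[top])]
  merge <- top & top_thick < nominal
  # merge into existing top layer
  if (any(merge)) {
    mc <- cells[merge]
    idx <- cbind(1L, mc)
    t0 <- strat$thick[idx]; p0 <- strat$mud[idx]
    strat$mud[idx] <- (p0 * t0 + frac[merge] * tot[merge]) / (t0 + tot[merge])
    strat$thick[idx] <- t0 + tot[merge]
  }
  # push a new top layer
  push <- !merge
  if (any(push)) {
    pc <- cells[push]
    need_grow <- strat$nlay[pc] >= strat_capacity(strat)
    if (any(need_grow)) {
      full <- pc[need_grow][strat$nlay[pc[need_grow]] >= 100L]
      if (length(full)) strat <- strat_merge_bottom(strat, full)
      if (any(strat$nlay[pc] >= strat_capacity(strat))) {
        strat <- strat_grow(strat)
      }
    }
    L <- strat_capacity(strat)
    strat$thick[2:L, pc] <- strat$thick[seq_len(L - 1), pc, drop = FALSE]
    strat$mud[2:L, pc]   <- strat$mud[seq_len(L - 1), pc, drop = FALSE]
    strat$thick[cbind(1L, pc)] <- tot[push]
    strat$mud[cbind(1L, pc)]   <- frac[push]
    strat$nlay[pc] <- strat$nlay[pc] + 1L
  }
  strat
}

#' Erode a given thickness from the top of the stack
#'
#' Consumes explicit layers top-down; erosion deeper than the explicit stack
#' simply exposes the implicit sand base (the caller enforces the non-erodible
#' floor on elevations).
#'
#' @param strat an `mm_strat`
#' @param cells integer cell indices
#' @param depth thickness to remove (m) per cell
#' @return updated `mm_strat`
#' @export
strat_erode <- function(strat, cells, depth) {
  keep <- depth > 1e-12
  cells <- cells[keep]; rem <- depth[keep]
  while (length(cells) > 0) {
    has <- strat$nlay[cells] > 0L
    if (!any(has)) break
    cells <- cells[has]; rem <- rem[has]
    idx <- cbind(1L, cells)
    t0 <- strat$thick[idx]
    take <- pmin(t0, rem)
    strat$thick[idx] <- t0 - take
    rem <- rem - take
    emptied <- strat$thick[idx] <= 1e-12
    if (any(emptied)) {
      ec <- cells[emptied]
      L <- strat_capacity(strat)
      strat$thick[seq_len(L - 1), ec] <- strat$thick[2:L, ec, drop = FALSE]
      strat$mud[seq_len(L - 1), ec]   <- strat$mud[2:L, ec, drop = FALSE]
      strat$thick[L, ec] <- 0; strat$mud[L, ec] <- 0
      strat$nlay[ec] <- strat$nlay[ec] - 1L
    }
    still <- rem > 1e-12
    cells <- cells[still]; rem <- rem[still]
  }
  strat
}

#' Remove specific mud and sand volumes from the top of the stack
#'
#' Constituent-aware erosion: removes the requested mud volume and sand
#' volume (m of thickness each) working down from the surface, shrinking
#' layers and updating their mud fractions, so the stack inventory stays in
#' exact agreement with the mass ledger of the flow solver. Sand demand
#' beyond the explicit stack falls through to the implicit sand base; mud
#' demand is capped at what the stack holds (the solver caps erosion by the
#' same inventory).
#'
#' @param strat an `mm_strat`
#' @param cells integer cell indices
#' @param vol_mud,vol_sand thickness of mud / sand to remove (m) per cell
#' @return updated `mm_strat`
#' @export
strat_remove <- function(strat, cells, vol_mud, vol_sand) {
  keep <- vol_mud + vol_sand > 1e-12
  cells <- cells[keep]; vm <- vol_mud[keep]; vs <- vol_sand[keep]
  while (length(cells) > 0) {
    has <- strat$nlay[cells] > 0L
    if (!any(has)) break
    cells <- cells[has]; vm <- vm[has]; vs <- vs[has]
    idx <- cbind(1L, cells)
    t0 <- strat$thick[idx]; p0 <- strat$mud[idx]
    lay_mud <- t0 * p0
    lay_sand <- t0 - lay_mud
    take_m <- pmin(lay_mud, vm)
    take_s <- pmin(lay_sand, vs)
    t1 <- t0 - take_m - take_s
    strat$thick[idx] <- t1
    strat$mud[idx] <- ifelse(t1 > 1e-12, (lay_mud - take_m) / t1, 0)
    vm <- vm - take_m; vs <- vs - take_s
    emptied <- t1 <= 1e-12
    if (any(emptied)) {
      ec <- cells[emptied]
      L <- strat_capacity(strat)
      strat$thick[seq_len(L - 1), ec] <- strat$thick[2:L, ec, drop = FALSE]
      strat$mud[seq_len(L - 1), ec]   <- strat$mud[2:L, ec, drop = FALSE]
      strat$thick[L, ec] <- 0; strat$mud[L, ec] <- 0
      strat$nlay[ec] <- strat$nlay[ec] - 1L
    }
    # cells done when both demands are met (sand falls through to the base);
    # park cells whose top layer cannot supply the demanded constituent
    progress <- emptied | (take_m + take_s > 1e-13)
    still <- (vm > 1e-12 | vs > 1e-12) & progress
    parked <- (vm > 1e-12) & !progress
    if (any(parked)) {
      strat <- strat_extract_mud(strat, cells[parked], vm[parked])
    }
    cells <- cells[still]; vm <- vm[still]; vs <- vs[still]
  }
  strat
}

# extract a mud volume from wherever it sits in the stack (winnowing through
# a sandy surface); zero-thickness interior layers are left in place
strat_extract_mud <- function(strat, cells, vol_mud) {
  Lmax <- max(strat$nlay[cells], 0L)
  for (l in seq_len(Lmax)) {
    if (length(cells) == 0) break
    idx <- cbind(l, cells)
    t0 <- strat$thick[idx]; p0 <- strat$mud[idx]
    lay_mud <- t0 * p0
    take <- pmin(lay_mud, vol_mud)
    t1 <- t0 - take
    strat$thick[idx] <- t1
    strat$mud[idx] <- ifelse(t1 > 1e-12, (lay_mud - take) / t1, 0)
    vol_mud <- vol_mud - take
    still <- vol_mud > 1e-12 & strat$nlay[cells] > l
    cells <- cells[still]; vol_mud <- vol_mud[still]
  }
  strat
}

#' Column-integrated mud inventory
#'
#' Total mud mass per unit area held in the explicit layer stack (kg/m2),
#' the cap on how much mud erosion can extract from the parent bed.
#' @param bed an `mm_bed` or `mm_strat`
#' @param rho_dry_mud dry bulk density of mud (kg/m3)
#' @return numeric vector per cell
#' @export
stack_mud_mass <- function(bed, rho_dry_mud = 500) {
  strat <- if (inherits(bed, "mm_strat")) bed else bed$strat
  colSums(strat$thick * strat$mud) * rho_dry_mud
}

#' Mud fraction of the uppermost metre of substrate
#'
#' Thickness-weighted mean mud fraction over the top 1 m, the quantity whose
#' 30 % exceedance defines the "muddy region" of the basin. Substrate below
#' the explicit layer stack counts as pure sand.
#'
#' @param bed an `mm_bed` (or an `mm_strat` directly)
#' @param depth averaging depth in m (default 1)
#' @return numeric vector, one fraction in `[0, 1]` per cell
#' @export
mud_fraction_top1m <- function(bed, depth = 1) {
  strat <- if (inherits(bed, "mm_strat")) bed else bed$strat
  ncell <- ncol(strat$thick)
  remaining <- rep(depth, ncell)
  mud_sum <- numeric(ncell)
  Lmax <- max(strat$nlay, 0L)
  for (l in seq_len(Lmax)) {
    w <- pmin(strat$thick[l, ], remaining)
    mud_sum <- mud_sum + w * strat$mud[l, ]
    remaining <- remaining - w
  }
  mud_sum / depth
}

#' Surface mud fraction
#'
#' Mud fraction of the current top layer (0 for a bare sand bed), used to
#' partition erosion fluxes between sand and mud.
#' @param bed an `mm_bed` or `mm_strat`
#' @return numeric vector per cell
#' @export
surface_mud_fraction <- function(bed) {
  strat <- if (inherits(bed, "mm_strat")) bed else bed$strat
  p <- strat$mud[1, ]
  p[strat$nlay == 0L] <- 0
  p
}

#' Apply net erosion/deposition fluxes to the bed
#'
#' Exner-style bed update with morphological acceleration: fluxes (kg/m2/s,
#' positive for deposition) are multiplied by `morfac`, converted to thickness
#' through the dry bulk densities, and recorded in the stratigraphy. Erosion
#' is partitioned by the surface-layer composition and floored at the
#' non-erodible substrate base.
#'
#' @param bed an `mm_bed`
#' @param mud_flux,sand_flux net mass flux per cell (kg/m2/s; vectors or
#'   matrices matching the elevation grid)
#' @param morfac morphological acceleration factor
#' @param dt time step (s)
#' @param cfg an [mm_config()] for the dry densities and layer thickness
#' @return updated `mm_bed`
#' @export
update_bed <- function(bed, mud_flux, sand_flux, morfac, dt, cfg = mm_config()) {
  sed <- cfg$sediment
  dmud <- as.vector(mud_flux) * morfac * dt / sed$rho_dry_mud
  dsand <- as.vector(sand_flux) * morfac * dt / sed$rho_dry_sand
  dmud[!bed$erodible & dmud < 0] <- 0
  dsand[!bed$erodible & dsand < 0] <- 0
  ero <- pmax(-(pmin(dmud, 0) + pmin(dsand, 0)), 0)
  # floor the erosion at the non-erodible base
  headroom <- as.vector(bed$elevation - bed$floor)
  scale <- ifelse(ero > headroom & ero > 0, headroom / ero, 1)
  dmud <- ifelse(dmud < 0, dmud * scale, dmud)
  dsand <- ifelse(dsand < 0, dsand * scale, dsand)
  ero <- pmax(-(pmin(dmud, 0) + pmin(dsand, 0)), 0)
  dep_mud <- pmax(dmud, 0); dep_sand <- pmax(dsand, 0)

  cells <- which(ero > 0 | dep_mud + dep_sand > 0)
  bed$strat <- strat_erode(bed$strat, cells, ero[cells])
  bed$strat <- strat_deposit(bed$strat, cells, dep_mud[cells], dep_sand[cells],
                             nominal = sed$layer_thickness)
  bed$elevation <- bed$elevation +
    matrix(dmud + dsand, nrow(bed$elevation), ncol(bed$elevation))
  bed$elevation <- pmax(bed$elevation, bed$floor)
  bed
}
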