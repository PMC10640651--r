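#' Accommodation space
#'
#' Total basin volume below the high-tide level that could still be filled
#' with sediment: \eqn{\sum \max(HW - z, 0) \times A_{cell}} over basin
#' cells. The headline indicator of estuarine infilling: it shrinks as the
#' basin fills.
#'
#' @param bed an `mm_bed` (or elevation matrix)
#' @param grid an `mm_grid`
#' @param hw high-tide level (m MSL); defaults to the tidal amplitude
#' @param cfg an [mm_config()]
#' @return volume (m3)
#' @export
accommodation_space <- function(bed, grid, hw = cfg$metrics$hw_level,
                                cfg = mm_config()) {
  z <- if (inherits(bed, "mm_bed")) bed$elevation else bed
  b <- basin_mask(grid)
  sum(pmax(hw - z[b], 0)) * grid$area
}

#' Muddy-region fraction
#'
#' Fraction of the basin area whose top-1 m substrate mud content exceeds the
#' 30 % threshold (strict inequality).
#'
#' @param bed an `mm_bed` with stratigraphy
#' @param grid an `mm_grid`
#' @param threshold mud-fraction threshold
#' @param cfg an [mm_config()]
#' @return fraction in `[0, 1]`
#' @export
muddy_region_fraction <- function(bed, grid,
                                  threshold = cfg$metrics$muddy_threshold,
                                  cfg = mm_config()) {
  frac <- mud_fraction_top1m(bed)
  b <- as.vector(basin_mask(grid))
  mean(frac[b] > threshold)
}

#' Mangrove coverage
#'
#' Fraction of basin cells carrying at least one living cohort.
#' @param veg an `mm_veg`
#' @param grid an `mm_grid`
#' @return fraction in `[0, 1]`
#' @export
mangrove_coverage <- function(veg, grid) {
  b <- as.vector(basin_mask(grid))
  vegetated <- rep(FALSE, grid$nx * grid$ny)
  vegetated[veg$cohorts$cell] <- TRUE
  sum(vegetated & b) / sum(b)
}

#' Relative basin area above mean sea level
#'
#' A_MSL/A_tot: the share of the high-tide-wetted basin surface lying above
#' mean sea level — the potential mangrove habitat fraction and the vertical
#' axis of the estuarine landscape-trajectory diagram.
#'
#' @param bed an `mm_bed` or elevation matrix
#' @param grid an `mm_grid`
#' @param hw high-tide level (m MSL)
#' @param cfg an [mm_config()]
#' @return ratio in `[0, 1]`
#' @export
relative_area_amsl <- function(bed, grid, hw = cfg$metrics$hw_level,
                               cfg = mm_config()) {
  z <- if (inherits(bed, "mm_bed")) bed$elevation else bed
  zb <- z[basin_mask(grid)]
  wetted <- zb < hw
  if (!any(wetted)) return(1)
  sum(zb > 0 & wetted) / sum(wetted)
}

#' Channel classification of the basin
#'
#' Identifies channelized cells from residual relief (elevation more than a
#' threshold below the local moving-window median) or subtidal position
#' (below mean low water while the surrounding platform is intertidal), then
#' bins the unchannelized cells by Euclidean distance to the nearest channel
#' into the near (<100 m) and far (300-400 m) classes used for
#' sedimentation-pattern diagnostics.
#'
#' @param bed an `mm_bed` or elevation matrix
#' @param grid an `mm_grid`
#' @param cfg an [mm_config()]; `metrics$relief_threshold` (m),
#'   `metrics$relief_window` (cells), `metrics$mlw_level` control the mask
#' @return tibble with one row per basin cell: `cell`, `i`, `j`,
#'   `channel` (logical), `distance_m`, `class`
#'   (`"channel"`, `"near"`, `"far"`, `"other"`)
#' @export
classify_channels <- function(bed, grid, cfg = mm_config()) {
  z <- if (inherits(bed, "mm_bed")) bed$elevation else bed
  mt <- cfg$metrics
  b <- basin_mask(grid)
  med <- moving_median(z, mt$relief_window, mask = b)
  chan <- b & (z < med - mt$relief_threshold |
                 (z < mt$mlw_level & med > mt$mlw_level))
  cells <- which(b)
  ii <- (cells - 1L) %% grid$nx + 1L
  jj <- (cells - 1L) %/% grid$nx + 1L
  ch_cells <- which(chan)
  if (length(ch_cells) == 0) {
    warn("no channels identified; all cells unclassified")
    dist <- rep(NA_real_, length(cells))
  } else {
    ci <- (ch_cells - 1L) %% grid$nx + 1L
    cj <- (ch_cells - 1L) %/% grid$nx + 1L
    # exact Euclidean distance to the nearest channel cell
    dist <- vapply(seq_along(cells), function(k) {
      sqrt(min((ii[k] - ci)^2 + (jj[k] - cj)^2))
    }, numeric(1)) * grid$dx
  }
  is_ch <- chan[cells]
  dist[is_ch] <- 0
  cls <- rep("other", length(cells))
  cls[is_ch] <- "channel"
  cls[!is_ch & dist < mt$near_channel_max] <- "near"
  cls[!is_ch & dist >= mt$far_channel_range[1] &
        dist <= mt$far_channel_range[2]] <- "far"
  tibble(cell = cells, i = ii, j = jj, channel = is_ch,
         distance_m = dist, class = cls)
}

# moving-window median filter restricted to masked cells
moving_median <- function(z, window, mask) {
  nx <- nrow(z); ny <- ncol(z)
  hw <- window %/% 2
  out <- z
  for (j in seq_len(ny)) {
    j0 <- max(1, j - hw); j1 <- min(ny, j + hw)
    for (i in seq_len(nx)) {
      if (!mask[i, j]) next
      i0 <- max(1, i - hw); i1 <- min(nx, i + hw)
      blk <- z[i0:i1, j0:j1][mask[i0:i1, j0:j1]]
      out[i, j] <- median(blk)
    }
  }
  out
}

#' Sedimentation rate between two bed snapshots
#'
#' Elevation change per year in mm/yr per cell, summarized per channel
#' class when a classification is supplied.
#'
#' @param bed_old,bed_new `mm_bed` objects or elevation matrices
#' @param years time between the snapshots (yr), > 0
#' @param classification optional tibble from [classify_channels()]
#' @return if `classification` is `NULL`, a matrix of rates (mm/yr);
#'   otherwise a tibble with per-cell rates joined to the classes plus a
#'   `summary` attribute of per-class means
#' @export
sedimentation_rate <- function(bed_old, bed_new, years,
                               classification = NULL) {
  if (years <= 0) abort("snapshots must be at least a year apart")
  z0 <- if (inherits(bed_old, "mm_bed")) bed_old$elevation else bed_old
  z1 <- if (inherits(bed_new, "mm_bed")) bed_new$elevation else bed_new
  rate <- (z1 - z0) * 1000 / years
  if (is.null(classification)) return(rate)
  out <- classification
  out$rate_mm_yr <- rate[out$cell]
  summ <- out %>%
    group_by(.data$class) %>%
    summarise(mean_rate = mean(.data$rate_mm_yr),
              median_rate = median(.data$rate_mm_yr),
              n = dplyr::n(), .groups = "drop")
  attr(out, "summary") <- summ
  out
}

#' Annual sediment yield and tidal prism
#'
#' SY is the total mud load delivered by the three rivers over a year
#' (kg/yr, and as deposited-bed volume via the dry bulk density); TP is the
#' tidal prism from the inlet discharge series. Their ratio (volume/volume)
#' is the non-dimensional catchment sediment yield driving estuarine
#' infilling trajectories.
#'
#' @param mud_conc river mud concentration (kg/m3)
#' @param inlet_q inlet discharge series over one tidal cycle (m3/s)
#' @param dt sampling interval of `inlet_q` (s)
#' @param cfg an [mm_config()]
#' @return tibble with `SY_kg`, `SY_m3`, `TP_m3`, `SY_TP`
#' @export
sediment_yield_and_prism <- function(mud_conc, inlet_q, dt,
                                     cfg = mm_config()) {
  rv <- cfg$rivers
  secs_yr <- 365.25 * 86400
  sy_kg <- rv$n * rv$discharge * mud_conc * secs_yr
  sy_m3 <- sy_kg / cfg$sediment$rho_dry_mud
  tp <- tidal_prism(inlet_q, dt)
  tibble(SY_kg = sy_kg, SY_m3 = sy_m3, TP_m3 = tp,
         SY_TP = ifelse(tp > 0, sy_m3 / tp, NA_real_))
}
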