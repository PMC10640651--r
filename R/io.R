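#' Write a gridded snapshot to a self-describing JSON container
#'
#' Serializes the gridded fields of a stored snapshot (elevation, top-1 m
#' mud fraction, vegetation cover, hydro diagnostics) together with
#' coordinates, units, the scenario name and the configuration hash, so a
#' file is interpretable and verifiable on its own. Reruns of a seeded run
#' produce byte-identical files.
#'
#' @param run an `mm_run`
#' @param year one of the stored snapshot epochs
#' @param path output file path (`.json`)
#' @return `path`, invisibly
#' @export
write_snapshot <- function(run, year, path) {
  sn <- run$snapshots[[as.character(year)]]
  if (is.null(sn)) {
    abort(paste0("year ", year, " is not a stored snapshot epoch"))
  }
  grid <- run$state$grid
  payload <- list(
    schema = "mangromorph-snapshot-1",
    scenario = sn$scenario,
    year = sn$year,
    config_hash = run$state$config_hash,
    grid = list(nx = grid$nx, ny = grid$ny, dx = grid$dx,
                x_orientation = "seaward to landward, cell-centred",
                origin = "offshore open boundary"),
    units = list(elevation = "m MSL", mud_top1m = "fraction",
                 vegetated = "0/1", mean_diameter_cm = "cm",
                 hydroperiod = "fraction of tidal cycle",
                 tau_max = "N/m2"),
    fields = list(
      elevation = round(unname(sn$elevation), 6),
      mud_top1m = round(unname(sn$mud_top1m), 6),
      vegetated = unname(sn$vegetated * 1L),
      mean_diameter_cm = round(unname(sn$mean_diameter_cm), 4),
      hydroperiod = round(unname(sn$hydroperiod), 6),
      tau_max = round(unname(sn$tau_max), 6)
    )
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' Read a snapshot JSON container
#'
#' @param path file written by [write_snapshot()]
#' @param expect_hash optional configuration hash; a mismatch aborts (guards
#'   resuming analyses against a different parameter set)
#' @return list with the snapshot fields as matrices plus metadata
#' @export
read_snapshot <- function(path, expect_hash = NULL) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "mangromorph-snapshot-1")) {
    abort("not a mangromorph snapshot file")
  }
  if (!is.null(expect_hash) && !identical(x$config_hash, expect_hash)) {
    abort("snapshot was produced under a different configuration")
  }
  x$fields <- lapply(x$fields, function(f) {
    if (is.list(f)) f <- do.call(cbind, f)
    as.matrix(f)
  })
  x
}

#' Export run metrics as a tidy CSV table
#'
#' Long format: one row per (scenario, year, metric). Re-exporting the same
#' run overwrites the file with identical content.
#'
#' @param runs an `mm_run` or list of runs
#' @param path output `.csv` path
#' @return `path`, invisibly
#' @export
export_metrics <- function(runs, path) {
  if (inherits(runs, "mm_run")) runs <- list(runs)
  df <- bind_rows(lapply(runs, function(r) tidy(r, long = TRUE)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a reference-estuary table
#'
#' Reader for a small table of real-estuary infilling descriptors (one row
#' per system: name, annual sediment yield, tidal prism, relative basin area
#' above MSL) used to overlay observed systems on the landscape-trajectory
#' diagram. A synthetic example with plausible magnitudes ships in
#' `inst/extdata/synthetic_estuary_infilling.csv`; it is illustrative, not
#' observational data.
#'
#' @param path CSV with columns `estuary`, `SY_m3_yr`, `TP_m3`, `amsl`
#' @return tibble with an added `SY_TP` column
#' @export
read_estuary_table <- function(path = system.file(
    "extdata", "synthetic_estuary_infilling.csv", package = "mangromorph")) {
  df <- as_tibble(read.csv(path))
  need <- c("estuary", "SY_m3_yr", "TP_m3", "amsl")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("estuary table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  df$SY_TP <- df$SY_m3_yr / df$TP_m3
  df
}
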