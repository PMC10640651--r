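#' Tidy a scenario run
#'
#' Broom-style accessor: the annual landscape metrics of a run as a long or
#' wide tibble.
#'
#' @param x an `mm_run`
#' @param long return long format (year, scenario, metric, value)?
#' @param ... unused
#' @return a tibble
#' @method tidy mm_run
#' @export
tidy.mm_run <- function(x, long = FALSE, ...) {
  m <- x$metrics
  if (!long) return(m)
  tidyr::pivot_longer(
    m, cols = -c("scenario", "year"),
    names_to = "metric", values_to = "value")
}

#' One-row summary of a scenario run
#'
#' End-state values of the headline landscape metrics plus the worst
#' mass-closure residuals observed over the whole run.
#'
#' @param x an `mm_run`
#' @param ... unused
#' @return a one-row tibble
#' @method glance mm_run
#' @export
glance.mm_run <- function(x, ...) {
  m <- tail(x$metrics, 1)
  tibble(
    scenario = x$plan$name,
    years = nrow(x$metrics),
    accommodation_m3 = m$accommodation_m3,
    muddy_fraction = m$muddy_fraction,
    coverage = m$coverage,
    amsl = m$amsl,
    SY_TP = m$SY_TP,
    max_susp_resid = m$susp_resid,
    max_bed_resid = m$bed_resid,
    runtime_s = x$runtime_s
  )
}

#' Plot the landscape-metric trajectories of one or more runs
#'
#' Time series of accommodation space, muddy-region fraction, mangrove
#' coverage and relative basin area above MSL, faceted per metric — the
#' standard way to compare management scenarios.
#'
#' @param object an `mm_run`
#' @param ... further `mm_run` objects to overlay
#' @return a ggplot object
#' @method autoplot mm_run
#' @export
autoplot.mm_run <- function(object, ...) {
  runs <- c(list(object), Filter(function(x) inherits(x, "mm_run"),
                                 list(...)))
  df <- bind_rows(lapply(runs, function(r) tidy(r, long = TRUE)))
  keep <- c("accommodation_m3", "muddy_fraction", "coverage", "amsl")
  df <- df[df$metric %in% keep, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$value,
                                   colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "year", y = NULL, colour = "scenario") +
    ggplot2::theme_minimal()
}

#' Map a snapshot field
#'
#' Raster map of a snapshot field (bed elevation, top-1 m mud fraction,
#' vegetation cover ...) in basin coordinates.
#'
#' @param run an `mm_run`
#' @param year snapshot year (must be one of the stored epochs)
#' @param field field name in the snapshot (default `"elevation"`)
#' @return a ggplot object
#' @export
plot_snapshot <- function(run, year, field = "elevation") {
  sn <- run$snapshots[[as.character(year)]]
  if (is.null(sn)) abort(paste0("no snapshot stored for year ", year))
  m <- sn[[field]]
  if (is.null(m)) abort(paste0("no field '", field, "' in snapshot"))
  dx <- run$state$grid$dx
  df <- expand.grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$x <- (df$i - 0.5) * dx
  df$y <- (df$j - 0.5) * dx
  df$value <- as.vector(m * 1) # logical -> numeric for cover maps
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0(run$plan$name, ", year ", sn$year),
                  x = "x (m, seaward to landward)", y = "y (m)",
                  fill = field) +
    ggplot2::theme_minimal()
}
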