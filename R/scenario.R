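#' Names of the built-in management scenarios
#'
#' Every scenario shares the same backbone: a 200-year vegetation-free
#' spin-up that lets the inlet and basin morphology equilibrate, a
#' pre-disturbance period (year 200-400) with low river mud concentration
#' (5 mg/L), and a disturbance period (year 400-500) at the elevated
#' concentration (15 mg/L) representing catchment deforestation. From year
#' 500 (or earlier for the early-reduction variants) the management branches
#' diverge.
#'
#' @return character vector of plan names accepted by [make_scenario()]
#' @export
scenario_catalogue <- function() {
  c("control_low", "high_forever", "mid_forever",
    "remove_25", "remove_50", "remove_100",
    "reduce_at_430", "reduce_at_450", "reduce_at_500",
    "reduce_intermediate", "no_vegetation_control")
}

#' Build a scenario plan
#'
#' Translates a catalogue name into an ordered, contiguous phase table
#' (start/end year and river mud concentration) plus an event table
#' (mangrove-removal interventions). The control run keeps the low mud
#' supply throughout; `high_forever` maintains the disturbance concentration
#' to year 600; removal plans clear 25/50/100 % of the vegetated area at
#' year 500; reduction plans drop the supply back to its pre-disturbance (or
#' intermediate) level at year 430, 450 or 500.
#'
#' @param name a name from [scenario_catalogue()]
#' @param cfg an [mm_config()]
#' @param root_persistence_years pneumatophore persistence after removal
#'   (years); the reference removal practice clears stems and roots together
#' @return an `mm_plan`: list with `name`, `horizon`, `phases` (tibble:
#'   `from`, `to`, `mud_mgL`, `vegetation`), `events` (tibble: `year`,
#'   `kind`, `fraction`, `persistence`)
#' @export
make_scenario <- function(name, cfg = mm_config(),
                          root_persistence_years = 0) {
  sc <- cfg$scenario
  rv <- cfg$rivers
  spin_end <- sc$spinup_years                       # 200
  dist_start <- spin_end + sc$predisturb_years      # 400
  manage_start <- dist_start + sc$disturb_years     # 500
  horizon <- sc$horizon                             # 600
  veg <- !identical(name, "no_vegetation_control")

  base <- tibble(from = c(0, spin_end),
                 to = c(spin_end, dist_start),
                 mud_mgL = c(0, rv$mud_low),
                 vegetation = c(FALSE, veg))
  tail_phase <- function(splits, muds) {
    tibble(from = c(dist_start, splits), to = c(splits, horizon),
           mud_mgL = muds, vegetation = veg)
  }
  phases <- switch(name,
    control_low = tibble(from = dist_start, to = horizon,
                         mud_mgL = rv$mud_low, vegetation = veg),
    mid_forever = tibble(from = dist_start, to = horizon,
                         mud_mgL = rv$mud_mid, vegetation = veg),
    high_forever = ,
    remove_25 = ,
    remove_50 = ,
    remove_100 = ,
    no_vegetation_control = tibble(from = dist_start, to = horizon,
                                   mud_mgL = rv$mud_high, vegetation = veg),
    reduce_at_430 = tail_phase(430, c(rv$mud_high, rv$mud_low)),
    reduce_at_450 = tail_phase(450, c(rv$mud_high, rv$mud_low)),
    reduce_at_500 = tail_phase(manage_start, c(rv$mud_high, rv$mud_low)),
    reduce_intermediate = tail_phase(manage_start,
                                     c(rv$mud_high, rv$mud_mid)),
    abort(paste0("unknown scenario: ", name))
  )
  phases <- bind_rows(base, phases)

  events <- tibble(year = numeric(), kind = character(),
                   fraction = numeric(), persistence = numeric())
  frac <- c(remove_25 = 0.25, remove_50 = 0.5, remove_100 = 1)[name]
  if (!is.na(frac)) {
    events <- tibble(year = manage_start, kind = "remove_vegetation",
                     fraction = unname(frac),
                     persistence = root_persistence_years)
  }
  stopifnot(all(phases$from[-1] == phases$to[-nrow(phases)]),
            phases$to[nrow(phases)] == horizon)
  structure(list(name = name, horizon = horizon, phases = phases,
                 events = events), class = "mm_plan")
}

#' @export
print.mm_plan <- function(x, ...) {
  cat("<mm_plan> ", x$name, " (", x$horizon, " yr)\n", sep = "")
  print(x$phases)
  if (nrow(x$events) > 0) print(x$events)
  invisible(x)
}

#' River mud concentration in force at a given year
#' @param plan an `mm_plan`
#' @param year simulation year
#' @return concentration in kg/m3
#' @export
plan_mud_conc <- function(plan, year) {
  ph <- plan$phases
  i <- findInterval(year, ph$from, rightmost.closed = FALSE)
  i <- pmin(pmax(i, 1L), nrow(ph))
  ph$mud_mgL[i] / 1000 # mg/L -> kg/m3
}

plan_vegetation_on <- function(plan, year) {
  ph <- plan$phases
  i <- pmin(pmax(findInterval(year, ph$from), 1L), nrow(ph))
  ph$vegetation[i]
}
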