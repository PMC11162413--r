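#' Run a simulation scenario described in YAML
#'
#' A scenario file bundles a grid, signal sources, receiver colonies and
#' times into one reproducible document:
#'
#' ```yaml
#' grid: {width: 35, height: 35, spacing: 0.5, D: 1.4, boundary: no-flux}
#' t_end: 20
#' snapshot_times: [2, 6, 20]
#' sources:
#'   - {kind: droplet, x_mm: 13, y_mm: 17.5, dose: 7.5}
#'   - {kind: sender, x_mm: 22, y_mm: 17.5, rate: 1.5, induced: yes}
#' colonies:
#'   - {kind: highpass, x_mm: 17.5, y_mm: 17.5, commit_time: 6}
#' ```
#'
#' Fields omitted from the file fall back to [sim_defaults()]. Positions
#' use `x_mm`/`y_mm` keys (a bare `y` key is a boolean in YAML 1.1).
#'
#' @param path YAML scenario file.
#' @return `read_scenario_yaml()` returns a list with `grid`, `sources`,
#'   `colonies`, `t_end` and `snapshot_times`; `run_scenario()` runs the
#'   diffusion simulation and the colony dynamics at every snapshot-resolved
#'   colony position and returns a list of class `scenario_result` with the
#'   `field` and per-colony `trajectories`.
#' @export
read_scenario_yaml <- function(path) {
  sc <- yaml::read_yaml(path)
  g <- sc$grid %||% list()
  grid <- sim_grid(
    width = g$width %||% sim_defaults()$width,
    height = g$height %||% sim_defaults()$height,
    spacing = g$spacing %||% sim_defaults()$spacing,
    D = g$D %||% sim_defaults()$D,
    dt = g$dt,
    boundary = g$boundary %||% "no-flux",
    decay = g$decay %||% 0
  )
  sources <- lapply(sc$sources %||% list(), function(s) {
    kind <- s$kind %||% "droplet"
    if (kind == "droplet") {
      droplet(c(s$x_mm, s$y_mm), dose = s$dose %||% sim_defaults()$droplet_dose)
    } else {
      sender(c(s$x_mm, s$y_mm), rate = s$rate %||% sim_defaults()$sender_rate,
             leak = s$leak %||% 0, induced = s$induced %||% TRUE)
    }
  })
  colonies <- lapply(sc$colonies %||% list(), function(co) {
    colony_spec(c(co$x_mm, co$y_mm), kind = co$kind %||% "highpass",
                commit_time = co$commit_time %||% sim_defaults()$commit_time)
  })
  t_end <- sc$t_end %||% sim_defaults()$t_read
  list(grid = grid, sources = sources, colonies = colonies,
       t_end = t_end,
       snapshot_times = unlist(sc$snapshot_times) %||% t_end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_scenario_yaml
#' @param scenario a path or the list returned by [read_scenario_yaml()].
#' @param mode colony read-out mode, see [colony_dynamics()].
#' @export
run_scenario <- function(scenario, mode = c("commit", "integrate")) {
  mode <- match.arg(mode)
  if (is.character(scenario)) scenario <- read_scenario_yaml(scenario)
  times <- sort(unique(c(scenario$snapshot_times, scenario$t_end,
                         vapply(scenario$colonies,
                                function(co) co$commit_time, 0))))
  field <- simulate_field(scenario$grid, scenario$sources, scenario$t_end,
                          snapshot_times = times)
  trajectories <- lapply(scenario$colonies, function(co) {
    conc <- vapply(seq_along(field$times), function(i) {
      field_at(field, cbind(co$position[1], co$position[2]), which = i)
    }, 0)
    colony_dynamics(co, field$times, conc, mode = mode)
  })
  structure(list(field = field, colonies = scenario$colonies,
                 trajectories = trajectories),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  print(x$field)
  for (i in seq_along(x$trajectories)) {
    tr <- x$trajectories[[i]]
    cat(sprintf("colony %d (%s): final fluorescence %.4g\n",
                i, x$colonies[[i]]$kind,
                tr$fluorescence[nrow(tr)]))
  }
  invisible(x)
}
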