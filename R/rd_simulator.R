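#' Simulation grid for the 2-D reaction-diffusion device
#'
#' Uniform square grid with an explicit (FTCS) finite-difference scheme for
#' the diffusion of the signaling molecule. The time step must satisfy the
#' explicit-scheme stability bound `dt <= spacing^2 / (4 D)`; by default 80%
#' of the bound is used.
#'
#' @param width,height domain extent in mm.
#' @param spacing grid spacing in mm.
#' @param D diffusion coefficient in mm^2/h.
#' @param dt time step in hours; defaults to `0.8 * spacing^2 / (4 D)`.
#' @param boundary `"no-flux"` (conserving) or `"absorbing"`.
#' @param decay first-order loss rate of the molecule (1/h); 0 by default
#'   (the signal is assumed conserved).
#' @return An object of class `sim_grid`.
#' @export
sim_grid <- function(width = sim_defaults()$width, height = sim_defaults()$height,
                     spacing = sim_defaults()$spacing, D = sim_defaults()$D,
                     dt = NULL, boundary = c("no-flux", "absorbing"),
                     decay = 0) {
  boundary <- match.arg(boundary)
  stopifnot(width > 0, height > 0, spacing > 0, D > 0, decay >= 0)
  dt_max <- spacing^2 / (4 * D)
  if (is.null(dt)) dt <- 0.8 * dt_max
  if (dt > dt_max + 1e-12) {
    stop(sprintf(
      "dt = %g violates the explicit-scheme stability bound; use dt <= spacing^2/(4 D) = %g h",
      dt, dt_max))
  }
  nx <- max(2L, round(width / spacing))
  ny <- max(2L, round(height / spacing))
  structure(
    list(width = nx * spacing, height = ny * spacing, spacing = spacing,
         nx = nx, ny = ny, D = D, dt = dt, boundary = boundary, decay = decay,
         x = (seq_len(nx) - 0.5) * spacing, y = (seq_len(ny) - 0.5) * spacing),
    class = "sim_grid"
  )
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("%g x %g mm grid (%d x %d cells, %g mm), D = %g mm^2/h, dt = %.4g h, %s boundary\n",
              x$width, x$height, x$nx, x$ny, x$spacing, x$D, x$dt, x$boundary))
  invisible(x)
}

#' Signal sources: inducer droplets and sender colonies
#'
#' A `droplet` deposits its dose instantaneously at t = 0 as a Gaussian of
#' width one grid cell (emulating a dispensed 1 uL droplet); a `sender`
#' produces signal at a constant rate while its environmental input is
#' present, and at its leak rate otherwise.
#'
#' @param position `(x, y)` in mm, inside the domain.
#' @param dose droplet amount (default the 1 uL x 7.5 mM standard dose).
#' @param rate sender production rate (amount/h) when induced.
#' @param leak sender leak rate when uninduced (`<= rate`).
#' @param induced logical: is the sender's environmental input present?
#' @return An object of class `sim_source`.
#' @export
droplet <- function(position, dose = sim_defaults()$droplet_dose) {
  stopifnot(length(position) == 2L, dose >= 0)
  structure(list(kind = "droplet", position = as.numeric(position), dose = dose),
            class = "sim_source")
}

#' @rdname droplet
#' @export
sender <- function(position, rate = sim_defaults()$sender_rate, leak = 0,
                   induced = TRUE) {
  stopifnot(length(position) == 2L, rate >= 0, leak >= 0)
  if (leak > rate) stop("'leak' cannot exceed the induced production rate")
  structure(list(kind = "sender", position = as.numeric(position),
                 rate = rate, leak = leak, induced = isTRUE(induced)),
            class = "sim_source")
}

check_inside <- function(grid, position) {
  if (position[1] < 0 || position[1] > grid$width ||
      position[2] < 0 || position[2] > grid$height) {
    stop(sprintf("position (%g, %g) lies outside the %g x %g mm domain",
                 position[1], position[2], grid$width, grid$height))
  }
}

# Gaussian deposit of total `amount`, sigma = one grid cell
deposit_matrix <- function(grid, position, amount) {
  sig <- grid$spacing
  gx <- stats::dnorm(grid$x, position[1], sig)
  gy <- stats::dnorm(grid$y, position[2], sig)
  u <- outer(gx, gy)
  tot <- sum(u) * grid$spacing^2
  if (tot <= 0) stop("deposit lies entirely outside the domain")
  u * (amount / tot)               # amount per mm^2
}

cell_index <- function(grid, position) {
  c(pmin(pmax(round(position[1] / grid$spacing + 0.5), 1), grid$nx),
    pmin(pmax(round(position[2] / grid$spacing + 0.5), 1), grid$ny))
}

# one FTCS step; conservative form with reflecting (no-flux) or zero
# (absorbing) ghost cells
diffuse_step <- function(u, grid) {
  nx <- grid$nx; ny <- grid$ny
  if (grid$boundary == "no-flux") {
    up    <- u[c(1L, 1:(nx - 1L)), ]
    down  <- u[c(2:nx, nx), ]
    left  <- u[, c(1L, 1:(ny - 1L))]
    right <- u[, c(2:ny, ny)]
  } else {
    z_row <- matrix(0, 1L, ny); z_col <- matrix(0, nx, 1L)
    up    <- rbind(z_row, u[1:(nx - 1L), , drop = FALSE])
    down  <- rbind(u[2:nx, , drop = FALSE], z_row)
    left  <- cbind(z_col, u[, 1:(ny - 1L), drop = FALSE])
    right <- cbind(u[, 2:ny, drop = FALSE], z_col)
  }
  lap <- (up + down + left + right - 4 * u) / grid$spacing^2
  u2 <- u + grid$dt * (grid$D * lap - grid$decay * u)
  pmax(u2, 0)
}

#' Simulate the diffusion field
#'
#' Explicit finite-difference solution of the diffusion equation
#' `du/dt = D lap(u) + sources`. Droplet sources are deposited at t = 0;
#' senders add signal every step. With no-flux boundaries and no decay the
#' total amount of a droplet is conserved to solver tolerance.
#'
#' @param grid a [sim_grid()].
#' @param sources list of [droplet()] / [sender()] sources.
#' @param t_end end time in hours.
#' @param snapshot_times times (h) at which to store the field; defaults to
#'   `t_end` only.
#' @return An object of class `sim_field`: `times`, `snapshots` (list of
#'   `nx x ny` matrices, amount/mm^2), the grid and the sources.
#' @examples
#' g <- sim_grid(width = 20, height = 20, spacing = 1)
#' f <- simulate_field(g, list(droplet(c(10, 10))), t_end = 2)
#' sum(field_at(f, cbind(10, 10)) > 0)
#' @export
simulate_field <- function(grid, sources, t_end,
                           snapshot_times = t_end) {
  stopifnot(inherits(grid, "sim_grid"), t_end > 0)
  if (inherits(sources, "sim_source")) sources <- list(sources)
  for (s in sources) check_inside(grid, s$position)
  snapshot_times <- sort(unique(pmin(snapshot_times, t_end)))
  u <- matrix(0, grid$nx, grid$ny)
  for (s in sources) {
    if (s$kind == "droplet" && s$dose > 0) {
      u <- u + deposit_matrix(grid, s$position, s$dose)
    }
  }
  senders <- Filter(function(s) s$kind == "sender", sources)
  s_rates <- vapply(senders, function(s) if (s$induced) s$rate else s$leak, 0)
  s_cells <- lapply(senders, function(s) cell_index(grid, s$position))

  n_steps <- ceiling(t_end / grid$dt)
  snap_steps <- pmin(pmax(round(snapshot_times / grid$dt), 1L), n_steps)
  snapshots <- vector("list", length(snapshot_times))
  k <- 1L
  for (step in seq_len(n_steps)) {
    u <- diffuse_step(u, grid)
    for (j in seq_along(senders)) {
      if (s_rates[j] > 0) {
        ij <- s_cells[[j]]
        u[ij[1], ij[2]] <- u[ij[1], ij[2]] + s_rates[j] * grid$dt / grid$spacing^2
      }
    }
    while (k <= length(snap_steps) && step == snap_steps[k]) {
      snapshots[[k]] <- u
      k <- k + 1L
    }
  }
  structure(
    list(grid = grid, times = snapshot_times, snapshots = snapshots,
         sources = sources),
    class = "sim_field"
  )
}

#' @export
print.sim_field <- function(x, ...) {
  cat(sprintf("diffusion field: %d source(s), %d snapshot(s) at t = %s h\n",
              length(x$sources), length(x$times),
              paste(signif(x$times, 4), collapse = ", ")))
  print(x$grid)
  invisible(x)
}

#' Total amount of signal in a field snapshot
#'
#' @param field a `sim_field`.
#' @param which snapshot index (default: last).
#' @return Integrated amount (`sum(u) * spacing^2`).
#' @export
field_total <- function(field, which = length(field$snapshots)) {
  sum(field$snapshots[[which]]) * field$grid$spacing^2
}

#' Bilinear interpolation of a field snapshot at arbitrary positions
#'
#' @param field a `sim_field`.
#' @param xy two-column matrix of positions (mm).
#' @param which snapshot index (default: last).
#' @return Concentration vector.
#' @export
field_at <- function(field, xy, which = length(field$snapshots)) {
  u <- field$snapshots[[which]]
  g <- field$grid
  xy <- matrix(as.numeric(xy), ncol = 2L)
  fx <- pmin(pmax(xy[, 1] / g$spacing + 0.5, 1), g$nx)
  fy <- pmin(pmax(xy[, 2] / g$spacing + 0.5, 1), g$ny)
  i0 <- pmin(floor(fx), g$nx - 1L); j0 <- pmin(floor(fy), g$ny - 1L)
  wx <- fx - i0; wy <- fy - j0
  u[cbind(i0, j0)] * (1 - wx) * (1 - wy) +
    u[cbind(i0 + 1L, j0)] * wx * (1 - wy) +
    u[cbind(i0, j0 + 1L)] * (1 - wx) * wy +
    u[cbind(i0 + 1L, j0 + 1L)] * wx * wy
}

#' Analytic free-space concentration kernels
#'
#' Closed-form 2-D solutions on an unbounded domain, used as fast surrogates
#' for mid-domain concentrations and as verification oracles for the
#' finite-difference solver. For an instantaneous droplet of amount `dose`,
#' `u(r, t) = dose / (4 pi D t) * exp(-r^2 / (4 D t))`; for a constant-rate
#' sender, the time-integrated kernel `rate / (4 pi D) * E1(r^2 / (4 D t))`
#' (exponential integral), evaluated no closer than `r_min` where it diverges.
#'
#' @param r distance(s) from the source, mm.
#' @param t time since the source started, h.
#' @param D diffusion coefficient, mm^2/h.
#' @param dose droplet amount.
#' @param rate sender production rate, amount/h.
#' @param r_min clamp radius for the sender kernel (mm).
#' @return Concentration (amount/mm^2).
#' @export
droplet_kernel <- function(r, t, D = sim_defaults()$D,
                           dose = sim_defaults()$droplet_dose) {
  stopifnot(t > 0)
  dose / (4 * pi * D * t) * exp(-r^2 / (4 * D * t))
}

#' @rdname droplet_kernel
#' @export
sender_kernel <- function(r, t, D = sim_defaults()$D,
                          rate = sim_defaults()$sender_rate,
                          r_min = 0.25) {
  stopifnot(t > 0)
  r <- pmax(r, r_min)
  rate / (4 * pi * D) * pracma::expint(r^2 / (4 * D * t))
}

#' Colony specification
#'
#' A receiver colony: a position, a strain (activation kind plus
#' [dose_response()]), logistic growth parameters and the response commitment
#' time. The colony reads the local signal concentration at `commit_time` and
#' holds its expression state thereafter (the observed ring position is
#' temporally static); a continuous-integration mode is available in
#' [colony_dynamics()].
#'
#' @param position `(x, y)` mm.
#' @param kind activation kind of the strain.
#' @param response a [dose_response()]; defaults to the stand-in for `kind`.
#' @param growth_rate,capacity,lag,n0 logistic growth parameters (1/h,
#'   OD-like capacity, lag h, initial biomass).
#' @param commit_time concentration read-out time, h.
#' @return An object of class `sim_colony`.
#' @export
colony_spec <- function(position, kind,
                        response = sim_defaults()$dose_response[[kind]],
                        growth_rate = sim_defaults()$growth_rate,
                        capacity = sim_defaults()$capacity,
                        lag = sim_defaults()$lag,
                        n0 = sim_defaults()$n0,
                        commit_time = sim_defaults()$commit_time) {
  kind <- match.arg(kind, activation_kinds())
  stopifnot(length(position) == 2L, growth_rate > 0, capacity > 0, lag >= 0,
            n0 > 0, commit_time > 0)
  structure(
    list(position = as.numeric(position), kind = kind, response = response,
         growth_rate = growth_rate, capacity = capacity, lag = lag, n0 = n0,
         commit_time = commit_time),
    class = "sim_colony"
  )
}

logistic_biomass <- function(colony, t) {
  te <- pmax(t - colony$lag, 0)
  K <- colony$capacity
  n0 <- colony$n0
  K / (1 + (K - n0) / n0 * exp(-colony$growth_rate * te))
}

#' Colony expression dynamics
#'
#' Integrates fluorescence accumulation: biomass grows logistically (after a
#' lag) and fluorescent protein accumulates proportionally to biomass times
#' the dose response of the local signal concentration. In the default
#' `"commit"` mode the concentration is read once at `commit_time` and held;
#' in `"integrate"` mode the instantaneous concentration drives accumulation
#' throughout.
#'
#' @param colony a [colony_spec()].
#' @param times time grid (h), covering `[0, t_end]`.
#' @param concentration local signal concentration at `times` (recycled if
#'   scalar).
#' @param mode `"commit"` or `"integrate"`.
#' @return A data frame with `time`, `biomass`, `fluorescence` (monotone
#'   non-decreasing).
#' @export
colony_dynamics <- function(colony, times, concentration,
                            mode = c("commit", "integrate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(colony, "sim_colony"))
  times <- as.numeric(times)
  conc <- rep_len(as.numeric(concentration), length(times))
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (max(times) < colony$commit_time && mode == "commit") {
    stop("'times' must cover the commit time")
  }
  biomass <- logistic_biomass(colony, times)
  resp <- if (mode == "commit") {
    u_commit <- stats::approx(times, conc, xout = colony$commit_time,
                              rule = 2)$y
    rep(predict(colony$response, u_commit), length(times))
  } else {
    predict(colony$response, conc)
  }
  rate <- resp * biomass
  fl <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * diff(times)))
  data.frame(time = times, biomass = biomass, fluorescence = fl)
}

#' Per-pixel gate map of a droplet-input device
#'
#' Runs one diffusion simulation per input configuration (via superposition of
#' the single-input fields: the PDE is linear), thresholds every pixel of
#' every configuration's field with the given activation function, assembles
#' the per-pixel truth table and encodes it as a hex gate code: the logic gate
#' a receiver would compute if placed at that pixel.
#'
#' @param grid a [sim_grid()].
#' @param input_positions two-column matrix of droplet positions (mm), input
#'   A first.
#' @param act an [activation()] with thresholds in concentration units.
#' @param t_read read-out time, h.
#' @param dose droplet dose.
#' @return An object of class `gate_map`: integer matrix `codes`
#'   (`nx x ny`) plus the grid and inputs.
#' @export
gate_map <- function(grid, input_positions, act, t_read = sim_defaults()$t_read,
                     dose = sim_defaults()$droplet_dose) {
  stopifnot(inherits(grid, "sim_grid"), inherits(act, "activation"))
  input_positions <- matrix(as.numeric(input_positions), ncol = 2L)
  n <- nrow(input_positions)
  if (n < 1L) stop("need at least one input position")
  singles <- lapply(seq_len(n), function(i) {
    simulate_field(grid, list(droplet(input_positions[i, ], dose = dose)),
                   t_end = t_read)$snapshots[[1L]]
  })
  m <- 2L^n
  S <- state_matrix(n)
  codes <- matrix(0, grid$nx, grid$ny)
  for (i in seq_len(m)) {
    u <- Reduce(`+`, c(list(matrix(0, grid$nx, grid$ny)),
                       singles[S[i, ] == 1L]))
    on <- matrix(apply_activation(act, as.numeric(u)), grid$nx, grid$ny)
    codes <- codes + on * 2^(m - i)   # state i-1 sits at bit m - i
  }
  structure(list(codes = codes, grid = grid, inputs = input_positions,
                 activation = act, t_read = t_read),
            class = "gate_map")
}

#' @export
print.gate_map <- function(x, ...) {
  tab <- sort(table(x$codes), decreasing = TRUE)
  m <- 2L^nrow(x$inputs)
  cat(sprintf("gate map (%d inputs, %s, t = %g h): %d distinct gates\n",
              nrow(x$inputs), x$activation$kind, x$t_read, length(tab)))
  top <- utils::head(tab, 8)
  cat(paste(sprintf("  %s: %d px",
                    sprintf(paste0("0x%0", max(1L, m %/% 4L), "X"),
                            as.numeric(names(top))), as.integer(top)),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Write a gate map as a PNG raster and a per-pixel CSV
#'
#' @param map a [gate_map()].
#' @param png_path,csv_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_gate_map <- function(map, png_path = NULL, csv_path = NULL) {
  stopifnot(inherits(map, "gate_map"))
  if (!is.null(png_path)) {
    codes <- sort(unique(as.numeric(map$codes)))
    pal <- grDevices::hcl.colors(max(length(codes), 2L), "Spectral")
    idx <- matrix(match(as.numeric(map$codes), codes), map$grid$nx, map$grid$ny)
    img <- array(0, dim = c(map$grid$ny, map$grid$nx, 3L))
    rgb <- grDevices::col2rgb(pal) / 255
    for (ch in 1:3) img[, , ch] <- t(matrix(rgb[ch, idx], map$grid$nx, map$grid$ny))[map$grid$ny:1, ]
    png::writePNG(img, png_path)
  }
  if (!is.null(csv_path)) {
    m <- 2L^nrow(map$inputs)
    df <- expand.grid(i = seq_len(map$grid$nx), j = seq_len(map$grid$ny))
    df <- data.frame(
      x_mm = map$grid$x[df$i], y_mm = map$grid$y[df$j],
      hex_code = sprintf(paste0("0x%0", max(1L, m %/% 4L), "X"),
                         as.numeric(map$codes[cbind(df$i, df$j)]))
    )
    utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(c(png = png_path, csv = csv_path))
}

#' Predict the digital behavior of a placed design
#'
#' Simulates every input state of a layout (droplet or sender inputs), reads
#' the concentration at each receiver colony, and converts expression into
#' per-state fold changes relative to the all-OFF configuration. A receiver's
#' digital verdict in a state is ON iff its expression exceeds
#' `decision_ratio` times its basal level (for highpass/bandpass strains this
#' is exactly a fold-change threshold, since their all-OFF expression is
#' basal). The device output per state is the implicit OR of the receiver
#' verdicts. Each output colony is scored against its own induced
#' sub-function (least fluorescent ON state divided by most fluorescent OFF
#' state, in fold-change units); the device score is the worst colony score.
#'
#' @param layout a [layout_spec()] whose receiver nodes match the design's
#'   receivers (in order).
#' @param design a `macchiato_design`.
#' @param t_read read-out time, h.
#' @param input_kind `"droplet"` or `"sender"`.
#' @param decision_ratio digital verdict threshold.
#' @param grid optional [sim_grid()]; defaults to the standard device grid
#'   with 0.5 mm spacing.
#' @param dose,rate droplet dose / sender production rate.
#' @return An object of class `gate_prediction`: per-state data frame
#'   (`state`, per-receiver fold changes and verdicts, `output`,
#'   `output_value`, `target`), plus `score` and `correct` (whether the
#'   simulated truth table matches the target on non-DC states).
#' @export
predict_gate <- function(layout, design, t_read = sim_defaults()$t_read,
                         input_kind = c("droplet", "sender"),
                         decision_ratio = sim_defaults()$decision_ratio,
                         grid = NULL,
                         dose = sim_defaults()$droplet_dose,
                         rate = sim_defaults()$sender_rate) {
  input_kind <- match.arg(input_kind)
  stopifnot(inherits(design, "macchiato_design"), inherits(layout, "layout_spec"))
  n <- design$target$n_inputs
  inputs <- layout$nodes[layout$nodes$role == "input", , drop = FALSE]
  recv <- layout$nodes[layout$nodes$role == "receiver", , drop = FALSE]
  if (nrow(inputs) != n) {
    stop(sprintf("layout has %d inputs but the design needs %d", nrow(inputs), n))
  }
  if (nrow(recv) != length(design$receivers)) {
    stop(sprintf("layout has %d receivers but the design has %d",
                 nrow(recv), length(design$receivers)))
  }
  if (is.null(grid)) {
    grid <- sim_grid(spacing = 0.5)
  }
  defaults <- sim_defaults()
  colonies <- lapply(seq_len(nrow(recv)), function(i) {
    colony_spec(c(recv$x[i], recv$y[i]),
                kind = design$receivers[[i]]$activation$kind)
  })
  commit <- if (length(colonies)) colonies[[1L]]$commit_time else defaults$commit_time

  # superposition: one simulation per input, then per-state sums
  singles <- lapply(seq_len(n), function(i) {
    src <- if (input_kind == "droplet") droplet(c(inputs$x[i], inputs$y[i]), dose = dose)
           else sender(c(inputs$x[i], inputs$y[i]), rate = rate)
    simulate_field(grid, list(src), t_end = commit)$snapshots[[1L]]
  })
  S <- state_matrix(n)
  m <- 2L^n
  fold <- matrix(NA_real_, m, length(colonies))
  verdict <- matrix(NA, m, length(colonies))
  for (s in seq_len(m)) {
    u <- Reduce(`+`, c(list(matrix(0, grid$nx, grid$ny)), singles[S[s, ] == 1L]))
    fld <- list(grid = grid, snapshots = list(u))
    for (j in seq_along(colonies)) {
      uc <- field_at(structure(fld, class = "sim_field"),
                     cbind(colonies[[j]]$position[1], colonies[[j]]$position[2]))
      resp <- predict(colonies[[j]]$response, uc)
      resp0 <- predict(colonies[[j]]$response, 0)
      fold[s, j] <- resp / resp0
      verdict[s, j] <- resp / colonies[[j]]$response$basal > decision_ratio
    }
  }
  summarize_prediction(design, fold, verdict, decision_ratio)
}

# shared by predict_gate() (grid simulation) and layout_fitness() (kernels)
summarize_prediction <- function(design, fold, verdict, decision_ratio) {
  n <- design$target$n_inputs
  m <- 2L^n
  target <- design$target$outputs
  k <- length(design$receivers)
  output <- if (k) apply(verdict, 1, any) else rep(FALSE, m)
  intended_on <- if (k) {
    vapply(seq_len(k), function(j) design$induced[[j]]$outputs == 1L,
           logical(m))
  } else matrix(FALSE, m, 0L)
  output_value <- vapply(seq_len(m), function(s) {
    if (!is.na(target[s]) && target[s] == 1L && any(intended_on[s, ])) {
      max(fold[s, intended_on[s, ]])
    } else if (k) {
      max(fold[s, ])
    } else 1
  }, 0)
  care <- !is.na(target)
  correct <- all(output[care] == (target[care] == 1L))
  # each output colony is scored against its own sub-function (a two-colony
  # gate displays two colony scores; the device score is the worst of them)
  score <- if (k == 0L) NA_real_ else min(vapply(seq_len(k), function(j) {
    on_j <- design$induced[[j]]$outputs == 1L
    suppressWarnings(gate_score(fold[on_j, j], fold[!on_j, j]))
  }, 0))
  df <- data.frame(state = state_labels(n))
  for (j in seq_len(k)) df[[sprintf("fold_%d", j)]] <- fold[, j]
  for (j in seq_len(k)) df[[sprintf("on_%d", j)]] <- verdict[, j]
  df$output <- as.integer(output)
  df$output_value <- output_value
  df$target <- ifelse(is.na(target), "DC", as.character(target))
  structure(
    list(states = df, score = score, correct = correct,
         decision_ratio = decision_ratio),
    class = "gate_prediction"
  )
}

#' @export
print.gate_prediction <- function(x, ...) {
  cat(sprintf("simulated gate: %s, score %.3g\n",
              if (x$correct) "correct truth table" else "INCORRECT truth table",
              x$score))
  df <- x$states
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
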