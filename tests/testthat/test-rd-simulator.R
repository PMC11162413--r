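test_that("droplet mass is conserved under no-flux boundaries", {
  g <- small_grid()
  f <- simulate_field(g, list(droplet(c(10, 10), dose = 7.5)), t_end = 3,
                      snapshot_times = c(1, 3))
  for (i in seq_along(f$times)) {
    expect_lt(abs(field_total(f, i) - 7.5) / 7.5, 1e-6)
    expect_true(all(f$snapshots[[i]] >= 0))
  }
})

test_that("absorbing boundaries lose mass", {
  g <- small_grid(boundary = "absorbing")
  f <- simulate_field(g, list(droplet(c(2, 10), dose = 1)), t_end = 5)
  expect_lt(field_total(f), 1)
})

test_that("the field matches the analytic free-space kernel away from walls", {
  g <- sim_grid(width = 35, height = 35, spacing = 0.5)
  f <- simulate_field(g, list(droplet(c(17.5, 17.5), dose = 7.5)), t_end = 6)
  xy <- expand.grid(x = g$x, y = g$y)
  r <- sqrt((xy$x - 17.5)^2 + (xy$y - 17.5)^2)
  ana <- droplet_kernel(r, 6, D = g$D, dose = 7.5)
  rmse <- sqrt(mean((as.numeric(f$snapshots[[1]]) - ana)^2))
  expect_lt(rmse / max(ana), 0.01)
})

test_that("the linear PDE superposes: joint field = sum of single fields", {
  g <- small_grid()
  a <- simulate_field(g, list(droplet(c(7, 10))), t_end = 2)
  b <- simulate_field(g, list(droplet(c(13, 10))), t_end = 2)
  ab <- simulate_field(g, list(droplet(c(7, 10)), droplet(c(13, 10))), t_end = 2)
  expect_equal(ab$snapshots[[1]], a$snapshots[[1]] + b$snapshots[[1]],
               tolerance = 1e-10)
})

test_that("sender sources inject mass at their production rate", {
  g <- small_grid()
  f <- simulate_field(g, list(sender(c(10, 10), rate = 2)), t_end = 4)
  expect_equal(field_total(f), 2 * 4, tolerance = 0.01)
  off <- simulate_field(g, list(sender(c(10, 10), rate = 2, induced = FALSE)),
                        t_end = 4)
  expect_equal(field_total(off), 0)
})

test_that("unstable time steps are rejected with the stability bound", {
  expect_error(sim_grid(spacing = 0.5, D = 1.4, dt = 1), "spacing\\^2/\\(4 D\\)")
})

test_that("bilinear field interpolation is exact on a constant field", {
  g <- small_grid()
  f <- simulate_field(g, list(droplet(c(10, 10))), t_end = 1)
  f$snapshots[[1]][] <- 3.5
  expect_equal(field_at(f, cbind(c(3.2, 11.7), c(8.9, 15.1))), c(3.5, 3.5))
})

test_that("dose-response curves have the engineered shapes", {
  hp <- dose_response("highpass", basal = 0.02, v_max = 1, K_act = 0.02)
  expect_equal(predict(hp, 0), 0.02)
  expect_gt(predict(hp, 1), 0.9)
  bp <- dose_response("bandpass", K_act = 0.005, K_rep = 0.04)
  mid <- sqrt(0.005 * 0.04)
  expect_gt(predict(bp, mid), predict(bp, 0))
  expect_gt(predict(bp, mid), predict(bp, 100 * 0.04))
  lp <- dose_response("lowpass", K_act = 0.01)
  expect_equal(predict(lp, 0), lp$v_max)
  expect_error(dose_response("highpass", K_rep = 1), "no repression")
  expect_error(dose_response("bandpass", K_act = 0.05, K_rep = 0.01), "K_rep > K_act")
})

test_that("colony fluorescence is monotone and commits at the read time", {
  col <- colony_spec(c(10, 10), "highpass")
  times <- seq(0, 20, by = 0.5)
  basal_traj <- colony_dynamics(col, times, 0)
  expect_true(all(diff(basal_traj$fluorescence) >= 0))
  sat <- colony_dynamics(col, times, 10)
  ratio <- sat$fluorescence[length(times)] / basal_traj$fluorescence[length(times)]
  expect_equal(ratio, predict(col$response, 10) / predict(col$response, 0),
               tolerance = 1e-6)
  # commit mode holds the early concentration even if it later drops to zero
  falling <- c(rep(10, sum(times <= col$commit_time)),
               rep(0, sum(times > col$commit_time)))
  committed <- colony_dynamics(col, times, falling, mode = "commit")
  expect_equal(committed$fluorescence[length(times)],
               sat$fluorescence[length(times)])
  integrated <- colony_dynamics(col, times, falling, mode = "integrate")
  expect_lt(integrated$fluorescence[length(times)],
            sat$fluorescence[length(times)])
})

test_that("gate maps assign FALSE far from sources and are deterministic", {
  g <- small_grid()
  act <- activation("highpass", 0.015)
  map1 <- gate_map(g, rbind(c(8, 10), c(12, 10)), act, t_read = 5)
  map2 <- gate_map(g, rbind(c(8, 10), c(12, 10)), act, t_read = 5)
  expect_identical(map1$codes, map2$codes)
  expect_equal(map1$codes[1, 1], 0)          # corner pixel: constant FALSE
  expect_true(any(map1$codes > 0))
})

test_that("the midpoint gate switches from OR to AND as sources separate", {
  g <- sim_grid(width = 35, height = 35, spacing = 0.5)
  act <- activation("highpass", 0.015)
  mid_gate <- vapply(c(4.5, 9, 13.5), function(sep) {
    pos <- rbind(c(17.5 - sep / 2, 17.5), c(17.5 + sep / 2, 17.5))
    map <- gate_map(g, pos, act, t_read = 20)
    ij <- macchiato:::cell_index(g, c(17.5, 17.5))
    map$codes[ij[1], ij[2]]
  }, 0)
  expect_equal(mid_gate[1], 0x7)   # close: OR
  expect_equal(mid_gate[3], 0x1)   # far: AND
  expect_true(all(diff(match(mid_gate, c(0x7, 0x1))) >= 0))  # monotone sweep
})

test_that("gate-map pixels are consistent with the axis model", {
  g <- small_grid()
  act <- activation("highpass", 0.015)
  map <- gate_map(g, rbind(c(8, 10), c(12, 10)), act, t_read = 5)
  set.seed(3)
  px <- cbind(sample(g$nx, 25, replace = TRUE), sample(g$ny, 25, replace = TRUE))
  for (i in seq_len(nrow(px))) {
    code <- map$codes[px[i, 1], px[i, 2]]
    expect_true(is_realizable_single(tt_from_hex(code, 2), act$kind)$realizable)
  }
})

test_that("gate prediction normalizes the all-OFF configuration to fold 1", {
  d <- or_design()
  lay <- make_layout(rbind(c(2, 2), c(4, 2)), rbind(c(3, 2)))
  p <- predict_gate(lay, d, grid = small_grid(35, 35, 0.5))
  expect_equal(p$states$fold_1[p$states$state == "00"], 1)
  expect_true(p$correct)
  expect_gt(p$score, 1)
})

test_that("gate prediction rejects mismatched layouts", {
  d <- or_design()
  lay <- make_layout(rbind(c(2, 2)), rbind(c(3, 2)))  # one input missing
  expect_error(predict_gate(lay, d), "1 inputs")
})

test_that("YAML scenarios run end to end with defaults filled in", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "grid: {width: 20, height: 20, spacing: 0.5}",
    "t_end: 8",
    "snapshot_times: [6, 8]",
    "sources:",
    "  - {kind: droplet, x_mm: 8, y_mm: 10}",
    "colonies:",
    "  - {kind: highpass, x_mm: 11, y_mm: 10, commit_time: 6}"
  ), path)
  sc <- read_scenario_yaml(path)
  expect_equal(sc$grid$width, 20)
  expect_length(sc$sources, 1L)
  res <- run_scenario(sc)
  expect_s3_class(res, "scenario_result")
  tr <- res$trajectories[[1]]
  expect_true(all(diff(tr$fluorescence) >= 0))
  expect_gt(tr$fluorescence[nrow(tr)], 0)
})

test_that("gate-map rasters and CSVs are written", {
  g <- small_grid()
  map <- gate_map(g, rbind(c(8, 10), c(12, 10)), activation("highpass", 0.015),
                  t_read = 5)
  png_path <- withr::local_tempfile(fileext = ".png")
  csv_path <- withr::local_tempfile(fileext = ".csv")
  write_gate_map(map, png_path, csv_path)
  expect_true(file.exists(png_path))
  df <- utils::read.csv(csv_path)
  expect_equal(nrow(df), g$nx * g$ny)
})
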