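test_that("the multiplexer decomposes into the demonstrated two-receiver design", {
  d <- macchiato_minimize(tt_from_hex(0x1B, 3), c("highpass", "bandpass"))
  expect_length(d$receivers, 2L)
  expect_setequal(d$codes, c(0x0A, 0x11))
  expect_true(validate_design(d)$valid)
  # the explicitly stated cover {bandpass -> 0x0A, highpass -> 0x11}
  explicit <- design_from_codes(tt_from_hex(0x1B, 3), c("0x0A", "0x11"),
                                c("highpass", "bandpass"))
  kinds <- vapply(explicit$receivers, function(r) r$activation$kind, "")
  expect_setequal(kinds, c("bandpass", "highpass"))
  expect_true(validate_design(explicit)$valid)
})

test_that("constant FALSE needs no receivers and validates trivially", {
  d <- macchiato_minimize(tt_from_hex(0x0, 2))
  expect_length(d$receivers, 0L)
  expect_true(validate_design(d)$valid)
})

test_that("infeasible targets raise an error naming the uncoverable state", {
  # ON at the zero state is unreachable with highpass/bandpass only
  expect_error(
    macchiato_minimize(tt_from_hex(0x80, 3), c("highpass", "bandpass")),
    "000")
})

test_that("every three-input gate needs at most two receivers (full kinds)", {
  sizes <- vapply(0:255, function(cd) {
    d <- macchiato_minimize(tt_from_hex(cd, 3))
    stopifnot(validate_design(d)$valid)
    length(d$receivers)
  }, 1L)
  expect_lte(max(sizes), 2L)
})

test_that("greedy never beats exact, and matches it at n = 3 full kinds", {
  for (cd in 0:255) {
    nx <- length(macchiato_minimize(tt_from_hex(cd, 3), exact = TRUE)$receivers)
    ng <- length(macchiato_minimize(tt_from_hex(cd, 3), exact = FALSE)$receivers)
    expect_gte(ng, nx)
    expect_equal(ng, nx)
  }
})

test_that("removing bandpass and bandstop loses most three-input gates", {
  feasible <- vapply(0:255, function(cd) {
    !inherits(try(macchiato_minimize(tt_from_hex(cd, 3),
                                     c("highpass", "lowpass"),
                                     exact = FALSE), silent = TRUE),
              "try-error")
  }, TRUE)
  expect_lt(mean(feasible), 0.5)
})

test_that("zero-OFF tables respect the n - 1 receiver bound", {
  # exhaustive at n = 3 with highpass + bandpass
  zero_off <- (0:255)[bitwAnd(0:255, 128L) == 0L]
  sizes3 <- vapply(zero_off, function(cd) {
    length(macchiato_minimize(tt_from_hex(cd, 3),
                              c("highpass", "bandpass"))$receivers)
  }, 1L)
  expect_lte(max(sizes3), 2L)
  # sampled at n = 4 (greedy upper-bounds the minimum)
  set.seed(20240601)
  codes <- sample(0:(2^15 - 1), 1000)
  ok <- vapply(codes, function(cd) {
    d <- macchiato_minimize(tt_from_hex(cd, 4), c("highpass", "bandpass"),
                            exact = FALSE)
    length(d$receivers) <= 3L && validate_design(d)$valid
  }, TRUE)
  expect_true(all(ok))
})

test_that("elementary CA rules are coverable within the two-colony builds", {
  # both rules admit a single-bandpass witness with free thresholds, and the
  # two-receiver demonstrated decompositions validate
  for (cd in c(0x78, 0x76)) {
    d <- macchiato_minimize(tt_from_hex(cd, 3), c("highpass", "bandpass"))
    expect_lte(length(d$receivers), 2L)
    expect_true(validate_design(d)$valid)
  }
  rule110 <- design_from_codes(tt_from_hex(0x76, 3), c(0x70, 0x66),
                               c("highpass", "bandpass"))
  expect_true(validate_design(rule110)$valid)
})

test_that("DC states are free: minimization may use them either way", {
  tt <- truth_table(c(0L, NA, NA, 1L), 2)   # only 11 must be ON, 00 OFF
  d <- macchiato_minimize(tt, "highpass")
  expect_length(d$receivers, 1L)
  v <- validate_design(d)
  expect_true(v$valid)
  expect_identical(v$report$target[2:3], c("DC", "DC"))
})

test_that("validation reports mismatches state by state instead of raising", {
  bad <- design_from_codes(tt_from_hex(0x6, 2), 0x6, "bandpass")
  v <- validate_design(bad, target = tt_from_hex(0x7, 2))  # wrong target
  expect_false(v$valid)
  expect_identical(v$report$state[!v$report$match], "11")
})

test_that("the explicit OR layer is structural and flags redundancy", {
  d <- macchiato_minimize(tt_from_hex(0x1B, 3), c("highpass", "bandpass"))
  layer <- explicit_or_layer(d)
  expect_equal(layer$n_nodes, 3L)
  expect_false(layer$redundant)
  expect_true(layer$extra_molecule)
  empty <- explicit_or_layer(macchiato_minimize(tt_from_hex(0x0, 2)))
  expect_equal(empty$n_nodes, 0L)
  single <- explicit_or_layer(or_design())
  expect_true(single$redundant)
})

test_that("designs survive a JSON round trip", {
  d <- macchiato_minimize(tt_from_hex(0x1B, 3), c("highpass", "bandpass"))
  path <- withr::local_tempfile(fileext = ".json")
  write_design_json(d, path)
  back <- read_design_json(path)
  expect_equal(tt_to_hex(back$target), 0x1B)
  expect_setequal(back$codes, d$codes)
  expect_true(validate_design(back)$valid)
})
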