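test_that("synthetic characterization is exact at zero noise and seeded", {
  dr <- dose_response("highpass", K_act = 0.05)
  conc <- 10^seq(-3, 0, length.out = 8)
  tab0 <- generate_characterization(dr, conc, noise_cv = 0, replicates = 2)
  expect_equal(tab0$fluorescence, predict(dr, tab0$concentration))
  t1 <- generate_characterization(dr, conc, noise_cv = 0.1, seed = 42)
  t2 <- generate_characterization(dr, conc, noise_cv = 0.1, seed = 42)
  expect_identical(t1, t2)
  t3 <- generate_characterization(dr, conc, noise_cv = 0.1, seed = 43)
  expect_false(identical(t1$fluorescence, t3$fluorescence))
})

test_that("bandpass characterization peaks at intermediate concentration", {
  dr <- dose_response("bandpass", K_act = 0.005, K_rep = 0.04)
  conc <- c(1e-4, sqrt(0.005 * 0.04), 10)
  tab <- generate_characterization(dr, conc, noise_cv = 0, replicates = 1)
  f <- tab$fluorescence
  expect_gt(f[2], f[1])
  expect_gt(f[2], f[3])
})

test_that("noiseless fits invert the generating parameters", {
  dr <- dose_response("highpass", basal = 0.03, v_max = 0.8, K_act = 0.07,
                      n_act = 3)
  tab <- generate_characterization(dr, 10^seq(-3, 0.5, length.out = 10),
                                   noise_cv = 0, replicates = 1)
  fit <- fit_dose_response(tab, "highpass")
  expect_lt(abs(coef(fit)[["K_act"]] - 0.07) / 0.07, 0.01)
  expect_lt(abs(coef(fit)[["v_max"]] - 0.8) / 0.8, 0.01)
  expect_false(fit$diagnostics$curvature_flag)
})

test_that("fitting the wrong response kind flags systematic curvature", {
  bp <- dose_response("bandpass", K_act = 0.005, K_rep = 0.04)
  tab <- generate_characterization(bp, 10^seq(-4, 0, length.out = 12),
                                   noise_cv = 0.02, replicates = 3, seed = 5)
  fit <- fit_dose_response(tab, "highpass")
  expect_true(fit$diagnostics$curvature_flag)
})

test_that("fits need at least six distinct concentrations", {
  dr <- dose_response("highpass")
  tab <- generate_characterization(dr, c(0.01, 0.1, 1), noise_cv = 0)
  expect_error(fit_dose_response(tab, "highpass"), "at least 6")
})

test_that("the sender catalog holds the four demonstrated two-input gates", {
  cat <- sender_gate_catalog()
  expect_named(cat, c("OR", "NOR", "NAND", "IMPLY"))
  for (sc in cat) expect_true(validate_design(sc$design)$valid)
  # NOR: a single lowpass receiver, ON only with both senders silent
  nor <- cat$NOR
  expect_length(nor$design$receivers, 1L)
  expect_equal(nor$design$receivers[[1]]$activation$kind, "lowpass")
  expect_equal(tt_to_hex(nor$design$induced[[1]]), 0x8)
  # NAND and IMPLY are the demonstrated two-colony NOT/IDENTITY builds
  expect_length(cat$NAND$design$receivers, 2L)
  expect_length(cat$IMPLY$design$receivers, 2L)
  expect_setequal(
    vapply(cat$NAND$design$receivers, function(r) r$activation$kind, ""),
    "lowpass")
})

test_that("the gate catalog is consistent with the minimization framework", {
  catal <- demonstrated_gate_catalog()
  expect_true(all(c("0x7F", "0x37", "Rule 30", "Rule 110", "Multiplexer") %in%
                    catal$label))
  expect_equal(catal$code[catal$label == "(A OR C OR D) AND NOT B"], 0x70F0)
  for (i in seq_len(nrow(catal))) {
    row <- catal[i, ]
    d <- macchiato_minimize(catalog_truth_table(row), catalog_kinds(row))
    expect_equal(length(d$receivers), row$receivers_min, info = row$label)
    expect_true(validate_design(d)$valid, info = row$label)
    if (!is.na(row$receivers_reported)) {
      expect_lte(length(d$receivers), row$receivers_reported)
    }
    b <- catalog_design(row)
    expect_true(validate_design(b)$valid, info = row$label)
    if (!is.na(row$build_codes)) {
      expect_equal(length(b$receivers), row$receivers_reported)
    }
  }
})

test_that("the four-input catalog gate is ON exactly off the B branch", {
  tt <- catalog_truth_table(
    demonstrated_gate_catalog()[demonstrated_gate_catalog()$label == "(A OR C OR D) AND NOT B", ])
  S <- macchiato:::state_matrix(4)
  expected <- as.integer(S[, "B"] == 0 &
                           (S[, "A"] | S[, "C"] | S[, "D"]))
  expect_identical(tt$outputs, expected)
})
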