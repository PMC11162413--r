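test_that("state concentration is the subset sum of present inputs", {
  expect_equal(state_concentration(c(1, 2), "11"), 3)
  expect_equal(state_concentration(c(1, 2), "00"), 0)
  expect_equal(state_concentration(c(1, 2, 4), "101"), 5)
  expect_error(state_concentration(c(1, 2), "101"), "3 bits")
})

test_that("activation functions threshold as defined, with the zero-state rule", {
  hp <- activation("highpass", 1)
  expect_identical(apply_activation(hp, c(2, 0.5, 0)), c(1L, 0L, 0L))
  bp <- activation("bandpass", 1, 3)
  expect_identical(apply_activation(bp, c(2, 4, 0)), c(1L, 0L, 0L))
  lp <- activation("lowpass", 1)
  expect_identical(apply_activation(lp, 0), 1L)   # NOR from lowpass needs this
  bs <- activation("bandstop", 1, 3)
  expect_identical(apply_activation(bs, c(2, 4, 0)), c(0L, 1L, 1L))
  expect_error(activation("bandpass", 2, 1), "exceed")
  expect_error(activation("highpass", 0), "positive")
  expect_error(activation("highpass", 1, 2), "single threshold")
})

test_that("symmetric contributions with a bandpass induce XOR, highpass AND", {
  xor <- induced_truth_table(axis_receiver(activation("bandpass", 0.5, 1.5), c(1, 1)))
  expect_equal(tt_to_hex(xor), 0x6)
  and <- induced_truth_table(axis_receiver(activation("highpass", 1.5), c(1, 1)))
  expect_equal(tt_to_hex(and), 0x1)
  # NIMPLY: asymmetric contributions, only state 10 in the band
  nim <- induced_truth_table(axis_receiver(activation("bandpass", 0.5, 1.5), c(1, 2)))
  expect_equal(tt_to_hex(nim), 0x2)
})

test_that("degenerate receivers (state on a threshold) are rejected by name", {
  expect_error(
    induced_truth_table(axis_receiver(activation("highpass", 1), c(1, 2))),
    "state 10")
})

test_that("admissible orderings are exhaustive and carry feasible witnesses", {
  o2 <- admissible_orders(2)
  expect_length(o2, 2L)
  o3 <- admissible_orders(3)
  expect_length(o3, 12L)
  for (ord in o3) {
    w <- attr(ord, "witness")
    sums <- as.numeric(macchiato:::state_matrix(3) %*% w)
    expect_identical(order(sums) - 1L, as.integer(ord))  # witness realizes it
  }
  expect_error(admissible_orders(5), "at most 4")
})

test_that("realizability matches the demonstrated gates and the block bound", {
  expect_true(is_realizable_single(tt_from_hex(0x6, 2), "bandpass")$realizable)
  r11 <- is_realizable_single(tt_from_hex(0x11, 3), "highpass")
  expect_true(r11$realizable)
  expect_equal(tt_to_hex(induced_truth_table(r11$witness)), 0x11)
  r1b <- is_realizable_single(tt_from_hex(0x1B, 3), c("highpass", "bandpass"))
  expect_false(r1b$realizable)
})

test_that("every returned witness induces exactly the queried table", {
  set.seed(42)
  enum <- enumerate_realizable(3)
  for (code in sample(realizable_codes(enum), 40)) {
    res <- is_realizable_single(tt_from_hex(code, 3))
    expect_true(res$realizable)
    expect_equal(tt_to_hex(induced_truth_table(res$witness)), code)
  }
})

test_that("witnesses are scale invariant", {
  set.seed(7)
  for (code in c(0x6, 0x2, 0x1)) {
    w <- is_realizable_single(tt_from_hex(code, 2))$witness
    for (lam in c(0.01, 3, 250)) {
      scaled <- axis_receiver(
        activation(w$activation$kind, lam * w$activation$theta_lo,
                   if (is.null(w$activation$theta_hi)) NULL
                   else lam * w$activation$theta_hi),
        lam * w$contributions, margin = w$margin)
      expect_equal(tt_to_hex(induced_truth_table(scaled)), code)
    }
  }
})

test_that("single-receiver enumeration reproduces the demonstrated capability counts", {
  expect_length(realizable_codes(enumerate_realizable(2, c("bandpass", "bandstop"))), 16L)
  expect_length(realizable_codes(enumerate_realizable(3)), 152L)
  expect_setequal(realizable_codes(enumerate_realizable(1, "highpass")), c(0, 1))
})

test_that("capability is monotone in the available kinds", {
  subsets <- list("highpass", c("highpass", "bandpass"),
                  c("highpass", "bandpass", "lowpass"), activation_kinds())
  for (n in 2:3) {
    prev <- realizable_codes(enumerate_realizable(n, subsets[[1]]))
    for (k in subsets[-1]) {
      cur <- realizable_codes(enumerate_realizable(n, k))
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("zero-state rule: highpass/bandpass gates are OFF with no inputs", {
  for (n in 2:3) {
    codes <- realizable_codes(enumerate_realizable(n, c("highpass", "bandpass")))
    zero_bit <- 2^(2^n - 1)   # output of state 00..0 sits in the MSB
    expect_true(all(bitwAnd(codes, zero_bit) == 0))
  }
})

test_that("complement duality links the threshold kinds and their inverses", {
  for (n in 2:3) {
    full <- 2^(2^n) - 1
    a <- realizable_codes(enumerate_realizable(n, c("highpass", "bandpass")))
    b <- realizable_codes(enumerate_realizable(n, c("lowpass", "bandstop")))
    expect_setequal(bitwAnd(bitwNot(a), full), b)
  }
})

test_that("block counts govern single-receiver realizability", {
  expect_equal(min_blocks(tt_from_hex(0xF, 2)), 1L)   # constant TRUE
  expect_equal(min_blocks(tt_from_hex(0x6, 2)), 3L)   # XOR: OFF-ON-OFF
  expect_gte(min_blocks(tt_from_hex(0x1B, 3)), 4L)
  # with the full kind set: realizable iff rearrangeable to <= 3 blocks
  realizable <- realizable_codes(enumerate_realizable(3))
  blocks <- vapply(0:255, function(cd) min_blocks(tt_from_hex(cd, 3)), 1L)
  expect_identical(which(blocks <= 3L) - 1L, as.integer(realizable))
})

test_that("DC states relax the block count", {
  tt <- truth_table(c(0L, NA, 1L, 0L), 2)     # DC can join either block
  expect_lte(min_blocks(tt), 3L)
  all_dc <- truth_table(rep(NA_integer_, 4), 2)
  expect_equal(min_blocks(all_dc), 1L)
})

test_that("kind-subset count table covers all 15 subsets", {
  counts <- realizable_kind_counts(2)
  expect_equal(nrow(counts), 15L)
  expect_equal(counts$n_realizable[counts$kinds == "bandpass+bandstop"], 16L)
})

test_that("enumeration CSV export includes every code of the width", {
  e <- enumerate_realizable(2, "highpass")
  path <- withr::local_tempfile(fileext = ".csv")
  write_enumeration_csv(e, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), 16L)
  expect_equal(sum(df$realizable), length(realizable_codes(e)))
})
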