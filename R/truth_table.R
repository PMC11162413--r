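#' Truth tables for spatial logic gates
#'
#' A `truth_table` is an n-input, single-output digital function. Input state
#' `i` (0-based) encodes input presence with input A as the most significant
#' bit: for three inputs, state `110` means A and B present, C absent. The
#' output at each state is `0`, `1`, or `NA` for "don't care" (DC) — a state
#' whose output is unconstrained during minimization.
#'
#' @section Hex gate codes:
#' DC-free tables are identified by a hex gate code. Bit position `p` of the
#' code holds the output of state `2^n - 1 - p`; equivalently, the code is the
#' binary string of outputs written with the all-zeros state `00...0` first
#' (most significant) down to the all-ones state `11...1` (least significant).
#' This is the convention under which a bandpass receiver reading "A AND NOT C"
#' is gate `0x0A` and "B AND C" is `0x11`; note it is the *reverse* of the
#' Wolfram cellular-automaton rule numbering, so CA rules must be bit-reversed
#' (Rule 30 is gate `0x78`, Rule 110 is `0x76`).
#'
#' @param outputs integer vector of length `2^n_inputs` over `{0, 1, NA}`
#'   (`NA` = don't care), ordered by state index (state `00...0` first).
#' @param n_inputs number of inputs (>= 1).
#' @param label optional free-text label (e.g. `"XOR"`, `"Rule 30"`).
#' @return An object of class `truth_table` with fields `n_inputs`, `outputs`
#'   and `label`.
#' @examples
#' tt_from_hex(0x6, 2, label = "XOR")
#' truth_table(c(0, 1, 1, 0), 2)
#' @seealso [tt_from_hex()], [tt_to_hex()], [tt_or()]
#' @export
truth_table <- function(outputs, n_inputs, label = NULL) {
  if (!is.numeric(n_inputs) || length(n_inputs) != 1L || n_inputs < 1 ||
      n_inputs != round(n_inputs)) {
    stop("'n_inputs' must be a single integer >= 1")
  }
  n_inputs <- as.integer(n_inputs)
  m <- 2L^n_inputs
  outputs <- as.integer(outputs)
  if (length(outputs) != m) {
    stop(sprintf("'outputs' must have exactly 2^%d = %d entries, got %d",
                 n_inputs, m, length(outputs)))
  }
  if (!all(outputs %in% c(0L, 1L) | is.na(outputs))) {
    stop("'outputs' entries must be 0, 1 or NA (don't care)")
  }
  structure(
    list(n_inputs = n_inputs, outputs = outputs,
         label = if (is.null(label)) NA_character_ else as.character(label)),
    class = "truth_table"
  )
}

#' @export
print.truth_table <- function(x, ...) {
  lab <- if (is.na(x$label)) "" else sprintf(" \"%s\"", x$label)
  hex <- if (tt_has_dc(x)) "(has DC states)" else tt_hex_string(x)
  cat(sprintf("%d-input truth table%s %s\n", x$n_inputs, lab, hex))
  out <- ifelse(is.na(x$outputs), "DC", as.character(x$outputs))
  df <- data.frame(state = state_labels(x$n_inputs), output = out)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
format.truth_table <- function(x, ...) {
  if (tt_has_dc(x)) {
    paste0(ifelse(is.na(x$outputs), "-", x$outputs), collapse = "")
  } else {
    tt_hex_string(x)
  }
}

#' @export
`==.truth_table` <- function(e1, e2) {
  e1$n_inputs == e2$n_inputs && identical(e1$outputs, e2$outputs)
}

#' Bitstring labels for the input states
#'
#' @param n_inputs number of inputs.
#' @return Character vector of `2^n_inputs` bitstrings, input A first
#'   (`"00"`, `"01"`, `"10"`, `"11"` for two inputs).
#' @export
state_labels <- function(n_inputs) {
  m <- 2L^n_inputs
  vapply(0:(m - 1L), function(i) {
    paste(rev(as.integer(intToBits(i))[seq_len(n_inputs)]), collapse = "")
  }, character(1))
}

#' Which inputs are present in each state
#'
#' @param n_inputs number of inputs.
#' @return A `2^n x n` 0/1 matrix; row `i` gives the presence of each input
#'   (column 1 = input A) in state `i - 1`.
#' @keywords internal
state_matrix <- function(n_inputs) {
  m <- 2L^n_inputs
  mat <- matrix(0L, m, n_inputs)
  for (k in seq_len(n_inputs)) {
    mat[, k] <- as.integer(bitwAnd(0:(m - 1L), 2L^(n_inputs - k)) != 0L)
  }
  colnames(mat) <- LETTERS[seq_len(n_inputs)]
  mat
}

tt_has_dc <- function(tt) anyNA(tt$outputs)

#' Build a truth table from its hex gate code
#'
#' @param code gate code: a non-negative integer or a string such as `"0x1B"`.
#' @param n_inputs number of inputs.
#' @param label optional label.
#' @return A DC-free [truth_table()] whose hex re-encoding equals `code`.
#' @examples
#' tt_from_hex("0x1B", 3)   # 2-to-1 multiplexer with C as selector
#' tt_from_hex(0x0A, 3)     # A AND NOT C
#' @export
tt_from_hex <- function(code, n_inputs, label = NULL) {
  code <- parse_gate_code(code)
  m <- 2L^as.integer(n_inputs)
  if (code < 0 || code >= 2^m) {
    stop(sprintf("gate code must lie in [0, 2^%d - 1] = [0, %.0f] for %d inputs",
                 m, 2^m - 1, n_inputs))
  }
  bits <- as.integer(intToBits(code))[seq_len(m)]   # bits[p + 1] = bit p
  outputs <- rev(bits)                              # state i at bit m - 1 - i
  truth_table(outputs, n_inputs, label = label)
}

#' Re-encode a DC-free truth table as its hex gate code
#'
#' @param tt a [truth_table()] without DC states.
#' @return The integer gate code. Use [tt_hex_string()] for the `0x..` form.
#' @export
tt_to_hex <- function(tt) {
  stopifnot(inherits(tt, "truth_table"))
  if (tt_has_dc(tt)) stop("DC states have no hex code")
  m <- length(tt$outputs)
  sum(tt$outputs * 2^((m - 1L):0L))
}

#' @rdname tt_to_hex
#' @export
tt_hex_string <- function(tt) {
  m <- length(tt$outputs)
  sprintf(paste0("0x%0", max(1L, m %/% 4L), "X"), tt_to_hex(tt))
}

parse_gate_code <- function(code) {
  if (is.character(code)) {
    code <- strtoi(sub("^0[xX]", "", code), base = 16L)
    if (is.na(code)) stop("could not parse hex gate code")
  }
  if (!is.numeric(code) || length(code) != 1L || code != round(code)) {
    stop("gate code must be a single integer or hex string")
  }
  as.numeric(code)
}

#' OR combination of truth tables
#'
#' Implicit-OR semantics of a multi-receiver device: the combined output at a
#' state is 1 iff any individual table is 1 there.
#'
#' @param tables a list of DC-free [truth_table()]s sharing `n_inputs`.
#' @return The pointwise OR as a [truth_table()].
#' @examples
#' tt_or(list(tt_from_hex(0x0A, 3), tt_from_hex(0x11, 3)))  # 0x1B
#' @export
tt_or <- function(tables) {
  if (inherits(tables, "truth_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L, all(vapply(tables, inherits, TRUE, "truth_table")))
  n <- tables[[1L]]$n_inputs
  if (!all(vapply(tables, function(t) t$n_inputs, 1L) == n)) {
    stop("all tables must share the same number of inputs")
  }
  if (any(vapply(tables, tt_has_dc, TRUE))) {
    stop("tt_or() is defined for DC-free tables only")
  }
  out <- Reduce(`|`, lapply(tables, function(t) t$outputs == 1L))
  truth_table(as.integer(out), n)
}

#' Enumerate every DC-free truth table
#'
#' @param n_inputs number of inputs; capped at 4 to guard against the
#'   double-exponential blow-up (`2^(2^n)` tables).
#' @return A list of all `2^(2^n)` distinct [truth_table()]s, in gate-code
#'   order.
#' @examples
#' length(enumerate_all_gates(2))  # 16
#' @export
enumerate_all_gates <- function(n_inputs) {
  if (n_inputs > 4) {
    stop("enumerate_all_gates() supports at most 4 inputs (2^(2^n) tables)")
  }
  lapply(0:(2^(2^n_inputs) - 1), tt_from_hex, n_inputs = n_inputs)
}

#' Gate score: worst-case ON/OFF separation
#'
#' The score of a measured (or simulated) gate is the least fluorescent ON
#' state divided by the most fluorescent OFF state, both expressed as fold
#' changes. A score above 1 means the gate separates its ON states from its
#' OFF states.
#'
#' @param on_values positive fold changes of the function-ON states.
#' @param off_values positive fold changes of the function-OFF states.
#' @return `min(on_values) / max(off_values)`. A constant-ON gate (no OFF
#'   state) scores `Inf`; a constant-OFF gate (no ON state) scores 0 with a
#'   warning. Batch scoring over catalogs therefore never aborts.
#' @examples
#' gate_score(c(4, 6), c(1, 2))  # 2
#' @export
gate_score <- function(on_values, off_values) {
  on_values <- as.numeric(on_values)
  off_values <- as.numeric(off_values)
  if (length(on_values) == 0L && length(off_values) == 0L) {
    stop("at least one of 'on_values'/'off_values' must be non-empty")
  }
  if (any(c(on_values, off_values) <= 0) || anyNA(c(on_values, off_values))) {
    stop("fold changes must be positive")
  }
  if (length(off_values) == 0L) return(Inf)
  if (length(on_values) == 0L) {
    warning("constant-OFF gate: no ON state, score is 0")
    return(0)
  }
  min(on_values) / max(off_values)
}

#' Read and write truth-table CSV files
#'
#' The on-disk format has a header `state,output`: `state` is the input
#' bitstring (input A first) and `output` is `0`, `1` or `DC`.
#'
#' @param path file path.
#' @param label optional label for the table read.
#' @return `read_truth_table_csv()` returns a [truth_table()];
#'   `write_truth_table_csv()` invisibly returns `path`.
#' @export
read_truth_table_csv <- function(path, label = NULL) {
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!all(c("state", "output") %in% names(df))) {
    stop("truth-table CSV needs columns 'state' and 'output'")
  }
  n <- unique(nchar(df$state))
  if (length(n) != 1L) stop("all states must be bitstrings of equal length")
  idx <- strtoi(df$state, base = 2L)
  if (anyNA(idx) || anyDuplicated(idx) || length(idx) != 2L^n) {
    stop(sprintf("need each of the %d states exactly once", 2L^n))
  }
  out <- rep(NA_integer_, 2L^n)
  val <- toupper(df$output)
  if (!all(val %in% c("0", "1", "DC"))) stop("outputs must be 0, 1 or DC")
  out[idx + 1L] <- c("0" = 0L, "1" = 1L, "DC" = NA_integer_)[val]
  truth_table(out, n, label = label)
}

#' @rdname read_truth_table_csv
#' @param tt a [truth_table()].
#' @export
write_truth_table_csv <- function(tt, path) {
  stopifnot(inherits(tt, "truth_table"))
  df <- data.frame(
    state = state_labels(tt$n_inputs),
    output = ifelse(is.na(tt$outputs), "DC", as.character(tt$outputs))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
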