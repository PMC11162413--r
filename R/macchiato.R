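## The Macchiato algorithm: minimal receiver-set decomposition of a truth
## table under implicit-OR semantics. Internally each candidate gate is a
## bitmask over input states (bit i = output at state i), so cover tests are
## single bitwAnd/bitwOr operations.

tt_onmask <- function(tt) {
  on <- which(!is.na(tt$outputs) & tt$outputs == 1L) - 1L
  if (!length(on)) 0 else sum(2^on)
}

tt_offmask <- function(tt) {
  off <- which(!is.na(tt$outputs) & tt$outputs == 0L) - 1L
  if (!length(off)) 0 else sum(2^off)
}

# hex gate code -> ON-state bitmask (bit p of code is state 2^n - 1 - p)
code_to_onmask <- function(code, m) {
  bits <- as.integer(intToBits(code))[seq_len(m)]
  on <- which(bits == 1L)
  if (!length(on)) 0 else sum(2^(m - on))
}

#' Minimal receiver-set decomposition (the Macchiato algorithm)
#'
#' Decomposes a truth table into the smallest set of single-receiver gates
#' whose implicit OR realizes it: every target-OFF state is OFF in every
#' receiver (hard constraint), every target-ON state is ON in at least one,
#' and DC states are free. Candidates are the realizable gates of
#' [enumerate_realizable()] restricted to those OFF wherever the target is
#' OFF; minimization is exact set cover (depth-first search with iterative
#' deepening) or a coverage-maximizing greedy heuristic.
#'
#' Ties are broken deterministically: candidates are ranked by threshold count
#' (single-threshold receivers first) then by gate code, and the exact search
#' returns the first minimal cover in that lexicographic order.
#'
#' @param tt target [truth_table()] (<= 4 inputs; DC allowed).
#' @param kinds available activation kinds.
#' @param exact if `TRUE` (default) the receiver count is globally minimal;
#'   if `FALSE` a greedy set cover is used.
#' @return An object of class `macchiato_design`: the target, the list of
#'   witness [axis_receiver()]s, their induced tables and codes, and the OR
#'   mode (`"implicit"`).
#' @examples
#' d <- macchiato_minimize(tt_from_hex(0x1B, 3), c("highpass", "bandpass"))
#' length(d$receivers)  # 2
#' @export
macchiato_minimize <- function(tt, kinds = activation_kinds(), exact = TRUE) {
  stopifnot(inherits(tt, "truth_table"))
  if (tt$n_inputs > 4) stop("macchiato_minimize() supports at most 4 inputs")
  kinds <- check_kinds(kinds)
  m <- 2L^tt$n_inputs
  target_on <- tt_onmask(tt)
  target_off <- tt_offmask(tt)

  if (target_on == 0) {
    return(new_design(tt, list(), list(), numeric(0), kinds))
  }

  cat_enum <- enumerate_realizable(tt$n_inputs, kinds)
  witnesses <- attr(cat_enum, "witnesses")
  onmasks <- vapply(cat_enum$code, code_to_onmask, 0, m = m)
  keep <- bitwAnd(onmasks, target_off) == 0 & bitwAnd(onmasks, target_on) != 0
  cand <- data.frame(code = cat_enum$code[keep], onmask = onmasks[keep],
                     kind = cat_enum$kind[keep])
  cand$nth <- n_thresholds(cand$kind)
  cand <- cand[order(cand$nth, cand$code), , drop = FALSE]

  coverable <- if (nrow(cand)) Reduce(bitwOr, cand$onmask) else 0
  uncoverable <- bitwAnd(target_on, bitwNot(coverable))
  if (uncoverable != 0) {
    states <- state_labels(tt$n_inputs)[which(bitwAnd(2^(0:(m - 1)), uncoverable) != 0)]
    stop(sprintf(
      "target is infeasible with kinds {%s}: no realizable receiver can be ON at state(s) %s while OFF at every target-OFF state",
      paste(kinds, collapse = ", "), paste(states, collapse = ", ")))
  }

  sel <- if (exact) cover_exact(target_on, cand, m) else cover_greedy(target_on, cand)
  receivers <- lapply(cand$code[sel], function(code) witnesses[[as.character(code)]])
  induced <- lapply(receivers, induced_truth_table)
  new_design(tt, receivers, induced, cand$code[sel], kinds)
}

new_design <- function(target, receivers, induced, codes, kinds,
                       or_mode = "implicit") {
  structure(
    list(target = target, receivers = receivers, induced = induced,
         codes = as.numeric(codes), kinds = kinds, or_mode = or_mode),
    class = "macchiato_design"
  )
}

# exact minimum cover: iterative deepening over cover size, DFS branching on
# the lowest uncovered state; candidate order fixes the tie-break
cover_exact <- function(target_on, cand, m) {
  state_bits <- 2^(0:(m - 1))
  dfs <- function(covered, chosen, depth) {
    if (bitwAnd(target_on, bitwNot(covered)) == 0) return(chosen)
    if (depth == 0L) return(NULL)
    uncovered <- bitwAnd(target_on, bitwNot(covered))
    pivot <- state_bits[which(bitwAnd(state_bits, uncovered) != 0)[1L]]
    for (i in seq_len(nrow(cand))) {
      if (i %in% chosen) next
      if (bitwAnd(cand$onmask[i], pivot) == 0) next
      res <- dfs(bitwOr(covered, cand$onmask[i]), c(chosen, i), depth - 1L)
      if (!is.null(res)) return(res)
    }
    NULL
  }
  for (k in 1:max(1L, m)) {
    res <- dfs(0, integer(0), k)
    if (!is.null(res)) return(res)
  }
  stop("internal error: cover search failed on a feasible target")
}

cover_greedy <- function(target_on, cand) {
  chosen <- integer(0)
  covered <- 0
  while (bitwAnd(target_on, bitwNot(covered)) != 0) {
    gain <- popcount(bitwAnd(bitwAnd(cand$onmask, target_on), bitwNot(covered)))
    gain[chosen] <- -1
    best <- which(gain == max(gain))[1L]  # cand is pre-sorted for tie-breaks
    chosen <- c(chosen, best)
    covered <- bitwOr(covered, cand$onmask[best])
  }
  chosen
}

popcount <- function(x) {
  if (!length(x)) return(integer(0))
  colSums(matrix(as.integer(intToBits(as.integer(x))), 32L))
}

#' @export
print.macchiato_design <- function(x, ...) {
  tgt <- if (tt_has_dc(x$target)) format(x$target) else tt_hex_string(x$target)
  cat(sprintf("Macchiato design for %d-input gate %s: %d receiver(s), %s OR\n",
              x$target$n_inputs, tgt, length(x$receivers), x$or_mode))
  for (i in seq_along(x$receivers)) {
    cat(sprintf("  [%d] %s -> %s\n", i,
                format_activation(x$receivers[[i]]$activation),
                tt_hex_string(x$induced[[i]])))
  }
  invisible(x)
}

#' @export
summary.macchiato_design <- function(object, ...) {
  v <- validate_design(object)
  print(object)
  cat(if (v$valid) "design validates: OR of receivers matches the target\n"
      else "design INVALID: see validate_design() report\n")
  invisible(v)
}

#' Build a design from chosen sub-gate codes
#'
#' Constructs a receiver design from an explicit list of single-receiver gate
#' codes (e.g. a decomposition chosen for device-level robustness rather than
#' minimality: a witness receiver that is realizable with free thresholds can
#' demand threshold ratios a fixed physical strain cannot deliver, in which
#' case a larger receiver set is the practical build). Each code must be
#' realizable with the available kinds, and the OR of the codes must match
#' the target on non-DC states.
#'
#' @param tt target [truth_table()].
#' @param codes vector of gate codes (integers or `"0x.."` strings).
#' @param kinds available activation kinds.
#' @return A `macchiato_design`.
#' @examples
#' design_from_codes(tt_from_hex(0x1B, 3), c("0x0A", "0x11"),
#'                   c("highpass", "bandpass"))
#' @export
design_from_codes <- function(tt, codes, kinds = activation_kinds()) {
  stopifnot(inherits(tt, "truth_table"))
  kinds <- check_kinds(kinds)
  codes <- vapply(codes, parse_gate_code, 0)
  cat_enum <- enumerate_realizable(tt$n_inputs, kinds)
  witnesses <- attr(cat_enum, "witnesses")
  missing <- setdiff(codes, cat_enum$code)
  if (length(missing)) {
    stop(sprintf("code(s) %s are not single-receiver realizable with {%s}",
                 paste(sprintf("0x%X", missing), collapse = ", "),
                 paste(kinds, collapse = ", ")))
  }
  receivers <- lapply(codes, function(code) witnesses[[as.character(code)]])
  induced <- lapply(receivers, induced_truth_table)
  design <- new_design(tt, receivers, induced, codes, kinds)
  v <- validate_design(design)
  if (!v$valid) {
    stop("the OR of the given codes does not match the target truth table")
  }
  design
}

#' Validate a receiver design against its target
#'
#' Checks the implicit-OR semantics: the design is valid iff the OR of the
#' receivers' induced tables matches the target on every non-DC state.
#' Mismatches are reported, not raised.
#'
#' @param design a `macchiato_design` (receivers may also be supplied as a
#'   list of [axis_receiver()]s via `receivers`).
#' @param target optional target [truth_table()] overriding `design$target`.
#' @return A list of class `macchiato_validation`: `valid` (logical) and
#'   `report`, a per-state data frame with each receiver's output, their OR
#'   and the target.
#' @export
validate_design <- function(design, target = NULL) {
  stopifnot(inherits(design, "macchiato_design"))
  if (is.null(target)) target <- design$target
  n <- target$n_inputs
  outs <- lapply(design$induced, function(t) {
    if (t$n_inputs != n) stop("receiver and target input counts differ")
    t$outputs
  })
  or_out <- if (length(outs)) as.integer(Reduce(`|`, lapply(outs, `==`, 1L)))
            else rep(0L, 2L^n)
  rpt <- data.frame(state = state_labels(n))
  for (i in seq_along(outs)) rpt[[sprintf("receiver_%d", i)]] <- outs[[i]]
  rpt$or <- or_out
  rpt$target <- ifelse(is.na(target$outputs), "DC", as.character(target$outputs))
  care <- !is.na(target$outputs)
  rpt$match <- !care | (or_out == target$outputs & care) | !care
  rpt$match[care] <- or_out[care] == target$outputs[care]
  structure(list(valid = all(rpt$match), report = rpt),
            class = "macchiato_validation")
}

#' @export
print.macchiato_validation <- function(x, ...) {
  cat(if (x$valid) "valid design\n" else "INVALID design\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Explicit OR output layer
#'
#' Augments a design with a second signaling layer: every first-layer receiver
#' produces a distinct diffusible channel and one highpass receiver reading
#' that channel activates if any first-layer receiver is ON. Purely
#' structural — no new feasibility computation — and it costs one extra
#' signaling molecule compared with the implicit-OR read-out.
#'
#' @param design a `macchiato_design`.
#' @return A list of class `or_layer` describing the two-layer device:
#'   `first_layer` (the receivers), `or_node`, `n_nodes`, `redundant` (`TRUE`
#'   when 0 or 1 receivers make the OR layer unnecessary) and
#'   `extra_molecule` (`TRUE` for non-empty designs).
#' @export
explicit_or_layer <- function(design) {
  stopifnot(inherits(design, "macchiato_design"))
  k <- length(design$receivers)
  if (k == 0L) {
    return(structure(list(first_layer = list(), or_node = NULL, n_nodes = 0L,
                          redundant = TRUE, extra_molecule = FALSE),
                     class = "or_layer"))
  }
  structure(
    list(
      first_layer = design$receivers,
      or_node = list(kind = "highpass", channel = "or-layer signal",
                     reads = sprintf("receiver_%d", seq_len(k))),
      n_nodes = k + 1L,
      redundant = k == 1L,
      extra_molecule = TRUE
    ),
    class = "or_layer"
  )
}

#' @export
print.or_layer <- function(x, ...) {
  if (x$n_nodes == 0L) {
    cat("empty design: no OR layer\n")
  } else {
    cat(sprintf("two-level device: %d first-layer receiver(s) + 1 highpass OR node%s\n",
                x$n_nodes - 1L,
                if (x$redundant) " (redundant for a single receiver)" else ""))
    cat("requires one extra signaling molecule for the OR channel\n")
  }
  invisible(x)
}

#' Read and write design JSON
#'
#' Serializes a `macchiato_design` as JSON: target hex code, input count, OR
#' mode and per-receiver kind, thresholds, contributions and induced code.
#'
#' @param design a `macchiato_design`.
#' @param path file path.
#' @export
write_design_json <- function(design, path) {
  stopifnot(inherits(design, "macchiato_design"))
  obj <- list(
    target_hex = if (tt_has_dc(design$target)) NA else tt_hex_string(design$target),
    n_inputs = design$target$n_inputs,
    outputs = ifelse(is.na(design$target$outputs), "DC",
                     as.character(design$target$outputs)),
    or_mode = design$or_mode,
    kinds = design$kinds,
    receivers = lapply(seq_along(design$receivers), function(i) {
      r <- design$receivers[[i]]
      list(kind = r$activation$kind,
           theta_lo = r$activation$theta_lo,
           theta_hi = r$activation$theta_hi,
           contributions = r$contributions,
           margin = r$margin,
           induced_hex = tt_hex_string(design$induced[[i]]))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_design_json
#' @export
read_design_json <- function(path) {
  obj <- jsonlite::read_json(path)
  outs <- vapply(obj$outputs, as.character, "")
  target <- truth_table(ifelse(outs == "DC", NA_integer_, as.integer(outs)),
                        obj$n_inputs)
  receivers <- lapply(obj$receivers, function(r) {
    axis_receiver(
      activation(r$kind, r$theta_lo,
                 if (is.null(r$theta_hi)) NULL else r$theta_hi),
      as.numeric(unlist(r$contributions)),
      margin = r$margin
    )
  })
  induced <- lapply(receivers, induced_truth_table)
  new_design(target, receivers, induced,
             vapply(induced, tt_to_hex, 0),
             unlist(obj$kinds), or_mode = obj$or_mode)
}
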