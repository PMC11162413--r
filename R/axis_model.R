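#' Activation functions: threshold responses on the signal axis
#'
#' A receiver strain converts the local signal concentration into a digital
#' output through one of four threshold response shapes: `highpass` (ON above
#' a threshold), `lowpass` (ON below), `bandpass` (ON between two thresholds)
#' and `bandstop` (OFF between two thresholds). Thresholds are strictly
#' positive, so at zero concentration highpass/bandpass are OFF and
#' lowpass/bandstop are ON — the property that lets a lowpass receiver compute
#' NOR in the absence of both inputs.
#'
#' @param kind one of `"highpass"`, `"lowpass"`, `"bandpass"`, `"bandstop"`.
#' @param theta_lo positive threshold (signal-concentration units).
#' @param theta_hi upper threshold, required (and `> theta_lo`) for the
#'   two-threshold kinds.
#' @return An object of class `activation`.
#' @examples
#' activation("bandpass", 0.5, 1.5)
#' @export
activation <- function(kind, theta_lo, theta_hi = NULL) {
  kind <- match.arg(kind, activation_kinds())
  if (!is.numeric(theta_lo) || length(theta_lo) != 1L || theta_lo <= 0) {
    stop("'theta_lo' must be a single positive number")
  }
  two <- kind %in% c("bandpass", "bandstop")
  if (two) {
    if (is.null(theta_hi) || !is.numeric(theta_hi) || length(theta_hi) != 1L) {
      stop(sprintf("'%s' needs an upper threshold 'theta_hi'", kind))
    }
    if (theta_hi <= theta_lo) stop("'theta_hi' must exceed 'theta_lo'")
  } else if (!is.null(theta_hi)) {
    stop(sprintf("'%s' takes a single threshold", kind))
  }
  structure(
    list(kind = kind, theta_lo = as.numeric(theta_lo),
         theta_hi = if (two) as.numeric(theta_hi) else NULL),
    class = "activation"
  )
}

#' @export
print.activation <- function(x, ...) {
  th <- if (is.null(x$theta_hi)) sprintf("theta = %g", x$theta_lo)
        else sprintf("thetas = (%g, %g)", x$theta_lo, x$theta_hi)
  cat(sprintf("%s activation, %s\n", x$kind, th))
  invisible(x)
}

#' @rdname activation
#' @export
activation_kinds <- function() c("highpass", "lowpass", "bandpass", "bandstop")

n_thresholds <- function(kind) ifelse(kind %in% c("bandpass", "bandstop"), 2L, 1L)

#' Apply an activation function to signal concentrations
#'
#' Inequalities at the thresholds are strict in both directions; concentrations
#' exactly at a threshold are rejected by [induced_truth_table()] through its
#' margin check rather than silently assigned.
#'
#' @param act an [activation()].
#' @param value non-negative concentration(s).
#' @return Integer 0/1 vector of digital outputs.
#' @examples
#' apply_activation(activation("highpass", 1), c(0.5, 2))  # 0 1
#' @export
apply_activation <- function(act, value) {
  stopifnot(inherits(act, "activation"))
  value <- as.numeric(value)
  if (any(value < 0) || anyNA(value)) stop("concentrations must be non-negative")
  on <- switch(act$kind,
    highpass = value > act$theta_lo,
    lowpass  = value < act$theta_lo,
    bandpass = value > act$theta_lo & value < act$theta_hi,
    bandstop = !(value > act$theta_lo & value < act$theta_hi)
  )
  as.integer(on)
}

#' Signal concentration seen by a receiver in a given input state
#'
#' Every present input adds its per-input contribution to the concentration at
#' the receiver; overlapping diffusion fields are additive, so the state
#' concentration is the subset sum of the contributions of the present inputs.
#'
#' @param contributions non-negative per-input contribution vector
#'   (signal-concentration units), input A first.
#' @param state input-state bitstring (e.g. `"101"`) or 0/1 vector.
#' @return The summed concentration; the all-zero state maps to 0.
#' @examples
#' state_concentration(c(1, 2, 4), "101")  # 5
#' @export
state_concentration <- function(contributions, state) {
  contributions <- check_contributions(contributions)
  if (is.character(state)) state <- as.integer(strsplit(state, "")[[1L]])
  state <- as.integer(state)
  if (length(state) != length(contributions)) {
    stop(sprintf("state has %d bits but there are %d contributions",
                 length(state), length(contributions)))
  }
  if (!all(state %in% c(0L, 1L))) stop("state must be a 0/1 bitstring")
  sum(contributions[state == 1L])
}

check_contributions <- function(contributions) {
  contributions <- as.numeric(contributions)
  if (length(contributions) < 1L || anyNA(contributions) || any(contributions < 0)) {
    stop("'contributions' must be a non-empty vector of non-negative numbers")
  }
  contributions
}

# concentration of every input state, in state-index order
all_state_concentrations <- function(contributions) {
  as.numeric(state_matrix(length(contributions)) %*% contributions)
}

#' Receiver specification on the signal-concentration axis
#'
#' An abstract receiver: an activation function plus per-input contribution
#' values. Placing inputs and receiver in space fixes the contribution each
#' input makes to the concentration at the receiver; the activation then
#' partitions the ordered input states into ON and OFF, inducing a truth
#' table. The `margin` is the minimum separation required between any state
#' concentration and any threshold, after normalizing the largest subset sum
#' to 1, so that the induced table is robust to small perturbations.
#'
#' @param act an [activation()].
#' @param contributions non-negative per-input contributions.
#' @param margin minimum normalized state-to-threshold separation.
#' @return An object of class `axis_receiver`.
#' @examples
#' r <- axis_receiver(activation("bandpass", 0.5, 1.5), c(1, 1))
#' induced_truth_table(r)  # XOR
#' @export
axis_receiver <- function(act, contributions, margin = 1e-6) {
  stopifnot(inherits(act, "activation"))
  contributions <- check_contributions(contributions)
  if (!is.numeric(margin) || margin <= 0) stop("'margin' must be positive")
  structure(
    list(activation = act, contributions = contributions,
         margin = as.numeric(margin)),
    class = "axis_receiver"
  )
}

#' @export
print.axis_receiver <- function(x, ...) {
  cat(sprintf("axis receiver: %s, contributions (%s)\n",
              format_activation(x$activation),
              paste(signif(x$contributions, 4), collapse = ", ")))
  invisible(x)
}

format_activation <- function(act) {
  if (is.null(act$theta_hi)) sprintf("%s theta=%.4g", act$kind, act$theta_lo)
  else sprintf("%s thetas=(%.4g, %.4g)", act$kind, act$theta_lo, act$theta_hi)
}

#' Truth table induced by an axis receiver
#'
#' Evaluates the activation at every state concentration. States whose
#' concentration lies within `margin` of a threshold (after normalizing the
#' largest subset sum to 1) make the receiver degenerate and raise an error naming
#' the offending state.
#'
#' @param spec an [axis_receiver()].
#' @return A DC-free [truth_table()].
#' @export
induced_truth_table <- function(spec) {
  stopifnot(inherits(spec, "axis_receiver"))
  conc <- all_state_concentrations(spec$contributions)
  scale <- max(conc, 1e-300)
  thetas <- c(spec$activation$theta_lo, spec$activation$theta_hi)
  for (th in thetas) {
    d <- abs(conc - th) / scale
    if (any(d < spec$margin)) {
      bad <- state_labels(length(spec$contributions))[which.min(d)]
      stop(sprintf(
        "degenerate receiver: state %s lies within margin %g of threshold %g",
        bad, spec$margin, th))
    }
  }
  truth_table(apply_activation(spec$activation, conc),
              length(spec$contributions))
}

## ---- admissible orderings of the subset sums ------------------------------

.macchiato_cache <- new.env(parent = emptyenv())

# Feasibility of { D %*% c >= 1, c >= 0 }: returns a witness c or NULL.
# Solved as the minimum-norm point of the polyhedron (quadprog); the system is
# homogeneous in c, so ">= 1" slack is equivalent to strict positivity.
gap_feasible <- function(D, n) {
  D <- D[rowSums(D != 0) > 0, , drop = FALSE]
  if (nrow(D) == 0L) return(rep(1, n))
  Amat <- t(rbind(D, diag(n)))
  bvec <- c(rep(1, nrow(D)), rep(0, n))
  out <- tryCatch(
    quadprog::solve.QP(diag(n), rep(0, n), Amat, bvec),
    error = function(e) NULL
  )
  if (is.null(out)) NULL else pmax(out$solution, 0)
}

#' Admissible strict orderings of the state concentrations
#'
#' Enumerates every strict total order of the `2^n` subset sums that is
#' achievable by some non-negative contribution vector, established by linear
#' feasibility (with unit slack between consecutive sums; the constraint
#' system is homogeneous, so the result is scale-free). Subset monotonicity
#' forces the all-zero state to the bottom and the all-one state to the top of
#' every order; the search enumerates linear extensions of the subset lattice
#' and prunes with feasibility checks.
#'
#' @param n_inputs number of inputs (<= 4).
#' @return A list of orders; each order is an integer vector of state indices
#'   (0-based) from lowest to highest concentration, with a `witness`
#'   attribute holding a feasible contribution vector. There are 2 admissible
#'   orders for two inputs and 12 for three.
#' @export
admissible_orders <- function(n_inputs) {
  if (n_inputs > 4) stop("admissible_orders() supports at most 4 inputs")
  key <- as.character(n_inputs)
  if (!is.null(.macchiato_cache[[key]])) return(.macchiato_cache[[key]])
  S <- state_matrix(n_inputs)
  m <- 2L^n_inputs
  res <- list()
  rec <- function(placed, remaining, witness) {
    if (!length(remaining)) {
      ord <- placed - 1L
      attr(ord, "witness") <- witness
      res[[length(res) + 1L]] <<- ord
      return(invisible())
    }
    for (x in remaining) {
      # x is eligible only if no unplaced state is a strict subset of it
      xb <- S[x, ]
      eligible <- TRUE
      for (r in remaining) {
        if (r != x && all(S[r, ] <= xb) && any(S[r, ] < xb)) {
          eligible <- FALSE
          break
        }
      }
      if (!eligible) next
      cand <- c(placed, x)
      w <- witness
      if (length(cand) >= 3L) {
        D <- S[cand[-1L], , drop = FALSE] - S[cand[-length(cand)], , drop = FALSE]
        w <- gap_feasible(D, n_inputs)
        if (is.null(w)) next
      }
      rec(cand, setdiff(remaining, x), w)
    }
  }
  rec(integer(0), seq_len(m), rep(1, n_inputs))
  .macchiato_cache[[key]] <- res
  res
}

## ---- realizability --------------------------------------------------------

# ON-position sets along an order of length m that an activation kind can cut
# out; returned as a list of integer position vectors (possibly empty).
# Position 1 is the axis minimum (always the all-zero state), which a positive
# lower threshold keeps OFF for highpass/bandpass and ON for lowpass/bandstop.
kind_patterns <- function(kind, m) {
  runs <- list(integer(0))
  for (i in 2:m) for (j in i:m) runs[[length(runs) + 1L]] <- i:j
  switch(kind,
    highpass = lapply(0:(m - 1L), function(k) if (k == 0L) integer(0) else (m - k + 1L):m),
    lowpass  = lapply(1:m, function(k) 1:k),
    bandpass = runs,
    bandstop = lapply(runs, function(r) setdiff(1:m, r))
  )
}

# hex code of the table that is ON exactly at `on_pos` (positions along `ord`)
code_from_pattern <- function(ord, on_pos) {
  m <- length(ord)
  out <- integer(m)
  if (length(on_pos)) out[ord[on_pos] + 1L] <- 1L
  sum(out * 2^((m - 1L):0L))
}

# Build a concrete axis_receiver witnessing a pattern on an order.
# `cvec` satisfies consecutive gaps >= 1 along the order; thresholds are set
# mid-gap, then everything is normalized so the largest subset sum is 1.
witness_receiver <- function(ord, on_pos, kind, cvec) {
  conc <- all_state_concentrations(cvec)
  s <- conc[ord + 1L]                       # sorted concentrations
  m <- length(s)
  top <- s[m]
  mid <- function(i) (s[i] + s[i + 1L]) / 2 # between positions i and i+1
  if (kind %in% c("highpass", "lowpass")) {
    k <- if (kind == "highpass") {
      if (length(on_pos)) min(on_pos) - 1L else m    # theta above position k
    } else {
      if (length(on_pos) < m) max(on_pos) else m     # ON prefix of length k
    }
    th <- if (k >= m) top + 1 else mid(k)
    act <- activation(kind, th)
  } else {
    off_run <- if (kind == "bandpass") on_pos else setdiff(1:m, on_pos)
    if (!length(off_run)) {                 # empty band: park it above the top
      act <- activation(kind, top + 1, top + 2)
    } else {
      lo <- mid(min(off_run) - 1L)
      hi <- if (max(off_run) >= m) top + 1 else mid(max(off_run))
      act <- activation(kind, lo, hi)
    }
  }
  scale <- max(conc, 1e-300)
  cvec_n <- cvec / scale
  act_n <- activation(act$kind, act$theta_lo / scale,
                      if (is.null(act$theta_hi)) NULL else act$theta_hi / scale)
  margin <- min(abs(outer(conc / scale, c(act_n$theta_lo, act_n$theta_hi), "-")))
  axis_receiver(act_n, cvec_n, margin = max(min(margin * 0.99, 1e-2), 1e-9))
}

check_kinds <- function(kinds) {
  kinds <- match.arg(kinds, activation_kinds(), several.ok = TRUE)
  # canonical order, single-threshold kinds first (cheaper hardware)
  intersect(c("highpass", "lowpass", "bandpass", "bandstop"), kinds)
}

#' Enumerate gates realizable by a single receiver
#'
#' Searches every admissible strict ordering of the subset sums combined with
#' every activation pattern of the available kinds, and collects the distinct
#' induced truth tables. With bandpass and bandstop available all 16 two-input
#' gates are realizable; with the full kind set 152 of the 256 three-input
#' gates are.
#'
#' @param n_inputs number of inputs (<= 4).
#' @param kinds available activation kinds (subset of [activation_kinds()]).
#' @return An object of class `gate_enumeration`: a data frame with one row
#'   per realizable gate (`code`, `hex`, `kind`, `blocks`, witness
#'   contributions and thresholds) and attributes `n_inputs`, `kinds` and
#'   `codes` (the sorted integer code set). Deterministic; per gate the first
#'   witness found is kept, preferring single-threshold kinds.
#' @examples
#' e <- enumerate_realizable(2, c("bandpass", "bandstop"))
#' length(realizable_codes(e))  # 16
#' @export
enumerate_realizable <- function(n_inputs, kinds = activation_kinds()) {
  if (n_inputs > 4) stop("enumerate_realizable() supports at most 4 inputs")
  kinds <- check_kinds(kinds)
  cache_key <- paste0("enum_", n_inputs, "_", paste(kinds, collapse = "+"))
  if (!is.null(.macchiato_cache[[cache_key]])) {
    return(.macchiato_cache[[cache_key]])
  }
  orders <- admissible_orders(n_inputs)
  m <- 2L^n_inputs
  seen <- new.env(parent = emptyenv())
  witnesses <- list()
  rows <- list()
  for (kind in kinds) {
    patterns <- kind_patterns(kind, m)
    for (ord in orders) {
      cvec <- attr(ord, "witness")
      for (on_pos in patterns) {
        code <- code_from_pattern(ord, on_pos)
        key <- as.character(code)
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        rec <- witness_receiver(ord, on_pos, kind, cvec)
        witnesses[[key]] <- rec
        outs <- integer(m); if (length(on_pos)) outs[on_pos] <- 1L
        rows[[length(rows) + 1L]] <- data.frame(
          code = code,
          hex = sprintf(paste0("0x%0", max(1L, m %/% 4L), "X"), code),
          kind = kind,
          blocks = count_runs(outs),
          witness_contributions = paste(signif(rec$contributions, 6), collapse = ";"),
          witness_theta_lo = rec$activation$theta_lo,
          witness_theta_hi = if (is.null(rec$activation$theta_hi)) NA_real_
                             else rec$activation$theta_hi,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$code), , drop = FALSE]
  rownames(df) <- NULL
  out <- structure(df, class = c("gate_enumeration", "data.frame"),
                   n_inputs = n_inputs, kinds = kinds, codes = df$code,
                   witnesses = witnesses)
  .macchiato_cache[[cache_key]] <- out
  out
}

#' @rdname enumerate_realizable
#' @param x a `gate_enumeration`.
#' @export
realizable_codes <- function(x) attr(x, "codes")

#' @export
print.gate_enumeration <- function(x, ...) {
  cat(sprintf("%d of %.0f %d-input gates realizable with {%s}\n",
              nrow(x), 2^(2^attr(x, "n_inputs")), attr(x, "n_inputs"),
              paste(attr(x, "kinds"), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Export an enumeration as CSV
#'
#' Columns: `hex_code,label,realizable,kinds,blocks,witness_contributions,`
#' `witness_thresholds` for every gate code of the input width, realizable or
#' not.
#'
#' @param x a `gate_enumeration`.
#' @param path output file.
#' @export
write_enumeration_csv <- function(x, path) {
  stopifnot(inherits(x, "gate_enumeration"))
  n <- attr(x, "n_inputs")
  m <- 2L^n
  all_codes <- 0:(2^m - 1)
  i <- match(all_codes, x$code)
  df <- data.frame(
    hex_code = sprintf(paste0("0x%0", max(1L, m %/% 4L), "X"), all_codes),
    label = "",
    realizable = !is.na(i),
    kinds = ifelse(is.na(i), "", x$kind[i]),
    blocks = ifelse(is.na(i), NA_integer_, x$blocks[i]),
    witness_contributions = ifelse(is.na(i), "", x$witness_contributions[i]),
    witness_thresholds = ifelse(
      is.na(i), "",
      ifelse(is.na(x$witness_theta_hi[i]),
             sprintf("%g", x$witness_theta_lo[i]),
             sprintf("%g;%g", x$witness_theta_lo[i], x$witness_theta_hi[i]))
    )
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

count_runs <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(1L)
  1L + sum(diff(v) != 0L)
}

# does the ordered output vector (0/1/NA) fit the kind's pattern?
# returns the ON-position set of a fitting pattern, or NULL
fit_pattern <- function(outs_ord, kind) {
  m <- length(outs_ord)
  on <- which(!is.na(outs_ord) & outs_ord == 1L)
  off <- which(!is.na(outs_ord) & outs_ord == 0L)
  contiguous_on <- function(exclude_min) {
    if (!length(on)) return(integer(0))
    run <- min(on):max(on)
    if (any(run %in% off)) return(NULL)
    if (exclude_min && 1L %in% run) return(NULL)
    run
  }
  switch(kind,
    highpass = {
      if (!length(on)) return(integer(0))
      run <- min(on):m
      if (any(run %in% off) || 1L %in% run) NULL else run
    },
    lowpass = {
      # ON must be a non-empty prefix: the minimum (zero state) is always ON
      if (1L %in% off) return(NULL)
      if (length(on) && length(off) && max(on) > min(off)) return(NULL)
      1:max(c(on, 1L))
    },
    bandpass = contiguous_on(TRUE),
    bandstop = {
      # OFF states must form a contiguous run excluding the minimum
      if (!length(off)) return(1:m)
      run <- min(off):max(off)
      if (any(run %in% on) || 1L %in% run) return(NULL)
      setdiff(1:m, run)
    }
  )
}

#' Single-receiver realizability of a truth table
#'
#' Searches the admissible orderings of the state concentrations combined with
#' each available activation kind for a witness receiver inducing the queried
#' table. DC states are unconstrained (they may fall on either side of a
#' threshold). The verdict is independent of the margin choice: feasibility is
#' established with open slack, so any sufficiently small margin admits the
#' same witness (scale freedom).
#'
#' @param tt a [truth_table()] with at most 4 inputs (DC allowed).
#' @param kinds available activation kinds.
#' @return A list of class `realizability`: `realizable` (logical), `witness`
#'   (an [axis_receiver()] or `NULL`) and `blocks` (block count of the witness
#'   ordering, `NA` if unrealizable).
#' @examples
#' is_realizable_single(tt_from_hex(0x6, 2), "bandpass")$realizable  # XOR: TRUE
#' @export
is_realizable_single <- function(tt, kinds = activation_kinds()) {
  stopifnot(inherits(tt, "truth_table"))
  if (tt$n_inputs > 4) stop("is_realizable_single() supports at most 4 inputs")
  kinds <- check_kinds(kinds)
  orders <- admissible_orders(tt$n_inputs)
  for (kind in kinds) {
    for (ord in orders) {
      outs_ord <- tt$outputs[ord + 1L]
      on_pos <- fit_pattern(outs_ord, kind)
      if (!is.null(on_pos)) {
        rec <- witness_receiver(ord, on_pos, kind, attr(ord, "witness"))
        pat <- integer(length(ord)); if (length(on_pos)) pat[on_pos] <- 1L
        return(structure(
          list(realizable = TRUE, witness = rec, blocks = count_runs(pat)),
          class = "realizability"))
      }
    }
  }
  structure(list(realizable = FALSE, witness = NULL, blocks = NA_integer_),
            class = "realizability")
}

#' @export
print.realizability <- function(x, ...) {
  if (x$realizable) {
    cat(sprintf("realizable by a single receiver (%d blocks)\n", x$blocks))
    print(x$witness)
  } else {
    cat("not realizable by a single receiver\n")
  }
  invisible(x)
}

#' Minimum block count over admissible orderings
#'
#' A block is a maximal run of identical outputs along the ordered
#' signal-concentration axis. The minimum achievable block count governs
#' single-receiver realizability: with the full activation set, a table is
#' realizable by one receiver iff it can be rearranged to at most 3 blocks
#' whose pattern matches an available kind. DC states may join any block.
#'
#' @param tt a [truth_table()] with at most 4 inputs.
#' @return The minimum number of blocks over all admissible orderings.
#' @examples
#' min_blocks(tt_from_hex(0x6, 2))   # XOR: 3 (OFF-ON-OFF)
#' min_blocks(tt_from_hex(0x1B, 3))  # 4: needs two receivers
#' @export
min_blocks <- function(tt) {
  stopifnot(inherits(tt, "truth_table"))
  if (tt$n_inputs > 4) stop("min_blocks() supports at most 4 inputs")
  orders <- admissible_orders(tt$n_inputs)
  min(vapply(orders, function(ord) count_runs(tt$outputs[ord + 1L]), 1L))
}

#' Realizable-gate counts for every activation subset
#'
#' Tabulates [enumerate_realizable()] counts for all 15 non-empty subsets of
#' the activation kinds, so the kind set behind any reported single-receiver
#' count can be identified.
#'
#' @param n_inputs number of inputs (<= 4).
#' @return A data frame with columns `kinds` and `n_realizable`.
#' @export
realizable_kind_counts <- function(n_inputs) {
  kinds <- activation_kinds()
  rows <- list()
  for (mask in 1:15) {
    sel <- kinds[as.logical(bitwAnd(mask, c(1L, 2L, 4L, 8L)))]
    rows[[mask]] <- data.frame(
      kinds = paste(sel, collapse = "+"),
      n_realizable = length(realizable_codes(enumerate_realizable(n_inputs, sel)))
    )
  }
  do.call(rbind, rows)
}
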