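# shared fixtures: small layouts and designs built in code

lattice_xy <- function(i, j, pitch = 4.5, origin = 1.75) {
  c(origin + i * pitch, origin + j * pitch)
}

make_layout <- function(ij_inputs, ij_receivers, pitch = 4.5, ...) {
  n <- nrow(ij_inputs); k <- nrow(ij_receivers)
  org <- macchiato:::lattice_origin(pitch, c(35, 35))
  nodes <- data.frame(
    id = c(LETTERS[seq_len(n)], sprintf("R%d", seq_len(k))),
    role = rep(c("input", "receiver"), c(n, k)),
    x = org[1] + c(ij_inputs[, 1], ij_receivers[, 1]) * pitch,
    y = org[2] + c(ij_inputs[, 2], ij_receivers[, 2]) * pitch
  )
  layout_spec(nodes, pitch = pitch, ...)
}

# a coarse grid that keeps simulator tests fast
small_grid <- function(width = 20, height = 20, spacing = 0.5, ...) {
  sim_grid(width = width, height = height, spacing = spacing, ...)
}

xor_design <- function() macchiato_minimize(tt_from_hex(0x6, 2), "bandpass")
or_design <- function() macchiato_minimize(tt_from_hex(0x7, 2), "highpass")
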