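#' Hill-type dose-response curves of receiver strains
#'
#' Continuous expression model behind each activation kind. The highpass is an
#' activating Hill function; the bandpass multiplies the activating Hill by a
#' repressing Hill at higher concentration, mirroring an
#' activator/high-threshold-repressor circuit (T7 RNAP driven output repressed
#' by PhlF at high inducer); lowpass and bandstop are the respective inverses.
#' All parameter defaults are reconstructed stand-ins with documented,
#' desk-calculated values — see [sim_defaults()] — expressed in the same
#' arbitrary concentration units as the simulated diffusion field.
#'
#' @param kind activation kind (see [activation_kinds()]).
#' @param basal basal fluorescence (leaky expression), `>= 0`.
#' @param v_max maximal fluorescence, `> basal`.
#' @param K_act activation half-maximal concentration.
#' @param n_act activation Hill exponent (`> 0`).
#' @param K_rep repression half-maximal concentration (two-threshold kinds
#'   only; must exceed `K_act`).
#' @param n_rep repression Hill exponent.
#' @return An object of class `dose_response`; evaluate it with `predict()`.
#' @examples
#' dr <- dose_response("highpass", K_act = 0.02)
#' predict(dr, c(0, 0.02, 1))
#' @export
dose_response <- function(kind, basal = 0.02, v_max = 1,
                          K_act = 0.02, n_act = 4,
                          K_rep = NULL, n_rep = 12) {
  kind <- match.arg(kind, activation_kinds())
  two <- kind %in% c("bandpass", "bandstop")
  if (two && is.null(K_rep)) K_rep <- 8 * K_act
  stopifnot(basal >= 0, v_max > basal, K_act > 0, n_act > 0)
  if (two) {
    stopifnot(K_rep > K_act, n_rep > 0)
  } else if (!is.null(K_rep)) {
    stop(sprintf("'%s' takes no repression parameters", kind))
  }
  structure(
    list(kind = kind, basal = basal, v_max = v_max,
         K_act = K_act, n_act = n_act,
         K_rep = if (two) K_rep else NULL, n_rep = if (two) n_rep else NULL),
    class = "dose_response"
  )
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("%s dose-response: basal %g, v_max %g, K_act %g (n %g)",
              x$kind, x$basal, x$v_max, x$K_act, x$n_act))
  if (!is.null(x$K_rep)) cat(sprintf(", K_rep %g (n %g)", x$K_rep, x$n_rep))
  cat("\n")
  invisible(x)
}

#' @rdname dose_response
#' @param object a `dose_response`.
#' @param concentration non-negative concentration vector.
#' @param ... unused.
#' @export
predict.dose_response <- function(object, concentration, ...) {
  u <- as.numeric(concentration)
  if (any(u < 0)) stop("concentrations must be non-negative")
  hill <- function(u, K, n) {
    x <- (u / K)^n
    x / (1 + x)
  }
  h_act <- hill(u, object$K_act, object$n_act)
  core <- switch(object$kind,
    highpass = h_act,
    lowpass  = 1 - h_act,
    bandpass = h_act * (1 - hill(u, object$K_rep, object$n_rep)),
    bandstop = 1 - h_act * (1 - hill(u, object$K_rep, object$n_rep))
  )
  object$basal + (object$v_max - object$basal) * core
}

#' Default device physics and strain parameters
#'
#' The single place the simulator's defaults live. Values are reconstructed
#' stand-ins anchored to the standard experimental conditions of such devices: a 35 x 35 mm
#' domain (one 6-well well), droplet inputs of 1 uL of 7.5 mM IPTG (7.5 nmol),
#' diffusion coefficient of order 1.4 mm^2/h for a small molecule in agar,
#' plates imaged at 20 h, colonies dispensed on a 4.5 mm (384-well) lattice.
#' Dose-response parameters were chosen by desk calculation so that the
#' resulting concentration scale (a few times 0.01 amount/mm^2 at
#' lattice-neighbor distance around the commit time) spans the response knees.
#'
#' @return A named list of defaults.
#' @export
sim_defaults <- function() {
  list(
    width = 35, height = 35,      # mm
    spacing = 0.25,               # mm
    D = 1.4,                      # mm^2/h
    droplet_dose = 7.5,           # amount units (1 uL x 7.5 mM)
    sender_rate = 1.5,            # amount/h while induced
    t_read = 20,                  # h
    commit_time = 6,              # h
    decision_ratio = 1.5,         # ON iff expression > ratio x basal
    pitch = 4.5,                  # mm, 384-well lattice
    growth_rate = 0.7,            # 1/h
    capacity = 1,                 # OD-like
    lag = 2,                      # h
    n0 = 0.05,                    # initial biomass
    dose_response = list(
      highpass = dose_response("highpass", basal = 0.02, v_max = 1,
                               K_act = 0.015, n_act = 4),
      lowpass  = dose_response("lowpass", basal = 0.02, v_max = 1,
                               K_act = 0.010, n_act = 4),
      bandpass = dose_response("bandpass", basal = 0.02, v_max = 1,
                               K_act = 0.005, n_act = 4,
                               K_rep = 0.04, n_rep = 12),
      bandstop = dose_response("bandstop", basal = 0.02, v_max = 1,
                               K_act = 0.005, n_act = 4,
                               K_rep = 0.04, n_rep = 12)
    )
  )
}
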