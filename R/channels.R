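## Voltage-gated channel specifications and gating kinetics for the six TRN
## currents: fast transient Na+ (NaT), delayed-rectifier K+ (Kd), transient
## A-type K+ (Kt), slowly inactivating K+ (K2), anomalous rectifier (AR),
## and low-threshold transient Ca2+ (CaT).

#' Channel names understood by the model
#'
#' The six voltage-gated currents of the TRN cell models, in the fixed order
#' used throughout the package: fast transient sodium (\code{NaT}), delayed
#' rectifier potassium (\code{Kd}), transient A-type potassium (\code{Kt}),
#' slowly inactivating potassium (\code{K2}), anomalous rectifier (\code{AR},
#' a hyperpolarization-activated mixed-cation current), and low-threshold
#' transient calcium (\code{CaT}).
#' @export
CHANNEL_NAMES <- c("NaT", "Kd", "Kt", "K2", "AR", "CaT")

#' Default reversal potentials (mV)
#'
#' 50 mV for sodium, -100 mV for the potassium currents, -40 mV for AR and
#' 125 mV for calcium. The calcium reversal is held fixed (no GHK or calcium
#' pool dynamics).
#' @export
DEFAULT_REVERSALS <- c(NaT = 50, Kd = -100, Kt = -100, K2 = -100,
                       AR = -40, CaT = 125)

## integer powers of (activation, inactivation) per channel; 0 = gate absent
GATING_EXPONENTS <- list(
  NaT = c(m = 3, h = 1),
  Kd  = c(m = 4, h = 0),
  Kt  = c(m = 4, h = 1),
  K2  = c(m = 1, h = 1),
  AR  = c(m = 1, h = 0),
  CaT = c(m = 2, h = 1)
)

## gate slots in the engine state vector, per channel
GATE_INDEX <- list(
  NaT = c(m = 1, h = 2), Kd = c(m = 3), Kt = c(m = 4, h = 5),
  K2 = c(m = 6, h = 7), AR = c(m = 8), CaT = c(m = 9, h = 10)
)
GATE_LABELS <- c("NaT.m", "NaT.h", "Kd.m", "Kt.m", "Kt.h",
                 "K2.m", "K2.h", "AR.m", "CaT.m", "CaT.h")

#' Construct a channel specification
#'
#' @param name one of \code{CHANNEL_NAMES}.
#' @param g_max maximal conductance density (mS/cm2), non-negative.
#' @param e_rev reversal potential (mV); defaults to the standard value for
#'   the ionic species (\code{DEFAULT_REVERSALS}).
#' @return an object of class \code{channel_spec} with fields \code{name},
#'   \code{g_max}, \code{e_rev} and \code{gating_exponents}.
#' @examples
#' channel_spec("NaT", 60.5)
#' @export
channel_spec <- function(name, g_max, e_rev = NULL) {
  name <- match.arg(name, CHANNEL_NAMES)
  stopifnot(is.numeric(g_max), length(g_max) == 1, is.finite(g_max), g_max >= 0)
  if (is.null(e_rev)) e_rev <- DEFAULT_REVERSALS[[name]]
  stopifnot(is.numeric(e_rev), length(e_rev) == 1, is.finite(e_rev))
  structure(list(name = name, g_max = g_max, e_rev = e_rev,
                 gating_exponents = GATING_EXPONENTS[[name]]),
            class = "channel_spec")
}

#' @export
print.channel_spec <- function(x, ...) {
  ex <- x$gating_exponents
  gates <- paste0(names(ex)[ex > 0], "^", ex[ex > 0], collapse = " * ")
  cat(sprintf("<channel %s>  g_max = %g mS/cm2, E_rev = %g mV, gating %s\n",
              x$name, x$g_max, x$e_rev, gates))
  invisible(x)
}

#' Steady-state activation and time constant of a channel's gates
#'
#' Evaluates the voltage-dependent gating kinetics (Traub-lineage nRT
#' formulations; see \code{\link{trn_kinetics_table}}) at membrane potential
#' \code{v}. The same C++ kinetics drive the integrator, so these values are
#' exactly what the engine uses.
#'
#' @param channel a \code{channel_spec} (or a channel name).
#' @param v membrane potential (mV), finite scalar or vector.
#' @return list with elements \code{x_inf} and \code{tau} (ms), each a matrix
#'   with one row per voltage and one named column per gate of the channel.
#' @examples
#' steady_state_and_tau("NaT", -60)
#' @export
steady_state_and_tau <- function(channel, v) {
  name <- if (inherits(channel, "channel_spec")) channel$name
          else match.arg(channel, CHANNEL_NAMES)
  if (!is.numeric(v) || !all(is.finite(v)))
    stop("membrane potential 'v' must be finite (got ",
         paste(utils::head(v, 3), collapse = ", "), ")")
  k <- gate_kinetics_cpp(as.numeric(v))
  idx <- GATE_INDEX[[name]]
  x_inf <- k$x_inf[, idx, drop = FALSE]
  tau <- k$tau[, idx, drop = FALSE]
  colnames(x_inf) <- colnames(tau) <- names(idx)
  list(x_inf = x_inf, tau = tau)
}

#' Ionic current density through one channel
#'
#' Computes \code{g_max * m^a * h^b * (e_rev - v)} in uA/cm2, with the sign
#' convention that a positive value is a depolarizing contribution to
#' \code{C_m dV/dt}.
#'
#' @param channel a \code{channel_spec}.
#' @param state named numeric vector of gating variables in [0,1]; names must
#'   cover the channel's gates (e.g. \code{c(m = 0.1, h = 0.6)}).
#' @param v membrane potential (mV).
#' @return current density (uA/cm2).
#' @examples
#' ch <- channel_spec("NaT", 60.5)
#' channel_current(ch, c(m = 1, h = 1), v = 0)  # 60.5 * 50
#' @export
channel_current <- function(channel, state, v) {
  stopifnot(inherits(channel, "channel_spec"),
            is.numeric(v), all(is.finite(v)))
  ex <- channel$gating_exponents
  gates <- names(ex)[ex > 0]
  if (!all(gates %in% names(state)))
    stop("state must provide gates: ", paste(gates, collapse = ", "))
  x <- state[gates]
  if (any(x < 0 | x > 1)) stop("gating variables must lie in [0, 1]")
  open <- prod(x^ex[gates])
  channel$g_max * open * (channel$e_rev - v)
}

#' Gating-kinetics constants, human readable
#'
#' One row per gate: the Boltzmann half-activation voltage and slope of the
#' steady-state curve (\code{x_inf(v) = 1/(1 + exp((v - v_half)/k))}, negative
#' \code{k} for activation gates) and a formula string for the time constant.
#' This is the single reference table for the kinetics compiled into the
#' engine; any temperature scaling is already folded into the constants.
#'
#' @return data.frame with columns \code{channel}, \code{gate}, \code{v_half},
#'   \code{slope} and \code{tau_formula}.
#' @export
trn_kinetics_table <- function() {
  data.frame(
    channel = c("NaT", "NaT", "Kd", "Kt", "Kt", "K2", "K2", "AR", "CaT", "CaT"),
    gate = c("m", "h", "m", "m", "h", "m", "h", "m", "m", "h"),
    v_half = c(-38, -62.9, -27, -60, -78, -10, -58, -75, -52, -80),
    slope = c(-10, 10.7, -11.5, -8.5, 6, -17, 10.6, 5.5, -7.4, 5),
    tau_formula = c(
      "v < -30: 0.0125 + 0.1525*exp((v+30)/10); else 0.02 + 0.145*exp(-(v+30)/10)",
      "0.225 + 1.125/(1 + exp((v+37)/15))",
      "v < -10: 0.25 + 4.35*exp((v+10)/10); else 0.25 + 4.35*exp(-(v+10)/10)",
      "0.185 + 0.5/(exp((v+35.8)/19.7) + exp(-(v+79.7)/12.7))",
      "v < -63: 0.5/(exp((v+46)/5) + exp(-(v+238)/37.5)); else 9.12",
      "4.95 + 0.5/(exp((v-81)/25.6) + exp(-(v+132)/18))",
      "60 + 0.5/(exp((v-1.33)/200) + exp(-(v+130)/7.1))",
      "1/(exp(-14.59 - 0.086*v) + exp(-1.87 + 0.0701*v))",
      "1 + 0.33/(exp((v+27)/10) + exp(-(v+102)/15))",
      "28.3 + 0.33/(exp((v+48)/4) + exp(-(v+407)/50))"),
    stringsAsFactors = FALSE
  )
}
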