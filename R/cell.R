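## Cell assembly: isopotential compartments and their internal coupling.
## All compartments are unit-area patches, so conductance densities (mS/cm2)
## and current densities (uA/cm2) are used directly as absolute quantities.

COMPARTMENT_LABELS <- c("S", "M", "D")

#' Construct one isopotential compartment
#'
#' @param label "S" (soma), "M" (middle dendrite) or "D" (distal dendrite).
#' @param c_m specific capacitance (uF/cm2), positive.
#' @param g_leak leak conductance density (mS/cm2), non-negative.
#' @param e_leak leak reversal potential (mV).
#' @param channels named numeric vector of maximal conductance densities
#'   (mS/cm2) keyed by channel name, or a list of \code{channel_spec}s.
#'   Dendritic compartments (M, D) may not carry NaT: TRN dendrites do not
#'   spike.
#' @return object of class \code{compartment_params}.
#' @export
compartment_params <- function(label, c_m, g_leak, e_leak = -75,
                               channels = numeric()) {
  label <- match.arg(label, COMPARTMENT_LABELS)
  stopifnot(is.numeric(c_m), c_m > 0, is.numeric(g_leak), g_leak >= 0,
            is.numeric(e_leak), is.finite(e_leak))
  if (is.numeric(channels)) {
    stopifnot(all(names(channels) %in% CHANNEL_NAMES))
    channels <- lapply(names(channels)[channels > 0], function(nm)
      channel_spec(nm, channels[[nm]]))
  }
  stopifnot(all(vapply(channels, inherits, logical(1), "channel_spec")))
  names(channels) <- vapply(channels, `[[`, character(1), "name")
  if (label %in% c("M", "D") && "NaT" %in% names(channels))
    stop("dendritic compartment '", label, "' may not carry the NaT current")
  structure(list(label = label, c_m = c_m, g_leak = g_leak, e_leak = e_leak,
                 channels = channels),
            class = "compartment_params")
}

#' Construct a cell from ordered compartments
#'
#' Compartments are listed soma-outward (S, then M, then D); adjacent
#' compartments are linked by reciprocal internal conductances.
#'
#' @param compartments list of \code{compartment_params}, ordered S, M, D.
#' @param g_internal numeric vector of conductances (mS/cm2) between adjacent
#'   compartments, one fewer than the number of compartments; names like
#'   \code{"S-M"}, \code{"M-D"} are attached automatically.
#' @return object of class \code{cell_params}.
#' @export
cell_params <- function(compartments, g_internal = numeric()) {
  stopifnot(all(vapply(compartments, inherits, logical(1),
                       "compartment_params")))
  labels <- vapply(compartments, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate compartment labels")
  stopifnot(length(g_internal) == length(compartments) - 1,
            all(g_internal >= 0))
  if (length(g_internal))
    names(g_internal) <- paste(labels[-length(labels)], labels[-1], sep = "-")
  names(compartments) <- labels
  structure(list(compartments = compartments, g_internal = g_internal),
            class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf("<cell_params: %d compartment(s)>\n", length(x$compartments)))
  for (cp in x$compartments) {
    ch <- vapply(cp$channels, function(c) sprintf("%s=%g", c$name, c$g_max),
                 character(1))
    cat(sprintf("  %s: c_m %g uF/cm2, g_leak %g, E_leak %g | %s\n",
                cp$label, cp$c_m, cp$g_leak, cp$e_leak,
                if (length(ch)) paste(ch, collapse = " ") else "passive"))
  }
  if (length(x$g_internal))
    cat("  G_internal:", paste(sprintf("%s %g", names(x$g_internal),
                                       x$g_internal), collapse = ", "), "\n")
  invisible(x)
}

#' Single-compartment TRN model cell
#'
#' Maximal conductances (mS/cm2): NaT 60.5, Kd 60, Kt 5, K2 0.5, AR 0.025,
#' CaT 0.75; capacitance 1 uF/cm2; leak 0.1 mS/cm2 reversing at -75 mV.
#' @return \code{cell_params} with a single soma compartment.
#' @export
make_single_compartment_trn <- function() {
  soma <- compartment_params("S", c_m = 1, g_leak = 0.1, e_leak = -75,
                             channels = c(NaT = 60.5, Kd = 60, Kt = 5,
                                          K2 = 0.5, AR = 0.025, CaT = 0.75))
  cell_params(list(soma))
}

#' Three-compartment TRN model cell (soma, middle and distal dendrite)
#'
#' Soma conductances (mS/cm2): NaT 60.5, Kd 90, Kt 5, K2 0.5, AR 0.005,
#' CaT 0.5; dendrites carry the same potassium and AR complement but no NaT
#' and a reduced CaT of 0.15. Leak is 0.1 mS/cm2 at the soma and 0.035 in
#' dendrites; capacitance 1.2 uF/cm2 everywhere. Internal coupling: 0.4
#' mS/cm2 between middle dendrite and soma, 0.35 between distal and middle.
#' @return \code{cell_params} with compartments S, M, D.
#' @export
make_three_compartment_trn <- function() {
  soma <- compartment_params("S", c_m = 1.2, g_leak = 0.1, e_leak = -75,
                             channels = c(NaT = 60.5, Kd = 90, Kt = 5,
                                          K2 = 0.5, AR = 0.005, CaT = 0.5))
  dend <- c(Kd = 90, Kt = 5, K2 = 0.5, AR = 0.005, CaT = 0.15)
  mid <- compartment_params("M", c_m = 1.2, g_leak = 0.035, e_leak = -75,
                            channels = dend)
  dist <- compartment_params("D", c_m = 1.2, g_leak = 0.035, e_leak = -75,
                             channels = dend)
  cell_params(list(soma, mid, dist), g_internal = c(0.4, 0.35))
}

#' Scale leak conductance of a cell
#'
#' Multiplies \code{g_leak} in the selected compartments; all other
#' parameters are untouched. The default scales every compartment, the
#' convention used to realise input-resistance changes (factors 0.75-1.45
#' bracket roughly +/-25\% input resistance for the three-compartment cell);
#' pass \code{compartments = "S"} for soma-only scaling.
#'
#' @param cell \code{cell_params}.
#' @param factor positive scale factor.
#' @param compartments labels to scale (default: all present).
#' @return modified \code{cell_params}.
#' @export
scale_leak <- function(cell, factor, compartments = NULL) {
  stopifnot(inherits(cell, "cell_params"),
            is.numeric(factor), length(factor) == 1, is.finite(factor))
  if (factor <= 0) stop("leak scale factor must be positive")
  if (is.null(compartments)) compartments <- names(cell$compartments)
  for (lab in compartments)
    cell$compartments[[lab]]$g_leak <- cell$compartments[[lab]]$g_leak * factor
  cell
}

#' Scale internal (inter-compartment) conductances
#'
#' @param cell three-compartment \code{cell_params}.
#' @param ms_factor positive factor applied to the middle-soma conductance.
#' @param dm_factor positive factor applied to the distal-middle conductance.
#' @return modified \code{cell_params}.
#' @export
scale_internal <- function(cell, ms_factor, dm_factor) {
  stopifnot(inherits(cell, "cell_params"), length(cell$g_internal) == 2)
  if (ms_factor <= 0 || dm_factor <= 0)
    stop("internal conductance factors must be positive")
  cell$g_internal[["S-M"]] <- cell$g_internal[["S-M"]] * ms_factor
  cell$g_internal[["M-D"]] <- cell$g_internal[["M-D"]] * dm_factor
  cell
}

#' Strip all voltage-gated channels from a cell
#'
#' Returns the passive (leak + capacitance + internal coupling) reduction of
#' the cell, used when cross-checking the integrator against the analytic
#' steady-state solver.
#' @param cell \code{cell_params}.
#' @return passive \code{cell_params}.
#' @export
zero_channels <- function(cell) {
  stopifnot(inherits(cell, "cell_params"))
  for (lab in names(cell$compartments))
    cell$compartments[[lab]]$channels <- list()
  cell
}

## flat key=value serialization of a cell parameter set
#' Write a cell parameter set to a flat key-value text file
#' @param cell \code{cell_params}.
#' @param path output file.
#' @export
write_cell_config <- function(cell, path) {
  lines <- character()
  for (cp in cell$compartments) {
    pre <- paste0("compartment.", cp$label, ".")
    lines <- c(lines,
               paste0(pre, "c_m=", cp$c_m),
               paste0(pre, "g_leak=", cp$g_leak),
               paste0(pre, "e_leak=", cp$e_leak),
               vapply(cp$channels, function(ch)
                 paste0(pre, "channel.", ch$name, "=", ch$g_max), character(1)))
  }
  for (nm in names(cell$g_internal))
    lines <- c(lines, paste0("g_internal.", nm, "=", cell$g_internal[[nm]]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cell parameter set from a flat key-value text file
#' @param path file written by \code{\link{write_cell_config}}.
#' @return \code{cell_params}.
#' @export
read_cell_config <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- as.numeric(vapply(kv, `[`, character(1), 2))
  labs <- unique(sub("^compartment\\.([SMD])\\..*$", "\\1",
                     grep("^compartment\\.", keys, value = TRUE)))
  labs <- intersect(COMPARTMENT_LABELS, labs)  # canonical order
  comps <- lapply(labs, function(lab) {
    pre <- paste0("compartment.", lab, ".")
    get1 <- function(f) vals[keys == paste0(pre, f)]
    chk <- grep(paste0("^", pre, "channel\\."), keys)
    ch <- stats::setNames(vals[chk], sub(paste0(pre, "channel."), "", keys[chk],
                                         fixed = TRUE))
    compartment_params(lab, c_m = get1("c_m"), g_leak = get1("g_leak"),
                       e_leak = get1("e_leak"), channels = ch)
  })
  gik <- grep("^g_internal\\.", keys)
  cell_params(comps, g_internal = unname(vals[gik]))
}
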