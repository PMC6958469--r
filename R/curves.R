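#' Dose-response curve container
#'
#' Holds one agent's (or one fixed-ratio mixture's) concentration/viability
#' series, the unit of all in vitro fitting. Viability is expressed as a
#' fraction of untreated control (1 = fully viable), concentrations in the
#' agent's native unit (kBq/mL for a radioconjugate, uM for a small molecule,
#' or a dimensionless fraction-of-top for fixed-ratio mixtures).
#'
#' @param conc numeric vector of non-negative concentrations.
#' @param viability numeric vector of viability fractions, same length.
#' @param agent label for the agent or mixture.
#' @param unit concentration unit tag (informational).
#' @param replicate optional integer replicate ids, same length as `conc`.
#' @return An object of class `dr_curve`: a list with fields `agent`, `unit`,
#'   `conc`, `viability`, `replicate`, sorted by concentration.
#' @examples
#' cv <- dose_response_curve(c(0.1, 1, 10, 100), c(0.99, 0.9, 0.5, 0.1))
#' print(cv)
#' @export
dose_response_curve <- function(conc, viability, agent = "agent",
                                unit = "conc", replicate = NULL) {
  conc <- as.numeric(conc)
  viability <- as.numeric(viability)
  if (length(conc) != length(viability))
    stop("`conc` and `viability` must have the same length", call. = FALSE)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(viability)))
    stop("viability values must be finite", call. = FALSE)
  if (!is.null(replicate) && length(replicate) != length(conc))
    stop("`replicate` must match the length of `conc`", call. = FALSE)
  ord <- order(conc)
  structure(
    list(agent = as.character(agent)[1L], unit = as.character(unit)[1L],
         conc = conc[ord], viability = viability[ord],
         replicate = if (is.null(replicate)) NULL else as.integer(replicate)[ord]),
    class = "dr_curve"
  )
}

#' @export
print.dr_curve <- function(x, ...) {
  cat(sprintf("<dr_curve> %s: %d wells, %d distinct concentrations [%s]\n",
              x$agent, length(x$conc), length(unique(x$conc)), x$unit))
  invisible(x)
}

# mean viability per distinct concentration (replicate averaging)
curve_means <- function(curve) {
  v <- tapply(curve$viability, curve$conc, mean)
  data.frame(conc = as.numeric(names(v)), viability = as.numeric(v))
}

#' Normalize raw plate signals to fraction-of-control viability
#'
#' Converts raw luminescence/absorbance readings to viability fractions by
#' anchoring at the mean of untreated control wells (viability 1) and the
#' mean of cell-free blank wells (viability 0):
#' `(raw - blank) / (control - blank)`.
#'
#' @param raw_signals numeric vector of treated-well signals.
#' @param control_signals numeric vector of untreated control-well signals.
#' @param blank_signals numeric vector of blank (no cell) well signals.
#' @return Numeric vector of viability fractions (controls map to 1.0).
#' @examples
#' normalize_viability(550, control_signals = 1050, blank_signals = 50) # 0.5
#' @export
normalize_viability <- function(raw_signals, control_signals, blank_signals) {
  ctrl <- mean(as.numeric(control_signals))
  blk <- mean(as.numeric(blank_signals))
  if (!is.finite(ctrl) || !is.finite(blk) || ctrl <= blk)
    stop("degenerate plate: control signal must exceed blank signal",
         call. = FALSE)
  (as.numeric(raw_signals) - blk) / (ctrl - blk)
}
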