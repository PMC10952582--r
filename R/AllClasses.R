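#' @import methods
NULL

.LIGAND_LEVELS <- c("none", "gaba", "analogue")

#' KineticScheme: a Markov gating scheme for a ligand-gated ion channel
#'
#' A directed state graph for a receptor gating scheme. Each transition is a
#' directed edge carrying a rate identifier and a ligand dependence: `"none"`
#' (unimolecular, s^-1), `"gaba"` or `"analogue"` (bimolecular association,
#' M^-1 s^-1, multiplied by the corresponding ligand concentration when the
#' generator matrix is built). Only the states flagged as conducting carry
#' current; in all packaged receptor schemes that is the single open state
#' `RA*`.
#'
#' @slot id scheme identifier (free text).
#' @slot states character vector of unique state labels; must contain the
#'   resting state.
#' @slot conducting subset of `states` that carries current.
#' @slot resting the unliganded resting state label (default `"R"`).
#' @slot transitions `data.frame` with columns `from`, `to`, `rate`,
#'   `ligand`; one row per directed edge.
#'
#' @seealso [kineticScheme()], [buildGenerator()], [makePaperModel()]
#' @export
setClass("KineticScheme",
  representation(
    id = "character",
    states = "character",
    conducting = "character",
    resting = "character",
    transitions = "data.frame"
  )
)

setValidity("KineticScheme", function(object) {
  msgs <- character()
  st <- object@states
  if (length(st) < 1L) msgs <- c(msgs, "scheme must declare at least one state")
  if (anyDuplicated(st)) msgs <- c(msgs, "state labels must be unique")
  if (length(object@resting) != 1L || !(object@resting %in% st))
    msgs <- c(msgs, "resting state must be one of the declared states")
  if (!all(object@conducting %in% st))
    msgs <- c(msgs, "conducting states must be declared states")
  tr <- object@transitions
  need <- c("from", "to", "rate", "ligand")
  if (!all(need %in% names(tr))) {
    msgs <- c(msgs, sprintf(
      "transitions must have columns %s", paste(need, collapse = ", ")))
  } else if (nrow(tr) > 0L) {
    bad <- !(tr$from %in% st) | !(tr$to %in% st)
    if (any(bad))
      msgs <- c(msgs, sprintf(
        "transition endpoints not declared as states: rows %s",
        paste(which(bad), collapse = ", ")))
    if (any(tr$from == tr$to))
      msgs <- c(msgs, "self-transitions are not allowed")
    if (!all(tr$ligand %in% .LIGAND_LEVELS))
      msgs <- c(msgs, sprintf(
        "ligand dependence must be one of %s",
        paste(.LIGAND_LEVELS, collapse = ", ")))
    if (anyDuplicated(tr$rate))
      msgs <- c(msgs, "each rate identifier may label only one edge")
  }
  if (length(msgs)) msgs else TRUE
})

#' RateSet: values for the rate identifiers of a kinetic scheme
#'
#' A named set of strictly positive, finite rate constants. Unimolecular rates
#' are in s^-1; ligand-association rates are in M^-1 s^-1 and are multiplied
#' by the ligand concentration when a generator matrix is built.
#'
#' @slot values named numeric vector, one entry per rate identifier.
#' @slot units named character vector parallel to `values`
#'   (`"s-1"` or `"M-1s-1"`).
#' @slot provenance free-text origin of the values (e.g. a packaged model id).
#'
#' @seealso [rateSet()], [makePaperModel()]
#' @export
setClass("RateSet",
  representation(values = "numeric", units = "character",
                 provenance = "character")
)

setValidity("RateSet", function(object) {
  msgs <- character()
  v <- object@values
  if (is.null(names(v)) || any(!nzchar(names(v))) || anyDuplicated(names(v)))
    msgs <- c(msgs, "rate values must have unique non-empty names")
  if (!all(is.finite(v)) || any(v <= 0))
    msgs <- c(msgs, "all rate values must be strictly positive and finite")
  if (length(object@units) &&
      !identical(sort(names(object@units)), sort(names(v))))
    msgs <- c(msgs, "units must be named for exactly the rate identifiers")
  if (length(msgs)) msgs else TRUE
})

#' ConcentrationProtocol: piecewise-constant ligand application epochs
#'
#' An ordered sequence of epochs, each with a duration and fixed GABA and
#' analogue concentrations (molar). The default protocol mimics a Y-tube
#' concentration-jump experiment: baseline, analogue pre-application,
#' GABA + analogue co-application, washout.
#'
#' @slot epochs `data.frame` with columns `label`, `duration_s`, `gaba_M`,
#'   `analogue_M`.
#' @slot exchangeTau solution-exchange time constant (s); 0 means
#'   instantaneous jumps.
#'
#' @seealso [concentrationProtocol()], [runProtocol()]
#' @export
setClass("ConcentrationProtocol",
  representation(epochs = "data.frame", exchangeTau = "numeric")
)

setValidity("ConcentrationProtocol", function(object) {
  msgs <- character()
  ep <- object@epochs
  need <- c("label", "duration_s", "gaba_M", "analogue_M")
  if (!all(need %in% names(ep)))
    msgs <- c(msgs, sprintf("epochs must have columns %s",
                            paste(need, collapse = ", ")))
  else {
    if (nrow(ep) < 1L) msgs <- c(msgs, "protocol must have at least one epoch")
    if (any(!is.finite(ep$duration_s)) || any(ep$duration_s <= 0))
      msgs <- c(msgs, "epoch durations must be positive")
    if (any(ep$gaba_M < 0) || any(ep$analogue_M < 0))
      msgs <- c(msgs, "concentrations must be non-negative")
  }
  if (length(object@exchangeTau) != 1L || object@exchangeTau < 0)
    msgs <- c(msgs, "exchangeTau must be a single non-negative number")
  if (length(msgs)) msgs else TRUE
})

#' OccupancyTrajectory: time course of state occupancies
#'
#' Occupancy fractions of every scheme state on a time grid, as produced by
#' [propagate()]. Occupancies are probabilities: non-negative and summing to
#' one at every sample.
#'
#' @slot time time grid (s), strictly increasing.
#' @slot occupancy numeric matrix, `length(time)` rows, one column per state.
#'
#' @export
setClass("OccupancyTrajectory",
  representation(time = "numeric", occupancy = "matrix")
)

setValidity("OccupancyTrajectory", function(object) {
  msgs <- character()
  occ <- object@occupancy
  if (nrow(occ) != length(object@time))
    msgs <- c(msgs, "occupancy must have one row per time point")
  if (length(object@time) > 1L && any(diff(object@time) <= 0))
    msgs <- c(msgs, "time grid must be strictly increasing")
  if (any(occ < -1e-9) || any(occ > 1 + 1e-9))
    msgs <- c(msgs, "occupancies must lie in [0, 1]")
  if (nrow(occ) && any(abs(rowSums(occ) - 1) > 1e-9))
    msgs <- c(msgs, "occupancies must sum to 1 at every sample")
  if (length(msgs)) msgs else TRUE
})

#' CurrentTrace: a sampled (virtual) whole-cell current
#'
#' A uniformly sampled current trace with the metadata needed to regenerate
#' it: scheme id, rate provenance, protocol epochs, output interval, noise
#' seed. Currents are reported as positive magnitudes; only normalized
#' quantities are used downstream.
#'
#' @slot time sample times (s).
#' @slot current current samples (dimensionless occupancy of the conducting
#'   states, optionally peak-normalized, optionally noisy).
#' @slot metadata named list (free-form; see [runProtocol()], [genTrace()]).
#'
#' @export
setClass("CurrentTrace",
  representation(time = "numeric", current = "numeric", metadata = "list")
)

setValidity("CurrentTrace", function(object) {
  msgs <- character()
  if (length(object@time) != length(object@current))
    msgs <- c(msgs, "time and current must have the same length")
  if (length(object@time) > 1L && any(diff(object@time) <= 0))
    msgs <- c(msgs, "time must be strictly increasing")
  if (any(!is.finite(object@current)))
    msgs <- c(msgs, "current samples must be finite")
  if (length(msgs)) msgs else TRUE
})

#' MeasurementSummary: peak / steady-state readouts of a current trace
#'
#' @slot peak peak response over the co-application window.
#' @slot steady steady-state response (mean over the final averaging window
#'   of the co-application).
#' @slot percentDesensitisation `100 * (1 - steady / peak)`.
#' @slot peakTime time of the peak (s).
#' @slot steadyWindow two-element numeric, start/end of the averaging
#'   window (s).
#' @slot flags character vector of quality flags (e.g. `"undefined"` when the
#'   peak is zero).
#'
#' @export
setClass("MeasurementSummary",
  representation(peak = "numeric", steady = "numeric",
                 percentDesensitisation = "numeric", peakTime = "numeric",
                 steadyWindow = "numeric", flags = "character")
)

#' DecayFit: biexponential decay fit with weighted time constant
#'
#' Parameters of `A1 exp(-t/tau1) + A2 exp(-t/tau2) + C` fitted to a current
#' decay, plus the area-weighted time constant
#' `tauw = (A1 tau1 + A2 tau2) / (A1 + A2)`, which deliberately excludes the
#' plateau term.
#'
#' @slot A1,A2 component amplitudes (>= 0).
#' @slot tau1,tau2 component time constants (s, > 0).
#' @slot plateau plateau level.
#' @slot tauw weighted time constant (s).
#' @slot window fit window, two-element numeric (s).
#' @slot rss residual sum of squares.
#' @slot converged logical.
#' @slot degenerate logical; `TRUE` when the input did not decay and the fit
#'   is not meaningful.
#'
#' @export
setClass("DecayFit",
  representation(A1 = "numeric", tau1 = "numeric", A2 = "numeric",
                 tau2 = "numeric", plateau = "numeric", tauw = "numeric",
                 window = "numeric", rss = "numeric", converged = "logical",
                 degenerate = "logical")
)

setValidity("DecayFit", function(object) {
  if (isTRUE(object@degenerate)) return(TRUE)
  msgs <- character()
  if (any(c(object@tau1, object@tau2) <= 0))
    msgs <- c(msgs, "time constants must be positive")
  if (any(c(object@A1, object@A2) < 0))
    msgs <- c(msgs, "amplitudes must be non-negative")
  tw <- object@tauw
  if (tw < min(object@tau1, object@tau2) - 1e-9 ||
      tw > max(object@tau1, object@tau2) + 1e-9)
    msgs <- c(msgs, "tauw must lie between tau1 and tau2")
  if (length(msgs)) msgs else TRUE
})

#' HillFit: concentration-inhibition fit
#'
#' Parameters of the inhibition relation
#' `I/Imax = 1 - B^n / (IC50^n + B^n)` fitted in log-concentration space,
#' with `pIC50 = -log10(IC50 in molar)` and standard errors from the local
#' curvature at the optimum.
#'
#' @slot ic50 half-inhibitory concentration (M).
#' @slot pic50 `-log10(ic50)`.
#' @slot hillSlope slope coefficient n.
#' @slot se named numeric, standard errors for `pic50` and `hillSlope`.
#' @slot rss residual sum of squares.
#' @slot nPoints number of fitted points.
#' @slot converged logical.
#'
#' @export
setClass("HillFit",
  representation(ic50 = "numeric", pic50 = "numeric", hillSlope = "numeric",
                 se = "numeric", rss = "numeric", nPoints = "numeric",
                 converged = "logical")
)

setValidity("HillFit", function(object) {
  if (object@ic50 <= 0) "IC50 must be positive" else TRUE
})

#' RegressionResult: ordinary least-squares line with R-squared
#'
#' @slot slope,intercept fitted coefficients.
#' @slot r2 coefficient of determination (squared Pearson correlation).
#' @slot n number of points.
#'
#' @export
setClass("RegressionResult",
  representation(slope = "numeric", intercept = "numeric", r2 = "numeric",
                 n = "numeric")
)

setValidity("RegressionResult", function(object) {
  if (object@r2 < -1e-12 || object@r2 > 1 + 1e-12)
    "R-squared must lie in [0, 1]" else TRUE
})

#' FitSpec: specification of a waveform-fitting problem
#'
#' Names the scheme, the seed rate set, which rate identifiers are free, the
#' (positive) box bounds applied in natural units, and the iteration budget
#' of the optimiser.
#'
#' @slot scheme a [KineticScheme-class].
#' @slot rates seed [RateSet-class] (defaults in packaged workflows are the
#'   published values).
#' @slot free character vector of free rate identifiers.
#' @slot lower,upper scalar bounds for the free rates (natural units).
#' @slot maxIter optimiser iteration budget (default 50).
#' @slot label hypothesis label used in comparisons.
#'
#' @export
setClass("FitSpec",
  representation(scheme = "KineticScheme", rates = "RateSet",
                 free = "character", lower = "numeric", upper = "numeric",
                 maxIter = "numeric", label = "character")
)

setValidity("FitSpec", function(object) {
  msgs <- character()
  rv <- object@rates@values
  if (!all(object@free %in% names(rv)))
    msgs <- c(msgs, sprintf("free rate ids not in the rate set: %s",
      paste(setdiff(object@free, names(rv)), collapse = ", ")))
  if (!all(object@free %in% object@scheme@transitions$rate))
    msgs <- c(msgs, "every free rate id must label an edge of the scheme")
  if (object@lower <= 0 || object@upper <= object@lower)
    msgs <- c(msgs, "bounds must satisfy 0 < lower < upper")
  if (length(object@free) &&
      (any(rv[object@free] < object@lower) ||
       any(rv[object@free] > object@upper)))
    msgs <- c(msgs, "seed values must lie within the bounds")
  if (object@maxIter < 1) msgs <- c(msgs, "maxIter must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' WaveformFitResult: outcome of a waveform fit
#'
#' @slot rates optimised [RateSet-class] (fixed rates bit-identical to the
#'   seeds).
#' @slot objective final sum of squared residuals.
#' @slot iterTrace best-so-far objective after each evaluation
#'   (non-increasing).
#' @slot converged logical optimiser status.
#' @slot spec the [FitSpec-class] that produced the result.
#'
#' @export
setClass("WaveformFitResult",
  representation(rates = "RateSet", objective = "numeric",
                 iterTrace = "numeric", converged = "logical",
                 spec = "FitSpec")
)
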