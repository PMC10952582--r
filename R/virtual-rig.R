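#' Build a concentration-jump application protocol
#'
#' The default protocol reproduces the recording design used throughout the
#' packaged workflows: 2 s baseline, 10 s analogue pre-application, 20 s
#' GABA + analogue co-application at 30 uM GABA (~EC90 for the receptor
#' isoform), 5 s washout. All concentrations are molar.
#'
#' @param gaba GABA concentration during co-application (M).
#' @param analogue analogue concentration during pre- and co-application (M).
#' @param baseline,preApplication,coApplication,washout epoch durations (s);
#'   set a duration to 0 to drop the epoch (the co-application epoch is
#'   mandatory).
#' @param exchangeTau optional exponential solution-exchange time constant
#'   (s); 0 (the default) means instantaneous jumps, appropriate because
#'   Y-tube exchange (~tens of ms) is far below the seconds-scale decay.
#' @return a [ConcentrationProtocol-class].
#' @export
concentrationProtocol <- function(gaba = 30e-6, analogue = 0, baseline = 2,
                                  preApplication = 10, coApplication = 20,
                                  washout = 5, exchangeTau = 0) {
  if (coApplication <= 0) stop("the co-application epoch is mandatory")
  ep <- data.frame(
    label = c("baseline", "pre", "co", "wash"),
    duration_s = c(baseline, preApplication, coApplication, washout),
    gaba_M = c(0, 0, gaba, 0),
    analogue_M = c(0, analogue, analogue, 0),
    stringsAsFactors = FALSE)
  ep <- ep[ep$duration_s > 0, , drop = FALSE]
  new("ConcentrationProtocol", epochs = ep, exchangeTau = exchangeTau)
}

#' @rdname concentrationProtocol
#' @param epochTable `data.frame` with columns `label`, `duration_s`,
#'   `gaba_M`, `analogue_M` for fully custom protocols.
#' @export
protocolFromEpochs <- function(epochTable, exchangeTau = 0) {
  new("ConcentrationProtocol",
      epochs = as.data.frame(epochTable, stringsAsFactors = FALSE),
      exchangeTau = exchangeTau)
}

## Replace the analogue concentration in the pre/co epochs of a template.
.withAnalogue <- function(protocol, analogue) {
  ep <- protocol@epochs
  ep$analogue_M[ep$label %in% c("pre", "co")] <- analogue
  new("ConcentrationProtocol", epochs = ep,
      exchangeTau = protocol@exchangeTau)
}

## Sub-epochs implementing exponential solution exchange: concentrations
## relax from the previous epoch's values with time constant tau, staircased
## at resolution dt over ~7 tau.
.exchangeSubEpochs <- function(prevG, prevP, ep, tau, dt) {
  ramp <- min(7 * tau, ep$duration_s)
  nsub <- max(1L, ceiling(ramp / dt))
  edges <- seq(0, ramp, length.out = nsub + 1L)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  w <- exp(-mid / tau)
  sub <- data.frame(
    label = ep$label, duration_s = diff(edges),
    gaba_M = ep$gaba_M + (prevG - ep$gaba_M) * w,
    analogue_M = ep$analogue_M + (prevP - ep$analogue_M) * w,
    stringsAsFactors = FALSE)
  if (ep$duration_s > ramp) {
    sub <- rbind(sub, data.frame(label = ep$label,
                                 duration_s = ep$duration_s - ramp,
                                 gaba_M = ep$gaba_M,
                                 analogue_M = ep$analogue_M))
  }
  sub
}

#' Simulate a current trace under an application protocol
#'
#' Concatenates per-epoch occupancy propagation (occupancy is continuous
#' across epoch boundaries) and reports the summed occupancy of the
#' conducting states as a positive-magnitude current. Time zero is the start
#' of the protocol; epoch start times are recorded in the trace metadata so
#' downstream measurement can locate the co-application window.
#'
#' @param scheme a [KineticScheme-class].
#' @param rates a [RateSet-class].
#' @param protocol a [ConcentrationProtocol-class].
#' @param dtOut output sample interval (s); default 1 ms.
#' @param normalize if `TRUE`, scale the current to unit peak.
#' @param p0 initial occupancy (default: all receptors in the resting state).
#' @return a [CurrentTrace-class]; the full state trajectory is attached as
#'   attribute `trajectory`.
#' @examples
#' mod <- makePaperModel("c_compound6")
#' tr <- runProtocol(mod$scheme, mod$rates,
#'                   concentrationProtocol(analogue = 1e-6), dtOut = 0.01)
#' measure(tr)
#' @export
runProtocol <- function(scheme, rates, protocol, dtOut = 1e-3,
                        normalize = FALSE, p0 = NULL) {
  stopifnot(is(scheme, "KineticScheme"), is(rates, "RateSet"),
            is(protocol, "ConcentrationProtocol"))
  ep <- protocol@epochs
  if (nrow(ep) == 0L) stop("protocol has no epochs")
  st <- scheme@states
  if (is.null(p0)) {
    p0 <- stats::setNames(numeric(length(st)), st)
    p0[scheme@resting] <- 1
  }
  segs <- if (protocol@exchangeTau > 0) {
    out <- list()
    prevG <- 0; prevP <- 0
    for (i in seq_len(nrow(ep))) {
      out[[i]] <- .exchangeSubEpochs(prevG, prevP, ep[i, ],
                                     protocol@exchangeTau, dtOut)
      prevG <- ep$gaba_M[i]; prevP <- ep$analogue_M[i]
    }
    do.call(rbind, out)
  } else ep
  times <- 0
  occ <- matrix(p0, 1L, length(st), dimnames = list(NULL, st))
  p <- p0
  t0 <- 0
  for (i in seq_len(nrow(segs))) {
    Q <- buildGenerator(scheme, rates, segs$gaba_M[i], segs$analogue_M[i])
    traj <- propagate(Q, p, segs$duration_s[i], dtOut)
    keep <- -1L  # epoch-initial sample duplicates the previous endpoint
    times <- c(times, t0 + traj@time[keep])
    occ <- rbind(occ, traj@occupancy[keep, , drop = FALSE])
    p <- traj@occupancy[nrow(traj@occupancy), ]
    t0 <- t0 + segs$duration_s[i]
  }
  current <- rowSums(occ[, scheme@conducting, drop = FALSE])
  if (normalize) {
    pk <- max(current)
    if (pk > 0) current <- current / pk
  }
  starts <- c(0, cumsum(ep$duration_s))[seq_len(nrow(ep))]
  md <- list(
    scheme_id = scheme@id, rates_provenance = rates@provenance,
    dt_s = dtOut, normalized = as.character(normalize),
    epochs = cbind(ep, start_s = starts))
  tr <- new("CurrentTrace", time = times, current = current, metadata = md)
  attr(tr, "trajectory") <- new("OccupancyTrajectory", time = times,
                                occupancy = occ)
  tr
}

## Locate the co-application window of a trace; traces without epoch
## metadata are measured over their full extent.
.coWindow <- function(trace) {
  ep <- trace@metadata$epochs
  if (is.null(ep) || !("co" %in% ep$label))
    return(range(trace@time))
  i <- which(ep$label == "co")[1]
  c(ep$start_s[i], ep$start_s[i] + ep$duration_s[i])
}

#' Measure peak, steady-state and percent desensitisation of a trace
#'
#' Peak = maximum current over the co-application window; steady-state =
#' mean over the final `steadyWindow` seconds of co-application (a short
#' average standing in for the "after 20 s" point readout); percent
#' desensitisation = `100 * (1 - steady / peak)`. A zero peak makes
#' desensitisation undefined: the summary is flagged `"undefined"` (with a
#' warning) rather than returning a silent number.
#'
#' @param trace a [CurrentTrace-class] covering the co-application epoch
#'   (traces without epoch metadata are measured over their full extent).
#' @param steadyWindow steady-state averaging window (s), default 0.2.
#' @return a [MeasurementSummary-class].
#' @export
measure <- function(trace, steadyWindow = 0.2) {
  win <- .coWindow(trace)
  sel <- trace@time >= win[1] - 1e-12 & trace@time <= win[2] + 1e-12
  if (!any(sel)) stop("trace does not cover the co-application window")
  tt <- trace@time[sel]
  yy <- trace@current[sel]
  ipk <- which.max(yy)
  peak <- yy[ipk]
  ssel <- tt >= win[2] - steadyWindow - 1e-12
  steady <- mean(yy[ssel])
  flags <- character()
  if (peak <= 0) {
    warning("peak response is zero; percent desensitisation is undefined")
    flags <- "undefined"
    pct <- NA_real_
  } else {
    pct <- 100 * (1 - steady / peak)
  }
  new("MeasurementSummary", peak = peak, steady = steady,
      percentDesensitisation = pct, peakTime = tt[ipk],
      steadyWindow = c(win[2] - steadyWindow, win[2]), flags = flags)
}

#' Peak and steady-state inhibition of a test trace relative to control
#'
#' Inhibition = `100 * (1 - test / control)` computed separately for the
#' peak and the steady-state readout. The control must have been simulated
#' under an identical protocol with zero analogue.
#'
#' @param control analogue-free [CurrentTrace-class].
#' @param test [CurrentTrace-class] with analogue.
#' @param steadyWindow passed to [measure()].
#' @return named numeric `c(peak =, steady =)` (percent).
#' @export
inhibitionReadouts <- function(control, test, steadyWindow = 0.2) {
  epc <- control@metadata$epochs
  ept <- test@metadata$epochs
  if (!is.null(epc) && !is.null(ept)) {
    same <- identical(epc$label, ept$label) &&
      isTRUE(all.equal(epc$duration_s, ept$duration_s)) &&
      isTRUE(all.equal(epc$gaba_M, ept$gaba_M))
    if (!same)
      stop("control and test traces must share the same protocol timing and GABA concentrations")
    if (any(epc$analogue_M > 0))
      stop("control trace must be analogue-free")
  }
  mc <- measure(control, steadyWindow)
  mt <- measure(test, steadyWindow)
  if (mc@peak <= 0) stop("control trace has zero peak; inhibition undefined")
  c(peak = 100 * (1 - mt@peak / mc@peak),
    steady = 100 * (1 - mt@steady / mc@steady))
}
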