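#' Area-weighted decay time constant
#'
#' `tauw = (A1 tau1 + A2 tau2) / (A1 + A2)`. The plateau term of a decay fit
#' is deliberately excluded: only the two exponential components contribute.
#'
#' @param A1,A2 component amplitudes (>= 0, not both zero).
#' @param tau1,tau2 component time constants (s, > 0).
#' @return weighted time constant (s).
#' @examples
#' weightedTau(3, 2, 1, 6)   # 3
#' @export
weightedTau <- function(A1, tau1, A2, tau2) {
  if (any(c(A1, A2) < 0) || any(c(tau1, tau2) <= 0))
    stop("amplitudes must be non-negative and time constants positive")
  if (any(A1 + A2 == 0))
    stop("weighted tau is undefined when A1 + A2 = 0")
  (A1 * tau1 + A2 * tau2) / (A1 + A2)
}

#' pIC50 / IC50 transforms
#'
#' `pic50(x)` converts a molar IC50 to `-log10(IC50)`; `ic50(x)` inverts it
#' back to molar. The round trip is exact.
#'
#' @param ic50M half-inhibitory concentration (M, > 0).
#' @param pic50 `-log10` molar potency.
#' @return numeric.
#' @examples
#' pic50(1e-6)   # 6
#' ic50(9)       # 1e-9
#' @export
pic50 <- function(ic50M) {
  if (any(!is.finite(ic50M)) || any(ic50M <= 0))
    stop("IC50 must be positive and finite")
  -log10(ic50M)
}

#' @rdname pic50
#' @export
ic50 <- function(pic50) {
  if (any(!is.finite(pic50))) stop("pIC50 must be finite")
  10^(-pic50)
}

#' Hill concentration-inhibition relation
#'
#' Normalized response `I/Imax = 1 - B^n / (IC50^n + B^n)` at analogue
#' concentration `B`; equals 1 at `B = 0`, 0.5 at `B = IC50` and tends to 0
#' as `B` grows.
#'
#' @param conc analogue concentration(s) `B` (M).
#' @param pic50Val potency as `-log10(IC50 molar)`.
#' @param n Hill slope coefficient.
#' @return normalized response(s).
#' @export
hillResponse <- function(conc, pic50Val, n = 1) {
  ic <- 10^(-pic50Val)
  bn <- (conc / ic)^n
  1 - bn / (1 + bn)
}

#' Fit a biexponential decay with plateau to a current trace
#'
#' Least-squares fit of `A1 exp(-t/tau1) + A2 exp(-t/tau2) + C` over a
#' window running from the co-application peak to the end of co-application
#' (the default), with the weighted time constant computed from the two
#' exponential components only. Time constants are optimised in log space to
#' keep them positive. If the biexponential is unidentifiable (single
#' exponential input, components collapsing), the fit falls back to a single
#' exponential and reports `tau1 = tau2 = tau`, so `tauw = tau`. A trace
#' that does not decay over the window is flagged degenerate.
#'
#' @param trace a [CurrentTrace-class].
#' @param window optional two-element numeric, fit window in trace time (s);
#'   default peak-of-co-application to end-of-co-application.
#' @return a [DecayFit-class].
#' @export
fitDecay <- function(trace, window = NULL) {
  if (is.null(window)) {
    win <- .coWindow(trace)
    sel <- trace@time >= win[1] - 1e-12 & trace@time <= win[2] + 1e-12
    ipk <- which.max(trace@current[sel])
    window <- c(trace@time[sel][ipk], win[2])
  }
  sel <- trace@time >= window[1] - 1e-12 & trace@time <= window[2] + 1e-12
  tt <- trace@time[sel] - window[1]
  yy <- trace@current[sel]
  if (length(tt) < 6L) stop("fit window contains too few samples")
  tailMean <- mean(yy[tt >= max(tt) * 0.9])
  span <- yy[1] - tailMean
  if (!is.finite(span) || span <= max(1e-12, 0.01 * abs(yy[1]))) {
    return(new("DecayFit", A1 = NA_real_, tau1 = NA_real_, A2 = NA_real_,
               tau2 = NA_real_, plateau = tailMean, tauw = NA_real_,
               window = window, rss = NA_real_, converged = FALSE,
               degenerate = TRUE))
  }
  Tw <- max(tt)
  ## nls.lm is used directly: the nls-object construction in the high-level
  ## wrapper fails on (near-)perfect fits with a singular gradient
  lmSolve <- function(start, resid, lower, upper) {
    tryCatch({
      out <- minpack.lm::nls.lm(
        par = start, fn = resid, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15))
      list(par = unlist(out$par), rss = sum(out$fvec^2),
           ok = out$info %in% 1:4)
    }, error = function(e) NULL)
  }
  fit2 <- lmSolve(
    start = list(A1 = span / 2, ltau1 = log(Tw / 20), A2 = span / 2,
                 ltau2 = log(Tw / 3), C = max(tailMean, 1e-12)),
    resid = function(p)
      yy - (p$A1 * exp(-tt / exp(p$ltau1)) +
            p$A2 * exp(-tt / exp(p$ltau2)) + p$C),
    lower = c(0, log(Tw * 1e-5), 0, log(Tw * 1e-5), 0),
    upper = c(Inf, log(Tw * 1e3), Inf, log(Tw * 1e3), Inf))
  .asFit <- function(A1, tau1, A2, tau2, C, rss, converged) {
    if (A2 > A1) {  # order components: tau1 = faster
      tmp <- A1; A1 <- A2; A2 <- tmp
      tmp <- tau1; tau1 <- tau2; tau2 <- tmp
    }
    if (tau1 > tau2) {
      tmp <- A1; A1 <- A2; A2 <- tmp
      tmp <- tau1; tau1 <- tau2; tau2 <- tmp
    }
    tw <- if (A1 + A2 > 0) weightedTau(A1, tau1, A2, tau2) else NA_real_
    new("DecayFit", A1 = A1, tau1 = tau1, A2 = A2, tau2 = tau2, plateau = C,
        tauw = tw, window = window, rss = rss, converged = converged,
        degenerate = FALSE)
  }
  single <- function() {
    fit1 <- lmSolve(
      start = list(A = span, ltau = log(Tw / 5), C = max(tailMean, 1e-12)),
      resid = function(p) yy - (p$A * exp(-tt / exp(p$ltau)) + p$C),
      lower = c(0, log(Tw * 1e-5), 0),
      upper = c(Inf, log(Tw * 1e3), Inf))
    if (is.null(fit1))
      return(new("DecayFit", A1 = NA_real_, tau1 = NA_real_, A2 = NA_real_,
                 tau2 = NA_real_, plateau = tailMean, tauw = NA_real_,
                 window = window, rss = NA_real_, converged = FALSE,
                 degenerate = TRUE))
    cf <- fit1$par
    tau <- exp(cf[["ltau"]])
    .asFit(cf[["A"]], tau, 0, tau, cf[["C"]], fit1$rss, fit1$ok)
  }
  if (is.null(fit2)) return(single())
  cf <- fit2$par
  tau1 <- exp(cf[["ltau1"]]); tau2 <- exp(cf[["ltau2"]])
  rss2 <- fit2$rss
  ## collapse test: components indistinguishable or one amplitude vanished
  ratio <- max(tau1, tau2) / min(tau1, tau2)
  amps <- c(cf[["A1"]], cf[["A2"]])
  if (ratio < 1.05 || min(amps) < 1e-6 * sum(amps)) {
    f1 <- single()
    if (!f1@degenerate && f1@rss <= rss2 * (1 + 1e-6)) return(f1)
  }
  .asFit(cf[["A1"]], tau1, cf[["A2"]], tau2, cf[["C"]], rss2, fit2$ok)
}

#' Fit the Hill concentration-inhibition relation
#'
#' Fits `I/Imax = 1 - B^n / (IC50^n + B^n)` to normalized responses in
#' log-concentration space with `pIC50` and the slope `n` free (`n` bounded
#' to [0.3, 5]). Standard errors come from the local (Gauss-Newton)
#' covariance at the optimum. Clearly non-monotone data draw a warning but
#' the fit is still returned.
#'
#' @param points `data.frame` with columns `concentration_M` and `response`
#'   (normalized to the analogue-free control), optionally `response_se`
#'   used as inverse-variance weights.
#' @param nBounds two-element numeric bounds for the Hill slope.
#' @return a [HillFit-class].
#' @examples
#' tab <- genDoseResponse(6.5, concentrations = 10^seq(-8, -5, length.out = 7))
#' fitInhibition(tab)
#' @export
fitInhibition <- function(points, nBounds = c(0.3, 5)) {
  for (needed in c("concentration_M", "response"))
    if (!(needed %in% names(points)))
      stop(sprintf("points must have a '%s' column", needed))
  pts <- points[points$concentration_M > 0, , drop = FALSE]
  if (length(unique(pts$concentration_M)) < 4L)
    stop("at least 4 distinct positive concentrations are required")
  if (nrow(pts) >= 4L) {
    rho <- suppressWarnings(stats::cor(log10(pts$concentration_M),
                                       pts$response, method = "spearman"))
    if (is.finite(rho) && rho > 0.2)
      warning("responses are not monotone decreasing in concentration; fit may be unreliable")
  }
  x <- log10(pts$concentration_M)
  y <- pts$response
  w <- if ("response_se" %in% names(pts) && all(pts$response_se > 0))
    1 / pts$response_se^2 else rep(1, nrow(pts))
  p0 <- -x[which.min(abs(y - 0.5))]
  dat <- data.frame(x = x, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ 1 - 1 / (1 + 10^(n * (-p - x))), data = dat, weights = w,
    start = list(p = p0, n = 1),
    lower = c(p = 0, n = nBounds[1]), upper = c(p = 12, n = nBounds[2]),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(p = NA_real_, n = NA_real_))
  new("HillFit", ic50 = 10^(-cf[["p"]]), pic50 = cf[["p"]],
      hillSlope = cf[["n"]],
      se = c(pic50 = unname(se[["p"]]), hillSlope = unname(se[["n"]])),
      rss = sum(stats::residuals(fit)^2), nPoints = nrow(pts),
      converged = fit$convInfo$isConv)
}

#' Ordinary least-squares line with R-squared
#'
#' Simple linear regression `y = slope * x + intercept` with `R^2` equal to
#' the squared Pearson correlation, as used for the desensitisation /
#' decay-speed proxy relationship.
#'
#' @param x,y numeric vectors (>= 3 points, `x` non-constant).
#' @return a [RegressionResult-class].
#' @examples
#' fig7b <- desensTauwTable()
#' linReg(fig7b$desens_percent, fig7b$tauw_s)
#' @export
linReg <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3L) stop("at least 3 points are required")
  if (stats::var(x) == 0) stop("x has zero variance")
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) 1 else stats::cor(x, y)^2
  new("RegressionResult", slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r2 = min(r2, 1), n = length(x))
}

#' Simulate and fit a concentration-response relationship
#'
#' For each analogue concentration, runs a paired control (analogue-free)
#' and test simulation under the protocol template, extracts the chosen
#' metric, normalizes to control (for `tau_w` the response is the fractional
#' tau-w remaining, `tauw(P)/tauw(0)`), and fits the Hill inhibition
#' relation. Concentrations where the metric is undefined are dropped with a
#' warning; an essentially flat curve rejects the fit (`fit = NULL`).
#'
#' @param scheme a [KineticScheme-class].
#' @param rates a [RateSet-class].
#' @param protocol template [ConcentrationProtocol-class]; the analogue
#'   concentration of its pre/co epochs is replaced per grid point.
#' @param concentrations analogue concentration grid (M, > 0).
#' @param metric one of `"steady_state"`, `"peak"`, `"tau_w"`.
#' @param dtOut simulation output interval (s).
#' @return list with `table` (`data.frame`: `concentration_M`, `response`)
#'   and `fit` (a [HillFit-class], or `NULL` when rejected).
#' @export
doseResponsePipeline <- function(scheme, rates, protocol = concentrationProtocol(),
                                 concentrations,
                                 metric = c("steady_state", "peak", "tau_w"),
                                 dtOut = 0.01) {
  metric <- match.arg(metric)
  if (!length(concentrations) || any(concentrations <= 0))
    stop("concentrations must be a non-empty positive grid")
  control <- runProtocol(scheme, rates, .withAnalogue(protocol, 0), dtOut)
  ref <- switch(metric,
    steady_state = measure(control)@steady,
    peak = measure(control)@peak,
    tau_w = fitDecay(control)@tauw)
  if (!is.finite(ref) || ref <= 0)
    stop(sprintf("control %s readout is undefined", metric))
  resp <- vapply(concentrations, function(conc) {
    tr <- runProtocol(scheme, rates, .withAnalogue(protocol, conc), dtOut)
    val <- switch(metric,
      steady_state = measure(tr)@steady,
      peak = measure(tr)@peak,
      tau_w = fitDecay(tr)@tauw)
    if (!is.finite(val)) NA_real_ else val / ref
  }, numeric(1))
  keep <- is.finite(resp)
  if (!all(keep))
    warning(sprintf("%d concentration(s) dropped: %s metric undefined",
                    sum(!keep), metric))
  tab <- data.frame(concentration_M = concentrations[keep],
                    response = resp[keep])
  fit <- NULL
  if (nrow(tab) >= 4L && diff(range(tab$response)) > 0.05) {
    fit <- tryCatch(fitInhibition(tab), error = function(e) NULL)
  } else {
    warning("response curve is flat (or has too few points); Hill fit rejected")
  }
  list(table = tab, fit = fit)
}
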