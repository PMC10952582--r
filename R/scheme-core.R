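#' Construct a kinetic scheme
#'
#' @param states character vector of unique state labels.
#' @param conducting subset of `states` carrying current.
#' @param transitions `data.frame` with columns `from`, `to`, `rate`,
#'   `ligand` (one row per directed edge; `ligand` is one of `"none"`,
#'   `"gaba"`, `"analogue"`).
#' @param resting label of the unliganded resting state.
#' @param id scheme identifier.
#' @return a [KineticScheme-class].
#' @examples
#' sch <- kineticScheme(
#'   states = c("C", "O"), conducting = "O",
#'   transitions = data.frame(
#'     from = c("C", "O"), to = c("O", "C"),
#'     rate = c("kf", "kb"), ligand = "none"),
#'   resting = "C")
#' @export
kineticScheme <- function(states, conducting, transitions, resting = "R",
                          id = "custom") {
  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  for (cc in intersect(c("from", "to", "rate", "ligand"), names(transitions)))
    transitions[[cc]] <- as.character(transitions[[cc]])
  new("KineticScheme", id = id, states = as.character(states),
      conducting = as.character(conducting), resting = resting,
      transitions = transitions)
}

#' Construct a rate set
#'
#' @param values named numeric vector of strictly positive rate constants.
#' @param units optional named character vector (`"s-1"` or `"M-1s-1"`)
#'   parallel to `values`.
#' @param provenance free-text origin of the values.
#' @return a [RateSet-class].
#' @examples
#' rateSet(c(kf = 100, kb = 50))
#' @export
rateSet <- function(values, units = character(), provenance = "user") {
  new("RateSet", values = values, units = units, provenance = provenance)
}

#' Modify rates in a rate set
#'
#' Returns a copy of `rates` with the named entries replaced.
#'
#' @param rates a [RateSet-class].
#' @param ... named replacement values, or a single named numeric vector.
#' @return a [RateSet-class].
#' @export
updateRates <- function(rates, ...) {
  repl <- c(...)
  if (is.null(names(repl)) || any(!nzchar(names(repl))))
    stop("replacement rates must be named")
  unknown <- setdiff(names(repl), names(rates@values))
  if (length(unknown))
    stop(sprintf("unknown rate id(s): %s", paste(unknown, collapse = ", ")))
  v <- rates@values
  v[names(repl)] <- repl
  new("RateSet", values = v, units = rates@units,
      provenance = rates@provenance)
}

#' Build the generator (Q) matrix of a scheme at fixed ligand concentrations
#'
#' Off-diagonal entry (i, j) is the transition intensity from state i to
#' state j: the rate constant of the edge, multiplied by the GABA or analogue
#' concentration for ligand-dependent (association) edges. Diagonal entries
#' are minus the row sums, so every row sums to zero and occupancies evolve
#' by the master equation `dp/dt = p Q`.
#'
#' @param scheme a [KineticScheme-class].
#' @param rates a [RateSet-class] covering every rate id used by the scheme.
#' @param gabaConc GABA concentration (M, >= 0).
#' @param analogueConc analogue concentration (M, >= 0).
#' @return a square numeric matrix with state labels as dimnames and
#'   attributes `gabaConc`, `analogueConc`, `schemeId`, `resting`,
#'   `conducting`.
#' @examples
#' mod <- makePaperModel("b_compound5")
#' Q <- buildGenerator(mod$scheme, mod$rates, gabaConc = 30e-6,
#'                     analogueConc = 0)
#' rowSums(Q)   # all zero
#' @export
buildGenerator <- function(scheme, rates, gabaConc, analogueConc) {
  stopifnot(is(scheme, "KineticScheme"), is(rates, "RateSet"))
  if (!is.numeric(gabaConc) || !is.numeric(analogueConc) ||
      gabaConc < 0 || analogueConc < 0)
    stop("ligand concentrations must be non-negative (molar)")
  tr <- scheme@transitions
  missing <- setdiff(tr$rate, names(rates@values))
  if (length(missing))
    stop(sprintf("rate set is missing rate id(s) required by scheme '%s': %s",
                 scheme@id, paste(missing, collapse = ", ")))
  st <- scheme@states
  n <- length(st)
  Q <- matrix(0, n, n, dimnames = list(st, st))
  mult <- c(none = 1, gaba = gabaConc, analogue = analogueConc)
  for (k in seq_len(nrow(tr))) {
    Q[tr$from[k], tr$to[k]] <- Q[tr$from[k], tr$to[k]] +
      rates@values[[tr$rate[k]]] * mult[[tr$ligand[k]]]
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  structure(Q, gabaConc = gabaConc, analogueConc = analogueConc,
            schemeId = scheme@id, resting = scheme@resting,
            conducting = scheme@conducting)
}

## Clamp tiny negative occupancies produced by finite-precision matrix
## exponentials and renormalise; anything below -tol is a real error.
.cleanOccupancy <- function(p, tol = 1e-9) {
  if (any(p < -tol))
    stop("propagation produced significantly negative occupancies")
  p[p < 0] <- 0
  p / sum(p)
}

#' Propagate state occupancies under a fixed-concentration generator
#'
#' Solves the linear master equation `dp/dt = p Q` on a uniform output grid
#' by stepping with the matrix exponential `expm(Q * dt)`, which is exact for
#' a fixed-concentration epoch and robust to the wide spread of rates
#' (stiffness) in receptor schemes.
#'
#' @param gen generator matrix from [buildGenerator()].
#' @param p0 initial occupancy vector (non-negative, sums to 1).
#' @param duration epoch duration (s, > 0).
#' @param dtOut output sample interval (s); default 1 ms.
#' @return an [OccupancyTrajectory-class] with samples at
#'   `seq(0, duration, by = dtOut)` (the endpoint is always included).
#' @examples
#' mod <- makePaperModel("a_wt")
#' Q <- buildGenerator(mod$scheme, mod$rates, 30e-6, 0)
#' p0 <- setNames(c(1, 0, 0, 0), schemeStates(mod$scheme))
#' tr <- propagate(Q, p0, duration = 0.1, dtOut = 1e-3)
#' @export
propagate <- function(gen, p0, duration, dtOut = 1e-3) {
  n <- nrow(gen)
  if (length(p0) != n || any(p0 < 0) || abs(sum(p0) - 1) > 1e-8)
    stop("p0 must be a non-negative occupancy vector summing to 1")
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be positive")
  nfull <- floor(duration / dtOut + 1e-9)
  times <- dtOut * seq_len(nfull)
  rem <- duration - nfull * dtOut
  if (rem > 1e-12 * max(1, duration)) times <- c(times, duration)
  times <- c(0, times)
  occ <- matrix(0, length(times), n, dimnames = list(NULL, rownames(gen)))
  p <- .cleanOccupancy(as.numeric(p0))
  occ[1L, ] <- p
  E <- as.matrix(Matrix::expm(gen * dtOut))
  for (i in seq_len(nfull)) {
    p <- .cleanOccupancy(as.numeric(p %*% E))
    occ[i + 1L, ] <- p
  }
  if (length(times) == nfull + 2L) {
    Erem <- as.matrix(Matrix::expm(gen * rem))
    p <- .cleanOccupancy(as.numeric(p %*% Erem))
    occ[nfull + 2L, ] <- p
  }
  new("OccupancyTrajectory", time = times, occupancy = occ)
}

## Forward reachability over edges with positive intensity.
.reachableStates <- function(gen, from) {
  n <- nrow(gen)
  adj <- gen > 0
  seen <- logical(n)
  names(seen) <- rownames(gen)
  frontier <- from
  seen[frontier] <- TRUE
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(s)
      rownames(gen)[adj[s, ] & !seen])))
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  rownames(gen)[seen]
}

#' Stationary occupancy distribution of a generator
#'
#' Solves `p Q = 0`, `sum(p) = 1`. When some states are unreachable from the
#' resting state at the given concentrations (e.g. analogue-bound states at
#' zero analogue), the chain is reducible: the solve is restricted to the
#' reachable component, the excluded states get zero occupancy, and a warning
#' reports them.
#'
#' @param gen generator matrix from [buildGenerator()].
#' @param from state(s) defining the reachable component; defaults to the
#'   scheme's resting state recorded on the generator.
#' @return named occupancy vector with attribute `reachable` listing the
#'   states the solve used.
#' @export
steadyState <- function(gen, from = attr(gen, "resting")) {
  st <- rownames(gen)
  if (is.null(from)) from <- st
  reach <- .reachableStates(gen, from)
  if (length(reach) < length(st))
    warning(sprintf(
      "chain is reducible at these concentrations; restricting to %d reachable states (excluded: %s)",
      length(reach), paste(setdiff(st, reach), collapse = ", ")))
  Qr <- gen[reach, reach, drop = FALSE]
  diag(Qr) <- 0
  diag(Qr) <- -rowSums(Qr)
  m <- length(reach)
  A <- t(Qr)
  A[m, ] <- 1
  b <- c(rep(0, m - 1L), 1)
  p <- tryCatch(solve(A, b), error = function(e) {
    sv <- svd(t(Qr))
    v <- sv$v[, m]
    v / sum(v)
  })
  p[abs(p) < 1e-15] <- 0
  out <- setNames(numeric(length(st)), st)
  out[reach] <- p
  structure(out, reachable = reach)
}
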