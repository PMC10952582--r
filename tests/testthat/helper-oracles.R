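# Independent oracles used across the suite. These deliberately avoid the
# package's propagation path: a brute-force fixed-step RK4 integrator for the
# master equation, and a closed-form detailed-balance ratio chain for the
# linear agonist scheme.

# Classical fixed-step RK4 on dp/dt = p Q.
rk4Propagate <- function(Q, p0, duration, dt) {
  f <- function(p) as.numeric(p %*% Q)
  n <- round(duration / dt)
  p <- as.numeric(p0)
  for (i in seq_len(n)) {
    k1 <- f(p)
    k2 <- f(p + dt / 2 * k1)
    k3 <- f(p + dt / 2 * k2)
    k4 <- f(p + dt * k3)
    p <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  stats::setNames(p, rownames(Q))
}

# Equilibrium occupancies of the linear chain R - RA - RA* - RD by successive
# ratios: RA/R = k1*A/k-1, RA*/RA = beta/alpha, RD/RA* = delta1/delta-1.
chainEquilibrium <- function(rates, gaba) {
  v <- gabakin::rateValues(rates)
  w <- c(R = 1,
         RA = v[["k1"]] * gaba / v[["k-1"]])
  w["RA*"] <- w[["RA"]] * v[["beta"]] / v[["alpha"]]
  w["RD"] <- w[["RA*"]] * v[["delta1"]] / v[["delta-1"]]
  w / sum(w)
}

# Fig-8 legend values, frozen independently of the YAML fixtures; used for
# the bit-for-bit packaging checks.
legendRates <- list(
  b_compound5 = c(k1 = 9.79e8, `k-1` = 1.25e4, beta = 6.10e3, alpha = 2.28e3,
                  delta1 = 2.48e-1, `delta-1` = 3.90e-2, k2 = 6.29e4,
                  `k-2` = 2.33e-1, k3 = 9.21e5, `k-3` = 1.40e-1),
  c_compound6 = c(k1 = 3.27e8, `k-1` = 2.00e4, beta = 1.44e4, alpha = 1.45e4,
                  delta1 = 8.72e-1, `delta-1` = 9.22e-2, k4 = 2.34e5,
                  `k-4` = 1.84e2, k2 = 1.29e5, `k-2` = 9.00e-2),
  d_preactivated = c(k1 = 3.27e8, `k-1` = 2.00e4, f1 = 1.03e4, `f-1` = 1.05e4,
                     beta = 1.18e4, alpha = 1.43e4, delta1 = 1.18e0,
                     `delta-1` = 8.07e-2, k2 = 1.73e5, `k-2` = 1.05e-1,
                     k4 = 1.84e5, `k-4` = 3.07e2)
)

# A tiny symmetric two-state scheme for closed-form checks.
twoStateScheme <- function(kf = 100, kb = 100) {
  sch <- gabakin::kineticScheme(
    states = c("C", "O"), conducting = "O",
    transitions = data.frame(from = c("C", "O"), to = c("O", "C"),
                             rate = c("kf", "kb"), ligand = "none",
                             stringsAsFactors = FALSE),
    resting = "C", id = "two_state")
  list(scheme = sch, rates = gabakin::rateSet(c(kf = kf, kb = kb)))
}

# Synthetic decaying trace with a co-application epoch in its metadata.
syntheticDecayTrace <- function(peak = 1, plateau = 0.32, tau = 3,
                                duration = 20, dt = 0.01) {
  tt <- seq(0, duration, by = dt)
  cur <- plateau + (peak - plateau) * exp(-tt / tau)
  new("CurrentTrace", time = tt, current = cur,
      metadata = list(
        dt_s = dt,
        epochs = data.frame(label = "co", duration_s = duration,
                            gaba_M = 30e-6, analogue_M = 0, start_s = 0)))
}
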