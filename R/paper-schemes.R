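#' Identifiers of the packaged receptor models
#'
#' Four gating-scheme topologies are packaged, with the rate constants from
#' the published waveform fits:
#' \describe{
#'   \item{`a_wt`}{simplified agonist-only scheme R, RA, RA*, RD (GABA-arm
#'     rates of the compound-6 fit).}
#'   \item{`b_compound5`}{adds analogue binding to the GABA-bound closed
#'     state (RAP) and a deep blocked state (RAPd).}
#'   \item{`c_compound6`}{analogue binds the GABA-bound closed state (RAP)
#'     and the desensitised state (RDP).}
#'   \item{`d_preactivated`}{explicit preactivated (flip) state RfA; the
#'     analogue binds RfA (RfAP) and RD (RDP).}
#' }
#'
#' @return character vector of model ids.
#' @export
paperModelIds <- function() {
  c("a_wt", "b_compound5", "c_compound6", "d_preactivated")
}

.schemeConfigPath <- function(id) {
  path <- system.file("extdata", "schemes", paste0(id, ".yaml"),
                      package = "gabakin")
  if (!nzchar(path))
    stop(sprintf("unknown model id '%s'; valid ids: %s", id,
                 paste(paperModelIds(), collapse = ", ")))
  path
}

## The published rate legend lists k2/k-2 and k4/k-4 for models c and d
## without naming edges. "standard" mirrors model b (k2/k-2 = analogue
## binding to the closed/preactivated state, k4/k-4 = binding to RD);
## "swapped" exchanges the two pairs.
.applyAssignment <- function(scheme, assignment) {
  if (assignment == "standard") return(scheme)
  tr <- scheme@transitions
  swap <- c("k2" = "k4", "k4" = "k2", "k-2" = "k-4", "k-4" = "k-2")
  hit <- tr$rate %in% names(swap)
  tr$rate[hit] <- unname(swap[tr$rate[hit]])
  scheme@transitions <- tr
  scheme
}

#' Load a packaged receptor model (scheme + published rate constants)
#'
#' Reads the packaged scheme configuration and returns the kinetic scheme
#' together with the exact published rate-constant values. For models with
#' two analogue-binding sites (`c_compound6`, `d_preactivated`) the edge
#' assignment of the k2/k-2 and k4/k-4 pairs is ambiguous in the published
#' legend; `assignment = "standard"` places k2/k-2 on the closed/preactivated
#' site (mirroring model b) and `assignment = "swapped"` exchanges the pairs.
#' The assignment is recorded in the returned rate-set provenance.
#'
#' @param id one of [paperModelIds()].
#' @param assignment `"standard"` or `"swapped"` (ignored for models a, b).
#' @return a list with elements `scheme` ([KineticScheme-class]) and `rates`
#'   ([RateSet-class]).
#' @examples
#' mod <- makePaperModel("b_compound5")
#' rateValues(mod$rates)[["k3"]]   # 9.21e5 s-1 on RAP -> RAPd
#' @export
makePaperModel <- function(id = paperModelIds(),
                           assignment = c("standard", "swapped")) {
  id <- match.arg(id)
  assignment <- match.arg(assignment)
  cfg <- readSchemeConfig(.schemeConfigPath(id))
  scheme <- .applyAssignment(cfg$scheme, assignment)
  rates <- cfg$rates
  rates@provenance <- if (id %in% c("c_compound6", "d_preactivated"))
    sprintf("packaged model %s (%s assignment)", id, assignment)
  else sprintf("packaged model %s", id)
  list(scheme = scheme, rates = rates)
}

#' Tabulate the published rate constants of a packaged model
#'
#' @inheritParams makePaperModel
#' @return `data.frame` with columns `rate`, `value`, `units`, `from`, `to`,
#'   `ligand` — one row per directed edge of the scheme.
#' @examples
#' listPaperRates("d_preactivated")
#' @export
listPaperRates <- function(id = paperModelIds(),
                           assignment = c("standard", "swapped")) {
  mod <- makePaperModel(id, assignment)
  tr <- transitions(mod$scheme)
  v <- rateValues(mod$rates)
  u <- rateUnits(mod$rates)
  data.frame(rate = tr$rate, value = unname(v[tr$rate]),
             units = unname(u[tr$rate]), from = tr$from, to = tr$to,
             ligand = tr$ligand, stringsAsFactors = FALSE)
}

#' Published analogue inhibition potencies (fixture table)
#'
#' The published pIC50 / IC50 values for compounds 2-8 on peak, steady-state
#' and decay readouts of 30 uM GABA currents at alpha1beta3gamma2L receptors.
#' These are experimental summaries used as generator parameters and
#' round-trip fixtures; they are not recomputable from the kinetic models.
#'
#' @return `data.frame`, one row per compound.
#' @export
potencyTable <- function() {
  path <- system.file("extdata", "analogue_potency.csv", package = "gabakin")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Published desensitisation / decay pairs for wild-type and mutants (fixture)
#'
#' Percent macroscopic desensitisation after 20 s of 1 mM GABA and weighted
#' decay time constant for the wild-type receptor and two desensitisation
#' mutants; the three pairs behind the desensitisation-decay proxy
#' regression.
#'
#' @return `data.frame` with columns `receptor`, `desens_percent`, `tauw_s`.
#' @export
desensTauwTable <- function() {
  path <- system.file("extdata", "desens_tauw_wt_mutants.csv",
                      package = "gabakin")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
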