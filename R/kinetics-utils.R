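#' Binding potential from receptor parameters
#'
#' The non-displaceable binding potential of a reversible receptor ligand is
#' \eqn{BP_{ND} = f_{ND} \, B_{avail} / K_D}, where `Bavail` is the available
#' receptor concentration (nM), `KD` the equilibrium dissociation constant of
#' the tracer (nM; raclopride has `KD` about 1.2 nM), and `fND` the free
#' fraction of tracer in the non-displaceable compartment.
#'
#' @param Bavail available receptor concentration, nM, `>= 0`.
#' @param KD dissociation constant, nM, `> 0`.
#' @param fND free fraction in `(0, 1]`.
#' @return `BPnd` (unitless). Vectorized.
#' @examples
#' bpnd_from_receptors(Bavail = 2.628, KD = 1.2) # 2.19
#' @export
bpnd_from_receptors <- function(Bavail, KD = 1.2, fND = 1) {
  if (any(KD <= 0)) stop("KD must be > 0")
  if (any(Bavail < 0)) stop("Bavail must be >= 0")
  if (any(fND <= 0 | fND > 1)) stop("fND must be in (0, 1]")
  fND * Bavail / KD
}

#' Percent change in binding potential (drug-challenge "release")
#'
#' In a paired placebo/drug challenge (e.g. oral methylphenidate raising
#' synaptic dopamine, which competes with the radioligand), endogenous release
#' is indexed by the percent reduction in binding potential:
#' \deqn{100 \, (BP_{placebo} - BP_{drug}) / BP_{placebo}.}
#' Positive values mean a decrease after drug; negative values are possible
#' and are returned as-is.
#'
#' @param bp_placebo baseline (placebo) `BPnd`, `> 0`.
#' @param bp_drug post-drug `BPnd`.
#' @return Percent change (vectorized).
#' @examples
#' percent_change(2.0, 1.0)   # 50
#' percent_change(2.19, 1.99) # 9.13...
#' @export
percent_change <- function(bp_placebo, bp_drug) {
  if (any(bp_placebo <= 0)) stop("bp_placebo must be > 0")
  100 * (bp_placebo - bp_drug) / bp_placebo
}
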