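#' Brain regions analyzed in the visual-learning pS6 study design
#'
#' Returns the standard configuration of 19 brain regions spanning the
#' telencephalon, diencephalon, mesencephalon and brainstem of the cichlid
#' brain, by their conventional abbreviations (e.g. `OB` olfactory bulb,
#' `Dmd`/`Dmv` medial division of the dorsal telencephalon, `NDl` nucleus
#' diffusus lobi inferioris, `TOp`/`TOs` tectum opticum layers, `RF`
#' reticular formation, `VL` vagal lobe).
#'
#' @return Character vector of 19 unique region abbreviations.
#' @export
#' @examples
#' cichlid_brain_regions()
cichlid_brain_regions <- function() {
  c(
    # telencephalon
    "OB", "Dmd", "Dmv", "Dldm", "Dldp", "Dlv", "Dcd", "Dcv", "Dp", "POA",
    # diencephalon
    "NG", "NDl", "PGc",
    # mesencephalon
    "TOp", "TOs", "TS", "TLat",
    # brainstem
    "RF", "VL"
  )
}

#' Experimental groups of the four-arm learning design
#'
#' The four standard treatment arms: an untreated `control`, a stressed
#' `avoidance` group (net chasing), an operant-conditioned `trained` group,
#' and a habituation/dishabituation `novelty` group. The control group is the
#' statistical reference for all activation comparisons.
#'
#' @return Character vector of 4 group labels; the first is the control.
#' @export
experiment_groups <- function() {
  c("control", "avoidance", "trained", "novelty")
}
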