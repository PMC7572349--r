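#' Desikan-Killiany cortical parcellation (35 regions per hemisphere)
#'
#' The fixed, documented region order used throughout the package: all matrix
#' rows/columns, edge indices and reported region-pair names follow this
#' order.  The list is the standard FreeSurfer `aparc` Desikan-Killiany label
#' set per hemisphere (34 cortical labels plus `corpuscallosum`), sorted
#' alphabetically.
#'
#' @return Character vector of 35 region names.
#' @export
#' @examples
#' length(dk_regions())  # 35
dk_regions <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal",
    "corpuscallosum", "cuneus", "entorhinal", "frontalpole", "fusiform",
    "inferiorparietal", "inferiortemporal", "insula", "isthmuscingulate",
    "lateraloccipital", "lateralorbitofrontal", "lingual",
    "medialorbitofrontal", "middletemporal", "paracentral",
    "parahippocampal", "parsopercularis", "parsorbitalis",
    "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal",
    "temporalpole", "transversetemporal")
}

#' The four cortical measurements
#'
#' Identifiers for the four morphological attributes a CMN can be derived
#' from: maximum principal curvature, mean cortical thickness, mean sulcal
#' depth and mean average curvature.
#'
#' @return Character vector of length 4.
#' @export
cmn_measurements <- function() {
  c("max_principal_curvature", "cortical_thickness", "sulcal_depth",
    "average_curvature")
}
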