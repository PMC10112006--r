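#' Cortical ROI catalog
#'
#' The 36 gyral regions of interest used throughout the package: 18 cortical
#' gyri per hemisphere, labelled `<gyrus>_<L|R>`. The gyrus abbreviations
#' follow common Desikan-style parcellation shorthand (PreCG precentral, PoCG
#' postcentral, STG superior temporal, aMFG/pMFG anterior/posterior middle
#' frontal, SMG supramarginal, aSFG/pSFG anterior/posterior superior frontal,
#' FG fusiform, pIFG posterior inferior frontal, MTG middle temporal, LOG
#' lateral occipital, ITG inferior temporal, OrbF orbitofrontal, MOG medial
#' occipital, SPL superior parietal, PCun precuneus, pCG posterior cingulate).
#'
#' @param hemisphere Optional `"L"` or `"R"` to restrict the catalog.
#' @return Character vector of ROI labels.
#' @examples
#' length(roi_catalog())   # 36
#' head(roi_catalog("L"))
#' @export
roi_catalog <- function(hemisphere = NULL) {
  gyri <- c("PreCG", "PoCG", "STG", "aMFG", "pMFG", "SMG", "aSFG", "pSFG",
            "FG", "pIFG", "MTG", "LOG", "ITG", "OrbF", "MOG", "SPL",
            "PCun", "pCG")
  labs <- c(paste0(gyri, "_L"), paste0(gyri, "_R"))
  if (is.null(hemisphere)) return(labs)
  hemisphere <- match.arg(hemisphere, c("L", "R"))
  labs[endsWith(labs, paste0("_", hemisphere))]
}

#' Hemisphere of an ROI label
#'
#' @param roi Character vector of `<gyrus>_<L|R>` labels.
#' @return `"L"`/`"R"` per element.
#' @export
roi_hemisphere <- function(roi) {
  hem <- sub(".*_", "", roi)
  bad <- !hem %in% c("L", "R")
  if (any(bad)) {
    stop("ROI label(s) without _L/_R hemisphere suffix: ",
         paste(unique(roi[bad]), collapse = ", "))
  }
  hem
}

#' Laterality class of an ROI pair
#'
#' Classifies an unordered ROI pair as `"left-intra"`, `"right-intra"` or
#' `"inter"` from the hemisphere suffixes of its labels.
#'
#' @param roi_a,roi_b Character vectors of ROI labels (recycled pairwise).
#' @return Character vector of laterality classes.
#' @examples
#' laterality_class("STG_L", "PreCG_L")  # "left-intra"
#' laterality_class("STG_L", "STG_R")    # "inter"
#' @export
laterality_class <- function(roi_a, roi_b) {
  ha <- roi_hemisphere(roi_a)
  hb <- roi_hemisphere(roi_b)
  ifelse(ha != hb, "inter",
         ifelse(ha == "L", "left-intra", "right-intra"))
}
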