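# Anatomical trait derivation: vein densities per unit leaf width, mean
# bundle-sheath area per leaf width, and carbon-isotope classification of
# the photosynthetic type.

#' Major and minor vein densities per unit leaf width
#'
#' For parallel-veined grass leaves, vein number per unit leaf width is
#' equivalent to vein length per unit area, so no correction factor is
#' applied.  The minor density (3-5 degree veins) is the trait usually
#' labelled VLA2.
#'
#' @param record an [anatomy_record()].
#' @return Named numeric vector `c(major_vla=, minor_vla=)` in mm^-1.
#' @export
vein_densities <- function(record) {
  stopifnot(inherits(record, "anatomy_record"))
  if (record$leaf_width <= 0) stop("leaf width must be positive")
  c(major_vla = record$major_vein_count / record$leaf_width,
    minor_vla = record$minor_vein_count / record$leaf_width)
}

#' Mean bundle-sheath area per unit leaf width
#'
#' Mean of the total inner and total parenchymatous bundle-sheath
#' cross-sectional areas, each divided by the leaf width:
#' ((IBSA/width) + (PBSA/width)) / 2, with the width converted from mm to
#' um so the result is in um^2 um^-1.
#'
#' @param record an [anatomy_record()].
#' @return BSA per leaf width (um^2 um^-1).
#' @export
bsa_per_leaf_width <- function(record) {
  stopifnot(inherits(record, "anatomy_record"))
  if (record$leaf_width <= 0) stop("leaf width must be positive")
  w_um <- record$leaf_width * 1000
  if (record$total_ibsa == 0 && record$total_pbsa == 0)
    warning("both bundle-sheath areas are zero", call. = FALSE)
  (record$total_ibsa / w_um + record$total_pbsa / w_um) / 2
}

#' Classify photosynthetic type from carbon isotope composition
#'
#' Tissue d13C above -17 per mil indicates C4 carbon fixation; -17 or below
#' is non-C4 (the boundary itself is assigned non-C4, since C4 is defined
#' strictly by d13C higher than the threshold).  Distinguishing C3 from
#' C3-C4 intermediates requires physiological/anatomical evidence and is a
#' user-supplied label, not computed here.
#'
#' @param d13c carbon isotope composition (per mil), vectorised.
#' @param threshold classification threshold (default -17).
#' @return Character vector with values `"C4"`, `"non-C4"` or `NA`
#'   (unclassified, for missing input).
#' @export
classify_photosynthetic_type <- function(d13c, threshold = -17) {
  out <- ifelse(is.na(d13c), NA_character_,
                ifelse(d13c > threshold, "C4", "non-C4"))
  if (any(!is.na(d13c) & (d13c < -40 | d13c > 0)))
    warning("d13C outside the plausible biological range [-40, 0] per mil",
            call. = FALSE)
  out
}

#' Derive the anatomy trait row for one record
#'
#' @param record an [anatomy_record()].
#' @return One-row data frame with vein densities, BSA per leaf width,
#'   leaf thickness, d13C and the classified type.
#' @export
anatomy_traits <- function(record) {
  vd <- vein_densities(record)
  data.frame(id = record$id,
             major_vla = unname(vd["major_vla"]),
             minor_vla = unname(vd["minor_vla"]),
             bsa_per_width = bsa_per_leaf_width(record),
             leaf_thickness = record$leaf_thickness,
             d13c = record$d13c,
             type = classify_photosynthetic_type(record$d13c))
}
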