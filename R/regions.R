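#' Region and side vocabularies
#'
#' The total-body scan area is split into 8 paired regions (16 region-sides):
#' hemihead, arm, forearm, hand, hemipelvis, thigh, leg and foot, each measured
#' on the left and right side. Hemithorax and hemiabdomen are deliberately
#' unrepresentable: the laterality of internal organs makes their two sides
#' incomparable, so the closed vocabulary enforces their exclusion.
#'
#' @return `lo_regions()` returns the character vector of the 8 valid region
#'   names; `lo_sides()` the two valid side labels; `lo_tissues()` the three
#'   tissue compartment names; `lo_diagnoses()` the diagnostic subgroup labels.
#' @export
#' @examples
#' lo_regions()
lo_regions <- function() {
  c("hemihead", "arm", "forearm", "hand", "hemipelvis", "thigh", "leg", "foot")
}

#' @rdname lo_regions
#' @export
lo_sides <- function() c("left", "right")

#' @rdname lo_regions
#' @export
lo_tissues <- function() c("adipose", "muscle", "bone")

#' @rdname lo_regions
#' @export
lo_diagnoses <- function() c("PROS", "BWSp", "ILO", "other")

#' Anatomical region groups used for limb-level analysis
#'
#' Clinical reporting of limb overgrowth pools the segments of a limb, so
#' concordance between clinical labels and DXA calls is evaluated at the level
#' of four region groups: the upper limb (arm, forearm, hand), the lower limb
#' (thigh, leg, foot), and the hemihead and hemipelvis as singletons.
#'
#' @return Named list mapping group name to its member regions.
#' @export
#' @examples
#' region_groups()$upper_limb
region_groups <- function() {
  list(
    upper_limb = c("arm", "forearm", "hand"),
    lower_limb = c("thigh", "leg", "foot"),
    hemihead   = "hemihead",
    hemipelvis = "hemipelvis"
  )
}

#' Map a region to its region group
#' @param region Character vector of region names.
#' @return Character vector of group names.
#' @export
region_group_of <- function(region) {
  groups <- region_groups()
  map <- setNames(rep(names(groups), lengths(groups)), unlist(groups))
  unname(map[region])
}

other_side <- function(side) {
  ifelse(side == "left", "right", "left")
}
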