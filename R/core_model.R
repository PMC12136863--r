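#' Tissue mass triple for one region-side
#'
#' A region-side measurement consists of the adipose (DXA fat), muscle (DXA
#' lean) and bone (DXA bone mineral content) masses in grams. The region total
#' mass m_t is their sum and is always derived, never stored.
#'
#' @param adipose_g,muscle_g,bone_g Non-negative masses in grams.
#' @return Named numeric vector with components `adipose`, `muscle`, `bone`.
#' @export
#' @examples
#' m <- tissue_masses(300, 650, 50)
#' total_mass(m)
tissue_masses <- function(adipose_g, muscle_g, bone_g) {
  m <- c(adipose = as.numeric(adipose_g), muscle = as.numeric(muscle_g),
         bone = as.numeric(bone_g))
  if (anyNA(m) || any(!is.finite(m))) stop("tissue masses must be finite", call. = FALSE)
  if (any(m < 0)) stop("tissue masses must be non-negative", call. = FALSE)
  m
}

#' @rdname tissue_masses
#' @param masses A tissue mass triple as returned by [tissue_masses()].
#' @export
total_mass <- function(masses) {
  unname(masses[["adipose"]] + masses[["muscle"]] + masses[["bone"]])
}

#' Relative tissue composition of a region
#'
#' The relative composition (RC) of each tissue is its mass divided by the
#' region total mass m_t, so RC_A + RC_M + RC_B = 1. RC is dimensionless and
#' scale-invariant: multiplying all masses by a constant leaves it unchanged.
#'
#' @param masses Tissue mass triple ([tissue_masses()]) with positive total.
#' @param region Optional region label used in the error message when the
#'   total mass is zero.
#' @return Named numeric fractions `adipose`, `muscle`, `bone` summing to 1.
#' @export
#' @examples
#' relative_composition(tissue_masses(300, 650, 50))
relative_composition <- function(masses, region = NULL) {
  mt <- total_mass(masses)
  if (mt <= 0) {
    where <- if (is.null(region)) "" else paste0(" in region '", region, "'")
    stop("zero total mass", where, ": relative composition undefined", call. = FALSE)
  }
  masses / mt
}

#' Total-mass discrepancy ratio between paired regions
#'
#' The signed fractional difference in total mass between the affected region
#' and its contralateral homologue:
#' `(m_t affected - m_t contralateral) / m_t contralateral`.
#' Negative values mean the candidate-affected side is the lighter one.
#'
#' @param mt_affected_g Total mass of the (candidate) affected region, grams.
#' @param mt_contra_g Total mass of the contralateral homologue, grams; must
#'   be strictly positive.
#' @return Signed fraction (0.18 means the affected side is 18% heavier).
#' @export
#' @examples
#' mt_discrepancy_ratio(1180, 1000)
mt_discrepancy_ratio <- function(mt_affected_g, mt_contra_g) {
  if (any(!is.finite(mt_affected_g)) || any(!is.finite(mt_contra_g))) {
    stop("masses must be finite", call. = FALSE)
  }
  if (any(mt_contra_g <= 0)) {
    stop("contralateral total mass must be positive", call. = FALSE)
  }
  (mt_affected_g - mt_contra_g) / mt_contra_g
}

#' Call lateralized overgrowth from a discrepancy ratio
#'
#' LO is called when the discrepancy ratio meets or exceeds the configured
#' cut-off (default 10%). The boundary is inclusive, so a ratio of exactly
#' 0.10 is flagged.
#'
#' @param ratio Signed discrepancy ratio(s).
#' @param config An [analysis_config()].
#' @return Logical vector of LO calls.
#' @export
#' @examples
#' call_lo(c(0.18, 0.08, 0.10))
call_lo <- function(ratio, config = analysis_config()) {
  if (any(!is.finite(ratio))) stop("ratio must be finite", call. = FALSE)
  ratio >= config$lo_threshold
}

#' Composition discrepancy between affected and contralateral regions
#'
#' dRC is the componentwise difference between the RC of the affected
#' region(s) and that of the contralateral unaffected region(s), reported in
#' percentage points. Because both RC vectors sum to 1, the three dRC
#' components sum to 0.
#'
#' @param rc_affected,rc_contra RC vectors from [relative_composition()].
#' @return Named numeric vector (`adipose`, `muscle`, `bone`) in percentage
#'   points, summing to zero.
#' @export
#' @examples
#' delta_rc(c(adipose = 0.32, muscle = 0.65, bone = 0.03),
#'          c(adipose = 0.30, muscle = 0.67, bone = 0.03))
delta_rc <- function(rc_affected, rc_contra) {
  check_rc(rc_affected, "rc_affected")
  check_rc(rc_contra, "rc_contra")
  100 * (rc_affected[lo_tissues()] - rc_contra[lo_tissues()])
}

check_rc <- function(rc, what) {
  if (!all(lo_tissues() %in% names(rc))) {
    stop(what, " must have components ", paste(lo_tissues(), collapse = ", "),
         call. = FALSE)
  }
  rc <- rc[lo_tissues()]
  if (any(!is.finite(rc)) || any(rc < 0) || any(rc > 1)) {
    stop(what, " components must be fractions in [0, 1]", call. = FALSE)
  }
  if (abs(sum(rc) - 1) > 1e-9) {
    stop(what, " components must sum to 1 (got ", format(sum(rc)), ")", call. = FALSE)
  }
  invisible(rc)
}

#' Predominant overgrown tissue
#'
#' The tissue with the largest dRC in the affected region (aggregate) marks
#' the predominant overgrown tissue. Exact ties are broken by the fixed
#' priority in `config$tie_order` (default adipose, then muscle, then bone).
#'
#' @param delta A dRC vector from [delta_rc()], percentage points.
#' @param config An [analysis_config()].
#' @return One of `"adipose"`, `"muscle"`, `"bone"`.
#' @export
#' @examples
#' classify_predominant(c(adipose = 2.0, muscle = -1.5, bone = -0.3))
classify_predominant <- function(delta, config = analysis_config()) {
  d <- delta[lo_tissues()]
  if (anyNA(d) || any(!is.finite(d))) stop("delta components must be finite", call. = FALSE)
  best <- lo_tissues()[d == max(d)]
  config$tie_order[config$tie_order %in% best][1L]
}

#' Sum tissue masses over a set of affected region-sides
#'
#' For multi-region LO, masses are summed componentwise over the named
#' affected region-sides and, in mirror, over their contralateral homologues;
#' RC and dRC are then computed on the summed masses.
#'
#' @param scan A [patient_scan()].
#' @param regions Data frame with columns `region` and `side` naming the
#'   affected region-sides; must be non-empty, contain each region at most
#'   once, and every named region-side and its mirror must be measured.
#' @return List with tissue mass triples `affected` and `contralateral`.
#' @export
aggregate_regions <- function(scan, regions) {
  stopifnot(inherits(scan, "lo_scan"))
  regions <- as.data.frame(regions)
  if (nrow(regions) == 0L) {
    stop("empty affected set: nothing to aggregate", call. = FALSE)
  }
  if (anyDuplicated(regions$region)) {
    stop("a region cannot be aggregated with both sides affected: ",
         paste(unique(regions$region[duplicated(regions$region)]), collapse = ", "),
         call. = FALSE)
  }
  meas <- scan$measurements
  key <- paste(meas$region, meas$side)
  pick <- function(region, side) {
    i <- match(paste(region, side), key)
    if (anyNA(i)) {
      miss <- paste(region, side)[is.na(i)]
      stop("region-side not measured in scan '", scan$patient_id, "': ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    tissue_masses(sum(meas$fat_mass_g[i]), sum(meas$lean_mass_g[i]),
                  sum(meas$bmc_g[i]))
  }
  list(
    affected = pick(regions$region, regions$side),
    contralateral = pick(regions$region, other_side(regions$side))
  )
}
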