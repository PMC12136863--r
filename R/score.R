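#' Score a patient scan
#'
#' Runs the full region-pair analysis for one patient: for every region
#' measured on both sides it computes the total-mass discrepancy ratio, the
#' relative composition of both sides, the composition discrepancy dRC and
#' the LO call. When the region carries a clinical label the clinically
#' affected side anchors the ratio; otherwise the heavier side is treated as
#' candidate-affected and the orientation is recorded. If the scan has a
#' non-empty clinical affected set, an aggregate result over the summed
#' affected (and mirrored contralateral) masses is also produced, including
#' the predominant overgrown tissue.
#'
#' Regions measured on only one side are skipped with a warning, never
#' imputed.
#'
#' @param scan A [patient_scan()].
#' @param config An [analysis_config()].
#' @return Object of class `lo_score`: a list with `patient_id`, `diagnosis`,
#'   `regions` (data frame, one row per bilateral region) and `aggregate`
#'   (one-row data frame over the clinical affected set, or `NULL`).
#' @export
#' @examples
#' m <- expand.grid(side = c("left", "right"), region = c("thigh", "leg"),
#'                  stringsAsFactors = FALSE)
#' m$fat_mass_g <- c(2400, 2000, 900, 760)
#' m$lean_mass_g <- c(5200, 4600, 2600, 2300)
#' m$bmc_g <- c(310, 300, 160, 150)
#' s <- patient_scan("p1", m,
#'                   clinical_affected = data.frame(region = c("thigh", "leg"),
#'                                                  side = "left"))
#' score_patient(s)
score_patient <- function(scan, config = analysis_config()) {
  stopifnot(inherits(scan, "lo_scan"))
  meas <- scan$measurements
  key <- paste(meas$region, meas$side)

  candidates <- intersect(lo_regions(), unique(meas$region))
  rows <- vector("list", length(candidates))
  for (k in seq_along(candidates)) {
    region <- candidates[k]
    iL <- match(paste(region, "left"), key)
    iR <- match(paste(region, "right"), key)
    if (is.na(iL) || is.na(iR)) {
      warning("patient '", scan$patient_id, "': region '", region,
              "' measured on one side only; skipped", call. = FALSE)
      next
    }
    clin <- scan$clinical_affected
    clin_side <- clin$side[clin$region == region]
    masses <- list(
      left = tissue_masses(meas$fat_mass_g[iL], meas$lean_mass_g[iL], meas$bmc_g[iL]),
      right = tissue_masses(meas$fat_mass_g[iR], meas$lean_mass_g[iR], meas$bmc_g[iR])
    )
    mt <- c(left = total_mass(masses$left), right = total_mass(masses$right))
    if (length(clin_side) == 1L) {
      aff <- clin_side
      orientation <- "clinical"
    } else {
      aff <- if (mt[["right"]] > mt[["left"]]) "right" else "left"
      orientation <- "heavier"
    }
    con <- other_side(aff)
    rc_aff <- relative_composition(masses[[aff]], region)
    rc_con <- relative_composition(masses[[con]], region)
    d <- delta_rc(rc_aff, rc_con)
    ratio <- mt_discrepancy_ratio(mt[[aff]], mt[[con]])
    rows[[k]] <- result_row("region", region, aff, orientation, mt[[aff]],
                            mt[[con]], ratio, rc_aff, rc_con, d,
                            call_lo(ratio, config), NA_character_)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  regions_df <- if (length(rows)) {
    as.data.frame(do.call(Map, c(list(f = c), rows)), stringsAsFactors = FALSE)
  } else empty_result_rows()

  aggregate_df <- NULL
  if (nrow(scan$clinical_affected)) {
    agg <- aggregate_regions(scan, scan$clinical_affected)
    mt_aff <- total_mass(agg$affected)
    mt_con <- total_mass(agg$contralateral)
    rc_aff <- relative_composition(agg$affected, "aggregate")
    rc_con <- relative_composition(agg$contralateral, "aggregate")
    d <- delta_rc(rc_aff, rc_con)
    ratio <- mt_discrepancy_ratio(mt_aff, mt_con)
    ca <- scan$clinical_affected
    aggregate_df <- as.data.frame(
      result_row("aggregate", paste(ca$region, collapse = "+"),
                 paste(unique(ca$side), collapse = "+"), "clinical",
                 mt_aff, mt_con, ratio, rc_aff, rc_con, d,
                 call_lo(ratio, config), classify_predominant(d, config)),
      stringsAsFactors = FALSE
    )
  }

  structure(
    list(patient_id = scan$patient_id, diagnosis = scan$diagnosis,
         regions = regions_df, aggregate = aggregate_df),
    class = "lo_score"
  )
}

result_row <- function(scope, region, affected_side, orientation, mt_aff,
                       mt_con, ratio, rc_aff, rc_con, d, lo, predominant) {
  list(scope = scope, region = region, affected_side = affected_side,
       orientation = orientation, mt_affected_g = mt_aff, mt_contra_g = mt_con,
       discrepancy_ratio = ratio,
       rc_affected_adipose = rc_aff[["adipose"]],
       rc_affected_muscle = rc_aff[["muscle"]],
       rc_affected_bone = rc_aff[["bone"]],
       rc_contra_adipose = rc_con[["adipose"]],
       rc_contra_muscle = rc_con[["muscle"]],
       rc_contra_bone = rc_con[["bone"]],
       delta_rc_adipose = d[["adipose"]],
       delta_rc_muscle = d[["muscle"]],
       delta_rc_bone = d[["bone"]],
       lo_call = lo, predominant_tissue = predominant)
}

empty_result_rows <- function() {
  data.frame(
    scope = character(), region = character(), affected_side = character(),
    orientation = character(), mt_affected_g = numeric(), mt_contra_g = numeric(),
    discrepancy_ratio = numeric(),
    rc_affected_adipose = numeric(), rc_affected_muscle = numeric(),
    rc_affected_bone = numeric(), rc_contra_adipose = numeric(),
    rc_contra_muscle = numeric(), rc_contra_bone = numeric(),
    delta_rc_adipose = numeric(), delta_rc_muscle = numeric(),
    delta_rc_bone = numeric(), lo_call = logical(),
    predominant_tissue = character(), stringsAsFactors = FALSE
  )
}

#' @export
print.lo_score <- function(x, ...) {
  cat(sprintf("<lo_score> patient %s (%s): %d region pairs, %d LO calls\n",
              x$patient_id, x$diagnosis, nrow(x$regions), sum(x$regions$lo_call)))
  if (!is.null(x$aggregate)) {
    cat(sprintf("  aggregate [%s | %s]: ratio %.1f%%, LO %s, predominant %s\n",
                x$aggregate$region, x$aggregate$affected_side,
                100 * x$aggregate$discrepancy_ratio,
                x$aggregate$lo_call, x$aggregate$predominant_tissue))
  }
  invisible(x)
}

#' Score every patient in a cohort
#'
#' @param cohort An [lo_cohort()] (or plain list of scans).
#' @param config An [analysis_config()].
#' @return Object of class `lo_scored_cohort`: list with `scores` (named list
#'   of [score_patient()] results) and `results` (the combined tidy results
#'   table, one row per patient-region plus one `scope = "aggregate"` row per
#'   labeled patient, with `patient_id` and `diagnosis` columns).
#' @export
score_cohort <- function(cohort, config = analysis_config()) {
  if (!inherits(cohort, "lo_cohort")) cohort <- lo_cohort(cohort)
  scores <- lapply(cohort, score_patient, config = config)
  tabs <- lapply(scores, function(s) {
    tab <- rbind(s$regions, s$aggregate)
    if (nrow(tab) == 0L) return(NULL)
    cbind(data.frame(patient_id = s$patient_id, diagnosis = s$diagnosis,
                     stringsAsFactors = FALSE), tab)
  })
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  results <- if (length(tabs)) do.call(rbind, c(tabs, make.row.names = FALSE)) else
    cbind(data.frame(patient_id = character(), diagnosis = character(),
                     stringsAsFactors = FALSE), empty_result_rows())
  structure(list(scores = scores, results = results), class = "lo_scored_cohort")
}

#' @export
print.lo_scored_cohort <- function(x, ...) {
  agg <- x$results[x$results$scope == "aggregate", , drop = FALSE]
  cat(sprintf("<lo_scored_cohort> %d patients, %d aggregate results, %d aggregate LO calls\n",
              length(x$scores), nrow(agg), sum(agg$lo_call)))
  invisible(x)
}
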