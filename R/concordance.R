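#' DXA overgrowth calls at region-group level
#'
#' Sums tissue masses over each anatomical region group ([region_groups()])
#' per side, computes the total-mass discrepancy ratio with either side as
#' candidate-affected, and makes the LO call on the heavier side's ratio.
#' Groups with any member region missing on either side are skipped with a
#' warning.
#'
#' @param scan A [patient_scan()].
#' @param config An [analysis_config()].
#' @param granularity `"group"` (default, limbs pooled) or `"region"`
#'   (each region its own group).
#' @return Data frame with one row per evaluable group: `group`,
#'   `ratio_left`, `ratio_right` (each side as candidate-affected),
#'   `heavier_side`, `ratio` (the heavier side's), `lo_call`.
#' @export
dxa_calls <- function(scan, config = analysis_config(),
                      granularity = c("group", "region")) {
  granularity <- match.arg(granularity)
  stopifnot(inherits(scan, "lo_scan"))
  groups <- if (granularity == "group") region_groups() else
    setNames(as.list(lo_regions()), lo_regions())
  meas <- scan$measurements
  key <- paste(meas$region, meas$side)

  rows <- list()
  for (gname in names(groups)) {
    members <- groups[[gname]]
    present <- intersect(members, unique(meas$region))
    need <- c(paste(members, "left"), paste(members, "right"))
    if (!all(need %in% key)) {
      if (length(present)) {
        warning("patient '", scan$patient_id, "': group '", gname,
                "' incomplete on one side; skipped", call. = FALSE)
      }
      next
    }
    mt_side <- function(side) {
      i <- match(paste(members, side), key)
      sum(meas$fat_mass_g[i] + meas$lean_mass_g[i] + meas$bmc_g[i])
    }
    mtL <- mt_side("left"); mtR <- mt_side("right")
    rL <- mt_discrepancy_ratio(mtL, mtR)
    rR <- mt_discrepancy_ratio(mtR, mtL)
    heavier <- if (mtR > mtL) "right" else "left"
    ratio <- if (heavier == "left") rL else rR
    rows[[gname]] <- data.frame(
      group = gname, ratio_left = rL, ratio_right = rR,
      heavier_side = heavier, ratio = ratio,
      lo_call = call_lo(ratio, config), stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(group = character(), ratio_left = numeric(),
                      ratio_right = numeric(), heavier_side = character(),
                      ratio = numeric(), lo_call = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Concordance between clinical labels and DXA calls for one patient
#'
#' A patient is concordant when every clinically affected region group is
#' also called LO by DXA on the same side. Clinical groups whose
#' clinical-side ratio falls in the near-threshold band
#' `[lo_threshold - near_threshold_band, lo_threshold)` are flagged
#' `near_threshold`; DXA calls on groups with no clinical label are listed
#' as `dxa_only` (they do not break concordance); a DXA call on the side
#' opposite the clinical label is `opposite_side` and discordant.
#'
#' @inheritParams dxa_calls
#' @return List with `concordant` (logical), `details` (per clinical group:
#'   `group`, `side`, `ratio` anchored on the clinical side, `status`), and
#'   `dxa_only` (data frame of unlabeled DXA-positive groups).
#' @export
patient_concordance <- function(scan, config = analysis_config(),
                                granularity = c("group", "region")) {
  granularity <- match.arg(granularity)
  if (nrow(scan$clinical_affected) == 0L) {
    stop("patient '", scan$patient_id,
         "' has no clinical labels: excluded from concordance", call. = FALSE)
  }
  calls <- dxa_calls(scan, config, granularity)
  ca <- scan$clinical_affected
  ca$group <- if (granularity == "group") region_group_of(ca$region) else ca$region
  clin <- unique(ca[c("group", "side")])

  details <- lapply(seq_len(nrow(clin)), function(i) {
    g <- clin$group[i]; s <- clin$side[i]
    row <- calls[calls$group == g, , drop = FALSE]
    if (nrow(row) == 0L) {
      return(data.frame(group = g, side = s, ratio = NA_real_,
                        status = "unevaluable", stringsAsFactors = FALSE))
    }
    r_clin <- if (s == "left") row$ratio_left else row$ratio_right
    status <- if (row$lo_call && row$heavier_side == s) {
      "confirmed"
    } else if (row$lo_call && row$heavier_side != s) {
      "opposite_side"
    } else if (r_clin >= config$lo_threshold - config$near_threshold_band &&
               r_clin < config$lo_threshold) {
      "near_threshold"
    } else {
      "below_threshold"
    }
    data.frame(group = g, side = s, ratio = r_clin, status = status,
               stringsAsFactors = FALSE)
  })
  details <- do.call(rbind, c(details, make.row.names = FALSE))

  called <- calls[calls$lo_call, , drop = FALSE]
  labeled <- paste(clin$group, clin$side)
  extra <- called[!paste(called$group, called$heavier_side) %in% labeled, ,
                  drop = FALSE]
  dxa_only <- data.frame(group = extra$group, side = extra$heavier_side,
                         ratio = extra$ratio, stringsAsFactors = FALSE)

  list(concordant = all(details$status == "confirmed"), details = details,
       dxa_only = dxa_only)
}

#' Cohort-level clinical-DXA concordance report
#'
#' Aggregates [patient_concordance()] over a labeled cohort. Patients whose
#' clinical affected set is empty are excluded from the rate's denominator
#' and listed separately.
#'
#' @param cohort An [lo_cohort()] with clinical labels attached.
#' @inheritParams dxa_calls
#' @return Object of class `lo_concordance`: list with `n_patients`,
#'   `n_evaluated`, `n_concordant`, `concordance_fraction`, and pooled
#'   `near_threshold`, `dxa_only`, `opposite_side` tables (each with
#'   `patient_id`, `group`, `side`, `ratio`), plus `excluded_patients`.
#' @export
cohort_concordance <- function(cohort, config = analysis_config(),
                               granularity = c("group", "region")) {
  granularity <- match.arg(granularity)
  if (!inherits(cohort, "lo_cohort")) cohort <- lo_cohort(cohort)
  labeled <- vapply(cohort, function(s) nrow(s$clinical_affected) > 0L, logical(1))
  if (!any(labeled)) stop("no patient has clinical labels: nothing to evaluate",
                          call. = FALSE)
  empty_tab <- data.frame(patient_id = character(), group = character(),
                          side = character(), ratio = numeric(),
                          stringsAsFactors = FALSE)
  near <- dxa_only <- opposite <- empty_tab
  n_conc <- 0L
  for (scan in cohort[labeled]) {
    pc <- patient_concordance(scan, config, granularity)
    n_conc <- n_conc + pc$concordant
    pick <- function(df, status = NULL) {
      if (!is.null(status)) df <- df[df$status == status, , drop = FALSE]
      if (nrow(df) == 0L) return(NULL)
      data.frame(patient_id = scan$patient_id, group = df$group, side = df$side,
                 ratio = df$ratio, stringsAsFactors = FALSE)
    }
    near <- rbind(near, pick(pc$details, "near_threshold"))
    opposite <- rbind(opposite, pick(pc$details, "opposite_side"))
    dxa_only <- rbind(dxa_only, pick(pc$dxa_only))
  }
  structure(
    list(n_patients = length(cohort), n_evaluated = sum(labeled),
         n_concordant = n_conc,
         concordance_fraction = n_conc / sum(labeled),
         near_threshold = near, dxa_only = dxa_only, opposite_side = opposite,
         excluded_patients = names(cohort)[!labeled]),
    class = "lo_concordance"
  )
}

#' @export
print.lo_concordance <- function(x, ...) {
  cat(sprintf("<lo_concordance> %d/%d patients concordant (%.0f%%); %d excluded (no labels)\n",
              x$n_concordant, x$n_evaluated, 100 * x$concordance_fraction,
              length(x$excluded_patients)))
  if (nrow(x$near_threshold)) {
    cat("near-threshold clinical findings:\n")
    for (i in seq_len(nrow(x$near_threshold))) {
      cat(sprintf("  %s %s (%s): %.1f%%\n", x$near_threshold$patient_id[i],
                  x$near_threshold$group[i], x$near_threshold$side[i],
                  100 * x$near_threshold$ratio[i]))
    }
  }
  if (nrow(x$dxa_only)) {
    cat("DXA-positive, clinically unlabeled:\n")
    for (i in seq_len(nrow(x$dxa_only))) {
      cat(sprintf("  %s %s (%s): %.1f%%\n", x$dxa_only$patient_id[i],
                  x$dxa_only$group[i], x$dxa_only$side[i],
                  100 * x$dxa_only$ratio[i]))
    }
  }
  invisible(x)
}

#' Write a concordance report as JSON
#'
#' @param report An `lo_concordance`.
#' @param path Output JSON path.
#' @return (Invisibly) the path written.
#' @export
write_concordance_json <- function(report, path) {
  stopifnot(inherits(report, "lo_concordance"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
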