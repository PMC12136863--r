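#' Construct a patient scan
#'
#' Bundles one patient's regional DXA measurements with clinical metadata.
#' A full scan carries 16 region-side records (8 paired regions), but partial
#' scans are allowed; regions missing a side are skipped (with a warning)
#' wherever a bilateral comparison is required.
#'
#' @param patient_id Opaque patient identifier string.
#' @param measurements Data frame with columns `region`, `side`,
#'   `fat_mass_g`, `lean_mass_g`, `bmc_g`; at most one row per (region, side).
#' @param diagnosis One of `"PROS"`, `"BWSp"`, `"ILO"`, `"other"`.
#' @param clinical_affected Data frame with columns `region`, `side` listing
#'   the region-sides judged affected at clinical examination (may be empty).
#'   Each listed region-side must be measured, and a region cannot be
#'   clinically affected on both sides.
#' @param sex `"M"`, `"F"` or `"unknown"`.
#' @param age_years Non-negative age in years (NA allowed).
#' @return An object of class `lo_scan`.
#' @export
#' @examples
#' m <- data.frame(region = c("thigh", "thigh"), side = c("left", "right"),
#'                 fat_mass_g = c(2400, 2000), lean_mass_g = c(5200, 4600),
#'                 bmc_g = c(310, 300))
#' patient_scan("p1", m,
#'              clinical_affected = data.frame(region = "thigh", side = "left"))
patient_scan <- function(patient_id, measurements, diagnosis = "other",
                         clinical_affected = NULL, sex = "unknown",
                         age_years = NA_real_) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L, nzchar(patient_id))
  diagnosis <- match.arg(diagnosis, lo_diagnoses())
  sex <- match.arg(sex, c("M", "F", "unknown"))
  if (!is.na(age_years) && age_years < 0) stop("age_years must be >= 0", call. = FALSE)

  measurements <- as.data.frame(measurements)
  need <- c("region", "side", "fat_mass_g", "lean_mass_g", "bmc_g")
  if (!all(need %in% names(measurements))) {
    stop("measurements must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  measurements <- measurements[need]
  measurements$region <- as.character(measurements$region)
  measurements$side <- as.character(measurements$side)
  check_vocab(measurements$region, lo_regions(), "region")
  check_vocab(measurements$side, lo_sides(), "side")
  for (col in c("fat_mass_g", "lean_mass_g", "bmc_g")) {
    v <- measurements[[col]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      stop(col, " must be finite numeric", call. = FALSE)
    }
    if (any(v < 0)) stop(col, " must be non-negative", call. = FALSE)
  }
  dup <- duplicated(measurements[c("region", "side")])
  if (any(dup)) {
    stop("duplicate (region, side) in measurements for patient '", patient_id,
         "': ", paste(unique(paste(measurements$region[dup],
                                   measurements$side[dup])), collapse = ", "),
         call. = FALSE)
  }
  ord <- order(match(measurements$region, lo_regions()),
               match(measurements$side, lo_sides()))
  measurements <- measurements[ord, , drop = FALSE]
  rownames(measurements) <- NULL

  if (is.null(clinical_affected)) {
    clinical_affected <- data.frame(region = character(), side = character())
  }
  clinical_affected <- as.data.frame(clinical_affected)[c("region", "side")]
  clinical_affected$region <- as.character(clinical_affected$region)
  clinical_affected$side <- as.character(clinical_affected$side)
  if (nrow(clinical_affected)) {
    check_vocab(clinical_affected$region, lo_regions(), "region")
    check_vocab(clinical_affected$side, lo_sides(), "side")
    clinical_affected <- unique(clinical_affected)
    if (anyDuplicated(clinical_affected$region)) {
      stop("both sides of a region marked clinically affected for patient '",
           patient_id, "'", call. = FALSE)
    }
    have <- paste(measurements$region, measurements$side)
    want <- paste(clinical_affected$region, clinical_affected$side)
    if (!all(want %in% have)) {
      stop("clinically affected region-side not measured for patient '",
           patient_id, "': ", paste(setdiff(want, have), collapse = ", "),
           call. = FALSE)
    }
    rownames(clinical_affected) <- NULL
  }

  structure(
    list(patient_id = patient_id, diagnosis = diagnosis, sex = sex,
         age_years = as.numeric(age_years), measurements = measurements,
         clinical_affected = clinical_affected),
    class = "lo_scan"
  )
}

check_vocab <- function(x, vocab, what) {
  bad <- setdiff(unique(x), vocab)
  if (length(bad)) {
    stop("unknown ", what, " token(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(vocab, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.lo_scan <- function(x, ...) {
  cat(sprintf("<lo_scan> patient %s (%s, %s, age %s)\n", x$patient_id,
              x$diagnosis, x$sex,
              if (is.na(x$age_years)) "?" else format(x$age_years)))
  cat(sprintf("  %d region-side measurements; %d clinically affected\n",
              nrow(x$measurements), nrow(x$clinical_affected)))
  invisible(x)
}

#' Bundle patient scans into a cohort
#'
#' @param scans List of [patient_scan()] objects with unique patient ids.
#' @return Object of class `lo_cohort` (a named list of scans).
#' @export
lo_cohort <- function(scans) {
  stopifnot(is.list(scans))
  ok <- vapply(scans, inherits, logical(1), "lo_scan")
  if (!all(ok)) stop("all elements must be lo_scan objects", call. = FALSE)
  ids <- vapply(scans, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids)) {
    stop("duplicate patient ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  structure(setNames(scans, ids), class = "lo_cohort")
}

#' @export
print.lo_cohort <- function(x, ...) {
  dx <- table(vapply(x, `[[`, character(1), "diagnosis"))
  cat(sprintf("<lo_cohort> %d patients (%s)\n", length(x),
              paste(sprintf("%s: %d", names(dx), dx), collapse = ", ")))
  invisible(x)
}
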