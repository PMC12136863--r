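#' Read a regional scan table
#'
#' Reads the canonical comma-separated scan export: one row per patient x
#' region x side with columns `patient_id,region,side,fat_mass_g,lean_mass_g,
#' bmc_g` (masses in grams). Validation is strict: unknown region or side
#' tokens, duplicate (patient, region, side) triples, malformed or negative
#' masses each raise an error naming the offending file line.
#'
#' @param path Path to the scans CSV.
#' @param column_map Optional named character vector mapping canonical column
#'   names to the vendor's header names, e.g.
#'   `c(fat_mass_g = "FatMass(g)")`, applied before validation.
#' @return An [lo_cohort()], one [patient_scan()] per `patient_id` (diagnosis
#'   `"other"` and empty clinical set until [read_labels()] attaches them).
#' @export
read_scans <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("scan file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 encoding = "UTF-8", check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      j <- match(column_map[[canon]], names(df))
      if (!is.na(j)) names(df)[j] <- canon
    }
  }
  need <- c("patient_id", "region", "side", "fat_mass_g", "lean_mass_g", "bmc_g")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("scan file ", path, " missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[need]
  line <- seq_len(nrow(df)) + 1L  # header is line 1

  bad <- !df$region %in% lo_regions()
  if (any(bad)) {
    stop_at(path, line[bad][1], "unknown region token '", df$region[bad][1], "'")
  }
  bad <- !df$side %in% lo_sides()
  if (any(bad)) {
    stop_at(path, line[bad][1], "unknown side token '", df$side[bad][1], "'")
  }
  for (col in c("fat_mass_g", "lean_mass_g", "bmc_g")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v) | !is.finite(v)
    if (any(bad)) {
      stop_at(path, line[bad][1], "malformed number in ", col, ": '",
              df[[col]][bad][1], "'")
    }
    if (any(v < 0)) {
      stop_at(path, line[v < 0][1], "negative mass in ", col)
    }
    df[[col]] <- v
  }
  dup <- duplicated(df[c("patient_id", "region", "side")])
  if (any(dup)) {
    stop_at(path, line[dup][1], "duplicate (patient, region, side): ",
            paste(df$patient_id[dup][1], df$region[dup][1], df$side[dup][1]))
  }

  ids <- unique(df$patient_id)
  scans <- lapply(ids, function(id) {
    patient_scan(id, df[df$patient_id == id,
                        c("region", "side", "fat_mass_g", "lean_mass_g", "bmc_g")])
  })
  message(sprintf("read %d rows for %d patient(s) from %s", nrow(df), length(ids), path))
  lo_cohort(scans)
}

stop_at <- function(path, line, ...) {
  stop(basename(path), " line ", line, ": ", ..., call. = FALSE)
}

#' Attach clinical labels to a cohort
#'
#' Reads the clinical label table (`patient_id,diagnosis,region,side,affected`)
#' and populates each scan's diagnosis and clinical affected set. Regions not
#' listed default to not-affected. `affected` accepts 0/1, TRUE/FALSE,
#' true/false, yes/no.
#'
#' @param path Path to the labels CSV.
#' @param cohort The [lo_cohort()] the labels refer to; every labeled
#'   (patient, region, side) must exist in it.
#' @return The cohort with `diagnosis` and `clinical_affected` populated.
#' @export
read_labels <- function(path, cohort) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  stopifnot(inherits(cohort, "lo_cohort"))
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 encoding = "UTF-8")
  need <- c("patient_id", "diagnosis", "region", "side", "affected")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("label file ", path, " missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  line <- seq_len(nrow(df)) + 1L

  bad <- !df$patient_id %in% names(cohort)
  if (any(bad)) {
    stop_at(path, line[bad][1], "label for unknown patient '", df$patient_id[bad][1], "'")
  }
  bad <- !df$diagnosis %in% lo_diagnoses()
  if (any(bad)) {
    stop_at(path, line[bad][1], "unknown diagnosis token '", df$diagnosis[bad][1], "'")
  }
  bad <- !df$region %in% lo_regions()
  if (any(bad)) {
    stop_at(path, line[bad][1], "unknown region token '", df$region[bad][1], "'")
  }
  bad <- !df$side %in% lo_sides()
  if (any(bad)) {
    stop_at(path, line[bad][1], "unknown side token '", df$side[bad][1], "'")
  }
  aff <- tolower(df$affected) %in% c("1", "true", "yes")
  bad <- !tolower(df$affected) %in% c("0", "1", "true", "false", "yes", "no")
  if (any(bad)) {
    stop_at(path, line[bad][1], "malformed affected flag '", df$affected[bad][1], "'")
  }

  scans <- lapply(names(cohort), function(id) {
    scan <- cohort[[id]]
    rows <- df[df$patient_id == id, , drop = FALSE]
    dx <- unique(rows$diagnosis)
    if (length(dx) > 1L) {
      stop("conflicting diagnoses for patient '", id, "' in ", basename(path),
           call. = FALSE)
    }
    ca <- rows[aff[df$patient_id == id], c("region", "side"), drop = FALSE]
    patient_scan(id, scan$measurements,
                 diagnosis = if (length(dx)) dx else scan$diagnosis,
                 clinical_affected = ca, sex = scan$sex,
                 age_years = scan$age_years)
  })
  lo_cohort(scans)
}

#' Write and re-read a results table
#'
#' Writes the combined results of [score_cohort()] with a deterministic
#' column order: all full-precision numeric columns, plus 1-decimal display
#' columns (`discrepancy_pct`, e.g. `"18.0%"`, and `predominant_tissue`)
#' for reading. Re-reading with [read_results()] reproduces the
#' full-precision values bit-exactly.
#'
#' @param results Either an `lo_scored_cohort` or its `$results` data frame.
#' @param path Output CSV path.
#' @return (Invisibly) the path written.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "lo_scored_cohort")) results <- results$results
  results <- as.data.frame(results)
  out <- results
  out$discrepancy_pct <- sprintf("%.1f%%", 100 * out$discrepancy_ratio)
  con <- file(path, open = "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  write.csv(format_full_precision(out), con, row.names = FALSE, quote = TRUE,
            eol = "\n")
  invisible(path)
}

# serialize doubles with enough digits for exact round-trip
format_full_precision <- function(df) {
  for (col in names(df)) {
    if (is.double(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  }
  df
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  df$lo_call <- as.logical(df$lo_call)
  df$discrepancy_pct <- NULL
  df$predominant_tissue <- as.character(df$predominant_tissue)
  df$predominant_tissue[df$predominant_tissue == ""] <- NA_character_
  df
}
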