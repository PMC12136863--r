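#' Default synthetic-cohort generator configuration
#'
#' Returns the generator parameterization emulating the study conditions the
#' analysis assumes. Per diagnostic subgroup (PROS, BWSp, ILO) it carries the
#' contralateral RC means/SDs and the dRC means/SDs (percentage points) of
#' the adipose and bone compartments — muscle is closed out so RC sums to 1
#' and dRC to 0 — together with the overgrowth-ratio distribution (truncated
#' normal, mean 0.25, SD 0.10, floor 0.10 so every masked region clears the
#' LO cut-off before noise), the physiological asymmetry SD on unaffected
#' regions (0.02), a small per-region RC noise SD (0.005), and the clinical
#' labeling sensitivity (1.0 = labels equal the true mask). Subgroup mix
#' defaults to 28:11:7 (61% PROS, 24% BWSp, 15% ILO) for a 46-patient cohort.
#'
#' Base region masses are an adult-scale phantom (e.g. thigh 7000 g, hand
#' 400 g); by scale invariance of RC they do not affect composition
#' statistics. The affected-mask catalog is a weighted list of region-side
#' sets built from complete region groups (lower limb, upper limb, hemihead,
#' limb combinations, hemibody, hemipelvis+lower limb).
#'
#' @return Object of class `lo_generator_config`.
#' @export
#' @examples
#' cfg <- default_generator_config()
#' cfg$subgroups$PROS$contra_rc_mean
default_generator_config <- function() {
  subgroup <- function(contra_mean, contra_sd, delta_mean, delta_sd,
                       age_mean, age_sd) {
    list(
      contra_rc_mean = contra_mean,   # fractions; muscle implied by closure
      contra_rc_sd = contra_sd,
      delta_rc_mean = delta_mean,     # percentage points; muscle = -(adipose+bone)
      delta_rc_sd = delta_sd,
      overgrowth_ratio_mean = 0.25,
      overgrowth_ratio_sd = 0.10,
      overgrowth_ratio_floor = 0.10,
      unaffected_asym_sd = 0.02,
      rc_noise_sd = 0.005,
      clinical_sensitivity = 1.0,
      age_mean = age_mean, age_sd = age_sd
    )
  }
  cfg <- list(
    n_patients = 46L,
    seed = 1L,
    subgroup_counts = c(PROS = 28L, BWSp = 11L, ILO = 7L),
    base_mass_g = c(hemihead = 2500, arm = 1800, forearm = 900, hand = 400,
                    hemipelvis = 4000, thigh = 7000, leg = 2800, foot = 900),
    mt_lognorm_sd = 0.15,
    mask_catalog = list(
      list(name = "lower_limb", members = c("thigh", "leg", "foot"), weight = 0.35),
      list(name = "upper_limb", members = c("arm", "forearm", "hand"), weight = 0.20),
      list(name = "hemihead", members = "hemihead", weight = 0.15),
      list(name = "upper_and_lower_limb",
           members = c("arm", "forearm", "hand", "thigh", "leg", "foot"),
           weight = 0.10),
      list(name = "hemibody", members = lo_regions(), weight = 0.10),
      list(name = "pelvis_and_lower_limb",
           members = c("hemipelvis", "thigh", "leg", "foot"), weight = 0.10)
    ),
    subgroups = list(
      PROS = subgroup(
        contra_mean = c(adipose = 0.292, muscle = 0.674, bone = 0.031),
        contra_sd = c(adipose = 0.100, muscle = 0.102, bone = 0.013),
        delta_mean = c(adipose = 2.0, muscle = -1.5, bone = -0.3),
        delta_sd = c(adipose = 3.8, muscle = 3.6, bone = 0.4),
        age_mean = 15.4, age_sd = 11.6),
      BWSp = subgroup(
        contra_mean = c(adipose = 0.2775, muscle = 0.692, bone = 0.031),
        contra_sd = c(adipose = 0.0898, muscle = 0.091, bone = 0.012),
        delta_mean = c(adipose = -0.5, muscle = 0.8, bone = -0.2),
        delta_sd = c(adipose = 1.1, muscle = 1.0, bone = 0.6),
        age_mean = 8.8, age_sd = 4.2),
      ILO = subgroup(
        contra_mean = c(adipose = 0.384, muscle = 0.584, bone = 0.031),
        contra_sd = c(adipose = 0.091, muscle = 0.090, bone = 0.008),
        delta_mean = c(adipose = -2.3, muscle = 2.3, bone = 0.1),
        delta_sd = c(adipose = 3.0, muscle = 3.2, bone = 0.2),
        age_mean = 8.9, age_sd = 3.0)
    )
  )
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_patients < 0) stop("n_patients must be >= 0", call. = FALSE)
  if (any(cfg$subgroup_counts < 0) || sum(cfg$subgroup_counts) == 0) {
    stop("subgroup_counts must be non-negative with positive total", call. = FALSE)
  }
  if (!all(names(cfg$base_mass_g) %in% lo_regions()) ||
      any(cfg$base_mass_g <= 0)) {
    stop("base_mass_g must be positive and keyed by valid regions", call. = FALSE)
  }
  w <- vapply(cfg$mask_catalog, `[[`, numeric(1), "weight")
  if (length(w) && (any(w < 0) || sum(w) <= 0)) {
    stop("mask catalog weights must be non-negative with positive total",
         call. = FALSE)
  }
  for (entry in cfg$mask_catalog) {
    check_vocab(entry$members, lo_regions(), "mask region")
  }
  for (nm in names(cfg$subgroups)) {
    p <- cfg$subgroups[[nm]]
    if (abs(sum(p$contra_rc_mean) - 1) > 0.01) {
      stop("subgroup ", nm, ": contralateral RC means must sum to 1 within 0.01",
           call. = FALSE)
    }
    if (any(p$contra_rc_sd <= 0) || any(p$delta_rc_sd <= 0)) {
      stop("subgroup ", nm, ": SDs must be positive", call. = FALSE)
    }
    if (p$clinical_sensitivity < 0 || p$clinical_sensitivity > 1) {
      stop("subgroup ", nm, ": clinical_sensitivity must lie in [0, 1]",
           call. = FALSE)
    }
  }
  structure(cfg, class = "lo_generator_config")
}

#' @export
print.lo_generator_config <- function(x, ...) {
  mix <- x$subgroup_counts / sum(x$subgroup_counts)
  cat(sprintf("<lo_generator_config> n = %d, seed = %d, mix: %s\n",
              x$n_patients, x$seed,
              paste(sprintf("%s %.0f%%", names(mix), 100 * mix), collapse = ", ")))
  invisible(x)
}

# truncated-normal draw via rejection; rejection count shared with caller
draw_truncnorm <- function(mean, sd, lower) {
  for (i in 1:1000) {
    x <- rnorm(1, mean, sd)
    if (x >= lower) return(x)
  }
  stop("infeasible truncated-normal parameters (mean ", mean, ", sd ", sd,
       ", floor ", lower, ")", call. = FALSE)
}

# contralateral RC: adipose and bone from truncated normals, muscle by closure
draw_contra_rc <- function(p) {
  for (i in 1:1000) {
    a <- rnorm(1, p$contra_rc_mean[["adipose"]], p$contra_rc_sd[["adipose"]])
    b <- rnorm(1, p$contra_rc_mean[["bone"]], p$contra_rc_sd[["bone"]])
    m <- 1 - a - b
    if (a > 0 && b > 0 && m > 0) return(c(adipose = a, muscle = m, bone = b))
  }
  stop("infeasible RC parameters: rejection sampling failed 1000 times",
       call. = FALSE)
}

# dRC in pp with zero-sum closure on muscle; affected RC must stay a simplex
draw_delta_and_affected <- function(contra, p) {
  for (i in 1:1000) {
    da <- rnorm(1, p$delta_rc_mean[["adipose"]], p$delta_rc_sd[["adipose"]])
    db <- rnorm(1, p$delta_rc_mean[["bone"]], p$delta_rc_sd[["bone"]])
    d <- c(adipose = da, muscle = -(da + db), bone = db)
    affected <- contra + d / 100
    if (all(affected > 0)) return(list(delta = d, affected = affected))
  }
  stop("infeasible RC parameters: affected simplex rejected 1000 times",
       call. = FALSE)
}

# small compositional jitter around a reference RC, for unmasked region-sides
perturb_rc <- function(rc, sd) {
  if (sd == 0) return(rc)
  for (i in 1:1000) {
    a <- rc[["adipose"]] + rnorm(1, 0, sd)
    b <- rc[["bone"]] + rnorm(1, 0, sd)
    m <- 1 - a - b
    if (a > 0 && b > 0 && m > 0) return(c(adipose = a, muscle = m, bone = b))
  }
  stop("infeasible RC noise parameters", call. = FALSE)
}

#' Simulate one synthetic patient scan
#'
#' Draws one patient from a subgroup's parameterization using the current
#' RNG stream: a contralateral RC vector and a zero-sum dRC vector (giving
#' the affected RC), an affected region-side mask from the catalog, and
#' per-region total masses (base mass x lognormal, with the overgrowth
#' ratio applied on masked regions and small symmetric asymmetry noise
#' elsewhere). Tissue masses are RC x m_t; masked region-sides carry the
#' affected RC exactly and their mirrors the contralateral RC exactly, while
#' unmasked region-sides carry independently jittered copies of the
#' contralateral RC. Clinical labels are the mask thinned by the subgroup's
#' clinical sensitivity.
#'
#' @param config An `lo_generator_config`.
#' @param diagnosis Subgroup to draw from (a name of `config$subgroups`).
#' @param patient_id Identifier for the generated scan.
#' @return List with `scan` (an [patient_scan()]) and `truth` (the drawn
#'   mask, RC vectors, dRC and per-region overgrowth ratios).
#' @export
simulate_patient <- function(config = default_generator_config(),
                             diagnosis = "PROS", patient_id = "S0001") {
  stopifnot(inherits(config, "lo_generator_config"))
  p <- config$subgroups[[diagnosis]]
  if (is.null(p)) stop("no generator parameters for subgroup '", diagnosis, "'",
                       call. = FALSE)

  contra_rc <- draw_contra_rc(p)
  dd <- draw_delta_and_affected(contra_rc, p)

  if (length(config$mask_catalog)) {
    w <- vapply(config$mask_catalog, `[[`, numeric(1), "weight")
    entry <- config$mask_catalog[[sample.int(length(w), 1L, prob = w)]]
    mask_side <- sample(lo_sides(), 1L)
    mask <- data.frame(region = entry$members, side = mask_side,
                       stringsAsFactors = FALSE)
    mask_name <- entry$name
  } else {
    mask <- data.frame(region = character(), side = character(),
                       stringsAsFactors = FALSE)
    mask_side <- NA_character_
    mask_name <- "none"
  }

  regions <- lo_regions()
  base <- config$base_mass_g[regions]
  mt_ref <- unname(base) * rlnorm(length(regions), 0, config$mt_lognorm_sd)
  masked <- regions %in% mask$region
  overgrowth <- rep(NA_real_, length(regions))
  names(overgrowth) <- regions

  nr <- 2L * length(regions)
  col_region <- character(nr); col_side <- character(nr)
  col_fat <- col_lean <- col_bmc <- numeric(nr)
  for (i in seq_along(regions)) {
    if (masked[i]) {
      g <- draw_truncnorm(p$overgrowth_ratio_mean, p$overgrowth_ratio_sd,
                          p$overgrowth_ratio_floor)
      overgrowth[i] <- g
      sides <- c(mask_side, other_side(mask_side))
      mt <- c(mt_ref[i] * (1 + g), mt_ref[i])
      rc <- list(dd$affected, contra_rc)
    } else {
      sides <- c("left", "right")
      mt <- c(mt_ref[i], mt_ref[i] * (1 + rnorm(1, 0, p$unaffected_asym_sd)))
      rc <- list(perturb_rc(contra_rc, p$rc_noise_sd),
                 perturb_rc(contra_rc, p$rc_noise_sd))
    }
    j <- c(2L * i - 1L, 2L * i)
    col_region[j] <- regions[i]
    col_side[j] <- sides
    col_fat[j] <- c(rc[[1]][["adipose"]], rc[[2]][["adipose"]]) * mt
    col_lean[j] <- c(rc[[1]][["muscle"]], rc[[2]][["muscle"]]) * mt
    col_bmc[j] <- c(rc[[1]][["bone"]], rc[[2]][["bone"]]) * mt
  }
  measurements <- data.frame(region = col_region, side = col_side,
                             fat_mass_g = col_fat, lean_mass_g = col_lean,
                             bmc_g = col_bmc, stringsAsFactors = FALSE)

  keep <- runif(nrow(mask)) <= p$clinical_sensitivity
  clinical <- mask[keep, , drop = FALSE]

  age <- max(0.5, rnorm(1, p$age_mean, p$age_sd))
  sex <- sample(c("M", "F"), 1L)

  scan <- patient_scan(patient_id, measurements,
                       diagnosis = if (diagnosis %in% lo_diagnoses()) diagnosis else "other",
                       clinical_affected = clinical, sex = sex, age_years = age)
  truth <- list(patient_id = patient_id, diagnosis = diagnosis,
                mask = mask, mask_name = mask_name,
                contra_rc = contra_rc, affected_rc = dd$affected,
                delta_rc = dd$delta,
                overgrowth_ratio = overgrowth[!is.na(overgrowth)])
  list(scan = scan, truth = truth)
}

#' Simulate a synthetic bilateral cohort
#'
#' Draws `n_patients` scans with diagnoses assigned by the configured
#' subgroup mix, using a master seed for the cohort and per-patient
#' subseeds derived from it, so identical seed and configuration reproduce
#' the cohort exactly (and written files byte-for-byte).
#'
#' @param config An `lo_generator_config`; `config$seed` and
#'   `config$n_patients` can be overridden with the `seed` / `n` arguments.
#' @param n,seed Optional overrides of `config$n_patients`, `config$seed`.
#' @param mix Optional character vector of subgroup names to force (e.g.
#'   `"PROS"` for a single-subgroup cohort); default uses
#'   `config$subgroup_counts` proportions.
#' @return Object of class `lo_sim`: list with `cohort` (an [lo_cohort()])
#'   and `truth` (per-patient ground-truth sidecar list).
#' @export
#' @examples
#' sim <- simulate_cohort(n = 5, seed = 42)
#' sim$cohort
simulate_cohort <- function(config = default_generator_config(), n = NULL,
                            seed = NULL, mix = NULL) {
  stopifnot(inherits(config, "lo_generator_config"))
  n <- as.integer(n %||% config$n_patients)
  seed <- as.integer(seed %||% config$seed)
  if (n == 0L) {
    return(structure(list(cohort = lo_cohort(list()), truth = list()),
                     class = "lo_sim"))
  }
  set.seed(seed)
  pool <- mix %||% names(config$subgroup_counts)
  prob <- if (is.null(mix)) {
    config$subgroup_counts / sum(config$subgroup_counts)
  } else rep(1 / length(pool), length(pool))
  diagnoses <- sample(pool, n, replace = TRUE, prob = prob)
  subseeds <- sample.int(.Machine$integer.max - 1L, n)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(subseeds[i])
    out[[i]] <- simulate_patient(config, diagnoses[i], sprintf("S%04d", i))
  }
  structure(
    list(cohort = lo_cohort(lapply(out, `[[`, "scan")),
         truth = lapply(out, `[[`, "truth")),
    class = "lo_sim"
  )
}

#' @export
print.lo_sim <- function(x, ...) {
  cat("<lo_sim> synthetic cohort\n")
  print(x$cohort)
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits `scans.csv`, `labels.csv` and `truth.json` into `dir` in the
#' package's interchange formats (see [read_scans()], [read_labels()]).
#' Output is deterministic: the same `lo_sim` always produces byte-identical
#' files.
#'
#' @param sim An `lo_sim` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return (Invisibly) the paths written.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "lo_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scans_path <- file.path(dir, "scans.csv")
  labels_path <- file.path(dir, "labels.csv")
  truth_path <- file.path(dir, "truth.json")

  scans <- lapply(sim$cohort, function(s) {
    cbind(data.frame(patient_id = s$patient_id, stringsAsFactors = FALSE),
          s$measurements)
  })
  scans <- if (length(scans)) do.call(rbind, c(scans, make.row.names = FALSE)) else
    data.frame(patient_id = character(), region = character(), side = character(),
               fat_mass_g = numeric(), lean_mass_g = numeric(), bmc_g = numeric())
  con <- file(scans_path, open = "wb")
  write.csv(format_full_precision(scans), con, row.names = FALSE, eol = "\n")
  close(con)

  labels <- lapply(sim$cohort, function(s) {
    grid <- s$measurements[c("region", "side")]
    aff <- paste(grid$region, grid$side) %in%
      paste(s$clinical_affected$region, s$clinical_affected$side)
    data.frame(patient_id = s$patient_id, diagnosis = s$diagnosis,
               region = grid$region, side = grid$side,
               affected = as.integer(aff), stringsAsFactors = FALSE)
  })
  labels <- if (length(labels)) do.call(rbind, c(labels, make.row.names = FALSE)) else
    data.frame(patient_id = character(), diagnosis = character(),
               region = character(), side = character(), affected = integer())
  con <- file(labels_path, open = "wb")
  write.csv(labels, con, row.names = FALSE, eol = "\n")
  close(con)

  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(c(scans = scans_path, labels = labels_path, truth = truth_path))
}
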