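#' Analysis configuration
#'
#' Holds the thresholds driving LO calling and reporting.
#'
#' @param lo_threshold Total-mass discrepancy cut-off, as a fraction. A region
#'   (or region aggregate) whose discrepancy ratio is at or above this value is
#'   called as lateralized overgrowth. Default 0.10, the clinical 10% cut-off.
#' @param near_threshold_band Width of the sub-threshold band, as a fraction.
#'   Ratios in `[lo_threshold - near_threshold_band, lo_threshold)` are flagged
#'   as near-threshold in the concordance report. Default 0.05.
#' @param tie_order Tissue priority used to break exact ties when classifying
#'   the predominant overgrown tissue. Default adipose, muscle, bone.
#'
#' @details The boundary is inclusive: a ratio of exactly `lo_threshold` is
#'   called LO, so borderline 10% cases are flagged for review. The clinical
#'   girth/length cut-off and the DXA mass cut-off are conceptually distinct;
#'   both default to 10% here but `lo_threshold` can be set independently.
#'
#' @return An object of class `lo_config`.
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$lo_threshold
analysis_config <- function(lo_threshold = 0.10,
                            near_threshold_band = 0.05,
                            tie_order = c("adipose", "muscle", "bone")) {
  stopifnot(is.numeric(lo_threshold), length(lo_threshold) == 1L,
            is.numeric(near_threshold_band), length(near_threshold_band) == 1L)
  if (!(lo_threshold > 0 && lo_threshold < 1)) {
    stop("`lo_threshold` must lie in (0, 1)", call. = FALSE)
  }
  if (!(near_threshold_band > 0 && near_threshold_band < lo_threshold)) {
    stop("`near_threshold_band` must lie in (0, lo_threshold)", call. = FALSE)
  }
  if (!setequal(tie_order, lo_tissues()) || length(tie_order) != 3L) {
    stop("`tie_order` must be a permutation of ", paste(lo_tissues(), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(lo_threshold = lo_threshold,
         near_threshold_band = near_threshold_band,
         tie_order = tie_order),
    class = "lo_config"
  )
}

#' Read a configuration file
#'
#' Reads a YAML (or JSON) configuration with optional `analysis`, `io` and
#' `generator` blocks, merging each over the package defaults. The `analysis`
#' block feeds [analysis_config()]; `io$column_map` renames vendor CSV headers
#' to the canonical ones on ingestion; the `generator` block overrides
#' [default_generator_config()] fields.
#'
#' @param path Path to a YAML/JSON configuration file.
#' @return A list with elements `analysis` (class `lo_config`), `io`
#'   (list with `column_map`), and `generator` (class `lo_generator_config`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must contain a mapping: ", path, call. = FALSE)

  an <- raw$analysis %||% list()
  analysis <- analysis_config(
    lo_threshold = an$lo_threshold %||% 0.10,
    near_threshold_band = an$near_threshold_band %||% 0.05,
    tie_order = unlist(an$tie_order %||% c("adipose", "muscle", "bone"))
  )

  io <- list(column_map = raw$io$column_map %||% NULL)
  if (!is.null(io$column_map)) io$column_map <- unlist(io$column_map)

  gen <- default_generator_config()
  for (nm in names(raw$generator %||% list())) {
    gen[[nm]] <- merge_config_field(gen[[nm]], raw$generator[[nm]])
  }
  gen <- validate_generator_config(gen)

  list(analysis = analysis, io = io, generator = gen)
}

# recursive overlay of user values onto defaults, keeping default structure
merge_config_field <- function(default, user) {
  if (is.list(default) && is.list(user)) {
    for (nm in names(user)) default[[nm]] <- merge_config_field(default[[nm]], user[[nm]])
    default
  } else if (is.numeric(default) && length(default) > 1L && is.list(user)) {
    v <- unlist(user)
    default[names(v)] <- v
    default
  } else {
    u <- if (is.list(user)) unlist(user) else user
    if (!is.null(names(default)) && !is.null(names(u))) {
      default[names(u)] <- u
      default
    } else u
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
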