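#' Cohort composition summary
#'
#' Builds the per-subgroup summary of relative composition: for every
#' diagnosis present (plus a `Total` row spanning the cohort) and every
#' tissue, the mean and SD of the affected-aggregate RC, the contralateral
#' RC, and the per-patient dRC, together with the paired t test p value
#' comparing affected vs contralateral RC across patients. RC values are
#' reported in percent, dRC in percentage points. Only patients with a
#' clinical affected set (hence an aggregate result) contribute.
#'
#' Groups with fewer than 2 patients, or with zero-variance differences,
#' get `NA` for the p value with a note instead of an error.
#'
#' @param scored An `lo_scored_cohort` from [score_cohort()].
#' @return Object of class `lo_summary`: a data frame with columns
#'   `diagnosis`, `n`, `tissue`, `affected_mean`, `affected_sd`,
#'   `contra_mean`, `contra_sd`, `delta_mean`, `delta_sd`, `paired_p`,
#'   `note`.
#' @export
build_composition_summary <- function(scored) {
  agg <- aggregate_results(scored)
  if (nrow(agg) == 0L) stop("no aggregate results: no patient has clinical labels",
                            call. = FALSE)
  groups <- c(stats::setNames(nm = sort(unique(agg$diagnosis))), Total = "Total")
  rows <- list()
  for (gname in names(groups)) {
    sub <- if (gname == "Total") agg else agg[agg$diagnosis == gname, , drop = FALSE]
    for (tissue in lo_tissues()) {
      aff <- 100 * sub[[paste0("rc_affected_", tissue)]]
      con <- 100 * sub[[paste0("rc_contra_", tissue)]]
      dlt <- sub[[paste0("delta_rc_", tissue)]]
      p <- NA_real_
      note <- ""
      if (nrow(sub) >= 2L) {
        res <- tryCatch(paired_t_test(aff, con), error = function(e) conditionMessage(e))
        if (inherits(res, "lo_test")) p <- res$p_value else note <- res
      } else {
        note <- "n < 2: paired test not computed"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        diagnosis = gname, n = nrow(sub), tissue = tissue,
        affected_mean = mean(aff), affected_sd = sd(aff),
        contra_mean = mean(con), contra_sd = sd(con),
        delta_mean = mean(dlt), delta_sd = sd(dlt),
        paired_p = p, note = note, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("lo_summary", "data.frame")
  out
}

aggregate_results <- function(scored) {
  stopifnot(inherits(scored, "lo_scored_cohort"))
  scored$results[scored$results$scope == "aggregate", , drop = FALSE]
}

#' @export
print.lo_summary <- function(x, ...) {
  cat("Relative composition by diagnostic subgroup (mean ± SD)\n")
  fmt <- function(m, s) sprintf("%.1f%% ± %.1f%%", m, s)
  for (g in unique(x$diagnosis)) {
    sub <- x[x$diagnosis == g, , drop = FALSE]
    cat(sprintf("%s (n = %d)\n", g, sub$n[1]))
    for (i in seq_len(nrow(sub))) {
      p <- if (is.na(sub$paired_p[i])) "-" else sprintf("p = %.3f", sub$paired_p[i])
      cat(sprintf("  %-7s affected %s | contralateral %s | dRC %+.1f pp ± %.1f | %s\n",
                  sub$tissue[i], fmt(sub$affected_mean[i], sub$affected_sd[i]),
                  fmt(sub$contra_mean[i], sub$contra_sd[i]),
                  sub$delta_mean[i], sub$delta_sd[i], p))
    }
  }
  invisible(x)
}

#' Between-group comparison of composition discrepancies
#'
#' For each tissue, compares per-patient dRC across the diagnostic
#' subgroups: a one-way ANOVA over all groups plus all pairwise pooled
#' (Student) unpaired t tests. No multiplicity adjustment is applied by
#' default; `p_adjust = "holm"` adds Holm-adjusted pairwise p values in an
#' extra column.
#'
#' @param scored An `lo_scored_cohort` from [score_cohort()].
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return Object of class `lo_group_comparison`: list with one element per
#'   tissue, each holding `anova` (an `lo_test`) and `pairwise` (data frame
#'   with `group1`, `group2`, `statistic`, `df`, `p_value`).
#' @export
compare_groups_delta_rc <- function(scored, p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  agg <- aggregate_results(scored)
  counts <- table(agg$diagnosis)
  use <- names(counts)[counts >= 2L]
  if (length(use) < 2L) {
    stop("need >= 2 diagnostic groups with n >= 2 (got ",
         length(use), ")", call. = FALSE)
  }
  out <- list()
  for (tissue in lo_tissues()) {
    col <- paste0("delta_rc_", tissue)
    groups <- lapply(use, function(g) agg[[col]][agg$diagnosis == g])
    names(groups) <- use
    an <- one_way_anova(groups)
    pairs <- utils::combn(use, 2L)
    pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      tt <- unpaired_t_test(groups[[g1]], groups[[g2]])
      data.frame(group1 = g1, group2 = g2, statistic = tt$statistic,
                 df = tt$df, p_value = tt$p_value, stringsAsFactors = FALSE)
    }))
    if (p_adjust == "holm") pw$p_holm <- stats::p.adjust(pw$p_value, "holm")
    out[[tissue]] <- list(anova = an, pairwise = pw)
  }
  structure(out, class = "lo_group_comparison", groups = use)
}

#' @export
print.lo_group_comparison <- function(x, ...) {
  cat("dRC comparisons across diagnostic subgroups (",
      paste(attr(x, "groups"), collapse = ", "), ")\n", sep = "")
  for (tissue in names(x)) {
    an <- x[[tissue]]$anova
    cat(sprintf("%s: ANOVA F(%g, %g) = %.3f, p = %.4g\n", tissue,
                an$df[1], an$df[2], an$statistic, an$p_value))
    pw <- x[[tissue]]$pairwise
    for (i in seq_len(nrow(pw))) {
      cat(sprintf("  %s vs %s: t = %.3f, p = %.4g\n", pw$group1[i], pw$group2[i],
                  pw$statistic[i], pw$p_value[i]))
    }
  }
  invisible(x)
}

#' Predominant-tissue prevalence across subgroups
#'
#' Cross-tabulates the predominant overgrown tissue against the diagnostic
#' subgroup and applies Fisher's exact r x c test to the counts.
#'
#' @param scored An `lo_scored_cohort` from [score_cohort()].
#' @return List with `table` (diagnosis x tissue counts) and `test`
#'   (an `lo_test` from [fisher_exact_rxc()]).
#' @export
predominant_prevalence_test <- function(scored) {
  agg <- aggregate_results(scored)
  if (nrow(agg) == 0L) stop("no aggregate results", call. = FALSE)
  tab <- table(diagnosis = agg$diagnosis,
               tissue = factor(agg$predominant_tissue, levels = lo_tissues()))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("prevalence table degenerate: need >= 2 diagnoses and >= 2 tissues observed",
         call. = FALSE)
  }
  list(table = tab, test = fisher_exact_rxc(unclass(tab)))
}

#' Export cohort statistics as JSON
#'
#' Serializes the composition summary and between-group comparisons to the
#' nested stats JSON layout:
#' `{group -> tissue -> {affected_mean, affected_sd, contra_mean, contra_sd,
#' delta_mean, delta_sd, paired_p}}` plus a `comparisons` block with the
#' per-tissue ANOVA and pairwise tests.
#'
#' @param summary An `lo_summary`.
#' @param comparisons Optional `lo_group_comparison`.
#' @param path Output path for the JSON file.
#' @return (Invisibly) the path written.
#' @export
write_stats_json <- function(summary, comparisons = NULL, path) {
  groups <- list()
  for (g in unique(summary$diagnosis)) {
    sub <- summary[summary$diagnosis == g, , drop = FALSE]
    tiss <- list()
    for (i in seq_len(nrow(sub))) {
      tiss[[sub$tissue[i]]] <- list(
        affected_mean = sub$affected_mean[i], affected_sd = sub$affected_sd[i],
        contra_mean = sub$contra_mean[i], contra_sd = sub$contra_sd[i],
        delta_mean = sub$delta_mean[i], delta_sd = sub$delta_sd[i],
        paired_p = sub$paired_p[i]
      )
    }
    tiss$n <- sub$n[1]
    groups[[g]] <- tiss
  }
  out <- list(groups = groups)
  if (!is.null(comparisons)) {
    out$comparisons <- lapply(comparisons, function(cmp) {
      list(anova = list(F = cmp$anova$statistic, df = cmp$anova$df,
                        p = cmp$anova$p_value),
           pairwise = cmp$pairwise)
    })
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}
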