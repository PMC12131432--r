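# Cohort-level analysis report: per-timepoint group comparisons, ROC
# accuracy and return-to-baseline tables, globally and per season stratum.

# long table of per-subject, per-timepoint values
.session_table <- function(sessions) {
  do.call(rbind, lapply(sessions, function(s) {
    data.frame(subject_id = s$subject_id, group = s$group, season = s$season,
               timepoint_label = names(s$artix),
               minutes = s$schedule$minutes,
               artix = unname(s$artix), thermal = unname(s$thermal),
               stringsAsFactors = FALSE)
  }))
}

.stratum_analysis <- function(sessions, tab) {
  grp <- vapply(sessions, function(s) s$group, character(1))
  # both groups must be present with enough subjects for the comparisons
  if (length(unique(grp)) < 2L || min(table(grp)) < 3L) return(NULL)
  labels <- protocol_schedule()$label

  per_tp <- lapply(labels, function(tp) {
    sub <- tab[tab$timepoint_label == tp, ]
    rp <- sub$artix[sub$group == "RP"]; hc <- sub$artix[sub$group == "HC"]
    rp_t <- sub$thermal[sub$group == "RP"]; hc_t <- sub$thermal[sub$group == "HC"]
    list(
      timepoint = tp,
      artix = compare_groups(rp, hc),
      thermal = compare_groups(rp_t, hc_t),
      roc = roc_analysis(sub$artix, sub$group, positive_class = "RP",
                         direction = "lower")
    )
  })
  names(per_tp) <- labels

  ret <- lapply(c("artix", "thermal"), function(m) {
    tb <- cohort_return_table(sessions, m)
    counts <- as.matrix(tb[, c("returned", "not_returned")])
    chisq <- tryCatch(chi_square_2x2(counts),
                      artix_error = function(e) NULL)
    list(table = tb, chi_square = chisq)
  })
  names(ret) <- c("artix", "thermal")

  # paired comparison of the two measures' return classification per group
  ret_art <- vapply(sessions, returned_to_baseline, logical(1), "artix")
  ret_th <- vapply(sessions, returned_to_baseline, logical(1), "thermal")
  mcn <- lapply(c("RP", "HC"), function(g) {
    suppressWarnings(mcnemar_exact(ret_art[grp == g], ret_th[grp == g]))
  })
  names(mcn) <- c("RP", "HC")

  # pooled group effect on the score: difference of per-subject means
  subj_mean <- tapply(tab$artix, tab$subject_id, mean)
  subj_grp <- grp[match(names(subj_mean), vapply(sessions, function(s)
    s$subject_id, character(1)))]
  mh <- subj_mean[subj_grp == "HC"]; mr <- subj_mean[subj_grp == "RP"]
  effect <- list(
    estimate = mean(mh) - mean(mr),
    se = sqrt(stats::var(mh) / length(mh) + stats::var(mr) / length(mr)),
    n = c(HC = length(mh), RP = length(mr))
  )

  list(per_timepoint = per_tp, return_to_baseline = ret,
       mcnemar_artix_vs_thermal = mcn, group_effect = effect)
}

#' Full cohort analysis report
#'
#' For the whole cohort and within each season stratum: per-timepoint
#' group comparisons (score and thermal), per-timepoint ROC accuracy of the
#' score, return-to-baseline tables with the uncorrected chi-square group
#' test, the exact McNemar comparison of the two measures' return
#' classification, and a pooled estimate of the group effect on the score
#' (difference of per-subject means, HC minus RP, with its standard error).
#' Strata that lack both groups, or hold fewer than 3 subjects in either
#' group, are skipped with a warning.
#'
#' @param sessions List of `challenge_session` objects, or an
#'   `artix_cohort`.
#' @return An object of class `analysis_report`.
#' @export
cohort_report <- function(sessions) {
  if (inherits(sessions, "artix_cohort")) sessions <- sessions$sessions
  stopifnot(length(sessions) >= 2L)
  tab <- .session_table(sessions)
  grp <- vapply(sessions, function(s) s$group, character(1))
  if (length(unique(grp)) < 2L) {
    artix_error("artix_bad_input", "both groups are required for the report")
  }
  seasons <- vapply(sessions, function(s) s$season, character(1))

  strata <- list(global = seq_along(sessions))
  for (s in c("MayJul", "SepDec")) {
    idx <- which(seasons == s)
    if (length(idx) > 0L) strata[[s]] <- idx
  }
  out <- lapply(names(strata), function(nm) {
    idx <- strata[[nm]]
    res <- .stratum_analysis(sessions[idx],
                             tab[tab$subject_id %in% vapply(sessions[idx],
                               function(s) s$subject_id, character(1)), ])
    if (is.null(res)) {
      artix_warn("artix_stratum_skipped",
                 sprintf("stratum %s lacks one group; skipped", nm))
    }
    res
  })
  names(out) <- names(strata)
  structure(list(strata = out[!vapply(out, is.null, logical(1))],
                 table = tab,
                 config = list(formula_version = .formula_version,
                               chi_square_correction = FALSE,
                               roc_ci = "delong",
                               operating_point = "youden")),
            class = "analysis_report")
}

#' Serialize an analysis report to JSON
#'
#' @param report An `analysis_report`.
#' @param path Output file; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  strip <- function(x) {
    if (inherits(x, "group_comparison")) {
      list(test = x$test_name, statistic = x$statistic, p_value = x$p_value,
           means = as.list(x$means), sds = as.list(x$sds),
           routing_reason = x$routing_reason)
    } else if (inherits(x, "roc_result")) {
      list(auc = x$auc, ci95 = c(x$ci95_low, x$ci95_high),
           threshold = x$threshold, sensitivity = x$sensitivity,
           specificity = x$specificity, confusion = as.list(x$confusion))
    } else if (is.list(x)) lapply(x, strip) else x
  }
  js <- jsonlite::toJSON(strip(report$strata), auto_unbox = TRUE, digits = 10,
                         dataframe = "rows", null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read sessions back from a session-level CSV
#'
#' Reconstructs `challenge_session` objects from the long table written by
#' [write_session_csv()] (columns `subject_id`, `group`, `season`,
#' `timepoint_label`, `minutes`, `artix`, `thermal`), e.g. to feed
#' [cohort_report()] from scored data on disk.
#'
#' @param path CSV file path.
#' @return A list of `challenge_session` objects.
#' @export
read_session_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "season", "timepoint_label", "artix",
            "thermal")
  if (!all(need %in% names(df))) {
    artix_error("artix_bad_input",
                paste("session CSV must contain columns:",
                      paste(need, collapse = ", ")))
  }
  sched <- protocol_schedule()
  lapply(split(df, df$subject_id), function(g) {
    g <- g[match(sched$label, g$timepoint_label), ]
    structure(list(subject_id = g$subject_id[1], group = g$group[1],
                   season = g$season[1], covariates = list(),
                   schedule = sched,
                   artix = stats::setNames(g$artix, sched$label),
                   thermal = stats::setNames(g$thermal, sched$label)),
              class = "challenge_session")
  })
}

#' Write per-timepoint scores to CSV
#'
#' Session-level long table: one row per subject and timepoint with the
#' score and thermal value and the return-to-baseline flags.
#'
#' @param sessions List of `challenge_session` objects or an `artix_cohort`.
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_session_csv <- function(sessions, path) {
  if (inherits(sessions, "artix_cohort")) sessions <- sessions$sessions
  tab <- .session_table(sessions)
  ra <- vapply(sessions, returned_to_baseline, logical(1), "artix")
  rt <- vapply(sessions, returned_to_baseline, logical(1), "thermal")
  ids <- vapply(sessions, function(s) s$subject_id, character(1))
  tab$returned_to_baseline_artix <- ra[match(tab$subject_id, ids)]
  tab$returned_to_baseline_thermal <- rt[match(tab$subject_id, ids)]
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
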