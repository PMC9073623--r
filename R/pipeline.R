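## End-to-end orchestration: per-participant preprocessing -> outings ->
## profiles -> geospatial features -> the three-step statistics report.

#' Process one participant's trace into outings and profiles
#'
#' @param trace A [gps_trace()].
#' @param diary Diary tibble (may be empty).
#' @param home c(lat, lon).
#' @param config A [pipeline_config()].
#' @return A list: `outings` (band- and accompaniment-labelled), `profiles`
#'   (one row per condition), `recorded_days`, `preprocessed` (the
#'   [preprocess_trace()] result), or `NULL` with attribute `reason` when the
#'   participant has no usable days.
#' @export
process_participant <- function(trace, diary, home,
                                config = pipeline_config()) {
  pre <- preprocess_trace(trace, home, config)
  if (pre$excluded) {
    gm_log("warning", sprintf("%s excluded: no usable days (almost no data)",
                              trace$participant_id))
    return(structure(list(), reason = "no usable days", excluded = TRUE))
  }
  outs <- detect_outings(pre$trace, home,
                         home_radius_m = config$home_radius_m,
                         min_outing_path_m = config$min_outing_path_m,
                         min_outing_displacement_m =
                           config$min_outing_displacement_m,
                         min_home_dwell_s = config$min_home_dwell_s,
                         gap_s = config$gap_s, rule = config$outing_rule)
  if (nrow(outs))
    outs$band <- classify_band(outs$start, config$day_band, config$tz)
  else outs$band <- character(0)
  outs <- match_diary(outs, diary, config$diary_match_window_min)
  rec_days <- length(pre$recorded_days)
  prof_all <- compute_profile(outs, rec_days, home, trace$interval_s, config)
  prof_all$condition <- "all"
  profiles <- prof_all
  if (!is.null(diary) && nrow(diary) > 0) {
    sp <- split_by_accompaniment(outs)
    for (cn in c("alone", "accompanied")) {
      p <- compute_profile(sp[[cn]], rec_days, home, trace$interval_s, config)
      p$condition <- cn
      profiles <- dplyr::bind_rows(profiles, p)
    }
  }
  list(outings = outs, profiles = profiles, recorded_days = rec_days,
       preprocessed = pre)
}

#' Analyse a cohort in memory
#'
#' Runs preprocessing, outing detection, mobility profiling, geospatial
#' feature extraction and the full statistics report over a `gps_cohort`.
#' Participants are processed in identifier order, so results do not depend
#' on input ordering; participants with no usable days are excluded with a
#' logged reason.
#'
#' @param cohort A `gps_cohort` (from [generate_cohort()] or [read_cohort()]).
#' @param config A [pipeline_config()].
#' @return A list: `profiles`, `geo`, `report` (list of tidy stat tables),
#'   `exclusions`, `outings` (per-participant list).
#' @export
analyze_cohort <- function(cohort, config = pipeline_config()) {
  set.seed(config$seed)
  man <- dplyr::arrange(cohort$participants, .data$participant_id)
  profiles <- list(); geo <- list(); outings <- list(); excl <- list()
  for (i in seq_len(nrow(man))) {
    id <- man$participant_id[i]
    home <- c(man$home_lat[i], man$home_lon[i])
    res <- process_participant(cohort$traces[[id]], cohort$diaries[[id]],
                               home, config)
    if (isTRUE(attr(res, "excluded"))) {
      excl[[length(excl) + 1L]] <- tibble::tibble(
        participant_id = id, reason = attr(res, "reason"))
      next
    }
    pr <- res$profiles
    pr$participant_id <- id
    pr$group <- man$group[i]
    pr$disoriented <- man$disoriented[i]
    profiles[[id]] <- pr
    g <- geo_features(res$outings, cohort$env, config)
    g$participant_id <- id
    g$group <- man$group[i]
    g$disoriented <- man$disoriented[i]
    geo[[id]] <- g
    outings[[id]] <- res$outings
  }
  profiles <- dplyr::bind_rows(profiles)
  geo <- dplyr::bind_rows(geo)
  exclusions <- if (length(excl)) dplyr::bind_rows(excl)
    else tibble::tibble(participant_id = character(), reason = character())
  report <- cohort_statistics(profiles, geo, config)
  list(profiles = profiles, geo = geo, report = report,
       exclusions = exclusions, outings = outings)
}

pull_var <- function(profiles, var, grp = NULL, cond = NULL,
                     disoriented = NULL) {
  d <- profiles
  if (!is.null(grp)) d <- d[d$group == grp, ]
  if (!is.null(cond)) d <- d[d$condition == cond, ]
  if (!is.null(disoriented)) d <- d[d$disoriented == disoriented, ]
  d[[var]]
}

#' The three-step statistics report
#'
#' Step 1: every mobility variable, controls vs patients (all outings),
#' normality-gated t/Wilcoxon. Step 2: linear mixed model per variable over
#' control-all / patient-accompanied / patient-alone with FDR-adjusted
#' pairwise contrasts. Step 3: controls vs patients with vs without
#' disorientation (one-way ANOVA / Kruskal-Wallis, gated), for the mobility
#' variables and the geospatial features.
#'
#' @param profiles Profile table from [analyze_cohort()].
#' @param geo Geospatial feature table.
#' @param config A [pipeline_config()].
#' @return A list of tidy tables: `two_group`, `mixed_omnibus`,
#'   `mixed_pairwise`, `disorientation_omnibus`, `disorientation_posthoc`.
#' @export
cohort_statistics <- function(profiles, geo, config = pipeline_config()) {
  two <- list(); mo <- list(); mp <- list(); do_ <- list(); dp <- list()
  for (v in profile_vars) {
    two[[v]] <- compare_two_groups(
      pull_var(profiles, v, "control", "all"),
      pull_var(profiles, v, "patient", "all"),
      normality_alpha = config$normality_alpha, variable = v)
    long <- dplyr::bind_rows(
      tibble::tibble(participant = pull_var(profiles, "participant_id",
                                            "control", "all"),
                     condition = "control_all",
                     value = pull_var(profiles, v, "control", "all")),
      tibble::tibble(participant = pull_var(profiles, "participant_id",
                                            "patient", "accompanied"),
                     condition = "patient_accompanied",
                     value = pull_var(profiles, v, "patient", "accompanied")),
      tibble::tibble(participant = pull_var(profiles, "participant_id",
                                            "patient", "alone"),
                     condition = "patient_alone",
                     value = pull_var(profiles, v, "patient", "alone")))
    mm <- tryCatch(fit_three_condition_mixed_model(long, variable = v),
                   error = function(e) NULL)
    if (!is.null(mm)) {
      mo[[v]] <- mm$omnibus
      mp[[v]] <- mm$pairwise
    }
    d3 <- compare_three_groups(
      list(control = pull_var(profiles, v, "control", "all"),
           disoriented = pull_var(profiles, v, "patient", "all",
                                  disoriented = TRUE),
           not_disoriented = pull_var(profiles, v, "patient", "all",
                                      disoriented = FALSE)),
      alpha = config$alpha, normality_alpha = config$normality_alpha,
      variable = v)
    do_[[v]] <- d3$omnibus
    dp[[v]] <- d3$posthoc
  }
  geo_vars <- c("landmark_density", "intersection_density",
                "mean_intersection_complexity", "orientation_entropy")
  for (v in geo_vars) {
    d3 <- compare_three_groups(
      list(control = pull_var(geo, v, "control"),
           disoriented = pull_var(geo, v, "patient", disoriented = TRUE),
           not_disoriented = pull_var(geo, v, "patient",
                                      disoriented = FALSE)),
      alpha = config$alpha, normality_alpha = config$normality_alpha,
      variable = v)
    do_[[v]] <- d3$omnibus
    dp[[v]] <- d3$posthoc
  }
  list(two_group = dplyr::bind_rows(two),
       mixed_omnibus = dplyr::bind_rows(mo),
       mixed_pairwise = dplyr::bind_rows(mp),
       disorientation_omnibus = dplyr::bind_rows(do_),
       disorientation_posthoc = dplyr::bind_rows(dp))
}

#' Run the full pipeline on a cohort directory (or in-memory cohort)
#'
#' Reads the cohort, analyses it, and writes the profile, geospatial-feature
#' and statistics tables as CSV plus a human-readable report. A run is fully
#' reproducible given `config$seed` and is invariant to the ordering of
#' participants in the manifest.
#'
#' @param input A cohort directory path or a `gps_cohort`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The [analyze_cohort()] bundle, invisibly.
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         out_dir = "pipeline_out") {
  cohort <- if (inherits(input, "gps_cohort")) input
    else read_cohort(input, tz = config$tz)
  res <- analyze_cohort(cohort, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(res$profiles, file.path(out_dir, "profiles.csv"),
                   progress = FALSE)
  readr::write_csv(res$geo, file.path(out_dir, "geo_features.csv"),
                   progress = FALSE)
  readr::write_csv(res$exclusions, file.path(out_dir, "exclusions.csv"),
                   progress = FALSE)
  rep <- res$report
  for (nm in names(rep))
    readr::write_csv(rep[[nm]], file.path(out_dir, paste0("stats_", nm,
                                                          ".csv")),
                     progress = FALSE)
  writeLines(report_text(res, config), file.path(out_dir, "report.txt"))
  invisible(res)
}

report_text <- function(res, config) {
  rep <- res$report
  fmt_p <- function(p) ifelse(is.na(p), "NA",
                              ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
  out <- c(
    "Outdoor navigation analysis report",
    sprintf("Normality gate: Shapiro-Wilk at alpha = %g; two-group test: Welch t / Wilcoxon rank-sum",
            config$normality_alpha),
    sprintf("Participants analysed: %d (excluded: %d)",
            length(unique(res$profiles$participant_id)),
            nrow(res$exclusions)),
    "",
    "Step 1 - controls vs patients (all outings):")
  for (i in seq_len(nrow(rep$two_group))) {
    r <- rep$two_group[i, ]
    out <- c(out, sprintf(
      "  %-30s %-9s stat=%8.3f p=%s  (control %0.2f+/-%0.2f, patient %0.2f+/-%0.2f)",
      r$variable, r$test, r$statistic, fmt_p(r$p),
      r$mean_x, r$sd_x, r$mean_y, r$sd_y))
  }
  out <- c(out, "",
           "Step 2 - mixed model (control all / patient accompanied / patient alone):")
  for (i in seq_len(nrow(rep$mixed_omnibus))) {
    r <- rep$mixed_omnibus[i, ]
    out <- c(out, sprintf("  %-30s %s F=%0.3f p=%s", r$variable, r$method,
                          r$f_value, fmt_p(r$p)))
    pw <- rep$mixed_pairwise[rep$mixed_pairwise$variable == r$variable, ]
    for (j in seq_len(nrow(pw)))
      out <- c(out, sprintf("      %-45s est=%9.3f p_adj=%s",
                            pw$contrast[j], pw$estimate[j], fmt_p(pw$p_adj[j])))
  }
  out <- c(out, "",
           "Step 3 - controls vs patients with vs without disorientation:")
  for (i in seq_len(nrow(rep$disorientation_omnibus))) {
    r <- rep$disorientation_omnibus[i, ]
    out <- c(out, sprintf("  %-30s %-15s stat=%8.3f p=%s", r$variable,
                          ifelse(is.na(r$test), "skipped", r$test),
                          r$statistic, fmt_p(r$p)))
  }
  out
}
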