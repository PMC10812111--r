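# Orchestration: per-session analysis of the on-disk streams and
# cohort-level assembly into condition tables, ANOVAs, post-hocs and the
# interaction power analysis.

session_file <- function(ses_dir, suffix) {
  f <- list.files(ses_dir, pattern = paste0(gsub("\\.", "\\\\.", suffix),
                                            "$"), full.names = TRUE)
  if (length(f) == 0) return(NA_character_)
  f[1]
}

analyze_alpha_recording <- function(rec, params = cleaning_params()) {
  rec <- remove_blink_artifacts(rec)
  rec <- preprocess_continuous(rec, params)
  bads <- detect_and_interpolate_bads(rec)
  epochs <- epoch_recording(bads$rec, epoch_len = 2)
  cleaned <- clean_epochs(epochs, params)
  tfr <- morlet_tfr(cleaned$epochs)
  mp <- mean_alpha_power(tfr)
  list(mean_alpha = mp$mean_alpha, n_epochs = mp$n_epochs,
       bad_channels = bads$bad_channels, report = cleaned$report)
}

#' Analyze one recorded session directory
#'
#' Runs the full analysis chain on one `sub-XX/ses-*` directory: IAF from
#' the baseline resting EEG; Morlet alpha power for the pre and post CPT
#' blocks and resting phases (the during-stimulation block is excluded);
#' CPT omission/commission/RTV; gaze dwell fractions and distractibility;
#' head actigraphy; symptom ratings. Summaries are written into
#' `<ses_dir>/derived/`. Missing streams produce a warning and a
#' `"partial"` status while the remaining modalities are still analyzed.
#'
#' @param ses_dir Session directory produced by [generate_cohort()].
#' @param params A [cleaning_params()].
#' @return List with `status` (`"ok"`/`"partial"`), `iaf`, and data.frames
#'   `alpha`, `cpt`, `gaze`, `motion`, `ratings`.
#' @export
run_session <- function(ses_dir, params = cleaning_params()) {
  status <- "ok"
  derived <- file.path(ses_dir, "derived")
  dir.create(derived, showWarnings = FALSE)
  ids <- strsplit(basename(ses_dir), "-")[[1]]
  intervention <- ids[length(ids)]
  subject <- basename(dirname(ses_dir))

  iaf <- NULL
  f <- session_file(ses_dir, "rest-baseline_eeg.edf")
  if (is.na(f)) {
    warning("missing baseline resting EEG in ", ses_dir)
    status <- "partial"
  } else {
    iaf <- iaf_from_rest(read_edf(f))
    jsonlite::write_json(
      list(subject = subject, session = intervention, iaf_hz = iaf$iaf,
           n_epochs_used = iaf$n_epochs_used),
      file.path(derived, "iaf.json"), auto_unbox = TRUE, digits = NA)
  }

  alpha <- NULL
  cleaning <- list()
  targets <- list(
    list(context = "cpt", block = "pre", suffix = "task-cpt_block-1_eeg.edf"),
    list(context = "cpt", block = "post", suffix = "task-cpt_block-3_eeg.edf"),
    list(context = "rest", block = "pre", suffix = "rest-pre_eeg.edf"),
    list(context = "rest", block = "post", suffix = "rest-post_eeg.edf"))
  for (tg in targets) {
    f <- session_file(ses_dir, tg$suffix)
    if (is.na(f)) {
      warning("missing EEG stream ", tg$suffix, " in ", ses_dir)
      status <- "partial"
      next
    }
    res <- analyze_alpha_recording(read_edf(f), params)
    alpha <- rbind(alpha, data.frame(
      subject = subject, intervention = intervention, block = tg$block,
      context = tg$context, mean_alpha = res$mean_alpha,
      n_epochs = res$n_epochs, stringsAsFactors = FALSE))
    cleaning[[paste(tg$context, tg$block, sep = "_")]] <- list(
      bad_channels = res$bad_channels,
      jp_rejected = res$report$jp_rejected,
      excluded_channels = res$report$excluded_channels,
      amplitude_rejected = res$report$amplitude_rejected,
      n_interpolations = length(res$report$interpolations),
      n_epochs_out = res$report$n_epochs_out)
  }
  if (!is.null(alpha)) write_tsv(alpha, file.path(derived,
                                                  "alpha_summary.tsv"))
  jsonlite::write_json(cleaning, file.path(derived,
                                           "cleaning_report.json"),
                       auto_unbox = TRUE, digits = NA)

  cpt <- NULL
  fe <- session_file(ses_dir, "events.tsv")
  fr <- session_file(ses_dir, "responses.tsv")
  if (is.na(fe) || is.na(fr)) {
    warning("missing events/responses stream in ", ses_dir)
    status <- "partial"
  } else {
    events <- read_tsv(fe)
    responses <- read_tsv(fr)
    for (block in c(1, 3)) {
      schedule <- events_to_schedule(events, block)
      resp <- responses[responses$block == block, , drop = FALSE]
      sc <- score_cpt(schedule, resp)
      cpt <- rbind(cpt, data.frame(
        subject = subject, intervention = intervention,
        block = block_label(block), omission_rate = sc$omission_rate,
        commission_rate = sc$commission_rate, rtv = sc$rtv,
        n_hits = sc$n_hits, stringsAsFactors = FALSE))
    }
    write_tsv(cpt, file.path(derived, "cpt_scores.tsv"))
  }

  gaze <- NULL
  f <- session_file(ses_dir, "gaze.tsv")
  if (is.na(f)) {
    warning("missing gaze stream in ", ses_dir)
    status <- "partial"
  } else {
    gz <- read_tsv(f)
    for (block in c(1, 3)) {
      g <- gz[gz$block == block, , drop = FALSE]
      dw <- dwell_fractions(g)
      gaze <- rbind(gaze, data.frame(
        subject = subject, intervention = intervention,
        block = block_label(block), pct_canvas = dw$pct_canvas,
        pct_distractor = dw$pct_distractor, pct_wander = dw$pct_wander,
        distractibility = distractibility_score(dw),
        stringsAsFactors = FALSE))
    }
    write_tsv(gaze, file.path(derived, "gaze_summary.tsv"))
  }

  motion <- NULL
  f <- session_file(ses_dir, "headtrack.tsv")
  if (is.na(f)) {
    warning("missing head-tracking stream in ", ses_dir)
    status <- "partial"
  } else {
    tk <- read_tsv(f)
    for (block in c(1, 3)) {
      ms <- motion_summary(tk[tk$block == block, , drop = FALSE])
      motion <- rbind(motion, data.frame(
        subject = subject, intervention = intervention,
        block = block_label(block),
        mean_displacement = ms$mean_displacement,
        mean_rotation = ms$mean_rotation, stringsAsFactors = FALSE))
    }
    write_tsv(motion, file.path(derived, "motion_summary.tsv"))
  }

  ratings <- NULL
  f <- session_file(ses_dir, "ratings.tsv")
  if (is.na(f)) {
    warning("missing ratings stream in ", ses_dir)
    status <- "partial"
  } else {
    rt <- read_tsv(f)
    rt <- rt[rt$block %in% c(1, 3), ]
    ratings <- data.frame(subject = subject, intervention = intervention,
                          block = block_label(rt$block), scale = rt$scale,
                          value = rt$value, stringsAsFactors = FALSE)
  }

  list(status = status, iaf = iaf, alpha = alpha, cpt = cpt, gaze = gaze,
       motion = motion, ratings = ratings)
}

cohort_dv_tables <- function(sessions) {
  alpha <- do.call(rbind, lapply(sessions, `[[`, "alpha"))
  cpt <- do.call(rbind, lapply(sessions, `[[`, "cpt"))
  gaze <- do.call(rbind, lapply(sessions, `[[`, "gaze"))
  motion <- do.call(rbind, lapply(sessions, `[[`, "motion"))
  ratings <- do.call(rbind, lapply(sessions, `[[`, "ratings"))

  tabs <- list()
  grab <- function(df, col) {
    if (is.null(df)) return(NULL)
    condition_table(df$subject, df$intervention, df$block, df[[col]])
  }
  if (!is.null(cpt)) {
    tabs$omission_rate <- grab(cpt, "omission_rate")
    tabs$commission_rate <- grab(cpt, "commission_rate")
    tabs$rtv <- grab(cpt, "rtv")
  }
  if (!is.null(ratings)) {
    for (sc in c("inattention", "hyperactivity", "impulsivity")) {
      r <- ratings[ratings$scale == sc, ]
      tabs[[sc]] <- condition_table(r$subject, r$intervention, r$block,
                                    r$value)
    }
  }
  if (!is.null(alpha)) {
    for (cx in c("cpt", "rest")) {
      a <- alpha[alpha$context == cx, ]
      if (nrow(a) > 0)
        tabs[[paste0("mean_alpha_", cx)]] <-
          condition_table(a$subject, a$intervention, a$block, a$mean_alpha)
    }
  }
  if (!is.null(gaze)) {
    tabs$gaze_canvas <- grab(gaze, "pct_canvas")
    tabs$gaze_distractor <- grab(gaze, "pct_distractor")
    tabs$gaze_wander <- grab(gaze, "pct_wander")
    tabs$distractibility <- grab(gaze, "distractibility")
  }
  if (!is.null(motion)) {
    tabs$head_displacement <- grab(motion, "mean_displacement")
    tabs$head_rotation <- grab(motion, "mean_rotation")
  }
  tabs
}

#' Run the full study pipeline over a cohort
#'
#' Generates the cohort on disk if `config$out_dir` does not already hold
#' one, analyzes every session, assembles a 2x2 condition table per
#' dependent variable, and runs the repeated-measures ANOVA, the four
#' Bonferroni-corrected post-hoc contrasts and (for the alpha-power
#' interaction) the achieved-power analysis. The study-level report is
#' written to `<out_dir>/derived/report.json`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed (used only if the cohort is generated).
#' @param params A [cleaning_params()].
#' @return List with `status`, `tables`, `anova` (per DV), `posthoc`
#'   (per DV), `power`, `outliers` and the report path, invisibly
#'   returnable.
#' @export
run_cohort <- function(config = cohort_config(), seed = 1,
                       params = cleaning_params()) {
  stopifnot(inherits(config, "cohort_config"))
  root <- config$out_dir
  if (!file.exists(file.path(root, "participants.tsv")))
    generate_cohort(config, seed)

  ses_dirs <- sort(list.dirs(root, recursive = TRUE))
  ses_dirs <- ses_dirs[grepl("ses-(active|sham)$", ses_dirs)]
  sessions <- lapply(ses_dirs, run_session, params = params)
  status <- if (any(vapply(sessions, `[[`, "", "status") == "partial"))
    "partial" else "ok"

  tabs <- cohort_dv_tables(sessions)
  anova <- lapply(tabs, rm_anova_2x2)
  posthoc <- lapply(tabs, posthoc_paired_tests)

  power <- NULL
  if (!is.null(tabs$mean_alpha_cpt)) {
    res <- anova$mean_alpha_cpt
    eta <- res$partial_eta_sq[res$effect == "Interaction"]
    n <- length(unique(tabs$mean_alpha_cpt$subject))
    power <- list(
      eta_p_sq = eta,
      achieved_power = interaction_power(power_spec(eta, n)),
      assumptions = list(g = 2, m = 2, rho = 0.5, epsilon = 1,
                         alpha = 0.05))
  }
  outliers <- if (!is.null(tabs$mean_alpha_cpt)) {
    a <- do.call(rbind, lapply(sessions, `[[`, "alpha"))
    flag_alpha_outliers(a[a$context == "cpt", ])
  } else NULL

  derived <- file.path(root, "derived")
  dir.create(derived, showWarnings = FALSE)
  report <- list(
    status = status,
    n_subjects = length(unique(basename(dirname(ses_dirs)))),
    bonferroni_alpha = bonferroni_threshold(0.05, 4),
    anova = lapply(anova, function(a) as.list(as.data.frame(a))),
    posthoc = lapply(posthoc, function(p) as.list(as.data.frame(p))),
    power = power)
  path <- file.path(derived, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(status = status, tables = tabs, anova = anova,
                 posthoc = posthoc, power = power, outliers = outliers,
                 report_path = path))
}
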