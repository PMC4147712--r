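#' Descriptive summary of one measure
#'
#' Mean, minimum, maximum, and sample standard deviation (n - 1
#' denominator), the descriptive row used for each measure and task in a
#' usability study summary table.
#'
#' @param values Numeric vector, length >= 2.
#' @param measure Optional measure name carried into the row.
#' @return A one-row data frame of class `descriptive_row` with columns
#'   `measure`, `mean`, `minimum`, `maximum`, `sd`, `n`.
#' @export
describe <- function(values, measure = NA_character_) {
  if (!is.numeric(values) || length(values) < 2L || anyNA(values)) {
    abort_sr("describe() needs at least 2 non-missing values (sample SD undefined below n = 2)",
             "sr_undefined_measure")
  }
  structure(
    data.frame(measure = measure, mean = mean(values), minimum = min(values),
               maximum = max(values), sd = stats::sd(values),
               n = length(values), stringsAsFactors = FALSE),
    class = c("descriptive_row", "data.frame")
  )
}

#' One-way between-groups ANOVA for two groups
#'
#' The classical equal-variance one-way analysis of variance,
#' `F = MS_between / MS_within` with `(k - 1, N - k)` degrees of freedom,
#' as used to compare the text- and graphic-task groups measure by measure.
#' For two groups, F equals the square of the pooled-variance two-sample t
#' statistic.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return A list of class `anova_result` with `F`, `df_between`,
#'   `df_within`, `p_value`.
#' @export
oneway_anova <- function(group_a, group_b) {
  if (!is.numeric(group_a) || !is.numeric(group_b) ||
      length(group_a) < 2L || length(group_b) < 2L ||
      anyNA(group_a) || anyNA(group_b)) {
    abort_sr("each group needs at least 2 non-missing values", "sr_undefined_measure")
  }
  values <- c(group_a, group_b)
  grp <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
  if (stats::var(values) == 0) {
    # fully degenerate data: no variance anywhere, F defined as 0
    return(structure(list(F = 0, df_between = 1L,
                          df_within = length(values) - 2L, p_value = 1),
                     class = "anova_result"))
  }
  fit <- stats::oneway.test(values ~ grp, var.equal = TRUE)
  structure(
    list(F = unname(fit$statistic),
         df_between = as.integer(fit$parameter[["num df"]]),
         df_within = as.integer(fit$parameter[["denom df"]]),
         p_value = unname(fit$p.value)),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.3f, p = %.3f\n",
              x$df_between, x$df_within, x$F, x$p_value))
  invisible(x)
}

#' Pearson correlation with t-transform significance
#'
#' Product-moment correlation between two measures, with a two-sided
#' p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @param names Optional length-2 character vector naming the measure pair.
#' @return A list of class `correlation_result` with `pair`, `r`, `n`,
#'   `p_value`.
#' @export
pearson <- function(x, y, names = c("x", "y")) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) ||
      length(x) < 3L || anyNA(x) || anyNA(y)) {
    abort_sr("pearson() needs two equal-length numeric vectors, n >= 3, no missing values",
             "sr_undefined_measure")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_sr("correlation is undefined for a constant vector", "sr_undefined_measure")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(
    list(pair = names, r = unname(ct$estimate), n = length(x),
         p_value = unname(ct$p.value)),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s ~ %s: r = %.3f (n = %d), p = %.3f\n",
              x$pair[1], x$pair[2], x$r, x$n, x$p_value))
  invisible(x)
}

STUDY_MEASURES <- c("avg_response_time_s", "avg_elapsed_per_question_s",
                    "correct_answer_score", "posttask_score", "tlx_score")

#' Replay a synthetic two-task usability study
#'
#' Runs the full experiment for every cohort member and both task
#' modalities: an assessment session calibrates the participant's recall
#' time, a training session runs at expanding intervals from that recall
#' time, the five measures are computed from the training session, and the
#' subjective instruments (TLX and post-task satisfaction) are simulated
#' from the session's difficulty. The study report then mirrors the
#' standard two-task summary: per-measure descriptives and a between-task
#' one-way ANOVA, and per-task Pearson correlations of the time and
#' workload measures against the correct answer score.
#'
#' @param cohort List of [participant_model()]s (e.g. [generate_cohort()]).
#' @param banks Named list with `text` and `graphic` [item_bank()]s;
#'   defaults to the built-in demonstration banks.
#' @param config An [engine_config()].
#' @param seed Integer seed controlling the subjective-instrument
#'   weighting draws and any session randomness beyond the cohort members'
#'   own streams.
#' @return A list of class `study_report` with `measures` (one row per
#'   participant x modality), `descriptives` (measure x task descriptive
#'   rows with F and p), `correlations` (per-task correlation rows against
#'   the correct answer score), and `sessions` (all session logs).
#' @export
run_synthetic_study <- function(cohort,
                                banks = list(text = builtin_bank("text"),
                                             graphic = builtin_bank("graphic")),
                                config = engine_config(),
                                seed = 1L) {
  if (!is.list(cohort) || !length(cohort)) {
    abort_sr("cohort must be a non-empty list of participant models", "sr_contract_error")
  }
  stopifnot(all(MODALITIES %in% names(banks)))

  rows <- list()
  sessions <- list()
  # fresh per-run participant streams so the same cohort object can be reused
  cohort <- lapply(cohort, function(m) {
    m$state <- rng_stream(m$seed)
    m
  })
  pair_grid <- t(utils::combn(TLX_SUBSCALES, 2))
  for (m in cohort) {
    for (modality in MODALITIES) {
      assess <- run_assessment(banks[[modality]], m, config)
      train <- run_training(banks[[modality]], m, config,
                            recall_time_s = max(assess$recall_time_s,
                                                config$min_delay_s))
      subj <- simulate_subjective_outcomes(m, train)
      # pairwise weighting: subscales rated higher win their comparisons
      wts <- withr::with_seed(as.integer(seed) + m$seed %% 1000L, {
        jitter_r <- unclass(subj$tlx) + stats::runif(6, 0, 1e-3)
        winner <- ifelse(jitter_r[pair_grid[, 1]] >= jitter_r[pair_grid[, 2]],
                         pair_grid[, 1], pair_grid[, 2])
        tlx_weights_from_pairs(data.frame(a = pair_grid[, 1], b = pair_grid[, 2],
                                          winner = winner,
                                          stringsAsFactors = FALSE))
      })
      ms <- compute_measures(train, subj$tlx, wts, subj$posttask)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = ms$participant_id, modality = modality,
        recall_time_s = assess$recall_time_s,
        avg_response_time_s = ms$avg_response_time_s,
        avg_elapsed_per_question_s = ms$avg_elapsed_per_question_s,
        correct_answer_score = ms$correct_answer_score,
        posttask_score = ms$posttask_score, tlx_score = ms$tlx_score,
        stringsAsFactors = FALSE)
      sessions[[paste(m$participant_id, modality, sep = ".")]] <-
        list(assessment = assess, training = train)
    }
  }
  measures_df <- do.call(rbind, rows)
  rownames(measures_df) <- NULL

  descr <- list()
  for (meas in STUDY_MEASURES) {
    a <- measures_df[[meas]][measures_df$modality == "text"]
    b <- measures_df[[meas]][measures_df$modality == "graphic"]
    an <- if (length(a) >= 2 && length(b) >= 2) {
      tryCatch(oneway_anova(a, b), spacedrecall_error = function(e) NULL)
    }
    for (modality in MODALITIES) {
      v <- measures_df[[meas]][measures_df$modality == modality]
      d <- if (length(v) >= 2) describe(v, meas) else
        data.frame(measure = meas, mean = mean(v), minimum = min(v),
                   maximum = max(v), sd = NA_real_, n = length(v))
      d$modality <- modality
      d$F <- if (is.null(an)) NA_real_ else an$F
      d$p_value <- if (is.null(an)) NA_real_ else an$p_value
      descr[[length(descr) + 1L]] <- as.data.frame(d)
    }
  }
  descriptives <- do.call(rbind, descr)
  rownames(descriptives) <- NULL

  corr <- list()
  for (modality in MODALITIES) {
    sub <- measures_df[measures_df$modality == modality, ]
    for (meas in c("avg_response_time_s", "avg_elapsed_per_question_s",
                   "posttask_score", "tlx_score")) {
      cr <- tryCatch(
        pearson(sub[[meas]], sub$correct_answer_score,
                names = c(meas, "correct_answer_score")),
        spacedrecall_error = function(e) NULL)
      corr[[length(corr) + 1L]] <- data.frame(
        modality = modality, measure = meas,
        against = "correct_answer_score",
        r = if (is.null(cr)) NA_real_ else cr$r,
        p_value = if (is.null(cr)) NA_real_ else cr$p_value,
        n = nrow(sub), stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, corr)
  rownames(correlations) <- NULL

  structure(list(measures = measures_df, descriptives = descriptives,
                 correlations = correlations, sessions = sessions,
                 seed = as.integer(seed)),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  n <- length(unique(x$measures$participant_id))
  cat(sprintf("<study_report> %d participants x 2 modalities (seed %d)\n",
              n, x$seed))
  cat("\nDescriptives (per measure and task, with between-task ANOVA):\n")
  print(format(x$descriptives, digits = 4), row.names = FALSE)
  cat("\nCorrelations against correct answer score:\n")
  print(format(x$correlations, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Write a study report to CSV (and JSON)
#'
#' Emits `measures.csv` (participant x modality rows), `descriptives.csv`
#' (summary-table shape: measure x task with mean/min/max/SD and the
#' between-task F and p), `correlations.csv` (per-task correlation rows),
#' and `report.json` holding all three.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    measures = file.path(dir, "measures.csv"),
    descriptives = file.path(dir, "descriptives.csv"),
    correlations = file.path(dir, "correlations.csv"),
    json = file.path(dir, "report.json")
  )
  utils::write.csv(report$measures, paths["measures"], row.names = FALSE)
  utils::write.csv(report$descriptives, paths["descriptives"], row.names = FALSE)
  utils::write.csv(report$correlations, paths["correlations"], row.names = FALSE)
  jsonlite::write_json(
    list(measures = report$measures, descriptives = report$descriptives,
         correlations = report$correlations, seed = report$seed),
    paths["json"], auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(paths)
}
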