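#' Write sessions to a tidy CSV
#'
#' One long file: columns `subject, visit, task, limb, t, ax, ay, az`;
#' missing samples become empty cells.
#'
#' @param sessions Tidy session tibble (one session or a whole cohort).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  readr::write_csv(sessions, path, na = "")
  invisible(path)
}

#' Read sessions from a tidy CSV
#'
#' Parses and validates the tidy session schema: all required columns
#' present, no duplicate `(subject, visit, task, limb, t)` rows, time
#' strictly increasing within each limb. Empty cells become missing
#' samples (`NA`).
#'
#' @param path CSV file written by [write_sessions()] (or any file in the
#'   same schema).
#' @return Long tidy session tibble; attribute `"rate_hz"` inferred from
#'   the median time step.
#' @export
read_sessions <- function(path) {
  # a missing column triggers our own schema error below, not readr's warning
  x <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    subject = readr::col_character(), visit = readr::col_character(),
    task = readr::col_character(), limb = readr::col_character(),
    t = readr::col_double(), ax = readr::col_double(),
    ay = readr::col_double(), az = readr::col_double()),
    na = c("", "NA")))
  need <- c("subject", "visit", "task", "limb", "t", "ax", "ay", "az")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("session file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  key <- paste(x$subject, x$visit, x$task, x$limb, x$t)
  if (anyDuplicated(key))
    stop("duplicate (subject, visit, task, limb, t) rows", call. = FALSE)
  bad <- x %>%
    dplyr::group_by(.data$subject, .data$visit, .data$task, .data$limb) %>%
    dplyr::summarise(mono = all(diff(.data$t) > 0), .groups = "drop")
  if (any(!bad$mono))
    stop("non-monotone time within a limb series", call. = FALSE)
  attr(x, "rate_hz") <- 1 / median(diff(x$t[x$limb == x$limb[1] &
    x$subject == x$subject[1] & x$visit == x$visit[1] &
    x$task == x$task[1]]))
  x
}

#' Apply the missing-data exclusion rule
#'
#' Sessions whose worst limb exceeds the missing-data threshold are moved
#' to an exclusion list with the offending fraction recorded; all other
#' sessions pass through unchanged. Exclusion is per session (all four
#' limbs are needed for the multidimensional analysis, so a single bad
#' channel sinks the session).
#'
#' @param sessions Long tidy session tibble.
#' @param threshold Maximum tolerated missing fraction in `(0, 1]`
#'   (default 0.15).
#' @return List with `kept` (tibble of sessions) and `excluded` (tibble
#'   `subject, visit, task, missing_fraction`).
#' @export
apply_exclusions <- function(sessions, threshold = 0.15) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  fr <- sessions %>%
    dplyr::group_by(.data$subject, .data$visit, .data$task, .data$limb) %>%
    dplyr::summarise(miss = mean(is.na(.data$ax) | is.na(.data$ay) |
                                   is.na(.data$az)), .groups = "drop") %>%
    dplyr::group_by(.data$subject, .data$visit, .data$task) %>%
    dplyr::summarise(missing_fraction = max(.data$miss), .groups = "drop")
  bad <- fr[fr$missing_fraction > threshold, ]
  kept <- dplyr::anti_join(sessions, bad,
                           by = c("subject", "visit", "task"))
  attr(kept, "rate_hz") <- attr(sessions, "rate_hz")
  list(kept = kept, excluded = bad)
}

#' Pipeline configuration
#'
#' Assembles the configuration of an end-to-end run: the cohort design (or
#' an input CSV of real sessions), the embedding preset or estimation
#' switch, the RQA conventions, the target recurrence rate, the
#' missing-data exclusion threshold and the stage toggles. Can also be
#' loaded from a flat YAML key-value file with [read_pipeline_config()].
#'
#' @param out_dir Output directory for the CSV/JSON artifacts.
#' @param design A [cohort_design()] used when simulating (ignored if
#'   `input_csv` is given).
#' @param input_csv Optional path to a tidy session CSV to analyse instead
#'   of simulating.
#' @param tau,m Embedding preset; set either to `NA` to estimate on each
#'   subject's anchor visit.
#' @param target_rr Target recurrence rate, percent.
#' @param rqa An [rqa_config()].
#' @param exclusion_threshold Missing-data exclusion rule (default 0.15).
#' @param per_task Calibrate embedding parameters per task (default) or
#'   pooled.
#' @param stages Character vector of enabled stages, a subset of
#'   `c("rqa", "surrogate", "stats")` (simulation/reading, preprocessing
#'   and exclusion always run).
#' @param seed Master seed for the surrogate shuffles.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = tempfile("limbrqa-run-"),
                            design = cohort_design(),
                            input_csv = NULL,
                            tau = 1, m = 14, target_rr = 5,
                            rqa = rqa_config(),
                            exclusion_threshold = 0.15,
                            per_task = TRUE,
                            stages = c("rqa", "surrogate", "stats"),
                            seed = 1) {
  structure(list(out_dir = out_dir, design = design, input_csv = input_csv,
                 tau = tau, m = m, target_rr = target_rr, rqa = rqa,
                 exclusion_threshold = exclusion_threshold,
                 per_task = per_task, stages = stages, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Recognized keys mirror the arguments of [pipeline_config()] and
#' [cohort_design()] (`n_per_visit`, `effect`, `rattle_s`, `freeplay_s`,
#' `missing_rate`, `rate_hz`, `tau`, `m`, `target_rr`, `lmin`, `theiler`,
#' `exclusion_threshold`, `stages`, `seed`, `out_dir`, `input_csv`).
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  kv <- yaml::read_yaml(path)
  design_keys <- intersect(names(kv), names(formals(cohort_design)))
  design <- do.call(cohort_design, kv[design_keys])
  rqa_keys <- intersect(names(kv), names(formals(rqa_config)))
  rqa <- do.call(rqa_config, kv[rqa_keys])
  args <- kv[intersect(names(kv), setdiff(names(formals(pipeline_config)),
                                          c("design", "rqa")))]
  do.call(pipeline_config, c(args, list(design = design, rqa = rqa)))
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate (or read), exclude,
#' preprocess, fix embedding parameters per subject, MdRQA, shuffled
#' surrogates, repeated-measures statistics — logging per-stage counts, and
#' writes the artifacts to `config$out_dir`: `measures.csv` (one row per
#' kept session), `control.csv` (surrogate measures and paired tests),
#' `params.csv` (per-subject embedding parameters) and `stats.json`
#' (per-measure Wald and contrast tables). Fully reproducible under the
#' config's seeds.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list: `sessions, kept, excluded, params, measures,
#'   surrogate_measures, surrogate_tests, stats, paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(measures = file.path(config$out_dir, "measures.csv"),
                control = file.path(config$out_dir, "control.csv"),
                params = file.path(config$out_dir, "params.csv"),
                stats = file.path(config$out_dir, "stats.json"))

  sessions <- if (!is.null(config$input_csv)) {
    log_stage("input", "reading sessions from %s", config$input_csv)
    read_sessions(config$input_csv)
  } else {
    log_stage("simulate", "generating cohort (seed %d)", config$design$seed)
    generate_cohort(config$design)
  }
  n_sessions <- nrow(dplyr::distinct(sessions, .data$subject, .data$visit,
                                     .data$task))
  log_stage("input", "%d sessions in", n_sessions)

  excl <- apply_exclusions(sessions, config$exclusion_threshold)
  log_stage("exclude", "%d kept, %d excluded (threshold %.2f)",
            n_sessions - nrow(excl$excluded), nrow(excl$excluded),
            config$exclusion_threshold)
  kept <- excl$kept

  keys <- dplyr::distinct(kept, .data$subject, .data$visit, .data$task)
  ms_list <- purrr::map(seq_len(nrow(keys)), function(i) {
    preprocess_session(dplyr::semi_join(kept, keys[i, ],
                                        by = c("subject", "visit", "task")))
  })
  log_stage("preprocess", "%d sessions preprocessed", length(ms_list))

  est_tau <- if (is.na(config$tau)) NULL else config$tau
  est_m <- if (is.na(config$m)) NULL else config$m
  params <- fix_params_per_subject(kept, target_rr = config$target_rr,
                                   tau = est_tau, m = est_m,
                                   per_task = config$per_task,
                                   theiler = config$rqa$theiler)
  readr::write_csv(params, paths$params)
  log_stage("params", "%d parameter sets calibrated", nrow(params))

  out <- list(sessions = sessions, kept = kept, excluded = excl$excluded,
              params = params, paths = paths)
  if (!("rqa" %in% config$stages)) return(invisible(out))

  param_for <- function(key) {
    p <- params[params$subject == key$subject, ]
    if (config$per_task) p <- p[p$task == key$task, ]
    p[1, ]
  }
  measures <- purrr::map_dfr(seq_len(nrow(keys)), function(i) {
    p <- param_for(keys[i, ])
    mdrqa(ms_list[[i]], tau = p$tau, m = p$m, epsilon = p$epsilon,
          config = config$rqa)
  })
  readr::write_csv(measures, paths$measures)
  log_stage("rqa", "%d measure rows written", nrow(measures))
  out$measures <- measures

  if ("surrogate" %in% config$stages) {
    shuf_seeds <- with_seed(config$seed, sample.int(2^31 - 2, nrow(keys)))
    surro <- purrr::map_dfr(seq_len(nrow(keys)), function(i) {
      p <- param_for(keys[i, ])
      mdrqa(shuffle_channels(ms_list[[i]], seed = shuf_seeds[i]),
            tau = p$tau, m = p$m, epsilon = p$epsilon, config = config$rqa)
    })
    tests <- surrogate_analysis(measures, surro)
    readr::write_csv(dplyr::bind_rows(
      dplyr::mutate(surro, role = "shuffled")), paths$control)
    readr::write_csv(tests, sub("[.]csv$", "_tests.csv", paths$control))
    log_stage("surrogate", "%d surrogate rows, %d paired tests",
              nrow(surro), nrow(tests))
    out$surrogate_measures <- surro
    out$surrogate_tests <- tests
  }

  if ("stats" %in% config$stages) {
    stats <- lapply(c("ent", "rr", "ml"), function(mm) {
      fit <- fit_gee(measures, mm)
      list(measure = mm, wald = wald_tests(fit),
           contrasts = bonferroni_pairwise(fit),
           cells = fit$cells)
    })
    names(stats) <- c("ent", "rr", "ml")
    jsonlite::write_json(stats, paths$stats, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    log_stage("stats", "Wald and contrast tables written for 3 measures")
    out$stats <- stats
  }
  invisible(out)
}
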