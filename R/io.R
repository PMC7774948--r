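SESSION_COLUMNS <- c("t_s", "eye_yaw_deg", "eye_pitch_deg", "eye_valid",
                     "head_yaw_deg", "head_pitch_deg", "head_valid")

#' Assemble a session from its parts
#'
#' Builds a `gaze_session` from synchronized eye and head traces, the trial
#' windows and metadata. [simulate_session()] and [read_session()] both
#' produce sessions through this constructor.
#'
#' @param eye eye `effector_trace` (head frame).
#' @param head head `effector_trace` (world frame), same clock as `eye`.
#' @param trials data.frame of half-open trial windows (`start`, `end`, s).
#' @param participant,condition,group metadata labels.
#' @param geometry a `scene_geometry`.
#' @param latent optional per-sample latent ground truth (simulated sessions).
#' @param params optional generating parameters.
#' @return A `gaze_session`.
#' @export
gaze_session <- function(eye, head,
                         trials = data.frame(start = numeric(0),
                                             end = numeric(0)),
                         participant = NA, condition = NA, group = NA,
                         geometry = default_geometry(), latent = NULL,
                         params = NULL) {
  stopifnot(is_effector_trace(eye), is_effector_trace(head))
  if (eye$effector != "eye" || head$effector != "head")
    stop("`eye` and `head` must be the matching effector traces", call. = FALSE)
  if (length(eye) != length(head))
    stop("eye and head traces must share one clock", call. = FALSE)
  structure(list(eye = eye, head = head, trials = trials,
                 meta = list(participant = participant, condition = condition,
                             group = group),
                 geometry = geometry, latent = latent, params = params),
            class = "gaze_session")
}

#' Write a session to CSV plus a JSON metadata sidecar
#'
#' The CSV carries the synchronized traces with columns `t_s`,
#' `eye_yaw_deg`, `eye_pitch_deg`, `eye_valid`, `head_yaw_deg`,
#' `head_pitch_deg`, (`head_roll_deg` when present), `head_valid`, written
#' at 9 significant digits so a read-back reproduces the session exactly.
#' Participant, condition, group and the trial windows go to a `.json`
#' sidecar next to the CSV.
#'
#' @param session a `gaze_session`.
#' @param path CSV output path; the sidecar is `<path without .csv>.json`.
#' @return Invisibly, the two paths written.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "gaze_session"))
  es <- session$eye$samples
  hs <- session$head$samples
  # 9 significant decimal digits: reading the file back and rewriting it
  # reproduces the bytes exactly
  num <- function(x) sprintf("%.9g", x)
  df <- data.frame(
    t_s = num(es$t),
    eye_yaw_deg = num(es$yaw),
    eye_pitch_deg = num(es$pitch),
    eye_valid = as.integer(es$valid),
    head_yaw_deg = num(hs$yaw),
    head_pitch_deg = num(hs$pitch),
    head_valid = as.integer(hs$valid)
  )
  if (!is.null(hs$roll)) df$head_roll_deg <- num(hs$roll)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta_path <- sub("\\.csv$", ".json", path)
  if (identical(meta_path, path)) meta_path <- paste0(path, ".json")
  meta <- list(participant = session$meta$participant,
               condition = session$meta$condition,
               group = session$meta$group,
               rate_hz = session$eye$rate,
               trial_windows = session$trials)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = path, meta = meta_path))
}

#' Read a session from CSV (+ JSON sidecar)
#'
#' Inverse of [write_session()]. The CSV must contain the schema columns
#' exactly; missing columns are reported by name, non-monotonic timestamps
#' by first offending row, and non-finite angles on valid samples by line
#' number.
#'
#' @param path CSV path; the metadata sidecar `<path without .csv>.json` is
#'   read when present.
#' @return A `gaze_session` (without latent ground truth).
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  miss <- setdiff(SESSION_COLUMNS, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_t <- which(diff(df$t_s) <= 0)
  if (length(bad_t))
    stop(sprintf("t_s not strictly increasing; first offense at row %d",
                 bad_t[1] + 1L), call. = FALSE)
  check_finite <- function(vals, valid, nm) {
    bad <- which(as.logical(valid) & !is.finite(vals))
    if (length(bad))
      stop(sprintf("non-finite %s on valid sample(s); first at line %d",
                   nm, bad[1] + 1L), call. = FALSE)
  }
  check_finite(df$eye_yaw_deg, df$eye_valid, "eye_yaw_deg")
  check_finite(df$eye_pitch_deg, df$eye_valid, "eye_pitch_deg")
  check_finite(df$head_yaw_deg, df$head_valid, "head_yaw_deg")
  check_finite(df$head_pitch_deg, df$head_valid, "head_pitch_deg")

  meta_path <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(meta_path) && meta_path != path) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  rate <- meta$rate_hz %||% 120
  trials <- if (!is.null(meta$trial_windows) && length(meta$trial_windows)) {
    as.data.frame(meta$trial_windows)
  } else data.frame(start = numeric(0), end = numeric(0))
  eye <- effector_trace(df$t_s, df$eye_yaw_deg, df$eye_pitch_deg,
                        as.logical(df$eye_valid), effector = "eye",
                        rate = rate)
  head <- effector_trace(df$t_s, df$head_yaw_deg, df$head_pitch_deg,
                         as.logical(df$head_valid), effector = "head",
                         rate = rate, roll = df$head_roll_deg)
  gaze_session(eye, head, trials,
               participant = meta$participant %||% NA,
               condition = meta$condition %||% NA,
               group = meta$group %||% NA)
}

#' Pipeline configuration
#'
#' Bundles every constant of the end-to-end analysis. The defaults are the
#' analysis constants: 120 ms entropy bins, 1 deg displacement threshold,
#' 1 deg density-filter bins with min count 20, standard entropy mode,
#' paper_df ANOVA mode.
#'
#' @param cohort a [cohort_spec()] to simulate, or `NULL` when reading files.
#' @param session_paths character vector of session CSVs (used when
#'   `cohort` is `NULL`).
#' @param geometry a `scene_geometry` (default [default_geometry()]).
#' @param bin_ms,theta,entropy_policy,entropy_mode entropy stage constants.
#' @param filter_bin_deg,filter_min_count density-filter constants.
#' @param stats_mode `"paper_df"` or `"mixed"`.
#' @param gaze_mode `"compose"` or `"additive"`.
#' @param out_dir output directory for the report CSVs (`NULL` = no files).
#' @param seed integer seed for the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_spec(), session_paths = NULL,
                            geometry = default_geometry(), bin_ms = 120,
                            theta = 1, entropy_policy = "displacement_threshold",
                            entropy_mode = "standard", filter_bin_deg = 1,
                            filter_min_count = 20,
                            stats_mode = c("paper_df", "mixed"),
                            gaze_mode = c("compose", "additive"),
                            out_dir = NULL, seed = 1L) {
  structure(list(cohort = cohort, session_paths = session_paths,
                 geometry = geometry, bin_ms = bin_ms, theta = theta,
                 entropy_policy = entropy_policy, entropy_mode = entropy_mode,
                 filter_bin_deg = filter_bin_deg,
                 filter_min_count = filter_min_count,
                 stats_mode = match.arg(stats_mode),
                 gaze_mode = match.arg(gaze_mode),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

session_metrics <- function(session, config) {
  slopes <- session_slopes(session, config$filter_bin_deg,
                           config$filter_min_count)
  ent <- lapply(c("eye", "head", "gaze"), function(eff) {
    r <- session_entropy(session, eff, policy = config$entropy_policy,
                         theta = config$theta, mode = config$entropy_mode,
                         bin_ms = config$bin_ms,
                         gaze_mode = config$gaze_mode)
    data.frame(participant = session$meta$participant,
               condition = session$meta$condition,
               group = session$meta$group, effector = eff,
               raw_bits = r$raw_bits, normalized = r$normalized,
               n_bins = r$n_bins, policy = r$policy, mode = r$mode)
  })
  list(slopes = slopes, entropy = do.call(rbind, ent))
}

#' Run the end-to-end analysis pipeline
#'
#' For each session (simulated from the config's cohort spec, or read from
#' CSV files): reconstruct gaze, compute trial-restricted density-filtered
#' coordination slopes (yaw and pitch) and full-scenario time-based
#' entropies (eye, head, gaze). Then at cohort level: the slope summary,
#' the entropy table, Kolmogorov-Smirnov comparisons of the rotation
#' distributions between conditions (per effector and axis, trial windows),
#' ANOVA (with Box-Cox skew gate) and Tukey HSD per outcome. Sessions that
#' fail are skipped with a logged reason; the run aborts when more than 20%
#' fail. Deterministic given the config seed.
#'
#' @param config a [pipeline_config()].
#' @return A report bundle (list): `slopes`, `slope_summary`, `entropy`,
#'   `ks`, `anova`, `tukey`, `failures`, `manifest`. Written as CSVs plus a
#'   JSON manifest under `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  if (!is.null(config$cohort)) {
    config$cohort$master_seed <- config$seed
    sim <- simulate_cohort(config$cohort)
    sessions <- sim$sessions
  } else {
    if (is.null(config$session_paths))
      stop("config needs either a cohort spec or session paths", call. = FALSE)
    sessions <- lapply(config$session_paths, read_session)
  }

  metrics <- vector("list", length(sessions))
  failures <- character(0)
  for (i in seq_along(sessions)) {
    m <- tryCatch(session_metrics(sessions[[i]], config), error = function(e) e)
    if (inherits(m, "error")) {
      failures <- c(failures, sprintf("session %d (%s): %s", i,
                                      sessions[[i]]$meta$participant,
                                      conditionMessage(m)))
    } else {
      metrics[[i]] <- m
    }
  }
  ok <- !vapply(metrics, is.null, logical(1))
  if (mean(!ok) > 0.2)
    stop(sprintf("%d of %d sessions failed:\n%s", sum(!ok), length(sessions),
                 paste(failures, collapse = "\n")), call. = FALSE)
  slopes <- do.call(rbind, lapply(metrics[ok], `[[`, "slopes"))
  entropy <- do.call(rbind, lapply(metrics[ok], `[[`, "entropy"))
  slope_summary <- group_average_slopes(slopes)

  # KS: rotation distributions between conditions, per effector x axis,
  # pooled across participants within the trial windows
  ks_rows <- list()
  for (eff in c("eye", "head", "gaze")) {
    for (ax in c("yaw", "pitch")) {
      pools <- lapply(c("optimal", "degraded"), function(cond) {
        unlist(lapply(sessions[ok], function(s) {
          if (s$meta$condition != cond) return(NULL)
          tr <- if (eff == "gaze") {
            reconstruct_gaze(s$eye, s$head, config$gaze_mode)
          } else s[[eff]]
          tr <- restrict_to_trials(tr, s$trials)
          tr$samples[[ax]][tr$samples$valid]
        }))
      })
      kr <- ks_two_sample(pools[[1]], pools[[2]])
      ks_rows[[length(ks_rows) + 1L]] <- data.frame(
        effector = eff, axis = ax, D = kr$statistic, p = kr$p_value,
        n_optimal = kr$n_a, n_degraded = kr$n_b)
    }
  }
  ks_tab <- do.call(rbind, ks_rows)

  # ANOVA + Tukey per outcome
  outcomes <- list(
    slope_yaw = slopes[slopes$axis == "yaw",
                       c("participant", "condition", "group", "slope")],
    slope_pitch = slopes[slopes$axis == "pitch",
                         c("participant", "condition", "group", "slope")],
    entropy_eye = entropy[entropy$effector == "eye",
                          c("participant", "condition", "group", "normalized")],
    entropy_head = entropy[entropy$effector == "head",
                           c("participant", "condition", "group", "normalized")],
    entropy_gaze = entropy[entropy$effector == "gaze",
                           c("participant", "condition", "group", "normalized")]
  )
  anova_tabs <- list()
  tukey_tabs <- list()
  transforms <- list()
  for (nm in names(outcomes)) {
    d <- outcomes[[nm]]
    names(d)[4] <- "value"
    bc <- boxcox_if_skewed(d$value)
    d$value <- bc$values
    transforms[[nm]] <- bc$record
    at <- anova_condition_group(d, config$stats_mode)
    at$outcome <- nm
    anova_tabs[[nm]] <- at
    tk <- tukey_hsd(d)
    tk$outcome <- nm
    tukey_tabs[[nm]] <- tk
  }
  anova_tab <- do.call(rbind, anova_tabs)
  rownames(anova_tab) <- NULL
  tukey_tab <- do.call(rbind, tukey_tabs)
  rownames(tukey_tab) <- NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("gazescan")),
    seed = config$seed,
    n_sessions = length(sessions), n_failed = sum(!ok),
    bin_ms = config$bin_ms, theta = config$theta,
    entropy_policy = config$entropy_policy,
    entropy_mode = config$entropy_mode,
    filter_bin_deg = config$filter_bin_deg,
    filter_min_count = config$filter_min_count,
    stats_mode = config$stats_mode, gaze_mode = config$gaze_mode,
    transforms = transforms,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  bundle <- list(slopes = slopes, slope_summary = slope_summary,
                 entropy = entropy, ks = ks_tab, anova = anova_tab,
                 tukey = tukey_tab, failures = failures, manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) utils::write.csv(
      x, file.path(config$out_dir, f), row.names = FALSE)
    wr(slopes, "slopes.csv")
    wr(slope_summary, "slope_summary.csv")
    wr(entropy, "entropy.csv")
    wr(ks_tab, "ks.csv")
    wr(anova_tab, "anova.csv")
    wr(tukey_tab, "tukey.csv")
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}
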