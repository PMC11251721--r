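# Trajectory CSV schema and JSON run configuration.
#
# Trajectory files are plain comma-separated UTF-8 text with a mandatory
# header and one row per sample, grouped by trial and time-sorted:
#   session_id, subject_id, condition, trial_id, start_direction_deg,
#   t_s, x_m, y_m, scene_dir_deg, outcome
# The first line is a schema stamp ("#placenav-trajectory vMAJOR.MINOR");
# readers reject files with a newer major version.

trajectory_schema_version <- c(major = 1L, minor = 0L)

trajectory_columns <- c("session_id", "subject_id", "condition", "trial_id",
                        "start_direction_deg", "t_s", "x_m", "y_m",
                        "scene_dir_deg", "outcome")

schema_stamp <- function()
  sprintf("#placenav-trajectory v%d.%d", trajectory_schema_version["major"],
          trajectory_schema_version["minor"])

#' Write sessions to a trajectory CSV file
#'
#' @param sessions a `vr_session` or a list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(sessions, path) {
  if (inherits(sessions, "vr_session")) sessions <- list(sessions)
  rows <- lapply(sessions, function(se) {
    do.call(rbind, lapply(se$trials, function(tr) {
      data.frame(session_id = tr$session_id, subject_id = tr$subject_id,
                 condition = tr$condition, trial_id = tr$trial_id,
                 start_direction_deg = tr$start_direction,
                 t_s = tr$samples$t, x_m = tr$samples$x, y_m = tr$samples$y,
                 scene_dir_deg = tr$samples$scene_dir, outcome = tr$outcome,
                 stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(schema_stamp(), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sessions from a trajectory CSV file
#'
#' Validates the schema stamp (rejecting newer major versions), the
#' column set, outcome tokens, and within-trial time monotonicity, naming
#' the offending trial on failure.
#'
#' @param path trajectory CSV path.
#' @return list of `vr_session` objects (possibly empty, with a warning).
#' @export
read_trajectories <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "#placenav-trajectory")) {
    ver <- regmatches(first, regexec("v([0-9]+)\\.([0-9]+)", first))[[1]]
    if (length(ver) == 3 &&
        as.integer(ver[2]) > trajectory_schema_version["major"])
      stop("trajectory file uses schema ", ver[1],
           ", newer than supported major version ",
           trajectory_schema_version["major"])
  }
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(trajectory_columns, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!nrow(df)) {
    warning("empty trajectory file: ", path)
    return(list())
  }
  bad <- setdiff(unique(df$outcome), c("high", "low", "timeout"))
  if (length(bad))
    stop("unknown outcome token(s): ", paste(bad, collapse = ", "))

  sessions <- list()
  for (sid in unique(df$session_id)) {
    sdf <- df[df$session_id == sid, , drop = FALSE]
    trials <- list()
    for (tid in unique(sdf$trial_id)) {
      tdf <- sdf[sdf$trial_id == tid, , drop = FALSE]
      if (is.unsorted(tdf$t_s, strictly = TRUE))
        stop("non-monotone time in session ", sid, ", trial ", tid)
      samples <- data.frame(t = tdf$t_s, x = tdf$x_m, y = tdf$y_m,
                            scene_dir = tdf$scene_dir_deg)
      trials[[length(trials) + 1]] <-
        new_trial(samples, tdf$start_direction_deg[1], tdf$outcome[1],
                  reward_drops = NA_integer_, bumps = integer(0),
                  condition = tdf$condition[1], trial_id = tdf$trial_id[1],
                  session_id = sid, subject_id = tdf$subject_id[1])
    }
    sessions[[length(sessions) + 1]] <-
      structure(list(trials = trials, subject_id = sdf$subject_id[1],
                     condition = sdf$condition[1], day = NA_integer_,
                     seed = NA),
                class = "vr_session")
  }
  sessions
}

#' Default run configuration
#'
#' A serializable description of a full pipeline run: environment
#' overrides, per-condition agent parameters, and analysis options.
#'
#' @param conditions agent conditions to include (names of `agents`).
#' @return nested list, JSON round-trippable via [write_run_config()].
#' @export
default_run_config <- function(conditions = c("expert", "dMUS", "iMUS")) {
  agents <- lapply(conditions, function(cn) unclass(default_params(cn)))
  names(agents) <- conditions
  list(
    schema = "placenav-config v1.0",
    environment = list(overrides = list()),
    agents = agents,
    simulation = list(n_trials = 40, n_subjects = 8, seed = 1),
    analysis = list(n_perm = 2000, alpha = 0.05, seed = 1,
                    first_turn_threshold = 10)
  )
}

#' Write a run configuration to JSON
#' @param config nested list as from [default_run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from JSON
#' @param path JSON path.
#' @return nested configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("agents", "simulation", "analysis")
  missing_f <- setdiff(needed, names(cfg))
  if (length(missing_f))
    stop("config missing field(s): ", paste(missing_f, collapse = ", "))
  cfg
}

config_agent_params <- function(cfg, condition) {
  a <- cfg$agents[[condition]]
  if (is.null(a)) return(default_params(condition))
  a$condition <- NULL
  do.call(default_params, c(list(condition = condition), a))
}

config_arena <- function(cfg) {
  ov <- cfg$environment$overrides %||% list()
  build_main_arena(ov)
}
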