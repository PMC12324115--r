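#' Read and write the pipeline's CSV tables
#'
#' Plain-CSV dialects used by the command-line pipeline:
#' * session table: `patient_id,day,event` with `day` an integer offset
#'   (day 0 = study start) and `event` one of `HD`, `PD`, `KT`, `DEATH`;
#' * patient table: `patient_id,entry_day,censor_day,archetype`;
#' * episode table: `patient_id,modality,start_day,end_day,duration_days`;
#' * state table: `patient_id,state,start_day,end_day,censored`.
#'
#' Readers validate structure and report offending rows by number.
#'
#' @param path file path.
#' @param x table to write.
#' @return the table (readers) or `path`, invisibly (writers).
#' @name traj_io
NULL

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort("%s: missing column(s) %s", path, paste(missing, collapse = ", "))
  }
  df
}

#' @rdname traj_io
#' @export
read_session_table <- function(path) {
  validate_sessions(read_csv_checked(path, c("patient_id", "day", "event")))
}

#' @rdname traj_io
#' @export
write_session_table <- function(x, path) {
  utils::write.csv(x[, c("patient_id", "day", "event")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname traj_io
#' @export
read_patient_table <- function(path) {
  df <- read_csv_checked(path, c("patient_id", "entry_day", "censor_day"))
  for (col in c("entry_day", "censor_day")) {
    if (!is.numeric(df[[col]]) || any(is.na(df[[col]]))) {
      abort("%s: column `%s` must be numeric day offsets", path, col)
    }
    df[[col]] <- as.integer(df[[col]])
  }
  df
}

#' @rdname traj_io
#' @export
write_patient_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname traj_io
#' @export
read_state_table <- function(path) {
  df <- read_csv_checked(path, c("patient_id", "state", "start_day",
                                 "end_day", "censored"))
  bad <- which(!df$state %in% STATE_LEVELS)
  if (length(bad) > 0) {
    abort("%s: unknown state(s) %s at row(s) %s", path,
          paste(sQuote(unique(df$state[bad])), collapse = ", "),
          paste(utils::head(bad, 5L), collapse = ", "))
  }
  df$censored <- as.logical(df$censored)
  df
}

#' @rdname traj_io
#' @export
write_state_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname traj_io
#' @export
write_episode_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML with two optional top-level sections, `cohort` and `analysis`,
#' whose keys are the arguments of [cohort_config()] and
#' [analysis_config()].  `cohort.archetype_mix` is a mapping from archetype
#' name to probability.  Unknown keys are rejected.
#'
#' @param path YAML file; `NULL` yields all defaults (the cohort section
#'   then requires `n_patients` at call time).
#' @param overrides named list merged over the file values (CLI flags).
#' @return list with elements `cohort` (arguments for [cohort_config()])
#'   and `analysis` (an [analysis_config()] object).
#' @export
read_config <- function(path = NULL, overrides = list()) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.list(raw)) abort("config file must be a YAML mapping")
  unknown <- setdiff(names(raw), c("cohort", "analysis"))
  if (length(unknown) > 0) {
    abort("unknown config section(s): %s", paste(unknown, collapse = ", "))
  }
  coh <- raw$cohort %||% list()
  ana <- raw$analysis %||% list()
  coh_keys <- setdiff(names(formals(cohort_config)), "archetype_mix")
  ana_keys <- names(formals(analysis_config))
  bad <- setdiff(names(coh), c(coh_keys, "archetype_mix"))
  if (length(bad) > 0) abort("unknown cohort key(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(names(ana), ana_keys)
  if (length(bad) > 0) abort("unknown analysis key(s): %s", paste(bad, collapse = ", "))
  if (!is.null(coh$archetype_mix)) {
    coh$archetype_mix <- unlist(coh$archetype_mix)
  }
  for (nm in names(overrides)) {
    if (nm %in% ana_keys) ana[[nm]] <- overrides[[nm]]
    else coh[[nm]] <- overrides[[nm]]
  }
  list(cohort = coh, analysis = do.call(analysis_config, ana))
}

write_manifest <- function(path, command, config, files, seed = NULL) {
  manifest <- list(
    tool = "pdtraj",
    version = as.character(utils::packageVersion("pdtraj")),
    command = command,
    seed = seed,
    config = config,
    outputs = files,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
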