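# On-disk artifacts: versioned, plain-text CSV schemas.
#
# Every file starts with a schema line `# gripscan <what> v<major>`; readers
# refuse mismatched majors. Time is integer milliseconds; forces are mN
# serialised at 6-decimal precision.

SCHEMA_MAJOR <- 1L

schema_line <- function(what) sprintf("# gripscan %s v%d", what, SCHEMA_MAJOR)

check_schema <- function(path, what) {
  first <- readLines(path, n = 1L)
  pat <- sprintf("^# gripscan %s v(\\d+)", what)
  if (!grepl(pat, first))
    stopf("format error in %s: missing or foreign schema header (field: schema)",
          path)
  ver <- as.integer(sub(pat, "\\1", first))
  if (ver != SCHEMA_MAJOR)
    stopf("format error in %s: schema version %d, reader supports %d (field: schema)",
          path, ver, SCHEMA_MAJOR)
  invisible(ver)
}

require_columns <- function(dt, cols, path) {
  miss <- setdiff(cols, names(dt))
  if (length(miss))
    stopf("format error in %s: missing column(s) %s", path,
          paste(miss, collapse = ", "))
}

write_schema_csv <- function(df, path, what) {
  writeLines(schema_line(what), path)
  data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
}

read_schema_csv <- function(path, what) {
  check_schema(path, what)
  data.table::fread(path, skip = 1L, header = TRUE, data.table = FALSE)
}

#' Write / read a continuous force recording
#'
#' CSV with columns time_ms, force_left_mN, force_right_mN, trigger.
#' Forces are serialised at 6-decimal precision; `read_recording(write_recording(x))`
#' is the identity at that precision.
#'
#' @param rec a `gf_recording`.
#' @param path file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `gf_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "gf_recording"))
  df <- data.frame(time_ms = as.integer(rec$time_ms),
                   force_left_mN = round(rec$force[, 1], 6),
                   force_right_mN = round(rec$force[, 2], 6),
                   trigger = as.integer(rec$trigger))
  write_schema_csv(df, path, "recording")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  df <- read_schema_csv(path, "recording")
  require_columns(df, c("time_ms", "force_left_mN", "force_right_mN",
                        "trigger"), path)
  if (is.unsorted(df$time_ms, strictly = TRUE))
    stopf("format error in %s: time_ms not strictly increasing (field: time_ms)",
          path)
  trig <- df$trigger[df$trigger != 0L]
  if (length(trig) > 1L && any(diff(trig) <= 0L))
    stopf("format error in %s: trigger ids not strictly increasing (field: trigger)",
          path)
  structure(list(sample_rate_hz = 1000L,
                 time_ms = as.integer(df$time_ms),
                 force = cbind(left = df$force_left_mN,
                               right = df$force_right_mN),
                 trigger = as.integer(df$trigger),
                 participant_id = NA_integer_,
                 filtered = FALSE),
            class = "gf_recording")
}

#' Write / read a trial table
#'
#' @param trials TrialTable data.frame.
#' @param path file path.
#' @export
write_trials <- function(trials, path) {
  require_columns(trials, c("trial_id", "side_code", "is_go",
                            "stimulus_class", "response_correct",
                            "onset_sample"), "trial table")
  write_schema_csv(trials, path, "trials")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- read_schema_csv(path, "trials")
  require_columns(df, c("trial_id", "side_code", "is_go", "stimulus_class",
                        "response_correct", "onset_sample"), path)
  if (anyDuplicated(df$trial_id))
    stopf("format error in %s: duplicate trial_id (field: trial_id)", path)
  df
}

#' Write / read an epoch set
#'
#' Long-format CSV (participant, trial, hand, t_ms, force_mN) plus a sidecar
#' mask file `<path>.mask` holding the accept flag, rejection reason and the
#' provenance of the preprocessing chain.
#'
#' @param ep a `gf_epochs`.
#' @param path file path for the long CSV.
#' @export
write_epochs <- function(ep, path) {
  stopifnot(inherits(ep, "gf_epochs"))
  n <- dim(ep$data)[1]
  long <- data.frame(
    participant = ep$participant_id,
    trial = rep(ep$trial_id, each = 2L * EPOCH_LEN),
    hand = rep(rep(c("left", "right"), each = EPOCH_LEN), n),
    t_ms = rep(ep$times, 2L * n),
    force_mN = round(as.vector(aperm(ep$data, c(3, 2, 1))), 6))
  write_schema_csv(long, path, "epochs")
  prov <- ep$provenance
  mask <- data.frame(trial = ep$trial_id,
                     accept = ep$accept,
                     reason = ep$reject_reason)
  writeLines(c(schema_line("epochmask"),
               sprintf("# provenance filtered=%s baseline=%s rejected=%s",
                       prov$filtered,
                       if (is.null(prov$baseline)) "none"
                       else paste(prov$baseline, collapse = ":"),
                       prov$rejected)),
             paste0(path, ".mask"))
  data.table::fwrite(mask, paste0(path, ".mask"), append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  df <- read_schema_csv(path, "epochs")
  require_columns(df, c("participant", "trial", "hand", "t_ms", "force_mN"),
                  path)
  trials <- unique(df$trial)
  n <- length(trials)
  if (nrow(df) != n * 2L * EPOCH_LEN)
    stopf("format error in %s: epoch length != %d samples per trial and hand",
          path, EPOCH_LEN)
  times <- sort(unique(df$t_ms))
  if (length(times) != EPOCH_LEN)
    stopf("format error in %s: epoch length != %d samples", path, EPOCH_LEN)
  # rows were written t fastest, then hand, then trial
  arr <- aperm(array(df$force_mN, dim = c(EPOCH_LEN, 2L, n)), c(3, 2, 1))
  dimnames(arr) <- list(NULL, c("left", "right"), NULL)

  mpath <- paste0(path, ".mask")
  check_schema(mpath, "epochmask")
  provline <- readLines(mpath, n = 2L)[2]
  kv <- strsplit(sub("^# provenance ", "", provline), " ")[[1]]
  kv <- strsplit(kv, "=")
  prov <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  baseline <- if (identical(prov$baseline, "none")) NULL
              else as.numeric(strsplit(prov$baseline, ":")[[1]])
  mask <- data.table::fread(mpath, skip = 2L, header = TRUE,
                            data.table = FALSE)
  require_columns(mask, c("trial", "accept", "reason"), mpath)
  structure(list(participant_id = df$participant[1],
                 trial_id = trials,
                 times = times,
                 data = arr,
                 accept = as.logical(mask$accept),
                 reject_reason = as.character(mask$reason),
                 provenance = list(filtered = identical(prov$filtered, "TRUE"),
                                   baseline = baseline,
                                   rejected = identical(prov$rejected, "TRUE"))),
            class = "gf_epochs")
}

#' Write a ground-truth table
#' @param truth GroundTruth data.frame from `simulate_experiment`.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  write_schema_csv(truth[, c("participant", "hand", "intercept_mN",
                             "side_slope_mN")], path, "truth")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Configuration
# ---------------------------------------------------------------------------

config_defaults <- function(kind = "stars") {
  list(experiment = kind,
       n_participants = NULL,  # per-kind default from experiment_spec()
       seed = 1L,
       spec = list(),     # overrides for experiment_spec()
       effect = list(),   # overrides for effect_params()
       noise = list(),    # overrides for noise_params()
       analysis = list(n_perm = 200L, alpha = 0.05, close_alpha = 0.1,
                       tfce_e = 0.5, tfce_h = 2))
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    if (!key %in% names(defaults))
      stopf("config validation error: unknown key '%s%s'", path, key)
    if (is.list(defaults[[key]]) && key %in% c("analysis")) {
      unknown <- setdiff(names(user[[key]]), names(defaults[[key]]))
      if (length(unknown))
        stopf("config validation error: unknown key '%s%s.%s'", path, key,
              unknown[1])
      defaults[[key]][names(user[[key]])] <- user[[key]]
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Read and validate a pipeline configuration
#'
#' YAML document with top-level keys `experiment`, `n_participants`, `seed`,
#' `spec`, `effect`, `noise`, `analysis`. Missing keys take documented
#' defaults; unknown keys are rejected; out-of-range values (e.g. a holding
#' force outside the 1500-3000 mN calibration band) raise validation
#' errors. An empty file yields all defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param quiet suppress the resolved-config log line.
#' @return list with validated `spec` (`gf_spec`), `effect` (`gf_effect`),
#'   `noise` (`gf_noise`), `analysis` settings and `seed`.
#' @export
read_config <- function(path = NULL, quiet = FALSE) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  kind <- user$experiment %||% "stars"
  cfg <- merge_config(config_defaults(kind), user)
  spec <- do.call(experiment_spec,
                  c(list(experiment_kind = cfg$experiment,
                         n_participants = cfg$n_participants), cfg$spec))
  effect <- do.call(effect_params,
                    c(list(experiment_kind = cfg$experiment), cfg$effect))
  noise <- tryCatch(
    do.call(noise_params,
            c(list(experiment_kind = cfg$experiment), cfg$noise)),
    error = function(e) stopf("config validation error: %s",
                              conditionMessage(e)))
  out <- list(spec = spec, effect = effect, noise = noise,
              analysis = cfg$analysis, seed = as.integer(cfg$seed))
  if (!quiet)
    message(sprintf(
      "config resolved: %s, %d participants, %d trials, seed %d, n_perm %d",
      spec$experiment_kind, spec$n_participants, spec$n_trials, out$seed,
      out$analysis$n_perm))
  out
}
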