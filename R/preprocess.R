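# Preprocessing: zero-phase low-pass filtering of the continuous recording,
# epoch extraction, baseline correction, threshold-based artifact rejection,
# critical-trial selection and condition averaging.
#
# Stage order is audited through provenance fields: filter -> epoch ->
# baseline -> reject -> average. Running a stage out of order raises a
# provenance error (the checks can be relaxed for unit-scale inputs).

#' Zero-phase low-pass Butterworth filter
#'
#' Fourth-order low-pass Butterworth applied forward and backward (zero
#' phase, squared magnitude response). Edges are stabilised by
#' odd-reflection padding long enough for the filter transient to decay
#' below numerical noise, so a constant trace stays constant (DC gain 1).
#'
#' @param x numeric force trace (mN) or a `gf_recording` (both channels are
#'   filtered and the recording is marked as filtered).
#' @param sample_rate sampling rate in Hz.
#' @param cutoff low-pass cutoff in Hz.
#' @param order filter order for each pass.
#' @return object of the same type as `x`.
#' @export
lowpass_filter <- function(x, sample_rate = 1000, cutoff = 15, order = 4) {
  UseMethod("lowpass_filter")
}

#' @export
lowpass_filter.default <- function(x, sample_rate = 1000, cutoff = 15,
                                   order = 4) {
  if (!all(is.finite(x))) stopf("filter input contains non-finite values")
  if (length(x) <= 3 * order)
    stopf("length error: trace of length %d too short for order-%d filter",
          length(x), order)
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  # pad until the slowest pole has decayed below ~1e-13
  pmax_ <- max(Mod(polyroot(rev(bf$a))))
  pad <- if (pmax_ >= 1 || pmax_ <= 0) length(x) - 1L
         else as.integer(ceiling(-30 / log(pmax_)))
  filtfilt_pad_cpp(bf$b, bf$a, as.numeric(x), pad)
}

#' @export
lowpass_filter.gf_recording <- function(x, sample_rate = NULL, cutoff = 15,
                                        order = 4) {
  sr <- sample_rate %||% x$sample_rate_hz
  x$force[, 1] <- lowpass_filter(x$force[, 1], sr, cutoff, order)
  x$force[, 2] <- lowpass_filter(x$force[, 2], sr, cutoff, order)
  x$filtered <- TRUE
  x
}

#' Extract fixed epochs around stimulus onsets
#'
#' Cuts a window (default -200 to +1000 ms, half-open) around every trigger
#' of the recording, for both hands. The stimulus onset sits at sample
#' index 201 (time 0 ms).
#'
#' @param recording a `gf_recording` (normally filtered first).
#' @param trials TrialTable with `onset_sample` filled.
#' @param window c(start, end) in ms relative to onset, end exclusive.
#' @param require_filtered enforce that the recording was low-pass filtered.
#' @return a `gf_epochs`: trials x hands x samples array plus accept mask.
#' @export
extract_epochs <- function(recording, trials, window = c(-200, 1000),
                           require_filtered = TRUE) {
  stopifnot(inherits(recording, "gf_recording"))
  if (require_filtered && !isTRUE(recording$filtered))
    stopf("provenance error: filter the recording before epoching")
  times <- seq.int(window[1], window[2] - 1L)
  len <- length(times)
  onsets <- trials$onset_sample
  N <- length(recording$time_ms)
  bad <- which(onsets + window[1] < 1L | onsets + window[2] - 1L > N)
  if (length(bad))
    stopf("epoch-bounds error: trial(s) %s too close to recording edge",
          paste(trials$trial_id[bad], collapse = ", "))
  n <- length(onsets)
  idx <- rep(onsets, each = len) + rep(times, n)
  arr <- array(NA_real_, dim = c(n, 2L, len),
               dimnames = list(NULL, c("left", "right"), NULL))
  arr[, 1L, ] <- matrix(recording$force[idx, 1], n, len, byrow = TRUE)
  arr[, 2L, ] <- matrix(recording$force[idx, 2], n, len, byrow = TRUE)
  structure(list(participant_id = trials$participant_id[1] %||%
                   recording$participant_id,
                 trial_id = trials$trial_id,
                 times = times,
                 data = arr,
                 accept = rep(TRUE, n),
                 reject_reason = rep(NA_character_, n),
                 provenance = list(filtered = isTRUE(recording$filtered),
                                   baseline = NULL,
                                   rejected = FALSE)),
            class = "gf_epochs")
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and hand, the mean force over a short pre-onset
#' interval (default the 20 ms before onset, half-open), so every epoch
#' crosses zero at stimulus onset and negative values mean "less force than
#' at onset", not absence of force. Applying the correction twice equals
#' applying it once.
#'
#' @param ep a `gf_epochs`.
#' @param baseline c(start, end) ms, end exclusive; must lie in the epoch.
#' @return the corrected `gf_epochs`.
#' @export
baseline_correct <- function(ep, baseline = c(-20, 0)) {
  stopifnot(inherits(ep, "gf_epochs"))
  sel <- ep$times >= baseline[1] & ep$times < baseline[2]
  if (!any(sel)) stopf("baseline window outside epoch")
  means <- apply(ep$data[, , sel, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - as.vector(means)  # recycles over the time dimension
  ep$provenance$baseline <- baseline
  ep
}

#' Reject epochs with force beyond a fixed threshold
#'
#' A trial is rejected iff any sample of either hand exceeds `threshold` in
#' absolute value (strictly). Applied to baseline-corrected forces.
#'
#' @param ep a baseline-corrected `gf_epochs`.
#' @param threshold rejection threshold in mN.
#' @return the `gf_epochs` with its accept mask and reasons updated.
#' @export
reject_artifacts <- function(ep, threshold = 500) {
  stopifnot(inherits(ep, "gf_epochs"))
  if (is.null(ep$provenance$baseline))
    stopf("provenance error: baseline-correct epochs before artifact rejection")
  peak <- apply(abs(ep$data), 1, max)
  bad <- peak > threshold
  ep$accept <- ep$accept & !bad
  ep$reject_reason[bad] <- "threshold"
  ep$provenance$rejected <- TRUE
  ep$provenance$threshold <- threshold
  ep
}

#' Select correct no-go critical trials
#'
#' Keeps only the trials entering the analysis: correct responses, no-go,
#' of the experiment's critical stimulus class (stars, arrows or real
#' words; symbol arrays are excluded), with a defined side code.
#'
#' @param trials TrialTable.
#' @return the filtered TrialTable.
#' @export
select_critical_trials <- function(trials) {
  keep <- !trials$is_go & trials$response_correct &
    trials$stimulus_class %in% c("star", "arrow", "word") &
    !is.na(trials$side_code)
  trials[keep, , drop = FALSE]
}

#' Per-participant rejection report
#'
#' Summarises, per participant, how many critical trials were lost to the
#' force threshold and whether the participant crosses the exclusion
#' criterion (more than 20% of critical trials rejected). The trial-level
#' table additionally labels go trials and error trials, which never enter
#' the analysis.
#'
#' @param ep a `gf_epochs` after `reject_artifacts`.
#' @param trials the matching TrialTable.
#' @param max_prop participant exclusion threshold on the rejected
#'   proportion.
#' @return list with `participants` and `trials` data.frames.
#' @export
rejection_report <- function(ep, trials, max_prop = 0.20) {
  stopifnot(inherits(ep, "gf_epochs"))
  if (!isTRUE(ep$provenance$rejected))
    stopf("provenance error: run reject_artifacts before the report")
  crit <- select_critical_trials(trials)
  is_crit <- trials$trial_id %in% crit$trial_id
  reason <- ifelse(trials$is_go, "go_trial",
                   ifelse(!trials$response_correct, "error_response",
                          ifelse(!ep$accept, "threshold", NA_character_)))
  n_crit <- sum(is_crit)
  n_rej <- sum(is_crit & !ep$accept)
  prop <- if (n_crit > 0) n_rej / n_crit else NA_real_
  list(participants = data.frame(
         participant = ep$participant_id,
         n_critical = n_crit,
         n_rejected = n_rej,
         proportion_rejected = prop,
         excluded = !is.na(prop) && prop > max_prop),
       trials = data.frame(participant = ep$participant_id,
                           trial_id = trials$trial_id,
                           reason = reason))
}

#' Aggregate epochs into condition averages
#'
#' Averages accepted critical epochs by hand and side within each
#' participant, yielding the participant x hand x side x time array that
#' feeds the permutation scan. Cells without any contributing trial are
#' flagged missing (NA) with a warning.
#'
#' @param epochs a `gf_epochs` or a list of them (one per participant).
#' @param trials the matching TrialTable or list of TrialTables.
#' @return a `gf_cond_avg` with `data` (n x 2 x 3 x T), `n_trials`
#'   (n x 2 x 3), `participants`, `times`.
#' @export
condition_averages <- function(epochs, trials) {
  if (inherits(epochs, "gf_epochs")) {
    epochs <- list(epochs)
    trials <- list(trials)
  }
  n <- length(epochs)
  T_ <- length(epochs[[1]]$times)
  sides <- c(-1L, 0L, 1L)
  arr <- array(NA_real_, dim = c(n, 2L, 3L, T_),
               dimnames = list(NULL, c("left", "right"), c("-1", "0", "1"),
                               NULL))
  ntr <- array(0L, dim = c(n, 2L, 3L))
  ids <- integer(n)
  missing_cells <- character(0)
  for (i in seq_len(n)) {
    ep <- epochs[[i]]
    tr <- trials[[i]]
    if (!isTRUE(ep$provenance$rejected))
      stopf("provenance error: reject_artifacts must precede averaging")
    ids[i] <- ep$participant_id
    crit <- select_critical_trials(tr)
    use <- ep$trial_id %in% crit$trial_id & ep$accept
    side_of <- tr$side_code[match(ep$trial_id, tr$trial_id)]
    for (s in 1:3) {
      pick <- use & !is.na(side_of) & side_of == sides[s]
      ntr[i, , s] <- sum(pick)
      if (any(pick)) {
        sub <- ep$data[pick, , , drop = FALSE]
        arr[i, 1L, s, ] <- colMeans(matrix(sub[, 1L, ], nrow = sum(pick)))
        arr[i, 2L, s, ] <- colMeans(matrix(sub[, 2L, ], nrow = sum(pick)))
      } else {
        missing_cells <- c(missing_cells,
                           sprintf("participant %d side %d", ids[i], sides[s]))
      }
    }
  }
  if (length(missing_cells))
    warning("missing cells (no accepted trials): ",
            paste(missing_cells, collapse = "; "), call. = FALSE)
  structure(list(data = arr, n_trials = ntr, participants = ids,
                 times = epochs[[1]]$times,
                 experiment_kind = trials[[1]]$experiment_kind[1]),
            class = "gf_cond_avg")
}
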