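# Synthetic bimanual grip-force experiments with known ground truth.
#
# The generator emulates the structure of event-related grip-force data in a
# go/no-go attention paradigm: a 1.5-3 N holding force, a multiphasic evoked
# response time-locked to stimulus onset, a lateralised hand-by-side effect
# whose latency and sign depend on the stimulus kind, positive inter-hand
# force coupling, slow drift, rare large movement artifacts, and go-trial
# force divergence. One sample is one millisecond (1000 Hz).

EPOCH_START <- -200L  # ms relative to stimulus onset
EPOCH_END <- 1000L    # exclusive
EPOCH_LEN <- 1200L

#' Visual angle subtended by a stimulus
#'
#' Small-angle approximation in degrees, `57.3 * w / d`.
#'
#' @param width_cm stimulus width in cm (>= 0).
#' @param distance_cm viewing distance in cm (> 0).
#' @return visual angle in degrees.
#' @examples
#' visual_angle(4, 60)    # lateralised star, ~3.82 deg
#' visual_angle(19.5, 60) # eccentricity of lateral positions, ~18.62 deg
#' @export
visual_angle <- function(width_cm, distance_cm) {
  if (!is.numeric(width_cm) || !is.numeric(distance_cm))
    stopf("invalid geometry: width_cm and distance_cm must be numeric")
  if (any(!is.finite(distance_cm)) || any(distance_cm <= 0))
    stopf("invalid geometry: distance_cm must be positive")
  if (any(!is.finite(width_cm)) || any(width_cm < 0))
    stopf("invalid geometry: width_cm must be non-negative")
  57.3 * width_cm / distance_cm
}

#' Experiment specification
#'
#' Describes one experiment of the paradigm. `stars` presents lateralised
#' stimuli (exogenous attention), `arrows` central direction cues and
#' `words` central spatial words (endogenous attention). Defaults follow the
#' paradigm: 360 trials with 25% go for stars/arrows; 450 trials for words
#' with 20% go words, 20% go symbol arrays, 40% critical no-go words and 20%
#' no-go symbol arrays.
#'
#' @param experiment_kind one of "stars", "arrows", "words".
#' @param n_participants number of participants.
#' @param n_trials trials per participant.
#' @param go_fraction total fraction of go (response) trials.
#' @param stimulus_width_cm,viewing_distance_cm stimulus geometry (cm).
#' @param iti_ms inter-trial interval after epoch end (ms, >= 0).
#' @param stimulus_duration_ms maximal stimulus presentation (ms).
#' @param condition_labels labels mapped onto side codes -1, 0, +1.
#' @return an object of class `gf_spec`.
#' @export
experiment_spec <- function(experiment_kind = c("stars", "arrows", "words"),
                            n_participants = NULL,
                            n_trials = NULL,
                            go_fraction = NULL,
                            stimulus_width_cm = NULL,
                            viewing_distance_cm = 60,
                            iti_ms = 1000L,
                            stimulus_duration_ms = 2000L,
                            condition_labels = NULL) {
  kind <- match.arg(experiment_kind)
  # study samples: 41 for stars/arrows, 27 native speakers for words
  n_participants <- n_participants %||% switch(kind, stars = 41L,
                                               arrows = 41L, words = 27L)
  n_trials <- n_trials %||% switch(kind, stars = 360L, arrows = 360L,
                                   words = 450L)
  go_fraction <- go_fraction %||% switch(kind, stars = 0.25, arrows = 0.25,
                                         words = 0.40)
  stimulus_width_cm <- stimulus_width_cm %||%
    switch(kind, stars = 4, arrows = 2, words = 2.5)
  condition_labels <- condition_labels %||%
    switch(kind,
           stars = c("left", "center", "right"),
           arrows = c("left", "both", "right"),
           words = c("left", "center", "right"))
  if (n_trials <= 0) stopf("n_trials must be positive")
  if (go_fraction <= 0 || go_fraction >= 1)
    stopf("go_fraction must be in (0, 1)")
  if (iti_ms < 0) stopf("design error: iti_ms must be >= 0 (epochs overlap)")
  if (length(condition_labels) != 3L)
    stopf("condition_labels must have length 3 (side codes -1, 0, +1)")
  structure(list(experiment_kind = kind,
                 n_participants = as.integer(n_participants),
                 n_trials = as.integer(n_trials),
                 go_fraction = go_fraction,
                 stimulus_width_cm = stimulus_width_cm,
                 viewing_distance_cm = viewing_distance_cm,
                 iti_ms = as.integer(iti_ms),
                 stimulus_duration_ms = as.integer(stimulus_duration_ms),
                 condition_labels = condition_labels),
            class = "gf_spec")
}

#' Lateralised effect parameters
#'
#' The hand-by-side effect injected by the generator: from `effect_onset_ms`
#' for `effect_duration_ms`, force in each hand changes by
#' `effect_amplitude_mN * side_code * hand_sign`, where `hand_sign` is +1
#' for the right hand and -1 for the left hand under the
#' `ipsilateral_positive` convention (stars, arrows) and reversed under
#' `contralateral_positive` (words). The time course is a rectangular pulse
#' convolved with a 20 ms Gaussian. Per-participant, per-hand slopes are
#' drawn with sd `participant_slope_sd_mN` around the population value.
#'
#' @param experiment_kind used to pick defaults; see `experiment_spec`.
#' @param effect_onset_ms,effect_duration_ms effect window (ms).
#' @param effect_amplitude_mN population amplitude per side-code unit (mN).
#' @param effect_sign_convention "ipsilateral_positive" or
#'   "contralateral_positive".
#' @param participant_slope_sd_mN between-participant slope sd (mN).
#' @return an object of class `gf_effect`.
#' @export
effect_params <- function(experiment_kind = c("stars", "arrows", "words"),
                          effect_onset_ms = NULL,
                          effect_duration_ms = NULL,
                          effect_amplitude_mN = NULL,
                          effect_sign_convention = NULL,
                          participant_slope_sd_mN = 3) {
  kind <- match.arg(experiment_kind)
  effect_onset_ms <- effect_onset_ms %||%
    switch(kind, stars = 60, arrows = 100, words = 250)
  effect_duration_ms <- effect_duration_ms %||%
    switch(kind, stars = 400, arrows = 50, words = 50)
  effect_amplitude_mN <- effect_amplitude_mN %||%
    switch(kind, stars = 10, arrows = 6, words = 6)
  effect_sign_convention <- effect_sign_convention %||%
    switch(kind, stars = "ipsilateral_positive",
           arrows = "ipsilateral_positive",
           words = "contralateral_positive")
  effect_sign_convention <- match.arg(effect_sign_convention,
                                      c("ipsilateral_positive",
                                        "contralateral_positive"))
  if (effect_onset_ms < 0) stopf("effect_onset_ms must be >= 0")
  if (!is.finite(effect_amplitude_mN)) stopf("effect amplitude must be finite")
  structure(list(experiment_kind = kind,
                 effect_onset_ms = effect_onset_ms,
                 effect_duration_ms = effect_duration_ms,
                 effect_amplitude_mN = effect_amplitude_mN,
                 effect_sign_convention = effect_sign_convention,
                 participant_slope_sd_mN = participant_slope_sd_mN),
            class = "gf_effect")
}

#' Noise and nuisance-signal parameters
#'
#' Holding force must lie in the 1500-3000 mN calibration band. Evoked peaks
#' are Gaussian bumps (latency, width sd, amplitude in mN) mimicking the
#' multiphasic response: stars peak near 130/330/600 ms with the 330 ms bump
#' tallest; arrows near 130/300/650 ms with the 130 ms bump tallest; words
#' near 130/250/350/850 ms. Drift is a per-hand random walk updated every
#' 10 ms (sd `drift_sd_mN` per square-root second); white noise is coupled
#' across hands with correlation `interhand_coupling`. Artifacts are 100 ms
#' half-sine excursions of `artifact_amplitude_mN` (> 500) occurring with
#' probability `artifact_rate` per trial. Go trials ramp to `go_plateau_mN`
#' diverging from no-go trials at `go_divergence_onset_ms`.
#'
#' @param experiment_kind used to pick defaults.
#' @param hold_force_mN baseline holding force (mN, in [1500, 3000]).
#' @param evoked_peaks list of c(latency_ms, width_ms, amplitude_mN).
#' @param interhand_coupling correlation of white noise across hands, [0,1].
#' @param drift_sd_mN random-walk dispersion (mN per sqrt second).
#' @param white_sd_mN white noise sd per sample (mN).
#' @param artifact_rate per-trial artifact probability.
#' @param artifact_amplitude_mN artifact excursion (mN, > 500).
#' @param participant_intercept_sd_mN sd of holding-force offsets (mN).
#' @param go_divergence_onset_ms,go_plateau_mN go-trial ramp parameters.
#' @return an object of class `gf_noise`.
#' @export
noise_params <- function(experiment_kind = c("stars", "arrows", "words"),
                         hold_force_mN = 2250,
                         evoked_peaks = NULL,
                         interhand_coupling = 0.3,
                         drift_sd_mN = 15,
                         white_sd_mN = 15,
                         artifact_rate = 0.02,
                         artifact_amplitude_mN = 800,
                         participant_intercept_sd_mN = 150,
                         go_divergence_onset_ms = 250,
                         go_plateau_mN = NULL) {
  kind <- match.arg(experiment_kind)
  evoked_peaks <- evoked_peaks %||% switch(kind,
    stars = list(c(130, 30, 20), c(330, 50, 30), c(600, 60, 15)),
    arrows = list(c(130, 30, 30), c(300, 50, 20), c(650, 60, 10)),
    words = list(c(130, 30, 25), c(250, 25, 8), c(350, 50, 25),
                 c(850, 60, 5)))
  go_plateau_mN <- go_plateau_mN %||%
    switch(kind, stars = 50, arrows = 55, words = 40)
  if (hold_force_mN < 1500 || hold_force_mN > 3000)
    stopf("hold_force_mN must lie in the calibration range [1500, 3000]")
  if (interhand_coupling < 0 || interhand_coupling > 1)
    stopf("interhand_coupling must lie in [0, 1]")
  if (artifact_amplitude_mN <= 500)
    stopf("artifact_amplitude_mN must exceed the 500 mN rejection threshold")
  structure(list(experiment_kind = kind,
                 hold_force_mN = hold_force_mN,
                 evoked_peaks = evoked_peaks,
                 interhand_coupling = interhand_coupling,
                 drift_sd_mN = drift_sd_mN,
                 white_sd_mN = white_sd_mN,
                 artifact_rate = artifact_rate,
                 artifact_amplitude_mN = artifact_amplitude_mN,
                 participant_intercept_sd_mN = participant_intercept_sd_mN,
                 go_divergence_onset_ms = go_divergence_onset_ms,
                 go_plateau_mN = go_plateau_mN),
            class = "gf_noise")
}

# Balanced assignment of `n` trials to the three side codes (within one
# stimulus class): each side gets floor(n/3); the remainder is assigned at
# random without replacement.
balanced_sides <- function(n) {
  base <- rep(c(-1L, 0L, 1L), n %/% 3L)
  extra <- n %% 3L
  if (extra > 0L) base <- c(base, sample(c(-1L, 0L, 1L), extra))
  base
}

#' Generate a pseudorandomised trial design
#'
#' Builds the per-trial metadata table for one participant run: side codes
#' balanced to within one trial per level inside each stimulus class, go
#' fraction matching the spec to within one trial, order pseudorandomised by
#' `seed`. For word experiments the table also contains go/no-go symbol
#' arrays (side code `NA`). Response correctness is drawn with the stated
#' accuracy (errors are rare, as in the paradigm).
#'
#' @param spec a `gf_spec`.
#' @param seed integer seed; the design is deterministic given (spec, seed).
#' @param accuracy probability of a correct response per trial.
#' @return a data.frame (TrialTable) with columns trial_id, experiment_kind,
#'   side_code, is_go, stimulus_class, response_correct, onset_sample.
#' @export
make_trial_design <- function(spec, seed, accuracy = 0.995) {
  stopifnot(inherits(spec, "gf_spec"))
  n <- spec$n_trials
  kind <- spec$experiment_kind
  with_rng(seed, {
    if (kind == "words") {
      n_go_word <- round(n * 0.20)
      n_go_sym <- round(n * 0.20)
      n_nogo_sym <- round(n * 0.20)
      n_nogo_word <- n - n_go_word - n_go_sym - n_nogo_sym
      cls <- c(rep("word", n_go_word), rep("symbol_array", n_go_sym),
               rep("word", n_nogo_word), rep("symbol_array", n_nogo_sym))
      go <- c(rep(TRUE, n_go_word + n_go_sym),
              rep(FALSE, n_nogo_word + n_nogo_sym))
      side <- rep(NA_integer_, n)
      side[cls == "word"] <- balanced_sides(n_go_word + n_nogo_word)
    } else {
      n_go <- round(n * spec$go_fraction)
      cls <- rep(switch(kind, stars = "star", arrows = "arrow"), n)
      go <- c(rep(TRUE, n_go), rep(FALSE, n - n_go))
      side <- balanced_sides(n)
    }
    ord <- sample.int(n)
    data.frame(trial_id = seq_len(n),
               experiment_kind = kind,
               side_code = side[ord],
               is_go = go[ord],
               stimulus_class = cls[ord],
               response_correct = stats::runif(n) < accuracy,
               onset_sample = NA_integer_,
               stringsAsFactors = FALSE)
  })
}

# Deterministic per-trial signal components on the epoch grid (-200..999 ms).
epoch_times <- function() seq.int(EPOCH_START, EPOCH_END - 1L)

evoked_template <- function(noise) {
  t <- epoch_times()
  out <- numeric(EPOCH_LEN)
  for (pk in noise$evoked_peaks)
    out <- out + pk[3] * exp(-0.5 * ((t - pk[1]) / pk[2])^2)
  out
}

# Rectangular side-effect pulse convolved with a 20 ms Gaussian; unit height.
effect_pulse <- function(effect) {
  t <- epoch_times()
  on <- effect$effect_onset_ms
  off <- on + effect$effect_duration_ms
  rect <- as.numeric(t >= on & t < off)
  if (all(rect == 0)) return(rect)
  kt <- seq(-60, 60)
  kern <- exp(-0.5 * (kt / 20)^2)
  kern <- kern / sum(kern)
  out <- stats::convolve(rect, rev(kern), type = "open")
  out[61:(60 + EPOCH_LEN)]
}

go_ramp <- function(noise) {
  t <- epoch_times()
  # smooth ramp: forces diverge at go_divergence_onset_ms, plateau ~500 ms on
  noise$go_plateau_mN *
    stats::plogis((t - (noise$go_divergence_onset_ms + 200)) / 80)
}

hand_sign <- function(hand, convention) {
  s <- ifelse(hand == "right", 1, -1)
  if (convention == "contralateral_positive") s <- -s
  s
}

artifact_shape <- function(amplitude, start, sign) {
  # one-sided half-sine excursion of 100 ms
  out <- numeric(EPOCH_LEN)
  idx <- start:min(start + 99L, EPOCH_LEN)
  out[idx] <- sign * amplitude * sin(pi * seq_along(idx) / 100)
  out
}

#' Simulate a single epoch-length force trace
#'
#' Composes the generative model for one trial and one hand on the epoch
#' grid (-200 to +999 ms relative to onset): holding force + evoked bumps +
#' side effect + coupled white noise + drift (+ go ramp, + rare artifact).
#' Both hands' noise streams are drawn from `seed`, so calling with the same
#' seed and the other hand gives the coupled counterpart.
#'
#' @param effect a `gf_effect`.
#' @param noise a `gf_noise`.
#' @param trial one row of a TrialTable (data.frame).
#' @param hand "left" or "right".
#' @param seed integer seed for the trial's random components.
#' @return numeric vector of 1200 force samples (mN).
#' @export
simulate_trial <- function(effect, noise, trial, hand = c("left", "right"),
                           seed = 1L) {
  hand <- match.arg(hand)
  stopifnot(inherits(effect, "gf_effect"), inherits(noise, "gf_noise"))
  side <- trial$side_code
  if (is.na(side)) side <- 0L
  det <- noise$hold_force_mN + evoked_template(noise) +
    effect$effect_amplitude_mN * side *
      hand_sign(hand, effect$effect_sign_convention) * effect_pulse(effect)
  if (isTRUE(trial$is_go)) det <- det + go_ramp(noise)
  nz <- sim_noise_cpp(EPOCH_LEN, noise$white_sd_mN, noise$interhand_coupling,
                      noise$drift_sd_mN / sqrt(100), 10L, as.numeric(seed))
  trace <- det + nz[, if (hand == "left") 1L else 2L]
  with_rng(derive_seed(seed, "artifact"), {
    if (stats::runif(1) < noise$artifact_rate) {
      start <- sample.int(EPOCH_LEN - 100L, 1L)
      trace <- trace + artifact_shape(noise$artifact_amplitude_mN, start,
                                      sample(c(-1, 1), 1L))
    }
  })
  trace
}

# Shared per-participant building blocks: trial design, onset grid, and the
# deterministic epoch additions (evoked response, side effect, go ramp,
# artifacts) per hand. truth: list(intercept = c(left, right),
# slope = c(left, right)).
build_participant <- function(spec, effect, noise, truth, seed) {
  trials <- make_trial_design(spec, derive_seed(seed, "design"))
  n <- spec$n_trials
  spacing <- EPOCH_LEN + spec$iti_ms
  onsets <- 500L + (seq_len(n) - 1L) * spacing  # sample index, 1-based
  trials$onset_sample <- onsets
  N <- onsets[n] + EPOCH_END + spec$iti_ms

  evoked <- evoked_template(noise)
  pulse <- effect_pulse(effect)
  ramp <- go_ramp(noise)
  side <- ifelse(is.na(trials$side_code), 0L, trials$side_code)

  art <- with_rng(derive_seed(seed, "artifact"), {
    hit <- stats::runif(n) < noise$artifact_rate
    list(hit = hit,
         start = sample.int(EPOCH_LEN - 100L, n, replace = TRUE),
         sign = sample(c(-1, 1), n, replace = TRUE),
         hand = sample(1:2, n, replace = TRUE))
  })

  base <- rep(evoked, n) + as.vector(ramp %o% as.numeric(trials$is_go))
  adds <- list()
  for (h in 1:2) {
    add <- base + as.vector(pulse %o% (truth$slope[h] * side))
    for (k in which(art$hit & art$hand == h)) {
      off <- (k - 1L) * EPOCH_LEN
      add[off + seq_len(EPOCH_LEN)] <- add[off + seq_len(EPOCH_LEN)] +
        artifact_shape(noise$artifact_amplitude_mN, art$start[k], art$sign[k])
    }
    adds[[h]] <- add
  }
  list(trials = trials, onsets = onsets, N = N, adds = adds,
       idx = rep(onsets, each = EPOCH_LEN) +
         rep(EPOCH_START:(EPOCH_END - 1L), n))
}

# Simulate one participant's continuous recording plus trial log.
simulate_participant <- function(spec, effect, noise, truth, seed,
                                 participant_id = 1L) {
  bp <- build_participant(spec, effect, noise, truth, seed)
  nz <- sim_noise_cpp(bp$N, noise$white_sd_mN, noise$interhand_coupling,
                      noise$drift_sd_mN / sqrt(100), 10L,
                      as.numeric(derive_seed(seed, "noise")))
  force <- nz
  force[, 1] <- force[, 1] + truth$intercept[1]
  force[, 2] <- force[, 2] + truth$intercept[2]
  force[bp$idx, 1] <- force[bp$idx, 1] + bp$adds[[1]]
  force[bp$idx, 2] <- force[bp$idx, 2] + bp$adds[[2]]
  colnames(force) <- c("left", "right")
  trigger <- integer(bp$N)
  trigger[bp$onsets] <- bp$trials$trial_id
  rec <- structure(list(sample_rate_hz = 1000L,
                        time_ms = seq_len(bp$N) - 1L,
                        force = force,
                        trigger = trigger,
                        participant_id = participant_id,
                        filtered = FALSE),
                   class = "gf_recording")
  trials <- bp$trials
  trials$participant_id <- participant_id
  list(recording = rec, trials = trials)
}

#' Simulate a full experiment
#'
#' Draws per-participant ground truth (holding-force intercepts and side
#' slopes per hand), then assembles one continuous two-channel recording per
#' participant with a trigger marking each stimulus onset. Fully
#' reproducible from `seed`.
#'
#' @param spec a `gf_spec`.
#' @param effect a `gf_effect`.
#' @param noise a `gf_noise`.
#' @param seed master integer seed.
#' @return list with elements `recordings` (list of `gf_recording`),
#'   `trials` (list of TrialTable data.frames), `truth` (GroundTruth
#'   data.frame: participant, hand, intercept_mN, side_slope_mN), and the
#'   inputs.
#' @export
simulate_experiment <- function(spec, effect, noise, seed) {
  stopifnot(inherits(spec, "gf_spec"))
  truth <- draw_ground_truth(spec, effect, noise, seed)
  recs <- vector("list", spec$n_participants)
  logs <- vector("list", spec$n_participants)
  for (i in seq_len(spec$n_participants)) {
    tr <- participant_truth(truth, i)
    sim <- simulate_participant(spec, effect, noise, tr,
                                derive_seed(seed, "participant", i), i)
    recs[[i]] <- sim$recording
    logs[[i]] <- sim$trials
  }
  list(recordings = recs, trials = logs, truth = truth,
       spec = spec, effect = effect, noise = noise)
}

# GroundTruth draws: one row per participant x hand.
draw_ground_truth <- function(spec, effect, noise, seed) {
  n <- spec$n_participants
  with_rng(derive_seed(seed, "truth"), {
    icpt <- noise$hold_force_mN +
      noise$participant_intercept_sd_mN * stats::rnorm(2L * n)
    icpt <- pmin(pmax(icpt, 1500), 3000)
    hs <- hand_sign(rep(c("left", "right"), n),
                    effect$effect_sign_convention)
    slope <- hs * effect$effect_amplitude_mN +
      effect$participant_slope_sd_mN * stats::rnorm(2L * n)
    if (effect$effect_amplitude_mN == 0 &&
        effect$participant_slope_sd_mN == 0) slope <- rep(0, 2L * n)
    structure(data.frame(participant = rep(seq_len(n), each = 2L),
                         hand = rep(c("left", "right"), n),
                         intercept_mN = icpt,
                         side_slope_mN = slope,
                         stringsAsFactors = FALSE),
              effect_window = c(effect$effect_onset_ms,
                                effect$effect_onset_ms +
                                  effect$effect_duration_ms),
              effect_amplitude_mN = effect$effect_amplitude_mN)
  })
}

participant_truth <- function(truth, i) {
  rows <- truth[truth$participant == i, ]
  list(intercept = stats::setNames(rows$intercept_mN, rows$hand),
       slope = stats::setNames(rows$side_slope_mN, rows$hand))
}
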