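# Shared fixtures and independent oracles, built in code.

# Wrap a participant x hand x side x time array as condition averages.
make_cond <- function(arr, times = seq_len(dim(arr)[4]) - 1L,
                      kind = "stars") {
  structure(list(data = arr,
                 n_trials = array(1L, dim(arr)[1:3]),
                 participants = seq_len(dim(arr)[1]),
                 times = as.integer(times),
                 experiment_kind = kind),
            class = "gf_cond_avg")
}

# Smooth null condition averages (exchangeable cells within participant).
null_cond <- function(n, T_, seed, sd = 5) {
  set.seed(seed)
  arr <- array(0, c(n, 2, 3, T_))
  for (i in seq_len(n)) for (j in 1:2) for (k in 1:3)
    arr[i, j, k, ] <- lowpass_filter(rnorm(T_, sd = sd), 1000, 15, 4)
  make_cond(arr)
}

# Brute-force TFCE oracle: per point, loop thresholds and expand the
# suprathreshold run containing it (same grid-edge tolerance as the
# definition: a point belongs to level h when f >= h up to 1e-12*dh).
brute_tfce <- function(f, E = 0.5, H = 2, dh) {
  T_ <- length(f)
  out <- numeric(T_)
  tol <- 1e-12 * dh
  mmax <- floor(max(f) / dh + 1e-9)
  for (t in seq_len(T_)) {
    for (k in seq_len(max(mmax, 0))) {
      h <- k * dh
      if (f[t] < h - tol) next
      lo <- t; while (lo > 1 && f[lo - 1] >= h - tol) lo <- lo - 1
      hi <- t; while (hi < T_ && f[hi + 1] >= h - tol) hi <- hi + 1
      out[t] <- out[t] + (hi - lo + 1)^E * h^H * dh
    }
  }
  out
}

# Tiny epochs object built directly (staged provenance controllable).
make_epochs <- function(arr, times = seq.int(-200, 999), participant = 1L,
                        filtered = TRUE, baseline = NULL, rejected = FALSE) {
  structure(list(participant_id = participant,
                 trial_id = seq_len(dim(arr)[1]),
                 times = as.integer(times),
                 data = arr,
                 accept = rep(TRUE, dim(arr)[1]),
                 reject_reason = rep(NA_character_, dim(arr)[1]),
                 provenance = list(filtered = filtered, baseline = baseline,
                                   rejected = rejected)),
            class = "gf_epochs")
}

# Minimal trial table.
make_trials <- function(n, side = rep(c(-1L, 0L, 1L), length.out = n),
                        is_go = rep(FALSE, n), correct = rep(TRUE, n),
                        class = "star", onset = NA_integer_) {
  data.frame(trial_id = seq_len(n), participant_id = 1L,
             experiment_kind = "stars", side_code = side, is_go = is_go,
             stimulus_class = class, response_correct = correct,
             onset_sample = onset)
}

# Window summary rows generated from a known linear model, one row per
# participant x hand x side.
make_window_data <- function(n, b_hand = 0, b_side = 0, b_int = 0,
                             icpt_sd = 0, resid_sd = 0, seed = 1,
                             intercept = 0) {
  set.seed(seed)
  d <- expand.grid(participant = seq_len(n), hand = c("left", "right"),
                   side_code = c(-1, 0, 1), stringsAsFactors = FALSE)
  d$hand_code <- ifelse(d$hand == "right", 0.5, -0.5)
  u <- rnorm(n, sd = icpt_sd)
  d$mean_force_mN <- intercept + u[d$participant] + b_hand * d$hand_code +
    b_side * d$side_code + b_int * d$hand_code * d$side_code +
    rnorm(nrow(d), sd = resid_sd)
  d$window_start_ms <- 0; d$window_end_ms <- 100
  d$experiment_kind <- "stars"
  d
}

# Independent R implementation of the pointwise 2x3 within-participant
# ANOVA (textbook SS decomposition), used as an oracle for the compiled
# scan and as a statistic for the generic permutation engine.
r_fscan <- function(arr, effect = "interaction") {
  n <- dim(arr)[1]; T_ <- dim(arr)[4]
  out <- numeric(T_)
  for (t in seq_len(T_)) {
    Y <- arr[, , , t, drop = FALSE][, , , 1]
    g <- mean(Y)
    mi <- apply(Y, 1, mean); mj <- apply(Y, 2, mean); mk <- apply(Y, 3, mean)
    mij <- apply(Y, c(1, 2), mean); mik <- apply(Y, c(1, 3), mean)
    mjk <- apply(Y, c(2, 3), mean)
    ssA <- 3 * n * sum((mj - g)^2)
    ssB <- 2 * n * sum((mk - g)^2)
    ssAB <- n * sum((mjk - outer(mj, rep(1, 3)) -
                       outer(rep(1, 2), mk) + g)^2)
    ssAS <- 3 * sum((mij - outer(mi, rep(1, 2)) -
                       outer(rep(1, n), mj) + g)^2)
    ssBS <- 2 * sum((mik - outer(mi, rep(1, 3)) -
                       outer(rep(1, n), mk) + g)^2)
    res <- Y
    for (i in 1:n) for (j in 1:2) for (k in 1:3)
      res[i, j, k] <- Y[i, j, k] - mij[i, j] - mik[i, k] - mjk[j, k] +
        mi[i] + mj[j] + mk[k] - g
    ssABS <- sum(res^2)
    f <- switch(effect,
                hand = if (ssAS / (n - 1) > 1e-12)
                  ssA / (ssAS / (n - 1)) else 0,
                side = if (ssBS / (2 * (n - 1)) > 1e-12)
                  (ssB / 2) / (ssBS / (2 * (n - 1))) else 0,
                interaction = if (ssABS / (2 * (n - 1)) > 1e-12)
                  (ssAB / 2) / (ssABS / (2 * (n - 1))) else 0)
    out[t] <- f
  }
  out
}
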