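# Exploratory scan: pointwise repeated-measures ANOVA, threshold-free
# cluster enhancement (TFCE), and a within-participant permutation null of
# the maximum enhanced statistic.
#
# The permutation scheme relabels the six hand-by-side cells freely within
# each participant, moving whole time courses together so the temporal
# autocorrelation of the signal is preserved under the null.

# Flatten a gf_cond_avg (complete participants only) to the (6n x T) matrix
# used by the compiled scan: row = (participant-1)*6 + cell,
# cell = hand*3 + side with hand 0 = left, 1 = right and side 0/1/2 for
# codes -1/0/+1.
cond_matrix <- function(cond) {
  stopifnot(inherits(cond, "gf_cond_avg"))
  arr <- cond$data
  complete <- apply(!is.na(arr), 1, all)
  if (sum(complete) < nrow(arr))
    message(sprintf("dropping %d participant(s) with missing cells",
                    sum(!complete)))
  arr <- arr[complete, , , , drop = FALSE]
  n <- dim(arr)[1]
  if (n < 3) stopf("insufficient data: need >= 3 complete participants")
  T_ <- dim(arr)[4]
  M <- matrix(0, 6L * n, T_)
  for (i in seq_len(n))
    for (j in 1:2)
      for (k in 1:3)
        M[(i - 1L) * 6L + (j - 1L) * 3L + k, ] <- arr[i, j, k, ]
  list(M = M, n = n, times = cond$times)
}

#' Pointwise two-way repeated-measures ANOVA scan
#'
#' At every timepoint, computes the classical two-way within-participant
#' ANOVA F statistics for Hand (df 1, n-1), Side (df 2, 2(n-1)) and their
#' interaction (df 2, 2(n-1)) from the hand-by-side condition averages.
#' Participants with missing cells are dropped (with a message). Degenerate
#' timepoints with a zero error mean square get F = 0.
#'
#' @param cond a `gf_cond_avg`.
#' @return list of three `gf_statscan` objects (`hand`, `side`,
#'   `interaction`), each with the F trace and its dfs.
#' @export
pointwise_rm_anova <- function(cond) {
  cm <- cond_matrix(cond)
  f <- fscan_cpp(cm$M, cm$n)
  n <- cm$n
  mk <- function(row, effect, df1, df2)
    structure(list(effect = effect, f = f[row, ], df1 = df1, df2 = df2,
                   n = n, times = cm$times), class = "gf_statscan")
  list(hand = mk(1, "hand", 1L, n - 1L),
       side = mk(2, "side", 2L, 2L * (n - 1L)),
       interaction = mk(3, "interaction", 2L, 2L * (n - 1L)))
}

#' Threshold-free cluster enhancement
#'
#' Enhances a non-negative statistic trace by integrating, over thresholds
#' h = dh, 2dh, ... up to the local statistic value, the term
#' extent^E * h^H * dh, where extent is the length (in samples) of the
#' contiguous suprathreshold run containing the timepoint. E = 0.5, H = 2
#' are the standard defaults; `dh` defaults to max(f)/100.
#'
#' @param f numeric non-negative statistic trace (or a `gf_statscan`).
#' @param E extent exponent.
#' @param H height exponent.
#' @param dh threshold step; `NULL` for max(f)/100.
#' @return numeric vector of enhanced values (same length as `f`).
#' @export
tfce <- function(f, E = 0.5, H = 2, dh = NULL) {
  if (inherits(f, "gf_statscan")) f <- f$f
  if (!all(is.finite(f))) stopf("input error: non-finite statistic values")
  if (is.null(dh)) {
    dh <- max(f) / 100
    if (dh <= 0) return(numeric(length(f)))
  }
  if (dh <= 0) stopf("dh must be positive")
  tfce_cpp(f, E, H, dh)
}

# Within-participant cell relabelings: an (n_perm x k*n) integer matrix of
# 0-based labels, row-blocked per participant, drawn with the R RNG.
gen_perms <- function(n_perm, n, k, seed) {
  with_rng(seed, {
    m <- matrix(0L, n_perm, k * n)
    for (p in seq_len(n_perm))
      m[p, ] <- as.integer(unlist(lapply(seq_len(n),
                                         function(i) sample.int(k) - 1L)))
    m
  })
}

#' Permutation null of a maximum statistic (generic engine)
#'
#' Relabels condition cells freely within each participant (identical
#' relabeling at every timepoint, so whole time courses move together) and
#' records the maximum over time of a user statistic for each permutation.
#'
#' @param x numeric array, participants x cells x time.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param statistic function mapping such an array to a numeric trace.
#' @return list with `observed` (statistic of `x`), `null_max` (length
#'   `n_perm`), `n_perm` and `seed`.
#' @export
perm_max_null <- function(x, n_perm, seed, statistic) {
  stopifnot(length(dim(x)) == 3L)
  n <- dim(x)[1]; k <- dim(x)[2]
  perms <- gen_perms(n_perm, n, k, seed)
  observed <- statistic(x)
  null_max <- numeric(n_perm)
  xp <- x
  for (p in seq_len(n_perm)) {
    for (i in seq_len(n))
      xp[i, perms[p, (i - 1L) * k + seq_len(k)] + 1L, ] <- x[i, , ]
    null_max[p] <- max(statistic(xp))
  }
  list(observed = observed, null_max = null_max, n_perm = n_perm,
       seed = seed)
}

#' Permutation null of the max TFCE-enhanced ANOVA statistic
#'
#' For one effect of the hand-by-side design, computes the observed
#' TFCE-enhanced F scan and the permutation distribution of its maximum
#' under within-participant relabeling of the six condition cells. The TFCE
#' threshold step is fixed from the observed scan (max F / 100) and reused
#' for every permutation. Deterministic given `seed`.
#'
#' @param cond a `gf_cond_avg`.
#' @param effect "hand", "side" or "interaction".
#' @param n_perm number of permutations (5000 for a full run; smaller for
#'   desk-scale work).
#' @param seed integer seed.
#' @param E,H,dh TFCE parameters (see [tfce()]).
#' @return a `gf_permnull`: observed F and enhanced traces, null maxima,
#'   parameters.
#' @export
permutation_null <- function(cond, effect = c("interaction", "hand", "side"),
                             n_perm = 5000, seed = 1L, E = 0.5, H = 2,
                             dh = NULL) {
  effect <- match.arg(effect)
  if (n_perm < 1) stopf("n_perm must be >= 1")
  cm <- cond_matrix(cond)
  eff_id <- match(effect, c("hand", "side", "interaction")) - 1L
  f_obs <- fscan_cpp(cm$M, cm$n)[eff_id + 1L, ]
  if (is.null(dh)) dh <- max(f_obs) / 100
  if (dh <= 0) {
    enhanced <- numeric(length(f_obs))
    null_max <- numeric(n_perm)
  } else {
    enhanced <- tfce_cpp(f_obs, E, H, dh)
    perms <- gen_perms(n_perm, cm$n, 6L, seed)
    null_max <- perm_max_tfce_cpp(cm$M, cm$n, perms, eff_id, E, H, dh)
  }
  structure(list(effect = effect, f = f_obs, enhanced = enhanced,
                 null_max = null_max, n_perm = n_perm, seed = seed,
                 times = cm$times, params = list(E = E, H = H, dh = dh)),
            class = "gf_permnull")
}

#' Timepoint p-values and significance windows from a permutation null
#'
#' Per-timepoint p-values use the add-one estimator
#' p(t) = (1 + #\{null max >= enhanced(t)\}) / (1 + n_perm), which never
#' returns zero and is family-wise valid through the max-statistic
#' correction. Windows are maximal runs of p below `alpha` ("significant")
#' and below `close_alpha` ("close"), reported with half-open bounds in ms.
#'
#' @param pn a `gf_permnull`.
#' @param alpha significance level.
#' @param close_alpha reporting level for close-to-significance windows.
#' @return a `gf_windows`: data.frame of windows (effect, start_ms, end_ms,
#'   min_p, alpha_level) with the p trace in attributes.
#' @export
scan_significance <- function(pn, alpha = 0.05, close_alpha = 0.1) {
  stopifnot(inherits(pn, "gf_permnull"))
  if (pn$n_perm < 1 || length(pn$null_max) < 1)
    stopf("empty permutation null")
  srt <- sort(pn$null_max)
  n_ge <- length(srt) - findInterval(pn$enhanced - 1e-12, srt)
  p <- (1 + n_ge) / (1 + pn$n_perm)
  runs_of <- function(level, label) {
    r <- rle(p < level)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (!length(keep))
      return(data.frame(effect = character(0), start_ms = numeric(0),
                        end_ms = numeric(0), min_p = numeric(0),
                        alpha_level = character(0)))
    data.frame(effect = pn$effect,
               start_ms = pn$times[starts[keep]],
               end_ms = pn$times[ends[keep]] + 1,
               min_p = vapply(keep, function(i)
                 min(p[starts[i]:ends[i]]), 0.0),
               alpha_level = label)
  }
  win <- rbind(runs_of(alpha, "significant"), runs_of(close_alpha, "close"))
  structure(win, p_values = p, times = pn$times, effect = pn$effect,
            n_perm = pn$n_perm, seed = pn$seed, class = c("gf_windows",
                                                          "data.frame"))
}

#' One-call exploratory scan
#'
#' Convenience wrapper: permutation null plus significance windows for one
#' effect.
#'
#' @inheritParams permutation_null
#' @inheritParams scan_significance
#' @return a `gf_windows` (see [scan_significance()]).
#' @export
cluster_scan <- function(cond, effect = "interaction", n_perm = 5000,
                         seed = 1L, alpha = 0.05, close_alpha = 0.1,
                         E = 0.5, H = 2, dh = NULL) {
  scan_significance(permutation_null(cond, effect, n_perm, seed, E, H, dh),
                    alpha, close_alpha)
}
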