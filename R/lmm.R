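# Confirmatory window-averaged linear mixed models: sum-coded Hand,
# continuous Side, backward elimination by single-term likelihood-ratio
# deletion, marginal/conditional R-squared, contralateral-force covariate
# models, per-participant random slopes and cross-experiment slope
# correlations.

#' Window-average condition means
#'
#' Averages the condition time courses over a time window (inclusive of the
#' start, exclusive of the end), yielding one row per participant, hand and
#' side: the data unit of the confirmatory models. Hand is sum-coded
#' (left -0.5, right +0.5); side is the continuous code (-1, 0, +1).
#'
#' @param cond a `gf_cond_avg`.
#' @param window c(start_ms, end_ms), end exclusive.
#' @return WindowSummary data.frame with columns participant, hand,
#'   hand_code, side_code, mean_force_mN, window_start_ms, window_end_ms,
#'   experiment_kind.
#' @export
window_average <- function(cond, window) {
  stopifnot(inherits(cond, "gf_cond_avg"))
  sel <- cond$times >= window[1] & cond$times < window[2]
  if (!any(sel)) stopf("bounds error: empty window [%g, %g)", window[1],
                       window[2])
  arr <- cond$data[, , , sel, drop = FALSE]
  m <- apply(arr, c(1, 2, 3), mean)
  n <- dim(m)[1]
  out <- expand.grid(participant = seq_len(n),
                     hand = c("left", "right"),
                     side_code = c(-1, 0, 1),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$participant <- cond$participants[out$participant]
  out$hand_code <- ifelse(out$hand == "right", 0.5, -0.5)
  out$mean_force_mN <- as.vector(m)
  out$window_start_ms <- window[1]
  out$window_end_ms <- window[2]
  out$experiment_kind <- cond$experiment_kind
  out[stats::complete.cases(out$mean_force_mN), , drop = FALSE]
}

new_gf_lmm <- function(model, data, fixed, random, method) {
  sm <- summary(model)$coefficients
  coefs <- data.frame(term = rownames(sm),
                      b = sm[, "Estimate"],
                      SE = sm[, "Std. Error"],
                      df = if ("df" %in% colnames(sm)) sm[, "df"] else NA,
                      t = sm[, "t value"],
                      p = if ("Pr(>|t|)" %in% colnames(sm))
                        sm[, "Pr(>|t|)"]
                      else 2 * stats::pnorm(-abs(sm[, "t value"])),
                      row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(model))
  r2 <- tryCatch(nakagawa_r2_merMod(model), error = function(e) c(NA, NA))
  structure(list(model = model, coefficients = coefs,
                 varcomp = vc[, c("grp", "var1", "var2", "vcov", "sdcor")],
                 singular = lme4::isSingular(model),
                 marginal_R2 = r2[1], conditional_R2 = r2[2],
                 fixed = fixed, random = random, method = method,
                 df_method = "Satterthwaite (Wald t)",
                 data = data),
            class = "gf_lmm")
}

#' @export
#' @method print gf_lmm
print.gf_lmm <- function(x, ...) {
  cat(sprintf("Linear mixed model (%s; p-values: %s)%s\n", x$method,
              x$df_method, if (x$singular) " [singular fit]" else ""))
  cat("Fixed:", deparse(x$fixed), " Random:", x$random, "\n")
  print(x$coefficients, digits = 4)
  cat(sprintf("Marginal R2 = %.3f, conditional R2 = %.3f\n",
              x$marginal_R2, x$conditional_R2))
  invisible(x)
}

#' Fit a window-averaged linear mixed model
#'
#' REML fit of `mean_force_mN` on the requested fixed terms with a
#' participant random term, via `lmerTest` so fixed-effect p-values come
#' from Wald t tests with Satterthwaite degrees of freedom. Singular fits
#' (e.g. a zero random-intercept variance) are flagged, not errors.
#'
#' @param data WindowSummary data.frame (see [window_average()]).
#' @param fixed right-hand-side formula of fixed terms, default
#'   `~ hand_code * side_code`.
#' @param random random-effects term, default `"(1 | participant)"`.
#' @param method "REML" or "ML".
#' @return a `gf_lmm`.
#' @export
fit_lmm <- function(data, fixed = ~ hand_code * side_code,
                    random = "(1 | participant)", method = c("REML", "ML")) {
  method <- match.arg(method)
  if (min(table(data$participant)) < 2)
    stopf("need >= 2 observations per participant")
  fml <- stats::as.formula(paste("mean_force_mN ~",
                                 paste(deparse(fixed[[2]]), collapse = ""),
                                 "+", random))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(fml, data = data, REML = method == "REML"))),
    error = function(e) stopf("fit error: %s", conditionMessage(e)))
  new_gf_lmm(fit, data, fixed, random, method)
}

droppable_terms <- function(fixed_terms) {
  # terms not marginal to any remaining higher-order term
  tl <- attr(stats::terms(stats::reformulate(fixed_terms)), "term.labels")
  keep_parts <- function(t) strsplit(t, ":", fixed = TRUE)[[1]]
  vapply(tl, function(t) {
    parts <- keep_parts(t)
    !any(vapply(tl, function(u) {
      up <- keep_parts(u)
      length(up) > length(parts) && all(parts %in% up)
    }, TRUE))
  }, TRUE)
}

#' Backward elimination by single-term deletion
#'
#' Starting from the fitted model, repeatedly tests every currently
#' droppable fixed term (marginality respected: a main effect is never
#' dropped while its interaction remains) by a likelihood-ratio test
#' between ML refits with and without the term, drops the least significant
#' term with p > `alpha_keep`, and stops when all droppable terms have
#' p <= `alpha_keep`. The final model is refit by REML.
#'
#' @param fit a `gf_lmm` (the full model).
#' @param alpha_keep retention threshold (terms with LRT p > this leave).
#' @return list with `fit` (reduced `gf_lmm`) and `trail` (data.frame of
#'   elimination steps: step, term, LRT chi-square, df, p).
#' @export
drop1_eliminate <- function(fit, alpha_keep = 0.1) {
  stopifnot(inherits(fit, "gf_lmm"))
  data <- fit$data
  random <- fit$random
  terms_now <- attr(stats::terms(fit$fixed), "term.labels")
  trail <- data.frame(step = integer(0), term = character(0),
                      chisq = numeric(0), df = numeric(0), p = numeric(0))
  step <- 0L
  ml_fit <- function(tl) {
    rhs <- if (length(tl)) paste(c(tl, random), collapse = " + ") else random
    suppressMessages(suppressWarnings(
      lme4::lmer(stats::as.formula(paste("mean_force_mN ~", rhs)),
                 data = data, REML = FALSE)))
  }
  repeat {
    if (!length(terms_now)) break
    full <- ml_fit(terms_now)
    cand <- terms_now[droppable_terms(terms_now)]
    if (!length(cand)) break
    ps <- vapply(cand, function(tm) {
      red <- ml_fit(setdiff(terms_now, tm))
      an <- stats::anova(red, full)
      c(an$Chisq[2], an$Df[2], an$`Pr(>Chisq)`[2])
    }, numeric(3))
    worst <- which.max(ps[3, ])
    if (ps[3, worst] <= alpha_keep) break
    step <- step + 1L
    trail <- rbind(trail, data.frame(step = step, term = cand[worst],
                                     chisq = ps[1, worst], df = ps[2, worst],
                                     p = ps[3, worst]))
    terms_now <- setdiff(terms_now, cand[worst])
  }
  reduced_fixed <- if (length(terms_now)) stats::reformulate(terms_now)
                   else ~ 1
  list(fit = fit_lmm(data, reduced_fixed, random, "REML"), trail = trail)
}

# Nakagawa-style variance decomposition for a merMod.
nakagawa_r2_merMod <- function(model) {
  var_f <- stats::var(as.vector(stats::model.matrix(model) %*%
                                  lme4::fixef(model)))
  vc <- lme4::VarCorr(model)
  mml <- lme4::getME(model, "mmList")
  var_r <- 0
  for (g in seq_along(vc)) {
    S <- as.matrix(vc[[g]])
    X <- mml[[g]]
    var_r <- var_r + mean(rowSums((X %*% S) * X))
  }
  var_e <- stats::sigma(model)^2
  denom <- var_f + var_r + var_e
  if (denom <= 0) stopf("undefined R2: zero total variance")
  c(marginal = var_f / denom, conditional = (var_f + var_r) / denom)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Marginal R2 is the variance of the fixed-effect predictions over the
#' total model variance (fixed + random + residual); conditional R2 adds
#' the random-effect variance to the numerator. Random-slope terms
#' contribute their design-weighted variance.
#'
#' @param fit a `gf_lmm` (or a `merMod`).
#' @return named numeric: `marginal`, `conditional`.
#' @export
nakagawa_r2 <- function(fit) {
  model <- if (inherits(fit, "gf_lmm")) fit$model else fit
  nakagawa_r2_merMod(model)
}

#' Contralateral-force covariate model
#'
#' Models one hand's window-averaged force on the grand-mean-centered force
#' of the opposite hand in the same window plus the continuous side code,
#' with a participant random intercept. The covariate absorbs the shared
#' inter-hand coordination signal so the side coefficient estimates the
#' lateralised effect beyond it.
#'
#' @param data WindowSummary containing both hands.
#' @param target_hand "left" or "right".
#' @return a `gf_lmm` with terms `contra_c` and `side_code`.
#' @export
contralateral_model <- function(data, target_hand = c("left", "right")) {
  target_hand <- match.arg(target_hand)
  other <- if (target_hand == "left") "right" else "left"
  tgt <- data[data$hand == target_hand, ]
  opp <- data[data$hand == other, ]
  key <- function(d) paste(d$participant, d$side_code)
  m <- match(key(tgt), key(opp))
  if (anyNA(m)) stopf("pairing error: missing opposite-hand rows")
  tgt$contra <- opp$mean_force_mN[m]
  tgt$contra_c <- tgt$contra - mean(tgt$contra)
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(mean_force_mN ~ contra_c + side_code + (1 | participant),
                   data = tgt, REML = TRUE)))
  out <- new_gf_lmm(fit, tgt, ~ contra_c + side_code, "(1 | participant)",
                    "REML")
  out$target_hand <- target_hand
  out
}

#' Per-participant side slopes (fixed + conditional mode)
#'
#' Fits, for one hand, force on the side code with a random intercept and
#' random side slope per participant, and returns each participant's
#' individual slope as the fixed coefficient plus the predicted (BLUP)
#' deviation. Singular fits are flagged; non-convergence is an error naming
#' the window and hand.
#'
#' @param data WindowSummary.
#' @param hand "left" or "right".
#' @return SlopeTable data.frame: participant, experiment_kind, window,
#'   hand, slope (mN per side unit); attribute `singular`.
#' @export
participant_slopes <- function(data, hand = c("left", "right")) {
  hand <- match.arg(hand)
  d <- data[data$hand == hand, ]
  win <- sprintf("%g-%g", d$window_start_ms[1], d$window_end_ms[1])
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(mean_force_mN ~ side_code + (1 + side_code | participant),
                 data = d, REML = TRUE))),
    error = function(e)
      stopf("slope fit failed for window %s, %s hand: %s", win, hand,
            conditionMessage(e)))
  re <- lme4::ranef(fit)$participant
  ids <- as.integer(rownames(re))
  out <- data.frame(participant = ids,
                    experiment_kind = d$experiment_kind[1],
                    window = win,
                    hand = hand,
                    slope = lme4::fixef(fit)[["side_code"]] +
                      re[["side_code"]])
  attr(out, "singular") <- lme4::isSingular(fit)
  out
}

#' Pairwise correlations of individual slopes
#'
#' Pearson correlations between per-participant slopes across experiments,
#' windows and hands, on pairwise-complete participants, with two-sided
#' p-values from the t transform and the participant count per pair. Pairs
#' with fewer than 3 overlapping participants are skipped with a notice.
#'
#' @param tables list of SlopeTables from [participant_slopes()].
#' @return data.frame: var1, var2, r, p, n, stars
#'   (* p<.05, ** p<.01, *** p<.001).
#' @export
slope_correlations <- function(tables) {
  all <- do.call(rbind, tables)
  all$key <- sprintf("%s %s %s", all$experiment_kind, all$window,
                     ifelse(all$hand == "left", "LH", "RH"))
  keys <- unique(all$key)
  ids <- sort(unique(all$participant))
  wide <- matrix(NA_real_, length(ids), length(keys),
                 dimnames = list(ids, keys))
  for (r in seq_len(nrow(all)))
    wide[as.character(all$participant[r]), all$key[r]] <- all$slope[r]
  out <- data.frame(var1 = character(0), var2 = character(0),
                    r = numeric(0), p = numeric(0), n = integer(0),
                    stars = character(0))
  for (i in seq_along(keys)) for (j in seq_along(keys)) {
    if (j <= i) next
    ok <- stats::complete.cases(wide[, c(i, j)])
    if (sum(ok) < 3) {
      message(sprintf("skipping %s vs %s: only %d overlapping participants",
                      keys[i], keys[j], sum(ok)))
      next
    }
    ct <- stats::cor.test(wide[ok, i], wide[ok, j], method = "pearson")
    p <- ct$p.value
    out <- rbind(out, data.frame(
      var1 = keys[i], var2 = keys[j], r = unname(ct$estimate), p = p,
      n = sum(ok),
      stars = if (p < .001) "***" else if (p < .01) "**"
              else if (p < .05) "*" else ""))
  }
  out
}
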