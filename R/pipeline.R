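# End-to-end orchestration: simulate -> preprocess -> scan -> confirm ->
# slopes, with per-stage seeds derived from one master seed, a manifest of
# outputs, and a human-readable report.

#' Simulate and preprocess one experiment (streaming)
#'
#' Runs the generator and the full preprocessing chain participant by
#' participant (filter, epoch, baseline, reject), excludes participants
#' losing more than 20% of critical trials to the force threshold, and
#' returns the condition averages together with the ground truth and the
#' rejection summary.
#'
#' @param spec,effect,noise generator settings (see [experiment_spec()]).
#' @param seed master integer seed for this experiment.
#' @param engine "fast" fuses the per-participant stages into a low-copy
#'   loop; "staged" runs the exported stage functions one by one. Both give
#'   identical numbers.
#' @return list: `cond` (`gf_cond_avg`), `truth`, `rejections`
#'   (per-participant data.frame), `excluded` (participant ids).
#' @export
simulate_condition_averages <- function(spec, effect, noise, seed,
                                        engine = c("fast", "staged")) {
  engine <- match.arg(engine)
  truth <- draw_ground_truth(spec, effect, noise, seed)
  if (engine == "fast")
    return(fast_condition_averages(spec, effect, noise, seed, truth))
  eps <- list(); trs <- list(); rep_rows <- list()
  for (i in seq_len(spec$n_participants)) {
    sim <- simulate_participant(spec, effect, noise,
                                participant_truth(truth, i),
                                derive_seed(seed, "participant", i), i)
    rec <- lowpass_filter(sim$recording)
    ep <- extract_epochs(rec, sim$trials)
    ep <- baseline_correct(ep)
    ep <- reject_artifacts(ep)
    rr <- rejection_report(ep, sim$trials)
    rep_rows[[i]] <- rr$participants
    eps[[i]] <- ep
    trs[[i]] <- sim$trials
  }
  rejections <- do.call(rbind, rep_rows)
  keep <- !rejections$excluded
  cond <- condition_averages(eps[keep], trs[keep])
  list(cond = cond, truth = truth, rejections = rejections,
       excluded = rejections$participant[!keep])
}

# Fused simulate+preprocess loop: same computation as the staged path
# (continuous-trace filtering, epoch slicing, baseline, threshold
# rejection, averaging) with minimal copying.
fast_condition_averages <- function(spec, effect, noise, seed, truth) {
  np <- spec$n_participants
  ntr <- spec$n_trials
  bf <- signal::butter(4, 15 / 500, type = "low")
  pmax_ <- max(Mod(polyroot(rev(bf$a))))
  pad <- as.integer(ceiling(-30 / log(pmax_)))
  bsel <- which(epoch_times() >= -20 & epoch_times() < 0)
  sides <- c(-1L, 0L, 1L)
  arr <- array(NA_real_, dim = c(np, 2L, 3L, EPOCH_LEN),
               dimnames = list(NULL, c("left", "right"), c("-1", "0", "1"),
                               NULL))
  cells_n <- array(0L, dim = c(np, 2L, 3L))
  rej <- data.frame(participant = seq_len(np), n_critical = 0L,
                    n_rejected = 0L, proportion_rejected = NA_real_,
                    excluded = FALSE)
  for (i in seq_len(np)) {
    tr_i <- participant_truth(truth, i)
    pseed <- derive_seed(seed, "participant", i)
    bp <- build_participant(spec, effect, noise, tr_i, pseed)
    nz <- sim_noise_cpp(bp$N, noise$white_sd_mN, noise$interhand_coupling,
                        noise$drift_sd_mN / sqrt(100), 10L,
                        as.numeric(derive_seed(pseed, "noise")))
    epo <- vector("list", 2L)
    for (h in 1:2) {
      f <- nz[, h] + tr_i$intercept[h]
      f[bp$idx] <- f[bp$idx] + bp$adds[[h]]
      f <- filtfilt_pad_cpp(bf$b, bf$a, f, pad)
      e <- matrix(f[bp$idx], EPOCH_LEN, ntr)   # column = trial
      e <- e - rep(colMeans(e[bsel, , drop = FALSE]), each = EPOCH_LEN)
      epo[[h]] <- e
    }
    peak <- pmax(col_absmax_cpp(epo[[1]]), col_absmax_cpp(epo[[2]]))
    accept <- peak <= 500
    trials <- bp$trials
    crit <- !trials$is_go & trials$response_correct &
      trials$stimulus_class %in% c("star", "arrow", "word") &
      !is.na(trials$side_code)
    rej$n_critical[i] <- sum(crit)
    rej$n_rejected[i] <- sum(crit & !accept)
    rej$proportion_rejected[i] <- rej$n_rejected[i] / max(rej$n_critical[i], 1L)
    rej$excluded[i] <- rej$proportion_rejected[i] > 0.20
    for (s in 1:3) {
      pick <- crit & accept & !is.na(trials$side_code) &
        trials$side_code == sides[s]
      cells_n[i, , s] <- sum(pick)
      if (any(pick)) for (h in 1:2)
        arr[i, h, s, ] <- rowMeans(epo[[h]][, pick, drop = FALSE])
    }
  }
  keep <- !rej$excluded
  cond <- structure(list(data = arr[keep, , , , drop = FALSE],
                         n_trials = cells_n[keep, , , drop = FALSE],
                         participants = which(keep),
                         times = epoch_times(),
                         experiment_kind = spec$experiment_kind),
                    class = "gf_cond_avg")
  list(cond = cond, truth = truth, rejections = rej,
       excluded = which(!keep))
}

confirm_windows <- function(cond, windows, alpha_keep = 0.1) {
  fits <- list()
  for (r in seq_len(nrow(windows))) {
    win <- c(windows$start_ms[r], windows$end_ms[r])
    ws <- window_average(cond, win)
    label <- sprintf("%g-%g", win[1], win[2])
    full <- fit_lmm(ws)
    fits[[label]] <- list(window = win,
                          anova2x3 = drop1_eliminate(full, alpha_keep),
                          contralateral = list(
                            left = contralateral_model(ws, "left"),
                            right = contralateral_model(ws, "right")))
  }
  fits
}

#' Run the full pipeline for one configuration
#'
#' simulate -> preprocess -> permutation scan (all three effects) ->
#' confirmatory mixed models on each interaction window -> per-participant
#' slopes. Writes trial logs, ground truth, condition averages, window
#' table, fit tables and a report to `outdir` and returns a manifest.
#'
#' @param config a config list from [read_config()] or a path to a YAML
#'   config (or `NULL` for defaults).
#' @param seed master seed; overrides the config seed if not `NULL`.
#' @param outdir output directory (created if needed).
#' @param n_perm permutations for the scan; overrides the config.
#' @return list: `manifest`, `results`.
#' @export
run_pipeline <- function(config = NULL, seed = NULL, outdir = tempfile(),
                         n_perm = NULL) {
  cfg <- if (is.character(config)) read_config(config)
         else if (is.null(config)) read_config(NULL, quiet = TRUE)
         else config
  seed <- seed %||% cfg$seed
  n_perm <- n_perm %||% cfg$analysis$n_perm
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  tic <- function() Sys.time()
  lap <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- tic()
  sim <- simulate_condition_averages(cfg$spec, cfg$effect, cfg$noise,
                                     derive_seed(seed, "simulate"))
  timings["simulate_preprocess"] <- lap(t0)

  t0 <- tic()
  scans <- lapply(c("hand", "side", "interaction"), function(e)
    cluster_scan(sim$cond, e, n_perm, derive_seed(seed, "scan"),
                 cfg$analysis$alpha, cfg$analysis$close_alpha,
                 cfg$analysis$tfce_e, cfg$analysis$tfce_h))
  names(scans) <- c("hand", "side", "interaction")
  windows <- do.call(rbind, lapply(scans, as.data.frame))
  timings["scan"] <- lap(t0)

  t0 <- tic()
  int_wins <- windows[windows$effect == "interaction" &
                        windows$alpha_level == "significant", , drop = FALSE]
  fits <- confirm_windows(sim$cond, int_wins)
  slopes <- list()
  for (label in names(fits)) {
    win <- fits[[label]]$window
    ws <- window_average(sim$cond, win)
    for (h in c("left", "right"))
      slopes[[paste(label, h)]] <- participant_slopes(ws, h)
  }
  correlations <- if (length(slopes) >= 2) slope_correlations(slopes)
                  else NULL
  timings["confirm"] <- lap(t0)

  results <- list(cond = sim$cond, truth = sim$truth,
                  rejections = sim$rejections, excluded = sim$excluded,
                  windows = windows, fits = fits, slopes = slopes,
                  correlations = correlations, seed = seed, n_perm = n_perm)

  files <- c(truth = file.path(outdir, "ground_truth.csv"),
             windows = file.path(outdir, "windows.csv"),
             rejections = file.path(outdir, "rejections.csv"),
             report = file.path(outdir, "report.txt"))
  write_ground_truth(sim$truth, files["truth"])
  write_schema_csv(as.data.frame(windows), files["windows"], "windows")
  write_schema_csv(sim$rejections, files["rejections"], "rejections")
  writeLines(render_report(results), files["report"])

  manifest <- list(package_version = as.character(utils::packageVersion("gripscan")),
                   seed = seed,
                   stage_seeds = c(simulate = derive_seed(seed, "simulate"),
                                   scan = derive_seed(seed, "scan")),
                   n_perm = n_perm,
                   experiment = cfg$spec$experiment_kind,
                   timings_s = round(timings, 3),
                   files = vapply(files, function(f)
                     unname(tools::md5sum(f)), ""))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  list(manifest = manifest, results = results)
}

fmt_fit <- function(fit, label) {
  tab <- fit$coefficients
  c(sprintf("  %s%s", label, if (fit$singular) " [singular]" else ""),
    sprintf("    %-28s %8s %7s %7s %7s", "term", "b", "SE", "t", "p"),
    sprintf("    %-28s %8.3f %7.3f %7.3f %7.3f", tab$term, tab$b, tab$SE,
            tab$t, tab$p),
    sprintf("    R2 marginal = %.3f, conditional = %.3f",
            fit$marginal_R2, fit$conditional_R2))
}

#' Render a human-readable pipeline report
#'
#' @param results the `results` element returned by [run_pipeline()].
#' @return character vector of report lines.
#' @export
render_report <- function(results) {
  if (is.null(results$windows))
    stopf("report error: missing pipeline outputs")
  lines <- c("gripscan pipeline report",
             sprintf("seed %d, %d permutations", results$seed,
                     results$n_perm),
             sprintf("participants excluded (>20%% rejected): %s",
                     if (length(results$excluded))
                       paste(results$excluded, collapse = ", ")
                     else "none"),
             "", "Permutation-scan windows:")
  sig <- results$windows[results$windows$alpha_level == "significant", ,
                         drop = FALSE]
  if (nrow(sig) == 0) {
    lines <- c(lines, "  no windows at alpha = .05")
  } else {
    lines <- c(lines, sprintf("  %-12s %8.0f-%-6.0f min p = %.4f",
                              sig$effect, sig$start_ms, sig$end_ms,
                              sig$min_p))
  }
  close <- results$windows[results$windows$alpha_level == "close", ,
                           drop = FALSE]
  if (nrow(close))
    lines <- c(lines, "Close to significance (p < .1):",
               sprintf("  %-12s %8.0f-%-6.0f min p = %.4f", close$effect,
                       close$start_ms, close$end_ms, close$min_p))
  for (label in names(results$fits)) {
    f <- results$fits[[label]]
    lines <- c(lines, "", sprintf("Window %s ms:", label),
               fmt_fit(f$anova2x3$fit, "hand x side model (after drop1)"),
               fmt_fit(f$contralateral$left, "left hand | contralateral"),
               fmt_fit(f$contralateral$right, "right hand | contralateral"))
  }
  if (!is.null(results$correlations)) {
    cr <- results$correlations
    lines <- c(lines, "", "Slope correlations:",
               sprintf("  %-28s vs %-28s r = %6.3f%-3s p = %.4f (N = %d)",
                       cr$var1, cr$var2, cr$r, cr$stars, cr$p, cr$n))
  }
  lines
}
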