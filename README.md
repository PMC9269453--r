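# gripscan

Event-related analysis of **bimanual grip-force recordings** from go/no-go
attention experiments: a synthetic-data generator with known ground truth,
signal preprocessing, an exploratory cluster-permutation scan with
threshold-free cluster enhancement (TFCE), and confirmatory window-averaged
linear mixed models.

## The problem

Participants hold a force sensor in each hand at a calibrated 1.5–3 N while
stimuli appear in a go/no-go task; vertical grip force (Fz, mN) is sampled
at 1000 Hz with a trigger at each stimulus onset. Analysing only correct
no-go trials isolates covert motor activity: does a stimulus's side, an
arrow's direction, or a word's spatial meaning change the force in each
hand, and when? The analysis has two stages:

1. **Exploratory scan.** Condition averages (participant × hand × side ×
   time) are scanned pointwise with a 2×3 within-participant ANOVA; each F
   trace is enhanced with TFCE,
   `TFCE(t) = Σ_h extent(t,h)^E · h^H · dh` (E = 0.5, H = 2), and compared
   against a within-participant permutation null of the maximum enhanced
   statistic (labels of the six cells shuffled per participant, whole time
   courses moving together). Maximal runs of p < .05 become candidate time
   windows.
2. **Confirmatory models.** Force averaged over a window is modelled as
   `force ~ hand * side + (1 | participant)` with sum-coded hand
   (−0.5/+0.5) and continuous side (−1/0/+1), backward-eliminated by
   likelihood-ratio `drop1` at p > .1, with Nakagawa marginal/conditional
   R². Contralateral-covariate models
   (`force_hand ~ contra_centered + side + (1 | participant)`) estimate
   each hand's lateralised slope beyond inter-hand coordination; random
   side slopes give per-participant coefficients that are correlated
   across experiments.

Because raw recordings of this kind are not redistributable, the package
ships a first-class generator (`simulate_experiment()`) that emulates the
paradigm — holding force, multiphasic evoked response, lateralised
hand-by-side effect with stimulus-dependent sign and latency, inter-hand
coupling, drift, artifacts, go-trial divergence — with every injected
parameter recorded as ground truth.

## Worked example

```r
library(gripscan)

spec <- experiment_spec("stars", n_participants = 12)
eff  <- effect_params("stars")      # ipsilateral-positive, 10 mN from 60 ms
nz   <- noise_params("stars")

sim  <- simulate_condition_averages(spec, eff, nz, seed = 1)
scan <- cluster_scan(sim$cond, "interaction", n_perm = 200, seed = 2)
scan[scan$alpha_level == "significant", ]
#>        effect start_ms end_ms    min_p alpha_level
#> 1 interaction     -183   -120 0.029851 significant
#> 2 interaction       22    492 0.004975 significant
```

The scan flags the injected hand-by-side interaction (true window
60–460 ms; the 22–492 ms run covers it, plus a pre-onset false positive
of the kind a max-statistic test admits at α = .05). The confirmatory
model on that window:

```r
ws  <- window_average(sim$cond, c(60, 460))
fit <- drop1_eliminate(fit_lmm(ws))$fit
fit
#> Linear mixed model (REML; p-values: Satterthwaite (Wald t)) [singular fit]
#> Fixed: ~hand_code + side_code + hand_code:side_code  Random: (1 | participant)
#>                  term       b     SE df       t         p
#> 1         (Intercept) 13.0674 0.3341 68 39.1118 2.396e-48
#> 2           hand_code  0.1128 0.6682 68  0.1687 8.665e-01
#> 3           side_code -0.8530 0.4092 68 -2.0845 4.088e-02
#> 4 hand_code:side_code 16.9812 0.8184 68 20.7497 3.965e-31
#> Marginal R2 = 0.860, conditional R2 = 0.860
```

The interaction coefficient (~17 mN) is the between-hand difference of
side slopes — the generator injected +10 mN per side unit in the right
hand and −10 in the left, so ≈ 20 is the population value at this sample
size. (The singular flag records the near-zero random-intercept variance:
baseline correction removes stable participant offsets by design.) The
right-hand contralateral-covariate model recovers its slope directly:

```r
contralateral_model(ws, "right")$coefficients
#>          term        b      SE df      t         p
#> 1 (Intercept) 13.12379 0.31963 33 41.060 6.564e-30
#> 2    contra_c -0.04777 0.09311 33 -0.513 6.114e-01
#> 3   side_code  7.19133 0.95403 33  7.538 1.140e-08
```

`run_pipeline(config, seed, outdir)` chains simulate → preprocess → scan →
confirm → slopes, writing CSV artifacts, a manifest with file digests, and
a plain-text report.

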