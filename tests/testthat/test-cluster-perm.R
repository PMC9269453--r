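# Pointwise RM-ANOVA scan, TFCE, and the within-participant permutation
# null of the max enhanced statistic.

test_that("the pointwise F scan matches a textbook repeated-measures ANOVA", {
  set.seed(3)
  n <- 4
  arr <- array(rnorm(n * 2 * 3 * 3), c(n, 2, 3, 3))
  sc <- pointwise_rm_anova(make_cond(arr))
  for (t in 1:3) {
    d <- expand.grid(p = factor(1:n), h = factor(1:2), s = factor(1:3))
    d$y <- as.vector(arr[, , , t])
    a <- summary(aov(y ~ h * s + Error(p / (h * s)), data = d))
    expect_equal(sc$hand$f[t], a[["Error: p:h"]][[1]]["h", "F value"],
                 tolerance = 1e-10)
    expect_equal(sc$side$f[t], a[["Error: p:s"]][[1]]["s", "F value"],
                 tolerance = 1e-10)
    expect_equal(sc$interaction$f[t],
                 a[["Error: p:h:s"]][[1]]["h:s", "F value"],
                 tolerance = 1e-10)
  }
  expect_equal(sc$hand$df1, 1L); expect_equal(sc$hand$df2, n - 1L)
  expect_equal(sc$side$df1, 2L); expect_equal(sc$side$df2, 2L * (n - 1L))
})

test_that("degenerate and additive designs behave as the decomposition dictates", {
  # identical cell means within participant -> F = 0 everywhere
  arr <- array(rep(rnorm(5), each = 1), c(5, 2, 3, 4))
  for (i in 1:5) arr[i, , , ] <- i
  sc <- pointwise_rm_anova(make_cond(arr))
  expect_true(all(sc$hand$f == 0))
  expect_true(all(sc$side$f == 0))
  expect_true(all(sc$interaction$f == 0))

  # adding a pure hand offset inflates the hand F, leaves interaction as is
  set.seed(8)
  base <- array(rnorm(6 * 2 * 3 * 5), c(6, 2, 3, 5))
  sc0 <- pointwise_rm_anova(make_cond(base))
  shifted <- base
  shifted[, 2, , ] <- shifted[, 2, , ] + 5
  sc1 <- pointwise_rm_anova(make_cond(shifted))
  expect_true(all(sc1$hand$f > sc0$hand$f))
  expect_equal(sc1$interaction$f, sc0$interaction$f, tolerance = 1e-9)
  expect_equal(sc1$side$f, sc0$side$f, tolerance = 1e-9)
})

test_that("participants with missing cells are dropped before scanning", {
  set.seed(4)
  arr <- array(rnorm(4 * 2 * 3 * 3), c(4, 2, 3, 3))
  arr[2, 1, 3, ] <- NA
  expect_message(sc <- pointwise_rm_anova(make_cond(arr)), "dropping 1")
  expect_equal(sc$hand$n, 3L)
  arr[3, 1, 1, ] <- NA
  expect_error(suppressMessages(pointwise_rm_anova(make_cond(arr))),
               "insufficient")
})

test_that("TFCE equals brute-force threshold integration", {
  expect_equal(tfce(numeric(50)), numeric(50))

  f <- c(rep(0, 3), rep(2, 5), rep(0, 2))  # rectangular bump
  expect_equal(tfce(f, dh = 0.01), brute_tfce(f, dh = 0.01),
               tolerance = 1e-9)

  set.seed(11)
  g <- round(runif(40, 0, 4), 2)
  expect_equal(tfce(g, E = 0.5, H = 2, dh = 0.05),
               brute_tfce(g, 0.5, 2, 0.05), tolerance = 1e-9)

  # monotone in height: doubling the bump raises interior enhancement
  e1 <- tfce(f, dh = 0.01)
  e2 <- tfce(2 * f, dh = 0.01)
  inside <- f > 0
  expect_true(all(e2[inside] > e1[inside]))
  expect_error(tfce(c(1, NA, 2)), "non-finite")
})

test_that("TFCE enhancement is monotone under pointwise domination", {
  set.seed(12)
  for (r in 1:20) {
    a <- runif(30, 0, 3)
    b <- a + runif(30, 0, 1)
    dh <- max(b) / 100
    expect_true(all(tfce(b, dh = dh) - tfce(a, dh = dh) > -1e-12))
  }
})

test_that("the generic permutation engine reproduces exact enumeration on a paired toy", {
  # 3 participants x 2 conditions x 3 timepoints; free relabeling within
  # participant = condition swap, so the null has exactly 2^3 = 8 states
  set.seed(7)
  x <- array(rnorm(3 * 2 * 3), c(3, 2, 3))
  stat <- function(a) abs(colMeans(a[, 1, ] - a[, 2, ]))
  obs <- max(stat(x))
  swaps <- expand.grid(c(FALSE, TRUE), c(FALSE, TRUE), c(FALSE, TRUE))
  exact_max <- apply(swaps, 1, function(sw) {
    xp <- x
    for (i in 1:3) if (sw[i]) xp[i, , ] <- x[i, 2:1, ]
    max(stat(xp))
  })
  p_exact <- mean(exact_max >= obs - 1e-12)
  pm <- perm_max_null(x, n_perm = 4000, seed = 99, statistic = stat)
  p_mc <- (1 + sum(pm$null_max >= obs - 1e-12)) / (1 + 4000)
  expect_lt(abs(p_mc - p_exact), 0.02)
})

test_that("exchangeable degenerate data give p = 1 everywhere", {
  tracep <- sin(seq(0, 3, length.out = 20))
  arr <- array(0, c(4, 2, 3, 20))
  for (i in 1:4) for (j in 1:2) for (k in 1:3) arr[i, j, k, ] <- tracep * i
  pn <- permutation_null(make_cond(arr), "interaction", n_perm = 50,
                         seed = 2)
  w <- scan_significance(pn)
  expect_true(all(attr(w, "p_values") == 1))
  expect_equal(nrow(w), 0L)
})

test_that("the add-one p estimator and window segmentation are exact", {
  pn <- structure(list(effect = "interaction",
                       f = rep(1, 10),
                       enhanced = c(0, 0, 9, 9, 9, 0, 0, 9, 0, 0),
                       null_max = seq_len(4999) / 1000,  # all below 9
                       n_perm = 4999L, seed = 1L, times = 0:9,
                       params = list(E = .5, H = 2, dh = .01)),
                  class = "gf_permnull")
  w <- scan_significance(pn, alpha = 0.05)
  p <- attr(w, "p_values")
  expect_equal(p[3], 1 / 5000)
  expect_equal(p[1], 1)
  sig <- w[w$alpha_level == "significant", ]
  expect_equal(sig$start_ms, c(2, 7))
  expect_equal(sig$end_ms, c(5, 8))  # half-open, maximal runs
  expect_equal(sig$min_p, rep(1 / 5000, 2))

  # observed below every null draw -> p = 1, no windows
  pn$enhanced <- rep(0.0001, 10)
  w2 <- scan_significance(pn)
  expect_true(all(attr(w2, "p_values") == 1))
  expect_equal(nrow(w2), 0L)
})

test_that("permutation nulls are deterministic given the seed", {
  cond <- null_cond(5, 30, seed = 13)
  a <- permutation_null(cond, "interaction", n_perm = 40, seed = 17)
  b <- permutation_null(cond, "interaction", n_perm = 40, seed = 17)
  expect_identical(a$null_max, b$null_max)
  c2 <- permutation_null(cond, "interaction", n_perm = 40, seed = 18)
  expect_false(identical(a$null_max, c2$null_max))
})

test_that("compiled and hand-written F scans agree", {
  set.seed(19)
  arr <- array(rnorm(5 * 2 * 3 * 6), c(5, 2, 3, 6))
  sc <- pointwise_rm_anova(make_cond(arr))
  expect_equal(sc$hand$f, r_fscan(arr, "hand"), tolerance = 1e-9)
  expect_equal(sc$side$f, r_fscan(arr, "side"), tolerance = 1e-9)
  expect_equal(sc$interaction$f, r_fscan(arr, "interaction"),
               tolerance = 1e-9)
})

test_that("max-F decisions are invariant to a common reordering of time", {
  # with the plain max statistic (no contiguity enhancement), permuting the
  # time axis identically in observed data and null leaves the decision
  # unchanged
  set.seed(21)
  x <- array(rnorm(5 * 6 * 10), c(5, 6, 10))
  stat <- function(a) r_fscan(array(a, c(dim(a)[1], 2, 3, dim(a)[3])),
                              "interaction")
  ord <- sample(10)
  a <- perm_max_null(x, n_perm = 40, seed = 5, statistic = stat)
  b <- perm_max_null(x[, , ord, drop = FALSE], n_perm = 40, seed = 5,
                     statistic = stat)
  expect_equal(max(a$observed), max(b$observed), tolerance = 1e-9)
  expect_equal(a$null_max, b$null_max, tolerance = 1e-9)
})

test_that("an injected interaction is found where it was injected", {
  # direct condition-average construction: interaction confined to 30-60
  set.seed(30)
  n <- 14; T_ <- 100
  arr <- array(0, c(n, 2, 3, T_))
  win <- 31:60
  for (i in seq_len(n)) {
    for (j in 1:2) for (k in 1:3) {
      arr[i, j, k, ] <- lowpass_filter(rnorm(T_, sd = 2), 1000, 15, 4)
      hsign <- if (j == 2) 1 else -1
      arr[i, j, k, win] <- arr[i, j, k, win] + hsign * (k - 2) * 4
    }
  }
  w <- cluster_scan(make_cond(arr), "interaction", n_perm = 200, seed = 3)
  sig <- w[w$alpha_level == "significant", ]
  expect_gt(nrow(sig), 0)
  expect_true(any(sig$start_ms < 60 & sig$end_ms > 30))
})
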