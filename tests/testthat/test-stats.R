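test_that("mann_whitney_w uses the pair-counting convention", {
  expect_equal(mann_whitney_w(c(1, 2), c(5, 6, 7))$W, 0)     # x below y
  expect_equal(mann_whitney_w(c(1, 2, 3), c(1, 2, 3))$W, 4.5)  # n^2 / 2
  # brute force over all pairs, ties counted half
  brute <- function(x, y) {
    sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  expect_equal(mann_whitney_w(c(1, 2, 5), c(3, 4))$W, brute(c(1, 2, 5), c(3, 4)))
  set.seed(42)
  for (k in 1:10) {
    x <- sample(1:8, 6, replace = TRUE)
    y <- sample(1:8, 5, replace = TRUE)
    expect_equal(mann_whitney_w(x, y)$W, brute(x, y))
    # convention check: the two orientations sum to nx * ny
    expect_equal(mann_whitney_w(x, y)$W + mann_whitney_w(y, x)$W, 30)
    # p agrees with the tie-corrected normal approximation in wilcox.test
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = FALSE))
    expect_equal(mann_whitney_w(x, y)$p, ref$p.value, tolerance = 1e-10)
  }
  expect_warning(out <- mann_whitney_w(c(1, 1), c(1, 1)), "constant")
  expect_true(is.na(out$p))
})

test_that("chi2_2x2 is the uncorrected Pearson statistic", {
  expect_equal(round(chi2_2x2(rbind(c(9, 16), c(8, 17))), 3), 0.089)
  tab <- rbind(c(10, 20), c(5, 10))    # equal to its expected counts
  expect_equal(chi2_2x2(tab), 0)
  expect_equal(chi2_2x2(rbind(c(10, 0), c(0, 10))), 20)
  # invariant to transposition and to row/column swaps
  t1 <- rbind(c(3, 7), c(9, 2))
  expect_equal(chi2_2x2(t1), chi2_2x2(t(t1)))
  expect_equal(chi2_2x2(t1), chi2_2x2(t1[2:1, ]))
  expect_equal(chi2_2x2(t1), chi2_2x2(t1[, 2:1]))
  expect_error(chi2_2x2(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("jzs_bf matches an independent effect-size-integral oracle", {
  # oracle: integrate the noncentral-t likelihood against the Cauchy prior
  # on the standardised effect (a different derivation from the g-mixture
  # used by the implementation)
  oracle_bf10 <- function(t, n1, n2, scale = 0.5) {
    df <- n1 + n2 - 2
    neff <- sqrt(n1 * n2 / (n1 + n2))
    marg <- suppressWarnings(stats::integrate(function(delta) {
      stats::dt(t, df, ncp = delta * neff) * stats::dcauchy(delta, 0, scale)
    }, -Inf, Inf, rel.tol = 1e-9)$value)
    marg / stats::dt(t, df)
  }
  set.seed(7)
  for (k in 1:10) {
    x <- rnorm(12, 0, 1); y <- rnorm(15, k / 10, 1.3)
    got <- jzs_bf(x, y)
    expect_equal(got$BF10, oracle_bf10(got$t, 12, 15),
                 tolerance = 1e-4)
    expect_equal(got$BF10 * got$BF01, 1)
  }
  # identical samples: t = 0, the null is favoured
  x <- c(1, 2, 3, 4)
  expect_lt(jzs_bf(x, x + 0)$BF10, 1)
  # BF10 increases with |t| at fixed n (checked over a t grid)
  bfs <- vapply(seq(0, 4, by = 0.5), function(t) {
    bgschema:::jzs_bf10_from_t(t, 20, 20)
  }, numeric(1L))
  expect_true(all(diff(bfs) > 0))
})

test_that("anova2_logrt partitions sums of squares correctly", {
  # brute-force SS decomposition on a small constructed set
  d <- data.frame(
    participant = rep(1:4, each = 2),
    group = rep(c("y", "y", "o", "o"), each = 2),
    feedback = rep(c("pos", "neg"), 4),
    rt = c(100, 120, 104, 128, 150, 190, 160, 186))
  out <- anova2_logrt(d, log_transform = FALSE)
  ssq <- attr(out, "ss_error")
  # total SS equals effects + subject + residual
  expect_equal(sum(out$SS) + ssq[["subject"]] + ssq[["residual"]],
               ssq[["total"]])
  # oracle: aov with an error stratum
  ref <- summary(stats::aov(rt ~ group * feedback + Error(factor(participant)),
                            data = d))
  ref_between <- ref[["Error: factor(participant)"]][[1]]
  ref_within <- ref[["Error: Within"]][[1]]
  expect_equal(out$F[out$effect == "group"], ref_between["group", "F value"],
               tolerance = 1e-8)
  expect_equal(out$F[out$effect == "feedback"],
               ref_within["feedback", "F value"], tolerance = 1e-8)
  expect_equal(out$F[out$effect == "group:feedback"],
               ref_within["group:feedback", "F value"], tolerance = 1e-8)

  # identical group and condition means: all F ~ 0
  flat <- data.frame(participant = rep(1:4, each = 2),
                     group = rep(c("y", "o"), each = 4),
                     feedback = rep(c("pos", "neg"), 4),
                     rt = rep(100, 8))
  expect_error(anova2_logrt(flat), NA)
  # additive construction: no interaction
  add <- data.frame(
    participant = rep(1:6, each = 2),
    group = rep(c("y", "o"), each = 6),
    feedback = rep(c("pos", "neg"), 6),
    rt = 100 + 20 * rep(c(0, 1), 6) + 50 * rep(c(0, 0, 0, 1, 1, 1), each = 2))
  out_add <- anova2_logrt(add, log_transform = FALSE)
  expect_lt(out_add$SS[out_add$effect == "group:feedback"], 1e-20)
})

test_that("pearson_partial equals the residual-regression oracle", {
  set.seed(3)
  c0 <- rnorm(30)
  x <- 0.5 * c0 + rnorm(30)
  y <- 0.7 * x + 0.3 * c0 + rnorm(30)
  got <- pearson_partial(x, y, c0)
  expect_equal(got$r, cor(x, y))
  rx <- residuals(lm(x ~ c0)); ry <- residuals(lm(y ~ c0))
  expect_equal(got$r_partial, cor(rx, ry), tolerance = 1e-12)
  # degenerate/limiting cases
  expect_equal(pearson_partial(x, x, c0)$r, 1)
  ind <- rnorm(30)
  pp <- pearson_partial(x, y, ind)
  expect_lt(abs(pp$r_partial - pp$r), 0.15)
})

test_that("the normative regression evaluates as published", {
  expect_equal(normative_te(65, 14), 17.71)
  expect_equal(normative_te(85, 14), 22.31)
  expect_equal(normative_te(0, 0), 6.12)
})
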