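test_that("the logistic saturation function behaves per definition", {
  expect_equal(logistic(0.5, 10, 0.5), 0.5)          # symmetry at threshold
  expect_equal(logistic(c(-3, 0, 7), 0, 0.5), rep(0.5, 3))  # zero gain
  expect_equal(logistic(0.7, 10, 0.5), 1 / (1 + exp(-2)), tolerance = 1e-12)
  # overflow-safe at extreme arguments
  expect_equal(logistic(1e6, 100, 0), 1)
  expect_equal(logistic(-1e6, 100, 0), 0)
})

test_that("schema feedback follows the matching/mismatching rule", {
  expect_equal(schema_feedback(TRUE, 0.5, 0.5, -1, 1), 1)
  expect_equal(schema_feedback(FALSE, 0, 0), -1)     # zero-parameter baseline
  expect_equal(schema_feedback(FALSE, 0.048, 0.165, f_prev = -1, r_prev = 1),
               2 * 0.048 - 1 - 0.165 * (-1) * 1)     # = -0.739
  expect_equal(schema_feedback(FALSE, 0.048, 0.165, -1, 1), -0.739)
  # vectorised over schemas
  expect_equal(schema_feedback(c(TRUE, FALSE), 0.2, 0, 0, 1), c(1, -0.6))
})

test_that("prediction error is reward times feedback-minus-activation", {
  expect_equal(prediction_error(1, 1, 1), 0)
  expect_equal(prediction_error(-1, -1, 0), 1)
  expect_equal(prediction_error(1, 1, 0.4), 0.6)
})

test_that("striatal threshold updates move against delta and clip to [0,1]", {
  expect_equal(update_striatum(0.4, 0, 0.5), 0.4)                # no error
  out <- update_striatum(0.05, 1, 0.139)
  expect_gte(out, 0)
  expect_lt(out, 0.05)
  expect_equal(update_striatum(0.99, -0.5, 0.1), 1)              # clipped
  expect_equal(update_striatum(0.5, 1, 0.2, zeta = 0.5), 0.5 - 0.2 * 1.5)
  # repeated negative feedback to a selected (matching) schema strictly
  # increases its threshold: the anti-perseveration mechanism
  beta <- 0.2
  for (k in 1:5) {
    f <- schema_feedback(TRUE, 0.3, 0)
    d <- prediction_error(-1, f, a_i = 0.8)
    new <- update_striatum(beta, d, 0.15)
    expect_gt(new, beta)
    beta <- new
  }
})

test_that("conflict-driven gain is monotone and degenerates at eps_sma 0", {
  g0 <- update_gain(c(0.2, 0.9), 0, 4.5)
  expect_equal(g0, 1 + 4.5)                  # product collapses to 1
  # increasing any output never decreases the gain
  expect_gte(update_gain(c(0.9, 0.9), 0.5, 4.5),
             update_gain(c(0.9, 0.2), 0.5, 4.5))
  expect_gt(update_gain(c(0.8, 0.8), 0.6, 4.5),
            update_gain(c(0.8, 0.1), 0.6, 4.5))
  # the literal printed parenthesisation is available behind the flag
  lit <- update_gain(c(0.5, 0.5), 0, 4.5, literal = TRUE)
  expect_equal(lit, 1 + 4.5 * (1.5)^2)
})

test_that("loop sets preserve symmetry and select under asymmetric drive", {
  p <- model_params()
  e <- p$cog_input
  run_set <- function(S, input, beta, cycles = 600) {
    for (k in seq_len(cycles)) S <- step_loops(S, input, p, beta_str = beta)
    S
  }
  # identical inputs, identical thresholds, no noise: perfect symmetry
  S <- run_set(new_loop_state(3), rep(e, 3), rep(0.5, 3))
  expect_true(all(S >= 0 & S <= 1))
  expect_equal(S["CTX", 1], S["CTX", 2])
  expect_equal(S["CTX", 2], S["CTX", 3])

  # sustained input advantage: exactly one schema dominates
  S <- run_set(new_loop_state(3), c(e + 0.15, e, e), rep(0.3, 3), 800)
  expect_gt(S["CTX", 1], 0.65)
  expect_lt(max(S["CTX", 2:3]), 0.3)

  # a threshold advantage also selects
  S <- run_set(new_loop_state(3), rep(e, 3), c(0.05, 0.6, 0.6), 800)
  expect_gt(S["CTX", 1], 0.65)
  expect_lt(max(S["CTX", 2:3]), 0.3)

  # raising the dominant schema's threshold reduces its activation and,
  # raised far enough, hands control to a competitor
  a_before <- S["CTX", 1]
  S2 <- run_set(S, rep(e, 3), c(0.45, 0.6, 0.6), 800)
  expect_lt(S2["CTX", 1], a_before)
  set.seed(11)
  S3 <- S
  for (k in 1:1000) {
    S3 <- step_loops(S3, rep(e, 3) + runif(3, -0.05, 0.05), p,
                     beta_str = c(0.95, 0.1, 0.6))
  }
  expect_lt(S3["CTX", 1], 0.3)
  expect_gt(S3["CTX", 2], 0.5)
  expect_gt(S3["CTX", 2], max(S3["CTX", c(1, 3)]))
})

test_that("select_and_respond is seeded-deterministic and respects k_sel", {
  p <- model_params()
  cog <- new_loop_state(3); sma <- new_loop_state(4)
  sma_in <- c(0.6, 0, 0, 0)
  go <- function() {
    select_and_respond(cog, sma, rep(0.5, 3), rep(p$cog_input, 3), sma_in,
                       td_map = c(1, 2, 3), alpha_sma = 6, params = p)
  }
  set.seed(5); r1 <- go()
  set.seed(5); r2 <- go()
  expect_identical(r1, r2)
  expect_equal(r1$response, 1L)        # the strongly driven candidate wins
  expect_gte(r1$cycles, p$k_sel)
  expect_true(all(r1$a_med >= 0 & r1$a_med <= 1))
})

test_that("sessions have the right shape and are reproducible", {
  p <- model_params()
  lw1 <- run_session(wcst_task(), p, seed = 21)
  lw2 <- run_session(wcst_task(), p, seed = 21)
  expect_identical(lw1, lw2)
  expect_equal(nrow(lw1), 64L)
  expect_true(all(lw1$response %in% 1:4))
  expect_true(all(lw1$feedback %in% c(-1L, 1L)))
  expect_true(all(attr(lw1, "beta_final") >= 0 & attr(lw1, "beta_final") <= 1))

  lb <- run_session(brxt_task(), p, seed = 22)
  expect_equal(nrow(lb), 50L)
  expect_true(all(lb$response %in% 1:9))
  expect_true(all(as.integer(lb$stimulus) %in% 1:9))
  expect_identical(lb, run_session(brxt_task(), p, seed = 22))
})

test_that("run_group summarises n runs with in-range means", {
  p <- model_params(w_neg = 0.1, eps_str = 0.45, eps_sma = 0.8)
  g <- run_group(wcst_task(), p, n = 5, seed = 99)
  expect_equal(nrow(g$scores), 5L)
  s <- g$summary
  expect_setequal(s$measure, c("TE", "PE", "SL3", "CA"))
  expect_true(all(s$mean >= 0))
  expect_lte(s$mean[s$measure == "TE"], 64)
  expect_lte(s$mean[s$measure == "CA"], 10)
  expect_true(all(is.finite(g$rt)))
})

test_that("the older parameterisation responds more slowly (directional)", {
  # reported fitted values: younger (0.457, 0, 0.139, 0.833) vs older
  # (0.106, 0, 0.097, 0.000); the ordering, not absolute counts, is the
  # reproduction target
  py <- model_params(w_neg = 0.457, m_r = 0, eps_str = 0.139, eps_sma = 0.833)
  po <- model_params(w_neg = 0.106, m_r = 0, eps_str = 0.097, eps_sma = 0)
  gy <- run_group(wcst_task(), py, n = 8, seed = 7)
  go <- run_group(wcst_task(), po, n = 8, seed = 8)
  expect_gt(mean(go$scores$rt_pos + go$scores$rt_neg),
            mean(gy$scores$rt_pos + gy$scores$rt_neg))
})
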