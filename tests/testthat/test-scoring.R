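test_that("an always-wrong responder scores TE = 64 and a perfect one 0", {
  wrong <- scripted_wcst_log(function(card, env) {
    correct <- which(wcst_targets()[[env$active_rule]] == card[[env$active_rule]])
    (correct %% 4) + 1  # any pile other than the correct one
  })
  expect_equal(score_wcst(wrong)$TE, 64L)

  perfect <- scripted_wcst_log(function(card, env) {
    which(wcst_targets()[[env$active_rule]] == card[[env$active_rule]])
  })
  sc <- score_wcst(perfect)
  expect_equal(sc$TE, 0L)
  expect_equal(sc$PE, 0L)
  expect_equal(sc$SL3, 0L)
  expect_equal(sc$CA, 10L)
})

test_that("SL3 is an error after an established set, without a rule change", {
  # three correct unambiguous color sorts, then an error matching no
  # earlier principle: SL3 = 1, PE = 0 (no rule change has occurred)
  log <- manual_wcst_log(
    stimulus = c("2|red|star", "3|red|circle", "2|red|circle", "1|green|star"),
    response = c(1, 1, 1, 4),        # pile 1 = red; final response blue pile
    feedback = c(1, 1, 1, -1),
    active_rule = rep("color", 4))
  sc <- score_wcst(log)
  expect_equal(sc$SL3, 1L)
  expect_equal(sc$PE, 0L)
  expect_equal(attr(sc, "labels"), c("correct", "correct", "correct", "SL3"))
})

test_that("errors matching the pre-switch rule are perseverative", {
  # six correct color sorts complete a category; the rule becomes shape
  # and two further color-matching errors follow
  stim <- c("2|red|star", "3|red|circle", "2|red|circle",
            "4|red|star", "3|red|star", "2|red|cross",
            "2|green|cross", "3|blue|star")
  log <- manual_wcst_log(
    stimulus = stim,
    response = c(rep(1, 6), 2, 4),   # pile 2 = green, pile 4 = blue
    feedback = c(rep(1, 6), -1, -1),
    active_rule = c(rep("color", 6), "shape", "shape"))
  sc <- score_wcst(log)
  expect_equal(sc$CA, 1L)
  expect_equal(sc$PE, 2L)
  expect_equal(sc$SL3, 0L)
  expect_equal(sc$TE, 2L)
})

test_that("PE and SL3 are mutually exclusive on agent-generated logs", {
  for (seed in 1:8) {
    log <- gen_agent_session(wcst_task(), default_profiles()$older,
                             seed = 400 + seed)
    sc <- score_wcst(log)
    lab <- attr(sc, "labels")
    expect_length(lab, 64L)
    # labels partition the trials: no trial is both PE and SL3 by
    # construction, and counts match labels
    expect_equal(sc$PE, sum(lab == "PE"))
    expect_equal(sc$SL3, sum(lab == "SL3"))
    expect_equal(sc$TE, sum(lab != "correct"))
    expect_lte(sc$PE + sc$SL3, sc$TE)
    expect_lte(sc$CA, 10L)
  }
})

test_that("adding an error trial never decreases TE and scoring is pure", {
  log <- gen_agent_session(wcst_task(), default_profiles()$younger, seed = 77)
  base <- score_wcst(log)
  again <- score_wcst(log)
  expect_identical(unclass(base)[c("TE", "PE", "SL3", "CA")],
                   unclass(again)[c("TE", "PE", "SL3", "CA")])
  extra <- log[1:40, ]
  # flip a correct trial to an error (wrong pile, negative feedback)
  i <- which(extra$feedback == 1L)[1]
  extra$feedback[i] <- -1L
  extra$response[i] <- (extra$response[i] %% 4) + 1
  expect_gte(score_wcst(extra)$TE, score_wcst(log[1:40, ])$TE)
})

test_that("the omniscient zero-propensity agent commits no errors", {
  pr <- agent_profile(lapse_prob = 0, persev_prob = 0, stim_pull = 0,
                      resp_pull = 0)
  sw <- score_wcst(gen_agent_session(wcst_task(), pr, seed = 1,
                                     omniscient = TRUE))
  sb <- score_brxt(gen_agent_session(brxt_task(), pr, seed = 2,
                                     omniscient = TRUE))
  expect_equal(sw$TE, 0L)
  expect_equal(sb$TE, 0L)
  expect_equal(sb$PSTIM + sb$PRESP + sb$PRULE, 0L)
})

test_that("BRXT scoring implements the three perseveration taxonomies", {
  # always tapping the currently filled disk: every error is a PSTIM
  echo <- scripted_brxt_log(function(stim, target) stim)
  sc <- score_brxt(echo)
  expect_equal(sc$PSTIM, sc$TE)
  expect_gt(sc$TE, 0L)

  # always wrong: TE = 50
  wrong <- scripted_brxt_log(function(stim, target) (target %% 9) + 1)
  expect_equal(score_brxt(wrong)$TE, 50L)

  # first trial after a rule change, responding per the old rule -> PRULE
  log <- scripted_brxt_log(function(stim, target) brxt_next_target("cw", stim),
                           rules = c("cw", "ccw", "walk15", "ccw_skip", "cw"))
  sc <- score_brxt(log)
  expect_gte(sc$PRULE, 1L)  # trial 11 follows cw although ccw is active

  # out-of-disk sentinel responses count toward TE only
  sentinel <- scripted_brxt_log(function(stim, target) 0L)
  sc0 <- score_brxt(sentinel)
  expect_equal(sc0$TE, 50L)
  expect_equal(sc0$PSTIM + sc0$PRESP + sc0$PRULE, 0L)

  # a PRESP error can simultaneously be a PSTIM error: repeating a tap
  # that has just become the filled disk
  log2 <- data.frame(participant_id = 1L, task = "brxt", trial = 1:3,
                     stimulus = c("1", "2", "2"), response = c(2, 2, 9),
                     correct = c(2, 3, 4), feedback = c(1, -1, -1),
                     active_rule = "cw", rt = 100, stringsAsFactors = FALSE)
  sc2 <- score_brxt(log2)
  expect_equal(sc2$PSTIM, 1L)
  expect_equal(sc2$PRESP, 1L)
})

test_that("rt_by_prior_feedback stratifies by the previous trial", {
  log <- data.frame(feedback = c(1, -1, 1, 1, -1, 1),
                    rt = c(90, 100, 120, 100, 100, 120))
  out <- rt_by_prior_feedback(log)
  # trials 2..6 have priors (1,-1,1,1,-1): rt after positive = (100,100,100),
  # after negative = (120,120)
  expect_equal(out[["after_positive"]], 100)
  expect_equal(out[["after_negative"]], 120)

  # brute-force per-trial partition oracle on an agent log
  al <- gen_agent_session(wcst_task(), default_profiles()$younger, seed = 9)
  got <- rt_by_prior_feedback(al)
  pos <- neg <- c()
  for (t in 2:nrow(al)) {
    if (al$feedback[t - 1] == 1) pos <- c(pos, al$rt[t]) else neg <- c(neg, al$rt[t])
  }
  expect_equal(got[["after_positive"]], mean(pos))
  expect_equal(got[["after_negative"]], mean(neg))

  # constant RT log: both means equal the constant
  cl <- data.frame(feedback = c(1, -1, 1), rt = c(5, 5, 5))
  expect_equal(unname(rt_by_prior_feedback(cl)), c(5, 5))
})
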