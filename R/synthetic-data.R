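# Synthetic participants: a stochastic rule-following agent that is
# deliberately NOT the dynamical model, so that scoring and statistics can
# be validated against an independent generative process.

#' Synthetic agent behavioural profile
#'
#' Tunable propensities of the stochastic task-playing agent:
#' * `lapse_prob` -- probability of abandoning the believed rule despite
#'   positive feedback (drives set-loss-type errors).
#' * `persev_prob` -- probability of retaining the believed rule after
#'   negative feedback (drives PE / PRULE).
#' * `stim_pull` -- probability of echoing the current stimulus (drives
#'   PSTIM; on the WCST, of choosing the pile with most matching
#'   features).
#' * `resp_pull` -- probability of repeating the previous response
#'   (drives PRESP).
#' * `induce_prob` -- probability that, when switching after negative
#'   feedback, the agent picks a rule consistent with the recent evidence
#'   (the last stimulus transition on the BRXT; an untried dimension on
#'   the WCST) rather than a uniformly random alternative.
#' * `rt_base`, `rt_error_penalty`, `rt_noise` -- RT generator (ms):
#'   baseline, additive slowing after negative feedback, Gaussian noise
#'   SD.
#' * `age_mean`, `age_sd`, `age_range`, `p_male` -- demographic samplers.
#'
#' @param lapse_prob,persev_prob,stim_pull,resp_pull,induce_prob
#'   Probabilities in `[0, 1]`.
#' @param rt_base,rt_error_penalty,rt_noise RT parameters (`rt_base > 0`).
#' @param age_mean,age_sd,age_range,p_male Demographics.
#' @return A list of class `agent_profile`.
#' @export
agent_profile <- function(lapse_prob = 0.02, persev_prob = 0.5,
                          stim_pull = 0.02, resp_pull = 0.02,
                          induce_prob = 0.8,
                          rt_base = 1500, rt_error_penalty = 400,
                          rt_noise = 150,
                          age_mean = 27.1, age_sd = 9.1,
                          age_range = c(19, 53), p_male = 9 / 25) {
  probs <- c(lapse_prob, persev_prob, stim_pull, resp_pull, induce_prob,
             p_male)
  stopifnot(all(probs >= 0 & probs <= 1), rt_base > 0)
  structure(list(
    lapse_prob = lapse_prob, persev_prob = persev_prob,
    stim_pull = stim_pull, resp_pull = resp_pull, induce_prob = induce_prob,
    rt_base = rt_base, rt_error_penalty = rt_error_penalty,
    rt_noise = rt_noise, age_mean = age_mean, age_sd = age_sd,
    age_range = age_range, p_male = p_male
  ), class = "agent_profile")
}

#' Default group profiles calibrated to the published group means
#'
#' Calibrated once by coarse grid search so that cohort-level score means
#' fall within one SD of the published younger/older tables (older: more
#' lapses and poorer rule induction, equal perseveration propensity;
#' slower overall and after negative feedback).  Demographic samplers
#' follow the published margins (gender 9/16 vs 8/17; ages ~N(27.1, 9.1)
#' truncated 19-53 and ~N(70.8, 6.4) truncated 62-84).
#'
#' @return Named list with `younger` and `older` [agent_profile()]s.
#' @export
default_profiles <- function() {
  list(
    younger = agent_profile(
      lapse_prob = 0.006, persev_prob = 0.45, stim_pull = 0.005,
      resp_pull = 0.012, induce_prob = 0.96,
      rt_base = 1450, rt_error_penalty = 350, rt_noise = 140,
      age_mean = 27.1, age_sd = 9.1, age_range = c(19, 53),
      p_male = 9 / 25),
    older = agent_profile(
      lapse_prob = 0.025, persev_prob = 0.55, stim_pull = 0.002,
      resp_pull = 0.016, induce_prob = 0.90,
      rt_base = 2100, rt_error_penalty = 520, rt_noise = 180,
      age_mean = 70.8, age_sd = 6.4, age_range = c(62, 84),
      p_male = 8 / 25)
  )
}

.rtruncnorm1 <- function(mean, sd, lo, hi) {
  repeat {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

.agent_rt <- function(profile, prev_fb) {
  max(100, profile$rt_base +
        profile$rt_error_penalty * (prev_fb == -1) +
        rnorm(1, 0, profile$rt_noise))
}

#' Generate one synthetic-agent session
#'
#' Plays the task with a stochastic rule-following policy (see
#' [agent_profile()]).  Response overrides are checked in the order
#' stimulus pull, response pull, rule-based response; rule maintenance is
#' updated from feedback after every trial.
#'
#' @param task A [wcst_task()] or [brxt_task()] descriptor.
#' @param profile An [agent_profile()].
#' @param seed Integer seed (fully determines the session).
#' @param participant_id Identifier recorded in the log.
#' @param omniscient If TRUE the agent always knows the active rule (or
#'   target) -- a perfect responder, useful as a scoring fixture.
#' @param initial_rule Optional believed rule at session start (default:
#'   drawn at random).
#' @return A session log data frame in the shared dialect.
#' @export
gen_agent_session <- function(task, profile, seed = 1L,
                              participant_id = 1L, omniscient = FALSE,
                              initial_rule = NULL) {
  stopifnot(inherits(task, "bg_task"), inherits(profile, "agent_profile"))
  if (!is.null(seed)) set.seed(seed)
  if (task$name == "wcst") {
    .agent_wcst(task, profile, participant_id, omniscient, initial_rule)
  } else {
    .agent_brxt(task, profile, participant_id, omniscient, initial_rule)
  }
}

.agent_wcst <- function(task, profile, participant_id,
                        omniscient = FALSE, initial_rule = NULL) {
  deck <- build_wcst_deck()
  deck <- deck[sample.int(64L), , drop = FALSE]
  env <- wcst_new_state(task$rule_sequence)
  dims <- .wcst_dims
  believed <- if (!is.null(initial_rule)) initial_rule else sample(dims, 1L)
  tried <- believed            # dimensions tried since last positive run
  habit <- NA_character_       # last rule abandoned after a success run
  streak <- 0L                 # successes under the current believed rule
  prev_resp <- NA_integer_
  prev_fb <- 1L
  rows <- vector("list", 64L)

  for (t in seq_len(64L)) {
    card <- as.list(deck[t, ])
    if (omniscient) believed <- env$active_rule
    u <- runif(1)
    if (u < profile$stim_pull) {
      nm <- vapply(1:4, function(j) length(wcst_match_dims(card, j)),
                   integer(1L))
      best <- which(nm == max(nm))
      resp <- if (length(best) > 1L) sample(best, 1L) else best
    } else if (u < profile$stim_pull + profile$resp_pull &&
               !is.na(prev_resp)) {
      resp <- prev_resp
    } else {
      if (prev_fb == 1L && runif(1) < profile$lapse_prob) {
        # attentional slips gravitate back to the old habitual rule;
        # perseveration then tends to keep the agent there, which couples
        # set-loss and perseverative error counts as observed empirically
        believed <- if (!is.na(habit) && habit != believed &&
                        runif(1) < 0.6) habit
          else sample(setdiff(dims, believed), 1L)
        tried <- believed
        streak <- 0L
      }
      resp <- wcst_pile_for(card, believed)
    }

    active_rule <- env$active_rule
    correct_pile <- wcst_pile_for(card, active_rule)
    step <- wcst_step(env, card, resp)
    env <- step$state
    fb <- step$feedback

    if (fb == -1L && runif(1) >= profile$persev_prob) {
      # switch: prefer an untried dimension, else any other
      if (streak >= 2L) habit <- believed
      cand <- setdiff(dims, tried)
      if (length(cand) == 0L || runif(1) >= profile$induce_prob) {
        cand <- setdiff(dims, believed)
      }
      believed <- if (length(cand) > 1L) sample(cand, 1L) else cand
      tried <- union(tried, believed)
      streak <- 0L
    } else if (fb == 1L) {
      tried <- believed
      streak <- streak + 1L
    } else {
      streak <- 0L
    }

    rows[[t]] <- data.frame(
      participant_id = participant_id, task = "wcst", trial = t,
      stimulus = wcst_card_label(card), response = resp,
      correct = correct_pile, feedback = fb, active_rule = active_rule,
      rt = round(.agent_rt(profile, prev_fb), 1),
      stringsAsFactors = FALSE
    )
    prev_resp <- resp
    prev_fb <- fb
  }
  do.call(rbind, rows)
}

.agent_brxt <- function(task, profile, participant_id,
                        omniscient = FALSE, initial_rule = NULL) {
  rules <- vapply(task$rules, function(r) {
    if (identical(r, "random")) sample(brxt_rules(), 1L) else r
  }, character(1L), USE.NAMES = FALSE)
  spec <- build_brxt_sequence(rules, start_pos = task$start_pos, seed = NULL)
  known <- brxt_rules()
  believed <- if (!is.null(initial_rule)) initial_rule else sample(known, 1L)
  stim <- spec$start_pos
  prev_stim <- NA_integer_
  prev_resp <- NA_integer_
  prev_fb <- 1L
  rows <- vector("list", 50L)

  for (t in seq_len(50L)) {
    target <- spec$target_sequence[[t]]
    # rule maintenance happens after seeing the new filled disk, so the
    # induction evidence is the transition that just played out
    if (prev_fb == -1L) {
      persist_p <- profile$persev_prob * (1 - profile$induce_prob)
      if (runif(1) >= persist_p) {
        consistent <- if (!is.na(prev_stim)) {
          known[vapply(known, function(r) {
            brxt_next_target(r, prev_stim) == stim
          }, logical(1L))]
        } else character(0L)
        believed <- if (length(consistent) > 0L &&
                        runif(1) < profile$induce_prob) {
          if (length(consistent) > 1L) sample(consistent, 1L)
          else consistent
        } else {
          sample(setdiff(known, believed), 1L)
        }
      }
    } else if (runif(1) < profile$lapse_prob) {
      believed <- sample(setdiff(known, believed), 1L)
    }
    u <- runif(1)
    if (omniscient) {
      resp <- target
    } else if (u < profile$stim_pull) {
      resp <- stim
    } else if (u < profile$stim_pull + profile$resp_pull &&
               !is.na(prev_resp)) {
      resp <- prev_resp
    } else {
      resp <- brxt_next_target(believed, stim)
    }
    fb <- if (resp == target) 1L else -1L

    rows[[t]] <- data.frame(
      participant_id = participant_id, task = "brxt", trial = t,
      stimulus = as.character(stim), response = resp, correct = target,
      feedback = fb, active_rule = brxt_rule_at(spec, t),
      rt = round(.agent_rt(profile, prev_fb), 1),
      stringsAsFactors = FALSE
    )
    prev_resp <- resp
    prev_fb <- fb
    prev_stim <- stim
    stim <- target
  }
  do.call(rbind, rows)
}

#' Generate a synthetic two-group cohort on both tasks
#'
#' Simulates both tasks for every synthetic participant and assembles a
#' cohort table (one row per participant: group, demographics, per-measure
#' scores, RT means by prior feedback per task) plus the underlying trial
#' logs.
#'
#' @param young_profile,old_profile [agent_profile()]s (defaults from
#'   [default_profiles()]).
#' @param n_per_group Participants per group.
#' @param seed Master seed.
#' @return List with `cohort` (data frame) and `logs` (named list of trial
#'   logs, `$wcst` and `$brxt`, each one element per participant).
#' @export
gen_cohort <- function(young_profile = default_profiles()$younger,
                       old_profile = default_profiles()$older,
                       n_per_group = 25L, seed = 1L) {
  stopifnot(n_per_group >= 2L)
  set.seed(seed)
  groups <- rep(c("younger", "older"), each = n_per_group)
  profiles <- list(younger = young_profile, older = old_profile)
  seeds <- matrix(sample.int(2^31 - 2L, 2L * 2L * n_per_group),
                  ncol = 2L)
  wcst <- wcst_task(); brxt <- brxt_task()

  rows <- vector("list", length(groups))
  logs <- list(wcst = vector("list", length(groups)),
               brxt = vector("list", length(groups)))
  for (i in seq_along(groups)) {
    pr <- profiles[[groups[[i]]]]
    age <- .rtruncnorm1(pr$age_mean, pr$age_sd, pr$age_range[[1L]],
                        pr$age_range[[2L]])
    gender <- if (runif(1) < pr$p_male) "m" else "f"
    lw <- gen_agent_session(wcst, pr, seed = seeds[i, 1L],
                            participant_id = i)
    lb <- gen_agent_session(brxt, pr, seed = seeds[i, 2L],
                            participant_id = i)
    sw <- score_wcst(lw); sb <- score_brxt(lb)
    rw <- rt_by_prior_feedback(lw); rb <- rt_by_prior_feedback(lb)
    logs$wcst[[i]] <- lw; logs$brxt[[i]] <- lb
    rows[[i]] <- data.frame(
      participant_id = i, group = groups[[i]], age = round(age, 1),
      gender = gender,
      wcst_TE = sw$TE, wcst_PE = sw$PE, wcst_SL3 = sw$SL3, wcst_CA = sw$CA,
      brxt_TE = sb$TE, brxt_PSTIM = sb$PSTIM, brxt_PRESP = sb$PRESP,
      brxt_PRULE = sb$PRULE,
      wcst_rt_pos = rw[["after_positive"]],
      wcst_rt_neg = rw[["after_negative"]],
      brxt_rt_pos = rb[["after_positive"]],
      brxt_rt_neg = rb[["after_negative"]],
      stringsAsFactors = FALSE
    )
  }
  list(cohort = do.call(rbind, rows), logs = logs)
}

.log_columns <- c("participant_id", "task", "trial", "stimulus", "response",
                  "correct", "feedback", "active_rule", "rt")

#' Write / read a trial log as CSV
#'
#' The shared dialect has header `participant_id, task, trial, stimulus,
#' response, correct, feedback, active_rule, rt`.  Round-trips are
#' lossless, including the out-of-disk sentinel response (`0`).
#'
#' @param trials Trial log data frame.
#' @param path File path.
#' @return `read_trial_log` returns the trial log data frame.
#' @export
write_trial_log <- function(trials, path) {
  if (nrow(trials) > 0L) stopifnot(all(.log_columns %in% names(trials)))
  df <- if (nrow(trials) > 0L) trials[, .log_columns] else
    as.data.frame(stats::setNames(rep(list(character(0L)),
                                      length(.log_columns)), .log_columns))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(stimulus = "character",
                                active_rule = "character",
                                task = "character"))
  bad <- which(!stats::complete.cases(df[, c("trial", "response", "feedback")]))
  if (length(bad) > 0L) {
    stop("malformed trial-log rows at lines: ",
         paste(bad + 1L, collapse = ", "))
  }
  df
}
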