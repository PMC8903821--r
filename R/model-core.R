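# The schema-selection model: competing cortico-striato-thalamic loops
# with reward-driven striatal threshold learning at the cognitive level
# and conflict-driven gain adaptation at the sensorimotor level.

#' Model parameters
#'
#' Bundles the four free parameters with the fixed dynamics constants.
#' The free parameters, all in `[0, 1]`:
#' * `w_neg` (mismatch reward sensitivity): raises the feedback baseline
#'   for mismatching schemas above -1.
#' * `m_r` (memory for negative feedback): carries previous-trial feedback
#'   into the current mismatching-schema feedback.
#' * `eps_str` (striatal learning rate): rate of threshold learning in the
#'   cognitive loops' striatal units.
#' * `eps_sma` (sensorimotor schema learning rate): extent to which
#'   conflict among sensorimotor schemas drives their shared gain.
#'
#' The remaining constants (inter-nucleus weights, tonic drives, unit
#' gains/thresholds, integration rate, selection threshold and sustain
#' count, noise half-widths) are not published for this model family;
#' defaults were chosen once so that the selection invariants hold (a
#' single schema wins under asymmetric drive, raising a loop's striatal
#' threshold lowers its activation, symmetric inputs stay symmetric) and
#' are all exposed here.  Absolute cycle counts are therefore
#' implementation-relative; only orderings are meaningful.
#'
#' @param w_neg,m_r,eps_str,eps_sma Free parameters, each in `[0, 1]`.
#' @param zeta_sma Sensorimotor gain scale (the noisy multiplier in the
#'   gain-adaptation rule).
#' @param zeta_sma_noise Half-width of the uniform multiplicative noise on
#'   `zeta_sma` at each feedback event.
#' @param zeta_str Half-width of the uniform noise on each striatal
#'   threshold update.
#' @param alpha_cog Fixed gain of cognitive schema (CTX) units.
#' @param cog_input Constant external drive to every cognitive loop.
#' @param w_bu Bottom-up drive added to rule schemas consistent with the
#'   observed stimulus transition (BRXT rule-induction cue).
#' @param w_inert Probability that, on the trial after the first error of
#'   an error streak, the just-punished response recaptures attention
#'   (imperfect response inhibition; the source of response-perseveration
#'   errors on the Brixton task).
#' @param w_stim Scale of stimulus-driven input to sensorimotor loops.
#' @param noise_cog,noise_sma Per-cycle uniform input noise half-widths.
#' @param noise_trial Baseline probability per trial of a transient
#'   attentional-capture event: one randomly chosen sensorimotor loop
#'   receives a decisive input spike for that trial.  The effective rate
#'   is `noise_trial * (6 / alpha_sma)^3` (a winner-take-all race's
#'   susceptibility to a fixed perturbation falls faster than 1/gain), so
#'   conflict-driven gain increases protect response selection against
#'   capture; lapses occur only on trials following positive feedback
#'   (post-error vigilance).
#' @param beta_str_init Initial striatal threshold of cognitive loops.
#' @param beta_sma_str Fixed striatal threshold of sensorimotor loops.
#' @param theta_sel Selection threshold on sensorimotor CTX activation.
#' @param k_sel Number of consecutive supra-threshold cycles required.
#' @param cycle_cap Maximum cycles per trial.
#' @param sel_onset Cycles before the selection check is armed (lets the
#'   cognitive competition settle before a response can be emitted).
#' @param retention Fraction of trial-end cognitive-loop activation
#'   retained across the inter-trial interval (blend toward the session's
#'   resting state); rule state persists between cards.
#' @param retention_sma As `retention`, for the sensorimotor loops;
#'   response state largely resets between cards.
#' @param eq2_literal Use the literal printed form of the gain rule
#'   (`1 + zeta * prod(1 + eps + o)`) instead of the adopted reading
#'   (`1 + zeta * prod(1 + eps * o)`).
#' @param cfg Named list of loop dynamics constants (see source).
#' @return A list of class `model_params`.
#' @export
model_params <- function(w_neg = 0.1, m_r = 0, eps_str = 0.1, eps_sma = 0.5,
                         zeta_sma = 4.5, zeta_sma_noise = 0.1, zeta_str = 0.05,
                         alpha_cog = 6, cog_input = 0.35, w_bu = 0.32, w_inert = 0.20,
                         w_stim = 0.15,
                         noise_cog = 0.02, noise_sma = 0.08, noise_trial = 0.16,
                         beta_str_init = 0.55, beta_sma_str = 0.2,
                         theta_sel = 0.8, k_sel = 40L, cycle_cap = 400L, sel_onset = 50L,
                         retention = 0.8, retention_sma = 0.35, eq2_literal = FALSE,
                         cfg = bg_loop_cfg()) {
  free <- c(w_neg = w_neg, m_r = m_r, eps_str = eps_str, eps_sma = eps_sma)
  if (any(free < 0 | free > 1)) {
    stop("free parameters w_neg, m_r, eps_str, eps_sma must lie in [0, 1]")
  }
  stopifnot(cycle_cap > 0, k_sel >= 1)
  structure(list(
    w_neg = w_neg, m_r = m_r, eps_str = eps_str, eps_sma = eps_sma,
    zeta_sma = zeta_sma, zeta_sma_noise = zeta_sma_noise, zeta_str = zeta_str,
    alpha_cog = alpha_cog, cog_input = cog_input, w_bu = w_bu,
    w_inert = w_inert, w_stim = w_stim,
    noise_cog = noise_cog, noise_sma = noise_sma,
    noise_trial = noise_trial,
    beta_str_init = beta_str_init, beta_sma_str = beta_sma_str,
    theta_sel = theta_sel, k_sel = as.integer(k_sel),
    sel_onset = as.integer(sel_onset),
    cycle_cap = as.integer(cycle_cap), retention = retention,
    retention_sma = retention_sma,
    eq2_literal = eq2_literal, cfg = cfg
  ), class = "model_params")
}

#' Fixed loop dynamics constants
#'
#' Inter-nucleus weights, tonic drives, unit gains and thresholds, and the
#' leaky-integration rate for the cortico-striato-thalamic loop sets.
#'
#' @param ... Named overrides of individual constants.
#' @return Named list consumed by the compiled cycle kernel.
#' @export
bg_loop_cfg <- function(...) {
  # Operating points designed so the symmetric state (CTX ~ 0.45,
  # GPe = GPi = 0.5, THAL ~ 0.37, STN ~ 0.3) carries a within-channel loop
  # gain ~4 through CTX -> D1 -| GPi -| THAL -> CTX, giving winner-take-all
  # with diffuse STN -> GPi surround suppression of the losers.
  cfg <- list(
    w_tc = 0.7,    w_cs = 1.0,   w_cstn = 1.0, w_ge_stn = 0.8,
    w_d2_gpe = 1.0, w_d1_gpi = 1.0, w_ge_gpi = 0.3, w_stn_gpi = 0.35,
    w_gpi_thal = 1.0, w_td = 0.6,
    t_gpe = 0.56, t_gpi = 0.295, t_thal = 0.859,
    a_str = 6, a_stn = 6, a_gpe = 6, a_gpi = 6, a_thal = 6,
    b_ctx = 0.75, b_stn = 0.191, b_gpe = 0.35, b_gpi = 0.25, b_thal = 0.45,
    b_str0 = 0.60, b_str_scale = 0.65,
    lambda = 0.1
  )
  dots <- list(...)
  stopifnot(all(names(dots) %in% names(cfg)))
  cfg[names(dots)] <- dots
  cfg
}

#' Overflow-safe logistic saturation function
#'
#' @param x Summed weighted input.
#' @param alpha Gain.
#' @param beta Threshold.
#' @return `1 / (1 + exp(-alpha * (x - beta)))`.
#' @export
logistic <- function(x, alpha, beta) {
  z <- -alpha * (x - beta)
  ifelse(z > 40, 0, ifelse(z < -40, 1, 1 / (1 + exp(z))))
}

#' Feedback value assigned to a schema
#'
#' Matching schemas receive +1.  Mismatching schemas receive
#' `2 * w_neg - 1 - m_r * f_prev * r_prev`: with both parameters zero the
#' baseline is -1; `w_neg` raises that baseline and `m_r` carries the
#' previous trial's feedback-by-reward product into it.
#'
#' @param matching Logical (vectorised).
#' @param w_neg,m_r Free parameters.
#' @param f_prev Schema feedback on the previous trial, in `[-1, 1]`.
#' @param r_prev Previous reward, -1 or +1.
#' @return Feedback value(s) `f_i`.
#' @export
schema_feedback <- function(matching, w_neg, m_r, f_prev = 0, r_prev = 1) {
  ifelse(matching, 1, 2 * w_neg - 1 - m_r * f_prev * r_prev)
}

#' Reward prediction error
#'
#' @param r Reward, -1 or +1.
#' @param f_i Schema feedback value.
#' @param a_i Median schema activation over the last trial, in `[0, 1]`.
#' @return The product r * (f_i - a_i).
#' @export
prediction_error <- function(r, f_i, a_i) r * (f_i - a_i)

#' Striatal threshold update
#'
#' `beta <- beta - eps_str * delta * (1 + zeta)`, clipped to `[0, 1]`.
#'
#' @param beta Current threshold(s) in `[0, 1]`.
#' @param delta Prediction error(s).
#' @param eps_str Striatal learning rate.
#' @param zeta Noise draw(s) (0 for the deterministic update).
#' @return Updated threshold(s), clipped to `[0, 1]`.
#' @export
update_striatum <- function(beta, delta, eps_str, zeta = 0) {
  pmin(1, pmax(0, beta - eps_str * delta * (1 + zeta)))
}

#' Conflict-driven sensorimotor gain update
#'
#' Adopted reading: `alpha_sma <- 1 + zeta * prod(1 + eps_sma * o_i)` over
#' all sensorimotor outputs `o_i`, applied once per feedback event, with
#' `zeta = zeta_sma * (1 + u)`, `u ~ U(-noise, +noise)`.  With
#' `eps_sma = 0` the product degenerates to 1 and the gain is constant (up
#' to noise): conflict no longer drives confidence.  The literal printed
#' form `1 + zeta * prod(1 + eps_sma + o_i)` is available via `literal`.
#'
#' @param sma_outputs Sensorimotor unit outputs, each in `[0, 1]`.
#' @param eps_sma Sensorimotor schema learning rate.
#' @param zeta_sma Gain scale.
#' @param noise Half-width of the uniform multiplicative noise (a draw is
#'   taken from the current RNG stream when positive).
#' @param literal Use the literal parenthesisation.
#' @return New gain `alpha_sma`.
#' @export
update_gain <- function(sma_outputs, eps_sma, zeta_sma, noise = 0,
                        literal = FALSE) {
  u <- if (noise > 0) runif(1, -noise, noise) else 0
  prd <- if (literal) prod(1 + eps_sma + sma_outputs)
         else prod(1 + eps_sma * sma_outputs)
  1 + zeta_sma * (1 + u) * prd
}

#' Initialise a loop-set state
#'
#' @param n Number of schemas in the set.
#' @param value Initial activation of every unit.
#' @return A 7 x `n` matrix with rows CTX, D1, D2, STN, GPE, GPI, THAL.
#' @export
new_loop_state <- function(n, value = 0.2) {
  matrix(value, nrow = 7L, ncol = n,
         dimnames = list(c("CTX", "D1", "D2", "STN", "GPE", "GPI", "THAL"),
                         NULL))
}

#' One integration cycle of a loop set
#'
#' Synchronously updates every unit of every schema loop in one competing
#' set, with leaky blending toward the logistic of its weighted input.
#'
#' @param state A 7 x n state matrix (see [new_loop_state()]).
#' @param inputs External input per schema (added to the CTX input).
#' @param params A [model_params()] object.
#' @param beta_str Per-schema striatal thresholds (default: the cognitive
#'   initial threshold).
#' @param alpha_ctx Gain of the CTX units (default: the cognitive gain).
#' @return The updated state matrix.
#' @export
step_loops <- function(state, inputs, params,
                       beta_str = rep(params$beta_str_init, ncol(state)),
                       alpha_ctx = params$alpha_cog) {
  stopifnot(nrow(state) == 7L, length(inputs) == ncol(state),
            length(beta_str) == ncol(state))
  out <- .bg_cycle_cpp(state, as.numeric(inputs), as.numeric(beta_str),
                       alpha_ctx, params$cfg)
  dimnames(out) <- dimnames(state)
  out
}

#' Run coupled loop sets until a sensorimotor schema is selected
#'
#' Iterates the cognitive and sensorimotor loop sets (the latter receiving
#' stimulus input plus top-down excitation from the cognitive CTX units via
#' `td_map`) until one sensorimotor schema's activation exceeds the
#' selection threshold for the sustain count, or the cycle cap is hit (the
#' highest-activation schema is then chosen and the trial flagged).
#'
#' @param cog,sma Loop-set state matrices.
#' @param beta_cog Cognitive striatal thresholds.
#' @param cog_in,sma_in External inputs (constant cognitive drive;
#'   stimulus-driven sensorimotor drive).
#' @param td_map Integer vector: for each cognitive schema, the index of
#'   the sensorimotor schema it currently excites.
#' @param alpha_sma Current sensorimotor gain.
#' @param params A [model_params()] object.
#' @return List with `response`, `cycles`, `capped`, updated `cog`/`sma`
#'   states, `a_med` (per-cognitive-schema median CTX activation over the
#'   trial) and `sma_out` (end-of-trial sensorimotor CTX activations).
#' @export
select_and_respond <- function(cog, sma, beta_cog, cog_in, sma_in, td_map,
                               alpha_sma, params) {
  .bg_trial_cpp(cog, sma, as.numeric(beta_cog),
                rep(params$beta_sma_str, ncol(sma)),
                as.numeric(cog_in), as.numeric(sma_in),
                as.integer(td_map), params$alpha_cog, alpha_sma,
                params$noise_cog, params$noise_sma,
                params$theta_sel, params$k_sel, params$cycle_cap,
                params$sel_onset, params$cfg)
}

# blend a state toward the resting snapshot across the inter-trial gap
.intertrial <- function(state, rest, retention) {
  rest + retention * (state - rest)
}

#' Run one full session of the model on a task
#'
#' Plays a complete WCST (64 trials; 3 cognitive and 4 sensorimotor
#' schemas) or BRXT (50 trials; 5 cognitive schemas -- the four canonical
#' rules plus one per-participant "other" rule -- and 9 sensorimotor
#' schemas) session.  Each trial: stimulus-driven input is routed to the
#' sensorimotor loops and top-down input from the cognitive loops; a
#' response is selected by sustained-threshold competition (cycle count
#' logged as RT); environment feedback `r` is obtained; per-schema
#' matching is determined (WCST: a cognitive schema matches iff it would
#' have produced the selected pile; BRXT: a rule matches iff it is
#' consistent with the two most recent filled-disk positions); then the
#' schema-feedback, prediction-error and striatal updates are applied to
#' each cognitive loop and the conflict-gain update at the sensorimotor
#' level.
#'
#' @param task A [wcst_task()] or [brxt_task()] descriptor.
#' @param params A [model_params()] object.
#' @param seed Integer seed (fully determines the session).
#' @param participant_id Identifier recorded in the log.
#' @return A session log data frame (one row per trial) with columns
#'   `participant_id`, `task`, `trial`, `stimulus`, `response`, `correct`,
#'   `feedback`, `active_rule`, `rt`, plus attributes `capped` (number of
#'   cap-exhausted trials) and `beta_final`.
#' @export
run_session <- function(task, params = model_params(), seed = 1L,
                        participant_id = 1L) {
  stopifnot(inherits(task, "bg_task"))
  if (!is.null(seed)) set.seed(seed)
  if (task$name == "wcst") .run_session_wcst(task, params, participant_id)
  else .run_session_brxt(task, params, participant_id)
}

# shared session bookkeeping: burn the loop sets to a resting state
.burn_in <- function(cog, sma, beta_cog, cog_in, params, n_cycles = 80L) {
  for (k in seq_len(n_cycles)) {
    cog <- step_loops(cog, cog_in, params, beta_str = beta_cog)
    sma <- step_loops(sma, rep(0, ncol(sma)), params,
                      beta_str = rep(params$beta_sma_str, ncol(sma)),
                      alpha_ctx = 1 + params$zeta_sma)
  }
  list(cog = cog, sma = sma)
}

# Integer coding exploited throughout: target pile j carries feature code
# j on every dimension, so the pile matching a card on dimension d is just
# the card's code on d, and the number of features shared with pile j is
# the count of card codes equal to j.
.card_code_matrix <- function(deck) {
  cbind(deck$number, match(deck$color, .wcst_colors),
        match(deck$shape, .wcst_shapes))
}

.run_session_wcst <- function(task, params, participant_id) {
  deck <- build_wcst_deck()
  deck <- deck[sample.int(64L), , drop = FALSE]
  codes <- .card_code_matrix(deck)          # 64 x 3 (number, color, shape)
  dim_idx <- match(task$rule_sequence, .wcst_dims)
  env <- wcst_new_state(task$rule_sequence)
  nc <- 3L; ns <- 4L

  beta_cog <- rep(params$beta_str_init, nc)
  cog_in <- rep(params$cog_input, nc)
  st <- .burn_in(new_loop_state(nc), new_loop_state(ns), beta_cog, cog_in,
                 params)
  cog <- st$cog; sma <- st$sma
  rest_cog <- cog; rest_sma <- sma
  alpha_sma <- 1 + params$zeta_sma
  f_prev <- rep(0, nc); r_prev <- 1
  n_capped <- 0L

  response <- integer(64L); correct <- integer(64L)
  feedback <- integer(64L); active <- character(64L); rt <- integer(64L)
  for (t in seq_len(64L)) {
    td_map <- codes[t, ]                    # pile per dimension
    sma_in <- params$w_stim * tabulate(td_map, 4L) / 3
    # transient attentional capture: only under routine success (post-error
    # vigilance suppresses lapses), at a rate damped by the conflict gain;
    # the capture target is occasionally the most stimulus-similar pile,
    # otherwise any pile
    if (r_prev == 1 &&
        runif(1) < min(1, params$noise_trial * (6 / alpha_sma)^3)) {
      lapse_to <- if (runif(1) < 0.12) which.max(sma_in)
        else sample.int(ns, 1L)
      sma_in[lapse_to] <- sma_in[lapse_to] + 1.1
    }

    res <- select_and_respond(cog, sma, beta_cog, cog_in, sma_in, td_map,
                              alpha_sma, params)
    cog <- res$cog; sma <- res$sma
    if (res$capped) n_capped <- n_capped + 1L

    active_rule_dim <- dim_idx[[env$rule_index]]
    correct_pile <- td_map[[active_rule_dim]]
    r <- if (res$response == correct_pile) 1L else -1L
    # environment bookkeeping (inline wcst_step for speed)
    if (r == 1L) {
      env$consecutive_correct <- env$consecutive_correct + 1L
      if (env$consecutive_correct == 6L) {
        env$categories_achieved <- env$categories_achieved + 1L
        env$consecutive_correct <- 0L
        env$rule_index <- env$rule_index %% length(task$rule_sequence) + 1L
      }
    } else env$consecutive_correct <- 0L

    matching <- td_map == res$response
    f_i <- schema_feedback(matching, params$w_neg, params$m_r, f_prev, r_prev)
    delta <- prediction_error(r, f_i, 2 * res$a_med - 1)
    zeta <- if (params$zeta_str > 0) {
      runif(nc, -params$zeta_str, params$zeta_str)
    } else 0
    beta_cog <- update_striatum(beta_cog, delta, params$eps_str, zeta)
    alpha_sma <- update_gain(res$sma_out, params$eps_sma, params$zeta_sma,
                             params$zeta_sma_noise, params$eq2_literal)
    f_prev <- f_i; r_prev <- r

    cog <- .intertrial(cog, rest_cog, params$retention)
    sma <- .intertrial(sma, rest_sma, params$retention_sma)

    response[[t]] <- res$response; correct[[t]] <- correct_pile
    feedback[[t]] <- r; rt[[t]] <- res$cycles
    active[[t]] <- .wcst_dims[[active_rule_dim]]
  }
  out <- data.frame(
    participant_id = participant_id, task = "wcst", trial = seq_len(64L),
    stimulus = paste(deck$number, deck$color, deck$shape, sep = "|"),
    response = response, correct = correct, feedback = feedback,
    active_rule = active, rt = rt, stringsAsFactors = FALSE
  )
  attr(out, "capped") <- n_capped
  attr(out, "beta_final") <- beta_cog
  out
}

.run_session_brxt <- function(task, params, participant_id) {
  spec <- local({
    rules <- vapply(task$rules, function(r) {
      if (identical(r, "random")) sample(brxt_rules(), 1L) else r
    }, character(1L), USE.NAMES = FALSE)
    build_brxt_sequence(rules, start_pos = task$start_pos, seed = NULL)
  })
  # cognitive schemas: the four canonical rules plus one per-participant
  # "other rules" schema (a distractor pattern, never the task's rule)
  rule_ids <- c(brxt_rules(), sample(brxt_distractor_rules(), 1L))
  nc <- length(rule_ids); ns <- 9L
  # transition table: nxt[i, p] = next position under rule i from p
  nxt <- t(vapply(rule_ids, function(r) {
    vapply(1:9, function(p) brxt_next_target(r, p), integer(1L))
  }, integer(9L)))

  beta_cog <- rep(params$beta_str_init, nc)
  cog_in <- rep(params$cog_input, nc)
  st <- .burn_in(new_loop_state(nc), new_loop_state(ns), beta_cog, cog_in,
                 params)
  cog <- st$cog; sma <- st$sma
  rest_cog <- cog; rest_sma <- sma
  alpha_sma <- 1 + params$zeta_sma
  f_prev <- rep(0, nc); r_prev <- 1; r_prev2 <- 1
  n_capped <- 0L

  stim <- spec$start_pos
  prev_stim <- NA_integer_
  response <- integer(50L); stimulus <- integer(50L)
  feedback <- integer(50L); rt <- integer(50L)
  for (t in seq_len(50L)) {
    # rules consistent with the observed stimulus transition receive
    # bottom-up activation (the model's rule-induction cue)
    cog_in_t <- cog_in
    if (!is.na(prev_stim)) {
      cog_in_t <- cog_in + params$w_bu * (nxt[, prev_stim] == stim)
    }
    sma_in <- rep(0, ns)
    sma_in[stim] <- 0.6 * params$w_stim  # the lit disk is one cue among 9
    # occasional decisive capture by the filled disk itself (stimulus
    # echo); a rare, group-independent slip
    if (runif(1) < 0.006) sma_in[stim] <- sma_in[stim] + 1.1
    # transient attentional capture (to any currently unfilled disk; gaze
    # is already on the filled one)
    if (r_prev == 1 &&
        runif(1) < min(1, params$noise_trial * (6 / alpha_sma)^3)) {
      lapse_to <- sample(setdiff(seq_len(ns), stim), 1L)
      sma_in[lapse_to] <- sma_in[lapse_to] + 1.1
    }
    # imperfect response inhibition: after the first error of a streak,
    # the just-punished tap recaptures attention with probability w_inert
    # (repeats cannot chain, since a repeat's predecessor is an error)
    if (t > 1L && r_prev == -1L && r_prev2 == 1L &&
        runif(1) < params$w_inert) {
      pr <- response[[t - 1L]]
      sma_in[pr] <- sma_in[pr] + 1.1
    }
    td_map <- nxt[, stim]

    res <- select_and_respond(cog, sma, beta_cog, cog_in_t, sma_in, td_map,
                              alpha_sma, params)
    cog <- res$cog; sma <- res$sma
    if (res$capped) n_capped <- n_capped + 1L

    target <- spec$target_sequence[[t]]
    r <- if (res$response == target) 1L else -1L

    # a rule matches iff it would have produced the emitted response from
    # the current stimulus (= consistency of the two most recent taps
    # whenever the previous prediction was correct)
    matching <- td_map == res$response
    f_i <- schema_feedback(matching, params$w_neg, params$m_r,
                           f_prev, r_prev)
    delta <- prediction_error(r, f_i, 2 * res$a_med - 1)
    zeta <- if (params$zeta_str > 0) {
      runif(nc, -params$zeta_str, params$zeta_str)
    } else 0
    beta_cog <- update_striatum(beta_cog, delta, params$eps_str, zeta)
    f_prev <- f_i
    alpha_sma <- update_gain(res$sma_out, params$eps_sma, params$zeta_sma,
                             params$zeta_sma_noise, params$eq2_literal)
    r_prev2 <- r_prev
    r_prev <- r

    cog <- .intertrial(cog, rest_cog, params$retention)
    sma <- .intertrial(sma, rest_sma, params$retention_sma)

    response[[t]] <- res$response; stimulus[[t]] <- stim
    feedback[[t]] <- r; rt[[t]] <- res$cycles
    prev_stim <- stim
    stim <- target
  }
  out <- data.frame(
    participant_id = participant_id, task = "brxt", trial = seq_len(50L),
    stimulus = as.character(stimulus), response = response,
    correct = spec$target_sequence, feedback = feedback,
    active_rule = rep(spec$rules, each = 10L), rt = rt,
    stringsAsFactors = FALSE
  )
  attr(out, "capped") <- n_capped
  attr(out, "beta_final") <- beta_cog
  out
}

#' Simulate a group of model runs and summarise
#'
#' Runs `n` independent sessions (seeds derived from `seed`), scores each
#' with the task's error taxonomy, and returns per-measure summary
#' statistics plus mean cycles-to-response after positive and negative
#' feedback.
#'
#' @param task A [wcst_task()] or [brxt_task()] descriptor.
#' @param params A [model_params()] object.
#' @param n Group size (default 25).
#' @param seed Master seed.
#' @return List with `summary` (data frame: measure, mean, sd, n),
#'   `scores` (one row per run), `rt` (mean cycles after positive/negative
#'   feedback per run) and `logs` invisibly omitted for size.
#' @export
run_group <- function(task, params = model_params(), n = 25L, seed = 1L) {
  stopifnot(n >= 2L)
  set.seed(seed)
  run_seeds <- sample.int(2^31 - 1L, n)
  logs <- lapply(seq_len(n), function(i) {
    run_session(task, params, seed = run_seeds[[i]], participant_id = i)
  })
  tab <- score_table(logs, task = task$name)
  measures <- if (task$name == "wcst") c("TE", "PE", "SL3", "CA")
              else c("TE", "PSTIM", "PRESP", "PRULE")
  summary <- data.frame(
    measure = measures,
    mean = vapply(measures, function(m) mean(tab[[m]]), numeric(1L)),
    sd   = vapply(measures, function(m) sd(tab[[m]]), numeric(1L)),
    n    = n, row.names = NULL, stringsAsFactors = FALSE
  )
  list(summary = summary, scores = tab,
       rt = c(after_positive = mean(tab$rt_pos, na.rm = TRUE),
              after_negative = mean(tab$rt_neg, na.rm = TRUE)))
}
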