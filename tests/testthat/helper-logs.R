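# Scripted session-log builders used across scoring tests.

# Play a full WCST session with a scripted responder: `respond(card, env)`
# returns a pile 1-4.  Returns a trial log in the shared dialect.
scripted_wcst_log <- function(respond, seed = 1,
                              rule_sequence = c("color", "shape", "number")) {
  set.seed(seed)
  deck <- build_wcst_deck()
  deck <- deck[sample.int(64L), , drop = FALSE]
  env <- wcst_new_state(rule_sequence)
  rows <- vector("list", 64L)
  for (t in seq_len(64L)) {
    card <- as.list(deck[t, ])
    resp <- respond(card, env)
    active <- env$active_rule
    correct <- which(wcst_targets()[[active]] == card[[active]])
    step <- wcst_step(env, card, resp)
    env <- step$state
    rows[[t]] <- data.frame(
      participant_id = 1L, task = "wcst", trial = t,
      stimulus = paste(card$number, card$color, card$shape, sep = "|"),
      response = resp, correct = correct, feedback = step$feedback,
      active_rule = active, rt = 100, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Play a full BRXT session with a scripted responder: `respond(stim, target)`
# returns a disk 1-9 (or the sentinel 0).
scripted_brxt_log <- function(respond, seed = 1,
                              rules = c("cw", "ccw", "walk15", "ccw_skip", "cw")) {
  spec <- build_brxt_sequence(rules, start_pos = 1L, seed = seed)
  stim <- spec$start_pos
  rows <- vector("list", 50L)
  for (t in seq_len(50L)) {
    target <- spec$target_sequence[[t]]
    resp <- respond(stim, target)
    rows[[t]] <- data.frame(
      participant_id = 1L, task = "brxt", trial = t,
      stimulus = as.character(stim), response = resp, correct = target,
      feedback = if (resp == target) 1L else -1L,
      active_rule = spec$rules[[(t - 1L) %/% 10L + 1L]],
      rt = 100, stringsAsFactors = FALSE)
    stim <- target
  }
  do.call(rbind, rows)
}

# a hand-built WCST log from explicit per-trial fields (for small cases)
manual_wcst_log <- function(stimulus, response, feedback, active_rule,
                            rt = 100) {
  n <- length(stimulus)
  data.frame(participant_id = 1L, task = "wcst", trial = seq_len(n),
             stimulus = stimulus, response = response,
             correct = NA_integer_, feedback = feedback,
             active_rule = active_rule, rt = rt, stringsAsFactors = FALSE)
}
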