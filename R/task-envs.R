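#' @useDynLib bgschema, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median runif rnorm integrate dt aov cor lm residuals
#'   complete.cases sd quantile
#' @importFrom utils read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# WCST environment
# ---------------------------------------------------------------------------

.wcst_colors <- c("red", "green", "yellow", "blue")
.wcst_shapes <- c("triangle", "star", "cross", "circle")
.wcst_dims   <- c("number", "color", "shape")

#' The four fixed WCST target cards
#'
#' Target piles are, left to right: one red triangle, two green stars,
#' three yellow crosses, four blue circles.  Each feature value occurs on
#' exactly one target, so for any stimulus card and any sorting dimension
#' there is exactly one pile that matches on that dimension.
#'
#' @return A data frame with columns `number`, `color`, `shape` and one row
#'   per pile (1-4).
#' @export
wcst_targets <- function() {
  data.frame(
    number = 1:4,
    color  = .wcst_colors,
    shape  = .wcst_shapes,
    stringsAsFactors = FALSE
  )
}

#' Build the 64-card WCST deck
#'
#' The full deck enumerates all 4 x 4 x 4 combinations of number, color and
#' shape exactly once.  The administration order is a seeded uniform shuffle
#' (the published task does not fix a card order); with `seed = NULL` the
#' factorial enumeration order is returned.
#'
#' @param seed Optional integer seed for the shuffle.
#' @return A 64-row data frame with columns `number`, `color`, `shape`.
#' @export
build_wcst_deck <- function(seed = NULL) {
  deck <- expand.grid(
    number = 1:4, color = .wcst_colors, shape = .wcst_shapes,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  if (!is.null(seed)) {
    set.seed(seed)
    deck <- deck[sample.int(64L), , drop = FALSE]
  }
  rownames(deck) <- NULL
  deck
}

#' Dimensions on which a card matches a target pile
#'
#' @param card A one-row data frame or list with `number`, `color`, `shape`.
#' @param pile Target pile index, 1-4.
#' @return Character vector, a subset of `c("number", "color", "shape")`.
#' @export
wcst_match_dims <- function(card, pile) {
  if (!is.numeric(pile) || length(pile) != 1L || is.na(pile) ||
      pile < 1 || pile > 4) {
    stop("`pile` must be a single integer in 1..4")
  }
  tgt <- wcst_targets()[pile, ]
  .wcst_dims[c(card$number == tgt$number,
               card$color  == tgt$color,
               card$shape  == tgt$shape)]
}

# Pile matching `card` on dimension `dim` (always unique by construction).
wcst_pile_for <- function(card, dim) {
  tgt <- wcst_targets()
  which(tgt[[dim]] == card[[dim]])
}

# A response is "unambiguous" when the chosen pile matches the card on
# exactly one dimension (the standard Heaton operationalisation).
wcst_unambiguous <- function(card, pile) {
  length(wcst_match_dims(card, pile)) == 1L
}

#' Initial WCST session state
#'
#' The sorting rule changes after every run of six correct responses,
#' advancing cyclically along `rule_sequence`.  The published order of
#' sorting rules is not fixed; the conventional color, shape, number cycle
#' is the default.
#'
#' @param rule_sequence Character vector of sorting rules cycled through.
#' @return A list of class `wcst_state` with fields `active_rule`,
#'   `consecutive_correct`, `categories_achieved`, `deck_position`,
#'   `rule_index`, `rule_sequence`.
#' @export
wcst_new_state <- function(rule_sequence = c("color", "shape", "number")) {
  stopifnot(all(rule_sequence %in% .wcst_dims), length(rule_sequence) >= 1L)
  structure(list(
    active_rule         = rule_sequence[[1L]],
    consecutive_correct = 0L,
    categories_achieved = 0L,
    deck_position       = 0L,
    rule_index          = 1L,
    rule_sequence       = rule_sequence
  ), class = "wcst_state")
}

#' Advance the WCST environment by one sorted card
#'
#' Feedback is +1 iff the response pile matches the current card on the
#' active rule's dimension.  On the sixth consecutive correct response the
#' active rule advances along the rule sequence (cyclically), the counter
#' resets and a category is credited; an error resets the counter.
#'
#' @param state A `wcst_state`.
#' @param card The current stimulus card.
#' @param response Chosen pile, 1-4.
#' @return `list(feedback = +1 or -1, state = next state)`.
#' @export
wcst_step <- function(state, card, response) {
  if (!is.numeric(response) || length(response) != 1L || is.na(response) ||
      response < 1 || response > 4) {
    stop("`response` must be a single integer in 1..4")
  }
  correct_pile <- wcst_pile_for(card, state$active_rule)
  if (response == correct_pile) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    feedback <- 1L
    if (state$consecutive_correct == 6L) {
      state$categories_achieved <- state$categories_achieved + 1L
      state$consecutive_correct <- 0L
      state$rule_index <- state$rule_index %% length(state$rule_sequence) + 1L
      state$active_rule <- state$rule_sequence[[state$rule_index]]
    }
  } else {
    state$consecutive_correct <- 0L
    feedback <- -1L
  }
  state$deck_position <- state$deck_position + 1L
  list(feedback = feedback, state = state)
}

# ---------------------------------------------------------------------------
# BRXT environment
# ---------------------------------------------------------------------------

#' Canonical Brixton rule identifiers
#'
#' The four rules administered are clockwise, counter-clockwise, a walk
#' through positions 1-5 (the adopted reading of "alternate between
#' positions 1-5"; the strict 1<->5 alternation is available as `alt15`),
#' and counter-clockwise skipping one disk.  `brxt_distractor_rules()`
#' lists the pool from which a per-participant "other rules" schema is
#' drawn.
#'
#' @return Character vector of rule ids.
#' @export
brxt_rules <- function() c("cw", "ccw", "walk15", "ccw_skip")

#' @rdname brxt_rules
#' @export
brxt_distractor_rules <- function() c("cw_skip", "cw2", "ccw2", "stay")

# Circular position arithmetic on 1..9 (1-based clockwise).
.circ9 <- function(p) ((p - 1L) %% 9L) + 1L

#' Next target disk under a Brixton rule
#'
#' Positions are numbered 1-9 clockwise around the circle; modular
#' arithmetic maps back into 1..9.  `alt15` is read as strict alternation
#' between positions 1 and 5 (from any other position it moves to 1).
#'
#' @param rule A rule id (see [brxt_rules()] and [brxt_distractor_rules()]).
#' @param current_pos Current filled-disk position, 1-9.
#' @return The next position, 1-9.
#' @export
brxt_next_target <- function(rule, current_pos) {
  if (!is.numeric(current_pos) || length(current_pos) != 1L ||
      is.na(current_pos) || current_pos < 1 || current_pos > 9) {
    stop("`current_pos` must be a single integer in 1..9")
  }
  p <- as.integer(current_pos)
  switch(rule,
    cw       = .circ9(p + 1L),
    ccw      = .circ9(p - 1L),
    ccw_skip = .circ9(p - 2L),
    cw_skip  = .circ9(p + 2L),
    cw2      = .circ9(p + 3L),
    ccw2     = .circ9(p - 3L),
    stay     = p,
    walk15   = if (p >= 1L && p < 5L) p + 1L else 1L,
    alt15    = if (p == 5L) 1L else if (p == 1L) 5L else 1L,
    stop("unknown BRXT rule: ", rule)
  )
}

#' Build a Brixton target sequence
#'
#' Five sequential rules each govern ten successive disk locations, giving
#' a 50-position target sequence.  The fifth rule may be the per-participant
#' "other" rule, materialised from `seed` when `rules[5]` is `"random"`.
#'
#' @param rules Character vector of exactly 5 rule ids (the literal id
#'   `"random"` draws one of the four canonical rules from the seeded
#'   stream; the administered task reuses the canonical rules).
#' @param start_pos Position of the filled disk shown before the first
#'   prediction trial.
#' @param seed Optional integer seed (materialises `"random"` entries).
#' @return A list of class `brxt_spec` with fields `n_positions`, `rules`,
#'   `trials_per_rule`, `start_pos`, `target_sequence` (length 50).
#' @export
build_brxt_sequence <- function(rules = c("cw", "ccw", "walk15", "ccw_skip", "random"),
                                start_pos = 1L, seed = NULL) {
  if (length(rules) != 5L) stop("exactly 5 rules are required")
  if (!is.null(seed)) set.seed(seed)
  rules <- vapply(rules, function(r) {
    if (identical(r, "random")) sample(brxt_rules(), 1L) else r
  }, character(1L), USE.NAMES = FALSE)
  pos <- as.integer(start_pos)
  seq_out <- integer(0L)
  for (r in rules) {
    for (k in seq_len(10L)) {
      pos <- brxt_next_target(r, pos)
      seq_out <- c(seq_out, pos)
    }
  }
  structure(list(
    n_positions     = 9L,
    rules           = rules,
    trials_per_rule = 10L,
    start_pos       = as.integer(start_pos),
    target_sequence = seq_out
  ), class = "brxt_spec")
}

# Rule active on BRXT trial t (1..50).
brxt_rule_at <- function(spec, trial) spec$rules[[(trial - 1L) %/% 10L + 1L]]

# ---------------------------------------------------------------------------
# Task descriptors shared by the model and the synthetic agent
# ---------------------------------------------------------------------------

#' Task descriptors
#'
#' Lightweight descriptions of one administration of each task, consumed by
#' [run_session()] and [gen_agent_session()].  All stochastic elements of
#' the administration (deck order, the fifth Brixton rule) are derived from
#' the session seed at run time, so a task object is reusable across
#' simulated participants.
#'
#' @param rule_sequence WCST sorting-rule cycle.
#' @param rules BRXT rule list (5 entries; `"random"` = per-participant
#'   distractor).
#' @param start_pos BRXT starting position.
#' @return A list of class `bg_task`.
#' @export
wcst_task <- function(rule_sequence = c("color", "shape", "number")) {
  structure(list(name = "wcst", rule_sequence = rule_sequence,
                 n_trials = 64L), class = "bg_task")
}

#' @rdname wcst_task
#' @export
brxt_task <- function(rules = c("cw", "ccw", "walk15", "ccw_skip", "random"),
                      start_pos = 1L) {
  structure(list(name = "brxt", rules = rules, start_pos = start_pos,
                 n_trials = 50L), class = "bg_task")
}

# Stimulus serialisation for the shared CSV trial-log dialect.
wcst_card_label <- function(card) {
  paste(card$number, card$color, card$shape, sep = "|")
}

wcst_parse_card <- function(label) {
  parts <- strsplit(label, "|", fixed = TRUE)[[1L]]
  list(number = as.integer(parts[[1L]]), color = parts[[2L]],
       shape = parts[[3L]])
}
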