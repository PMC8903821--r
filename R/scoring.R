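# Error taxonomies for the two tasks, applied to trial logs in the shared
# CSV dialect (one row per trial: participant_id, task, trial, stimulus,
# response, correct, feedback, active_rule, rt).

#' Score a WCST session
#'
#' Computes total errors (TE), perseverative errors (PE, Heaton scoring),
#' set-loss errors (SL3, three-correct criterion of Stuss et al.) and
#' categories achieved (CA) from a 64-trial session log.
#'
#' Scoring rules:
#' * TE is the number of negative-feedback trials.
#' * The perseverated-to principle is the sorting rule in force before the
#'   most recent rule change.  In addition, once an incorrect rule has been
#'   applied consistently and unambiguously on more than three successive
#'   trials, that rule becomes the principle and immediately subsequent
#'   errors matching it are perseverative.
#' * An error is a PE when the chosen pile matches the card on the
#'   principle's dimension (i.e. the response would have been correct
#'   under the perseverated-to rule).  With `pe_unambiguous_only = TRUE`
#'   the response must additionally be unambiguous (match on exactly one
#'   dimension), the stricter Heaton operationalisation; in that variant
#'   `sandwich = TRUE` also counts ambiguous principle-matching errors
#'   flanked by unambiguous PEs (with no intervening rule change or
#'   non-matching response).
#' * An error following an established set is an SL3.  By default a set is
#'   established by three or more successive correct responses under the
#'   current rule, at least one of which was unambiguous (so the set was
#'   unambiguously evidenced); with `sl3_strict = TRUE` all of the
#'   establishing responses must themselves be unambiguous.  Errors after
#'   a set-loss error are not SL3 until a new establishing run accrues
#'   (automatic here, because any error resets the run).  SL3 and PE are
#'   mutually exclusive: a trial qualifying as SL3 (no rule change since
#'   the establishing run) is never counted as PE.
#'
#' @param trials Session log data frame (see [run_session()]).
#' @param sandwich Apply the ambiguous-error sandwiching rule (only
#'   relevant with `pe_unambiguous_only = TRUE`; default TRUE).
#' @param pe_unambiguous_only Require PEs to match the principle
#'   unambiguously (Heaton variant; default FALSE, the plain definition).
#' @param sl3_strict If TRUE, an ambiguous correct response resets the
#'   unambiguous-correct run that establishes a set; by default such
#'   trials are neutral (the set, once being established, survives
#'   ambiguous correct sorts).
#' @return A list of class `wcst_scores` with fields `TE`, `PE`, `SL3`,
#'   `CA`, plus a `labels` attribute giving the per-trial classification
#'   (`correct`, `PE`, `SL3` or `other_error`).
#' @export
score_wcst <- function(trials, sandwich = TRUE, sl3_strict = FALSE,
                       pe_unambiguous_only = FALSE) {
  stopifnot(is.data.frame(trials), nrow(trials) >= 1L)
  if (any(is.na(trials$active_rule)) || !all(trials$active_rule %in% .wcst_dims)) {
    stop("WCST trial log must carry valid active_rule annotations")
  }
  n <- nrow(trials)
  parts <- strsplit(trials$stimulus, "|", fixed = TRUE)
  codes <- cbind(as.integer(vapply(parts, `[`, "", 1L)),
                 match(vapply(parts, `[`, "", 2L), .wcst_colors),
                 match(vapply(parts, `[`, "", 3L), .wcst_shapes))
  resp  <- as.integer(trials$response)
  fb    <- as.integer(trials$feedback)
  rule  <- trials$active_rule

  # dimensions on which the chosen pile matches the card (pile j matches
  # the card on dimension d iff the card's code on d is j)
  match_dims <- lapply(seq_len(n), function(t) .wcst_dims[codes[t, ] == resp[[t]]])
  unamb <- vapply(match_dims, function(d) length(d) == 1L, logical(1L))

  labels <- character(n)
  principle <- NA_character_
  chain_dim <- NA_character_   # incorrect rule applied in an unambiguous chain
  chain_len <- 0L
  cc_unamb  <- 0L              # consecutive correct unambiguous responses
  cc_corr   <- 0L              # consecutive correct since error/rule change
  cc        <- 0L              # consecutive correct (for CA)
  ca        <- 0L

  for (t in seq_len(n)) {
    if (t > 1L && rule[[t]] != rule[[t - 1L]]) {
      principle <- rule[[t - 1L]]
      cc_unamb <- 0L; cc_corr <- 0L
      chain_dim <- NA_character_; chain_len <- 0L
    }
    if (fb[[t]] == 1L) {
      labels[[t]] <- "correct"
      cc <- cc + 1L
      if (cc == 6L) { ca <- ca + 1L; cc <- 0L }
      cc_corr <- cc_corr + 1L
      if (unamb[[t]]) cc_unamb <- cc_unamb + 1L
      else if (sl3_strict) cc_unamb <- 0L
      # (default: an ambiguous correct sort neither extends nor breaks
      # the established set)
      chain_dim <- NA_character_; chain_len <- 0L
    } else {
      established <- if (sl3_strict) cc_unamb >= 3L
                     else cc_corr >= 3L && cc_unamb >= 1L
      if (established) {
        labels[[t]] <- "SL3"
      } else if (!is.na(principle) && principle %in% match_dims[[t]] &&
                 (!pe_unambiguous_only || unamb[[t]])) {
        labels[[t]] <- "PE"
      } else {
        labels[[t]] <- "other_error"
      }
      cc <- 0L
      cc_unamb <- 0L; cc_corr <- 0L
      # track unambiguous consistent application of one incorrect rule
      if (unamb[[t]]) {
        d <- match_dims[[t]][[1L]]
        if (!is.na(chain_dim) && d == chain_dim) chain_len <- chain_len + 1L
        else { chain_dim <- d; chain_len <- 1L }
        if (chain_len > 3L) principle <- chain_dim
      } else {
        chain_dim <- NA_character_; chain_len <- 0L
      }
    }
  }

  if (sandwich) {
    # Ambiguous principle-matching errors flanked by unambiguous PEs count
    # as PEs when every intervening trial is such an ambiguous error.
    pe_idx <- which(labels == "PE")
    if (length(pe_idx) >= 2L) {
      # principle in force at each trial (recomputed from rule annotations)
      for (k in seq_len(length(pe_idx) - 1L)) {
        lo <- pe_idx[[k]]; hi <- pe_idx[[k + 1L]]
        if (hi - lo <= 1L) next
        between <- (lo + 1L):(hi - 1L)
        if (any(rule[between] != rule[[lo]])) next
        ok <- all(labels[between] == "other_error" & !unamb[between] &
                  vapply(between, function(t) {
                    # principle at lo still applies across the gap
                    any(.wcst_dims[.wcst_dims %in% match_dims[[t]]] %in% match_dims[[lo]])
                  }, logical(1L)))
        if (ok) labels[between] <- "PE"
      }
    }
  }

  structure(
    list(TE = sum(fb == -1L), PE = sum(labels == "PE"),
         SL3 = sum(labels == "SL3"), CA = ca),
    labels = labels, class = "wcst_scores"
  )
}

#' Score a Brixton session
#'
#' Computes total errors (TE) and the three perseveration subtypes from a
#' 50-trial session log:
#' * PSTIM: on an error, the selected disk is the currently filled disk
#'   (the previous target).
#' * PRESP: on an error, the selected disk is the participant's previous
#'   response.  A PRESP error can also count as a PSTIM error.
#' * PRULE: on an error, the selected disk is the one that would have been
#'   correct under the previously active rule (0 before the first rule
#'   change).
#'
#' Out-of-disk responses (sentinel `0`) count toward TE only.
#'
#' @param trials Session log data frame.
#' @return A list of class `brxt_scores` with fields `TE`, `PSTIM`,
#'   `PRESP`, `PRULE`.
#' @export
score_brxt <- function(trials) {
  stopifnot(is.data.frame(trials), nrow(trials) >= 1L)
  n <- nrow(trials)
  stim <- as.integer(trials$stimulus)
  resp <- as.integer(trials$response)
  fb   <- as.integer(trials$feedback)
  rule <- trials$active_rule
  if (any(is.na(stim)) || any(is.na(resp))) stop("malformed BRXT trial log")

  prev_rule <- NA_character_
  pstim <- presp <- prule <- 0L
  for (t in seq_len(n)) {
    if (t > 1L && rule[[t]] != rule[[t - 1L]]) prev_rule <- rule[[t - 1L]]
    if (fb[[t]] != -1L) next
    if (resp[[t]] < 1L || resp[[t]] > 9L) next  # out-of-disk: TE only
    if (resp[[t]] == stim[[t]]) pstim <- pstim + 1L
    if (t > 1L && resp[[t - 1L]] >= 1L && resp[[t]] == resp[[t - 1L]]) {
      presp <- presp + 1L
    }
    if (!is.na(prev_rule) && resp[[t]] == brxt_next_target(prev_rule, stim[[t]])) {
      prule <- prule + 1L
    }
  }
  structure(list(TE = sum(fb == -1L), PSTIM = pstim, PRESP = presp,
                 PRULE = prule), class = "brxt_scores")
}

#' Mean response time conditioned on previous-trial feedback
#'
#' Trial 1 is excluded (it has no prior feedback).  An empty condition
#' yields `NA` for that mean.
#'
#' @param trials Session log data frame with `rt` and `feedback` columns.
#' @return Named numeric vector `c(after_positive, after_negative)`.
#' @export
rt_by_prior_feedback <- function(trials) {
  stopifnot(is.data.frame(trials), nrow(trials) >= 2L)
  prior <- trials$feedback[-nrow(trials)]
  rt    <- trials$rt[-1L]
  c(after_positive = if (any(prior == 1))  mean(rt[prior == 1])  else NA_real_,
    after_negative = if (any(prior == -1)) mean(rt[prior == -1]) else NA_real_)
}

#' Score a bundle of per-participant trial logs into a table
#'
#' @param logs A list of session log data frames (one per participant).
#' @param task `"wcst"` or `"brxt"`.
#' @return A data frame, one row per participant, one column per measure,
#'   plus `rt_pos`/`rt_neg` mean response times by prior feedback.
#' @export
score_table <- function(logs, task = c("wcst", "brxt")) {
  task <- match.arg(task)
  rows <- lapply(seq_along(logs), function(i) {
    log <- logs[[i]]
    rts <- rt_by_prior_feedback(log)
    sc <- if (task == "wcst") unclass(score_wcst(log))[c("TE", "PE", "SL3", "CA")]
          else unclass(score_brxt(log))[c("TE", "PSTIM", "PRESP", "PRULE")]
    c(list(participant_id = if (!is.null(log$participant_id)) log$participant_id[[1L]] else i),
      sc, list(rt_pos = rts[["after_positive"]], rt_neg = rts[["after_negative"]]))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
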