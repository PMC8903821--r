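# JSON serialisation of model configurations, task specs and fitting
# targets (the interchange formats used by the command-line interface).

#' Read and write model parameters, task specs and targets as JSON
#'
#' `write_model_params()`/`read_model_params()` round-trip a full
#' [model_params()] object including the fixed dynamics constants.
#' `write_task()`/`read_task()` round-trip a task descriptor.
#' `read_targets()` reads a fitting-target summary from a JSON object of
#' the form `{"measure": {"mean": ..., "sd": ..., "n": ...}, ...}`,
#' mirroring the published group tables.
#'
#' @param params A [model_params()] object.
#' @param task A [wcst_task()] or [brxt_task()] descriptor.
#' @param path File path.
#' @return The read functions return the reconstructed object.
#' @export
write_model_params <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$cfg <- do.call(bg_loop_cfg, as.list(raw$cfg))
  do.call(model_params, raw[setdiff(names(raw), character(0))])
}

#' @rdname write_model_params
#' @export
write_task <- function(task, path) {
  stopifnot(inherits(task, "bg_task"))
  jsonlite::write_json(unclass(task), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_task <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (raw$name == "wcst") wcst_task(rule_sequence = raw$rule_sequence)
  else brxt_task(rules = raw$rules, start_pos = raw$start_pos)
}

#' @rdname write_model_params
#' @export
read_targets <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  data.frame(
    measure = names(raw),
    mean = vapply(raw, function(x) as.numeric(x$mean), numeric(1L)),
    sd   = vapply(raw, function(x) as.numeric(x$sd), numeric(1L)),
    n    = vapply(raw, function(x) as.integer(x$n), integer(1L)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
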