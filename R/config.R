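#' Read a loop model from a JSON config file
#'
#' The config is a JSON object with exactly the keys
#' `arm_A {gamma, delta, h}`, `arm_P {gamma, delta, h}`, `tau_A`,
#' `tau_P`, `stimulus_mode` (`"gain"` or `"threshold"`) and `stimulus`.
#' Unknown keys are rejected so that typos in parameter names fail loudly
#' rather than silently falling back to defaults.
#'
#' @param path Path to a JSON file (or a JSON string).
#' @return A [loop_model()].
#' @export
read_loop_model <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  allowed <- c("arm_A", "arm_P", "tau_A", "tau_P", "stimulus_mode", "stimulus")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown model config key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(allowed, names(cfg))
  if (length(missing))
    stop("missing model config key(s): ", paste(missing, collapse = ", "))
  arm_keys <- c("gamma", "delta", "h")
  for (nm in c("arm_A", "arm_P")) {
    bad <- setdiff(names(cfg[[nm]]), arm_keys)
    if (length(bad))
      stop("unknown key(s) in ", nm, ": ", paste(bad, collapse = ", "))
  }
  loop_model(arm_A = hill_arm(cfg$arm_A$gamma, cfg$arm_A$delta, cfg$arm_A$h),
             arm_P = hill_arm(cfg$arm_P$gamma, cfg$arm_P$delta, cfg$arm_P$h),
             tau_A = cfg$tau_A, tau_P = cfg$tau_P,
             stimulus_mode = cfg$stimulus_mode,
             stimulus = cfg$stimulus)
}

#' Write a loop model to a JSON config file
#'
#' Inverse of [read_loop_model()]; the round trip preserves all
#' parameters to full double precision.
#'
#' @param model A [loop_model()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_loop_model <- function(model, path) {
  stopifnot(inherits(model, "loop_model"))
  cfg <- list(arm_A = unclass(model$arm_A),
              arm_P = unclass(model$arm_P),
              tau_A = model$tau_A, tau_P = model$tau_P,
              stimulus_mode = model$stimulus_mode,
              stimulus = model$stimulus)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
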