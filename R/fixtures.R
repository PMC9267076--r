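#' Specification for the seeded model sampler
#'
#' Describes how to draw random loop models for testing: a seed, a model
#' count, per-parameter (low, high) bounds and the stimulus-coupling
#' mode. Parameters are drawn log-uniformly so that both weak and strong
#' loops are represented. The defaults span the monostable/bistable
#' boundary of the symmetric model (which sits at `gamma = 2` for
#' `delta = 1`, `h = 2`), so default draws cover both regimes.
#'
#' @param seed Integer seed (Mersenne-Twister, via [set.seed()]).
#' @param n_models Positive number of models to draw.
#' @param ranges Named list of `c(low, high)` bounds for `gamma`,
#'   `delta`, `h`, `tau`; bounds must be positive and the `h` lower
#'   bound at least 1.
#' @param stimulus_mode `"gain"` or `"threshold"`.
#' @return An object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed, n_models = 50L,
                         ranges = list(gamma = c(0.5, 10), delta = c(0.5, 2),
                                       h = c(1, 4), tau = c(0.5, 2)),
                         stimulus_mode = c("gain", "threshold")) {
  stimulus_mode <- match.arg(stimulus_mode)
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(n_models), n_models >= 1L,
            setequal(names(ranges), c("gamma", "delta", "h", "tau")))
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || any(r <= 0) || r[1L] > r[2L])
      stop("invalid range for '", nm, "'")
  }
  if (ranges$h[1L] < 1) stop("'h' lower bound must be >= 1")
  structure(list(seed = as.integer(seed), n_models = as.integer(n_models),
                 ranges = ranges, stimulus_mode = stimulus_mode),
            class = "fixture_spec")
}

# log-uniform draw within c(low, high)
.rlogunif <- function(n, bounds) exp(stats::runif(n, log(bounds[1L]), log(bounds[2L])))

.draw_model <- function(spec) {
  r <- spec$ranges
  loop_model(
    arm_A = hill_arm(.rlogunif(1, r$gamma), .rlogunif(1, r$delta), .rlogunif(1, r$h)),
    arm_P = hill_arm(.rlogunif(1, r$gamma), .rlogunif(1, r$delta), .rlogunif(1, r$h)),
    tau_A = .rlogunif(1, r$tau), tau_P = .rlogunif(1, r$tau),
    stimulus_mode = spec$stimulus_mode, stimulus = 1)
}

#' Sample seeded random loop models
#'
#' Draws `n_models` loop models with parameters log-uniform within the
#' spec's bounds (stimulus fixed at 1), labels each by its regime
#' ([classify_regime()] over [find_equilibria()]), and returns the
#' models with labels. The draw is deterministic given the seed. When
#' the set does not contain both a bistable and a monostable model, the
#' whole set is redrawn (continuing the seeded stream) up to 25 times
#' before failing — with the default ranges a single draw virtually
#' always covers both regimes.
#'
#' The caller's RNG state is saved and restored, so sampling does not
#' perturb outer simulations.
#'
#' @param spec A [fixture_spec()].
#' @param require_both_regimes Enforce regime coverage (default `TRUE`).
#' @return An object of class `"loop_model_sample"`: a list with
#'   `models` (list of [loop_model()]) and `regimes` (character vector
#'   of matching labels).
#' @export
sample_models <- function(spec, require_both_regimes = TRUE) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  max_redraws <- 25L
  for (attempt in seq_len(max_redraws)) {
    models <- replicate(spec$n_models, .draw_model(spec), simplify = FALSE)
    regimes <- vapply(models, function(m) classify_regime(find_equilibria(m)),
                      character(1))
    covered <- any(regimes == "bistable") &&
      any(regimes %in% c("monostable_low", "monostable_high"))
    if (!require_both_regimes || covered)
      return(structure(list(models = models, regimes = regimes, spec = spec),
                       class = "loop_model_sample"))
  }
  stop("fixture coverage failure: no draw of ", spec$n_models, " models in ",
       max_redraws, " attempts contained both a bistable and a monostable model")
}

#' @export
print.loop_model_sample <- function(x, ...) {
  cat(sprintf("Seeded model sample: %d models (seed %d)\n",
              length(x$models), x$spec$seed))
  print(table(regime = x$regimes))
  invisible(x)
}

#' Named reference models
#'
#' A fixed set of models anchoring tests and examples:
#' \describe{
#'   \item{`canonical_bistable`}{symmetric `gamma = 3`, `delta = 1`,
#'     `h = 2`, `tau = 1`, `s = 1` (gain). Bistable with closed-form
#'     asymmetric stable equilibria `((3 +- sqrt(5))/2, (3 -+ sqrt(5))/2)`
#'     and a symmetric saddle whose A solves `A^3 + A - 3 = 0`.}
#'   \item{`subcritical_monostable`}{as above with `gamma = 1`; single
#'     stable symmetric equilibrium `A = P = x*` with `x*(1 + x*^2) = 1`.}
#'   \item{`pitchfork_threshold`}{as above with `gamma = 2`; the
#'     symmetric point `(1, 1)` has a zero eigenvalue — the bistability
#'     threshold.}
#'   \item{`hill1_monostable`}{`gamma = 3`, `h = 1`; Hill coefficient 1
#'     cannot produce bistability (the fixed-point equation is a
#'     quadratic with exactly one nonnegative root).}
#' }
#'
#' @return Named list of [loop_model()] objects.
#' @export
reference_models <- function() {
  sym <- function(gamma, h = 2) {
    arm <- hill_arm(gamma = gamma, delta = 1, h = h)
    loop_model(arm, arm, tau_A = 1, tau_P = 1,
               stimulus_mode = "gain", stimulus = 1)
  }
  list(canonical_bistable     = sym(3),
       subcritical_monostable = sym(1),
       pitchfork_threshold    = sym(2),
       hill1_monostable       = sym(3, h = 1))
}

#' Write a model sample to disk
#'
#' One JSON config per model (`model_001.json`, ...) via
#' [write_loop_model()], plus a manifest CSV `name,regime`.
#'
#' @param sample A `"loop_model_sample"` from [sample_models()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest path.
#' @export
write_model_sample <- function(sample, dir) {
  stopifnot(inherits(sample, "loop_model_sample"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  names <- sprintf("model_%03d", seq_along(sample$models))
  for (i in seq_along(sample$models))
    write_loop_model(sample$models[[i]], file.path(dir, paste0(names[i], ".json")))
  manifest <- data.frame(name = names, regime = sample$regimes)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
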