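#' Double-inhibitory feedback loop model
#'
#' Constructs the planar ODE model of two mutually inhibiting agents,
#' \deqn{\tau_A \dot A + A = g_A(P; s), \qquad \tau_P \dot P + P = g_P(A),}
#' where each `g` is a decreasing Hill arm ([hill_arm()]). In the
#' Alzheimer's-disease reading, `A` lumps the amyloidogenic axis (BACE1
#' through amyloid-beta oligomers, Abo) and `P` is the pool of
#' oligomer-free cellular prion protein (PrPC) that inhibits BACE1.
#' Because the loop contains an even number of inhibitions it acts as
#' positive feedback and can be bistable.
#'
#' A scalar stimulus `s >= 0` models the cyclic-nucleotide (cAMP/cGMP)
#' input that promotes amyloid production. Two coupling modes are
#' supported:
#' \describe{
#'   \item{`"gain"`}{the effective maximal-output parameter of the A arm is
#'     `s * gamma_A` (default; the stimulus scales how much A can be made);}
#'   \item{`"threshold"`}{the effective half-inhibition scale of the A arm is
#'     `delta_A / max(s, 1e-9)` (the stimulus weakens the inhibition of A by
#'     P; the floor `1e-9` keeps the arm well defined at `s = 0`).}
#' }
#' In either mode larger `s` pushes the system toward the high-A
#' (pathogenic) state, and `s` acts as a bifurcation parameter.
#'
#' All quantities are dimensionless; time is measured in units of the
#' relaxation constants, which default to 1.
#'
#' @param arm_A [hill_arm()] for the inhibition of A by P (enters the
#'   A equation).
#' @param arm_P [hill_arm()] for the inhibition of P by A (enters the
#'   P equation).
#' @param tau_A,tau_P Positive relaxation time constants.
#' @param stimulus_mode `"gain"` or `"threshold"` (see Details).
#' @param stimulus Nonnegative scalar stimulus `s`.
#'
#' @return An object of class `"loop_model"`.
#' @examples
#' m <- loop_model(hill_arm(3, 1, 2), hill_arm(3, 1, 2))
#' vector_field(m, c(A = 1, P = 1))
#' @seealso [find_equilibria()], [simulate.loop_model()],
#'   [bifurcation_sweep()], [basin_map()]
#' @export
loop_model <- function(arm_A, arm_P, tau_A = 1, tau_P = 1,
                       stimulus_mode = c("gain", "threshold"),
                       stimulus = 1) {
  stopifnot(inherits(arm_A, "hill_arm"), inherits(arm_P, "hill_arm"),
            is.numeric(tau_A), length(tau_A) == 1L, is.finite(tau_A),
            is.numeric(tau_P), length(tau_P) == 1L, is.finite(tau_P),
            is.numeric(stimulus), length(stimulus) == 1L, is.finite(stimulus))
  stimulus_mode <- match.arg(stimulus_mode)
  if (tau_A <= 0) stop("'tau_A' must be > 0")
  if (tau_P <= 0) stop("'tau_P' must be > 0")
  if (stimulus < 0) stop("'stimulus' must be >= 0")
  structure(list(arm_A = arm_A, arm_P = arm_P,
                 tau_A = as.numeric(tau_A), tau_P = as.numeric(tau_P),
                 stimulus_mode = stimulus_mode,
                 stimulus = as.numeric(stimulus)),
            class = "loop_model")
}

# stimulus floor for threshold mode (documented in ?loop_model)
.stimulus_eps <- 1e-9

#' Stimulus-adjusted A arm
#'
#' Returns the effective [hill_arm()] acting in the A equation once the
#' cAMP/cGMP stimulus has been applied: in gain mode `gamma_A` is scaled
#' by `s`; in threshold mode `delta_A` is divided by `max(s, 1e-9)`.
#' A zero stimulus in gain mode yields a degenerate arm with zero output,
#' represented internally by `gamma = 0` tolerated only here.
#'
#' @param model A [loop_model()].
#' @return A list with fields `gamma`, `delta`, `h` (not validated as a
#'   `hill_arm` because gain mode with `s = 0` legitimately has zero gain).
#' @export
effective_arm_A <- function(model) {
  stopifnot(inherits(model, "loop_model"))
  a <- model$arm_A
  s <- model$stimulus
  if (model$stimulus_mode == "gain") {
    list(gamma = s * a$gamma, delta = a$delta, h = a$h)
  } else {
    list(gamma = a$gamma, delta = a$delta / max(s, .stimulus_eps), h = a$h)
  }
}

# raw Hill evaluation on a plain parameter list (gamma may be 0 for s = 0)
.hill_raw <- function(p, x) p$gamma / (p$delta^p$h + x^p$h)
.hill_raw_deriv <- function(p, x) -p$gamma * p$h * x^(p$h - 1) / (p$delta^p$h + x^p$h)^2

#' Set the stimulus of a loop model
#'
#' Convenience for parameter sweeps: returns a copy of `model` with the
#' stimulus replaced.
#'
#' @inheritParams effective_arm_A
#' @param s New nonnegative stimulus value.
#' @return A [loop_model()].
#' @export
set_stimulus <- function(model, s) {
  stopifnot(inherits(model, "loop_model"),
            is.numeric(s), length(s) == 1L, is.finite(s), s >= 0)
  model$stimulus <- as.numeric(s)
  model
}

#' Forward-invariant box of a loop model
#'
#' The rectangle `[0, max g_A] x [0, max g_P]` (with the A arm
#' stimulus-adjusted) is forward invariant: on its boundary the flow
#' points inward, so trajectories starting inside stay inside. Its upper
#' corners bound all equilibria.
#'
#' @inheritParams effective_arm_A
#' @return Named numeric vector `c(A_max = , P_max = )`.
#' @export
invariant_box <- function(model) {
  stopifnot(inherits(model, "loop_model"))
  eA <- effective_arm_A(model)
  c(A_max = eA$gamma / eA$delta^eA$h, P_max = hill_max(model$arm_P))
}

#' Vector field of the loop
#'
#' Evaluates the right-hand side of the loop ODEs at a state:
#' `dA/dt = (g_A(P; s) - A) / tau_A`, `dP/dt = (g_P(A) - P) / tau_P`.
#'
#' @inheritParams effective_arm_A
#' @param state Numeric vector `c(A, P)` with nonnegative entries (names
#'   optional).
#' @return Named numeric vector `c(dA = , dP = )`.
#' @export
vector_field <- function(model, state) {
  stopifnot(inherits(model, "loop_model"), is.numeric(state), length(state) == 2L)
  if (any(state < 0)) stop("state must satisfy A >= 0, P >= 0")
  A <- state[[1]]; P <- state[[2]]
  eA <- effective_arm_A(model)
  c(dA = (.hill_raw(eA, P) - A) / model$tau_A,
    dP = (hill(model$arm_P, A) - P) / model$tau_P)
}

#' Jacobian of the loop vector field
#'
#' Analytic linearization at a state:
#' `[[-1/tau_A, g_A'(P)/tau_A], [g_P'(A)/tau_P, -1/tau_P]]`.
#' The diagonal (relaxation) entries are strictly negative and the
#' off-diagonal entries are `<= 0` (strictly negative for positive
#' states), reflecting the monotone double-inhibition structure.
#'
#' @inheritParams vector_field
#' @return A 2x2 numeric matrix, rows ordered (A, P).
#' @export
jacobian <- function(model, state) {
  stopifnot(inherits(model, "loop_model"), is.numeric(state), length(state) == 2L)
  if (any(state < 0)) stop("state must satisfy A >= 0, P >= 0")
  A <- state[[1]]; P <- state[[2]]
  eA <- effective_arm_A(model)
  matrix(c(-1 / model$tau_A,                  .hill_raw_deriv(eA, P) / model$tau_A,
           hill_deriv(model$arm_P, A) / model$tau_P, -1 / model$tau_P),
         nrow = 2L, byrow = TRUE,
         dimnames = list(c("A", "P"), c("A", "P")))
}

#' @export
print.loop_model <- function(x, ...) {
  eA <- effective_arm_A(x)
  cat("Double-inhibitory loop model (PrPC vs BACE1/Abeta axis)\n")
  cat(sprintf("  A arm (P -| A): gamma = %.6g, delta = %.6g, h = %.6g\n",
              x$arm_A$gamma, x$arm_A$delta, x$arm_A$h))
  cat(sprintf("  P arm (A -| P): gamma = %.6g, delta = %.6g, h = %.6g\n",
              x$arm_P$gamma, x$arm_P$delta, x$arm_P$h))
  cat(sprintf("  tau_A = %.6g, tau_P = %.6g\n", x$tau_A, x$tau_P))
  cat(sprintf("  stimulus s = %.6g (%s mode; effective A arm gamma = %.6g, delta = %.6g)\n",
              x$stimulus, x$stimulus_mode, eA$gamma, eA$delta))
  invisible(x)
}

#' @export
summary.loop_model <- function(object, ...) {
  print(object)
  eq <- find_equilibria(object)
  cat("\n")
  print(eq)
  invisible(eq)
}

#' Phase-plane plot of a loop model
#'
#' Draws the two nullclines `A = g_A(P; s)` and `P = g_P(A)` over the
#' invariant box and marks the equilibria (filled circles stable, open
#' circles saddle/unstable).
#'
#' @param x A [loop_model()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the equilibria of the model.
#' @export
plot.loop_model <- function(x, ...) {
  box <- invariant_box(x)
  eq <- find_equilibria(x)
  eA <- effective_arm_A(x)
  P_grid <- seq(0, max(box[["P_max"]], 1e-6), length.out = 400L)
  A_grid <- seq(0, max(box[["A_max"]], 1e-6), length.out = 400L)
  graphics::plot(NA, xlim = range(A_grid), ylim = range(P_grid),
                 xlab = "A (BACE1/Abeta axis)", ylab = "P (free PrPC)", ...)
  graphics::lines(.hill_raw(eA, P_grid), P_grid, col = "steelblue")
  graphics::lines(A_grid, hill(x$arm_P, A_grid), col = "firebrick")
  stable <- eq$stability == "stable"
  graphics::points(eq$A[stable], eq$P[stable], pch = 19)
  graphics::points(eq$A[!stable], eq$P[!stable], pch = 1)
  graphics::legend("topright", bty = "n", lty = 1,
                   col = c("steelblue", "firebrick"),
                   legend = c("A-nullcline", "P-nullcline"))
  invisible(eq)
}
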