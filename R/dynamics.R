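# deSolve right-hand side; tiny negative excursions from the integrator are
# evaluated at 0 so the Hill arms stay in-domain.
.loop_rhs <- function(t, y, model) {
  A <- max(y[[1]], 0); P <- max(y[[2]], 0)
  eA <- effective_arm_A(model)
  list(c((.hill_raw(eA, P) - A) / model$tau_A,
         (hill(model$arm_P, A) - P) / model$tau_P))
}

#' Integrate the loop ODEs
#'
#' Solves the initial-value problem for a [loop_model()] with an adaptive
#' variable-step integrator (LSODA via \pkg{deSolve}), reporting the
#' solution on a uniform output grid. Local error per step is controlled
#' to `rtol * |state| + atol`. States that come out negative by less than
#' `atol` (integrator round-off below an absorbing axis) are clipped to
#' 0; larger negativity signals an integration fault and is an error.
#'
#' @param model A [loop_model()].
#' @param initial Numeric `c(A, P)`, nonnegative initial state.
#' @param t_end Positive end time (in units of the relaxation constants).
#' @param rtol,atol Relative and absolute local error tolerances.
#' @param n_out Number of output rows (uniform time grid including 0).
#' @return An object of class `"loop_trajectory"`: a data frame with
#'   columns `t`, `A`, `P`, plus attributes `final_state` (named vector)
#'   and `converged` (`TRUE` if the vector-field norm at the final state
#'   is below `sqrt(atol)`).
#' @examples
#' m <- reference_models()$canonical_bistable
#' tr <- integrate_loop(m, c(2.5, 0.5), t_end = 50)
#' tail(tr, 1)  # near the high-A attractor ((3 + sqrt(5))/2, (3 - sqrt(5))/2)
#' @export
integrate_loop <- function(model, initial, t_end, rtol = 1e-8, atol = 1e-10,
                           n_out = 201L) {
  stopifnot(inherits(model, "loop_model"),
            is.numeric(initial), length(initial) == 2L, all(initial >= 0),
            t_end > 0, rtol > 0, atol > 0, n_out >= 2L)
  times <- seq(0, t_end, length.out = n_out)
  out <- deSolve::ode(y = c(A = initial[[1]], P = initial[[2]]), times = times,
                      func = .loop_rhs, parms = model, method = "lsoda",
                      rtol = rtol, atol = atol)
  diagn <- attr(out, "istate")
  if (!is.null(diagn) && diagn[1L] < 0)
    stop(sprintf("integration failed at t = %.6g (lsoda istate %d)",
                 max(out[, "time"]), diagn[1L]))
  out <- as.data.frame(out)
  names(out) <- c("t", "A", "P")
  for (v in c("A", "P")) {
    neg <- out[[v]] < 0
    if (any(out[[v]] < -atol))
      stop("state went negative beyond atol during integration: min ",
           min(out[[v]]))
    out[[v]][neg] <- 0
  }
  final <- c(A = out$A[nrow(out)], P = out$P[nrow(out)])
  structure(out,
            final_state = final,
            converged = sqrt(sum(vector_field(model, final)^2)) < sqrt(atol),
            model = model,
            class = c("loop_trajectory", "data.frame"))
}

#' Run a loop model to steady state
#'
#' Integrates forward until the Euclidean norm of the vector field at the
#' current state falls below `tol`, or `max_time` is reached. The
#' stopping criterion is the vector-field norm, not state displacement,
#' so a slow transit past a saddle is not mistaken for convergence.
#' Implemented with LSODAR's root-finding so the integration halts
#' exactly when the criterion is met.
#'
#' @inheritParams integrate_loop
#' @param max_time Time budget for convergence.
#' @param tol Vector-field norm threshold declaring a steady state.
#' @return A list with `state` (named numeric `c(A, P)`) and `converged`
#'   (logical).
#' @examples
#' m <- reference_models()$canonical_bistable
#' run_to_steady_state(m, c(0.1, 3))$state  # the high-P (physiological) attractor
#' @export
run_to_steady_state <- function(model, initial, max_time = 1e4, tol = 1e-9,
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "loop_model"),
            is.numeric(initial), length(initial) == 2L, all(initial >= 0),
            max_time > 0, tol > 0)
  y0 <- c(A = initial[[1]], P = initial[[2]])
  norm0 <- sqrt(sum(vector_field(model, y0)^2))
  if (norm0 < tol) return(list(state = y0, converged = TRUE))
  rootfun <- function(t, y, model) {
    v <- .loop_rhs(t, y, model)[[1]]
    sqrt(sum(v^2)) - tol
  }
  out <- deSolve::lsodar(y = y0, times = c(0, max_time), func = .loop_rhs,
                         parms = model, rtol = rtol, atol = atol,
                         rootfunc = rootfun)
  diagn <- attr(out, "istate")
  if (!is.null(diagn) && diagn[1L] < 0)
    stop(sprintf("integration failed at t = %.6g (lsodar istate %d)",
                 max(out[, "time"]), diagn[1L]))
  last <- out[nrow(out), ]
  state <- pmax(c(A = last[["A"]], P = last[["P"]]), 0)
  converged <- sqrt(sum(vector_field(model, state)^2)) < tol * (1 + 1e-6)
  list(state = state, converged = converged)
}

#' Simulate a loop model
#'
#' [stats::simulate()] method wrapping [integrate_loop()]. The model is
#' deterministic, so `nsim` and `seed` are accepted for interface
#' compatibility but a single trajectory is returned.
#'
#' @param object A [loop_model()].
#' @param nsim,seed Ignored (deterministic model); present for the
#'   generic's signature.
#' @param initial,t_end,... Passed to [integrate_loop()].
#' @return A `"loop_trajectory"` data frame.
#' @export
simulate.loop_model <- function(object, nsim = 1, seed = NULL,
                                initial = c(1, 1), t_end = 100, ...) {
  integrate_loop(object, initial = initial, t_end = t_end, ...)
}

#' @export
print.loop_trajectory <- function(x, ...) {
  fs <- attr(x, "final_state")
  cat(sprintf("Loop trajectory: %d points on t in [%.6g, %.6g]\n",
              nrow(x), x$t[1], x$t[nrow(x)]))
  cat(sprintf("  final state A = %.8g, P = %.8g (converged: %s)\n",
              fs[["A"]], fs[["P"]], attr(x, "converged")))
  invisible(x)
}

#' Plot a loop trajectory
#'
#' Time courses of A and P.
#'
#' @param x A `"loop_trajectory"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.loop_trajectory <- function(x, ...) {
  graphics::matplot(x$t, cbind(x$A, x$P), type = "l", lty = 1,
                    col = c("firebrick", "steelblue"),
                    xlab = "time", ylab = "activity", ...)
  graphics::legend("right", bty = "n", lty = 1,
                   col = c("firebrick", "steelblue"), legend = c("A", "P"))
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' Header `t,A,P`, one row per output point, 17 significant digits so the
#' file round-trips to full double precision.
#'
#' @param trajectory A `"loop_trajectory"`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "loop_trajectory"))
  .write_csv_precise(trajectory[, c("t", "A", "P")], path)
}

# shared CSV writer: fixed column order, one-line header, 17 sig digits
.write_csv_precise <- function(df, path) {
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) format(col, digits = 17, scientific = NA, trim = TRUE)
    else as.character(col)
  }, FUN.VALUE = character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L, dimnames = list(NULL, names(df)))
  utils::write.table(fmt, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = names(df))
  invisible(path)
}
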