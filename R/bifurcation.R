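#' Classify the multistability regime from an equilibrium set
#'
#' `"bistable"` when exactly 2 stable equilibria coexist (plus the
#' separating saddle). With a single stable equilibrium, the regime is
#' `"monostable_low"` or `"monostable_high"` according to whether its A
#' value lies below or above the geometric mean of the invariant-box
#' bounds `sqrt(A_max * P_max)` — a scale-free midpoint for the
#' dimensionless activities. Marginal points (folds) are not counted as
#' stable.
#'
#' @param equilibria A `"loop_equilibria"` object from [find_equilibria()].
#' @return One of `"monostable_low"`, `"bistable"`, `"monostable_high"`.
#' @export
classify_regime <- function(equilibria) {
  stopifnot(inherits(equilibria, "loop_equilibria"), nrow(equilibria) >= 1L)
  model <- attr(equilibria, "model")
  n_stable <- sum(equilibria$stability == "stable")
  if (n_stable == 0L)
    stop("no stable equilibria: cannot occur for Hill double-inhibitory ",
         "loops away from folds; indicates an upstream numerics problem")
  if (n_stable == 2L) return("bistable")
  if (n_stable > 2L)
    stop("more than 2 stable equilibria: outside the single-Hill model class")
  box <- invariant_box(model)
  mid <- sqrt(max(box[["A_max"]], .Machine$double.xmin) * box[["P_max"]])
  A_st <- equilibria$A[equilibria$stability == "stable"]
  if (A_st < mid) "monostable_low" else "monostable_high"
}

#' Bifurcation diagram over the cAMP/cGMP stimulus
#'
#' Sweeps the stimulus `s` over `[s_min, s_max]`, running
#' [find_equilibria()] at each grid value, and assembles the equilibrium
#' branches, the saddle-node (fold) points and the regime labels — the
#' computational content of the classic S-shaped steady-state curve of
#' the pathogenic variable versus stimulus. Folds are located by
#' bisection on the stimulus between adjacent grid points where the
#' equilibrium count changes, refined to a stimulus tolerance of `1e-6`;
#' the fold's A value is taken as the midpoint of the merging
#' stable/saddle pair on the bistable side.
#'
#' @param model_base A [loop_model()]; its `stimulus` field is overridden
#'   along the sweep.
#' @param s_min,s_max Sweep bounds, `0 <= s_min < s_max`.
#' @param n_points Number of stimulus grid points (`>= 50`; the
#'   degenerate case `s_max - s_min < 1e-9` collapses to one point).
#' @param grid_n Passed to [find_equilibria()].
#' @return An object of class `"bifurcation_diagram"` with fields
#'   `stimulus_grid`, `branches` (data frame `s, A, P, stability`),
#'   `folds` (data frame `s_fold, A_fold`) and `regimes` (data frame
#'   `s_lo, s_hi, regime`).
#' @examples
#' \donttest{
#' bd <- bifurcation_sweep(reference_models()$canonical_bistable, 0.1, 2)
#' bd$regimes   # monostable_low -> bistable -> monostable_high
#' }
#' @export
bifurcation_sweep <- function(model_base, s_min, s_max, n_points = 101L,
                              grid_n = 2000L) {
  stopifnot(inherits(model_base, "loop_model"),
            s_min >= 0, s_max > s_min)
  degenerate <- (s_max - s_min) < 1e-9
  if (!degenerate) stopifnot(n_points >= 50L)
  s_grid <- if (degenerate) s_min else seq(s_min, s_max, length.out = as.integer(n_points))
  eqs <- lapply(s_grid, function(s)
    find_equilibria(set_stimulus(model_base, s), grid_n = grid_n))
  counts <- vapply(eqs, nrow, integer(1))
  regimes_pt <- vapply(eqs, classify_regime, character(1))

  branches <- do.call(rbind, Map(function(s, eq)
    data.frame(s = s, A = eq$A, P = eq$P, stability = eq$stability),
    s_grid, eqs))
  rownames(branches) <- NULL

  folds <- data.frame(s_fold = numeric(0), A_fold = numeric(0))
  if (!degenerate) {
    for (i in seq_len(length(s_grid) - 1L)) {
      dc <- counts[i + 1L] - counts[i]
      if (dc == 0L) next
      if (abs(dc) > 2L)
        stop("equilibrium count changes by more than 2 between adjacent ",
             "stimulus points; the sweep grid is too coarse - increase n_points")
      lo <- s_grid[i]; hi <- s_grid[i + 1L]
      n_lo <- counts[i]
      # bisect on the count transition
      while ((hi - lo) > 1e-6) {
        mid <- (lo + hi) / 2
        n_mid <- nrow(find_equilibria(set_stimulus(model_base, mid),
                                      grid_n = grid_n))
        if (n_mid == n_lo) lo <- mid else hi <- mid
      }
      s_fold <- (lo + hi) / 2
      # A at the fold: closest stable/saddle pair on the 3-equilibria side
      s_tri <- if (counts[i] > counts[i + 1L]) lo else hi
      eq_tri <- find_equilibria(set_stimulus(model_base, s_tri), grid_n = grid_n)
      if (nrow(eq_tri) >= 2L) {
        gaps <- diff(eq_tri$A)
        j <- which.min(gaps)
        A_fold <- mean(eq_tri$A[c(j, j + 1L)])
      } else A_fold <- eq_tri$A[1L]
      folds <- rbind(folds, data.frame(s_fold = s_fold, A_fold = A_fold))
    }
  }

  # merge consecutive grid points of equal regime into intervals
  r <- rle(regimes_pt)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  regimes <- data.frame(s_lo = s_grid[starts], s_hi = s_grid[ends],
                        regime = r$values)

  structure(list(stimulus_grid = s_grid, branches = branches,
                 folds = folds, regimes = regimes, model_base = model_base),
            class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("Bifurcation diagram: %d stimulus points in [%.6g, %.6g], %d fold(s)\n",
              length(x$stimulus_grid), min(x$stimulus_grid),
              max(x$stimulus_grid), nrow(x$folds)))
  if (nrow(x$folds))
    cat(sprintf("  fold at s = %.6g (A = %.6g)\n", x$folds$s_fold, x$folds$A_fold),
        sep = "")
  cat("Regimes:\n")
  print.data.frame(x$regimes, row.names = FALSE)
  invisible(x)
}

#' Plot a bifurcation diagram
#'
#' Settled-A branches versus stimulus: stable branches as solid green
#' curves, the unstable (saddle) branch dashed red, folds as open
#' circles — the conventional rendering of a bistable S-curve.
#'
#' @param x A `"bifurcation_diagram"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bifurcation_diagram <- function(x, ...) {
  b <- x$branches
  graphics::plot(NA, xlim = range(x$stimulus_grid), ylim = range(b$A),
                 xlab = "cAMP/cGMP stimulus s", ylab = "steady-state A", ...)
  st <- b$stability == "stable"
  graphics::points(b$s[st], b$A[st], pch = 16, cex = 0.4, col = "forestgreen")
  graphics::points(b$s[!st], b$A[!st], pch = 16, cex = 0.4, col = "red")
  if (nrow(x$folds))
    graphics::points(x$folds$s_fold, x$folds$A_fold, pch = 1, cex = 1.4)
  invisible(x)
}

#' Quasi-static hysteresis protocol
#'
#' Emulates a slow up-then-down sweep of the cyclic-nucleotide stimulus:
#' starting from the (lowest-A) steady state at `s_min`, the stimulus is
#' stepped up across `n_steps` values, re-settling with
#' [run_to_steady_state()] at each step using the previous settled state
#' as the initial condition; the down sweep then returns from `s_max`
#' continuing from the last settled state. Jumps — the signature of
#' crossing a fold — are flagged where the settled A changes between
#' consecutive steps by more than `jump_frac` of the total A range of the
#' protocol. In a bistable window the down-sweep jump occurs at a lower
#' stimulus than the up-sweep jump (hysteresis).
#'
#' @param model_base A [loop_model()].
#' @param s_min,s_max Sweep bounds.
#' @param n_steps Number of stimulus steps per sweep (`>= 10`).
#' @param settle_time Time budget for settling at each step.
#' @param jump_frac Jump threshold as a fraction of the overall A range.
#'   Folds in this model class produce order-one jumps, far above
#'   numerical drift, so the default 0.25 separates them cleanly.
#' @param tol Steady-state tolerance per step.
#' @return An object of class `"hysteresis_result"` with data frames
#'   `up_sweep` and `down_sweep` (`s`, `A`, `P`) and scalars `jump_up_at`
#'   and `jump_down_at` (`NA` if no jump); a jump is reported at the
#'   stimulus value just after the transition.
#' @export
hysteresis <- function(model_base, s_min, s_max, n_steps = 200L,
                       settle_time = 1e4, jump_frac = 0.25, tol = 1e-9) {
  stopifnot(inherits(model_base, "loop_model"),
            s_min >= 0, s_max > s_min, n_steps >= 10L)
  s_up <- seq(s_min, s_max, length.out = as.integer(n_steps))
  eq0 <- find_equilibria(set_stimulus(model_base, s_min))
  stable0 <- eq0[eq0$stability == "stable", , drop = FALSE]
  state <- c(A = stable0$A[1L], P = stable0$P[1L])  # lowest-A stable start

  settle <- function(s, state) {
    res <- run_to_steady_state(set_stimulus(model_base, s), state,
                               max_time = settle_time, tol = tol)
    if (!res$converged)
      stop(sprintf("hysteresis protocol failed to settle at stimulus s = %.8g",
                   s))
    res$state
  }
  up <- matrix(NA_real_, nrow = length(s_up), ncol = 2L)
  for (i in seq_along(s_up)) {
    state <- settle(s_up[i], state)
    up[i, ] <- state
  }
  s_down <- rev(s_up)
  down <- matrix(NA_real_, nrow = length(s_down), ncol = 2L)
  for (i in seq_along(s_down)) {
    state <- settle(s_down[i], state)
    down[i, ] <- state
  }
  A_range <- diff(range(c(up[, 1L], down[, 1L])))
  thr <- jump_frac * A_range
  find_jump <- function(svec, Avec) {
    j <- which(abs(diff(Avec)) > thr)
    if (length(j)) svec[j[1L] + 1L] else NA_real_
  }
  structure(list(
    up_sweep = data.frame(s = s_up, A = up[, 1L], P = up[, 2L]),
    down_sweep = data.frame(s = s_down, A = down[, 1L], P = down[, 2L]),
    jump_up_at = find_jump(s_up, up[, 1L]),
    jump_down_at = find_jump(s_down, down[, 1L]),
    step_width = if (length(s_up) > 1L) s_up[2L] - s_up[1L] else 0,
    model_base = model_base),
    class = "hysteresis_result")
}

#' @export
print.hysteresis_result <- function(x, ...) {
  cat(sprintf("Hysteresis protocol: %d steps over s in [%.6g, %.6g]\n",
              nrow(x$up_sweep), min(x$up_sweep$s), max(x$up_sweep$s)))
  cat(sprintf("  jump up at   s = %s\n  jump down at s = %s\n",
              format(x$jump_up_at, digits = 8), format(x$jump_down_at, digits = 8)))
  invisible(x)
}

#' Plot a hysteresis loop
#'
#' Settled A versus stimulus for the up (solid) and down (dashed) sweeps.
#'
#' @param x A `"hysteresis_result"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hysteresis_result <- function(x, ...) {
  graphics::plot(x$up_sweep$s, x$up_sweep$A, type = "l", col = "firebrick",
                 xlab = "cAMP/cGMP stimulus s", ylab = "settled A", ...)
  graphics::lines(x$down_sweep$s, x$down_sweep$A, lty = 2, col = "steelblue")
  graphics::legend("topleft", bty = "n", lty = c(1, 2),
                   col = c("firebrick", "steelblue"),
                   legend = c("up sweep", "down sweep"))
  invisible(x)
}
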