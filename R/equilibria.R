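#' Composed fixed-point residual
#'
#' Equilibria of the loop satisfy `A = g_A(P; s)` and `P = g_P(A)`;
#' substituting the second into the first reduces the 2-D fixed-point
#' problem to a scalar one. This function evaluates
#' `F(a) = g_A(g_P(a); s) - a`, whose roots are in one-to-one
#' correspondence with equilibria `(A*, P* = g_P(A*))`. Because
#' `g_A(g_P(.))` is an increasing bounded map (composition of two
#' decreasing maps), `F(0) > 0` and `F(a) < 0` above `max g_A`, so at
#' least one root always exists.
#'
#' @param model A [loop_model()].
#' @param a Numeric vector of nonnegative candidate A values.
#' @return Numeric vector `F(a)`.
#' @export
composed_residual <- function(model, a) {
  stopifnot(inherits(model, "loop_model"), is.numeric(a))
  if (any(a < 0)) stop("composed_residual() is defined for a >= 0 only")
  eA <- effective_arm_A(model)
  .hill_raw(eA, hill(model$arm_P, a)) - a
}

# plain bisection on a bracketing interval of f; returns the midpoint once
# the bracket is narrower than xtol
.bisect <- function(f, lo, hi, xtol = 1e-10, max_iter = 200L) {
  flo <- f(lo); fhi <- f(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (sign(flo) == sign(fhi)) stop("bisection bracket does not straddle a root")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0 || (hi - lo) < xtol) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

#' Classify linear stability from eigenvalues
#'
#' Standard planar classification from the Jacobian eigenvalues:
#' `"stable"` if both real parts are below `-tol_marginal`, `"saddle"`
#' if the real parts straddle zero by more than the tolerance,
#' `"unstable"` if both exceed `+tol_marginal`, and `"marginal"` when the
#' leading real part sits within the tolerance band around zero (the
#' fold / pitchfork threshold case).
#'
#' @param eigs Complex (or numeric) vector of length 2: eigenvalues of a
#'   real 2x2 matrix.
#' @param tol_marginal Half-width of the marginal band around zero.
#' @return One of `"stable"`, `"saddle"`, `"unstable"`, `"marginal"`.
#' @export
classify_stability <- function(eigs, tol_marginal = 1e-6) {
  stopifnot(length(eigs) == 2L)
  re <- Re(eigs)
  if (all(re < -tol_marginal)) return("stable")
  if (all(re > tol_marginal)) return("unstable")
  if (max(re) > tol_marginal && min(re) < -tol_marginal) return("saddle")
  "marginal"
}

#' Find all equilibria of a loop model
#'
#' Locates every equilibrium by bracketing sign changes of the
#' [composed_residual()] on a uniform grid over `[0, 1.05 * max g_A]`,
#' refining each bracket by bisection to an interval width of `1e-10`,
#' and de-duplicating roots closer than `1e-8`. Each root `A*` is lifted
#' to the state `(A*, g_P(A*))`, the Jacobian eigenvalues are attached,
#' and the point is classified with [classify_stability()]. The 1-D
#' reduction is exhaustive for this monotone loop structure, unlike a 2-D
#' Newton search, which can diverge depending on the starting basin.
#'
#' A grid too coarse to separate nearly-coincident roots (e.g. just past
#' a fold) is not detected automatically; increase `grid_n` when working
#' close to a bifurcation point. At an exact fold the merged double root
#' is reported once, classified `"marginal"`.
#'
#' @param model A [loop_model()].
#' @param grid_n Number of grid points for bracketing (`>= 100`).
#' @param tol_marginal Passed to [classify_stability()].
#' @return An object of class `"loop_equilibria"`: a data frame with one
#'   row per equilibrium, sorted by `A` ascending, with columns `A`, `P`,
#'   `eig1`, `eig2` (complex) and `stability`, and the model stored as an
#'   attribute.
#' @examples
#' eq <- find_equilibria(reference_models()$canonical_bistable)
#' eq$stability                 # "stable" "saddle" "stable"
#' eq$A[c(1, 3)]                # (3 -+ sqrt(5))/2
#' @export
find_equilibria <- function(model, grid_n = 2000L, tol_marginal = 1e-6) {
  stopifnot(inherits(model, "loop_model"), grid_n >= 100L)
  eA <- effective_arm_A(model)
  a_max <- eA$gamma / eA$delta^eA$h
  if (a_max <= 0) {
    # zero-gain degenerate case (s = 0 in gain mode): A* = 0 exactly
    roots <- 0
  } else {
    grid <- seq(0, 1.05 * a_max, length.out = as.integer(grid_n))
    Fv <- composed_residual(model, grid)
    roots <- grid[Fv == 0]
    idx <- which(sign(Fv[-length(Fv)]) * sign(Fv[-1]) < 0)
    f <- function(a) composed_residual(model, a)
    refined <- vapply(idx, function(i) .bisect(f, grid[i], grid[i + 1L]),
                      numeric(1))
    roots <- sort(c(roots, refined))
    if (length(roots) > 1L)
      roots <- roots[c(TRUE, diff(roots) > 1e-8)]
  }
  if (length(roots) == 0L)
    stop("no equilibria found: impossible by the sign structure of the ",
         "composed residual; this indicates a numerics bug")
  rows <- lapply(roots, function(a) {
    st <- c(A = a, P = hill(model$arm_P, a))
    ev <- eigen(jacobian(model, st), only.values = TRUE)$values
    ev <- ev[order(-Re(ev))]
    if (is.numeric(ev)) ev <- as.complex(ev)
    data.frame(A = st[["A"]], P = st[["P"]],
               eig1 = ev[1], eig2 = ev[2],
               stability = classify_stability(ev, tol_marginal),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, model = model,
            class = c("loop_equilibria", "data.frame"))
}

#' @export
print.loop_equilibria <- function(x, ...) {
  cat(sprintf("Equilibria: %d (%d stable, %d saddle, %d unstable, %d marginal)\n",
              nrow(x), sum(x$stability == "stable"),
              sum(x$stability == "saddle"), sum(x$stability == "unstable"),
              sum(x$stability == "marginal")))
  df <- data.frame(A = signif(x$A, 8), P = signif(x$P, 8),
                   `Re(eig1)` = signif(Re(x$eig1), 6),
                   `Re(eig2)` = signif(Re(x$eig2), 6),
                   stability = x$stability, check.names = FALSE)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Write equilibria to CSV
#'
#' Columns `A,P,eig1_re,eig1_im,eig2_re,eig2_im,stability`, 17
#' significant digits.
#'
#' @param equilibria A `"loop_equilibria"` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_equilibria_csv <- function(equilibria, path) {
  stopifnot(inherits(equilibria, "loop_equilibria"))
  df <- data.frame(A = equilibria$A, P = equilibria$P,
                   eig1_re = Re(equilibria$eig1), eig1_im = Im(equilibria$eig1),
                   eig2_re = Re(equilibria$eig2), eig2_im = Im(equilibria$eig2),
                   stability = equilibria$stability)
  .write_csv_precise(df, path)
}
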