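#' Map attraction basins in the P/A plane
#'
#' Lays a uniform grid of initial conditions over the invariant box and
#' integrates each to steady state ([run_to_steady_state()]), labelling
#' every cell by the stable equilibrium it reaches (within a matching
#' tolerance of `1e-4`). Cells that do not converge within `max_time` —
#' in practice only those starting on or extremely close to the
#' separatrix, the saddle's stable manifold — are left unresolved rather
#' than force-assigned. Assignment is by forward integration, which is
#' robust and treats cells independently; backward manifold tracing is a
#' possible refinement, not implemented.
#'
#' @param model A [loop_model()] with at least one stable equilibrium.
#' @param n_A,n_P Grid resolution along A and P (`>= 10`).
#' @param max_time Settling budget per cell.
#' @param tol Steady-state tolerance per cell.
#' @return An object of class `"basin_map"` with fields `A_grid`,
#'   `P_grid`, `labels` (an `n_A x n_P` integer matrix indexing
#'   `attractors`, `NA` for unresolved cells), `attractors` (data frame
#'   of the stable equilibria) and `saddle` (data frame, possibly empty).
#' @examples
#' \donttest{
#' bm <- basin_map(reference_models()$canonical_bistable, 25, 25)
#' table(bm$labels, useNA = "ifany")
#' }
#' @export
basin_map <- function(model, n_A = 50L, n_P = 50L, max_time = 1e4,
                      tol = 1e-9) {
  stopifnot(inherits(model, "loop_model"), n_A >= 10L, n_P >= 10L)
  eq <- find_equilibria(model)
  att <- eq[eq$stability == "stable", , drop = FALSE]
  if (nrow(att) == 0L)
    stop("model has no stable equilibria; basin mapping is undefined")
  box <- invariant_box(model)
  A_grid <- seq(0, box[["A_max"]], length.out = as.integer(n_A))
  P_grid <- seq(0, box[["P_max"]], length.out = as.integer(n_P))
  labels <- matrix(NA_integer_, nrow = n_A, ncol = n_P)
  for (i in seq_len(n_A)) {
    for (j in seq_len(n_P)) {
      res <- run_to_steady_state(model, c(A_grid[i], P_grid[j]),
                                 max_time = max_time, tol = tol)
      if (!res$converged) next
      d <- sqrt((att$A - res$state[["A"]])^2 + (att$P - res$state[["P"]])^2)
      k <- which.min(d)
      if (d[k] < 1e-4) labels[i, j] <- k
    }
  }
  structure(list(A_grid = A_grid, P_grid = P_grid, labels = labels,
                 attractors = as.data.frame(att[, c("A", "P")]),
                 saddle = as.data.frame(eq[eq$stability == "saddle",
                                           c("A", "P"), drop = FALSE]),
                 model = model),
            class = "basin_map")
}

#' Estimate the separatrix from a basin map
#'
#' Returns the midpoints of every grid edge whose two cells carry
#' different resolved labels, ordered along the diagonal direction
#' `A + P` (the direction in which the separatrix of a double-negative
#' loop is traversed). An unresolved cell whose two neighbours along a
#' grid axis belong to different basins lies on the boundary itself and
#' contributes its own coordinates (this covers grids where the
#' separatrix passes exactly through a line of cells, which then never
#' resolve). The polyline approximates the saddle's stable manifold and
#' passes within one grid cell of the saddle.
#'
#' @param map A `"basin_map"` with exactly 2 attractors.
#' @return A data frame with columns `A`, `P` (ordered polyline vertices).
#' @export
separatrix_estimate <- function(map) {
  stopifnot(inherits(map, "basin_map"))
  if (nrow(map$attractors) != 2L)
    stop("separatrix_estimate() requires a map with exactly 2 attractors, got ",
         nrow(map$attractors))
  L <- map$labels
  nA <- length(map$A_grid); nP <- length(map$P_grid)
  pts <- list()
  # vertical edges (neighbours along A)
  dif <- L[-1L, , drop = FALSE] != L[-nA, , drop = FALSE]
  idx <- which(dif & !is.na(dif), arr.ind = TRUE)
  if (nrow(idx))
    pts[[1L]] <- cbind(A = (map$A_grid[idx[, 1L]] + map$A_grid[idx[, 1L] + 1L]) / 2,
                       P = map$P_grid[idx[, 2L]])
  # horizontal edges (neighbours along P)
  dif <- L[, -1L, drop = FALSE] != L[, -nP, drop = FALSE]
  idx <- which(dif & !is.na(dif), arr.ind = TRUE)
  if (nrow(idx))
    pts[[2L]] <- cbind(A = map$A_grid[idx[, 1L]],
                       P = (map$P_grid[idx[, 2L]] + map$P_grid[idx[, 2L] + 1L]) / 2)
  # unresolved cells bridging the two basins along either axis
  if (nA >= 3L) {
    mid_na <- is.na(L[2:(nA - 1L), , drop = FALSE]) &
      !is.na(L[1:(nA - 2L), , drop = FALSE]) &
      !is.na(L[3:nA, , drop = FALSE]) &
      L[1:(nA - 2L), , drop = FALSE] != L[3:nA, , drop = FALSE]
    idx <- which(mid_na, arr.ind = TRUE)
    if (nrow(idx))
      pts[[3L]] <- cbind(A = map$A_grid[idx[, 1L] + 1L], P = map$P_grid[idx[, 2L]])
  }
  if (nP >= 3L) {
    mid_na <- is.na(L[, 2:(nP - 1L), drop = FALSE]) &
      !is.na(L[, 1:(nP - 2L), drop = FALSE]) &
      !is.na(L[, 3:nP, drop = FALSE]) &
      L[, 1:(nP - 2L), drop = FALSE] != L[, 3:nP, drop = FALSE]
    idx <- which(mid_na, arr.ind = TRUE)
    if (nrow(idx))
      pts[[4L]] <- cbind(A = map$A_grid[idx[, 1L]], P = map$P_grid[idx[, 2L] + 1L])
  }
  pts <- do.call(rbind, pts)
  if (is.null(pts) || nrow(pts) == 0L)
    stop("no label-changing edges found; basins are not separated on this grid")
  pts <- as.data.frame(pts)
  pts[order(pts$A + pts$P), , drop = FALSE]
}

#' @export
print.basin_map <- function(x, ...) {
  n_cells <- length(x$labels)
  n_unres <- sum(is.na(x$labels))
  cat(sprintf("Basin map: %d x %d grid, %d attractor(s), %d unresolved cell(s)\n",
              length(x$A_grid), length(x$P_grid), nrow(x$attractors), n_unres))
  for (k in seq_len(nrow(x$attractors)))
    cat(sprintf("  attractor %d at (A = %.6g, P = %.6g): %d cells\n",
                k, x$attractors$A[k], x$attractors$P[k],
                sum(x$labels == k, na.rm = TRUE)))
  invisible(x)
}

#' Plot a basin map
#'
#' Raster of basin labels in the P/A plane with stable attractors as
#' filled circles and the saddle as an open circle (the conventional
#' phase-portrait rendering).
#'
#' @param x A `"basin_map"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.basin_map <- function(x, ...) {
  cols <- grDevices::hcl.colors(max(2L, nrow(x$attractors)), "Pastel 1")
  graphics::image(x$A_grid, x$P_grid, x$labels, col = cols,
                  xlab = "A (BACE1/Abeta axis)", ylab = "P (free PrPC)", ...)
  graphics::points(x$attractors$A, x$attractors$P, pch = 19, cex = 1.3)
  if (nrow(x$saddle))
    graphics::points(x$saddle$A, x$saddle$P, pch = 1, cex = 1.3)
  invisible(x)
}

#' Write a basin map to CSV
#'
#' Long format `A0,P0,label`, one row per grid cell; unresolved cells
#' carry the label `NA`.
#'
#' @param map A `"basin_map"`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_basin_csv <- function(map, path) {
  stopifnot(inherits(map, "basin_map"))
  grid <- expand.grid(A0 = map$A_grid, P0 = map$P_grid,
                      KEEP.OUT.ATTRS = FALSE)
  df <- data.frame(A0 = grid$A0, P0 = grid$P0,
                   label = as.vector(map$labels))
  .write_csv_precise(df, path)
}
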