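# Free-energy-surface reconstruction from deposited hills, plus
# barrier-crossing diagnostics on CV trajectories.

#' Construct a free-energy grid
#'
#' @param x,y strictly increasing axis node vectors (cv1 = distance in
#'   Angstrom, cv2 = coordination number).
#' @param values `length(x)` x `length(y)` matrix, kcal/mol.
#' @param normalized has the minimum been shifted to zero?
#' @param n_hills,bias_factor provenance of the reconstruction.
#' @return a `fes_grid`.
#' @export
new_fes_grid <- function(x, y, values, normalized = FALSE, n_hills = 0L,
                         bias_factor = Inf) {
  stopifnot(is.matrix(values), nrow(values) == length(x),
            ncol(values) == length(y))
  if (any(diff(x) <= 0) || any(diff(y) <= 0))
    .stop_param("grid axes must be strictly increasing")
  if (!all(is.finite(values))) .stop_param("grid values must be finite")
  structure(list(x = x, y = y, values = values, normalized = normalized,
                 n_hills = as.integer(n_hills), bias_factor = bias_factor),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat("FES grid ", length(x$x), "x", length(x$y), " over [",
      signif(min(x$x), 4), ",", signif(max(x$x), 4), "] x [",
      signif(min(x$y), 4), ",", signif(max(x$y), 4), "]\n", sep = "")
  cat("  range:", signif(min(x$values), 5), "-", signif(max(x$values), 5),
      "kcal/mol;", x$n_hills, "hills; gamma", format(x$bias_factor),
      if (x$normalized) "; normalized (min = 0)" else "", "\n")
  invisible(x)
}

#' Default grid specification from a hill list
#'
#' Covers the hill centers padded by `pad_sig` standard deviations on a
#' `n x n` grid.
#'
#' @param hills a `hill_list`.
#' @param n nodes per axis (default 200).
#' @param pad_sig padding in hill sigmas (default 6, which also satisfies
#'   the 5-sigma coverage precondition of [bias_potential()]).
#' @return list with axis vectors `x` and `y`.
#' @export
grid_spec_from_hills <- function(hills, n = 200L, pad_sig = 6) {
  stopifnot(nrow(hills) > 0)
  px <- pad_sig * max(hills$sigma1)
  py <- pad_sig * max(hills$sigma2)
  list(x = seq(min(hills$center1) - px, max(hills$center1) + px,
               length.out = n),
       y = seq(min(hills$center2) - py, max(hills$center2) + py,
               length.out = n))
}

#' Accumulated metadynamics bias on a grid
#'
#' Sums the deposited Gaussians,
#' \eqn{V_B(s) = \sum_k h_k \exp[-\sum_j (s_j - c_{kj})^2 / (2\sigma_{kj}^2)]},
#' truncating each hill beyond `cutoff_sig` standard deviations.
#'
#' @param hills a `hill_list`.
#' @param grid list with axis vectors `x`, `y` (see
#'   [grid_spec_from_hills()]); must cover every hill center ± 5 sigma.
#' @param cutoff_sig truncation radius in sigmas (default 6.5; `Inf`
#'   disables).  The dropped tail of one hill is bounded by
#'   h exp(-cutoff^2/2), i.e. 6.6e-10 h at 6.5 sigma, which keeps the
#'   summed truncation error of even thousands of kcal-scale hills below
#'   1e-6 kcal/mol.
#' @return a `fes_grid` holding the bias potential (kcal/mol).
#' @export
bias_potential <- function(hills, grid, cutoff_sig = 6.5) {
  stopifnot(inherits(hills, "hill_list"))
  out1 <- hills$center1 - 5 * hills$sigma1 < min(grid$x) |
          hills$center1 + 5 * hills$sigma1 > max(grid$x)
  out2 <- hills$center2 - 5 * hills$sigma2 < min(grid$y) |
          hills$center2 + 5 * hills$sigma2 > max(grid$y)
  if (any(out1 | out2))
    .stop_param("grid does not cover hills (with 5 sigma margin): rows ",
                paste(head(which(out1 | out2), 10), collapse = ", "))
  vb <- cpp_sum_hills(grid$x, grid$y, .hills_matrix(hills), cutoff_sig)
  new_fes_grid(grid$x, grid$y, vb, normalized = FALSE,
               n_hills = nrow(hills),
               bias_factor = attr(hills, "bias_factor"))
}

#' Reconstruct the unbiased free-energy surface from hills
#'
#' For well-tempered metadynamics with bias factor gamma the unbiased
#' estimate is \eqn{F(s) = -\frac{\gamma}{\gamma - 1} V_B(s)}; for standard
#' metadynamics (gamma = Inf) it is \eqn{F(s) = -V_B(s)}.  The surface is
#' shifted so its minimum is zero when `normalize = TRUE`.
#'
#' @inheritParams bias_potential
#' @param bias_factor gamma; defaults to the value recorded in `hills`.
#' @param normalize shift minimum to 0 (default TRUE).
#' @return a `fes_grid` (kcal/mol).
#' @export
reconstruct_fes <- function(hills, grid = grid_spec_from_hills(hills),
                            bias_factor = attr(hills, "bias_factor"),
                            cutoff_sig = 6.5, normalize = TRUE) {
  if (!is.infinite(bias_factor) && bias_factor <= 1)
    .stop_param("bias_factor must be > 1 or Inf")
  vb <- bias_potential(hills, grid, cutoff_sig)
  scale <- if (is.infinite(bias_factor)) 1 else
    bias_factor / (bias_factor - 1)
  f <- -scale * vb$values
  norm <- FALSE
  if (normalize) { f <- f - min(f); norm <- TRUE }
  new_fes_grid(grid$x, grid$y, f, normalized = norm,
               n_hills = nrow(hills), bias_factor = bias_factor)
}

#' Count committed barrier crossings of a CV trajectory
#'
#' Uses a two-threshold (hysteresis) rule on the first CV: the walker is
#' committed to side A below `divide - hysteresis/2` and to side B above
#' `divide + hysteresis/2`; a crossing is counted each time the committed
#' side flips.  Oscillations confined to the hysteresis band are ignored.
#'
#' @param traj a `cv_trajectory`, or a numeric vector of cv1 values.
#' @param divide dividing value on the first CV.
#' @param hysteresis full band width (default 0.2, in cv1 units).
#' @return integer number of committed transitions.  If `divide` lies
#'   outside the trajectory range, returns 0 with a warning.
#' @export
count_crossings <- function(traj, divide, hysteresis = 0.2) {
  if (hysteresis < 0) .stop_param("hysteresis must be >= 0")
  x <- if (inherits(traj, "cv_trajectory")) traj$cv[, 1] else as.numeric(traj)
  if (divide < min(x) || divide > max(x)) {
    warning("dividing value outside trajectory range; no crossings",
            call. = FALSE)
    return(0L)
  }
  lo <- divide - hysteresis / 2
  hi <- divide + hysteresis / 2
  side <- ifelse(x < lo, -1L, ifelse(x > hi, 1L, 0L))
  side <- side[side != 0L]
  if (!length(side)) return(0L)
  sum(diff(side) != 0L)
}
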