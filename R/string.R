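# Zero-temperature string method on a 2-D FES: steepest-descent relaxation
# of a discretized path with equal-arc-length reparameterization.  Endpoints
# are free (they descend into the basin minima) because reactant and product
# states are wells, not fixed points.

.reparam_equal_arc <- function(X) {
  seg <- sqrt(rowSums(diff(X)^2))
  s <- c(0, cumsum(seg))
  if (s[length(s)] == 0) return(X)
  target <- seq(0, s[length(s)], length.out = nrow(X))
  cbind(stats::approx(s, X[, 1], xout = target, ties = "ordered")$y,
        stats::approx(s, X[, 2], xout = target, ties = "ordered")$y)
}

#' Zero-temperature string method minimum-energy path
#'
#' Relaxes an `n_images`-point string between `start` and `end` on the
#' interpolated FES by alternating (i) a steepest-descent displacement of
#' every image along the negative bicubic gradient and (ii)
#' reparameterization to equal arc length by piecewise-linear interpolation.
#' The step size adapts per image: it is halved when a step would raise that
#' image's energy or leave the grid, and grown gently after accepted steps.
#' Iteration stops at `n_steps` or earlier when the maximum image
#' displacement in one iteration falls below `tol`.
#'
#' @param fes a `fes_grid`.
#' @param start,end length-2 CV endpoints (inside the grid).
#' @param n_images number of images (default 30).
#' @param n_steps maximum optimization steps (default 3000).
#' @param step_init initial per-image step size in CV^2 mol/kcal units
#'   (default 2e-3); adapted automatically.
#' @param tol convergence threshold on max per-iteration displacement
#'   (default 1e-8).
#' @return a `string_path`: `images` (n x 2), `energy` (kcal/mol per image),
#'   `arc` (normalized arc length), `converged`, `iterations`.
#'   `start == end` yields a flagged degenerate single-point path.
#' @export
zero_t_string <- function(fes, start, end, n_images = 30L, n_steps = 3000L,
                          step_init = 2e-3, tol = 1e-8) {
  stopifnot(inherits(fes, "fes_grid"), length(start) == 2, length(end) == 2)
  interp <- make_interpolant(fes)
  # endpoint validity check (errors if outside grid)
  interp(rbind(start, end))
  if (all(start == end)) {
    e <- interp(rbind(start))$value
    return(structure(list(images = rbind(start), energy = e, arc = 0,
                          converged = TRUE, iterations = 0L,
                          degenerate = TRUE), class = "string_path"))
  }
  tfrac <- seq(0, 1, length.out = n_images)
  X <- cbind(start[1] + tfrac * (end[1] - start[1]),
             start[2] + tfrac * (end[2] - start[2]))
  xr <- range(fes$x); yr <- range(fes$y)
  inside <- function(P) P[, 1] >= xr[1] & P[, 1] <= xr[2] &
    P[, 2] >= yr[1] & P[, 2] <= yr[2]
  alpha <- rep(step_init, n_images)
  alpha_min <- 1e-12
  # per-iteration displacement cap keeps moves local (an uncapped step can
  # jump an image across the barrier to a lower-energy point and fold the
  # path); half a grid cell is ample for 3000 iterations
  cap <- 0.5 * min(min(diff(fes$x)), min(diff(fes$y)))
  converged <- FALSE
  it <- 0L
  E <- interp(X)$value
  step_of <- function(a, G) {
    d <- a * sqrt(rowSums(G^2))
    a * ifelse(d > cap, cap / d, 1)
  }
  for (it in seq_len(n_steps)) {
    G <- interp(X)$gradient
    Xnew <- X - step_of(alpha, G) * G
    ok <- inside(Xnew)
    Enew <- E
    if (any(ok))
      Enew[ok] <- interp(Xnew[ok, , drop = FALSE])$value
    bad <- !ok | Enew > E + 1e-12
    tries <- 0L
    while (any(bad) && tries < 60L) {
      alpha[bad] <- alpha[bad] / 2
      Xnew[bad, ] <- X[bad, , drop = FALSE] -
        step_of(alpha[bad], G[bad, , drop = FALSE]) *
          G[bad, , drop = FALSE]
      ok2 <- inside(Xnew[bad, , drop = FALSE])
      Eb <- E[bad]
      if (any(ok2))
        Eb[ok2] <- interp(Xnew[bad, , drop = FALSE][ok2, ,
                                                    drop = FALSE])$value
      Enew[bad] <- Eb
      bad[bad] <- !ok2 | Eb > E[bad] + 1e-12
      tries <- tries + 1L
    }
    if (any(bad)) {
      if (all(alpha[bad] <= alpha_min))
        stop(errorCondition(
          "string image persistently rejected (cannot descend inside grid)",
          class = c("metacage_convergence_error", "error", "condition")))
      Xnew[bad, ] <- X[bad, , drop = FALSE]  # keep, retry next iteration
    }
    alpha[!bad] <- pmin(alpha[!bad] * 1.2, 0.1)
    Xre <- .reparam_equal_arc(Xnew)
    disp <- max(sqrt(rowSums((Xre - X)^2)))
    X <- Xre
    E <- interp(X)$value
    if (disp < tol) { converged <- TRUE; break }
  }
  seg <- sqrt(rowSums(diff(X)^2))
  arc <- c(0, cumsum(seg))
  structure(list(images = X, energy = E,
                 arc = if (max(arc) > 0) arc / max(arc) else arc,
                 converged = converged,
                 iterations = it, degenerate = FALSE,
                 interp = interp),
            class = "string_path")
}

#' @export
print.string_path <- function(x, ...) {
  cat("String path:", nrow(x$images), "images,", x$iterations,
      "iterations,", if (x$converged) "converged" else "NOT converged", "\n")
  if (!isTRUE(x$degenerate) && nrow(x$images) > 2) {
    b <- tryCatch(barrier(x), error = function(e) NULL)
    if (!is.null(b))
      cat(sprintf("  barrier %.3f kcal/mol at TS (%.4f, %.4f)\n",
                  b$dG, b$ts_point[1], b$ts_point[2]))
  }
  invisible(x)
}

#' Activation free energy and transition state from a string path
#'
#' The barrier is the maximum image energy minus the reactant-side minimum
#' (the side of the path's first image), with the transition state refined
#' by a parabolic fit through the three highest images in arc length.
#'
#' @param path a `string_path`.
#' @return list with `dG` (kcal/mol), `ts_point`, `rs_point`, `ps_point`
#'   (CV coordinates) and `ts_index`.
#' @export
barrier <- function(path) {
  stopifnot(inherits(path, "string_path"))
  E <- path$energy
  n <- length(E)
  if (n < 3) stop(errorCondition("path too short for a barrier",
                                 class = c("metacage_no_barrier", "error",
                                           "condition")))
  imax <- which.max(E)
  if (imax == 1L || imax == n ||
      max(E) - max(E[1], E[n]) < sqrt(.Machine$double.eps))
    stop(errorCondition("no barrier on path (no interior maximum)",
                        class = c("metacage_no_barrier", "error",
                                  "condition")))
  # refine the TS across the three highest images: densely resample the
  # interpolated FES along the piecewise-linear path when the interpolant
  # is available, otherwise fit a parabola in arc length
  s <- path$arc[(imax - 1):(imax + 1)]
  e <- E[(imax - 1):(imax + 1)]
  if (!is.null(path$interp)) {
    s_dense <- seq(s[1], s[3], length.out = 801)
    pts <- cbind(stats::approx(path$arc, path$images[, 1], xout = s_dense,
                               ties = "ordered")$y,
                 stats::approx(path$arc, path$images[, 2], xout = s_dense,
                               ties = "ordered")$y)
    e_dense <- path$interp(pts)$value
    k <- which.max(e_dense)
    s_ts <- s_dense[k]
    e_ts <- e_dense[k]
  } else {
    denom <- (s[1] - s[2]) * (s[1] - s[3]) * (s[2] - s[3])
    a <- (s[3] * (e[2] - e[1]) + s[2] * (e[1] - e[3]) +
            s[1] * (e[3] - e[2])) / denom
    b <- (s[3]^2 * (e[1] - e[2]) + s[2]^2 * (e[3] - e[1]) +
            s[1]^2 * (e[2] - e[3])) / denom
    s_ts <- if (a < 0) -b / (2 * a) else path$arc[imax]
    s_ts <- min(max(s_ts, s[1]), s[3])
    cc <- e[1] - a * s[1]^2 - b * s[1]
    e_ts <- if (a < 0) a * s_ts^2 + b * s_ts + cc else E[imax]
  }
  ts_point <- c(stats::approx(path$arc, path$images[, 1], xout = s_ts,
                              ties = "ordered")$y,
                stats::approx(path$arc, path$images[, 2], xout = s_ts,
                              ties = "ordered")$y)
  i_rs <- which.min(E[1:imax])
  i_ps <- imax - 1L + which.min(E[imax:n])
  list(dG = e_ts - E[i_rs], ts_point = ts_point,
       rs_point = path$images[i_rs, ], ps_point = path$images[i_ps, ],
       ts_index = imax)
}

#' Write a string path as CSV plus JSON summary
#'
#' @param path a `string_path`.
#' @param csv_path output CSV (index, cv1, cv2, free_energy).
#' @param json_path optional JSON summary (barrier, TS, convergence).
#' @return `csv_path`, invisibly.
#' @export
write_string_path <- function(path, csv_path, json_path = NULL) {
  df <- data.frame(index = seq_len(nrow(path$images)),
                   cv1 = path$images[, 1], cv2 = path$images[, 2],
                   free_energy = path$energy)
  write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    b <- barrier(path)
    jsonlite::write_json(
      list(dG_kcal_mol = b$dG, ts_point = b$ts_point,
           rs_point = b$rs_point, ps_point = b$ps_point,
           converged = path$converged, iterations = path$iterations),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
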