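# Continuous view of a gridded FES: bicubic Hermite interpolation with
# analytic gradients.  Node derivatives come from second-order finite
# differences, which makes the interpolant C1 across cell boundaries --
# string descent on merely bilinear gradients stalls at cell edges.

# second-order finite-difference derivative along the rows of a matrix
.fd_rows <- function(v, x) {
  n <- length(x)
  d <- v
  d[2:(n - 1), ] <- (v[3:n, ] - v[1:(n - 2), ]) /
    (x[3:n] - x[1:(n - 2)])
  d[1, ] <- (-3 * v[1, ] + 4 * v[2, ] - v[3, ]) / (x[3] - x[1])
  d[n, ] <- (3 * v[n, ] - 4 * v[n - 1, ] + v[n - 2, ]) / (x[n] - x[n - 2])
  d
}

.node_derivs <- function(fes) {
  v <- fes$values
  fx <- .fd_rows(v, fes$x)
  fy <- t(.fd_rows(t(v), fes$y))
  fxy <- t(.fd_rows(t(fx), fes$y))
  list(fx = fx, fy = fy, fxy = fxy)
}

# Hermite basis h(t) and derivative, for value/derivative node data
.hermite <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  list(h00 = 2 * t3 - 3 * t2 + 1, h10 = t3 - 2 * t2 + t,
       h01 = -2 * t3 + 3 * t2,    h11 = t3 - t2)
}
.dhermite <- function(t) {
  t2 <- t * t
  list(h00 = 6 * t2 - 6 * t, h10 = 3 * t2 - 4 * t + 1,
       h01 = -6 * t2 + 6 * t, h11 = 3 * t2 - 2 * t)
}

#' Build a reusable bicubic interpolant for a FES grid
#'
#' @param fes a `fes_grid`.
#' @return a function `f(points)` taking an n x 2 matrix of CV points and
#'   returning `list(value, gradient)` with an n-vector and an n x 2 matrix.
#' @export
make_interpolant <- function(fes) {
  stopifnot(inherits(fes, "fes_grid"))
  nd <- .node_derivs(fes)
  x <- fes$x; y <- fes$y; v <- fes$values
  fx <- nd$fx; fy <- nd$fy; fxy <- nd$fxy
  nx <- length(x); ny <- length(y)

  function(points) {
    points <- matrix(points, ncol = 2)
    px <- points[, 1]; py <- points[, 2]
    if (any(px < x[1] | px > x[nx] | py < y[1] | py > y[ny]))
      stop(errorCondition("point outside FES grid",
                          class = c("metacage_domain_error", "error",
                                    "condition")))
    i <- pmin(pmax(findInterval(px, x), 1L), nx - 1L)
    j <- pmin(pmax(findInterval(py, y), 1L), ny - 1L)
    dx <- x[i + 1L] - x[i]; dy <- y[j + 1L] - y[j]
    u <- (px - x[i]) / dx; w <- (py - y[j]) / dy

    idx <- function(ii, jj) cbind(ii, jj)
    g <- list(f00 = v[idx(i, j)],      f10 = v[idx(i + 1L, j)],
              f01 = v[idx(i, j + 1L)], f11 = v[idx(i + 1L, j + 1L)],
              x00 = fx[idx(i, j)] * dx,      x10 = fx[idx(i + 1L, j)] * dx,
              x01 = fx[idx(i, j + 1L)] * dx, x11 = fx[idx(i + 1L, j + 1L)] * dx,
              y00 = fy[idx(i, j)] * dy,      y10 = fy[idx(i + 1L, j)] * dy,
              y01 = fy[idx(i, j + 1L)] * dy, y11 = fy[idx(i + 1L, j + 1L)] * dy,
              m00 = fxy[idx(i, j)] * dx * dy,
              m10 = fxy[idx(i + 1L, j)] * dx * dy,
              m01 = fxy[idx(i, j + 1L)] * dx * dy,
              m11 = fxy[idx(i + 1L, j + 1L)] * dx * dy)

    # tensor-product Hermite: interpolate along x at the two j levels
    # (values and y-derivatives), then along y
    eval_uv <- function(hu, hw) {
      a0 <- hu$h00 * g$f00 + hu$h01 * g$f10 + hu$h10 * g$x00 +
        hu$h11 * g$x10
      a1 <- hu$h00 * g$f01 + hu$h01 * g$f11 + hu$h10 * g$x01 +
        hu$h11 * g$x11
      b0 <- hu$h00 * g$y00 + hu$h01 * g$y10 + hu$h10 * g$m00 +
        hu$h11 * g$m10
      b1 <- hu$h00 * g$y01 + hu$h01 * g$y11 + hu$h10 * g$m01 +
        hu$h11 * g$m11
      hw$h00 * a0 + hw$h01 * a1 + hw$h10 * b0 + hw$h11 * b1
    }
    hu <- .hermite(u); hw <- .hermite(w)
    dhu <- .dhermite(u); dhw <- .dhermite(w)
    val <- eval_uv(hu, hw)
    gx <- eval_uv(dhu, hw) / dx
    gy <- eval_uv(hu, dhw) / dy
    list(value = val, gradient = unname(cbind(gx, gy)))
  }
}

#' Interpolate a FES grid at one or more points
#'
#' Bicubic Hermite value and analytic gradient, continuous (C1) across
#' cell boundaries.
#'
#' @param fes a `fes_grid`.
#' @param point length-2 CV point, or an n x 2 matrix of points.
#' @return for one point, `list(value, gradient)` with scalar and length-2
#'   vector; for a matrix, an n-vector and n x 2 matrix.
#' @export
fes_interpolate <- function(fes, point) {
  res <- make_interpolant(fes)(point)
  if (is.null(dim(point)) && length(point) == 2)
    list(value = res$value[1], gradient = drop(res$gradient))
  else res
}
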