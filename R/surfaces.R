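# Model potential-energy surfaces in 2-D collective-variable space.
# These stand in for the ab initio landscape so that every downstream stage
# (metadynamics, FES reconstruction, string method, committor shooting) can be
# validated against analytically known minima, saddles and barriers.

.surface_form_code <- function(form) {
  switch(form, double_well = 1L, harmonic = 2L,
         .stop_param("unknown surface form '", form, "'"))
}

#' Symmetric double-well model surface
#'
#' Constructs the quartic double well
#' \deqn{V(x, y) = h\,[(x/a)^2 - 1]^2 + \tfrac{1}{2} k y^2 + t\,x}
#' with minima at (±a, 0) where V = 0 (for tilt t = 0) and a saddle at
#' (0, 0) where V = h.  The x axis plays the role of the reactive collective
#' variable (e.g. methyl--methyl distance relative to the dividing surface)
#' and y a transverse coordinate.  A nonzero `tilt` offsets the wells to give
#' an asymmetric reaction profile.
#'
#' @param h barrier height, kcal/mol.
#' @param a well half-separation in CV units.
#' @param k transverse harmonic stiffness, kcal/mol per CV-unit^2.
#' @param tilt optional linear asymmetry, kcal/mol per CV unit (default 0).
#' @param domain evaluation box `c(xmin, xmax, ymin, ymax)`; defaults to
#'   `c(-3a, 3a, -3, 3)`.
#' @return an object of class `model_surface`.
#' @examples
#' v <- make_double_well(h = 24, a = 1, k = 2)
#' surface_value(v, 0, 0)     # saddle energy = h
#' surface_gradient(v, 0, 0)  # stationary point
#' @export
make_double_well <- function(h, a, k, tilt = 0,
                             domain = c(-3 * a, 3 * a, -3, 3)) {
  if (!is.numeric(h) || h <= 0) .stop_param("barrier height h must be > 0")
  if (!is.numeric(a) || a <= 0) .stop_param("well half-separation a must be > 0")
  if (!is.numeric(k) || k <= 0) .stop_param("transverse stiffness k must be > 0")
  structure(list(form = "double_well",
                 params = c(h = h, a = a, k = k, tilt = tilt),
                 stationary_points = if (tilt == 0)
                   rbind(c(-a, 0), c(a, 0), c(0, 0)) else NULL,
                 domain = domain),
            class = "model_surface")
}

#' Harmonic model surface
#'
#' \eqn{V(x, y) = \tfrac{1}{2} k_x x^2 + \tfrac{1}{2} k_y y^2}, used mainly to
#' check the Langevin sampler against equipartition (Var(x) = k_B T / k_x).
#'
#' @param kx,ky stiffness along each CV, kcal/mol per CV-unit^2.
#' @param domain evaluation box `c(xmin, xmax, ymin, ymax)`.
#' @return an object of class `model_surface`.
#' @export
make_harmonic <- function(kx, ky = kx, domain = c(-10, 10, -10, 10)) {
  if (kx <= 0 || ky <= 0) .stop_param("stiffness must be > 0")
  structure(list(form = "harmonic", params = c(kx = kx, ky = ky),
                 stationary_points = rbind(c(0, 0)), domain = domain),
            class = "model_surface")
}

#' Evaluate a model surface
#'
#' @param surface a `model_surface`.
#' @param x,y CV coordinates (vectorised).
#' @return potential energy values, kcal/mol.
#' @export
surface_value <- function(surface, x, y) {
  stopifnot(inherits(surface, "model_surface"), length(x) == length(y))
  code <- .surface_form_code(surface$form)
  vapply(seq_along(x), function(i)
    cpp_surface_value(code, unname(surface$params), x[i], y[i]), numeric(1))
}

#' Gradient of a model surface
#'
#' @inheritParams surface_value
#' @return for scalar input a length-2 vector; otherwise an n x 2 matrix.
#' @export
surface_gradient <- function(surface, x, y) {
  stopifnot(inherits(surface, "model_surface"), length(x) == length(y))
  code <- .surface_form_code(surface$form)
  g <- t(vapply(seq_along(x), function(i)
    cpp_surface_gradient(code, unname(surface$params), x[i], y[i]),
    numeric(2)))
  if (length(x) == 1L) drop(g) else g
}

#' @export
print.model_surface <- function(x, ...) {
  cat("Model surface '", x$form, "'\n", sep = "")
  cat("  parameters:", paste(names(x$params), signif(x$params, 6),
                             sep = " = ", collapse = ", "), "\n")
  cat("  domain: [", x$domain[1], ",", x$domain[2], "] x [",
      x$domain[3], ",", x$domain[4], "]\n")
  invisible(x)
}
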