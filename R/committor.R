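# Committor analysis: transition-state candidate selection by CV windows
# and commitment-probability estimation by stochastic shooting on a model
# surface.  A point with committor ~ 0.5 is a genuine transition state
# regardless of how it was proposed.

#' Select transition-state candidate frames by CV windows
#'
#' Returns the frames whose CVs fall within the selection windows around a
#' candidate transition-state point: |dist - dist_TS| <= `tol_distance` and
#' |CN - CN_TS| <= `tol_cn` (defaults 0.05 Angstrom and 0.005, the
#' ensemble-selection windows of the reference workflow).
#'
#' @param series data.frame with columns `dist` and `cn` (see [cv_series()]),
#'   or a `cv_trajectory` (cv1 = dist, cv2 = cn).
#' @param ts_point length-2 `(dist, cn)` transition-state location.
#' @param tol_distance half-window on the distance CV, Angstrom.
#' @param tol_cn half-window on the coordination number.
#' @return integer vector of frame indices (empty, with a warning, when no
#'   frame is in-window).
#' @export
select_candidates <- function(series, ts_point, tol_distance = 0.05,
                              tol_cn = 0.005) {
  if (tol_distance <= 0 || tol_cn <= 0) .stop_param("tolerances must be > 0")
  if (inherits(series, "cv_trajectory"))
    series <- data.frame(dist = series$cv[, 1], cn = series$cv[, 2])
  idx <- which(abs(series$dist - ts_point[1]) <= tol_distance &
                 abs(series$cn - ts_point[2]) <= tol_cn)
  if (!length(idx))
    warning("no frames within the selection windows", call. = FALSE)
  idx
}

.check_rect <- function(r, name) {
  if (length(r) != 4 || r[1] >= r[2] || r[3] >= r[4])
    .stop_param(name, " basin must be c(xmin, xmax, ymin, ymax) with ",
                "min < max")
}

#' Basin windows centered on the reactant/product minima of a string path
#'
#' Rectangular CV windows centered on the path's RS/PS minima with
#' half-widths `frac` times the well separation.
#'
#' @param path a `string_path` (or the result of [barrier()]).
#' @param frac half-width as a fraction of the RS--PS separation
#'   (default 0.3).
#' @return list with `reactant` and `product` rectangles
#'   `c(xmin, xmax, ymin, ymax)`.
#' @export
basins_from_path <- function(path, frac = 0.3) {
  b <- if (inherits(path, "string_path")) barrier(path) else path
  sep <- sqrt(sum((b$ps_point - b$rs_point)^2))
  h <- frac * sep
  list(reactant = c(b$rs_point[1] - h, b$rs_point[1] + h,
                    b$rs_point[2] - h, b$rs_point[2] + h),
       product = c(b$ps_point[1] - h, b$ps_point[1] + h,
                   b$ps_point[2] - h, b$ps_point[2] + h))
}

#' Estimate the committor of a CV point by Langevin shooting
#'
#' Launches `n_shots` momentum-free overdamped Langevin trajectories from
#' `point`; each shot ends on first entry into the reactant or product
#' window, or at `max_steps` (timeout).  Timeout shots are excluded from
#' the committor estimate and reported separately (with a warning above 10%).
#' Shots consume one seeded RNG stream, so the full result is reproducible
#' from `seed`.
#'
#' @param surface a `model_surface` to shoot on.
#' @param point length-2 CV shooting point.
#' @param basins list with `reactant` and `product` rectangles
#'   `c(xmin, xmax, ymin, ymax)`; must be disjoint.
#' @param n_shots number of shots (>= 1).
#' @param max_steps per-shot step budget (default 20000).
#' @param T temperature, K.
#' @param friction friction, 1/fs.
#' @param dt timestep, fs.
#' @param seed integer RNG seed.
#' @return a `committor_result`: `p_product`, `n_shots`, `ci95` (Wilson),
#'   `outcomes` (product/reactant/timeout counts), `point`, `seed`.
#' @export
estimate_committor <- function(surface, point, basins, n_shots = 400L,
                               max_steps = 20000L, T = 298.15, friction = 50,
                               dt = 0.5, seed) {
  stopifnot(inherits(surface, "model_surface"), length(point) == 2)
  if (n_shots < 1) .stop_param("n_shots must be >= 1")
  if (missing(seed)) .stop_param("seed must be supplied")
  .check_rect(basins$reactant, "reactant")
  .check_rect(basins$product, "product")
  r <- basins$reactant; p <- basins$product
  overlap <- r[1] < p[2] && p[1] < r[2] && r[3] < p[4] && p[3] < r[4]
  if (overlap) .stop_param("reactant and product basins overlap")
  set.seed(seed)
  shots <- cpp_committor_shots(.surface_form_code(surface$form),
                               unname(surface$params), point[1], point[2],
                               dt, friction, kBT(T), as.integer(n_shots),
                               as.integer(max_steps), r, p)
  n_prod <- sum(shots == 1L)
  n_reac <- sum(shots == -1L)
  n_to <- sum(shots == 0L)
  if (n_to > 0.1 * n_shots)
    warning(sprintf("%d of %d shots timed out (> 10%%)", n_to, n_shots),
            call. = FALSE)
  n_eff <- n_prod + n_reac
  p_prod <- if (n_eff > 0) n_prod / n_eff else NA_real_
  ci <- if (n_eff > 0)
    as.numeric(prop.test(n_prod, n_eff, correct = FALSE)$conf.int)
  else c(NA_real_, NA_real_)
  structure(list(p_product = p_prod, n_shots = as.integer(n_shots),
                 ci95 = ci,
                 outcomes = c(product = n_prod, reactant = n_reac,
                              timeout = n_to),
                 per_shot = c("reactant", "timeout",
                              "product")[shots + 2L],
                 point = point, seed = seed),
            class = "committor_result")
}

#' @export
print.committor_result <- function(x, ...) {
  cat(sprintf(
    "Committor at (%.4g, %.4g): p_product = %.3f [%.3f, %.3f] (n = %d",
    x$point[1], x$point[2], x$p_product, x$ci95[1], x$ci95[2], x$n_shots))
  cat(sprintf(", %d timeouts)\n", x$outcomes["timeout"]))
  invisible(x)
}

#' Is a committor result consistent with a transition state?
#'
#' TRUE iff the Wilson 95% confidence interval of p_product intersects the
#' acceptance band (default [0.40, 0.60]).  CI-overlap semantics are
#' deliberately permissive: small candidate ensembles with early commitment
#' (e.g. p = 0.38 at n = 50) still qualify.
#'
#' @param result a `committor_result`.
#' @param band length-2 acceptance band on p_product.
#' @return logical.
#' @export
is_transition_state <- function(result, band = c(0.40, 0.60)) {
  stopifnot(inherits(result, "committor_result"))
  if (is.na(result$p_product)) return(FALSE)
  result$ci95[1] <= band[2] && result$ci95[2] >= band[1]
}

#' Write a committor result as JSON (and optional per-shot CSV)
#'
#' @param result a `committor_result`.
#' @param json_path output JSON path.
#' @param csv_path optional per-shot outcome log.
#' @return `json_path`, invisibly.
#' @export
write_committor_result <- function(result, json_path, csv_path = NULL) {
  jsonlite::write_json(
    list(point = result$point, p_product = result$p_product,
         ci95 = result$ci95, outcomes = as.list(result$outcomes),
         n_shots = result$n_shots, seed = result$seed),
    json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path))
    write.csv(data.frame(shot = seq_along(result$per_shot),
                         outcome = result$per_shot),
              csv_path, row.names = FALSE, quote = FALSE)
  invisible(json_path)
}
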