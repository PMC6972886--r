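# Stochastic stand-in dynamics: overdamped (first-order) Langevin propagation
# on model surfaces, plain or under a metadynamics bias.  Only basin-commitment
# and sampling behaviour matter for the downstream committor and FES stages,
# so inertia is deliberately omitted.

.as_cv_trajectory <- function(traj, dt, temperature, seed) {
  n <- nrow(traj) - 1L
  structure(list(times = seq(0, by = dt, length.out = n + 1L),
                 cv = traj, dt = dt, n_steps = n,
                 temperature = temperature, seed = seed),
            class = "cv_trajectory")
}

#' @export
print.cv_trajectory <- function(x, ...) {
  cat("CV trajectory:", x$n_steps, "steps of", x$dt, "fs at",
      x$temperature, "K (seed", paste0(x$seed, ")"), "\n")
  cat("  final point: (", signif(x$cv[nrow(x$cv), 1], 5), ",",
      signif(x$cv[nrow(x$cv), 2], 5), ")\n")
  invisible(x)
}

.hills_matrix <- function(bias) {
  # internal 5-column (center1, center2, sigma1, sigma2, height) form
  if (is.null(bias)) return(matrix(numeric(0), 0, 5))
  h <- as.data.frame(bias)
  as.matrix(h[, c("center1", "center2", "sigma1", "sigma2", "height")])
}

#' Overdamped Langevin trajectory on a model surface
#'
#' Propagates the Euler--Maruyama discretisation of overdamped Langevin
#' dynamics, \eqn{x_{n+1} = x_n - \nabla V\, \Delta t/\gamma + \sqrt{2 k_B T
#' \Delta t/\gamma}\,\xi}, with forces from `surface` plus (optionally) a
#' fixed metadynamics hill bias.  Identical seeds give bitwise-identical
#' trajectories.  The integrator is stable for
#' \eqn{\Delta t\, V'' / \gamma < 2}; stiff surfaces need larger friction.
#'
#' @param surface a `model_surface`.
#' @param start length-2 CV starting point.
#' @param T temperature, K.
#' @param friction friction coefficient gamma, 1/fs (default 1).
#' @param dt timestep, fs (default 0.5).
#' @param n_steps number of steps.
#' @param seed integer RNG seed (required: determinism is part of the contract).
#' @param bias optional `hill_list` applied as a static bias.
#' @param cutoff_sig Gaussian truncation radius for the bias, in sigmas.
#' @return a `cv_trajectory` with `(n_steps + 1)` rows of (cv1, cv2).
#' @details If the walker leaves the surface's declared domain box the run
#'   aborts with a condition of class `metacage_domain_escape` whose
#'   `last_frame` and `trajectory` fields carry the last valid state.
#' @export
langevin_trajectory <- function(surface, start, T = 298.15, friction = 1,
                                dt = 0.5, n_steps, seed, bias = NULL,
                                cutoff_sig = 6.5) {
  stopifnot(inherits(surface, "model_surface"), length(start) == 2)
  if (dt <= 0) .stop_param("dt must be > 0")
  if (friction <= 0) .stop_param("friction must be > 0")
  if (missing(seed)) .stop_param("seed must be supplied")
  if (n_steps < 0) .stop_param("n_steps must be >= 0")
  set.seed(seed)
  res <- cpp_langevin(.surface_form_code(surface$form),
                      unname(surface$params), start[1], start[2],
                      dt, friction, kBT(T), as.integer(n_steps),
                      .hills_matrix(bias), cutoff_sig, surface$domain)
  if (res$status != 0L) {
    tr <- res$traj[seq_len(res$n_done + 1L), , drop = FALSE]
    stop(errorCondition(
      sprintf("trajectory left the domain box after %d valid steps",
              res$n_done),
      class = c("metacage_domain_escape", "error", "condition"),
      last_frame = tr[nrow(tr), ],
      trajectory = .as_cv_trajectory(tr, dt, T, seed)))
  }
  .as_cv_trajectory(res$traj, dt, T, seed)
}

#' Well-tempered metadynamics on a model surface
#'
#' Runs overdamped Langevin dynamics while depositing one Gaussian hill every
#' `pace` steps at the walker's current CV position.  With a finite bias
#' factor gamma the deposited height is damped well-tempered style by
#' \eqn{\exp[-V_B(s)/(k_B \Delta T)]} with \eqn{\Delta T = (\gamma - 1) T};
#' `bias_factor = Inf` selects standard (undamped) metadynamics.
#'
#' @inheritParams langevin_trajectory
#' @param height nominal hill height, kcal/mol.  The literature schedule of
#'   0.005 Hartree corresponds to `0.005 * 627.509 = 3.1375`.
#' @param pace steps between deposits (default 30).
#' @param widths length-2 Gaussian sigma per CV.
#' @param bias_factor well-tempered gamma > 1, or `Inf` for standard
#'   metadynamics (default 15).
#' @param stop_crossings optional stopping rule: halt the run once the
#'   dividing surface on the first CV has been crossed this many times
#'   (with hysteresis, as in [count_crossings()]); 0 disables (default).
#' @param stop_divide,stop_hysteresis dividing value and hysteresis band
#'   for the stopping rule.
#' @param stop_min_steps minimum number of steps before the stopping rule
#'   may fire (the reference protocol required both >= 3 crossings and
#'   tens of picoseconds of accumulated bias).
#' @param wall optional restraining box `c(xlo, xhi, ylo, yhi)`: outside it
#'   a harmonic restoring force of stiffness `wall_k` confines the walker
#'   (standard metadynamics walls, preventing slow bias creep out of the
#'   CV region of interest).  `NULL` disables.
#' @param wall_k wall stiffness, kcal/mol per CV-unit^2.
#' @return list with elements `trajectory` (a `cv_trajectory`) and `hills`
#'   (a `hill_list`: time fs, center1, center2, sigma1, sigma2, height
#'   kcal/mol, with the bias factor and temperature in attributes).
#' @export
run_metadynamics <- function(surface, start, height = 3.1375, pace = 30,
                             widths = c(0.2, 0.2), bias_factor = 15,
                             T = 298.15, friction = 1, dt = 0.5,
                             n_steps, seed, cutoff_sig = 6.5,
                             stop_crossings = 0L, stop_divide = 0,
                             stop_hysteresis = 0.2, stop_min_steps = 0L,
                             wall = NULL, wall_k = 100) {
  stopifnot(inherits(surface, "model_surface"), length(start) == 2,
            length(widths) == 2)
  if (pace < 1) .stop_param("pace must be >= 1")
  if (any(widths <= 0)) .stop_param("hill widths must be > 0")
  if (height < 0) .stop_param("hill height must be >= 0")
  if (!is.infinite(bias_factor) && bias_factor <= 1)
    .stop_param("bias_factor must be > 1 (Delta T = (gamma-1) T must be ",
                "positive) or Inf for standard metadynamics")
  if (missing(seed)) .stop_param("seed must be supplied")
  set.seed(seed)
  kB_dT <- if (is.infinite(bias_factor)) Inf else
    (bias_factor - 1) * kBT(T) / 1  # k_B DeltaT in kcal/mol
  res <- cpp_metadynamics(.surface_form_code(surface$form),
                          unname(surface$params), start[1], start[2],
                          dt, friction, kBT(T), as.integer(n_steps),
                          as.integer(pace), height, widths[1], widths[2],
                          kB_dT, cutoff_sig, surface$domain,
                          as.integer(stop_crossings), stop_divide,
                          stop_hysteresis, as.integer(stop_min_steps),
                          if (is.null(wall)) numeric(4) else wall,
                          if (is.null(wall)) 0 else wall_k)
  if (res$status != 0L)
    stop(errorCondition(
      sprintf("metadynamics walker left the domain box after %d valid steps",
              res$n_done),
      class = c("metacage_domain_escape", "error", "condition"),
      last_frame = res$traj[res$n_done + 1L, ]))
  traj <- res$traj[seq_len(res$n_done + 1L), , drop = FALSE]
  hills <- as.data.frame(res$hills)
  names(hills) <- c("time", "center1", "center2", "sigma1", "sigma2", "height")
  hills <- new_hill_list(hills, bias_factor = bias_factor,
                         energy_unit = "kcal/mol", temperature = T)
  list(trajectory = .as_cv_trajectory(traj, dt, T, seed), hills = hills)
}
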