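# Model surfaces, Langevin dynamics, metadynamics hill deposition, and
# grouped point-charge environments.

test_that("double well has the declared minima, saddle and gradients", {
  v <- make_double_well(h = 24, a = 1, k = 2)
  expect_equal(surface_value(v, 1, 0), 0)
  expect_equal(surface_value(v, -1, 0), 0)
  expect_equal(surface_value(v, 0, 0), 24)
  for (p in list(c(-1, 0), c(1, 0), c(0, 0)))
    expect_lt(sqrt(sum(surface_gradient(v, p[1], p[2])^2)), 1e-8)
  # finite everywhere on the declared domain
  xs <- seq(v$domain[1], v$domain[2], length.out = 11)
  ys <- seq(v$domain[3], v$domain[4], length.out = 11)
  expect_true(all(is.finite(surface_value(
    v, rep(xs, each = 11), rep(ys, 11)))))
  expect_error(make_double_well(-1, 1, 1),
               class = "metacage_parameter_error")
  expect_error(make_double_well(1, 0, 1),
               class = "metacage_parameter_error")
})

test_that("langevin sampling of a harmonic well satisfies equipartition", {
  s <- make_harmonic(1)
  tr <- langevin_trajectory(s, c(0, 0), T = 298.15, friction = 1,
                            dt = 0.5, n_steps = 2e5, seed = 42)
  expect_equal(var(tr$cv[, 1]), kBT(298.15), tolerance = 0.05)
  expect_equal(var(tr$cv[, 2]), kBT(298.15), tolerance = 0.05)
})

test_that("langevin trajectories are deterministic and honor n_steps = 0", {
  s <- make_double_well(2, 1, 2)
  # friction 10 keeps overdamped Euler stable on this well (V'' = 16)
  t1 <- langevin_trajectory(s, c(-1, 0), friction = 10, n_steps = 500,
                            seed = 7)
  t2 <- langevin_trajectory(s, c(-1, 0), friction = 10, n_steps = 500,
                            seed = 7)
  expect_identical(t1$cv, t2$cv)
  t3 <- langevin_trajectory(s, c(-1, 0), friction = 10, n_steps = 500,
                            seed = 8)
  expect_false(identical(t1$cv, t3$cv))
  t0 <- langevin_trajectory(s, c(-0.7, 0.1), n_steps = 0, seed = 1)
  expect_equal(nrow(t0$cv), 1L)
  expect_equal(t0$cv[1, ], c(-0.7, 0.1))
})

test_that("leaving the domain raises a domain-escape condition with state", {
  s <- make_double_well(0.5, 1, 0.5, domain = c(-1.4, 1.4, -0.6, 0.6))
  err <- tryCatch(
    langevin_trajectory(s, c(1, 0), T = 2000, friction = 1, dt = 0.5,
                        n_steps = 5000, seed = 3),
    metacage_domain_escape = function(e) e)
  expect_s3_class(err, "metacage_domain_escape")
  expect_length(err$last_frame, 2)
  expect_s3_class(err$trajectory, "cv_trajectory")
})

test_that("metadynamics deposits on schedule and damps well-tempered", {
  s <- make_harmonic(2)
  run <- run_metadynamics(s, c(0, 0), height = 1, pace = 30,
                          widths = c(0.2, 0.2), bias_factor = Inf,
                          n_steps = 3000, seed = 5)
  expect_equal(nrow(run$hills), 100L)
  expect_true(all(run$hills$height == 1))  # no damping at gamma = Inf
  expect_equal(run$hills$time, (1:100) * 30 * 0.5)

  wt <- run_metadynamics(s, c(0, 0), height = 1, pace = 30,
                         widths = c(0.2, 0.2), bias_factor = 5,
                         n_steps = 6000, seed = 5)
  expect_lt(min(wt$hills$height), 1)   # later hills shrink
  expect_equal(max(wt$hills$height), 1)
  expect_error(run_metadynamics(s, c(0, 0), bias_factor = 1,
                                n_steps = 100, seed = 1),
               class = "metacage_parameter_error")
})

test_that("metadynamics drives the walker over a 6 kcal/mol barrier", {
  cfg <- default_config()
  surf <- make_double_well(6, 1, cfg$surface$k)
  m <- cfg$metadynamics
  run <- run_metadynamics(surf, c(-1, 0), height = m$height, pace = m$pace,
                          widths = m$widths, bias_factor = m$bias_factor,
                          friction = m$friction, dt = m$dt,
                          n_steps = 20000, seed = 12,
                          wall = m$wall, wall_k = m$wall_k)
  expect_gte(count_crossings(run$trajectory, 0, m$hysteresis), 3)
  expect_true(any(run$trajectory$cv[, 1] < -0.5) &&
                any(run$trajectory$cv[, 1] > 0.5))
})

test_that("point-charge fields follow Coulomb's law and superpose", {
  # lone +1 e charge 10 A from the probe along the bond axis:
  # |E| = 1439.96/10^2 = 14.40 MV/cm
  probe <- list(midpoint = c(0, 0, 0), unit = c(1, 0, 0))
  env1 <- list(groups = list(g = data.frame(q = 1, x = 10, y = 0, z = 0)),
               probes = list(bond1 = probe))
  f <- group_fields(env1)$g
  expect_equal(abs(unname(f[1])), 14.39965, tolerance = 1e-5)

  # mirror-symmetric pair about the probe, perpendicular to the bond
  env2 <- list(groups = list(g = data.frame(q = c(1, 1), x = c(0, 0),
                                            y = c(5, -5), z = c(0, 0))),
               probes = list(bond1 = probe))
  expect_equal(unname(group_fields(env2)$g[1]), 0)

  # per-group fields sum exactly to the merged-group field
  env <- make_charge_environment(seed = 19)
  merged <- do.call(rbind, env$groups)
  env_m <- list(groups = list(all = merged), probes = env$probes)
  fm <- group_fields(env_m)$all
  fg <- group_fields(env)
  expect_equal(fg$bulk_water + fg$complexed_water + fg$cage, fm,
               tolerance = 1e-12)
})

test_that("environment generator stores matching analytic ground truth", {
  env <- make_charge_environment(seed = 4)
  gf <- group_fields(env)
  for (g in names(gf))
    expect_equal(gf[[g]], env$ground_truth[[g]], tolerance = 1e-12)
  # all charges clear the probes by the minimum separation
  for (ch in env$groups) {
    if (!nrow(ch)) next
    for (pb in env$probes) {
      d <- sqrt((ch$x - pb$midpoint[1])^2 + (ch$y - pb$midpoint[2])^2 +
                  (ch$z - pb$midpoint[3])^2)
      expect_gt(min(d), 0.5)
    }
  }
  expect_warning(make_charge_environment(list(bulk_water = list(n = 0)),
                                         seed = 2),
                 "empty")
})
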