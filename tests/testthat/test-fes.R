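# Bias summation, well-tempered unbiasing, and crossing diagnostics.

test_that("a single hill reproduces its own Gaussian shape", {
  h <- new_hill_list(data.frame(time = 15, center1 = 0.5, center2 = 0.2,
                                sigma1 = 0.2, sigma2 = 0.1, height = 2))
  grid <- list(x = seq(-1, 2, length.out = 301),
               y = seq(-1, 1, length.out = 201))
  vb <- bias_potential(h, grid)
  at <- function(x, y) vb$values[which.min(abs(grid$x - x)),
                                 which.min(abs(grid$y - y))]
  expect_equal(at(0.5, 0.2), 2, tolerance = 1e-9)
  expect_equal(at(0.5 + 0.2, 0.2), 2 * exp(-0.5), tolerance = 1e-6)
  expect_equal(at(0.5, 0.2 - 0.1), 2 * exp(-0.5), tolerance = 1e-6)
})

test_that("truncated summation matches the brute-force oracle", {
  hills <- random_hill_list(100, seed = 31)
  grid <- list(x = seq(-3, 3, length.out = 121),
               y = seq(-3, 3, length.out = 121))
  vb <- bias_potential(hills, grid)  # default truncation radius
  oracle <- brute_force_bias(hills, grid$x, grid$y)
  expect_lt(max(abs(vb$values - oracle)), 1e-6)
  # untruncated evaluation agrees to round-off
  vb_inf <- bias_potential(hills, grid, cutoff_sig = Inf)
  expect_lt(max(abs(vb_inf$values - oracle)), 1e-10)
})

test_that("hills outside the grid margin are rejected by row", {
  hills <- random_hill_list(10, seed = 1)
  grid <- list(x = seq(-0.5, 0.5, length.out = 11),
               y = seq(-3, 3, length.out = 11))
  expect_error(bias_potential(hills, grid), "rows",
               class = "metacage_parameter_error")
})

test_that("well-tempered unbiasing rescales by gamma/(gamma-1)", {
  hills <- random_hill_list(40, seed = 8)
  grid <- list(x = seq(-3, 3, length.out = 61),
               y = seq(-3, 3, length.out = 61))
  f_std <- reconstruct_fes(hills, grid, bias_factor = Inf,
                           normalize = FALSE)
  f_wt <- reconstruct_fes(hills, grid, bias_factor = 15,
                          normalize = FALSE)
  expect_equal(f_wt$values, 15 / 14 * f_std$values, tolerance = 1e-12)
  # single hill at gamma = Inf: mirrored Gaussian of depth = height
  h1 <- new_hill_list(data.frame(time = 1, center1 = 0, center2 = 0,
                                 sigma1 = 0.2, sigma2 = 0.2, height = 3))
  f1 <- reconstruct_fes(h1, grid, bias_factor = Inf, normalize = FALSE)
  expect_equal(min(f1$values), -3, tolerance = 1e-9)
  f1n <- reconstruct_fes(h1, grid, bias_factor = Inf)
  expect_equal(min(f1n$values), 0)
  expect_true(f1n$normalized)
  expect_error(reconstruct_fes(hills, grid, bias_factor = 0.5),
               class = "metacage_parameter_error")
})

test_that("FES is monotone and linear in the deposited hills", {
  hills <- random_hill_list(30, seed = 12)
  grid <- list(x = seq(-3, 3, length.out = 41),
               y = seq(-3, 3, length.out = 41))
  f_all <- reconstruct_fes(hills, grid, bias_factor = Inf,
                           normalize = FALSE)
  f_sub <- reconstruct_fes(new_hill_list(hills[1:29, ]), grid,
                           bias_factor = Inf, normalize = FALSE)
  # adding a hill never increases F anywhere (before normalization)
  expect_true(all(f_all$values <= f_sub$values + 1e-12))
  # linearity in hill heights at gamma = Inf
  doubled <- hills
  doubled$height <- 2 * doubled$height
  f2 <- reconstruct_fes(new_hill_list(doubled), grid, bias_factor = Inf,
                        normalize = FALSE)
  expect_equal(f2$values, 2 * f_all$values, tolerance = 1e-12)
})

test_that("crossing counter uses committed (hysteresis) transitions", {
  expect_equal(count_crossings(c(-1, -0.5, 0.5, 1), 0, 0.2), 1L)
  # oscillation confined to the hysteresis band is noise, not crossings
  expect_equal(count_crossings(c(-1, -0.05, 0.05, -0.05, 0.05, -1),
                               0, 0.2), 0L)
  # scripted A -> B -> A -> B
  expect_equal(count_crossings(c(-1, 1, -1, 1), 0, 0.2), 3L)
  expect_warning(n <- count_crossings(c(0.5, 0.6, 0.7), 5, 0.2),
                 "outside")
  expect_equal(n, 0L)
  expect_error(count_crossings(c(-1, 1), 0, hysteresis = -1),
               class = "metacage_parameter_error")
})
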