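# Candidate selection by CV windows and committor estimation by shooting.

test_that("selection windows return exactly the planted frames", {
  ts <- c(2.1, 0.35)
  px <- planted_series(1000, 45, ts, seed = 77)
  got <- select_candidates(px$series, ts)
  expect_identical(got, px$planted)
  # a series containing exactly the TS point selects that frame
  s1 <- data.frame(dist = c(1.0, ts[1], 3.0), cn = c(0.9, ts[2], 0.05))
  expect_identical(select_candidates(s1, ts), 2L)
  # nothing in-window: empty with a warning, not an error
  far <- data.frame(dist = ts[1] + 1, cn = ts[2] + 1)
  expect_warning(none <- select_candidates(far, ts), "no frames")
  expect_length(none, 0)
  expect_error(select_candidates(s1, ts, tol_distance = 0),
               class = "metacage_parameter_error")
})

test_that("saddle shots split evenly; basin shots commit to themselves", {
  surf <- make_double_well(6, 1, 8)
  basins <- list(reactant = c(-1.3, -0.7, -0.3, 0.3),
                 product = c(0.7, 1.3, -0.3, 0.3))
  cr <- estimate_committor(surf, c(0, 0), basins, n_shots = 400,
                           friction = 50, seed = 5)
  expect_gte(cr$p_product, 0.44)
  expect_lte(cr$p_product, 0.56)
  expect_equal(sum(cr$outcomes), 400)
  expect_equal(cr$outcomes[["timeout"]], 0)
  deep <- estimate_committor(surf, c(-1, 0), basins, n_shots = 400,
                             friction = 50, seed = 6)
  expect_lt(deep$p_product, 0.05)
  # reproducible from the seed
  cr2 <- estimate_committor(surf, c(0, 0), basins, n_shots = 400,
                            friction = 50, seed = 5)
  expect_identical(cr$outcomes, cr2$outcomes)
})

test_that("committor rises monotonically from saddle toward product", {
  surf <- make_double_well(6, 1, 8)
  basins <- list(reactant = c(-1.3, -0.7, -0.3, 0.3),
                 product = c(0.7, 1.3, -0.3, 0.3))
  ps <- vapply(c(0, 0.2, 0.4), function(x)
    estimate_committor(surf, c(x, 0), basins, n_shots = 300,
                       friction = 50, seed = 40 + round(10 * x))$p_product,
    numeric(1))
  # allow binomial noise: each step must not DECREASE beyond CI slack
  expect_gt(ps[2], ps[1] - 0.07)
  expect_gt(ps[3], ps[2] - 0.07)
  expect_gt(ps[3], ps[1])
})

test_that("parameter guards: shots, basins, bands", {
  surf <- make_double_well(6, 1, 8)
  basins <- list(reactant = c(-1.3, -0.7, -0.3, 0.3),
                 product = c(0.7, 1.3, -0.3, 0.3))
  expect_error(estimate_committor(surf, c(0, 0), basins, n_shots = 0,
                                  seed = 1),
               class = "metacage_parameter_error")
  overlapping <- list(reactant = c(-1, 0.5, -1, 1),
                      product = c(0, 1, -1, 1))
  expect_error(estimate_committor(surf, c(0, 0), overlapping, n_shots = 10,
                                  seed = 1),
               "overlap", class = "metacage_parameter_error")
})

test_that("transition-state acceptance uses CI-band intersection", {
  # the reference workflow accepted 57% (n ~ 100) and an early 38%
  # commitment measured on a small ensemble; both must qualify
  expect_true(is_transition_state(fake_committor(57, 100)))
  expect_true(is_transition_state(fake_committor(19, 50)))   # p = 0.38
  expect_false(is_transition_state(fake_committor(396, 400)))  # p = 0.99
  expect_false(is_transition_state(fake_committor(4, 400)))
})

test_that("committor results serialize to JSON with their provenance", {
  surf <- make_double_well(6, 1, 8)
  basins <- list(reactant = c(-1.3, -0.7, -0.3, 0.3),
                 product = c(0.7, 1.3, -0.3, 0.3))
  cr <- estimate_committor(surf, c(0.1, 0), basins, n_shots = 50,
                           friction = 50, seed = 9)
  js <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_committor_result(cr, js, csv)
  back <- jsonlite::read_json(js)
  expect_equal(back$p_product, cr$p_product, tolerance = 1e-12)
  expect_equal(back$seed, 9)
  expect_equal(nrow(read.csv(csv)), 50)
})
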