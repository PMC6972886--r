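# Independent oracles and programmatic fixtures shared across tests.

# brute-force, untruncated Gaussian hill summation in plain R (the oracle
# for the compiled, truncated evaluation)
brute_force_bias <- function(hills, x, y) {
  v <- matrix(0, length(x), length(y))
  for (k in seq_len(nrow(hills))) {
    gx <- exp(-(x - hills$center1[k])^2 / (2 * hills$sigma1[k]^2))
    gy <- exp(-(y - hills$center2[k])^2 / (2 * hills$sigma2[k]^2))
    v <- v + hills$height[k] * outer(gx, gy)
  }
  v
}

# random hill list confined so a fixed grid covers every center +- 5 sigma
random_hill_list <- function(n, seed, bias_factor = Inf) {
  set.seed(seed)
  new_hill_list(data.frame(
    time = seq_len(n) * 15,
    center1 = runif(n, -1.2, 1.2),
    center2 = runif(n, -0.8, 0.8),
    sigma1 = runif(n, 0.1, 0.3),
    sigma2 = runif(n, 0.1, 0.3),
    height = runif(n, 0.2, 3)), bias_factor = bias_factor)
}

# FES grid sampled from an analytic function
analytic_fes <- function(f, xlim = c(-2, 2), ylim = c(-1.5, 1.5), n = 200) {
  x <- seq(xlim[1], xlim[2], length.out = n)
  y <- seq(ylim[1], ylim[2], length.out = n)
  new_fes_grid(x, y, outer(x, y, f))
}

quartic_dw <- function(h, a = 1, k = 2, tilt = 0) {
  function(x, y) h * ((x / a)^2 - 1)^2 + 0.5 * k * y^2 + tilt * x
}

# CV series with a known number of frames planted inside the selection
# windows around ts_point; the rest are placed well outside
planted_series <- function(n_total, n_in, ts_point, tol_d = 0.05,
                           tol_cn = 0.005, seed = 1) {
  set.seed(seed)
  in_idx <- sort(sample(n_total, n_in))
  d <- ts_point[1] + runif(n_total, 3 * tol_d, 10 * tol_d) *
    sample(c(-1, 1), n_total, replace = TRUE)
  cn <- ts_point[2] + runif(n_total, 3 * tol_cn, 10 * tol_cn) *
    sample(c(-1, 1), n_total, replace = TRUE)
  d[in_idx] <- ts_point[1] + runif(n_in, -tol_d, tol_d)
  cn[in_idx] <- ts_point[2] + runif(n_in, -tol_cn, tol_cn)
  list(series = data.frame(dist = d, cn = cn), planted = in_idx)
}

# two-frame XYZ fixture written programmatically
write_xyz_fixture <- function(path) {
  writeLines(c(
    "4", "frame 1",
    "Au 0.0 0.0 0.0", "C 2.1 0.0 0.0", "C 0.0 2.1 0.0", "P -2.3 0.0 0.1",
    "4", "frame 2",
    "Au 0.0 0.0 0.0", "C 2.4 0.0 0.0", "C 0.0 2.5 0.0", "P -2.3 0.0 0.1"),
    path)
  path
}

# a committor_result with a prescribed count, for band/CI semantics tests
fake_committor <- function(n_prod, n_shots) {
  structure(list(
    p_product = n_prod / n_shots, n_shots = as.integer(n_shots),
    ci95 = as.numeric(prop.test(n_prod, n_shots,
                                correct = FALSE)$conf.int),
    outcomes = c(product = n_prod, reactant = n_shots - n_prod,
                 timeout = 0L),
    point = c(0, 0), seed = 0L), class = "committor_result")
}
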