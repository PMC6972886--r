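# Grouped point-charge environments around a two-bond probe substrate.
# These emulate the three electrostatic source groups of the nanocage
# problem -- bulk solvent shell, one complexed (vicinal) water, and the
# charged cage shell -- around a model Au(CH3)2 fragment, with per-group
# projected fields known analytically by direct Coulomb summation.

.unit <- function(v) v / sqrt(sum(v^2))

#' Coulomb field of a point-charge set at a probe point
#'
#' Direct superposition \eqn{E = \sum_k k_e q_k (r - r_k)/|r - r_k|^3},
#' returned in MV/cm (charges in e, positions in Angstrom).
#'
#' @param charges data.frame with columns `q`, `x`, `y`, `z`.
#' @param probe length-3 probe position, Angstrom.
#' @return length-3 field vector, MV/cm.
#' @export
coulomb_field <- function(charges, probe) {
  if (!nrow(charges)) return(c(0, 0, 0))
  d <- cbind(probe[1] - charges$x, probe[2] - charges$y, probe[3] - charges$z)
  r <- sqrt(rowSums(d^2))
  colSums(.const$coulomb_MVcm * charges$q / r^3 * d)
}

.default_env_spec <- function() {
  list(
    bond_length = 2.1,       # Au-C distance, Angstrom
    bond_angle_deg = 90,     # C-Au-C angle
    bulk_water = list(n = 60, r_min = 8, r_max = 14, q = 0.4238),
    complexed_water = list(distance = 3.0),
    cage = list(n = 12, radius = 7, q = -1)
  )
}

#' Synthetic grouped point-charge environment with analytic ground truth
#'
#' Builds a model substrate (Au at the origin, two probe carbons at the
#' given bond length and angle) surrounded by three named charge groups:
#' `bulk_water` (randomly placed ± partial charges in a spherical shell),
#' `complexed_water` (one 3-point water near the substrate) and `cage`
#' (a symmetric shell of negative unit charges).  The per-group electric
#' fields projected on the two Au--C bonds at their midpoints are computed
#' by direct Coulomb summation and stored as ground truth alongside the
#' environment.
#'
#' @param spec nested list of group parameters; see
#'   `metacage:::.default_env_spec()` for the shape and defaults.  Set a
#'   group's `n` to 0 (or `distance` to `NULL`) for an empty group.
#' @param seed integer RNG seed.
#' @return a `charge_environment` with elements `substrate` (atoms data.frame),
#'   `groups` (named list of charge data.frames), `probes` (per-bond midpoint
#'   and Au->C unit vector) and `ground_truth` (per-group, per-bond projected
#'   fields in MV/cm).
#' @details Charges falling within 0.5 Angstrom of a probe point are resampled
#'   (rejection) so the minimum-separation invariant always holds.  An empty
#'   group is recorded with zero field and a warning.
#' @export
make_charge_environment <- function(spec = list(), seed) {
  if (missing(seed)) .stop_param("seed must be supplied")
  set.seed(seed)
  sp <- utils::modifyList(.default_env_spec(), spec)

  d <- sp$bond_length
  th <- sp$bond_angle_deg * pi / 180
  c1 <- d * c(1, 0, 0)
  c2 <- d * c(cos(th), sin(th), 0)
  substrate <- data.frame(
    atom = c("Au", "C1", "C2"),
    x = c(0, c1[1], c2[1]), y = c(0, c1[2], c2[2]), z = c(0, c1[3], c2[3]),
    q = c(0.9, -0.55, -0.55))  # nominal Au(III)+ fragment partial charges
  probes <- list(
    bond1 = list(midpoint = c1 / 2, unit = .unit(c1)),
    bond2 = list(midpoint = c2 / 2, unit = .unit(c2)))

  probe_pts <- rbind(probes$bond1$midpoint, probes$bond2$midpoint)
  min_sep_ok <- function(p)
    all(sqrt(rowSums(sweep(probe_pts, 2, p)^2)) > 0.5)
  sample_shell <- function(r_min, r_max) {
    repeat {
      v <- stats::rnorm(3)
      r <- stats::runif(1, r_min, r_max)
      p <- r * .unit(v)
      if (min_sep_ok(p)) return(p)
    }
  }

  groups <- list()
  bw <- sp$bulk_water
  if (!is.null(bw) && bw$n > 0) {
    pos <- t(vapply(seq_len(bw$n), function(i) sample_shell(bw$r_min, bw$r_max),
                    numeric(3)))
    groups$bulk_water <- data.frame(
      q = sample(c(-1, 1), bw$n, replace = TRUE) * bw$q,
      x = pos[, 1], y = pos[, 2], z = pos[, 3])
  } else groups$bulk_water <- data.frame(q = numeric(0), x = numeric(0),
                                         y = numeric(0), z = numeric(0))
  cw <- sp$complexed_water
  if (!is.null(cw) && !is.null(cw$distance)) {
    # 3-point water (O, H, H; SPC-like charges) on the bisector of the bonds
    o <- cw$distance * .unit(probes$bond1$unit + probes$bond2$unit)
    groups$complexed_water <- data.frame(
      q = c(-0.8476, 0.4238, 0.4238),
      x = o[1],
      y = o[2] + c(0, 0.59, 0.59),
      z = o[3] + c(0, 0.76, -0.76))
  } else groups$complexed_water <- data.frame(q = numeric(0), x = numeric(0),
                                              y = numeric(0), z = numeric(0))
  cg <- sp$cage
  if (!is.null(cg) && cg$n > 0) {
    # symmetric shell: vertices spread on a sphere by golden-angle spiral
    i <- seq_len(cg$n)
    zc <- (2 * i - 1) / cg$n - 1
    phi <- pi * (3 - sqrt(5)) * i
    rho <- sqrt(pmax(0, 1 - zc^2))
    groups$cage <- data.frame(q = rep(cg$q, cg$n),
                              x = cg$radius * rho * cos(phi),
                              y = cg$radius * rho * sin(phi),
                              z = cg$radius * zc)
  } else groups$cage <- data.frame(q = numeric(0), x = numeric(0),
                                   y = numeric(0), z = numeric(0))

  for (g in names(groups))
    if (!nrow(groups[[g]]))
      warning("group '", g, "' is empty; zero field recorded",
              call. = FALSE)

  ground_truth <- lapply(groups, function(ch)
    vapply(probes, function(pb)
      sum(coulomb_field(ch, pb$midpoint) * pb$unit), numeric(1)))

  structure(list(substrate = substrate, groups = groups, probes = probes,
                 ground_truth = ground_truth, spec = sp, seed = seed),
            class = "charge_environment")
}

#' @export
print.charge_environment <- function(x, ...) {
  cat("Point-charge environment (seed", x$seed, ")\n")
  for (g in names(x$groups))
    cat(sprintf("  %-16s %3d charges, projected fields (%.3f, %.3f) MV/cm\n",
                g, nrow(x$groups[[g]]),
                x$ground_truth[[g]][1], x$ground_truth[[g]][2]))
  invisible(x)
}
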