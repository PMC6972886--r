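# Electrostatic decomposition of the activation free energy: per-group
# electric fields projected onto the two Au-C bonds, bond dipoles from
# partial charges, and the bond-dipole/field stabilization energy
#
#   dG_elec = sum_i -K (mu_TS^i E_TS^i - mu_RS^i E_RS^i),   i = bond 1, 2
#
# with K = 0.048 kcal/mol per (Debye * MV/cm).  Positive projected fields
# point along the declared Au -> C bond direction (opposite to the electron
# flow of the forward reaction, i.e. the stabilizing orientation).

#' Energy conversion constant for dipole--field products
#'
#' The interaction energy of a 1-Debye bond dipole with a 1-MV/cm projected
#' field, per mole:
#' \eqn{(3.33564\times 10^{-30}\,\mathrm{C\,m}) (10^8\,\mathrm{V/m})
#' N_A / 4184 = 0.0480} kcal/mol.  Computed from CODATA constants at call
#' time and asserted equal to 0.048 at three decimals rather than
#' hard-coded.
#'
#' @return kcal/mol per (Debye x MV/cm).
#' @export
dipole_field_energy_constant <- function() {
  k <- .const$debye_Cm * 1e8 * .const$avogadro / .const$J_per_kcal
  stopifnot(abs(k - 0.048) < 5e-4)
  k
}

#' Project a field vector onto a bond
#'
#' Signed scalar projection of a 3-vector field onto the (normalized)
#' Au -> C bond unit vector.  Positive values point from Au to C.
#'
#' @param field length-3 field vector, MV/cm.
#' @param bond_unit length-3 unit vector (normalized within 1e-9).
#' @return signed scalar projection, MV/cm.
#' @export
project_field <- function(field, bond_unit) {
  stopifnot(length(field) == 3, length(bond_unit) == 3)
  if (abs(sqrt(sum(bond_unit^2)) - 1) > 1e-9)
    .stop_param("bond vector is not normalized")
  sum(field * bond_unit)
}

#' Bond dipole from two partial charges
#'
#' Symmetric two-point dipole about the bond midpoint:
#' \eqn{\mu = \tfrac{1}{2}(q_C - q_{Au})\, d \times 4.8032} Debye, with the
#' sign carrying orientation along Au -> C.  Other dipole conventions can be
#' swapped in by supplying precomputed dipoles to the snapshot table.
#'
#' @param q_au,q_c partial charges, e.
#' @param d bond length, Angstrom (> 0).
#' @return bond dipole, Debye.
#' @export
bond_dipole <- function(q_au, q_c, d) {
  if (any(d <= 0)) .stop_param("bond length must be > 0")
  (q_c - q_au) / 2 * d * .const$debye_per_eA
}

#' Per-group fields projected on the probe bonds of an environment
#'
#' Direct Coulomb superposition of each charge group evaluated at each bond
#' midpoint, projected on the Au -> C unit vector.  Charges closer than
#' 0.5 Angstrom to a probe are excluded with a warning (near-singular
#' contributions).
#'
#' @param env a `charge_environment` (see [make_charge_environment()]), or
#'   any list with `groups` and `probes` of the same shape.
#' @return named list (per group) of length-2 vectors (per bond), MV/cm.
#' @export
group_fields <- function(env) {
  probes <- env$probes
  lapply(env$groups, function(ch) {
    vapply(probes, function(pb) {
      if (!nrow(ch)) return(0)
      d <- sqrt((ch$x - pb$midpoint[1])^2 + (ch$y - pb$midpoint[2])^2 +
                  (ch$z - pb$midpoint[3])^2)
      if (any(d <= 0.5)) {
        warning(sum(d <= 0.5), " charge(s) within 0.5 A of a probe ",
                "excluded", call. = FALSE)
        ch <- ch[d > 0.5, , drop = FALSE]
        if (!nrow(ch)) return(0)
      }
      sum(coulomb_field(ch, pb$midpoint) * pb$unit)
    }, numeric(1))
  })
}

#' Electrostatic transition-state stabilization for one source group
#'
#' Applies the bond-dipole/field decomposition summed over both bonds:
#' \eqn{\Delta G_{elec} = \sum_{i=1,2} -K (\mu^i_{TS} E^i_{TS} -
#' \mu^i_{RS} E^i_{RS})} with K from
#' [dipole_field_energy_constant()] rounded to the conventional 0.048.
#'
#' @param table a `snapshot_table` holding both states and both bonds.
#' @param group source-group name (e.g. `"bulk_water"`).
#' @param K conversion constant (default 0.048 kcal/mol per Debye MV/cm,
#'   the conventional rounding of the derived constant).
#' @return kcal/mol (negative = net TS stabilization by this group).
#' @export
delta_g_elec <- function(table, group, K = 0.048) {
  stopifnot(inherits(table, "snapshot_table"))
  terms <- vapply(c(1L, 2L), function(b) {
    mu_ts <- snapshot_value(table, "TS", b)
    mu_rs <- snapshot_value(table, "RS", b)
    e_ts <- snapshot_value(table, "TS", b, group)
    e_rs <- snapshot_value(table, "RS", b, group)
    -K * (mu_ts * e_ts - mu_rs * e_rs)
  }, numeric(1))
  sum(terms)
}

#' Decompose the electrostatic activation energy of one reaction by group
#'
#' Computes `delta_g_elec` for every group present in the table plus their
#' total.  The table must be complete: both states x both bonds for each
#' group (groups absent from the table are simply not decomposed -- absent,
#' not zero).
#'
#' @inheritParams delta_g_elec
#' @return an `electrostatic_decomposition`: named per-group contributions,
#'   `total`, and the conversion constant used.
#' @export
decompose <- function(table, K = 0.048) {
  stopifnot(inherits(table, "snapshot_table"))
  groups <- unique(table$group)
  missing_keys <- character(0)
  for (g in groups) for (s in c("RS", "TS")) for (b in 1:2)
    if (!any(table$state == s & table$bond == b & table$group == g))
      missing_keys <- c(missing_keys, paste(s, b, g, sep = "/"))
  if (length(missing_keys))
    .stop_schema("incomplete snapshot table; missing keys: ",
                 paste(missing_keys, collapse = ", "))
  per_group <- vapply(groups, function(g) delta_g_elec(table, g, K),
                      numeric(1))
  structure(list(groups = setNames(as.numeric(per_group), groups),
                 total = sum(per_group), K = K),
            class = "electrostatic_decomposition")
}

#' @export
print.electrostatic_decomposition <- function(x, ...) {
  cat("Electrostatic TS stabilization (kcal/mol):\n")
  for (g in names(x$groups))
    cat(sprintf("  %-16s %8.3f\n", g, x$groups[g]))
  cat(sprintf("  %-16s %8.3f\n", "total", x$total))
  invisible(x)
}

#' Compare the electrostatic totals of two reactions
#'
#' @param catalyzed,uncatalyzed `electrostatic_decomposition` objects (or
#'   `snapshot_table`s, which are decomposed first).
#' @return list with both totals, their difference
#'   (catalyzed - uncatalyzed, kcal/mol) and its magnitude -- the net
#'   electrostatic contribution to catalysis.
#' @export
compare_decompositions <- function(catalyzed, uncatalyzed) {
  if (inherits(catalyzed, "snapshot_table")) catalyzed <- decompose(catalyzed)
  if (inherits(uncatalyzed, "snapshot_table"))
    uncatalyzed <- decompose(uncatalyzed)
  d <- catalyzed$total - uncatalyzed$total
  list(catalyzed_total = catalyzed$total,
       uncatalyzed_total = uncatalyzed$total,
       difference = d, magnitude = abs(d))
}
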