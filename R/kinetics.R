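# Transition-state-theory rate comparisons.

#' TST rate acceleration from two activation free energies
#'
#' Ratio of TST rates, \eqn{\exp[(\Delta G^\ddagger_{uncat} -
#' \Delta G^\ddagger_{cat}) / RT]}, with RT in kcal/mol (0.5925 at
#' 298.15 K).
#'
#' @param dg_uncat,dg_cat activation free energies, kcal/mol.
#' @param T temperature, K (default 298.15).
#' @return dimensionless acceleration factor (`> 1` when the catalyzed
#'   barrier is lower).
#' @export
tst_acceleration <- function(dg_uncat, dg_cat, T = 298.15) {
  if (T <= 0) .stop_param("T must be > 0")
  exp((dg_uncat - dg_cat) / kBT(T))
}

#' TST comparison report
#'
#' @inheritParams tst_acceleration
#' @return a `rate_comparison` list: barriers, T, RT, acceleration.
#' @export
rate_comparison <- function(dg_uncat, dg_cat, T = 298.15) {
  structure(list(dg_uncat = dg_uncat, dg_cat = dg_cat, T = T,
                 RT = kBT(T),
                 acceleration = tst_acceleration(dg_uncat, dg_cat, T)),
            class = "rate_comparison")
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat(sprintf(
    "TST: dG(uncat) = %.3f, dG(cat) = %.3f kcal/mol at %.2f K\n",
    x$dg_uncat, x$dg_cat, x$T))
  cat(sprintf("  rate acceleration = %.3g\n", x$acceleration))
  invisible(x)
}
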