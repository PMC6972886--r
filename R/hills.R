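# hill_list: the record of deposited metadynamics Gaussians.  A data.frame
# with columns time (fs), center1 (distance CV, Angstrom), center2 (CN CV),
# sigma1, sigma2, height (kcal/mol), plus bias_factor / energy_unit /
# temperature attributes.

#' Construct a hill list
#'
#' @param df data.frame with columns `time`, `center1`, `center2`, `sigma1`,
#'   `sigma2`, `height`.
#' @param bias_factor well-tempered gamma used at deposition (`Inf` for
#'   standard metadynamics).
#' @param energy_unit unit of the `height` column as stored (always kcal/mol
#'   internally).
#' @param temperature simulation temperature, K.
#' @return a `hill_list` (data.frame subclass).
#' @export
new_hill_list <- function(df, bias_factor = Inf, energy_unit = "kcal/mol",
                          temperature = 298.15) {
  need <- c("time", "center1", "center2", "sigma1", "sigma2", "height")
  if (!all(need %in% names(df)))
    .stop_schema("hill list lacks columns: ",
                 paste(setdiff(need, names(df)), collapse = ", "))
  df <- as.data.frame(df)[need]
  if (nrow(df)) {
    if (any(df$sigma1 <= 0) || any(df$sigma2 <= 0))
      .stop_param("hill widths must be > 0")
    if (any(df$height < 0)) .stop_param("hill heights must be >= 0")
    if (is.unsorted(df$time)) .stop_param("hill times must be non-decreasing")
  }
  structure(df, class = c("hill_list", "data.frame"),
            bias_factor = bias_factor, energy_unit = energy_unit,
            temperature = temperature)
}

#' @export
print.hill_list <- function(x, ...) {
  cat("Hill list:", nrow(x), "Gaussians, bias factor",
      attr(x, "bias_factor"), "\n")
  if (nrow(x)) {
    cat("  time span:", min(x$time), "-", max(x$time), "fs;",
        "heights", signif(min(x$height), 4), "-",
        signif(max(x$height), 4), "kcal/mol\n")
    print(head(as.data.frame(x), 5L))
    if (nrow(x) > 5L) cat("  ...", nrow(x) - 5L, "more rows\n")
  }
  invisible(x)
}
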