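# Collective variables of the reductive-elimination reaction: the distance
# between the two leaving methyl carbons, and the rational-switching
# coordination number between gold and those carbons.

#' Coordination-number switching parameters
#'
#' The rational switching function uses exponent pair (p, q) = (8, 14) and a
#' reference equilibrium Au--C distance R0; the default R0 of 2.1 Angstrom is
#' a typical Au(III)--C bond length.
#'
#' @param R0 reference distance, Angstrom.
#' @param p,q numerator/denominator exponents, 0 < p < q.
#' @return a `cn_params` list.
#' @export
cn_params <- function(R0 = 2.1, p = 8L, q = 14L) {
  if (R0 <= 0) .stop_param("R0 must be > 0")
  if (!(p > 0 && q > p)) .stop_param("exponents must satisfy 0 < p < q")
  structure(list(R0 = R0, p = as.integer(p), q = as.integer(q)),
            class = "cn_params")
}

#' Distance between the two leaving methyl carbons
#'
#' @param frame a `frame` (see [read_xyz()]) or any list with an n x 3
#'   `coords` matrix.
#' @param c1,c2 atom indices of the two carbons.
#' @return Euclidean distance, Angstrom.  Coincident positions return 0 with
#'   a degenerate-geometry warning.
#' @export
methyl_distance <- function(frame, c1, c2) {
  xyz <- frame$coords
  n <- nrow(xyz)
  if (c1 == c2) .stop_param("c1 and c2 must be distinct atom indices")
  if (c1 < 1 || c2 < 1 || c1 > n || c2 > n)
    .stop_param("atom index out of range (frame has ", n, " atoms)")
  d <- sqrt(sum((xyz[c1, ] - xyz[c2, ])^2))
  if (d == 0)
    warning("degenerate geometry: the two carbons coincide", call. = FALSE)
  d
}

# switching term [1 - (r/R0)^p] / [1 - (r/R0)^q], with the removable
# singularity at r = R0 evaluated as its limit p/q
.switch_term <- function(r, params) {
  u <- r / params$R0
  out <- numeric(length(u))
  at_R0 <- abs(u - 1) < 1e-9
  out[at_R0] <- params$p / params$q
  out[!at_R0] <- (1 - u[!at_R0]^params$p) / (1 - u[!at_R0]^params$q)
  out
}

#' Gold--carbon coordination number
#'
#' Smooth count of Au--C bonds,
#' \deqn{CN = \tfrac{1}{2}\sum_{i\in\{1,2\}}
#'   \frac{1 - (r_i/R_0)^p}{1 - (r_i/R_0)^q},}
#' continuous and strictly decreasing in each distance, with value p/q at
#' r = R0 and limits 1 (r -> 0) and 0 (r -> Inf).
#'
#' @param frame a `frame` with a `coords` matrix.
#' @param au atom index of the gold.
#' @param carbons length-2 atom indices of the two methyl carbons.
#' @param params a [cn_params()] object.
#' @return dimensionless coordination number in (0, 1].
#' @export
coordination_number <- function(frame, au, carbons, params = cn_params()) {
  stopifnot(inherits(params, "cn_params"), length(carbons) == 2)
  xyz <- frame$coords
  if (au %in% carbons) .stop_param("gold and carbon indices must differ")
  r <- vapply(carbons, function(ci)
    sqrt(sum((xyz[ci, ] - xyz[au, ])^2)), numeric(1))
  cn_from_distances(r, params)
}

#' Coordination number from the two Au--C distances directly
#'
#' @param r numeric vector of Au--C distances, Angstrom.
#' @param params a [cn_params()] object.
#' @return mean switching-function value over `r`.
#' @export
cn_from_distances <- function(r, params = cn_params()) {
  if (any(r < 0)) .stop_param("distances must be non-negative")
  mean(.switch_term(r, params))
}

#' Evaluate both CVs over an XYZ trajectory
#'
#' @param frames list of `frame` objects.
#' @param au,carbons atom indices (see [coordination_number()]).
#' @param params a [cn_params()] object.
#' @return data.frame with columns `frame`, `dist` (methyl--methyl, Angstrom)
#'   and `cn`.
#' @export
cv_series <- function(frames, au, carbons, params = cn_params()) {
  out <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    data.frame(frame = i,
               dist = methyl_distance(f, carbons[1], carbons[2]),
               cn = coordination_number(f, au, carbons, params))
  })
  do.call(rbind, out)
}
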