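# File formats.  All pairs (write_x, read_x) round-trip bit-compatibly; all
# readers reject malformed input rather than silently repairing it.
#
#   HILLS       PLUMED-style whitespace table: time cv1 cv2 sigma1 sigma2
#               height biasf, with '#!'-prefixed header lines.  The cp2k
#               dialect stores heights in Hartree (converted to kcal/mol
#               on read).
#   XYZ         standard multi-frame Cartesian trajectory.
#   FES         three-column text (cv1 cv2 free_energy) with a metadata
#               header; row-major over the cv1 grid.
#   snapshot    CSV of per-state, per-bond, per-group projected fields and
#               bond dipoles (the worked-example table layout).

.hartree_to_kcal <- function(x) x * .const$hartree_kcal

#' Read a metadynamics HILLS file
#'
#' @param path file path.
#' @param dialect `"plumed"` (heights already in energy units, default
#'   kcal/mol, overridable by a `#! SET energy_unit hartree` header line) or
#'   `"cp2k"` (heights in Hartree, converted to kcal/mol).
#' @return a `hill_list`.  Hill heights are always kcal/mol in memory.
#' @export
read_hills <- function(path, dialect = c("plumed", "cp2k")) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) .stop_param("unknown dialect"))
  if (!file.exists(path)) .stop_param("no such file: ", path)
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  unit <- "kcal/mol"
  biasf <- Inf
  for (h in lines[hdr]) {
    if (grepl("SET energy_unit", h))
      unit <- trimws(sub(".*SET energy_unit", "", h))
    if (grepl("SET biasfactor", h)) {
      bf <- trimws(sub(".*SET biasfactor", "", h))
      biasf <- if (bf %in% c("Inf", "inf")) Inf else as.numeric(bf)
    }
  }
  body_idx <- which(!hdr & nzchar(trimws(lines)))
  rows <- vector("list", length(body_idx))
  for (i in seq_along(body_idx)) {
    fields <- strsplit(trimws(lines[body_idx[i]]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 6 || anyNA(vals[1:6]))
      stop(errorCondition(
        sprintf("malformed HILLS line %d: '%s'", body_idx[i],
                lines[body_idx[i]]),
        class = c("metacage_parse_error", "error", "condition")))
    rows[[i]] <- vals[1:7]
  }
  m <- do.call(rbind, rows)
  if (is.null(m)) m <- matrix(numeric(0), 0, 7)
  df <- data.frame(time = m[, 1], center1 = m[, 2], center2 = m[, 3],
                   sigma1 = m[, 4], sigma2 = m[, 5], height = m[, 6])
  if (nrow(m) && !all(is.na(m[, 7]))) {
    bf <- unique(m[, 7][!is.na(m[, 7])])
    if (length(bf) == 1) biasf <- if (bf <= 0) Inf else bf
  }
  if (nrow(df) && is.unsorted(df$time)) {
    bad <- which(diff(df$time) < 0)[1] + 1L
    stop(errorCondition(
      sprintf("decreasing time at HILLS line %d", body_idx[bad]),
      class = c("metacage_parse_error", "error", "condition")))
  }
  if (dialect == "cp2k" || tolower(unit) %in% c("hartree", "ha", "au"))
    df$height <- .hartree_to_kcal(df$height)
  new_hill_list(df, bias_factor = biasf, energy_unit = "kcal/mol")
}

#' Write a metadynamics HILLS file
#'
#' @param hills a `hill_list`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hills <- function(hills, path) {
  stopifnot(inherits(hills, "hill_list"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#! FIELDS time cv1 cv2 sigma_cv1 sigma_cv2 height biasf",
               "#! SET energy_unit kcal/mol",
               paste("#! SET biasfactor", attr(hills, "bias_factor"))), con)
  bf <- attr(hills, "bias_factor")
  bf_col <- if (is.infinite(bf)) -1 else bf
  if (nrow(hills)) {
    m <- cbind(hills$time, hills$center1, hills$center2,
               hills$sigma1, hills$sigma2, hills$height, bf_col)
    writeLines(apply(m, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path file path.
#' @return list of `frame` objects (`labels`, n x 3 `coords` in Angstrom,
#'   `index`, `comment`).
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) .stop_param("no such file: ", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  fi <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    fi <- fi + 1L
    if (is.na(n) || n < 1 || i + 1L + n > length(lines))
      stop(errorCondition(
        sprintf("XYZ atom-count mismatch at frame %d (line %d)", fi, i),
        class = c("metacage_parse_error", "error", "condition")))
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    if (any(lengths(parts) < 4))
      stop(errorCondition(
        sprintf("malformed XYZ atom line in frame %d", fi),
        class = c("metacage_parse_error", "error", "condition")))
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(coords))
      stop(errorCondition(
        sprintf("non-numeric coordinate in XYZ frame %d", fi),
        class = c("metacage_parse_error", "error", "condition")))
    frames[[fi]] <- structure(
      list(labels = vapply(parts, `[`, "", 1L), coords = coords,
           index = fi, comment = lines[i + 1L]),
      class = "frame")
    i <- i + 2L + n
  }
  frames
}

#' Write a multi-frame XYZ trajectory
#'
#' @param frames list of `frame` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    writeLines(c(as.character(nrow(f$coords)),
                 if (is.null(f$comment)) "" else f$comment), con)
    writeLines(sprintf("%s %.10f %.10f %.10f", f$labels,
                       f$coords[, 1], f$coords[, 2], f$coords[, 3]), con)
  }
  invisible(path)
}

#' Write a free-energy surface grid as three-column text
#'
#' Metadata (grid shape, normalization, provenance) goes into `#`-prefixed
#' header lines; the body is `cv1 cv2 value` row-major over the cv1 axis.
#'
#' @param grid a `fes_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fes <- function(grid, path) {
  stopifnot(inherits(grid, "fes_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# metacage FES nx %d ny %d normalized %d n_hills %d gamma %s",
    length(grid$x), length(grid$y), as.integer(grid$normalized),
    grid$n_hills, format(grid$bias_factor)), con)
  xs <- rep(grid$x, times = length(grid$y))
  ys <- rep(grid$y, each = length(grid$x))
  writeLines(sprintf("%.17g %.17g %.17g", xs, ys, as.vector(grid$values)),
             con)
  invisible(path)
}

#' Read a free-energy surface grid written by [write_fes()]
#'
#' @param path file path.
#' @return a `fes_grid`.
#' @export
read_fes <- function(path) {
  if (!file.exists(path)) .stop_param("no such file: ", path)
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)][1]
  if (is.na(hdr) || !grepl("metacage FES", hdr))
    stop(errorCondition("not a metacage FES file (missing header)",
                        class = c("metacage_parse_error", "error",
                                  "condition")))
  toks <- strsplit(trimws(sub("^#", "", hdr)), "\\s+")[[1]]
  get <- function(key) toks[which(toks == key) + 1L]
  nx <- as.integer(get("nx")); ny <- as.integer(get("ny"))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) != nx * ny)
    stop(errorCondition(
      sprintf("FES body has %d rows, expected %d", length(body), nx * ny),
      class = c("metacage_parse_error", "error", "condition")))
  m <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
              ncol = 3, byrow = TRUE)
  x <- unique(m[, 1]); y <- unique(m[, 2])
  gamma <- get("gamma")
  new_fes_grid(x = x, y = y,
               values = matrix(m[, 3], nrow = nx, ncol = ny),
               normalized = as.integer(get("normalized")) == 1L,
               n_hills = as.integer(get("n_hills")),
               bias_factor = if (gamma %in% c("Inf", "inf")) Inf
                             else as.numeric(gamma))
}

.snapshot_cols <- c("state", "bond", "group", "field_MV_cm", "dipole_D")

#' Read a snapshot field/dipole table
#'
#' The table holds, for one reaction, the per-source-group electric fields
#' projected on each Au--C bond and the bond dipoles, for the reactant (RS)
#' and transition (TS) states.  Required columns: `state` (RS/TS), `bond`
#' (1/2), `group`, `field_MV_cm`, `dipole_D`; optional raw-data columns
#' `q_au_e`, `q_c_e`, `d_A`.
#'
#' @param path CSV file path.
#' @return a `snapshot_table` (data.frame subclass).
#' @export
read_snapshot_table <- function(path) {
  if (!file.exists(path)) .stop_param("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.snapshot_cols, names(df))
  if (length(missing_cols))
    .stop_schema("snapshot table lacks columns: ",
                 paste(missing_cols, collapse = ", "))
  new_snapshot_table(df)
}

#' Construct/validate a snapshot table
#'
#' @param df data.frame with the snapshot schema (see
#'   [read_snapshot_table()]).
#' @return a `snapshot_table`.
#' @export
new_snapshot_table <- function(df) {
  missing_cols <- setdiff(.snapshot_cols, names(df))
  if (length(missing_cols))
    .stop_schema("snapshot table lacks columns: ",
                 paste(missing_cols, collapse = ", "))
  if (!all(df$state %in% c("RS", "TS")))
    .stop_schema("state must be RS or TS")
  if (!all(df$bond %in% c(1L, 2L)))
    .stop_schema("bond must be 1 or 2")
  # dipoles are a per-(state, bond) property: must be single-valued
  for (s in unique(df$state)) for (b in unique(df$bond)) {
    mu <- unique(df$dipole_D[df$state == s & df$bond == b])
    if (length(mu) > 1)
      .stop_schema("inconsistent dipole for state ", s, " bond ", b)
  }
  structure(as.data.frame(df), class = c("snapshot_table", "data.frame"))
}

#' Write a snapshot table as CSV
#'
#' @param table a `snapshot_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snapshot_table <- function(table, path) {
  stopifnot(inherits(table, "snapshot_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up one snapshot-table entry
#'
#' @param table a `snapshot_table`.
#' @param state `"RS"` or `"TS"`.
#' @param bond 1 or 2.
#' @param group source-group name; `NULL` returns the bond dipole instead.
#' @return projected field (MV/cm) or dipole (Debye).
#' @export
snapshot_value <- function(table, state, bond, group = NULL) {
  if (is.null(group)) {
    v <- unique(table$dipole_D[table$state == state & table$bond == bond])
    if (!length(v)) .stop_schema("no dipole for state ", state,
                                 " bond ", bond)
    return(v)
  }
  v <- table$field_MV_cm[table$state == state & table$bond == bond &
                           table$group == group]
  if (!length(v)) .stop_schema("no field entry for (", state, ", ", bond,
                               ", ", group, ")")
  v
}
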