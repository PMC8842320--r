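## File interfaces: extended-XYZ configurations, LAMMPS-style data files
## (for cross-checks against external MD codes), and friction-trace CSV.

.layer_tag <- function(sys) {
  paste0(ifelse(sys$layer == 0L, "SUB", "SUP"),
         ifelse(sys$group %in% c(0L, 1L), "-rigid", "-mol"))
}

#' Write a configuration in extended-XYZ format
#'
#' Columns: species, x, y, z (nm), charge (e), layer tag.  The comment line
#' carries the Lattice (with the non-periodic z extent) and Properties
#' fields in the usual extended-XYZ convention.
#'
#' @param sys a `zw_system`.
#' @param file output path.
#' @param positions optional positions overriding `sys$positions`.
#' @param comment extra text appended to the comment line.
#' @export
write_extxyz <- function(sys, file, positions = NULL, comment = "") {
  pos <- if (is.null(positions)) sys$positions else positions
  n <- nrow(pos)
  zext <- diff(range(pos[, 3])) + 2
  hdr <- sprintf(
    paste0('Lattice="%.8f 0 0 0 %.8f 0 0 0 %.8f" ',
           'Properties=species:S:1:pos:R:3:charge:R:1:layer:S:1 ',
           'pbc="T T F" %s'),
    sys$box[[1]], sys$box[[2]], zext, comment)
  lines <- c(as.character(n), trimws(hdr),
             sprintf("%-4s %.9f %.9f %.9f %.4f %s",
                     sys$species, pos[, 1], pos[, 2], pos[, 3],
                     sys$charge, .layer_tag(sys)))
  writeLines(lines, file)
  invisible(file)
}

#' Read an extended-XYZ configuration written by [write_extxyz()]
#'
#' @param file path.
#' @return list with `positions`, `species`, `charge`, `layer_tag`, `box`.
#' @export
read_extxyz <- function(file) {
  lines <- readLines(file)
  n <- as.integer(lines[1])
  hdr <- lines[2]
  lat <- regmatches(hdr, regexpr('Lattice="[^"]*"', hdr))
  box <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", lat), " ")[[1]])
  body <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  species <- vapply(body, `[`, "", 1)
  pos <- t(vapply(body, function(x) as.numeric(x[2:4]), numeric(3)))
  charge <- vapply(body, function(x) as.numeric(x[5]), 0)
  tag <- vapply(body, `[`, "", 6)
  list(positions = pos, species = species, charge = charge,
       layer_tag = tag, box = c(lx = box[1], ly = box[5], lz = box[9]))
}

#' Write a LAMMPS-style data file
#'
#' Full-style atoms (id, molecule, type, charge, x, y, z) with Masses,
#' Bonds and Angles sections, for loading the system into an external MD
#' code for cross-checks.  Atom types are numbered in the order CA, R1,
#' R2, R3, AN, NP1, NP2, RIG.
#'
#' @param sys a `zw_system`.
#' @param file output path.
#' @param positions optional positions overriding `sys$positions`.
#' @export
write_lammps_data <- function(sys, file, positions = NULL) {
  pos <- if (is.null(positions)) sys$positions else positions
  n <- nrow(pos)
  zlo <- min(pos[, 3]) - 2; zhi <- max(pos[, 3]) + 2
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("LAMMPS data file: two sliding zwitterionic monolayers (units: nm, eV, e)")
  w("")
  w("%d atoms", n)
  w("%d bonds", nrow(sys$bonds))
  w("%d angles", nrow(sys$angles))
  w("%d atom types", 8L)
  w("%d bond types", length(unique(sys$bond_r0)))
  w("%d angle types", length(unique(sys$angle_theta0)))
  w("")
  w("0.0 %.8f xlo xhi", sys$box[[1]])
  w("0.0 %.8f ylo yhi", sys$box[[2]])
  w("%.8f %.8f zlo zhi", zlo, zhi)
  w("")
  w("Masses")
  w("")
  mass_by_type <- c(60, 15, 15, 15, 80, 50, 50, 50)
  for (t in 1:8) w("%d %.4f", t, mass_by_type[t])
  w("")
  w("Atoms # full")
  w("")
  for (i in seq_len(n))
    w("%d %d %d %.4f %.9f %.9f %.9f", i, sys$mol_id[i], sys$type[i],
      sys$charge[i], pos[i, 1], pos[i, 2], pos[i, 3])
  w("")
  w("Bonds")
  w("")
  bt <- match(sys$bond_r0, unique(sys$bond_r0))
  for (b in seq_len(nrow(sys$bonds)))
    w("%d %d %d %d", b, bt[b], sys$bonds[b, 1], sys$bonds[b, 2])
  w("")
  w("Angles")
  w("")
  at <- match(sys$angle_theta0, unique(sys$angle_theta0))
  for (aa in seq_len(nrow(sys$angles)))
    w("%d %d %d %d %d", aa, at[aa], sys$angles[aa, 1], sys$angles[aa, 2],
      sys$angles[aa, 3])
  invisible(file)
}

#' Write / read a friction trace as CSV
#'
#' The header comment names the units of every column.
#'
#' @param trace a `zw_trace`.
#' @param file path.
#' @export
write_trace_csv <- function(trace, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0(
    "# time:ps x_stage:nm x_sup:nm stress:MPa U:eV h:percent d:nm ",
    "T_inst:K ke:eV vz_sup:nm/ps e_recip:eV step:1"), con)
  for (a in c("area", "v_stage_ms", "dt_ps", "load_mpa", "temperature"))
    if (!is.null(attr(trace, a)))
      writeLines(sprintf("# %s = %g", a, attr(trace, a)), con)
  utils::write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trace_csv
#' @return `read_trace_csv`: the `zw_trace`.
#' @export
read_trace_csv <- function(file) {
  lines <- readLines(file)
  meta <- grep("^# \\w+ = ", lines, value = TRUE)
  tr <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  for (m in meta) {
    kv <- strsplit(sub("^# ", "", m), " = ")[[1]]
    attr(tr, kv[1]) <- as.numeric(kv[2])
  }
  class(tr) <- c("zw_trace", "data.frame")
  tr
}
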