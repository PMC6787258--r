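# Readers and writers for the coordinate dialects the pipeline accepts:
# GRO (fixed columns, nm), PDB (CRYST1 + ATOM/HETATM, Angstrom) and a
# whitespace XYZ table with an explicit role column. Coordinates are nm
# internally (GRO convention); PDB Angstroms are converted on read/write.

#' Default bead-name-to-role rules
#'
#' Named character vector of regular expressions mapping bead/atom names to
#' roles: names are roles, values are patterns. Defaults cover common
#' coarse-grained head-bead and backbone names.
#' @return Named character vector.
#' @export
default_role_rules <- function() {
  c(membrane_head = "^(PO4|NC3|NH3|CNO|PO1|PO2)$",
    protein_backbone = "^(BB|BAS|CA)$")
}

assign_roles <- function(names, rules = default_role_rules()) {
  role <- rep("other", length(names))
  for (r in names(rules)) {
    role[grepl(rules[[r]], names)] <- r
  }
  role
}

parse_gro_block <- function(lines, start, rules) {
  natoms <- suppressWarnings(as.integer(trimws(lines[start + 1L])))
  if (is.na(natoms)) {
    rlang::abort(sprintf("GRO: invalid atom count at line %d.", start + 1L))
  }
  end <- start + 1L + natoms
  if (end + 1L > length(lines)) {
    rlang::abort(sprintf("GRO: truncated frame starting at line %d.", start))
  }
  at <- lines[(start + 2L):end]
  nm <- trimws(substr(at, 11, 15))
  x <- suppressWarnings(as.numeric(substr(at, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(at, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(at, 37, 44)))
  if (anyNA(c(x, y, z))) {
    bad <- start + 1L + which(is.na(x) | is.na(y) | is.na(z))[1]
    rlang::abort(sprintf("GRO: unparseable coordinates at line %d.", bad))
  }
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[end + 1L]),
                                              "\\s+")[[1]][1:3]))
  if (anyNA(box)) {
    rlang::abort(sprintf("GRO: invalid box line at line %d.", end + 1L))
  }
  title <- lines[start]
  time <- 0
  tm <- regmatches(title, regexpr("t=\\s*[0-9.eE+-]+", title))
  if (length(tm)) time <- as.numeric(sub("t=\\s*", "", tm))
  list(frame = labeled_frame(cbind(x, y, z), assign_roles(nm, rules), box,
                             time = time, name = nm),
       next_line = end + 2L)
}

read_gro <- function(path, rules) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    blk <- parse_gro_block(lines, i, rules)
    frames[[length(frames) + 1L]] <- blk$frame
    i <- blk$next_line
  }
  frames
}

write_gro <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  resname <- c(membrane_head = "LIP", protein_backbone = "PRO", other = "OTH")
  for (fr in frames) {
    n <- nrow(fr$coords)
    writeLines(sprintf("synthetic frame t= %g", fr$time), con)
    writeLines(sprintf("%5d", n), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       (seq_len(n) - 1L) %% 99999L + 1L,
                       resname[fr$role], substr(fr$name, 1, 5),
                       (seq_len(n) - 1L) %% 99999L + 1L,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]),
               con)
  }
  invisible(path)
}

read_pdb <- function(path, rules, box = NULL) {
  lines <- readLines(path)
  cryst <- grep("^CRYST1", lines, value = TRUE)
  if (length(cryst)) {
    box_nm <- as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                           substr(cryst[1], 25, 33))) / 10
  } else if (!is.null(box)) {
    box_nm <- box
  } else {
    rlang::abort("PDB: no CRYST1 record; supply `box` (nm) explicitly.")
  }
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  split_idx <- if (length(model_starts) > 1L) {
    findInterval(which(is_atom), model_starts)
  } else {
    rep(1L, sum(is_atom))
  }
  atoms <- lines[is_atom]
  frames <- lapply(split(seq_along(atoms), split_idx), function(ii) {
    at <- atoms[ii]
    nm <- trimws(substr(at, 13, 16))
    x <- suppressWarnings(as.numeric(substr(at, 31, 38))) / 10
    y <- suppressWarnings(as.numeric(substr(at, 39, 46))) / 10
    z <- suppressWarnings(as.numeric(substr(at, 47, 54))) / 10
    if (anyNA(c(x, y, z))) {
      rlang::abort(sprintf("PDB: unparseable ATOM record (frame %s).",
                           names(ii)[1]))
    }
    labeled_frame(cbind(x, y, z), assign_roles(nm, rules), box_nm, name = nm)
  })
  unname(frames)
}

write_pdb <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  resname <- c(membrane_head = "LIP", protein_backbone = "PRO", other = "OTH")
  b <- frames[[1]]$box * 10
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     b[1], b[2], b[3], 90, 90, 90), con)
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    n <- nrow(fr$coords)
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf("ATOM  %5d %-4s%3s  %4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                       (seq_len(n) - 1L) %% 99999L + 1L,
                       substr(fr$name, 1, 4), resname[fr$role],
                       (seq_len(n) - 1L) %% 9999L + 1L,
                       fr$coords[, 1] * 10, fr$coords[, 2] * 10,
                       fr$coords[, 3] * 10, 1, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

read_xyz <- function(path, rules = NULL) {
  lines <- readLines(path)
  boxline <- grep("^#\\s*box:", lines, value = TRUE)
  if (!length(boxline)) rlang::abort("XYZ: missing '# box: bx by bz' header.")
  box <- as.numeric(strsplit(sub("^#\\s*box:\\s*", "", boxline[1]),
                             "\\s+")[[1]])
  tab <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("frame", "time", "name", "x", "y", "z", "role")
  if (!all(need %in% names(tab))) {
    rlang::abort(paste0("XYZ: need tab-separated columns ",
                        paste(need, collapse = ", "), "."))
  }
  lapply(split(tab, tab$frame), function(d) {
    labeled_frame(cbind(d$x, d$y, d$z), d$role, box, time = d$time[1],
                  name = d$name)
  })
}

write_xyz <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# box: %.6f %.6f %.6f", frames[[1]]$box[1],
                     frames[[1]]$box[2], frames[[1]]$box[3]), con)
  writeLines("# coordinates in nm", con)
  writeLines(paste(c("frame", "time", "name", "x", "y", "z", "role"),
                   collapse = "\t"), con)
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    writeLines(sprintf("%d\t%g\t%s\t%.6f\t%.6f\t%.6f\t%s",
                       k, fr$time, fr$name, fr$coords[, 1], fr$coords[, 2],
                       fr$coords[, 3], fr$role), con)
  }
  invisible(path)
}

guess_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gro")) return("gro")
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext %in% c("xyz", "tsv", "txt")) return("xyz")
  rlang::abort(sprintf("Cannot guess coordinate dialect from '%s'.", path))
}

#' Read coordinate frames with bead roles
#'
#' Reads one or more coordinate snapshots from GRO (single- or multi-frame,
#' nm), PDB (`CRYST1` + `ATOM`/`HETATM`, converted from Angstrom to nm) or a
#' tab-separated XYZ table with an explicit `role` column. Roles are assigned
#' from bead/atom names by the regular-expression rules (for XYZ, the file's
#' own role column wins).
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension), `"gro"`, `"pdb"` or `"xyz"`.
#' @param role_rules Named character vector of regex rules, see
#'   [default_role_rules()].
#' @param box Length-3 box (nm) for PDB files lacking a CRYST1 record.
#' @return A list of [labeled_frame()] objects.
#' @export
read_frames <- function(path, dialect = "auto",
                        role_rules = default_role_rules(), box = NULL) {
  if (!file.exists(path)) rlang::abort(sprintf("No such file: %s", path))
  dialect <- match.arg(dialect, c("auto", "gro", "pdb", "xyz"))
  if (dialect == "auto") dialect <- guess_dialect(path)
  frames <- switch(dialect,
                   gro = read_gro(path, role_rules),
                   pdb = read_pdb(path, role_rules, box),
                   xyz = read_xyz(path))
  if (!length(frames)) rlang::abort(sprintf("No frames found in %s.", path))
  frames
}

#' Write coordinate frames
#'
#' Inverse of [read_frames()], in any of the three dialects. GRO keeps 3
#' decimals (0.001 nm), PDB 3 decimals in Angstrom (0.0001 nm), the XYZ table
#' 6 decimals.
#'
#' @param frames A [labeled_frame()] or list of them.
#' @param path Output file path.
#' @param dialect `"auto"` (by extension), `"gro"`, `"pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path, dialect = "auto") {
  if (inherits(frames, "labeled_frame")) frames <- list(frames)
  dialect <- match.arg(dialect, c("auto", "gro", "pdb", "xyz"))
  if (dialect == "auto") dialect <- guess_dialect(path)
  switch(dialect,
         gro = write_gro(frames, path),
         pdb = write_pdb(frames, path),
         xyz = write_xyz(frames, path))
  invisible(path)
}
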