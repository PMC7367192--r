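# File formats: CG structures as PDB + CSV sidecar, multi-model trajectory
# PDB, events CSV, OpenDX density grids, FASTA sequences.
# Coordinates are nm internally and Angstrom on disk (PDB convention).

pdb_elety <- function(beads) {
  ifelse(beads$group == "phosphate", "P",
         ifelse(beads$group == "bp", "C1", "CA"))
}

pdb_resid <- function(beads) {
  ifelse(beads$group %in% c("bp", "phosphate"),
         paste0("D", substr(beads$label, 1, 1)),
         substr(beads$label, 1, 3))
}

#' Write a CG structure as PDB (+ bead sidecar table)
#'
#' One pseudo-atom per bead ("CA" for residues, "C1" for base-pair cores,
#' "P" for phosphates).  Charges, radii and group tags do not fit in PDB
#' columns and go to a CSV sidecar (`<file>.beads.csv`).
#'
#' @param x a `cg_structure`.
#' @param file output PDB path.
#' @param sidecar write the CSV sidecar?
#' @return invisibly, the sidecar path (or `NULL`).
#' @export
write_cg_pdb <- function(x, file, sidecar = TRUE) {
  stopifnot(inherits(x, "cg_structure"))
  b <- x$beads
  xyz <- as.vector(t(as.matrix(b[, c("x", "y", "z")]) * 10))  # nm -> A
  chain <- ifelse(b$group %in% c("bp", "phosphate"), "B", "A")
  bio3d::write.pdb(file = file, xyz = xyz, resno = b$resno,
                   resid = pdb_resid(b), elety = pdb_elety(b),
                   chain = chain, eleno = b$index)
  side <- NULL
  if (sidecar) {
    side <- paste0(file, ".beads.csv")
    write.csv(data.frame(index = b$index, label = b$label, resno = b$resno,
                         radius = b$radius, charge = b$charge,
                         group = b$group, molecule = x$molecule),
              side, row.names = FALSE)
  }
  invisible(side)
}

#' Read a CG structure from PDB (+ sidecar)
#'
#' Inverse of [write_cg_pdb()]: bead positions from the ATOM records
#' (Angstrom -> nm), charges/radii/groups from the sidecar.  Rigid-body
#' frames and springs are not stored in PDB and are absent from the result
#' (geometric structure only).
#'
#' @param file PDB path.
#' @param sidecar sidecar CSV path (default `<file>.beads.csv`).
#' @return a `cg_structure`.
#' @export
read_cg_pdb <- function(file, sidecar = paste0(file, ".beads.csv")) {
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  beads <- data.frame(index = seq_len(nrow(at)), label = at$resid,
                      resno = at$resno,
                      x = at$x / 10, y = at$y / 10, z = at$z / 10,
                      radius = 0.3, charge = 0, group = "bead",
                      stringsAsFactors = FALSE)
  molecule <- "generic"
  if (file.exists(sidecar)) {
    sc <- read.csv(sidecar, stringsAsFactors = FALSE)
    beads$label <- sc$label
    beads$radius <- as.numeric(sc$radius)
    beads$charge <- as.numeric(sc$charge)
    beads$group <- sc$group
    molecule <- sc$molecule[1]
  }
  cg_structure(beads, molecule = molecule)
}

#' Export a trajectory as multi-model PDB
#'
#' One MODEL per frame; metadata (time step, seed, units, package version)
#' in REMARK records.  A bead sidecar is written alongside.
#'
#' @param traj a `cg_trajectory`.
#' @param file output path.
#' @param stride write every `stride`-th frame.
#' @return invisibly, `file`.
#' @export
write_traj_pdb <- function(traj, file, stride = 1) {
  stopifnot(inherits(traj, "cg_trajectory"))
  b <- traj$beads
  elety <- pdb_elety(b); resid <- pdb_resid(b)
  chain <- ifelse(b$molecule == "dna", "B", "A")
  con <- file(file, "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("REMARK   cgbind %s trajectory", as.character(utils::packageVersion("cgbind"))),
    sprintf("REMARK   units: nm->Angstrom, time ns; dt %g ns; seed %s",
            traj$config$dt, traj$config$seed),
    sprintf("REMARK   %d beads, %d frames", nrow(b), length(traj$times))),
    con)
  frames <- seq(1, length(traj$times), by = stride)
  for (k in seq_along(frames)) {
    f <- frames[k]
    writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- matrix(traj$xyz[f, , ], ncol = 3) * 10
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      b$index %% 100000, substr(elety, 1, 4), substr(resid, 1, 3),
      chain, b$resno %% 10000, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  write.csv(data.frame(index = b$index, label = b$label, resno = b$resno,
                       radius = b$radius, charge = b$charge, group = b$group,
                       molecule = b$molecule),
            paste0(file, ".beads.csv"), row.names = FALSE)
  invisible(file)
}

#' Export docked poses as multi-model PDB
#'
#' The transformed protein (chain A) and the fixed DNA (chain B) per model,
#' plus a CSV of energies and cluster assignments.
#'
#' @param poses a `dock_poses` object.
#' @param file output PDB path.
#' @param n number of poses to write (default: all).
#' @return invisibly, `file`.
#' @export
write_poses_pdb <- function(poses, file, n = nrow(poses$data)) {
  pb <- poses$protein$beads; db <- poses$dna$beads
  dxyz <- as.matrix(db[, c("x", "y", "z")])
  con <- file(file, "wt")
  on.exit(close(con))
  writeLines(sprintf("REMARK   cgbind docked poses, I = %g M",
                     poses$ionic_strength), con)
  atom_line <- function(i, ele, res, ch, rn, v)
    sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            i %% 100000, ele, substr(res, 1, 3), ch, rn %% 10000,
            v[1] * 10, v[2] * 10, v[3] * 10, 1, 0)
  for (m in seq_len(min(n, nrow(poses$data)))) {
    writeLines(sprintf("MODEL     %4d", m), con)
    pxyz <- pose_coords(poses, m)
    for (i in seq_len(nrow(pb)))
      writeLines(atom_line(i, "CA", substr(pb$label[i], 1, 3), "A",
                           pb$resno[i], pxyz[i, ]), con)
    for (j in seq_len(nrow(db)))
      writeLines(atom_line(nrow(pb) + j,
                           if (db$group[j] == "phosphate") "P" else "C1",
                           paste0("D", substr(db$label[j], 1, 1)), "B",
                           db$resno[j], dxyz[j, ]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  write.csv(cbind(model = seq_len(nrow(poses$data)), poses$data),
            paste0(file, ".energies.csv"), row.names = FALSE)
  invisible(file)
}

#' Write / read association events as CSV
#'
#' Columns: replica, time_ns, censored; the concentration, cutoff and run
#' length travel in comment header lines.
#'
#' @param events an [association_events()] object.
#' @param file CSV path.
#' @return `write_events_csv`: invisibly `file`; `read_events_csv`: an
#'   `association_events` object.
#' @export
write_events_csv <- function(events, file) {
  con <- file(file, "wt")
  on.exit(close(con))
  writeLines(sprintf("# conc_M=%g cutoff_nm=%g run_length_ns=%g",
                     events$conc, events$cutoff, events$run_length), con)
  write.csv(as.data.frame(events), con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(file) {
  hdr <- readLines(file, n = 1)
  meta <- as.numeric(sub(".*=", "", strsplit(sub("^# ", "", hdr), " ")[[1]]))
  df <- read.csv(file, comment.char = "#")
  association_events(df$time_ns, as.logical(df$censored), conc = meta[1],
                     cutoff = meta[2], run_length = meta[3])
}

#' Write a density grid in OpenDX format
#'
#' @param grid a `density_grid` from [occupancy_density()].
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_dx <- function(grid, file) {
  stopifnot(inherits(grid, "density_grid"))
  d <- grid$dim
  con <- file(file, "wt")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX density (sigma units), written by cgbind",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %g 0 0", grid$voxel),
    sprintf("delta 0 %g 0", grid$voxel),
    sprintf("delta 0 0 %g", grid$voxel),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # DX order: z fastest
  v <- aperm(grid$values, c(3, 2, 1))
  vals <- as.numeric(v)
  pad <- (3 - length(vals) %% 3) %% 3
  vals <- c(vals, rep(NA, pad))
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r)
    paste(formatC(r[!is.na(r)], format = "g", digits = 6), collapse = " "))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(file)
}

#' Read a nucleotide sequence from FASTA or plain text
#'
#' @param file path to a FASTA file (first record used) or a plain text file
#'   containing the sequence.
#' @return upper-case sequence string.
#' @export
read_sequence <- function(file) {
  first <- readLines(file, n = 1)
  if (startsWith(first, ">")) {
    fa <- seqinr::read.fasta(file, as.string = TRUE, seqonly = TRUE)
    toupper(gsub("\\s", "", fa[[1]]))
  } else {
    toupper(gsub("\\s", "", paste(readLines(file), collapse = "")))
  }
}
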