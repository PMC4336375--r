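# Trajectory input/output.
#
# The native exchange format is a plain-text snapshot dialect: one line per
# water per frame,
#
#   frame_index molecule_id Ox Oy Oz H1x H1y H1z H2x H2y H2z
#
# whitespace-separated, '#' comments, coordinates in Angstrom, frames
# sorted. PDB (single- or multi-model) and DCD trajectories are read
# through bio3d behind the same interface; solute nonbonded parameters are
# never parsed from force-field files but supplied as a simple per-atom
# table.

.WATER_RESIDUES <- c("HOH", "TIP", "TIP3", "TIP4", "WAT", "SPC", "SOL", "H2O")

#' Assemble a water trajectory from per-frame pose sets
#'
#' @param frames list of per-frame lists with fields \code{frame_index},
#'   \code{mol_id}, \code{position} (m x 3) and \code{quaternion} (m x 4).
#' @return An object of class \code{water_trajectory}.
#' @export
water_trajectory <- function(frames) {
  idx <- vapply(frames, function(f) f$frame_index, numeric(1))
  if (is.unsorted(idx, strictly = TRUE))
    stop("format error: frames must be sorted and unique")
  structure(list(frames = frames, n_frames = length(frames)),
            class = "water_trajectory")
}

#' @export
print.water_trajectory <- function(x, ...) {
  nw <- vapply(x$frames, function(f) nrow(f$position), integer(1))
  cat(sprintf("water_trajectory: %d frames, %d-%d waters per frame\n",
              x$n_frames, min(nw), max(nw)))
  invisible(x)
}

#' Write poses to the plain-text snapshot dialect
#'
#' Atomic coordinates are rebuilt from each pose under the rigid water
#' geometry. Accepts a \code{water_trajectory}, a \code{site_series} or
#' \code{pose_series} (one molecule), or a \code{pair_series} (two
#' molecules per frame, site order preserved).
#'
#' @param x the object to write.
#' @param path output file.
#' @param comment optional character vector written as '#' header lines
#'   (generator provenance, seeds, analytic references).
#' @param model water model supplying the rigid geometry.
#' @return \code{path}, invisibly.
#' @export
write_snapshots <- function(x, path, comment = NULL, model = tip4p2005()) {
  lines <- c("# hydrosite snapshot dialect",
             "# frame mol Ox Oy Oz H1x H1y H1z H2x H2y H2z",
             if (!is.null(comment)) paste("#", comment))
  fmt <- function(frame, mol, ps_pos, ps_quat) {
    at <- pose_to_atoms(ps_pos, ps_quat, model)
    sprintf("%d %s %.6f %.6f %.6f %.6f %.6f %.6f %.6f %.6f %.6f",
            frame, mol,
            at$oxygen[1], at$oxygen[2], at$oxygen[3],
            at$hydrogen1[1], at$hydrogen1[2], at$hydrogen1[3],
            at$hydrogen2[1], at$hydrogen2[2], at$hydrogen2[3])
  }
  if (inherits(x, "water_trajectory")) {
    for (f in x$frames)
      for (i in seq_len(nrow(f$position)))
        lines <- c(lines, fmt(f$frame_index, f$mol_id[i],
                              f$position[i, ], f$quaternion[i, ]))
  } else if (inherits(x, "pair_series")) {
    for (i in seq_len(n_poses(x))) {
      lines <- c(lines,
                 fmt(x$a$frame[i], "W1", x$a$position[i, ], x$a$quaternion[i, ]),
                 fmt(x$b$frame[i], "W2", x$b$position[i, ], x$b$quaternion[i, ]))
    }
  } else {
    ps <- if (inherits(x, "site_series")) x$poses else x
    for (i in seq_len(nrow(ps$position)))
      lines <- c(lines, fmt(ps$frame[i], "W1", ps$position[i, ],
                            ps$quaternion[i, ]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a snapshot-dialect file
#'
#' @param path input file.
#' @return a \code{water_trajectory}; poses are constructed from the atom
#'   records via [body_frame_quaternion()].
#' @export
read_snapshots <- function(path) {
  raw <- readLines(path)
  raw <- raw[!grepl("^\\s*(#|$)", raw)]
  if (!length(raw)) stop("format error: no snapshot records in ", path)
  tab <- utils::read.table(text = raw, stringsAsFactors = FALSE)
  if (ncol(tab) != 11)
    stop("format error: expected 11 whitespace-separated fields per record")
  names(tab) <- c("frame", "mol", "ox", "oy", "oz",
                  "h1x", "h1y", "h1z", "h2x", "h2y", "h2z")
  if (is.unsorted(tab$frame)) stop("format error: frames must be sorted")
  frames <- lapply(split(tab, tab$frame), function(d) {
    if (anyDuplicated(d$mol))
      stop("format error: duplicate molecule_id within a frame")
    O <- as.matrix(d[c("ox", "oy", "oz")])
    H1 <- as.matrix(d[c("h1x", "h1y", "h1z")])
    H2 <- as.matrix(d[c("h2x", "h2y", "h2z")])
    ps <- .poses_from_atoms(O, H1, H2, rep(d$frame[1], nrow(d)))
    list(frame_index = d$frame[1], mol_id = as.character(d$mol),
         position = ps$position, quaternion = ps$quaternion)
  })
  water_trajectory(unname(frames))
}

# split a bio3d pdb into water triplets and solute atoms for one coordinate
# frame (xyz: length-3N vector)
.pdb_frame <- function(pdb, xyz, frame_index) {
  atom <- pdb$atom
  coords <- matrix(xyz, ncol = 3, byrow = TRUE)
  is_w <- atom$resid %in% .WATER_RESIDUES
  wat <- atom[is_w, , drop = FALSE]
  wat_xyz <- coords[is_w, , drop = FALSE]
  key <- paste(wat$chain, wat$resno)
  O <- H <- list()
  mol_ids <- unique(key)
  Om <- H1m <- H2m <- NULL
  for (m in mol_ids) {
    rows <- which(key == m)
    el <- toupper(substr(wat$elety[rows], 1, 1))
    o <- rows[el == "O"]
    h <- rows[el == "H"]
    if (length(o) != 1 || length(h) < 2)
      stop("format error: water ", m, " lacks an oxygen or two hydrogens")
    Om <- rbind(Om, wat_xyz[o, ])
    H1m <- rbind(H1m, wat_xyz[h[1], ])
    H2m <- rbind(H2m, wat_xyz[h[2], ])
  }
  ps <- .poses_from_atoms(Om, H1m, H2m, rep(frame_index, length(mol_ids)))
  list(frame_index = frame_index, mol_id = mol_ids,
       position = ps$position, quaternion = ps$quaternion)
}

#' Load a trajectory from PDB/DCD files or the snapshot dialect
#'
#' Water residues (HOH/TIP/WAT/... names) become per-frame rigid poses;
#' all other atoms are returned as the fixed solute coordinate set.
#' Reading of the binary formats is delegated to bio3d. The solute
#' coordinate table carries no nonbonded parameters; join it with a
#' user-supplied parameter table ([read_solute_table()]) before energy
#' calculations.
#'
#' @param coords coordinate file: \code{.dcd} (requires \code{topology}),
#'   \code{.pdb} (single- or multi-model; serves as its own topology), or a
#'   snapshot-dialect text file.
#' @param topology PDB topology path, required for DCD input.
#' @return list with \code{trajectory} (a \code{water_trajectory}) and
#'   \code{solute} (data frame: name, resid, x, y, z; empty for the
#'   dialect, which carries waters only).
#' @export
load_trajectory <- function(coords, topology = NULL) {
  ext <- tolower(tools::file_ext(coords))
  if (ext == "dcd") {
    if (is.null(topology)) stop("DCD input requires a PDB topology")
    pdb <- bio3d::read.pdb(topology)
    xyz <- bio3d::read.dcd(coords, verbose = FALSE)
    if (ncol(xyz) != nrow(pdb$atom) * 3)
      stop("format error: atom count mismatch between topology and coordinates")
    frames <- lapply(seq_len(nrow(xyz)), function(i)
      .pdb_frame(pdb, xyz[i, ], i - 1L))
  } else if (ext == "pdb") {
    pdb <- bio3d::read.pdb(coords, multi = TRUE)
    nf <- if (length(dim(pdb$xyz)) == 2) nrow(pdb$xyz) else 1
    frames <- lapply(seq_len(nf), function(i)
      .pdb_frame(pdb, if (nf > 1) pdb$xyz[i, ] else as.numeric(pdb$xyz),
                 i - 1L))
  } else {
    return(list(trajectory = read_snapshots(coords),
                solute = data.frame(name = character(0), resid = character(0),
                                    x = numeric(0), y = numeric(0),
                                    z = numeric(0))))
  }
  atom <- pdb$atom
  sol <- atom[!(atom$resid %in% .WATER_RESIDUES), , drop = FALSE]
  solute <- data.frame(name = sol$elety, resid = sol$resid,
                       x = sol$x, y = sol$y, z = sol$z,
                       stringsAsFactors = FALSE)
  list(trajectory = water_trajectory(frames), solute = solute)
}

#' Read a per-atom solute parameter table
#'
#' A whitespace- or comma-separated table with columns
#' \code{name, x, y, z, charge, sigma, epsilon} (Angstrom, e, Angstrom,
#' kcal/mol). This is the only route by which solute nonbonded parameters
#' enter: force-field file parsing is out of scope.
#'
#' @param path file path.
#' @return a \code{nonbonded_sites} table.
#' @export
read_solute_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  if (!all(c("name", "x", "y", "z", "charge", "sigma", "epsilon") %in%
             names(tab)))
    stop("solute table needs columns: name x y z charge sigma epsilon")
  nonbonded_sites(tab$name, as.matrix(tab[c("x", "y", "z")]),
                  tab$charge, tab$sigma, tab$epsilon)
}

#' Read hydration-site definitions from a table
#'
#' Columns \code{site_id, x, y, z} and optionally \code{radius}.
#'
#' @param path file path.
#' @param radius default radius for rows without one, Angstrom.
#' @return list of \code{hydration_site} objects.
#' @export
read_sites <- function(path, radius = 1.2) {
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  if (!all(c("site_id", "x", "y", "z") %in% names(tab)))
    stop("site table needs columns: site_id x y z [radius]")
  if (is.null(tab$radius)) tab$radius <- radius
  lapply(seq_len(nrow(tab)), function(i)
    hydration_site(tab$site_id[i], c(tab$x[i], tab$y[i], tab$z[i]),
                   radius = tab$radius[i]))
}

#' Hydration sites from the water records of a PDB
#'
#' Uses the crystallographic water oxygen positions as site centers.
#'
#' @param path PDB file path.
#' @param radius site radius, Angstrom.
#' @return list of \code{hydration_site} objects labelled by residue
#'   number.
#' @export
sites_from_pdb <- function(path, radius = 1.2) {
  pdb <- bio3d::read.pdb(path)
  atom <- pdb$atom
  w <- atom[atom$resid %in% .WATER_RESIDUES &
              toupper(substr(atom$elety, 1, 1)) == "O", , drop = FALSE]
  if (!nrow(w)) stop("no water oxygen records in ", path)
  lapply(seq_len(nrow(w)), function(i)
    hydration_site(paste0("W", w$resno[i]), c(w$x[i], w$y[i], w$z[i]),
                   radius = radius,
                   source_label = paste(w$resid[i], w$resno[i])))
}

#' Read a run configuration file
#'
#' YAML with any of the fields: \code{traj}, \code{topology},
#' \code{sites}, \code{solute}, \code{out}, \code{n_blocks},
#' \code{block_size}, \code{seed}, \code{pair_gate}, \code{scheme},
#' \code{temperature}, \code{rho}, \code{E_bulk}, \code{S_bulk},
#' \code{n_permutations}. Referenced paths must exist at load time.
#'
#' @param path YAML file.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in intersect(c("traj", "topology", "sites", "solute"), names(cfg)))
    if (!file.exists(cfg[[f]]))
      stop("config path does not exist: ", cfg[[f]])
  cfg
}

#' Write a per-site report to CSV and JSON
#'
#' The CSV is rounded to 4 decimals for human consumption; the JSON keeps
#' full precision together with the bulk constants used, so a rerun with
#' the same seed is byte-identical.
#'
#' @param report output of [ifst_site_report()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_site_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  per <- report$per_site
  num <- vapply(per, is.numeric, logical(1))
  per_csv <- per
  per_csv[num] <- round(per_csv[num], 4)
  utils::write.csv(per_csv, file.path(dir, "per_site.csv"),
                   row.names = FALSE)
  utils::write.csv(report$pairs, file.path(dir, "pairs.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(per_site = per, pairs = report$pairs,
         constants = report$bulk[c("rho", "E_bulk", "S_bulk", "temperature",
                                   "dG_insertion")]),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
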