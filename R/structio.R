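# Structure I/O: protein-ligand complexes, binding sites, pose RMSD and
# cross-docking receptor selection.  File parsing is delegated to bio3d;
# this layer owns the complex/site containers and their conventions.

#' Construct a protein-ligand complex structure
#'
#' A `complex_structure` holds one protein-ligand complex as a flat atom
#' table plus an optional bond table.  It is the carrier for all geometric
#' operations in the package: binding-site extraction, interaction
#' detection and fingerprint generation.
#'
#' @param atoms data frame with columns `atom_id` (integer, unique),
#'   `name`, `element`, `x`, `y`, `z` (Angstrom), `charge` (formal charge;
#'   fractional input is rounded when formal charges are needed),
#'   `is_aromatic` (logical), `resname`, `resid` (integer), `chain`, and
#'   `role` (one of `"protein"`, `"ligand"`, `"metal"`, `"water"`).
#' @param bonds optional data frame with columns `a`, `b` (atom ids) and
#'   `type` (mol2 bond type string; `"ar"` marks aromatic bonds).
#' @param structure_id identifier, e.g. a PDB code.
#' @param target_id identifier of the target protein.
#' @return An object of class `complex_structure`.
#' @export
complex_structure <- function(atoms, bonds = NULL, structure_id = "",
                              target_id = "") {
  required <- c("atom_id", "name", "element", "x", "y", "z", "charge",
                "is_aromatic", "resname", "resid", "chain", "role")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty structure: no atoms")
  if (anyDuplicated(atoms$atom_id))
    stop("atom_id must be unique within a structure")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("non-finite atom coordinates")
  bad_role <- setdiff(unique(atoms$role),
                      c("protein", "ligand", "metal", "water"))
  if (length(bad_role))
    stop("unknown atom role: ", paste(bad_role, collapse = ", "))
  if (!is.null(bonds)) {
    if (!all(c("a", "b") %in% names(bonds)))
      stop("bonds must have columns a, b")
    if (is.null(bonds$type)) bonds$type <- "1"
    if (!all(c(bonds$a, bonds$b) %in% atoms$atom_id))
      stop("bond references unknown atom_id")
  }
  structure(list(structure_id = structure_id, target_id = target_id,
                 atoms = atoms, bonds = bonds),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  tab <- table(x$atoms$role)
  cat("complex_structure", if (nzchar(x$structure_id)) x$structure_id else "",
      "\n  atoms:", nrow(x$atoms),
      sprintf("(%s)", paste(names(tab), tab, sep = "=", collapse = ", ")),
      "\n  bonds:", if (is.null(x$bonds)) 0L else nrow(x$bonds), "\n")
  invisible(x)
}

# mol2 SYBYL atom type -> element symbol ("C.ar" -> "C")
.elem_from_sybyl <- function(elety) sub("\\..*$", "", elety)

# split a mol2 substructure name like "ALA17" into name + number
.split_subst <- function(s) {
  num <- suppressWarnings(as.integer(sub("^.*?([0-9]+)$", "\\1", s)))
  num[!grepl("[0-9]$", s)] <- NA_integer_
  name <- sub("[0-9]+$", "", s)
  list(resname = name, resid = ifelse(is.na(num), 1L, num))
}

.METAL_ELEMENTS <- c("Zn", "Mg", "Mn", "Fe", "Ca", "Ni", "Cu", "Co",
                     "Cd", "Na", "K")
.WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")
.ION_RESNAMES   <- c("NA", "CL", "K", "BR", "IOD", "CS", "F")

# one bio3d mol2 block -> atoms/bonds in our convention
.mol2_block_to_atoms <- function(m, role, id_offset) {
  at <- m$atom
  subst <- .split_subst(as.character(at$resid))
  elem <- .elem_from_sybyl(as.character(at$elety))
  aromatic <- grepl("\\.ar$", as.character(at$elety))
  if (!is.null(m$bond) && nrow(m$bond) > 0) {
    ar_bonds <- m$bond[as.character(m$bond$type) == "ar", , drop = FALSE]
    aromatic[at$eleno %in% c(ar_bonds$origin, ar_bonds$target)] <- TRUE
  }
  role_i <- rep(role, nrow(at))
  role_i[elem %in% .METAL_ELEMENTS] <- "metal"
  atoms <- data.frame(
    atom_id = at$eleno + id_offset, name = as.character(at$elena),
    element = elem, x = at$x, y = at$y, z = at$z,
    charge = ifelse(is.na(at$charge), 0, at$charge),
    is_aromatic = aromatic, resname = subst$resname, resid = subst$resid,
    chain = "A", role = role_i, stringsAsFactors = FALSE)
  bonds <- NULL
  if (!is.null(m$bond) && nrow(m$bond) > 0)
    bonds <- data.frame(a = m$bond$origin + id_offset,
                        b = m$bond$target + id_offset,
                        type = as.character(m$bond$type),
                        stringsAsFactors = FALSE)
  list(atoms = atoms, bonds = bonds)
}

#' Read a protein-ligand complex from mol2 or PDB
#'
#' For mol2, a multi-molecule file is expected: the block whose molecule
#' name matches `ligand_block` (default: a block literally named
#' `"ligand"`, else the block with the fewest atoms) is taken as the
#' ligand and every other block as protein.  For PDB, `ATOM` records are
#' protein; `HETATM` records are the ligand after waters are dropped,
#' monoatomic ions on `ion_resnames` are dropped, and metals are kept with
#' role `"metal"` so metal complexation remains detectable.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"mol2"` or `"pdb"`.
#' @param ligand_block mol2 molecule name of the ligand block.
#' @param ligand_resname for PDB: restrict the ligand to these HETATM
#'   residue names (default: all non-water, non-ion HETATM records).
#' @param ion_resnames PDB residue names treated as free ions and dropped
#'   (bound metals, identified by element, are kept as role `"metal"`).
#' @return A [complex_structure()].
#' @export
read_complex <- function(path, format = c("auto", "mol2", "pdb"),
                         ligand_block = NULL, ligand_resname = NULL,
                         ion_resnames = .ION_RESNAMES) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdb", "ent")) "pdb" else "mol2"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mol2") .read_complex_mol2(path, ligand_block)
  else .read_complex_pdb(path, ligand_resname, ion_resnames)
}

# normalize TRIPOS blocks so the bio3d parser accepts bond-less molecules:
# an empty @<TRIPOS>BOND header is dropped and every block without a bond
# section is terminated by a @<TRIPOS>SUBSTRUCTURE marker
.preprocess_mol2 <- function(txt) {
  starts <- grep("^@<TRIPOS>MOLECULE", txt)
  ends <- c(starts[-1] - 1L, length(txt))
  out <- character(0)
  for (k in seq_along(starts)) {
    block <- txt[starts[k]:ends[k]]
    hdr <- grep("^@<TRIPOS>", block)
    bond_at <- grep("^@<TRIPOS>BOND", block)
    if (length(bond_at)) {
      nxt <- c(hdr[hdr > bond_at[1]], length(block) + 1L)[1]
      body <- block[seq(bond_at[1] + 1L, length.out = nxt - bond_at[1] - 1L)]
      if (!any(nzchar(trimws(body))))
        block <- block[-seq(bond_at[1], nxt - 1L)]
    }
    if (!any(grepl("^@<TRIPOS>BOND", block)) &&
        !any(grepl("^@<TRIPOS>SUBSTRUCTURE", block)))
      block <- c(block, "@<TRIPOS>SUBSTRUCTURE")
    out <- c(out, block)
  }
  out
}

.read_complex_mol2 <- function(path, ligand_block) {
  txt <- readLines(path, warn = FALSE)
  if (!any(grepl("@<TRIPOS>ATOM", txt, fixed = TRUE)))
    stop("mol2 format error: no @<TRIPOS>ATOM section in ", path)
  starts <- grep("^@<TRIPOS>MOLECULE", txt)
  if (length(starts) == 0L)
    stop("mol2 format error: no @<TRIPOS>MOLECULE section in ", path)
  ends <- c(starts[-1] - 1L, length(txt))
  # blocks are parsed one at a time: a shared parse would require every
  # molecule to carry a bond section
  blocks <- lapply(seq_along(starts), function(k) {
    tmp <- tempfile(fileext = ".mol2")
    on.exit(unlink(tmp))
    writeLines(.preprocess_mol2(txt[starts[k]:ends[k]]), tmp)
    suppressWarnings(bio3d::read.mol2(tmp))
  })
  if (length(blocks) == 0L) stop("empty structure: ", path)
  nm <- vapply(blocks, function(b) as.character(b$name)[1], "")
  n_at <- vapply(blocks, function(b) nrow(b$atom), 0L)
  if (length(blocks) == 1L) {
    lig_idx <- 1L  # single block: all ligand (a bare docked pose)
  } else if (!is.null(ligand_block)) {
    lig_idx <- which(tolower(nm) == tolower(ligand_block))
    if (length(lig_idx) != 1L)
      stop("ligand_block '", ligand_block, "' not found (blocks: ",
           paste(nm, collapse = ", "), ")")
  } else if (any(tolower(nm) == "ligand")) {
    lig_idx <- which(tolower(nm) == "ligand")[1]
  } else {
    lig_idx <- which.min(n_at)
  }
  atoms <- NULL; bonds <- NULL; offset <- 0L
  for (i in seq_along(blocks)) {
    role <- if (i == lig_idx) "ligand" else "protein"
    part <- .mol2_block_to_atoms(blocks[[i]], role, offset)
    atoms <- rbind(atoms, part$atoms)
    bonds <- rbind(bonds, part$bonds)
    offset <- offset + max(blocks[[i]]$atom$eleno)
  }
  complex_structure(atoms, bonds,
                    structure_id = tools::file_path_sans_ext(basename(path)))
}

.read_complex_pdb <- function(path, ligand_resname, ion_resnames) {
  p <- bio3d::read.pdb(path)
  at <- p$atom
  if (nrow(at) == 0L) stop("empty structure: ", path)
  elem <- as.character(at$elesy)
  blank <- is.na(elem) | elem == ""
  if (any(blank)) # fall back to first letter of the atom name
    elem[blank] <- sub("^[0-9]*([A-Za-z]).*$", "\\1", at$elety[blank])
  elem <- paste0(toupper(substr(elem, 1, 1)),
                 tolower(substr(elem, 2, 2)))
  role <- ifelse(at$type == "ATOM", "protein", "ligand")
  resname <- toupper(as.character(at$resid))
  drop <- role == "ligand" & resname %in% .WATER_RESNAMES
  is_ion <- role == "ligand" & resname %in% toupper(ion_resnames)
  is_metal <- role == "ligand" & elem %in% .METAL_ELEMENTS
  role[is_metal] <- "metal"
  drop <- drop | (is_ion & !is_metal)
  if (!is.null(ligand_resname))
    drop <- drop | (role == "ligand" & !(resname %in% toupper(ligand_resname)))
  keep <- !drop
  fc <- rep(0, nrow(at))
  if (!is.null(at$charge)) {
    fc_in <- suppressWarnings(as.numeric(at$charge))
    fc[!is.na(fc_in)] <- fc_in[!is.na(fc_in)]
  }
  atoms <- data.frame(
    atom_id = at$eleno[keep], name = as.character(at$elety)[keep],
    element = elem[keep], x = at$x[keep], y = at$y[keep], z = at$z[keep],
    charge = fc[keep], is_aromatic = FALSE,
    resname = resname[keep], resid = at$resno[keep],
    chain = ifelse(is.na(at$chain[keep]), "A", as.character(at$chain)[keep]),
    role = role[keep], stringsAsFactors = FALSE)
  complex_structure(atoms, bonds = NULL,
                    structure_id = tools::file_path_sans_ext(basename(path)))
}

# format one role subset as a bio3d mol2 object
.as_bio3d_mol2 <- function(atoms, bonds, name) {
  id_map <- stats::setNames(seq_len(nrow(atoms)), atoms$atom_id)
  elety <- ifelse(atoms$is_aromatic & atoms$element %in% c("C", "N"),
                  paste0(atoms$element, ".ar"), atoms$element)
  bond_df <- data.frame(id = integer(0), origin = integer(0),
                        target = integer(0), type = character(0))
  if (!is.null(bonds) && nrow(bonds) > 0) {
    keep <- bonds$a %in% atoms$atom_id & bonds$b %in% atoms$atom_id
    bonds <- bonds[keep, , drop = FALSE]
    if (nrow(bonds) > 0)
      bond_df <- data.frame(id = seq_len(nrow(bonds)),
                            origin = unname(id_map[as.character(bonds$a)]),
                            target = unname(id_map[as.character(bonds$b)]),
                            type = bonds$type)
  }
  obj <- list(
    atom = data.frame(
      eleno = seq_len(nrow(atoms)), elena = atoms$name,
      x = atoms$x, y = atoms$y, z = atoms$z, elety = elety,
      resno = atoms$resid, resid = paste0(atoms$resname, atoms$resid),
      charge = atoms$charge, stringsAsFactors = FALSE),
    bond = bond_df,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    info = c(nrow(atoms), nrow(bond_df), 1),
    name = name)
  class(obj) <- "mol2"
  obj
}

#' Write a complex (or site) to a multi-molecule mol2 file
#'
#' The protein (plus any metals) and the ligand are written as two TRIPOS
#' MOLECULE blocks named `"protein"` and `"ligand"`, the convention
#' [read_complex()] expects.
#'
#' @param x a [complex_structure()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_complex <- function(x, path) {
  stopifnot(inherits(x, "complex_structure"))
  prot <- x$atoms[x$atoms$role %in% c("protein", "metal"), , drop = FALSE]
  lig <- x$atoms[x$atoms$role == "ligand", , drop = FALSE]
  tmp <- character(0)
  for (part in list(list(prot, "protein"), list(lig, "ligand"))) {
    if (nrow(part[[1]]) == 0) next
    f <- tempfile(fileext = ".mol2")
    bio3d::write.mol2(.as_bio3d_mol2(part[[1]], x$bonds, part[[2]]), file = f)
    tmp <- c(tmp, f)
  }
  writeLines(unlist(lapply(tmp, readLines, warn = FALSE)), path)
  unlink(tmp)
  invisible(path)
}

#' Extract the binding site of a complex
#'
#' A protein residue belongs to the binding site iff the minimum distance
#' between any of its atoms and any ligand atom is at most `cutoff`
#' (default 6 Angstrom); included residues are kept whole.  Metal atoms
#' within `cutoff` of the ligand are retained as part of the site.
#'
#' @param complex a [complex_structure()] with protein and ligand atoms.
#' @param cutoff inclusion distance in Angstrom.
#' @return An object of class `binding_site`: list with `residue_keys`
#'   (data frame `chain`, `resid`), `atoms` (site atom table), `bonds`
#'   (bonds among site atoms) and `cutoff`.
#' @export
extract_binding_site <- function(complex, cutoff = 6.0) {
  stopifnot(inherits(complex, "complex_structure"))
  if (cutoff < 0) stop("cutoff must be non-negative")
  at <- complex$atoms
  lig <- at[at$role == "ligand", , drop = FALSE]
  prot <- at[at$role == "protein", , drop = FALSE]
  met <- at[at$role == "metal", , drop = FALSE]
  if (nrow(lig) == 0L) stop("no ligand atoms in complex")
  if (nrow(prot) == 0L) stop("no protein atoms in complex")
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  mind <- function(df) {
    if (nrow(df) == 0) return(numeric(0))
    pxyz <- as.matrix(df[, c("x", "y", "z")])
    d2 <- outer(rowSums(pxyz^2), rep(1, nrow(lxyz))) +
      outer(rep(1, nrow(pxyz)), rowSums(lxyz^2)) - 2 * pxyz %*% t(lxyz)
    sqrt(pmax(apply(d2, 1, min), 0))
  }
  dmin <- mind(prot)
  key <- paste(prot$chain, prot$resid, sep = "|")
  res_min <- tapply(dmin, key, min)
  keep_keys <- names(res_min)[res_min <= cutoff]
  site_atoms <- prot[key %in% keep_keys, , drop = FALSE]
  if (nrow(met) > 0) {
    met_keep <- met[mind(met) <= cutoff, , drop = FALSE]
    site_atoms <- rbind(site_atoms, met_keep)
  }
  rk <- unique(site_atoms[site_atoms$role == "protein", c("chain", "resid")])
  bonds <- complex$bonds
  if (!is.null(bonds))
    bonds <- bonds[bonds$a %in% site_atoms$atom_id &
                   bonds$b %in% site_atoms$atom_id, , drop = FALSE]
  structure(list(residue_keys = rk[order(rk$chain, rk$resid), , drop = FALSE],
                 atoms = site_atoms, bonds = bonds, cutoff = cutoff),
            class = "binding_site")
}

#' @export
print.binding_site <- function(x, ...) {
  cat("binding_site:", nrow(x$residue_keys), "residues,",
      nrow(x$atoms), "atoms within", x$cutoff, "A of the ligand\n")
  invisible(x)
}

#' Write binding-site atoms as mol2
#'
#' @param site a `binding_site`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_binding_site <- function(site, path) {
  stopifnot(inherits(site, "binding_site"))
  bio3d::write.mol2(.as_bio3d_mol2(site$atoms, site$bonds, "site"),
                    file = path)
  invisible(path)
}

#' Root-mean-square deviation between two poses
#'
#' Plain coordinate RMSD under the stored atom-order correspondence: no
#' re-superposition and no graph-symmetry correction, matching the docked
#' vs. native comparison of poses that share a receptor frame.
#'
#' @param coords_a,coords_b numeric n x 3 matrices (rows correspond).
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) == 0L) stop("empty coordinate set")
  if (!all(dim(coords_a) == dim(coords_b)))
    stop("coordinate sets differ in size")
  sqrt(mean(rowSums((coords_a - coords_b)^2)))
}

#' Select a receptor structure by smallest mean cross-docking RMSD
#'
#' Given the cross-docking RMSD table of one target (every extracted
#' ligand docked back into every candidate crystal structure), returns the
#' candidate with the smallest mean RMSD over its ligands.  Missing
#' entries (failed dockings) are skipped by default or replaced by a
#' penalty value; exact ties go to the lexicographically smallest id.
#'
#' @param table data frame with columns `structure_id`, `ligand_id`,
#'   `rmsd` (NA = failed docking).
#' @param na_action `"skip"` to average over present entries only, or
#'   `"penalize"` to substitute `penalty` for missing ones.
#' @param penalty RMSD substituted for failures when penalizing.
#' @return The selected `structure_id` (character scalar) with the mean
#'   RMSDs of all candidates attached as attribute `"means"`.
#' @export
select_receptor <- function(table, na_action = c("skip", "penalize"),
                            penalty = 10) {
  na_action <- match.arg(na_action)
  if (is.null(table) || nrow(table) == 0L) stop("empty RMSD table")
  stopifnot(all(c("structure_id", "ligand_id", "rmsd") %in% names(table)))
  if (any(table$rmsd < 0, na.rm = TRUE)) stop("negative RMSD in table")
  rmsd <- table$rmsd
  if (na_action == "penalize") rmsd[is.na(rmsd)] <- penalty
  ok <- !is.na(rmsd)
  means <- tapply(rmsd[ok], table$structure_id[ok], mean)
  if (any(!table$structure_id %in% names(means)))
    stop("candidate with no successful docking: ",
         paste(setdiff(unique(table$structure_id), names(means)),
               collapse = ", "))
  means <- means[order(names(means))]  # lexicographic tie-break
  best <- names(means)[which.min(means)]
  attr(best, "means") <- means
  best
}
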