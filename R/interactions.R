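# Geometric detection of protein-ligand interactions and their abstraction
# into typed pseudoatoms.  Five interaction classes are recognized:
# hydrophobic contacts, aromatic (ring stacking), hydrogen bonds (split by
# direction), ionic interactions (split by ligand charge sign) and metal
# complexation.

#' Interaction detection thresholds
#'
#' Geometric criteria used by [detect_interactions()].  Defaults follow
#' standard structural-biology practice and are fully configurable:
#' hydrophobic apolar-carbon/sulfur contact at <= 4.5 A; hydrogen bond
#' with heavy-atom donor-acceptor distance <= 3.5 A and D-H...A angle
#' >= 120 degrees (angle test applied only when the donor carries explicit
#' hydrogens); ring stacking with centroid distance <= 5 A and interplane
#' angle <= 30 degrees (face-to-face) or >= 60 degrees (edge-to-face);
#' opposite formal charges at <= 4 A; metal-heteroatom contact <= 2.8 A.
#'
#' @param hyd_max_dist,hb_max_dist,aro_centroid_max_dist,ion_max_dist,metal_max_dist
#'   distance thresholds in Angstrom.
#' @param hb_min_angle minimum D-H...A angle in degrees.
#' @param aro_face_angle_max,aro_edge_angle_min interplane angle limits in
#'   degrees (angles folded to `[0, 90]`).
#' @return An object of class `interaction_rules`.
#' @export
interaction_rules <- function(hyd_max_dist = 4.5,
                              hb_max_dist = 3.5, hb_min_angle = 120,
                              aro_centroid_max_dist = 5.0,
                              aro_face_angle_max = 30,
                              aro_edge_angle_min = 60,
                              ion_max_dist = 4.0, metal_max_dist = 2.8) {
  r <- list(hyd_max_dist = hyd_max_dist, hb_max_dist = hb_max_dist,
            hb_min_angle = hb_min_angle,
            aro_centroid_max_dist = aro_centroid_max_dist,
            aro_face_angle_max = aro_face_angle_max,
            aro_edge_angle_min = aro_edge_angle_min,
            ion_max_dist = ion_max_dist, metal_max_dist = metal_max_dist)
  dists <- c("hyd_max_dist", "hb_max_dist", "aro_centroid_max_dist",
             "ion_max_dist", "metal_max_dist")
  for (f in dists)
    if (!is.finite(r[[f]]) || r[[f]] <= 0)
      stop("rule '", f, "' must be a positive distance")
  for (f in c("hb_min_angle", "aro_face_angle_max", "aro_edge_angle_min"))
    if (!is.finite(r[[f]]) || r[[f]] < 0 || r[[f]] > 180)
      stop("rule '", f, "' must be an angle in [0, 180]")
  structure(r, class = "interaction_rules")
}

#' Read interaction rules from a JSON config file
#'
#' @param path JSON file whose top-level fields name [interaction_rules()]
#'   arguments (missing fields keep their defaults).
#' @return An `interaction_rules` object.
#' @export
read_interaction_rules <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  keep <- intersect(names(cfg), names(formals(interaction_rules)))
  do.call(interaction_rules, cfg[keep])
}

# ---- bond graph and atom typing ------------------------------------------

# distance-based bond guess for structures without bond records:
# heavy-heavy <= 1.9 A, X-H <= 1.2 A
.guess_bonds <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2) return(data.frame(a = integer(0), b = integer(0),
                               type = character(0)))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  is_h <- atoms$element == "H"
  lim <- matrix(1.9, n, n)
  lim[is_h, ] <- 1.2; lim[, is_h] <- 1.2
  hit <- which(d > 1e-6 & d <= lim & upper.tri(d), arr.ind = TRUE)
  data.frame(a = atoms$atom_id[hit[, 1]], b = atoms$atom_id[hit[, 2]],
             type = rep("1", nrow(hit)), stringsAsFactors = FALSE)
}

# per-atom typing flags for one side (site or ligand atom table + bonds)
.type_atoms <- function(atoms, bonds) {
  if (is.null(bonds) || nrow(bonds) == 0) bonds <- .guess_bonds(atoms)
  id <- atoms$atom_id
  nbr_elem <- function(aid) {
    nb <- c(bonds$b[bonds$a == aid], bonds$a[bonds$b == aid])
    atoms$element[match(nb, id)]
  }
  elems <- atoms$element
  fc <- round(atoms$charge)
  n_h <- integer(nrow(atoms))
  polarized <- logical(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    ne <- nbr_elem(id[i])
    n_h[i] <- sum(ne == "H", na.rm = TRUE)
    polarized[i] <- any(ne %in% c("N", "O", "F"), na.rm = TRUE)
  }
  has_any_h <- any(elems == "H")
  polar_no <- elems %in% c("N", "O")
  # exclusive donor/acceptor typing; charged atoms belong to the ionic
  # class only (see vignette for the rationale)
  if (has_any_h) {
    donor <- polar_no & n_h > 0 & fc == 0
    acceptor <- polar_no & n_h == 0 & fc == 0
  } else {  # heavy-atom fallback: direction is ambiguous without H
    donor <- polar_no & fc == 0
    acceptor <- polar_no & fc == 0
  }
  apolar <- (elems == "C" & !atoms$is_aromatic & !polarized & fc == 0) |
            (elems == "S" & fc == 0 & !polarized)
  data.frame(atom_id = id, donor = donor, acceptor = acceptor,
             apolar = apolar, fc = fc, n_h = n_h,
             is_metal = atoms$role == "metal",
             hetero = elems %in% c("N", "O", "S"),
             stringsAsFactors = FALSE)
}

# ---- rings ----------------------------------------------------------------

#' Centroid and best-fit plane normal of a ring
#'
#' @param ring_atoms numeric matrix (>= 3 rows) of 3D coordinates.
#' @return list with `centroid` (length-3) and `normal` (unit length;
#'   sign-canonicalized to a positive z component, falling back to y then
#'   x when the leading component is zero).
#' @export
ring_centroid_normal <- function(ring_atoms) {
  m <- as.matrix(ring_atoms)
  if (nrow(m) < 3) stop("ring needs at least 3 atoms")
  centroid <- colMeans(m)
  cm <- sweep(m, 2, centroid)
  sv <- svd(cm)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate (collinear) ring atoms")
  normal <- sv$v[, 3]
  normal <- normal / sqrt(sum(normal^2))
  for (k in 3:1) {
    if (abs(normal[k]) > 1e-12) {
      if (normal[k] < 0) normal <- -normal
      break
    }
  }
  list(centroid = as.numeric(centroid), normal = as.numeric(normal))
}

# connected components of the subgraph induced by aromatic-flagged atoms
.rings_from_flags <- function(atoms, bonds) {
  ar <- atoms$atom_id[atoms$is_aromatic]
  if (length(ar) < 3) return(list())
  if (is.null(bonds) || nrow(bonds) == 0) bonds <- .guess_bonds(atoms)
  sub <- bonds[bonds$a %in% ar & bonds$b %in% ar, , drop = FALSE]
  comp <- stats::setNames(seq_along(ar), ar)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(sub))) {
      ca <- comp[as.character(sub$a[k])]; cb <- comp[as.character(sub$b[k])]
      if (ca != cb) { comp[comp == max(ca, cb)] <- min(ca, cb); changed <- TRUE }
    }
    if (!changed) break
  }
  out <- split(as.integer(names(comp)), comp)
  out[vapply(out, length, 0L) >= 3]
}

# SSSR-style fallback: shortest cycle through each edge (sizes 3..max_size)
.rings_from_graph <- function(atoms, bonds, max_size = 6) {
  if (is.null(bonds) || nrow(bonds) == 0) bonds <- .guess_bonds(atoms)
  if (nrow(bonds) == 0) return(list())
  heavy <- atoms$atom_id[atoms$element != "H"]
  bonds <- bonds[bonds$a %in% heavy & bonds$b %in% heavy, , drop = FALSE]
  adj <- list()
  for (k in seq_len(nrow(bonds))) {
    a <- as.character(bonds$a[k]); b <- as.character(bonds$b[k])
    adj[[a]] <- c(adj[[a]], bonds$b[k]); adj[[b]] <- c(adj[[b]], bonds$a[k])
  }
  cycles <- list()
  for (k in seq_len(nrow(bonds))) {
    src <- bonds$a[k]; dst <- bonds$b[k]
    # BFS from src to dst avoiding the (src,dst) edge itself
    prev <- list(); dist <- list(); queue <- src
    dist[[as.character(src)]] <- 0L
    found <- FALSE
    while (length(queue) && !found) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[as.character(v)]]) {
        if (v == src && w == dst) next
        cw <- as.character(w)
        if (is.null(dist[[cw]])) {
          dist[[cw]] <- dist[[as.character(v)]] + 1L
          prev[[cw]] <- v
          if (w == dst) { found <- TRUE; break }
          if (dist[[cw]] < max_size - 1L) queue <- c(queue, w)
        }
      }
    }
    if (found) {
      path <- dst
      while (path[1] != src) path <- c(prev[[as.character(path[1])]], path)
      if (length(path) <= max_size) {
        key <- paste(sort(path), collapse = ",")
        cycles[[key]] <- path
      }
    }
  }
  unname(cycles)
}

# ring entities of one side -> list of (atom_ids, centroid, normal)
.ring_entities <- function(atoms, bonds, planar_tol = 0.2) {
  rings <- .rings_from_flags(atoms, bonds)
  if (length(rings) == 0) {
    cand <- .rings_from_graph(atoms, bonds)
    rings <- Filter(function(idx) {
      sub <- atoms[match(idx, atoms$atom_id), , drop = FALSE]
      if (length(idx) < 5 || length(idx) > 6) return(FALSE)
      if (!all(sub$element %in% c("C", "N", "O", "S"))) return(FALSE)
      m <- as.matrix(sub[, c("x", "y", "z")])
      cn <- tryCatch(ring_centroid_normal(m), error = function(e) NULL)
      if (is.null(cn)) return(FALSE)
      dev <- abs(sweep(m, 2, cn$centroid) %*% cn$normal)
      max(dev) <= planar_tol
    }, cand)
  }
  lapply(rings, function(idx) {
    m <- as.matrix(atoms[match(idx, atoms$atom_id), c("x", "y", "z")])
    cn <- ring_centroid_normal(m)
    list(atom_ids = idx, centroid = cn$centroid, normal = cn$normal)
  })
}

# charged-group centers: charged atoms, with same-sign atoms that are
# bonded or share a bonded neighbor collapsed to their centroid
.charge_centers <- function(atoms, bonds) {
  ch <- atoms[round(atoms$charge) != 0, , drop = FALSE]
  if (nrow(ch) == 0)
    return(list())
  if (is.null(bonds) || nrow(bonds) == 0) bonds <- .guess_bonds(atoms)
  nbrs <- function(aid) c(bonds$b[bonds$a == aid], bonds$a[bonds$b == aid])
  grp <- seq_len(nrow(ch))
  for (i in seq_len(nrow(ch))) for (j in seq_len(nrow(ch))) {
    if (i >= j || sign(ch$charge[i]) != sign(ch$charge[j])) next
    ni <- nbrs(ch$atom_id[i]); nj <- nbrs(ch$atom_id[j])
    linked <- ch$atom_id[j] %in% ni || length(intersect(ni, nj)) > 0
    if (linked) grp[grp == grp[j]] <- grp[i]
  }
  lapply(split(seq_len(nrow(ch)), grp), function(idx) {
    list(atom_ids = ch$atom_id[idx],
         center = colMeans(as.matrix(ch[idx, c("x", "y", "z")])),
         sign = sign(round(ch$charge[idx[1]])))
  })
}

# ---- detection ------------------------------------------------------------

.xyz <- function(df) as.matrix(df[, c("x", "y", "z")])

.rec <- function(itype, p_center, l_center, p_atoms, l_atoms,
                 dist, angle = NA_real_, acc = c(NA, NA, NA)) {
  data.frame(itype = itype,
             px = p_center[1], py = p_center[2], pz = p_center[3],
             lx = l_center[1], ly = l_center[2], lz = l_center[3],
             ax = acc[1], ay = acc[2], az = acc[3],
             dist = dist, angle = angle,
             protein_atoms = paste(sort(p_atoms), collapse = ","),
             ligand_atoms = paste(sort(l_atoms), collapse = ","),
             stringsAsFactors = FALSE)
}

# best D-H...A angle (degrees) over the donor's hydrogens; NA if none
.best_dha_angle <- function(d_pos, h_pos_list, a_pos) {
  if (length(h_pos_list) == 0) return(NA_real_)
  best <- -Inf
  for (h in h_pos_list) {
    v1 <- d_pos - h; v2 <- a_pos - h
    ca <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    ang <- acos(pmin(pmax(ca, -1), 1)) * 180 / pi
    if (ang > best) best <- ang
  }
  best
}

#' Detect protein-ligand interactions
#'
#' Recognizes, between a binding site and a ligand, every atom pair, ring
#' pair, charged-group pair and metal contact satisfying the geometric
#' criteria in `rules`.  One record is emitted per qualifying pair.
#' Hydrogen bonds are directional: `HBD` means the ligand donates, `HBA`
#' that it accepts.  Ionic records carry the ligand charge sign (`ION_P`
#' / `ION_N`).  Results are sorted deterministically and independent of
#' atom input order.
#'
#' @param site a `binding_site` (see [extract_binding_site()]), or a
#'   [complex_structure()] from which the site is taken at 6 A.
#' @param ligand ligand atom table (with optional `bonds` attribute), or a
#'   [complex_structure()] whose `role == "ligand"` atoms are used.
#' @param rules an [interaction_rules()] object.
#' @param collapse_types if `TRUE`, report the five paper-level classes
#'   (`HB`, `ION`) instead of the direction/sign-split seven.
#' @return data frame of class `interaction_records`, one row per
#'   interaction: `itype`, participating centers (`px..pz` protein side,
#'   `lx..lz` ligand side, `ax..az` acceptor atom for hydrogen bonds),
#'   measured `dist`/`angle`, and comma-separated participating atom ids.
#' @export
detect_interactions <- function(site, ligand, rules = interaction_rules(),
                                collapse_types = FALSE) {
  if (inherits(site, "complex_structure")) site <- extract_binding_site(site)
  stopifnot(inherits(site, "binding_site"),
            inherits(rules, "interaction_rules"))
  if (inherits(ligand, "complex_structure")) {
    lb <- ligand$bonds
    lat <- ligand$atoms[ligand$atoms$role == "ligand", , drop = FALSE]
    if (!is.null(lb))
      lb <- lb[lb$a %in% lat$atom_id & lb$b %in% lat$atom_id, , drop = FALSE]
    ligand <- lat
    attr(ligand, "bonds") <- lb
  }
  if (nrow(ligand) == 0) stop("ligand must be non-empty")
  if (nrow(site$atoms) == 0)   # nothing near the ligand: no interactions
    return(structure(.rec("HYD", c(0, 0, 0), c(0, 0, 0), integer(0),
                          integer(0), 0)[0, ],
                     class = c("interaction_records", "data.frame")))
  lbonds <- attr(ligand, "bonds")
  sat <- site$atoms; sbonds <- site$bonds
  st <- .type_atoms(sat, sbonds)
  lt <- .type_atoms(ligand, lbonds)
  if (is.null(sbonds) || nrow(sbonds) == 0) sbonds <- .guess_bonds(sat)
  if (is.null(lbonds) || nrow(lbonds) == 0) lbonds <- .guess_bonds(ligand)

  recs <- list()
  sxyz <- .xyz(sat); lxyz <- .xyz(ligand)
  pos_of <- function(df, aid) as.numeric(df[match(aid, df$atom_id),
                                            c("x", "y", "z")])
  h_of <- function(atoms, bonds, aid) {
    nb <- c(bonds$b[bonds$a == aid], bonds$a[bonds$b == aid])
    nb <- nb[atoms$element[match(nb, atoms$atom_id)] == "H"]
    lapply(nb, function(h) pos_of(atoms, h))
  }

  # hydrophobic contacts
  si <- which(st$apolar & sat$role == "protein"); li <- which(lt$apolar)
  for (i in si) for (j in li) {
    d <- sqrt(sum((sxyz[i, ] - lxyz[j, ])^2))
    if (d <= rules$hyd_max_dist)
      recs[[length(recs) + 1L]] <-
        .rec("HYD", sxyz[i, ], lxyz[j, ], sat$atom_id[i],
             ligand$atom_id[j], d)
  }

  # hydrogen bonds, both directions
  hb <- function(don_at, don_ty, don_bonds, acc_at, acc_ty, lig_donates) {
    di <- which(don_ty$donor); ai <- which(acc_ty$acceptor)
    for (i in di) for (j in ai) {
      dpos <- as.numeric(don_at[i, c("x", "y", "z")])
      apos <- as.numeric(acc_at[j, c("x", "y", "z")])
      d <- sqrt(sum((dpos - apos)^2))
      if (d > rules$hb_max_dist || d < 1e-6) next
      hs <- h_of(don_at, don_bonds, don_at$atom_id[i])
      ang <- .best_dha_angle(dpos, hs, apos)
      if (!is.na(ang) && ang < rules$hb_min_angle) next
      if (lig_donates)
        recs[[length(recs) + 1L]] <<-
          .rec("HBD", apos, dpos, acc_at$atom_id[j], don_at$atom_id[i],
               d, ang, acc = apos)
      else
        recs[[length(recs) + 1L]] <<-
          .rec("HBA", dpos, apos, don_at$atom_id[i], acc_at$atom_id[j],
               d, ang, acc = apos)
    }
  }
  hb(ligand, lt, lbonds, sat, st, lig_donates = TRUE)
  hb(sat, st, sbonds, ligand, lt, lig_donates = FALSE)

  # aromatic ring stacking
  srings <- .ring_entities(sat, sbonds)
  lrings <- .ring_entities(ligand, lbonds)
  for (rs in srings) for (rl in lrings) {
    d <- sqrt(sum((rs$centroid - rl$centroid)^2))
    if (d > rules$aro_centroid_max_dist) next
    ca <- abs(sum(rs$normal * rl$normal))
    ang <- acos(pmin(pmax(ca, 0), 1)) * 180 / pi  # folded to [0, 90]
    face <- ang <= rules$aro_face_angle_max
    edge <- ang >= rules$aro_edge_angle_min
    if (face || edge)
      recs[[length(recs) + 1L]] <-
        .rec("ARO", rs$centroid, rl$centroid, rs$atom_ids, rl$atom_ids,
             d, ang)
  }

  # ionic interactions between opposite-sign charged-group centers
  scent <- .charge_centers(sat, sbonds)
  lcent <- .charge_centers(ligand, lbonds)
  for (cs in scent) for (cl in lcent) {
    if (cs$sign * cl$sign >= 0) next
    d <- sqrt(sum((cs$center - cl$center)^2))
    if (d <= rules$ion_max_dist)
      recs[[length(recs) + 1L]] <-
        .rec(if (cl$sign > 0) "ION_P" else "ION_N",
             cs$center, cl$center, cs$atom_ids, cl$atom_ids, d)
  }

  # metal complexation: site metals vs ligand heteroatoms
  mi <- which(st$is_metal); hi <- which(lt$hetero)
  for (i in mi) for (j in hi) {
    d <- sqrt(sum((sxyz[i, ] - lxyz[j, ])^2))
    if (d <= rules$metal_max_dist)
      recs[[length(recs) + 1L]] <-
        .rec("MET", sxyz[i, ], lxyz[j, ], sat$atom_id[i],
             ligand$atom_id[j], d)
  }

  out <- if (length(recs)) do.call(rbind, recs) else
    .rec("HYD", c(0, 0, 0), c(0, 0, 0), integer(0), integer(0), 0)[0, ]
  if (collapse_types && nrow(out)) {
    out$itype[out$itype %in% c("HBD", "HBA")] <- "HB"
    out$itype[out$itype %in% c("ION_P", "ION_N")] <- "ION"
  }
  out <- out[order(out$itype, out$protein_atoms, out$ligand_atoms), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_records", "data.frame")
  out
}

#' Abstract interaction records into typed pseudoatoms
#'
#' Hydrophobic, aromatic, ionic and metal interactions are placed at the
#' geometric center (midpoint) of the two participating centers; hydrogen
#' bonds at the position of the accepting atom.
#'
#' @param records an `interaction_records` data frame.
#' @return data frame of class `pseudoatoms` with columns `ptype`, `x`,
#'   `y`, `z`.
#' @export
place_pseudoatoms <- function(records) {
  if (nrow(records) == 0)
    return(structure(data.frame(ptype = character(0), x = numeric(0),
                                y = numeric(0), z = numeric(0)),
                     class = c("pseudoatoms", "data.frame")))
  is_hb <- records$itype %in% c("HBD", "HBA", "HB")
  x <- ifelse(is_hb, records$ax, (records$px + records$lx) / 2)
  y <- ifelse(is_hb, records$ay, (records$py + records$ly) / 2)
  z <- ifelse(is_hb, records$az, (records$pz + records$lz) / 2)
  structure(data.frame(ptype = records$itype, x = x, y = y, z = z,
                       stringsAsFactors = FALSE),
            class = c("pseudoatoms", "data.frame"))
}

#' Write interaction records to CSV
#'
#' @param records an `interaction_records` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
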