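# Deterministic generators: toy 3D complexes with planted interactions of
# each class, and labelled fingerprint datasets with a screening-style
# class imbalance.  They make every pipeline stage testable without any
# external structures.

#' Specification of a toy complex
#'
#' Each requested interaction is planted as an isolated ligand/protein
#' atom group whose geometry satisfies the default [interaction_rules()]
#' with at least a 0.3 Angstrom / 10 degree margin from every threshold;
#' groups are spaced far apart and filler atoms sit well outside every
#' rule's range, so detection recovers exactly the planted records.
#'
#' @param n_hyd,n_hbd,n_hba,n_aro,n_ion,n_met planted counts per class
#'   (ionic contacts are planted with a positively charged ligand group).
#' @param decoy_atoms number of non-interacting protein filler atoms.
#' @param seed integer seed.
#' @return Object of class `complex_spec`.
#' @export
complex_spec <- function(n_hyd = 0, n_hbd = 0, n_hba = 0, n_aro = 0,
                         n_ion = 0, n_met = 0, decoy_atoms = 0, seed = 1L) {
  counts <- c(n_hyd = n_hyd, n_hbd = n_hbd, n_hba = n_hba, n_aro = n_aro,
              n_ion = n_ion, n_met = n_met, decoy_atoms = decoy_atoms)
  if (any(counts < 0)) stop("counts must be >= 0")
  structure(c(as.list(counts), list(seed = as.integer(seed))),
            class = "complex_spec")
}

# random unit vector
.runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# a unit vector orthogonal to v
.perp <- function(v) {
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- ref - sum(ref * v) * v
  p / sqrt(sum(p^2))
}

#' Generate a toy complex with planted interactions
#'
#' @param spec a [complex_spec()].
#' @return List with `complex` (a [complex_structure()]) and `truth`
#'   (data frame of the planted interactions: `itype` plus the
#'   participating protein/ligand atom ids as comma-separated strings).
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "complex_spec"))
  set.seed(spec$seed)
  n_units <- spec$n_hyd + spec$n_hbd + spec$n_hba + spec$n_aro +
    spec$n_ion + spec$n_met
  if (n_units > 400) stop("infeasible spec: too many planted units")
  atoms <- list(); bonds <- list(); truth <- list()
  next_id <- 0L
  new_atom <- function(name, element, pos, charge = 0, aromatic = FALSE,
                       resname = "UNK", resid = 1L, role = "protein") {
    next_id <<- next_id + 1L
    atoms[[length(atoms) + 1L]] <<- data.frame(
      atom_id = next_id, name = name, element = element,
      x = pos[1], y = pos[2], z = pos[3], charge = charge,
      is_aromatic = aromatic, resname = resname, resid = resid,
      chain = "A", role = role, stringsAsFactors = FALSE)
    next_id
  }
  new_bond <- function(a, b, type = "1")
    bonds[[length(bonds) + 1L]] <<- data.frame(a = a, b = b, type = type,
                                               stringsAsFactors = FALSE)
  add_truth <- function(itype, p_ids, l_ids)
    truth[[length(truth) + 1L]] <<- data.frame(
      itype = itype, protein_atoms = paste(sort(p_ids), collapse = ","),
      ligand_atoms = paste(sort(l_ids), collapse = ","),
      stringsAsFactors = FALSE)

  hexagon <- function(center, normal, radius = 1.4) {
    u <- .perp(normal); w <- .cross(normal, u)
    t(vapply(0:5, function(k) {
      a <- k * pi / 3
      center + radius * (cos(a) * u + sin(a) * w)
    }, numeric(3)))
  }

  types <- c(rep("HYD", spec$n_hyd), rep("HBD", spec$n_hbd),
             rep("HBA", spec$n_hba), rep("ARO", spec$n_aro),
             rep("ION_P", spec$n_ion), rep("MET", spec$n_met))
  unit <- 0L
  for (ty in types) {
    unit <- unit + 1L
    c0 <- c(25 * unit, 0, 0)      # units are 25 A apart: no cross-talk
    d <- .runit()
    res <- unit
    if (ty == "HYD") {
      r <- stats::runif(1, 3.6, 4.2)      # <= 4.5 - 0.3
      l <- new_atom("CL1", "C", c0, role = "ligand", resname = "LIG")
      p <- new_atom("CP1", "C", c0 + r * d, resname = "HYD", resid = res)
      add_truth("HYD", p, l)
    } else if (ty == "HBD") {
      # ligand N-H donating to a protein carbonyl-like O at ~160 degrees
      hdir <- .runit()
      D <- new_atom("N1", "N", c0, role = "ligand", resname = "LIG")
      H <- new_atom("H1", "H", c0 + 1.0 * hdir, role = "ligand",
                    resname = "LIG")
      p <- .perp(hdir)
      a_dir <- cos(pi * 20 / 180) * hdir + sin(pi * 20 / 180) * p
      # |D-A| = 2.9 with the D-H...A angle at 160 degrees
      b_lin <- 2 * cos(pi * 20 / 180)
      t_len <- (-b_lin + sqrt(b_lin^2 + 4 * (2.9^2 - 1))) / 2
      A <- new_atom("O1", "O", c0 + 1.0 * hdir + t_len * a_dir,
                    resname = "HBD", resid = res)
      new_bond(D, H)
      add_truth("HBD", A, D)
    } else if (ty == "HBA") {
      # protein N-H donating to a ligand carbonyl-like O
      hdir <- .runit()
      A <- new_atom("O1", "O", c0, role = "ligand", resname = "LIG")
      p <- .perp(hdir)
      a_dir <- cos(pi * 20 / 180) * hdir + sin(pi * 20 / 180) * p
      b_lin <- 2 * cos(pi * 20 / 180)
      t_len <- (-b_lin + sqrt(b_lin^2 + 4 * (2.9^2 - 1))) / 2
      Dpos <- c0 + 1.0 * hdir + t_len * a_dir
      D <- new_atom("N1", "N", Dpos, resname = "HBA", resid = res)
      H <- new_atom("H1", "H", Dpos - 1.0 * hdir, resname = "HBA",
                    resid = res)
      new_bond(D, H)
      add_truth("HBA", D, A)
    } else if (ty == "ARO") {
      # parallel stacked six-membered rings, 3.6 A apart, face-to-face
      lring <- hexagon(c0, d)
      pring <- hexagon(c0 + 3.6 * d, d)
      l_ids <- integer(6); p_ids <- integer(6)
      for (k in 1:6) {
        l_ids[k] <- new_atom(paste0("CL", k), "C", lring[k, ],
                             aromatic = TRUE, role = "ligand",
                             resname = "LIG")
        p_ids[k] <- new_atom(paste0("CP", k), "C", pring[k, ],
                             aromatic = TRUE, resname = "PHE", resid = res)
      }
      for (k in 1:6) {
        new_bond(l_ids[k], l_ids[k %% 6 + 1], "ar")
        new_bond(p_ids[k], p_ids[k %% 6 + 1], "ar")
      }
      add_truth("ARO", p_ids, l_ids)
    } else if (ty == "ION_P") {
      r <- stats::runif(1, 2.9, 3.5)      # <= 4.0 - 0.3
      l <- new_atom("N1", "N", c0, charge = 1, role = "ligand",
                    resname = "LIG")
      p <- new_atom("O1", "O", c0 + r * d, charge = -1, resname = "ASP",
                    resid = res)
      add_truth("ION_P", p, l)
    } else if (ty == "MET") {
      r <- stats::runif(1, 2.0, 2.4)      # <= 2.8 - 0.3
      l <- new_atom("O1", "O", c0, role = "ligand", resname = "LIG")
      m <- new_atom("ZN", "Zn", c0 + r * d, resname = "ZN", resid = res,
                    role = "metal")
      add_truth("MET", m, l)
    }
  }
  # filler protein carbons, far from every ligand atom
  if (spec$decoy_atoms > 0) {
    span <- 25 * max(n_units, 1)
    for (k in seq_len(spec$decoy_atoms)) {
      pos <- c(stats::runif(1, -10, span + 10),
               stats::runif(1, 15, 30) * sample(c(-1, 1), 1),
               stats::runif(1, -10, 10))
      new_atom(paste0("CF", k), "C", pos, resname = "FIL",
               resid = 1000L + k)
    }
  }
  at <- do.call(rbind, atoms)
  if (!any(at$role == "ligand"))  # keep the container contract satisfied
    at <- rbind(at, data.frame(atom_id = next_id + 1L, name = "CL0",
                               element = "C", x = 0, y = 0, z = 0,
                               charge = 0, is_aromatic = FALSE,
                               resname = "LIG", resid = 1L, chain = "A",
                               role = "ligand", stringsAsFactors = FALSE))
  if (!any(at$role %in% c("protein", "metal")))
    at <- rbind(at, data.frame(atom_id = max(at$atom_id) + 1L, name = "CP0",
                               element = "C", x = 500, y = 500, z = 500,
                               charge = 0, is_aromatic = FALSE,
                               resname = "GLY", resid = 999L, chain = "A",
                               role = "protein", stringsAsFactors = FALSE))
  bd <- if (length(bonds)) do.call(rbind, bonds) else NULL
  cx <- complex_structure(at, bd, structure_id = sprintf("toy%04d",
                                                         spec$seed))
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(itype = character(0), protein_atoms = character(0),
               ligand_atoms = character(0))
  truth_df <- truth_df[order(truth_df$itype, truth_df$protein_atoms,
                             truth_df$ligand_atoms), , drop = FALSE]
  rownames(truth_df) <- NULL
  list(complex = cx, truth = truth_df)
}

.cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' Specification of a synthetic labelled fingerprint dataset
#'
#' Emulates the class structure of a screening corpus: 1740 samples with
#' 446 positives by default.  Positives activate a set of signal
#' features with probability `baseline + effect`, negatives with
#' `baseline`; observed labels are then flipped at rate `flip_noise`.
#'
#' @param n_samples dataset size.
#' @param prevalence positive fraction in `(0, 1)`.
#' @param n_signal_bits number of informative features (<= `n_features`).
#' @param effect activation-probability shift of signal bits in
#'   positives.
#' @param flip_noise fraction of labels flipped, in `[0, 0.5)`.
#' @param mode `"count"` or `"binary"` feature values.
#' @param baseline background activation probability.
#' @param n_features fingerprint length (default 211).
#' @param seed integer seed.
#' @return Object of class `fingerprint_dataset_spec`.
#' @export
fingerprint_dataset_spec <- function(n_samples = 1740,
                                     prevalence = 446 / 1740,
                                     n_signal_bits = 20, effect = 0.5,
                                     flip_noise = 0,
                                     mode = c("count", "binary"),
                                     baseline = 0.05, n_features = 211,
                                     seed = 1L) {
  mode <- match.arg(mode)
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  if (flip_noise < 0 || flip_noise >= 0.5)
    stop("flip_noise must be in [0, 0.5)")
  if (n_signal_bits > n_features)
    stop("n_signal_bits exceeds the number of features")
  if (baseline + effect > 1) stop("baseline + effect must be <= 1")
  structure(list(n_samples = as.integer(n_samples), prevalence = prevalence,
                 n_signal_bits = as.integer(n_signal_bits), effect = effect,
                 flip_noise = flip_noise, mode = mode, baseline = baseline,
                 n_features = as.integer(n_features),
                 seed = as.integer(seed)),
            class = "fingerprint_dataset_spec")
}

#' Generate a labelled fingerprint dataset
#'
#' @param spec a [fingerprint_dataset_spec()].
#' @return List with `x` (n x n_features matrix), `y` (observed 0/1
#'   labels after flips), `y_true` (pre-flip ground truth), and
#'   `signal_bits` (indices of the informative features).
#' @export
make_fingerprint_dataset <- function(spec) {
  stopifnot(inherits(spec, "fingerprint_dataset_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples; p <- spec$n_features
  n_pos <- round(n * spec$prevalence)
  y_true <- integer(n)
  y_true[sample.int(n, n_pos)] <- 1L
  prob <- matrix(spec$baseline, n, p)
  sig <- seq_len(spec$n_signal_bits)
  prob[y_true == 1L, sig] <- spec$baseline + spec$effect
  active <- matrix(stats::runif(n * p) < prob, n, p)
  x <- if (spec$mode == "binary") active * 1 else
    active * (1 + matrix(stats::rpois(n * p, 1), n, p))
  y <- y_true
  n_flip <- round(spec$flip_noise * n)
  if (n_flip > 0) {
    fl <- sample.int(n, n_flip)
    y[fl] <- 1L - y[fl]
  }
  rownames(x) <- sprintf("mol%05d", seq_len(n))
  colnames(x) <- sprintf("f%03d", seq_len(p))
  list(x = x, y = stats::setNames(y, rownames(x)),
       y_true = stats::setNames(y_true, rownames(x)), signal_bits = sig)
}
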