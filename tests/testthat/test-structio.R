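test_that("mol2 complexes parse with coordinates, roles and charges", {
  f <- write_tiny_mol2()
  cx <- read_complex(f)
  expect_s3_class(cx, "complex_structure")
  expect_equal(nrow(cx$atoms), 3)
  expect_equal(sum(cx$atoms$role == "ligand"), 1)
  lig <- cx$atoms[cx$atoms$role == "ligand", ]
  expect_equal(unlist(lig[, c("x", "y", "z")], use.names = FALSE),
               c(3.0, 0.5, 0.25))
  expect_equal(cx$atoms$charge[cx$atoms$name == "N1"], -0.3)
  expect_equal(nrow(cx$bonds), 1)
})

test_that("write + re-read is the identity on atoms within mol2 precision", {
  tc <- make_toy_complex(complex_spec(2, 1, 1, 1, 1, 1, decoy_atoms = 4,
                                      seed = 7))
  f <- tempfile(fileext = ".mol2")
  write_complex(tc$complex, f)
  cx2 <- read_complex(f)
  a1 <- tc$complex$atoms; a2 <- cx2$atoms
  expect_equal(nrow(a1), nrow(a2))
  a1 <- a1[order(a1$role, a1$resid, a1$name), ]
  a2 <- a2[order(a2$role, a2$resid, a2$name), ]
  expect_equal(a1$element, a2$element)
  expect_equal(a1$role, a2$role)
  expect_equal(a1$is_aromatic, a2$is_aromatic)
  expect_lt(max(abs(as.matrix(a1[, c("x", "y", "z")]) -
                    as.matrix(a2[, c("x", "y", "z")]))), 1e-3)
})

test_that("malformed and degenerate structure files are rejected", {
  bad <- tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "m", "0 0 0"), bad)
  expect_error(read_complex(bad), "ATOM")
  expect_error(read_complex(tempfile(fileext = ".mol2")), "not found")
  expect_error(complex_structure(data.frame()), "missing columns")
})

test_that("binding-site inclusion follows the any-atom distance rule", {
  # residue 1 nearest atom at 5.9 A, residue 2 at 6.1 A, two-atom residues
  at <- mk_atoms(
    atom("C", c(0, 0, 0), role = "ligand", res = "LIG", ri = 1),
    atom("C", c(5.9, 0, 0), res = "ALA", ri = 10),
    atom("C", c(9.0, 0, 0), res = "ALA", ri = 10),
    atom("C", c(6.1, 0, 0), res = "GLY", ri = 20),
    atom("C", c(12, 0, 0), res = "GLY", ri = 20))
  cx <- complex_structure(at)
  site <- extract_binding_site(cx, 6.0)
  expect_equal(site$residue_keys$resid, 10)
  # whole residue kept, including the atom at 9 A
  expect_setequal(site$atoms$atom_id, c(2, 3))
  # degenerate cutoff
  expect_equal(nrow(extract_binding_site(cx, 0)$atoms), 0)
  expect_error(extract_binding_site(
    complex_structure(mk_atoms(atom("C", c(0, 0, 0))))), "ligand")
})

test_that("binding-site membership is monotone in the cutoff", {
  tc <- make_toy_complex(complex_spec(3, 1, 1, 1, 0, 0, decoy_atoms = 8,
                                      seed = 21))
  cuts <- c(0, 2, 4, 6, 9, 15)
  sites <- lapply(cuts, function(cc) extract_binding_site(tc$complex, cc))
  for (i in seq_len(length(cuts) - 1)) {
    ids_lo <- sites[[i]]$atoms$atom_id
    ids_hi <- sites[[i + 1]]$atoms$atom_id
    expect_true(all(ids_lo %in% ids_hi))
  }
})

test_that("pose_rmsd matches the closed form and its invariances", {
  set.seed(42)
  a <- matrix(rnorm(15), 5, 3)
  expect_equal(pose_rmsd(a, a), 0)
  expect_equal(pose_rmsd(a, sweep(a, 2, c(3, 0, 0), "+")), 3)
  b <- matrix(rnorm(15), 5, 3)
  brute <- sqrt(sum((a - b)^2) / 5)
  expect_equal(pose_rmsd(a, b), brute)
  expect_equal(pose_rmsd(b, a), pose_rmsd(a, b))
  # invariant under a shared rigid motion
  r <- random_rotation(); tr <- c(1, -2, 5)
  a2 <- sweep(a %*% t(r), 2, tr, "+"); b2 <- sweep(b %*% t(r), 2, tr, "+")
  expect_equal(pose_rmsd(a2, b2), pose_rmsd(a, b))
  expect_error(pose_rmsd(a, b[1:3, ]), "size")
  expect_error(pose_rmsd(a[0, ], b[0, ]), "empty")
})

test_that("receptor selection minimizes the mean cross-docking RMSD", {
  tab <- data.frame(structure_id = c("A", "A", "B", "B"),
                    ligand_id = c("l1", "l2", "l1", "l2"),
                    rmsd = c(1.0, 2.0, 3.0, 0.5))
  expect_equal(as.character(select_receptor(tab)), "A")
  single <- data.frame(structure_id = "X", ligand_id = "l", rmsd = 2)
  expect_equal(as.character(select_receptor(single)), "X")
  tie <- data.frame(structure_id = c("5mvs", "1nw3"),
                    ligand_id = c("l", "l"), rmsd = c(1.5, 1.5))
  expect_equal(as.character(select_receptor(tie)), "1nw3")
  expect_error(select_receptor(data.frame()), "empty")
})

test_that("receptor selection agrees with brute-force argmin and handles NA", {
  for (s in 1:100) {
    set.seed(s)
    n_cand <- sample(2:6, 1); n_lig <- sample(2:5, 1)
    tab <- expand.grid(structure_id = paste0("s", 1:n_cand),
                       ligand_id = paste0("l", 1:n_lig),
                       stringsAsFactors = FALSE)
    tab$rmsd <- round(runif(nrow(tab), 0, 8), 3)
    got <- as.character(select_receptor(tab))
    means <- sapply(split(tab$rmsd, tab$structure_id), mean)
    means <- means[order(names(means))]
    expect_equal(got, names(means)[which.min(means)])
  }
  # NA entries are skipped by default, penalized on request
  tab <- data.frame(structure_id = c("A", "A", "B", "B"),
                    ligand_id = c("l1", "l2", "l1", "l2"),
                    rmsd = c(1.0, NA, 1.2, 1.2))
  expect_equal(as.character(select_receptor(tab)), "A")
  expect_equal(as.character(select_receptor(tab, "penalize", penalty = 10)),
               "B")
})

test_that("PDB complexes assign roles from record types", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1, 1, 0, 0, 0),
    sprintf("ATOM  %5d  CB  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            2, 1, 1.5, 0, 0),
    sprintf("HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
            3, 101, 8, 8, 8),
    sprintf("HETATM%5d ZN    ZN A%4d    %8.3f%8.3f%8.3f  1.00  0.00          ZN",
            4, 102, 2, 2, 2),
    sprintf("HETATM%5d  C1  LIG A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            5, 103, 3, 0, 0),
    "END"), f)
  cx <- read_complex(f, format = "pdb")
  expect_setequal(cx$atoms$role, c("protein", "metal", "ligand"))
  expect_false(any(cx$atoms$resname == "HOH"))
  expect_equal(cx$atoms$element[cx$atoms$role == "metal"], "Zn")
})
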