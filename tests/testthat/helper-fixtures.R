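# shared fixture builders and independent oracles

# minimal atoms data frame with defaults filled in
mk_atoms <- function(..., role = "protein") {
  pos <- list(...)
  n <- length(pos)
  df <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- pos[[i]]
    data.frame(atom_id = i, name = paste0("A", i),
               element = p$el, x = p$xyz[1], y = p$xyz[2], z = p$xyz[3],
               charge = if (is.null(p$q)) 0 else p$q,
               is_aromatic = isTRUE(p$ar),
               resname = if (is.null(p$res)) "UNK" else p$res,
               resid = if (is.null(p$ri)) i else p$ri,
               chain = "A",
               role = if (is.null(p$role)) role else p$role,
               stringsAsFactors = FALSE)
  }))
  df
}

atom <- function(el, xyz, q = 0, ar = FALSE, res = NULL, ri = NULL,
                 role = NULL)
  list(el = el, xyz = xyz, q = q, ar = ar, res = res, ri = ri, role = role)

# random proper rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a rigid motion to a complex_structure
transform_complex <- function(cx, rot, trans) {
  xyz <- as.matrix(cx$atoms[, c("x", "y", "z")]) %*% t(rot)
  cx$atoms$x <- xyz[, 1] + trans[1]
  cx$atoms$y <- xyz[, 2] + trans[2]
  cx$atoms$z <- xyz[, 3] + trans[3]
  cx
}

# brute-force canonicalizer: minimum key encoding over all 6 vertex orders
oracle_triplet_key <- function(types, pos, scheme = bin_scheme()) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  d <- as.matrix(stats::dist(pos))
  enc <- vapply(perms, function(pr) {
    opp <- vapply(1:3, function(i) {
      others <- pr[-i]
      d[others[1], others[2]]
    }, 0)
    paste(paste(types[pr], bin_distance(opp, scheme), sep = "|"),
          collapse = ";")
  }, "")
  min(enc)
}

# exhaustive triple-loop triplet enumeration
oracle_enumerate <- function(pa, scheme = bin_scheme()) {
  n <- nrow(pa)
  if (n < 3) return(stats::setNames(integer(0), character(0)))
  keys <- character(0)
  pos <- as.matrix(pa[, c("x", "y", "z")])
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
    keys <- c(keys, oracle_triplet_key(pa$ptype[c(i, j, k)],
                                       pos[c(i, j, k), ], scheme))
  tb <- table(keys)
  stats::setNames(as.integer(tb), names(tb))
}

# O(P*N) pairwise-concordance ROC-AUC
oracle_roc_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# a tiny two-block mol2 file; returns its path
write_tiny_mol2 <- function(path = tempfile(fileext = ".mol2")) {
  writeLines(c(
    "@<TRIPOS>MOLECULE", "protein", " 2 1 1", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    "1 N1 0.000 0.000 0.000 N.3 1 ALA1 -0.300",
    "2 O1 2.100 1.100 0.000 O.2 1 ALA1 -0.500",
    "@<TRIPOS>BOND", "1 1 2 1",
    "@<TRIPOS>MOLECULE", "ligand", " 1 0 1", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    "1 C1 3.000 0.500 0.250 C.3 1 LIG1 0.000"), path)
  path
}
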