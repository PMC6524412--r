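test_that("distance binning follows the half-open range convention", {
  expect_equal(bin_distance(3.9), 0)
  expect_equal(bin_distance(4.0), 1)     # boundary goes up
  expect_equal(bin_distance(c(0, 5.99, 6, 8.9, 9, 12.9, 13, 16.9, 17, 18.5)),
               c(0, 1, 2, 2, 3, 3, 4, 4, 5, 5))
  expect_error(bin_distance(-0.1), ">= 0")
  expect_error(bin_scheme(c(4, 4, 9)), "increasing")
})

test_that("triplet keys are identical for all six vertex orders", {
  pa <- data.frame(ptype = c("HYD", "HBA", "ARO"),
                   x = c(0, 5, 2), y = c(0, 0, 7), z = c(0, 1, 3))
  pos <- as.matrix(pa[, c("x", "y", "z")])
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  keys <- vapply(perms, function(p) {
    d <- as.matrix(dist(pos[p, ]))
    canonical_triplet_key(pa$ptype[p], dists = c(d[2, 3], d[1, 3], d[1, 2]))
  }, "")
  expect_length(unique(keys), 1)
})

test_that("an equilateral HYD triangle of side 5 bins to (1,1,1)", {
  key <- canonical_triplet_key(c("HYD", "HYD", "HYD"), dists = c(5, 5, 5))
  expect_equal(key, "HYD|1;HYD|1;HYD|1")
})

test_that("canonicalization matches the 6-permutation enumeration oracle", {
  set.seed(123)
  impl <- character(1000); orac <- character(1000)
  types_pool <- c("HYD", "ARO", "HBD", "HBA", "ION_P", "ION_N", "MET")
  for (i in 1:1000) {
    ty <- sample(types_pool, 3, replace = TRUE)
    pos <- matrix(runif(9, 0, 20), 3)
    impl[i] <- canonical_triplet_key(ty, pos)
    orac[i] <- oracle_triplet_key(ty, pos)
  }
  expect_identical(impl, orac)
  expect_equal(length(unique(impl)), length(unique(orac)))
})

test_that("triplet enumeration counts every unordered 3-subset once", {
  pa0 <- data.frame(ptype = character(0), x = numeric(0), y = numeric(0),
                    z = numeric(0))
  expect_length(enumerate_triplets(pa0), 0)
  pa2 <- data.frame(ptype = c("HYD", "ARO"), x = 0:1, y = 0, z = 0)
  expect_length(enumerate_triplets(pa2), 0)
  pa3 <- data.frame(ptype = c("HYD", "ARO", "MET"), x = 0:2, y = 0, z = 0)
  expect_equal(sum(enumerate_triplets(pa3)), 1)
  set.seed(7)
  pa6 <- data.frame(ptype = sample(c("HYD", "HBA"), 6, TRUE),
                    x = runif(6, 0, 15), y = runif(6, 0, 15),
                    z = runif(6, 0, 15))
  tr <- enumerate_triplets(pa6)
  expect_equal(sum(tr), choose(6, 3))
  expect_equal(as.list(tr), as.list(oracle_enumerate(pa6)))
})

test_that("dictionary ranking is by count with a lexicographic tie rule", {
  corpus <- list(c("B|1;B|1;B|1" = 10L, "A|0;A|0;A|0" = 4L),
                 c("C|2;C|2;C|2" = 4L, "B|1;B|1;B|1" = 1L))
  d <- build_dictionary(corpus, size = 211)
  expect_equal(d$keys[1], "B|1;B|1;B|1")        # count 11
  # A and C tie at 4: lexicographically smaller first
  expect_equal(d$keys[2:3], c("A|0;A|0;A|0", "C|2;C|2;C|2"))
  expect_equal(d$n_active, 3)
  expect_equal(length(d$keys), 211)
  expect_error(build_dictionary(corpus, size = 0), "size")
})

test_that("dictionary ranking equals a full sort of the corpus counts", {
  set.seed(11)
  corpus <- lapply(1:20, function(i) {
    pa <- data.frame(ptype = sample(c("HYD", "ARO", "HBD"), 8, TRUE),
                     x = runif(8, 0, 12), y = runif(8, 0, 12),
                     z = runif(8, 0, 12))
    enumerate_triplets(pa)
  })
  d <- build_dictionary(corpus)
  tot <- tapply(unlist(corpus, use.names = FALSE),
                unlist(lapply(corpus, names)), sum)
  expected <- utils::head(names(tot)[order(-as.numeric(tot), names(tot))],
                          211)
  expect_equal(d$keys[seq_along(expected)], expected)
})

test_that("vectorization maps counts to dictionary slots exactly", {
  corpus <- list(stats::setNames(rep(1L, 8), paste0("K", 1:8, "|0;X|1;Y|2")))
  d <- build_dictionary(corpus, size = 211)
  z <- vectorize(stats::setNames(integer(0), character(0)), d)
  expect_length(z, 211)
  expect_true(all(z == 0))
  k <- d$keys[8]
  v <- vectorize(stats::setNames(3L, k), d)
  expect_equal(as.numeric(v[8]), 3)
  expect_equal(sum(v), 3)
  vb <- vectorize(stats::setNames(3L, k), d, mode = "binary")
  expect_equal(as.numeric(vb[8]), 1)
  # conservation: in-dictionary mass + dropped = total multiplicity
  tri <- stats::setNames(c(2L, 5L, 4L), c(d$keys[1], d$keys[3], "ZZ|9;Z|9;Z|9"))
  v2 <- vectorize(tri, d)
  expect_equal(sum(v2) + attr(v2, "dropped"), sum(tri))
})

test_that("descriptor appending extends without touching base features", {
  v <- vectorize(stats::setNames(integer(0), character(0)),
                 build_dictionary(list(c("A|0;A|0;A|0" = 1L))))
  v2 <- append_descriptors(v, -8.4)
  expect_length(v2, 212)
  expect_equal(as.numeric(v2[212]), -8.4)
  expect_equal(as.numeric(v2[1:211]), as.numeric(v))
  expect_identical(as.numeric(append_descriptors(v, numeric(0))),
                   as.numeric(v))
  expect_error(append_descriptors(v, NaN), "finite")
})

test_that("dictionary and fingerprint files round-trip", {
  set.seed(3)
  corpus <- lapply(1:5, function(i) {
    pa <- data.frame(ptype = sample(c("HYD", "HBA"), 6, TRUE),
                     x = runif(6, 0, 10), y = runif(6, 0, 10),
                     z = runif(6, 0, 10))
    enumerate_triplets(pa)
  })
  d <- build_dictionary(corpus, provenance = "unit-test corpus")
  f <- tempfile(fileext = ".json")
  write_dictionary(d, f)
  d2 <- read_dictionary(f)
  expect_equal(d2$keys, d$keys)
  expect_equal(d2$counts, d$counts)
  expect_equal(d2$n_active, d$n_active)
  fps <- rbind(mol1 = as.numeric(vectorize(corpus[[1]], d)),
               mol2 = as.numeric(vectorize(corpus[[2]], d)))
  fc <- tempfile(fileext = ".csv")
  write_fingerprints(fps, fc, target_id = "DOT1L")
  back <- read_fingerprints(fc)
  expect_equal(as.numeric(back), as.numeric(fps))
  expect_equal(rownames(back), c("mol1", "mol2"))
  expect_equal(unique(attr(back, "target_id")), "DOT1L")
})

test_that("the end-to-end fingerprint is rigid-motion and order invariant", {
  tc <- make_toy_complex(complex_spec(2, 1, 1, 1, 1, 1, decoy_atoms = 5,
                                      seed = 31))
  recs <- detect_interactions(extract_binding_site(tc$complex), tc$complex)
  dict <- build_dictionary(
    list(enumerate_triplets(place_pseudoatoms(recs))))
  fp <- fingerprint_complex(tc$complex, dict)
  set.seed(31)
  moved <- transform_complex(tc$complex, random_rotation(), c(-4, 2, 9))
  moved$atoms <- moved$atoms[sample(nrow(moved$atoms)), ]
  expect_equal(as.numeric(fingerprint_complex(moved, dict)),
               as.numeric(fp))
  expect_lte(sum(fp), choose(nrow(place_pseudoatoms(recs)), 3))
})
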