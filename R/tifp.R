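# The triplet pseudoatom fingerprint: every unordered triple of typed
# pseudoatoms is encoded as its three types joined with the distance bin
# of the opposite triangle side, canonicalized so that the key is
# independent of input order; counts over a corpus define a 211-entry
# feature dictionary and each complex becomes a length-211 vector.

#' Distance binning scheme
#'
#' Six half-open distance ranges: 0-4, 4-6, 6-9, 9-13, 13-17 and 17+ A.
#'
#' @param edges strictly increasing interior bin boundaries in Angstrom.
#' @return Object of class `bin_scheme` with `edges` and `n_bins`.
#' @export
bin_scheme <- function(edges = c(4, 6, 9, 13, 17)) {
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  structure(list(edges = edges, n_bins = length(edges) + 1L),
            class = "bin_scheme")
}

#' Bin a pseudoatom-pair distance
#'
#' Half-open convention `[lo, hi)`: a distance equal to an edge falls in
#' the upper bin, and anything at or beyond the last edge falls in the
#' final open-ended bin.
#'
#' @param d distance(s) in Angstrom, non-negative.
#' @param scheme a [bin_scheme()].
#' @return Integer bin index in `0 .. n_bins - 1` (vectorized).
#' @export
bin_distance <- function(d, scheme = bin_scheme()) {
  if (any(!is.finite(d)) || any(d < 0)) stop("distances must be >= 0")
  findInterval(d, scheme$edges)
}

# encode sorted (type, bin) pairs as a key string
.encode_key <- function(types, bins) {
  parts <- paste(types, bins, sep = "|")
  paste(sort(parts), collapse = ";")
}

#' Canonical key of one pseudoatom triplet
#'
#' Each vertex is paired with the distance bin of the *opposite* triangle
#' side; the canonical form is the lexicographically smallest ordering of
#' the three (type, opposite-side bin) pairs, so all six input orders of
#' the same triplet yield a byte-identical key.
#'
#' @param types character vector of 3 pseudoatom type codes.
#' @param positions 3 x 3 numeric matrix of pseudoatom coordinates, or
#'   `NULL` if `dists` is given.
#' @param dists optional length-3 vector of side lengths *opposite* each
#'   vertex (`dists[i]` = distance between the other two pseudoatoms).
#' @param scheme a [bin_scheme()].
#' @return Key string, e.g. `"ARO|2;HBD|0;HYD|1"`.
#' @export
canonical_triplet_key <- function(types, positions = NULL, dists = NULL,
                                  scheme = bin_scheme()) {
  if (length(types) != 3) stop("a triplet has exactly 3 pseudoatoms")
  if (is.null(dists)) {
    p <- as.matrix(positions)
    if (!all(dim(p) == c(3, 3))) stop("positions must be 3 x 3")
    dists <- c(sqrt(sum((p[2, ] - p[3, ])^2)),   # opposite vertex 1
               sqrt(sum((p[1, ] - p[3, ])^2)),   # opposite vertex 2
               sqrt(sum((p[1, ] - p[2, ])^2)))   # opposite vertex 3
  }
  .encode_key(types, bin_distance(dists, scheme))
}

#' Enumerate all pseudoatom triplets of a complex
#'
#' Every unordered 3-subset of the pseudoatom set contributes one
#' canonical key, i.e. `choose(n, 3)` keys counted with multiplicity.
#'
#' @param pseudoatoms a `pseudoatoms` data frame (see
#'   [place_pseudoatoms()]).
#' @param scheme a [bin_scheme()].
#' @return Named integer vector: canonical key -> multiplicity.  Empty
#'   for fewer than 3 pseudoatoms.
#' @export
enumerate_triplets <- function(pseudoatoms, scheme = bin_scheme()) {
  n <- nrow(pseudoatoms)
  if (n < 3) return(stats::setNames(integer(0), character(0)))
  xyz <- as.matrix(pseudoatoms[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(xyz))
  types <- pseudoatoms$ptype
  idx <- utils::combn(n, 3)
  keys <- character(ncol(idx))
  for (k in seq_len(ncol(idx))) {
    i <- idx[1, k]; j <- idx[2, k]; l <- idx[3, k]
    keys[k] <- .encode_key(types[c(i, j, l)],
                           bin_distance(c(dm[j, l], dm[i, l], dm[i, j]),
                                        scheme))
  }
  tb <- table(keys)
  stats::setNames(as.integer(tb), names(tb))
}

#' Build a fixed-size feature dictionary from a corpus
#'
#' Keys are ranked by total count over the corpus (descending, ties by
#' lexicographic key order) and the top `size` kept.  If the corpus holds
#' fewer distinct keys, inert placeholder slots pad the dictionary so the
#' fingerprint length is always `size`.
#'
#' @param corpus list of named count vectors as returned by
#'   [enumerate_triplets()].
#' @param size dictionary length (default 211).
#' @param provenance free-text identifier of the corpus the dictionary
#'   was built from.
#' @return Object of class `feature_dictionary`: `keys` (length `size`),
#'   `counts`, `n_active`, `size`, `provenance`.
#' @export
build_dictionary <- function(corpus, size = 211, provenance = "") {
  if (size < 1) stop("size must be >= 1")
  if (length(corpus) == 0) stop("empty corpus")
  all_keys <- unlist(lapply(corpus, names))
  all_counts <- unlist(corpus, use.names = FALSE)
  tot <- tapply(all_counts, all_keys, sum)
  if (length(tot)) {
    ord <- order(-as.numeric(tot), names(tot))
    tot <- tot[ord]
  }
  n_active <- min(length(tot), size)
  keys <- names(tot)[seq_len(n_active)]
  counts <- as.integer(tot)[seq_len(n_active)]
  if (n_active < size) {
    pad <- sprintf("__unused_%03d", seq_len(size - n_active))
    keys <- c(keys, pad)
    counts <- c(counts, rep(0L, size - n_active))
  }
  structure(list(keys = keys, counts = counts, n_active = n_active,
                 size = as.integer(size), provenance = provenance),
            class = "feature_dictionary")
}

#' @export
print.feature_dictionary <- function(x, ...) {
  cat("feature_dictionary:", x$size, "slots,", x$n_active, "active keys\n")
  invisible(x)
}

#' Serialize / load a feature dictionary (JSON)
#'
#' @param dict a `feature_dictionary`.
#' @param path file path.
#' @return `path` (write) or the dictionary (read).
#' @export
write_dictionary <- function(dict, path) {
  jsonlite::write_json(list(size = dict$size, n_active = dict$n_active,
                            provenance = dict$provenance, keys = dict$keys,
                            counts = dict$counts),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  d <- jsonlite::fromJSON(path)
  structure(list(keys = as.character(d$keys), counts = as.integer(d$counts),
                 n_active = as.integer(d$n_active),
                 size = as.integer(d$size),
                 provenance = as.character(d$provenance)),
            class = "feature_dictionary")
}

#' Map triplet counts onto a dictionary vector
#'
#' @param triplets named count vector from [enumerate_triplets()].
#' @param dict a [build_dictionary()] result.
#' @param mode `"count"` (triplet multiplicities, the default) or
#'   `"binary"` (presence bits).
#' @return Numeric vector of length `dict$size` with class
#'   `tifp_fingerprint`; the number of enumerated triplets whose key is
#'   not in the dictionary is attached as attribute `"dropped"`.
#' @export
vectorize <- function(triplets, dict, mode = c("count", "binary")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dict, "feature_dictionary"))
  v <- numeric(dict$size)
  if (length(triplets)) {
    pos <- match(names(triplets), dict$keys)
    hit <- !is.na(pos)
    v[pos[hit]] <- as.numeric(triplets[hit])
    dropped <- sum(triplets[!hit])
  } else dropped <- 0L
  if (mode == "binary") v <- as.numeric(v > 0)
  structure(v, mode = mode, dropped = as.integer(dropped),
            class = "tifp_fingerprint")
}

#' Append extra descriptors to a fingerprint
#'
#' Used e.g. to add a docking score as descriptor 212 for the hybrid
#' fingerprint-plus-docking model; base positions are unchanged.
#'
#' @param fp fingerprint vector.
#' @param extra finite numeric values to append, in order.
#' @return The extended fingerprint.
#' @export
append_descriptors <- function(fp, extra) {
  if (length(extra) == 0) return(fp)
  if (any(!is.finite(extra))) stop("appended descriptors must be finite")
  out <- c(unclass(fp), as.numeric(extra))
  attributes(out) <- attributes(fp)[setdiff(names(attributes(fp)), "names")]
  out
}

#' End-to-end fingerprint of one complex
#'
#' Convenience pipeline: binding-site extraction, interaction detection,
#' pseudoatom placement, triplet enumeration and dictionary lookup.
#'
#' @param complex a [complex_structure()].
#' @param dict a `feature_dictionary`.
#' @param rules an [interaction_rules()].
#' @param cutoff binding-site cutoff in Angstrom.
#' @param mode `"count"` or `"binary"`.
#' @param scheme a [bin_scheme()].
#' @return A `tifp_fingerprint` vector of length `dict$size`.
#' @export
fingerprint_complex <- function(complex, dict, rules = interaction_rules(),
                                cutoff = 6.0, mode = "count",
                                scheme = bin_scheme()) {
  site <- extract_binding_site(complex, cutoff)
  recs <- detect_interactions(site, complex, rules)
  pa <- place_pseudoatoms(recs)
  vectorize(enumerate_triplets(pa, scheme), dict, mode)
}

#' Write a fingerprint matrix to CSV
#'
#' One row per molecule: `molecule_id`, `target_id`, then one column per
#' feature (`f001`, `f002`, ...).
#'
#' @param fps numeric matrix (rows = molecules).
#' @param path output path.
#' @param molecule_id,target_id row identifiers.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path, molecule_id = rownames(fps),
                               target_id = "") {
  fps <- as.matrix(fps)
  if (is.null(molecule_id)) molecule_id <- sprintf("mol%04d", seq_len(nrow(fps)))
  df <- data.frame(molecule_id = molecule_id, target_id = target_id,
                   fps, check.names = FALSE)
  colnames(df)[-(1:2)] <- sprintf("f%03d", seq_len(ncol(fps)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$molecule_id
  attr(m, "target_id") <- df$target_id
  m
}
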