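#' @include AllClasses.R utils.R
NULL

#' Per-amino-acid neighbor radii for NBR-NBR contact maps
#'
#' The neighbor atom of a residue is its C-beta (C-alpha for glycine), and
#' two residues are in contact when the distance between their neighbor
#' atoms is below the sum of the pair's neighbor radii. A neighbor radius
#' approximates the interaction sphere swept by the side chain over its
#' rotamers, following the Rosetta convention; the exact values are data,
#' not code, and can be overridden via the `radii` argument of
#' [buildContactMap()].
#'
#' @return Named numeric vector, Angstrom, keyed by one-letter residue code.
#' @export
neighborRadii <- function() {
  c(G = 2.9, A = 3.4, S = 3.6, C = 3.7, T = 3.7, P = 3.8, V = 4.0,
    D = 4.0, N = 4.1, I = 4.4, L = 4.4, E = 4.6, Q = 4.7, M = 4.8,
    H = 4.9, F = 5.0, K = 5.4, Y = 5.6, W = 5.7, R = 6.1)
}

#' Bundle per-residue atom coordinates
#'
#' Light container for parsed coordinates: the one-letter sequence and,
#' per residue, a small matrix of atom coordinates with atom names as row
#' names. A bare L x 3 matrix elsewhere in the package is shorthand for
#' C-alpha-only coordinates (the synthetic bead chains).
#'
#' @param sequence One-letter residue string of length L.
#' @param atoms List of L matrices (atoms x 3, rownames = atom names, Angstrom).
#' @param chain Chain identifier.
#' @return A `residueCoordinates` object.
#' @export
residueCoordinates <- function(sequence, atoms, chain = "A") {
  stopifnot(nchar(sequence) == length(atoms))
  structure(list(sequence = sequence, atoms = atoms, chain = chain),
            class = "residueCoordinates")
}

caMatrix <- function(coords) {
  if (is.matrix(coords)) return(coords)
  stopifnot(inherits(coords, "residueCoordinates"))
  missing <- which(vapply(coords$atoms,
                          function(a) !"CA" %in% rownames(a), logical(1)))
  if (length(missing))
    stop(sprintf("residue(s) without a CA atom: %s",
                 paste(missing, collapse = ", ")))
  t(vapply(coords$atoms, function(a) a["CA", ], numeric(3)))
}

#' Build a residue-residue contact map
#'
#' Three contact definitions are supported. `CA_CA`: residues are in
#' contact when their C-alpha distance is strictly below `threshold`
#' (default 10 Angstrom). `ANY_ANY`: contact when any inter-atom distance
#' is strictly below `threshold` (default 6.5). `NBR_NBR`: contact when the
#' distance between the residues' neighbor atoms (C-beta, C-alpha for
#' glycine) is strictly below the sum of the pair's neighbor radii (see
#' [neighborRadii()]). All thresholds are strict: boundary equality is not
#' a contact. The diagonal is zero.
#'
#' @param coords A `residueCoordinates` object, or a bare L x 3 matrix of
#'   C-alpha coordinates (sufficient for `CA_CA`).
#' @param mode `"CA_CA"`, `"ANY_ANY"` or `"NBR_NBR"`.
#' @param threshold Distance threshold in Angstrom (ignored for `NBR_NBR`).
#' @param radii Neighbor-radius table for `NBR_NBR`.
#' @return A [ContactMap-class].
#' @export
#' @examples
#' xyz <- cbind(seq(0, 38, by = 3.8), 0, 0)  # straight 11-bead chain
#' cm <- buildContactMap(xyz, "CA_CA", 10)
#' adjacency(cm)[1, 2:4]  # 3.8 and 7.6 A are contacts, 11.4 A is not
buildContactMap <- function(coords,
                            mode = c("CA_CA", "ANY_ANY", "NBR_NBR"),
                            threshold = NULL, radii = neighborRadii()) {
  mode <- match.arg(mode)
  if (mode == "CA_CA") {
    if (is.null(threshold)) threshold <- 10
    xyz <- caMatrix(coords)
    L <- nrow(xyz)
    if (L < 1L) stop("empty coordinate set")
    D <- as.matrix(stats::dist(xyz))
    A <- (D < threshold) * 1
  } else if (mode == "ANY_ANY") {
    if (is.null(threshold)) threshold <- 6.5
    if (is.matrix(coords)) {
      coords <- residueCoordinates(
        paste(rep("A", nrow(coords)), collapse = ""),
        lapply(seq_len(nrow(coords)), function(i) {
          m <- coords[i, , drop = FALSE]; rownames(m) <- "CA"; m
        }))
    }
    L <- length(coords$atoms)
    allAtoms <- do.call(rbind, coords$atoms)
    resOf <- rep(seq_len(L), vapply(coords$atoms, nrow, integer(1)))
    D <- as.matrix(stats::dist(allAtoms))
    A <- matrix(0, L, L)
    inContact <- which(D < threshold, arr.ind = TRUE)
    ij <- cbind(resOf[inContact[, 1]], resOf[inContact[, 2]])
    A[ij] <- 1
    threshold <- threshold
  } else {
    if (!inherits(coords, "residueCoordinates"))
      stop("NBR_NBR mode needs full residueCoordinates (C-beta atoms)")
    chars <- strsplit(coords$sequence, "")[[1]]
    unknown <- setdiff(unique(chars), names(radii))
    if (length(unknown))
      stop(sprintf("no neighbor radius for residue code(s): %s",
                   paste(unknown, collapse = ", ")))
    L <- length(chars)
    nbr <- matrix(NA_real_, L, 3)
    for (i in seq_len(L)) {
      a <- coords$atoms[[i]]
      want <- if (chars[i] == "G") "CA" else "CB"
      if (!want %in% rownames(a))
        stop(sprintf("residue %d (%s) lacks required atom %s",
                     i, chars[i], want))
      nbr[i, ] <- a[want, ]
    }
    D <- as.matrix(stats::dist(nbr))
    r <- radii[chars]
    rsum <- outer(r, r, "+")
    A <- (D < rsum) * 1
    threshold <- NA_real_
  }
  diag(A) <- 0
  dimnames(A) <- NULL
  new("ContactMap", adjacency = A, mode = mode,
      threshold = if (is.null(threshold)) NA_real_ else threshold)
}

#' Retain proteins inside a residue-length window
#'
#' Keeps records whose length L satisfies `min <= L <= max` (bounds
#' inclusive), preserving order. The number of removed records is reported
#' in a message.
#'
#' @param records List of [ProteinRecord-class] objects.
#' @param min,max Inclusive residue-count bounds (defaults 60 and 1000).
#' @return Filtered list.
#' @export
filterByLength <- function(records, min = 60L, max = 1000L) {
  stopifnot(min <= max)
  lens <- vapply(records, function(r) nchar(r@sequence), numeric(1))
  keep <- lens >= min & lens <= max
  if (any(!keep))
    message(sprintf("filterByLength: removed %d of %d records outside [%d, %d]",
                    sum(!keep), length(records), min, max))
  records[keep]
}

#' Randomly flip contact-map entries
#'
#' Each upper-triangle off-diagonal entry is flipped independently with
#' probability `flip_rate` and mirrored to preserve symmetry; the diagonal
#' stays zero. A desk-scale surrogate for degraded model quality.
#'
#' @param cmap A [ContactMap-class].
#' @param flip_rate Flip probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A perturbed [ContactMap-class].
#' @export
perturbContactMap <- function(cmap, flip_rate, seed) {
  stopifnot(flip_rate >= 0, flip_rate <= 1)
  A <- cmap@adjacency
  L <- nrow(A)
  if (L > 1L && flip_rate > 0) {
    withr::with_seed(as.integer(seed), {
      ut <- upper.tri(A)
      flips <- runif(sum(ut)) < flip_rate
      vals <- A[ut]
      vals[flips] <- 1 - vals[flips]
      A[ut] <- vals
      A[lower.tri(A)] <- t(A)[lower.tri(A)]
    })
  }
  new("ContactMap", adjacency = A, mode = cmap@mode,
      threshold = cmap@threshold)
}

#' Read a single-chain PDB file into residue coordinates
#'
#' Parses a PDB-format file via \pkg{bio3d}, selects one chain, keeps the
#' first model only, resolves alternate locations by highest occupancy
#' (first on ties), and remaps author numbering (gaps, insertion codes) to
#' a dense 1-based residue index; the mapping is returned as an attribute.
#' Non-standard residues map through their one-letter code where \pkg{bio3d}
#' provides one, else to the gap symbol.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier (default first chain present).
#' @return A `residueCoordinates` object with attribute `author_numbering`.
#' @export
readPDBCoordinates <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  atom <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(atom)) stop("no ATOM records in ", path)
  if (is.null(chain)) chain <- atom$chain[1]
  atom <- atom[atom$chain == chain, , drop = FALSE]
  if (!nrow(atom)) stop(sprintf("no atoms for chain %s in %s", chain, path))
  ## altloc: keep blank or, per residue+atom, the highest occupancy (first on tie)
  key <- paste(atom$resno, atom$insert, atom$elety)
  ord <- order(key, -replace(atom$o, is.na(atom$o), 1))
  atom <- atom[ord, , drop = FALSE]
  atom <- atom[!duplicated(paste(atom$resno, atom$insert, atom$elety)), ,
               drop = FALSE]
  reskey <- paste(atom$resno, atom$insert)
  ures <- unique(reskey)
  atoms <- vector("list", length(ures))
  seqChars <- character(length(ures))
  for (i in seq_along(ures)) {
    sub <- atom[reskey == ures[i], , drop = FALSE]
    m <- as.matrix(sub[, c("x", "y", "z")])
    rownames(m) <- sub$elety
    atoms[[i]] <- m
    one <- suppressWarnings(bio3d::aa321(sub$resid[1]))
    seqChars[i] <- if (is.na(one) || one == "X") GAP_SYMBOL else one
  }
  out <- residueCoordinates(paste(seqChars, collapse = ""), atoms, chain)
  attr(out, "author_numbering") <- ures
  out
}

#' Write a contact map as a plain-text edge list
#'
#' One `i j` pair per line with `i < j`, 0-based residue indices.
#'
#' @param cmap A [ContactMap-class].
#' @param path Output file path.
#' @export
writeEdgeList <- function(cmap, path) {
  A <- cmap@adjacency
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L)
  df <- df[order(df$i, df$j), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
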