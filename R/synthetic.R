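#' @include AllClasses.R utils.R contacts.R ontology.R
NULL

## Geometry constants for the bead-chain model: the canonical CA-CA virtual
## bond, and the steric floor between non-adjacent residues. Internal clash
## checks use a small safety margin above the 4 A contract so that floating
## point never lands below it.
BOND_LEN <- 3.8
CLASH_MIN <- 4.0
CLASH_SAFE <- 4.05

#' Specification of one planted functional motif
#'
#' A motif is a set of residues that the generator pulls into mutual
#' spatial proximity (pairwise within `spatial_radius`), emulating a
#' site-specific function such as a ligand-binding or catalytic site.
#' `sequence_dispersion` controls whether the motif residues are close in
#' sequence (`local`) or include at least one pair at least
#' `min(50, L/2)` positions apart (`long_range`).
#'
#' @param motif_size Number of motif residues (>= 2).
#' @param spatial_radius Pairwise distance bound in Angstrom; must stay
#'   below the downstream contact threshold so planted motifs are
#'   guaranteed mutually in contact.
#' @param sequence_dispersion `"local"` or `"long_range"`.
#' @return A `MotifSpec` list.
#' @export
motifSpec <- function(motif_size, spatial_radius = 8,
                      sequence_dispersion = c("local", "long_range")) {
  sequence_dispersion <- match.arg(sequence_dispersion)
  stopifnot(motif_size >= 2L, spatial_radius > CLASH_SAFE)
  structure(list(motif_size = as.integer(motif_size),
                 spatial_radius = spatial_radius,
                 sequence_dispersion = sequence_dispersion),
            class = "MotifSpec")
}

#' Configuration of the synthetic dataset generator
#'
#' The generator emulates the study conditions of the desk-scale
#' experiments: bead-chain structures of 60-120 residues, a handful of
#' function terms whose planting frequencies span common and rare labels
#' (a >= 5x expected spread, so term-selection and class-weight logic is
#' exercised), planted spatially clustered motifs that determine the
#' labels, and symmetric label-flip noise.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Inclusive (min, max) residue counts; min >= 2.
#' @param n_terms Number of function terms (>= 1).
#' @param motif_library List of [motifSpec()] objects, one per term.
#'   Default: sizes spanning 6-10 residues, all `local`.
#' @param planting_probs Per-term probability that a protein carries the
#'   motif. Default: geometric spread from 0.03 to 0.5.
#' @param label_noise_rate Symmetric flip probability in `[0, 0.5)`.
#' @param contact_mode,contact_threshold Downstream contact definition; the
#'   motif radii must stay below the threshold.
#' @param seed Integer root seed.
#' @return A `SyntheticConfig` list.
#' @export
syntheticConfig <- function(n_proteins = 300L, length_range = c(60L, 120L),
                            n_terms = 6L, motif_library = NULL,
                            planting_probs = NULL,
                            label_noise_rate = 0.05,
                            contact_mode = "CA_CA",
                            contact_threshold = 10, seed = 1L) {
  stopifnot(length_range[1] >= 2L, length_range[1] <= length_range[2],
            label_noise_rate >= 0, label_noise_rate < 0.5, n_terms >= 1L)
  if (is.null(motif_library)) {
    sizes <- round(seq(6L, 10L, length.out = n_terms))
    motif_library <- lapply(sizes, function(s) motifSpec(s, 8, "local"))
  }
  stopifnot(length(motif_library) == n_terms)
  for (m in motif_library)
    if (m$spatial_radius >= contact_threshold)
      stop("motif spatial_radius must be below the contact threshold")
  if (is.null(planting_probs)) {
    planting_probs <- if (n_terms == 1L) 0.3 else
      0.03 * (0.5 / 0.03)^((seq_len(n_terms) - 1) / (n_terms - 1))
  }
  stopifnot(length(planting_probs) == n_terms,
            all(planting_probs > 0), all(planting_probs < 1))
  list(n_proteins = as.integer(n_proteins),
       length_range = as.integer(length_range),
       n_terms = as.integer(n_terms), motif_library = motif_library,
       planting_probs = planting_probs,
       label_noise_rate = label_noise_rate,
       contact_mode = contact_mode, contact_threshold = contact_threshold,
       seed = as.integer(seed))
}

## minimum distance from point p to a set of points (matrix), Inf if empty
minDistTo <- function(p, pts) {
  if (is.null(pts) || nrow(pts) == 0L) return(Inf)
  sqrt(min(colSums((t(pts) - p)^2)))
}

## candidate position for residue `idx` must keep >= CLASH_SAFE from every
## already-placed residue except its sequence neighbours idx-1, idx+1
clashOK <- function(cand, idx, xyz, placed) {
  others <- placed[abs(placed - idx) > 1L]
  minDistTo(cand, xyz[others, , drop = FALSE]) >= CLASH_SAFE
}

## unconstrained self-avoiding extension walk from residue `fromIdx`
## in direction step = +1 (suffix) or -1 (prefix)
extendWalk <- function(xyz, placed, fromIdx, toIdx, step) {
  idxs <- seq(fromIdx + step, toIdx, by = step)
  prevDir <- NULL
  for (i in idxs) {
    prev <- xyz[i - step, ]
    ok <- FALSE
    for (try in seq_len(80L)) {
      d <- if (is.null(prevDir)) unitVec(rnorm(3)) else
        unitVec(prevDir + rnorm(3) * (0.7 + 0.05 * try))
      cand <- prev + BOND_LEN * d
      if (clashOK(cand, i, xyz, placed)) { ok <- TRUE; break }
    }
    if (!ok) return(NULL)
    xyz[i, ] <- cand
    placed <- c(placed, i)
    prevDir <- d
  }
  list(xyz = xyz, placed = placed)
}

## fixed-step bridge from placed residue aIdx to placed residue bIdx,
## filling the free residues strictly between them. The walk aims at a
## waypoint one bond outside the crowded neighbourhood of the target pin
## so that it approaches the motif cluster from its accessible side.
bridgeWalk <- function(xyz, placed, aIdx, bIdx, outerTries = 40L) {
  g <- bIdx - aIdx                      # number of bonds
  if (g < 2L) stop("bridge needs at least one free residue")
  b <- xyz[bIdx, ]
  others <- placed[placed != bIdx]
  nearB <- others[colSums((t(xyz[others, , drop = FALSE]) - b)^2) < 81]
  approach <- if (length(nearB))
    unitVec(b - colMeans(xyz[nearB, , drop = FALSE])) else unitVec(rnorm(3))
  for (outer in seq_len(outerTries)) {
    res <- bridgeOnce(xyz, placed, aIdx, bIdx,
                      unitVec(approach + rnorm(3) * 0.25 * (outer - 1) /
                                outerTries))
    if (!is.null(res)) return(res)
  }
  NULL
}

bridgeOnce <- function(xyz, placed, aIdx, bIdx, approach) {
  g <- bIdx - aIdx
  free <- seq(aIdx + 1L, bIdx - 1L)
  b <- xyz[bIdx, ]
  wp <- b + 1.2 * BOND_LEN * approach   # approach waypoint outside the crowd
  q <- xyz[aIdx, ]
  prevDir <- NULL
  if (g > 2L) {
    for (j in seq_len(g - 2L)) {
      i <- free[j]
      k <- g - j                        # bonds remaining after this residue
      ok <- FALSE
      for (try in seq_len(70L)) {
        remT <- l2norm(wp - q)
        urgency <- remT / (BOND_LEN * max(k - 1L, 1L))
        wB <- 1.3 * urgency + 0.06 * try
        d <- unitVec(wB * unitVec(wp - q) +
                       (if (k > 2L) 0.45 * approach else 0) +
                       (if (is.null(prevDir)) 0 else 0.3 * prevDir) +
                       rnorm(3) * 0.8)
        cand <- q + BOND_LEN * d
        rem <- l2norm(b - cand)
        upper <- if (k == 2L) 2 * BOND_LEN - 0.35 else BOND_LEN * k - 0.2
        if (rem <= upper && clashOK(cand, i, xyz, placed)) { ok <- TRUE; break }
      }
      if (!ok) return(NULL)
      xyz[i, ] <- cand
      placed <- c(placed, i)
      prevDir <- d
      q <- cand
    }
  }
  ## last free residue: intersection circle of the two 3.8 A spheres
  ## around its neighbours; take the best-clearance point on the circle
  i <- free[g - 1L]
  dvec <- b - q
  dn <- l2norm(dvec)
  if (dn > 2 * BOND_LEN - 0.05 || dn < 1e-6) return(NULL)
  mid <- q + dvec / 2
  circR <- sqrt(BOND_LEN^2 - (dn / 2)^2)
  axis <- unitVec(dvec)
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitVec(pracmaCross(axis, ref))
  v <- pracmaCross(axis, u)
  othersI <- placed[abs(placed - i) > 1L]
  best <- NULL; bestClear <- 0
  for (phi in seq(0, 2 * pi, length.out = 49L)[-49L] + runif(1, 0, 0.13)) {
    cand <- mid + circR * (cos(phi) * u + sin(phi) * v)
    clear <- minDistTo(cand, xyz[othersI, , drop = FALSE])
    if (clear > bestClear) { bestClear <- clear; best <- cand }
  }
  if (bestClear < CLASH_SAFE) return(NULL)
  xyz[i, ] <- best
  placed <- c(placed, i)
  list(xyz = xyz, placed = placed)
}

## Deterministic arc bridge: the g-1 free residues between two placed
## residues lie on a circular arc of g equal 3.8 A chords in the plane
## spanned by the endpoint axis and a bulge normal; a fan of candidate
## normals (preferring the outward-facing one) is tried for clearance.
arcBridge <- function(xyz, placed, aIdx, bIdx, outwardCtr) {
  g <- bIdx - aIdx
  a <- xyz[aIdx, ]; b <- xyz[bIdx, ]
  d <- l2norm(b - a)
  if (d >= BOND_LEN * g * 0.995 || d < 0.4) return(NULL)
  ## solve the per-chord arc angle theta: chord(theta) = d, monotone
  lo <- 1e-6; hi <- 2 * pi / g - 1e-6
  chordAt <- function(th) 2 * (BOND_LEN / 2) * sin(g * th / 2) / sin(th / 2)
  if (chordAt(hi) > d) return(NULL)
  for (it in 1:60) {
    midTh <- (lo + hi) / 2
    if (chordAt(midTh) > d) lo <- midTh else hi <- midTh
  }
  theta <- (lo + hi) / 2
  R <- (BOND_LEN / 2) / sin(theta / 2)
  phi <- g * theta
  h <- R * cos(phi / 2)                  # signed center offset from chord
  e <- unitVec(b - a)
  mid <- (a + b) / 2
  out0 <- mid - outwardCtr
  out0 <- out0 - sum(out0 * e) * e
  if (l2norm(out0) < 1e-6) { out0 <- rnorm(3); out0 <- out0 - sum(out0 * e) * e }
  n0 <- unitVec(out0)
  n90 <- pracmaCross(e, n0)
  jit <- runif(1, -0.12, 0.12)
  for (ang in c(0, 0.4, -0.4, 0.8, -0.8, 1.2, -1.2, 1.6, -1.6, 2.1,
                -2.1, 2.6, -2.6, pi) + jit) {
    n <- cos(ang) * n0 + sin(ang) * n90
    ctr <- mid - h * n
    alphaA <- atan2(-d / 2, h)
    pts <- t(vapply(seq_len(g - 1L), function(j) {
      al <- alphaA + j * theta
      ctr + R * (cos(al) * n + sin(al) * e)
    }, numeric(3)))
    okAll <- TRUE
    tmp <- placed
    for (j in seq_len(g - 1L)) {
      if (!clashOK(pts[j, ], aIdx + j, xyz, tmp)) { okAll <- FALSE; break }
      xyz[aIdx + j, ] <- pts[j, ]
      tmp <- c(tmp, aIdx + j)
    }
    if (okAll) return(list(xyz = xyz, placed = tmp))
    xyz[aIdx + seq_len(g - 1L), ] <- NA_real_
  }
  NULL
}

pracmaCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Sample a self-avoiding bead chain
#'
#' A persistent random walk with fixed 3.8 Angstrom virtual bonds between
#' consecutive residues and a steric contract: no two non-adjacent residues
#' come closer than 4 Angstrom. Deterministic given `seed`.
#'
#' @param length Residue count (>= 2).
#' @param seed Integer seed.
#' @return length x 3 coordinate matrix.
#' @export
#' @examples
#' xyz <- sampleChain(10, seed = 1)
#' sqrt(sum((xyz[2, ] - xyz[1, ])^2))  # exactly 3.8
sampleChain <- function(length, seed) {
  if (length < 2L) stop("chain length must be at least 2")
  withr::with_seed(as.integer(seed), sampleChainNoSeed(length))
}

sampleChainNoSeed <- function(length, maxRestarts = 50L) {
  for (attempt in seq_len(maxRestarts)) {
    xyz <- matrix(NA_real_, length, 3L)
    xyz[1L, ] <- 0
    xyz[2L, ] <- BOND_LEN * unitVec(rnorm(3))
    if (length == 2L) return(xyz)
    res <- extendWalk(xyz, c(1L, 2L), 2L, length, +1L)
    if (!is.null(res)) return(res$xyz)
  }
  stop("generation-failure: self-avoiding walk did not complete after ",
       maxRestarts, " restarts")
}

## Relax `m` target points to mutual distances within
## [CLASH_SAFE, 0.97 * radius]; NULL if infeasible.
motifTargets <- function(m, radius, maxIter = 400L, restarts = 10L) {
  cap <- 0.97 * radius
  if (m == 1L) return(matrix(0, 1L, 3L))
  for (rs in seq_len(restarts)) {
    pts <- matrix(rnorm(3 * m), m, 3L) * cap * 0.35
    for (iter in seq_len(maxIter)) {
      D <- as.matrix(stats::dist(pts))
      diag(D) <- NA
      tooClose <- which(D < CLASH_SAFE, arr.ind = TRUE)
      tooFar <- which(D > cap, arr.ind = TRUE)
      if (!nrow(tooClose) && !nrow(tooFar)) return(pts)
      adj <- matrix(0, m, 3L)
      if (nrow(tooClose)) {
        for (r in seq_len(nrow(tooClose))) {
          i <- tooClose[r, 1]; j <- tooClose[r, 2]
          if (i >= j) next
          ax <- unitVec(pts[i, ] - pts[j, ])
          push <- (CLASH_SAFE + 0.08 - D[i, j]) / 2
          adj[i, ] <- adj[i, ] + ax * push
          adj[j, ] <- adj[j, ] - ax * push
        }
      }
      if (nrow(tooFar)) {
        for (r in seq_len(nrow(tooFar))) {
          i <- tooFar[r, 1]; j <- tooFar[r, 2]
          if (i >= j) next
          ax <- unitVec(pts[i, ] - pts[j, ])
          pull <- (D[i, j] - cap + 0.08) / 2
          adj[i, ] <- adj[i, ] - ax * pull
          adj[j, ] <- adj[j, ] + ax * pull
        }
      }
      ## damped, step-capped update; restart if the relaxation blows up
      stepN <- sqrt(rowSums(adj^2))
      big <- stepN > 1
      if (any(big)) adj[big, ] <- adj[big, ] / stepN[big]
      pts <- pts + 0.65 * adj
      if (any(!is.finite(pts))) break
    }
  }
  NULL
}

## Compact self-avoiding path for a local motif: m points with exact
## 3.8 A consecutive bonds, non-adjacent pairs >= CLASH_SAFE apart, and
## every pair within `cap`. The motif then occupies consecutive sequence
## positions, so it needs no internal chain bridges.
compactPath <- function(m, cap, maxIter = 600L, restarts = 25L) {
  if (m == 1L) return(matrix(0, 1L, 3L))
  for (rs in seq_len(restarts)) {
    pts <- matrix(0, m, 3L)
    d <- unitVec(rnorm(3))
    for (i in seq_len(m - 1L)) {
      d <- unitVec(d * 0.3 + rnorm(3))
      pts[i + 1L, ] <- pts[i, ] + BOND_LEN * d
    }
    for (iter in seq_len(maxIter)) {
      D <- as.matrix(stats::dist(pts))
      sep <- abs(row(D) - col(D))
      adj <- matrix(0, m, 3L)
      close <- which(sep > 1L & upper.tri(D) & D < CLASH_SAFE, arr.ind = TRUE)
      far <- which(sep >= 1L & upper.tri(D) & D > cap, arr.ind = TRUE)
      if (nrow(close)) for (r in seq_len(nrow(close))) {
        i <- close[r, 1]; j <- close[r, 2]
        ax <- unitVec(pts[i, ] - pts[j, ])
        push <- (CLASH_SAFE + 0.08 - D[i, j]) / 2
        adj[i, ] <- adj[i, ] + ax * push
        adj[j, ] <- adj[j, ] - ax * push
      }
      if (nrow(far)) for (r in seq_len(nrow(far))) {
        i <- far[r, 1]; j <- far[r, 2]
        ax <- unitVec(pts[i, ] - pts[j, ])
        pull <- (D[i, j] - cap + 0.08) / 2
        adj[i, ] <- adj[i, ] - ax * pull
        adj[j, ] <- adj[j, ] + ax * pull
      }
      stepN <- sqrt(rowSums(adj^2))
      big <- stepN > 0.8
      if (any(big)) adj[big, ] <- 0.8 * adj[big, ] / stepN[big]
      pts <- pts + 0.6 * adj
      if (any(!is.finite(pts))) break
      ## project bonds back to exact length
      for (s in 1:6) for (i in seq_len(m - 1L)) {
        v <- pts[i + 1L, ] - pts[i, ]
        dn <- l2norm(v)
        corr <- (dn - BOND_LEN) / dn / 2
        pts[i, ] <- pts[i, ] + v * corr
        pts[i + 1L, ] <- pts[i + 1L, ] - v * corr
      }
      ## convergence check on the full contract
      D <- as.matrix(stats::dist(pts))
      sep <- abs(row(D) - col(D))
      bondErr <- max(abs(D[cbind(seq_len(m - 1L), seq(2L, m))] - BOND_LEN))
      nonAdjMin <- if (m > 2L) min(D[sep > 1L]) else Inf
      allMax <- max(D[sep >= 1L])
      if (bondErr < 1e-4 && nonAdjMin >= CLASH_SAFE - 0.01 &&
          allMax <= cap + 0.01) {
        ## polish bonds tight
        for (s in 1:40) for (i in seq_len(m - 1L)) {
          v <- pts[i + 1L, ] - pts[i, ]
          dn <- l2norm(v)
          corr <- (dn - BOND_LEN) / dn / 2
          pts[i, ] <- pts[i, ] + v * corr
          pts[i + 1L, ] <- pts[i + 1L, ] - v * corr
        }
        D <- as.matrix(stats::dist(pts))
        if ((m == 2L || min(D[sep > 1L]) >= CLASH_SAFE - 0.04) &&
            max(D[sep >= 1L]) <= cap + 0.02 &&
            max(abs(D[cbind(seq_len(m - 1L), seq(2L, m))] - BOND_LEN)) < 1e-6)
          return(pts)
      }
    }
  }
  NULL
}

## Order target points along a greedy nearest-neighbour path (starting from
## an extremal point) so that sequence-consecutive pinned residues are
## spatially adjacent and the connecting bridges stay short.
orderTargetsNN <- function(pts) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  ctr <- colMeans(pts)
  cur <- which.max(rowSums(sweep(pts, 2L, ctr)^2))
  path <- cur
  left <- setdiff(seq_len(n), cur)
  while (length(left)) {
    d <- colSums((t(pts[left, , drop = FALSE]) - pts[cur, ])^2)
    cur <- left[which.min(d)]
    path <- c(path, cur)
    left <- setdiff(left, cur)
  }
  pts[path, , drop = FALSE]
}

## choose motif residue indices inside a window; spacing >= 3 so that no
## two pinned residues are chain neighbours (bonds are exactly 3.8 A while
## pinned pairs must stay >= 4 A apart)
motifIndicesInWindow <- function(winStart, winLen, spec, L) {
  m <- spec$motif_size
  first <- winStart
  last <- winStart + winLen - 1L
  if (spec$sequence_dispersion == "long_range") {
    if (m == 2L) return(c(first, last))
    inner <- as.integer(round(seq(first, last, length.out = m)))
    for (k in 2:m) inner[k] <- max(inner[k], inner[k - 1L] + 3L)
    if (inner[m] > last || (m > 2L && last - inner[m - 1L] < 3L))
      return(NULL)
    inner[m] <- last
    sort(unique(inner))
  } else {
    ## local motifs occupy consecutive residues (a compact segment)
    idx <- first + seq_len(m) - 1L
    if (idx[m] > last) return(NULL)
    idx
  }
}

windowLength <- function(spec, L) {
  if (spec$sequence_dispersion == "long_range")
    max(3L * spec$motif_size, min(50L, as.integer(L) %/% 2L) + 1L)
  else spec$motif_size
}

WINDOW_GAP <- 8L

## Total chain length needed by a set of motif windows (inter-window gaps
## plus margins at the chain ends).
windowsNeed <- function(L, specs) {
  wl <- vapply(specs, windowLength, integer(1), L = L)
  sum(wl) + WINDOW_GAP * (length(specs) - 1L) + 4L
}

## Allocate disjoint sequence windows (gap >= WINDOW_GAP between windows,
## >= 2 from the chain ends) for the planted motifs; NULL if they don't fit.
allocateWindows <- function(L, specs) {
  k <- length(specs)
  wl <- vapply(specs, windowLength, integer(1), L = L)
  need <- sum(wl) + WINDOW_GAP * (k - 1L) + 4L
  if (need > L) return(NULL)
  slack <- L - need
  cuts <- if (k >= 1L) sort(sample.int(slack + 1L, k + 1L,
                                       replace = TRUE) - 1L) else integer(0)
  gaps <- diff(c(0L, cuts[seq_len(k)]))
  extra <- c(gaps, slack - sum(gaps))
  starts <- integer(k)
  pos <- 3L + extra[1L]
  for (i in seq_len(k)) {
    starts[i] <- pos
    pos <- pos + wl[i] + WINDOW_GAP + extra[i + 1L]
  }
  list(starts = starts, lengths = wl)
}

## Build a full chain with all motif residues pinned to relaxed targets.
## Returns list(xyz, indices = list per motif) or NULL on failure.
buildPlantedChain <- function(L, specs) {
  k <- length(specs)
  if (k == 0L) return(list(xyz = sampleChainNoSeed(L), indices = list()))
  win <- allocateWindows(L, specs)
  if (is.null(win)) return(NULL)
  ord <- order(win$starts)
  idxSets <- vector("list", k)
  for (i in seq_len(k)) {
    idxSets[[i]] <- motifIndicesInWindow(win$starts[i], win$lengths[i],
                                         specs[[i]], L)
    if (is.null(idxSets[[i]]) ||
        length(idxSets[[i]]) != specs[[i]]$motif_size) return(NULL)
  }
  ## targets per motif, then place the motif centers along a 3D path whose
  ## spacing respects the chain-reach between consecutive pinned residues
  targets <- vector("list", k)
  for (i in seq_len(k)) {
    if (specs[[i]]$sequence_dispersion == "local") {
      targets[[i]] <- compactPath(specs[[i]]$motif_size,
                                  0.97 * specs[[i]]$spatial_radius)
      if (is.null(targets[[i]])) return(NULL)
    } else {
      targets[[i]] <- motifTargets(specs[[i]]$motif_size,
                                   specs[[i]]$spatial_radius)
      if (is.null(targets[[i]])) return(NULL)
      targets[[i]] <- orderTargetsNN(targets[[i]])
    }
  }
  centers <- matrix(0, k, 3L)
  for (i in seq_len(k)[-1L]) {
    gapSeq <- min(idxSets[[i]]) - max(idxSets[[i - 1L]])
    delta <- min(20, 0.62 * BOND_LEN * gapSeq)
    centers[i, ] <- centers[i - 1L, ] + delta * unitVec(rnorm(3))
  }
  xyz <- matrix(NA_real_, L, 3L)
  placed <- integer(0)
  for (i in seq_len(k)) {
    pts <- sweep(targets[[i]], 2L, centers[i, ], "+")
    ## within-motif geometry is pre-validated; clash-check only against
    ## residues of previously placed motifs
    for (j in seq_along(idxSets[[i]])) {
      if (!clashOK(pts[j, ], idxSets[[i]][j], xyz, placed)) return(NULL)
    }
    xyz[idxSets[[i]], ] <- pts
    placed <- c(placed, idxSets[[i]])
  }
  pinned <- sort(placed)
  ## reach feasibility between consecutive pinned residues (gap-1 pairs are
  ## consecutive residues of a local segment, already bonded at 3.8 A)
  for (j in seq_len(length(pinned) - 1L)) {
    a <- pinned[j]; b <- pinned[j + 1L]
    if (b - a == 1L) next
    if (l2norm(xyz[b, ] - xyz[a, ]) > BOND_LEN * (b - a) - 0.3) return(NULL)
  }
  ## which motif each pinned residue belongs to, for arch bridges
  motifOf <- integer(L)
  for (i in seq_len(k)) motifOf[idxSets[[i]]] <- i
  ## bridges between consecutive pinned residues: deterministic arc first,
  ## stochastic walk as fallback
  for (j in seq_len(length(pinned) - 1L)) {
    a <- pinned[j]; bb <- pinned[j + 1L]
    if (bb - a == 1L) next
    ctr <- if (motifOf[a] > 0L) centers[motifOf[a], ] else
      if (motifOf[bb] > 0L) centers[motifOf[bb], ] else colMeans(rbind(
        xyz[a, ], xyz[bb, ]))
    res <- arcBridge(xyz, placed, a, bb, ctr)
    if (is.null(res)) res <- bridgeWalk(xyz, placed, a, bb)
    if (is.null(res)) return(NULL)
    xyz <- res$xyz; placed <- res$placed
  }
  ## prefix and suffix free walks
  if (pinned[1L] > 1L) {
    res <- extendWalk(xyz, placed, pinned[1L], 1L, -1L)
    if (is.null(res)) return(NULL)
    xyz <- res$xyz; placed <- res$placed
  }
  if (max(pinned) < L) {
    res <- extendWalk(xyz, placed, max(pinned), L, +1L)
    if (is.null(res)) return(NULL)
    xyz <- res$xyz; placed <- res$placed
  }
  list(xyz = xyz, indices = idxSets)
}

#' Plant a spatially clustered motif into a bead chain
#'
#' Selects motif residue indices according to the spec's sequence
#' dispersion, pins them to mutually proximal target positions (pairwise
#' within `spec$spatial_radius`, centred on the selected residues'
#' original centroid), and rebuilds the connecting chain segments as
#' fixed-bond-length self-avoiding bridges, so that all bonds remain
#' exactly 3.8 Angstrom and the steric contract is preserved.
#'
#' @param coords L x 3 coordinate matrix (e.g. from [sampleChain()]).
#' @param spec A [motifSpec()].
#' @param seed Integer seed.
#' @return List with `coords` (modified matrix) and `indices` (1-based
#'   motif residue indices).
#' @export
plantMotif <- function(coords, spec, seed) {
  L <- nrow(coords)
  if (spec$motif_size > L) stop("motif_size exceeds chain length")
  withr::with_seed(as.integer(seed), {
    for (attempt in seq_len(30L)) {
      res <- buildPlantedChain(L, list(spec))
      if (!is.null(res)) {
        centerOld <- colMeans(coords[res$indices[[1L]], , drop = FALSE])
        shift <- centerOld -
          colMeans(res$xyz[res$indices[[1L]], , drop = FALSE])
        return(list(coords = sweep(res$xyz, 2L, shift, "+"),
                    indices = res$indices[[1L]]))
      }
    }
    stop("generation-failure: could not plant a motif of size ",
         spec$motif_size, " in a chain of length ", L,
         " after 30 attempts")
  })
}

## Term-specific signature: one strictly conserved residue type per term
## (emulating key catalytic/binding residues), cycling the standard
## alphabet. Decoy placement keeps overall composition uninformative.
signatureAlphabets <- function(n_terms) {
  as.list(STANDARD_AA[(seq_len(n_terms) - 1L) %% length(STANDARD_AA) + 1L])
}

#' Generate a synthetic planted-motif dataset
#'
#' For each protein: a self-avoiding bead chain is generated; each term's
#' motif is planted independently with its configured probability (motifs
#' that cannot jointly fit the chain are dropped at random); the residue
#' sequence is uniform over the 20 standard amino acids except that motif
#' positions draw from a small term-specific signature alphabet -- and, in
#' proteins where a term's motif is absent, the same number of decoy
#' positions draw from the same alphabet at scattered (non-clustered)
#' positions, so sequence composition alone carries no label signal and
#' only the spatial clustering in the contact map does. Observed labels
#' are the planted indicators with symmetric flip noise; planted truth and
#' motif indices are retained on each record for saliency evaluation.
#'
#' @param config From [syntheticConfig()].
#' @return List with `records` (list of [ProteinRecord-class]),
#'   `labelSpace` (a [LabelSpace-class] built from the observed labels),
#'   and `config`.
#' @export
generateDataset <- function(config) {
  termIds <- sprintf("SYN:%04d", seq_len(config$n_terms))
  sig <- signatureAlphabets(config$n_terms)
  withr::with_seed(config$seed, {
    records <- vector("list", config$n_proteins)
    for (p in seq_len(config$n_proteins)) {
      lens <- seq(config$length_range[1], config$length_range[2])
      L <- lens[sample.int(length(lens), 1L)]
      planted <- runif(config$n_terms) < config$planting_probs
      ## drop motifs at random until the joint window allocation fits
      repeat {
        specs <- config$motif_library[planted]
        if (!sum(planted)) break
        if (windowsNeed(L, specs) <= L) break
        on <- which(planted)
        planted[sample(on, 1L)] <- FALSE
      }
      built <- NULL
      for (attempt in seq_len(40L)) {
        built <- buildPlantedChain(L, config$motif_library[planted])
        if (!is.null(built)) break
      }
      if (is.null(built))
        stop("generation-failure: protein ", p, " (length ", L,
             ", ", sum(planted), " motifs) could not be built")
      motifIdx <- setNames(built$indices, termIds[planted])
      ## sequence: uniform background + signature/decoy positions
      seqChars <- sample(STANDARD_AA, L, replace = TRUE)
      used <- unlist(built$indices)
      for (j in seq_len(config$n_terms)) {
        if (planted[j]) {
          pos <- motifIdx[[termIds[j]]]
        } else {
          freePos <- setdiff(seq_len(L), used)
          m <- config$motif_library[[j]]$motif_size
          pos <- sample(freePos, min(m, length(freePos)))
          used <- c(used, pos)
        }
        seqChars[pos] <- sample(sig[[j]], length(pos), replace = TRUE)
      }
      cmap <- buildContactMap(built$xyz, config$contact_mode,
                              config$contact_threshold)
      truth <- as.numeric(planted)
      noise <- runif(config$n_terms) < config$label_noise_rate
      observed <- ifelse(noise, 1 - truth, truth)
      records[[p]] <- new("ProteinRecord",
        id = sprintf("P%04d", p),
        sequence = paste(seqChars, collapse = ""),
        coords = built$xyz, cmap = cmap,
        labels = setNames(observed, termIds),
        plantedLabels = setNames(truth, termIds),
        motifIndices = motifIdx)
    }
    counts <- colSums(do.call(rbind, lapply(records, function(r) r@labels)))
    if (any(counts == 0))
      stop("a term received no positive observed labels; ",
           "increase n_proteins or the planting probabilities")
    N <- length(records)
    space <- new("LabelSpace", termIds = termIds, termNames = termIds,
                 counts = as.numeric(counts),
                 ic = informationContent(counts / N),
                 weights = N / as.numeric(counts), nProteins = N)
    list(records = records, labelSpace = space, config = config)
  })
}

#' Label matrices of a record list
#'
#' @param records List of [ProteinRecord-class] objects.
#' @param space A [LabelSpace-class].
#' @param truth Use the planted ground-truth labels instead of the
#'   observed (noisy) ones.
#' @return N x T binary matrix.
#' @export
labelMatrix <- function(records, space, truth = FALSE) {
  out <- do.call(rbind, lapply(records, function(r) {
    v <- if (truth) r@plantedLabels else r@labels
    v <- v[space@termIds]
    v[is.na(v)] <- 0
    as.numeric(v)
  }))
  dimnames(out) <- list(vapply(records, function(r) r@id, character(1)),
                        space@termIds)
  out
}

#' Write a synthetic dataset to disk
#'
#' Writes sequences as FASTA, per-protein coordinate tables (0-based
#' residue index, x, y, z, whitespace-delimited), observed labels and
#' planted motif indices as TSVs, and a JSON manifest of the
#' configuration.
#'
#' @param dataset From [generateDataset()].
#' @param dir Output directory (created if needed).
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "coords"), showWarnings = FALSE)
  recs <- dataset$records
  seqs <- Biostrings::AAStringSet(
    setNames(vapply(recs, function(r) r@sequence, character(1)),
             vapply(recs, function(r) r@id, character(1))))
  Biostrings::writeXStringSet(seqs, file.path(dir, "sequences.fasta"))
  lab <- list(); mot <- list()
  for (r in recs) {
    df <- data.frame(idx = seq_len(nrow(r@coords)) - 1L,
                     x = r@coords[, 1], y = r@coords[, 2],
                     z = r@coords[, 3])
    write.table(format(df, digits = 8), file.path(dir, "coords",
                paste0(r@id, ".xyz")), sep = " ", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    pos <- names(r@labels)[r@labels == 1]
    if (length(pos))
      lab[[r@id]] <- data.frame(protein_id = r@id, term_id = pos)
    for (t in names(r@motifIndices))
      mot[[paste(r@id, t)]] <- data.frame(
        protein_id = r@id, term_id = t,
        residues = paste(r@motifIndices[[t]] - 1L, collapse = ","))
  }
  write.table(do.call(rbind, lab), file.path(dir, "labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(do.call(rbind, mot), file.path(dir, "motifs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- dataset$config
  manifest$motif_library <- lapply(manifest$motif_library, unclass)
  manifest$package_version <- as.character(packageVersion("strucfun"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
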