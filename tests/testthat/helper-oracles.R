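# Independent reference implementations ("oracles") used to check package
# operations. These deliberately share no code with the package internals.

# Exhaustive enumeration of all global alignments with affine gaps (a gap
# of length L costs open + L * extend). Exponential; for short sequences.
oracle_align_score <- function(a, b, submat, gap_open = 10,
                               gap_extend = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  la <- length(A); lb <- length(B)
  rec <- function(i, j, state) {
    if (i > la && j > lb) return(0)
    best <- -Inf
    if (i <= la && j <= lb)
      best <- max(best, submat[A[i], B[j]] + rec(i + 1, j + 1, 0L))
    if (i <= la)
      best <- max(best, -(gap_extend + if (state != 1L) gap_open else 0) +
                    rec(i + 1, j, 1L))
    if (j <= lb)
      best <- max(best, -(gap_extend + if (state != 2L) gap_open else 0) +
                    rec(i, j + 1, 2L))
    best
  }
  rec(1, 1, 0L)
}

# Plain queue-based breadth-first-search connected components over the
# full distance matrix.
oracle_bfs_components <- function(pts, r) {
  n <- nrow(pts)
  dmat <- as.matrix(dist(pts))
  adj <- dmat <= r
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Partition labels canonicalized by first appearance, so two labelings of
# the same partition compare equal.
canonical <- function(memb) match(memb, unique(memb))

# Naive per-center nonpolar:polar patch scan (no vectorization, no shared
# helpers): returns the max ratio and its center.
oracle_npp_scan <- function(structure, atom_sasa, patch_radius = 13,
                            cap = 1e3) {
  at <- structure$atoms
  n <- nrow(at)
  best <- -Inf
  best_center <- NA_integer_
  for (i in seq_len(n)) {
    if (atom_sasa[i] <= 0) next
    np <- 0; po <- 0
    for (j in seq_len(n)) {
      dx <- at$x[i] - at$x[j]; dy <- at$y[i] - at$y[j]; dz <- at$z[i] - at$z[j]
      if (sqrt(dx * dx + dy * dy + dz * dz) <= patch_radius) {
        if (at$polarity[j] == "nonpolar") np <- np + atom_sasa[j]
        else po <- po + atom_sasa[j]
      }
    }
    ratio <- if (po > 0) np / po else cap
    if (ratio > best) {
      best <- ratio
      best_center <- i
    }
  }
  list(value = best, center_atom = best_center)
}

# Point-in-any-sphere burial test used to verify SASA against direct
# geometry on small systems.
oracle_exposed_fraction <- function(i, xyz, rexp, n_dirs = 2000) {
  set.seed(1234)
  dirs <- matrix(rnorm(3 * n_dirs), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- sweep(dirs * rexp[i], 2, xyz[i, ], "+")
  exposed <- rep(TRUE, n_dirs)
  for (j in seq_len(nrow(xyz))) {
    if (j == i) next
    d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
      (pts[, 3] - xyz[j, 3])^2
    exposed <- exposed & d2 >= rexp[j]^2
  }
  mean(exposed)
}

blosum62 <- function() {
  e <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
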