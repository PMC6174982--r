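# Physical constants (SI) and derived electrostatic quantities.
.const <- list(
  e    = 1.602176634e-19,   # elementary charge, C
  kB   = 1.380649e-23,      # Boltzmann, J/K
  eps0 = 8.8541878128e-12,  # vacuum permittivity, F/m
  NA_  = 6.02214076e23      # Avogadro
)

#' Thermal voltage kT/e in millivolts
#' @param temperature Kelvin
#' @return numeric, mV (25.693 mV at 298.15 K)
#' @export
kT_mV <- function(temperature = 298.15) {
  1000 * .const$kB * temperature / .const$e
}

# Vacuum Bjerrum length in Angstrom: e^2 / (4 pi eps0 kT), ~560.5 A at 298 K.
# Multiplying by q1*q2/(eps*r[A]) gives an interaction energy in kT.
bjerrum_vacuum_A <- function(temperature = 298.15) {
  .const$e^2 / (4 * pi * .const$eps0 * .const$kB * temperature) * 1e10
}

#' Inverse Debye screening length
#'
#' @param ionic_strength mol/L of a 1:1 electrolyte
#' @param eps_solvent relative solvent dielectric
#' @param temperature Kelvin
#' @return kappa in 1/Angstrom (Debye length 1/kappa is about 7.9 A at
#'   0.15 M, 298 K in water)
#' @export
debye_kappa <- function(ionic_strength, eps_solvent = 78.4,
                        temperature = 298.15) {
  if (ionic_strength <= 0) return(0)
  # kappa^2 = 2 NA e^2 I[mol/m^3] / (eps eps0 kB T), in 1/m^2
  k2 <- 2 * .const$NA_ * .const$e^2 * (ionic_strength * 1000) /
    (eps_solvent * .const$eps0 * .const$kB * temperature)
  sqrt(k2) * 1e-10
}

# Quasi-uniform unit-sphere point template (golden-spiral lattice).
# Deterministic; the same template is reused for every atom.
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  theta <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}

# Squared euclidean cross-distances between rows of a (n x 3) and b (m x 3).
cross_dist2 <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# All index pairs (i < j) among rows of pts with distance <= r.
# Sweep over the x-sorted order; window lookups keep it near-linear for
# surface point clouds.
radius_pairs <- function(pts, r) {
  n <- nrow(pts)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  ord <- order(pts[, 1])
  px <- pts[ord, 1]; py <- pts[ord, 2]; pz <- pts[ord, 3]
  r2 <- r * r
  out_i <- vector("list", n)
  hi_all <- findInterval(px + r, px)
  for (i in seq_len(n - 1L)) {
    hi <- hi_all[i]
    if (hi <= i) next
    j <- (i + 1L):hi
    d2 <- (px[j] - px[i])^2 + (py[j] - py[i])^2 + (pz[j] - pz[i])^2
    keep <- j[d2 <= r2]
    if (length(keep)) out_i[[i]] <- cbind(rep.int(i, length(keep)), keep)
  }
  prs <- do.call(rbind, out_i)
  if (is.null(prs)) return(matrix(integer(0), ncol = 2))
  # back to original indexing
  cbind(ord[prs[, 1]], ord[prs[, 2]])
}

# Evaluate with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
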