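#' Specification for a synthetic pseudo-protein blob
#'
#' Synthetic structures stand in for homology models so every pipeline
#' stage can be validated against planted ground truth. A blob is a
#' quasi-spherical cloud of pseudo-atoms with real element radii, packed by
#' rejection sampling at a minimum separation; optional planted clusters
#' place charges (or nonpolar atoms) in geodesic surface caps of known
#' extent. Generation is a pure function of the spec: the same spec yields
#' bit-identical coordinates.
#'
#' @param seed RNG seed (controls the coordinate jitter and element draw).
#' @param n_atoms number of pseudo-atoms (>= 50 for blob generators).
#' @param clusters list of [planted_cluster()] specs.
#' @param nonpolar_fraction fraction of background atoms drawn as carbon
#'   (nonpolar); the rest alternate N/O (polar).
#' @param background_charge charge (e) placed on every surface atom outside
#'   the planted caps. The default 0 is the idealized neutral control; a
#'   weak negative value (e.g. -0.1) emulates the acidic surface sprinkle
#'   of soluble proteins and gives planted positive caps sharply bounded
#'   potential patches.
#' @param lattice_spacing nearest-neighbour distance of the packing,
#'   Angstrom (>= 2.8 after jitter).
#' @param jitter uniform coordinate jitter half-width, Angstrom.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed, n_atoms, clusters = list(),
                           nonpolar_fraction = 0.5, background_charge = 0,
                           lattice_spacing = 3.0, jitter = 0.05) {
  structure(
    list(seed = as.integer(seed), n_atoms = as.integer(n_atoms),
         clusters = clusters, nonpolar_fraction = nonpolar_fraction,
         background_charge = background_charge,
         lattice_spacing = lattice_spacing, jitter = jitter),
    class = "synthetic_spec"
  )
}

#' Planted surface cluster specification
#'
#' A geodesic cap of surface atoms, centred on `direction`, of arc extent
#' `geodesic_radius` (Angstrom along the blob surface). For charge planting
#' each member carries `sign` * 1e; for nonpolar planting members become
#' carbon.
#'
#' @param geodesic_radius cap extent along the surface, Angstrom; must not
#'   exceed a hemisphere.
#' @param sign +1 or -1 (charge clusters).
#' @param direction unit 3-vector of the cap centre.
#' @param n_charges optionally restrict the cluster to the `n_charges` cap
#'   atoms nearest the cap centre.
#' @return object of class `planted_cluster`.
#' @export
planted_cluster <- function(geodesic_radius, sign = 1,
                            direction = c(0, 0, 1), n_charges = NULL) {
  direction <- direction / sqrt(sum(direction^2))
  structure(list(geodesic_radius = geodesic_radius, sign = sign,
                 direction = direction, n_charges = n_charges),
            class = "planted_cluster")
}

# Quasi-spherical close packing: the n face-centred-cubic lattice sites
# nearest the origin (nearest-neighbour distance nn), with a small uniform
# jitter. Close packing leaves no probe-sized interior voids, so the
# solvent-accessible surface is a single outer envelope with no spurious
# cavity patches; the jitter keeps the surface aperiodic.
lattice_pack <- function(n, nn, jitter) {
  a <- nn * sqrt(2)
  m <- ceiling((3 * n * nn^3 / (4 * pi * sqrt(2)))^(1 / 3) / a) + 2L
  base <- as.matrix(expand.grid(i = -m:m, j = -m:m, k = -m:m))
  sites <- rbind(base,
                 sweep(base, 2, c(0.5, 0.5, 0), "+"),
                 sweep(base, 2, c(0.5, 0, 0.5), "+"),
                 sweep(base, 2, c(0, 0.5, 0.5), "+")) * a
  d <- rowSums(sites^2)
  ord <- order(d, sites[, 1], sites[, 2], sites[, 3])
  xyz <- sites[ord[seq_len(n)], , drop = FALSE]
  xyz + matrix(runif(3 * n, -jitter, jitter), ncol = 3)
}

blob_atoms <- function(spec, background) {
  n <- spec$n_atoms
  xyz <- lattice_pack(n, spec$lattice_spacing, spec$jitter)
  element <- switch(background,
    mixed = ifelse(runif(n) < spec$nonpolar_fraction, "C",
                   ifelse(runif(n) < 0.5, "N", "O")),
    polar = rep(c("N", "O"), length.out = n),
    nonpolar = rep("C", n)
  )
  radii <- default_scheme()$radii
  data.frame(
    serial = seq_len(n), name = element, element = element,
    resid = "BLB", resno = seq_len(n), chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0,
    radius = unname(radii[element]), charge = 0,
    polarity = ifelse(element == "C", "nonpolar", "polar"),
    stringsAsFactors = FALSE
  )
}

# Surface atoms (outer packing shell) and per-cluster cap membership.
# The blob radius is the realized outer radius of the packing.
blob_surface <- function(atoms, spec) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- sqrt(rowSums(xyz^2))
  R <- max(rad)
  list(radius = R, radial = rad,
       atoms = which(rad >= R - spec$lattice_spacing))
}

resolve_clusters <- function(atoms, spec) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  surf <- blob_surface(atoms, spec)
  surface <- surf$atoms
  lapply(spec$clusters, function(cl) {
    theta_max <- cl$geodesic_radius / surf$radius
    if (theta_max > pi / 2 + 1e-9)
      stop("spec error: planted cluster extent exceeds a hemisphere")
    u <- xyz[surface, , drop = FALSE] / surf$radial[surface]
    ang <- acos(pmin(pmax(u %*% cl$direction, -1), 1))
    in_cap <- surface[ang <= theta_max]
    ang_cap <- ang[ang <= theta_max]
    if (!is.null(cl$n_charges)) {
      if (length(in_cap) < cl$n_charges)
        stop(sprintf("spec error: cap holds %d atoms, %d requested",
                     length(in_cap), cl$n_charges))
      keep <- order(ang_cap)[seq_len(cl$n_charges)]
      in_cap <- in_cap[keep]; ang_cap <- ang_cap[keep]
    }
    if (!length(in_cap)) stop("spec error: planted cap contains no surface atoms")
    list(members = in_cap, center_atom = in_cap[which.min(ang_cap)],
         direction = cl$direction, geodesic_radius = cl$geodesic_radius,
         sign = cl$sign)
  })
}

finish_blob <- function(atoms, spec, clusters, label, sasa_truth = TRUE) {
  st <- protein_structure(atoms, label = label)
  st$parameterized <- TRUE
  surf <- blob_surface(atoms, spec)
  gt <- list(blob_radius = surf$radius, surface_atoms = surf$atoms,
             clusters = clusters)
  if (sasa_truth && length(clusters)) {
    # ground-truth cap areas by direct point classification (ownership),
    # independent of the patch-clustering code
    sasa <- compute_sasa(st)
    gt$clusters <- lapply(clusters, function(cl) {
      cl$sas_area <- sum(sasa$cloud$area[sasa$cloud$owner %in% cl$members])
      cl
    })
    gt$atom_sasa <- sasa$atom_sasa
  }
  list(structure = st, ground_truth = gt)
}

#' Generate a charged synthetic blob with planted surface charge caps
#'
#' @param spec a [synthetic_spec()]; its `clusters` receive +/-1e per
#'   member atom according to their `sign`.
#' @return list with `structure` (parameterized `protein_structure`) and
#'   `ground_truth` (cap membership, centre atoms, cap SAS areas in
#'   Angstrom^2, surface-atom indices).
#' @examples
#' b <- make_charged_blob(synthetic_spec(seed = 7, n_atoms = 80,
#'   clusters = list(planted_cluster(4))))
#' length(b$ground_truth$clusters[[1]]$members)
#' @export
make_charged_blob <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_atoms < 50) stop("spec error: blob generators need n_atoms >= 50")
  with_seed(spec$seed, {
    atoms <- blob_atoms(spec, "mixed")
    clusters <- resolve_clusters(atoms, spec)
    if (spec$background_charge != 0) {
      surface <- blob_surface(atoms, spec)$atoms
      atoms$charge[surface] <- spec$background_charge
    }
    for (cl in clusters) atoms$charge[cl$members] <- cl$sign * 1
    finish_blob(atoms, spec, clusters,
                label = sprintf("charged_blob_seed%d", spec$seed))
  })
}

#' Generate a polar blob with a planted nonpolar surface cap
#'
#' Background atoms are polar (alternating N/O); planted cap members become
#' carbon (nonpolar). Exercises the nonpolar:polar patch measure with known
#' cap extent and location.
#'
#' @param spec a [synthetic_spec()] whose clusters mark nonpolar caps.
#' @return as [make_charged_blob()].
#' @export
make_nonpolar_blob <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_atoms < 50) stop("spec error: blob generators need n_atoms >= 50")
  with_seed(spec$seed, {
    background <- if (spec$nonpolar_fraction >= 1) "nonpolar" else "polar"
    atoms <- blob_atoms(spec, background)
    clusters <- resolve_clusters(atoms, spec)
    radii <- default_scheme()$radii
    for (cl in clusters) {
      atoms$element[cl$members] <- "C"
      atoms$name[cl$members] <- "C"
      atoms$polarity[cl$members] <- "nonpolar"
      atoms$radius[cl$members] <- unname(radii["C"])
    }
    finish_blob(atoms, spec, clusters,
                label = sprintf("nonpolar_blob_seed%d", spec$seed))
  })
}

#' Born ion: one charged sphere with its closed-form LPB potential
#'
#' The standard solver-validation fixture: a single pseudo-atom of radius
#' `sphere_radius` carrying `charge`, together with the analytic linearized
#' Poisson-Boltzmann (Kirkwood) sphere solution. Ions are excluded inside
#' the sphere itself, so pair it with `stern_layer = 0` in [grid_spec()]
#' when comparing solver output to the analytic curve.
#'
#' @param charge in units of e.
#' @param sphere_radius Angstrom.
#' @param eps_in,eps_out relative dielectrics inside/outside the sphere.
#' @param ionic_strength mol/L.
#' @param temperature Kelvin.
#' @return list: `structure` (single-atom `protein_structure`) and
#'   `analytic_potential`, a function of radial distance r (Angstrom)
#'   returning the potential in mV. With `I = 0` and uniform dielectric it
#'   reduces to Coulomb's law; with salt the tail decays with the Debye
#'   length (~7.9 A at 0.15 M).
#' @export
make_born_ion <- function(charge = 1, sphere_radius = 2.0,
                          eps_in = 78.4, eps_out = 78.4,
                          ionic_strength = 0.15, temperature = 298.15) {
  if (sphere_radius <= 0) stop("sphere_radius must be > 0")
  atoms <- data.frame(
    serial = 1L, name = "Q", element = "C", resid = "ION", resno = 1L,
    chain = "A", x = 0, y = 0, z = 0, o = 1, b = 0,
    radius = sphere_radius, charge = charge, polarity = "nonpolar",
    stringsAsFactors = FALSE
  )
  st <- protein_structure(atoms, label = "born_ion")
  st$parameterized <- TRUE
  a <- sphere_radius
  kap <- debye_kappa(ionic_strength, eps_out, temperature)
  lB <- bjerrum_vacuum_A(temperature)
  mV <- kT_mV(temperature)
  analytic <- function(r) {
    r <- pmax(r, 1e-9)
    out_part <- lB * charge * exp(-kap * (r - a)) /
      (eps_out * (1 + kap * a) * r)
    in_part <- lB * charge *
      (1 / (eps_in * r) - 1 / (eps_in * a) + 1 / (eps_out * a * (1 + kap * a)))
    ifelse(r >= a, out_part, in_part) * mV
  }
  list(structure = st, analytic_potential = analytic,
       kappa = kap, sphere_radius = a)
}
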