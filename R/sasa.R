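#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Places a quasi-uniform golden-spiral template of `n_sphere_points` on
#' every atom's solvent-expanded sphere (radius + probe) and removes points
#' buried inside any neighbouring expanded sphere. Each surviving point
#' carries an equal share of the expanded-sphere area, so per-atom SASA is
#' `exposed fraction * 4 pi (r + p)^2` and the points form an area-weighted
#' sample of the solvent-accessible surface used by the patch measures.
#'
#' @param structure a parameterized `protein_structure` (radii assigned).
#' @param probe_radius solvent probe radius in Angstrom (water: 1.4).
#' @param n_sphere_points template points per atom; more points give a
#'   finer area estimate at linear cost.
#' @return list with `atom_sasa` (numeric, Angstrom^2 per atom) and `cloud`,
#'   a `surface_cloud`: matrix `points` (n x 3), `area` weights (Angstrom^2
#'   per point), `owner` (atom index) and `polarity` (owner atom class).
#' @examples
#' blob <- make_charged_blob(synthetic_spec(seed = 1, n_atoms = 60))
#' sasa <- compute_sasa(blob$structure)
#' sum(sasa$atom_sasa)
#' @export
compute_sasa <- function(structure, probe_radius = 1.4,
                         n_sphere_points = 960) {
  at <- structure$atoms
  if (!all(is.finite(at$radius)) || any(at$radius <= 0))
    stop("parameterization error: radii unassigned; run assign_parameters()")
  n <- nrow(at)
  xyz <- coords(structure)
  rexp <- at$radius + probe_radius
  tmpl <- golden_spiral_points(n_sphere_points)

  # neighbour lists from pairwise centre distances (n is typically <= a few
  # thousand for the single-domain structures this screen targets)
  d2 <- cross_dist2(xyz, xyz)
  pts_list <- vector("list", n)
  area_list <- vector("list", n)
  owner_list <- vector("list", n)
  atom_sasa <- numeric(n)
  point_area <- 4 * pi * rexp^2 / n_sphere_points

  for (i in seq_len(n)) {
    cutoff2 <- (rexp[i] + rexp)^2
    nb <- which(d2[i, ] < cutoff2)
    nb <- nb[nb != i]
    pts <- tmpl * rexp[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    if (length(nb)) {
      dd <- cross_dist2(pts, xyz[nb, , drop = FALSE])
      buried <- dd < matrix(rexp[nb]^2, nrow = n_sphere_points,
                            ncol = length(nb), byrow = TRUE)
      keep <- !apply(buried, 1, any)
    } else {
      keep <- rep(TRUE, n_sphere_points)
    }
    k <- sum(keep)
    atom_sasa[i] <- k * point_area[i]
    if (k) {
      pts_list[[i]] <- pts[keep, , drop = FALSE]
      area_list[[i]] <- rep(point_area[i], k)
      owner_list[[i]] <- rep(i, k)
    }
  }

  cloud <- structure(
    list(points = do.call(rbind, pts_list),
         area = unlist(area_list) %||% numeric(0),
         owner = unlist(owner_list) %||% integer(0),
         polarity = at$polarity[unlist(owner_list) %||% integer(0)],
         probe_radius = probe_radius,
         n_sphere_points = n_sphere_points),
    class = "surface_cloud"
  )
  list(atom_sasa = atom_sasa, cloud = cloud)
}

#' @export
print.surface_cloud <- function(x, ...) {
  cat(sprintf("<surface_cloud> %d points, %.1f A^2 total area\n",
              length(x$area), sum(x$area)))
  invisible(x)
}

#' Maximal nonpolar:polar surface ratio over 13 Angstrom atom patches
#'
#' For every solvent-exposed atom taken as a patch centre, the patch is the
#' set of atoms whose centres lie within `patch_radius` of the centre
#' atom's centre; the patch ratio is the summed nonpolar SASA over the
#' summed polar SASA of its members. The score is the maximum ratio over
#' all centres — an estimate of the most concentrated nonpolar surface
#' region, which tracks nonpolar-driven interactions and poor solubility.
#'
#' @param structure a parameterized `protein_structure`.
#' @param sasa result of [compute_sasa()] (or `NULL` to compute here).
#' @param patch_radius patch radius in Angstrom (13 by default).
#' @param polar_zero_cap ratio assigned to patches with zero polar area, so
#'   caps rather than infinities propagate into rankings.
#' @return object of class `npp_score`: `value`, `center_atom`,
#'   `patch_nonpolar_area`, `patch_polar_area`, plus the per-centre ratio
#'   vector `all_ratios` (NA for buried atoms).
#' @export
npp_score <- function(structure, sasa = NULL, patch_radius = 13.0,
                      polar_zero_cap = 1e3) {
  if (is.null(sasa)) sasa <- compute_sasa(structure)
  at <- structure$atoms
  if (anyNA(at$polarity))
    stop("parameterization error: polarity classes unassigned")
  asa <- sasa$atom_sasa
  if (all(asa <= 0)) stop("degenerate-input error: structure has no exposed surface")
  np_area <- ifelse(at$polarity == "nonpolar", asa, 0)
  po_area <- ifelse(at$polarity == "polar", asa, 0)
  xyz <- coords(structure)
  d2 <- cross_dist2(xyz, xyz)
  centers <- which(asa > 0)
  ratios <- rep(NA_real_, nrow(at))
  np_sum <- po_sum <- rep(NA_real_, nrow(at))
  r2 <- patch_radius^2
  for (i in centers) {
    members <- d2[i, ] <= r2
    np <- sum(np_area[members])
    po <- sum(po_area[members])
    np_sum[i] <- np; po_sum[i] <- po
    ratios[i] <- if (po > 0) np / po else polar_zero_cap
  }
  best <- centers[which.max(ratios[centers])]
  structure(
    list(value = ratios[best], center_atom = best,
         patch_nonpolar_area = np_sum[best], patch_polar_area = po_sum[best],
         patch_radius = patch_radius, polar_zero_cap = polar_zero_cap,
         all_ratios = ratios),
    class = "npp_score"
  )
}

#' @export
print.npp_score <- function(x, ...) {
  cat(sprintf("<npp_score> %.3f (centre atom %d: %.1f/%.1f A^2 nonpolar/polar in %.0f A patch)\n",
              x$value, x$center_atom, x$patch_nonpolar_area,
              x$patch_polar_area, x$patch_radius))
  invisible(x)
}

#' Per-atom SASA table
#' @param structure a `protein_structure`
#' @param sasa result of [compute_sasa()]
#' @return data.frame: serial, name, resid, resno, chain, polarity, sasa
#' @export
sasa_table <- function(structure, sasa) {
  at <- structure$atoms
  data.frame(serial = at$serial, name = at$name, resid = at$resid,
             resno = at$resno, chain = at$chain, polarity = at$polarity,
             sasa = sasa$atom_sasa, stringsAsFactors = FALSE)
}
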