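#' Contour and cluster positive-potential surface patches
#'
#' Selects surface points whose potential meets the contour level (>= 25 mV
#' by default) and groups them into connected components under a
#' fixed-radius adjacency: two selected points are linked when closer than
#' `link_radius`. The default link radius is twice the mean inter-point
#' spacing of the cloud (estimated as the square root of the mean per-point
#' area weight), which decouples clustering from the sphere-point count.
#'
#' @param cloud a `surface_cloud` from [compute_sasa()].
#' @param potentials_mV per-point potentials aligned with the cloud (from
#'   [surface_potential()]).
#' @param contour_mV contour level in mV; selection is closed (`>=`).
#' @param link_radius adjacency distance in Angstrom; `NULL` for the
#'   density-derived default.
#' @return list of `patch` objects sorted by area descending; each has
#'   `members` (point indices), `area` (Angstrom^2), `max_potential_mV`,
#'   `centroid`. Empty list when no point reaches the contour.
#' @export
positive_patches <- function(cloud, potentials_mV, contour_mV = 25.0,
                             link_radius = NULL) {
  if (length(potentials_mV) != length(cloud$area))
    stop("potentials are not aligned with the surface cloud")
  if (is.null(link_radius))
    link_radius <- 2 * sqrt(mean(cloud$area))
  sel <- which(potentials_mV >= contour_mV)
  if (!length(sel)) return(list())
  pts <- cloud$points[sel, , drop = FALSE]
  comp <- cluster_points(pts, link_radius)
  patches <- lapply(split(seq_along(sel), comp), function(ii) {
    members <- sel[ii]
    structure(
      list(members = members,
           area = sum(cloud$area[members]),
           max_potential_mV = max(potentials_mV[members]),
           centroid = colMeans(cloud$points[members, , drop = FALSE]),
           contour_mV = contour_mV, link_radius = link_radius),
      class = "patch")
  })
  patches[order(vapply(patches, `[[`, 0, "area"), decreasing = TRUE)]
}

# Connected components of points under distance <= r adjacency (igraph).
cluster_points <- function(pts, r) {
  n <- nrow(pts)
  prs <- radius_pairs(pts, r)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(prs)) g <- igraph::add_edges(g, t(prs))
  igraph::components(g)$membership
}

#' PosQ: normalized size of the largest positive-potential patch
#'
#' The ratio of the largest positive electrostatic-potential patch area to
#' a calibration threshold; higher PosQ means a larger maximal positive
#' patch and predicts poorer solubility/secretability. Patch "size" is
#' solvent-accessible area of the member points (sampling-density
#' invariant). Note the packaged default threshold (400 Angstrom^2) is a
#' placeholder for the unpublished solubility-calibrated value; every
#' ranking produced by [rank_report()] is invariant to the threshold.
#'
#' @param patches list of patches from [positive_patches()].
#' @param threshold_A2 calibration threshold in Angstrom^2 (> 0).
#' @return object of class `posq_score`: `value`, `max_patch_area`,
#'   `threshold`, `contour_mV`, `n_patches`.
#' @export
posq <- function(patches, threshold_A2 = 400) {
  if (!is.numeric(threshold_A2) || threshold_A2 <= 0)
    stop("config error: threshold must be > 0")
  max_area <- if (length(patches)) patches[[1]]$area else 0
  structure(
    list(value = max_area / threshold_A2, max_patch_area = max_area,
         threshold = threshold_A2,
         contour_mV = if (length(patches)) patches[[1]]$contour_mV else NA_real_,
         n_patches = length(patches)),
    class = "posq_score"
  )
}

#' @export
print.posq_score <- function(x, ...) {
  cat(sprintf("<posq_score> %.3f (max patch %.1f A^2 / threshold %.0f A^2, %d patch(es))\n",
              x$value, x$max_patch_area, x$threshold, x$n_patches))
  invisible(x)
}

#' Ranked expressability report
#'
#' Orders structures by increasing PosQ — the convention of the screen's
#' summary table, where low PosQ predicts good secretion. Ties are broken
#' by NPP ratio descending, then label.
#'
#' @param scored data.frame with columns `label`, `posq`, `max_patch_area`,
#'   `npp` (and optionally more), or a list of
#'   `list(label, posq_score, npp_score)` triples.
#' @param file optional TSV output path.
#' @return the sorted data.frame.
#' @export
rank_report <- function(scored, file = NULL) {
  if (!is.data.frame(scored)) {
    scored <- do.call(rbind, lapply(scored, function(e) {
      data.frame(label = e$label,
                 posq = e$posq_score$value,
                 max_patch_area = e$posq_score$max_patch_area,
                 npp = e$npp_score$value,
                 contour_mV = e$posq_score$contour_mV,
                 threshold_A2 = e$posq_score$threshold,
                 stringsAsFactors = FALSE)
    }))
  }
  if (nrow(scored) < 1) stop("rank_report needs at least one entry")
  ord <- order(scored$posq, -scored$npp, scored$label)
  out <- scored[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(file))
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
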