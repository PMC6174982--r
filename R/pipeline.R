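#' Pipeline run configuration
#'
#' Bundles every tunable of the screen with its default: the parameter
#' scheme, grid/electrostatics settings, the 25 mV contour, the PosQ
#' threshold, the 13 Angstrom patch radius and the SASA settings. A run's
#' config is echoed into its output directory for provenance.
#'
#' @param contour_mV positive-potential contour level.
#' @param threshold_A2 PosQ calibration threshold (rankings are invariant
#'   to it).
#' @param patch_radius_A nonpolar:polar patch radius.
#' @param probe_radius SASA probe radius.
#' @param n_sphere_points SASA template points per atom.
#' @param grid_spacing,grid_margin,eps_protein,eps_solvent,ionic_strength,temperature,stern_layer
#'   electrostatics settings, see [grid_spec()].
#' @param link_radius patch adjacency radius; `NULL` = density-derived.
#' @param polar_zero_cap NPP value for all-nonpolar patches.
#' @param seed seed for any stochastic component (synthetic generators).
#' @param out_dir output directory for command-style runs.
#' @return object of class `run_config`.
#' @export
run_config <- function(contour_mV = 25.0, threshold_A2 = 400,
                       patch_radius_A = 13.0, probe_radius = 1.4,
                       n_sphere_points = 960, grid_spacing = 0.8,
                       grid_margin = 10, eps_protein = 4.0,
                       eps_solvent = 78.4, ionic_strength = 0.15,
                       temperature = 298.15, stern_layer = 2.0,
                       link_radius = NULL, polar_zero_cap = 1e3,
                       seed = 1L, out_dir = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

config_lines <- function(cfg) {
  vals <- vapply(cfg, function(v)
    if (is.null(v)) "auto" else paste(format(v), collapse = ","), "")
  paste0(names(cfg), " = ", vals)
}

#' Score one structure end-to-end
#'
#' Runs the full screen on a parameterized structure: SASA and surface
#' cloud, LPBE solve, surface potential, positive-patch contouring, PosQ
#' and NPP scores.
#'
#' @param structure a parameterized `protein_structure`.
#' @param config a [run_config()].
#' @return list: `label`, `posq_score`, `npp_score`, `patches`, `sasa`,
#'   `surface` (per-point/per-atom potentials), `field`.
#' @export
score_structure <- function(structure, config = run_config()) {
  sasa <- compute_sasa(structure, probe_radius = config$probe_radius,
                       n_sphere_points = config$n_sphere_points)
  grid <- grid_spec(structure, spacing = config$grid_spacing,
                    margin = config$grid_margin,
                    eps_protein = config$eps_protein,
                    eps_solvent = config$eps_solvent,
                    ionic_strength = config$ionic_strength,
                    temperature = config$temperature,
                    stern_layer = config$stern_layer,
                    dielectric_probe = config$probe_radius)
  field <- solve_lpbe(structure, grid)
  surf <- surface_potential(field, sasa$cloud)
  patches <- positive_patches(sasa$cloud, surf$point_potential_mV,
                              contour_mV = config$contour_mV,
                              link_radius = config$link_radius)
  list(label = structure$label,
       posq_score = posq(patches, config$threshold_A2),
       npp_score = npp_score(structure, sasa,
                             patch_radius = config$patch_radius_A,
                             polar_zero_cap = config$polar_zero_cap),
       patches = patches, sasa = sasa, surface = surf, field = field)
}

#' Score structures and write the ranked report with annotated PDBs
#'
#' The `score` command: reads/accepts structures, scores each, writes a
#' ranked TSV (increasing PosQ), two annotated PDBs per structure (mean
#' surface potential and NPP patch ratio in the B-factor field), a per-atom
#' SASA table, and the echoed config. Per-structure failures are logged and
#' skipped.
#'
#' @param inputs character vector of PDB paths, or a list of
#'   `protein_structure`s (parameterized or not; a default scheme is
#'   applied to unparameterized ones).
#' @param config a [run_config()]; `out_dir = NULL` skips file output.
#' @return list: `report` (ranked data.frame), `results` (per-structure
#'   details), `failures` (named character of error messages). Exit status
#'   semantics for CLI use: 0 all scored, 1 partial, 2 nothing scored.
#' @export
score_structures <- function(inputs, config = run_config()) {
  if (!length(inputs)) stop("config error: no input structures")
  if (is.character(inputs)) inputs <- as.list(inputs)
  if (inherits(inputs, "protein_structure")) inputs <- list(inputs)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  results <- list()
  failures <- character(0)
  for (inp in inputs) {
    label <- NULL
    res <- tryCatch({
      st <- if (inherits(inp, "protein_structure")) inp else read_pdb(inp)
      label <- st$label
      if (!isTRUE(st$parameterized)) st <- assign_parameters(st)
      t0 <- proc.time()[["elapsed"]]
      sc <- score_structure(st, config)
      message(sprintf("[posq] scored %s: PosQ %.3f, NPP %.3f (%.1f s)",
                      label, sc$posq_score$value, sc$npp_score$value,
                      proc.time()[["elapsed"]] - t0))
      sc$structure <- st
      sc
    }, error = function(e) e)
    if (inherits(res, "error")) {
      lbl <- label %||% (if (is.character(inp)) inp else "structure")
      failures[lbl] <- conditionMessage(res)
      message(sprintf("[posq] FAILED %s: %s", lbl, conditionMessage(res)))
    } else {
      results[[res$label]] <- res
    }
  }
  if (!length(results))
    stop("all inputs failed: ", paste(failures, collapse = "; "))

  report <- rank_report(unname(results))
  if (!is.null(out_dir)) {
    write.table(report, file.path(out_dir, "report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(config_lines(config), file.path(out_dir, "config.txt"))
    for (res in results) {
      st <- res$structure
      pot <- res$surface$atom_potential_mV
      pot[!is.finite(pot)] <- 0
      write_annotated_pdb(st, pot,
                          file.path(out_dir, paste0(res$label, "_potential.pdb")))
      npr <- res$npp_score$all_ratios
      npr[!is.finite(npr)] <- 0
      write_annotated_pdb(st, npr,
                          file.path(out_dir, paste0(res$label, "_npp.pdb")))
      write.table(sasa_table(st, res$sasa),
                  file.path(out_dir, paste0(res$label, "_sasa.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(report = report, results = results, failures = failures)
}

#' Design chimeric constructs (domain swaps and region replacements)
#'
#' The `chimera` command: applies [swap_domains()] and/or
#' [replace_region()] to parent sequences and writes the products as FASTA
#' plus a TSV construct report with junctions, lengths and per-residue
#' provenance counts.
#'
#' @param parents list of `sequence_record`s (or a FASTA path).
#' @param swaps list of `list(a, b, boundary_a, boundary_b)` (parent ids).
#' @param replacements list of `list(acceptor, acc_start, acc_end, donor,
#'   donor_start, donor_end)`.
#' @param out_dir optional output directory.
#' @return list: `constructs` (sequence records), `report` (data.frame).
#' @export
design_chimeras <- function(parents, swaps = list(), replacements = list(),
                            out_dir = NULL) {
  if (is.character(parents)) parents <- read_fasta_records(parents)
  ids <- vapply(parents, `[[`, "", "id")
  names(parents) <- ids
  get_parent <- function(id) {
    if (!id %in% ids) stop("config error: unknown parent sequence '", id, "'")
    parents[[id]]
  }
  constructs <- list()
  rows <- list()
  for (sw in swaps) {
    fs <- swap_domains(get_parent(sw$a), get_parent(sw$b),
                       sw$boundary_a, sw$boundary_b)
    for (f in fs) {
      constructs[[f$id]] <- f
      rows[[length(rows) + 1L]] <- data.frame(
        construct = f$id, parents = paste(sw$a, sw$b, sep = "+"),
        operation = "domain_swap", junction = attr(f, "junction"),
        length = seq_len_aa(f), length_delta = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  for (rp in replacements) {
    ch <- replace_region(get_parent(rp$acceptor),
                         region_spec(rp$acc_start, rp$acc_end),
                         get_parent(rp$donor),
                         region_spec(rp$donor_start, rp$donor_end))
    constructs[[ch$id]] <- ch
    rows[[length(rows) + 1L]] <- data.frame(
      construct = ch$id, parents = paste(rp$acceptor, rp$donor, sep = "+"),
      operation = "region_replacement", junction = rp$acc_start,
      length = seq_len_aa(ch), length_delta = attr(ch, "length_delta"),
      stringsAsFactors = FALSE)
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(construct = character(0))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (length(constructs))
      write_fasta_records(constructs, file.path(out_dir, "constructs.fasta"))
    write.table(report, file.path(out_dir, "constructs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (ch in constructs) {
      prov <- attr(ch, "provenance")
      if (!is.null(prov))
        write.table(prov, file.path(out_dir, paste0(ch$id, "_provenance.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(constructs = constructs, report = report)
}

#' Run the built-in validation suite
#'
#' The `validate` command: fast end-to-end checks with known answers —
#' Born-ion solver accuracy against the closed-form sphere solution, LPBE
#' superposition, patch-clustering equivalence to breadth-first search,
#' the sign property (negative-only blob has PosQ 0) and planted-cap
#' recovery. Returns a machine-readable pass/fail table.
#'
#' @param config a [run_config()]; `seed` feeds the stochastic checks.
#' @param quick use smaller grids/structures (default TRUE).
#' @return data.frame: `check`, `metric`, `value`, `threshold`, `pass`.
#' @export
run_validation <- function(config = run_config(), quick = TRUE) {
  rows <- list()
  add <- function(check, metric, value, threshold, pass) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, metric = metric, value = value, threshold = threshold,
      pass = pass, stringsAsFactors = FALSE)
  }

  # Born ion vs analytic
  born <- make_born_ion()
  g <- grid_spec(born$structure, spacing = if (quick) 0.8 else 0.6,
                 margin = 10, eps_protein = 78.4, eps_solvent = 78.4,
                 stern_layer = 0)
  f <- solve_lpbe(born$structure, g)
  r <- seq(born$sphere_radius + 2 * g$spacing, 9, by = 0.5)
  num <- sample_field(f, cbind(r, 0, 0))
  err <- max(abs(num - born$analytic_potential(r)) / abs(born$analytic_potential(r)))
  add("born_ion", "max_rel_err", err, 0.05, err < 0.05)

  # superposition
  sup <- superposition_error(seed = config$seed)
  add("superposition", "rms_rel_err", sup, 0.01, sup < 0.01)

  # clustering vs BFS on random clouds
  agree <- bfs_agreement(n_clouds = if (quick) 20 else 200, seed = config$seed)
  add("patch_bfs", "fraction_identical", agree, 1.0, agree == 1.0)

  # sign property
  neg <- make_charged_blob(synthetic_spec(seed = config$seed, n_atoms = 60,
    clusters = list(planted_cluster(4, sign = -1))))
  sc <- score_structure(neg$structure, config)
  add("negative_blob", "posq", sc$posq_score$value, 0, sc$posq_score$value == 0)

  pos <- neg
  pos$structure$atoms$charge <- -pos$structure$atoms$charge
  sc2 <- score_structure(pos$structure, config)
  add("flipped_blob", "posq", sc2$posq_score$value, 0, sc2$posq_score$value > 0)

  out <- do.call(rbind, rows)
  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
    write.table(out, file.path(config$out_dir, "validation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

# RMS relative error between a two-charge LPBE solve and the sum of the
# single-charge solves (linearity check). Internal; also used by tests.
superposition_error <- function(seed = 1, spacing = 0.8) {
  atoms <- data.frame(
    serial = 1:2, name = c("Q1", "Q2"), element = "C", resid = "ION",
    resno = 1:2, chain = "A", x = c(-3, 3), y = 0, z = 0, o = 1, b = 0,
    radius = 2, charge = c(1, -1), polarity = "nonpolar",
    stringsAsFactors = FALSE)
  both <- protein_structure(atoms, "two_charges"); both$parameterized <- TRUE
  g <- grid_spec(both, spacing = spacing, margin = 10)
  solve_q <- function(q) {
    s <- both
    s$atoms$charge <- q
    solve_lpbe(s, g, tol = 1e-7)$values_mV
  }
  v12 <- solve_q(c(1, -1))
  vsum <- solve_q(c(1, 0)) + solve_q(c(0, -1))
  sqrt(mean((v12 - vsum)^2)) / sqrt(mean(v12^2))
}

# Fraction of random point clouds on which igraph clustering matches a
# plain breadth-first search partition.
bfs_agreement <- function(n_clouds = 200, seed = 1, n_max = 500) {
  ok <- 0L
  with_seed(seed, {
    for (i in seq_len(n_clouds)) {
      n <- sample(20:n_max, 1)
      pts <- matrix(runif(3 * n, 0, 10), ncol = 3)
      r <- runif(1, 0.5, 2.0)
      memb <- cluster_points(pts, r)
      ref <- bfs_components(pts, r)
      if (identical(canonical_partition(memb), canonical_partition(ref)))
        ok <- ok + 1L
    }
  })
  ok / n_clouds
}

# Reference connected components by queue-based BFS on the full distance
# matrix. Independent of igraph; O(n^2), for validation sizes only.
bfs_components <- function(pts, r) {
  n <- nrow(pts)
  d2 <- cross_dist2(pts, pts)
  adj <- d2 <= r * r
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

canonical_partition <- function(memb) {
  # relabel components by first appearance so labels are comparable
  match(memb, unique(memb))
}
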