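#' Toy system specification
#'
#' Defines the synthetic study system: a rigid multi-subunit receptor whose
#' subunits are related by a screw transform (mirroring a helical
#' ring-complex segment), a flexible ligand chain following a ground-truth
#' surface path, and simulated DSS/EDC crosslink tables with a controlled
#' false-positive rate.
#'
#' @param n_subunits number of receptor subunits (default 2).
#' @param subunit_dims grid dimensions of the pseudo-Calpha block per
#'   subunit (default `c(3, 3, 14)`, an elongated block emulating a
#'   GCP-like subunit; the assembly extent is then large relative to the
#'   crosslinker arm, which is what makes the restraints informative).
#' @param spacing subunit grid spacing in Angstrom (default 5).
#' @param twist,rise inter-subunit screw parameters (defaults 54.5 degrees
#'   and 21.2 Angstrom, an open-state-like helical geometry).
#' @param axis_offset distance of the first subunit center from the screw
#'   axis (z), in Angstrom (default 40).
#' @param jitter per-atom positional jitter in Angstrom (default 0.5),
#'   breaking the exact grid degeneracy.
#' @param n_residues ligand chain length (default 150).
#' @param anchor_atom receptor atom (index into subunit 1) near which the
#'   ground-truth path starts (default 1).
#' @param n_true,n_false counts of true and decoy crosslinks (defaults 30
#'   and 2).
#' @param linker_mix named fractions of DSS/EDC among true links (default
#'   all DSS).
#' @param margin placement margin m in (0,1): true links are sampled among
#'   pairs with ground-truth distance at most `m * threshold` (default
#'   0.8); decoys among pairs beyond `1.5 * threshold`.
#' @param thresholds per-linker Calpha-Calpha thresholds in Angstrom.
#' @return a list of class `xlwalk_toy_spec`.
#' @export
toy_spec <- function(n_subunits = 2, subunit_dims = c(3, 3, 14), spacing = 5,
                     twist = 54.5, rise = 21.2, axis_offset = 40,
                     jitter = 0.5, n_residues = 150, anchor_atom = 1,
                     n_true = 30, n_false = 2,
                     linker_mix = c(DSS = 1, EDC = 0), margin = 0.8,
                     thresholds = c(DSS = 35, EDC = 25)) {
  stopifnot(n_subunits >= 1, length(subunit_dims) == 3,
            all(subunit_dims >= 1), n_true + n_false >= 0,
            margin > 0, margin < 1)
  structure(list(n_subunits = n_subunits, subunit_dims = subunit_dims,
                 atoms_per_subunit = prod(subunit_dims), spacing = spacing,
                 twist = twist, rise = rise, axis_offset = axis_offset,
                 jitter = jitter, n_residues = n_residues,
                 anchor_atom = anchor_atom, n_true = n_true,
                 n_false = n_false, linker_mix = linker_mix,
                 margin = margin, thresholds = thresholds),
            class = "xlwalk_toy_spec")
}

#' Generate the toy receptor
#'
#' Builds `n_subunits` rigid pseudo-Calpha blocks related by the spec screw
#' transform (twist/rise about the z axis).  Deterministic for a fixed
#' seed.
#'
#' @param spec an [toy_spec()].
#' @param seed integer seed (controls the per-atom jitter).
#' @return an object of class `xlwalk_toy_receptor`: `coords`, `subunit`
#'   (per-atom subunit index), `transform` (the generating
#'   [rigid_transform()], `NULL` for a single subunit), `spec`.
#' @export
make_toy_receptor <- function(spec, seed = 1) {
  set.seed(seed)
  dm <- spec$subunit_dims
  g <- as.matrix(expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]),
                             z = seq_len(dm[3]))) * spec$spacing
  g <- sweep(g, 2, colMeans(g))
  g <- g + matrix(stats::rnorm(length(g), 0, spec$jitter), nrow(g), 3)
  g[, 1] <- g[, 1] + spec$axis_offset  # place off the screw (z) axis
  tf <- if (spec$n_subunits > 1)
    screw_transform(spec$twist, spec$rise, axis = c(0, 0, 1)) else NULL
  coords <- g
  subunit <- rep(1L, nrow(g))
  cur <- g
  for (s in seq_len(spec$n_subunits - 1)) {
    cur <- apply_transform(cur, tf)
    coords <- rbind(coords, cur)
    subunit <- c(subunit, rep(s + 1L, nrow(g)))
  }
  structure(list(coords = coords, subunit = subunit, transform = tf,
                 spec = spec),
            class = "xlwalk_toy_receptor")
}

#' Write the toy receptor as a PDB file
#'
#' One chain per subunit (A, B, ...), pseudo-Calpha atoms numbered 1..n
#' within each subunit.
#'
#' @param receptor an [make_toy_receptor()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_receptor_pdb <- function(receptor, path) {
  n <- nrow(receptor$coords)
  per <- receptor$spec$atoms_per_subunit
  xyz <- matrix(as.numeric(t(receptor$coords)), nrow = 1)
  class(xyz) <- c("xyz", "matrix")
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = rep(seq_len(per), receptor$spec$n_subunits),
                   resid = rep("ALA", n), eleno = seq_len(n),
                   elety = rep("CA", n),
                   chain = chain_id_pool[receptor$subunit])
  invisible(path)
}

#' Ground-truth surface path for the flexible ligand
#'
#' A self-avoiding walk with 3.8 Angstrom steps that hugs the receptor
#' surface: every point stays within `max_dist` of a receptor atom while
#' keeping at least `min_clear` clearance, anchored near the spec anchor
#' atom.
#'
#' @param receptor an [make_toy_receptor()] result.
#' @param n_residues path length (>= 2); defaults to the spec value.
#' @param seed integer seed.
#' @param max_dist maximum distance to the nearest receptor atom
#'   (default 10).
#' @param min_clear minimum clearance from receptor atoms (default 6.4,
#'   about one ligand-bead plus one receptor-particle radius, so the truth
#'   is sterically plausible for the coarse-grained model).
#' @return an object of class `xlwalk_ground_truth`: `path` (n x 3, one
#'   Calpha per residue), `anchor_atom`.
#' @export
make_ground_truth_path <- function(receptor, n_residues = NULL, seed = 1,
                                   max_dist = 10, min_clear = 6.4) {
  spec <- receptor$spec
  n_residues <- n_residues %||% spec$n_residues
  if (n_residues < 2) stop("n_residues must be >= 2")
  set.seed(seed)
  rec <- receptor$coords
  anchor <- rec[spec$anchor_atom, ]
  start <- NULL
  for (try in 1:200) {
    dir <- stats::rnorm(3)
    cand <- anchor + (min_clear + 1.0) * dir / vec_norm(dir)
    d <- point_dists(rec, cand)
    if (min(d) >= min_clear && min(d) <= max_dist) {
      start <- cand
      break
    }
  }
  if (is.null(start)) stop("could not place the path anchor point")
  path <- saw_walk(start, n_residues, step = 3.8, near_xyz = rec,
                   clear_min = min_clear, clear_max = max_dist,
                   self_min = 3.4)
  structure(list(path = path, anchor_atom = spec$anchor_atom),
            class = "xlwalk_ground_truth")
}

## ground-truth Calpha coordinate lookup: molecule name + residue -> point
toy_protein_names <- function(spec) {
  c(sprintf("SUB%d", seq_len(spec$n_subunits)), "LIG")
}

toy_point <- function(receptor, truth, protein, residue) {
  spec <- receptor$spec
  if (protein == "LIG") return(truth$path[residue, ])
  s <- as.integer(sub("^SUB", "", protein))
  receptor$coords[(s - 1) * spec$atoms_per_subunit + residue, ]
}

#' Simulate a crosslink PSM table from the ground truth
#'
#' True links are sampled among ligand-receptor and ligand-ligand residue
#' pairs whose ground-truth Calpha distance is at most
#' `margin * threshold` for the sampled linker chemistry, weighted by an
#' empirical span prior (Gaussian around the typical Calpha-Calpha span of
#' each chemistry: ~17 A for DSS, ~10 A for EDC) so simulated link lengths
#' resemble real identifications rather than piling up at the margin cap.
#' Decoys are sampled uniformly from pairs beyond `1.5 * threshold` so
#' truth and decoy are unambiguous at the default thresholds.  All rows get q-values <= 0.01 and PSM counts
#' >= 2 by default; filter-violating rows can be injected for testing the
#' evidence filter.
#'
#' @param truth an [make_ground_truth_path()] result.
#' @param receptor the matching [make_toy_receptor()] result.
#' @param spec the [toy_spec()] (defaults to the receptor's).
#' @param seed integer seed; a fixed seed reproduces the table exactly.
#' @param min_seq_sep minimum sequence separation for ligand-ligand pairs
#'   (default 6).
#' @param inject_bad_q,inject_low_psm numbers of extra rows violating the
#'   q-value / PSM-count filter (default 0).
#' @return a list of class `xlwalk_simulated_xlinks`: `psms` (PSM table
#'   data frame in the default column layout), `truth_table` (each
#'   simulated link with its ground-truth distance and label).
#' @export
simulate_crosslinks <- function(truth, receptor, spec = receptor$spec,
                                seed = 1, min_seq_sep = 6,
                                inject_bad_q = 0, inject_low_psm = 0) {
  set.seed(seed)
  n_res <- nrow(truth$path)
  nsub <- spec$n_subunits
  per <- spec$atoms_per_subunit
  ## candidate pair distances: ligand x receptor, ligand x ligand
  d_lr <- matrix(0, n_res, nsub * per)
  for (i in seq_len(n_res)) d_lr[i, ] <- point_dists(receptor$coords,
                                                     truth$path[i, ])
  d_ll <- as.matrix(stats::dist(truth$path))
  ## empirical Calpha-Calpha span distributions per chemistry: DSS spacer
  ## 11.4 A plus lysine side chains peaks near 17 A; EDC is zero-length
  span_prior <- list(DSS = c(mean = 17, sd = 5), EDC = c(mean = 10, sd = 4))
  pick_links <- function(n, lo_fun, hi_fun, label, use_prior) {
    if (n == 0) return(NULL)
    linkers <- sample(names(spec$linker_mix), n, replace = TRUE,
                      prob = spec$linker_mix)
    out <- vector("list", n)
    for (k in seq_len(n)) {
      L <- spec$thresholds[[linkers[k]]]
      lo <- lo_fun(L); hi <- hi_fun(L)
      lr <- which(d_lr > lo & d_lr <= hi, arr.ind = TRUE)
      ll <- which(d_ll > lo & d_ll <= hi & upper.tri(d_ll), arr.ind = TRUE)
      ll <- ll[abs(ll[, 1] - ll[, 2]) >= min_seq_sep, , drop = FALSE]
      ncand <- nrow(lr) + nrow(ll)
      if (ncand == 0)
        stop("no candidate pairs for a ", label, " ", linkers[k], " link")
      dcand <- c(d_lr[lr], d_ll[ll])
      wt <- if (use_prior) {
        pr <- span_prior[[linkers[k]]]
        stats::dnorm(dcand, pr[["mean"]], pr[["sd"]]) + 1e-12
      } else rep(1, ncand)
      j <- sample.int(ncand, 1, prob = wt)
      if (j <= nrow(lr)) {
        li <- lr[j, 1]; rj <- lr[j, 2]
        sub <- (rj - 1) %/% per + 1
        out[[k]] <- data.frame(protein1 = "LIG", residue1 = li,
                               protein2 = sprintf("SUB%d", sub),
                               residue2 = rj - (sub - 1) * per,
                               linker = linkers[k],
                               distance = d_lr[li, rj], label = label,
                               stringsAsFactors = FALSE)
      } else {
        pr <- ll[j - nrow(lr), ]
        out[[k]] <- data.frame(protein1 = "LIG", residue1 = min(pr),
                               protein2 = "LIG", residue2 = max(pr),
                               linker = linkers[k],
                               distance = d_ll[pr[1], pr[2]], label = label,
                               stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  }
  links <- rbind(
    pick_links(spec$n_true, function(L) 0, function(L) spec$margin * L,
               "true", use_prior = TRUE),
    pick_links(spec$n_false, function(L) 1.5 * L, function(L) Inf,
               "decoy", use_prior = FALSE))
  ## drop accidental duplicates of the same residue pair
  if (!is.null(links)) {
    key <- paste(links$protein1, links$residue1, links$protein2,
                 links$residue2, links$linker)
    links <- links[!duplicated(key), , drop = FALSE]
  }
  n <- if (is.null(links)) 0 else nrow(links)
  psms <- data.frame(protein_1 = links$protein1, position_1 = links$residue1,
                     protein_2 = links$protein2, position_2 = links$residue2,
                     linker = links$linker,
                     q_value = round(stats::runif(n, 1e-4, 9e-3), 6),
                     psm_count = 2L + stats::rpois(n, 1),
                     stringsAsFactors = FALSE)
  if (inject_bad_q > 0 && n > 0) {
    extra <- psms[sample.int(n, inject_bad_q, replace = TRUE), ]
    extra$q_value <- round(stats::runif(inject_bad_q, 0.02, 0.5), 6)
    extra$position_1 <- extra$position_1 + 1L  # distinct pair
    psms <- rbind(psms, extra)
  }
  if (inject_low_psm > 0 && n > 0) {
    extra <- psms[sample.int(n, inject_low_psm, replace = TRUE), ]
    extra$psm_count <- 1L
    extra$position_1 <- extra$position_1 + 2L
    psms <- rbind(psms, extra)
  }
  rownames(psms) <- NULL
  structure(list(psms = psms, truth_table = links),
            class = "xlwalk_simulated_xlinks")
}

#' Write a simulated PSM table as CSV
#'
#' @param sim an [simulate_crosslinks()] result (or a plain PSM data
#'   frame).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_psm_table <- function(sim, path) {
  tab <- if (inherits(sim, "xlwalk_simulated_xlinks")) sim$psms else sim
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Ground-truth path recovery inside a density contour
#'
#' Fraction of ground-truth path points whose voxel value in a
#' localization density is at or above the relative contour level
#' (see [contour_level()]).
#'
#' @param density an `xlwalk_density`.
#' @param truth an [make_ground_truth_path()] result (or an n x 3 matrix of
#'   path points).
#' @param contour_fraction fraction of the map maximum (default 0.025).
#' @return fraction in `[0, 1]`.
#' @export
recovery_metrics <- function(density, truth, contour_fraction = 0.025) {
  pts <- if (inherits(truth, "xlwalk_ground_truth")) truth$path else truth
  level <- contour_level(density, contour_fraction)
  mean(grid_value_at(density, pts) >= level)
}

#' Run the full synthetic modeling study
#'
#' Generates the toy receptor, ground-truth path and crosslink table;
#' writes and re-reads them through the same PDB/CSV pathway used for real
#' data; filters the PSMs; builds the hybrid system; samples `n_runs`
#' independent annealing runs; pools, filters to good-scoring models,
#' clusters, and evaluates the top cluster's crosslink satisfaction and
#' ground-truth recovery inside the 2.5 percent contour.
#'
#' @param spec an [toy_spec()].
#' @param seed master seed driving every stage.
#' @param n_runs independent Monte Carlo runs (default 4).
#' @param config an [sampler_config()] shared by the runs.
#' @param rmsd_threshold clustering threshold in Angstrom, or `"auto"`
#'   (default) to cluster at the estimated sampling precision.
#' @param voxel localization density voxel in Angstrom (default 3).
#' @param dir working directory for the intermediate files (default: a
#'   temporary directory).
#' @return a list with the generated objects plus `clustering`,
#'   `top_ensemble`, `density`, `satisfaction` (report for the top
#'   cluster), `occupancy`, `satisfaction_fraction`, `recovery`.
#' @export
run_toy_pipeline <- function(spec = toy_spec(), seed = 1, n_runs = 4,
                             config = sampler_config(),
                             rmsd_threshold = "auto", voxel = 3,
                             dir = tempdir()) {
  receptor <- make_toy_receptor(spec, seed = seed)
  truth <- make_ground_truth_path(receptor, seed = seed + 1)
  sim <- simulate_crosslinks(truth, receptor, spec, seed = seed + 2)

  rec_pdb <- file.path(dir, "toy_receptor.pdb")
  write_receptor_pdb(receptor, rec_pdb)
  csv <- file.path(dir, "toy_xlinks.csv")
  write_psm_table(sim, csv)

  xl <- filter_psms(read_psm_table(csv))
  mols <- lapply(seq_len(spec$n_subunits), function(s)
    molecule_def(sprintf("SUB%d", s), spec$atoms_per_subunit,
                 list(segment_rigid(1, spec$atoms_per_subunit, "receptor",
                                    chain_id_pool[s])),
                 fixed = TRUE))
  mols <- c(mols, list(molecule_def("LIG", spec$n_residues,
                                    list(segment_beads(1, spec$n_residues)))))
  top <- do.call(topology, mols)
  system <- build_system(top, structures = list(receptor = rec_pdb),
                         seed = seed + 3)
  ## the ligand anchor residue binds a known receptor site (the toy analog
  ## of a docked crystal-structure anchor), restrained like a tight link
  anchors <- data.frame(protein1 = "LIG", residue1 = 1,
                        protein2 = "SUB1", residue2 = spec$anchor_atom,
                        threshold = 10)
  rset <- restraint_set(xl, thresholds = spec$thresholds, anchors = anchors)

  pooled <- sample_models(system, rset, config, n_runs = n_runs, seed = seed)
  good <- filter_good_scoring(pooled)
  if (!length(good$models))
    stop("no good-scoring models; the sampling stage did not converge")
  clustering <- cluster_models(good, rmsd_threshold = rmsd_threshold)
  top_ens <- cluster_ensemble(good, clustering, 1)
  density <- localization_density(top_ens, voxel = voxel)
  sat <- satisfaction_report(top_ens, xl, thresholds = spec$thresholds)
  list(spec = spec, receptor = receptor, truth = truth, sim = sim,
       xlinks = xl, system = system, restraints = rset, pooled = pooled,
       good = good, clustering = clustering, top_ensemble = top_ens,
       density = density, satisfaction = sat,
       occupancy = clustering$occupancy[1],
       satisfaction_fraction = attr(sat, "fraction"),
       recovery = recovery_metrics(density, truth))
}
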