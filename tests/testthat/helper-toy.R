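# Builders and independent brute-force oracles shared across tests.
# The oracles deliberately use plain double loops and re-state the scoring
# rules from scratch so they share no code with the package internals.

# Hand-built system: each molecule is a chain of 1-residue beads at given
# coordinates; `mols` is a named list, each element a list of per-copy
# n x 3 coordinate matrices.  `fixed` names molecules whose beads are
# immobile; `bodies` optionally groups a molecule's particles into one
# rigid body per copy.
manual_system <- function(mols, fixed = character(), rigid = character()) {
  particles <- list()
  coords <- list()
  residue_map <- list()
  body_id <- 0
  chain_i <- 0
  defs <- list()
  for (mname in names(mols)) {
    copies <- mols[[mname]]
    n_res <- nrow(copies[[1]])
    residue_map[[mname]] <- vector("list", length(copies))
    for (cp in seq_along(copies)) {
      chain_i <- chain_i + 1
      xy <- copies[[cp]]
      is_rigid <- mname %in% rigid
      if (is_rigid) body_id <- body_id + 1
      rmap <- rep(NA_integer_, n_res)
      for (r in seq_len(n_res)) {
        idx <- length(coords) + 1
        coords[[idx]] <- xy[r, ]
        particles[[idx]] <- data.frame(
          molecule = mname, copy = cp, res_first = r, res_last = r,
          kind = if (is_rigid) "ca" else "bead",
          radius = bead_radius(1),
          body = if (is_rigid) body_id else NA_integer_,
          mobile = !(mname %in% fixed),
          chain = LETTERS[(chain_i - 1) %% 26 + 1],
          stringsAsFactors = FALSE)
        rmap[r] <- idx
      }
      residue_map[[mname]][[cp]] <- rmap
    }
    defs[[length(defs) + 1]] <- molecule_def(
      mname, n_res, list(segment_beads(1, n_res)),
      copies = length(copies), fixed = mname %in% fixed)
  }
  structure(list(coords = do.call(rbind, coords),
                 particles = do.call(rbind, particles),
                 residue_map = residue_map,
                 topology = do.call(topology, defs)),
            class = "xlwalk_system")
}

random_chain <- function(n, seed, origin = c(0, 0, 0), step = 3.8) {
  set.seed(seed)
  steps <- matrix(rnorm(3 * (n - 1)), n - 1, 3)
  steps <- steps / sqrt(rowSums(steps^2)) * step
  rbind(origin, origin + apply(steps, 2, cumsum))[seq_len(n), , drop = FALSE]
}

# small end-to-end inputs: 1-subunit receptor, short ligand, a few links
tiny_pipeline <- function(seed = 11, n_residues = 30, n_true = 8) {
  spec <- toy_spec(n_subunits = 1, subunit_dims = c(3, 3, 3), spacing = 4,
                   n_residues = n_residues, n_true = n_true, n_false = 0)
  receptor <- make_toy_receptor(spec, seed = seed)
  truth <- make_ground_truth_path(receptor, seed = seed + 1)
  sim <- simulate_crosslinks(truth, receptor, spec, seed = seed + 2)
  csv <- tempfile(fileext = ".csv")
  write_psm_table(sim, csv)
  xl <- filter_psms(read_psm_table(csv))
  pdb <- tempfile(fileext = ".pdb")
  write_receptor_pdb(receptor, pdb)
  top <- topology(
    molecule_def("SUB1", spec$atoms_per_subunit,
                 list(segment_rigid(1, spec$atoms_per_subunit, "rec", "A")),
                 fixed = TRUE),
    molecule_def("LIG", n_residues, list(segment_beads(1, n_residues))))
  system <- build_system(top, structures = list(rec = pdb), seed = seed + 3)
  anchors <- data.frame(protein1 = "LIG", residue1 = 1, protein2 = "SUB1",
                        residue2 = spec$anchor_atom, threshold = 10)
  list(spec = spec, receptor = receptor, truth = truth, sim = sim,
       xlinks = xl, system = system,
       rset = restraint_set(xl, anchors = anchors))
}

# ---- oracles ------------------------------------------------------------

bf_min_pair_distance <- function(models, system, p1, r1, p2, r2) {
  best <- Inf
  rm1 <- system$residue_map[[p1]]
  rm2 <- system$residue_map[[p2]]
  for (m in seq_along(models)) {
    xyz <- models[[m]]
    for (c1 in seq_along(rm1)) for (c2 in seq_along(rm2)) {
      i <- rm1[[c1]][r1]; j <- rm2[[c2]][r2]
      if (is.na(i) || is.na(j)) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

bf_rmsd <- function(a, b, sel) {
  s <- 0
  for (i in sel) s <- s + sum((a[i, ] - b[i, ])^2)
  sqrt(s / length(sel))
}

# full score breakdown with explicit loops; restates the rules:
# crosslink: truncated flat-bottom on the copy-ambiguity minimum;
# excluded volume: all pairs except same body / sequence-adjacent;
# connectivity: consecutive particles per chain, same-body pairs exempt
bf_score <- function(system, rset) {
  p <- system$particles
  xyz <- system$coords
  n <- nrow(p)
  xl_term <- 0
  if (!is.null(rset$xlinks) && nrow(rset$xlinks)) {
    for (i in seq_len(nrow(rset$xlinks))) {
      r <- rset$xlinks[i, ]
      d <- bf_min_pair_distance(list(xyz), system, r$protein1, r$residue1,
                                r$protein2, r$residue2)
      L <- rset$thresholds[[r$linker]]
      xl_term <- xl_term + rset$k_xl * min(max(0, d - L), rset$max_excess)^2
    }
  }
  adjacent <- matrix(FALSE, n, n)
  for (m in unique(p$molecule)) for (cp in unique(p$copy[p$molecule == m])) {
    idx <- which(p$molecule == m & p$copy == cp)
    idx <- idx[order(p$res_first[idx])]
    if (length(idx) > 1)
      for (k in seq_len(length(idx) - 1))
        adjacent[idx[k], idx[k + 1]] <- adjacent[idx[k + 1], idx[k]] <- TRUE
  }
  ev_term <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!is.na(p$body[i]) && !is.na(p$body[j]) && p$body[i] == p$body[j]) next
    if (adjacent[i, j]) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    ov <- p$radius[i] + p$radius[j] - d
    if (ov > 0) ev_term <- ev_term + rset$k_ev * ov^2
  }
  conn_term <- 0
  for (m in unique(p$molecule)) for (cp in unique(p$copy[p$molecule == m])) {
    idx <- which(p$molecule == m & p$copy == cp)
    idx <- idx[order(p$res_first[idx])]
    if (length(idx) < 2) next
    for (k in seq_len(length(idx) - 1)) {
      i <- idx[k]; j <- idx[k + 1]
      if (!is.na(p$body[i]) && !is.na(p$body[j]) && p$body[i] == p$body[j])
        next
      g <- p$res_first[j] - p$res_last[i]
      u <- p$radius[i] + p$radius[j] + rset$c_conn * g
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d > u) conn_term <- conn_term + rset$k_conn * (d - u)^2
    }
  }
  w <- rset$weights
  c(crosslink = w[["crosslink"]] * xl_term,
    excluded_volume = w[["excluded_volume"]] * ev_term,
    connectivity = w[["connectivity"]] * conn_term)
}

bf_site_context <- function(at, chain, resno, partners, cutoff) {
  self <- which(at$chain == chain & at$resno == resno)
  out <- numeric(0)
  for (ch in partners) {
    idx <- which(at$chain == ch)
    best <- Inf
    for (i in self) for (j in idx)
      best <- min(best, sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                               (at$z[i] - at$z[j])^2))
    out[ch] <- best
  }
  list(distances = out, within = any(out <= cutoff))
}

random_transform <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3)
  rigid_transform(rotation_matrix(ax, runif(1, 10, 170)),
                  rnorm(3, 0, 20))
}
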