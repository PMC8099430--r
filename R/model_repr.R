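#' Volume-equivalent bead radius
#'
#' Radius of a sphere with the volume of `n_residues` average amino-acid
#' residues: `r = (3 n v_res / 4 pi)^(1/3)`.
#'
#' @param n_residues number of residues represented by the bead (>= 1).
#' @param v_res average residue volume in cubic Angstrom (default 132.3).
#' @return radius in Angstrom.
#' @export
bead_radius <- function(n_residues, v_res = 132.3) {
  if (any(n_residues < 1)) stop("n_residues must be >= 1")
  (3 * n_residues * v_res / (4 * pi))^(1 / 3)
}

#' Rigid segment of a topology
#'
#' Residues `[first, last]` represented as one rigid body of Calpha
#' particles taken from a deposited structure.
#'
#' @param first,last inclusive 1-based residue range.
#' @param structure name of an entry in the `structures` list passed to
#'   [build_system()].
#' @param chain chain identifier within that structure.
#' @return segment descriptor.
#' @export
segment_rigid <- function(first, last, structure, chain) {
  if (last < first) stop("invalid residue range [", first, ",", last, "]")
  list(type = "rigid", first = first, last = last,
       structure = structure, chain = chain)
}

#' Flexible bead segment of a topology
#'
#' Residues `[first, last]` represented as a string of beads, each covering
#' `per_bead` consecutive residues (the last bead may cover fewer).
#'
#' @param first,last inclusive 1-based residue range.
#' @param per_bead residues per bead (>= 1; default 1).
#' @return segment descriptor.
#' @export
segment_beads <- function(first, last, per_bead = 1) {
  if (last < first) stop("invalid residue range [", first, ",", last, "]")
  if (per_bead < 1) stop("per_bead must be >= 1")
  list(type = "beads", first = first, last = last, per_bead = per_bead)
}

#' Molecule definition
#'
#' @param name molecule name (matched against crosslink protein names).
#' @param length sequence length in residues.
#' @param segments list of [segment_rigid()] / [segment_beads()] descriptors.
#' @param copies number of chain copies (>= 1).
#' @param fixed if `TRUE` the molecule is fixed in the lab frame (typical
#'   for the receptor the flexible chain is modeled onto).
#' @return molecule descriptor.
#' @export
molecule_def <- function(name, length, segments, copies = 1, fixed = FALSE) {
  if (copies < 1) stop("copies must be >= 1")
  covered <- integer(0)
  for (s in segments) {
    if (s$first < 1 || s$last > length)
      stop("segment [", s$first, ",", s$last, "] outside molecule '",
           name, "' (length ", length, ")")
    rng <- s$first:s$last
    if (any(rng %in% covered))
      stop("overlapping segments in molecule '", name, "'")
    covered <- c(covered, rng)
  }
  list(name = name, length = length, segments = segments,
       copies = copies, fixed = fixed)
}

#' System topology
#'
#' @param ... molecule descriptors from [molecule_def()].
#' @return an object of class `xlwalk_topology`.
#' @export
topology <- function(...) {
  mols <- list(...)
  nms <- vapply(mols, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate molecule names in topology")
  structure(list(molecules = mols), class = "xlwalk_topology")
}

## chain id pool for PDB output
chain_id_pool <- c(LETTERS, letters, as.character(0:9))

## self-avoiding random walk with fixed step length.
## Constraints: >= self_min from non-adjacent own points; >= clear_min from
## every row of near_xyz; within clear_max of at least one row of near_xyz
## (surface hugging) when clear_max is finite.
saw_walk <- function(start, n, step = 3.8, near_xyz = NULL,
                     clear_min = 0, clear_max = Inf, self_min = 3.0,
                     n_dir_tries = 60, n_backtracks = 200) {
  pts <- matrix(NA_real_, n, 3)
  pts[1, ] <- start
  ok_point <- function(p, k) {
    if (!is.null(near_xyz) && nrow(near_xyz)) {
      d <- point_dists(near_xyz, p)
      if (min(d) < clear_min) return(FALSE)
      if (is.finite(clear_max) && min(d) > clear_max) return(FALSE)
    }
    if (k > 2) {
      ds <- point_dists(pts[seq_len(k - 2), , drop = FALSE], p)
      if (min(ds) < self_min) return(FALSE)
    }
    TRUE
  }
  k <- 2
  backtracks <- 0
  while (k <= n) {
    placed <- FALSE
    for (try in seq_len(n_dir_tries)) {
      dir <- stats::rnorm(3)
      cand <- pts[k - 1, ] + step * dir / vec_norm(dir)
      if (ok_point(cand, k)) {
        pts[k, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (placed) {
      k <- k + 1
    } else {
      backtracks <- backtracks + 1
      if (backtracks > n_backtracks)
        stop("self-avoiding walk failed after ", n_backtracks,
             " backtracks; consider a larger receptor or looser constraints")
      k <- max(2, k - 5)
    }
  }
  pts
}

## load a structure argument: bio3d pdb object or a file path
as_pdb <- function(x) {
  if (inherits(x, "pdb")) return(x)
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop("structure file not found: ", x)
    return(bio3d::read.pdb(x, verbose = FALSE))
  }
  stop("structure must be a bio3d 'pdb' object or a file path")
}

#' Build a hybrid rigid-body / flexible-bead system
#'
#' Builds the particle representation declared by a topology: rigid
#' segments become rigid bodies of Calpha particles read from their source
#' structures; bead segments become flexible strings of volume-equivalent
#' beads, initialized on a seeded self-avoiding walk anchored to an
#' adjacent rigid particle when one exists (otherwise started near the
#' fixed bodies).  A global residue map connects `(molecule, copy,
#' residue)` to particle indices.
#'
#' @param top an [topology()] object.
#' @param structures named list of bio3d `pdb` objects or file paths,
#'   referenced by rigid segments.
#' @param seed integer seed for bead initialization.
#' @param ca_radius radius assigned to rigid Calpha particles (default: the
#'   1-residue volume-equivalent radius, [bead_radius()]).
#' @return an object of class `xlwalk_system`: list with `coords` (n x 3
#'   matrix, Angstrom), `particles` (data frame), `residue_map`, `topology`.
#' @export
build_system <- function(top, structures = list(), seed = 1,
                         ca_radius = bead_radius(1)) {
  stopifnot(inherits(top, "xlwalk_topology"))
  set.seed(seed)
  particles <- list()
  coords <- list()
  residue_map <- list()
  body_id <- 0
  chain_idx <- 0
  for (mol in top$molecules) {
    residue_map[[mol$name]] <- vector("list", mol$copies)
    for (cp in seq_len(mol$copies)) {
      chain_idx <- chain_idx + 1
      chain <- chain_id_pool[((chain_idx - 1) %% length(chain_id_pool)) + 1]
      rmap <- rep(NA_integer_, mol$length)
      segs <- mol$segments[order(vapply(mol$segments, `[[`, 0, "first"))]
      for (s in segs) {
        if (s$type == "rigid") {
          body_id <- body_id + 1
          pdb <- as_pdb(structures[[s$structure]] %||%
                          stop("rigid segment references unknown structure '",
                               s$structure, "'"))
          sel <- bio3d::atom.select(pdb, "calpha", chain = s$chain,
                                    resno = s$first:s$last, verbose = FALSE)
          if (!length(sel$atom))
            stop("chain '", s$chain, "' residues ", s$first, "-", s$last,
                 " not found in structure '", s$structure, "'")
          at <- pdb$atom[sel$atom, , drop = FALSE]
          at <- at[!duplicated(at$resno), , drop = FALSE]
          for (ri in seq_len(nrow(at))) {
            idx <- length(coords) + 1
            coords[[idx]] <- c(at$x[ri], at$y[ri], at$z[ri])
            particles[[idx]] <- list(
              molecule = mol$name, copy = cp,
              res_first = at$resno[ri], res_last = at$resno[ri],
              kind = "ca", radius = ca_radius, body = body_id,
              mobile = !mol$fixed, chain = chain)
            rmap[at$resno[ri]] <- idx
          }
        } else {
          n_res <- s$last - s$first + 1
          n_beads <- ceiling(n_res / s$per_bead)
          spans <- lapply(seq_len(n_beads), function(b) {
            a <- s$first + (b - 1) * s$per_bead
            c(a, min(a + s$per_bead - 1, s$last))
          })
          ## placeholder coordinates; initialized after all rigid bodies below
          for (sp in spans) {
            idx <- length(coords) + 1
            coords[[idx]] <- c(NA_real_, NA_real_, NA_real_)
            particles[[idx]] <- list(
              molecule = mol$name, copy = cp,
              res_first = sp[1], res_last = sp[2],
              kind = "bead", radius = bead_radius(sp[2] - sp[1] + 1),
              body = NA_integer_, mobile = TRUE, chain = chain)
            rmap[sp[1]:sp[2]] <- idx
          }
        }
      }
      residue_map[[mol$name]][[cp]] <- rmap
    }
  }
  particles <- do.call(rbind, lapply(particles, as.data.frame,
                                     stringsAsFactors = FALSE))
  rownames(particles) <- NULL
  coords <- do.call(rbind, coords)
  sys <- structure(list(coords = coords, particles = particles,
                        residue_map = residue_map, topology = top),
                   class = "xlwalk_system")
  init_bead_coords(sys)
}

## initialize all NA bead coordinates with anchored self-avoiding walks
init_bead_coords <- function(sys) {
  p <- sys$particles
  rigid_xyz <- sys$coords[p$kind == "ca", , drop = FALSE]
  todo <- which(p$kind == "bead" & is.na(sys$coords[, 1]))
  if (!length(todo)) return(sys)
  ## group contiguous bead runs per (molecule, copy)
  grp <- paste(p$molecule[todo], p$copy[todo])
  for (g in unique(grp)) {
    run <- todo[grp == g]
    run <- run[order(p$res_first[run])]
    mol <- p$molecule[run[1]]; cp <- p$copy[run[1]]
    rmap <- sys$residue_map[[mol]][[cp]]
    ## anchor: rigid particle adjacent in sequence, if any
    before <- p$res_first[run[1]] - 1
    after <- p$res_last[run[length(run)]] + 1
    anchor <- NULL
    if (before >= 1 && !is.na(rmap[before])) anchor <- sys$coords[rmap[before], ]
    if (is.null(anchor) && after <= length(rmap) && !is.na(rmap[after]))
      anchor <- sys$coords[rmap[after], ]
    clear <- if (nrow(rigid_xyz))
      max(p$radius[run]) + max(p$radius[p$kind == "ca"]) else 0
    ## unanchored chains start next to a random rigid particle and hug the
    ## receptor surface, so sampling begins in the restraint-relevant region
    hug <- Inf
    if (is.null(anchor)) {
      if (nrow(rigid_xyz)) {
        near <- rigid_xyz[sample.int(nrow(rigid_xyz), 1), ]
        dir <- stats::rnorm(3)
        anchor <- near + (clear + 1) * dir / vec_norm(dir)
        hug <- clear + 8
      } else anchor <- c(0, 0, 0)
    }
    start <- anchor + stats::rnorm(3, 0, 1)
    ## retry the whole walk with relaxed constraints if an attempt fails
    pts <- tryCatch(
      saw_walk(start, length(run) + 1, step = 3.8, near_xyz = rigid_xyz,
               clear_min = clear, clear_max = hug, self_min = 3.0),
      error = function(e) tryCatch(
        saw_walk(start, length(run) + 1, step = 3.8, near_xyz = rigid_xyz,
                 clear_min = clear, self_min = 3.0),
        error = function(e)
          saw_walk(start, length(run) + 1, step = 3.8, near_xyz = NULL,
                   self_min = 3.0)))
    sys$coords[run, ] <- pts[-1, , drop = FALSE]
  }
  sys
}

#' Re-initialize all flexible bead chains
#'
#' Draws fresh seeded self-avoiding walks for every bead chain, leaving
#' rigid bodies untouched.  Used to start independent sampling runs from
#' independent configurations.
#'
#' @param system an `xlwalk_system`.
#' @param seed integer seed.
#' @return the system with re-initialized bead coordinates.
#' @export
randomize_beads <- function(system, seed = 1) {
  set.seed(seed)
  system$coords[system$particles$kind == "bead", ] <- NA_real_
  init_bead_coords(system)
}

#' Clone copies of a molecule
#'
#' Extends a system so that `molecule` has `n` copies.  New copies of rigid
#' bodies are placed by the supplied transforms (applied to the copy-1
#' coordinates); new bead chains are re-initialized on fresh seeded walks.
#' Existing particles keep their indices; new particles are appended.
#'
#' @param system an `xlwalk_system`.
#' @param molecule molecule name.
#' @param n total number of copies (>= 1).
#' @param transforms list of [rigid_transform()] for copies
#'   `existing+1 .. n` (default: identity transforms).
#' @param seed seed for new bead initialization.
#' @return the extended `xlwalk_system`.
#' @export
clone_copies <- function(system, molecule, n, transforms = NULL, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  mols <- vapply(system$topology$molecules, `[[`, "", "name")
  mi <- match(molecule, mols)
  if (is.na(mi)) stop("unknown molecule: ", molecule)
  mol <- system$topology$molecules[[mi]]
  n_old <- mol$copies
  if (n <= n_old) return(system)
  set.seed(seed)
  p <- system$particles
  body_id <- max(c(0, p$body), na.rm = TRUE)
  chain_idx <- length(unique(paste(p$molecule, p$copy)))
  src <- which(p$molecule == molecule & p$copy == 1)
  new_parts <- list(); new_coords <- list()
  for (cp in (n_old + 1):n) {
    chain_idx <- chain_idx + 1
    chain <- chain_id_pool[((chain_idx - 1) %% length(chain_id_pool)) + 1]
    tf <- if (!is.null(transforms) && length(transforms) >= cp - n_old)
      transforms[[cp - n_old]] else rigid_transform()
    rmap <- rep(NA_integer_, mol$length)
    body_remap <- new.env()
    for (i in src) {
      idx <- nrow(p) + length(new_parts) + 1
      b <- p$body[i]
      if (!is.na(b)) {
        key <- as.character(b)
        if (is.null(body_remap[[key]])) {
          body_id <- body_id + 1
          body_remap[[key]] <- body_id
        }
        b <- body_remap[[key]]
      }
      if (p$kind[i] == "bead") {
        xyz <- c(NA_real_, NA_real_, NA_real_)  # re-initialized below
      } else {
        xyz <- apply_transform(system$coords[i, ], tf)
      }
      new_coords[[length(new_coords) + 1]] <- xyz
      new_parts[[length(new_parts) + 1]] <- list(
        molecule = molecule, copy = cp,
        res_first = p$res_first[i], res_last = p$res_last[i],
        kind = p$kind[i], radius = p$radius[i], body = b,
        mobile = p$mobile[i], chain = chain)
      rmap[p$res_first[i]:p$res_last[i]] <- idx
    }
    system$residue_map[[molecule]][[cp]] <- rmap
  }
  system$particles <- rbind(p, do.call(rbind, lapply(new_parts, as.data.frame,
                                                     stringsAsFactors = FALSE)))
  rownames(system$particles) <- NULL
  system$coords <- rbind(system$coords, do.call(rbind, new_coords))
  system$topology$molecules[[mi]]$copies <- n
  init_bead_coords(system)
}

#' Select particle indices
#'
#' @param system an `xlwalk_system`.
#' @param molecule,kind,copy optional filters (`kind` is `"ca"` or
#'   `"bead"`).
#' @param mobile optional logical filter on mobility.
#' @return integer vector of particle indices.
#' @export
select_particles <- function(system, molecule = NULL, kind = NULL,
                             mobile = NULL, copy = NULL) {
  p <- system$particles
  keep <- rep(TRUE, nrow(p))
  if (!is.null(molecule)) keep <- keep & p$molecule %in% molecule
  if (!is.null(kind)) keep <- keep & p$kind %in% kind
  if (!is.null(mobile)) keep <- keep & p$mobile == mobile
  if (!is.null(copy)) keep <- keep & p$copy %in% copy
  which(keep)
}

#' @export
print.xlwalk_system <- function(x, ...) {
  p <- x$particles
  cat("xlwalk system:", nrow(p), "particles (",
      sum(p$kind == "ca"), "rigid Calpha,", sum(p$kind == "bead"), "beads;",
      sum(p$mobile), "mobile )\n")
  for (m in x$topology$molecules)
    cat(sprintf("  %s: %d residues x %d cop%s, %d segment(s)%s\n",
                m$name, m$length, m$copies, if (m$copies > 1) "ies" else "y",
                length(m$segments), if (m$fixed) " [fixed]" else ""))
  invisible(x)
}

## PDB fields for the particles of a system
particle_pdb_fields <- function(system) {
  p <- system$particles
  list(resno = p$res_first,
       resid = ifelse(p$kind == "bead", "BEA", "ALA"),
       elety = ifelse(p$kind == "bead", "BB", "CA"),
       chain = p$chain,
       eleno = seq_len(nrow(p)))
}

#' Write a system (or ensemble) as a PDB file
#'
#' Beads are written as pseudo-atoms named `BB` with the residue number of
#' their span start; rigid Calpha particles as `CA`.  An ensemble yields a
#' multi-model PDB.
#'
#' @param x an `xlwalk_system` or `xlwalk_ensemble`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_system_pdb <- function(x, path) {
  if (inherits(x, "xlwalk_ensemble")) {
    system <- x$system
    xyz <- do.call(rbind, lapply(x$models, function(m) as.numeric(t(m))))
  } else {
    system <- x
    xyz <- matrix(as.numeric(t(system$coords)), nrow = 1)
  }
  class(xyz) <- c("xyz", "matrix")
  f <- particle_pdb_fields(system)
  bio3d::write.pdb(file = path, xyz = xyz, resno = f$resno, resid = f$resid,
                   eleno = f$eleno, elety = f$elety, chain = f$chain)
  invisible(path)
}
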