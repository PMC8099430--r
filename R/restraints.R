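#' Restraint set
#'
#' Bundles the crosslink, excluded-volume and sequence-connectivity
#' restraints with their parameters and term weights.
#'
#' @param xlinks crosslinks from [filter_psms()] (may be empty).
#' @param thresholds per-linker Calpha-Calpha upper bounds L in Angstrom.
#' @param k_xl crosslink force constant (score/A^2) applied beyond L.
#' @param max_excess truncation of the crosslink penalty: the excess
#'   `d - L` is capped at this value (Angstrom, default 10), so a single
#'   false-positive link far beyond its threshold cannot outweigh many
#'   satisfied ones (robust restraint).
#' @param k_ev excluded-volume force constant (score/A^2) on sphere
#'   overlaps.
#' @param k_conn connectivity force constant (score/A^2) beyond the bonded
#'   upper bound.
#' @param c_conn per-residue contour length in Angstrom (Calpha-Calpha
#'   virtual bond, default 3.8).
#' @param weights named weights for the three terms.
#' @param scope crosslink copy-ambiguity scope (see [min_pair_distance()]).
#' @param anchors optional data frame of known-site distance restraints
#'   (columns `protein1, residue1, protein2, residue2, threshold`), e.g. a
#'   ligand segment whose binding site is known from a docked crystal
#'   structure.  Scored with the same flat-bottom form as crosslinks but
#'   excluded from crosslink satisfaction statistics.
#' @return an object of class `xlwalk_restraints`.
#' @export
restraint_set <- function(xlinks = NULL, thresholds = c(DSS = 35, EDC = 25),
                          k_xl = 1, max_excess = 10, k_ev = 1, k_conn = 1,
                          c_conn = 3.8,
                          weights = c(crosslink = 1, excluded_volume = 1,
                                      connectivity = 1),
                          scope = "all", anchors = NULL) {
  stopifnot(k_xl >= 0, max_excess > 0, k_ev >= 0, k_conn >= 0, c_conn > 0,
            all(thresholds > 0), all(weights >= 0))
  if (!is.null(anchors))
    stopifnot(all(c("protein1", "residue1", "protein2", "residue2",
                    "threshold") %in% names(anchors)))
  structure(list(xlinks = xlinks, thresholds = thresholds, k_xl = k_xl,
                 max_excess = max_excess, k_ev = k_ev, k_conn = k_conn,
                 c_conn = c_conn, weights = weights, scope = scope,
                 anchors = anchors),
            class = "xlwalk_restraints")
}

## --- compiled scoring context -------------------------------------------
## Precomputes, for a fixed system topology, everything needed to evaluate
## (and incrementally update) the three restraint terms.
score_context <- function(system, rset) {
  p <- system$particles
  n <- nrow(p)
  ## sequence-adjacent pairs and connectivity pairs per (molecule, copy)
  conn_i <- integer(0); conn_j <- integer(0); conn_u <- numeric(0)
  grp <- paste(p$molecule, p$copy, sep = "\r")
  for (g in unique(grp)) {
    idx <- which(grp == g)
    idx <- idx[order(p$res_first[idx])]
    if (length(idx) < 2) next
    a <- idx[-length(idx)]; b <- idx[-1]
    ## pairs inside one rigid body have fixed distances: no restraint needed
    free <- is.na(p$body[a]) | is.na(p$body[b]) | p$body[a] != p$body[b]
    a <- a[free]; b <- b[free]
    if (!length(a)) next
    gap <- p$res_first[b] - p$res_last[a]
    conn_i <- c(conn_i, a); conn_j <- c(conn_j, b)
    conn_u <- c(conn_u, p$radius[a] + p$radius[b] + rset$c_conn * gap)
  }
  ## adjacency lookup for the excluded-volume exemption
  adj <- vector("list", n)
  for (k in seq_along(conn_i)) {
    adj[[conn_i[k]]] <- c(adj[[conn_i[k]]], conn_j[k])
    adj[[conn_j[k]]] <- c(adj[[conn_j[k]]], conn_i[k])
  }
  ## crosslink (counted) and anchor (uncounted) endpoint particle sets
  tab <- NULL
  if (!is.null(rset$xlinks) && nrow(rset$xlinks)) {
    xl <- rset$xlinks
    missing <- setdiff(unique(xl$linker), names(rset$thresholds))
    if (length(missing))
      stop("no distance threshold configured for linker(s): ",
           paste(missing, collapse = ", "))
    tab <- data.frame(protein1 = xl$protein1, residue1 = xl$residue1,
                      protein2 = xl$protein2, residue2 = xl$residue2,
                      L = as.numeric(rset$thresholds[xl$linker]),
                      counted = TRUE, stringsAsFactors = FALSE)
  }
  n_counted <- if (is.null(tab)) 0L else nrow(tab)
  if (!is.null(rset$anchors) && nrow(rset$anchors)) {
    an <- rset$anchors
    tab <- rbind(tab, data.frame(protein1 = an$protein1,
                                 residue1 = an$residue1,
                                 protein2 = an$protein2,
                                 residue2 = an$residue2,
                                 L = as.numeric(an$threshold),
                                 counted = FALSE, stringsAsFactors = FALSE))
  }
  links <- NULL
  if (!is.null(tab) && nrow(tab)) {
    links <- vector("list", nrow(tab))
    for (i in seq_len(nrow(tab))) {
      i1 <- residue_particle_indices(system, tab$protein1[i], tab$residue1[i])
      i2 <- residue_particle_indices(system, tab$protein2[i], tab$residue2[i])
      if (!length(i1) || !length(i2))
        stop("restraint endpoint not mapped: ",
             tab$protein1[i], ":", tab$residue1[i], " - ",
             tab$protein2[i], ":", tab$residue2[i])
      c1 <- attr(i1, "copy"); c2 <- attr(i2, "copy")
      combos <- expand.grid(a = seq_along(i1), b = seq_along(i2))
      if (identical(rset$scope, "paired")) {
        keep <- c1[combos$a] == c2[combos$b]
        if (any(keep)) combos <- combos[keep, , drop = FALSE]
      }
      links[[i]] <- list(p1 = as.integer(i1[combos$a]),
                         p2 = as.integer(i2[combos$b]), L = tab$L[i],
                         counted = tab$counted[i])
    }
  }
  ## particle -> link incidence (for incremental updates)
  link_of <- vector("list", n)
  if (!is.null(links)) {
    for (li in seq_along(links)) {
      for (pp in unique(c(links[[li]]$p1, links[[li]]$p2)))
        link_of[[pp]] <- c(link_of[[pp]], li)
    }
  }
  list(n = n, radius = p$radius, body = p$body, adj = adj,
       conn = list(i = conn_i, j = conn_j, u = conn_u),
       links = links, n_counted = n_counted, link_of = link_of, rset = rset)
}

## per-link minimum distance for a coordinate matrix
link_min_dist <- function(xyz, link) {
  d <- xyz[link$p1, , drop = FALSE] - xyz[link$p2, , drop = FALSE]
  min(sqrt(rowSums(d * d)))
}

ctx_crosslink_scores <- function(xyz, ctx) {
  if (is.null(ctx$links)) return(list(dist = numeric(0), score = numeric(0)))
  d <- vapply(ctx$links, function(l) link_min_dist(xyz, l), 0)
  L <- vapply(ctx$links, `[[`, 0, "L")
  excess <- pmin(pmax(0, d - L), ctx$rset$max_excess)
  list(dist = d, score = ctx$rset$k_xl * excess^2)
}

## excluded-volume contribution of particle i against particles js
ev_pair_terms <- function(xyz, ctx, i, js) {
  if (!length(js)) return(0)
  d <- point_dists(xyz[js, , drop = FALSE], xyz[i, ])
  ov <- pmax(0, ctx$radius[i] + ctx$radius[js] - d)
  ## exemptions: same rigid body, sequence-adjacent
  if (!is.na(ctx$body[i])) ov[!is.na(ctx$body[js]) & ctx$body[js] == ctx$body[i]] <- 0
  if (length(ctx$adj[[i]])) ov[js %in% ctx$adj[[i]]] <- 0
  ctx$rset$k_ev * sum(ov * ov)
}

ctx_ev_score <- function(xyz, ctx) {
  s <- 0
  for (i in seq_len(ctx$n - 1))
    s <- s + ev_pair_terms(xyz, ctx, i, (i + 1):ctx$n)
  s
}

ctx_conn_score <- function(xyz, ctx) {
  if (!length(ctx$conn$i)) return(0)
  d <- sqrt(rowSums((xyz[ctx$conn$i, , drop = FALSE] -
                       xyz[ctx$conn$j, , drop = FALSE])^2))
  ctx$rset$k_conn * sum(pmax(0, d - ctx$conn$u)^2)
}

## --- user-facing scoring ------------------------------------------------

#' Flat-bottom crosslink score for one link
#'
#' Zero when the ambiguity-minimum endpoint distance d is at or below the
#' linker threshold L; `k (d - L)^2` beyond it, with the excess truncated
#' at `max_excess` so a gross outlier contributes a bounded penalty.
#'
#' @param system an `xlwalk_system`.
#' @param protein1,residue1,protein2,residue2 crosslink endpoints.
#' @param L distance threshold in Angstrom.
#' @param k force constant (score/A^2), default 1.
#' @param max_excess truncation of the excess in Angstrom (default 10).
#' @param scope copy-ambiguity scope.
#' @return the score (unitless).
#' @export
crosslink_score <- function(system, protein1, residue1, protein2, residue2,
                            L, k = 1, max_excess = 10, scope = "all") {
  d <- min_pair_distance(system, protein1, residue1, protein2, residue2,
                         scope = scope)$distance
  k * min(max(0, d - L), max_excess)^2
}

#' Excluded-volume score
#'
#' Soft-sphere overlap penalty `sum k_ev max(0, r_i + r_j - d_ij)^2` over
#' all unordered particle pairs, exempting pairs within one rigid body and
#' sequence-adjacent pairs.
#'
#' @param system an `xlwalk_system`.
#' @param k_ev force constant (score/A^2).
#' @param c_conn per-residue length used only to define sequence adjacency
#'   bookkeeping (kept consistent with [connectivity_score()]).
#' @return the score.
#' @export
excluded_volume_score <- function(system, k_ev = 1, c_conn = 3.8) {
  ctx <- score_context(system, restraint_set(NULL, k_ev = k_ev,
                                             c_conn = c_conn))
  ctx_ev_score(system$coords, ctx)
}

#' Sequence-connectivity score
#'
#' For consecutive particles spanning `g` residues, the center-to-center
#' distance is restrained below `U = r_i + r_j + c g` by an upper harmonic
#' `k_conn max(0, d - U)^2`, summed over all consecutive pairs including
#' bead-to-rigid anchors.  Pairs inside one rigid body are exempt: their
#' distances are fixed by construction.
#'
#' @param system an `xlwalk_system`.
#' @param c per-residue contour length (Angstrom/residue).
#' @param k_conn force constant (score/A^2).
#' @return the score.
#' @export
connectivity_score <- function(system, c = 3.8, k_conn = 1) {
  ctx <- score_context(system, restraint_set(NULL, k_conn = k_conn,
                                             c_conn = c))
  ctx_conn_score(system$coords, ctx)
}

#' Total restraint score with per-term breakdown
#'
#' @param system an `xlwalk_system`.
#' @param rset an [restraint_set()].
#' @return a list of class `xlwalk_score`: `total`, `terms` (named vector:
#'   crosslink, excluded_volume, connectivity, already weighted),
#'   `per_crosslink` (data frame of per-link distance and score),
#'   `frac_satisfied`.
#' @export
total_score <- function(system, rset) {
  ctx <- score_context(system, rset)
  score_from_ctx(system$coords, ctx)
}

score_from_ctx <- function(xyz, ctx) {
  xl <- ctx_crosslink_scores(xyz, ctx)
  w <- ctx$rset$weights
  terms <- c(crosslink = w[["crosslink"]] * sum(xl$score),
             excluded_volume = w[["excluded_volume"]] * ctx_ev_score(xyz, ctx),
             connectivity = w[["connectivity"]] * ctx_conn_score(xyz, ctx))
  per <- NULL
  frac <- NA_real_
  if (!is.null(ctx$links)) {
    L <- vapply(ctx$links, `[[`, 0, "L")
    cnt <- seq_len(ctx$n_counted)
    per <- data.frame(min_distance = xl$dist[cnt], threshold = L[cnt],
                      score = xl$score[cnt], satisfied = xl$dist[cnt] <= L[cnt])
    if (ctx$n_counted > 0) frac <- mean(per$satisfied)
  }
  structure(list(total = sum(terms), terms = terms, per_crosslink = per,
                 frac_satisfied = frac),
            class = "xlwalk_score")
}

#' @export
print.xlwalk_score <- function(x, ...) {
  cat(sprintf("total %.4f | crosslink %.4f, excluded-volume %.4f, connectivity %.4f",
              x$total, x$terms["crosslink"], x$terms["excluded_volume"],
              x$terms["connectivity"]))
  if (!is.na(x$frac_satisfied))
    cat(sprintf(" | %.1f%% links satisfied", 100 * x$frac_satisfied))
  cat("\n")
  invisible(x)
}

#' Write the per-crosslink score table as TSV
#'
#' @param score an `xlwalk_score` from [total_score()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_score_table <- function(score, path) {
  if (is.null(score$per_crosslink)) stop("score has no per-crosslink table")
  utils::write.table(score$per_crosslink, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
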