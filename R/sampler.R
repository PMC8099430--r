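#' Sampler configuration
#'
#' @param steps number of Monte Carlo sweeps per run (>= 0); each sweep
#'   attempts one move per mobile entity (bead or rigid body), so the
#'   per-particle move budget is independent of system size.
#' @param t_start,t_end simulated-annealing temperatures; the schedule is
#'   geometric over `n_stages` equal-length stages (set
#'   `t_start == t_end` or `n_stages = 1` for constant temperature).  The
#'   defaults (20 down to 0.5) start hot enough to melt mis-threaded
#'   chains and end cold enough that thermal kicks rarely push satisfied
#'   links over their thresholds.
#' @param n_stages number of annealing stages.
#' @param record_every record one snapshot every this many sweeps (the
#'   initial configuration is always recorded).
#' @param bead_sigma flexible-bead translation sigma (Angstrom).
#' @param rigid_trans_sigma rigid-body translation sigma (Angstrom).
#' @param rigid_rot_sigma rigid-body rotation sigma (degrees).
#' @param seed integer random seed (recorded in the output provenance).
#' @param run_id run identifier stored in provenance.
#' @return an object of class `xlwalk_sampler_config`.
#' @export
sampler_config <- function(steps = 20000, t_start = 20, t_end = 0.5,
                           n_stages = 10, record_every = 50,
                           bead_sigma = 2, rigid_trans_sigma = 1,
                           rigid_rot_sigma = 5, seed = 1, run_id = 1L) {
  stopifnot(steps >= 0, t_start > 0, t_end > 0, n_stages >= 1,
            record_every >= 1)
  structure(list(steps = as.integer(steps), t_start = t_start, t_end = t_end,
                 n_stages = as.integer(n_stages),
                 record_every = as.integer(record_every),
                 bead_sigma = bead_sigma,
                 rigid_trans_sigma = rigid_trans_sigma,
                 rigid_rot_sigma = rigid_rot_sigma,
                 seed = as.integer(seed), run_id = as.integer(run_id)),
            class = "xlwalk_sampler_config")
}

## temperature for step s (1-based) of n steps: geometric stage schedule
stage_temperature <- function(s, n, cfg) {
  if (cfg$n_stages == 1 || n == 0) return(rep(cfg$t_start, length(s)))
  stage <- pmin(cfg$n_stages, 1 + (s - 1) %/% ceiling(n / cfg$n_stages))
  cfg$t_start * (cfg$t_end / cfg$t_start)^((stage - 1) / (cfg$n_stages - 1))
}

#' Monte Carlo sampling run
#'
#' Metropolis Monte Carlo with simulated annealing over individual-bead
#' translations and rigid-body translation/rotation moves, scored against a
#' restraint set.  The trajectory is fully determined by
#' `(system, rset, config)`: identical inputs give bit-identical snapshots.
#'
#' @param system an `xlwalk_system` (initial configuration).
#' @param rset an [restraint_set()].
#' @param config an [sampler_config()].
#' @return an object of class `xlwalk_ensemble`: `models` (list of n x 3
#'   coordinate snapshots), `scores` (one row per snapshot: per-term
#'   scores, satisfied fraction, worst link excess, temperature, step),
#'   `provenance` (run id, seed, snapshot index), `system` (template),
#'   `acceptance_rate`.
#' @export
mc_run <- function(system, rset, config = sampler_config()) {
  ctx <- score_context(system, rset)
  set.seed(config$seed)
  xyz <- system$coords
  p <- system$particles

  ## movable entities: mobile beads (single-bead, segment and pivot moves
  ## operate on contiguous bead runs) and mobile rigid bodies
  bead_idx <- which(p$kind == "bead" & p$mobile)
  body_ids <- unique(p$body[p$mobile & !is.na(p$body)])
  chain_runs <- split(bead_idx, paste(p$molecule[bead_idx], p$copy[bead_idx]))
  chain_runs <- lapply(chain_runs, function(v) v[order(p$res_first[v])])
  bodies <- lapply(body_ids, function(b) which(!is.na(p$body) & p$body == b))
  if (!length(bead_idx) && !length(body_ids) && config$steps > 0)
    stop("system has no mobile particles to sample")
  if (!is.finite(score_from_ctx(xyz, ctx)$total))
    stop("non-finite score for the initial configuration")

  ## restraint bookkeeping handed to the compiled sampling core
  exempt <- lapply(seq_len(ctx$n), function(i) {
    e <- i
    if (!is.na(ctx$body[i]))
      e <- c(e, which(!is.na(ctx$body) & ctx$body == ctx$body[i]))
    as.integer(unique(c(e, ctx$adj[[i]])))
  })
  conn_touch <- lapply(seq_len(ctx$n), function(i)
    which(ctx$conn$i == i | ctx$conn$j == i))
  link_of <- lapply(seq_len(ctx$n), function(i)
    as.integer(ctx$link_of[[i]] %||% integer(0)))
  combo_a <- lapply(ctx$links %||% list(), `[[`, "p1")
  combo_b <- lapply(ctx$links %||% list(), `[[`, "p2")
  link_L <- vapply(ctx$links %||% list(), `[[`, 0, "L")
  w <- rset$weights
  temps <- stage_temperature(seq_len(config$steps), config$steps, config)

  snapshots <- list(xyz)
  snap_step <- 0L
  snap_temp <- stage_temperature(1, config$steps, config)
  if (config$steps > 0) {
    out <- .mc_core(xyz, p$radius, exempt,
                    as.integer(ctx$conn$i), as.integer(ctx$conn$j),
                    as.numeric(ctx$conn$u), conn_touch,
                    combo_a, combo_b, as.numeric(link_L), link_of,
                    as.integer(bead_idx), chain_runs, bodies,
                    as.numeric(temps), as.integer(config$record_every),
                    config$bead_sigma, config$rigid_trans_sigma,
                    config$rigid_rot_sigma,
                    rset$k_xl, rset$max_excess, rset$k_ev, rset$k_conn,
                    w[["crosslink"]], w[["excluded_volume"]],
                    w[["connectivity"]])
    snapshots <- c(snapshots, out$snapshots)
    snap_step <- c(snap_step, out$snap_sweep)
    snap_temp <- c(snap_temp, temps[out$snap_sweep])
    acc <- out$n_accept / max(1, out$n_proposals)
  } else acc <- NA_real_

  ## full score breakdown per snapshot, recomputed from scratch
  rows <- vapply(seq_along(snapshots), function(k) {
    sc <- score_from_ctx(snapshots[[k]], ctx)
    excess <- if (!is.null(sc$per_crosslink) && nrow(sc$per_crosslink))
      max(sc$per_crosslink$min_distance - sc$per_crosslink$threshold)
    else NA_real_
    c(sc$total, sc$terms[["crosslink"]], sc$terms[["excluded_volume"]],
      sc$terms[["connectivity"]], sc$frac_satisfied, excess)
  }, numeric(6))
  scores <- data.frame(model = seq_along(snapshots), step = snap_step,
                       temperature = snap_temp, total = rows[1, ],
                       crosslink = rows[2, ], excluded_volume = rows[3, ],
                       connectivity = rows[4, ], frac_satisfied = rows[5, ],
                       max_link_excess = rows[6, ])
  template <- system
  template$coords <- snapshots[[length(snapshots)]]
  structure(list(models = snapshots, scores = scores,
                 provenance = data.frame(model = seq_along(snapshots),
                                         run = config$run_id,
                                         seed = config$seed,
                                         snapshot = seq_along(snapshots)),
                 system = template,
                 acceptance_rate = acc),
            class = "xlwalk_ensemble")
}

#' Run several independent sampling runs and pool them
#'
#' Each run gets its own pseudo-random stream derived from
#' `(master seed, run index)`, so runs are reproducible independently and
#' the pooled result does not depend on execution order.  Flexible bead
#' chains are re-initialized on a fresh seeded walk per run, so the runs
#' start from independent configurations.
#'
#' @param system an `xlwalk_system`.
#' @param rset an [restraint_set()].
#' @param config an [sampler_config()] shared by all runs (its `seed` /
#'   `run_id` fields are overridden per run).
#' @param n_runs number of independent runs.
#' @param seed master seed.
#' @return pooled `xlwalk_ensemble` (see [pool_runs()]).
#' @export
sample_models <- function(system, rset, config = sampler_config(),
                          n_runs = 4, seed = 1) {
  runs <- lapply(seq_len(n_runs), function(r) {
    cfg <- config
    cfg$seed <- as.integer((seed + 7919 * r) %% 2147483647L)
    cfg$run_id <- as.integer(r)
    sys_r <- if (r == 1) system else randomize_beads(system, cfg$seed)
    mc_run(sys_r, rset, cfg)
  })
  pool_runs(runs)
}

#' Good-scoring model criteria
#'
#' @param min_fraction a model is good-scoring when its satisfied crosslink
#'   fraction is at least this value (default 0.9).  Set to `NULL` to
#'   instead require every link within `link_tol` of its threshold.
#' @param link_tol per-link tolerance in Angstrom beyond the linker
#'   threshold, used when `min_fraction` is `NULL` (default 0).
#' @param ev_cap,conn_cap caps on the excluded-volume and connectivity
#'   scores; `NULL` means 1.0 score unit per mobile particle, about twice
#'   the thermal expectation of one active quadratic constraint per
#'   particle at the final annealing temperature.
#' @return a list of class `xlwalk_criteria`.
#' @export
good_scoring_criteria <- function(min_fraction = 0.9, link_tol = 0,
                                  ev_cap = NULL, conn_cap = NULL) {
  structure(list(min_fraction = min_fraction, link_tol = link_tol,
                 ev_cap = ev_cap, conn_cap = conn_cap),
            class = "xlwalk_criteria")
}

#' Filter an ensemble down to good-scoring models
#'
#' @param ensemble an `xlwalk_ensemble`.
#' @param criteria an [good_scoring_criteria()].
#' @return the filtered `xlwalk_ensemble` (idempotent).
#' @export
filter_good_scoring <- function(ensemble, criteria = good_scoring_criteria()) {
  if (!inherits(criteria, "xlwalk_criteria"))
    stop("criteria must be built with good_scoring_criteria()")
  sc <- ensemble$scores
  n_mobile <- sum(ensemble$system$particles$mobile)
  ev_cap <- criteria$ev_cap %||% (1.0 * n_mobile)
  conn_cap <- criteria$conn_cap %||% (1.0 * n_mobile)
  keep <- sc$excluded_volume <= ev_cap & sc$connectivity <= conn_cap
  if (!is.null(criteria$min_fraction)) {
    keep <- keep & (is.na(sc$frac_satisfied) |
                      sc$frac_satisfied >= criteria$min_fraction)
  } else {
    keep <- keep & (is.na(sc$max_link_excess) |
                      sc$max_link_excess <= criteria$link_tol)
  }
  subset_ensemble(ensemble, which(keep))
}

subset_ensemble <- function(ensemble, idx) {
  out <- ensemble
  out$models <- ensemble$models[idx]
  out$scores <- ensemble$scores[idx, , drop = FALSE]
  out$scores$model <- seq_along(idx)
  rownames(out$scores) <- NULL
  out$provenance <- ensemble$provenance[idx, , drop = FALSE]
  out$provenance$model <- seq_along(idx)
  rownames(out$provenance) <- NULL
  out
}

#' Pool ensembles from several runs
#'
#' Concatenates run ensembles over the same topology, keeping run/seed
#' provenance so the pool can be partitioned back into its runs exactly.
#' Models are ordered by (position in the list, snapshot index).
#'
#' @param runs list of `xlwalk_ensemble` objects.
#' @return pooled `xlwalk_ensemble`.
#' @export
pool_runs <- function(runs) {
  if (!length(runs)) stop("no runs to pool")
  sig <- function(e) {
    p <- e$system$particles
    paste(nrow(p), paste(p$molecule, p$copy, p$res_first, collapse = ";"))
  }
  if (length(unique(vapply(runs, sig, ""))) != 1)
    stop("cannot pool runs with different topologies")
  out <- runs[[1]]
  out$models <- do.call(c, lapply(runs, `[[`, "models"))
  out$scores <- do.call(rbind, lapply(runs, `[[`, "scores"))
  prov <- lapply(seq_along(runs), function(r) {
    pr <- runs[[r]]$provenance
    pr$run <- r
    pr
  })
  out$provenance <- do.call(rbind, prov)
  out$scores$model <- seq_len(nrow(out$scores))
  out$provenance$model <- seq_len(nrow(out$provenance))
  rownames(out$scores) <- rownames(out$provenance) <- NULL
  out$acceptance_rate <- mean(vapply(runs, `[[`, 0, "acceptance_rate"))
  out
}

#' @export
print.xlwalk_ensemble <- function(x, ...) {
  cat("xlwalk ensemble:", length(x$models), "models from",
      length(unique(x$provenance$run)), "run(s)")
  if (!is.na(x$acceptance_rate))
    cat(sprintf("; MC acceptance %.2f", x$acceptance_rate))
  cat("\n")
  if (nrow(x$scores)) {
    cat(sprintf("  score range [%.3f, %.3f], median satisfied fraction %.3f\n",
                min(x$scores$total), max(x$scores$total),
                stats::median(x$scores$frac_satisfied)))
  }
  invisible(x)
}
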