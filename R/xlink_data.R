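#' Default PSM table column mapping
#'
#' Column names expected in a crosslink identification table, in the style
#' of ProXL CSV exports.  Override individual entries to ingest tables with
#' different headers.
#'
#' @param protein1,position1,protein2,position2,linker,q_value,psm_count
#'   column names in the input file.
#' @return named list of column names.
#' @export
psm_columns <- function(protein1 = "protein_1", position1 = "position_1",
                        protein2 = "protein_2", position2 = "position_2",
                        linker = "linker", q_value = "q_value",
                        psm_count = "psm_count") {
  list(protein1 = protein1, position1 = position1,
       protein2 = protein2, position2 = position2,
       linker = linker, q_value = q_value, psm_count = psm_count)
}

xlwalk_linkers <- c("DSS", "EDC")

#' Read a crosslink PSM table
#'
#' Reads a CSV/TSV table of crosslinked peptide identifications (one row per
#' peptide pair, with aggregated PSM count and peptide-level q-value) and
#' validates every row.  Residue positions are 1-based sequence positions.
#'
#' @param path path to a CSV (default) or TSV file.
#' @param columns column mapping, see [psm_columns()].
#' @param sep field separator; guessed from the file extension when `NULL`.
#' @return a `data.frame` with columns `protein1`, `residue1`, `protein2`,
#'   `residue2`, `linker`, `q_value`, `psm_count`, `source_row`.
#' @export
read_psm_table <- function(path, columns = psm_columns(), sep = NULL) {
  if (!file.exists(path)) stop("PSM table not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unlist(columns), names(raw))
  if (length(missing))
    stop("PSM table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(raw) == 0) {
    warning("PSM table '", path, "' contains a header but no rows")
    return(data.frame(protein1 = character(), residue1 = integer(),
                      protein2 = character(), residue2 = integer(),
                      linker = character(), q_value = numeric(),
                      psm_count = integer(), source_row = integer(),
                      stringsAsFactors = FALSE))
  }
  rec <- data.frame(
    protein1 = as.character(raw[[columns$protein1]]),
    residue1 = suppressWarnings(as.integer(raw[[columns$position1]])),
    protein2 = as.character(raw[[columns$protein2]]),
    residue2 = suppressWarnings(as.integer(raw[[columns$position2]])),
    linker = toupper(as.character(raw[[columns$linker]])),
    q_value = suppressWarnings(as.numeric(raw[[columns$q_value]])),
    psm_count = suppressWarnings(as.integer(raw[[columns$psm_count]])),
    source_row = seq_len(nrow(raw)),
    stringsAsFactors = FALSE)

  bad_linker <- which(!rec$linker %in% xlwalk_linkers)
  if (length(bad_linker))
    stop("unknown linker value(s) in row(s): ",
         paste(bad_linker, collapse = ", "),
         " (expected one of ", paste(xlwalk_linkers, collapse = ", "), ")")
  bad_q <- which(is.na(rec$q_value) | rec$q_value < 0 | rec$q_value > 1)
  if (length(bad_q))
    stop("q_value outside [0,1] (or non-numeric) in row(s): ",
         paste(bad_q, collapse = ", "))
  bad_res <- which(is.na(rec$residue1) | is.na(rec$residue2) |
                     rec$residue1 < 1 | rec$residue2 < 1)
  if (length(bad_res))
    stop("residue positions must be integers >= 1; bad row(s): ",
         paste(bad_res, collapse = ", "))
  bad_psm <- which(is.na(rec$psm_count) | rec$psm_count < 1)
  if (length(bad_psm))
    stop("psm_count must be a positive integer; bad row(s): ",
         paste(bad_psm, collapse = ", "))
  rec
}

#' Filter and deduplicate PSM records into unique crosslinks
#'
#' Applies the evidence filter used for XL-MS identifications: a crosslink
#' (unique residue pair + linker chemistry) is kept when its best
#' peptide-level q-value is `<= q_max` and its total aggregated PSM count is
#' `>= min_psms`.  Endpoints are canonicalized lexicographically so that
#' A-B and B-A records merge; self-links (same protein, same residue) are
#' rejected.
#'
#' @param records PSM records from [read_psm_table()].
#' @param q_max maximum peptide-level q-value (default 0.01).
#' @param min_psms minimum total PSM count per unique pair (default 2).
#' @return a `data.frame` of class `xlwalk_xlinks` with columns `protein1`,
#'   `residue1`, `protein2`, `residue2`, `linker`, `n_psms`, `q_min`,
#'   sorted deterministically.  Attribute `n_self_dropped` counts rejected
#'   self-links.
#' @export
filter_psms <- function(records, q_max = 0.01, min_psms = 2) {
  r <- records
  self <- r$protein1 == r$protein2 & r$residue1 == r$residue2
  n_self <- sum(self)
  r <- r[!self, , drop = FALSE]
  if (nrow(r)) {
    swap <- !endpoint_leq(r$protein1, r$residue1, r$protein2, r$residue2)
    tmp_p <- r$protein1[swap]; tmp_r <- r$residue1[swap]
    r$protein1[swap] <- r$protein2[swap]; r$residue1[swap] <- r$residue2[swap]
    r$protein2[swap] <- tmp_p; r$residue2[swap] <- tmp_r
  }
  key <- paste(r$protein1, r$residue1, r$protein2, r$residue2, r$linker,
               sep = "\r")
  agg_psm <- tapply(r$psm_count, key, sum)
  agg_q <- tapply(r$q_value, key, min)
  keys <- names(agg_psm)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    protein1 = vapply(parts, `[`, "", 1),
    residue1 = as.integer(vapply(parts, `[`, "", 2)),
    protein2 = vapply(parts, `[`, "", 3),
    residue2 = as.integer(vapply(parts, `[`, "", 4)),
    linker = vapply(parts, `[`, "", 5),
    n_psms = as.integer(agg_psm),
    q_min = as.numeric(agg_q),
    stringsAsFactors = FALSE)
  out <- out[out$q_min <= q_max & out$n_psms >= min_psms, , drop = FALSE]
  out <- out[order(out$protein1, out$residue1, out$protein2, out$residue2,
                   out$linker), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_self_dropped") <- n_self
  class(out) <- c("xlwalk_xlinks", "data.frame")
  out
}

## particle indices mapping (molecule, residue) across chain copies;
## returns integer(0) when the endpoint is unresolved everywhere
residue_particle_indices <- function(system, protein, residue) {
  rm <- system$residue_map[[protein]]
  if (is.null(rm)) return(structure(integer(0), copy = integer(0)))
  idx <- integer(0); cp <- integer(0)
  for (k in seq_along(rm)) {
    v <- rm[[k]]
    if (residue >= 1 && residue <= length(v) && !is.na(v[residue])) {
      idx <- c(idx, v[residue]); cp <- c(cp, k)
    }
  }
  structure(idx, copy = cp)
}

#' Minimum crosslink endpoint distance over copy ambiguity
#'
#' Computes the minimum Euclidean distance between the particles mapped by
#' the two endpoints of a crosslink, over all chain-copy combinations and,
#' for an ensemble, over all member models.  The minimum handles the
#' ambiguity of crosslinks in systems with multiple copies of a protein
#' (a link satisfied by either copy counts as satisfied).
#'
#' @param object an `xlwalk_system` or `xlwalk_ensemble`.
#' @param protein1,residue1,protein2,residue2 crosslink endpoints
#'   (1-based residue positions).
#' @param scope `"all"` (default) considers every copy-pair combination;
#'   `"paired"` restricts to equal copy indices (within-dimer ambiguity).
#' @return a list with `distance` (Angstrom), `copy1`, `copy2` and `model`
#'   (the argmin identifiers; ties broken toward the lowest copy and model
#'   index).
#' @export
min_pair_distance <- function(object, protein1, residue1, protein2, residue2,
                              scope = c("all", "paired")) {
  scope <- match.arg(scope)
  if (inherits(object, "xlwalk_ensemble")) {
    system <- object$system
    coords_list <- object$models
  } else {
    system <- object
    coords_list <- list(object$coords)
  }
  i1 <- residue_particle_indices(system, protein1, residue1)
  if (!length(i1))
    stop("crosslink endpoint not mapped to any particle: ",
         protein1, " residue ", residue1)
  i2 <- residue_particle_indices(system, protein2, residue2)
  if (!length(i2))
    stop("crosslink endpoint not mapped to any particle: ",
         protein2, " residue ", residue2)
  c1 <- attr(i1, "copy"); c2 <- attr(i2, "copy")
  combos <- expand.grid(a = seq_along(i1), b = seq_along(i2))
  if (scope == "paired") {
    keep <- c1[combos$a] == c2[combos$b]
    if (!any(keep)) keep <- rep(TRUE, nrow(combos))  # fall back: no paired copy
    combos <- combos[keep, , drop = FALSE]
  }
  best <- list(distance = Inf, copy1 = NA_integer_, copy2 = NA_integer_,
               model = NA_integer_)
  for (m in seq_along(coords_list)) {
    xyz <- coords_list[[m]]
    d <- sqrt(rowSums((xyz[i1[combos$a], , drop = FALSE] -
                         xyz[i2[combos$b], , drop = FALSE])^2))
    j <- which.min(d)
    if (d[j] < best$distance) {
      best <- list(distance = d[j], copy1 = c1[combos$a[j]],
                   copy2 = c2[combos$b[j]], model = m)
    }
  }
  best
}

#' Crosslink satisfaction report
#'
#' Evaluates every unique crosslink against a model or model ensemble:
#' a link is satisfied when its ambiguity-minimum endpoint distance is at
#' or below the Calpha-Calpha threshold for its linker chemistry.  Links
#' whose endpoints fall entirely in unrepresented regions are reported as
#' unmappable and excluded from the denominator of the satisfied fraction.
#'
#' @param object an `xlwalk_system` or `xlwalk_ensemble`.
#' @param xlinks crosslinks from [filter_psms()] (or any data frame with the
#'   same columns).
#' @param thresholds named vector of per-linker Calpha-Calpha thresholds in
#'   Angstrom.  Defaults: DSS 35, EDC 25.
#' @param scope copy-ambiguity scope, see [min_pair_distance()].
#' @return a `data.frame` of class `xlwalk_satisfaction`, one row per
#'   crosslink, with `min_distance`, `threshold`, `status` (satisfied /
#'   violated / unmappable), the argmin copy pair and model index.
#'   Attributes: `fraction` (satisfied / mappable), `n_unmappable`.
#' @export
satisfaction_report <- function(object, xlinks,
                                thresholds = c(DSS = 35, EDC = 25),
                                scope = "all") {
  linkers <- unique(xlinks$linker)
  missing <- setdiff(linkers, names(thresholds))
  if (length(missing))
    stop("no distance threshold configured for linker(s): ",
         paste(missing, collapse = ", "))
  n <- nrow(xlinks)
  out <- data.frame(xlinks[, c("protein1", "residue1", "protein2", "residue2",
                               "linker")],
                    min_distance = NA_real_,
                    threshold = as.numeric(thresholds[xlinks$linker]),
                    status = character(n),
                    copy1 = NA_integer_, copy2 = NA_integer_,
                    model = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    res <- tryCatch(
      min_pair_distance(object, xlinks$protein1[i], xlinks$residue1[i],
                        xlinks$protein2[i], xlinks$residue2[i], scope = scope),
      error = function(e) NULL)
    if (is.null(res)) {
      out$status[i] <- "unmappable"
    } else {
      out$min_distance[i] <- res$distance
      out$copy1[i] <- res$copy1
      out$copy2[i] <- res$copy2
      out$model[i] <- res$model
      out$status[i] <- if (res$distance <= out$threshold[i]) "satisfied"
                       else "violated"
    }
  }
  n_sat <- sum(out$status == "satisfied")
  n_map <- sum(out$status != "unmappable")
  attr(out, "fraction") <- if (n_map > 0) n_sat / n_map else NA_real_
  attr(out, "n_unmappable") <- n - n_map
  class(out) <- c("xlwalk_satisfaction", "data.frame")
  out
}

#' @export
print.xlwalk_satisfaction <- function(x, ...) {
  cat(sprintf("Crosslink satisfaction: %d links, %d unmappable, fraction %.3f\n",
              nrow(x), attr(x, "n_unmappable"), attr(x, "fraction")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a satisfaction report as TSV
#'
#' @param report output of [satisfaction_report()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_satisfaction_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write crosslinks as a pseudo-bond annotation file
#'
#' One line per link: `atomspec1 atomspec2 color`, suitable for molecular
#' visualization tools.  Satisfied and violated links are colored by linker
#' chemistry, following the usual cyan/purple (DSS) and blue/red (EDC)
#' convention.
#'
#' @param report output of [satisfaction_report()].
#' @param path output file path.
#' @param chain_map optional named vector mapping protein names to chain ids
#'   used in the atomspec; defaults to the protein names themselves.
#' @return the path, invisibly.
#' @export
write_pseudobonds <- function(report, path, chain_map = NULL) {
  spec <- function(prot, res) {
    ch <- if (!is.null(chain_map) && prot %in% names(chain_map))
      chain_map[[prot]] else prot
    sprintf("/%s:%d@CA", ch, res)
  }
  col <- ifelse(report$linker == "DSS",
                ifelse(report$status == "satisfied", "cyan", "purple"),
                ifelse(report$status == "satisfied", "blue", "red"))
  keep <- report$status != "unmappable"
  lines <- sprintf("%s %s %s",
                   mapply(spec, report$protein1[keep], report$residue1[keep]),
                   mapply(spec, report$protein2[keep], report$residue2[keep]),
                   col[keep])
  writeLines(lines, path)
  invisible(path)
}
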