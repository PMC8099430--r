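test_that("PSM tables parse with row-level validation", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("protein_1,position_1,protein_2,position_2,linker,q_value,psm_count",
               "Spc110,10,Spc97,20,DSS,0.001,3",
               "Spc110,30,Spc98,40,EDC,0.005,2",
               "Spc110,50,Tub4,60,DSS,0.009,5"), f)
  rec <- read_psm_table(f)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$residue1, c(10L, 30L, 50L))
  expect_equal(rec$linker, c("DSS", "EDC", "DSS"))

  writeLines(c("protein_1,position_1,protein_2,position_2,linker,q_value,psm_count",
               "A,1,B,2,DSS,1.5,2"), f)
  expect_error(read_psm_table(f), "q_value.*row.*1")

  writeLines(c("protein_1,position_1,protein_2,position_2,linker,q_value,psm_count",
               "A,1,B,2,BS3,0.001,2"), f)
  expect_error(read_psm_table(f), "linker")

  writeLines("protein_1,position_1,protein_2,position_2,linker,q_value,psm_count", f)
  expect_warning(rec <- read_psm_table(f), "no rows")
  expect_equal(nrow(rec), 0)

  writeLines(c("protein_1,position_1,protein_2,position_2,q_value,psm_count",
               "A,1,B,2,0.001,2"), f)
  expect_error(read_psm_table(f), "linker")
})

test_that("the evidence filter applies q <= 0.01 AND >= 2 PSMs on merged pairs", {
  rec <- data.frame(
    protein1 = c("A", "A", "B", "A", "A"),
    residue1 = c(10L, 11L, 20L, 10L, 12L),
    protein2 = c("B", "B", "A", "B", "A"),
    residue2 = c(20L, 21L, 10L, 20L, 12L),
    linker = "DSS",
    q_value = c(0.005, 0.02, 0.001, 0.003, 0.001),
    psm_count = c(1L, 5L, 1L, 1L, 4L),
    source_row = 1:5, stringsAsFactors = FALSE)
  out <- filter_psms(rec)
  # A10-B20 appears three ways (incl. reversed B20-A10): 3 PSMs total, kept;
  # A11-B21 fails q; the self-link A12-A12 is rejected
  expect_equal(nrow(out), 1)
  expect_equal(out$n_psms, 3L)
  expect_equal(out$q_min, 0.001)
  expect_equal(out$protein1, "A")
  expect_equal(attr(out, "n_self_dropped"), 1L)
})

test_that("filter boundaries sit exactly at q = 0.01 and 2 PSMs", {
  mk <- function(q, n) data.frame(protein1 = "A", residue1 = 1L,
                                  protein2 = "B", residue2 = 2L,
                                  linker = "DSS", q_value = q,
                                  psm_count = n, source_row = 1L,
                                  stringsAsFactors = FALSE)
  expect_equal(nrow(filter_psms(mk(0.01, 2L))), 1)
  expect_equal(nrow(filter_psms(mk(0.0100001, 2L))), 0)
  expect_equal(nrow(filter_psms(mk(0.005, 1L))), 0)
  expect_equal(nrow(filter_psms(mk(0.005, 2L))), 1)
})

test_that("deduplication is idempotent", {
  set.seed(42)
  rec <- data.frame(
    protein1 = sample(c("A", "B", "C"), 40, replace = TRUE),
    residue1 = sample(1:10, 40, replace = TRUE),
    protein2 = sample(c("A", "B", "C"), 40, replace = TRUE),
    residue2 = sample(1:10, 40, replace = TRUE),
    linker = sample(c("DSS", "EDC"), 40, replace = TRUE),
    q_value = runif(40, 0, 0.02),
    psm_count = sample(1:4, 40, replace = TRUE),
    source_row = 1:40, stringsAsFactors = FALSE)
  once <- filter_psms(rec)
  reexpanded <- data.frame(protein1 = once$protein1, residue1 = once$residue1,
                           protein2 = once$protein2, residue2 = once$residue2,
                           linker = once$linker, q_value = once$q_min,
                           psm_count = once$n_psms,
                           source_row = seq_len(nrow(once)),
                           stringsAsFactors = FALSE)
  twice <- filter_psms(reexpanded)
  expect_equal(as.data.frame(twice), as.data.frame(once),
               ignore_attr = TRUE)
})

test_that("minimum pair distance handles copies, symmetry and ensembles", {
  sys <- manual_system(list(
    REC = list(matrix(c(0, 0, 0), 1, 3)),
    LIG = list(matrix(c(3, 4, 0), 1, 3), matrix(c(0, 20, 0), 1, 3))),
    fixed = "REC")
  expect_equal(min_pair_distance(sys, "REC", 1, "LIG", 1)$distance, 5)
  # ambiguity minimum over the two ligand copies
  sys$coords[2, ] <- c(50, 0, 0)
  expect_equal(min_pair_distance(sys, "REC", 1, "LIG", 1)$distance, 20)
  expect_equal(min_pair_distance(sys, "REC", 1, "LIG", 1)$copy2, 2L)
  # endpoint swap symmetry
  expect_equal(min_pair_distance(sys, "LIG", 1, "REC", 1)$distance,
               min_pair_distance(sys, "REC", 1, "LIG", 1)$distance)
  expect_error(min_pair_distance(sys, "REC", 5, "LIG", 1), "not mapped")
})

test_that("ensemble minimum distance matches the exhaustive double loop", {
  set.seed(7)
  sys <- manual_system(list(
    REC = list(random_chain(6, 1)),
    LIG = list(random_chain(5, 2, origin = c(10, 0, 0)),
               random_chain(5, 3, origin = c(-10, 5, 0)))),
    fixed = "REC")
  models <- lapply(1:10, function(m) sys$coords + matrix(rnorm(nrow(sys$coords) * 3, 0, 4),
                                                         ncol = 3))
  ens <- structure(list(models = models, system = sys,
                        provenance = data.frame(model = 1:10, run = 1,
                                                seed = 1, snapshot = 1:10)),
                   class = "xlwalk_ensemble")
  for (k in 1:25) {
    r1 <- sample(6, 1); r2 <- sample(5, 1)
    got <- min_pair_distance(ens, "REC", r1, "LIG", r2)
    want <- bf_min_pair_distance(models, sys, "REC", r1, "LIG", r2)
    expect_equal(got$distance, want, tolerance = 1e-12)
  }
})

test_that("satisfaction reports fraction, unmappables and monotonicity", {
  set.seed(9)
  sys <- manual_system(list(
    REC = list(random_chain(10, 4)),
    LIG = list(random_chain(10, 5, origin = c(12, 0, 0)))),
    fixed = "REC")
  xl <- data.frame(protein1 = "REC", residue1 = 1:8, protein2 = "LIG",
                   residue2 = 1:8, linker = "DSS", n_psms = 2L, q_min = 0.001,
                   stringsAsFactors = FALSE)
  rep35 <- satisfaction_report(sys, xl, thresholds = c(DSS = 35))
  expect_true(all(rep35$status %in% c("satisfied", "violated")))
  frac <- function(th) attr(satisfaction_report(sys, xl,
                                                thresholds = c(DSS = th)),
                            "fraction")
  fr <- vapply(c(5, 10, 20, 40, 80), frac, 0)
  expect_true(all(diff(fr) >= 0))     # raising threshold never lowers it
  expect_equal(frac(1e6), 1)

  xl2 <- rbind(xl, data.frame(protein1 = "REC", residue1 = 99L,
                              protein2 = "LIG", residue2 = 1L,
                              linker = "DSS", n_psms = 2L, q_min = 0.001))
  rep2 <- satisfaction_report(sys, xl2, thresholds = c(DSS = 35))
  expect_equal(attr(rep2, "n_unmappable"), 1L)
  expect_equal(sum(rep2$status == "unmappable"), 1L)
  # unmappables leave the denominator
  expect_equal(attr(rep2, "fraction"),
               sum(rep2$status == "satisfied") / 8)

  expect_error(satisfaction_report(sys, xl, thresholds = c(EDC = 25)),
               "threshold")
})
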