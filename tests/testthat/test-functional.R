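test_that("local protein alignment matches the independent aligner", {
  set.seed(51)
  p <- rand_aa(100)
  self <- local_align_protein(p, p)
  expect_equal(self$identity, 1.0)
  expect_equal(self$coverage, 1.0)

  # query = first half of target -> coverage ~ 0.5
  half <- substr(p, 1, 50)
  hv <- local_align_protein(half, p)
  expect_true(abs(hv$coverage - 0.5) <= 1 / 100)

  # score/identity agreement with Biostrings Smith-Waterman on random pairs
  # (gap open 11 + 1 per extra position => Biostrings opening 10, ext 1)
  for (i in 1:5) {
    q <- rand_aa(80)
    t <- sub_exact(rand_aa(80), 25, alphabet = AA_SET)
    mine <- local_align_protein(q, t)
    bs <- Biostrings::pairwiseAlignment(
      q, t, type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1)
    expect_equal(mine$score, Biostrings::score(bs))
  }
  # a mutated copy keeps close to the planted identity (local trimming may
  # nudge it slightly upward)
  q2 <- sub_exact(p, 20, alphabet = AA_SET)
  al <- local_align_protein(q2, p)
  expect_true(abs(al$identity - 0.80) < 0.04)

  expect_error(local_align_protein("", p), "empty")
})

test_that("enzyme annotation respects all three thresholds", {
  set.seed(53)
  db <- c(Pct = rand_aa(300), But = rand_aa(300))
  # planted homologs at 70% and 50% identity
  prot70 <- sub_exact(db[["Pct"]], 90, alphabet = AA_SET)
  prot50 <- sub_exact(db[["But"]], 150, alphabet = AA_SET)
  proteome <- c(h70 = prot70, h50 = prot50, junk = rand_aa(200))
  hits <- annotate_enzymes(proteome, db)
  expect_true(hits$present[hits$label == "Pct"])
  expect_false(hits$present[hits$label == "But"])  # below the 0.60 floor
  expect_equal(hits$query[hits$label == "Pct"], "h70")

  # tightening min_identity never adds hits
  loose <- annotate_enzymes(proteome, db, homology_thresholds(0.50, 0.5))
  tight <- annotate_enzymes(proteome, db, homology_thresholds(0.75, 0.5))
  expect_true(all(tight$present <= loose$present))

  # empty proteome: everything absent
  none <- annotate_enzymes(character(0), db)
  expect_false(any(none$present))
  expect_error(annotate_enzymes(proteome, unname(db)), "labeled")
})

test_that("butyrate completeness matches the boolean oracle on all 2^7 patterns", {
  labels <- c("Thl", "Hbd", "Cro", "Bcd", "But", "Ptb", "Buk")
  for (mask in 0:(2^7 - 1)) {
    present <- setNames(bitwAnd(bitwShiftR(mask, 0:6), 1L) == 1L, labels)
    prof <- pathway_completeness(present, models = list(butyrate_model()))
    has <- function(x) unname(present[x])
    oracle_transferase <- has("Thl") && has("Hbd") && has("Cro") &&
      has("Bcd") && has("But")
    oracle_kinase <- has("Thl") && has("Hbd") && has("Cro") && has("Bcd") &&
      has("Ptb") && has("Buk")
    expect_equal(unname(prof$butyrate$routes["transferase"]), oracle_transferase)
    expect_equal(unname(prof$butyrate$routes["kinase"]), oracle_kinase)
    expect_equal(prof$butyrate$complete, oracle_transferase || oracle_kinase)
  }
})

test_that("propionate routes implement OR-within-step semantics", {
  mk <- function(...) {
    present <- setNames(rep(FALSE, 9),
                        c("Pct", "ACSS1_2", "ACSS3", "Acd", "Pta", "PduL",
                          "AckA", "TdcD", "Thl"))
    present[c(...)] <- TRUE
    pathway_completeness(present, models = list(propionate_model()))$propionate
  }
  expect_true(mk("Pct")$complete)
  expect_true(mk("ACSS3")$complete)
  expect_true(mk("Pta", "TdcD")$complete)
  expect_false(mk("Pta")$complete)         # kinase step missing
  expect_false(mk("AckA")$complete)        # phosphotransferase step missing
  expect_true(mk("PduL", "AckA")$complete)

  # monotone: adding a hit never breaks a complete route
  base <- mk("Pta", "TdcD")
  more <- mk("Pta", "TdcD", "Pct")
  expect_true(all(more$routes >= base$routes))
})

test_that("planted pathway identities flip presence across the 60% threshold", {
  cfg <- sim_config(n_species = 1, strains_per_species = 2,
                    genome_length = 30000, core_families = 10,
                    accessory_families = 0,
                    planted_pathway_identities = c(Pct = 0.70, But = 0.50),
                    seed = 61)
  col <- simulate_collection(cfg)
  for (gid in names(col$genomes)) {
    hits <- annotate_enzymes(col$proteins[[gid]], col$enzyme_refs)
    expect_true(hits$present[hits$label == "Pct"], label = gid)
    expect_false(hits$present[hits$label == "But"], label = gid)
  }
})

test_that("sporulation screen counts case-insensitive name matches", {
  sig <- c("spo0A", "sspA", "gerD", "cotJ", "dpaA", "sigF")
  ann <- list(g1 = c("Spo0A", "SSPA", "gerD", "xyz"),
              g2 = c("gerD", "cotJ"),
              g3 = character(0))
  sp <- sporulation_profile(ann, sig)
  expect_equal(unname(sp$completeness), c(3 / 6, 2 / 6, 0))
  expect_equal(unname(sp$master_absent), c(FALSE, TRUE, TRUE))
  expect_equal(dim(sp$presence), c(3L, 6L))
  expect_error(sporulation_profile(ann, character(0)), "empty")

  # planted fraction through the generator: 10 named of 66 signature genes
  sig66 <- sprintf("sg%02d", 1:66)
  cfg <- sim_config(n_species = 1, strains_per_species = 1,
                    genome_length = 20000, core_families = 10,
                    accessory_families = 0, seed = 62)
  gene_names <- setNames(sig66[1:10], sprintf("F%04d", 1:10))
  col <- simulate_collection(cfg, gene_names = gene_names)
  sp2 <- sporulation_profile(col, sig66)
  expect_equal(unname(sp2$completeness), 10 / 66)
})

test_that("classical-scaling PCoA reproduces known geometries", {
  # two points at distance d: coordinates +/- d/2 on axis 1
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  p2 <- pcoa(d2, k = 1)
  expect_equal(sort(unname(p2$points[, 1])), c(-1.5, 1.5))

  # equilateral triangle: two equal positive eigenvalues, distances kept
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  p3 <- pcoa(d3, k = 2)
  ev <- p3$eig[1:2]
  expect_equal(ev[1], ev[2], tolerance = 1e-9)
  expect_true(all(abs(as.matrix(dist(p3$points)) - d3) < 1e-9))

  # Euclidean distances reproduced exactly at full k
  set.seed(71)
  x <- matrix(rnorm(20), 5, 4)
  de <- as.matrix(dist(x)); dimnames(de) <- list(paste0("p", 1:5), paste0("p", 1:5))
  pf <- pcoa(de, k = 4)
  expect_true(all(abs(as.matrix(dist(pf$points)) - de) < 1e-9))

  # deterministic sign: each axis's largest-magnitude coordinate is positive
  for (j in seq_len(ncol(pf$points))) {
    expect_gte(pf$points[which.max(abs(pf$points[, j])), j], 0)
  }
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})
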