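test_that("gene-family clustering obeys identity thresholds exactly", {
  set.seed(23)
  g <- rand_dna(1000)
  # exact duplicates fall into one family
  fm <- cluster_gene_families(c(x = g, y = g),
                              c(x = "A", y = "B"),
                              clustering_params(0.95, 0.9))
  expect_equal(nrow(fm$presence), 1L)

  # 40 substitutions in 1000 nt = 96% identity: one family at 0.95,
  # two at 0.97
  m <- sub_exact(g, 40)
  fm95 <- cluster_gene_families(c(x = g, y = m), c(x = "A", y = "B"),
                                clustering_params(0.95, 0.9))
  fm97 <- cluster_gene_families(c(x = g, y = m), c(x = "A", y = "B"),
                                clustering_params(0.97, 0.9))
  expect_equal(nrow(fm95$presence), 1L)
  expect_equal(nrow(fm97$presence), 2L)

  expect_error(cluster_gene_families(c(x = "MKLV"), c(x = "A"),
                                     clustering_params(alphabet = "nt")),
               "alphabet")
})

test_that("greedy family clustering equals brute-force replay on small sets", {
  set.seed(29)
  base1 <- rand_dna(900); base2 <- rand_dna(600)
  seqs <- c(setNames(c(base1, sub_exact(base1, 20), sub_exact(base1, 80),
                       base2, sub_exact(base2, 12), rand_dna(750)),
                     paste0("q", 1:6)))
  genome_of <- setNames(rep("G1", 6), names(seqs))
  params <- clustering_params(0.95, 0.9)
  fm <- cluster_gene_families(seqs, genome_of, params)

  ident <- function(i, j) {
    pc <- panlachno:::pair_identity_coverage(seqs[[i]], seqs[[j]], params)
    if (pc$coverage >= params$coverage) pc$identity else -1
  }
  want <- greedy_replay(names(seqs), nchar(seqs), ident, params$identity)
  got <- setNames(match(fm$membership, unique(fm$membership[names(seqs)])),
                  names(seqs))
  expect_true(same_partition(got, want))
  # every sequence in exactly one family; family sizes sum to input size
  expect_equal(sum(fm$families$n_members), length(seqs))

  # raising identity never decreases the family count
  n_by_id <- vapply(c(0.90, 0.95, 0.99), function(i) {
    nrow(cluster_gene_families(seqs, genome_of,
                               clustering_params(i, 0.9))$presence)
  }, 1L)
  expect_true(all(diff(n_by_id) >= 0))
})

test_that("prevalence categories partition families and count planted structure", {
  pres <- rbind(matrix(TRUE, 5, 20), matrix(FALSE, 3, 20))
  pres[6, 1:2] <- TRUE; pres[7, 3] <- TRUE; pres[8, 10:12] <- TRUE
  dimnames(pres) <- list(paste0("f", 1:8), paste0("g", 1:20))
  fm <- family_matrix(pres)
  pv <- classify_prevalence(fm)
  expect_equal(unname(pv$counts["core"]), 5L, ignore_attr = TRUE)
  expect_equal(unname(pv$counts["cloud"]), 2L, ignore_attr = TRUE)
  expect_equal(unname(pv$counts["shell"]), 1L, ignore_attr = TRUE)  # 3/20 = 0.15
  expect_equal(sum(pv$counts), 8L)
  expect_equal(pv$max_prevalence, 100)
})

test_that("accumulation curves follow closed forms on constructed matrices", {
  # identical genomes: pan = core = constant
  pres <- matrix(TRUE, 50, 6, dimnames = list(paste0("f", 1:50), paste0("g", 1:6)))
  ac <- accumulation_curves(family_matrix(pres), n_permutations = 5, seed = 1)
  expect_true(all(ac$pan == 50) && all(ac$core == 50))

  # 100 shared + 10 unique per genome: pan(n) = 100 + 10n, core(n) = 100
  ng <- 8
  shared <- matrix(TRUE, 100, ng)
  unique_blocks <- matrix(FALSE, 10 * ng, ng)
  for (g in seq_len(ng)) unique_blocks[(g - 1) * 10 + 1:10, g] <- TRUE
  pres2 <- rbind(shared, unique_blocks)
  dimnames(pres2) <- list(paste0("f", seq_len(nrow(pres2))), paste0("g", 1:ng))
  ac2 <- accumulation_curves(family_matrix(pres2), n_permutations = 7, seed = 2)
  expect_equal(ac2$pan, 100 + 10 * seq_len(ng))
  # core(1) sees one genome's 110 families; from n = 2 on only the shared 100
  expect_equal(ac2$core, c(110, rep(100, ng - 1)))

  # monotonicity in n
  expect_true(all(diff(ac2$pan) >= 0) && all(diff(ac2$core) <= 0))
})

test_that("jaccard distances equal the set-arithmetic oracle", {
  # identical presence vectors -> 0; disjoint -> 1
  pres <- cbind(g1 = c(rep(TRUE, 100), rep(TRUE, 50), rep(FALSE, 50)),
                g2 = c(rep(TRUE, 100), rep(FALSE, 50), rep(TRUE, 50)),
                g3 = c(rep(TRUE, 100), rep(TRUE, 50), rep(FALSE, 50)))
  rownames(pres) <- paste0("f", 1:200)
  d <- jaccard_matrix(family_matrix(pres))
  expect_equal(d["g1", "g3"], 0)
  expect_equal(d["g1", "g2"], 0.5)   # 1 - 100/200
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_identical(d, t(d))

  disj <- cbind(a = c(TRUE, TRUE, FALSE, FALSE), b = c(FALSE, FALSE, TRUE, TRUE))
  rownames(disj) <- paste0("f", 1:4)
  expect_equal(jaccard_matrix(family_matrix(disj))["a", "b"], 1)

  # hand-rolled Jaccard oracle on random matrices + triangle inequality
  set.seed(33)
  rp <- matrix(runif(300) < 0.4, 30, 10,
               dimnames = list(paste0("f", 1:30), paste0("g", 1:10)))
  rp[1, ] <- TRUE  # avoid empty genomes
  dj <- jaccard_matrix(family_matrix(rp))
  for (pair in list(c(1, 2), c(3, 7), c(5, 10))) {
    A <- which(rp[, pair[1]]); B <- which(rp[, pair[2]])
    expect_equal(dj[pair[1], pair[2]],
                 1 - length(intersect(A, B)) / length(union(A, B)))
  }
  for (trip in list(c(1, 2, 3), c(4, 8, 9))) {
    expect_lte(dj[trip[1], trip[3]],
               dj[trip[1], trip[2]] + dj[trip[2], trip[3]] + 1e-12)
  }

  empty <- cbind(a = c(TRUE, TRUE), b = c(FALSE, FALSE))
  rownames(empty) <- c("f1", "f2")
  expect_warning(de <- jaccard_matrix(family_matrix(empty)), "zero families")
  expect_equal(de["a", "b"], 1)
})

test_that("branch divergence separates planted branches and matches wilcox", {
  # two branches of identical genomes with disjoint accessory content
  pres <- cbind(a1 = rep(c(TRUE, FALSE), c(50, 50)),
                a2 = rep(c(TRUE, FALSE), c(50, 50)),
                a3 = rep(c(TRUE, FALSE), c(50, 50)),
                b1 = rep(c(FALSE, TRUE), c(50, 50)),
                b2 = rep(c(FALSE, TRUE), c(50, 50)),
                b3 = rep(c(FALSE, TRUE), c(50, 50)))
  rownames(pres) <- paste0("f", 1:100)
  d <- jaccard_matrix(family_matrix(pres))
  bd <- branch_divergence(d, setNames(rep(c("A", "B"), each = 3), colnames(d)))
  expect_equal(bd$median_within, 0)
  expect_gt(bd$median_between, 0)
  expect_lt(bd$p, 0.05)

  # exact enumeration agrees with the normal approximation at n1 = n2 = 8
  set.seed(41)
  w <- runif(8); b <- runif(8) + 0.5
  p_exact <- wilcox.test(w, b, exact = TRUE)$p.value
  p_norm <- wilcox.test(w, b, exact = FALSE, correct = FALSE)$p.value
  expect_lt(abs(p_exact - p_norm), 0.01)

  expect_error(branch_divergence(d, setNames(rep("A", 6), colnames(d))),
               "two branches")
})
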