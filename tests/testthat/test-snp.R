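test_that("SNP calling is exact on planted no-indel strains", {
  # identical genomes: zero variants
  set.seed(81)
  r <- rand_dna(50000)
  cs0 <- call_snps(c(q = r), c(r = r))
  expect_equal(nrow(cs0$variants), 0L)
  expect_equal(cs0$sites_compared, 50000L)

  cfg <- sim_config(n_species = 1, strains_per_species = 2,
                    genome_length = 50000, within_species_divergence = 0.02,
                    core_families = 10, accessory_families = 0, seed = 82)
  col <- simulate_collection(cfg)
  ref <- col$ancestors[1]
  for (gid in names(col$genomes)) {
    cs <- call_snps(col$genomes[gid], ref)
    tr <- col$truth$variants[[gid]]
    called <- paste(cs$variants$pos, cs$variants$alt)
    truth <- paste(tr$pos, tr$alt)
    recall <- mean(truth %in% called)
    precision <- mean(called %in% truth)
    expect_gte(recall, 0.99)
    expect_gte(precision, 0.99)
  }

  # query/reference swap mirrors each variant
  g <- col$genomes["S01G01"]
  fwd <- call_snps(g, ref)$variants
  rev <- call_snps(ref, g)$variants
  expect_equal(fwd$pos, rev$pos)
  expect_equal(fwd$ref, rev$alt)
  expect_equal(fwd$alt, rev$ref)

  # unrelated genome: unalignable warning, empty calls
  expect_warning(cs2 <- call_snps(c(x = rand_dna(5000)), c(y = rand_dna(5000))),
                 "unalignable")
  expect_equal(nrow(cs2$variants), 0L)
})

test_that("SNP calling F1 stays >= 0.99 across divergences", {
  set.seed(83)
  for (d in c(0.001, 0.01, 0.05)) {
    r <- rand_dna(60000)
    m <- mutate_sequence(r, d)
    cs <- call_snps(c(q = m$seq), c(r = r))
    called <- paste(cs$variants$pos, cs$variants$alt)
    truth <- paste(m$variants$pos, m$variants$alt)
    tp <- sum(called %in% truth)
    f1 <- 2 * tp / (length(called) + length(truth))
    expect_gte(f1, 0.99)
  }
})

test_that("variant effects match fixed classic cases", {
  # gene: ATG GAA TGG TAA at positions 11..22
  ref <- paste0(paste(rep("C", 10), collapse = ""), "ATGGAATGGTAA",
                paste(rep("C", 10), collapse = ""))
  gm <- data.frame(start = 11L, end = 22L, strand = "+", ID = "g1")
  # GAA -> GAG at codon position 3: synonymous (Glu), LOW
  v1 <- annotate_variant_effect(data.frame(pos = 16L, ref = "A", alt = "G"), gm, ref)
  expect_equal(v1$effect, "synonymous")
  expect_equal(v1$impact, "LOW")
  # TGG -> TGA: stop gained, HIGH
  v2 <- annotate_variant_effect(data.frame(pos = 19L, ref = "G", alt = "A"), gm, ref)
  expect_equal(v2$effect, "stop_gained")
  expect_equal(v2$impact, "HIGH")
  # TAA -> CAA: stop lost, HIGH
  v3 <- annotate_variant_effect(data.frame(pos = 20L, ref = "T", alt = "C"), gm, ref)
  expect_equal(v3$effect, "stop_lost")
  # ATG -> ATA: start lost, HIGH
  v4 <- annotate_variant_effect(data.frame(pos = 13L, ref = "G", alt = "A"), gm, ref)
  expect_equal(v4$effect, "start_lost")
  # outside any gene: intergenic, MODIFIER
  v5 <- annotate_variant_effect(data.frame(pos = 2L, ref = "C", alt = "A"), gm, ref)
  expect_equal(v5$effect, "intergenic")
  expect_equal(v5$impact, "MODIFIER")
  expect_error(annotate_variant_effect(data.frame(pos = 99L, ref = "C", alt = "A"),
                                       gm, ref), "outside")
})

test_that("effect classifier agrees with translate-and-compare on sampled codons", {
  set.seed(84)
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  codons <- c("TGG", "TAA", "GAA", sample(codons, 9))  # keep stop/classic cases
  bases <- c("A", "C", "G", "T")
  for (strand in c("+", "-")) {
    for (cod in codons) {
      gene_fwd <- paste0("ATG", cod, "GGCTAA")  # ATG <codon> GGC TAA
      ref <- if (strand == "+") {
        paste0("CCCCC", gene_fwd, "CCCCC")
      } else {
        paste0("CCCCC",
               as.character(Biostrings::reverseComplement(Biostrings::DNAString(gene_fwd))),
               "CCCCC")
      }
      gm <- data.frame(start = 6L, end = 17L, strand = strand, ID = "g")
      for (wi in 0:2) {
        pos_in_gene <- 3L + wi          # 0-based offset of codon 2
        pos <- if (strand == "+") 6L + pos_in_gene else 17L - pos_in_gene
        ref_base <- substr(ref, pos, pos)
        for (alt in setdiff(bases, ref_base)) {
          got <- annotate_variant_effect(
            data.frame(pos = pos, ref = ref_base, alt = alt), gm, ref)
          # oracle: full-gene translation with and without the variant
          mut <- ref
          substr(mut, pos, pos) <- alt
          gseq <- function(s) {
            x <- substr(s, 6, 17)
            if (strand == "-") {
              x <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
            }
            x
          }
          aa_ref <- bs_translate(gseq(ref))
          aa_alt <- bs_translate(gseq(mut))
          cr <- substr(aa_ref, 2, 2); ca <- substr(aa_alt, 2, 2)
          oracle <- if (cr != "*" && ca == "*") "stop_gained" else
            if (cr == "*" && ca != "*") "stop_lost" else
              if (cr == ca) "synonymous" else "missense"
          expect_equal(got$effect, oracle,
                       label = paste(strand, cod, wi, alt))
        }
      }
    }
  }
})

test_that("neighbor joining recovers additive four-taxon trees exactly", {
  # tree ((A:1,B:2):3,(C:4,D:5)) -> additive distances
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A","B"] <- d["B","A"] <- 3
  d["A","C"] <- d["C","A"] <- 8;  d["A","D"] <- d["D","A"] <- 9
  d["B","C"] <- d["C","B"] <- 9;  d["B","D"] <- d["D","B"] <- 10
  d["C","D"] <- d["D","C"] <- 9
  st <- snp_distance_tree(d)
  patristic <- ape::cophenetic.phylo(st$tree)[LETTERS[1:4], LETTERS[1:4]]
  expect_true(all(abs(patristic - d) < 1e-9))
  expect_error(snp_distance_tree(d[1:2, 1:2]), "three")
})

test_that("planted clades are monophyletic in the SNP tree", {
  set.seed(85)
  root <- rand_dna(40000)
  clades <- lapply(1:3, function(i) mutate_sequence(root, 0.01)$seq)
  genomes <- list()
  for (ci in 1:3) {
    for (s in 1:4) {
      genomes[[sprintf("c%ds%d", ci, s)]] <- mutate_sequence(clades[[ci]], 0.001)$seq
    }
  }
  calls <- lapply(names(genomes), function(g)
    call_snps(setNames(genomes[g], g), c(root = root)))
  names(calls) <- names(genomes)
  st <- snp_distance_tree(calls, k = 3)
  truth <- rep(1:3, each = 4)
  names(truth) <- names(genomes)
  expect_equal(mclust::adjustedRandIndex(st$clades[names(truth)], truth), 1.0)
  # monophyly of each clade in the NJ tree (root at a tip of another clade)
  for (ci in 1:3) {
    tips <- names(truth)[truth == ci]
    out <- names(truth)[truth != ci][1]
    rooted <- ape::root(st$tree, outgroup = out, resolve.root = TRUE)
    expect_true(ape::is.monophyletic(rooted, tips), label = paste("clade", ci))
  }
})

test_that("gene variant density bins counts and finds stop carriers", {
  ref <- paste0(paste(rep("C", 10), collapse = ""), "ATGGAATGGAAATAA",
                paste(rep("C", 10), collapse = ""))
  gm <- data.frame(start = 11L, end = 25L, strand = "+", ID = "g1")
  mk <- function(df) annotate_variant_effect(df, gm, ref)
  ann <- list(
    a = mk(data.frame(pos = 19L, ref = "G", alt = "A")),   # stop gained
    b = mk(data.frame(pos = 16L, ref = "A", alt = "G")),   # synonymous
    c = mk(data.frame(pos = integer(0), ref = character(0), alt = character(0))))
  gv <- gene_variant_density(ann, "g1", gm, bin = 5)
  expect_equal(sum(gv$histogram), 2)
  expect_equal(gv$stop_carrier_fraction, 1 / 3)
  clades <- c(a = 1, b = 1, c = 2)
  gv2 <- gene_variant_density(ann, "g1", gm, bin = 5, clades = clades)
  expect_equal(unname(gv2$stop_carrier_by_clade), c(0.5, 0))
  # no variants anywhere: zero histogram
  gv3 <- gene_variant_density(ann["c"], "g1", gm)
  expect_true(all(gv3$histogram == 0) && gv3$stop_carrier_fraction == 0)
  expect_error(gene_variant_density(ann, "nope", gm), "unknown")
})

test_that("VCF output is well-formed and round-trips through a VCF parser", {
  ref <- paste0(paste(rep("C", 10), collapse = ""), "ATGGAATGGTAA",
                paste(rep("C", 10), collapse = ""))
  gm <- data.frame(start = 11L, end = 22L, strand = "+", ID = "g1")
  av <- annotate_variant_effect(
    data.frame(pos = c(2L, 16L, 19L), ref = c("C", "A", "G"),
               alt = c("A", "G", "A")), gm, ref)
  path <- tempfile(fileext = ".vcf")
  write_vcf(av, path, chrom = "contig1", sample_id = "gX")
  lines <- readLines(path)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- read.delim(path, comment.char = "#", header = FALSE)
  expect_equal(nrow(body), 3L)
  expect_equal(body$V2, c(2L, 16L, 19L))
  expect_true(grepl("IMPACT=HIGH", body$V8[3]))
})
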