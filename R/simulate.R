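# Synthetic genome-collection generator with planted ground truth.
#
# The generator emulates the study conditions downstream stages are exercised
# under: multi-species strain collections at controlled nucleotide divergence,
# per-genome gene gain/loss over a shared family pool, planted pathway /
# 16S genes at controlled identity to references, and negative-binomial count
# tables with planted group fold-changes. Mutation is substitution-only so
# nucleotide-level truth (ANI, SNPs) is exactly columnwise.

#' Configuration for the synthetic genome-collection generator
#'
#' @param n_species Number of species (independent ancestors mutated from a
#'   shared root).
#' @param strains_per_species Strains per species, each an independently
#'   mutated copy of its species ancestor.
#' @param genome_length Genome length in bp (one contig).
#' @param within_species_divergence Per-site substitution fraction applied to
#'   each strain relative to its species ancestor.
#' @param between_species_divergence Per-site substitution fraction applied to
#'   each species ancestor relative to the shared root; pairwise
#'   between-species divergence is therefore approximately twice this value,
#'   and the truth object records it empirically.
#' @param core_families Number of gene families present in every genome.
#' @param accessory_families Number of gene families subject to gain/loss.
#' @param accessory_retention_prob Probability that a genome retains a given
#'   accessory family (ignored when `accessory_presence_count` is set).
#' @param accessory_presence_count Optional integer: each accessory family is
#'   planted in exactly this many genomes (exact prevalence, no sampling
#'   noise).
#' @param accessory_loss `"annotation"` (default): a lost family is simply
#'   omitted from the genome's annotation and protein set, the chromosomal
#'   span is retained so nucleotide truth stays exactly columnwise;
#'   `"scramble"`: the span is additionally replaced by random sequence
#'   (sequence-level loss; scrambled spans are reported in
#'   `truth$lost_regions`).
#' @param gene_length_range Two integers, bounds (bp) for gene lengths; drawn
#'   uniformly and rounded to codon multiples.
#' @param planted_pathway_identities Optional named numeric vector mapping
#'   enzyme labels (e.g. `"Pct"`) to the target protein identity fraction of
#'   the copy planted in every genome.
#' @param planted_16s_identities Optional numeric vector (length
#'   `n_species`): identity of each species' planted 16S gene to its
#'   synthetic reference.
#' @param reverse_strand_frac Fraction of gene families placed on the reverse
#'   strand (0 by default).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A validated `sim_config` object (a list).
#' @export
sim_config <- function(n_species = 3L,
                       strains_per_species = 4L,
                       genome_length = 100000L,
                       within_species_divergence = 0.01,
                       between_species_divergence = 0.15,
                       core_families = 100L,
                       accessory_families = 50L,
                       accessory_retention_prob = 0.5,
                       accessory_presence_count = NULL,
                       accessory_loss = c("annotation", "scramble"),
                       gene_length_range = c(300L, 600L),
                       planted_pathway_identities = NULL,
                       planted_16s_identities = NULL,
                       reverse_strand_frac = 0,
                       seed = 1L) {
  accessory_loss <- match.arg(accessory_loss)
  if (n_species < 1L || strains_per_species < 1L) {
    stop("need at least one species and one strain per species")
  }
  for (d in c(within_species_divergence, between_species_divergence)) {
    if (d < 0 || d > 0.75) stop("divergence must be in [0, 0.75]")
  }
  if (within_species_divergence >= between_species_divergence &&
      n_species > 1L) {
    stop("within-species divergence must be below between-species divergence")
  }
  stop_if_not_fraction(accessory_retention_prob, "accessory_retention_prob")
  stop_if_not_fraction(reverse_strand_frac, "reverse_strand_frac")
  if (!is.null(planted_pathway_identities)) {
    stop_if_not_fraction(planted_pathway_identities, "planted_pathway_identities")
    if (is.null(names(planted_pathway_identities))) {
      stop("planted_pathway_identities must be named by enzyme label")
    }
  }
  if (!is.null(planted_16s_identities)) {
    stop_if_not_fraction(planted_16s_identities, "planted_16s_identities")
    if (length(planted_16s_identities) != n_species) {
      stop("planted_16s_identities must have one entry per species")
    }
  }
  if (length(gene_length_range) != 2L || gene_length_range[1] > gene_length_range[2] ||
      gene_length_range[1] < 60L) {
    stop("gene_length_range must be an increasing pair of lengths >= 60")
  }
  structure(list(
    n_species = as.integer(n_species),
    strains_per_species = as.integer(strains_per_species),
    genome_length = as.integer(genome_length),
    within_species_divergence = within_species_divergence,
    between_species_divergence = between_species_divergence,
    core_families = as.integer(core_families),
    accessory_families = as.integer(accessory_families),
    accessory_retention_prob = accessory_retention_prob,
    accessory_presence_count = accessory_presence_count,
    accessory_loss = accessory_loss,
    gene_length_range = as.integer(gene_length_range),
    planted_pathway_identities = planted_pathway_identities,
    planted_16s_identities = planted_16s_identities,
    reverse_strand_frac = reverse_strand_frac,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Apply random substitutions to a nucleotide sequence
#'
#' The number of substituted sites is Binomial(length, rate); substituted
#' bases are drawn uniformly over the three other bases, so every recorded
#' variant has `ref != alt`.
#'
#' @param seq A single nucleotide string.
#' @param rate Substitution fraction per site, in `[0, 0.75]`.
#' @param seed Optional seed (local to this call).
#' @param strict If `TRUE` (default) non-ACGT characters are rejected;
#'   otherwise they are passed through unchanged and never mutated.
#' @return `list(seq = mutated string, variants = data.frame(pos, ref, alt))`
#'   with 1-based positions.
#' @export
mutate_sequence <- function(seq, rate, seed = NULL, strict = TRUE) {
  if (rate < 0 || rate > 0.75) stop("rate must be in [0, 0.75]")
  n <- nchar(seq)
  raw <- strsplit(seq, "")[[1]]
  valid <- which(raw %in% DNA_BASES)
  if (strict && length(valid) < n) stop("non-ACGT characters in input")
  with_seed(seed, {
    n_mut <- rbinom(1L, length(valid), rate)
    if (n_mut == 0L) {
      list(seq = seq,
           variants = data.frame(pos = integer(0), ref = character(0),
                                 alt = character(0)))
    } else {
      pos <- sort(sample(valid, n_mut))
      ref <- raw[pos]
      alt <- OTHER_BASES[cbind(match(ref, DNA_BASES),
                               sample.int(3L, n_mut, replace = TRUE))]
      raw[pos] <- alt
      list(seq = paste(raw, collapse = ""),
           variants = data.frame(pos = pos, ref = unname(ref), alt = unname(alt)))
    }
  })
}

# Substitute exactly n_sub positions (used to plant sequences at an exact
# identity); alphabet is the residue set to draw replacements from.
mutate_exact <- function(seq, n_sub, alphabet = DNA_BASES) {
  raw <- strsplit(seq, "")[[1]]
  if (n_sub == 0L) return(seq)
  pos <- sample(length(raw), n_sub)
  raw[pos] <- vapply(raw[pos], function(b) sample(setdiff(alphabet, b), 1L),
                     character(1))
  paste(raw, collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Random ORF: ATG + non-stop internal codons + TAA; len_nt rounded down to a
# codon multiple >= 9.
random_orf <- function(len_nt) {
  len_nt <- max(9L, (len_nt %/% 3L) * 3L)
  n_internal <- len_nt / 3L - 2L
  codons <- apply(matrix(sample(DNA_BASES, 3L * n_internal, replace = TRUE),
                         nrow = 3L), 2L, paste, collapse = "")
  bad <- codons %in% STOP_CODONS
  while (any(bad)) {
    codons[bad] <- apply(matrix(sample(DNA_BASES, 3L * sum(bad), replace = TRUE),
                                nrow = 3L), 2L, paste, collapse = "")
    bad <- codons %in% STOP_CODONS
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

random_protein <- function(len_aa) {
  paste(sample(AA20, len_aa, replace = TRUE), collapse = "")
}

# Reverse-translate a protein with uniformly chosen synonymous codons
# (translation table 11), appending a TAA stop.
reverse_translate <- function(protein) {
  code <- genetic_code_11()
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(a) {
    opts <- names(code)[code == a & !names(code) %in% STOP_CODONS]
    if (length(opts) == 0L) stop("cannot encode residue ", a)
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1))
  paste0(paste(codons, collapse = ""), "TAA")
}

genetic_code_11 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- Biostrings::getGeneticCode("11")
    cache
  }
})

# Translate a CDS (nucleotide string, forward orientation) with table 11.
translate_cds <- function(nt) {
  n <- (nchar(nt) %/% 3L) * 3L
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  code <- genetic_code_11()
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

str_assign <- function(s, start, replacement) {
  # overwrite s[start .. start+nchar(replacement)-1] with replacement
  paste0(substr(s, 1L, start - 1L), replacement,
         substr(s, start + nchar(replacement), nchar(s)))
}

#' Generate a synthetic genome collection with planted truth
#'
#' Builds a shared root genome carrying all gene families, derives one
#' ancestor per species by mutating the root at the between-species rate, and
#' one strain per genome by mutating its ancestor at the within-species rate
#' (substitutions only). Accessory families are dropped per genome; pathway
#' and 16S genes are planted per genome at their configured exact identity to
#' synthetic references. All randomness is governed by `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @param gene_names Optional named character vector mapping family ids
#'   (`"F0001"`, ...) to gene names used in the annotation `gene` attribute.
#' @return A `genome_collection` list with elements `genomes` (named vector of
#'   sequences), `annotations` (per-genome feature data frames),
#'   `proteins` / `genes_nt` (per-genome named vectors), `r16s` and
#'   `r16s_refs`, `enzyme_refs`, `metadata` (data frame), `root`,
#'   `ancestors`, `truth` (species_of, family_presence, variants,
#'   variants_vs_root, planted_pathway, planted_16s, lost_regions) and
#'   `config`.
#' @export
simulate_collection <- function(config, gene_names = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_collection_impl(config, gene_names))
}

simulate_collection_impl <- function(config, gene_names) {
  ns <- config$n_species
  nst <- config$strains_per_species
  n_genomes <- ns * nst
  genome_ids <- as.vector(vapply(seq_len(ns), function(s) {
    sprintf("S%02dG%02d", s, seq_len(nst))
  }, character(nst)))
  species_of <- setNames(rep(seq_len(ns), each = nst), genome_ids)

  n_fam <- config$core_families + config$accessory_families
  fam_ids <- sprintf("F%04d", seq_len(n_fam))
  is_core <- c(rep(TRUE, config$core_families), rep(FALSE, config$accessory_families))

  # --- layout: genes, pathway slots, 16S slot, spacers -----------------------
  lr <- config$gene_length_range
  fam_len <- (sample(lr[1]:lr[2], n_fam, replace = TRUE) %/% 3L) * 3L
  labels <- names(config$planted_pathway_identities)
  enz_len_aa <- if (length(labels)) rep(300L, length(labels)) else integer(0)
  slot_lens <- c(fam_len,
                 if (length(labels)) enz_len_aa * 3L + 3L,
                 if (!is.null(config$planted_16s_identities)) 1550L)
  spacers <- sample(20:100, length(slot_lens), replace = TRUE)
  starts <- cumsum(c(1L, head(slot_lens + spacers, -1L)))
  ends <- starts + slot_lens - 1L
  if (max(ends) > config$genome_length) {
    stop("genome_length too small for the configured genes (need >= ",
         max(ends), " bp)")
  }
  fam_start <- starts[seq_len(n_fam)]
  fam_end <- ends[seq_len(n_fam)]
  idx <- n_fam
  if (length(labels)) {
    enz_start <- starts[idx + seq_along(labels)]
    enz_end <- ends[idx + seq_along(labels)]
    idx <- idx + length(labels)
  }
  if (!is.null(config$planted_16s_identities)) {
    r16_start <- starts[idx + 1L]
    r16_end <- ends[idx + 1L]
  }
  fam_strand <- ifelse(runif(n_fam) < config$reverse_strand_frac, "-", "+")

  # --- root genome -----------------------------------------------------------
  root <- random_dna(config$genome_length)
  fam_seq_root <- vapply(fam_len, random_orf, character(1))
  for (i in seq_len(n_fam)) {
    s <- if (fam_strand[i] == "-") revcomp_fast(fam_seq_root[i]) else fam_seq_root[i]
    root <- str_assign(root, fam_start[i], s)
  }

  # --- species ancestors and strains ----------------------------------------
  ancestors <- character(ns)
  for (s in seq_len(ns)) {
    ancestors[s] <- mutate_sequence(root, config$between_species_divergence)$seq
  }
  names(ancestors) <- sprintf("S%02d", seq_len(ns))

  # --- accessory presence ----------------------------------------------------
  presence <- matrix(TRUE, nrow = n_fam, ncol = n_genomes,
                     dimnames = list(fam_ids, genome_ids))
  acc_idx <- which(!is_core)
  if (length(acc_idx)) {
    if (!is.null(config$accessory_presence_count)) {
      k <- as.integer(config$accessory_presence_count)
      if (k < 1L || k > n_genomes) stop("accessory_presence_count out of range")
      for (f in acc_idx) {
        present <- sample(n_genomes, k)
        presence[f, ] <- FALSE
        presence[f, present] <- TRUE
      }
    } else {
      presence[acc_idx, ] <-
        matrix(runif(length(acc_idx) * n_genomes) < config$accessory_retention_prob,
               nrow = length(acc_idx))
    }
  }

  # --- enzyme / 16S references ----------------------------------------------
  enzyme_refs <- NULL
  if (length(labels)) {
    enzyme_refs <- setNames(vapply(enz_len_aa, random_protein, character(1)), labels)
  }
  r16s_refs <- NULL
  if (!is.null(config$planted_16s_identities)) {
    r16s_refs <- setNames(vapply(rep(1550L, ns), random_dna, character(1)),
                          sprintf("ref16S_S%02d", seq_len(ns)))
  }

  # --- per-genome assembly ---------------------------------------------------
  genomes <- setNames(character(n_genomes), genome_ids)
  annotations <- vector("list", n_genomes); names(annotations) <- genome_ids
  proteins <- vector("list", n_genomes); names(proteins) <- genome_ids
  genes_nt <- vector("list", n_genomes); names(genes_nt) <- genome_ids
  r16s <- character(0)
  planted_pathway <- NULL
  planted_16s <- NULL
  lost_regions <- NULL
  variants <- vector("list", n_genomes); names(variants) <- genome_ids

  rraw <- charToRaw(root)
  code <- genetic_code_11()

  for (g in seq_len(n_genomes)) {
    gid <- genome_ids[g]
    sp <- species_of[[gid]]
    seq <- mutate_sequence(ancestors[sp], config$within_species_divergence)$seq

    # plant pathway genes at exact protein identity
    if (length(labels)) {
      for (li in seq_along(labels)) {
        ref <- enzyme_refs[[li]]
        t_id <- config$planted_pathway_identities[[labels[li]]]
        n_sub <- round((1 - t_id) * nchar(ref))
        prot <- mutate_exact(ref, n_sub, alphabet = AA20)
        nt <- reverse_translate(prot) # slot length = enz_len_aa codons + stop
        seq <- str_assign(seq, enz_start[li], nt)
        planted_pathway <- rbind(planted_pathway,
          data.frame(genome = gid, label = labels[li],
                     identity = 1 - n_sub / nchar(ref)))
      }
    }

    # plant 16S at exact identity to the species reference
    if (!is.null(config$planted_16s_identities)) {
      ref <- r16s_refs[[sp]]
      t_id <- config$planted_16s_identities[[sp]]
      n_sub <- round((1 - t_id) * nchar(ref))
      s16 <- mutate_exact(ref, n_sub)
      seq <- str_assign(seq, r16_start, s16)
      r16s[gid] <- s16
      planted_16s <- rbind(planted_16s,
        data.frame(genome = gid, ref = names(r16s_refs)[sp],
                   identity = 1 - n_sub / nchar(ref)))
    }

    # accessory loss
    lost <- which(!presence[, g])
    if (config$accessory_loss == "scramble" && length(lost)) {
      for (f in lost) {
        seq <- str_assign(seq, fam_start[f], random_dna(fam_len[f]))
        lost_regions <- rbind(lost_regions,
          data.frame(genome = gid, family = fam_ids[f],
                     start = fam_start[f], end = fam_end[f]))
      }
    }

    genomes[gid] <- seq

    # variants vs species ancestor and vs root, columnwise (exact truth)
    sraw <- charToRaw(seq)
    araw <- charToRaw(ancestors[sp])
    d <- which(sraw != araw)
    variants[[gid]] <- data.frame(
      pos = d,
      ref = strsplit(rawToChar(araw[d]), "")[[1]] %||% character(0),
      alt = strsplit(rawToChar(sraw[d]), "")[[1]] %||% character(0))

    # annotation + emitted genes/proteins for present families
    pres <- which(presence[, g])
    gene_attr <- if (!is.null(gene_names)) {
      ifelse(fam_ids[pres] %in% names(gene_names),
             gene_names[fam_ids[pres]], fam_ids[pres])
    } else fam_ids[pres]
    feats <- data.frame(
      seqid = gid, source = "panlachno_sim", type = "CDS",
      start = fam_start[pres], end = fam_end[pres],
      score = NA, strand = fam_strand[pres], phase = 0L,
      ID = paste0(gid, "_", fam_ids[pres]),
      gene = unname(gene_attr),
      product = "hypothetical protein",
      family = fam_ids[pres],
      stringsAsFactors = FALSE)
    if (length(labels)) {
      feats <- rbind(feats, data.frame(
        seqid = gid, source = "panlachno_sim", type = "CDS",
        start = enz_start, end = enz_end, score = NA, strand = "+",
        phase = 0L, ID = paste0(gid, "_", labels),
        gene = labels, product = paste0(labels, " enzyme"),
        family = labels, stringsAsFactors = FALSE))
    }
    if (!is.null(config$planted_16s_identities)) {
      feats <- rbind(feats, data.frame(
        seqid = gid, source = "panlachno_sim", type = "rRNA",
        start = r16_start, end = r16_end, score = NA, strand = "+",
        phase = NA, ID = paste0(gid, "_16S"), gene = "rrs",
        product = "16S ribosomal RNA", family = NA, stringsAsFactors = FALSE))
    }
    annotations[[gid]] <- feats

    cds <- feats[feats$type == "CDS", ]
    nts <- vapply(seq_len(nrow(cds)), function(i) {
      sub <- substr(seq, cds$start[i], cds$end[i])
      if (cds$strand[i] == "-") revcomp_fast(sub) else sub
    }, character(1))
    names(nts) <- cds$ID
    genes_nt[[gid]] <- nts
    prots <- vapply(nts, function(nt) sub("\\*$", "", translate_cds(nt)), character(1))
    proteins[[gid]] <- prots
  }

  # variants vs root (columnwise against emitted sequence)
  variants_vs_root <- lapply(genomes, function(seq) {
    sraw <- charToRaw(seq)
    d <- which(sraw != rraw)
    data.frame(pos = d,
               ref = strsplit(rawToChar(rraw[d]), "")[[1]] %||% character(0),
               alt = strsplit(rawToChar(sraw[d]), "")[[1]] %||% character(0))
  })

  habitats <- c("human_gut", "animal_gut", "environment")
  countries <- c("China", "Denmark", "USA", "UK", "Japan", "Germany")
  sp_habitat <- sample(habitats, ns, replace = TRUE)
  metadata <- data.frame(
    genome = genome_ids,
    species = sprintf("S%02d", species_of),
    habitat = sp_habitat[species_of],
    country = sample(countries, n_genomes, replace = TRUE),
    source = "synthetic",
    stringsAsFactors = FALSE)

  gene_models <- annotations[[1]][annotations[[1]]$type == "CDS",
                                  c("seqid", "start", "end", "strand", "ID",
                                    "gene", "family")]

  structure(list(
    genomes = genomes,
    annotations = annotations,
    proteins = proteins,
    genes_nt = genes_nt,
    r16s = r16s,
    r16s_refs = r16s_refs,
    enzyme_refs = enzyme_refs,
    metadata = metadata,
    root = root,
    ancestors = ancestors,
    gene_models = gene_models,
    truth = list(
      species_of = species_of,
      family_presence = presence,
      family_is_core = setNames(is_core, fam_ids),
      variants = variants,
      variants_vs_root = variants_vs_root,
      planted_pathway = planted_pathway,
      planted_16s = planted_16s,
      lost_regions = lost_regions),
    config = config
  ), class = "genome_collection")
}

#' Simulate a genome-by-sample abundance study with planted fold-changes
#'
#' Counts are negative binomial with group means `mean * 2^(effect/2)` (case)
#' and `mean * 2^(-effect/2)` (control), so the true case/control fold-change
#' of a genome is `2^effect`. Dispersion 0 degenerates to Poisson.
#'
#' @param n_samples_per_group Samples per group (>= 1).
#' @param genomes Character vector of genome ids (rows).
#' @param effect Named numeric vector of true log2 fold-changes (genomes not
#'   named get 0), or a single number recycled.
#' @param mean Expected baseline count (> 0).
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2), >= 0.
#' @param seed Integer seed.
#' @return An `abundance_study` list: integer `counts` matrix
#'   (genome x sample), `groups` (factor, levels `control`, `case`),
#'   `library_sizes`, and `truth_lfc`.
#' @export
simulate_abundance_study <- function(n_samples_per_group, genomes,
                                     effect = 0, mean = 200,
                                     dispersion = 0.1, seed = 1L) {
  if (n_samples_per_group < 1L) stop("need at least one sample per group")
  if (mean <= 0) stop("mean must be positive")
  if (dispersion < 0) stop("dispersion must be >= 0")
  ng <- length(genomes)
  if (length(effect) == 1L && is.null(names(effect))) {
    effect <- setNames(rep(effect, ng), genomes)
  } else {
    full <- setNames(rep(0, ng), genomes)
    full[names(effect)] <- effect
    effect <- full
  }
  n <- as.integer(n_samples_per_group)
  with_seed(seed, {
    mu_case <- mean * 2^(effect / 2)
    mu_ctrl <- mean * 2^(-effect / 2)
    draw <- function(mu, nn) {
      if (dispersion == 0) rpois(nn, mu) else rnbinom(nn, mu = mu, size = 1 / dispersion)
    }
    counts <- matrix(0L, nrow = ng, ncol = 2L * n,
                     dimnames = list(genomes,
                                     c(sprintf("ctrl%02d", seq_len(n)),
                                       sprintf("case%02d", seq_len(n)))))
    for (i in seq_len(ng)) {
      counts[i, ] <- c(draw(mu_ctrl[i], n), draw(mu_case[i], n))
    }
    groups <- factor(rep(c("control", "case"), each = n),
                     levels = c("control", "case"))
    structure(list(counts = counts, groups = groups,
                   library_sizes = colSums(counts),
                   truth_lfc = effect),
              class = "abundance_study")
  })
}

#' Write a genome collection to disk
#'
#' Emits one genome FASTA and one GFF3 per genome, a combined protein FASTA,
#' 16S FASTA files where planted, metadata and truth tables as TSV. Output is
#' byte-identical for a fixed generator seed.
#'
#' @param collection A [simulate_collection()] result.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_collection <- function(collection, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (gid in names(collection$genomes)) {
    write_fasta(setNames(collection$genomes[gid], gid),
                file.path(outdir, paste0(gid, ".fasta")))
    write_gff3(collection$annotations[[gid]],
               file.path(outdir, paste0(gid, ".gff3")))
  }
  prots <- unlist(unname(collection$proteins))
  if (length(prots)) write_fasta(prots, file.path(outdir, "proteins.faa"))
  if (length(collection$r16s)) {
    write_fasta(collection$r16s, file.path(outdir, "r16s.fasta"))
    write_fasta(collection$r16s_refs, file.path(outdir, "r16s_refs.fasta"))
  }
  write.table(collection$metadata, file.path(outdir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth_sp <- data.frame(genome = names(collection$truth$species_of),
                         species = collection$truth$species_of)
  write.table(truth_sp, file.path(outdir, "truth_species.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
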