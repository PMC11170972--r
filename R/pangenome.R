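# Greedy incremental gene-family clustering (the common engine behind
# CD-HIT-, linclust- and Roary-style catalogs), prevalence partitioning,
# accumulation curves, and Jaccard-based lineage divergence.

#' Parameters for greedy gene-family clustering
#'
#' Presets mirror the three catalog constructions used in practice:
#' `"gene_catalog"` (nucleotide, identity 0.95, coverage 0.90 of the shorter
#' sequence), `"protein_catalog"` (amino acid, identity 0.95, coverage 0.80
#' of the target/representative), `"pangenome"` (nucleotide, identity 0.90,
#' no coverage requirement).
#'
#' @param identity Identity fraction in (0, 1].
#' @param coverage Coverage fraction in \[0, 1\].
#' @param coverage_mode `"shorter_sequence"` or `"target_sequence"`.
#' @param alphabet `"nt"` or `"aa"`.
#' @param preset Optional preset name; overrides the other arguments.
#' @return A `clustering_params` list.
#' @export
clustering_params <- function(identity = 0.95, coverage = 0.9,
                              coverage_mode = c("shorter_sequence", "target_sequence"),
                              alphabet = c("nt", "aa"),
                              preset = NULL) {
  if (!is.null(preset)) {
    return(switch(match.arg(preset, c("gene_catalog", "protein_catalog", "pangenome")),
      gene_catalog = clustering_params(0.95, 0.90, "shorter_sequence", "nt"),
      protein_catalog = clustering_params(0.95, 0.80, "target_sequence", "aa"),
      pangenome = clustering_params(0.90, 0, "shorter_sequence", "nt")))
  }
  coverage_mode <- match.arg(coverage_mode)
  alphabet <- match.arg(alphabet)
  if (identity <= 0 || identity > 1) stop("identity must be in (0, 1]")
  if (coverage < 0 || coverage > 1) stop("coverage must be in [0, 1]")
  structure(list(identity = identity, coverage = coverage,
                 coverage_mode = coverage_mode, alphabet = alphabet),
            class = "clustering_params")
}

# Global-alignment identity and coverage between a sequence and a
# representative. Coverage is the fraction of residues of the shorter (or
# target) sequence aligned to residues of the other.
pair_identity_coverage <- function(s, rep, params) {
  al <- if (params$alphabet == "aa") {
    cpp_global_align(s, rep, gap_open = 11L, gap_ext = 1L, blosum = TRUE)
  } else {
    cpp_global_align(s, rep, match = 2L, mismatch = -3L,
                     gap_open = 5L, gap_ext = 2L, blosum = FALSE)
  }
  denom <- if (params$coverage_mode == "shorter_sequence") {
    min(nchar(s), nchar(rep))
  } else {
    nchar(rep)
  }
  list(identity = al$matches / al$columns,
       coverage = al$aligned_pairs / denom)
}

#' Cluster sequences into gene families (greedy incremental)
#'
#' Sequences are sorted by length (descending, ties by id). Each sequence
#' joins the earliest-founded representative it matches at the configured
#' identity and coverage, else founds a new family. Candidate
#' representatives are prefiltered by shared k-mers; identity is
#' matches/alignment-columns of a global alignment.
#'
#' @param sequences Named character vector of gene (nt) or protein (aa)
#'   sequences.
#' @param genome_of Named character vector mapping sequence id to genome id.
#' @param params [clustering_params()].
#' @return A `family_matrix` (see [family_matrix()]), with `membership`
#'   (sequence id to family id) and `representative` per family.
#' @export
cluster_gene_families <- function(sequences, genome_of,
                                  params = clustering_params()) {
  if (length(sequences) == 0L) stop("empty sequence set")
  if (is.null(names(sequences))) stop("sequences must be named")
  if (any(!names(sequences) %in% names(genome_of))) {
    stop("every sequence needs a genome-of-origin label")
  }
  looks_aa <- any(grepl("[EFILPQZ]", toupper(substr(sequences, 1, 200))))
  if (params$alphabet == "nt" && looks_aa) {
    stop("sequence alphabet does not match params$alphabet = 'nt'")
  }
  k <- if (params$alphabet == "aa") 5L else 12L
  min_shared <- 2L
  ord <- order(-nchar(sequences), names(sequences))
  ids <- names(sequences)[ord]

  rep_ids <- character(0)
  kmer_env <- new.env(hash = TRUE, parent = emptyenv())
  membership <- setNames(integer(length(sequences)), names(sequences))

  for (id in ids) {
    s <- sequences[[id]]
    km <- unique(kmers_of(toupper(s), k))
    # query every other k-mer against the representative index; at the
    # identities of interest (>= 0.90) shared k-mers are abundant
    qkm <- km[seq(1L, length(km), by = 2L)]
    cand <- integer(0)
    if (length(rep_ids)) {
      hits <- unlist(mget(qkm, envir = kmer_env, ifnotfound = list(NULL)),
                     use.names = FALSE)
      if (length(hits)) {
        tab <- tabulate(hits, nbins = length(rep_ids))
        cand <- which(tab >= min_shared)
      }
    }
    assigned <- 0L
    for (ci in cand) {
      pc <- pair_identity_coverage(s, sequences[[rep_ids[ci]]], params)
      if (pc$identity >= params$identity && pc$coverage >= params$coverage) {
        assigned <- ci
        break
      }
    }
    if (assigned == 0L) {
      rep_ids <- c(rep_ids, id)
      assigned <- length(rep_ids)
      for (x in km) kmer_env[[x]] <- c(kmer_env[[x]], assigned)
    }
    membership[id] <- assigned
  }

  fam_ids <- sprintf("FAM%05d", seq_along(rep_ids))
  mem_fam <- setNames(fam_ids[membership], names(membership))
  genomes <- sort(unique(unname(genome_of[names(sequences)])))
  presence <- matrix(FALSE, nrow = length(fam_ids), ncol = length(genomes),
                     dimnames = list(fam_ids, genomes))
  gx <- cbind(membership[names(sequences)],
              match(genome_of[names(sequences)], genomes))
  presence[gx] <- TRUE
  family_matrix(presence,
                representative = setNames(rep_ids, fam_ids),
                membership = mem_fam)
}

#' Construct a gene-family presence/absence matrix object
#'
#' @param presence Logical matrix, families x genomes, with dimnames.
#' @param representative Optional named vector of representative sequence ids.
#' @param membership Optional named vector mapping sequence id to family id.
#' @return A `family_matrix` list: `presence`, `prevalence` (row means),
#'   `families` data frame, `membership`.
#' @export
family_matrix <- function(presence, representative = NULL, membership = NULL) {
  stopifnot(is.matrix(presence), is.logical(presence),
            !is.null(rownames(presence)), !is.null(colnames(presence)))
  prevalence <- rowMeans(presence)
  n_members <- if (!is.null(membership)) {
    tab <- table(membership)
    as.integer(tab[rownames(presence)])
  } else {
    as.integer(rowSums(presence))
  }
  families <- data.frame(family = rownames(presence),
                         representative = if (!is.null(representative)) {
                           unname(representative[rownames(presence)])
                         } else NA_character_,
                         n_members = n_members,
                         prevalence = unname(prevalence),
                         stringsAsFactors = FALSE)
  structure(list(presence = presence, prevalence = prevalence,
                 families = families, membership = membership),
            class = "family_matrix")
}

#' Prevalence category bounds (Roary-style defaults)
#' @param core,soft_core,shell Lower prevalence bounds of the core
#'   (default 0.99), soft-core (0.95) and shell (0.15) categories; cloud is
#'   everything below `shell`.
#' @return Named numeric vector of bounds.
#' @export
prevalence_categories <- function(core = 0.99, soft_core = 0.95, shell = 0.15) {
  if (!(shell < soft_core && soft_core < core)) stop("bounds must increase")
  c(core = core, soft_core = soft_core, shell = shell)
}

#' Classify families into core/soft-core/shell/cloud by prevalence
#'
#' @param fm A [family_matrix()].
#' @param categories [prevalence_categories()].
#' @return List: `category` (factor per family), `counts`, `histogram`
#'   (table of prevalence values), `max_prevalence` (the most prevalent
#'   family's genome fraction, in percent).
#' @export
classify_prevalence <- function(fm, categories = prevalence_categories()) {
  stopifnot(inherits(fm, "family_matrix"))
  p <- fm$prevalence
  cat <- cut(p, breaks = c(-Inf, categories["shell"], categories["soft_core"],
                           categories["core"], Inf),
             labels = c("cloud", "shell", "soft_core", "core"),
             right = FALSE)
  cat <- factor(cat, levels = c("core", "soft_core", "shell", "cloud"))
  names(cat) <- names(p)
  list(category = cat,
       counts = table(cat),
       histogram = table(round(p, 4)),
       max_prevalence = 100 * max(p))
}

#' Pan- and core-genome accumulation curves
#'
#' For each of `n_permutations` random genome orderings, `pan(n)` is the
#' number of families seen in the first `n` genomes and `core(n)` the number
#' present in all of them; the mean over permutations is returned.
#'
#' @param fm A [family_matrix()].
#' @param n_permutations Number of random orderings (default 10).
#' @param seed Integer seed.
#' @return Data frame: `n`, `pan`, `core` (means over permutations).
#' @export
accumulation_curves <- function(fm, n_permutations = 10L, seed = 1L) {
  pres <- fm$presence
  ng <- ncol(pres)
  if (ng < 2L) stop("need at least two genomes")
  with_seed(seed, {
    pan <- core <- matrix(0, n_permutations, ng)
    for (p in seq_len(n_permutations)) {
      ord <- sample(ng)
      seen <- rep(FALSE, nrow(pres))
      inall <- rep(TRUE, nrow(pres))
      for (n in seq_len(ng)) {
        v <- pres[, ord[n]]
        seen <- seen | v
        inall <- inall & v
        pan[p, n] <- sum(seen)
        core[p, n] <- sum(inall)
      }
    }
    data.frame(n = seq_len(ng), pan = colMeans(pan), core = colMeans(core))
  })
}

#' Pairwise Jaccard distances between genomes' family sets
#'
#' `distance(a, b) = 1 - |A intersect B| / |A union B|`, computed with
#' [vegan::vegdist()] (`method = "jaccard", binary = TRUE`) on the
#' genome x family incidence matrix. A genome with zero families is assigned
#' distance 1 to every other genome, with a warning.
#'
#' @param fm A [family_matrix()] (or a logical families x genomes matrix).
#' @return Symmetric numeric distance matrix (genomes x genomes).
#' @export
jaccard_matrix <- function(fm) {
  pres <- if (inherits(fm, "family_matrix")) fm$presence else fm
  x <- t(pres) * 1
  empty <- rowSums(x) == 0
  if (any(empty)) {
    warning("genome(s) with zero families: ",
            paste(rownames(x)[empty], collapse = ", "))
  }
  d <- as.matrix(suppressWarnings(
    vegan::vegdist(x, method = "jaccard", binary = TRUE)))
  d[is.na(d)] <- 1
  diag(d) <- 0
  d
}

#' Within- vs between-branch Jaccard divergence
#'
#' Splits all genome pairs into intra- and inter-branch sets, reports both
#' medians on the percent scale, and a two-sided Wilcoxon rank-sum test
#' (exact when both samples have <= 10 pairs, otherwise the tie-corrected
#' normal approximation).
#'
#' @param jaccard Symmetric Jaccard distance matrix.
#' @param branch_labels Named vector of branch labels for every genome.
#' @return List: `median_within`, `median_between` (percent), `p`,
#'   `n_within`, `n_between`.
#' @export
branch_divergence <- function(jaccard, branch_labels) {
  ids <- rownames(jaccard)
  lab <- branch_labels[ids]
  if (length(unique(lab)) < 2L) stop("need at least two branches")
  if (min(table(lab)) < 2L) stop("need >= 2 genomes per branch")
  iu <- which(upper.tri(jaccard), arr.ind = TRUE)
  same <- lab[iu[, 1]] == lab[iu[, 2]]
  within <- jaccard[iu][same]
  between <- jaccard[iu][!same]
  exact <- length(within) <= 10L && length(between) <= 10L
  wt <- suppressWarnings(
    wilcox.test(within, between, exact = exact, correct = FALSE))
  list(median_within = 100 * median(within),
       median_between = 100 * median(between),
       p = wt$p.value, n_within = length(within), n_between = length(between))
}
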