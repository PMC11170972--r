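# Fragment-mapping average nucleotide identity (ANI), complete-linkage
# species delineation at 95% ANI, and habitat specificity of clusters.
#
# ANI follows the fragment definition used by whole-genome mappers: the query
# is cut into consecutive windows, each window is placed on the reference by
# shared-k-mer seeding and best-diagonal voting, and ANI is 100 x the mean
# identity over windows whose identity clears the mapping floor.

#' Parameters for fragment-mapping ANI
#'
#' @param fragment_length Query window size in bp (default 1000).
#' @param kmer_size Seed k-mer size (default 16).
#' @param min_fragment_identity Identity floor for a fragment to count as
#'   mapped (default 0.80).
#' @param min_mapped_fraction Minimum fraction of fragments mapped for the
#'   estimate to be considered reliable (default 0.2).
#' @param seed_step Spacing between seed k-mers within a fragment.
#' @return An `ani_params` list.
#' @export
ani_params <- function(fragment_length = 1000L, kmer_size = 16L,
                       min_fragment_identity = 0.80,
                       min_mapped_fraction = 0.2,
                       seed_step = 50L) {
  if (fragment_length <= kmer_size) stop("fragment_length must exceed kmer_size")
  stop_if_not_fraction(min_fragment_identity, "min_fragment_identity")
  stop_if_not_fraction(min_mapped_fraction, "min_mapped_fraction")
  structure(list(fragment_length = as.integer(fragment_length),
                 kmer_size = as.integer(kmer_size),
                 min_fragment_identity = min_fragment_identity,
                 min_mapped_fraction = min_mapped_fraction,
                 seed_step = as.integer(seed_step)),
            class = "ani_params")
}

# Precompute a reference k-mer index (positions of each k-mer; collisions in
# random genomes at k=16 are negligible, the first occurrence is kept).
ani_index <- function(ref, k) {
  km <- kmers_of(ref, k)
  list(kmers = km, raw = charToRaw(ref), n = nchar(ref))
}

#' Fragment-mapping ANI of a query genome against a reference
#'
#' @param query,reference Nucleotide sequence strings (a genome each), or
#'   named length-1 character vectors.
#' @param params [ani_params()].
#' @param ref_index Optional precomputed index (internal use by
#'   [ani_matrix()]).
#' @return An `ani_result` list: `query`, `reference`, `ani` (percent, NA if
#'   nothing mapped), `fragments_mapped`, `fragments_total`, `reliable`.
#' @export
fragment_ani <- function(query, reference, params = ani_params(),
                         ref_index = NULL) {
  qid <- names(query) %||% "query"
  rid <- names(reference) %||% "reference"
  q <- unname(query[[1]])
  r <- unname(reference[[1]])
  if (nchar(q) == 0L || nchar(r) == 0L) stop("empty genome")
  fl <- params$fragment_length
  k <- params$kmer_size
  if (nchar(q) < fl) {
    warning("query shorter than one fragment; using a single truncated fragment")
  }
  idx <- ref_index %||% ani_index(r, k)
  rraw <- idx$raw
  rn <- idx$n

  frag_starts <- seq(1L, max(1L, nchar(q) - fl + 1L), by = fl)
  # also cover a trailing partial fragment
  if (length(frag_starts) && (tail_len <- nchar(q) - (frag_starts[length(frag_starts)] + fl - 1L)) > 0) {
    frag_starts <- c(frag_starts, frag_starts[length(frag_starts)] + fl)
  }
  n_frag <- length(frag_starts)
  frag_ends <- pmin(frag_starts + fl - 1L, nchar(q))

  # seed positions (global query coordinates) for all fragments at once
  seed_off <- seq(1L, fl - k + 1L, by = params$seed_step)
  seed_pos <- as.vector(outer(seed_off - 1L, frag_starts, `+`))
  seed_pos <- seed_pos[seed_pos + k - 1L <= nchar(q)]
  seed_frag <- findInterval(seed_pos, frag_starts)
  seed_kmers <- substring(q, seed_pos, seed_pos + k - 1L)
  hit <- match(seed_kmers, idx$kmers)   # first reference occurrence
  diag_all <- hit - seed_pos            # ref_start - query_start offset

  qraw <- charToRaw(q)
  identities <- rep(NA_real_, n_frag)
  for (f in seq_len(n_frag)) {
    d <- diag_all[seed_frag == f]
    d <- d[!is.na(d)]
    if (!length(d)) next
    diag <- as.integer(names(sort(table(d), decreasing = TRUE))[1])
    qs <- frag_starts[f]; qe <- frag_ends[f]
    rs <- qs + diag; re <- qe + diag
    # clip to reference bounds
    clip_lo <- max(0L, 1L - rs)
    clip_hi <- max(0L, re - rn)
    qs2 <- qs + clip_lo; qe2 <- qe - clip_hi
    rs2 <- rs + clip_lo; re2 <- re - clip_hi
    if (qe2 - qs2 + 1L < k) next
    ident <- mean(qraw[qs2:qe2] == rraw[rs2:re2])
    # identity over the full fragment window (unaligned overhang counts
    # against identity, mirroring ungapped extension over the window)
    ident <- ident * (qe2 - qs2 + 1L) / (qe - qs + 1L)
    identities[f] <- ident
  }
  mapped <- !is.na(identities) & identities >= params$min_fragment_identity
  ani <- if (any(mapped)) 100 * mean(identities[mapped]) else NA_real_
  structure(list(query = qid, reference = rid, ani = ani,
                 fragments_mapped = sum(mapped), fragments_total = n_frag,
                 reliable = sum(mapped) / n_frag >= params$min_mapped_fraction),
            class = "ani_result")
}

#' Symmetric pairwise ANI matrix for a genome collection
#'
#' Entry (i, j) is the mean of the two directional fragment ANI estimates;
#' the diagonal is 100. Unreliable pairs (mapped fraction below the floor in
#' both directions) are imputed as 0 ANI, i.e. maximal distance, which keeps
#' the downstream linkage well-defined.
#'
#' @param genomes Named character vector of genome sequences (or a
#'   `genome_collection`, whose `$genomes` is used).
#' @param params [ani_params()].
#' @return Symmetric numeric matrix of ANI percent values.
#' @export
ani_matrix <- function(genomes, params = ani_params()) {
  if (inherits(genomes, "genome_collection")) genomes <- genomes$genomes
  n <- length(genomes)
  if (n < 2L) stop("need at least two genomes")
  ids <- names(genomes)
  idx <- lapply(genomes, ani_index, k = params$kmer_size)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ij <- fragment_ani(genomes[i], genomes[j], params, ref_index = idx[[j]])
      ji <- fragment_ani(genomes[j], genomes[i], params, ref_index = idx[[i]])
      vals <- c(if (ij$reliable) ij$ani, if (ji$reliable) ji$ani)
      a <- if (length(vals)) mean(vals) else 0
      m[i, j] <- m[j, i] <- a
    }
  }
  m
}

#' Delineate species clusters from an ANI matrix
#'
#' Distances are `(100 - ANI)/100`; a complete-linkage dendrogram
#' ([stats::hclust()]) is cut at height `(100 - threshold)/100` with
#' [stats::cutree()], so genome pairs at exactly the threshold co-cluster
#' (inclusive boundary: sharing >= 95 percent ANI means same species).
#' Cluster ids are ordered by size (descending), ties broken by the
#' lexicographically smallest member id.
#'
#' @param matrix Symmetric ANI matrix (percent) with 100 on the diagonal.
#' @param threshold_percent Species threshold in ANI percent (default 95).
#' @return A `species_clustering` list: `cluster_of` (named integer vector),
#'   `clusters` (list of member ids), `threshold`, `linkage`, `hclust`.
#' @export
cluster_species <- function(matrix, threshold_percent = 95) {
  if (!isSymmetric(unname(matrix))) stop("ANI matrix must be symmetric")
  if (nrow(matrix) == 1L) {
    cl <- setNames(1L, rownames(matrix))
    return(structure(list(cluster_of = cl, clusters = list(rownames(matrix)),
                          threshold = threshold_percent, linkage = "complete",
                          hclust = NULL),
                     class = "species_clustering"))
  }
  d <- as.dist((100 - matrix) / 100)
  hc <- hclust(d, method = "complete")
  raw <- cutree(hc, h = (100 - threshold_percent) / 100)
  cluster_of <- relabel_clusters(raw)
  clusters <- split(names(cluster_of), cluster_of)
  structure(list(cluster_of = cluster_of, clusters = unname(clusters),
                 threshold = threshold_percent, linkage = "complete",
                 hclust = hc),
            class = "species_clustering")
}

# Renumber cluster labels: size descending, ties by smallest member id.
relabel_clusters <- function(raw) {
  tab <- table(raw)
  rep_member <- vapply(names(tab), function(cl) min(names(raw)[raw == cl]), character(1))
  ord <- order(-as.integer(tab), rep_member)
  new_id <- setNames(seq_along(ord), names(tab)[ord])
  setNames(as.integer(new_id[as.character(raw)]), names(raw))
}

#' Habitat specificity of species clusters
#'
#' Reports the percentage of clusters whose members were all isolated from a
#' single habitat, and a Pearson chi-squared test (no continuity correction)
#' of the cluster x habitat contingency table.
#'
#' @param clustering A [cluster_species()] result.
#' @param metadata Data frame with columns `genome` and `habitat` covering
#'   every clustered genome.
#' @return List: `fraction_single_habitat` (percent), `chi2`, `df`, `p`,
#'   `table` (the contingency table).
#' @export
habitat_specificity <- function(clustering, metadata) {
  if (is.null(metadata) || nrow(metadata) == 0L) stop("empty metadata")
  hab <- setNames(metadata$habitat, metadata$genome)
  ids <- names(clustering$cluster_of)
  if (any(!ids %in% names(hab)) || any(is.na(hab[ids]))) {
    stop("every genome needs a habitat label")
  }
  cl <- clustering$cluster_of
  single <- vapply(split(hab[ids], cl[ids]),
                   function(h) length(unique(h)) == 1L, logical(1))
  tab <- table(cluster = cl[ids], habitat = hab[ids])
  if (nrow(tab) > 1L && ncol(tab) > 1L) {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    chi2 <- unname(ct$statistic); df <- unname(ct$parameter); p <- ct$p.value
  } else {
    chi2 <- 0; df <- 0L; p <- 1
  }
  list(fraction_single_habitat = 100 * mean(single),
       chi2 = chi2, df = df, p = p, table = tab)
}
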