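# 16S rRNA novelty gating and greedy OTU clustering.
#
# Identity is matches / alignment columns of a full-length global
# (Needleman-Wunsch) alignment with match +2, mismatch -3, gap open -5,
# gap extend -2 (a gap of length L costs 5 + 2(L-1)). Thresholds follow the
# conventional 16S demarcations: 98.7% (species) and 94.5% (genus).

#' Novelty thresholds for 16S identity
#' @param species_identity Species demarcation in identity percent
#'   (default 98.7).
#' @param genus_identity Genus demarcation (default 94.5); must be below the
#'   species threshold.
#' @return A `novelty_thresholds` list.
#' @export
novelty_thresholds <- function(species_identity = 98.7, genus_identity = 94.5) {
  if (!(genus_identity < species_identity && species_identity <= 100)) {
    stop("need genus_identity < species_identity <= 100")
  }
  structure(list(species_identity = species_identity,
                 genus_identity = genus_identity),
            class = "novelty_thresholds")
}

# Global alignment identity (percent) between two nucleotide sequences.
global_identity_nt <- function(a, b) {
  al <- cpp_global_align(a, b, match = 2L, mismatch = -3L,
                         gap_open = 5L, gap_ext = 2L, blosum = FALSE)
  list(identity = 100 * al$matches / al$columns, score = al$score)
}

#' Best 16S identity of a query against a reference set
#'
#' Scans all references with global alignment; the best-scoring reference
#' wins, ties broken by lexicographically smaller reference id.
#'
#' @param query A single 16S sequence (string).
#' @param references Named character vector of reference 16S sequences.
#' @return List: `reference` (id), `identity` (percent), `score`.
#' @export
best_identity_16s <- function(query, references) {
  if (length(references) == 0L) stop("empty reference set")
  if (is.null(names(references))) stop("references must be named")
  if (nchar(query) < 500L) warning("query shorter than 500 nt")
  if (any(nchar(references) < 500L)) warning("reference(s) shorter than 500 nt")
  best <- NULL
  for (rid in sort(names(references))) {   # lexicographic order => ties keep smaller id
    al <- global_identity_nt(query, references[[rid]])
    if (is.null(best) || al$score > best$score) {
      best <- list(reference = rid, identity = al$identity, score = al$score)
    }
  }
  best
}

#' Classify taxonomic novelty from a best 16S identity
#'
#' `identity >= species threshold` is a known species; identities in
#' `[genus, species)` a potentially novel species; below the genus threshold
#' a potentially novel genus. Boundaries are inclusive on the "known" side.
#'
#' @param best_identity Identity percent in `[0, 100]`.
#' @param thresholds [novelty_thresholds()].
#' @return One of `"known_species"`, `"novel_species"`, `"novel_genus"`.
#' @export
classify_novelty <- function(best_identity, thresholds = novelty_thresholds()) {
  if (any(best_identity < 0 | best_identity > 100)) stop("identity outside [0, 100]")
  ifelse(best_identity >= thresholds$species_identity, "known_species",
         ifelse(best_identity >= thresholds$genus_identity, "novel_species",
                "novel_genus"))
}

#' Call novelty for a set of query 16S sequences
#'
#' @param queries Named character vector of query 16S sequences.
#' @param references Named character vector of reference sequences.
#' @param thresholds [novelty_thresholds()].
#' @return Data frame: `query`, `best_reference`, `best_identity`, `call`.
#' @export
novelty_calls <- function(queries, references,
                          thresholds = novelty_thresholds()) {
  rows <- lapply(names(queries), function(qid) {
    b <- best_identity_16s(queries[[qid]], references)
    data.frame(query = qid, best_reference = b$reference,
               best_identity = b$identity,
               call = classify_novelty(b$identity, thresholds))
  })
  do.call(rbind, rows)
}

#' Greedy centroid OTU clustering of 16S sequences
#'
#' Sequences are sorted by length (descending; ties by id); the first founds
#' the first OTU; each subsequent sequence joins the earliest-founded
#' centroid it matches at `identity >= identity_threshold`, else founds a new
#' OTU (the usearch-style greedy scheme).
#'
#' @param sequences Named character vector.
#' @param identity_threshold Identity percent (e.g. 98.7 for species-level,
#'   94.5 for genus-level OTUs).
#' @return An `otu_clustering` list: `otu_of` (named integer), `centroids`
#'   (ids), `n_otus`.
#' @export
greedy_otu_cluster <- function(sequences, identity_threshold) {
  if (length(sequences) == 0L) stop("need at least one sequence")
  ord <- order(-nchar(sequences), names(sequences))
  ids <- names(sequences)[ord]
  centroids <- character(0)
  otu_of <- setNames(integer(length(sequences)), names(sequences))
  for (id in ids) {
    assigned <- 0L
    for (ci in seq_along(centroids)) {
      al <- global_identity_nt(sequences[[id]], sequences[[centroids[ci]]])
      if (al$identity >= identity_threshold) { assigned <- ci; break }
    }
    if (assigned == 0L) {
      centroids <- c(centroids, id)
      assigned <- length(centroids)
    }
    otu_of[id] <- assigned
  }
  structure(list(otu_of = otu_of, centroids = centroids,
                 n_otus = length(centroids),
                 identity_threshold = identity_threshold),
            class = "otu_clustering")
}
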