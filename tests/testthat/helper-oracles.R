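# Shared fixtures and independent oracles used across the suite.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

AA_SET <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
rand_aa <- function(n) paste(sample(AA_SET, n, TRUE), collapse = "")

# Columnwise identity between equal-length strings (oracle for no-indel pairs).
col_identity <- function(a, b) mean(charToRaw(a) == charToRaw(b))

# Substitute exactly n positions (deterministic count, for exact identities).
sub_exact <- function(s, n, alphabet = c("A", "C", "G", "T")) {
  x <- strsplit(s, "")[[1]]
  pos <- sample(length(x), n)
  x[pos] <- vapply(x[pos], function(b) sample(setdiff(alphabet, b), 1), "")
  paste(x, collapse = "")
}

# Brute-force complete-linkage agglomeration cut at height h: merge the two
# clusters with the smallest maximum pairwise distance while it is <= h.
bf_complete_linkage <- function(d, h) {
  clusters <- as.list(rownames(d))
  repeat {
    if (length(clusters) == 1L) break
    best <- NULL
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        cd <- max(d[clusters[[i]], clusters[[j]]])
        if (is.null(best) || cd < best$d) best <- list(i = i, j = j, d = cd)
      }
    }
    if (best$d > h) break
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  out <- integer(0)
  for (k in seq_along(clusters)) out[clusters[[k]]] <- k
  out
}

# Partition equality up to relabeling.
same_partition <- function(a, b) {
  a <- a[sort(names(a))]; b <- b[sort(names(b))]
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# Biostrings global alignment identity with the package's gap convention
# (open 5 + 2 per extra position => Biostrings opening 3, extension 2).
biostrings_nt_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = TRUE),
    gapOpening = 3, gapExtension = 2)
  aln <- as.character(Biostrings::alignedPattern(pa))
  100 * Biostrings::nmatch(pa) / nchar(aln)
}

# Greedy clustering replay from an exhaustive identity table (oracle for
# greedy OTU / gene-family clustering; no prefilter, same ordering rule).
greedy_replay <- function(ids, lens, ident_fun, threshold) {
  ord <- order(-lens, ids)
  centroids <- character(0)
  assign <- setNames(integer(length(ids)), ids)
  for (id in ids[ord]) {
    hit <- 0L
    for (ci in seq_along(centroids)) {
      if (ident_fun(id, centroids[ci]) >= threshold) { hit <- ci; break }
    }
    if (hit == 0L) { centroids <- c(centroids, id); hit <- length(centroids) }
    assign[id] <- hit
  }
  assign
}

# Translate with table 11 through Biostrings (independent of the package's
# own codon handling).
bs_translate <- function(nt) {
  as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    genetic.code = Biostrings::getGeneticCode("11"),
    no.init.codon = TRUE,   # literal codon-1 translation (package convention)
    if.fuzzy.codon = "X"))
}
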