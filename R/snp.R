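# Reference-anchored SNP calling (anchor-and-compare), coding-effect
# annotation with HIGH/MODERATE/LOW/MODIFIER impact classes, SNP-distance
# neighbor-joining trees, and per-gene variant density.

#' Call SNPs of a genome against a reference by unique-k-mer anchoring
#'
#' Unique k-mers shared by query and reference are used as colinear anchors
#' on the dominant diagonal; the sequence between consecutive anchors (and
#' the flanks) is compared columnwise. Substitutions only: indel-containing
#' regions fall off the dominant diagonal and are not compared.
#'
#' @param genome Query sequence string (or named length-1 vector).
#' @param reference Reference sequence string.
#' @param k Anchor k-mer size (default 21).
#' @return A `snp_calls` list: `variants` (data.frame `pos`, `ref`, `alt`,
#'   1-based on the reference), `sites_compared`, `genome`, `reference`.
#'   Unalignable input gives zero variants with a warning.
#' @export
call_snps <- function(genome, reference, k = 21L) {
  gid <- names(genome) %||% "query"
  rid <- names(reference) %||% "reference"
  q <- unname(genome[[1]])
  r <- unname(reference[[1]])
  qk <- kmers_of(q, k)
  rk <- kmers_of(r, k)
  # unique within each sequence
  qu <- which(!(duplicated(qk) | duplicated(qk, fromLast = TRUE)))
  ru <- which(!(duplicated(rk) | duplicated(rk, fromLast = TRUE)))
  m <- match(qk[qu], rk[ru])
  keep <- !is.na(m)
  qpos <- qu[keep]
  rpos <- ru[m[keep]]
  if (length(qpos) == 0L) {
    warning("no unique anchors shared with the reference; genome unalignable")
    return(structure(list(variants = data.frame(pos = integer(0),
                                                ref = character(0),
                                                alt = character(0)),
                          sites_compared = 0L, genome = gid,
                          reference = rid),
                     class = "snp_calls"))
  }
  offs <- qpos - rpos
  diag <- as.integer(names(sort(table(offs), decreasing = TRUE))[1])
  on_diag <- offs == diag
  qpos <- qpos[on_diag]; rpos <- rpos[on_diag]
  ord <- order(rpos)
  qpos <- qpos[ord]; rpos <- rpos[ord]

  # columnwise comparison over the contiguous span covered by the dominant
  # diagonal, extended to the sequence bounds
  r_lo <- max(1L, 1L - diag)
  r_hi <- min(nchar(r), nchar(q) - diag)
  q_lo <- r_lo + diag
  qraw <- charToRaw(q)[q_lo:(r_hi + diag)]
  rraw <- charToRaw(r)[r_lo:r_hi]
  mism <- which(qraw != rraw)
  pos <- r_lo + mism - 1L
  variants <- data.frame(
    pos = pos,
    ref = if (length(mism)) strsplit(rawToChar(rraw[mism]), "")[[1]] else character(0),
    alt = if (length(mism)) strsplit(rawToChar(qraw[mism]), "")[[1]] else character(0))
  structure(list(variants = variants,
                 sites_compared = r_hi - r_lo + 1L,
                 genome = gid, reference = rid),
            class = "snp_calls")
}

IMPACT_OF_EFFECT <- c(stop_gained = "HIGH", stop_lost = "HIGH",
                      start_lost = "HIGH", missense = "MODERATE",
                      synonymous = "LOW", intergenic = "MODIFIER")

START_CODONS <- c("ATG", "GTG", "TTG")

#' Annotate the coding effect and impact of substitution variants
#'
#' Positions inside a CDS are classified by recomputing the affected codon
#' with the alternate base (respecting strand; bacterial translation table
#' 11, start codons ATG/GTG/TTG). Effects map to impact classes: HIGH
#' (stop_gained, stop_lost, start_lost), MODERATE (missense), LOW
#' (synonymous), MODIFIER (intergenic). A variant in the first codon that
#' destroys the start takes precedence over the amino-acid comparison.
#'
#' @param variants Data frame with columns `pos`, `ref`, `alt` (1-based on
#'   the reference).
#' @param gene_models Data frame with columns `start`, `end`, `strand`, `ID`
#'   (1-based inclusive CDS coordinates, non-overlapping).
#' @param reference Reference sequence string.
#' @return The input data frame with added columns `region`, `gene`,
#'   `effect`, `impact`, `codon_ref`, `codon_alt`, `aa_ref`, `aa_alt`.
#' @export
annotate_variant_effect <- function(variants, gene_models, reference) {
  n <- nrow(variants)
  rl <- nchar(reference)
  if (n && (any(variants$pos < 1L) || any(variants$pos > rl))) {
    stop("variant position outside the reference")
  }
  code <- genetic_code_11()
  region <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  effect <- rep("intergenic", n)
  codon_ref <- codon_alt <- aa_ref <- aa_alt <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    pos <- variants$pos[i]
    hit <- which(gene_models$start <= pos & gene_models$end >= pos)
    if (!length(hit)) next
    gmod <- gene_models[hit[1], ]
    region[i] <- "genic"
    gene[i] <- gmod$ID
    if (gmod$strand == "-") {
      off <- gmod$end - pos               # 0-based offset in gene orientation
    } else {
      off <- pos - gmod$start
    }
    ci <- off %/% 3L                       # codon index (0-based)
    wi <- off %% 3L                        # position within codon (0-based)
    if (gmod$strand == "-") {
      c_end <- gmod$end - ci * 3L
      cod <- revcomp_fast(substr(reference, c_end - 2L, c_end))
      alt_base <- chartr("ACGT", "TGCA", variants$alt[i])
    } else {
      c_start <- gmod$start + ci * 3L
      cod <- substr(reference, c_start, c_start + 2L)
      alt_base <- variants$alt[i]
    }
    cod_alt <- cod
    substr(cod_alt, wi + 1L, wi + 1L) <- alt_base
    aa_r <- unname(code[cod]); aa_a <- unname(code[cod_alt])
    codon_ref[i] <- cod; codon_alt[i] <- cod_alt
    aa_ref[i] <- aa_r; aa_alt[i] <- aa_a
    effect[i] <- if (ci == 0L && cod %in% START_CODONS && !cod_alt %in% START_CODONS) {
      "start_lost"
    } else if (!is.na(aa_r) && aa_r != "*" && !is.na(aa_a) && aa_a == "*") {
      "stop_gained"
    } else if (!is.na(aa_r) && aa_r == "*" && !is.na(aa_a) && aa_a != "*") {
      "stop_lost"
    } else if (identical(aa_r, aa_a)) {
      "synonymous"
    } else {
      "missense"
    }
  }
  variants$region <- region
  variants$gene <- gene
  variants$effect <- effect
  variants$impact <- unname(IMPACT_OF_EFFECT[effect])
  variants$codon_ref <- codon_ref
  variants$codon_alt <- codon_alt
  variants$aa_ref <- aa_ref
  variants$aa_alt <- aa_alt
  variants
}

#' Pairwise SNP distances between genomes called against one reference
#'
#' The distance between two genomes is the number of sites at which their
#' alleles differ divided by the number of jointly compared reference sites.
#'
#' @param calls Named list of [call_snps()] results (one per genome, same
#'   reference).
#' @return Symmetric numeric distance matrix.
#' @export
snp_distance_matrix <- function(calls) {
  ids <- names(calls)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  alleles <- lapply(calls, function(x) {
    setNames(x$variants$alt, as.character(x$variants$pos))
  })
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ai <- alleles[[i]]; aj <- alleles[[j]]
      pos <- union(names(ai), names(aj))
      bi <- ifelse(pos %in% names(ai), ai[pos], NA)
      bj <- ifelse(pos %in% names(aj), aj[pos], NA)
      # NA means reference allele at that site
      diff <- sum(ifelse(is.na(bi), "", bi) != ifelse(is.na(bj), "", bj))
      sites <- min(calls[[i]]$sites_compared, calls[[j]]$sites_compared)
      m[i, j] <- m[j, i] <- if (sites > 0) diff / sites else 1
    }
  }
  m
}

#' Neighbor-joining tree from SNP distances, with clade assignment
#'
#' Builds a neighbor-joining tree ([ape::nj()]; negative branch lengths
#' clamped to zero) and assigns clades by cutting an average-linkage
#' clustering of the same distances at `k` groups or height `h`.
#'
#' @param calls Named list of [call_snps()] results, or a precomputed
#'   distance matrix.
#' @param k,h Number of clades or cut height for the clade assignment
#'   (optional; `k` wins if both given).
#' @return A `snp_tree` list: `tree` (`phylo`), `newick`, `distances`,
#'   `clades` (named integer vector, NULL if no cut requested).
#' @export
snp_distance_tree <- function(calls, k = NULL, h = NULL) {
  d <- if (is.matrix(calls)) calls else snp_distance_matrix(calls)
  if (nrow(d) < 3L) stop("need at least three genomes")
  tree <- ape::nj(as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  clades <- NULL
  if (!is.null(k) || !is.null(h)) {
    hc <- hclust(as.dist(d), method = "average")
    clades <- if (!is.null(k)) cutree(hc, k = k) else cutree(hc, h = h)
  }
  structure(list(tree = tree, newick = ape::write.tree(tree),
                 distances = d, clades = clades),
            class = "snp_tree")
}

#' Per-gene variant density and premature-stop carrier fraction
#'
#' Bins annotated variants along a gene and reports, per effect type, the
#' count per bin, plus the fraction of genomes carrying at least one
#' stop-gained variant in the gene (overall and per clade).
#'
#' @param annotated Named list (per genome) of [annotate_variant_effect()]
#'   data frames.
#' @param gene_id Gene `ID` to profile.
#' @param gene_models Data frame of gene models (must contain `gene_id`).
#' @param bin Bin width in bp (default 50).
#' @param clades Optional named clade assignment for the genomes.
#' @return List: `histogram` (bin x effect count matrix),
#'   `stop_carrier_fraction`, `stop_carrier_by_clade`.
#' @export
gene_variant_density <- function(annotated, gene_id, gene_models, bin = 50L,
                                 clades = NULL) {
  gmod <- gene_models[gene_models$ID == gene_id, ]
  if (nrow(gmod) == 0L) stop("unknown gene: ", gene_id)
  glen <- gmod$end - gmod$start + 1L
  breaks <- seq(0L, glen + bin - 1L, by = bin)
  effects <- c("synonymous", "missense", "stop_gained", "stop_lost", "start_lost")
  hist <- matrix(0L, nrow = length(breaks) - 1L, ncol = length(effects),
                 dimnames = list(paste0("bin", seq_len(length(breaks) - 1L)),
                                 effects))
  carriers <- logical(length(annotated))
  names(carriers) <- names(annotated)
  for (g in names(annotated)) {
    v <- annotated[[g]]
    v <- v[!is.na(v$gene) & v$gene == gene_id, , drop = FALSE]
    if (nrow(v)) {
      off <- v$pos - gmod$start  # position within gene, forward coordinates
      bidx <- pmin(off %/% bin + 1L, nrow(hist))
      for (r in seq_len(nrow(v))) {
        e <- v$effect[r]
        if (e %in% effects) hist[bidx[r], e] <- hist[bidx[r], e] + 1L
      }
      carriers[g] <- any(v$effect == "stop_gained")
    }
  }
  by_clade <- NULL
  if (!is.null(clades)) {
    by_clade <- vapply(split(carriers[names(clades)], clades),
                       mean, numeric(1))
  }
  list(histogram = hist,
       stop_carrier_fraction = mean(carriers),
       stop_carrier_by_clade = by_clade)
}

#' Write variants as a minimal VCF v4.2
#'
#' @param annotated An [annotate_variant_effect()] data frame.
#' @param path Output path.
#' @param chrom Chromosome/contig name.
#' @param sample_id Genome id recorded in the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(annotated, path, chrom = "chr1", sample_id = "sample") {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=panlachno"),
           paste0("##SAMPLE=<ID=", sample_id, ">"),
           "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Predicted effect\">",
           "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Impact class\">",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- sprintf("EFFECT=%s;IMPACT=%s%s", annotated$effect, annotated$impact,
                  ifelse(is.na(annotated$gene), "",
                         paste0(";GENE=", annotated$gene)))
  lines <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                   chrom, annotated$pos, annotated$ref, annotated$alt, info)
  writeLines(c(hdr, lines), path)
  invisible(path)
}
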