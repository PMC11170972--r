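# Short-chain fatty acid pathway-completeness scoring from protein homology,
# sporulation signature screening, and principal coordinates analysis.

#' Homology-call thresholds for enzyme annotation
#'
#' @param min_identity Identity fraction floor (default 0.60).
#' @param min_coverage Coverage floor on the reference enzyme (default 0.50).
#' @param min_score Raw Smith-Waterman score floor (default 50), standing in
#'   for the usual database-size-dependent e-value cutoff.
#' @return A `homology_thresholds` list.
#' @export
homology_thresholds <- function(min_identity = 0.60, min_coverage = 0.50,
                                min_score = 50) {
  stop_if_not_fraction(min_identity, "min_identity")
  stop_if_not_fraction(min_coverage, "min_coverage")
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 min_score = min_score),
            class = "homology_thresholds")
}

#' Local protein alignment (Smith-Waterman, BLOSUM62)
#'
#' Gap open 11, extend 1 (a gap of length L costs 11 + (L-1)); undetermined
#' residues (X) score 0. Identity is identities/alignment columns; coverage
#' is the aligned target span divided by the target length.
#'
#' @param query,target Amino-acid sequence strings.
#' @return List: `identity`, `coverage`, `score`, `q_start`, `q_end`,
#'   `t_start`, `t_end`.
#' @export
local_align_protein <- function(query, target) {
  if (nchar(query) == 0L || nchar(target) == 0L) stop("empty sequence")
  al <- cpp_local_align(query, target, gap_open = 11L, gap_ext = 1L)
  identity <- if (al$columns > 0) al$matches / al$columns else 0
  coverage <- if (al$t_end >= al$t_start && al$t_end > 0) {
    (al$t_end - al$t_start + 1) / nchar(target)
  } else 0
  list(identity = identity, coverage = coverage, score = al$score,
       q_start = al$q_start, q_end = al$q_end,
       t_start = al$t_start, t_end = al$t_end)
}

#' Best enzyme hits in a proteome
#'
#' For each enzyme label, the best-scoring proteome member passing all three
#' thresholds (identity, reference coverage, score) is retained; ties are
#' broken by score then query id.
#'
#' @param proteome Named character vector of protein sequences (one genome).
#' @param enzyme_db Named character vector of reference enzymes; names are
#'   the labels.
#' @param thresholds [homology_thresholds()].
#' @return Data frame with one row per enzyme label: `label`, `query`,
#'   `identity`, `coverage`, `score`, `present`.
#' @export
annotate_enzymes <- function(proteome, enzyme_db,
                             thresholds = homology_thresholds()) {
  if (is.null(names(enzyme_db)) || any(!nzchar(names(enzyme_db)))) {
    stop("enzyme_db entries must be labeled")
  }
  rows <- lapply(names(enzyme_db), function(lab) {
    best <- NULL
    if (length(proteome)) {
      for (qid in sort(names(proteome))) {
        al <- local_align_protein(proteome[[qid]], enzyme_db[[lab]])
        ok <- al$identity >= thresholds$min_identity &&
          al$coverage >= thresholds$min_coverage &&
          al$score >= thresholds$min_score
        if (ok && (is.null(best) || al$score > best$score)) {
          best <- c(al, list(query = qid))
        }
      }
    }
    if (is.null(best)) {
      data.frame(label = lab, query = NA_character_, identity = NA_real_,
                 coverage = NA_real_, score = NA_real_, present = FALSE)
    } else {
      data.frame(label = lab, query = best$query, identity = best$identity,
                 coverage = best$coverage, score = best$score, present = TRUE)
    }
  })
  do.call(rbind, rows)
}

#' Pathway model constructors
#'
#' A pathway model is a named list of routes; each route is an ordered list
#' of steps and each step a set of acceptable enzyme labels (OR within a
#' step). `butyrate_model()` has two routes from acetyl-CoA: the
#' butyryl-CoA:acetate CoA-transferase route (Thl, Hbd, Cro, Bcd, But) and
#' the butyrate kinase route (Thl, Hbd, Cro, Bcd, Ptb, Buk).
#' `propionate_model()` has three routes from propionyl-CoA: the
#' CoA-transferase one-step route (Pct), the CoA-ligase one-step route
#' (ACSS1_2 or ACSS3 or Acd), and the two-step phosphotransferase/kinase
#' route (Pta or PduL, then AckA or TdcD).
#'
#' @param name Pathway name.
#' @param routes Named list of routes (each a list of character vectors).
#' @return A `pathway_model` list.
#' @export
pathway_model <- function(name, routes) {
  if (length(routes) < 1L) stop("need at least one route")
  for (r in routes) {
    if (length(r) < 1L || any(!vapply(r, length, 1L))) stop("empty step in route")
  }
  structure(list(name = name, routes = routes), class = "pathway_model")
}

#' @rdname pathway_model
#' @export
butyrate_model <- function() {
  pathway_model("butyrate", list(
    transferase = list("Thl", "Hbd", "Cro", "Bcd", "But"),
    kinase = list("Thl", "Hbd", "Cro", "Bcd", "Ptb", "Buk")))
}

#' @rdname pathway_model
#' @export
propionate_model <- function() {
  pathway_model("propionate", list(
    coa_transferase = list("Pct"),
    coa_ligase = list(c("ACSS1_2", "ACSS3", "Acd")),
    phosphotransferase_kinase = list(c("Pta", "PduL"), c("AckA", "TdcD"))))
}

#' Pathway completeness from enzyme hits
#'
#' A route is complete iff every step has at least one present label; a
#' pathway is complete iff any of its routes is.
#'
#' @param hits Either an [annotate_enzymes()] data frame or a named logical
#'   vector of label presence.
#' @param models List of [pathway_model()] objects (default: butyrate and
#'   propionate).
#' @return A `pathway_profile` list: per-pathway list with `routes` (named
#'   logical) and `complete`.
#' @export
pathway_completeness <- function(hits,
                                 models = list(butyrate_model(), propionate_model())) {
  present <- if (is.data.frame(hits)) {
    setNames(hits$present, hits$label)
  } else hits
  has <- function(lab) isTRUE(unname(present[lab]))
  out <- lapply(models, function(m) {
    routes <- vapply(m$routes, function(r) {
      all(vapply(r, function(step) any(vapply(step, has, logical(1))), logical(1)))
    }, logical(1))
    list(routes = routes, complete = any(routes))
  })
  names(out) <- vapply(models, function(m) m$name, character(1))
  structure(out, class = "pathway_profile")
}

#' Sporulation signature screen
#'
#' Exact, case-insensitive matching of annotation gene names against a
#' signature gene-name list (the machine-learning-derived 66-gene sporulation
#' signature in the original application; supplied as configuration).
#'
#' @param annotations Named list: genome id to character vector of annotated
#'   gene names (or a `genome_collection`, whose CDS `gene` attributes are
#'   used).
#' @param signature Character vector of signature gene names.
#' @param master_gene Name whose absence is specially flagged (default
#'   `"spo0A"`, the sporulation master regulator).
#' @return List: `presence` (genomes x signature logical matrix),
#'   `completeness` (per-genome fraction), `master_absent` (named logical).
#' @export
sporulation_profile <- function(annotations, signature, master_gene = "spo0A") {
  if (length(signature) == 0L) stop("empty signature list")
  if (inherits(annotations, "genome_collection")) {
    annotations <- lapply(annotations$annotations, function(f) {
      f$gene[f$type == "CDS"]
    })
  }
  sig_lc <- tolower(signature)
  pres <- t(vapply(annotations, function(genes) {
    sig_lc %in% tolower(genes)
  }, logical(length(signature))))
  colnames(pres) <- signature
  completeness <- rowMeans(pres)
  master_absent <- if (tolower(master_gene) %in% sig_lc) {
    !pres[, which(sig_lc == tolower(master_gene))[1]]
  } else {
    setNames(rep(NA, nrow(pres)), rownames(pres))
  }
  list(presence = pres, completeness = completeness,
       master_absent = master_absent)
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Wraps [stats::cmdscale()]; axis signs are fixed deterministically so that
#' each axis's largest-magnitude coordinate is positive.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @param k Number of axes (default 2).
#' @return List: `points` (n x k coordinates), `eig` (all eigenvalues).
#' @export
pcoa <- function(d, k = 2L) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  k <- min(k, nrow(d) - 1L)
  sc <- cmdscale(as.dist(d), k = k, eig = TRUE)
  pts <- sc$points
  if (!is.null(pts) && ncol(pts) > 0) {
    for (j in seq_len(ncol(pts))) {
      i <- which.max(abs(pts[, j]))
      if (pts[i, j] < 0) pts[, j] <- -pts[, j]
    }
  }
  list(points = pts, eig = sc$eig)
}
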