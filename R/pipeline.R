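# End-to-end driver tying the stages together on a synthetic collection:
# simulate -> ANI -> species clusters -> 16S novelty -> pan-genome ->
# functional screens -> SNPs -> abundance markers, with a JSON summary.

#' Pipeline configuration
#'
#' Stage toggles plus every stage threshold, all defaulting to the
#' conventional values used throughout the package (ANI 95; 16S 98.7/94.5;
#' homology 0.60/0.50; presence 1e-5/0.10; selection alpha 0.01, |log2FC| >
#' 1; network |r| > 0.3, alpha 0.01).
#'
#' @param sim A [sim_config()] for the synthetic collection stage.
#' @param stages Character vector of stages to run (subset of `"ani"`,
#'   `"novelty"`, `"pangenome"`, `"screens"`, `"snps"`, `"markers"`).
#' @param ani_threshold Species ANI threshold (percent).
#' @param species_identity,genus_identity 16S novelty thresholds (percent).
#' @param seed Integer master seed; per-stage seeds are derived from it with
#'   a fixed counter scheme.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c("ani", "novelty", "pangenome",
                                       "screens", "snps", "markers"),
                            ani_threshold = 95,
                            species_identity = 98.7,
                            genus_identity = 94.5,
                            seed = 1L) {
  structure(list(sim = sim, stages = stages, ani_threshold = ani_threshold,
                 species_identity = species_identity,
                 genus_identity = genus_identity, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the synthetic end-to-end pipeline
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory; when given, per-stage tables and
#'   a `summary.json` are written.
#' @return A list with the per-stage results and a `summary` list of
#'   headline statistics (species cluster count, novelty fractions,
#'   prevalence counts, pathway-complete fraction, marker counts).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  sim <- config$sim
  sim$seed <- derive_seed(config$seed, 1L)
  collection <- simulate_collection(sim)
  out <- list(collection = collection)
  summary <- list(n_genomes = length(collection$genomes),
                  seed = config$seed)

  if ("ani" %in% config$stages) {
    am <- ani_matrix(collection$genomes)
    cl <- cluster_species(am, config$ani_threshold)
    hs <- habitat_specificity(cl, collection$metadata)
    out$ani <- list(matrix = am, clustering = cl, habitat = hs)
    summary$n_species_clusters <- length(cl$clusters)
    summary$fraction_single_habitat <- hs$fraction_single_habitat
  }

  if ("novelty" %in% config$stages && length(collection$r16s)) {
    thr <- novelty_thresholds(config$species_identity, config$genus_identity)
    calls <- novelty_calls(collection$r16s, collection$r16s_refs, thr)
    out$novelty <- calls
    summary$novelty_fractions <- as.list(table(calls$call) / nrow(calls))
  }

  if ("pangenome" %in% config$stages) {
    seqs <- unlist(unname(collection$genes_nt))
    genome_of <- setNames(rep(names(collection$genes_nt),
                              lengths(collection$genes_nt)),
                          names(seqs))
    fm <- cluster_gene_families(seqs, genome_of,
                                clustering_params(preset = "gene_catalog"))
    pv <- classify_prevalence(fm)
    out$pangenome <- list(families = fm, prevalence = pv,
                          jaccard = jaccard_matrix(fm))
    summary$prevalence_counts <- as.list(pv$counts)
    summary$n_families <- nrow(fm$presence)
  }

  if ("screens" %in% config$stages && !is.null(collection$enzyme_refs)) {
    profiles <- lapply(collection$proteins, function(pr) {
      pathway_completeness(annotate_enzymes(pr, collection$enzyme_refs))
    })
    out$screens <- profiles
    summary$butyrate_complete_fraction <-
      mean(vapply(profiles, function(p) isTRUE(p$butyrate$complete), logical(1)))
  }

  if ("snps" %in% config$stages) {
    ref <- collection$ancestors[1]
    sp1 <- names(collection$truth$species_of)[collection$truth$species_of == 1L]
    calls <- lapply(sp1, function(g) {
      call_snps(collection$genomes[g], ref)
    })
    names(calls) <- sp1
    annotated <- lapply(calls, function(cc) {
      annotate_variant_effect(cc$variants, collection$gene_models, ref[[1]])
    })
    out$snps <- list(calls = calls, annotated = annotated)
    if (length(sp1) >= 3L) {
      out$snps$tree <- snp_distance_tree(calls)
    }
    summary$n_variants_species1 <-
      sum(vapply(calls, function(x) nrow(x$variants), integer(1)))
    summary$n_missense_species1 <-
      sum(vapply(annotated, function(a) sum(a$effect == "missense"), integer(1)))
  }

  if ("markers" %in% config$stages) {
    ids <- names(collection$genomes)
    effect <- setNames(rep(0, length(ids)), ids)
    effect[seq_len(min(3L, length(ids)))] <- 2
    study <- simulate_abundance_study(20L, ids, effect, mean = 200,
                                      dispersion = 0.1,
                                      seed = derive_seed(config$seed, 7L))
    filt <- presence_filter(study)
    mt <- nb_test(filt)
    sel <- select_markers(mt)
    net <- cooccurrence_network(filt)
    out$markers <- list(study = study, table = mt, selection = sel,
                        network = net)
    summary$n_case_enriched <- length(sel$case_enriched)
    summary$n_control_enriched <- length(sel$control_enriched)
  }

  out$summary <- summary
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_collection(collection, file.path(outdir, "collection"))
    if (!is.null(out$ani)) {
      write_matrix_tsv(out$ani$matrix, file.path(outdir, "ani_matrix.tsv"))
      write.table(data.frame(genome = names(out$ani$clustering$cluster_of),
                             cluster = out$ani$clustering$cluster_of),
                  file.path(outdir, "species_clusters.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(out$novelty)) {
      write.table(out$novelty, file.path(outdir, "novelty_calls.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(out$markers)) {
      write.table(out$markers$table, file.path(outdir, "marker_table.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
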