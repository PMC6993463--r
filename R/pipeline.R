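#' Configure an end-to-end run
#'
#' One top-level seed governs every stage; per-stage seeds are derived with
#' [derive_seed()] so reruns with the same config are byte-identical.
#'
#' @param seed integer run seed.
#' @param n_individuals_per_pop individuals per population in the simulate
#'   stage.
#' @param reads_per_individual skim depth per individual.
#' @param read_length read length in bp.
#' @param families list of [repeat_family_spec()] for the simulated world;
#'   NULL uses a small three-family default.
#' @param chrom_lengths simulated chromosome lengths.
#' @param min_bits graph edge threshold in bits.
#' @param alpha FDR threshold for differential abundance.
#' @param k,top_k k-mer painting parameters.
#' @param window,step painting window geometry.
#' @param span loess span.
#' @param snp_count,snp_divergence,repeat_effect,heterozygosity_rate
#'   population-simulation parameters, see [population_config()].
#' @param paint_top_clusters how many of the largest clusters to paint.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, n_individuals_per_pop = 4L,
                       reads_per_individual = 300L, read_length = 150L,
                       families = NULL,
                       chrom_lengths = c(chr1 = 400000L, chr2 = 300000L),
                       min_bits = 100, alpha = 0.05, k = 12L, top_k = 100L,
                       window = 200000L, step = 100000L, span = 0.1,
                       snp_count = 200L, snp_divergence = 0.2,
                       repeat_effect = 1.0, heterozygosity_rate = 0.02,
                       paint_top_clusters = 3L) {
  if (is.null(families)) {
    families <- list(
      repeat_family_spec("GypsyA", "Gypsy-like", monomer_length = 3000L,
                         target_copy_number = 60L,
                         intra_family_divergence = 0.03, placement_bias = -1),
      repeat_family_spec("CopiaB", "Copia-like", monomer_length = 2000L,
                         target_copy_number = 50L,
                         intra_family_divergence = 0.03, placement_bias = 1),
      repeat_family_spec("TandemC", "tandem", monomer_length = 180L,
                         target_copy_number = 300L,
                         intra_family_divergence = 0.02, placement_bias = 0))
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline on a simulated world
#'
#' simulate -> similarity -> cluster -> annotate -> differential abundance
#' -> paint -> structure, writing every artifact and a JSON manifest into
#' `outdir`. Reruns with the same config produce identical outputs.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if absent).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[repeatpop] ", ...)

  # --- simulate ---------------------------------------------------------
  lib <- make_repeat_library(config$families, derive_seed(config$seed, "library"))
  genome <- build_genome(lib, chrom_lengths = config$chrom_lengths,
                         seed = derive_seed(config$seed, "genome"))
  pc <- population_config(
    n_individuals_per_pop = config$n_individuals_per_pop,
    snp_count = config$snp_count, snp_divergence = config$snp_divergence,
    repeat_effect = config$repeat_effect,
    heterozygosity_rate = config$heterozygosity_rate,
    seed = derive_seed(config$seed, "population"))
  pop <- simulate_population(genome, pc)
  reads <- do.call(rbind, lapply(seq_len(nrow(pop$labels)), function(i) {
    shotgun_reads(genome, config$reads_per_individual, config$read_length,
                  seed = derive_seed(config$seed,
                                     paste0("reads_", pop$labels$individual[i])),
                  individual = pop$labels$individual[i],
                  population = pop$labels$population[i])
  }))
  class(reads) <- c("ReadSet", "data.frame")
  write_fasta(genome$chromosomes, file.path(outdir, "genome.fa"))
  write_bed(genome$genes, file.path(outdir, "genes.bed"))
  write_bed(data.frame(chrom = genome$truth$chrom, start = genome$truth$start,
                       end = genome$truth$end, name = genome$truth$family,
                       score = 0L, strand = genome$truth$strand),
            file.path(outdir, "truth_placements.bed"))
  write_library_fasta(lib, file.path(outdir, "library.fa"))
  write_reads_fasta(reads, file.path(outdir, "reads.fa"))
  write_tsv_matrix(pop$genotypes, file.path(outdir, "genotypes.tsv"),
                   id_col = "individual")
  log_msg("simulated ", nrow(reads), " reads from ",
          nrow(pop$labels), " individuals")

  # --- similarity -> graph -> clusters ----------------------------------
  params <- scoring_params(min_report_bits = config$min_bits)
  hits <- all_vs_all(reads, params)
  write_hits(hits, file.path(outdir, "hits.tsv"))
  labels <- reads[, c("read_id", "individual", "population")]
  g <- build_graph(hits, min_bits = config$min_bits, read_labels = labels)
  log_msg("graph: ", igraph::vcount(g), " vertices, ", igraph::ecount(g),
          " edges, mean degree ", round(mean_degree(g), 2))
  gc_ <- largest_component(g)
  log_msg("largest component keeps ", igraph::vcount(gc_), " of ",
          igraph::vcount(g), " vertices")
  assignment <- detect_communities(gc_)
  unclustered <- setdiff(reads$read_id, assignment$read_id)
  write.table(assignment, file.path(outdir, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(unclustered, file.path(outdir, "unclustered_reads.txt"))
  ab <- abundance_matrix(assignment, labels)
  write_tsv_matrix(ab, file.path(outdir, "abundance.tsv"), id_col = "individual")
  mg <- cluster_metagraph(gc_, assignment)
  write.table(igraph::as_data_frame(mg, "edges"),
              file.path(outdir, "cluster_metagraph.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # --- annotate + differential abundance --------------------------------
  ann <- annotate_clusters(reads, assignment, lib)
  write.table(ann, file.path(outdir, "annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  diff_clusters <- differential_abundance(ab, alpha = config$alpha)
  write.table(diff_clusters, file.path(outdir, "differential_clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  byclass <- aggregate_by_annotation(ab, ann)
  diff_class <- if (ncol(byclass) >= 1 &&
                    all(apply(byclass, 2, function(x) length(unique(x)) >= 1)))
    differential_abundance(byclass, alpha = config$alpha) else NULL
  if (!is.null(diff_class))
    write.table(diff_class, file.path(outdir, "differential_classes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  # --- paint the largest clusters ---------------------------------------
  sizes <- sort(table(assignment$cluster_id), decreasing = TRUE)
  paint <- list()
  for (cl in head(names(sizes), config$paint_top_clusters)) {
    ids <- assignment$read_id[assignment$cluster_id == cl]
    res <- paint_cluster(reads[match(ids, reads$read_id), , drop = FALSE],
                         genome, genome$genes, k = config$k,
                         top = config$top_k, width = config$window,
                         step = config$step, span = config$span)
    paint[[cl]] <- res
    write.table(res$track,
                file.path(outdir, paste0("paint_", cl, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  corr <- do.call(rbind, lapply(names(paint), function(cl)
    cbind(data.frame(cluster_id = cl), paint[[cl]]$correlation)))
  if (!is.null(corr))
    write.table(corr, file.path(outdir, "paint_correlations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  # --- population structure ---------------------------------------------
  # structure uses the simulated copy-number panel (the full 2n individuals)
  sc <- structure_contrast(pop$copy_number, pop$genotypes,
                           pop$labels$population)
  write_tsv_matrix(sc$repeat_pca$scores,
                   file.path(outdir, "repeat_pca_scores.tsv"),
                   id_col = "individual")
  write_tsv_matrix(sc$snp_pca$scores,
                   file.path(outdir, "snp_pca_scores.tsv"),
                   id_col = "individual")

  manifest <- list(
    package_version = as.character(utils::packageVersion("repeatpop")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "families")],
    families = lapply(config$families, unclass),
    stage_seeds = list(library = derive_seed(config$seed, "library"),
                       genome = derive_seed(config$seed, "genome"),
                       population = derive_seed(config$seed, "population")),
    n_reads = nrow(reads),
    n_clusters = length(sizes),
    n_unclustered = length(unclustered),
    repeat_silhouette = sc$repeat_silhouette,
    snp_silhouette = sc$snp_silhouette)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(library = lib, genome = genome, population = pop,
                 reads = reads, hits = hits, graph = g,
                 assignment = assignment, abundance = ab, annotations = ann,
                 differential = diff_clusters, differential_classes = diff_class,
                 paint = paint, structure = sc, manifest = manifest))
}

#' Command-line entry point
#'
#' Minimal dispatcher used by the `repeatpop` script in `inst/scripts`:
#' `repeatpop run --seed N --outdir D` runs the demo pipeline on a
#' simulated world.
#'
#' @param args character vector of command-line arguments.
#' @return exit code (0 ok, 2 bad input).
#' @export
repeatpop_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: repeatpop run [--seed N] [--outdir D]"
  if (!length(args)) { message(usage); return(2L) }
  cmd <- args[1]
  opt <- function(name, default) {
    i <- which(args == paste0("--", name))
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  if (cmd == "run") {
    seed <- as.integer(opt("seed", "1"))
    outdir <- opt("outdir", "repeatpop_run")
    run_pipeline(run_config(seed = seed), outdir)
    return(0L)
  }
  message("unknown command: ", cmd, "\n", usage)
  2L
}
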