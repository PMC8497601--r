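#' End-to-end comparative methylome pipeline
#'
#' Orchestrates the stages — SNP-corrected references, methylome loading,
#' pairwise DMR calling, species/tissue classification, feature building,
#' permutation enrichment, and expression integration — from a single
#' configuration, writing every stage artefact plus a manifest with file
#' hashes and seeds. Reruns with the same configuration reproduce
#' identical manifest hashes.
#'
#' @param config a named list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{genome_fasta}{reference genome FASTA.}
#'     \item{vcf}{SNP VCF with per-species `SPECIES=` INFO tags
#'       (optional; enables the reference-correction stage).}
#'     \item{gene_table}{gene TSV (gene_id, contig, strand, tss, tes).}
#'     \item{te_table}{TE annotation (.out or 6-column TSV; optional).}
#'     \item{samples}{data.frame or TSV path: sample_id, species, tissue,
#'       replicate, path (cytosine reports).}
#'     \item{expression_tsv, de_table_tsv}{TPM matrix and DE table
#'       (optional; enable the integration stage).}
#'     \item{out_dir}{output directory.}
#'     \item{seed}{integer seed for the permutation stages.}
#'     \item{min_coverage, max_coverage, dmr, n_iter, n_shuffles}{optional
#'       overrides (`dmr` is a list of [dmr_params()] arguments).}
#'   }
#' @return The manifest (invisibly), a list with per-stage outputs,
#'   file md5 hashes and the seeds used.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  for (f in c("genome_fasta", "gene_table", "samples", "out_dir"))
    if (is.null(config[[f]])) stop("config is missing '", f, "'")
  for (f in c("genome_fasta", "vcf", "gene_table", "te_table",
              "expression_tsv", "de_table_tsv"))
    if (!is.null(config[[f]]) && is.character(config[[f]]) &&
        !file.exists(config[[f]]))
      stop("input file not found: ", config[[f]])
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  min_cov <- config$min_coverage %||% 4L
  max_cov <- config$max_coverage %||% 100L
  params <- do.call(dmr_params, config$dmr %||% list())
  n_iter <- config$n_iter %||% 1000L
  n_shuffles <- config$n_shuffles %||% 500L
  outputs <- character(0)
  log <- function(...) message(sprintf(...))

  genome <- Biostrings::readDNAStringSet(config$genome_fasta)
  samples_tab <- config$samples
  if (is.character(samples_tab))
    samples_tab <- as.data.frame(data.table::fread(samples_tab))
  for (p in samples_tab$path)
    if (!file.exists(p)) stop("cytosine report not found: ", p)
  species <- sort(unique(samples_tab$species))
  tissues <- sort(unique(samples_tab$tissue))

  ## stage 1: SNP-corrected reference genomes -------------------------
  snps <- NULL
  if (!is.null(config$vcf)) {
    log("[bsref] building SNP-corrected genomes for %d species",
        length(species))
    snps <- read_snp_table(config$vcf)
    reports <- list()
    for (sp in species) {
      fa <- file.path(out_dir, sprintf("genome_corrected_%s.fa", sp))
      r <- build_snp_corrected_reference(genome, snps, species = sp,
                                         out_fasta = fa)
      reports[[sp]] <- r$report
      outputs <- c(outputs, fa)
    }
    rep_path <- file.path(out_dir, "bsref_report.tsv")
    data.table::fwrite(do.call(rbind, reports), rep_path, sep = "\t")
    outputs <- c(outputs, rep_path)
  }

  ## stage 2: methylomes -----------------------------------------------
  log("[methio] loading %d cytosine reports", nrow(samples_tab))
  samples <- lapply(seq_len(nrow(samples_tab)), function(i)
    load_methylome(samples_tab$path[i], min_coverage = min_cov,
                   max_coverage = max_cov,
                   sample_id = samples_tab$sample_id[i],
                   species = samples_tab$species[i],
                   tissue = samples_tab$tissue[i],
                   replicate = samples_tab$replicate[i]))
  names(samples) <- samples_tab$sample_id

  ## stage 3: genomic features ------------------------------------------
  log("[features] predicting CGIs and building the feature map")
  main_contigs <- setdiff(names(genome), config$spike_contig %||% "lambda_spike")
  contig_sizes <- stats::setNames(Biostrings::width(genome[main_contigs]),
                                  main_contigs)
  genes <- as.data.frame(data.table::fread(config$gene_table))
  cgis <- predict_cgi(genome[main_contigs])
  tes <- if (!is.null(config$te_table))
    parse_repeatmasker_out(config$te_table) else NULL
  fmap <- build_feature_map(genes, cgis, tes, contig_sizes)

  ## stage 4: pairwise DMRs and classification --------------------------
  log("[dmr] calling pairwise DMRs (%d species, %d tissue(s))",
      length(species), length(tissues))
  pairs <- utils::combn(species, 2, simplify = FALSE)
  dmrs_by_tissue <- list()
  classified <- list()
  for (tt in tissues) {
    dl <- lapply(pairs, function(pr) {
      sa <- samples[samples_tab$sample_id[samples_tab$species == pr[1] &
                                            samples_tab$tissue == tt]]
      sb <- samples[samples_tab$sample_id[samples_tab$species == pr[2] &
                                            samples_tab$tissue == tt]]
      call_dmrs(sa, sb, params, group_a = pr[1], group_b = pr[2],
                tissue = tt)
    })
    names(dl) <- vapply(pairs, paste, character(1), collapse = "|")
    dmrs_by_tissue[[tt]] <- dl
    all_dmrs <- do.call(rbind, dl)
    bed <- file.path(out_dir, sprintf("dmrs_%s.bed", tt))
    write_dmr_bed(all_dmrs, bed)
    outputs <- c(outputs, bed)
    if (length(species) == 3)
      classified[[tt]] <- classify_species_dmrs(dl, species)
  }
  scope <- NULL
  if (length(classified) == 2) {
    scope <- classify_tissue_scope(classified[[1]], classified[[2]])
    sc_path <- file.path(out_dir, "species_dmr_tissue_scope.tsv")
    data.table::fwrite(scope$regions, sc_path, sep = "\t")
    outputs <- c(outputs, sc_path)
  }

  ## stage 5: enrichment -------------------------------------------------
  enrich <- te_fam <- te_div <- NULL
  union_dmrs <- do.call(rbind, lapply(dmrs_by_tissue[[1]], identity))
  if (NROW(union_dmrs)) {
    log("[enrich] O/E enrichment over %d iterations", n_iter)
    enrich <- oe_enrichment(union_dmrs, fmap, n_iter = n_iter, seed = seed)
    en_path <- file.path(out_dir, "enrichment.tsv")
    data.table::fwrite(enrich$table, en_path, sep = "\t")
    outputs <- c(outputs, en_path)
    if (!is.null(tes) && NROW(tes)) {
      te_fam <- te_family_enrichment(union_dmrs, tes, contig_sizes,
                                     n_iter = n_iter, seed = seed + 1L)
      te_div <- tryCatch(
        te_divergence_profile(union_dmrs, tes, contig_sizes,
                              n_shuffles = n_shuffles, seed = seed + 2L),
        error = function(e) NULL)
      tf_path <- file.path(out_dir, "te_family_enrichment.tsv")
      data.table::fwrite(te_fam$table, tf_path, sep = "\t")
      outputs <- c(outputs, tf_path)
    }
  }

  ## stage 6: integration -------------------------------------------------
  integ <- NULL
  if (!is.null(config$expression_tsv) && !is.null(config$de_table_tsv) &&
      NROW(union_dmrs)) {
    log("[integrate] pfDMRs and methylation-expression correlation")
    tpm_dt <- data.table::fread(config$expression_tsv)
    tpm <- as.matrix(tpm_dt[, -1, drop = FALSE])
    rownames(tpm) <- tpm_dt[[1]]
    meta <- data.frame(sample_id = colnames(tpm))
    parts <- data.table::tstrsplit(meta$sample_id, "_")
    meta$species <- parts[[1]]
    meta$tissue <- parts[[2]]
    expr <- list(tpm = tpm, metadata = meta)
    de_table <- as.data.frame(data.table::fread(config$de_table_tsv))
    assigned <- assign_dmr_to_gene(union_dmrs, fmap)
    degs <- filter_degs(de_table, expr, tissue = tissues[1])
    integ <- pfdmr_overlap_test(assigned, degs, rownames(tpm), fmap)
    pf_path <- file.path(out_dir, "pfdmrs.tsv")
    data.table::fwrite(integ$pfdmrs, pf_path, sep = "\t")
    outputs <- c(outputs, pf_path)
  }

  ## stage 7: clustering ---------------------------------------------------
  clust <- NULL
  if (length(samples) >= 3) {
    log("[cluster] conserved-CpG matrix and dendrogram")
    mat <- conserved_cpg_matrix(samples, snps)
    clust <- cluster_methylomes(mat)
    cm_path <- file.path(out_dir, "sample_correlation.tsv")
    data.table::fwrite(data.table::data.table(sample_id =
                                                rownames(clust$correlation),
                                              clust$correlation),
                       cm_path, sep = "\t")
    nw_path <- file.path(out_dir, "dendrogram.nwk")
    writeLines(clust$newick, nw_path)
    outputs <- c(outputs, cm_path, nw_path)
  }

  manifest <- list(
    seed = seed,
    inputs = as.list(tools::md5sum(unlist(Filter(
      function(x) is.character(x) && file.exists(x),
      config[c("genome_fasta", "vcf", "gene_table", "te_table",
               "expression_tsv", "de_table_tsv")])))),
    outputs = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, dmrs = dmrs_by_tissue,
                 classified = classified, tissue_scope = scope,
                 enrichment = enrich, te_family = te_fam,
                 te_divergence = te_div, integration = integ,
                 clustering = clust, feature_map = fmap))
}
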