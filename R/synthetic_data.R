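#' Synthetic WGBS study generator with planted truth
#'
#' Generates a complete, internally consistent toy dataset — genome, SNPs,
#' gene models, transposable elements, CpG islands, replicated multi-species
#' multi-tissue methylomes, and expression — with machine-readable ground
#' truth, so that every downstream stage (SNP correction, DMR calling,
#' classification, enrichment, integration) can be verified against what
#' was planted.
#'
#' The count model is the standard WGBS one: per CpG and sample, coverage
#' is Poisson(mean_coverage) and the methylated count is beta-binomial with
#' mean p and overdispersion phi (alpha = p(1-phi)/phi,
#' beta = (1-p)(1-phi)/phi), so phi = 0 collapses to the binomial. Both
#' strands of each CpG are emitted, counts split binomially between
#' strands.
#'
#' @name synthetic_data
NULL

#' Design of a synthetic comparative-methylome study
#'
#' Returns a validated design object; all arguments have defaults
#' describing a three-species, two-tissue study on a 1-Mb toy genome.
#'
#' @param seed integer seed; the same design yields byte-identical outputs.
#' @param n_contigs,contig_length genome shape.
#' @param n_species,n_tissues,n_replicates sampling design (species are
#'   labelled sp1..spN; tissues liver, muscle, ...).
#' @param mean_coverage mean reads per CpG (Poisson).
#' @param dispersion beta-binomial overdispersion phi in \[0, 1).
#' @param background_meth genome-wide background methylation fraction
#'   (high, mimicking a globally methylated vertebrate genome).
#' @param n_dmrs number of planted species-specific DMRs.
#' @param dmr_length_range planted DMR lengths (bp).
#' @param dmr_delta planted methylation-fraction difference in (0, 1\].
#' @param frac_multi_tissue fraction of planted species-DMRs present in
#'   both tissues.
#' @param frac_promoter_dmrs,frac_te_dmrs fractions of planted DMRs
#'   centred on gene promoters (driving the expression coupling) and
#'   inside young TEs.
#' @param n_tissue_dmrs,tissue_delta planted tissue-differential regions
#'   shared by all species (these dominate the clustering structure, as
#'   between-tissue differences do in real data).
#' @param n_genes,gene_length_range gene landscape.
#' @param n_tes,te_length_range,te_young_divergence,te_old_divergence,frac_young_te
#'   TE landscape: Kimura-style percent divergence means of the young and
#'   old fractions.
#' @param n_cgis,cgi_length_range,frac_promoter_cgi CpG-island truth
#'   intervals (sequence composition is CG-enriched inside them).
#' @param n_snps,snp_bisulfite_frac SNPs per species and the fraction that
#'   are bisulfite-confounded (C>T / G>A).
#' @param expr_coupling strength (log2 units per unit methylation
#'   difference) of the planted promoter-methylation -> expression
#'   relation; positive values mean promoter hypermethylation lowers
#'   expression.
#' @param off_fraction fraction of genes silent (TPM = 0 in all
#'   replicates).
#' @param frac_species_de fraction of genes with species-level expression
#'   differences unrelated to methylation.
#' @param spike_in,spike_length,nonconversion unmethylated spike-in contig
#'   emulating the lambda conversion control.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(seed = 1L,
                              n_contigs = 2L, contig_length = 5e5,
                              n_species = 3L, n_tissues = 2L,
                              n_replicates = 2L,
                              mean_coverage = 15, dispersion = 0.05,
                              background_meth = 0.8,
                              n_dmrs = 100L, dmr_length_range = c(300L, 800L),
                              dmr_delta = 0.5, frac_multi_tissue = 0.45,
                              frac_promoter_dmrs = 0.3, frac_te_dmrs = 0.3,
                              n_tissue_dmrs = 150L, tissue_delta = 0.4,
                              n_genes = 150L,
                              gene_length_range = c(1000L, 3000L),
                              n_tes = 300L, te_length_range = c(100L, 600L),
                              te_young_divergence = 5,
                              te_old_divergence = 25, frac_young_te = 0.5,
                              n_cgis = 60L, cgi_length_range = c(300L, 600L),
                              frac_promoter_cgi = 0.5,
                              n_snps = 400L, snp_bisulfite_frac = 0.6,
                              expr_coupling = 4, off_fraction = 0.2,
                              frac_species_de = 0.1,
                              spike_in = TRUE, spike_length = 2000L,
                              nonconversion = 0.005) {
  d <- as.list(environment())
  fr <- c("dispersion", "background_meth", "frac_multi_tissue",
          "frac_promoter_dmrs", "frac_te_dmrs", "snp_bisulfite_frac",
          "off_fraction", "frac_species_de", "frac_young_te",
          "frac_promoter_cgi", "nonconversion")
  for (f in fr)
    if (d[[f]] < 0 || d[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (d$dispersion >= 1) stop("dispersion must be < 1")
  if (d$dmr_delta <= 0 || d$dmr_delta > 1)
    stop("dmr_delta must lie in (0, 1]")
  for (f in c("n_contigs", "contig_length", "n_species", "n_tissues",
              "n_replicates", "mean_coverage"))
    if (d[[f]] <= 0) stop(f, " must be positive")
  if (any(d$dmr_length_range <= 0) || diff(d$dmr_length_range) < 0)
    stop("invalid dmr_length_range")
  structure(d, class = "simulation_design")
}

.tissue_names <- function(n) c("liver", "muscle",
                               paste0("tissue", seq_len(max(0, n - 2)) + 2))[seq_len(n)]
.species_names <- function(n) paste0("sp", seq_len(n))

.rand_intervals <- function(n, len_range, contig_sizes) {
  len <- if (len_range[1] == len_range[2]) rep(len_range[1], n) else
    sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  ctg <- sample(names(contig_sizes), n, replace = TRUE,
                prob = contig_sizes / sum(contig_sizes))
  maxs <- contig_sizes[ctg] - len + 1
  if (any(maxs < 1)) stop("interval longer than contig")
  start <- floor(stats::runif(n, 1, maxs + 1))
  GenomicRanges::GRanges(ctg, IRanges::IRanges(as.integer(start),
                                               as.integer(start + len - 1L)))
}

# rejection-sample n intervals that avoid `avoid` and satisfy `predicate`
.place_nonoverlapping <- function(n, len_range, contig_sizes,
                                  avoid = GenomicRanges::GRanges(),
                                  predicate = NULL, what = "intervals",
                                  max_rounds = 200L) {
  placed <- GenomicRanges::GRanges()
  rounds <- 0L
  while (length(placed) < n) {
    rounds <- rounds + 1L
    if (rounds > max_rounds)
      stop(sprintf(
        "infeasible placement: could not fit %d non-overlapping %s of %d-%d bp into %g bp of genome",
        n, what, len_range[1], len_range[2], sum(contig_sizes)))
    cand <- .rand_intervals(max(16L, n - length(placed)), len_range,
                            contig_sizes)
    ok <- !IRanges::overlapsAny(cand, c(placed, avoid))
    cand <- cand[ok]
    if (!is.null(predicate) && length(cand)) cand <- cand[predicate(cand)]
    cand <- .greedy_nonoverlap(cand)
    need <- n - length(placed)
    placed <- c(placed, cand[seq_len(min(need, length(cand)))])
  }
  placed
}

# keep a maximal left-to-right non-overlapping subset, plain vectors
.greedy_nonoverlap <- function(gr) {
  if (length(gr) < 2) return(gr)
  ctg <- as.character(GenomicRanges::seqnames(gr))
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  keep <- logical(length(gr))
  for (cc in unique(ctg)) {
    i <- which(ctg == cc)
    o <- i[order(st[i])]
    last_end <- -Inf
    for (j in o) {
      if (st[j] > last_end) {
        keep[j] <- TRUE
        last_end <- en[j]
      }
    }
  }
  gr[keep]
}

.random_seq <- function(n, probs) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

#' Generate the synthetic reference set
#'
#' Builds the genome (FASTA), per-species SNP table (VCF), gene models,
#' TE annotation, CpG-island truth and the planted-DMR truth records.
#' Sequence is drawn i.i.d. per base with a CG-enriched composition inside
#' the designated CGI intervals, giving the island predictor a real
#' signal; planted DMRs are only placed where at least 4 CpGs fall inside
#' the interval, so they are callable by construction.
#'
#' @param design a [simulation_design()].
#' @param out_dir optional directory; if given, `genome.fa`, `snps.vcf`,
#'   `genes.tsv`, `tes.tsv`, `truth.tsv`, `truth.json` and `design.yaml`
#'   are written there.
#' @return A `reference_set` list with the genome (`DNAStringSet`),
#'   `contig_sizes`, `genes`, `tes`, `snps`, `cgi_truth`, `dmr_truth`,
#'   `tissue_dmr_truth`, per-contig CpG positions and per-gene regulatory
#'   attributes (activity, baseline promoter/body methylation, OFF flag).
#' @export
generate_reference_set <- function(design, out_dir = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  d <- design
  contigs <- paste0("ctg", seq_len(d$n_contigs))
  contig_sizes <- stats::setNames(rep(as.integer(d$contig_length),
                                      d$n_contigs), contigs)

  ## --- gene models: evenly slotted so placement is always feasible ----
  per_ctg <- diff(round(seq(0, d$n_genes, length.out = d$n_contigs + 1)))
  genes <- list()
  gid <- 0L
  for (ci in seq_along(contigs)) {
    ng <- per_ctg[ci]
    if (ng == 0) next
    slot <- d$contig_length / ng
    pad <- 700L  # promoter + vicinity margin
    if (slot < max(d$gene_length_range) + 2 * pad)
      stop(sprintf(
        "infeasible placement: %d genes of up to %d bp do not fit contig of %g bp",
        ng, max(d$gene_length_range), d$contig_length))
    len <- sample(seq(d$gene_length_range[1], d$gene_length_range[2]), ng,
                  replace = TRUE)
    jitter_max <- slot - len - 2 * pad
    start <- as.integer((seq_len(ng) - 1) * slot + pad +
                          floor(stats::runif(ng) * jitter_max))
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    gene_ids <- sprintf("gene%04d", gid + seq_len(ng))
    gid <- gid + ng
    genes[[ci]] <- data.frame(
      gene_id = gene_ids, contig = contigs[ci], strand = strand,
      tss = ifelse(strand == "+", start, start + len - 1L),
      tes = ifelse(strand == "+", start + len - 1L, start))
  }
  genes <- do.call(rbind, genes)

  ## --- CpG-island truth: part on promoters, part orphan ---------------
  n_prom_cgi <- round(d$n_cgis * d$frac_promoter_cgi)
  prom_gr <- GenomicRanges::GRanges(
    genes$contig, IRanges::IRanges(genes$tss - 500L, genes$tss + 499L))
  cgi_genes <- sample(nrow(genes), min(n_prom_cgi, nrow(genes)))
  cgi_len <- sample(seq(d$cgi_length_range[1], d$cgi_length_range[2]),
                    length(cgi_genes) + (d$n_cgis - length(cgi_genes)),
                    replace = TRUE)
  prom_cgi <- GenomicRanges::GRanges(
    genes$contig[cgi_genes],
    IRanges::IRanges(
      pmax(1L, genes$tss[cgi_genes] -
             as.integer(cgi_len[seq_along(cgi_genes)] / 2)),
      width = cgi_len[seq_along(cgi_genes)]))
  n_orphan <- d$n_cgis - length(cgi_genes)
  orphan_cgi <- .place_nonoverlapping(
    n_orphan, d$cgi_length_range, contig_sizes,
    avoid = c(GenomicRanges::reduce(prom_gr), GenomicRanges::reduce(prom_cgi)),
    what = "orphan CGIs")
  cgi_truth <- c(prom_cgi, orphan_cgi)
  S4Vectors::mcols(cgi_truth)$cgi_class <-
    rep(c("promoter", "orphan"), c(length(prom_cgi), length(orphan_cgi)))

  ## --- sequence: iid bases, CG-enriched inside CGI truth --------------
  bg_probs <- c(A = 0.295, C = 0.205, G = 0.205, T = 0.295)
  cgi_probs <- c(A = 0.12, C = 0.38, G = 0.38, T = 0.12)
  seqs <- character(length(contigs))
  names(seqs) <- contigs
  for (ctg in contigs) {
    s <- sample(c("A", "C", "G", "T"), contig_sizes[[ctg]], replace = TRUE,
                prob = bg_probs)
    isl <- cgi_truth[GenomicRanges::seqnames(cgi_truth) == ctg]
    for (i in seq_along(isl)) {
      idx <- GenomicRanges::start(isl[i]):GenomicRanges::end(isl[i])
      s[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE,
                       prob = cgi_probs)
    }
    seqs[[ctg]] <- paste(s, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(seqs)

  # CpG (C on plus strand) positions per contig
  cpg_pos <- lapply(contigs, function(ctg)
    Biostrings::start(Biostrings::matchPattern("CG", genome[[ctg]])))
  names(cpg_pos) <- contigs

  n_cpg_in <- function(gr) {
    ctg <- as.character(GenomicRanges::seqnames(gr))
    st <- GenomicRanges::start(gr)
    en <- GenomicRanges::end(gr)
    out <- integer(length(gr))
    for (cc in unique(ctg)) {
      i <- ctg == cc
      p <- cpg_pos[[cc]]  # sorted
      out[i] <- findInterval(en[i], p) - findInterval(st[i] - 1L, p)
    }
    out
  }

  ## --- TEs: uniform placement, young/old divergence mixture -----------
  te_gr <- .rand_intervals(d$n_tes, d$te_length_range, contig_sizes)
  young <- stats::runif(d$n_tes) < d$frac_young_te
  young_fams <- c("hAT6", "SINE/Alu", "LINE/L1")
  old_fams <- c("LINE/R2-Hero", "DNA/Maverick", "Tc2-Mariner")
  fam <- ifelse(young, sample(young_fams, d$n_tes, replace = TRUE),
                sample(old_fams, d$n_tes, replace = TRUE))
  divg <- pmax(0.1, stats::rnorm(d$n_tes,
                                 ifelse(young, d$te_young_divergence,
                                        d$te_old_divergence), 3))
  tes <- data.frame(contig = as.character(GenomicRanges::seqnames(te_gr)),
                    start = GenomicRanges::start(te_gr),
                    end = GenomicRanges::end(te_gr),
                    family = fam,
                    te_class = ifelse(grepl("^(hAT|DNA|Tc2)", fam), "DNA",
                                      ifelse(grepl("SINE", fam), "SINE",
                                             "LINE")),
                    divergence = round(divg, 2))
  tes <- tes[order(tes$contig, tes$start), ]
  rownames(tes) <- NULL

  ## --- per-gene regulatory attributes ---------------------------------
  ng <- nrow(genes)
  activity <- stats::runif(ng)
  off <- activity <= stats::quantile(activity, d$off_fraction)
  prom_meth <- pmin(0.98, pmax(0.02,
                               0.92 - 0.85 * activity +
                                 stats::rnorm(ng, 0, 0.03)))
  body_meth <- pmin(0.98, pmax(0.02,
                               0.45 + 0.45 * activity +
                                 stats::rnorm(ng, 0, 0.03)))
  gene_attrs <- data.frame(gene_id = genes$gene_id, activity = activity,
                           off = off, prom_meth = prom_meth,
                           body_meth = body_meth)

  ## --- planted tissue-differential regions ----------------------------
  tissue_dmr_gr <- if (d$n_tissues >= 2 && d$n_tissue_dmrs > 0)
    .place_nonoverlapping(d$n_tissue_dmrs, d$dmr_length_range, contig_sizes,
                          avoid = GenomicRanges::reduce(prom_gr),
                          predicate = function(g) n_cpg_in(g) >= 4,
                          what = "tissue-DMRs")
  else GenomicRanges::GRanges()

  ## --- planted species-specific DMRs -----------------------------------
  species <- .species_names(d$n_species)
  tissues <- .tissue_names(d$n_tissues)
  n_prom_dmr <- round(d$n_dmrs * d$frac_promoter_dmrs)
  n_te_dmr <- round(d$n_dmrs * d$frac_te_dmrs)
  n_bg_dmr <- d$n_dmrs - n_prom_dmr - n_te_dmr

  placed <- GenomicRanges::GRanges()
  kind_vec <- character(0)
  gene_of <- character(0)

  # promoter-centred DMRs carry the expression coupling; they are planted
  # on strongly expressed genes (activity boosted into [0.8, 1]) so that
  # the planted regulatory shift is measurable on the TPM scale, mirroring
  # the strongly expressed metabolic genes such divergence shows up in
  if (n_prom_dmr > 0) {
    cand_genes <- which(!gene_attrs$off)
    if (length(cand_genes) < n_prom_dmr)
      stop("infeasible placement: not enough expressed genes for promoter DMRs")
    pick <- sample(cand_genes, n_prom_dmr)
    gene_attrs$activity[pick] <- stats::runif(n_prom_dmr, 0.8, 1)
    gene_attrs$prom_meth[pick] <- pmin(0.98, pmax(
      0.02, 0.92 - 0.85 * gene_attrs$activity[pick] +
        stats::rnorm(n_prom_dmr, 0, 0.03)))
    gene_attrs$body_meth[pick] <- pmin(0.98, pmax(
      0.02, 0.45 + 0.45 * gene_attrs$activity[pick] +
        stats::rnorm(n_prom_dmr, 0, 0.03)))
    len <- sample(seq(d$dmr_length_range[1], d$dmr_length_range[2]),
                  n_prom_dmr, replace = TRUE)
    pg <- GenomicRanges::GRanges(
      genes$contig[pick],
      IRanges::IRanges(pmax(1L, genes$tss[pick] - as.integer(len / 2)),
                       width = len))
    ok <- !IRanges::overlapsAny(pg, c(placed, tissue_dmr_gr)) &
      n_cpg_in(pg) >= 4
    pg <- pg[ok]
    pg1 <- .greedy_nonoverlap(pg)
    if (length(pg1) < n_prom_dmr)
      stop("infeasible placement: not enough promoter DMR sites with >= 4 CpGs")
    pg1 <- pg1[seq_len(n_prom_dmr)]
    hit <- GenomicRanges::findOverlaps(pg1, prom_gr, select = "first")
    placed <- c(placed, pg1)
    kind_vec <- c(kind_vec, rep("promoter", n_prom_dmr))
    gene_of <- c(gene_of, genes$gene_id[hit])
  }

  # TE-hosted DMRs: centred inside young TEs
  if (n_te_dmr > 0) {
    yte <- te_gr[young]
    if (!length(yte)) stop("no young TEs to host TE-DMRs")
    te_dmrs <- GenomicRanges::GRanges()
    tries <- 0L
    while (length(te_dmrs) < n_te_dmr) {
      tries <- tries + 1L
      if (tries > 200L)
        stop("infeasible placement: could not fit TE-hosted DMRs")
      i <- sample(length(yte), 1)
      len <- sample(seq(d$dmr_length_range[1], d$dmr_length_range[2]), 1)
      ctr <- as.integer((GenomicRanges::start(yte[i]) +
                           GenomicRanges::end(yte[i])) / 2)
      g <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(yte[i]),
        IRanges::IRanges(max(1L, ctr - as.integer(len / 2)), width = len))
      if (GenomicRanges::end(g) > contig_sizes[[as.character(
        GenomicRanges::seqnames(g))]]) next
      if (IRanges::overlapsAny(g, c(placed, te_dmrs, tissue_dmr_gr,
                                    GenomicRanges::reduce(prom_gr))))
        next
      if (n_cpg_in(g) < 4) next
      te_dmrs <- c(te_dmrs, g)
    }
    placed <- c(placed, te_dmrs)
    kind_vec <- c(kind_vec, rep("te", n_te_dmr))
    gene_of <- c(gene_of, rep(NA_character_, n_te_dmr))
  }

  # background DMRs anywhere else with >= 4 CpGs
  if (n_bg_dmr > 0) {
    bg <- .place_nonoverlapping(
      n_bg_dmr, d$dmr_length_range, contig_sizes,
      avoid = c(placed, tissue_dmr_gr, GenomicRanges::reduce(prom_gr)),
      predicate = function(g) n_cpg_in(g) >= 4, what = "planted DMRs")
    placed <- c(placed, bg)
    kind_vec <- c(kind_vec, rep("background", n_bg_dmr))
    gene_of <- c(gene_of, rep(NA_character_, n_bg_dmr))
  }

  target <- rep(species, length.out = length(placed))
  multi <- stats::runif(length(placed)) < d$frac_multi_tissue
  scope <- ifelse(multi, "multi",
                  sample(tissues, length(placed), replace = TRUE))
  if (d$n_tissues == 1) scope <- rep(tissues[1], length(placed))

  # baseline methylation at the DMR decides the shift direction: regions
  # sitting high get hypomethylated in the target species and vice versa
  base_at <- rep(d$background_meth, length(placed))
  if (n_prom_dmr > 0)
    base_at[kind_vec == "promoter"] <-
      gene_attrs$prom_meth[match(gene_of[kind_vec == "promoter"],
                                 gene_attrs$gene_id)]
  direction <- ifelse(base_at >= 0.5, -1L, 1L)

  dmr_truth <- data.frame(
    contig = as.character(GenomicRanges::seqnames(placed)),
    start = GenomicRanges::start(placed),
    end = GenomicRanges::end(placed),
    species = target, tissue_scope = scope, direction = direction,
    delta = rep(d$dmr_delta, length(placed)), kind = kind_vec,
    gene_id = gene_of, n_cpgs = n_cpg_in(placed))
  dmr_truth <- dmr_truth[order(dmr_truth$contig, dmr_truth$start), ]
  rownames(dmr_truth) <- NULL

  tissue_dmr_truth <- if (length(tissue_dmr_gr)) data.frame(
    contig = as.character(GenomicRanges::seqnames(tissue_dmr_gr)),
    start = GenomicRanges::start(tissue_dmr_gr),
    end = GenomicRanges::end(tissue_dmr_gr),
    delta = d$tissue_delta,
    n_cpgs = n_cpg_in(tissue_dmr_gr)) else
      data.frame(contig = character(0), start = integer(0),
                 end = integer(0), delta = numeric(0), n_cpgs = integer(0))
  if (NROW(tissue_dmr_truth)) {
    tissue_dmr_truth <- tissue_dmr_truth[order(tissue_dmr_truth$contig,
                                               tissue_dmr_truth$start), ]
    rownames(tissue_dmr_truth) <- NULL
  }

  ## --- SNPs per species -------------------------------------------------
  snps <- list()
  for (sp in species) {
    n_bis <- round(d$n_snps * d$snp_bisulfite_frac)
    n_oth <- d$n_snps - n_bis
    per <- round(c(n_bis, n_oth) * contig_sizes / sum(contig_sizes))
    rows <- list()
    for (ci in seq_along(contigs)) {
      ctg <- contigs[ci]
      b <- strsplit(seqs[[ctg]], "", fixed = TRUE)[[1]]
      cg_pos <- which(b %in% c("C", "G"))
      at_pos <- which(b %in% c("A", "T"))
      nb <- round(n_bis * contig_sizes[[ctg]] / sum(contig_sizes))
      no <- round(n_oth * contig_sizes[[ctg]] / sum(contig_sizes))
      p1 <- sample(cg_pos, nb)
      r1 <- b[p1]
      a1 <- ifelse(r1 == "C", "T", "A")
      p2 <- sample(setdiff(c(cg_pos, at_pos), p1), no)
      r2 <- b[p2]
      a2 <- vapply(r2, function(rb) {
        alts <- setdiff(c("A", "C", "G", "T"), rb)
        if (rb == "C") alts <- setdiff(alts, "T")
        if (rb == "G") alts <- setdiff(alts, "A")
        sample(alts, 1)
      }, character(1))
      rows[[ci]] <- data.frame(contig = ctg, pos = c(p1, p2),
                               ref = c(r1, r2), alt = c(a1, a2),
                               species = sp)
    }
    snps[[sp]] <- do.call(rbind, rows)
  }
  snps <- do.call(rbind, snps)
  snps <- snps[order(snps$contig, snps$pos), ]
  rownames(snps) <- NULL

  ## --- spike-in contig --------------------------------------------------
  spike_seq <- if (d$spike_in)
    .random_seq(d$spike_length, c(0.25, 0.25, 0.25, 0.25)) else NULL
  if (d$spike_in)
    genome <- c(genome,
                Biostrings::DNAStringSet(c(lambda_spike = spike_seq)))

  ref <- structure(list(
    design = d, genome = genome, contig_sizes = contig_sizes,
    genes = genes, tes = tes, snps = snps, cgi_truth = cgi_truth,
    dmr_truth = dmr_truth, tissue_dmr_truth = tissue_dmr_truth,
    gene_attrs = gene_attrs, cpg_pos = cpg_pos,
    species = species, tissues = tissues,
    spike_contig = if (d$spike_in) "lambda_spike" else NULL),
    class = "reference_set")

  if (!is.null(out_dir)) .write_reference_set(ref, out_dir)
  ref
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf(
    "reference_set: %d contig(s) x %g bp, %d genes, %d TEs, %d CGIs, %d planted DMRs, %d tissue regions, %d SNPs\n",
    length(x$contig_sizes), x$design$contig_length, nrow(x$genes),
    nrow(x$tes), length(x$cgi_truth), nrow(x$dmr_truth),
    nrow(x$tissue_dmr_truth), nrow(x$snps)))
  invisible(x)
}

.write_reference_set <- function(ref, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(ref$genome, file.path(out_dir, "genome.fa"),
                              width = 60L)
  data.table::fwrite(ref$genes, file.path(out_dir, "genes.tsv"), sep = "\t")
  data.table::fwrite(ref$tes, file.path(out_dir, "tes.tsv"), sep = "\t",
                     col.names = FALSE)
  # truth: 0-based half-open on disk
  tr <- rbind(
    data.frame(kind = "dmr", contig = ref$dmr_truth$contig,
               start = ref$dmr_truth$start - 1L, end = ref$dmr_truth$end,
               attributes = sprintf(
                 "species=%s;tissue_scope=%s;direction=%d;delta=%g;kind=%s;gene=%s",
                 ref$dmr_truth$species, ref$dmr_truth$tissue_scope,
                 ref$dmr_truth$direction, ref$dmr_truth$delta,
                 ref$dmr_truth$kind, ref$dmr_truth$gene_id)),
    data.frame(kind = "cgi",
               contig = as.character(GenomicRanges::seqnames(ref$cgi_truth)),
               start = GenomicRanges::start(ref$cgi_truth) - 1L,
               end = GenomicRanges::end(ref$cgi_truth),
               attributes = paste0("class=",
                                   S4Vectors::mcols(ref$cgi_truth)$cgi_class)))
  data.table::fwrite(tr, file.path(out_dir, "truth.tsv"), sep = "\t")
  jsonlite::write_json(
    list(dmr = ref$dmr_truth, tissue_dmr = ref$tissue_dmr_truth,
         gene_attrs = ref$gene_attrs),
    file.path(out_dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  yaml::write_yaml(unclass(ref$design), file.path(out_dir, "design.yaml"))
  .write_vcf(ref$snps, ref$contig_sizes, file.path(out_dir, "snps.vcf"))
  invisible(out_dir)
}

.write_vcf <- function(snps, contig_sizes, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contig_sizes),
                   as.integer(contig_sizes)),
           "##INFO=<ID=SPECIES,Number=1,Type=String,Description=\"Species carrying the alternate allele\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tSPECIES=%s",
                  snps$contig, snps$pos, snps$ref, snps$alt, snps$species)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# index range of sorted positions inside [start, end]
.pos_slice <- function(pos, start, end) {
  lo <- findInterval(start - 1L, pos) + 1L
  hi <- findInterval(end, pos)
  if (hi < lo) integer(0) else lo:hi
}

# per-CpG baseline methylation for one tissue (before species DMR shifts)
.baseline_meth <- function(ref, tissue) {
  d <- ref$design
  out <- list()
  for (ctg in names(ref$cpg_pos)) {
    pos <- ref$cpg_pos[[ctg]]
    p <- rep(d$background_meth, length(pos))
    g <- ref$genes[ref$genes$contig == ctg, ]
    ga <- ref$gene_attrs[match(g$gene_id, ref$gene_attrs$gene_id), ]
    if (nrow(g)) {
      plus <- g$strand == "+"
      bs <- ifelse(plus, g$tss + 500L, pmin(g$tss, g$tes))
      be <- ifelse(plus, pmax(g$tss, g$tes), g$tss - 500L)
      for (i in seq_len(nrow(g)))
        if (bs[i] <= be[i])
          p[.pos_slice(pos, bs[i], be[i])] <- ga$body_meth[i]
      for (i in seq_len(nrow(g)))  # promoter overrides body
        p[.pos_slice(pos, g$tss[i] - 500L, g$tss[i] + 499L)] <-
          ga$prom_meth[i]
    }
    # tissue-differential regions: second and later tissues shift
    if (tissue != ref$tissues[1] && NROW(ref$tissue_dmr_truth)) {
      td <- ref$tissue_dmr_truth[ref$tissue_dmr_truth$contig == ctg, ]
      for (i in seq_len(nrow(td))) {
        sel <- .pos_slice(pos, td$start[i], td$end[i])
        p[sel] <- p[sel] + ifelse(p[sel] >= 0.5, -1, 1) * td$delta[i]
      }
    }
    out[[ctg]] <- p
  }
  out
}

#' Simulate replicated multi-species methylomes
#'
#' For each sample (species x tissue x replicate) and CpG, draws coverage
#' ~ Poisson(mean_coverage) and a methylated count ~ beta-binomial
#' (coverage, p, dispersion), where p is the regional baseline modified
#' inside planted DMRs (shifted by the planted delta for the target
#' species, in the tissues the truth record covers). Both strands are
#' emitted with counts split binomially. If the design includes a
#' spike-in, an unmethylated spike contig is appended to every report
#' (all cytosine contexts).
#'
#' @param design the [simulation_design()] used to build `ref`.
#' @param ref a [generate_reference_set()] result.
#' @param out_dir optional directory for one cytosine-report TSV per
#'   sample.
#' @return A `methylome_set`: list with `samples` (per-sample metadata and
#'   raw stranded count tables) and the design. Use
#'   [as_methylome_samples()] to destrand and coverage-filter.
#' @export
simulate_methylomes <- function(design, ref, out_dir = NULL) {
  stopifnot(inherits(ref, "reference_set"))
  d <- design
  set.seed(d$seed + 1L)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  contigs <- names(ref$contig_sizes)
  all_pos <- unlist(ref$cpg_pos, use.names = FALSE)
  all_ctg <- rep(contigs, lengths(ref$cpg_pos))
  ncpg <- length(all_pos)

  # trinucleotides (cosmetic column of the report)
  tri_plus <- character(ncpg)
  tri_minus <- character(ncpg)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  off <- 0L
  for (ctg in contigs) {
    s <- as.character(ref$genome[[ctg]])
    pos <- ref$cpg_pos[[ctg]]
    nx <- substring(s, pos + 2L, pos + 2L)
    pv <- substring(s, pos - 1L, pos - 1L)
    nx[nx == ""] <- "N"; pv[pv == ""] <- "N"
    tri_plus[off + seq_along(pos)] <- paste0("CG", nx)
    tri_minus[off + seq_along(pos)] <- paste0("CG", comp[pv])
    off <- off + length(pos)
  }

  baselines <- lapply(ref$tissues, function(tt)
    unlist(.baseline_meth(ref, tt), use.names = FALSE))
  names(baselines) <- ref$tissues

  ctg_offset <- c(0L, cumsum(lengths(ref$cpg_pos)))
  names(ctg_offset) <- c(names(ref$cpg_pos), "_end")
  clamp_warned <- FALSE
  p_for <- function(sp, tissue) {
    p <- baselines[[tissue]]
    tr <- ref$dmr_truth[ref$dmr_truth$species == sp &
                          (ref$dmr_truth$tissue_scope == "multi" |
                             ref$dmr_truth$tissue_scope == tissue), ]
    for (i in seq_len(nrow(tr))) {
      sel <- ctg_offset[[tr$contig[i]]] +
        .pos_slice(ref$cpg_pos[[tr$contig[i]]], tr$start[i], tr$end[i])
      p[sel] <- p[sel] + tr$direction[i] * tr$delta[i]
    }
    if (any(p < 0 | p > 1)) {
      if (!clamp_warned) {
        warning("planted delta pushed methylation outside [0, 1]; clamped")
        clamp_warned <<- TRUE
      }
      p <- pmin(1, pmax(0, p))
    }
    p
  }

  spike <- NULL
  if (!is.null(ref$spike_contig))
    spike <- .spike_rows(as.character(ref$genome[[ref$spike_contig]]),
                         ref$spike_contig, d)

  samples <- list()
  for (sp in ref$species) {
    for (tt in ref$tissues) {
      p <- p_for(sp, tt)
      for (r in seq_len(d$n_replicates)) {
        N <- stats::rpois(ncpg, d$mean_coverage)
        if (d$dispersion > 0) {
          phi <- d$dispersion
          a <- p * (1 - phi) / phi
          b <- (1 - p) * (1 - phi) / phi
          pd <- numeric(ncpg)
          deg <- p <= 0 | p >= 1
          pd[deg] <- p[deg]
          pd[!deg] <- stats::rbeta(sum(!deg), a[!deg], b[!deg])
        } else pd <- p
        M <- stats::rbinom(ncpg, N, pd)
        Np <- stats::rbinom(ncpg, N, 0.5)
        Mp <- .split_counts(M, N, Np)
        dt <- data.table::data.table(
          contig = c(all_ctg, all_ctg),
          pos = c(all_pos, all_pos + 1L),
          strand = rep(c("+", "-"), each = ncpg),
          meth = c(Mp, M - Mp),
          unmeth = c(Np - Mp, (N - Np) - (M - Mp)),
          context = "CG",
          tri = c(tri_plus, tri_minus))
        data.table::setkey(dt, contig, pos)
        if (!is.null(spike)) {
          sdt <- data.table::copy(spike)
          scov <- stats::rpois(nrow(sdt), d$mean_coverage)
          smeth <- stats::rbinom(nrow(sdt), scov, d$nonconversion)
          data.table::set(sdt, j = "meth", value = smeth)
          data.table::set(sdt, j = "unmeth", value = scov - smeth)
          dt <- rbind(dt, sdt[, names(dt), with = FALSE])
        }
        sid <- sprintf("%s_%s_rep%d", sp, tt, r)
        path <- NULL
        if (!is.null(out_dir)) {
          path <- file.path(out_dir, paste0(sid, ".CpG_report.txt"))
          data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
        }
        samples[[sid]] <- list(sample_id = sid, species = sp, tissue = tt,
                               replicate = r, path = path, raw = dt)
      }
    }
  }
  structure(list(samples = samples, design = d,
                 spike_contig = ref$spike_contig), class = "methylome_set")
}

# hypergeometric split of M methylated among Np plus-strand reads
.split_counts <- function(M, N, Np) {
  out <- integer(length(M))
  pos <- N > 0
  out[pos] <- stats::rhyper(sum(pos), m = M[pos], n = N[pos] - M[pos],
                            k = Np[pos])
  out
}

# cytosine-report skeleton rows for the unmethylated spike contig
.spike_rows <- function(seq, contig, design) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(b)
  ctx_of <- function(b1, b2) {
    ifelse(b1 == "G", "CG", ifelse(b2 == "G", "CHG", "CHH"))
  }
  cpos <- which(b == "C")
  cpos <- cpos[cpos <= L - 2]
  gpos <- which(b == "G")
  gpos <- gpos[gpos >= 3]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rows <- data.table::data.table(
    contig = contig,
    pos = c(cpos, gpos),
    strand = rep(c("+", "-"), c(length(cpos), length(gpos))),
    meth = 0L, unmeth = 0L,
    context = c(ctx_of(b[cpos + 1L], b[cpos + 2L]),
                ctx_of(comp[b[gpos - 1L]], comp[b[gpos - 2L]])),
    tri = c(paste0("C", b[cpos + 1L], b[cpos + 2L]),
            paste0("C", comp[b[gpos - 1L]], comp[b[gpos - 2L]])))
  data.table::setkey(rows, contig, pos)
  rows
}

#' Destrand and coverage-filter simulated methylomes
#'
#' Applies the same destranding and coverage rules as [load_methylome()]
#' to the in-memory tables of a [simulate_methylomes()] result.
#'
#' @param sim a `methylome_set`.
#' @param min_coverage,max_coverage coverage bounds (keep coverage
#'   strictly above `min_coverage` and at most `max_coverage`).
#' @return list of `methylome_sample` objects.
#' @export
as_methylome_samples <- function(sim, min_coverage = 4L,
                                 max_coverage = 100L) {
  stopifnot(inherits(sim, "methylome_set"))
  lapply(sim$samples, function(s) {
    dt <- s$raw[s$raw$context == "CG"]
    if (!is.null(sim$spike_contig)) dt <- dt[dt$contig != sim$spike_contig]
    dt <- .destrand_filter(dt[, c("contig", "pos", "strand", "meth",
                                  "unmeth")],
                           min_coverage, max_coverage, destrand = TRUE)
    methylome_sample(dt, s$sample_id, s$species, s$tissue, s$replicate)
  })
}

#' Simulate expression coupled to promoter methylation
#'
#' Log-normal TPM per gene and sample; a stated fraction of genes is OFF
#' (TPM = 0 in all replicates). Gene expression follows the latent
#' activity that also sets the methylation baselines (low promoter
#' methylation and high gene-body methylation go with high expression).
#' Genes whose promoter hosts a planted species-DMR receive, in the
#' target species, a log2 expression shift opposite in sign to the
#' methylation shift, scaled by `expr_coupling`; an additional fraction
#' of genes gets species-level expression differences unrelated to
#' methylation. The differential-expression table carries q-values drawn
#' from the generative truth.
#'
#' @param design the [simulation_design()] used to build `ref`.
#' @param ref a [generate_reference_set()] result.
#' @param out_dir optional directory for `expression_tpm.tsv` and
#'   `de_table.tsv`.
#' @return An `expression_set`: `tpm` (genes x samples matrix),
#'   `metadata` (sample annotation), `de_table` (gene_id, q_value) and
#'   `coupling_truth` (gene_id, species, meth_direction).
#' @export
simulate_expression <- function(design, ref, out_dir = NULL) {
  stopifnot(inherits(ref, "reference_set"))
  d <- design
  set.seed(d$seed + 2L)
  genes <- ref$genes
  ga <- ref$gene_attrs
  if (!NROW(genes)) stop("reference set has no genes (no promoters)")
  ng <- nrow(genes)

  meanlog <- 7 * ga$activity - 1  # TPM from ~0.4 to ~400
  coupling <- ref$dmr_truth[ref$dmr_truth$kind == "promoter" &
                              !is.na(ref$dmr_truth$gene_id), ]

  # background species-level DE unrelated to methylation
  n_bg_de <- round(d$frac_species_de * ng)
  bg_pool <- setdiff(which(!ga$off), match(coupling$gene_id, ga$gene_id))
  bg_de <- sample(bg_pool, min(n_bg_de, length(bg_pool)))
  bg_de_sp <- sample(ref$species, length(bg_de), replace = TRUE)
  bg_de_shift <- sample(c(-1, 1), length(bg_de), replace = TRUE) *
    stats::runif(length(bg_de), 1.2, 2)

  sample_meta <- expand.grid(replicate = seq_len(d$n_replicates),
                             tissue = ref$tissues, species = ref$species,
                             stringsAsFactors = FALSE)
  sample_meta <- sample_meta[, c("species", "tissue", "replicate")]
  sample_meta$sample_id <- sprintf("%s_%s_rep%d", sample_meta$species,
                                   sample_meta$tissue,
                                   sample_meta$replicate)

  tpm <- matrix(0, nrow = ng, ncol = nrow(sample_meta),
                dimnames = list(genes$gene_id, sample_meta$sample_id))
  for (j in seq_len(nrow(sample_meta))) {
    sp <- sample_meta$species[j]
    mu <- meanlog
    ci <- which(coupling$species == sp)
    if (length(ci)) {
      gi <- match(coupling$gene_id[ci], genes$gene_id)
      # expression shift opposite in sign to the methylation shift
      mu[gi] <- mu[gi] - log(2) * d$expr_coupling *
        coupling$direction[ci] * coupling$delta[ci]
    }
    bi <- which(bg_de_sp == sp)
    if (length(bi))
      mu[bg_de[bi]] <- mu[bg_de[bi]] + log(2) * bg_de_shift[bi]
    x <- exp(stats::rnorm(ng, mu, 0.15))
    x[ga$off] <- 0
    tpm[, j] <- x
  }

  is_de_truth <- seq_len(ng) %in% c(match(coupling$gene_id, genes$gene_id),
                                    bg_de)
  q <- stats::runif(ng)
  q[is_de_truth] <- 10^stats::runif(sum(is_de_truth), -12, -3)
  de_table <- data.frame(gene_id = genes$gene_id, q_value = q)

  out <- structure(list(
    tpm = tpm, metadata = sample_meta, de_table = de_table,
    coupling_truth = data.frame(gene_id = coupling$gene_id,
                                species = coupling$species,
                                meth_direction = coupling$direction)),
    class = "expression_set")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(data.table::data.table(gene_id = rownames(tpm),
                                              as.data.frame(tpm)),
                       file.path(out_dir, "expression_tpm.tsv"), sep = "\t")
    data.table::fwrite(de_table, file.path(out_dir, "de_table.tsv"),
                       sep = "\t")
  }
  out
}
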