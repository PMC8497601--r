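#' Methylation-expression integration
#'
#' Connects DMRs to genes and transcription: gene assignment with a
#' promoter > gene-body > vicinity precedence, filtering of
#' differentially expressed genes (DEGs), the hypergeometric overlap test
#' defining putative functional DMRs (pfDMRs), expression/methylation
#' binning with Spearman correlation, and methylome clustering.
#'
#' @name integration
NULL

#' Assign DMRs to genes
#'
#' A DMR is assigned to a gene when it overlaps the gene's promoter
#' (TSS +/- 500 bp), its gene body (gene extent minus the first 500 bp
#' downstream of the TSS), or lies in the vicinity of the gene (more
#' than 0.5 kb and at most 4 kb from the gene extent). Assignment
#' precedence is promoter > gene_body > vicinity, so each DMR gets at
#' most one (gene, location class); the nearest gene wins ties in the
#' vicinity class. DMRs farther than 4 kb from every gene stay
#' unassigned.
#'
#' @param dmrs DMR data.frame (from [call_dmrs()]) or `GRanges`.
#' @param feature_map a [build_feature_map()] result built from the same
#'   gene table.
#' @param vicinity_range distance window, default `c(500, 4000)` bp
#'   (exclusive lower, inclusive upper).
#' @return data.frame with one row per assigned DMR: `dmr_index`,
#'   `contig`, `start`, `end`, `gene_id`, `location_class` (promoter /
#'   gene_body / vicinity_0.5_4kb).
#' @export
assign_dmr_to_gene <- function(dmrs, feature_map,
                               vicinity_range = c(500, 4000)) {
  stopifnot(inherits(feature_map, "feature_map"))
  gr <- .as_granges(dmrs)
  n <- length(gr)
  gene_id <- rep(NA_character_, n)
  klass <- rep(NA_character_, n)

  take <- function(target, label) {
    fo <- GenomicRanges::findOverlaps(gr, target)
    q <- S4Vectors::queryHits(fo)
    free <- is.na(klass)[q]
    q <- q[free]
    h <- S4Vectors::subjectHits(fo)[free]
    first <- !duplicated(q)
    gene_id[q[first]] <<- S4Vectors::mcols(target)$gene_id[h[first]]
    klass[q[first]] <<- label
  }
  take(feature_map$promoter, "promoter")
  take(feature_map$gene_body, "gene_body")

  # vicinity: gap to the nearest gene extent in (lo, hi]
  free <- which(is.na(klass))
  if (length(free) && length(feature_map$genes)) {
    nearest <- GenomicRanges::distanceToNearest(gr[free], feature_map$genes)
    q <- S4Vectors::queryHits(nearest)
    d <- S4Vectors::mcols(nearest)$distance
    ok <- d > vicinity_range[1] & d <= vicinity_range[2]
    gi <- S4Vectors::mcols(feature_map$genes)$gene_id[
      S4Vectors::subjectHits(nearest)[ok]]
    gene_id[free[q[ok]]] <- gi
    klass[free[q[ok]]] <- "vicinity_0.5_4kb"
  }

  assigned <- which(!is.na(klass))
  data.frame(dmr_index = assigned,
             contig = as.character(GenomicRanges::seqnames(gr))[assigned],
             start = GenomicRanges::start(gr)[assigned],
             end = GenomicRanges::end(gr)[assigned],
             gene_id = gene_id[assigned],
             location_class = klass[assigned])
}

#' Filter differentially expressed genes
#'
#' Retains genes with q-value below `q_max` AND a maximum absolute
#' pairwise difference of species-mean TPM of at least `min_diff`.
#' Species means average the replicates of one tissue (or of all tissues
#' when `tissue` is `NULL`).
#'
#' @param de_table data.frame with `gene_id` and `q_value`.
#' @param expression an `expression_set` (from [simulate_expression()]) or
#'   a list with `tpm` (genes x samples matrix) and `metadata`
#'   (sample_id, species, tissue).
#' @param q_max q-value cutoff (default 0.01).
#' @param min_diff minimum max-pairwise species-mean TPM difference
#'   (default 50).
#' @param tissue restrict to one tissue's samples (default all).
#' @return data.frame of retained genes: `gene_id`, `q_value`,
#'   `max_pairwise_tpm_diff`.
#' @export
filter_degs <- function(de_table, expression, q_max = 0.01, min_diff = 50,
                        tissue = NULL) {
  tpm <- expression$tpm
  meta <- expression$metadata
  missing_genes <- setdiff(de_table$gene_id, rownames(tpm))
  if (length(missing_genes))
    stop("gene(s) in DE table missing from the expression matrix: ",
         paste(utils::head(missing_genes, 3), collapse = ", "))
  if (!is.null(tissue)) {
    keep <- meta$tissue == tissue
    tpm <- tpm[, meta$sample_id[keep], drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  sp <- unique(meta$species)
  means <- vapply(sp, function(s)
    rowMeans(tpm[, meta$sample_id[meta$species == s], drop = FALSE]),
    numeric(nrow(tpm)))
  maxdiff <- apply(means, 1, function(x) max(x) - min(x))
  md <- maxdiff[de_table$gene_id]
  keep <- de_table$q_value < q_max & md >= min_diff
  out <- data.frame(gene_id = de_table$gene_id[keep],
                    q_value = de_table$q_value[keep],
                    max_pairwise_tpm_diff = unname(md[keep]))
  rownames(out) <- NULL
  out
}

#' Putative functional DMRs and their gene-level overlap test
#'
#' pfDMRs are gene-assigned DMRs whose gene is a filtered DEG. The
#' association is tested with the exact hypergeometric upper tail on
#' genes: universe N, K = DEG genes, n = genes with at least one
#' assigned DMR, k = genes in both sets.
#'
#' @param assigned [assign_dmr_to_gene()] result.
#' @param degs [filter_degs()] result.
#' @param universe character vector of all genes considered (e.g. the
#'   expression matrix rows).
#' @param feature_map optional; if given, each pfDMR is flagged for TE
#'   and CGI content.
#' @return list with `pfdmrs` (assigned rows restricted to DEG genes,
#'   plus flags), `test` (a `test_result` with N/K/n/k) and
#'   `composition` (fractions of pfDMRs per location class).
#' @export
pfdmr_overlap_test <- function(assigned, degs, universe,
                               feature_map = NULL) {
  if (!length(universe)) stop("empty gene universe")
  deg_genes <- intersect(unique(degs$gene_id), universe)
  dmr_genes <- intersect(unique(assigned$gene_id), universe)
  k <- length(intersect(deg_genes, dmr_genes))
  tr <- new_test_result(
    k, hypergeom_tail(length(universe), length(deg_genes),
                      length(dmr_genes), k),
    "hypergeometric gene-overlap test",
    N = length(universe), K = length(deg_genes), n = length(dmr_genes),
    k = k)
  pf <- assigned[assigned$gene_id %in% deg_genes, , drop = FALSE]
  if (!is.null(feature_map) && NROW(pf)) {
    gr <- GenomicRanges::GRanges(pf$contig,
                                 IRanges::IRanges(pf$start, pf$end))
    pf$in_te <- IRanges::overlapsAny(gr, feature_map$te)
    pf$in_cgi <- IRanges::overlapsAny(gr, c(feature_map$cgi_promoter,
                                            feature_map$cgi_orphan))
  }
  comp <- if (NROW(pf))
    as.data.frame(prop.table(table(location_class = pf$location_class)))
  else data.frame(location_class = character(0), Freq = numeric(0))
  list(pfdmrs = pf, test = tr, composition = comp)
}

# per-gene mean methylation over a set of gene-linked intervals,
# computed from averaged 50-bp window tracks of several samples
.gene_region_meth <- function(samples, regions, window = 50L) {
  tracks <- lapply(samples, window_methylation, window = window)
  pooled <- data.table::rbindlist(tracks)
  avg <- pooled[, list(mean_meth = mean(mean_meth)),
                by = c("contig", "start", "end")]
  win_gr <- GenomicRanges::GRanges(avg$contig,
                                   IRanges::IRanges(avg$start + 1L,
                                                    avg$end))
  fo <- GenomicRanges::findOverlaps(regions, win_gr)
  q <- S4Vectors::queryHits(fo)
  vals <- avg$mean_meth[S4Vectors::subjectHits(fo)]
  out <- rep(NA_real_, length(regions))
  agg <- tapply(vals, q, mean)
  out[as.integer(names(agg))] <- agg
  out
}

#' Bin genes by expression and methylation, and correlate the two
#'
#' For one species and tissue: genes are binned into 11 expression
#' categories — OFF (TPM = 0 in all replicates) plus 10 equal-count bins
#' of the expressed genes — and 11 methylation categories — exactly 0%
#' plus ten 10%-increments. Gene-wise Spearman correlations between mean
#' methylation and mean TPM are computed separately for promoters and
#' gene bodies.
#'
#' @param expression an `expression_set` (or list with `tpm` and
#'   `metadata`).
#' @param samples list of `methylome_sample` objects for the chosen
#'   species and tissue (replicates).
#' @param feature_map a [build_feature_map()] result.
#' @param species,tissue which expression columns to use.
#' @param min_genes minimum genes with both measures (default 30).
#' @return list with `gene_table` (gene_id, mean_tpm, promoter_meth,
#'   body_meth, expr_bin, prom_meth_bin), `expr_bin_profile`,
#'   `meth_bin_profile`, `rho_promoter` and `rho_genebody` (both
#'   `test_result`s).
#' @export
bin_and_correlate <- function(expression, samples, feature_map, species,
                              tissue, min_genes = 30L) {
  meta <- expression$metadata
  cols <- meta$sample_id[meta$species == species & meta$tissue == tissue]
  if (!length(cols)) stop("no expression samples for ", species, "/", tissue)
  tpm <- expression$tpm[, cols, drop = FALSE]
  mean_tpm <- rowMeans(tpm)
  off <- apply(tpm, 1, function(x) all(x == 0))

  prom <- feature_map$promoter
  body <- feature_map$gene_body
  gid_prom <- S4Vectors::mcols(prom)$gene_id
  gid_body <- S4Vectors::mcols(body)$gene_id
  genes <- rownames(expression$tpm)
  pm <- .gene_region_meth(samples, prom)
  bm <- .gene_region_meth(samples, body)
  promoter_meth <- stats::setNames(pm[match(genes, gid_prom)], genes)
  body_meth <- stats::setNames(bm[match(genes, gid_body)], genes)

  both <- !is.na(promoter_meth) & !is.na(body_meth)
  if (sum(both) < min_genes)
    stop(sprintf("only %d gene(s) with both methylation and expression",
                 sum(both)))

  # expression bins: OFF + 10 equal-count bins of expressed genes
  expr_bin <- rep(NA_character_, length(genes))
  expr_bin[off] <- "OFF"
  on_idx <- which(!off)
  ord <- on_idx[order(mean_tpm[on_idx], genes[on_idx])]
  bins <- ceiling(seq_along(ord) / (length(ord) / 10))
  bins[bins > 10] <- 10
  expr_bin[ord] <- as.character(bins)

  # methylation bins: exactly 0, then (0,10], ..., (90,100]
  meth_bin <- function(m) {
    pct <- m * 100
    b <- rep(NA_character_, length(pct))
    b[!is.na(pct) & pct == 0] <- "0"
    nz <- !is.na(pct) & pct > 0
    b[nz] <- as.character(pmin(10, ceiling(pct[nz] / 10)) * 10)
    b
  }
  prom_meth_bin <- meth_bin(promoter_meth)

  gene_table <- data.frame(gene_id = genes, mean_tpm = mean_tpm,
                           promoter_meth = promoter_meth,
                           body_meth = body_meth, expr_bin = expr_bin,
                           prom_meth_bin = prom_meth_bin)
  rownames(gene_table) <- NULL

  ok_bin <- !is.na(gene_table$expr_bin) & !is.na(gene_table$promoter_meth)
  expr_bin_profile <- stats::aggregate(
    cbind(promoter_meth, body_meth, mean_tpm) ~ expr_bin,
    data = gene_table[ok_bin, ], FUN = mean)
  ok_mb <- !is.na(gene_table$prom_meth_bin)
  meth_bin_profile <- stats::aggregate(
    mean_tpm ~ prom_meth_bin, data = gene_table[ok_mb, ], FUN = mean)

  use <- which(both)
  list(gene_table = gene_table,
       expr_bin_profile = expr_bin_profile,
       meth_bin_profile = meth_bin_profile,
       rho_promoter = spearman_rho(promoter_meth[use], mean_tpm[use]),
       rho_genebody = spearman_rho(body_meth[use], mean_tpm[use]))
}

#' Cluster methylomes from the conserved-CpG matrix
#'
#' Computes the pairwise Spearman correlation matrix over samples, then
#' hierarchically clusters the samples with complete linkage on
#' Euclidean distances between correlation-matrix rows. Sample order is
#' fixed by sample id first, so ties break deterministically.
#'
#' @param mat a [conserved_cpg_matrix()] result (sites x samples).
#' @param k optional number of clusters to cut.
#' @return list with `correlation` (samples x samples Spearman matrix),
#'   `hclust`, `newick` (dendrogram as a newick string) and, if `k`
#'   given, `clusters`.
#' @export
cluster_methylomes <- function(mat, k = NULL) {
  if (ncol(mat) < 3) stop("need at least 3 samples to cluster")
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  cm <- stats::cor(mat, method = "spearman")
  hc <- stats::hclust(stats::dist(cm, method = "euclidean"),
                      method = "complete")
  nw <- ape::write.tree(ape::as.phylo(hc))
  out <- list(correlation = cm, hclust = hc, newick = nw)
  if (!is.null(k)) out$clusters <- stats::cutree(hc, k = k)
  out
}
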