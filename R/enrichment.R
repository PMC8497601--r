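#' Permutation-based genomic enrichment of DMRs
#'
#' Observed/expected (O/E) enrichment of DMRs in genomic feature
#' categories, computed by randomly shuffling the DMRs across the genome
#' (preserving their number and lengths), per-TE-family enrichment, and
#' the transposon-age (divergence) comparison between TEs inside DMRs,
#' outside DMRs, and under shuffled DMRs.
#'
#' @name enrichment
NULL

#' Randomly relocate intervals across the genome
#'
#' Preserves the multiset of interval lengths; each interval is placed
#' uniformly at random (the contig is chosen with probability
#' proportional to its length, among contigs long enough to hold the
#' interval). Shuffled intervals may overlap each other.
#'
#' @param intervals `GRanges` or data.frame with contig/start/end
#'   (1-based).
#' @param contig_sizes named vector of contig lengths.
#' @param seed optional integer seed for reproducible placement.
#' @return `GRanges` of the same length as the input.
#' @export
shuffle_intervals <- function(intervals, contig_sizes, seed = NULL) {
  gr <- .as_granges(intervals)
  contig_sizes <- .as_seqlengths(contig_sizes)
  if (!is.null(seed)) set.seed(seed)
  w <- GenomicRanges::width(gr)
  if (any(w > max(contig_sizes)))
    stop("interval longer than every contig")
  n <- length(gr)
  ctg <- character(n)
  # contigs long enough for each width; all-same-size fast path
  if (length(unique(contig_sizes)) == 1 || max(w) <= min(contig_sizes)) {
    ctg <- sample(names(contig_sizes), n, replace = TRUE,
                  prob = contig_sizes / sum(contig_sizes))
  } else {
    for (i in seq_len(n)) {
      ok <- contig_sizes >= w[i]
      ctg[i] <- sample(names(contig_sizes)[ok], 1,
                       prob = contig_sizes[ok] / sum(contig_sizes[ok]))
    }
  }
  maxstart <- contig_sizes[ctg] - w + 1
  start <- floor(stats::runif(n, 1, maxstart + 1))
  GenomicRanges::GRanges(ctg, IRanges::IRanges(as.integer(start), width = w))
}

.count_by_category <- function(gr, feature_map, cats) {
  vapply(cats, function(cc)
    sum(IRanges::overlapsAny(gr, feature_map[[cc]])), numeric(1))
}

.empirical_p <- function(observed, perm_counts) {
  n_iter <- nrow(perm_counts)
  p_up <- (1 + colSums(perm_counts >= rep(observed,
                                          each = n_iter))) / (n_iter + 1)
  p_dn <- (1 + colSums(perm_counts <= rep(observed,
                                          each = n_iter))) / (n_iter + 1)
  ifelse(observed >= colMeans(perm_counts), p_up, p_dn)
}

#' Observed/expected enrichment of DMRs in feature categories
#'
#' Counts, per category, the DMRs overlapping it (>= 1 bp; categories
#' are not mutually exclusive), then estimates the expected count as the
#' mean over `n_iter` random genome-wide shuffles of the DMRs. Reports
#' O/E ratios, add-one empirical p-values (upper tail for enrichment,
#' mirrored for depletion) and a chi-square goodness-of-fit of observed
#' versus expected counts across categories.
#'
#' @param dmrs DMR data.frame (from [call_dmrs()]) or `GRanges`.
#' @param feature_map a [build_feature_map()] result.
#' @param n_iter number of shuffles (default 1000).
#' @param seed optional seed.
#' @param categories feature categories to score.
#' @return list with `table` (category, observed, expected_mean,
#'   expected_sd, oe_ratio, empirical_p) and `chi2` (a `test_result`).
#' @export
oe_enrichment <- function(dmrs, feature_map, n_iter = 1000L, seed = NULL,
                          categories = c("promoter", "gene_body",
                                         "intergenic", "cgi_promoter",
                                         "cgi_orphan", "te")) {
  stopifnot(inherits(feature_map, "feature_map"))
  if (n_iter < 100) stop("n_iter must be at least 100")
  gr <- .as_granges(dmrs)
  if (!length(gr)) stop("empty DMR set")
  categories <- categories[vapply(categories, function(cc)
    length(feature_map[[cc]]) > 0, logical(1))]
  if (!length(categories)) stop("no non-empty feature categories")
  if (!is.null(seed)) set.seed(seed)
  observed <- .count_by_category(gr, feature_map, categories)
  perm <- matrix(0, nrow = n_iter, ncol = length(categories),
                 dimnames = list(NULL, categories))
  for (it in seq_len(n_iter)) {
    sh <- shuffle_intervals(gr, feature_map$contig_sizes)
    perm[it, ] <- .count_by_category(sh, feature_map, categories)
  }
  exp_mean <- colMeans(perm)
  tab <- data.frame(category = categories, observed = observed,
                    expected_mean = exp_mean,
                    expected_sd = apply(perm, 2, stats::sd),
                    oe_ratio = ifelse(exp_mean > 0, observed / exp_mean,
                                      NA_real_),
                    empirical_p = .empirical_p(observed, perm))
  rownames(tab) <- NULL
  ok <- exp_mean > 0
  chi2 <- chi2_goodness_of_fit(observed[ok], exp_mean[ok])
  list(table = tab, chi2 = chi2)
}

#' Per-TE-family observed/expected DMR enrichment
#'
#' Same shuffle machinery as [oe_enrichment()], with one category per TE
#' family (a DMR overlapping >= 1 TE of a family counts once for that
#' family). The filtered table keeps families with O/E >=
#' `min_abs_ratio` or <= 1/`min_abs_ratio` (the display rule); the full
#' table is also returned.
#'
#' @param dmrs DMR data.frame or `GRanges`.
#' @param tes TE data.frame (from [parse_repeatmasker_out()]) with a
#'   `family` column, or `GRanges` with a `family` metadata column.
#' @param contig_sizes named contig lengths.
#' @param n_iter shuffles (default 1000).
#' @param seed optional seed.
#' @param min_abs_ratio display-filter threshold (default 2).
#' @return list with `table` (all families) and `filtered`.
#' @export
te_family_enrichment <- function(dmrs, tes, contig_sizes, n_iter = 1000L,
                                 seed = NULL, min_abs_ratio = 2) {
  gr <- .as_granges(dmrs)
  te_gr <- .as_granges(tes)
  fam <- S4Vectors::mcols(te_gr)$family
  if (is.null(fam)) stop("TEs must carry a family column")
  contig_sizes <- .as_seqlengths(contig_sizes)
  if (!is.null(seed)) set.seed(seed)
  fams <- sort(unique(fam))
  count_fams <- function(g) {
    fo <- GenomicRanges::findOverlaps(g, te_gr)
    hits <- unique(data.frame(q = S4Vectors::queryHits(fo),
                              f = fam[S4Vectors::subjectHits(fo)]))
    tab <- table(factor(hits$f, levels = fams))
    as.numeric(tab)
  }
  observed <- count_fams(gr)
  perm <- matrix(0, nrow = n_iter, ncol = length(fams),
                 dimnames = list(NULL, fams))
  for (it in seq_len(n_iter))
    perm[it, ] <- count_fams(shuffle_intervals(gr, contig_sizes))
  exp_mean <- colMeans(perm)
  tab <- data.frame(family = fams, observed = observed,
                    expected_mean = exp_mean,
                    expected_sd = apply(perm, 2, stats::sd),
                    oe_ratio = ifelse(exp_mean > 0, observed / exp_mean,
                                      NA_real_),
                    empirical_p = .empirical_p(observed, perm))
  rownames(tab) <- NULL
  if (all(observed == 0))
    warning("no DMR overlaps any TE")
  keep <- !is.na(tab$oe_ratio) &
    (tab$oe_ratio >= min_abs_ratio | tab$oe_ratio <= 1 / min_abs_ratio)
  list(table = tab, filtered = tab[keep, , drop = FALSE])
}

#' Transposon-age profile of DMR-overlapping TEs
#'
#' Compares the sequence divergence (Kimura-style percent, a TE age
#' proxy) of three TE groups: TEs overlapping the DMRs (`te_dmr`), TEs
#' overlapping no DMR (`outside`), and TEs overlapping randomly shuffled
#' DMRs pooled over `n_shuffles` iterations (`shuffle`), with a
#' Kruskal-Wallis/Dunn comparison.
#'
#' @param dmrs DMR data.frame or `GRanges`.
#' @param tes TE data.frame or `GRanges` with a `divergence` column.
#' @param contig_sizes named contig lengths.
#' @param n_shuffles shuffle iterations (default 500).
#' @param seed optional seed.
#' @return list with `groups` (named list of divergence samples),
#'   `summary` (medians/means/n) and `test` (a [kruskal_dunn()] result).
#' @export
te_divergence_profile <- function(dmrs, tes, contig_sizes,
                                  n_shuffles = 500L, seed = NULL) {
  gr <- .as_granges(dmrs)
  te_gr <- .as_granges(tes)
  divg <- S4Vectors::mcols(te_gr)$divergence
  if (is.null(divg)) stop("TEs must carry a divergence column")
  contig_sizes <- .as_seqlengths(contig_sizes)
  if (!is.null(seed)) set.seed(seed)
  in_dmr <- IRanges::overlapsAny(te_gr, gr)
  g1 <- divg[in_dmr]
  g2 <- divg[!in_dmr]
  if (!length(g1)) stop("empty group: no TE overlaps a DMR")
  if (!length(g2)) stop("empty group: every TE overlaps a DMR")
  g3 <- vector("list", n_shuffles)
  for (it in seq_len(n_shuffles)) {
    sh <- shuffle_intervals(gr, contig_sizes)
    g3[[it]] <- divg[IRanges::overlapsAny(te_gr, sh)]
  }
  g3 <- unlist(g3)
  if (!length(g3)) stop("empty group: shuffled DMRs hit no TE")
  groups <- list(te_dmr = g1, outside = g2, shuffle = g3)
  summ <- data.frame(group = names(groups),
                     n = lengths(groups),
                     median = vapply(groups, stats::median, numeric(1)),
                     mean = vapply(groups, mean, numeric(1)))
  rownames(summ) <- NULL
  list(groups = groups, summary = summ, test = kruskal_dunn(groups))
}
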