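#' Differential methylation testing and DMR segmentation
#'
#' Two-group per-CpG differential methylation testing with a
#' replicate-aware beta-binomial model, segmentation of significant CpGs
#' into differentially methylated regions (DMRs) under the four headline
#' criteria (>= 25% methylation difference, >= 50 bp, >= 4 CpGs, site
#' p < 0.05), and classification of pairwise DMRs into species-specific
#' and multi-tissue sets.
#'
#' The per-CpG test is a Wald-type z on the difference of group mean
#' methylation with the variance evaluated under the null (pooled
#' proportion), beta-binomial count variance and a method-of-moments
#' dispersion estimate pooled over a 500-bp smoothing neighbourhood. With
#' a single replicate per group it falls back to Fisher's exact test on
#' the pooled 2x2 counts.
#'
#' @name dmrcall
NULL

#' DMR calling parameters
#'
#' @param min_diff minimum absolute mean methylation difference over the
#'   region (default 0.25, the ">= 25% difference" rule).
#' @param min_length minimum region length in bp (default 50).
#' @param min_cpgs minimum CpGs in the region (default 4).
#' @param site_p per-CpG significance level (default 0.05).
#' @param max_gap maximum gap (bp) between consecutive significant CpGs
#'   chained into one region (default 100).
#' @param min_sig_fraction minimum fraction of significant CpGs among all
#'   CpGs in the region (default 0.5).
#' @param smooth_bp width of the dispersion-smoothing neighbourhood
#'   (default 500 bp).
#' @return A validated `dmr_params` list.
#' @export
dmr_params <- function(min_diff = 0.25, min_length = 50L, min_cpgs = 4L,
                       site_p = 0.05, max_gap = 100L,
                       min_sig_fraction = 0.5, smooth_bp = 500L) {
  p <- as.list(environment())
  if (min_diff <= 0 || min_diff > 1) stop("min_diff must lie in (0, 1]")
  for (f in c("min_length", "min_cpgs", "site_p", "max_gap",
              "min_sig_fraction", "smooth_bp"))
    if (p[[f]] <= 0) stop(f, " must be positive")
  structure(p, class = "dmr_params")
}

# row variances without apply overhead
.row_var <- function(m) {
  k <- ncol(m)
  if (k < 2) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (k - 1)
}

# vectorised per-site engine; meth/cov are sites x replicates matrices
.percpg_engine <- function(methA, covA, methB, covB, contig = NULL,
                           pos = NULL, smooth_bp = 500L) {
  if (any(rowSums(covA) == 0) || any(rowSums(covB) == 0))
    stop("site with zero total coverage in one group")
  rA <- ncol(methA); rB <- ncol(methB)
  mA <- rowSums(methA); mB <- rowSums(methB)
  nA <- rowSums(covA); nB <- rowSums(covB)
  pA <- mA / nA; pB <- mB / nB
  diff <- pA - pB

  if (rA == 1 && rB == 1) {
    p <- vapply(seq_along(mA), function(i)
      stats::fisher.test(matrix(c(methA[i, 1], covA[i, 1] - methA[i, 1],
                                  methB[i, 1], covB[i, 1] - methB[i, 1]),
                                nrow = 2))$p.value, numeric(1))
    return(data.frame(diff = diff, p_value = pmin(1, p),
                      method = "fisher"))
  }

  p0 <- (mA + mB) / (nA + nB)
  v0 <- p0 * (1 - p0)

  phi_of <- function(meth, cov) {
    prop <- meth / cov
    s2 <- .row_var(prop)
    w <- rowMeans(1 / cov)
    phi <- (s2 / v0 - w) / (1 - w)
    phi[!is.finite(phi)] <- NA_real_
    phi
  }
  phis <- cbind(if (rA >= 2) phi_of(methA, covA) else NA_real_,
                if (rB >= 2) phi_of(methB, covB) else NA_real_)
  phi <- rowMeans(phis, na.rm = TRUE)
  phi[!is.finite(phi)] <- 0

  # pool the noisy per-site estimate over a local neighbourhood before
  # clamping, so that negative sampling noise can cancel out
  if (!is.null(pos) && smooth_bp > 0) {
    half <- smooth_bp / 2
    sm <- numeric(length(phi))
    for (ctg in unique(contig)) {
      i <- which(contig == ctg)
      p_i <- pos[i]
      cs <- cumsum(phi[i])
      lo <- findInterval(p_i - half - 0.5, p_i)      # sites strictly before
      hi <- findInterval(p_i + half + 0.5 - 1e-9, p_i)
      sm[i] <- (cs[hi] - c(0, cs)[lo + 1L]) / (hi - lo)
    }
    phi <- sm
  }
  phi <- pmin(0.95, pmax(0, phi))

  var_g <- function(cov, n_tot)
    v0 * rowSums(cov * (1 + (cov - 1) * phi)) / n_tot^2
  se <- sqrt(var_g(covA, nA) + var_g(covB, nB))
  z <- ifelse(se > 0, diff / se, 0)
  data.frame(diff = diff, p_value = 2 * stats::pnorm(-abs(z)),
             method = "bbwald")
}

#' Per-CpG two-group differential methylation test
#'
#' Tests one CpG site given per-replicate (methylated, coverage) counts
#' for each group. With at least two replicates per group a beta-binomial
#' Wald test with method-of-moments dispersion is used; with one
#' replicate per group, Fisher's exact test on the pooled 2x2 table.
#'
#' @param group_a,group_b two-column matrices (or vectors of length 2)
#'   with columns (methylated count, coverage), one row per replicate.
#' @return A `test_result` with `statistic` = signed difference of group
#'   mean methylation (A minus B) and a two-sided `p_value`.
#' @export
percpg_test <- function(group_a, group_b) {
  as2 <- function(x) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    if (ncol(x) != 2) stop("expected columns (methylated, coverage)")
    x
  }
  a <- as2(group_a); b <- as2(group_b)
  if (any(a[, 2] <= 0) || any(b[, 2] <= 0)) stop("coverage must be positive")
  if (any(a[, 1] > a[, 2]) || any(b[, 1] > b[, 2]))
    stop("methylated count exceeds coverage")
  res <- .percpg_engine(matrix(a[, 1], nrow = 1), matrix(a[, 2], nrow = 1),
                        matrix(b[, 1], nrow = 1), matrix(b[, 2], nrow = 1),
                        smooth_bp = 0)
  new_test_result(res$diff, res$p_value,
                  if (res$method == "fisher")
                    "Fisher exact (single replicate)" else
                      "beta-binomial Wald")
}

# align a list of methylome samples on the common covered sites
.common_site_counts <- function(samples) {
  keys <- lapply(samples, function(s)
    paste0(s$sites$contig, "\r", s$sites$pos))
  common <- Reduce(intersect, keys)
  if (!length(common)) return(NULL)
  parts <- data.table::tstrsplit(common, "\r", fixed = TRUE)
  ord <- order(parts[[1]], as.integer(parts[[2]]))
  common <- common[ord]
  meth <- matrix(vapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    s$sites$meth[match(common, keys[[i]])]
  }, numeric(length(common))), nrow = length(common))
  cov <- matrix(vapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    idx <- match(common, keys[[i]])
    s$sites$meth[idx] + s$sites$unmeth[idx]
  }, numeric(length(common))), nrow = length(common))
  list(contig = parts[[1]][ord], pos = as.integer(parts[[2]])[ord],
       meth = meth, cov = cov)
}

#' Call DMRs between two groups of methylome samples
#'
#' Restricts to CpGs covered in every sample of both groups, tests each
#' site, chains significant CpGs (site p < `site_p`) whose consecutive
#' gaps are at most `max_gap` bp, and reports a chained region iff its
#' length is >= `min_length`, it holds >= `min_cpgs` CpGs, the absolute
#' mean group difference over the region is >= `min_diff`, and at least
#' `min_sig_fraction` of its CpGs are individually significant. The
#' region p-value combines the (direction-signed) site p-values by
#' Stouffer's method.
#'
#' @param samples_a,samples_b lists of `methylome_sample` objects (the
#'   two groups, e.g. two species).
#' @param params a [dmr_params()].
#' @param group_a,group_b group labels (default from the samples'
#'   species).
#' @param tissue tissue label attached to the output.
#' @return data.frame of DMRs (`contig`, `start`, `end` — 1-based
#'   inclusive —, `n_cpgs`, `mean_diff` (A minus B), `region_p`,
#'   `direction` hyper/hypo in group A, `group_a`, `group_b`, `tissue`),
#'   sorted and non-overlapping.
#' @export
call_dmrs <- function(samples_a, samples_b, params = dmr_params(),
                      group_a = NULL, group_b = NULL,
                      tissue = NA_character_) {
  stopifnot(inherits(params, "dmr_params"))
  group_a <- group_a %||% samples_a[[1]]$species
  group_b <- group_b %||% samples_b[[1]]$species
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), n_cpgs = integer(0),
                      mean_diff = numeric(0), region_p = numeric(0),
                      sig_fraction = numeric(0), direction = character(0),
                      group_a = character(0), group_b = character(0),
                      tissue = character(0))
  cs <- .common_site_counts(c(samples_a, samples_b))
  if (is.null(cs)) {
    warning("no CpG site covered in every sample; returning no DMRs")
    return(empty)
  }
  iA <- seq_along(samples_a)
  iB <- length(samples_a) + seq_along(samples_b)
  res <- .percpg_engine(cs$meth[, iA, drop = FALSE],
                        cs$cov[, iA, drop = FALSE],
                        cs$meth[, iB, drop = FALSE],
                        cs$cov[, iB, drop = FALSE],
                        contig = cs$contig, pos = cs$pos,
                        smooth_bp = params$smooth_bp)

  sig <- res$p_value < params$site_p
  out <- list()
  for (ctg in unique(cs$contig)) {
    ic <- which(cs$contig == ctg)
    cand <- ic[sig[ic]]
    if (!length(cand)) next
    cp <- cs$pos[cand]
    chain_id <- cumsum(c(1L, as.integer(diff(cp) > params$max_gap)))
    for (ch in split(cand, chain_id)) {
      start <- cs$pos[ch[1]]
      end <- cs$pos[ch[length(ch)]] + 1L  # cover the G of the last CpG
      in_reg <- ic[cs$pos[ic] >= start & cs$pos[ic] <= end]
      n_cpgs <- length(in_reg)
      mean_diff <- mean(res$diff[in_reg])
      sig_frac <- length(ch) / n_cpgs
      len <- end - start + 1L
      if (len < params$min_length || n_cpgs < params$min_cpgs ||
          abs(mean_diff) < params$min_diff ||
          sig_frac < params$min_sig_fraction) next
      pv <- pmax(res$p_value[in_reg], 1e-300)
      zs <- sign(res$diff[in_reg]) * stats::qnorm(pv / 2,
                                                  lower.tail = FALSE)
      zc <- sum(zs) / sqrt(length(zs))
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, start = start, end = end, n_cpgs = n_cpgs,
        mean_diff = mean_diff, region_p = 2 * stats::pnorm(-abs(zc)),
        sig_fraction = sig_frac,
        direction = if (mean_diff > 0) "hyper" else "hypo")
    }
  }
  if (!length(out)) return(empty)
  dmrs <- do.call(rbind, out)
  dmrs$group_a <- group_a
  dmrs$group_b <- group_b
  dmrs$tissue <- tissue
  dmrs <- dmrs[order(dmrs$contig, dmrs$start), ]
  rownames(dmrs) <- NULL
  # every reported region satisfies all four thresholds
  stopifnot(all(dmrs$end - dmrs$start + 1L >= params$min_length),
            all(dmrs$n_cpgs >= params$min_cpgs),
            all(abs(dmrs$mean_diff) >= params$min_diff),
            all(dmrs$sig_fraction >= params$min_sig_fraction))
  dmrs
}

.dmr_granges <- function(dmrs) {
  if (!NROW(dmrs)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(dmrs$contig, IRanges::IRanges(dmrs$start, dmrs$end))
}

# signed difference relative to a focal species
.focal_sign <- function(dmrs, focal) {
  ifelse(dmrs$group_a == focal, sign(dmrs$mean_diff),
         -sign(dmrs$mean_diff))
}

#' Classify pairwise DMRs into species-specific methylome patterns
#'
#' Given DMR sets for the three pairwise comparisons of a species triple
#' (one tissue), a region is specific to species S iff DMRs overlapping
#' it (>= 1 bp) exist in BOTH comparisons involving S, with a consistent
#' direction relative to S, and no DMR between the other two species
#' overlaps it. Output regions are coordinate unions of the supporting
#' DMRs.
#'
#' @param pairwise_dmrs list of three [call_dmrs()] data.frames covering
#'   all pairs of `species`.
#' @param species character vector of the three species labels.
#' @return data.frame with `contig`, `start`, `end`, `focal_species`,
#'   `direction` (hyper/hypo in the focal species) and `tissue`.
#' @export
classify_species_dmrs <- function(pairwise_dmrs, species) {
  stopifnot(length(species) == 3)
  if (length(pairwise_dmrs) < 3)
    stop("need DMR lists for all 3 pairwise comparisons")
  pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  keys <- vapply(pairwise_dmrs, function(d)
    if (NROW(d)) pair_key(d$group_a[1], d$group_b[1]) else NA_character_,
    character(1))
  want <- utils::combn(species, 2, function(x) pair_key(x[1], x[2]))
  # empty frames cannot carry their labels; match the rest, then assign
  lookup <- function(key) {
    i <- which(keys == key)
    if (length(i)) pairwise_dmrs[[i[1]]] else {
      j <- which(is.na(keys))
      if (!length(j)) stop("missing pairwise comparison ", key)
      pairwise_dmrs[[j[1]]]
    }
  }
  tissue <- NA_character_
  for (d in pairwise_dmrs) if (NROW(d)) tissue <- d$tissue[1]

  out <- list()
  for (s in species) {
    others <- setdiff(species, s)
    d1 <- lookup(pair_key(s, others[1]))
    d2 <- lookup(pair_key(s, others[2]))
    d3 <- lookup(pair_key(others[1], others[2]))
    if (!NROW(d1) || !NROW(d2)) next
    g1 <- .dmr_granges(d1); g2 <- .dmr_granges(d2)
    s1 <- .focal_sign(d1, s); s2 <- .focal_sign(d2, s)
    fo <- GenomicRanges::findOverlaps(g1, g2)
    if (!length(fo)) next
    q <- S4Vectors::queryHits(fo); h <- S4Vectors::subjectHits(fo)
    same <- s1[q] == s2[h]
    if (!any(same)) next
    q <- q[same]; h <- h[same]
    uni <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(g1)[q],
      IRanges::IRanges(pmin(GenomicRanges::start(g1)[q],
                            GenomicRanges::start(g2)[h]),
                       pmax(GenomicRanges::end(g1)[q],
                            GenomicRanges::end(g2)[h])),
      sgn = s1[q])
    # merge overlapping support of the same direction
    res <- list()
    for (sg in unique(S4Vectors::mcols(uni)$sgn)) {
      red <- GenomicRanges::reduce(uni[S4Vectors::mcols(uni)$sgn == sg])
      if (length(red))
        res[[as.character(sg)]] <- GenomicRanges::GRanges(
          GenomicRanges::seqnames(red), IRanges::ranges(red), sgn = sg)
    }
    uni <- unname(do.call(c, unname(res)))
    # the other two species must not differ here
    if (NROW(d3))
      uni <- uni[!IRanges::overlapsAny(uni, .dmr_granges(d3))]
    if (!length(uni)) next
    out[[s]] <- data.frame(
      contig = as.character(GenomicRanges::seqnames(uni)),
      start = GenomicRanges::start(uni), end = GenomicRanges::end(uni),
      focal_species = s,
      direction = ifelse(S4Vectors::mcols(uni)$sgn > 0, "hyper", "hypo"),
      tissue = tissue)
  }
  if (!length(out))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), focal_species = character(0),
                      direction = character(0), tissue = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$start), ]
  rownames(res) <- NULL
  res
}

#' Assign tissue scope to species-specific methylome patterns
#'
#' A species-S region found in the first tissue that overlaps (>= 1 bp) a
#' species-S region of the same direction in the second tissue becomes
#' one multi-tissue record (coordinate union); unmatched records stay
#' tissue-specific.
#'
#' @param tissue1,tissue2 [classify_species_dmrs()] results for the same
#'   species triple in two tissues (e.g. liver and muscle).
#' @return list with `regions` (classified records with a `tissue_scope`
#'   column: `<tissue1>_specific`, `<tissue2>_specific` or `multi_tissue`)
#'   and `proportions` (per-species proportion table; rows sum to 1).
#' @export
classify_tissue_scope <- function(tissue1, tissue2) {
  sp1 <- sort(unique(tissue1$focal_species))
  sp2 <- sort(unique(tissue2$focal_species))
  if (NROW(tissue1) && NROW(tissue2) && !length(intersect(sp1, sp2)))
    stop("species labels do not match between the two tissue sets")
  t1name <- if (NROW(tissue1)) tissue1$tissue[1] else "tissue1"
  t2name <- if (NROW(tissue2)) tissue2$tissue[1] else "tissue2"
  if (is.na(t1name)) t1name <- "tissue1"
  if (is.na(t2name)) t2name <- "tissue2"

  rows <- list()
  for (s in union(sp1, sp2)) {
    for (dir in c("hyper", "hypo")) {
      a <- tissue1[tissue1$focal_species == s & tissue1$direction == dir, ]
      b <- tissue2[tissue2$focal_species == s & tissue2$direction == dir, ]
      ga <- .classified_granges(a); gb <- .classified_granges(b)
      fo <- GenomicRanges::findOverlaps(ga, gb)
      q <- S4Vectors::queryHits(fo); h <- S4Vectors::subjectHits(fo)
      if (length(fo)) {
        multi <- GenomicRanges::reduce(c(ga[unique(q)], gb[unique(h)]))
        rows[[length(rows) + 1L]] <- data.frame(
          contig = as.character(GenomicRanges::seqnames(multi)),
          start = GenomicRanges::start(multi),
          end = GenomicRanges::end(multi),
          focal_species = s, direction = dir,
          tissue_scope = "multi_tissue")
      }
      only_a <- setdiff(seq_along(ga), q)
      if (length(only_a))
        rows[[length(rows) + 1L]] <- data.frame(
          contig = a$contig[only_a], start = a$start[only_a],
          end = a$end[only_a], focal_species = s, direction = dir,
          tissue_scope = paste0(t1name, "_specific"))
      only_b <- setdiff(seq_along(gb), h)
      if (length(only_b))
        rows[[length(rows) + 1L]] <- data.frame(
          contig = b$contig[only_b], start = b$start[only_b],
          end = b$end[only_b], focal_species = s, direction = dir,
          tissue_scope = paste0(t2name, "_specific"))
    }
  }
  regions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), start = integer(0),
               end = integer(0), focal_species = character(0),
               direction = character(0), tissue_scope = character(0))
  if (NROW(regions)) {
    regions <- regions[order(regions$contig, regions$start), ]
    rownames(regions) <- NULL
  }
  tab <- table(regions$focal_species, regions$tissue_scope)
  props <- if (NROW(regions)) prop.table(tab, 1) else tab
  list(regions = regions, proportions = props)
}

.classified_granges <- function(df) {
  if (!NROW(df)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(df$contig, IRanges::IRanges(df$start, df$end))
}

#' Benchmark called DMRs against planted truth
#'
#' Reciprocal-coverage matching: a truth region counts as recovered when
#' the union of called regions overlapping it covers at least
#' `min_overlap` of its length, and a called region counts as correct
#' when at least `min_overlap` of its length lies inside truth regions.
#' The union-based reading makes the benchmark robust to a single
#' planted region being reported as two adjacent calls (or one call
#' spanning two planted regions), while still demanding 50% reciprocal
#' coverage.
#'
#' @param called DMR data.frame or `GRanges`.
#' @param truth truth data.frame (`contig`, `start`, `end`, 1-based
#'   inclusive) or `GRanges`.
#' @param min_overlap required covered fraction on each side (default
#'   0.5).
#' @return list with `sensitivity`, `precision`, `n_called`, `n_truth`.
#' @export
dmr_recovery <- function(called, truth, min_overlap = 0.5) {
  gt <- .as_granges(truth)
  gd <- .as_granges(called)
  if (!length(gt)) stop("empty truth set")
  cov_frac <- function(a, b) {
    # fraction of each interval in `a` covered by the union of `b`
    if (!length(b)) return(rep(0, length(a)))
    red <- GenomicRanges::reduce(b)
    ov <- GenomicRanges::intersect(
      GenomicRanges::GRanges(GenomicRanges::seqnames(a),
                             IRanges::ranges(a)), red,
      ignore.strand = TRUE)
    fo <- GenomicRanges::findOverlaps(a, ov)
    covered <- numeric(length(a))
    if (length(fo)) {
      w <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(a)[S4Vectors::queryHits(fo)],
        IRanges::ranges(ov)[S4Vectors::subjectHits(fo)]))
      agg <- tapply(w, S4Vectors::queryHits(fo), sum)
      covered[as.integer(names(agg))] <- agg
    }
    covered / GenomicRanges::width(a)
  }
  sens <- mean(cov_frac(gt, gd) >= min_overlap)
  prec <- if (length(gd)) mean(cov_frac(gd, gt) >= min_overlap) else
    NA_real_
  list(sensitivity = sens, precision = prec, n_called = length(gd),
       n_truth = length(gt))
}

#' Export DMRs as BED6+
#'
#' BED with name = comparison, score = floor(1000 * |mean_diff|), strand
#' '.', and extra columns n_cpgs, mean_diff, region_p, tissue.
#'
#' @param dmrs a [call_dmrs()] data.frame.
#' @param path output file.
#' @export
write_dmr_bed <- function(dmrs, path) {
  dt <- data.table::data.table(
    chrom = dmrs$contig, start = dmrs$start - 1L, end = dmrs$end,
    name = paste0(dmrs$group_a, "_vs_", dmrs$group_b),
    score = pmin(1000L, as.integer(floor(1000 * abs(dmrs$mean_diff)))),
    strand = ".", n_cpgs = dmrs$n_cpgs, mean_diff = dmrs$mean_diff,
    region_p = dmrs$region_p, tissue = dmrs$tissue)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
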