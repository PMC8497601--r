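#' Genomic annotation universe
#'
#' Construction of the feature sets the comparative methylome analysis is
#' annotated against: CpG islands (sliding-window prediction), promoters
#' (TSS +/- 500 bp), gene bodies (gene extent minus the first 500 bp
#' downstream of the TSS), intergenic space (more than 500 bp away from any
#' gene), and transposable elements with their sequence divergence.
#'
#' All intervals are held as `GRanges` (1-based, closed); BED and bedGraph
#' exports use their native 0-based conventions.
#'
#' @name genomic_features
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.as_seqlengths <- function(contig_sizes) {
  if (is.null(names(contig_sizes)) || any(names(contig_sizes) == ""))
    stop("contig_sizes must be a named vector of contig lengths")
  contig_sizes
}

#' Predict CpG islands with the classical sliding-window rule
#'
#' Scans each contig with 200-bp windows at 1-bp step; windows with GC
#' fraction >= `min_gc`, observed/expected CpG >= `min_obs_exp`
#' (CpG count * N / (nC * nG)) qualify, overlapping qualifying windows are
#' merged, and each merged interval is re-evaluated against all three
#' thresholds (length >= 200 bp).
#'
#' @param genome a `DNAStringSet` or path to a FASTA file.
#' @param window window size in bp (default 200).
#' @param min_gc minimum GC fraction (default 0.5).
#' @param min_obs_exp minimum observed/expected CpG ratio (default 0.6).
#' @return `GRanges` with metadata columns `gc_fraction` and `obs_exp_cpg`.
#' @export
predict_cgi <- function(genome, window = 200L, min_gc = 0.5,
                        min_obs_exp = 0.6) {
  genome <- .load_genome(genome)
  out <- list()
  for (ctg in names(genome)) {
    s <- as.character(genome[[ctg]])
    L <- nchar(s)
    if (L < window) {
      warning(sprintf("contig %s shorter than %d bp, skipped", ctg, window))
      next
    }
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    isC <- b == "C"; isG <- b == "G"
    isCpG <- c(isC[-L] & isG[-1], FALSE)
    csC <- cumsum(isC); csG <- cumsum(isG); csCpG <- cumsum(isCpG)
    # window starting at i covers [i, i + window - 1]
    starts <- seq_len(L - window + 1L)
    ends <- starts + window - 1L
    wC <- csC[ends] - c(0, csC)[starts]
    wG <- csG[ends] - c(0, csG)[starts]
    # CpG starts fully inside the window
    wCpG <- csCpG[ends - 1L] - c(0, csCpG)[starts]
    gc <- (wC + wG) / window
    oe <- ifelse(wC * wG > 0, wCpG * window / (wC * wG), 0)
    ok <- gc >= min_gc & oe >= min_obs_exp
    if (!any(ok)) next
    merged <- IRanges::reduce(IRanges::IRanges(starts[ok], ends[ok]))
    st <- IRanges::start(merged); en <- IRanges::end(merged)
    mC <- csC[en] - c(0, csC)[st]
    mG <- csG[en] - c(0, csG)[st]
    mCpG <- csCpG[en - 1L] - c(0, csCpG)[st]
    mlen <- en - st + 1L
    mgc <- (mC + mG) / mlen
    moe <- ifelse(mC * mG > 0, mCpG * mlen / (mC * mG), 0)
    keep <- mlen >= window & mgc >= min_gc & moe >= min_obs_exp
    if (!any(keep)) next
    gr <- GenomicRanges::GRanges(ctg, IRanges::IRanges(st[keep], en[keep]),
                                 gc_fraction = mgc[keep],
                                 obs_exp_cpg = moe[keep])
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    out[[ctg]] <- gr
  }
  if (!length(out))
    return(GenomicRanges::GRanges(gc_fraction = numeric(0),
                                  obs_exp_cpg = numeric(0)))
  unname(do.call(c, unname(out)))
}

#' Build the feature map from gene models, CGIs and TEs
#'
#' Promoters are TSS +/- 500 bp; gene bodies are the gene extent minus the
#' first 500 bp downstream of the TSS (in transcription direction);
#' intergenic space is the complement of genes padded by 500 bp on each
#' side; CGIs overlapping any promoter by >= 1 bp are classed as promoter
#' CGIs, the rest as orphan CGIs. Intervals are clipped to contig bounds.
#'
#' @param genes data.frame with columns `gene_id`, `contig`, `strand`,
#'   `tss`, `tes` (1-based inclusive; on the minus strand tss > tes).
#' @param cgis `GRanges` of predicted CpG islands (may be empty).
#' @param tes data.frame of TE intervals as returned by
#'   [parse_repeatmasker_out()] (may be `NULL`).
#' @param contig_sizes named vector of contig lengths.
#' @param promoter_halfwidth,body_offset promoter half width and the TSS-
#'   downstream trim applied to gene bodies, both 500 bp by default.
#' @param intergenic_pad gene padding excluded from intergenic space
#'   (500 bp).
#' @return A `feature_map`: a list of `GRanges` named `promoter`,
#'   `gene_body`, `intergenic`, `cgi_promoter`, `cgi_orphan`, `te`, plus
#'   the `contig_sizes` used.
#' @export
build_feature_map <- function(genes, cgis = NULL, tes = NULL, contig_sizes,
                              promoter_halfwidth = 500L, body_offset = 500L,
                              intergenic_pad = 500L) {
  contig_sizes <- .as_seqlengths(contig_sizes)
  need <- c("gene_id", "contig", "strand", "tss", "tes")
  if (!all(need %in% names(genes)))
    stop("genes must have columns ", paste(need, collapse = ", "))

  clip <- function(gr) {
    if (!length(gr)) return(gr)
    L <- contig_sizes[as.character(GenomicRanges::seqnames(gr))]
    if (anyNA(L)) stop("gene on unknown contig")
    ns <- pmax(GenomicRanges::start(gr), 1L)
    ne <- pmin(GenomicRanges::end(gr), as.integer(L))
    keep <- ns <= ne
    if (any(GenomicRanges::start(gr) < 1 | GenomicRanges::end(gr) > L))
      warning("intervals extending past contig bounds were clipped")
    gr <- gr[keep]
    GenomicRanges::ranges(gr) <- IRanges::IRanges(ns[keep], ne[keep])
    gr
  }

  tss <- genes$tss; tes_pos <- genes$tes
  promoter <- GenomicRanges::GRanges(
    genes$contig,
    IRanges::IRanges(tss - promoter_halfwidth, tss + promoter_halfwidth - 1L),
    gene_id = genes$gene_id)
  promoter <- clip(promoter)

  # gene body: extent minus first `body_offset` bp downstream of TSS
  plus <- genes$strand == "+"
  bstart <- ifelse(plus, tss + body_offset, pmin(tss, tes_pos))
  bend <- ifelse(plus, pmax(tss, tes_pos), tss - body_offset)
  ok <- bstart <= bend
  gene_body <- GenomicRanges::GRanges(
    genes$contig[ok], IRanges::IRanges(bstart[ok], bend[ok]),
    gene_id = genes$gene_id[ok])
  gene_body <- clip(gene_body)

  extent <- GenomicRanges::GRanges(
    genes$contig,
    IRanges::IRanges(pmin(tss, tes_pos), pmax(tss, tes_pos)),
    gene_id = genes$gene_id)
  extent <- clip(extent)

  padded <- clip(GenomicRanges::GRanges(
    GenomicRanges::seqnames(extent),
    IRanges::IRanges(GenomicRanges::start(extent) - intergenic_pad,
                     GenomicRanges::end(extent) + intergenic_pad)))
  genome_gr <- GenomicRanges::GRanges(
    names(contig_sizes), IRanges::IRanges(1L, as.integer(contig_sizes)))
  intergenic <- GenomicRanges::setdiff(genome_gr,
                                       GenomicRanges::reduce(padded))

  if (is.null(cgis)) cgis <- GenomicRanges::GRanges()
  is_prom <- IRanges::overlapsAny(cgis, promoter)
  cgi_promoter <- cgis[is_prom]
  cgi_orphan <- cgis[!is_prom]

  te_gr <- if (is.null(tes) || !NROW(tes)) GenomicRanges::GRanges() else
    GenomicRanges::GRanges(tes$contig, IRanges::IRanges(tes$start, tes$end),
                           family = tes$family, te_class = tes$te_class,
                           divergence = tes$divergence)

  out <- list(promoter = promoter, gene_body = gene_body,
              intergenic = intergenic, cgi_promoter = cgi_promoter,
              cgi_orphan = cgi_orphan, te = te_gr,
              genes = extent, contig_sizes = contig_sizes)
  # one shared seqinfo so that feature sets can be combined silently
  for (nm in setdiff(names(out), "contig_sizes"))
    GenomeInfoDb::seqlevels(out[[nm]]) <- names(contig_sizes)
  structure(out, class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat("feature_map over", length(x$contig_sizes), "contig(s):\n")
  for (nm in c("promoter", "gene_body", "intergenic", "cgi_promoter",
               "cgi_orphan", "te"))
    cat(sprintf("  %-13s %6d interval(s)\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Parse a RepeatMasker .out file (or its 6-column TSV equivalent)
#'
#' Auto-detects the RepeatMasker `.out` layout (3 header lines,
#' whitespace-separated columns with percent divergence in column 2 and
#' query coordinates in columns 5-7) versus a plain 6-column TSV
#' (contig, start, end, family, class, divergence; 1-based inclusive).
#'
#' @param path input file.
#' @return data.frame with columns `contig`, `start`, `end` (1-based
#'   inclusive), `family`, `te_class`, `divergence`.
#' @export
parse_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  empty <- function() data.frame(contig = character(0), start = integer(0),
                                 end = integer(0), family = character(0),
                                 te_class = character(0),
                                 divergence = numeric(0))
  head_txt <- paste(utils::head(lines, 2), collapse = " ")
  is_out <- grepl("\\bscore\\b", head_txt, ignore.case = TRUE) ||
    grepl("\\bSW\\b", head_txt)
  if (is_out) {
    body <- lines[-seq_len(min(3L, length(lines)))]
    body <- body[nzchar(trimws(body))]
    if (!length(body)) return(empty())
    rows <- lapply(seq_along(body), function(i) {
      f <- strsplit(trimws(body[i]), "\\s+")[[1]]
      if (length(f) < 11 || is.na(suppressWarnings(as.numeric(f[2]))) ||
          is.na(suppressWarnings(as.integer(f[6]))))
        stop(sprintf("unparseable RepeatMasker row at line %d",
                     i + 3L))
      data.frame(contig = f[5], start = as.integer(f[6]),
                 end = as.integer(f[7]), family = f[10], te_class = f[11],
                 divergence = as.numeric(f[2]))
    })
    out <- do.call(rbind, rows)
  } else {
    body <- lines[nzchar(trimws(lines))]
    body <- body[!startsWith(body, "#")]
    if (!length(body)) return(empty())
    rows <- lapply(seq_along(body), function(i) {
      f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
      if (length(f) != 6 || is.na(suppressWarnings(as.integer(f[2]))))
        stop(sprintf("unparseable TE table row at line %d", i))
      data.frame(contig = f[1], start = as.integer(f[2]),
                 end = as.integer(f[3]), family = f[4], te_class = f[5],
                 divergence = as.numeric(f[6]))
    })
    out <- do.call(rbind, rows)
  }
  out[order(out$contig, out$start), , drop = FALSE]
}

#' Annotate intervals against the feature map
#'
#' Multi-label annotation: every query interval is labelled with every
#' feature category it overlaps by at least 1 bp (the categories are not
#' mutually exclusive). Queries overlapping no annotated feature fall into
#' whatever `intergenic` space they occupy.
#'
#' @param query `GRanges` (or a data.frame with contig/start/end, 1-based).
#' @param feature_map a [build_feature_map()] result.
#' @return list with `labels` (list of category character vectors, one per
#'   query), `counts` (named integer vector of queries per category) and
#'   `in_te` (logical, the TE-containing flag).
#' @export
annotate_intervals <- function(query, feature_map) {
  stopifnot(inherits(feature_map, "feature_map"))
  query <- .as_granges(query)
  if (length(query)) {
    unknown <- !as.character(GenomicRanges::seqnames(query)) %in%
      names(feature_map$contig_sizes)
    if (any(unknown))
      stop("query on unknown contig: ",
           paste(unique(as.character(
             GenomicRanges::seqnames(query))[unknown]), collapse = ", "))
  }
  cats <- c("promoter", "gene_body", "intergenic", "cgi_promoter",
            "cgi_orphan", "te")
  hit <- vapply(cats, function(cc)
    IRanges::overlapsAny(query, feature_map[[cc]]), logical(length(query)))
  if (length(query) == 1L) hit <- matrix(hit, nrow = 1,
                                         dimnames = list(NULL, cats))
  labels <- apply(hit, 1L, function(h) cats[h], simplify = FALSE)
  counts <- if (length(query)) colSums(hit) else
    stats::setNames(rep(0L, length(cats)), cats)
  list(labels = labels, counts = as.integer(counts) |>
         stats::setNames(cats), in_te = if (length(query)) hit[, "te"]
       else logical(0))
}

# coerce data.frame (contig,start,end, 1-based inclusive) or GRanges
.as_granges <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  if (is.data.frame(x)) {
    if (!NROW(x))
      return(GenomicRanges::GRanges())
    gr <- GenomicRanges::GRanges(x$contig,
                                 IRanges::IRanges(x$start, x$end))
    extra <- setdiff(names(x), c("contig", "start", "end"))
    if (length(extra))
      S4Vectors::mcols(gr) <- x[, extra, drop = FALSE]
    return(gr)
  }
  stop("cannot coerce to GRanges")
}

#' Write intervals as BED (0-based half-open)
#'
#' @param x `GRanges` or data.frame with contig/start/end (1-based).
#' @param path output file.
#' @param name,score optional vectors for BED columns 4-5.
#' @export
write_bed <- function(x, path, name = ".", score = 0L) {
  gr <- .as_granges(x)
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = name, score = score, strand = ".")
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
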