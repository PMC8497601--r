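#' Methylome loading, destranding, windows and the conserved-CpG matrix
#'
#' Per-CpG methylation counts come in as cytosine reports (one row per
#' cytosine: contig, 1-based position, strand, methylated count,
#' unmethylated count, context, trinucleotide). A CpG is symmetric: the C
#' on the plus strand and the paired G one base downstream on the minus
#' strand interrogate the same dinucleotide, so their counts are summed
#' ("destranded") onto the plus-strand C position. Coverage filtering is
#' applied after destranding, because the symmetric CpG is the biological
#' unit.
#'
#' @name methio
NULL

#' Construct a methylome sample
#'
#' @param sites data.frame/data.table with columns `contig`, `pos`
#'   (1-based position of the plus-strand C), `meth`, `unmeth`.
#' @param sample_id,species,tissue,replicate sample metadata.
#' @return A `methylome_sample`: metadata plus a coordinate-sorted,
#'   duplicate-free site table.
#' @export
methylome_sample <- function(sites, sample_id, species = NA_character_,
                             tissue = NA_character_, replicate = NA_integer_) {
  sites <- data.table::as.data.table(sites)[, c("contig", "pos", "meth",
                                                "unmeth")]
  if (any(sites$meth < 0 | sites$unmeth < 0)) stop("negative counts")
  data.table::setkey(sites, contig, pos)
  if (anyDuplicated(sites, by = c("contig", "pos")))
    stop("duplicate (contig, pos) sites")
  structure(list(sample_id = sample_id, species = species, tissue = tissue,
                 replicate = replicate, sites = sites),
            class = "methylome_sample")
}

#' @export
print.methylome_sample <- function(x, ...) {
  cat(sprintf("methylome_sample %s (%s, %s, rep %s): %d CpG site(s)\n",
              x$sample_id, x$species, x$tissue, x$replicate, nrow(x$sites)))
  invisible(x)
}

# destrand a raw CG-context table and apply the coverage filter
.destrand_filter <- function(dt, min_coverage, max_coverage, destrand) {
  dt <- data.table::as.data.table(dt)
  if (destrand && nrow(dt)) {
    minus <- dt$strand == "-"
    n_orphan <- sum(minus & !(paste(dt$contig, dt$pos - 1L) %in%
                                paste(dt$contig, dt$pos)[!minus]))
    if (n_orphan > 0)
      warning(sprintf(
        "%d minus-strand record(s) without a CpG partner kept at position-1",
        n_orphan))
    data.table::set(dt, i = which(minus), j = "pos",
                    value = dt$pos[minus] - 1L)
  }
  dt <- dt[, list(meth = sum(meth), unmeth = sum(unmeth)),
           by = c("contig", "pos")]
  cov <- dt$meth + dt$unmeth
  dt[cov > min_coverage & cov <= max_coverage]
}

#' Load a cytosine report into a methylome sample
#'
#' Reads a 7-column cytosine report, keeps CG-context rows, destrands
#' (plus-strand C counts and the adjacent minus-strand G counts are summed
#' onto the C position), then removes sites whose destranded coverage is
#' not in (`min_coverage`, `max_coverage`\].
#'
#' @param path cytosine report (TSV: contig, 1-based position, strand,
#'   count methylated, count unmethylated, context, trinucleotide).
#' @param min_coverage keep sites with coverage strictly greater than this
#'   (default 4, i.e. the ">4 reads" rule).
#' @param max_coverage keep sites with coverage at most this (default 100).
#' @param destrand sum symmetric CpG counts onto the C position (default
#'   `TRUE`).
#' @param sample_id,species,tissue,replicate sample metadata; `sample_id`
#'   defaults to the file name.
#' @return A `methylome_sample`.
#' @export
load_methylome <- function(path, min_coverage = 4L, max_coverage = 100L,
                           destrand = TRUE, sample_id = NULL,
                           species = NA_character_, tissue = NA_character_,
                           replicate = NA_integer_) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) != 7)
    stop(sprintf("expected 7 columns in cytosine report, got %d", ncol(dt)))
  data.table::setnames(dt, c("contig", "pos", "strand", "meth", "unmeth",
                             "context", "tri"))
  bad <- which(!dt$strand %in% c("+", "-") | is.na(dt$pos) |
                 is.na(dt$meth) | is.na(dt$unmeth))
  if (length(bad))
    stop(sprintf("malformed cytosine report row at line %d", bad[1]))
  dt <- dt[dt$context == "CG"]
  if (!nrow(dt)) warning("no CG-context rows in ", path)
  dt <- .destrand_filter(dt[, c("contig", "pos", "strand", "meth", "unmeth")],
                         min_coverage, max_coverage, destrand)
  methylome_sample(dt, sample_id %||% basename(path), species, tissue,
                   replicate)
}

#' Mean methylation in non-overlapping genomic windows
#'
#' Tiles every contig with non-overlapping windows and reports, per
#' window, the unweighted mean of the per-site methylation fractions of
#' the CpGs whose C falls in the window (a CpG at 0-based position p
#' belongs to window floor(p / window)). Windows without CpGs are absent
#' from the result (missing, not zero).
#'
#' @param sample a `methylome_sample`.
#' @param window window size in bp (default 50).
#' @return data.table with columns `contig`, `start` (0-based), `end`
#'   (half-open) and `mean_meth`.
#' @export
window_methylation <- function(sample, window = 50L) {
  stopifnot(inherits(sample, "methylome_sample"))
  if (window <= 0) stop("window size must be positive")
  s <- sample$sites
  if (!nrow(s))
    return(data.table::data.table(contig = character(0), start = integer(0),
                                  end = integer(0), mean_meth = numeric(0)))
  lev <- s$meth / (s$meth + s$unmeth)
  dt <- data.table::data.table(contig = s$contig,
                               start = ((s$pos - 1L) %/% window) * window,
                               level = lev)
  out <- dt[, list(mean_meth = mean(level)), by = c("contig", "start")]
  data.table::set(out, j = "end", value = out$start + window)
  data.table::setkey(out, contig, start)
  out[, c("contig", "start", "end", "mean_meth")]
}

#' Write a window track as bedGraph
#' @param track a [window_methylation()] result.
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  data.table::fwrite(track[, c("contig", "start", "end", "mean_meth")],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Estimate the bisulfite non-conversion rate from a spike-in contig
#'
#' The unmethylated spike-in (lambda phage DNA) carries no methylation, so
#' any methylated call on it reflects incomplete bisulfite conversion.
#' The rate is total methylated calls over total calls across ALL cytosine
#' contexts on the spike contig.
#'
#' @param path cytosine report.
#' @param spike_contig name of the spike-in contig.
#' @return list with `nonconversion_rate`, `conversion_efficiency` and
#'   `n_calls`.
#' @export
estimate_nonconversion <- function(path, spike_contig) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  data.table::setnames(dt, c("contig", "pos", "strand", "meth", "unmeth",
                             "context", "tri")[seq_len(ncol(dt))])
  dt <- dt[dt$contig == spike_contig]
  total <- sum(dt$meth) + sum(dt$unmeth)
  if (!nrow(dt) || total == 0)
    stop(sprintf("no calls on spike contig '%s'", spike_contig))
  rate <- sum(dt$meth) / total
  list(nonconversion_rate = rate, conversion_efficiency = 1 - rate,
       n_calls = total)
}

#' Methylation-fraction matrix at conserved CpG sites
#'
#' Restricts to CpG positions (a) present, after coverage filtering, in
#' every sample and (b) not overlapping — at either the C or the paired G
#' base — any bisulfite-confounded (C>T or G>A) SNP in any species, then
#' returns the per-sample methylation fractions.
#'
#' @param samples list of coverage-filtered `methylome_sample` objects
#'   (>= 2).
#' @param snps optional SNP table as from [read_snp_table()]; only C>T and
#'   G>A records trigger exclusion.
#' @return numeric matrix, rows = `contig:pos` site keys, columns =
#'   sample ids; attribute `metadata` holds the sample annotation.
#' @export
conserved_cpg_matrix <- function(samples, snps = NULL) {
  stopifnot(length(samples) >= 2)
  keys <- lapply(samples, function(s) paste0(s$sites$contig, ":",
                                             s$sites$pos))
  common <- Reduce(intersect, keys)
  if (!is.null(snps) && NROW(snps)) {
    conf <- snps[(snps$ref == "C" & snps$alt == "T") |
                   (snps$ref == "G" & snps$alt == "A"), , drop = FALSE]
    # a CpG at pos covers bases pos (C) and pos+1 (G)
    bad <- c(paste0(conf$contig, ":", conf$pos),
             paste0(conf$contig, ":", conf$pos - 1L))
    common <- setdiff(common, bad)
  }
  if (!length(common))
    stop(paste("no CpG site is covered in every sample;",
               "consider relaxing the coverage thresholds"))
  common <- common[order(common)]
  mat <- matrix(vapply(samples, function(s) {
    k <- paste0(s$sites$contig, ":", s$sites$pos)
    i <- match(common, k)
    s$sites$meth[i] / (s$sites$meth[i] + s$sites$unmeth[i])
  }, numeric(length(common))), nrow = length(common))
  rownames(mat) <- common
  colnames(mat) <- vapply(samples, function(s) s$sample_id, character(1))
  attr(mat, "metadata") <- data.frame(
    sample_id = colnames(mat),
    species = vapply(samples, function(s) s$species, character(1)),
    tissue = vapply(samples, function(s) s$tissue, character(1)),
    replicate = vapply(samples, function(s) as.integer(s$replicate),
                       integer(1)))
  mat
}
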