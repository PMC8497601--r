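#' SNP-corrected reference genomes for bisulfite mapping
#'
#' Bisulfite treatment converts unmethylated C to T, so a genuine C>T SNP
#' (or G>A on the reverse strand) in a given species is indistinguishable
#' from a bisulfite conversion event when reads are mapped against a
#' common reference. Substituting exactly these two substitution classes
#' into the reference, per species, removes that bias; every other SNP
#' class is left untouched.
#'
#' @name bsref
NULL

.load_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1)
    return(Biostrings::readDNAStringSet(genome))
  stop("genome must be a DNAStringSet or a FASTA path")
}

#' Read a per-species SNP table from a VCF
#'
#' Parses a VCF (v4.2) and returns the biallelic single-base records as a
#' data.frame, carrying the species label from the given INFO tag.
#' Multi-base (indel) and multiallelic records are dropped with a warning.
#'
#' @param path VCF file.
#' @param species_tag INFO key holding the species label (default
#'   `"SPECIES"`); records without the tag get species `NA`.
#' @return data.frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`, `species`.
#' @export
read_snp_table <- function(path, species_tag = "SPECIES") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (!NROW(fix))
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      species = character(0)))
  species <- sub(sprintf(".*%s=([^;]+).*", species_tag), "\\1", fix$INFO)
  species[!grepl(paste0(species_tag, "="), fix$INFO)] <- NA_character_
  out <- data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, species = species)
  bad <- nchar(out$ref) != 1 | nchar(out$alt) != 1 |
    grepl(",", out$alt, fixed = TRUE)
  if (any(bad)) {
    warning(sprintf("%d multiallelic/indel record(s) skipped", sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Build a species-specific SNP-corrected reference genome
#'
#' Substitutes, for one species, exactly the bisulfite-confounded SNP
#' classes (ref C > alt T, and ref G > alt A) into the reference. All
#' other positions — including SNPs of any other substitution class — are
#' left unchanged, so contig names and lengths are preserved and the
#' operation is idempotent.
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param snps data.frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt` and optionally `species`; or a VCF path (read with
#'   [read_snp_table()]).
#' @param species species label to select from `snps$species`; `NULL`
#'   uses all records.
#' @param out_fasta optional path; if given the corrected genome is
#'   written there (line width 60).
#' @return list with `genome` (corrected `DNAStringSet`) and `report`, a
#'   one-row data.frame counting `applied_c_to_t`, `applied_g_to_a`,
#'   `skipped_non_bisulfite` and `skipped_invalid` records.
#' @export
build_snp_corrected_reference <- function(genome, snps, species = NULL,
                                          out_fasta = NULL) {
  genome <- .load_genome(genome)
  if (is.character(snps) && length(snps) == 1) snps <- read_snp_table(snps)
  need <- c("contig", "pos", "ref", "alt")
  if (!all(need %in% names(snps)))
    stop("snps must have columns ", paste(need, collapse = ", "))
  if (!is.null(species)) {
    if (!"species" %in% names(snps))
      stop("snps table has no species column")
    snps <- snps[!is.na(snps$species) & snps$species == species, ,
                 drop = FALSE]
  }

  bases <- c("A", "C", "G", "T")
  invalid <- !(snps$ref %in% bases) | !(snps$alt %in% bases)
  if (any(invalid)) {
    warning(sprintf("%d record(s) with non-ACGT/multi-base alleles skipped",
                    sum(invalid)))
    snps <- snps[!invalid, , drop = FALSE]
  }

  # ref allele must match the template genome
  if (NROW(snps)) {
    unknown <- !snps$contig %in% names(genome)
    if (any(unknown))
      stop("SNP on unknown contig: ", snps$contig[which(unknown)[1]])
    for (ctg in unique(snps$contig)) {
      idx <- which(snps$contig == ctg)
      pos <- snps$pos[idx]
      if (any(pos < 1 | pos > Biostrings::width(genome[ctg])))
        stop(sprintf("SNP position outside contig %s", ctg))
      at <- strsplit(as.character(Biostrings::extractAt(
        genome[[ctg]], IRanges::IRanges(pos, pos))), "")
      have <- vapply(at, `[`, character(1), 1)
      # a base already equal to the alt allele means the substitution was
      # applied before; accept it so that re-application is a no-op
      mism <- have != snps$ref[idx] & have != snps$alt[idx]
      if (any(mism))
        stop(sprintf("ref allele mismatch at %s:%d (genome %s, record %s)",
                     ctg, pos[which(mism)[1]], have[which(mism)[1]],
                     snps$ref[idx][which(mism)[1]]))
    }
  }

  is_ct <- snps$ref == "C" & snps$alt == "T"
  is_ga <- snps$ref == "G" & snps$alt == "A"
  apply_idx <- which(is_ct | is_ga)

  corrected <- genome
  if (length(apply_idx)) {
    sub <- snps[apply_idx, , drop = FALSE]
    for (ctg in unique(sub$contig)) {
      idx <- sub$contig == ctg
      corrected[[ctg]] <- Biostrings::replaceLetterAt(
        corrected[[ctg]], sub$pos[idx], sub$alt[idx])
    }
  }

  report <- data.frame(
    species = if (is.null(species)) NA_character_ else species,
    n_input = NROW(snps) + sum(invalid),
    applied_c_to_t = sum(is_ct),
    applied_g_to_a = sum(is_ga),
    skipped_non_bisulfite = sum(!is_ct & !is_ga),
    skipped_invalid = sum(invalid))

  if (!is.null(out_fasta))
    Biostrings::writeXStringSet(corrected, out_fasta, width = 60L)
  list(genome = corrected, report = report)
}
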