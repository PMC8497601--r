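at_run <- function(n) paste(rep(c("A", "T"), length.out = n), collapse = "")
cg_run <- function(n) paste(rep(c("C", "G"), length.out = n), collapse = "")

test_that("CGI prediction honours the window thresholds", {
  # 250 bp of CG repeats inside an AT background
  g <- Biostrings::DNAStringSet(c(
    chr = paste0(at_run(300), cg_run(250), at_run(300))))
  cgi <- predict_cgi(g)
  expect_equal(length(cgi), 1)
  # the island is contained; window merging may extend < 1 window outwards
  expect_lte(GenomicRanges::start(cgi), 301)
  expect_gte(GenomicRanges::end(cgi), 550)
  expect_gte(GenomicRanges::start(cgi), 301 - 199)
  expect_lte(GenomicRanges::end(cgi), 550 + 199)
  expect_gte(S4Vectors::mcols(cgi)$gc_fraction, 0.5)
  expect_gte(S4Vectors::mcols(cgi)$obs_exp_cpg, 0.6)
  expect_gte(GenomicRanges::width(cgi), 200)
  # 150-bp island fails the length threshold
  g2 <- Biostrings::DNAStringSet(c(
    chr = paste0(at_run(300), cg_run(150), at_run(300))))
  expect_equal(length(predict_cgi(g2)), 0)
  # pure AT sequence yields nothing; short contigs are skipped with warning
  expect_equal(length(predict_cgi(Biostrings::DNAStringSet(
    c(chr = at_run(600))))), 0)
  expect_warning(predict_cgi(Biostrings::DNAStringSet(c(tiny = "ACGT"))),
                 "skipped")
})

test_that("every reported CGI satisfies all three thresholds", {
  d <- simulation_design(seed = 17, n_contigs = 1, contig_length = 60000,
                         n_genes = 8, n_cgis = 8, n_tes = 10, n_dmrs = 4,
                         n_tissue_dmrs = 0)
  ref <- generate_reference_set(d)
  cgi <- predict_cgi(ref$genome["ctg1"])
  expect_gt(length(cgi), 0)
  expect_true(all(S4Vectors::mcols(cgi)$gc_fraction >= 0.5))
  expect_true(all(S4Vectors::mcols(cgi)$obs_exp_cpg >= 0.6))
  expect_true(all(GenomicRanges::width(cgi) >= 200))
  # most planted islands are rediscovered (the composition signal is real)
  hit <- IRanges::overlapsAny(ref$cgi_truth, cgi)
  expect_gt(mean(hit), 0.7)
})

test_that("feature map encodes promoter/body/intergenic definitions", {
  genes <- data.frame(gene_id = "g1", contig = "chr", strand = "+",
                      tss = 1001, tes = 3000)
  fm <- build_feature_map(genes, NULL, NULL, c(chr = 10000L))
  # promoter [1001-500, 1001+499]; width exactly 1000
  expect_equal(GenomicRanges::start(fm$promoter), 501)
  expect_equal(GenomicRanges::end(fm$promoter), 1500)
  expect_equal(GenomicRanges::width(fm$promoter), 1000)
  # gene body starts 500 bp downstream of the TSS
  expect_equal(GenomicRanges::start(fm$gene_body), 1501)
  expect_equal(GenomicRanges::end(fm$gene_body), 3000)
  # 400 bp downstream of the gene end is NOT intergenic; 600 bp is
  pt <- function(p) GenomicRanges::GRanges("chr", IRanges::IRanges(p, p))
  expect_false(IRanges::overlapsAny(pt(3400), fm$intergenic))
  expect_true(IRanges::overlapsAny(pt(3600), fm$intergenic))

  # minus-strand gene: body ends 500 bp downstream of its TSS
  genes2 <- data.frame(gene_id = "g2", contig = "chr", strand = "-",
                       tss = 3000, tes = 1001)
  fm2 <- build_feature_map(genes2, NULL, NULL, c(chr = 10000L))
  expect_equal(GenomicRanges::start(fm2$promoter), 2500)
  expect_equal(GenomicRanges::end(fm2$promoter), 3499)
  expect_equal(GenomicRanges::start(fm2$gene_body), 1001)
  expect_equal(GenomicRanges::end(fm2$gene_body), 2500)

  # a CGI overlapping a promoter by a single bp is a promoter CGI
  cgis <- GenomicRanges::GRanges("chr", IRanges::IRanges(c(1400, 1501),
                                                         c(1500, 1800)))
  fm3 <- build_feature_map(genes, cgis, NULL, c(chr = 10000L))
  expect_equal(length(fm3$cgi_promoter), 1)
  expect_equal(GenomicRanges::start(fm3$cgi_promoter), 1400)
  expect_equal(length(fm3$cgi_orphan), 1)
  # genes running past the contig end are clipped (warnings emitted)
  fm4 <- suppressWarnings(build_feature_map(
    data.frame(gene_id = "g3", contig = "chr", strand = "+", tss = 9800,
               tes = 12000), NULL, NULL, c(chr = 10000L)))
  expect_lte(max(GenomicRanges::end(fm4$genes)), 10000)
  expect_lte(max(GenomicRanges::end(fm4$promoter)), 10000)
})

test_that("RepeatMasker .out and the TSV dialect parse identically", {
  out_lines <- c(
    "   SW   perc perc perc  query      position in query",
    "score   div. del. ins.  sequence   begin end (left)",
    "",
    "  463    5.2  0.0  0.0  chr1       1001  1500 (8500) + hAT6 DNA/hAT 1 500 (0) 1",
    " 1200   25.0  1.0  0.0  chr2        201   800 (9200) C Tc2-Mariner DNA/TcMar 1 600 (0) 2")
  f1 <- tempfile(fileext = ".out")
  writeLines(out_lines, f1)
  te1 <- parse_repeatmasker_out(f1)
  expect_equal(nrow(te1), 2)
  expect_equal(te1$start[1], 1001)
  expect_equal(te1$end[1], 1500)
  expect_equal(te1$divergence[1], 5.2)
  expect_equal(te1$family[1], "hAT6")

  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("chr1\t1001\t1500\thAT6\tDNA/hAT\t5.2",
               "chr2\t201\t800\tTc2-Mariner\tDNA/TcMar\t25.0"), f2)
  te2 <- parse_repeatmasker_out(f2)
  expect_equal(te1[, c("contig", "start", "end", "family", "divergence")],
               te2[, c("contig", "start", "end", "family", "divergence")])

  # empty after headers; unparseable row names its line
  f3 <- tempfile()
  writeLines(out_lines[1:3], f3)
  expect_equal(nrow(parse_repeatmasker_out(f3)), 0)
  f4 <- tempfile()
  writeLines("chr1\toops\t10\tf\tc\t1", f4)
  expect_error(parse_repeatmasker_out(f4), "line 1")
})

test_that("interval annotation is multi-label and matches brute force", {
  genes <- data.frame(gene_id = c("g1", "g2"), contig = "chr",
                      strand = c("+", "+"), tss = c(2001, 12001),
                      tes = c(6000, 16000))
  cgis <- GenomicRanges::GRanges("chr", IRanges::IRanges(c(1900, 8000),
                                                         c(2300, 8300)))
  tes <- data.frame(contig = "chr", start = c(1950, 9000),
                    end = c(2100, 9400), family = "hAT6",
                    te_class = "DNA", divergence = 5)
  fm <- build_feature_map(genes, cgis, tes, c(chr = 20000L))
  # a DMR inside a promoter that also holds a TE gets both labels
  ann <- annotate_intervals(
    data.frame(contig = "chr", start = 2000, end = 2050), fm)
  expect_true(all(c("promoter", "te") %in% ann$labels[[1]]))
  expect_true(ann$in_te[1])
  # unannotated space is intergenic only
  ann2 <- annotate_intervals(
    data.frame(contig = "chr", start = 10000, end = 10050), fm)
  expect_equal(ann2$labels[[1]], "intergenic")
  # empty query: all-zero counts
  ann0 <- annotate_intervals(GenomicRanges::GRanges(), fm)
  expect_true(all(ann0$counts == 0))
  expect_error(
    annotate_intervals(data.frame(contig = "nope", start = 1, end = 2), fm),
    "unknown contig")

  # brute-force all-pairs equivalence on random intervals
  set.seed(31)
  qs <- sort(sample.int(19900, 40))
  q <- data.frame(contig = "chr", start = qs, end = qs + 99)
  ann3 <- annotate_intervals(q, fm)
  cats <- c("promoter", "gene_body", "intergenic", "cgi_promoter",
            "cgi_orphan", "te")
  for (cc in cats) {
    f <- fm[[cc]]
    brute <- vapply(seq_len(nrow(q)), function(i)
      any(q$start[i] <= GenomicRanges::end(f) &
            q$end[i] >= GenomicRanges::start(f)), logical(1))
    expect_equal(vapply(ann3$labels, function(l) cc %in% l, logical(1)),
                 brute, info = cc)
  }
})
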