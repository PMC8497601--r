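small_design <- function(seed = 42, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_contigs = 2, contig_length = 60000, n_genes = 10,
         n_tes = 20, n_cgis = 6, n_dmrs = 6, n_tissue_dmrs = 6,
         n_snps = 40),
    list(...))
  do.call(simulation_design, args)
}

test_that("design validation rejects out-of-range parameters", {
  expect_error(simulation_design(dispersion = 1.2), "dispersion")
  expect_error(simulation_design(dmr_delta = 0), "dmr_delta")
  expect_error(simulation_design(background_meth = -0.1), "background_meth")
  expect_error(simulation_design(n_species = 0), "positive")
  # infeasible placement names the constraint
  expect_error(generate_reference_set(
    simulation_design(n_contigs = 1, contig_length = 20000, n_genes = 50)),
    "infeasible placement")
})

test_that("reference set respects the configured counts and layout", {
  d <- small_design()
  ref <- generate_reference_set(d)
  expect_equal(length(ref$contig_sizes), 2)
  expect_true(all(ref$contig_sizes == 60000))
  expect_equal(nrow(ref$genes), 10)
  expect_equal(nrow(ref$tes), 20)
  expect_equal(nrow(ref$dmr_truth), 6)
  expect_equal(nrow(ref$snps), 40 * d$n_species)
  # every TE inside its contig
  expect_true(all(ref$tes$start >= 1 &
                    ref$tes$end <= ref$contig_sizes[ref$tes$contig]))
  # planted DMRs never overlap each other and all hold >= 4 CpGs
  gr <- GenomicRanges::GRanges(ref$dmr_truth$contig,
                               IRanges::IRanges(ref$dmr_truth$start,
                                                ref$dmr_truth$end))
  expect_equal(sum(GenomicRanges::countOverlaps(gr, gr) > 1), 0)
  expect_true(all(ref$dmr_truth$n_cpgs >= 4))
  # realistic CpG density: at least 1 CpG per 100 bp on average
  expect_gt(sum(lengths(ref$cpg_pos)) / sum(ref$contig_sizes), 0.01)
  # SNP mix: both bisulfite-confounded and other classes present
  bis <- (ref$snps$ref == "C" & ref$snps$alt == "T") |
    (ref$snps$ref == "G" & ref$snps$alt == "A")
  expect_gt(sum(bis), 0)
  expect_gt(sum(!bis), 0)
  expect_equal(mean(bis), d$snp_bisulfite_frac, tolerance = 0.1)
})

test_that("identical designs give byte-identical output files", {
  d <- small_design(seed = 7)
  out1 <- file.path(tempdir(), "det1")
  out2 <- file.path(tempdir(), "det2")
  ref1 <- generate_reference_set(d, out_dir = out1)
  suppressWarnings(simulate_methylomes(d, ref1, out_dir = out1))
  simulate_expression(d, ref1, out_dir = out1)
  ref2 <- generate_reference_set(d, out_dir = out2)
  suppressWarnings(simulate_methylomes(d, ref2, out_dir = out2))
  simulate_expression(d, ref2, out_dir = out2)
  f1 <- list.files(out1, full.names = TRUE)
  f2 <- list.files(out2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("counts conserve coverage and sample layout matches the design", {
  d <- small_design(seed = 9)
  ref <- generate_reference_set(d)
  sim <- suppressWarnings(simulate_methylomes(d, ref))
  # n_species x n_tissues x n_replicates samples
  expect_equal(length(sim$samples), d$n_species * d$n_tissues *
                 d$n_replicates)
  raw <- sim$samples[[1]]$raw
  expect_true(all(raw$meth >= 0 & raw$unmeth >= 0))
  # both strands emitted for every CpG of the genome
  main <- raw[raw$contig != "lambda_spike"]
  expect_equal(nrow(main), 2 * sum(lengths(ref$cpg_pos)))
  expect_setequal(unique(main$strand), c("+", "-"))
  # destranding conserves the raw totals
  sm <- as_methylome_samples(sim, min_coverage = 0, max_coverage = 1e9)
  expect_equal(sum(sm[[1]]$sites$meth), sum(main$meth))
  expect_equal(sum(sm[[1]]$sites$meth) + sum(sm[[1]]$sites$unmeth),
               sum(main$meth) + sum(main$unmeth))
})

test_that("a planted gain DMR on a low background reaches the planted mean", {
  # background 0.3, delta 0.5: target species mean inside the region ~ 0.8
  d <- small_design(seed = 19, background_meth = 0.3, dmr_delta = 0.5,
                    frac_promoter_dmrs = 0, frac_te_dmrs = 0,
                    n_tissues = 1, frac_multi_tissue = 1,
                    mean_coverage = 30)
  ref <- generate_reference_set(d)
  sim <- suppressWarnings(simulate_methylomes(d, ref))
  sm <- as_methylome_samples(sim)
  tr <- ref$dmr_truth[1, ]
  expect_equal(tr$direction, 1)  # low background implies a gain
  target <- sample_group(sm, tr$species)
  lvl <- unlist(lapply(target, function(s) {
    sel <- s$sites$contig == tr$contig & s$sites$pos >= tr$start &
      s$sites$pos <= tr$end
    s$sites$meth[sel] / (s$sites$meth[sel] + s$sites$unmeth[sel])
  }))
  expect_gt(length(lvl), 20)
  se <- sd(lvl) / sqrt(length(lvl))
  expect_lt(abs(mean(lvl) - 0.8), 3 * se + 0.02)
  # non-target species stay at background inside the same region
  other <- sample_group(sm, setdiff(ref$species, tr$species)[1])
  lvl0 <- unlist(lapply(other, function(s) {
    sel <- s$sites$contig == tr$contig & s$sites$pos >= tr$start &
      s$sites$pos <= tr$end
    s$sites$meth[sel] / (s$sites$meth[sel] + s$sites$unmeth[sel])
  }))
  expect_lt(abs(mean(lvl0) - 0.3), 3 * sd(lvl0) / sqrt(length(lvl0)) + 0.02)
})

test_that("dispersion 0 gives binomial replicate variance, dispersion > 0 more", {
  moment_stat <- function(phi) {
    d <- simulation_design(seed = 33, n_contigs = 1, contig_length = 50000,
                           n_species = 1, n_tissues = 1, n_replicates = 6,
                           n_genes = 2, n_tes = 2, n_cgis = 2, n_dmrs = 0,
                           n_tissue_dmrs = 0, dispersion = phi,
                           mean_coverage = 20, spike_in = FALSE)
    ref <- generate_reference_set(d)
    sim <- suppressWarnings(simulate_methylomes(d, ref))
    sm <- as_methylome_samples(sim)
    cs <- methdiverge:::.common_site_counts(sm)
    prop <- cs$meth / cs$cov
    p_hat <- rowSums(cs$meth) / rowSums(cs$cov)
    s2 <- apply(prop, 1, var)
    w <- rowMeans(1 / cs$cov)
    # binomial expectation of the replicate variance is p(1-p) * mean(1/n)
    excess <- s2 - p_hat * (1 - p_hat) * w
    mean(excess, na.rm = TRUE)
  }
  e0 <- moment_stat(0)
  e2 <- moment_stat(0.2)
  expect_lt(abs(e0), 0.002)   # matches binomial within sampling error
  expect_gt(e2, 0.01)         # overdispersion inflates replicate variance
})

test_that("expression honours OFF fraction, coupling sign and DE truth", {
  d <- small_design(seed = 55, n_genes = 20, off_fraction = 0.2,
                    frac_promoter_dmrs = 0.5, n_dmrs = 6)
  ref <- generate_reference_set(d)
  expr <- simulate_expression(d, ref)
  # exactly off_fraction * n_genes genes are all-zero
  all_zero <- rownames(expr$tpm)[apply(expr$tpm, 1, function(x) all(x == 0))]
  expect_equal(length(all_zero), 4)
  expect_setequal(all_zero, ref$gene_attrs$gene_id[ref$gene_attrs$off])
  # coupled genes: expression shifted against the methylation direction
  ct <- expr$coupling_truth
  expect_gt(nrow(ct), 0)
  for (i in seq_len(nrow(ct))) {
    sp <- ct$species[i]
    meta <- expr$metadata
    own <- rowMeans(expr$tpm[ct$gene_id[i],
                             meta$sample_id[meta$species == sp],
                             drop = FALSE])
    rest <- rowMeans(expr$tpm[ct$gene_id[i],
                              meta$sample_id[meta$species != sp],
                              drop = FALSE])
    if (ct$meth_direction[i] > 0) expect_lt(own, rest)
    else expect_gt(own, rest)
  }
  # DE truth genes carry small q-values
  expect_true(all(expr$de_table$q_value[
    expr$de_table$gene_id %in% ct$gene_id] < 0.01))
  # no promoters -> error
  ref_nogenes <- ref
  ref_nogenes$genes <- ref$genes[0, ]
  expect_error(simulate_expression(d, ref_nogenes), "no genes")
})

test_that("zero coupling leaves planted-DMR genes expressionally unremarkable", {
  d <- small_design(seed = 77, n_genes = 60, contig_length = 200000,
                    expr_coupling = 0, frac_promoter_dmrs = 0.5,
                    n_dmrs = 10, frac_species_de = 0)
  ref <- generate_reference_set(d)
  expr <- simulate_expression(d, ref)
  ct <- expr$coupling_truth
  sp <- ct$species[1]
  meta <- expr$metadata
  cols <- meta$sample_id[meta$species == sp]
  m <- rowMeans(expr$tpm[, cols, drop = FALSE])
  on <- m > 0
  coupled <- rownames(expr$tpm) %in% ct$gene_id
  # compare log-TPM of coupled vs background expressed genes
  kw <- kruskal_dunn(list(coupled = log1p(m[coupled & on]),
                          background = log1p(m[!coupled & on])))
  expect_gt(kw$omnibus$p_value, 0.01)
})

test_that("the spike-in contig is unmethylated and drives the rate estimate", {
  d <- small_design(seed = 88)
  ref <- generate_reference_set(d)
  out <- file.path(tempdir(), "spike_sim")
  sim <- suppressWarnings(simulate_methylomes(d, ref, out_dir = out))
  r <- estimate_nonconversion(sim$samples[[1]]$path, "lambda_spike")
  expect_lt(r$nonconversion_rate, 0.02)
  expect_gt(r$conversion_efficiency, 0.98)
})
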