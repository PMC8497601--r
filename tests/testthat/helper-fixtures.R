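# shared fixtures, built once per test session

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# a three-species, two-tissue study with 200 planted species-DMRs
# (45% multi-tissue), reused by the classification and clustering checks
study_sim <- function() {
  fixture("study_sim", {
    d <- simulation_design(seed = 101L, n_contigs = 2L,
                           contig_length = 750000, n_dmrs = 200L,
                           n_tissue_dmrs = 200L)
    ref <- generate_reference_set(d)
    sim <- suppressWarnings(simulate_methylomes(d, ref))
    samples <- as_methylome_samples(sim)
    list(design = d, ref = ref, sim = sim, samples = samples)
  })
}

sample_group <- function(samples, species, tissue = NULL) {
  samples[vapply(samples, function(s)
    s$species == species && (is.null(tissue) || s$tissue == tissue),
    logical(1))]
}

# write a cytosine report from a data.frame of rows
write_report <- function(rows, path = tempfile(fileext = ".txt")) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}

report_row <- function(contig, pos, strand, meth, unmeth, context = "CG",
                       tri = "CGA") {
  data.frame(contig = contig, pos = pos, strand = strand, meth = meth,
             unmeth = unmeth, context = context, tri = tri)
}

# methylome sample with exact (deterministic) counts
exact_sample <- function(pos, meth, cov, contig = "ctg1", id = "s",
                         species = NA_character_, tissue = NA_character_,
                         replicate = 1L) {
  methylome_sample(data.frame(contig = contig, pos = pos, meth = meth,
                              unmeth = cov - meth),
                   id, species, tissue, replicate)
}

# adjusted Rand index between two label vectors
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# beta-binomial null counts for calibration checks
draw_bb_group <- function(n, coverage, p, phi) {
  N <- stats::rpois(n, coverage)
  pd <- if (phi > 0)
    stats::rbeta(n, p * (1 - phi) / phi, (1 - p) * (1 - phi) / phi)
  else rep(p, n)
  cbind(meth = stats::rbinom(n, N, pd), cov = N)
}
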