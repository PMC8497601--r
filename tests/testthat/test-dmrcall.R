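test_that("per-CpG test handles identity, Fisher fallback and errors", {
  same <- matrix(c(5, 10, 5, 10), 2, byrow = TRUE)
  r <- percpg_test(same, same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # single replicate per group: exact Fisher on the pooled 2x2 table
  rf <- percpg_test(c(10, 10), c(0, 10))
  expect_match(rf$method, "Fisher")
  expect_equal(rf$p_value, 2 / 184756, tolerance = 1e-12)
  expect_error(percpg_test(c(1, 0), c(1, 2)), "coverage")
  expect_error(percpg_test(c(3, 2), c(1, 2)), "exceeds coverage")
})

test_that("a clean planted region is called as exactly one DMR", {
  # 10 CpGs across 500 bp, strong consistent difference, 2 replicates
  pos <- seq(1001, 1451, by = 50)
  A <- list(exact_sample(pos, rep(80, 10), rep(100, 10), id = "a1"),
            exact_sample(pos, rep(82, 10), rep(100, 10), id = "a2"))
  B <- list(exact_sample(pos, rep(10, 10), rep(100, 10), id = "b1"),
            exact_sample(pos, rep(12, 10), rep(100, 10), id = "b2"))
  dm <- call_dmrs(A, B, group_a = "A", group_b = "B")
  expect_equal(nrow(dm), 1)
  expect_equal(dm$start, 1001)
  expect_equal(dm$end, 1452)
  expect_equal(dm$n_cpgs, 10)
  expect_equal(dm$direction, "hyper")
  expect_gt(dm$mean_diff, 0.6)
  expect_lt(dm$region_p, 1e-10)
})

test_that("each of the four region thresholds is enforced individually", {
  strong <- function(pos, n) list(
    exact_sample(pos, rep(80, n), rep(100, n), id = "a1"),
    exact_sample(pos, rep(82, n), rep(100, n), id = "a2"))
  weak <- function(pos, n, meth = 10) list(
    exact_sample(pos, rep(meth, n), rep(100, n), id = "b1"),
    exact_sample(pos, rep(meth + 2, n), rep(100, n), id = "b2"))

  # 3 CpGs, all significant, large difference: rejected (needs >= 4 CpGs)
  p3 <- c(1001, 1101, 1201)
  expect_equal(nrow(call_dmrs(strong(p3, 3), weak(p3, 3))), 0)

  # 5 CpGs within < 50 bp: rejected (needs >= 50 bp)
  p5 <- c(1001, 1009, 1017, 1025, 1033)
  expect_equal(nrow(call_dmrs(strong(p5, 5), weak(p5, 5))), 0)

  # large, significant region but difference 0.20: rejected (needs >= 25%)
  p10 <- seq(1001, 1451, by = 50)
  A20 <- list(exact_sample(p10, rep(120, 10), rep(200, 10), id = "a1"),
              exact_sample(p10, rep(120, 10), rep(200, 10), id = "a2"))
  B20 <- list(exact_sample(p10, rep(80, 10), rep(200, 10), id = "b1"),
              exact_sample(p10, rep(80, 10), rep(200, 10), id = "b2"))
  expect_equal(nrow(call_dmrs(A20, B20)), 0)

  # no site significant: no candidates at all
  A0 <- list(exact_sample(p10, rep(8, 10), rep(15, 10), id = "a1"),
             exact_sample(p10, rep(7, 10), rep(15, 10), id = "a2"))
  B0 <- list(exact_sample(p10, rep(7, 10), rep(15, 10), id = "b1"),
             exact_sample(p10, rep(8, 10), rep(15, 10), id = "b2"))
  expect_equal(nrow(call_dmrs(A0, B0)), 0)

  # the all-pass construction is accepted
  expect_equal(nrow(call_dmrs(strong(p10, 10), weak(p10, 10))), 1)
})

test_that("chaining splits candidate runs at gaps above max_gap", {
  pos <- c(seq(1001, 1201, by = 50), seq(1500, 1700, by = 50))
  n <- length(pos)
  A <- list(exact_sample(pos, rep(80, n), rep(100, n), id = "a1"),
            exact_sample(pos, rep(82, n), rep(100, n), id = "a2"))
  B <- list(exact_sample(pos, rep(10, n), rep(100, n), id = "b1"),
            exact_sample(pos, rep(12, n), rep(100, n), id = "b2"))
  dm <- call_dmrs(A, B)  # gap 1500 - 1201 = 299 > 100 splits the run
  expect_equal(nrow(dm), 2)
  # no two reported regions overlap
  expect_true(all(dm$start[-1] > dm$end[-nrow(dm)]))
  # with a permissive gap the run stays together
  dm2 <- call_dmrs(A, B, dmr_params(max_gap = 400))
  expect_equal(nrow(dm2), 1)
})

test_that("disjoint coverage yields an empty result with a warning", {
  A <- list(exact_sample(c(101, 201), c(9, 9), c(10, 10), id = "a1"))
  B <- list(exact_sample(c(501, 601), c(1, 1), c(10, 10), id = "b1"))
  expect_warning(dm <- call_dmrs(A, B), "no CpG site")
  expect_equal(nrow(dm), 0)
})

make_dmr_df <- function(start, end, diff, ga, gb, tissue = "liver",
                        contig = "c1") {
  data.frame(contig = contig, start = start, end = end,
             n_cpgs = 5L, mean_diff = diff, region_p = 1e-6,
             sig_fraction = 1, direction = ifelse(diff > 0, "hyper", "hypo"),
             group_a = ga, group_b = gb, tissue = tissue)
}

test_that("species classification requires both comparisons and no third", {
  # hyper-in-A present in A-vs-B and A-vs-C, absent in B-vs-C
  ab <- make_dmr_df(1000, 1500, 0.4, "A", "B")
  ac <- make_dmr_df(1100, 1600, 0.5, "A", "C")
  bc <- make_dmr_df(50000, 50500, 0.4, "B", "C")
  cl <- classify_species_dmrs(list(ab, ac, bc), c("A", "B", "C"))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$focal_species, "A")
  expect_equal(cl$direction, "hyper")
  # coordinate union of the supporting DMRs
  expect_equal(cl$start, 1000)
  expect_equal(cl$end, 1600)

  # present in only one comparison: unassigned
  empty_ac <- ac[0, ]
  cl2 <- classify_species_dmrs(list(ab, empty_ac, bc), c("A", "B", "C"))
  expect_equal(nrow(cl2), 0)

  # direction conflict between the two comparisons: unassigned
  ac_flip <- make_dmr_df(1100, 1600, -0.5, "A", "C")
  cl3 <- classify_species_dmrs(list(ab, ac_flip, bc), c("A", "B", "C"))
  expect_equal(nrow(cl3), 0)

  # an overlapping B-vs-C DMR vetoes the region
  bc_here <- make_dmr_df(1400, 1700, 0.4, "B", "C")
  cl4 <- classify_species_dmrs(list(ab, ac, bc_here), c("A", "B", "C"))
  expect_equal(nrow(cl4), 0)

  expect_error(classify_species_dmrs(list(ab, ac), c("A", "B", "C")),
               "3 pairwise")
})

test_that("classification is symmetric under relabelling non-focal species", {
  ab <- make_dmr_df(c(1000, 9000), c(1500, 9400), c(0.4, -0.3), "A", "B")
  ac <- make_dmr_df(c(1100, 9100), c(1600, 9500), c(0.5, -0.4), "A", "C")
  bc <- make_dmr_df(30000, 30500, 0.4, "B", "C")
  cl_abc <- classify_species_dmrs(list(ab, ac, bc), c("A", "B", "C"))
  # swap the roles of B and C (flip the sign of the B-vs-C comparison)
  bc_swapped <- make_dmr_df(30000, 30500, -0.4, "C", "B")
  cl_acb <- classify_species_dmrs(list(ac, ab, bc_swapped), c("A", "C", "B"))
  a1 <- cl_abc[cl_abc$focal_species == "A", c("contig", "start", "end",
                                              "direction")]
  a2 <- cl_acb[cl_acb$focal_species == "A", c("contig", "start", "end",
                                              "direction")]
  expect_equal(a1, a2)
})

test_that("tissue scope merges congruent regions and splits the rest", {
  liv <- data.frame(contig = "c1", start = c(1000, 5000), end = c(1500, 5400),
                    focal_species = "A", direction = c("hyper", "hypo"),
                    tissue = "liver")
  mus <- data.frame(contig = "c1", start = 1200, end = 1700,
                    focal_species = "A", direction = "hyper",
                    tissue = "muscle")
  ts <- classify_tissue_scope(liv, mus)
  expect_setequal(ts$regions$tissue_scope,
                  c("multi_tissue", "liver_specific"))
  multi <- ts$regions[ts$regions$tissue_scope == "multi_tissue", ]
  expect_equal(multi$start, 1000)
  expect_equal(multi$end, 1700)
  expect_equal(sum(ts$proportions["A", ]), 1)

  # same coordinates but opposite directions never merge
  mus_flip <- transform(mus, direction = "hypo")
  ts2 <- classify_tissue_scope(liv, mus_flip)
  expect_false("multi_tissue" %in% ts2$regions$tissue_scope)

  expect_error(
    classify_tissue_scope(liv, transform(mus, focal_species = "B")),
    "species labels")
})

test_that("planted multi-tissue fraction is recovered from the study design", {
  st <- study_sim()
  samples <- st$samples
  species <- st$ref$species
  pairs <- utils::combn(species, 2, simplify = FALSE)
  cls <- lapply(c("liver", "muscle"), function(tt) {
    dl <- lapply(pairs, function(pr)
      call_dmrs(sample_group(samples, pr[1], tt),
                sample_group(samples, pr[2], tt), tissue = tt))
    classify_species_dmrs(dl, species)
  })
  ts <- classify_tissue_scope(cls[[1]], cls[[2]])
  tab <- table(ts$regions$tissue_scope)
  recovered <- tab[["multi_tissue"]] / sum(tab)
  expect_lt(abs(recovered - st$design$frac_multi_tissue), 0.07)
  assign("tissue_scope_result", ts, envir = .fixture_env)
})
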