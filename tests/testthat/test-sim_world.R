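test_that("worlds are deterministic under a seed and share ids across tables", {
  cfg <- sim_config(n_per_pop = 5, n_snp_loci = 100, seed = 61)
  w1 <- sim_world(cfg)
  w2 <- sim_world(cfg)
  expect_identical(w1$snps$genotypes, w2$snps$genotypes)
  expect_identical(w1$alignment$seqs, w2$alignment$seqs)
  expect_identical(w1$climate, w2$climate)
  w3 <- sim_world(sim_config(n_per_pop = 5, n_snp_loci = 100, seed = 62))
  expect_false(identical(w1$snps$genotypes, w3$snps$genotypes))
  ids <- names(w1$truth)
  expect_identical(w1$snps$sample_ids, ids)
  expect_identical(w1$alignment$ids, ids)
  expect_identical(w1$traits$specimen_id, ids)
  expect_identical(w1$localities$specimen_id, ids)
  expect_identical(w1$climate$specimen_id, ids)
  expect_identical(names(w1$truth_climate), ids)
})

test_that("drift vanishes in the c -> 0 limit", {
  cfg <- sim_config(n_pops = 2, tree = "(pop1:0.0001,pop2:0.0001);",
                    n_per_pop = 2, n_snp_loci = 3000, seed = 63)
  freqs <- with_seed(1, codelim:::bn_tip_frequencies(cfg))
  anc <- with_seed(1, stats::runif(3000, 0.05, 0.95))
  dev <- abs(freqs - anc)
  expect_lt(quantile(dev, 0.99), 0.02)
})

test_that("Hudson-style FST between two drifted populations recovers c", {
  cc <- 0.2
  cfg <- sim_config(n_pops = 2, n_per_pop = 2, n_snp_loci = 5000,
                    tree = sprintf("(pop1:%g,pop2:%g);", cc, cc), seed = 64)
  freqs <- with_seed(9, codelim:::bn_tip_frequencies(cfg))
  p1 <- freqs[, "pop1"]; p2 <- freqs[, "pop2"]
  # ratio-of-sums Hudson numerator/denominator on population frequencies:
  # E[(p1-p2)^2] = 2c p(1-p), E[p1(1-p2) + p2(1-p1)] = 2 p(1-p) -> FST = c
  fst <- sum((p1 - p2)^2) / sum(p1 * (1 - p2) + p2 * (1 - p1))
  # block-jackknife CI over loci
  blocks <- split(seq_len(5000), ceiling(seq_len(5000) / 100))
  jk <- vapply(blocks, function(b) {
    sum((p1[-b] - p2[-b])^2) /
      sum(p1[-b] * (1 - p2[-b]) + p2[-b] * (1 - p1[-b]))
  }, numeric(1))
  se <- sqrt((length(jk) - 1) / length(jk) * sum((jk - mean(jk))^2))
  expect_lt(abs(fst - cc), 3 * se + 0.01)
})

test_that("admixture pulls recipient frequencies toward the donor", {
  cfg0 <- d_quartet_config(seed = 65, gamma = 0)
  cfgA <- d_quartet_config(seed = 65, gamma = 0.3)
  f0 <- with_seed(2, codelim:::bn_tip_frequencies(cfg0))
  fA <- with_seed(2, codelim:::bn_tip_frequencies(cfgA))
  expect_identical(f0[, "pop1"], fA[, "pop1"])
  d0 <- mean(abs(f0[, "pop2"] - f0[, "pop3"]))
  dA <- mean(abs(fA[, "pop2"] - fA[, "pop3"]))
  expect_lt(dA, d0)
  expect_equal(fA[, "pop2"], 0.7 * f0[, "pop2"] + 0.3 * f0[, "pop3"],
               tolerance = 1e-12)
})

test_that("mtDNA alignments respect length, rates and Poisson divergence", {
  cfg0 <- sim_config(n_per_pop = 3, mtdna_rate = 0, mtdna_tip_rate = 0,
                     seed = 66)
  aln0 <- sim_mtdna(cfg0)
  expect_equal(length(unique(aln0$seqs)), 1L)
  expect_equal(aln0$length, 590L)

  # pairwise differences between sister populations match the
  # Jukes-Cantor expectation for the path length between them
  rate <- 0.05
  cfg <- sim_config(n_per_pop = 4, mtdna_rate = rate, mtdna_tip_rate = 0,
                    seed = 67)
  diffs <- vapply(1:20, function(s) {
    aln <- sim_mtdna(cfg, seed = 200 + s)
    a <- strsplit(aln$seqs[aln$ids == "pop1_01"], "")[[1]]
    b <- strsplit(aln$seqs[aln$ids == "pop2_01"], "")[[1]]
    mean(a != b)
  }, numeric(1))
  mu_path <- rate * (0.25 + 0.25)  # substitutions per site on the path
  p_exp <- 3 / 4 * (1 - exp(-4 / 3 * mu_path))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - p_exp), 3 * se + 0.002)
})

test_that("traits encode lineage structure and allometric slopes", {
  # noiseless morphometrics with distinct slopes separate lineages exactly
  cfg <- sim_config(n_pops = 2, tree = "(pop1:0.2,pop2:0.2);",
                    n_per_pop = 30, trait_sigma = 1e-12,
                    alpha_effect = 0, beta = c(1, 1.3), seed = 68)
  tr <- sim_traits(cfg)
  fm <- size_correct_morphometrics(tr)
  expect_equal(ncol(fm$values), 27L)
  truth <- sim_truth(cfg)
  st <- slope_heterogeneity(tr$body_length, tr$L01, truth)
  expect_lt(st$p, 1e-4)
  expect_equal(unname(round(st$slopes["2"] - st$slopes["1"], 2)), 0.3)

  cfg2 <- sim_config(n_pops = 2, tree = "(pop1:0.2,pop2:0.2);",
                     n_per_pop = 50, trait_sigma = 0.02,
                     beta = c(1, 1.3), seed = 69)
  tr2 <- sim_traits(cfg2)
  expect_lt(slope_heterogeneity(tr2$body_length, tr2$L05,
                                sim_truth(cfg2))$p, 1e-4)
})

test_that("localities fall inside their population ellipses", {
  cfg <- sim_config(n_per_pop = 40, seed = 70)
  loc <- sim_localities(cfg)
  truth <- sim_truth(cfg)
  ctr <- cfg$range_centers[truth, ]
  u <- (loc$lon - ctr[, 1]) / cfg$range_axes[1]
  v <- (loc$lat - ctr[, 2]) / cfg$range_axes[2]
  expect_true(all(u^2 + v^2 <= 1 + 1e-12))
  expect_equal(as.integer(table(truth)), rep(40L, 4))
  # empirical centroid near the ellipse centre
  for (g in 1:4) {
    i <- truth == g
    se_lon <- sd(loc$lon[i]) / sqrt(sum(i))
    expect_lt(abs(mean(loc$lon[i]) - cfg$range_centers[g, 1]), 3 * se_lon)
  }
})

test_that("climate variables mirror the latent temperature/precipitation blocks", {
  cfg <- sim_config(n_per_pop = 25, seed = 71)
  w <- sim_world(cfg)
  expect_true(all(as.matrix(w$climate[, sprintf("bio%02d", 12:19)]) >= 0))
  ss <- pca_correlation(climate_transform(w$climate))
  l1 <- abs(ss$loadings[, 1]); l2 <- abs(ss$loadings[, 2])
  temp <- sprintf("bio%02d", 1:11); prec <- sprintf("bio%02d", 12:19)
  # axis 1 is dominated by the temperature block, axis 2 by precipitation
  expect_gt(mean(l1[temp]), 1.5 * mean(l1[prec]))
  expect_gt(mean(l2[prec]), 1.5 * mean(l2[temp]))
  # both regions occur, and the aligned scenario tracks the lineage split
  expect_setequal(unique(w$truth_climate), 1:2)
  wa <- sim_world(sim_config(n_per_pop = 25, seed = 71,
                             climate_scenario = "aligned"))
  east <- as.integer(wa$truth >= 3) + 1L
  expect_gt(adjusted_rand(wa$truth_climate, east), 0.95)
})

test_that("sim worlds serialize to the documented table formats", {
  w <- sim_world(sim_config(n_per_pop = 4, n_snp_loci = 60, seed = 72))
  dir <- tempfile("world")
  write_sim_world(w, dir)
  aln <- read_fasta(file.path(dir, "mtdna.fasta"))
  expect_identical(aln$seqs, w$alignment$seqs)
  G <- read_genotype_table(file.path(dir, "snps.tsv"), "tsv012")
  expect_identical(G$genotypes, w$snps$genotypes)
  expect_s3_class(read_trait_table(file.path(dir, "traits.csv")),
                  "trait_table")
  expect_s3_class(read_locality_table(file.path(dir, "localities.csv")),
                  "locality_table")
  expect_s3_class(read_climate_table(file.path(dir, "climate.csv")),
                  "climate_table")
})
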