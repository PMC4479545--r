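test_that("adjusted Rand index matches pair-counting brute force", {
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand(rep(1, 10), 1:10), 0)
  set.seed(20)
  for (i in 1:5) {
    p <- sample(1:3, 12, TRUE); q <- sample(1:4, 12, TRUE)
    # brute force over all specimen pairs
    n11 <- n10 <- n01 <- n00 <- 0
    for (a in 1:11) for (b in (a + 1):12) {
      sp <- p[a] == p[b]; sq <- q[a] == q[b]
      if (sp && sq) n11 <- n11 + 1
      else if (sp) n10 <- n10 + 1
      else if (sq) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
    total <- choose(12, 2)
    exp_idx <- (n11 + n10) * (n11 + n01) / total
    oracle <- (n11 - exp_idx) /
      ((n11 + n10 + n11 + n01) / 2 - exp_idx)
    expect_equal(adjusted_rand(p, q), oracle, tolerance = 1e-12)
    expect_equal(adjusted_rand(q, p), adjusted_rand(p, q))
    # label-permutation invariance
    relab <- sample(10)[p]
    expect_equal(adjusted_rand(relab, q), adjusted_rand(p, q))
  }
  # named vectors join on shared specimens; disjoint sets error
  expect_equal(adjusted_rand(c(a = 1, b = 1, c = 2), c(c = 5, b = 5, a = 5,
                                                       z = 1)),
               adjusted_rand(c(1, 1, 2), c(5, 5, 5)))
  expect_error(adjusted_rand(c(a = 1), c(b = 1)), class = "codelim_join_error")
})

test_that("adjusted Rand agrees with the mclust implementation", {
  skip_if_not_installed("mclust")
  set.seed(21)
  for (i in 1:10) {
    p <- sample(1:4, 30, TRUE); q <- sample(1:3, 30, TRUE)
    expect_equal(adjusted_rand(p, q), mclust::adjustedRandIndex(p, q),
                 tolerance = 1e-12)
  }
})

test_that("Delaunay edges satisfy planarity, hull and nearest-neighbour properties", {
  set.seed(22)
  n <- 40
  pts <- cbind(runif(n), runif(n))
  g <- codelim:::delaunay_graph(pts[, 1], pts[, 2])
  m <- g$n_nodes
  expect_lte(nrow(g$edges), 3 * m - 6)
  # convex hull edges are Delaunay edges
  hull <- rev(grDevices::chull(pts))
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  edge_keys <- key(g$edges[, 1], g$edges[, 2])
  for (h in seq_along(hull)) {
    a <- hull[h]; b <- hull[(h %% length(hull)) + 1]
    expect_true(key(a, b) %in% edge_keys)
  }
  # every point's nearest neighbour is connected to it
  D <- as.matrix(dist(pts)); diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  expect_true(all(key(seq_len(n), nn) %in% edge_keys))
})

test_that("contiguity scores connected patches 1 and split clusters lower", {
  # one tight patch among a scattered field
  set.seed(23)
  field <- make_locality_df(n = 100, seed = 23)
  patch <- field$specimen_id[field$lon < quantile(field$lon, 0.3)]
  res <- contiguity(patch, field)
  expect_true(res$flag)
  expect_equal(res$score, 1)
  # two members isolated at opposite corners of the field, pruned apart
  far <- rbind(field,
               data.frame(specimen_id = c("iso1", "iso2"),
                          lon = c(-150, -60), lat = c(5, 60)))
  res2 <- contiguity(c("iso1", "iso2"), far)
  expect_false(res2$flag)
  expect_equal(res2$score, 0)
  expect_equal(res2$n_components, 2L)
})

test_that("contiguity component counts equal a brute-force union-find", {
  set.seed(24)
  loc <- make_locality_df(n = 60, seed = 24)
  members <- sample(loc$specimen_id, 25)
  res <- contiguity(members, loc)
  # rebuild the same pruned graph and count components by union-find
  g <- codelim:::delaunay_graph(loc$lon, loc$lat)
  cutoff <- quantile(g$lengths, 0.95, names = FALSE)
  keep <- g$lengths <= cutoff
  mnodes <- sort(unique(g$node_id[match(members, loc$specimen_id)]))
  parent <- stats::setNames(mnodes, mnodes)
  find <- function(i) { while (parent[[as.character(i)]] != i) i <- parent[[as.character(i)]]; i }
  for (e in which(keep)) {
    a <- g$edges[e, 1]; b <- g$edges[e, 2]
    if (a %in% mnodes && b %in% mnodes) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[[as.character(ra)]] <- rb
    }
  }
  ncomp <- length(unique(vapply(mnodes, find, numeric(1))))
  expect_equal(res$n_components, ncomp)
  expect_equal(res$score, 1 - (ncomp - 1) / (length(members) - 1))
})

test_that("convex hull overlap fraction behaves on constructed polygons", {
  # identical squares: full overlap
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(codelim:::hull_overlap_fraction(sq[, 1], sq[, 2],
                                               sq[, 1], sq[, 2]), 1)
  # half-shifted squares: half of the smaller hull
  expect_equal(codelim:::hull_overlap_fraction(sq[, 1], sq[, 2],
                                               sq[, 1] + 0.5, sq[, 2]), 0.5,
               tolerance = 1e-9)
  # disjoint squares: none
  expect_equal(codelim:::hull_overlap_fraction(sq[, 1], sq[, 2],
                                               sq[, 1] + 5, sq[, 2]), 0)
})

test_that("diffuse overlapping cluster pairs merge to a fixed point", {
  set.seed(25)
  n <- 60
  # one cloud artificially split by two nearly coincident components:
  # posteriors sit near 0.5 and the ranges interleave completely
  X <- cbind(rnorm(n, 0, 1), rnorm(n, 0, 1))
  loc <- data.frame(specimen_id = sprintf("s%02d", 1:n),
                    lon = runif(n, -114, -112), lat = runif(n, 28, 30))
  fit <- structure(list(family = "EEE", K = 2L, weights = c(0.5, 0.5),
                        means = rbind(c(-0.15, 0), c(0.15, 0)),
                        covariances = list(diag(2), diag(2)),
                        n = n, d = 2, n_params = 8L, loglik = 0, bic = 0,
                        converged = TRUE, singular = FALSE),
                   class = "mixture_fit")
  part <- classify(fit, X, specimen_ids = loc$specimen_id, dataset = "snp")
  expect_gt(mean(part$uncertainty), 0.25)  # genuinely diffuse
  merged <- merge_diffuse_clusters(part, loc)
  expect_equal(length(unique(merged$labels)), 1L)
  expect_equal(length(merged$merges), 1L)
  # idempotent
  again <- merge_diffuse_clusters(merged, loc)
  expect_identical(again$labels, merged$labels)
  expect_length(again$merges, 0)

  # two fully separated confident clusters stay untouched
  Y <- rbind(cbind(rnorm(30, 0), rnorm(30)), cbind(rnorm(30, 12), rnorm(30)))
  locY <- data.frame(specimen_id = sprintf("y%02d", 1:60),
                     lon = -113 + Y[, 1] / 5, lat = 29 + Y[, 2] / 5)
  fitY <- em_fit(Y, 2, "EEE", seed = 3)
  partY <- classify(fitY, Y, specimen_ids = locY$specimen_id, dataset = "snp")
  mY <- merge_diffuse_clusters(partY, locY)
  expect_equal(length(unique(mY$labels)), 2L)
})

test_that("delimitation applies the >=2-dataset most-inclusive rule", {
  ids <- letters[1:9]
  mk <- function(labels, tag) partition_table(ids, tag, labels, 0)
  # two identical 3-cluster partitions -> the 3 groups, support 2
  p <- mk(rep(1:3, each = 3), "mtdna")
  q <- mk(rep(1:3, each = 3), "snp")
  hyp <- delimit(list(p, q))
  expect_length(hyp$groups, 3)
  expect_true(all(hyp$assignments$support >= 2))
  # p = A|B vs q = A|B1|B2: most inclusive congruent cluster is B
  p2 <- mk(c(1, 1, 1, 2, 2, 2, 2, 2, 2), "mtdna")
  q2 <- mk(c(1, 1, 1, 2, 2, 2, 3, 3, 3), "snp")
  hyp2 <- delimit(list(p2, q2))
  expect_length(hyp2$groups, 2)
  expect_setequal(hyp2$groups[[2]], letters[4:9])
  # supplying the partitions in the other order changes nothing
  hyp2r <- delimit(list(q2, p2))
  expect_equal(lapply(hyp2$groups, sort), lapply(hyp2r$groups, sort))
  # groups partition the joined specimen set
  expect_setequal(unlist(hyp2$groups), ids)
  expect_error(delimit(list(p)), class = "codelim_argument_error")
})

test_that("delimitation recovers the true lineages of a divergent synthetic world", {
  cfg <- sim_config(n_per_pop = 10, n_snp_loci = 600,
                    tree = "((pop1:0.4,pop2:0.4):0.4,(pop3:0.4,pop4:0.4):0.4);",
                    meristic_effect = 0.3, alpha_effect = 0.06, seed = 31)
  w <- sim_world(cfg)
  run <- function(ss, tag) {
    sel <- model_select(ss, K_max = 6, restarts = 4,
                        seed = codelim:::derive_seed(31, match(tag, c("mtdna", "snp", "phenotype"))))
    classify(sel$best, ss, specimen_ids = rownames(ss$scores),
             dataset = tag)$table
  }
  suppressMessages({
    Gm <- extract_snps(w$alignment)
    sm <- select_axes(pca_correlation(impute_missing(Gm, source = "mtdna")),
                      missingness_vector(Gm))
    sn <- select_axes(pca_correlation(impute_missing(w$snps)),
                      missingness_vector(w$snps))
    sp <- select_axes(pca_correlation(size_correct_morphometrics(w$traits)))
  })
  parts <- list(run(sm, "mtdna"), run(sn, "snp"), run(sp, "phenotype"))
  hyp <- delimit(parts, localities = w$localities)
  grp <- stats::setNames(hyp$assignments$group, hyp$assignments$specimen_id)
  expect_equal(adjusted_rand(grp, w$truth[names(grp)]), 1)
  expect_true(all(hyp$assignments$contiguous))
})
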