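# End-to-end orchestration: apply the identical encode -> PCA -> retain ->
# cluster procedure to every supplied dataset, then congruence, species
# delimitation and (optionally) the D-statistic battery.

#' Run the comparative-signal pipeline
#'
#' Each supplied dataset goes through the same procedure: numeric encoding,
#' correlation-matrix PCA, retention of axes explaining >5% variance (plus
#' screening of missingness-correlated axes for the molecular datasets),
#' and Gaussian-mixture clustering with BIC model selection. The climate
#' dataset can instead be routed through spatial thinning with consensus
#' clustering (\code{climate_reps > 0}) to correct occurrence sampling
#' bias. Partitions are then compared (pairwise adjusted Rand), intrinsic
#' partitions are combined into a species hypothesis, and a D-statistic
#' battery is run when quartets are given.
#'
#' @param alignment optional \code{\link{seq_alignment}} (mtDNA).
#' @param snps optional diploid \code{\link{genotype_matrix}}.
#' @param traits optional trait table.
#' @param climate optional climate table.
#' @param localities locality table (needed for climate thinning, the
#'   diffuse-cluster merge and contiguity).
#' @param quartets optional data.frame (P1, P2, P3, O) for the D battery.
#' @param seed master seed.
#' @param threshold PCA variance-fraction retention cutoff (default 0.05).
#' @param r_threshold missingness-axis screening correlation (default 0.7).
#' @param K_max,families,restarts model-search controls.
#' @param climate_reps thinning replicates for the climate dataset; 0
#'   clusters climate like the other datasets (no thinning).
#' @param cell_minutes thinning grid cell size, arc-minutes.
#' @param merge_diffuse merge high-uncertainty range-overlapping cluster
#'   pairs in the intrinsic partitions (needs localities).
#' @param min_support datasets required to support a species group.
#' @return A list of class \code{compare_signal}: per-dataset
#'   \code{partitions} (list of \code{partition_table}), \code{scores},
#'   \code{ari} matrix, \code{species} hypothesis, \code{dstats},
#'   \code{manifest}.
#' @export
run_compare_signal <- function(alignment = NULL, snps = NULL, traits = NULL,
                               climate = NULL, localities = NULL,
                               quartets = NULL, seed = 1L,
                               threshold = 0.05, r_threshold = 0.7,
                               K_max = 12L, families = GMM_FAMILIES,
                               restarts = 10L, climate_reps = 1000L,
                               cell_minutes = 0.5, merge_diffuse = TRUE,
                               min_support = 2L) {
  supplied <- c(mtdna = !is.null(alignment), snp = !is.null(snps),
                phenotype = !is.null(traits), climate = !is.null(climate))
  if (sum(supplied) < 2) {
    cd_stop("need at least two datasets to compare", "config")
  }
  if (!is.null(climate) && climate_reps > 0 && is.null(localities)) {
    cd_stop("climate thinning requires 'localities'", "config")
  }
  partitions <- list()
  scores <- list()
  extra <- list()

  cluster_scores <- function(ss, tag, sd) {
    sel <- model_select(ss, K_max = K_max, families = families,
                        restarts = restarts, seed = sd)
    part <- classify(sel$best, ss,
                     specimen_ids = rownames(ss$scores), dataset = tag)
    if (merge_diffuse && !is.null(localities)) {
      loc <- localities[localities$specimen_id %in% part$table$specimen_id, ]
      if (nrow(loc) == nrow(part$table)) {
        part <- merge_diffuse_clusters(part, loc)
      }
    }
    list(selection = sel, partition = part)
  }

  if (!is.null(alignment)) {
    G <- extract_snps(alignment)
    fm <- impute_missing(G, source = "mtdna")
    ss <- select_axes(pca_correlation(fm),
                      missing_fraction = missingness_vector(G),
                      threshold = threshold, r_threshold = r_threshold)
    res <- cluster_scores(ss, "mtdna", derive_seed(seed, 1L))
    partitions$mtdna <- res$partition$table
    scores$mtdna <- ss
    extra$mtdna_selection <- res$selection
  }
  if (!is.null(snps)) {
    fm <- impute_missing(snps, source = "snp")
    ss <- select_axes(pca_correlation(fm),
                      missing_fraction = missingness_vector(snps),
                      threshold = threshold, r_threshold = r_threshold)
    res <- cluster_scores(ss, "snp", derive_seed(seed, 2L))
    partitions$snp <- res$partition$table
    scores$snp <- ss
    extra$snp_selection <- res$selection
  }
  if (!is.null(traits)) {
    fm <- size_correct_morphometrics(traits)
    ss <- select_axes(pca_correlation(fm), threshold = threshold)
    res <- cluster_scores(ss, "phenotype", derive_seed(seed, 3L))
    partitions$phenotype <- res$partition$table
    scores$phenotype <- ss
    extra$phenotype_selection <- res$selection
  }
  if (!is.null(climate)) {
    fm <- climate_transform(climate)
    ss <- select_axes(pca_correlation(fm), threshold = threshold)
    scores$climate <- ss
    if (climate_reps > 0) {
      joined <- join_specimens(climate, localities, quiet = TRUE)
      loc <- joined[[2]]
      X <- retained_scores(ss)[match(loc$specimen_id,
                                     climate$specimen_id), , drop = FALSE]
      cons <- consensus_cluster(X, loc,
                                grid = grid_spec(loc, cell_minutes),
                                reps = climate_reps,
                                seed = derive_seed(seed, 4L),
                                K_max = K_max, families = families,
                                restarts = restarts)
      partitions$climate <- cons$final_partition
      extra$climate_consensus <- cons
    } else {
      res <- cluster_scores(ss, "climate", derive_seed(seed, 4L))
      partitions$climate <- res$partition$table
      extra$climate_selection <- res$selection
    }
  }

  tags <- names(partitions)
  ari <- matrix(1, length(tags), length(tags), dimnames = list(tags, tags))
  for (i in seq_along(tags)) {
    for (j in seq_along(tags)) {
      if (i < j) {
        pi_ <- stats::setNames(partitions[[i]]$cluster,
                               partitions[[i]]$specimen_id)
        pj <- stats::setNames(partitions[[j]]$cluster,
                              partitions[[j]]$specimen_id)
        ari[i, j] <- ari[j, i] <- adjusted_rand(pi_, pj)
      }
    }
  }

  intrinsic <- partitions[names(partitions) != "climate"]
  species <- if (length(intrinsic) >= 2) {
    delimit(intrinsic, localities = localities, min_support = min_support)
  } else NULL

  dstats <- if (!is.null(quartets) && !is.null(snps)) {
    test_battery(snps, quartets)
  } else NULL

  structure(list(partitions = partitions, scores = scores, ari = ari,
                 species = species, dstats = dstats, extra = extra,
                 manifest = list(seed = seed, threshold = threshold,
                                 r_threshold = r_threshold, K_max = K_max,
                                 families = families, restarts = restarts,
                                 climate_reps = climate_reps,
                                 cell_minutes = cell_minutes,
                                 min_support = min_support,
                                 datasets = tags)),
            class = "compare_signal")
}

#' @export
print.compare_signal <- function(x, ...) {
  cat("Comparative-signal run over datasets:",
      paste(x$manifest$datasets, collapse = ", "), "\n")
  ks <- vapply(x$partitions, function(p) length(unique(p$cluster)),
               integer(1))
  cat("  clusters per dataset:",
      paste(sprintf("%s=%d", names(ks), ks), collapse = " "), "\n")
  if (!is.null(x$species)) {
    cat(sprintf("  species hypothesis: %d groups\n", length(x$species$groups)))
  }
  invisible(x)
}

#' Cluster an mtDNA alignment end to end
#'
#' Convenience benchmark pipeline: biallelic-site extraction, mean
#' imputation, correlation PCA, >5% axis retention, and BIC model selection
#' with many restarts; returns the selected cluster count together with the
#' full BIC table so sensitivity to the family lattice is visible.
#'
#' @param fasta_path path to an aligned FASTA of mtDNA sequences.
#' @param seed master seed.
#' @param restarts EM restarts per model (default 50).
#' @param K_max largest cluster count searched.
#' @return A list: \code{K} (selected), \code{partition}, \code{bic_table},
#'   \code{retained_axes}.
#' @export
benchmark_mtdna_clusters <- function(fasta_path, seed = 1L, restarts = 50L,
                                     K_max = 12L) {
  aln <- read_fasta(fasta_path)
  G <- extract_snps(aln)
  fm <- impute_missing(G, source = "mtdna")
  ss <- select_axes(pca_correlation(fm))
  sel <- model_select(ss, K_max = K_max, restarts = restarts, seed = seed)
  part <- classify(sel$best, ss, specimen_ids = aln$ids, dataset = "mtdna")
  list(K = length(unique(part$labels)), partition = part$table,
       bic_table = sel$bic_table, retained_axes = ss$retained)
}
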