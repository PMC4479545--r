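# Synthetic-data generator: a population tree with Balding-Nichols allele-
# frequency drift, a Jukes-Cantor mtDNA alignment, Poisson/allometric trait
# tables, uniform-in-ellipse localities, and a climate landscape built from
# two latent fields (temperature gradient, precipitation "monsoon" front)
# that is deliberately decoupled from the lineage boundaries. Every table
# shares specimen ids and carries known truth labels, so the whole
# delimitation pipeline can be verified in silico.

#' Simulation configuration
#'
#' @param n_pops number of terminal populations (lineages).
#' @param tree newick string with one tip per population; branch lengths are
#'   Balding-Nichols drift parameters c in (0,1). The default is a balanced
#'   four-lineage tree with c = 0.25 on every branch.
#' @param n_per_pop specimens sampled per population.
#' @param n_snp_loci biallelic SNP loci to simulate.
#' @param mtdna_length alignment length in bp (default 590).
#' @param mtdna_rate substitutions per site per unit branch length.
#' @param mtdna_tip_rate within-population star-phylogeny tip rate.
#' @param missing_rate fraction of SNP genotype cells masked missing.
#' @param admixture optional data.frame(donor, recipient, gamma): after
#'   drift, the recipient population's allele frequencies become
#'   (1-gamma) p_recipient + gamma p_donor.
#' @param meristic_base expected counts for the 18 meristic characters.
#' @param meristic_effect log-scale between-lineage spread of meristic
#'   means.
#' @param morpho_frac baseline size of each of the 9 morphometric lengths
#'   as a fraction of body length.
#' @param alpha_effect between-lineage spread of allometric intercepts
#'   (log10 units).
#' @param beta per-lineage allometric slopes (recycled; default isometry).
#' @param trait_sigma residual sd of log10 morphometrics.
#' @param adult_frac,adult_svl,subadult_svl ontogeny mix and body-length
#'   (snout-vent) distributions, mm (mean, sd).
#' @param range_centers matrix (n_pops x 2) of ellipse centers (lon, lat).
#' @param range_axes semi-axes (lon, lat) of each range ellipse, degrees.
#' @param climate_scenario "crossing" (climate regions run orthogonal to
#'   the lineage ranges) or "aligned" (the region boundary coincides with
#'   one lineage boundary).
#' @param monsoon_amplitude latent precipitation-field amplitude.
#' @param seed master seed; all generators derive their streams from it.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_pops = 4L,
                       tree = NULL,
                       n_per_pop = 15L,
                       n_snp_loci = 1000L,
                       mtdna_length = 590L,
                       mtdna_rate = 0.05,
                       mtdna_tip_rate = 0.008,
                       missing_rate = 0.05,
                       admixture = NULL,
                       meristic_base = NULL,
                       meristic_effect = 0.15,
                       morpho_frac = c(0.05, 0.03, 0.02, 0.015, 0.01,
                                       0.04, 0.025, 0.018, 0.012),
                       alpha_effect = 0.03,
                       beta = 1.0,
                       trait_sigma = 0.02,
                       adult_frac = 0.75,
                       adult_svl = c(850, 90),
                       subadult_svl = c(450, 70),
                       range_centers = NULL,
                       range_axes = c(0.9, 0.75),
                       climate_scenario = c("crossing", "aligned"),
                       monsoon_amplitude = 6,
                       seed = 1L) {
  climate_scenario <- match.arg(climate_scenario)
  if (is.null(tree)) {
    if (n_pops == 4L) {
      tree <- "((pop1:0.25,pop2:0.25):0.25,(pop3:0.25,pop4:0.25):0.25);"
    } else {
      tips <- paste0("pop", seq_len(n_pops), ":0.25", collapse = ",")
      tree <- paste0("(", tips, ");")
    }
  }
  phy <- ape::read.tree(text = tree)
  if (length(phy$tip.label) != n_pops) {
    cd_stop("tree tip count must equal n_pops", "config")
  }
  if (is.null(phy$edge.length) ||
      any(phy$edge.length <= 0) || any(phy$edge.length >= 1)) {
    cd_stop("branch lengths (drift c) must lie in (0,1)", "config")
  }
  if (!is.null(admixture)) {
    if (!all(c("donor", "recipient", "gamma") %in% colnames(admixture))) {
      cd_stop("admixture needs columns donor, recipient, gamma", "config")
    }
    if (any(admixture$gamma < 0 | admixture$gamma >= 1)) {
      cd_stop("gamma must lie in [0,1)", "config")
    }
  }
  if (is.null(meristic_base)) {
    meristic_base <- c(25, 12, 35, 8, 17, 140, 23, 10, 30,
                       27, 14, 42, 9, 21, 65, 31, 11, 19)
  }
  if (length(meristic_base) != 18) cd_stop("need 18 meristic baselines", "config")
  if (length(morpho_frac) != 9) cd_stop("need 9 morphometric baselines", "config")
  if (is.null(range_centers)) {
    lons <- seq(-117, by = 2.5, length.out = n_pops)
    range_centers <- cbind(lon = lons, lat = rep(30, n_pops))
  }
  if (any(range_axes <= 0)) cd_stop("ellipse axes must be positive", "config")
  beta <- rep_len(beta, n_pops)
  n_per_pop <- rep_len(as.integer(n_per_pop), n_pops)
  structure(as.list(environment()), class = "sim_config")
}

sim_specimen_ids <- function(config) {
  unlist(lapply(seq_len(config$n_pops), function(g) {
    sprintf("pop%d_%02d", g, seq_len(config$n_per_pop[g]))
  }))
}

#' True lineage labels of a configuration
#' @param config a \code{\link{sim_config}}.
#' @return Named integer vector: specimen id -> lineage.
#' @export
sim_truth <- function(config) {
  stats::setNames(rep(seq_len(config$n_pops), config$n_per_pop),
                  sim_specimen_ids(config))
}

# edge indices ordered so every parent is visited before its children
preorder_edges <- function(phy) {
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  done <- root
  ord <- integer(0)
  pending <- seq_len(nrow(phy$edge))
  while (length(pending)) {
    ready <- pending[phy$edge[pending, 1] %in% done]
    if (!length(ready)) cd_stop("malformed tree edges", "config")
    ord <- c(ord, ready)
    done <- c(done, phy$edge[ready, 2])
    pending <- setdiff(pending, ready)
  }
  ord
}

# tip allele frequencies: Balding-Nichols drift down the tree, then
# admixture edges applied at the tips
bn_tip_frequencies <- function(config) {
  phy <- config$phy
  L <- config$n_snp_loci
  n_node <- max(phy$edge)
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  freq <- vector("list", n_node)
  freq[[root]] <- stats::runif(L, 0.05, 0.95)
  for (e in preorder_edges(phy)) {
    parent <- phy$edge[e, 1]; child <- phy$edge[e, 2]
    c_drift <- phy$edge.length[e]
    p <- freq[[parent]]
    a <- p * (1 - c_drift) / c_drift
    b <- (1 - p) * (1 - c_drift) / c_drift
    freq[[child]] <- stats::rbeta(L, pmax(a, 1e-12), pmax(b, 1e-12))
  }
  tips <- stats::setNames(seq_along(phy$tip.label), phy$tip.label)
  out <- do.call(cbind, freq[tips])
  colnames(out) <- phy$tip.label
  if (!is.null(config$admixture)) {
    orig <- out
    for (i in seq_len(nrow(config$admixture))) {
      don <- as.character(config$admixture$donor[i])
      rec <- as.character(config$admixture$recipient[i])
      gam <- config$admixture$gamma[i]
      out[, rec] <- (1 - gam) * orig[, rec] + gam * orig[, don]
    }
  }
  out
}

#' Simulate a SNP genotype matrix
#'
#' Per locus, an ancestral frequency Uniform(0.05, 0.95) drifts down the
#' population tree under the Balding-Nichols model (child frequency
#' Beta(p(1-c)/c, (1-p)(1-c)/c) along a branch with drift c); admixture
#' edges mix tip frequencies; individual genotypes are Binomial(2, p_pop);
#' cells are masked missing at \code{missing_rate}.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed overrides the config seed when given.
#' @return A diploid \code{\link{genotype_matrix}}.
#' @export
sim_snps <- function(config, seed = config$seed) {
  with_seed(derive_seed(seed, 11L), {
    tipfreq <- bn_tip_frequencies(config)  # loci x pops
    ids <- sim_specimen_ids(config)
    truth <- sim_truth(config)
    L <- config$n_snp_loci
    g <- matrix(NA_integer_, length(ids), L,
                dimnames = list(ids, paste0("L", seq_len(L))))
    for (gpop in seq_len(config$n_pops)) {
      rows <- which(truth == gpop)
      p <- tipfreq[, paste0("pop", gpop)]
      draws <- stats::rbinom(length(rows) * L, 2,
                             rep(p, each = length(rows)))
      g[rows, ] <- matrix(draws, nrow = length(rows))
    }
    if (config$missing_rate > 0) {
      mask <- stats::runif(length(g)) < config$missing_rate
      g[mask] <- NA_integer_
    }
    genotype_matrix(g, ploidy = 2)
  })
}

# apply n_sub Jukes-Cantor substitutions to integer-coded sequence (1..4)
jc_mutate <- function(seq_int, n_sub) {
  if (n_sub == 0) return(seq_int)
  sites <- sample.int(length(seq_int), n_sub, replace = TRUE)
  shift <- sample.int(3, n_sub, replace = TRUE)
  seq_int[sites] <- ((seq_int[sites] - 1 + shift) %% 4) + 1
  seq_int
}

#' Simulate an mtDNA alignment
#'
#' A random ancestral sequence evolves down the population tree under
#' equal-rate (Jukes-Cantor) substitution with Poisson(rate x branch x
#' length) changes per branch; individuals within a population radiate from
#' their population sequence as a star phylogeny with a small tip rate.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed overrides the config seed when given.
#' @return A \code{\link{seq_alignment}} of all specimens.
#' @export
sim_mtdna <- function(config, seed = config$seed) {
  with_seed(derive_seed(seed, 22L), {
    phy <- config$phy
    Lbp <- config$mtdna_length
    n_node <- max(phy$edge)
    root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
    seqs <- vector("list", n_node)
    seqs[[root]] <- sample.int(4, Lbp, replace = TRUE)
    for (e in preorder_edges(phy)) {
      parent <- phy$edge[e, 1]; child <- phy$edge[e, 2]
      n_sub <- stats::rpois(1, config$mtdna_rate * phy$edge.length[e] * Lbp)
      seqs[[child]] <- jc_mutate(seqs[[parent]], n_sub)
    }
    tips <- stats::setNames(seq_along(phy$tip.label), phy$tip.label)
    ids <- sim_specimen_ids(config)
    truth <- sim_truth(config)
    bases <- c("A", "C", "G", "T")
    out <- vapply(seq_along(ids), function(i) {
      popseq <- seqs[[tips[paste0("pop", truth[i])]]]
      n_sub <- stats::rpois(1, config$mtdna_tip_rate * Lbp)
      paste(bases[jc_mutate(popseq, n_sub)], collapse = "")
    }, character(1))
    seq_alignment(ids, out)
  })
}

#' Simulate the quantitative trait table
#'
#' Meristic counts are Poisson around per-lineage means (baseline counts
#' times a lineage-specific log-normal effect); morphometrics follow the
#' allometric model log10(y) = alpha_g + beta_g log10(SVL) + noise with
#' body length (SVL) drawn per ontogeny class.
#'
#' @param config a \code{\link{sim_config}}.
#' @param body_lengths optional per-specimen body lengths (mm); generated
#'   from the ontogeny mix when absent.
#' @param seed overrides the config seed when given.
#' @return A \code{trait_table} data.frame.
#' @export
sim_traits <- function(config, body_lengths = NULL, seed = config$seed) {
  with_seed(derive_seed(seed, 33L), {
    ids <- sim_specimen_ids(config)
    truth <- sim_truth(config)
    n <- length(ids)
    G <- config$n_pops
    ontogeny <- ifelse(stats::runif(n) < config$adult_frac,
                       "adult", "subadult")
    if (is.null(body_lengths)) {
      svl <- ifelse(ontogeny == "adult",
                    stats::rnorm(n, config$adult_svl[1], config$adult_svl[2]),
                    stats::rnorm(n, config$subadult_svl[1],
                                 config$subadult_svl[2]))
      svl <- pmax(svl, 150)
    } else {
      svl <- body_lengths
    }
    # lineage effects, drawn once per configuration seed
    mer_shift <- matrix(stats::rnorm(G * 18, 0, config$meristic_effect), G, 18)
    alpha_shift <- matrix(stats::rnorm(G * 9, 0, config$alpha_effect), G, 9)
    meristic <- matrix(0, n, 18)
    for (j in 1:18) {
      lam <- config$meristic_base[j] * exp(mer_shift[truth, j])
      meristic[, j] <- stats::rpois(n, lam)
    }
    morpho <- matrix(0, n, 9)
    alpha_base <- log10(config$morpho_frac)
    for (j in 1:9) {
      mu <- alpha_base[j] + alpha_shift[truth, j] +
        config$beta[truth] * log10(svl) +
        (1 - config$beta[truth]) * log10(config$adult_svl[1])
      morpho[, j] <- 10^(mu + stats::rnorm(n, 0, config$trait_sigma))
    }
    df <- data.frame(specimen_id = ids,
                     sex = sample(c("M", "F"), n, replace = TRUE),
                     ontogeny = ontogeny,
                     body_length = svl,
                     stringsAsFactors = FALSE)
    df[trait_meristic_cols()] <- as.data.frame(meristic)
    df[trait_morpho_cols()] <- as.data.frame(morpho)
    validate_trait_table(df)
  })
}

#' Simulate specimen localities
#'
#' Uniform points inside each population's range ellipse.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed overrides the config seed when given.
#' @return A \code{locality_table} data.frame.
#' @export
sim_localities <- function(config, seed = config$seed) {
  with_seed(derive_seed(seed, 44L), {
    ids <- sim_specimen_ids(config)
    truth <- sim_truth(config)
    n <- length(ids)
    r <- sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    lon <- config$range_centers[truth, 1] + config$range_axes[1] * r * cos(th)
    lat <- config$range_centers[truth, 2] + config$range_axes[2] * r * sin(th)
    validate_locality_table(data.frame(specimen_id = ids, lon = lon,
                                       lat = lat, stringsAsFactors = FALSE))
  })
}

# deterministic latent climate fields at given coordinates
climate_latent <- function(config, lon, lat) {
  lat0 <- mean(config$range_centers[, 2])
  lon0 <- mean(config$range_centers[, 1])
  A <- config$monsoon_amplitude
  Tfield <- 0.5 * (lat - lat0)
  if (config$climate_scenario == "crossing") {
    # monsoon front running east-west: the high-precipitation regime covers
    # the northern part of every lineage's range
    Pfield <- A * stats::plogis((lat - (lat0 + 0.25)) / 0.04) +
      0.3 * (lat - lat0)
  } else {
    # front in the gap between the two easternmost ranges and the rest: the
    # regime boundary coincides with one lineage boundary
    ord <- order(config$range_centers[, 1])
    b <- mean(config$range_centers[ord[config$n_pops - c(2, 1)], 1])
    Pfield <- A * stats::plogis((lon - b) / 0.15) + 0.05 * (lat - lat0)
  }
  list(T = Tfield, P = Pfield)
}

#' True climate-region labels at the specimen localities
#'
#' Region 2 is the "monsoon" side of the latent precipitation field
#' (deterministic field above half its amplitude), region 1 the rest.
#'
#' @param config a \code{\link{sim_config}}.
#' @param localities localities generated from the same config.
#' @return Named integer vector: specimen id -> climate region.
#' @export
sim_truth_climate <- function(config, localities) {
  latent <- climate_latent(config, localities$lon, localities$lat)
  stats::setNames(ifelse(latent$P >= config$monsoon_amplitude / 2, 2L, 1L),
                  localities$specimen_id)
}

softplus <- function(x) log1p(exp(pmin(x, 30))) + pmax(x - 30, 0)

#' Simulate the climate table
#'
#' The 19 observed bioclim-style variables are fixed linear mixtures of two
#' latent fields evaluated at each specimen's locality — a temperature
#' gradient T and a precipitation "monsoon" front P — plus a specimen-level
#' shared disturbance per block and independent noise. Variables
#' bio01..bio11 load mainly on T; bio12..bio19 load mainly on P and are
#' made non-negative through a softplus. The landscape is a property of
#' geography alone: in the "crossing" scenario its regional boundary runs
#' orthogonal to the lineage ranges, in the "aligned" scenario it
#' coincides with one lineage boundary.
#'
#' @param config a \code{\link{sim_config}}.
#' @param localities localities generated from the same config.
#' @param seed overrides the config seed when given.
#' @return A \code{climate_table} data.frame.
#' @export
sim_climate <- function(config, localities, seed = config$seed) {
  with_seed(derive_seed(seed, 55L), {
    n <- nrow(localities)
    latent <- climate_latent(config, localities$lon, localities$lat)
    # shared per-specimen disturbances keep variables within a block
    # strongly correlated without adding spatial structure
    uT <- stats::rnorm(n, 0, 2.0)
    uP <- stats::rnorm(n, 0, 0.5)
    Tval <- latent$T + uT
    Pval <- latent$P + uP
    temp_load <- seq(0.8, 1.2, length.out = 11)
    temp_base <- seq(8, 28, length.out = 11)
    precip_load <- seq(0.8, 1.2, length.out = 8)
    precip_base <- seq(0.5, 2.5, length.out = 8)
    out <- matrix(0, n, 19)
    for (j in 1:11) {
      out[, j] <- temp_base[j] + temp_load[j] * Tval + 0.02 * Pval +
        stats::rnorm(n, 0, 0.3)
    }
    for (j in 1:8) {
      pre <- precip_base[j] + precip_load[j] * Pval + 0.05 * Tval +
        stats::rnorm(n, 0, 0.4)
      out[, 11 + j] <- 10 * softplus(pre)
    }
    df <- data.frame(specimen_id = localities$specimen_id,
                     stringsAsFactors = FALSE)
    df[climate_cols()] <- as.data.frame(out)
    validate_climate_table(df)
  })
}

#' Simulate a complete world
#'
#' Composes the five generators under one master seed, returning every
#' input table plus the truth labels.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list of class \code{sim_world}: alignment, snps, traits,
#'   localities, climate, truth, truth_climate, config.
#' @export
sim_world <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  localities <- sim_localities(config)
  structure(list(alignment = sim_mtdna(config),
                 snps = sim_snps(config),
                 traits = sim_traits(config),
                 localities = localities,
                 climate = sim_climate(config, localities),
                 truth = sim_truth(config),
                 truth_climate = sim_truth_climate(config, localities),
                 config = config),
            class = "sim_world")
}

#' @export
print.sim_world <- function(x, ...) {
  cat(sprintf("Synthetic world: %d lineages, %d specimens, %d SNP loci, %d bp mtDNA (%s climate)\n",
              x$config$n_pops, length(x$truth), x$config$n_snp_loci,
              x$config$mtdna_length, x$config$climate_scenario))
  invisible(x)
}

#' Write a simulated world's tables to a directory
#'
#' @param world a \code{\link{sim_world}} result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_sim_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(world$alignment, file.path(dir, "mtdna.fasta"))
  g <- world$snps$genotypes
  df <- data.frame(sample_id = rownames(g), g, check.names = FALSE)
  utils::write.table(df, file.path(dir, "snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(world$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  utils::write.csv(world$localities, file.path(dir, "localities.csv"),
                   row.names = FALSE)
  utils::write.csv(world$climate, file.path(dir, "climate.csv"),
                   row.names = FALSE)
  truth <- data.frame(specimen_id = names(world$truth),
                      lineage = as.integer(world$truth),
                      climate_region = as.integer(
                        world$truth_climate[names(world$truth)]))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
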