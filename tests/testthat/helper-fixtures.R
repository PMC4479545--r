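# Shared fixture builders. All data are generated in code; temporary files
# live under tempdir().

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

fasta_tmp <- function(ids, seqs) {
  write_lines_tmp(as.vector(rbind(paste0(">", ids), seqs)), ".fasta")
}

# a valid trait table data.frame with n specimens
make_trait_df <- function(n = 20, seed = 1) {
  set.seed(seed)
  df <- data.frame(specimen_id = sprintf("t%02d", seq_len(n)),
                   sex = sample(c("M", "F"), n, TRUE),
                   ontogeny = sample(c("adult", "subadult"), n, TRUE),
                   body_length = runif(n, 400, 1000))
  for (j in 1:18) df[[sprintf("M%02d", j)]] <- rpois(n, 20)
  for (j in 1:9) df[[sprintf("L%02d", j)]] <- df$body_length * runif(n, 0.02, 0.06)
  df
}

make_climate_df <- function(n = 15, seed = 1) {
  set.seed(seed)
  df <- data.frame(specimen_id = sprintf("c%02d", seq_len(n)))
  for (j in 1:11) df[[sprintf("bio%02d", j)]] <- rnorm(n, 20, 3)
  for (j in 12:19) df[[sprintf("bio%02d", j)]] <- rexp(n, 1 / 50)
  df
}

make_locality_df <- function(n = 15, seed = 1, lon = c(-116, -110),
                             lat = c(28, 32)) {
  set.seed(seed)
  data.frame(specimen_id = sprintf("c%02d", seq_len(n)),
             lon = runif(n, lon[1], lon[2]),
             lat = runif(n, lat[1], lat[2]))
}

csv_tmp <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

# the deeply diverged quartet configuration used for D-statistic
# calibration: single-individual representatives, 5000 loci, no missingness
d_quartet_config <- function(seed, gamma = 0, n_snp_loci = 5000) {
  adm <- if (gamma > 0) {
    data.frame(donor = "pop3", recipient = "pop2", gamma = gamma)
  } else NULL
  sim_config(n_pops = 4,
             tree = "(((pop1:0.5,pop2:0.5):0.5,pop3:0.7):0.3,pop4:0.8);",
             n_per_pop = 1, n_snp_loci = n_snp_loci, missing_rate = 0,
             admixture = adm, seed = seed)
}

d_quartet <- c(P1 = "pop1_01", P2 = "pop2_01", P3 = "pop3_01", O = "pop4_01")

# three well-separated spherical blobs (delta/sigma = 10) in 2D
make_blobs <- function(n_per = 50, centers = rbind(c(0, 0), c(10, 0), c(5, 9)),
                       sigma = 1, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
    cbind(rnorm(n_per, centers[k, 1], sigma),
          rnorm(n_per, centers[k, 2], sigma))
  }))
  list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
}
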