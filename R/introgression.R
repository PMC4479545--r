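# Four-taxon ABBA-BABA tests of introgression: Patterson's D from single-
# individual representatives of (P1, P2, P3, Outgroup), block-jackknife
# standard errors in locus order, and the battery runner that mirrors a
# table of quartets.

#' ABBA and BABA site weights from derived-allele frequencies
#'
#' With derived-allele frequencies \code{p1..p4} for (P1, P2, P3, O):
#' \code{abba = (1-p1) p2 p3 (1-p4)} and \code{baba = p1 (1-p2) p3 (1-p4)}.
#'
#' @param p1,p2,p3,p4 frequencies in [0,1] (vectorized over sites).
#' @return A list with numeric vectors \code{abba} and \code{baba}.
#' @export
site_weights <- function(p1, p2, p3, p4) {
  for (p in list(p1, p2, p3, p4)) {
    if (any(p < 0 | p > 1, na.rm = TRUE)) {
      cd_stop("frequencies must lie in [0,1]", "domain")
    }
  }
  list(abba = (1 - p1) * p2 * p3 * (1 - p4),
       baba = p1 * (1 - p2) * p3 * (1 - p4))
}

#' Patterson's D for one quartet
#'
#' Sites with a missing genotype in any quartet member, or a heterozygous
#' outgroup, are excluded. The outgroup's major allele is taken as
#' ancestral, so the derived-allele frequency of a genotype code g is
#' g/ploidy after polarization. D = (sum abba - sum baba) /
#' (sum abba + sum baba); when no site is informative, D is returned as an
#' undefined-state result (\code{defined = FALSE}), not an error.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param quartet character vector or list with elements P1, P2, P3, O
#'   naming samples of \code{G}.
#' @return An object of class \code{d_result}: quartet, n_sites_used,
#'   abba_sum, baba_sum, D, defined, and per-site weights (for the
#'   jackknife).
#' @export
patterson_d <- function(G, quartet) {
  stopifnot(inherits(G, "genotype_matrix"))
  q <- unlist(quartet)[c("P1", "P2", "P3", "O")]
  if (any(is.na(q))) {
    q <- unlist(quartet)
    if (length(q) != 4) cd_stop("quartet must have 4 members", "argument")
    names(q) <- c("P1", "P2", "P3", "O")
  }
  if (anyDuplicated(q)) cd_stop("quartet members must be distinct", "argument")
  missing_ids <- setdiff(q, G$sample_ids)
  if (length(missing_ids)) {
    cd_stop(sprintf("sample(s) not in genotype matrix: %s",
                    paste(missing_ids, collapse = ", ")), "id")
  }
  g <- G$genotypes[q, , drop = FALSE]
  ploidy <- G$ploidy
  usable <- colSums(is.na(g)) == 0
  # exclude heterozygous outgroup: its major allele is the only ancestral cue
  if (ploidy == 2) usable <- usable & g[4, ] != 1
  g <- g[, usable, drop = FALSE]
  # polarize: outgroup major allele is ancestral; code counts the alternate
  # allele, so flip sites where the outgroup carries the alternate
  flip <- g[4, ] > ploidy / 2
  g[, flip] <- ploidy - g[, flip]
  freq <- g / ploidy
  w <- site_weights(freq[1, ], freq[2, ], freq[3, ], freq[4, ])
  abba_sum <- sum(w$abba); baba_sum <- sum(w$baba)
  defined <- (abba_sum + baba_sum) > 0
  structure(list(quartet = q,
                 n_sites_used = ncol(g),
                 abba_sum = abba_sum, baba_sum = baba_sum,
                 D = if (defined) (abba_sum - baba_sum) / (abba_sum + baba_sum)
                     else NA_real_,
                 defined = defined,
                 site_abba = w$abba, site_baba = w$baba,
                 locus_ids = G$locus_ids[usable]),
            class = "d_result")
}

#' @export
print.d_result <- function(x, ...) {
  cat(sprintf("Patterson's D [%s]: D=%s over %d sites",
              paste(x$quartet, collapse = ","),
              if (x$defined) sprintf("%.4f", x$D) else "undefined",
              x$n_sites_used))
  if (!is.null(x$Z)) cat(sprintf(", Z=%.2f, p=%.3g", x$Z, x$p))
  cat("\n")
  invisible(x)
}

#' Block-jackknife significance for Patterson's D
#'
#' Splits the per-site ABBA/BABA weights into contiguous blocks in locus
#' order, recomputes D with each block deleted, and forms the standard
#' delete-m_j jackknife variance; Z = D/SE and p is two-sided normal. When
#' fewer informative sites than blocks are available the block count is
#' reduced to floor(sites/5) with a warning. A zero jackknife variance
#' yields Z = +/-Inf and p = 0.
#'
#' @param d a \code{\link{patterson_d}} result with per-site weights.
#' @param n_blocks number of contiguous blocks (default 50).
#' @return The \code{d_result} with \code{SE}, \code{Z}, \code{p},
#'   \code{n_blocks} added.
#' @export
block_jackknife <- function(d, n_blocks = 50L) {
  stopifnot(inherits(d, "d_result"))
  if (!d$defined) cd_stop("D undefined: no informative sites", "degenerate")
  S <- length(d$site_abba)
  if (S < n_blocks) {
    n_blocks <- max(2L, S %/% 5L)
    cd_warn(sprintf("fewer sites than blocks; reduced to %d blocks", n_blocks),
            "jackknife")
  }
  block <- ceiling(seq_len(S) / (S / n_blocks))
  block <- pmin(block, n_blocks)
  ab <- tapply(d$site_abba, block, sum)
  bb <- tapply(d$site_baba, block, sum)
  m <- tabulate(block, n_blocks)
  D_full <- d$D
  D_del <- (d$abba_sum - ab - (d$baba_sum - bb)) / (d$abba_sum - ab +
                                                     d$baba_sum - bb)
  # delete-m_j jackknife variance, weighted for unequal block sizes
  h <- S / m
  pseudo <- h * D_full - (h - 1) * D_del
  theta_J <- n_blocks * D_full - sum((1 - m / S) * D_del)
  var_J <- sum((pseudo - theta_J)^2 / (h - 1)) / n_blocks
  SE <- sqrt(var_J)
  Z <- if (SE > 0) D_full / SE else sign(D_full) * Inf
  if (!is.finite(Z) && D_full == 0) Z <- 0
  p <- if (is.finite(Z)) 2 * (1 - stats::pnorm(abs(Z))) else
    (if (Z == 0) 1 else 0)
  d$SE <- SE; d$Z <- Z; d$p <- p; d$n_blocks <- n_blocks
  d
}

#' Run a battery of D-statistic tests
#'
#' One row per quartet, mirroring the usual supplementary-table layout
#' (P1, P2, P3, O, nsites, D, Z, p, significant), with significance flagged
#' at p <= 0.001.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param quartets data.frame with columns P1, P2, P3, O.
#' @param n_blocks jackknife blocks per test.
#' @param alpha significance threshold (default 0.001).
#' @return A data.frame of class \code{d_battery}.
#' @export
test_battery <- function(G, quartets, n_blocks = 50L, alpha = 0.001) {
  need <- c("P1", "P2", "P3", "O")
  if (!all(need %in% colnames(quartets))) {
    cd_stop("quartets must have columns P1, P2, P3, O", "schema")
  }
  rows <- lapply(seq_len(nrow(quartets)), function(i) {
    q <- as.character(unlist(quartets[i, need]))
    names(q) <- need
    d <- patterson_d(G, q)
    if (d$defined) d <- block_jackknife(d, n_blocks = n_blocks)
    data.frame(P1 = q["P1"], P2 = q["P2"], P3 = q["P3"], O = q["O"],
               nsites = d$n_sites_used,
               D = if (d$defined) d$D else NA_real_,
               Z = if (d$defined) d$Z else NA_real_,
               p = if (d$defined) d$p else NA_real_,
               significant = if (d$defined) d$p <= alpha else NA,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("d_battery", "data.frame")
  out
}
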