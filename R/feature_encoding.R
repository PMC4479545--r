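# Conversion of raw inputs into the numeric matrices that feed PCA:
# biallelic-site extraction from alignments, mean imputation of missing
# genotypes, bilateral averaging, allometric size correction, and the
# log-transform of precipitation-type climate variables.

#' Construct a feature matrix
#'
#' A finite numeric matrix (specimens x features) tagged with its data
#' source. Constant columns carry no signal for a correlation-matrix PCA and
#' are dropped with a message.
#'
#' @param values numeric matrix.
#' @param specimen_ids,feature_ids dimension names.
#' @param source one of mtdna, snp, phenotype, climate.
#' @return An object of class \code{feature_matrix}.
#' @export
feature_matrix <- function(values, specimen_ids = rownames(values),
                           feature_ids = colnames(values),
                           source = c("snp", "mtdna", "phenotype", "climate")) {
  source <- match.arg(source)
  values <- as.matrix(values)
  if (is.null(specimen_ids)) specimen_ids <- paste0("s", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(values)))
  if (any(!is.finite(values))) cd_stop("non-finite feature values", "domain")
  keep <- apply(values, 2, function(v) stats::sd(v) > 0)
  if (any(!keep)) {
    message(sprintf("feature_matrix: dropped %d constant column(s)",
                    sum(!keep)))
    values <- values[, keep, drop = FALSE]
    feature_ids <- feature_ids[keep]
  }
  dimnames(values) <- list(as.character(specimen_ids),
                           as.character(feature_ids))
  structure(list(values = values,
                 specimen_ids = as.character(specimen_ids),
                 feature_ids = as.character(feature_ids),
                 source = source),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix (%s): %d specimens x %d features\n",
              x$source, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Extract biallelic variable sites from an alignment
#'
#' Scans every site of the alignment; sites with exactly two distinct
#' unambiguous bases (A/C/G/T) among the observed sequences become haploid
#' 0/1 loci. Gaps, N and IUPAC ambiguity codes are treated as missing.
#' Monomorphic sites and sites with more than two bases are excluded. The
#' majority base is coded 0 (alphabetical tie-break); locus ids record the
#' 1-based site position.
#'
#' @param alignment a \code{\link{seq_alignment}}.
#' @return A \code{\link{genotype_matrix}} with ploidy 1. A zero-locus
#'   matrix (with a warning) if no site is biallelic.
#' @export
extract_snps <- function(alignment) {
  stopifnot(inherits(alignment, "seq_alignment"))
  mat <- do.call(rbind, strsplit(alignment$seqs, ""))
  mat[!(mat %in% c("A", "C", "G", "T"))] <- NA
  keep <- integer(0)
  codes <- list()
  for (s in seq_len(ncol(mat))) {
    col <- mat[, s]
    tab <- table(col[!is.na(col)])
    if (length(tab) != 2L) next
    bases <- names(tab)
    # majority allele coded 0; ties broken alphabetically
    major <- if (tab[1] == tab[2]) bases[1] else bases[which.max(tab)]
    keep <- c(keep, s)
    codes[[length(codes) + 1L]] <- as.integer(col != major)
  }
  if (length(keep) == 0L) {
    cd_warn("alignment has no biallelic variable sites", "empty_matrix")
    g <- matrix(integer(0), nrow = length(alignment$ids), ncol = 0)
    return(genotype_matrix(g, sample_ids = alignment$ids,
                           locus_ids = character(0), ploidy = 1))
  }
  g <- do.call(cbind, codes)
  genotype_matrix(g, sample_ids = alignment$ids,
                  locus_ids = paste0("site", keep), ploidy = 1)
}

#' Replace missing genotypes by locus means
#'
#' Missing cells are replaced by the mean of the observed codes at the same
#' locus; observed cells are untouched. The result is a real-valued feature
#' matrix ready for PCA.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param source provenance tag for the resulting feature matrix.
#' @return A \code{\link{feature_matrix}}.
#' @export
impute_missing <- function(G, source = if (G$ploidy == 1) "mtdna" else "snp") {
  stopifnot(inherits(G, "genotype_matrix"))
  g <- G$genotypes
  storage.mode(g) <- "double"
  all_na <- colSums(!is.na(g)) == 0
  if (any(all_na)) {
    cd_stop(sprintf("locus/loci with no observed genotypes: %s",
                    paste(G$locus_ids[all_na], collapse = ", ")), "column")
  }
  mu <- colMeans(g, na.rm = TRUE)
  idx <- which(is.na(g), arr.ind = TRUE)
  if (nrow(idx)) g[idx] <- mu[idx[, 2]]
  feature_matrix(g, specimen_ids = G$sample_ids, feature_ids = G$locus_ids,
                 source = source)
}

#' Per-sample missing-data fraction
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @return Named numeric vector in [0,1], one entry per sample.
#' @export
missingness_vector <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (ncol(G$genotypes) == 0) {
    return(stats::setNames(rep(0, nrow(G$genotypes)), G$sample_ids))
  }
  stats::setNames(rowMeans(is.na(G$genotypes)), G$sample_ids)
}

#' Average a bilateral count
#'
#' Bilateral scale counts are averaged across sides (half-integers allowed);
#' if one side is missing the observed side is used; both missing gives
#' missing.
#'
#' @param left,right numeric vectors of non-negative counts, \code{NA}
#'   allowed.
#' @return Numeric vector of averaged counts.
#' @export
bilateral_average <- function(left, right) {
  if (any(left < 0, na.rm = TRUE) || any(right < 0, na.rm = TRUE)) {
    cd_stop("counts must be non-negative", "domain")
  }
  out <- (left + right) / 2
  out[is.na(left)] <- right[is.na(left)]
  out[is.na(right)] <- left[is.na(right)]
  out
}

#' Size-correct morphometric traits and assemble the phenotype matrix
#'
#' Each of the 9 morphometric lengths is log10-transformed and regressed by
#' ordinary least squares on log10 body length over all specimens pooled;
#' the residuals replace the raw measurements. Body length itself is
#' excluded from the output, and the 18 meristic columns pass through
#' untransformed, giving 27 phenotype features.
#'
#' @param traits a \code{\link{read_trait_table}} data.frame.
#' @return A \code{\link{feature_matrix}} with source \code{"phenotype"}.
#' @export
size_correct_morphometrics <- function(traits) {
  morpho <- as.matrix(traits[, trait_morpho_cols()])
  meristic <- as.matrix(traits[, trait_meristic_cols()])
  if (any(!is.finite(morpho)) || any(morpho <= 0) ||
      any(!is.finite(traits$body_length)) || any(traits$body_length <= 0)) {
    cd_stop("morphometrics and body length must be positive and observed",
            "domain")
  }
  x <- log10(traits$body_length)
  resid <- apply(morpho, 2, function(y) stats::resid(stats::lm(log10(y) ~ x)))
  out <- cbind(meristic, resid)
  colnames(out) <- c(trait_meristic_cols(), trait_morpho_cols())
  feature_matrix(out, specimen_ids = traits$specimen_id, source = "phenotype")
}

#' Transform climate variables for normality
#'
#' Precipitation-type columns (bio12..bio19) are log10(x+1)-transformed
#' (they are right-skewed and may be exactly zero in deserts);
#' temperature-type columns (bio01..bio11) pass through unchanged.
#'
#' @param climate a \code{\link{read_climate_table}} data.frame.
#' @return A \code{\link{feature_matrix}} with source \code{"climate"}.
#' @export
climate_transform <- function(climate) {
  vals <- as.matrix(climate[, climate_cols()])
  precip <- climate_precipitation_cols()
  if (any(vals[, precip] < 0)) {
    cd_stop("precipitation-type variables must be non-negative", "domain")
  }
  vals[, precip] <- log10(vals[, precip] + 1)
  feature_matrix(vals, specimen_ids = climate$specimen_id, source = "climate")
}
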