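# Readers and writers for the five standard inputs and the partition output.
#
# All tables use the specimen id as the join key; readers validate their
# type's invariants and fail with classed errors so callers (and tests) can
# distinguish a malformed file from a malformed analysis.

IUPAC_OK <- c("A", "C", "G", "T", "N", "-",
              "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
MISSING_TOKENS <- c("NA", "", "-9", "?")

#' Construct a sequence alignment
#'
#' An alignment is a set of equal-length uppercase DNA sequences with unique
#' specimen ids. Gaps (\code{-}), \code{N} and IUPAC ambiguity codes are
#' retained; downstream SNP extraction treats them as missing.
#'
#' @param ids character vector of unique specimen identifiers.
#' @param seqs character vector of sequences, same length as \code{ids}.
#' @return An object of class \code{seq_alignment} with fields \code{ids},
#'   \code{seqs} and \code{length} (alignment length in bp).
#' @export
seq_alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) {
    cd_stop("ids and seqs differ in length", "format")
  }
  if (length(ids) == 0) cd_stop("empty alignment", "format")
  if (anyDuplicated(ids)) {
    cd_stop(sprintf("duplicate specimen id(s): %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
            "id")
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    cd_stop(sprintf("ragged alignment: lengths %s",
                    paste(sort(unique(widths)), collapse = ", ")),
            "alignment")
  }
  if (widths[1] < 1L) cd_stop("zero-length sequences", "alignment")
  bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]),
                 IUPAC_OK)
  if (length(bad)) {
    cd_stop(sprintf("invalid base symbol(s): %s", paste(bad, collapse = " ")),
            "format")
  }
  structure(list(ids = ids, seqs = seqs, length = widths[1]),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("Sequence alignment: %d specimens x %d bp\n",
              length(x$ids), x$length))
  invisible(x)
}

#' Read a FASTA alignment
#'
#' Reads single-line or wrapped FASTA, preserving record order, and validates
#' that all sequences have equal length and ids are unique.
#'
#' @param path path to a FASTA file.
#' @return A \code{\link{seq_alignment}}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) cd_stop(sprintf("file not found: %s", path), "io")
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) cd_stop(sprintf("cannot parse FASTA: %s",
                                        conditionMessage(e)), "format"))
  if (length(set) == 0) cd_stop("empty FASTA file", "format")
  ids <- sub("\\s.*$", "", names(set))
  seq_alignment(ids, as.character(set))
}

#' Write a FASTA alignment
#'
#' @param alignment a \code{\link{seq_alignment}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(alignment, path) {
  stopifnot(inherits(alignment, "seq_alignment"))
  set <- Biostrings::BStringSet(alignment$seqs)
  names(set) <- alignment$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a genotype matrix
#'
#' Integer allele-count codes per sample and locus: 0..ploidy, or \code{NA}
#' for missing. Haploid matrices (ploidy 1) carry mtDNA-derived variants,
#' diploid matrices (ploidy 2) carry SNPs.
#'
#' @param genotypes integer matrix, samples in rows, loci in columns.
#' @param sample_ids,locus_ids row and column identifiers.
#' @param ploidy 1 or 2.
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(genotypes, sample_ids = rownames(genotypes),
                            locus_ids = colnames(genotypes), ploidy = 2) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (!ploidy %in% c(1L, 2L)) cd_stop("ploidy must be 1 or 2", "argument")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(genotypes)))
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(ncol(genotypes)))
  if (anyDuplicated(sample_ids)) cd_stop("duplicate sample ids", "id")
  obs <- genotypes[!is.na(genotypes)]
  if (length(obs) && (min(obs) < 0L || max(obs) > ploidy)) {
    cd_stop(sprintf("genotype codes outside 0..%d", ploidy), "format")
  }
  dimnames(genotypes) <- list(as.character(sample_ids),
                              as.character(locus_ids))
  structure(list(genotypes = genotypes, sample_ids = as.character(sample_ids),
                 locus_ids = as.character(locus_ids),
                 ploidy = as.integer(ploidy)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d samples x %d loci (ploidy %d, %.1f%% missing)\n",
              nrow(x$genotypes), ncol(x$genotypes), x$ploidy,
              100 * mean(is.na(x$genotypes))))
  invisible(x)
}

#' Read a genotype table
#'
#' Two dialects are supported. \code{tsv012}: one row per sample,
#' \code{sample_id} column plus one integer 0/1/2 column per locus.
#' \code{two_row_alleles}: two consecutive rows per sample (one allele per
#' row, arbitrary positive integer allele codes, as produced by common
#' population-genetics pipelines); alleles are recoded to 0/1/2 counts of the
#' minor allele per locus. Missing tokens \code{NA}, empty, \code{-9} and
#' \code{?} all map to missing.
#'
#' @param path path to a tab-separated file with a header row of locus ids.
#' @param dialect \code{"tsv012"} or \code{"two_row_alleles"}.
#' @return A \code{\link{genotype_matrix}} with ploidy 2.
#' @export
read_genotype_table <- function(path, dialect = c("tsv012", "two_row_alleles")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) cd_stop(sprintf("file not found: %s", path), "io")
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL)
  if (nrow(raw) == 0) cd_stop("empty genotype table", "format")
  if (colnames(raw)[1] != "sample_id") {
    cd_stop("first column must be 'sample_id'", "schema")
  }
  locus_ids <- colnames(raw)[-1]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  cells[cells %in% MISSING_TOKENS] <- NA
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  if (any(!is.na(cells) & is.na(num))) cd_stop("non-integer genotype token", "format")
  if (any(num[!is.na(num)] %% 1 != 0)) cd_stop("non-integer genotype value", "format")

  if (dialect == "tsv012") {
    if (length(obs <- num[!is.na(num)]) && (min(obs) < 0 || max(obs) > 2)) {
      cd_stop("tsv012 codes must be 0, 1 or 2", "format")
    }
    return(genotype_matrix(num, sample_ids = raw$sample_id,
                           locus_ids = locus_ids, ploidy = 2))
  }

  # two_row_alleles: consecutive row pairs share a sample id
  if (nrow(num) %% 2 != 0) cd_stop("two_row_alleles needs an even row count", "format")
  first <- seq(1, nrow(num), by = 2)
  if (!all(raw$sample_id[first] == raw$sample_id[first + 1])) {
    cd_stop("allele row pairs must share a sample id", "format")
  }
  a1 <- num[first, , drop = FALSE]
  a2 <- num[first + 1, , drop = FALSE]
  out <- matrix(NA_integer_, nrow = length(first), ncol = ncol(num))
  for (j in seq_len(ncol(num))) {
    al <- c(a1[, j], a2[, j])
    alleles <- sort(unique(al[!is.na(al)]))
    if (length(alleles) > 2) {
      cd_stop(sprintf("locus %s has >2 alleles", locus_ids[j]), "format")
    }
    if (length(alleles) == 0) next
    # count copies of the minor (least frequent; tie -> larger code) allele
    if (length(alleles) == 2) {
      n1 <- sum(al == alleles[1], na.rm = TRUE)
      n2 <- sum(al == alleles[2], na.rm = TRUE)
      minor <- if (n2 <= n1) alleles[2] else alleles[1]
    } else {
      minor <- NA  # monomorphic: all genotypes are 0 copies of a minor allele
    }
    g <- (if (is.na(minor)) 0L else (a1[, j] == minor) + (a2[, j] == minor))
    g[is.na(a1[, j]) | is.na(a2[, j])] <- NA
    out[, j] <- as.integer(g)
  }
  genotype_matrix(out, sample_ids = raw$sample_id[first],
                  locus_ids = locus_ids, ploidy = 2)
}

trait_meristic_cols <- function() sprintf("M%02d", 1:18)
trait_morpho_cols <- function() sprintf("L%02d", 1:9)
climate_cols <- function() sprintf("bio%02d", 1:19)

# temperature-type vs precipitation-type bioclim-style columns
climate_temperature_cols <- function() sprintf("bio%02d", 1:11)
climate_precipitation_cols <- function() sprintf("bio%02d", 12:19)

#' Read a quantitative trait table
#'
#' Expects columns \code{specimen_id}, \code{sex}, \code{ontogeny}
#' (adult/subadult), \code{body_length} (mm), 18 meristic count columns
#' \code{M01..M18} (half-integers allowed, from bilateral averaging) and 9
#' morphometric length columns \code{L01..L09} (mm).
#'
#' @param path path to a CSV file.
#' @return A validated \code{data.frame} of class \code{trait_table}.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) cd_stop(sprintf("file not found: %s", path), "io")
  df <- utils::read.csv(path, check.names = FALSE,
                        na.strings = MISSING_TOKENS)
  need <- c("specimen_id", "sex", "ontogeny", "body_length",
            trait_meristic_cols(), trait_morpho_cols())
  if (!all(need %in% colnames(df))) {
    cd_stop(sprintf("missing column(s): %s",
                    paste(setdiff(need, colnames(df)), collapse = ", ")),
            "schema")
  }
  df <- df[, need]
  validate_trait_table(df)
}

validate_trait_table <- function(df) {
  if (anyDuplicated(df$specimen_id)) cd_stop("duplicate specimen ids", "id")
  if (!all(df$ontogeny %in% c("adult", "subadult"))) {
    cd_stop("ontogeny must be adult or subadult", "bounds")
  }
  if (any(df$body_length <= 0, na.rm = TRUE)) {
    cd_stop("body_length must be positive", "bounds")
  }
  morpho <- as.matrix(df[, trait_morpho_cols()])
  if (any(morpho <= 0, na.rm = TRUE)) {
    cd_stop("morphometric measurements must be positive", "bounds")
  }
  meristic <- as.matrix(df[, trait_meristic_cols()])
  if (any(meristic < 0, na.rm = TRUE)) {
    cd_stop("meristic counts must be non-negative", "bounds")
  }
  df$specimen_id <- as.character(df$specimen_id)
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Read a specimen locality table
#'
#' @param path CSV with columns \code{specimen_id}, \code{lon}, \code{lat}
#'   (WGS84 decimal degrees).
#' @return A validated \code{data.frame} of class \code{locality_table}.
#' @export
read_locality_table <- function(path) {
  if (!file.exists(path)) cd_stop(sprintf("file not found: %s", path), "io")
  df <- utils::read.csv(path, check.names = FALSE, na.strings = MISSING_TOKENS)
  need <- c("specimen_id", "lon", "lat")
  if (!all(need %in% colnames(df))) {
    cd_stop(sprintf("missing column(s): %s",
                    paste(setdiff(need, colnames(df)), collapse = ", ")),
            "schema")
  }
  validate_locality_table(df[, need])
}

validate_locality_table <- function(df) {
  if (anyDuplicated(df$specimen_id)) cd_stop("duplicate specimen ids", "id")
  if (any(is.na(df$lon)) || any(is.na(df$lat))) {
    cd_stop("missing coordinates", "bounds")
  }
  if (any(df$lon < -180 | df$lon > 180)) cd_stop("longitude out of [-180,180]", "bounds")
  if (any(df$lat < -90 | df$lat > 90)) cd_stop("latitude out of [-90,90]", "bounds")
  df$specimen_id <- as.character(df$specimen_id)
  class(df) <- c("locality_table", "data.frame")
  df
}

#' Read a per-specimen climate table
#'
#' Expects \code{specimen_id} plus exactly 19 bioclim-style columns
#' \code{bio01..bio19}: 11 temperature-type variables (\code{bio01..bio11},
#' real-valued) and 8 precipitation-type variables (\code{bio12..bio19},
#' non-negative).
#'
#' @param path CSV path.
#' @return A validated \code{data.frame} of class \code{climate_table}.
#' @export
read_climate_table <- function(path) {
  if (!file.exists(path)) cd_stop(sprintf("file not found: %s", path), "io")
  df <- utils::read.csv(path, check.names = FALSE, na.strings = MISSING_TOKENS)
  if (!"specimen_id" %in% colnames(df)) cd_stop("missing specimen_id", "schema")
  vars <- setdiff(colnames(df), "specimen_id")
  if (length(vars) != 19 || !setequal(vars, climate_cols())) {
    cd_stop(sprintf("expected 19 climate columns bio01..bio19, found %d",
                    length(vars)), "schema")
  }
  validate_climate_table(df[, c("specimen_id", climate_cols())])
}

validate_climate_table <- function(df) {
  if (anyDuplicated(df$specimen_id)) cd_stop("duplicate specimen ids", "id")
  precip <- as.matrix(df[, climate_precipitation_cols()])
  if (any(precip < 0, na.rm = TRUE)) {
    cd_stop("precipitation-type variables must be non-negative", "bounds")
  }
  if (any(is.na(df[, climate_cols()]))) cd_stop("missing climate values", "bounds")
  df$specimen_id <- as.character(df$specimen_id)
  class(df) <- c("climate_table", "data.frame")
  df
}

#' Construct / validate a partition table
#'
#' One row per specimen: the dataset the partition came from, an integer
#' cluster label (contiguous from 1) and a classification uncertainty in
#' [0, 1].
#'
#' @param specimen_id,dataset,cluster,uncertainty column vectors.
#' @return A \code{data.frame} of class \code{partition_table}.
#' @export
partition_table <- function(specimen_id, dataset, cluster, uncertainty) {
  df <- data.frame(specimen_id = as.character(specimen_id),
                   dataset = as.character(dataset),
                   cluster = as.integer(cluster),
                   uncertainty = as.numeric(uncertainty),
                   stringsAsFactors = FALSE)
  ok_tags <- c("mtdna", "snp", "phenotype", "climate", "synthetic")
  if (!all(df$dataset %in% ok_tags)) {
    cd_stop(sprintf("dataset tag must be one of %s",
                    paste(ok_tags, collapse = ", ")), "bounds")
  }
  for (tag in unique(df$dataset)) {
    labs <- sort(unique(df$cluster[df$dataset == tag]))
    if (!identical(labs, seq_along(labs))) {
      cd_stop(sprintf("cluster labels for '%s' must be contiguous from 1", tag),
              "bounds")
    }
  }
  if (any(df$uncertainty < 0 | df$uncertainty > 1)) {
    cd_stop("uncertainty must lie in [0,1]", "bounds")
  }
  class(df) <- c("partition_table", "data.frame")
  df
}

#' Write partition tables to TSV
#'
#' @param partitions a \code{\link{partition_table}} (possibly several
#'   datasets stacked).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_partition <- function(partitions, path) {
  partitions <- partition_table(partitions$specimen_id, partitions$dataset,
                                partitions$cluster, partitions$uncertainty)
  ok <- tryCatch({
    suppressWarnings(utils::write.table(partitions, path, sep = "\t",
                                        quote = FALSE, row.names = FALSE))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) cd_stop(sprintf("cannot write to %s", path), "io")
  invisible(path)
}

#' Read a partition table written by \code{\link{write_partition}}
#'
#' @param path TSV path.
#' @return A \code{\link{partition_table}}.
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) cd_stop(sprintf("file not found: %s", path), "io")
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character",
                                         "integer", "numeric"))
  partition_table(df$specimen_id, df$dataset, df$cluster, df$uncertainty)
}

#' Inner-join tables on specimen id
#'
#' Joins any number of specimen-keyed tables on their shared ids, preserving
#' the id order of the first table and reporting how many ids were dropped.
#'
#' @param ... data.frames with a \code{specimen_id} column.
#' @param quiet suppress the dropped-id message.
#' @return A list of the input tables restricted to the common specimens.
#' @export
join_specimens <- function(..., quiet = FALSE) {
  tabs <- list(...)
  ids <- lapply(tabs, function(t) as.character(t$specimen_id))
  common <- Reduce(intersect, ids)
  if (length(common) == 0) cd_stop("no specimens shared across tables", "join")
  dropped <- length(unique(unlist(ids))) - length(common)
  if (dropped > 0 && !quiet) {
    message(sprintf("join_specimens: dropped %d specimen id(s) not present in all tables",
                    dropped))
  }
  common <- ids[[1]][ids[[1]] %in% common]
  lapply(tabs, function(t) {
    out <- t[match(common, t$specimen_id), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
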