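# Spatial sampling-bias correction for the climatic dataset: overlay a grid
# (default 0.5 arc-minutes) on the extent of the occurrences, keep one
# random specimen per occupied cell, cluster the subsample, and repeat;
# replicates are combined through a co-assignment consensus.

#' Grid specification over the data extent
#'
#' @param localities a locality table (used for the grid origin).
#' @param cell_minutes cell size in arc-minutes (default 0.5).
#' @return A list of class \code{grid_spec}: \code{cell_size} (degrees) and
#'   \code{origin} (min lon, min lat of the extent).
#' @export
grid_spec <- function(localities, cell_minutes = 0.5) {
  if (nrow(localities) == 0) cd_stop("no localities", "argument")
  cell <- cell_minutes / 60
  if (cell <= 0) cd_stop("cell size must be positive", "argument")
  structure(list(cell_size = cell,
                 origin = c(lon_min = min(localities$lon),
                            lat_min = min(localities$lat))),
            class = "grid_spec")
}

#' Assign specimens to grid cells
#'
#' Cell indices are \code{floor((coord - origin) / cell_size)}; a point
#' sitting exactly on a cell boundary goes to the higher-index cell.
#'
#' @param localities a locality table.
#' @param grid a \code{\link{grid_spec}}.
#' @return Character vector of cell ids ("ix:iy"), one per specimen.
#' @export
assign_cells <- function(localities, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  ix <- floor((localities$lon - grid$origin[["lon_min"]]) / grid$cell_size)
  iy <- floor((localities$lat - grid$origin[["lat_min"]]) / grid$cell_size)
  stats::setNames(paste0(ix, ":", iy), localities$specimen_id)
}

#' Thin occurrences to one specimen per occupied grid cell
#'
#' @param localities a locality table.
#' @param grid a \code{\link{grid_spec}}.
#' @param seed integer seed for the within-cell draw.
#' @return Character vector of the retained specimen ids (one per occupied
#'   cell).
#' @export
thin_one_per_cell <- function(localities, grid, seed = 1L) {
  cells <- assign_cells(localities, grid)
  with_seed(seed, {
    # occupants sorted by id, so the draw is invariant to input row order
    picks <- vapply(split(names(cells), cells), function(ids) {
      ids <- sort(ids)
      if (length(ids) == 1) ids else ids[sample.int(length(ids), 1)]
    }, character(1))
  })
  unname(picks[order(match(picks, localities$specimen_id))])
}

#' Consensus clustering of spatially thinned replicates
#'
#' Each replicate thins the occurrences to one specimen per grid cell,
#' clusters the thinned climate scores by \code{\link{model_select}} and
#' classifies the subsample. Replicates are combined through (i) a histogram
#' of selected K, with the modal K (ties toward smaller K) as the consensus
#' cluster count, and (ii) a specimen x specimen co-assignment frequency
#' matrix (frequency of being clustered together among replicates that
#' retained both specimens). The final partition cuts the average-linkage
#' tree of (1 - co-assignment) into modal K groups, so every specimen —
#' thinned out of any given replicate or not — receives a label; per-
#' specimen uncertainty is one minus the mean within-group co-assignment.
#'
#' @param climate_scores numeric matrix or \code{score_set} of climate PCA
#'   scores (all specimens).
#' @param localities locality table, same specimens in the same order.
#' @param grid a \code{\link{grid_spec}}.
#' @param reps number of replicates (default 1000).
#' @param seed master seed; replicate streams are derived by index.
#' @param K_max,families,restarts passed to \code{\link{model_select}}.
#' @return A list of class \code{consensus_result}: \code{k_histogram},
#'   \code{modal_K}, \code{coassignment}, \code{final_partition} (a
#'   \code{\link{partition_table}}), \code{grid}.
#' @export
consensus_cluster <- function(climate_scores, localities, grid = NULL,
                              reps = 1000L, seed = 1L, K_max = 12L,
                              families = GMM_FAMILIES, restarts = 10L) {
  if (reps < 1) cd_stop("reps must be at least 1", "argument")
  X <- if (inherits(climate_scores, "score_set"))
    retained_scores(climate_scores) else as.matrix(climate_scores)
  ids <- as.character(localities$specimen_id)
  if (nrow(X) != length(ids)) {
    cd_stop("scores and localities must describe the same specimens", "join")
  }
  rownames(X) <- ids
  if (is.null(grid)) grid <- grid_spec(localities)

  n <- length(ids)
  together <- matrix(0, n, n, dimnames = list(ids, ids))
  both <- matrix(0, n, n, dimnames = list(ids, ids))
  k_count <- integer(0)
  for (r in seq_len(reps)) {
    rs <- derive_seed(seed, r)
    keep <- thin_one_per_cell(localities, grid, seed = rs)
    Xi <- X[keep, , drop = FALSE]
    sel <- model_select(Xi, K_max = min(K_max, nrow(Xi)),
                        families = families, restarts = restarts,
                        seed = derive_seed(rs, 7L))
    part <- classify(sel$best, Xi, specimen_ids = keep, dataset = "climate")
    kk <- length(unique(part$labels))
    k_count[as.character(kk)] <- (if (is.na(k_count[as.character(kk)])) 0L
                                  else k_count[as.character(kk)]) + 1L
    idx <- match(keep, ids)
    both[idx, idx] <- both[idx, idx] + 1
    same <- outer(part$labels, part$labels, "==")
    together[idx, idx] <- together[idx, idx] + same
  }
  co <- ifelse(both > 0, together / both, 0)
  diag(co) <- 1
  ks <- as.integer(names(k_count))
  modal_K <- min(ks[k_count == max(k_count)])

  hc <- stats::hclust(stats::as.dist(1 - co), method = "average")
  labels <- stats::cutree(hc, k = min(modal_K, n))
  # relabel by descending group size
  sizes <- tabulate(labels)
  order_k <- order(-sizes, seq_along(sizes))
  relabel <- integer(length(sizes)); relabel[order_k] <- seq_along(sizes)
  labels <- relabel[labels]
  unc <- vapply(seq_len(n), function(i) {
    grp <- setdiff(which(labels == labels[i]), i)
    if (length(grp) == 0) 0 else 1 - mean(co[i, grp])
  }, numeric(1))
  unc <- pmin(pmax(unc, 0), 1)

  structure(list(k_histogram = stats::setNames(as.integer(k_count),
                                               names(k_count)),
                 modal_K = modal_K,
                 coassignment = co,
                 final_partition = partition_table(ids, "climate", labels, unc),
                 grid = grid),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus over %d replicates: modal K = %d\n",
              sum(x$k_histogram), x$modal_K))
  print(x$k_histogram)
  invisible(x)
}
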