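# Cross-dataset congruence and the species-delimitation rule: adjusted Rand
# agreement between partitions, geographic contiguity of clusters via a
# pruned Delaunay graph, merging of diffuse (high-uncertainty, range-
# overlapping) cluster pairs, and the >=2-dataset co-assignment rule that
# yields the species hypothesis.

#' Hubert-Arabie adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same specimens:
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param p,q integer label vectors over the same specimens (named vectors
#'   are matched by name; unnamed vectors are matched by position).
#' @return The adjusted Rand index in [-1, 1].
#' @export
adjusted_rand <- function(p, q) {
  if (!is.null(names(p)) && !is.null(names(q))) {
    common <- intersect(names(p), names(q))
    if (length(common) == 0) cd_stop("partitions share no specimens", "join")
    p <- p[common]; q <- q[common]
  }
  if (length(p) != length(q)) {
    cd_stop("partitions must cover the same specimens", "join")
  }
  n <- length(p)
  tab <- table(p, q)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c_ <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  expected <- b * c_ / total
  denom <- (b + c_) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial and identical in structure
  (a - expected) / denom
}

# Delaunay edges over possibly-duplicated coordinates: duplicates collapse
# to one node; returns node edges, node lengths, and specimen -> node map.
delaunay_graph <- function(lon, lat) {
  key <- paste(lon, lat, sep = "_")
  nodes <- !duplicated(key)
  node_id <- match(key, key[nodes])
  ux <- lon[nodes]; uy <- lat[nodes]
  m <- length(ux)
  if (m < 2) {
    return(list(edges = matrix(integer(0), 0, 2), lengths = numeric(0),
                node_id = node_id, n_nodes = m))
  }
  if (m <= 3) {
    edges <- t(utils::combn(m, 2))
  } else {
    edges <- delaunay_edges_cpp(ux, uy)
    if (nrow(edges) == 0) edges <- t(utils::combn(m, 2))  # degenerate geometry
  }
  lens <- sqrt((ux[edges[, 1]] - ux[edges[, 2]])^2 +
               (uy[edges[, 1]] - uy[edges[, 2]])^2)
  list(edges = edges, lengths = lens, node_id = node_id, n_nodes = m)
}

#' Geographic contiguity of a cluster
#'
#' Builds the Delaunay graph over all specimen localities, prunes edges
#' longer than the 95th percentile of Delaunay edge lengths, and measures
#' how connected the cluster's members remain in the induced subgraph:
#' \code{score = 1 - (components - 1) / max(1, members - 1)}; a cluster is
#' flagged contiguous when the score reaches 0.9. Islands therefore count as
#' contiguous with the mainland when their connecting edges are within the
#' pruning length. With fewer than 3 distinct localities the graph is
#' complete (trivially contiguous).
#'
#' @param cluster_members specimen ids in the cluster.
#' @param all_localities locality table for every specimen.
#' @param prune_quantile edge-length quantile above which edges are removed
#'   (default 0.95).
#' @param flag_threshold score at which the contiguity flag is set
#'   (default 0.9).
#' @return A list: \code{flag}, \code{score}, \code{n_components}.
#' @export
contiguity <- function(cluster_members, all_localities,
                       prune_quantile = 0.95, flag_threshold = 0.9) {
  ids <- as.character(all_localities$specimen_id)
  cluster_members <- as.character(cluster_members)
  if (!all(cluster_members %in% ids)) {
    cd_stop("cluster members missing from the locality table", "join")
  }
  g <- delaunay_graph(all_localities$lon, all_localities$lat)
  if (g$n_nodes < 2) {
    return(list(flag = TRUE, score = 1, n_components = 1L))
  }
  cutoff <- stats::quantile(g$lengths, prune_quantile, names = FALSE)
  keep <- g$lengths <= cutoff
  member_nodes <- sort(unique(g$node_id[match(cluster_members, ids)]))
  sub <- g$edges[keep & (g$edges[, 1] %in% member_nodes) &
                   (g$edges[, 2] %in% member_nodes), , drop = FALSE]
  gr <- igraph::graph_from_edgelist(
    matrix(as.character(sub), ncol = 2), directed = FALSE)
  gr <- gr + igraph::vertices(setdiff(as.character(member_nodes),
                                      igraph::V(gr)$name))
  ncomp <- igraph::components(gr)$no
  n_members <- length(cluster_members)
  score <- 1 - (ncomp - 1) / max(1, n_members - 1)
  list(flag = score >= flag_threshold, score = score,
       n_components = as.integer(ncomp))
}

# ---- convex hull helpers (degrees-plane geometry) -------------------------

# shoelace area of a polygon given as a matrix of vertices
polygon_area <- function(P) {
  if (is.null(P) || nrow(P) < 3) return(0)
  x <- P[, 1]; y <- P[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

convex_hull <- function(lon, lat) {
  pts <- unique(cbind(lon, lat))
  if (nrow(pts) < 3) return(pts)
  pts[rev(grDevices::chull(pts)), , drop = FALSE]  # counterclockwise
}

# Sutherland-Hodgman clipping of convex polygon P by convex polygon Q (CCW)
clip_polygon <- function(P, Q) {
  out <- P
  nq <- nrow(Q)
  for (e in seq_len(nq)) {
    if (is.null(out) || nrow(out) == 0) return(NULL)
    A <- Q[e, ]; B <- Q[(e %% nq) + 1, ]
    inside <- function(p) {
      (B[1] - A[1]) * (p[2] - A[2]) - (B[2] - A[2]) * (p[1] - A[1]) >= -1e-12
    }
    inter <- function(p1, p2) {
      d1 <- c(p2[1] - p1[1], p2[2] - p1[2])
      d2 <- c(B[1] - A[1], B[2] - A[2])
      denom <- d1[1] * d2[2] - d1[2] * d2[1]
      t <- ((A[1] - p1[1]) * d2[2] - (A[2] - p1[2]) * d2[1]) / denom
      p1 + t * d1
    }
    res <- list()
    np <- nrow(out)
    for (i in seq_len(np)) {
      cur <- out[i, ]; nxt <- out[(i %% np) + 1, ]
      if (inside(cur)) {
        res[[length(res) + 1]] <- cur
        if (!inside(nxt)) res[[length(res) + 1]] <- inter(cur, nxt)
      } else if (inside(nxt)) {
        res[[length(res) + 1]] <- inter(cur, nxt)
      }
    }
    out <- if (length(res)) do.call(rbind, res) else NULL
  }
  out
}

# fraction of the smaller hull's area overlapped by the other hull
hull_overlap_fraction <- function(lon1, lat1, lon2, lat2) {
  H1 <- convex_hull(lon1, lat1)
  H2 <- convex_hull(lon2, lat2)
  a1 <- polygon_area(H1); a2 <- polygon_area(H2)
  if (a1 == 0 || a2 == 0) {
    # degenerate hull: overlap if bounding boxes intersect
    bb <- function(l, t) c(min(l), max(l), min(t), max(t))
    b1 <- bb(lon1, lat1); b2 <- bb(lon2, lat2)
    hit <- b1[1] <= b2[2] && b2[1] <= b1[2] && b1[3] <= b2[4] && b2[3] <= b1[4]
    return(if (hit) 1 else 0)
  }
  inter <- clip_polygon(H1, H2)
  polygon_area(inter) / min(a1, a2)
}

#' Merge diffuse cluster pairs
#'
#' Two clusters are merged when their members are poorly separated (mean
#' classification uncertainty across both clusters above
#' \code{uncertainty_threshold}) and their geographic ranges overlap
#' (convex-hull overlap above \code{overlap_threshold} of the smaller
#' hull) — the signature of one variable species split in two. Applied to
#' all cluster pairs and iterated to a fixed point; merges are logged.
#'
#' @param partition a \code{\link{classify}} result.
#' @param localities locality table covering the partition's specimens.
#' @param uncertainty_threshold mean-uncertainty trigger (default 0.25).
#' @param overlap_threshold hull-overlap trigger (default 0.2).
#' @return A \code{partition} with possibly fewer clusters; merged pairs are
#'   recorded in \code{$merges}.
#' @export
merge_diffuse_clusters <- function(partition, localities,
                                   uncertainty_threshold = 0.25,
                                   overlap_threshold = 0.2) {
  stopifnot(inherits(partition, "partition"))
  ids <- partition$table$specimen_id
  loc <- localities[match(ids, localities$specimen_id), ]
  if (any(is.na(loc$lon))) cd_stop("localities missing for some specimens", "join")
  labels <- partition$labels
  post <- partition$posterior
  merges <- list()
  repeat {
    ks <- sort(unique(labels))
    if (length(ks) < 2) break
    merged <- FALSE
    for (a in ks) {
      for (b in ks[ks > a]) {
        ia <- labels == a; ib <- labels == b
        unc_pair <- 1 - apply(post[ia | ib, , drop = FALSE], 1, max)
        if (mean(unc_pair) <= uncertainty_threshold) next
        ov <- hull_overlap_fraction(loc$lon[ia], loc$lat[ia],
                                    loc$lon[ib], loc$lat[ib])
        if (ov <= overlap_threshold) next
        # merge b into a: posterior mass combines
        post[, a] <- post[, a] + post[, b]
        post <- post[, -b, drop = FALSE]
        labels[ib] <- a
        labels[labels > b] <- labels[labels > b] - 1L
        merges[[length(merges) + 1]] <- c(a, b)
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  unc <- pmin(pmax(1 - apply(post, 1, max), 0), 1)
  structure(list(labels = labels, posterior = post, uncertainty = unc,
                 table = partition_table(ids, partition$table$dataset[1],
                                         labels, unc),
                 merges = merges),
            class = "partition")
}

#' Delimit species from congruent partitions
#'
#' Implements the conservative rule that species are the most inclusive
#' clusters congruent across two or more independent datasets. Specimens
#' are first joined into a co-assignment graph with an edge wherever at
#' least \code{min_support} datasets place both specimens in the same
#' cluster; connected components form fine-grained cores. Cores are then
#' merged under the most-inclusive rule: whenever one dataset infers a
#' cluster that contains several whole cores and that cluster is consistent
#' (a union of whole clusters) in at least \code{min_support} datasets, the
#' cores it contains become one group. Geographic contiguity is evaluated
#' per group and recorded (groups failing it are flagged, not dissolved).
#'
#' @param partitions a list of two or more \code{\link{partition_table}}s
#'   from intrinsic datasets (inner-joined on specimen id).
#' @param localities locality table used for the contiguity check (optional;
#'   when absent, contiguity is reported as NA).
#' @param min_support datasets that must agree for an edge / a merge
#'   (default 2).
#' @return A list of class \code{species_hypothesis}: \code{groups} (list of
#'   specimen-id vectors), \code{assignments} (data.frame specimen_id /
#'   group / support / contiguous), \code{pairwise_ari} (matrix across
#'   datasets).
#' @export
delimit <- function(partitions, localities = NULL, min_support = 2L) {
  if (length(partitions) < 2) {
    cd_stop("delimitation needs at least two partitions", "argument")
  }
  labsets <- lapply(partitions, function(p) {
    stats::setNames(p$cluster, p$specimen_id)
  })
  common <- Reduce(intersect, lapply(labsets, names))
  if (length(common) < 2) cd_stop("fewer than 2 shared specimens", "join")
  labsets <- lapply(labsets, function(v) v[common])
  n <- length(common)

  support <- matrix(0L, n, n, dimnames = list(common, common))
  for (v in labsets) {
    support <- support + outer(v, v, "==")
  }
  diag(support) <- length(labsets)
  adj <- support >= min_support
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            diag = FALSE)
  comp <- igraph::components(gr)$membership

  # most-inclusive closure: a dataset's cluster that wholly contains several
  # cores, and is a union of whole clusters in >= min_support datasets,
  # merges those cores
  candidates <- list()
  for (v in labsets) {
    candidates <- c(candidates, split(common, v))
  }
  candidates <- unique(lapply(candidates, sort))
  sizes <- vapply(candidates, length, integer(1))
  keys <- vapply(candidates, paste, character(1), collapse = "|")
  candidates <- candidates[order(-sizes, keys)]  # deterministic, large first
  parent <- seq_len(n)  # union-find over specimens (indices in `common`)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (C in candidates) {
    idx <- match(C, common)
    # skip candidates that cut across a core
    cores_in <- unique(comp[idx])
    if (any(comp %in% cores_in & !(seq_len(n) %in% idx))) next
    if (length(cores_in) < 2) next
    # consistency: C is a union of whole clusters in how many datasets?
    consistent <- sum(vapply(labsets, function(v) {
      all(!(v %in% v[idx]) | (common %in% C))
    }, logical(1)))
    if (consistent < min_support) next
    root <- find(idx[1])
    for (i in idx[-1]) parent[find(i)] <- root
  }
  # cores joined by union-find (cores are already connected specimen sets)
  for (cr in unique(comp)) {
    members <- which(comp == cr)
    for (i in members[-1]) parent[find(i)] <- find(members[1])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  first <- tapply(seq_len(n), roots, min)
  relabel <- rank(first, ties.method = "first")
  group <- as.integer(relabel[as.character(roots)])
  groups <- split(common, group)

  grp_support <- vapply(groups, function(g) {
    if (length(g) < 2) return(length(labsets))
    idx <- match(g, common)
    s <- support[idx, idx]
    as.integer(max(s[upper.tri(s)]))
  }, integer(1))
  contig <- rep(NA, length(groups))
  if (!is.null(localities)) {
    contig <- vapply(groups, function(g) {
      contiguity(g, all_localities = localities)$flag
    }, logical(1))
  }

  tags <- vapply(partitions, function(p) p$dataset[1], character(1))
  ari <- matrix(1, length(labsets), length(labsets),
                dimnames = list(tags, tags))
  for (i in seq_along(labsets)) {
    for (j in seq_along(labsets)) {
      if (i < j) {
        ari[i, j] <- ari[j, i] <- adjusted_rand(labsets[[i]], labsets[[j]])
      }
    }
  }

  structure(list(groups = groups,
                 assignments = data.frame(
                   specimen_id = common,
                   group = group,
                   support = grp_support[group],
                   contiguous = contig[group],
                   stringsAsFactors = FALSE),
                 pairwise_ari = ari),
            class = "species_hypothesis")
}

#' @export
print.species_hypothesis <- function(x, ...) {
  cat(sprintf("Species hypothesis: %d groups over %d specimens\n",
              length(x$groups), nrow(x$assignments)))
  sizes <- vapply(x$groups, length, integer(1))
  cat("  group sizes:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}
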