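# UPGMA clustering of the compound similarity matrix ------------------------

#' UPGMA hierarchical clustering of a similarity matrix
#'
#' Distances are `1 - similarity`. Clusters are merged greedily at minimum
#' distance with size-weighted arithmetic-average linkage (UPGMA proper), so
#' the inter-cluster distance always equals the mean of the original leaf
#' distances across the two clusters and merge heights are nondecreasing.
#' Ties are broken deterministically: each cluster is represented by its
#' lexicographically smallest member label, and among equidistant pairs the
#' lexicographically smallest (representative) pair merges first, so the tree
#' does not depend on input order.
#'
#' Implemented here rather than via [stats::hclust()] to pin down the
#' tie-breaking rule; the result is an `hclust`-compatible object (plot it,
#' cut it with [stats::cutree()]).
#'
#' @param sim square symmetric similarity matrix with values in `[0, 1]` and
#'   compound ids as dimnames.
#' @return an object of classes `c("upgma", "hclust")` with the usual
#'   `merge`, `height`, `order`, `labels` components.
#' @export
upgma <- function(sim) {
  if (!is.matrix(sim) || nrow(sim) != ncol(sim))
    stop("upgma: `sim` must be a square matrix", call. = FALSE)
  if (anyNA(sim)) stop("upgma: NA/NaN in similarity matrix", call. = FALSE)
  if (max(abs(sim - t(sim))) > 1e-10)
    stop("upgma: similarity matrix must be symmetric", call. = FALSE)
  n <- nrow(sim)
  if (n < 2L) stop("upgma: need at least 2 compounds", call. = FALSE)
  labels <- rownames(sim) %||% as.character(seq_len(n))
  D <- 1 - sim
  diag(D) <- 0

  # active cluster bookkeeping: id < 0 = leaf (-index), > 0 = merge row
  id <- -seq_len(n)
  size <- rep(1L, n)
  rep_label <- labels
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n))

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    dmin <- Inf
    pick <- NULL
    for (ai in seq_along(idx)) {
      for (bi in seq_along(idx)) {
        if (bi <= ai) next
        a <- idx[ai]; b <- idx[bi]
        dv <- D[a, b]
        if (dv < dmin) {
          dmin <- dv
          pick <- c(a, b)
        } else if (dv == dmin) {
          # lexicographic tie-break on sorted representative labels
          cand <- sort(c(rep_label[a], rep_label[b]))
          cur <- sort(c(rep_label[pick[1]], rep_label[pick[2]]))
          if (cand[1] < cur[1] ||
              (cand[1] == cur[1] && cand[2] < cur[2])) pick <- c(a, b)
        }
      }
    }
    a <- pick[1]; b <- pick[2]
    # smaller representative first, for a deterministic merge matrix
    if (rep_label[b] < rep_label[a]) { tmp <- a; a <- b; b <- tmp }
    merge[step, ] <- c(id[a], id[b])
    height[step] <- dmin
    # UPGMA update: size-weighted average of the two cluster distances
    for (k in idx) {
      if (k == a || k == b) next
      D[a, k] <- D[k, a] <-
        (size[a] * D[a, k] + size[b] * D[b, k]) / (size[a] + size[b])
    }
    size[a] <- size[a] + size[b]
    members[[a]] <- c(members[[a]], members[[b]])
    active[b] <- FALSE
    id[a] <- step
  }

  order <- dendro_order(merge, n)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "upgma",
                 dist.method = "1 - MSWO similarity",
                 call = match.call()),
            class = c("upgma", "hclust"))
}

# leaf ordering by depth-first traversal of the merge matrix
dendro_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(n - 1L)
}

#' Newick export of a UPGMA dendrogram
#'
#' Branch lengths derive from the ultrametric node elevations (merge height /
#' 2, the molecular-clock convention for average-linkage trees); leaves sit
#' at elevation 0. A 2-leaf tree at merge distance `d` becomes
#' `(A:d/2,B:d/2);`.
#'
#' @param dendro an object from [upgma()] (any `hclust`-shaped object).
#' @return a Newick string (terminated by `;`).
#' @export
to_newick <- function(dendro) {
  merge <- dendro$merge
  height <- dendro$height
  labels <- dendro$labels
  elev <- function(node) if (node < 0L) 0 else height[node] / 2
  build <- function(node) {
    if (node < 0L) return(labels[-node])
    h <- elev(node)
    kids <- vapply(merge[node, ], function(child) {
      paste0(build(child), ":", format(h - elev(child), digits = 15))
    }, "")
    paste0("(", paste(kids, collapse = ","), ")")
  }
  paste0(build(nrow(merge)), ";")
}

#' Flat cluster assignment from a dendrogram
#'
#' Thin wrapper over [stats::cutree()].
#'
#' @param dendro an [upgma()] result.
#' @param k number of clusters (or use `h`).
#' @param h cut height on the merge-distance scale.
#' @return named integer vector of cluster memberships.
#' @export
cut_dendrogram <- function(dendro, k = NULL, h = NULL) {
  cutree(dendro, k = k, h = h)
}
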