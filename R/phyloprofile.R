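#' City-block distances between genome TSSR profiles
#'
#' Pairwise L1 (city-block, Manhattan) distances between the raw 9-scalar
#' Genomic-TSSR vectors: `d(i, j) = sum_k |x_ik - x_jk|`.  No
#' standardization or centering is applied -- the ratio values are compared
#' directly.
#'
#' @param table A `tssr_profiles` data frame or a numeric matrix with one
#'   genome per row.
#' @param method Distance, `"cityblock"` (the default used for profile
#'   trees) or `"euclidean"` for exploration.
#' @return A [stats::dist] object labeled by genome id.
#' @export
tssr_dist <- function(table, method = c("cityblock", "euclidean")) {
  method <- match.arg(method)
  m <- if (inherits(table, "tssr_profiles")) profile_matrix(table)
       else as.matrix(table)
  if (nrow(m) < 2L) stop("need at least 2 genome profiles")
  stats::dist(m, method = if (method == "cityblock") "manhattan" else method)
}

#' Agglomerative clustering of genome TSSR profiles
#'
#' Builds the genome profile dendrogram: city-block distances between
#' Genomic-TSSR vectors, agglomerated with complete linkage (inter-cluster
#' distance = maximum member-pair distance), which is monotone, so merge
#' heights never decrease.  Average and single linkage are available for
#' exploration.
#'
#' Rounded published tables produce exact distance ties, so the
#' agglomeration uses a fully deterministic, input-order-invariant tie
#' rule: among all cluster pairs at the minimal distance, the pair whose
#' (alphabetically) smallest member labels sort lowest is merged, and the
#' cluster with the smaller key becomes the left child.  Permuting the
#' input rows therefore never changes the tree.
#'
#' @param x A `tssr_profiles` data frame, a numeric profile matrix, or a
#'   precomputed [stats::dist].
#' @param linkage `"complete"` (default), `"average"` or `"single"`.
#' @param distance Passed to [tssr_dist()] when `x` is not already a dist.
#' @return An object of class `tssr_dendrogram` wrapping the merge tree;
#'   see [smallest_containing_cluster()], [is_monophyletic()],
#'   [to_newick()].
#' @examples
#' tree <- tssr_cluster(tssr_table2())
#' is_monophyletic(tree, grep("^Rickettsia", tree$labels, value = TRUE))
#' @export
tssr_cluster <- function(x, linkage = c("complete", "average", "single"),
                         distance = "cityblock") {
  linkage <- match.arg(linkage)
  d <- if (inherits(x, "dist")) x else tssr_dist(x, method = distance)
  hc <- agglomerate(d, linkage)
  structure(list(merge = hc$merge, height = hc$height, labels = hc$labels,
                 order = hc$order, linkage = linkage,
                 distance = if (inherits(x, "dist")) "precomputed" else distance,
                 hclust = hc),
            class = "tssr_dendrogram")
}

# deterministic agglomerative clustering; returns an hclust-classed object
agglomerate <- function(d, linkage) {
  dm <- as.matrix(d)
  labels <- rownames(dm)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(dm)))
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 items to cluster")
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  id <- -seq_len(n)            # hclust code of each active cluster
  size <- rep(1L, n)
  key <- labels                # alphabetically smallest member label
  D <- dm
  diag(D) <- Inf
  active <- seq_len(n)
  for (step in seq_len(n - 1L)) {
    sub <- D[active, active, drop = FALSE]
    h <- min(sub)
    cand <- which(sub == h, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    # order candidate pairs by their sorted key pair
    k1 <- pmin(key[active[cand[, 1L]]], key[active[cand[, 2L]]])
    k2 <- pmax(key[active[cand[, 1L]]], key[active[cand[, 2L]]])
    pick <- order(k1, k2)[1L]
    i <- active[cand[pick, 1L]]
    j <- active[cand[pick, 2L]]
    if (key[j] < key[i]) { tmp <- i; i <- j; j <- tmp }
    merge[step, ] <- c(id[i], id[j])
    height[step] <- h
    upd <- setdiff(active, c(i, j))
    D[i, upd] <- D[upd, i] <- switch(linkage,
      complete = pmax(D[i, upd], D[j, upd]),
      single = pmin(D[i, upd], D[j, upd]),
      average = (size[i] * D[i, upd] + size[j] * D[j, upd]) /
        (size[i] + size[j]))
    id[i] <- step
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  order_leaves <- function(node) {
    if (node < 0L) return(-node)
    c(order_leaves(merge[node, 1L]), order_leaves(merge[node, 2L]))
  }
  structure(list(merge = merge, height = height,
                 order = order_leaves(n - 1L), labels = labels,
                 method = linkage,
                 dist.method = attr(d, "method"),
                 call = match.call()),
            class = "hclust")
}

#' @export
print.tssr_dendrogram <- function(x, ...) {
  cat(sprintf("TSSR dendrogram: %d leaves, %s linkage, %s distance\n",
              length(x$labels), x$linkage, x$distance))
  cat(sprintf("  merge heights: %.4g .. %.4g\n", min(x$height), max(x$height)))
  invisible(x)
}

#' @export
plot.tssr_dendrogram <- function(x, ...) {
  plot(x$hclust, ...)
  invisible(x)
}

#' @export
as.hclust.tssr_dendrogram <- function(x, ...) x$hclust

# leaf indices (into labels) under a node; node < 0 is leaf -node,
# node > 0 is row 'node' of the merge table
leaf_indices <- function(tree, node) {
  if (node < 0L) return(-node)
  stack <- node
  leaves <- integer(0)
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    if (nd < 0L) leaves <- c(leaves, -nd)
    else stack <- c(stack, tree$merge[nd, 1L], tree$merge[nd, 2L])
  }
  sort(leaves)
}

#' Smallest cluster containing a set of leaves
#'
#' Finds the lowest node of the dendrogram whose leaf set contains every
#' query label (the most recent common cluster).  With a monotone linkage
#' the merges are in non-decreasing height order, so the first merge whose
#' leaf set covers the query is the lowest such node.
#'
#' @param tree A `tssr_dendrogram`.
#' @param leaves Character vector of leaf labels.
#' @return A list with `members` (leaf labels under the node), `size`,
#'   `height` (the node's merge height; 0 for a single leaf) and `node`
#'   (merge row index, or negative leaf index).
#' @export
smallest_containing_cluster <- function(tree, leaves) {
  stopifnot(inherits(tree, "tssr_dendrogram"))
  idx <- match(leaves, tree$labels)
  if (anyNA(idx))
    stop("unknown leaf label(s): ", paste(leaves[is.na(idx)], collapse = ", "))
  idx <- unique(idx)
  if (length(idx) == 1L)
    return(list(members = tree$labels[idx], size = 1L, height = 0,
                node = -idx))
  # grow leaf sets merge by merge; merges are sorted by height
  sets <- vector("list", nrow(tree$merge))
  for (k in seq_len(nrow(tree$merge))) {
    kids <- tree$merge[k, ]
    sets[[k]] <- c(if (kids[1L] < 0L) -kids[1L] else sets[[kids[1L]]],
                   if (kids[2L] < 0L) -kids[2L] else sets[[kids[2L]]])
    if (all(idx %in% sets[[k]]))
      return(list(members = tree$labels[sort(sets[[k]])],
                  size = length(sets[[k]]), height = tree$height[k], node = k))
  }
  stop("internal error: no containing cluster found")  # unreachable
}

#' Is a set of leaves monophyletic in the profile tree?
#'
#' `TRUE` when the smallest cluster containing the group holds exactly the
#' group's leaves and no others.
#'
#' @inheritParams smallest_containing_cluster
#' @param group Character vector of leaf labels.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, group) {
  node <- smallest_containing_cluster(tree, group)
  setequal(node$members, group)
}

#' Export a profile dendrogram as Newick text
#'
#' Writes the merge tree as a rooted ultrametric Newick string.  Each merge
#' at height `h` splits into branches so that the two children sit `h / 2`
#' below it (the usual dendrogram-to-phylogram convention); a 2-leaf tree
#' merged at 0.4 becomes `"(A:0.2,B:0.2);"`.  With `scale = "unit"` all
#' heights are first divided by the root height, so the displayed tree runs
#' from 0 to 1, the customary presentation for these profile trees.
#'
#' @param tree A `tssr_dendrogram`.
#' @param scale `"raw"` (merge distances as-is) or `"unit"` (root height 1).
#' @param file Optional path; when given the Newick text is also written
#'   there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
to_newick <- function(tree, scale = c("raw", "unit"), file = NULL) {
  scale <- match.arg(scale)
  hc <- tree$hclust
  if (scale == "unit") hc$height <- hc$height / max(hc$height)
  txt <- ape::write.tree(ape::as.phylo(hc))
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
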