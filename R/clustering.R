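#' Z-score standardize a descriptor table
#'
#' Centers each numeric column to mean 0 and scales to population standard
#' deviation 1. Constant columns carry no information for Euclidean distances
#' and are dropped with a warning. The transformation parameters are attached
#' as attributes `"center"` and `"scale"`.
#'
#' @param table data.frame or matrix of numeric descriptor columns (an
#'   `identifier` column, if present, becomes row names)
#' @return standardized numeric matrix
#' @export
standardize <- function(table) {
  m <- as_descriptor_matrix(table)
  if (nrow(m) < 2L) stop("standardize requires at least two rows")
  pop_sd <- apply(m, 2L, function(x) sqrt(mean((x - mean(x))^2)))
  constant <- pop_sd == 0
  if (any(constant)) {
    warning(sprintf("dropping constant column(s): %s",
                    paste(colnames(m)[constant], collapse = ", ")))
    m <- m[, !constant, drop = FALSE]
    pop_sd <- pop_sd[!constant]
  }
  ctr <- colMeans(m)
  out <- sweep(sweep(m, 2L, ctr), 2L, pop_sd, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- pop_sd
  out
}

as_descriptor_matrix <- function(table) {
  if (is.matrix(table)) return(table)
  tb <- as.data.frame(table)
  rn <- rownames(tb)
  if ("identifier" %in% names(tb)) {
    rn <- tb$identifier
    tb$identifier <- NULL
  }
  num <- vapply(tb, is.numeric, logical(1L))
  m <- as.matrix(tb[, num, drop = FALSE])
  rownames(m) <- rn
  m
}

#' Euclidean distance matrix between table rows
#'
#' @param table numeric matrix or descriptor data.frame
#' @return symmetric `dist_matrix` with zero diagonal, identifiers as dimnames
#' @export
euclidean_distances <- function(table) {
  m <- as_descriptor_matrix(table)
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    rn <- if (is.null(rownames(m))) as.character(idx[1L]) else rownames(m)[idx[1L]]
    cn <- if (is.null(colnames(m))) as.character(idx[2L]) else colnames(m)[idx[2L]]
    stop(sprintf("missing value at row '%s', column '%s'", rn, cn))
  }
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  class(d) <- c("dist_matrix", class(d))
  d
}

#' Group-average (UPGMA) agglomerative clustering
#'
#' Repeatedly merges the closest pair of clusters; the distance between two
#' clusters is the unweighted mean of all cross-cluster leaf distances, and
#' the merge height is that distance. Ties resolve to the smallest
#' (row, column) index pair in cluster-creation order (leaves first, then
#' merge products), which makes the tree bit-reproducible.
#'
#' @param dist symmetric distance matrix (zero diagonal) with identifiers as
#'   dimnames
#' @return a `cluster_tree`: list with `merges` (data.frame: left, right,
#'   height, size; negative entries are leaves, positive entries earlier
#'   merges, as in [stats::hclust()]), `labels`, and `heights`
#' @export
agglomerate <- function(dist) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 2L) stop("agglomerate requires at least two leaves")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("L", seq_len(n))
  labels <- rownames(d)

  active <- seq_len(n)             # current cluster ids (1..n leaves, then n+k)
  members <- lapply(seq_len(n), identity)
  cur <- d                         # distance matrix over active clusters
  hclust_id <- -seq_len(n)         # hclust-style code of each active cluster
  merges <- data.frame(left = integer(), right = integer(),
                       height = numeric(), size = integer())
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best_i <- best_j <- 0L; best_d <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        if (cur[i, j] < best_d - 1e-12) {
          best_d <- cur[i, j]; best_i <- i; best_j <- j
        }
      }
    }
    sz_i <- length(members[[best_i]]); sz_j <- length(members[[best_j]])
    new_members <- c(members[[best_i]], members[[best_j]])
    # group-average update against every other active cluster
    newd <- numeric(k)
    for (t in seq_len(k)) {
      if (t == best_i || t == best_j) next
      newd[t] <- (sz_i * cur[best_i, t] + sz_j * cur[best_j, t]) / (sz_i + sz_j)
    }
    merges <- rbind(merges, data.frame(
      left = hclust_id[best_i], right = hclust_id[best_j],
      height = best_d, size = length(new_members)
    ))
    keep <- setdiff(seq_len(k), c(best_i, best_j))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], newd[keep]),
                 c(newd[keep], 0))
    members <- c(members[keep], list(new_members))
    hclust_id <- c(hclust_id[keep], step)
    active <- c(active[keep], n + step)
  }
  structure(
    list(merges = merges, labels = labels, heights = merges$height, n = n),
    class = "cluster_tree"
  )
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d leaves, %d merges, heights %.3g .. %.3g\n",
              x$n, nrow(x$merges), min(x$heights), max(x$heights)))
  invisible(x)
}

#' Convert a cluster tree to an hclust object
#'
#' Gives access to the standard toolbox ([stats::cutree()],
#' [stats::cophenetic()], plotting).
#'
#' @param x a `cluster_tree`
#' @param ... unused
#' @return an object of class `hclust`
#' @export
as.hclust.cluster_tree <- function(x, ...) {
  structure(
    list(
      merge = as.matrix(x$merges[, c("left", "right")]),
      height = x$merges$height,
      order = order_for_plot(x),
      labels = x$labels,
      method = "average",
      dist.method = "euclidean"
    ),
    class = "hclust"
  )
}

# leaf order for plotting: left-to-right traversal (same rule as
# heatmap_order)
order_for_plot <- function(tree) {
  match(heatmap_order(tree), tree$labels)
}

# leaves under hclust-style node code (negative = leaf index, positive =
# merge row)
node_leaves <- function(tree, code) {
  if (code < 0L) return(-code)
  c(node_leaves(tree, tree$merges$left[code]),
    node_leaves(tree, tree$merges$right[code]))
}

#' Leaf identifiers of a clade
#'
#' @param tree a `cluster_tree`
#' @param node merge index (1-based, in merge order; the root is the last
#'   merge) or a negative leaf code
#' @return character vector of leaf identifiers in the clade
#' @export
clade_members <- function(tree, node) {
  if (node > nrow(tree$merges) || node == 0L || node < -tree$n) {
    stop(sprintf("unknown node id %d", node))
  }
  tree$labels[sort(node_leaves(tree, node))]
}

#' Are two leaves siblings (sharing their immediate parent)?
#'
#' @param tree a `cluster_tree`
#' @param idA,idB leaf identifiers
#' @return logical
#' @export
are_siblings <- function(tree, idA, idB) {
  ia <- match(idA, tree$labels); ib <- match(idB, tree$labels)
  if (is.na(ia)) stop(sprintf("unknown identifier '%s'", idA))
  if (is.na(ib)) stop(sprintf("unknown identifier '%s'", idB))
  any(
    (tree$merges$left == -ia & tree$merges$right == -ib) |
    (tree$merges$left == -ib & tree$merges$right == -ia)
  )
}

#' Clustroid of a member set
#'
#' The member minimizing the sum of distances to all other members; ties
#' resolve to the lexicographically smallest identifier.
#'
#' @param dist distance matrix with identifiers as dimnames
#' @param members non-empty character vector of identifiers
#' @return the clustroid identifier
#' @export
clustroid <- function(dist, members) {
  if (length(members) == 0L) stop("clustroid of an empty member set")
  d <- as.matrix(dist)
  missing <- setdiff(members, rownames(d))
  if (length(missing) > 0L) {
    stop(sprintf("unknown identifier(s): %s", paste(missing, collapse = ", ")))
  }
  sums <- vapply(members, function(m) sum(d[m, members]), numeric(1L))
  members[order(sums, members)][1L]
}

#' Export a cluster tree as a Newick string
#'
#' Branch lengths are parent height minus child height (leaves sit at height
#' zero); children are ordered by their smallest leaf identifier.
#'
#' @param tree a `cluster_tree`
#' @param digits significant digits for branch lengths
#' @return Newick string terminated by a semicolon
#' @export
newick_export <- function(tree, digits = 6L) {
  fmt <- function(x) format(x, digits = digits, trim = TRUE, scientific = FALSE)
  node_height <- function(code) if (code < 0L) 0 else tree$merges$height[code]
  rec <- function(code, parent_h) {
    if (code < 0L) {
      return(sprintf("%s:%s", tree$labels[-code], fmt(parent_h)))
    }
    h <- tree$merges$height[code]
    kids <- c(tree$merges$left[code], tree$merges$right[code])
    key <- vapply(kids, function(k) min(tree$labels[node_leaves(tree, k)]), "")
    kids <- kids[order(key)]
    inner <- paste(vapply(kids, function(k) rec(k, h - node_height(k)), ""),
                   collapse = ",")
    sprintf("(%s):%s", inner, fmt(parent_h))
  }
  root <- nrow(tree$merges)
  h <- tree$merges$height[root]
  kids <- c(tree$merges$left[root], tree$merges$right[root])
  key <- vapply(kids, function(k) min(tree$labels[node_leaves(tree, k)]), "")
  kids <- kids[order(key)]
  inner <- paste(vapply(kids, function(k) rec(k, h - node_height(k)), ""),
                 collapse = ",")
  sprintf("(%s);", inner)
}

#' Leaf ordering for heatmap display
#'
#' Left-to-right traversal of the tree with children ordered by their
#' smallest leaf identifier.
#'
#' @param tree a `cluster_tree`
#' @return character vector of leaf identifiers
#' @export
heatmap_order <- function(tree) {
  rec <- function(code) {
    if (code < 0L) return(tree$labels[-code])
    kids <- c(tree$merges$left[code], tree$merges$right[code])
    key <- vapply(kids, function(k) min(tree$labels[node_leaves(tree, k)]), "")
    kids <- kids[order(key)]
    unlist(lapply(kids, rec))
  }
  rec(nrow(tree$merges))
}

#' Cophenetic distance matrix of a cluster tree
#'
#' @param tree a `cluster_tree`
#' @return symmetric matrix of merge heights at which leaf pairs first join
#' @export
cophenetic_matrix <- function(tree) {
  n <- tree$n
  m <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  for (k in seq_len(nrow(tree$merges))) {
    left <- node_leaves(tree, tree$merges$left[k])
    right <- node_leaves(tree, tree$merges$right[k])
    m[left, right] <- tree$merges$height[k]
    m[right, left] <- tree$merges$height[k]
  }
  m
}
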