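#' Average-linkage agglomerative clustering on an association matrix
#'
#' Greedy agglomeration working directly on the similarity (HWI) scale:
#' at each step the two clusters with the maximal average pairwise HWI are
#' merged, and the merge height is that average. Average linkage is
#' reducible, so heights are non-increasing along the merge sequence. Ties
#' are broken deterministically: among equal-average pairs, the pair whose
#' lexicographically smallest member id sorts first wins (then the other
#' cluster's smallest id).
#'
#' @param m an \code{association_matrix} (symmetric, >= 2 individuals, no
#'   missing off-diagonal values).
#' @return an object of class \code{alliance_dendrogram}: list with
#'   \code{merge} (hclust-convention matrix: negative entries are leaves,
#'   positive entries earlier merges), \code{height} (average HWI at each
#'   merge), and \code{labels} (individual ids).
#' @export
average_linkage <- function(m) {
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 individuals to cluster")
  vals <- unclass(m); diag(vals) <- NA
  if (any(is.na(vals[upper.tri(vals)])))
    stop("association matrix has missing off-diagonal values")
  labels <- rownames(m)

  sim <- unclass(m)
  size <- rep(1L, n)
  min_id <- labels                 # lexicographically smallest member per cluster
  node <- -seq_len(n)              # hclust code of each active cluster
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (i in which(active)) for (j in which(active)) {
      if (j <= i) next
      s <- sim[i, j]
      cand_key <- sort(c(min_id[i], min_id[j]))
      if (is.null(best) || s > best$s + 1e-12 ||
          (abs(s - best$s) <= 1e-12 &&
           (cand_key[1] < best$key[1] ||
            (cand_key[1] == best$key[1] && cand_key[2] < best$key[2])))) {
        best <- list(i = i, j = j, s = s, key = cand_key)
      }
    }
    i <- best$i; j <- best$j
    # canonical row order: singletons before clusters, then by index
    v <- c(node[i], node[j])
    merge[step, ] <- v[order(v > 0, abs(v))]
    height[step] <- best$s
    # UPGMA update: cluster i absorbs j
    for (k in which(active)) {
      if (k == i || k == j) next
      sim[i, k] <- sim[k, i] <-
        (size[i] * sim[i, k] + size[j] * sim[j, k]) / (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    min_id[i] <- min(min_id[i], min_id[j])
    node[i] <- step
    active[j] <- FALSE
  }

  structure(list(merge = merge, height = height, labels = labels),
            class = "alliance_dendrogram")
}

#' @export
print.alliance_dendrogram <- function(x, ...) {
  cat("Average-linkage dendrogram:", length(x$labels), "individuals;",
      "merge heights (HWI)", sprintf("%.3f", max(x$height)), "down to",
      sprintf("%.3f", min(x$height)), "\n")
  invisible(x)
}

#' Convert to a base hclust object
#'
#' Heights are mapped to the distance scale as \code{1 - HWI} so the object
#' is a valid (monotone non-decreasing) \code{hclust} for plotting, newick
#' export, and interoperation with \pkg{stats}/\pkg{ape}.
#'
#' @param x an \code{alliance_dendrogram}.
#' @param ... unused.
#' @return an object of class \code{hclust}.
#' @export
as.hclust.alliance_dendrogram <- function(x, ...) {
  n <- length(x$labels)
  ord_of <- vector("list", n - 1L)
  leaf_seq <- function(code) if (code < 0) -code else ord_of[[code]]
  for (s in seq_len(n - 1L))
    ord_of[[s]] <- c(leaf_seq(x$merge[s, 1]), leaf_seq(x$merge[s, 2]))
  structure(list(merge = x$merge, height = 1 - x$height,
                 order = ord_of[[n - 1L]], labels = x$labels,
                 method = "average", call = match.call(),
                 dist.method = "1 - HWI"),
            class = "hclust")
}

#' Cophenetic join heights of a dendrogram
#'
#' @param dend an \code{alliance_dendrogram}.
#' @return symmetric matrix of the HWI level at which each dyad is joined.
#' @export
cophenetic_heights <- function(dend) {
  n <- length(dend$labels)
  members <- vector("list", n - 1L)
  leaves <- function(code) if (code < 0) -code else members[[code]]
  H <- matrix(NA_real_, n, n, dimnames = list(dend$labels, dend$labels))
  for (s in seq_len(n - 1L)) {
    a <- leaves(dend$merge[s, 1]); b <- leaves(dend$merge[s, 2])
    H[a, b] <- H[b, a] <- dend$height[s]
    members[[s]] <- c(a, b)
  }
  diag(H) <- NA
  H
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the dyadic association indices and the
#' dendrogram level at which each dyad is joined, computed directly on the
#' similarity scale. A CCC above 0.8 is conventionally taken to mean the
#' hierarchical model represents the social network well.
#'
#' @param dend an \code{alliance_dendrogram}.
#' @param m the \code{association_matrix} it was built from (same ids).
#' @return list with \code{ccc} and \code{good_fit} (\code{ccc > 0.8});
#'   \code{ccc} is \code{NA} with a warning when either vector has zero
#'   variance.
#' @export
cophenetic_correlation <- function(dend, m) {
  if (!identical(sort(dend$labels), sort(rownames(m))))
    stop("dendrogram and matrix cover different individuals")
  H <- cophenetic_heights(dend)[rownames(m), rownames(m)]
  ut <- upper.tri(H)
  a <- unclass(m)[ut]; h <- H[ut]
  if (length(a) < 2L || isTRUE(stats::sd(a) == 0) || is.na(stats::sd(a)) ||
      isTRUE(stats::sd(h) == 0) || is.na(stats::sd(h))) {
    warning("cophenetic correlation undefined: zero variance")
    return(list(ccc = NA_real_, good_fit = NA))
  }
  ccc <- stats::cor(a, h)
  list(ccc = ccc, good_fit = ccc > 0.8)
}

#' Newman modularity of a partition of a weighted association network
#'
#' \deqn{Q = \sum_c [ W_c / W - (S_c / 2W)^2 ]}
#' where \eqn{W} is the total edge weight of the HWI-weighted complete
#' graph (each dyad once; zero dyads contribute nothing), \eqn{W_c} the
#' within-cluster weight and \eqn{S_c} the summed node strengths in cluster
#' \eqn{c}. A single-cluster partition gives \eqn{Q = 0}. The
#' \code{"unweighted"} variant evaluates the same formula on the binarised
#' (HWI > 0) graph.
#'
#' @param m an \code{association_matrix}.
#' @param membership named vector (by individual id) of cluster labels
#'   covering all individuals in \code{m}.
#' @param variant \code{"weighted"} (default) or \code{"unweighted"}.
#' @return the modularity Q (in \eqn{[-0.5, 1)}); \code{NA} with a warning
#'   for an all-zero matrix.
#' @export
modularity_q <- function(m, membership, variant = c("weighted", "unweighted")) {
  variant <- match.arg(variant)
  ids <- rownames(m)
  if (!all(ids %in% names(membership)))
    stop("membership must cover all individuals in the matrix")
  w <- unclass(m)[ids, ids]
  if (variant == "unweighted") w <- (w > 0) + 0
  diag(w) <- 0
  W <- sum(w) / 2
  if (W == 0) {
    warning("modularity undefined for an all-zero matrix")
    return(NA_real_)
  }
  s <- rowSums(w)
  q <- 0
  for (cl in unique(membership[ids])) {
    in_c <- ids[membership[ids] == cl]
    Wc <- sum(w[in_c, in_c]) / 2
    Sc <- sum(s[in_c])
    q <- q + Wc / W - (Sc / (2 * W))^2
  }
  q
}

#' Cut a dendrogram at an association level
#'
#' A cut at level \code{h} groups together every pair of individuals whose
#' cophenetic join height is at least \code{h} (i.e., all merges at height
#' >= \code{h} are applied). \code{h = Inf} yields all singletons;
#' \code{h <=} the smallest merge height yields one cluster. Cluster labels
#' are the lexicographically smallest member id of each cluster.
#'
#' @param dend an \code{alliance_dendrogram}.
#' @param level HWI cut level.
#' @return named character vector mapping individual id to cluster label.
#' @export
cut_dendrogram <- function(dend, level) {
  n <- length(dend$labels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  members <- vector("list", n - 1L)
  roots <- integer(n - 1L)
  leaves <- function(code) if (code < 0) -code else members[[code]]
  for (s in seq_len(n - 1L)) {
    a <- leaves(dend$merge[s, 1]); b <- leaves(dend$merge[s, 2])
    members[[s]] <- c(a, b)
    if (dend$height[s] >= level - 1e-12) {
      ra <- find(a[1]); rb <- find(b[1])
      parent[rb] <- ra
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  lab <- vapply(unique(root), function(r)
    min(dend$labels[root == r]), character(1))
  stats::setNames(lab[match(root, unique(root))], dend$labels)
}

#' Modularity-maximised dendrogram cut with cophenetic validation
#'
#' Evaluates modularity Q at the partition induced by cutting the
#' dendrogram at every distinct merge height (plus the all-singleton cut)
#' and returns the maximising partition. Both the merge height of the
#' maximising cut and the midpoint between it and the next (lower) merge
#' height are reported, since either convention may be used to quote "the
#' HWI level of the cut". Cophenetic correlation of the dendrogram against
#' the matrix is included. Ties in Q are broken towards the higher cut
#' level (fewer merges applied); the result is deterministic.
#'
#' @param dend an \code{alliance_dendrogram}; built from \code{m} if
#'   missing.
#' @param m an \code{association_matrix}.
#' @param variant modularity variant, see [modularity_q()].
#' @return an object of class \code{cluster_diagnostics}: list with
#'   \code{ccc}, \code{ccc_good_fit}, \code{q_by_cut} (data frame
#'   \code{level}, \code{q}, \code{k}), \code{q_max}, \code{cut_at_qmax},
#'   \code{cut_midpoint}, \code{membership} (named vector), \code{clusters}
#'   (list of id vectors), \code{n_communities}.
#' @export
best_partition <- function(m, dend = NULL, variant = c("weighted", "unweighted")) {
  variant <- match.arg(variant)
  if (is.null(dend)) dend <- average_linkage(m)
  levels <- c(sort(unique(dend$height), decreasing = TRUE), Inf)
  rows <- lapply(levels, function(h) {
    memb <- cut_dendrogram(dend, h)
    data.frame(level = h, q = modularity_q(m, memb, variant),
               k = length(unique(memb)))
  })
  q_by_cut <- do.call(rbind, rows)
  # ties towards the higher level: scan from high (finer) to low
  ord <- order(q_by_cut$level, decreasing = TRUE)
  best_row <- ord[which.max(q_by_cut$q[ord])]
  cut_level <- q_by_cut$level[best_row]
  membership <- cut_dendrogram(dend, cut_level)
  below <- dend$height[dend$height < cut_level - 1e-12]
  midpoint <- if (is.infinite(cut_level)) NA_real_
              else if (length(below)) (cut_level + max(below)) / 2
              else cut_level / 2
  clusters <- split(names(membership), membership)
  structure(list(ccc = cophenetic_correlation(dend, m)$ccc,
                 ccc_good_fit = NA,
                 q_by_cut = q_by_cut,
                 q_max = q_by_cut$q[best_row],
                 cut_at_qmax = cut_level,
                 cut_midpoint = midpoint,
                 membership = membership,
                 clusters = clusters,
                 n_communities = length(clusters),
                 variant = variant,
                 dendrogram = dend),
            class = "cluster_diagnostics") -> out
  out$ccc_good_fit <- if (is.na(out$ccc)) NA else out$ccc > 0.8
  out
}

#' @export
print.cluster_diagnostics <- function(x, ...) {
  cat(sprintf("Cluster diagnostics: %d communities, max Q = %.4f at HWI = %.4f (midpoint %.4f), CCC = %.4f\n",
              x$n_communities, x$q_max, x$cut_at_qmax,
              if (is.na(x$cut_midpoint)) NA else x$cut_midpoint, x$ccc))
  for (lab in names(x$clusters))
    cat("  ", lab, ": ", paste(x$clusters[[lab]], collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Write cluster diagnostics as JSON
#'
#' @param diag a \code{cluster_diagnostics}.
#' @param path output path.
#' @export
write_diagnostics_json <- function(diag, path) {
  payload <- list(
    ccc = diag$ccc,
    q_by_cut = unname(apply(diag$q_by_cut[, c("level", "q")], 1, as.list)),
    q_max = diag$q_max,
    cut_at_qmax = diag$cut_at_qmax,
    cut_midpoint = diag$cut_midpoint,
    clusters = diag$clusters)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export the association network as a weighted edge list
#'
#' @param m an \code{association_matrix}.
#' @param path output CSV path (columns \code{id_a,id_b,hwi}).
#' @param min_weight drop dyads at or below this HWI (default 0: keep
#'   positive dyads only).
#' @export
export_edgelist <- function(m, path, min_weight = 0) {
  ids <- rownames(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  df <- data.frame(id_a = ids[ut[, 1]], id_b = ids[ut[, 2]],
                   hwi = unclass(m)[ut])
  df <- df[df$hwi > min_weight, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export the association network as GraphML
#'
#' @param m an \code{association_matrix}.
#' @param path output \code{.graphml} path.
#' @param vertex_attrs optional data frame of per-individual attributes
#'   with an \code{id} column (e.g. alliance, strength values).
#' @export
export_graphml <- function(m, path, vertex_attrs = NULL) {
  g <- igraph::graph_from_adjacency_matrix(unclass(m), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (!is.null(vertex_attrs)) {
    idx <- match(igraph::V(g)$name, vertex_attrs$id)
    for (col in setdiff(names(vertex_attrs), "id"))
      g <- igraph::set_vertex_attr(g, col, value = vertex_attrs[[col]][idx])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a dendrogram in newick format
#'
#' Branch lengths are on the \code{1 - HWI} distance scale (the similarity
#' dendrogram flipped so the tree is ultrametric with non-negative edges).
#'
#' @param dend an \code{alliance_dendrogram}.
#' @param path output newick path.
#' @export
export_newick <- function(dend, path) {
  ape::write.tree(ape::as.phylo(as.hclust(dend)), file = path)
  invisible(path)
}
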