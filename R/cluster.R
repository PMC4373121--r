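# profiles -> sample x bin frequency matrix
.freq_matrix <- function(profiles) {
  if (inherits(profiles, "kmer_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "kmer_profile")))
  sp <- profiles[[1L]]$space
  for (p in profiles)
    if (!.same_space(p$space, sp))
      stop("profiles were counted over different k-mer spaces")
  ids <- vapply(profiles, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ", ids[anyDuplicated(ids)])
  m <- t(vapply(profiles, function(p) kmer_frequencies(p),
                numeric(sp$n_bins)))
  rownames(m) <- ids
  colnames(m) <- sp$bin_label
  m
}

#' Ward hierarchical clustering of k-mer profiles
#'
#' Agglomerative clustering of per-bin frequency vectors by Ward's minimum
#' variance method on Euclidean distances. Genomes with similar
#' tetranucleotide signatures merge at low junction heights.
#'
#' @param profiles list of at least 3 [kmer_profile()]s over one space,
#'   with distinct sample ids.
#' @return A list of class `ward_tree` with `hclust` (the [stats::hclust()]
#'   object) and `merge_heights` (the `n - 1` junction heights, ascending
#'   by Ward monotonicity).
#' @export
ward_cluster <- function(profiles) {
  m <- .freq_matrix(profiles)
  if (nrow(m) < 3L) stop("need at least 3 profiles to cluster")
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "ward.D2")
  structure(list(hclust = hc, merge_heights = hc$height),
            class = "ward_tree")
}

#' @export
print.ward_tree <- function(x, ...) {
  cat(sprintf("Ward tree over %d profiles; junction heights %.4g .. %.4g\n",
              length(x$hclust$labels), min(x$merge_heights),
              max(x$merge_heights)))
  invisible(x)
}

#' Objective cluster count from dendrogram junction heights
#'
#' Finds the largest change between successive junction heights of the
#' dendrogram and cuts below that junction. With `n` items and the maximal
#' gap between the `i`-th and `(i+1)`-th junctions, the cut yields `n - i`
#' clusters. Ties go to the earliest gap (the larger cluster count).
#'
#' @param merge_heights ascending junction heights (at least 2), or a
#'   `ward_tree`.
#' @return The selected number of clusters.
#' @examples
#' select_n_clusters(c(1, 2, 9, 10))  # gap 2 -> 9 selects 3 clusters
#' @export
select_n_clusters <- function(merge_heights) {
  if (inherits(merge_heights, "ward_tree"))
    merge_heights <- merge_heights$merge_heights
  if (!is.numeric(merge_heights) || length(merge_heights) < 2L)
    stop("need at least 2 junction heights")
  gaps <- diff(merge_heights)
  i <- which.max(gaps)             # earliest maximal gap on ties
  n <- length(merge_heights) + 1L  # number of clustered items
  n - i
}

#' K-means validation of a hierarchical clustering
#'
#' Re-clusters the frequency vectors with k-means at a pre-specified cluster
#' count (the count selected from the dendrogram), to check that the
#' partition is reproducible by a non-hierarchical method.
#'
#' @param profiles list of [kmer_profile()]s.
#' @param n_clusters number of clusters (at least 2, at most the number of
#'   profiles).
#' @param seed RNG seed for reproducibility.
#' @param nstart random restarts; the best within-cluster sum of squares is
#'   kept (default 10).
#' @return Integer cluster labels named by sample id.
#' @export
kmeans_validate <- function(profiles, n_clusters, seed = 1L, nstart = 10L) {
  m <- .freq_matrix(profiles)
  n_clusters <- as.integer(n_clusters)
  if (is.na(n_clusters) || n_clusters < 2L)
    stop("n_clusters must be at least 2")
  if (n_clusters > nrow(m))
    stop("n_clusters exceeds the number of profiles")
  # degenerate regimes stats::kmeans rejects: as many clusters as distinct
  # points (or more, for tied profiles) -> each distinct point is its own
  # cluster, the exact within-SS optimum
  key <- apply(m, 1, paste, collapse = "\r")
  if (length(unique(key)) <= n_clusters)
    return(stats::setNames(as.integer(factor(key, levels = unique(key))),
                           rownames(m)))
  set.seed(as.integer(seed))
  km <- stats::kmeans(m, centers = n_clusters, nstart = nstart,
                      iter.max = 100L)
  stats::setNames(km$cluster, rownames(m))
}

# best one-to-one relabelling of b onto a by total agreement; exact over all
# permutations for small label sets, greedy otherwise
.align_labels <- function(a, b) {
  la <- sort(unique(a)); lb <- sort(unique(b))
  if (length(la) != length(lb))
    return(b)  # differing cluster counts: kappa computed on raw labels
  tab <- table(factor(b, levels = lb), factor(a, levels = la))
  nl <- length(lb)
  if (nl <= 8L) {
    perms <- .permutations(nl)
    agree <- apply(perms, 1, function(p) sum(tab[cbind(seq_len(nl), p)]))
    best <- perms[which.max(agree), ]
  } else {
    best <- integer(nl)
    t2 <- tab
    for (i in seq_len(nl)) {
      idx <- which(t2 == max(t2), arr.ind = TRUE)[1L, ]
      best[idx[1L]] <- idx[2L]
      t2[idx[1L], ] <- -1; t2[, idx[2L]] <- -1
    }
  }
  la[best][match(b, lb)]
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Cohen's kappa between two clusterings
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` between two label
#' vectors. Cluster labels are arbitrary, so the labels of `labels_b` are
#' first aligned to `labels_a` by the one-to-one assignment maximizing
#' agreement; two partitions identical up to renaming therefore score 1.
#'
#' @param labels_a,labels_b cluster label vectors of equal length.
#' @param align align labels before computing kappa (default `TRUE`).
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(labels_a, labels_b, align = TRUE) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  n <- length(labels_a)
  if (n == 0L) stop("empty labelings")
  if (align) labels_b <- .align_labels(labels_a, labels_b)
  lev <- sort(unique(c(labels_a, labels_b)))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  po <- mean(a == b)
  pe <- sum(prop.table(table(a)) * prop.table(table(b)))
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Cluster k-mer profiles end to end
#'
#' Ward clustering, objective cluster-count selection from the largest
#' junction-height gap, k-means validation at that count, and Cohen's kappa
#' between the two labelings.
#'
#' @param profiles list of at least 3 [kmer_profile()]s.
#' @param n_clusters override the selected cluster count (default `NULL`:
#'   select from the dendrogram).
#' @param seed seed for the k-means validation.
#' @return An object of class `cluster_result`: list with `tree`
#'   (`ward_tree`), `n_clusters`, `labels_hier`, `labels_kmeans`,
#'   `merge_heights` and `kappa`.
#' @export
cluster_profiles <- function(profiles, n_clusters = NULL, seed = 1L) {
  tree <- ward_cluster(profiles)
  if (is.null(n_clusters)) n_clusters <- select_n_clusters(tree)
  n_clusters <- max(2L, min(as.integer(n_clusters),
                            length(tree$hclust$labels)))
  hier <- stats::cutree(tree$hclust, k = n_clusters)
  km <- kmeans_validate(profiles, n_clusters, seed = seed)
  structure(list(tree = tree, n_clusters = n_clusters,
                 labels_hier = hier, labels_kmeans = km,
                 merge_heights = tree$merge_heights,
                 kappa = cohen_kappa(hier, km)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d profiles, %d clusters, kappa = %.3f\n",
              length(x$labels_hier), x$n_clusters, x$kappa))
  invisible(x)
}

#' Write clustering outputs
#'
#' Dendrogram as Newick (junction heights as branch lengths), labels as TSV
#' (`sample_id`, `hier_label`, `kmeans_label`) and a JSON summary
#' (`n_clusters`, `kappa`).
#'
#' @param result a [cluster_profiles()] result.
#' @param newick_path,labels_path,json_path output files; `NULL` skips.
#' @return Invisibly, the written paths.
#' @export
write_cluster_result <- function(result, newick_path = NULL,
                                 labels_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  if (!is.null(newick_path))
    ape::write.tree(ape::as.phylo(result$tree$hclust), file = newick_path)
  if (!is.null(labels_path))
    utils::write.table(
      data.frame(sample_id = names(result$labels_hier),
                 hier_label = unname(result$labels_hier),
                 kmeans_label = unname(
                   result$labels_kmeans[names(result$labels_hier)])),
      labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(n_clusters = result$n_clusters,
                              kappa = result$kappa),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(newick_path, labels_path, json_path))
}
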