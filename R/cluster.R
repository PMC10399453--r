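#' Euclidean distance between missingness profiles
#'
#' Distance between variables j and k is the Euclidean distance between rows
#' j and k of the pairwise complete-observation count matrix, so variables
#' that co-occur with the rest of the table in the same way are close.
#'
#' @param profile a `"miss_profile"` from [profile_missingness()].
#' @param normalize divide counts by the subject count first, making the
#'   distance scale-invariant (default `FALSE`: raw counts).
#' @return A symmetric P x P matrix with zero diagonal.
#' @export
missingness_distance <- function(profile, normalize = FALSE) {
  pc <- profile$pairwise_complete
  if (normalize) pc <- pc / profile$n_subjects
  d <- as.matrix(stats::dist(pc, method = "euclidean"))
  dimnames(d) <- dimnames(profile$pairwise_complete)
  d
}

#' Average-linkage (UPGMA) agglomerative clustering
#'
#' Begins with each variable in its own cluster and repeatedly merges the
#' two closest clusters, where the inter-cluster distance is the unweighted
#' mean of all cross-pair distances.  Ties are broken by the
#' lexicographically smallest active-cluster index pair, so the result is
#' invariant to relabelling up to label names.
#'
#' @param distance symmetric non-negative distance matrix with zero
#'   diagonal; dimnames supply leaf labels.
#' @return An object of class `"magic_dendrogram"`: `merge` and `height` in
#'   [stats::hclust()] convention plus `labels`.  Convert with
#'   [as.hclust.magic_dendrogram()].
#' @export
upgma <- function(distance) {
  distance <- as.matrix(distance)
  p <- nrow(distance)
  if (p < 2L) stop("need at least 2 leaves")
  if (!isTRUE(all.equal(distance, t(distance), tolerance = 1e-10)))
    stop("distance matrix is not symmetric")
  if (any(distance < 0)) stop("distance matrix has negative entries")
  labels <- rownames(distance)
  if (is.null(labels)) labels <- as.character(seq_len(p))
  D <- distance
  size <- rep(1L, p)
  id <- -seq_len(p)            # hclust convention: negative = leaf
  active <- rep(TRUE, p)
  merge <- matrix(0L, p - 1L, 2L)
  height <- numeric(p - 1L)
  for (step in seq_len(p - 1L)) {
    idx <- which(active)
    Dm <- D[idx, idx, drop = FALSE]
    diag(Dm) <- Inf
    best <- min(Dm)
    # first (row-major over i<j) pair achieving the minimum
    hit <- which(Dm <= best + 0, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- idx[hit[1, 1]]; j <- idx[hit[1, 2]]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- best
    # Lance-Williams update for UPGMA
    ni <- size[i]; nj <- size[j]
    newd <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    D[i, ] <- newd; D[, i] <- newd; D[i, i] <- 0
    active[j] <- FALSE
    size[i] <- ni + nj
    id[i] <- step
  }
  structure(list(merge = merge, height = height, labels = labels),
            class = "magic_dendrogram")
}

#' @export
print.magic_dendrogram <- function(x, ...) {
  cat("UPGMA dendrogram: ", length(x$labels), " leaves, merge heights ",
      signif(min(x$height), 4), " .. ", signif(max(x$height), 4), "\n", sep = "")
  invisible(x)
}

#' Convert to an hclust object
#'
#' @param x a `"magic_dendrogram"`.
#' @param ... unused.
#' @return A `stats::hclust` object (enables `plot()`, `cutree()` etc.).
#' @export
as.hclust.magic_dendrogram <- function(x, ...) {
  # leaf order for plotting: depth-first traversal
  ord <- integer(0)
  walk <- function(node) {
    if (node < 0) ord <<- c(ord, -node)
    else { walk(x$merge[node, 1]); walk(x$merge[node, 2]) }
  }
  walk(nrow(x$merge))
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

# membership vector (named by leaf) from merges strictly below `height`
dendrogram_membership <- function(dend, height) {
  p <- length(dend$labels)
  parent <- seq_len(p)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  node_rep <- integer(nrow(dend$merge))   # leaf representative of each merge
  for (s in seq_len(nrow(dend$merge))) {
    a <- dend$merge[s, 1]; b <- dend$merge[s, 2]
    ra <- if (a < 0) -a else node_rep[a]
    rb <- if (b < 0) -b else node_rep[b]
    ra <- find(ra); rb <- find(rb)
    if (dend$height[s] < height) parent[rb] <- ra
    node_rep[s] <- ra
  }
  roots <- vapply(seq_len(p), find, 1L)
  stats::setNames(match(roots, unique(roots)), dend$labels)
}

#' Cut a dendrogram and report cluster diagnostics
#'
#' Clusters are the connected components of merges strictly below `height`
#' (so height 0 gives all singletons).  Diagnostics per cluster: number of
#' variables, mean observed count, and complete cases over the cluster's
#' variables.  Clusters are numbered by decreasing size.
#'
#' @param dendrogram a `"magic_dendrogram"`.
#' @param height non-negative cut height.
#' @param profile the `"miss_profile"` the distances came from.
#' @param subject_idx optional subject indices over which complete cases are
#'   counted (e.g. the measured set); default all subjects.
#' @return A list of class `"cluster_assignment"`: `cut_height`,
#'   `membership` (named integer vector) and `diagnostics` (data frame).
#' @export
cut_tree <- function(dendrogram, height, profile, subject_idx = NULL) {
  stopifnot(height >= 0)
  mem <- dendrogram_membership(dendrogram, height)
  sizes <- table(mem)
  # renumber: by decreasing size, ties by smallest member index
  first_member <- vapply(as.integer(names(sizes)),
                         function(k) min(which(mem == k)), 1L)
  new_order <- order(-as.integer(sizes), first_member)
  relabel <- stats::setNames(seq_along(new_order),
                             names(sizes)[new_order])
  mem <- stats::setNames(relabel[as.character(mem)], names(mem))
  ind <- profile$indicator[, dendrogram$labels, drop = FALSE]
  if (!is.null(subject_idx)) ind <- ind[subject_idx, , drop = FALSE]
  diags <- do.call(rbind, lapply(sort(unique(mem)), function(k) {
    vars <- names(mem)[mem == k]
    data.frame(cluster = k, n_variables = length(vars),
               mean_observed_count = mean(profile$observed_count[vars]),
               complete_cases = sum(rowSums(!ind[, vars, drop = FALSE]) == 0))
  }))
  structure(list(cut_height = height, membership = mem, diagnostics = diags),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Cut at height ", signif(x$cut_height, 4), ": ",
      nrow(x$diagnostics), " clusters\n", sep = "")
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

#' Tabulate diagnostics across candidate cut heights
#'
#' The cut height is chosen empirically from the per-cluster diagnostics;
#' this evaluates each candidate so the operator (or the automated rule in
#' [choose_cut_height()]) can compare them.
#'
#' @inheritParams cut_tree
#' @param candidate_heights non-empty numeric vector.
#' @return Data frame with one row per candidate: `height`, `n_clusters`,
#'   `n_singletons`, `min/median_complete_cases` over non-singleton
#'   clusters, `n_zero_complete` (clusters with no complete cases).
#' @export
evaluate_cut_heights <- function(dendrogram, profile, candidate_heights,
                                 subject_idx = NULL) {
  stopifnot(length(candidate_heights) >= 1)
  do.call(rbind, lapply(candidate_heights, function(h) {
    cl <- cut_tree(dendrogram, h, profile, subject_idx)
    d <- cl$diagnostics
    ns <- d[d$n_variables > 1L, , drop = FALSE]
    data.frame(height = h,
               n_clusters = nrow(d),
               n_singletons = sum(d$n_variables == 1L),
               min_complete_cases = if (nrow(ns)) min(ns$complete_cases) else NA_integer_,
               median_complete_cases = if (nrow(ns)) median(ns$complete_cases) else NA_real_,
               n_zero_complete = sum(d$complete_cases == 0L))
  }))
}

#' Automated cut-height selection
#'
#' Codifies the empirical choice as a conservative rule: among the candidate
#' heights, pick the smallest at which every non-singleton cluster has at
#' least `max(min_complete, 2 * n_variables)` complete cases.  If no
#' candidate qualifies, fall back to the candidate whose worst non-singleton
#' cluster has the most complete cases (smallest height on ties).
#'
#' @inheritParams evaluate_cut_heights
#' @param min_complete baseline complete-case requirement (default 100).
#' @return The chosen height (scalar).
#' @export
choose_cut_height <- function(dendrogram, profile, candidate_heights,
                              subject_idx = NULL, min_complete = 100) {
  hs <- sort(unique(candidate_heights))
  worst <- rep(-Inf, length(hs)); ok <- logical(length(hs))
  for (i in seq_along(hs)) {
    cl <- cut_tree(dendrogram, hs[i], profile, subject_idx)
    d <- cl$diagnostics
    ns <- d[d$n_variables > 1L, , drop = FALSE]
    if (!nrow(ns)) { ok[i] <- TRUE; worst[i] <- Inf; next }
    ok[i] <- all(ns$complete_cases >= pmax(min_complete, 2L * ns$n_variables))
    worst[i] <- min(ns$complete_cases)
  }
  if (any(ok)) hs[which(ok)[1]] else hs[which.max(worst)]
}

#' Candidate cut heights yielding given cluster counts
#'
#' For each requested cluster count k, returns the midpoint of the height
#' interval that yields exactly k clusters (omitted where tied merge
#' heights make k unattainable).
#'
#' @param dendrogram a `"magic_dendrogram"`.
#' @param k_values integer vector of desired cluster counts.
#' @return Numeric vector of heights, ascending.
#' @export
cut_candidates_for_k <- function(dendrogram, k_values) {
  h <- sort(dendrogram$height)
  p <- length(dendrogram$labels)
  out <- numeric(0)
  for (k in sort(unique(as.integer(k_values)), decreasing = TRUE)) {
    if (k < 1L || k > p) next
    if (k == p) {            # all singletons: no merge strictly below 0
      out <- c(out, if (h[1] > 0) h[1] / 2 else 0)
      next
    }
    lo <- h[p - k]
    hi <- if (k == 1L) h[p - 1] * 1.01 + 1e-9 else h[p - k + 1]
    if (hi > lo) out <- c(out, (lo + hi) / 2)
  }
  sort(unique(out))
}

#' Export a dendrogram as Newick
#'
#' Ultrametric: each leaf sits at depth `height/2` below its parent merge.
#'
#' @param dendrogram a `"magic_dendrogram"`.
#' @param path optional file path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
export_newick <- function(dendrogram, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the 'ape' package is required for Newick export")
  phy <- ape::as.phylo(as.hclust.magic_dendrogram(dendrogram))
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
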