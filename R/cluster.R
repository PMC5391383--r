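# Conformational clustering: superposed CA RMSD, single-linkage clusters at
# a distance cutoff, and medoid ("median structure") extraction.

#' RMSD after optimal superposition
#'
#' Least-squares (Kabsch) rigid-body superposition of two matched point
#' sets -- rotation plus translation, no reflection -- followed by the RMSD
#' of the fitted coordinates. Used on CA subsets throughout the clustering
#' stage; translation and rotation of a free peptide are physically
#' meaningless, so distances are always computed after fitting.
#'
#' @param coords_a,coords_b Matched n x 3 coordinate matrices (n >= 3).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b)) {
    stop("point sets differ in size", call. = FALSE)
  }
  if (nrow(coords_a) < 3) {
    stop("at least 3 points are required for superposition", call. = FALSE)
  }
  a0 <- sweep(coords_a, 2, colMeans(coords_a))
  if (min(svd(a0)$d) < 1e-8) {
    warning("degenerate (collinear) point set; superposition is ill-conditioned")
  }
  kabsch_fit(coords_a, coords_b)$rmsd
}

ca_selection <- function(topology, selection = NULL) {
  idx <- which(topology$name == "CA")
  if (!is.null(selection)) {
    idx <- idx[topology$res_seq[idx] %in% selection]
  }
  if (length(idx) == 0) {
    stop("selection contains no CA atoms of the topology", call. = FALSE)
  }
  idx
}

#' All-vs-all superposed CA RMSD matrix of a trajectory
#'
#' @param traj A `tail_trajectory`.
#' @param selection Residue numbers whose CA atoms enter the RMSD (default:
#'   all residues). Passing `1:15` reproduces the tip re-clustering
#'   selection of the first 15 N-terminal alpha-carbons.
#' @return An n_frames x n_frames symmetric matrix (class `rmsd_matrix`)
#'   with an `atom_selection` attribute describing the subset used.
#' @export
rmsd_matrix <- function(traj, selection = NULL) {
  idx <- ca_selection(traj$topology, selection)
  nf <- n_frames(traj)
  sets <- lapply(seq_len(nf), function(i) traj$coords[i, idx, , drop = TRUE])
  m <- matrix(0, nf, nf)
  if (nf > 1) {
    for (i in seq_len(nf - 1)) {
      for (j in (i + 1):nf) {
        m[i, j] <- m[j, i] <- kabsch_fit(sets[[i]], sets[[j]])$rmsd
      }
    }
  }
  attr(m, "atom_selection") <- sprintf(
    "CA of residues %s (%d atoms)",
    if (is.null(selection)) "all" else paste(range(selection), collapse = "-"),
    length(idx)
  )
  class(m) <- c("rmsd_matrix", class(m))
  m
}

#' Single-linkage clustering of an RMSD matrix at a cutoff
#'
#' Frames are merged whenever any cross-pair RMSD is at most the cutoff --
#' the connected components of the threshold graph (computed through
#' single-linkage agglomeration cut at the cutoff height). Clusters are
#' ranked by descending population, ties broken by lowest member frame
#' index; each cluster's medoid is the member minimising summed RMSD to
#' its cluster (ties again to the lowest frame index).
#'
#' @param m A symmetric distance matrix (e.g. from [rmsd_matrix()]).
#' @param cutoff Linkage cutoff in Angstrom (the trajectory analysis used
#'   13 A for full tails).
#' @return An object of class `tail_clustering`; see [tidy.tail_clustering()].
#' @export
single_linkage <- function(m, cutoff = 13) {
  m <- unclass(m)
  stopifnot(is.matrix(m), nrow(m) == ncol(m), cutoff >= 0)
  if (max(abs(m - t(m))) > 1e-6) stop("distance matrix is not symmetric", call. = FALSE)
  n <- nrow(m)
  if (n == 1) {
    raw <- 1L
  } else {
    hc <- stats::hclust(stats::as.dist(m), method = "single")
    raw <- stats::cutree(hc, h = cutoff)
  }
  # Rank clusters by population (desc), ties by lowest member frame index.
  sizes <- tapply(seq_len(n), raw, length)
  firsts <- tapply(seq_len(n), raw, min)
  ord <- order(-sizes, firsts)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  assignment <- relabel[raw]
  medoid <- vapply(seq_along(ord), function(k) {
    members <- which(assignment == k)
    if (length(members) == 1) {
      return(members)
    }
    sums <- rowSums(m[members, members, drop = FALSE])
    members[which.min(sums)] # which.min takes the first (lowest frame) tie
  }, integer(1))
  structure(
    list(
      assignment = assignment, cutoff = cutoff, medoid = medoid,
      sizes = as.integer(table(assignment))
    ),
    class = "tail_clustering"
  )
}

#' @export
print.tail_clustering <- function(x, ...) {
  cat(
    "<tail_clustering> ", length(x$assignment), " frames in ",
    length(x$sizes), " cluster(s) at cutoff ", x$cutoff, " A\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a clustering into per-frame assignments
#'
#' @param x A `tail_clustering`.
#' @param ... Unused.
#' @return A tibble with columns `frame`, `cluster`, `is_medoid`.
#' @method tidy tail_clustering
#' @export
tidy.tail_clustering <- function(x, ...) {
  tibble::tibble(
    frame = seq_along(x$assignment),
    cluster = x$assignment,
    is_medoid = seq_along(x$assignment) %in% x$medoid
  )
}

#' One-row clustering summary
#'
#' @param x A `tail_clustering`.
#' @param ... Unused.
#' @return A tibble with `n_frames`, `n_clusters`, `cutoff`,
#'   `largest_cluster`.
#' @method glance tail_clustering
#' @export
glance.tail_clustering <- function(x, ...) {
  tibble::tibble(
    n_frames = length(x$assignment),
    n_clusters = length(x$sizes),
    cutoff = x$cutoff,
    largest_cluster = max(x$sizes)
  )
}

#' Representative (medoid) structure of a cluster
#'
#' Materialises the medoid frame of the k-th most populated cluster as a
#' structure, labelled with its frame index and simulation time. The medoid
#' -- the member minimising summed RMSD to its cluster -- stands in for the
#' "median structure"; coordinates are never averaged.
#'
#' @param traj The clustered `tail_trajectory`.
#' @param clustering A `tail_clustering` from [single_linkage()].
#' @param k Cluster rank (1 = most populated).
#' @return An atom tibble of the medoid frame.
#' @export
representative <- function(traj, clustering, k = 1) {
  if (k < 1 || k > length(clustering$sizes)) {
    stop("cluster rank ", k, " out of range (", length(clustering$sizes),
      " clusters)",
      call. = FALSE
    )
  }
  frame_structure(traj, clustering$medoid[k])
}
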