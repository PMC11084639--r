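# Family clustering: bit-score distance matrices, Ward and average-linkage
# hierarchical clustering via the Lance-Williams update with the
# agglomerative coefficient, and the TM-score distance transform.

#' Bit-score distance matrix
#'
#' All-vs-all Smith-Waterman bit scores \eqn{b(i,j)} are converted to the
#' self-normalized distance
#' \eqn{d(i,j) = 1 - b(i,j) / \min(b(i,i), b(j,j))}, clipped to [0, 1].
#' Identical sequences get distance 0; pairs whose bit score is floored at
#' 0 get distance 1.
#'
#' @param seqs list of at least 3 \code{mh_sequence} records.
#' @param scheme an \code{\link{scoring_scheme}}.
#' @param membrane_only logical; restrict each annotated sequence to its
#'   concatenated membrane-segment residues before aligning.
#' @return symmetric distance matrix with zero diagonal, labelled by
#'   sequence ids; the raw bit-score matrix is attached as
#'   \code{attr(, "bits")}.
#' @export
bitscore_distance_matrix <- function(seqs, scheme = scoring_scheme(),
                                     membrane_only = FALSE) {
  stopifnot(length(seqs) >= 3)
  if (membrane_only) {
    seqs <- lapply(seqs, function(s) {
      if (is.null(s$topology)) return(s)
      segs <- membrane_segments(s$topology)
      parts <- vapply(seq_len(nrow(segs)), function(i) {
        substr(s$residues, segs$start[i], segs$end[i])
      }, character(1))
      sequence_record(s$id, paste(parts, collapse = ""), s$description)
    })
  }
  n <- length(seqs)
  ids <- vapply(seqs, function(s) id_of(s), character(1))
  bits <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      b <- smith_waterman(seqs[[i]], seqs[[j]], scheme)$bits
      bits[i, j] <- bits[j, i] <- b
    }
  }
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      denom <- min(bits[i, i], bits[j, j])
      d[i, j] <- if (denom <= 0) 1 else min(max(1 - bits[i, j] / denom, 0), 1)
    }
  }
  attr(d, "bits") <- bits
  d
}

# Agglomerative clustering by the Lance-Williams update. Ward operates on
# squared dissimilarities with merge heights reported on the original scale
# (the "ward.D2" convention); average linkage on the dissimilarities
# themselves.
#' @keywords internal
lance_williams <- function(dm, method = c("ward", "average")) {
  method <- match.arg(method)
  n <- nrow(dm)
  stopifnot(n >= 2, isTRUE(all.equal(dm, t(dm))), all(diag(dm) == 0))
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("L", seq_len(n))
  D <- if (method == "ward") unname(dm)^2 else unname(dm)
  active <- seq_len(n)
  sizes <- rep(1L, n)
  node <- -seq_len(n)            # hclust convention: negatives are leaves
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bv <- Inf
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1):length(active)) {
        v <- D[active[ii], active[jj]]
        if (v < bv) { bv <- v; best <- c(ii, jj) }
      }
    }
    i <- active[best[1]]; j <- active[best[2]]
    height[step] <- if (method == "ward") sqrt(bv) else bv
    a <- node[i]; b <- node[j]
    # hclust layout: leaves before clusters, leaves by label index,
    # clusters by merge step
    merge[step, ] <- c(a, b)[order(c(a, b) >= 0, abs(c(a, b)))]
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- sizes[k]
      D[i, k] <- D[k, i] <- if (method == "ward") {
        ((ni + nk) * D[i, k] + (nj + nk) * D[j, k] - nk * D[i, j]) /
          (ni + nj + nk)
      } else {
        (ni * D[i, k] + nj * D[j, k]) / (ni + nj)
      }
    }
    sizes[i] <- ni + nj
    node[i] <- step
    active <- active[active != j]
  }
  # leaf order for plotting: left-to-right traversal
  order_of <- function(nd) {
    if (nd < 0) return(-nd)
    c(order_of(merge[nd, 1]), order_of(merge[nd, 2]))
  }
  # first-merge height per leaf, for the agglomerative coefficient
  h_first <- numeric(n)
  for (step in seq_len(n - 1)) {
    for (child in merge[step, ]) {
      if (child < 0) h_first[-child] <- height[step]
    }
  }
  h_final <- height[n - 1]
  ac <- if (h_final > 0) mean(1 - h_first / h_final) else 0
  structure(list(merge = merge, height = height, order = order_of(n - 1L),
                 labels = labels, method = method,
                 agglomerative_coefficient = ac),
            class = "mh_dendrogram")
}

#' Ward hierarchical clustering with the agglomerative coefficient
#'
#' Ward linkage computed by the Lance-Williams update on squared
#' dissimilarities (merge heights reported on the input scale). The
#' agglomerative coefficient is the mean over leaves of
#' \eqn{1 - h_{first}(i) / h_{final}}, where \eqn{h_{first}(i)} is the
#' height at which leaf i first merges; values near 1 indicate strong
#' cluster structure, and a star-shaped matrix (all distances equal) gives
#' 0.
#'
#' @param dm symmetric distance matrix with zero diagonal (e.g. from
#'   \code{\link{bitscore_distance_matrix}}).
#' @return an \code{mh_dendrogram}: merge table and heights in
#'   \code{hclust} layout, leaf labels, linkage tag, and
#'   \code{agglomerative_coefficient}.
#' @export
ward_tree <- function(dm) lance_williams(dm, "ward")

#' @export
print.mh_dendrogram <- function(x, ...) {
  cat(sprintf("Dendrogram (%s linkage): %d leaves, AC = %.3f\n",
              x$method, length(x$labels), x$agglomerative_coefficient))
  invisible(x)
}

#' @export
as.hclust.mh_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$method,
                 call = match.call(), dist.method = "user"),
            class = "hclust")
}

#' TM-score distance between two structures
#'
#' The squared complement \eqn{d = (1 - TMscore)^2}: identical folds
#' (TM-score 1) are at distance 0, and the conventional TM-score threshold
#' of 0.8 corresponds to \eqn{d \le 0.04}.
#'
#' @param tm_score TM-score in [0, 1].
#' @return distance in [0, 1].
#' @examples
#' structure_distance(0.8)  # 0.04
#' @export
structure_distance <- function(tm_score) {
  stopifnot(all(tm_score >= 0), all(tm_score <= 1))
  (1 - tm_score)^2
}

#' Average-linkage clusters at a distance cut
#'
#' Builds an average-linkage tree by the Lance-Williams update and cuts it
#' at the given height; with distances from
#' \code{\link{structure_distance}}, a cut of 0.04 groups pairs with
#' TM-score >= 0.8.
#'
#' @param dm symmetric distance matrix with zero diagonal.
#' @param cut cut height (>= 0).
#' @return named integer vector of cluster assignments.
#' @export
average_linkage_clusters <- function(dm, cut) {
  stopifnot(cut >= 0)
  tree <- lance_williams(dm, "average")
  stats::cutree(as.hclust(tree), h = cut)
}
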