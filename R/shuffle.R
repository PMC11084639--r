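# Topology-preserving shuffle null models. Membrane proteins carry strong
# hydrophobic compositional bias in their membrane-spanning segments, so a
# plain composition-preserving shuffle overstates significance. The nulls
# here preserve the amino-acid composition, the topology (segment bounds,
# lengths and order) and the spacing between membrane segments of the
# subject, and only randomize residue order within segment classes.

#' @keywords internal
segment_class_ids <- function(topo, len, per_segment = FALSE) {
  # integer group id per position; membrane positions pooled across segments
  # (TMS and RL together) unless per_segment; loop positions pooled together
  cls <- position_classes(topo, len)
  mem <- cls %in% MEMBRANE_KINDS
  ids <- integer(len)
  if (per_segment) {
    r <- rle(mem)
    seg <- rep(seq_along(r$lengths), r$lengths)
    ids[mem] <- seg[mem]
    ids[!mem] <- 0L
  } else {
    ids[mem] <- 1L
    ids[!mem] <- 0L
  }
  ids
}

#' Topology-preserving shuffle of an annotated sequence
#'
#' Residues from all membrane segments (TMS and reentrant loops, which share
#' the hydrophobic composition) are pooled and randomly redistributed into
#' the same membrane-segment coordinates; loop residues likewise among loop
#' coordinates. Segment boundaries, lengths and order - and hence the
#' distances between membrane segments - are untouched, as are global and
#' per-class composition. With \code{per_segment = TRUE}, membrane residues
#' are instead permuted within each individual segment.
#'
#' @param seq an \code{mh_annotated_sequence}.
#' @param seed integer seed.
#' @param per_segment logical; permute membrane residues within each segment
#'   rather than pooling across segments.
#' @return a shuffled \code{mh_annotated_sequence} with the same topology.
#' @export
shuffle_sequence_topology_preserving <- function(seq, seed, per_segment = FALSE) {
  if (is.null(seq$topology)) stop("sequence has no attached topology")
  ch <- strsplit(seq$residues, "", fixed = TRUE)[[1]]
  ids <- segment_class_ids(seq$topology, length(ch), per_segment)
  with_seed(seed, {
    for (g in unique(ids)) {
      idx <- which(ids == g)
      if (length(idx) > 1) ch[idx] <- ch[sample(idx)]
    }
  })
  annotated_sequence(seq$id, paste(ch, collapse = ""), seq$topology,
                     seq$description)
}

#' Topology-preserving shuffle of an MSA
#'
#' Alignment columns are permuted uniformly within each consensus-topology
#' segment: membrane-segment columns among the columns of the same segment,
#' loop columns within the same loop (uncovered column stretches count as
#' loops). Row order and column count are unchanged.
#'
#' @param m an \code{mh_msa} with a consensus topology in column
#'   coordinates.
#' @param seed integer seed.
#' @return a shuffled \code{mh_msa}.
#' @export
shuffle_msa_topology_preserving <- function(m, seed) {
  stopifnot(inherits(m, "mh_msa"))
  if (is.null(m$topology)) stop("MSA has no attached consensus topology")
  L <- msa_ncol(m)
  cls <- position_classes(m$topology, L)
  mem <- cls %in% MEMBRANE_KINDS
  r <- rle(mem)
  seg <- rep(seq_along(r$lengths), r$lengths)  # every segment its own group
  perm <- seq_len(L)
  with_seed(seed, {
    for (g in unique(seg)) {
      idx <- which(seg == g)
      if (length(idx) > 1) perm[idx] <- idx[sample(length(idx))]
    }
  })
  mat <- do.call(rbind, strsplit(m$rows, "", fixed = TRUE))
  rows <- apply(mat[, perm, drop = FALSE], 1, paste, collapse = "")
  msa(stats::setNames(rows, m$ids), topo = m$topology,
      id = paste0(m$id, "_shuffled"))
}

#' Shuffle-null comparison of two membrane proteins
#'
#' Compares the Smith-Waterman score of query vs subject against a null of
#' topology-preserving shuffles of the subject
#' (\code{\link{shuffle_sequence_topology_preserving}}), fits a GEV to the
#' null scores, and reports the tail p-value of the observed score.
#'
#' @param query,subject \code{mh_annotated_sequence} objects.
#' @param n_shuffles number of shuffles (>= 100; 10000 by default).
#' @param scheme an \code{\link{scoring_scheme}}.
#' @param seed integer seed for the shuffle stream.
#' @param per_segment see
#'   \code{\link{shuffle_sequence_topology_preserving}}.
#' @param keep_null logical; retain the null score vector in the result.
#' @return an object of class \code{mh_shuffle_null}: observed score and
#'   alignment, \code{mh_gev_fit}, shuffle count, GEV p-value, seed.
#' @export
shuffle_null_compare <- function(query, subject, n_shuffles = 10000,
                          scheme = scoring_scheme(), seed = 1,
                          per_segment = FALSE, keep_null = FALSE) {
  if (n_shuffles < 100) stop("n_shuffles must be at least 100")
  if (is.null(subject$topology)) stop("subject has no attached topology")
  observed <- smith_waterman(query, subject, scheme)
  qa <- encode_residues(residues_of(query))
  sb <- encode_residues(residues_of(subject))
  ids <- segment_class_ids(subject$topology, length(sb), per_segment)
  groups <- lapply(unique(ids), function(g) which(ids == g))
  null_scores <- numeric(n_shuffles)
  with_seed(subseed(seed, 1), {
    for (k in seq_len(n_shuffles)) {
      sk <- sb
      for (idx in groups) {
        if (length(idx) > 1) sk[idx] <- sk[sample(idx)]
      }
      null_scores[k] <- .sw_score_ints(qa, sk, scheme$matrix,
                                       scheme$gap_open, scheme$gap_extend)
    }
  })
  fit <- fit_gev(null_scores)
  structure(list(observed = observed$raw, alignment = observed, gev = fit,
                 n_shuffles = as.integer(n_shuffles),
                 p_value = gev_pvalue(observed$raw, fit), seed = seed,
                 null_scores = if (keep_null) null_scores else NULL),
            class = "mh_shuffle_null")
}

#' @export
print.mh_shuffle_null <- function(x, ...) {
  cat(sprintf(paste0("Shuffle null (%d shuffles): observed %.1f, ",
                     "GEV(mu %.2f, sigma %.2f, xi %.3f), p = %.3g\n"),
              x$n_shuffles, x$observed, x$gev$location, x$gev$scale,
              x$gev$shape, x$p_value))
  invisible(x)
}
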