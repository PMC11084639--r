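# Pairwise homology layer: Smith-Waterman local alignment with affine gaps,
# Karlin-Altschul bit scores and pairwise E-values, TMS coverage filtering,
# greedy redundancy reduction, and transitivity-path assembly.

#' @keywords internal
new_local_alignment <- function(query_id, subject_id, q_map, s_map, raw,
                                m, n, scheme) {
  ka <- bitscore_evalue(raw, m, n, scheme)
  empty <- length(q_map) == 0
  qpos <- q_map[!is.na(q_map)]
  spos <- s_map[!is.na(s_map)]
  matches <- if (empty) 0L else sum(!is.na(q_map) & !is.na(s_map))
  ncols <- length(q_map)
  shorter <- min(m, n)
  cov_len <- if (m <= n) length(qpos) else length(spos)
  structure(list(
    query_id = query_id, subject_id = subject_id,
    q_start = if (empty) NA_integer_ else min(qpos),
    q_end = if (empty) NA_integer_ else max(qpos),
    s_start = if (empty) NA_integer_ else min(spos),
    s_end = if (empty) NA_integer_ else max(spos),
    q_map = q_map, s_map = s_map,
    raw = raw, bits = ka$bits, evalue = ka$evalue,
    pident = if (empty) NA_real_ else NA_real_,  # filled by caller
    coverage = if (empty) 0 else cov_len / shorter,
    ncols = ncols, matches = matches, empty = empty),
    class = "mh_local_alignment")
}

#' Smith-Waterman local alignment
#'
#' Optimal local alignment under affine gap penalties (Gotoh recurrences);
#' a gap of length \eqn{k} costs \code{gap_open + k * gap_extend}. \code{X}
#' residues score 0 against everything. Ties are resolved deterministically:
#' the reported optimum ends at the smallest (query, subject) position, and
#' traceback prefers diagonal over up over left.
#'
#' @param a,b query and subject: \code{mh_sequence} records or plain
#'   residue strings.
#' @param scheme an \code{\link{scoring_scheme}}.
#' @return an \code{mh_local_alignment} with the aligned-column mapping
#'   (\code{q_map}/\code{s_map}, \code{NA} marking gaps), raw and bit scores,
#'   pairwise E-value, percent identity and coverage of the shorter
#'   sequence. A raw score of 0 yields an empty alignment flagged
#'   \code{empty = TRUE}.
#' @examples
#' aln <- smith_waterman("MKTAYIAKQR", "MKTAYIAKQR")
#' aln$pident
#' @export
smith_waterman <- function(a, b, scheme = scoring_scheme()) {
  ra <- residues_of(a); rb <- residues_of(b)
  if (nchar(ra) == 0 || nchar(rb) == 0) stop("sequences must be non-empty")
  qa <- encode_residues(ra); qb <- encode_residues(rb)
  res <- .sw_align_ints(qa, qb, scheme$matrix, scheme$gap_open, scheme$gap_extend)
  aln <- new_local_alignment(id_of(a, "query"), id_of(b, "subject"),
                             res$q_map, res$s_map, res$score,
                             length(qa), length(qb), scheme)
  if (!aln$empty) {
    both <- !is.na(res$q_map) & !is.na(res$s_map)
    ach <- strsplit(ra, "")[[1]][res$q_map[both]]
    bch <- strsplit(rb, "")[[1]][res$s_map[both]]
    aln$pident <- 100 * sum(ach == bch) / aln$ncols
    aln$matches <- sum(ach == bch)
  }
  aln
}

#' @export
print.mh_local_alignment <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("%s vs %s: no positive-scoring local alignment\n",
                x$query_id, x$subject_id))
  } else {
    cat(sprintf("%s[%d-%d] vs %s[%d-%d]: raw %g, %.1f bits, E = %.3g, id %.1f%%, cov %.2f\n",
                x$query_id, x$q_start, x$q_end, x$subject_id, x$s_start,
                x$s_end, x$raw, x$bits, x$evalue, x$pident, x$coverage))
  }
  invisible(x)
}

#' Bit score and pairwise E-value from a raw alignment score
#'
#' \eqn{bits = (\lambda \cdot raw - \ln K) / \ln 2} and
#' \eqn{E = K m n e^{-\lambda \cdot raw}}, using the two sequences' lengths
#' (a pairwise search space, not a database size). Negative bit scores are
#' floored at 0 and flagged.
#'
#' @param raw raw score (>= 0).
#' @param m,n query and subject lengths (residues).
#' @param scheme an \code{\link{scoring_scheme}} supplying \eqn{\lambda}
#'   and \eqn{K}.
#' @return list with \code{bits}, \code{evalue}, \code{floored}.
#' @export
bitscore_evalue <- function(raw, m, n, scheme = scoring_scheme()) {
  stopifnot(raw >= 0, m >= 1, n >= 1)
  bits <- (scheme$lambda * raw - log(scheme$K)) / log(2)
  # raw 0 means no positive-scoring alignment exists: floor to 0 bits
  floored <- bits < 0 || raw == 0
  if (floored) bits <- 0
  evalue <- scheme$K * m * n * exp(-scheme$lambda * raw)
  list(bits = bits, evalue = evalue, floored = floored)
}

#' Filter an alignment by transmembrane-segment coverage
#'
#' A membrane segment (TMS or RL) counts as covered when at least half of
#' its residues fall inside the alignment's aligned interval on that side.
#'
#' @param aln an \code{mh_local_alignment}.
#' @param topoA,topoB topologies of query and subject.
#' @param min_tms minimum covered membrane segments required on each side.
#' @return list with \code{accept}, \code{covered_query},
#'   \code{covered_subject}.
#' @export
tms_coverage_filter <- function(aln, topoA, topoB, min_tms = 3) {
  count_covered <- function(topo, pos) {
    segs <- membrane_segments(topo)
    if (nrow(segs) == 0) return(0L)
    sum(vapply(seq_len(nrow(segs)), function(i) {
      len <- segs$end[i] - segs$start[i] + 1
      inside <- sum(pos >= segs$start[i] & pos <= segs$end[i])
      inside >= 0.5 * len
    }, logical(1)))
  }
  if (aln$empty) {
    return(list(accept = FALSE, covered_query = 0L, covered_subject = 0L))
  }
  qpos <- aln$q_map[!is.na(aln$q_map)]
  spos <- aln$s_map[!is.na(aln$s_map)]
  cq <- count_covered(topoA, qpos)
  cs <- count_covered(topoB, spos)
  list(accept = cq >= min_tms && cs >= min_tms,
       covered_query = cq, covered_subject = cs)
}

#' Greedy redundancy reduction
#'
#' Sequences are visited in order of decreasing length; a sequence is dropped
#' when its Smith-Waterman identity (matches / alignment columns) to any
#' already-retained sequence reaches the threshold.
#'
#' @param seqs list of \code{mh_sequence} records.
#' @param identity_threshold fraction in (0, 1].
#' @param scheme an \code{\link{scoring_scheme}}.
#' @return the retained subset, in the greedy visiting order.
#' @export
reduce_redundancy <- function(seqs, identity_threshold = 0.9,
                              scheme = scoring_scheme()) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  ord <- order(-vapply(seqs, function(s) nchar(residues_of(s)), integer(1)))
  retained <- list()
  for (i in ord) {
    dup <- FALSE
    for (r in retained) {
      aln <- smith_waterman(seqs[[i]], r, scheme)
      if (!aln$empty && aln$matches / aln$ncols >= identity_threshold) {
        dup <- TRUE
        break
      }
    }
    if (!dup) retained[[length(retained) + 1]] <- seqs[[i]]
  }
  retained
}

#' Assemble a transitivity path from chained alignments
#'
#' Given alignments A-B, B-C, ... the path supports transitive homology when
#' at every shared protein the two alignments' intervals overlap by at least
#' \code{min_junction_overlap} residues.
#'
#' @param links list of \code{mh_local_alignment}, chained so that each
#'   link's subject id equals the next link's query id.
#' @param min_junction_overlap minimum junction overlap (residues).
#' @return an object of class \code{mh_transitivity_path} with the ordered
#'   protein ids, per-link E-values, per-junction overlaps and the overall
#'   \code{accept} flag.
#' @export
assemble_transitive_path <- function(links, min_junction_overlap = 30) {
  stopifnot(length(links) >= 2)
  ids <- c(links[[1]]$query_id,
           vapply(links, function(l) l$subject_id, character(1)))
  overlaps <- integer(length(links) - 1)
  for (k in seq_len(length(links) - 1)) {
    a <- links[[k]]; b <- links[[k + 1]]
    if (a$subject_id != b$query_id) {
      stop(sprintf("broken chain at junction %d: '%s' vs '%s'",
                   k, a$subject_id, b$query_id))
    }
    ov <- min(a$s_end, b$q_end) - max(a$s_start, b$q_start) + 1
    overlaps[k] <- max(0L, as.integer(ov))
  }
  structure(list(ids = ids, links = links, overlaps = overlaps,
                 evalues = vapply(links, function(l) l$evalue, numeric(1)),
                 min_junction_overlap = min_junction_overlap,
                 accept = all(overlaps >= min_junction_overlap)),
            class = "mh_transitivity_path")
}

#' @export
print.mh_transitivity_path <- function(x, ...) {
  cat(sprintf("Transitivity path %s: %s (junction overlaps %s)\n",
              paste(x$ids, collapse = " -> "),
              if (x$accept) "accepted" else "rejected",
              paste(x$overlaps, collapse = ", ")))
  invisible(x)
}
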