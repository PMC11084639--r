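# Internal repeat detection: cut a family MSA at a designated loop, align
# every sequence of the first half to every sequence of the second half,
# and call repeat support from membrane-segment coverage on both sides.

#' Split an MSA at the loop after a membrane segment
#'
#' Cuts the alignment at the midpoint column of the loop following the
#' \code{after_segment}-th membrane segment of the consensus topology, and
#' degaps each row within each half for subsequent pairwise alignment.
#'
#' @param m an \code{mh_msa} with a consensus topology.
#' @param after_segment index (among membrane segments) of the segment
#'   after which to cut.
#' @return an object of class \code{mh_msa_split}: \code{halfA} /
#'   \code{halfB} (lists of \code{mh_sequence}, rows degapped),
#'   \code{cut_column}, per-row maps from degapped position to original
#'   column (\code{mapA}, \code{mapB}), and the consensus topologies of the
#'   halves in column coordinates (\code{topoA}, \code{topoB}).
#' @export
split_msa_at_loop <- function(m, after_segment) {
  stopifnot(inherits(m, "mh_msa"))
  if (is.null(m$topology)) stop("MSA has no consensus topology")
  L <- msa_ncol(m)
  segs <- membrane_segments(m$topology)
  if (after_segment < 1 || after_segment > nrow(segs)) {
    stop("after_segment (", after_segment, ") exceeds membrane segment count (",
         nrow(segs), ")")
  }
  loop_start <- segs$end[after_segment] + 1L
  loop_end <- if (after_segment < nrow(segs)) segs$start[after_segment + 1] - 1L
              else L
  if (loop_end < loop_start) {
    stop("no loop after membrane segment ", after_segment)
  }
  cut <- loop_start + (loop_end - loop_start) %/% 2L
  half <- function(cols, tag) {
    recs <- list(); maps <- list()
    for (i in seq_along(m$rows)) {
      ch <- strsplit(m$rows[i], "", fixed = TRUE)[[1]][cols]
      keep <- ch != "-"
      if (!any(keep)) next
      recs[[length(recs) + 1]] <-
        sequence_record(paste0(m$ids[i], tag), paste(ch[keep], collapse = ""))
      maps[[length(maps) + 1]] <- cols[keep]
      names(maps)[length(maps)] <- m$ids[i]
    }
    list(recs = recs, maps = maps)
  }
  A <- half(seq_len(cut), "_A")
  B <- half(seq(cut + 1L, L), "_B")
  structure(list(halfA = A$recs, halfB = B$recs, cut_column = cut,
                 mapA = A$maps, mapB = B$maps,
                 topoA = topology_slice(m$topology, 1L, cut),
                 topoB = topology_slice(m$topology, cut + 1L, L),
                 cut_offset = cut),
            class = "mh_msa_split")
}

#' Cross-align the two halves of a split MSA
#'
#' All-vs-all Smith-Waterman between the degapped rows of half A and half
#' B; only alignments with pairwise E-value below \code{evalue_max} are
#' retained.
#'
#' @param split an \code{mh_msa_split}.
#' @param scheme an \code{\link{scoring_scheme}}.
#' @param evalue_max E-value cutoff (default \code{1e-3}).
#' @return list of retained \code{mh_local_alignment} objects; each carries
#'   \code{row_a} / \code{row_b} attributes naming the source rows.
#' @export
cross_align_halves <- function(split, scheme = scoring_scheme(),
                               evalue_max = 1e-3) {
  stopifnot(inherits(split, "mh_msa_split"))
  if (length(split$halfA) == 0 || length(split$halfB) == 0) {
    stop("both halves must be non-empty")
  }
  out <- list()
  for (i in seq_along(split$halfA)) {
    for (j in seq_along(split$halfB)) {
      aln <- smith_waterman(split$halfA[[i]], split$halfB[[j]], scheme)
      if (!aln$empty && aln$evalue < evalue_max) {
        attr(aln, "row_a") <- names(split$mapA)[i]
        attr(aln, "row_b") <- names(split$mapB)[j]
        out[[length(out) + 1]] <- aln
      }
    }
  }
  out
}

#' Call internal-repeat support from cross-half alignments
#'
#' An alignment supports an internal repeat when at least
#' \code{min_segments} membrane segments of the consensus topology are
#' >= 50%-covered by the aligned columns on both halves (the same residue
#' coverage rule as \code{\link{tms_coverage_filter}}, applied in column
#' space through each row's gap structure). Because membrane segments
#' share a hydrophobic composition, unrelated halves can align with small
#' E-values; coverage-passing alignments are therefore verified against
#' the topology-preserving shuffle null (\code{\link{shuffle_null_compare}}) and
#' must reach \code{p_threshold} to count as supported.
#'
#' @param alns alignments from \code{\link{cross_align_halves}}.
#' @param split the \code{mh_msa_split} they came from.
#' @param min_segments minimum covered membrane segments per side.
#' @param verify logical; run the shuffle-null verification.
#' @param n_shuffles,p_threshold shuffle-null verification controls.
#' @param scheme an \code{\link{scoring_scheme}}.
#' @param seed integer seed for the verification shuffles.
#' @return data frame with one row per alignment: \code{row_a},
#'   \code{row_b}, \code{evalue}, \code{covered_a}, \code{covered_b},
#'   \code{shuffle_p}, \code{supported}.
#' @export
call_repeat_support <- function(alns, split, min_segments = 3, verify = TRUE,
                                n_shuffles = 200, p_threshold = 1e-3,
                                scheme = scoring_scheme(), seed = 1) {
  stopifnot(inherits(split, "mh_msa_split"))
  row_topology <- function(maps, id, topo, offset = 0L) {
    cols <- maps[[id]] - offset
    cls <- position_classes(topo, max(max(cols), max(topo$end)))
    segs <- labels_to_segments(cls[cols])
    topology(segs$start, segs$end, segs$kind)
  }
  count_covered <- function(topo, cols, offset = 0L) {
    segs <- membrane_segments(topo)
    if (nrow(segs) == 0) return(0L)
    sum(vapply(seq_len(nrow(segs)), function(i) {
      s <- segs$start[i] + offset; e <- segs$end[i] + offset
      sum(cols >= s & cols <= e) >= 0.5 * (e - s + 1)
    }, logical(1)))
  }
  rows <- lapply(seq_along(alns), function(k) {
    aln <- alns[[k]]
    ra <- attr(aln, "row_a"); rb <- attr(aln, "row_b")
    qpos <- aln$q_map[!is.na(aln$q_map)]
    spos <- aln$s_map[!is.na(aln$s_map)]
    cols_a <- split$mapA[[ra]][qpos]
    cols_b <- split$mapB[[rb]][spos]
    ca <- count_covered(split$topoA, cols_a)
    cb <- count_covered(split$topoB, cols_b, offset = split$cut_offset)
    supported <- ca >= min_segments && cb >= min_segments
    p <- NA_real_
    if (supported && verify) {
      ia <- match(ra, names(split$mapA))
      ib <- match(rb, names(split$mapB))
      q <- split$halfA[[ia]]
      s <- annotated_sequence(split$halfB[[ib]]$id,
                              split$halfB[[ib]]$residues,
                              row_topology(split$mapB, rb, split$topoB,
                                           offset = split$cut_offset))
      p <- shuffle_null_compare(q, s, n_shuffles = n_shuffles, scheme = scheme,
                         seed = subseed(seed, k))$p_value
      supported <- p <= p_threshold
    }
    data.frame(row_a = ra, row_b = rb, evalue = aln$evalue,
               covered_a = ca, covered_b = cb, shuffle_p = p,
               supported = supported, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(row_a = character(0), row_b = character(0),
                      evalue = numeric(0), covered_a = integer(0),
                      covered_b = integer(0), supported = logical(0))
  }
  out
}
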