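# Family-level comparison: per-column frequency profiles with pseudocounts,
# seed-gap injection, profile-profile local alignment with a log-odds
# column score, and the shuffled-MSA GEV null.

#' Build a frequency profile from an MSA
#'
#' Column frequencies are \code{(counts + w * background) / (n + w)} where
#' \code{n} counts the column's non-gap, non-X residues and \code{w} is the
#' pseudocount weight. Columns with gap fraction above 0.3 are flagged (the
#' conventional trimming threshold for poorly aligned columns).
#'
#' @param m an \code{mh_msa}; its consensus topology (if any) supplies
#'   per-column segment labels.
#' @param pseudocount_weight pseudocount mass (dimensionless).
#' @param background background frequencies.
#' @return an object of class \code{mh_profile}: \code{freq} (20 x L),
#'   \code{gap_fraction}, \code{flagged}, \code{labels}, \code{id}.
#' @export
build_profile <- function(m, pseudocount_weight = 1.0,
                          background = RR_BACKGROUND) {
  stopifnot(inherits(m, "mh_msa"), pseudocount_weight >= 0)
  if (length(m$rows) < 5) {
    warning("profile built from fewer than 5 rows; frequencies are noisy")
  }
  L <- msa_ncol(m)
  mat <- do.call(rbind, strsplit(m$rows, "", fixed = TRUE))
  counts <- apply(mat, 2, function(col) {
    tabulate(factor(col, levels = AA20), nbins = 20)
  })
  rownames(counts) <- AA20
  n_eff <- colSums(counts)
  freq <- sweep(counts + pseudocount_weight * background, 2,
                n_eff + pseudocount_weight, "/")
  gap_fraction <- colMeans(mat == "-")
  labels <- if (!is.null(m$topology)) position_classes(m$topology, L) else NULL
  structure(list(freq = freq, gap_fraction = gap_fraction,
                 flagged = gap_fraction > 0.3, labels = labels, id = m$id),
            class = "mh_profile")
}

#' @export
print.mh_profile <- function(x, ...) {
  cat(sprintf("Profile '%s': %d columns (%d flagged for > 30%% gaps)\n",
              x$id, ncol(x$freq), sum(x$flagged)))
  invisible(x)
}

#' Inject seed-pair gaps into two MSAs
#'
#' Given a pairwise alignment between one (degapped) seed row of each MSA,
#' inserts all-gap columns into each MSA so that the two seed rows, read
#' side by side, reproduce the pairwise alignment's gapping - the manual
#' MSA-editing step of profile comparison pipelines, automated.
#'
#' @param msaA,msaB \code{mh_msa} objects.
#' @param seed_aln an \code{mh_local_alignment} whose \code{query_id} names
#'   a row of \code{msaA} and \code{subject_id} a row of \code{msaB}.
#' @return list of the two adjusted \code{mh_msa} objects.
#' @export
inject_seed_gaps <- function(msaA, msaB, seed_aln) {
  locate <- function(m, id) {
    i <- match(id, m$ids)
    if (is.na(i)) stop("seed id '", id, "' not found in MSA '", m$id, "'")
    i
  }
  ia <- locate(msaA, seed_aln$query_id)
  ib <- locate(msaB, seed_aln$subject_id)
  col_of <- function(row) which(strsplit(row, "")[[1]] != "-")
  colsA <- col_of(msaA$rows[ia])  # residue index -> column
  colsB <- col_of(msaB$rows[ib])
  insertions <- function(own_map, cols) {
    # for each alignment column where this side has a gap, insert an all-gap
    # column after the column of the previous own residue (0 = at the front)
    ins <- integer(0)
    last <- if (any(!is.na(own_map))) cols[own_map[which(!is.na(own_map))[1]]] - 1L else 0L
    prev_col <- last
    for (k in seq_along(own_map)) {
      if (is.na(own_map[k])) ins <- c(ins, prev_col)
      else prev_col <- cols[own_map[k]]
    }
    ins
  }
  apply_ins <- function(m, ins) {
    if (length(ins) == 0) return(m)
    L <- msa_ncol(m)
    n_after <- tabulate(ins + 1L, nbins = L + 1L)  # insertions after col 0..L
    rows <- vapply(m$rows, function(row) {
      ch <- strsplit(row, "", fixed = TRUE)[[1]]
      pieces <- character(0)
      if (n_after[1] > 0) pieces <- strrep("-", n_after[1])
      for (j in seq_len(L)) {
        pieces <- c(pieces, ch[j],
                    if (n_after[j + 1] > 0) strrep("-", n_after[j + 1]))
      }
      paste(pieces, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    msa(stats::setNames(rows, m$ids), topo = NULL, id = m$id)
  }
  list(apply_ins(msaA, insertions(seed_aln$q_map, colsA)),
       apply_ins(msaB, insertions(seed_aln$s_map, colsB)))
}

#' @keywords internal
profile_columns <- function(p, include_loops) {
  if (include_loops || is.null(p$labels)) seq_len(ncol(p$freq))
  else which(p$labels %in% MEMBRANE_KINDS)
}

#' Local profile-profile alignment
#'
#' Aligns two frequency profiles under the log-odds column score
#' \eqn{s(c_1,c_2) = \log_2 \sum_a f_1(a) f_2(a) / bg(a)} with affine gap
#' costs in bits, using the same local DP and tie-breaking contract as
#' \code{\link{smith_waterman}}. By default only membrane-region columns
#' are compared when both profiles carry topology labels.
#'
#' @param p1,p2 \code{mh_profile} objects.
#' @param gap_open,gap_extend gap costs (bits).
#' @param include_loops logical; also align loop columns.
#' @param background background frequencies.
#' @return an object of class \code{mh_profile_alignment}: \code{score}
#'   (bits), \code{q_map}/\code{s_map} in original column coordinates, and
#'   per-column scores.
#' @export
profile_profile_align <- function(p1, p2, gap_open = 2.5, gap_extend = 0.5,
                                  include_loops = FALSE,
                                  background = RR_BACKGROUND) {
  stopifnot(inherits(p1, "mh_profile"), inherits(p2, "mh_profile"))
  u1 <- profile_columns(p1, include_loops)
  u2 <- profile_columns(p2, include_loops)
  if (length(u1) == 0 || length(u2) == 0) stop("no columns to align")
  S <- log2(crossprod(p1$freq[, u1, drop = FALSE],
                      p2$freq[, u2, drop = FALSE] / background))
  res <- .sw_align_mat(S, gap_open, gap_extend)
  q_map <- ifelse(is.na(res$q_map), NA_integer_, u1[res$q_map])
  s_map <- ifelse(is.na(res$s_map), NA_integer_, u2[res$s_map])
  both <- !is.na(res$q_map) & !is.na(res$s_map)
  percol <- rep(NA_real_, length(res$q_map))
  percol[both] <- S[cbind(res$q_map[both], res$s_map[both])]
  structure(list(score = res$score, q_map = q_map, s_map = s_map,
                 column_scores = percol, ids = c(p1$id, p2$id)),
            class = "mh_profile_alignment")
}

#' @export
print.mh_profile_alignment <- function(x, ...) {
  cat(sprintf("Profile alignment %s vs %s: %.1f bits over %d columns\n",
              x$ids[1], x$ids[2], x$score, length(x$q_map)))
  invisible(x)
}

#' Family comparison with a shuffled-MSA GEV null
#'
#' The observed statistic is the profile-profile alignment score of the two
#' family MSAs. The null regenerates the subject profile from
#' topology-preserving column shuffles of the subject MSA
#' (\code{\link{shuffle_msa_topology_preserving}}), realigns, fits a GEV to
#' the null scores and reports the tail p-value of the observed score.
#'
#' @param msaA,msaB query and subject \code{mh_msa}; the subject must carry
#'   a consensus topology.
#' @param n_shuffles number of shuffled MSAs (>= 100; the reference
#'   protocol uses 10000).
#' @param seed integer seed.
#' @param pseudocount_weight see \code{\link{build_profile}}.
#' @param gap_open,gap_extend gap costs (bits).
#' @param include_loops see \code{\link{profile_profile_align}}.
#' @param keep_null retain the null score vector.
#' @return an \code{mh_shuffle_null} (scores in bits).
#' @export
family_compare <- function(msaA, msaB, n_shuffles = 10000, seed = 1,
                           pseudocount_weight = 1.0, gap_open = 2.5,
                           gap_extend = 0.5, include_loops = FALSE,
                           keep_null = FALSE) {
  if (n_shuffles < 100) stop("n_shuffles must be at least 100")
  if (is.null(msaB$topology)) stop("subject MSA has no consensus topology")
  p1 <- build_profile(msaA, pseudocount_weight)
  p2 <- build_profile(msaB, pseudocount_weight)
  obs_aln <- profile_profile_align(p1, p2, gap_open, gap_extend, include_loops)
  u1 <- profile_columns(p1, include_loops)
  u2 <- profile_columns(p2, include_loops)
  S <- log2(crossprod(p1$freq[, u1, drop = FALSE],
                      p2$freq[, u2, drop = FALSE] / RR_BACKGROUND))
  # a column shuffle of the subject MSA permutes profile columns, so the
  # null rescoring only needs column-permuted copies of the score matrix
  L <- msa_ncol(msaB)
  cls <- position_classes(msaB$topology, L)
  r <- rle(cls %in% MEMBRANE_KINDS)
  seg <- rep(seq_along(r$lengths), r$lengths)
  null_scores <- numeric(n_shuffles)
  with_seed(subseed(seed, 2), {
    for (k in seq_len(n_shuffles)) {
      perm <- seq_len(L)
      for (g in unique(seg)) {
        idx <- which(seg == g)
        if (length(idx) > 1) perm[idx] <- idx[sample(length(idx))]
      }
      idx2 <- match(perm[u2], u2)
      null_scores[k] <- .sw_score_mat(S[, idx2, drop = FALSE],
                                      gap_open, gap_extend)
    }
  })
  fit <- fit_gev(null_scores)
  structure(list(observed = obs_aln$score, alignment = obs_aln, gev = fit,
                 n_shuffles = as.integer(n_shuffles),
                 p_value = gev_pvalue(obs_aln$score, fit), seed = seed,
                 null_scores = if (keep_null) null_scores else NULL),
            class = "mh_shuffle_null")
}

#' Reference-anchored star MSA
#'
#' Aligns every family member to a reference member with
#' \code{\link{smith_waterman}} and stacks the results in reference
#' coordinates (insertions relative to the reference are dropped). A
#' convenience for building family MSAs of closely related synthetic
#' members; externally built MSAs should be preferred for real, divergent
#' families.
#'
#' @param members list of \code{mh_annotated_sequence}.
#' @param ref reference member id; default the longest member.
#' @param scheme an \code{\link{scoring_scheme}}.
#' @param id MSA identifier.
#' @return an \code{mh_msa} whose consensus topology is the reference
#'   member's topology.
#' @export
quick_msa <- function(members, ref = NULL, scheme = scoring_scheme(),
                      id = "family") {
  stopifnot(length(members) >= 2)
  ids <- vapply(members, `[[`, character(1), "id")
  if (is.null(ref)) {
    ref <- ids[which.max(vapply(members, function(m) nchar(m$residues),
                                integer(1)))]
  }
  iref <- match(ref, ids)
  if (is.na(iref)) stop("reference id not among members")
  refseq <- members[[iref]]
  L <- nchar(refseq$residues)
  rows <- vapply(seq_along(members), function(i) {
    if (i == iref) return(refseq$residues)
    aln <- smith_waterman(refseq, members[[i]], scheme)
    row <- rep("-", L)
    if (!aln$empty) {
      both <- !is.na(aln$q_map) & !is.na(aln$s_map)
      ch <- strsplit(members[[i]]$residues, "", fixed = TRUE)[[1]]
      row[aln$q_map[both]] <- ch[aln$s_map[both]]
    }
    paste(row, collapse = "")
  }, character(1))
  msa(stats::setNames(rows, ids), topo = refseq$topology, id = id)
}
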