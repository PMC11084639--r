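# Geometry layer: Kabsch least-squares superposition, TM-score for a given
# residue correspondence, the CA-proximity segment refinement rule, and
# TMS/reentrant-loop length statistics.

#' @keywords internal
kabsch_core <- function(P, Q, w = NULL) {
  # optimal rotation R and translation t minimizing sum w |R p + t - q|^2
  if (is.null(w)) w <- rep(1, nrow(P))
  w <- w / sum(w)
  cp <- colSums(P * w); cq <- colSums(Q * w)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- t(P0 * w) %*% Q0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cq - as.numeric(R %*% cp)
  list(R = R, t = t)
}

#' Kabsch superposition of two CA chains
#'
#' Least-squares optimal rotation and translation (SVD with reflection
#' correction) mapping chain \code{a} onto chain \code{b} over the given
#' residue correspondence; reports the RMSD over corresponded pairs.
#'
#' @param a,b \code{mh_structure} chains.
#' @param correspondence integer matrix with two columns (indices into
#'   \code{a} and \code{b}); at least 3 non-collinear pairs. Default: the
#'   identity correspondence over the shorter chain.
#' @return an object of class \code{mh_superposition}: \code{rotation}
#'   (orthonormal, det +1), \code{translation}, \code{rmsd} (Angstrom),
#'   \code{correspondence}, \code{coverage} (fraction of \code{a} in the
#'   correspondence).
#' @export
kabsch_superpose <- function(a, b, correspondence = NULL) {
  stopifnot(inherits(a, "mh_structure"), inherits(b, "mh_structure"))
  if (is.null(correspondence)) {
    n <- min(nrow(a$xyz), nrow(b$xyz))
    correspondence <- cbind(seq_len(n), seq_len(n))
  }
  correspondence <- as.matrix(correspondence)
  if (nrow(correspondence) < 3) stop("need at least 3 correspondence pairs")
  P <- a$xyz[correspondence[, 1], , drop = FALSE]
  Q <- b$xyz[correspondence[, 2], , drop = FALSE]
  # collinear (or coincident) point sets leave the rotation underdetermined
  if (svd(scale(P, scale = FALSE))$d[2] < 1e-8 ||
      svd(scale(Q, scale = FALSE))$d[2] < 1e-8) {
    stop("degenerate geometry: correspondence points are collinear")
  }
  k <- kabsch_core(P, Q)
  Pm <- sweep(P %*% t(k$R), 2, k$t, "+")
  rmsd <- sqrt(mean(rowSums((Pm - Q)^2)))
  structure(list(rotation = k$R, translation = k$t, rmsd = rmsd,
                 correspondence = correspondence,
                 coverage = nrow(correspondence) / nrow(a$xyz)),
            class = "mh_superposition")
}

#' @export
print.mh_superposition <- function(x, ...) {
  cat(sprintf("Superposition over %d pairs: RMSD %.3f A, coverage %.1f%%\n",
              nrow(x$correspondence), x$rmsd, 100 * x$coverage))
  invisible(x)
}

#' TM-score of a correspondence between two chains
#'
#' \eqn{TM = \frac{1}{L_{ref}} \sum_i \frac{1}{1 + (d_i / d_0)^2}} with
#' \eqn{d_0 = 1.24 (L_{ref} - 15)^{1/3} - 1.8}. The superposition is
#' optimized for the TM-score sum by iteratively reweighted Kabsch fits
#' (weights \eqn{1/(1 + (d_i/d_0)^2)^2}, a fixed 20 iterations); the best
#' score over the iterations is returned. Note the score is asymmetric
#' under reference swap when the chains differ in length.
#'
#' @param a,b \code{mh_structure} chains.
#' @param correspondence integer index pairs as in
#'   \code{\link{kabsch_superpose}}.
#' @param reference \code{"a"} or \code{"b"}; supplies the normalizing
#'   length \eqn{L_{ref}} (>= 16).
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(a, b, correspondence = NULL, reference = c("a", "b")) {
  reference <- match.arg(reference)
  if (is.null(correspondence)) {
    n <- min(nrow(a$xyz), nrow(b$xyz))
    correspondence <- cbind(seq_len(n), seq_len(n))
  }
  correspondence <- as.matrix(correspondence)
  L_ref <- if (reference == "a") nrow(a$xyz) else nrow(b$xyz)
  if (L_ref < 16) stop("reference length must be at least 16 for the d0 formula")
  d0 <- 1.24 * (L_ref - 15)^(1 / 3) - 1.8
  P <- a$xyz[correspondence[, 1], , drop = FALSE]
  Q <- b$xyz[correspondence[, 2], , drop = FALSE]
  w <- rep(1, nrow(P))
  best <- 0
  for (it in seq_len(20)) {
    k <- kabsch_core(P, Q, w)
    d2 <- rowSums((sweep(P %*% t(k$R), 2, k$t, "+") - Q)^2)
    frac <- 1 / (1 + d2 / d0^2)
    tm <- sum(frac) / L_ref
    if (tm > best) best <- tm
    w <- frac^2
  }
  best
}

#' Refine segment assignments by CA proximity
#'
#' Iterates to a fixed point: an unlabeled (loop) residue joins a TMS or
#' reentrant loop when its alpha carbon lies within \code{cutoff} of any CA
#' of that segment's residues AND its residue index is within
#' \code{max_index_dist} of a labeled residue. Scanning is
#' N-terminus-to-C-terminus with TMS winning over RL on conflict, so the
#' result is deterministic; originally labeled residues are never
#' relabeled.
#'
#' @param chain a labeled \code{mh_structure}.
#' @param cutoff CA-CA distance cutoff (Angstrom). The default follows the
#'   literal refinement rule of 1.5 A; note the bonded CA-CA distance is
#'   about 3.8 A, so values near 4 A admit sequence-adjacent residues.
#' @param max_index_dist maximum residue-index separation.
#' @return the chain with refined labels.
#' @export
refine_segment_assignments <- function(chain, cutoff = 1.5,
                                       max_index_dist = 3) {
  stopifnot(inherits(chain, "mh_structure"), !is.null(chain$labels))
  labels <- chain$labels
  original <- labels %in% MEMBRANE_KINDS
  repeat {
    changed <- FALSE
    for (i in seq_along(labels)) {
      if (labels[i] %in% MEMBRANE_KINDS) next
      assigned <- NA_character_
      for (kind in c("TMS", "RL")) {          # TMS before RL on conflict
        members <- which(labels == kind)
        near_idx <- members[abs(chain$resno[members] - chain$resno[i]) <=
                              max_index_dist]
        if (length(near_idx) == 0) next
        d <- sqrt(rowSums((chain$xyz[near_idx, , drop = FALSE] -
                             matrix(chain$xyz[i, ], length(near_idx), 3,
                                    byrow = TRUE))^2))
        near <- near_idx[d <= cutoff]
        if (length(near) > 0) { assigned <- kind; break }
      }
      if (!is.na(assigned)) {
        labels[i] <- assigned
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  stopifnot(all(labels[original] == chain$labels[original]))
  chain$labels <- labels
  chain
}

#' Segment length statistics over labeled chains
#'
#' Per-kind mean and SD of segment lengths, the within-protein mean TMS
#' minus mean RL length difference, and the squared correlation of
#' per-protein (mean TMS length, mean RL length).
#'
#' @param chains list of labeled \code{mh_structure}.
#' @return list with \code{by_kind} (data frame kind/mean/sd/n),
#'   \code{mean_tms_rl_difference}, \code{r_squared} (NA with fewer than 3
#'   proteins carrying both kinds).
#' @export
segment_length_report <- function(chains) {
  if (inherits(chains, "mh_structure")) chains <- list(chains)
  per_chain <- lapply(chains, function(ch) {
    stopifnot(!is.null(ch$labels))
    segs <- labels_to_segments(ch$labels)
    segs$len <- segs$end - segs$start + 1
    segs
  })
  all_segs <- do.call(rbind, per_chain)
  by_kind <- do.call(rbind, lapply(c("TMS", "RL", "LOOP"), function(k) {
    lens <- all_segs$len[all_segs$kind == k]
    if (length(lens) == 0) return(NULL)
    data.frame(kind = k, mean = mean(lens),
               sd = if (length(lens) > 1) stats::sd(lens) else 0,
               n = length(lens))
  }))
  means <- do.call(rbind, lapply(per_chain, function(s) {
    data.frame(tms = mean(s$len[s$kind == "TMS"]),
               rl = mean(s$len[s$kind == "RL"]))
  }))
  means <- means[is.finite(means$tms) & is.finite(means$rl), , drop = FALSE]
  diff <- if (nrow(means) > 0) mean(means$tms - means$rl) else NA_real_
  r2 <- if (nrow(means) >= 3 && stats::sd(means$tms) > 0 &&
            stats::sd(means$rl) > 0) {
    stats::cor(means$tms, means$rl)^2
  } else NA_real_
  list(by_kind = by_kind, mean_tms_rl_difference = diff, r_squared = r2)
}
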