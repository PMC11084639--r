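# Hydropathy profiles and sequence-based TMS calling. Reentrant loops are
# deliberately never predicted from sequence: in several channel families
# they are as hydrophobic as true TMSs, so RL labels come only from
# annotation (topology tables or toy structures).

#' Kyte-Doolittle hydropathy profile
#'
#' Sliding-window mean of per-residue Kyte-Doolittle hydropathy values.
#' Positions whose window would run off the end carry the nearest
#' full-window value, so the profile has one value per residue. \code{X}
#' residues contribute a neutral value of 0.
#'
#' @param seq an \code{mh_sequence} or residue string.
#' @param window odd window length, >= 7 and <= the sequence length.
#' @return an object of class \code{mh_hydropathy}: list with \code{values}
#'   and \code{window}.
#' @examples
#' hydropathy_profile(strrep("I", 30), window = 19)$values[1]  # 4.5
#' @export
hydropathy_profile <- function(seq, window = 7) {
  res <- residues_of(seq)
  L <- nchar(res)
  if (window %% 2 == 0) stop("window must be odd")
  if (window < 7) stop("window must be at least 7")
  if (window > L) stop("window exceeds sequence length")
  ch <- strsplit(res, "", fixed = TRUE)[[1]]
  v <- unname(KD_SCALE[ch])
  v[is.na(v)] <- 0
  full <- as.numeric(stats::filter(v, rep(1 / window, window), sides = 2))
  h <- (window - 1) / 2
  full[seq_len(h)] <- full[h + 1]
  full[(L - h + 1):L] <- full[L - h]
  structure(list(values = full, window = window), class = "mh_hydropathy")
}

#' Predict transmembrane segments from a hydropathy profile
#'
#' Maximal runs of smoothed hydropathy at or above \code{threshold} are
#' taken as membrane-spanning cores. Because a \code{w}-residue moving
#' average erodes a hydrophobic stretch by about \code{w - 1} positions,
#' each super-threshold run is dilated by \code{(window - 1) / 2} on both
#' sides, and adjacent sub-\code{min_len} fragments separated by at most
#' \code{rescue_gap} positions are merged (re-joining the halves of a
#' helix notched by a weak residue). Segments are kept when they are at
#' least \code{min_len} long and their mean smoothed hydropathy stays at
#' or above the threshold - the second condition rejects brief hydrophobic
#' excursions inside loops. Segments longer than \code{max_len} are split
#' at internal profile minima. Everything else is labeled \code{LOOP}.
#'
#' @param profile an \code{mh_hydropathy}.
#' @param threshold hydropathy threshold (Kyte-Doolittle units).
#' @param min_len minimum TMS length (residues) after dilation.
#' @param max_len maximum TMS length before splitting.
#' @param rescue_gap maximum gap (residues) between sub-\code{min_len}
#'   fragments merged by the rescue step.
#' @return an \code{mh_topology} with \code{source = "predicted"}.
#' @export
predict_tms <- function(profile, threshold = 1.6, min_len = 15, max_len = 35,
                        rescue_gap = 6) {
  stopifnot(inherits(profile, "mh_hydropathy"))
  v <- profile$values
  L <- length(v)
  h <- (profile$window - 1) / 2
  r <- rle(v >= threshold)
  ends <- cumsum(r$lengths)
  runs <- data.frame(start = ends - r$lengths + 1L, end = ends)[r$values, ,
                                                                drop = FALSE]
  if (nrow(runs) == 0) {
    return(topology(1L, L, "LOOP", source = "predicted"))
  }
  runs$start <- pmax(1L, runs$start - h)
  runs$end <- pmin(L, runs$end + h)
  # dilation bridges sub-window notches inside one helix; merge the overlaps
  out <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$start[i] <= out$end[nrow(out)] + 1) {
      out$end[nrow(out)] <- runs$end[i]
    } else {
      out <- rbind(out, runs[i, ])
    }
  }
  # rescue: two nearby fragments that are each too short to be a TMS are
  # usually the halves of one helix split by a hydrophilic notch
  repeat {
    lens <- out$end - out$start + 1
    merged_one <- FALSE
    for (i in seq_len(max(nrow(out) - 1, 0))) {
      if (lens[i] < min_len && lens[i + 1] < min_len &&
          out$start[i + 1] - out$end[i] - 1 <= rescue_gap) {
        out$end[i] <- out$end[i + 1]
        out <- out[-(i + 1), , drop = FALSE]
        merged_one <- TRUE
        break
      }
    }
    if (!merged_one) break
  }
  # a genuine TMS stays above threshold on average over its whole dilated
  # extent; brief hydrophobic excursions inside loops do not
  keep <- vapply(seq_len(nrow(out)), function(i) {
    out$end[i] - out$start[i] + 1 >= min_len &&
      mean(v[out$start[i]:out$end[i]]) >= threshold
  }, logical(1))
  out <- out[keep, , drop = FALSE]
  split_long <- function(s, e) {
    if (e - s + 1 <= max_len) return(data.frame(start = s, end = e))
    inner <- (s + 5):(e - 5)
    # internal minimum; ties (e.g. a flat profile) break toward the center
    m <- inner[order(v[inner], abs(inner - (s + e) / 2))[1]]
    rbind(split_long(s, m - 1L), split_long(m + 1L, e))
  }
  if (nrow(out) > 0) {
    out <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
      s <- out$start[i]; e <- out$end[i]
      if (e - s + 1 <= max_len) return(data.frame(start = s, end = e))
      # over-long segments are split on their undilated core, otherwise the
      # dilation margins force spurious extra splits
      split_long(min(s + h, e), max(e - h, s))
    }))
    out <- out[out$end - out$start + 1 >= min_len, , drop = FALSE]
  }
  if (nrow(out) == 0) {
    return(topology(1L, L, "LOOP", source = "predicted"))
  }
  starts <- out$start; ends2 <- out$end
  k <- rep("TMS", length(starts))
  # fill gaps with LOOP segments
  gs <- c(1L, ends2 + 1L); ge <- c(starts - 1L, L)
  keep <- ge >= gs
  topology(c(starts, gs[keep]), c(ends2, ge[keep]),
           c(k, rep("LOOP", sum(keep))), source = "predicted")
}

#' Classify the membrane architecture of a topology
#'
#' Membrane segments separated by loops shorter than \code{long_loop} are
#' grouped; the label joins group sizes with \code{"+"} (e.g. \code{"3+1"}
#' for three clustered hydrophobic peaks plus a fourth behind a long
#' hydrophilic region). Loop-length changes below the threshold do not
#' change the label.
#'
#' @param topo an \code{mh_topology}.
#' @param long_loop minimum loop length (residues) separating groups.
#' @return architecture label; \code{"0"} when there is no membrane
#'   segment.
#' @export
classify_architecture <- function(topo, long_loop = 50) {
  segs <- membrane_segments(topo)
  if (nrow(segs) == 0) return("0")
  if (nrow(segs) == 1) return("1")
  gaps <- segs$start[-1] - segs$end[-nrow(segs)] - 1
  groups <- cumsum(c(1, as.integer(gaps >= long_loop)))
  paste(tabulate(groups), collapse = "+")
}

#' Segment length summary
#'
#' @param topos list of \code{mh_topology}.
#' @param kind segment kind (\code{"TMS"}, \code{"RL"} or \code{"LOOP"}).
#' @return list with \code{mean}, \code{sd} (sample SD; 0 with \code{n = 1})
#'   and \code{n}.
#' @export
segment_lengths <- function(topos, kind) {
  if (inherits(topos, "mh_topology")) topos <- list(topos)
  lens <- unlist(lapply(topos, function(t) {
    s <- t[t$kind == kind, , drop = FALSE]
    s$end - s$start + 1
  }))
  if (length(lens) == 0) stop("no segments of kind ", kind)
  list(mean = mean(lens),
       sd = if (length(lens) > 1) stats::sd(lens) else 0,
       n = length(lens))
}
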