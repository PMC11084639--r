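# Synthetic membrane-protein families with known ground truth: ancestors
# with fixed TMS architectures, class-conditional divergence, implanted
# motifs, tandem duplications and fusions, matched-topology non-homolog
# controls, and ideal-helix toy structures.

#' Build a topology specification from an architecture label
#'
#' Architectures are written as "+"-joined group sizes ("3+1", "4",
#' "3+1+3"): TMSs within a group are separated by short loops, groups by a
#' long hydrophilic loop. No terminal loops are added, so e.g. "3+1" with
#' the defaults is TMS 21 / loop 15 / TMS 21 / loop 15 / TMS 21 / loop 120 /
#' TMS 21 (234 residues). Defaults follow typical membrane-protein segment
#' lengths (TMS about 21 residues, reentrant loops 12-25).
#'
#' @param arch architecture label, e.g. \code{"3+1"}.
#' @param tms_len TMS length (residues).
#' @param short_loop loop length between TMSs of the same group.
#' @param long_loop loop length between groups.
#' @param rl_index optional index (among membrane segments) to mark as a
#'   reentrant loop instead of a TMS.
#' @param rl_len length of the reentrant-loop segment, if any.
#' @return an \code{mh_topology_spec}: list with \code{topology}
#'   (an \code{mh_topology}), \code{length} and \code{label}.
#' @examples
#' make_topology_spec("3+1")$length  # 234
#' @export
make_topology_spec <- function(arch = "3+1", tms_len = 21, short_loop = 15,
                               long_loop = 120, rl_index = NULL, rl_len = 18) {
  groups <- as.integer(strsplit(arch, "+", fixed = TRUE)[[1]])
  if (any(is.na(groups)) || any(groups < 1)) stop("bad architecture label: ", arch)
  kinds <- character(0); lens <- integer(0)
  mem_i <- 0L
  for (g in seq_along(groups)) {
    for (t in seq_len(groups[g])) {
      mem_i <- mem_i + 1L
      is_rl <- !is.null(rl_index) && mem_i %in% rl_index
      kinds <- c(kinds, if (is_rl) "RL" else "TMS")
      lens <- c(lens, if (is_rl) rl_len else tms_len)
      last <- g == length(groups) && t == groups[g]
      if (!last) {
        kinds <- c(kinds, "LOOP")
        lens <- c(lens, if (t == groups[g]) long_loop else short_loop)
      }
    }
  }
  ends <- cumsum(lens)
  topo <- topology(ends - lens + 1L, ends, kinds)
  structure(list(topology = topo, length = sum(lens), label = arch),
            class = "mh_topology_spec")
}

#' @keywords internal
draw_residues <- function(n, kind) {
  p <- if (kind %in% MEMBRANE_KINDS) TMS_COMPOSITION else RR_BACKGROUND
  paste(sample(AA20, n, replace = TRUE, prob = p), collapse = "")
}

#' Sample an ancestral membrane protein
#'
#' Residues in TMS and reentrant-loop segments are drawn from a
#' hydrophobic-biased membrane composition (80% of the mass on
#' I,L,V,F,A,M,W,G,C); loop residues from a Robinson-Robinson soluble
#' background. The topology of the specification is attached exactly.
#'
#' @param spec an \code{mh_topology_spec}.
#' @param seed integer seed; the same seed reproduces the same ancestor.
#' @param id sequence identifier.
#' @return an \code{mh_annotated_sequence}.
#' @export
sample_ancestor <- function(spec, seed, id = "anc") {
  stopifnot(inherits(spec, "mh_topology_spec"))
  topo <- spec$topology
  if (nrow(topo) == 0 || spec$length == 0) stop("zero-length topology spec")
  cls <- position_classes(topo, spec$length)
  res <- with_seed(seed, {
    vapply(seq_len(nrow(topo)), function(i) {
      draw_residues(topo$end[i] - topo$start[i] + 1, topo$kind[i])
    }, character(1))
  })
  annotated_sequence(id, paste(res, collapse = ""), topo,
                     description = paste0("synthetic ancestor ", spec$label))
}

# Mutate one segment's residues: each site is hit with probability
# p = 1 - exp(-divergence) and resampled from its class distribution.
#' @keywords internal
mutate_segment <- function(ch, kind, divergence) {
  p <- 1 - exp(-divergence)
  hit <- stats::runif(length(ch)) < p
  if (any(hit)) {
    prob <- if (kind %in% MEMBRANE_KINDS) TMS_COMPOSITION else RR_BACKGROUND
    ch[hit] <- sample(AA20, sum(hit), replace = TRUE, prob = prob)
  }
  ch
}

# Apply loop-only indels: per site, an indel event occurs with probability
# rate; geometric lengths (mean 3); deletions are clipped to the segment.
#' @keywords internal
indel_loop <- function(ch, rate) {
  if (rate <= 0 || length(ch) < 2) return(ch)
  out <- character(0)
  i <- 1
  while (i <= length(ch)) {
    if (stats::runif(1) < rate) {
      len <- stats::rgeom(1, 1 / 3) + 1
      if (stats::runif(1) < 0.5) {  # insertion before site i
        ins <- sample(AA20, len, replace = TRUE, prob = RR_BACKGROUND)
        out <- c(out, ins, ch[i])
        i <- i + 1
      } else {                      # deletion of up to len sites
        i <- i + min(len, length(ch) - i + 1)
      }
    } else {
      out <- c(out, ch[i])
      i <- i + 1
    }
  }
  if (length(out) == 0) out <- ch[1]  # never delete a loop entirely
  out
}

#' Evolve a family from an ancestor
#'
#' Each member is derived independently from the ancestor. Substitutions are
#' class-conditional: hit sites in membrane segments are resampled from the
#' membrane composition, loop sites from the loop background, so the
#' compositional contrast is maintained at any divergence. Indels occur only
#' inside loops (geometric lengths, mean 3; per-site rate
#' \code{indel_rate * (1 - exp(-divergence))}), so every member keeps the
#' ancestor's segment count, and topology coordinates are updated for
#' indels.
#'
#' @param ancestor an \code{mh_annotated_sequence}.
#' @param n number of members (>= 1).
#' @param divergence expected substitutions per site (>= 0).
#' @param seed integer seed.
#' @param indel_rate indel intensity relative to substitutions; 0 disables
#'   indels (members then all have the ancestor's length).
#' @param prefix member id prefix.
#' @return list with \code{members} (list of \code{mh_annotated_sequence})
#'   and \code{truth} (an \code{mh_family_truth}: family id, member ids,
#'   symmetric pairwise homology flags).
#' @export
evolve_family <- function(ancestor, n, divergence, seed, indel_rate = 0.05,
                          prefix = ancestor$id) {
  if (divergence < 0) stop("divergence must be non-negative")
  stopifnot(n >= 1)
  topo <- ancestor$topology
  if (is.null(topo)) stop("ancestor has no topology")
  cls <- position_classes(topo, nchar(ancestor$residues))
  segs <- labels_to_segments(cls)  # full cover, implicit loops included
  ch_all <- strsplit(ancestor$residues, "", fixed = TRUE)[[1]]
  ind_rate <- indel_rate * (1 - exp(-divergence))
  members <- with_seed(seed, {
    lapply(seq_len(n), function(m) {
      new_kinds <- character(0); new_lens <- integer(0); parts <- character(0)
      for (i in seq_len(nrow(segs))) {
        ch <- ch_all[segs$start[i]:segs$end[i]]
        ch <- mutate_segment(ch, segs$kind[i], divergence)
        if (segs$kind[i] == "LOOP") ch <- indel_loop(ch, ind_rate)
        parts <- c(parts, paste(ch, collapse = ""))
        new_kinds <- c(new_kinds, segs$kind[i])
        new_lens <- c(new_lens, length(ch))
      }
      ends <- cumsum(new_lens)
      new_topo <- topology(ends - new_lens + 1L, ends, new_kinds)
      annotated_sequence(sprintf("%s_m%02d", prefix, m),
                         paste(parts, collapse = ""), new_topo,
                         description = sprintf("divergence %.2f", divergence))
    })
  })
  ids <- vapply(members, `[[`, character(1), "id")
  truth <- structure(list(family_id = prefix, member_ids = ids,
                          homologous = matrix(TRUE, n, n,
                                              dimnames = list(ids, ids)),
                          implants = NULL, breakpoint = NULL),
                     class = "mh_family_truth")
  list(members = members, truth = truth)
}

#' Matched-topology non-homolog pair
#'
#' Two independent ancestors drawn from the same topology specification:
#' identical segment coordinates and composition model, but independent
#' residues. Serves as the negative control for the shuffle-null
#' calibration.
#'
#' @param spec an \code{mh_topology_spec}.
#' @param seed integer seed; two sub-seeds are derived from it.
#' @param seeds optional explicit pair of sub-seeds; identical values are
#'   refused.
#' @return list of two \code{mh_annotated_sequence} objects flagged
#'   non-homologous.
#' @export
make_nonhomolog_pair <- function(spec, seed, seeds = NULL) {
  if (is.null(seeds)) seeds <- c(subseed(seed, 101), subseed(seed, 202))
  if (seeds[1] == seeds[2]) {
    stop("identical sub-seeds would create identical 'non-homologs'")
  }
  a <- sample_ancestor(spec, seeds[1], id = "nhA")
  b <- sample_ancestor(spec, seeds[2], id = "nhB")
  a$description <- b$description <- "matched-topology non-homolog"
  list(a, b)
}

#' Position weight matrix from a consensus
#'
#' Convenience constructor for implant experiments: each position puts
#' \code{conservation} on the consensus residue and spreads the remainder
#' over the background.
#'
#' @param consensus residue string (the PWM width is its length).
#' @param conservation probability mass on the consensus residue.
#' @param background background frequencies (named over the 20 residues).
#' @return an \code{mh_pwm} (see \code{\link{discover_motif_oops}}).
#' @export
pwm_from_consensus <- function(consensus, conservation = 0.9,
                               background = RR_BACKGROUND) {
  ch <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  stopifnot(all(ch %in% AA20), conservation > 0, conservation < 1)
  w <- length(ch)
  mat <- matrix(rep(background * (1 - conservation), w), nrow = 20,
                dimnames = list(AA20, NULL))
  for (k in seq_len(w)) {
    mat[ch[k], k] <- mat[ch[k], k] + conservation
  }
  mat <- sweep(mat, 2, colSums(mat), "/")
  new_pwm(mat, background)
}

#' Implant a motif into a family
#'
#' In \code{round(fraction * n)} members (chosen at random), the central
#' window of the designated membrane segment is replaced by a sample from
#' the PWM; implant coordinates are recorded in the returned truth.
#'
#' @param family list of \code{mh_annotated_sequence}.
#' @param pwm an \code{mh_pwm}.
#' @param segment_index index of the target segment among each member's
#'   membrane segments (or among all topology segments with
#'   \code{among = "all"}, so wide motifs can sit in a long loop).
#' @param fraction fraction of members receiving the implant, in [0, 1].
#' @param seed integer seed.
#' @param among index \code{segment_index} among membrane segments only
#'   (default) or among all segments.
#' @return list with \code{members} and \code{truth} (implant intervals per
#'   member id; \code{NULL} for members without implant).
#' @export
implant_motif <- function(family, pwm, segment_index, fraction, seed,
                          among = c("membrane", "all")) {
  among <- match.arg(among)
  stopifnot(inherits(pwm, "mh_pwm"), fraction >= 0, fraction <= 1)
  n <- length(family)
  k <- round(fraction * n)
  w <- pwm$width
  implants <- stats::setNames(vector("list", n),
                              vapply(family, `[[`, character(1), "id"))
  members <- family
  with_seed(seed, {
    chosen <- if (k > 0) sample(n, k) else integer(0)
    for (i in chosen) {
      seq_i <- members[[i]]
      segs <- if (among == "membrane") membrane_segments(seq_i$topology)
              else seq_i$topology
      if (segment_index > nrow(segs)) {
        stop("segment_index exceeds membrane segment count")
      }
      s <- segs$start[segment_index]; e <- segs$end[segment_index]
      if (w > e - s + 1) {
        stop(sprintf("PWM width %d exceeds segment length %d", w, e - s + 1))
      }
      off <- s + floor((e - s + 1 - w) / 2)
      sampled <- vapply(seq_len(w), function(j) {
        sample(AA20, 1, prob = pwm$mat[, j])
      }, character(1))
      ch <- strsplit(seq_i$residues, "", fixed = TRUE)[[1]]
      ch[off:(off + w - 1)] <- sampled
      members[[i]] <- annotated_sequence(seq_i$id, paste(ch, collapse = ""),
                                         seq_i$topology, seq_i$description)
      implants[[seq_i$id]] <- c(start = off, end = off + w - 1)
    }
  })
  truth <- structure(list(family_id = "implant", member_ids = names(implants),
                          homologous = NULL, implants = implants,
                          breakpoint = NULL),
                     class = "mh_family_truth")
  list(members = members, truth = truth)
}

#' Compose two annotated sequences into a tandem repeat or fusion
#'
#' Concatenates \code{partA}, a loop linker, and \code{partB}, with
#' topologies offset accordingly. In \code{tandem} mode \code{partB} is a
#' fresh evolution of \code{partA} (the duplicated unit) at the given
#' divergence; in \code{fusion} mode \code{partB} is used as supplied.
#'
#' @param partA,partB \code{mh_annotated_sequence} objects (\code{partB}
#'   ignored in tandem mode).
#' @param mode \code{"tandem"} or \code{"fusion"}.
#' @param linker linker loop length (residues).
#' @param divergence tandem-unit divergence (tandem mode).
#' @param seed integer seed.
#' @param id identifier of the composite.
#' @return an \code{mh_annotated_sequence}; the breakpoint (first position
#'   of the second part) is recorded in \code{attr(, "breakpoint")}.
#' @export
compose_architectures <- function(partA, partB = NULL,
                                  mode = c("tandem", "fusion"), linker = 20,
                                  divergence = 0.35, seed = 1,
                                  id = paste0(partA$id, "_", match.arg(mode))) {
  mode <- match.arg(mode)
  if (mode == "tandem") {
    partB <- evolve_family(partA, 1, divergence, subseed(seed, 7),
                           indel_rate = 0)$members[[1]]
  } else if (is.null(partB)) {
    stop("fusion mode requires partB")
  }
  linker_res <- with_seed(subseed(seed, 8), draw_residues(linker, "LOOP"))
  lenA <- nchar(partA$residues)
  offset <- lenA + linker
  topoB <- shift_topology(partB$topology, offset)
  topo <- topology(c(partA$topology$start, lenA + 1L, topoB$start),
                   c(partA$topology$end, lenA + linker, topoB$end),
                   c(partA$topology$kind, "LOOP", topoB$kind))
  out <- annotated_sequence(id,
                            paste0(partA$residues, linker_res, partB$residues),
                            topo, description = paste0("composite ", mode))
  attr(out, "breakpoint") <- offset + 1L
  out
}

#' Ideal-helix toy structure for a topology
#'
#' Builds an alpha-carbon trace with ideal helix geometry (rise 1.5 A,
#' radius 2.3 A, 100 degrees per residue) for each TMS, alternating membrane
#' crossings; loops are laid out as arcs with consecutive CA-CA spacing of
#' 3.8 A. Reentrant loops form hairpins: either a descending helix followed
#' by a climbing loop (\code{helix_loop}) or two sub-helices separated by a
#' 2-residue turn whose residues are glycine and glutamate
#' (\code{helix_helix}).
#'
#' @param spec an \code{mh_topology_spec}.
#' @param rl_shape reentrant-loop geometry, \code{"helix_loop"} or
#'   \code{"helix_helix"}.
#' @param seed integer seed (a small seeded coordinate jitter, sd 0.02 A,
#'   makes replicates distinguishable while preserving geometry).
#' @return an \code{mh_structure} with per-residue segment labels.
#' @export
make_toy_structure <- function(spec, rl_shape = c("helix_loop", "helix_helix"),
                               seed = 1) {
  rl_shape <- match.arg(rl_shape)
  stopifnot(inherits(spec, "mh_topology_spec"))
  topo <- spec$topology
  cls <- position_classes(topo, spec$length)
  segs <- labels_to_segments(cls)
  rise <- 1.5; radius <- 2.3; turn <- 100 * pi / 180; ca <- 3.8
  helix_pts <- function(n, origin, dz) {
    k <- seq_len(n) - 1
    pts <- cbind(radius * cos(k * turn), radius * sin(k * turn), k * rise * dz)
    sweep(pts, 2, pts[1, ] - origin)  # first point sits at `origin`
  }
  # n unit steps of length `ca` whose direction rotates through a half-turn
  # in the given plane: a flat arc (plane = "xy") or a climbing arc ("xz").
  arc_pts <- function(n, from, plane = "xy", zsign = 1) {
    ang <- pi * (seq_len(n) - 0.5) / n
    dirs <- if (plane == "xy") cbind(sin(ang), cos(ang), 0)
            else cbind(sin(ang), 0, cos(ang) * zsign)
    sweep(apply(dirs * ca, 2, cumsum), 2, from, "+")
  }
  xyz <- NULL; labels <- character(0); residues <- character(0)
  cursor <- c(0, 0, 0); dz <- 1
  add <- function(pts, lab, res) {
    pts <- matrix(pts, ncol = 3)
    xyz <<- rbind(xyz, pts)
    labels <<- c(labels, rep(lab, nrow(pts)))
    residues <<- c(residues, res)
    cursor <<- pts[nrow(pts), ]
  }
  for (i in seq_len(nrow(segs))) {
    n <- segs$end[i] - segs$start[i] + 1
    kind <- segs$kind[i]
    first <- is.null(xyz)
    entry <- if (first) cursor else cursor + c(ca, 0, 0)
    if (kind == "TMS") {
      add(helix_pts(n, entry, dz), "TMS", rep("A", n))
      dz <- -dz  # a TMS crosses the membrane
    } else if (kind == "RL") {
      half <- floor((n - 2) / 2)
      if (rl_shape == "helix_helix") {
        add(helix_pts(half, entry, dz), "RL", rep("A", half))
        add(rbind(cursor + c(ca, 0, 0), cursor + c(ca, ca, 0)), "RL",
            c("G", "E"))
        add(helix_pts(n - half - 2, cursor + c(ca, 0, 0), -dz), "RL",
            rep("A", n - half - 2))
      } else {
        deep <- n - half
        add(helix_pts(deep, entry, dz), "RL", rep("A", deep))
        add(arc_pts(half, cursor, plane = "xz", zsign = -dz), "RL",
            rep("A", half))
      }
      # a reentrant loop exits on the side it entered: dz is not flipped
    } else {
      pts <- rbind(entry, if (n > 1) arc_pts(n - 1, entry, plane = "xy"))
      add(pts, "LOOP", rep("A", n))
    }
  }
  jitter <- with_seed(seed, matrix(stats::rnorm(length(xyz), sd = 0.02),
                                   nrow = nrow(xyz)))
  structure_chain(xyz + jitter, labels = labels, residues = residues,
                  id = paste0("toy_", spec$label, "_", rl_shape))
}
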