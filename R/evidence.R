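# Evidence orchestration: run the independent lines of homology evidence
# over a pair of families and emit a structured report. No line's failure
# blocks another; a line that cannot run is marked unavailable.

#' @keywords internal
evidence_line <- function(expr) {
  tryCatch(expr, error = function(e) {
    list(status = "unavailable", reason = conditionMessage(e))
  })
}

#' Run the multi-line homology evidence pipeline on two families
#'
#' Executes, in order: redundancy reduction; topology/architecture
#' comparison; best cross-family pairwise alignment with TMS-coverage
#' filtering and the sequence shuffle-null GEV p-value; domain projection
#' (when direct domain annotations are supplied); family-level profile
#' comparison with the shuffled-MSA GEV null; shared motif discovery,
#' scanning and per-family recovery; internal repeat detection (for
#' families whose architecture contains at least twice the repeat unit);
#' and bit-score Ward clustering of the combined membership. Each line
#' reports a verdict plus its statistics; failures downgrade a line to
#' "unavailable" without stopping the pipeline.
#'
#' @param famA,famB lists of \code{mh_annotated_sequence}.
#' @param config an \code{\link{run_config}}; its master seed drives every
#'   random stream, so identical configs reproduce the report exactly.
#' @param msaA,msaB optional \code{mh_msa} family alignments; built with
#'   \code{\link{quick_msa}} when absent.
#' @param domains optional list of \code{mh_domain} direct annotations on
#'   members of either family.
#' @param motif_width motif width for discovery.
#' @param repeat_after membrane-segment index after which to cut for repeat
#'   detection (\code{NULL} skips the line).
#' @return an object of class \code{mh_evidence_report}.
#' @export
run_evidence_pipeline <- function(famA, famB, config = run_config(),
                                  msaA = NULL, msaB = NULL, domains = NULL,
                                  motif_width = 15, repeat_after = NULL) {
  stopifnot(length(famA) >= 1, length(famB) >= 1)
  sc <- config$scheme
  seed <- config$seed
  report <- list(families = c(id_of(famA[[1]]), id_of(famB[[1]])),
                 parameters = list(n_shuffles = config$n_shuffles,
                                   seed = seed, scheme = sc$name))
  mh_log("evidence pipeline on %d + %d members, seed %d, digest %s/%s",
         length(famA), length(famB), seed, mh_digest(famA), mh_digest(famB))

  famA <- reduce_redundancy(famA, scheme = sc)
  famB <- reduce_redundancy(famB, scheme = sc)
  report$n_members <- c(length(famA), length(famB))

  # line 2: topology compatibility (architecture labels)
  report$topology <- evidence_line({
    archA <- vapply(famA, function(s) classify_architecture(s$topology),
                    character(1))
    archB <- vapply(famB, function(s) classify_architecture(s$topology),
                    character(1))
    modal <- function(x) names(sort(table(x), decreasing = TRUE))[1]
    list(status = "ok", architecture_a = modal(archA),
         architecture_b = modal(archB),
         positive = modal(archA) == modal(archB))
  })

  # line 1: best cross-family alignment + coverage filter + shuffle null
  report$sequence_similarity <- evidence_line({
    best <- NULL
    for (a in famA) for (b in famB) {
      aln <- smith_waterman(a, b, sc)
      if (is.null(best) || aln$raw > best$aln$raw) best <- list(aln = aln, a = a, b = b)
    }
    cov <- tms_coverage_filter(best$aln, best$a$topology, best$b$topology,
                               min_tms = 3)
    null <- shuffle_null_compare(best$a, best$b, n_shuffles = config$n_shuffles,
                          scheme = sc, seed = subseed(seed, 11))
    list(status = "ok", query = best$a$id, subject = best$b$id,
         evalue = best$aln$evalue, bits = best$aln$bits,
         coverage_accept = cov$accept, gev_p = null$p_value,
         positive = best$aln$evalue <= config$evalue_threshold &&
           cov$accept && null$p_value <= config$shuffle_p_threshold)
  })

  # line 3: domain projection (first iteration only). Each projecting
  # alignment must itself beat the topology-preserving shuffle null, or
  # compositional alignments would project domains between unrelated
  # membrane proteins.
  report$domain_projection <- if (is.null(domains)) {
    list(status = "unavailable", reason = "no direct domain annotations supplied")
  } else evidence_line({
    ids_a <- vapply(famA, `[[`, character(1), "id")
    ids_b <- vapply(famB, `[[`, character(1), "id")
    projected <- list()
    for (d in seq_along(domains)) {
      dom <- domains[[d]]
      carrier_in_a <- dom$carrier %in% ids_a
      targets <- if (carrier_in_a) famB else famA
      carrier <- c(famA, famB)[[match(dom$carrier, c(ids_a, ids_b))]]
      for (ti in seq_along(targets)) {
        t <- targets[[ti]]
        pr <- project_domain(dom, smith_waterman(carrier, t, sc))
        if (inherits(pr, "mh_domain")) {
          null <- shuffle_null_compare(carrier, t, n_shuffles = config$n_shuffles,
                                scheme = sc,
                                seed = subseed(seed, 1500 + 100 * d + ti))
          if (null$p_value <= config$shuffle_p_threshold) {
            projected[[length(projected) + 1]] <- pr
          }
        }
      }
    }
    list(status = "ok", n_projected = length(projected),
         positive = length(projected) > 0)
  })

  # line 5: profile comparison with shuffled-MSA null
  report$profile_comparison <- evidence_line({
    if (is.null(msaA)) msaA <- quick_msa(famA, scheme = sc, id = "famA")
    if (is.null(msaB)) msaB <- quick_msa(famB, scheme = sc, id = "famB")
    null <- family_compare(msaA, msaB, n_shuffles = config$n_shuffles,
                           seed = subseed(seed, 13))
    list(status = "ok", score_bits = null$observed, gev_p = null$p_value,
         positive = null$p_value <= config$profile_p_threshold)
  })

  # line 4: shared motif. The motif is discovered on family A alone and
  # must be recovered in family B - discovering on the union would accept
  # a superposition of two family-private motifs. A decoy set of
  # topology-preserving shuffles is the negative control for residual
  # compositional matching.
  report$motif <- evidence_line({
    combined <- c(famA, famB)
    disc <- discover_motif_oops(famA, width = motif_width,
                                n_starts = 3, seed = subseed(seed, 17))
    hits <- scan_sequences(disc$pwm, combined,
                           evalue_threshold = config$motif_evalue_threshold)
    recA <- recovery_rate(hits, vapply(famA, `[[`, character(1), "id"))
    recB <- recovery_rate(hits, vapply(famB, `[[`, character(1), "id"))
    # per-segment shuffles keep each segment's exact composition, so a
    # "motif" that is only a compositional preference still hits the decoys
    decoys <- lapply(seq_along(combined), function(i) {
      d <- shuffle_sequence_topology_preserving(combined[[i]],
                                                subseed(seed, 1700 + i),
                                                per_segment = TRUE)
      d$id <- paste0(d$id, "_decoy")
      d
    })
    dec_hits <- scan_sequences(disc$pwm, decoys,
                               evalue_threshold = config$motif_evalue_threshold)
    recD <- recovery_rate(dec_hits, vapply(decoys, `[[`, character(1), "id"))
    topos <- stats::setNames(lapply(combined, `[[`, "topology"),
                             vapply(combined, `[[`, character(1), "id"))
    loc <- locate_motif(hits, topos, disc$pwm$width)
    list(status = "ok", recovery_a = recA, recovery_b = recB,
         recovery_decoy = recD,
         modal_segment = if (length(loc)) names(which.max(loc)) else NA,
         positive = recA >= 100 * config$recovery_threshold &&
           recB >= 100 * config$recovery_threshold && recD < 10)
  })

  # line 6: internal repeat support
  report$repeat_unit <- if (is.null(repeat_after)) {
    list(status = "unavailable",
         reason = "no repeat-unit cut point configured for these architectures")
  } else evidence_line({
    m <- if (is.null(msaA)) quick_msa(famA, scheme = sc, id = "famA") else msaA
    sp <- split_msa_at_loop(m, repeat_after)
    hits <- call_repeat_support(cross_align_halves(sp, sc), sp)
    list(status = "ok", n_supported = sum(hits$supported),
         positive = any(hits$supported))
  })

  # line 7: clustering of the combined membership. Cross-family distances
  # are judged against a decoy block (family B shuffled topology-
  # preservingly), which carries the compositional similarity floor.
  report$clustering <- evidence_line({
    decoyB <- lapply(seq_along(famB), function(i) {
      d <- shuffle_sequence_topology_preserving(famB[[i]],
                                                subseed(seed, 1900 + i))
      d$id <- paste0(d$id, "_decoy")
      d
    })
    all_seqs <- c(famA, famB, decoyB)
    dm <- bitscore_distance_matrix(all_seqs, sc, membrane_only = TRUE)
    tree <- ward_tree(dm[seq_len(length(famA) + length(famB)),
                         seq_len(length(famA) + length(famB))])
    ids_a <- vapply(famA, `[[`, character(1), "id")
    ids_b <- vapply(famB, `[[`, character(1), "id")
    ids_d <- vapply(decoyB, `[[`, character(1), "id")
    cross <- mean(dm[ids_a, ids_b])
    cross_decoy <- mean(dm[ids_a, ids_d])
    list(status = "ok", ac = tree$agglomerative_coefficient,
         mean_cross_distance = cross, mean_decoy_distance = cross_decoy,
         positive = cross < cross_decoy - 0.05)
  })

  lines <- c("sequence_similarity", "topology", "domain_projection", "motif",
             "profile_comparison", "repeat_unit", "clustering")
  verdicts <- vapply(lines, function(l) {
    isTRUE(report[[l]]$positive)
  }, logical(1))
  available <- vapply(lines, function(l) {
    identical(report[[l]]$status, "ok")
  }, logical(1))
  report$summary <- list(lines_positive = sum(verdicts),
                         lines_available = sum(available),
                         verdicts = as.list(verdicts))
  structure(report, class = "mh_evidence_report")
}

#' @export
print.mh_evidence_report <- function(x, ...) {
  cat(sprintf("Evidence report %s vs %s: %d/%d lines positive\n",
              x$families[1], x$families[2], x$summary$lines_positive,
              x$summary$lines_available))
  for (l in names(x$summary$verdicts)) {
    st <- x[[l]]$status
    cat(sprintf("  %-20s %s\n", l,
                if (!identical(st, "ok")) paste0("unavailable (", x[[l]]$reason, ")")
                else if (isTRUE(x[[l]]$positive)) "positive" else "negative"))
  }
  invisible(x)
}

#' Write an evidence report to JSON
#'
#' @param report an \code{mh_evidence_report}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_evidence_report <- function(report, path) {
  stopifnot(inherits(report, "mh_evidence_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
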