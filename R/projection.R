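# Domain projection: transfer a domain interval from an annotated carrier
# protein to a homolog through a pairwise alignment, recording projection
# depth so downstream analyses can restrict to first-iteration projections.

#' Create a domain annotation
#'
#' @param name domain name (e.g. a Pfam accession).
#' @param carrier id of the protein carrying the domain.
#' @param start,end interval on the carrier (1-based inclusive).
#' @param depth 0 for a direct annotation; incremented per projection.
#' @param path alignment ids traversed by projections.
#' @return an object of class \code{mh_domain}.
#' @export
domain_annotation <- function(name, carrier, start, end, depth = 0L,
                              path = character(0)) {
  stopifnot(start >= 1, end >= start, depth >= 0)
  structure(list(name = name, carrier = carrier, start = as.integer(start),
                 end = as.integer(end), depth = as.integer(depth),
                 path = path),
            class = "mh_domain")
}

#' Project a domain through a pairwise alignment
#'
#' Maps the domain interval through the alignment's column mapping onto the
#' partner protein. The projection is accepted when the mapped (non-gap)
#' residues cover at least \code{min_fraction} of the domain length; the
#' projected interval is the span of the mapped positions, the depth is
#' incremented and the path extended.
#'
#' @param dom an \code{mh_domain} whose carrier is one side of \code{aln}.
#' @param aln an \code{mh_local_alignment}.
#' @param min_fraction minimum mapped fraction for acceptance.
#' @return on acceptance, the projected \code{mh_domain} (with
#'   \code{mapped_fraction} attached); otherwise a list with
#'   \code{accepted = FALSE} and the mapped fraction.
#' @export
project_domain <- function(dom, aln, min_fraction = 0.5) {
  stopifnot(inherits(dom, "mh_domain"), inherits(aln, "mh_local_alignment"))
  if (dom$carrier == aln$query_id) {
    own <- aln$q_map; other <- aln$s_map; target <- aln$subject_id
  } else if (dom$carrier == aln$subject_id) {
    own <- aln$s_map; other <- aln$q_map; target <- aln$query_id
  } else {
    stop("domain carrier '", dom$carrier, "' is not part of the alignment")
  }
  in_dom <- !is.na(own) & own >= dom$start & own <= dom$end
  mapped <- other[in_dom & !is.na(other)]
  frac <- length(mapped) / (dom$end - dom$start + 1)
  if (frac < min_fraction || length(mapped) == 0) {
    return(list(accepted = FALSE, mapped_fraction = frac))
  }
  out <- domain_annotation(dom$name, target, min(mapped), max(mapped),
                           depth = dom$depth + 1L,
                           path = c(dom$path,
                                    paste0(aln$query_id, "|", aln$subject_id)))
  attr(out, "mapped_fraction") <- frac
  out
}
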