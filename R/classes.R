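# Core containers: topologies, sequence records, annotated sequences,
# multiple sequence alignments, CA-trace structure chains.

#' Build a topology from typed segments
#'
#' A topology is an ordered set of non-overlapping segments, each of kind
#' \code{"TMS"} (transmembrane segment), \code{"RL"} (reentrant loop) or
#' \code{"LOOP"}. Coordinates are 1-based inclusive, the convention used both
#' internally and in on-disk tables. Abutting segments of identical kind are
#' merged. Positions not covered by any segment are implicitly \code{LOOP}.
#'
#' @param start,end integer segment bounds (1-based, inclusive).
#' @param kind character vector over \code{c("TMS","RL","LOOP")}.
#' @param source \code{"annotated"} or \code{"predicted"}.
#' @return an object of class \code{mh_topology} (a data frame with columns
#'   \code{start}, \code{end}, \code{kind}).
#' @examples
#' topology(c(5, 40), c(25, 60), c("TMS", "TMS"))
#' @export
topology <- function(start, end, kind, source = "annotated") {
  stopifnot(length(start) == length(end), length(end) == length(kind))
  kind <- as.character(kind)
  if (!all(kind %in% SEGMENT_KINDS)) {
    stop("segment kind must be one of ", paste(SEGMENT_KINDS, collapse = ", "))
  }
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   kind = kind, stringsAsFactors = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  if (any(df$end < df$start)) {
    i <- which(df$end < df$start)[1]
    stop(sprintf("segment %d has end < start (%d < %d)", i, df$end[i], df$start[i]))
  }
  if (nrow(df) > 1 && any(df$start[-1] <= df$end[-nrow(df)])) {
    i <- which(df$start[-1] <= df$end[-nrow(df)])[1]
    stop(sprintf("segments %d and %d overlap", i, i + 1))
  }
  # merge abutting segments of identical kind so adjacency is well defined
  if (nrow(df) > 1) {
    keep <- rep(TRUE, nrow(df))
    for (i in seq_len(nrow(df) - 1)) {
      j <- max(which(keep[seq_len(i)]))
      if (df$start[i + 1] == df$end[j] + 1 && df$kind[i + 1] == df$kind[j]) {
        df$end[j] <- df$end[i + 1]
        keep[i + 1] <- FALSE
      }
    }
    df <- df[keep, , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "source") <- source
  class(df) <- c("mh_topology", "data.frame")
  df
}

#' @keywords internal
validate_topology <- function(topo, seq_length = NULL) {
  stopifnot(inherits(topo, "mh_topology"))
  if (!is.null(seq_length) && nrow(topo) > 0 && max(topo$end) > seq_length) {
    stop("topology extends beyond sequence length ", seq_length)
  }
  invisible(topo)
}

#' Per-position segment classes of a topology
#'
#' @param topo an \code{mh_topology}.
#' @param len sequence length.
#' @return character vector of length \code{len} over
#'   \code{c("TMS","RL","LOOP")}; uncovered positions are \code{"LOOP"}.
#' @export
position_classes <- function(topo, len) {
  validate_topology(topo, len)
  cls <- rep("LOOP", len)
  for (i in seq_len(nrow(topo))) {
    cls[topo$start[i]:topo$end[i]] <- topo$kind[i]
  }
  cls
}

#' @keywords internal
membrane_segments <- function(topo) {
  topo[topo$kind %in% MEMBRANE_KINDS, , drop = FALSE]
}

# Restrict a topology to [from, to] and shift to the slice's coordinates.
#' @keywords internal
topology_slice <- function(topo, from, to) {
  keep <- topo$end >= from & topo$start <= to
  df <- topo[keep, , drop = FALSE]
  if (nrow(df) == 0) return(topology(integer(0), integer(0), character(0)))
  df$start <- pmax(df$start, from) - from + 1L
  df$end <- pmin(df$end, to) - from + 1L
  topology(df$start, df$end, df$kind, source = attr(topo, "source"))
}

#' @keywords internal
shift_topology <- function(topo, offset) {
  if (nrow(topo) == 0) return(topo)
  topology(topo$start + offset, topo$end + offset, topo$kind,
           source = attr(topo, "source"))
}

#' Create a sequence record
#'
#' @param id identifier (first whitespace-delimited token of a FASTA header).
#' @param residues uppercase amino-acid string over the 20 standard letters
#'   plus \code{X}; \code{-} is permitted only in aligned records.
#' @param description free-text description.
#' @param aligned logical; allow gap characters.
#' @return an object of class \code{mh_sequence}.
#' @export
sequence_record <- function(id, residues, description = "", aligned = FALSE) {
  residues <- toupper(residues)
  if (nchar(residues) == 0) stop("residues must be non-empty")
  allowed <- c(AA_ALPHABET_X, if (aligned) "-")
  ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!(ch %in% allowed))
  if (length(bad) > 0) {
    stop(sprintf("illegal character '%s' at position %d in sequence '%s'",
                 ch[bad[1]], bad[1], id))
  }
  structure(list(id = id, residues = residues, description = description),
            class = "mh_sequence")
}

#' Attach a topology to a sequence
#'
#' @param id identifier.
#' @param residues amino-acid string.
#' @param topo an \code{mh_topology} within the sequence bounds.
#' @param description free text.
#' @return an object of class \code{c("mh_annotated_sequence","mh_sequence")}.
#' @export
annotated_sequence <- function(id, residues, topo, description = "") {
  rec <- sequence_record(id, residues, description)
  validate_topology(topo, nchar(rec$residues))
  rec$topology <- topo
  class(rec) <- c("mh_annotated_sequence", "mh_sequence")
  rec
}

#' @export
print.mh_sequence <- function(x, ...) {
  cat(sprintf(">%s %s\n%d aa", x$id, x$description, nchar(x$residues)))
  if (!is.null(x$topology)) {
    k <- table(factor(x$topology$kind, SEGMENT_KINDS))
    cat(sprintf("  [%d TMS, %d RL, %d annotated loops]",
                k[["TMS"]], k[["RL"]], k[["LOOP"]]))
  }
  cat("\n")
  invisible(x)
}

#' Multiple sequence alignment container
#'
#' @param records list of aligned \code{mh_sequence} records (equal lengths,
#'   gaps as \code{-}) or a named character vector of aligned rows.
#' @param topo optional consensus \code{mh_topology} in column coordinates.
#' @param id alignment identifier.
#' @return an object of class \code{mh_msa} with fields \code{ids},
#'   \code{rows}, \code{topology}, \code{id}.
#' @export
msa <- function(records, topo = NULL, id = "msa") {
  if (is.character(records)) {
    rows <- unname(records)
    ids <- names(records)
    if (is.null(ids)) ids <- paste0("row", seq_along(rows))
  } else {
    rows <- vapply(records, residues_of, character(1))
    ids <- vapply(seq_along(records), function(i) id_of(records[[i]], paste0("row", i)),
                  character(1))
  }
  L <- unique(nchar(rows))
  if (length(L) != 1) stop("alignment rows must have equal length")
  if (!is.null(topo)) validate_topology(topo, L)
  structure(list(ids = ids, rows = toupper(rows), topology = topo, id = id),
            class = "mh_msa")
}

#' @export
print.mh_msa <- function(x, ...) {
  cat(sprintf("MSA '%s': %d rows x %d columns\n", x$id, length(x$rows),
              nchar(x$rows[1])))
  invisible(x)
}

#' @keywords internal
msa_ncol <- function(m) nchar(m$rows[1])

#' CA-trace structure chain
#'
#' @param xyz numeric n x 3 matrix of alpha-carbon coordinates (Angstrom).
#' @param resno integer residue numbers, strictly increasing.
#' @param labels optional per-residue segment labels
#'   (\code{"TMS"}, \code{"RL"}, \code{"LOOP"}).
#' @param residues optional per-residue one-letter codes.
#' @param id chain identifier.
#' @return an object of class \code{mh_structure}.
#' @export
structure_chain <- function(xyz, resno = seq_len(nrow(xyz)), labels = NULL,
                            residues = NULL, id = "chain") {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, length(resno) == nrow(xyz))
  if (is.unsorted(resno, strictly = TRUE)) {
    stop("residue numbers must be strictly increasing")
  }
  if (!is.null(labels)) stopifnot(length(labels) == nrow(xyz))
  structure(list(xyz = unname(xyz), resno = as.integer(resno),
                 labels = labels, residues = residues, id = id),
            class = "mh_structure")
}

#' @export
print.mh_structure <- function(x, ...) {
  cat(sprintf("Structure chain '%s': %d CA atoms\n", x$id, nrow(x$xyz)))
  invisible(x)
}

# Convert per-residue labels to run-length segments.
#' @keywords internal
labels_to_segments <- function(labels) {
  r <- rle(labels)
  end <- cumsum(r$lengths)
  data.frame(start = end - r$lengths + 1L, end = end, kind = r$values,
             stringsAsFactors = FALSE)
}
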