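# Readers and writers: FASTA (plain and aligned), topology TSV tables,
# Newick dendrograms, CA coordinates from PDB/mmCIF, JSON run configuration.

#' Read a FASTA file
#'
#' @param path file path.
#' @param aligned logical; allow gap characters (\code{-}) for aligned FASTA.
#' @return list of \code{mh_sequence} records, in file order, residues
#'   uppercased.
#' @export
parse_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error in ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  lapply(seq_along(set), function(i) {
    sequence_record(ids[i], as.character(set[[i]]), descs[i], aligned = aligned)
  })
}

#' Write sequence records to FASTA
#'
#' @param records non-empty list of \code{mh_sequence} records.
#' @param path output path.
#' @param width line-wrap width in characters.
#' @return \code{path}, invisibly. \code{parse_fasta(emit_fasta(x))} returns
#'   \code{x} unchanged.
#' @export
emit_fasta <- function(records, path, width = 60) {
  if (length(records) == 0) stop("no records to write")
  stopifnot(width >= 1)
  headers <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, character(1))
  set <- Biostrings::BStringSet(vapply(records, residues_of, character(1)))
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read a topology table
#'
#' The table is tab-separated with columns \code{id}, \code{start},
#' \code{end}, \code{kind} (\code{TMS}/\code{RL}/\code{LOOP}); coordinates
#' are 1-based inclusive. A header row is optional.
#'
#' @param path file path.
#' @return named list of \code{mh_topology}, one per sequence id.
#' @export
read_topology_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  header <- grepl("^id\\t", first)
  df <- if (header) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, sep = "\t", header = FALSE,
                      col.names = c("id", "start", "end", "kind"),
                      stringsAsFactors = FALSE)
  }
  names(df) <- c("id", "start", "end", "kind")
  out <- lapply(split(df, factor(df$id, unique(df$id))), function(d) {
    tryCatch(topology(d$start, d$end, d$kind),
             error = function(e) stop("invalid topology for '", d$id[1], "': ",
                                      conditionMessage(e)))
  })
  out
}

#' Write topologies to a TSV table
#'
#' Inverse of \code{\link{read_topology_table}}.
#'
#' @param topos named list of \code{mh_topology}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_topology_table <- function(topos, path) {
  stopifnot(length(topos) > 0, !is.null(names(topos)))
  rows <- do.call(rbind, lapply(names(topos), function(id) {
    t <- topos[[id]]
    data.frame(id = id, start = t$start, end = t$end, kind = t$kind,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read alpha-carbon coordinates from a PDB or mmCIF file
#'
#' Only the CA trace is read; alternate locations are resolved to the
#' highest-occupancy record per residue.
#'
#' @param path PDB (\code{.pdb}/\code{.ent}) or mmCIF (\code{.cif}) file.
#' @param chain chain identifier.
#' @return an \code{mh_structure}.
#' @export
read_ca_coordinates <- function(path, chain) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path, rm.alt = FALSE)
  } else {
    bio3d::read.pdb(path, rm.alt = FALSE)
  }
  at <- pdb$atom
  if (!chain %in% unique(at$chain)) {
    stop("chain '", chain, "' not present in ", path)
  }
  ca <- at[at$chain == chain & at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0) stop("chain '", chain, "' has no CA atoms")
  if (is.null(ca$o)) ca$o <- 1
  ca <- ca[order(ca$resno, -ca$o), , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  structure_chain(cbind(ca$x, ca$y, ca$z), resno = ca$resno,
                  id = paste0(basename(path), "_", chain))
}

#' @keywords internal
quote_newick_label <- function(lab) {
  if (grepl("[][()':;, \t]", lab)) {
    paste0("'", gsub("'", "''", lab), "'")
  } else lab
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are merge-height differences (leaves sit at height zero).
#' Labels containing Newick metacharacters are quoted. The output parses
#' with standard Newick readers such as \code{ape::read.tree}.
#'
#' @param tree an \code{mh_dendrogram} (see \code{\link{ward_tree}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "mh_dendrogram"))
  labs <- tree$labels
  if (length(labs) < 2) stop("tree must have at least 2 leaves")
  if (anyDuplicated(labs)) {
    stop("duplicate leaf labels: ", labs[duplicated(labs)][1])
  }
  node_str <- function(node, parent_height) {
    if (node < 0) {
      sprintf("%s:%.6g", quote_newick_label(labs[-node]), parent_height)
    } else {
      h <- tree$height[node]
      kids <- tree$merge[node, ]
      sprintf("(%s,%s):%.6g", node_str(kids[1], h), node_str(kids[2], h),
              parent_height - h)
    }
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  kids <- tree$merge[root, ]
  txt <- sprintf("(%s,%s);", node_str(kids[1], h), node_str(kids[2], h))
  writeLines(txt, path)
  invisible(path)
}

#' Run configuration
#'
#' Global parameter set shared by the pipeline stages: the scoring scheme,
#' shuffle count for the null models, significance thresholds, and the
#' master seed from which every random stream in a run is derived.
#'
#' @param scheme scoring scheme name (see \code{\link{scoring_scheme}}).
#' @param gap_open,gap_extend gap penalties (score units, > 0); \code{NULL}
#'   takes the preset's defaults.
#' @param n_shuffles shuffle count for null models (>= 100).
#' @param evalue_threshold pairwise-alignment significance threshold.
#' @param shuffle_p_threshold GEV p-value threshold for sequence-level nulls.
#' @param profile_p_threshold GEV p-value threshold for profile comparison.
#' @param motif_evalue_threshold motif scan E-value threshold.
#' @param recovery_threshold minimum motif recovery rate (fraction) for the
#'   motif evidence line.
#' @param seed master seed (integer).
#' @return an object of class \code{mh_run_config}.
#' @export
run_config <- function(scheme = "BLOSUM62", gap_open = NULL, gap_extend = NULL,
                       n_shuffles = 10000, evalue_threshold = 1e-4,
                       shuffle_p_threshold = 1e-3, profile_p_threshold = 0.01,
                       motif_evalue_threshold = 1e-4, recovery_threshold = 0.5,
                       seed = 1L) {
  sc <- scoring_scheme(scheme, gap_open = gap_open, gap_extend = gap_extend)
  stopifnot(n_shuffles >= 100)
  for (p in c(evalue_threshold, shuffle_p_threshold, profile_p_threshold,
              motif_evalue_threshold, recovery_threshold)) {
    if (!(p > 0 && p < 1)) stop("thresholds must lie in (0, 1)")
  }
  structure(list(scheme = sc, n_shuffles = as.integer(n_shuffles),
                 evalue_threshold = evalue_threshold,
                 shuffle_p_threshold = shuffle_p_threshold,
                 profile_p_threshold = profile_p_threshold,
                 motif_evalue_threshold = motif_evalue_threshold,
                 recovery_threshold = recovery_threshold,
                 seed = as.integer(seed)),
            class = "mh_run_config")
}

#' Write a run configuration to JSON
#' @param config an \code{mh_run_config}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "mh_run_config"))
  x <- config
  x$scheme <- list(name = config$scheme$name, gap_open = config$scheme$gap_open,
                   gap_extend = config$scheme$gap_extend,
                   lambda = config$scheme$lambda, K = config$scheme$K)
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration from JSON
#' @param path JSON file written by \code{\link{write_run_config}}.
#' @return an \code{mh_run_config}.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(scheme = x$scheme$name, gap_open = x$scheme$gap_open,
             gap_extend = x$scheme$gap_extend, n_shuffles = x$n_shuffles,
             evalue_threshold = x$evalue_threshold,
             shuffle_p_threshold = x$shuffle_p_threshold,
             profile_p_threshold = x$profile_p_threshold,
             motif_evalue_threshold = x$motif_evalue_threshold,
             recovery_threshold = x$recovery_threshold, seed = x$seed)
}
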