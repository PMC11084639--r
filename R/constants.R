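# Fixed tables: amino-acid alphabet, Kyte-Doolittle hydropathy, background
# and membrane-segment residue compositions, substitution-matrix schemes.

#' @keywords internal
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @keywords internal
AA_ALPHABET_X <- c(AA20, "X")

# Kyte & Doolittle (1982) hydropathy scale.
#' @keywords internal
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

# Robinson & Robinson amino-acid background frequencies (soluble proteins).
#' @keywords internal
RR_BACKGROUND <- local({
  f <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
         Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
         L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
         S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
  f / sum(f)
})

# Membrane-segment (TMS / reentrant-loop) residue model: 80% of the mass on
# the hydrophobic set {I,L,V,F,A,M,W,G,C}, weighted toward the residues that
# dominate real transmembrane helices, and the remaining 20% on the small
# polar residues tolerated inside the bilayer (S/T-rich, almost no charges).
#' @keywords internal
TMS_COMPOSITION <- local({
  hydro <- c(L = 0.30, I = 0.25, V = 0.20, F = 0.10, A = 0.08,
             M = 0.04, G = 0.02, C = 0.005, W = 0.005)
  polar <- c(S = 0.35, T = 0.30, Y = 0.15, P = 0.10, N = 0.04,
             Q = 0.03, H = 0.03)
  p <- setNames(numeric(20), AA20)
  p[names(hydro)] <- 0.8 * hydro / sum(hydro)
  p[names(polar)] <- 0.2 * polar / sum(polar)
  p
})

#' @keywords internal
HYDROPHOBIC_SET <- c("I", "L", "V", "F", "A", "M", "W", "G", "C")

MEMBRANE_KINDS <- c("TMS", "RL")
SEGMENT_KINDS <- c("TMS", "RL", "LOOP")

.mh_env <- new.env(parent = emptyenv())

# Substitution matrix over the 20 standard residues plus X; X scores 0
# against everything.
#' @keywords internal
get_submat <- function(name) {
  key <- paste0("submat_", name)
  if (!is.null(.mh_env[[key]])) return(.mh_env[[key]])
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- e[[name]][AA_ALPHABET_X, AA_ALPHABET_X]
  m["X", ] <- 0
  m[, "X"] <- 0
  storage.mode(m) <- "double"
  .mh_env[[key]] <- m
  m
}

#' Scoring scheme for local alignment
#'
#' Bundles a substitution matrix with affine gap penalties and the
#' Karlin-Altschul parameters used to convert raw scores into bit scores and
#' E-values. A gap of length \eqn{k} costs \code{gap_open + k * gap_extend}.
#' Two presets are provided: \code{"BLOSUM62"} (gap 11/1, the standard gapped
#' \eqn{\lambda = 0.267}, \eqn{K = 0.041}) and \code{"BLOSUM50"} with
#' SSEARCH-style penalties 10/2 (\eqn{\lambda = 0.158}, \eqn{K = 0.019}).
#'
#' @param name substitution matrix preset, \code{"BLOSUM62"} or
#'   \code{"BLOSUM50"}.
#' @param gap_open,gap_extend positive gap penalties in raw score units;
#'   defaults depend on the preset.
#' @param lambda,K Karlin-Altschul parameters; defaults depend on the preset.
#' @return an object of class \code{mh_scoring_scheme}.
#' @examples
#' sc <- scoring_scheme()
#' sc$gap_open
#' @export
scoring_scheme <- function(name = c("BLOSUM62", "BLOSUM50"),
                           gap_open = NULL, gap_extend = NULL,
                           lambda = NULL, K = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    BLOSUM62 = list(gap_open = 11, gap_extend = 1, lambda = 0.267, K = 0.041),
    BLOSUM50 = list(gap_open = 10, gap_extend = 2, lambda = 0.158, K = 0.019))
  gap_open <- if (is.null(gap_open)) defaults$gap_open else gap_open
  gap_extend <- if (is.null(gap_extend)) defaults$gap_extend else gap_extend
  lambda <- if (is.null(lambda)) defaults$lambda else lambda
  K <- if (is.null(K)) defaults$K else K
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, K > 0)
  structure(list(name = name, matrix = get_submat(name),
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "mh_scoring_scheme")
}

#' @export
print.mh_scoring_scheme <- function(x, ...) {
  cat(sprintf("Scoring scheme %s  gap %g/%g  lambda %g  K %g\n",
              x$name, x$gap_open, x$gap_extend, x$lambda, x$K))
  invisible(x)
}
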