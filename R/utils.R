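# Seed management and small shared helpers.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the random seed, evaluates \code{expr}, and restores the previous RNG
#' state, so seeded operations never disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a deterministic sub-seed
#'
#' Hashes a master seed and a stream index into a new seed, so independent
#' random streams can be derived reproducibly from one master seed. Values
#' stay well inside the 32-bit integer range (and exact in double
#' arithmetic).
#'
#' @param seed master seed (integer).
#' @param i stream index (integer).
#' @return an integer seed.
#' @export
subseed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) %% 1e6 * 2654435 + as.numeric(i) * 9973 + 17) %%
               2147483629)
}

#' @keywords internal
encode_residues <- function(residues) {
  v <- match(strsplit(residues, "", fixed = TRUE)[[1]], AA_ALPHABET_X)
  if (anyNA(v)) {
    stop("illegal residue character at position ", which(is.na(v))[1])
  }
  v
}

#' @keywords internal
residues_of <- function(x) {
  if (is.character(x)) return(x)
  if (is.list(x) && !is.null(x$residues)) return(x$residues)
  stop("cannot extract residues from object of class ", class(x)[1])
}

#' @keywords internal
id_of <- function(x, default = "seq") {
  if (is.list(x) && !is.null(x$id)) x$id else default
}

#' @keywords internal
mh_log <- function(...) {
  if (isTRUE(getOption("memhomology.verbose", FALSE))) {
    message("[memhomology] ", sprintf(...))
  }
  invisible(NULL)
}

# Digest used when logging pipeline stage inputs: cheap, dependency-free.
#' @keywords internal
mh_digest <- function(x) {
  s <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}
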