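# Shared fixtures and independent oracles used across the suite.

AA <- c("A","R","N","D","C","Q","E","G","H","I",
        "L","K","M","F","P","S","T","W","Y","V")

KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
        E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
        M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
        Y = -1.3, V = 4.2)

random_aa <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

# Naive exhaustive affine-gap local DP: the independent scoring oracle.
# Plain three-matrix recurrences over every cell, no vectorization.
naive_sw_score <- function(x, y, scheme) {
  xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
  m <- length(xs); n <- length(ys)
  S <- scheme$matrix; go <- scheme$gap_open; ge <- scheme$gap_extend
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i - 1, j] - go - ge, E[i - 1, j] - ge)
      F[i, j] <- max(H[i, j - 1] - go - ge, F[i, j - 1] - ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + S[xs[i - 1], ys[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# One family of n members at the given divergence from a fresh 3+1 ancestor.
make_family <- function(seed, n = 8, divergence = 0.3, split = NULL,
                        prefix = "f", indel_rate = 0.05) {
  spec <- make_topology_spec("3+1")
  anc <- sample_ancestor(spec, subseed(seed, 1))
  if (!is.null(split)) {
    anc <- evolve_family(anc, 1, split, subseed(seed, 2),
                         indel_rate = 0)$members[[1]]
  }
  evolve_family(anc, n, divergence, subseed(seed, 3), prefix = prefix,
                indel_rate = indel_rate)$members
}

# Tandem-duplicated 3-TMS family (no indels, so the raw sequences stack
# into an alignment and the ancestor topology is the consensus).
make_tandem_family <- function(seed, n = 6, unit_div = 0.4, fam_div = 0.15) {
  unit_spec <- make_topology_spec("3", tms_len = 21, short_loop = 15)
  unit <- sample_ancestor(unit_spec, subseed(seed, 1), id = paste0("t", seed))
  tandem <- compose_architectures(unit, mode = "tandem", linker = 25,
                                  divergence = unit_div,
                                  seed = subseed(seed, 2))
  evolve_family(tandem, n, fam_div, seed = subseed(seed, 3),
                indel_rate = 0)$members
}

# Matched 6-TMS family without duplication (the repeat-finder control).
make_control_family <- function(seed, n = 6, fam_div = 0.15) {
  spec <- make_topology_spec("3+3", tms_len = 21, short_loop = 15,
                             long_loop = 25)
  anc <- sample_ancestor(spec, subseed(seed, 1))
  evolve_family(anc, n, fam_div, seed = subseed(seed, 3),
                indel_rate = 0)$members
}
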