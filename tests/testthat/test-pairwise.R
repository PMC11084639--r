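test_that("identical sequences align fully with 100% identity", {
  aln <- smith_waterman("MKTAYIAKQR", "MKTAYIAKQR")
  expect_equal(aln$pident, 100)
  expect_equal(aln$coverage, 1)
  expect_equal(aln$q_start, 1)
  expect_equal(aln$q_end, 10)
  expect_error(smith_waterman("", "MKT"), "non-empty")
})

test_that("aligner matches the exhaustive DP oracle on random small pairs", {
  sc <- scoring_scheme()
  with_seed(42, {
    for (k in 1:50) {
      x <- random_aa(sample(3:12, 1))
      y <- random_aa(sample(3:12, 1))
      expect_equal(smith_waterman(x, y, sc)$raw, naive_sw_score(x, y, sc))
    }
  })
})

test_that("aligner agrees with an independent reference implementation", {
  sc <- scoring_scheme()
  with_seed(17, {
    for (k in 1:10) {
      x <- random_aa(40)
      y <- random_aa(35)
      ref <- Biostrings::pairwiseAlignment(
        x, y, substitutionMatrix = sc$matrix[1:20, 1:20],
        gapOpening = sc$gap_open, gapExtension = sc$gap_extend,
        type = "local", scoreOnly = TRUE)
      expect_equal(smith_waterman(x, y, sc)$raw, ref)
    }
  })
})

test_that("all-negative score pairs produce a flagged empty alignment", {
  aln <- smith_waterman(strrep("K", 12), strrep("D", 12))
  expect_true(aln$empty)
  expect_equal(aln$raw, 0)
  expect_equal(aln$coverage, 0)
})

test_that("score is symmetric and never decreases under sequence extension", {
  with_seed(5, {
    for (k in 1:10) {
      x <- random_aa(30); y <- random_aa(30)
      expect_equal(smith_waterman(x, y)$raw, smith_waterman(y, x)$raw)
      ext <- paste0(y, random_aa(10))
      expect_gte(smith_waterman(x, ext)$raw, smith_waterman(x, y)$raw)
    }
  })
})

test_that("X residues score zero against everything", {
  sc <- scoring_scheme()
  a <- smith_waterman("MKTXXAYI", "MKTAYI", sc)
  b <- smith_waterman("MKTAYI", "MKTAYI", sc)
  expect_lte(a$raw, b$raw)
  expect_true(all(sc$matrix["X", ] == 0))
})

test_that("Karlin-Altschul conversion matches direct arithmetic and is monotone", {
  sc <- scoring_scheme()  # lambda 0.267, K 0.041
  ka <- bitscore_evalue(100, 300, 300, sc)
  expect_equal(ka$evalue, 0.041 * 9e4 * exp(-26.7), tolerance = 1e-10)
  expect_equal(ka$bits, (0.267 * 100 - log(0.041)) / log(2), tolerance = 1e-10)
  expect_false(ka$floored)
  floor0 <- bitscore_evalue(0, 300, 300, sc)
  expect_equal(floor0$bits, 0)
  expect_true(floor0$floored)
  raws <- seq(10, 200, by = 10)
  es <- vapply(raws, function(r) bitscore_evalue(r, 300, 300, sc)$evalue,
               numeric(1))
  expect_true(all(diff(es) < 0))
})

test_that("TMS coverage filter applies the 50% residue rule on both sides", {
  spec <- make_topology_spec("3+1")
  a <- sample_ancestor(spec, 3)
  full <- smith_waterman(a, a)
  expect_true(tms_coverage_filter(full, a$topology, a$topology, 3)$accept)

  # alignment confined to the long loop covers no membrane segment
  loop_aln <- full
  keep <- !is.na(full$q_map) & full$q_map >= 100 & full$q_map <= 200
  loop_aln$q_map <- full$q_map[keep]
  loop_aln$s_map <- full$s_map[keep]
  cov <- tms_coverage_filter(loop_aln, a$topology, a$topology, 3)
  expect_false(cov$accept)
  expect_equal(cov$covered_query, 0L)

  # boundary: aligned interval covering exactly half of a 20-residue TMS
  topo <- topology(c(1, 31, 61), c(20, 50, 80), c("TMS", "TMS", "TMS"))
  half <- full
  half$q_map <- half$s_map <- 1:40  # TMS1 fully, TMS2 10/20 residues
  cov2 <- tms_coverage_filter(half, topo, topo, 2)
  expect_true(cov2$accept)          # >= 50% counts as covered
  expect_equal(cov2$covered_query, 2L)
  half$q_map <- half$s_map <- 1:39  # TMS2 at 9/20 < 50%
  expect_equal(tms_coverage_filter(half, topo, topo, 2)$covered_query, 1L)
})

test_that("greedy redundancy reduction drops near-duplicates only", {
  a <- sequence_record("a", random_aa(60))
  dup <- sequence_record("a2", a$residues)
  expect_length(reduce_redundancy(list(a, dup)), 1)

  spec31 <- make_topology_spec("3+1")
  distinct <- lapply(1:4, function(i) {
    sample_ancestor(spec31, 5000 + i, id = paste0("s", i))
  })
  expect_length(reduce_redundancy(distinct, identity_threshold = 0.9), 4)

  anc <- sample_ancestor(make_topology_spec("3+1"), 12)
  copies <- evolve_family(anc, 10, 0.02, seed = 3, indel_rate = 0)$members
  unrelated <- sample_ancestor(make_topology_spec("3+1"), 55, id = "other")
  kept <- reduce_redundancy(c(copies, list(unrelated)), 0.9)
  expect_length(kept, 2)
})

test_that("transitivity paths require junction overlaps on the shared protein", {
  mk_aln <- function(q, s, qs, qe, ss, se) {
    structure(list(query_id = q, subject_id = s, q_start = qs, q_end = qe,
                   s_start = ss, s_end = se, evalue = 1e-6),
              class = "mh_local_alignment")
  }
  ab <- mk_aln("A", "B", 1, 180, 10, 199)
  bc <- mk_aln("B", "C", 50, 229, 5, 190)
  path <- assemble_transitive_path(list(ab, bc), min_junction_overlap = 30)
  expect_true(path$accept)
  expect_equal(path$overlaps, 150L)
  expect_equal(path$ids, c("A", "B", "C"))

  bc_far <- mk_aln("B", "C", 300, 400, 5, 100)
  expect_false(assemble_transitive_path(list(ab, bc_far), 30)$accept)
  cd <- mk_aln("C", "D", 1, 100, 1, 100)
  expect_error(assemble_transitive_path(list(ab, cd), 30), "junction 1")
})

test_that("a four-protein chain of synthetic homologs is accepted with significant links", {
  spec <- make_topology_spec("3+1")
  anc <- sample_ancestor(spec, 71, id = "A")
  b <- evolve_family(anc, 1, 0.3, seed = 72, prefix = "B")$members[[1]]
  c_ <- evolve_family(b, 1, 0.3, seed = 73, prefix = "C")$members[[1]]
  d <- evolve_family(c_, 1, 0.3, seed = 74, prefix = "D")$members[[1]]
  links <- list(smith_waterman(anc, b), smith_waterman(b, c_),
                smith_waterman(c_, d))
  path <- assemble_transitive_path(links, min_junction_overlap = 30)
  expect_true(path$accept)
  expect_true(all(path$evalues <= 1e-4))
})
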