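test_that("profile frequencies respect counts, pseudocounts and gap flags", {
  m <- msa(c(a = "AAC-", b = "AA--", c = "AACD", d = "AACD", e = "AACD"))
  p0 <- build_profile(m, pseudocount_weight = 0)
  expect_equal(unname(p0$freq["A", 1]), 1)
  expect_equal(unname(p0$freq["C", 3]), 1)
  expect_equal(p0$gap_fraction, c(0, 0, 0.2, 0.4))
  expect_equal(p0$flagged, c(FALSE, FALSE, FALSE, TRUE))
  expect_true(all(abs(colSums(p0$freq) - 1) < 1e-9))

  single <- suppressWarnings(build_profile(msa(c(x = "AC")), 1.0))
  expect_gt(single$freq["A", 1], 0.5)       # delta smoothed by pseudocounts
  expect_true(all(single$freq[, 1] > 0))
  # row order invariance
  p1 <- build_profile(m)
  p2 <- build_profile(msa(c(e = "AACD", b = "AA--", a = "AAC-", d = "AACD",
                            c = "AACD")))
  expect_equal(unname(p1$freq), unname(p2$freq))
})

test_that("seed gaps are injected as all-gap columns at the mapped positions", {
  flank <- "WNDPHTQRCEYGKMS"
  qres <- paste0(flank, "A", flank)
  sres <- paste0(flank, flank)
  msaA <- msa(stats::setNames(rep(qres, 2), c("s1", "s2")))
  msaB <- msa(stats::setNames(rep(sres, 2), c("t1", "t2")))
  # seed alignment: the middle query residue faces a gap in the subject
  seed_aln <- smith_waterman(qres, sres)
  seed_aln$query_id <- "s1"; seed_aln$subject_id <- "t1"
  expect_equal(sum(is.na(seed_aln$s_map)), 1)
  out <- inject_seed_gaps(msaA, msaB, seed_aln)
  expect_equal(nchar(out[[1]]$rows[1]), nchar(out[[2]]$rows[1]))
  degap <- function(x) gsub("-", "", x)
  expect_equal(degap(out[[2]]$rows[1]), sres)
  # the seed rows now reproduce the pairwise gapping column by column
  qa <- strsplit(out[[1]]$rows[1], "")[[1]]
  qb <- strsplit(out[[2]]$rows[1], "")[[1]]
  expect_equal(sum(qa != "-" & qb == "-"), sum(is.na(seed_aln$s_map)))

  none <- smith_waterman(qres, qres)
  none$query_id <- "s1"; none$subject_id <- "t1"
  un <- inject_seed_gaps(msaA, msa(stats::setNames(qres, "t1")), none)
  expect_identical(un[[1]]$rows, msaA$rows)
  bad <- none; bad$query_id <- "absent"
  expect_error(inject_seed_gaps(msaA, msaB, bad), "absent")
})

test_that("a three-column seed gap creates three all-gap columns", {
  flank <- "WNDPHTQRCEYGKMS"
  qres <- paste0(flank, "AAA", flank)
  sres <- paste0(flank, flank)
  msaA <- msa(stats::setNames(rep(qres, 2), c("s1", "s2")))
  msaB <- msa(stats::setNames(rep(sres, 2), c("t1", "t2")))
  seed_aln <- smith_waterman(qres, sres)
  seed_aln$query_id <- "s1"; seed_aln$subject_id <- "t1"
  expect_equal(sum(is.na(seed_aln$s_map)), 3)
  out <- inject_seed_gaps(msaA, msaB, seed_aln)
  added <- nchar(out[[2]]$rows[1]) - nchar(msaB$rows[1])
  expect_equal(added, 3)
  cols <- do.call(rbind, strsplit(out[[2]]$rows, ""))
  all_gap <- which(colSums(cols == "-") == nrow(cols))
  expect_length(all_gap, 3)
})

test_that("profile-profile alignment scores delta profiles in closed form", {
  bg <- memhomology:::RR_BACKGROUND
  cons <- "MKWYH"
  delta <- function(id) {
    build_profile(msa(stats::setNames(rep(cons, 5), paste0(id, 1:5))),
                  pseudocount_weight = 0)
  }
  p1 <- delta("a"); p2 <- delta("b")
  aln <- profile_profile_align(p1, p2)
  expected <- sum(log2(1 / bg[strsplit(cons, "")[[1]]]))
  expect_equal(aln$score, unname(expected), tolerance = 1e-9)
  expect_equal(aln$q_map, 1:5)
  expect_equal(aln$s_map, 1:5)
  # self-alignment of an informative profile maps the identity
  fam <- make_family(301, n = 6, divergence = 0.2)
  pr <- build_profile(quick_msa(fam))
  self <- profile_profile_align(pr, pr, include_loops = TRUE)
  expect_true(all(self$q_map == self$s_map, na.rm = TRUE))
  # reversing the columns changes the optimum: no spurious symmetry
  rev_p <- pr; rev_p$freq <- pr$freq[, rev(seq_len(ncol(pr$freq)))]
  rev_p$labels <- rev(pr$labels)
  expect_false(isTRUE(all.equal(profile_profile_align(pr, rev_p)$score,
                                self$score)))
})

test_that("family comparison separates shared ancestry from matched topology", {
  spec <- make_topology_spec("3+1")
  root <- sample_ancestor(spec, 77)
  mkfam <- function(s, pre) {
    anc <- evolve_family(root, 1, 0.4, s, indel_rate = 0)$members[[1]]
    evolve_family(anc, 8, 0.3, subseed(s, 5), prefix = pre)$members
  }
  fa <- mkfam(1, "fa"); fb <- mkfam(2, "fb")
  msaA <- quick_msa(fa, id = "A"); msaB <- quick_msa(fb, id = "B")
  same <- family_compare(msaA, msaB, n_shuffles = 300, seed = 5)
  expect_lte(same$p_value, 1e-3)
  other <- evolve_family(sample_ancestor(spec, 5077), 8, 0.3, 99,
                         prefix = "fc")$members
  indep <- family_compare(msaA, quick_msa(other, id = "C"),
                          n_shuffles = 300, seed = 6)
  expect_gt(indep$p_value, 0.01)
  expect_error(family_compare(msaA, msaB, n_shuffles = 10), "at least 100")
})
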