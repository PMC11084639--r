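test_that("OOPS discovery validates width and keeps the likelihood non-decreasing", {
  seqs <- with_seed(1, lapply(1:10, function(i) {
    sequence_record(paste0("s", i), random_aa(40))
  }))
  expect_error(discover_motif_oops(seqs, width = 5, seed = 1), "\\[8, 50\\]")
  expect_error(discover_motif_oops(seqs, width = 51, seed = 1), "\\[8, 50\\]")
  expect_error(discover_motif_oops(seqs, width = 45, seed = 1), "at least")
  disc <- discover_motif_oops(seqs, width = 10, n_starts = 2, seed = 1,
                              n_screen = 10)
  expect_true(all(diff(disc$loglik_trace) > -1e-6))
  expect_equal(disc$pwm$width, 10)
  expect_true(all(abs(colSums(disc$pwm$mat) - 1) < 1e-9))
})

test_that("an implanted motif in random sequences is recovered position by position", {
  cons <- "WNDPHTQRCEYGKMSAHWQRNDECYKGMSTAWN"  # 33 positions
  pwm <- pwm_from_consensus(substr(cons, 1, 33), conservation = 0.95)
  seqs <- with_seed(9, lapply(1:30, function(i) {
    base <- strsplit(random_aa(80), "")[[1]]
    site <- vapply(seq_len(33), function(k) {
      sample(AA, 1, prob = pwm$mat[, k])
    }, character(1))
    base[21:53] <- site
    sequence_record(paste0("s", i), paste(base, collapse = ""))
  }))
  disc <- discover_motif_oops(seqs, width = 33, n_starts = 3, seed = 2,
                              n_screen = 60)
  got <- strsplit(pwm_consensus(disc$pwm), "")[[1]]
  want <- strsplit(substr(cons, 1, 33), "")[[1]]
  expect_gte(sum(got == want), 30)
  expect_true(all(abs(disc$sites$start - 21) <= 2))
})

test_that("the exact window-score null is a proper distribution with the right tail", {
  pwm <- pwm_from_consensus("WNDPHTQRCEYG", conservation = 0.9)
  dist <- pwm_score_distribution(pwm)
  expect_equal(sum(dist$prob), 1, tolerance = 1e-9)
  # maximum achievable score: every position at its argmax residue
  bg <- pwm$background
  best_res <- apply(pwm$mat, 2, which.max)
  p_max <- prod(bg[best_res])
  expect_equal(dist$tail[length(dist$tail)], unname(p_max), tolerance = 1e-9)
  # a width-1 PWM's distribution is the background-weighted log-odds table
  p1 <- memhomology:::new_pwm(matrix(pwm$mat[, 1], ncol = 1), bg)
  d1 <- pwm_score_distribution(p1)
  lo <- log2(p1$mat[, 1] / bg)
  expect_equal(sum(d1$prob[d1$prob > 0]), 1, tolerance = 1e-9)
  expect_equal(length(unique(round(lo, 2))),
               sum(d1$prob > 0))
})

test_that("window p-values are uniform on background sequences", {
  pwm <- pwm_from_consensus("WNDPHTQRCEYG", conservation = 0.9)
  dist <- pwm_score_distribution(pwm)
  # the null is discrete, so uniformity is checked on randomized p-values
  # p' = P(S > s) + U * P(S = s), which are exactly uniform iff the atoms
  # and tail of the computed distribution are correct; scores are taken on
  # the distribution's own discretization grid
  lo_bin <- round(log2(pwm$mat / pwm$background) / dist$resolution)
  ps <- with_seed(3, vapply(1:1000, function(i) {
    win <- sample(20, 12, replace = TRUE, prob = pwm$background)
    s <- sum(lo_bin[cbind(win, 1:12)]) * dist$resolution
    p_ge <- memhomology:::tail_probability(dist, s)
    atom <- p_ge - memhomology:::tail_probability(dist, s + dist$resolution)
    p_ge - stats::runif(1) * atom
  }, numeric(1)))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("scanning recovers implanted members and stays silent on background", {
  spec <- make_topology_spec("3+1")
  fam <- evolve_family(sample_ancestor(spec, 61), 40, 2.0, seed = 62)$members
  pwm <- pwm_from_consensus("WNDPHTQRCEYGKMS", conservation = 0.9)
  imp <- implant_motif(fam, pwm, 6, 0.9, seed = 63, among = "all")
  hits <- scan_sequences(pwm, imp$members, evalue_threshold = 1e-4)
  implanted <- names(imp$truth$implants)[!vapply(imp$truth$implants, is.null,
                                                 logical(1))]
  expect_gte(mean(implanted %in% hits$id), 0.9)
  bg_seqs <- lapply(1:40, function(i) {
    sample_ancestor(spec, 8000 + i, id = paste0("bg", i))
  })
  expect_lte(nrow(scan_sequences(pwm, bg_seqs, evalue_threshold = 1e-4)), 1)
  short <- list(sequence_record("tiny", "MKT"))
  expect_warning(out <- scan_sequences(pwm, short, evalue_threshold = 1),
                 "shorter")
  expect_equal(nrow(out), 0)
})

test_that("recovery rate is plain percentage arithmetic", {
  hits <- data.frame(id = paste0("m", 1:21))
  expect_equal(recovery_rate(hits, paste0("m", 1:26)), 80.76923, tolerance = 1e-5)
  expect_equal(recovery_rate(hits[0, , drop = FALSE], paste0("m", 1:26)), 0)
  # monotone non-decreasing in implant fraction
  spec <- make_topology_spec("3+1")
  fam <- evolve_family(sample_ancestor(spec, 71), 30, 2.0, seed = 72)$members
  pwm <- pwm_from_consensus("WNDPHTQRCEYGKMS", conservation = 0.9)
  recs <- vapply(c(0.2, 0.5, 0.8), function(fr) {
    imp <- implant_motif(fam, pwm, 6, fr, seed = 73, among = "all")
    recovery_rate(scan_sequences(pwm, imp$members, 1e-4),
                  vapply(imp$members, `[[`, character(1), "id"))
  }, numeric(1))
  expect_true(all(diff(recs) >= 0))
})

test_that("hits are located on the segment containing their midpoint", {
  spec <- make_topology_spec("3+1")
  fam <- evolve_family(sample_ancestor(spec, 81), 20, 2.0, seed = 82)$members
  pwm <- pwm_from_consensus("WNDPHTQRCEYG", conservation = 0.9)
  imp <- implant_motif(fam, pwm, 3, 1.0, seed = 83)   # third TMS
  hits <- scan_sequences(pwm, imp$members, evalue_threshold = 1e-4)
  topos <- stats::setNames(lapply(imp$members, `[[`, "topology"),
                           vapply(imp$members, `[[`, character(1), "id"))
  loc <- locate_motif(hits, topos, pwm$width)
  expect_equal(names(which.max(loc)), "TMS 3")
  expect_length(locate_motif(hits[0, , drop = FALSE], topos, 12), 0)
  # a hit in the long loop counts as "loop"
  fake <- data.frame(id = imp$members[[1]]$id, start = 120, score = 1,
                     pvalue = 1e-9, evalue = 1e-8)
  expect_equal(names(locate_motif(fake, topos, 12)), "loop")
})
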