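test_that("Kabsch superposition recovers exact rigid transforms", {
  P <- with_seed(3, matrix(stats::rnorm(30), 10))
  a <- structure_chain(P)
  expect_lt(kabsch_superpose(a, a)$rmsd, 1e-9)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  b <- structure_chain(P %*% t(R) + matrix(c(1, 2, 3), 10, 3, byrow = TRUE))
  s <- kabsch_superpose(a, b)
  expect_lt(s$rmsd, 1e-6)
  expect_lt(max(abs(s$rotation - R)), 1e-6)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  expect_lt(max(abs(crossprod(s$rotation) - diag(3))), 1e-9)
  expect_error(kabsch_superpose(a, b, cbind(1:2, 1:2)), "at least 3")
  line <- structure_chain(cbind(1:5, 0, 0))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("RMSD matches a rotation-grid-search oracle on a perturbed toy", {
  P <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, byrow = TRUE)
  Q <- P
  Q[4, ] <- Q[4, ] + c(0.3, -0.2, 0.1)
  s <- kabsch_superpose(structure_chain(P), structure_chain(Q))
  # brute force over Euler angles with centroid translation
  P0 <- sweep(P, 2, colMeans(P)); Q0 <- sweep(Q, 2, colMeans(Q))
  grid <- seq(-pi / 8, pi / 8, length.out = 50)
  best <- Inf
  for (a1 in grid) for (a2 in grid) for (a3 in grid) {
    Rz <- matrix(c(cos(a1), -sin(a1), 0, sin(a1), cos(a1), 0, 0, 0, 1), 3,
                 byrow = TRUE)
    Ry <- matrix(c(cos(a2), 0, sin(a2), 0, 1, 0, -sin(a2), 0, cos(a2)), 3,
                 byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cos(a3), -sin(a3), 0, sin(a3), cos(a3)), 3,
                 byrow = TRUE)
    r <- sqrt(mean(rowSums((P0 %*% t(Rz %*% Ry %*% Rx) - Q0)^2)))
    if (r < best) best <- r
  }
  expect_lt(abs(s$rmsd - best), 1e-3)
})

test_that("RMSD is invariant under rigid pre-transformation of either chain", {
  P <- with_seed(6, matrix(stats::rnorm(36), 12))
  Q <- P + with_seed(7, matrix(stats::rnorm(36, sd = 0.5), 12))
  base <- kabsch_superpose(structure_chain(P), structure_chain(Q))$rmsd
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3,
              byrow = TRUE)
  moved <- kabsch_superpose(structure_chain(P %*% t(R) + 5),
                            structure_chain(Q))$rmsd
  expect_equal(moved, base, tolerance = 1e-9)
})

test_that("TM-score is 1 for identical chains, asymmetric for unequal lengths", {
  spec <- make_topology_spec("3+1")
  ts <- make_toy_structure(spec, "helix_loop", seed = 4)
  expect_equal(tm_score(ts, ts), 1, tolerance = 1e-6)
  short <- structure_chain(ts$xyz[1:100, ])
  corr <- cbind(1:100, 1:100)
  ta <- tm_score(ts, short, corr, reference = "a")
  tb <- tm_score(ts, short, corr, reference = "b")
  expect_gt(tb, ta)           # normalizing by the shorter chain
  # 50% correspondence of an identical copy: every aligned residue at d = 0,
  # so TM equals coverage exactly
  half <- cbind(1:117, 1:117)
  expect_equal(tm_score(ts, ts, half, reference = "a"), 117 / nrow(ts$xyz),
               tolerance = 1e-9)
  tiny <- structure_chain(ts$xyz[1:10, ])
  expect_error(tm_score(tiny, tiny), "at least 16")
})

test_that("segment refinement applies the literal distance-and-index rule", {
  mk <- function(xyz, resno, labels) {
    refine_segment_assignments(structure_chain(xyz, resno = resno,
                                               labels = labels))
  }
  # 1.2 A away and 2 residues apart: joins the reentrant loop
  r1 <- mk(rbind(c(0, 0, 0), c(1.2, 0, 0)), c(1, 3), c("RL", "LOOP"))
  expect_equal(r1$labels[2], "RL")
  # 1.6 A away: distance rule fails
  r2 <- mk(rbind(c(0, 0, 0), c(1.6, 0, 0)), c(1, 3), c("RL", "LOOP"))
  expect_equal(r2$labels[2], "LOOP")
  # 1.2 A away but 4 residues apart: index rule fails
  r3 <- mk(rbind(c(0, 0, 0), c(1.2, 0, 0)), c(1, 5), c("RL", "LOOP"))
  expect_equal(r3$labels[2], "LOOP")
  # TMS wins over RL on conflict; originally labeled residues never change
  r4 <- mk(rbind(c(0, 0, 0), c(1.0, 0, 0), c(2.0, 0, 0)), c(1, 2, 3),
           c("TMS", "LOOP", "RL"))
  expect_equal(r4$labels[2], "TMS")
  expect_equal(r4$labels[c(1, 3)], c("TMS", "RL"))
  # idempotence at the fixed point
  r5 <- refine_segment_assignments(r1)
  expect_identical(r5$labels, r1$labels)
})

test_that("segment length reports summarize chains and their correlation", {
  lab <- c(rep("TMS", 20), rep("LOOP", 5), rep("RL", 18), rep("LOOP", 5),
           rep("TMS", 22))
  ch <- structure_chain(cbind(seq_along(lab) * 3.8, 0, 0), labels = lab)
  rep1 <- segment_length_report(list(ch))
  tms <- rep1$by_kind[rep1$by_kind$kind == "TMS", ]
  expect_equal(tms$mean, 21)
  expect_equal(tms$n, 2)
  expect_equal(rep1$by_kind$mean[rep1$by_kind$kind == "RL"], 18)
  expect_equal(rep1$mean_tms_rl_difference, 3)

  mk_chain <- function(tms_len, rl_len) {
    lab <- c(rep("TMS", tms_len), rep("LOOP", 4), rep("RL", rl_len))
    structure_chain(cbind(seq_along(lab), 0, 0), labels = lab)
  }
  perfect <- lapply(15:24, function(l) mk_chain(l, l - 3))
  expect_equal(segment_length_report(perfect)$r_squared, 1, tolerance = 1e-9)
  indep_r2 <- with_seed(12, vapply(1:20, function(rep) {
    chains <- lapply(1:100, function(i) {
      mk_chain(sample(15:30, 1), sample(12:25, 1))
    })
    segment_length_report(chains)$r_squared
  }, numeric(1)))
  expect_gte(mean(indep_r2 < 0.1), 0.9)
})
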