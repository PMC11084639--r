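test_that("topology specs produce the advertised segment layout", {
  spec <- make_topology_spec("3+1")
  expect_equal(spec$length, 234)  # 4 x 21 TMS + 2 x 15 loops + 120 loop
  expect_equal(sum(spec$topology$kind == "TMS"), 4)
  anc <- sample_ancestor(spec, 7)
  expect_equal(nchar(anc$residues), 234)
  expect_identical(anc$residues, sample_ancestor(spec, 7)$residues)
  expect_false(identical(anc$residues, sample_ancestor(spec, 8)$residues))
  expect_error(make_topology_spec("0"), "bad architecture")
})

test_that("membrane segments are hydrophobically biased relative to loops", {
  spec <- make_topology_spec("3+1")
  wins <- 0
  for (s in 1:100) {
    anc <- sample_ancestor(spec, 4000 + s)
    cls <- position_classes(anc$topology, nchar(anc$residues))
    v <- KD[strsplit(anc$residues, "")[[1]]]
    if (mean(v[cls == "TMS"]) > mean(v[cls == "LOOP"])) wins <- wins + 1
  }
  expect_gte(wins, 99)
})

test_that("family evolution preserves topology and controls identity", {
  spec <- make_topology_spec("3+1")
  anc <- sample_ancestor(spec, 7)
  same <- evolve_family(anc, 3, 0, seed = 5)$members
  for (m in same) expect_identical(m$residues, anc$residues)

  fam <- evolve_family(anc, 10, 0.5, seed = 6)$members
  expect_true(all(vapply(fam, function(m) nrow(m$topology), integer(1)) ==
                    nrow(anc$topology)))
  # segment coordinates stay consistent with the residues after indels
  for (m in fam) {
    expect_lte(max(m$topology$end), nchar(m$residues))
    expect_equal(max(m$topology$end), nchar(m$residues))
  }
  ids <- utils::combn(5, 2)
  pid <- apply(ids, 2, function(p) {
    smith_waterman(fam[[p[1]]], fam[[p[2]]])$pident
  })
  expect_true(all(pid >= 20 & pid <= 70))
  expect_error(evolve_family(anc, 3, -0.1, seed = 1), "non-negative")
})

test_that("non-homolog pairs share topology but not residues", {
  spec <- make_topology_spec("3+1")
  pr <- make_nonhomolog_pair(spec, 11)
  expect_false(identical(pr[[1]]$residues, pr[[2]]$residues))
  expect_equal(as.data.frame(pr[[1]]$topology), as.data.frame(pr[[2]]$topology))
  expect_error(make_nonhomolog_pair(spec, 11, seeds = c(3, 3)), "identical")
})

test_that("motif implantation respects fraction and segment bounds", {
  spec <- make_topology_spec("3+1")
  fam <- evolve_family(sample_ancestor(spec, 3), 10, 0.3, seed = 4)$members
  pwm <- pwm_from_consensus("WNDPHTQRCEYG", conservation = 0.9)
  all_in <- implant_motif(fam, pwm, 3, 1.0, seed = 5)
  expect_equal(sum(!vapply(all_in$truth$implants, is.null, logical(1))), 10)
  # implant intervals lie inside the third TMS
  for (id in names(all_in$truth$implants)) {
    iv <- all_in$truth$implants[[id]]
    m <- all_in$members[[match(id, vapply(all_in$members, `[[`, character(1), "id"))]]
    seg <- membrane_segments(m$topology)[3, ]
    expect_gte(iv["start"], seg$start)
    expect_lte(iv["end"], seg$end)
  }
  none <- implant_motif(fam, pwm, 3, 0, seed = 5)
  expect_identical(vapply(none$members, `[[`, character(1), "residues"),
                   vapply(fam, `[[`, character(1), "residues"))
  wide <- pwm_from_consensus(strrep("W", 35))
  expect_error(implant_motif(fam, wide, 3, 1.0, seed = 5), "width 35")
})

test_that("tandem composition doubles the membrane segment count and marks the breakpoint", {
  unit <- sample_ancestor(make_topology_spec("3", short_loop = 15), 9)
  tandem <- compose_architectures(unit, mode = "tandem", linker = 20, seed = 2)
  expect_equal(sum(tandem$topology$kind == "TMS"), 6)
  bp <- attr(tandem, "breakpoint")
  expect_equal(bp, nchar(unit$residues) + 20 + 1)
  fuse <- compose_architectures(unit, sample_ancestor(make_topology_spec("1"), 10),
                                mode = "fusion", linker = 10, seed = 3)
  expect_equal(sum(fuse$topology$kind == "TMS"), 4)
  expect_equal(nchar(fuse$residues), nchar(unit$residues) + 10 + 21)
})

test_that("toy structures have helix geometry, hairpin turns and seeded determinism", {
  spec <- make_topology_spec("3+1", rl_index = 2, rl_len = 18)
  for (shape in c("helix_loop", "helix_helix")) {
    ts <- make_toy_structure(spec, shape, seed = 2)
    d <- sqrt(rowSums(diff(ts$xyz)^2))
    expect_true(all(abs(d - 3.8) <= 0.2))
    expect_equal(nrow(ts$xyz), spec$length)
    expect_equal(sum(ts$labels == "RL"), 18)
  }
  hh <- make_toy_structure(spec, "helix_helix", seed = 2)
  expect_equal(hh$residues[hh$labels == "RL"][9:10], c("G", "E"))
  expect_identical(make_toy_structure(spec, "helix_helix", seed = 2)$xyz, hh$xyz)
  expect_false(identical(make_toy_structure(spec, "helix_helix", seed = 3)$xyz,
                         hh$xyz))
})
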