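test_that("FASTA parsing normalizes case, preserves order and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "mkt"), f)
  recs <- parse_fasta(f)
  expect_length(recs, 1)
  expect_equal(recs[[1]]$id, "a")
  expect_equal(recs[[1]]$residues, "MKT")

  two <- list(sequence_record("a", "MKTAYIAKQR", "first protein"),
              sequence_record("b", strrep("ACDEFGHIKL", 8)))
  out <- withr::local_tempfile(fileext = ".fasta")
  emit_fasta(two, out, width = 60)
  lines <- readLines(out)
  # 80 residues wrapped at 60 -> two sequence lines for record b
  expect_equal(sum(grepl("^[^>]", lines[grep(">b", lines):length(lines)])), 2)
  back <- parse_fasta(out)
  expect_equal(lapply(back, unclass), lapply(two, unclass))
})

test_that("FASTA error contract: empty files, bad characters, empty record list", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_error(parse_fasta(f), "empty")
  g <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MK7T"), g)
  expect_error(parse_fasta(g), "position 3")
  expect_error(emit_fasta(list(), withr::local_tempfile()), "no records")
})

test_that("topology tables validate coordinates and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("p1\t5\t24\tTMS", f)
  topos <- read_topology_table(f)
  expect_equal(topos$p1$start, 5L)
  expect_equal(topos$p1$end, 24L)
  expect_equal(topos$p1$kind, "TMS")

  # abutting segments of different kinds are accepted
  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("p1\t1\t20\tTMS", "p1\t21\t40\tLOOP"), g)
  expect_silent(read_topology_table(g))

  h <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("p1\t1\t20\tTMS", "p1\t15\t40\tLOOP"), h)
  expect_error(read_topology_table(h), "overlap")
  h2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("p1\t24\t5\tTMS", h2)
  expect_error(read_topology_table(h2), "end < start")

  topos2 <- list(p1 = topology(c(5, 40), c(25, 60), c("TMS", "RL")),
                 p2 = topology(1, 20, "TMS"))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_topology_table(topos2, out)
  expect_equal(lapply(read_topology_table(out), as.data.frame),
               lapply(topos2, as.data.frame))
})

test_that("CA reader returns ordered coordinates and resolves altlocs by occupancy", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA AVAL A   2       3.800   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BVAL A   2       3.900   0.000   0.000  0.60  0.00           C",
    "ATOM      4  CA  GLY A   3       7.600   0.000   0.000  1.00  0.00           C",
    "ATOM      5  CA  SER A   4      11.400   0.000   0.000  1.00  0.00           C",
    "END"), pdb)
  ch <- read_ca_coordinates(pdb, "A")
  expect_equal(nrow(ch$xyz), 4)           # one coordinate per residue
  expect_equal(ch$xyz[2, 1], 3.9)         # highest occupancy altloc wins
  expect_equal(ch$resno, 1:4)
  expect_error(read_ca_coordinates(pdb, "Z"), "chain 'Z'")
})

test_that("Newick export is readable by a standard parser and validates labels", {
  dm <- matrix(c(0, 2, 6, 10, 2, 0, 5, 9, 6, 5, 0, 4, 10, 9, 4, 0), 4, 4,
               dimnames = list(c("a", "b", "c", "d"), c("a", "b", "c", "d")))
  tr <- ward_tree(dm)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, c("a", "b", "c", "d"))
  # leaves sit at height 0: root-to-tip path lengths all equal the root height
  depths <- ape::node.depth.edgelength(phy)[seq_len(4)]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-9)

  tr_dup <- tr
  tr_dup$labels <- c("a", "a", "c", "d")
  expect_error(write_newick(tr_dup, f), "duplicate")

  tr_q <- tr
  tr_q$labels <- c("a x", "b(1)", "c", "d")
  write_newick(tr_q, f)
  tips <- gsub("^'|'$", "", ape::read.tree(f)$tip.label)
  expect_setequal(tips, c("a x", "b(1)", "c", "d"))
})

test_that("run configuration validates thresholds and round-trips through JSON", {
  expect_error(run_config(n_shuffles = 50), "n_shuffles")
  expect_error(run_config(evalue_threshold = 2), "thresholds")
  cfg <- run_config(n_shuffles = 500, seed = 42)
  f <- withr::local_tempfile(fileext = ".json")
  write_run_config(cfg, f)
  cfg2 <- read_run_config(f)
  expect_equal(cfg2$seed, 42L)
  expect_equal(cfg2$n_shuffles, 500L)
  expect_equal(cfg2$scheme$lambda, cfg$scheme$lambda)
})

test_that("seeded streams reproduce and do not disturb the caller's RNG", {
  x1 <- with_seed(7, stats::runif(3))
  x2 <- with_seed(7, stats::runif(3))
  expect_identical(x1, x2)
  set.seed(1)
  a <- stats::runif(1)
  set.seed(1)
  invisible(with_seed(99, stats::runif(10)))
  expect_identical(stats::runif(1), a)
  expect_identical(subseed(1, 2), subseed(1, 2))
  expect_false(subseed(1, 2) == subseed(1, 3))
  expect_true(subseed(.Machine$integer.max, 1e6) < 2^31)
})
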