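# Linker excision, chain splitting, interchain geometry, PDB round trips.

test_that("split_and_excise renumbers chains and drops the linker", {
  pair <- chain_pair("r", "ACDEF", "p", "KLM")
  f <- fuse(pair, linker_spec(length = 3))
  s <- predict_structure(prediction_request(f$sequence, seed = 1),
                         mock_backend(f$spans))
  m <- split_and_excise(s, f$spans)
  recA <- m$atoms[m$atoms$chain == "A", ]
  pepB <- m$atoms[m$atoms$chain == "B", ]
  expect_equal(sort(unique(recA$resno)), 1:5)
  expect_equal(sort(unique(pepB$resno)), 1:3)
  expect_equal(unique(recA$aa[order(recA$resno)]),
               strsplit("ACDEF", "")[[1]])
  # coordinates pass through unchanged
  ca_fused <- s$atoms[s$atoms$resno == 1 & s$atoms$atom == "CA", c("x", "y", "z")]
  ca_split <- recA[recA$resno == 1 & recA$atom == "CA", c("x", "y", "z")]
  expect_equal(unname(unlist(ca_split)), unname(unlist(ca_fused)))
})

test_that("residue counts balance: |A| + |B| + linker = fused length", {
  for (llen in c(0L, 7L, 30L)) {
    pair <- chain_pair("r", strrep("A", 15), "p", strrep("K", 4))
    f <- fuse(pair, linker_spec(length = llen))
    s <- predict_structure(prediction_request(f$sequence, seed = 1),
                           mock_backend(f$spans))
    m <- split_and_excise(s, f$spans)
    nA <- length(unique(m$atoms$resno[m$atoms$chain == "A"]))
    nB <- length(unique(m$atoms$resno[m$atoms$chain == "B"]))
    expect_equal(nA + nB + llen, nchar(f$sequence))
  }
})

test_that("span/structure length mismatch is a consistency error", {
  pair <- chain_pair("r", "ACDEF", "p", "KLM")
  f <- fuse(pair, linker_spec(length = 3))
  s <- predict_structure(prediction_request(f$sequence, seed = 1),
                         mock_backend(f$spans))
  wrong <- list(receptor = c(0L, 5L), linker = c(5L, 8L), peptide = c(8L, 12L))
  expect_error(split_and_excise(s, wrong), "span")
})

test_that("PDB write/read round-trips coordinates and pLDDT", {
  dir <- withr::local_tempdir()
  nat <- small_native(seed = 5, plddt_mode = "contact_correlated")
  path <- file.path(dir, "native.pdb")
  write_complex_pdb(nat$model, path)
  back <- read_complex_pdb(path)
  expect_equal(back$atoms$x, round(nat$model$atoms$x, 3))
  expect_equal(back$atoms$y, round(nat$model$atoms$y, 3))
  expect_equal(back$atoms$z, round(nat$model$atoms$z, 3))
  expect_equal(back$atoms$plddt, round(nat$model$atoms$plddt, 2))
  expect_identical(back$atoms$aa, nat$model$atoms$aa)
  expect_identical(back$atoms$chain, nat$model$atoms$chain)
})

test_that("fused single-chain PDB files are split when spans are supplied", {
  dir <- withr::local_tempdir()
  pair <- chain_pair("r", "ACDEFAC", "p", "KLM")
  f <- fuse(pair, linker_spec(length = 4))
  s <- predict_structure(prediction_request(f$sequence, seed = 2),
                         mock_backend(f$spans))
  m <- split_and_excise(s, f$spans)
  # write the fused structure as one chain
  path <- file.path(dir, "fused.pdb")
  a <- s$atoms
  bio3d::write.pdb(file = path, xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = bio3d::aa123(a$aa),
                   elety = a$atom, chain = rep("A", nrow(a)),
                   eleno = seq_len(nrow(a)), o = rep(1, nrow(a)),
                   b = s$plddt[a$resno])
  back <- read_complex_pdb(path, spans = f$spans)
  expect_equal(back$atoms$x, round(m$atoms$x, 3))
  expect_identical(back$atoms$chain, m$atoms$chain)
})

test_that("min_interchain_distance matches simple geometry and the
           exhaustive all-pairs oracle", {
  expect_equal(min_interchain_distance(point_model(c(0, 0, 0), c(0, 0, 4))),
               4.0)
  expect_equal(min_interchain_distance(point_model(c(1, 2, 3), c(1, 2, 3))),
               0.0)
  for (seed in 1:25) {
    m <- random_toy_model(seed)
    expect_equal(min_interchain_distance(m), brute_min_distance(m),
                 tolerance = 1e-12)
    expect_equal(min_interchain_distance(m, "backbone_only"),
                 brute_min_distance(m, "backbone_only"), tolerance = 1e-12)
  }
})

test_that("contacting_peptide_residues matches construction and is monotone", {
  # one peptide residue at 3 A, two at 12 A
  m <- plddt_fixture(c(50, 60, 70), contacts = 2)
  expect_equal(contacting_peptide_residues(m, 5), 2L)
  expect_equal(contacting_peptide_residues(m, 1e6), 1:3)

  far <- point_model(c(0, 0, 0), c(50, 0, 0))
  expect_length(contacting_peptide_residues(far, 5), 0)
  expect_error(contacting_peptide_residues(far, 0), "positive")

  for (seed in 1:10) {
    m <- random_toy_model(seed)
    c5 <- contacting_peptide_residues(m, 5)
    c8 <- contacting_peptide_residues(m, 8)
    expect_true(all(c5 %in% c8))
    expect_equal(c8, brute_contacting_residues(m, 8))
  }
})

test_that("is_docked uses an inclusive 8 A boundary and agrees with the
           contact set", {
  expect_true(is_docked(point_model(c(0, 0, 0), c(4, 0, 0))))
  expect_true(is_docked(point_model(c(0, 0, 0), c(8, 0, 0))))
  expect_false(is_docked(point_model(c(0, 0, 0), c(9, 0, 0))))
  for (seed in 1:10) {
    m <- random_toy_model(seed)
    expect_identical(is_docked(m),
                     length(contacting_peptide_residues(m, 8)) > 0)
  }
})
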