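# Fusion and masking.

test_that("fuse concatenates receptor, linker and peptide with exact spans", {
  pair <- chain_pair("r", "ACDEF", "p", "KLM")

  f <- fuse(pair, linker_spec(length = 3))
  expect_equal(f$sequence, "ACDEFGGGKLM")
  expect_equal(f$spans, list(receptor = c(0L, 5L), linker = c(5L, 8L),
                             peptide = c(8L, 11L)))

  f0 <- fuse(pair, linker_spec(length = 0))
  expect_equal(f0$sequence, "ACDEFKLM")
  expect_equal(f0$spans$linker, c(5L, 5L))

  fn <- fuse(pair, linker_spec(length = 3,
                               placement = "peptide_at_N_terminus"))
  expect_equal(fn$sequence, "KLMGGGACDEF")
  expect_equal(fn$spans$peptide, c(0L, 3L))
  expect_equal(fn$spans$receptor, c(6L, 11L))
})

test_that("non-standard residues are rejected with the offending position", {
  expect_error(chain_pair("r", "ACDBF", "p", "KLM"), "position 4")
  expect_error(chain_pair("r", "ACDEF", "p", "KLZ"), "position 3")
})

test_that("fuse then strip recovers the inputs for all lengths and termini", {
  set.seed(42)
  aas <- pepdock:::AA_STANDARD
  for (len in c(0L, 30L, 100L, 200L)) {
    for (placement in c("peptide_at_C_terminus", "peptide_at_N_terminus")) {
      r <- paste(sample(aas, sample(20:80, 1), replace = TRUE), collapse = "")
      p <- paste(sample(aas, sample(3:15, 1), replace = TRUE), collapse = "")
      pair <- chain_pair("r", r, "p", p)
      back <- unfuse(fuse(pair, linker_spec(length = len,
                                            placement = placement)))
      expect_identical(back$receptor_seq, r)
      expect_identical(back$peptide_seq, p)
    }
  }
})

test_that("each variant masks exactly round(rate * n_eligible) positions", {
  pair <- chain_pair("r", strrep("A", 15), "p", strrep("K", 5))  # 20 eligible
  f <- fuse(pair, linker_spec(length = 4))
  v <- mask_variants(f, mask_spec(rate = 0.25, n_variants = 8), seed = 3)
  expect_length(v, 8)
  n_masked <- vapply(v, function(s) sum(strsplit(s, "")[[1]] == "X"),
                     numeric(1))
  expect_true(all(n_masked == 5))  # round(0.25 * 20)

  # randomized sweep over rates and lengths
  set.seed(7)
  for (i in 1:20) {
    rl <- sample(5:60, 1); pl <- sample(1:12, 1)
    rate <- runif(1)
    pair <- chain_pair("r", strrep("A", rl), "p", strrep("K", pl))
    f <- fuse(pair, linker_spec(length = sample(0:30, 1)))
    v <- mask_variants(f, mask_spec(rate = rate, n_variants = 2), seed = i)
    got <- sum(strsplit(v[1], "")[[1]] == "X")
    expect_equal(got, round_half_up(rate * (rl + pl)))
  }
})

test_that("rate 0 yields unmasked copies and identical seeds reproduce", {
  pair <- chain_pair("r", "ACDEFGHIKL", "p", "MNP")
  f <- fuse(pair, linker_spec(length = 5))
  v0 <- mask_variants(f, mask_spec(rate = 0, n_variants = 8), seed = 1)
  expect_true(all(v0 == f$sequence))

  a <- mask_variants(f, mask_spec(), seed = 99)
  b <- mask_variants(f, mask_spec(), seed = 99)
  expect_identical(a, b)
  expect_false(identical(a, mask_variants(f, mask_spec(), seed = 100)))
})

test_that("linker positions are never masked under the default policy", {
  pair <- chain_pair("r", strrep("A", 12), "p", strrep("K", 6))
  f <- fuse(pair, linker_spec(length = 10))
  lidx <- (f$spans$linker[1] + 1):f$spans$linker[2]
  for (seed in 1:20) {
    v <- mask_variants(f, mask_spec(rate = 0.5, n_variants = 4), seed = seed)
    for (s in v) {
      expect_true(all(strsplit(s, "")[[1]][lidx] == "G"))
    }
  }
  # whole_fusion policy, by contrast, may mask the linker
  v <- mask_variants(f, mask_spec(rate = 1, n_variants = 1,
                                  eligible_policy = "whole_fusion"), seed = 1)
  expect_true(all(strsplit(v, "")[[1]] == "X"))
})

test_that("mask rate outside [0,1] and bad placeholders are rejected", {
  expect_error(mask_spec(rate = 1.2), "rate")
  expect_error(mask_spec(rate = -0.1), "rate")
  expect_error(mask_spec(mask_symbol = "G"), "mask_symbol")
})

test_that("restore_masked inverts masking", {
  pair <- chain_pair("r", "ACDEFGHIKL", "p", "MNP")
  f <- fuse(pair, linker_spec(length = 4))
  v <- mask_variants(f, mask_spec(rate = 0.5), seed = 2)
  expect_identical(restore_masked(v[1], f$sequence), f$sequence)
})

test_that("FASTA round trips preserve sequences and segment maps", {
  dir <- withr::local_tempdir()
  pair <- chain_pair("rec1", "ACDEFGHIKLMNPQRSTVWY", "pep1", "KLMKL")
  fa <- file.path(dir, "pair.fasta")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(c(rec1 = pair$receptor_seq,
                              pep1 = pair$peptide_seq)), fa)
  back <- read_chain_pair(fa)
  expect_identical(back$receptor_seq, pair$receptor_seq)
  expect_identical(back$peptide_seq, pair$peptide_seq)
  expect_identical(back$receptor_id, "rec1")

  f <- fuse(pair, linker_spec(length = 7))
  ff <- file.path(dir, "fused.fasta")
  write_fused_fasta(f, ff)
  f2 <- read_fused_fasta(ff)
  expect_identical(f2$sequence, f$sequence)
  expect_equal(f2$spans, f$spans)

  # masked variants share the span map through the description line
  v <- mask_variants(f, mask_spec(n_variants = 3), seed = 1)
  fv <- file.path(dir, "variants.fasta")
  write_fused_fasta(v, fv, spans = f$spans)
  vs <- read_fused_fasta(fv)
  expect_length(vs, 3)
  expect_identical(vs[[2]]$sequence, v[2])
  expect_equal(vs[[3]]$spans, f$spans)
})
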