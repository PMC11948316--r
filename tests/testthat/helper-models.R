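# Fixture builders used across the test files.

# Complex model from explicit coordinates: one CA atom per residue.
# rec/pep are n x 3 matrices; plddt vectors are recycled per residue.
point_model <- function(rec, pep, rec_plddt = 80, pep_plddt = 80) {
  rec <- matrix(rec, ncol = 3)
  pep <- matrix(pep, ncol = 3)
  mk <- function(xyz, chain, plddt) {
    data.frame(chain = chain, resno = seq_len(nrow(xyz)),
               aa = "A", atom = "CA", element = "C",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               plddt = rep_len(plddt, nrow(xyz)), stringsAsFactors = FALSE)
  }
  pepdock:::new_complex_model(rbind(mk(rec, "A", rec_plddt),
                                    mk(pep, "B", pep_plddt)))
}

# Random toy complex: random atom subsets per residue, coordinates in a box
# whose overlap guarantees plenty of near and far atom pairs.
random_toy_model <- function(seed, n_rec = NULL, n_pep = NULL) {
  set.seed(seed)
  if (is.null(n_rec)) n_rec <- sample(8:40, 1)
  if (is.null(n_pep)) n_pep <- sample(3:10, 1)
  mk_chain <- function(n, chain, shift) {
    rows <- lapply(seq_len(n), function(r) {
      atoms <- c("CA", sample(c("N", "C", "O", "CB"),
                              sample(0:4, 1)))
      data.frame(chain = chain, resno = r, aa = "G", atom = atoms,
                 element = substr(atoms, 1, 1),
                 x = runif(length(atoms), 0, 25) + shift,
                 y = runif(length(atoms), 0, 25),
                 z = runif(length(atoms), 0, 25),
                 plddt = runif(1, 0, 100), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  pepdock:::new_complex_model(rbind(mk_chain(n_rec, "A", 0),
                                    mk_chain(n_pep, "B", runif(1, 0, 15))))
}

# Peptide pLDDT scoring fixture: receptor is one residue at the origin;
# contact residues sit 3 A away, the rest 12 A away (5 A cutoff).
plddt_fixture <- function(pep_plddt, contacts) {
  n <- length(pep_plddt)
  pep <- t(vapply(seq_len(n), function(i) {
    if (i %in% contacts) c(3, 0, 0.3 * i) else c(12, 0, 0.3 * i)
  }, numeric(3)))
  m <- point_model(matrix(c(0, 0, 0), 1), pep)
  m$atoms$plddt[m$atoms$chain == "B"] <- pep_plddt
  m
}

# A 252-residue protocol-scale problem (receptor 240 + peptide 12), the
# median complex size the protocol targets.
protocol_native <- function(seed = 1, plddt_mode = "uniform") {
  make_native(fixture_spec(receptor_length = 240L, peptide_length = 12L,
                           plddt_mode = plddt_mode, seed = seed))
}

small_native <- function(seed = 1, ...) {
  make_native(fixture_spec(receptor_length = 30L, peptide_length = 8L,
                           seed = seed, ...))
}
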