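# Post-processing: excise the linker, split into receptor (chain A) and
# peptide (chain B), interchain geometry, and PDB round-tripping.

#' Two-chain complex model
#'
#' Internal constructor. `atoms` is a data.frame with columns chain ("A"
#' receptor / "B" peptide), resno (numbered from 1 within each chain), aa
#' (one-letter), atom, element, x, y, z, plddt. pLDDT is replicated over a
#' residue's atoms.
#'
#' @keywords internal
new_complex_model <- function(atoms, provenance = list()) {
  stopifnot(all(atoms$chain %in% c("A", "B")))
  if (!any(atoms$chain == "A") || !any(atoms$chain == "B")) {
    stop("complex model needs a nonempty receptor (A) and peptide (B) chain",
         call. = FALSE)
  }
  if (any(!is.finite(atom_xyz(atoms)))) {
    stop("non-finite coordinates in complex model", call. = FALSE)
  }
  if (any(atoms$plddt < 0 | atoms$plddt > 100)) {
    stop("pLDDT values must lie in [0, 100]", call. = FALSE)
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, provenance = provenance),
            class = "complex_model")
}

chain_atoms <- function(model, chain, policy = c("heavy_atoms",
                                                 "backbone_only")) {
  policy <- match.arg(policy)
  a <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  keep <- if (policy == "backbone_only") a$atom %in% BACKBONE_ATOMS
          else a$element != "H"
  a[keep, , drop = FALSE]
}

#' Per-residue pLDDT of one chain
#'
#' @param model a `complex_model`.
#' @param chain `"A"` (receptor) or `"B"` (peptide).
#' @return numeric vector, one value per residue in residue order.
#' @export
residue_plddt <- function(model, chain = "B") {
  a <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  tapply(a$plddt, a$resno, function(v) v[1])[as.character(sort(unique(a$resno)))]
}

#' Split a fused prediction and excise the linker
#'
#' Receptor-span residues become chain A (renumbered 1..R), peptide-span
#' residues chain B (1..P); linker residues are discarded. Coordinates and
#' pLDDT pass through unchanged.
#'
#' @param predicted a `predicted_structure`.
#' @param spans segment map partitioning the predicted length.
#' @return a `complex_model`.
#' @export
split_and_excise <- function(predicted, spans) {
  stopifnot(inherits(predicted, "predicted_structure"))
  n <- nchar(predicted$sequence)
  validate_span_map(spans, n)
  if (length(unique(predicted$atoms$resno)) != n) {
    stop("span map length ", n, " does not match predicted structure (",
         length(unique(predicted$atoms$resno)), " residues)", call. = FALSE)
  }
  take <- function(idx, chain_id) {
    a <- predicted$atoms[predicted$atoms$resno %in% idx, , drop = FALSE]
    a$plddt <- predicted$plddt[a$resno]
    a$chain <- chain_id
    a$resno <- match(a$resno, idx)
    a
  }
  atoms <- rbind(take(span_idx(spans$receptor), "A"),
                 take(span_idx(spans$peptide), "B"))
  atoms <- atoms[, c("chain", "resno", "aa", "atom", "element",
                     "x", "y", "z", "plddt")]
  new_complex_model(atoms, provenance = predicted$provenance)
}

#' Minimum interchain distance
#'
#' Minimum distance over all receptor-peptide atom pairs, under either the
#' heavy-atom policy (hydrogens excluded; the default, used by the misdock
#' criterion) or backbone-only (N, CA, C, O).
#'
#' @param model a `complex_model`.
#' @param atom_policy `"heavy_atoms"` or `"backbone_only"`.
#' @return distance in Angstrom.
#' @export
min_interchain_distance <- function(model,
                                    atom_policy = c("heavy_atoms",
                                                    "backbone_only")) {
  atom_policy <- match.arg(atom_policy)
  a <- chain_atoms(model, "A", atom_policy)
  b <- chain_atoms(model, "B", atom_policy)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("a chain has no atoms under the ", atom_policy, " policy",
         call. = FALSE)
  }
  min_cross_distance_xyz(atom_xyz(a), atom_xyz(b))
}

#' Peptide residues in contact with the receptor
#'
#' A peptide residue is in contact when its minimum heavy-atom distance to
#' any receptor atom is at most `cutoff` (boundary included).
#'
#' @param model a `complex_model`.
#' @param cutoff contact distance in Angstrom (> 0); 5 A is the interface
#'   definition used by the ranking schemes.
#' @return integer vector of peptide residue numbers.
#' @export
contacting_peptide_residues <- function(model, cutoff = 5) {
  check_number(cutoff, "cutoff")
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  a <- chain_atoms(model, "A")
  b <- chain_atoms(model, "B")
  bx <- atom_xyz(b)
  ax <- atom_xyz(a)
  res <- sort(unique(b$resno))
  d_res <- vapply(res, function(r) {
    min_cross_distance_xyz(ax, bx[b$resno == r, , drop = FALSE])
  }, numeric(1))
  res[d_res <= cutoff]
}

#' Is the peptide docked?
#'
#' TRUE when the minimum heavy-atom interchain distance is at most `cutoff`
#' (default 8 A, the misdock criterion); a distance of exactly `cutoff`
#' counts as docked.
#'
#' @param model a `complex_model`.
#' @param cutoff distance criterion in Angstrom.
#' @return logical.
#' @export
is_docked <- function(model, cutoff = 8) {
  min_interchain_distance(model, "heavy_atoms") <= cutoff
}

# ---- PDB I/O (bio3d-backed) -------------------------------------------------

#' Write a complex model to PDB
#'
#' Chain A is the receptor, chain B the peptide; per-residue pLDDT goes to
#' the B-factor column (the structure-predictor convention).
#'
#' @param model a `complex_model`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_complex_pdb <- function(model, file) {
  a <- model$atoms
  xyz <- as.vector(t(atom_xyz(a)))
  # TER between chains is emitted by bio3d when chain ids change
  bio3d::write.pdb(file = file, xyz = xyz,
                   resno = a$resno,
                   resid = bio3d::aa123(a$aa),
                   elety = a$atom,
                   chain = a$chain,
                   eleno = seq_len(nrow(a)),
                   o = rep(1, nrow(a)),
                   b = a$plddt,
                   elesy = a$element)
  invisible(file)
}

#' Read a complex model from PDB
#'
#' Accepts either a pre-split two-chain file (receptor chain, peptide chain)
#' or a single-chain fused file accompanied by a span map. HETATM records
#' are skipped, hydrogens retained (distance policies exclude them), and
#' only the first alternate-location conformer is kept. B-factors are read
#' back as pLDDT.
#'
#' @param file PDB path.
#' @param spans optional segment map; required for single-chain fused files.
#' @param chain_map length-2 character vector naming the receptor and
#'   peptide chains in the file (default `c("A", "B")`).
#' @return a `complex_model`.
#' @export
read_complex_pdb <- function(file, spans = NULL, chain_map = c("A", "B")) {
  pdb <- bio3d::read.pdb(file, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  aa1 <- bio3d::aa321(at$resid)
  elem <- ifelse(is.na(at$elesy) | at$elesy == "",
                 substr(trimws(at$elety), 1L, 1L), trimws(at$elesy))
  atoms <- data.frame(chain = at$chain, resno = at$resno, aa = aa1,
                      atom = trimws(at$elety), element = elem,
                      x = at$x, y = at$y, z = at$z, plddt = at$b,
                      stringsAsFactors = FALSE)
  if (is.null(spans)) {
    if (!all(chain_map %in% atoms$chain)) {
      stop("chains ", paste(chain_map, collapse = "/"),
           " not both present in ", file, call. = FALSE)
    }
    atoms <- atoms[atoms$chain %in% chain_map, , drop = FALSE]
    atoms$chain <- ifelse(atoms$chain == chain_map[1], "A", "B")
    # renumber each chain from 1, preserving order of appearance
    for (ch in c("A", "B")) {
      sel <- atoms$chain == ch
      atoms$resno[sel] <- match(atoms$resno[sel], unique(atoms$resno[sel]))
    }
    new_complex_model(atoms)
  } else {
    # fused single-chain file: positions follow the span map
    seqres <- tapply(atoms$aa, atoms$resno, function(v) v[1])
    sequence <- paste(seqres[as.character(sort(unique(atoms$resno)))],
                      collapse = "")
    atoms$resno <- match(atoms$resno, sort(unique(atoms$resno)))
    ps <- new_predicted_structure(sequence,
                                  atoms[, c("resno", "aa", "atom", "element",
                                            "x", "y", "z")],
                                  plddt = as.numeric(
                                    tapply(atoms$plddt, atoms$resno,
                                           function(v) v[1])))
    split_and_excise(ps, spans)
  }
}
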