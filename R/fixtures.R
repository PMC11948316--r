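# Synthetic fixtures: toy native complexes, decoys with controlled docking
# quality, and pLDDT profiles. These stand in for experimental complexes so
# every pipeline stage runs without downloads or GPU inference; they are
# geometric toys, not physically realistic folds.

#' Fixture specification
#'
#' @param receptor_length receptor residues (>= 3).
#' @param peptide_length peptide residues (>= 1).
#' @param peptide_displacement native minimum heavy-atom peptide-receptor
#'   distance in Angstrom (default 4, a bound peptide).
#' @param rotation Euler-angle triple (degrees) applied to the peptide.
#' @param coordinate_noise_sigma isotropic coordinate noise in Angstrom.
#' @param plddt_mode pLDDT profile: `"uniform"`, `"contact_correlated"` or
#'   `"anticorrelated"`.
#' @param seed integer seed controlling sequences, noise and pLDDT draws.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(receptor_length = 60L, peptide_length = 12L,
                         peptide_displacement = 4, rotation = c(0, 0, 0),
                         coordinate_noise_sigma = 0,
                         plddt_mode = c("uniform", "contact_correlated",
                                        "anticorrelated"),
                         seed = 1L) {
  receptor_length <- check_count(receptor_length, "receptor_length", lower = 3L)
  peptide_length <- check_count(peptide_length, "peptide_length", lower = 1L)
  check_number(peptide_displacement, "peptide_displacement", lower = 0)
  check_number(coordinate_noise_sigma, "coordinate_noise_sigma", lower = 0)
  structure(list(receptor_length = receptor_length,
                 peptide_length = peptide_length,
                 peptide_displacement = peptide_displacement,
                 rotation = rotation,
                 coordinate_noise_sigma = coordinate_noise_sigma,
                 plddt_mode = match.arg(plddt_mode),
                 seed = check_count(seed, "seed")),
            class = "fixture_spec")
}

random_aa <- function(n, seed) {
  withr::with_seed(seed, sample(AA_STANDARD, n, replace = TRUE))
}

#' Build a toy native complex
#'
#' Receptor: ideal alpha-helix (1.5 A rise, 100 degrees twist per residue,
#' backbone + CB). Peptide: extended segment centered on the receptor
#' midsection and placed at the spec's minimum heavy-atom distance.
#' Sequences are drawn uniformly over the 20 standard residues from the
#' seed; everything is deterministic per seed.
#'
#' @param spec a [fixture_spec()].
#' @return list of class `native_fixture`: `model` (a `complex_model`),
#'   `receptor_seq`, `peptide_seq`, `spec`.
#' @export
make_native <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  rec_aa <- random_aa(spec$receptor_length, derive_seed(spec$seed, 1L))
  pep_aa <- random_aa(spec$peptide_length, derive_seed(spec$seed, 2L))
  receptor <- build_helix(rec_aa)
  peptide <- build_extended(pep_aa)
  if (!all(spec$rotation == 0)) {
    peptide <- rigid_move(peptide, rotation = spec$rotation)
  }
  rxyz <- atom_xyz(receptor)
  ctr <- colMeans(atom_xyz(peptide))
  peptide <- rigid_move(peptide,
                        translation = c(0, 0, mean(range(rxyz[, 3])) - ctr[3]))
  peptide <- place_at_min_distance(receptor, peptide,
                                   spec$peptide_displacement)
  if (spec$coordinate_noise_sigma > 0) {
    jitter <- function(a, tag) {
      xyz <- atom_xyz(a)
      n <- withr::with_seed(derive_seed(spec$seed, tag),
        matrix(stats::rnorm(length(xyz), sd = spec$coordinate_noise_sigma),
               ncol = 3))
      set_atom_xyz(a, xyz + n)
    }
    receptor <- jitter(receptor, 3L)
    peptide <- jitter(peptide, 4L)
  }
  receptor$chain <- "A"; peptide$chain <- "B"
  atoms <- rbind(receptor, peptide)
  atoms$plddt <- 0
  atoms <- atoms[, c("chain", "resno", "aa", "atom", "element",
                     "x", "y", "z", "plddt")]
  model <- new_complex_model(atoms,
                             provenance = list(seed = spec$seed,
                                               fixture = "native"))
  model <- assign_plddt(model, spec$plddt_mode,
                        seed = derive_seed(spec$seed, 5L),
                        true_displacement = spec$peptide_displacement)
  structure(list(model = model,
                 receptor_seq = paste(rec_aa, collapse = ""),
                 peptide_seq = paste(pep_aa, collapse = ""),
                 spec = spec),
            class = "native_fixture")
}

#' Build a decoy from a native complex
#'
#' The receptor is untouched; the peptide is rotated about its centroid,
#' translated by `displacement` along the receptor-to-peptide axis (away
#' from the receptor), then perturbed by isotropic Gaussian noise. The true
#' transform is recorded in provenance.
#'
#' @param native a `complex_model` or `native_fixture`.
#' @param displacement rigid translation magnitude in Angstrom.
#' @param rotation Euler-angle triple in degrees.
#' @param noise_sigma Gaussian noise on peptide coordinates, in Angstrom.
#' @param seed integer seed for the noise.
#' @return a `complex_model` decoy.
#' @export
make_decoy <- function(native, displacement = 0, rotation = c(0, 0, 0),
                       noise_sigma = 0, seed = 1L) {
  model <- if (inherits(native, "native_fixture")) native$model else native
  stopifnot(inherits(model, "complex_model"))
  check_number(displacement, "displacement", lower = 0)
  check_number(noise_sigma, "noise_sigma", lower = 0)
  a <- model$atoms
  rec <- a[a$chain == "A", , drop = FALSE]
  pep <- a[a$chain == "B", , drop = FALSE]
  axis <- colMeans(atom_xyz(pep)) - colMeans(atom_xyz(rec))
  axis <- axis / sqrt(sum(axis^2))
  pep <- rigid_move(pep, rotation = rotation,
                    translation = displacement * axis)
  if (noise_sigma > 0) {
    xyz <- atom_xyz(pep)
    n <- withr::with_seed(derive_seed(seed, 11L),
      matrix(stats::rnorm(length(xyz), sd = noise_sigma), ncol = 3))
    pep <- set_atom_xyz(pep, xyz + n)
  }
  new_complex_model(rbind(rec, pep),
                    provenance = list(
                      seed = seed, fixture = "decoy",
                      true_transform = list(displacement = displacement,
                                            direction = axis,
                                            rotation = rotation,
                                            noise_sigma = noise_sigma)))
}

#' Assign a pLDDT profile to a model
#'
#' `"uniform"` sets every residue to `uniform_value`. The contact-aware
#' modes use the model's docking state (true displacement if supplied, else
#' the measured minimum interchain distance, docked when <= 8 A):
#' `"contact_correlated"` draws peptide pLDDT from 75-95 when docked and
#' 20-50 otherwise, `"anticorrelated"` swaps the bands; the receptor is
#' always drawn from 80-95.
#'
#' @param model a `complex_model`.
#' @param mode pLDDT mode.
#' @param seed integer seed.
#' @param uniform_value constant for the uniform mode (default 80).
#' @param true_displacement optional known peptide displacement in Angstrom.
#' @return the model with pLDDT filled in.
#' @export
assign_plddt <- function(model, mode = c("uniform", "contact_correlated",
                                         "anticorrelated"),
                         seed = 1L, uniform_value = 80,
                         true_displacement = NULL) {
  mode <- match.arg(mode)
  check_number(uniform_value, "uniform_value", lower = 0, upper = 100)
  a <- model$atoms
  if (mode == "uniform") {
    a$plddt <- uniform_value
    model$atoms <- a
    return(model)
  }
  d <- if (is.null(true_displacement)) min_interchain_distance(model)
       else true_displacement
  docked <- d <= 8
  high <- c(75, 95); low <- c(20, 50)
  pep_band <- if (mode == "contact_correlated") {
    if (docked) high else low
  } else {
    if (docked) low else high
  }
  rec_res <- sort(unique(a$resno[a$chain == "A"]))
  pep_res <- sort(unique(a$resno[a$chain == "B"]))
  vals <- withr::with_seed(seed, list(
    rec = stats::runif(length(rec_res), 80, 95),
    pep = stats::runif(length(pep_res), pep_band[1], pep_band[2])))
  a$plddt[a$chain == "A"] <- vals$rec[match(a$resno[a$chain == "A"], rec_res)]
  a$plddt[a$chain == "B"] <- vals$pep[match(a$resno[a$chain == "B"], pep_res)]
  model$atoms <- a
  model
}

#' Generate a decoy pool with controlled docking quality
#'
#' Produces `n` decoys of a native complex: each is docked (minimum
#' interchain distance drawn from `docked_range`) with probability
#' `p_docked`, otherwise misdocked (`undocked_range`), with the peptide
#' re-placed at exactly that distance, lightly jittered, and given a pLDDT
#' profile in the requested mode. Provenance records the true distance and
#' variant index, so filtering and ranking behavior can be checked against
#' ground truth.
#'
#' @param native a `native_fixture` or `complex_model`.
#' @param n pool size (default 8, the masked-variant count).
#' @param p_docked docking probability per decoy.
#' @param docked_range,undocked_range true-distance ranges in Angstrom.
#' @param noise_sigma peptide coordinate jitter in Angstrom.
#' @param plddt_mode pLDDT profile mode.
#' @param seed integer seed.
#' @return list of `complex_model` decoys.
#' @export
make_decoy_pool <- function(native, n = 8L, p_docked = 0.5,
                            docked_range = c(3.5, 7.5),
                            undocked_range = c(12, 30),
                            noise_sigma = 0.1,
                            plddt_mode = "contact_correlated",
                            seed = 1L) {
  model <- if (inherits(native, "native_fixture")) native$model else native
  n <- check_count(n, "n", lower = 1L)
  a <- model$atoms
  rec <- a[a$chain == "A", , drop = FALSE]
  pep <- a[a$chain == "B", , drop = FALSE]
  lapply(seq_len(n), function(i) {
    si <- derive_seed(seed, i)
    target <- withr::with_seed(si, {
      docked <- stats::runif(1) < p_docked
      rng <- if (docked) docked_range else undocked_range
      stats::runif(1, rng[1], rng[2])
    })
    pep_i <- place_at_min_distance(rec, pep, target)
    if (noise_sigma > 0) {
      xyz <- atom_xyz(pep_i)
      noise <- withr::with_seed(derive_seed(si, 7L),
        matrix(stats::rnorm(length(xyz), sd = noise_sigma), ncol = 3))
      pep_i <- set_atom_xyz(pep_i, xyz + noise)
    }
    decoy <- new_complex_model(rbind(rec, pep_i),
                               provenance = list(variant = i, seed = si,
                                                 fixture = "decoy",
                                                 true_distance = target))
    assign_plddt(decoy, plddt_mode, seed = derive_seed(si, 13L),
                 true_displacement = target)
  })
}

#' Write a fixture to disk
#'
#' Emits the paired FASTA (receptor, peptide), the native PDB, and a JSON
#' manifest recording the seed, geometry parameters and expected qualitative
#' outcome.
#'
#' @param fixture a `native_fixture`.
#' @param dir output directory (created if needed).
#' @param name file stem (default `"fixture"`).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir, name = "fixture") {
  stopifnot(inherits(fixture, "native_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(name, ".fasta"))
  pdb <- file.path(dir, paste0(name, "_native.pdb"))
  manifest <- file.path(dir, paste0(name, "_manifest.json"))
  x <- Biostrings::AAStringSet(c(receptor = fixture$receptor_seq,
                                 peptide = fixture$peptide_seq))
  Biostrings::writeXStringSet(x, fasta)
  write_complex_pdb(fixture$model, pdb)
  spec <- fixture$spec
  jsonlite::write_json(
    list(seed = spec$seed,
         receptor_length = spec$receptor_length,
         peptide_length = spec$peptide_length,
         peptide_displacement = spec$peptide_displacement,
         rotation = spec$rotation,
         coordinate_noise_sigma = spec$coordinate_noise_sigma,
         plddt_mode = spec$plddt_mode,
         expected = list(docked = spec$peptide_displacement <= 8,
                         self_dockq = 1)),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(fasta = fasta, pdb = pdb, manifest = manifest))
}
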