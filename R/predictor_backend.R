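# Predictor contract, deterministic synthetic backend, adaptive recycling.
#
# A backend is any function taking a `prediction_request` and returning a
# `predicted_structure`, deterministic for identical (sequence, num_recycles,
# seed). The shipped mock backend builds idealized geometry so the whole
# docking protocol runs without GPU inference. An adapter for a real
# predictor is described in the vignette: invoke the external tool on the
# fused sequence, read back its PDB with per-residue confidence in the
# B-factor column via read_complex_pdb(), and wrap that in the same callable
# surface; such adapters are deliberately outside the test surface.

#' Prediction request
#'
#' @param sequence one-letter sequence, possibly containing the mask
#'   placeholder.
#' @param num_recycles non-negative recycle count (default 3, the standard
#'   protocol).
#' @param seed integer seed forwarded to the backend.
#' @param mask_symbol placeholder character allowed in `sequence`.
#' @return an object of class `prediction_request`.
#' @export
prediction_request <- function(sequence, num_recycles = 3L, seed = 1L,
                               mask_symbol = "X") {
  check_aa_sequence(sequence, "sequence", extra = mask_symbol)
  num_recycles <- check_count(num_recycles, "num_recycles", lower = 0L)
  seed <- check_count(seed, "seed", lower = -2147483647L)
  structure(list(sequence = sequence, num_recycles = num_recycles,
                 seed = seed, mask_symbol = mask_symbol),
            class = "prediction_request")
}

#' Run a prediction through a backend
#'
#' Thin, validating dispatcher: checks the request, surfaces backend
#' failures with the request attached, verifies length conservation, and
#' stamps provenance (seed, recycles) on the result.
#'
#' @param request a [prediction_request()].
#' @param backend a backend callable (e.g. from [mock_backend()]).
#' @return a `predicted_structure`: atom table, per-residue pLDDT, sequence
#'   and provenance.
#' @export
predict_structure <- function(request, backend) {
  stopifnot(inherits(request, "prediction_request"), is.function(backend))
  out <- tryCatch(backend(request), error = function(e) {
    stop("prediction backend failed for sequence of length ",
         nchar(request$sequence), " (seed ", request$seed, ", recycles ",
         request$num_recycles, "): ", conditionMessage(e), call. = FALSE)
  })
  n <- nchar(request$sequence)
  if (length(unique(out$atoms$resno)) != n || length(out$plddt) != n) {
    stop("backend returned ", length(out$plddt),
         " residues for a sequence of length ", n, call. = FALSE)
  }
  out$provenance$seed <- request$seed
  out$provenance$num_recycles <- request$num_recycles
  out
}

new_predicted_structure <- function(sequence, atoms, plddt,
                                    provenance = list()) {
  stopifnot(all(is.finite(atom_xyz(atoms))), all(plddt >= 0 & plddt <= 100))
  structure(list(sequence = sequence, atoms = atoms, plddt = plddt,
                 provenance = provenance),
            class = "predicted_structure")
}

#' Deterministic synthetic predictor backend
#'
#' Builds the receptor span as an ideal alpha-helix, the peptide span as an
#' extended segment placed at a controllable minimum heavy-atom distance
#' from the receptor midsection, and the linker as a connecting path. The
#' peptide displacement is chosen, in order of precedence, by
#' `displacement_schedule(num_recycles)`, by `dock_at_recycles` (docked
#' distance once `num_recycles >= dock_at_recycles`, use `Inf` for
#' never-docking), or stochastically: each (sequence, seed, recycle count)
#' combination docks with probability `p_docked`, emulating the variability
#' that random masking induces in a real predictor.
#'
#' pLDDT profiles are configurable so ranking schemes can be stress-tested:
#' `"uniform"` assigns a constant; `"contact_correlated"` gives the peptide
#' high confidence (75-95) when it is docked (placement <= 8 A) and low
#' (20-50) otherwise; `"anticorrelated"` swaps the bands. Masked input
#' positions keep their geometry but have their pLDDT damped, reflecting the
#' reduced sequence information at those sites.
#'
#' @param spans segment map of the fused sequence this backend will be asked
#'   to fold (mock-only requirement; a real predictor needs no spans).
#' @param displacement_schedule optional function mapping a recycle count to
#'   a peptide displacement in Angstrom.
#' @param dock_at_recycles optional recycle threshold at which the peptide
#'   becomes docked; `Inf` means never.
#' @param p_docked docking probability in stochastic mode (default 0.5).
#' @param docked_range,undocked_range displacement ranges (A) sampled in the
#'   docked and undocked states.
#' @param noise_sigma isotropic Gaussian coordinate noise, in Angstrom.
#' @param plddt_mode one of `"uniform"`, `"contact_correlated"`,
#'   `"anticorrelated"`.
#' @param plddt_uniform constant used by the uniform mode.
#' @param mask_symbol placeholder character treated as low-information.
#' @return a backend function suitable for [predict_structure()].
#' @export
mock_backend <- function(spans,
                         displacement_schedule = NULL,
                         dock_at_recycles = NULL,
                         p_docked = 0.5,
                         docked_range = c(3.5, 7.5),
                         undocked_range = c(12, 30),
                         noise_sigma = 0,
                         plddt_mode = c("uniform", "contact_correlated",
                                        "anticorrelated"),
                         plddt_uniform = 80,
                         mask_symbol = "X") {
  plddt_mode <- match.arg(plddt_mode)
  check_number(p_docked, "p_docked", lower = 0, upper = 1)
  check_number(noise_sigma, "noise_sigma", lower = 0)
  force(spans)

  function(request) {
    sequence <- request$sequence
    validate_span_map(spans, nchar(sequence))
    seed0 <- derive_seed(request$seed, hash_string(sequence),
                         request$num_recycles)

    d <- if (!is.null(displacement_schedule)) {
      displacement_schedule(request$num_recycles)
    } else if (!is.null(dock_at_recycles)) {
      docked <- request$num_recycles >= dock_at_recycles
      rng <- if (docked) docked_range else undocked_range
      withr::with_seed(seed0, stats::runif(1, rng[1], rng[2]))
    } else {
      withr::with_seed(seed0, {
        docked <- stats::runif(1) < p_docked
        rng <- if (docked) docked_range else undocked_range
        stats::runif(1, rng[1], rng[2])
      })
    }

    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    ridx <- span_idx(spans$receptor)
    pidx <- span_idx(spans$peptide)
    lidx <- span_idx(spans$linker)

    receptor <- build_helix(chars[ridx])
    peptide <- build_extended(chars[pidx])
    # center the peptide on the receptor midsection before radial placement
    rxyz <- atom_xyz(receptor)
    pep_ctr <- colMeans(atom_xyz(peptide))
    peptide <- rigid_move(peptide,
                          translation = c(0, 0, mean(range(rxyz[, 3])) - pep_ctr[3]))
    peptide <- place_at_min_distance(receptor, peptide, d)

    parts <- list()
    receptor$resno <- ridx[receptor$resno]
    peptide$resno <- pidx[peptide$resno]
    parts <- list(receptor, peptide)
    if (length(lidx) > 0L) {
      from <- atom_xyz(receptor)[receptor$atom == "CA", , drop = FALSE]
      to <- atom_xyz(peptide)[peptide$atom == "CA", , drop = FALSE]
      linker <- build_path(chars[lidx], from[nrow(from), ], to[1, ])
      linker$resno <- lidx[linker$resno]
      parts <- c(parts, list(linker))
    }
    atoms <- do.call(rbind, parts)
    atoms <- atoms[order(atoms$resno, match(atoms$atom,
                                            c("N", "CA", "C", "O", "CB"))), ]
    rownames(atoms) <- NULL

    if (noise_sigma > 0) {
      xyz <- atom_xyz(atoms)
      noise <- withr::with_seed(derive_seed(seed0, 17L),
        matrix(stats::rnorm(length(xyz), sd = noise_sigma), ncol = 3))
      atoms <- set_atom_xyz(atoms, xyz + noise)
    }

    plddt <- mock_plddt(nchar(sequence), pidx, d, plddt_mode, plddt_uniform,
                        seed = derive_seed(seed0, 23L))
    plddt[chars == request$mask_symbol] <- plddt[chars == request$mask_symbol] * 0.8

    new_predicted_structure(sequence, atoms, plddt,
                            provenance = list(backend = "mock",
                                              displacement = d))
  }
}

mock_plddt <- function(n, pidx, displacement, mode, uniform_value, seed) {
  if (mode == "uniform") return(rep(uniform_value, n))
  docked <- displacement <= 8
  high <- c(75, 95); low <- c(20, 50)
  pep_band <- if (mode == "contact_correlated") {
    if (docked) high else low
  } else {
    if (docked) low else high
  }
  withr::with_seed(seed, {
    p <- stats::runif(n, 80, 95)           # receptor + linker: confident
    p[pidx] <- stats::runif(length(pidx), pep_band[1], pep_band[2])
    p
  })
}

#' Adaptive recycling
#'
#' Runs the backend at `base` recycles, and re-predicts with `step` more
#' recycles (up to `maximum`) while the peptide's minimum heavy-atom
#' distance to the receptor stays above `dock_cutoff`. Returns the first
#' docked structure, or the `maximum`-recycle structure flagged undocked.
#'
#' @param request a [prediction_request()]; its `num_recycles` is overridden
#'   by the schedule.
#' @param backend backend callable.
#' @param spans segment map locating receptor/linker/peptide in the sequence.
#' @param base,maximum,step recycle schedule (defaults 3, 12, 3).
#' @param dock_cutoff docking distance criterion in Angstrom (default 8).
#' @return list with `structure` (the `predicted_structure`), `model` (the
#'   excised [split_and_excise()] two-chain model), `recycles_used`, and
#'   `docked`.
#' @export
adaptive_predict <- function(request, backend, spans,
                             base = 3L, maximum = 12L, step = 3L,
                             dock_cutoff = 8) {
  base <- check_count(base, "base", lower = 0L)
  maximum <- check_count(maximum, "maximum", lower = 0L)
  step <- check_count(step, "step", lower = 1L)
  if (maximum < base) {
    stop("maximum recycles (", maximum, ") must be >= base (", base, ")",
         call. = FALSE)
  }
  r <- base
  repeat {
    req <- prediction_request(request$sequence, num_recycles = r,
                              seed = request$seed,
                              mask_symbol = request$mask_symbol)
    s <- predict_structure(req, backend)
    model <- split_and_excise(s, spans)
    docked <- is_docked(model, cutoff = dock_cutoff)
    if (docked || r >= maximum) {
      return(list(structure = s, model = model, recycles_used = r,
                  docked = docked))
    }
    r <- min(r + step, maximum)
  }
}
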