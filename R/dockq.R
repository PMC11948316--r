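# CAPRI-derived model quality: FNAT, iRMSD, LRMSD, and their DockQ
# combination. Conventions follow the community-standard DockQ definition:
# 5 A heavy-atom cutoff for native contacts, 10 A for the interface residue
# set, backbone atoms N/CA/C/O for RMSDs, characteristic scales 1.5 A
# (iRMSD) and 8.5 A (LRMSD).

#' Kabsch superposition
#'
#' Least-squares rigid superposition of `moving` onto `reference` via SVD of
#' the covariance matrix, with the reflection corrected so the rotation is
#' proper (determinant +1).
#'
#' @param moving,reference numeric matrices of matched points (rows), >= 3
#'   points each.
#' @return list with `rotation` (3x3, proper), `translation` (length 3) such
#'   that `moving %*% t(rotation) + translation` superposes onto
#'   `reference`, and `rmsd`, the minimized RMSD in Angstrom.
#' @export
kabsch_superpose <- function(moving, reference) {
  moving <- as.matrix(moving); reference <- as.matrix(reference)
  if (nrow(moving) != nrow(reference) || ncol(moving) != 3L ||
      ncol(reference) != 3L) {
    stop("moving and reference must be matched n x 3 coordinate matrices",
         call. = FALSE)
  }
  if (nrow(moving) < 3L) {
    stop("superposition needs at least 3 points", call. = FALSE)
  }
  if (any(!is.finite(moving)) || any(!is.finite(reference))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  cm <- colMeans(moving); cr <- colMeans(reference)
  M <- sweep(moving, 2, cm); R0 <- sweep(reference, 2, cr)
  H <- crossprod(M, R0)
  s <- svd(H)
  # collinear point sets leave the rotation about the axis undetermined
  if (s$d[2] < 1e-8 * max(s$d[1], 1e-12)) {
    stop("degenerate (collinear) point set: superposition is ambiguous",
         call. = FALSE)
  }
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- M %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - R0)^2)))
  list(rotation = rot, translation = as.numeric(cr - rot %*% cm), rmsd = rmsd)
}

apply_superposition <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% t(fit$rotation), 2, fit$translation, "+")
}

## Residue-level minimum heavy-atom cross-distance matrix (receptor x
## peptide), used by FNAT and the interface definition.
residue_cross_distances <- function(model) {
  a <- chain_atoms(model, "A")
  b <- chain_atoms(model, "B")
  ax <- atom_xyz(a); bx <- atom_xyz(b)
  d2 <- outer(rowSums(ax^2), rowSums(bx^2), "+") - 2 * tcrossprod(ax, bx)
  d2[d2 < 0] <- 0
  ra <- sort(unique(a$resno)); rb <- sort(unique(b$resno))
  out <- matrix(NA_real_, length(ra), length(rb),
                dimnames = list(ra, rb))
  ia <- split(seq_len(nrow(a)), a$resno)
  ib <- split(seq_len(nrow(b)), b$resno)
  for (i in seq_along(ra)) {
    rows <- ia[[as.character(ra[i])]]
    for (j in seq_along(rb)) {
      out[i, j] <- sqrt(min(d2[rows, ib[[as.character(rb[j])]]]))
    }
  }
  out
}

## Verify model/native correspondence: identical chain lengths and residue
## identities under the chain id + residue number pairing.
check_correspondence <- function(model, native) {
  for (ch in c("A", "B")) {
    m <- model$atoms[model$atoms$chain == ch, ]
    n <- native$atoms[native$atoms$chain == ch, ]
    maa <- tapply(m$aa, m$resno, function(v) v[1])
    naa <- tapply(n$aa, n$resno, function(v) v[1])
    if (length(maa) != length(naa)) {
      stop("chain ", ch, " length differs between model (", length(maa),
           ") and native (", length(naa), ")", call. = FALSE)
    }
    if (!identical(unname(maa), unname(naa))) {
      bad <- which(maa != naa)[1]
      stop("chain ", ch, " residue ", names(maa)[bad],
           " differs between model (", maa[bad], ") and native (",
           naa[bad], ")", call. = FALSE)
    }
  }
  invisible(TRUE)
}

## Matched backbone coordinate matrices for a set of (chain, resno) keys.
## Residues missing any backbone atom in either structure are dropped with a
## warning; more than 10% missing is an error.
matched_backbone <- function(model, native, keys) {
  get_bb <- function(m, ch, res) {
    a <- m$atoms[m$atoms$chain == ch & m$atoms$resno == res &
                   m$atoms$atom %in% BACKBONE_ATOMS, , drop = FALSE]
    a <- a[match(BACKBONE_ATOMS, a$atom), , drop = FALSE]
    if (any(is.na(a$atom))) return(NULL)
    atom_xyz(a)
  }
  mm <- list(); nn <- list(); dropped <- 0L
  for (k in seq_len(nrow(keys))) {
    bm <- get_bb(model, keys$chain[k], keys$resno[k])
    bn <- get_bb(native, keys$chain[k], keys$resno[k])
    if (is.null(bm) || is.null(bn)) { dropped <- dropped + 1L; next }
    mm[[length(mm) + 1L]] <- bm
    nn[[length(nn) + 1L]] <- bn
  }
  if (dropped > 0L) {
    warning(dropped, " residue(s) dropped for missing backbone atoms")
    if (dropped > 0.1 * nrow(keys)) {
      stop("more than 10% of required backbone atoms are missing",
           call. = FALSE)
    }
  }
  list(model = do.call(rbind, mm), native = do.call(rbind, nn))
}

#' Fraction of native contacts (FNAT)
#'
#' Native contacts are receptor-peptide residue pairs with any heavy-atom
#' distance at most `contact_cutoff` in the native; FNAT is the fraction of
#' those pairs still in contact in the model.
#'
#' @param model,native `complex_model` objects with matching chains.
#' @param contact_cutoff contact distance in Angstrom (default 5).
#' @return fraction in \[0, 1\].
#' @export
fnat <- function(model, native, contact_cutoff = 5) {
  check_correspondence(model, native)
  dn <- residue_cross_distances(native)
  native_contacts <- which(dn <= contact_cutoff)
  if (length(native_contacts) == 0L) {
    stop("native complex has no cross-chain contacts at ", contact_cutoff,
         " A: malformed reference", call. = FALSE)
  }
  dm <- residue_cross_distances(model)
  sum(dm[native_contacts] <= contact_cutoff) / length(native_contacts)
}

#' Ligand RMSD (LRMSD)
#'
#' Superposes the model onto the native over receptor backbone atoms, then
#' reports the RMSD over peptide backbone atoms under that transform.
#'
#' @param model,native `complex_model` objects with matching chains.
#' @return RMSD in Angstrom.
#' @export
lrmsd <- function(model, native) {
  check_correspondence(model, native)
  rec_res <- sort(unique(native$atoms$resno[native$atoms$chain == "A"]))
  pep_res <- sort(unique(native$atoms$resno[native$atoms$chain == "B"]))
  rec <- matched_backbone(model, native,
                          data.frame(chain = "A", resno = rec_res))
  pep <- matched_backbone(model, native,
                          data.frame(chain = "B", resno = pep_res))
  fit <- kabsch_superpose(rec$model, rec$native)
  moved <- apply_superposition(pep$model, fit)
  sqrt(mean(rowSums((moved - pep$native)^2)))
}

#' Interface RMSD (iRMSD)
#'
#' Interface residues are those of either chain with any cross-chain
#' heavy-atom distance at most `interface_cutoff` in the native. The model
#' is superposed onto the native over the backbone atoms of that set and the
#' minimized RMSD is reported.
#'
#' @param model,native `complex_model` objects with matching chains.
#' @param interface_cutoff interface distance in Angstrom (default 10).
#' @return RMSD in Angstrom.
#' @export
irmsd <- function(model, native, interface_cutoff = 10) {
  check_correspondence(model, native)
  dn <- residue_cross_distances(native)
  in_a <- as.integer(rownames(dn))[apply(dn <= interface_cutoff, 1, any)]
  in_b <- as.integer(colnames(dn))[apply(dn <= interface_cutoff, 2, any)]
  if (length(in_a) + length(in_b) == 0L) {
    stop("native complex has an empty interface at ", interface_cutoff, " A",
         call. = FALSE)
  }
  keys <- rbind(data.frame(chain = "A", resno = in_a),
                data.frame(chain = "B", resno = in_b))
  bb <- matched_backbone(model, native, keys)
  kabsch_superpose(bb$model, bb$native)$rmsd
}

#' Combine FNAT, iRMSD and LRMSD into the DockQ score
#'
#' `DockQ = (FNAT + 1/(1 + (iRMSD/1.5)^2) + 1/(1 + (LRMSD/8.5)^2)) / 3`.
#'
#' @param fnat fraction of native contacts in \[0, 1\].
#' @param irmsd,lrmsd RMSDs in Angstrom (>= 0).
#' @return DockQ score in \[0, 1\].
#' @export
dockq_score <- function(fnat, irmsd, lrmsd) {
  check_number(fnat, "fnat", lower = 0, upper = 1)
  check_number(irmsd, "irmsd", lower = 0)
  check_number(lrmsd, "lrmsd", lower = 0)
  (fnat + 1 / (1 + (irmsd / 1.5)^2) + 1 / (1 + (lrmsd / 8.5)^2)) / 3
}

#' Classify a DockQ score into a CAPRI quality category
#'
#' Bins (left-closed): incorrect \[0, 0.23), acceptable \[0.23, 0.5),
#' medium \[0.5, 0.8), high \[0.8, 1\].
#'
#' @param dockq score in \[0, 1\].
#' @return one of `"incorrect"`, `"acceptable"`, `"medium"`, `"high"`.
#' @export
classify_dockq <- function(dockq) {
  check_number(dockq, "dockq", lower = 0, upper = 1)
  if (dockq >= 0.8) "high"
  else if (dockq >= 0.5) "medium"
  else if (dockq >= 0.23) "acceptable"
  else "incorrect"
}

#' Evaluate a model against a native complex
#'
#' Computes FNAT, iRMSD, LRMSD, the combined DockQ score, and its quality
#' category.
#'
#' @param model,native `complex_model` objects with matching chains.
#' @param contact_cutoff FNAT contact cutoff (default 5 A).
#' @param interface_cutoff iRMSD interface cutoff (default 10 A).
#' @return an object of class `dockq_result` with elements `fnat`, `irmsd`,
#'   `lrmsd`, `dockq`, `category`.
#' @export
dockq_eval <- function(model, native, contact_cutoff = 5,
                       interface_cutoff = 10) {
  f <- fnat(model, native, contact_cutoff)
  ir <- irmsd(model, native, interface_cutoff)
  lr <- lrmsd(model, native)
  q <- dockq_score(f, ir, lr)
  structure(list(fnat = f, irmsd = ir, lrmsd = lr, dockq = q,
                 category = classify_dockq(q)),
            class = "dockq_result")
}

#' @export
print.dockq_result <- function(x, ...) {
  cat(sprintf("DockQ %.3f (%s)  FNAT %.3f  iRMSD %.2f A  LRMSD %.2f A\n",
              x$dockq, x$category, x$fnat, x$irmsd, x$lrmsd))
  invisible(x)
}
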