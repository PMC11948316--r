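# Independent oracles: deliberately different code paths from the package
# internals they check.

# Exhaustive minimum cross-chain distance: iterate atoms of one chain,
# vectorized distance to every atom of the other.
brute_min_distance <- function(model, policy = "heavy_atoms") {
  pick <- function(chain) {
    a <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
    if (policy == "backbone_only") a <- a[a$atom %in% c("N", "CA", "C", "O"), ]
    else a <- a[a$element != "H", ]
    as.matrix(a[, c("x", "y", "z")])
  }
  A <- pick("A"); B <- pick("B")
  best <- Inf
  for (i in seq_len(nrow(A))) {
    d <- sqrt(colSums((t(B) - A[i, ])^2))
    best <- min(best, min(d))
  }
  best
}

# Exhaustive residue-pair contact enumeration (heavy atoms).
brute_contact_pairs <- function(model, cutoff) {
  a <- model$atoms[model$atoms$chain == "A" & model$atoms$element != "H", ]
  b <- model$atoms[model$atoms$chain == "B" & model$atoms$element != "H", ]
  out <- NULL
  for (ra in sort(unique(a$resno))) {
    xa <- as.matrix(a[a$resno == ra, c("x", "y", "z")])
    for (rb in sort(unique(b$resno))) {
      xb <- as.matrix(b[b$resno == rb, c("x", "y", "z")])
      dmin <- Inf
      for (i in seq_len(nrow(xa))) {
        dmin <- min(dmin, sqrt(colSums((t(xb) - xa[i, ])^2)))
      }
      if (dmin <= cutoff) out <- rbind(out, c(ra, rb))
    }
  }
  out
}

# Peptide residues in contact, from the exhaustive pair enumeration.
brute_contacting_residues <- function(model, cutoff) {
  pairs <- brute_contact_pairs(model, cutoff)
  if (is.null(pairs)) integer(0) else sort(unique(pairs[, 2]))
}

# Horn's quaternion superposition: closed-form optimal rotation from the
# largest eigenvalue of the 4x4 key matrix.
quaternion_superpose <- function(moving, reference) {
  p <- sweep(moving, 2, colMeans(moving))
  q <- sweep(reference, 2, colMeans(reference))
  R <- crossprod(p, q)
  K <- rbind(
    c(R[1, 1] + R[2, 2] + R[3, 3], R[2, 3] - R[3, 2],
      R[3, 1] - R[1, 3], R[1, 2] - R[2, 1]),
    c(R[2, 3] - R[3, 2], R[1, 1] - R[2, 2] - R[3, 3],
      R[1, 2] + R[2, 1], R[1, 3] + R[3, 1]),
    c(R[3, 1] - R[1, 3], R[1, 2] + R[2, 1],
      -R[1, 1] + R[2, 2] - R[3, 3], R[2, 3] + R[3, 2]),
    c(R[1, 2] - R[2, 1], R[1, 3] + R[3, 1],
      R[2, 3] + R[3, 2], -R[1, 1] - R[2, 2] + R[3, 3]))
  e <- eigen(K, symmetric = TRUE)
  lambda <- e$values[1]
  v <- e$vectors[, 1]
  w <- v[1]; x <- v[2]; y <- v[3]; z <- v[4]
  rot <- rbind(
    c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2))
  msd <- (sum(p^2) + sum(q^2) - 2 * lambda) / nrow(p)
  list(rotation = rot, rmsd = sqrt(max(msd, 0)))
}

# Two-step LRMSD oracle: quaternion superposition on the receptor backbone,
# explicit transform of the peptide backbone, plain RMSD.
oracle_lrmsd <- function(model, native) {
  bb <- function(m, ch) {
    a <- m$atoms[m$atoms$chain == ch & m$atoms$atom %in% c("N", "CA", "C", "O"), ]
    a <- a[order(a$resno, match(a$atom, c("N", "CA", "C", "O"))), ]
    as.matrix(a[, c("x", "y", "z")])
  }
  rm_ <- bb(model, "A"); rn <- bb(native, "A")
  pm <- bb(model, "B"); pn <- bb(native, "B")
  fit <- quaternion_superpose(rm_, rn)
  moved <- sweep(sweep(rm_, 2, colMeans(rm_)), 2, colMeans(rm_), "+") # no-op, clarity
  pep_moved <- sweep(sweep(pm, 2, colMeans(rm_)) %*% t(fit$rotation),
                     2, colMeans(rn), "+")
  sqrt(mean(rowSums((pep_moved - pn)^2)))
}
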