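# Idealized chain geometry and rigid-body helpers. Chains carry backbone
# (N, CA, C, O) plus CB; that atom set supports every distance and RMSD
# operation in the protocol without side-chain chemistry.

deg2rad <- function(d) d * pi / 180

## Atom tables are data.frames: resno, aa, atom, element, x, y, z.
new_atom_table <- function(resno, aa, atom, x, y, z) {
  data.frame(resno = as.integer(resno), aa = aa, atom = atom,
             element = substr(atom, 1L, 1L),
             x = x, y = y, z = z, stringsAsFactors = FALSE)
}

atom_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

set_atom_xyz <- function(atoms, xyz) {
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

## Ideal alpha-helix along +z: 1.5 A rise and 100 degree twist per residue,
## CA on a 2.3 A cylinder; N/C/O/CB placed at fixed offsets in the local
## helical frame. Geometrically idealized, not energetically minimized.
build_helix <- function(aa_seq, rise = 1.5, twist = 100, radius = 2.3) {
  n <- length(aa_seq)
  per_res <- function(i) {
    th <- deg2rad((i - 1) * twist)
    z0 <- (i - 1) * rise
    cyl <- function(r, dth, dz) c(r * cos(th + deg2rad(dth)),
                                  r * sin(th + deg2rad(dth)), z0 + dz)
    rbind(N  = cyl(1.6, -35, -0.9),
          CA = cyl(radius, 0, 0),
          C  = cyl(1.7, 35, 0.9),
          O  = cyl(2.9, 40, 1.1),
          CB = cyl(3.6, -12, -0.2))
  }
  xyz <- do.call(rbind, lapply(seq_len(n), per_res))
  new_atom_table(rep(seq_len(n), each = 5L), rep(aa_seq, each = 5L),
                 rep(c("N", "CA", "C", "O", "CB"), n),
                 xyz[, 1], xyz[, 2], xyz[, 3])
}

## Extended strand along +z with 3.5 A per residue and a small zigzag.
build_extended <- function(aa_seq, spacing = 3.5) {
  n <- length(aa_seq)
  per_res <- function(i) {
    z0 <- (i - 1) * spacing
    y0 <- 0.6 * (-1)^i
    rbind(N  = c(0.0, y0 + 0.4, z0 - 1.2),
          CA = c(0.0, y0, z0),
          C  = c(0.0, y0 + 0.4, z0 + 1.2),
          O  = c(1.1, y0 + 0.8, z0 + 1.4),
          CB = c(-1.3, y0 - 0.7, z0))
  }
  xyz <- do.call(rbind, lapply(seq_len(n), per_res))
  new_atom_table(rep(seq_len(n), each = 5L), rep(aa_seq, each = 5L),
                 rep(c("N", "CA", "C", "O", "CB"), n),
                 xyz[, 1], xyz[, 2], xyz[, 3])
}

## Straight CA-trace path between two anchor points (used for linker
## residues, which are excised after prediction; only finiteness matters).
build_path <- function(aa_seq, from, to) {
  n <- length(aa_seq)
  f <- seq(0, 1, length.out = n + 2L)[2:(n + 1L)]
  per_res <- function(i) {
    p <- from + f[i] * (to - from)
    rbind(N  = p + c(-0.5, 0.3, 0),
          CA = p,
          C  = p + c(0.5, 0.3, 0),
          O  = p + c(0.7, 1.3, 0),
          CB = p + c(0, -1.0, 1.0))
  }
  xyz <- do.call(rbind, lapply(seq_len(n), per_res))
  new_atom_table(rep(seq_len(n), each = 5L), rep(aa_seq, each = 5L),
                 rep(c("N", "CA", "C", "O", "CB"), n),
                 xyz[, 1], xyz[, 2], xyz[, 3])
}

## Minimum distance between two coordinate sets (rows are points).
min_cross_distance_xyz <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

## Rotation matrix from an xyz Euler-angle triple (degrees).
euler_rotation <- function(angles) {
  a <- deg2rad(angles[1]); b <- deg2rad(angles[2]); g <- deg2rad(angles[3])
  rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

## Rotate atoms about their centroid, then translate.
rigid_move <- function(atoms, rotation = c(0, 0, 0), translation = c(0, 0, 0)) {
  xyz <- atom_xyz(atoms)
  ctr <- colMeans(xyz)
  R <- euler_rotation(rotation)
  moved <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr + translation, "+")
  set_atom_xyz(atoms, moved)
}

## Translate peptide atoms along +x until the minimum interatomic distance
## to the receptor equals `target` (fixed-point iteration; monotone once the
## peptide is outside the receptor envelope).
place_at_min_distance <- function(receptor_atoms, peptide_atoms, target,
                                  tol = 0.02, max_iter = 60L) {
  rx <- atom_xyz(receptor_atoms)
  px <- atom_xyz(peptide_atoms)
  # start from a safe offset beyond the receptor's +x extent
  shift <- max(rx[, 1]) - min(px[, 1]) + target + 10
  px[, 1] <- px[, 1] + shift
  for (i in seq_len(max_iter)) {
    d <- min_cross_distance_xyz(rx, px)
    if (abs(d - target) < tol) break
    px[, 1] <- px[, 1] - (d - target)
  }
  set_atom_xyz(peptide_atoms, px)
}
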