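# Kabsch superposition, CAPRI components, DockQ combination, classification.

test_that("kabsch recovers exact rigid motions", {
  set.seed(5)
  x <- matrix(rnorm(30), ncol = 3)
  id <- kabsch_superpose(x, x)
  expect_equal(id$rmsd, 0, tolerance = 1e-10)
  expect_equal(id$rotation, diag(3), tolerance = 1e-8)

  R <- pepdock:::euler_rotation(c(25, -40, 110))
  t0 <- c(3, -7, 2)
  y <- x %*% t(R) + matrix(t0, nrow(x), 3, byrow = TRUE)
  fit <- kabsch_superpose(x, y)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(fit$rotation, R, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_equal(x %*% t(fit$rotation) +
                 matrix(fit$translation, nrow(x), 3, byrow = TRUE),
               y, tolerance = 1e-8)
})

test_that("kabsch agrees with an independent quaternion superposition", {
  set.seed(17)
  for (i in 1:30) {
    a <- matrix(rnorm(30, sd = 5), ncol = 3)
    b <- matrix(rnorm(30, sd = 5), ncol = 3)
    k <- kabsch_superpose(a, b)
    q <- quaternion_superpose(a, b)
    expect_equal(k$rmsd, q$rmsd, tolerance = 1e-6)
    expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  }
})

test_that("degenerate point sets are rejected", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("fnat is exact on constructed contact sets", {
  nat <- small_native(seed = 2)
  expect_equal(fnat(nat$model, nat$model), 1.0)

  far <- make_decoy(nat$model, displacement = 50)
  expect_equal(fnat(far, nat$model), 0.0)

  # 8 native contacts, exactly half preserved: receptor residues on a 10 A
  # grid, one peptide residue 3 A from each; the model moves 4 of them away
  rec <- cbind(0, 10 * (0:7), 0)
  pep_native <- cbind(3, 10 * (0:7), 0)
  pep_model <- pep_native
  pep_model[5:8, 1] <- 20
  native <- point_model(rec, pep_native)
  model <- point_model(rec, pep_model)
  dn <- pepdock:::residue_cross_distances(native)
  expect_equal(sum(dn <= 5), 8)
  expect_equal(fnat(model, native), 0.5)
})

test_that("fnat and the production contact index match exhaustive
           enumeration on random toys", {
  for (seed in 1:15) {
    m <- random_toy_model(seed)
    d <- pepdock:::residue_cross_distances(m)
    got <- which(d <= 5, arr.ind = TRUE)
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    want <- brute_contact_pairs(m, 5)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(unname(cbind(as.integer(rownames(d))[got[, 1]],
                                as.integer(colnames(d))[got[, 2]])),
                   unname(want))
    }
  }
})

test_that("lrmsd equals a rigid peptide offset and the two-step oracle", {
  nat <- small_native(seed = 3)
  expect_equal(lrmsd(nat$model, nat$model), 0, tolerance = 1e-10)

  shifted <- make_decoy(nat$model, displacement = 5)
  expect_equal(lrmsd(shifted, nat$model), 5.0, tolerance = 1e-6)

  noisy <- make_decoy(nat$model, displacement = 3, rotation = c(10, 5, -15),
                      noise_sigma = 0.3, seed = 9)
  expect_equal(lrmsd(noisy, nat$model), oracle_lrmsd(noisy, nat$model),
               tolerance = 1e-6)
})

test_that("irmsd is zero on self, positive for interface perturbations, and
           its interface set matches brute-force enumeration", {
  nat <- small_native(seed = 4)
  expect_equal(irmsd(nat$model, nat$model), 0, tolerance = 1e-10)

  # peptide-only perturbation: receptor-only RMSD stays 0, iRMSD > 0
  decoy <- make_decoy(nat$model, displacement = 2)
  rec_m <- decoy$atoms[decoy$atoms$chain == "A" &
                         decoy$atoms$atom %in% c("N", "CA", "C", "O"), ]
  rec_n <- nat$model$atoms[nat$model$atoms$chain == "A" &
                             nat$model$atoms$atom %in% c("N", "CA", "C", "O"), ]
  rec_fit <- kabsch_superpose(as.matrix(rec_m[, c("x", "y", "z")]),
                              as.matrix(rec_n[, c("x", "y", "z")]))
  expect_equal(rec_fit$rmsd, 0, tolerance = 1e-10)
  expect_gt(irmsd(decoy, nat$model), 0)

  # interface residues at 10 A match the exhaustive scan
  pairs <- brute_contact_pairs(nat$model, 10)
  d <- pepdock:::residue_cross_distances(nat$model)
  in_a <- as.integer(rownames(d))[apply(d <= 10, 1, any)]
  in_b <- as.integer(colnames(d))[apply(d <= 10, 2, any)]
  expect_equal(in_a, sort(unique(pairs[, 1])))
  expect_equal(in_b, sort(unique(pairs[, 2])))
})

test_that("dockq_score matches its closed form and limits", {
  expect_equal(dockq_score(1, 0, 0), 1.0)
  expect_equal(dockq_score(0.5, 1.5, 8.5), 0.5)
  expect_lt(dockq_score(0, 1e6, 1e6), 1e-6)
})

test_that("dockq_score is monotone in each component", {
  set.seed(23)
  for (i in 1:50) {
    f <- runif(1); ir <- runif(1, 0, 20); lr <- runif(1, 0, 40)
    df <- runif(1, 0, 1 - f); dr <- runif(1, 0, 5)
    expect_gte(dockq_score(f + df, ir, lr), dockq_score(f, ir, lr))
    expect_lte(dockq_score(f, ir + dr, lr), dockq_score(f, ir, lr))
    expect_lte(dockq_score(f, ir, lr + dr), dockq_score(f, ir, lr))
  }
})

test_that("classification uses left-closed CAPRI bins", {
  expect_equal(classify_dockq(0.25), "acceptable")
  expect_equal(classify_dockq(0.8), "high")
  expect_equal(classify_dockq(0.22), "incorrect")
  expect_equal(classify_dockq(0.23), "acceptable")
  expect_equal(classify_dockq(0.5), "medium")
  expect_equal(classify_dockq(0), "incorrect")
  expect_equal(classify_dockq(1), "high")
  expect_error(classify_dockq(1.2), "dockq")
})

test_that("dockq_eval is internally consistent and perfect on self", {
  for (seed in c(1, 6, 11)) {
    nat <- small_native(seed = seed)
    self <- dockq_eval(nat$model, nat$model)
    expect_equal(self$fnat, 1)
    expect_equal(self$irmsd, 0, tolerance = 1e-10)
    expect_equal(self$lrmsd, 0, tolerance = 1e-10)
    expect_equal(self$dockq, 1, tolerance = 1e-10)
    expect_equal(self$category, "high")

    decoy <- make_decoy(nat$model, displacement = runif(1, 0, 10),
                        noise_sigma = 0.2, seed = seed)
    r <- dockq_eval(decoy, nat$model)
    expect_equal(r$dockq, dockq_score(r$fnat, r$irmsd, r$lrmsd))
    expect_equal(r$category, classify_dockq(r$dockq))
  }
})

test_that("model/native correspondence is enforced", {
  nat <- small_native(seed = 2)
  other <- small_native(seed = 12)
  expect_error(dockq_eval(other$model, nat$model), "differs")
})
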