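test_that("inbreeding is zero for founders and exact for classic matings", {
  # full-sib mating: offspring of two full sibs has F = 0.25
  fullsib <- tibble::tibble(
    animal_id = c("A", "B", "C", "D", "E"),
    sire_id = c(NA, NA, "A", "A", "C"),
    dam_id = c(NA, NA, "B", "B", "D"),
    birth_date = as.Date("2000-01-01") + 0:4, sex = c("M", "F", "M", "F", "F"))
  f <- compute_inbreeding(fullsib)
  expect_equal(f$F[f$animal_id %in% c("A", "B")], c(0, 0))
  expect_equal(f$F[f$animal_id == "E"], 0.25)

  # parent-offspring mating: F = 0.25
  po <- tibble::tibble(
    animal_id = c("A", "B", "C", "E"),
    sire_id = c(NA, NA, "A", "A"),
    dam_id = c(NA, NA, "B", "C"),
    birth_date = as.Date("2000-01-01") + 0:3, sex = c("M", "F", "F", "F"))
  f2 <- compute_inbreeding(po)
  expect_equal(f2$F[f2$animal_id == "E"], 0.25)
})

test_that("inbreeding matches the tabular-method diagonal on random pedigrees", {
  for (seed in 1:4) {
    ped <- random_pedigree(60, seed = seed)
    f <- compute_inbreeding(ped)
    A <- tabular_A(ped)
    expect_equal(f$F, unname(diag(A)[ped$animal_id]) - 1, tolerance = 1e-12)
  }
})

test_that("pedigree cycles are rejected", {
  bad <- tibble::tibble(animal_id = c("A", "B"), sire_id = c("B", "A"),
                        dam_id = c(NA, NA))
  expect_error(compute_inbreeding(bad), "cycle")
})

test_that("A-inverse follows Henderson's rules exactly on the trio", {
  Ainv <- build_A_inverse(trio_pedigree())
  expected <- matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3, 3,
                     dimnames = list(c("S", "D", "O"), c("S", "D", "O")))
  expect_equal(as.matrix(Ainv), expected, tolerance = 1e-12)

  # two unrelated founders: identity
  two <- tibble::tibble(animal_id = c("X", "Y"), sire_id = NA_character_,
                        dam_id = NA_character_)
  expect_equal(unname(as.matrix(build_A_inverse(two))), diag(2))
})

test_that("A-inverse inverts the tabular A on random pedigrees with inbreeding", {
  for (seed in c(11, 12, 13)) {
    ped <- random_pedigree(200, seed = seed)
    A <- tabular_A(ped)
    Ainv <- as.matrix(build_A_inverse(ped))
    expect_lt(max(abs(Ainv %*% A - diag(nrow(A)))), 1e-8)
  }
})

test_that("pedigree relationship block reproduces the tabular submatrix", {
  ped <- random_pedigree(80, seed = 5)
  A <- tabular_A(ped)
  ids <- ped$animal_id[c(3, 20, 50, 77)]
  blk <- pedigree_relationship_block(build_A_inverse(ped), ids)
  expect_equal(blk, A[ids, ids], tolerance = 1e-8)
})

test_that("VanRaden G has the expected structure", {
  # fully heterozygous animal at p = 0.5 everywhere: zero diagonal entry
  M <- rbind(a1 = rep(1L, 50), a2 = rep(c(0L, 2L), 25))
  G <- build_G(M, allele_freqs = rep(0.5, 50))
  expect_equal(G["a1", "a1"], 0)

  # identical genotype rows give identical G rows
  M2 <- rbind(x = c(0, 1, 2, 1, 0), y = c(0, 1, 2, 1, 0), z = c(2, 1, 0, 1, 2))
  G2 <- build_G(M2)
  expect_equal(G2["x", ], G2["y", ])

  # all monomorphic fails
  expect_error(build_G(rbind(a = c(0, 0), b = c(0, 0))), "monomorphic")
})

test_that("genomic relationships of simulated sibs match pedigree expectation", {
  # many half-sib pairs through a common sire, plus unrelated founders
  n_fam <- 120
  ped <- tibble::tibble(
    animal_id = c("SIRE", sprintf("D%03d", 1:n_fam), sprintf("O%03d", 1:n_fam)),
    sire_id = c(NA, rep(NA, n_fam), rep("SIRE", n_fam)),
    dam_id = c(NA, rep(NA, n_fam), sprintf("D%03d", 1:n_fam)),
    birth_date = as.Date("2000-01-01") + seq_len(2 * n_fam + 1),
    sex = c("M", rep("F", 2 * n_fam)))
  cfg <- sim_config(n_founders = 2, n_snps = 5000, seed = 42)
  gen <- simulate_genotypes(ped, cfg)
  G <- build_G(gen$dosages, allele_freqs = gen$allele_freqs)
  off <- sprintf("O%03d", 1:n_fam)
  offdiag <- G[off, off][upper.tri(diag(n_fam))]
  expect_equal(mean(offdiag), 0.25, tolerance = 0.05)
})

test_that("APY inverse with a full core equals the direct inverse", {
  set.seed(9)
  Z <- matrix(rbinom(40 * 400, 2, 0.4), 40, 400,
              dimnames = list(sprintf("g%02d", 1:40), NULL))
  G <- build_G(Z)
  G <- 0.95 * G + 0.05 * diag(40)  # ensure invertibility
  dimnames(G) <- list(rownames(Z), rownames(Z))
  Ginv <- solve(G)
  apy_full <- invert_G_apy(G, core_ids = rownames(G))
  expect_lt(max(abs(apy_full - Ginv)), 1e-8)
})

test_that("APY with a large random core approximates the direct inverse", {
  set.seed(10)
  n <- 120
  Z <- matrix(rbinom(n * 800, 2, 0.35), n, 800,
              dimnames = list(sprintf("g%03d", 1:n), NULL))
  G <- build_G(Z)
  G <- 0.95 * G + 0.05 * diag(n)
  dimnames(G) <- list(rownames(Z), rownames(Z))
  set.seed(11)
  apy <- invert_G_apy(G, n_core = 100)
  # APY is an approximation off-core; demand good reconstruction of G^-1 G
  err <- max(abs(G %*% apy - diag(n)))
  expect_lt(err, 0.35)
  # and convergence: a bigger core does strictly better
  set.seed(11)
  apy_all <- invert_G_apy(G, n_core = n)
  expect_lt(max(abs(G %*% apy_all - diag(n))), 1e-8)
})

test_that("H-inverse equals A-inverse outside the genotyped block and adds G/A22 corrections inside", {
  ped <- random_pedigree(40, seed = 21)
  Ainv <- build_A_inverse(ped)
  geno_ids <- ped$animal_id[c(10, 25, 33)]
  A22 <- tabular_A(ped)[geno_ids, geno_ids]
  set.seed(22)
  M <- matrix(rbinom(3 * 200, 2, 0.4), 3, 200,
              dimnames = list(geno_ids, NULL))
  G <- build_G(M, A22 = A22, blend_weight = 0.95)
  Ginv <- solve(G)
  A22inv <- solve(A22)
  Hinv <- assemble_H_inverse(Ainv, Ginv, A22inv)

  D <- as.matrix(Hinv - Ainv)
  pos <- match(geno_ids, ped$animal_id)
  expect_equal(D[pos, pos], Ginv - A22inv, tolerance = 1e-10,
               ignore_attr = TRUE)
  D[pos, pos] <- 0
  expect_equal(max(abs(D)), 0)

  # no genotyped animals: H-inverse reduces to A-inverse
  emptyG <- matrix(0, 0, 0)
  # degenerate case covered via G numerically equal to A22
  Hsame <- assemble_H_inverse(Ainv, A22inv, A22inv)
  expect_lt(max(abs(Hsame - Ainv)), 1e-10)
  expect_true(Matrix::isSymmetric(Hinv))
})

test_that("blended G is positive definite", {
  ped <- random_pedigree(30, seed = 31)
  ids <- ped$animal_id[15:30]
  A22 <- tabular_A(ped)[ids, ids]
  set.seed(32)
  M <- matrix(rbinom(16 * 10, 2, 0.5), 16, 10, dimnames = list(ids, NULL))
  G_raw <- build_G(M)                      # rank-deficient: more animals than SNPs
  ev_raw <- eigen(G_raw, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev_raw), -1e-8)            # PSD before blending
  G <- build_G(M, A22 = A22, blend_weight = 0.95)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 1e-6)                 # PD after blending
})
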