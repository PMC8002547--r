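#' Relationship-matrix machinery for single-step evaluation
#'
#' These functions build the pedigree and genomic relationship structures the
#' single-step evaluation rests on: inbreeding coefficients, the sparse
#' pedigree-relationship inverse by Henderson's rules, the VanRaden genomic
#' relationship matrix, its APY inverse, and the combined H-inverse in which
#' the genomic information replaces the pedigree block for genotyped animals.
#'
#' A pedigree is a tibble with columns `animal_id`, `sire_id`, `dam_id`
#' (character; `NA` is the unknown-parent sentinel). All matrices carry
#' animal ids as dimnames.
#'
#' @name relmat
NULL

# Topological ordering of a pedigree (parents before offspring). Errors on a
# cycle or on a parent that never appears as an animal being silently created:
# parents not listed as animals are treated as unknown founders of the listed
# animal (a warning is raised).
order_pedigree <- function(pedigree) {
  stopifnot(all(c("animal_id", "sire_id", "dam_id") %in% names(pedigree)))
  ped <- as_tibble(pedigree)
  if (anyDuplicated(ped$animal_id) > 0) {
    abort("duplicated animal_id in pedigree")
  }
  id <- ped$animal_id
  sire <- match(ped$sire_id, id)
  dam <- match(ped$dam_id, id)
  unknown_parent <- (!is.na(ped$sire_id) & is.na(sire)) |
    (!is.na(ped$dam_id) & is.na(dam))
  if (any(unknown_parent)) {
    warn(sprintf("%d parent id(s) absent from pedigree; treated as unknown",
                 sum(unknown_parent)))
  }
  n <- nrow(ped)
  sire[is.na(sire)] <- 0L
  dam[is.na(dam)] <- 0L
  # Kahn's algorithm
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire[i], dam[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue) > 0) {
    ord <- c(ord, queue)
    nxt <- integer(0)
    for (v in queue) {
      for (k in kids[[v]]) {
        indeg[k] <- indeg[k] - 1L
        if (indeg[k] == 0L) nxt <- c(nxt, k)
      }
    }
    queue <- nxt
  }
  if (length(ord) < n) abort("pedigree contains a cycle")
  perm <- ord
  list(pedigree = ped[perm, , drop = FALSE],
       sire = match(ped$sire_id[perm], ped$animal_id[perm], nomatch = 0L),
       dam = match(ped$dam_id[perm], ped$animal_id[perm], nomatch = 0L))
}

#' Inbreeding coefficients from a pedigree
#'
#' Exact per-animal inbreeding coefficients by the Meuwissen & Luo
#' algorithm, equivalent to the diagonal of the tabular relationship matrix
#' (`A_ii = 1 + F_i`). Founders have `F = 0`.
#'
#' @param pedigree Tibble with `animal_id`, `sire_id`, `dam_id` columns
#'   (`NA` = unknown parent).
#' @return A tibble with columns `animal_id` and `F`, in the input order.
#' @export
compute_inbreeding <- function(pedigree) {
  top <- order_pedigree(pedigree)
  f <- inbreeding_ml_cpp(top$sire, top$dam)
  out <- tibble(animal_id = top$pedigree$animal_id, F = f)
  out[match(pedigree$animal_id, out$animal_id), , drop = FALSE]
}

#' Sparse inverse of the pedigree relationship matrix
#'
#' Henderson's rules with inbreeding-adjusted Mendelian-sampling variances:
#' the exact inverse of the tabular relationship matrix A.
#'
#' @inheritParams compute_inbreeding
#' @param inbreeding Optional tibble as returned by [compute_inbreeding()];
#'   computed when missing.
#' @return A sparse symmetric matrix (`dsCMatrix`) with animal ids as
#'   dimnames, rows/columns in pedigree input order.
#' @export
build_A_inverse <- function(pedigree, inbreeding = NULL) {
  inbreeding <- inbreeding %||% compute_inbreeding(pedigree)
  fvec <- inbreeding$F[match(pedigree$animal_id, inbreeding$animal_id)]
  id <- pedigree$animal_id
  n <- length(id)
  sire <- match(pedigree$sire_id, id, nomatch = 0L)
  dam <- match(pedigree$dam_id, id, nomatch = 0L)

  fs <- ifelse(sire > 0L, fvec[pmax(sire, 1L)], 0)
  fd <- ifelse(dam > 0L, fvec[pmax(dam, 1L)], 0)
  n_known <- (sire > 0L) + (dam > 0L)
  m <- ifelse(n_known == 2L, 0.5 - 0.25 * (fs + fd),
       ifelse(n_known == 1L, 0.75 - 0.25 * (fs + fd), 1))
  alpha <- 1 / m

  # vectorized triplet assembly (duplicate triplets are summed)
  ii <- c(seq_len(n))
  jj <- c(seq_len(n))
  xx <- alpha
  ks <- which(sire > 0L)
  kd <- which(dam > 0L)
  ii <- c(ii, ks, sire[ks], kd, dam[kd])
  jj <- c(jj, sire[ks], ks, dam[kd], kd)
  xx <- c(xx, rep(-alpha[ks] / 2, 2), rep(-alpha[kd] / 2, 2))
  ii <- c(ii, sire[ks], dam[kd])
  jj <- c(jj, sire[ks], dam[kd])
  xx <- c(xx, alpha[ks] / 4, alpha[kd] / 4)
  kb <- which(sire > 0L & dam > 0L)
  ii <- c(ii, sire[kb], dam[kb])
  jj <- c(jj, dam[kb], sire[kb])
  xx <- c(xx, rep(alpha[kb] / 4, 2))

  A_inv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                                dimnames = list(id, id))
  methods::as(Matrix::forceSymmetric(A_inv), "symmetricMatrix")
}

#' Pedigree relationships among a subset of animals
#'
#' Extracts the block of the (implicit) tabular relationship matrix A for the
#' given animals by solving against the sparse A-inverse, avoiding the dense
#' full-pedigree tabular matrix.
#'
#' @param A_inv Sparse A-inverse from [build_A_inverse()].
#' @param ids Character vector of animal ids (must be in `A_inv` dimnames).
#' @return Dense symmetric matrix `A[ids, ids]`.
#' @export
pedigree_relationship_block <- function(A_inv, ids) {
  pos <- match(ids, rownames(A_inv))
  if (anyNA(pos)) abort("some ids are not in the pedigree")
  n <- nrow(A_inv)
  E <- Matrix::sparseMatrix(i = pos, j = seq_along(pos), x = 1,
                            dims = c(n, length(pos)))
  X <- Matrix::solve(A_inv, E)
  out <- as.matrix(X[pos, , drop = FALSE])
  out <- (out + t(out)) / 2
  dimnames(out) <- list(ids, ids)
  out
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = ZZ' / (2 * sum(p * (1 - p)))` with `Z` the allele-dosage matrix
#' centered at twice the allele frequency. Optionally blended with the
#' pedigree relationships among the genotyped animals
#' (`blend_weight * G + (1 - blend_weight) * A22`) to guarantee
#' invertibility.
#'
#' @param genotypes Matrix of 0/1/2 dosages, animals in rows, with rownames;
#'   or a `twin_genotypes` object from [simulate_genotypes()].
#' @param allele_freqs Optional per-SNP allele frequencies used for
#'   centering; observed frequencies among the genotyped animals by default.
#' @param A22 Optional dense pedigree-relationship block for the same
#'   animals; when supplied the blended matrix is returned.
#' @param blend_weight Weight on the genomic component, default 0.95.
#' @return Dense symmetric matrix with animal ids as dimnames; the unblended
#'   matrix is kept in attribute `"G_raw"` when blending is applied.
#' @export
build_G <- function(genotypes, allele_freqs = NULL, A22 = NULL,
                    blend_weight = 0.95) {
  M <- dosage_matrix(genotypes)
  if (nrow(M) < 2) abort("need at least 2 genotyped animals")
  p <- allele_freqs %||% (colMeans(M) / 2)
  poly <- p > 0 & p < 1
  if (!any(poly)) abort("all SNPs are monomorphic under the chosen frequencies")
  Z <- sweep(M[, poly, drop = FALSE], 2, 2 * p[poly], "-")
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(M), rownames(M))
  if (!is.null(A22)) {
    stopifnot(identical(dim(A22), dim(G)))
    A22 <- A22[rownames(G), rownames(G)]
    G_raw <- G
    G <- blend_weight * G + (1 - blend_weight) * A22
    attr(G, "G_raw") <- G_raw
  }
  G
}

# accept either a plain dosage matrix or the simulate_genotypes() container
dosage_matrix <- function(genotypes) {
  if (is.matrix(genotypes)) return(genotypes)
  if (inherits(genotypes, "twin_genotypes")) return(genotypes$dosages)
  abort("genotypes must be a dosage matrix or a twin_genotypes object")
}

#' Inverse of G by the algorithm for proven and young (APY)
#'
#' Splits the genotyped animals into a core and a non-core set; the inverse
#' is exact on the core and uses diagonal Mendelian-sampling-like terms for
#' non-core animals. With all animals in the core, the result equals the
#' direct inverse.
#'
#' @param G Dense genomic relationship matrix with animal-id dimnames.
#' @param core_ids Animal ids forming the core; when `NULL`, `n_core` animals
#'   are drawn uniformly at random (set the RNG seed beforehand for
#'   reproducibility).
#' @param n_core Core size when `core_ids` is not supplied; defaults to all
#'   animals (exact inverse).
#' @return Dense symmetric inverse with a `"core_ids"` attribute.
#' @export
invert_G_apy <- function(G, core_ids = NULL, n_core = NULL) {
  ids <- rownames(G)
  if (is.null(core_ids)) {
    n_core <- n_core %||% length(ids)
    core_ids <- if (n_core >= length(ids)) ids else sort(sample(ids, n_core))
  }
  if (!all(core_ids %in% ids)) abort("core_ids must be genotyped animals")
  core <- match(core_ids, ids)
  noncore <- setdiff(seq_along(ids), core)

  Gcc <- G[core, core, drop = FALSE]
  Gcc_inv <- tryCatch(chol2inv(chol(Gcc)),
                      error = function(e) abort(paste0(
                        "core block of G is singular; enlarge the core or ",
                        "increase blending with A22")))
  n <- length(ids)
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  if (length(noncore) == 0) {
    out[core, core] <- Gcc_inv
    attr(out, "core_ids") <- core_ids
    return(out)
  }
  Gcn <- G[core, noncore, drop = FALSE]
  W <- Gcc_inv %*% Gcn                                   # Gcc^-1 Gcn
  m <- diag(G)[noncore] - colSums(Gcn * W)               # g_ii - g_ic Gcc^-1 g_ci
  if (any(m <= 0)) abort("non-positive APY Mendelian-sampling terms; increase blending")
  Minv <- 1 / m
  out[core, core] <- Gcc_inv + W %*% (Minv * t(W))
  out[core, noncore] <- -W * rep(Minv, each = nrow(W))
  out[noncore, core] <- t(out[core, noncore])
  out[cbind(noncore, noncore)] <- Minv
  out <- (out + t(out)) / 2
  attr(out, "core_ids") <- core_ids
  out
}

#' Assemble the single-step H-inverse
#'
#' `H^-1 = A^-1` plus, in the genotyped block only,
#' `tau * G^-1 - omega * A22^-1`. With the default `tau = omega = 1` the
#' genotyped block of `H^-1` equals the pedigree block plus
#' `G^-1 - A22^-1`.
#'
#' @param A_inv Sparse pedigree-relationship inverse over all animals.
#' @param G_inv Dense inverse genomic relationship matrix (genotyped
#'   animals; dimnames required).
#' @param A22_inv Dense inverse of the pedigree relationships among the same
#'   genotyped animals, same id order as `G_inv`.
#' @param tau,omega Scaling of the genomic and pedigree corrections,
#'   both 1 by default.
#' @return Sparse symmetric H-inverse over all pedigree animals.
#' @export
assemble_H_inverse <- function(A_inv, G_inv, A22_inv, tau = 1, omega = 1) {
  ids <- rownames(G_inv)
  if (!identical(ids, rownames(A22_inv))) {
    abort("G_inv and A22_inv must be indexed by the same animals, same order")
  }
  pos <- match(ids, rownames(A_inv))
  if (anyNA(pos)) abort("genotyped animals missing from the pedigree A-inverse")
  delta <- tau * G_inv - omega * A22_inv
  n <- nrow(A_inv)
  D <- Matrix::sparseMatrix(i = rep(pos, times = length(pos)),
                            j = rep(pos, each = length(pos)),
                            x = as.numeric(delta), dims = c(n, n),
                            dimnames = dimnames(A_inv))
  H_inv <- A_inv + D
  methods::as(Matrix::forceSymmetric(H_inv), "symmetricMatrix")
}
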