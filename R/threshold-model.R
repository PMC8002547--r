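#' Model frame for the threshold repeatability animal model
#'
#' Lays out the liability model
#' `lambda = parity + hys + animal + permanent environment + residual`:
#' parity collapsed to the five classes 1, 2, 3, 4, 5+ (fixed), HYS and
#' permanent environment as i.i.d. random effects, and the additive animal
#' effect over *all* pedigree animals (animals without records are carried
#' by the relationship matrix).
#'
#' @param records Filtered cow-lactation tibble (needs `cow_id`,
#'   `parity_class`, `hys_key`, `twin`).
#' @param pedigree Pedigree tibble; every record's cow must appear in it.
#' @return A `twin_model_frame`: list with `data` (record tibble plus
#'   0-based index columns `i_parity`, `i_hys`, `i_animal`, `i_pe`) and the
#'   level tables `parity_levels`, `hys_levels`, `animal_levels`,
#'   `pe_levels`.
#' @export
build_model_frame <- function(records, pedigree) {
  miss <- setdiff(unique(records$cow_id), pedigree$animal_id)
  if (length(miss) > 0) {
    abort(sprintf("%d record cow(s) missing from the pedigree", length(miss)))
  }
  parity_levels <- c("1", "2", "3", "4", "5+")
  if (!all(records$parity_class %in% parity_levels)) {
    abort("parity_class must be one of 1, 2, 3, 4, 5+")
  }
  hys_levels <- sort(unique(records$hys_key))
  animal_levels <- pedigree$animal_id
  pe_levels <- sort(unique(records$cow_id))
  data <- records |>
    mutate(i_parity = match(.data$parity_class, parity_levels) - 1L,
           i_hys = match(.data$hys_key, hys_levels) - 1L,
           i_animal = match(.data$cow_id, animal_levels) - 1L,
           i_pe = match(.data$cow_id, pe_levels) - 1L)
  structure(list(data = data,
                 parity_levels = parity_levels,
                 hys_levels = hys_levels,
                 animal_levels = animal_levels,
                 pe_levels = pe_levels),
            class = "twin_model_frame")
}

#' Gibbs sampler settings
#'
#' @param n_iter Total chain length (default 20000).
#' @param burn_in Burn-in iterations discarded (default 4000).
#' @param thin Thinning interval for stored variance draws (default 10).
#' @param seed Integer RNG seed.
#' @param prior_nu Degrees of freedom of the scaled-inverse-chi-square
#'   variance priors (default 4, weakly informative).
#' @param prior_scale Prior scale parameters `S0^2` for the additive,
#'   permanent-environment and HYS variances (prior mean is
#'   `nu * S0^2 / (nu - 2)`).
#' @param init Starting values for the three variances.
#' @return A `gibbs_config` list.
#' @export
gibbs_config <- function(n_iter = 20000, burn_in = 4000, thin = 10,
                         seed = 1L, prior_nu = 4,
                         prior_scale = c(sigma2_a = 0.05, sigma2_pe = 0.05,
                                         sigma2_hys = 0.05),
                         init = c(sigma2_a = 0.1, sigma2_pe = 0.1,
                                  sigma2_hys = 0.1)) {
  stopifnot(burn_in < n_iter, n_iter > 0, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 prior_nu = prior_nu, prior_scale = prior_scale, init = init),
            class = "gibbs_config")
}

# symmetric sparse matrix -> full-storage CSR triplets for the sampler
sparse_to_csr <- function(S) {
  T <- methods::as(methods::as(S, "generalMatrix"), "TsparseMatrix")
  ord <- order(T@i, T@j)
  i <- T@i[ord]; j <- T@j[ord]; x <- T@x[ord]
  p <- c(0L, cumsum(tabulate(i + 1L, nbins = nrow(S))))
  list(p = as.integer(p), j = as.integer(j), x = as.numeric(x))
}

#' Estimate variance components by threshold-model Gibbs sampling
#'
#' Data-augmentation Gibbs sampler on the liability scale: truncated-normal
#' liability draws given the binary outcomes, single-site conjugate normal
#' updates for all location effects, and scaled-inverse-chi-square updates
#' for the additive, permanent-environment, and HYS variances. The model is
#' identified by fixing the threshold at 0 and the residual variance at 1.
#' Component estimation is normally run with the pedigree-only
#' relationship inverse (no genotypes); pass an H-inverse for the
#' genomically augmented variant.
#'
#' @param frame A [build_model_frame()] result.
#' @param K_inv Sparse relationship inverse over `frame$animal_levels`
#'   (A-inverse or H-inverse), matching row order.
#' @param config A [gibbs_config()].
#' @param liabilities Optional numeric vector of *observed* liabilities
#'   (degenerate continuous-response mode used for calibration checks);
#'   when supplied the augmentation step is skipped.
#' @return A `twin_gibbs` object: posterior draws (`chains` tibble),
#'   posterior summaries, effective sample sizes, posterior means of all
#'   location effects, and the derived heritability/repeatability. Methods:
#'   [tidy()], [glance()], [autoplot()].
#' @export
gibbs_variance_components <- function(frame, K_inv, config = gibbs_config(),
                                      liabilities = NULL) {
  stopifnot(inherits(frame, "twin_model_frame"))
  d <- frame$data
  if (!identical(rownames(K_inv), frame$animal_levels)) {
    abort("K_inv rows must match frame$animal_levels")
  }
  csr <- sparse_to_csr(K_inv)
  gaussian <- !is.null(liabilities)
  set.seed(config$seed)
  res <- gibbs_threshold_cpp(
    y = as.integer(d$twin),
    liab_obs = if (gaussian) as.numeric(liabilities) else numeric(nrow(d)),
    gaussian = gaussian,
    parity = d$i_parity, hys = d$i_hys, animal = d$i_animal, pe = d$i_pe,
    pe_of_animal = {
      m <- rep(-1L, length(frame$animal_levels))
      m[match(frame$pe_levels, frame$animal_levels)] <-
        seq_along(frame$pe_levels) - 1L
      m
    },
    n_parity = length(frame$parity_levels),
    n_hys = length(frame$hys_levels),
    n_animal = length(frame$animal_levels),
    n_pe = length(frame$pe_levels),
    Ai_p = csr$p, Ai_j = csr$j, Ai_x = csr$x,
    n_iter = config$n_iter, burn_in = config$burn_in, thin = config$thin,
    nu0 = config$prior_nu,
    s2_a0 = config$prior_scale[["sigma2_a"]],
    s2_pe0 = config$prior_scale[["sigma2_pe"]],
    s2_hys0 = config$prior_scale[["sigma2_hys"]],
    init_a = config$init[["sigma2_a"]],
    init_pe = config$init[["sigma2_pe"]],
    init_hys = config$init[["sigma2_hys"]])

  chains <- tibble(iteration = config$burn_in +
                     config$thin * (seq_along(res$sigma2_a) - 1L) + 1L,
                   sigma2_a = res$sigma2_a,
                   sigma2_pe = res$sigma2_pe,
                   sigma2_hys = res$sigma2_hys)
  h2_draws <- chains$sigma2_a /
    (chains$sigma2_a + chains$sigma2_pe + chains$sigma2_hys + 1)
  r2_draws <- (chains$sigma2_a + chains$sigma2_pe) /
    (chains$sigma2_a + chains$sigma2_pe + chains$sigma2_hys + 1)
  ess <- vapply(chains[, c("sigma2_a", "sigma2_pe", "sigma2_hys")],
                ess_chain, numeric(1))
  if (any(ess < 30)) {
    warn(sprintf(
      "low effective sample size (min %.0f); the chain may not have mixed",
      min(ess)))
  }
  vc <- c(sigma2_a = mean(chains$sigma2_a),
          sigma2_pe = mean(chains$sigma2_pe),
          sigma2_hys = mean(chains$sigma2_hys), sigma2_e = 1)
  structure(list(
    chains = chains,
    h2_draws = h2_draws, r2_draws = r2_draws,
    posterior_mean = vc,
    posterior_sd = c(sigma2_a = sd(chains$sigma2_a),
                     sigma2_pe = sd(chains$sigma2_pe),
                     sigma2_hys = sd(chains$sigma2_hys)),
    ess = ess,
    effects = list(parity = setNames(res$mean_parity, frame$parity_levels),
                   hys = setNames(res$mean_hys, frame$hys_levels),
                   animal = setNames(res$mean_animal, frame$animal_levels),
                   pe = setNames(res$mean_pe, frame$pe_levels)),
    config = config),
    class = "twin_gibbs")
}

# effective sample size by Geyer's initial positive sequence (simplified:
# truncate the autocorrelation sum at the first negative value)
ess_chain <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(NA_real_)
  rho <- acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  neg <- which(rho < 0)
  if (length(neg) > 0) rho <- rho[seq_len(neg[1] - 1)]
  n / (1 + 2 * sum(rho))
}

#' Heritability and repeatability from variance components
#'
#' On the liability scale with residual variance 1:
#' `h2 = s2_a / (s2_a + s2_pe + s2_hys + s2_e)` and
#' `r2 = (s2_a + s2_pe) / (s2_a + s2_pe + s2_hys + s2_e)`.
#'
#' @param sigma2_a,sigma2_pe,sigma2_hys,sigma2_e Variance components
#'   (residual defaults to 1); alternatively pass a `twin_gibbs` object as
#'   the first argument.
#' @return Tibble with columns `h2` and `r2`.
#' @export
compute_ratios <- function(sigma2_a, sigma2_pe = NULL, sigma2_hys = NULL,
                           sigma2_e = 1) {
  if (inherits(sigma2_a, "twin_gibbs")) {
    vc <- sigma2_a$posterior_mean
    sigma2_e <- vc[["sigma2_e"]]
    sigma2_hys <- vc[["sigma2_hys"]]
    sigma2_pe <- vc[["sigma2_pe"]]
    sigma2_a <- vc[["sigma2_a"]]
  }
  stopifnot(sigma2_a >= 0, sigma2_pe >= 0, sigma2_hys >= 0, sigma2_e > 0)
  denom <- sigma2_a + sigma2_pe + sigma2_hys + sigma2_e
  tibble(h2 = sigma2_a / denom, r2 = (sigma2_a + sigma2_pe) / denom)
}

# sparse design blocks and coefficient matrix of the mixed-model equations
mme_system <- function(frame, K_inv, vc) {
  d <- frame$data
  n <- nrow(d)
  np <- length(frame$parity_levels)
  nh <- length(frame$hys_levels)
  na <- length(frame$animal_levels)
  nq <- length(frame$pe_levels)
  W <- cbind(
    Matrix::sparseMatrix(i = seq_len(n), j = d$i_parity + 1L, x = 1,
                         dims = c(n, np)),
    Matrix::sparseMatrix(i = seq_len(n), j = d$i_hys + 1L, x = 1,
                         dims = c(n, nh)),
    Matrix::sparseMatrix(i = seq_len(n), j = d$i_animal + 1L, x = 1,
                         dims = c(n, na)),
    Matrix::sparseMatrix(i = seq_len(n), j = d$i_pe + 1L, x = 1,
                         dims = c(n, nq)))
  lam_h <- vc[["sigma2_e"]] / vc[["sigma2_hys"]]
  lam_a <- vc[["sigma2_e"]] / vc[["sigma2_a"]]
  lam_p <- vc[["sigma2_e"]] / vc[["sigma2_pe"]]
  Sigma_inv <- Matrix::bdiag(
    Matrix::Diagonal(np, 0),
    Matrix::Diagonal(nh, lam_h),
    K_inv * lam_a,
    Matrix::Diagonal(nq, lam_p))
  C <- Matrix::forceSymmetric(Matrix::crossprod(W) + Sigma_inv)
  list(W = W, C = C,
       index = tibble(
         effect = rep(c("parity", "hys", "animal", "pe"),
                      times = c(np, nh, na, nq)),
         level = c(frame$parity_levels, frame$hys_levels,
                   frame$animal_levels, frame$pe_levels)))
}

# preconditioned conjugate gradients with a Jacobi (diagonal) preconditioner
pcg_solve <- function(C, b, tol = 1e-10, max_rounds = 200, x0 = NULL) {
  dC <- Matrix::diag(C)
  dC[dC == 0] <- 1
  x <- x0 %||% numeric(length(b))
  r <- b - as.numeric(C %*% x)
  z <- r / dC
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) bnorm <- 1
  history <- numeric(0)
  worse <- 0L
  best <- Inf
  for (k in seq_len(max_rounds)) {
    Cp <- as.numeric(C %*% p)
    alpha <- rz / sum(p * Cp)
    x <- x + alpha * p
    r <- r - alpha * Cp
    rel <- sqrt(sum(r^2)) / bnorm
    history <- c(history, rel)
    if (rel <= tol) break
    best <- min(best, rel)
    # genuine divergence: sustained growth well above the best residual
    # (a plateau jittering at machine precision is not divergence)
    if (k > 1 && rel > history[k - 1] && rel > 4 * best) {
      worse <- worse + 1L
    } else {
      worse <- 0L
    }
    if (worse >= 10L) {
      abort(sprintf("PCG diverged: residual grew for 10 consecutive rounds (round %d, rel %.3g)",
                    k, rel))
    }
    z <- r / dC
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  list(x = x, rounds = length(history), rel_residual = history[length(history)],
       history = history)
}

#' Solve the mixed-model equations by preconditioned conjugate gradients
#'
#' Henderson's mixed-model equations for the liability model, solved with a
#' Jacobi-preconditioned conjugate-gradient solver (stopping at the relative
#' residual tolerance or the round cap, whichever comes first). The primary
#' `"threshold"` mode iterates an expected-liability working response
#' (truncated-normal means given the binary outcomes and the current fit,
#' threshold 0) around the linear solver; `"linear"` mode solves directly on
#' the 0/1 codes and is a documented approximation for speed.
#'
#' @param frame A [build_model_frame()] result.
#' @param K_inv Sparse relationship inverse over all animals (H-inverse for
#'   the single-step evaluation, A-inverse for the pedigree-only one).
#' @param vc Named variance components (`sigma2_a`, `sigma2_pe`,
#'   `sigma2_hys`, `sigma2_e`), e.g. `posterior_mean` of a `twin_gibbs` fit.
#' @param mode `"threshold"` (default) or `"linear"`.
#' @param max_rounds PCG round cap per solve (default 200).
#' @param tol PCG relative-residual tolerance (default 1e-10).
#' @param max_outer Cap on threshold-mode working-response updates.
#' @return A `twin_solutions` object: tibble of per-level solutions plus
#'   convergence diagnostics. Methods: [tidy()], [glance()].
#' @export
solve_mme_pcg <- function(frame, K_inv, vc, mode = c("threshold", "linear"),
                          max_rounds = 200, tol = 1e-10, max_outer = 30) {
  mode <- match.arg(mode)
  if (inherits(vc, "twin_gibbs")) vc <- vc$posterior_mean
  sys <- mme_system(frame, K_inv, vc)
  y <- as.numeric(frame$data$twin)
  W <- sys$W
  x <- numeric(ncol(W))
  total_rounds <- 0L
  outer <- 1L
  if (mode == "linear") {
    sol <- pcg_solve(sys$C, as.numeric(Matrix::crossprod(W, y)),
                     tol = tol, max_rounds = max_rounds)
    x <- sol$x
    total_rounds <- sol$rounds
    rel <- sol$rel_residual
  } else {
    rel <- NA_real_
    for (outer in seq_len(max_outer)) {
      eta <- as.numeric(W %*% x)
      lambda <- working_liability(y, eta)
      sol <- pcg_solve(sys$C, as.numeric(Matrix::crossprod(W, lambda)),
                       tol = tol, max_rounds = max_rounds, x0 = x)
      delta <- max(abs(sol$x - x))
      x <- sol$x
      total_rounds <- total_rounds + sol$rounds
      rel <- sol$rel_residual
      if (delta < 1e-8) break
    }
  }
  solutions <- sys$index
  solutions$solution <- x
  structure(list(solutions = as_tibble(solutions),
                 mode = mode, vc = vc,
                 pcg_rounds = total_rounds, outer_iterations = outer,
                 rel_residual = rel),
            class = "twin_solutions")
}

# E[liability | y, eta] for a probit threshold at 0 with unit residual
working_liability <- function(y, eta) {
  z <- dnorm(-eta)
  upper <- pnorm(-eta)           # P(liability < 0 | eta)
  lower <- 1 - upper
  ifelse(y == 1, eta + z / pmax(lower, 1e-12),
         eta - z / pmax(upper, 1e-12))
}

#' Extract per-animal liability solutions
#'
#' @param x A `twin_solutions` object.
#' @return Tibble `animal_id`, `solution` for the additive animal effect.
#' @export
animal_solutions <- function(x) {
  stopifnot(inherits(x, "twin_solutions"))
  x$solutions |>
    filter(.data$effect == "animal") |>
    select(animal_id = "level", "solution")
}

#' @export
print.twin_gibbs <- function(x, ...) {
  cat("Threshold-model Gibbs fit\n")
  cat(sprintf("  chain: %d iterations, %d burn-in, thin %d\n",
              x$config$n_iter, x$config$burn_in, x$config$thin))
  pm <- x$posterior_mean
  cat(sprintf("  sigma2_a = %.4f  sigma2_pe = %.4f  sigma2_hys = %.4f\n",
              pm[["sigma2_a"]], pm[["sigma2_pe"]], pm[["sigma2_hys"]]))
  r <- compute_ratios(x)
  cat(sprintf("  h2 = %.4f  r2 = %.4f  (min ESS %.0f)\n",
              r$h2, r$r2, min(x$ess)))
  invisible(x)
}

#' @export
print.twin_solutions <- function(x, ...) {
  cat(sprintf("Mixed-model solutions (%s mode): %d equations, %d PCG rounds, rel residual %.2g\n",
              x$mode, nrow(x$solutions), x$pcg_rounds, x$rel_residual))
  invisible(x)
}
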