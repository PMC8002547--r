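#' Base cohort for expressing transmitting abilities
#'
#' The percent-scale transmitting abilities are expressed as deviations from
#' the mean of a base cohort: animals born in a given year that have a
#' recorded twin phenotype.
#'
#' @param records Cow-lactation records (after filtering), with `cow_id`.
#' @param pedigree Pedigree tibble with `animal_id` and `birth_date`.
#' @param birth_year Calendar birth year of the base cohort (default 2015).
#' @return Character vector of base-cohort animal ids.
#' @export
base_cohort <- function(records, pedigree, birth_year = 2015) {
  phenotyped <- unique(records$cow_id)
  born <- pedigree$animal_id[
    as.integer(format(pedigree$birth_date, "%Y")) == birth_year]
  out <- intersect(phenotyped, born)
  if (length(out) == 0) {
    abort(sprintf("base cohort is empty (no phenotyped animals born %d)",
                  birth_year))
  }
  out
}

# latest birth year with a usably large phenotyped cohort, used when a
# snapshot evaluation needs a base cohort older than the configured one
latest_base_year <- function(records, pedigree, min_cows = 20) {
  phen <- unique(records$cow_id)
  yrs <- as.integer(format(
    pedigree$birth_date[match(phen, pedigree$animal_id)], "%Y"))
  tab <- table(yrs)
  ok <- as.integer(names(tab))[tab >= min_cows]
  if (length(ok) == 0) ok <- as.integer(names(tab))[tab == max(tab)]
  max(ok)
}

#' Liability solutions to percent-scale predicted transmitting abilities
#'
#' For each animal the probability that a standard-normal variable centred
#' at its liability solution exceeds the threshold is computed,
#' `p = pnorm(solution - threshold)`; the probability is multiplied by 100
#' (percent) and divided by 2 (a parent transmits half its additive merit),
#' and expressed as a deviation from the mean of the base cohort. A PTA of
#' -2.0 reads as a 2% lower risk of a twin pregnancy than the base animal;
#' +2.0 as a 2% higher risk.
#'
#' @param solutions Tibble `animal_id`, `solution` (see
#'   [animal_solutions()]).
#' @param threshold Liability threshold on the solution scale. The fitted
#'   cutpoint is 0 under the identification constraint; shifted by the
#'   overall fixed-effect mean it becomes `-mean(Xb)`, which
#'   [score_animals()] supplies automatically.
#' @param base_ids Animal ids of the base cohort (must be non-empty and
#'   present in `solutions`).
#' @return Tibble `animal_id`, `probability`, `pta` where `probability` is
#'   the raw twinning probability attached to the solution and `pta` the
#'   percent deviation from the base-cohort mean.
#' @export
liability_to_pta <- function(solutions, threshold, base_ids) {
  stopifnot(all(c("animal_id", "solution") %in% names(solutions)))
  if (length(base_ids) == 0) abort("base cohort is empty")
  if (!all(base_ids %in% solutions$animal_id)) {
    abort("some base-cohort animals have no solution")
  }
  p <- pnorm(solutions$solution - threshold)
  raw <- 100 * p / 2
  base_mean <- mean(raw[solutions$animal_id %in% base_ids])
  tibble(animal_id = solutions$animal_id,
         probability = p,
         pta = raw - base_mean)
}

#' Percent PTAs to standardized transmitting abilities
#'
#' STAs are PTAs rescaled over a scaling cohort to mean 100 and standard
#' deviation 5 with the sign reversed, so that *higher* STA means *lower*
#' genetic risk of twinning: `sta = 100 - 5 * (pta - mean) / sd`. Reported
#' STAs are rounded to integers; full precision is retained in `sta`.
#'
#' @param ptas Tibble `animal_id`, `pta` from [liability_to_pta()].
#' @param scaling_ids Animal ids of the scaling cohort over which the mean
#'   and SD are taken (defaults to all animals in `ptas`).
#' @return Tibble `animal_id`, `pta`, `sta` (full precision),
#'   `sta_reported` (integer).
#' @export
pta_to_sta <- function(ptas, scaling_ids = NULL) {
  scaling_ids <- scaling_ids %||% ptas$animal_id
  sel <- ptas$animal_id %in% scaling_ids
  if (!any(sel)) abort("scaling cohort is empty")
  m <- mean(ptas$pta[sel])
  s <- sd(ptas$pta[sel])
  if (!is.finite(s) || s == 0) abort("scaling cohort has zero PTA variance")
  sta <- 100 - 5 * (ptas$pta - m) / s
  tibble(animal_id = ptas$animal_id, pta = ptas$pta,
         sta = sta, sta_reported = as.integer(round(sta)))
}

#' Approximate reliabilities of the liability EBVs
#'
#' Information-accumulation approximation: each animal's information is the
#' sum of effective record contributions (on the progeny-equivalent scale
#' `lambda = (4 - h2) / h2`) from its own repeated phenotypes, from its
#' phenotyped/informative progeny (one bottom-up pass), from its parents
#' (one top-down pass), and -- for genotyped animals -- a genomic
#' contribution proportional to the diagonal of the genomic relationship
#' matrix, `g_ii`. The total is mapped to
#' `REL = 100 * alpha / (alpha + lambda)`, i.e. `1 - PEV / sigma2_a` in
#' percent, clamped to `[0, 100]`. Animals with no records, progeny,
#' genotype, or known parents get 0.
#'
#' @param records Cow-lactation records (for own-record counts).
#' @param pedigree Pedigree tibble.
#' @param vc Named variance components (or a `twin_gibbs` fit) giving
#'   heritability and repeatability.
#' @param g_diag Optional named vector of G diagonals for genotyped animals.
#' @param genomic_weight Effective-record weight per unit of `g_ii`
#'   (default 30, giving the familiar ~40% reliability for young genotyped
#'   animals at `h2` near 0.09).
#' @return Tibble `animal_id`, `reliability` (percent).
#' @export
approximate_reliability <- function(records, pedigree, vc, g_diag = NULL,
                                    genomic_weight = 30) {
  if (inherits(vc, "twin_gibbs")) vc <- vc$posterior_mean
  ratios <- compute_ratios(vc[["sigma2_a"]], vc[["sigma2_pe"]],
                           vc[["sigma2_hys"]], vc[["sigma2_e"]])
  h2 <- ratios$h2
  r2 <- ratios$r2
  if (h2 <= 0) abort("heritability must be positive for reliabilities")
  lam <- (4 - h2) / h2

  top <- order_pedigree(pedigree)
  ped <- top$pedigree
  n <- nrow(ped)
  nrec <- tabulate(match(records$cow_id, ped$animal_id), nbins = n)

  # own repeated records: rel of the phenotype mean as predictor of the EBV
  rel_own <- ifelse(nrec > 0, nrec * h2 / (1 + (nrec - 1) * r2), 0)
  rel_own <- pmin(rel_own, 0.99)
  erc_own <- lam * rel_own / (1 - rel_own)

  erc_gen <- numeric(n)
  if (!is.null(g_diag)) {
    pos <- match(names(g_diag), ped$animal_id)
    ok <- !is.na(pos)
    erc_gen[pos[ok]] <- genomic_weight * pmax(as.numeric(g_diag)[ok], 0)
  }

  # bottom-up: progeny information flows to parents (halved twice: a progeny
  # record reflects half the parent's additive merit)
  erc_prog <- numeric(n)
  for (i in rev(seq_len(n))) {
    contrib <- 0.25 * (erc_own[i] + erc_gen[i] + erc_prog[i])
    if (top$sire[i] > 0L) erc_prog[top$sire[i]] <- erc_prog[top$sire[i]] + contrib
    if (top$dam[i] > 0L) erc_prog[top$dam[i]] <- erc_prog[top$dam[i]] + contrib
  }
  # top-down: parent-average information
  erc_pa <- numeric(n)
  rel_of <- function(alpha) alpha / (alpha + lam)
  for (i in seq_len(n)) {
    rs <- if (top$sire[i] > 0L) {
      j <- top$sire[i]; rel_of(erc_own[j] + erc_gen[j] + erc_prog[j] + erc_pa[j])
    } else 0
    rd <- if (top$dam[i] > 0L) {
      j <- top$dam[i]; rel_of(erc_own[j] + erc_gen[j] + erc_prog[j] + erc_pa[j])
    } else 0
    rel_pa <- (rs + rd) / 4
    erc_pa[i] <- lam * rel_pa / (1 - rel_pa)
  }

  alpha <- erc_own + erc_gen + erc_prog + erc_pa
  rel <- 100 * alpha / (alpha + lam)
  out <- tibble(animal_id = ped$animal_id,
                reliability = pmin(pmax(rel, 0), 100))
  out[match(pedigree$animal_id, out$animal_id), , drop = FALSE]
}

#' Pearson correlation between two score vectors
#'
#' Product-moment correlation used for cross-trait score summaries.
#'
#' @param a,b Equal-length numeric vectors (at least 3 complete pairs, both
#'   with non-zero variance).
#' @return The Pearson correlation coefficient.
#' @export
correlate_scores <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) abort("need at least 3 complete pairs")
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0) {
    abort("correlation undefined: a score vector has zero variance")
  }
  cor(a[ok], b[ok])
}

#' Weighted-sum selection index over trait STAs
#'
#' Each trait STA is multiplied by its economic weight and the products
#' summed into one index value per animal. Weights come from configuration;
#' their derivation is outside this package's scope.
#'
#' @param sta_by_trait Tibble with columns `animal_id`, `trait`, `sta`
#'   (long format).
#' @param weights Named numeric vector of economic weights, names matching
#'   `trait` values.
#' @param missing `"exclude"` (default) drops animals missing any weighted
#'   trait; `"mean_impute"` substitutes the trait mean.
#' @return Tibble `animal_id`, `index`.
#' @export
index_combine <- function(sta_by_trait, weights,
                          missing = c("exclude", "mean_impute")) {
  missing <- match.arg(missing)
  stopifnot(all(c("animal_id", "trait", "sta") %in% names(sta_by_trait)))
  traits <- names(weights)
  x <- filter(sta_by_trait, .data$trait %in% traits)
  wide <- tidyr::pivot_wider(x, id_cols = "animal_id",
                             names_from = "trait", values_from = "sta")
  for (tr in setdiff(traits, names(wide))) wide[[tr]] <- NA_real_
  if (missing == "mean_impute") {
    for (tr in traits) {
      wide[[tr]][is.na(wide[[tr]])] <- mean(wide[[tr]], na.rm = TRUE)
    }
  } else {
    wide <- wide[stats::complete.cases(wide[, traits, drop = FALSE]), ,
                 drop = FALSE]
  }
  idx <- as.matrix(wide[, traits, drop = FALSE]) %*% weights[traits]
  tibble(animal_id = wide$animal_id, index = as.numeric(idx))
}

#' Score every animal of an evaluation
#'
#' Convenience wrapper tying the transforms together: takes the liability
#' solutions of a solved evaluation, derives the probability/PTA/STA scores
#' against the base cohort, and attaches approximate reliabilities.
#'
#' @param solutions A `twin_solutions` object from [solve_mme_pcg()].
#' @param records,pedigree The filtered records and pedigree of the run.
#' @param vc Variance components (named vector or `twin_gibbs`).
#' @param base_birth_year Birth year of the base cohort (default 2015).
#' @param scaling Scaling cohort for the STA mean/SD: `"base"` (default,
#'   the base cohort) or `"all"` (all scored animals).
#' @param g_diag Optional named G diagonals for the reliability
#'   approximation.
#' @param genomic_weight Passed to [approximate_reliability()].
#' @return A `twin_scores` tibble: `animal_id`, `solution`, `probability`,
#'   `pta`, `sta`, `sta_reported`, `reliability`, plus attributes
#'   `base_ids`, `scaling_ids`, `threshold`.
#' @export
score_animals <- function(solutions, records, pedigree, vc,
                          base_birth_year = 2015,
                          scaling = c("base", "all"),
                          g_diag = NULL, genomic_weight = 30) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(solutions, "twin_solutions"))
  sol <- animal_solutions(solutions)
  # fitted cutpoint 0 shifted by the overall fixed-effect mean
  fixed <- filter(solutions$solutions, .data$effect == "parity")
  threshold <- -mean(fixed$solution)
  base_ids <- base_cohort(records, pedigree, base_birth_year)
  ptas <- liability_to_pta(sol, threshold, base_ids)
  scaling_ids <- if (scaling == "base") base_ids else ptas$animal_id
  stas <- pta_to_sta(ptas, scaling_ids)
  rel <- approximate_reliability(records, pedigree, vc, g_diag,
                                 genomic_weight)
  out <- sol |>
    left_join(ptas, by = "animal_id") |>
    left_join(select(stas, "animal_id", "sta", "sta_reported"),
              by = "animal_id") |>
    left_join(rel, by = "animal_id")
  attr(out, "base_ids") <- base_ids
  attr(out, "scaling_ids") <- scaling_ids
  attr(out, "threshold") <- threshold
  class(out) <- c("twin_scores", class(out))
  out
}
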