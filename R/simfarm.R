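#' Configuration for the synthetic herd generator
#'
#' Describes a multi-herd Holstein-like population: a multi-generation
#' pedigree, gene-dropped SNP genotypes, and repeated lactation records whose
#' binary twin outcome is generated from the threshold liability model
#' (parity + herd-year-season + additive + permanent environment + residual,
#' residual variance 1). Defaults are calibrated to the published evaluation
#' conditions: twinning incidence ~3.25%, additive variance 0.1315,
#' permanent-environment variance 0.1318, HYS variance 0.2272 on the
#' liability scale.
#'
#' @param n_founders Number of founder animals (>= 2, both sexes present).
#' @param n_generations Number of descendant generations.
#' @param n_offspring_per_gen Offspring born in each generation
#'   (default: `n_founders`).
#' @param n_herds Number of herds.
#' @param years Inclusive calendar-year range for descendant births/calvings.
#' @param n_snps Number of simulated biallelic SNPs.
#' @param founder_maf Length-2 range; founder minor-allele frequencies are
#'   drawn uniformly from it.
#' @param sigma2_a,sigma2_pe,sigma2_hys True liability-scale variances
#'   (residual fixed at 1).
#' @param parity_effects Liability offsets for parity classes 1..5+; the
#'   default rises with parity, mirroring the strong observed increase of
#'   twinning frequency after first lactation.
#' @param target_incidence Population twinning incidence the liability
#'   threshold is calibrated to, in (0,1).
#' @param mean_lactations_per_cow Mean number of lactations per cow
#'   (geometric survival across lactations, capped at 8).
#' @param interval_violation_rate Fraction of calving intervals drawn outside
#'   the plausible 250-999 day range, to exercise the record edits.
#' @param nonrecording_hys_fraction Fraction of herd-year-season groups in
#'   which all twin remarks are suppressed (herds that do not record twins).
#' @param error_record_rate Fraction of records given data-entry defects
#'   (assigned to a pedigree male, or dated before birth), to exercise the
#'   animal edits.
#' @param genetic_mode `"pedigree"`: breeding values by pedigree recursion
#'   (parent average + Mendelian sampling scaled by parental inbreeding);
#'   `"snp"`: breeding values as a sum of true SNP effects over the
#'   gene-dropped genotypes.
#' @param seed Integer seed; a fixed seed makes every artifact reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_founders = 1600,
                       n_generations = 4,
                       n_offspring_per_gen = n_founders,
                       n_herds = 3,
                       years = c(2008, 2019),
                       n_snps = 1000,
                       founder_maf = c(0.05, 0.5),
                       sigma2_a = 0.1315,
                       sigma2_pe = 0.1318,
                       sigma2_hys = 0.2272,
                       parity_effects = c(-0.6, 0, 0.2, 0.3, 0.35),
                       target_incidence = 0.0325,
                       mean_lactations_per_cow = 3,
                       interval_violation_rate = 0.02,
                       nonrecording_hys_fraction = 0,
                       error_record_rate = 0,
                       genetic_mode = c("pedigree", "snp"),
                       seed = 1L) {
  genetic_mode <- match.arg(genetic_mode)
  stopifnot(n_founders >= 2, n_generations >= 1, n_snps >= 1,
            length(years) == 2, years[1] <= years[2],
            target_incidence > 0, target_incidence < 1,
            sigma2_a >= 0, sigma2_pe >= 0, sigma2_hys >= 0,
            length(parity_effects) == 5,
            mean_lactations_per_cow >= 1)
  structure(as.list(environment()), class = "sim_config")
}

sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1000003) %% 2147483647)
}

#' Simulate a multi-generation pedigree
#'
#' Founders are assigned alternating sexes (M, F, M, ...); each later
#' generation is produced by sampling sires from a small pool of available
#' males and dams from available females of earlier generations, giving the
#' paternal half-sib family structure typical of dairy populations. Birth
#' dates of successive generations occupy successive year blocks within
#' `config$years`, so parents are always born before their offspring.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `animal_id`, `sire_id`, `dam_id`,
#'   `birth_date`, `sex`, `generation`, `herd_id`.
#' @export
simulate_pedigree <- function(config) {
  set.seed(sub_seed(config$seed, 1))
  nf <- config$n_founders
  sex <- rep(c("M", "F"), length.out = nf)
  if (!all(c("M", "F") %in% sex)) abort("founder pool must contain both sexes")
  # generation blocks occupy the early part of the year range so the last
  # generation still completes a lactation career inside it
  span <- config$years[2] - config$years[1] + 1
  step <- max(1, span %/% (config$n_generations + 1))
  founder_year <- config$years[1] - 3

  width <- nchar(as.character(nf + config$n_generations *
                                config$n_offspring_per_gen))
  fmt <- function(i) sprintf("A%0*d", width, i)

  ped <- tibble(
    animal_id = fmt(seq_len(nf)),
    sire_id = NA_character_, dam_id = NA_character_,
    birth_date = as.Date(sprintf("%d-01-01", founder_year)) +
      sample.int(720, nf, replace = TRUE) - 1,
    sex = sex, generation = 0L,
    herd_id = sprintf("H%02d", sample.int(config$n_herds, nf, replace = TRUE)))

  next_id <- nf + 1L
  for (g in seq_len(config$n_generations)) {
    males <- filter(ped, .data$sex == "M")
    females <- filter(ped, .data$sex == "F")
    if (nrow(males) == 0 || nrow(females) == 0) {
      abort("mating pool is impossible: need at least one male and one female")
    }
    n_off <- config$n_offspring_per_gen
    n_sires <- max(1L, ceiling(0.08 * nrow(males)))
    sire_pool <- males$animal_id[sample.int(nrow(males), n_sires)]
    sires <- sample(sire_pool, n_off, replace = TRUE)
    dam_rows <- sample.int(nrow(females), n_off, replace = TRUE)
    y0 <- config$years[1] + (g - 1L) * step
    born <- as.Date(sprintf("%d-01-01", y0)) +
      sample.int(step * 365L, n_off, replace = TRUE) - 1
    dam_herd <- females$herd_id[dam_rows]
    herd <- if_else(runif(n_off) < 0.9, dam_herd,
                    sprintf("H%02d", sample.int(config$n_herds, n_off,
                                                replace = TRUE)))
    off <- tibble(
      animal_id = fmt(seq.int(next_id, length.out = n_off)),
      sire_id = sires,
      dam_id = females$animal_id[dam_rows],
      birth_date = born,
      sex = sample(c("M", "F"), n_off, replace = TRUE),
      generation = g,
      herd_id = herd)
    next_id <- next_id + n_off
    ped <- bind_rows(ped, off)
  }
  ped
}

#' Simulate SNP genotypes by gene dropping
#'
#' Founder genotypes are drawn from Hardy-Weinberg proportions at per-SNP
#' allele frequencies sampled from `config$founder_maf`; descendants receive
#' one allele from each parent by Mendelian transmission (SNPs unlinked).
#'
#' @param pedigree Pedigree tibble from [simulate_pedigree()].
#' @param config A [sim_config()].
#' @return A `twin_genotypes` object: list with `animal_ids`, a `dosages`
#'   matrix (animals x SNPs, values 0/1/2, rownames = ids), and
#'   `allele_freqs` (founder frequencies used).
#' @export
simulate_genotypes <- function(pedigree, config) {
  set.seed(sub_seed(config$seed, 2))
  top <- order_pedigree(pedigree)
  ped <- top$pedigree
  n <- nrow(ped)
  m <- config$n_snps
  freqs <- runif(m, config$founder_maf[1], config$founder_maf[2])
  # store maternal/paternal allele counts jointly as dosage; transmission of
  # a heterozygote is a fair coin per SNP, which is exact for unlinked loci
  dos <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    s <- top$sire[i]; d <- top$dam[i]
    from_sire <- if (s > 0L) rbinom(m, 1L, dos[s, ] / 2) else rbinom(m, 1L, freqs)
    from_dam <- if (d > 0L) rbinom(m, 1L, dos[d, ] / 2) else rbinom(m, 1L, freqs)
    dos[i, ] <- from_sire + from_dam
  }
  rownames(dos) <- ped$animal_id
  ord <- match(pedigree$animal_id, ped$animal_id)
  structure(list(animal_ids = pedigree$animal_id,
                 dosages = dos[ord, , drop = FALSE],
                 allele_freqs = freqs),
            class = "twin_genotypes")
}

#' The standardized on-farm vocabulary for twin events
#'
#' Every (event, remark) combination that is collapsed to a twin outcome by
#' [standardize_twin_events()]. An `ABORT` event additionally maps to a twin
#' when its remark is exactly the two letters `TW`.
#'
#' @return Tibble with columns `event` and `remark`.
#' @export
twin_vocabulary <- function() {
  abort_remarks <- c("TWIN", "TW M", "TW F", "TW=", "TWF", "TWDOA", "TWM",
                     "BULHFRTW", "TW2BULL", "TWNB", "TWNH", "BULLSTW",
                     "TWNHFRS", "TWBULL", "TW")
  other_events <- c("RP", "MISC", "DRYOFF", "ILL", "OK", "REMARK", "SOLD",
                    "FRESH")
  bind_rows(tibble(event = "ABORT", remark = abort_remarks),
            tibble(event = other_events, remark = "TWIN"))
}

#' Simulate farm event records under the liability model
#'
#' Each cow-lactation receives a liability
#' `parity effect + HYS effect + breeding value + permanent environment +
#' residual` (residual variance 1); the binary twin outcome is the liability
#' exceeding a threshold calibrated by root-finding so that the expected
#' population incidence equals `config$target_incidence`. Twin outcomes are
#' written into the raw event log using the on-farm vocabulary
#' ([twin_vocabulary()], sampled uniformly); singletons are written as plain
#' calving events. A configurable fraction of HYS groups suppresses all twin
#' remarks, emulating herds that do not record twinning.
#'
#' @param pedigree Pedigree tibble from [simulate_pedigree()].
#' @param genotypes Optional `twin_genotypes`; required for
#'   `genetic_mode = "snp"`.
#' @param config A [sim_config()].
#' @return A tibble (class `twin_event_log`) with columns `cow_id`,
#'   `herd_id`, `event_date`, `event`, `remark`, `parity`. The simulation
#'   truth (threshold, per-animal breeding values, permanent-environment and
#'   HYS effects, per-record liabilities and true outcomes) is attached as
#'   attribute `"truth"`.
#' @export
simulate_records <- function(pedigree, genotypes = NULL, config) {
  set.seed(sub_seed(config$seed, 3))
  cfg <- config
  v_total <- cfg$sigma2_a + cfg$sigma2_pe + cfg$sigma2_hys + 1

  bv <- simulate_breeding_values(pedigree, genotypes, cfg)

  cows <- filter(pedigree, .data$sex == "F",
                 .data$birth_date <= as.Date(sprintf("%d-12-31",
                                                     cfg$years[2] - 2)))
  if (nrow(cows) == 0) abort("no cows available to lactate in the year range")

  n_lact <- pmin(1L + stats::rgeom(nrow(cows), 1 / cfg$mean_lactations_per_cow), 8L)
  first_calving <- cows$birth_date + round(rnorm(nrow(cows), 730, 40))

  rec <- tibble(cow_id = rep(cows$animal_id, n_lact),
                herd_id = rep(cows$herd_id, n_lact),
                parity = unlist(lapply(n_lact, seq_len), use.names = FALSE))
  base_date <- rep(first_calving, n_lact)
  n <- nrow(rec)
  interval <- round(rnorm(n, 390, 45))
  interval <- pmin(pmax(interval, 260), 900)
  bad <- runif(n) < cfg$interval_violation_rate
  interval[bad] <- ifelse(runif(sum(bad)) < 0.5,
                          round(runif(sum(bad), 100, 249)),
                          round(runif(sum(bad), 1000, 1100)))
  # cumulative intervals within cow give the calving dates
  cum <- stats::ave(interval, rec$cow_id, FUN = function(x) cumsum(c(0, x[-length(x)])))
  rec$event_date <- base_date + cum
  rec$calving_interval <- ifelse(rec$parity == 1L, NA_integer_, interval)

  rec <- filter(rec,
                .data$event_date <= as.Date(sprintf("%d-12-31", cfg$years[2])),
                .data$event_date >= as.Date(sprintf("%d-01-01", cfg$years[1])))
  if (nrow(rec) == 0) abort("no lactation records fall inside the year range")

  rec$season <- assign_season(rec$event_date)
  rec$hys_key <- hys_key(rec$herd_id, rec$event_date)

  # liability components
  parity_class <- pmin(rec$parity, 5L)
  eta_fixed <- cfg$parity_effects[parity_class]
  hys_levels <- unique(rec$hys_key)
  hys_eff <- setNames(rnorm(length(hys_levels), 0, sqrt(cfg$sigma2_hys)),
                      hys_levels)
  pe_eff <- setNames(rnorm(nrow(cows), 0, sqrt(cfg$sigma2_pe)), cows$animal_id)
  a_eff <- setNames(bv$true_bv, bv$animal_id)

  liab <- eta_fixed + hys_eff[rec$hys_key] + a_eff[rec$cow_id] +
    pe_eff[rec$cow_id] + rnorm(nrow(rec))

  threshold <- calibrate_threshold(eta_fixed, v_total, cfg$target_incidence)
  twin <- as.integer(liab > threshold)

  # express outcomes in on-farm vocabulary
  vocab <- twin_vocabulary()
  pick <- sample.int(nrow(vocab), nrow(rec), replace = TRUE)
  singleton_remark <- sample(c("", "", "", "EASY", "ASSIST"), nrow(rec),
                             replace = TRUE)
  rec$event <- ifelse(twin == 1L, vocab$event[pick], "FRESH")
  rec$remark <- ifelse(twin == 1L, vocab$remark[pick], singleton_remark)

  # non-recording HYS groups: all twin remarks suppressed
  if (cfg$nonrecording_hys_fraction > 0) {
    nr <- hys_levels[runif(length(hys_levels)) < cfg$nonrecording_hys_fraction]
    sup <- rec$hys_key %in% nr & twin == 1L
    rec$event[sup] <- "FRESH"
    rec$remark[sup] <- ""
    rec$suppressed <- rec$hys_key %in% nr
  } else {
    rec$suppressed <- FALSE
  }

  # data-entry defects to exercise the animal edits
  if (cfg$error_record_rate > 0) {
    males <- pedigree$animal_id[pedigree$sex == "M"]
    k <- which(runif(nrow(rec)) < cfg$error_record_rate)
    if (length(k) > 0 && length(males) > 0) {
      half <- k[seq_len(ceiling(length(k) / 2))]
      rec$cow_id[half] <- sample(males, length(half), replace = TRUE)
      rest <- setdiff(k, half)
      if (length(rest) > 0) {
        bd <- pedigree$birth_date[match(rec$cow_id[rest], pedigree$animal_id)]
        rec$event_date[rest] <- bd - 30
      }
    }
  }

  out <- select(rec, "cow_id", "herd_id", "event_date", "event", "remark",
                "parity")
  attr(out, "truth") <- list(
    threshold = threshold,
    breeding_values = bv,
    pe_effects = tibble(animal_id = names(pe_eff), true_pe = unname(pe_eff)),
    hys_effects = tibble(hys_key = names(hys_eff), true_hys = unname(hys_eff)),
    records = tibble(cow_id = rec$cow_id, parity = rec$parity,
                     hys_key = rec$hys_key, liability = liab,
                     twin_true = twin, suppressed = rec$suppressed))
  class(out) <- c("twin_event_log", class(out))
  out
}

# threshold such that mean_i P(liability_i > t) = target, where the marginal
# liability of record i is N(eta_fixed_i, v_total)
calibrate_threshold <- function(eta_fixed, v_total, target) {
  f <- function(t) mean(pnorm((eta_fixed - t) / sqrt(v_total))) - target
  # 6 standard deviations beyond the fixed effects: a threshold outside this
  # bracket would need an incidence below ~1e-9 (or above 1 - 1e-9), which
  # no finite herd realizes
  lo <- min(eta_fixed) - 6 * sqrt(v_total)
  hi <- max(eta_fixed) + 6 * sqrt(v_total)
  if (f(lo) < 0 || f(hi) > 0) {
    abort("target incidence is unattainable under the variance configuration")
  }
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# true breeding values: pedigree recursion (parent average + Mendelian
# sampling with inbreeding-adjusted variance) or a sum of true SNP effects
simulate_breeding_values <- function(pedigree, genotypes, cfg) {
  if (cfg$genetic_mode == "snp") {
    if (is.null(genotypes)) abort("genetic_mode = 'snp' requires genotypes")
    M <- genotypes$dosages[pedigree$animal_id, , drop = FALSE]
    u <- rnorm(ncol(M))
    g <- as.numeric(M %*% u)
    g <- (g - mean(g)) / stats::sd(g) * sqrt(cfg$sigma2_a)
    return(tibble(animal_id = pedigree$animal_id, true_bv = g))
  }
  top <- order_pedigree(pedigree)
  ped <- top$pedigree
  fvec <- inbreeding_ml_cpp(top$sire, top$dam)
  n <- nrow(ped)
  a <- numeric(n)
  z <- rnorm(n)
  for (i in seq_len(n)) {
    s <- top$sire[i]; d <- top$dam[i]
    if (s == 0L && d == 0L) {
      a[i] <- z[i] * sqrt(cfg$sigma2_a)
    } else {
      pa <- (if (s > 0L) a[s] else 0) / 2 + (if (d > 0L) a[d] else 0) / 2
      fs <- if (s > 0L) fvec[s] else 0
      fd <- if (d > 0L) fvec[d] else 0
      msv <- if (s > 0L && d > 0L) 0.5 - 0.25 * (fs + fd)
             else 0.75 - 0.25 * (fs + fd)
      a[i] <- pa + z[i] * sqrt(cfg$sigma2_a * msv)
    }
  }
  out <- tibble(animal_id = ped$animal_id, true_bv = a)
  out[match(pedigree$animal_id, out$animal_id), , drop = FALSE]
}
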