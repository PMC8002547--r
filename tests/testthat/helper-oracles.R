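# Independent oracles and small fixtures used across the suite.

# Dense tabular relationship matrix: the classic recursive construction,
# independent of the package's Henderson-rule / Meuwissen-Luo code paths.
tabular_A <- function(pedigree) {
  id <- pedigree$animal_id
  n <- length(id)
  s <- match(pedigree$sire_id, id, nomatch = 0L)
  d <- match(pedigree$dam_id, id, nomatch = 0L)
  # order parents before offspring
  ord <- integer(0)
  placed <- logical(n)
  while (length(ord) < n) {
    ready <- which(!placed &
                     (s == 0L | placed[pmax(s, 1L)] | s == 0) &
                     (d == 0L | placed[pmax(d, 1L)]))
    ready <- ready[(s[ready] == 0L | placed[pmax(s[ready], 1L)]) &
                     (d[ready] == 0L | placed[pmax(d[ready], 1L)])]
    stopifnot(length(ready) > 0)
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in ord) {
    si <- s[i]; di <- d[i]
    A[i, i] <- 1 + (if (si > 0 && di > 0) 0.5 * A[si, di] else 0)
    for (j in ord) {
      if (j == i) break
      aij <- 0
      if (si > 0) aij <- aij + 0.5 * A[j, si]
      if (di > 0) aij <- aij + 0.5 * A[j, di]
      A[i, j] <- A[j, i] <- aij
    }
  }
  A
}

# random valid pedigree: generation structure guarantees acyclicity
random_pedigree <- function(n, seed, n_founders = max(4, n %/% 4)) {
  set.seed(seed)
  id <- sprintf("P%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[1:2] <- c("M", "F")
  for (i in seq.int(n_founders + 1, n)) {
    males <- which(sex[seq_len(i - 1)] == "M")
    females <- which(sex[seq_len(i - 1)] == "F")
    if (length(males) > 0 && runif(1) < 0.9) sire[i] <- id[sample(males, 1)]
    if (length(females) > 0 && runif(1) < 0.9) dam[i] <- id[sample(females, 1)]
  }
  tibble::tibble(animal_id = id, sire_id = sire, dam_id = dam,
                 birth_date = as.Date("2000-01-01") + seq_len(n), sex = sex)
}

# trio: unrelated sire and dam, one offspring
trio_pedigree <- function() {
  tibble::tibble(animal_id = c("S", "D", "O"),
                 sire_id = c(NA, NA, "S"),
                 dam_id = c(NA, NA, "D"),
                 birth_date = as.Date(c("2000-01-01", "2000-01-02",
                                        "2003-01-01")),
                 sex = c("M", "F", "F"))
}

# a small event log covering the standardization vocabulary
toy_event_log <- function(rows) {
  tibble::tibble(cow_id = rows$cow_id %||% sprintf("C%02d", seq_len(nrow(rows))),
                 herd_id = rows$herd_id %||% "H01",
                 event_date = rows$event_date,
                 event = rows$event,
                 remark = rows$remark,
                 parity = rows$parity %||% 1L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# small, fast generator settings for property tests
tiny_sim_config <- function(seed = 1, ...) {
  twinblup::sim_config(n_founders = 120, n_generations = 3,
                       n_offspring_per_gen = 120, n_herds = 2,
                       years = c(2010, 2017), n_snps = 120,
                       mean_lactations_per_cow = 3, seed = seed, ...)
}
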