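# Published per-herd tertile incidences (marginal means) and the derived
# arithmetic used as frozen expectations throughout this file.
tertile_incidence <- tibble::tibble(
  herd_id = rep(sprintf("herd%d", 1:5), each = 3),
  group = rep(c("worst 33%", "34-66%", "best 33%"), 5),
  incidence = c(0.19, 0.14, 0.10,
                0.09, 0.06, 0.04,
                0.12, 0.09, 0.06,
                0.09, 0.07, 0.03,
                0.09, 0.06, 0.02))
tertile_costs <- c(31, 23, 16, 14, 10, 6, 19, 14, 10, 14, 11, 5, 14, 10, 3)

test_that("tertile assignment splits each herd by STA with stable ties", {
  scores <- tibble::tibble(animal_id = sprintf("a%02d", 1:9),
                           sta = c(95, 96, 97, 100, 101, 102, 105, 106, 107))
  herds <- tibble::tibble(animal_id = scores$animal_id, herd_id = "H1")
  out <- assign_tertiles(scores, herds)
  expect_equal(table(out$group)[["worst 33%"]], 3L)
  worst <- out$animal_id[out$group == "worst 33%"]
  expect_setequal(worst, sprintf("a%02d", 1:3))

  # 10 animals: remainder goes to the extremes low-first -> 4/3/3
  scores10 <- tibble::tibble(animal_id = sprintf("b%02d", 1:10),
                             sta = 10:1 * 1.0)
  herds10 <- tibble::tibble(animal_id = scores10$animal_id, herd_id = "H1")
  out10 <- assign_tertiles(scores10, herds10)
  expect_equal(as.integer(table(out10$group)), c(4L, 3L, 3L))

  # ties: assignment deterministic by animal id
  scores_tie <- tibble::tibble(animal_id = sprintf("c%02d", 1:6), sta = 100)
  herds_tie <- tibble::tibble(animal_id = scores_tie$animal_id, herd_id = "H1")
  t1 <- assign_tertiles(scores_tie, herds_tie)
  t2 <- assign_tertiles(scores_tie[sample(6), ], herds_tie)
  expect_equal(t1, dplyr::arrange(t2, animal_id))

  # undersized herds are excluded with a warning
  herds_small <- tibble::tibble(animal_id = scores$animal_id,
                                herd_id = c(rep("H1", 7), "H2", "H2"))
  expect_warning(out_small <- assign_tertiles(scores, herds_small),
                 "excluding")
  expect_setequal(unique(out_small$herd_id), "H1")
})

test_that("economic cost reproduces every published per-case cell exactly", {
  expect_equal(economic_cost(0.19), 31L)
  expect_equal(economic_cost(0.02), 3L)
  expect_equal(economic_cost(0), 0L)
  expect_equal(economic_cost(tertile_incidence$incidence), tertile_costs)
})

test_that("gap, relative-reduction and decreased-loss sequences reproduce from the printed incidences", {
  rep_ <- economic_report(tertile_incidence)
  expect_equal(rep_$costs$cost_per_case_dollars, tertile_costs)
  s <- rep_$summary[match(sprintf("herd%d", 1:5), rep_$summary$herd_id), ]
  expect_equal(s$tertile_gap_points, c(9, 5, 6, 6, 7))
  expect_equal(s$relative_reduction_percent, c(47, 56, 50, 67, 78))
  expect_equal(s$decreased_loss_dollars, c(15, 8, 9, 9, 11))
})

# build a demonstration-style data set with a known group -> risk mapping
demo_records <- function(seed, n_per_herd = 150, herds = c("H1", "H2"),
                         effect = 0) {
  set.seed(seed)
  grid <- tidyr::expand_grid(herd_id = herds,
                             idx = seq_len(n_per_herd))
  grid$animal_id <- sprintf("%s_c%03d", grid$herd_id, grid$idx)
  grid$sta <- rnorm(nrow(grid), 100, 5)
  rec <- tidyr::expand_grid(animal_id = grid$animal_id, parity = 2:4)
  rec <- dplyr::inner_join(rec, grid, by = "animal_id")
  eta <- qlogis(0.08) - effect * (rec$sta - 100) / 5
  rec$twin <- rbinom(nrow(rec), 1, plogis(eta))
  rec$cow_id <- rec$animal_id
  list(records = rec[, c("cow_id", "herd_id", "parity", "twin")],
       scores = grid[, c("animal_id", "herd_id", "sta")])
}

test_that("a strong STA effect orders the marginal means worst > middle > best", {
  d <- demo_records(seed = 1, effect = 1.2)
  tert <- assign_tertiles(d$scores, d$scores[, c("animal_id", "herd_id")])
  fit <- fit_incidence_model(d$records, tert)
  expect_s3_class(fit, "twin_incidence_fit")
  for (h in unique(fit$herd_id)) {
    x <- fit[fit$herd_id == h, ]
    expect_equal(as.character(x$group),
                 c("worst 33%", "34-66%", "best 33%"))
    expect_true(all(diff(x$incidence) < 0))
    expect_lt(x$p_value[1], 0.05)
  }
  expect_true(all(fit$sem > 0))
})

test_that("a single-lactation incidence model matches direct logistic marginal means", {
  d <- demo_records(seed = 2, effect = 1.0)
  rec <- d$records[d$records$parity == 2, ]
  tert <- assign_tertiles(d$scores, d$scores[, c("animal_id", "herd_id")])
  fit <- fit_incidence_model(rec, tert, lactations = 2)
  # oracle: plain logistic regression per herd (one record per cow, the
  # random intercept is unidentified and shrinks to zero)
  x <- dplyr::inner_join(rec, tert, by = c(cow_id = "animal_id",
                                           "herd_id"))
  for (h in unique(x$herd_id)) {
    g <- stats::glm(twin ~ group, data = x[x$herd_id == h, ],
                    family = stats::binomial())
    pred <- stats::predict(
      g, newdata = data.frame(group = c("worst 33%", "34-66%", "best 33%")),
      type = "response")
    got <- fit$incidence[fit$herd_id == h]
    expect_equal(got, unname(pred), tolerance = 0.02)
  }
})

test_that("the group test keeps its nominal size under the null", {
  reps <- 40
  pvals <- vapply(seq_len(reps), function(i) {
    d <- demo_records(seed = 100 + i, n_per_herd = 90, herds = "H1",
                      effect = 0)
    tert <- assign_tertiles(d$scores, d$scores[, c("animal_id", "herd_id")])
    fit <- fit_incidence_model(d$records, tert)
    fit$p_value[1]
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 0.08)
})

test_that("sta_regression clamps STAs and reports Type III tests", {
  d <- demo_records(seed = 3, effect = 1.0)
  rec <- d$records
  out <- sta_regression(rec, d$scores, model = "secondary")
  expect_setequal(out$effect, c("sta", "lactation"))
  expect_lt(out$p_value[out$effect == "sta"], 0.05)
  m <- attr(out, "model")
  expect_true(all(m@frame$sta >= 85 & m@frame$sta <= 115))

  # tertiary variant: 3rd-lactation records, season + peak yield covariates
  rec3 <- rec
  set.seed(4)
  rec3$conception_season <- sample(c("Winter", "Spring", "Summer", "Fall"),
                                   nrow(rec3), replace = TRUE)
  rec3$peak_yield <- rnorm(nrow(rec3), 45, 6)
  out3 <- sta_regression(rec3, d$scores, model = "tertiary")
  expect_setequal(out3$effect, c("sta", "conception_season", "peak_yield"))
  # pure-noise season must not wash out a strong STA signal
  expect_lt(out3$p_value[out3$effect == "sta"], 0.05)

  # constant covariate is dropped with a warning
  rec3$peak_yield <- 45
  expect_warning(out_c <- sta_regression(rec3, d$scores, model = "tertiary"),
                 "constant")
  expect_false("peak_yield" %in% out_c$effect)
})

test_that("STA has a uniform p-value distribution under a null effect", {
  reps <- 30
  pv <- vapply(seq_len(reps), function(i) {
    d <- demo_records(seed = 300 + i, n_per_herd = 80, herds = "H1",
                      effect = 0)
    rec <- d$records[d$records$parity == 3, ]
    set.seed(1000 + i)
    rec$conception_season <- sample(c("Winter", "Spring"), nrow(rec),
                                    replace = TRUE)
    rec$peak_yield <- rnorm(nrow(rec), 45, 6)
    out <- sta_regression(rec, d$scores, model = "tertiary")
    out$p_value[out$effect == "sta"]
  }, numeric(1))
  # crude uniformity check: mean near 0.5, no pile-up below 0.05
  expect_lt(abs(mean(pv) - 0.5), 0.2)
  expect_lt(mean(pv < 0.05), 0.2)
})
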