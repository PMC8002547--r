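#' Within-herd tertile genetic groups
#'
#' Ranks animals by STA within each herd and allocates them to three genetic
#' groups: the worst 33% (lowest STA, highest predicted risk), the middle
#' 34-66%, and the best 33%. Ties are broken by stable animal-id order; when
#' the herd size is not divisible by 3 the remainder goes to the extreme
#' groups, lowest first (10 animals split 4/3/3).
#'
#' @param scores Tibble with `animal_id` and `sta`.
#' @param herds Tibble with `animal_id` and `herd_id` mapping animals to
#'   herds.
#' @param min_herd_size Herds with fewer animals are excluded with a
#'   warning (default 3).
#' @return Tibble `herd_id`, `animal_id`, `sta`, `group` with `group` a
#'   factor `worst 33%` < `34-66%` < `best 33%`.
#' @export
assign_tertiles <- function(scores, herds, min_herd_size = 3) {
  x <- inner_join(select(scores, "animal_id", "sta"), herds, by = "animal_id")
  sizes <- count(x, .data$herd_id)
  small <- sizes$herd_id[sizes$n < min_herd_size]
  if (length(small) > 0) {
    warn(sprintf("excluding %d herd(s) with fewer than %d animals",
                 length(small), min_herd_size))
    x <- filter(x, !.data$herd_id %in% small)
  }
  levels <- c("worst 33%", "34-66%", "best 33%")
  x |>
    arrange(.data$herd_id, .data$sta, .data$animal_id) |>
    group_by(.data$herd_id) |>
    mutate(group = factor(tertile_labels(n()), levels = levels)) |>
    ungroup() |>
    select("herd_id", "animal_id", "sta", "group")
}

# group sizes for n animals: remainder to the extreme groups, lowest first
tertile_labels <- function(n) {
  base <- n %/% 3
  rem <- n %% 3
  sizes <- c(base, base, base)
  if (rem >= 1) sizes[1] <- sizes[1] + 1
  if (rem == 2) sizes[3] <- sizes[3] + 1
  rep(c("worst 33%", "34-66%", "best 33%"), times = sizes)
}

#' Incidence marginal means by genetic group
#'
#' Fits, per herd, a binomial logit mixed model of the binary twin outcome
#' on genetic group and lactation (fixed) with a per-animal random
#' intercept (Laplace approximation via `lme4::glmer`), restricted to 2nd-
#' 4th lactations where twinning incidence is appreciable. Marginal means on
#' the probability scale are averaged over lactation levels with equal
#' weights (delta-method SEM via `emmeans`); the group effect gets a joint
#' Wald chi-square p-value. Groups with zero twins are flagged as possible
#' separation.
#'
#' @param records Cow-lactation tibble with `cow_id`, `herd_id`, `parity`,
#'   `twin`.
#' @param groups Tertile assignment from [assign_tertiles()].
#' @param lactations Parities retained (default `2:4`).
#' @return A `twin_incidence_fit`: tibble `herd_id`, `group`, `incidence`,
#'   `sem`, `p_value`, `separation`; fitted models in attribute `"models"`.
#' @export
fit_incidence_model <- function(records, groups, lactations = 2:4) {
  x <- records |>
    filter(.data$parity %in% lactations) |>
    inner_join(select(groups, "animal_id", "group"),
               by = c(cow_id = "animal_id")) |>
    mutate(lactation = factor(.data$parity))
  herd_ids <- sort(unique(x$herd_id))
  models <- list()
  out <- purrr::map(herd_ids, function(h) {
    d <- filter(x, .data$herd_id == h)
    d$group <- droplevels(d$group)
    sep <- d |>
      group_by(.data$group) |>
      summarise(tw = sum(.data$twin), .groups = "drop")
    single_lact <- length(unique(d$lactation)) < 2
    has_repeats <- anyDuplicated(d$cow_id) > 0
    rhs <- if (single_lact) "group" else "group + lactation"
    # the per-animal intercept accounts for repeated measures; with a single
    # record per cow its variance is unidentified, so the model reduces to
    # ordinary logistic regression
    fit <- if (has_repeats) {
      suppressMessages(lme4::glmer(
        stats::as.formula(paste("twin ~", rhs, "+ (1 | cow_id)")),
        data = d, family = stats::binomial(),
        control = lme4::glmerControl(calc.derivs = FALSE,
                                     check.conv.singular = "ignore")))
    } else {
      stats::glm(stats::as.formula(paste("twin ~", rhs)),
                 data = d, family = stats::binomial())
    }
    models[[h]] <<- fit
    em <- emmeans::emmeans(fit, "group", type = "response")
    ems <- as.data.frame(em)
    p <- tryCatch({
      a <- car::Anova(fit, type = "III")
      a["group", "Pr(>Chisq)"]
    }, error = function(e) NA_real_)
    tibble(herd_id = h,
           group = ems$group,
           incidence = ems$prob,
           sem = ems$SE,
           p_value = p,
           separation = ems$group %in% sep$group[sep$tw == 0])
  }) |> bind_rows()
  attr(out, "models") <- models
  class(out) <- c("twin_incidence_fit", class(out))
  out
}

#' Economic cost of twinning per cow
#'
#' Cost per case is the incidence multiplied by the mean of the most and
#' least conservative published per-event cost estimates ($97 and $225),
#' rounded to whole dollars.
#'
#' @param incidence Twinning incidence (proportion in `[0, 1]`).
#' @param cost_range Most and least conservative per-event cost estimates
#'   in dollars (default `c(97, 225)`).
#' @return Integer dollars per cow.
#' @export
economic_cost <- function(incidence, cost_range = c(97, 225)) {
  stopifnot(all(incidence >= 0 & incidence <= 1))
  as.integer(round(incidence * mean(cost_range)))
}

#' Per-herd economic summary of the tertile demonstration
#'
#' From the per-group marginal incidences: per-case cost
#' ([economic_cost()]), the worst-to-best tertile incidence gap in
#' percentage points, the relative reduction in incidence
#' (`(worst - best) / worst`, rounded to whole percent), and the decreased
#' loss per cow as the difference of the *rounded* per-case costs.
#'
#' @param incidence_report Tibble from [fit_incidence_model()] (or any
#'   tibble with `herd_id`, `group`, `incidence`).
#' @param cost_range Passed to [economic_cost()].
#' @return A list of two tibbles: `costs` (per herd and group, with
#'   `cost_per_case_dollars`) and `summary` (per herd: `tertile_gap_points`,
#'   `relative_reduction_percent`, `decreased_loss_dollars`).
#' @export
economic_report <- function(incidence_report, cost_range = c(97, 225)) {
  costs <- incidence_report |>
    select("herd_id", "group", "incidence") |>
    mutate(cost_per_case_dollars = economic_cost(.data$incidence, cost_range))
  wide <- costs |>
    filter(.data$group %in% c("worst 33%", "best 33%")) |>
    tidyr::pivot_wider(id_cols = "herd_id", names_from = "group",
                       values_from = c("incidence", "cost_per_case_dollars"))
  summary <- tibble(
    herd_id = wide$herd_id,
    tertile_gap_points = round(100 * (wide$`incidence_worst 33%` -
                                        wide$`incidence_best 33%`)),
    relative_reduction_percent = round(
      100 * (wide$`incidence_worst 33%` - wide$`incidence_best 33%`) /
        wide$`incidence_worst 33%`),
    decreased_loss_dollars = wide$`cost_per_case_dollars_worst 33%` -
      wide$`cost_per_case_dollars_best 33%`)
  list(costs = costs, summary = summary)
}

#' Regression of twin outcomes on individual STAs
#'
#' Supporting association models mirroring the demonstration analyses.
#' `model = "secondary"`: binomial logit mixed model of the twin outcome on
#' the individual STA (clamped to 85-115, i.e. +/-3 SD) and lactation
#' (1st-4th) with a per-animal random intercept. `model = "tertiary"`:
#' 3rd-lactation records only, fixed effects of STA, season of conception,
#' and previous-lactation peak yield (one record per cow, so a plain
#' binomial GLM). Type III marginal Wald chi-square tests are reported per
#' fixed effect; constant covariates are dropped with a warning.
#'
#' @param records Cow-lactation tibble with `cow_id`, `parity`, `twin`, and
#'   for the tertiary model `conception_season` and `peak_yield` columns.
#' @param scores Tibble with `animal_id`, `sta`.
#' @param model `"secondary"` or `"tertiary"`.
#' @param sta_range Clamping range for STAs (default `c(85, 115)`).
#' @return Tibble `effect`, `df`, `statistic`, `p_value`; the fitted model
#'   in attribute `"model"`.
#' @export
sta_regression <- function(records, scores, model = c("secondary", "tertiary"),
                           sta_range = c(85, 115)) {
  model <- match.arg(model)
  x <- inner_join(records, select(scores, "animal_id", "sta"),
                  by = c(cow_id = "animal_id"))
  x$sta <- pmin(pmax(x$sta, sta_range[1]), sta_range[2])
  if (model == "secondary") {
    x <- filter(x, .data$parity %in% 1:4) |>
      mutate(lactation = factor(.data$parity))
    terms <- c("sta", "lactation")
    x <- drop_constant_terms(x, terms)
    form <- stats::reformulate(c(attr(x, "kept"), "(1 | cow_id)"),
                               response = "twin")
    fit <- suppressMessages(lme4::glmer(
      form, data = x, family = stats::binomial(),
      control = lme4::glmerControl(calc.derivs = FALSE,
                                   check.conv.singular = "ignore")))
  } else {
    x <- filter(x, .data$parity == 3)
    need <- c("conception_season", "peak_yield")
    if (!all(need %in% names(x))) {
      abort("tertiary model needs conception_season and peak_yield columns")
    }
    terms <- c("sta", "conception_season", "peak_yield")
    x <- drop_constant_terms(x, terms)
    form <- stats::reformulate(attr(x, "kept"), response = "twin")
    fit <- stats::glm(form, data = x, family = stats::binomial())
  }
  a <- car::Anova(fit, type = "III")
  keep <- rownames(a) %in% attr(x, "kept")
  out <- tibble(effect = rownames(a)[keep],
                df = a$Df[keep],
                statistic = a$Chisq[keep],
                p_value = a$`Pr(>Chisq)`[keep])
  attr(out, "model") <- fit
  out
}

drop_constant_terms <- function(x, terms) {
  kept <- terms[vapply(terms, function(t) length(unique(x[[t]])) > 1,
                       logical(1))]
  dropped <- setdiff(terms, kept)
  if (length(dropped) > 0) {
    warn(paste("dropping constant covariate(s):",
               paste(dropped, collapse = ", ")))
  }
  attr(x, "kept") <- kept
  x
}
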