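#' Season of calving
#'
#' Four seasons are used for contemporary grouping: Winter
#' (December-February), Spring (March-May), Summer (June-August), Fall
#' (September-November).
#'
#' @param date A `Date` vector.
#' @return Character vector of season labels.
#' @export
assign_season <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  c("Winter", "Winter", "Spring", "Spring", "Spring",
    "Summer", "Summer", "Summer", "Fall", "Fall", "Fall", "Winter")[m]
}

# HYS year: December is grouped with the following January-February so each
# winter is one contiguous contemporary group
hys_year <- function(date) {
  d <- as.Date(date)
  y <- as.integer(format(d, "%Y"))
  y + as.integer(format(d, "%m") == "12")
}

#' @rdname assign_season
#' @param herd_id Herd identifier vector, recycled against `date`.
#' @export
hys_key <- function(herd_id, date) {
  paste(herd_id, hys_year(date), assign_season(date), sep = "_")
}

#' Standardize raw farm events to per-lactation twin outcomes
#'
#' Collapses the heterogeneous on-farm (event, remark) vocabulary to the
#' binary twin outcome: a lactation is a twin (1) if any of its events
#' matches a combination in [twin_vocabulary()] -- including an `ABORT`
#' event whose remark is exactly the two letters `TW` -- and a singleton (0)
#' otherwise. Matching is case-insensitive after trimming surrounding
#' whitespace; unknown combinations default to singleton. One row per
#' cow-lactation is returned, with the calving interval computed from
#' consecutive calving dates within cow and the herd-year-season key
#' attached.
#'
#' @param log Raw event log: tibble with `cow_id`, `herd_id`, `event_date`,
#'   `event`, `remark`, `parity`.
#' @return Tibble with one row per cow-lactation: `cow_id`, `herd_id`,
#'   `calving_date`, `parity`, `parity_class` (1-4, `"5+"`),
#'   `calving_interval_days` (`NA` for first parity), `twin`, `season`,
#'   `hys_key`.
#' @export
standardize_twin_events <- function(log) {
  stopifnot(all(c("cow_id", "herd_id", "event_date", "event", "remark",
                  "parity") %in% names(log)))
  ev <- toupper(trimws(log$event))
  rk <- toupper(trimws(ifelse(is.na(log$remark), "", log$remark)))
  vocab <- twin_vocabulary()
  key <- paste(vocab$event, vocab$remark, sep = "\r")
  hit <- paste(ev, rk, sep = "\r") %in% key |
    (ev == "ABORT" & nchar(rk) == 2L & rk == "TW")
  out <- tibble(cow_id = log$cow_id, herd_id = log$herd_id,
                calving_date = as.Date(log$event_date),
                parity = as.integer(log$parity), twin = as.integer(hit))
  out <- out |>
    group_by(.data$cow_id, .data$parity) |>
    summarise(herd_id = first(.data$herd_id),
              calving_date = min(.data$calving_date),
              twin = max(.data$twin), .groups = "drop") |>
    arrange(.data$cow_id, .data$parity)
  out <- out |>
    group_by(.data$cow_id) |>
    mutate(calving_interval_days =
             as.integer(.data$calving_date - lag(.data$calving_date))) |>
    ungroup()
  out$parity_class <- ifelse(out$parity >= 5L, "5+",
                             as.character(out$parity))
  out$season <- assign_season(out$calving_date)
  out$hys_key <- hys_key(out$herd_id, out$calving_date)
  select(out, "cow_id", "herd_id", "calving_date", "parity", "parity_class",
         "calving_interval_days", "twin", "season", "hys_key")
}

#' Animal-level record edits
#'
#' Removes lactation records that fail the evaluation edits: records of
#' animals recorded as male in the pedigree, records whose calving date does
#' not follow the animal's birth date, and records (beyond first parity)
#' whose calving interval falls outside the plausible range (inclusive
#' bounds, 250-999 days by default). First-parity records have no calving
#' interval and are exempt from the interval rule.
#'
#' @param records Cow-lactation tibble from [standardize_twin_events()].
#' @param pedigree Pedigree tibble with `animal_id`, `sex`, `birth_date`.
#' @param interval_bounds Inclusive calving-interval bounds in days.
#' @param missing_cow `"drop"` (default) removes records of cows absent from
#'   the pedigree; `"keep"` retains them.
#' @return The surviving records; the per-rule removal counts are attached
#'   as a tibble in attribute `"audit"` (see [edit_audit()]).
#' @export
apply_animal_edits <- function(records, pedigree,
                               interval_bounds = c(250, 999),
                               missing_cow = c("drop", "keep")) {
  missing_cow <- match.arg(missing_cow)
  ped <- select(pedigree, "animal_id", "sex", "birth_date")
  x <- left_join(records, ped, by = c(cow_id = "animal_id"))

  in_ped <- !is.na(x$sex)
  is_male <- in_ped & x$sex == "M"
  bad_date <- in_ped & !is.na(x$birth_date) & x$calving_date <= x$birth_date
  bad_interval <- !is.na(x$calving_interval_days) &
    (x$calving_interval_days < interval_bounds[1] |
       x$calving_interval_days > interval_bounds[2])
  drop_missing <- if (missing_cow == "drop") !in_ped else rep(FALSE, nrow(x))

  keep <- !(is_male | bad_date | bad_interval | drop_missing)
  audit <- tibble(
    rule = c("male_in_pedigree", "calving_before_birth",
             "calving_interval_out_of_bounds", "cow_missing_from_pedigree"),
    n_removed = c(sum(is_male), sum(bad_date & !is_male),
                  sum(bad_interval & !is_male & !bad_date),
                  sum(drop_missing)))
  out <- records[keep, , drop = FALSE]
  attr(out, "audit") <- audit
  out
}

#' Herd-year-season contemporary-group filter
#'
#' Drops every record in a herd-year-season group with fewer than
#' `min_records` records or fewer than `min_twins` recorded twin events;
#' such groups are assumed to come from herds that did not record twinning
#' in that period.
#'
#' @param records Cow-lactation tibble with `hys_key` and `twin` columns.
#' @param min_records Minimum group size (default 20).
#' @param min_twins Minimum recorded twin events per group (default 1).
#' @return Surviving records; the surviving group table (`hys_key`,
#'   `n_records`, `n_twins`) is in attribute `"hys_groups"`, removal counts
#'   in attribute `"audit"`.
#' @export
apply_hys_filter <- function(records, min_records = 20, min_twins = 1) {
  grp <- records |>
    group_by(.data$hys_key) |>
    summarise(n_records = n(), n_twins = sum(.data$twin), .groups = "drop")
  ok <- grp$n_records >= min_records & grp$n_twins >= min_twins
  keep_keys <- grp$hys_key[ok]
  out <- filter(records, .data$hys_key %in% keep_keys)
  if (nrow(out) == 0) warn("no records survive the HYS filter")
  attr(out, "hys_groups") <- grp[ok, , drop = FALSE]
  attr(out, "audit") <- tibble(
    rule = c("hys_group_too_small_or_no_twins"),
    n_removed = nrow(records) - nrow(out))
  out
}

#' @rdname apply_animal_edits
#' @param x A filtered record tibble.
#' @export
edit_audit <- function(x) attr(x, "audit")

#' @rdname apply_hys_filter
#' @export
hys_groups <- function(x) attr(x, "hys_groups")
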