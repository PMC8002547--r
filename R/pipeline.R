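#' Configuration of a complete evaluation run
#'
#' Collects every stage's settings in one serializable object: the
#' synthetic-herd generator block, the Gibbs block, relationship-matrix
#' options (blending, APY core, tau/omega), scoring options (base cohort
#' birth year, scaling cohort), and validation options (lactation window,
#' cost constants). Every numeric constant used as a default by the
#' evaluation lives here, not in code. One global seed fans out to
#' per-stage substreams so stages can be rerun independently.
#'
#' @param sim A [sim_config()] block.
#' @param gibbs A [gibbs_config()] block.
#' @param genotyped_generations Pedigree generations whose animals are
#'   treated as genotyped (default: the last two).
#' @param blend_weight Weight on G when blending with A22 (default 0.95).
#' @param apy_n_core APY core size; `NULL` uses the exact inverse.
#' @param tau,omega H-inverse conditioning scalars (default 1).
#' @param base_birth_year Base-cohort birth year (default 2015).
#' @param scaling STA scaling cohort, `"base"` or `"all"`.
#' @param interval_bounds Calving-interval edit bounds (default
#'   `c(250, 999)`).
#' @param hys_min_records,hys_min_twins HYS filter thresholds (20 and 1).
#' @param validation_lactations Lactations for the incidence model (2:4).
#' @param validation_cutoff_year Last calving year included in the snapshot
#'   evaluation whose scores feed the tertile demonstration; outcomes from
#'   later years are the validation data. Defaults to three years before
#'   the end of the simulated range. `NA` disables the snapshot and
#'   validates in-sample (biased optimistic; see the methods vignette).
#' @param cost_range Economic cost constants (default `c(97, 225)`).
#' @param seed Global seed.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       gibbs = gibbs_config(),
                       genotyped_generations = NULL,
                       blend_weight = 0.95,
                       apy_n_core = NULL,
                       tau = 1, omega = 1,
                       base_birth_year = 2015,
                       scaling = "base",
                       interval_bounds = c(250, 999),
                       hys_min_records = 20,
                       hys_min_twins = 1,
                       validation_lactations = 2:4,
                       validation_cutoff_year = NULL,
                       cost_range = c(97, 225),
                       seed = 1L) {
  genotyped_generations <- genotyped_generations %||% sim$n_generations
  validation_cutoff_year <- validation_cutoff_year %||% (sim$years[2] - 3)
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the [run_config()]
#'   arguments (with `sim` and `gibbs` sub-blocks).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$sim %||% list())
  gibbs <- do.call(gibbs_config, y$gibbs %||% list())
  rest <- y[setdiff(names(y), c("sim", "gibbs"))]
  do.call(run_config, c(list(sim = sim, gibbs = gibbs), rest))
}

config_hash <- function(config) {
  canon <- config[sort(names(config))]
  rlang::hash(canon)
}

stage_files <- list(
  simulate = c("pedigree.csv", "genotypes.tsv", "events.csv"),
  standardize = c("records.csv", "edit_audit.json"),
  estimate = c("variance_components.json", "gibbs_chains.tsv"),
  solve = c("solutions.csv"),
  score = c("scores.csv"),
  validate = c("validation_report.csv", "validation_summary.json"))

#' Run the complete synthetic evaluation pipeline
#'
#' Executes simulate -> standardize -> relate -> estimate -> solve ->
#' score -> validate. Each stage persists its artifacts under `out_dir`
#' and is skipped on rerun when its outputs already exist for the same
#' configuration hash (`resume = TRUE`); a manifest with the configuration
#' hash, stage timings, and output checksums is written at the end.
#' Variance components are estimated with the pedigree-only A-inverse;
#' breeding values are solved with the single-step H-inverse.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param resume Reuse persisted stage outputs when the configuration hash
#'   matches (default `TRUE`).
#' @return A `twin_run`: list with the in-memory artifacts of every stage
#'   (`pedigree`, `genotypes`, `events`, `records`, `relationships`,
#'   `gibbs`, `solutions`, `scores`, `tertiles`, `incidence`, `economics`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir = tempfile("twinrun"),
                         resume = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  manifest_path <- file.path(out_dir, "manifest.json")
  old_manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else NULL
  reusable <- resume && !is.null(old_manifest) &&
    identical(old_manifest$config_hash, hash)
  timings <- list()
  done <- function(stage) {
    reusable && all(file.exists(file.path(out_dir, stage_files[[stage]])))
  }
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    value <- tryCatch(force(expr), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    value
  }

  # -- simulate -------------------------------------------------------------
  if (done("simulate")) {
    pedigree <- read_pedigree(file.path(out_dir, "pedigree.csv"))
    genotypes <- read_genotypes(file.path(out_dir, "genotypes.tsv"))
    events <- read_event_log(file.path(out_dir, "events.csv"))
  } else {
    sim <- tick("simulate", {
      cfg <- config$sim
      cfg$seed <- sub_seed(config$seed, 11)
      ped <- simulate_pedigree(cfg)
      gen <- simulate_genotypes(ped, cfg)
      ev <- simulate_records(ped, gen, cfg)
      list(ped = ped, gen = gen, ev = ev)
    })
    pedigree <- sim$ped; genotypes <- sim$gen; events <- sim$ev
    write_pedigree(pedigree, file.path(out_dir, "pedigree.csv"))
    write_genotypes(genotypes, file.path(out_dir, "genotypes.tsv"))
    write_event_log(events, file.path(out_dir, "events.csv"))
  }

  # -- standardize ----------------------------------------------------------
  if (done("standardize")) {
    records <- readr::read_csv(file.path(out_dir, "records.csv"),
                               show_col_types = FALSE)
    records$calving_date <- as.Date(records$calving_date)
  } else {
    records <- tick("standardize", {
      r <- standardize_twin_events(events)
      r <- apply_animal_edits(r, pedigree,
                              interval_bounds = config$interval_bounds)
      audit1 <- edit_audit(r)
      r <- apply_hys_filter(r, config$hys_min_records, config$hys_min_twins)
      audit <- bind_rows(audit1, edit_audit(r))
      jsonlite::write_json(audit, file.path(out_dir, "edit_audit.json"))
      r
    })
    readr::write_csv(records, file.path(out_dir, "records.csv"))
  }

  # -- relate (always rebuilt in memory; cheap at desk scale) ---------------
  relationships <- tick("relate", {
    set.seed(sub_seed(config$seed, 13))
    A_inv <- build_A_inverse(pedigree)
    geno_ids <- pedigree$animal_id[
      pedigree$generation %in% config$genotyped_generations]
    geno <- genotypes$dosages[geno_ids, , drop = FALSE]
    A22 <- pedigree_relationship_block(A_inv, geno_ids)
    G <- build_G(geno, A22 = A22, blend_weight = config$blend_weight)
    G_inv <- invert_G_apy(G, n_core = config$apy_n_core %||% length(geno_ids))
    A22_inv <- chol2inv(chol(A22))
    dimnames(A22_inv) <- dimnames(A22)
    H_inv <- assemble_H_inverse(A_inv, G_inv, A22_inv,
                                tau = config$tau, omega = config$omega)
    list(A_inv = A_inv, G = G, G_inv = G_inv, A22_inv = A22_inv,
         H_inv = H_inv, genotyped_ids = geno_ids)
  })

  frame <- build_model_frame(records, pedigree)

  # -- estimate -------------------------------------------------------------
  vc_path <- file.path(out_dir, "variance_components.json")
  if (done("estimate")) {
    vc <- unlist(jsonlite::read_json(vc_path))
    gibbs <- NULL
  } else {
    gibbs <- tick("estimate", {
      gc <- config$gibbs
      gc$seed <- sub_seed(config$seed, 17)
      gibbs_variance_components(frame, relationships$A_inv, gc)
    })
    vc <- gibbs$posterior_mean
    jsonlite::write_json(as.list(vc), vc_path, auto_unbox = TRUE, digits = NA)
    readr::write_tsv(gibbs$chains, file.path(out_dir, "gibbs_chains.tsv"))
  }

  # -- solve ----------------------------------------------------------------
  if (done("solve")) {
    soltab <- readr::read_csv(file.path(out_dir, "solutions.csv"),
                              show_col_types = FALSE)
    solutions <- structure(list(solutions = soltab, mode = "threshold",
                                vc = vc, pcg_rounds = NA_integer_,
                                outer_iterations = NA_integer_,
                                rel_residual = NA_real_),
                           class = "twin_solutions")
  } else {
    solutions <- tick("solve", {
      solve_mme_pcg(frame, relationships$H_inv, vc)
    })
    readr::write_csv(solutions$solutions, file.path(out_dir, "solutions.csv"))
  }

  # -- score ----------------------------------------------------------------
  scores <- tick("score", {
    score_animals(solutions, records, pedigree, vc,
                  base_birth_year = config$base_birth_year,
                  scaling = config$scaling,
                  g_diag = setNames(diag(relationships$G),
                                    rownames(relationships$G)))
  })
  readr::write_csv(scores, file.path(out_dir, "scores.csv"))

  # -- validate -------------------------------------------------------------
  # Tertile demonstration on a temporal split: scores from a snapshot
  # evaluation truncated at the cutoff year, outcomes from later calvings.
  # Validating the full-data scores on their own records would be circular
  # (a cow's own twin record feeds her score), so the in-sample path only
  # runs when the snapshot is disabled or leaves too little data.
  validation <- tick("validate", {
    cutoff <- config$validation_cutoff_year
    cut_date <- if (is.na(cutoff)) as.Date(NA) else
      as.Date(sprintf("%d-12-31", cutoff))
    snap_rec <- if (is.na(cutoff)) records else
      filter(records, .data$calving_date <= cut_date)
    val_rec <- if (is.na(cutoff)) records else
      filter(records, .data$calving_date > cut_date)
    use_snapshot <- !is.na(cutoff) && nrow(val_rec) >= 50 &&
      nrow(snap_rec) >= 200 && sum(val_rec$twin) >= 1
    if (use_snapshot) {
      snap_frame <- build_model_frame(snap_rec, pedigree)
      snap_sol <- solve_mme_pcg(snap_frame, relationships$H_inv, vc)
      base_year <- latest_base_year(snap_rec, pedigree)
      snap_scores <- score_animals(
        snap_sol, snap_rec, pedigree, vc, base_birth_year = base_year,
        scaling = config$scaling,
        g_diag = setNames(diag(relationships$G), rownames(relationships$G)))
    } else {
      warn("validating in-sample: snapshot split disabled or too thin")
      val_rec <- records
      snap_scores <- scores
    }
    herds <- val_rec |> distinct(.data$cow_id, .data$herd_id) |>
      rename(animal_id = "cow_id")
    tert <- assign_tertiles(snap_scores, herds)
    inc <- fit_incidence_model(val_rec, tert,
                               lactations = config$validation_lactations)
    eco <- economic_report(inc, config$cost_range)
    list(tertiles = tert, incidence = inc, economics = eco,
         snapshot_scores = if (use_snapshot) snap_scores else NULL,
         validation_records = val_rec)
  })
  readr::write_csv(left_join(validation$incidence, validation$economics$costs,
                             by = c("herd_id", "group", "incidence")),
                   file.path(out_dir, "validation_report.csv"))
  jsonlite::write_json(validation$economics$summary,
                       file.path(out_dir, "validation_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    config_hash = hash,
    created = format(Sys.time(), tz = "UTC"),
    stage_seconds = timings,
    checksums = as.list(tools::md5sum(
      list.files(out_dir, pattern = "\\.(csv|tsv|json)$",
                 full.names = TRUE))))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  manifest$checksums$manifest.json <- NULL
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)

  structure(list(config = config, out_dir = out_dir,
                 pedigree = pedigree, genotypes = genotypes, events = events,
                 records = records, relationships = relationships,
                 frame = frame, gibbs = gibbs, vc = vc,
                 solutions = solutions, scores = scores,
                 tertiles = validation$tertiles,
                 incidence = validation$incidence,
                 economics = validation$economics,
                 manifest = manifest),
            class = "twin_run")
}

#' @export
print.twin_run <- function(x, ...) {
  cat("Twin-pregnancy evaluation run\n")
  cat(sprintf("  %d pedigree animals, %d records after edits, %d genotyped\n",
              nrow(x$pedigree), nrow(x$records),
              length(x$relationships$genotyped_ids)))
  cat(sprintf("  vc: sigma2_a=%.4f sigma2_pe=%.4f sigma2_hys=%.4f (h2=%.4f)\n",
              x$vc[["sigma2_a"]], x$vc[["sigma2_pe"]], x$vc[["sigma2_hys"]],
              compute_ratios(x$vc[["sigma2_a"]], x$vc[["sigma2_pe"]],
                             x$vc[["sigma2_hys"]])$h2))
  cat(sprintf("  artifacts: %s\n", x$out_dir))
  invisible(x)
}

# ---- plain-text readers/writers ------------------------------------------

#' Read and write pipeline artifacts
#'
#' Plain-text persistence for the pipeline stages: pedigree and event-log
#' CSVs and a tab-separated dosage table (animals in rows, SNPs in columns,
#' first column `animal_id`, allele frequencies in a `#freq` header line).
#'
#' @param x Object to write.
#' @param path File path.
#' @name twin_io
NULL

#' @rdname twin_io
#' @export
write_pedigree <- function(x, path) {
  readr::write_csv(x, path)
}

#' @rdname twin_io
#' @export
read_pedigree <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           animal_id = "c", sire_id = "c", dam_id = "c"))
  out$birth_date <- as.Date(out$birth_date)
  out
}

#' @rdname twin_io
#' @export
write_event_log <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
}

#' @rdname twin_io
#' @export
read_event_log <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(cow_id = "c", herd_id = "c",
                                                 event = "c", remark = "c"))
  out$event_date <- as.Date(out$event_date)
  out$remark[is.na(out$remark)] <- ""
  out
}

#' @rdname twin_io
#' @export
write_genotypes <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#freq\t", paste(format(x$allele_freqs, digits = 17),
                                     collapse = "\t")), con)
  df <- cbind(data.frame(animal_id = rownames(x$dosages)),
              as.data.frame(x$dosages))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname twin_io
#' @export
read_genotypes <- function(path) {
  first <- readLines(path, n = 1)
  freqs <- as.numeric(strsplit(first, "\t")[[1]][-1])
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                          colClasses = c(animal_id = "character"))
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df$animal_id
  colnames(M) <- NULL
  structure(list(animal_ids = df$animal_id, dosages = M,
                 allele_freqs = freqs),
            class = "twin_genotypes")
}
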