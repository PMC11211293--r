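#' Run the full study-shaped cohort experiment
#'
#' Orchestrates the whole pipeline for a synthetic cohort: phantom
#' generation, simulated automated segmentation, segmentation metrics,
#' vessel trunk/branch classification, blood-filled and blood-free
#' volumetry with both the manual (ground-truth) and automated masks,
#' candidacy decisions, and the cohort agreement statistics. With `n`
#' patients the report holds exactly `n x 2 methods x 2 settings` FLR%
#' measurements. Two runs with the same configuration and seed produce
#' identical reports.
#'
#' @param n Number of patients.
#' @param config A [phantom_config()].
#' @param perturb A [perturbation_config()] describing the simulated
#'   automated method, or `NULL` for an identity method (automated ==
#'   manual).
#' @param seed Master seed; phantom and perturbation substreams are derived
#'   from it.
#' @param out_dir Optional directory: NIfTI volumes, CSV tables, a JSON
#'   report and a log file are written there.
#' @param tolerance_mm Coverage tolerance for vessel classification
#'   (default one voxel).
#' @param verbose Announce per-patient progress.
#' @return A `flr_cohort_report`: list of tibbles `patients`, `metrics`,
#'   `classification`, `accuracy`, `volumetry`, `flr_measurements`,
#'   `candidacy`, `bland_altman`, `mcnemar`, `rank_tests`, plus `meta`.
#' @export
run_cohort <- function(n = 32, config = phantom_config(),
                       perturb = perturbation_config(), seed = 1L,
                       out_dir = NULL, tolerance_mm = NULL,
                       verbose = FALSE) {
  seeds <- derive_seeds(seed, 2)
  cohort <- generate_cohort(n, config, seeds[1])
  pseeds <- derive_seeds(seeds[2], n)

  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, paste(format(Sys.time()), msg))
    if (verbose) message(msg)
  }

  patients <- list(); metrics <- list(); classification <- list()
  volumetry_rows <- list(); flr_rows <- list(); cand_rows <- list()

  for (i in seq_len(n)) {
    ph <- cohort[[i]]
    say("patient %s: %s liver, %s hepatectomy", ph$id, ph$condition,
        ph$resection$type)
    stage <- "perturbation"
    res <- tryCatch({
      pred <- if (is.null(perturb)) {
        ph$truth
      } else {
        cfg_i <- perturb
        cfg_i$seed <- pseeds[i]
        perturb_segmentation(ph, cfg_i)
      }
      stage <- "metrics"
      met <- overlap_metrics(pred, ph$truth)
      stage <- "classification"
      cls <- dplyr::bind_rows(lapply(ph$trees, classify_vessel,
                                     pred_volume = pred,
                                     tolerance_mm = tolerance_mm))
      stage <- "volumetry"
      vol_m <- volumetry(ph$truth, plan = ph$resection)
      vol_a <- volumetry(pred, plan = ph$resection)
      list(pred = pred, met = met, cls = cls, vol_m = vol_m, vol_a = vol_a)
    }, error = function(e) {
      stop("stage '", stage, "' failed for patient ", ph$id, ": ",
           conditionMessage(e), call. = FALSE)
    })

    patients[[i]] <- tibble(id = ph$id, condition = ph$condition,
                            resection = ph$resection$type,
                            phantom_seed = ph$seed,
                            blood_fraction = ph$blood_fraction)
    metrics[[i]] <- dplyr::mutate(res$met, id = ph$id,
                                  condition = ph$condition, .before = 1)
    classification[[i]] <- dplyr::mutate(res$cls, id = ph$id, .before = 1)
    vol <- dplyr::bind_rows(
      dplyr::mutate(res$vol_m, method = "manual"),
      dplyr::mutate(res$vol_a, method = "automated")
    )
    volumetry_rows[[i]] <- dplyr::mutate(vol, id = ph$id,
                                         condition = ph$condition,
                                         .before = 1)
    long <- vol |>
      dplyr::select("method", "flr_filled_ml", "flr_free_ml",
                    "flr_pct_filled", "flr_pct_free") |>
      tidyr::pivot_longer(-"method",
                          names_to = c(".value", "setting"),
                          names_pattern = "(flr(?:_pct)?)_(filled|free)_?m?l?") |>
      dplyr::mutate(setting = paste0("blood_", .data$setting)) |>
      dplyr::rename(flr_ml = "flr", flr_pct = "flr_pct")
    flr_rows[[i]] <- dplyr::mutate(long, id = ph$id,
                                   condition = ph$condition, .before = 1)
    cand_rows[[i]] <- long |>
      dplyr::rowwise() |>
      dplyr::reframe(candidacy(.data$flr_pct, ph$condition,
                               basis = .data$setting),
                     method = .data$method) |>
      dplyr::mutate(id = ph$id, .before = 1)

    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_label_volume(ph$truth,
                         file.path(out_dir,
                                   paste0(ph$id, "_truth.nii.gz")),
                         meta = list(id = ph$id, condition = ph$condition,
                                     resection = ph$resection$type,
                                     seed = ph$seed))
      write_label_volume(res$pred,
                         file.path(out_dir, paste0(ph$id, "_pred.nii.gz")),
                         meta = list(id = ph$id, method = "automated"))
    }
  }

  patients <- dplyr::bind_rows(patients)
  metrics <- dplyr::bind_rows(metrics)
  classification <- dplyr::bind_rows(classification)
  volumetry_tbl <- dplyr::bind_rows(volumetry_rows)
  flr_measurements <- dplyr::bind_rows(flr_rows)
  candidacy_tbl <- dplyr::bind_rows(cand_rows)

  accuracy <- accuracy_table(classification)
  bland_altman_tbl <- cohort_bland_altman(volumetry_tbl, flr_measurements)
  mcnemar_tbl <- cohort_mcnemar(candidacy_tbl)
  rank_tbl <- cohort_rank_tests(metrics, flr_measurements)

  say("cohort complete: %d patients, %d FLR%% measurements", n,
      nrow(flr_measurements))

  report <- structure(list(
    patients = patients, metrics = metrics,
    classification = classification, accuracy = accuracy,
    volumetry = volumetry_tbl, flr_measurements = flr_measurements,
    candidacy = candidacy_tbl, bland_altman = bland_altman_tbl,
    mcnemar = mcnemar_tbl, rank_tests = rank_tbl,
    meta = list(n = n, seed = seed, config_hash = rlang::hash(config),
                perturb = if (is.null(perturb)) "identity"
                          else unclass(perturb))
  ), class = "flr_cohort_report")

  if (!is.null(out_dir)) {
    report_tables(report, out_dir)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  report
}

# Bland-Altman set: automated vs manual for vessel volumes and FLR
# quantities, and blood-free vs blood-filled within each method.
cohort_bland_altman <- function(volumetry_tbl, flr_measurements) {
  out <- list()
  n <- length(unique(volumetry_tbl$id))
  if (n < 3) return(tibble())
  wide <- volumetry_tbl |>
    dplyr::arrange(.data$id) |>
    tidyr::pivot_wider(id_cols = "id", names_from = "method",
                       values_from = c("v_hv_ml", "v_pv_ml",
                                       "flr_filled_ml", "flr_free_ml",
                                       "flr_pct_filled", "flr_pct_free"))
  for (q in c("v_hv_ml", "v_pv_ml", "flr_filled_ml", "flr_free_ml",
              "flr_pct_filled", "flr_pct_free")) {
    ba <- bland_altman(wide[[paste0(q, "_automated")]],
                       wide[[paste0(q, "_manual")]])
    out[[length(out) + 1]] <-
      dplyr::mutate(tidy(ba), comparison = "automated_vs_manual",
                    quantity = q, .before = 1)
  }
  fw <- flr_measurements |>
    dplyr::arrange(.data$id) |>
    tidyr::pivot_wider(id_cols = c("id", "method"), names_from = "setting",
                       values_from = c("flr_ml", "flr_pct"))
  for (m in unique(fw$method)) {
    sub <- fw[fw$method == m, ]
    for (q in c("flr_ml", "flr_pct")) {
      ba <- bland_altman(sub[[paste0(q, "_blood_free")]],
                         sub[[paste0(q, "_blood_filled")]])
      out[[length(out) + 1]] <-
        dplyr::mutate(tidy(ba), comparison = paste0("free_vs_filled_", m),
                      quantity = q, .before = 1)
    }
  }
  dplyr::bind_rows(out)
}

# McNemar 2x2 summaries: manual vs automated per setting, and blood-free vs
# blood-filled per method.
cohort_mcnemar <- function(candidacy_tbl) {
  out <- list()
  for (s in unique(candidacy_tbl$basis)) {
    w <- candidacy_tbl[candidacy_tbl$basis == s, ] |>
      tidyr::pivot_wider(id_cols = "id", names_from = "method",
                         values_from = "candidate")
    b <- sum(w$manual & !w$automated)
    cc <- sum(!w$manual & w$automated)
    mc <- mcnemar_exact(b, cc)
    out[[length(out) + 1]] <-
      dplyr::mutate(tidy(mc), comparison = "manual_vs_automated",
                    stratum = s,
                    n_candidates_a = sum(w$manual),
                    n_candidates_b = sum(w$automated), .before = 1)
  }
  for (m in unique(candidacy_tbl$method)) {
    w <- candidacy_tbl[candidacy_tbl$method == m, ] |>
      tidyr::pivot_wider(id_cols = "id", names_from = "basis",
                         values_from = "candidate")
    b <- sum(w$blood_free & !w$blood_filled)
    cc <- sum(!w$blood_free & w$blood_filled)
    mc <- mcnemar_exact(b, cc)
    out[[length(out) + 1]] <-
      dplyr::mutate(tidy(mc), comparison = "free_vs_filled",
                    stratum = m,
                    n_candidates_a = sum(w$blood_free),
                    n_candidates_b = sum(w$blood_filled), .before = 1)
  }
  dplyr::bind_rows(out)
}

# Mann-Whitney comparisons of FLR and FLR% between methods, and
# Kruskal-Wallis subgroup comparisons of DSC by liver condition.
cohort_rank_tests <- function(metrics, flr_measurements) {
  out <- list()
  for (s in unique(flr_measurements$setting)) {
    sub <- flr_measurements[flr_measurements$setting == s, ]
    for (q in c("flr_ml", "flr_pct")) {
      mw <- mann_whitney_u(sub[[q]][sub$method == "manual"],
                           sub[[q]][sub$method == "automated"])
      out[[length(out) + 1]] <-
        dplyr::mutate(tidy(mw),
                      comparison = paste0("manual_vs_automated_", q),
                      stratum = s, .before = 1)
    }
  }
  for (g in unique(metrics$structure_group)) {
    sub <- metrics[metrics$structure_group == g, ]
    if (length(unique(sub$condition)) >= 2) {
      kw <- kruskal_wallis(split(sub$dsc, sub$condition))
      out[[length(out) + 1]] <-
        dplyr::mutate(tidy(kw), comparison = "dsc_by_condition",
                      stratum = g, .before = 1)
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.flr_cohort_report <- function(x, ...) {
  cat(sprintf("<flr_cohort_report> %d patients, %d FLR%% measurements\n",
              x$meta$n, nrow(x$flr_measurements)))
  hv <- x$metrics$dsc[x$metrics$structure_group == "HEPATIC_VEINS"]
  pv <- x$metrics$dsc[x$metrics$structure_group == "PORTAL_VEINS"]
  cat(sprintf("  DSC hepatic veins %.3f, portal veins %.3f (cohort means)\n",
              mean(hv), mean(pv)))
  cand <- x$candidacy |>
    dplyr::group_by(.data$method, .data$basis) |>
    dplyr::summarise(k = sum(.data$candidate), .groups = "drop")
  for (r in seq_len(nrow(cand)))
    cat(sprintf("  candidates (%s, %s): %d/%d\n", cand$method[r],
                cand$basis[r], cand$k[r], x$meta$n))
  invisible(x)
}

#' @export
glance.flr_cohort_report <- function(x, ...) {
  tibble(
    n_patients = x$meta$n,
    n_flr_measurements = nrow(x$flr_measurements),
    dsc_hepatic_veins = mean(
      x$metrics$dsc[x$metrics$structure_group == "HEPATIC_VEINS"]),
    dsc_portal_veins = mean(
      x$metrics$dsc[x$metrics$structure_group == "PORTAL_VEINS"]),
    vs_hepatic_veins = mean(
      x$metrics$vs[x$metrics$structure_group == "HEPATIC_VEINS"]),
    vs_portal_veins = mean(
      x$metrics$vs[x$metrics$structure_group == "PORTAL_VEINS"]),
    flr_pct_filled_mean = mean(
      x$flr_measurements$flr_pct[x$flr_measurements$setting ==
                                 "blood_filled"]),
    flr_pct_free_mean = mean(
      x$flr_measurements$flr_pct[x$flr_measurements$setting ==
                                 "blood_free"])
  )
}

#' Write the cohort report tables to CSV
#'
#' Produces the familiar table shapes: a per-vessel trunk/branch accuracy
#' table (vessels across the columns), a volumes table comparing manual and
#' automated mean vessel volumes by liver condition, a 2x2 candidacy count
#' table (method by setting), and the per-patient measurement tables.
#'
#' @param report An `flr_cohort_report`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
report_tables <- function(report, dir) {
  if (!inherits(report, "flr_cohort_report") ||
      !all(c("accuracy", "metrics", "candidacy", "flr_measurements") %in%
           names(report)))
    stop("incomplete report", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  acc_wide <- report$accuracy |>
    dplyr::mutate(cell = ifelse(is.na(.data$accuracy_pct), "NA",
                                sprintf("%.2f (%.2f, %.2f)",
                                        .data$accuracy_pct, .data$ci_low,
                                        .data$ci_high))) |>
    tidyr::pivot_wider(id_cols = "measure", names_from = "vessel",
                       values_from = "cell")
  p <- file.path(dir, "accuracy.csv")
  utils::write.csv(acc_wide, p, row.names = FALSE)
  paths <- c(paths, p)

  volumes <- report$metrics |>
    dplyr::filter(.data$structure_group != "LIVER") |>
    dplyr::group_by(.data$structure_group, .data$condition) |>
    dplyr::summarise(
      mean_volume_manual_ml = mean(.data$volume_truth_ml),
      mean_volume_automated_ml = mean(.data$volume_pred_ml),
      n = dplyr::n(), .groups = "drop")
  p <- file.path(dir, "volumes.csv")
  utils::write.csv(volumes, p, row.names = FALSE)
  paths <- c(paths, p)

  cand <- report$candidacy |>
    dplyr::group_by(.data$method, .data$basis) |>
    dplyr::summarise(candidates = sum(.data$candidate), .groups = "drop") |>
    tidyr::pivot_wider(id_cols = "method", names_from = "basis",
                       values_from = "candidates")
  p <- file.path(dir, "candidacy.csv")
  utils::write.csv(cand, p, row.names = FALSE)
  paths <- c(paths, p)

  for (tb in c("metrics", "classification", "volumetry",
               "flr_measurements")) {
    p <- file.path(dir, paste0(tb, ".csv"))
    utils::write.csv(report[[tb]], p, row.names = FALSE)
    paths <- c(paths, p)
  }

  p <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(meta = report$meta, accuracy = report$accuracy,
         bland_altman = report$bland_altman, mcnemar = report$mcnemar,
         rank_tests = report$rank_tests, glance = glance(report)),
    p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
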