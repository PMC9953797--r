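# Cohort-level orchestration: per-patient measurement, report tables in the
# LD/TV/ETV and FTV layouts, AUC surfaces with optimal-threshold selection,
# and the C2-vs-C4 comparison. Works from an on-disk cohort directory, an
# in-memory synthetic cohort, or (streamed, one patient at a time) straight
# from a cohort configuration.

#' Measure one patient-timepoint set
#'
#' For each timepoint: selects the pre-contrast, early (1 and 2.5 min) and
#' late (7 min) phases, optionally refines the supplied mask on each early
#' subtraction image (Otsu over the masked histogram), and computes LD/TV
#' from bounding-box diameters on the 1-min and 7-min subtraction masks,
#' ETV per early phase, and the full FTV threshold grid per early phase.
#'
#' @param studies,masks named lists (`BL`, `C2`, `C4`) of [dce_study()] /
#'   [tumor_mask()].
#' @param grid a [build_grid()] threshold grid.
#' @param refine logical: refine masks by histogram thresholding before
#'   voxel counting (the default), or count the supplied masks as-is.
#' @param early_mins nominal early-phase times in minutes.
#' @param late_min nominal late-phase time in minutes.
#' @return list with `rows` (one data-frame row per timepoint) and `grids`
#'   (`grids[[early label]][[timepoint]]` FTV matrices).
#' @export
measure_patient <- function(studies, masks, grid = build_grid(),
                            refine = TRUE, early_mins = c(1, 2.5),
                            late_min = 7) {
  tps <- c("BL", "C2", "C4")
  stopifnot(all(tps %in% names(studies)), all(tps %in% names(masks)))
  grids <- stats::setNames(
    rep(list(stats::setNames(vector("list", 3), tps)), length(early_mins)),
    as.character(early_mins))
  rows <- NULL
  for (tp in tps) {
    study <- studies[[tp]]
    mask <- masks[[tp]]
    sp <- study$voxel_spacing
    etvs <- ftv_masks <- list()
    for (e in early_mins) {
      sub_e <- subtraction_image(study, select_phase(study, e * 60))
      m_e <- if (refine) refine_mask_histogram(mask, sub_e) else mask
      maps_e <- enhancement_maps(study, early_min = e, late_min = late_min)
      key <- as.character(e)
      etvs[[key]] <- etv(m_e, sp)
      ftv_masks[[key]] <- m_e
      grids[[key]][[tp]] <- ftv_grid(m_e, maps_e, grid, sp)
    }
    sub_late <- subtraction_image(study, select_phase(study, late_min * 60))
    m_late <- if (refine) refine_mask_histogram(mask, sub_late) else mask
    d1 <- mask_to_diameters(ftv_masks[[as.character(early_mins[1])]], sp, 1)
    d7 <- mask_to_diameters(m_late, sp, late_min)
    rows <- rbind(rows, data.frame(
      patient_id = study$patient_id, timepoint = tp,
      ld_1min = longest_dimension(d1), ld_7min = longest_dimension(d7),
      tv_1min = ellipsoid_tv(d1), tv_7min = ellipsoid_tv(d7),
      etv_1min = etvs[["1"]],
      etv_2p5min = if ("2.5" %in% names(etvs)) etvs[["2.5"]] else NA_real_,
      stringsAsFactors = FALSE))
  }
  list(rows = rows, grids = grids)
}

# Internal: uniform patient access over the three input forms. Returns ids,
# labels (1 = pCR), fetch(id) -> list(studies, masks), and exclusion log.
cohort_source <- function(x, refine_source = "manual") {
  if (inherits(x, "synthetic_cohort")) {
    list(ids = names(x$patients), labels = unname(x$labels),
         fetch = function(id) x$patients[[id]][c("studies", "masks")],
         log = character())
  } else if (inherits(x, "cohort_config")) {
    set.seed(x$seed)
    labels <- stats::rbinom(x$n_patients, 1, x$pcr_rate)
    if (min(sum(labels), sum(1 - labels)) < 2L)
      stop("cohort draw produced fewer than 2 patients in one response ",
           "class; increase n_patients or change the seed")
    ids <- sprintf("P%03d", seq_len(x$n_patients))
    # pre-draw each patient's RNG substream seed so streaming generation
    # matches generate_cohort()'s sequential draws patient by patient
    list(ids = ids, labels = labels,
         fetch = local({
           cfg <- x
           function(id) {
             i <- match(id, ids)
             arm <- if (labels[i] == 1L) "pCR" else "non_pCR"
             generate_patient(cfg, arm, id)[c("studies", "masks")]
           }
         }),
         log = character())
  } else if (is.character(x) && length(x) == 1L) {
    tab <- read_cohort_table(x)
    log <- character()
    keep <- logical(nrow(tab))
    for (i in seq_len(nrow(tab))) {
      have <- file.exists(file.path(x, tab$patient_id[i],
                                    paste0(c("BL", "C2", "C4"), ".nii.gz")))
      keep[i] <- all(have)
      if (!keep[i])
        log <- c(log, sprintf(
          "excluded %s: missing timepoint(s) %s", tab$patient_id[i],
          paste(c("BL", "C2", "C4")[!have], collapse = ", ")))
    }
    tab <- tab[keep, , drop = FALSE]
    list(ids = tab$patient_id,
         labels = as.integer(tab$label == "pCR"),
         fetch = function(id) {
           out <- lapply(c(BL = "BL", C2 = "C2", C4 = "C4"), function(tp)
             read_study(file.path(x, id), tp))
           list(studies = lapply(out, `[[`, "study"),
                masks = lapply(out, `[[`, "mask"))
         },
         log = log)
  } else {
    stop("`x` must be a cohort directory, a synthetic_cohort, ",
         "or a cohort_config")
  }
}

# Internal: one report row of group statistics for a vector of per-patient
# scores. y is the positive-class indicator (1 = non-pCR). NA scores are
# dropped pairwise.
stat_row <- function(values, y, measurement, timepoint, pe = NA, ser = NA,
                     log_sink = NULL) {
  ok <- !is.na(values)
  v <- values[ok]; yy <- y[ok]
  n_dropped <- sum(!ok)
  if (length(unique(yy)) < 2L || min(table(yy)) < 2L) {
    return(list(row = data.frame(
      measurement = measurement, timepoint = timepoint,
      pe = pe, ser = ser, auc = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, p_value = NA_real_,
      mean_nonpcr = NA_real_, sd_nonpcr = NA_real_,
      mean_pcr = NA_real_, sd_pcr = NA_real_, cutoff = NA_real_,
      n_nonpcr = sum(yy == 1L), n_pcr = sum(yy == 0L),
      n_dropped = n_dropped, stringsAsFactors = FALSE),
      log = sprintf("%s %s: too few cases per class after drops", measurement,
                    timepoint)))
  }
  dl <- suppressWarnings(auc_ci_delong(v, yy, positive_high = TRUE))
  mw <- mann_whitney(v[yy == 1L], v[yy == 0L])
  list(row = data.frame(
    measurement = measurement, timepoint = timepoint,
    pe = pe, ser = ser,
    auc = dl$auc, ci_low = dl$ci_low, ci_high = dl$ci_high,
    p_value = mw$p_value,
    mean_nonpcr = mean(v[yy == 1L]), sd_nonpcr = stats::sd(v[yy == 1L]),
    mean_pcr = mean(v[yy == 0L]), sd_pcr = stats::sd(v[yy == 0L]),
    cutoff = youden_cutoff(v, yy, positive_high = TRUE),
    n_nonpcr = sum(yy == 1L), n_pcr = sum(yy == 0L),
    n_dropped = n_dropped, stringsAsFactors = FALSE),
    log = if (n_dropped > 0)
      sprintf("%s %s: %d patient(s) dropped (undefined value)",
              measurement, timepoint, n_dropped) else character())
}

#' Run the full cohort analysis
#'
#' Measures every patient at BL, C2, and C4, then builds the two report
#' tables: direct AUC/CI/p/cutoff rows for LD, TV and ETV, and, for FTV,
#' the per-timepoint AUC surface over the PE x SER grid, the optimal
#' threshold pair (minimum-PE-then-SER tie-break), and group statistics of
#' the FTV values at that pair. Relative changes (%C2/BL, %C4/BL) are
#' analyzed the same way, with zero-baseline patients dropped per cell and
#' logged. The positive class throughout is non-pCR (residual disease), with
#' higher values positive; on-treatment volumes and their changes are both
#' larger in non-pCR patients, so reported AUCs follow the >= 0.5
#' convention without flipping.
#'
#' @param x cohort directory path, [generate_cohort()] result, or
#'   [cohort_config()] (generated patient-by-patient without holding the
#'   whole cohort in memory).
#' @param grid a [build_grid()] threshold grid.
#' @param refine refine masks by histogram thresholding (default TRUE).
#' @param early_mins nominal early phases in minutes.
#' @param late_min nominal late phase in minutes.
#' @return object of class `cohort_report`: `table_volumetrics` (LD/TV/ETV
#'   rows), `table_ftv` (FTV rows with optimal PE/SER), `surfaces` (named
#'   list of [auc_surface()]), `ftv_values` (per-patient FTV/change values
#'   at each kind's optimal pair), `measurements` (per-patient rows),
#'   `labels`, `run_log`, `n_analyzed`, `n_excluded`.
#' @export
analyze_cohort <- function(x, grid = build_grid(), refine = TRUE,
                           early_mins = c(1, 2.5), late_min = 7) {
  src <- cohort_source(x)
  run_log <- src$log
  if (length(unique(src$labels)) < 2L)
    stop("single-class cohort: analysis requires both pCR and non-pCR ",
         "patients (got ", sum(src$labels), " pCR of ", length(src$labels), ")")
  ids <- src$ids
  ekeys <- as.character(early_mins)
  meas <- NULL
  grids <- stats::setNames(
    rep(list(stats::setNames(
      rep(list(stats::setNames(vector("list", length(ids)), ids)), 3),
      c("BL", "C2", "C4"))), length(ekeys)), ekeys)
  for (id in ids) {
    p <- src$fetch(id)
    pm <- measure_patient(p$studies, p$masks, grid = grid, refine = refine,
                          early_mins = early_mins, late_min = late_min)
    meas <- rbind(meas, pm$rows)
    for (e in ekeys) for (tp in c("BL", "C2", "C4"))
      grids[[e]][[tp]][[id]] <- pm$grids[[e]][[tp]]
  }
  pcr <- src$labels                 # 1 = pCR
  y <- 1L - pcr                     # positive class for ROC = non-pCR
  val <- function(col, tp) {
    m <- meas[meas$timepoint == tp, ]
    m[[col]][match(ids, m$patient_id)]
  }

  # --- LD / TV / ETV table -------------------------------------------------
  vol_cols <- c(ld_1min = "LD at 1 min", ld_7min = "LD at 7 min",
                tv_1min = "TV at 1 min", tv_7min = "TV at 7 min",
                etv_1min = "ETV at 1 min", etv_2p5min = "ETV at 2.5 min")
  tab_vol <- NULL
  for (col in names(vol_cols)) {
    bl <- val(col, "BL")
    series <- list(BL = bl, C2 = val(col, "C2"), C4 = val(col, "C4"),
                   `%C2/BL` = relative_change(bl, val(col, "C2")),
                   `%C4/BL` = relative_change(bl, val(col, "C4")))
    for (tp in names(series)) {
      sr <- stat_row(series[[tp]], y, vol_cols[[col]], tp)
      tab_vol <- rbind(tab_vol, sr$row)
      run_log <- c(run_log, sr$log)
    }
  }

  # --- FTV table: surface -> optimal pair -> values at the pair ------------
  tab_ftv <- NULL
  surfaces <- list()
  ftv_values <- list()
  value_at <- function(glist, pe, ser) {
    vapply(glist, function(g) g[as.character(pe), as.character(ser)],
           numeric(1))
  }
  for (e in ekeys) {
    elab <- sprintf("FTV at %s min", e)
    kinds <- list(
      BL = grids[[e]]$BL, C2 = grids[[e]]$C2, C4 = grids[[e]]$C4,
      `%C2/BL` = Map(change_grid, grids[[e]]$BL, grids[[e]]$C2),
      `%C4/BL` = Map(change_grid, grids[[e]]$BL, grids[[e]]$C4))
    for (tp in names(kinds)) {
      kind_id <- sprintf("%s_%s", elab, tp)
      surf <- auc_surface(kinds[[tp]], y, positive_high = TRUE,
                          kind = kind_id)
      surfaces[[kind_id]] <- surf
      if (nrow(surf$ties) > 1)
        run_log <- c(run_log, sprintf(
          "%s: %d threshold pairs tied at max AUC %.4f; selected (%g, %.2f)",
          kind_id, nrow(surf$ties), surf$max_auc, surf$optimal_pe,
          surf$optimal_ser))
      vals <- value_at(kinds[[tp]], surf$optimal_pe, surf$optimal_ser)
      ftv_values[[kind_id]] <- vals
      sr <- stat_row(vals, y, elab, tp, pe = surf$optimal_pe,
                     ser = surf$optimal_ser)
      tab_ftv <- rbind(tab_ftv, sr$row)
      run_log <- c(run_log, sr$log)
    }
  }

  structure(
    list(table_volumetrics = tab_vol, table_ftv = tab_ftv,
         surfaces = surfaces, ftv_values = ftv_values,
         measurements = meas,
         labels = stats::setNames(pcr, ids),
         run_log = run_log,
         n_analyzed = length(ids),
         n_excluded = length(src$log)),
    class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d patients analyzed (%d excluded), %d pCR / %d non-pCR\n",
              x$n_analyzed, x$n_excluded, sum(x$labels), sum(1 - x$labels)))
  best <- x$table_ftv[which.max(x$table_ftv$auc), ]
  cat(sprintf("  best FTV AUC %.2f: %s %s at PE %g%%, SER %.2f\n",
              best$auc, best$measurement, best$timepoint, best$pe, best$ser))
  invisible(x)
}

#' Compare C2 and C4 value distributions per measurement kind
#'
#' Two-sided Mann-Whitney test of the C2 values against the C4 values for
#' each measurement kind (LD, TV, ETV per phase, and FTV at each kind's own
#' optimal thresholds), flagged for significance at alpha = 0.05.
#'
#' @param report a [analyze_cohort()] result.
#' @param alpha significance level for the flag.
#' @return data frame with `measurement`, `U`, `p_value`, `significant`.
#' @export
compare_timepoints <- function(report, alpha = 0.05) {
  stopifnot(inherits(report, "cohort_report"))
  meas <- report$measurements
  out <- NULL
  for (col in c("ld_1min", "ld_7min", "tv_1min", "tv_7min",
                "etv_1min", "etv_2p5min")) {
    c2 <- meas[[col]][meas$timepoint == "C2"]
    c4 <- meas[[col]][meas$timepoint == "C4"]
    if (all(is.na(c2)) || all(is.na(c4))) next
    mw <- mann_whitney(c2[!is.na(c2)], c4[!is.na(c4)])
    out <- rbind(out, data.frame(measurement = col, U = mw$U,
                                 p_value = mw$p_value,
                                 stringsAsFactors = FALSE))
  }
  for (e in c("1", "2.5")) {
    k2 <- sprintf("FTV at %s min_C2", e)
    k4 <- sprintf("FTV at %s min_C4", e)
    if (!k2 %in% names(report$ftv_values) ||
        !k4 %in% names(report$ftv_values)) next
    mw <- mann_whitney(report$ftv_values[[k2]], report$ftv_values[[k4]])
    out <- rbind(out, data.frame(measurement = sprintf("ftv_%smin", e),
                                 U = mw$U, p_value = mw$p_value,
                                 stringsAsFactors = FALSE))
  }
  out$significant <- out$p_value < alpha
  out
}

#' Write a cohort report to CSV/JSON files
#'
#' Writes `report_volumetrics.csv`, `report_ftv.csv`, per-patient
#' `measurements.csv`, `surfaces_long.csv` (pe, ser, auc per kind),
#' `optimal_thresholds.json`, and a `run_log.jsonl` of structured log lines.
#'
#' @param report a [analyze_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$table_volumetrics,
                   file.path(dir, "report_volumetrics.csv"), row.names = FALSE)
  utils::write.csv(report$table_ftv,
                   file.path(dir, "report_ftv.csv"), row.names = FALSE)
  utils::write.csv(report$measurements,
                   file.path(dir, "measurements.csv"), row.names = FALSE)
  long <- do.call(rbind, lapply(report$surfaces, surface_to_long))
  utils::write.csv(long, file.path(dir, "surfaces_long.csv"),
                   row.names = FALSE)
  opt <- lapply(report$surfaces, function(s)
    list(kind = s$kind, optimal_pe = s$optimal_pe, optimal_ser = s$optimal_ser,
         max_auc = s$max_auc, n_pcr = s$n_neg, n_nonpcr = s$n_pos,
         n_tied = nrow(s$ties)))
  jsonlite::write_json(opt, file.path(dir, "optimal_thresholds.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(vapply(report$run_log, function(m)
    jsonlite::toJSON(list(msg = m), auto_unbox = TRUE), character(1)),
    file.path(dir, "run_log.jsonl"))
  invisible(dir)
}
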