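# Cohort orchestration: measurement, report structure, exclusions,
# determinism, disk roundtrip, and the C2-vs-C4 comparison.

test_that("a 4-patient zero-noise cohort reproduces hand-computed values", {
  cfg <- tiny_config(n = 4, seed = 8, noise = 0)
  co <- generate_cohort(cfg)
  rep <- analyze_cohort(co, refine = FALSE)
  voxvol <- voxel_volume_cm3(cfg$spacing_mm)

  # ETV per patient-timepoint equals truth count x voxel volume
  for (id in names(co$patients)) {
    m <- rep$measurements[rep$measurements$patient_id == id, ]
    for (tp in c("BL", "C2", "C4"))
      expect_equal(m$etv_1min[m$timepoint == tp],
                   co$patients[[id]]$truth[[tp]]$n_enhancing * voxvol)
  }

  # FTV C4 values at the selected pair; AUC recomputed by pairwise counting
  vals <- rep$ftv_values[["FTV at 1 min_C4"]]
  y <- 1L - unname(co$labels)
  row <- rep$table_ftv[rep$table_ftv$measurement == "FTV at 1 min" &
                         rep$table_ftv$timepoint == "C4", ]
  expect_equal(row$auc, oracle_auc(vals[y == 1], vals[y == 0]))
  # at thresholds (0, 0) every enhancing voxel counts
  g <- co$patients[[1]]
  f00 <- ftv(g$masks$C4, enhancement_maps(g$studies$C4), 0, 0,
             cfg$spacing_mm)
  expect_equal(f00, g$truth$C4$n_enhancing * voxvol)
})

test_that("analysis errors on a single-class cohort", {
  cfg <- tiny_config(n = 5, seed = 12)
  co <- generate_cohort(cfg)
  co$labels[] <- 1L
  expect_error(analyze_cohort(co), "single-class")
})

test_that("invalid voxels never reach the FTV counts end-to-end", {
  cfg <- tiny_config(n = 2, seed = 83, noise = 0)
  set.seed(cfg$seed)
  p <- generate_patient(cfg, "non_pCR", "P1")
  # zero out the pre-contrast signal in part of the tumor: PE undefined there
  study <- p$studies$BL
  vols <- study$volumes
  idx <- which(p$masks$BL$mask, arr.ind = TRUE)
  kill <- idx[seq_len(floor(nrow(idx) / 2)), , drop = FALSE]
  vols[cbind(kill, 1L)] <- 0
  broken <- dce_study(vols, study$phase_times, study$voxel_spacing,
                      study$patient_id, study$timepoint)
  maps <- enhancement_maps(broken)
  expect_false(any(maps$valid[cbind(kill)]))
  f <- ftv(p$masks$BL, maps, 0, 0, cfg$spacing_mm)
  n_valid <- sum(p$masks$BL$mask) - nrow(kill)
  expect_lte(f / voxel_volume_cm3(cfg$spacing_mm), n_valid)
  g <- ftv_grid(p$masks$BL, maps, build_grid(), cfg$spacing_mm)
  expect_lte(max(g) / voxel_volume_cm3(cfg$spacing_mm), n_valid)
})

test_that("reports are deterministic and identical streamed or in memory", {
  cfg <- tiny_config(n = 6, seed = 15)
  r1 <- analyze_cohort(cfg)
  r2 <- analyze_cohort(cfg)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
  r3 <- analyze_cohort(generate_cohort(cfg))
  expect_equal(r1$table_ftv, r3$table_ftv)
  expect_equal(r1$table_volumetrics, r3$table_volumetrics)
  expect_equal(r1$measurements, r3$measurements)
})

test_that("every reported FTV is bounded by the matching ETV", {
  cfg <- tiny_config(n = 8, seed = 25)
  rep <- analyze_cohort(cfg)
  meas <- rep$measurements
  for (e in c("1", "2.5")) {
    etv_col <- if (e == "1") "etv_1min" else "etv_2p5min"
    for (tp in c("BL", "C2", "C4")) {
      vals <- rep$ftv_values[[sprintf("FTV at %s min_%s", e, tp)]]
      etvs <- meas[[etv_col]][meas$timepoint == tp]
      expect_true(all(vals <= etvs + 1e-12))
    }
  }
})

test_that("cohort directories roundtrip and missing timepoints are excluded", {
  cfg <- tiny_config(n = 5, seed = 16)
  co <- generate_cohort(cfg)
  dir <- file.path(tempdir(), "ftvdce-roundtrip")
  unlink(dir, recursive = TRUE)
  write_cohort(co, dir)

  rd <- read_study(file.path(dir, "P001"), "BL")
  expect_equal(rd$study$phase_times, cfg$phase_times_s)
  expect_equal(rd$study$voxel_spacing, cfg$spacing_mm)
  expect_equal(array(rd$study$volumes, dim = dim(rd$study$volumes)),
               array(co$patients$P001$studies$BL$volumes,
                     dim = dim(rd$study$volumes)),
               tolerance = 1e-6)
  expect_equal(rd$mask$mask, co$patients$P001$masks$BL$mask)

  r_disk <- analyze_cohort(dir)
  r_mem <- analyze_cohort(co)
  expect_equal(r_disk$table_ftv$auc, r_mem$table_ftv$auc, tolerance = 1e-6)

  # drop one patient's C4 series -> excluded with a logged reason
  unlink(file.path(dir, "P002", "C4.nii.gz"))
  r_part <- analyze_cohort(dir)
  expect_equal(r_part$n_excluded, 1)
  expect_equal(r_part$n_analyzed, 4)
  expect_true(any(grepl("P002", r_part$run_log)))
  expect_equal(r_part$n_analyzed + r_part$n_excluded, cfg$n_patients)
  unlink(dir, recursive = TRUE)
})

test_that("report files are written in the declared formats", {
  cfg <- tiny_config(n = 6, seed = 17)
  rep <- analyze_cohort(cfg)
  out <- file.path(tempdir(), "ftvdce-report")
  unlink(out, recursive = TRUE)
  write_report(rep, out)
  expect_true(all(file.exists(file.path(out, c(
    "report_volumetrics.csv", "report_ftv.csv", "measurements.csv",
    "surfaces_long.csv", "optimal_thresholds.json", "run_log.jsonl")))))
  long <- utils::read.csv(file.path(out, "surfaces_long.csv"))
  expect_equal(nrow(long), 10 * 1845)   # 2 early phases x 5 kinds x grid
  opt <- jsonlite::read_json(file.path(out, "optimal_thresholds.json"))
  expect_length(opt, 10)
  unlink(out, recursive = TRUE)
})

test_that("C2-vs-C4 comparison covers each measurement kind", {
  cfg <- tiny_config(n = 8, seed = 18)
  rep <- analyze_cohort(cfg)
  cmp <- compare_timepoints(rep)
  expect_setequal(cmp$measurement,
                  c("ld_1min", "ld_7min", "tv_1min", "tv_7min",
                    "etv_1min", "etv_2p5min", "ftv_1min", "ftv_2.5min"))
  expect_true(all(cmp$p_value > 0 & cmp$p_value <= 1))

  # identical C2 and C4 distributions -> p = 1
  fake <- rep
  m <- fake$measurements
  m[m$timepoint == "C4", 3:8] <- m[m$timepoint == "C2", 3:8]
  fake$measurements <- m
  fake$ftv_values[["FTV at 1 min_C4"]] <- fake$ftv_values[["FTV at 1 min_C2"]]
  fake$ftv_values[["FTV at 2.5 min_C4"]] <- fake$ftv_values[["FTV at 2.5 min_C2"]]
  cmp2 <- compare_timepoints(fake)
  expect_true(all(cmp2$p_value[cmp2$measurement %in%
                                 c("ld_1min", "ftv_1min")] == 1))
})
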