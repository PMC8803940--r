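#' End-to-end desk-scale demonstration run
#'
#' Exercises the whole pipeline on synthetic data: generates training
#' phantoms, trains the cropping and segmentation networks, simulates a
#' head-motion study (CONV / 5-nod / 10-nod conditions with graded
#' HM1/HM2/HM3 quality tiers), predicts masks for every record with the
#' trained pipeline and with a nearest-tissue-mean baseline, runs the
#' head-motion pairing design, aggregates per-region metrics, and compares
#' the two methods with Wilcoxon / Mann-Whitney tests under
#' Benjamini-Hochberg correction.  Every stochastic component derives its
#' seed from \code{seed}, so two runs with the same seed produce identical
#' result tables.
#'
#' @param out_dir writable output directory.
#' @param seed run seed.
#' @param n_subjects study subjects (default 8).
#' @param n_train,n_val training/validation phantoms for both networks.
#' @param geometry a \code{\link{pipeline_geometry}} (default desk scale).
#' @param crop_cfg,seg_cfg training configurations; demo-sized defaults.
#' @param verbose print training progress.
#' @return invisibly, a list with the result tables
#'   (\code{region_metrics}, \code{summary}, \code{stats}), the evaluation
#'   \code{roster}, the trained \code{models} and the output \code{paths}.
#' @export
run_demo <- function(out_dir, seed = 1, n_subjects = 8, n_train = 8,
                     n_val = 2, geometry = desk_geometry(),
                     crop_cfg = crop_train_config(batch_size = 4,
                                                  max_epochs = 60,
                                                  patience = 20),
                     seg_cfg = seg_train_config(max_epochs = 3,
                                                subvols_per_pair = 14),
                     verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scheme <- default_scheme()
  stages <- list()

  run_stage <- function(name, expr) {
    if (verbose) message("[demo] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("demo stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- training phantoms ----------------------------------------------------
  models <- run_stage("train", {
    mk_pair <- function(i) {
      ph <- generate_phantom(phantom_spec(shape = geometry$input_shape,
                                          seed = derive_seed(seed, "train", i)),
                             scheme)
      vol <- normalize_intensity(ph$volume)
      box <- bbox_target(ph$mask)
      fixed <- finalize_bbox(c(box$start, box$lengths) * geometry$downsample,
                             geometry, vol_shape = dim(vol$data))
      list(volume = vol, box = box,
           cropped = list(volume = crop(vol, fixed),
                          mask = crop(ph$mask, fixed)))
    }
    all_pairs <- lapply(seq_len(n_train + n_val), mk_pair)
    tr <- all_pairs[seq_len(n_train)]
    va <- all_pairs[n_train + seq_len(n_val)]
    crop_model <- train_cropnet(tr, crop_cfg, va, geometry,
                                seed = derive_seed(seed, "cropnet"),
                                verbose = verbose)
    seg_model <- train_segnet(lapply(tr, `[[`, "cropped"), seg_cfg,
                              lapply(va, `[[`, "cropped"), geometry,
                              seed = derive_seed(seed, "segnet"),
                              verbose = verbose)
    baseline <- nearest_mean_model(lapply(tr, `[[`, "cropped"), geometry)
    list(crop = crop_model, seg = seg_model, baseline = baseline)
  })

  # -- synthetic head-motion study ------------------------------------------
  study <- run_stage("simulate", {
    generate_study(n_subjects, derive_seed(seed, "study"),
                   file.path(out_dir, "study"),
                   shape = geometry$input_shape)
  })

  # -- segmentation of every record by both methods -------------------------
  roster <- run_stage("predict", {
    mask_dir <- file.path(out_dir, "masks")
    dir.create(mask_dir, showWarnings = FALSE)
    rows <- list()
    for (i in seq_len(nrow(study))) {
      vol <- read_nifti(study$volume[i])
      for (method in c("cnn", "nearest_mean")) {
        seg <- if (method == "cnn") models$seg else models$baseline
        pred <- predict_mask(vol, models$crop, seg, geometry = geometry)
        path <- file.path(mask_dir, sprintf("%s_%s_%s.nii.gz", method,
                                            study$subject[i],
                                            study$condition[i]))
        write_nifti(pred, path)
        rows[[length(rows) + 1]] <- data.frame(
          subject = study$subject[i], method = method,
          condition = study$condition[i], session = study$session[i],
          tier = study$tier[i], mask = path, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  # -- reliability evaluation and statistics --------------------------------
  results <- run_stage("evaluate", {
    prs <- build_pairs(roster, "head_motion")
    rm <- evaluate_pairs(prs, scheme)
    sm <- aggregate_metrics(rm)
    st <- list()
    for (metric in c("dsc", "iou", "hd_mm", "vd"))
      for (mr in unique(sm$macro_region))
        for (pt in unique(sm$pairing_type)) {
          row <- tryCatch(
            compare_methods(sm, "cnn", "nearest_mean", metric, mr, pt),
            error = function(e) NULL)
          if (!is.null(row)) st[[length(st) + 1]] <- row
        }
    st <- if (length(st) > 0) bh_adjust(do.call(rbind, st)) else
      data.frame()
    list(region_metrics = rm, summary = sm, stats = st)
  })

  paths <- list(region_metrics = file.path(out_dir, "region_metrics.csv"),
                summary = file.path(out_dir, "summary.csv"),
                stats = file.path(out_dir, "stats.csv"),
                config = file.path(out_dir, "run_config.yaml"))
  utils::write.csv(results$region_metrics, paths$region_metrics,
                   row.names = FALSE)
  utils::write.csv(results$summary, paths$summary, row.names = FALSE)
  utils::write.csv(results$stats, paths$stats, row.names = FALSE)
  yaml::write_yaml(list(
    seed = seed, n_subjects = n_subjects, n_train = n_train, n_val = n_val,
    geometry = list(input_shape = geometry$input_shape,
                    crop_lengths = geometry$crop_lengths,
                    sub_shape = geometry$sub_shape, step = geometry$step,
                    downsample = geometry$downsample),
    crop_cfg = unclass(crop_cfg), seg_cfg = list(
      lr = seg_cfg$lr, batch_size = seg_cfg$batch_size,
      patience = seg_cfg$patience, max_epochs = seg_cfg$max_epochs,
      subvols_per_pair = seg_cfg$subvols_per_pair)), paths$config)

  invisible(list(region_metrics = results$region_metrics,
                 summary = results$summary, stats = results$stats,
                 roster = roster, study = study, models = models,
                 paths = paths))
}
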