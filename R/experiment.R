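# Leave-one-out experiment orchestration: one experiment instance per
# subject, each training fresh networks on the remaining subjects and
# predicting the held-out subject's synthetic CT.

#' Leave-one-out splits
#'
#' One split per subject, ordered by subject id: the held-out subject and
#' the pre-augmentation training slice pool drawn from all other
#' subjects. On a cohort shaped like the reference one (subjects 1, 2, 3,
#' 5 with 50 slices, the rest 44; 508 total) this reproduces the
#' published split sizes: four instances with (458 training, 50 test)
#' slices and seven with (464, 44).
#'
#' @param cases list of [paired_case()] (>= 2).
#' @return tibble with `held_out_id`, `train_ids` (list column),
#'   `n_train_slices`, `n_test_slices`.
#' @export
loo_splits <- function(cases) {
  if (length(cases) < 2L)
    stop("leave-one-out needs at least 2 cases")
  ids <- vapply(cases, `[[`, "", "subject_id")
  if (anyDuplicated(ids)) stop("subject identifiers must be unique")
  slices <- vapply(cases, function(k) dim(k$ct$data)[3], 0L)
  ord <- order(ids)
  ids <- ids[ord]; slices <- slices[ord]
  total <- sum(slices)
  tibble::tibble(
    held_out_id = ids,
    train_ids = lapply(seq_along(ids), function(i) ids[-i]),
    n_train_slices = total - slices,
    n_test_slices = slices)
}

#' Run the leave-one-out experiment
#'
#' For every split: freshly He-initialised generator and discriminator
#' (seed = base seed + split index, recorded in the manifest), training on
#' the split's slice pool with flip augmentation, prediction of the
#' held-out subject's synthetic CT, per-contour evaluation, and
#' persistence of checkpoint, prediction and report. A failing split is
#' recorded in the manifest and the experiment continues. Finally the
#' cohort summary (mean and SD per metric and region) is written.
#'
#' @param cohort list of [paired_case()].
#' @param config a [train_config()].
#' @param out_dir output directory (created if missing).
#' @param gen_spec generator architecture, see [generator_spec()].
#' @param disc_spec discriminator architecture, see [discriminator_spec()].
#' @param predict_dropout keep dropout active at prediction.
#' @return the experiment manifest: a list with the config snapshot, one
#'   entry per split (seeds, artifact paths, status) and the summary
#'   table.
#' @export
run_loo_experiment <- function(cohort, config = train_config(),
                               out_dir = tempfile("loo"),
                               gen_spec = generator_spec(),
                               disc_spec = discriminator_spec(),
                               predict_dropout = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  splits <- loo_splits(cohort)
  ids <- vapply(cohort, `[[`, "", "subject_id")
  entries <- list()
  reports <- list()
  for (i in seq_len(nrow(splits))) {
    held <- splits$held_out_id[i]
    split_seed <- config$seed + i
    entry <- list(held_out_id = held, seed = split_seed,
                  n_train_slices = splits$n_train_slices[i],
                  n_train_slices_augmented = splits$n_train_slices[i] *
                    (1L + config$augment_flip),
                  n_test_slices = splits$n_test_slices[i])
    res <- tryCatch({
      gen <- he_initialize(build_generator_for(gen_spec), split_seed)
      disc <- he_initialize(build_discriminator(disc_spec), split_seed + 1000L)
      split_config <- config
      split_config$seed <- split_seed
      train_cases <- cohort[ids != held]
      fit <- train(gen, disc, train_cases, split_config)
      held_case <- cohort[ids == held][[1]]
      sct <- predict_volume(fit$generator, held_case$mr, config$ct_scale,
                            use_dropout = predict_dropout, seed = split_seed)
      rep <- contour_metrics(held_case, sct)
      ck <- file.path(out_dir, sprintf("checkpoint_%s.rds", held))
      save_checkpoint(fit$generator, ck)
      sp <- file.path(out_dir, sprintf("sct_%s.nii.gz", held))
      write_volume(sct, sp)
      rp <- file.path(out_dir, sprintf("report_%s.csv", held))
      utils::write.csv(rep, rp, row.names = FALSE)
      hp <- file.path(out_dir, sprintf("history_%s.csv", held))
      utils::write.csv(fit$history, hp, row.names = FALSE)
      list(status = "ok", checkpoint = ck, sct = sp, report = rp,
           history = hp, metrics = rep)
    }, error = function(e) list(status = "failed", error = conditionMessage(e)))
    entry <- c(entry, res[setdiff(names(res), "metrics")])
    entries[[held]] <- entry
    if (identical(res$status, "ok")) reports[[held]] <- res$metrics
  }
  summary_tbl <- if (length(reports)) summarize_cohort(do.call(rbind, reports))
                 else NULL
  if (!is.null(summary_tbl))
    utils::write.csv(summary_tbl, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  manifest <- list(config = unclass_config(config), splits = entries,
                   out_dir = out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  list(manifest = manifest, reports = reports, summary = summary_tbl)
}

build_generator_for <- function(spec) {
  if (spec$depth == 2L) build_sunet_generator(spec) else build_unet3_generator(spec)
}

unclass_config <- function(config) {
  x <- unclass(config)
  x$ct_scale <- unclass(x$ct_scale)
  x
}
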