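# End-to-end orchestration: simulate -> track -> extract -> train ->
# evaluate -> enrich. One structured JSON config drives everything; each
# stage consumes only the on-disk artifacts of the previous stage, so any
# stage can be rerun independently with identical results.

#' Pipeline configuration
#'
#' Plain nested list (JSON-serialisable, exact round trip) with every
#' threshold of the analysis protocol explicit: hull-ratio filter 1.1,
#' 3-SD radius filter, 70/15/15 split. All randomness derives from the
#' single root `seed`.
#'
#' @param n_per_phenotype Cells per phenotype to simulate.
#' @param phenotypes Phenotype config tibble (default
#'   [default_phenotypes()]).
#' @param geometry,acquisition Parameter lists overriding
#'   [channel_geometry()] / [acquisition_config()] defaults.
#' @param artifacts List: `impossible_fraction`, `concave_fraction`.
#' @param tracking List: `max_displacement` (um), `x_entry_threshold`.
#' @param filters List: `hull_threshold`, `radius_sd_limit`.
#' @param split List: `ratios`, `seed` (defaults to root seed).
#' @param models List: `pair` (two phenotype names), `tabular`
#'   ("random_forest" or "svm"), `extended_moments` (logical), `gru` (list
#'   with `enabled`, `units`, `epochs`, ...).
#' @param enrichment_rarity Target prior for the enrichment stage.
#' @param compression_ratio Compressive response ratio of the simulator.
#' @param seed Root seed.
#' @return A `dc_pipeline_config` (plain list).
#' @export
pipeline_config <- function(n_per_phenotype = 40,
                            phenotypes = default_phenotypes(),
                            geometry = list(),
                            acquisition = list(),
                            artifacts = list(impossible_fraction = 0.05,
                                             concave_fraction = 0.05),
                            tracking = list(max_displacement = 16,
                                            x_entry_threshold = 0),
                            filters = list(hull_threshold = 1.1,
                                           radius_sd_limit = 3),
                            split = list(ratios = c(0.70, 0.15, 0.15),
                                         seed = NULL),
                            models = list(pair = c("hl60", "hl60d"),
                                          tabular = "random_forest",
                                          extended_moments = FALSE,
                                          gru = list(enabled = FALSE,
                                                     units = 16,
                                                     epochs = 30)),
                            enrichment_rarity = 0.001,
                            compression_ratio = 0.06,
                            seed = 1) {
  cfg <- list(
    n_per_phenotype = n_per_phenotype,
    phenotypes = lapply(seq_len(nrow(phenotypes)),
                        function(i) as.list(phenotypes[i, ])),
    geometry = geometry,
    acquisition = acquisition,
    artifacts = utils::modifyList(list(impossible_fraction = 0.05,
                                       concave_fraction = 0.05), artifacts),
    tracking = utils::modifyList(list(max_displacement = 16,
                                      x_entry_threshold = 0), tracking),
    filters = utils::modifyList(list(hull_threshold = 1.1,
                                     radius_sd_limit = 3), filters),
    split = utils::modifyList(list(ratios = c(0.70, 0.15, 0.15), seed = NULL),
                              split),
    models = utils::modifyList(list(pair = c("hl60", "hl60d"),
                                    tabular = "random_forest",
                                    extended_moments = FALSE,
                                    gru = list(enabled = FALSE, units = 16,
                                               epochs = 30)),
                               models),
    enrichment_rarity = enrichment_rarity,
    compression_ratio = compression_ratio,
    seed = as.integer(seed)
  )
  if (is.null(cfg$split$seed)) cfg$split$seed <- cfg$seed
  structure(cfg, class = c("dc_pipeline_config", "list"))
}

#' Write / read a pipeline config (JSON)
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `read_pipeline_config` returns the config; `write_pipeline_config`
#'   its path, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  structure(cfg, class = c("dc_pipeline_config", "list"))
}

config_phenotypes <- function(config) {
  dplyr::bind_rows(lapply(config$phenotypes, tibble::as_tibble))
}

config_geometry <- function(config) {
  do.call(channel_geometry, config$geometry)
}

config_acquisition <- function(config) {
  do.call(acquisition_config, config$acquisition)
}

config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small stable polynomial hash; enough to stamp artifacts with their config
  bytes <- utf8ToInt(json)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> track -> extract -> train -> evaluate -> enrich,
#' writing every artifact under `out_dir`: masks (multi-page TIFF),
#' trajectories (JSON-lines), features (CSV), reports (JSON), enrichment
#' curve (CSV). Re-running with the same config and seed reproduces the
#' tabular outputs byte for byte. Stage failures abort with the failing
#' stage named.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the key in-memory results (dataset,
#'   trajectories, features, model, reports, enrichment) and `paths`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "dc_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  geom <- config_geometry(config)
  acq <- config_acquisition(config)
  write_pipeline_config(config, file.path(out_dir, "config.json"))
  writeLines(c(sprintf("config_hash: %s", hash),
               sprintf("seed: %d", config$seed)),
             file.path(out_dir, "run_stamp.txt"))

  # -- simulate ---------------------------------------------------------
  dataset <- run_stage("simulate", {
    pop <- sample_population(config_phenotypes(config),
                             config$n_per_phenotype, config$seed, acq)
    ds <- generate_dataset(pop, geom, acq,
                           artifact_config(config$artifacts$impossible_fraction,
                                           config$artifacts$concave_fraction),
                           compression_ratio = config$compression_ratio,
                           seed = config$seed)
    write_dataset(ds, out_dir)
    stage_log("simulate", "%d cells (%d artifacts), %d detections, %d frames",
              nrow(ds$cells), sum(ds$cells$is_artifact), nrow(ds$detections),
              length(unique(ds$detections$frame)))
    ds
  })

  # -- track (from the on-disk stack) ------------------------------------
  trackres <- run_stage("track", {
    pages <- read_mask_stack(file.path(out_dir, "masks.tif"))
    fmap <- readr::read_csv(file.path(out_dir, "frames.csv"),
                            show_col_types = FALSE)
    det <- detect_cells(pages, fmap$frame, acq)
    tracked <- link_detections(det, config$tracking$max_displacement)
    val <- validate_trajectories(tracked, geom,
                                 config$tracking$x_entry_threshold)
    write_jsonl(dplyr::select(tracked, -"mask"),
                file.path(out_dir, "trajectories.jsonl"))
    readr::write_csv(val, file.path(out_dir, "track_validation.csv"))
    stage_log("track", "%d detections -> %d tracks (%d kept, %d impossible start, %d incomplete)",
              nrow(det), nrow(val), sum(val$keep),
              sum(val$reason == "impossible start", na.rm = TRUE),
              sum(val$reason == "incomplete span", na.rm = TRUE))
    list(tracked = tracked, validation = val)
  })

  # -- extract -----------------------------------------------------------
  extractres <- run_stage("extract", {
    keep_ids <- trackres$validation$track_id[trackres$validation$keep]
    trajs <- split(trackres$tracked, trackres$tracked$track_id)[keep_ids]
    # attach ground-truth phenotype by matching truth positions
    truth <- read_jsonl(file.path(out_dir, "truth.jsonl"))
    cells <- readr::read_csv(file.path(out_dir, "cells.csv"),
                             show_col_types = FALSE)
    trajs <- purrr::map(trajs, function(tr) {
      key <- dplyr::inner_join(tr, truth, by = "frame",
                               suffix = c("", "_true"))
      key <- key[abs(key$x - key$x_true) < 3, , drop = FALSE]
      if (nrow(key)) {
        major <- names(which.max(table(key$cell_id)))
        tr$cell_id <- major
        tr$phenotype <- cells$phenotype[match(major, cells$cell_id)]
      }
      tr
    })
    filt <- apply_filters(trajs, config$filters$hull_threshold,
                          config$filters$radius_sd_limit, acq)
    if (length(filt$kept) == 0) {
      warning("all trajectories filtered out; empty feature table",
              call. = FALSE)
    }
    feats <- derive_features(filt$kept, geom, acq,
                             extended = isTRUE(config$models$extended_moments))
    readr::write_csv(feats, file.path(out_dir, "features.csv"))
    readr::write_csv(filt$discarded, file.path(out_dir, "filtered_events.csv"))
    seqs <- prepare_sequences(filt$kept, geom, acq)
    saveRDS(seqs, file.path(out_dir, "sequences.rds"))
    stage_log("extract", "%d trajectories in, %d kept (%s), %d features each",
              length(trajs), length(filt$kept),
              if (nrow(filt$discarded)) {
                paste(sprintf("%d %s", filt$counts$n, filt$counts$reason),
                      collapse = ", ")
              } else "none discarded",
              ncol(feats) - 3)
    list(features = feats, sequences = seqs, filtered = filt$discarded)
  })

  # -- train -------------------------------------------------------------
  trainres <- run_stage("train", {
    feats <- readr::read_csv(file.path(out_dir, "features.csv"),
                             show_col_types = FALSE)
    pair <- config$models$pair
    sub <- dplyr::filter(feats, .data$phenotype %in% pair, !.data$degenerate)
    if (nrow(sub) < 20) stop("too few usable trajectories for training")
    fcols <- setdiff(names(sub), c("id", "phenotype", "degenerate"))
    spec <- split_spec(config$split$ratios, config$split$seed)
    kind <- if (identical(config$models$tabular, "svm")) "svm" else "random_forest"
    model <- train_tabular(sub[fcols], factor(sub$phenotype, levels = pair),
                           kind, spec = spec, seed = config$seed)
    saveRDS(model, file.path(out_dir, "model.rds"))
    gru_model <- NULL
    if (isTRUE(config$models$gru$enabled)) {
      seqs <- readRDS(file.path(out_dir, "sequences.rds"))
      sel <- which(seqs$phenotype %in% pair)
      gru_model <- train_gru(subset_samples(seqs, sel),
                             factor(seqs$phenotype[sel], levels = pair),
                             units = config$models$gru$units %||% 16,
                             epochs = config$models$gru$epochs %||% 30,
                             spec = spec, seed = config$seed)
      saveRDS(gru_model, file.path(out_dir, "gru_model.rds"))
    }
    stage_log("train", "%s on %d samples (train %d / val %d / test %d)",
              kind, nrow(sub), length(model$split$train),
              length(model$split$val), length(model$split$test))
    list(model = model, gru = gru_model)
  })

  # -- evaluate ----------------------------------------------------------
  reports <- run_stage("evaluate", {
    model <- readRDS(file.path(out_dir, "model.rds"))
    rep <- list(tabular = report_to_list(model$report, model$kind))
    if (file.exists(file.path(out_dir, "gru_model.rds"))) {
      g <- readRDS(file.path(out_dir, "gru_model.rds"))
      rep$gru <- report_to_list(g$report, "gru")
    }
    jsonlite::write_json(rep, file.path(out_dir, "reports.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stage_log("evaluate", "test accuracy: %s",
              paste(sprintf("%s %.3f", names(rep),
                            vapply(rep, `[[`, numeric(1), "accuracy")),
                    collapse = ", "))
    rep
  })

  # -- enrich ------------------------------------------------------------
  enrichres <- run_stage("enrich", {
    rep <- jsonlite::fromJSON(file.path(out_dir, "reports.json"),
                              simplifyDataFrame = FALSE)
    best <- rep[[length(rep)]]
    pos <- config$models$pair[2]
    point <- enrichment(best$tpr[[pos]],
                        best$fpr[[pos]],
                        config$enrichment_rarity)
    curve <- enrichment_curve(best$tpr[[pos]], config$enrichment_rarity)
    readr::write_csv(curve, file.path(out_dir, "enrichment_curve.csv"))
    jsonlite::write_json(as.list(point), file.path(out_dir, "enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
    stage_log("enrich", "%.1f-fold at rarity %.4g (tpr %.3f, fpr %.3f)",
              point$enrichment, config$enrichment_rarity, point$tpr, point$fpr)
    point
  })

  invisible(list(dataset = dataset, tracking = trackres,
                 features = extractres$features,
                 sequences = extractres$sequences,
                 model = trainres$model, gru = trainres$gru,
                 reports = reports, enrichment = enrichres,
                 config_hash = hash, out_dir = out_dir))
}

report_to_list <- function(report, kind) {
  list(kind = kind, accuracy = report$accuracy,
       confusion = apply(report$confusion, 1, as.list),
       tpr = as.list(report$tpr), fpr = as.list(report$fpr),
       classes = report$classes, n = report$n)
}
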