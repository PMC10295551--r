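#' Default pipeline configuration
#'
#' Nested configuration for [run_pipeline()], with one section per stage
#' (`synth`, `preprocess`, `balance`, `model`, `train`) plus a global
#' `seed` that propagates to every stage unless a stage overrides it, and
#' an `augment` section controlling whether expansion happens before or
#' after splitting.
#'
#' @param ... Named overrides merged (recursively) over the defaults, e.g.
#'   `synth = list(n_per_grade = 20)`.
#' @param seed Global seed.
#' @return A nested configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., seed = 1) {
  base <- list(
    seed = seed,
    synth = list(n_per_grade = 20),
    preprocess = list(enabled = TRUE),
    balance = list(cap_mode = "explicit", explicit_cap = 2384),
    augment = list(enabled = TRUE, scope = "all"),  # "all" or "train_only"
    model = list(),
    train = list(epochs = 10, batch_size = 64)
  )
  user <- list(...)
  cfg <- utils::modifyList(base, user)
  structure(cfg, class = c("pipeline_config", "list"))
}

read_pipeline_config <- function(x) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  if (!inherits(x, "pipeline_config")) x <- do.call(pipeline_config, x)
  x
}

#' Run the full pipeline
#'
#' Chains every stage on a synthetic dataset: generation, preprocessing,
#' under-sampling, augmentation expansion, stratified splitting, training,
#' and evaluation. Writes per-stage manifests, the epoch history, the test
#' metrics, and a machine-readable run record containing every resolved
#' configuration value and the model's trainable-parameter count.
#'
#' @param config A [pipeline_config()], a nested list of overrides, or a
#'   path to a YAML file of such overrides.
#' @param out_dir Run directory to write into (created; default a fresh
#'   temporary directory).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the fitted model, manifests, metrics and
#'   the run record.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("dr_run_"),
                         verbose = FALSE) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) cat(sprintf(...), "\n")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage [%s] failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  say("stage synth")
  scfg <- do.call(synth_config,
                  utils::modifyList(list(seed = cfg$seed),
                                    cfg$synth[setdiff(names(cfg$synth), "n_per_grade")]))
  ds <- stage("synth", generate_fundus_dataset(cfg$synth$n_per_grade, scfg))
  manifest <- ds$manifest
  images <- ds$images
  write_manifest(manifest, file.path(out_dir, "manifest_raw.csv"))

  model <- do.call(cct_config, cfg$model)

  if (isTRUE(cfg$preprocess$enabled)) {
    say("stage preprocess (%d images)", length(images))
    pcfg <- do.call(preprocess_config,
                    cfg$preprocess[setdiff(names(cfg$preprocess), "enabled")])
    images <- stage("preprocess", lapply(images, function(im)
      raster_resize(preprocess_image(im, pcfg), model$image_size,
                    model$image_size)))
  }

  say("stage balance")
  bcfg <- do.call(balance_config,
                  utils::modifyList(list(rng_seed = cfg$seed), cfg$balance))
  manifest <- stage("balance", undersample(manifest, bcfg))
  write_manifest(manifest, file.path(out_dir, "manifest_balanced.csv"))

  tcfg <- do.call(train_control,
                  utils::modifyList(list(rng_seed = cfg$seed), cfg$train))

  if (isTRUE(cfg$augment$enabled) && identical(cfg$augment$scope, "train_only"))
    manifest <- split_manifest(manifest, tcfg)

  if (isTRUE(cfg$augment$enabled)) {
    say("stage augment")
    sel <- if (identical(cfg$augment$scope, "train_only"))
      manifest$split == "train" else rep(TRUE, nrow(manifest))
    kept <- manifest[!sel, , drop = FALSE]
    expanded <- stage("augment", expand_manifest(manifest[sel, , drop = FALSE]))
    images <- stage("augment",
                    c(images[kept$image_ref],
                      expand_images(images[manifest$image_ref[sel]])))
    manifest <- rbind(kept, expanded)
    class(manifest) <- c("dr_manifest", "data.frame")
    write_manifest(manifest, file.path(out_dir, "manifest_augmented.csv"))
  }

  if (all(manifest$split == "unassigned"))
    manifest <- split_manifest(manifest, tcfg)
  write_manifest(manifest, file.path(out_dir, "manifest_split.csv"))

  say("stage train")
  res <- stage("train", train_cct(manifest, images, model, tcfg,
                                  verbose = verbose))
  utils::write.csv(res$fit$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  if (!is.null(res$confusion))
    utils::write.csv(as.data.frame(unclass(res$confusion)),
                     file.path(out_dir, "confusion.csv"))

  record <- list(
    seed = cfg$seed,
    synth = unclass(scfg),
    balance = unclass(bcfg),
    model = unclass(model),
    train = unclass(tcfg),
    n_params = count_parameters(model),
    class_counts = as.list(class_counts(manifest))
  )
  jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(res$metrics))
    jsonlite::write_json(as.list(unclass(res$metrics)),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)

  invisible(list(out_dir = out_dir, fit = res$fit, manifest = manifest,
                 confusion = res$confusion, metrics = res$metrics,
                 record = record))
}
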