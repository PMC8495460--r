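# End-to-end clearance pipeline: per-animal stack processing, per-group
# characteristic-curve extraction, AUC readout, group comparison, and the
# file-based runner with config/manifest handling.

STAGE_ORDER <- c("register", "ztransform", "downsample", "mask_and_crop",
                 "change_rates", "cluster", "assign", "filter",
                 "weighted_average", "auc", "compare")

#' Pipeline configuration
#'
#' Bundles every tunable stage parameter plus the seed. The processing order
#' itself is fixed (register, z-transform, down-sample, crop, change rates,
#' cluster, assign, filter, weighted average, AUC, compare) and cannot be
#' permuted through the configuration. The configuration round-trips
#' losslessly through JSON.
#'
#' @param k number of characteristic curves per group.
#' @param downsample_factor temporal block-averaging factor.
#' @param linear_start_frame 1-based down-sampled frame where the linear tail
#'   starts.
#' @param reference_index registration reference frame (1-based).
#' @param upsample registration correlation upsampling factor.
#' @param nstart k-means restarts.
#' @param seed integer seed; required, so that every stochastic stage is
#'   explicitly seeded.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 4L, downsample_factor = 4L,
                            linear_start_frame = 8L, reference_index = 1L,
                            upsample = 20, nstart = 10L, seed) {
  assert_that(!missing(seed) && is.numeric(seed) && is.finite(seed),
              "an explicit integer `seed` is required")
  cfg <- list(k = as.integer(k),
              downsample_factor = as.integer(downsample_factor),
              linear_start_frame = as.integer(linear_start_frame),
              reference_index = as.integer(reference_index),
              upsample = as.numeric(upsample),
              nstart = as.integer(nstart),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$stage_order) &&
      !identical(as.character(raw$stage_order), STAGE_ORDER)) {
    stop_hepaclear("the processing stage order is fixed and cannot be changed via configuration",
                   "hepaclear_invalid_input")
  }
  raw$stage_order <- NULL
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
config_hash <- function(cfg) {
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- as.integer(charToRaw(as.character(js)))
  # FNV-1a, 32-bit, carried out in double precision
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^31 * (h %% 2^32 >= 2^31)), b)
    h <- (as.numeric(h) %% 2^32) * 16777619 %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Process one animal's stacks into change-rate vectors
#'
#' Runs the fixed per-animal stage order: estimate transforms on the anatomy
#' channel, apply them to the contrast channel, z-transform against the
#' first frame, down-sample in time, crop/zero to the ROI, and export
#' per-pixel change rates.
#'
#' @param icg contrast-channel [dynamic_stack()].
#' @param anatomy anatomy-channel [dynamic_stack()] used for registration;
#'   `NULL` skips motion correction (e.g. for motion-free simulations).
#' @param roi logical in-contour mask.
#' @param config a [pipeline_config()].
#' @return A list: `change_rates` (a `change_rate_matrix`), `transforms`
#'   (the estimated [transform_series()] or `NULL`), `zstack` (the processed
#'   `zstack`).
#' @export
process_animal_stack <- function(icg, anatomy, roi, config) {
  stopifnot(inherits(config, "pipeline_config"))
  series <- NULL
  if (!is.null(anatomy)) {
    series <- estimate_transforms(anatomy, config$reference_index,
                                  config$upsample)
    icg <- apply_transforms(icg, series)
  }
  z <- ztransform(icg, roi)
  z <- downsample_time(z, config$downsample_factor)
  z <- mask_and_crop(z)
  list(change_rates = change_rates(z), transforms = series, zstack = z)
}

#' Run the full clearance pipeline on in-memory cohorts
#'
#' Characteristic curves are fitted per treatment group on the pooled pixels
#' of all the group's animals, then applied per animal — the two-level design
#' of the analysis. Animals whose retained-curve abundance is empty are
#' flagged undefined (AUC `NA`) and the group analysis proceeds without them.
#'
#' @param animals list of per-animal records, each a list with fields
#'   `animal_id`, `group`, `icg` ([dynamic_stack()]), `anatomy`
#'   ([dynamic_stack()] or `NULL`), `roi` (logical mask).
#' @param config a [pipeline_config()].
#' @param compare run the group comparison (requires >= 2 groups of >= 2).
#' @return An object of class `clearance_run`: `results` (data frame
#'   `animal_id`, `group`, `auc`, `undefined`), `curves` (per-group
#'   `characteristic_curves`), `weighted_curves`, `abundances`,
#'   `comparison` (a `group_comparison` or `NULL`), `config`.
#' @export
run_clearance <- function(animals, config, compare = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  ids <- vapply(animals, function(a) a$animal_id, character(1L))
  assert_that(!anyDuplicated(ids), "animal_ids must be unique")
  groups <- vapply(animals, function(a) a$group, character(1L))

  processed <- vector("list", length(animals))
  for (i in seq_along(animals)) {
    a <- animals[[i]]
    processed[[i]] <- tryCatch(
      process_animal_stack(a$icg, a$anatomy, a$roi, config),
      error = function(e) stop_hepaclear(
        sprintf("stage failure for animal '%s': %s", a$animal_id,
                conditionMessage(e)),
        "hepaclear_stage_failure")
    )
  }

  curve_sets <- list()
  for (g in unique(groups)) {
    pooled <- lapply(processed[groups == g], `[[`, "change_rates")
    curve_sets[[g]] <- extract_characteristic_curves(
      pooled, k = config$k, seed = config$seed, nstart = config$nstart,
      group_label = g)
  }

  weighted_curves <- setNames(vector("list", length(animals)), ids)
  abundances <- setNames(vector("list", length(animals)), ids)
  auc <- rep(NA_real_, length(animals))
  for (i in seq_along(animals)) {
    cs <- curve_sets[[groups[i]]]
    asg <- assign_pixels(processed[[i]]$change_rates, cs)
    abundances[[i]] <- asg$abundance
    wc <- withCallingHandlers(
      weighted_average_curve(cs, asg$abundance),
      warning = function(w) invokeRestart("muffleWarning")
    )
    weighted_curves[[i]] <- wc
    if (!is.null(wc)) auc[i] <- linear_tail_auc(wc, config$linear_start_frame)
  }
  undefined <- !is.finite(auc)
  if (any(undefined)) {
    warning(sprintf("clearance undefined for animal(s): %s",
                    paste(ids[undefined], collapse = ", ")))
  }
  results <- data.frame(animal_id = ids, group = groups, auc = auc,
                        undefined = undefined)
  comparison <- NULL
  if (compare && length(unique(groups)) >= 2L) {
    comparison <- compare_groups(results[!undefined, , drop = FALSE])
  }
  structure(
    list(results = results, curves = curve_sets,
         weighted_curves = weighted_curves, abundances = abundances,
         comparison = comparison, config = config,
         stage_order = STAGE_ORDER),
    class = "clearance_run"
  )
}

#' @export
print.clearance_run <- function(x, ...) {
  cat(sprintf("<clearance_run> %d animals, %d group(s), k = %d, seed %d\n",
              nrow(x$results), length(x$curves), x$config$k, x$config$seed))
  print(x$results, row.names = FALSE)
  if (!is.null(x$comparison)) {
    cat("\n"); print(x$comparison)
  }
  invisible(x)
}

#' Run the pipeline from a file manifest
#'
#' Loads per-animal stacks and masks named in a manifest, runs
#' [run_clearance()], and (optionally) writes the result bundle: per-animal
#' AUC table (CSV), characteristic curves (CSV), group comparison and a
#' summary JSON echoing the configuration, its hash, the seed and the fixed
#' stage order. Rerunning with an identical configuration and inputs
#' reproduces the summary byte-identically (no timestamps are embedded).
#'
#' @param config a [pipeline_config()].
#' @param manifest data frame with columns `animal_id`, `group`,
#'   `stack_path` (contrast TIFF), `anatomy_path` (anatomy TIFF, or `NA` to
#'   skip registration), `mask_path` (ROI TIFF).
#' @param out_dir output directory; `NULL` writes nothing.
#' @return The `clearance_run` object, invisibly when `out_dir` is set.
#' @export
run_pipeline <- function(config, manifest, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  req <- c("animal_id", "group", "stack_path", "mask_path")
  assert_that(is.data.frame(manifest) && all(req %in% names(manifest)),
              paste("manifest must have columns",
                    paste(req, collapse = ", ")))
  assert_that(!anyDuplicated(manifest$animal_id),
              "manifest animal_ids must be unique")
  paths <- c(manifest$stack_path, manifest$mask_path,
             if ("anatomy_path" %in% names(manifest))
               manifest$anatomy_path[!is.na(manifest$anatomy_path)])
  missing <- paths[!file.exists(paths)]
  assert_that(length(missing) == 0L,
              paste("manifest references missing file(s):",
                    paste(missing, collapse = ", ")))
  animals <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    anatomy <- NULL
    if ("anatomy_path" %in% names(manifest) && !is.na(m$anatomy_path)) {
      anatomy <- read_stack(m$anatomy_path)
    }
    list(animal_id = as.character(m$animal_id), group = as.character(m$group),
         icg = read_stack(m$stack_path), anatomy = anatomy,
         roi = read_roi_mask(m$mask_path))
  })
  run <- run_clearance(animals, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(run$results, file.path(out_dir, "auc_per_animal.csv"),
              row.names = FALSE)
    curves_df <- do.call(rbind, lapply(names(run$curves), function(g) {
      cs <- run$curves[[g]]
      data.frame(group = g, curve = rep(seq_len(cs$k), each = ncol(cs$centroids)),
                 bin = rep(seq_len(ncol(cs$centroids)), times = cs$k),
                 change_rate = as.vector(t(cs$centroids)),
                 net_increase = rep(cs$net_increase, each = ncol(cs$centroids)))
    }))
    write.csv(curves_df, file.path(out_dir, "characteristic_curves.csv"),
              row.names = FALSE)
    summary <- list(
      config = unclass(config), config_hash = config_hash(config),
      stage_order = STAGE_ORDER,
      results = run$results,
      comparison = if (!is.null(run$comparison)) {
        list(omnibus = run$comparison$omnibus,
             pairwise = run$comparison$pairwise,
             summary = run$comparison$summary)
      } else NULL)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(run))
  }
  run
}
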