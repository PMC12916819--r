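#' Read a multi-channel volume from single-channel NIfTI files
#'
#' Each channel is stored as its own NIfTI-1 file; all files must share grid
#' dimensions and affine (no implicit resampling).
#'
#' @param paths character vector of NIfTI paths, one per channel, in channel
#'   order (channel order is declared, never inferred from filenames).
#' @param channels channel names; defaults to the basenames.
#' @return a [as_volume()] volume; the first file's image is attached as
#'   attribute `reference` for aligned writing.
#' @export
read_volume <- function(paths, channels = NULL) {
  stopifnot(length(paths) >= 1L)
  imgs <- lapply(paths, RNifti::readNifti)
  dims <- lapply(imgs, dim)
  affs <- lapply(imgs, function(i) unclass(RNifti::xform(i)))
  for (i in seq_along(imgs)[-1]) {
    if (!identical(dims[[i]], dims[[1]]) ||
        max(abs(affs[[i]] - affs[[1]])) > 1e-4) {
      stop("channel files are not aligned (grid or affine mismatch); refusing to resample implicitly")
    }
  }
  d <- dims[[1]]
  if (length(d) == 2L) d <- c(d, 1L)
  data <- array(0, c(d, length(imgs)))
  for (i in seq_along(imgs)) data[, , , i] <- as.array(imgs[[i]])
  spacing <- RNifti::pixdim(imgs[[1]])[seq_len(min(3, length(dims[[1]])))]
  if (length(spacing) == 2L) spacing <- c(spacing, 1)
  if (is.null(channels)) channels <- basename(paths)
  v <- as_volume(data, channels = channels, spacing = spacing)
  attr(v, "reference") <- imgs[[1]]
  v
}

#' Read a NIfTI mask as an integer array
#' @param path NIfTI file.
#' @return integer array.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  storage.mode(a) <- "integer"
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  a
}

#' Write an array as NIfTI aligned to a reference grid
#'
#' @param arr numeric or integer array (spatial dims only).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param reference optional RNifti image (e.g. the `reference` attribute of
#'   [read_volume()]) the output inherits grid and affine from.
#' @param spacing voxel spacing used when no reference is given.
#' @export
write_map <- function(arr, path, reference = NULL, spacing = c(1, 1, 1)) {
  if (!is.null(reference)) {
    img <- RNifti::asNifti(arr, reference = reference)
  } else {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- spacing[seq_len(min(3, length(dim(arr))))]
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles every method parameter with its default: probability threshold
#' t = 0.3, SmoothGrad N = 50 and sigma = 0.05, 18-connectivity, 5 mm^3
#' minimum component volume, ten 93 mm^3 control spheres, saliency band
#' filter (-0.1, 0.1), 35 context-probe iterations and the 90-120 mm^3
#' near-average lesion-size window. Every stochastic stage derives its seed
#' from `seed`.
#'
#' @param image character vector of per-channel NIfTI paths, or `NULL` to
#'   generate a phantom.
#' @param gt,brain_mask NIfTI mask paths (ignored for phantom input).
#' @param model a model object, a model configuration list (see
#'   [model_from_config()]), or a path to a saved model.
#' @param out_dir output directory.
#' @param channels channel names, in the declared order.
#' @param phantom_cfg [phantom_config()] used when `image` is `NULL`.
#' @param t,n,sigma,connectivity,min_volume_mm3,tn_n,tn_volume_mm3,band,probe_iterations,volume_window
#'   method parameters (defaults above).
#' @param max_instances cap on the number of instances receiving saliency
#'   maps (NULL = all).
#' @param run_probe run the contextual-information probe.
#' @param seed master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(image = NULL, gt = NULL, brain_mask = NULL, model,
                       out_dir, channels = c("flair", "mprage"),
                       phantom_cfg = NULL, t = 0.3, n = 50L, sigma = 0.05,
                       connectivity = 18L, min_volume_mm3 = 5, tn_n = 10L,
                       tn_volume_mm3 = 93, band = c(-0.1, 0.1),
                       probe_iterations = 35L, volume_window = c(90, 120),
                       max_instances = NULL, run_probe = FALSE, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full saliency pipeline
#'
#' Loads (or generates) the input, runs the model, extracts instances and
#' TP/FP/FN/TN examples, computes SmoothGrad and Grad-CAM++ maps per
#' instance, peak statistics and (optionally) the context probe, writing all
#' artifacts plus a JSON manifest of parameters, seeds and stage status to
#' `out_dir`.
#'
#' @param config a [run_config()].
#' @return invisibly, the manifest list (also written to
#'   `manifest.json`; any stage failure is recorded there with a nonzero
#'   status).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("instasal")),
    seed = config$seed,
    parameters = config[c("t", "n", "sigma", "connectivity", "min_volume_mm3",
                          "tn_n", "tn_volume_mm3", "band",
                          "probe_iterations", "volume_window")],
    stages = list(), status = 0L
  )
  stage <- function(name, fun) {
    if (manifest$status != 0L) return(NULL)
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(ok = FALSE, error = conditionMessage(res))
      manifest$status <<- 1L
      NULL
    } else {
      manifest$stages[[name]] <<- list(ok = TRUE)
      res
    }
  }

  model <- stage("model", function() {
    m <- config$model
    if (is.character(m)) {
      if (!file.exists(m)) stop(sprintf("model path '%s' does not exist", m))
      m <- load_model(m)
    } else if (is.list(m) && !inherits(m, "sal_model")) {
      m <- model_from_config(m)
    }
    if (!inherits(m, "sal_model")) stop("no usable model supplied")
    m
  })

  data <- stage("input", function() {
    if (is.null(config$image)) {
      cfg <- if (is.null(config$phantom_cfg)) {
        phantom_config(seed = config$seed)
      } else {
        config$phantom_cfg
      }
      ph <- generate_phantom(cfg)
      list(volume = ph$volume, gt = ph$gt_mask, brain = ph$brain_mask,
           reference = NULL)
    } else {
      v <- read_volume(config$image, config$channels)
      list(volume = v, gt = read_mask(config$gt),
           brain = read_mask(config$brain_mask),
           reference = attr(v, "reference"))
    }
  })

  es <- stage("instances", function() {
    p <- forward_logits(model, data$volume)$p
    es <- extract_example_set(
      p, data$gt, data$brain, t = config$t,
      connectivity = config$connectivity,
      min_volume_mm3 = config$min_volume_mm3, tn_n = config$tn_n,
      tn_volume_mm3 = config$tn_volume_mm3, spacing = data$volume$spacing,
      seed = config$seed
    )
    tab <- example_table(es)
    utils::write.csv(tab, file.path(config$out_dir, "instances.csv"),
                     row.names = FALSE)
    lab <- array(0L, dim(data$gt))
    for (inst in c(es$tp, es$fp)) lab[inst$lin] <- inst$label
    write_map(lab, file.path(config$out_dir, "instance_labels.nii.gz"),
              reference = data$reference, spacing = data$volume$spacing)
    es
  })

  maps <- stage("saliency", function() {
    insts <- c(es$tp, es$fp)
    if (!is.null(config$max_instances)) {
      insts <- utils::head(insts, config$max_instances)
    }
    cfg <- noise_config(n = config$n, sigma = config$sigma, seed = config$seed)
    for (inst in insts) {
      sg <- smoothgrad_instance(model, data$volume, inst, cfg,
                                aggregation = "max_signed")
      full <- embed_saliency(sg)
      for (c in seq_along(data$volume$channels)) {
        write_map(full[, , , c],
                  file.path(config$out_dir, sprintf(
                    "saliency_smoothgrad_l%03d_%s.nii.gz", inst$label,
                    data$volume$channels[c]
                  )),
                  reference = data$reference, spacing = data$volume$spacing)
      }
      if (length(activation_names(model)) > 0L) {
        gc_map <- gradcam_instance_map(model, data$volume, omega = inst)
        write_map(gc_map$values,
                  file.path(config$out_dir, sprintf(
                    "saliency_gradcam_l%03d.nii.gz", inst$label
                  )),
                  reference = data$reference, spacing = data$volume$spacing)
      }
    }
    cats <- example_saliency_maps(
      model, data$volume, es,
      noise_config(n = config$n, sigma = config$sigma, seed = config$seed)
    )
    cats
  })

  stage("peaks", function() {
    ps <- peak_value_distributions(maps, channel = 1L, seed = config$seed)
    utils::write.csv(ps$peaks, file.path(config$out_dir, "peaks.csv"),
                     row.names = FALSE)
    if (!is.null(ps$summary)) {
      utils::write.csv(ps$summary, file.path(config$out_dir, "peak_summary.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(ps$tests, file.path(config$out_dir, "peak_tests.json"),
                         dataframe = "rows", digits = NA)
    ps
  })

  if (isTRUE(config$run_probe)) {
    stage("context_probe", function() {
      sel <- select_average_size_lesions(es$tp, config$volume_window[1],
                                         config$volume_window[2])
      if (length(sel) == 0L) sel <- es$tp
      if (length(sel) == 0L) stop("no lesions available for the context probe")
      cp <- context_probe_summary(model, data$volume, sel,
                                  iterations = config$probe_iterations,
                                  t = config$t)
      utils::write.csv(cp, file.path(config$out_dir, "context_probe.csv"),
                       row.names = FALSE)
      cp
    })
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
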