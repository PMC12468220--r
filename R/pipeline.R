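#' Default pipeline configuration
#'
#' Nested named list with every tunable of the pipeline stages; serializable
#' to YAML ([save_config()] / [load_config()]). `refine.a_min_fraction`
#' expresses the minimum component area as a fraction of the image area
#' (scale-free across crop sizes); it is resolved to pixels per image.
#'
#' @return Nested configuration list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    enhancement = list(
      bilateral = list(spatial_sigma = 3, range_sigma = 0.1, window_radius = 6L),
      gamma = list(convention = "equations", max = 5)
    ),
    segmentation = list(
      grayscale_weights = c(0.299, 0.587, 0.114),
      class_index = 1L
    ),
    refine = list(
      a_min_fraction = 0.001,
      open_radius = 2L, close_radius = 3L,
      jaggedness_threshold = 1.15, hole_area = 10L,
      edge_method = "off", hole_connectivity = 4L
    ),
    baselines = list(
      window_radius = 15L, bradley_k = 12, niblack_k = -0.2, nick_k = -0.13,
      sauvola_k = 0.1, sauvola_R = 128,
      feng_alpha1 = 0.12, feng_gamma = 2, feng_k1 = 0.25, feng_k2 = 0.04,
      feng_secondary_factor = 2L
    ),
    evaluation = list(alpha = 0.05)
  ), class = "pipeline_config")
}

check_config_keys <- function(cfg, ref, path = character(0)) {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra) > 0L)
    stop("unknown config key: ", paste(c(path, extra[1L]), collapse = "."),
         call. = FALSE)
  for (nm in names(cfg)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
      check_config_keys(as.list(cfg[[nm]]), ref[[nm]], c(path, nm))
  }
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) &&
        is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else
      base[[nm]] <- if (is.list(override[[nm]]) && is.null(names(override[[nm]])))
        unlist(override[[nm]]) else override[[nm]]
  }
  base
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys present in the file override the defaults; unknown keys are rejected
#' with the offending dotted path named.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- default_config()
  check_config_keys(raw, defaults)
  structure(merge_config(unclass(defaults), raw), class = "pipeline_config")
}

#' Save a pipeline configuration to YAML
#'
#' @param cfg A `pipeline_config` list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

cfg_refinement <- function(cfg, h, w) {
  rf <- cfg$refine
  refinement_config(
    a_min = max(1L, as.integer(round(rf$a_min_fraction * h * w))),
    se_open = structuring_element("disk", rf$open_radius),
    se_close = structuring_element("disk", rf$close_radius),
    jaggedness_threshold = rf$jaggedness_threshold,
    hole_area_threshold = rf$hole_area,
    edge_refinement = rf$edge_method,
    hole_connectivity = rf$hole_connectivity)
}

#' Segment one RGB image with the full proposed pipeline
#'
#' enhance -> grayscale -> histogram -> multi-Otsu -> darkest-class mask ->
#' conditional morphological post-processing.
#'
#' @param img `h x w x 3` RGB array in \[0,1\].
#' @param cfg A `pipeline_config` (default [default_config()]).
#' @param refine Set `FALSE` to stop after mask extraction (skip
#'   post-processing).
#' @return List: `mask` (refined), `raw_mask`, `enhanced` (RGB), `gray`
#'   (levels 0..255), `log` (mean intensity, gamma, branch, thresholds,
#'   between-class variance at the optimum, refinement branches fired).
#' @export
segment_image <- function(img, cfg = default_config(), refine = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  assert_rgb(img)
  bp <- bilateral_params(cfg$enhancement$bilateral$spatial_sigma,
                         cfg$enhancement$bilateral$range_sigma,
                         cfg$enhancement$bilateral$window_radius)
  enh <- enhance(img, bp, gamma_convention = cfg$enhancement$gamma$convention,
                 gamma_max = cfg$enhancement$gamma$max)
  gray <- to_grayscale(enh$image, cfg$segmentation$grayscale_weights)
  hist <- compute_histogram(gray)
  ot <- multi_otsu(hist)
  raw_mask <- extract_class_mask(gray, ot$t, cfg$segmentation$class_index)
  log <- list(mean_intensity = enh$mean_v, gamma = enh$gamma,
              branch = enh$branch, t1 = ot$t[1L], t2 = ot$t[2L],
              sigma_b2 = ot$sigma_b2)
  if (refine) {
    rf <- cfg_refinement(cfg, nrow(gray), ncol(gray))
    pp <- postprocess(raw_mask, gray, rf)
    mask <- pp$mask
    log <- c(log, pp$log)
  } else {
    mask <- raw_mask
  }
  list(mask = mask, raw_mask = raw_mask, enhanced = enh$image, gray = gray,
       log = log)
}

read_input_image <- function(x) {
  img <- if (is.character(x)) read_image(x) else x
  if (is.matrix(img)) {          # grayscale input: replicate to RGB
    img <- array(rep(img, 3L), c(dim(img), 3L))
  }
  img
}

#' Run the segmentation pipeline over a batch of images
#'
#' Failures on individual images are logged and skipped rather than aborting
#' the batch. Masks are written as 8-bit \{0,255\} PNGs named
#' `<input>_mask.png`.
#'
#' @param inputs Character vector of image paths, or a list of RGB arrays.
#' @param cfg A `pipeline_config`.
#' @param out_dir Output directory for masks (`NULL` = do not write).
#' @param save_intermediates Also write the enhanced image and the raw
#'   pre-refinement mask.
#' @return List: `log` (one data-frame row per input: gamma decision,
#'   thresholds, refinement branches, status), `masks` (list of logical
#'   matrices, `NULL` where failed).
#' @export
run_pipeline <- function(inputs, cfg = default_config(), out_dir = NULL,
                         save_intermediates = FALSE) {
  n <- length(inputs)
  if (n == 0L) stop("no inputs", call. = FALSE)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- if (is.character(inputs)) basename(inputs) else paste0("img_", seq_len(n))
  masks <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      img <- read_input_image(if (is.character(inputs)) inputs[i] else inputs[[i]])
      seg <- segment_image(img, cfg)
      masks[[i]] <- seg$mask
      if (!is.null(out_dir)) {
        stem <- tools::file_path_sans_ext(ids[i])
        write_mask(seg$mask, file.path(out_dir, paste0(stem, "_mask.png")))
        if (save_intermediates) {
          write_image(seg$enhanced, file.path(out_dir, paste0(stem, "_enhanced.png")))
          write_mask(seg$raw_mask, file.path(out_dir, paste0(stem, "_rawmask.png")))
        }
      }
      lg <- seg$log
      data.frame(image = ids[i], status = "ok", message = "",
                 mean_intensity = lg$mean_intensity, gamma = lg$gamma,
                 branch = lg$branch, t1 = lg$t1, t2 = lg$t2,
                 sigma_b2 = lg$sigma_b2,
                 opened = isTRUE(lg$opened), filled = isTRUE(lg$filled),
                 closed = isTRUE(lg$closed),
                 edge_refined = isTRUE(lg$edge_refined),
                 jaggedness = if (is.null(lg$jaggedness)) NA_real_ else lg$jaggedness,
                 n_components_before = if (is.null(lg$n_components_before))
                   NA_integer_ else lg$n_components_before,
                 n_components_after = if (is.null(lg$n_components_after))
                   NA_integer_ else lg$n_components_after,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(image = ids[i], status = "error",
                 message = conditionMessage(e),
                 mean_intensity = NA_real_, gamma = NA_real_,
                 branch = NA_character_, t1 = NA_integer_, t2 = NA_integer_,
                 sigma_b2 = NA_real_, opened = NA, filled = NA, closed = NA,
                 edge_refined = NA, jaggedness = NA_real_,
                 n_components_before = NA_integer_,
                 n_components_after = NA_integer_, stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  log <- do.call(rbind, rows)
  if (all(log$status == "error"))
    stop("no input could be processed; first error: ", log$message[1L],
         call. = FALSE)
  list(log = log, masks = masks)
}

baseline_methods <- c("bradley", "feng", "niblack", "nick", "sauvola")

baseline_params_from_cfg <- function(method, cfg) {
  b <- cfg$baselines
  baseline_params(method, window_radius = b$window_radius,
                  bradley_k = b$bradley_k, niblack_k = b$niblack_k,
                  nick_k = b$nick_k, sauvola_k = b$sauvola_k,
                  sauvola_R = b$sauvola_R, feng_alpha1 = b$feng_alpha1,
                  feng_gamma = b$feng_gamma, feng_k1 = b$feng_k1,
                  feng_k2 = b$feng_k2,
                  feng_secondary_factor = b$feng_secondary_factor)
}

#' Compare the proposed pipeline against the five local-threshold baselines
#'
#' Runs the proposed method plus Bradley, Feng, Niblack, Nick and Sauvola on
#' every image (baselines binarize the raw grayscale), scores each against
#' the ground truth, and reports a per-method summary table
#' (precision / F-measure / sensitivity / accuracy, mean and sd) plus paired
#' t-tests between the proposed method and selected baselines over the
#' per-image F1, precision, sensitivity and accuracy values.
#'
#' @param images List of RGB arrays (or character paths).
#' @param truths List of ground-truth logical masks (or paths to mask
#'   images).
#' @param cfg A `pipeline_config`.
#' @param t_test_against Baselines to t-test against (default Sauvola and
#'   Bradley, the strongest competitors).
#' @return List: `per_image` (long data frame: image, method, metrics),
#'   `table` (method-by-metric summary in the shape of a comparison table),
#'   `t_tests` (named list of per-metric data frames).
#' @export
run_comparison <- function(images, truths, cfg = default_config(),
                           t_test_against = c("sauvola", "bradley")) {
  n <- length(images)
  if (n < 1L || length(truths) != n)
    stop("images and truths must be non-empty paired lists", call. = FALSE)
  t_test_against <- match.arg(t_test_against, baseline_methods, several.ok = TRUE)
  per <- list()
  for (i in seq_len(n)) {
    img <- read_input_image(if (is.character(images)) images[i] else images[[i]])
    truth <- if (is.character(truths)) read_mask(truths[i]) else truths[[i]]
    seg <- segment_image(img, cfg)
    masks <- list(proposed = seg$mask)
    gray_raw <- to_grayscale(img, cfg$segmentation$grayscale_weights)
    for (m in baseline_methods)
      masks[[m]] <- local_threshold(gray_raw, baseline_params_from_cfg(m, cfg))
    for (m in names(masks)) {
      sc <- seg_metrics(confusion(masks[[m]], truth))
      per[[length(per) + 1L]] <- data.frame(
        image = i, method = m, precision = sc$precision,
        f_measure = sc$f1, sensitivity = sc$recall, accuracy = sc$accuracy,
        stringsAsFactors = FALSE)
    }
  }
  per_image <- do.call(rbind, per)
  methods <- c(baseline_methods, "proposed")
  table <- do.call(rbind, lapply(methods, function(m) {
    d <- per_image[per_image$method == m, ]
    data.frame(method = m,
               precision = mean(d$precision), f_measure = mean(d$f_measure),
               sensitivity = mean(d$sensitivity), accuracy = mean(d$accuracy),
               precision_sd = sd_or0(d$precision),
               f_measure_sd = sd_or0(d$f_measure),
               sensitivity_sd = sd_or0(d$sensitivity),
               accuracy_sd = sd_or0(d$accuracy),
               stringsAsFactors = FALSE)
  }))
  t_tests <- list()
  if (n >= 2L) {
    prop <- per_image[per_image$method == "proposed", ]
    for (m in t_test_against) {
      base <- per_image[per_image$method == m, ]
      t_tests[[m]] <- do.call(rbind, lapply(
        c("precision", "f_measure", "sensitivity", "accuracy"),
        function(metric) {
          tt <- paired_t_test(prop[[metric]], base[[metric]],
                              alpha = cfg$evaluation$alpha)
          data.frame(metric = metric,
                     proposed_mean = mean(prop[[metric]]),
                     proposed_sd = sd_or0(prop[[metric]]),
                     baseline_mean = mean(base[[metric]]),
                     baseline_sd = sd_or0(base[[metric]]),
                     mean_difference = tt$mean_difference,
                     t = tt$t, p_value = tt$p_value,
                     significant = tt$significant, flag = tt$flag,
                     stringsAsFactors = FALSE)
        }))
    }
  }
  list(per_image = per_image, table = table, t_tests = t_tests)
}

sd_or0 <- function(x) if (length(x) > 1L) sd(x) else 0
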