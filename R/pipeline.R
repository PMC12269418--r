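# End-to-end orchestration: segment vessels per spheroid window, count
# co-localized cancer particles, and summarize per condition; plus the
# simulation study that validates the whole chain against planted ground
# truth.

#' Pipeline run configuration
#'
#' Every filter default equals the published analysis setting: minimum
#' particle area 50 um^2, circularity window [0.5, 1.0], tROI side 115% of
#' the spheroid major axis, permeability diameter bound 50 um, 200-tree
#' forest.
#'
#' @param pixel_size_um Calibration applied to all images (um/px).
#' @param feature_config A [feature_config()] for the vessel classifier.
#' @param min_area_um2 Minimum intravasation-particle area (um^2).
#' @param circ_min,circ_max Particle circularity window.
#' @param troi_scale tROI side as a fraction of the spheroid major axis.
#' @param d_max_um Permeability vessel-diameter selection bound (um).
#' @param min_spheroid_area_um2 Minimum component area treated as a spheroid.
#' @param n_trees Random-forest size.
#' @param morph_erosions,morph_dilations Mask cleanup iterations.
#' @param seed Integer seed for classifier training.
#' @param output_dir Optional directory for tables/report; `NULL` keeps the
#'   run in memory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(pixel_size_um = 1,
                       feature_config = mvnquant::feature_config(),
                       min_area_um2 = 50, circ_min = 0.5, circ_max = 1.0,
                       troi_scale = 1.15, d_max_um = 50,
                       min_spheroid_area_um2 = 500, n_trees = 200L,
                       morph_erosions = 1L, morph_dilations = 1L,
                       seed = 1L, output_dir = NULL) {
  abort_if(!is_scalar_number(pixel_size_um) || pixel_size_um <= 0,
           "pixel_size_um must be > 0")
  abort_if(min_area_um2 < 0, "min_area_um2 must be >= 0")
  abort_if(circ_min < 0 || circ_max > 1 || circ_min > circ_max,
           "need 0 <= circ_min <= circ_max <= 1")
  abort_if(troi_scale <= 0, "troi_scale must be > 0")
  abort_if(d_max_um <= 0, "d_max_um must be > 0")
  stopifnot(inherits(feature_config, "feature_config"))
  structure(as.list(environment()), class = "run_config")
}

# Normalize a pipeline input entry into (channels, id, group).
as_pipeline_entry <- function(x, i, pixel_size_um) {
  if (inherits(x, "synthetic_scene")) {
    return(list(channels = x$channels, id = sprintf("img%03d", i),
                group = ""))
  }
  abort_if(!is.list(x) || !all(c("phase", "gfp", "cancer") %in% names(x)),
           "pipeline entries need phase, gfp and cancer channels")
  ch <- lapply(c(phase = "phase", gfp = "gfp", cancer = "cancer"), function(nm) {
    v <- x[[nm]]
    if (is.character(v)) load_image(v, nm, pixel_size_um) else v
  })
  list(channels = ch,
       id = if (!is.null(x$id)) x$id else sprintf("img%03d", i),
       group = if (!is.null(x$group)) x$group else "")
}

# Segment vessels inside one tROI window: crop phase + binarized GFP,
# compute the feature bank, classify, clean.
segment_vessels_in_troi <- function(channels, gfp_bin, troi, classifier,
                                    config) {
  phase_w <- crop_to_troi(channels$phase, troi)
  gfp_w <- crop_to_troi(gfp_bin, troi)
  stack <- compute_feature_stack(list(phase_w, gfp_w), config$feature_config)
  m <- predict_mask(classifier, stack, config$pixel_size_um)
  morph_clean(m, config$morph_erosions, config$morph_dilations)
}

#' Build training scribbles from a ground-truth vessel mask
#'
#' Samples pixel labels from a known vessel mask: useful both for synthetic
#' scenes (truth is available) and for real images with an annotated
#' reference mask.
#'
#' @param vessel_mask `binary_mask` of true vessel pixels.
#' @param n_per_class Labels per class.
#' @param seed Sampling seed.
#' @param image_id Identifier recorded on the labels.
#' @return A [scribble_labels()] object.
#' @export
scribbles_from_mask <- function(vessel_mask, n_per_class = 400L, seed = 1L,
                                image_id = "") {
  stopifnot(inherits(vessel_mask, "binary_mask"))
  v_idx <- which(vessel_mask$pixels, arr.ind = TRUE)
  b_idx <- which(!vessel_mask$pixels, arr.ind = TRUE)
  abort_if(nrow(v_idx) == 0L || nrow(b_idx) == 0L,
           "mask must contain both vessel and background pixels")
  with_seed(seed, {
    vs <- v_idx[sample(nrow(v_idx), min(n_per_class, nrow(v_idx))), ,
                drop = FALSE]
    bs <- b_idx[sample(nrow(b_idx), min(n_per_class, nrow(b_idx))), ,
                drop = FALSE]
    scribble_labels(rbind(vs, bs),
                    c(rep("vessel", nrow(vs)), rep("background", nrow(bs))),
                    image_id = image_id)
  })
}

#' Train a vessel classifier from scenes with known vessel masks
#'
#' Computes the phase + binarized-GFP feature bank on each training scene
#' and fits the random forest on scribbles sampled from the reference
#' vessel masks.
#'
#' @param scenes List of `synthetic_scene` objects (or lists with
#'   `channels` and a truth `vessel_mask`).
#' @param config A [run_config()].
#' @param n_per_class Scribbles per class per scene.
#' @return A `pixel_classifier`.
#' @export
train_from_scenes <- function(scenes, config = run_config(),
                              n_per_class = 400L) {
  abort_if(length(scenes) == 0L, "no training scenes")
  stacks <- list(); labels <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    gfp_bin <- default_threshold(sc$channels$gfp)
    stacks[[i]] <- compute_feature_stack(
      list(sc$channels$phase, gfp_bin), config$feature_config)
    labels[[i]] <- scribbles_from_mask(
      sc$truth$vessel_mask, n_per_class,
      seed = child_seed(config$seed, 5000 + i),
      image_id = sprintf("train%02d", i))
  }
  train_pixel_classifier(stacks, labels, n_trees = config$n_trees,
                         random_seed = config$seed)
}

#' Run the full intravasation quantification pipeline
#'
#' For every input image: binarize the GFP channel (IsoData), locate
#' spheroids in the cancer channel, draw the 115%-of-major-axis tROI around
#' each, classify vessels inside each tROI from the phase and binarized GFP
#' channels, clean the mask, and count cancer particles co-localizing with
#' the vessel area under the size/circularity filters. Per-image failures
#' are logged and the run continues.
#'
#' @param images List of `synthetic_scene` objects or lists with `phase`,
#'   `gfp`, `cancer` (`calibrated_image`s or file paths) plus optional
#'   `id` and `group`.
#' @param config A [run_config()].
#' @param classifier A trained `pixel_classifier`, or `NULL` to train from
#'   `training_scenes`.
#' @param training_scenes Scenes with reference vessel masks used when no
#'   classifier is supplied.
#' @param groups Optional character vector of group labels (one per image),
#'   overriding per-entry labels.
#' @return A `run_report`: `summary` and `per_spheroid` tables (see
#'   [summarize_events()]), `event_counts`, `failures`, `config` and
#'   `classifier_summary`. Tables are also written under
#'   `config$output_dir` when set.
#' @export
run_quantification <- function(images, config = run_config(),
                               classifier = NULL, training_scenes = NULL,
                               groups = NULL) {
  stopifnot(inherits(config, "run_config"))
  abort_if(length(images) == 0L, "no input images")
  if (is.null(classifier)) {
    abort_if(is.null(training_scenes),
             "either a trained classifier or training scenes are required")
    classifier <- train_from_scenes(training_scenes, config)
  }
  abort_if(!setequal(classifier$feature_config$families,
                     config$feature_config$families),
           "classifier feature families do not match the run configuration")
  counts <- list(); failures <- character(0)
  for (i in seq_along(images)) {
    entry <- tryCatch(as_pipeline_entry(images[[i]], i, config$pixel_size_um),
                      error = function(e) e)
    if (inherits(entry, "error")) {
      failures <- c(failures, sprintf("entry %d: %s", i, conditionMessage(entry)))
      next
    }
    if (!is.null(groups)) entry$group <- groups[i]
    res <- tryCatch({
      ch <- entry$channels
      sph_mask <- default_threshold(ch$cancer)
      trois <- extract_spheroid_rois(sph_mask, config$min_spheroid_area_um2,
                                     config$troi_scale)
      gfp_bin <- default_threshold(ch$gfp)
      lapply(trois, function(troi) {
        vmask <- segment_vessels_in_troi(ch, gfp_bin, troi, classifier, config)
        vroi <- structure(list(
          spheroid_id = sprintf("%s_%s", entry$id, troi$spheroid_id),
          mask = vmask,
          vessel_area_um2 = area_um2(sum(vmask$pixels), vmask$pixel_size_um),
          troi = troi), class = "vessel_roi")
        ev <- count_intravasation_events(crop_to_troi(ch$cancer, troi), vroi,
                                         config$min_area_um2,
                                         config$circ_min, config$circ_max)
        ev$spheroid_id <- vroi$spheroid_id
        ev$condition_label <- entry$group
        ev
      })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", entry$id, conditionMessage(res)))
    } else {
      counts <- c(counts, res)
    }
  }
  summ <- if (length(counts)) summarize_events(counts)
  else list(summary = NULL, per_spheroid = NULL)
  report <- structure(list(
    summary = summ$summary, per_spheroid = summ$per_spheroid,
    event_counts = counts, failures = failures,
    config = unclass(config)[setdiff(names(config), "feature_config")],
    feature_families = config$feature_config$families,
    classifier_summary = classifier$training_summary,
    version = as.character(utils::packageVersion("mvnquant"))),
    class = "run_report")
  if (!is.null(config$output_dir)) write_run_report(report, config$output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d spheroids, %d failures\n",
              length(x$event_counts), length(x$failures)))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$per_spheroid)) {
    utils::write.csv(report$per_spheroid,
                     file.path(dir, "events_per_spheroid.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$summary)) {
    utils::write.csv(report$summary, file.path(dir, "group_summary.csv"),
                     row.names = FALSE)
  }
  particles <- do.call(rbind, lapply(report$event_counts,
                                     function(e) e$particles))
  if (!is.null(particles) && nrow(particles)) {
    utils::write.csv(particles, file.path(dir, "particles.csv"),
                     row.names = FALSE)
  }
  meta <- report[c("failures", "config", "feature_families",
                   "classifier_summary", "version")]
  jsonlite::write_json(meta, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Simulation study: condition-mean recovery of the full pipeline
#'
#' Generates a control-like and an induction-like batch of synthetic scenes
#' (per-spheroid true event counts Poisson with the given means), trains the
#' vessel classifier on separate training scenes, runs the full
#' quantification pipeline blind to the planted truth, and reports
#' estimated versus true per-condition means along with per-scene count
#' errors.
#'
#' @param config A [run_config()].
#' @param template A [scene_spec()] shared by all scenes (event counts and
#'   seeds are overridden per scene).
#' @param n_scenes Scenes per condition.
#' @param means Named numeric vector of true per-spheroid event means.
#' @param n_train Number of training scenes.
#' @param seed Master seed for generation and training.
#' @param classifier Optional pre-trained `pixel_classifier`; when supplied,
#'   no training scenes are generated (one classifier can serve many
#'   batches, the usual workflow).
#' @return A `study_report`: data frame `conditions` (truth mean, estimated
#'   mean, absolute error, exact-count fraction) plus `per_scene` records.
#' @export
run_simulation_study <- function(config = run_config(),
                                 template = scene_spec(),
                                 n_scenes = 100L,
                                 means = c(control = 1, emt_ic = 3),
                                 n_train = 3L, seed = 1L,
                                 classifier = NULL) {
  stopifnot(inherits(config, "run_config"), inherits(template, "scene_spec"))
  if (is.null(classifier)) {
    train_scenes <- lapply(seq_len(n_train), function(i) {
      sp <- template
      sp$n_intravascular <- 2L
      sp$seed <- child_seed(seed, 9000 + i)
      generate_scene(sp)
    })
    classifier <- train_from_scenes(train_scenes, config)
  }
  per_scene <- list()
  cond_rows <- lapply(seq_along(means), function(ci) {
    cond <- names(means)[ci]
    batch <- generate_condition_batch(n_scenes, means[[ci]], template,
                                      seed = child_seed(seed, ci))
    rep <- run_quantification(batch$scenes, config, classifier = classifier,
                              groups = rep(cond, n_scenes))
    est <- rep$per_spheroid$n_events
    abort_if(length(est) != n_scenes,
             "pipeline did not return one count per scene")
    per_scene[[cond]] <<- data.frame(
      condition = cond, scene = seq_len(n_scenes),
      truth = batch$truth_counts, estimated = est,
      error = est - batch$truth_counts)
    data.frame(condition = cond,
               truth_mean = mean(batch$truth_counts),
               estimated_mean = mean(est),
               abs_error = abs(mean(est) - mean(batch$truth_counts)),
               exact_fraction = mean(est == batch$truth_counts))
  })
  structure(list(conditions = do.call(rbind, cond_rows),
                 per_scene = do.call(rbind, per_scene),
                 n_scenes = n_scenes, seed = seed),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d scenes/condition\n", x$n_scenes))
  print(x$conditions, row.names = FALSE)
  invisible(x)
}
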