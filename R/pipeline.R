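# Pipeline orchestration: selection -> segmentation adapter ->
# post-processing -> endpoint extraction, with stage-count logging and
# reproducible tabular output. The segmentation stage is an adapter
# boundary: any external segmenter's masks can be supplied; a bundled
# intensity-band null segmenter makes the end-to-end path testable on
# synthetic scenes without a neural network.

#' Pipeline run configuration
#'
#' @param mode `"larva"` or `"egg"`.
#' @param scale a [px_scale()] or mm/px number.
#' @param window,threshold,min_area_mm2,connectivity frame-selection
#'   parameters (see [selection_config()]).
#' @param slack post-processing containment slack in pixels.
#' @param max_turn_rad centerline turning-angle flag threshold.
#' @param seed RNG seed recorded with the run.
#' @return a `run_config` list; serialized into every output directory for
#'   reproducibility ([write_config_echo()]).
#' @export
run_config <- function(mode = c("larva", "egg"), scale = px_scale(0.0036),
                       window = 50, threshold = 25, min_area_mm2 = 0.2,
                       connectivity = 8, slack = 0,
                       max_turn_rad = 1.25 * pi, seed = 1L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, scale = as_scale(scale), window = window,
                 threshold = threshold, min_area_mm2 = min_area_mm2,
                 connectivity = connectivity, slack = slack,
                 max_turn_rad = max_turn_rad, seed = as.integer(seed)),
            class = "run_config")
}

#' Null segmenter: intensity-band thresholding
#'
#' Classifies pixels of a back-lit image into feature classes by fixed
#' intensity bands below the background level and splits each class into
#' connected components. Suitable for synthetic scenes and for very clean
#' back-lit imagery; it stands in for the external instance segmenter at
#' the adapter boundary.
#'
#' @param image `h x w` intensity matrix (0-255 counts).
#' @param mode `"larva"` or `"egg"`.
#' @param background assumed background level in counts.
#' @param min_region_px components smaller than this are dropped as noise.
#' @return list of [labeled_region()].
#' @export
null_segmenter <- function(image, mode = c("larva", "egg"),
                           background = 220, min_region_px = 30) {
  mode <- match.arg(mode)
  comps <- function(mask, class) {
    lab <- label_components(mask, 8)
    n <- max(lab)
    out <- list()
    for (i in seq_len(n)) {
      m <- lab == i
      if (sum(m) >= min_region_px)
        out <- c(out, list(labeled_region(class, m, confidence = 1)))
    }
    out
  }
  if (mode == "egg") return(comps(image < background - 30, "egg"))
  c(comps(image < background - 30, "body"),
    comps(image < background - 150, "eye"),
    comps(image >= background - 150 & image < background - 80, "yolk"))
}

#' Run the measurement pipeline
#'
#' Input is either a [frame_stream()] (candidate frames are selected first)
#' or a list of single images / `synthetic_scene`s (selection skipped). Each
#' frame is segmented by `segmenter`, post-processed, and measured; stage
#' in/out counts are logged and every dropped region is accounted for.
#'
#' @param input a [frame_stream()], a list of matrices, or a list of
#'   [render_scene()] scenes.
#' @param config a [run_config()].
#' @param segmenter `function(image, mode)` returning [labeled_region()]s;
#'   default [null_segmenter()]. Ignored for inputs that carry pre-computed
#'   regions when `use_truth_masks = TRUE`.
#' @param use_truth_masks for `synthetic_scene` inputs: feed the generator's
#'   truth masks instead of segmenting the rendered image.
#' @return a `pipeline_result`: `results` (one row per individual), `log`
#'   (per-stage counts), `config`.
#' @export
run_pipeline <- function(input, config = run_config(),
                         segmenter = null_segmenter,
                         use_truth_masks = FALSE) {
  frames <- list(); frame_ids <- integer(); pre_regions <- list()
  if (inherits(input, "frame_stream")) {
    sel <- select_candidates(input, selection_config(
      window = config$window, threshold = config$threshold,
      min_area_mm2 = config$min_area_mm2,
      connectivity = config$connectivity, scale = config$scale))
    frame_ids <- which(sel$manifest$selected)
    frames <- lapply(frame_ids, function(i) get_frame(input, i))
    pre_regions <- vector("list", length(frames))
    n_candidates <- nrow(sel$manifest)
  } else {
    if (!is.list(input)) stop("`input` must be a frame_stream or a list", call. = FALSE)
    frame_ids <- seq_along(input)
    frames <- lapply(input, function(x)
      if (inherits(x, "synthetic_scene")) x$image else x)
    pre_regions <- lapply(input, function(x)
      if (use_truth_masks && inherits(x, "synthetic_scene")) x$regions else NULL)
    n_candidates <- length(frames)
  }
  rows <- list(); n_regions <- 0L; n_segs <- 0L
  if (length(frames) == 0L) {
    warning("no candidate frames; empty result", call. = FALSE)
  }
  for (k in seq_along(frames)) {
    regions <- pre_regions[[k]] %||% segmenter(frames[[k]], config$mode)
    n_regions <- n_regions + length(regions)
    segs <- postprocess(regions, dim(frames[[k]]), mode = config$mode,
                        slack = config$slack)
    n_segs <- n_segs + length(segs)
    for (j in seq_along(segs)) {
      rows[[length(rows) + 1L]] <-
        measure_individual(segs[[j]], config$scale, mode = config$mode,
                           frame_id = frame_ids[k], seg_id = j,
                           max_turn_rad = config$max_turn_rad)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    if (config$mode == "larva") larva_record()[0, ] else egg_record()[0, ]
  structure(list(results = results,
                 log = data.frame(stage = c("candidate_frames", "raw_regions",
                                            "segmentations", "individuals"),
                                  n = c(n_candidates, n_regions, n_segs,
                                        nrow(results))),
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$log, row.names = FALSE)
  invisible(x)
}

#' Summarize a results table
#'
#' Per-group mean, SD, quartiles and n for every numeric endpoint,
#' restricted to rows whose relevant validity flag is set; invalid row
#' counts are reported alongside. With a single valid row the SD is absent
#' (`NA`); empty groups are omitted with a warning.
#'
#' @param results the `results` data.frame of a [run_pipeline()] (or the
#'   `pipeline_result` itself).
#' @param group_by optional vector (e.g. day or batch labels), one per row.
#' @return data.frame with one row per group x endpoint.
#' @export
summarize_results <- function(results, group_by = NULL) {
  if (inherits(results, "pipeline_result")) results <- results$results
  if (nrow(results) == 0L) {
    warning("no rows to summarize", call. = FALSE)
    return(data.frame(group = character(), endpoint = character(),
                      n = integer(), n_invalid = integer(), mean = numeric(),
                      sd = numeric(), q25 = numeric(), median = numeric(),
                      q75 = numeric()))
  }
  group_by <- group_by %||% rep("all", nrow(results))
  num_cols <- names(results)[vapply(results, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, c("frame_id", "seg_id", "n_eyes",
                                  "facing_drow", "facing_dcol"))
  valid_col_for <- function(col) {
    if (grepl("^egg_", col) || col == "circularity") return("egg_valid")
    if (grepl("^eye_", col)) return("eyes_valid")
    if (grepl("^yolk_", col)) return("yolk_valid")
    "body_valid"
  }
  out <- list()
  for (g in unique(group_by)) {
    sub <- results[group_by == g, , drop = FALSE]
    for (col in num_cols) {
      vc <- valid_col_for(col)
      ok <- if (vc %in% names(sub)) sub[[vc]] else rep(TRUE, nrow(sub))
      v <- sub[[col]][ok & !is.na(sub[[col]])]
      if (length(v) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        group = g, endpoint = col, n = length(v),
        n_invalid = sum(!ok | is.na(sub[[col]])),
        mean = mean(v), sd = if (length(v) > 1L) sd(v) else NA_real_,
        q25 = unname(quantile(v, 0.25)), median = median(v),
        q75 = unname(quantile(v, 0.75)))
    }
  }
  if (length(out) == 0L) {
    warning("all rows invalid; empty summary", call. = FALSE)
    return(data.frame(group = character(), endpoint = character(),
                      n = integer(), n_invalid = integer(), mean = numeric(),
                      sd = numeric(), q25 = numeric(), median = numeric(),
                      q75 = numeric()))
  }
  do.call(rbind, out)
}

#' Robust outlier report
#'
#' Reports (never drops) rows whose endpoint value lies outside
#' median +/- 5 MAD — an audit aid replacing manual exclusion of extreme
#' data points.
#'
#' @param results a results data.frame or `pipeline_result`.
#' @param endpoints endpoint columns to screen (default: all numeric).
#' @param k MAD multiplier (default 5).
#' @return data.frame of flagged (row, endpoint, value, median, mad) tuples.
#' @export
outlier_report <- function(results, endpoints = NULL, k = 5) {
  if (inherits(results, "pipeline_result")) results <- results$results
  num_cols <- names(results)[vapply(results, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, c("frame_id", "seg_id", "n_eyes"))
  endpoints <- endpoints %||% num_cols
  out <- list()
  for (col in endpoints) {
    v <- results[[col]]
    ok <- which(!is.na(v))
    if (length(ok) < 3L) next
    m <- median(v[ok]); s <- mad(v[ok])
    if (!is.finite(s) || s == 0) next
    hit <- ok[abs(v[ok] - m) > k * s]
    for (i in hit) {
      out[[length(out) + 1L]] <- data.frame(row = i, endpoint = col,
                                            value = v[i], median = m, mad = s)
    }
  }
  if (length(out) == 0L)
    return(data.frame(row = integer(), endpoint = character(),
                      value = numeric(), median = numeric(), mad = numeric()))
  do.call(rbind, out)
}

#' Write results / config echo
#'
#' `write_results()` writes the results table with fixed 6-decimal float
#' formatting so identical runs produce byte-identical CSVs.
#' `write_config_echo()` serializes the configuration (and a content hash)
#' as JSON next to the outputs.
#'
#' @param results a results data.frame or `pipeline_result`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "pipeline_result")) results <- results$results
  out <- results
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), "",
                           sprintf("%.6f", out[[col]]))
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @param config a [run_config()].
#' @export
write_config_echo <- function(config, path) {
  lst <- unclass(config)
  lst$scale <- config$scale$mm_per_px
  lst$config_hash <- config_hash(config)
  lst$package_version <- as.character(utils::packageVersion("ichmorph"))
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

config_hash <- function(config) {
  lst <- unclass(config)
  lst$scale <- config$scale$mm_per_px
  txt <- paste(names(lst), vapply(lst, function(x) paste(format(x), collapse = ","),
                                  character(1)),
               sep = "=", collapse = ";")
  # small polynomial rolling hash; stable across sessions
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
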