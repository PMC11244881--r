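# Batch processing over folders of Day-0/Day-2 image pairs, result
# consolidation and robust outlier flagging.

#' Pair initial/final images in a directory
#'
#' Files are matched by a regular expression with two capture groups: the
#' spheroid id and the timepoint code. The default pattern pairs
#' \code{<id>_d0.<ext>} with \code{<id>_d2.<ext>} (TIFF or PNG). The result
#' is deterministic: pairs are sorted lexicographically by id. Unmatched
#' files are reported with a warning and listed in the
#' \code{"unmatched"} attribute.
#'
#' @param input_dir directory to scan.
#' @param pattern regex with capture group 1 = spheroid id, group 2 =
#'   timepoint (\code{"0"} initial, anything else final).
#' @return data.frame with columns \code{spheroid_id}, \code{day0},
#'   \code{day2} (full paths).
#' @export
pair_images <- function(input_dir,
                        pattern = "^(.*)_[dD]([02])\\.(tif|tiff|png)$") {
  if (!dir.exists(input_dir)) stop("directory not found: ", input_dir)
  files <- sort(list.files(input_dir))
  hit <- grepl(pattern, files)
  unmatched <- files[!hit]
  files <- files[hit]
  if (length(files) == 0L) {
    warning("no images matching the pairing pattern in ", input_dir)
    out <- data.frame(spheroid_id = character(0L), day0 = character(0L),
                      day2 = character(0L), stringsAsFactors = FALSE)
    attr(out, "unmatched") <- unmatched
    return(out)
  }
  id <- sub(pattern, "\\1", files)
  tp <- sub(pattern, "\\2", files)
  key <- paste(id, tp)
  if (anyDuplicated(key))
    stop("ambiguous pairing; multiple files for: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  ids <- sort(unique(id))
  d0 <- files[match(paste(ids, "0"), key)]
  d2 <- files[match(paste(ids, "2"), key)]
  complete <- !is.na(d0) & !is.na(d2)
  incomplete <- c(d0[!complete], d2[!complete])
  incomplete <- incomplete[!is.na(incomplete)]
  if (length(incomplete) > 0L)
    warning("unpaired images excluded: ", paste(incomplete, collapse = ", "))
  out <- data.frame(spheroid_id = ids[complete],
                    day0 = file.path(input_dir, d0[complete]),
                    day2 = file.path(input_dir, d2[complete]),
                    stringsAsFactors = FALSE)
  attr(out, "unmatched") <- c(unmatched, incomplete)
  out
}

#' Read a batch run configuration from YAML or JSON
#'
#' Recognized keys mirror the arguments of [spheroid_invasion()]:
#' \code{threshold}, \code{pixel_size_um}, \code{subtract_background},
#' \code{enhance_contrast}, \code{circular_mask}, \code{pairing_pattern},
#' \code{pca_origin}, \code{random_seed}.
#'
#' @param path path to a .yaml/.yml or .json file.
#' @return named list of settings.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext))
  if (!is.null(cfg$threshold) &&
      (cfg$threshold < 0 || cfg$threshold > 1))
    stop("config: threshold must be in [0, 1]")
  if (!is.null(cfg$pixel_size_um) && cfg$pixel_size_um <= 0)
    stop("config: pixel_size_um must be positive")
  cfg
}

#' Process one Day-0/Day-2 image pair
#'
#' Thin wrapper around [spheroid_invasion()] taking file paths and a config
#' list; returns the one-row record used by [consolidate()].
#'
#' @param day0_path,day2_path image files.
#' @param config named list of settings (see [read_run_config()]).
#' @param spheroid_id identifier; defaults to the Day-0 file stem.
#' @return a one-row data.frame with a \code{status} column (\code{"ok"}),
#'   plus the full \code{spheroid_invasion} fit in attribute \code{"fit"}.
#' @export
process_pair <- function(day0_path, day2_path, config = list(),
                         spheroid_id = NULL) {
  if (is.null(spheroid_id))
    spheroid_id <- sub("_[dD]0$", "",
                       tools::file_path_sans_ext(basename(day0_path)))
  fit <- spheroid_invasion(
    day0_path, day2_path,
    pixel_size_um = config$pixel_size_um %||% 1,
    threshold = config$threshold %||% 0.16,
    subtract_background = isTRUE(config$subtract_background),
    enhance_contrast = isTRUE(config$enhance_contrast),
    circular_mask = config$circular_mask %||% TRUE,
    pca_origin = config$pca_origin %||% "mean",
    spheroid_id = spheroid_id)
  rec <- as.data.frame(fit)
  rec$status <- "ok"
  rec$message <- ""
  attr(rec, "fit") <- fit
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# empty record schema used for failed spheroids
.error_record <- function(spheroid_id, message) {
  data.frame(spheroid_id = spheroid_id, delta_area_mm2 = NA_real_,
             mean_distance_mm = NA_real_, max_distance_mm = NA_real_,
             radial_moment_mm4 = NA_real_, n_outer_pixels = NA_integer_,
             shrinkage = NA, angle_max_deg = NA_real_,
             angle_min_deg = NA_real_, I_max_mm4 = NA_real_,
             I_min_mm4 = NA_real_, mean_d_max_mm = NA_real_,
             mean_d_min_mm = NA_real_, fold_change_moment = NA_real_,
             fold_change_distance = NA_real_, isotropic = NA,
             status = "error", message = message, stringsAsFactors = FALSE)
}

#' Flag outliers by scaled median absolute deviation
#'
#' Scaled MAD = 1.4826 x median(|x - median(x)|). Values farther than
#' \code{k} scaled MADs from the median are flagged. When the scaled MAD is
#' zero (more than half the values identical), every value differing from
#' the median is flagged.
#'
#' @param values numeric vector, length >= 1 (NAs are never flagged).
#' @param k multiplier; the conventional cut is 3.
#' @return list with \code{kept} (values retained), \code{removed_indices}
#'   (integer positions flagged) and \code{outlier} (logical vector).
#' @export
mad_outlier_filter <- function(values, k = 3) {
  if (length(values) == 0L) stop("empty input")
  med <- stats::median(values, na.rm = TRUE)
  s <- stats::mad(values, na.rm = TRUE)  # constant 1.4826 by default
  dev <- abs(values - med)
  out <- if (is.na(s) || s == 0) dev > 0 else dev > k * s
  out[is.na(out)] <- FALSE
  list(kept = values[!out], removed_indices = which(out), outlier = out)
}

#' Consolidate per-spheroid records into one table
#'
#' Binds records into a single data.frame with a stable column order and
#' adds per-metric outlier flags computed with [mad_outlier_filter()] over
#' the successfully processed rows. Outliers are flagged, never dropped, so
#' every input record is preserved for audit.
#'
#' @param records list of one-row data.frames from [process_pair()]
#'   (failed spheroids contribute rows with \code{status = "error"}).
#' @param k MAD multiplier for outlier flagging.
#' @param outlier_metrics columns to screen for outliers.
#' @return data.frame, one row per spheroid, with logical
#'   \code{outlier_<metric>} columns and a combined \code{outlier} column.
#' @export
consolidate <- function(records, k = 3,
                        outlier_metrics = c("delta_area_mm2",
                                            "mean_distance_mm",
                                            "radial_moment_mm4")) {
  if (length(records) == 0L)
    return(.error_record("x", "")[0L, ])
  tab <- do.call(rbind, lapply(records, function(r) {
    attr(r, "fit") <- NULL
    r
  }))
  if (anyDuplicated(tab$spheroid_id))
    stop("duplicate spheroid_id in records: ",
         paste(unique(tab$spheroid_id[duplicated(tab$spheroid_id)]),
               collapse = ", "))
  any_out <- rep(FALSE, nrow(tab))
  for (mcol in outlier_metrics) {
    flag <- rep(FALSE, nrow(tab))
    ok <- tab$status == "ok" & !is.na(tab[[mcol]])
    if (sum(ok) > 0L)
      flag[ok] <- mad_outlier_filter(tab[[mcol]][ok], k = k)$outlier
    tab[[paste0("outlier_", mcol)]] <- flag
    any_out <- any_out | flag
  }
  tab$outlier <- any_out
  rownames(tab) <- NULL
  tab
}

#' Run the full pipeline over a directory of image pairs
#'
#' Pairs images, processes each pair (fail-soft: an error in one spheroid
#' is recorded in its row and the batch continues), writes per-spheroid
#' pixel CSVs, the consolidated metrics table, a directionality table and
#' a JSON run manifest. Outputs are byte-reproducible for fixed inputs and
#' configuration.
#'
#' @param input_dir directory of images (see [pair_images()]).
#' @param output_dir directory for results (created if needed).
#' @param config named list of settings; see [read_run_config()].
#' @param drop_outliers also write \code{metrics_filtered.csv} with
#'   MAD-flagged rows removed.
#' @param verbose print per-spheroid progress.
#' @return the consolidated data.frame, invisibly.
#' @export
run_batch <- function(input_dir, output_dir, config = list(),
                      drop_outliers = FALSE, verbose = FALSE) {
  pairs <- pair_images(input_dir,
                       pattern = config$pairing_pattern %||%
                         "^(.*)_[dD]([02])\\.(tif|tiff|png)$")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(output_dir, "pixels"), showWarnings = FALSE)
  records <- vector("list", nrow(pairs))
  logline <- character(0L)
  for (i in seq_len(nrow(pairs))) {
    id <- pairs$spheroid_id[i]
    rec <- tryCatch(
      process_pair(pairs$day0[i], pairs$day2[i], config, spheroid_id = id),
      error = function(e) .error_record(id, conditionMessage(e)))
    if (rec$status == "ok") {
      fit <- attr(rec, "fit")
      write_pixel_csv(fit$cloud,
                      file.path(output_dir, "pixels", paste0(id, ".csv")))
      logline <- c(logline, sprintf("INFO %s: %d outer px, dA %.4g mm2",
                                    id, rec$n_outer_pixels,
                                    rec$delta_area_mm2))
      if (isTRUE(rec$shrinkage))
        logline <- c(logline, sprintf("WARNING %s: spheroid shrinkage", id))
      if (isTRUE(rec$isotropic))
        logline <- c(logline, sprintf("WARNING %s: isotropic invasion", id))
    } else {
      logline <- c(logline, sprintf("ERROR %s: %s", id, rec$message))
    }
    if (verbose) message(utils::tail(logline, 1L))
    records[[i]] <- rec
  }
  tab <- consolidate(records)
  utils::write.csv(tab, file.path(output_dir, "metrics.csv"),
                   row.names = FALSE)
  dir_cols <- c("spheroid_id", "angle_max_deg", "angle_min_deg",
                "I_max_mm4", "I_min_mm4", "mean_d_max_mm", "mean_d_min_mm",
                "fold_change_moment", "fold_change_distance", "isotropic")
  utils::write.csv(tab[, intersect(dir_cols, names(tab))],
                   file.path(output_dir, "directionality.csv"),
                   row.names = FALSE)
  if (isTRUE(drop_outliers))
    utils::write.csv(tab[!tab$outlier, ],
                     file.path(output_dir, "metrics_filtered.csv"),
                     row.names = FALSE)
  writeLines(logline, file.path(output_dir, "run.log"))
  manifest <- list(
    package = "invquant",
    version = as.character(utils::packageVersion("invquant")),
    config = config,
    n_pairs = nrow(pairs),
    unmatched = as.character(attr(pairs, "unmatched")))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(tab)
}
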