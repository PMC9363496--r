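# Pipeline orchestration, configuration, and delimited-text pulse tables.

pulse_table_columns <- c("datetime", "onset_s", "type", "cf_hz", "bw_hz",
                         "snr_db", "ipi_s")

#' Pipeline configuration
#'
#' One nested plain list holding every stage's parameters, with defaults
#' set to the published analysis values. Round-trips losslessly through
#' YAML serialization.
#'
#' @param seed Global seed; all pipeline randomness derives from it.
#' @return A `fin_pipeline_config` nested list.
#' @export
pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    frontend = list(target_rate = 200, fft_size = 256, hop = 32,
                    n_mels = 128, f_min = 0, f_max = 100),
    cnn = list(n_layers = 3, kernel = 5, channels = c(128, 128, 1),
               dropout = 0.25),
    training = list(epochs = 50, batch = 16, lr = 0.001, lr_decay = 0.03,
                    weight_decay = 0.04, positive_oversampling = 4,
                    augment_snr = -3, window = 5),
    detection = list(threshold = 0.5, min_separation = 4),
    analysis = list(window_s = 8, out_rate = 250, band = c(10, 30),
                    win_length = 256, n_fft = 1024, hop = 8,
                    dedup_s = 2),
    filters = list(max_bw = 6, cf_range = c(18.5, 22.5), min_snr = 8,
                   min_pulses = 3, ipi_range = c(11, 45), seq_gap = 45,
                   bout_gap = 7200),
    gmm = list(restarts = 5, tol = 1e-6, max_iter = 500,
               fallback_threshold = 19.96, min_fit_pulses = 50),
    trends = list(ipi_resolution = 0.1, ipi_min_count = 100,
                  ipi_min_fraction = 0.05, cf_resolution = 0.1,
                  cf_min_count = 200)
  ), class = "fin_pipeline_config")
}

#' Write / read a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_config` returns the configuration list.
#' @export
write_config <- function(config, path) {
  writeLines(yaml::as.yaml(unclass(config)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  structure(yaml::yaml.load_file(path), class = "fin_pipeline_config")
}

# tiny FNV-1a hash for manifests (no external digest dependency)
config_hash <- function(config) {
  bytes <- utf8ToInt(yaml::as.yaml(unclass(config))) %% 256
  h <- 216613626
  for (b in bytes) h <- (bitwXor(h, b) * 16777619) %% 2^31
  sprintf("%08x", h)
}

#' Write a pulse-record table
#'
#' Tab-delimited UTF-8 text with a header row and ISO-8601 datetimes;
#' columns `datetime`, `onset_s`, `type`, `cf_hz`, `bw_hz`, `snr_db`,
#' `ipi_s` (extra columns are preserved).
#'
#' @param records Pulse-record data frame.
#' @param path Output path.
#' @export
write_pulse_table <- function(records, path) {
  missing <- setdiff(pulse_table_columns, names(records))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  out <- records
  out$datetime <- format(as.POSIXct(out$datetime, tz = "UTC"),
                         "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a pulse-record table
#'
#' Reads tables written by [write_pulse_table()] (tab-delimited, header
#' row). Unknown extra columns are tolerated; missing required columns and
#' malformed datetimes are reported with their names / line numbers.
#'
#' @param path Input path.
#' @return Pulse-record data frame with POSIXct `datetime`.
#' @export
read_pulse_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(pulse_table_columns, names(tab))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  # strptime returns NA on mismatch instead of throwing, so malformed rows
  # can be reported with their line numbers
  dt <- as.POSIXct(rep(NA_real_, nrow(tab)), origin = "1970-01-01",
                   tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    miss <- is.na(dt)
    if (!any(miss)) break
    parsed <- strptime(tab$datetime[miss], fmt, tz = "UTC")
    dt[miss] <- as.POSIXct(parsed, tz = "UTC")
  }
  bad <- which(is.na(dt) & !is.na(tab$datetime) & tab$datetime != "")
  if (length(bad) > 0) {
    stop("malformed datetime on line(s): ",
         paste(bad + 1, collapse = ", ")) # +1 for the header row
  }
  tab$datetime <- dt
  tab
}

#' Run the full detection-to-trends pipeline
#'
#' Executes detect, analyze, filter, classify and trend stages on one or
#' more recordings, recording stage counts in a manifest. Counts are
#' non-increasing across the filter stages.
#'
#' @param model A trained `fin_cnn`.
#' @param recordings List of recordings, each a list with `waveform`,
#'   `sampling_rate`, and `start_time` (POSIXct).
#' @param config A [pipeline_config()].
#' @return List: `records` (filtered, typed pulse table), `bigrams`,
#'   `gmm` (the type GMM or `NULL`), `threshold` (type threshold used),
#'   `trends` (per-bigram IPI trends + monthly cf trend), `manifest`.
#' @export
run_pipeline <- function(model, recordings, config = pipeline_config()) {
  stopifnot(inherits(model, "fin_cnn"))
  t_start <- Sys.time()
  all_records <- list()
  n_detections <- 0L
  for (ri in seq_along(recordings)) {
    rec <- recordings[[ri]]
    wf <- preprocess(rec$waveform, rec$sampling_rate,
                     config$frontend$target_rate)
    scores <- predict_frames(model, wf)
    det <- detect(scores, config$detection$threshold,
                  config$detection$min_separation)
    n_detections <- n_detections + nrow(det)
    if (nrow(det) == 0) next
    rows <- lapply(det$time, function(tt) {
      analyze_pulse(wf, config$frontend$target_rate, tt)
    })
    rows <- do.call(rbind, rows)
    # the refined times collapse duplicate detections of one pulse onto the
    # same instant; keep the strongest record of each such group
    rows <- rows[order(rows$t_s), , drop = FALSE]
    if (nrow(rows) > 1 && config$analysis$dedup_s > 0) {
      grp <- cumsum(c(1, as.integer(diff(rows$t_s) >=
                                      config$analysis$dedup_s)))
      keep <- unlist(lapply(split(seq_len(nrow(rows)), grp), function(i) {
        i[which.max(rows$snr_db[i])]
      }))
      rows <- rows[sort(keep), , drop = FALSE]
    }
    rows$datetime <- as.POSIXct(rec$start_time, tz = "UTC") + rows$t_s
    rows$onset_s <- rows$t_s
    rows$recording <- ri
    all_records[[length(all_records) + 1]] <- rows
  }
  records <- if (length(all_records) > 0) {
    do.call(rbind, all_records)
  } else {
    data.frame(t_s = numeric(), cf_hz = numeric(), bw_hz = numeric(),
               snr_db = numeric(), peak_hz = numeric(),
               centroid_hz = numeric(), valid = logical(),
               edge_padded = logical(),
               datetime = as.POSIXct(character(), tz = "UTC"),
               onset_s = numeric(), recording = integer())
  }
  n_analyzed <- nrow(records)
  # pulse-level filters, then sequence formation on absolute time, then
  # sequence-level filters
  records <- filter_pulses(records, config$filters$max_bw,
                           config$filters$cf_range)
  n_pulse_filtered <- nrow(records)
  if (nrow(records) > 0) {
    records$t_abs <- as.numeric(records$datetime)
    records <- records[order(records$t_abs), ]
    tmp <- records
    tmp$t_s <- tmp$t_abs
    tmp <- group_sequences(tmp, config$filters$seq_gap)
    tmp <- group_bouts(tmp, config$filters$bout_gap)
    records$seq_id <- tmp$seq_id
    records$bout_id <- tmp$bout_id
    n_sequences <- length(unique(records$seq_id))
    tmp <- filter_sequences(tmp, config$filters$min_snr,
                            config$filters$min_pulses,
                            config$filters$ipi_range)
    records <- records[records$seq_id %in% unique(tmp$seq_id), ,
                       drop = FALSE]
  } else {
    records$t_abs <- numeric(0)
    records$seq_id <- integer(0)
    records$bout_id <- integer(0)
    n_sequences <- 0L
  }
  n_seq_filtered <- nrow(records)
  # classification
  g <- NULL
  threshold <- config$gmm$fallback_threshold
  if (nrow(records) >= config$gmm$min_fit_pulses &&
      length(unique(records$cf_hz)) >= 2) {
    g <- fit_gmm_1d(records$cf_hz, seed = config$seed,
                    restarts = config$gmm$restarts,
                    max_iter = config$gmm$max_iter, tol = config$gmm$tol)
    threshold <- type_threshold(g)
  }
  records <- assign_types(records, threshold)
  # bi-grams per sequence
  bigrams <- NULL
  if (nrow(records) > 0) {
    bg <- lapply(split(records, records$seq_id), function(r) {
      r <- r[order(r$t_abs), ]
      r$t_s <- r$t_abs
      label_bigrams(r)
    })
    bigrams <- do.call(rbind, bg)
    rownames(bigrams) <- NULL
  }
  # trends (gates usually leave these empty on short runs)
  trends <- list()
  if (!is.null(bigrams) && nrow(bigrams) > 0) {
    for (lb in c("AA", "AB", "BA", "BB")) {
      trends[[lb]] <- ipi_trend(bigrams, lb,
                                config$trends$ipi_resolution,
                                config$trends$ipi_min_count,
                                config$trends$ipi_min_fraction)
    }
  }
  if (nrow(records) > 0) {
    trends$cf_monthly <- monthly_cf_trend(records,
                                          config$trends$cf_resolution,
                                          config$trends$cf_min_count)
  }
  manifest <- list(
    config_hash = config_hash(config),
    started = format(t_start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    n_recordings = length(recordings),
    counts = list(detections = n_detections,
                  analyzed = n_analyzed,
                  after_pulse_filter = n_pulse_filtered,
                  sequences = n_sequences,
                  after_sequence_filter = n_seq_filtered,
                  type_a = sum(records$type == "A"),
                  type_b = sum(records$type == "B"))
  )
  list(records = records, bigrams = bigrams, gmm = g, threshold = threshold,
       trends = trends, manifest = manifest)
}
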