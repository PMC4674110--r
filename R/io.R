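# Readers, writers and the end-to-end pipeline driver.
#
# Label files use the Audacity-compatible 3-column TSV dialect with a header
# (onset_s, offset_s, label); tables are CSV with explicit headers; nested
# reports are JSON. WAV I/O is a minimal RIFF PCM implementation (mono,
# 8/16/32-bit integer) written here because the analysis needs nothing more.

#' Read a syllable label file
#'
#' Tab-separated with header `onset_s`, `offset_s`, `label`; one row per
#' syllable, time-ordered. Malformed rows are reported with their line
#' numbers; overlapping intervals, non-monotone times and multi-character
#' labels are errors.
#'
#' @param path File path.
#' @param rendition_id Rendition identifier; defaults to the file name
#'   without extension.
#' @return Tibble with `rendition_id`, `label`, `onset_s`, `offset_s`.
#' @export
read_label_file <- function(path, rendition_id = NULL) {
  if (is.null(rendition_id)) {
    rendition_id <- sub("\\.[^.]*$", "", basename(path))
  }
  d <- readr::read_tsv(path, col_types = readr::cols(
    onset_s = readr::col_double(),
    offset_s = readr::col_double(),
    label = readr::col_character()))
  if (!all(c("onset_s", "offset_s", "label") %in% names(d))) {
    abort(sprintf("%s: header must be onset_s, offset_s, label", basename(path)))
  }
  line <- seq_len(nrow(d)) + 1L   # header is line 1
  bad <- which(is.na(d$onset_s) | is.na(d$offset_s) | is.na(d$label))
  if (length(bad)) {
    abort(sprintf("%s: malformed rows at lines %s", basename(path),
                  paste(line[bad], collapse = ", ")))
  }
  multi <- which(nchar(d$label) != 1)
  if (length(multi)) {
    abort(sprintf("%s: multi-character labels at lines %s", basename(path),
                  paste(line[multi], collapse = ", ")))
  }
  neg <- which(d$offset_s <= d$onset_s | d$onset_s < 0)
  if (length(neg)) {
    abort(sprintf("%s: offset <= onset (or negative time) at lines %s",
                  basename(path), paste(line[neg], collapse = ", ")))
  }
  if (nrow(d) > 1) {
    nonmono <- which(diff(d$onset_s) < 0) + 1L
    if (length(nonmono)) {
      abort(sprintf("%s: non-monotone onsets at lines %s", basename(path),
                    paste(line[nonmono], collapse = ", ")))
    }
    ov <- which(d$onset_s[-1] < d$offset_s[-nrow(d)] - 1e-9) + 1L
    if (length(ov)) {
      abort(sprintf("%s: overlapping intervals at lines %s", basename(path),
                    paste(line[ov], collapse = ", ")))
    }
    close_ <- which(d$onset_s[-1] - d$offset_s[-nrow(d)] < 0.005 - 1e-9) + 1L
    if (length(close_)) {
      warn(sprintf("%s: gaps below 5 ms at lines %s (syllables are defined by >= 5 ms of silence)",
                   basename(path), paste(line[close_], collapse = ", ")))
    }
  }
  tibble(rendition_id = rendition_id, label = d$label,
         onset_s = d$onset_s, offset_s = d$offset_s)
}

#' Write a syllable label file
#'
#' @param intervals Tibble with `label`, `onset_s`, `offset_s`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_file <- function(intervals, path) {
  readr::write_tsv(intervals[, c("onset_s", "offset_s", "label")], path)
  invisible(path)
}

#' Write a corpus to disk
#'
#' One label TSV per rendition (and optionally one PCM WAV), plus the ground
#' truth as JSON. File names are `<condition>_<rendition_id>.{txt,wav}`.
#'
#' @param corpus A `"song_corpus"`.
#' @param dir Output directory (created if needed).
#' @param waveforms Render and write audio as well.
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir, waveforms = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ev <- corpus$events
  for (d in split(ev, ~ condition + rendition_id, drop = TRUE)) {
    d <- d[order(d$position), ]
    stem <- paste0(d$condition[1], "_", d$rendition_id[1])
    write_label_file(d, file.path(dir, paste0(stem, ".txt")))
  }
  if (waveforms) {
    wavs <- render_corpus(corpus)
    for (nm in names(wavs)) {
      stem <- sub("\\.", "_", nm)
      write_wav(wavs[[nm]]$samples, wavs[[nm]]$sample_rate,
                file.path(dir, paste0(stem, ".wav")))
    }
  }
  truth <- corpus$truth
  truth$seed <- corpus$config$seed
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read all label files from a directory
#'
#' @param dir Directory of `.txt` label TSVs; file stems become rendition
#'   ids. Stems of the form `<condition>_<rendition>` split into condition
#'   and rendition when `split_condition = TRUE`.
#' @param bird_pattern Regular expression extracting the bird id from the
#'   rendition id (first capture group), or `NULL` for a single bird.
#' @param split_condition Interpret the stem prefix as a condition tag.
#' @return Combined tibble of labelled intervals with `bird_id`,
#'   `condition`, `rendition_id`, `position` columns.
#' @export
read_labels_dir <- function(dir, bird_pattern = "(b[0-9]+)",
                            split_condition = TRUE) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (!length(files)) abort(sprintf("no label files found in %s", dir))
  all <- lapply(files, read_label_file)
  d <- bind_rows(all)
  if (split_condition && all(grepl("^[^_]+_", d$rendition_id))) {
    d$condition <- sub("_.*$", "", d$rendition_id)
    d$rendition_id <- sub("^[^_]+_", "", d$rendition_id)
  } else {
    d$condition <- "A"
  }
  if (!is.null(bird_pattern)) {
    m <- regmatches(d$rendition_id, regexpr(bird_pattern, d$rendition_id))
    d$bird_id <- if (length(m) == nrow(d)) m else "bird01"
  } else {
    d$bird_id <- "bird01"
  }
  d <- d[order(d$bird_id, d$condition, d$rendition_id, d$onset_s), ]
  d$position <- ave(seq_len(nrow(d)),
                    paste(d$bird_id, d$condition, d$rendition_id),
                    FUN = seq_along)
  d
}

# ---- minimal RIFF/WAVE PCM I/O -------------------------------------------

#' Write a mono PCM WAV file
#'
#' @param samples Numeric samples in \[-1, 1\] (clipped if outside).
#' @param rate Sampling rate in Hz.
#' @param path Output path.
#' @param bits Bits per sample: 8, 16 or 32 (integer PCM).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path, bits = 16) {
  stopifnot(bits %in% c(8, 16, 32))
  x <- pmax(-1, pmin(1, samples))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")       # PCM
  writeBin(1L, con, size = 2, endian = "little")       # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 8) {
    writeBin(as.integer(round((x + 1) / 2 * 255)), con, size = 1)
  } else if (bits == 16) {
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(round(x * 2147483647)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono PCM WAV file
#'
#' Supports uncompressed integer PCM (8/16/32-bit), mono; rates of at least
#' 8 kHz are expected downstream.
#'
#' @param path File path.
#' @return List with `samples` (numeric in \[-1, 1\]) and `rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) abort(sprintf("%s: not a RIFF file", basename(path)))
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) abort(sprintf("%s: not a WAVE file", basename(path)))
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt != 1) abort("only uncompressed PCM WAV is supported")
      channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      if (is.null(bits)) abort("data chunk before fmt chunk")
      nsmp <- size / (bits / 8)
      if (bits == 8) {
        raw8 <- readBin(con, "integer", nsmp, size = 1, signed = FALSE)
        samples <- raw8 / 255 * 2 - 1
      } else if (bits == 16) {
        samples <- readBin(con, "integer", nsmp, size = 2,
                           endian = "little") / 32767
      } else if (bits == 32) {
        samples <- readBin(con, "integer", nsmp, size = 4,
                           endian = "little") / 2147483647
      } else {
        abort(sprintf("unsupported bit depth: %d", bits))
      }
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(samples)) abort(sprintf("%s: no data chunk found", basename(path)))
  if (!is.null(channels) && channels > 1) {
    samples <- samples[seq(1, length(samples), by = channels)]  # first channel
  }
  list(samples = samples, rate = rate)
}

# ---- flat key-value generator config files --------------------------------

#' Write a generator configuration as flat key-value text
#'
#' Scalar fields are written as `key = value`; branch specs as
#' `branch.<ctx> = target:prob,...`; chains as a comma-separated list.
#'
#' @param config A [song_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_song_config <- function(config, path) {
  lines <- c(
    sprintf("n_birds = %d", config$n_birds),
    sprintf("renditions_per_bird = %d", config$renditions_per_bird),
    sprintf("seed = %d", config$seed),
    sprintf("start_label = %s", config$start_label),
    sprintf("end_token = %s", config$end_token),
    sprintf("max_syllables = %d", config$max_syllables),
    sprintf("bird_concentration = %.10g", config$bird_concentration),
    sprintf("chains = %s", paste(config$stereotyped_chains, collapse = ",")),
    vapply(names(config$branch_specs), function(ctx) {
      p <- config$branch_specs[[ctx]]
      sprintf("branch.%s = %s", ctx,
              paste(sprintf("%s:%.10g", names(p), p), collapse = ","))
    }, character(1)),
    vapply(names(config$gap_model), function(k) {
      sprintf("gap.%s = %.10g", k, config$gap_model[[k]])
    }, character(1)),
    vapply(names(config$waveform), function(k) {
      sprintf("waveform.%s = %.10g", k, config$waveform[[k]])
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key-value generator configuration
#'
#' @param path Path written by [write_song_config()].
#' @return A [song_config()].
#' @export
read_song_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", lines))
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  getv <- function(k, default) if (k %in% keys) vals[keys == k] else default
  branch_keys <- keys[startsWith(keys, "branch.")]
  branch_specs <- setNames(lapply(branch_keys, function(k) {
    parts <- strsplit(vals[keys == k], ",")[[1]]
    pr <- strsplit(parts, ":")
    setNames(vapply(pr, function(x) as.numeric(x[2]), numeric(1)),
             vapply(pr, `[`, character(1), 1))
  }), sub("^branch\\.", "", branch_keys))
  num <- function(k, d) as.numeric(getv(k, d))
  gap_keys <- keys[startsWith(keys, "gap.")]
  gap_model <- setNames(lapply(gap_keys, function(k) as.numeric(vals[keys == k])),
                        sub("^gap\\.", "", gap_keys))
  wf_keys <- keys[startsWith(keys, "waveform.")]
  waveform <- setNames(lapply(wf_keys, function(k) as.numeric(vals[keys == k])),
                       sub("^waveform\\.", "", wf_keys))
  song_config(
    n_birds = as.integer(num("n_birds", 22)),
    renditions_per_bird = as.integer(num("renditions_per_bird", 30)),
    branch_specs = if (length(branch_specs)) branch_specs else default_branch_specs(),
    stereotyped_chains = strsplit(getv("chains", "ib,bcd,ea,kg,ghj"), ",")[[1]],
    gap_model = gap_model,
    waveform = waveform,
    bird_concentration = num("bird_concentration", 12),
    start_label = getv("start_label", "i"),
    end_token = getv("end_token", "*"),
    max_syllables = as.integer(num("max_syllables", 200)),
    seed = as.integer(num("seed", 1))
  )
}

# ---- pipeline -------------------------------------------------------------

#' Run the full sequencing/timing analysis pipeline
#'
#' Executes repeat exclusion, transition counting, context resolution,
#' gap-timing aggregation and the coupling analyses on a corpus (or an event
#' table from [read_labels_dir()]). With two conditions present, the paired
#' change analyses (change records, change-coupling regressions and the
#' category contrast) run as well. The pipeline itself is deterministic:
#' rerunning with the same inputs reproduces every artifact.
#'
#' @param corpus A `"song_corpus"`, or an event tibble with `bird_id`,
#'   `condition`, `rendition_id`, `position`, `label` and either
#'   `gap_to_next_ms` or `onset_s`/`offset_s`.
#' @param out_dir Optional directory for CSV/JSON artifacts.
#' @param alpha Significance level for every test.
#' @param min_occurrences,min_instances Eligibility filters.
#' @param max_context_order Longest history tested.
#' @param change_test `"chisq"` or `"lrt"` for change categorisation.
#' @return List of class `"song_pipeline"`: `branch_points`, `rows` (per
#'   condition), `coupling` fits, `type_contrast`, and when two conditions
#'   are present `change` (`records`, `coupling`, `contrast`), plus a
#'   `report` with surviving row counts, seed and config hash.
#' @export
run_pipeline <- function(corpus, out_dir = NULL, alpha = 0.05,
                         min_occurrences = 10, min_instances = 5,
                         max_context_order = 2,
                         change_test = c("chisq", "lrt")) {
  change_test <- match.arg(change_test)
  if (inherits(corpus, "song_corpus")) {
    events <- corpus$events
    seed <- corpus$config$seed
  } else {
    events <- corpus
    seed <- NA_integer_
    if (!"gap_to_next_ms" %in% names(events)) {
      if (!all(c("onset_s", "offset_s") %in% names(events))) {
        abort("pipeline error [segment]: events carry neither gaps nor boundaries")
      }
      d <- events[order(events$bird_id, events$condition, events$rendition_id,
                        events$position), ]
      n <- nrow(d)
      gid <- paste(d$bird_id, d$condition, d$rendition_id, sep = "\r")
      same <- c(gid[-1] == gid[-n], FALSE)
      gap <- c((d$onset_s[-1] - d$offset_s[-n]) * 1000, NA_real_)
      gap[!same] <- NA_real_
      if (any(gap < 0, na.rm = TRUE)) {
        abort("pipeline error [segment]: negative gaps (overlapping labels)")
      }
      d$gap_to_next_ms <- gap
      events <- d
    }
  }
  if (nrow(events) == 0) abort("pipeline error [segment]: no input events")
  conds <- unique(events$condition)   # order of appearance: baseline first
  events <- exclude_repeats(events)
  tt <- count_transitions(events, max_context_order = max_context_order)
  bp <- resolve_contexts(tt, alpha = alpha, min_occurrences = min_occurrences)
  rows_all <- transition_timing(events, bp, min_instances = min_instances)
  rows <- lapply(setNames(conds, conds), function(cc) {
    r <- filter(rows_all, .data$condition == cc)
    class(r) <- class(rows_all)
    r
  })
  coupling <- lapply(rows, function(r) {
    br <- filter(r, .data$transition_type == "branch")
    if (nrow(br) >= 3 && dplyr::n_distinct(br$bird_id) >= 2) {
      fit_coupling_model(br)
    } else NULL
  })
  type_contrast <- tryCatch(compare_transition_types(rows[[1]]),
                            error = function(e) NULL)
  result <- list(branch_points = bp, rows = rows, coupling = coupling,
                 type_contrast = type_contrast)
  if (length(conds) == 2) {
    bpl <- lapply(setNames(conds, conds), function(cc) {
      structure(filter(bp, .data$condition == cc), class = class(bp))
    })
    rec <- change_records(rows[[1]], rows[[2]], bpl[[1]], bpl[[2]],
                          alpha = alpha, test = change_test)
    chg_fit <- tryCatch(change_coupling_analysis(rec), error = function(e) NULL)
    contrast <- tryCatch(suppressWarnings(category_contrast(rec)),
                         error = function(e) NULL)
    result$change <- list(records = rec, coupling = chg_fit,
                          contrast = contrast)
  }
  cfg_hash <- fnv1a(paste(deparse(list(alpha = alpha,
                                       min_occurrences = min_occurrences,
                                       min_instances = min_instances,
                                       max_context_order = max_context_order,
                                       change_test = change_test)),
                          collapse = ""))
  result$report <- list(
    seed = seed,
    config_hash = cfg_hash,
    n_events = nrow(events),
    n_transitions_counted = sum(tt$n[!is.na(tt$target) & tt$order == 1L]),
    n_branch_points = nrow(distinct(bp, .data$bird_id, .data$condition, .data$context)),
    n_analyzed_branch_points = nrow(distinct(filter(bp, .data$analyzed),
                                             .data$bird_id, .data$condition,
                                             .data$context)),
    n_rows = vapply(rows, nrow, integer(1)),
    n_change_records = if (length(conds) == 2) nrow(result$change$records) else NA_integer_
  )
  class(result) <- "song_pipeline"
  if (!is.null(out_dir)) .write_pipeline(result, out_dir)
  result
}

.write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) {
    df$seed <- result$report$seed
    df$config_hash <- result$report$config_hash
    df
  }
  readr::write_csv(stamp(as_tibble(result$branch_points)),
                   file.path(out_dir, "branch_points.csv"))
  readr::write_csv(stamp(bind_rows(result$rows)),
                   file.path(out_dir, "coupling_rows.csv"))
  fits <- list()
  for (cc in names(result$coupling)) {
    if (!is.null(result$coupling[[cc]])) {
      f <- tidy(result$coupling[[cc]])
      f$analysis <- paste0("coupling_", cc)
      fits[[length(fits) + 1]] <- f
    }
  }
  if (!is.null(result$type_contrast)) {
    f <- tidy(result$type_contrast); f$analysis <- "type_contrast"
    fits[[length(fits) + 1]] <- f
  }
  if (!is.null(result$change$coupling)) {
    f <- tidy(result$change$coupling$dlog10_fit); f$analysis <- "change_dlog10"
    fits[[length(fits) + 1]] <- f
    f <- tidy(result$change$coupling$pct_fit); f$analysis <- "change_pct"
    fits[[length(fits) + 1]] <- f
  }
  if (length(fits)) {
    readr::write_csv(stamp(bind_rows(fits)), file.path(out_dir, "results.csv"))
  }
  if (!is.null(result$change)) {
    readr::write_csv(stamp(as_tibble(result$change$records)),
                     file.path(out_dir, "change_records.csv"))
  }
  jsonlite::write_json(result$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.song_pipeline <- function(x, ...) {
  r <- x$report
  cat(sprintf("<song_pipeline> %d events, %d branch points (%d analysed)\n",
              r$n_events, r$n_branch_points, r$n_analyzed_branch_points))
  for (cc in names(x$coupling)) {
    if (!is.null(x$coupling[[cc]])) {
      f <- x$coupling[[cc]]
      cat(sprintf("  coupling [%s]: slope %.3f +/- %.3f, F(%d, %.1f) = %.1f, p = %.3g\n",
                  cc, f$estimate, f$std_error, f$num_df, f$den_df,
                  f$F_statistic, f$p_value))
    }
  }
  if (!is.null(x$change$coupling)) {
    f <- x$change$coupling$dlog10_fit
    cat(sprintf("  change coupling: slope %.3f +/- %.3f, p = %.3g\n",
                f$estimate, f$std_error, f$p_value))
  }
  invisible(x)
}
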