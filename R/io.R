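# On-disk interchange. All formats are plain-text CSV: a main data file
# plus sidecar files derived from its name ("_events.csv", "_meta.csv").
# Doubles are serialized with %.17g, which round-trips IEEE float64
# exactly, so load(save(x)) is bit-identical on payload arrays.

fmt_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

sidecar_path <- function(path, suffix) {
  sub("(\\.[A-Za-z0-9]+)?$", paste0("_", suffix, ".csv"),
      path, perl = TRUE)
}

write_csv_raw <- function(df, path) {
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE, qmethod = "double",
                     na = "NA")
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("'%s' is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")))
  }
}

check_format <- function(format) {
  format <- match.arg(format, c("csv", "hdf5"))
  if (format == "hdf5") {
    stop("format 'hdf5' is not supported by this build; use 'csv'")
  }
  format
}

#' Save a photometry recording to CSV
#'
#' Writes the main trace file (columns `time_s`, `ch465`, `ch405`), an
#' events sidecar (`<stem>_events.csv`: `onset_s`, `offset_s`) and a
#' meta sidecar (`<stem>_meta.csv`: `key`, `value`) holding `fs` and any
#' free-form metadata. Doubles are written at full precision so the
#' round-trip through [load_photometry()] is lossless.
#'
#' @param rec a valid [photometry_recording()].
#' @param path path of the main CSV file.
#' @param format only `"csv"` is supported.
#' @return `path`, invisibly.
#' @export
save_photometry <- function(rec, path, format = "csv") {
  check_format(format)
  validate_photometry_recording(rec)
  n <- length(rec$ch465)
  time_s <- (seq_len(n) - 1L) / rec$fs
  write_csv_raw(
    data.frame(time_s = fmt_full(time_s), ch465 = fmt_full(rec$ch465),
               ch405 = fmt_full(rec$ch405)),
    path)
  write_csv_raw(
    data.frame(onset_s = fmt_full(rec$tone_onsets),
               offset_s = fmt_full(rec$tone_offsets)),
    sidecar_path(path, "events"))
  meta <- c(list(fs = fmt_full(rec$fs)),
            lapply(rec$meta, as.character))
  write_csv_raw(
    data.frame(key = names(meta), value = unlist(meta, use.names = FALSE)),
    sidecar_path(path, "meta"))
  invisible(path)
}

#' Load a photometry recording from CSV
#'
#' Counterpart of [save_photometry()]. The sampling rate is taken from
#' the meta sidecar; if that file is absent, `fs` is inferred from the
#' spacing of the `time_s` column with a warning. Any invariant
#' violation in the file (missing channel, non-monotone onsets, ...) is
#' rejected with the invariant named.
#'
#' @param path path of the main CSV file.
#' @param format only `"csv"` is supported.
#' @return a [photometry_recording()].
#' @export
load_photometry <- function(path, format = "csv") {
  check_format(format)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  df <- utils::read.csv(path)
  require_columns(df, c("time_s", "ch465", "ch405"), path)

  ev_path <- sidecar_path(path, "events")
  onsets <- numeric(0); offsets <- numeric(0)
  if (file.exists(ev_path)) {
    ev <- utils::read.csv(ev_path)
    require_columns(ev, c("onset_s", "offset_s"), ev_path)
    onsets <- ev$onset_s; offsets <- ev$offset_s
  }

  meta_path <- sidecar_path(path, "meta")
  meta <- list(); fs <- NA_real_
  if (file.exists(meta_path)) {
    md <- utils::read.csv(meta_path, colClasses = "character")
    require_columns(md, c("key", "value"), meta_path)
    meta <- as.list(md$value); names(meta) <- md$key
    fs <- as.numeric(meta[["fs"]])
    meta[["fs"]] <- NULL
  }
  if (!is.finite(fs)) {
    dt <- diff(df$time_s)
    if (!length(dt) || any(dt <= 0)) {
      stop(sprintf("'%s': cannot infer fs from time_s", path))
    }
    fs <- 1 / stats::median(dt)
    warning(sprintf("'%s': no meta sidecar; fs inferred as %.6g Hz",
                    path, fs))
  }
  photometry_recording(df$ch465, df$ch405, fs, onsets, offsets, meta)
}

#' Save a set of voltage-clamp sweeps to CSV
#'
#' Long-format data file (columns `sweep`, `t_s`, `i_pa`) plus a meta
#' sidecar (`sweep`, `fs`, `holding_mv`, `stim_times` with
#' semicolon-separated times). Full float64 precision.
#'
#' @param sweeps list of [sweep_vc()] objects.
#' @param path path of the main CSV file.
#' @param format only `"csv"` is supported.
#' @return `path`, invisibly.
#' @export
save_sweepset <- function(sweeps, path, format = "csv") {
  check_format(format)
  lapply(sweeps, validate_sweep)
  dat <- do.call(rbind, lapply(seq_along(sweeps), function(k) {
    sw <- sweeps[[k]]
    data.frame(sweep = k, t_s = fmt_full(sw$t), i_pa = fmt_full(sw$i))
  }))
  write_csv_raw(dat, path)
  meta <- do.call(rbind, lapply(seq_along(sweeps), function(k) {
    sw <- sweeps[[k]]
    data.frame(sweep = k, fs = fmt_full(sw$fs),
               holding_mv = fmt_full(sw$holding_mv),
               stim_times = paste(fmt_full(sw$stim_times), collapse = ";"))
  }))
  write_csv_raw(meta, sidecar_path(path, "meta"))
  invisible(path)
}

#' Load a set of voltage-clamp sweeps from CSV
#'
#' Counterpart of [save_sweepset()]. A missing `holding_mv` column in
#' the meta sidecar defaults to -70 mV (the recording configuration the
#' analyses assume) with a warning.
#'
#' @param path path of the main CSV file.
#' @param format only `"csv"` is supported.
#' @return list of [sweep_vc()] objects.
#' @export
load_sweepset <- function(path, format = "csv") {
  check_format(format)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  df <- utils::read.csv(path)
  require_columns(df, c("sweep", "t_s", "i_pa"), path)

  meta_path <- sidecar_path(path, "meta")
  meta <- NULL
  if (file.exists(meta_path)) {
    meta <- utils::read.csv(meta_path,
                            colClasses = c(stim_times = "character"))
    require_columns(meta, c("sweep", "fs"), meta_path)
    if (!"holding_mv" %in% names(meta)) {
      warning("holding_mv absent; defaulting to -70 mV")
      meta$holding_mv <- -70
    }
  }
  ids <- sort(unique(df$sweep))
  lapply(ids, function(k) {
    sub <- df[df$sweep == k, , drop = FALSE]
    if (!is.null(meta)) {
      mrow <- meta[meta$sweep == k, , drop = FALSE]
      if (nrow(mrow) != 1) {
        stop(sprintf("'%s': sweep %s missing from meta sidecar",
                     meta_path, k))
      }
      fs <- mrow$fs
      hv <- mrow$holding_mv
      st <- if (!is.null(mrow$stim_times) && !is.na(mrow$stim_times) &&
                nzchar(mrow$stim_times) && mrow$stim_times != "NA") {
        as.numeric(strsplit(mrow$stim_times, ";")[[1]])
      } else numeric(0)
    } else {
      dt <- diff(sub$t_s)
      fs <- 1 / stats::median(dt)
      warning(sprintf("'%s': no meta sidecar; fs inferred for sweep %s",
                      path, k))
      hv <- -70
      st <- numeric(0)
    }
    sweep_vc(sub$t_s, sub$i_pa, fs, holding_mv = hv, stim_times = st)
  })
}

#' Write a table of homogeneous records as RFC-4180 CSV
#'
#' Header row plus one line per record; doubles serialized at full
#' precision (round-trip exact); fields containing commas, quotes or
#' newlines are quoted with doubled inner quotes.
#'
#' @param rows a data.frame, or a list of identically-named lists.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  if (is.data.frame(rows)) {
    df <- rows
  } else {
    if (!length(rows)) stop("write_table: empty record list; pass a ",
                            "0-row data.frame for a header-only file")
    nms <- lapply(rows, names)
    if (any(vapply(nms, function(x) !identical(x, nms[[1]]), logical(1)))) {
      stop("write_table: ragged records (field names differ)")
    }
    df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  }
  out <- df
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (is.double(v)) {
      out[[j]] <- fmt_full(v)
    } else {
      v <- as.character(v)
      needs <- grepl('[",\n]', v)
      v[needs] <- paste0('"', gsub('"', '""', v[needs]), '"')
      out[[j]] <- v
    }
  }
  header <- paste(names(out), collapse = ",")
  body <- if (nrow(out)) do.call(paste, c(unname(as.list(out)), sep = ","))
          else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}
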