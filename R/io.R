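#' Read and write CID spectra
#'
#' MGF files carry one `BEGIN IONS`/`END IONS` block per spectrum with
#' `PEPMASS` (the \[M-H\]- parent m/z), optional `RTINSECONDS` and
#' `TITLE`, and one `m/z intensity` peak per line (intensity optional).
#' CSV files carry one peak per row with columns `parent_mz`, `rt_min`,
#' `mz`, `intensity` and optionally `source_label`; rows sharing a
#' (label, parent, RT) triple form one spectrum.
#'
#' @param path File path.
#' @return `read_spectra_mgf`/`read_spectra_csv` return a list of
#'   [spectrum_record()] objects.
#' @export
read_spectra_mgf <- function(path) {
  if (!file.exists(path)) parse_error("file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  spectra <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (lines[i] != "BEGIN IONS") {
      if (nzchar(lines[i]) && !startsWith(lines[i], "#"))
        parse_error("line %d: expected BEGIN IONS", i)
      i <- i + 1L
      next
    }
    pep <- NA_real_; rt <- NA_real_; title <- ""
    mz <- numeric(0); inten <- numeric(0)
    i <- i + 1L
    repeat {
      if (i > length(lines)) parse_error("unterminated spectrum block")
      ln <- lines[i]
      if (ln == "END IONS") { i <- i + 1L; break }
      if (grepl("^PEPMASS=", ln)) {
        pep <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "[ \t]")[[1L]][1L])
      } else if (grepl("^RTINSECONDS=", ln)) {
        rt <- as.numeric(sub("^RTINSECONDS=", "", ln)) / 60
      } else if (grepl("^TITLE=", ln)) {
        title <- sub("^TITLE=", "", ln)
      } else if (grepl("^[0-9]", ln)) {
        parts <- as.numeric(strsplit(ln, "[ \t]+")[[1L]])
        if (anyNA(parts)) parse_error("line %d: malformed peak line", i)
        mz <- c(mz, parts[1L])
        inten <- c(inten, if (length(parts) > 1L) parts[2L] else NA_real_)
      } else if (nzchar(ln) && !grepl("=", ln)) {
        parse_error("line %d: unrecognized MGF content", i)
      }
      i <- i + 1L
    }
    if (is.na(pep)) parse_error("spectrum block without PEPMASS")
    spectra[[length(spectra) + 1L]] <-
      spectrum_record(pep, data.frame(mz = mz, intensity = inten),
                      rt_min = rt, source_label = title)
  }
  spectra
}

#' @rdname read_spectra_mgf
#' @param spectra A list of [spectrum_record()] objects.
#' @export
write_spectra_mgf <- function(spectra, path) {
  out <- character(0)
  for (s in spectra) {
    out <- c(out, "BEGIN IONS",
             paste0("TITLE=", s$source_label),
             paste0("PEPMASS=", format_num(s$parent_mz)))
    if (!is.na(s$rt_min))
      out <- c(out, paste0("RTINSECONDS=", format_num(s$rt_min * 60)))
    pk <- s$peaks
    out <- c(out, ifelse(is.na(pk$intensity), format_num(pk$mz),
                         paste(format_num(pk$mz), format_num(pk$intensity))),
             "END IONS")
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname read_spectra_mgf
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) parse_error("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("parent_mz", "rt_min", "mz")
  if (!all(need %in% names(df)))
    parse_error("spectra CSV needs columns %s", paste(need, collapse = ", "))
  if (!"intensity" %in% names(df)) df$intensity <- NA_real_
  if (!"source_label" %in% names(df)) df$source_label <- ""
  key <- paste(df$source_label, df$parent_mz, df$rt_min, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(g)
    spectrum_record(g$parent_mz[1L],
                    data.frame(mz = g$mz, intensity = g$intensity),
                    rt_min = g$rt_min[1L],
                    source_label = g$source_label[1L]))
}

#' Read and write MRM chromatograms
#'
#' One chromatogram per file: a metadata header (`run_label, batch_id,
#' q1, q3`) and its value row, then a `time_min,intensity_cps` block.
#'
#' @param path File path.
#' @return `read_chromatogram_csv` returns a [chromatogram()].
#' @export
read_chromatogram_csv <- function(path) {
  if (!file.exists(path)) parse_error("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L) parse_error("chromatogram CSV too short: %s", path)
  hdr <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (!identical(trimws(hdr), c("run_label", "batch_id", "q1", "q3")))
    parse_error("line 1: expected header run_label,batch_id,q1,q3")
  meta <- strsplit(lines[2L], ",", fixed = TRUE)[[1L]]
  q1 <- as.numeric(meta[3L]); q3 <- as.numeric(meta[4L])
  if (is.na(q1) || is.na(q3)) parse_error("line 2: malformed q1/q3")
  body <- utils::read.csv(text = paste(lines[-(1:2)], collapse = "\n"),
                          stringsAsFactors = FALSE)
  if (!all(c("time_min", "intensity_cps") %in% names(body)))
    parse_error("expected time_min,intensity_cps block")
  chromatogram(transition(q1, q3), body$time_min, body$intensity_cps,
               run_label = meta[1L], batch_id = meta[2L])
}

#' @rdname read_chromatogram_csv
#' @param chrom A [chromatogram()].
#' @export
write_chromatogram_csv <- function(chrom, path) {
  stopifnot(inherits(chrom, "pg_chromatogram"))
  lines <- c("run_label,batch_id,q1,q3",
             paste(chrom$run_label, chrom$batch_id,
                   format_num(chrom$transition$q1),
                   format_num(chrom$transition$q3), sep = ","),
             "time_min,intensity_cps",
             paste(format_num(chrom$times), format_num(chrom$intensities),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write sperm tracks
#'
#' Tracks travel as CSV with columns `gonad_id`, `track_id`,
#' `frame_index`, `t_sec`, `x_um`, `y_um`.
#'
#' @param path File path.
#' @return `read_tracks_csv` returns a list of [sperm_track()] objects.
#' @export
read_tracks_csv <- function(path) {
  if (!file.exists(path)) parse_error("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gonad_id", "track_id", "frame_index", "t_sec", "x_um", "y_um")
  if (!all(need %in% names(df)))
    parse_error("tracks CSV needs columns %s", paste(need, collapse = ", "))
  if (nrow(df) == 0L) parse_error("tracks CSV contains no rows")
  key <- paste(df$gonad_id, df$track_id, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(g) {
    g <- g[order(g$frame_index), ]
    sperm_track(cbind(g$x_um, g$y_um), t = g$t_sec,
                track_id = as.character(g$track_id[1L]),
                gonad_id = as.character(g$gonad_id[1L]))
  })
}

#' @rdname read_tracks_csv
#' @param tracks A list of [sperm_track()] objects.
#' @export
write_tracks_csv <- function(tracks, path) {
  rows <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(gonad_id = tr$gonad_id, track_id = tr$track_id,
               frame_index = seq_len(nrow(tr$positions)) - 1L,
               t_sec = tr$t, x_um = tr$positions[, 1L],
               y_um = tr$positions[, 2L], stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write uterus geometry
#'
#' JSON with keys `vulva_xy`, `spermatheca_xy`, `zone3_depth_um`, either
#' as a single object or as a map from gonad id to such objects.
#'
#' @param path File path.
#' @return A [uterus_geometry()] or a named list of them.
#' @export
read_geometry_json <- function(path) {
  if (!file.exists(path)) parse_error("file not found: %s", path)
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  build <- function(g)
    uterus_geometry(g$vulva_xy, g$spermatheca_xy,
                    g$zone3_depth_um %||% 50)
  if (!is.null(x$vulva_xy)) build(x) else lapply(x, build)
}

#' @rdname read_geometry_json
#' @param geom A [uterus_geometry()] or named list of them.
#' @export
write_geometry_json <- function(geom, path) {
  enc <- function(g) list(vulva_xy = g$vulva, spermatheca_xy = g$spermatheca_center,
                          zone3_depth_um = g$zone3_depth)
  obj <- if (inherits(geom, "pg_geometry")) enc(geom) else lapply(geom, enc)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
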