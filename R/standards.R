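#' Reference prostaglandin standards and compound libraries
#'
#' A `pg_standard` is one reference compound: its name, series class,
#' deprotonated parent mass (\[M-H\]-, unit resolution), reverse-phase
#' retention time in minutes (may be `NA`), the tabulated list of key CID
#' product ions, and a batch identifier.  Standards run together share a
#' batch; retention times are only directly comparable within a batch
#' (cross-day runs show a slight RT shift).
#'
#' @param name Compound name (unique within a library).
#' @param series One of `"F1"`, `"F2"`, `"F3"`, `"F18"`, `"DEH"`,
#'   `"metabolite"`, `"hydroxylated"`.
#' @param parent_mz Parent ion m/z in Da, \[M-H\]-.
#' @param rt_min Reverse-phase retention time (minutes) or `NA`.
#' @param product_ions Numeric vector of product-ion m/z values (Da),
#'   strictly positive, duplicate-free, all below `parent_mz`.
#' @param batch_id Batch label; RTs are comparable only within a batch.
#' @return An object of class `pg_standard`.
#' @seealso [pg_library()], [find_standards()]
#' @export
pg_standard <- function(name, series, parent_mz, rt_min = NA_real_,
                        product_ions, batch_id = "default") {
  series_levels <- c("F1", "F2", "F3", "F18", "DEH", "metabolite",
                     "hydroxylated")
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    validation_error("standard name must be a non-empty string")
  if (!series %in% series_levels)
    validation_error("unknown series '%s' for standard '%s'", series, name)
  assert_number(parent_mz, "parent_mz", positive = TRUE)
  product_ions <- as.numeric(product_ions)
  if (length(product_ions) == 0L)
    validation_error("standard '%s' has an empty product-ion list", name)
  if (any(!is.finite(product_ions)) || any(product_ions <= 0))
    validation_error("standard '%s' has non-positive product ions", name)
  if (anyDuplicated(product_ions))
    validation_error("standard '%s' has duplicate product ions", name)
  if (parent_mz <= max(product_ions))
    validation_error("standard '%s': parent_mz must exceed all product ions",
                     name)
  rt_min <- as.numeric(rt_min)
  if (!is.na(rt_min) && (rt_min <= 0 || rt_min >= 20))
    validation_error("standard '%s': rt_min must lie in (0, 20) minutes", name)
  structure(
    list(name = name, series = series, parent_mz = parent_mz,
         rt_min = rt_min, product_ions = product_ions, batch_id = batch_id),
    class = "pg_standard")
}

#' @export
print.pg_standard <- function(x, ...) {
  cat(sprintf("<pg_standard> %s [%s]  [M-H]- %s  RT %s min  batch %s\n",
              x$name, x$series, format(x$parent_mz),
              ifelse(is.na(x$rt_min), "NA", format(x$rt_min)), x$batch_id))
  cat("  product ions:", paste(format(x$product_ions), collapse = ", "), "\n")
  invisible(x)
}

#' Build a standards library
#'
#' Container for a set of [pg_standard()] entries together with the mass
#' and retention-time tolerances used for matching.  Default tolerances
#' suit unit-resolution triple-quadrupole data (all tabulated masses are
#' integers) and a chromatography program that resolves stereoisomers
#' differing by >= 7 s while calling co-elutions indistinguishable.
#'
#' @param entries List of [pg_standard()] objects with unique names.
#' @param mz_tol Mass tolerance in Da (default 0.5).
#' @param rt_tol Retention-time tolerance in minutes (default 0.05).
#' @return An object of class `pg_library`.
#' @export
pg_library <- function(entries = list(), mz_tol = 0.5, rt_tol = 0.05) {
  assert_number(mz_tol, "mz_tol", positive = TRUE)
  assert_number(rt_tol, "rt_tol", positive = TRUE)
  if (!all(vapply(entries, inherits, logical(1), "pg_standard")))
    validation_error("all library entries must be pg_standard objects")
  nms <- vapply(entries, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    validation_error("duplicate standard name(s): %s",
                     paste(unique(nms[duplicated(nms)]), collapse = ", "))
  structure(list(entries = entries, mz_tol = mz_tol, rt_tol = rt_tol),
            class = "pg_library")
}

#' @export
print.pg_library <- function(x, ...) {
  cat(sprintf("<pg_library> %d entries  mz_tol %g Da  rt_tol %g min\n",
              length(x$entries), x$mz_tol, x$rt_tol))
  if (length(x$entries)) {
    tab <- table(vapply(x$entries, `[[`, character(1), "series"))
    cat("  series:", paste(sprintf("%s=%d", names(tab), tab),
                           collapse = "  "), "\n")
  }
  invisible(x)
}

#' @export
length.pg_library <- function(x) length(x$entries)

#' @rdname pg_library
#' @param x A `pg_library`.
#' @export
as.data.frame.pg_library <- function(x, ...) {
  data.frame(
    name = vapply(x$entries, `[[`, character(1), "name"),
    series = vapply(x$entries, `[[`, character(1), "series"),
    parent_mz = vapply(x$entries, `[[`, numeric(1), "parent_mz"),
    rt_min = vapply(x$entries, `[[`, numeric(1), "rt_min"),
    product_ions = vapply(x$entries, function(e)
      paste(format_num(e$product_ions), collapse = ";"), character(1)),
    batch_id = vapply(x$entries, `[[`, character(1), "batch_id"),
    stringsAsFactors = FALSE)
}

# canonical, locale-free number formatting used by all writers
format_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    format(v, trim = TRUE, scientific = FALSE, drop0trailing = TRUE,
           digits = 15)
  }, character(1))
}

#' Read or write a standards library
#'
#' TSV files carry the columns `name`, `series`, `parent_mz`, `rt_min`,
#' `product_ions` (semicolon-separated) and `batch_id` with a header row;
#' JSON files carry an array of objects with the same keys and
#' `product_ions` as a number array.  `write_standard_library` followed
#' by `read_standard_library` round-trips exactly (entry order preserved,
#' and a second write is byte-identical to the first).
#'
#' @param path File path.
#' @param format `"tsv"` or `"json"`; inferred from the file extension
#'   when missing.
#' @param mz_tol,rt_tol Tolerances stored on the returned library.
#' @return `read_standard_library` returns a [pg_library()];
#'   `write_standard_library` returns `path` invisibly.
#' @export
read_standard_library <- function(path, format = c("auto", "tsv", "json"),
                                  mz_tol = 0.5, rt_tol = 0.05) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (!file.exists(path)) parse_error("file not found: %s", path)
  if (format == "json") {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) return(pg_library(mz_tol = mz_tol, rt_tol = rt_tol))
    rows <- jsonlite::fromJSON(txt, simplifyDataFrame = FALSE)
    entries <- lapply(rows, function(r)
      pg_standard(r$name, r$series, r$parent_mz,
                  r$rt_min %||% NA_real_,
                  unlist(r$product_ions), r$batch_id %||% "default"))
    return(pg_library(entries, mz_tol = mz_tol, rt_tol = rt_tol))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(pg_library(mz_tol = mz_tol, rt_tol = rt_tol))
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  need <- c("name", "series", "parent_mz", "rt_min", "product_ions",
            "batch_id")
  if (!all(need %in% header))
    parse_error("line 1: TSV header must contain columns %s",
                paste(need, collapse = ", "))
  entries <- vector("list", length(lines) - 1L)
  for (i in seq_along(entries)) {
    fields <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != length(header))
      parse_error("line %d: expected %d fields, got %d",
                  i + 1L, length(header), length(fields))
    names(fields) <- header
    ions <- suppressWarnings(
      as.numeric(strsplit(fields[["product_ions"]], ";", fixed = TRUE)[[1L]]))
    if (anyNA(ions))
      parse_error("line %d: malformed product_ions field", i + 1L)
    rt <- fields[["rt_min"]]
    rt <- if (rt %in% c("", "NA")) NA_real_ else suppressWarnings(as.numeric(rt))
    pmz <- suppressWarnings(as.numeric(fields[["parent_mz"]]))
    if (is.na(pmz)) parse_error("line %d: malformed parent_mz", i + 1L)
    entries[[i]] <- pg_standard(fields[["name"]], fields[["series"]], pmz,
                                rt, ions, fields[["batch_id"]])
  }
  pg_library(entries, mz_tol = mz_tol, rt_tol = rt_tol)
}

#' @rdname read_standard_library
#' @param lib A [pg_library()].
#' @export
write_standard_library <- function(lib, path, format = c("auto", "tsv", "json")) {
  stopifnot(inherits(lib, "pg_library"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "json") {
    rows <- lapply(lib$entries, function(e)
      list(name = e$name, series = e$series, parent_mz = e$parent_mz,
           rt_min = if (is.na(e$rt_min)) NULL else e$rt_min,
           product_ions = e$product_ions, batch_id = e$batch_id))
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(path))
  }
  df <- as.data.frame(lib)
  lines <- c(paste(names(df), collapse = "\t"),
             apply(cbind(df$name, df$series, format_num(df$parent_mz),
                         format_num(df$rt_min), df$product_ions,
                         df$batch_id),
                   1L, paste, collapse = "\t"))
  if (nrow(df) == 0L) lines <- lines[1L]
  writeLines(lines, path)
  invisible(path)
}

#' Packaged reference fixtures
#'
#' `table2_standards()` loads the 20 chemically synthesized F-series
#' prostaglandin standards (name, series, RT, \[M-H\]- and key CID
#' product ions); `table3_compounds()` loads the 11 *C. elegans*
#' F-series prostaglandin records (CePGF1, CePGF2, CePGF2b and unnamed
#' class 1/3 isomers).
#'
#' @param mz_tol,rt_tol Tolerances for the returned [pg_library()].
#' @return A [pg_library()].
#' @export
table2_standards <- function(mz_tol = 0.5, rt_tol = 0.05) {
  read_standard_library(
    system.file("extdata", "table2_standards.tsv", package = "pgsperm",
                mustWork = TRUE),
    "tsv", mz_tol = mz_tol, rt_tol = rt_tol)
}

#' @rdname table2_standards
#' @export
table3_compounds <- function(mz_tol = 0.5, rt_tol = 0.05) {
  read_standard_library(
    system.file("extdata", "table3_compounds.tsv", package = "pgsperm",
                mustWork = TRUE),
    "tsv", mz_tol = mz_tol, rt_tol = rt_tol)
}

#' Find standards by parent mass and retention time
#'
#' Returns the library entries whose parent m/z lies within `mz_tol` of
#' `parent_mz` and, when `rt` is given, whose retention time lies within
#' `rt_tol` of `rt` (entries without an RT are excluded in that case).
#' Matches are sorted by RT distance, ties broken by name.  Extracts and
#' standards are assumed to have been run consecutively, so RTs are
#' directly comparable; use [align_rt()] first for cross-batch data.
#'
#' @param lib A [pg_library()].
#' @param parent_mz Query parent m/z (Da).
#' @param rt Optional query retention time (minutes).
#' @return A list of [pg_standard()] entries (possibly empty).
#' @export
find_standards <- function(lib, parent_mz, rt = NULL) {
  stopifnot(inherits(lib, "pg_library"))
  assert_number(parent_mz, "parent_mz", positive = TRUE)
  if (length(lib$entries) == 0L) return(list())
  pmz <- vapply(lib$entries, `[[`, numeric(1), "parent_mz")
  rts <- vapply(lib$entries, `[[`, numeric(1), "rt_min")
  keep <- abs(pmz - parent_mz) <= lib$mz_tol
  if (!is.null(rt)) {
    assert_number(rt, "rt")
    keep <- keep & !is.na(rts) & abs(rts - rt) <= lib$rt_tol
  }
  hits <- lib$entries[keep]
  if (length(hits) == 0L) return(list())
  dist <- if (is.null(rt)) rep(0, length(hits)) else
    abs(vapply(hits, `[[`, numeric(1), "rt_min") - rt)
  nms <- vapply(hits, `[[`, character(1), "name")
  hits[order(dist, nms)]
}
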