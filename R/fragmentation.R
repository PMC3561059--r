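#' Predict the parent mass of an F-series prostaglandin
#'
#' F-series prostaglandins observed as \[M-H\]- ions lose 2 Da per
#' additional precursor double bond and 14 Da (CH2) per missing backbone
#' carbon relative to the 20:3-derived F1 parent at m/z 355.  The
#' 18:3n3-derived parent is therefore m/z 327, 28 Da (C2H4) lighter than
#' the F1 parent.
#'
#' @param carbons Precursor PUFA carbon count, 18 or 20.
#' @param double_bonds Precursor double-bond count, 3, 4 or 5.
#' @return Predicted \[M-H\]- m/z (Da).
#' @examples
#' predict_parent_mz(20, 4)  # 353, the F2 class parent
#' predict_parent_mz(18, 3)  # 327
#' @export
predict_parent_mz <- function(carbons, double_bonds) {
  if (!carbons %in% c(18, 20))
    validation_error("carbons must be 18 or 20 (got %s)", format(carbons))
  if (!double_bonds %in% c(3, 4, 5))
    validation_error("double_bonds must be 3, 4 or 5 (got %s)",
                     format(double_bonds))
  355 - 2 * (double_bonds - 3) - 14 * (20 - carbons)
}

#' Diagnostic CID ions for an F-series parent mass
#'
#' Computes the product ions diagnostic of F-series prostaglandins: the
#' z1 cleavage ion (loss of 44 Da, C2H4O, from the parent), the two
#' subsequent water losses from it (z1 - 18, z1 - 36), the direct parent
#' dehydrations (parent - 18, parent - 36), the cyclopentane ring ions
#' (m/z 193 for the F2 parent near 353; m/z 193 and 191 for the F3
#' parent near 351), the m/z 189 marker that detects D/E/H-series
#' intermediates, and the m/z 115 marker abundant in isomers carrying a
#' C5 hydroxyl.
#'
#' @param parent_mz Parent \[M-H\]- m/z (> 100 Da).
#' @param mz_tol Tolerance (Da) used to key the ring ions off parents
#'   near 353 or 351.
#' @return An object of class `pg_diagnostic_ions` with fields
#'   `parent_mz`, `z1`, `chain`, `dehydrations`, `ring_ions`,
#'   `deh_marker` (189) and `c5_marker` (115).
#' @examples
#' diagnostic_ions(353)$z1  # 309
#' @export
diagnostic_ions <- function(parent_mz, mz_tol = 0.5) {
  assert_number(parent_mz, "parent_mz")
  if (parent_mz <= 100)
    validation_error("parent_mz must exceed 100 Da")
  z1 <- parent_mz - 44
  ring <- if (abs(parent_mz - 353) <= mz_tol) 193 else
    if (abs(parent_mz - 351) <= mz_tol) c(193, 191) else numeric(0)
  structure(
    list(parent_mz = parent_mz, z1 = z1,
         chain = c(z1 - 18, z1 - 36),
         dehydrations = c(parent_mz - 18, parent_mz - 36),
         ring_ions = ring, deh_marker = 189, c5_marker = 115),
    class = "pg_diagnostic_ions")
}

#' @export
print.pg_diagnostic_ions <- function(x, ...) {
  cat(sprintf("<pg_diagnostic_ions> parent %s\n", format(x$parent_mz)))
  cat(sprintf("  z1 (parent-44): %s;  z1-H2O chain: %s\n", format(x$z1),
              paste(format(x$chain), collapse = ", ")))
  cat(sprintf("  dehydrations: %s;  ring ions: %s\n",
              paste(format(x$dehydrations), collapse = ", "),
              if (length(x$ring_ions))
                paste(format(x$ring_ions), collapse = ", ") else "none"))
  invisible(x)
}

#' Construct a CID spectrum record
#'
#' Normalizes an observed product-ion spectrum: peaks are sorted by m/z,
#' duplicate m/z values are merged keeping the maximum intensity, and
#' peaks at or above `parent_mz + mz_tol` are rejected.  Intensities are
#' optional (`NA` throughout for presence-only ion lists such as the
#' packaged reference tables).
#'
#' @param parent_mz Parent \[M-H\]- m/z.
#' @param peaks Either a numeric vector of m/z values or a data frame
#'   with columns `mz` and (optionally) `intensity`.
#' @param rt_min Retention time in minutes, or `NA`.
#' @param source_label Free-text provenance label.
#' @param mz_tol Tolerance used for the upper m/z cutoff.
#' @return An object of class `pg_spectrum`.
#' @export
spectrum_record <- function(parent_mz, peaks, rt_min = NA_real_,
                            source_label = "", mz_tol = 0.5) {
  assert_number(parent_mz, "parent_mz", positive = TRUE)
  if (is.numeric(peaks))
    peaks <- data.frame(mz = as.numeric(peaks), intensity = NA_real_)
  if (!is.data.frame(peaks) || !"mz" %in% names(peaks))
    validation_error("peaks must be a numeric vector or a data frame with 'mz'")
  if (!"intensity" %in% names(peaks)) peaks$intensity <- NA_real_
  peaks <- peaks[is.finite(peaks$mz) & peaks$mz < parent_mz + mz_tol,
                 c("mz", "intensity")]
  if (nrow(peaks)) {
    # merge duplicate m/z, keeping the most intense observation
    peaks <- peaks[order(peaks$mz, -xtfrm(peaks$intensity)), ]
    peaks <- peaks[!duplicated(peaks$mz), ]
    rownames(peaks) <- NULL
  }
  structure(
    list(parent_mz = parent_mz, rt_min = as.numeric(rt_min), peaks = peaks,
         source_label = source_label),
    class = "pg_spectrum")
}

#' @export
print.pg_spectrum <- function(x, ...) {
  cat(sprintf("<pg_spectrum> %s  parent %s  RT %s min  %d peaks\n",
              if (nzchar(x$source_label)) x$source_label else "(unlabelled)",
              format(x$parent_mz),
              ifelse(is.na(x$rt_min), "NA", format(x$rt_min)),
              nrow(x$peaks)))
  invisible(x)
}

# ion list used for matching/classification: peaks >= `floor` of the base
# peak when intensities are known, all peaks otherwise
considered_ions <- function(spectrum, floor = 0.05) {
  pk <- spectrum$peaks
  if (nrow(pk) == 0L) return(numeric(0))
  if (all(is.na(pk$intensity))) return(pk$mz)
  base <- max(pk$intensity, na.rm = TRUE)
  pk$mz[is.na(pk$intensity) | pk$intensity >= floor * base]
}

ion_list <- function(x, floor = 0.05) {
  if (inherits(x, "pg_spectrum")) considered_ions(x, floor)
  else if (inherits(x, "pg_standard")) x$product_ions
  else if (is.numeric(x)) as.numeric(x)
  else validation_error("cannot extract an ion list from class '%s'",
                        paste(class(x), collapse = "/"))
}

#' Shared-ion comparison of two product-ion spectra
#'
#' Pairs the ions of a query spectrum against a reference by greedy
#' nearest-neighbour matching within `mz_tol` (ions taken in ascending
#' m/z, each used at most once) and reports the shared ions, the ions
#' unique to either side, and the Jaccard fraction
#' shared / (shared + only_query + only_reference).  At unit resolution
#' (integer masses, 0.5 Da tolerance) this is exactly set intersection.
#'
#' @param query,reference A [spectrum_record()], [pg_standard()] or bare
#'   numeric ion vector; both must be non-empty.
#' @param mz_tol Pairing tolerance in Da.
#' @return An object of class `pg_ion_report` with fields `shared`,
#'   `only_query`, `only_reference` and `jaccard`.
#' @export
match_spectrum <- function(query, reference, mz_tol = 0.5) {
  q <- sort(ion_list(query))
  r <- sort(ion_list(reference))
  if (length(q) == 0L || length(r) == 0L)
    validation_error("match_spectrum requires non-empty ion lists")
  used <- rep(FALSE, length(r))
  paired_q <- logical(length(q))
  for (i in seq_along(q)) {
    d <- abs(r - q[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= mz_tol) {
      used[j] <- TRUE
      paired_q[i] <- TRUE
    }
  }
  shared <- q[paired_q]
  only_q <- q[!paired_q]
  only_r <- r[!used]
  structure(
    list(shared = shared, only_query = only_q, only_reference = only_r,
         jaccard = length(shared) /
           (length(shared) + length(only_q) + length(only_r))),
    class = "pg_ion_report")
}

#' @export
print.pg_ion_report <- function(x, ...) {
  cat(sprintf("<pg_ion_report> %d shared, %d query-only, %d reference-only, jaccard %.3f\n",
              length(x$shared), length(x$only_query),
              length(x$only_reference), x$jaccard))
  if (length(x$shared))
    cat("  shared:", paste(format(x$shared), collapse = ", "), "\n")
  invisible(x)
}

near <- function(ions, target, tol) any(abs(ions - target) <= tol)

# enantiomer pairs are named "X" / "ent-X"; unresolved when both elute
# within rt_tol on the reverse-phase column
enantiomer_partner_name <- function(name) {
  if (startsWith(name, "ent-")) sub("^ent-", "", name)
  else paste0("ent-", name)
}

#' Classify a CID spectrum into a prostaglandin series
#'
#' Applies the diagnostic fragmentation rules: the parent mass selects
#' the candidate series (355 F1, 353 F2, 351 F3 or D/E/H intermediate,
#' 327 the 18:3n3-derived class, 369/367 hydroxylated F); F-series
#' evidence is the z1 ion (parent - 44), or at least two of the four
#' dehydration-chain ions (parent - 18, parent - 36, z1 - 18, z1 - 36),
#' or (for F2/F3/hydroxylated parents) a cyclopentane ring ion
#' (m/z 193, plus 191 for parent 351).  A parent near 351 showing the
#' m/z 189 marker without a ring ion is called a D/E/H-series candidate.
#' The best library match maximizes the shared-ion Jaccard fraction
#' among entries with a compatible parent mass, preferring entries whose
#' RT lies within `rt_tol` of the query when the query RT is known; ties
#' break on RT distance then name.  The call is flagged
#' `enantiomer_unresolved` when the best match belongs to a co-eluting
#' enantiomer pair (e.g. PGF2a / ent-PGF2a), which reverse-phase
#' chromatography cannot separate.
#'
#' @param query A [spectrum_record()] with `parent_mz` set.
#' @param lib A [pg_library()] such as [table2_standards()].
#' @param intensity_floor When the query has intensities, only ions at
#'   or above this fraction of the base peak are considered (default
#'   0.05).
#' @return An object of class `pg_class_call` with fields `series`
#'   (`"F1"`, `"F2"`, `"F3"`, `"F18"`, `"DEH_candidate"`,
#'   `"hydroxylated_F"` or `"unclassified"`), `evidence` (character flag
#'   set), `best_match`, `match_report`, `jaccard` and
#'   `enantiomer_unresolved`.
#' @export
classify_spectrum <- function(query, lib, intensity_floor = 0.05) {
  stopifnot(inherits(query, "pg_spectrum"), inherits(lib, "pg_library"))
  tol <- lib$mz_tol
  p <- query$parent_mz
  ions <- considered_ions(query, intensity_floor)
  di <- diagnostic_ions(p, mz_tol = tol)

  evidence <- character(0)
  has <- function(target) length(ions) && near(ions, target, tol)
  z1_present <- has(di$z1)
  chain_ions <- c(di$dehydrations, di$chain)
  n_chain <- sum(vapply(chain_ions, has, logical(1)))
  ring193 <- has(193)
  ring191 <- abs(p - 351) <= tol && has(191)
  if (z1_present) evidence <- c(evidence, "Z1_PRESENT")
  if (n_chain >= 2) evidence <- c(evidence, "CHAIN_PRESENT")
  if (ring193) evidence <- c(evidence, "RING_193")
  if (ring191) evidence <- c(evidence, "RING_191")
  if (has(di$deh_marker)) evidence <- c(evidence, "MARKER_189")
  if (has(di$c5_marker)) evidence <- c(evidence, "MARKER_115")

  candidate <- if (abs(p - 355) <= tol) "F1"
    else if (abs(p - 353) <= tol) "F2"
    else if (abs(p - 351) <= tol) "F3"
    else if (abs(p - 327) <= tol) "F18"
    else if (abs(p - 369) <= tol || abs(p - 367) <= tol) "hydroxylated_F"
    else NA_character_
  if (!is.na(candidate)) evidence <- c(evidence, "PARENT_MASS_MATCH")

  f_evidence <- z1_present || n_chain >= 2
  series <- "unclassified"
  if (!is.na(candidate)) {
    if (candidate == "F3" && "MARKER_189" %in% evidence &&
        !ring193 && !ring191) {
      series <- "DEH_candidate"
    } else if (candidate %in% c("F2", "F3", "hydroxylated_F")) {
      if (f_evidence || ring193 || ring191) series <- candidate
    } else if (f_evidence) {
      series <- candidate
    }
  }

  # library retrieval: parent-mass-compatible entries, preferring the
  # RT-compatible subset when the query has an RT
  best <- NULL; report <- NULL; enant <- FALSE
  if (length(lib$entries) && length(ions)) {
    pmz <- vapply(lib$entries, `[[`, numeric(1), "parent_mz")
    rts <- vapply(lib$entries, `[[`, numeric(1), "rt_min")
    cand <- which(abs(pmz - p) <= tol)
    if (length(cand) && !is.na(query$rt_min)) {
      rt_ok <- cand[!is.na(rts[cand]) &
                      abs(rts[cand] - query$rt_min) <= lib$rt_tol]
      if (length(rt_ok)) cand <- rt_ok
    }
    if (length(cand)) {
      reports <- lapply(lib$entries[cand], match_spectrum, query = ions,
                        mz_tol = tol)
      jac <- vapply(reports, `[[`, numeric(1), "jaccard")
      drt <- abs(rts[cand] - query$rt_min)
      drt[is.na(drt)] <- Inf
      nms <- vapply(lib$entries[cand], `[[`, character(1), "name")
      k <- order(-jac, drt, nms)[1L]
      best <- lib$entries[[cand[k]]]
      report <- reports[[k]]
      partner <- enantiomer_partner_name(best$name)
      all_nms <- vapply(lib$entries, `[[`, character(1), "name")
      pi <- match(partner, all_nms)
      if (!is.na(pi)) {
        prt <- lib$entries[[pi]]$rt_min
        enant <- !is.na(prt) && !is.na(best$rt_min) &&
          abs(prt - best$rt_min) <= lib$rt_tol
      }
    }
  }

  structure(
    list(source_label = query$source_label, parent_mz = p,
         rt_min = query$rt_min, series = series, evidence = evidence,
         best_match = if (is.null(best)) NA_character_ else best$name,
         match_report = report,
         jaccard = if (is.null(report)) NA_real_ else report$jaccard,
         enantiomer_unresolved = enant),
    class = "pg_class_call")
}

#' @export
print.pg_class_call <- function(x, ...) {
  cat(sprintf("<pg_class_call> %s  parent %s -> %s\n",
              if (nzchar(x$source_label)) x$source_label else "(unlabelled)",
              format(x$parent_mz), x$series))
  cat("  evidence:", if (length(x$evidence))
    paste(x$evidence, collapse = ", ") else "none", "\n")
  cat(sprintf("  best match: %s (jaccard %s)%s\n",
              x$best_match,
              ifelse(is.na(x$jaccard), "NA", sprintf("%.3f", x$jaccard)),
              if (isTRUE(x$enantiomer_unresolved))
                "  [enantiomer unresolved]" else ""))
  invisible(x)
}

#' Screen spectra for hydroxylated F-series prostaglandins
#'
#' Returns class calls for the spectra whose parent mass lies near
#' m/z 369 or 367 (hydroxylated F2/F3 candidates, the species monitored
#' by the 369/193 and 367/193 transitions) and that show the m/z 193
#' ring ion.
#'
#' @param query_set A list of [spectrum_record()] objects.
#' @param lib A [pg_library()].
#' @return A list of `pg_class_call` objects (possibly empty).
#' @export
screen_hydroxylated <- function(query_set, lib) {
  stopifnot(inherits(lib, "pg_library"))
  tol <- lib$mz_tol
  hits <- Filter(function(s) {
    (abs(s$parent_mz - 369) <= tol || abs(s$parent_mz - 367) <= tol) &&
      near(considered_ions(s), 193, tol)
  }, query_set)
  lapply(hits, classify_spectrum, lib = lib)
}

#' Annotate a set of spectra against a standards library
#'
#' Runs [classify_spectrum()] over a list of spectra and collects the
#' calls into one data frame, one row per spectrum.
#'
#' @param spectra A list of [spectrum_record()] objects.
#' @param lib A [pg_library()].
#' @return A data frame with columns `source_label`, `parent_mz`,
#'   `rt_min`, `series`, `evidence` (comma-joined flags), `best_match`,
#'   `jaccard`, `enantiomer_unresolved`.
#' @export
annotate_spectra <- function(spectra, lib) {
  calls <- lapply(spectra, classify_spectrum, lib = lib)
  data.frame(
    source_label = vapply(calls, `[[`, character(1), "source_label"),
    parent_mz = vapply(calls, `[[`, numeric(1), "parent_mz"),
    rt_min = vapply(calls, `[[`, numeric(1), "rt_min"),
    series = vapply(calls, `[[`, character(1), "series"),
    evidence = vapply(calls, function(x)
      paste(x$evidence, collapse = ","), character(1)),
    best_match = vapply(calls, `[[`, character(1), "best_match"),
    jaccard = vapply(calls, `[[`, numeric(1), "jaccard"),
    enantiomer_unresolved = vapply(calls, `[[`, logical(1),
                                   "enantiomer_unresolved"),
    stringsAsFactors = FALSE)
}

#' Convert library entries to spectrum records
#'
#' Convenience for re-annotating a library against itself or another
#' library: each [pg_standard()] becomes a presence-only
#' [spectrum_record()] carrying the entry's parent mass, RT and tabulated
#' ion list.
#'
#' @param lib A [pg_library()].
#' @return A list of [spectrum_record()] objects.
#' @export
library_as_spectra <- function(lib) {
  stopifnot(inherits(lib, "pg_library"))
  lapply(lib$entries, function(e)
    spectrum_record(e$parent_mz, e$product_ions, rt_min = e$rt_min,
                    source_label = e$name, mz_tol = lib$mz_tol))
}
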