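# Readers and writers for the three text formats the workflow touches:
# NIST-dialect MSP spectral libraries, feature/intensity tables (CSV) and
# suspect lists (CSV), plus the cohort design and the FeatureSet container.

#' Construct an MS/MS spectrum
#'
#' @param mz,intensity Numeric vectors of equal length (at least one peak,
#'   intensities >= 0). Peaks are sorted by m/z.
#' @param precursor_mz Optional precursor m/z (Th).
#' @param precursor_type Optional adduct name.
#' @param name Record name.
#' @param formula Optional formula string.
#' @param inchikey Optional 27-character InChIKey. `structure_known` is FALSE
#'   iff no structure identifier is present.
#' @param metadata Named list of additional header fields.
#' @return An object of class `"spectrum"`.
#' @export
new_spectrum <- function(mz, intensity, precursor_mz = NULL, precursor_type = NULL,
                         name = NULL, formula = NULL, inchikey = NULL,
                         metadata = list()) {
  if (length(mz) < 1L || length(mz) != length(intensity))
    stop("a spectrum needs at least one (mz, intensity) peak pair")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  o <- order(mz)
  structure(list(
    mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
    precursor_mz = precursor_mz, precursor_type = precursor_type,
    name = name, formula = formula,
    inchikey = if (!is.null(inchikey) && nzchar(inchikey)) inchikey else NULL,
    structure_known = !is.null(inchikey) && nzchar(inchikey),
    metadata = metadata
  ), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum>", if (!is.null(x$name)) x$name else "(unnamed)",
      "| peaks:", length(x$mz),
      if (!is.null(x$precursor_mz)) sprintf("| precursor %.4f %s", x$precursor_mz,
                                            x$precursor_type %||% ""), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a NIST-dialect MSP spectral library
#'
#' Accepts the header keys `NAME`, `PRECURSORMZ`, `PRECURSORTYPE`, `FORMULA`,
#' `INCHIKEY` and both `Num Peaks` and `NumPeaks` (MoNA and MS-DIAL exports
#' differ); unknown keys are preserved in each spectrum's `metadata`. Peak
#' lines are split on whitespace or tab.
#'
#' @param path Path to an MSP file.
#' @return List of [new_spectrum()] objects. An empty file yields an empty
#'   list with a warning; a record whose peak count disagrees with its
#'   `Num Peaks` header is a record-level error naming the line.
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(trimws(lines)[nzchar(trimws(lines))])) {
    warning("empty MSP file: ", path)
    return(list())
  }
  spectra <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L
    if (i > n) break
    meta <- list()
    npeaks <- NA_integer_
    while (i <= n && grepl(":", lines[i], fixed = TRUE)) {
      key <- toupper(gsub("[[:space:]]", "", sub(":.*$", "", lines[i])))
      val <- trimws(sub("^[^:]*:", "", lines[i]))
      if (key == "NUMPEAKS") npeaks <- as.integer(val) else meta[[key]] <- val
      i <- i + 1L
    }
    if (is.na(npeaks))
      stop("MSP record without 'Num Peaks' header near line ", i)
    first_peak_line <- i
    mzs <- numeric(0); ints <- numeric(0)
    while (i <= n && nzchar(trimws(lines[i]))) {
      parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
      if (length(parts) < 2L)
        stop("malformed peak line ", i, ": '", lines[i], "'")
      mzs <- c(mzs, as.numeric(parts[1]))
      ints <- c(ints, as.numeric(parts[2]))
      i <- i + 1L
    }
    if (length(mzs) != npeaks)
      stop("peak-count mismatch in record '", meta[["NAME"]] %||% "?",
           "' starting at line ", first_peak_line, ": header says ", npeaks,
           ", found ", length(mzs))
    known <- c("NAME", "PRECURSORMZ", "PRECURSORTYPE", "FORMULA", "INCHIKEY")
    spectra[[length(spectra) + 1L]] <- new_spectrum(
      mz = mzs, intensity = ints,
      precursor_mz = if (!is.null(meta$PRECURSORMZ)) as.numeric(meta$PRECURSORMZ),
      precursor_type = meta$PRECURSORTYPE,
      name = meta$NAME, formula = meta$FORMULA, inchikey = meta$INCHIKEY,
      metadata = meta[setdiff(names(meta), known)]
    )
  }
  spectra
}

#' Write spectra to an MSP file
#'
#' Inverse of [read_msp()]: peak m/z written to 5 decimals so a round trip
#' preserves peaks to at least 4 decimals.
#'
#' @param spectra List of spectrum objects.
#' @param path Output path.
#' @export
write_msp <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    if (!is.null(s$name)) writeLines(paste0("NAME: ", s$name), con)
    if (!is.null(s$precursor_mz))
      writeLines(sprintf("PRECURSORMZ: %.5f", s$precursor_mz), con)
    if (!is.null(s$precursor_type))
      writeLines(paste0("PRECURSORTYPE: ", s$precursor_type), con)
    if (!is.null(s$formula)) writeLines(paste0("FORMULA: ", s$formula), con)
    if (!is.null(s$inchikey)) writeLines(paste0("INCHIKEY: ", s$inchikey), con)
    for (k in names(s$metadata)) writeLines(paste0(k, ": ", s$metadata[[k]]), con)
    writeLines(sprintf("Num Peaks: %d", length(s$mz)), con)
    writeLines(sprintf("%.5f %.6g", s$mz, s$intensity), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Construct a cohort design
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param groups Group label per sample, each one of `"PD"`, `"Ctrl"`, `"QC"`,
#'   `"Blank"`.
#' @return Named character vector mapping sample id to group.
#' @export
cohort_design <- function(sample_ids, groups) {
  if (length(sample_ids) != length(groups)) stop("sample_ids and groups differ in length")
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids in design")
  ok <- c("PD", "Ctrl", "QC", "Blank")
  if (!all(groups %in% ok))
    stop("group labels must be one of: ", paste(ok, collapse = ", "))
  stats::setNames(as.character(groups), sample_ids)
}

#' Read a cohort design CSV (columns `sample_id`, `group`)
#' @param path Path to the CSV.
#' @return Named character vector as from [cohort_design()].
#' @export
read_design <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort_design(d$sample_id, d$group)
}

#' Construct a FeatureSet
#'
#' The container for aligned LC-HRMS features: a feature annotation table,
#' an intensity matrix, the cohort design, and optional per-feature MS/MS
#' spectra and observed isotope patterns.
#'
#' @param features Data frame with columns `feature_id`, `mz`, `rt`,
#'   `esi_mode` (`"+"`/`"-"`), `lc_mode` (`"RP"`/`"HILIC"`), `fraction`.
#' @param intensities Numeric matrix, rows = features (rownames = feature_id),
#'   columns = samples. Samples present in `design` but absent from the matrix
#'   are filled with 0 with a warning.
#' @param design Named group vector from [cohort_design()].
#' @param ms2 Named list of spectrum objects keyed by feature_id.
#' @param iso Named list of observed isotope patterns (data frames with
#'   `mass`, `abundance`) keyed by feature_id.
#' @return An object of class `"FeatureSet"`.
#' @export
feature_set <- function(features, intensities, design, ms2 = list(), iso = list()) {
  req <- c("feature_id", "mz", "rt", "esi_mode", "lc_mode", "fraction")
  miss <- setdiff(req, names(features))
  if (length(miss)) stop("features table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(features$feature_id))
    stop("duplicated feature_id: ",
         paste(unique(features$feature_id[duplicated(features$feature_id)]), collapse = ", "))
  if (any(features$mz <= 0)) stop("feature m/z must be > 0")
  if (any(features$rt < 0)) stop("feature RT must be >= 0")
  intensities <- as.matrix(intensities)
  rownames(intensities) <- features$feature_id
  orphan <- setdiff(colnames(intensities), names(design))
  if (length(orphan))
    stop("sample column(s) absent from design: ", paste(orphan, collapse = ", "))
  absent <- setdiff(names(design), colnames(intensities))
  if (length(absent)) {
    warning("sample(s) missing from intensity table filled with 0: ",
            paste(absent, collapse = ", "))
    fill <- matrix(0, nrow(intensities), length(absent),
                   dimnames = list(rownames(intensities), absent))
    intensities <- cbind(intensities, fill)
  }
  intensities <- intensities[, names(design), drop = FALSE]
  if (any(intensities < 0)) stop("intensities must be >= 0")
  structure(list(features = features, intensities = intensities,
                 design = design, ms2 = ms2, iso = iso),
            class = "FeatureSet")
}

#' @export
print.FeatureSet <- function(x, ...) {
  cat("<FeatureSet>", nrow(x$features), "features x", ncol(x$intensities),
      "samples |", sum(lengths(x$ms2) > 0), "with MS/MS\n")
  cat("  groups:", paste(sprintf("%s=%d", names(table(x$design)), table(x$design)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Subset a FeatureSet by feature id
#' @param fs A FeatureSet.
#' @param ids Feature ids to keep (order preserved as given).
#' @return A FeatureSet.
#' @export
subset_features <- function(fs, ids) {
  keep <- match(ids, fs$features$feature_id)
  if (anyNA(keep)) stop("unknown feature id(s): ", paste(ids[is.na(keep)], collapse = ", "))
  feature_set(fs$features[keep, , drop = FALSE],
              fs$intensities[keep, , drop = FALSE], fs$design,
              ms2 = fs$ms2[intersect(names(fs$ms2), ids)],
              iso = fs$iso[intersect(names(fs$iso), ids)])
}

#' Read a feature/intensity table CSV
#'
#' Expects a header row `feature_id, mz, rt, esi_mode, lc_mode, fraction`
#' followed by one column per sample id. All sample columns must appear in
#' the design; intensities must be numeric (locale-independent "." decimal).
#'
#' @param path Path to the CSV.
#' @param design Cohort design from [cohort_design()].
#' @return A [feature_set()].
#' @export
read_feature_table <- function(path, design) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("feature_id", "mz", "rt", "esi_mode", "lc_mode", "fraction")
  miss <- setdiff(meta_cols, names(d))
  if (length(miss)) stop("feature table lacks column(s): ", paste(miss, collapse = ", "))
  sample_cols <- setdiff(names(d), meta_cols)
  orphan <- setdiff(sample_cols, names(design))
  if (length(orphan))
    stop("sample column(s) absent from design: ", paste(orphan, collapse = ", "))
  mat <- matrix(NA_real_, nrow(d), length(sample_cols),
                dimnames = list(d$feature_id, sample_cols))
  for (sc in sample_cols) {
    v <- d[[sc]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(v) & !is.na(d[[sc]]))
    if (length(bad))
      stop("non-numeric intensity at row ", bad[1], ", column '", sc, "'")
    if (anyNA(v))
      stop("missing intensity at row ", which(is.na(v))[1], ", column '", sc, "'")
    mat[, sc] <- v
  }
  feature_set(d[meta_cols], mat, design)
}

#' Write the feature/intensity table of a FeatureSet to CSV
#' @param fs A FeatureSet.
#' @param path Output path.
#' @export
write_feature_table <- function(fs, path) {
  out <- cbind(fs$features, as.data.frame(fs$intensities, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a suspect list CSV
#'
#' Expects at least `name` plus one of `formula` or `monoisotopic_mass`
#' (optionally `inchikey`). The neutral mass is backfilled from the formula
#' when absent; rows lacking both formula and mass are skipped with a
#' warning. When both are present they must agree to 0.001 Da.
#'
#' @param path Path to the CSV.
#' @param list_code Short code identifying the list (e.g. `"LITMIN"`,
#'   `"PD-CTD"`, a MeSH code).
#' @return Data frame with columns `name`, `formula`, `neutral_mass`,
#'   `inchikey`, `list_code`.
#' @export
read_suspect_list <- function(path, list_code) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"name" %in% names(d)) stop("suspect list lacks a 'name' column")
  if (!"formula" %in% names(d)) d$formula <- NA_character_
  if (!"monoisotopic_mass" %in% names(d)) d$monoisotopic_mass <- NA_real_
  if (!"inchikey" %in% names(d)) d$inchikey <- NA_character_
  d$formula[!is.na(d$formula) & !nzchar(d$formula)] <- NA_character_
  has_formula <- !is.na(d$formula)
  has_mass <- !is.na(d$monoisotopic_mass)
  drop <- !has_formula & !has_mass
  if (any(drop))
    warning(sum(drop), " suspect row(s) without formula or mass skipped")
  d <- d[!drop, , drop = FALSE]
  mass <- d$monoisotopic_mass
  calc <- rep(NA_real_, nrow(d))
  calc[!is.na(d$formula)] <- vapply(d$formula[!is.na(d$formula)],
                                    function(f) monoisotopic_mass(f), numeric(1))
  both <- !is.na(mass) & !is.na(calc)
  if (any(both & abs(mass - calc) > 0.001))
    stop("suspect mass disagrees with formula by > 0.001 Da for: ",
         paste(d$name[both & abs(mass - calc) > 0.001], collapse = ", "))
  mass[is.na(mass)] <- calc[is.na(mass)]
  data.frame(name = d$name, formula = d$formula, neutral_mass = mass,
             inchikey = d$inchikey, list_code = list_code,
             stringsAsFactors = FALSE)
}

#' Read a pathway definition file
#'
#' Two-column CSV `pathway_id, member` (one compound name per row).
#'
#' @param path Path to the CSV.
#' @return Data frame with columns `pathway_id`, `member`.
#' @export
read_pathways <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("pathway_id", "member") %in% names(d)))
    stop("pathway file needs columns 'pathway_id' and 'member'")
  d[c("pathway_id", "member")]
}
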