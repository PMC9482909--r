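# Orchestration: run the full chain (read -> QC filter -> annotate ->
# confidence levels -> statistics -> overlap -> pathway ORA) from one
# configuration, with a structured log and a hashed output manifest.

#' Default run configuration
#'
#' All module thresholds in one auditable place. Defaults are the study's:
#' QC RSD 50%, precursor/suspect tolerance 5 ppm, MS/MS tolerance 0.01 Da,
#' p < 0.1, FC > 2 or < 0.5, VIP > 1, and the Table-of-rules score
#' boundaries used by the confidence engine. Formula enumeration bounds
#' default to a CHNO space sized for a polar small-molecule scan range.
#'
#' @param ... Named overrides of individual keys.
#' @return Named list of configuration values.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    qc_rsd_max_pct = 50,
    ms1_tol_ppm = 5,
    ms2_tol_mz = 0.01,
    rel_int_floor = 0.01,
    element_bounds = c(C = 30, H = 60, N = 5, O = 10),
    iso_max_peaks = 3L,
    adducts = .DEFAULT_ADDUCTS,
    p_max = 0.1, fc_up = 2, fc_down = 0.5, vip_min = 1,
    fdr = FALSE,
    n_components = 1L, orthogonal = TRUE,
    groups = c("PD", "Ctrl"),
    seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Read a run configuration from YAML
#'
#' Flat keys as in [default_run_config()]; keys absent from the file keep
#' their defaults. Element symbols under `element_bounds` must be quoted
#' (`"N"`, `"F"`), since bare N/F are YAML 1.1 booleans.
#'
#' @param path Path to a YAML file.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$element_bounds)) {
    y$element_bounds <- unlist(y$element_bounds)
    if (any(names(y$element_bounds) %in% c("TRUE", "FALSE")))
      stop("quote element symbols in element_bounds (\"N\", \"F\"): ",
           "bare N/F parse as YAML booleans")
  }
  do.call(default_run_config, y)
}

#' Read a generated dataset directory back into memory
#'
#' Loads the files written by [generate_cohort()] into the same in-memory
#' shape (FeatureSet with MS/MS and isotope patterns attached, library,
#' suspects, pathways, ground truth).
#'
#' @param dir Dataset directory.
#' @return List with `fs`, `library`, `suspects`, `pathways`, `truth`.
#' @export
read_dataset <- function(dir) {
  design <- read_design(file.path(dir, "design.csv"))
  fs <- read_feature_table(file.path(dir, "features.csv"), design)
  ms2 <- read_msp(file.path(dir, "features_ms2.msp"))
  names(ms2) <- vapply(ms2, function(s) s$name, character(1))
  iso_df <- utils::read.csv(file.path(dir, "iso_patterns.csv"),
                            stringsAsFactors = FALSE)
  iso <- lapply(split(iso_df, iso_df$feature_id),
                function(d) data.frame(mass = d$mass, abundance = d$abundance))
  fs <- feature_set(fs$features, fs$intensities, fs$design, ms2 = ms2, iso = iso)
  suspect_files <- list.files(dir, pattern = "^suspects_.*\\.csv$", full.names = TRUE)
  suspects <- do.call(rbind, lapply(sort(suspect_files), function(p) {
    code <- sub("^suspects_(.*)\\.csv$", "\\1", basename(p))
    read_suspect_list(p, code)
  }))
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  list(fs = fs, library = read_msp(file.path(dir, "library.msp")),
       suspects = suspects, pathways = read_pathways(file.path(dir, "pathways.csv")),
       truth = truth)
}

#' Run the full screening and selection pipeline
#'
#' Stage order is fixed: QC RSD filter, suspect screening, evidence
#' assembly, confidence levels (all three schemes), IQR filter,
#' normalization and scaling, univariate statistics, PLS-DA VIP, the
#' three-way selection rule, InChIKey overlap reports, and pathway
#' over-representation on the selected, annotated compounds. Every stage
#' appends a line to the run log; when `out_dir` is given all tables are
#' written as CSV along with the log and an md5 MANIFEST.
#'
#' @param data List with `fs`, `library`, `suspects`, `pathways` — e.g. from
#'   [generate_cohort()] or [read_dataset()].
#' @param config List from [default_run_config()].
#' @param out_dir Optional output directory for CSV tables, log and
#'   MANIFEST.
#' @return List with `qc`, `hits`, `hit_summary`, `evidence`, `levels`,
#'   `selection`, `overlap_esi`, `overlap_lists`, `ora`, `log`, and `config`.
#' @export
run_pipeline <- function(data, config = default_run_config(), out_dir = NULL) {
  log_lines <- character(0)
  say <- function(stage, ...) {
    line <- sprintf("[%s] %s", stage, paste0(...))
    log_lines <<- c(log_lines, line)
    invisible(line)
  }
  say("config", paste(names(config), vapply(config, function(v)
    paste(as.character(v), collapse = ","), character(1)),
    sep = "=", collapse = " "))

  ## 1. QC filter
  qc <- qc_rsd_filter(data$fs, threshold_pct = config$qc_rsd_max_pct)
  fs <- qc$features
  say("qc_filter", nrow(data$fs$features), " features in, ",
      nrow(fs$features), " retained (RSD < ", config$qc_rsd_max_pct, "%)")

  ## 2. Suspect screening + evidence + levels
  hits <- screen_suspects(fs, data$suspects, adducts = config$adducts,
                          tol_ppm = config$ms1_tol_ppm)
  hit_summary <- merge_hits_across_lists(hits)
  say("suspect_screen", nrow(hits), " hits over ",
      length(unique(hits$feature_id)), " features, ",
      nrow(hit_summary), " merged rows")
  evidence <- assemble_evidence(fs, hits, data$library, config)
  levels_tbl <- do.call(rbind, lapply(
    c("suspect_patroon", "nt_patroon", "nt_msdial"),
    function(s) assign_levels(evidence, s)))
  for (s in unique(levels_tbl$scheme)) {
    tb <- table(levels_tbl$level[levels_tbl$scheme == s])
    say("levels", s, ": ", paste(names(tb), tb, sep = "=", collapse = " "))
  }

  ## 3. Statistics on the biological samples
  bio <- names(fs$design)[fs$design %in% config$groups]
  iqr <- iqr_filter(fs$intensities[, bio, drop = FALSE])
  say("iqr_filter", nrow(fs$intensities), " features in, ",
      nrow(iqr$matrix), " retained (", 100 * iqr$frac, "% dropped)")
  ns <- normalize_and_scale(iqr$matrix)
  uni <- univariate_stats(ns$normalized, ns$scaled, fs$design, config$groups)
  vip <- plsda_vip(ns$scaled, fs$design, config$groups,
                   n_components = config$n_components,
                   orthogonal = config$orthogonal)
  selection <- select_significant(uni, vip, p_max = config$p_max,
                                  fc_up = config$fc_up, fc_down = config$fc_down,
                                  vip_min = config$vip_min, fdr = config$fdr)
  say("stats_select", sum(selection$significant), " of ", nrow(selection),
      " features significant (p<", config$p_max, ", FC>", config$fc_up,
      " or <", config$fc_down, ", VIP>", config$vip_min, ")")

  ## 4. Overlap reports by InChIKey (features whose level carries a
  ##    structure identity; 2b/3c/5 have none and are counted as excluded).
  msdial <- levels_tbl[levels_tbl$scheme == "nt_msdial", ]
  keyed <- merge(hit_summary[, c("feature_id", "key", "list_codes")],
                 msdial[, c("feature_id", "level")], by = "feature_id")
  with_key <- keyed[!keyed$level %in% c("2b", "3c", "5"), , drop = FALSE]
  excluded <- sum(keyed$level %in% c("2b", "3c", "5"))
  fmode <- fs$features$esi_mode[match(with_key$feature_id, fs$features$feature_id)]
  overlap_esi <- if (length(unique(fmode)) == 2L) {
    ov <- overlap_sets(list(`ESI+` = with_key$key[fmode == "+"],
                            `ESI-` = with_key$key[fmode == "-"]))
    ov$excluded_count <- excluded
    ov
  } else NULL
  codes <- sort(unique(unlist(strsplit(with_key$list_codes, ","))))
  codes <- utils::head(codes, 4L)
  overlap_lists <- if (length(codes) >= 2L) {
    sets <- lapply(codes, function(cd)
      with_key$key[grepl(cd, with_key$list_codes, fixed = TRUE)])
    names(sets) <- codes
    ov <- overlap_sets(sets)
    ov$excluded_count <- excluded
    ov
  } else NULL
  say("overlap", nrow(with_key), " keyed annotations, ", excluded,
      " excluded (no structure identity)")

  ## 5. Pathway ORA on selected annotated compounds
  universe <- unique(hit_summary$name)
  sig_ids <- selection$feature_id[selection$significant]
  selected <- unique(hit_summary$name[hit_summary$feature_id %in% sig_ids])
  ora <- if (length(selected) && length(universe)) {
    suppressWarnings(pathway_ora(selected, universe, data$pathways))
  } else NULL
  say("pathway_ora", length(selected), " selected of ", length(universe),
      " annotated compounds; ", if (is.null(ora)) 0 else nrow(ora),
      " pathways tested")

  result <- list(qc = qc$stats, hits = hits, hit_summary = hit_summary,
                 evidence = evidence, levels = levels_tbl,
                 iqr_dropped = iqr$dropped, univariate = uni, vip = vip,
                 selection = selection, overlap_esi = overlap_esi,
                 overlap_lists = overlap_lists, ora = ora,
                 log = log_lines, config = config)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wcsv <- function(x, name) {
      p <- file.path(out_dir, name)
      utils::write.csv(x, p, row.names = FALSE, quote = TRUE)
      p
    }
    paths <- c(
      wcsv(qc$stats, "qc_stats.csv"),
      wcsv(hits, "suspect_hits.csv"),
      wcsv(hit_summary, "hit_summary.csv"),
      wcsv(evidence, "evidence.csv"),
      wcsv(levels_tbl, "levels.csv"),
      wcsv(selection, "selection.csv"))
    if (!is.null(overlap_esi))
      paths <- c(paths, wcsv(overlap_esi$cells, "overlap_esi.csv"))
    if (!is.null(overlap_lists))
      paths <- c(paths, wcsv(overlap_lists$cells, "overlap_lists.csv"))
    if (!is.null(ora)) paths <- c(paths, wcsv(ora, "ora.csv"))
    log_path <- file.path(out_dir, "run_log.txt")
    writeLines(log_lines, log_path)
    paths <- c(paths, log_path)
    jsonlite::write_json(
      list(config = lapply(config, function(v) if (is.numeric(v) && length(v) > 1)
        as.list(v) else v),
        files = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                        basename(paths)))),
      file.path(out_dir, "MANIFEST.json"), auto_unbox = TRUE)
  }
  result
}
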