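# Ground-truth synthetic cohort generator: feature tables, MSP libraries,
# suspect lists and pathway files emulating a two-group case/control study
# with pooled QC injections. Annotated "archetype" compounds are engineered
# so that, after processing, every identification confidence level is
# realized in every scheme; spiked differential features with known fold
# change drive the statistical recovery checks.
#
# All structure identifiers (InChIKeys) emitted by the generator are
# deterministic synthetic stand-ins with the real 14-10-1 layout, not real
# database keys.

#' Default synthetic cohort configuration
#'
#' The study conditions: 10 vs 10 samples with 6 pooled QC injections,
#' 500 features of which 20 are spiked at fold change 4, log-normal
#' intensity noise with 20% coefficient of variation, 1 ppm mass error SD,
#' QC RSD around 15% except for 25 features deliberately targeted at 80%
#' to exercise the QC filter.
#'
#' @return Named list of generator parameters.
#' @export
default_cohort_config <- function() {
  list(
    n_pd = 10L, n_ctrl = 10L, n_qc = 6L,
    n_features = 500L, n_spiked = 20L, spike_fc = 4,
    cv = 0.20, ppm_sd = 1.0,
    qc_rsd = 0.15, n_qc_fail = 25L, qc_fail_rsd = 0.80,
    baseline_log10 = c(4, 6), compound_baseline_log10 = c(5.7, 6.3),
    rt_range = c(0.5, 25)
  )
}

## Deterministic synthetic InChIKey (14-10-1 layout) derived from a name.
.synthetic_inchikey <- function(name) {
  x <- utf8ToInt(toupper(gsub("[^A-Za-z0-9]", "", name)))
  if (!length(x)) x <- 7L
  h <- function(k, n) {
    v <- vapply(seq_len(n), function(i) {
      sum(x * (seq_along(x) + i * k)) %% 26L
    }, integer(1))
    paste(LETTERS[v + 1L], collapse = "")
  }
  paste0(h(3L, 14L), "-", h(11L, 8L), "SA-N")
}

## Fragment ion m/z values from neutral losses of a formula; protonated for
## ESI+, deprotonated for ESI-. Returns up to `need` values, precursor-ion
## first, deduplicated to > 0.05 Da spacing.
.fragment_mzs <- function(formula, esi_mode, need) {
  counts <- .as_counts(formula)
  losses <- list(character(0), "H2O", "NH3", "CO", "CO2", "CH2O", "C2H4",
                 "C2H2", "CH4", "H2", c("H2O", "CO"), c("H2O", "CO2"),
                 c("H2O", "NH3"), c("CO", "NH3"), c("H2O", "H2O"))
  shift <- if (esi_mode == "+") .PROTON_MASS else -.PROTON_MASS
  out <- numeric(0)
  for (ls in losses) {
    sub <- counts
    ok <- TRUE
    for (l in ls) {
      lc <- .as_counts(l)
      for (el in names(lc)) {
        cur <- if (el %in% names(sub)) sub[[el]] else 0L
        if (cur < lc[[el]]) { ok <- FALSE; break }
        sub[el] <- cur - lc[[el]]
      }
      if (!ok) break
    }
    if (!ok) next
    sub <- sub[sub > 0]
    if (!length(sub)) next
    mz <- sum(sub * .MONO_MASS[names(sub)]) + shift
    if (mz < 50) next
    if (all(abs(out - mz) > 0.05)) out <- c(out, mz)
    if (length(out) >= need) break
  }
  if (length(out) < need)
    stop("cannot derive ", need, " fragments for ", formula_string(counts))
  out
}

## Deterministic decoy peaks with a ~0.5 mass defect no small-molecule
## sub-formula can reach; `frac` separates ref decoys from query noise.
.decoy_mzs <- function(n, idx, frac) {
  if (n == 0L) return(numeric(0))
  61 + (idx %% 7) * 2.3 + (seq_len(n) - 1L) * 7.1 + frac
}

## The archetype compound table: the identities printed in the study's
## level-2a tables plus synthetic companions, with per-archetype spectral
## construction parameters. true_fc values for the named compounds are the
## study's printed fold changes; synthetic companions are non-differential.
.archetype_compounds <- function() {
  df <- function(...) data.frame(..., stringsAsFactors = FALSE)
  rbind(
    df(name = "L-Valine",         formula = "C5H11NO2",  adduct = "[M+H]+",  lc = "RP",    fraction = "polar",     rt = 2.15,  fc = 2.2627, arch = "A", lists = "PD-CTD"),
    df(name = "Choline",          formula = "C5H14NO",   adduct = "[M]+",    lc = "RP",    fraction = "polar",     rt = 1.88,  fc = 2.0994, arch = "A", lists = "LITMIN"),
    df(name = "Alanine betaine",  formula = "C6H13NO2",  adduct = "[M+H]+",  lc = "HILIC", fraction = "polar",     rt = 4.35,  fc = 0.2875, arch = "A", lists = "LITMIN"),
    df(name = "Glycocholic acid", formula = "C26H43NO6", adduct = "[M-H]-",  lc = "RP",    fraction = "plasma",    rt = 10.8,  fc = 1,      arch = "A", lists = "LITMIN,PD-CTD"),
    df(name = "Isonicotinic acid",formula = "C6H5NO2",   adduct = "[M+H]+",  lc = "RP",    fraction = "non-polar", rt = 2.45,  fc = 2.8013, arch = "B", lists = "PD-CTD"),
    df(name = "syn-b1",           formula = "C4H9NO2",   adduct = "[M+H]+",  lc = "RP",    fraction = "polar",     rt = 3.1,   fc = 1,      arch = "B", lists = "LITMIN"),
    df(name = "syn-b2",           formula = "C7H7NO2",   adduct = "[M+H]+",  lc = "HILIC", fraction = "polar",     rt = 5.2,   fc = 1,      arch = "B", lists = "LITMIN"),
    df(name = "Nicotinamide",     formula = "C6H6N2O",   adduct = "[M+H]+",  lc = "HILIC", fraction = "polar",     rt = 2.47,  fc = 0.2333, arch = "C", lists = "LITMIN,PD-CTD,D003863"),
    df(name = "syn-c1",           formula = "C3H7NO2",   adduct = "[M+H]+",  lc = "HILIC", fraction = "polar",     rt = 6.0,   fc = 1,      arch = "C", lists = "LITMIN"),
    df(name = "syn-c2",           formula = "C8H9NO2",   adduct = "[M+H]+",  lc = "RP",    fraction = "polar",     rt = 7.4,   fc = 1,      arch = "C", lists = "PD-CTD"),
    df(name = "Levodopa",         formula = "C9H11NO4",  adduct = "[M+H]+",  lc = "RP",    fraction = "plasma",    rt = 2.38,  fc = 9.8904, arch = "D", lists = "PD-CTD"),
    df(name = "syn-d1",           formula = "C6H13NO",   adduct = "[M+H]+",  lc = "RP",    fraction = "polar",     rt = 8.3,   fc = 1,      arch = "D", lists = "LITMIN"),
    df(name = "syn-d2",           formula = "C7H14N2O2", adduct = "[M+H]+",  lc = "HILIC", fraction = "polar",     rt = 4.9,   fc = 1,      arch = "D", lists = "LITMIN"),
    df(name = "syn-e1",           formula = "C5H9NO4",   adduct = "[M+H]+",  lc = "RP",    fraction = "polar",     rt = 9.6,   fc = 1,      arch = "E", lists = "LITMIN"),
    df(name = "syn-e2",           formula = "C8H15NO2",  adduct = "[M+H]+",  lc = "RP",    fraction = "non-polar", rt = 12.2,  fc = 1,      arch = "E", lists = "LITMIN"),
    df(name = "syn-e3",           formula = "C4H7NO3",   adduct = "[M+H]+",  lc = "HILIC", fraction = "polar",     rt = 3.8,   fc = 1,      arch = "E", lists = "PD-CTD"),
    df(name = "3-HPPA",           formula = "C9H10O3",   adduct = "[M-H]-",  lc = "RP",    fraction = "non-polar", rt = 13.14, fc = 0.1459, arch = "F", lists = "LITMIN"),
    df(name = "Cholic acid",      formula = "C24H40O5",  adduct = "[M-H]-",  lc = "RP",    fraction = "plasma",    rt = 14.6,  fc = 1,      arch = "F", lists = "LITMIN,PD-CTD"),
    df(name = "syn-f1",           formula = "C10H13NO",  adduct = "[M+H]+",  lc = "RP",    fraction = "non-polar", rt = 15.1,  fc = 1,      arch = "F", lists = "D003863"),
    df(name = "syn-g1",           formula = "C6H11NO2",  adduct = "[M+H]+",  lc = "RP",    fraction = "polar",     rt = 6.7,   fc = 1,      arch = "G", lists = "D003863"),
    df(name = "syn-g2",           formula = "C9H11NO2",  adduct = "[M+H]+",  lc = "RP",    fraction = "polar",     rt = 10.2,  fc = 1,      arch = "G", lists = "D003863"),
    df(name = "syn-g3",           formula = "C5H8O4",    adduct = "[M-H]-",  lc = "HILIC", fraction = "polar",     rt = 5.5,   fc = 1,      arch = "G", lists = "LITMIN"),
    df(name = "syn-h1",           formula = "C4H8N2O3",  adduct = "[M+H]+",  lc = "HILIC", fraction = "polar",     rt = 7.9,   fc = 1,      arch = "H", lists = "LITMIN"),
    df(name = "syn-h2",           formula = "C10H12N2O", adduct = "[M+H]+",  lc = "RP",    fraction = "polar",     rt = 11.4,  fc = 1,      arch = "H", lists = "LITMIN"),
    df(name = "syn-h3",           formula = "C7H8N4O2",  adduct = "[M+H]+",  lc = "RP",    fraction = "polar",     rt = 9.1,   fc = 1,      arch = "H", lists = "PD-CTD"),
    df(name = "syn-i1",           formula = "C11H16N2O2", adduct = "[M+H]+", lc = "RP",    fraction = "polar",     rt = 8.8,   fc = 1,      arch = "I", lists = "PD-CTD"),
    df(name = "syn-i2",           formula = "C6H9N3O2",  adduct = "[M+H]+",  lc = "HILIC", fraction = "polar",     rt = 4.2,   fc = 1,      arch = "I", lists = "PD-CTD"),
    df(name = "syn-i3",           formula = "C12H17NO3", adduct = "[M+H]+",  lc = "RP",    fraction = "non-polar", rt = 16.3,  fc = 1,      arch = "I", lists = "LITMIN"),
    df(name = "syn-j1",           formula = "C5H4N4O",   adduct = "[M+H]+",  lc = "HILIC", fraction = "polar",     rt = 2.9,   fc = 1,      arch = "J", lists = "PD-CTD,D003863"),
    df(name = "syn-j2",           formula = "C8H10N4O2", adduct = "[M+H]+",  lc = "RP",    fraction = "polar",     rt = 6.2,   fc = 1,      arch = "J", lists = "PD-CTD"),
    df(name = "syn-j3",           formula = "C6H8O7",    adduct = "[M-H]-",  lc = "HILIC", fraction = "polar",     rt = 1.6,   fc = 1,      arch = "J", lists = "LITMIN,D003863")
  )
}

## Expected confidence level per archetype under each scheme.
.ARCHETYPE_LEVELS <- list(
  A = c(suspect_patroon = "2a", nt_patroon = "2a", nt_msdial = "2a"),
  B = c(suspect_patroon = "2a", nt_patroon = "2a", nt_msdial = "2b"),
  C = c(suspect_patroon = "3a", nt_patroon = "3a", nt_msdial = "2a"),
  D = c(suspect_patroon = "3a", nt_patroon = "3b", nt_msdial = "3a"),
  E = c(suspect_patroon = "3b", nt_patroon = "5",  nt_msdial = "4a"),
  F = c(suspect_patroon = "3a", nt_patroon = "3a", nt_msdial = "3b"),
  G = c(suspect_patroon = "3a", nt_patroon = "3a", nt_msdial = "3c"),
  H = c(suspect_patroon = "3c", nt_patroon = "4a", nt_msdial = "5"),
  I = c(suspect_patroon = "4a", nt_patroon = "4a", nt_msdial = "4a"),
  J = c(suspect_patroon = "4b", nt_patroon = "5",  nt_msdial = "5")
)

## Reference (library) and query (acquired) spectra for one compound,
## constructed so the spectral scores land in the intended rule bands.
## Equal peak intensities make the cosines exact count ratios.
.compound_spectra <- function(name, formula, adduct, esi_mode, arch, idx) {
  fr <- function(k) .fragment_mzs(formula, esi_mode, k)
  eq <- function(mz) new_spectrum(mz, rep(100, length(mz)))
  ref_mz <- NULL; query <- NULL
  if (arch %in% c("A", "B")) {
    f <- fr(5)
    ints <- c(100, 80, 60, 40, 20)
    ref_mz <- f
    ref <- new_spectrum(f, ints)
    query <- new_spectrum(f, ints)
  } else if (arch == "C") {           # 5 of 6 shared + 1 extra: cos 5/6
    f <- fr(6)
    ref <- eq(f)
    query <- eq(c(f[1:5], .decoy_mzs(1, idx, 0.6333)))
  } else if (arch == "D") {           # 3 shared, query 6, ref 4: cos 0.612
    f <- fr(4)
    ref <- eq(f)
    query <- eq(c(f[1:3], .decoy_mzs(3, idx, 0.6333)))
  } else if (arch == "E") {           # 4 shared, query 13, ref 16: cos 0.277
    f <- fr(4)
    ref <- eq(c(f, .decoy_mzs(12, idx, 0.5111)))
    query <- eq(c(f, .decoy_mzs(9, idx, 0.6333)))
  } else if (arch %in% c("F", "G")) { # 2 of ref 3 matched: cos 0.816
    f <- fr(3)
    ref <- eq(f)
    query <- eq(f[1:2])
  } else if (arch == "H") {           # not in library; fully explainable MS2
    ref <- NULL
    query <- eq(fr(4))
  } else if (arch == "I") {           # poor library match, explainable MS2
    f <- fr(5)
    ref <- eq(c(f[1:2], .decoy_mzs(14, idx, 0.5111)))
    query <- eq(f)
  } else {                            # J: mass + isotope evidence only
    ref <- NULL
    query <- NULL
  }
  if (!is.null(ref)) {
    ref$precursor_mz <- adduct_mz(formula, adduct)
    ref$precursor_type <- adduct
    ref$name <- name
    ref$formula <- formula
    if (!arch %in% c("B", "G")) {     # B/G: structure unknown in library
      ref$inchikey <- .synthetic_inchikey(name)
      ref$structure_known <- TRUE
    }
  }
  list(ref = ref, query = query)
}

#' Generate a synthetic two-group LC-HRMS cohort with ground truth
#'
#' Produces a [feature_set()] (PD vs Ctrl plus pooled QC samples), an MSP
#' reference library, suspect lists, a pathway definition table and a
#' ground-truth record. Intensities are log-normal around per-feature
#' baselines with multiplicative group effects; measured m/z carries a
#' Gaussian ppm error; MS/MS spectra are built from sub-formula fragment
#' ions (plus controlled unexplainable peaks) so that every confidence
#' level of every scheme is realized by at least three compounds.
#'
#' @param config List from [default_cohort_config()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly
#'   (byte-identical files when `dir` is given).
#' @param dir Optional output directory; when given, all tables, MSP files
#'   and the ground truth are written there along with a MANIFEST of md5
#'   hashes.
#' @return List with `fs` (FeatureSet), `library` (list of spectra),
#'   `suspects` (row-bound suspect lists), `pathways`, `truth` (ground-truth
#'   list) and `files` (named paths, or NULL).
#' @export
generate_cohort <- function(config = default_cohort_config(), seed = 1L, dir = NULL) {
  comp <- .archetype_compounds()
  n_comp <- nrow(comp)
  if (config$n_spiked + n_comp + config$n_qc_fail > config$n_features)
    stop("infeasible config: spiked + compound + QC-fail features exceed n_features")
  set.seed(seed)

  comp$esi_mode <- ifelse(grepl("\\+$", comp$adduct), "+", "-")
  comp$theo_mz <- vapply(seq_len(n_comp),
                         function(i) adduct_mz(comp$formula[i], comp$adduct[i]),
                         numeric(1))
  comp$inchikey <- vapply(comp$name, .synthetic_inchikey, character(1))
  comp$in_library <- !comp$arch %in% c("H", "J")
  comp$structure_known <- comp$in_library & !comp$arch %in% c("B", "G")

  samples <- c(sprintf("PD%02d", seq_len(config$n_pd)),
               sprintf("CTRL%02d", seq_len(config$n_ctrl)),
               sprintf("QC%02d", seq_len(config$n_qc)))
  design <- cohort_design(samples, c(rep("PD", config$n_pd),
                                     rep("Ctrl", config$n_ctrl),
                                     rep("QC", config$n_qc)))

  n_other <- config$n_features - n_comp
  ids <- sprintf("F%04d", seq_len(config$n_features))
  comp$feature_id <- ids[seq_len(n_comp)]
  spiked_ids <- ids[n_comp + seq_len(config$n_spiked)]
  null_ids <- ids[(n_comp + config$n_spiked + 1L):config$n_features]
  qc_fail_ids <- null_ids[seq_len(config$n_qc_fail)]

  # Random masses for spiked/null features, kept away from any suspect
  # adduct m/z so they stay unannotated.
  avoid <- comp$theo_mz
  draw_mass <- function() {
    repeat {
      m <- stats::runif(1, 60, 900)
      if (all(abs(ppm_error(m, avoid)) > 30)) return(m)
    }
  }
  other_mz <- vapply(seq_len(n_other), function(i) draw_mass(), numeric(1))

  feats <- data.frame(
    feature_id = ids,
    mz = c(comp$theo_mz, other_mz),
    rt = c(comp$rt, stats::runif(n_other, config$rt_range[1], config$rt_range[2])),
    esi_mode = c(comp$esi_mode, sample(c("+", "-"), n_other, TRUE, prob = c(0.7, 0.3))),
    lc_mode = c(comp$lc, sample(c("RP", "HILIC"), n_other, TRUE)),
    fraction = c(comp$fraction, sample(c("polar", "non-polar", "plasma"), n_other, TRUE)),
    stringsAsFactors = FALSE)
  feats$mz <- feats$mz * (1 + stats::rnorm(nrow(feats)) * config$ppm_sd * 1e-6)

  true_fc <- c(comp$fc,
               rep(config$spike_fc, config$n_spiked),
               rep(1, length(null_ids)))
  names(true_fc) <- ids
  b <- config$compound_baseline_log10
  n <- config$baseline_log10
  baseline <- c(10^stats::runif(n_comp + config$n_spiked, b[1], b[2]),
                10^stats::runif(length(null_ids), n[1], n[2]))
  names(baseline) <- ids

  sdlog <- sqrt(log(1 + config$cv^2))
  qc_rsd <- ifelse(ids %in% qc_fail_ids, config$qc_fail_rsd, config$qc_rsd)
  sdlog_qc <- sqrt(log(1 + qc_rsd^2))
  nf <- config$n_features
  draw <- function(mean_vec, sd_vec, ncol) {
    meanlog <- log(mean_vec) - sd_vec^2 / 2   # log-normal mean = mean_vec
    matrix(stats::rlnorm(nf * ncol, meanlog = rep(meanlog, ncol),
                         sdlog = rep(sd_vec, ncol)),
           nrow = nf, ncol = ncol)
  }
  pd_mat <- draw(baseline * true_fc, rep(sdlog, nf), config$n_pd)
  ctrl_mat <- draw(baseline, rep(sdlog, nf), config$n_ctrl)
  qc_mat <- draw(baseline * (1 + true_fc) / 2, sdlog_qc, config$n_qc)
  intensities <- cbind(pd_mat, ctrl_mat, qc_mat)
  dimnames(intensities) <- list(ids, samples)

  # Spectra and observed isotope patterns per archetype construction.
  ms2 <- list(); iso <- list(); library_specs <- list()
  for (i in seq_len(n_comp)) {
    sp <- .compound_spectra(comp$name[i], comp$formula[i], comp$adduct[i],
                            comp$esi_mode[i], comp$arch[i], i)
    if (!is.null(sp$ref)) library_specs[[length(library_specs) + 1L]] <- sp$ref
    if (!is.null(sp$query)) {
      sp$query$name <- comp$feature_id[i]
      sp$query$precursor_mz <- feats$mz[i]
      ms2[[comp$feature_id[i]]] <- sp$query
    }
    if (comp$arch[i] %in% c("H", "I", "J"))
      iso[[comp$feature_id[i]]] <- isotope_pattern(comp$formula[i], max_peaks = 3L)
  }
  # Library decoys at masses no feature carries.
  for (k in 1:5) {
    dm <- 500 + k * 17.3
    s <- new_spectrum(.decoy_mzs(4, k, 0.5111), rep(100, 4),
                      precursor_mz = dm, precursor_type = "[M+H]+",
                      name = sprintf("decoy-%02d", k),
                      inchikey = .synthetic_inchikey(sprintf("decoy-%02d", k)))
    library_specs[[length(library_specs) + 1L]] <- s
  }

  fs <- feature_set(feats, intensities, design, ms2 = ms2, iso = iso)

  # Suspect lists: archetype compounds by membership, plus a small
  # dyssomnia-style list of decoy suspects that matches nothing.
  mem <- strsplit(comp$lists, ",")
  suspect_rows <- do.call(rbind, lapply(seq_len(n_comp), function(i) {
    data.frame(name = comp$name[i], formula = comp$formula[i],
               neutral_mass = monoisotopic_mass(comp$formula[i]),
               inchikey = comp$inchikey[i], list_code = mem[[i]],
               stringsAsFactors = FALSE)
  }))
  decoy_suspects <- data.frame(
    name = sprintf("decoy-suspect-%02d", 1:6),
    formula = c("C14H22N2O", "C16H13ClN2O", "C13H16N2O2",
                "C15H21NO2", "C17H19NO3", "C18H21NO4"),
    stringsAsFactors = FALSE)
  decoy_suspects$neutral_mass <- vapply(decoy_suspects$formula,
                                        monoisotopic_mass, numeric(1))
  decoy_suspects$inchikey <- vapply(decoy_suspects$name, .synthetic_inchikey,
                                    character(1))
  decoy_suspects$list_code <- "D020920"
  suspects <- rbind(suspect_rows, decoy_suspects)

  pathways <- data.frame(
    pathway_id = c(rep("amino acid metabolism", 5),
                   rep("nicotinate and nicotinamide metabolism", 3),
                   rep("bile acid biosynthesis", 3),
                   rep("background metabolism", 8)),
    member = c("L-Valine", "Levodopa", "Alanine betaine", "syn-d1", "syn-d2",
               "Nicotinamide", "Isonicotinic acid", "syn-c1",
               "Cholic acid", "Glycocholic acid", "syn-f1",
               "syn-g1", "syn-g2", "syn-g3", "syn-h1", "syn-h2", "syn-h3",
               "syn-i1", "syn-j1"),
    stringsAsFactors = FALSE)

  truth <- list(
    seed = seed, config = config,
    compounds = data.frame(
      feature_id = comp$feature_id, name = comp$name, formula = comp$formula,
      adduct = comp$adduct, esi_mode = comp$esi_mode, archetype = comp$arch,
      true_fc = comp$fc, in_library = comp$in_library,
      structure_known = comp$structure_known, lists = comp$lists,
      inchikey = comp$inchikey,
      expected_suspect = vapply(comp$arch, function(a) .ARCHETYPE_LEVELS[[a]][["suspect_patroon"]], character(1)),
      expected_nt_patroon = vapply(comp$arch, function(a) .ARCHETYPE_LEVELS[[a]][["nt_patroon"]], character(1)),
      expected_nt_msdial = vapply(comp$arch, function(a) .ARCHETYPE_LEVELS[[a]][["nt_msdial"]], character(1)),
      stringsAsFactors = FALSE),
    spiked = spiked_ids, qc_fail = qc_fail_ids, null = setdiff(null_ids, qc_fail_ids),
    true_fc = true_fc)

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c(
      features = file.path(dir, "features.csv"),
      design = file.path(dir, "design.csv"),
      library = file.path(dir, "library.msp"),
      ms2 = file.path(dir, "features_ms2.msp"),
      iso = file.path(dir, "iso_patterns.csv"),
      pathways = file.path(dir, "pathways.csv"),
      truth = file.path(dir, "ground_truth.json"))
    write_feature_table(fs, files[["features"]])
    utils::write.csv(data.frame(sample_id = names(design), group = unname(design)),
                     files[["design"]], row.names = FALSE, quote = FALSE)
    write_msp(library_specs, files[["library"]])
    write_msp(ms2, files[["ms2"]])
    iso_df <- do.call(rbind, lapply(names(iso), function(fid) {
      data.frame(feature_id = fid, mass = iso[[fid]]$mass,
                 abundance = iso[[fid]]$abundance, stringsAsFactors = FALSE)
    }))
    utils::write.csv(iso_df, files[["iso"]], row.names = FALSE, quote = FALSE)
    for (code in unique(suspects$list_code)) {
      p <- file.path(dir, sprintf("suspects_%s.csv", code))
      sl <- suspects[suspects$list_code == code,
                     c("name", "formula", "neutral_mass", "inchikey", "list_code")]
      names(sl)[names(sl) == "neutral_mass"] <- "monoisotopic_mass"
      utils::write.csv(sl, p, row.names = FALSE, quote = TRUE)
      files[paste0("suspects_", code)] <- p
    }
    utils::write.csv(pathways, files[["pathways"]], row.names = FALSE, quote = TRUE)
    jsonlite::write_json(truth, files[["truth"]], auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    manifest <- file.path(dir, "MANIFEST.json")
    hashes <- tools::md5sum(unname(files))
    jsonlite::write_json(
      list(files = as.list(stats::setNames(unname(hashes), basename(names(hashes))))),
      manifest, auto_unbox = TRUE)
    files <- c(files, manifest = manifest)
  }

  list(fs = fs, library = library_specs, suspects = suspects,
       pathways = pathways, truth = truth, files = files)
}
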