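# Pooled-QC relative standard deviation filtering: only features whose
# intensity RSD over the QC injections stays below the threshold are kept.

#' Filter features by QC relative standard deviation
#'
#' For every feature the mean, sample standard deviation (n-1 denominator) and
#' RSD (100 * sd / mean) over the QC samples are computed. Features are
#' retained when RSD is strictly below `threshold_pct` and the QC mean is
#' positive; features with zero QC mean (RSD undefined) are removed rather
#' than erroring, so blank-like synthetic features cannot crash the pipeline.
#'
#' @param fs A [feature_set()] whose design contains at least 3 QC samples.
#' @param threshold_pct RSD retention threshold in percent (default 50; the
#'   boundary itself is excluded).
#' @return List with `features` (the retained FeatureSet, input order
#'   preserved) and `stats` (a `QCStats` data frame for every input feature:
#'   `feature_id`, `mean`, `sd`, `rsd`, `retained`).
#' @export
qc_rsd_filter <- function(fs, threshold_pct = 50) {
  qc_samples <- names(fs$design)[fs$design == "QC"]
  if (length(qc_samples) < 3L)
    stop("QC RSD filter needs >= 3 QC samples; design has ", length(qc_samples))
  qm <- fs$intensities[, qc_samples, drop = FALSE]
  mu <- rowMeans(qm)
  sdev <- apply(qm, 1L, stats::sd)
  rsd <- ifelse(mu > 0, 100 * sdev / mu, NA_real_)
  retained <- !is.na(rsd) & rsd < threshold_pct
  stats <- data.frame(feature_id = fs$features$feature_id,
                      mean = mu, sd = sdev, rsd = rsd, retained = retained,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(features = subset_features(fs, fs$features$feature_id[retained]),
       stats = stats)
}
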