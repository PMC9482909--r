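# Molecular formula arithmetic, adduct m/z and theoretical isotope patterns:
# the mass backbone used by suspect screening and formula annotation.

## Monoisotopic atomic masses (Da) of the most abundant isotope, IUPAC values.
.MONO_MASS <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.9737619984,
  S  = 31.9720711744,
  F  = 18.9984031627,
  Cl = 34.9688526820,
  Br = 78.9183376,
  Na = 22.9897692820
)

.PROTON_MASS   <- 1.00727646
.ELECTRON_MASS <- 0.00054858

## Natural isotope distributions on the nominal-mass (A, A+1, ...) grid.
## offset = nominal mass units above the principal isotope.
.ISOTOPES <- list(
  C  = list(offset = c(0L, 1L), mass = c(12.0, 13.0033548378),
            abundance = c(0.9893, 0.0107)),
  H  = list(offset = c(0L, 1L), mass = c(1.0078250319, 2.0141017780),
            abundance = c(0.999885, 0.000115)),
  N  = list(offset = c(0L, 1L), mass = c(14.0030740052, 15.0001088984),
            abundance = c(0.99636, 0.00364)),
  O  = list(offset = c(0L, 1L, 2L),
            mass = c(15.9949146221, 16.9991317012, 17.9991596129),
            abundance = c(0.99757, 0.00038, 0.00205)),
  S  = list(offset = c(0L, 1L, 2L, 4L),
            mass = c(31.9720711744, 32.9714589098, 33.9678670040, 35.9670807100),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Cl = list(offset = c(0L, 2L), mass = c(34.9688526820, 36.9659026000),
            abundance = c(0.7576, 0.2424)),
  Br = list(offset = c(0L, 2L), mass = c(78.9183376, 80.9162897),
            abundance = c(0.5069, 0.4931)),
  F  = list(offset = 0L, mass = 18.9984031627, abundance = 1),
  P  = list(offset = 0L, mass = 30.9737619984, abundance = 1),
  Na = list(offset = 0L, mass = 22.9897692820, abundance = 1)
)

## Supported adducts. mass_shift is the neutral-atom mass added to (or removed
## from) M; the electron bookkeeping is done from the charge, so that
## m/z = (M + mass_shift - charge * m_e) / |charge|.
.ADDUCTS <- data.frame(
  name = c("[M+H]+", "[M+Na]+", "[M+NH4]+", "[M]+", "[M-H]-", "[M+HCOO]-"),
  mass_shift = c(
    1.0078250319,
    22.9897692820,
    14.0030740052 + 4 * 1.0078250319,
    0,
    -1.0078250319,
    12.0 + 1.0078250319 + 2 * 15.9949146221
  ),
  charge = c(1L, 1L, 1L, 1L, -1L, -1L),
  stringsAsFactors = FALSE
)

#' Parse a molecular formula in Hill notation
#'
#' Parses a formula string such as `"C5H11NO2"` into named element counts.
#' Supported elements: C, H, N, O, P, S, F, Cl, Br, Na.
#'
#' @param text A single formula string (element symbols with optional counts).
#' @return Named integer vector of element counts, in Hill order.
#' @examples
#' parse_formula("C5H11NO2")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  text <- gsub("[[:space:]_]", "", text)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (!length(toks) || paste(toks, collapse = "") != text)
    stop("cannot parse formula string: '", text, "'")
  sym <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Za-z]+", "", toks)
  bad <- setdiff(sym, names(.MONO_MASS))
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  if (any(cnt == "0" | grepl("^0", cnt)))
    stop("zero element count in formula: '", text, "'")
  n <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  counts <- tapply(n, sym, sum)
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (sum(counts) < 1L) stop("formula must contain at least one atom")
  counts[.hill_order(names(counts))]
}

## Hill ordering of element symbols: C, H first when carbon present,
## everything else alphabetical.
.hill_order <- function(symbols) {
  if ("C" %in% symbols) {
    rest <- sort(setdiff(symbols, c("C", "H")))
    c("C", intersect("H", symbols), rest)
  } else {
    sort(symbols)
  }
}

## Coerce a formula given as string or named count vector to counts.
.as_counts <- function(f) {
  if (is.character(f)) return(parse_formula(f))
  if (is.null(names(f)) || !is.numeric(f))
    stop("formula must be a string or a named count vector")
  f <- f[f != 0]
  bad <- setdiff(names(f), names(.MONO_MASS))
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  if (any(f < 0)) stop("negative element count")
  stats::setNames(as.integer(f), names(f))[.hill_order(names(f))]
}

#' Serialize element counts to a canonical Hill formula string
#'
#' @param counts Named element counts (or a formula string, which is
#'   canonicalized).
#' @return Canonical Hill-notation string.
#' @export
formula_string <- function(counts) {
  counts <- .as_counts(counts)
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of element counts times the mass of each element's most abundant
#' isotope.
#'
#' @param f Formula string or named count vector.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C5H11NO2") # 117.078979
#' @export
monoisotopic_mass <- function(f) {
  counts <- .as_counts(f)
  sum(counts * .MONO_MASS[names(counts)])
}

#' Supported ESI adducts
#'
#' @return Data frame with columns `name`, `mass_shift` (Da, neutral-atom sum),
#'   and `charge`.
#' @export
supported_adducts <- function() .ADDUCTS

#' Canonicalize and look up an adduct by name
#'
#' Whitespace and unicode minus signs inside the bracketed name are tolerated
#' on input (`"[M + H] +"` parses as `"[M+H]+"`).
#'
#' @param name Adduct name in the bracketed convention.
#' @return One-row data frame with `name`, `mass_shift`, `charge`.
#' @export
parse_adduct <- function(name) {
  if (!is.character(name) || length(name) != 1L) stop("adduct name must be a single string")
  canon <- gsub("[[:space:]]", "", name)
  canon <- gsub("−|–", "-", canon)
  i <- match(canon, .ADDUCTS$name)
  if (is.na(i))
    stop("unsupported adduct '", name, "'; supported: ",
         paste(.ADDUCTS$name, collapse = ", "))
  .ADDUCTS[i, , drop = FALSE]
}

#' Theoretical m/z of a formula under an adduct
#'
#' Computes `(M + mass_shift - charge * m_e) / |charge|`. For `"[M]+"` the
#' formula describes the intact cation's atoms (e.g. quaternary ammonium
#' species such as choline) and one electron mass is subtracted.
#'
#' @param f Formula string or named counts.
#' @param adduct Adduct name (see [supported_adducts()]) or a one-row adduct
#'   data frame.
#' @return m/z in Th.
#' @examples
#' adduct_mz("C5H11NO2", "[M+H]+") # 118.086255
#' @export
adduct_mz <- function(f, adduct) {
  if (is.character(adduct)) adduct <- parse_adduct(adduct)
  m <- monoisotopic_mass(f)
  (m + adduct$mass_shift - adduct$charge * .ELECTRON_MASS) / abs(adduct$charge)
}

## Invert adduct_mz: neutral (or ion-atom) monoisotopic mass from observed m/z.
.neutral_mass_from_mz <- function(mz, adduct) {
  if (is.character(adduct)) adduct <- parse_adduct(adduct)
  mz * abs(adduct$charge) - adduct$mass_shift + adduct$charge * .ELECTRON_MASS
}

#' Signed mass error in parts per million
#'
#' @param observed Observed m/z.
#' @param theoretical Theoretical m/z (must be positive).
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  1e6 * (observed - theoretical) / theoretical
}

#' Theoretical isotope pattern of a formula
#'
#' Convolution of per-element natural isotope distributions, aggregated on the
#' unit-mass grid (A, A+1, A+2, ...), truncated to `max_peaks` and normalized
#' so the most abundant peak equals 1. Fine isotopologue structure is not
#' resolved; the envelope matches what an Orbitrap-resolved pattern comparison
#' consumes.
#'
#' @param f Formula string or named counts.
#' @param max_peaks Number of envelope peaks to keep (>= 2).
#' @return Data frame with columns `mass` (Da, abundance-weighted within each
#'   nominal bin) and `abundance` (base peak = 1), ordered by mass. The full
#'   untruncated probability vector is attached as attribute `"raw_abundance"`.
#' @export
isotope_pattern <- function(f, max_peaks = 4L) {
  if (max_peaks < 2L) stop("max_peaks must be >= 2")
  counts <- .as_counts(f)
  cap <- 40L  # offsets tracked internally; plenty for natural-abundance tails
  p <- c(1, numeric(cap))          # probability per offset 0..cap
  mexp <- numeric(cap + 1L)        # expected mass per offset
  for (el in names(counts)) {
    iso <- .ISOTOPES[[el]]
    for (i in seq_len(counts[[el]])) {
      pnew <- numeric(cap + 1L)
      mnew <- numeric(cap + 1L)
      for (k in seq_along(iso$offset)) {
        off <- iso$offset[k]
        idx <- seq_len(cap + 1L - off)
        contrib <- p[idx] * iso$abundance[k]
        pnew[idx + off] <- pnew[idx + off] + contrib
        mnew[idx + off] <- mnew[idx + off] + contrib * (mexp[idx] + iso$mass[k])
      }
      p <- pnew
      mexp <- ifelse(pnew > 0, mnew / pnew, 0)
    }
  }
  keep <- which(p > 0)
  keep <- keep[seq_len(min(length(keep), max_peaks))]
  out <- data.frame(mass = mexp[keep], abundance = p[keep] / max(p[keep]))
  attr(out, "raw_abundance") <- p
  out
}
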