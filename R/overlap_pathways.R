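# Set-overlap reports across ESI modes, LC modes and suspect lists
# (by InChIKey), and hypergeometric pathway over-representation.

#' Exact Venn partition of 2-4 named identifier sets
#'
#' Counts, for every non-empty combination of the input sets, the
#' identifiers belonging to exactly that combination. Cell counts sum to the
#' size of the union; ordering of cells is deterministic (by combination
#' size, then set order as given) and invariant to input ordering of
#' members.
#'
#' @param sets Named list of 2-4 character vectors (e.g. InChIKeys);
#'   duplicates within a set are ignored.
#' @param first_block Compare by the 14-character InChIKey first block
#'   instead of the full key (default FALSE).
#' @return List with `cells` (data frame `cell`, `count`), `n_union`, and
#'   `set_sizes`.
#' @export
overlap_sets <- function(sets, first_block = FALSE) {
  if (length(sets) < 2L || length(sets) > 4L)
    stop("overlap_sets takes 2-4 sets; report pairwise for more")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  sets <- lapply(sets, function(s) {
    s <- unique(as.character(s[!is.na(s) & nzchar(s)]))
    if (first_block) unique(substr(s, 1L, 14L)) else s
  })
  universe <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))[-(2^length(sets)), , drop = FALSE]
  names(combos) <- names(sets)
  combos <- combos[order(rowSums(combos), apply(!combos, 1L, paste, collapse = "")), , drop = FALSE]
  cells <- data.frame(
    cell = apply(combos, 1L, function(r) paste(names(sets)[unlist(r)], collapse = "&")),
    count = apply(combos, 1L, function(r) {
      sum(apply(member, 1L, function(m) all(m == unlist(r))))
    }),
    row.names = NULL, stringsAsFactors = FALSE)
  list(cells = cells, n_union = length(universe),
       set_sizes = vapply(sets, length, integer(1)))
}

#' Hypergeometric pathway over-representation analysis
#'
#' For each pathway, tests whether the selected compounds contain at least
#' the observed number of pathway members, against random draws of
#' `|selected|` compounds from the universe: the upper-tail hypergeometric
#' probability `P(X >= hits)`. Compound names are matched exactly after
#' case-folding and whitespace normalization; duplicates are removed before
#' testing. Pathways with no member in the universe are excluded with a
#' warning.
#'
#' @param selected Character vector of selected compound names (must be a
#'   subset of `universe` after normalization).
#' @param universe Character vector of all candidate compound names.
#' @param pathways Data frame with columns `pathway_id`, `member`.
#' @return `PathwayResult` data frame sorted by p-value: `pathway_id`,
#'   `hits`, `pathway_size`, `universe_size`, `selected_size`, `p_value`.
#' @export
pathway_ora <- function(selected, universe, pathways) {
  norm <- function(x) tolower(trimws(gsub("[[:space:]]+", " ", x)))
  universe <- unique(norm(universe))
  if (!length(universe)) stop("empty universe")
  selected <- unique(norm(selected))
  extra <- setdiff(selected, universe)
  if (length(extra))
    stop("selected compound(s) not in universe: ", paste(extra, collapse = ", "))
  N <- length(universe); k <- length(selected)
  rows <- lapply(split(norm(pathways$member), pathways$pathway_id), function(members) {
    members <- unique(members)
    m <- length(intersect(members, universe))
    if (m == 0L) return(NULL)
    hits <- length(intersect(members, selected))
    p <- stats::phyper(hits - 1L, m, N - m, k, lower.tail = FALSE)
    data.frame(hits = hits, pathway_size = m, universe_size = N,
               selected_size = k, p_value = p)
  })
  skipped <- names(rows)[vapply(rows, is.null, logical(1))]
  if (length(skipped))
    warning("pathway(s) disjoint from universe excluded: ",
            paste(skipped, collapse = ", "))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(pathway_id = character(0), hits = integer(0),
                      pathway_size = integer(0), universe_size = integer(0),
                      selected_size = integer(0), p_value = numeric(0),
                      stringsAsFactors = FALSE))
  out <- cbind(data.frame(pathway_id = names(rows), stringsAsFactors = FALSE),
               do.call(rbind, rows))
  out <- out[order(out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
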