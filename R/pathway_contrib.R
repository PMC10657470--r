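# Per-taxon contribution to stratified pathways, summarized by diagnosis
# group — the "which genera drive the arginine pathways" tables.

parse_strat_taxon <- function(keys, rank = c("genus", "species")) {
  rank <- match.arg(rank)
  tax <- sub("^[^|]*\\|", "", keys)
  if (rank == "genus") {
    out <- ifelse(grepl("g__", tax), sub("^.*?(g__[^.|]+).*$", "\\1", tax), tax)
  } else {
    out <- ifelse(grepl("s__", tax), sub("^.*?(s__[^.|]+).*$", "\\1", tax), tax)
  }
  out  # "unclassified" strata pass through unchanged
}

#' Per-sample taxon fractions within one pathway
#'
#' For each sample, each taxon's share of the pathway's total stratified
#' abundance at the chosen taxonomic rank (several stratified rows
#' mapping to the same taxon are pooled). Samples whose stratified total
#' is zero yield `NA` fractions and are excluded by downstream
#' summaries.
#'
#' @param pathways a [pathway_table()].
#' @param pathway_id pathway identifier (the key part before `:`), e.g.
#'   `"ARGSYN-PWY"`.
#' @param rank `"genus"` (default) or `"species"`.
#' @return matrix of fractions, taxa x samples, columns summing to 1 (or
#'   all-`NA`); attributes `pathway_id`, `rank`, and `abundance` (the
#'   pooled stratified abundances, for pooled-mode summaries).
#' @export
taxon_fractions <- function(pathways, pathway_id,
                            rank = c("genus", "species")) {
  stopifnot(inherits(pathways, "pathway_table"))
  rank <- match.arg(rank)
  keys <- pathways$row_keys
  id_of <- sub(":.*$", "", sub("\\|.*$", "", keys))
  strat <- grepl("|", keys, fixed = TRUE) & id_of == pathway_id
  if (!pathway_id %in% id_of)
    stop("lookup error: unknown pathway '", pathway_id, "'")
  if (!any(strat))
    stop("lookup error: pathway '", pathway_id, "' has no stratified rows")
  taxa <- parse_strat_taxon(keys[strat], rank)
  ab <- rowsum(pathways$values[strat, , drop = FALSE], taxa)
  tot <- colSums(ab)
  frac <- sweep(ab, 2, tot, "/")
  frac[, tot == 0] <- NA_real_
  structure(frac, pathway_id = pathway_id, rank = rank, abundance = ab)
}

#' Group-stratified percent contribution table
#'
#' Summarizes per-sample taxon fractions by diagnosis group. In
#' `"mean"` mode (default) each sample is first normalized to fractions
#' and the group value is the mean fraction, renormalized to sum to 100
#' — so high-biomass samples do not dominate. In `"pooled"` mode
#' abundances are summed across the group's samples before normalizing.
#'
#' @param fractions output of [taxon_fractions()].
#' @param groups group label per sample: a vector named by sample id, or
#'   unnamed and aligned with the fraction columns.
#' @param mode `"mean"` or `"pooled"`.
#' @param digits decimals for the reported percents (default 2).
#' @return data.frame of class `contribution_table`: `pathway_id`,
#'   `taxon`, `group`, `percent`; within each group the percents sum to
#'   100 (up to rounding). Groups with no usable sample are omitted with
#'   a warning.
#' @export
group_contribution <- function(fractions, groups, mode = c("mean", "pooled"),
                               digits = 2) {
  mode <- match.arg(mode)
  if (!is.null(names(groups))) {
    if (!all(colnames(fractions) %in% names(groups)))
      stop("validation error: every sample needs a group label")
    groups <- groups[colnames(fractions)]
  } else if (length(groups) != ncol(fractions)) {
    stop("validation error: group labels do not align with samples")
  }
  groups <- as.character(groups)
  ab <- attr(fractions, "abundance")
  out <- list()
  for (g in unique(groups)) {
    cols <- which(groups == g)
    usable <- cols[!is.na(fractions[1, cols])]
    if (length(usable) == 0) {
      warning("group '", g, "' has no sample with stratified abundance; omitted")
      next
    }
    v <- if (mode == "mean") {
      rowMeans(fractions[, usable, drop = FALSE])
    } else {
      tot <- rowSums(ab[, usable, drop = FALSE])
      tot / sum(tot)
    }
    out[[g]] <- data.frame(pathway_id = attr(fractions, "pathway_id"),
                           taxon = rownames(fractions), group = g,
                           percent = round(100 * v / sum(v), digits),
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  if (length(out) == 0) stop("validation error: no usable group")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("contribution_table", "data.frame")
  res
}
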