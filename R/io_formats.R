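# Readers/writers for the two taxonomic/functional interchange formats
# (MetaPhlAn merged-profile TSV, HUMAnN pathabundance TSV) plus cohort
# accounting helpers.

#' Construct a species relative-abundance table
#'
#' Container for a samples-by-species relative-abundance matrix on the
#' percent scale (0--100), stored with species as rows and samples as
#' columns, matching the on-disk layout of MetaPhlAn merged profiles.
#'
#' @param values numeric matrix, species x samples, percent scale.
#' @param species character vector of taxon names (full lineage strings or
#'   terminal species names); defaults to `rownames(values)`.
#' @param samples character vector of sample identifiers; defaults to
#'   `colnames(values)`.
#' @return An object of class `species_table`: a list with elements
#'   `species`, `samples` and `values`.
#' @details Invariants enforced: all values finite and >= 0; per-sample
#'   column sums <= 100 + 1e-6; species and sample names unique.
#' @export
species_table <- function(values, species = rownames(values),
                          samples = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("validation error: abundance values must be numeric")
  if (is.null(species) || is.null(samples))
    stop("validation error: species and sample names are required")
  species <- as.character(species)
  samples <- as.character(samples)
  if (length(species) != nrow(values) || length(samples) != ncol(values))
    stop("validation error: dimension mismatch between names and values")
  if (anyDuplicated(species)) stop("validation error: duplicated species names")
  if (anyDuplicated(samples)) stop("validation error: duplicated sample ids")
  if (any(!is.finite(values))) stop("validation error: non-finite abundance value")
  if (any(values < 0)) stop("validation error: negative abundance value")
  if (ncol(values) > 0 && any(colSums(values) > 100 + 1e-6))
    stop("validation error: per-sample species abundances exceed 100%")
  dimnames(values) <- list(species, samples)
  structure(list(species = species, samples = samples, values = values),
            class = "species_table")
}

#' @export
print.species_table <- function(x, ...) {
  cat("<species_table> ", length(x$species), " species x ",
      length(x$samples), " samples (percent scale)\n", sep = "")
  invisible(x)
}

#' Construct a pathway-abundance table
#'
#' Container for HUMAnN-style pathway abundances. Row keys are either a
#' community total (`PWY-ID: name`), a taxon-stratified row
#' (`PWY-ID: name|g__Genus.s__species` or `...|unclassified`), or the
#' special rows `UNMAPPED` / `UNINTEGRATED`.
#'
#' @param values numeric matrix, rows x samples, abundance units (e.g. CPM).
#' @param row_keys character row keys; defaults to `rownames(values)`.
#' @param samples character sample ids; defaults to `colnames(values)`.
#' @return An object of class `pathway_table` with elements `row_keys`,
#'   `samples`, `values`.
#' @details For every pathway that has stratified rows, the per-sample sum
#'   of stratified rows must not exceed the community-total row beyond a
#'   small tolerance (`UNMAPPED`/`UNINTEGRATED` excluded).
#' @export
pathway_table <- function(values, row_keys = rownames(values),
                          samples = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("validation error: abundance values must be numeric")
  if (is.null(row_keys) || is.null(samples))
    stop("validation error: row keys and sample ids are required")
  row_keys <- as.character(row_keys)
  samples <- as.character(samples)
  if (length(row_keys) != nrow(values) || length(samples) != ncol(values))
    stop("validation error: dimension mismatch between names and values")
  if (anyDuplicated(row_keys)) stop("validation error: duplicated row keys")
  if (anyDuplicated(samples)) stop("validation error: duplicated sample ids")
  if (any(!is.finite(values))) stop("validation error: non-finite abundance value")
  if (any(values < 0)) stop("validation error: negative abundance value")
  dimnames(values) <- list(row_keys, samples)

  strat <- grepl("|", row_keys, fixed = TRUE)
  special <- row_keys %in% c("UNMAPPED", "UNINTEGRATED")
  pwy_of <- function(k) sub("\\|.*$", "", k)
  for (pwy in unique(pwy_of(row_keys[strat]))) {
    tot_row <- which(!strat & !special & row_keys == pwy)
    if (length(tot_row) != 1)
      stop("validation error: stratified rows for '", pwy,
           "' have no community-total row")
    srows <- which(strat & pwy_of(row_keys) == pwy)
    ssum <- colSums(values[srows, , drop = FALSE])
    tot <- values[tot_row, ]
    if (any(ssum > tot + 1e-6 + 1e-6 * tot))
      stop("validation error: stratified rows exceed community total for '",
           pwy, "'")
  }
  structure(list(row_keys = row_keys, samples = samples, values = values),
            class = "pathway_table")
}

#' @export
print.pathway_table <- function(x, ...) {
  n_strat <- sum(grepl("|", x$row_keys, fixed = TRUE))
  cat("<pathway_table> ", length(x$row_keys), " rows (", n_strat,
      " stratified) x ", length(x$samples), " samples\n", sep = "")
  invisible(x)
}

# Shared TSV front-end. MetaPhlAn/HUMAnN tables comment with '#' but their
# header row may itself start with '#' ("#clade_name", "# Pathway"): if the
# first non-comment line already looks like data, the preceding comment
# line is taken as the header.
read_profile_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("format error: empty file '", path, "'")
  is_comment <- startsWith(lines, "#")
  first_data <- which(!is_comment)[1]
  looks_numeric <- function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    length(f) >= 2 && !anyNA(suppressWarnings(as.numeric(f[-1])))
  }
  if (is.na(first_data)) {
    # all lines are comments; the last one must be the header of an empty table
    header_line <- lines[length(lines)]
    body <- character(0)
  } else if (looks_numeric(lines[first_data])) {
    if (first_data == 1 || !grepl("\t", lines[first_data - 1], fixed = TRUE))
      stop("format error: no header row found in '", path, "'")
    header_line <- lines[first_data - 1]
    body <- lines[first_data:length(lines)]
  } else {
    header_line <- lines[first_data]
    body <- if (first_data < length(lines)) lines[(first_data + 1):length(lines)] else character(0)
  }
  header <- strsplit(sub("^#\\s*", "", header_line), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2)
    stop("format error: malformed header (no sample columns) in '", path, "'")
  rows <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(rows) != length(header)))
    stop("format error: ragged rows in '", path, "'")
  keys <- vapply(rows, `[`, character(1), 1)
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(header) - 1)
  if (length(rows) > 0) {
    vals <- do.call(rbind, lapply(rows, function(f) {
      v <- suppressWarnings(as.numeric(f[-1]))
      if (anyNA(v)) stop("format error: non-numeric abundance value in '", path, "'")
      v
    }))
  }
  list(keys = keys, samples = header[-1], values = vals)
}

#' Read a MetaPhlAn-style merged species abundance table
#'
#' Parses a merged taxonomic-profile TSV (taxon lineage in the first
#' column, one column per sample, percent-scale abundances, `#` comment
#' lines) and retains only species-level rows: lineages containing a
#' species rank (`s__`) and no strain rank (`t__`). Row and column order
#' is preserved.
#'
#' @param path path to the TSV file.
#' @return A [species_table()].
#' @export
read_species_table <- function(path) {
  raw <- read_profile_tsv(path)
  keep <- grepl("s__", raw$keys) & !grepl("t__", raw$keys)
  species_table(raw$values[keep, , drop = FALSE],
                species = raw$keys[keep], samples = raw$samples)
}

#' Read a HUMAnN-style pathway abundance table
#'
#' Parses a pathabundance TSV (pathway key in the first column, `|` as the
#' taxon-stratification separator). All rows are preserved, including
#' `UNMAPPED` and `UNINTEGRATED`; community-total and stratified rows are
#' distinguishable by the presence of `|` in the key.
#'
#' @param path path to the TSV file.
#' @return A [pathway_table()].
#' @export
read_pathway_table <- function(path) {
  raw <- read_profile_tsv(path)
  pathway_table(raw$values, row_keys = raw$keys, samples = raw$samples)
}

write_profile_tsv <- function(keys, samples, values, key_name, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c(key_name, samples), collapse = "\t"), con)
  if (length(keys) > 0) {
    body <- vapply(seq_along(keys), function(i) {
      paste(c(keys[i], sprintf("%.10g", values[i, ])), collapse = "\t")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' Write a species abundance table to TSV
#'
#' @param x a [species_table()].
#' @param path output path.
#' @return `path`, invisibly. Round-trips through [read_species_table()]
#'   up to floating-point formatting.
#' @export
write_species_table <- function(x, path) {
  stopifnot(inherits(x, "species_table"))
  write_profile_tsv(x$species, x$samples, x$values, "#clade_name", path)
}

#' Write a pathway abundance table to TSV
#'
#' @param x a [pathway_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pathway_table <- function(x, path) {
  stopifnot(inherits(x, "pathway_table"))
  write_profile_tsv(x$row_keys, x$samples, x$values, "# Pathway", path)
}

#' Write a named list of tables to a directory
#'
#' Dispatches on table class; species tables go to `<name>_species.tsv`,
#' pathway tables to `<name>_pathways.tsv`, data frames to `<name>.csv`.
#'
#' @param tables named list of `species_table`, `pathway_table` or
#'   `data.frame` objects.
#' @param out_dir output directory, created if absent.
#' @return named character vector of written paths.
#' @export
write_tables <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    x <- tables[[nm]]
    if (inherits(x, "species_table")) {
      write_species_table(x, file.path(out_dir, paste0(nm, "_species.tsv")))
    } else if (inherits(x, "pathway_table")) {
      write_pathway_table(x, file.path(out_dir, paste0(nm, "_pathways.tsv")))
    } else if (is.data.frame(x)) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(x, p, row.names = FALSE)
      p
    } else stop("I/O error: cannot write object of class ", class(x)[1])
  }, character(1))
  invisible(paths)
}

#' Cohort retention percentage
#'
#' Percentage retained at a cohort accounting step, with half-up rounding
#' to one decimal — the convention used when reporting, e.g., the fraction
#' of consented participants who provided a stool sample.
#'
#' @param numerator count retained.
#' @param denominator count at risk; must be positive.
#' @return `100 * numerator / denominator`, rounded half-up to 1 decimal.
#' @examples
#' retention_percent(74, 106) # 69.8
#' retention_percent(69, 74)  # 93.2
#' @export
retention_percent <- function(numerator, denominator) {
  if (length(denominator) != 1 || length(numerator) != 1)
    stop("validation error: scalar counts expected")
  if (!is.finite(denominator) || denominator <= 0)
    stop("domain error: denominator must be positive")
  if (!is.finite(numerator) || numerator < 0 || numerator > denominator)
    stop("validation error: numerator must lie in [0, denominator]")
  floor(1000 * numerator / denominator + 0.5) / 10
}
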