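#' Read a log2 expression table
#'
#' Reads a tab-delimited expression table: first column the gene identifier,
#' header row of sample identifiers, every other cell a finite decimal number
#' (log2-scale expression). Parsing is strict: ragged rows, duplicated gene or
#' sample identifiers, and non-numeric or missing cells are errors, never
#' silently imputed.
#'
#' @param path Path to a tab-delimited text file (UTF-8, `.` decimal point,
#'   no quoting).
#' @return A tibble with a `gene_id` character column followed by one numeric
#'   column per sample.
#' @export
read_expression_table <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) abort("expression table is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != widths[1L])) {
    bad <- which(widths != widths[1L])[1L]
    abort(sprintf(
      "ragged row in expression table: line %d has %d fields, expected %d",
      bad, widths[bad], widths[1L]
    ))
  }
  header <- fields[[1L]]
  sample_ids <- header[-1L]
  if (length(sample_ids) < 1L) abort("expression table has no sample columns")
  if (anyDuplicated(sample_ids)) {
    abort(sprintf(
      "duplicate sample id(s) in expression table: %s",
      paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")
    ))
  }
  body <- fields[-1L]
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids)) {
    abort(sprintf(
      "duplicate gene id(s) in expression table: %s",
      paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")
    ))
  }
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(length(sample_ids)))
  )
  vals <- matrix(vals, nrow = length(sample_ids))
  if (anyNA(vals) || any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "non-numeric or missing value in expression table at gene '%s', sample '%s'",
      gene_ids[bad[["col"]]], sample_ids[bad[["row"]]]
    ))
  }
  out <- as_tibble(t(vals), .name_repair = "minimal")
  names(out) <- sample_ids
  dplyr::bind_cols(tibble(gene_id = gene_ids), out)
}

#' Write a log2 expression table
#'
#' Inverse of [read_expression_table()]; the two round-trip to identical
#' values on valid tables.
#'
#' @param expr Expression tibble (`gene_id` plus numeric sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  validate_expression(expr)
  readr::write_tsv(expr, path)
  invisible(path)
}

validate_expression <- function(expr) {
  if (!is.data.frame(expr) || !"gene_id" %in% names(expr)) {
    abort("expression table must be a data frame with a 'gene_id' column")
  }
  if (anyDuplicated(expr$gene_id)) abort("duplicate gene_id in expression table")
  num <- expr[setdiff(names(expr), "gene_id")]
  if (ncol(num) < 1L) abort("expression table has no sample columns")
  if (anyDuplicated(names(num))) abort("duplicate sample id in expression table")
  if (!all(vapply(num, is.numeric, logical(1)))) {
    abort("all sample columns must be numeric")
  }
  if (!all(vapply(num, function(x) all(is.finite(x)), logical(1)))) {
    abort("expression values must all be finite (missing values are not supported)")
  }
  invisible(expr)
}

#' Convert an expression tibble to a genes-by-samples matrix
#'
#' @param expr Expression tibble.
#' @return Numeric matrix with gene ids as row names, sample ids as columns.
#' @export
expr_matrix <- function(expr) {
  validate_expression(expr)
  m <- as.matrix(expr[setdiff(names(expr), "gene_id")])
  rownames(m) <- expr$gene_id
  m
}

sample_cols <- function(expr) setdiff(names(expr), "gene_id")

.sites <- c("SITE_A", "SITE_B")
.treatments <- c("NONE", "MS", "IAA", "ACC")

#' Read a sample sheet
#'
#' A sample sheet describes one microarray sample per row: its identifier,
#' genotype (the set of knocked-out genes, semicolon-joined; empty means wild
#' type), profiling site, replicate number, and hormone treatment. The
#' delimiter (tab or comma) is detected from the header line.
#'
#' @param path Path to the delimited sheet with columns
#'   `sample_id, genotype, site, replicate, treatment`.
#' @return A tibble with `sample_id` (character), `genotype` (list column of
#'   character vectors), `site` (`SITE_A`/`SITE_B`), `replicate` (integer),
#'   `treatment` (`NONE`/`MS`/`IAA`/`ACC`).
#' @export
read_sample_sheet <- function(path) {
  first <- readr::read_lines(path, n_max = 1L)
  delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    sample_id = readr::col_character(),
    genotype = readr::col_character(),
    site = readr::col_character(),
    replicate = readr::col_integer(),
    treatment = readr::col_character()
  ), quote = "", progress = FALSE)
  validate_samples(tibble(
    sample_id = raw$sample_id,
    genotype = parse_genotype(raw$genotype),
    site = raw$site,
    replicate = raw$replicate,
    treatment = raw$treatment
  ))
}

parse_genotype <- function(x) {
  lapply(x, function(g) {
    if (is.na(g) || !nzchar(g)) character(0) else strsplit(g, ";", fixed = TRUE)[[1L]]
  })
}

#' Write a sample sheet
#'
#' @param samples Sample tibble as returned by [read_sample_sheet()].
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  validate_samples(samples)
  out <- tibble(
    sample_id = samples$sample_id,
    genotype = vapply(samples$genotype, paste, character(1), collapse = ";"),
    site = samples$site,
    replicate = samples$replicate,
    treatment = samples$treatment
  )
  readr::write_tsv(out, path)
  invisible(path)
}

validate_samples <- function(samples) {
  req <- c("sample_id", "genotype", "site", "replicate", "treatment")
  if (!all(req %in% names(samples))) {
    abort(paste("sample sheet must have columns:", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) {
    abort(sprintf(
      "duplicate sample id(s): %s",
      paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", ")
    ))
  }
  if (!all(samples$site %in% .sites)) {
    abort(sprintf("unknown site value(s): %s",
                  paste(setdiff(unique(samples$site), .sites), collapse = ", ")))
  }
  if (!all(samples$treatment %in% .treatments)) {
    abort(sprintf("unknown treatment value(s): %s",
                  paste(setdiff(unique(samples$treatment), .treatments), collapse = ", ")))
  }
  if (any(is.na(samples$replicate)) || any(samples$replicate < 1L)) {
    abort("replicate must be a positive integer")
  }
  as_tibble(samples)
}

#' Check that a sample sheet and expression table describe the same samples
#'
#' The join must be total and bijective on sample ids; any sample present on
#' one side only is reported by id.
#'
#' @param expr Expression tibble.
#' @param samples Sample tibble.
#' @param gene_universe Optional character vector of genes considered "on the
#'   chip"; genotype genes outside it are reported (with a warning) as
#'   external knockouts rather than errors.
#' @return Invisibly, the character vector of external knockout genes.
#' @export
check_design <- function(expr, samples, gene_universe = expr$gene_id) {
  validate_expression(expr)
  validate_samples(samples)
  in_expr <- sample_cols(expr)
  only_expr <- setdiff(in_expr, samples$sample_id)
  only_sheet <- setdiff(samples$sample_id, in_expr)
  if (length(only_expr) || length(only_sheet)) {
    abort(sprintf(
      "sample sheet and expression table disagree; only in matrix: [%s]; only in sheet: [%s]",
      paste(only_expr, collapse = ", "), paste(only_sheet, collapse = ", ")
    ))
  }
  ko <- unique(unlist(samples$genotype))
  external <- setdiff(ko, gene_universe)
  if (length(external)) {
    warn(sprintf("genotype gene(s) not in the expression matrix (external knockouts): %s",
                 paste(external, collapse = ", ")))
  }
  invisible(external)
}

#' Read / write a hair / non-hair gene set
#'
#' Two-column tab-delimited format: `gene_id`, `class` (`HAIR` or `NONHAIR`).
#' The classes partition the members; a gene may not carry both labels.
#'
#' @param path File path.
#' @return `read_gene_set()`: a tibble with `gene_id` and `class`.
#' @export
read_gene_set <- function(path) {
  gs <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), class = readr::col_character()
  ), progress = FALSE)
  validate_gene_set(gs)
}

#' @rdname read_gene_set
#' @param gene_set Gene-set tibble (`gene_id`, `class`).
#' @export
write_gene_set <- function(gene_set, path) {
  validate_gene_set(gene_set)
  readr::write_tsv(gene_set, path)
  invisible(path)
}

validate_gene_set <- function(gene_set) {
  if (!all(c("gene_id", "class") %in% names(gene_set))) {
    abort("gene set must have columns gene_id, class")
  }
  if (!all(gene_set$class %in% c("HAIR", "NONHAIR"))) {
    abort("gene set classes must be HAIR or NONHAIR")
  }
  if (anyDuplicated(gene_set$gene_id)) {
    abort("a gene may not appear in both classes (duplicate gene_id)")
  }
  as_tibble(gene_set)
}
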