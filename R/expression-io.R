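#' Read a gene-by-sample expression table
#'
#' Reads a delimited text file of non-negative abundances (FPKM or comparable)
#' into a validated expression tibble: one `gene_id` character column followed
#' by one numeric column per sample.
#'
#' @param path Path to a delimited text file. The first row holds sample
#'   identifiers and the first column gene identifiers (or the transpose, see
#'   `genes_in_rows`).
#' @param delim Field delimiter, tab by default.
#' @param genes_in_rows If `TRUE` (default) rows are genes and columns are
#'   samples; if `FALSE` the table is transposed after reading.
#' @return A tibble with a `gene_id` column and one numeric column per sample.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t3\t4"), tf)
#' read_expression_table(tf)
#' @export
read_expression_table <- function(path, delim = "\t", genes_in_rows = TRUE) {
  if (!file.exists(path)) {
    stop("expression table not found: ", path, call. = FALSE)
  }
  # leading '#' lines (e.g. a tool's config header) are skipped
  first <- readLines(path, n = 100L, warn = FALSE)
  skip <- match(FALSE, startsWith(first, "#")) - 1L
  raw <- utils::read.table(path, header = TRUE, sep = delim, quote = "",
                           comment.char = "", check.names = FALSE, skip = skip,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) {
    stop("expression table needs an identifier column plus at least one sample column",
         call. = FALSE)
  }
  ids <- raw[[1L]]
  body <- raw[, -1L, drop = FALSE]
  num <- matrix(NA_real_, nrow = nrow(body), ncol = ncol(body),
                dimnames = list(NULL, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                   ids[bad[1L]], colnames(body)[j], body[[j]][bad[1L]]),
           call. = FALSE)
    }
    num[, j] <- v
  }
  if (!genes_in_rows) {
    sample_ids <- ids
    gene_ids <- colnames(num)
    num <- t(num)
    colnames(num) <- sample_ids
  } else {
    gene_ids <- ids
  }
  out <- tibble::tibble(gene_id = gene_ids)
  out <- dplyr::bind_cols(out, tibble::as_tibble(num))
  validate_expression(out)
}

#' Write an expression tibble as delimited text
#'
#' Round-trip companion of [read_expression_table()]: gene identifiers in the
#' first column, one column per sample.
#'
#' @param x Expression tibble (`gene_id` + numeric sample columns).
#' @param path Output file path.
#' @param delim Field delimiter, tab by default.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, delim = "\t") {
  x <- validate_expression(x)
  utils::write.table(x, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate an expression tibble
#'
#' Checks the container invariants: a character `gene_id` column without
#' duplicates, unique sample columns, and a finite non-negative numeric body
#' with no missing entries.
#'
#' @param x A data frame with a `gene_id` column and numeric sample columns.
#' @return The validated tibble (invisibly coerced with [tibble::as_tibble()]).
#' @export
validate_expression <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"gene_id" %in% names(x)) {
    stop("expression data must have a 'gene_id' column", call. = FALSE)
  }
  ids <- as.character(x$gene_id)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate gene identifiers: ", paste(utils::head(dup, 5L), collapse = ", "),
         call. = FALSE)
  }
  samp <- setdiff(names(x), "gene_id")
  if (length(samp) == 0L) stop("no sample columns present", call. = FALSE)
  if (anyDuplicated(samp)) stop("duplicate sample identifiers", call. = FALSE)
  vals <- as.matrix(x[samp])
  if (!is.numeric(vals)) stop("sample columns must be numeric", call. = FALSE)
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("expression values must be finite with no missing entries", call. = FALSE)
  }
  if (any(vals < 0)) stop("expression values must be non-negative", call. = FALSE)
  x$gene_id <- ids
  x
}

# gene x sample numeric matrix with gene_id rownames
expr_values <- function(x) {
  x <- validate_expression(x)
  m <- as.matrix(x[setdiff(names(x), "gene_id")])
  rownames(m) <- x$gene_id
  m
}

expr_sample_ids <- function(x) setdiff(names(x), "gene_id")

#' Sum isoform-level rows into gene-level rows
#'
#' Collapses an isoform-level expression table to gene level by summing, per
#' sample, the expression of all isoforms mapped to the same gene.
#'
#' @param x Expression tibble whose `gene_id` column holds isoform identifiers.
#' @param isoform_to_gene Two-column data frame (isoform id, gene id) or a
#'   named character vector (`names` = isoform ids, values = gene ids).
#' @param unmapped What to do with isoform ids absent from the map:
#'   `"error"` (default) or `"drop"`.
#' @return A gene-level expression tibble; sample order is preserved and the
#'   output rows follow the first appearance of each gene in the input.
#' @export
aggregate_isoforms <- function(x, isoform_to_gene, unmapped = c("error", "drop")) {
  x <- validate_expression(x)
  unmapped <- match.arg(unmapped)
  if (is.data.frame(isoform_to_gene)) {
    map <- stats::setNames(as.character(isoform_to_gene[[2L]]),
                           as.character(isoform_to_gene[[1L]]))
  } else {
    map <- isoform_to_gene
  }
  if (anyDuplicated(names(map))) {
    stop("isoform map assigns some isoforms more than once", call. = FALSE)
  }
  missing_ids <- setdiff(x$gene_id, names(map))
  if (length(missing_ids) > 0L) {
    if (unmapped == "error") {
      stop("unmapped isoform identifiers: ",
           paste(utils::head(missing_ids, 5L), collapse = ", "), call. = FALSE)
    }
    x <- x[!x$gene_id %in% missing_ids, , drop = FALSE]
    if (nrow(x) == 0L) stop("all isoforms were unmapped", call. = FALSE)
  }
  gene <- unname(map[x$gene_id])
  x |>
    dplyr::mutate(gene_id = gene) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), sum), .groups = "drop") |>
    dplyr::arrange(match(.data$gene_id, unique(gene))) |>
    validate_expression()
}

#' Read a two-column isoform-to-gene map
#'
#' @param path Delimited text file; column 1 isoform id, column 2 gene id. A
#'   header line is detected and skipped when its first field is not repeated
#'   as a data row... the file is read without a header by default.
#' @param delim Field delimiter.
#' @return Named character vector mapping isoform id to gene id.
#' @export
read_isoform_map <- function(path, delim = "\t") {
  tb <- utils::read.table(path, header = FALSE, sep = delim, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(tb) < 2L) stop("isoform map needs two columns", call. = FALSE)
  stats::setNames(as.character(tb[[2L]]), as.character(tb[[1L]]))
}

#' Filter genes by minimum expression prevalence
#'
#' Keeps a gene when the fraction of samples with abundance at or above
#' `min_value` is at least `min_fraction`. The defaults implement the standard
#' bulk rule for homogeneous RNA-seq panels: FPKM >= 1 in at least 95% of the
#' samples. Both comparisons are inclusive.
#'
#' @param x Expression tibble.
#' @param min_value Abundance threshold (default 1 FPKM).
#' @param min_fraction Required fraction of samples in `[0, 1]` (default 0.95).
#' @return The filtered expression tibble with a `"filter_report"` attribute
#'   (see [filter_report()]).
#' @examples
#' m <- tibble::tibble(gene_id = c("a", "b"), s1 = c(0.5, 2), s2 = c(2, 3),
#'                     s3 = c(3, 0), s4 = c(4, 1))
#' filter_report(filter_by_expression(m, 1, 0.75))
#' @export
filter_by_expression <- function(x, min_value = 1, min_fraction = 0.95) {
  x <- validate_expression(x)
  if (min_fraction < 0 || min_fraction > 1) {
    stop("min_fraction must lie in [0, 1]", call. = FALSE)
  }
  m <- expr_values(x)
  frac <- rowMeans(m >= min_value)
  keep <- frac >= min_fraction
  out <- x[keep, , drop = FALSE]
  attr(out, "filter_report") <- tibble::tibble(
    n_genes_in = nrow(x),
    n_genes_out = sum(keep),
    min_value = min_value,
    min_fraction = min_fraction,
    dropped_gene_ids = list(x$gene_id[!keep])
  )
  out
}

#' Retrieve the report attached by [filter_by_expression()]
#'
#' @param x A filtered expression tibble.
#' @return One-row tibble with counts, thresholds and the dropped gene ids.
#' @export
filter_report <- function(x) {
  rep <- attr(x, "filter_report")
  if (is.null(rep)) stop("no filter report attached", call. = FALSE)
  rep
}

#' Joint gene filter across single-cell batches
#'
#' Keeps a gene only when it is expressed (abundance at or above
#' `expression_floor`) in at least `batch size - allowed_misses` cells of
#' EVERY batch. With two batches of 10 cells and the default one allowed miss
#' per batch this is the "expressed in at least 18 of the 20 cells" rule used
#' for first-generation single-cell panels.
#'
#' @param batches List of expression tibbles sharing a gene universe.
#' @param allowed_misses Non-expressing cells tolerated per batch (default 1).
#' @param expression_floor Abundance at which a cell counts as expressing the
#'   gene (default 1).
#' @param min_expressed_cells Optional explicit per-batch count overriding
#'   `allowed_misses`; recycled across batches.
#' @return List with `genes` (character vector kept in every batch) and
#'   `batches` (the input tibbles subset to those genes).
#' @export
filter_multi_batch <- function(batches, allowed_misses = 1,
                               expression_floor = 1,
                               min_expressed_cells = NULL) {
  stopifnot(length(batches) >= 1L)
  batches <- lapply(batches, validate_expression)
  universe <- Reduce(intersect, lapply(batches, function(b) b$gene_id))
  if (length(universe) == 0L) {
    stop("batches have no genes in common", call. = FALSE)
  }
  keep <- rep(TRUE, length(universe))
  for (i in seq_along(batches)) {
    m <- expr_values(batches[[i]])[universe, , drop = FALSE]
    need <- if (is.null(min_expressed_cells)) {
      ncol(m) - allowed_misses
    } else {
      rep_len(min_expressed_cells, length(batches))[i]
    }
    keep <- keep & (rowSums(m >= expression_floor) >= need)
  }
  genes <- universe[keep]
  list(
    genes = genes,
    batches = lapply(batches, function(b) b[match(genes, b$gene_id), , drop = FALSE])
  )
}
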