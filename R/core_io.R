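# Readers/writers for the external formats the pipeline touches, with
# validation. Expression: TSV genes x samples. Gene sets: GMT. Purity,
# sample labels, biotype map: 2-column TSV. All outputs: TSV with headers
# and deterministic row order.

#' Construct a validated expression matrix
#'
#' An expression matrix is a base numeric matrix (genes in rows, samples in
#' columns) with unique dimnames, all values finite and non-negative, and a
#' `cancer_label` attribute.
#'
#' @param values Numeric matrix with rownames (gene ids) and colnames
#'   (sample ids).
#' @param cancer_label Single string naming the cancer/cohort.
#' @return The validated matrix, classed `irlnc_expr`.
#' @export
expression_matrix <- function(values, cancer_label = "cancer") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("expression matrix needs both rownames (genes) and colnames (samples)",
         call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers in expression matrix", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("expression values must all be finite", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  attr(values, "cancer_label") <- as.character(cancer_label)[1]
  class(values) <- c("irlnc_expr", class(values))
  values
}

#' Cancer label of an expression matrix
#' @param expr An expression matrix from [expression_matrix()].
#' @return A string.
#' @export
cancer_label <- function(expr) {
  lab <- attr(expr, "cancer_label")
  if (is.null(lab)) "cancer" else lab
}

#' Read a genes-by-samples expression TSV
#'
#' First column holds gene identifiers, the header row sample identifiers.
#' Rows containing negative or non-numeric values, duplicate gene ids, or an
#' empty file are format errors.
#'
#' @param path Path to a TSV file.
#' @param cancer_label Cohort name stored on the matrix; defaults to the
#'   file name without extension.
#' @return A validated expression matrix ([expression_matrix()]).
#' @export
read_expression <- function(path, cancer_label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("format error: expression file '", path,
         "' is empty or has no sample columns", call. = FALSE)
  }
  genes <- df[[1]]
  if (anyDuplicated(genes)) {
    stop("format error: duplicated gene id(s) in '", path, "': ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  m <- vapply(df[-1], function(col) suppressWarnings(as.numeric(col)),
              numeric(nrow(df)))
  m <- matrix(m, nrow = nrow(df), dimnames = list(genes, names(df)[-1]))
  if (anyNA(m)) {
    stop("format error: non-numeric or missing expression value in '",
         path, "'", call. = FALSE)
  }
  if (is.null(cancer_label)) {
    cancer_label <- sub("\\.[^.]*$", "", basename(path))
  }
  expression_matrix(m, cancer_label)
}

#' Read a two-column gene biotype map
#'
#' TSV with columns `gene_id` and `biotype` (values such as `mRNA`,
#' `lncRNA`, `other`). Ensembl-style version suffixes (".N") are stripped
#' from gene ids so versioned annotation matches symbol-level gene sets.
#'
#' @param path Path to a 2-column TSV (header required).
#' @return A named character vector: gene id -> biotype.
#' @export
read_biotype_map <- function(path) {
  df <- read_two_column(path, c("gene_id", "biotype"))
  ids <- strip_gene_version(df[[1]])
  if (anyDuplicated(ids)) {
    stop("format error: gene mapped more than once in '", path, "'",
         call. = FALSE)
  }
  stats::setNames(df[[2]], ids)
}

#' Split an expression matrix by gene biotype
#'
#' Genes absent from the map are dropped with a warning stating the count.
#' Version suffixes on the matrix's gene ids are stripped before matching.
#'
#' @param expr Expression matrix.
#' @param biotypes Named character vector gene id -> biotype
#'   (see [read_biotype_map()]).
#' @return A list with elements `mrna` and `lncrna`, both expression
#'   matrices over disjoint gene sets.
#' @export
split_by_biotype <- function(expr, biotypes) {
  ids <- strip_gene_version(rownames(expr))
  bt <- unname(biotypes[ids])
  unmapped <- sum(is.na(bt))
  if (unmapped > 0L) {
    warning(unmapped, " gene(s) absent from the biotype map were dropped",
            call. = FALSE)
  }
  lab <- cancer_label(expr)
  pick <- function(type) {
    keep <- !is.na(bt) & bt == type
    m <- expr[keep, , drop = FALSE]
    class(m) <- "matrix"
    rownames(m) <- ids[keep]
    m
  }
  mrna <- pick("mRNA")
  lncrna <- pick("lncRNA")
  if (nrow(mrna) == 0L || nrow(lncrna) == 0L) {
    stop("empty split: need at least one mRNA and one lncRNA after ",
         "biotype matching", call. = FALSE)
  }
  list(mrna = expression_matrix(mrna, lab),
       lncrna = expression_matrix(lncrna, lab))
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one pathway per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (pathway -> gene ids).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("format error: empty GMT file '", path, "'", call. = FALSE)
  }
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("format error in '", path, "' line ", i,
           ": GMT lines need name, description and >= 1 gene", call. = FALSE)
    }
    name <- fields[[1]]
    if (name %in% names(sets)) {
      stop("format error in '", path, "' line ", i,
           ": duplicate pathway name '", name, "'", call. = FALSE)
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      stop("format error in '", path, "' line ", i,
           ": pathway '", name, "' has no genes", call. = FALSE)
    }
    sets[[name]] <- genes
  }
  sets
}

#' Read a per-sample tumour purity table
#'
#' TSV with columns `sample_id` and `purity`; purity must lie in \[0, 1\].
#'
#' @param path Path to a 2-column TSV (header required).
#' @return A named numeric vector sample id -> purity.
#' @export
read_purity <- function(path) {
  df <- read_two_column(path, c("sample_id", "purity"))
  p <- suppressWarnings(as.numeric(df[[2]]))
  bad <- which(is.na(p) | p < 0 | p > 1)
  if (length(bad)) {
    stop("range error in '", path, "' line ", bad[1] + 1L,
         ": purity must be a number in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(df[[1]])) {
    stop("format error: duplicated sample id in '", path, "'", call. = FALSE)
  }
  stats::setNames(p, df[[1]])
}

#' Read tumour/normal sample labels
#'
#' TSV with columns `sample_id` and `group` (`tumor` or `normal`).
#'
#' @param path Path to a 2-column TSV (header required).
#' @return A named character vector sample id -> group.
#' @export
read_labels <- function(path) {
  df <- read_two_column(path, c("sample_id", "group"))
  grp <- df[[2]]
  bad <- which(!grp %in% c("tumor", "normal"))
  if (length(bad)) {
    stop("format error in '", path, "' line ", bad[1] + 1L,
         ": group must be 'tumor' or 'normal'", call. = FALSE)
  }
  if (anyDuplicated(df[[1]])) {
    stop("format error: duplicated sample id in '", path, "'", call. = FALSE)
  }
  stats::setNames(grp, df[[1]])
}

#' Read a per-sample immune infiltration table
#'
#' TSV whose first column is the sample id and whose remaining columns are
#' infiltration levels for immune cell types (conventionally six: B cell,
#' CD4+ T cell, CD8+ T cell, neutrophil, macrophage, myeloid dendritic
#' cell). All values must be finite.
#'
#' @param path Path to a TSV (header required).
#' @return A tibble with a `sample_id` column plus one numeric column per
#'   cell type.
#' @export
read_infiltration <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (ncol(df) < 2L) {
    stop("format error: infiltration table '", path,
         "' needs >= 1 cell-type column", call. = FALSE)
  }
  names(df)[1] <- "sample_id"
  df[-1] <- lapply(df[-1], function(col) suppressWarnings(as.numeric(col)))
  if (anyDuplicated(df$sample_id)) {
    stop("format error: duplicated sample id in '", path, "'", call. = FALSE)
  }
  if (anyNA(df)) {
    stop("format error: non-finite infiltration value in '", path, "'",
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write a result table as TSV
#'
#' Writes any tibble/data frame as a TSV with a header and deterministic
#' row order: rows are sorted by all character/factor columns (left to
#' right). Numeric values are written in full precision.
#'
#' @param records A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  key_cols <- names(records)[vapply(records, function(x)
    is.character(x) || is.factor(x), logical(1))]
  if (length(key_cols)) {
    records <- dplyr::arrange(records,
                              dplyr::across(dplyr::all_of(key_cols)))
  }
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Read back a result table written by [write_records()]
#' @param path Path to a TSV.
#' @return A tibble.
#' @export
read_records <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}

# -- internal helpers ---------------------------------------------------

strip_gene_version <- function(ids) sub("\\.\\d+$", "", ids)

read_two_column <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(df) < 2L || nrow(df) == 0L) {
    stop("format error: '", path, "' must be a 2-column TSV (",
         paste(what, collapse = ", "), ") with >= 1 row", call. = FALSE)
  }
  df[, 1:2]
}
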