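#' Construct an expression matrix
#'
#' Wraps a genes-by-samples numeric matrix together with a dataset label.
#' Gene and sample identifiers are taken from the matrix dimnames, must be
#' unique, and are matched exactly (case-sensitive) throughout the package.
#'
#' @param values Numeric matrix, genes as rows, samples as columns, with
#'   complete dimnames. All values must be finite.
#' @param dataset_label Single string naming the dataset (e.g. a cohort).
#' @return An object of class `metica_expr` with elements `values` and
#'   `dataset_label`.
#' @export
expression_matrix <- function(values, dataset_label = "dataset") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate gene IDs: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample IDs")
  }
  if (!all(is.finite(values))) stop("`values` contains non-finite entries")
  structure(list(values = values,
                 dataset_label = as.character(dataset_label)[1]),
            class = "metica_expr")
}

#' @export
print.metica_expr <- function(x, ...) {
  cat(sprintf("<metica_expr '%s'> %d genes x %d samples\n",
              x$dataset_label, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read an expression matrix from a tab-separated file
#'
#' Expects a header row of sample IDs and a first column of gene IDs.
#' Gene rows containing any non-finite value are dropped (with a message
#' reporting the count), as are zero-variance genes: the downstream
#' decomposition requires complete matrices with informative genes.
#'
#' @param path Path to a TSV file.
#' @param dataset_label Dataset label to attach.
#' @return A [expression_matrix()] object.
#' @export
read_expression <- function(path, dataset_label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1) {
    stop("ragged rows in ", path, ": rows ",
         paste(utils::head(which(nf != nf[1]), 5), collapse = ", "))
  }
  tab <- utils::read.delim(path, check.names = FALSE, quote = "",
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate gene IDs in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  m <- suppressWarnings(
    vapply(tab[-1], function(col) as.numeric(as.character(col)),
           numeric(nrow(tab))))
  m <- matrix(m, nrow = nrow(tab),
              dimnames = list(ids, colnames(tab)[-1]))
  bad <- !apply(is.finite(m), 1, all)
  if (any(bad)) {
    message(sum(bad), " gene row(s) with non-finite values dropped")
    m <- m[!bad, , drop = FALSE]
  }
  novar <- apply(m, 1, stats::sd) == 0
  if (any(novar)) {
    message(sum(novar), " zero-variance gene row(s) dropped")
    m <- m[!novar, , drop = FALSE]
  }
  expression_matrix(m, dataset_label)
}

#' Write an expression matrix as TSV
#'
#' @param x A `metica_expr` (or a plain matrix with dimnames).
#' @param path Output path.
#' @param id_column Header for the gene-ID column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, id_column = "gene_id") {
  m <- if (inherits(x, "metica_expr")) x$values else x
  write_matrix_tsv(m, path, id_column)
}

# Shared TSV matrix writer (row IDs in the first column).
write_matrix_tsv <- function(m, path, id_column = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, quote = "",
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[-1])
  rownames(m) <- as.character(tab[[1]])
  m
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene IDs. Duplicate genes
#'   within a set are removed; empty sets and duplicate set names are
#'   rejected.
#' @param descriptions Optional character vector of per-set descriptions
#'   (recycled from the collection label if missing).
#' @param collection_label Label for the source catalogue.
#' @return An object of class `metica_genesets`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL,
                                collection_label = "sets") {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("all gene sets must be named")
  }
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0)) stop("empty gene set(s)")
  descriptions <- descriptions %||% rep(collection_label, length(sets))
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions,
                 collection_label = collection_label),
            class = "metica_genesets")
}

#' @export
print.metica_genesets <- function(x, ...) {
  cat(sprintf("<metica_genesets '%s'> %d sets, median size %d\n",
              x$collection_label, length(x$sets),
              as.integer(stats::median(lengths(x$sets)))))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate member genes are removed with a warning; a line with fewer than
#' three fields is a parse error naming the line number.
#'
#' @param path Path to a GMT file.
#' @param collection_label Label for the collection.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, collection_label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(structure(list(sets = list(), descriptions = character(),
                          collection_label = collection_label),
                     class = "metica_genesets"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stop("malformed GMT line ", short[1], " in ", path,
         " (fewer than 3 tab-separated fields)")
  }
  nm <- vapply(fields, `[[`, character(1), 1)
  desc <- vapply(fields, `[[`, character(1), 2)
  members <- lapply(fields, function(f) f[-(1:2)])
  ndup <- sum(vapply(members, function(g) sum(duplicated(g)), integer(1)))
  if (ndup > 0) {
    warning(ndup, " duplicate member gene(s) removed across sets")
  }
  names(members) <- nm
  gene_set_collection(members, descriptions = desc,
                      collection_label = collection_label)
}

#' Write gene sets in GMT format
#'
#' @param gsc A `metica_genesets` collection.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$descriptions[[nm]], gsc$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a compendium manifest
#'
#' Book-keeping record of a multi-dataset compendium: per-dataset sample
#' counts, per-collection gene-set counts, per-class sample counts, and
#' which datasets are cell-line panels.
#'
#' @param datasets Named integer vector of per-dataset sample counts.
#' @param gene_set_collections Named integer vector of per-collection
#'   gene-set counts.
#' @param sample_classes Named integer vector of per-class sample counts.
#' @param cell_line_datasets Names of the datasets that are cell-line panels.
#' @return An object of class `metica_manifest`.
#' @export
compendium_manifest <- function(datasets = integer(),
                                gene_set_collections = integer(),
                                sample_classes = integer(),
                                cell_line_datasets = character()) {
  for (v in list(datasets, gene_set_collections, sample_classes)) {
    if (length(v) && (any(!is.finite(v)) || any(v < 0) ||
                      any(v != round(v)))) {
      stop("manifest counts must be non-negative integers")
    }
  }
  unknown <- setdiff(cell_line_datasets, names(datasets))
  if (length(unknown)) {
    stop("cell_line_datasets not in datasets: ",
         paste(unknown, collapse = ", "))
  }
  structure(list(datasets = datasets,
                 gene_set_collections = gene_set_collections,
                 sample_classes = sample_classes,
                 cell_line_datasets = cell_line_datasets),
            class = "metica_manifest")
}

#' Read a compendium manifest from JSON
#'
#' @param path Path to a JSON manifest.
#' @return A [compendium_manifest()].
#' @export
read_manifest <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  compendium_manifest(
    datasets = unlist(raw$datasets) %||% integer(),
    gene_set_collections = unlist(raw$gene_set_collections) %||% integer(),
    sample_classes = unlist(raw$sample_classes) %||% integer(),
    cell_line_datasets = as.character(raw$cell_line_datasets %||%
                                        character()))
}

#' Write a compendium manifest as JSON
#'
#' @param manifest A `metica_manifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  out <- list(datasets = as.list(manifest$datasets),
              gene_set_collections = as.list(manifest$gene_set_collections),
              sample_classes = as.list(manifest$sample_classes),
              cell_line_datasets = I(manifest$cell_line_datasets))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Summarize a compendium manifest
#'
#' @param manifest A [compendium_manifest()].
#' @return List with `total_samples` (sum over datasets),
#'   `total_gene_sets` (sum over collections) and `total_cell_line_samples`
#'   (sum over the cell-line datasets).
#' @export
summarize_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "metica_manifest"))
  list(
    total_samples = as.integer(sum(manifest$datasets)),
    total_gene_sets = as.integer(sum(manifest$gene_set_collections)),
    total_cell_line_samples =
      as.integer(sum(manifest$datasets[manifest$cell_line_datasets]))
  )
}
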