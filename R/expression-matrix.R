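#' Expression matrix with sample-to-tissue design
#'
#' Light container for a gene x sample FPKM matrix plus an optional
#' sample-to-tissue assignment. Values must be finite and non-negative;
#' gene and sample identifiers must be unique. Identifiers are opaque,
#' case-sensitive strings.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param design Optional named character vector mapping every sample id to a
#'   tissue label, or `NULL` when no design is attached yet.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `design`.
#' @examples
#' m <- matrix(c(1, 2, 0, 5, 7, 7), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' em <- ExpressionMatrix(m, design = c(s1 = "liver", s2 = "lung"))
#' dim(em)
#' @export
ExpressionMatrix <- function(values, design = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene ids as rownames and sample ids as colnames")
  x <- structure(list(values = values, design = design),
                 class = "ExpressionMatrix")
  validate_expression_matrix(x)
  x
}

validate_expression_matrix <- function(x) {
  v <- x$values
  dup <- rownames(v)[duplicated(rownames(v))]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(v)[duplicated(colnames(v))]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(v) || any(!is.finite(v)))
    stop("expression values must be finite and non-missing")
  if (any(v < 0))
    stop("expression values must be non-negative")
  if (!is.null(x$design)) {
    d <- x$design
    if (is.null(names(d)) || !is.character(d))
      stop("'design' must be a named character vector (sample id -> tissue)")
    missing <- setdiff(colnames(v), names(d))
    if (length(missing))
      stop("sample(s) missing from design: ", paste(missing, collapse = ", "))
  }
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (is.null(x$design)) {
    cat("design: none attached\n")
  } else {
    tab <- table(x$design[colnames(x$values)])
    cat(sprintf("design: %d tissues (%s)\n", length(tab),
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  }
  invisible(x)
}

#' Tissues of an ExpressionMatrix
#'
#' Tissue labels in order of first appearance among the matrix samples.
#' @param x An `ExpressionMatrix` with design attached.
#' @return Character vector of tissue labels.
#' @export
tissues <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (is.null(x$design)) stop("no design attached; see attach_design()")
  unique(unname(x$design[colnames(x$values)]))
}

#' Samples belonging to one tissue
#' @param x An `ExpressionMatrix` with design.
#' @param tissue A tissue label present in the design.
#' @return Character vector of sample ids.
#' @export
tissue_samples <- function(x, tissue) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  smp <- colnames(x$values)
  smp[unname(x$design[smp]) == tissue]
}

#' Read a delimited expression matrix
#'
#' Expects a header row of sample ids and gene ids in the first column.
#' Parsing is strict: duplicated identifiers, non-numeric cells and negative
#' values are hard errors that name the offending gene/sample.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field separator; tab by default, use `","` for CSV.
#' @return An `ExpressionMatrix` without design.
#' @export
read_expression_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (ncol(raw) < 2) stop("expected a gene-id column plus >= 1 sample column")
  gene_ids <- raw[[1]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene id(s) in ", path, ": ", paste(dup, collapse = ", "))
  sample_ids <- colnames(raw)[-1]
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample id(s) in ", path, ": ", paste(dup, collapse = ", "))
  chr <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(chr), dim = dim(chr)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("non-numeric value %s at gene '%s', sample '%s' in %s",
                 dQuote(chr[i, j]), gene_ids[i], sample_ids[j], path))
  }
  bad <- which(num < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("negative value %s at gene '%s', sample '%s' in %s",
                 chr[i, j], gene_ids[i], sample_ids[j], path))
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  ExpressionMatrix(num)
}

#' Write an expression matrix as delimited text
#'
#' Values are written with full double precision (17 significant digits), so
#' a write-then-read round trip reproduces them bit-exactly.
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path.
#' @param delimiter Field separator.
#' @param id_column Header name of the gene-id column.
#' @export
write_expression_matrix <- function(x, path, delimiter = "\t",
                                    id_column = "gene_id") {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  df <- data.frame(id = rownames(v),
                   apply(v, 2, format_num), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

format_num <- function(x) {
  # decimal representation that round-trips a double
  formatC(x, digits = 17, format = "g")
}

#' Read a two-column sample-to-tissue design table
#'
#' @param path Path to a delimited file with header and columns
#'   `sample_id`, `tissue` (names not enforced; the first two columns are
#'   used).
#' @param delimiter Field separator.
#' @return Named character vector: sample id -> tissue.
#' @export
read_design <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("design file not found: ", path)
  d <- utils::read.table(path, sep = delimiter, header = TRUE,
                         check.names = FALSE, colClasses = "character",
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "")
  if (ncol(d) < 2) stop("design must have two columns: sample_id, tissue")
  stats::setNames(d[[2]], d[[1]])
}

#' Write a design table
#' @param design Named character vector (sample id -> tissue).
#' @param path Output path.
#' @export
write_design <- function(design, path) {
  utils::write.table(
    data.frame(sample_id = names(design), tissue = unname(design)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach a sample-to-tissue design to an expression matrix
#'
#' Every matrix sample must be covered by the design; design rows for samples
#' absent from the matrix are ignored with a warning.
#'
#' @param x An `ExpressionMatrix` (design-less or not; any existing design is
#'   replaced).
#' @param design A file path (read via [read_design()]), a two-column
#'   data.frame, or a named character vector.
#' @return `x` with `design` attached.
#' @export
attach_design <- function(x, design) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (is.character(design) && length(design) == 1L && is.null(names(design)))
    design <- read_design(design)
  if (is.data.frame(design)) {
    if (ncol(design) < 2) stop("design must have columns sample_id, tissue")
    design <- stats::setNames(as.character(design[[2]]),
                              as.character(design[[1]]))
  }
  smp <- colnames(x$values)
  missing <- setdiff(smp, names(design))
  if (length(missing))
    stop("matrix sample(s) missing from design: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(design), smp)
  if (length(extra))
    warning("design sample(s) absent from matrix ignored: ",
            paste(extra, collapse = ", "))
  x$design <- design[smp]
  validate_expression_matrix(x)
  x
}

#' Read gene sets in GMT format
#'
#' One set per line: set id, description, then one field per member gene,
#' tab-separated. Lines with fewer than three fields are hard errors.
#'
#' @param path Path to a GMT file.
#' @return A named list of gene sets; each element is a character vector of
#'   member ids with a `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need set id, description and >= 1 member",
                   i, length(f)))
    members <- unique(f[-(1:2)])
    attr(members, "description") <- f[[2]]
    if (f[[1]] %in% names(out))
      stop("duplicate gene-set id: ", f[[1]])
    out[[f[[1]]]] <- members
  }
  out
}

#' Read a gene annotation table
#'
#' Expects a header and columns `gene_id`, `biotype`, and optionally
#' `symbol`. Used only for descriptive group-bys (e.g. biotype composition).
#'
#' @param path Path to a delimited file.
#' @param delimiter Field separator.
#' @return data.frame with one row per gene.
#' @export
read_gene_annotation <- function(path, delimiter = "\t") {
  ann <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  if (!all(c("gene_id", "biotype") %in% colnames(ann)))
    stop("annotation needs columns 'gene_id' and 'biotype'")
  dup <- unique(ann$gene_id[duplicated(ann$gene_id)])
  if (length(dup))
    stop("duplicate gene id(s) in annotation: ", paste(dup, collapse = ", "))
  ann
}
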