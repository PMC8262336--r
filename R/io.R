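#' Canonicalize gene symbols
#'
#' Gene identifiers are handled as HGNC-style symbols throughout the package.
#' Canonicalization uppercases and strips surrounding whitespace; it is
#' idempotent, so symbols read from different files compare reliably.
#'
#' @param x character vector of gene symbols.
#' @return character vector of canonical symbols.
#' @export
canonicalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Construct a count matrix
#'
#' Container for gene x sample integer feature counts, the shared input of the
#' differential-expression, PCA, enrichment and ratio stages.
#'
#' @param counts numeric matrix (genes x samples) of nonnegative integers with
#'   rownames (gene symbols) and colnames (sample IDs).
#' @param batch optional per-sample batch labels (length = ncol(counts)).
#' @return an object of class `count_matrix` with fields `genes`, `samples`,
#'   `counts` and `batch`.
#' @export
count_matrix <- function(counts, batch = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  storage.mode(counts) <- "double"
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  rownames(counts) <- canonicalize_symbols(rownames(counts))
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    warning(sprintf("collapsing %d duplicated gene symbol(s) by summation: %s",
                    length(dup), paste(utils::head(dup, 5), collapse = ", ")))
    counts <- rowsum(counts, group = rownames(counts), reorder = FALSE)
  }
  if (anyDuplicated(colnames(counts))) stop("duplicate sample IDs")
  if (!is.null(batch)) {
    if (length(batch) != ncol(counts))
      stop("batch must have one label per sample")
    batch <- as.character(batch)
  }
  structure(list(genes = rownames(counts), samples = colnames(counts),
                 counts = counts, batch = batch),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$batch)) "" else
                sprintf(" (%d batches)", length(unique(x$batch)))))
  invisible(x)
}

#' Subset a count matrix by genes and/or samples
#'
#' @param x a `count_matrix`.
#' @param genes optional character vector of gene symbols to keep.
#' @param samples optional character vector of sample IDs to keep.
#' @return a `count_matrix` restricted to the requested rows/columns.
#' @export
subset_counts <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts
  b <- x$batch
  if (!is.null(genes)) {
    genes <- canonicalize_symbols(genes)
    missing <- setdiff(genes, rownames(m))
    if (length(missing))
      stop(sprintf("genes absent from count matrix: %s",
                   paste(utils::head(missing, 10), collapse = ", ")))
    m <- m[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(m))
    if (length(missing))
      stop(sprintf("samples absent from count matrix: %s",
                   paste(utils::head(missing, 10), collapse = ", ")))
    idx <- match(samples, colnames(m))
    m <- m[, idx, drop = FALSE]
    if (!is.null(b)) b <- b[idx]
  }
  count_matrix(m, batch = b)
}

#' Read a gene x sample count table
#'
#' TSV is the canonical format: a header row of sample IDs with a leading
#' "gene" column. MatrixMarket (`mtx`) is supported read-only; it must be
#' accompanied by `<stem>.rownames.txt` and `<stem>.colnames.txt` files
#' holding one gene symbol / sample ID per line. Duplicate gene rows are
#' collapsed by summation with a warning (transcript-to-gene aggregation).
#'
#' @param path file path.
#' @param format "tsv" or "mtx".
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "tsv") {
    if (file.size(path) == 0) stop(sprintf("empty counts file: %s", path))
    df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2 || tolower(names(df)[1]) != "gene")
      stop("malformed counts header: first column must be 'gene'")
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("counts contain non-numeric cells")
    rownames(m) <- df[[1]]
    count_matrix(m)
  } else {
    stem <- sub("\\.mtx$", "", path)
    rn <- paste0(stem, ".rownames.txt")
    cn <- paste0(stem, ".colnames.txt")
    if (!file.exists(rn) || !file.exists(cn))
      stop("mtx input requires <stem>.rownames.txt and <stem>.colnames.txt")
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(rn)
    colnames(m) <- readLines(cn)
    count_matrix(m)
  }
}

#' Read a GMT gene-set file
#'
#' Standard Broad-style tab-separated format: set name, description, then
#' member gene symbols. Members are canonicalized and deduplicated; set names
#' must be unique and member lists non-empty.
#'
#' @param path file path.
#' @return a named list of character vectors of class `gene_sets`, with a
#'   `description` attribute parallel to the list.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file")
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    nms[i] <- f[1]
    desc[i] <- f[2]
    members <- unique(canonicalize_symbols(f[-(1:2)]))
    members <- members[nzchar(members)]
    if (!length(members))
      stop(sprintf("GMT line %d ('%s') has no members", i, f[1]))
    sets[[i]] <- members
  }
  if (anyDuplicated(nms))
    stop(sprintf("duplicate gene-set name(s): %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  names(sets) <- nms
  names(desc) <- nms
  structure(sets, description = desc, class = c("gene_sets", "list"))
}

KNOWN_ASSAYS <- c("ATP2B4", "ATP2A2", "B2M", "RPL30")

#' Read a qPCR Ct table
#'
#' Expected TSV columns: `sample_id`, `assay` (gene symbol), `well`
#' (replicate index), `ct` (cycle threshold; empty cell = missing well).
#' Unknown assay symbols are retained with a warning.
#'
#' @param path file path.
#' @return data.frame of class `ct_table`.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("sample_id", "assay", "well", "ct")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("ct table missing column(s): %s", paste(miss, collapse = ", ")))
  df$assay <- canonicalize_symbols(df$assay)
  unknown <- setdiff(unique(df$assay), KNOWN_ASSAYS)
  if (length(unknown))
    warning(sprintf("unknown assay symbol(s) retained: %s",
                    paste(unknown, collapse = ", ")))
  df$ct <- as.numeric(df$ct)
  if (any(!is.na(df$ct) & df$ct <= 0)) stop("ct values must be positive")
  ok <- stats::aggregate(!is.na(df$ct),
                         by = list(sample_id = df$sample_id, assay = df$assay),
                         FUN = any)
  if (any(!ok$x))
    stop("each (sample, assay) needs at least one non-missing well")
  class(df) <- c("ct_table", "data.frame")
  df
}

SAMPLE_GROUPS <- c("TL", "TNL", "PTB-sPTL", "PTB-PPROM", "PTB-PI", "unknown")

#' Read a sample metadata table
#'
#' Expected TSV columns: `sample_id`, `group` (TL, TNL, PTB-sPTL, PTB-PPROM,
#' PTB-PI or unknown); optional `phenotype_label` (Q/NQ), `batch`, `incision`,
#' plus the clinical fields consumed by [score_case()] (`ga_weeks`,
#' `contractions_raw`, `dilation_cm`, `membranes`, `triple_i`,
#' `spontaneous_onset`, `provider_initiated`).
#'
#' @param path file path.
#' @return data.frame of class `sample_table`.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("sample_id", "group")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("sample table missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample IDs")
  bad <- setdiff(unique(df$group), SAMPLE_GROUPS)
  if (length(bad))
    warning(sprintf("unrecognized group label(s): %s",
                    paste(bad, collapse = ", ")))
  for (col in c("spontaneous_onset", "provider_initiated"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Write a package object to a TSV file
#'
#' The inverse of the readers: `write_table` followed by the matching reader
#' reproduces the object. Count matrices are written with a leading "gene"
#' column; tabular objects are written as plain TSV.
#'
#' @param obj a `count_matrix`, `ct_table`, `sample_table` or data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path) {
  if (inherits(obj, "count_matrix")) {
    df <- data.frame(gene = obj$genes, obj$counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (is.data.frame(obj)) {
    utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
  } else {
    stop("unsupported object type for write_table")
  }
  invisible(path)
}
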