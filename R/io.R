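## Readers and writers for the standard formats the pipeline touches:
## 10x-style MatrixMarket count matrices, VDJ contig tables, and TSV/JSON
## result directories.

.findFile <- function(directory, stems) {
  for (stem in stems) {
    for (candidate in c(stem, paste0(stem, ".gz"))) {
      p <- file.path(directory, candidate)
      if (file.exists(p)) return(p)
    }
  }
  stop("missing file in '", directory, "': expected one of ",
       paste(stems, collapse = ", "), " (optionally gzipped)")
}

.readTsvMaybeGz <- function(path) {
  ## read.delim opens .gz transparently
  read.delim(path, header = FALSE, stringsAsFactors = FALSE, sep = "\t")
}

#' Read a 10x-convention MatrixMarket count directory
#'
#' Expects `matrix.mtx`, `features.tsv` (or `genes.tsv`) and
#' `barcodes.tsv`, each optionally gzipped. Gene identifiers are taken
#' from the symbol column of the features file (second column when
#' present); duplicate symbols are made unique with `.1`, `.2` suffixes
#' (10x convention). Barcodes must be unique within the directory and are
#' prefixed internally as `sample:barcode` so that cells from different
#' samples never collide.
#'
#' @param directory path containing the three files.
#' @param sample sample label attached to every cell (default: directory
#'   basename).
#' @return a [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   integer `counts` assay, `rowData$symbol` and
#'   `colData(sample, barcode)`.
#' @export
readMTXCounts <- function(directory, sample = basename(normalizePath(directory, mustWork = FALSE))) {
  if (!dir.exists(directory)) stop("no such directory: '", directory, "'")
  mtx_path <- .findFile(directory, "matrix.mtx")
  feat_path <- .findFile(directory, c("features.tsv", "genes.tsv"))
  bc_path <- .findFile(directory, "barcodes.tsv")

  m <- if (endsWith(mtx_path, ".gz")) {
    Matrix::readMM(gzfile(mtx_path))
  } else {
    Matrix::readMM(mtx_path)
  }
  m <- methods::as(m, "CsparseMatrix")

  feats <- .readTsvMaybeGz(feat_path)
  barcodes <- .readTsvMaybeGz(bc_path)[[1L]]

  if (nrow(feats) != nrow(m)) {
    stop("format error: features file lists ", nrow(feats),
         " genes but matrix header declares ", nrow(m))
  }
  if (length(barcodes) != ncol(m)) {
    stop("format error: barcodes file lists ", length(barcodes),
         " cells but matrix header declares ", ncol(m))
  }
  if (anyDuplicated(barcodes)) {
    stop("duplicate barcode(s) in '", bc_path, "': ",
         paste(unique(barcodes[duplicated(barcodes)]), collapse = ", "))
  }
  if (any(m@x < 0) || any(m@x != round(m@x))) {
    stop("format error: counts must be nonnegative integers")
  }

  symbols <- if (ncol(feats) >= 2L) feats[[2L]] else feats[[1L]]
  symbols <- make.unique(as.character(symbols), sep = ".")
  rownames(m) <- symbols
  colnames(m) <- paste(sample, barcodes, sep = ":")

  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    rowData = S4Vectors::DataFrame(symbol = symbols,
                                   id = as.character(feats[[1L]])),
    colData = S4Vectors::DataFrame(sample = rep(sample, length(barcodes)),
                                   barcode = as.character(barcodes),
                                   row.names = colnames(m))
  )
}

.contig_required <- c("barcode", "chain", "cdr3", "cdr3_nt", "productive", "umis")

#' Read a 10x-style VDJ filtered-contig table
#'
#' Parses a `filtered_contig_annotations.csv`-dialect file into one chain
#' record per contig row. Chains `TRA`/`TRB` are mapped to loci
#' `alpha`/`beta`; contigs from other loci are dropped (count reported as
#' an attribute). Non-productive rows are retained with
#' `productive = FALSE`.
#'
#' @param path CSV file with columns `barcode`, `chain`, `cdr3`,
#'   `cdr3_nt`, `productive`, `umis`.
#' @param sample optional sample label stored with each record.
#' @return data.frame with columns `barcode`, `locus` (`alpha`/`beta`),
#'   `cdr3_aa`, `cdr3_nt`, `productive`, `umis`, `sample`.
#' @export
readTCRContigs <- function(path, sample = NA_character_) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.contig_required, colnames(df))
  if (length(missing_cols)) {
    stop("format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  locus <- c(TRA = "alpha", TRB = "beta")[toupper(df$chain)]
  dropped <- sum(is.na(locus))
  keep <- !is.na(locus)
  productive <- tolower(as.character(df$productive)) %in% c("true", "t")
  out <- data.frame(
    barcode = as.character(df$barcode)[keep],
    locus = unname(locus[keep]),
    cdr3_aa = as.character(df$cdr3)[keep],
    cdr3_nt = as.character(df$cdr3_nt)[keep],
    productive = productive[keep],
    umis = as.integer(df$umis)[keep],
    sample = if (is.na(sample)) NA_character_ else sample,
    stringsAsFactors = FALSE
  )
  bad_nt <- out$productive & nchar(out$cdr3_nt) %% 3L != 0L
  if (any(bad_nt)) {
    warning(sum(bad_nt), " productive contig(s) with CDR3 nt length not ",
            "divisible by 3; flagged non-productive")
    out$productive[bad_nt] <- FALSE
  }
  attr(out, "dropped_other_loci") <- dropped
  out
}

## numeric columns rendered with maximal precision so re-reading is exact
.formatForTsv <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' Write result tables as a TSV directory with a JSON manifest
#'
#' Each table becomes `<name>.tsv` (tab-separated, UTF-8, "." decimal,
#' full double precision) and a `manifest.json` records table names, row
#' counts, parameters and seeds. Re-reading a written table with
#' [readResultTable()] reproduces its values exactly.
#'
#' @param tables named list of data.frames; names must be unique.
#' @param directory output directory (created if absent).
#' @param params optional named list recorded in the manifest.
#' @param seed optional seed recorded in the manifest.
#' @return the manifest, invisibly, as a list.
#' @export
writeResults <- function(tables, directory, params = list(), seed = NULL) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("all tables must be named")
  }
  if (anyDuplicated(names(tables))) {
    stop("duplicate table name(s): ",
         paste(unique(names(tables)[duplicated(names(tables))]), collapse = ", "))
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory '", directory, "'")
  files <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    path <- file.path(directory, paste0(nm, ".tsv"))
    out <- tryCatch(
      write.table(.formatForTsv(tab), path, sep = "\t", quote = FALSE,
                  row.names = FALSE, fileEncoding = "UTF-8"),
      error = function(e) stop("cannot write '", path, "': ", conditionMessage(e))
    )
    files[nm] <- basename(path)
  }
  manifest <- list(
    tables = lapply(tables, function(t) list(rows = nrow(t), cols = ncol(t))),
    files = as.list(files),
    params = params,
    seed = seed,
    package = "clonofate"
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(manifest)
}

#' Read back a table written by [writeResults()]
#'
#' @param path path to a `.tsv` file produced by [writeResults()].
#' @return data.frame with original column types (numeric columns parsed
#'   back to full precision).
#' @export
readResultTable <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a count matrix in the 10x MTX convention
#'
#' Emits `matrix.mtx`, `features.tsv` and `barcodes.tsv` (uncompressed)
#' so that [readMTXCounts()] restores the matrix exactly. Barcodes are
#' written without the internal `sample:` prefix.
#'
#' @param counts SingleCellExperiment or sparse count matrix.
#' @param directory output directory (created if absent).
#' @return the directory, invisibly.
#' @export
writeMTXCounts <- function(counts, directory) {
  m <- .getCounts(counts)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(m, "CsparseMatrix"),
                  file.path(directory, "matrix.mtx"))
  feats <- data.frame(id = rownames(m), symbol = rownames(m),
                      type = "Gene Expression")
  write.table(feats, file.path(directory, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  barcodes <- if (methods::is(counts, "SummarizedExperiment") &&
                  "barcode" %in% colnames(SummarizedExperiment::colData(counts))) {
    SummarizedExperiment::colData(counts)$barcode
  } else {
    colnames(m)
  }
  writeLines(barcodes, file.path(directory, "barcodes.tsv"))
  invisible(directory)
}

#' Write a chain table in the 10x filtered-contig CSV dialect
#'
#' Inverse of [readTCRContigs()]: writes `barcode`, `chain` (TRA/TRB),
#' `cdr3`, `cdr3_nt`, `productive` (True/False), `umis`.
#'
#' @param chains data.frame in the [readTCRContigs()] layout.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeTCRContigs <- function(chains, path) {
  out <- data.frame(
    barcode = chains$barcode,
    chain = c(alpha = "TRA", beta = "TRB")[chains$locus],
    cdr3 = chains$cdr3_aa,
    cdr3_nt = chains$cdr3_nt,
    productive = ifelse(chains$productive, "True", "False"),
    umis = chains$umis
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
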