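## Text serialization of a ReferenceMap: TSV matrices plus JSON metadata.

#' Save a reference map as a directory of TSV files
#'
#' Writes `loadings.tsv`, `scaling.tsv`, `embedding.tsv`,
#' `corrected_embedding.tsv`, `labels.tsv`, `subtype_means.tsv` and a
#' `metadata.json` carrying the build parameters. Values are written at
#' full double precision so that [loadReferenceMap()] restores the map
#' exactly.
#'
#' @param map a [ReferenceMap-class].
#' @param directory output directory (created if absent).
#' @return the directory, invisibly.
#' @export
saveReferenceMap <- function(map, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, path) {
    df <- data.frame(.row = rownames(m) %||% as.character(seq_len(nrow(m))),
                     m, check.names = FALSE)
    write.table(.formatForTsv(df), file.path(directory, path), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  wm(map@loadings, "loadings.tsv")
  wm(map@embedding, "embedding.tsv")
  wm(map@correctedEmbedding, "corrected_embedding.tsv")
  wm(map@subtypeMeans, "subtype_means.tsv")
  write.table(.formatForTsv(map@scaling), file.path(directory, "scaling.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  labels <- data.frame(cell = rownames(map@embedding) %||%
                         as.character(seq_len(nrow(map@embedding))),
                       cluster = map@cluster,
                       subtype = as.character(map@subtype))
  write.table(labels, file.path(directory, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(map@annotation)) {
    write.table(.formatForTsv(map@annotation),
                file.path(directory, "annotation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    c(map@params, list(genePanel = map@genePanel,
                       subtypeLevels = levels(map@subtype),
                       package = "clonofate")),
    file.path(directory, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(directory)
}

.readMatrixTsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Load a reference map saved by [saveReferenceMap()]
#'
#' @param directory directory written by [saveReferenceMap()].
#' @return a [ReferenceMap-class].
#' @export
loadReferenceMap <- function(directory) {
  meta <- jsonlite::read_json(file.path(directory, "metadata.json"),
                              simplifyVector = TRUE)
  labels <- read.delim(file.path(directory, "labels.tsv"),
                       stringsAsFactors = FALSE)
  scaling <- read.delim(file.path(directory, "scaling.tsv"),
                        stringsAsFactors = FALSE)
  rownames(scaling) <- scaling$gene
  ann_path <- file.path(directory, "annotation.tsv")
  sm <- .readMatrixTsv(file.path(directory, "subtype_means.tsv"))
  methods::new("ReferenceMap",
    genePanel = meta$genePanel,
    scaling = scaling,
    loadings = .readMatrixTsv(file.path(directory, "loadings.tsv")),
    embedding = .readMatrixTsv(file.path(directory, "embedding.tsv")),
    correctedEmbedding = .readMatrixTsv(file.path(directory,
                                                  "corrected_embedding.tsv")),
    cluster = as.integer(labels$cluster),
    subtype = factor(labels$subtype, levels = meta$subtypeLevels),
    subtypeMeans = sm,
    prototypes = t(sm[meta$genePanel, , drop = FALSE]),
    annotation = if (file.exists(ann_path)) {
      read.delim(ann_path, stringsAsFactors = FALSE)
    } else {
      data.frame()
    },
    params = meta[c("dims", "k", "resolution", "seed", "scaleFactor")])
}
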