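# Readers and writers for the external formats: 10x-style MTX directories,
# annotation / gene-list / DE TSVs, and Newick trees.  All tabular formats
# are tab-separated UTF-8; annotation-style tables carry a mandatory header
# row, while features/barcodes follow the headerless 10x convention.

.firstExisting <- function(dir, candidates) {
    for (f in candidates) {
        p <- file.path(dir, f)
        if (file.exists(p)) return(p)
    }
    NA_character_
}

.readMaybeGz <- function(path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    lines <- readLines(con, warn = FALSE)
    if (!length(lines))
        return(data.frame(V1 = character(0), stringsAsFactors = FALSE))
    read.delim(text = lines, header = FALSE, stringsAsFactors = FALSE,
               colClasses = "character")
}

.readMMFile <- function(path) {
    if (grepl("\\.gz$", path)) {
        tmp <- tempfile(fileext = ".mtx")
        on.exit(unlink(tmp))
        con <- gzfile(path, "rt")
        writeLines(readLines(con), tmp)
        close(con)
        Matrix::readMM(tmp)
    } else {
        Matrix::readMM(path)
    }
}

#' Read a 10x-style Matrix Market count directory
#'
#' Expects `matrix.mtx`, a feature table (`features.tsv` or `genes.tsv`,
#' 1-3 columns: ID, optional name, optional type) and `barcodes.tsv`, each
#' optionally gzipped.  Rows of the returned object follow the feature
#' table, columns the barcode table.
#'
#' @param path directory containing the three files.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   integer `counts` assay; feature names land in `rowData(x)$gene_name`
#'   when present.
#' @examples
#' sim <- simulateAtlas(nClusters = 3, cellsPerCluster = 10, nGenes = 50,
#'                      seed = 1)
#' d <- tempfile(); writeCountMatrix(sim$sce, d)
#' sce <- readCountMatrix(d)
#' dim(sce)
#' @seealso [writeCountMatrix()]
#' @export
readCountMatrix <- function(path) {
    if (!dir.exists(path))
        stop("count directory not found: ", path)
    mtx <- .firstExisting(path, c("matrix.mtx", "matrix.mtx.gz"))
    feat <- .firstExisting(path, c("features.tsv", "features.tsv.gz",
                                   "genes.tsv", "genes.tsv.gz"))
    bc <- .firstExisting(path, c("barcodes.tsv", "barcodes.tsv.gz"))
    if (is.na(mtx))
        stop("format error: matrix.mtx(.gz) missing from ", path)
    if (is.na(feat))
        stop("format error: features.tsv/genes.tsv(.gz) missing from ", path)
    if (is.na(bc))
        stop("format error: barcodes.tsv(.gz) missing from ", path)
    m <- .readMMFile(mtx)
    features <- .readMaybeGz(feat)
    barcodes <- .readMaybeGz(bc)
    if (nrow(features) != nrow(m))
        stop(sprintf(
            "integrity error: MTX declares %d genes but feature table lists %d",
            nrow(m), nrow(features)))
    if (nrow(barcodes) != ncol(m))
        stop(sprintf(
            "integrity error: MTX declares %d cells but barcode table lists %d",
            ncol(m), nrow(barcodes)))
    geneIds <- features[[1L]]
    cellIds <- barcodes[[1L]]
    if (anyDuplicated(geneIds)) stop("integrity error: duplicate gene IDs")
    if (anyDuplicated(cellIds)) stop("integrity error: duplicate cell IDs")
    if (any(m@x < 0)) stop("integrity error: negative counts")
    m <- as(m, "CsparseMatrix")
    dimnames(m) <- list(geneIds, cellIds)
    rd <- S4Vectors::DataFrame(row.names = geneIds)
    if (ncol(features) >= 2L) rd$gene_name <- features[[2L]]
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m), rowData = rd)
}

#' Write a count matrix as a 10x-style MTX directory
#'
#' Emits `matrix.mtx` (Matrix Market coordinate integer), a three-column
#' `features.tsv` (ID, name, "Gene Expression") and `barcodes.tsv`.
#'
#' @param x a SingleCellExperiment (its `counts` assay is written) or any
#'   matrix-like object with gene rownames and cell colnames.
#' @param path output directory (created if needed).
#' @return invisibly, `path`.
#' @seealso [readCountMatrix()]
#' @export
writeCountMatrix <- function(x, path) {
    m <- .countsOf(x)
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(path)) stop("cannot create directory: ", path)
    ms <- as(as(m, "CsparseMatrix"), "TsparseMatrix")
    con <- file(file.path(path, "matrix.mtx"), "wt")
    writeLines(c("%%MatrixMarket matrix coordinate integer general",
                 sprintf("%d %d %d", nrow(ms), ncol(ms), length(ms@x))), con)
    if (length(ms@x)) {
        o <- order(ms@j, ms@i)
        writeLines(sprintf("%d %d %d", ms@i[o] + 1L, ms@j[o] + 1L,
                           as.integer(round(ms@x[o]))), con)
    }
    close(con)
    genes <- rownames(m)
    if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
    cells <- colnames(m)
    if (is.null(cells)) cells <- sprintf("c%d", seq_len(ncol(m)))
    gnames <- genes
    if (is(x, "SummarizedExperiment")) {
        rd <- SummarizedExperiment::rowData(x)
        if ("gene_name" %in% colnames(rd)) gnames <- rd$gene_name
    }
    write.table(
        data.frame(genes, gnames, rep("Gene Expression", length(genes))),
        file.path(path, "features.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    writeLines(cells, file.path(path, "barcodes.tsv"))
    invisible(path)
}

# Extract the counts matrix from whatever container the caller handed us.
.countsOf <- function(x) {
    if (is(x, "SummarizedExperiment"))
        return(SummarizedExperiment::assay(x, "counts"))
    if (is(x, "Matrix") || is.matrix(x)) return(x)
    stop("expected a SingleCellExperiment or a matrix")
}

.readHeaderTSV <- function(path, required, optional = character()) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                     check.names = FALSE)
    missing <- setdiff(required, colnames(df))
    if (length(missing))
        stop("missing required column(s) in ", basename(path), ": ",
             paste(missing, collapse = ", "))
    extra <- setdiff(colnames(df), c(required, optional))
    if (length(extra)) {
        warning("ignoring unknown column(s) in ", basename(path), ": ",
                paste(extra, collapse = ", "))
        df <- df[, setdiff(colnames(df), extra), drop = FALSE]
    }
    df
}

#' Read a cell annotation table
#'
#' Tab-separated with header; required column `cell_id`, `cluster`; optional
#' `subcluster` and `replicate`.  Unknown columns are dropped with a warning.
#'
#' @param path TSV file.
#' @return a data.frame with one row per cell.
#' @seealso [annotateCells()]
#' @export
readAnnotation <- function(path) {
    df <- .readHeaderTSV(path, c("cell_id", "cluster"),
                         c("subcluster", "replicate"))
    if (anyDuplicated(df$cell_id))
        stop("integrity error: duplicate cell_id in annotation: ",
             df$cell_id[anyDuplicated(df$cell_id)])
    df
}

#' Attach a cell annotation to a count object
#'
#' @param x a SingleCellExperiment.
#' @param ann a data.frame as returned by [readAnnotation()]; every
#'   annotated cell must exist in `x`, and every cell of `x` must be
#'   annotated.
#' @return `x` with `cluster` (and, when present, `subcluster`,
#'   `replicate`) columns in its colData.
#' @export
annotateCells <- function(x, ann) {
    stopifnot(is(x, "SummarizedExperiment"))
    unknown <- setdiff(ann$cell_id, colnames(x))
    if (length(unknown))
        stop("annotation refers to unknown cell(s): ",
             paste(head(unknown, 5), collapse = ", "))
    idx <- match(colnames(x), ann$cell_id)
    if (anyNA(idx))
        stop("cells missing annotation: ",
             paste(head(colnames(x)[is.na(idx)], 5), collapse = ", "))
    for (col in intersect(c("cluster", "subcluster", "replicate"),
                          colnames(ann)))
        SummarizedExperiment::colData(x)[[col]] <- ann[[col]][idx]
    x
}

#' Read a gene list (one panel of gene IDs)
#'
#' Tab-separated with header; required column `gene_id`.  Duplicates and
#' empty lists are integrity errors.
#'
#' @param path TSV file.
#' @param name panel name (defaults to the file name).
#' @return a character vector of gene IDs with a `"panel"` name attribute.
#' @export
readGeneList <- function(path, name = NULL) {
    df <- .readHeaderTSV(path, "gene_id", c("gene_name", "family"))
    ids <- df$gene_id
    if (!length(ids)) stop("empty gene list: ", path)
    if (anyDuplicated(ids))
        stop("integrity error: duplicate gene_id in gene list: ",
             ids[anyDuplicated(ids)])
    attr(ids, "panel") <- name %||% sub("\\.[^.]*$", "", basename(path))
    ids
}

#' Read a bulk differential-expression table
#'
#' Tab-separated with header; required columns `gene_id`, `log_fc`
#' (knockdown-vs-control orientation: negative = downregulated in the
#' knockdown) and `adj_p`; optional logical `significant` (derived as
#' `adj_p < 0.05` when absent).
#'
#' @param path TSV file.
#' @return a data.frame with columns gene_id, log_fc, adj_p, significant.
#' @seealso [kdIntersect()]
#' @export
readDETable <- function(path) {
    df <- .readHeaderTSV(path, c("gene_id", "log_fc", "adj_p"), "significant")
    df$log_fc <- as.numeric(df$log_fc)
    df$adj_p <- as.numeric(df$adj_p)
    if (anyDuplicated(df$gene_id))
        stop("integrity error: duplicate gene_id in DE table")
    if (any(is.na(df$adj_p)) || any(df$adj_p < 0) || any(df$adj_p > 1))
        stop("range error: adj_p must lie in [0, 1]")
    if (!"significant" %in% colnames(df))
        df$significant <- df$adj_p < 0.05
    df$significant <- as.logical(df$significant)
    df
}

#' Write / read cell-type trees in Newick format
#'
#' Standard Newick with branch lengths; integer internal-node labels carry
#' bootstrap supports.  A write/read round trip preserves topology, branch
#' lengths (to at least 6 decimals) and supports.
#'
#' @param tree a [CellTypeTree-class].
#' @param path file path.
#' @return `writeNewick` invisibly returns `path`; `readNewick` returns a
#'   [CellTypeTree-class].
#' @export
writeNewick <- function(tree, path) {
    stopifnot(is(tree, "CellTypeTree"))
    ape::write.tree(asPhylo(tree), file = path, digits = 10)
    invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    txt <- paste(readLines(path, warn = FALSE), collapse = "")
    .checkNewickSyntax(txt)
    phy <- tryCatch(ape::read.tree(text = txt),
                    error = function(e) NULL, warning = function(w) NULL)
    if (is.null(phy))
        stop("malformed Newick in ", path)
    .asCellTypeTree(phy)
}

# Cheap syntax check so parse errors report a character position.
.checkNewickSyntax <- function(txt) {
    chars <- strsplit(txt, "")[[1L]]
    depth <- 0L
    for (i in seq_along(chars)) {
        if (chars[i] == "(") depth <- depth + 1L
        if (chars[i] == ")") {
            depth <- depth - 1L
            if (depth < 0L)
                stop("malformed Newick: unmatched ')' at position ", i)
        }
    }
    if (depth != 0L)
        stop("malformed Newick: ", depth, " unclosed '(' at end of input")
    if (!grepl(";", txt))
        stop("malformed Newick: missing terminating ';' at position ",
             nchar(txt))
}

# Build a CellTypeTree from a phylo, harvesting numeric node labels as
# bipartition supports.
.asCellTypeTree <- function(phy, supports = NULL) {
    if (is.null(phy$edge.length))
        phy$edge.length <- rep(0, nrow(phy$edge))
    if (is.null(supports)) {
        supports <- numeric(0)
        if (!is.null(phy$node.label)) {
            keys <- .nodeBipartitionKeys(phy)
            lab <- suppressWarnings(as.numeric(phy$node.label))
            keep <- !is.na(lab) & !is.na(keys)
            supports <- setNames(lab[keep], keys[keep])
        }
    }
    new("CellTypeTree", phylo = phy, supports = supports)
}
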