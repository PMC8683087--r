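# Germ-layer transcription-factor sharing and knockdown-DE intersection.

#' Per-germ-layer expressed transcription-factor sets
#'
#' For each germ layer (ectoderm, mesoderm, endoderm), the union over its
#' clusters of the cluster's expressed genes intersected with the
#' transcription-factor catalogue.
#'
#' @param expressed an [ExpressedGeneSets-class].
#' @param layers named character vector mapping every cluster of
#'   `expressed` to one of `"ectoderm"`, `"mesoderm"`, `"endoderm"`.
#'   Clusters may be left out of the analysis by omitting them from
#'   `expressed`, but every cluster present there must be mapped.
#' @param tfCatalogue non-empty character vector of TF gene IDs.
#' @return named list of three character vectors (ectoderm, mesoderm,
#'   endoderm).
#' @seealso [vennRegions()], [pairwiseShared()]
#' @export
layerTFSets <- function(expressed, layers, tfCatalogue) {
    stopifnot(is(expressed, "ExpressedGeneSets"))
    tfCatalogue <- as.character(tfCatalogue)
    if (!length(tfCatalogue)) stop("empty transcription-factor catalogue")
    sets <- geneSets(expressed)
    unmapped <- setdiff(names(sets), names(layers))
    if (length(unmapped))
        stop("cluster(s) missing from the germ-layer map: ",
             paste(unmapped, collapse = ", "))
    bad <- setdiff(unique(layers[names(sets)]),
                   c("ectoderm", "mesoderm", "endoderm"))
    if (length(bad))
        stop("unknown germ layer value(s): ", paste(bad, collapse = ", "))
    out <- lapply(c(ectoderm = "ectoderm", mesoderm = "mesoderm",
                    endoderm = "endoderm"), function(ly) {
        cls <- names(sets)[layers[names(sets)] == ly]
        sort(unique(intersect(unlist(sets[cls], use.names = FALSE),
                              tfCatalogue)))
    })
    out
}

#' Exclusive region counts of a three-set Venn diagram
#'
#' @param a,b,c character vectors (coerced to sets).
#' @return a list with `counts`, a named integer vector over the seven
#'   exclusive regions (`a_only`, `b_only`, `c_only`, `ab`, `ac`, `bc`,
#'   `abc`), and `members`, the corresponding element lists.  The counts
#'   always sum to the size of the union.
#' @examples
#' vennRegions(c("1", "2", "3"), c("2", "3", "4"), c("3", "4", "5"))$counts
#' @export
vennRegions <- function(a, b, c) {
    a <- unique(as.character(a)); b <- unique(as.character(b))
    c <- unique(as.character(c))
    u <- union(union(a, b), c)
    inA <- u %in% a; inB <- u %in% b; inC <- u %in% c
    members <- list(
        a_only = u[inA & !inB & !inC],
        b_only = u[!inA & inB & !inC],
        c_only = u[!inA & !inB & inC],
        ab = u[inA & inB & !inC],
        ac = u[inA & !inB & inC],
        bc = u[!inA & inB & inC],
        abc = u[inA & inB & inC])
    list(counts = vapply(members, length, integer(1)), members = members)
}

#' Pairwise shared-gene counts between sets
#'
#' @param sets named list of character vectors.
#' @return symmetric integer matrix of pairwise intersection sizes; the
#'   diagonal holds the set sizes.
#' @export
pairwiseShared <- function(sets) {
    if (length(sets) < 2L) stop("need at least 2 sets")
    if (is.null(names(sets))) stop("sets must be named")
    sets <- lapply(sets, function(s) unique(as.character(s)))
    n <- length(sets)
    m <- matrix(0L, n, n, dimnames = list(names(sets), names(sets)))
    for (i in seq_len(n)) for (j in seq_len(n))
        m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    m
}

#' Intersect a cluster's genes with a knockdown DE table
#'
#' The overlap between a set of cluster/subcluster genes and the genes
#' called differentially expressed (`adj_p < alpha`) in a bulk knockdown
#' experiment, with the downregulated fraction (log fold change strictly
#' below zero in the knockdown-vs-control orientation).
#'
#' @param clusterGenes character vector of gene IDs from the single-cell
#'   side.
#' @param de DE table as returned by [readDETable()] or [simulateKdDe()].
#' @param alpha significance cutoff applied to `adj_p` (in (0, 1]).
#' @return a list: `n_cluster_genes`, `n_de`, `n_overlap`, `n_down`,
#'   `frac_down` (NULL when the overlap is empty), and `overlap`, the
#'   per-gene table (gene_id, log_fc, adj_p) of intersected genes.
#' @examples
#' de <- data.frame(gene_id = c("g2", "g3"), log_fc = c(-1.2, 0.4),
#'                  adj_p = c(0.001, 0.002))
#' kdIntersect(c("g1", "g2", "g3"), de)[c("n_overlap", "n_down", "frac_down")]
#' @export
kdIntersect <- function(clusterGenes, de, alpha = 0.05) {
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
        stop("parameter error: alpha must lie in (0, 1]")
    stopifnot(all(c("gene_id", "log_fc", "adj_p") %in% colnames(de)))
    clusterGenes <- unique(as.character(clusterGenes))
    sig <- de[de$adj_p < alpha, , drop = FALSE]
    overlap <- sig[sig$gene_id %in% clusterGenes,
                   c("gene_id", "log_fc", "adj_p"), drop = FALSE]
    overlap <- overlap[order(overlap$adj_p, overlap$gene_id), , drop = FALSE]
    rownames(overlap) <- NULL
    nOv <- nrow(overlap)
    nDown <- sum(overlap$log_fc < 0)
    list(
        n_cluster_genes = length(clusterGenes),
        n_de = nrow(sig),
        n_overlap = nOv,
        n_down = nDown,
        frac_down = if (nOv > 0) nDown / nOv else NULL,
        overlap = overlap)
}
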