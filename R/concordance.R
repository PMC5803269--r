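#' @include AllClasses.R ExprMatrix-methods.R
NULL

.mapProteins <- function(proteins, mapping = NULL) {
    if (!all(c("protein_id", "abundance") %in% names(proteins)))
        stop("protein table needs 'protein_id' and 'abundance' columns")
    if (anyDuplicated(proteins$protein_id))
        stop("duplicate protein ids")
    if (any(proteins$abundance < 0, na.rm = TRUE))
        stop("protein abundances must be nonnegative")
    if (is.null(mapping)) {
        if ("gene_id" %in% names(proteins))
            return(proteins$gene_id)
        return(proteins$protein_id)   # identifiers already in gene namespace
    }
    mapping$gene_id[match(proteins$protein_id, mapping$protein_id)]
}

#' Overlap of a protein table with a gene signature
#'
#' Maps protein identifiers into the signature's gene namespace (via the
#' table's own `gene_id` column, a user-supplied two-column mapping, or
#' identity) and reports the exact set intersection; unmapped identifiers
#' are reported, never silently dropped into the count.
#'
#' @param proteins `data.frame` with `protein_id`, `abundance` and
#'   optionally `gene_id`.
#' @param signature character vector of signature gene ids.
#' @param mapping optional `data.frame` with `protein_id`, `gene_id`.
#' @return A list with `count`, `genes` (the shared gene ids) and
#'   `unmapped` (protein ids without a gene mapping).
#' @export
signatureOverlap <- function(proteins, signature, mapping = NULL) {
    genes <- .mapProteins(proteins, mapping)
    unmapped <- proteins$protein_id[is.na(genes)]
    shared <- intersect(unique(genes[!is.na(genes)]), signature)
    list(count = length(shared), genes = shared, unmapped = unmapped)
}

#' Rank correlation of protein and transcript abundance
#'
#' Spearman correlation between protein abundance and summarized mRNA
#' expression (mean, optionally median, of the log-scale values across
#' samples) over the matched genes, with average ranks for ties and a
#' t-approximation p-value.
#'
#' @param proteins protein table as in [signatureOverlap()].
#' @param x a log-scale [ExprMatrix-class] (typically purified samples).
#' @param mapping optional protein-to-gene mapping.
#' @param summary mRNA summary across samples: `"mean"` (default) or
#'   `"median"`.
#' @return A list with `rho`, `p_value` and `n` matched genes.
#' @export
rankCorrelation <- function(proteins, x, mapping = NULL,
                            summary = c("mean", "median")) {
    summary <- match.arg(summary)
    genes <- .mapProteins(proteins, mapping)
    v <- exprValues(x)
    mrna <- if (summary == "mean") rowMeans(v) else
        apply(v, 1L, stats::median)
    ok <- !is.na(genes) & genes %in% rownames(v)
    if (sum(ok) < 3L)
        stop("fewer than 3 matched identifiers between proteins and ",
             "expression matrix")
    ct <- stats::cor.test(proteins$abundance[ok], mrna[genes[ok]],
                          method = "spearman", exact = FALSE)
    list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
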