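#' @include AllClasses.R
NULL

#' Read / write expression matrices as TSV
#'
#' Genes as rows (first column `gene_id`), samples as remaining columns.
#' Readers validate uniqueness of gene and sample ids and nonnegativity on
#' the raw scale, reporting the offending rows.
#'
#' @param path file path.
#' @param scale scale tag to attach on read (the file itself is scale-free).
#' @return `readExprTSV` returns an [ExprMatrix-class]; `writeExprTSV`
#'   returns `path` invisibly.
#' @export
readExprTSV <- function(path, scale = c("raw", "log2", "normalized")) {
    scale <- match.arg(scale)
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (!ncol(df) >= 2L) stop("expression TSV needs gene_id + >=1 sample")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate gene ids in ", path, ": ",
             paste(unique(ids[duplicated(ids)])[1:5], collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- ids
    if (scale == "raw" && any(m < 0, na.rm = TRUE)) {
        bad <- which(apply(m, 1L, function(r) any(r < 0, na.rm = TRUE)))
        stop("negative raw values at genes: ",
             paste(utils::head(ids[bad], 5L), collapse = ", "))
    }
    ExprMatrix(m, scale = scale)
}

#' @rdname readExprTSV
#' @param x an [ExprMatrix-class] to write.
#' @export
writeExprTSV <- function(x, path) {
    v <- exprValues(x)
    df <- data.frame(gene_id = rownames(v), v, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read / write GCT v1.2 expression files
#'
#' The two-line header (`#1.2`, then `nrow<TAB>ncol`) is followed by a table
#' with `Name`, `Description` and one column per sample.
#'
#' @param path file path.
#' @param scale scale tag to attach on read.
#' @return `readGCT` returns an [ExprMatrix-class].
#' @export
readGCT <- function(path, scale = c("raw", "log2", "normalized")) {
    scale <- match.arg(scale)
    hdr <- readLines(path, n = 2L)
    if (!grepl("^#1\\.2", hdr[1L]))
        stop("not a GCT v1.2 file: ", path)
    dims <- as.integer(strsplit(hdr[2L], "\t")[[1L]][1:2])
    df <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (nrow(df) != dims[1L] || ncol(df) - 2L != dims[2L])
        stop("GCT header dimensions disagree with table in ", path)
    m <- as.matrix(df[, -(1:2), drop = FALSE])
    rownames(m) <- as.character(df[[1L]])
    ExprMatrix(m, scale = scale)
}

#' @rdname readGCT
#' @param x an [ExprMatrix-class] to write.
#' @export
writeGCT <- function(x, path) {
    v <- exprValues(x)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(v), ncol(v), sep = "\t")), con)
    df <- data.frame(Name = rownames(v), Description = rownames(v), v,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write gene-set collections in GMT format
#'
#' One set per line: name, description, then member genes, tab separated.
#' Sets round-trip set-identically (duplicate members are dropped on read).
#'
#' @param path file path.
#' @return `readGMT` returns a named list of character vectors.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- lapply(lines, function(l) {
        f <- strsplit(l, "\t")[[1L]]
        if (length(f) < 3L)
            stop("malformed GMT line (need name, description, >=1 gene): ",
                 substr(l, 1L, 60L))
        unique(f[-(1:2)])
    })
    names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1L]][1L], "")
    sets
}

#' @rdname readGMT
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
        stop("gene sets must be named")
    if (is.null(descriptions)) descriptions <- rep("na", length(sets))
    lines <- mapply(function(nm, ds, genes)
        paste(c(nm, ds, genes), collapse = "\t"),
        names(sets), descriptions, sets)
    writeLines(lines, path)
    invisible(path)
}

#' Read / write per-sample trait tables
#'
#' TSV with a `sample_id` column and one column per trait (age at death,
#' sex, clinical AD status, pathology measures, APOE allele dosages, ...).
#' APOE allele-count columns, when present, are validated to lie in
#' \{0, 1, 2\}.
#'
#' @param path file path.
#' @return `readTraitTable` returns a `data.frame`.
#' @export
readTraitTable <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(df))
        stop("trait table must have a 'sample_id' column")
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample ids in trait table")
    for (col in intersect(c("apoe_e2_count", "apoe_e4_count"), names(df))) {
        v <- df[[col]]
        bad <- !is.na(v) & !v %in% c(0, 1, 2)
        if (any(bad))
            stop("allele counts in '", col, "' outside {0,1,2} at rows: ",
                 paste(utils::head(which(bad), 5L), collapse = ", "))
    }
    df
}

#' @rdname readTraitTable
#' @param traits trait `data.frame` to write.
#' @export
writeTraitTable <- function(traits, path) {
    utils::write.table(traits, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read / write gene annotation tables
#'
#' TSV with columns `gene_id`, `symbol`, `gc_fraction` (in \[0,1\]),
#' `length_bp` (positive) and `has_uniprot` (logical). One row per gene.
#'
#' @param path file path.
#' @return `readGeneAnnotation` returns a validated `data.frame`.
#' @export
readGeneAnnotation <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    need <- c("gene_id", "gc_fraction", "length_bp", "has_uniprot")
    if (!all(need %in% names(df)))
        stop("annotation must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(df$gene_id))
        stop("duplicate gene ids in annotation")
    bad <- which(df$gc_fraction < 0 | df$gc_fraction > 1)
    if (length(bad))
        stop("gc_fraction outside [0,1] at rows: ",
             paste(utils::head(bad, 5L), collapse = ", "))
    bad <- which(df$length_bp <= 0)
    if (length(bad))
        stop("nonpositive length_bp at rows: ",
             paste(utils::head(bad, 5L), collapse = ", "))
    df$has_uniprot <- as.logical(df$has_uniprot)
    df
}

#' @rdname readGeneAnnotation
#' @param annotation annotation `data.frame` to write.
#' @export
writeGeneAnnotation <- function(annotation, path) {
    utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
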