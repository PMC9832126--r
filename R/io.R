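#' Read a gene-by-sample expression table
#'
#' Reads a tab-delimited expression table (header row of sample ids, first
#' column gene identifiers), optionally applies the \code{log2(x + 1)}
#' transform, collapses duplicate gene rows by their mean, and attaches
#' tumor/normal sample labels.
#'
#' @param path TSV file path.
#' @param sample_class character vector of "tumor"/"normal" labels, either
#'   named by sample id or parallel to the sample columns.
#' @param annotation optional annotation data.frame
#'   (\code{gene_id}, \code{symbol}, \code{biotype}).
#' @param log_transform if TRUE, values are transformed as log2(x + 1).
#' @return A \linkS4class{TumorNormalExperiment}.
#' @export
readExpression <- function(path, sample_class, annotation = NULL,
                           log_transform = FALSE) {
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(raw) < 2L)
        stop("expression table needs a gene column plus >= 1 sample column")
    samples <- colnames(raw)[-1L]
    if (anyDuplicated(samples))
        stop("duplicate sample column(s): ",
             paste(unique(samples[duplicated(samples)]), collapse = ", "))
    gene_ids <- as.character(raw[[1L]])
    vals <- raw[, -1L, drop = FALSE]
    for (j in seq_along(vals)) {
        v <- vals[[j]]
        if (!is.numeric(v)) {
            suppressWarnings(num <- as.numeric(v))
            bad <- which(is.na(num) & !is.na(v))
            if (length(bad))
                stop(sprintf(
                    "non-numeric value '%s' at row %d (gene %s), column '%s'",
                    v[bad[1L]], bad[1L], gene_ids[bad[1L]], samples[j]))
            vals[[j]] <- num
        }
    }
    m <- as.matrix(vals)
    rownames(m) <- gene_ids
    if (log_transform) m <- log2(m + 1)
    m <- collapseDuplicateGenes(m)
    TumorNormalExperiment(m, sample_class, annotation = annotation)
}

#' Collapse duplicate gene rows by their mean
#'
#' Rows sharing a gene id are averaged; applying it to an already-unique
#' matrix is the identity. Row order follows first occurrence.
#'
#' @param m numeric matrix with gene-id rownames.
#' @return Matrix with unique rownames.
#' @export
collapseDuplicateGenes <- function(m) {
    if (!anyDuplicated(rownames(m))) return(m)
    ndup <- sum(duplicated(rownames(m)))
    ids <- factor(rownames(m), levels = unique(rownames(m)))
    out <- rowsum(m, ids, reorder = FALSE) / as.vector(table(ids))
    message(ndup, " duplicate gene row(s) collapsed by mean")
    out
}

#' Write an expression table to TSV
#'
#' Round-trips with \code{\link{readExpression}} at full stored precision
#' (\code{write.table} writes the full double-precision representation).
#'
#' @param x a \linkS4class{TumorNormalExperiment} or numeric matrix.
#' @param path output file path.
#' @export
writeExpression <- function(x, path) {
    m <- if (methods::is(x, "TumorNormalExperiment")) exprValues(x) else x
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a two-column (or three-column) gene annotation table
#'
#' Expects columns \code{gene_id}, \code{biotype} and optionally
#' \code{symbol}; missing symbols default to the gene id.
#'
#' @param path TSV file path.
#' @return data.frame with gene_id, symbol, biotype.
#' @export
readAnnotation <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "biotype") %in% colnames(df)))
        stop("annotation must contain 'gene_id' and 'biotype' columns")
    if (anyDuplicated(df$gene_id))
        stop("annotation gene_id values must be unique")
    if (is.null(df$symbol)) df$symbol <- df$gene_id
    df[, c("gene_id", "symbol", "biotype")]
}

#' Read gene annotation from an Ensembl-style GTF (gene features only)
#'
#' Convenience reader mapping \code{gene_id}, \code{gene_name} and
#' \code{gene_biotype} attributes of \code{gene} feature lines into the
#' annotation table consumed elsewhere. Biotypes other than
#' \code{protein_coding}/\code{lncRNA} are mapped to \code{other}.
#'
#' @param path GTF file path (uncompressed).
#' @return data.frame with gene_id, symbol, biotype.
#' @export
readGTFAnnotation <- function(path) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    keep <- vapply(fields, function(f) length(f) >= 9 && f[3] == "gene",
                   logical(1))
    attr9 <- vapply(fields[keep], `[[`, character(1), 9L)
    getAttr <- function(a, key) {
        m <- regmatches(a, regexpr(paste0(key, ' "[^"]*"'), a))
        ifelse(lengths(regmatches(a, gregexpr(paste0(key, ' "'), a))) > 0,
               sub(paste0(key, ' "([^"]*)"'), "\\1", m), NA_character_)
    }
    gene_id <- sub('.*gene_id "([^"]*)".*', "\\1", attr9)
    symbol <- ifelse(grepl('gene_name "', attr9),
                     sub('.*gene_name "([^"]*)".*', "\\1", attr9), gene_id)
    biotype <- ifelse(grepl('gene_biotype "', attr9),
                      sub('.*gene_biotype "([^"]*)".*', "\\1", attr9), "other")
    biotype[!biotype %in% c("protein_coding", "lncRNA")] <- "other"
    df <- data.frame(gene_id = gene_id, symbol = symbol, biotype = biotype,
                     stringsAsFactors = FALSE)
    df[!duplicated(df$gene_id), ]
}

#' Partition an expression object into mRNA and lncRNA matrices
#'
#' Genes are routed by annotation biotype; genes lacking annotation are
#' treated as "other" and dropped with a message reporting the count.
#'
#' @param x a \linkS4class{TumorNormalExperiment}.
#' @param annotation optional annotation data.frame; if NULL, the object's
#'   rowData biotype is used.
#' @return list with elements \code{mRNA} and \code{lncRNA}, both
#'   \linkS4class{TumorNormalExperiment}s.
#' @export
splitByBiotype <- function(x, annotation = NULL) {
    if (is.null(annotation)) {
        bt <- SummarizedExperiment::rowData(x)$biotype
        if (is.null(bt))
            stop("no biotype annotation available on object or argument")
        bt <- as.character(bt)
    } else {
        bt <- annotation$biotype[match(rownames(x), annotation$gene_id)]
    }
    bt[is.na(bt)] <- "other"
    n_other <- sum(!bt %in% c("protein_coding", "lncRNA"))
    if (n_other > 0)
        message(n_other, " gene(s) without mRNA/lncRNA biotype dropped")
    mRNA <- x[bt == "protein_coding", ]
    lncRNA <- x[bt == "lncRNA", ]
    if (nrow(mRNA) == 0L)
        stop("no genes with biotype 'protein_coding' after partition")
    if (nrow(lncRNA) == 0L)
        stop("no genes with biotype 'lncRNA' after partition")
    list(mRNA = mRNA, lncRNA = lncRNA)
}

#' Read a clinical table
#'
#' Expects at least \code{sample}, \code{time} (days) and \code{event}
#' (0/1) columns; covariates (age, sex, stage, t_stage, n_stage, m_stage)
#' may be present with missing values.
#'
#' @param path TSV file path.
#' @return data.frame, one row per sample.
#' @export
readClinical <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    validateClinical(df)
    df
}

#' @keywords internal
validateClinical <- function(df) {
    need <- c("sample", "time", "event")
    if (!all(need %in% colnames(df)))
        stop("clinical table must contain columns: ",
             paste(need, collapse = ", "))
    if (anyDuplicated(df$sample))
        stop("duplicate sample ids in clinical table")
    if (any(is.na(df$time)) || any(is.na(df$event)))
        stop("samples with survival data must have non-missing time and event")
    if (any(df$time < 0)) stop("survival times must be >= 0")
    if (!all(df$event %in% c(0, 1))) stop("event must be coded 0/1")
    invisible(df)
}

#' Write a clinical (or any per-sample) table to TSV
#' @param df data.frame.
#' @param path output file path.
#' @export
writeTable <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a gene set (one symbol per line)
#'
#' @param path plain-text file, one gene symbol per line; blank lines and
#'   lines starting with '#' are ignored.
#' @param name gene-set name.
#' @return list with \code{name} and \code{symbols} (unique, non-empty).
#' @export
readGeneSet <- function(path, name = basename(path)) {
    lines <- trimws(readLines(path))
    symbols <- unique(lines[nzchar(lines) & !startsWith(lines, "#")])
    if (!length(symbols)) stop("gene set is empty")
    list(name = name, symbols = symbols)
}

#' Drop samples with insufficient follow-up
#'
#' Keeps samples with \code{time >= min_days}; the boundary is inclusive.
#'
#' @param clinical clinical data.frame (see \code{\link{readClinical}}).
#' @param min_days minimum follow-up in days (default 1).
#' @return Filtered clinical data.frame.
#' @export
filterFollowup <- function(clinical, min_days = 1) {
    stopifnot(min_days >= 0)
    keep <- clinical$time >= min_days
    if (!any(keep))
        stop("all samples removed by the follow-up filter (min_days = ",
             min_days, ")")
    clinical[keep, , drop = FALSE]
}

#' Read a long-format score panel table
#'
#' @param path TSV with columns sample, panel_kind, variable, method, value.
#' @return data.frame.
#' @export
readScorePanel <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample", "panel_kind", "variable", "value")
    if (!all(need %in% colnames(df)))
        stop("score panel must contain columns: ", paste(need, collapse = ", "))
    if (is.null(df$method)) df$method <- NA_character_
    df
}

#' Map TCGA-style barcodes to tumor/normal classes
#'
#' Sample-type codes 01-09 are tumor, 10-19 normal (the fourth barcode
#' field, e.g. "TCGA-XX-XXXX-01A").
#'
#' @param samples character vector of barcodes.
#' @return named character vector of "tumor"/"normal".
#' @export
parseBarcodeClass <- function(samples) {
    code <- sub("^[^-]+-[^-]+-[^-]+-(\\d{2}).*$", "\\1", samples)
    ok <- grepl("^\\d{2}$", code)
    if (!all(ok))
        stop("not a recognisable barcode: ", samples[!ok][1L])
    cls <- ifelse(as.integer(code) <= 9, "tumor", "normal")
    names(cls) <- samples
    cls
}
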