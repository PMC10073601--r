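#' @include AllClasses.R
NULL

#' Write a gene annotation as 6-column BED
#'
#' Columns: chrom, start (0-based), end, gene_id, score (0), strand.
#'
#' @param annot GRanges annotation.
#' @param path output path.
#' @export
writeAnnotationBed <- function(annot, path) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(annot)),
                     start = GenomicRanges::start(annot) - 1L,
                     end = GenomicRanges::end(annot),
                     name = annot$gene_id, score = 0L,
                     strand = as.character(GenomicRanges::strand(annot)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
}

#' Read a 6-column BED gene annotation
#'
#' @param path BED file path.
#' @param genomeLength circular chromosome length in bp (optional).
#' @return GRanges with gene_id metadata.
#' @export
readAnnotationBed <- function(path, genomeLength = NA) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
    gr <- GenomicRanges::GRanges(
        seqnames = df$chrom,
        ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
        strand = df$strand, gene_id = df$name)
    names(gr) <- gr$gene_id
    if (!is.na(genomeLength)) {
        sl <- as.integer(genomeLength)
        names(sl) <- as.character(GenomicRanges::seqnames(gr))[1]
        GenomeInfoDb::seqlengths(gr) <- sl
        GenomeInfoDb::isCircular(gr) <- stats::setNames(TRUE, names(sl))
    }
    gr
}

#' Write/read a genes-by-samples matrix as TSV
#'
#' First column \code{gene_id}, remaining columns one per sample.
#'
#' @param mat matrix with rownames (gene ids) and colnames (samples).
#' @param path file path.
#' @export
writeMatrixTsv <- function(mat, path) {
    df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' @rdname writeMatrixTsv
#' @export
readMatrixTsv <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
}

#' Write/read a condition design table as TSV
#'
#' Columns: sample, genome, stress, evolved, replicate.
#'
#' @param design data.frame design table.
#' @param path file path.
#' @export
writeDesignTsv <- function(design, path) {
    utils::write.table(design, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' @rdname writeDesignTsv
#' @export
readDesignTsv <- function(path) {
    d <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    rownames(d) <- d$sample
    d
}

#' Write/read growth curves as long-format CSV
#'
#' Columns: well, time_h, od600.
#'
#' @param curves data.frame of growth curves.
#' @param path file path.
#' @export
writeGrowthCsv <- function(curves, path) {
    utils::write.csv(curves, path, row.names = FALSE, quote = FALSE)
}

#' @rdname writeGrowthCsv
#' @export
readGrowthCsv <- function(path) {
    utils::read.csv(path, stringsAsFactors = FALSE)
}
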