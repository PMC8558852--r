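#' Read / write count matrices
#'
#' TSV layout: first column `gene_id`, remaining columns one per sample
#' (header row of sample ids). The MatrixMarket variant writes the sparse
#' counts plus sidecar `<stem>.genes.txt` / `<stem>.samples.txt` id lists.
#'
#' @param counts integer matrix or [count_matrix()].
#' @param path output file.
#' @name counts_io
NULL

#' @rdname counts_io
#' @export
write_counts <- function(counts, path) {
  m <- as_count_mat(counts)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname counts_io
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname counts_io
#' @export
write_counts_mm <- function(counts, path) {
  m <- as_count_mat(counts)
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
  stem <- sub("\\.mtx$", "", path)
  writeLines(rownames(m), paste0(stem, ".genes.txt"))
  writeLines(colnames(m), paste0(stem, ".samples.txt"))
  invisible(path)
}

#' @rdname counts_io
#' @export
read_counts_mm <- function(path) {
  m <- as.matrix(Matrix::readMM(path))
  stem <- sub("\\.mtx$", "", path)
  rownames(m) <- readLines(paste0(stem, ".genes.txt"))
  colnames(m) <- readLines(paste0(stem, ".samples.txt"))
  storage.mode(m) <- "integer"
  m
}

#' Read / write gene annotation
#'
#' TSV with columns `gene_id`, `symbol`, `biotype`, `chrom`, `start`,
#' `end`, `strand`; or a minimal GTF holding one `gene` line per gene with
#' `gene_id`, `gene_name` and `gene_biotype` attributes.
#'
#' @param annotation annotation data.frame.
#' @param path file path.
#' @name annotation_io
NULL

#' @rdname annotation_io
#' @export
write_annotation <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname annotation_io
#' @export
read_annotation <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname annotation_io
#' @export
write_annotation_gtf <- function(annotation, path) {
  attrs <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                   annotation$gene_id, annotation$symbol,
                   annotation$biotype)
  lines <- sprintf("%s\tlncoex\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   annotation$chrom, annotation$start, annotation$end,
                   annotation$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname annotation_io
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "gene"]
  data.frame(gene_id = gr$gene_id,
             symbol = gr$gene_name,
             biotype = gr$gene_biotype,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write a threshold scan or DE table as TSV
#'
#' @param x data.frame-like result.
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
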