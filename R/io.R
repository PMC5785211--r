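#' Read and write long expression tables
#'
#' Tab-separated long layout with columns `gene_id`, `condition`,
#' `time_h`, `value`. Lines starting with `#` are treated as comments
#' (used for provenance headers).
#'
#' @param path file path.
#' @param x data.frame to write.
#' @param header optional comment lines (without the leading `#`).
#' @return `read_expression_tsv`: the data.frame;
#'   `write_expression_tsv`: the path, invisibly.
#' @export
read_expression_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation from GFF3
#'
#' Imports gene features from a GFF3 file (1-based, inclusive
#' coordinates) into the simple gene table used by
#' [assign_peak_targets()].
#'
#' @param path GFF3 file.
#' @param feature_type feature types to keep (default `gene`/`CDS`).
#' @return data.frame `gene_id`, `start`, `end`, `strand`, plus attribute
#'   `"genome_length"` if declared via a `##sequence-region` directive.
#' @export
read_gene_annotation <- function(path, feature_type = c("gene", "CDS")) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    as.character(seq_along(gr))
  out <- data.frame(gene_id = ids,
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)))
  lines <- readLines(path, n = 50)
  sr <- grep("^##sequence-region", lines, value = TRUE)
  if (length(sr))
    attr(out, "genome_length") <-
      as.integer(utils::tail(strsplit(sr[1], "\\s+")[[1]], 1))
  out
}

#' @rdname read_gene_annotation
#' @param annotation gene table (`gene_id`, `start`, `end`, `strand`).
#' @param genome_length chromosome length for the `##sequence-region`
#'   directive.
#' @param seqname chromosome name.
#' @export
write_gene_annotation <- function(annotation, path, genome_length,
                                  seqname = "chr") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = annotation$start,
                              end = annotation$end),
    strand = annotation$strand)
  gr$type <- "gene"
  gr$ID <- annotation$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  # prepend the sequence-region directive rtracklayer omits for plain
  # GRanges input
  lines <- readLines(path)
  if (!any(grepl("^##sequence-region", lines))) {
    ins <- paste("##sequence-region", seqname, 1, genome_length)
    writeLines(append(lines, ins, after = 1), path)
  }
  invisible(path)
}

#' Read and write per-base signal tracks as bedGraph
#'
#' bedGraph uses 0-based, half-open intervals; runs of equal values are
#' collapsed on export and expanded to one value per base on import.
#'
#' @param path bedGraph file.
#' @param genome_length chromosome length (bases); on import, positions
#'   not covered by any interval get 0.
#' @param circular circular chromosome flag for the resulting track.
#' @return `read_signal_bedgraph`: a [signal_track()];
#'   `write_signal_bedgraph`: the path, invisibly.
#' @export
read_signal_bedgraph <- function(path, genome_length, circular = TRUE) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  values <- numeric(genome_length)
  s <- GenomicRanges::start(gr)          # 1-based after import
  e <- GenomicRanges::end(gr)
  v <- S4Vectors::mcols(gr)$score
  for (i in seq_along(gr)) values[s[i]:e[i]] <- v[i]
  signal_track(values, circular = circular,
               seqname = as.character(GenomicRanges::seqnames(gr)[1]))
}

#' @rdname read_signal_bedgraph
#' @param track a [signal_track()].
#' @export
write_signal_bedgraph <- function(track, path) {
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gr <- GenomicRanges::GRanges(
    seqnames = track$seqname,
    ranges = IRanges::IRanges(start = starts, end = ends),
    score = r$values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write called peaks as BED6
#'
#' Score is `10 x` summit enrichment, capped at 1000; the name encodes
#' the summit position.
#'
#' @param peaks a [call_peaks()] result.
#' @param path output file.
#' @param seqname chromosome name.
#' @return the path, invisibly.
#' @export
write_peaks_bed <- function(peaks, path, seqname = "chr") {
  df <- data.frame(chrom = seqname, start = peaks$start, end = peaks$end,
                   name = paste0("peak_", seq_len(nrow(peaks)),
                                 "_summit", peaks$summit),
                   score = pmin(1000, round(10 * peaks$enrichment)),
                   strand = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
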