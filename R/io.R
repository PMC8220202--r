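# File-format glue.  Conventions: FPKM TSV has gene ids in column 1 and one
# column per sample; annotation travels as BED (0-based half-open, via
# rtracklayer) or as a 1-based inclusive TSV; FISH counts as CSV; karyotypes
# as headerless replicate_id<TAB>condition<TAB>ISCN lines.  Internally all
# coordinates are 1-based inclusive; conversion happens only at the BED
# boundary.

#' Read / write an FPKM gene-by-sample TSV
#'
#' Column 1 holds gene identifiers; every further column is one sample.
#'
#' @param path file path.
#' @return `read_fpkm_tsv`: numeric matrix with gene rownames.
#' @export
read_fpkm_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("FPKM TSV needs a gene-id column plus >= 1 sample")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  .check_fpkm(m)
  m
}

#' @rdname read_fpkm_tsv
#' @param m gene-by-sample matrix.
#' @export
write_fpkm_tsv <- function(m, path) {
  .check_fpkm(m)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene annotation
#'
#' BED files (`*.bed`) are read through rtracklayer, which converts the
#' 0-based half-open records to the 1-based inclusive coordinates used
#' internally; any other extension is read as a TSV with header columns
#' `gene_id`, `chrom`, `start`, `end` already 1-based inclusive.
#'
#' @param path file path (`.bed` or TSV).
#' @return data.frame `gene_id`, `chrom`, `start`, `end`.
#' @export
read_annotation <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    ann <- data.frame(
      gene_id = if (!is.null(gr$name)) as.character(gr$name) else
        paste0("feature_", seq_along(gr)),
      chrom = sub("^chr", "", as.character(GenomicRanges::seqnames(gr))),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE
    )
  } else {
    ann <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    ann$chrom <- sub("^chr", "", as.character(ann$chrom))
  }
  .check_annotation(ann)
  ann
}

#' @rdname read_annotation
#' @param ann annotation data.frame (1-based inclusive).
#' @export
write_annotation_bed <- function(ann, path) {
  .check_annotation(ann)
  gr <- GenomicRanges::GRanges(
    seqnames = paste0("chr", ann$chrom),
    ranges = IRanges::IRanges(start = ann$start, end = ann$end,
                              names = ann$gene_id)
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write per-cell FISH count CSV
#'
#' Columns: `sample_id`, `probe_set`, `cell_index`, `red`, `green`,
#' `fusion`.
#'
#' @param path file path.
#' @return data.frame of per-cell counts.
#' @export
read_fish_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "probe_set", "cell_index", "red", "green", "fusion")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("FISH CSV missing column(s): ", paste(missing, collapse = ", "))
  }
  counts <- as.matrix(df[c("red", "green", "fusion")])
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    stop("FISH counts must be nonnegative integers")
  }
  df
}

#' @rdname read_fish_csv
#' @param counts per-cell count data.frame.
#' @export
write_fish_csv <- function(counts, path) {
  utils::write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write karyotype text files
#'
#' One record per line: `replicate_id<TAB>condition<TAB>ISCN`, no header.
#'
#' @param path file path.
#' @return data.frame `replicate_id`, `condition`, `iscn`.
#' @export
read_karyotype_file <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("replicate_id", "condition", "iscn"))
  for (i in seq_len(nrow(df))) {
    tryCatch(parse_karyotype(df$iscn[i]), error = function(e) {
      stop("line ", i, " of ", path, ": ", conditionMessage(e))
    })
  }
  df
}

#' @rdname read_karyotype_file
#' @param records data.frame with columns `replicate_id`, `condition`,
#'   `iscn`.
#' @export
write_karyotype_file <- function(records, path) {
  stopifnot(all(c("replicate_id", "condition", "iscn") %in% names(records)))
  utils::write.table(records[c("replicate_id", "condition", "iscn")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
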