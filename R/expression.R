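# FPKM normalization and breakpoint-window fold-change screen.
#
# Normalization: each sample is divided by its own median over all genes
# (zeros included), then transformed as expression = log10(1 + 99 * x).
# The transform has two fixed points by construction: a gene not expressed
# at all keeps normalized expression 0, and the gene sitting at the
# per-sample median (adjusted FPKM 1) gets normalized expression 2.

#' Construct a breakpoint region window
#'
#' @param id band label, e.g. `"2p22"`.
#' @param chrom chromosome label (`"1"`..`"22"`, `"X"`, `"Y"`).
#' @param start,end 1-based inclusive Hg19 coordinates, `1 <= start <= end`.
#' @return A list of class `"region_window"`.
#' @export
region_window <- function(id, chrom, start, end) {
  chrom <- as.character(chrom)
  if (!chrom %in% .chrom_labels) stop("invalid chromosome label ", sQuote(chrom))
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 1 || start > end) {
    stop("window needs 1 <= start <= end")
  }
  structure(list(id = as.character(id), chrom = chrom,
                 start = start, end = end),
            class = "region_window")
}

#' Default breakpoint windows on 2p22, 10q22, and 16q22 (Hg19)
#'
#' Explicit intervals spanning the breakpoint regions probed on the three
#' translocation partner chromosomes.  The probes' exact genomic extent is
#' not published, so each window is the minimal interval covering the
#' Hg19 coordinates of the breakpoint-region genes in
#' [breakpoint_genes()]: chr2 27.71–33.79 Mb, chr10 81.66–90.68 Mb,
#' chr16 66.96–68.31 Mb.
#'
#' @return Named list of three [region_window()] objects.
#' @export
default_windows <- function() {
  g <- breakpoint_genes()
  mk <- function(id, chrom) {
    w <- g[g$window == id, ]
    region_window(id, chrom, min(w$start), max(w$end))
  }
  list(`2p22` = mk("2p22", "2"),
       `10q22` = mk("10q22", "10"),
       `16q22` = mk("16q22", "16"))
}

.check_fpkm <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expected a numeric matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop("matrix needs unique gene ids as rownames")
  }
  if (any(m < 0, na.rm = TRUE) || anyNA(m)) {
    stop("FPKM values must be nonnegative and non-missing")
  }
  invisible(m)
}

#' Set each sample's median to 1
#'
#' Divides every sample (column) by its own median over all genes, zeros
#' included, so the per-sample median of the result is exactly 1.  Gene-wise
#' ratios between samples change only by the per-sample scalar, and the
#' operation is idempotent.
#'
#' @param m nonnegative gene-by-sample matrix (genes as rownames).
#' @param nonzero if `TRUE`, use the median of positive values instead —
#'   the "median of all genes that are expressed" variant.  By default a
#'   per-sample median <= 0 (more than half the genes unexpressed) is an
#'   error rather than a silent division by zero.
#' @return Matrix of the same shape with per-sample median 1.
#' @examples
#' m <- matrix(c(2, 4, 8), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
#' median_adjust(m)[, 1]  # 0.5 1 2
#' @export
median_adjust <- function(m, nonzero = FALSE) {
  .check_fpkm(m)
  med <- if (nonzero) {
    apply(m, 2, function(x) if (any(x > 0)) stats::median(x[x > 0]) else 0)
  } else {
    apply(m, 2, stats::median)
  }
  bad <- med <= 0
  if (any(bad)) {
    stop("per-sample median is not positive for: ",
         paste(colnames(m)[bad], collapse = ", "),
         if (!nonzero) " (consider nonzero = TRUE to use the median of expressed genes)")
  }
  sweep(m, 2, med, "/")
}

#' Log-normalize a median-adjusted FPKM matrix
#'
#' Elementwise `expression = log10(1 + 99 * x)` on median-adjusted FPKM.
#' Strictly increasing; maps 0 to 0 (unexpressed genes) and 1 (the
#' per-sample median) to 2.
#'
#' @param m nonnegative gene-by-sample matrix.
#' @param already_adjusted set `TRUE` if `m` has already been through
#'   [median_adjust()]; otherwise adjustment is applied first.
#' @param nonzero passed to [median_adjust()].
#' @return Matrix of normalized expression values (all >= 0; 0 iff the
#'   adjusted FPKM is 0).
#' @export
log_normalize <- function(m, already_adjusted = FALSE, nonzero = FALSE) {
  .check_fpkm(m)
  if (!already_adjusted) m <- median_adjust(m, nonzero = nonzero)
  log10(1 + 99 * m)
}

#' Signed fold change between two abundance values
#'
#' A ratio `r` is reported as `+r` when `r >= 1` and `-1/r` otherwise, so
#' magnitude is symmetric for up- and downregulation and `|fc| >= 1` always.
#' Two modes:
#' \describe{
#'   \item{`shifted`}{`r = (1 + 99 a) / (1 + 99 b)` — the ratio on the
#'     normalization's shifted scale, i.e. `10^` (difference of normalized
#'     expression).  Finite at zero denominators: a gene absent in `b` and
#'     at the median in `a` gives +100.}
#'   \item{`raw`}{`r = (a + pseudocount) / (b + pseudocount)` — the plain
#'     FPKM ratio stabilized by a pseudocount.}
#' }
#'
#' @param a,b nonnegative median-adjusted FPKM values (vectors recycle);
#'   `a` is the numerator condition.
#' @param mode `"shifted"` (default) or `"raw"`.
#' @param pseudocount added to both values in `raw` mode (default 0.01).
#' @return Signed fold change(s); `+1` when `a == b`.
#' @examples
#' signed_fold_change(1, 0)          # +100 (shifted)
#' signed_fold_change(0, 1)          # -100
#' signed_fold_change(8, 2, "raw", pseudocount = 0)  # +4
#' @export
signed_fold_change <- function(a, b, mode = c("shifted", "raw"),
                               pseudocount = 0.01) {
  mode <- match.arg(mode)
  if (anyNA(c(a, b)) || any(c(a, b) < 0)) {
    stop("abundances must be nonnegative and non-missing")
  }
  r <- if (mode == "shifted") {
    (1 + 99 * a) / (1 + 99 * b)
  } else {
    if (pseudocount <= 0 && any(b + pseudocount <= 0)) {
      stop("raw mode needs b > 0 or a positive pseudocount")
    }
    (a + pseudocount) / (b + pseudocount)
  }
  ifelse(r >= 1, r, -1 / r)
}

.check_annotation <- function(ann) {
  stopifnot(is.data.frame(ann),
            all(c("gene_id", "chrom", "start", "end") %in% names(ann)))
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene_id in annotation")
  if (any(ann$start > ann$end)) stop("annotation has start > end")
  if (any(ann$start < 1)) stop("annotation coordinates are 1-based; start >= 1")
  bad <- setdiff(unique(as.character(ann$chrom)), .chrom_labels)
  if (length(bad)) stop("invalid chromosome label(s): ",
                        paste(sQuote(bad), collapse = ", "))
  invisible(ann)
}

#' Genes overlapping a breakpoint window
#'
#' Membership is overlap by at least 1 bp (not containment): a gene
#' straddling the window edge is included.  Results are sorted by start
#' coordinate, ties broken by gene id.
#'
#' @param ann annotation data.frame with columns `gene_id`, `chrom`,
#'   `start`, `end` (1-based inclusive).
#' @param w a [region_window()].
#' @return The overlapping annotation rows, coordinate-ordered.
#' @export
extract_window <- function(ann, w) {
  .check_annotation(ann)
  stopifnot(inherits(w, "region_window"))
  sub <- ann[as.character(ann$chrom) == w$chrom, , drop = FALSE]
  if (nrow(sub) == 0L) return(sub)
  hit <- IRanges::overlapsAny(IRanges::IRanges(sub$start, sub$end),
                              IRanges::IRanges(w$start, w$end))
  sub <- sub[hit, , drop = FALSE]
  sub <- sub[order(sub$start, sub$gene_id), , drop = FALSE]
  rownames(sub) <- NULL
  sub
}

.log10fc_contrast <- function(norm, contrast, mode, pseudocount) {
  stopifnot(length(contrast) == 2L)
  missing <- setdiff(contrast, colnames(norm))
  if (length(missing)) {
    stop("unknown sample(s) in contrast: ", paste(sQuote(missing), collapse = ", "))
  }
  va <- norm[, contrast[1]]
  vb <- norm[, contrast[2]]
  if (mode == "shifted") {
    va - vb
  } else {
    xa <- (10^va - 1) / 99
    xb <- (10^vb - 1) / 99
    log10((xa + pseudocount) / (xb + pseudocount))
  }
}

.signed_from_log10 <- function(l10) ifelse(l10 >= 0, 10^l10, -10^(-l10))

#' Breakpoint-window candidate-gene screen
#'
#' For every gene overlapping the given windows, computes the signed fold
#' change and log10 fold change between two samples, attaches an empirical
#' p-value, and flags genes passing the screen's filter
#' (`|fc| > fc_threshold` and `p < alpha`; defaults: more than twofold at
#' p < 0.025).  The full per-window gene lists are returned unfiltered with
#' the pass flag, so non-passing genes remain visible.
#'
#' The p-value is the two-sided empirical rank of the gene's `|log10 fc|`
#' in the genome-wide background distribution over all non-window genes,
#' with the usual +1 correction: `p = (1 + #\{bg >= obs\}) / (1 + n_bg)`.
#' This empirical-null construction is a package convention for
#' single-sample-per-condition designs, where no replicate-based test is
#' available; a gene is "significant" when its contrast is extreme relative
#' to the genome-wide null.
#'
#' @param norm normalized matrix from [log_normalize()].
#' @param ann gene annotation data.frame (`gene_id`, `chrom`, `start`,
#'   `end`); genes absent from `norm` are dropped with a warning.
#' @param windows list of [region_window()]s (default [default_windows()]).
#' @param contrast length-2 character vector `(numerator, denominator)`,
#'   e.g. `c("BEC40W", "BEC20W")`.
#' @param fc_threshold pass requires `|fc|` strictly greater than this
#'   (default 2).
#' @param alpha pass requires `p` strictly below this (default 0.025).
#' @param mode,pseudocount fold-change mode, see [signed_fold_change()].
#' @return data.frame grouped by window (in the order given),
#'   coordinate-sorted within window: `window`, `gene_id`, `chrom`, `start`,
#'   `end`, `fc`, `log10fc`, `p`, `passes`.
#' @export
candidate_genes <- function(norm, ann, windows = default_windows(),
                            contrast, fc_threshold = 2, alpha = 0.025,
                            mode = c("shifted", "raw"), pseudocount = 0.01) {
  mode <- match.arg(mode)
  .check_annotation(ann)
  if (!length(windows)) stop("windows must be nonempty")
  dropped <- setdiff(ann$gene_id, rownames(norm))
  ann <- ann[ann$gene_id %in% rownames(norm), , drop = FALSE]
  if (length(dropped)) {
    warning(length(dropped), " annotated gene(s) absent from the matrix dropped")
  }
  l10 <- .log10fc_contrast(norm, contrast, mode, pseudocount)

  win_tabs <- lapply(names(windows), function(nm) {
    wg <- extract_window(ann, windows[[nm]])
    if (nrow(wg)) cbind(window = windows[[nm]]$id, wg) else NULL
  })
  win_tab <- do.call(rbind, win_tabs)
  window_ids <- if (is.null(win_tab)) character() else unique(win_tab$gene_id)
  bg_abs <- abs(l10[setdiff(rownames(norm), window_ids)])
  n_bg <- length(bg_abs)
  if (is.null(win_tab)) {
    return(data.frame(window = character(), gene_id = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      fc = numeric(), log10fc = numeric(), p = numeric(),
                      passes = logical(), stringsAsFactors = FALSE))
  }
  g_l10 <- l10[win_tab$gene_id]
  p <- vapply(abs(g_l10),
              function(x) (1 + sum(bg_abs >= x)) / (1 + n_bg), numeric(1))
  fc <- .signed_from_log10(g_l10)
  out <- data.frame(window = win_tab$window, gene_id = win_tab$gene_id,
                    chrom = as.character(win_tab$chrom),
                    start = win_tab$start, end = win_tab$end,
                    fc = fc, log10fc = unname(g_l10), p = p,
                    passes = abs(fc) > fc_threshold & p < alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Whole-chromosome fold-change track
#'
#' All annotated genes on one chromosome, coordinate-ordered, with the
#' signed log10 fold change of the contrast — the data behind an
#' up/down (red/green) transcriptional-landscape rendering.
#'
#' @inheritParams candidate_genes
#' @param chromosome chromosome label, e.g. `"2"`.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `log10fc`, `fc`,
#'   one row per gene; empty if the chromosome has no annotated genes.
#' @export
chromosome_landscape <- function(norm, ann, chromosome, contrast,
                                 mode = c("shifted", "raw"),
                                 pseudocount = 0.01) {
  mode <- match.arg(mode)
  .check_annotation(ann)
  sub <- ann[as.character(ann$chrom) == as.character(chromosome) &
               ann$gene_id %in% rownames(norm), , drop = FALSE]
  sub <- sub[order(sub$start, sub$gene_id), , drop = FALSE]
  l10 <- .log10fc_contrast(norm, contrast, mode, pseudocount)
  out <- data.frame(gene_id = sub$gene_id, chrom = as.character(sub$chrom),
                    start = sub$start, end = sub$end,
                    log10fc = unname(l10[sub$gene_id]),
                    fc = .signed_from_log10(unname(l10[sub$gene_id])),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
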