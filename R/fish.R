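# Dual-color FISH enumeration: breakpoint regions of two chromosomes are
# labeled red and green; two signals of one color mean intact homologues,
# three or more mean gain or a break without fusion, and a co-localized
# (yellow) signal marks a translocation fusion of the two loci.

.cell_categories <- c("normal", "gain_or_break", "fusion_positive",
                      "uninformative")

#' The three shipped breakpoint probe sets
#'
#' Pairings of the 2p22, 10q22, and 16q22 breakpoint probes used to screen
#' for the three pairwise fusions of a three-way t(2;10;16) translocation:
#' set1 = (2p22 red; 16q22 green), set2 = (2p22; 10q22),
#' set3 = (10q22; 16q22).
#'
#' @return A data.frame with columns `id`, `red_locus`, `green_locus`.
#' @export
default_probe_sets <- function() {
  data.frame(
    id = c("set1", "set2", "set3"),
    red_locus = c("2p22", "2p22", "10q22"),
    green_locus = c("16q22", "10q22", "16q22"),
    stringsAsFactors = FALSE
  )
}

#' Classify per-nucleus FISH signal counts
#'
#' Applies the enumeration rules in strict precedence: (1) any co-localized
#' signal makes the cell `fusion_positive`; (2) exactly two red and two
#' green signals are `normal`; (3) three or more signals of either color are
#' `gain_or_break` (gain of a chromosome or a break without fusion; the two
#' are not distinguishable from counts); (4) anything else — fewer than two
#' signals of some color, typically a truncated nucleus in a 4–5 um tissue
#' section — is `uninformative`.  The rules are total: every nonnegative
#' count triple maps to exactly one category.
#'
#' A cell such as (3, 3, 1) is `fusion_positive`: the yellow signal is the
#' defined positive event and extra same-color signals are secondary.
#'
#' @param red,green,fusion nonnegative integer vectors (recycled to a
#'   common length): red-probe, green-probe, and co-localized signal counts.
#' @return A factor over the four categories, one element per cell.
#' @examples
#' classify_cell(2, 2, 0)  # normal
#' classify_cell(3, 2, 0)  # gain_or_break
#' classify_cell(2, 2, 1)  # fusion_positive
#' @export
classify_cell <- function(red, green, fusion) {
  n <- max(length(red), length(green), length(fusion))
  red <- rep_len(red, n); green <- rep_len(green, n)
  fusion <- rep_len(fusion, n)
  counts <- c(red, green, fusion)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    stop("signal counts must be nonnegative integers")
  }
  cat <- ifelse(fusion >= 1, "fusion_positive",
         ifelse(red == 2 & green == 2, "normal",
         ifelse(red >= 3 | green >= 3, "gain_or_break", "uninformative")))
  factor(cat, levels = .cell_categories)
}

#' Call one sample positive or negative for a fusion
#'
#' Classifies every cell with [classify_cell()], excludes `uninformative`
#' cells from the informative denominator, and calls the sample `positive`
#' when at least `min_fusion_cells` cells carry a fusion signal.  At least
#' `min_cells` informative nuclei (default 25, the minimum scored per
#' hybridization) are required; otherwise the call is `insufficient_cells`.
#'
#' `min_fusion_cells = 2` operationalizes "multiple cells ... some with a
#' fusion signal"; it is a package convention, not a published threshold.
#'
#' @param cells data.frame with integer columns `red`, `green`, `fusion`
#'   (one row per nucleus); zero rows allowed.
#' @param min_cells minimum informative cells for a definitive call.
#' @param min_fusion_cells minimum fusion-positive cells for a positive call.
#' @return One-row data.frame: `n_cells_scored`, the four category tallies,
#'   `informative`, and `call` (`positive`/`negative`/`insufficient_cells`).
#' @export
call_sample <- function(cells, min_cells = 25L, min_fusion_cells = 2L) {
  stopifnot(min_cells >= 1L, min_fusion_cells >= 1L)
  if (is.null(cells) || nrow(cells) == 0L) {
    tal <- setNames(as.list(integer(4)), .cell_categories)
    return(data.frame(n_cells_scored = 0L, tal, informative = 0L,
                      call = "insufficient_cells", stringsAsFactors = FALSE))
  }
  stopifnot(all(c("red", "green", "fusion") %in% names(cells)))
  cat <- classify_cell(cells$red, cells$green, cells$fusion)
  tal <- table(cat)
  informative <- nrow(cells) - as.integer(tal[["uninformative"]])
  call <- if (informative < min_cells) {
    "insufficient_cells"
  } else if (tal[["fusion_positive"]] >= min_fusion_cells) {
    "positive"
  } else {
    "negative"
  }
  data.frame(n_cells_scored = nrow(cells),
             normal = as.integer(tal[["normal"]]),
             gain_or_break = as.integer(tal[["gain_or_break"]]),
             fusion_positive = as.integer(tal[["fusion_positive"]]),
             uninformative = as.integer(tal[["uninformative"]]),
             informative = informative,
             call = call, stringsAsFactors = FALSE)
}

#' Screen a cohort across breakpoint probe sets
#'
#' Groups a per-cell count table by `(sample_id, probe_set)` and calls each
#' group with [call_sample()].  Output order is by sample then probe set,
#' regardless of input row order.
#'
#' @param counts data.frame with columns `sample_id`, `probe_set`, `red`,
#'   `green`, `fusion` (plus any others, e.g. `cell_index`, which are
#'   ignored).
#' @param probe_sets data.frame of known probe sets (default
#'   [default_probe_sets()]); rows with a `probe_set` not listed there raise
#'   a configuration error.
#' @param min_cells,min_fusion_cells passed to [call_sample()].
#' @return A data.frame with one row per `(sample_id, probe_set)` group:
#'   the two keys followed by the [call_sample()] columns.
#' @export
screen_probe_sets <- function(counts, probe_sets = default_probe_sets(),
                              min_cells = 25L, min_fusion_cells = 2L) {
  stopifnot(is.data.frame(counts),
            all(c("sample_id", "probe_set", "red", "green", "fusion") %in%
                  names(counts)))
  unknown <- setdiff(unique(counts$probe_set), probe_sets$id)
  if (length(unknown)) {
    stop("unknown probe set id(s): ", paste(sQuote(unknown), collapse = ", "))
  }
  keys <- unique(counts[c("sample_id", "probe_set")])
  keys <- keys[order(keys$sample_id, keys$probe_set), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    grp <- counts[counts$sample_id == keys$sample_id[i] &
                    counts$probe_set == keys$probe_set[i], , drop = FALSE]
    cbind(keys[i, , drop = FALSE],
          call_sample(grp, min_cells = min_cells,
                      min_fusion_cells = min_fusion_cells))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
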