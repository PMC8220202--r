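# Synthetic cytogenetic and expression data with known ground truth.
# Every generator takes an explicit seed and restores the caller's RNG
# state (withr), so a fixed seed gives bit-identical output and no hidden
# global random state leaks between stages.

#' Specify one planted expression effect
#'
#' @param gene_id unique gene identifier.
#' @param fold_change signed true fold change; `|fold_change| >= 1`
#'   (`+4` = fourfold up in the contrast numerator, `-8` = eightfold down).
#' @param window `"2p22"`, `"10q22"`, `"16q22"` (gene is placed inside that
#'   breakpoint window) or `"background"` (placed outside every window).
#' @return A list of class `"effect_spec"`.
#' @export
effect_spec <- function(gene_id, fold_change,
                        window = c("background", "2p22", "10q22", "16q22")) {
  window <- match.arg(window)
  fold_change <- as.numeric(fold_change)
  if (is.na(fold_change) || abs(fold_change) < 1) {
    stop("|fold_change| must be >= 1 (signed convention)")
  }
  structure(list(gene_id = as.character(gene_id), fold_change = fold_change,
                 window = window),
            class = "effect_spec")
}

# Genomic regions guaranteed disjoint from the shipped breakpoint windows;
# background genes are laid out round-robin across them (Hg19-sized).
.background_regions <- function() {
  data.frame(
    chrom = c("1", "3", "4", "5", "6", "7", "8", "9", "11", "12",
              "2", "10", "16"),
    start = c(rep(1e6, 10), 1.2e8, 1.0e8, 1e6),
    end = c(2.4e8, 1.9e8, 1.8e8, 1.7e8, 1.6e8, 1.5e8, 1.4e8, 1.3e8,
            1.3e8, 1.3e8, 2.3e8, 1.3e8, 6.0e7),
    stringsAsFactors = FALSE
  )
}

#' Generate an FPKM matrix with planted window effects
#'
#' Background genes get a gene-level log-normal baseline abundance
#' (`exp(baseline_meanlog + baseline_sdlog * Z)`) shared across samples,
#' multiplied by independent per-sample log-normal noise of standard
#' deviation `background_sd` (natural-log scale); a configurable fraction
#' of genes is exactly zero in every sample (genes not expressed at all,
#' exercising the normalization's zero fixed point).  Effect genes sit at
#' the typical baseline (`exp(baseline_meanlog)`) and have their value in
#' the contrast numerator sample multiplied by the true fold ratio, so
#' their expected contrast equals the planted fold change; with
#' `background_sd = 0` the ratio is exact.
#'
#' Annotation places each effect gene uniformly inside its declared
#' breakpoint window and every other gene in regions disjoint from all
#' windows, so a background gene can never fall inside a declared window.
#'
#' @param n_genes total genes (>= number of effects).
#' @param sample_names sample (column) names; defaults to the four
#'   culture time points of the model.
#' @param effects list of [effect_spec()]s with unique gene ids.
#' @param background_sd natural-log sd of per-sample noise (default 0.2,
#'   ~1.2-fold typical between-sample variation).
#' @param contrast length-2 `(numerator, denominator)` pair of sample names
#'   the fold changes apply to.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   gene-level baseline abundance (defaults `log(5)` and 1).
#' @param zero_fraction fraction of background genes set to exactly 0 in
#'   all samples (default 0.05).
#' @param gene_length annotated gene length in bp (default 20 kb).
#' @param seed integer seed fixing all randomness.
#' @return `list(fpkm = matrix, annotation = data.frame, truth = data.frame)`
#'   where `truth` has columns `gene_id`, `fold_change`, `window`.
#' @export
gen_expression_dataset <- function(n_genes,
                                   sample_names = c("BEC0W", "BEC20W",
                                                    "BEC40W", "BEC60W"),
                                   effects = list(),
                                   background_sd = 0.2,
                                   contrast = c("BEC40W", "BEC20W"),
                                   baseline_meanlog = log(5),
                                   baseline_sdlog = 1,
                                   zero_fraction = 0.05,
                                   gene_length = 2e4,
                                   seed) {
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  stopifnot(all(vapply(effects, inherits, logical(1), "effect_spec")),
            length(sample_names) >= 2L,
            all(contrast %in% sample_names),
            background_sd >= 0, zero_fraction >= 0, zero_fraction <= 1)
  eff_ids <- vapply(effects, `[[`, character(1), "gene_id")
  if (anyDuplicated(eff_ids)) stop("duplicate gene_id in effects")
  n_eff <- length(effects)
  if (n_genes < n_eff) stop("n_genes must be >= number of effects")
  withr::local_preserve_seed()
  set.seed(seed)

  n_bg <- n_genes - n_eff
  bg_ids <- sprintf("BG%05d", seq_len(n_bg))
  ids <- c(eff_ids, bg_ids)
  n_s <- length(sample_names)

  baseline <- c(rep(exp(baseline_meanlog), n_eff),
                exp(stats::rnorm(n_bg, baseline_meanlog, baseline_sdlog)))
  if (n_bg > 0 && zero_fraction > 0) {
    zero <- stats::runif(n_bg) < zero_fraction
    baseline[n_eff + which(zero)] <- 0
  }
  noise <- matrix(exp(stats::rnorm(n_genes * n_s, 0, background_sd)),
                  nrow = n_genes)
  m <- baseline * noise
  dimnames(m) <- list(ids, sample_names)
  for (e in effects) {
    ratio <- if (e$fold_change >= 0) e$fold_change else 1 / abs(e$fold_change)
    m[e$gene_id, contrast[1]] <- m[e$gene_id, contrast[1]] * ratio
  }

  windows <- default_windows()
  regions <- .background_regions()
  chrom <- character(n_genes); start <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    w <- if (i <= n_eff && effects[[i]]$window != "background") {
      windows[[effects[[i]]$window]]
    } else {
      r <- regions[((i - 1L) %% nrow(regions)) + 1L, ]
      list(chrom = r$chrom, start = r$start, end = r$end)
    }
    chrom[i] <- w$chrom
    start[i] <- floor(stats::runif(1, w$start, max(w$start + 1, w$end - gene_length)))
  }
  ann <- data.frame(gene_id = ids, chrom = chrom, start = start,
                    end = start + gene_length - 1, stringsAsFactors = FALSE)
  truth <- data.frame(
    gene_id = eff_ids,
    fold_change = vapply(effects, `[[`, numeric(1), "fold_change"),
    window = vapply(effects, `[[`, character(1), "window"),
    stringsAsFactors = FALSE
  )
  list(fpkm = m, annotation = ann, truth = truth)
}

#' Specify a mixture of FISH ground-truth nucleus states
#'
#' @param normal,gain,break_no_fusion,fusion state fractions; must sum to 1
#'   (tolerance 1e-9).
#' @param dropout_prob probability that any one true signal goes unobserved
#'   (section-truncation artifact).
#' @param spurious_overlap_prob probability that an unrelated red/green pair
#'   is miscounted as one co-localized signal.
#' @return A list of class `"fish_state_mix"`.
#' @export
fish_state_mix <- function(normal = 1, gain = 0, break_no_fusion = 0,
                           fusion = 0, dropout_prob = 0,
                           spurious_overlap_prob = 0) {
  fr <- c(normal = normal, gain = gain, break_no_fusion = break_no_fusion,
          fusion = fusion)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    stop("state fractions must be nonnegative and sum to 1")
  }
  pr <- c(dropout_prob, spurious_overlap_prob)
  if (any(pr < 0) || any(pr > 1)) stop("probabilities must be in [0, 1]")
  structure(list(fractions = fr, dropout_prob = dropout_prob,
                 spurious_overlap_prob = spurious_overlap_prob),
            class = "fish_state_mix")
}

#' Simulate per-nucleus FISH signal counts
#'
#' Each nucleus draws a ground-truth state from the mixture and emits
#' pre-noise counts: `normal` gives (2 red, 2 green, 0 fusion); `gain` adds
#' one extra signal of a random color; `break_no_fusion` gives 3 of one
#' color and 2 of the other; `fusion` starts from (2, 2) and, by default,
#' consumes one red and one green into the co-localized signal (so (1,1,1);
#' with `consume_parents = FALSE` the parental counts are kept, (2,2,1)).
#' Dropout then thins every signal independently, and each potential
#' red/green pair is converted to a spurious co-localized signal with the
#' stated probability.
#'
#' @param n_cells number of nuclei (>= 1).
#' @param mix a [fish_state_mix()].
#' @param seed integer seed fixing all randomness.
#' @param consume_parents whether the fused pair decrements both parental
#'   color counts (default `TRUE`).
#' @return `list(cells = data.frame(cell_index, red, green, fusion),
#'   truth = character vector of state labels aligned index-wise)`.
#' @export
gen_fish_cells <- function(n_cells, mix, seed, consume_parents = TRUE) {
  stopifnot(inherits(mix, "fish_state_mix"), n_cells >= 1L)
  withr::local_preserve_seed()
  set.seed(seed)
  states <- sample(names(mix$fractions), n_cells, replace = TRUE,
                   prob = mix$fractions)
  red <- rep(2L, n_cells); green <- rep(2L, n_cells)
  fus <- rep(0L, n_cells)

  extra_red <- stats::runif(n_cells) < 0.5      # color of extra/3rd signal
  is_gain <- states == "gain"
  red[is_gain] <- red[is_gain] + as.integer(extra_red[is_gain])
  green[is_gain] <- green[is_gain] + as.integer(!extra_red[is_gain])
  is_brk <- states == "break_no_fusion"
  red[is_brk] <- red[is_brk] + as.integer(extra_red[is_brk])
  green[is_brk] <- green[is_brk] + as.integer(!extra_red[is_brk])
  is_fus <- states == "fusion"
  fus[is_fus] <- 1L
  if (consume_parents) {
    red[is_fus] <- red[is_fus] - 1L
    green[is_fus] <- green[is_fus] - 1L
  }

  if (mix$dropout_prob > 0) {
    keep <- 1 - mix$dropout_prob
    red <- stats::rbinom(n_cells, red, keep)
    green <- stats::rbinom(n_cells, green, keep)
    fus <- stats::rbinom(n_cells, fus, keep)
  }
  if (mix$spurious_overlap_prob > 0) {
    k <- stats::rbinom(n_cells, pmin(red, green), mix$spurious_overlap_prob)
    red <- red - k; green <- green - k; fus <- fus + k
  }
  list(cells = data.frame(cell_index = seq_len(n_cells), red = red,
                          green = green, fusion = fus),
       truth = states)
}

#' Generate replicate karyotype strings with configurable penetrance
#'
#' Each replicate serializes the base karyotype; with probability
#' `penetrance` it additionally carries every aberration in `added` (the
#' modal count is adjusted by the net gain/loss count).  Output strings are
#' valid input for [parse_karyotype()].
#'
#' @param base a [karyotype()] object (or ISCN string).
#' @param added list of [aberration()]s acquired together by carriers.
#' @param penetrance carrier probability in `[0, 1]`.
#' @param n_replicates number of replicate strings.
#' @param seed integer seed (unused when `carriers` is given).
#' @param carriers optional logical vector of length `n_replicates`
#'   deterministically assigning carrier status (overrides `penetrance`
#'   sampling).
#' @return Character vector of ISCN strings with a logical `carriers`
#'   attribute.
#' @export
gen_karyotype_set <- function(base, added = list(), penetrance,
                              n_replicates, seed = NULL, carriers = NULL) {
  if (is.character(base)) base <- parse_karyotype(base)
  stopifnot(inherits(base, "karyotype"),
            all(vapply(added, inherits, logical(1), "aberration")),
            penetrance >= 0, penetrance <= 1, n_replicates >= 1L)
  if (is.null(carriers)) {
    if (is.null(seed)) stop("seed required when carriers is not given")
    withr::local_preserve_seed()
    set.seed(seed)
    carriers <- stats::runif(n_replicates) < penetrance
  }
  stopifnot(is.logical(carriers), length(carriers) == n_replicates)
  delta <- sum(vapply(added, function(a) {
    switch(a$kind, gain = 1L, loss = -1L, 0L)
  }, integer(1)))
  out <- vapply(carriers, function(carry) {
    k <- base
    if (carry) {
      k$aberrations <- c(k$aberrations, added)
      k$modal_count <- k$modal_count + delta
    }
    format_karyotype(k)
  }, character(1))
  attr(out, "carriers") <- carriers
  out
}
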