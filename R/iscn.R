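# ISCN karyotype dialect used by replicate karyotypes of acid/bile-exposed
# Barrett's epithelial cultures: modal count, sex field, and the structural
# aberrations add, i (isochromosome), dup, t (multi-way translocation),
# +n gain, -n loss.  Anything outside that dialect (der, ins, inv, mosaic
# "[n]", uncertain "?") is rejected with a token-level error rather than
# silently skipped.

.chrom_labels <- c(as.character(1:22), "X", "Y")
.band_regex <- "[pq][0-9]+(\\.[0-9]+)?"
.aberration_kinds <- c("gain", "loss", "add", "iso", "dup", "translocation")

#' Construct a chromosomal aberration
#'
#' An aberration is one token of a karyotype string: a whole-chromosome
#' gain (`+20`) or loss (`-Y`), additional material of unknown origin
#' (`add(4)(p16.1)`), an isochromosome (`i(8)(q10)`), a duplication span
#' (`dup(11)(q13q25)`), or a translocation over two or more chromosomes
#' (`t(2;10;16)(p22;q22;q22)`).
#'
#' @param kind one of `"gain"`, `"loss"`, `"add"`, `"iso"`, `"dup"`,
#'   `"translocation"`.
#' @param chromosomes character vector of chromosome labels (`"1"`..`"22"`,
#'   `"X"`, `"Y"`), ordered as written.
#' @param bands character vector of band addresses such as `"p22"` or
#'   `"q16.1"` (arm letter followed by digits, optionally one dot).  Empty
#'   for gain/loss; one entry for add/iso; two for dup (span ends); one per
#'   chromosome for a translocation.
#' @return An object of class `"aberration"`.
#' @examples
#' aberration("translocation", c("2", "10", "16"), c("p22", "q22", "q22"))
#' aberration("gain", "20")
#' @seealso [parse_aberration()], [match_aberration()]
#' @export
aberration <- function(kind, chromosomes, bands = character()) {
  kind <- match.arg(kind, .aberration_kinds)
  chromosomes <- as.character(chromosomes)
  bands <- as.character(bands)
  bad <- setdiff(chromosomes, .chrom_labels)
  if (length(bad)) {
    stop("invalid chromosome label(s): ", paste(sQuote(bad), collapse = ", "))
  }
  if (length(bands) &&
      !all(grepl(paste0("^", .band_regex, "$"), bands))) {
    stop("invalid band address(es): ",
         paste(sQuote(bands[!grepl(paste0("^", .band_regex, "$"), bands)]),
               collapse = ", "))
  }
  n_chr <- length(chromosomes)
  n_bnd <- length(bands)
  ok <- switch(kind,
    gain = ,
    loss = n_chr == 1L && n_bnd == 0L,
    add = ,
    iso = n_chr == 1L && n_bnd == 1L,
    dup = n_chr == 1L && n_bnd == 2L,
    translocation = n_chr >= 2L && n_bnd == n_chr
  )
  if (!ok) {
    stop("structural error: ", kind, " with ", n_chr, " chromosome(s) and ",
         n_bnd, " band(s)")
  }
  structure(list(kind = kind, chromosomes = chromosomes, bands = bands),
            class = "aberration")
}

#' Serialize one aberration to its ISCN token
#'
#' Inverse of [parse_aberration()].
#'
#' @param a an [aberration()] object.
#' @return A single ISCN token string, e.g. `"t(2;10;16)(p22;q22;q22)"`.
#' @export
format_aberration <- function(a) {
  stopifnot(inherits(a, "aberration"))
  switch(a$kind,
    gain = paste0("+", a$chromosomes),
    loss = paste0("-", a$chromosomes),
    add = sprintf("add(%s)(%s)", a$chromosomes, a$bands),
    iso = sprintf("i(%s)(%s)", a$chromosomes, a$bands),
    dup = sprintf("dup(%s)(%s%s)", a$chromosomes, a$bands[1], a$bands[2]),
    translocation = sprintf("t(%s)(%s)",
                            paste(a$chromosomes, collapse = ";"),
                            paste(a$bands, collapse = ";"))
  )
}

#' @export
print.aberration <- function(x, ...) {
  cat("<aberration> ", format_aberration(x), "\n", sep = "")
  invisible(x)
}

#' Parse one ISCN aberration token
#'
#' @param token a single token, e.g. `"add(4)(p16.1)"` or `"+20"`.
#'   Whitespace is ignored.
#' @param position optional 1-based field position used in error messages
#'   when parsing a full karyotype string.
#' @return An [aberration()] object.
#' @examples
#' parse_aberration("i(8)(q10)")
#' parse_aberration("dup(11)(q13q25)")
#' @export
parse_aberration <- function(token, position = NA_integer_) {
  stopifnot(is.character(token), length(token) == 1L)
  tok <- gsub("[[:space:]]", "", token)
  tok <- gsub("[−–]", "-", tok)  # unicode minus / en-dash
  where <- if (is.na(position)) "" else paste0(" at position ", position)
  chr_re <- "([0-9]+|X|Y)"
  b <- .band_regex

  if (grepl("^\\+", tok) || grepl("^-", tok)) {
    kind <- if (startsWith(tok, "+")) "gain" else "loss"
    lab <- substring(tok, 2L)
    if (!lab %in% .chrom_labels) {
      stop("unrecognized aberration token ", sQuote(token), where,
           ": ", sQuote(lab), " is not a chromosome label")
    }
    return(aberration(kind, lab))
  }
  m <- regmatches(tok, regexec(sprintf("^add\\(%s\\)\\((%s)\\)$", chr_re, b), tok))[[1]]
  if (length(m)) return(aberration("add", m[2], m[3]))
  m <- regmatches(tok, regexec(sprintf("^i\\(%s\\)\\((%s)\\)$", chr_re, b), tok))[[1]]
  if (length(m)) return(aberration("iso", m[2], m[3]))
  m <- regmatches(tok, regexec(sprintf("^dup\\(%s\\)\\((%s)(%s)\\)$", chr_re, b, b), tok))[[1]]
  if (length(m)) return(aberration("dup", m[2], c(m[3], m[5])))
  m <- regmatches(tok, regexec("^t\\(([0-9XY;]+)\\)\\(([pq0-9.;]+)\\)$", tok))[[1]]
  if (length(m)) {
    chroms <- strsplit(m[2], ";", fixed = TRUE)[[1]]
    bands <- strsplit(m[3], ";", fixed = TRUE)[[1]]
    if (length(chroms) < 2L || length(bands) != length(chroms)) {
      stop("structural error in ", sQuote(token), where, ": translocation needs ",
           ">= 2 chromosomes and one band per chromosome (got ",
           length(chroms), " and ", length(bands), ")")
    }
    return(aberration("translocation", chroms, bands))
  }
  stop("unrecognized aberration token ", sQuote(token), where)
}

#' Construct a karyotype
#'
#' @param modal_count integer chromosome count (>= 1).
#' @param sex_designation string over X/Y, e.g. `"XY"`. Stored verbatim; no
#'   consistency check against the modal count is applied, since published
#'   strings are not always internally consistent with strict ISCN rules.
#' @param aberrations list of [aberration()] objects, order preserved;
#'   repeated tokens (e.g. a doubled `+20`) are kept as distinct entries, so
#'   trisomy and tetrasomy remain distinguishable by gain multiplicity.
#' @return An object of class `"karyotype"`.
#' @export
karyotype <- function(modal_count, sex_designation, aberrations = list()) {
  modal_count <- as.integer(modal_count)
  if (is.na(modal_count) || modal_count < 1L) stop("modal_count must be >= 1")
  if (!is.character(sex_designation) || length(sex_designation) != 1L ||
      !grepl("^[XY]+$", sex_designation)) {
    stop("sex_designation must be a nonempty string over X and Y")
  }
  if (!is.list(aberrations) ||
      !all(vapply(aberrations, inherits, logical(1), "aberration"))) {
    stop("aberrations must be a list of aberration objects")
  }
  structure(list(modal_count = modal_count,
                 sex_designation = sex_designation,
                 aberrations = aberrations),
            class = "karyotype")
}

#' Parse an ISCN karyotype string
#'
#' Accepts the comma-separated dialect `"<modal>,<sex>,<tok>,<tok>,..."`,
#' e.g. `"48,XY,i(8)(q10),t(2;10;16)(p22;q22;q22),+20,+20"`.  Whitespace
#' around (or inside) tokens is ignored.  Unknown token forms raise an error
#' naming the token and its field position.
#'
#' @param text one ISCN string.
#' @return A [karyotype()] object.
#' @examples
#' parse_karyotype("47,XY,add(4)(p16.1),add(7)(p22),i(8)(q10),+20")
#' @export
parse_karyotype <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- gsub("[−–]", "-", text)
  raw <- gsub("[[:space:]]", "", raw)
  fields <- strsplit(raw, ",", fixed = TRUE)[[1]]
  if (length(fields) < 2L) {
    stop("karyotype must start with modal count and sex designation: ",
         sQuote(text))
  }
  modal <- suppressWarnings(as.integer(fields[1]))
  if (is.na(modal) || as.character(modal) != fields[1]) {
    stop("invalid modal count ", sQuote(fields[1]), " at position 1")
  }
  if (!grepl("^[XY]+$", fields[2])) {
    stop("invalid sex designation ", sQuote(fields[2]), " at position 2")
  }
  aberrations <- lapply(seq_along(fields)[-(1:2)], function(i) {
    parse_aberration(fields[i], position = i)
  })
  karyotype(modal, fields[2], aberrations)
}

#' Serialize a karyotype to ISCN text
#'
#' Round-trip identity: `parse_karyotype(format_karyotype(k))` equals `k`,
#' with aberration order preserved.
#'
#' @param k a [karyotype()] object.
#' @return A single ISCN string without whitespace.
#' @export
format_karyotype <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  parts <- c(as.character(k$modal_count), k$sex_designation,
             vapply(k$aberrations, format_aberration, character(1)))
  paste(parts, collapse = ",")
}

#' @export
print.karyotype <- function(x, ...) {
  cat("<karyotype> ", format_karyotype(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.karyotype <- function(x, ...) format_karyotype(x)

.major_band <- function(bands) sub("^([pq][0-9]).*$", "\\1", bands)

#' Compare two aberrations at a chosen band resolution
#'
#' Published replicate karyotypes can print the same recurrent event with
#' slightly different terminal bands (e.g. `q22` vs `q21` on the third
#' partner of a three-way translocation).  Rather than deciding whether such
#' variants are typographical, comparison is exposed at three resolutions:
#' `exact` (full band equality), `major_band` (arm plus first band digit, so
#' q21 and q22 both reduce to q2), and `chromosomes_only` (bands ignored).
#' Kind and the ordered chromosome list must always agree.
#'
#' The relation at each resolution is reflexive and symmetric, and matches
#' are nested: exact implies major_band implies chromosomes_only.
#'
#' @param a,b [aberration()] objects.
#' @param resolution `"exact"`, `"major_band"`, or `"chromosomes_only"`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' x <- parse_aberration("t(2;10;16)(p22;q22;q22)")
#' y <- parse_aberration("t(2;10;16)(p22;q22;q21)")
#' match_aberration(x, y, "exact")       # FALSE
#' match_aberration(x, y, "major_band")  # TRUE
#' @export
match_aberration <- function(a, b,
                             resolution = c("exact", "major_band",
                                            "chromosomes_only")) {
  stopifnot(inherits(a, "aberration"), inherits(b, "aberration"))
  resolution <- match.arg(resolution)
  if (a$kind != b$kind) return(FALSE)
  if (!identical(a$chromosomes, b$chromosomes)) return(FALSE)
  switch(resolution,
    chromosomes_only = TRUE,
    major_band = identical(.major_band(a$bands), .major_band(b$bands)),
    exact = identical(a$bands, b$bands)
  )
}

#' Mine a set of karyotypes for recurrent aberrations
#'
#' Groups aberrations across karyotypes by [match_aberration()] equivalence
#' at the given resolution.  A token repeated within one karyotype (e.g.
#' `+20,+20`) counts once toward that karyotype's membership in the group;
#' multiplicity is reported separately, so that e.g. "the chromosome-20 gain
#' is present in 6 of 6 replicates and doubled in 4 of them" can be read off
#' one row.
#'
#' @param karyotypes list of [karyotype()] objects, or a character vector of
#'   ISCN strings (parsed first).
#' @param min_count minimum number of karyotypes a group must appear in to
#'   be reported (>= 1).
#' @param resolution band resolution passed to [match_aberration()].
#' @return A data.frame with one row per recurrent group, sorted by
#'   descending `n_karyotypes` then by the serialized representative:
#'   `aberration` (first-seen representative token), `n_karyotypes`
#'   (karyotypes containing the event at least once), `n_karyotypes_multiple`
#'   (karyotypes containing it two or more times), `total_copies`.
#' @export
find_recurrent <- function(karyotypes, min_count = 1L,
                           resolution = c("exact", "major_band",
                                          "chromosomes_only")) {
  resolution <- match.arg(resolution)
  min_count <- as.integer(min_count)
  if (is.na(min_count) || min_count < 1L) stop("min_count must be >= 1")
  if (is.character(karyotypes)) karyotypes <- lapply(karyotypes, parse_karyotype)
  stopifnot(all(vapply(karyotypes, inherits, logical(1), "karyotype")))
  n_k <- length(karyotypes)
  empty <- data.frame(aberration = character(), n_karyotypes = integer(),
                      n_karyotypes_multiple = integer(),
                      total_copies = integer(), stringsAsFactors = FALSE)
  if (n_k == 0L) return(empty)

  reps <- list()                # group representatives, first seen
  counts <- list()              # per-group integer vector over karyotypes
  for (i in seq_len(n_k)) {
    for (ab in karyotypes[[i]]$aberrations) {
      hit <- 0L
      for (g in seq_along(reps)) {
        if (match_aberration(reps[[g]], ab, resolution)) { hit <- g; break }
      }
      if (hit == 0L) {
        reps[[length(reps) + 1L]] <- ab
        counts[[length(counts) + 1L]] <- integer(n_k)
        hit <- length(reps)
      }
      counts[[hit]][i] <- counts[[hit]][i] + 1L
    }
  }
  if (!length(reps)) return(empty)
  out <- data.frame(
    aberration = vapply(reps, format_aberration, character(1)),
    n_karyotypes = vapply(counts, function(x) sum(x > 0L), integer(1)),
    n_karyotypes_multiple = vapply(counts, function(x) sum(x >= 2L), integer(1)),
    total_copies = vapply(counts, sum, integer(1)),
    stringsAsFactors = FALSE
  )
  out <- out[out$n_karyotypes >= min_count, , drop = FALSE]
  out <- out[order(-out$n_karyotypes, out$aberration), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Multiset difference between two karyotypes
#'
#' Matches aberrations of `a` against those of `b` greedily under
#' [match_aberration()] at the given resolution (each aberration consumed at
#' most once).  Unmatched aberrations of `b` are `gained`, unmatched
#' aberrations of `a` are `lost`; `diff_karyotypes(k, k)` is empty.
#'
#' @param a,b [karyotype()] objects (or ISCN strings).
#' @param resolution band resolution passed to [match_aberration()].
#' @return `list(gained = , lost = )`, each a list of [aberration()]s sorted
#'   by their serialization.
#' @export
diff_karyotypes <- function(a, b,
                            resolution = c("exact", "major_band",
                                           "chromosomes_only")) {
  resolution <- match.arg(resolution)
  if (is.character(a)) a <- parse_karyotype(a)
  if (is.character(b)) b <- parse_karyotype(b)
  stopifnot(inherits(a, "karyotype"), inherits(b, "karyotype"))
  A <- a$aberrations
  B <- b$aberrations
  used_b <- rep(FALSE, length(B))
  lost <- list()
  for (ab in A) {
    hit <- 0L
    for (j in seq_along(B)) {
      if (!used_b[j] && match_aberration(ab, B[[j]], resolution)) { hit <- j; break }
    }
    if (hit > 0L) used_b[hit] <- TRUE else lost[[length(lost) + 1L]] <- ab
  }
  gained <- B[!used_b]
  sort_ab <- function(xs) xs[order(vapply(xs, format_aberration, character(1)))]
  list(gained = sort_ab(gained), lost = sort_ab(lost))
}
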