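# End-to-end orchestration: simulate -> karyotype recurrence -> FISH calls
# -> breakpoint-window expression screen -> structured report.

#' Default demo configuration
#'
#' One self-contained parameterization of the whole pipeline, emulating the
#' study design: six replicate exposed cultures of which four acquire the
#' three-way t(2;10;16) translocation plus a second chromosome-20 gain;
#' tumor and benign samples screened over the three breakpoint probe sets
#' with fusions confined to the 2p22/16q22 pairing; and an FPKM matrix over
#' four culture time points with six effects planted inside the breakpoint
#' windows for the BEC40W vs BEC20W contrast.
#'
#' @param seed integer master seed; every stage seed derives from it.
#' @return Nested configuration list; YAML-serializable.
#' @export
demo_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    karyotype = list(
      base = "47,XY,add(4)(p16.1),add(7)(p22),i(8)(q10),+20",
      added = c("t(2;10;16)(p22;q22;q22)", "+20"),
      n_replicates = 6L,
      n_carriers = 4L,
      resolution = "major_band",
      min_count = 2L
    ),
    fish = list(
      n_cells = 60L,
      min_cells = 25L,
      min_fusion_cells = 2L,
      positive_samples = c("EAC_1", "EAC_2"),
      negative_samples = c("BE_1", "BE_2"),
      fusion_probe_set = "set1",
      fusion_fraction = 0.3,
      break_fraction = 0.2,
      dropout_prob = 0.02,
      spurious_overlap_prob = 0
    ),
    expression = list(
      n_genes = 400L,
      background_sd = 0.2,
      contrast = c("BEC40W", "BEC20W"),
      fc_threshold = 2,
      alpha = 0.025,
      mode = "shifted",
      effects = list(
        list(gene_id = "EFF_2P22_UP", fold_change = 4, window = "2p22"),
        list(gene_id = "EFF_2P22_DN", fold_change = -6, window = "2p22"),
        list(gene_id = "EFF_10Q22_UP", fold_change = 8, window = "10q22"),
        list(gene_id = "EFF_10Q22_DN", fold_change = -3, window = "10q22"),
        list(gene_id = "EFF_16Q22_UP", fold_change = 10, window = "16q22"),
        list(gene_id = "EFF_16Q22_DN", fold_change = -5, window = "16q22")
      )
    )
  )
}

#' Run the full synthetic demo pipeline
#'
#' Generates synthetic data from the configuration seed, runs the three
#' analysis stages (karyotype recurrence mining, FISH sample calling,
#' breakpoint-window expression screen), compares results against the
#' planted ground truth, and returns a structured report.  Identical seed
#' and configuration give an identical report.  A failure in any stage
#' aborts with a stage-tagged error and removes any partially written
#' output files.
#'
#' @param config configuration list as from [demo_config()], or a path to a
#'   YAML file holding one.
#' @param out_dir optional directory; when given, writes `report.json`,
#'   `karyotypes.txt`, `recurrent_aberrations.tsv`, `fish_calls.tsv`, and
#'   `candidate_genes.tsv` there.
#' @return The report list, invisibly when `out_dir` is given.
#' @export
run_demo <- function(config = demo_config(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  written <- character()
  run <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      if (length(written)) unlink(written)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  seeds <- withr::with_seed(config$seed,
                            sample.int(.Machine$integer.max - 1L, 40L))

  # -- karyotypes ----------------------------------------------------------
  kary <- run("karyotype", function() {
    kc <- config$karyotype
    added <- lapply(kc$added, parse_aberration)
    carriers <- rep(FALSE, kc$n_replicates)
    carriers[seq_len(kc$n_carriers)] <- TRUE
    strings <- gen_karyotype_set(kc$base, added,
                                 penetrance = kc$n_carriers / kc$n_replicates,
                                 n_replicates = kc$n_replicates,
                                 carriers = carriers)
    list(
      replicates = data.frame(replicate_id = seq_along(strings),
                              condition = "exposed", iscn = as.character(strings),
                              stringsAsFactors = FALSE),
      recurrent = find_recurrent(as.character(strings),
                                 min_count = kc$min_count,
                                 resolution = kc$resolution),
      carriers = carriers
    )
  })

  # -- FISH ----------------------------------------------------------------
  fish <- run("fish", function() {
    fc <- config$fish
    sets <- default_probe_sets()$id
    samples <- c(fc$positive_samples, fc$negative_samples)
    truth_positive <- samples %in% fc$positive_samples
    i <- 0L
    tabs <- list()
    for (s in samples) {
      for (ps in sets) {
        i <- i + 1L
        carries_fusion <- s %in% fc$positive_samples && ps == fc$fusion_probe_set
        mix <- if (carries_fusion) {
          fish_state_mix(normal = 1 - fc$fusion_fraction - fc$break_fraction,
                         break_no_fusion = fc$break_fraction,
                         fusion = fc$fusion_fraction,
                         dropout_prob = fc$dropout_prob,
                         spurious_overlap_prob = fc$spurious_overlap_prob)
        } else {
          fish_state_mix(normal = 1, dropout_prob = fc$dropout_prob,
                         spurious_overlap_prob = fc$spurious_overlap_prob)
        }
        g <- gen_fish_cells(fc$n_cells, mix, seed = seeds[5L + i])
        tabs[[i]] <- data.frame(sample_id = s, probe_set = ps, g$cells,
                                stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(rbind, tabs)
    list(counts = counts,
         calls = screen_probe_sets(counts, min_cells = fc$min_cells,
                                   min_fusion_cells = fc$min_fusion_cells),
         truth = data.frame(sample_id = samples, fusion_truth = truth_positive,
                            stringsAsFactors = FALSE))
  })

  # -- expression ----------------------------------------------------------
  expr <- run("expression", function() {
    ec <- config$expression
    effects <- lapply(ec$effects, function(e) {
      effect_spec(e$gene_id, e$fold_change, e$window)
    })
    ds <- gen_expression_dataset(n_genes = ec$n_genes, effects = effects,
                                 background_sd = ec$background_sd,
                                 contrast = ec$contrast, seed = seeds[2L])
    norm <- log_normalize(ds$fpkm)
    cand <- candidate_genes(norm, ds$annotation, default_windows(),
                            contrast = ec$contrast,
                            fc_threshold = ec$fc_threshold,
                            alpha = ec$alpha, mode = ec$mode)
    tracks <- lapply(c("2", "10", "16"), function(ch) {
      chromosome_landscape(norm, ds$annotation, ch, ec$contrast,
                           mode = ec$mode)
    })
    names(tracks) <- c("chr2", "chr10", "chr16")
    list(candidates = cand, landscape = tracks, truth = ds$truth)
  })

  metrics <- run("metrics", function() {
    planted <- expr$truth[expr$truth$window != "background", , drop = FALSE]
    rec <- expr$candidates[match(planted$gene_id, expr$candidates$gene_id), ]
    passing <- !is.na(rec$passes) & rec$passes
    fish_calls <- fish$calls
    fp_set <- config$fish$fusion_probe_set
    fusion_rows <- fish_calls[fish_calls$probe_set == fp_set, ]
    tp <- fish$truth$fusion_truth[match(fusion_rows$sample_id,
                                        fish$truth$sample_id)]
    list(
      expression_sensitivity = if (nrow(planted)) mean(passing) else NA_real_,
      expression_sign_agreement = if (any(passing)) {
        mean(sign(rec$fc[passing]) == sign(planted$fold_change[passing]))
      } else NA_real_,
      n_background_candidates_passing =
        sum(expr$candidates$passes[!expr$candidates$gene_id %in%
                                     planted$gene_id]),
      fish_positive_rate_true_samples =
        if (any(tp)) mean(fusion_rows$call[tp] == "positive") else NA_real_,
      fish_negative_rate_null_samples =
        if (any(!tp)) mean(fusion_rows$call[!tp] == "negative") else NA_real_,
      karyotype_translocation_replicates =
        local({
          r <- kary$recurrent
          hit <- grepl("^t\\(", r$aberration)
          if (any(hit)) max(r$n_karyotypes[hit]) else 0L
        })
    )
  })

  report <- list(parameters = config,
                 karyotype = kary[c("replicates", "recurrent")],
                 fish = fish[c("calls", "truth")],
                 expression = expr[c("candidates", "truth")],
                 metrics = metrics)

  if (!is.null(out_dir)) {
    run("write", function() {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      p <- function(f) file.path(out_dir, f)
      written <<- c(written, p("karyotypes.txt"))
      write_karyotype_file(kary$replicates, p("karyotypes.txt"))
      tsv <- function(df, f) {
        written <<- c(written, p(f))
        utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                           row.names = FALSE)
      }
      tsv(kary$recurrent, "recurrent_aberrations.tsv")
      tsv(fish$calls, "fish_calls.tsv")
      tsv(expr$candidates, "candidate_genes.tsv")
      written <<- c(written, p("report.json"))
      jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    })
    return(invisible(report))
  }
  report
}

#' Validate pipeline input files
#'
#' Checks each file against its declared format and reports per-file
#' pass/fail with the first offending line.  Never raises on unreadable or
#' malformed input and never mutates files.
#'
#' @param paths character vector of file paths.
#' @param formats character vector (recycled) over `"fpkm_tsv"`, `"bed"`,
#'   `"fish_csv"`, `"karyotype_txt"`.
#' @return data.frame `path`, `format`, `ok`, `detail`.
#' @export
validate_inputs <- function(paths, formats) {
  formats <- rep_len(formats, length(paths))
  ok_fmt <- c("fpkm_tsv", "bed", "fish_csv", "karyotype_txt")
  rows <- lapply(seq_along(paths), function(i) {
    fmt <- formats[i]
    detail <- tryCatch({
      if (!fmt %in% ok_fmt) stop("unknown format ", sQuote(fmt))
      if (!file.exists(paths[i])) stop("file does not exist")
      switch(fmt,
             fpkm_tsv = .validate_fpkm_tsv(paths[i]),
             bed = .validate_bed(paths[i]),
             fish_csv = .validate_fish_csv(paths[i]),
             karyotype_txt = .validate_karyotype_txt(paths[i]))
    }, error = function(e) conditionMessage(e))
    data.frame(path = paths[i], format = fmt, ok = is.null(detail),
               detail = if (is.null(detail)) "" else detail,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.validate_fpkm_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  if (ncol(df) < 2L) return("needs a gene-id column plus >= 1 sample column")
  if (anyDuplicated(df[[1]])) {
    return(paste0("line ", which(duplicated(df[[1]]))[1] + 1L,
                  ": duplicate gene id"))
  }
  vals <- suppressWarnings(
    vapply(df[-1], function(x) as.numeric(as.character(x)),
           numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df))
  bad <- which(apply(vals, 1, function(x) anyNA(x) || any(x < 0)))
  if (length(bad)) {
    return(paste0("line ", bad[1] + 1L, ": non-numeric or negative value"))
  }
  NULL
}

.validate_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE)
  if (ncol(df) < 3L) return("BED needs >= 3 columns")
  start <- suppressWarnings(as.numeric(df[[2]]))
  end <- suppressWarnings(as.numeric(df[[3]]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    return(paste0("line ", bad[1],
                  ": BED records are 0-based half-open and need start < end"))
  }
  NULL
}

.validate_fish_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("sample_id", "probe_set", "red", "green", "fusion")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    return(paste("missing column(s):", paste(missing, collapse = ", ")))
  }
  counts <- suppressWarnings(
    cbind(as.numeric(df$red), as.numeric(df$green), as.numeric(df$fusion)))
  bad <- which(apply(counts, 1, function(x) {
    anyNA(x) || any(x < 0) || any(x != floor(x))
  }))
  if (length(bad)) {
    return(paste0("line ", bad[1] + 1L,
                  ": signal counts must be nonnegative integers"))
  }
  NULL
}

.validate_karyotype_txt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    if (!nzchar(lines[i])) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 3L) {
      return(paste0("line ", i, ": expected replicate_id<TAB>condition<TAB>ISCN"))
    }
    msg <- tryCatch({ parse_karyotype(fields[3]); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(msg)) return(paste0("line ", i, ": ", msg))
  }
  NULL
}

#' Check a demo report against the shipped structural schema
#'
#' A lightweight structural validator over the schema at
#' `inst/schema/demo_report_schema.json`: required top-level sections,
#' their kinds (object / table / scalar list), and required table columns.
#'
#' @param report a report list from [run_demo()].
#' @param schema_path path to the schema JSON (default: the shipped one).
#' @return Character vector of problems; `character(0)` when the report
#'   conforms.
#' @export
validate_report <- function(report,
                            schema_path = system.file(
                              "schema", "demo_report_schema.json",
                              package = "karyoscreen")) {
  schema <- jsonlite::read_json(schema_path)
  problems <- character()
  check <- function(node, spec, path) {
    for (nm in unlist(spec$required)) {
      if (!nm %in% names(node)) {
        problems <<- c(problems, paste0(path, ": missing required ", sQuote(nm)))
      }
    }
    for (nm in names(spec$properties)) {
      if (!nm %in% names(node)) next
      sub <- spec$properties[[nm]]
      val <- node[[nm]]
      kind <- sub$kind
      sp <- paste0(path, "$", nm)
      if (identical(kind, "table")) {
        if (!is.data.frame(val)) {
          problems <<- c(problems, paste0(sp, ": expected a table"))
        } else {
          miss <- setdiff(unlist(sub$columns), names(val))
          if (length(miss)) {
            problems <<- c(problems, paste0(sp, ": missing column(s) ",
                                            paste(miss, collapse = ", ")))
          }
        }
      } else if (identical(kind, "object")) {
        if (!is.list(val)) {
          problems <<- c(problems, paste0(sp, ": expected an object"))
        } else {
          check(val, sub, sp)
        }
      }
    }
  }
  check(report, schema, "report")
  problems
}
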