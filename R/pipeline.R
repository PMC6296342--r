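#' Write a simulated cohort to disk as plain-text files
#'
#' Emits `betas.tsv`, `detection_p.tsv`, `beadcounts.tsv`, `phenotypes.csv`
#' (without the latent moderator), `annotation.tsv`, `reference.tsv`,
#' `locus_list.txt` and `truth.json` into `dir`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation_bundle <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(cohort$betas, p("betas.tsv"))
  readr::write_tsv(cohort$detection_p, p("detection_p.tsv"))
  readr::write_tsv(cohort$beadcounts, p("beadcounts.tsv"))
  readr::write_csv(dplyr::select(cohort$phenotypes, -"latent_mmthfr"),
                   p("phenotypes.csv"))
  readr::write_tsv(cohort$annotation, p("annotation.tsv"))
  readr::write_tsv(cohort$reference, p("reference.tsv"))
  writeLines(cohort$locus_list, p("locus_list.txt"))
  jsonlite::write_json(list(
    loci = cohort$truth$loci,
    latent = cohort$truth$latent,
    mmthfr_probes = cohort$mmthfr_probes
  ), p("truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

read_numeric_tsv <- function(path, what) {
  if (!file.exists(path)) abort(sprintf("Missing input file: %s", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  prob <- readr::problems(x)
  if (nrow(prob)) {
    abort(sprintf("Parse error in %s at row %d, column %d: expected %s.",
                  path, prob$row[1], prob$col[1], prob$expected[1]))
  }
  if (names(x)[1] != "probe_id") {
    abort(sprintf("%s must have `probe_id` as its first column.", path))
  }
  bad <- !vapply(x[-1], is.numeric, logical(1))
  if (any(bad)) {
    abort(sprintf("%s: non-numeric sample column(s): %s.", what,
                  paste(names(x)[-1][bad], collapse = ", ")))
  }
  x
}

#' Load and cross-validate pipeline inputs from disk
#'
#' Reads the beta matrix, optional detection p-value/beadcount matrices, the
#' phenotype table, optional probe annotation, cell reference and locus list,
#' and checks that sample identifiers align and that the locus list is a
#' subset of the probes.
#'
#' @param paths Named list of file paths: `betas` and `phenotypes`
#'   (required); `detection_p`, `beadcounts`, `annotation`, `reference`,
#'   `locus_list` (optional).
#' @return A list with the loaded tibbles (`NULL` where not supplied) and
#'   `locus_list` (character or `NULL`), suitable for [run_pipeline()].
#' @export
load_inputs <- function(paths) {
  if (is.null(paths$betas) || is.null(paths$phenotypes)) {
    abort("`paths` must name at least `betas` and `phenotypes`.")
  }
  betas <- read_numeric_tsv(paths$betas, "betas")
  if (!file.exists(paths$phenotypes)) {
    abort(sprintf("Missing input file: %s", paths$phenotypes))
  }
  pheno <- readr::read_csv(paths$phenotypes, show_col_types = FALSE,
                           progress = FALSE)
  samples <- setdiff(names(betas), "probe_id")
  missing_ph <- setdiff(samples, pheno$sample_id)
  extra_ph <- setdiff(pheno$sample_id, samples)
  if (length(missing_ph) || length(extra_ph)) {
    abort(sprintf(
      "Sample identifiers disagree between betas and phenotypes.%s%s",
      if (length(missing_ph)) sprintf(" Missing from phenotypes: %s.",
                                      paste(missing_ph, collapse = ", ")) else "",
      if (length(extra_ph)) sprintf(" Missing from betas: %s.",
                                    paste(extra_ph, collapse = ", ")) else ""))
  }
  pheno <- pheno[match(samples, pheno$sample_id), , drop = FALSE]
  opt_tsv <- function(key) {
    if (is.null(paths[[key]])) return(NULL)
    read_numeric_tsv(paths[[key]], key)
  }
  annotation <- NULL
  if (!is.null(paths$annotation)) {
    if (!file.exists(paths$annotation)) {
      abort(sprintf("Missing input file: %s", paths$annotation))
    }
    annotation <- readr::read_tsv(paths$annotation, show_col_types = FALSE,
                                  progress = FALSE)
  }
  locus_list <- NULL
  if (!is.null(paths$locus_list)) {
    if (!file.exists(paths$locus_list)) {
      abort(sprintf("Missing input file: %s", paths$locus_list))
    }
    locus_list <- readLines(paths$locus_list)
    absent <- setdiff(locus_list, betas$probe_id)
    if (length(absent)) {
      abort(sprintf("Locus list has %d probes absent from betas (e.g. %s).",
                    length(absent), absent[1]))
    }
  }
  list(
    betas = betas,
    detection_p = opt_tsv("detection_p"),
    beadcounts = opt_tsv("beadcounts"),
    phenotypes = pheno,
    annotation = annotation,
    reference = opt_tsv("reference"),
    locus_list = locus_list
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full moderation analysis pipeline
#'
#' Stages, in order: sample/probe QC (when detection p-values or beadcounts
#' are present) -> quantile normalization -> boundary squeeze -> cell-type
#' deconvolution (only when the phenotype table lacks cell-fraction columns
#' and a reference is supplied) -> moderator index construction -> per-locus
#' interaction scan -> classification -> contingency table and chi-square ->
#' outcome indices -> covariate-adjusted index models -> simple slopes.
#'
#' @param inputs A list as returned by [load_inputs()] or
#'   [simulate_cohort()]: `betas`, `phenotypes`, and optionally
#'   `detection_p`, `beadcounts`, `annotation`, `reference`, `locus_list`,
#'   `mmthfr_probes`.
#' @param alpha Significance level for classification.
#' @param tier Interaction p-value tier used to classify loci (`"nominal"`,
#'   `"bonferroni"` or `"bh"`).
#' @param smoking_measure `"status"` or `"consumption"`.
#' @param mmthfr_probes Probe ids of the moderator index; defaults to
#'   `inputs$mmthfr_probes`, else probes annotated with gene `"MTHFR"`.
#' @param normalize Run quantile normalization?
#' @return A `pipeline_report` list: `qc`, `index_definitions`,
#'   `scan_counts`, `contingency` (counts, percentages, chi-square,
#'   sign-concordant fraction), `index_models` (term tables), `simple_slopes`,
#'   `alpha`, `tier`, `smoking_measure`, `config_hash`, plus the underlying
#'   `scan`, `classification` and `pheno` for further work.
#' @export
run_pipeline <- function(inputs, alpha = 0.05,
                         tier = c("nominal", "bonferroni", "bh"),
                         smoking_measure = c("status", "consumption"),
                         mmthfr_probes = NULL, normalize = TRUE) {
  tier <- match.arg(tier)
  smoking_measure <- match.arg(smoking_measure)
  betas <- stage("load", {
    assert_beta_tbl(inputs$betas)
    inputs$betas
  })
  pheno <- inputs$phenotypes
  qc_log <- list()

  if (!is.null(inputs$detection_p)) {
    betas <- stage("sample_qc", filter_samples(betas, inputs$detection_p))
    qc_log$samples <- qc_report(betas)
    pheno <- pheno[pheno$sample_id %in% sample_cols(betas), , drop = FALSE]
  }
  if (!is.null(inputs$beadcounts) || !is.null(inputs$detection_p)) {
    betas <- stage("probe_qc",
                   filter_probes(betas, inputs$beadcounts, inputs$detection_p))
    qc_log$probes <- qc_report(betas)
  }
  if (normalize) {
    betas <- stage("normalize", quantile_normalize(betas, inputs$annotation))
  }
  n_samples <- length(sample_cols(betas))
  betas_sq <- stage("squeeze", {
    m <- beta_values(betas)
    out <- matrix_to_beta_tbl(squeeze_unit_interval(m, n_samples))
    out$probe_id <- betas$probe_id
    out
  })

  cells <- c("cd8t", "cd4t", "nk", "bcell", "mono")
  if (!all(cells %in% names(pheno))) {
    if (is.null(inputs$reference)) {
      abort("Pipeline stage 'deconvolve' failed: phenotypes lack cell fractions and no reference was supplied.")
    }
    frac <- stage("deconvolve", {
      common <- intersect(inputs$reference$probe_id, betas_sq$probe_id)
      if (length(common) < ncol(inputs$reference) - 1L) {
        abort("Too few reference probes present in the beta matrix.")
      }
      estimate_cell_fractions(betas_sq,
                              inputs$reference[inputs$reference$probe_id %in% common, ])
    })
    pheno <- dplyr::left_join(pheno, frac, by = "sample_id")
  }

  mmthfr_probes <- mmthfr_probes %||% inputs$mmthfr_probes %||% {
    if (!is.null(inputs$annotation)) {
      inputs$annotation$probe_id[inputs$annotation$gene == "MTHFR"]
    } else NULL
  }
  if (is.null(mmthfr_probes) || length(mmthfr_probes) == 0L) {
    abort("Pipeline stage 'moderator_index' failed: no moderator probes identified.")
  }
  mmthfr_probes <- intersect(mmthfr_probes, betas$probe_id)
  idx <- stage("moderator_index",
               build_index(betas, mmthfr_probes, name = "mmthfr"))
  pheno <- dplyr::left_join(dplyr::select(pheno, -dplyr::any_of("mmthfr")),
                            idx, by = "sample_id")

  locus_list <- inputs$locus_list %||%
    setdiff(betas$probe_id, mmthfr_probes)
  locus_list <- intersect(locus_list, betas_sq$probe_id)
  pheno <- pheno[match(sample_cols(betas_sq), pheno$sample_id), , drop = FALSE]
  scan <- stage("scan",
                scan_loci(betas_sq, pheno, locus_list, smoking_measure, alpha))
  classification <- stage("classify", classify_interactions(scan, alpha, tier))
  counts <- attr(classification, "counts")
  ctab <- stage("contingency", contingency_from_classification(classification))
  chi <- if (sum(counts) > 0 && all(rowSums(unclass(ctab)) > 0) &&
             all(colSums(unclass(ctab)) > 0)) pearson_chi2(ctab) else NULL
  props <- if (sum(counts) > 0) row_proportions(ctab) else NULL
  concordant <- if (sum(counts) > 0) {
    unname((counts["hyper_neg"] + counts["hypo_pos"]) / sum(counts))
  } else NA_real_

  indices <- stage("outcome_indices",
                   suppressWarnings(build_outcome_indices(betas, classification)))
  models <- list()
  slopes <- list()
  for (which in c("hypo", "hyper")) {
    ix <- indices[[which]]
    if (is.null(ix)) next
    m1 <- stage("index_models",
                moderated_index_regression(ix, pheno, smoking_measure, FALSE))
    m2 <- stage("index_models",
                moderated_index_regression(ix, pheno, smoking_measure, TRUE))
    models[[which]] <- list(model1 = tidy(m1), model2 = tidy(m2),
                            r_squared = c(model1 = m1$r_squared,
                                          model2 = m2$r_squared))
    slopes[[which]] <- stage("simple_slopes",
                             simple_slopes(m2, sd(pheno$mmthfr)))
  }

  report <- list(
    qc = lapply(qc_log, function(r) list(counts = r$counts,
                                         removals = r$removals)),
    index_definitions = list(mmthfr = mmthfr_probes,
                             hypo = indices$definitions$hypo,
                             hyper = indices$definitions$hyper),
    scan_counts = list(
      n_scanned = nrow(scan),
      n_converged = sum(scan$model1_converged & scan$model2_converged),
      n_classified = sum(counts),
      by_class = as.list(counts)
    ),
    contingency = list(
      counts = as.list(counts),
      row_percentages = props,
      chi_square = chi,
      sign_concordant_fraction = concordant
    ),
    index_models = models,
    simple_slopes = slopes,
    alpha = alpha, tier = tier, smoking_measure = smoking_measure,
    n_samples = n_samples,
    config_hash = rlang::hash(list(alpha, tier, smoking_measure,
                                   mmthfr_probes, locus_list)),
    scan = scan,
    classification = classification,
    pheno = pheno
  )
  class(report) <- "pipeline_report"
  report
}

#' Serialize a pipeline report to JSON
#'
#' Floating-point values are written with 6 significant digits; counts stay
#' integers. The heavyweight `scan`, `classification` and `pheno` components
#' are omitted (export the scan with [readr::write_tsv()] instead).
#'
#' @param report A [run_pipeline()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  keep <- setdiff(names(report), c("scan", "classification", "pheno"))
  jsonlite::write_json(report[keep], path, auto_unbox = TRUE, digits = I(6),
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Moderation pipeline report (%s, tier %s, alpha %g)\n",
              x$smoking_measure, x$tier, x$alpha))
  cat(sprintf("Scanned %d loci; %d classified (hyper-:%d hyper+:%d hypo+:%d hypo-:%d)\n",
              x$scan_counts$n_scanned, x$scan_counts$n_classified,
              x$scan_counts$by_class$hyper_neg, x$scan_counts$by_class$hyper_pos,
              x$scan_counts$by_class$hypo_pos, x$scan_counts$by_class$hypo_neg))
  if (!is.null(x$contingency$chi_square)) {
    cat(sprintf("Sign-consistency chi-square(1) = %.3f, log10 p = %.2f; concordant fraction %.3f\n",
                x$contingency$chi_square$statistic,
                x$contingency$chi_square$log10_p,
                x$contingency$sign_concordant_fraction))
  }
  invisible(x)
}
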