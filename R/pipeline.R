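# End-to-end orchestration: simulate (or read) -> TPM -> cascade ->
# annotate -> report, with an echoed config and a machine-readable summary.

#' Pipeline run configuration
#'
#' Collects everything one reproducible run needs: either paths to counts /
#' lengths / design TSVs, or simulation parameters; cascade threshold
#' overrides; optional annotation and edge tables; the output directory and
#' the root seed governing all stochastic stages.
#'
#' @param out_dir Output directory for all results.
#' @param seed Integer root seed.
#' @param counts_path,lengths_path,design_path Input TSVs (all three, or
#'   none to simulate).
#' @param simulate Named list of arguments for [simulate_study()] (used when
#'   no input paths are given; an empty list uses its defaults).
#' @param cascade Named list of [cascade_config()] overrides; unknown keys
#'   are errors.
#' @param annotations_path Optional annotation TSV (see
#'   [read_annotations()]).
#' @param edges_path,focus_gene Optional edge TSV and focal gene for a
#'   neighborhood report.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1,
                       counts_path = NULL, lengths_path = NULL,
                       design_path = NULL,
                       simulate = list(),
                       cascade = list(),
                       annotations_path = NULL,
                       edges_path = NULL, focus_gene = NULL) {
  paths <- c(!is.null(counts_path), !is.null(lengths_path),
             !is.null(design_path))
  if (any(paths) && !all(paths)) {
    stop("provide counts_path, lengths_path and design_path together",
         call. = FALSE)
  }
  if (!is.list(simulate) || !is.list(cascade)) {
    stop("simulate and cascade must be named lists", call. = FALSE)
  }
  if (length(simulate) > 0) {
    unknown <- setdiff(names(simulate), names(formals(simulate_study)))
    if (length(unknown) > 0) {
      stop(sprintf("unknown simulate key(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         counts_path = counts_path, lengths_path = lengths_path,
         design_path = design_path, simulate = simulate,
         cascade = cascade, annotations_path = annotations_path,
         edges_path = edges_path, focus_gene = focus_gene),
    class = "run_config"
  )
}

# Flat key=value echo of the effective configuration.
serialize_config <- function(config, cascade_cfg) {
  sim_part <- if (length(config$simulate) > 0) {
    stats::setNames(config$simulate,
                    paste0("simulate.", names(config$simulate)))
  } else {
    list()
  }
  flat <- c(
    list(seed = config$seed, out_dir = config$out_dir),
    unclass(cascade_cfg),
    sim_part
  )
  paste0(names(flat), "=", vapply(flat, function(v) paste(format(v),
                                                          collapse = ","),
                                  character(1)))
}

#' Run the whole contact-normalization pipeline
#'
#' Executes simulate (or read) -> TPM normalization -> classification
#' cascade -> optional annotation summaries, writing into the configured
#' output directory: the effective config (`config.txt`), the per-gene
#' classification (`classification.tsv`), the onion summary
#' (`summary.json` with fields detected, expressed, src_up, src_down,
#' reversed_up, reversed_down, dependent_up, dependent_down), and — when
#' available — the recovery report (`recovery.tsv`), location contingency
#' (`locations.tsv`), and neighborhood report (`neighborhood.tsv`). Any
#' stage failure aborts the run, removes partial outputs, and names the
#' stage.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the cascade result, the onion summary,
#'   the recovery report (or `NULL`), and the output paths.
#' @export
#' @examples
#' cfg <- run_config(out_dir = tempfile(), seed = 1,
#'                   simulate = list(n_genes = 100))
#' res <- run_all(cfg)
#' res$summary
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  note <- function(p) {
    written <<- c(written, p)
    p
  }
  stage <- "setup"
  result <- tryCatch({
    cascade_cfg <- apply_config_overrides(cascade_config(), config$cascade)
    writeLines(serialize_config(config, cascade_cfg),
               note(file.path(config$out_dir, "config.txt")))

    truth <- NULL
    if (is.null(config$counts_path)) {
      stage <- "simulate"
      sim_args <- modifyList(list(seed = config$seed), config$simulate)
      sim <- do.call(simulate_study, sim_args)
      message(sprintf("[simulate] %d genes x %d samples, seed %d",
                      nrow(sim$counts), nrow(sim$design), config$seed))
      for (p in write_simulation(sim, file.path(config$out_dir, "inputs"))) {
        note(p)
      }
      expression <- sim$counts
      design <- sim$design
      truth <- sim$truth
    } else {
      stage <- "read"
      inputs <- read_expression(config$counts_path, config$lengths_path,
                                config$design_path)
      expression <- inputs$expression
      design <- inputs$design
      message(sprintf("[read] %d genes x %d samples",
                      nrow(expression), nrow(design)))
    }

    stage <- "normalize"
    tpm <- tpm_normalize(expression)
    readr::write_tsv(tpm, note(file.path(config$out_dir, "tpm.tsv")))

    stage <- "classify"
    res <- run_cascade(tpm, design, cascade_cfg)
    message(sprintf(
      "[classify] thresholds: TPM>=%g, src fold>=%g p<%g, reversal>=%g p<%g, cadherin fold>=%g p<%g",
      cascade_cfg$min_tpm, cascade_cfg$src_fold, cascade_cfg$src_alpha,
      cascade_cfg$reversal_fraction, cascade_cfg$reversal_alpha,
      cascade_cfg$cdh_fold, cascade_cfg$cdh_alpha))
    readr::write_tsv(res$genes,
                     note(file.path(config$out_dir, "classification.tsv")))
    jsonlite::write_json(as.list(res$summary),
                         note(file.path(config$out_dir, "summary.json")),
                         auto_unbox = TRUE, digits = NA)

    recovery <- NULL
    if (!is.null(truth)) {
      stage <- "recovery"
      recovery <- evaluate_recovery(truth, res)
      readr::write_tsv(recovery$stages,
                       note(file.path(config$out_dir, "recovery.tsv")))
    }

    if (!is.null(config$annotations_path)) {
      stage <- "annotate"
      ann <- read_annotations(config$annotations_path)
      readr::write_tsv(location_summary(res, ann),
                       note(file.path(config$out_dir, "locations.tsv")))
    }
    if (!is.null(config$edges_path) && !is.null(config$focus_gene)) {
      stage <- "neighborhood"
      edges <- read_edges(config$edges_path)
      nb <- neighborhood(edges, config$focus_gene)
      readr::write_tsv(tibble(focus = config$focus_gene, neighbor = nb),
                       note(file.path(config$out_dir, "neighborhood.tsv")))
    }

    list(cascade = res, summary = res$summary, recovery = recovery,
         paths = written)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
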