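#' Build and validate a pipeline run configuration
#'
#' A run configuration drives [run_pipeline()]: which stages to execute,
#' where inputs live, where outputs go, the RNG seed, and any hyperparameter
#' overrides. Unknown keys are rejected so typos cannot silently change a
#' run. Configurations round-trip through YAML.
#'
#' @param out_dir output directory (created if needed).
#' @param stages character subset of
#'   `c("simulate", "preprocess", "fit", "correct_cn", "qc")`, executed in
#'   that order.
#' @param seed integer seed used by every stochastic stage.
#' @param scenario scenario name from [default_scenarios()] (simulate stage).
#' @param counts,sequence_map,guide_map input paths (ignored when the
#'   simulate stage produces them).
#' @param copy_number optional copy-number CSV; when absent the correct_cn
#'   stage is skipped with a notice.
#' @param essential_genes,nonessential_genes,expression optional control-list
#'   files (one gene per line) and expression CSV for the qc stage.
#' @param lfc_threshold,gap_threshold outgrowth-masking thresholds.
#' @param hyperparameters named list of [screen_hyperparameters()] overrides.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, stages = c("preprocess", "fit"), seed = 0,
                       scenario = NULL, counts = NULL, sequence_map = NULL,
                       guide_map = NULL, copy_number = NULL,
                       essential_genes = NULL, nonessential_genes = NULL,
                       expression = NULL, lfc_threshold = 2,
                       gap_threshold = 2, hyperparameters = list()) {
  known <- c("simulate", "preprocess", "fit", "correct_cn", "qc")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  bad_hp <- setdiff(names(hyperparameters),
                    names(formals(screen_hyperparameters)))
  if (length(bad_hp))
    stop("unknown hyperparameter(s): ", paste(bad_hp, collapse = ", "))
  cfg <- list(out_dir = out_dir, stages = stages, seed = as.integer(seed),
              scenario = scenario, counts = counts,
              sequence_map = sequence_map, guide_map = guide_map,
              copy_number = copy_number, essential_genes = essential_genes,
              nonessential_genes = nonessential_genes,
              expression = expression, lfc_threshold = lfc_threshold,
              gap_threshold = gap_threshold,
              hyperparameters = hyperparameters)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()];
#'   unknown keys are rejected.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), names(formals(run_config)))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, raw)
}

pipeline_log <- function(out_dir, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...))
  cat(line, "\n", sep = "", file = file.path(out_dir, "run.log"), append = TRUE)
  message(line)
}

#' Run the screen-analysis workflow
#'
#' Executes the requested stages in order: simulate (write a synthetic screen
#' with its truth tables), preprocess (mask clonal outgrowths, write the
#' masked counts and a report), fit (estimate gene effects and efficacies),
#' correct_cn (copy-number bias removal, skipped with a notice when no
#' copy-number input exists), and qc (control-separation metrics, requires
#' control lists). Every run writes `run.log` (seed, package version, config
#' hash, stage progress) and echoes the effective configuration to
#' `run_config.yaml` in the output directory. Reruns with the same
#' configuration are byte-identical.
#'
#' @param config a [run_config()], or a path to a YAML file for
#'   [read_run_config()].
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(config$out_dir, "run.log"))
  cfg_plain <- unclass(config)
  yaml::write_yaml(cfg_plain, file.path(config$out_dir, "run_config.yaml"))
  cfg_hash <- sum(utf8ToInt(paste(deparse(cfg_plain), collapse = "")) *
                    seq_along(utf8ToInt(paste(deparse(cfg_plain), collapse = "")))) %% 1e9
  pipeline_log(config$out_dir, "seed=%d version=%s config_hash=%.0f",
               config$seed, as.character(utils::packageVersion("screenpop")),
               cfg_hash)
  hp <- do.call(screen_hyperparameters, config$hyperparameters)
  paths <- list(counts = config$counts, sequence_map = config$sequence_map,
                guide_map = config$guide_map)

  run_stage <- function(stage, fn) {
    pipeline_log(config$out_dir, "stage %s: start", stage)
    out <- tryCatch(fn(), error = function(e) {
      pipeline_log(config$out_dir, "stage %s: FAILED: %s", stage,
                   conditionMessage(e))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    pipeline_log(config$out_dir, "stage %s: done", stage)
    out
  }

  if ("simulate" %in% config$stages) {
    run_stage("simulate", function() {
      reg <- default_scenarios(seed = config$seed)
      if (is.null(config$scenario) || !config$scenario %in% names(reg))
        stop("scenario must be one of: ", paste(names(reg), collapse = ", "))
      sim <- simulate_screen(reg[[config$scenario]])
      write_matrix_csv(sim$screen$counts,
                       file.path(config$out_dir, "counts.csv"), "sequence_ID")
      utils::write.table(sim$screen$sequence_map,
                         file.path(config$out_dir, "sequence_map.csv"),
                         sep = ",", row.names = FALSE, quote = FALSE)
      utils::write.table(sim$screen$guide_map,
                         file.path(config$out_dir, "guide_map.csv"),
                         sep = ",", row.names = FALSE, quote = FALSE)
      write_matrix_csv(sim$truth$r,
                       file.path(config$out_dir, "truth_gene_effect.csv"),
                       "cell_line")
      if (!is.null(sim$truth$cn))
        write_matrix_csv(sim$truth$cn,
                         file.path(config$out_dir, "copy_number.csv"),
                         "cell_line")
      paths$counts <<- file.path(config$out_dir, "counts.csv")
      paths$sequence_map <<- file.path(config$out_dir, "sequence_map.csv")
      paths$guide_map <<- file.path(config$out_dir, "guide_map.csv")
      if (!is.null(sim$truth$cn) && is.null(config$copy_number))
        config$copy_number <<- file.path(config$out_dir, "copy_number.csv")
    })
  }

  sd <- NULL
  load_screen <- function() {
    if (is.null(paths$counts)) stop("no counts input configured")
    read_screen_data(paths$counts, paths$sequence_map, paths$guide_map)
  }

  if ("preprocess" %in% config$stages) {
    run_stage("preprocess", function() {
      x <- load_screen()
      masked <- remove_clonal_outgrowths(x, config$lfc_threshold,
                                         config$gap_threshold)
      report <- attr(masked, "outgrowth_report")
      write_matrix_csv(masked$counts,
                       file.path(config$out_dir, "masked_counts.csv"),
                       "sequence_ID")
      utils::write.table(report,
                         file.path(config$out_dir, "outgrowth_report.csv"),
                         sep = ",", row.names = FALSE, quote = FALSE)
      pipeline_log(config$out_dir, "masked %d suspected outgrowth entries",
                   nrow(report))
      sd <<- masked
    })
  }

  fit <- NULL
  if ("fit" %in% config$stages) {
    run_stage("fit", function() {
      if (is.null(sd)) sd <<- load_screen()
      fit <<- screenpop(sd, hp = hp, seed = config$seed)
      write_matrix_csv(unclass(coef(fit)),
                       file.path(config$out_dir, "gene_effect.csv"),
                       "cell_line")
      utils::write.table(
        data.frame(sgrna = names(fit$guide_efficacy),
                   efficacy = unname(fit$guide_efficacy)),
        file.path(config$out_dir, "guide_efficacy.csv"),
        sep = ",", row.names = FALSE, quote = FALSE)
      utils::write.table(summary(fit)$per_line,
                         file.path(config$out_dir, "cell_line_summary.csv"),
                         sep = ",", row.names = FALSE, quote = FALSE)
      utils::write.table(
        data.frame(epoch = seq_along(fit$cost_history) - 1L,
                   cost = fit$cost_history),
        file.path(config$out_dir, "training_log.csv"),
        sep = ",", row.names = FALSE, quote = FALSE)
    })
  }

  if ("correct_cn" %in% config$stages) {
    if (is.null(config$copy_number)) {
      pipeline_log(config$out_dir,
                   "stage correct_cn: skipped (no copy-number input)")
    } else {
      run_stage("correct_cn", function() {
        ge <- if (is.null(fit))
          gene_effect_matrix(
            read_matrix_csv(file.path(config$out_dir, "gene_effect.csv")),
            "raw")
        else coef(fit)
        cn <- read_matrix_csv(config$copy_number)
        corrected <- correct_copy_number(ge, cn)
        model <- attr(corrected, "cn_model")
        write_matrix_csv(unclass(corrected),
                         file.path(config$out_dir,
                                   "corrected_gene_effect.csv"), "cell_line")
        utils::write.table(
          data.frame(cell_line = names(model$w_c), w_c = unname(model$w_c)),
          file.path(config$out_dir, "cn_model_report.csv"),
          sep = ",", row.names = FALSE, quote = FALSE)
      })
    }
  }

  if ("qc" %in% config$stages) {
    run_stage("qc", function() {
      ge_path <- file.path(config$out_dir, "gene_effect.csv")
      ge <- if (!is.null(fit)) coef(fit) else
        gene_effect_matrix(read_matrix_csv(ge_path), "raw")
      if (is.null(config$essential_genes) || is.null(config$nonessential_genes))
        stop("qc stage needs essential_genes and nonessential_genes files")
      ess <- readLines(config$essential_genes)
      non <- readLines(config$nonessential_genes)
      expr <- if (!is.null(config$expression))
        read_matrix_csv(config$expression) else NULL
      ctl <- control_sets(ess, non, expr)
      ge_n <- normalize_global(ge, ctl)
      report <- data.frame(cell_line = rownames(ge_n), stringsAsFactors = FALSE)
      report$nnmd <- vapply(rownames(ge_n), function(cl) {
        nnmd(ge_n[cl, intersect(ess, colnames(ge_n))],
             ge_n[cl, intersect(non, colnames(ge_n))])
      }, numeric(1))
      if (!is.null(expr)) {
        fpr <- unexpressed_false_positive_rate(ge_n, ctl)
        report$unexpressed_fp_rate <- fpr$per_line[report$cell_line]
        rec <- essential_recall_metrics(ge_n, ctl)
        report <- merge(report, rec, by = "cell_line", sort = FALSE)
        pipeline_log(config$out_dir, "pooled unexpressed FP rate %.4f",
                     fpr$pooled)
      }
      utils::write.table(report, file.path(config$out_dir, "qc_report.csv"),
                         sep = ",", row.names = FALSE, quote = FALSE)
      write_matrix_csv(unclass(ge_n),
                       file.path(config$out_dir,
                                 "gene_effect_normalized.csv"), "cell_line")
    })
  }

  invisible(config$out_dir)
}
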