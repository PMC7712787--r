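#' Pipeline configuration
#'
#' Bundles the configuration of every stage of the end-to-end run: phantom
#' cohort generation, conventional quantification, ROC analysis per parameter
#' and subgroup, and CNN training/evaluation per modality/timepoint before and
#' after augmentation. Every stochastic stage has an explicit seed, so a
#' config fully determines the report.
#'
#' @param phantom a [cohort_config()].
#' @param quant a [quant_config()].
#' @param cnn list: `arch` ([arch_config()]), `folds`, `train_fraction`,
#'   `threshold`, `split_seed`, `cv_seed`, `modalities`.
#' @param subgroups subset of `c("all", "HER2_negative", "triple_negative")`.
#' @param output_dir where volumes, tables and the report are written.
#' @param write_volumes write per-patient NIfTI volumes (default `TRUE`).
#' @param log_level `"info"` for stage messages, `"quiet"` for none.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = cohort_config(),
                            quant = quant_config(),
                            cnn = list(),
                            subgroups = c("all", "HER2_negative", "triple_negative"),
                            output_dir = tempfile("nacresp_run_"),
                            write_volumes = TRUE,
                            log_level = "info") {
  cnn_defaults <- list(arch = arch_config(), folds = 3L, train_fraction = 0.8,
                       threshold = 0.5, split_seed = 11L, cv_seed = 22L,
                       modalities = c("PET0", "PET1", "MRI0", "MRI1"))
  cnn <- utils::modifyList(cnn_defaults, cnn)
  stopifnot(inherits(phantom, "cohort_config"), inherits(quant, "quant_config"),
            inherits(cnn$arch, "arch_config"))
  subgroups <- match.arg(subgroups, several.ok = TRUE)
  structure(list(phantom = phantom, quant = quant, cnn = cnn,
                 subgroups = subgroups, output_dir = output_dir,
                 write_volumes = isTRUE(write_volumes), log_level = log_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML mirrors [pipeline_config()]: top-level blocks `phantom`, `quant`,
#' `cnn` (with nested `arch`), `subgroups`, `output_dir`, `write_volumes`.
#' Missing fields take the package defaults.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cnn <- y$cnn %||% list()
  if (!is.null(cnn$arch)) cnn$arch <- do.call(arch_config, cnn$arch)
  args <- list(phantom = do.call(cohort_config, y$phantom %||% list()),
               quant = do.call(quant_config, y$quant %||% list()),
               cnn = cnn)
  if (!is.null(y$subgroups)) args$subgroups <- unlist(y$subgroups)
  if (!is.null(y$output_dir)) args$output_dir <- y$output_dir
  if (!is.null(y$write_volumes)) args$write_volumes <- y$write_volumes
  if (!is.null(y$log_level)) args$log_level <- y$log_level
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_stage <- function(name, log_level, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
  if (identical(log_level, "info"))
    message(sprintf("[nacresp] stage %-10s done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
  res
}

roc_row <- function(subgroup, parameter, scores, labels) {
  base <- data.frame(subgroup = subgroup, parameter = parameter,
                     n = NA_integer_, n_pos = NA_integer_, n_neg = NA_integer_,
                     auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                     p_value = NA_real_, cutoff = NA_real_,
                     sensitivity = NA_real_, specificity = NA_real_,
                     direction = NA_character_, note = "",
                     stringsAsFactors = FALSE)
  r <- roc_analysis(scores, labels)
  base$n <- r$n_pos + r$n_neg; base$n_pos <- r$n_pos; base$n_neg <- r$n_neg
  base$auc <- r$auc; base$ci_low <- r$ci_low; base$ci_high <- r$ci_high
  base$p_value <- r$p_value; base$cutoff <- r$cutoff
  base$sensitivity <- r$sensitivity; base$specificity <- r$specificity
  base$direction <- r$direction
  base
}

#' Run the full phantom-to-report pipeline
#'
#' Generates the seeded phantom cohort, extracts the twelve conventional
#' parameters per patient, runs ROC analysis for every parameter in every
#' configured subgroup, trains and evaluates the CNN per modality/timepoint
#' with and without rotation augmentation (shared patient-level 80/20 split,
#' k-fold cross-validation, fold-ensemble test evaluation), compares pre- vs
#' post-augmentation fold metrics with the Mann-Whitney U test, and writes a
#' manifest, a parameters CSV, a ROC results CSV and a JSON report to
#' `config$output_dir`. Everything in the report is regenerable from the
#' config alone; the report embeds a hash of the scientific configuration.
#'
#' @param config a [pipeline_config()].
#' @return the report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  lvl <- config$log_level

  cohort <- run_stage("simulate", lvl, {
    co <- generate_cohort(config$phantom)
    if (length(co) == 0L) stop("empty cohort")
    if (config$write_volumes) write_cohort(co, file.path(out, "volumes"))
    co
  })

  params <- run_stage("quantify", lvl, {
    p <- extract_cohort_parameters(cohort, config$quant)
    p$grade <- vapply(cohort, function(s) s$grade, integer(1))
    p$responder <- classify_response(p$grade)
    p$ER <- vapply(cohort, function(s) unname(s$subtype["ER"]), logical(1))
    p$PR <- vapply(cohort, function(s) unname(s$subtype["PR"]), logical(1))
    p$HER2 <- vapply(cohort, function(s) unname(s$subtype["HER2"]), logical(1))
    write.csv(p, file.path(out, "parameters.csv"), row.names = FALSE)
    p
  })

  parameters <- c("suv0", "suv1", "mtv0", "mtv1", "tlg0", "tlg1",
                  "adc0", "adc1", "dsuv", "dmtv", "dtlg", "dadc")
  roc_table <- run_stage("roc", lvl, {
    rows <- list()
    for (sg in config$subgroups) {
      rec <- subgroup_filter(params, sg)
      for (pm in parameters) {
        row <- if (sg == "all") {
          roc_row(sg, pm, rec[[pm]], rec$responder)   # errors abort the stage
        } else {
          tryCatch(roc_row(sg, pm, rec[[pm]], rec$responder),
                   error = function(e) {
                     data.frame(subgroup = sg, parameter = pm,
                                     n = nrow(rec), n_pos = sum(rec$responder),
                                     n_neg = sum(!rec$responder),
                                     auc = NA_real_, ci_low = NA_real_,
                                     ci_high = NA_real_, p_value = NA_real_,
                                     cutoff = NA_real_, sensitivity = NA_real_,
                                     specificity = NA_real_,
                                     direction = NA_character_,
                                     note = conditionMessage(e),
                                     stringsAsFactors = FALSE)
                   })
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
    tab <- do.call(rbind, rows)
    write.csv(tab, file.path(out, "roc_results.csv"), row.names = FALSE)
    tab
  })

  cnn_results <- run_stage("cnn", lvl, {
    res <- list()
    for (mod in config$cnn$modalities) {
      res[[mod]] <- list()
      for (aug in c(FALSE, TRUE)) {
        dataset <- build_dataset(cohort, mod, augment = aug, config = config$quant)
        split <- split_train_test(dataset, config$cnn$train_fraction,
                                  seed = config$cnn$split_seed)
        ens <- train_crossval(split$train, config$cnn$arch, k = config$cnn$folds,
                              seed = config$cnn$cv_seed,
                              threshold = config$cnn$threshold)
        test <- evaluate_ensemble(ens, split$test, config$cnn$threshold)
        test$probabilities <- NULL
        res[[mod]][[if (aug) "post" else "pre"]] <-
          list(n_crops = length(dataset),
               n_train = length(split$train), n_test = length(split$test),
               validation = ens$validation, test = test)
      }
    }
    res
  })

  aug_compare <- run_stage("compare", lvl, {
    rows <- list()
    for (mod in names(cnn_results)) {
      pre <- cnn_results[[mod]]$pre$validation$fold_values
      post <- cnn_results[[mod]]$post$validation$fold_values
      for (met in c("sensitivity", "specificity", "accuracy", "auc")) {
        rows[[length(rows) + 1L]] <- data.frame(
          modality = mod, metric = met,
          pre_median = median(pre[[met]]), post_median = median(post[[met]]),
          p_value = rank_compare(pre[[met]], post[[met]]),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  report <- run_stage("report", lvl, {
    sci_cfg <- list(phantom = unclass(config$phantom),
                    quant = unclass(config$quant),
                    cnn = lapply(config$cnn, function(x)
                      if (inherits(x, "arch_config")) unclass(x) else x),
                    subgroups = config$subgroups)
    rep <- list(
      provenance = list(package = "nacresp",
                        version = as.character(utils::packageVersion("nacresp")),
                        config_hash = rlang::hash(sci_cfg),
                        seeds = list(phantom = config$phantom$seed,
                                     split = config$cnn$split_seed,
                                     cv = config$cnn$cv_seed),
                        generated = format(Sys.time(), tz = "UTC")),
      cohort = list(n = length(cohort),
                    n_responders = sum(vapply(cohort, function(s) s$true_response, logical(1))),
                    n_nonresponders = sum(!vapply(cohort, function(s) s$true_response, logical(1))),
                    responder_share_percent =
                      round(100 * mean(vapply(cohort, function(s) s$true_response, logical(1))))),
      roc = roc_table,
      cnn = cnn_results,
      augmentation_compare = aug_compare)
    jsonlite::write_json(rep, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", na = "null")
    rep
  })

  invisible(report)
}
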