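# End-to-end orchestration: simulate/load -> pretreat -> split -> GFA ->
# validate -> applicability domain -> report. Every stochastic stage gets
# a seed derived deterministically from the global seed, so a config fully
# determines the artifact bundle.

#' Pipeline configuration
#'
#' @param input path to a descriptor/activity CSV, or `NULL` to simulate
#'   with `synthetic` (the default world: 50 compounds, 300 descriptors).
#' @param id_column,activity_column CSV column names (when `input` given).
#' @param synthetic a [synthetic_spec()] used when `input` is `NULL`; its
#'   seed is overridden by the derived stage seed.
#' @param variance_tol,r_threshold pretreatment thresholds.
#' @param normalize normalization variant, `"paper"` or `"minmax"`.
#' @param n_train training-set size for the Kennard-Stone split.
#' @param gfa named list of [gfa_config()] overrides (e.g.
#'   `list(generations = 100)`).
#' @param yrand_iterations Y-randomization permutations (default 10).
#' @param seed global integer seed.
#' @param out_dir output directory for artifacts, or `NULL` to skip
#'   writing.
#' @param quiet suppress progress messages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, id_column = "ID",
                            activity_column = "pKi",
                            synthetic = synthetic_spec(),
                            variance_tol = 1e-6, r_threshold = 0.95,
                            normalize = c("paper", "minmax"),
                            n_train = 36, gfa = list(),
                            yrand_iterations = 10, seed = 1,
                            out_dir = NULL, quiet = FALSE) {
  normalize <- match.arg(normalize)
  structure(list(input = input, id_column = id_column,
                 activity_column = activity_column, synthetic = synthetic,
                 variance_tol = variance_tol, r_threshold = r_threshold,
                 normalize = normalize, n_train = as.integer(n_train),
                 gfa = gfa, yrand_iterations = as.integer(yrand_iterations),
                 seed = as.integer(seed), out_dir = out_dir, quiet = quiet),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; the
#' `synthetic` and `gfa` entries are nested objects of [synthetic_spec()]
#' / [gfa_config()] overrides.
#'
#' @param path JSON file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_named("unknown config field(s): %s", paste(unknown, collapse = ", "))
  if (!is.null(raw$synthetic))
    raw$synthetic <- do.call(synthetic_spec, raw$synthetic)
  do.call(pipeline_config, raw)
}

# Deterministic per-stage seeds, all < 2^31.
stage_seed <- function(seed, stage)
  (as.integer(seed) * 101L +
     match(stage, c("simulate", "gfa", "yrand"))) %% .Machine$integer.max

#' Run the full QSAR pipeline
#'
#' Executes simulate/load, variance and correlation filtering, min-max
#' normalization (parameters fitted on the training partition),
#' Kennard-Stone division, GFA model search, the validation battery,
#' Y-randomization, and the applicability-domain table; optionally writes
#' every stage artifact plus a rendered report under `config$out_dir`.
#' Identical config and seed give identical bundles.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_bundle` with elements `dataset`,
#'   `truth` (when simulated), `pretreatment`, `split`, `descriptives`,
#'   `gfa`, `model`, `validation`, `yrand`, `checklist`, `ad`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(name, fmt, ...)
    if (!config$quiet) message(sprintf(paste0("[", name, "] ", fmt), ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_named("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  truth <- NULL
  dataset <- stage("input", {
    if (is.null(config$input)) {
      spec <- config$synthetic
      spec$seed <- stage_seed(config$seed, "simulate")
      gen <- generate_dataset(spec)
      truth <- gen$truth
      say("simulate", "generated %d x %d (seed %d)", length(gen$dataset$ids),
          ncol(gen$dataset$X), spec$seed)
      gen$dataset
    } else
      read_dataset(config$input, config$id_column, config$activity_column,
                   quiet = config$quiet)
  })

  pre <- stage("pretreat", {
    lv <- remove_low_variance(dataset, config$variance_tol)
    cf <- correlation_filter(lv$dataset, config$r_threshold)
    say("pretreat", "%d -> %d descriptors (variance), -> %d (correlation)",
        ncol(dataset$X), ncol(lv$dataset$X), ncol(cf$dataset$X))
    list(dataset = cf$dataset, variance_log = lv$log,
         correlation_log = cf$log)
  })

  split <- stage("split", {
    # distance geometry must not be dominated by wide columns: split on a
    # provisional full-data min-max scaling (the real normalizer is fitted
    # on the training partition below)
    prov <- apply_normalizer(pre$dataset,
                             fit_normalizer(pre$dataset, "minmax"))
    kennard_stone_split(prov, config$n_train, quiet = TRUE)
  })
  say("split", "%d train / %d test", length(split$train_ids),
      length(split$test_ids))

  train_raw <- ds_subset(pre$dataset, rows = split$train_ids)
  test_raw <- if (length(split$test_ids))
    ds_subset(pre$dataset, rows = split$test_ids) else NULL

  norm <- stage("normalize", fit_normalizer(train_raw, config$normalize))
  train <- apply_normalizer(train_raw, norm)
  test <- if (!is.null(test_raw)) apply_normalizer(test_raw, norm)

  descriptives <- list(train = describe_activity(train$y),
                       test = if (!is.null(test)) describe_activity(test$y))

  gfa_res <- stage("train", {
    args <- config$gfa
    args$seed <- args$seed %||% stage_seed(config$seed, "gfa")
    # cap the default model size at the Topliss-style guard M/5 unless the
    # caller chose max_terms explicitly
    if (is.null(args$max_terms))
      args$max_terms <- max(args$min_terms %||% 2L,
                            min(8L, floor(nrow(train$X) / 5)))
    gfa <- do.call(gfa_config, args)
    gfa_search(train, gfa)
  })
  model <- gfa_res$models[[1L]]$model
  say("train", "best model: %s (LOF %.5g)",
      paste(names(model$coefficients), collapse = " + "),
      gfa_res$models[[1L]]$lof$lof)

  report <- stage("validate", validate_model(model, train, test))
  yrand <- stage("yrand", y_randomization(
    train$X[, names(model$coefficients), drop = FALSE], train$y,
    n_iterations = config$yrand_iterations,
    seed = stage_seed(config$seed, "yrand")))
  checklist <- acceptance_checklist(report, yrand)
  ad <- stage("domain", williams_table(model, train, test))
  say("validate", "R2 = %.4f, Q2 = %.4f, checklist %s", report$r2,
      report$q2_loo, if (attr(checklist, "overall")) "PASS" else "FAIL")

  bundle <- structure(
    list(dataset = dataset, truth = truth, pretreatment = pre[-1L],
         split = split, descriptives = descriptives, gfa = gfa_res,
         model = model, validation = report, yrand = yrand,
         checklist = checklist, ad = ad, config = config),
    class = "pipeline_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# Serialize the bundle: one artifact per stage plus the rendered report.
# Deliberately timestamp-free so identical runs are byte-identical.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, name)
    jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  write_dataset(bundle$dataset, file.path(out_dir, "dataset.csv"))
  if (!is.null(bundle$truth))
    wj(list(intercept = bundle$truth$intercept,
            coefficients = as.list(bundle$truth$coefficients),
            noise_sd = attr(bundle$truth, "noise_sd")),
       "ground_truth.json")
  wj(list(variance = unclass(bundle$pretreatment$variance_log),
          correlation = unclass(bundle$pretreatment$correlation_log)),
     "pretreatment.json")
  wj(unclass(bundle$split), "split.json")
  wj(list(intercept = bundle$model$intercept,
          coefficients = as.list(bundle$model$coefficients),
          n_train = bundle$model$n_train, r2 = bundle$model$r2,
          see = bundle$model$see),
     "model.json")
  v <- bundle$validation
  wj(list(r2 = v$r2, r2_adjusted = v$r2_adjusted, see = v$see,
          f_statistic = v$f_statistic, q2_loo = v$q2_loo,
          r2_test = v$r2_test, n_train = v$n_train, n_test = v$n_test,
          coefficients = v$coefficients, vif = as.list(v$vif),
          contributions = v$contributions),
     "validation.json")
  wj(unclass(bundle$yrand), "yrand.json")
  wj(as.data.frame(bundle$checklist), "checklist.json")
  utils::write.csv(bundle$ad$table, file.path(out_dir, "ad.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(render_report(bundle), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

fmt_stats_table <- function(descr, label) {
  keys <- c("n", "standard_error", "median", "standard_deviation",
            "sample_variance", "kurtosis", "skewness", "range", "minimum",
            "maximum", "mean")
  vapply(keys, function(k) {
    tr <- descr$train[[k]]
    te <- if (!is.null(descr$test)) descr$test[[k]] else NA
    sprintf("| %-18s | %10s | %10s |", k,
            ifelse(is.na(tr), "-", sprintf("%.3f", tr)),
            ifelse(is.na(te), "-", sprintf("%.3f", te)))
  }, "")
}

#' Render a pipeline bundle as markdown
#'
#' Deterministic, fixed-precision tables mirroring the standard QSAR
#' report: partition descriptives, the model equation, the contribution
#' table, the acceptance checklist, the correlation/VIF/t diagnostics,
#' and the Y-randomization table. Pure formatting: every number comes
#' from the bundle.
#'
#' @param bundle a [run_pipeline()] result.
#' @return Character vector of markdown lines.
#' @export
render_report <- function(bundle) {
  m <- bundle$model; v <- bundle$validation
  eqn <- paste(c(sprintf("%+.3f(%s)", m$coefficients,
                         names(m$coefficients)),
                 sprintf("%+.3f", m$intercept)), collapse = " ")
  out <- c(
    "# QSAR pipeline report", "",
    sprintf("Compounds: %d train / %d test; descriptors in model: %d",
            v$n_train, v$n_test, m$p), "",
    "## Activity descriptives", "",
    "| statistic          |   training |       test |",
    "|--------------------|------------|------------|",
    fmt_stats_table(bundle$descriptives), "",
    "## Model", "",
    sprintf("    %s = %s", bundle$dataset$activity_name, eqn), "",
    sprintf("R2 = %.4f, adjusted R2 = %.4f, SEE = %.4f, F = %.2f, Q2(LOO) = %.4f%s",
            v$r2, v$r2_adjusted, v$see, v$f_statistic, v$q2_loo,
            ifelse(is.na(v$r2_test), "",
                   sprintf(", R2(test) = %.4f", v$r2_test))), "",
    "## Descriptor contributions", "",
    "| descriptor | std. coef | percent |",
    "|------------|-----------|---------|",
    sprintf("| %-10s | %9.3f | %6.1f%% |", v$contributions$descriptor,
            v$contributions$std_coef, v$contributions$percent), "",
    "## Acceptance checklist", "",
    "| criterion | value | verdict |",
    "|-----------|-------|---------|",
    sprintf("| %-18s | %8s | %s |", bundle$checklist$criterion,
            ifelse(is.na(bundle$checklist$value), "-",
                   sprintf("%.4f", bundle$checklist$value)),
            ifelse(is.na(bundle$checklist$pass), "not evaluable",
                   ifelse(bundle$checklist$pass, "pass", "FAIL"))),
    sprintf("| overall | | %s |",
            ifelse(attr(bundle$checklist, "overall"), "PASS", "FAIL")), "")
  if (!is.null(v$pearson_matrix)) {
    nm <- rownames(v$pearson_matrix)
    co <- v$coefficients[match(nm, v$coefficients$term), ]
    out <- c(out,
      "## Collinearity and significance", "",
      paste0("| descriptor | ", paste(nm, collapse = " | "),
             " | VIF | t | p |"),
      paste0("|---", paste(rep("|---", length(nm) + 3), collapse = ""), "|"),
      vapply(seq_along(nm), function(i)
        paste0("| ", nm[i], " | ",
               paste(sprintf("%.4f", v$pearson_matrix[i, ]), collapse = " | "),
               sprintf(" | %.4f | %.4f | %.3g |", v$vif[[i]], co$t[i],
                       co$p[i])),
        ""), "")
  }
  yr <- bundle$yrand
  out <- c(out,
    "## Y-randomization", "",
    "| model | R | R2 | Q2 |",
    "|-------|----|----|----|",
    sprintf("| Original | %.4f | %.4f | %.4f |", yr$original[["R"]],
            yr$original[["R2"]], yr$original[["Q2"]]),
    sprintf("| Random %d | %.4f | %.4f | %.4f |", yr$iterations$iteration,
            yr$iterations$R, yr$iterations$R2, yr$iterations$Q2),
    sprintf("| Average | %.4f | %.4f | %.4f |", yr$average_r, yr$average_r2,
            yr$average_q2),
    sprintf("| cRp2 | %.4f | | |", yr$crp2), "",
    sprintf("## Applicability domain"), "",
    sprintf("h* = %.4f; outliers: %d of %d compounds", bundle$ad$h_star,
            sum(bundle$ad$table$flag != "in_domain"), nrow(bundle$ad$table)))
  out
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("<pipeline_bundle>\n")
  print(x$model)
  print(x$validation)
  print(x$checklist)
  invisible(x)
}
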