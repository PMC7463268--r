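#' Pipeline run configuration
#'
#' Assembles the nested configuration of a full run — cohort generation (or
#' image-directory input), pre-processing, feature extraction, selection and
#' classification — with every default matching the corresponding module
#' default. Unknown keys are rejected. A resolved copy is written into each
#' run's output directory, and `(config, seed)` fully determines all
#' outputs.
#'
#' @param ... named overrides of the default sections: `seed`, `input`
#'   (`mode` = `"synthetic"` or `"directory"`, `dir`, `bit_depth`),
#'   `cohort` (arguments of [cohort_spec()]), `preprocess` (arguments of
#'   [preprocess_config()]), `features` (`Ng`, `d`, `symmetric`,
#'   `sum_variance_center`, `per_direction`), `selection` (`k`, `nested`),
#'   `classify` (`kind`, `protocol`, `C`, `knn_k`, `var_floor`, `fraction`).
#'   Sections may be given as lists (e.g. `cohort = list(seed = 3)`).
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    input = list(mode = "synthetic", dir = NULL, bit_depth = 8L),
    cohort = as.list(formals(cohort_spec)),
    preprocess = as.list(formals(preprocess_config)),
    features = list(Ng = 8L, d = 1L, symmetric = TRUE,
                    sum_variance_center = "sum_average",
                    per_direction = FALSE),
    selection = list(k = 5L, nested = FALSE),
    classify = list(kind = "svm_linear", protocol = "loocv",
                    C = 1, knn_k = 3L, var_floor = 1e-9, fraction = 0.5)
  )
  defaults$cohort$lesion_radius_range <- c(2, 6)
  defaults$preprocess$clahe_tiles <- c(8L, 8L)
  defaults$preprocess$stretch_percentiles <- c(2, 98)
  defaults$preprocess$order <- c("median", "clahe")
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad) > 0L) {
    stop("unknown config sections: ", paste(bad, collapse = ", "))
  }
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      bad_keys <- setdiff(names(overrides[[nm]]), names(defaults[[nm]]))
      if (length(bad_keys) > 0L) {
        stop("unknown keys in section '", nm, "': ",
             paste(bad_keys, collapse = ", "))
      }
      defaults[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  structure(defaults, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with (a subset of) the configuration sections.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Validate an image directory against a labels table
#'
#' Checks that every labeled image exists, is readable and single-channel,
#' that every image file has a label, and that label values are `"case"` or
#' `"control"` (common synonyms such as `"ME"` get a remapping hint).
#' Reports issues; never throws.
#'
#' @param dir directory of PNG/TIFF images.
#' @param labels data frame with columns `image_id`, `label`; defaults to
#'   `labels.csv` inside `dir`.
#' @return Data frame `image_id`, `issue` (zero rows when clean).
#' @export
validate_inputs <- function(dir, labels = NULL) {
  issues <- data.frame(image_id = character(0), issue = character(0),
                       stringsAsFactors = FALSE)
  note <- function(id, msg) {
    issues <<- rbind(issues, data.frame(image_id = id, issue = msg,
                                        stringsAsFactors = FALSE))
  }
  if (is.null(labels)) {
    lp <- file.path(dir, "labels.csv")
    if (!file.exists(lp)) {
      note("<labels>", "labels.csv not found")
      return(issues)
    }
    labels <- read.csv(lp, stringsAsFactors = FALSE)
  }
  if (!all(c("image_id", "label") %in% names(labels))) {
    note("<labels>", "labels table must have columns image_id, label")
    return(issues)
  }
  files <- list.files(dir, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE)
  ids_on_disk <- tools::file_path_sans_ext(files)
  for (i in seq_len(nrow(labels))) {
    id <- labels$image_id[i]; lab <- labels$label[i]
    if (!lab %in% LABEL_LEVELS) {
      hint <- if (toupper(lab) %in% c("ME", "EDEMA", "OEDEMA", "POSITIVE"))
        "; map it to \"case\"" else
        if (toupper(lab) %in% c("NORMAL", "HEALTHY", "NEGATIVE"))
          "; map it to \"control\"" else ""
      note(id, paste0("label \"", lab,
                      "\" is not one of case/control", hint))
    }
    fi <- which(ids_on_disk == id)
    if (length(fi) == 0L) {
      note(id, "image file not found")
      next
    }
    img <- tryCatch(read_gray_image(file.path(dir, files[fi[1]])),
                    error = function(e) conditionMessage(e))
    if (is.character(img)) {
      if (grepl("single-channel", img)) {
        note(id, "not single-channel")
      } else {
        note(id, paste0("unreadable: ", img))
      }
    }
  }
  for (id in setdiff(ids_on_disk, labels$image_id)) {
    note(id, "image present on disk but missing from the labels table")
  }
  issues
}

read_cohort_dir <- function(dir, bit_depth = 8L) {
  labels <- read.csv(file.path(dir, "labels.csv"),
                     stringsAsFactors = FALSE)
  files <- list.files(dir, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE)
  ids_on_disk <- tools::file_path_sans_ext(files)
  lapply(seq_len(nrow(labels)), function(i) {
    fi <- which(ids_on_disk == labels$image_id[i])
    if (length(fi) == 0L) {
      stop("no image file for labeled id: ", labels$image_id[i])
    }
    list(image_id = labels$image_id[i],
         image = read_gray_image(file.path(dir, files[fi[1]]), bit_depth),
         label = labels$label[i])
  })
}

#' Run the full detection pipeline
#'
#' Executes simulate (or load) -> preprocess -> extract -> rank -> classify
#' -> report as one seeded run. Writes `features.csv`, `ranking.csv`,
#' `diagnostics.csv`, `report.json`, the resolved `config.yaml` and a
#' `run.log` with per-stage timings into `output_dir`. Any stage error
#' aborts with a stage-named message; outputs written so far are retained
#' and `MANIFEST` marks the run incomplete until it finishes.
#'
#' @param config a [run_config()] (or path to a YAML config).
#' @param output_dir directory for run artifacts (created; `NULL` = no
#'   files are written and the results are only returned).
#' @param seed optional override of `config$seed`.
#' @return Invisibly, a list with `features` (data frame), `ranking`,
#'   `selected` (feature names), `diagnostics`, `report`
#'   (classifier report), `comparison` (group means table) and `config`.
#' @export
run_pipeline <- function(config = run_config(), output_dir = NULL,
                         seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)

  log_lines <- character(0)
  t_stage <- Sys.time()
  log_stage <- function(msg) {
    now <- Sys.time()
    line <- sprintf("[%s] %s (%.2fs)", format(now, "%H:%M:%S"), msg,
                    as.numeric(now - t_stage, units = "secs"))
    t_stage <<- now
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- !is.null(output_dir)
  if (emit) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines("status: incomplete", file.path(output_dir, "MANIFEST"))
    yaml::write_yaml(unclass(config), file.path(output_dir, "config.yaml"))
  }

  cohort <- stage("input", {
    if (config$input$mode == "synthetic") {
      ccfg <- config$cohort
      ccfg$seed <- config$seed
      generate_cohort(do.call(cohort_spec, ccfg))
    } else {
      issues <- validate_inputs(config$input$dir)
      if (nrow(issues) > 0L) {
        stop("input validation failed: ",
             paste(issues$image_id, issues$issue, sep = ": ",
                   collapse = "; "))
      }
      read_cohort_dir(config$input$dir, config$input$bit_depth)
    }
  })
  log_stage(sprintf("input: %d images (seed %d)", length(cohort),
                    config$seed))

  pre_cfg <- do.call(preprocess_config, config$preprocess)
  fc <- config$features
  features <- stage("extract", extract_feature_table(
    cohort, pre_cfg, per_direction = isTRUE(fc$per_direction),
    Ng = fc$Ng, d = fc$d, symmetric = fc$symmetric,
    sum_variance_center = fc$sum_variance_center))
  if (emit) {
    write.csv(format(features, digits = 12, trim = TRUE),
              file.path(output_dir, "features.csv"), row.names = FALSE,
              quote = FALSE)
  }
  log_stage("preprocess + feature extraction")

  ranking <- stage("rank", rank_features(features))
  selected <- stage("rank", select_top_k(
    ranking, min(config$selection$k, nrow(ranking))))
  if (emit) {
    write.csv(ranking, file.path(output_dir, "ranking.csv"),
              row.names = FALSE, quote = FALSE)
  }
  log_stage(sprintf("ANOVA ranking: top feature %s (F = %.3g)",
                    ranking$feature[1], ranking$F[1]))

  diagnostics <- stage("diagnostics", feature_diagnostics(features))
  comparison <- stage("diagnostics", group_comparison(features))
  if (emit) {
    write.csv(diagnostics, file.path(output_dir, "diagnostics.csv"),
              row.names = FALSE, quote = FALSE)
  }
  log_stage(sprintf("per-feature diagnostics: best %s (AUC %.3f)",
                    diagnostics$feature[1], diagnostics$auc[1]))

  cl <- config$classify
  report <- stage("classify", {
    if (cl$protocol == "loocv") {
      loocv(features, kind = cl$kind, feature_names = selected,
            nested = isTRUE(config$selection$nested),
            top_k = config$selection$k,
            C = cl$C, k = cl$knn_k, var_floor = cl$var_floor)
    } else {
      split_eval(features, kind = cl$kind, feature_names = selected,
                 fraction = cl$fraction, seed = config$seed,
                 C = cl$C, k = cl$knn_k, var_floor = cl$var_floor)
    }
  })
  log_stage(sprintf("%s/%s: sens %.1f%% spec %.1f%% acc %.1f%%",
                    cl$kind, cl$protocol, report$sensitivity,
                    report$specificity, report$accuracy))

  if (emit) {
    jsonlite::write_json(
      list(seed = config$seed, selected_features = selected,
           classifier = unclass(report),
           diagnostics = diagnostics),
      file.path(output_dir, "report.json"), auto_unbox = TRUE,
      digits = NA)
    writeLines(log_lines, file.path(output_dir, "run.log"))
    writeLines("status: complete", file.path(output_dir, "MANIFEST"))
  }
  invisible(list(features = features, ranking = ranking,
                 selected = selected, diagnostics = diagnostics,
                 report = report, comparison = comparison,
                 config = config))
}
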