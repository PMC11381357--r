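#' @title Study pipeline
#' @name pipeline
#' @description Configuration and an end-to-end driver running the study
#'   stages (simulate -> fit kinetics -> featurize -> train -> rank) with a
#'   reproducibility manifest. Each stage can also be invoked on its own
#'   through the exported module functions.
NULL

#' Pipeline configuration
#'
#' @param out_dir output directory (created if missing).
#' @param synthetic a \code{synthetic_config}; drives the simulate stage.
#' @param sequences_path,traces_path optional paths to measured inputs; when
#'   given they replace the corresponding synthetic stage.
#' @param ppairs_dir optional directory of ppairs files named
#'   \code{<sample_id>.ppairs} used instead of the builtin structure engine.
#' @param model an \code{energy_model}.
#' @param f_star completion fraction defining time to equilibrium.
#' @param t_fast,t_slow rate-class boundaries (s).
#' @param split_frac,cv_folds,models ml-stage settings.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir, synthetic = synthetic_config(),
                            sequences_path = NULL, traces_path = NULL,
                            ppairs_dir = NULL, model = energy_model(),
                            f_star = 0.95, t_fast = 1000, t_slow = 3600,
                            split_frac = 0.8, cv_folds = 5L,
                            models = MODEL_SPECS, seed = 1L) {
  if (t_fast <= 0 || t_slow <= t_fast)
    stop("need 0 < t_fast < t_slow", call. = FALSE)
  structure(
    list(out_dir = out_dir, synthetic = synthetic,
         sequences_path = sequences_path, traces_path = traces_path,
         ppairs_dir = ppairs_dir, model = model, f_star = f_star,
         t_fast = t_fast, t_slow = t_slow, split_frac = split_frac,
         cv_folds = as.integer(cv_folds), models = models,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

config_fingerprint <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  dump_cfg <- cfg
  # paths identify where, not what: only the scientific settings are hashed
  dump_cfg[c("out_dir", "sequences_path", "traces_path", "ppairs_dir")] <- NULL
  dump_cfg$model$stacks <- as.list(dump_cfg$model$stacks)
  writeLines(jsonlite::toJSON(dump_cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Run the study pipeline end-to-end
#'
#' Stages: (1) obtain systems (synthetic generation or \code{sequences_path});
#' (2) obtain kinetic traces (simulation with planted rates, or
#' \code{traces_path}) and fit per-trace second-order rate constants,
#' combining replicates by geometric mean; (3) featurize every system;
#' (4) assemble the labeled dataset, rank variables by random-forest
#' importance, compute Pearson correlations, and evaluate the configured
#' classifiers; (5) rank systems by the X2/X5/X11 key. All tabular outputs
#' are CSV, the evaluation report is JSON, and a manifest records the config
#' fingerprint, seeds, inputs and outputs. Reruns with the same config
#' reproduce identical outputs.
#'
#' @param cfg a \code{pipeline_config}.
#' @return list with the in-memory stage results and \code{manifest}.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  produced <- character(0)
  consumed <- character(0)
  emit <- function(name) {
    path <- file.path(cfg$out_dir, name)
    produced <<- c(produced, name)
    path
  }
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message("[pipeline] ", msg)
  }

  # stage 1: systems
  if (is.null(cfg$sequences_path)) {
    systems <- gen_systems(cfg$synthetic)
    say("simulate: generated %d systems (seed %d)", length(systems),
        cfg$synthetic$seed)
  } else {
    if (!file.exists(cfg$sequences_path))
      stop("sequences_path does not exist: ", cfg$sequences_path, call. = FALSE)
    consumed <- c(consumed, cfg$sequences_path)
    systems <- load_sequences(cfg$sequences_path,
                              toehold_len = cfg$synthetic$toehold_len)
    say("load: %d systems from %s", length(systems), cfg$sequences_path)
  }
  if (length(systems) == 0L) stop("no systems to analyze", call. = FALSE)
  write_sequences_csv(systems, emit("sequences.csv"))
  write_sequences_fasta(systems, emit("sequences.fasta"))

  # stage 2: features
  ppms <- NULL
  if (!is.null(cfg$ppairs_dir)) {
    consumed <- c(consumed, cfg$ppairs_dir)
    ppms <- lapply(systems, function(s) {
      f <- file.path(cfg$ppairs_dir, paste0(s$id, ".ppairs"))
      if (!file.exists(f)) stop("missing ppairs file: ", f, call. = FALSE)
      read_pair_probabilities(f)
    })
    features <- do.call(rbind, lapply(seq_along(systems), function(i) {
      fv <- featurize_system(systems[[i]], cfg$model, c0 = cfg$synthetic$c0,
                             ppm = ppms[[i]])
      data.frame(sample_id = systems[[i]]$id, t(unclass(fv)),
                 stringsAsFactors = FALSE)
    }))
  } else {
    features <- featurize_systems(systems, cfg$model, c0 = cfg$synthetic$c0)
  }
  utils::write.csv(features, emit("features.csv"), row.names = FALSE)
  say("featurize: %d x %d feature table", nrow(features), 16L)

  # stage 3: kinetics
  calib <- list(slope = cfg$synthetic$calibration$slope,
                intercept = cfg$synthetic$calibration$intercept)
  class(calib) <- "calibration_curve"
  if (is.null(cfg$traces_path)) {
    kseeds <- derive_seeds(cfg$synthetic$seed, length(systems), salt = 1L)
    tseeds <- derive_seeds(cfg$synthetic$seed, length(systems), salt = 2L)
    k_true <- vapply(seq_along(systems), function(i) {
      fv <- unlist(features[i, feature_names()])
      planted_log_rate(fv, cfg$synthetic, seed = kseeds[i])
    }, numeric(1L))
    traces <- lapply(seq_along(systems), function(i)
      simulate_trace(k_true[i], cfg$synthetic, seed = tseeds[i],
                     sample_id = systems[[i]]$id))
    write_traces_csv(traces, emit("traces.csv"))
    say("simulate: %d traces with planted rates", length(traces))
  } else {
    if (!file.exists(cfg$traces_path))
      stop("traces_path does not exist: ", cfg$traces_path, call. = FALSE)
    consumed <- c(consumed, cfg$traces_path)
    traces <- load_traces(cfg$traces_path)
    say("load: %d traces from %s", length(traces), cfg$traces_path)
  }
  fits <- lapply(traces, function(tr) {
    conc <- trace_to_concentration(tr, calib, cfg$synthetic$background)
    fit_rate_constant(conc, tr$times, cfg$synthetic$c0, f_star = cfg$f_star)
  })
  ids <- vapply(traces, function(tr) tr$sample_id, character(1L))
  # replicate traces of one sample combine by geometric mean of k
  k_fit <- tapply(vapply(fits, function(f) f$k, numeric(1L)), ids,
                  geometric_mean_k)
  k_fit <- k_fit[unique(ids)]
  no_rxn <- tapply(vapply(fits, function(f) f$no_reaction, logical(1L)), ids,
                   any)[unique(ids)]
  if (any(no_rxn)) say("warning: no-reaction flag for %s",
                       paste(names(no_rxn)[no_rxn], collapse = ", "))
  t_eq <- ifelse(k_fit > 0,
                 cfg$f_star / ((1 - cfg$f_star) * k_fit * cfg$synthetic$c0),
                 Inf)
  rates <- data.frame(sample_id = names(k_fit), k = unname(k_fit),
                      t_eq = unname(t_eq),
                      rate_class = classify_rate(t_eq, cfg$t_fast, cfg$t_slow),
                      no_reaction = unname(no_rxn), stringsAsFactors = FALSE)
  utils::write.csv(rates, emit("rates.csv"), row.names = FALSE)
  say("fit-kinetics: %d samples, classes %s", nrow(rates),
      paste(table(factor(rates$rate_class, 0:2)), collapse = "/"))

  # stage 4: dataset, importance, correlations, evaluation
  ds <- assemble_dataset(features, rates[, c("sample_id", "k", "rate_class")])
  cls_counts <- table(factor(ds$rate_class, 0:2))
  evaluable <- sum(cls_counts > 0) >= 2L &&
    all(cls_counts[cls_counts > 0] >= cfg$cv_folds)
  reports <- list()
  if (evaluable) {
    imp <- feature_importance(ds, seed = cfg$seed)
    utils::write.csv(imp, emit("importance.csv"), row.names = FALSE)
    cors <- pearson_correlations(ds)
    utils::write.csv(as.data.frame(cors), emit("correlations.csv"))
    reports <- lapply(cfg$models, function(ms)
      train_and_evaluate(ds, ms, split_frac = cfg$split_frac,
                         cv_folds = cfg$cv_folds, seed = cfg$seed))
    names(reports) <- cfg$models
    rep_json <- lapply(reports, function(r) {
      r$confusion <- as.data.frame(r$confusion)
      unclass(r)
    })
    writeLines(jsonlite::toJSON(rep_json, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, force = TRUE),
               emit("eval_report.json"))
    for (ms in cfg$models)
      say("train [%s]: val acc %.3f, macro AUC %.3f", ms,
          reports[[ms]]$val_accuracy, reports[[ms]]$auc_macro)
    imp_out <- imp
    cors_out <- cors
  } else {
    say("train: skipped (class counts %s leave < %d members in a class)",
        paste(cls_counts, collapse = "/"), cfg$cv_folds)
    writeLines(jsonlite::toJSON(list(skipped = "class counts too small"),
                                auto_unbox = TRUE), emit("eval_report.json"))
    imp_out <- NULL
    cors_out <- NULL
  }

  # stage 5: ranking by the key variables
  ranking <- rank_by_key(features)
  utils::write.csv(ranking, emit("ranking.csv"), row.names = FALSE)

  manifest <- list(config_md5 = config_fingerprint(cfg), seed = cfg$seed,
                   synthetic_seed = cfg$synthetic$seed,
                   inputs = consumed,
                   outputs = sort(unique(c(produced, "manifest.json",
                                           "pipeline.log"))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(cfg$out_dir, "manifest.json"))
  writeLines(log_lines, file.path(cfg$out_dir, "pipeline.log"))

  invisible(list(systems = systems, features = features, rates = rates,
                 dataset = ds, importance = imp_out, correlations = cors_out,
                 reports = reports, ranking = ranking, manifest = manifest))
}
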