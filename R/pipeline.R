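# End-to-end orchestration: simulate/ingest -> embed -> impute -> assemble ->
# split -> train -> evaluate, persisting every intermediate artifact with a
# self-describing JSON sidecar (producing stage, seed, config hash).

#' Pipeline configuration
#'
#' One global seed deterministically derives every stage seed, so any stage
#' can be re-run in isolation and the end-to-end run is reproducible
#' byte-for-byte.
#'
#' @param sim a [sim_config()] (its own seed is overridden by the derived
#'   stage seed).
#' @param embedding list of [train_embedding()] settings plus `p`, the PCA
#'   target dimension. `p` is clamped to the feasible rank
#'   `min(p, V - 1, d)` for small vocabularies.
#' @param gp list with `starts` and `max_iter`: GP fitting effort per series.
#' @param model a [model_config()] (seed and input size are overridden).
#' @param imputation_method `"gp"`, `"mean_substitution"`, `"locf"` or
#'   `"linear"`.
#' @param split train/validation/test fractions.
#' @param seed global integer seed.
#' @param log_level `"info"` or `"quiet"`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            embedding = list(algorithm = "cbow", d = 100,
                                             window = 5, epochs = 5,
                                             lr = 0.025, negative = 0, p = 99),
                            gp = list(starts = 1, max_iter = 50),
                            model = model_config(),
                            imputation_method = "gp",
                            split = c(0.6, 0.2, 0.2), seed = 1,
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  stopifnot(inherits(sim, "sim_config"), inherits(model, "model_config"))
  imputation_method <- match.arg(imputation_method,
                                 c("gp", "mean_substitution", "locf", "linear"))
  structure(list(sim = sim, embedding = embedding, gp = gp, model = model,
                 imputation_method = imputation_method, split = split,
                 seed = as.integer(seed), log_level = log_level),
            class = "pipeline_config")
}

config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  sprintf("%08x", derive_seed(0L, txt))
}

pipe_log <- function(config, stage, seed, t0) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[icurisk] stage=%s seed=%d elapsed=%.2fs", stage, seed,
                  as.numeric(proc.time()[3] - t0)))
}

write_sidecar <- function(path, stage, seed, config) {
  jsonlite::write_json(list(stage = stage, seed = seed,
                            config_hash = config_hash(config),
                            package = "icurisk"),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
}

#' Persist / restore an embedding
#'
#' The matrix goes to a plain CSV (tokens as the first column) with a JSON
#' sidecar holding the vocabulary counts and training settings.
#'
#' @param embedding an [train_embedding()] or [reduce_dimensions()] object.
#' @param path CSV file path (sidecar gets `.json` appended).
#' @export
write_embedding <- function(embedding, path) {
  X <- embedding$matrix
  df <- data.frame(token = rownames(X), X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- embedding[setdiff(names(embedding), "matrix")]
  meta$class <- class(embedding)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  if (!file.exists(path)) stopf("embedding artifact missing: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df$token
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cls <- meta$class; meta$class <- NULL
  out <- c(list(matrix = X), meta)
  if ("vocab" %in% names(out)) out$vocab <- as.data.frame(out$vocab)
  if ("projection" %in% names(out)) out$projection <- as.matrix(out$projection)
  structure(out, class = cls)
}

#' Persist / restore a trained classifier
#'
#' All weight matrices, gate parameters, the feature scaler and the model
#' configuration go to a single JSON file at full numeric precision.
#'
#' @param model a `risk_model`.
#' @param path JSON file path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  obj <- list(
    config = unclass(model$config),
    layers = lapply(model$layers, function(l) {
      list(params = lapply(unclass(l$params), identity),
           gate = if (!is.null(l$gate)) unclass(l$gate))
    }),
    W_out = model$W_out, b_out = model$b_out, scaler = model$scaler,
    feature_names = model$feature_names, trace = model$trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stopf("model artifact missing: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- structure(obj$config, class = "model_config")
  # rebuild the layer list from the unsimplified parse (matrix shapes matter)
  raw_layers <- jsonlite::read_json(path, simplifyVector = FALSE)$layers
  layers <- lapply(raw_layers, function(l) {
    par <- l$params
    p <- structure(list(
      W_x = do.call(rbind, lapply(par$W_x, unlist)),
      W_h = do.call(rbind, lapply(par$W_h, unlist)),
      b = unlist(par$b), w_ci = unlist(par$w_ci), w_cf = unlist(par$w_cf),
      w_co = unlist(par$w_co), input_size = par$input_size,
      hidden_size = par$hidden_size), class = "lstm_params")
    g <- if (!is.null(l$gate)) {
      structure(list(tau = unlist(l$gate$tau), s = unlist(l$gate$s),
                     r_on = l$gate$r_on, leak = l$gate$leak,
                     hidden_size = l$gate$hidden_size),
                class = "phased_gate_params")
    }
    list(params = p, gate = g)
  })
  structure(list(config = cfg, layers = layers,
                 W_out = as.matrix(obj$W_out), b_out = as.numeric(obj$b_out),
                 scaler = list(mu = as.numeric(obj$scaler$mu),
                               sd = as.numeric(obj$scaler$sd)),
                 feature_names = obj$feature_names, trace = obj$trace),
            class = "risk_model")
}

#' Subset assembled sequences by patient id
#'
#' @param sequences an [assemble_event_vectors()] object.
#' @param ids patient ids to keep (order preserved from `sequences`).
#' @return an `event_sequences` object.
#' @export
subset_sequences <- function(sequences, ids) {
  keep <- sequences$patient_id %in% ids
  out <- sequences
  out$x <- sequences$x[keep, , , drop = FALSE]
  out$times <- sequences$times[keep, , drop = FALSE]
  out$mask <- sequences$mask[keep, , drop = FALSE]
  out$labels <- sequences$labels[keep]
  out$patient_id <- sequences$patient_id[keep]
  out
}

#' Run the end-to-end mortality-risk pipeline
#'
#' Executes simulate (or ingest) -> embed -> impute -> assemble -> split ->
#' train -> evaluate, persisting each intermediate under `out_dir` with a
#' JSON sidecar, and returns the final evaluation report. With the same
#' config (and its global seed) the persisted evaluation report is
#' byte-identical across runs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created).
#' @param cohort optional pre-built/ingested `icu_cohort`; when supplied the
#'   simulate stage is skipped.
#' @return list with `report` ([evaluate_model()] result), `model`, `cohort`,
#'   `sequences`, `splits` (patient ids) and `paths` of persisted artifacts.
#' @export
run_pipeline <- function(config, out_dir = tempfile("icurisk_run_"),
                         cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  t0 <- proc.time()[3]

  # -- simulate -------------------------------------------------------------
  sseed <- derive_seed(config$seed, "simulate")
  if (is.null(cohort)) {
    sim <- config$sim; sim$seed <- sseed
    cohort <- simulate_cohort(sim)
  }
  paths$tables <- file.path(out_dir, "cohort")
  write_cohort_tables(cohort, paths$tables)
  write_sidecar(file.path(paths$tables, "labels.csv"), "simulate", sseed, config)
  v <- validate_input_tables(paths$tables)
  if (nrow(v)) stopf("stage simulate wrote invalid tables: %s", v$message[1])
  pipe_log(config, "simulate", sseed, t0)

  # -- embed ----------------------------------------------------------------
  eseed <- derive_seed(config$seed, "embed")
  emb_cfg <- config$embedding
  corpus <- suppressWarnings(build_corpus(cohort))
  embedding <- train_embedding(corpus, algorithm = emb_cfg$algorithm %||% "cbow",
                               d = emb_cfg$d %||% 100,
                               window = emb_cfg$window %||% 5,
                               epochs = emb_cfg$epochs %||% 5,
                               lr = emb_cfg$lr %||% 0.025,
                               negative = emb_cfg$negative %||% 0,
                               seed = eseed)
  p_eff <- min(emb_cfg$p %||% 99, nrow(embedding$matrix) - 1L,
               ncol(embedding$matrix))
  reduced <- reduce_dimensions(embedding, p_eff)
  paths$embedding <- file.path(out_dir, "embedding.csv")
  write_embedding(reduced, paths$embedding)
  write_sidecar(paths$embedding, "embed", eseed, config)
  pipe_log(config, "embed", eseed, t0)

  # -- impute ---------------------------------------------------------------
  iseed <- derive_seed(config$seed, "impute")
  imputed <- impute_cohort(cohort, method = config$imputation_method,
                           gp_starts = config$gp$starts %||% 1,
                           gp_max_iter = config$gp$max_iter %||% 50,
                           seed = iseed)
  paths$imputed <- file.path(out_dir, "imputed")
  write_cohort_tables(imputed, paths$imputed, imputed_flags = TRUE)
  write_sidecar(file.path(paths$imputed, "labels.csv"), "impute", iseed, config)
  pipe_log(config, "impute", iseed, t0)

  # -- assemble + split -----------------------------------------------------
  sequences <- suppressWarnings(assemble_event_vectors(imputed, reduced))
  spseed <- derive_seed(config$seed, "split")
  splits <- split_data(imputed, fractions = config$split, seed = spseed)
  ids <- lapply(splits, attr, "ids")
  seq_train <- subset_sequences(sequences, ids$train)
  seq_val <- subset_sequences(sequences, ids$validation)
  seq_test <- subset_sequences(sequences, ids$test)
  pipe_log(config, "assemble", spseed, t0)

  # -- train ----------------------------------------------------------------
  tseed <- derive_seed(config$seed, "model")
  mcfg <- config$model; mcfg$seed <- tseed
  mcfg$input_size <- dim(sequences$x)[3]
  mcfg$horizon <- config$sim$horizon_hours %||% mcfg$horizon
  model <- train_classifier(seq_train, seq_val, mcfg)
  paths$model <- file.path(out_dir, "model.json")
  write_model(model, paths$model)
  write_sidecar(paths$model, "train", tseed, config)
  pipe_log(config, "train", tseed, t0)

  # -- evaluate -------------------------------------------------------------
  report <- evaluate_model(model, seq_test)
  paths$report <- file.path(out_dir, "report.json")
  write_eval_report(report, paths$report)
  write_sidecar(paths$report, "evaluate", tseed, config)
  pipe_log(config, "evaluate", tseed, t0)

  list(report = report, model = model, cohort = imputed,
       sequences = sequences, splits = ids, paths = paths)
}
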