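# Shared fixtures, memoised so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# desk-scale cohort used across modules
small_config <- function(...) {
  args <- list(n_patients = 60, n_items = 12, n_groups = 3,
               events_per_patient_mean = 12, horizon_hours = 24,
               vitals_step_hours = 2, missing_rate = 0.3, seed = 42)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

small_cohort <- function() memo("small_cohort", simulate_cohort(small_config()))

small_embedding <- function() {
  memo("small_embedding", {
    corpus <- build_corpus(small_cohort())
    train_embedding(corpus, d = 16, window = 5, epochs = 8, seed = 7)
  })
}

small_reduced <- function() memo("small_reduced",
                                 reduce_dimensions(small_embedding(), 8))

small_imputed <- function() {
  memo("small_imputed",
       impute_cohort(small_cohort(), "gp", gp_starts = 1, gp_max_iter = 30,
                     seed = 3))
}

small_sequences <- function() {
  memo("small_sequences",
       suppressWarnings(assemble_event_vectors(small_imputed(),
                                               small_reduced())))
}

# hand-built two-patient cohort with fully observed values (no missingness)
manual_cohort <- function(temp_value = 37) {
  mk_vitals <- function() {
    g <- seq(0, 10, by = 2)
    list(body_temperature = data.frame(time = g, value = rep(temp_value, length(g))),
         pulse_rate = data.frame(time = g, value = 80 + g),
         respiration_rate = data.frame(time = g, value = rep(15, length(g))),
         blood_pressure = data.frame(time = g, value = rep(95, length(g))))
  }
  mk_events <- function(items, start, end) {
    data.frame(itemid = items, starttime = start, endtime = end,
               rate = seq_along(items) * 10, totalamount = seq_along(items) * 100,
               stringsAsFactors = FALSE)
  }
  structure(list(patients = list(
    list(patient_id = 1L,
         events = mk_events(c("Sodium Chloride 0.9%", "Heparin"), c(1, 4), c(3, 6)),
         vitals = mk_vitals(), label = 0L),
    list(patient_id = 2L,
         events = mk_events(c("Heparin", "Insulin"), c(0.5, 2), c(2, 5)),
         vitals = mk_vitals(), label = 1L)),
    config = NULL, ground_truth = NULL), class = "icu_cohort")
}

# random tiny classifier + batch used by gradient and invariance tests
tiny_model_and_batch <- function(cell = "phased_lstm", loss = "mse",
                                 hidden = 2, layers = 2, L = 3, B = 2,
                                 seed = 11) {
  cfg <- model_config(cell = cell, input_size = 3, hidden_size = hidden,
                      layers = layers, loss = loss, horizon = 10, seed = 4)
  model <- icurisk:::init_model(cfg)
  withr::with_seed(seed, {
    flat <- icurisk:::collect_params(model)
    for (nm in names(flat)) {
      if (grepl("log_tau$|_s$", nm)) next
      v <- flat[[nm]]; v[] <- rnorm(length(v), 0, 0.4); flat[[nm]] <- v
    }
    model <- icurisk:::apply_params(model, flat)
    X <- array(rnorm(B * L * 3), c(B, L, 3))
    Tm <- t(apply(matrix(runif(B * L, 0, 10), B, L), 1, sort))
    Mk <- matrix(1, B, L); if (B > 1) Mk[B, L] <- 0
    y <- rep_len(c(0, 1), B)
    list(model = model, X = X, Tm = Tm, Mk = Mk, y = y, cfg = cfg)
  })
}
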