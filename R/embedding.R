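# Semantic representation of medication events: each drug token is a "word",
# each patient's time-ordered event sequence a "document", and the cohort the
# corpus. A word2vec model (CBOW by default, Skip-Gram optionally) embeds the
# vocabulary; PCA reduces the embedding; event feature vectors concatenate
# the reduced embedding with the six numeric channels.

#' Build the patient-document corpus
#'
#' One document per patient (in `patient_id` order), the document being the
#' patient's drug tokens ordered by event `starttime`. Multi-word item names
#' are kept as single tokens. Patients with zero events contribute an empty
#' document (kept, with a warning).
#'
#' @param cohort an `icu_cohort`.
#' @return named list of character vectors.
#' @export
build_corpus <- function(cohort) {
  stopifnot(inherits(cohort, "icu_cohort"))
  if (length(cohort$patients) == 0) stopf("cohort has no patients")
  docs <- lapply(cohort$patients, function(p) {
    ev <- p$events
    as.character(ev$itemid[order(ev$starttime)])
  })
  names(docs) <- vapply(cohort$patients, function(p) as.character(p$patient_id), "")
  n_empty <- sum(lengths(docs) == 0)
  if (n_empty > 0) {
    warning(sprintf("%d patient(s) with zero events produce empty documents",
                    n_empty))
  }
  docs
}

#' Train a word2vec embedding over the event vocabulary
#'
#' Stochastic-gradient training of CBOW (a context window predicts the centre
#' token) or Skip-Gram (the centre token predicts each context token) with a
#' full-softmax objective — exact and fast for vocabularies of the size seen
#' in fluid-event extracts — or negative sampling when `negative > 0`. The
#' learning rate decays linearly over training, as in the original word2vec.
#' Deterministic given `seed`.
#'
#' @param corpus list of character vectors ([build_corpus()]).
#' @param algorithm `"cbow"` (default) or `"sg"`.
#' @param d embedding dimension.
#' @param window context half-width (tokens on each side).
#' @param epochs passes over the corpus; `epochs = 0` returns the seeded
#'   random initialisation unchanged.
#' @param lr initial learning rate.
#' @param negative number of negative samples per prediction (0 = full
#'   softmax).
#' @param seed integer RNG seed.
#' @return object of class `embedding_matrix`: `matrix` (V x d, rownames are
#'   tokens), `vocab` (token, index, count), and the training settings.
#' @export
train_embedding <- function(corpus, algorithm = c("cbow", "sg"), d = 100,
                            window = 5, epochs = 5, lr = 0.025, negative = 0,
                            seed = 1) {
  algorithm <- match.arg(algorithm)
  if (!is.numeric(d) || d < 1) stopf("embedding dimension d must be >= 1")
  if (!is.numeric(window) || window < 1) stopf("window must be >= 1")
  if (epochs < 0) stopf("epochs must be >= 0")
  tokens_all <- unlist(corpus, use.names = FALSE)
  counts <- table(tokens_all)
  if (length(counts) < 2) stopf("corpus must contain at least 2 distinct tokens")
  ord <- order(-as.integer(counts), names(counts))
  vocab <- data.frame(token = names(counts)[ord],
                      index = seq_along(counts),
                      count = as.integer(counts)[ord],
                      stringsAsFactors = FALSE)
  V <- nrow(vocab)
  idx_of <- stats::setNames(vocab$index, vocab$token)
  docs <- lapply(corpus, function(doc) unname(idx_of[doc]))
  docs <- docs[lengths(docs) > 0]
  with_seed(seed, {
    W_in <- matrix(stats::runif(V * d, -0.5 / d, 0.5 / d), nrow = V)
    W_out <- matrix(0, nrow = V, ncol = d)
    if (epochs > 0) {
      # unigram^(3/4) table for negative sampling
      neg_prob <- (vocab$count ^ 0.75); neg_prob <- neg_prob / sum(neg_prob)
      total <- sum(lengths(docs)) * epochs
      done <- 0
      for (ep in seq_len(epochs)) {
        for (doc in docs) {
          n <- length(doc)
          for (pos in seq_len(n)) {
            alpha <- max(lr * (1 - done / total), lr * 1e-4)
            done <- done + 1
            lo <- max(1, pos - window); hi <- min(n, pos + window)
            ctx <- doc[seq(lo, hi)][seq(lo, hi) != pos]
            if (length(ctx) == 0) next
            centre <- doc[pos]
            if (algorithm == "cbow") {
              h <- if (length(ctx) > 1) colMeans(W_in[ctx, , drop = FALSE])
                   else W_in[ctx, ]
              g <- softmax_grad_update(h, centre, W_out, neg_prob, negative,
                                       alpha)
              W_out <- g$W_out
              W_in[ctx, ] <- W_in[ctx, , drop = FALSE] -
                matrix(alpha * g$dh / length(ctx), nrow = length(ctx),
                       ncol = d, byrow = TRUE)
            } else {  # skip-gram: centre predicts each context token
              for (cx in ctx) {
                h <- W_in[centre, ]
                g <- softmax_grad_update(h, cx, W_out, neg_prob, negative,
                                         alpha)
                W_out <- g$W_out
                W_in[centre, ] <- W_in[centre, ] - alpha * g$dh
              }
            }
          }
        }
      }
    }
    rownames(W_in) <- vocab$token
    structure(list(matrix = W_in, vocab = vocab, algorithm = algorithm,
                   d = as.integer(d), window = as.integer(window),
                   epochs = epochs, lr = lr, negative = negative, seed = seed),
              class = "embedding_matrix")
  })
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("event embedding: %d tokens x %d dims (%s, window %d, %g epochs)\n",
              nrow(x$matrix), x$d, toupper(x$algorithm), x$window, x$epochs))
  invisible(x)
}

#' Reduce an embedding with principal component analysis
#'
#' Centres the embedding rows and projects them onto the top `p` principal
#' axes, preserving the pairwise geometry that encodes event similarity while
#' shrinking the downstream model's input size.
#'
#' @param embedding an [train_embedding()] result.
#' @param p target dimension, `1 <= p <= min(d, V)`.
#' @return object of class `reduced_embedding`: `matrix` (V x p),
#'   `projection` (d x p, orthonormal columns), `explained_variance`
#'   (fraction per component, non-increasing), `center`.
#' @export
reduce_dimensions <- function(embedding, p) {
  stopifnot(inherits(embedding, "embedding_matrix"))
  X <- embedding$matrix
  if (!is.numeric(p) || p < 1) stopf("p must be >= 1")
  if (p > ncol(X)) stopf("p (%d) exceeds embedding dimension d (%d)", p, ncol(X))
  if (p > nrow(X)) stopf("p (%d) exceeds vocabulary size (%d)", p, nrow(X))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  if (p > ncol(pc$rotation)) stopf("p (%d) exceeds available components (%d)",
                                   p, ncol(pc$rotation))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  red <- pc$x[, seq_len(p), drop = FALSE]
  rownames(red) <- rownames(X)
  structure(list(matrix = red,
                 projection = pc$rotation[, seq_len(p), drop = FALSE],
                 explained_variance = ev[seq_len(p)],
                 center = pc$center),
            class = "reduced_embedding")
}

#' Nearest tokens by cosine similarity
#'
#' @param token query token (must be in the vocabulary).
#' @param embedding an [embedding_matrix][train_embedding()] or
#'   [reduced_embedding][reduce_dimensions()].
#' @param k number of neighbours (self excluded).
#' @return data.frame `token`, `similarity`, similarity non-increasing.
#' @export
nearest_neighbors <- function(token, embedding, k = 5) {
  X <- embedding$matrix
  if (!token %in% rownames(X)) stopf("unknown token '%s'", token)
  if (k == 0) return(data.frame(token = character(0), similarity = numeric(0)))
  q <- X[token, ]
  nq <- sqrt(sum(q^2))
  nr <- sqrt(rowSums(X^2))
  sims <- as.vector(X %*% q) / (nr * nq)
  sims[!is.finite(sims)] <- -Inf
  sims <- sims[rownames(X) != token]
  ord <- order(-sims)
  top <- ord[seq_len(min(k, length(sims)))]
  data.frame(token = names(sims)[top], similarity = unname(sims[top]),
             stringsAsFactors = FALSE)
}

# One softmax (or negative-sampling) gradient step on the output matrix for
# hidden vector h and target token; returns the updated output matrix and the
# gradient wrt h.
softmax_grad_update <- function(h, target, W_out, neg_prob, negative, alpha) {
  if (negative <= 0) {
    z <- drop(W_out %*% h)
    z <- z - max(z)
    p <- exp(z); p <- p / sum(p)
    e <- p; e[target] <- e[target] - 1              # dL/dz, full softmax
    dh <- drop(crossprod(W_out, e))
    W_out <- W_out - alpha * tcrossprod(e, h)
    list(W_out = W_out, dh = dh)
  } else {
    neg <- sample.int(length(neg_prob), negative, replace = TRUE,
                      prob = neg_prob)
    idx <- c(target, neg)
    lab <- c(1, rep(0, negative))
    z <- drop(W_out[idx, , drop = FALSE] %*% h)
    e <- 1 / (1 + exp(-z)) - lab
    dh <- drop(crossprod(W_out[idx, , drop = FALSE], e))
    W_out[idx, ] <- W_out[idx, , drop = FALSE] - alpha * tcrossprod(e, h)
    list(W_out = W_out, dh = dh)
  }
}

#' Assemble fixed-length per-patient event-vector sequences
#'
#' For each event: the reduced embedding row of its drug (`p` dims), followed
#' by `totalamount`, `rate`, and the interval mean of each regularly
#' resampled vitals channel over `[starttime, endtime)` (nearest grid point
#' when the interval contains none). Sequences are ordered by `starttime` and
#' padded at the end (or truncated) to `L`, by default the 95th percentile of
#' cohort event counts, with a validity mask. The cohort must already be
#' imputed ([impute_cohort()]) so no sentinel values remain.
#'
#' Patients with zero events cannot form a sequence and are dropped with a
#' warning.
#'
#' @param cohort an imputed `icu_cohort`.
#' @param reduced a [reduce_dimensions()] result built from the same cohort.
#' @param L fixed sequence length; `NULL` for the 95th-percentile default.
#' @return object of class `event_sequences`: arrays `x` (n x L x D),
#'   `times` and `mask` (n x L), `labels`, `patient_id`, `feature_names`.
#' @export
assemble_event_vectors <- function(cohort, reduced, L = NULL) {
  stopifnot(inherits(cohort, "icu_cohort"),
            inherits(reduced, "reduced_embedding"))
  if (is.null(cohort$imputation)) {
    has_na <- any(vapply(cohort$patients, function(p)
      anyNA(p$events$rate) || anyNA(p$events$totalamount) ||
        any(vapply(p$vitals, function(v) anyNA(v$value), TRUE)), TRUE))
    if (has_na) stopf("cohort contains missing values; run impute_cohort() first")
  }
  keep <- vapply(cohort$patients, function(p) nrow(p$events) > 0, TRUE)
  if (!all(keep)) {
    warning(sprintf("dropping %d patient(s) with zero events", sum(!keep)))
  }
  patients <- cohort$patients[keep]
  if (length(patients) == 0) stopf("no patients with events")
  counts <- vapply(patients, function(p) nrow(p$events), 0)
  L <- L %||% max(1L, ceiling(stats::quantile(counts, 0.95, names = FALSE)))
  p_dim <- ncol(reduced$matrix)
  vit_ch <- VITALS_CHANNELS
  D <- p_dim + 2 + length(vit_ch)
  feature_names <- c(paste0("emb", seq_len(p_dim)), "totalamount", "rate",
                     vit_ch)
  n <- length(patients)
  X <- array(0, dim = c(n, L, D))
  Tm <- matrix(0, n, L); Mk <- matrix(0, n, L)
  labels <- integer(n); ids <- vapply(patients, `[[`, 1, "patient_id")
  for (i in seq_len(n)) {
    pt <- patients[[i]]
    ev <- pt$events[order(pt$events$starttime), , drop = FALSE]
    if (anyNA(ev$rate) || anyNA(ev$totalamount)) {
      stopf("patient %s has unimputed event values", pt$patient_id)
    }
    miss <- setdiff(unique(ev$itemid), rownames(reduced$matrix))
    if (length(miss)) {
      stopf("event item(s) not in vocabulary: %s (vocabulary must be built from the same cohort)",
            paste(miss, collapse = ", "))
    }
    m <- min(nrow(ev), L)
    emb <- reduced$matrix[ev$itemid[seq_len(m)], , drop = FALSE]
    vit <- matrix(0, m, length(vit_ch))
    for (j in seq_along(vit_ch)) {
      g <- pt$vitals_grid[[vit_ch[j]]]
      if (is.null(g)) stopf("cohort lacks resampled vitals; run impute_cohort() first")
      vit[, j] <- interval_means(g$time, g$value, ev$starttime[seq_len(m)],
                                 ev$endtime[seq_len(m)])
    }
    X[i, seq_len(m), ] <- cbind(emb, ev$totalamount[seq_len(m)],
                                ev$rate[seq_len(m)], vit)
    Tm[i, seq_len(m)] <- ev$starttime[seq_len(m)]
    if (m < L && m > 0) Tm[i, seq(m + 1, L)] <- ev$starttime[m]
    Mk[i, seq_len(m)] <- 1
    labels[i] <- pt$label
  }
  structure(list(x = X, times = Tm, mask = Mk, labels = labels,
                 patient_id = ids, feature_names = feature_names,
                 L = as.integer(L), p = as.integer(p_dim)),
            class = "event_sequences")
}

# mean of grid values with time in [start, end); nearest grid point if the
# interval contains none
interval_means <- function(grid_t, grid_v, start, end) {
  vapply(seq_along(start), function(i) {
    in_int <- grid_t >= start[i] & grid_t < end[i]
    if (any(in_int)) mean(grid_v[in_int])
    else grid_v[which.min(abs(grid_t - start[i]))]
  }, 0)
}

#' @export
print.event_sequences <- function(x, ...) {
  cat(sprintf("event sequences: %d patients, length %d, %d features (p = %d + 6 channels)\n",
              dim(x$x)[1], x$L, dim(x$x)[3], x$p))
  invisible(x)
}
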