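dom_uniform <- function(lo, hi) list(type = "uniform", lo = lo, hi = hi)
dom_int <- function(lo, hi) list(type = "uniform_int", lo = lo, hi = hi)
dom_cat <- function(values) list(type = "categorical", values = values)

#' The hyperparameter search space
#'
#' Per-hyperparameter domains of the published search, per model: uniform
#' distributions for the continuous CNN knobs (batch size 10–30, learning
#' rate 0.0005–0.005, dropout 0.1–0.5, 64–1526 filters of width 3–12,
#' 3–20 epochs), categorical domains for the rest (max-norm constraint
#' 1/1.5/2/2.5/3, optimizer, embedding architecture/dimensions/iterations),
#' the finite SVM grid (kernel, kernel coefficient, regularization
#' parameter, n-grams, vectorization), and the shared class-imbalance
#' domains (sampling ratio, class weights).
#'
#' @return An object of class `"search_space"`, a named list of per-model
#'   domain lists.
#' @export
search_space <- function() {
  cnn <- list(
    max_length = dom_cat(list(100L, 150L, 200L, 250L, 300L, 350L)),
    batch_size = dom_int(10L, 30L),
    learning_rate = dom_uniform(0.0005, 0.005),
    dropout_rate = dom_uniform(0.1, 0.5),
    n_filters = dom_int(64L, 1526L),
    kernel_size = dom_int(3L, 12L),
    n_epochs = dom_int(3L, 20L),
    maxnorm_constraint = dom_cat(list(1, 1.5, 2, 2.5, 3)),
    optimizer = dom_cat(list("adadelta", "adam")),
    embedding_architecture = dom_cat(list("skipgram", "cbow")),
    embedding_dim = dom_cat(list(50L, 100L, 200L, 300L)),
    embedding_epochs = dom_cat(list(5L, 10L, 15L, 20L)),
    sampling_ratio = dom_cat(list(c(1411, 589), c(2411, 589), c(3411, 589),
                                  c(4411, 589))),
    class_weights = dom_cat(list(c(1, 1), c(1, 5), c(0.59, 3.4), c(1, 17),
                                 c(1, 20))))
  svm <- list(
    kernel = dom_cat(list("linear", "polynomial", "sigmoid", "radial")),
    gamma = dom_cat(list(1, 0.1, 0.01, 0.001, 0.0001)),
    cost = dom_cat(list(1, 10, 100, 1000)),
    ngram_range = dom_cat(list(c(1L, 1L), c(1L, 2L), c(1L, 3L), c(1L, 4L))),
    vectorization = dom_cat(list("bow", "tfidf")),
    sampling_ratio = cnn$sampling_ratio,
    class_weights = cnn$class_weights)
  structure(list(cnn_wholeword = cnn, cnn_subword = cnn, svm = svm),
            class = "search_space")
}

#' The chosen ("paper preset") configurations
#'
#' The chosen value of every searched hyperparameter, per model.  Each
#' preset is a valid member of [search_space()] (see
#' [validate_presets()]).
#'
#' @return Named list of configuration lists.
#' @export
paper_presets <- function() {
  list(
    cnn_wholeword = list(max_length = 300L, batch_size = 11L,
                         learning_rate = 0.0047, dropout_rate = 0.29,
                         n_filters = 923L, kernel_size = 8L, n_epochs = 7L,
                         maxnorm_constraint = 2, optimizer = "adam",
                         embedding_architecture = "skipgram",
                         embedding_dim = 100L, embedding_epochs = 10L,
                         sampling_ratio = c(3411, 589),
                         class_weights = c(0.59, 3.4)),
    cnn_subword = list(max_length = 300L, batch_size = 16L,
                       learning_rate = 0.0026, dropout_rate = 0.47,
                       n_filters = 532L, kernel_size = 11L, n_epochs = 14L,
                       maxnorm_constraint = 2, optimizer = "adam",
                       embedding_architecture = "skipgram",
                       embedding_dim = 100L, embedding_epochs = 10L,
                       sampling_ratio = c(3411, 589),
                       class_weights = c(0.59, 3.4)),
    svm = list(kernel = "radial", gamma = 0.001, cost = 100,
               ngram_range = c(1L, 2L), vectorization = "tfidf",
               sampling_ratio = c(3411, 589), class_weights = c(0.59, 3.4)))
}

value_in_domain <- function(value, dom) {
  switch(dom$type,
    uniform = value >= dom$lo && value <= dom$hi,
    uniform_int = value >= dom$lo && value <= dom$hi &&
      value == round(value),
    categorical = any(vapply(dom$values, function(v)
      isTRUE(all.equal(unname(v), unname(value))), logical(1))))
}

#' Check that every preset lies inside the search space
#'
#' @param space A [search_space()].
#' @param presets Configurations to validate (default [paper_presets()]).
#' @return `TRUE` invisibly; errors if a preset leaves its domain.
#' @export
validate_presets <- function(space = search_space(),
                             presets = paper_presets()) {
  for (model in names(presets)) {
    doms <- space[[model]]
    for (par in names(presets[[model]])) {
      if (is.null(doms[[par]])) stop2(model, ": no domain for ", par)
      if (!value_in_domain(presets[[model]][[par]], doms[[par]]))
        stop2(model, ": preset value of ", par, " outside its domain")
    }
  }
  invisible(TRUE)
}

sample_domain <- function(dom) {
  switch(dom$type,
    uniform = runif(1, dom$lo, dom$hi),
    uniform_int = sample(seq.int(dom$lo, dom$hi), 1L),
    categorical = dom$values[[sample.int(length(dom$values), 1L)]])
}

#' Sample one configuration from a model's search space
#'
#' Continuous domains are sampled uniformly, integer domains from the
#' discrete uniform, categorical domains uniformly over their values.
#' Deterministic under `seed`.
#'
#' @param space_model One element of [search_space()] (a named domain list).
#' @param seed Integer seed.
#' @return Named list with one sampled value per hyperparameter.
#' @export
sample_configuration <- function(space_model, seed = 1L) {
  if (!length(space_model)) stop2("empty search space")
  for (dom in space_model)
    if (dom$type == "categorical" && !length(dom$values))
      stop2("empty categorical domain")
  set.seed(seed)
  lapply(space_model, sample_domain)
}

# ---- simplified tree-structured Parzen estimator ----------------------------
# Splits completed trials into good/bad by objective quantile, models each
# hyperparameter's density in both groups (Gaussian KDE for continuous,
# Laplace-smoothed counts for categorical), draws candidates from the good
# density and keeps the candidate maximizing the good/bad density ratio.
tpe_propose <- function(space_model, history, n_candidates = 24L,
                        gamma = 0.25) {
  done <- Filter(function(tr) !is.na(tr$auroc), history)
  scores <- vapply(done, `[[`, numeric(1), "auroc")
  cut <- quantile(scores, 1 - gamma, type = 7)
  good <- done[scores >= cut]
  bad <- done[scores < cut]
  if (!length(good) || !length(bad)) return(lapply(space_model, sample_domain))
  dens <- function(values, x, dom) {
    if (dom$type == "categorical") {
      keys <- vapply(dom$values, function(v) paste(v, collapse = "|"),
                     character(1))
      obs <- vapply(values, function(v) paste(v, collapse = "|"),
                    character(1))
      counts <- vapply(keys, function(k) sum(obs == k) + 1, numeric(1))
      p <- counts / sum(counts)
      p[match(paste(x, collapse = "|"), keys)]
    } else {
      v <- unlist(values)
      bw <- max((dom$hi - dom$lo) / (1 + length(v))^0.5, 1e-9)
      mean(stats::dnorm(as.numeric(x[1]), mean = v, sd = bw))
    }
  }
  draw_from <- function(values, dom) {
    if (dom$type == "categorical") values[[sample.int(length(values), 1L)]]
    else {
      v <- unlist(values)
      bw <- max((dom$hi - dom$lo) / (1 + length(v))^0.5, 1e-9)
      x <- stats::rnorm(1, mean = sample(v, 1L), sd = bw)
      x <- min(max(x, dom$lo), dom$hi)
      if (dom$type == "uniform_int") as.integer(round(x)) else x
    }
  }
  best <- NULL; best_score <- -Inf
  for (cand in seq_len(n_candidates)) {
    cfg <- list()
    score <- 0
    for (par in names(space_model)) {
      dom <- space_model[[par]]
      g_vals <- lapply(good, function(tr) tr$configuration[[par]])
      b_vals <- lapply(bad, function(tr) tr$configuration[[par]])
      x <- draw_from(g_vals, dom)
      cfg[[par]] <- x
      lg <- dens(g_vals, x, dom); lb <- dens(b_vals, x, dom)
      score <- score + log(lg + 1e-12) - log(lb + 1e-12)
    }
    if (score > best_score) { best_score <- score; best <- cfg }
  }
  best
}

stratified_split <- function(labels, validation_fraction, seed) {
  set.seed(seed)
  val <- integer(0)
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    n_val <- max(1L, round(length(idx) * validation_fraction))
    val <- c(val, sample(idx, n_val))
  }
  sort(val)
}

apply_trial_config <- function(model, config, train_docs, seed) {
  imb <- imbalance_config(sampling_ratio = config$sampling_ratio,
                          class_weights = config$class_weights,
                          seed = seed)
  if (model == "svm") {
    cfg <- svm_config(kernel = config$kernel, gamma = config$gamma,
                      cost = config$cost, ngram_range = config$ngram_range,
                      use_idf = identical(config$vectorization, "tfidf"),
                      seed = seed)
    train_svm(train_docs, cfg = cfg, imbalance = imb)
  } else {
    variant <- sub("cnn_", "", model)
    emb_cfg <- embedding_config(method = variant,
                                dim = config$embedding_dim,
                                epochs = config$embedding_epochs,
                                architecture = config$embedding_architecture,
                                seed = seed)
    emb <- train_embeddings(train_docs, emb_cfg)
    cfg <- cnn_config(variant, max_length = config$max_length,
                      batch_size = config$batch_size,
                      learning_rate = config$learning_rate,
                      dropout_rate = config$dropout_rate,
                      n_filters = config$n_filters,
                      kernel_size = config$kernel_size,
                      n_epochs = config$n_epochs,
                      maxnorm_constraint = config$maxnorm_constraint,
                      optimizer = config$optimizer, embedding = emb_cfg,
                      seed = seed)
    train_cnn(train_docs, emb, cfg, imbalance = imb)
  }
}

#' Run a hyperparameter search
#'
#' Trains one member model per trial on a stratified training split and
#' scores validation AUROC.  Samplers: `"random"` (default), `"tpe"`
#' (tree-structured Parzen estimator), or `grid = TRUE` for exhaustive
#' enumeration of the finite SVM domains.
#'
#' @param corpus Labeled `token_document`s.
#' @param model `"cnn_wholeword"`, `"cnn_subword"` or `"svm"`.
#' @param space A [search_space()] (possibly with reduced domains).
#' @param budget Number of trials (ignored when `grid = TRUE`).
#' @param sampler `"random"` or `"tpe"`.
#' @param grid Exhaustively enumerate all finite domains (SVM-style grid
#'   search); every domain must be categorical.
#' @param validation_fraction Stratified holdout fraction (default 0.2).
#' @param trial_overrides Named list of values fixed across trials
#'   (overriding sampled ones) — used for reduced-budget searches.
#' @param seed Integer seed driving the split and the trial seed-stream.
#' @return List with `best` (a trial: `configuration`, `auroc`, `seed`,
#'   `status`), `trials` (full log) and `model`.
#' @export
run_search <- function(corpus, model = c("svm", "cnn_wholeword",
                                         "cnn_subword"),
                       space = search_space(), budget = 10L,
                       sampler = c("random", "tpe"), grid = FALSE,
                       validation_fraction = 0.2, trial_overrides = list(),
                       seed = 1L) {
  model <- match.arg(model)
  sampler <- match.arg(sampler)
  labels <- check_labeled(corpus)
  val_idx <- stratified_split(labels, validation_fraction,
                              derive_seed(seed, "split"))
  train_docs <- corpus[-val_idx]
  val_docs <- corpus[val_idx]
  val_labels <- labels[val_idx]
  doms <- space[[model]]

  configs <- list()
  if (grid) {
    for (dom in doms)
      if (dom$type != "categorical")
        stop2("grid search requires finite (categorical) domains")
    counts <- vapply(doms, function(d) length(d$values), integer(1))
    idx_grid <- do.call(expand.grid, lapply(counts, seq_len))
    configs <- lapply(seq_len(nrow(idx_grid)), function(r) {
      cfg <- list()
      for (j in seq_along(doms))
        cfg[[names(doms)[j]]] <- doms[[j]]$values[[idx_grid[r, j]]]
      cfg
    })
  }

  n_trials <- if (grid) length(configs) else budget
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    trial_seed <- seed * 1000L + i
    config <- if (grid) {
      configs[[i]]
    } else if (sampler == "tpe" && i > 10L) {
      set.seed(trial_seed)
      tpe_propose(doms, trials[seq_len(i - 1L)])
    } else {
      sample_configuration(doms, trial_seed)
    }
    config <- utils::modifyList(config, trial_overrides)
    fit <- tryCatch(apply_trial_config(model, config, train_docs, trial_seed),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      trials[[i]] <- list(configuration = config, auroc = NA_real_,
                          seed = trial_seed, status = "failed",
                          message = conditionMessage(fit))
      next
    }
    au <- roc_auc(predict(fit, val_docs), val_labels)
    trials[[i]] <- list(configuration = config, auroc = au,
                        seed = trial_seed, status = "completed")
  }
  ok <- !vapply(trials, function(t) is.na(t$auroc), logical(1))
  if (!any(ok)) stop2("all ", n_trials, " trials failed")
  best <- trials[ok][[which.max(vapply(trials[ok], `[[`, numeric(1),
                                       "auroc"))]]
  list(best = best, trials = trials, model = model)
}

#' Write a trial log as JSON lines
#'
#' @param result A [run_search()] result.
#' @param path Output path (one JSON object per trial per line).
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(result, path) {
  lines <- vapply(result$trials, function(tr)
    as.character(jsonlite::toJSON(tr, auto_unbox = TRUE, digits = NA)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
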