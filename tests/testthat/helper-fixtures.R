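# in-code fixtures shared across test files

make_doc <- function(id, tokens, label = NA_integer_) {
  structure(list(record_id = as.character(id), tokens = as.character(tokens),
                 source_label = label),
            class = "token_document")
}

# labeled toy corpus: positives carry a signal token, negatives a decoy
separable_docs <- function(n = 60, seed = 1, signal = "clusterrand",
                           decoy = "placebo") {
  set.seed(seed)
  filler <- paste0("w", letters[1:12])
  lapply(seq_len(n), function(i) {
    lab <- as.integer(i <= n / 2)
    toks <- sample(filler, 8, replace = TRUE)
    toks <- c(if (lab == 1) signal else decoy, toks)
    make_doc(paste0("d", i), sample(toks), lab)
  })
}

# reduced-size model configurations used for fast end-to-end tests
tiny_embedding <- function(method, seed = 1)
  embedding_config(method, dim = 16L, epochs = 2L, min_count = 2L,
                   seed = seed)

tiny_cnn <- function(variant, seed = 1, max_length = 80L)
  cnn_config(variant, max_length = max_length, n_filters = 16L, n_epochs = 2L,
             batch_size = 16L, learning_rate = 0.003, dropout_rate = 0.2,
             vocab_cap = 2000L, embedding = tiny_embedding(variant, seed),
             seed = seed)

tiny_svm <- function(seed = 1)
  svm_config(max_features = 1500L, seed = seed)

# one small fitted screener, shared (memoized) across test files
fixture_screener <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(n_records = 500, seed = 101)
      corp <- generate_corpus(cfg)
      cache <<- crt_screener(
        corp,
        cnn_wholeword = tiny_cnn("wholeword"),
        cnn_subword = tiny_cnn("subword"),
        svm = tiny_svm(),
        validation_fraction = 0.2,
        bootstrap = bootstrap_config(n_replicates = 200L, seed = 1L),
        seed = 11L)
    }
    cache
  }
})

fixture_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_corpus(generator_config(n_records = 500, seed = 101))
    cache
  }
})
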