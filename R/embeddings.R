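#' Embedding training configuration
#'
#' Controls the unsupervised word-representation trainer.  Two methods are
#' supported: `"wholeword"` (one vector per vocabulary word; unseen words map
#' to the zero vector) and `"subword"` (a word's vector is composed from the
#' word and its character n-grams, so unseen words still get a meaningful
#' vector from their n-grams).  The defaults pin the published training
#' choices: 100 dimensions, 10 iterations, skip-gram architecture.
#'
#' @param method `"wholeword"` or `"subword"`.
#' @param dim Vector dimensionality (default 100).
#' @param epochs Training iterations over the corpus (default 10).
#' @param architecture `"skipgram"` (default) or `"cbow"`.
#' @param window Maximum context window half-width (default 5).
#' @param min_count Minimum corpus frequency for a word to enter the
#'   vocabulary (default 2).
#' @param negative_samples Negative samples per positive pair (default 5).
#' @param subword_ngram_range Length-2 integer vector of character n-gram
#'   sizes, used only by the subword method (default `c(3, 5)`).
#' @param learning_rate Initial learning rate, linearly decayed (default
#'   0.05 for CBOW-style updates, 0.025 for skip-gram).
#' @param seed Integer seed; training is single-threaded and fully
#'   reproducible under a fixed seed.
#' @return An object of class `"embedding_config"`.
#' @export
embedding_config <- function(method = c("wholeword", "subword"), dim = 100L,
                             epochs = 10L,
                             architecture = c("skipgram", "cbow"),
                             window = 5L, min_count = 2L,
                             negative_samples = 5L,
                             subword_ngram_range = c(3L, 5L),
                             learning_rate = NULL, seed = 1L) {
  method <- match.arg(method)
  architecture <- match.arg(architecture)
  stopifnot(dim > 0, epochs > 0, window > 0, min_count >= 1,
            negative_samples >= 1, length(subword_ngram_range) == 2,
            subword_ngram_range[1] <= subword_ngram_range[2])
  learning_rate <- learning_rate %||%
    (if (architecture == "skipgram") 0.025 else 0.05)
  structure(list(method = method, dim = as.integer(dim),
                 epochs = as.integer(epochs), architecture = architecture,
                 window = as.integer(window), min_count = as.integer(min_count),
                 negative_samples = as.integer(negative_samples),
                 subword_ngram_range = as.integer(subword_ngram_range),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "embedding_config")
}

# character n-grams of a word bounded by "<" and ">"
char_ngrams <- function(token, range) {
  w <- paste0("<", token, ">")
  nc <- nchar(w)
  out <- character(0)
  for (n in range[1]:range[2]) {
    if (n > nc) break
    out <- c(out, substring(w, 1:(nc - n + 1), n:nc))
  }
  unique(out)
}

#' Train word embeddings on a token corpus
#'
#' Runs the seeded, single-threaded skip-gram (or CBOW) trainer with
#' negative sampling over the corpus.  Vocabulary order is deterministic:
#' frequency-descending with lexicographic tie-break.
#'
#' @param corpus List of `token_document`s (see [preprocess_citation()]).
#' @param cfg An [embedding_config()].
#' @return An object of class `"embedding_model"` with elements
#'   `vocabulary` (token -> row index), `vectors` (|V| x dim matrix,
#'   rownames are tokens), `method`, `cfg`, and for the subword method
#'   `ngram_vocabulary` and `ngram_vectors`.
#' @export
train_embeddings <- function(corpus, cfg = embedding_config()) {
  if (!length(corpus)) stop2("empty corpus")
  tokens <- unlist(lapply(corpus, `[[`, "tokens"), use.names = FALSE)
  if (!length(tokens)) stop2("corpus contains no tokens")
  tab <- table(tokens)
  tab <- tab[tab >= cfg$min_count]
  if (!length(tab)) stop2("no token meets min_count = ", cfg$min_count)
  ord <- order(-as.integer(tab), names(tab))
  vocab <- names(tab)[ord]
  counts <- as.numeric(tab)[ord]
  index <- setNames(seq_along(vocab), vocab)

  docs <- lapply(corpus, function(d) {
    ids <- unname(index[d$tokens])
    as.integer(ids[!is.na(ids)])
  })
  docs <- docs[vapply(docs, length, integer(1)) > 0]
  if (!length(docs)) stop2("no document retains any in-vocabulary token")

  subword <- cfg$method == "subword"
  if (subword) {
    ngram_lists <- lapply(vocab, char_ngrams, range = cfg$subword_ngram_range)
    ngram_vocab <- sort(unique(unlist(ngram_lists, use.names = FALSE)))
    ngram_index <- setNames(seq_along(ngram_vocab), ngram_vocab)
    ngram_ids <- lapply(ngram_lists, function(g) as.integer(ngram_index[g]))
  } else {
    ngram_vocab <- character()
    ngram_ids <- list()
  }

  fit <- cpp_train_embeddings(
    docs, length(vocab), counts, cfg$dim, cfg$window, cfg$epochs,
    cfg$negative_samples, cfg$architecture == "cbow", ngram_ids,
    length(ngram_vocab), cfg$learning_rate, cfg$seed)

  vectors <- fit$vectors
  rownames(vectors) <- vocab
  out <- list(vocabulary = index, vectors = vectors, method = cfg$method,
              cfg = cfg)
  if (subword) {
    out$ngram_vocabulary <- setNames(seq_along(ngram_vocab), ngram_vocab)
    out$ngram_vectors <- fit$ngram_vectors
    rownames(out$ngram_vectors) <- ngram_vocab
  }
  structure(out, class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat("<embedding_model> method=", x$method, " |V|=", length(x$vocabulary),
      " dim=", ncol(x$vectors), "\n", sep = "")
  invisible(x)
}

#' Look up the vector of a token
#'
#' In-vocabulary tokens return their trained row.  Out-of-vocabulary
#' behaviour depends on the method: the whole-word model returns the zero
#' vector (contributing nothing to downstream convolution sums); the subword
#' model returns the mean of the vectors of the token's known character
#' n-grams (zero if none are known).
#'
#' @param m An `embedding_model`.
#' @param token A single token.
#' @return Numeric vector of length `dim`.
#' @export
embed_token <- function(m, token) {
  i <- m$vocabulary[token]
  if (!is.na(i)) return(m$vectors[i, ])
  if (m$method == "wholeword") return(numeric(ncol(m$vectors)))
  grams <- char_ngrams(token, m$cfg$subword_ngram_range)
  ids <- m$ngram_vocabulary[grams]
  ids <- ids[!is.na(ids)]
  if (!length(ids)) return(numeric(ncol(m$vectors)))
  colMeans(m$ngram_vectors[ids, , drop = FALSE])
}
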