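#' Build the token-index encoder for the convolutional models
#'
#' Retains the `vocab_cap` most frequent corpus tokens (frequency ties broken
#' lexicographically), assigning indices `1..|V|`; index 0 is reserved for
#' padding and unknown tokens.
#'
#' @param corpus List of `token_document`s.
#' @param vocab_cap Maximum vocabulary size (default 5000).
#' @param max_length Fixed encoded sequence length (default 300).
#' @return An object of class `"sequence_encoder"`.
#' @export
build_sequence_encoder <- function(corpus, vocab_cap = 5000L,
                                   max_length = 300L) {
  if (!length(corpus)) stop2("empty corpus")
  tokens <- unlist(lapply(corpus, `[[`, "tokens"), use.names = FALSE)
  tab <- table(tokens)
  ord <- order(-as.integer(tab), names(tab))
  vocab <- head(names(tab)[ord], vocab_cap)
  structure(list(vocabulary = setNames(seq_along(vocab), vocab),
                 max_length = as.integer(max_length),
                 vocab_cap = as.integer(vocab_cap), pad_index = 0L),
            class = "sequence_encoder")
}

#' Encode a token document as a fixed-length index sequence
#'
#' Tokens map to their vocabulary indices (unknown tokens to 0); sequences
#' are right-padded with 0 to `max_length` or truncated keeping the leading
#' tokens (the title comes first in preprocessing, and carries the strongest
#' design signal).
#'
#' @param enc A [build_sequence_encoder()] result.
#' @param doc A `token_document`.
#' @return Integer vector of length `enc$max_length`.
#' @export
encode_sequence <- function(enc, doc) {
  ids <- unname(enc$vocabulary[doc$tokens])
  ids[is.na(ids)] <- 0L
  n <- length(ids)
  L <- enc$max_length
  if (n >= L) ids[seq_len(L)] else c(ids, rep(0L, L - n))
}

encode_corpus <- function(enc, corpus) {
  t(vapply(corpus, function(d) as.integer(encode_sequence(enc, d)),
           integer(enc$max_length)))
}

doc_ngrams <- function(tokens, ngram_range) {
  n_tok <- length(tokens)
  out <- character(0)
  for (n in ngram_range[1]:ngram_range[2]) {
    if (n_tok < n) break
    if (n == 1L) {
      out <- c(out, tokens)
    } else {
      idx <- seq_len(n_tok - n + 1L)
      grams <- tokens[idx]
      for (j in 2:n) grams <- paste(grams, tokens[idx + j - 1L])
      out <- c(out, grams)
    }
  }
  out
}

#' Fit a TF-IDF n-gram model
#'
#' Builds the n-gram vocabulary (adjacent post-preprocessing tokens joined by
#' single spaces) and inverse-document-frequency weights
#' `idf(g) = ln((1 + n_docs) / (1 + df(g))) + 1` — the smoothed logarithmic
#' variant, so that a term present in every document receives the minimum
#' weight 1.
#'
#' @param corpus List of `token_document`s.
#' @param ngram_range Length-2 integer vector, default `c(1, 2)` (unigrams
#'   and bigrams).
#' @param max_features Optional cap on the n-gram vocabulary: the most
#'   frequent n-grams by total count are kept (ties lexicographic).
#' @param use_idf If `FALSE`, weights are raw counts (bag-of-words mode);
#'   l2 normalization still applies.
#' @return An object of class `"tfidf_model"` with `ngram_vocabulary`,
#'   `idf`, `ngram_range`, `norm = "l2"`.
#' @export
fit_tfidf <- function(corpus, ngram_range = c(1L, 2L), max_features = NULL,
                      use_idf = TRUE) {
  if (!length(corpus)) stop2("empty corpus")
  per_doc <- lapply(corpus, function(d) doc_ngrams(d$tokens, ngram_range))
  df_tab <- table(unlist(lapply(per_doc, unique), use.names = FALSE))
  if (!is.null(max_features) && length(df_tab) > max_features) {
    tf_tab <- table(unlist(per_doc, use.names = FALSE))
    ord <- order(-as.integer(tf_tab), names(tf_tab))
    keep <- head(names(tf_tab)[ord], max_features)
    df_tab <- df_tab[names(df_tab) %in% keep]
  }
  grams <- sort(names(df_tab))
  df <- as.numeric(df_tab[grams])
  n_docs <- length(corpus)
  idf <- if (use_idf) log((1 + n_docs) / (1 + df)) + 1 else rep(1, length(df))
  structure(list(ngram_vocabulary = setNames(seq_along(grams), grams),
                 idf = setNames(idf, grams),
                 ngram_range = as.integer(ngram_range), norm = "l2",
                 use_idf = use_idf),
            class = "tfidf_model")
}

#' Transform documents into TF-IDF vectors
#'
#' Each entry is `tf(g, doc) * idf(g)` (raw in-document count times inverse
#' document frequency), followed by l2 normalization.  N-grams unseen at fit
#' time are ignored; an empty or all-unseen document yields the zero vector
#' (no normalization applied).
#'
#' @param m A fitted [fit_tfidf()] model.
#' @param docs A single `token_document` or a list of them.
#' @return A sparse `dgCMatrix` with one row per document and one column per
#'   n-gram in the fitted vocabulary.
#' @export
transform_tfidf <- function(m, docs) {
  if (inherits(docs, "token_document")) docs <- list(docs)
  nV <- length(m$ngram_vocabulary)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in seq_along(docs)) {
    grams <- doc_ngrams(docs[[i]]$tokens, m$ngram_range)
    ids <- m$ngram_vocabulary[grams]
    ids <- ids[!is.na(ids)]
    if (!length(ids)) next
    cnt <- table(ids)
    j <- as.integer(names(cnt))
    v <- as.numeric(cnt) * m$idf[j]
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
    ii <- c(ii, rep(i, length(j))); jj <- c(jj, j); xx <- c(xx, v)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(docs), nV),
                       dimnames = list(NULL, names(m$ngram_vocabulary)))
}
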