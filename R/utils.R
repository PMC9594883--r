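#' @useDynLib crtscreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats predict quantile rbinom rnbinom rpois runif setNames
#' @importFrom utils head read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

# deterministic child seeds: small integers derived from a user seed so that
# independent stages (embeddings, each member model, splits, bootstrap) get
# distinct but reproducible streams; kept below 2^31
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2011L + match(
    stream,
    c("split", "embed_wholeword", "embed_subword", "cnn_wholeword",
      "cnn_subword", "svm", "subsample", "bootstrap", "search", "generator"),
    nomatch = 0L) * 7919L + 17L
}

is_binary01 <- function(x) all(x %in% c(0L, 1L))
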