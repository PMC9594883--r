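#' Default English stopword list
#'
#' The fixed stopword list shipped with the package (one lowercase token per
#' line under `extdata/`).  Shipping a versioned list rather than relying on
#' an external resource keeps preprocessing byte-reproducible.
#'
#' @return Character vector of lowercase stopword tokens.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "crtscreen")
  readLines(path, warn = FALSE)
}

# headings recognized in structured abstracts; matching is canonical
# (singular/plural variants collapse onto these)
RECOGNIZED_HEADINGS <- c("OBJECTIVE", "OBJECTIVES", "BACKGROUND", "METHOD",
                         "METHODS", "RESULT", "RESULTS", "DISCUSSION",
                         "CONCLUSION", "CONCLUSIONS", "INTERPRETATION",
                         "FINDINGS", "MATERIALS AND METHODS", "DESIGN",
                         "SETTING", "PARTICIPANTS", "INTERVENTIONS",
                         "IMPORTANCE", "PURPOSE", "AIM", "AIMS")

#' Preprocessing configuration
#'
#' @param stopword_list Set of lowercase tokens removed after tokenization;
#'   defaults to the shipped English list ([default_stopwords()]).
#' @param sections_to_drop Uppercase canonical headings of structured-abstract
#'   sections whose text is removed before tokenization.  Discussion and
#'   conclusion sections rarely describe the study design, so they are
#'   dropped by default.
#' @param min_token_length Minimum token length kept (default 1).
#' @return An object of class `"preprocess_config"`.
#' @export
preprocess_config <- function(stopword_list = default_stopwords(),
                              sections_to_drop = c("DISCUSSION", "CONCLUSION",
                                                   "CONCLUSIONS"),
                              min_token_length = 1L) {
  stopifnot(min_token_length >= 1L)
  structure(list(stopword_list = tolower(stopword_list),
                 sections_to_drop = toupper(sections_to_drop),
                 min_token_length = as.integer(min_token_length)),
            class = "preprocess_config")
}

#' Remove selected sections from a structured abstract
#'
#' A structured abstract carries labeled sections whose headings appear as
#' line-initial or sentence-initial UPPERCASE words followed by `":"` (e.g.
#' `"BACKGROUND: ... METHODS: ..."`).  Text belonging to any section whose
#' heading matches `sections_to_drop` is removed, from the heading up to the
#' next recognized heading or the end of the text.  Unstructured abstracts
#' pass through unchanged.
#'
#' @param abstract Abstract text.
#' @param sections_to_drop Uppercase canonical heading names to drop.
#' @return The abstract with the dropped sections removed.
#' @export
strip_structured_sections <- function(abstract,
                                      sections_to_drop = c("DISCUSSION",
                                                           "CONCLUSION",
                                                           "CONCLUSIONS")) {
  if (is.na(abstract) || abstract == "") return(abstract %||% "")
  heading_re <- "(^|[.!?]\\s+|\\n\\s*)([A-Z][A-Z]+(?: [A-Z]+)*)\\s*:"
  m <- gregexpr(heading_re, abstract, perl = TRUE)[[1]]
  if (m[1] == -1) return(abstract)
  starts <- as.integer(m)
  caps <- attr(m, "capture.start")
  caplen <- attr(m, "capture.length")
  headings <- substring(abstract, caps[, 2], caps[, 2] + caplen[, 2] - 1)
  recognized <- headings %in% RECOGNIZED_HEADINGS
  if (!any(recognized)) return(abstract)
  h_start <- caps[recognized, 2]
  h_name <- headings[recognized]
  # section i spans from its heading to just before the next recognized one
  n <- length(h_start)
  seg_end <- c(h_start[-1] - 1, nchar(abstract))
  drop <- toupper(h_name) %in% toupper(sections_to_drop)
  if (!any(drop)) return(abstract)
  keep_mask <- rep(TRUE, nchar(abstract))
  for (i in which(drop)) keep_mask[h_start[i]:seg_end[i]] <- FALSE
  chars <- strsplit(abstract, "", fixed = TRUE)[[1]]
  out <- paste(chars[keep_mask], collapse = "")
  trimws(out)
}

#' Clean citation text for tokenization
#'
#' Applies the fixed cleaning rules in a fixed order: Unicode NFKC-style
#' transliteration to ASCII, lowercasing, removal of bracket and parenthesis
#' characters (their content is kept), removal of whole whitespace-delimited
#' words containing any digit (so `"covid-19"` disappears entirely, before
#' hyphens are split), replacement of remaining punctuation by spaces, and
#' whitespace normalization.
#'
#' @param raw Free text.
#' @return Cleaned lowercase text containing only alphabetic words.
#' @export
clean_text <- function(raw) {
  if (length(raw) == 0 || is.na(raw)) return("")
  x <- enc2utf8(as.character(raw))
  # transliterate accents to ASCII, drop what cannot be represented
  x <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT", sub = " ")
  if (is.na(x)) x <- iconv(enc2utf8(as.character(raw)), from = "UTF-8",
                           to = "ASCII", sub = " ")
  x <- tolower(x)
  x <- gsub("[][(){}<>]", "", x)                 # brackets: keep content
  words <- strsplit(x, "\\s+")[[1]]
  words <- words[!grepl("[0-9]", words)]          # digit-bearing words out
  x <- paste(words, collapse = " ")
  x <- gsub("[^a-z ]", " ", x)                    # punctuation -> space
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Preprocess a citation into its token document
#'
#' The deterministic pipeline feeding every model: structured-abstract
#' section stripping, concatenation of title + abstract + keywords +
#' subject headings, [clean_text()], whitespace tokenization, stopword
#' removal, and a minimum-length filter.
#'
#' @param c A [citation_record()] record.
#' @param cfg A [preprocess_config()].
#' @return An object of class `"token_document"`: `record_id`, `tokens`
#'   (ordered lowercase alphabetic tokens), `source_label`.
#' @export
preprocess_citation <- function(c, cfg = preprocess_config()) {
  abstract <- strip_structured_sections(c$abstract, cfg$sections_to_drop)
  full <- paste(c(c$title, abstract, c$keywords, c$subject_headings),
                collapse = " ")
  cleaned <- clean_text(full)
  tokens <- if (cleaned == "") character() else strsplit(cleaned, " ",
                                                         fixed = TRUE)[[1]]
  tokens <- tokens[!(tokens %in% cfg$stopword_list)]
  tokens <- tokens[nchar(tokens) >= cfg$min_token_length]
  structure(list(record_id = c$record_id, tokens = tokens,
                 source_label = c$label %||% NA_integer_),
            class = "token_document")
}

#' @export
print.token_document <- function(x, ...) {
  cat("<token_document ", x$record_id, "> ", length(x$tokens), " tokens\n",
      sep = "")
  invisible(x)
}

# vectorized convenience used throughout the package
preprocess_corpus <- function(citations, cfg = preprocess_config()) {
  lapply(citations, preprocess_citation, cfg = cfg)
}

token_document <- function(record_id, tokens, label = NA_integer_) {
  structure(list(record_id = as.character(record_id),
                 tokens = as.character(tokens),
                 source_label = label),
            class = "token_document")
}
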