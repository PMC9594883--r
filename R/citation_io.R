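#' Construct a bibliographic citation record
#'
#' A citation is the unit of screening: the bibliographic fields of one
#' article (title, abstract, author keywords, controlled-vocabulary subject
#' headings) plus an optional binary label (1 = report of a cluster
#' randomized trial, 0 = not).
#'
#' @param record_id Opaque identifier, unique within a corpus.
#' @param title,abstract Free text; at least one must be non-empty for the
#'   record to be screenable.
#' @param keywords Character vector of author keywords.
#' @param subject_headings Character vector of controlled-vocabulary terms
#'   (MeSH/Emtree).
#' @param label Optional integer label, exactly 0 or 1, or `NA`.
#' @return An object of class `"citation_record"`.
#' @export
citation_record <- function(record_id, title = "", abstract = "",
                     keywords = character(), subject_headings = character(),
                     label = NA_integer_) {
  if (!is.na(label) && !label %in% c(0L, 1L))
    stop2("label must be 0, 1 or NA for record ", record_id)
  structure(
    list(record_id = as.character(record_id),
         title = as.character(title %||% ""),
         abstract = as.character(abstract %||% ""),
         keywords = as.character(keywords),
         subject_headings = as.character(subject_headings),
         label = if (is.na(label)) NA_integer_ else as.integer(label)),
    class = "citation_record")
}

#' @export
print.citation_record <- function(x, ...) {
  cat("<citation ", x$record_id, "> ", substr(x$title, 1, 60),
      if (nchar(x$title) > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

citation_labels <- function(citations) {
  vapply(citations, function(c) c$label %||% NA_integer_, integer(1))
}

# case-insensitive auto-detection of the usual export column names
detect_columns <- function(cols) {
  lc <- tolower(cols)
  pick <- function(cands) {
    i <- which(lc %in% cands)
    if (length(i)) cols[i[1]] else NA_character_
  }
  list(record_id = pick(c("record_id", "id", "pmid", "accession")),
       title = pick("title"),
       abstract = pick("abstract"),
       keywords = pick(c("keywords", "keyword", "author_keywords")),
       subject_headings = pick(c("subject_headings", "subject headings",
                                 "subject.headings", "mesh", "mesh_terms",
                                 "mh")),
       label = pick(c("label", "crt", "class")))
}

#' Read citation records from a CSV export
#'
#' Reads the comma-separated export format produced by bibliographic
#' databases: a header row plus one record per row.  Column names for the
#' standard fields are auto-detected case-insensitively
#' (`title`, `abstract`, `keywords`, `mesh`/`subject_headings`, `label`,
#' `id`/`record_id`) and can be overridden via `column_map`.  Keyword and
#' subject-heading cells packed as `"a; b; c"` are split on `";"`.
#'
#' @param path Path to the CSV file.
#' @param column_map Optional named list mapping the canonical field names
#'   (`title`, `abstract`, `keywords`, `subject_headings`, `label`,
#'   `record_id`) to column names in the file.
#' @param label_values Optional named vector mapping label strings to 0/1,
#'   e.g. `c(CRT = 1, nonCRT = 0)`.  By default labels must already be 0/1.
#' @param delimiter Field delimiter, default `","`.
#' @return A list of [citation_record()] records in file order.
#' @export
read_citations_csv <- function(path, column_map = NULL, label_values = NULL,
                               delimiter = ",") {
  if (!file.exists(path)) stop2("file not found: ", path)
  df <- read.csv(path, sep = delimiter, colClasses = "character",
                 check.names = FALSE, na.strings = character())
  auto <- detect_columns(names(df))
  map <- utils::modifyList(auto, as.list(column_map %||% list()))
  for (required in c("title", "abstract")) {
    if (is.na(map[[required]] %||% NA) || !(map[[required]] %in% names(df)))
      stop2("mandatory column not found: ", required,
            " (map it explicitly via column_map)")
  }
  n <- nrow(df)
  get <- function(field) {
    col <- map[[field]]
    if (is.null(col) || is.na(col) || !(col %in% names(df))) rep("", n)
    else df[[col]]
  }
  ids <- get("record_id")
  if (all(ids == "")) ids <- as.character(seq_len(n))
  labels_raw <- get("label")
  has_label <- !is.null(map$label) && !is.na(map$label) &&
    map$label %in% names(df)
  split_multi <- function(x) {
    if (x == "") character() else trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  }
  out <- vector("list", n)
  bad <- character()
  for (i in seq_len(n)) {
    lab <- NA_integer_
    if (has_label) {
      raw <- trimws(labels_raw[i])
      if (!is.null(label_values) && raw %in% names(label_values)) {
        lab <- as.integer(label_values[[raw]])
      } else if (raw %in% c("0", "1")) {
        lab <- as.integer(raw)
      } else if (raw != "") {
        bad <- c(bad, ids[i])
        next
      }
    }
    out[[i]] <- citation_record(ids[i], title = df[[map$title]][i],
                         abstract = df[[map$abstract]][i],
                         keywords = split_multi(get("keywords")[i]),
                         subject_headings = split_multi(get("subject_headings")[i]),
                         label = lab)
  }
  if (length(bad))
    stop2("unparseable label value(s) for record(s): ",
          paste(bad, collapse = ", "))
  out
}

#' Read citation records from a MEDLINE tagged export
#'
#' Parses the `.nbib`-style tagged format (`TI  - `, `AB  - `, `OT  - `,
#' `MH  - `; continuation lines indented).  Records are split on `PMID`
#' tags or blank lines; continuation lines are joined with single spaces.
#'
#' @param path Path to the tagged file.
#' @return A list of [citation_record()] records in file order.
#' @export
read_medline_tagged <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  tag_re <- "^([A-Z0-9]{1,4})\\s*- (.*)$"
  is_tag <- grepl(tag_re, lines)
  is_cont <- grepl("^\\s+\\S", lines)
  if (!any(is_tag)) stop2("no recognizable MEDLINE field tags in ", path)

  records <- list()
  current <- list()
  cur_tag <- NULL
  flush_record <- function(rec) {
    if (!length(rec)) return(NULL)
    val <- function(tag) {
      v <- unlist(rec[names(rec) == tag], use.names = FALSE)
      if (is.null(v)) character() else v
    }
    one <- function(tag) {
      v <- val(tag)
      if (length(v)) paste(v, collapse = " ") else ""
    }
    id <- one("PMID")
    citation_record(if (id != "") id else as.character(length(records) + 1L),
             title = one("TI"), abstract = one("AB"),
             keywords = val("OT"), subject_headings = val("MH"))
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (is_tag[i]) {
      tag <- sub(tag_re, "\\1", line)
      value <- sub(tag_re, "\\2", line)
      if (tag == "PMID" && length(current)) {
        records[[length(records) + 1L]] <- flush_record(current)
        current <- list()
      }
      current[[length(current) + 1L]] <- value
      names(current)[length(current)] <- tag
      cur_tag <- tag
    } else if (is_cont[i] && length(current)) {
      # continuation of the previous field, joined with a single space
      current[[length(current)]] <-
        paste(current[[length(current)]], trimws(line))
    } else if (trimws(line) == "" && length(current)) {
      records[[length(records) + 1L]] <- flush_record(current)
      current <- list()
      cur_tag <- NULL
    }
  }
  if (length(current)) records[[length(records) + 1L]] <- flush_record(current)
  records
}

#' Read citation records from an RIS export
#'
#' RIS records are delimited by `TY` (start) and `ER` (end) tags.  Field
#' precedence: `TI` over `T1` for the title, `AB` over `N2` for the
#' abstract; `KW` tags (repeatable) become keywords.
#'
#' @param path Path to the RIS file.
#' @return A list of [citation_record()] records in file order.
#' @export
read_ris <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  tag_re <- "^([A-Z][A-Z0-9])\\s*- ?(.*)$"
  records <- list()
  current <- NULL
  rec_index <- 0L
  for (line in lines) {
    if (!grepl(tag_re, line)) next
    tag <- sub(tag_re, "\\1", line)
    value <- trimws(sub(tag_re, "\\2", line))
    if (tag == "TY") {
      if (!is.null(current))
        stop2("RIS record ", rec_index, " has no ER terminator")
      rec_index <- rec_index + 1L
      current <- list()
    } else if (tag == "ER") {
      if (is.null(current))
        stop2("ER tag without a matching TY at record ", rec_index + 1L)
      one <- function(tags) {
        for (t in tags) {
          v <- unlist(current[names(current) == t], use.names = FALSE)
          if (length(v)) return(v[1])
        }
        ""
      }
      kw <- unlist(current[names(current) == "KW"], use.names = FALSE)
      id <- one(c("ID", "AN"))
      records[[length(records) + 1L]] <-
        citation_record(if (id != "") id else as.character(rec_index),
                 title = one(c("TI", "T1")), abstract = one(c("AB", "N2")),
                 keywords = if (is.null(kw)) character() else kw)
      current <- NULL
    } else if (!is.null(current)) {
      current[[length(current) + 1L]] <- value
      names(current)[length(current)] <- tag
    }
  }
  if (!is.null(current))
    stop2("RIS record ", rec_index, " has no ER terminator")
  records
}

#' Write screening results to CSV
#'
#' Writes one row per screened record, sorted by ensemble probability in
#' descending order (ties broken by `record_id` ascending) so a reviewer can
#' read from the top and stop when relevant records become unlikely.
#' Probabilities are written with 6 decimal places.
#'
#' @param results A `screening_results` data frame as returned by
#'   [predict.crt_screener()]: columns `record_id`, `probability`,
#'   `predicted_label`, plus one probability column per ensemble member.
#' @param path Output file path.
#' @return Invisibly, the sorted data frame that was written.
#' @export
write_results_csv <- function(results, path) {
  results <- as.data.frame(results)
  ord <- order(-results$probability, results$record_id)
  results <- results[ord, , drop = FALSE]
  out <- results
  num_cols <- setdiff(names(out)[vapply(out, is.numeric, logical(1))],
                      "predicted_label")
  for (cn in num_cols) out[[cn]] <- sprintf("%.6f", out[[cn]])
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop2("cannot write results to ", path, ": ",
                         conditionMessage(ok))
  invisible(results)
}
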