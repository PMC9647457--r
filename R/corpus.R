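#' Tokenize text into whole-word spans
#'
#' Splits text into maximal runs of word characters (letters and digits),
#' where internal hyphens and apostrophes join a single token, so
#' `"anti-coagulant"` is one token and `"hba1c"` is one token. Offsets are
#' 0-based, half-open, counted in Unicode code points; spans are
#' non-overlapping and strictly increasing, and interleaving the non-token
#' gaps with the token surfaces reconstructs the input exactly.
#'
#' @param text a single string.
#' @return data frame with columns `start`, `end` (integers, half-open) and
#'   `surface` (the exact substring `text[start:end]`).
#' @examples
#' tokenize("No TIA or CVA")
#' tokenize("anti-coagulant therapy")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(start = integer(), end = integer(),
                      surface = character(), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("[[:alnum:]]+(?:['’-][[:alnum:]]+)*", text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(empty)
  len <- attr(m, "match.length")
  start1 <- as.integer(m)
  data.frame(
    start = start1 - 1L,
    end = start1 - 1L + len,
    surface = substring(text, start1, start1 + len - 1L),
    stringsAsFactors = FALSE
  )
}

#' Coerce to a corpus
#'
#' A corpus is an ordered data frame of documents with columns `doc_id`,
#' `patient_id`, `doc_type`, `date` and `text`, ordered by
#' (`patient_id`, `date`, `doc_id`). A named character vector of texts is
#' accepted as a shorthand (names become `doc_id`s).
#'
#' @param x a corpus data frame or a named character vector of document texts.
#' @param patient_id,doc_type,date defaults used for the character-vector
#'   shorthand.
#' @return a data frame of class `mednote_corpus`.
#' @export
as_corpus <- function(x, patient_id = "P01", doc_type = "note",
                      date = "2021-01-01") {
  if (inherits(x, "mednote_corpus")) return(x)
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- sprintf("D%02d", seq_along(x))
    x <- data.frame(doc_id = ids, patient_id = patient_id,
                    doc_type = doc_type, date = date, text = unname(x),
                    stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x),
            all(c("doc_id", "patient_id", "doc_type", "date", "text") %in%
                  names(x)))
  if (anyDuplicated(x$doc_id))
    stop("duplicate doc_id in corpus: ",
         paste(unique(x$doc_id[duplicated(x$doc_id)]), collapse = ", "))
  x <- x[order(x$patient_id, x$date, x$doc_id), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("mednote_corpus", "data.frame")
  x
}

#' Load a corpus of patient documents
#'
#' Reads a JSON manifest (`{"documents": [{"doc_id", "patient_id",
#' "doc_type", "date", "file"}, ...]}`) and the referenced UTF-8 plain-text
#' bodies. Documents are returned ordered by (`patient_id`, `date`,
#' `doc_id`) regardless of manifest order.
#'
#' @param path path to the manifest file, or a directory containing
#'   `manifest.json`.
#' @return a corpus data frame of class `mednote_corpus` (see [as_corpus()]).
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  if (!file.exists(path)) stop("corpus manifest not found: ", path)
  man <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  docs <- man$documents
  if (is.null(docs)) stop("manifest has no \"documents\" field: ", path)
  if (length(docs) == 0L) {
    return(as_corpus(data.frame(doc_id = character(), patient_id = character(),
                                doc_type = character(), date = character(),
                                text = character(), stringsAsFactors = FALSE)))
  }
  base <- dirname(path)
  rows <- lapply(docs, function(d) {
    for (f in c("doc_id", "patient_id", "doc_type", "date", "file")) {
      if (is.null(d[[f]])) stop("manifest entry missing field \"", f, "\"")
    }
    fp <- file.path(base, d$file)
    if (!file.exists(fp))
      stop("document file missing for doc_id ", d$doc_id, ": ", fp)
    txt <- paste(readLines(fp, encoding = "UTF-8", warn = FALSE),
                 collapse = "\n")
    data.frame(doc_id = d$doc_id, patient_id = d$patient_id,
               doc_type = d$doc_type, date = d$date, text = txt,
               stringsAsFactors = FALSE)
  })
  as_corpus(do.call(rbind, rows))
}

#' Write a corpus as manifest plus plain-text files
#'
#' @param corpus a corpus (see [as_corpus()]).
#' @param dir output directory (created if needed); bodies are written as
#'   `<doc_id>.txt` and the manifest as `manifest.json`.
#' @return the manifest path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  corpus <- as_corpus(corpus)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- paste0(corpus$doc_id, ".txt")
  for (i in seq_len(nrow(corpus))) {
    writeLines(corpus$text[i], file.path(dir, files[i]), useBytes = TRUE)
  }
  man <- list(documents = lapply(seq_len(nrow(corpus)), function(i) {
    list(doc_id = corpus$doc_id[i], patient_id = corpus$patient_id[i],
         doc_type = corpus$doc_type[i], date = corpus$date[i],
         file = files[i])
  }))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.mednote_corpus <- function(x, ...) {
  cat(sprintf("<corpus: %d document(s), %d patient(s)>\n", nrow(x),
              length(unique(x$patient_id))))
  if (nrow(x) > 0L) {
    show <- utils::head(x[, c("doc_id", "patient_id", "doc_type", "date")], 10L)
    show$chars <- nchar(utils::head(x$text, 10L))
    print.data.frame(show)
    if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more\n")
  }
  invisible(x)
}
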