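#' Load and validate a medical lexicon
#'
#' The lexicon is the knowledge base driving query expansion: each entry has a
#' canonical term, a set of synonyms, a set of abbreviation (short, long)
#' pairs, and a free-form category tag. The file format is a JSON array of
#' objects `{"canonical": str, "synonyms": [str], "abbreviations":
#' [{"short": str, "long": str}], "category": str}` (UTF-8,
#' order-insensitive). Entries are validated on load: canonical terms must be
#' non-empty, lowercase with single internal spaces (hyphens preserved),
#' unique across the file, and not members of their own synonym sets; long
#' forms must be non-empty and short forms at least 2 characters. Short forms
#' keep their stored case but are indexed case-insensitively.
#'
#' @param path path to a lexicon JSON file.
#' @return an object of class `medical_lexicon`: a list with `entries` (list
#'   of entry lists) and a term index mapping every normalized surface form
#'   (canonical, synonym, short form, long form, and each whole word of a
#'   long form) to the entries containing it.
#' @seealso [demo_lexicon()], [entries_for_term()], [write_lexicon()]
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("lexicon JSON parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.list(raw)) stop("lexicon must be a JSON array of entry objects")
  entries <- lapply(seq_along(raw), function(i) .validate_entry(raw[[i]], i))
  canon <- vapply(entries, `[[`, character(1L), "canonical")
  if (anyDuplicated(canon)) {
    stop("duplicate canonical term(s) in lexicon: ",
         paste(unique(canon[duplicated(canon)]), collapse = ", "))
  }
  .build_lexicon(entries)
}

# lexicon-side normalization: lowercase, squeeze spaces, keep hyphens
.lex_norm <- function(x) trimws(gsub("[[:space:]]+", " ", tolower(x)))

.validate_entry <- function(e, i) {
  fail <- function(msg) stop("lexicon entry ", i, ": ", msg, call. = FALSE)
  canonical <- e$canonical
  if (is.null(canonical) || !nzchar(canonical)) fail("empty canonical term")
  if (!identical(canonical, .lex_norm(canonical)))
    fail(sprintf("canonical %-30s is not normalized (lowercase, single spaces)",
                 shQuote(canonical)))
  synonyms <- unique(vapply(e$synonyms, .lex_norm, character(1L)))
  if (normalize_term(canonical) %in% normalize_term(synonyms))
    fail(sprintf("canonical %s listed among its own synonyms",
                 shQuote(canonical)))
  abbrev <- lapply(e$abbreviations, function(ab) {
    if (is.null(ab$short) || nchar(ab$short) < 2L)
      fail("abbreviation short form must be at least 2 characters")
    if (is.null(ab$long) || !nzchar(ab$long))
      fail("abbreviation long form must be non-empty")
    list(short = as.character(ab$short), long = .lex_norm(ab$long))
  })
  list(canonical = canonical, synonyms = synonyms, abbreviations = abbrev,
       category = if (is.null(e$category)) "" else as.character(e$category))
}

.build_lexicon <- function(entries) {
  index <- new.env(parent = emptyenv())
  add <- function(term, i) {
    key <- normalize_term(term)
    if (!nzchar(key)) return(invisible())
    index[[key]] <- unique(c(index[[key]], i))
  }
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    add(e$canonical, i)
    for (s in e$synonyms) add(s, i)
    for (ab in e$abbreviations) {
      add(ab$short, i)
      add(ab$long, i)
      for (w in strsplit(normalize_term(ab$long), " ", fixed = TRUE)[[1L]])
        add(w, i)
    }
  }
  structure(list(entries = entries, index = index),
            class = "medical_lexicon")
}

#' Construct a lexicon from entry lists (mainly for tests)
#'
#' @param entries list of entries, each a list with `canonical`, `synonyms`
#'   (character vector), `abbreviations` (list of `list(short=, long=)`), and
#'   `category`.
#' @return a `medical_lexicon`.
#' @export
lexicon <- function(entries = list()) {
  entries <- lapply(seq_along(entries), function(i)
    .validate_entry(entries[[i]], i))
  canon <- vapply(entries, `[[`, character(1L), "canonical")
  if (anyDuplicated(canon))
    stop("duplicate canonical term(s): ",
         paste(unique(canon[duplicated(canon)]), collapse = ", "))
  .build_lexicon(entries)
}

#' Write a lexicon in canonical JSON form
#'
#' Entries keep their order; synonyms and abbreviations are sorted, so that
#' load/save round-trips are byte-stable.
#'
#' @param lex a `medical_lexicon`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "medical_lexicon"))
  out <- lapply(lex$entries, function(e) {
    ab <- e$abbreviations
    if (length(ab) > 0L) {
      ord <- order(vapply(ab, `[[`, character(1L), "short"),
                   vapply(ab, `[[`, character(1L), "long"))
      ab <- ab[ord]
    }
    list(canonical = e$canonical,
         synonyms = as.list(sort(e$synonyms)),
         abbreviations = lapply(ab, function(a)
           list(short = a$short, long = a$long)),
         category = e$category)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Look up the lexicon entries containing a term
#'
#' Returns every entry in which the normalized term appears as the canonical
#' term, a synonym, an abbreviation short form (case-insensitively), the full
#' long form, or a whole word inside a long form — so `"heart"` reaches an
#' entry carrying the abbreviation pair (HF, heart failure). Unknown terms
#' yield an empty list.
#'
#' @param lex a `medical_lexicon`.
#' @param term a term, normalized as by [normalize_term()].
#' @return list of matching entries (possibly empty).
#' @export
entries_for_term <- function(lex, term) {
  stopifnot(inherits(lex, "medical_lexicon"))
  idx <- lex$index[[normalize_term(term)]]
  if (is.null(idx)) list() else lex$entries[sort(idx)]
}

#' The bundled demonstration lexicon
#'
#' A small fixture lexicon (not a medical authority) covering the worked
#' vocabulary used throughout the package — heart/cardiac/coronary/HF,
#' stroke/TIA/CVA, anticoagulant, smoking, respiratory infection terms — plus
#' about fifty filler entries of common conditions, drugs and investigations,
#' so that the synthetic-note generator has a realistic vocabulary.
#'
#' @return a `medical_lexicon`.
#' @export
demo_lexicon <- function() {
  read_lexicon(system.file("extdata", "demo_lexicon.json",
                           package = "mednotesearch", mustWork = TRUE))
}

#' @export
print.medical_lexicon <- function(x, ...) {
  n_syn <- sum(vapply(x$entries, function(e) length(e$synonyms), integer(1L)))
  n_ab <- sum(vapply(x$entries, function(e) length(e$abbreviations),
                     integer(1L)))
  cat(sprintf("<medical_lexicon: %d entries, %d synonyms, %d abbreviation pairs, %d indexed surface forms>\n",
              length(x$entries), n_syn, n_ab, length(ls(x$index))))
  invisible(x)
}
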