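#' Normalize a search term or token surface
#'
#' Canonical normalization used throughout the package before any comparison:
#' lowercase, hyphens removed, runs of whitespace collapsed to a single space,
#' leading/trailing whitespace stripped. Under this normalization
#' `"Anti-Coagulant"` and `"anticoagulant"` are the same term.
#'
#' @param x character vector of terms.
#' @return character vector of normalized terms, same length as `x`.
#' @examples
#' normalize_term("Anti-Coagulant")  # "anticoagulant"
#' normalize_term("  Heart   Failure ")
#' @export
normalize_term <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("-", "", x, fixed = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Levenshtein edit distance
#'
#' Unit-cost insertion/deletion/substitution distance between two strings,
#' computed over Unicode code points. Symmetric, zero iff the strings are
#' equal, and satisfies the triangle inequality.
#'
#' @param a,b character vectors (recycled to a common length).
#' @return integer vector of distances.
#' @examples
#' edit_distance("atriall", "atrial")  # 1
#' @export
edit_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- .lev1(a[i], b[i])
  out
}

# scalar Levenshtein, two-row dynamic programme
.lev1 <- function(a, b) {
  if (identical(a, b)) return(0L)
  sa <- strsplit(a, "", fixed = TRUE)[[1L]]
  sb <- strsplit(b, "", fixed = TRUE)[[1L]]
  na <- length(sa)
  nb <- length(sb)
  if (na == 0L) return(nb)
  if (nb == 0L) return(na)
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    cur[1L] <- i
    sub_cost <- as.integer(sb != sa[i])
    for (j in seq_len(nb)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L, prev[j] + sub_cost[j])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' Suffix-stripping stem of a normalized token
#'
#' A small deterministic stemmer in the Porter family: strips common English
#' inflectional suffixes (plural -s/-es/-ies, -ing, -ed, -er, -ly families,
#' final -e) and undoubles a trailing doubled consonant left by the strip.
#' Only equality of stems matters to the search: `"smoke"`, `"smokes"`,
#' `"smoker"` and `"smoking"` all share the stem `"smok"`. Tokens shorter
#' than 5 characters (typically abbreviations such as `"cva"`) are returned
#' unchanged, and a stem is never empty.
#'
#' @param token character vector of single normalized tokens.
#' @return character vector of stems.
#' @examples
#' stem_token(c("smoke", "smoker", "smoking", "smokes"))
#' stem_token("cva")
#' @export
stem_token <- function(token) {
  vapply(as.character(token), .stem1, character(1L), USE.NAMES = FALSE)
}

.stem1 <- function(t) {
  if (nchar(t) < 5L || grepl("[0-9]", t)) return(t)
  s <- t
  # plural family (one rule fires at most)
  if (grepl("ies$", s) && nchar(s) >= 5L) {
    s <- sub("ies$", "y", s)
  } else if (grepl("sses$", s)) {
    s <- sub("sses$", "ss", s)
  } else if (grepl("es$", s) && nchar(s) - 2L >= 3L) {
    s <- sub("es$", "", s)
  } else if (grepl("[^aeiousu]s$", s) && nchar(s) - 1L >= 3L) {
    # strip a plural -s only after a consonant, so stems like "diseas"
    # (from "disease") are stable under re-stemming
    s <- sub("s$", "", s)
  }
  # inflectional suffixes, longest first
  for (suf in c("ingly", "edly", "fully", "ing", "ed", "er")) {
    if (grepl(paste0(suf, "$"), s) && nchar(s) - nchar(suf) >= 3L) {
      s <- sub(paste0(suf, "$"), "", s)
      # undouble trailing consonant (running -> runn -> run), keep -ll/-ss
      if (grepl("([b-df-hj-np-rtv-z])\\1$", s)) s <- sub(".$", "", s)
      break
    }
  }
  if (grepl("e$", s) && nchar(s) - 1L >= 3L) s <- sub("e$", "", s)
  if (!nzchar(s)) t else s
}

#' Construct a fuzzy match policy
#'
#' The policy bands the allowed Levenshtein distance by the length of the
#' (normalized) target term: by default 0 edits for targets shorter than 5
#' characters, 1 edit for lengths 5-8, and 2 edits for longer targets.
#' Targets shorter than `min_fuzzy_length` only ever match exactly, which
#' protects short abbreviations ("CVA" must not fire on "CBA") while still
#' catching misspellings such as "atriall" for "atrial".
#'
#' @param breaks increasing integer vector of band lower bounds; a target of
#'   normalized length `L` falls in band `findInterval(L, breaks) + 1`.
#' @param distances non-decreasing integer vector of allowed edit distances,
#'   one per band (`length(breaks) + 1` values).
#' @param min_fuzzy_length minimum normalized target length for any non-exact
#'   match (>= 1).
#' @param case_sensitive logical; kept for completeness, the default (FALSE)
#'   matches the recall-oriented behaviour of the tool.
#' @return an object of class `"match_policy"`.
#' @examples
#' p <- match_policy()
#' fuzzy_equal("atriall", "atrial", p)
#' @export
match_policy <- function(breaks = c(5L, 9L), distances = c(0L, 1L, 2L),
                         min_fuzzy_length = 5L, case_sensitive = FALSE) {
  breaks <- as.integer(breaks)
  distances <- as.integer(distances)
  if (length(distances) != length(breaks) + 1L)
    stop("`distances` must have one more element than `breaks`")
  if (is.unsorted(breaks, strictly = TRUE))
    stop("`breaks` must be strictly increasing")
  if (is.unsorted(distances))
    stop("allowed edit distance must be non-decreasing in target length")
  if (min_fuzzy_length < 1L) stop("`min_fuzzy_length` must be >= 1")
  structure(
    list(breaks = breaks, distances = distances,
         min_fuzzy_length = as.integer(min_fuzzy_length),
         case_sensitive = isTRUE(case_sensitive)),
    class = "match_policy"
  )
}

#' @export
print.match_policy <- function(x, ...) {
  lo <- c(1L, x$breaks)
  hi <- c(x$breaks - 1L, Inf)
  cat("<match_policy>\n")
  for (i in seq_along(x$distances)) {
    cat(sprintf("  target length %s-%s: <= %d edit(s)\n", lo[i], hi[i],
                x$distances[i]))
  }
  cat(sprintf("  min fuzzy length: %d; case sensitive: %s\n",
              x$min_fuzzy_length, x$case_sensitive))
  invisible(x)
}

#' Allowed edit distance for a target of a given normalized length
#' @param policy a [match_policy()].
#' @param len integer vector of normalized target lengths.
#' @return integer vector of allowed distances.
#' @export
allowed_edits <- function(policy, len) {
  stopifnot(inherits(policy, "match_policy"))
  policy$distances[findInterval(len, policy$breaks) + 1L]
}

#' Fuzzy token equality under a match policy
#'
#' Tests whether a document token matches a target term after normalization,
#' allowing at most the policy's banded edit distance for the target's length.
#' Exact equality (after normalization) always matches; non-exact matches
#' require the target to be at least `min_fuzzy_length` characters.
#'
#' @param doc_token,target single strings (any case/hyphenation).
#' @param policy a [match_policy()].
#' @return list with elements `match` (logical) and `distance` (integer
#'   Levenshtein distance between the normalized strings).
#' @examples
#' fuzzy_equal("anti-coagulant", "anticoagulant", match_policy())
#' fuzzy_equal("HF", "of", match_policy())  # no: short tokens are exact-only
#' @export
fuzzy_equal <- function(doc_token, target, policy = match_policy()) {
  a <- normalize_term(doc_token)
  b <- normalize_term(target)
  if (!policy$case_sensitive) {
    # normalize_term already lowercases; nothing further
  } else {
    a <- gsub("-", "", trimws(gsub("[[:space:]]+", " ", doc_token)))
    b <- gsub("-", "", trimws(gsub("[[:space:]]+", " ", target)))
  }
  if (identical(a, b)) return(list(match = TRUE, distance = 0L))
  d <- .lev1(a, b)
  len <- nchar(b)
  ok <- len >= policy$min_fuzzy_length && d <= allowed_edits(policy, len)
  list(match = ok, distance = d)
}

#' Whole-word exact string search (the baseline)
#'
#' The study's baseline search: the query matches only whole words (or, for
#' multi-word queries, contiguous runs of whole words), never prefixes or
#' substrings, with no stemming, fuzzy matching, or lexicon expansion.
#' Comparison is on [normalize_term()] forms, so case and hyphenation do not
#' matter, but `"anticoag"` finds nothing in a note containing
#' `"anticoagulant"`.
#'
#' @param query non-empty query string (may be multi-word).
#' @param corpus a corpus data frame (see [read_corpus()]) or anything
#'   accepted by [as_corpus()].
#' @return a data frame of token spans with columns `doc_id`, `start`, `end`
#'   (0-based, half-open, in code points) and `surface`, ordered by corpus
#'   document order then `start`.
#' @examples
#' corp <- as_corpus(c(d1 = "Heart rate normal. No heart failure."))
#' string_search("heart", corp)
#' @export
string_search <- function(query, corpus) {
  corpus <- as_corpus(corpus)
  qtok <- tokenize(normalize_term(query))
  if (nrow(qtok) == 0L) stop("`query` must contain at least one word")
  qwords <- normalize_term(qtok$surface)
  k <- length(qwords)
  res <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    toks <- tokenize(corpus$text[i])
    nt <- nrow(toks)
    if (nt < k) next
    norm <- normalize_term(toks$surface)
    hit <- rep(TRUE, nt - k + 1L)
    for (j in seq_len(k)) {
      hit <- hit & (norm[seq_len(nt - k + 1L) + j - 1L] == qwords[j])
    }
    at <- which(hit)
    if (length(at) == 0L) next
    res[[i]] <- data.frame(
      doc_id = corpus$doc_id[i],
      start = toks$start[at],
      end = toks$end[at + k - 1L],
      surface = substring(corpus$text[i], toks$start[at] + 1L,
                          toks$end[at + k - 1L]),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1L))])
  if (is.null(out)) {
    out <- data.frame(doc_id = character(), start = integer(),
                      end = integer(), surface = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
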