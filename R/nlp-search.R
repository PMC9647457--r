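#' Expand a query into its equivalent terms
#'
#' The first stage of NLP-enhanced search: the query is rewritten into the
#' set of terms that should be located in the text. The set always contains
#' the direct (normalized) query; for every lexicon entry reachable from the
#' query via [entries_for_term()], it further contains the entry's canonical
#' term and synonyms (kind `"synonym"`) and both sides of its abbreviation
#' pairs (kind `"abbreviation"`); and for single-word queries a word-form
#' marker (the query's stem) that enables stem-equality matching of
#' inflectional variants such as "smoker" for "smoke". Expansion is one hop:
#' synonyms of synonyms are not chased.
#'
#' @param query non-empty query string.
#' @param lex a `medical_lexicon`.
#' @return data frame with columns `surface` (normalized term; for
#'   `word_form` rows, the stem), `kind` (`direct`, `word_form`,
#'   `abbreviation`, `synonym`), `source_entry` (canonical term of the
#'   originating lexicon entry, or `NA` for `direct`, or `"stem"` for
#'   `word_form`), and `fuzzy` (whether edit-distance matching is allowed for
#'   this term; short abbreviation forms and stem markers are exact-only).
#'   One row per surface, keeping the highest-priority kind; rows ordered by
#'   kind priority then surface, so the expansion is deterministic.
#' @examples
#' ex <- expand_query("heart", demo_lexicon())
#' subset(ex, kind == "abbreviation")
#' @export
expand_query <- function(query, lex) {
  q <- normalize_term(query)
  if (!nzchar(q)) stop("`query` must be non-empty")
  rows <- list(data.frame(surface = q, kind = "direct",
                          source_entry = NA_character_, fuzzy = TRUE,
                          stringsAsFactors = FALSE))
  if (!grepl(" ", q, fixed = TRUE)) {
    rows[[length(rows) + 1L]] <- data.frame(
      surface = stem_token(q), kind = "word_form", source_entry = "stem",
      fuzzy = FALSE, stringsAsFactors = FALSE)
  }
  for (e in entries_for_term(lex, q)) {
    for (s in unique(c(e$canonical, e$synonyms))) {
      rows[[length(rows) + 1L]] <- data.frame(
        surface = normalize_term(s), kind = "synonym",
        source_entry = e$canonical, fuzzy = TRUE, stringsAsFactors = FALSE)
    }
    for (ab in e$abbreviations) {
      rows[[length(rows) + 1L]] <- data.frame(
        surface = normalize_term(c(ab$short, ab$long)),
        kind = "abbreviation", source_entry = e$canonical,
        fuzzy = c(FALSE, TRUE), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[nzchar(out$surface), , drop = FALSE]
  # a non-direct surface equal to the query adds nothing
  out <- out[out$kind == "direct" | out$kind == "word_form" |
               out$surface != q, , drop = FALSE]
  out <- out[order(.kind_rank(out$kind), out$surface, out$source_entry), ,
             drop = FALSE]
  out <- out[!duplicated(out$surface) | out$kind == "word_form", ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.kind_rank <- function(kind) {
  match(kind, c("direct", "word_form", "spelling_variant", "abbreviation",
                "synonym"))
}

#' NLP-enhanced search
#'
#' Locates all expansions of the query ([expand_query()]) in the corpus as
#' whole words or contiguous whole-word runs, allowing per-token fuzzy
#' matching under the edit-distance `policy` (exact-only for short
#' abbreviation forms) and stem-equality word-form matching. Each hit carries
#' provenance: the expanded term it matched, its kind (a fuzzy hit is
#' reclassified `spelling_variant`), the edit distance spent, and a
#' `highlight_class` of `"direct"` (an exact hit on the query itself) or
#' `"semantic"` (everything else) — the two highlight colours of the viewer.
#' When expansions hit overlapping spans, the longest span wins; ties prefer
#' direct > word_form > spelling_variant > abbreviation > synonym, then the
#' lowest edit distance.
#'
#' The span set of [string_search()] for the same query is always covered:
#' every baseline span lies inside some returned span.
#'
#' @param query non-empty query string.
#' @param corpus a corpus (see [as_corpus()]).
#' @param lex a `medical_lexicon`.
#' @param policy a [match_policy()].
#' @return data frame of class `mednote_matches` with columns `doc_id`,
#'   `start`, `end`, `surface`, `query`, `term`, `kind`, `source_entry`,
#'   `edit_distance`, `highlight_class`, ordered by corpus document order
#'   then `start`.
#' @examples
#' corp <- as_corpus(c(d1 = "No TIA or CVA.", d2 = "Has had a stroke."))
#' nlp_search("stroke", corp, demo_lexicon())
#' @export
nlp_search <- function(query, corpus, lex, policy = match_policy()) {
  corpus <- as_corpus(corpus)
  exp <- expand_query(query, lex)
  res <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    res[[i]] <- .match_doc(corpus$doc_id[i], corpus$text[i], query, exp,
                           policy)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1L))])
  if (is.null(out)) {
    out <- data.frame(doc_id = character(), start = integer(),
                      end = integer(), surface = character(),
                      query = character(), term = character(),
                      kind = character(), source_entry = character(),
                      edit_distance = integer(),
                      highlight_class = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("mednote_matches", "data.frame")
  out
}

# all candidate hits of all expansion terms within one document, then
# overlap resolution
.match_doc <- function(doc_id, text, query, exp, policy) {
  toks <- tokenize(text)
  nt <- nrow(toks)
  if (nt == 0L) return(NULL)
  norm <- normalize_term(toks$surface)
  stems <- stem_token(norm)
  cand <- list()
  for (r in seq_len(nrow(exp))) {
    surface <- exp$surface[r]
    kind <- exp$kind[r]
    if (kind == "word_form") {
      at <- which(stems == surface & !grepl(" ", norm, fixed = TRUE))
      for (a in at) {
        cand[[length(cand) + 1L]] <- list(first = a, last = a, dist = 0L,
                                          kind = "word_form", row = r)
      }
      next
    }
    words <- strsplit(surface, " ", fixed = TRUE)[[1L]]
    k <- length(words)
    if (nt < k) next
    allow_fuzzy <- exp$fuzzy[r]
    for (a in seq_len(nt - k + 1L)) {
      total <- 0L
      ok <- TRUE
      for (j in seq_len(k)) {
        tokn <- norm[a + j - 1L]
        w <- words[j]
        if (tokn == w) next
        if (!allow_fuzzy) { ok <- FALSE; break }
        if (abs(nchar(tokn) - nchar(w)) > allowed_edits(policy, nchar(w)) ||
            nchar(w) < policy$min_fuzzy_length) { ok <- FALSE; break }
        d <- .lev1(tokn, w)
        if (d > allowed_edits(policy, nchar(w))) { ok <- FALSE; break }
        total <- total + d
      }
      if (!ok) next
      cand[[length(cand) + 1L]] <- list(
        first = a, last = a + k - 1L, dist = total,
        kind = if (total > 0L) "spelling_variant" else kind, row = r)
    }
  }
  if (length(cand) == 0L) return(NULL)
  cf <- data.frame(
    first = vapply(cand, `[[`, integer(1L), "first"),
    last = vapply(cand, `[[`, integer(1L), "last"),
    dist = vapply(cand, `[[`, integer(1L), "dist"),
    kind = vapply(cand, `[[`, character(1L), "kind"),
    row = vapply(cand, `[[`, integer(1L), "row"),
    stringsAsFactors = FALSE
  )
  cf$start <- toks$start[cf$first]
  cf$end <- toks$end[cf$last]
  # longest span first, then kind priority, then distance, then position
  cf <- cf[order(-(cf$end - cf$start), .kind_rank(cf$kind), cf$dist,
                 cf$start), , drop = FALSE]
  keep <- logical(nrow(cf))
  taken_start <- integer(0)
  taken_end <- integer(0)
  for (i in seq_len(nrow(cf))) {
    if (!any(cf$start[i] < taken_end & cf$end[i] > taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, cf$start[i])
      taken_end <- c(taken_end, cf$end[i])
    }
  }
  cf <- cf[keep, , drop = FALSE]
  cf <- cf[order(cf$start), , drop = FALSE]
  data.frame(
    doc_id = doc_id,
    start = cf$start,
    end = cf$end,
    surface = substring(text, cf$start + 1L, cf$end),
    query = query,
    term = exp$surface[cf$row],
    kind = cf$kind,
    source_entry = exp$source_entry[cf$row],
    edit_distance = cf$dist,
    highlight_class = ifelse(cf$kind == "direct" & cf$dist == 0L,
                             "direct", "semantic"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.mednote_matches <- function(x, ...) {
  cat(sprintf("<matches: %d hit(s) in %d document(s)>\n", nrow(x),
              length(unique(x$doc_id))))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 20L))
  if (nrow(x) > 20L) cat("  ...", nrow(x) - 20L, "more\n")
  invisible(x)
}

#' Cluster matches into sentence-level mentions
#'
#' A mention is a maximal group of matches falling in the same sentence of
#' the same document (sentences delimited by `.`, `!`, `?` or newlines).
#' This is the unit in which the study counts "mentions": the phrase
#' "No TIA or CVA" contains two matched tokens but is one mention.
#'
#' @param matches a match table from [nlp_search()] or [string_search()].
#' @param corpus the corpus the matches refer to.
#' @return data frame with one row per mention: `doc_id`, `sentence` (index
#'   within the document), `n_matches`, `start`, `end` (covering span).
#' @seealso [count_mentions()]
#' @export
mentions <- function(matches, corpus) {
  corpus <- as_corpus(corpus)
  if (nrow(matches) == 0L) {
    return(data.frame(doc_id = character(), sentence = integer(),
                      n_matches = integer(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  sent_of <- function(text, starts) {
    # 0-based offsets of sentence boundaries
    b <- gregexpr("[.!?\n]+", text, perl = TRUE)[[1L]]
    if (b[1L] == -1L) return(rep(1L, length(starts)))
    ends <- as.integer(b) - 1L  # 0-based boundary starts
    findInterval(starts, ends) + 1L
  }
  matches$sentence <- NA_integer_
  for (d in unique(matches$doc_id)) {
    sel <- matches$doc_id == d
    text <- corpus$text[match(d, corpus$doc_id)]
    matches$sentence[sel] <- sent_of(text, matches$start[sel])
  }
  agg <- stats::aggregate(
    cbind(n_matches = start) ~ doc_id + sentence, data = matches, FUN = length)
  lo <- stats::aggregate(start ~ doc_id + sentence, data = matches, FUN = min)
  hi <- stats::aggregate(end ~ doc_id + sentence, data = matches, FUN = max)
  out <- merge(merge(agg, lo, by = c("doc_id", "sentence")), hi,
               by = c("doc_id", "sentence"))
  out <- out[order(match(out$doc_id, corpus$doc_id), out$sentence), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count sentence-level mentions
#' @inheritParams mentions
#' @return integer: the number of distinct mentions.
#' @export
count_mentions <- function(matches, corpus) nrow(mentions(matches, corpus))

#' Rank documents by match count
#'
#' The viewer's "retrieved subset of documents": documents with at least one
#' match, ordered by match count (descending), ties broken by corpus order.
#'
#' @param matches a match table.
#' @param corpus the corpus searched.
#' @return data frame with columns `doc_id`, `n_matches`.
#' @export
retrieve_documents <- function(matches, corpus) {
  corpus <- as_corpus(corpus)
  if (nrow(matches) == 0L) {
    return(data.frame(doc_id = character(), n_matches = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(matches$doc_id)
  out <- data.frame(doc_id = names(tab), n_matches = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_matches, match(out$doc_id, corpus$doc_id)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render highlighted matches for one document
#'
#' Produces either a plain-text bracket rendering (direct hits wrapped in
#' `[[D|...]]`, semantic hits in `[[S|...]]`) or an HTML rendering using
#' `<mark class="direct">` / `<mark class="semantic">`.
#' [strip_highlights()] on the output reproduces the document text exactly.
#'
#' @param matches a match table whose rows all belong to `doc`; spans must be
#'   non-overlapping (as produced by [nlp_search()]).
#' @param doc a single-row corpus data frame (one document).
#' @param format `"text"` or `"html"`.
#' @return a single string.
#' @export
render_highlights <- function(matches, doc, format = c("text", "html")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(doc), nrow(doc) == 1L)
  text <- doc$text
  n <- nchar(text)
  if (nrow(matches) > 0L) {
    if (!all(matches$doc_id == doc$doc_id))
      stop("matches refer to a different doc_id than `doc`")
    if (any(matches$start < 0L | matches$end > n | matches$start >=
              matches$end))
      stop("match span outside document text")
  }
  m <- matches[order(matches$start), , drop = FALSE]
  cls <- if (nrow(m) > 0L && "highlight_class" %in% names(m)) {
    m$highlight_class
  } else rep("direct", nrow(m))
  esc <- function(s) {
    if (format == "html") {
      s <- gsub("&", "&amp;", s, fixed = TRUE)
      s <- gsub("<", "&lt;", s, fixed = TRUE)
      s <- gsub(">", "&gt;", s, fixed = TRUE)
    }
    s
  }
  open <- function(class) {
    if (format == "html") sprintf("<mark class=\"%s\">", class)
    else if (class == "direct") "[[D|" else "[[S|"
  }
  close_ <- if (format == "html") "</mark>" else "]]"
  pieces <- character(0)
  pos <- 0L  # 0-based, chars emitted so far
  for (i in seq_len(nrow(m))) {
    if (m$start[i] < pos) stop("overlapping match spans cannot be rendered")
    pieces <- c(pieces,
                esc(substring(text, pos + 1L, m$start[i])),
                open(cls[i]),
                esc(substring(text, m$start[i] + 1L, m$end[i])),
                close_)
    pos <- m$end[i]
  }
  pieces <- c(pieces, esc(substring(text, pos + 1L, n)))
  paste(pieces, collapse = "")
}

#' Strip highlight markup
#'
#' Inverse of [render_highlights()]: removes the bracket or HTML markup (and
#' undoes HTML escaping), recovering the original document text.
#'
#' @param rendered string produced by [render_highlights()].
#' @param format `"text"` or `"html"` (must match the rendering).
#' @return the plain document text.
#' @export
strip_highlights <- function(rendered, format = c("text", "html")) {
  format <- match.arg(format)
  if (format == "text") {
    out <- gsub("\\[\\[[DS]\\|", "", rendered)
    out <- gsub("]]", "", out, fixed = TRUE)
  } else {
    out <- gsub("</?mark[^>]*>", "", rendered)
    out <- gsub("&lt;", "<", out, fixed = TRUE)
    out <- gsub("&gt;", ">", out, fixed = TRUE)
    out <- gsub("&amp;", "&", out, fixed = TRUE)
  }
  out
}

#' Write matches as JSON lines
#'
#' One JSON object per match with fields `doc_id`, `start`, `end`, `surface`,
#' `query`, `term`, `kind`, `edit_distance`, `highlight_class` — the span
#' report format of the command-line tool.
#'
#' @param matches a match table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(matches))) {
    writeLines(jsonlite::toJSON(as.list(matches[i, , drop = FALSE][1, ]),
                                auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}
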