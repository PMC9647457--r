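# small in-code fixtures shared across test files

mini_lexicon <- function() {
  lexicon(list(
    list(canonical = "heart",
         synonyms = c("cardiac", "coronary", "atrial"),
         abbreviations = list(list(short = "HF", long = "heart failure")),
         category = "cardiology"),
    list(canonical = "stroke",
         synonyms = c("cerebrovascular accident"),
         abbreviations = list(
           list(short = "CVA", long = "cerebrovascular accident"),
           list(short = "TIA", long = "transient ischemic attack")),
         category = "neurology"),
    list(canonical = "anticoagulant",
         synonyms = c("blood thinner"),
         abbreviations = list(),
         category = "medication")
  ))
}

# brute-force reference for entries_for_term: linear scan of all surfaces
scan_entries_for_term <- function(lex, term) {
  term <- normalize_term(term)
  hits <- vapply(lex$entries, function(e) {
    surfaces <- c(normalize_term(e$canonical), normalize_term(e$synonyms))
    for (ab in e$abbreviations) {
      long_n <- normalize_term(ab$long)
      surfaces <- c(surfaces, normalize_term(ab$short), long_n,
                    strsplit(long_n, " ", fixed = TRUE)[[1L]])
    }
    term %in% surfaces
  }, logical(1L))
  lex$entries[hits]
}

# exponential recursive Levenshtein, independent of the DP implementation
recursive_lev <- function(a, b) {
  if (nchar(a) == 0L) return(nchar(b))
  if (nchar(b) == 0L) return(nchar(a))
  cost <- as.integer(substring(a, 1, 1) != substring(b, 1, 1))
  min(recursive_lev(substring(a, 2), b) + 1L,
      recursive_lev(a, substring(b, 2)) + 1L,
      recursive_lev(substring(a, 2), substring(b, 2)) + cost)
}

random_word <- function(len, alphabet = letters[1:3]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# small random corpus of space-separated words
random_corpus <- function(n_docs = 4, words = c("heart", "rate", "no", "cva",
                                                "stroke", "stable", "plan"),
                          n_words = 12) {
  texts <- vapply(seq_len(n_docs), function(i) {
    paste(sample(words, n_words, replace = TRUE), collapse = " ")
  }, character(1L))
  names(texts) <- sprintf("R%02d", seq_len(n_docs))
  as_corpus(texts)
}

# brute-force whole-word n-gram scan, the oracle for string_search
scan_string_search <- function(query, corpus) {
  qwords <- normalize_term(tokenize(normalize_term(query))$surface)
  k <- length(qwords)
  rows <- list()
  for (i in seq_len(nrow(corpus))) {
    toks <- tokenize(corpus$text[i])
    if (nrow(toks) < k) next
    norm <- normalize_term(toks$surface)
    for (a in seq_len(nrow(toks) - k + 1L)) {
      if (all(norm[a:(a + k - 1L)] == qwords)) {
        rows[[length(rows) + 1L]] <- data.frame(
          doc_id = corpus$doc_id[i], start = toks$start[a],
          end = toks$end[a + k - 1L],
          surface = substring(corpus$text[i], toks$start[a] + 1L,
                              toks$end[a + k - 1L]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(doc_id = character(), start = integer(),
                      end = integer(), surface = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

make_question <- function(n_gold = 2, answer_type = "multiple_choice") {
  ge <- data.frame(doc_id = sprintf("D%02d", seq_len(n_gold)),
                   area_id = rep("a1", n_gold), stringsAsFactors = FALSE)
  question("Q1", "Does the patient have a history of stroke?", answer_type,
           gold_answer = if (answer_type == "free_text") "stroke" else "Yes",
           gold_evidence = ge,
           options = if (answer_type == "free_text") character() else
             c("Yes", "No", "Information not available"))
}
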