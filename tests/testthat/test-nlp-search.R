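test_that("expand_query covers synonyms, both abbreviation forms and a stem marker", {
  lex <- mini_lexicon()
  ex <- expand_query("heart", lex)
  expect_true(all(c("heart", "coronary", "hf", "heart failure") %in%
                    ex$surface))
  expect_identical(ex$kind[ex$surface == "heart" & ex$kind == "direct"],
                   "direct")
  expect_identical(ex$kind[ex$surface == "coronary"], "synonym")
  expect_setequal(ex$kind[ex$surface %in% c("hf", "heart failure")],
                  "abbreviation")
  expect_true("word_form" %in% ex$kind)

  ex <- expand_query("stroke", lex)
  expect_true(all(c("tia", "cva") %in% ex$surface))

  # no knowledge: exactly the direct term plus its stem marker
  ex <- expand_query("qqq", lexicon(list()))
  expect_identical(ex$surface[ex$kind == "direct"], "qqq")
  expect_true(all(ex$kind %in% c("direct", "word_form")))
  expect_error(expand_query("", lex), "non-empty")
})

test_that("expansion is deterministic across runs", {
  lex <- demo_lexicon()
  expect_identical(expand_query("heart", lex), expand_query("heart", lex))
})

test_that("nlp_search reproduces the worked stroke example", {
  lex <- demo_lexicon()
  corp <- as_corpus(c(
    d1 = "Seen in clinic. It does not look like she has a stroke.",
    d2 = "Neurology review. No TIA or CVA.",
    d3 = "Past history reviewed. No CVA.",
    d4 = "Discharge summary. No CVA."))
  m <- nlp_search("stroke", corp, lex)
  expect_identical(nrow(m), 5L)  # stroke, TIA, CVA, CVA, CVA tokens
  expect_identical(count_mentions(m, corp), 4L)  # 4 negative mentions
  expect_identical(sum(m$highlight_class == "direct"), 1L)
})

test_that("nlp_search reproduces the Figure-1 style heart example", {
  lex <- demo_lexicon()
  corp <- as_corpus(c(
    d = "heart rate regular. atriall fibrillation noted. coronary disease. HF."))
  m <- nlp_search("heart", corp, lex)
  expect_identical(m$surface[m$highlight_class == "direct"], "heart")
  sem <- m[m$highlight_class == "semantic", ]
  expect_true(all(c("atriall", "coronary", "HF") %in% sem$surface))
  expect_identical(m$kind[m$surface == "atriall"], "spelling_variant")
  expect_identical(m$edit_distance[m$surface == "atriall"], 1L)
  expect_identical(m$kind[m$surface == "HF"], "abbreviation")
})

test_that("word forms match through the stem", {
  m <- nlp_search("smoke", as_corpus(c(d = "patient is a smoker")),
                  demo_lexicon())
  expect_identical(nrow(m), 1L)
  expect_identical(m$kind, "word_form")
  expect_identical(m$surface, "smoker")
})

test_that("hyphenation variants match with distance 0", {
  m <- nlp_search("anticoagulant",
                  as_corpus(c(d = "remains on anti-coagulant therapy")),
                  demo_lexicon())
  expect_identical(nrow(m), 1L)
  expect_identical(m$surface, "anti-coagulant")
  expect_identical(m$edit_distance, 0L)
})

test_that("string-search spans are always covered by nlp-search spans", {
  lex <- demo_lexicon()
  set.seed(31)
  words <- c("heart", "cva", "stroke", "rate", "hf", "coronary", "plan",
             "smoker", "anticoagulant")
  for (i in 1:20) {
    corp <- random_corpus(n_docs = 3,
                          words = words, n_words = sample(6:15, 1))
    for (q in c("heart", "stroke", "anticoagulant")) {
      ss <- string_search(q, corp)
      nl <- nlp_search(q, corp, lex)
      for (j in seq_len(nrow(ss))) {
        covered <- any(nl$doc_id == ss$doc_id[j] &
                         nl$start <= ss$start[j] & nl$end >= ss$end[j])
        expect_true(covered, info = paste(i, q, j))
      }
    }
  }
})

test_that("adding a lexicon entry never removes a match", {
  small <- lexicon(list(
    list(canonical = "stroke", synonyms = character(),
         abbreviations = list(list(short = "CVA",
                                   long = "cerebrovascular accident")),
         category = "neurology")))
  bigger <- lexicon(list(
    list(canonical = "stroke", synonyms = c("cerebrovascular accident"),
         abbreviations = list(
           list(short = "CVA", long = "cerebrovascular accident"),
           list(short = "TIA", long = "transient ischemic attack")),
         category = "neurology"),
    list(canonical = "heart", synonyms = "cardiac",
         abbreviations = list(), category = "cardiology")))
  corp <- as_corpus(c(d1 = "No CVA. No TIA.", d2 = "stroke suspected"))
  m1 <- nlp_search("stroke", corp, small)
  m2 <- nlp_search("stroke", corp, bigger)
  key <- function(m) paste(m$doc_id, m$start, m$end)
  expect_true(all(key(m1) %in% key(m2)))
  expect_gt(nrow(m2), nrow(m1))  # TIA found only with the richer lexicon
})

test_that("match provenance replays against the policy (self-check)", {
  lex <- demo_lexicon()
  corp <- as_corpus(c(
    d = "atriall fibrillation, coronary disease, HF, heart rate, smoker"))
  pol <- match_policy()
  m <- nlp_search("heart", corp, lex, pol)
  for (i in seq_len(nrow(m))) {
    if (m$kind[i] == "word_form") {
      expect_identical(stem_token(normalize_term(m$surface[i])), m$term[i])
    } else {
      words_t <- strsplit(m$term[i], " ", fixed = TRUE)[[1]]
      words_s <- normalize_term(tokenize(m$surface[i])$surface)
      expect_identical(length(words_s), length(words_t))
      total <- 0L
      for (j in seq_along(words_t)) {
        r <- fuzzy_equal(words_s[j], words_t[j], pol)
        expect_true(r$match)
        total <- total + r$distance
      }
      expect_identical(total, m$edit_distance[i])
      expect_lte(m$edit_distance[i],
                 allowed_edits(pol, nchar(m$term[i])))
    }
  }
})

test_that("search output is deterministic and ordered by doc then offset", {
  lex <- demo_lexicon()
  corp <- random_corpus(n_docs = 4,
                        words = c("heart", "hf", "coronary", "rate", "plan"))
  m1 <- nlp_search("heart", corp, lex)
  m2 <- nlp_search("heart", corp, lex)
  expect_identical(m1, m2)
  ord <- order(match(m1$doc_id, corp$doc_id), m1$start)
  expect_identical(ord, seq_len(nrow(m1)))
})

test_that("overlapping candidates resolve to the longest span", {
  lex <- demo_lexicon()
  corp <- as_corpus(c(d = "known heart failure since 2019"))
  m <- nlp_search("heart", corp, lex)
  expect_identical(m$surface, "heart failure")
  expect_identical(m$kind, "abbreviation")
})

test_that("render_highlights round-trips in both formats", {
  lex <- demo_lexicon()
  corp <- as_corpus(c(d = "heart rate & <vitals> ok. coronary disease."))
  m <- nlp_search("heart", corp, lex)
  doc <- corp[corp$doc_id == "d", ]
  txt <- render_highlights(m, doc, "text")
  expect_true(grepl("[[D|heart]]", txt, fixed = TRUE))
  expect_true(grepl("[[S|coronary]]", txt, fixed = TRUE))
  expect_identical(strip_highlights(txt, "text"), doc$text)
  html <- render_highlights(m, doc, "html")
  expect_true(grepl("<mark class=\"direct\">heart</mark>", html,
                    fixed = TRUE))
  expect_true(grepl("&amp;", html, fixed = TRUE))
  expect_identical(strip_highlights(html, "html"), doc$text)
  # no matches: output equals input
  none <- m[0, ]
  expect_identical(render_highlights(none, doc, "text"), doc$text)
  # out-of-range span errors
  bad <- m
  bad$end[1] <- nchar(doc$text) + 5L
  expect_error(render_highlights(bad, doc, "text"), "outside")
})

test_that("document retrieval ranks by match count", {
  lex <- demo_lexicon()
  corp <- as_corpus(c(a = "plan stable", b = "heart heart HF",
                      c = "coronary disease"))
  r <- retrieve_documents(nlp_search("heart", corp, lex), corp)
  expect_identical(r$doc_id, c("b", "c"))
  expect_identical(r$n_matches, c(3L, 1L))
})
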