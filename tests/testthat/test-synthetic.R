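test_that("generation is byte-identical under a fixed seed", {
  lex <- demo_lexicon()
  cfg <- generator_config(seed = 99, n_patients = 2, docs_per_patient = 5)
  g1 <- generate_corpus(cfg, lex)
  g2 <- generate_corpus(cfg, lex)
  expect_identical(g1, g2)
  t1 <- generate_tasks(cfg, g1$corpus, g1$gold)
  t2 <- generate_tasks(cfg, g2$corpus, g2$gold)
  expect_identical(t1, t2)
  cfg3 <- generator_config(seed = 3, n_patients = 3, docs_per_patient = 8)
  g3 <- generate_corpus(cfg3, lex)
  t3 <- generate_tasks(cfg3, g3$corpus, g3$gold)
  s1 <- simulate_study(cfg3, g3$corpus, t3, lex)
  s2 <- simulate_study(cfg3, g3$corpus, t3, lex)
  expect_identical(s1, s2)
})

test_that("default configuration mirrors the study shape", {
  lex <- demo_lexicon()
  cfg <- generator_config(seed = 5)
  expect_identical(cfg$docs_per_patient, 20L)
  expect_identical(cfg$question_template_size, 10L)
  g <- generate_corpus(cfg, lex)
  expect_identical(as.integer(table(g$corpus$patient_id)),
                   rep(20L, 3))
  tasks <- generate_tasks(cfg, g$corpus, g$gold)
  expect_length(tasks, 3)
  expect_true(all(vapply(tasks, function(t) length(t$questions),
                         integer(1)) == 10L))
})

test_that("gold spans quote the document text exactly", {
  lex <- demo_lexicon()
  g <- generate_corpus(generator_config(seed = 7, n_patients = 1,
                                        docs_per_patient = 6), lex)
  for (i in seq_len(nrow(g$gold))) {
    row <- g$gold[i, ]
    text <- g$corpus$text[match(row$doc_id, g$corpus$doc_id)]
    expect_identical(substring(text, row$start + 1, row$end), row$surface)
  }
})

test_that("zero injection rates plant only direct variants", {
  lex <- demo_lexicon()
  cfg <- generator_config(seed = 8, n_patients = 1, docs_per_patient = 4,
                          injection_rates = c(misspelling = 0,
                                              abbreviation = 0, synonym = 0))
  g <- generate_corpus(cfg, lex)
  expect_true(all(g$gold$kind == "direct"))
})

test_that("empirical injection fractions track the configured rates", {
  lex <- demo_lexicon()
  # enough documents for >= 10000 planted terms
  cfg <- generator_config(seed = 9, n_patients = 3, docs_per_patient = 1100,
                          injection_rates = c(misspelling = 0.1,
                                              abbreviation = 0.1,
                                              synonym = 0.1))
  g <- generate_corpus(cfg, lex)
  expect_gt(nrow(g$gold), 10000)
  frac <- table(g$gold$kind) / nrow(g$gold)
  expect_lt(abs(frac[["misspelling"]] - 0.1), 0.02)
  expect_lt(abs(frac[["abbreviation"]] - 0.1), 0.02)
  expect_lt(abs(frac[["synonym"]] - 0.1), 0.02)
  expect_lt(abs(frac[["direct"]] - 0.7), 0.02)
})

test_that("tasks reference existing documents and planted evidence", {
  lex <- demo_lexicon()
  cfg <- generator_config(seed = 10)
  g <- generate_corpus(cfg, lex)
  tasks <- generate_tasks(cfg, g$corpus, g$gold)
  for (tk in tasks) {
    for (q in tk$questions) {
      expect_true(all(q$gold_evidence$doc_id %in% g$corpus$doc_id))
      own <- g$corpus$patient_id[match(q$gold_evidence$doc_id,
                                       g$corpus$doc_id)]
      expect_true(all(own == tk$patient_id))
      # evidence areas point at real plants of the question's term
      for (j in seq_len(nrow(q$gold_evidence))) {
        expect_true(any(g$gold$doc_id == q$gold_evidence$doc_id[j] &
                          g$gold$canonical == q$gold_evidence$area_id[j]))
      }
    }
  }
})

test_that("planted variants are recoverable by nlp search but misspellings defeat string search", {
  lex <- demo_lexicon()
  cfg <- generator_config(seed = 12, n_patients = 1, docs_per_patient = 8,
                          injection_rates = c(misspelling = 0.25,
                                              abbreviation = 0.25,
                                              synonym = 0.25))
  g <- generate_corpus(cfg, lex)
  gold <- g$gold
  expect_true(all(c("misspelling", "abbreviation", "synonym") %in%
                    gold$kind))
  for (canon in unique(gold$canonical)) {
    plants <- gold[gold$canonical == canon, ]
    m <- nlp_search(canon, g$corpus, lex)
    ss <- string_search(canon, g$corpus)
    for (j in seq_len(nrow(plants))) {
      covered <- any(m$doc_id == plants$doc_id[j] &
                       m$start <= plants$start[j] & m$end >= plants$end[j])
      expect_true(covered, info = paste(canon, plants$kind[j]))
      if (plants$kind[j] == "misspelling") {
        hit_ss <- any(ss$doc_id == plants$doc_id[j] &
                        ss$start == plants$start[j])
        expect_false(hit_ss, info = paste(canon, "misspelling"))
      }
    }
  }
})

test_that("misspell_term yields a nearby but different spelling", {
  set.seed(21)
  for (i in 1:50) {
    out <- misspell_term("anticoagulant")
    expect_false(identical(out, "anticoagulant"))
    expect_lte(edit_distance(normalize_term(out), "anticoagulant"), 2L)
  }
  expect_identical(misspell_term("cva"), "cva")  # nothing editable
})

test_that("the simulated study follows the crossover rotation", {
  lex <- demo_lexicon()
  cfg <- generator_config(seed = 14, docs_per_patient = 8)
  g <- generate_corpus(cfg, lex)
  tasks <- generate_tasks(cfg, g$corpus, g$gold)
  recs <- simulate_study(cfg, g$corpus, tasks, lex)
  expect_length(recs, 35 * 3)
  assign <- attr(recs, "assignments")
  expect_identical(sort(as.integer(table(assign$group))),
                   sort(c(7L, 13L, 15L)))
  orders <- crossover_orders(vapply(tasks, `[[`, character(1), "task_id"))
  for (r in recs) {
    expect_identical(r$functionality,
                     unname(orders[[as.character(r$group)]][[r$task_id]]))
    expect_gt(r$elapsed_minutes, 0)
    if (r$functionality == "none") expect_identical(nrow(r$search_log), 0L)
  }
  # the full cohort is protocol-compliant by construction
  v <- validate_protocol(recs, orders)
  expect_length(v$excluded, 0)
})

test_that("a null recall configuration centres the accuracy contrast on zero", {
  lex <- demo_lexicon()
  cfg <- generator_config(seed = 15, docs_per_patient = 6,
                          cohort = list(recall = c(none = 0.8,
                                                   string = 0.85,
                                                   nlp = 0.85)))
  g <- generate_corpus(cfg, lex)
  tasks <- generate_tasks(cfg, g$corpus, g$gold)
  diffs <- vapply(1:60, function(i) {
    recs <- simulate_study(cfg, g$corpus, tasks, lex, seed = 1000 + i)
    met <- study_metrics(recs, tasks)
    ct <- crossover_contrasts(met, "accuracy")
    ct$mean_diff[ct$contrast == "string vs nlp"]
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 4 * se + 0.5)
})
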