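#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic-data pipeline: corpus shape (3
#' patients with 20 documents each, mirroring the study's design), injection
#' rates for planted term variants, task template size (10 questions), and
#' the simulated evaluator cohort. Cohort defaults use the study's observed
#' values as plausibility anchors: group sizes 7/13/15 (35 evaluators),
#' per-functionality evidence recall 0.838/0.837/0.881 (none/string/nlp),
#' mean task times 20.2/17.0/17.9 minutes, search usage 83.7%/95.1% and mean
#' terms per searched answer 3.51/2.05 (string/nlp).
#'
#' @param seed integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @param n_patients number of synthetic patients.
#' @param docs_per_patient documents per patient.
#' @param doc_length_range integer range of sentences per document.
#' @param injection_rates named probabilities for planting a `misspelling`,
#'   `abbreviation` or `synonym` variant instead of the canonical term
#'   (remainder is planted directly).
#' @param question_template_size questions per task.
#' @param cohort list with `group_sizes` (length 3), `recall`, `search_use`,
#'   `terms_mean`, `time_mean` (minutes), `time_sdlog` (lognormal shape).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_patients = 3L,
                             docs_per_patient = 20L,
                             doc_length_range = c(4L, 9L),
                             injection_rates = c(misspelling = 0.1,
                                                 abbreviation = 0.1,
                                                 synonym = 0.1),
                             question_template_size = 10L,
                             cohort = list()) {
  stopifnot(docs_per_patient >= 1L, n_patients >= 1L,
            all(c("misspelling", "abbreviation", "synonym") %in%
                  names(injection_rates)),
            all(injection_rates >= 0), all(injection_rates <= 1),
            sum(injection_rates) <= 1, question_template_size >= 1L)
  default_cohort <- list(
    group_sizes = c(7L, 13L, 15L),
    recall = c(none = 0.838, string = 0.837, nlp = 0.881),
    search_use = c(string = 0.837, nlp = 0.951),
    terms_mean = c(string = 3.51, nlp = 2.05),
    time_mean = c(none = 20.2, string = 17.0, nlp = 17.9),
    time_sdlog = 0.35
  )
  cohort <- utils::modifyList(default_cohort, cohort)
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 docs_per_patient = as.integer(docs_per_patient),
                 doc_length_range = as.integer(doc_length_range),
                 injection_rates = injection_rates,
                 question_template_size = as.integer(question_template_size),
                 cohort = cohort),
            class = "generator_config")
}

# sentence templates with a {TERM} slot, and term-free filler
.term_templates <- c(
  "Past medical history includes {TERM}.",
  "The patient denies any {TERM}.",
  "There is no evidence of {TERM} on examination.",
  "Ongoing treatment for {TERM} was discussed.",
  "Admission was complicated by {TERM}.",
  "Review of systems was notable for {TERM}.",
  "Previous episode of {TERM} documented in 2019.",
  "No further {TERM} reported since discharge.",
  "Family history is positive for {TERM}.",
  "Symptoms consistent with {TERM} were noted."
)

.filler_sentences <- c(
  "The patient was seen in clinic today.",
  "Observations were stable throughout.",
  "Bloods were unremarkable.",
  "Follow up arranged in six weeks.",
  "The plan was discussed with the patient.",
  "The patient was comfortable at rest.",
  "Examination was otherwise unremarkable.",
  "Medication compliance was confirmed.",
  "A copy of this letter was sent to the ward.",
  "The patient attended with a relative."
)

.doc_types <- c("discharge letter", "outpatient clinic letter",
                "operation note", "general practice referral letter")

#' Apply one random edit to a term (misspelling generator)
#'
#' One random insertion, deletion, substitution, or adjacent transposition
#' applied to a word of the term (only words of at least 5 letters are
#' edited). The edit is constrained to stay within the default fuzzy
#' policy's reach for the word's length: transpositions (Levenshtein
#' distance 2) are only applied to words long enough to allow 2 edits.
#' The result always differs from the input; terms with no editable word are
#' returned unchanged.
#'
#' @param term a term string.
#' @return a misspelled variant within the default policy's edit bound.
#' @export
misspell_term <- function(term) {
  words <- strsplit(term, " ", fixed = TRUE)[[1L]]
  editable <- which(nchar(gsub("-", "", words)) >= 5L)
  if (length(editable) == 0L) return(term)
  wi <- if (length(editable) == 1L) editable else sample(editable, 1L)
  w <- words[wi]
  ch <- strsplit(w, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  ops <- c("insert", "delete", "substitute")
  if (allowed_edits(match_policy(), nchar(normalize_term(w))) >= 2L)
    ops <- c(ops, "transpose")
  for (attempt in 1:10) {
    op <- sample(ops, 1L)
    out <- switch(op,
      insert = {
        pos <- sample(0:n, 1L)
        paste(c(ch[seq_len(pos)], sample(letters, 1L),
                ch[seq_len(n - pos) + pos]), collapse = "")
      },
      delete = {
        pos <- sample(seq_len(n), 1L)
        paste(ch[-pos], collapse = "")
      },
      substitute = {
        pos <- sample(seq_len(n), 1L)
        ch2 <- ch
        ch2[pos] <- sample(letters, 1L)
        paste(ch2, collapse = "")
      },
      transpose = {
        pos <- sample(seq_len(n - 1L), 1L)
        ch2 <- ch
        ch2[c(pos, pos + 1L)] <- ch2[c(pos + 1L, pos)]
        paste(ch2, collapse = "")
      })
    if (!identical(out, w)) {
      words[wi] <- out
      return(paste(words, collapse = " "))
    }
  }
  term
}

#' Generate a synthetic corpus with gold annotations
#'
#' Assembles clinical-style notes from template sentences seeded with
#' lexicon terms. Each planted term is, with the configured probabilities,
#' replaced by a misspelling (one random edit), an abbreviation short form,
#' or a synonym; the variant kind is sampled first and an entry supporting
#' it is then drawn, so empirical injection fractions match the configured
#' rates. Every planted occurrence is recorded in the gold table with its
#' exact character span (0-based, half-open), source canonical term and
#' variant kind. Deterministic under `cfg$seed`.
#'
#' @param cfg a [generator_config()].
#' @param lex a non-empty `medical_lexicon`.
#' @return list with `corpus` (a `mednote_corpus`) and `gold` (data frame
#'   `doc_id`, `start`, `end`, `surface`, `canonical`, `kind`). The number
#'   of kind fallbacks (a variant requested that no lexicon entry supports)
#'   is attached as attribute `"fallbacks"` on `gold`.
#' @export
generate_corpus <- function(cfg, lex) {
  stopifnot(inherits(cfg, "generator_config"),
            inherits(lex, "medical_lexicon"))
  if (length(lex$entries) == 0L) stop("lexicon must be non-empty")
  set.seed(cfg$seed)
  has_abbr <- which(vapply(lex$entries, function(e)
    length(e$abbreviations) > 0L, logical(1L)))
  has_syn <- which(vapply(lex$entries, function(e)
    length(e$synonyms) > 0L, logical(1L)))
  can_misspell <- which(vapply(lex$entries, function(e)
    any(nchar(gsub("-", "", strsplit(e$canonical, " ",
                                     fixed = TRUE)[[1L]])) >= 5L),
    logical(1L)))
  all_idx <- seq_along(lex$entries)
  rates <- cfg$injection_rates
  fallbacks <- 0L
  docs <- list()
  gold <- list()
  base_date <- as.Date("2020-01-05")
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%02d", p)
    for (d in seq_len(cfg$docs_per_patient)) {
      doc_id <- sprintf("%s-D%02d", pid, d)
      n_sent <- sample(cfg$doc_length_range[1L]:cfg$doc_length_range[2L], 1L)
      text <- ""
      for (s in seq_len(n_sent)) {
        plant <- stats::runif(1) < 0.6
        if (!plant) {
          sent <- sample(.filler_sentences, 1L)
          text <- paste0(text, if (nzchar(text)) " ", sent)
          next
        }
        u <- stats::runif(1)
        p_mis <- rates[["misspelling"]]
        p_ab <- rates[["abbreviation"]]
        p_syn <- rates[["synonym"]]
        kind <- if (u < p_mis) "misspelling"
                else if (u < p_mis + p_ab) "abbreviation"
                else if (u < p_mis + p_ab + p_syn) "synonym"
                else "direct"
        pool <- switch(kind, misspelling = can_misspell,
                       abbreviation = has_abbr, synonym = has_syn, all_idx)
        if (length(pool) == 0L) {
          fallbacks <- fallbacks + 1L
          kind <- "direct"
          pool <- all_idx
        }
        e <- lex$entries[[if (length(pool) == 1L) pool else
          sample(pool, 1L)]]
        surface <- switch(kind,
          direct = e$canonical,
          misspelling = misspell_term(e$canonical),
          abbreviation = {
            ab <- e$abbreviations[[sample.int(length(e$abbreviations), 1L)]]
            ab$short
          },
          synonym = e$synonyms[[sample.int(length(e$synonyms), 1L)]])
        tmpl <- sample(.term_templates, 1L)
        pre <- sub("\\{TERM\\}.*$", "", tmpl)
        post <- sub("^.*\\{TERM\\}", "", tmpl)
        sep <- if (nzchar(text)) " " else ""
        start <- nchar(text) + nchar(sep) + nchar(pre)
        text <- paste0(text, sep, pre, surface, post)
        gold[[length(gold) + 1L]] <- data.frame(
          doc_id = doc_id, start = start, end = start + nchar(surface),
          surface = surface, canonical = e$canonical, kind = kind,
          stringsAsFactors = FALSE)
      }
      docs[[length(docs) + 1L]] <- data.frame(
        doc_id = doc_id, patient_id = pid,
        doc_type = sample(.doc_types, 1L),
        date = as.character(base_date + (d - 1L) * 11L),
        text = text, stringsAsFactors = FALSE)
    }
  }
  gold <- do.call(rbind, gold)
  attr(gold, "fallbacks") <- fallbacks
  list(corpus = as_corpus(do.call(rbind, docs)), gold = gold)
}

#' Generate information-retrieval tasks from gold annotations
#'
#' Builds one task per patient with `question_template_size` questions whose
#' gold evidence units point at planted spans, mixing multiple-choice,
#' multi-select and free-text patterns. Evidence areas cluster planted
#' occurrences of the question's term per document, so a question whose
#' evidence lives in two documents carries two markable areas. Every
#' question is answerable from the corpus by construction.
#'
#' @param cfg a [generator_config()].
#' @param corpus the generated corpus.
#' @param gold the gold table from [generate_corpus()].
#' @return list of [task()]s, one per patient.
#' @export
generate_tasks <- function(cfg, corpus, gold) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(gold) || nrow(gold) == 0L) stop("gold annotations are empty")
  set.seed(cfg$seed + 1L)
  gold$patient_id <- corpus$patient_id[match(gold$doc_id, corpus$doc_id)]
  tasks <- list()
  for (pid in unique(corpus$patient_id)) {
    g <- gold[gold$patient_id == pid, , drop = FALSE]
    terms <- unique(g$canonical)
    if (length(terms) < cfg$question_template_size)
      stop("insufficient planted terms for patient ", pid,
           ": increase docs_per_patient or document length")
    chosen <- sample(terms, cfg$question_template_size)
    qs <- lapply(seq_along(chosen), function(i) {
      term <- chosen[i]
      plants <- g[g$canonical == term, , drop = FALSE]
      docs_with <- unique(plants$doc_id)
      ev_docs <- docs_with[seq_len(min(3L, length(docs_with)))]
      ge <- data.frame(doc_id = ev_docs, area_id = term,
                       stringsAsFactors = FALSE)
      qid <- sprintf("%s-Q%02d", pid, i)
      type <- c("multiple_choice", "free_text", "multi_select")[(i %% 3L) + 1L]
      switch(type,
        multiple_choice = question(
          qid, sprintf("Does the patient have a history of %s?", term),
          "multiple_choice", "Yes", ge,
          options = c("Yes", "No", "Information not available")),
        free_text = question(
          qid,
          sprintf("Which condition mentioned in the notes relates to %s?",
                  term),
          "free_text", term, ge),
        multi_select = {
          decoys <- setdiff(terms, term)
          decoys <- decoys[seq_len(min(3L, length(decoys)))]
          question(
            qid,
            "Does this patient have a history of any of the following?",
            "multi_select", term, ge,
            options = c(sort(c(term, decoys)), "None of the above"))
        })
    })
    tasks[[length(tasks) + 1L]] <- task(
      task_id = sprintf("T-%s", pid), patient_id = pid,
      scenario_text = sprintf(
        "You are reviewing the notes of patient %s prior to clinic.", pid),
      questions = qs)
  }
  tasks
}

#' The predetermined functionality rotation of the crossover design
#'
#' Group 1 performs the tasks with none/string/nlp, group 2 with
#' string/nlp/none, group 3 with nlp/none/string — a cyclic rotation so each
#' functionality appears once per group and once per task position.
#'
#' @param task_ids character vector of the 3 task ids in task order.
#' @return named list mapping group id (`"1"`, `"2"`, `"3"`) to a named
#'   character vector `task_id -> functionality`, as consumed by
#'   [validate_protocol()].
#' @export
crossover_orders <- function(task_ids) {
  stopifnot(length(task_ids) == 3L)
  base <- c("none", "string", "nlp")
  stats::setNames(lapply(0:2, function(k) {
    stats::setNames(base[((0:2 + k) %% 3L) + 1L], task_ids)
  }), as.character(1:3))
}

#' Simulate a crossover study over the synthetic tasks
#'
#' Assigns the configured cohort of evaluators to the 3 study groups at
#' random (stratified assignment is seeded and deterministic), walks each
#' evaluator through the 3 tasks under the group's predetermined
#' functionality order ([crossover_orders()]), and draws outcomes: each gold
#' evidence area is found independently with the functionality-specific
#' recall probability, marks follow the study's marking scheme, task times
#' are lognormal with functionality-specific location, and search logs are
#' emitted with the configured usage probability and term counts.
#'
#' @param cfg a [generator_config()] (its `cohort` must define 3 groups).
#' @param corpus,tasks the generated corpus and tasks (exactly 3 tasks).
#' @param lex the lexicon (search-log terms are drawn from it).
#' @param seed RNG seed; defaults to `cfg$seed + 2`.
#' @return list of [study_record()]s (one per evaluator x task), with the
#'   group assignment table attached as attribute `"assignments"`.
#' @export
simulate_study <- function(cfg, corpus, tasks, lex, seed = cfg$seed + 2L) {
  stopifnot(inherits(cfg, "generator_config"))
  co <- cfg$cohort
  if (length(co$group_sizes) != 3L)
    stop("the crossover cohort must have exactly 3 groups")
  if (length(tasks) != 3L)
    stop("the crossover design uses exactly 3 tasks")
  set.seed(seed)
  n <- sum(co$group_sizes)
  ev_ids <- sprintf("E%02d", seq_len(n))
  groups <- sample(rep(1:3, co$group_sizes))
  bands <- sample(c("preclinical student", "clinical student",
                    "doctor 1-5y", "doctor 6-10y", "doctor 11+y"),
                  n, replace = TRUE)
  task_ids <- vapply(tasks, `[[`, character(1L), "task_id")
  orders <- crossover_orders(task_ids)
  records <- list()
  for (i in seq_len(n)) {
    for (t in seq_along(tasks)) {
      tk <- tasks[[t]]
      func <- orders[[as.character(groups[i])]][[tk$task_id]]
      marks <- integer(0)
      log_rows <- list()
      for (q in tk$questions) {
        n_gold <- nrow(q$gold_evidence)
        found <- stats::rbinom(n_gold, 1L, co$recall[[func]])
        marks[[q$question_id]] <- sum(found)
        if (func != "none" && stats::runif(1) < co$search_use[[func]]) {
          n_terms <- 1L + stats::rpois(1L, max(co$terms_mean[[func]] - 1, 0))
          area <- q$gold_evidence$area_id[1L]
          vocab <- unique(c(area,
                            unlist(lapply(entries_for_term(lex, area),
                                          `[[`, "synonyms")),
                            "history", "diagnosis", "treatment"))
          terms <- c(area, sample(vocab, n_terms - 1L, replace = TRUE))
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            question_id = q$question_id, term = terms[seq_len(n_terms)],
            stringsAsFactors = FALSE)
        }
      }
      log <- if (length(log_rows)) do.call(rbind, log_rows) else
        data.frame(question_id = character(), term = character(),
                   stringsAsFactors = FALSE)
      minutes <- stats::rlnorm(1L,
                               meanlog = log(co$time_mean[[func]]) -
                                 co$time_sdlog^2 / 2,
                               sdlog = co$time_sdlog)
      records[[length(records) + 1L]] <- study_record(
        ev_ids[i], groups[i], tk$task_id, func, marks, minutes, log,
        clinical_band = bands[i])
    }
  }
  attr(records, "assignments") <- data.frame(
    evaluator_id = ev_ids, group = groups, clinical_band = bands,
    stringsAsFactors = FALSE)
  records
}
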