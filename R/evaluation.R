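#' Construct a question
#'
#' A question in an information-retrieval task: a prompt, an answer type
#' (`multiple_choice`, `multi_select` or `free_text`), the options for choice
#' types, the gold answer (for `free_text`, a vector of accepted strings,
#' compared after [normalize_term()]), and the gold evidence: the set of
#' (document, evidence-area) units that together constitute a full answer.
#' Marks are awarded per evidence area found, gated on answer correctness.
#'
#' @param question_id identifier.
#' @param prompt question text.
#' @param answer_type one of `"multiple_choice"`, `"multi_select"`,
#'   `"free_text"`.
#' @param gold_answer correct answer (character; may be a vector for
#'   `multi_select` and for accepted `free_text` strings).
#' @param gold_evidence data frame with columns `doc_id`, `area_id`; must be
#'   non-empty with unique rows.
#' @param options character vector of options (choice types only).
#' @return list of class `mednote_question`.
#' @export
question <- function(question_id, prompt, answer_type, gold_answer,
                     gold_evidence, options = character()) {
  answer_type <- match.arg(answer_type,
                           c("multiple_choice", "multi_select", "free_text"))
  stopifnot(is.data.frame(gold_evidence),
            all(c("doc_id", "area_id") %in% names(gold_evidence)))
  if (nrow(gold_evidence) == 0L) stop("gold_evidence must be non-empty")
  if (anyDuplicated(gold_evidence[, c("doc_id", "area_id")]))
    stop("duplicate (doc_id, area_id) in gold_evidence")
  if (answer_type != "free_text" && !all(gold_answer %in% options))
    stop("gold_answer must be among the options for choice questions")
  structure(list(question_id = question_id, prompt = prompt,
                 answer_type = answer_type, options = options,
                 gold_answer = gold_answer,
                 gold_evidence = gold_evidence[, c("doc_id", "area_id")]),
            class = "mednote_question")
}

#' Construct a task
#'
#' @param task_id identifier.
#' @param patient_id the patient whose notes answer the task.
#' @param scenario_text clinical scenario shown to the evaluator.
#' @param questions list of [question()] objects (at least one; the study
#'   default is a template of 10).
#' @return list of class `mednote_task`.
#' @export
task <- function(task_id, patient_id, scenario_text, questions) {
  if (length(questions) < 1L) stop("a task needs at least one question")
  ids <- vapply(questions, `[[`, character(1L), "question_id")
  if (anyDuplicated(ids)) stop("duplicate question_id within task")
  structure(list(task_id = task_id, patient_id = patient_id,
                 scenario_text = scenario_text, questions = questions),
            class = "mednote_task")
}

.is_correct <- function(submitted, q) {
  switch(q$answer_type,
    multiple_choice = {
      if (length(submitted) != 1L || !submitted %in% q$options)
        stop("malformed answer: must be exactly one of the options")
      identical(submitted, q$gold_answer[1L])
    },
    multi_select = {
      if (!all(submitted %in% q$options))
        stop("malformed answer: selections outside the options")
      setequal(submitted, q$gold_answer)
    },
    free_text = {
      if (length(submitted) != 1L || !is.character(submitted))
        stop("malformed answer: free text must be a single string")
      normalize_term(submitted) %in% normalize_term(q$gold_answer)
    })
}

#' Mark one answer
#'
#' The study's marking scheme: if the submitted answer is wrong the question
#' scores 0; if it is right, one mark is awarded per gold evidence area the
#' evaluator found. With 3 pieces of information clustered into 2 documents'
#' areas, finding both areas with the correct answer scores 2 marks.
#'
#' @param submitted the submitted answer (character; vector for
#'   `multi_select`).
#' @param found_evidence data frame of evidence units found (`doc_id`,
#'   `area_id`); may have zero rows.
#' @param q a [question()].
#' @return integer marks in `0:nrow(q$gold_evidence)`.
#' @export
score_answer <- function(submitted, found_evidence, q) {
  stopifnot(inherits(q, "mednote_question"))
  if (!.is_correct(submitted, q)) return(0L)
  if (is.null(found_evidence) || nrow(found_evidence) == 0L) return(0L)
  found <- unique(found_evidence[, c("doc_id", "area_id")])
  nrow(merge(found, q$gold_evidence, by = c("doc_id", "area_id")))
}

#' Task accuracy percentage
#'
#' Questions are weighted equally: each question contributes its fraction of
#' marks obtained (`marks / |gold evidence|`), and the task accuracy is the
#' mean fraction times 100.
#'
#' @param record a study record (see [study_record()]) whose `marks` cover
#'   exactly the task's questions.
#' @param task a [task()].
#' @return accuracy in percent, in `[0, 100]`.
#' @export
task_accuracy <- function(record, task) {
  stopifnot(inherits(task, "mednote_task"))
  qids <- vapply(task$questions, `[[`, character(1L), "question_id")
  marks <- record$marks
  if (!setequal(names(marks), qids))
    stop("record marks do not cover the task's question set")
  frac <- vapply(task$questions, function(q) {
    m <- marks[[q$question_id]]
    g <- nrow(q$gold_evidence)
    if (m > g) stop("marks exceed gold evidence count for ", q$question_id)
    m / g
  }, numeric(1L))
  100 * mean(frac)
}

#' Construct a study record
#'
#' One evaluator x one task outcome: the search functionality used, the marks
#' per question, the elapsed time, and the search log of terms entered per
#' question.
#'
#' @param evaluator_id,task_id identifiers.
#' @param group study group (1, 2 or 3).
#' @param functionality `"none"`, `"string"` or `"nlp"`.
#' @param marks named integer vector (names are question ids).
#' @param elapsed_minutes positive task time in minutes.
#' @param search_log data frame with columns `question_id`, `term` (zero rows
#'   for no searches).
#' @param clinical_band free-form experience band label.
#' @return list of class `mednote_record`.
#' @export
study_record <- function(evaluator_id, group, task_id, functionality, marks,
                         elapsed_minutes,
                         search_log = data.frame(question_id = character(),
                                                 term = character(),
                                                 stringsAsFactors = FALSE),
                         clinical_band = NA_character_) {
  functionality <- match.arg(functionality, c("none", "string", "nlp"))
  if (!is.numeric(elapsed_minutes) || elapsed_minutes <= 0)
    stop("elapsed_minutes must be > 0")
  stopifnot(is.data.frame(search_log),
            all(c("question_id", "term") %in% names(search_log)))
  structure(list(evaluator_id = evaluator_id, group = as.integer(group),
                 clinical_band = clinical_band, task_id = task_id,
                 functionality = functionality, marks = marks,
                 elapsed_minutes = as.numeric(elapsed_minutes),
                 search_log = search_log[, c("question_id", "term")]),
            class = "mednote_record")
}

#' Search-log usage metrics per functionality
#'
#' For each search functionality present among the records (the `none` arm
#' has no log by definition and is skipped), computes the percentage of
#' answered questions for which at least one search term was logged, and the
#' mean and standard deviation of the number of terms over those searched
#' answers only.
#'
#' @param records list of [study_record()]s.
#' @return data frame with columns `functionality`,
#'   `pct_answers_using_search`, `mean_terms_per_searched_answer`, `sd_terms`,
#'   `n_answers`, `n_searched`.
#' @export
summarize_search_logs <- function(records) {
  recs <- Filter(function(r) r$functionality %in% c("string", "nlp"), records)
  funcs <- unique(vapply(recs, `[[`, character(1L), "functionality"))
  rows <- lapply(sort(funcs), function(f) {
    rr <- Filter(function(r) r$functionality == f, recs)
    counts <- unlist(lapply(rr, function(r) {
      per_q <- table(factor(r$search_log$question_id,
                            levels = names(r$marks)))
      as.integer(per_q)
    }))
    searched <- counts[counts > 0L]
    data.frame(
      functionality = f,
      pct_answers_using_search = 100 * length(searched) / length(counts),
      mean_terms_per_searched_answer =
        if (length(searched)) mean(searched) else NA_real_,
      sd_terms = if (length(searched) > 1L) stats::sd(searched) else NA_real_,
      n_answers = length(counts),
      n_searched = length(searched),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(functionality = character(),
                      pct_answers_using_search = numeric(),
                      mean_terms_per_searched_answer = numeric(),
                      sd_terms = numeric(), n_answers = integer(),
                      n_searched = integer(), stringsAsFactors = FALSE)
  }
  out
}

#' Flag protocol violations in study records
#'
#' The study excluded evaluators whose search logs showed use of a search
#' functionality other than the one assigned for a task (including any
#' logged search under an assigned `"none"` arm). Flagged evaluators are
#' excluded from analysis entirely.
#'
#' @param records list of [study_record()]s.
#' @param group_assignments named list: for each group id (as character), a
#'   named character vector mapping `task_id` to the assigned functionality.
#' @return list with `violations` (data frame `evaluator_id`, `task_id`,
#'   `reason`) and `excluded` (character vector of evaluator ids).
#' @export
validate_protocol <- function(records, group_assignments) {
  rows <- list()
  for (r in records) {
    g <- as.character(r$group)
    if (is.null(group_assignments[[g]]))
      stop("unknown group id: ", g)
    assigned <- group_assignments[[g]][[r$task_id]]
    if (is.null(assigned) || is.na(assigned))
      stop("no assignment for task ", r$task_id, " in group ", g)
    if (!identical(r$functionality, assigned)) {
      rows[[length(rows) + 1L]] <- data.frame(
        evaluator_id = r$evaluator_id, task_id = r$task_id,
        reason = sprintf("used %s where %s was assigned", r$functionality,
                         assigned), stringsAsFactors = FALSE)
    } else if (assigned == "none" && nrow(r$search_log) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        evaluator_id = r$evaluator_id, task_id = r$task_id,
        reason = "search terms logged under the no-search arm",
        stringsAsFactors = FALSE)
    }
  }
  violations <- do.call(rbind, rows)
  if (is.null(violations)) {
    violations <- data.frame(evaluator_id = character(),
                             task_id = character(), reason = character(),
                             stringsAsFactors = FALSE)
  }
  list(violations = violations,
       excluded = unique(violations$evaluator_id))
}

#' Read and write task definition files
#'
#' Tasks are stored as JSON: `{"tasks": [{"task_id", "patient_id",
#' "scenario_text", "questions": [{"question_id", "prompt", "answer_type",
#' "options", "gold_answer", "gold_evidence": [{"doc_id", "area_id"}]}]}]}`.
#'
#' @param path file path.
#' @return `read_tasks()`: list of [task()] objects.
#' @export
read_tasks <- function(path) {
  if (!file.exists(path)) stop("task file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw$tasks, function(t) {
    qs <- lapply(t$questions, function(q) {
      ge <- do.call(rbind, lapply(q$gold_evidence, function(u)
        data.frame(doc_id = u$doc_id, area_id = u$area_id,
                   stringsAsFactors = FALSE)))
      question(q$question_id, q$prompt, q$answer_type,
               unlist(q$gold_answer), ge,
               options = as.character(unlist(q$options)))
    })
    task(t$task_id, t$patient_id, t$scenario_text, qs)
  })
}

#' @param tasks list of [task()] objects.
#' @rdname read_tasks
#' @return `write_tasks()`: `path`, invisibly.
#' @export
write_tasks <- function(tasks, path) {
  out <- list(tasks = lapply(tasks, function(t) {
    list(task_id = t$task_id, patient_id = t$patient_id,
         scenario_text = t$scenario_text,
         questions = lapply(t$questions, function(q) {
           list(question_id = q$question_id, prompt = q$prompt,
                answer_type = q$answer_type, options = as.list(q$options),
                gold_answer = as.list(q$gold_answer),
                gold_evidence = lapply(seq_len(nrow(q$gold_evidence)),
                                       function(i)
                  list(doc_id = q$gold_evidence$doc_id[i],
                       area_id = q$gold_evidence$area_id[i])))
         }))
  }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read and write study records as JSON lines
#'
#' One JSON object per line, mirroring the fields of [study_record()].
#'
#' @param path file path.
#' @return `read_study_records()`: list of [study_record()]s.
#' @export
read_study_records <- function(path) {
  if (!file.exists(path)) stop("study log not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    marks <- vapply(x$marks, as.integer, integer(1L))
    log <- if (length(x$search_log)) {
      do.call(rbind, lapply(x$search_log, function(s)
        data.frame(question_id = s$question_id, term = s$term,
                   stringsAsFactors = FALSE)))
    } else {
      data.frame(question_id = character(), term = character(),
                 stringsAsFactors = FALSE)
    }
    study_record(x$evaluator_id, x$group, x$task_id, x$functionality,
                 marks, x$elapsed_minutes, log,
                 clinical_band = if (is.null(x$clinical_band)) NA_character_
                                 else x$clinical_band)
  })
}

#' @param records list of [study_record()]s.
#' @rdname read_study_records
#' @return `write_study_records()`: `path`, invisibly.
#' @export
write_study_records <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (r in records) {
    obj <- list(evaluator_id = r$evaluator_id, group = r$group,
                clinical_band = r$clinical_band, task_id = r$task_id,
                functionality = r$functionality,
                marks = as.list(r$marks),
                elapsed_minutes = r$elapsed_minutes,
                search_log = lapply(seq_len(nrow(r$search_log)), function(i)
                  list(question_id = r$search_log$question_id[i],
                       term = r$search_log$term[i])))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}
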