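#' Weights compensating for group-size imbalance
#'
#' Each study group receives equal total weight: an evaluator in group g of
#' size n_g gets weight N / (G * n_g), where N is the total number of
#' evaluators and G the number of groups, so weights sum to N and every
#' group's weight total is N / G. With equal group sizes all weights are 1.
#'
#' @param groups vector of group labels, one per evaluator (names, if any,
#'   are carried to the result).
#' @return named numeric vector of per-evaluator weights.
#' @examples
#' w <- group_weights(rep(c(1, 2, 3), c(7, 13, 15)))
#' tapply(w, rep(c(1, 2, 3), c(7, 13, 15)), sum)  # equal totals
#' @export
group_weights <- function(groups) {
  nm <- names(groups)
  groups <- as.character(groups)
  names(groups) <- nm
  sizes <- table(groups)
  if (any(sizes == 0L)) stop("zero-size group")
  n <- length(groups)
  g <- length(sizes)
  w <- n / (g * as.numeric(sizes[groups]))
  names(w) <- names(groups)
  w
}

#' Weighted paired two-tailed t-test
#'
#' The study's paired contrast between two search functionalities, with
#' sample weights compensating for group-size imbalance. Differences are
#' `d = b - a`. The weighted mean and weighted SD (frequency-weight
#' convention, denominator `sum(w) - 1`) of the differences are combined
#' with the Kish effective sample size `n_eff = (sum w)^2 / sum(w^2)`:
#' `t = mean / (sd / sqrt(n_eff))`, two-tailed p from the t distribution
#' with `n_eff - 1` degrees of freedom. With all weights equal this is
#' exactly the textbook paired t-test. The mean percentage difference is the
#' weighted mean of the per-pair relative differences `100 * d / a`.
#'
#' @param a,b numeric vectors of paired metric values (e.g. accuracy under
#'   each of two functionalities); complete cases only.
#' @param w positive weights (default all 1).
#' @param contrast optional label for printing.
#' @return object of class `weighted_paired_t`: list with `contrast`,
#'   `mean_diff`, `mean_pct_diff`, `sd_diff`, `t_stat`, `p_value`, `n_eff`,
#'   `df`, `n`, `degenerate` (TRUE when all differences are identical so the
#'   SD is zero and p is reported at its limiting value).
#' @examples
#' weighted_paired_t(c(80, 85, 78, 90, 84), c(86, 88, 80, 95, 85))
#' @export
weighted_paired_t <- function(a, b, w = rep(1, length(a)), contrast = NULL) {
  stopifnot(length(a) == length(b), length(w) == length(a))
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("paired values must be complete (no missing values)")
  if (any(w <= 0)) stop("weights must be positive")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- b - a
  sw <- sum(w)
  m <- sum(w * d) / sw
  v <- sum(w * (d - m)^2) / (sw - 1)
  sdd <- sqrt(v)
  n_eff <- sw^2 / sum(w^2)
  df <- n_eff - 1
  pct <- if (any(a == 0)) NA_real_ else sum(w * (100 * d / a)) / sw
  degenerate <- FALSE
  if (sdd == 0) {
    degenerate <- TRUE
    if (m == 0) {
      t_stat <- 0
      p <- 1
    } else {
      # zero variance, nonzero mean: limiting values
      t_stat <- sign(m) * Inf
      p <- 0
    }
  } else {
    t_stat <- m / (sdd / sqrt(n_eff))
    p <- 2 * stats::pt(-abs(t_stat), df = df)
  }
  structure(list(contrast = contrast, mean_diff = m, mean_pct_diff = pct,
                 sd_diff = sdd, t_stat = t_stat, p_value = p, n_eff = n_eff,
                 df = df, n = length(a), degenerate = degenerate),
            class = "weighted_paired_t")
}

#' @export
print.weighted_paired_t <- function(x, ...) {
  cat("Weighted paired two-tailed t-test",
      if (!is.null(x$contrast)) paste0(" (", x$contrast, ")"), "\n", sep = "")
  cat(sprintf("  mean difference: %.3f (%.2f%%; SD %.3f)\n", x$mean_diff,
              x$mean_pct_diff, x$sd_diff))
  cat(sprintf("  t = %.3f, df = %.1f (n = %d, effective n = %.1f), p = %.4g\n",
              x$t_stat, x$df, x$n, x$n_eff, x$p_value))
  if (x$degenerate)
    cat("  note: zero variance in differences; p is a limiting value\n")
  invisible(x)
}

#' Significance at a given level
#'
#' Strict inequality: a result is significant iff `p < alpha`. The study
#' applied a significance level of 0.10.
#'
#' @param result a [weighted_paired_t()] result (or anything with a
#'   `p_value`).
#' @param alpha significance level in (0, 1); default 0.10.
#' @return logical.
#' @export
significance_flag <- function(result, alpha = 0.10) {
  stopifnot(alpha > 0, alpha < 1)
  result$p_value < alpha
}

#' Per-evaluator metric table from study records
#'
#' Computes accuracy ([task_accuracy()]) for each record against its task and
#' assembles the analysis table: one row per evaluator x functionality with
#' the accuracy percentage, elapsed minutes, group, and group-imbalance
#' weight.
#'
#' @param records list of [study_record()]s.
#' @param tasks list of [task()]s covering every `task_id` in the records.
#' @return data frame with columns `evaluator_id`, `group`, `task_id`,
#'   `functionality`, `accuracy`, `minutes`, `weight`.
#' @export
study_metrics <- function(records, tasks) {
  task_ids <- vapply(tasks, `[[`, character(1L), "task_id")
  rows <- lapply(records, function(r) {
    tk <- tasks[[match(r$task_id, task_ids)]]
    if (is.na(match(r$task_id, task_ids)))
      stop("no task definition for task_id ", r$task_id)
    data.frame(evaluator_id = r$evaluator_id, group = r$group,
               task_id = r$task_id, functionality = r$functionality,
               accuracy = task_accuracy(r, tk),
               minutes = r$elapsed_minutes, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ev <- out[!duplicated(out$evaluator_id), c("evaluator_id", "group")]
  w <- group_weights(stats::setNames(ev$group, ev$evaluator_id))
  out$weight <- as.numeric(w[out$evaluator_id])
  out
}

#' Weighted summary of accuracy and time per functionality
#'
#' Weighted mean and SD (frequency-weight convention) of accuracy and task
#' time for each functionality, across evaluators. Every evaluator must
#' contribute exactly one record per functionality (the crossover design);
#' a missing cell is an error naming the evaluator and functionality.
#'
#' @param metrics a table from [study_metrics()] (columns `evaluator_id`,
#'   `functionality`, `accuracy`, `minutes`, `weight`).
#' @return data frame with one row per functionality: weighted
#'   `accuracy_mean`, `accuracy_sd`, `minutes_mean`, `minutes_sd`, and `n`.
#'   With a single evaluator the SDs are 0 and flagged by attribute
#'   `"single_evaluator"`.
#' @export
summarize_by_functionality <- function(metrics) {
  funcs <- intersect(c("none", "string", "nlp"),
                     unique(metrics$functionality))
  evals <- unique(metrics$evaluator_id)
  for (e in evals) {
    for (f in funcs) {
      if (sum(metrics$evaluator_id == e & metrics$functionality == f) != 1L)
        stop("evaluator ", e, " lacks exactly one record for functionality ",
             f)
    }
  }
  wstat <- function(x, w) {
    m <- sum(w * x) / sum(w)
    s <- if (length(x) > 1L) sqrt(sum(w * (x - m)^2) / (sum(w) - 1)) else 0
    c(mean = m, sd = s)
  }
  rows <- lapply(funcs, function(f) {
    sub <- metrics[metrics$functionality == f, , drop = FALSE]
    acc <- wstat(sub$accuracy, sub$weight)
    tim <- wstat(sub$minutes, sub$weight)
    data.frame(functionality = f, accuracy_mean = acc[["mean"]],
               accuracy_sd = acc[["sd"]], minutes_mean = tim[["mean"]],
               minutes_sd = tim[["sd"]], n = nrow(sub),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (length(evals) == 1L) attr(out, "single_evaluator") <- TRUE
  out
}

#' Pairwise functionality contrasts (the crossover analysis)
#'
#' Runs the weighted paired two-tailed t-test for each of the three
#' functionality contrasts (none vs string, none vs nlp, string vs nlp) on a
#' chosen metric, reproducing the shape of the study's pairwise-comparison
#' table. No multiple-testing correction is applied across the contrasts.
#'
#' @param metrics a table from [study_metrics()].
#' @param metric `"accuracy"` or `"minutes"`.
#' @param alpha significance level (default 0.10).
#' @return data frame of class `crossover_contrasts` with one row per
#'   contrast: `contrast`, `mean_diff`, `mean_pct_diff`, `sd_diff`, `t_stat`,
#'   `p_value`, `n_eff`, `significant`.
#' @export
crossover_contrasts <- function(metrics, metric = c("accuracy", "minutes"),
                                alpha = 0.10) {
  metric <- match.arg(metric)
  wide <- stats::reshape(
    metrics[, c("evaluator_id", "functionality", metric, "weight")],
    direction = "wide", idvar = c("evaluator_id", "weight"),
    timevar = "functionality")
  val <- function(f) wide[[paste0(metric, ".", f)]]
  pairs <- list(c("none", "string"), c("none", "nlp"), c("string", "nlp"))
  rows <- lapply(pairs, function(p) {
    a <- val(p[1L]); b <- val(p[2L])
    if (is.null(a) || is.null(b)) return(NULL)
    r <- weighted_paired_t(a, b, wide$weight,
                           contrast = paste(p, collapse = " vs "))
    data.frame(contrast = r$contrast, mean_diff = r$mean_diff,
               mean_pct_diff = r$mean_pct_diff, sd_diff = r$sd_diff,
               t_stat = r$t_stat, p_value = r$p_value, n_eff = r$n_eff,
               significant = significance_flag(r, alpha),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  rownames(out) <- NULL
  class(out) <- c("crossover_contrasts", "data.frame")
  attr(out, "metric") <- metric
  attr(out, "alpha") <- alpha
  out
}

#' @export
print.crossover_contrasts <- function(x, ...) {
  cat(sprintf("Crossover contrasts on %s (alpha = %.2f)\n",
              attr(x, "metric"), attr(x, "alpha")))
  df <- as.data.frame(x)
  df$mean_diff <- round(df$mean_diff, 2)
  df$mean_pct_diff <- round(df$mean_pct_diff, 2)
  df$sd_diff <- round(df$sd_diff, 2)
  df$t_stat <- round(df$t_stat, 2)
  df$p_value <- signif(df$p_value, 2)
  df$n_eff <- round(df$n_eff, 1)
  print.data.frame(df)
  invisible(x)
}
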