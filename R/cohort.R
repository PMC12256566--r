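# Cohort aggregation: outcome tabulation, failure-mode breakdowns,
# per-metric summaries and pooled-variance significance testing.
# Percentages are rounded half-up to one decimal, the convention of the
# audit's printed tables.

#' Percentage breakdown of counts
#'
#' Counts as percentages of their total, rounded half-up to one decimal.
#'
#' @param counts named integer vector.
#' @return Named numeric percentages (sum 100 up to rounding).
#' @export
#' @examples
#' cohortPercentages(c(pass = 271, fail = 10))  # 96.4 / 3.6
cohortPercentages <- function(counts) {
  roundHalfUp(100 * counts / sum(counts), 1)
}

#' Aggregate audit results into a cohort summary
#'
#' Tabulates outcomes per case (counts and percentages), breaks down
#' failure modes over the out-of-tolerance plans, and summarizes each
#' numeric metric per case with mean, SD, median and quartiles. Counts
#' are conserved across every breakdown.
#'
#' @param results list of [AuditResult-class] objects.
#' @param comparisons optional named list of `list(a =, b =)` numeric
#'   series passed to [compareSeries()].
#' @return A [CohortSummary-class].
#' @export
aggregateCohort <- function(results, comparisons = list()) {
  if (!length(results)) stop("empty result list")
  ok <- vapply(results, function(r) is(r, "AuditResult"), TRUE)
  if (!all(ok)) stop("all elements must be AuditResult objects")
  cid <- vapply(results, caseId, "")
  if (any(!cid %in% .CASE_IDS)) stop("unknown case ids present")
  outc <- vapply(results, auditOutcome, "")
  lv <- c("optimal", "action", "out_of_tolerance")
  outcomes <- do.call(rbind, lapply(unique(cid), function(cc) {
    n <- table(factor(outc[cid == cc], levels = lv))
    data.frame(case = cc, outcome = lv, n = as.integer(n),
               pct = cohortPercentages(as.integer(n)))
  }))
  fm <- vapply(results, failureMode, "")[outc == "out_of_tolerance"]
  failureModes <- if (length(fm)) {
    tb <- sort(table(fm), decreasing = TRUE)
    data.frame(failure_mode = names(tb), n = as.integer(tb),
               pct = cohortPercentages(as.integer(tb)))
  } else data.frame(failure_mode = character(), n = integer(),
                    pct = numeric())
  metNames <- unique(unlist(lapply(results, function(r)
    names(Filter(function(x) is.numeric(x) && length(x) == 1,
                 r@metrics)))))
  metNames <- setdiff(metNames, "seed")
  metrics <- do.call(rbind, lapply(unique(cid), function(cc) {
    sub <- results[cid == cc]
    do.call(rbind, lapply(metNames, function(nm) {
      x <- unlist(lapply(sub, function(r) r@metrics[[nm]]))
      x <- x[is.finite(x)]
      if (!length(x)) return(NULL)
      data.frame(case = cc, metric = nm, n = length(x), mean = mean(x),
                 sd = if (length(x) > 1) sd(x) else NA_real_,
                 median = median(x),
                 q25 = unname(quantile(x, 0.25)),
                 q75 = unname(quantile(x, 0.75)))
    }))
  }))
  comp <- lapply(comparisons, function(cp) compareSeries(cp$a, cp$b))
  new("CohortSummary", outcomes = outcomes,
      failureModes = failureModes,
      metrics = if (is.null(metrics)) data.frame() else metrics,
      nTotal = length(results), comparisons = comp)
}

#' Two-sample equal-variance comparison
#'
#' Pooled-variance two-sample t-test (two-sided) between two series of
#' audit metrics, with significance declared strictly below p = 0.05.
#' Degenerate series with zero pooled variance return p = 1 when the
#' means agree and are flagged otherwise.
#'
#' @param a,b numeric series (each n >= 2).
#' @return List with `statistic`, `p.value`, `df`, `significant` and
#'   `degenerate`.
#' @export
#' @examples
#' compareSeries(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, p = 0.021
compareSeries <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each series needs at least 2 values")
  if (sd(a) == 0 && sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (eq) 0 else Inf,
                p.value = if (eq) 1 else NA_real_,
                df = length(a) + length(b) - 2,
                significant = FALSE, degenerate = !eq))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter), significant = tt$p.value < 0.05,
       degenerate = FALSE)
}

#' Write per-plan results and cohort summaries
#'
#' `writeResultsCsv` flattens a list of [AuditResult-class] objects to a
#' per-plan CSV; `writeCohortSummary` writes the outcome and failure-mode
#' tables as CSV plus a JSON digest.
#'
#' @param results list of [AuditResult-class] objects.
#' @param summary a [CohortSummary-class].
#' @param path CSV path; for `writeCohortSummary`, a directory.
#' @return The path, invisibly.
#' @export
writeResultsCsv <- function(results, path) {
  rows <- lapply(results, function(r) {
    m <- Filter(function(x) is.numeric(x) && length(x) == 1, r@metrics)
    cbind(data.frame(case = r@caseId, outcome = r@outcome,
                     failure_mode = r@failureMode,
                     injected_mode = r@injectedMode, seed = r@seed,
                     triggers = paste(r@triggers, collapse = ";")),
          as.data.frame(m))
  })
  cols <- unique(unlist(lapply(rows, names)))
  df <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(cols, names(r))] <- NA
    r[cols]
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResultsCsv
#' @export
writeCohortSummary <- function(summary, path) {
  stopifnot(is(summary, "CohortSummary"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write.csv(summary@outcomes, file.path(path, "outcomes.csv"),
            row.names = FALSE)
  write.csv(summary@failureModes, file.path(path, "failure_modes.csv"),
            row.names = FALSE)
  write.csv(summary@metrics, file.path(path, "metrics.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(n_total = summary@nTotal,
         outcomes = summary@outcomes,
         failure_modes = summary@failureModes,
         comparisons = summary@comparisons),
    file.path(path, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
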