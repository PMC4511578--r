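# Scoring a system knowledge base against a gold knowledge base. Each
# query's result set from the system graph is compared to the result set
# from the gold graph; recall = TP / |gold|, precision = TP / |system|,
# F1 = harmonic mean, all reported as percentages rounded half-up to two
# decimals from the unrounded recall and precision. Empty gold or system
# sets score 0 by convention.

#' Score from result-set sizes
#'
#' The arithmetic core of the evaluation: given the gold result size, the
#' system result size (positives) and the number of true positives,
#' returns recall, precision and F1 as percentages.
#'
#' @param gold_count size of the gold result set (GS).
#' @param sys_count size of the system result set (P, positives).
#' @param tp number of true positives (rows in both sets).
#' @return one-row tibble: `gold_count`, `sys_count`, `tp`, `recall`,
#'   `precision`, `f1` (percentages, half-up to 2 decimals).
#' @export
#' @examples
#' kb_score(604, 604, 497) # 82.28 / 82.28 / 82.28
kb_score <- function(gold_count, sys_count, tp) {
  if (tp > min(gold_count, sys_count)) {
    stop_usage("true positives exceed a result-set size")
  }
  r <- if (gold_count == 0) 0 else 100 * tp / gold_count
  p <- if (sys_count == 0) 0 else 100 * tp / sys_count
  f <- if (r + p == 0) 0 else 2 * r * p / (r + p)
  tibble(gold_count = as.integer(gold_count),
         sys_count = as.integer(sys_count), tp = as.integer(tp),
         recall = round_half_up(r), precision = round_half_up(p),
         f1 = round_half_up(f))
}

#' Score a system result set against a gold result set
#'
#' Set comparison: a system row is a true positive iff the identical tuple
#' occurs in the gold set. Both sets must have the same arity.
#'
#' @param gold,system result-set tibbles from [run_query()] (columns `s1`
#'   or `s1`,`s2`).
#' @return one-row tibble as in [kb_score()].
#' @export
score <- function(gold, system) {
  cols_g <- intersect(c("s1", "s2"), names(gold))
  cols_s <- intersect(c("s1", "s2"), names(system))
  if (!length(cols_g) || !identical(cols_g, cols_s)) {
    stop_usage("gold and system result sets have different arity")
  }
  g <- distinct(as_tibble(gold)[cols_g])
  s <- distinct(as_tibble(system)[cols_s])
  kb_score(nrow(g), nrow(s), nrow(inner_join(g, s, by = cols_g)))
}

#' Expected pair-retrieval score under independence
#'
#' If single items are retrieved with F-score P (a percentage), retrieving
#' pairs is expected to succeed at P x P; e.g. a 59.12% single-protein
#' score predicts 34.95% on pairs. Observed pair scores below this mark a
#' difficulty beyond finding the two members, such as deciding collective
#' versus distributive readings.
#'
#' @param single_f percentage in \[0, 100\].
#' @return percentage, half-up to 2 decimals.
#' @export
#' @examples
#' expected_pair_score(59.12) # 34.95
expected_pair_score <- function(single_f) {
  if (single_f < 0 || single_f > 100) {
    stop_usage("single_f must be a percentage in [0, 100]")
  }
  round_half_up(100 * (single_f / 100)^2)
}

span_doc_bases <- function(g, cfg) {
  spans <- g$triples$object[g$triples$predicate == paste0(cfg$tao, "denoted_by")]
  unique(sub("/spans/.*$", "", spans))
}

#' Evaluate a system graph against a gold graph over the benchmark queries
#'
#' Runs each query on both graphs and scores the result sets. The two
#' graphs must cover the same documents (share span-IRI document bases);
#' disjoint bases mean every score would be vacuously zero and raise a
#' configuration error.
#'
#' @param gold_graph,sys_graph [triple_graph()]s over the same documents.
#' @param queries character vector of query ids, default Q1..Q8.
#' @param cfg a [ns_config()].
#' @return a `kb_evaluation`: tibble with one row per query (`query`,
#'   `gold_count`, `sys_count`, `tp`, `recall`, `precision`, `f1`).
#' @export
evaluate_submission <- function(gold_graph, sys_graph,
                                queries = paste0("Q", 1:8),
                                cfg = ns_config()) {
  gb <- span_doc_bases(gold_graph, cfg)
  sb <- span_doc_bases(sys_graph, cfg)
  if (length(gb) && length(sb) && !length(intersect(gb, sb))) {
    stop_config("gold and system graphs cover disjoint documents (span-IRI bases do not overlap)")
  }
  rows <- list_rbind(map(queries, function(q) {
    res <- score(run_query(gold_graph, q, cfg), run_query(sys_graph, q, cfg))
    bind_cols(tibble(query = q), res)
  }))
  structure(rows, class = c("kb_evaluation", class(rows)))
}

#' @export
print.kb_evaluation <- function(x, ...) {
  cat("KB-oriented evaluation (", nrow(x), " queries)\n", sep = "")
  cat(format_eval_table(x), sep = "\n")
  invisible(x)
}

#' Tidy a KB evaluation
#'
#' @param x a `kb_evaluation` from [evaluate_submission()].
#' @param ... unused.
#' @return a plain tibble, one row per query.
#' @export
tidy.kb_evaluation <- function(x, ...) {
  as_tibble(unclass_eval(x))
}

#' One-row summary of a KB evaluation
#'
#' @param x a `kb_evaluation`.
#' @param ... unused.
#' @return tibble with query count, total gold/system/TP counts, micro-
#'   and macro-averaged F1.
#' @export
glance.kb_evaluation <- function(x, ...) {
  micro <- kb_score(sum(x$gold_count), sum(x$sys_count), sum(x$tp))
  tibble(n_queries = nrow(x),
         gold_total = sum(x$gold_count),
         sys_total = sum(x$sys_count),
         tp_total = sum(x$tp),
         micro_f1 = micro$f1,
         macro_f1 = round_half_up(mean(x$f1)))
}

unclass_eval <- function(x) {
  class(x) <- setdiff(class(x), "kb_evaluation")
  x
}

#' Format an evaluation as the benchmark tables print it
#'
#' Columns query, P (positives), TP, and `R / Pr / F` with each percentage
#' zero-padded to two integer digits (so 4.2 prints as 04.20 and an empty
#' system row as 00.00 / 00.00 / 00.00).
#'
#' @param ev a `kb_evaluation` (or compatible tibble).
#' @param format "tsv" or "markdown".
#' @return character vector of lines.
#' @export
format_eval_table <- function(ev, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  rpf <- sprintf("%s / %s / %s", format_pct(ev$recall),
                 format_pct(ev$precision), format_pct(ev$f1))
  if (format == "tsv") {
    c("query\tGS\tP\tTP\tR / Pr / F",
      sprintf("%s\t%d\t%d\t%d\t%s", ev$query, ev$gold_count, ev$sys_count,
              ev$tp, rpf))
  } else {
    c("| query | GS | P | TP | R / Pr / F |",
      "|---|---|---|---|---|",
      sprintf("| %s | %d | %d | %d | %s |", ev$query, ev$gold_count,
              ev$sys_count, ev$tp, rpf))
  }
}

#' Plot a KB evaluation
#'
#' Grouped bars of recall, precision and F1 per query.
#'
#' @param object a `kb_evaluation`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.kb_evaluation <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy.kb_evaluation(object),
                              c("recall", "precision", "f1"),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, c("recall", "precision", "f1"))
  ggplot2::ggplot(long, ggplot2::aes(x = query, y = value, fill = metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(y = "%", x = NULL, fill = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
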