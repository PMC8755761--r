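#' Paired t-test on replicate (experiment) means
#'
#' Cell-level measurements are not independent across one experiment, so
#' significance is computed on the replicate means: cells are averaged
#' within each replicate x condition, replicates are paired across the two
#' conditions, and a classical two-sided paired Student's t-test is run on
#' the paired means. Significance stars follow the *P < 0.05,
#' **P < 0.01, ***P < 0.001 convention. Zero variance of the paired
#' differences (infinite t) is returned flagged as degenerate.
#'
#' @param table data.frame with columns value, cell_id, replicate,
#'   condition.
#' @param condition_a,condition_b the two condition labels to compare.
#' @return list of class `paired_test`: t, df, p_value, stars,
#'   replicate_means (data.frame), degenerate.
#' @examples
#' tb <- data.frame(value = c(10, 12, 11, 15, 9, 12),
#'                  cell_id = 1:6,
#'                  replicate = rep(1:3, each = 2),
#'                  condition = rep(c("a", "b"), 3))
#' paired_experiment_test(tb, "a", "b")
#' @export
paired_experiment_test <- function(table, condition_a, condition_b) {
  need <- c("value", "cell_id", "replicate", "condition")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  ta <- table[table$condition == condition_a, ]
  tb <- table[table$condition == condition_b, ]
  reps_a <- sort(unique(ta$replicate))
  reps_b <- sort(unique(tb$replicate))
  unpaired <- union(setdiff(reps_a, reps_b), setdiff(reps_b, reps_a))
  if (length(unpaired))
    stop("replicate(s) without a pair in both conditions: ",
         paste(unpaired, collapse = ", "))
  reps <- reps_a
  if (length(reps) < 2)
    stop("need at least 2 complete replicate pairs")
  mean_a <- vapply(reps, function(r)
    mean(ta$value[ta$replicate == r]), numeric(1))
  mean_b <- vapply(reps, function(r)
    mean(tb$value[tb$replicate == r]), numeric(1))
  rm_tab <- data.frame(replicate = reps, mean_a = mean_a, mean_b = mean_b,
                       difference = mean_b - mean_a)
  d <- rm_tab$difference
  if (stats::sd(d) < .Machine$double.eps^0.5 * max(1, mean(abs(d)))) {
    t_val <- if (all(d == 0)) 0 else Inf * sign(mean(d))
    return(structure(list(
      t = t_val, df = length(d) - 1,
      p_value = if (all(d == 0)) 1 else 0,
      stars = "", replicate_means = rm_tab,
      degenerate = !all(d == 0)), class = "paired_test"))
  }
  ht <- stats::t.test(mean_b, mean_a, paired = TRUE)
  structure(list(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, stars = p_stars(ht$p.value),
    replicate_means = rm_tab, degenerate = FALSE),
    class = "paired_test")
}

p_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else ""
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("paired t-test on replicate means: t = %.4g, df = %d, p = %.4g %s%s\n",
              x$t, x$df, x$p_value, x$stars,
              if (x$degenerate) " [degenerate: zero-variance differences]"
              else ""))
  invisible(x)
}

#' Superplot-style export of a cell-level experiment table
#'
#' Produces the tidy long table behind a superplot: every cell-level point
#' tagged with its replicate, the replicate means (the units on which the
#' statistics run), and the condition-level summary. Conditions with no
#' cells are dropped with a warning.
#'
#' @param table data.frame with columns value, cell_id, replicate,
#'   condition.
#' @param plot if `TRUE` and ggplot2 is installed, also return a ggplot.
#' @return list: `cells` (level = "cell" rows), `replicates` (per-replicate
#'   means), `conditions` (condition mean, sd, n_replicates), and `plot`
#'   (ggplot or NULL).
#' @export
superplot_export <- function(table, plot = FALSE) {
  need <- c("value", "cell_id", "replicate", "condition")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  empty <- setdiff(unique(table$condition),
                   unique(table$condition[!is.na(table$value)]))
  if (length(empty)) {
    warning("condition(s) with no values omitted: ",
            paste(empty, collapse = ", "))
    table <- table[!table$condition %in% empty, ]
  }
  cells <- data.frame(level = "cell", table[, need])
  key <- interaction(table$condition, table$replicate, drop = TRUE)
  reps <- do.call(rbind, lapply(split(table, key), function(d)
    data.frame(level = "replicate", condition = d$condition[1],
               replicate = d$replicate[1], n_cells = nrow(d),
               value = mean(d$value))))
  conds <- do.call(rbind, lapply(split(reps, reps$condition), function(d)
    data.frame(level = "condition", condition = d$condition[1],
               n_replicates = nrow(d), value = mean(d$value),
               sd = stats::sd(d$value))))
  rownames(reps) <- rownames(conds) <- NULL
  p <- NULL
  if (plot && requireNamespace("ggplot2", quietly = TRUE)) {
    p <- ggplot2::ggplot(cells,
           ggplot2::aes(x = condition, y = value,
                        colour = factor(replicate))) +
      ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 1) +
      ggplot2::geom_point(data = reps, size = 4, shape = 17) +
      ggplot2::labs(colour = "replicate") +
      ggplot2::theme_classic()
  }
  list(cells = cells, replicates = reps, conditions = conds, plot = p)
}
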