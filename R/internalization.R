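#' Percent antigen on the cell surface, quench statistic
#'
#' The quench readout of internalization: surface-exposed probe is quenched,
#' so the surviving fluorescence reports the internalized pool. The percent
#' of antigen still on the surface is
#' \deqn{100 - \frac{F_Q - F_{bg}}{F_{noQ} - F_{bg}} \times 100}
#' where `F_Q` is the mean fluorescence of the quenched sample, `F_noQ` of
#' its unquenched pair at the same timepoint, and `F_bg` the background.
#' Values outside \[0, 100\] can arise from noise; they are returned raw and
#' flagged unless `clip = TRUE`.
#'
#' @param F_Q mean fluorescence after quenching (a.u.).
#' @param F_noQ mean fluorescence before quenching, same timepoint (a.u.).
#' @param F_bg background fluorescence (a.u.).
#' @param clip clip results into \[0, 100\] instead of flagging?
#' @param sample_label label used in error messages for failing samples.
#' @return numeric percent with attribute `out_of_range` (logical vector).
#' @examples
#' percent_surface_quench(55, 105, 5)   # 50
#' @export
percent_surface_quench <- function(F_Q, F_noQ, F_bg, clip = FALSE,
                                   sample_label = NULL) {
  check_finite(F_Q, F_noQ, F_bg)
  denom <- F_noQ - F_bg
  if (any(denom <= 0))
    stop(sprintf(
      "non-positive denominator F_noQ - F_bg%s: F_noQ = %s, F_bg = %s",
      if (is.null(sample_label)) "" else paste0(" for sample ", sample_label),
      format(F_noQ[denom <= 0][1]), format(F_bg[denom <= 0][1])))
  p <- 100 - (F_Q - F_bg) / denom * 100
  finish_percent(p, clip)
}

#' Percent antigen on the cell surface, time-zero statistic
#'
#' For surface stains that do not use the quencher (e.g. biotinylated
#' ligand + surface streptavidin): the surface signal at time `x` is
#' referenced to the non-internalised time-0 control, which defines 100\%:
#' \deqn{\frac{F_x - F_{bg}}{F_0 - F_{bg}} \times 100}
#'
#' @param F_x mean fluorescence at time x (a.u.).
#' @param F_0 mean fluorescence at time 0, kept on ice (a.u.).
#' @param F_bg background fluorescence (a.u.).
#' @param clip clip results into \[0, 100\] instead of flagging?
#' @param sample_label label used in error messages.
#' @return numeric percent with attribute `out_of_range`.
#' @examples
#' percent_surface_timezero(60, 110, 10)   # 50
#' percent_surface_timezero(110, 110, 10)  # 100: the time-0 identity
#' @export
percent_surface_timezero <- function(F_x, F_0, F_bg, clip = FALSE,
                                     sample_label = NULL) {
  check_finite(F_x, F_0, F_bg)
  denom <- F_0 - F_bg
  if (any(denom <= 0))
    stop(sprintf(
      "non-positive denominator F_0 - F_bg%s: F_0 = %s, F_bg = %s",
      if (is.null(sample_label)) "" else paste0(" for sample ", sample_label),
      format(F_0[denom <= 0][1]), format(F_bg[denom <= 0][1])))
  p <- (F_x - F_bg) / denom * 100
  finish_percent(p, clip)
}

check_finite <- function(...) {
  vals <- c(...)
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop("all fluorescence summaries must be finite numbers")
}

finish_percent <- function(p, clip) {
  oor <- p < 0 | p > 100
  if (clip) {
    p <- pmin(pmax(p, 0), 100)
    oor <- rep(FALSE, length(p))
  }
  attr(p, "out_of_range") <- oor
  p
}

#' Summarize a per-cell flow table into an internalization curve
#'
#' Aggregates a per-cell fluorescence table (simulator output or a flow
#' cytometry CSV export) into per-timepoint percent-surface /
#' percent-internalized values. In `"quench"` mode each timepoint needs a
#' paired quenched and unquenched group and the quench statistic is
#' applied; in `"timezero"` mode unquenched groups are referenced to the
#' time-0 group. Background is the group statistic of the `"unstained"`
#' rows when present, else `background` must be given. Per-replicate values
#' are propagated: one row per replicate x timepoint.
#'
#' @param table data.frame with columns cell_id, timepoint_min, quenched,
#'   replicate, intensity and optionally group (stained/unstained).
#' @param mode `"quench"`, `"timezero"`, or `"auto"` (quench when any
#'   quenched rows exist).
#' @param statistic group statistic, `"mean"` (MFI convention) or
#'   `"median"`.
#' @param background background constant used when no unstained rows exist.
#' @param clip clip out-of-range percentages?
#' @return data.frame of class `internalization_curve`: replicate,
#'   timepoint_min, percent_surface, percent_internalized, n_cells, flag,
#'   method. `percent_surface + percent_internalized` is exactly 100.
#' @export
summarize_flow_table <- function(table, mode = c("auto", "quench", "timezero"),
                                 statistic = c("mean", "median"),
                                 background = NULL, clip = FALSE) {
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  need <- c("cell_id", "timepoint_min", "quenched", "replicate", "intensity")
  if (!all(need %in% names(table)))
    stop("flow table must have columns: ", paste(need, collapse = ", "))
  if (!"group" %in% names(table)) table$group <- "stained"
  stat_fun <- if (statistic == "mean") mean else stats::median

  stained <- table[table$group != "unstained", ]
  if (mode == "auto")
    mode <- if (any(stained$quenched == 1, na.rm = TRUE)) "quench"
            else "timezero"

  out <- list()
  for (rep_i in sort(unique(stained$replicate))) {
    rt <- stained[stained$replicate == rep_i, ]
    un <- table[table$group == "unstained" & table$replicate == rep_i, ]
    F_bg <- if (nrow(un) > 0) stat_fun(un$intensity)
            else if (!is.null(background)) background
            else stop("no unstained rows in replicate ", rep_i,
                      " and no `background` constant supplied")
    tps <- sort(unique(rt$timepoint_min))
    if (mode == "quench") {
      for (tp in tps) {
        fq  <- rt$intensity[rt$timepoint_min == tp & rt$quenched == 1]
        fnq <- rt$intensity[rt$timepoint_min == tp & rt$quenched == 0]
        if (!length(fq) || !length(fnq))
          stop("timepoint ", tp, " min (replicate ", rep_i,
               ") lacks a quenched/unquenched pair")
        p <- percent_surface_quench(stat_fun(fq), stat_fun(fnq), F_bg,
                                    clip = clip,
                                    sample_label = paste0("t=", tp, "min"))
        out[[length(out) + 1L]] <- curve_row(rep_i, tp, p,
                                             length(fq) + length(fnq),
                                             "quench")
      }
    } else {
      f0 <- rt$intensity[rt$timepoint_min == 0 & rt$quenched %in% 0]
      if (!length(f0))
        stop("timezero mode requires an unquenched time-0 group",
             " (replicate ", rep_i, ")")
      F_0 <- stat_fun(f0)
      for (tp in tps) {
        fx <- rt$intensity[rt$timepoint_min == tp & rt$quenched %in% 0]
        p <- percent_surface_timezero(stat_fun(fx), F_0, F_bg, clip = clip,
                                      sample_label = paste0("t=", tp, "min"))
        out[[length(out) + 1L]] <- curve_row(rep_i, tp, p, length(fx),
                                             "timezero")
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("internalization_curve", "data.frame")
  res
}

curve_row <- function(rep_i, tp, p, n, method) {
  data.frame(replicate = rep_i, timepoint_min = tp,
             percent_surface = as.numeric(p),
             percent_internalized = 100 - as.numeric(p),
             n_cells = n,
             flag = if (attr(p, "out_of_range")) "out_of_range" else "ok",
             method = method)
}

#' Fit delayed-exponential kinetics to an internalization curve
#'
#' Least-squares fit of `100 * (1 - exp(-k * max(0, t - lag)))` to the
#' percent-internalized values, used to recover the simulator's kinetics
#' from an estimated curve. A curve with (near-)constant percent values is
#' non-identifiable and returned flagged instead of fitted.
#'
#' @param curve an `internalization_curve` from [summarize_flow_table()],
#'   or any data.frame with timepoint_min and percent_internalized.
#' @return list: `lag_min`, `rate_k`, `residual_norm`, `identifiable`,
#'   `fit` (the nls object or NULL).
#' @export
fit_internalization_kinetics <- function(curve) {
  stopifnot(all(c("timepoint_min", "percent_internalized") %in% names(curve)))
  t <- curve$timepoint_min
  y <- curve$percent_internalized
  if (length(t) < 3) stop("need at least 3 timepoints to fit kinetics")
  if (stats::sd(y) < 1e-8 || diff(range(y)) < 0.5)
    return(list(lag_min = NA_real_, rate_k = NA_real_,
                residual_norm = NA_real_, identifiable = FALSE, fit = NULL))
  # crude rate guess from the largest observed fraction
  ymax <- max(min(max(y) / 100, 0.99), 0.01)
  k0 <- -log(1 - ymax) / max(max(t), 1)
  model_fn <- function(p) 100 * (1 - exp(-p[1] * pmax(0, t - p[2])))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(k = k0, lag = min(c(t[y > max(y) / 20], 1))),
      fn = function(p) y - model_fn(p),
      lower = c(k = 1e-6, lag = 0),
      upper = c(k = 10, lag = max(t)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$deviance))
    return(list(lag_min = NA_real_, rate_k = NA_real_,
                residual_norm = NA_real_, identifiable = FALSE, fit = NULL))
  cf <- fit$par
  list(lag_min = unname(cf["lag"]), rate_k = unname(cf["k"]),
       residual_norm = sqrt(fit$deviance),
       identifiable = TRUE, fit = fit)
}
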