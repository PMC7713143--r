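#' Group summary statistics
#'
#' @param label Group labels.
#' @param mean,sd Per-group mean and SD (any variable units).
#' @param n Per-group sample sizes (>= 2).
#' @return A `group_summary` data.frame.
#' @export
group_summary <- function(label, mean, sd, n) {
  if (any(n < 2)) stopf("every group needs n >= 2")
  if (any(sd < 0)) stopf("SDs must be >= 0")
  structure(data.frame(label = as.character(label), mean = mean, sd = sd,
                       n = as.integer(n), stringsAsFactors = FALSE),
            class = c("group_summary", "data.frame"))
}

as_group_summary <- function(x) {
  if (inherits(x, "group_summary")) return(x)
  if (is.data.frame(x)) {
    cols <- c("label", "mean", "sd", "n")
    if (!all(cols %in% names(x)))
      stopf("summary input needs columns %s", paste(cols, collapse = ", "))
    return(group_summary(x$label, x$mean, x$sd, x$n))
  }
  if (is.list(x)) return(do.call(rbind, lapply(x, as_group_summary)))
  stopf("cannot interpret input as group summaries")
}

#' One-way ANOVA from summary statistics
#'
#' Computes the one-way fixed-effects ANOVA exactly from per-group means,
#' SDs and sizes:
#' `MS_between = sum(n_i (m_i - grand)^2) / (k - 1)`,
#' `MS_within  = sum((n_i - 1) sd_i^2) / (N - k)`, `F = MSB / MSW`,
#' p from the F distribution on (k - 1, N - k) df. Identical to a raw-data
#' ANOVA on any dataset with those moments (machine precision).
#'
#' @param groups A [group_summary()] (or data.frame with columns `label`,
#'   `mean`, `sd`, `n`); at least 2 groups.
#' @return A `stats_result` list: `F`, `df` (between, within), `p`,
#'   `ms_within`, `flag` (`"zero_within_variance"` when MSW = 0 with
#'   unequal means, in which case p = 0).
#' @export
anova_from_summary <- function(groups) {
  g <- as_group_summary(groups)
  k <- nrow(g)
  if (k < 2L) stopf("need at least 2 groups")
  N <- sum(g$n)
  grand <- sum(g$n * g$mean) / N
  msb <- sum(g$n * (g$mean - grand)^2) / (k - 1)
  msw <- sum((g$n - 1) * g$sd^2) / (N - k)
  flag <- NA_character_
  if (msw == 0) {
    if (msb == 0) { F <- 0; p <- 1 }
    else { F <- Inf; p <- 0; flag <- "zero_within_variance" }
  } else {
    F <- msb / msw
    p <- stats::pf(F, k - 1, N - k, lower.tail = FALSE)
  }
  structure(list(F = F, df = c(between = k - 1, within = N - k), p = p,
                 ms_within = msw, groups = g, flag = flag),
            class = "stats_result")
}

#' @export
print.stats_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Tukey HSD adjusted p-values from summary statistics
#'
#' Studentized-range test per group pair using the pooled within-group mean
#' square: `q = |m_i - m_j| / sqrt(MSW/2 * (1/n_i + 1/n_j))`, referred to
#' the studentized range distribution with `k` means and `N - k` df. For
#' balanced designs this is the exact Tukey HSD; for unbalanced input it is
#' the Tukey-Kramer form.
#'
#' @inheritParams anova_from_summary
#' @return data.frame with `pair`, `diff`, `q` and adjusted `p_adj`.
#' @export
tukey_from_summary <- function(groups) {
  g <- as_group_summary(groups)
  a <- anova_from_summary(g)
  k <- nrow(g)
  pairs <- utils::combn(k, 2)
  out <- data.frame(pair = character(0), diff = numeric(0), q = numeric(0),
                    p_adj = numeric(0))
  for (c_i in seq_len(ncol(pairs))) {
    i <- pairs[1, c_i]; j <- pairs[2, c_i]
    diff <- g$mean[j] - g$mean[i]
    if (a$ms_within == 0) {
      q <- if (diff == 0) 0 else Inf
      p <- if (diff == 0) 1 else 0
    } else {
      se <- sqrt(a$ms_within / 2 * (1 / g$n[i] + 1 / g$n[j]))
      q <- abs(diff) / se
      p <- stats::ptukey(q, nmeans = k, df = a$df[["within"]],
                         lower.tail = FALSE)
    }
    out <- rbind(out, data.frame(
      pair = paste0(g$label[j], "/", g$label[i]), diff = diff, q = q,
      p_adj = p))
  }
  out
}

#' Percent difference with printed-table rounding
#'
#' `100 * (test / reference - 1)`, rounded half away from zero to the
#' requested number of digits (the convention used when tabulating percent
#' columns: integer percent for volume comparisons, one decimal for
#' biomechanical columns).
#'
#' @param test,reference Values to compare; `reference` must be non-zero.
#' @param digits Decimal digits of the printed percent (default 0).
#' @return Percent difference (vectorized).
#' @export
percent_difference <- function(test, reference, digits = 0) {
  if (any(reference == 0)) stopf("reference value must be non-zero")
  round_half_away(100 * (test / reference - 1), digits)
}

#' Paired cis-vs-trans comparison within a group
#'
#' Wilcoxon signed-rank test of per-sample cis versus trans callus volumes
#' (the non-parametric branch; it needs raw per-sample data and cannot run
#' from summary tables).
#'
#' @param cis,trans Paired per-sample values.
#' @return `htest` object from [stats::wilcox.test()].
#' @export
compare_cis_trans <- function(cis, trans) {
  if (length(cis) != length(trans)) stopf("cis/trans must be paired")
  stats::wilcox.test(cis, trans, paired = TRUE, exact = TRUE)
}

#' Group comparison table from per-sample data
#'
#' Builds a printed-table-style report: per-variable group summaries,
#' one-way ANOVA, Tukey post-hoc p-values and all pairwise percent
#' differences of group means. Accepts long-format raw data (one row per
#' sample and variable) or a ready-made summary table.
#'
#' @param data Long data.frame with columns `sample`, `group`, `variable`,
#'   `value`, or a summary data.frame with columns `variable`, `label`,
#'   `mean`, `sd`, `n`.
#' @param group_order Optional character vector fixing group order (the
#'   first group is the percent-difference reference).
#' @param digits Percent rounding digits per variable (single value or named
#'   vector by variable).
#' @return A `comparison_table` list with data.frames `summary`, `anova`,
#'   `posthoc`, `percent_diffs`.
#' @export
build_comparison_table <- function(data, group_order = NULL, digits = 0) {
  if (all(c("sample", "group", "variable", "value") %in% names(data))) {
    miss <- is.na(data$value)
    flagged <- unique(data$sample[miss])
    data <- data[!miss, , drop = FALSE]
    summ <- do.call(rbind, lapply(split(data, data[c("variable", "group")],
                                        drop = TRUE), function(d)
      data.frame(variable = d$variable[1], label = d$group[1],
                 mean = mean(d$value), sd = stats::sd(d$value),
                 n = nrow(d))))
    if (length(flagged))
      warning("samples with missing values flagged: ",
              paste(flagged, collapse = ", "), call. = FALSE)
  } else if (all(c("variable", "label", "mean", "sd", "n") %in% names(data))) {
    summ <- data
  } else stopf("unrecognized input layout for build_comparison_table")
  rownames(summ) <- NULL
  if (is.null(group_order)) group_order <- unique(summ$label)
  summ$label <- factor(summ$label, levels = group_order)
  summ <- summ[order(summ$variable, summ$label), ]
  summ$label <- as.character(summ$label)

  anova <- list(); posthoc <- list(); pct <- list()
  for (v in unique(summ$variable)) {
    s <- summ[summ$variable == v, ]
    if (nrow(s) < 2L) { warning("variable ", v, " has < 2 groups; skipped",
                                call. = FALSE); next }
    gs <- group_summary(s$label, s$mean, s$sd, s$n)
    a <- anova_from_summary(gs)
    anova[[v]] <- data.frame(variable = v, F = a$F,
                             df_between = a$df[["between"]],
                             df_within = a$df[["within"]], p = a$p,
                             flag = a$flag)
    tk <- tukey_from_summary(gs)
    posthoc[[v]] <- cbind(variable = v, tk)
    dg <- if (length(digits) > 1L) digits[[v]] else digits
    pairs <- utils::combn(nrow(s), 2)
    ref <- s$mean[pairs[1, ]]
    pc <- rep(NA_real_, ncol(pairs))   # NA when the reference mean is 0
    ok <- ref != 0
    pc[ok] <- percent_difference(s$mean[pairs[2, ]][ok], ref[ok], dg)
    pct[[v]] <- data.frame(
      variable = v,
      pair = paste0(s$label[pairs[2, ]], "/", s$label[pairs[1, ]]),
      pct = pc)
  }
  structure(list(summary = summ,
                 anova = do.call(rbind, c(anova, make.row.names = FALSE)),
                 posthoc = do.call(rbind, c(posthoc, make.row.names = FALSE)),
                 percent_diffs = do.call(rbind, c(pct, make.row.names = FALSE))),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  for (v in unique(x$summary$variable)) {
    s <- x$summary[x$summary$variable == v, ]
    a <- x$anova[x$anova$variable == v, ]
    cat(sprintf("%s: %s | ANOVA p = %.4g\n", v,
                paste(sprintf("%s %.4g +/- %.3g (n=%d)", s$label, s$mean,
                              s$sd, s$n), collapse = ", "), a$p))
    ph <- x$posthoc[x$posthoc$variable == v & x$posthoc$p_adj < 0.05, ]
    if (nrow(ph))
      cat("  post-hoc:", paste(sprintf("%s (p = %.4g)", ph$pair, ph$p_adj),
                               collapse = ", "), "\n")
  }
  invisible(x)
}
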