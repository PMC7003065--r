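#' Summarize immobile fractions across biological replicates
#'
#' @param fractions Numeric vector of per-replicate immobile percentages
#'   (one value per biological replicate, each in `[0, 100]`).
#' @param condition Condition label.
#' @param n_cells,n_tracks Optional totals carried through for reporting.
#'
#' @return An object of class `replicate_summary`: `condition`,
#'   `replicate_fractions`, `mean`, `sd` (sample standard deviation, n - 1
#'   denominator; `NA` for a single replicate), `n_replicates`, `n_cells`,
#'   `n_tracks`.
#' @export
#' @examples
#' summarize_replicates(c(30, 40), condition = "darT")
summarize_replicates <- function(fractions, condition = "",
                                 n_cells = NA_integer_,
                                 n_tracks = NA_integer_) {
  if (length(fractions) == 0L) {
    stop("need at least one replicate fraction", call. = FALSE)
  }
  if (any(!is.finite(fractions)) || any(fractions < 0 | fractions > 100)) {
    stop("replicate fractions must be percentages in [0, 100]", call. = FALSE)
  }
  structure(
    list(
      condition = condition,
      replicate_fractions = as.numeric(fractions),
      mean = mean(fractions),
      sd = if (length(fractions) > 1L) sd(fractions) else NA_real_,
      n_replicates = length(fractions),
      n_cells = n_cells,
      n_tracks = n_tracks
    ),
    class = "replicate_summary"
  )
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("%s: immobile %.1f%% +/- %.1f (n = %d replicates)\n",
              if (nzchar(x$condition)) x$condition else "<condition>",
              x$mean, x$sd, x$n_replicates))
  invisible(x)
}

#' Unpaired two-sample comparison of replicate fractions
#'
#' Classic unpaired two-tailed t-test between two groups of per-replicate
#' percentages. The default uses the pooled-variance (Student) form with
#' `n_a + n_b - 2` degrees of freedom; `welch = TRUE` switches to the
#' Welch-Satterthwaite form. When both groups are constant and equal the
#' statistic is defined as `t = 0`, `p = 1`.
#'
#' @param a,b Numeric vectors of per-replicate percentages, each of length
#'   `>= 2`.
#' @param labels Character vector of length 2 naming the conditions.
#' @param welch Use the Welch unequal-variance form? Default `FALSE`.
#'
#' @return An object of class `group_comparison`: `condition_a`,
#'   `condition_b`, `mean_a`, `mean_b`, `t_statistic`, `df`, `p_value`,
#'   `test`.
#' @export
#' @examples
#' compare_groups(c(10, 12), c(20, 22), labels = c("control", "darT"))
compare_groups <- function(a, b, labels = c("a", "b"), welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 replicates", call. = FALSE)
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("replicate fractions must be finite", call. = FALSE)
  }
  na <- length(a)
  nb <- length(b)
  delta <- mean(a) - mean(b)
  if (welch) {
    va <- var(a) / na
    vb <- var(b) / nb
    se <- sqrt(va + vb)
    df <- if (se > 0) (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1)) else na + nb - 2
  } else {
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  if (se == 0) {
    t_stat <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 1 else 0
  } else {
    t_stat <- delta / se
    p <- 2 * pt(-abs(t_stat), df = df)
  }
  structure(
    list(
      condition_a = labels[1L], condition_b = labels[2L],
      mean_a = mean(a), mean_b = mean(b),
      t_statistic = t_stat, df = df, p_value = p,
      test = paste0("unpaired two-tailed t-test (",
                    if (welch) "Welch" else "pooled variance", ")")
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s (%.1f%%) vs %s (%.1f%%): t = %.3f, df = %.2f, p = %.4g\n",
              x$condition_a, x$mean_a, x$condition_b, x$mean_b,
              x$t_statistic, x$df, x$p_value))
  cat(" ", x$test, "\n")
  invisible(x)
}
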