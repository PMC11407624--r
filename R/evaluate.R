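#' Detection accuracy as a function of window length
#'
#' Summarizes a table of per-trial detection results (possibly pooled
#' over several window lengths and methods) into percent accuracy per
#' method and window length, with the standard deviation of the per-block
#' accuracies (one block = one presentation of all targets).
#'
#' @param results data.frame as returned by [classify_cca()] and friends,
#'   rows from several window lengths may be concatenated.
#' @return An `evaluation_summary`: data.frame with `method`,
#'   `window_length`, `n_trials`, `accuracy_pct`, `sd_pct` (across
#'   blocks), and `itr_bits_min` computed with the window length as the
#'   selection time.
#' @export
accuracy_over_time <- function(results) {
  if (is.null(results) || nrow(results) == 0) {
    stop("no detection results to summarize", call. = FALSE)
  }
  n_targets <- length(unique(results$true_frequency))
  groups <- split(results, list(results$method, results$window_length),
                  drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    correct <- g$true_frequency == g$detected_frequency
    acc <- 100 * mean(correct)
    block_acc <- tapply(correct, g$block, mean) * 100
    data.frame(
      method = g$method[1],
      window_length = g$window_length[1],
      n_trials = nrow(g),
      accuracy_pct = acc,
      sd_pct = if (length(block_acc) > 1) stats::sd(block_acc) else NA_real_,
      itr_bits_min = itr(n_targets, mean(correct), g$window_length[1])
    )
  }))
  rownames(out) <- NULL
  out <- out[order(out$method, out$window_length), ]
  class(out) <- c("evaluation_summary", class(out))
  out
}

#' Information transfer rate of a selection system
#'
#' Wolpaw's formula: `ITR = 60/T * (log2 N + p log2 p +
#' (1-p) log2((1-p)/(N-1)))` bits per minute, where `N` is the number of
#' targets, `p` the accuracy and `T` the selection time in seconds. The
#' `p log2 p` term is taken as 0 at `p = 0`; at `p = 1` the rate is
#' `60/T * log2 N`. The formula is 0 at chance (`p = 1/N`) and, by
#' convention, clamped to 0 below chance.
#'
#' @param n_targets number of selectable targets N (>= 2).
#' @param p accuracy in `[0, 1]`.
#' @param t_select selection time T in seconds (> 0).
#' @return bits per minute.
#' @examples
#' itr(4, 1, 5)     # 24 bits/min
#' itr(4, 0.25, 5)  # 0 at chance
#' @export
itr <- function(n_targets, p, t_select) {
  stopifnot(n_targets >= 2, t_select > 0)
  if (any(p < 0 | p > 1)) {
    stop("accuracy p must lie in [0, 1]", call. = FALSE)
  }
  xlog2x <- function(x) ifelse(x > 0, x * log2(x), 0)
  bits <- log2(n_targets) + xlog2x(p) +
    ifelse(p < 1, (1 - p) * log2((1 - p) / (n_targets - 1)), 0)
  bits <- ifelse(p < 1 / n_targets, 0, bits)   # clamp below chance
  60 / t_select * bits
}

#' Paired comparison of two experimental conditions
#'
#' Tests the paired differences for normality (Shapiro-Wilk at 0.05) and
#' applies a paired t-test when normal, a Wilcoxon signed-rank test
#' otherwise. Stars follow the reporting convention `*` for p < 0.01 and
#' `**` for p < 0.05.
#'
#' @param a,b equal-length paired numeric vectors (n >= 3), e.g. per-block
#'   accuracies under two conditions.
#' @param alpha significance level used for the `significant` flag
#'   (default 0.05).
#' @param labels length-2 character vector naming the conditions.
#' @return A `condition_comparison` list: `test` (`"paired t"` or
#'   `"wilcoxon signed-rank"`), `normal` (Shapiro flag), `p_value`,
#'   `stars`, `significant`, `mean_difference`.
#' @export
compare_conditions <- function(a, b, alpha = 0.05,
                               labels = c("A", "B")) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  d <- b - a
  if (all(d == 0)) {
    return(structure(
      list(labels = labels, test = "none (identical samples)",
           normal = NA, p_value = 1, stars = "", significant = FALSE,
           mean_difference = 0),
      class = "condition_comparison"))
  }
  if (stats::sd(d) == 0) {
    # constant non-zero shift: a t statistic is undefined and normality
    # untestable; the signed-rank test still applies (all signs agree)
    warning("paired differences are constant; using the signed-rank test",
            call. = FALSE)
    p <- suppressWarnings(stats::wilcox.test(b, a, paired = TRUE)$p.value)
    stars <- if (p < 0.01) "*" else if (p < 0.05) "**" else ""
    return(structure(
      list(labels = labels, test = "wilcoxon signed-rank", normal = NA,
           p_value = p, stars = stars, significant = p < alpha,
           mean_difference = mean(d)),
      class = "condition_comparison"))
  }
  normal <- stats::shapiro.test(d)$p.value >= 0.05
  if (normal) {
    test <- "paired t"
    p <- stats::t.test(b, a, paired = TRUE)$p.value
  } else {
    test <- "wilcoxon signed-rank"
    p <- suppressWarnings(stats::wilcox.test(b, a, paired = TRUE)$p.value)
  }
  stars <- if (p < 0.01) "*" else if (p < 0.05) "**" else ""
  structure(
    list(labels = labels, test = test, normal = normal, p_value = p,
         stars = stars, significant = p < alpha,
         mean_difference = mean(d)),
    class = "condition_comparison"
  )
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> %s vs %s: %s, p = %.4g %s\n",
              x$labels[1], x$labels[2], x$test, x$p_value, x$stars))
  invisible(x)
}

#' Confusion matrix of detection results
#'
#' Counts of (true, detected) frequency pairs over all trials; rows are
#' true frequencies, columns detected.
#'
#' @param results data.frame of per-trial detection results.
#' @param candidates optional frequency levels fixing the matrix layout.
#' @return An integer matrix, rows = true, columns = detected.
#' @export
confusion_matrix <- function(results, candidates = NULL) {
  if (is.null(results) || nrow(results) == 0) {
    stop("no detection results", call. = FALSE)
  }
  if (is.null(candidates)) {
    candidates <- sort(unique(c(results$true_frequency,
                                results$detected_frequency)))
  }
  tru <- factor(results$true_frequency, levels = candidates)
  det <- factor(results$detected_frequency, levels = candidates)
  unclass(table(true = tru, detected = det))
}
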