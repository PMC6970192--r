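#' Per-group summaries of RP indexes
#'
#' Summarizes retained acini by a grouping column of the results table:
#' count, mean, standard deviation and standard error of the signed RP
#' index, plus the group-mean radial profile.
#'
#' @param table Results table (data frame) with RP columns, e.g.
#'   `analysis$table` from [analyze_dataset()].
#' @param by Grouping column, usually `"condition"`.
#' @return Data frame with one row per non-empty group (`group`, `n_acini`,
#'   `mean_rp`, `sd_rp`, `sem_rp`) and attribute `profiles`, a matrix of
#'   per-terrace group-mean RP values (groups in rows).
#' @export
summarize_groups <- function(table, by = "condition") {
  keep <- table[table$excluded_reason == "none", , drop = FALSE]
  groups <- unique(table[[by]])
  empty <- setdiff(groups, unique(keep[[by]]))
  if (length(empty) > 0L)
    warning("groups with no retained acini omitted: ",
            paste(empty, collapse = ", "))
  groups <- setdiff(groups, empty)
  if (length(groups) == 0L) {
    out <- data.frame(group = character(), n_acini = integer(),
                      mean_rp = numeric(), sd_rp = numeric(),
                      sem_rp = numeric())
    attr(out, "profiles") <- NULL
    return(out)
  }
  rp_cols <- grep("^RP_\\d+$", names(table), value = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- keep$rp_index[keep[[by]] == g]
    data.frame(group = g, n_acini = length(v), mean_rp = mean(v),
               sd_rp = if (length(v) > 1L) stats::sd(v) else 0,
               sem_rp = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0)
  }))
  prof <- do.call(rbind, lapply(groups, function(g)
    colMeans(keep[keep[[by]] == g, rp_cols, drop = FALSE])))
  rownames(prof) <- groups
  attr(out, "profiles") <- prof
  out
}

#' Student's t-test between two groups of RP indexes
#'
#' Classical pooled-variance two-sample Student's t-test (two-sided) on the
#' signed RP indexes of two groups of acini. Welch's unequal-variance
#' variant is available behind `var_equal = FALSE`.
#'
#' @param a,b Numeric vectors of RP indexes, each of length >= 2.
#' @param labels Length-2 character vector naming the groups.
#' @param var_equal Pool the variances (classical Student) if `TRUE`.
#' @return Data frame row with `group_a`, `group_b`, `t`, `df`, `p`.
#' @export
rp_t_test <- function(a, b, labels = c("a", "b"), var_equal = TRUE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  res <- tryCatch(
    stats::t.test(a, b, var.equal = var_equal),
    error = function(e) NULL)  # both samples essentially constant
  if (is.null(res)) {
    df <- length(a) + length(b) - 2
    if (isTRUE(all.equal(mean(a), mean(b))))
      res <- list(statistic = c(t = 0), parameter = c(df = df), p.value = 1)
    else
      res <- list(statistic = c(t = sign(mean(a) - mean(b)) * Inf),
                  parameter = c(df = df), p.value = 0)
  }
  data.frame(group_a = labels[1], group_b = labels[2],
             t = unname(res$statistic), df = unname(res$parameter),
             p = res$p.value)
}

#' Pairwise group comparisons of a results table
#'
#' @param table Results table with retained acini.
#' @param by Grouping column.
#' @param var_equal Passed to [rp_t_test()].
#' @return Data frame with one row per group pair (groups with fewer than
#'   two retained acini are skipped with a warning).
#' @export
compare_groups <- function(table, by = "condition", var_equal = TRUE) {
  keep <- table[table$excluded_reason == "none", , drop = FALSE]
  cnt <- table(keep[[by]])
  groups <- names(cnt)[cnt >= 2L]
  if (length(groups) < length(cnt))
    warning("groups with < 2 retained acini skipped in comparisons")
  if (length(groups) < 2L) return(NULL)
  combs <- utils::combn(groups, 2L)
  do.call(rbind, lapply(seq_len(ncol(combs)), function(j) {
    g1 <- combs[1, j]; g2 <- combs[2, j]
    rp_t_test(keep$rp_index[keep[[by]] == g1],
              keep$rp_index[keep[[by]] == g2],
              labels = c(g1, g2), var_equal = var_equal)
  }))
}
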