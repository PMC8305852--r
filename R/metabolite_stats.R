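#' Read a summary metabolite table (mean +/- sd)
#'
#' Long-format CSV with columns `line`, `compound`, `mean`, `sd` (and
#' optionally `n`, defaulting to 3 biological replicates).  Not-detected
#' entries may be written "ND"; they are kept as a distinct missing state
#' (`nd = TRUE`) and count as 0 in totals.
#'
#' @param path CSV file.
#' @return data.frame with columns `line`, `compound`, `mean`, `sd`, `n`,
#'   `nd`.
#' @export
read_metabolite_summary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line", "compound", "mean", "sd")
  missing_c <- setdiff(need, names(df))
  if (length(missing_c))
    stopf("summary table lacks column(s): %s", paste(missing_c, collapse = ", "))
  nd <- toupper(trimws(as.character(df$mean))) == "ND"
  df$nd <- nd
  df$mean <- suppressWarnings(as.numeric(df$mean))
  df$sd <- suppressWarnings(as.numeric(df$sd))
  df$mean[nd] <- NA_real_
  df$sd[nd] <- NA_real_
  if (is.null(df$n)) df$n <- 3L
  df
}

#' Read a replicate-level metabolite table
#'
#' Long-format CSV with columns `line`, `replicate`, `compound`, `value`.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_metabolite_replicates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line", "replicate", "compound", "value")
  missing_c <- setdiff(need, names(df))
  if (length(missing_c))
    stopf("replicate table lacks column(s): %s", paste(missing_c, collapse = ", "))
  df
}

# Per-line compound means from either table shape.
profile_means <- function(table, line) {
  t <- table[table$line == line, , drop = FALSE]
  if (!nrow(t)) stopf("line not in table: %s", line)
  if ("mean" %in% names(t)) {
    m <- t$mean
    m[isTRUE_vec(t$nd)] <- 0
    m[is.na(m)] <- 0
    stats::setNames(m, t$compound)
  } else {
    agg <- tapply(t$value, t$compound, mean)
    stats::setNames(as.numeric(agg), names(agg))
  }
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE

#' Total concentration of one line's profile
#'
#' Arithmetic sum of compound means, with not-detected compounds counting as
#' zero, rounded half away from zero to the table's printed precision.
#'
#' @param table summary or replicate metabolite table.
#' @param line line name.
#' @param digits decimals to report (2 for micromole-scale tables, 1 for
#'   microgram-scale hydrolysis tables).
#' @return rounded total.
#' @export
total_concentration <- function(table, line, digits = 2) {
  m <- profile_means(table, line)
  if (any(m < 0)) stopf("negative concentration in profile of %s", line)
  round_half_up(sum(m), digits)
}

#' Percentage of the total carried by one compound
#'
#' `100 * mean(compound) / total`, rounded to the nearest integer for
#' range-style reporting ("80 to 91% of the total").
#'
#' @param table metabolite table.
#' @param line line name.
#' @param compound compound name.
#' @return integer percentage.
#' @export
component_fraction <- function(table, line, compound) {
  m <- profile_means(table, line)
  total <- sum(m)
  if (total <= 0) stopf("total is zero for line %s; fraction undefined", line)
  if (!compound %in% names(m)) stopf("compound %s absent for line %s",
                                     compound, line)
  as.integer(round_half_up(100 * m[[compound]] / total, 0))
}

#' Fold enrichment of a line over a control
#'
#' Ratio of the line's value to the control's, on the total (component sum)
#' or on a single compound, reported to 1 decimal (fold-column convention).
#'
#' @param table metabolite table containing both lines.
#' @param line,control line names.
#' @param compound one compound name, or NULL for the total.
#' @param digits decimals for the reported fold (default 1).
#' @return rounded fold change.
#' @export
fold_change <- function(table, line, control, compound = NULL, digits = 1) {
  ml <- profile_means(table, line)
  mc <- profile_means(table, control)
  if (is.null(compound)) {
    num <- sum(ml)
    den <- sum(mc)
  } else {
    if (!compound %in% names(ml) || !compound %in% names(mc))
      stopf("compound %s absent", compound)
    num <- ml[[compound]]
    den <- mc[[compound]]
  }
  if (den == 0) stopf("control value is zero; fold undefined")
  round_half_up(num / den, digits)
}

#' Select lines by a compound threshold
#'
#' Lines whose compound mean satisfies the inequality — e.g. the selection of
#' high-GSL lines by progoitrin content below 0.6.
#'
#' @param table metabolite table.
#' @param compound compound name.
#' @param threshold numeric threshold.
#' @param direction one of "<", "<=", ">", ">=".
#' @return character vector of passing line names.
#' @export
screen_lines <- function(table, compound, threshold, direction = "<") {
  cmp <- switch(direction, "<" = `<`, "<=" = `<=`, ">" = `>`, ">=" = `>=`,
                stopf("direction must be one of <, <=, >, >="))
  lines <- unique(table$line)
  vals <- vapply(lines, function(ln) {
    m <- profile_means(table, ln)
    if (!compound %in% names(m)) stopf("compound %s absent for line %s",
                                       compound, ln)
    m[[compound]]
  }, numeric(1))
  lines[cmp(vals, threshold)]
}

#' One-way ANOVA with a compact letter display
#'
#' Fixed-effects one-way ANOVA from replicate vectors, or reconstructed from
#' per-level (n, mean, sd) summaries when only printed mean +/- sd values are
#' available (flagged `summary_based`).  Post-hoc pairwise comparisons use
#' Tukey's honest significant difference or Duncan's multiple range test;
#' letters are assigned from the level with the highest mean ("a"), each
#' letter shared by a maximal set of mutually non-different levels (maximal
#' cliques of the non-significance graph).
#'
#' @param data either a replicate data.frame with columns `level` and
#'   `value`, or a summary data.frame with columns `level`, `n`, `mean`,
#'   `sd`.
#' @param alpha significance level (default 0.05).
#' @param method "tukey" (default) or "duncan".
#' @return object of class `dh_group_comparison`: list with `anova`
#'   (data.frame: term, df, sum_sq, mean_sq, statistic, p_value), `means`
#'   (level, n, mean, sd, letters, ordered by decreasing mean), `significant`
#'   (logical matrix of pairwise differences), `alpha`, `method`,
#'   `summary_based`.
#' @export
anova_with_letters <- function(data, alpha = 0.05, method = c("tukey", "duncan")) {
  method <- match.arg(method)
  if (all(c("level", "value") %in% names(data))) {
    summary_based <- FALSE
    lv <- split(data$value, data$level)
    bad <- names(lv)[vapply(lv, length, integer(1)) < 2]
    if (length(bad))
      stopf("level(s) with fewer than 2 replicates: %s",
            paste(bad, collapse = ", "))
    n <- vapply(lv, length, numeric(1))
    m <- vapply(lv, mean, numeric(1))
    s <- vapply(lv, stats::sd, numeric(1))
  } else if (all(c("level", "n", "mean", "sd") %in% names(data))) {
    summary_based <- TRUE
    if (any(data$n < 2))
      stopf("level(s) with fewer than 2 replicates: %s",
            paste(data$level[data$n < 2], collapse = ", "))
    n <- stats::setNames(as.numeric(data$n), data$level)
    m <- stats::setNames(as.numeric(data$mean), data$level)
    s <- stats::setNames(as.numeric(data$sd), data$level)
  } else {
    stopf("data must have columns (level, value) or (level, n, mean, sd)")
  }
  k <- length(m)
  if (k < 2) stopf("at least 2 levels required")
  N <- sum(n)
  grand <- sum(n * m) / N
  ss_between <- sum(n * (m - grand)^2)
  ss_within <- sum((n - 1) * s^2)
  df_b <- k - 1
  df_w <- N - k
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  f <- if (ms_w > 0) ms_b / ms_w else if (ms_b == 0) 0 else Inf
  p <- if (is.finite(f)) stats::pf(f, df_b, df_w, lower.tail = FALSE) else 0
  if (ms_b == 0 && ms_w == 0) p <- 1

  ord <- order(-m)
  lev <- names(m)[ord]
  sig <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      li <- lev[i]; lj <- lev[j]
      diff_ij <- abs(m[li] - m[lj])
      if (ms_w == 0) {
        sig[li, lj] <- sig[lj, li] <- diff_ij > 0
        next
      }
      if (method == "tukey") {
        se <- sqrt(ms_w / 2 * (1 / n[li] + 1 / n[lj]))
        pv <- stats::ptukey(diff_ij / se, k, df_w, lower.tail = FALSE)
        s_ij <- pv < alpha
      } else {
        # Duncan: critical range depends on how many ranked means the pair
        # spans, at protection level 1 - (1 - alpha)^(span - 1)
        span <- j - i + 1
        nh <- 2 / (1 / n[li] + 1 / n[lj])
        se <- sqrt(ms_w / nh)
        crit <- stats::qtukey(1 - (1 - (1 - alpha)^(span - 1)), span, df_w,
                              lower.tail = FALSE)
        s_ij <- diff_ij / se > crit
      }
      sig[li, lj] <- sig[lj, li] <- s_ij
    }
  }
  letters_map <- letter_display(sig, m[lev])
  means <- data.frame(level = lev, n = n[lev], mean = m[lev], sd = s[lev],
                      letters = letters_map[lev], stringsAsFactors = FALSE)
  rownames(means) <- NULL
  anova_tab <- data.frame(
    term = c("between", "within", "total"),
    df = c(df_b, df_w, N - 1),
    sum_sq = c(ss_between, ss_within, ss_between + ss_within),
    mean_sq = c(ms_b, ms_w, NA),
    statistic = c(f, NA, NA),
    p_value = c(p, NA, NA))
  structure(list(anova = anova_tab, means = means, significant = sig,
                 alpha = alpha, method = method,
                 summary_based = summary_based),
            class = "dh_group_comparison")
}

# Compact letter display: maximal cliques of the "not significantly
# different" graph, lettered from the clique containing the highest mean.
letter_display <- function(sig, means) {
  lev <- rownames(sig)
  if (length(lev) == 1) return(stats::setNames("a", lev))
  g <- igraph::graph_from_adjacency_matrix(!sig & !diag(nrow(sig)),
                                           mode = "undirected")
  cl <- igraph::max_cliques(g)
  cl_levels <- lapply(cl, function(x) lev[as.integer(x)])
  cl_max <- vapply(cl_levels, function(x) max(means[x]), numeric(1))
  cl_levels <- cl_levels[order(-cl_max)]
  out <- stats::setNames(rep("", length(lev)), lev)
  for (i in seq_along(cl_levels)) {
    for (l in cl_levels[[i]]) out[l] <- paste0(out[l], letters[i])
  }
  vapply(out, function(x) paste(sort(strsplit(x, "")[[1]]), collapse = ""),
         character(1))
}

#' @export
print.dh_group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA (%s post-hoc, alpha = %g%s)\n",
              x$method, x$alpha,
              if (x$summary_based) ", reconstructed from mean +/- sd" else ""))
  print(x$anova, row.names = FALSE)
  cat("\n")
  print(x$means, row.names = FALSE)
  invisible(x)
}

#' Path to a packaged metabolite or genotype fixture
#'
#' @param name fixture file name, e.g. "table1_gsl.csv",
#'   "table4_hydrolysis.csv", "table3_matrix.csv".
#' @return absolute path.
#' @export
dhblocks_fixture <- function(name) {
  p <- system.file("extdata", name, package = "dhblocks")
  if (p == "") stopf("no packaged fixture named %s", name)
  p
}
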