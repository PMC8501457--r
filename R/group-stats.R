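# Experiment-level statistics over field-of-view summaries:
# interaction-gated factorial ANOVA (type II when interactions are not
# significant, type III otherwise) and Tukey-adjusted pairwise
# comparisons, with the field of view as the statistical unit.

#' Interaction-gated factorial ANOVA
#'
#' Fits the full factorial linear model `response ~ f1 * f2 * ...` and
#' examines the interaction terms.  If no interaction is significant at
#' `gate_alpha` the term table reported is a type II ANOVA; if any
#' interaction is significant, the model is refit with sum-to-zero
#' contrasts and a type III table is reported (type III is only
#' interpretable under such contrasts).
#'
#' @param table Data frame of field-of-view summaries.
#' @param response Name of the numeric response column.
#' @param factors Character vector of factor column names (each coerced
#'   to factor).
#' @param gate_alpha Significance level for the interaction gate.
#' @return An object of class `anova_result`: data frame `terms`
#'   (`term`, `ss`, `df`, `f`, `p`), `ss_type` (`"II"` or `"III"`), and
#'   `interaction_significant`.
#' @export
factorial_anova <- function(table, response, factors, gate_alpha = 0.05) {
  assert_that(all(c(response, factors) %in% names(table)),
              "missing columns in table")
  df <- table
  for (f in factors) df[[f]] <- factor(df[[f]])
  counts <- table(df[factors])
  assert_that(all(counts >= 2),
              "every factor-level cell needs >= 2 observations",
              class = "design_error")
  fml <- stats::as.formula(paste(response, "~",
                                 paste(factors, collapse = " * ")))
  m2 <- lm(fml, data = df)
  if (var(df[[response]]) < .Machine$double.eps) {
    terms2 <- attr(stats::terms(m2), "term.labels")
    return(structure(list(
      terms = data.frame(term = terms2, ss = 0, df = NA_integer_,
                         f = 0, p = NA_real_),
      ss_type = "II", interaction_significant = FALSE,
      note = "constant response; F undefined"),
      class = "anova_result"))
  }
  a2 <- car::Anova(m2, type = 2)
  t2 <- as.data.frame(a2)
  t2$term <- rownames(t2)
  inter <- grepl(":", t2$term, fixed = TRUE)
  pcol <- grep("^Pr", names(t2), value = TRUE)
  inter_sig <- any(t2[[pcol]][inter] < gate_alpha, na.rm = TRUE)
  if (inter_sig) {
    contr <- lapply(factors, function(f) "contr.sum")
    names(contr) <- factors
    m3 <- lm(fml, data = df, contrasts = contr)
    a3 <- as.data.frame(car::Anova(m3, type = 3))
    a3$term <- rownames(a3)
    a3 <- a3[!a3$term %in% c("(Intercept)", "Residuals"), ]
    out <- data.frame(term = a3$term, ss = a3[["Sum Sq"]], df = a3$Df,
                      f = a3[["F value"]], p = a3[[grep("^Pr", names(a3))]])
    ss_type <- "III"
  } else {
    a2d <- t2[t2$term != "Residuals", ]
    out <- data.frame(term = a2d$term, ss = a2d[["Sum Sq"]], df = a2d$Df,
                      f = a2d[["F value"]], p = a2d[[pcol]])
    ss_type <- "II"
  }
  structure(list(terms = out, ss_type = ss_type,
                 interaction_significant = inter_sig),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> type %s (interaction %ssignificant)\n",
              x$ss_type, if (x$interaction_significant) "" else "not "))
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' Significance stars for adjusted p-values
#'
#' `****` for p < 1e-4, `***` < 1e-3, `**` < 0.01, `*` < 0.05, else `ns`.
#' @param p Numeric vector of p-values.
#' @return Character vector of annotations.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Tukey-adjusted pairwise comparisons
#'
#' Groups are all combinations of the given factors; every pair is
#' compared with the studentized-range (Tukey HSD) adjustment.
#'
#' @param table Data frame of field-of-view summaries.
#' @param response Name of the response column.
#' @param factors Character vector of grouping factor columns.
#' @param alpha Familywise significance level.
#' @return Data frame with `pair`, `diff`, `lwr`, `upr`, `p_adj`,
#'   `stars`, `significant`.
#' @export
tukey_pairwise <- function(table, response, factors, alpha = 0.05) {
  grp <- interaction(table[factors], sep = ":", drop = TRUE)
  assert_that(nlevels(grp) >= 2, "need at least two groups")
  assert_that(all(table(grp) >= 2),
              "every group needs >= 2 observations", class = "design_error")
  df <- data.frame(.y = table[[response]], .g = grp)
  tk <- TukeyHSD(aov(.y ~ .g, data = df), conf.level = 1 - alpha)$.g
  out <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"], row.names = NULL)
  # exact ties can produce tiny negative adjusted p from ptukey round-off
  out$p_adj <- pmin(pmax(out$p_adj, 0), 1)
  out$stars <- significance_stars(out$p_adj)
  out$significant <- out$p_adj < alpha
  out
}

#' Per-group mean and SEM over fields of view
#'
#' @param table Data frame of field-of-view summaries.
#' @param response Name of the response column.
#' @param grouping Character vector of grouping columns.
#' @return Data frame with the grouping columns plus `n`, `mean`, `sem`.
#' @export
experiment_sem <- function(table, response, grouping) {
  split_idx <- interaction(table[grouping], sep = ":", drop = TRUE)
  parts <- split(table[[response]], split_idx)
  assert_that(all(lengths(parts) >= 2),
              "need >= 2 fields per group for an SEM", class = "design_error")
  agg <- aggregate(table[[response]],
                   by = lapply(grouping, function(g) table[[g]]),
                   FUN = function(v) c(n = length(v), mean = mean(v),
                                       sem = sd(v) / sqrt(length(v))))
  res <- data.frame(agg[seq_along(grouping)], agg$x)
  names(res) <- c(grouping, "n", "mean", "sem")
  res
}
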