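#' Pearson correlation of paired per-gene fold-changes
#'
#' Pairs two per-gene log2 fold-change tables by `gene_id` (genes
#' missing from either side are dropped and counted) and computes the
#' Pearson coefficient with the usual two-sided t-transform p-value,
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df.
#'
#' @param x,y tibbles with `gene_id` and a fold-change column.
#' @param x_col,y_col fold-change column names (default `"log2fc"`).
#' @return object of class `fc_cor` with `r`, `n`, `p`, `n_dropped`;
#'   see [tidy.fc_cor()].
#' @export
fc_correlation <- function(x, y, x_col = "log2fc", y_col = "log2fc") {
  paired <- inner_join(select(x, "gene_id", xv = all_of(x_col)),
                       select(y, "gene_id", yv = all_of(y_col)),
                       by = "gene_id")
  paired <- paired[complete.cases(paired), , drop = FALSE]
  n_dropped <- nrow(x) + nrow(y) - 2 * nrow(paired)
  if (nrow(paired) < 3) abort("fewer than 3 paired genes")
  if (sd(paired$xv) == 0 || sd(paired$yv) == 0) {
    abort("correlation undefined: one of the fold-change vectors is constant")
  }
  ct <- stats::cor.test(paired$xv, paired$yv, method = "pearson")
  structure(list(r = unname(ct$estimate), n = nrow(paired),
                 p = ct$p.value, statistic = unname(ct$statistic),
                 n_dropped = n_dropped, data = paired),
            class = "fc_cor")
}

#' @exportS3Method base::print
print.fc_cor <- function(x, ...) {
  cat(sprintf("Pearson fold-change correlation: r = %.4f, n = %d, p = %.3g (%d unpaired genes dropped)\n",
              x$r, x$n, x$p, x$n_dropped))
  invisible(x)
}

#' Tidiers for chiprx result objects
#'
#' `tidy()` returns one row per estimated quantity; `glance()` a
#' one-row model summary, following broom conventions.
#'
#' @param x an `fc_cor` or `bulk_anova` object.
#' @param ... unused.
#' @return a tibble.
#' @exportS3Method generics::tidy
tidy.fc_cor <- function(x, ...) {
  tibble(estimate = x$r, statistic = x$statistic, p.value = x$p,
         n = x$n, n.dropped = x$n_dropped)
}

#' @rdname tidy.fc_cor
#' @exportS3Method generics::glance
glance.fc_cor <- function(x, ...) tidy.fc_cor(x)

#' Multi-factor main-effects ANOVA
#'
#' Fits a main-effects linear model (no interactions) of a single
#' response on the supplied design factors and reports, per factor, the
#' Type II sum of squares, degrees of freedom, F statistic and p-value
#' (Type II equals the sequential decomposition on balanced designs).
#' This is the analysis behind "the bulk signal varied independently
#' with condition, cell type and mark" style statements.
#'
#' @param data data frame of observations.
#' @param response name of the response column.
#' @param factors character vector of factor column names.
#' @param log_response analyse `log(response)` instead (default FALSE).
#' @return object of class `bulk_anova`; see [tidy.bulk_anova()].
#' @export
anova_main_effects <- function(data, response, factors,
                               log_response = FALSE) {
  data <- as.data.frame(data)
  stopifnot(response %in% names(data), all(factors %in% names(data)))
  for (f in factors) {
    data[[f]] <- droplevels(factor(data[[f]]))
    if (nlevels(data[[f]]) < 2) {
      abort(sprintf("factor '%s' has fewer than 2 levels", f))
    }
  }
  y <- if (log_response) log(data[[response]]) else data[[response]]
  data$.y <- y
  fml <- as.formula(paste(".y ~", paste(factors, collapse = " + ")))
  fit <- lm(fml, data = data)
  if (anyNA(coef(fit))) {
    abort("design is rank-deficient: factors are confounded/aliased")
  }
  if (fit$df.residual < 1) {
    abort("degenerate design: zero residual degrees of freedom")
  }
  rss <- sum(residuals(fit)^2)
  if (rss <= .Machine$double.eps * sum(y^2)) {
    abort("degenerate design: zero residual variance")
  }
  tab <- car::Anova(fit, type = 2)
  structure(list(fit = fit, table = tab, response = response,
                 factors = factors, log_response = log_response),
            class = "bulk_anova")
}

#' @exportS3Method base::print
print.bulk_anova <- function(x, ...) {
  cat(sprintf("Main-effects ANOVA of %s%s\n",
              if (x$log_response) "log " else "", x$response))
  print(x$table)
  invisible(x)
}

#' @rdname tidy.fc_cor
#' @exportS3Method generics::tidy
tidy.bulk_anova <- function(x, ...) {
  tab <- as.data.frame(x$table)
  tibble(term = rownames(tab), sumsq = tab$`Sum Sq`, df = tab$Df,
         statistic = tab$`F value`, p.value = tab$`Pr(>F)`)
}

#' @rdname tidy.fc_cor
#' @exportS3Method generics::glance
glance.bulk_anova <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, sigma = s$sigma,
         df.residual = x$fit$df.residual,
         nobs = length(residuals(x$fit)))
}

#' Ordered-rank fold-change table and induction summary
#'
#' Orders a per-gene log2 fold-change table ascending (the "each gene
#' against its ordered rank" display) and summarises the fraction of
#' detected genes with positive fold-change, reported in the
#' "induced/detected" style.
#'
#' @param fc tibble with `gene_id` and `log2fc`.
#' @return tibble `rank, gene_id, log2fc`, with attribute `summary`, a
#'   tibble `n_induced, n_detected, fraction, label`; also retrievable
#'   with [induction_summary()].
#' @export
rank_table <- function(fc) {
  out <- fc |>
    select("gene_id", "log2fc") |>
    arrange(.data$log2fc, .data$gene_id) |>
    mutate(rank = row_number()) |>
    select("rank", "gene_id", "log2fc")
  attr(out, "summary") <- induction_summary(fc)
  out
}

#' @rdname rank_table
#' @export
induction_summary <- function(fc) {
  n_ind <- sum(fc$log2fc > 0)
  n_det <- nrow(fc)
  tibble(n_induced = n_ind, n_detected = n_det,
         fraction = n_ind / n_det,
         label = sprintf("%d/%d", n_ind, n_det))
}

#' Rank-curve plot of per-gene fold-changes
#'
#' @param ranked [rank_table()] output (or any tibble with `rank` and
#'   `log2fc`).
#' @return a ggplot.
#' @export
plot_rank_curve <- function(ranked) {
  ggplot2::ggplot(ranked, ggplot2::aes(x = .data$rank, y = .data$log2fc)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::labs(x = "ordered rank", y = "log2 fold-change") +
    ggplot2::theme_minimal()
}
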