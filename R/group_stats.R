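# Per-genotype summaries (mean +/- SEM) and one-way ANOVA with pairwise
# contrasts against the wild type.

#' Summarize a parameter by genotype
#'
#' Sample mean and standard error of the mean (SD/sqrt(n)) per group. SEM
#' is \code{NA} (flagged) for singleton groups.
#'
#' @param values Numeric vector.
#' @param group Grouping vector (genotype labels), same length.
#' @param parameter Optional parameter name carried into the output.
#' @return data.frame: \code{parameter, genotype, n, mean, sem}.
#' @export
summarize_by_genotype <- function(values, group, parameter = NA_character_) {
  stopifnot(length(values) == length(group))
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- as.character(group[keep])
  if (length(values) == 0) stop("no non-missing values to summarize")
  levs <- unique(group)
  rows <- lapply(levs, function(g) {
    x <- values[group == g]
    data.frame(parameter = parameter, genotype = g, n = length(x),
               mean = mean(x),
               sem = if (length(x) >= 2) sd(x) / sqrt(length(x))
                     else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square F statistic with its F-distribution
#' p-value (equal-variance one-way ANOVA). Degenerate inputs with zero
#' between- and within-group variance return F = 0, p = 1, flagged.
#'
#' @param values Numeric vector.
#' @param group Grouping vector; at least 2 groups with at least 2 values
#'   each.
#' @return List: \code{f, p, df1, df2, degenerate}.
#' @export
anova_oneway <- function(values, group) {
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- factor(as.character(group[keep]))
  sizes <- table(group)
  if (nlevels(group) < 2) stop("anova_oneway needs at least 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 values")

  grand <- mean(values)
  means <- tapply(values, group, mean)
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum((values - means[group])^2)
  df1 <- nlevels(group) - 1L
  df2 <- length(values) - nlevels(group)

  if (ssw == 0 && ssb == 0) {
    return(list(f = 0, p = 1, df1 = df1, df2 = df2, degenerate = TRUE))
  }
  ow <- oneway.test(values ~ group, var.equal = TRUE)
  list(f = unname(ow$statistic), p = unname(ow$p.value),
       df1 = df1, df2 = df2, degenerate = FALSE)
}

#' Pairwise contrasts of each genotype against the wild type
#'
#' Two-sided Welch t-tests of every non-reference group against the
#' reference (default uncorrected, mirroring per-contrast reporting of
#' pairwise p-values after an ANOVA gate); Holm correction available.
#'
#' @param values Numeric vector.
#' @param group Grouping vector; must contain the reference level.
#' @param ref Reference genotype label (default \code{"WT"}).
#' @param adjust \code{"none"} (default) or \code{"holm"}.
#' @param parameter Optional parameter name carried into the output.
#' @return List of class \code{"comparison_result"}: \code{parameter},
#'   \code{anova} (from \code{\link{anova_oneway}}) and \code{contrasts}
#'   (data.frame \code{genotype, n, difference, p}).
#' @export
contrasts_vs_wt <- function(values, group, ref = "WT",
                            adjust = c("none", "holm"),
                            parameter = NA_character_) {
  adjust <- match.arg(adjust)
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- as.character(group[keep])
  if (!ref %in% group) stop("reference group '", ref, "' not present")
  aov_res <- anova_oneway(values, group)

  wt <- values[group == ref]
  others <- setdiff(unique(group), ref)
  rows <- lapply(others, function(g) {
    x <- values[group == g]
    identical_groups <- length(x) == length(wt) &&
      sd(c(x, wt)) == 0
    p <- if (identical_groups) 1 else {
      tryCatch(t.test(x, wt)$p.value, error = function(e) NA_real_)
    }
    data.frame(genotype = g, n = length(x),
               difference = mean(x) - mean(wt), p = p,
               stringsAsFactors = FALSE)
  })
  contrasts <- do.call(rbind, rows)
  if (adjust == "holm") contrasts$p <- p.adjust(contrasts$p, "holm")
  structure(list(parameter = parameter, anova = aov_res,
                 contrasts = contrasts, ref = ref, adjust = adjust),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result%s> ANOVA F(%d,%d) = %.3g, p = %.4g\n",
              if (is.na(x$parameter)) "" else paste0(" ", x$parameter),
              x$anova$df1, x$anova$df2, x$anova$f, x$anova$p))
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}
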