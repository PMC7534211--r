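#' The four experimental groups
#'
#' Group labels of the 2-geometry x 2-flow design: capillary tube vs
#' parallel-plate chamber, static (0 mPa) vs perfused (10 mPa).
#' @export
PERFUSION_GROUPS <- c("cap_static", "cap_flow", "ppfc_static", "ppfc_flow")

check_grouped <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  if (anyNA(values)) {
    keep <- !is.na(values)
    values <- values[keep]; groups <- groups[keep]
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2) {
    stop("insufficient-replication error: need >= 2 groups", call. = FALSE)
  }
  n <- table(groups)
  if (any(n < 2)) {
    stop("insufficient-replication error: group(s) ",
         paste(names(n)[n < 2], collapse = ", "), " have n < 2",
         call. = FALSE)
  }
  list(values = values, groups = groups)
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance: F is the ratio of
#' the between-group to within-group mean squares on (k - 1, N - k) degrees
#' of freedom. All groups identical gives F = 0, p = 1.
#'
#' @param values Numeric observations (per-sample means in the intended
#'   design).
#' @param groups Group labels, same length.
#' @return List with `F`, `p`, `df` (c(between, within)).
#' @export
#' @examples
#' anova_oneway(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
anova_oneway <- function(values, groups) {
  d <- check_grouped(values, groups)
  k <- nlevels(d$groups)
  N <- length(d$values)
  tol <- 1e-12 * (sum(d$values^2) + 1)
  sst <- sum((d$values - mean(d$values))^2)
  ssw <- sum(unlist(tapply(d$values, d$groups,
                           function(x) (x - mean(x))^2)))
  dfs <- c(between = k - 1L, within = N - k)
  # degenerate dispersion handled explicitly: floating-point dust from the
  # linear-model fit must not produce spurious F values
  if (sst < tol) return(list(F = 0, p = 1, df = dfs))
  if (ssw < tol) return(list(F = Inf, p = 0, df = dfs))
  fit <- stats::aov(v ~ g, data = data.frame(v = d$values, g = d$groups))
  tab <- summary(fit)[[1]]
  list(F = tab[1, "F value"], p = tab[1, "Pr(>F)"], df = dfs)
}

#' Tukey HSD post hoc comparisons
#'
#' All pairwise group-mean differences with studentized-range adjusted
#' p-values after a one-way ANOVA; the Tukey-Kramer extension handles
#' unbalanced designs.
#'
#' @param values,groups As in [anova_oneway()].
#' @param alpha Family-wise significance level.
#' @return Data frame: `pair`, `group1`, `group2`, `diff` (group1 - group2),
#'   `lwr`, `upr`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  d <- check_grouped(values, groups)
  fit <- stats::aov(v ~ g, data = data.frame(v = d$values, g = d$groups))
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  tk <- matrix(tk, ncol = 4, dimnames = dimnames(tk))
  ssw <- sum(unlist(tapply(d$values, d$groups,
                           function(x) (x - mean(x))^2)))
  if (ssw < 1e-12 * (sum(d$values^2) + 1)) {
    # zero residual variance: identical groups are indistinguishable (p = 1),
    # any non-zero difference is an exact separation (p = 0)
    dtol <- 1e-8 * (1 + max(abs(d$values)))
    tk[, "p adj"] <- ifelse(abs(tk[, "diff"]) < dtol, 1, 0)
  }
  pairs <- rownames(tk)
  parts <- strsplit(pairs, "-", fixed = TRUE)
  data.frame(pair = pairs,
             group1 = vapply(parts, `[`, character(1), 1),
             group2 = vapply(parts, `[`, character(1), 2),
             diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
             p_adj = tk[, "p adj"],
             significant = tk[, "p adj"] < alpha,
             row.names = NULL)
}

#' Aggregate per-cell measurements to the replication unit
#'
#' Averages cells within each (group, sample) stratum. The sample — one
#' tube or chamber — is the independent replication unit: cells within a
#' device share its micro-environment and are not independent, so testing
#' at the cell level would be pseudo-replication.
#'
#' @param cells Data frame with columns `group`, `sample` and the measure
#'   columns.
#' @param measures Character vector of measure columns to aggregate.
#' @return Data frame with one row per (group, sample).
#' @export
aggregate_samples <- function(cells,
                              measures = c("runx2_mean", "contrast",
                                           "entropy")) {
  need <- c("group", "sample", measures)
  missing <- setdiff(need, names(cells))
  if (length(missing)) {
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cells) == 0) stop("schema error: empty per-cell table",
                             call. = FALSE)
  stats::aggregate(cells[measures],
                   by = list(group = cells$group, sample = cells$sample),
                   FUN = mean, na.rm = TRUE)
}

# Brown-Forsythe variance-homogeneity check: one-way ANOVA on absolute
# deviations from the group medians. Used only to log a warning.
levene_p <- function(values, groups) {
  groups <- factor(groups)
  dev <- abs(values - stats::ave(values, groups,
                                 FUN = stats::median))
  if (all(dev < 1e-12 * (1 + max(abs(values))))) return(NA_real_)
  tryCatch(anova_oneway(dev, groups)$p, error = function(e) NA_real_)
}

# The planned contrasts of the 2x2 design, in the reporting notation of the
# source experiment: '#' marks geometry contrasts at matched flow, '*' marks
# flow contrasts within a geometry.
planned_pairs <- function() {
  data.frame(
    group1 = c("cap_static", "cap_flow", "cap_flow", "ppfc_flow"),
    group2 = c("ppfc_static", "ppfc_flow", "cap_static", "ppfc_static"),
    marker = c("#", "#", "*", "*"))
}

#' Compare the experimental groups on each measure
#'
#' Aggregates a per-cell table to per-sample means (unless
#' `unit = "cell"`), then runs a one-way ANOVA and Tukey HSD per measure.
#' The result highlights the design's planned contrasts: geometry
#' comparisons at matched flow (capillary vs chamber, marker `#`) and flow
#' comparisons within a geometry (perfused vs static, marker `*`).
#'
#' @param cells Per-cell data frame with `group`, `sample` and measure
#'   columns.
#' @param measures Measures to test.
#' @param alpha Significance level.
#' @param unit `"sample"` (default; cells averaged within sample) or
#'   `"cell"` (every cell an observation — pseudo-replication, labelled as
#'   such in the output).
#' @return Object of class `group_comparison`: per-measure list of
#'   `anova` and `tukey`, plus `unit`, `alpha`, `n_obs`.
#' @export
compare_groups <- function(cells,
                           measures = c("runx2_mean", "contrast", "entropy"),
                           alpha = 0.05, unit = c("sample", "cell")) {
  unit <- match.arg(unit)
  obs <- if (unit == "sample") aggregate_samples(cells, measures) else {
    missing <- setdiff(c("group", measures), names(cells))
    if (length(missing) || nrow(cells) == 0) {
      stop("schema error: missing column(s) or empty table", call. = FALSE)
    }
    cells
  }
  res <- lapply(measures, function(m) {
    lev_p <- levene_p(obs[[m]], obs$group)
    if (!is.na(lev_p) && lev_p < alpha) {
      warning(sprintf(paste0("heterogeneous group variances for '%s' ",
                             "(Brown-Forsythe p = %.3g); ANOVA assumes ",
                             "equal variances"), m, lev_p), call. = FALSE)
    }
    list(anova = anova_oneway(obs[[m]], obs$group),
         tukey = tukey_hsd(obs[[m]], obs$group, alpha),
         levene_p = lev_p)
  })
  names(res) <- measures
  structure(list(measures = res, unit = unit, alpha = alpha,
                 n_obs = nrow(obs),
                 pseudo_replication = unit == "cell"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison (unit = %s%s, alpha = %g, N = %d)\n",
              x$unit,
              if (x$pseudo_replication) ", PSEUDO-REPLICATION" else "",
              x$alpha, x$n_obs))
  pp <- planned_pairs()
  for (m in names(x$measures)) {
    a <- x$measures[[m]]$anova
    cat(sprintf("\n%s: F(%d,%d) = %.3f, p = %.4g\n", m,
                a$df[1], a$df[2], a$F, a$p))
    tk <- x$measures[[m]]$tukey
    for (i in seq_len(nrow(tk))) {
      mk <- ""
      for (j in seq_len(nrow(pp))) {
        if ((tk$group1[i] == pp$group1[j] && tk$group2[i] == pp$group2[j]) ||
            (tk$group1[i] == pp$group2[j] && tk$group2[i] == pp$group1[j])) {
          mk <- pp$marker[j]
        }
      }
      cat(sprintf("  %-24s diff = %8.3f  p.adj = %.4g %s%s\n",
                  tk$pair[i], tk$diff[i], tk$p_adj[i],
                  if (tk$significant[i]) "SIG " else "    ", mk))
    }
  }
  invisible(x)
}

#' Significant planned contrasts of a comparison
#'
#' Extracts, per measure, which of the design's planned contrasts
#' (geometry `#`, flow `*`) are significant.
#'
#' @param comparison A [compare_groups()] result.
#' @return Data frame: `measure`, `group1`, `group2`, `marker`, `p_adj`,
#'   `significant`.
#' @export
planned_contrasts <- function(comparison) {
  stopifnot(inherits(comparison, "group_comparison"))
  pp <- planned_pairs()
  out <- list()
  for (m in names(comparison$measures)) {
    tk <- comparison$measures[[m]]$tukey
    for (j in seq_len(nrow(pp))) {
      hit <- (tk$group1 == pp$group1[j] & tk$group2 == pp$group2[j]) |
        (tk$group1 == pp$group2[j] & tk$group2 == pp$group1[j])
      if (any(hit)) {
        i <- which(hit)[1]
        out[[length(out) + 1]] <- data.frame(
          measure = m, group1 = pp$group1[j], group2 = pp$group2[j],
          marker = pp$marker[j], p_adj = tk$p_adj[i],
          significant = tk$significant[i])
      }
    }
  }
  do.call(rbind, out)
}
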