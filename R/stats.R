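#' Normality gate for a feature
#'
#' Applies the Shapiro-Wilk test to one feature within each group at
#' `alpha = 0.05`: when both groups pass, the feature is routed to the
#' two-way ANOVA, otherwise to the nonparametric Kruskal-Wallis analysis.
#' (In practice the local-minima count routes nonparametric and the
#' remaining landscape features parametric.)
#'
#' @param table long-format feature table with `group` and `stimulus`
#'   columns (see [cohort_features()]).
#' @param feature feature column name.
#' @param alpha significance level for the Shapiro-Wilk test.
#' @return list with `route` (`"parametric"` or `"nonparametric"`) and
#'   `shapiro` (data frame of per-cell W and p).
#' @export
normality_gate <- function(table, feature, alpha = 0.05) {
  if (!feature %in% names(table)) stop("no such feature column: ", feature)
  cells <- split(table[[feature]], table$group, drop = TRUE)
  res <- lapply(names(cells), function(nm) {
    x <- cells[[nm]]
    if (length(x) < 3) stop("cell ", nm, " has < 3 observations")
    if (stats::sd(x) == 0) stop("constant feature in cell ", nm,
                                ": Shapiro-Wilk undefined")
    if (length(x) > 5000) x <- x[seq_len(5000)]
    sw <- stats::shapiro.test(x)
    data.frame(cell = nm, W = unname(sw$statistic), p = sw$p.value)
  })
  sw_tab <- do.call(rbind, res)
  route <- if (all(sw_tab$p >= alpha)) "parametric" else "nonparametric"
  list(route = route, shapiro = sw_tab)
}

#' Group-level tests over energy-landscape features
#'
#' For each feature, routes through [normality_gate()] and then runs either
#' a two-way ANOVA with interaction (`feature ~ group * stimulus`; balanced
#' design, so sums of squares are unambiguous) with Tukey HSD post-hoc
#' stimulus contrasts, or Kruskal-Wallis tests by group and by stimulus.
#' Each participant x stimulus row is treated as an independent observation
#' (matching a 2 x 4 x n design with residual df `N - 8`); the
#' repeated-measures caveat is documented in the methods vignette.
#'
#' @param table long-format feature table (both groups, all four stimuli).
#' @param features feature columns to analyse.
#' @param alpha routing significance level.
#' @return a `stats_report`: per feature a list with `route`, `shapiro`,
#'   and either `anova` (data frame: effect, df1, df2, F, p) and `tukey`
#'   (stimulus contrasts), or `kruskal` (data frame: factor, chisq, df, p).
#' @export
run_group_tests <- function(table, features = c("n_LM", "mean_gap",
                                                "basin_size_sd",
                                                "gm_duration"),
                            alpha = 0.05) {
  stopifnot(all(c("group", "stimulus") %in% names(table)))
  combos <- table(table$group, table$stimulus)
  if (any(combos == 0)) {
    miss <- which(combos == 0, arr.ind = TRUE)
    stop("missing group x stimulus cells: ",
         paste(rownames(combos)[miss[, 1]], colnames(combos)[miss[, 2]],
               sep = ":", collapse = ", "))
  }
  out <- list()
  for (f in features) {
    # a constant cell leaves Shapiro-Wilk undefined; such a degenerate
    # distribution is treated as a normality rejection (count features like
    # the number of local minima routinely produce this)
    gate <- tryCatch(normality_gate(table, f, alpha = alpha),
                     error = function(e) {
                       if (grepl("constant feature", conditionMessage(e))) {
                         list(route = "nonparametric", shapiro = NULL)
                       } else stop(e)
                     })
    entry <- list(feature = f, route = gate$route, shapiro = gate$shapiro)
    if (gate$route == "parametric") {
      fit <- stats::aov(stats::reformulate(c("group", "stimulus",
                                             "group:stimulus"), f),
                        data = table)
      an <- summary(fit)[[1]]
      eff <- trimws(rownames(an))
      df_res <- an[eff == "Residuals", "Df"]
      keep <- eff != "Residuals"
      entry$anova <- data.frame(effect = eff[keep],
                                df1 = an[keep, "Df"], df2 = df_res,
                                F = an[keep, "F value"],
                                p = an[keep, "Pr(>F)"])
      tk <- stats::TukeyHSD(fit, "stimulus")$stimulus
      entry$tukey <- data.frame(contrast = rownames(tk),
                                diff = tk[, "diff"], p = tk[, "p adj"])
      entry$group_p <- entry$anova$p[entry$anova$effect == "group"]
    } else {
      kg <- stats::kruskal.test(table[[f]], table$group)
      ks <- stats::kruskal.test(table[[f]], table$stimulus)
      entry$kruskal <- data.frame(
        factor = c("group", "stimulus"),
        chisq = c(unname(kg$statistic), unname(ks$statistic)),
        df = c(unname(kg$parameter), unname(ks$parameter)),
        p = c(kg$p.value, ks$p.value))
      entry$group_p <- kg$p.value
    }
    out[[f]] <- entry
  }
  structure(out, class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  for (f in names(x)) {
    e <- x[[f]]
    cat(sprintf("%-14s [%s] group p = %.4g\n", f, e$route, e$group_p))
  }
  invisible(x)
}

#' Demographic comparisons between groups
#'
#' Independent-sample t-tests for numeric fields (age, clinical scales) and
#' a chi-square test for gender, reproducing the usual cohort table.
#'
#' @param metadata data frame with a `group` column plus demographic
#'   fields; `gender` (if present) is tested by chi-square, all other
#'   numeric columns by t-test.
#' @return data frame: field, test, statistic, df, p.
#' @export
demographics_tests <- function(metadata) {
  stopifnot("group" %in% names(metadata))
  out <- list()
  for (f in setdiff(names(metadata), "group")) {
    x <- metadata[[f]]
    if (f == "gender" || is.factor(x) || is.character(x)) {
      tb <- table(metadata$group, x)
      cs <- suppressWarnings(stats::chisq.test(tb))
      out[[f]] <- data.frame(field = f, test = "chi-square",
                             statistic = unname(cs$statistic),
                             df = unname(cs$parameter), p = cs$p.value)
    } else if (is.numeric(x)) {
      groups <- split(x, metadata$group)
      if (length(groups) != 2) {
        warning("field ", f, " skipped: need exactly 2 groups")
        next
      }
      if (stats::var(x) == 0) {
        # identical constant values in both groups: no difference
        out[[f]] <- data.frame(field = f, test = "t-test", statistic = 0,
                               df = length(x) - 2, p = 1)
      } else {
        tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE)
        out[[f]] <- data.frame(field = f, test = "t-test",
                               statistic = unname(tt$statistic),
                               df = unname(tt$parameter), p = tt$p.value)
      }
    } else {
      warning("field ", f, " skipped: unsupported type")
    }
  }
  do.call(rbind, out)
}
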