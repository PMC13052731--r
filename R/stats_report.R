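# Group comparisons matching the study's statistical conventions, and a
# deterministic report bundle for downstream consumption.

#' Compare measurement groups
#'
#' Two groups: unpaired two-sided t-test (pooled variance by default;
#' `welch = TRUE` drops the equal-variance assumption). Three or more
#' groups: one-way ANOVA with Tukey's HSD post hoc pairwise comparisons.
#' Significance is flagged at `alpha`.
#'
#' @param values named list (>= 2) of numeric vectors, each with >= 2
#'   values.
#' @param alpha significance level (default 0.05).
#' @param welch use the Welch t-test for the two-group path.
#' @return object of class `group_comparison`: list with `test`,
#'   `statistic`, `p_value`, `significant`, `groups` (names), and, for the
#'   ANOVA path, `tukey` (data.frame: comparison, diff, p_adj,
#'   significant).
#' @export
compare_groups <- function(values, alpha = 0.05, welch = FALSE) {
  stopifnot(is.list(values), length(values) >= 2)
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    names(values) <- paste0("group", seq_along(values))
  }
  sizes <- vapply(values, length, integer(1))
  if (any(sizes < 2)) stop("every group needs at least 2 values")
  if (length(values) == 2) {
    ht <- stats::t.test(values[[1]], values[[2]], var.equal = !welch)
    res <- list(test = if (welch) "welch_t" else "t",
                statistic = unname(ht$statistic),
                p_value = ht$p.value,
                significant = ht$p.value < alpha,
                groups = names(values), tukey = NULL)
  } else {
    g <- factor(rep(names(values), sizes), levels = names(values))
    y <- unlist(values, use.names = FALSE)
    fit <- stats::aov(y ~ g)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
    res <- list(test = "anova_tukey",
                statistic = an[1, "F value"],
                p_value = an[1, "Pr(>F)"],
                significant = an[1, "Pr(>F)"] < alpha,
                groups = names(values),
                tukey = data.frame(comparison = rownames(tk),
                                   diff = tk[, "diff"],
                                   p_adj = tk[, "p adj"],
                                   significant = tk[, "p adj"] < alpha,
                                   row.names = NULL))
  }
  res$alpha <- alpha
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("group_comparison (", x$test, "): statistic ",
      signif(x$statistic, 5), ", p = ", signif(x$p_value, 4),
      if (x$significant) " *" else "", "\n", sep = "")
  if (!is.null(x$tukey)) {
    print(x$tukey)
  }
  invisible(x)
}

#' Assemble a deterministic report bundle from stage outputs
#'
#' Collects named stage outputs (data frames or lists) into a single JSON
#' document plus one CSV per tabular section. Field ordering is fixed and
#' no timestamps are embedded, so reruns on identical inputs are
#' byte-identical.
#'
#' @param stages named list (nonempty) of stage outputs; data frames are
#'   written as CSVs, anything else is embedded in the JSON.
#' @param dir output directory, created if needed; when `NULL` nothing is
#'   written and the bundle is only returned.
#' @param config optional list echoed into the bundle.
#' @return the bundle list, invisibly when written.
#' @export
build_report <- function(stages, dir = NULL, config = list()) {
  stopifnot(is.list(stages))
  if (length(stages) == 0) stop("no stage outputs supplied")
  if (is.null(names(stages)) || any(!nzchar(names(stages)))) {
    stop("stage outputs must be named")
  }
  stages <- stages[order(names(stages))]
  sections <- lapply(stages, function(s) {
    if (is.data.frame(s)) {
      list(kind = "table", n_rows = nrow(s), columns = names(s))
    } else {
      list(kind = "values", values = s)
    }
  })
  bundle <- list(
    software = list(package = "nucmorph",
                    version = as.character(utils::packageVersion("nucmorph"))),
    config = config,
    sections = sections)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(bundle, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (nm in names(stages)) {
      if (is.data.frame(stages[[nm]])) {
        utils::write.csv(stages[[nm]],
                         file.path(dir, paste0(nm, ".csv")),
                         row.names = FALSE)
      }
    }
    return(invisible(bundle))
  }
  bundle
}
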