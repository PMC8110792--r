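#' Consolidated assay report
#'
#' Builds one tidy summary table per assay from pipeline outputs: group
#' n, mean, SEM (SD / sqrt(n)), plus the group test the assay calls for
#' (one-way ANOVA with Tukey for continuous measures; Fisher's exact or
#' chi-squared for collapse counts).  Analysis parameters supplied via
#' `params` are recorded alongside for provenance.  Measurements carry
#' their experimental unit (`growth_cone` or `sphere`) in the `unit`
#' column when provided, and are summarized per unit level without
#' hidden pooling.
#'
#' @param preference Data frame with `value` (normalized preference) and
#'   `group`, or NULL.
#' @param collapse Data frame with `condition` and `collapsed`, or NULL.
#' @param rates Data frame with `value` (um/hr) and `group`, or NULL.
#' @param intensities Data frame with `value` and `group`, or NULL.
#' @param fret Data frame with `value` (efficiency) and `group`, or NULL.
#' @param glisa Data frame with `fold_activity` and `condition`, or NULL.
#' @param params Named list of analysis parameters to record.
#' @return An `assay_report`: named list of data.frames (`summary`
#'   tables keyed by assay, plus `tests` and `parameters`).
#' @export
assay_report <- function(preference = NULL, collapse = NULL, rates = NULL,
                         intensities = NULL, fret = NULL, glisa = NULL,
                         params = list()) {
  out <- list()
  tests <- list()

  summarize_groups <- function(df, value_col = "value",
                               group_col = "group") {
    sp <- split(df[[value_col]], df[[group_col]])
    data.frame(
      group = names(sp),
      n = vapply(sp, length, integer(1)),
      mean = vapply(sp, mean, numeric(1)),
      sem = vapply(sp, function(v) {
        if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
      }, numeric(1)),
      row.names = NULL
    )
  }

  add_continuous <- function(name, df) {
    out[[name]] <<- summarize_groups(df)
    g <- factor(df$group)
    if (nlevels(g) >= 2L && all(tabulate(g) >= 2L)) {
      at <- anova_tukey(df)
      tests[[name]] <<- data.frame(
        assay = name, test = "one-way ANOVA",
        statistic = at$F, df = paste(at$df, collapse = ","),
        p_value = at$p_value)
      tk <- at$tukey
      tk$assay <- name
      tests[[paste0(name, "_tukey")]] <<- data.frame(
        assay = name, test = paste("Tukey", tk$comparison),
        statistic = tk$diff, df = "", p_value = tk$p_adj)
    }
  }

  if (!is.null(preference)) add_continuous("preference", preference)
  if (!is.null(rates)) add_continuous("rates", rates)
  if (!is.null(intensities)) add_continuous("intensities", intensities)
  if (!is.null(fret)) add_continuous("fret", fret)
  if (!is.null(glisa)) {
    df <- data.frame(value = glisa$fold_activity, group = glisa$condition)
    out$glisa <- summarize_groups(df)
  }
  if (!is.null(collapse)) {
    ct <- collapse_table(collapse)
    out$collapse <- as.data.frame(ct)
    counts <- attr(ct, "counts")
    if (ncol(counts) == 2L) {
      ft <- fisher_exact_2x2(counts)
      tests$collapse <- data.frame(
        assay = "collapse", test = "Fisher exact (two-sided)",
        statistic = ft$odds_ratio, df = "", p_value = ft$p_value)
    } else if (ncol(counts) > 2L) {
      cs <- chi_squared(counts)
      tests$collapse <- data.frame(
        assay = "collapse", test = "chi-squared",
        statistic = cs$statistic, df = as.character(cs$df),
        p_value = cs$p_value)
    }
  }
  if (!length(out)) stop("no assay tables supplied", call. = FALSE)

  out$tests <- if (length(tests)) {
    do.call(rbind, c(tests, list(make.row.names = FALSE)))
  } else {
    data.frame(assay = character(), test = character(),
               statistic = numeric(), df = character(),
               p_value = numeric())
  }
  out$parameters <- data.frame(
    parameter = names(params) %||% character(),
    value = vapply(params, function(p) paste(format(p), collapse = ";"),
                   character(1)),
    row.names = NULL
  )
  structure(out, class = "assay_report")
}

#' Write an assay report to CSV files
#'
#' One CSV per table, with fixed float formatting (15 significant
#' digits) so identical inputs produce byte-identical files.
#'
#' @param report An [assay_report()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "assay_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(report)) {
    df <- as.data.frame(report[[nm]])
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) {
      ifelse(is.na(v), "NA", formatC(v, digits = 15, format = "g"))
    })
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(df, p, row.names = FALSE, quote = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
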