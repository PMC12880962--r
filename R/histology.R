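# Histopathology rubric: four categories (neutrophil infiltration,
# hepatocyte necrosis, sinusoidal congestion, sinusoidal oedema), each
# scored 0-3 from the most severe observation in the examined field, summed
# to a 0-12 composite.

HISTOLOGY_CATEGORIES <- c("neutrophil", "necrosis", "congestion", "oedema")

severityLevels <- list(
  neutrophil = c("none", "sparse-focal", "widespread-focal", "diffuse"),
  congestion = c("none", "mild", "moderate", "severe"),
  oedema = c("none", "mild", "moderate", "severe"))

#' Score one histological category
#'
#' Deterministic rubric lookup. Hepatocyte necrosis is scored from the
#' percentage of hepatocytes affected: 0 for none, 1 below 10 %, 2 for
#' 10-30 % and 3 above 30 % (boundary percentages take the higher score).
#' The other categories are scored from a severity level: either the
#' generic `none`/`mild`/`moderate`/`severe` or, for neutrophil
#' infiltration, `none`/`sparse-focal`/`widespread-focal`/`diffuse`.
#' When several observations (fields) are supplied the most severe one
#' wins.
#'
#' @param feature one of `"neutrophil"`, `"necrosis"`, `"congestion"`,
#'   `"oedema"`.
#' @param observation numeric percentage(s) for necrosis; character
#'   severity level(s) otherwise.
#' @return Integer score 0-3.
#' @examples
#' scoreCategory("necrosis", 20)        # moderate: 2
#' scoreCategory("neutrophil", "none")  # 0
#' @export
scoreCategory <- function(feature, observation) {
  feature <- match.arg(feature, HISTOLOGY_CATEGORIES)
  if (feature == "necrosis") {
    p <- as.numeric(observation)
    if (any(is.na(p)) || any(p < 0) || any(p > 100))
      stop("necrosis observation must be a percentage in [0, 100]")
    sc <- ifelse(p >= 30, 3L, ifelse(p >= 10, 2L, ifelse(p > 0, 1L, 0L)))
    return(max(as.integer(sc)))
  }
  obs <- tolower(as.character(observation))
  lv <- severityLevels[[feature]]
  alt <- c("none", "mild", "moderate", "severe")
  sc <- vapply(obs, function(o) {
    i <- match(o, lv)
    if (is.na(i)) i <- match(o, alt)
    if (is.na(i)) stop(sprintf("unknown %s observation: '%s'", feature, o))
    i - 1L
  }, integer(1))
  max(sc)
}

#' Composite pathology score
#'
#' The sum of the four category scores, ranging 0-12. Accepts integer
#' biopsy scores or fractional group means (each in `[0, 3]`).
#'
#' @param scores numeric length 4, each in `[0, 3]`.
#' @return The sum.
#' @examples
#' compositeScore(c(3, 3, 3, 3))   # the rubric ceiling, 12
#' @export
compositeScore <- function(scores) {
  if (length(scores) != 4L || any(is.na(scores)) || any(scores < 0) ||
      any(scores > 3))
    stop("scores must be four values in [0, 3]")
  sum(scores)
}

#' Summarize histology scores per group and time point
#'
#' Arithmetic category means per group x timepoint cell; the composite
#' mean is the sum of the category means, which by linearity equals the
#' mean of the per-biopsy composites (verified internally). Full precision
#' is retained; round for reporting.
#'
#' @param table data.frame with columns `group`, `timepoint`, the four
#'   category columns and optionally `composite`.
#' @return data.frame with one row per group x timepoint: category means
#'   and `composite_mean`.
#' @export
summarizeGroups <- function(table) {
  need <- c("group", "timepoint", HISTOLOGY_CATEGORIES)
  if (!nrow(table) || !all(need %in% names(table)))
    stop(sprintf("table must be non-empty with columns %s",
                 paste(need, collapse = ", ")))
  cells <- unique(table[, c("group", "timepoint")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- table$group == cells$group[i] & table$timepoint == cells$timepoint[i]
    sub <- table[sel, ]
    means <- colMeans(sub[, HISTOLOGY_CATEGORIES])
    comp <- sum(means)
    if ("composite" %in% names(sub))
      stopifnot(abs(comp - mean(sub$composite)) < 1e-9)
    data.frame(group = cells$group[i], timepoint = cells$timepoint[i],
               t(means), composite_mean = comp)
  }))
  rownames(out) <- NULL
  out
}

# Brown-Forsythe variant of Levene's test: ANOVA on absolute deviations
# from group medians
leveneTest2 <- function(values, groups) {
  groups <- factor(groups)
  med <- tapply(values, groups, median)
  dev <- abs(values - med[groups])
  fit <- stats::anova(stats::lm(dev ~ groups))
  list(statistic = fit$`F value`[1], p.value = fit$`Pr(>F)`[1])
}

#' Compare composite scores between two groups at one time point
#'
#' An independent two-sample t test (pooled variance) on the composite
#' scores, with Shapiro-Wilk normality diagnostics per group and a
#' Levene (Brown-Forsythe) homogeneity-of-variance diagnostic. A reporting
#' convenience for simulated or user-supplied biopsy tables.
#'
#' @param table biopsy-level data.frame as in [summarizeGroups()], with a
#'   `composite` column (computed if absent).
#' @param timepoint the time point label to compare at.
#' @return A list: `t`, `p`, `df`, per-group `means`, `n`, `shapiro_p`
#'   (named per group) and `levene_p`.
#' @export
compareGroups <- function(table, timepoint) {
  if (!"composite" %in% names(table))
    table$composite <- rowSums(table[, HISTOLOGY_CATEGORIES])
  sub <- table[table$timepoint == timepoint, ]
  gs <- unique(sub$group)
  if (length(gs) != 2L)
    stop("exactly two groups are required at the chosen time point")
  x <- sub$composite[sub$group == gs[1]]
  y <- sub$composite[sub$group == gs[2]]
  if (length(x) < 2L || length(y) < 2L)
    stop("at least two records per group are required")
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  df <- length(x) + length(y) - 2
  if (sp2 <= 0) {
    tstat <- if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y))
    p <- if (tstat == 0) 1 else 0
  } else {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    tstat <- unname(tt$statistic)
    p <- tt$p.value
  }
  sw <- vapply(list(x, y), function(v) {
    out <- tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
    out
  }, numeric(1))
  lv <- tryCatch(leveneTest2(sub$composite, sub$group)$p.value,
                 error = function(e) NA_real_)
  list(t = tstat, p = p, df = df,
       means = stats::setNames(c(mean(x), mean(y)), gs),
       n = stats::setNames(c(length(x), length(y)), gs),
       shapiro_p = stats::setNames(sw, gs), levene_p = lv)
}

#' Read / write a histology score table as CSV
#'
#' Columns `group`, `timepoint`, `biopsy_id`, the four categories and
#' `composite`. On read, category scores are checked to be integers in
#' 0..3 and `composite` (recomputed if absent) to equal the category sum.
#'
#' @param table data.frame to write.
#' @param path CSV path.
#' @return `readHistologyCsv`: the validated data.frame.
#' @export
writeHistologyCsv <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHistologyCsv
#' @export
readHistologyCsv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "timepoint", HISTOLOGY_CATEGORIES)
  if (!all(need %in% names(tab)))
    stop(sprintf("histology CSV must have columns %s",
                 paste(need, collapse = ", ")))
  sc <- as.matrix(tab[, HISTOLOGY_CATEGORIES])
  if (any(sc != round(sc)) || any(sc < 0) || any(sc > 3))
    stop("category scores must be integers in 0..3")
  comp <- rowSums(sc)
  if ("composite" %in% names(tab)) {
    if (any(tab$composite != comp))
      stop("composite column does not equal the category sum")
  } else tab$composite <- comp
  tab
}
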