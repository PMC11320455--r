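#' Paired t test, optionally on log-transformed values
#'
#' Classical two-sided paired t test on (optionally log10-transformed)
#' within-pair differences, with `n - 1` degrees of freedom. The base of the
#' logarithm does not affect the statistic or p value (a log-base change
#' rescales all differences by the same constant); base 10 is used for the
#' reported mean difference.
#'
#' @param x,y Paired measurement vectors of equal length (n >= 2).
#' @param log_transform Test the log10 values (all inputs must be positive).
#' @return `list(t, df, p, mean_diff, log_transform)`.
#' @export
paired_t_test <- function(x, y, log_transform = FALSE) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)", call. = FALSE)
  if (length(x) < 2L) stop("paired t test needs at least 2 pairs", call. = FALSE)
  if (log_transform) {
    if (any(x <= 0) || any(y <= 0))
      stop("log transform requires strictly positive values", call. = FALSE)
    x <- log10(x)
    y <- log10(y)
  }
  d <- x - y
  if (stats::sd(d) == 0)
    stop("degenerate test: within-pair differences have zero variance", call. = FALSE)
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate),
       log_transform = log_transform)
}

#' Mean, standard deviation and standard error of a sample
#'
#' @param values Numeric vector (n >= 1); `sd`/`sem` are `NA` for n = 1.
#' @param digits Rounding for the presentation fields (2 decimals, as in the
#'   reported tables); exact values are also returned.
#' @return `list(mean, sd, sem, n, mean_2dp, sd_2dp, sem_2dp)`.
#' @export
group_summary <- function(values, digits = 2L) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  n <- length(values)
  m <- mean(values)
  s <- if (n > 1L) stats::sd(values) else NA_real_
  sem <- if (n > 1L) s / sqrt(n) else NA_real_
  list(mean = m, sd = s, sem = sem, n = n,
       mean_2dp = round_half_up(m, digits),
       sd_2dp = if (is.na(s)) NA_real_ else round_half_up(s, digits),
       sem_2dp = if (is.na(sem)) NA_real_ else round_half_up(sem, digits))
}

#' Contaminant genomes delivered at a clinical dose
#'
#' Multiplies a vector-genome dose by the cross-packaged percentage and
#' reports the result to 2 significant figures, the precision used when
#' discussing systemic doses (e.g. the 2.2e14-genome Zolgensma dose).
#'
#' @param dose_vg Total dose in vector genomes (> 0).
#' @param backbone_pct Cross-packaged percentage (0..100).
#' @return Contaminant genomes (2 significant figures).
#' @export
dose_contaminant_load <- function(dose_vg, backbone_pct) {
  if (any(dose_vg <= 0)) stop("dose must be positive", call. = FALSE)
  if (any(backbone_pct < 0 | backbone_pct > 100))
    stop("backbone_pct must lie in [0, 100]", call. = FALSE)
  signif(dose_vg * backbone_pct / 100, 2L)
}

#' Compare serotype-paired preps made with two proviral plasmids
#'
#' Computes group means, the paired t test on cross-packaged percentages, the
#' paired t test on log10 yields (when yields are present), and the percent
#' change between the group means. Percent change is reported under both
#' conventions — the remaining fraction `mean(B)/mean(A)` and the reduction
#' `1 - mean(B)/mean(A)` — because both appear in common use and they are
#' easily conflated.
#'
#' @param metrics_a,metrics_b `data.frame(serotype, backbone_pct[, yield_drp])`
#'   for the two plasmids (e.g. the original and the insulated-stuffer
#'   design); serotypes must pair up exactly.
#' @return `list(mean_a, mean_b, remaining_fraction, reduction,
#'   backbone_test, yield_test, n_pairs)`.
#' @export
compare_constructs <- function(metrics_a, metrics_b) {
  need <- c("serotype", "backbone_pct")
  stopifnot(all(need %in% names(metrics_a)), all(need %in% names(metrics_b)))
  if (!setequal(metrics_a$serotype, metrics_b$serotype) ||
      anyDuplicated(metrics_a$serotype) || anyDuplicated(metrics_b$serotype))
    stop("serotypes must pair up one-to-one across the two groups", call. = FALSE)
  b <- metrics_b[match(metrics_a$serotype, metrics_b$serotype), , drop = FALSE]
  a <- metrics_a
  mean_a <- mean(a$backbone_pct)
  mean_b <- mean(b$backbone_pct)
  backbone_test <- if (stats::sd(a$backbone_pct - b$backbone_pct) > 0)
    paired_t_test(a$backbone_pct, b$backbone_pct) else NULL
  yield_test <- NULL
  if ("yield_drp" %in% names(a) && "yield_drp" %in% names(b) &&
      all(is.finite(a$yield_drp)) && all(is.finite(b$yield_drp)))
    yield_test <- paired_t_test(a$yield_drp, b$yield_drp, log_transform = TRUE)
  list(mean_a = mean_a, mean_b = mean_b,
       remaining_fraction = mean_b / mean_a,
       reduction = 1 - mean_b / mean_a,
       backbone_test = backbone_test, yield_test = yield_test,
       n_pairs = nrow(a))
}

#' Repeated-measures one-way ANOVA (generic utility)
#'
#' Thin wrapper over `aov(value ~ condition + Error(subject))` for
#' within-subject designs (e.g. expression measured per experiment across
#' constructs).
#'
#' @param value Numeric response.
#' @param subject Subject/block factor (the repeated unit).
#' @param condition Condition factor.
#' @return `list(F, df1, df2, p)`.
#' @export
repeated_measures_anova <- function(value, subject, condition) {
  d <- data.frame(value = value, subject = factor(subject),
                  condition = factor(condition))
  fit <- stats::aov(value ~ condition + Error(subject), data = d)
  tab <- summary(fit)[["Error: Within"]][[1L]]
  list(F = tab["condition", "F value"],
       df1 = tab["condition", "Df"],
       df2 = tab["Residuals", "Df"],
       p = tab["condition", "Pr(>F)"])
}

#' Read counts transcribed from a published AAV2 sequencing table
#'
#' Loads the bundled per-sample read counts (unique mapped reads split into
#' insert, backbone and other) for the five sequentially modified proviral
#' plasmids packaged into AAV2.
#'
#' @return `data.frame(sample, insert, backbone, other)`.
#' @export
aav2_prep_counts <- function() {
  path <- system.file("extdata", "aav2_prep_read_counts.tsv",
                      package = "provpack", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write classification summaries as JSON and a Markdown table
#'
#' @param summaries List of [classification_summary()] objects.
#' @param json Output JSON path (or `NULL`).
#' @param markdown Output Markdown path (or `NULL`).
#' @return The report list, invisibly.
#' @export
write_classification_report <- function(summaries, json = NULL, markdown = NULL) {
  rows <- lapply(summaries, function(s) list(
    sample = s$sample, unique_mapped = s$unique_mapped,
    insert = unname(s$counts["insert"]), insert_pct = s$insert_pct,
    backbone = unname(s$counts["backbone"]), backbone_pct = s$backbone_pct,
    other = unname(s$counts["other"]), other_pct = s$other_pct,
    insert_backbone_ratio = s$insert_backbone_ratio_int,
    insert_other_ratio = s$insert_other_ratio_int))
  if (!is.null(json))
    jsonlite::write_json(rows, json, auto_unbox = TRUE, digits = NA)
  if (!is.null(markdown)) {
    hdr <- "| sample | unique mapped | insert % | backbone % | other % | insert:backbone |"
    sep <- "|---|---|---|---|---|---|"
    body <- vapply(rows, function(r) sprintf(
      "| %s | %s | %.2f | %.2f | %.2f | %s:1 |",
      r$sample, format(r$unique_mapped, big.mark = ","), r$insert_pct,
      r$backbone_pct, r$other_pct, format(r$insert_backbone_ratio)),
      character(1))
    writeLines(c(hdr, sep, body), markdown)
  }
  invisible(rows)
}
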