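#' Per-sample, per-locus editing summary
#'
#' Counts structure-accepted, locus-assigned reads (`reads_pass`) and the
#' subset carrying at least one indel, and reports the indel frequency as a
#' percentage: `pct_indels = 100 * reads_with_indel / reads_pass`.
#'
#' @param calls `data.frame` from [callIndels()], joined to sample ids (a
#'   `sample_id` column must be present).
#' @return A `data.frame` with one row per (sample_id, locus):
#'   `sample_id, locus, reads_pass, reads_with_indel, pct_indels`.
#'   A (sample, locus) group with zero passing reads raises an error rather
#'   than reporting a silent 0.
#' @export
editingSummary <- function(calls) {
  ok <- !is.na(calls$locus)
  d <- calls[ok, , drop = FALSE]
  if (nrow(d) == 0L)
    stop("undefined editing frequency: no assigned reads (reads_pass = 0)",
         call. = FALSE)
  key <- interaction(d$sample_id, d$locus, drop = TRUE)
  agg <- lapply(split(d, key), function(g) data.frame(
    sample_id = g$sample_id[1], locus = g$locus[1],
    reads_pass = nrow(g),
    reads_with_indel = sum(g$has_indel),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out$pct_indels <- 100 * out$reads_with_indel / out$reads_pass
  out
}

#' On-target specificity statistic
#'
#' `100 * on / (on + sum(off))`, where `on` and `off` are per-locus
#' percentages of reads containing indels: the percentage of observed indels
#' that happen on-target, corrected for the read counts at each locus. With
#' two off-target loci this is the three-locus form used throughout the
#' dose-response analyses. Undefined (error) when all inputs are zero, as in
#' a no-RNP condition where specificity values are meaningless.
#'
#' @param onPct On-target percentage of reads with indels.
#' @param offPcts Numeric vector of off-target percentages.
#' @return Specificity as a percentage in `[0, 100]`.
#' @examples
#' specificity(60, c(20, 20))  # 60
#' specificity(40, c(0, 0))    # 100
#' @export
specificity <- function(onPct, offPcts) {
  stopifnot(onPct >= 0, all(offPcts >= 0))
  denom <- onPct + sum(offPcts)
  if (denom == 0)
    stop("specificity undefined: no indels at any locus", call. = FALSE)
  100 * onPct / denom
}

#' Tidy dose-response table of editing and specificity
#'
#' Joins per-sample editing summaries to their experimental conditions and
#' adds per-(condition, replicate) specificity computed from the on-target
#' row against all off-target rows. One row per (locus, inhibitor_kind,
#' relative_concentration, replicate); replicates are preserved as rows.
#'
#' @param summaries `data.frame` from [editingSummary()].
#' @param samples Sample sheet with condition columns (see [makeSamples()]).
#' @param loci Named list of [AmpliconLocus-class] (for on/off roles).
#' @return A long-format `data.frame` with columns `locus, role,
#'   inhibitor_kind, relative_concentration, replicate, pct_indels,
#'   pct_specificity` (specificity repeated on every locus row of its group;
#'   `NA` if undefined).
#' @export
doseResponse <- function(summaries, samples, loci) {
  idx <- match(summaries$sample_id, samples$sample_id)
  if (anyNA(idx))
    stop(sprintf("summary rows with no matching sample: %s",
                 paste(summaries$sample_id[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  roles <- vapply(loci, function(l) l@role, character(1))
  out <- data.frame(
    locus = summaries$locus,
    role = unname(roles[summaries$locus]),
    inhibitor_kind = samples$inhibitor_kind[idx],
    relative_concentration = samples$relative_concentration[idx],
    replicate = samples$replicate[idx],
    pct_indels = summaries$pct_indels,
    stringsAsFactors = FALSE)
  grp <- interaction(out$inhibitor_kind, out$relative_concentration,
                     out$replicate, drop = TRUE)
  out$pct_specificity <- NA_real_
  for (g in levels(grp)) {
    sel <- grp == g
    on <- out$pct_indels[sel & out$role == "on_target"]
    off <- out$pct_indels[sel & out$role == "off_target"]
    if (length(on) != 1L)
      stop(sprintf("group '%s' must contain exactly one on-target row", g),
           call. = FALSE)
    sp <- tryCatch(specificity(on, off), error = function(e) NA_real_)
    out$pct_specificity[sel] <- sp
  }
  out[order(out$locus, out$inhibitor_kind, out$relative_concentration,
            out$replicate), , drop = FALSE]
}

#' Replicate group comparison: Shapiro-Wilk, Levene, ANOVA, Tukey
#'
#' Runs the standard chain for comparing condition groups of replicate
#' measurements: Shapiro-Wilk normality on the ANOVA residuals, Levene's test
#' for equal variances (Brown-Forsythe median centring), one-way ANOVA, and a
#' Tukey range post hoc test with one row per unordered group pair.
#' Significance tiers follow the usual 0.05 / 0.01 / 0.001 cutoffs.
#'
#' @param values Numeric vector of measurements.
#' @param groups Grouping vector (coerced to factor), >= 2 groups with >= 2
#'   values each.
#' @return A list with `shapiro_p`, `levene_p`, `anova_F`, `anova_p`, and
#'   `tukey` (`data.frame`: pair, diff, p_adj, signif).
#' @examples
#' compareGroups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))$anova_F
#' @export
compareGroups <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("every group needs at least 2 values", call. = FALSE)
  if (all(tapply(values, groups, stats::var) == 0))
    stop("degenerate input: zero within-group variance everywhere",
         call. = FALSE)
  fit <- aov(values ~ groups)
  res <- stats::residuals(fit)
  shapiroP <- tryCatch(shapiro.test(res)$p.value, error = function(e) NA_real_)
  leveneP <- car::leveneTest(values ~ groups)[1, "Pr(>F)"]
  anovaTab <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$groups
  tiers <- function(p) ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "n.s.")))
  list(shapiro_p = shapiroP,
       levene_p = leveneP,
       anova_F = anovaTab[1, "F value"],
       anova_p = anovaTab[1, "Pr(>F)"],
       tukey = data.frame(pair = rownames(tk),
                          diff = tk[, "diff"],
                          p_adj = tk[, "p adj"],
                          signif = tiers(tk[, "p adj"]),
                          stringsAsFactors = FALSE, row.names = NULL))
}
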