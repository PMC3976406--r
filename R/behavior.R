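#' Pool the two exhaustion VAS ratings
#'
#' The "rested" scale is reversed and averaged with the "tiredness"
#' scale: `(tired + (scale_max - rested)) / 2`. Vectorised.
#'
#' @param tired,rested ratings in [0, scale_max]
#' @param scale_max scale maximum (default 150)
#' @return pooled exhaustion score on the same scale
#' @export
pool_vas <- function(tired, rested, scale_max = 150) {
  if (any(tired < 0 | tired > scale_max) ||
      any(rested < 0 | rested > scale_max))
    stop(sprintf("pool_vas: ratings must lie in [0, %g]", scale_max))
  (tired + (scale_max - rested)) / 2
}

#' Per-subject z-standardisation
#'
#' Subtracts each subject's mean and divides by the subject's sample SD
#' (divisor n - 1). Subjects with fewer than two ratings or constant
#' ratings are unusable and raise an error naming them.
#'
#' @param values numeric ratings
#' @param subject parallel subject ids
#' @return z-scores in the input order
#' @export
zstandardize <- function(values, subject) {
  if (length(values) != length(subject))
    stop("zstandardize: values and subject lengths differ")
  out <- numeric(length(values))
  for (sub in unique(subject)) {
    sel <- subject == sub
    if (sum(sel) < 2)
      stop(sprintf("zstandardize: subject %s has fewer than two ratings", sub))
    s <- stats::sd(values[sel])
    if (s == 0)
      stop(sprintf("zstandardize: subject %s has constant ratings (unusable)",
                   sub))
    out[sel] <- (values[sel] - mean(values[sel])) / s
  }
  out
}

#' Two-way exhaustion ANOVA with Bonferroni simple effects
#'
#' Univariate two-way ANOVA of the z-standardised exhaustion score on
#' day activity (FD/WD) and time of day (T1/T3) with interaction, on a
#' balanced design. Simple effects contrast the two days at each time
#' point using the full model's pooled error term, with p values
#' Bonferroni-multiplied by the number of comparisons (2) and capped at 1.
#'
#' @param table data.frame with columns `subject`, `day` (FD/WD),
#'   `timepoint` (T1/T3), `z` (z-standardised exhaustion)
#' @return list with `anova` (data.frame: effect, df1, df2, F, p),
#'   `simple_effects` (data.frame: timepoint, F, df1, df2, p,
#'   p_bonferroni)
#' @export
exhaustion_anova <- function(table) {
  need <- c("subject", "day", "timepoint", "z")
  if (!all(need %in% names(table)))
    stop("exhaustion_anova: table must have subject, day, timepoint, z")
  table$day <- factor(table$day, levels = c("FD", "WD"))
  table$timepoint <- factor(table$timepoint)
  if (nlevels(table$timepoint) != 2 || nlevels(droplevels(table$day)) != 2)
    stop("exhaustion_anova: need a 2 x 2 design (two days, two time points)")
  counts <- table(table$day, table$timepoint)
  if (length(unique(as.vector(counts))) != 1)
    stop("exhaustion_anova: unbalanced design")
  if (counts[1, 1] < 3) stop("exhaustion_anova: need >= 3 subjects per cell")

  fit <- stats::aov(z ~ day * timepoint, data = table)
  tab <- summary(fit)[[1]]
  df_res <- tab["Residuals", "Df"]
  ms_res <- tab["Residuals", "Mean Sq"]
  eff <- rownames(tab)[seq_len(3)]
  anova_df <- data.frame(
    effect = trimws(eff),
    df1 = tab[seq_len(3), "Df"], df2 = df_res,
    F = tab[seq_len(3), "F value"], p = tab[seq_len(3), "Pr(>F)"])

  n_cell <- counts[1, 1]
  se <- do.call(rbind, lapply(levels(table$timepoint), function(tp) {
    sel <- table$timepoint == tp
    m <- tapply(table$z[sel], droplevels(table$day[sel]), mean)
    ss <- n_cell * (m["WD"] - m["FD"])^2 / 2
    f <- ss / ms_res
    p <- stats::pf(f, 1, df_res, lower.tail = FALSE)
    data.frame(timepoint = tp, F = unname(f), df1 = 1, df2 = df_res,
               p = unname(p), p_bonferroni = min(1, 2 * unname(p)))
  }))
  list(anova = anova_df, simple_effects = se)
}

#' Prepare the behavioural analysis table from a study's VAS ratings
#'
#' Pools the tiredness and reversed restedness scales, z-standardises per
#' subject over all of the subject's scans, and keeps the T1/T3 rows used
#' by the exhaustion ANOVA.
#'
#' @param behavior data.frame with subject, day, timepoint, tired_vas,
#'   rested_vas (as produced by [simulate_group_study()])
#' @param scale_max VAS scale maximum (default 150)
#' @return the input with `pooled` and `z` columns, subset to T1/T3
#' @export
prepare_exhaustion_table <- function(behavior, scale_max = 150) {
  behavior$pooled <- pool_vas(behavior$tired_vas, behavior$rested_vas,
                              scale_max)
  behavior$z <- zstandardize(behavior$pooled, behavior$subject)
  behavior[behavior$timepoint %in% c("T1", "T3"), , drop = FALSE]
}
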