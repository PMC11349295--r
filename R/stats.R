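# Two-condition comparison of EKMr spectra: two-way ANOVA (condition x EKMr
# level, with interaction) and Bonferroni-corrected per-level post hoc tests.

#' Two-way ANOVA of spectrum observations
#'
#' Fits `intensity ~ condition * ekmr_level` with sum-to-zero contrasts and
#' reports a Type III effect table (via [car::Anova()]), which handles the
#' unbalanced replicate counts of the reference design (3 vs 4 biological
#' replicates). For the highest-order interaction term the F statistic is
#' invariant to the sums-of-squares type; main-effect rows are type-dependent
#' on unbalanced data and flagged as such.
#'
#' @param observations data.frame with columns `condition`, `ekmr_level`,
#'   `replicate`, `intensity`. At least 2 conditions, 2 levels and one cell
#'   with 2 or more replicates; no empty cells.
#' @return list of class `idep_anova`: `effects` (term, sum_sq, df, F, p),
#'   `ms_error`, `df_error`, the fitted `model`, and the input data.
#' @export
two_way_anova <- function(observations) {
  req <- c("condition", "ekmr_level", "replicate", "intensity")
  if (!all(req %in% names(observations)))
    stop("observations lack columns: ",
         paste(setdiff(req, names(observations)), collapse = ", "))
  d <- data.frame(condition = factor(observations$condition),
                  ekmr_level = factor(observations$ekmr_level),
                  intensity = observations$intensity)
  if (nlevels(d$condition) < 2L) stop("need at least 2 conditions")
  if (nlevels(d$ekmr_level) < 2L) stop("need at least 2 EKMr levels")
  cells <- table(d$condition, d$ekmr_level)
  if (any(cells == 0L))
    stop("empty condition x level cell(s): interaction is inestimable")
  if (!any(cells >= 2L)) stop("need at least one cell with 2+ replicates")

  model <- stats::lm(
    intensity ~ condition * ekmr_level, data = d,
    contrasts = list(condition = "contr.sum", ekmr_level = "contr.sum"))
  # Type III; for a perfect fit (zero residual SS) fall back to the
  # sequential table — all SS types coincide when every cell is constant
  a3 <- tryCatch(car::Anova(model, type = 3),
                 error = function(e) suppressWarnings(stats::anova(model)))
  terms_keep <- c("condition", "ekmr_level", "condition:ekmr_level", "Residuals")
  a3 <- a3[rownames(a3) %in% terms_keep, ]
  effects <- data.frame(
    term = rownames(a3),
    sum_sq = a3[["Sum Sq"]],
    df = as.integer(a3[["Df"]]),
    F = a3[["F value"]],
    p = a3[["Pr(>F)"]],
    row.names = NULL
  )
  res <- effects[effects$term == "Residuals", ]
  structure(list(effects = effects,
                 ms_error = res$sum_sq / res$df,
                 df_error = res$df,
                 model = model,
                 data = d),
            class = "idep_anova")
}

#' @export
print.idep_anova <- function(x, ...) {
  cat("Two-way ANOVA (Type III, sum-to-zero contrasts)\n")
  print(x$effects, digits = 4)
  invisible(x)
}

#' Interaction test summary
#'
#' @param anova a [two_way_anova()] result.
#' @return list with `F`, `df1`, `df2`, `p` for the condition x level
#'   interaction.
#' @export
interaction_test <- function(anova) {
  stopifnot(inherits(anova, "idep_anova"))
  row <- anova$effects[anova$effects$term == "condition:ekmr_level", ]
  list(F = row$F, df1 = row$df, df2 = anova$df_error, p = row$p)
}

#' Bonferroni-corrected per-level post hoc comparisons
#'
#' For each EKMr level, compares the two condition means with a t statistic
#' built on the pooled ANOVA error variance (Welch-type per-level variances
#' available as a fallback), then multiplies each raw p by the number of
#' levels, capping at 1.
#'
#' @param anova a [two_way_anova()] result on exactly 2 conditions.
#' @param alpha significance level for the `significant` flag.
#' @param pooled use the pooled ANOVA mean-square error (default); otherwise
#'   a Welch two-sample test per level.
#' @return data.frame: `ekmr_level`, `mean_diff` (second condition minus
#'   first, by factor order), `raw_p`, `bonferroni_p`, `significant`.
#' @export
bonferroni_posthoc <- function(anova, alpha = 0.05, pooled = TRUE) {
  stopifnot(inherits(anova, "idep_anova"))
  d <- anova$data
  conds <- levels(d$condition)
  if (length(conds) != 2L) stop("post hoc comparison requires exactly 2 conditions")
  lvls <- levels(d$ekmr_level)
  m <- length(lvls)
  out <- lapply(lvls, function(l) {
    x1 <- d$intensity[d$condition == conds[1] & d$ekmr_level == l]
    x2 <- d$intensity[d$condition == conds[2] & d$ekmr_level == l]
    if (length(x1) == 0L || length(x2) == 0L)
      stop("level ", l, " lacks observations in one condition")
    diff <- mean(x2) - mean(x1)
    if (pooled) {
      se <- sqrt(anova$ms_error * (1 / length(x1) + 1 / length(x2)))
      df <- anova$df_error
      p <- if (se == 0) as.numeric(diff == 0) else 2 * stats::pt(-abs(diff / se), df)
    } else {
      p <- tryCatch(stats::t.test(x2, x1)$p.value, error = function(e) 1)
    }
    data.frame(ekmr_level = l, mean_diff = diff, raw_p = p)
  })
  out <- do.call(rbind, out)
  out$bonferroni_p <- pmin(out$raw_p * m, 1)
  out$significant <- out$bonferroni_p < alpha
  out
}
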