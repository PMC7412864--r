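# Efficacy statistics: uptake-ratio comparison against the reference
# formulation (one-tailed Welch t-test), cumulative GAG variation, one-way
# ANOVA with Tukey post hoc.

#' Uptake ratio of a conjugate arm against the reference formulation
#'
#' The headline screening statistic: the ratio of mean drug uptake (ug drug
#' per mg wet cartilage) using the polymer conjugate to mean uptake using the
#' reference phosphate-prodrug solution at the same exposure time and drug
#' dose. The 95% CI comes from the delta method on the log ratio with
#' Welch-Satterthwaite degrees of freedom; the p-value is a one-tailed Welch
#' t-test taken in the direction of the observed difference (polymers can
#' both enhance and suppress uptake, so the tested direction is data-driven
#' and is reported; note this doubles the effective null rejection rate
#' relative to a fixed one-sided test).
#'
#' @param conjugate Numeric vector of replicate uptake values, conjugate arm.
#' @param reference Numeric vector of replicate uptake values, reference arm.
#' @param conf_level Confidence level for the ratio CI (default 0.95).
#' @param var_equal Use a pooled-variance t-test instead of Welch
#'   (default `FALSE`).
#' @return Object of class `uptake_ratio`: list with `ratio`, `ci_lower`,
#'   `ci_upper`, `p_one_tailed`, `direction` (`"greater"`/`"less"`),
#'   `n_conjugate`, `n_reference`.
#' @export
uptake_ratio <- function(conjugate, reference, conf_level = 0.95,
                         var_equal = FALSE) {
  conjugate <- as.numeric(conjugate); reference <- as.numeric(reference)
  if (length(conjugate) < 2L || length(reference) < 2L) {
    stop("need >= 2 replicates per arm")
  }
  if (any(conjugate < 0) || any(reference < 0)) {
    stop("uptake values must be nonnegative")
  }
  mc <- mean(conjugate); mr <- mean(reference)
  if (mr == 0) stop("reference arm mean is zero; ratio undefined")
  ratio <- mc / mr

  direction <- if (mc >= mr) "greater" else "less"
  nc <- length(conjugate); nr <- length(reference)
  vc <- stats::var(conjugate); vr <- stats::var(reference)
  # one-tailed t-test in the observed direction (Welch by default); computed
  # directly so that two identical noiseless arms give t = 0, p = 0.5
  # rather than an error
  if (var_equal) {
    sp2 <- ((nc - 1L) * vc + (nr - 1L) * vr) / (nc + nr - 2L)
    se_t <- sqrt(sp2 * (1 / nc + 1 / nr))
    df_t <- nc + nr - 2L
  } else {
    se_t <- sqrt(vc / nc + vr / nr)
    num <- (vc / nc + vr / nr)^2
    den <- (vc / nc)^2 / (nc - 1L) + (vr / nr)^2 / (nr - 1L)
    df_t <- if (den == 0) nc + nr - 2L else num / den
  }
  p_one <- if (se_t == 0) {
    if (mc == mr) 0.5 else 0
  } else {
    stats::pt(abs(mc - mr) / se_t, df = df_t, lower.tail = FALSE)
  }
  # delta-method CI on the log ratio, Welch-Satterthwaite df
  if (mc > 0) {
    se_log <- sqrt(vc / (nc * mc^2) + vr / (nr * mr^2))
    num <- (vc / nc + vr / nr)^2
    den <- (vc / nc)^2 / (nc - 1L) + (vr / nr)^2 / (nr - 1L)
    df <- if (den == 0) nc + nr - 2L else num / den
    crit <- stats::qt(1 - (1 - conf_level) / 2, df = df)
    ci <- exp(log(ratio) + c(-1, 1) * crit * se_log)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  structure(
    list(ratio = ratio, ci_lower = ci[1L], ci_upper = ci[2L],
         p_one_tailed = p_one, direction = direction,
         n_conjugate = nc, n_reference = nr),
    class = "uptake_ratio"
  )
}

#' @export
print.uptake_ratio <- function(x, ...) {
  cat(sprintf(
    "<uptake_ratio> %.3g [%.3g, %.3g], one-tailed p = %.3g (%s), n = %d/%d\n",
    x$ratio, x$ci_lower, x$ci_upper, x$p_one_tailed, x$direction,
    x$n_conjugate, x$n_reference))
  invisible(x)
}

#' Cumulative GAG variation from baseline
#'
#' Per-sample relative change of glycosaminoglycan content against day 0,
#' as a percentage: `delta(t) = 100 (GAG(t) - GAG(0)) / GAG(0)`. Group
#' summaries are the mean with a t-based confidence interval per day.
#'
#' @param tc Data frame with columns `group`, `sample_id`, `day`, `gag_ug`;
#'   every sample must include day 0 with positive content.
#' @param conf_level Confidence level for group summaries (default 0.95).
#' @return List with `per_sample` (data frame: group, sample_id, day,
#'   variation_pct) and `summary` (data frame: group, day, mean_pct,
#'   ci_lower, ci_upper, n).
#' @export
gag_cumulative_variation <- function(tc, conf_level = 0.95) {
  need <- c("group", "sample_id", "day", "gag_ug")
  if (!all(need %in% names(tc))) {
    stop("timecourse needs columns: ", paste(need, collapse = ", "))
  }
  per <- do.call(rbind, lapply(split(tc, tc$sample_id), function(s) {
    base <- s$gag_ug[s$day == 0]
    if (length(base) == 0L) {
      stop("sample ", s$sample_id[1L], " lacks a day-0 measurement")
    }
    if (base[1L] <= 0) {
      stop("sample ", s$sample_id[1L], " has nonpositive day-0 GAG")
    }
    data.frame(group = s$group, sample_id = s$sample_id, day = s$day,
               variation_pct = 100 * (s$gag_ug - base[1L]) / base[1L],
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  summ <- do.call(rbind, lapply(split(per, list(per$group, per$day),
                                      drop = TRUE), function(g) {
    n <- nrow(g); m <- mean(g$variation_pct)
    half <- if (n >= 2L) {
      stats::qt(1 - (1 - conf_level) / 2, n - 1L) *
        stats::sd(g$variation_pct) / sqrt(n)
    } else NA_real_
    data.frame(group = g$group[1L], day = g$day[1L], mean_pct = m,
               ci_lower = m - half, ci_upper = m + half, n = n,
               stringsAsFactors = FALSE)
  }))
  summ <- summ[order(summ$group, summ$day), ]
  rownames(summ) <- NULL
  list(per_sample = per, summary = summ)
}

#' One-way analysis of variance
#'
#' Standard between/within sum-of-squares decomposition, fitted through
#' [stats::aov]. Used to compare GAG content across treatment groups at a
#' given day.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor (or coercible) of group labels, >= 2 levels, each
#'   with n >= 2.
#' @return List with `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs n >= 2")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1L]]
  list(F = tab[["F value"]][1L],
       df_between = tab[["Df"]][1L],
       df_within = tab[["Df"]][2L],
       p = tab[["Pr(>F)"]][1L])
}

#' Tukey honestly-significant-difference post hoc test
#'
#' All pairwise group comparisons controlled at the family level using the
#' studentized range distribution. Computed directly from group means and the
#' pooled within-group mean square via `ptukey`/`qtukey` (the Tukey-Kramer
#' form for unequal group sizes), which keeps the test fast enough for
#' large-scale null simulation; it agrees with [stats::TukeyHSD] to numerical
#' precision.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels (>= 2 levels, each n >= 2).
#' @param conf_level Family confidence level (default 0.95).
#' @return Data frame with one row per pair: `group_a`, `group_b`, `diff`
#'   (mean a - mean b), `ci_lower`, `ci_upper`, `p_adj`.
#' @export
tukey_hsd <- function(values, groups, conf_level = 0.95) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("need >= 2 groups")
  ni <- tabulate(groups)
  if (any(ni < 2L)) stop("each group needs n >= 2")
  means <- tapply(values, groups, mean)
  n <- length(values)
  df <- n - k
  mse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) / df

  pairs <- utils::combn(k, 2L)
  out <- do.call(rbind, apply(pairs, 2L, function(ij) {
    i <- ij[2L]; j <- ij[1L]  # later level minus earlier, like TukeyHSD
    d <- means[i] - means[j]
    se <- sqrt(mse / 2 * (1 / ni[i] + 1 / ni[j]))
    if (se == 0) {
      p <- if (d == 0) 1 else 0
      half <- 0
    } else {
      qstat <- abs(d) / se
      p <- stats::ptukey(qstat, nmeans = k, df = df, lower.tail = FALSE)
      half <- stats::qtukey(conf_level, nmeans = k, df = df) * se
    }
    data.frame(group_a = levels(groups)[i], group_b = levels(groups)[j],
               diff = unname(d), ci_lower = unname(d - half),
               ci_upper = unname(d + half), p_adj = p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Flag polymers with significant uptake differences
#'
#' Collapses a set of uptake-ratio results over polymers, end-caps and
#' exposure times into the significance table behind the screening figures:
#' which conjugates move drug uptake significantly, and in which direction.
#' No multiplicity adjustment is applied across the library by default
#' (matching per-comparison screening practice); Benjamini-Hochberg is
#' available.
#'
#' @param results Data frame with columns `polymer_id`, `endcap`, `time_min`,
#'   plus either a `p_one_tailed` and `ratio`/`direction` column set, or a
#'   list-column of `uptake_ratio` objects named `result`.
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame: `polymer_id`, `endcap`, `time_min`, `ratio`,
#'   `direction`, `p`, `significant`.
#' @export
flag_significant_uptake <- function(results, alpha = 0.05,
                                    adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (nrow(results) == 0L) {
    return(data.frame(polymer_id = character(), endcap = character(),
                      time_min = numeric(), ratio = numeric(),
                      direction = character(), p = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  if (!is.null(results$result)) {
    results$ratio <- vapply(results$result, `[[`, 0, "ratio")
    results$direction <- vapply(results$result, `[[`, "", "direction")
    results$p_one_tailed <- vapply(results$result, `[[`, 0, "p_one_tailed")
  }
  p <- results$p_one_tailed
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  data.frame(polymer_id = results$polymer_id, endcap = results$endcap,
             time_min = results$time_min, ratio = results$ratio,
             direction = results$direction, p = p,
             significant = p < alpha, stringsAsFactors = FALSE)
}
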