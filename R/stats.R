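# Group-comparison statistics with normality-gated test selection.
# Parametric branches use base stats (t.test, aov, cor.test); the gate is
# Shapiro-Wilk at alpha = 0.05 on each sample (paired: on the differences).

.is_normal <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 3) return(FALSE)
  stats::shapiro.test(x)$p.value >= alpha
}

# Wilcoxon signed-rank with the Pratt zero-difference convention:
# zeros are ranked with the rest, then their ranks are discarded; normal
# approximation with tie correction. All-zero differences give p = 1.
.wilcoxon_pratt <- function(d) {
  n <- length(d)
  nz <- sum(d == 0)
  if (nz == n) return(list(statistic = 0, p = 1))
  r <- rank(abs(d))
  keep <- d != 0
  W <- sum(r[keep][d[keep] > 0])
  e_w <- (n * (n + 1) - nz * (nz + 1)) / 4
  ties <- table(r[keep])
  v_w <- (n * (n + 1) * (2 * n + 1) - nz * (nz + 1) * (2 * nz + 1)) / 24 -
    sum(ties^3 - ties) / 48
  z <- (W - e_w) / sqrt(v_w)
  list(statistic = W, p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Normality-gated two-sample comparison
#'
#' Paired data: paired t-test when the differences pass Shapiro-Wilk at
#' alpha = 0.05, otherwise the Wilcoxon signed-rank test (Pratt
#' zero-handling). Unpaired: Welch t-test when both samples pass, otherwise
#' the Mann-Whitney U test. All p-values two-tailed.
#'
#' @param x,y Numeric samples (equal length if `paired`).
#' @param paired Logical.
#' @param alpha Normality-gate level (default 0.05).
#' @return List of class `comparison_result`: `statistic_name` (`"t"`,
#'   `"W"`, `"U"`), `statistic`, `p`, `test_used`, `n` (per sample),
#'   `direction` (sign of mean(x) - mean(y)), `normal` (gate outcome).
#' @export
select_test <- function(x, y, paired = FALSE, alpha = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (paired) stopifnot(length(x) == length(y))
  if (length(x) < 3 || length(y) < 3)
    stop("select_test: need at least 3 observations per sample")
  if (!paired && stats::var(x) == 0 && stats::var(y) == 0)
    stop("select_test: zero variance in both samples")
  if (paired) {
    d <- x - y
    if (stats::sd(d) == 0 && all(d == 0)) {
      res <- list(statistic_name = "W", statistic = 0, p = 1,
                  test_used = "wilcoxon_signed_rank",
                  n = c(length(x), length(y)), direction = 0, normal = FALSE)
      return(structure(res, class = "comparison_result"))
    }
    if (.is_normal(d, alpha)) {
      tt <- stats::t.test(x, y, paired = TRUE)
      res <- list(statistic_name = "t", statistic = unname(tt$statistic),
                  p = tt$p.value, test_used = "paired_t", normal = TRUE)
    } else {
      wr <- .wilcoxon_pratt(d)
      res <- list(statistic_name = "W", statistic = wr$statistic, p = wr$p,
                  test_used = "wilcoxon_signed_rank", normal = FALSE)
    }
  } else {
    if (.is_normal(x, alpha) && .is_normal(y, alpha)) {
      tt <- stats::t.test(x, y)
      res <- list(statistic_name = "t", statistic = unname(tt$statistic),
                  p = tt$p.value, test_used = "independent_t", normal = TRUE)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
      res <- list(statistic_name = "U", statistic = unname(wt$statistic),
                  p = wt$p.value, test_used = "mann_whitney_u", normal = FALSE)
    }
  }
  res$n <- c(length(x), length(y))
  res$direction <- sign(mean(x) - mean(y))
  structure(res, class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g, p = %.4g (n = %s)\n", x$test_used,
              x$statistic_name, x$statistic, x$p,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' One-way ANOVA across vowels
#'
#' Standard between-groups F decomposition of a value (e.g. PAP diameter)
#' over vowel categories.
#'
#' @param values Numeric vector.
#' @param vowel Factor/character of the same length.
#' @return `comparison_result` with the F statistic, its p-value and the
#'   degrees of freedom in `df`.
#' @export
anova_one_way <- function(values, vowel) {
  vowel <- factor(vowel)
  if (nlevels(vowel) < 2) stop("anova_one_way: need at least 2 vowels")
  if (any(table(vowel) < 2)) stop("anova_one_way: a vowel cell has fewer than 2 values")
  fit <- stats::aov(values ~ vowel)
  s <- summary(fit)[[1]]
  structure(list(statistic_name = "F", statistic = s[["F value"]][1],
                 p = s[["Pr(>F)"]][1], test_used = "one_way_anova",
                 df = c(s[["Df"]][1], s[["Df"]][2]),
                 n = length(values), direction = NA_real_),
            class = "comparison_result")
}

#' Mixed two-way repeated-measures ANOVA (group x vowel)
#'
#' Group is between-subjects, vowel within-subjects, with subject error
#' strata (`aov` with `Error(subject/vowel)`). The group x vowel interaction
#' is the headline test that the See-to-Sah change differs between groups.
#' Subjects missing a vowel condition are excluded listwise with a warning.
#'
#' @param data data.frame with columns `participant_id`, `group`, `vowel`,
#'   `value`.
#' @return List of class `rm_anova_result` with one row per term (`group`,
#'   `vowel`, `group:vowel`) in `$table` (F, df, p) and the interaction
#'   p-value as `$interaction_p`.
#' @export
anova_two_way_rm <- function(data) {
  stopifnot(all(c("participant_id", "group", "vowel", "value") %in% names(data)))
  d <- data
  d$participant_id <- factor(d$participant_id)
  d$group <- factor(d$group)
  d$vowel <- factor(d$vowel)
  nlev <- nlevels(d$vowel)
  cnt <- table(d$participant_id)
  incomplete <- names(cnt)[cnt < nlev]
  if (length(incomplete)) {
    warning("anova_two_way_rm: excluding subject(s) missing a condition: ",
            paste(incomplete, collapse = ", "))
    d <- d[!d$participant_id %in% incomplete, , drop = FALSE]
    d$participant_id <- droplevels(d$participant_id)
  }
  fit <- stats::aov(value ~ group * vowel + Error(participant_id / vowel),
                    data = d)
  s <- summary(fit)
  between <- s[["Error: participant_id"]][[1]]
  within <- s[["Error: participant_id:vowel"]][[1]]
  rn <- function(tab) trimws(rownames(tab))
  tab <- rbind(
    data.frame(term = "group", df = between[rn(between) == "group", "Df"],
               F = between[rn(between) == "group", "F value"],
               p = between[rn(between) == "group", "Pr(>F)"]),
    data.frame(term = "vowel", df = within[rn(within) == "vowel", "Df"],
               F = within[rn(within) == "vowel", "F value"],
               p = within[rn(within) == "vowel", "Pr(>F)"]),
    data.frame(term = "group:vowel", df = within[rn(within) == "group:vowel", "Df"],
               F = within[rn(within) == "group:vowel", "F value"],
               p = within[rn(within) == "group:vowel", "Pr(>F)"]))
  structure(list(table = tab, interaction_p = tab$p[tab$term == "group:vowel"],
                 n_subjects = nlevels(d$participant_id)),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat("Mixed repeated-measures ANOVA (", x$n_subjects, "subjects )\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Per-participant See-minus-Sah deltas
#'
#' @param data data.frame with `participant_id`, `group`, `vowel` and a
#'   value column.
#' @param value Name of the value column (default `"pap_mm"`).
#' @param from,to Vowels differenced as `from - to` (defaults `/i/ - /a/`,
#'   i.e. See minus Sah).
#' @return data.frame with `participant_id`, `group`, `value_see`,
#'   `value_sah`, `delta`.
#' @export
delta_table <- function(data, value = "pap_mm", from = "i", to = "a") {
  a <- data[data$vowel == from, c("participant_id", "group", value)]
  b <- data[data$vowel == to, c("participant_id", value)]
  names(a)[3] <- "value_see"; names(b)[2] <- "value_sah"
  m <- merge(a, b, by = "participant_id")
  m$delta <- m$value_see - m$value_sah
  m
}

#' Feature-PAP correlations per vowel
#'
#' For every feature x vowel cell, correlates the feature with the PAP
#' diameter across participants, using Pearson when both variables pass
#' Shapiro-Wilk at alpha = 0.05 and Spearman otherwise. Constant features
#' give a missing-value cell with a warning. No multiple-testing correction
#' is applied (raw p-values, matching the study's reporting).
#'
#' @param features Feature table from [extract_features()] (columns
#'   `participant_id`, `vowel`, features).
#' @param pap PAP table with `participant_id`, `vowel`, `pap_mm`.
#' @param feature_cols Feature columns to correlate (default: all 106).
#' @return data.frame with `feature`, `vowel`, `r`, `p`, `method`, `n`.
#' @export
correlate_features <- function(features, pap,
                               feature_cols = intersect(feature_names(),
                                                        names(features))) {
  out <- NULL
  for (v in unique(features$vowel)) {
    fv <- features[features$vowel == v, , drop = FALSE]
    pv <- pap[pap$vowel == v, c("participant_id", "pap_mm")]
    m <- merge(fv, pv, by = "participant_id")
    for (fc in feature_cols) {
      x <- m[[fc]]; y <- m$pap_mm
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3 || stats::sd(x[ok]) == 0) {
        warning("correlate_features: constant or missing feature '", fc,
                "' for vowel ", v)
        out <- rbind(out, data.frame(feature = fc, vowel = v, r = NA_real_,
                                     p = NA_real_, method = NA_character_,
                                     n = sum(ok)))
        next
      }
      method <- if (.is_normal(x[ok]) && .is_normal(y[ok])) "pearson" else "spearman"
      ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = method,
                                             exact = FALSE))
      out <- rbind(out, data.frame(feature = fc, vowel = v,
                                   r = unname(ct$estimate), p = ct$p.value,
                                   method = method, n = sum(ok)))
    }
  }
  out
}

#' Wide correlation matrix (features x vowels) for heatmap export
#'
#' @param cells Output of [correlate_features()].
#' @return data.frame, one row per feature, one `r_<vowel>` column per vowel.
#' @export
correlation_matrix <- function(cells) {
  vs <- unique(cells$vowel)
  wide <- data.frame(feature = unique(cells$feature))
  for (v in vs) {
    sub <- cells[cells$vowel == v, c("feature", "r")]
    names(sub)[2] <- paste0("r_", v)
    wide <- merge(wide, sub, by = "feature", all.x = TRUE, sort = FALSE)
  }
  wide[match(unique(cells$feature), wide$feature), , drop = FALSE]
}
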