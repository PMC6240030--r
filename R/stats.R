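# The statistical battery used for CSD susceptibility studies: Mann-Whitney
# U for two independent groups, Kruskal-Wallis across groups followed by
# Dunn's multiple comparisons with Bonferroni correction, ordinary linear
# regression with a slope t-test, and paired t-tests. All tests two-tailed
# at alpha = 0.05.

test_result <- function(test, statistic, df = NA_real_, n, p_value,
                        comparison = "", corrected = FALSE) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(test = test, statistic = statistic, df = df, n = n,
                 p_value = p_value, comparison = comparison,
                 corrected = corrected),
            class = "csd_test_result")
}

#' @export
print.csd_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g%s\n    [%s; n = %s]\n",
              x$test, x$statistic, format(x$df), x$p_value,
              if (x$corrected) " (corrected)" else "",
              x$comparison, paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum test for two independent samples with midrank tie handling.
#' Reports the larger of the two U values (the convention under which
#' complete separation gives U = n1*n2) and a two-tailed p value: exact by
#' enumeration when `n1 + n2 <= 25` with no ties, otherwise the normal
#' approximation with tie and continuity correction. The df field holds
#' `n1 + n2 - 2` (the convention used when reporting e.g. U(15) for group
#' sizes 8 and 9).
#'
#' @param a,b Numeric samples.
#' @param comparison Label carried into the result.
#' @return A `csd_test_result` with the U statistic.
#' @export
mann_whitney_u <- function(a, b, comparison = "a vs b") {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- max(u1, u2)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (n1 + n2 <= 25) && !ties
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  if (is.na(p)) p <- 1   # both samples identical constants
  test_result("Mann-Whitney U", statistic = u, df = n1 + n2 - 2,
              n = c(n1, n2), p_value = min(p, 1), comparison = comparison)
}

#' Kruskal-Wallis test
#'
#' Rank-based one-way test across k groups with tie correction;
#' chi-squared reference with df = k - 1. When all observations are equal
#' the statistic is 0 with p = 1.
#'
#' @param groups List of numeric samples.
#' @param comparison Label carried into the result.
#' @return A `csd_test_result` with the H statistic.
#' @export
kruskal_wallis <- function(groups, comparison = "groups") {
  stopifnot(is.list(groups), length(groups) >= 2L, all(lengths(groups) > 0))
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L) {
    return(test_result("Kruskal-Wallis", statistic = 0,
                       df = length(groups) - 1, n = lengths(groups),
                       p_value = 1, comparison = comparison))
  }
  kt <- stats::kruskal.test(groups)
  test_result("Kruskal-Wallis", statistic = unname(kt$statistic),
              df = unname(kt$parameter), n = lengths(groups),
              p_value = kt$p.value, comparison = comparison)
}

#' Dunn's multiple comparisons with Bonferroni correction
#'
#' Post-hoc pairwise z tests on mean-rank differences after a
#' Kruskal-Wallis test, with tie-corrected pooled variance. Each unordered
#' pair yields one z; p values are multiplied by the number of pairwise
#' comparisons and capped at 1.
#'
#' @param groups List of numeric samples (length >= 2).
#' @param labels Group labels.
#' @return `data.frame` with one row per pair: `group1`, `group2`, `n1`,
#'   `n2`, `mean_rank1`, `mean_rank2`, `z`, `p_unadjusted`, `p_adjusted`.
#' @export
dunn_bonferroni <- function(groups, labels = names(groups)) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups for Dunn's test")
  }
  if (is.null(labels)) labels <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  tt <- table(x)
  tie_c <- sum(tt^3 - tt) / (12 * (N - 1))
  mr <- tapply(r, g, mean)
  n <- lengths(groups)
  pr <- utils::combn(length(groups), 2L)
  m <- ncol(pr)
  rows <- lapply(seq_len(m), function(k) {
    i <- pr[1L, k]; j <- pr[2L, k]
    se <- sqrt((N * (N + 1) / 12 - tie_c) * (1 / n[i] + 1 / n[j]))
    z <- if (se > 0) (mr[[i]] - mr[[j]]) / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = labels[i], group2 = labels[j],
               n1 = n[[i]], n2 = n[[j]],
               mean_rank1 = mr[[i]], mean_rank2 = mr[[j]], z = z,
               p_unadjusted = p, p_adjusted = min(1, m * p))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Linear regression slope t-test
#'
#' Ordinary least squares of y on x; reports the slope, its standard
#' error, t = slope / SE with df = n - 2 and the two-tailed p value. A
#' perfect fit (zero residual variance) is flagged with t = Inf, p = 0.
#'
#' @param x,y Numeric vectors of equal length (n >= 3); x must vary.
#' @param comparison Label carried into the result.
#' @return A `csd_test_result`; `slope` and `se` are attached.
#' @export
linear_regression_t <- function(x, y, comparison = "y ~ x") {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0) stop("x is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  res_ss <- sum(stats::residuals(fit)^2)
  slope <- unname(stats::coef(fit)[2L])
  if (res_ss < 1e-12 * max(1, sum(y^2))) {
    out <- test_result("linear regression", statistic = Inf, df = n - 2,
                       n = n, p_value = 0, comparison = comparison)
  } else {
    sm <- summary(fit)$coefficients
    out <- test_result("linear regression", statistic = sm[2L, "t value"],
                       df = n - 2, n = n, p_value = sm[2L, "Pr(>|t|)"],
                       comparison = comparison)
  }
  attr(out, "slope") <- slope
  attr(out, "se") <- if (is.infinite(out$statistic)) 0 else
    summary(fit)$coefficients[2L, "Std. Error"]
  out
}

#' Paired t-test
#'
#' t test on paired differences with df = n - 1, two-tailed. A constant
#' nonzero shift (zero difference variance) is flagged with t = +/-Inf and
#' p = 0; identical samples raise a degenerate-case error.
#'
#' @param a,b Paired numeric vectors of equal length (n >= 2).
#' @param comparison Label carried into the result.
#' @return A `csd_test_result`.
#' @export
paired_t <- function(a, b, comparison = "a vs b") {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2L) stop("need at least 2 complete pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) stop("degenerate-case error: zero difference variance")
    return(test_result("paired t-test", statistic = sign(mean(d)) * Inf,
                       df = n - 1, n = n, p_value = 0,
                       comparison = comparison))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  test_result("paired t-test", statistic = unname(tt$statistic),
              df = unname(tt$parameter), n = n, p_value = tt$p.value,
              comparison = comparison)
}

# --- study-level battery ---------------------------------------------------

GROUPS <- c("male", "female", "aged_male", "PM_female")

study_row <- function(analysis, comparison, groups, n, test, statistic, df,
                      p, p_adj = NA_real_, note = "") {
  data.frame(analysis = analysis, comparison = comparison,
             groups = as.character(groups), n = as.character(n),
             test = test, statistic = statistic, df = as.numeric(df),
             p_value = p, p_adjusted = p_adj,
             significant = is.finite(if (is.na(p_adj)) p else p_adj) &&
               (if (is.na(p_adj)) p else p_adj) < 0.05,
             note = note, stringsAsFactors = FALSE)
}

#' Run the full group-statistics battery over a cohort
#'
#' Given per-subject summaries, emits the study's battery:
#' * per-group WT vs G301R Mann-Whitney tests on CSD frequency and
#'   propagation speed;
#' * within-genotype Kruskal-Wallis across the four groups on frequency
#'   and speed, followed by Dunn-Bonferroni post hocs when significant;
#' * epileptiform-onset Kruskal-Wallis over pooled wild types plus the
#'   four G301R groups (wild types are pooled because few develop any
#'   activity), with Dunn-Bonferroni post hocs;
#' * linear regressions severity ~ frequency, onset ~ frequency and
#'   severity ~ onset on G301R subjects only;
#' * paired t-tests comparing the three cross-correlation peak
#'   coefficients, and their absolute peak lags, between channel pairs.
#'
#' Subjects with no epileptiform onset are excluded from onset tests (the
#' count is noted); subjects failing channel QC are excluded from the
#' cross-correlation tests.
#'
#' @param summaries `data.frame` with one row per subject; see
#'   [analyze_subject()] for the expected columns.
#' @param alpha Significance level for gating post hocs.
#' @return List of class `study_report`: `tables` (all test rows),
#'   `dunn` (post-hoc frames), `skipped` (named reasons), `n_excluded_onset`,
#'   `n_excluded_xcorr`.
#' @export
run_study <- function(summaries, alpha = 0.05) {
  s <- summaries
  stopifnot(is.data.frame(s), all(c("genotype", "group") %in% names(s)))
  rows <- list()
  dunns <- list()
  skipped <- character(0)
  cell <- function(gt, gr, var) {
    v <- s[[var]][s$genotype == gt & s$group == gr]
    v[is.finite(v)]
  }

  # 1. per-group WT vs G301R Mann-Whitney on frequency and speed
  for (var in c("csd_frequency", "propagation_speed")) {
    vlab <- if (var == "csd_frequency") "CSD frequency" else "propagating speed"
    for (gr in GROUPS) {
      a <- cell("WT", gr, var); b <- cell("G301R", gr, var)
      cmp <- sprintf("WT %s vs G301R %s", gr, gr)
      if (!length(a) || !length(b)) {
        skipped[cmp] <- paste("empty cell for", vlab)
        next
      }
      mw <- mann_whitney_u(a, b, cmp)
      rows[[length(rows) + 1L]] <- study_row(
        vlab, cmp, gr, sprintf("%d,%d", length(a), length(b)),
        mw$test, mw$statistic, mw$df, mw$p_value)
    }
    # 2. within-genotype Kruskal-Wallis + Dunn
    for (gt in c("WT", "G301R")) {
      gl <- lapply(GROUPS, function(gr) cell(gt, gr, var))
      names(gl) <- GROUPS
      gl <- gl[lengths(gl) > 0]
      if (length(gl) < 2L) {
        skipped[paste(gt, vlab, "KW")] <- "fewer than 2 populated groups"
        next
      }
      kw <- kruskal_wallis(gl, paste(gt, "groups"))
      rows[[length(rows) + 1L]] <- study_row(
        vlab, sprintf("%s: %s", gt, paste(names(gl), collapse = ", ")),
        gt, paste(lengths(gl), collapse = ","),
        kw$test, kw$statistic, kw$df, kw$p_value)
      if (kw$p_value < alpha && length(gl) > 2L) {
        dn <- dunn_bonferroni(gl)
        dunns[[paste(gt, var, sep = ".")]] <- dn
        for (i in seq_len(nrow(dn))) {
          rows[[length(rows) + 1L]] <- study_row(
            vlab, sprintf("%s %s vs %s", gt, dn$group1[i], dn$group2[i]),
            gt, sprintf("%d,%d", dn$n1[i], dn$n2[i]),
            "Dunn (Bonferroni)", dn$z[i], NA, dn$p_unadjusted[i],
            dn$p_adjusted[i])
        }
      }
    }
  }

  # 3. epileptiform onset: pooled WT + 4 G301R groups
  if ("epi_onset" %in% names(s)) {
    n_excl <- sum(s$genotype %in% c("WT", "G301R") & !is.finite(s$epi_onset))
    wt_on <- s$epi_onset[s$genotype == "WT" & is.finite(s$epi_onset)]
    gl <- c(list(WT_pooled = wt_on),
            stats::setNames(lapply(GROUPS, function(gr)
              cell("G301R", gr, "epi_onset")), paste0("G301R_", GROUPS)))
    gl <- gl[lengths(gl) > 0]
    if (length(gl) >= 2L) {
      kw <- kruskal_wallis(gl, "epileptiform onset")
      rows[[length(rows) + 1L]] <- study_row(
        "epileptiform onset", paste(names(gl), collapse = ", "), "pooled",
        paste(lengths(gl), collapse = ","), kw$test, kw$statistic, kw$df,
        kw$p_value, note = sprintf("%d subjects without onset excluded", n_excl))
      if (kw$p_value < alpha && length(gl) > 2L) {
        dn <- dunn_bonferroni(gl)
        dunns[["epi_onset"]] <- dn
        for (i in seq_len(nrow(dn))) {
          rows[[length(rows) + 1L]] <- study_row(
            "epileptiform onset",
            sprintf("%s vs %s", dn$group1[i], dn$group2[i]), "pooled",
            sprintf("%d,%d", dn$n1[i], dn$n2[i]),
            "Dunn (Bonferroni)", dn$z[i], NA, dn$p_unadjusted[i],
            dn$p_adjusted[i])
        }
      }
    } else {
      skipped[["epileptiform onset"]] <- "fewer than 2 populated groups"
    }
  }

  # 4. regressions on G301R subjects only
  g3 <- s[s$genotype == "G301R", , drop = FALSE]
  regs <- list(
    c("severity", "csd_frequency", "severity ~ CSD frequency"),
    c("epi_onset", "csd_frequency", "onset ~ CSD frequency"),
    c("severity", "epi_onset", "severity ~ onset"))
  for (rg in regs) {
    if (!all(rg[1:2] %in% names(g3))) next
    yv <- g3[[rg[1]]]; xv <- g3[[rg[2]]]
    ok <- is.finite(yv) & is.finite(xv)
    if (sum(ok) < 3L || stats::sd(xv[ok]) == 0) {
      skipped[rg[3]] <- "insufficient complete G301R observations"
      next
    }
    lr <- linear_regression_t(xv[ok], yv[ok], rg[3])
    rows[[length(rows) + 1L]] <- study_row(
      "regression (G301R)", rg[3], "G301R", sum(ok), lr$test,
      lr$statistic, lr$df, lr$p_value)
  }

  # 5. paired t-tests on cross-correlation peaks and |lags|
  xc_coef <- c("xc_coeff_m1s1", "xc_coeff_m1m1r", "xc_coeff_s1m1r")
  xc_lag <- c("xc_lag_m1s1", "xc_lag_m1m1r", "xc_lag_s1m1r")
  n_excl_xc <- 0L
  if (all(xc_coef %in% names(s))) {
    keep <- !apply(is.na(s[, xc_coef]), 1L, any)
    if ("excluded" %in% names(s)) keep <- keep & !s$excluded
    n_excl_xc <- sum(!keep)
    xs <- s[keep, , drop = FALSE]
    prs <- list(c(1L, 2L, "M1L-S1L vs M1L-M1R"),
                c(1L, 3L, "M1L-S1L vs S1L-M1R"),
                c(2L, 3L, "M1L-M1R vs S1L-M1R"))
    if (nrow(xs) >= 2L) {
      for (pp in prs) {
        i <- as.integer(pp[1]); j <- as.integer(pp[2])
        pt <- tryCatch(paired_t(xs[[xc_coef[i]]], xs[[xc_coef[j]]], pp[3]),
                       error = function(e) NULL)
        if (!is.null(pt)) {
          rows[[length(rows) + 1L]] <- study_row(
            "max cross-correlation", pp[3], "G301R+WT", pt$n, pt$test,
            pt$statistic, pt$df, pt$p_value)
        }
        pt <- tryCatch(paired_t(abs(xs[[xc_lag[i]]]), abs(xs[[xc_lag[j]]]),
                                pp[3]), error = function(e) NULL)
        if (!is.null(pt)) {
          rows[[length(rows) + 1L]] <- study_row(
            "cross-correlation |lag|", pp[3], "G301R+WT", pt$n, pt$test,
            pt$statistic, pt$df, pt$p_value)
        }
      }
    } else {
      skipped[["cross-correlation"]] <- "fewer than 2 subjects pass channel QC"
    }
  }

  tables <- if (length(rows)) do.call(rbind, rows) else
    data.frame()
  structure(list(tables = tables, dunn = dunns, skipped = skipped,
                 n_excluded_xcorr = n_excl_xc, alpha = alpha),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d tests, alpha = %g\n", nrow(x$tables), x$alpha))
  if (nrow(x$tables)) {
    df <- x$tables
    df$statistic <- signif(df$statistic, 4)
    df$p_value <- signif(df$p_value, 3)
    df$p_adjusted <- signif(df$p_adjusted, 3)
    print(df[, c("analysis", "comparison", "n", "test", "statistic",
                 "p_value", "p_adjusted", "significant")], row.names = FALSE)
  }
  if (length(x$skipped)) {
    cat("skipped:\n")
    for (nm in names(x$skipped)) cat("  -", nm, ":", x$skipped[[nm]], "\n")
  }
  invisible(x)
}
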