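#' Two-way ANOVA of an outcome by ager status and sex
#'
#' General-linear-model ANOVA with main effects of MAA status and sex and
#' their interaction, using type-III sums of squares with sum-to-zero
#' contrasts (type I available via `ss_type = 1`). Raw group means with
#' standard errors are reported per status, overall and within sex, together
#' with Bonferroni-adjusted pairwise status contrasts (pooled-variance t
#' tests; the adjustment family is the three pairwise contrasts within each
#' reporting stratum).
#'
#' When `sex` has a single level the model reduces to a one-way ANOVA on
#' status. A constant outcome is reported as F = 0, p = 1.
#'
#' @param outcome Numeric outcome vector.
#' @param status Ager class vector (e.g. decelerated/normal/accelerated).
#' @param sex Sex vector; may be constant.
#' @param ss_type 3 (default) or 1.
#' @return Object of class `anova_result`: `effects` (term, df, F, p),
#'   `means` (stratum, group, n, mean, sem), `pairwise` (stratum, contrast,
#'   raw_p, adj_p).
#' @export
two_way_anova <- function(outcome, status, sex, ss_type = 3) {
  if (!length(outcome) || length(status) != length(outcome) ||
      length(sex) != length(outcome)) {
    stop("`outcome`, `status` and `sex` must have equal length", call. = FALSE)
  }
  keep <- is.finite(outcome) & !is.na(status) & !is.na(sex)
  outcome <- outcome[keep]
  status <- droplevels(factor(status))[keep]
  sex <- droplevels(factor(sex))[keep]
  status <- droplevels(status); sex <- droplevels(sex)
  if (nlevels(status) < 2) stop("need at least 2 status groups", call. = FALSE)

  two_factor <- nlevels(sex) >= 2
  if (two_factor) {
    cells <- table(status, sex)
    if (any(cells == 0)) {
      empty <- which(cells == 0, arr.ind = TRUE)
      lab <- apply(empty, 1, function(i) {
        paste0(rownames(cells)[i[1]], ":", colnames(cells)[i[2]])
      })
      stop("empty design cell(s): ", paste(lab, collapse = ", "), call. = FALSE)
    }
  }

  constant <- sd(outcome) == 0
  if (constant) {
    terms <- if (two_factor) c("status", "sex", "status:sex") else "status"
    effects <- data.frame(term = terms, F = 0, p = 1)
  } else if (two_factor) {
    dat <- data.frame(outcome = outcome, status = status, sex = sex)
    fit <- lm(outcome ~ status * sex, data = dat,
              contrasts = list(status = "contr.sum", sex = "contr.sum"))
    if (ss_type == 3) {
      a <- car::Anova(fit, type = 3)
      rows <- c("status", "sex", "status:sex")
      effects <- data.frame(term = rows,
                            F = a[rows, "F value"],
                            p = a[rows, "Pr(>F)"])
    } else {
      a <- stats::anova(fit)
      rows <- c("status", "sex", "status:sex")
      effects <- data.frame(term = rows,
                            F = a[rows, "F value"],
                            p = a[rows, "Pr(>F)"])
    }
  } else {
    a <- stats::anova(lm(outcome ~ status))
    effects <- data.frame(term = "status",
                          F = a["status", "F value"],
                          p = a["status", "Pr(>F)"])
  }
  rownames(effects) <- NULL

  strata <- list(overall = rep(TRUE, length(outcome)))
  if (two_factor) {
    for (s in levels(sex)) strata[[s]] <- sex == s
  }
  means <- do.call(rbind, lapply(names(strata), function(st) {
    idx <- strata[[st]]
    do.call(rbind, lapply(levels(status), function(g) {
      x <- outcome[idx & status == g]
      data.frame(stratum = st, group = g, n = length(x),
                 mean = if (length(x)) mean(x) else NA_real_,
                 sem = if (length(x) >= 2) sd(x) / sqrt(length(x)) else NA_real_)
    }))
  }))
  rownames(means) <- NULL

  pairs <- utils::combn(levels(status), 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(names(strata), function(st) {
    idx <- strata[[st]]
    do.call(rbind, lapply(pairs, function(pr) {
      xa <- outcome[idx & status == pr[1]]
      xb <- outcome[idx & status == pr[2]]
      raw <- if (length(xa) >= 2 && length(xb) >= 2 &&
                 (sd(xa) > 0 || sd(xb) > 0)) {
        t.test(xa, xb, var.equal = TRUE)$p.value
      } else if (constant) 1 else NA_real_
      data.frame(stratum = st, contrast = paste(pr, collapse = " vs "),
                 raw_p = raw, adj_p = pmin(1, raw * length(pairs)))
    }))
  }))
  rownames(pairwise) <- NULL

  structure(list(effects = effects, means = means, pairwise = pairwise,
                 ss_type = ss_type, n = length(outcome)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Two-way GLM ANOVA (type %s SS), n = %d\n", x$ss_type, x$n))
  eff <- x$effects
  eff$F <- round(eff$F, 2)
  eff$p <- signif(eff$p, 3)
  print(eff)
  cat("Bonferroni-adjusted pairwise status contrasts:\n")
  pw <- x$pairwise
  pw$raw_p <- signif(pw$raw_p, 3)
  pw$adj_p <- signif(pw$adj_p, 3)
  print(pw)
  invisible(x)
}

#' Pairwise Pearson correlation matrix
#'
#' Pearson r with two-sided p-values for every pair of columns, overall and
#' optionally within strata, using pairwise-complete observations. Pairs with
#' fewer than 3 complete observations are flagged as not estimable (`NA` r
#' and p with the pair n recorded).
#'
#' @param columns Data.frame of numeric columns.
#' @param stratify_by Optional class vector (e.g. sex) for per-stratum
#'   matrices.
#' @return Object of class `correlation_matrix`: per stratum, matrices `r`,
#'   `p` and `n`.
#' @export
pearson_correlations <- function(columns, stratify_by = NULL) {
  stopifnot(is.data.frame(columns))
  columns <- columns[vapply(columns, is.numeric, logical(1))]
  if (ncol(columns) < 2) stop("need at least two numeric columns", call. = FALSE)
  strata <- list(overall = rep(TRUE, nrow(columns)))
  if (!is.null(stratify_by)) {
    sb <- factor(stratify_by)
    for (s in levels(sb)) strata[[s]] <- !is.na(sb) & sb == s
  }
  vars <- names(columns)
  out <- lapply(strata, function(idx) {
    k <- length(vars)
    r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
    nm <- matrix(0L, k, k, dimnames = list(vars, vars))
    diag(r) <- 1
    for (i in seq_len(k)) {
      nm[i, i] <- sum(idx & is.finite(columns[[i]]))
      if (i == k) next
      for (j in seq.int(i + 1, k)) {
        ok <- idx & is.finite(columns[[i]]) & is.finite(columns[[j]])
        nm[i, j] <- nm[j, i] <- sum(ok)
        if (sum(ok) >= 3 && sd(columns[[i]][ok]) > 0 && sd(columns[[j]][ok]) > 0) {
          ct <- cor.test(columns[[i]][ok], columns[[j]][ok])
          r[i, j] <- r[j, i] <- unname(ct$estimate)
          p[i, j] <- p[j, i] <- ct$p.value
        }
      }
    }
    list(r = r, p = p, n = nm)
  })
  structure(out, class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  for (st in names(x)) {
    cat("Stratum:", st, "\n")
    print(round(x[[st]]$r, 3))
  }
  invisible(x)
}

#' Percent difference between two group means
#'
#' `100 * (comparison - reference) / reference`. Run reports round this to
#' the nearest integer percent.
#'
#' @param reference_mean Reference group mean (non-zero).
#' @param comparison_mean Comparison group mean.
#' @return Percent difference (numeric, unrounded).
#' @export
percent_difference <- function(reference_mean, comparison_mean) {
  if (any(reference_mean == 0)) {
    stop("reference mean must be non-zero", call. = FALSE)
  }
  100 * (comparison_mean - reference_mean) / reference_mean
}
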