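## Group statistics: demographic comparison tables, Welch tests on PC
## weights, and the significance-masked Pearson correlation matrix.
## The global significance level is 0.05 throughout.

#' Significance level used throughout the analysis
#' @export
SIG_LEVEL <- 0.05

.contVars <- c(age = "age", height = "height", weight = "weight", bmi = "bmi")
.cartVars <- c(cart_mfc = "cart_mfc", cart_mtp = "cart_mtp",
               cart_lfc = "cart_lfc", cart_ltp = "cart_ltp")

#' Compare demographics and cartilage status between groups
#'
#' Continuous variables (age, height, weight, BMI) are compared by the
#' two-sided pooled-variance Student t test, sex by Fisher's exact test on
#' the 2 x 2 table, and cartilage status per region by a chi-squared test
#' of independence on the grade x group contingency table (no continuity
#' correction). Grade categories empty in both groups are dropped with a
#' warning. Missing values are excluded per variable.
#'
#' @param records validated patient-record data.frame (see
#'   [readRecords()]); both groups must be non-empty.
#' @return data.frame with one row per variable: group summaries
#'   (mean +/- SD or counts), test name, statistic, p-value, and a
#'   significance flag at p < `r SIG_LEVEL`.
#' @export
compareDemographics <- function(records) {
  g <- records$group
  if (!all(c("R", "MPMS") %in% g)) stop("both groups must be non-empty")
  rows <- list()
  msd <- function(x) sprintf("%.1f ± %.1f", mean(x), sd(x))

  for (v in .contVars) {
    x <- records[[v]][g == "R"]; y <- records[[v]][g == "MPMS"]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (sd(c(x, y)) == 0) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- t.test(x, y, var.equal = TRUE)
    }
    rows[[v]] <- data.frame(variable = v,
      summary_R = msd(x), summary_MPMS = msd(y), test = "t",
      statistic = unname(tt$statistic), p = tt$p.value)
  }

  sexTab <- table(factor(records$sex, levels = c(0, 1)),
                  factor(g, levels = c("R", "MPMS")))
  ft <- fisher.test(sexTab)
  cnt <- function(grp) sprintf("%d (%.1f%%) female", sexTab["0", grp],
                               100 * sexTab["0", grp] / sum(sexTab[, grp]))
  rows$sex <- data.frame(variable = "sex", summary_R = cnt("R"),
    summary_MPMS = cnt("MPMS"), test = "fisher", statistic = NA_real_,
    p = ft$p.value)

  for (v in .cartVars) {
    tab <- table(factor(records[[v]], levels = .cartilageLevels),
                 factor(g, levels = c("R", "MPMS")))
    empty <- rowSums(tab) == 0
    if (any(empty)) {
      warning("dropping cartilage categories empty in both groups for '", v,
              "': ", paste(rownames(tab)[empty], collapse = ", "))
      tab <- tab[!empty, , drop = FALSE]
    }
    if (nrow(tab) < 2L) {
      ct <- list(statistic = 0, p.value = 1)
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    }
    fmt <- function(grp) paste(sprintf("%s:%d", rownames(tab), tab[, grp]),
                               collapse = " ")
    rows[[v]] <- data.frame(variable = v, summary_R = fmt("R"),
      summary_MPMS = fmt("MPMS"), test = "chisq",
      statistic = unname(ct$statistic), p = ct$p.value)
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$significant <- out$p < SIG_LEVEL
  out
}

#' Welch's unequal-variances t test
#'
#' Two-sided Welch t test with Welch-Satterthwaite degrees of freedom,
#' used to compare PC-weight distributions between the R and MPMS groups.
#' When both groups have zero variance and equal means the test is
#' degenerate and p = 1 is returned by convention (t = 0).
#'
#' @param x,y numeric vectors (at least 2 values each).
#' @return list with `t`, `df` and two-sided `p`.
#' @export
welchTest <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stop("need at least 2 values per group")
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_, p = 0))
  }
  tt <- t.test(x, y)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Assemble the analysis variables for the correlation matrix
#'
#' Builds the variable table relating outcome, demographics, KOOS
#' subscores and morphology: RTT recoded 1 for the R group / 0 for MPMS,
#' sex as 0/1, and the PC weights of the first three modes of each
#' supplied shape model.
#'
#' @param records validated record data.frame.
#' @param femur,tibia,joint optional n x >=3 PC-weight matrices (rows in
#'   record order).
#' @return data.frame of numeric variables.
#' @export
morphologyVariables <- function(records, femur = NULL, tibia = NULL,
                                joint = NULL) {
  out <- data.frame(
    rtt = as.integer(records$group == "R"),
    sex = records$sex, age = records$age, height = records$height,
    weight = records$weight, bmi = records$bmi,
    koos_symptoms = records$koos_symptoms, koos_pain = records$koos_pain,
    koos_adl = records$koos_adl, koos_sport = records$koos_sport,
    koos_qol = records$koos_qol, koos_total = records$koos_total)
  addW <- function(out, w, prefix) {
    if (is.null(w)) return(out)
    w <- as.matrix(w)
    if (nrow(w) != nrow(records)) stop("PC-weight rows must match records")
    for (j in 1:3) out[[sprintf("%s_pc%d", prefix, j)]] <- w[, j]
    out
  }
  out <- addW(out, femur, "femur")
  out <- addW(out, tibia, "tibia")
  out <- addW(out, joint, "joint")
  out
}

#' Significance-masked Pearson correlation matrix
#'
#' Pairwise Pearson correlation coefficients with two-sided p-values,
#' complete cases per pair. The `masked` matrix shows a coefficient only
#' where p < `r SIG_LEVEL` (and on the diagonal); zero-variance variables
#' yield undefined correlations, reported masked and listed in `notes`.
#'
#' @param variables numeric data.frame, e.g. from [morphologyVariables()];
#'   at least 3 complete rows.
#' @return list with matrices `r`, `p`, `masked`, and character vector
#'   `notes`.
#' @export
correlationMatrix <- function(variables) {
  variables <- as.data.frame(variables)
  if (nrow(variables) < 3L) stop("need at least 3 records")
  nm <- names(variables)
  k <- length(nm)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  notes <- character(0)
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    x <- variables[[i]]; y <- variables[[j]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      notes <- c(notes, sprintf("undefined correlation: %s vs %s", nm[i], nm[j]))
      next
    }
    ct <- cor.test(x[ok], y[ok])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  masked <- r
  masked[!is.na(p) & p >= SIG_LEVEL] <- NA_real_
  masked[is.na(p)] <- NA_real_
  diag(masked) <- 1
  list(r = r, p = p, masked = masked, notes = notes)
}
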