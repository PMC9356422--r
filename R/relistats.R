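## Inter-rater reliability statistics: two-way absolute-agreement
## single-measure ICC with F-based confidence intervals, Cohen's kappa,
## Cronbach's alpha, ROC-AUC with Hanley-McNeil intervals, Kendall's W with
## tie correction, and the agreement report builder. Ratings tables are
## complete n_subjects x k_raters matrices (no missing cells).

asRatingsMatrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("ratings table must be complete (no missing cells)",
                     call. = FALSE)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("ratings table needs at least 2 subjects and 2 raters",
         call. = FALSE)
  m
}

#' Intraclass correlation: two-way model, absolute agreement, single measure
#'
#' Reliability of continuous ratings across k raters (e.g. per-slide
#' probabilities from three retrained CNNs). The two-way ANOVA mean squares
#' are obtained with `stats::aov(value ~ subject + rater)` and combined as
#'
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`
#'
#' the absolute-agreement single-measure coefficient; the two-way
#' mixed-effects label shares this point estimate with the two-way random
#' model (standard convention). Confidence limits use the F-distribution
#' method with Satterthwaite degrees of freedom, the convention of the usual
#' statistical packages; default level 99 percent.
#'
#' @param table n x k matrix of ratings (subjects in rows).
#' @param ci_level confidence level, default 0.99.
#' @return List: `icc`, `lower`, `upper`, `level`, mean squares `MSR`,
#'   `MSC`, `MSE`, and `degenerate` (TRUE when the table has zero total
#'   variance, in which case ICC is reported as 1).
#' @export
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4), b = c(1.1, 2.2, 2.9, 4.2))
#' iccSingleAbsolute(m)
iccSingleAbsolute <- function(table, ci_level = 0.99) {
  m <- asRatingsMatrix(table)
  n <- nrow(m); k <- ncol(m)
  if (stats::var(as.vector(m)) == 0)
    return(list(icc = 1, lower = NA_real_, upper = NA_real_,
                level = ci_level, MSR = 0, MSC = 0, MSE = 0,
                degenerate = TRUE))
  long <- data.frame(value = as.vector(m),
                     subject = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(value ~ subject + rater, data = long))[[1]]
  MSR <- tab["subject", "Mean Sq"]
  MSC <- tab["rater", "Mean Sq"]
  MSE <- tab["Residuals", "Mean Sq"]
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  ## F-based limits (Satterthwaite df for the rater/error composite)
  alpha <- 1 - ci_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  list(icc = icc, lower = lower, upper = upper, level = ci_level,
       MSR = MSR, MSC = MSC, MSE = MSE, degenerate = FALSE)
}

#' Cohen's kappa for two categorical raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' `p_o = trace / n` and `p_e = sum_c row_c * col_c / n^2`. Accepts either a
#' pre-built c x c confusion table (rows = reference rater, columns = second
#' rater) or the two raw label vectors.
#'
#' @param x square confusion matrix of counts, or a label vector.
#' @param y second label vector when `x` is a vector.
#' @return List: `kappa`, `po`, `pe`, `n`, and `degenerate` (TRUE when both
#'   raters are constant and identical, where kappa is defined as 1).
#' @export
#' @examples
#' cohensKappa(matrix(c(20, 10, 5, 15), 2))
cohensKappa <- function(x, y = NULL) {
  if (is.null(y)) {
    tab <- as.matrix(x)
    if (nrow(tab) != ncol(tab))
      stop("confusion table must be square", call. = FALSE)
    if (any(tab < 0) || any(tab != round(tab)))
      stop("confusion table must hold non-negative integer counts",
           call. = FALSE)
  } else {
    if (length(x) != length(y))
      stop("label vectors must have equal length", call. = FALSE)
    lev <- union(unique(as.character(x)), unique(as.character(y)))
    lev <- c(intersect(srhClasses(), lev), setdiff(lev, srhClasses()))
    tab <- table(factor(as.character(x), levels = lev),
                 factor(as.character(y), levels = lev))
    tab <- unclass(tab)
  }
  n <- sum(tab)
  if (n == 0) stop("empty confusion table", call. = FALSE)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-15)
    return(list(kappa = 1, po = po, pe = pe, n = n, degenerate = TRUE))
  list(kappa = (po - pe) / (1 - pe), po = po, pe = pe, n = n,
       degenerate = FALSE)
}

#' Cronbach's alpha
#'
#' Internal consistency of k parallel measurements (here: the three random
#' scan areas A/B/C of one specimen, rated by the same model):
#' `alpha = k/(k-1) * (1 - sum_i var(item_i) / var(total))` with sample
#' variances (n-1 denominator).
#'
#' @param table n x k matrix (subjects x items).
#' @return List: `alpha`, `k`, `n`, `degenerate` (TRUE with zero total
#'   variance, where alpha is undefined and returned as NA).
#' @export
#' @examples
#' cronbachAlpha(cbind(c(1, 2, 3), c(1, 2, 3), c(2, 3, 4)))
cronbachAlpha <- function(table) {
  m <- asRatingsMatrix(table)
  k <- ncol(m)
  vt <- stats::var(rowSums(m))
  if (vt == 0)
    return(list(alpha = NA_real_, k = k, n = nrow(m), degenerate = TRUE))
  vi <- sum(apply(m, 2, stats::var))
  list(alpha = k / (k - 1) * (1 - vi / vt), k = k, n = nrow(m),
       degenerate = FALSE)
}

#' ROC-AUC with Hanley-McNeil confidence interval
#'
#' The area under the ROC curve computed by the Mann-Whitney pair-counting
#' identity (ties count 1/2, evaluated via midranks), with the Hanley-McNeil
#' standard error. The normal-approximation interval is deliberately not
#' truncated at 1 (matching the nonparametric convention of clinical
#' statistics packages, which can print limits above 1).
#'
#' @param scores continuous per-subject scores (e.g. a slide's aggregated
#'   class probability).
#' @param truth binary labels (logical, 0/1, or a factor with the positive
#'   class as its second level).
#' @param ci_level confidence level, default 0.99.
#' @return List: `auc`, `lower`, `upper`, `se`, `level`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' rocAuc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
rocAuc <- function(scores, truth, ci_level = 0.99) {
  if (is.factor(truth)) truth <- as.integer(truth) - 1L
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), !anyNA(scores), !anyNA(truth))
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L)
    stop("both truth classes must be present for ROC analysis",
         call. = FALSE)
  r <- rank(scores)                      # midranks handle ties as 1/2
  auc <- (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  list(auc = auc, lower = auc - z * se, upper = auc + z * se, se = se,
       level = ci_level, n_pos = n1, n_neg = n0)
}

#' Kendall's coefficient of concordance W
#'
#' Concordance of k raters' rankings of n subjects (used to test for
#' systematic differences between the retrained models' probability values).
#' Subjects are ranked within each rater (midranks for ties);
#' `W = 12 S / (k^2 (n^3 - n) - k sum_j T_j)` with the tie correction
#' `T_j = sum (t^3 - t)` over tie groups of rater j, and the chi-squared
#' approximation `chi2 = k (n - 1) W` on n - 1 degrees of freedom.
#'
#' @param table n x k matrix of ratings.
#' @return List: `W`, `chi2`, `df`, `p`, and `small_n` (TRUE when n < 3,
#'   where the chi-squared p-value is unreliable).
#' @export
#' @examples
#' kendallsW(cbind(c(1, 2, 3, 4), c(1, 2, 4, 3), c(2, 1, 3, 4)))
kendallsW <- function(table) {
  m <- asRatingsMatrix(table)
  n <- nrow(m); k <- ncol(m)
  ranks <- apply(m, 2, rank)
  Tj <- apply(m, 2, function(col) {
    t <- base::table(col)
    sum(t^3 - t)
  })
  R <- rowSums(ranks)
  S <- sum((R - mean(R))^2)
  denom <- k^2 * (n^3 - n) - k * sum(Tj)
  W <- if (denom <= 0) NA_real_ else 12 * S / denom
  chi2 <- k * (n - 1) * W
  p <- stats::pchisq(chi2, df = n - 1, lower.tail = FALSE)
  list(W = W, chi2 = chi2, df = n - 1, p = p, small_n = n < 3L)
}

#' Agreement report for several models against a reference rater
#'
#' Per-class correct counts and percentages, overall percent agreement and
#' Cohen's kappa for each model against the reference categorical labels
#' (the blinded rater's ground truth). Percentages are exact; a one-decimal
#' half-up rendering is included for display.
#'
#' @param predictions named list of per-slide class-label vectors, one per
#'   model.
#' @param reference character vector of reference labels, same length.
#' @param file optional CSV path for the per-class table.
#' @return List of class `srh_agreement`: `per_class` (data.frame),
#'   `overall` (data.frame with `model`, `correct`, `n`, `percent`,
#'   `kappa`).
#' @export
#' @examples
#' ref <- c("tumor", "tumor", "non_tumor")
#' agreementReport(list(cnn1 = c("tumor", "non_tumor", "non_tumor")), ref)
agreementReport <- function(predictions, reference, file = NULL) {
  stopifnot(is.list(predictions), length(predictions) >= 1L)
  if (is.null(names(predictions)))
    names(predictions) <- paste0("model", seq_along(predictions))
  n <- length(reference)
  per_class <- NULL
  overall <- NULL
  for (nm in names(predictions)) {
    pred <- predictions[[nm]]
    if (length(pred) != n)
      stop("prediction vector '", nm, "' length differs from the reference",
           call. = FALSE)
    correct_total <- 0L
    for (cls in srhClasses()) {
      in_class <- reference == cls
      n_class <- sum(in_class)
      n_correct <- sum(in_class & pred == reference)
      correct_total <- correct_total + n_correct
      pct <- if (n_class > 0) 100 * n_correct / n_class else NA_real_
      per_class <- rbind(per_class, data.frame(
        model = nm, class = cls, n = n_class, correct = n_correct,
        percent = pct, percent_1dp = roundHalfUp(pct, 1L)))
    }
    kp <- cohensKappa(reference, pred)
    overall <- rbind(overall, data.frame(
      model = nm, correct = correct_total, n = n,
      percent = 100 * correct_total / n,
      percent_1dp = roundHalfUp(100 * correct_total / n, 1L),
      kappa = kp$kappa))
  }
  out <- structure(list(per_class = per_class, overall = overall),
                   class = "srh_agreement")
  if (!is.null(file)) utils::write.csv(per_class, file, row.names = FALSE)
  out
}

#' @export
print.srh_agreement <- function(x, ...) {
  cat("Agreement vs reference rater\n")
  for (i in seq_len(nrow(x$overall))) {
    o <- x$overall[i, ]
    cat(sprintf("  %s: %d/%d (%.1f%%), kappa = %.3f\n", o$model, o$correct,
                o$n, o$percent_1dp, o$kappa))
    pc <- x$per_class[x$per_class$model == o$model, ]
    for (j in seq_len(nrow(pc)))
      cat(sprintf("    %-12s %3d/%3d (%s)\n", pc$class[j], pc$correct[j],
                  pc$n[j],
                  ifelse(is.na(pc$percent[j]), "-",
                         sprintf("%.1f%%", pc$percent_1dp[j]))))
  }
  invisible(x)
}

#' Read / write ratings tables
#'
#' Ratings CSVs have a `subject_id` column plus one column per rater.
#'
#' @param path CSV path.
#' @return Numeric matrix with subject ids as row names.
#' @export
readRatings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df))
    stop("ratings CSV needs a 'subject_id' column: ", path, call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  rownames(m) <- df$subject_id
  storage.mode(m) <- "double"
  m
}

#' @rdname readRatings
#' @param ratings matrix with row names as subject ids.
#' @export
writeRatings <- function(ratings, path) {
  df <- data.frame(subject_id = rownames(ratings) %||%
                     seq_len(nrow(ratings)), ratings)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
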