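#' Ratings matrix for reliability analysis
#'
#' Cases-by-raters table of one measured parameter. Missing entries are a
#' hard error: silently dropping cases changes the ICC.
#'
#' @param values numeric matrix, n_cases x k_raters (n >= 3, k >= 2, finite,
#'   no missing entries).
#' @param case_ids,rater_ids optional identifiers.
#' @param parameter,units parameter name and units (metadata).
#' @return An object of class `ratings_matrix`.
#' @export
ratings_matrix <- function(values, case_ids = NULL, rater_ids = NULL,
                           parameter = "parameter", units = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("incomplete ratings: missing entries are not allowed",
                          call. = FALSE)
  if (!all(is.finite(values))) stop("ratings must be finite", call. = FALSE)
  if (nrow(values) < 3) stop("n_cases must be >= 3", call. = FALSE)
  if (ncol(values) < 2) stop("k_raters must be >= 2", call. = FALSE)
  structure(list(values = values,
                 case_ids = case_ids %||% rownames(values) %||%
                   as.character(seq_len(nrow(values))),
                 rater_ids = rater_ids %||% colnames(values) %||%
                   paste0("rater", seq_len(ncol(values))),
                 parameter = parameter, units = units),
            class = "ratings_matrix")
}

#' @export
print.ratings_matrix <- function(x, ...) {
  cat(sprintf("ratings_matrix: %s [%s], %d cases x %d raters\n",
              x$parameter, x$units, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Interrater ICC (two-way random, absolute agreement, single measures)
#'
#' Computes ICC(A,1) from the two-way ANOVA mean squares of the ratings
#' table: with rows = cases (MSR), columns = raters (MSC) and residual (MSE),
#'
#'   ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))
#'
#' The 95% confidence interval uses the F-distribution method for this form
#' (Satterthwaite degrees of freedom for the rater term). A table with no
#' variance at all is perfect agreement by convention: ICC 1 with CI [1, 1]
#' and a warning.
#'
#' @param ratings a [ratings_matrix()].
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `icc_estimate`: `icc`, `ci_low`, `ci_high`,
#'   `model`, `category` (Landis-Koch label), `n`, `k` and the mean squares.
#' @export
icc_absolute_agreement <- function(ratings, conf_level = 0.95) {
  stopifnot(inherits(ratings, "ratings_matrix"))
  x <- ratings$values
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm - grand)^2) / (k - 1)
  mse <- sum((x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + grand)^2) /
    ((n - 1) * (k - 1))

  model <- "two-way random, absolute agreement, single measures"
  if (msr < 1e-300 && msc < 1e-300 && mse < 1e-300) {
    warning("zero-variance ratings table: ICC defined as 1", call. = FALSE)
    out <- structure(list(icc = 1, ci_low = 1, ci_high = 1, model = model,
                          category = landis_koch_category(1), n = n, k = k,
                          msr = msr, msc = msc, mse = mse),
                     class = "icc_estimate")
    return(out)
  }

  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf_level
  if (mse < 1e-300 && msc < 1e-300) {
    ci <- c(1, 1)
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    if (!is.finite(a) || !is.finite(b)) {
      ci <- c(1, 1)
    } else {
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      f_l <- stats::qf(1 - alpha / 2, n - 1, v)
      f_u <- stats::qf(1 - alpha / 2, v, n - 1)
      lower <- n * (msr - f_l * mse) /
        (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
      upper <- n * (f_u * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f_u * msr)
      ci <- c(lower, upper)
    }
  }
  ci <- pmin(pmax(ci, -1), 1)
  ci[1] <- min(ci[1], icc); ci[2] <- max(ci[2], icc)
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2], model = model,
                 category = landis_koch_category(max(min(icc, 1), -1)),
                 n = n, k = k, msr = msr, msc = msc, mse = mse),
            class = "icc_estimate")
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf("ICC = %.3f (95%% CI %.3f-%.3f), %s agreement\n",
              x$icc, x$ci_low, x$ci_high, x$category))
  cat(sprintf("  model: %s; n = %d cases, k = %d raters\n", x$model, x$n, x$k))
  invisible(x)
}

#' Landis-Koch agreement category
#'
#' Maps an agreement coefficient to the conventional qualitative bands:
#' <= 0.20 slight, 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80 substantial,
#' >= 0.81 almost perfect. The value is rounded to two decimals before
#' banding so boundary values behave as printed tables imply; negative
#' values map to slight.
#'
#' @param icc_value numeric in [-1, 1].
#' @return character label.
#' @export
landis_koch_category <- function(icc_value) {
  if (!is.finite(icc_value) || icc_value < -1 - 1e-9 || icc_value > 1 + 1e-9) {
    stop("icc value must lie in [-1, 1]", call. = FALSE)
  }
  v <- round(icc_value, 2)
  if (v <= 0.20) "slight"
  else if (v <= 0.40) "fair"
  else if (v <= 0.60) "moderate"
  else if (v <= 0.80) "substantial"
  else "almost perfect"
}

#' Average raters per case
#'
#' @param ratings a [ratings_matrix()].
#' @return numeric vector of per-case means, in case order.
#' @export
average_raters <- function(ratings) {
  stopifnot(inherits(ratings, "ratings_matrix"))
  stats::setNames(rowMeans(ratings$values), ratings$case_ids)
}

#' Distribution-gated paired comparison
#'
#' Tests paired differences for normality (Kolmogorov-Smirnov with Lilliefors
#' correction, since the distribution parameters are estimated from the
#' data), then applies the paired t-test when the differences look normal
#' (p >= 0.05) and the Wilcoxon signed-rank test otherwise (exact for
#' n <= 25, normal approximation with continuity correction above).
#'
#' @param values_a,values_b paired per-case values (equal length >= 5,
#'   finite).
#' @param alpha significance level (default 0.05).
#' @return An object of class `paired_comparison` with summary statistics of
#'   both arms, `normality_p`, `test_used`, `statistic`, `p_value`,
#'   `significant`.
#' @export
compare_paired <- function(values_a, values_b, alpha = 0.05) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) != length(b)) stop("paired samples must have equal length",
                                   call. = FALSE)
  if (length(a) < 5) stop("need at least 5 pairs", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("values must be finite", call. = FALSE)
  }
  d <- a - b
  n <- length(d)
  summ <- function(x) list(mean = mean(x), sd = stats::sd(x),
                           range = c(min(x), max(x)))

  if (all(d == 0)) {
    warning("all paired differences are zero; Wilcoxon undefined, p set to 1",
            call. = FALSE)
    return(structure(c(list(a = summ(a), b = summ(b), n = n,
                            mean_difference = 0,
                            normality_p = NA_real_, test_used = "Wilcoxon",
                            statistic = NA_real_, p_value = 1,
                            significant = FALSE, alpha = alpha)),
                     class = "paired_comparison"))
  }

  norm_p <- tryCatch(nortest::lillie.test(d)$p.value,
                     error = function(e) NA_real_)
  if (!is.na(norm_p) && norm_p >= 0.05) {
    tt <- stats::t.test(a, b, paired = TRUE)
    test_used <- "paired t"; statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, paired = TRUE, exact = n <= 25, correct = TRUE))
    test_used <- "Wilcoxon"; statistic <- unname(wt$statistic); p <- wt$p.value
  }
  structure(list(a = summ(a), b = summ(b), n = n,
                 mean_difference = mean(d),
                 normality_p = norm_p, test_used = test_used,
                 statistic = statistic, p_value = p,
                 significant = is.finite(p) && p < alpha, alpha = alpha),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  fmt <- function(s) sprintf("%.3g +/- %.3g (%.3g-%.3g)",
                             s$mean, s$sd, s$range[1], s$range[2])
  cat(sprintf("paired comparison (n = %d)\n  A: %s\n  B: %s\n",
              x$n, fmt(x$a), fmt(x$b)))
  cat(sprintf("  normality p = %s -> %s: statistic %.4g, p = %.4g%s\n",
              ifelse(is.na(x$normality_p), "NA",
                     sprintf("%.3f", x$normality_p)),
              x$test_used, x$statistic, x$p_value,
              ifelse(x$significant, " (significant)", "")))
  invisible(x)
}

#' Mean, SD and range summary
#'
#' @param values at least 2 finite values.
#' @return list with `mean`, `sd` (n-1 denominator), `min`, `max`.
#' @export
summarize_values <- function(values) {
  x <- as.numeric(values)
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least 2 finite values", call. = FALSE)
  list(mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x))
}

#' Read a long-format ratings CSV
#'
#' Expects columns `case_id`, `rater_id`, `parameter`, `value` and returns
#' one [ratings_matrix()] per parameter. Duplicate (case, rater, parameter)
#' rows and incomplete case-rater grids are errors.
#'
#' @param path CSV file path.
#' @return named list of [ratings_matrix()] objects.
#' @export
read_ratings_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "rater_id", "parameter", "value")
  if (!all(need %in% names(df))) {
    stop(sprintf("ratings CSV must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  key <- paste(df$case_id, df$rater_id, df$parameter, sep = "|")
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate rating rows (first at line %d)",
                 which(duplicated(key))[1] + 1L), call. = FALSE)
  }
  out <- list()
  for (p in unique(df$parameter)) {
    sub <- df[df$parameter == p, ]
    cases <- sort(unique(sub$case_id)); raters <- sort(unique(sub$rater_id))
    if (length(raters) < 2) stop("k_raters >= 2 required", call. = FALSE)
    m <- matrix(NA_real_, length(cases), length(raters),
                dimnames = list(cases, raters))
    m[cbind(match(sub$case_id, cases), match(sub$rater_id, raters))] <- sub$value
    if (anyNA(m)) stop(sprintf("incomplete ratings for parameter '%s'", p),
                       call. = FALSE)
    out[[p]] <- ratings_matrix(m, cases, raters, parameter = p)
  }
  out
}

#' Per-parameter reliability table
#'
#' @param ratings_list named list of [ratings_matrix()] (e.g. from
#'   [read_ratings_csv()]).
#' @param conf_level confidence level.
#' @return data.frame with one row per parameter: icc, ci bounds, category,
#'   n, k, model.
#' @export
reliability_table <- function(ratings_list, conf_level = 0.95) {
  rows <- lapply(ratings_list, function(rm_) {
    est <- icc_absolute_agreement(rm_, conf_level)
    data.frame(parameter = rm_$parameter, icc = est$icc,
               ci_low = est$ci_low, ci_high = est$ci_high,
               category = est$category, n = est$n, k = est$k,
               model = est$model, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
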