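#' Two-sided Fisher exact test for a 2 x 2 table
#'
#' Exact test of association in a 2 x 2 count table with both margins
#' fixed. The two-sided p value is the sum of hypergeometric probabilities
#' of all tables (with the observed margins) whose probability does not
#' exceed that of the observed table — the probability-mass summation
#' convention of standard statistical software. The odds ratio reported is
#' the sample odds ratio `a*d / (b*c)` (infinite when `b*c == 0` with
#' `a*d > 0`). A table with a zero margin carries no information about
#' association: p is 1 by convention and the result is flagged degenerate.
#'
#' @param table a 2 x 2 matrix of non-negative integer counts
#'   `rbind(c(a, b), c(c, d))`, rows = groups, columns = outcome yes/no.
#' @return A list with `p_value`, `odds_ratio`, `degenerate`.
#' @examples
#' fisher_exact_two_sided(rbind(c(32, 2), c(5, 8)))$p_value
#' @export
fisher_exact_two_sided <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L)) || any(m < 0) || any(m != round(m))) {
    stop("table must be a 2 x 2 matrix of non-negative integer counts")
  }
  a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
  n <- a + b + cc + d
  if (n < 1) stop("table total must be >= 1")
  r1 <- a + b; c1 <- a + cc
  odds <- if (a * d == 0 && b * cc == 0) NaN
  else if (b * cc == 0) Inf
  else a * d / (b * cc)
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    return(list(p_value = 1, odds_ratio = odds, degenerate = TRUE))
  }
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  # standard relative tolerance so ties in probability are included
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p_value = min(p, 1), odds_ratio = odds, degenerate = FALSE)
}

#' Two-sided Student's t-test
#'
#' Two-sample two-sided t-test from the closed form: equal-variance
#' (pooled) Student's t by default, Welch's unequal-variance t on request.
#' When both samples have zero variance, equal means give p = 1 and
#' unequal means are flagged degenerate (the difference is certain but the
#' statistic is undefined).
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param welch use the Welch unequal-variance form.
#' @return A list with `t`, `df`, `p_value`, `degenerate`.
#' @export
student_t_two_sided <- function(x, y, welch = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each sample needs at least 2 values")
  vx <- stats::var(x); vy <- stats::var(y)
  diff <- mean(x) - mean(y)
  if (vx == 0 && vy == 0) {
    if (diff == 0) {
      return(list(t = 0, df = nx + ny - 2, p_value = 1, degenerate = FALSE))
    }
    return(list(t = sign(diff) * Inf, df = nx + ny - 2, p_value = 0,
                degenerate = TRUE))
  }
  if (welch) {
    se2 <- vx / nx + vy / ny
    t_stat <- diff / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    t_stat <- diff / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  list(t = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df), degenerate = FALSE)
}

#' Build a qPCR Ct table
#'
#' Long-format container for qPCR Ct values: one row per technical
#' replicate, identified by sample, condition (`control` or `test`),
#' biological replicate, gene. The reference gene (default `eef1b2`) must
#' be measured for every sample.
#'
#' @param data a data frame with columns `sample_id`, `condition`,
#'   `biological_replicate`, `technical_replicate`, `gene`, `ct`.
#' @param reference_gene name of the reference gene.
#' @return An object of class `qpcr_table` (a validated data frame with
#'   the reference gene attached).
#' @export
qpcr_table <- function(data, reference_gene = "eef1b2") {
  need <- c("sample_id", "condition", "biological_replicate",
            "technical_replicate", "gene", "ct")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("qPCR table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!all(data$condition %in% c("control", "test"))) {
    stop("condition must be 'control' or 'test'")
  }
  if (any(data$ct <= 0) || anyNA(data$ct)) stop("Ct values must be positive")
  for (s in unique(data$sample_id)) {
    if (!reference_gene %in% data$gene[data$sample_id == s]) {
      stop("missing reference gene '", reference_gene, "' for sample '",
           s, "'")
    }
  }
  structure(as.data.frame(data), reference_gene = reference_gene,
            class = c("qpcr_table", "data.frame"))
}

#' qPCR fold changes by the 2^-ddCt method
#'
#' Relative quantification: technical replicates are averaged per
#' (biological replicate, gene); dCt is the gene's Ct minus the reference
#' gene's Ct per biological replicate; ddCt is each test replicate's dCt
#' minus the mean control dCt for the same gene; the fold change per test
#' replicate is `2^-ddCt`. Reported per gene with the per-replicate folds,
#' their mean and standard deviation.
#'
#' @param table a [qpcr_table()].
#' @return A list per gene (reference excluded), each with `per_replicate`
#'   (data frame `sample_id`, `ddct`, `fold`), `mean_fold`, `sd_fold`.
#' @export
ddct_fold_change <- function(table) {
  stopifnot(inherits(table, "qpcr_table"))
  ref <- attr(table, "reference_gene")
  # average technical replicates per biological sample and gene
  avg <- stats::aggregate(ct ~ sample_id + condition + biological_replicate +
                            gene, data = table, FUN = mean)
  ref_ct <- avg[avg$gene == ref, c("sample_id", "ct")]
  names(ref_ct)[2] <- "ref_ct"
  avg <- merge(avg, ref_ct, by = "sample_id")
  avg$dct <- avg$ct - avg$ref_ct
  genes <- setdiff(unique(avg$gene), ref)
  out <- list()
  for (g in genes) {
    sub <- avg[avg$gene == g, ]
    ctrl <- sub$dct[sub$condition == "control"]
    test <- sub[sub$condition == "test", ]
    if (!length(ctrl) || !nrow(test)) {
      stop("gene '", g, "' needs dCt values in both conditions")
    }
    ddct <- test$dct - mean(ctrl)
    fold <- 2^(-ddct)
    out[[g]] <- list(
      per_replicate = data.frame(sample_id = test$sample_id, ddct = ddct,
                                 fold = fold),
      mean_fold = mean(fold),
      sd_fold = if (length(fold) > 1L) stats::sd(fold) else NA_real_
    )
  }
  out
}

#' Summary statistics of a group of values
#'
#' Mean, standard deviation (n - 1 denominator), SEM (sd / sqrt(n)) and
#' the five-number summary with inclusive linear-interpolation quartiles
#' (R's default `quantile` type 7). A single value flags sd and SEM as
#' undefined (`NA`).
#'
#' @param values numeric vector, length >= 1.
#' @return A list with `n`, `mean`, `sd`, `sem`, `min`, `q1`, `median`,
#'   `q3`, `max`.
#' @export
group_summary <- function(values) {
  values <- as.numeric(values)
  if (!length(values) || anyNA(values)) {
    stop("values must be a non-empty numeric vector without NAs")
  }
  n <- length(values)
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  list(n = n, mean = mean(values),
       sd = if (n > 1L) stats::sd(values) else NA_real_,
       sem = if (n > 1L) stats::sd(values) / sqrt(n) else NA_real_,
       min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
}
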