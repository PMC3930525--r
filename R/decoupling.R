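# Inferential layer: Mann-Whitney comparison of Ka/Ks between horn-biased
# and background homologue pairs, and the developmental-decoupling general
# linear model regressing log(Ka/Ks) on expression covariates with per-term
# partial r-squared.

#' Mann-Whitney rank test
#'
#' Reports `W`, the first-sample U statistic: the number of `(x_i, y_j)`
#' pairs with `x_i > y_j`, ties counted one half (equivalently the rank sum
#' of `x` minus `n1 (n1 + 1) / 2`). The exact two-sided p-value is used when
#' there are no ties and `n1 * n2 <= 400` (via the exact Wilcoxon
#' distribution); otherwise a normal approximation with tie-corrected
#' variance and continuity correction. Swapping the samples maps
#' `u -> n1 * n2 - u`.
#'
#' @param x,y Non-empty numeric samples.
#' @return Object of class `rank_test`: list with `w`, `u` (both the
#'   first-sample U), `u2`, `n1`, `n2`, `p_two_sided`, `method`.
#' @export
#' @examples
#' mann_whitney(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
mann_whitney <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  ties <- any(duplicated(c(x, y)))
  mu <- n1 * n2 / 2
  if (!ties && n1 * n2 <= 400) {
    method <- "exact"
    p <- if (u1 > mu) {
      2 * (1 - stats::pwilcox(u1 - 1, n1, n2))
    } else if (u1 < mu) {
      2 * stats::pwilcox(u1, n1, n2)
    } else 1
  } else {
    method <- "normal-approximation"
    tab <- table(c(x, y))
    N <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tab^3 - tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u1 - mu - 0.5 * sign(u1 - mu)) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  structure(list(w = u1, u = u1, u2 = u2, n1 = n1, n2 = n2,
                 p_two_sided = min(p, 1), method = method),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney: W = %g, p = %.5g (%s; n1 = %d, n2 = %d)\n",
              x$w, x$p_two_sided, x$method, x$n1, x$n2))
  invisible(x)
}

group_stats <- function(ratios) {
  q <- stats::quantile(ratios, c(0.25, 0.5, 0.75), names = FALSE)
  list(n = length(ratios), mean = mean(ratios), sd = stats::sd(ratios),
       median = q[2], q1 = q[1], q3 = q[3],
       n_positive = sum(ratios > 1),
       frac_positive = mean(ratios > 1))
}

#' Compare Ka/Ks between horn-biased and background pairs
#'
#' Splits usable Ka/Ks estimates (finite ratio, i.e. status ok including
#' ratio 0) into the horn-biased stratum and the background, summarises each
#' group and tests the difference with [mann_whitney()] (horn-biased group
#' first).
#'
#' @param kaks_tbl Data frame from [kaks_table()] (columns `ratio` plus an
#'   identifier column).
#' @param horn_biased_ids Identifiers of the horn-biased stratum.
#' @param id_col Column of `kaks_tbl` matched against `horn_biased_ids`
#'   (default `"id_a"`, falling back to `"pair_id"`).
#' @return List with `horn`, `background` (each `n`, `mean`, `sd`, `median`,
#'   quartiles, `n_positive`, `frac_positive`) and `test` (a `rank_test`, or
#'   `NULL` when the horn-biased stratum is empty).
#' @export
stratified_kaks_compare <- function(kaks_tbl, horn_biased_ids,
                                    id_col = if ("id_a" %in% names(kaks_tbl)) "id_a" else "pair_id") {
  usable <- kaks_tbl[!is.na(kaks_tbl$ratio), , drop = FALSE]
  missing <- setdiff(horn_biased_ids, kaks_tbl[[id_col]])
  if (length(missing)) {
    warning("horn-biased id(s) absent from estimates, skipped: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  is_horn <- usable[[id_col]] %in% horn_biased_ids
  horn <- usable$ratio[is_horn]
  bg <- usable$ratio[!is_horn]
  list(horn = if (length(horn)) group_stats(horn) else NULL,
       background = if (length(bg)) group_stats(bg) else NULL,
       test = if (length(horn) && length(bg)) mann_whitney(horn, bg) else NULL)
}

DECOUPLING_TERMS <- c("overall_expression", "aln_length", "sequence_length",
                      "n_tissues", "sex_biased_expression",
                      "morph_biased_expression", "morph_x_sex")

#' Fit the developmental-decoupling general linear model
#'
#' Ordinary least squares of `log(Ka/Ks)` on overall expression, alignment
#' length, sequence length, number of tissues/arrays with expression,
#' sex-biased expression, morph-biased expression, and the morph x sex
#' interaction (the product of the two log-transformed bias covariates),
#' plus an intercept. Under the default `"methods"` transform profile the
#' ratio, sex bias, morph bias and overall expression are log-transformed;
#' the `"log_lengths"` profile additionally logs sequence length and alignment
#' length. Rows with a non-positive value under any log are excluded and
#' counted; ratio-zero rows are excluded by default or floored to half the
#' smallest positive ratio (`zero_ratio = "floor"`).
#'
#' @param records Data frame with columns `ratio`, `overall_expression`,
#'   `aln_length`, `sequence_length`, `n_tissues`, `sex_bias`, `morph_bias`.
#' @param transform_profile `"methods"` (default) or `"log_lengths"`.
#' @param zero_ratio `"exclude"` (default) or `"floor"`.
#' @return Object of class `decoupling_fit`: `terms` (data frame with
#'   `term`, `estimate`, `se`, `t_value`, `partial_r2`), `residual_df`
#'   (`n` minus 8), `adjusted_r2`, `n`, `transform_profile`, `n_excluded`
#'   (named counts), and the underlying `stats::lm` fit as `model`.
#' @export
fit_decoupling_glm <- function(records,
                               transform_profile = c("methods", "log_lengths"),
                               zero_ratio = c("exclude", "floor")) {
  transform_profile <- match.arg(transform_profile)
  zero_ratio <- match.arg(zero_ratio)
  req <- c("ratio", "overall_expression", "aln_length", "sequence_length",
           "n_tissues", "sex_bias", "morph_bias")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n_excluded <- c(ratio_missing = 0L, ratio_zero = 0L, nonpositive_covariate = 0L)
  d <- records
  drop_na <- is.na(d$ratio)
  n_excluded[["ratio_missing"]] <- sum(drop_na)
  d <- d[!drop_na, , drop = FALSE]
  if (zero_ratio == "floor" && any(d$ratio == 0)) {
    pos <- d$ratio[d$ratio > 0]
    if (!length(pos)) stop("no positive Ka/Ks ratios to floor against", call. = FALSE)
    d$ratio[d$ratio == 0] <- min(pos) / 2
  }
  drop_zero <- d$ratio <= 0
  n_excluded[["ratio_zero"]] <- sum(drop_zero)
  d <- d[!drop_zero, , drop = FALSE]
  logged <- c("overall_expression", "sex_bias", "morph_bias")
  if (transform_profile == "log_lengths") {
    logged <- c(logged, "sequence_length", "aln_length")
  }
  bad <- rep(FALSE, nrow(d))
  for (cl in logged) bad <- bad | d[[cl]] <= 0
  n_excluded[["nonpositive_covariate"]] <- sum(bad)
  d <- d[!bad, , drop = FALSE]
  n <- nrow(d)
  n_terms <- length(DECOUPLING_TERMS) + 1L
  if (n < n_terms + 10L) {
    stop("need at least ", n_terms + 10L, " usable observations, have ", n,
         call. = FALSE)
  }
  log_sex <- log(d$sex_bias)
  log_morph <- log(d$morph_bias)
  X <- data.frame(
    y = log(d$ratio),
    overall_expression = log(d$overall_expression),
    aln_length = if ("aln_length" %in% logged) log(d$aln_length) else d$aln_length,
    sequence_length = if ("sequence_length" %in% logged) log(d$sequence_length) else d$sequence_length,
    n_tissues = d$n_tissues,
    sex_biased_expression = log_sex,
    morph_biased_expression = log_morph,
    morph_x_sex = log_morph * log_sex)
  fit <- stats::lm(y ~ ., data = X)
  if (anyNA(stats::coef(fit))) {
    stop("singular fit; collinear term(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients[DECOUPLING_TERMS, , drop = FALSE]
  df_res <- fit$df.residual
  terms <- data.frame(term = DECOUPLING_TERMS,
                      estimate = ct[, "Estimate"],
                      se = ct[, "Std. Error"],
                      t_value = ct[, "t value"],
                      partial_r2 = ct[, "t value"]^2 / (ct[, "t value"]^2 + df_res),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(terms = terms, residual_df = df_res,
                 adjusted_r2 = sm$adj.r.squared, n = n,
                 transform_profile = transform_profile,
                 n_excluded = n_excluded, model = fit, data = X),
            class = "decoupling_fit")
}

#' @export
print.decoupling_fit <- function(x, ...) {
  cat(sprintf("Decoupling GLM (%s profile): n = %d, residual df = %d, adjusted r2 = %.4g\n",
              x$transform_profile, x$n, x$residual_df, x$adjusted_r2))
  print(x$terms, digits = 4)
  invisible(x)
}

#' Partial r-squared of a model term
#'
#' `t^2 / (t^2 + residual_df)`: the share of residual variation explained by
#' the term, identical to the drop-one-term sum-of-squares comparison
#' `(SSE_reduced - SSE_full) / SSE_reduced`.
#'
#' @param fit A `decoupling_fit`.
#' @param term A term name from `fit$terms$term` (the intercept is not a
#'   term).
#' @return Value in `[0, 1)`.
#' @export
partial_r2 <- function(fit, term) {
  if (term %in% c("(Intercept)", "intercept")) {
    stop("partial r-squared is not defined for the intercept", call. = FALSE)
  }
  i <- match(term, fit$terms$term)
  if (is.na(i)) stop("unknown term: ", term, call. = FALSE)
  fit$terms$partial_r2[i]
}
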