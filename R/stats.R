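#' Symmetric percentage distance
#'
#' `SPD = 200 (v1 - v2) / (|v1| + |v2|)`: a signed, dimensionless,
#' bounded (\[-200, 200\]) measure of change between two values.
#' Antisymmetric in its arguments; defined as 0 when both are zero.
#' In the covariate analyses `v1` is the changed condition and `v2` the
#' reference.
#'
#' @param v1,v2 Numeric vectors (recycled).
#' @return Numeric vector of SPD values (percent).
#' @examples
#' spd(3, 1)   # 100
#' spd(2, 1)   # 66.67: a two-fold change
#' @export
spd <- function(v1, v2) {
  den <- abs(v1) + abs(v2)
  ifelse(den == 0, 0, 200 * (v1 - v2) / den)
}

#' Trimmed mean excluding 2.5% of outliers on both extremes
#'
#' Removes `floor(0.025 n)` values from each tail before averaging, so
#' samples with fewer than 40 values are not trimmed at all.
#'
#' @param values Numeric vector.
#' @return Scalar mean of the retained values.
#' @export
trimmed_mean <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no values to average", call. = FALSE)
  k <- floor(0.025 * length(values))
  if (k > 0) {
    s <- sort(values)
    values <- s[(k + 1):(length(s) - k)]
  }
  mean(values)
}

#' Compare two groups with Wilcoxon's test, reported in SPD units
#'
#' Runs the paired signed-rank or unpaired rank-sum test with the
#' Hodges-Lehmann location estimate and 95% confidence interval, then
#' converts estimate and CI to symmetric-percentage-distance units by
#' multiplying with `200 / (median(a) + median(b))`. P-values across a
#' family of comparisons are FDR-adjusted with [fdr_adjust()].
#'
#' @param a,b Numeric vectors; in the marker convention `a` is the
#'   expressing (+) group and `b` the non-expressing (-) group.
#' @param paired Paired test (requires equal lengths).
#' @return One-row tibble of class data: `estimate_spd`, `conf_low_spd`,
#'   `conf_high_spd`, `estimate_raw`, `p_value`, `p_adjusted` (equal to
#'   `p_value` until family adjustment), `paired`, `n_a`, `n_b`.
#' @export
group_compare <- function(a, b, paired = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (paired && length(a) != length(b)) {
    stop("paired comparison needs equal-length groups", call. = FALSE)
  }
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, paired = paired, conf.int = TRUE,
                       conf.level = 0.95, exact = FALSE))
  conv <- 200 / (stats::median(a) + stats::median(b))
  tibble::tibble(
    estimate_raw = unname(wt$estimate),
    estimate_spd = unname(wt$estimate) * conv,
    conf_low_spd = wt$conf.int[1] * conv,
    conf_high_spd = wt$conf.int[2] * conv,
    p_value = wt$p.value,
    p_adjusted = wt$p.value,
    paired = paired, n_a = length(a), n_b = length(b)
  )
}

#' Benjamini-Hochberg adjustment across a family of comparisons
#'
#' @param comparisons Tibble with a `p_value` column (e.g. rows from
#'   [group_compare()]).
#' @return The tibble with `p_adjusted` recomputed across the family.
#' @export
fdr_adjust <- function(comparisons) {
  comparisons$p_adjusted <- stats::p.adjust(comparisons$p_value, method = "BH")
  comparisons
}

#' Coefficient-of-variation analysis across groupings
#'
#' For each presynaptic (or postsynaptic) neuron type, measures the
#' coefficient of variation of each parameter across that type's
#' potential connections, applying the small-sample correction
#' `(1 + 1/(4n))`, with a seeded percentile-bootstrap 95% CI. The
#' presynaptic and postsynaptic CV distributions can then be compared
#' with an unpaired Wilcoxon test.
#'
#' @param table Tibble with `pre`, `post` and parameter columns.
#' @param grouping `"presynaptic"` or `"postsynaptic"`.
#' @param parameters Parameter column names; defaults to the five TPM
#'   parameters present in the table.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @return Tibble: `group`, `parameter`, `cv`, `conf_low`, `conf_high`,
#'   `n`; groups of size 1 are omitted.
#' @export
grouping_cv <- function(table, grouping = c("presynaptic", "postsynaptic"),
                        parameters = NULL, n_boot = 2000, seed = 1L) {
  grouping <- match.arg(grouping)
  key <- if (grouping == "presynaptic") "pre" else "post"
  if (is.null(parameters)) {
    parameters <- intersect(c("g", "tau_d", "tau_r", "tau_f", "U"),
                            names(table))
  }
  set.seed(seed)
  cv1 <- function(x) {
    n <- length(x)
    (stats::sd(x) / mean(x)) * (1 + 1 / (4 * n))
  }
  out <- list()
  for (grp in unique(table[[key]])) {
    rows <- table[table[[key]] == grp, ]
    if (nrow(rows) < 2) next
    for (p in parameters) {
      x <- rows[[p]]
      boots <- vapply(seq_len(n_boot), function(i) {
        cv1(sample(x, length(x), replace = TRUE))
      }, numeric(1))
      ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
      out[[length(out) + 1L]] <- tibble::tibble(
        group = grp, parameter = p, cv = cv1(x),
        conf_low = min(ci[1], cv1(x)), conf_high = max(ci[2], cv1(x)),
        n = nrow(rows))
    }
  }
  dplyr::bind_rows(out)
}

#' Compare presynaptic vs postsynaptic CV distributions
#'
#' @param table Tibble with `pre`, `post` and parameter columns.
#' @param ... Passed to [grouping_cv()].
#' @return List with `pre`, `post` (CV tibbles) and `comparison`
#'   (unpaired Wilcoxon in SPD units).
#' @export
grouping_cv_compare <- function(table, ...) {
  pre <- grouping_cv(table, "presynaptic", ...)
  post <- grouping_cv(table, "postsynaptic", ...)
  list(pre = pre, post = post,
       comparison = group_compare(pre$cv, post$cv, paired = FALSE))
}

#' Covariate perturbation effect on normalized predictions
#'
#' Predicts every connection's parameters at the reference condition and
#' with one covariate flipped, computes the per-connection SPD (change vs
#' reference) per parameter, summarises with the trimmed mean, tests the
#' shift with a paired Wilcoxon test per parameter, and labels effect
#' sizes (`|SPD| > 20` strong, `> 10` moderate, else negligible).
#'
#' @param ensemble A [train_ensemble()] object.
#' @param covariate One of `"species"`, `"sex"`, `"age"`,
#'   `"temperature"`, `"modality"`, or any condition column.
#' @param connections Tibble with `pre` and `post` columns.
#' @param reference One-row reference condition; default
#'   [standard_condition()].
#' @param changed_value Value of the flipped covariate; defaults to the
#'   standard flip (rat->mouse, male->female, 56->14, 32->22,
#'   voltage->current clamp).
#' @return List of class `covariate_effect`: `per_connection` (tibble of
#'   SPDs), `summary` (trimmed-mean SPD, paired Wilcoxon p, FDR-adjusted
#'   across the five parameters, effect label).
#' @export
covariate_effect <- function(ensemble, covariate, connections,
                             reference = standard_condition(),
                             changed_value = NULL) {
  flips <- list(species = "mouse", sex = "female", age = 14,
                temperature = 22, modality = "current_clamp")
  changed <- reference
  if (covariate == "modality") {
    changed$v_m <- if (is.null(changed_value)) -65 else changed_value
  } else {
    if (!covariate %in% names(reference)) {
      stop("covariate '", covariate, "' is not in the condition schema",
           call. = FALSE)
    }
    changed[[covariate]] <- changed_value %||% flips[[covariate]]
    if (is.null(changed[[covariate]])) {
      stop("no default flip for covariate '", covariate, "'", call. = FALSE)
    }
  }
  per <- purrr::pmap_dfr(connections[, c("pre", "post")], function(pre, post) {
    ref <- predict_normalized(ensemble, pre, post, reference)
    chg <- predict_normalized(ensemble, pre, post, changed)
    tibble::tibble(pre = pre, post = post, parameter = ref$parameter,
                   reference = ref$mean, changed = chg$mean,
                   spd = spd(chg$mean, ref$mean))
  })
  summ <- per |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      spd_trimmed_mean = trimmed_mean(.data$spd),
      p_value = suppressWarnings(
        stats::wilcox.test(.data$changed, .data$reference,
                           paired = TRUE, exact = FALSE)$p.value),
      .groups = "drop") |>
    dplyr::mutate(
      p_adjusted = stats::p.adjust(.data$p_value, method = "BH"),
      effect = dplyr::case_when(
        abs(.data$spd_trimmed_mean) > 20 ~ "strong",
        abs(.data$spd_trimmed_mean) > 10 ~ "moderate",
        TRUE ~ "negligible"))
  structure(list(per_connection = per, summary = summ, covariate = covariate),
            class = "covariate_effect")
}

#' @export
print.covariate_effect <- function(x, ...) {
  cat("<covariate_effect>", x$covariate, "\n")
  print(x$summary)
  invisible(x)
}

#' Pearson correlations between synaptic parameters
#'
#' @param table Tibble of per-connection parameters (and derived
#'   synaptometrics such as `ab3_a1` if present).
#' @param pairs List of 2-element character vectors naming the column
#'   pairs to correlate, e.g. `list(c("g", "tau_d"), c("g", "U"))`.
#' @return Tibble: `var1`, `var2`, `r`, `p_value`, `n`; zero-variance
#'   pairs are reported with `NA`.
#' @export
param_correlations <- function(table, pairs) {
  if (nrow(table) < 3) stop("need at least 3 rows", call. = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    x <- table[[pr[1]]]; y <- table[[pr[2]]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble::tibble(var1 = pr[1], var2 = pr[2], r = NA_real_,
                            p_value = NA_real_, n = length(x)))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    tibble::tibble(var1 = pr[1], var2 = pr[2], r = unname(ct$estimate),
                   p_value = ct$p.value, n = length(x))
  })
}
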