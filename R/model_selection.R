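## AIC from residuals, Akaike weights and cross-pathway comparison.

#' Akaike information criterion from residuals
#'
#' Assuming normally distributed errors, `AIC = n * log(rss / n) + 2k` where
#' `rss` is the residual sum of squares over `n` fitted values and `k` the
#' number of optimised parameters.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of data points.
#' @param k Number of optimised parameters.
#' @return AIC value.
#' @export
aic <- function(rss, n, k) {
  if (!is.numeric(rss) || rss <= 0) {
    stop("rss must be > 0 (a perfect fit has no finite log-likelihood scale)")
  }
  if (n < 1) stop("n must be >= 1")
  if (k < 0) stop("k must be >= 0")
  n * log(rss / n) + 2 * k
}

#' Akaike weights
#'
#' `delta_i = AIC_i - min(AIC)`; `w_i = exp(-delta_i / 2) / sum_j
#' exp(-delta_j / 2)`. Weights are the normalised relative likelihoods of the
#' compared models and are invariant to adding a constant to every AIC.
#'
#' @param aics Numeric vector of (possibly normalised) AIC values.
#' @return Numeric vector of weights summing to 1.
#' @examples
#' # normalised total AICs of the eight candidate pathways
#' akaike_weights(c(0, 40.9, 3.43, 31.2, 16.5, 36.1, 11.7, 28.4))
#' @export
akaike_weights <- function(aics) {
  if (length(aics) < 1L) stop("need at least one AIC value")
  if (any(!is.finite(aics))) stop("AIC values must be finite")
  delta <- aics - min(aics)
  rel <- exp(-delta / 2)
  rel / sum(rel)
}

#' Compare fitted pathways by AIC
#'
#' Pools each fit's per-series residuals into a total AIC (`aic(sum rss,
#' sum n, k)`), normalises against a reference model (by convention the first,
#' pathway I) and against the minimum, computes Akaike weights, and builds the
#' per-series AIC matrix together with its column-normalised form (each column
#' shifted so its minimum is 0) for heat-map display.
#'
#' @param fits Named list of `"fit_result"` objects evaluated against the same
#'   data (names are model ids).
#' @param reference Model id used for the reported `delta_aic_ref` column;
#'   defaults to the first fit.
#' @return An object of class `"comparison_table"` with elements `table`
#'   (model, mechanisms, total/delta AIC, weight), `per_series_aic` and
#'   `per_series_normalized` matrices.
#' @export
compare_pathways <- function(fits, reference = NULL) {
  stopifnot(length(fits) >= 1L)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  if (is.null(reference)) reference <- names(fits)[1L]

  series_key <- function(f) paste(f$per_series$experiment,
                                  f$per_series$species, sep = "/")
  keys <- lapply(fits, series_key)
  npts <- vapply(fits, function(f) f$n_points, numeric(1))
  if (length(unique(vapply(keys, paste, character(1), collapse = "|"))) != 1L ||
      length(unique(npts)) != 1L) {
    stop("all fits must be evaluated against the same data series")
  }

  total_aic <- vapply(fits, function(f) {
    aic(sum(f$per_series$rss), sum(f$per_series$n), f$k_params)
  }, numeric(1))
  delta_ref <- total_aic - total_aic[[reference]]
  delta_min <- total_aic - min(total_aic)
  weights <- akaike_weights(total_aic)

  per_series <- do.call(rbind, lapply(names(fits), function(id) {
    f <- fits[[id]]
    vapply(seq_len(nrow(f$per_series)), function(i) {
      aic(f$per_series$rss[i], f$per_series$n[i], f$k_params)
    }, numeric(1))
  }))
  rownames(per_series) <- names(fits)
  colnames(per_series) <- keys[[1L]]
  normalized <- sweep(per_series, 2L, apply(per_series, 2L, min), "-")

  tab <- data.frame(
    model = names(fits),
    co2 = vapply(fits, function(f) f$variant$co2_mech, character(1)),
    post = vapply(fits, function(f) f$variant$post_mech, character(1)),
    elongation = vapply(fits, function(f) f$variant$elongation_mech,
                        character(1)),
    k_params = vapply(fits, function(f) f$k_params, numeric(1)),
    total_aic = total_aic,
    delta_aic_ref = delta_ref,
    delta_aic_min = delta_min,
    weight = weights,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(table = tab, per_series_aic = per_series,
                 per_series_normalized = normalized,
                 reference = reference),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("Pathway comparison (reference:", x$reference, ")\n")
  tab <- x$table
  tab$total_aic <- signif(tab$total_aic, 5)
  tab$delta_aic_ref <- signif(tab$delta_aic_ref, 4)
  tab$weight <- signif(tab$weight, 3)
  print(tab[, c("model", "co2", "post", "elongation", "delta_aic_ref",
                "weight")], row.names = FALSE)
  invisible(x)
}
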