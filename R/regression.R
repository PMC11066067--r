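#' Fit a gene abundance vs phosphate regression
#'
#' Ordinary least squares of (optionally log-transformed) per-sample gene
#' abundance on raw phosphate concentration.  The `"linear"` form fits
#' `abundance ~ phosphate`; the `"log-linear"` form — the working
#' interpretation of an exponential regression — fits
#' `log(abundance + pseudocount) ~ phosphate`, with the pseudocount defaulting
#' to half the smallest non-zero abundance in the table.  The slope's
#' two-sided t-test p-value and residual degrees of freedom (`n - 2`) are
#' reported; samples with missing phosphate or abundance are dropped with a
#' recorded count.
#'
#' @param table An abundance tibble: columns `phosphate_uM` and one column per
#'   gene (see [simulate_abundance()], [read_abundance_table()]).
#' @param gene Name of the gene column to fit.
#' @param form `"linear"` or `"log-linear"`.
#' @param pseudocount Pseudocount for the log form (default: half the
#'   smallest non-zero abundance).
#' @return An `abundance_fit` object; see [tidy.abundance_fit()] and
#'   [glance.abundance_fit()] for tabular views.
#' @examples
#' tb <- tibble::tibble(phosphate_uM = 0:9, g = 2 - 0.1 * (0:9))
#' fit <- fit_abundance_model(tb, "g", "linear")
#' glance(fit)
#' @export
fit_abundance_model <- function(table, gene, form = c("linear", "log-linear"),
                                pseudocount = NULL) {
  form <- match.arg(form)
  if (!gene %in% names(table)) abort(sprintf("No column '%s' in the table.", gene))
  if (!"phosphate_uM" %in% names(table)) abort("The table needs a 'phosphate_uM' column.")
  x <- table$phosphate_uM
  y <- table[[gene]]
  keep <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("At least 3 samples with finite values are required.")
  if (any(x < 0)) abort("Phosphate concentrations must be non-negative.")
  if (stats::var(x) == 0) abort("Phosphate concentration has zero variance; no slope is identifiable.")
  if (form == "log-linear") {
    if (all(y == 0)) {
      abort("All abundances are zero; the log-linear form needs a positive pseudocount and non-degenerate data.")
    }
    pseudocount <- pseudocount %||% (min(y[y > 0]) / 2)
    yt <- log(y + pseudocount)
  } else {
    pseudocount <- 0
    yt <- y
  }
  fit <- stats::lm(yt ~ x)
  cf <- suppressWarnings(summary(fit))$coefficients
  pval <- if (nrow(cf) >= 2) cf[2, 4] else NA_real_
  # a perfectly constant response has slope 0 and no evidence against it
  if (is.nan(pval) || (stats::var(yt) == 0)) pval <- 1
  structure(list(
    gene = gene, form = form,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    p_value = pval,
    df = fit$df.residual,
    n = length(x),
    n_dropped = n_dropped,
    pseudocount = pseudocount,
    lm = fit
  ), class = "abundance_fit")
}

#' @export
print.abundance_fit <- function(x, ...) {
  cat(sprintf("<abundance_fit> %s (%s): slope %.4g, intercept %.4g, p = %.3g, df = %d (n = %d)\n",
              x$gene, x$form, x$slope, x$intercept, x$p_value, x$df, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy views of an abundance fit
#'
#' `tidy()` returns one row per coefficient (term, estimate, std.error,
#' statistic, p.value); `glance()` returns the one-row model summary
#' (`gene`, `form`, `slope`, `intercept`, `p_value`, `df`, `n`).
#'
#' @param x An `abundance_fit`.
#' @param ... Unused.
#' @export
tidy.abundance_fit <- function(x, ...) {
  cf <- suppressWarnings(summary(x$lm))$coefficients
  tibble(
    term = c("intercept", "phosphate_uM")[seq_len(nrow(cf))],
    estimate = unname(cf[, 1]),
    std.error = unname(cf[, 2]),
    statistic = unname(cf[, 3]),
    p.value = unname(cf[, 4])
  )
}

#' @rdname tidy.abundance_fit
#' @export
glance.abundance_fit <- function(x, ...) {
  tibble(
    gene = x$gene, form = x$form, slope = x$slope, intercept = x$intercept,
    p_value = x$p_value, df = x$df, n = x$n
  )
}

#' Predict abundance at a phosphate concentration
#'
#' Inverts the fitted model: `intercept + slope * x` for the linear form,
#' `exp(intercept + slope * x) - pseudocount` for the log-linear form;
#' predictions are floored at zero (an abundance cannot be negative).  Used
#' for extrapolation to hypothetical phosphate levels.
#'
#' @param fit An `abundance_fit`.
#' @param phosphate Concentration(s) in micromolar (>= 0).
#' @return Predicted abundance(s).
#' @export
predict_abundance <- function(fit, phosphate) {
  stopifnot(inherits(fit, "abundance_fit"))
  if (any(phosphate < 0)) abort("Phosphate concentrations must be non-negative.")
  raw <- if (fit$form == "linear") {
    fit$intercept + fit$slope * phosphate
  } else {
    exp(fit$intercept + fit$slope * phosphate) - fit$pseudocount
  }
  pmax(raw, 0)
}

#' Median abundance drop across a phosphate threshold
#'
#' Ratio of the median abundance in samples below the threshold to the median
#' in samples at or above it — the "drop-off factor" used to characterise
#' genes concentrated in phosphate-poor waters (e.g. the factor 4-5 drop of
#' CP-lyase genes above 0.1 uM).
#'
#' @param table An abundance tibble (as in [fit_abundance_model()]).
#' @param gene Gene column name.
#' @param threshold Phosphate threshold in micromolar.
#' @return The ratio (possibly `Inf` with a warning when the upper-side
#'   median is zero).
#' @export
threshold_ratio <- function(table, gene, threshold = 0.1) {
  x <- table$phosphate_uM
  y <- table[[gene]]
  if (is.null(y)) abort(sprintf("No column '%s' in the table.", gene))
  below <- y[x < threshold]
  above <- y[x >= threshold]
  if (length(below) == 0 || length(above) == 0) {
    abort("Both sides of the threshold must contain samples.")
  }
  denom <- stats::median(above)
  if (denom == 0) {
    warn("Median abundance above the threshold is zero; ratio is infinite.")
    return(Inf)
  }
  stats::median(below) / denom
}

#' Read/write abundance tables
#'
#' TSV with header: `sample`, `phosphate_uM`, one column per gene.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_abundance_table <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"phosphate_uM" %in% names(tb)) {
    abort("An abundance table needs a 'phosphate_uM' column.")
  }
  gene_cols <- setdiff(names(tb), c("sample", "phosphate_uM"))
  neg <- gene_cols[vapply(gene_cols, function(g) any(tb[[g]] < 0, na.rm = TRUE), TRUE)]
  if (any(tb$phosphate_uM < 0, na.rm = TRUE) || length(neg)) {
    abort("Abundance tables must not contain negative values.")
  }
  tb
}

#' @rdname read_abundance_table
#' @param table An abundance tibble.
#' @export
write_abundance_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' Fit all genes of an abundance table
#'
#' Convenience wrapper mapping [fit_abundance_model()] over every gene column
#' and binding the [glance()] rows.
#'
#' @inheritParams fit_abundance_model
#' @return A tibble, one row per gene.
#' @export
fit_all_genes <- function(table, form = c("linear", "log-linear"),
                          pseudocount = NULL) {
  form <- match.arg(form)
  genes <- setdiff(names(table), c("sample", "phosphate_uM"))
  purrr::map_dfr(genes, function(g) {
    glance(fit_abundance_model(table, g, form, pseudocount))
  })
}
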