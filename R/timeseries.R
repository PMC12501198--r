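# Data-frame-first entry points: decomposition straight from time series,
# batch pairwise decomposition of multivariate recordings, the
# storage-transfer overlap analysis, file I/O and the AR noise-correlation
# sweep.

#' Decompose a bivariate time series (or system) in one call
#'
#' Estimates a two-part model from the data and computes its integrated
#' information decomposition. Real-valued series are modelled as jointly
#' Gaussian from the lagged sample covariance; integer-valued series by the
#' plug-in empirical pmf. A ready-made [discrete_system()] or
#' [gaussian_system()] may also be passed directly.
#'
#' @param data A data frame or matrix with two numeric columns (rows = time
#'   points), or a system object.
#' @param lag Time delay between past and future (default 1).
#' @param model `"auto"` (Gaussian for real-valued data, discrete for
#'   integer-valued), `"gaussian"` or `"discrete"`.
#' @param redundancy Double-redundancy backend, `"mmi"` or `"ccs"`.
#' @return A `phiid` object; see [phiid_decompose()].
#' @examples
#' x <- simulate_ar(matrix(0.4, 2, 2), diag(2), 2000, seed = 1)
#' glance(phiid(x))
#' @export
phiid <- function(data, lag = 1, model = c("auto", "gaussian", "discrete"),
                  redundancy = c("mmi", "ccs")) {
  model <- match.arg(model)
  redundancy <- match.arg(redundancy)
  if (is_phiid_system(data)) {
    return(phiid_decompose(data, redundancy))
  }
  m <- as.matrix(data)
  if (model == "auto") {
    model <- if (all(m == round(m)) && all(m >= 0)) "discrete" else "gaussian"
  }
  system <- if (model == "discrete") {
    estimate_discrete(m, lag, paired = isTRUE(attr(data, "paired")))
  } else {
    estimate_gaussian(m, lag)
  }
  phiid_decompose(system, redundancy)
}

#' Read a multivariate time series from CSV
#'
#' Rows are time points and columns are variables; a header line is detected
#' automatically and column names are generated (`V1`, `V2`, ...) when it is
#' absent. Ragged rows and non-numeric or missing values are errors naming
#' the offending line.
#'
#' @param path Path to a CSV file.
#' @return A tibble of numeric columns.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(nf) == 0) stop("Empty file: ", path, call. = FALSE)
  bad <- which(nf != nf[1])
  if (length(bad) > 0) {
    stop("Ragged CSV: line ", bad[1], " has ", nf[bad[1]],
         " fields, expected ", nf[1], ".", call. = FALSE)
  }
  first <- strsplit(readLines(path, n = 1), ",")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  d <- if (has_header) {
    utils::read.csv(path, header = TRUE)
  } else {
    utils::read.csv(path, header = FALSE,
                    col.names = paste0("V", seq_along(first)))
  }
  for (j in seq_along(d)) {
    v <- suppressWarnings(as.numeric(d[[j]]))
    if (any(is.na(v))) {
      stop("Non-numeric or missing value in column ", names(d)[j],
           ", line ", which(is.na(v))[1] + has_header, ".", call. = FALSE)
    }
    d[[j]] <- v
  }
  tibble::as_tibble(d)
}

#' Write a decomposition or analysis result to disk
#'
#' `phiid` fits are flattened with [measure_report()]; data frames are
#' written as-is. JSON output round-trips through [read_report()].
#'
#' @param result A `phiid` object, a report list, or a data frame.
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (inherits(result, "phiid")) result <- measure_report(result)
  if (format == "json") {
    jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    d <- if (is.data.frame(result)) {
      result
    } else {
      flat <- utils::modifyList(result, list(atoms = NULL))
      out <- data.frame(key = names(flat), value = unlist(flat),
                        row.names = NULL)
      if (!is.null(result$atoms)) {
        out <- rbind(out, data.frame(key = paste0("atom:",
                                                  names(result$atoms)),
                                     value = unlist(result$atoms)))
      }
      out
    }
    utils::write.csv(d, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path Path to a JSON report.
#' @return A named list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Pairwise decomposition of a multivariate time series
#'
#' Estimates a two-part system for every unordered pair of variables and
#' decomposes it, reporting one row per ordered pair: the transfer entropy,
#' the source's active information storage, and the duplication atom
#' (`un -> red` with the source as part 1) that both measures share.
#' Degenerate columns (for example constant ones) cause their pairs to be
#' skipped with a warning rather than an error.
#'
#' @param data Data frame or matrix, rows = time points, `V >= 2` columns.
#' @param lag Time delay between past and future.
#' @param redundancy Double-redundancy backend.
#' @param model As in [phiid()].
#' @return A tibble of class `phiid_pairwise` with columns `source`,
#'   `target`, `te`, `ais_source`, `un_to_red` and a list-column `fit` of
#'   `phiid` objects (one per unordered pair, shared by its two rows).
#' @export
pairwise_decompose <- function(data, lag = 1, redundancy = c("mmi", "ccs"),
                               model = c("auto", "gaussian", "discrete")) {
  redundancy <- match.arg(redundancy)
  model <- match.arg(model)
  m <- as.matrix(data)
  if (ncol(m) < 2) stop("Need at least two variables.", call. = FALSE)
  nm <- colnames(m)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(m)))
  paired <- isTRUE(attr(data, "paired"))
  rows <- list()
  for (i in seq_len(ncol(m) - 1)) {
    for (j in (i + 1):ncol(m)) {
      sub <- m[, c(i, j)]
      attr(sub, "paired") <- paired
      fit <- tryCatch(
        phiid(sub, lag = lag, model = model, redundancy = redundancy),
        error = function(e) {
          warning("Skipping pair (", nm[i], ", ", nm[j], "): ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (is.null(fit)) next
      ms <- fit$measures
      rows[[length(rows) + 1]] <- tibble::tibble(
        source = c(nm[i], nm[j]), target = c(nm[j], nm[i]),
        te = c(ms$te_1to2, ms$te_2to1),
        ais_source = c(ms$ais_1, ms$ais_2),
        un_to_red = unname(c(fit$atoms["un1->red"], fit$atoms["un2->red"])),
        fit = list(fit, fit))
    }
  }
  if (length(rows) == 0) {
    stop("No valid variable pair could be decomposed.", call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("phiid_pairwise", class(out))
  out
}

#' Partial correlation of two variables given a third
#'
#' Pearson partial correlation
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.
#'
#' @param x,y,z Numeric vectors of equal length (at least 4) with nonzero
#'   variance.
#' @return Scalar in `[-1, 1]`.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) {
    stop("`x`, `y` and `z` must have equal length.", call. = FALSE)
  }
  if (n < 4) stop("Need at least 4 observations.", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0 || stats::var(z) == 0) {
    stop("`x`, `y` and `z` must have nonzero variance.", call. = FALSE)
  }
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12) {
    stop("Degenerate conditioning: |cor with z| is 1.", call. = FALSE)
  }
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' Storage-transfer overlap analysis
#'
#' Across all ordered variable pairs (pooled over datasets when `data` is a
#' list), correlates the source's active information storage with the
#' transfer entropy, and then partials out the duplication atom
#' (`un -> red`) that both measures share. A correlation that collapses
#' after partialling indicates that the apparent storage-transfer
#' association is driven by information duplication rather than by distinct
#' phenomena.
#'
#' @param data A data frame/matrix of time series, or a list of them.
#' @inheritParams pairwise_decompose
#' @return An object of class `phiid_ais_te`: a list with `correlation`,
#'   `partial_correlation`, `n_pairs` and the per-pair tibble `pairs`.
#' @export
ais_te_analysis <- function(data, lag = 1, redundancy = c("mmi", "ccs"),
                            model = c("auto", "gaussian", "discrete")) {
  redundancy <- match.arg(redundancy)
  model <- match.arg(model)
  datasets <- if (is.data.frame(data) || is.matrix(data)) list(data) else data
  pairs <- purrr::imap(datasets, function(d, i) {
    p <- pairwise_decompose(d, lag = lag, redundancy = redundancy,
                            model = model)
    p$fit <- NULL
    p$dataset <- as.character(i)
    tibble::as_tibble(p)
  }) |> dplyr::bind_rows()
  if (nrow(pairs) < 4) {
    stop("Insufficient data: fewer than 4 valid ordered pairs.", call. = FALSE)
  }
  structure(list(
    correlation = stats::cor(pairs$ais_source, pairs$te),
    partial_correlation = partial_correlation(pairs$ais_source, pairs$te,
                                              pairs$un_to_red),
    n_pairs = nrow(pairs),
    pairs = pairs
  ), class = "phiid_ais_te")
}

#' @export
print.phiid_ais_te <- function(x, ...) {
  cat("Storage-transfer overlap analysis (", x$n_pairs, " ordered pairs)\n",
      "  cor(AIS, TE)                  = ", round(x$correlation, 4), "\n",
      "  partial cor | un->red atom    = ",
      round(x$partial_correlation, 4), "\n", sep = "")
  invisible(x)
}

#' Sweep the AR noise correlation
#'
#' Evaluates the analytic stationary decomposition of the two-node AR system
#' of [make_ar_system()] over a grid of noise correlations, returning the
#' whole-minus-sum and revised integrated information together with the
#' double-redundancy that separates them.
#'
#' @param a Coupling strength (default 0.4, with `|2a| < 1`).
#' @param noise_corr Numeric vector of innovation correlations.
#' @param redundancy Double-redundancy backend (`"mmi"`, the Gaussian
#'   default).
#' @return A tibble of class `phiid_ar_sweep` with columns `noise_corr`,
#'   `tdmi`, `phi_wms`, `phi_r` and `double_red`.
#' @export
ar_sweep <- function(a = 0.4, noise_corr = seq(0, 0.9, by = 0.1),
                     redundancy = "mmi") {
  rows <- purrr::map(noise_corr, function(cc) {
    fit <- phiid_decompose(make_ar_system(a, cc), redundancy)
    tibble::tibble(noise_corr = cc, tdmi = fit$measures$tdmi,
                   phi_wms = fit$measures$phi_wms,
                   phi_r = fit$measures$phi_r,
                   double_red = unname(fit$redundancies["red->red"]))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("phiid_ar_sweep", class(out))
  out
}

#' Plot an AR noise-correlation sweep
#'
#' @param object A [ar_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phiid_ar_sweep <- function(object, ...) {
  d <- tidyr::pivot_longer(tibble::as_tibble(object),
                           c("phi_wms", "phi_r"),
                           names_to = "measure", values_to = "bits")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$noise_corr, y = .data$bits,
                                  colour = .data$measure)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "noise correlation", y = "bits", colour = NULL) +
    ggplot2::theme_minimal()
}
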