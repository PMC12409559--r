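## Temperature-regression engine: linear model y = a + k*T and
## single-exponential model y = B0 * exp(k*T), applied globally and per
## residue, with Pearson r, Fisher-z confidence interval and two-tailed
## p-value.

#' Control parameters for exponential fitting
#'
#' @param maxit maximum Levenberg-Marquardt iterations.
#' @param ftol relative tolerance on the loss change.
#' @return list of control values.
#' @export
thermal_control <- function(maxit = 200, ftol = 1e-10) {
  list(maxit = maxit, ftol = ftol)
}

# Pearson r with Fisher-z 95% CI and two-tailed p on n-2 df.
# Returns r = NA for zero-variance input.
.pearson_stats <- function(x, y) {
  n <- length(x)
  r <- suppressWarnings(stats::cor(x, y))
  if (is.na(r)) return(list(r = NA_real_, ci = c(NA_real_, NA_real_),
                            p = NA_real_, n = n))
  ci <- c(NA_real_, NA_real_)
  if (n >= 4 && abs(r) < 1) {
    z <- atanh(r)
    hw <- stats::qnorm(0.975) / sqrt(n - 3)
    ci <- tanh(c(z - hw, z + hw))
  } else if (n >= 4 && abs(r) >= 1) {
    ci <- c(r, r)
  }
  p <- NA_real_
  if (n >= 3) {
    if (abs(r) >= 1) p <- 0 else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  list(r = r, ci = ci, p = p, n = n)
}

.thermal_fit <- function(model_form, amplitude, k, ps, converged,
                         pearson_r_ty = NA_real_) {
  structure(list(model_form = model_form, amplitude = amplitude, k = k,
                 pearson_r = if (is.na(ps$r)) 0 else ps$r,
                 r_ci95 = ps$ci, p_two_tailed = ps$p,
                 n_points = ps$n, converged = converged,
                 pearson_r_ty = pearson_r_ty),
            class = "thermal_fit")
}

#' @export
print.thermal_fit <- function(x, ...) {
  cat(sprintf("thermal_fit (%s): amplitude %.6g, k %.6g, r %.4f, p %.3g, n %d%s\n",
              x$model_form, x$amplitude, x$k, x$pearson_r, x$p_two_tailed,
              x$n_points, if (x$converged) "" else " [not converged]"))
  invisible(x)
}

.drop_na_pairs <- function(t, y) {
  ok <- is.finite(t) & is.finite(y)
  list(t = t[ok], y = y[ok])
}

#' Linear temperature regression
#'
#' Ordinary least squares of the response on temperature (closed-form
#' solution): `y = amplitude + k * T`. Pearson r is computed between T
#' and y, with a Fisher-z 95% CI and a two-tailed p-value on n-2 df.
#' A constant response gives k = 0 with `converged = FALSE` (r is
#' undefined and reported as 0).
#'
#' @param t temperatures in Kelvin (>= 2 distinct values).
#' @param y response values, same length.
#' @return a `thermal_fit`.
#' @export
fit_linear <- function(t, y) {
  if (length(t) != length(y)) stop("t and y must have equal length")
  d <- .drop_na_pairs(t, y); t <- d$t; y <- d$y
  if (length(unique(t)) < 2)
    stop("singular design: need >= 2 distinct temperatures")
  tm <- mean(t); ym <- mean(y)
  k <- sum((t - tm) * (y - ym)) / sum((t - tm)^2)
  a <- ym - k * tm
  ps <- .pearson_stats(t, y)
  .thermal_fit("linear", a, k, ps, converged = !is.na(ps$r),
               pearson_r_ty = ps$r)
}

#' Single-exponential temperature regression
#'
#' Nonlinear least squares of `y = B0 * exp(k * T)` on untransformed
#' residuals (Levenberg-Marquardt), seeded by OLS on `(T, log y)` over
#' the positive responses. Reports the amplitude B0 (the value
#' extrapolated to zero Kelvin), the thermal constant k, and Pearson r
#' between observed and fitted values (`pearson_r_ty` additionally
#' carries r between T and y).
#'
#' @param t temperatures in Kelvin (>= 3 points, >= 3 distinct).
#' @param y response values, same length.
#' @param control see [thermal_control()].
#' @return a `thermal_fit`; `converged = FALSE` flags a failed or
#'   unconverged fit (best point still reported when available).
#' @export
fit_exponential <- function(t, y, control = thermal_control()) {
  if (length(t) != length(y)) stop("t and y must have equal length")
  d <- .drop_na_pairs(t, y); t <- d$t; y <- d$y
  if (length(y) < 3 || length(unique(t)) < 3)
    stop("exponential fit needs >= 3 points at >= 3 distinct temperatures")
  r_ty <- .pearson_stats(t, y)$r
  # log-linear seed from the positive responses only
  pos <- y > 0
  if (sum(pos) >= 2 && length(unique(t[pos])) >= 2) {
    tm <- mean(t[pos]); lm_ <- mean(log(y[pos]))
    k0 <- sum((t[pos] - tm) * (log(y[pos]) - lm_)) / sum((t[pos] - tm)^2)
    b0 <- exp(lm_ - k0 * tm)
  } else if (any(pos)) {
    b0 <- mean(y[pos]); k0 <- 0
  } else {
    ps <- .pearson_stats(y, y * NA)
    return(.thermal_fit("exponential", NA_real_, NA_real_, ps,
                        converged = FALSE, pearson_r_ty = r_ty))
  }
  dat <- data.frame(tt = t, yy = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ b0 * exp(k * tt), data = dat,
                      start = list(b0 = b0, k = k0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = control$maxit, ftol = control$ftol,
                        ptol = control$ftol)),
    error = function(e) NULL)
  if (is.null(fit)) {
    ps <- .pearson_stats(y, b0 * exp(k0 * t))
    return(.thermal_fit("exponential", b0, k0, ps, converged = FALSE,
                        pearson_r_ty = r_ty))
  }
  cf <- stats::coef(fit)
  fitted <- as.numeric(stats::predict(fit))
  ps <- .pearson_stats(y, fitted)
  conv <- isTRUE(fit$convInfo$isConv) && is.finite(cf[["b0"]]) &&
    is.finite(cf[["k"]]) && !is.na(ps$r)
  .thermal_fit("exponential", cf[["b0"]], cf[["k"]], ps, converged = conv,
               pearson_r_ty = r_ty)
}

# long table of (chain,resseq,icode, temperature, value) for a response
.response_table <- function(series, selection, response) {
  if (response %in% c("b_raw", "b_norm")) {
    do.call(rbind, lapply(series$models, function(m) {
      p <- normalize_b(aggregate_b(m, selection, "per_residue"))
      data.frame(chain = p$chain, resseq = p$resseq, icode = p$icode,
                 temperature_K = resolve_temperature(m),
                 value = p[[response]], stringsAsFactors = FALSE)
    }))
  } else {
    aligned <- align_series(series)
    ref <- aligned$models[[aligned$reference_id]]
    do.call(rbind, lapply(aligned$models, function(m) {
      p <- displacement_profile(m, ref)
      data.frame(chain = p$chain, resseq = p$resseq, icode = p$icode,
                 temperature_K = resolve_temperature(m),
                 value = p[[response]], stringsAsFactors = FALSE)
    }))
  }
}

#' Per-residue temperature regression over a series
#'
#' Collects, for every residue, its response value in each structure of
#' the series (replicates enter as separate points) and fits the chosen
#' temperature model. Residues covered by fewer than
#' `min_coverage * n_structures` structures are omitted (with a
#' message).
#'
#' @param series a [temperature_series()].
#' @param selection `"calpha"` or `"side_chain"` (ignored for
#'   displacement responses, whose name fixes the selection).
#' @param response one of `"b_raw"`, `"b_norm"`, `"d_calpha"`,
#'   `"d_side_chain"`.
#' @param model_form `"exponential"` or `"linear"`.
#' @param min_coverage minimum fraction of structures a residue must
#'   appear in (default two-thirds).
#' @param control see [thermal_control()].
#' @return data.frame of class `profile_fits`: one row per residue with
#'   columns `chain`, `resseq`, `icode`, `amplitude`, `k`, `pearson_r`,
#'   `ci_low`, `ci_high`, `p`, `n`, `converged`.
#' @export
fit_profile_series <- function(series,
                               selection = c("calpha", "side_chain"),
                               response = c("b_raw", "b_norm", "d_calpha",
                                            "d_side_chain"),
                               model_form = c("exponential", "linear"),
                               min_coverage = 2 / 3,
                               control = thermal_control()) {
  selection <- match.arg(selection)
  response <- match.arg(response)
  model_form <- match.arg(model_form)
  if (!length(series$models)) stop("empty series")
  if (response == "d_calpha") selection <- "calpha"
  if (response == "d_side_chain") selection <- "side_chain"
  tab <- .response_table(series, selection, response)
  tab <- tab[is.finite(tab$value), , drop = FALSE]
  need <- min_coverage * length(series$models)
  key <- paste(tab$chain, tab$resseq, tab$icode, sep = "|")
  cov <- table(key)
  drop <- names(cov)[cov < need]
  if (length(drop))
    message(length(drop), " residues below coverage threshold omitted")
  keep <- !(key %in% drop)
  tab <- tab[keep, , drop = FALSE]; key <- key[keep]
  idx <- split(seq_len(nrow(tab)), key)
  rows <- lapply(idx, function(i) {
    f <- if (model_form == "linear") fit_linear(tab$temperature_K[i], tab$value[i])
         else fit_exponential(tab$temperature_K[i], tab$value[i], control)
    data.frame(chain = tab$chain[i[1]], resseq = tab$resseq[i[1]],
               icode = tab$icode[i[1]], amplitude = f$amplitude, k = f$k,
               pearson_r = f$pearson_r, ci_low = f$r_ci95[1],
               ci_high = f$r_ci95[2], p = f$p_two_tailed, n = f$n_points,
               converged = f$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chain, out$resseq, out$icode), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "selection") <- selection
  attr(out, "response") <- response
  attr(out, "model_form") <- model_form
  class(out) <- c("profile_fits", "data.frame")
  out
}

#' Global exponential B(T) fits
#'
#' Fits `B = B0 * exp(k * T)` to three per-structure average-B series:
#' the header Wilson B, the side-chain average and the Calpha average;
#' reports the mean thermal constant and mean zero-Kelvin amplitude
#' over the available channels. A channel with missing data is skipped
#' with a warning.
#'
#' @param series a [temperature_series()].
#' @param control see [thermal_control()].
#' @return list of class `global_b_fits` with elements `wilson`,
#'   `side_chain`, `calpha` (each a `thermal_fit` or `NULL`), `mean_k`
#'   and `mean_b0`.
#' @export
global_b_fits <- function(series, control = thermal_control()) {
  tt <- .series_temperatures(series)
  if (length(unique(tt)) < 3) stop("need >= 3 distinct temperatures")
  wb <- vapply(series$models, function(m)
    if (is.null(m$wilson_b)) NA_real_ else m$wilson_b, numeric(1))
  fits <- list(wilson = NULL, side_chain = NULL, calpha = NULL)
  if (all(is.finite(wb))) {
    fits$wilson <- fit_exponential(tt, wb, control)
  } else {
    warning("Wilson B missing for ",
            sum(!is.finite(wb)), " structures; Wilson fit skipped")
  }
  for (sel in c("side_chain", "calpha")) {
    y <- vapply(series$models, aggregate_b, numeric(1),
                selection = sel, level = "per_structure")
    fits[[sel]] <- fit_exponential(tt, y, control)
  }
  have <- Filter(Negate(is.null), fits[c("wilson", "side_chain", "calpha")])
  fits$mean_k <- mean(vapply(have, function(f) f$k, numeric(1)))
  fits$mean_b0 <- mean(vapply(have, function(f) f$amplitude, numeric(1)))
  class(fits) <- "global_b_fits"
  fits
}

#' @export
print.global_b_fits <- function(x, ...) {
  for (ch in c("wilson", "side_chain", "calpha")) {
    cat(sprintf("%-11s", ch))
    if (is.null(x[[ch]])) cat(" (skipped)\n") else print(x[[ch]])
  }
  cat(sprintf("mean k  %.6g K^-1, mean B0 %.4g A^2\n", x$mean_k, x$mean_b0))
  invisible(x)
}

#' Export per-residue fits as TSV
#'
#' @param fits a `profile_fits` data.frame (or a named list of them).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fits <- function(fits, path) {
  if (is.data.frame(fits)) fits <- list(fits)
  tab <- do.call(rbind, lapply(fits, function(f) {
    sel <- attr(f, "selection"); resp <- attr(f, "response")
    f <- as.data.frame(f)
    f$selection <- sel %||% NA_character_
    f$response <- resp %||% NA_character_
    f
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
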