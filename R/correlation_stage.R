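## Cross-correlation of per-residue thermal parameters: zero-Kelvin
## amplitude B0 and B-factor thermal constant against displacement
## thermal constants, plus trends along the sequence.

#' Pearson correlation with Fisher-z interval
#'
#' Product-moment correlation with a Fisher-z 95% confidence interval
#' and a two-tailed p-value on n-2 degrees of freedom (via
#' [stats::cor.test()]). Pairs with a missing member are dropped; with
#' `x_transform = "log10"`, pairs with non-positive x are dropped too
#' (with a message).
#'
#' @param x,y numeric vectors of equal length.
#' @param x_transform `"identity"` or `"log10"` (applied to x before
#'   correlating).
#' @param x_label,y_label labels carried into the result.
#' @return object of class `correlation_result`: list with
#'   `pearson_r`, `r_ci95`, `p_two_tailed`, `n`, `x_transform`,
#'   `x_label`, `y_label`.
#' @export
pearson_cor <- function(x, y, x_transform = c("identity", "log10"),
                        x_label = "x", y_label = "y") {
  x_transform <- match.arg(x_transform)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  if (x_transform == "log10") {
    bad <- ok & x <= 0
    if (any(bad)) message(sum(bad), " non-positive x values dropped for log10")
    ok <- ok & x > 0
  }
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 complete pairs, got ", length(x))
  if (x_transform == "log10") x <- log10(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(x_label = x_label, y_label = y_label,
                 pearson_r = unname(ct$estimate),
                 r_ci95 = if (is.null(ct$conf.int)) c(NA_real_, NA_real_)
                          else as.numeric(ct$conf.int),
                 p_two_tailed = ct$p.value, n = length(x),
                 x_transform = x_transform),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("pearson %s vs %s%s: r = %.4f (95%% CI %.4f to %.4f), p = %.4g, n = %d\n",
              x$x_label, x$y_label,
              if (x$x_transform == "log10") " (log10 x)" else "",
              x$pearson_r, x$r_ci95[1], x$r_ci95[2], x$p_two_tailed, x$n))
  invisible(x)
}

.merge_fit_pair <- function(a, b, a_col, b_col) {
  key_a <- paste(a$chain, a$resseq, a$icode, sep = "|")
  key_b <- paste(b$chain, b$resseq, b$icode, sep = "|")
  common <- intersect(key_a, key_b)
  if (length(common) < 3)
    stop("fewer than 3 overlapping residues between fit tables")
  data.frame(x = a[[a_col]][match(common, key_a)],
             y = b[[b_col]][match(common, key_b)])
}

#' B-factor parameters versus conformational plasticity
#'
#' The four cross-correlations relating per-residue B-factor
#' parameters to the displacement thermal constant: zero-Kelvin
#' amplitude B0 (log10-transformed) vs the displacement slope, and the
#' B-factor thermal constant vs the displacement slope, each for
#' Calpha and side chains.
#'
#' @param displacement_fits named list with elements `calpha` and
#'   `side_chain`: per-residue linear `profile_fits` (the displacement
#'   slope is the `k` column).
#' @param bfactor_fits named list with elements `calpha` and
#'   `side_chain`: per-residue exponential `profile_fits` on raw B
#'   (`amplitude` = B0, `k` = thermal constant).
#' @return named list of four `correlation_result`s:
#'   `calpha_b0`, `calpha_bk`, `side_chain_b0`, `side_chain_bk`.
#' @export
b_vs_plasticity <- function(displacement_fits, bfactor_fits) {
  out <- list()
  for (sel in c("calpha", "side_chain")) {
    d <- displacement_fits[[sel]]; b <- bfactor_fits[[sel]]
    if (is.null(d) || is.null(b))
      stop("missing per-residue fits for selection ", sel)
    m0 <- .merge_fit_pair(b, d, "amplitude", "k")
    out[[paste0(sel, "_b0")]] <-
      pearson_cor(m0$x, m0$y, "log10", x_label = paste0(sel, " B0"),
                  y_label = paste0(sel, " displacement k"))
    mk <- .merge_fit_pair(b, d, "k", "k")
    out[[paste0(sel, "_bk")]] <-
      pearson_cor(mk$x, mk$y, "identity", x_label = paste0(sel, " Bk"),
                  y_label = paste0(sel, " displacement k"))
  }
  out
}

#' Trend of a per-residue quantity along the sequence
#'
#' Pearson correlation between the residue number and the value, used
#' to test whether a thermal parameter drifts along the chain.
#'
#' @param values either a data.frame with columns `resseq` and `value`
#'   (a `profile_fits` table may be passed with `column` naming the
#'   parameter), or a numeric vector named by residue number.
#' @param column column to use when `values` is a data.frame holding
#'   several parameters (default `"k"`).
#' @return a `correlation_result`.
#' @export
sequence_trend <- function(values, column = "k") {
  if (is.data.frame(values)) {
    resseq <- values$resseq
    v <- if ("value" %in% names(values)) values$value else values[[column]]
  } else {
    resseq <- as.numeric(names(values))
    v <- as.numeric(values)
  }
  pearson_cor(resseq, v, "identity", x_label = "residue", y_label = column)
}
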