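# Four-parameter logistic dose-response fitting, relative EC50 and
# absolute IC50, fold-selectivity, growth-rate-corrected GR metrics and
# the population doubling level formula.
#
# Model (decreasing viability, hill > 0):
#   v(c) = bottom + (top - bottom) / (1 + (c / ec50)^hill)
# fitted by least squares on the log10-concentration axis with
# multi-start initialization (4PL fits are initialization-sensitive).

LN10 <- log(10)

rss_4pl <- function(par, lc, y) {
  # par = (bottom, top, log10(ec50), log(hill))
  b <- par[1L]; t <- par[2L]; le <- par[3L]; h <- exp(par[4L])
  s <- 1 / (1 + 10^(h * (lc - le)))
  f <- b + (t - b) * s
  sum((f - y)^2)
}

grad_4pl <- function(par, lc, y) {
  b <- par[1L]; t <- par[2L]; le <- par[3L]; h <- exp(par[4L])
  k <- LN10 * h * (lc - le)
  s <- 1 / (1 + exp(k))
  f <- b + (t - b) * s
  r2 <- 2 * (f - y)
  dk <- -(t - b) * s * (1 - s)   # df/dk
  c(sum(r2 * (1 - s)),
    sum(r2 * s),
    sum(r2 * dk * (-LN10 * h)),
    sum(r2 * dk * k))            # dk/dlog(h) = k
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `v(c) = bottom + (top - bottom) / (1 +
#' (c/ec50)^hill)` with hill constrained positive (decreasing-viability
#' parameterization). EC50 is initialized at the 25/50/75% quantiles of
#' the observed doses and the best residual sum of squares wins, ties
#' broken toward the smallest EC50. Zero-dose points are dropped from
#' the log axis (the vehicle enters as the normalization denominator,
#' not as a fitted point). Monotone-increasing input is fit with
#' bottom/top unordered and flagged `non_inhibitory` rather than given
#' a negative hill.
#'
#' @param concentration_nM dose series in nM (>= 4 distinct positive
#'   doses required).
#' @param viability relative viability values, finite.
#' @param compound_id,cell_line optional identifiers carried through.
#' @return object of class `dr_fit`: `bottom, top, hill, ec50_rel_nM,
#'   rss, converged, degenerate, non_inhibitory, n_points, conc_range`.
#' @export
fit_4pl <- function(concentration_nM, viability,
                    compound_id = NA_character_, cell_line = NA_character_) {
  keep <- concentration_nM > 0
  conc <- concentration_nM[keep]
  y <- viability[keep]
  if (!all(is.finite(y))) stopf("viabilities must be finite")
  if (length(unique(conc)) < 4L) {
    stopf("need >= 4 distinct positive concentrations, got %d",
          length(unique(conc)))
  }
  out <- list(compound_id = compound_id, cell_line = cell_line,
              n_points = length(y),
              conc_range = range(conc))
  if (stats::sd(y) == 0) {
    out <- c(out, list(bottom = y[1L], top = y[1L], hill = NA_real_,
                       ec50_rel_nM = NA_real_, rss = 0,
                       converged = FALSE, degenerate = TRUE,
                       non_inhibitory = FALSE))
    return(structure(out, class = "dr_fit"))
  }
  lc <- log10(conc)
  lo <- c(-0.5, -0.5, min(lc) - 2, log(0.05))
  hi <- c(2, 2, max(lc) + 2, log(20))
  starts <- stats::quantile(lc, c(0.25, 0.5, 0.75), names = FALSE)
  # two stages per start: a robust pass, then a tight polish; the polish
  # can abort in the line search at machine precision, in which case the
  # robust solution stands
  run_lbfgsb <- function(par0, factr) {
    tryCatch(
      stats::optim(par0, rss_4pl, grad_4pl, lc = lc, y = y,
                   method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(factr = factr, maxit = 1000L)),
      error = function(e) NULL)
  }
  fits <- lapply(starts, function(le0) {
    best <- NULL
    par0 <- c(min(y), max(y), le0, log(1))
    conv <- 1L
    for (factr in c(1e1, 1e7, 1e1)) {
      res <- run_lbfgsb(par0, factr)
      if (is.null(res)) next
      conv <- min(conv, res$convergence)
      if (is.null(best) || res$value <= best$value) best <- res
      par0 <- best$par
    }
    if (!is.null(best)) best$convergence <- conv
    best
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) {
    out <- c(out, list(bottom = NA_real_, top = NA_real_, hill = NA_real_,
                       ec50_rel_nM = NA_real_, rss = NA_real_,
                       converged = FALSE, degenerate = FALSE,
                       non_inhibitory = FALSE))
    return(structure(out, class = "dr_fit"))
  }
  rss <- vapply(fits, function(f) f$value, 1)
  ec <- vapply(fits, function(f) f$par[3L], 1)
  best <- fits[[order(rss, ec)[1L]]]
  b <- best$par[1L]; t <- best$par[2L]
  non_inhib <- b > t
  if (non_inhib) { tmp <- b; b <- t; t <- tmp }  # report ordered asymptotes
  # L-BFGS-B can abort its line search at machine precision while sitting
  # on a stationary point; a near-zero gradient counts as converged
  gnorm <- max(abs(grad_4pl(best$par, lc, y)))
  converged <- best$convergence == 0 || gnorm < 1e-6 * (1 + best$value)
  out <- c(out, list(bottom = b, top = t, hill = exp(best$par[4L]),
                     ec50_rel_nM = 10^best$par[3L], rss = best$value,
                     converged = converged,
                     degenerate = FALSE, non_inhibitory = non_inhib))
  structure(out, class = "dr_fit")
}

#' @export
print.dr_fit <- function(x, ...) {
  cat(sprintf("<dr_fit> %s / %s: bottom=%.3f top=%.3f hill=%.3f ec50=%.4g nM rss=%.3g%s%s\n",
              x$compound_id, x$cell_line, x$bottom, x$top, x$hill,
              x$ec50_rel_nM, x$rss,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (isTRUE(x$non_inhibitory)) " [non-inhibitory]" else ""))
  invisible(x)
}

#' Predict viability from a 4PL fit
#' @param object a `dr_fit`.
#' @param newdata concentrations in nM.
#' @param ... unused.
#' @return fitted relative viability.
#' @export
predict.dr_fit <- function(object, newdata, ...) {
  four_pl(newdata, object$bottom, object$top, object$hill,
          object$ec50_rel_nM)
}

#' Absolute IC50 from a fitted curve
#'
#' Solves `fitted viability = 0.5` in closed form,
#' `c = ec50 * ((top - 0.5)/(0.5 - bottom))^(1/hill)`, and censors the
#' answer when the curve does not cross 0.5 inside the tested range:
#' `>c_max` when the curve stays above 0.5 (including bottom >= 0.5),
#' `<c_min` when already below 0.5 at the lowest dose (including
#' top <= 0.5). The absolute IC50 equals the relative EC50 exactly when
#' the curve midpoint (top + bottom)/2 is 0.5.
#'
#' @param fit a converged `dr_fit`.
#' @param c_min,c_max tested concentration range in nM (defaults: the
#'   fit's observed range).
#' @return list `ic50_nM` (NA when censored), `censored` (`"none"`,
#'   `"above_range"`, `"below_range"`) and `label` (e.g. `">10000"`).
#' @export
absolute_ic50 <- function(fit, c_min = fit$conc_range[1L],
                          c_max = fit$conc_range[2L]) {
  stopifnot(inherits(fit, "dr_fit"))
  if (!isTRUE(fit$converged)) stopf("absolute IC50 requires a converged fit")
  censor <- function(side) {
    list(ic50_nM = NA_real_,
         censored = if (side == "hi") "above_range" else "below_range",
         label = if (side == "hi") sprintf(">%g", c_max)
                 else sprintf("<%g", c_min))
  }
  if (fit$bottom >= 0.5) return(censor("hi"))
  if (fit$top <= 0.5) return(censor("lo"))
  c50 <- fit$ec50_rel_nM *
    ((fit$top - 0.5) / (0.5 - fit$bottom))^(1 / fit$hill)
  if (c50 > c_max) return(censor("hi"))
  if (c50 < c_min) return(censor("lo"))
  list(ic50_nM = c50, censored = "none", label = sprintf("%g", c50))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Fold-selectivity between two cell lines
#'
#' Ratio of the less-sensitive line's IC50 to the more-sensitive
#' line's, with the reported value rounded half-away-from-zero to an
#' integer. Censored IC50s yield a bound (e.g. `">28"`), not a number.
#'
#' @param ic50_a,ic50_b IC50s in nM: numbers or [absolute_ic50()]
#'   results. `a` is conventionally the resistant-direction line; if
#'   both are finite the ratio is taken as max/min.
#' @return list `fold`, `reported_fold`, `label`, `bound` (TRUE when
#'   only a bound can be given).
#' @export
fold_selectivity <- function(ic50_a, ic50_b) {
  get_val <- function(x) {
    if (is.list(x)) list(v = x$ic50_nM, cens = x$censored) else
      list(v = as.numeric(x), cens = "none")
  }
  a <- get_val(ic50_a); b <- get_val(ic50_b)
  if (a$cens != "none" || b$cens != "none") {
    # a censored above or b censored below gives a lower bound on fold
    if (identical(a$cens, "above_range") && b$cens == "none") {
      bound <- as.numeric(sub(">", "", ic50_a$label)) / b$v
      return(list(fold = NA_real_, reported_fold = NA_real_,
                  label = sprintf(">%g", round_half_away(bound)),
                  bound = TRUE))
    }
    return(list(fold = NA_real_, reported_fold = NA_real_,
                label = "indeterminate (censored input)", bound = TRUE))
  }
  if (!is.finite(a$v) || !is.finite(b$v) || a$v <= 0 || b$v <= 0) {
    stopf("fold selectivity needs finite positive IC50s")
  }
  fold <- max(a$v, b$v) / min(a$v, b$v)
  list(fold = fold, reported_fold = round_half_away(fold),
       label = sprintf("%g", round_half_away(fold)), bound = FALSE)
}

#' Growth-rate inhibition metrics
#'
#' Computes the normalized growth rate inhibition value per
#' concentration, `GR(c) = 2^(log2(x(c)/x0) / log2(x_ctrl/x0)) - 1`,
#' where `x0` is the cell count at treatment start, `x_ctrl` the
#' untreated count at endpoint and `x(c)` the treated count at
#' endpoint. GR is 1 for no effect, 0 for complete cytostasis and
#' negative for net cell loss. GR50 (concentration with GR = 0.5) is
#' obtained from a 4PL fit to the GR values, censored when the fitted
#' curve does not cross 0.5 inside the tested range.
#'
#' @param concentration_nM dose series (nM).
#' @param x_c treated cell counts at endpoint, one per dose (> 0).
#' @param x0 count at treatment start (> 0).
#' @param x_ctrl untreated count at endpoint (must exceed `x0`).
#' @param fit_gr50 also fit GR50 (requires >= 4 distinct doses).
#' @return list with `gr_table` (concentration_nM, gr), `gr50` (an
#'   [absolute_ic50()]-style list, or NULL) and `fit`.
#' @export
compute_gr <- function(concentration_nM, x_c, x0, x_ctrl,
                       fit_gr50 = TRUE) {
  if (x0 <= 0) stopf("x0 must be > 0")
  if (x_ctrl <= x0) stopf("no control growth (x_ctrl <= x0); GR undefined")
  if (any(x_c <= 0)) stopf("treated counts must be > 0")
  gr <- 2^(log2(x_c / x0) / log2(x_ctrl / x0)) - 1
  tab <- data.frame(concentration_nM = concentration_nM, gr = gr)
  res <- list(gr_table = tab, gr50 = NULL, fit = NULL)
  if (fit_gr50 && length(unique(concentration_nM[concentration_nM > 0])) >= 4L) {
    fit <- fit_4pl(concentration_nM, gr)
    res$fit <- fit
    if (isTRUE(fit$converged)) {
      res$gr50 <- absolute_ic50(fit)   # 0.5-crossing of fitted GR curve
    }
  }
  res
}

#' Correlate IC50 and GR50 across a panel
#'
#' Spearman rank correlation of log-transformed potencies; censored
#' pairs are dropped and counted.
#'
#' @param ic50_nM,gr50_nM paired potency vectors (NA = censored).
#' @return list `rho, p_value, n_used, n_censored`.
#' @export
correlate_ic50_gr50 <- function(ic50_nM, gr50_nM) {
  stopifnot(length(ic50_nM) == length(gr50_nM))
  ok <- is.finite(ic50_nM) & is.finite(gr50_nM) & ic50_nM > 0 & gr50_nM > 0
  if (sum(ok) < 3L) stopf("need >= 3 uncensored IC50/GR50 pairs, got %d",
                          sum(ok))
  ct <- suppressWarnings(
    stats::cor.test(log10(ic50_nM[ok]), log10(gr50_nM[ok]),
                    method = "spearman", alternative = "two.sided"))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_used = sum(ok), n_censored = sum(!ok))
}

#' Population doubling level
#'
#' `PDL_n = 3.32 (log10 X_t - log10 X_0) + PDL_{n-1}`. The constant is
#' the published 3.32 by default; `exact_log2 = TRUE` substitutes
#' `1/log10(2) = 3.3219...` so that one doubling increments the PDL by
#' exactly 1.
#'
#' @param x0 inoculum cell count (> 0).
#' @param xt harvested cell count (> 0).
#' @param pdl_prev PDL at the previous passage (default 0).
#' @param exact_log2 use the exact constant instead of 3.32.
#' @return list `x0, xt, pdl_prev, pdl, constant`.
#' @export
pdl <- function(x0, xt, pdl_prev = 0, exact_log2 = FALSE) {
  if (any(x0 <= 0) || any(xt <= 0)) stopf("cell counts must be > 0")
  k <- if (exact_log2) 1 / log10(2) else 3.32
  list(x0 = x0, xt = xt, pdl_prev = pdl_prev,
       pdl = k * (log10(xt) - log10(x0)) + pdl_prev, constant = k)
}

#' Fit a table of dose-response curves
#'
#' Convenience wrapper: groups a long viability table by
#' (compound, cell line), fits each group with [fit_4pl()] and extracts
#' relative EC50 and absolute IC50 (with censoring labels).
#'
#' @param df dose-response table (see [read_dose_response()]).
#' @return data.frame, one row per (compound_id, cell_line).
#' @export
fit_dr_table <- function(df) {
  groups <- split(df, list(df$compound_id, df$cell_line), drop = TRUE)
  rows <- lapply(groups, function(d) {
    fit <- fit_4pl(d$concentration_nM, d$viability,
                   compound_id = d$compound_id[1L],
                   cell_line = d$cell_line[1L])
    ic <- if (isTRUE(fit$converged)) absolute_ic50(fit) else
      list(ic50_nM = NA_real_, censored = "not_converged", label = "NA")
    data.frame(compound_id = d$compound_id[1L], cell_line = d$cell_line[1L],
               bottom = fit$bottom, top = fit$top, hill = fit$hill,
               ec50_rel_nM = fit$ec50_rel_nM, ic50_abs_nM = ic$ic50_nM,
               ic50_label = ic$label, censored = ic$censored,
               rss = fit$rss, converged = fit$converged,
               non_inhibitory = isTRUE(fit$non_inhibitory),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$compound_id, out$cell_line), ]
}
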