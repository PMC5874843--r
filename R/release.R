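# Experimental-statistics stage: min-max factor coding, 2^N screening with
# standardized effects, reduced-model regression, swelling index, drug
# content, cumulative release with aliquot correction, and release-profile
# summaries.
#
# Ordinary least squares is delegated to stats::lm(); the coding,
# standardized-effect (Pareto) conventions, percent-R-squared scale and the
# mass-balance bookkeeping are the package's own layer.

#' Code a factor to [-1, 1]
#'
#' `coded = 2 (x - x_min) / (x_max - x_min) - 1`. Values outside the design
#' range are rejected (no extrapolation).
#'
#' @param x Natural value(s).
#' @param x_min,x_max Design range (`x_max > x_min`).
#' @return Coded value(s) in `[-1, 1]`.
#' @seealso [decode_factor()] for the inverse transform.
#' @export
#' @examples
#' code_factor(8, 1, 48)      # -0.70213
#' code_factor(2.44, 0, 9.1)  # -0.4637
code_factor <- function(x, x_min, x_max) {
  if (x_max <= x_min) stop_gf("x_max must exceed x_min", "gelforge_invalid")
  if (any(x < x_min - 1e-12 | x > x_max + 1e-12)) {
    stop_gf("value outside the design range: no extrapolation", "gelforge_invalid")
  }
  2 * (x - x_min) / (x_max - x_min) - 1
}

#' Decode a coded factor back to natural units
#'
#' @param coded Coded value(s) in `[-1, 1]`.
#' @inheritParams code_factor
#' @return Natural value(s).
#' @export
decode_factor <- function(coded, x_min, x_max) {
  if (x_max <= x_min) stop_gf("x_max must exceed x_min", "gelforge_invalid")
  (coded + 1) / 2 * (x_max - x_min) + x_min
}

# Build the model matrix for coded terms like "A", "B", "A:B" (or "AB").
term_matrix <- function(design, terms) {
  cols <- lapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(parts) == 1L && !parts %in% names(design) && nchar(parts) > 1L) {
      parts <- strsplit(parts, "")[[1]]  # "AB" shorthand
    }
    missing <- setdiff(parts, names(design))
    if (length(missing)) {
      stop_gf(sprintf("unknown factor column(s): %s", paste(missing, collapse = ", ")),
              "gelforge_invalid")
    }
    Reduce(`*`, design[parts])
  })
  m <- do.call(cbind, cols)
  colnames(m) <- terms
  m
}

#' Screen factorial effects with standardized (Pareto) ordering
#'
#' Ordinary least squares on the coded regressors with an intercept;
#' standardized effect = |coefficient / SE|, ordered descending, with
#' significance against the two-sided critical t at the stated confidence
#' and residual degrees of freedom.
#'
#' @param design data.frame with coded factor columns (e.g. `A`, `B`) and
#'   the response.
#' @param terms Character vector of terms: single factors (`"A"`) and
#'   interactions (`"A:B"` or `"AB"`).
#' @param response Response column name.
#' @param confidence Confidence level for the critical t (default 0.95).
#' @return An `effect_screen`: data.frame with columns `term`,
#'   `coefficient`, `se`, `t`, `significant`, Pareto-ordered, with the
#'   critical t and residual d.f. as attributes.
#' @export
screen_effects <- function(design, terms = c("A", "B", "A:B"),
                           response = "response", confidence = 0.95) {
  y <- design[[response]]
  if (is.null(y)) stop_gf(sprintf("no response column '%s'", response), "gelforge_invalid")
  X <- term_matrix(design, terms)
  if (nrow(X) <= ncol(X) + 1L) {
    stop_gf("model not estimable: need more records than parameters", "gelforge_invalid")
  }
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1L) {
    keep <- qx$pivot[seq_len(qx$rank)]
    aliased <- setdiff(colnames(X), colnames(X)[keep[keep > 1] - 1L])
    stop_gf(sprintf("rank-deficient design: aliased term(s) %s",
                    paste(aliased, collapse = ", ")), "gelforge_invalid")
  }
  fit <- stats::lm(y ~ X)
  # summary.lm warns on noiseless (zero-residual) designs, which are
  # legitimate inputs for screening synthetic constructions
  sm <- suppressWarnings(summary(fit))$coefficients
  est <- sm[-1, 1]
  se <- sm[-1, 2]
  tval <- ifelse(se > 0, abs(est / se), ifelse(abs(est) > 0, Inf, 0))
  df <- fit$df.residual
  tcrit <- stats::qt(1 - (1 - confidence) / 2, df)
  out <- data.frame(term = terms, coefficient = unname(est), se = unname(se),
                    t = unname(tval), significant = unname(tval > tcrit))
  out <- out[order(-out$t), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("effect_screen", "data.frame"),
            t_critical = tcrit, df = df, confidence = confidence)
}

#' @export
print.effect_screen <- function(x, ...) {
  cat(sprintf("Standardized effects (critical |t| = %.3f at %.0f%% confidence, %d d.f.)\n",
              attr(x, "t_critical"), attr(x, "confidence") * 100, attr(x, "df")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Fit a reduced factorial regression model
#'
#' Ordinary least squares on exactly the included coded terms plus an
#' intercept. R-squared is reported in percent; a constant response yields
#' R-squared 0 by convention.
#'
#' @param design data.frame with coded factor columns and the response.
#' @param included_terms Terms to keep (same syntax as [screen_effects()]).
#' @param response Response column name.
#' @return A `factorial_fit` with `coefficients`, `r_squared` (percent),
#'   `df_residual`, and the underlying `lm` fit; supports `coef`,
#'   `predict`, `residuals`, `summary` and `print`.
#' @export
fit_reduced_model <- function(design, included_terms, response = "response") {
  y <- design[[response]]
  if (is.null(y)) stop_gf(sprintf("no response column '%s'", response), "gelforge_invalid")
  X <- term_matrix(design, included_terms)
  if (nrow(X) <= ncol(X)) {
    stop_gf("model not estimable: need more records than parameters", "gelforge_invalid")
  }
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    stop_gf("rank-deficient design for the included terms", "gelforge_invalid")
  }
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 100 * (1 - sum(stats::residuals(fit)^2) / sst) else 0
  cf <- stats::coef(fit)
  names(cf) <- c("(Intercept)", included_terms)
  structure(list(coefficients = cf, r_squared = r2,
                 df_residual = fit$df.residual, terms = included_terms,
                 response = response, lm = fit),
            class = "factorial_fit")
}

#' @export
print.factorial_fit <- function(x, ...) {
  eq <- paste(sprintf("%.2f", x$coefficients[1]),
              paste(sprintf("%+.2f*%s", x$coefficients[-1], x$terms),
                    collapse = " "))
  cat(sprintf("<factorial_fit> %s = %s  (R2 = %.2f%%)\n", x$response, eq,
              x$r_squared))
  invisible(x)
}

#' @export
coef.factorial_fit <- function(object, ...) object$coefficients

#' @export
predict.factorial_fit <- function(object, newdata, ...) {
  X <- term_matrix(newdata, object$terms)
  drop(cbind(1, X) %*% object$coefficients)
}

#' @export
residuals.factorial_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
summary.factorial_fit <- function(object, ...) {
  list(coefficients = summary(object$lm)$coefficients,
       r_squared = object$r_squared, df_residual = object$df_residual)
}

#' Swelling index
#'
#' Percent mass gain relative to the swollen mass:
#' `(Mh - Mx) / Mh * 100` for swollen mass `Mh` and xerogel mass `Mx`
#' (note the swollen-mass denominator).
#'
#' @param m_swollen Swollen hydrogel mass (g).
#' @param m_xerogel Xerogel (dried) mass (g).
#' @return Swelling index in percent.
#' @export
#' @examples
#' swelling_index(2, 1)  # 50
swelling_index <- function(m_swollen, m_xerogel) {
  if (any(m_xerogel <= 0)) stop_gf("xerogel mass must be positive", "gelforge_invalid")
  if (any(m_swollen < m_xerogel)) {
    stop_gf("swollen mass below xerogel mass: negative swelling not modeled",
            "gelforge_invalid")
  }
  (m_swollen - m_xerogel) / m_swollen * 100
}

#' Loaded drug content by mass difference
#'
#' Positive difference between the drug-loaded and unloaded xerogel masses.
#'
#' @param x_loaded Mass of the loaded xerogel (mg).
#' @param x_unloaded Mass of the unloaded xerogel (mg).
#' @return Drug content in mg.
#' @export
drug_content <- function(x_loaded, x_unloaded) {
  if (any(x_loaded < 0) || any(x_unloaded < 0)) {
    stop_gf("masses must be non-negative", "gelforge_invalid")
  }
  out <- x_loaded - x_unloaded
  if (any(out < 0)) {
    stop_gf("loaded mass below unloaded mass: inconsistent masses", "gelforge_invalid")
  }
  out
}

#' Cumulative drug release with aliquot correction
#'
#' Released mass at step i is `c_i * V + sum_{j<i} c_j * v_j` when the
#' sampling correction is on (mass balance for withdrawn-and-replaced
#' aliquots), else `c_i * V`. Percent release divides by the absorbed mass.
#'
#' @param records data.frame with columns `time_h`, `conc_mg_per_mL` and
#'   optionally `withdrawn_mL`, `volume_mL` (defaults 1 and 5).
#' @param absorbed Absorbed drug mass (mg, positive).
#' @param correct_sampling Apply the aliquot mass-balance correction.
#' @param tolerance Percent overshoot above 100 that triggers the warning
#'   flag.
#' @return data.frame `time_h`, `released_mg`, `released_pct` with
#'   attribute `overshoot` flagging release above `100 + tolerance`.
#' @export
cumulative_release <- function(records, absorbed, correct_sampling = TRUE,
                               tolerance = 2) {
  stopifnot(all(c("time_h", "conc_mg_per_mL") %in% names(records)))
  if (absorbed <= 0) stop_gf("absorbed mass must be positive", "gelforge_invalid")
  t <- records$time_h
  if (any(diff(t) <= 0)) stop_gf("times must be strictly increasing", "gelforge_invalid")
  V <- records$volume_mL %||% rep(5, nrow(records))
  v <- records$withdrawn_mL %||% rep(1, nrow(records))
  if (any(V <= 0) || any(v < 0)) stop_gf("volumes must be positive", "gelforge_invalid")
  cc <- records$conc_mg_per_mL
  n <- length(cc)
  removed <- c(0, cumsum(cc * v)[-n])
  mass <- if (correct_sampling) cc * V + removed else cc * V
  pct <- mass / absorbed * 100
  out <- data.frame(time_h = t, released_mg = mass, released_pct = pct)
  attr(out, "overshoot") <- any(pct > 100 + tolerance)
  out
}

#' Summarize a biphasic release profile
#'
#' Burst percent = interpolated cumulative release at `burst_window`;
#' zero-order slope = OLS slope of the cumulative release over
#' `late_window`, with its fit R-squared.
#'
#' @param series data.frame with `time_h` and `released_pct` (e.g. from
#'   [cumulative_release()] or [make_release_curve()]).
#' @param burst_window End of the burst phase (h).
#' @param late_window Length-2 vector of the zero-order window (h).
#' @return List with `burst_pct`, `slope_pct_per_h`, `slope_r_squared`.
#' @export
release_profile_summary <- function(series, burst_window = 2,
                                    late_window = NULL) {
  t <- series$time_h
  y <- series$released_pct
  if (is.null(late_window)) late_window <- c(burst_window, max(t))
  if (burst_window < min(t) || burst_window > max(t) ||
      late_window[1] < min(t) || late_window[2] > max(t) ||
      late_window[2] <= late_window[1]) {
    stop_gf("summary windows fall outside the data span", "gelforge_invalid")
  }
  burst <- stats::approx(t, y, xout = burst_window)$y
  sel <- t >= late_window[1] & t <= late_window[2]
  if (sum(sel) < 2L) stop_gf("too few points in the late window", "gelforge_invalid")
  fit <- stats::lm(y[sel] ~ t[sel])
  sst <- sum((y[sel] - mean(y[sel]))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  list(burst_pct = burst,
       slope_pct_per_h = unname(stats::coef(fit)[2]),
       slope_r_squared = r2)
}

#' The packaged 20-row release design table
#'
#' Cyclodextrin proportion (factor A, percent over 0-9.1) and release time
#' (factor B, hours over 1-48) with coded levels and the measured release
#' percentage, transcribed from the published experiment.
#'
#' @return data.frame with columns `gamma_cd_pct`, `time_h`, `A`, `B`,
#'   `release_pct`.
#' @export
release_design_table <- function() {
  path <- system.file("extdata", "release_design.csv", package = "gelforge")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "release_design.csv")
  utils::read.csv(path)
}
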