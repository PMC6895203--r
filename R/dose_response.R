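# Single and double Boltzmann concentration-response fitting.
#
# The "Boltzmann" sigmoid in log-concentration is algebraically the Hill
# form R(c) = base + A * sum_i f_i / (1 + (EC50_i / c)^h_i). Fitting is by
# least squares with a deterministic multi-start over log-spaced EC50
# grids; zero-concentration points constrain the baseline term only.

boltzmann_eval <- function(conc, base, amp, ec50, h, fraction) {
  s <- numeric(length(conc))
  pos <- conc > 0
  for (i in seq_along(ec50))
    s[pos] <- s[pos] + fraction[i] / (1 + (ec50[i] / conc[pos])^h[i])
  base + amp * s
}

#' Fit a single or double Boltzmann concentration-response relation
#'
#' @param concentrations Molar concentrations (`>= 0`; zeros anchor the
#'   baseline only).
#' @param responses Observed responses (occupancies or normalized FRET
#'   changes).
#' @param weights Optional fitting weights; when `sem` is supplied instead,
#'   weights default to `1/sem^2`.
#' @param n_phases 1 or 2.
#' @param sem Optional per-point standard errors.
#' @param fix_baseline Optional numeric: hold the baseline at this value
#'   (e.g. 0 for normalized data); default free.
#' @param fix_amplitude Optional numeric: hold the total amplitude (e.g. 1
#'   for plateau-normalized data); default free.
#' @param h_bounds Slope bounds per phase (default `c(0.5, 3)`): slopes are
#'   left free within the physically plausible band for saturable binding,
#'   which also removes boundary-slope local optima that can swallow a
#'   poorly sampled phase.
#' @return A `dose_response_fit`: list with `n_phases`, `phases`
#'   (data.frame: ec50, h, fraction, ordered by ascending EC50), `baseline`,
#'   `amplitude`, `rss`, `converged`, and `fitted(conc)` closure.
#' @export
fit_boltzmann <- function(concentrations, responses, weights = NULL,
                          n_phases = 1L, sem = NULL, fix_baseline = NULL,
                          fix_amplitude = NULL, h_bounds = c(0.5, 3)) {
  n_phases <- as.integer(n_phases)
  stopifnot(n_phases %in% c(1L, 2L),
            length(concentrations) == length(responses))
  # pinned slope (h_bounds c(1, 1)): widen marginally for the box optimizer
  if (diff(range(h_bounds)) < 1e-6)
    h_bounds <- h_bounds + c(-5e-4, 5e-4)
  npar_model <- 2L * n_phases
  if (length(concentrations) < 2L * npar_model + 1L)
    stop(sprintf("need at least %d points for a %d-phase fit",
                 2L * npar_model + 1L, n_phases))
  if (stats::sd(responses) == 0)
    stop("degenerate data: responses are constant")
  if (is.null(weights)) {
    weights <- if (!is.null(sem)) {
      # variance-shrunk weights: with a handful of movies the raw SEMs are
      # too noisy to use directly, and a fortuitously small one would let a
      # single point dominate the fit
      s2 <- sem^2
      s2[!is.finite(s2)] <- stats::median(s2[is.finite(s2)])
      1 / (s2 + stats::median(s2))
    } else rep(1, length(responses))
  }

  cpos <- concentrations[concentrations > 0]
  lrange <- range(log10(cpos))
  free_base <- is.null(fix_baseline)
  base_fix <- if (free_base) 0 else fix_baseline
  free_amp <- is.null(fix_amplitude)

  # parameter vector: [base?], [amp?], f1 (2-phase), log10 ec50s, hs
  unpack <- function(p) {
    i <- 0L
    base <- if (free_base) { i <- i + 1L; p[i] } else base_fix
    amp <- if (free_amp) { i <- i + 1L; p[i] } else fix_amplitude
    f1 <- if (n_phases == 2L) { i <- i + 1L; p[i] } else 1
    ec50 <- 10^p[i + seq_len(n_phases)]; i <- i + n_phases
    h <- p[i + seq_len(n_phases)]
    list(base = base, amp = amp, ec50 = ec50, h = h,
         fraction = if (n_phases == 2L) c(f1, 1 - f1) else 1)
  }
  obj <- function(p) {
    q <- unpack(p)
    r <- boltzmann_eval(concentrations, q$base, q$amp, q$ec50, q$h,
                        q$fraction)
    sum(weights * (responses - r)^2)
  }
  rng <- diff(range(responses))
  lower <- c(if (free_base) min(responses) - rng,
             if (free_amp) 0,
             if (n_phases == 2L) 0.01,
             rep(lrange[1] - 2, n_phases), rep(h_bounds[1], n_phases))
  upper <- c(if (free_base) max(responses),
             if (free_amp) 2 * rng + max(responses),
             if (n_phases == 2L) 0.99,
             rep(lrange[2] + 2, n_phases), rep(h_bounds[2], n_phases))

  grid <- seq(lrange[1] - 0.5, lrange[2] + 0.5, length.out = 6L)
  starts <- if (n_phases == 1L) as.list(grid) else {
    gg <- expand.grid(a = grid, b = grid)
    gg <- gg[gg$a < gg$b, ]
    asplit(as.matrix(gg), 1L)
  }
  best <- NULL
  base0 <- min(responses)
  amp0 <- max(rng, 1e-6)
  for (st in starts) {
    p0 <- c(if (free_base) base0, if (free_amp) amp0,
            if (n_phases == 2L) 0.7,
            as.numeric(st), rep(1, n_phases))
    ft <- try(stats::optim(p0, obj, method = "L-BFGS-B", lower = lower,
                           upper = upper,
                           control = list(maxit = 800, factr = 1e3)),
              silent = TRUE)
    if (inherits(ft, "try-error")) next
    if (is.null(best) || ft$value < best$value) best <- ft
  }
  if (is.null(best)) stop("Boltzmann fit failed to converge")
  # polish the winner
  ft <- try(stats::optim(best$par, obj, method = "L-BFGS-B", lower = lower,
                         upper = upper,
                         control = list(maxit = 2000, factr = 1e2)),
            silent = TRUE)
  if (!inherits(ft, "try-error") && ft$value < best$value &&
      ft$convergence == 0) best <- ft
  q <- unpack(best$par)
  ord <- order(q$ec50)
  phases <- data.frame(ec50 = q$ec50[ord], h = q$h[ord],
                       fraction = q$fraction[ord])
  structure(list(n_phases = n_phases, phases = phases, baseline = q$base,
                 amplitude = q$amp, rss = best$value,
                 converged = best$convergence == 0,
                 fitted = function(conc)
                   boltzmann_eval(conc, q$base, q$amp, q$ec50, q$h,
                                  q$fraction)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("%d-phase Boltzmann fit: baseline %.4g, amplitude %.4g, rss %.3g%s\n",
              x$n_phases, x$baseline, x$amplitude, x$rss,
              if (x$converged) "" else " (NOT converged)"))
  ph <- x$phases
  ph$ec50_label <- sprintf("%.3g M", ph$ec50)
  print(ph, row.names = FALSE)
  invisible(x)
}

#' Compare 1- vs 2-phase fits with an F-test
#'
#' Nested-model F-test at the given alpha; used by the `auto` phase mode.
#'
#' @param fit1,fit2 Fits from [fit_boltzmann()] on the same data.
#' @param n_points Number of data points.
#' @param alpha Significance level (default 0.05).
#' @return List with `p_value` and `prefer` (1 or 2).
#' @export
compare_phase_fits <- function(fit1, fit2, n_points, alpha = 0.05) {
  df1 <- n_points - (2L + 2L * fit1$n_phases)
  df2 <- n_points - (2L + 2L * fit2$n_phases + 1L)
  if (df2 <= 0) return(list(p_value = NA_real_, prefer = 1L))
  F <- ((fit1$rss - fit2$rss) / (df1 - df2)) / (fit2$rss / df2)
  p <- stats::pf(F, df1 - df2, df2, lower.tail = FALSE)
  list(p_value = p, prefer = if (is.finite(p) && p < alpha) 2L else 1L)
}
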