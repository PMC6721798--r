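#' Competition EMSA binding reaction
#'
#' Describes the two-phase competition protocol used to probe IRP1
#' binding: labeled RNA and protein are pre-incubated without competitor,
#' then unlabeled competitor RNA is added at a fold excess over the
#' labeled probe and the reaction is incubated to equilibrium. Defaults
#' follow the published protocol: 300 pM labeled RNA, 225 nM IRP1, 30 min
#' pre-incubation, 18 h competition (total 1110 min), and
#' `koff = 0.006` per minute. `kon` is not reported by the assay and
#' defaults to 1e6 per molar per minute, which brings the pre-incubation
#' beyond 95% of equilibrium.
#'
#' @param labeled_rna Labeled RNA concentration in molar (default 3e-10).
#' @param protein Protein concentration in molar (default 2.25e-7).
#' @param competitor_fold Competitor excess over labeled RNA
#'   (dimensionless, `>= 0`; 0 means no competitor).
#' @param kon,koff Association (per molar per minute) and dissociation
#'   (per minute) rate constants of the labeled RNA.
#' @param kon_comp,koff_comp Competitor rate constants; default to the
#'   labeled-RNA values.
#' @param preincubation Minutes before competitor addition (default 30).
#' @param duration Total incubation in minutes (default 1110 = 30 min +
#'   18 h).
#' @param inert_fraction Speculative fraction of the labeled complex
#'   present at competitor addition that never exchanges (default 0).
#'   Provided only to mimic a non-exchangeable residual; there is no
#'   direct evidence for it.
#' @return An object of class `"binding_reaction"`.
#' @export
binding_reaction <- function(labeled_rna = 300e-12, protein = 225e-9,
                             competitor_fold = 0,
                             kon = 1e6, koff = 0.006,
                             kon_comp = kon, koff_comp = koff,
                             preincubation = 30, duration = 1110,
                             inert_fraction = 0) {
  r <- list(labeled_rna = labeled_rna, protein = protein,
            competitor_fold = competitor_fold,
            kon = kon, koff = koff,
            kon_comp = kon_comp, koff_comp = koff_comp,
            preincubation = preincubation, duration = duration,
            inert_fraction = inert_fraction)
  with(r, {
    stopifnot(labeled_rna >= 0, protein >= 0, competitor_fold >= 0,
              kon > 0, koff > 0, kon_comp > 0, koff_comp > 0,
              preincubation >= 0, preincubation <= duration,
              inert_fraction >= 0, inert_fraction <= 1)
  })
  structure(r, class = "binding_reaction")
}

#' @export
print.binding_reaction <- function(x, ...) {
  cat("Competition EMSA reaction\n")
  cat(sprintf("  labeled RNA %.3g M, protein %.3g M, competitor %gx\n",
              x$labeled_rna, x$protein, x$competitor_fold))
  cat(sprintf("  kon %.3g /M/min, koff %.3g /min (competitor %.3g, %.3g)\n",
              x$kon, x$koff, x$kon_comp, x$koff_comp))
  cat(sprintf("  pre-incubation %g min, total %g min\n",
              x$preincubation, x$duration))
  invisible(x)
}

# --- adaptive Cash-Karp RK45 -------------------------------------------
# No ODE-solver package ships with this toolchain, so the integrator is
# local. State is in nanomolar; atol 1e-6 nM corresponds to 1e-15 M.
.ck <- list(
  a = list(c2 = 1 / 5,
           c3 = c(3 / 40, 9 / 40),
           c4 = c(3 / 10, -9 / 10, 6 / 5),
           c5 = c(-11 / 54, 5 / 2, -70 / 27, 35 / 27),
           c6 = c(1631 / 55296, 175 / 512, 575 / 13824,
                  44275 / 110592, 253 / 4096)),
  b5 = c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771),
  b4 = c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296, 277 / 14336, 1 / 4)
)

rk45_integrate <- function(rhs, y0, times, atol = 1e-9, rtol = 1e-10,
                           max_steps = 2e6, label = "integration") {
  a <- .ck$a; b5 <- .ck$b5; b4 <- .ck$b4
  ns <- length(y0)
  out <- matrix(NA_real_, length(times), ns)
  out[1, ] <- y0
  t <- times[1]
  y <- y0
  h <- max((times[length(times)] - t) / 1e4, 1e-8)
  steps <- 0L
  for (i in seq_along(times)[-1]) {
    tend <- times[i]
    while (t < tend - 1e-10 * max(1, abs(tend))) {
      h <- min(h, tend - t)
      repeat {
        steps <- steps + 1L
        if (steps > max_steps) {
          stop("stiff-integration failure in ", label, " near t = ",
               signif(t, 6), " min (step budget exceeded)", call. = FALSE)
        }
        k1 <- rhs(t, y)
        k2 <- rhs(t + h / 5, y + h * a$c2 * k1)
        k3 <- rhs(t + 3 * h / 10, y + h * (a$c3[1] * k1 + a$c3[2] * k2))
        k4 <- rhs(t + 3 * h / 5,
                  y + h * (a$c4[1] * k1 + a$c4[2] * k2 + a$c4[3] * k3))
        k5 <- rhs(t + h,
                  y + h * (a$c5[1] * k1 + a$c5[2] * k2 + a$c5[3] * k3 +
                             a$c5[4] * k4))
        k6 <- rhs(t + 7 * h / 8,
                  y + h * (a$c6[1] * k1 + a$c6[2] * k2 + a$c6[3] * k3 +
                             a$c6[4] * k4 + a$c6[5] * k5))
        y5 <- y + h * (b5[1] * k1 + b5[3] * k3 + b5[4] * k4 + b5[6] * k6)
        y4 <- y + h * (b4[1] * k1 + b4[3] * k3 + b4[4] * k4 +
                         b4[5] * k5 + b4[6] * k6)
        sc <- atol + rtol * pmax(abs(y), abs(y5))
        err <- sqrt(mean(((y5 - y4) / sc)^2))
        if (err <= 1 || h < 1e-12) break
        h <- h * max(0.2, 0.9 * err^-0.25)
      }
      t <- t + h
      y <- y5
      if (any(y < -10 * atol)) {
        stop("negative concentration beyond tolerance in ", label,
             " at t = ", signif(t, 6), " min", call. = FALSE)
      }
      y <- pmax(y, 0)
      h <- h * min(5, max(0.2, 0.9 * max(err, 1e-10)^-0.2))
    }
    out[i, ] <- y
  }
  out
}

#' Simulate a two-phase competition EMSA time course
#'
#' Integrates the mass-action scheme
#' `R* + P <-> R*P` and `C + P <-> CP` with a shared free-protein pool.
#' Competitor concentration is zero before the end of the pre-incubation;
#' free species are obtained from conservation, so total RNA, competitor
#' and protein are conserved exactly along the trajectory.
#'
#' @param reaction A [binding_reaction()].
#' @param sample_times Minutes at which to report the labeled bound
#'   fraction; must lie in `[0, duration]`. Default: 121 equally spaced
#'   points over the full duration.
#' @return A data frame of class `"time_course"` with columns `time_min`
#'   and `bound_fraction` (labeled complex over total labeled RNA), with
#'   the reaction and the competitor-addition time stored as attributes.
#' @examples
#' r <- binding_reaction(competitor_fold = 1000, duration = 510)
#' tc <- simulate_competition(r, sample_times = seq(0, 510, by = 30))
#' head(tc)
#' @export
simulate_competition <- function(reaction, sample_times = NULL) {
  stopifnot(inherits(reaction, "binding_reaction"))
  if (is.null(sample_times)) {
    sample_times <- seq(0, reaction$duration, length.out = 121)
  }
  sample_times <- sort(unique(as.numeric(sample_times)))
  if (any(sample_times < 0) || any(sample_times > reaction$duration)) {
    stop("sample_times must lie within [0, duration]", call. = FALSE)
  }
  rtot <- reaction$labeled_rna * 1e9      # nM
  ptot <- reaction$protein * 1e9
  ctot <- reaction$competitor_fold * rtot
  kon <- reaction$kon * 1e-9              # /nM/min
  koff <- reaction$koff
  konc <- reaction$kon_comp * 1e-9
  koffc <- reaction$koff_comp
  tsw <- reaction$preincubation

  rhs1 <- function(t, y) {          # pre-incubation: labeled complex only
    rp <- y[1]
    c(kon * (rtot - rp) * (ptot - rp) - koff * rp, 0)
  }
  pre_times <- unique(c(0, sample_times[sample_times <= tsw], tsw))
  pre <- rk45_integrate(rhs1, c(0, 0), pre_times,
                        label = "pre-incubation phase")
  rp_sw <- pre[nrow(pre), 1]

  inert <- reaction$inert_fraction * rp_sw
  y_sw <- c(rp_sw - inert, 0)       # exchangeable labeled complex, competitor
  rtot_x <- rtot - inert            # labeled RNA still exchanging
  ptot_x <- ptot - inert            # protein sequestered in inert complex
  rhs2 <- function(t, y) {
    rp <- y[1]; cp <- y[2]
    pfree <- ptot_x - rp - cp
    c(kon * (rtot_x - rp) * pfree - koff * rp,
      konc * (ctot - cp) * pfree - koffc * cp)
  }
  post_times <- unique(c(tsw, sample_times[sample_times > tsw]))
  post <- if (length(post_times) > 1L) {
    rk45_integrate(rhs2, y_sw, post_times, label = "competition phase")
  } else {
    matrix(y_sw, nrow = 1)
  }

  bf <- numeric(length(sample_times))
  for (j in seq_along(sample_times)) {
    tj <- sample_times[j]
    bf[j] <- if (tj <= tsw) {
      pre[match(tj, pre_times), 1] / rtot
    } else {
      (post[match(tj, post_times), 1] + inert) / rtot
    }
  }
  structure(
    data.frame(time_min = sample_times, bound_fraction = bf),
    class = c("time_course", "data.frame"),
    reaction = reaction,
    competitor_added = tsw
  )
}

#' Competitive binding equilibrium of a reaction
#'
#' Closed-form (root-solved) equilibrium of the shared-protein
#' competition scheme: solves for free protein from the two binding
#' isotherms and the protein conservation law, by bisection on a
#' monotone scalar equation. Used as the algebraic counterpart of the
#' long-time limit of [simulate_competition()].
#'
#' @param reaction A [binding_reaction()].
#' @return Named vector with `bound_fraction` (labeled), `bound_comp`
#'   (competitor bound fraction) and `free_protein` (molar).
#' @export
equilibrium_bound <- function(reaction) {
  stopifnot(inherits(reaction, "binding_reaction"))
  rtot <- reaction$labeled_rna
  ptot <- reaction$protein
  ctot <- reaction$competitor_fold * rtot
  kd1 <- reaction$koff / reaction$kon
  kd2 <- reaction$koff_comp / reaction$kon_comp
  g <- function(pf) {
    pf + rtot * pf / (kd1 + pf) + ctot * pf / (kd2 + pf) - ptot
  }
  pf <- uniroot(g, c(0, ptot), tol = 1e-18 * max(ptot, 1e-12))$root
  c(bound_fraction = pf / (kd1 + pf),
    bound_comp = pf / (kd2 + pf),
    free_protein = pf)
}

as_time_course <- function(x) {
  x <- as.data.frame(x)
  if (!all(c("time_min", "bound_fraction") %in% names(x))) {
    stop("time course needs columns time_min and bound_fraction",
         call. = FALSE)
  }
  if (is.unsorted(x$time_min[!duplicated(x$time_min)])) {
    x <- x[order(x$time_min), , drop = FALSE]
  }
  x
}

#' Estimate the dissociation rate constant from a chase time course
#'
#' Fits `F(t) = F_inf + (F0 - F_inf) * exp(-koff * (t - t0))` by
#' nonlinear least squares to the post-competitor segment of a time
#' course (replicate points, if present, enter the fit individually).
#'
#' @param tc A time course data frame (`time_min`, `bound_fraction`,
#'   optional `replicate`), e.g. from [simulate_competition()] or
#'   [gen_timecourse()].
#' @param t_min Start of the fitted segment in minutes. Defaults to the
#'   competitor-addition time stored on the object, else 0.
#' @return A list of class `"koff_fit"`: `koff`, `se`, `f0`, `finf`,
#'   `converged`. On a flat or non-decaying curve `converged` is `FALSE`
#'   and the parameters are `NA`.
#' @export
fit_koff <- function(tc, t_min = NULL) {
  if (is.null(t_min)) {
    t_min <- attr(tc, "competitor_added")
    if (is.null(t_min)) t_min <- 0
  }
  tc <- as_time_course(tc)
  seg <- tc[tc$time_min >= t_min, , drop = FALSE]
  if (length(unique(seg$time_min)) < 5) {
    stop("fit_koff needs at least 5 time points past t_min", call. = FALSE)
  }
  failed <- list(koff = NA_real_, se = NA_real_, f0 = NA_real_,
                 finf = NA_real_, converged = FALSE)
  t0 <- min(seg$time_min)
  tt <- seg$time_min - t0
  ff <- seg$bound_fraction
  if (diff(range(ff)) < 1e-10) {
    return(structure(c(failed, list(reason = "flat time course")),
                     class = "koff_fit"))
  }
  finf0 <- min(ff)
  f00 <- max(ff[tt == min(tt)])
  # log-linear start for the rate, guarded against non-positive residuals
  resid0 <- pmax(ff - finf0 + 1e-6 * max(ff), 1e-12)
  k0 <- tryCatch(max(1e-6, -coef(lm(log(resid0) ~ tt))[[2]]),
                 error = function(e) 1e-3)
  fit <- tryCatch(
    nls(ff ~ finf + (f0 - finf) * exp(-k * tt),
        start = list(finf = finf0, f0 = f00, k = k0),
        algorithm = "port",
        lower = c(finf = 0, f0 = 0, k = 1e-10),
        upper = c(finf = 1, f0 = 1, k = Inf),
        control = nls.control(maxiter = 200, scaleOffset = 1,
                              warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(c(failed, list(reason = "nls did not converge")),
                     class = "koff_fit"))
  }
  cf <- coef(fit)
  if (cf[["k"]] <= 1e-9) {
    return(structure(c(failed, list(reason = "no measurable decay")),
                     class = "koff_fit"))
  }
  se <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(koff = cf[["k"]], se = se,
                 f0 = cf[["f0"]], finf = cf[["finf"]],
                 converged = TRUE, reason = NULL),
            class = "koff_fit")
}

#' @export
print.koff_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("koff = %.4g /min (SE %.2g); F0 = %.3g, Finf = %.3g\n",
                x$koff, x$se, x$f0, x$finf))
  } else {
    cat("koff fit failed:", x$reason, "\n")
  }
  invisible(x)
}

#' Has a competition reaction reached equilibrium?
#'
#' Mirrors the experimental checkpoint of comparing the residual bound
#' fraction after two long incubations: returns `TRUE` when the bound
#' fraction changes by at most `tol` between the sampled points nearest
#' to `t1` and `t2`.
#'
#' @param tc A time course data frame.
#' @param t1,t2 Checkpoint times in minutes, `t1 < t2`; `t2` must not
#'   exceed the last sampled time.
#' @param tol Absolute bound-fraction tolerance (default 0.02, below
#'   visual gel-quantification resolution).
#' @return Logical scalar.
#' @export
equilibrium_reached <- function(tc, t1, t2, tol = 0.02) {
  tc <- as_time_course(tc)
  if (t1 >= t2) stop("t1 must be earlier than t2", call. = FALSE)
  if (t2 > max(tc$time_min) + 1e-9) {
    stop("t2 lies beyond the last sampled time (",
         max(tc$time_min), " min)", call. = FALSE)
  }
  f_at <- function(t) {
    i <- which.min(abs(tc$time_min - t))
    mean(tc$bound_fraction[tc$time_min == tc$time_min[i]])
  }
  abs(f_at(t2) - f_at(t1)) <= tol
}

#' Fit a four-parameter logistic competition curve
#'
#' Fits `response = bottom + (top - bottom) / (1 + 10^(hill * (log10(fold)
#' - log10(IC50))))` on the log10 fold-excess axis, the same
#' parameterization used for competition EMSA dose-response curves. The
#' IC50 is the fold excess at the inflection, i.e. halfway between the
#' asymptotes. Curves showing no competition (fitted amplitude under
#' three times the residual scale) or failing to converge are flagged
#' not determinable, mirroring how a non-competing mutant is reported.
#'
#' @param dr Data frame with columns `fold_excess`, `response` and
#'   optional `replicate`; at least 4 distinct fold levels.
#' @param response_limits Optional `c(lower, upper)` physical limits for
#'   the asymptotes (e.g. `c(0, 1)` for bound fractions). Constraining
#'   the plateaus is the standard remedy when the tested fold window
#'   covers only part of the transition. Default: unconstrained.
#' @return A list of class `"dose_response_fit"`: `ic50`, `hill`, `top`,
#'   `bottom`, `se` (named vector), `sigma` (residual scale),
#'   `converged`, `determinable`, `reason`.
#' @export
fit_dose_response <- function(dr, response_limits = NULL) {
  dr <- as.data.frame(dr)
  if (!all(c("fold_excess", "response") %in% names(dr))) {
    stop("dose response needs columns fold_excess and response",
         call. = FALSE)
  }
  if (any(dr$fold_excess <= 0)) stop("fold_excess must be > 0", call. = FALSE)
  if (any(!is.finite(dr$response))) stop("responses must be finite",
                                         call. = FALSE)
  if (length(unique(dr$fold_excess)) < 4) {
    stop("at least 4 distinct fold-excess levels are required",
         call. = FALSE)
  }
  x <- log10(dr$fold_excess)
  y <- dr$response
  nd <- function(reason, sigma = NA_real_) {
    structure(list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
                   bottom = NA_real_, se = NULL, sigma = sigma,
                   converged = FALSE, determinable = FALSE,
                   reason = reason),
              class = "dose_response_fit")
  }
  # pre-fit non-competition guard: the spread of per-fold mean responses
  # must clear the within-fold replicate scatter
  fold_means <- tapply(y, x, mean)
  n_per <- tapply(y, x, length)
  if (any(n_per > 1)) {
    within_sd <- sqrt(mean(unlist(tapply(y, x, function(v) {
      if (length(v) > 1) (v - mean(v))^2 else numeric(0)
    }))))
    if (diff(range(fold_means)) < 3 * within_sd) {
      return(nd("no detectable competition (response range within noise)",
                sigma = within_sd))
    }
  }

  asym_lo <- -Inf
  asym_hi <- Inf
  if (!is.null(response_limits)) {
    stopifnot(length(response_limits) == 2L,
              response_limits[1] < response_limits[2])
    asym_lo <- response_limits[1]
    asym_hi <- response_limits[2]
  }
  top0 <- min(max(y), asym_hi)
  bot0 <- max(min(y), asym_lo)
  best <- NULL
  for (h0 in c(0.5, 1, 2)) {
    for (m0 in quantile(x, c(0.25, 0.5, 0.75), names = FALSE)) {
      fit <- tryCatch(
        nls(y ~ bottom + (top - bottom) / (1 + 10^(hill * (x - logm))),
            start = list(bottom = bot0, top = top0, logm = m0, hill = h0),
            algorithm = "port",
            lower = c(bottom = asym_lo, top = asym_lo, logm = min(x) - 3,
                      hill = 1e-3),
            upper = c(bottom = asym_hi, top = asym_hi, logm = max(x) + 3,
                      hill = 50),
            control = nls.control(maxiter = 200, scaleOffset = 1,
                                  warnOnly = FALSE)),
        error = function(e) NULL)
      if (!is.null(fit) &&
          (is.null(best) || deviance(fit) < deviance(best))) best <- fit
    }
  }
  if (is.null(best)) return(nd("4PL fit did not converge"))
  cf <- coef(best)
  dfres <- max(length(y) - 4L, 1L)
  sigma <- sqrt(deviance(best) / dfres)
  amplitude <- abs(cf[["top"]] - cf[["bottom"]])
  # non-competition guard: amplitude must clear the residual scale; on
  # noiseless data require it to clear a response-scale epsilon instead
  floor_scale <- max(3 * sigma, 1e-6 * max(abs(y), 1))
  if (amplitude < floor_scale) {
    return(nd("no detectable competition (amplitude below residual scale)",
              sigma = sigma))
  }
  if (cf[["logm"]] < min(x) - 2 || cf[["logm"]] > max(x) + 2) {
    return(nd("inflection far outside the tested fold range", sigma = sigma))
  }
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  ic50 <- 10^cf[["logm"]]
  ic50_se <- if (is.finite(se[["logm"]])) log(10) * ic50 * se[["logm"]] else NA
  structure(list(
    ic50 = ic50,
    hill = cf[["hill"]],
    top = max(cf[["top"]], cf[["bottom"]]),
    bottom = min(cf[["top"]], cf[["bottom"]]),
    se = c(ic50 = ic50_se, hill = unname(se[["hill"]]),
           top = unname(se[["top"]]), bottom = unname(se[["bottom"]])),
    sigma = sigma,
    converged = TRUE,
    determinable = TRUE,
    reason = NULL
  ), class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$determinable) {
    cat(sprintf("IC50 = %.4g-fold excess (Hill %.3g; top %.3g, bottom %.3g)\n",
                x$ic50, x$hill, x$top, x$bottom))
  } else {
    cat("IC50 not determinable:", x$reason, "\n")
  }
  invisible(x)
}
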