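#' Three-state occupancy parameters for FTL mRNA
#'
#' The model assumes IRP and eIF3 cannot occupy the same ferritin light
#' chain (FTL) transcript, leaving three mRNA states: bound solely by IRP
#' (`x1`), bound solely by eIF3 (`x2`), and unbound (`x3`). Bound states
#' translate with efficiencies `y1` and `y2` in `[0, 1]` (0 = fully
#' repressed, 1 = unrepressed); the unbound state translates at 1. When a
#' binding site is mutated, the liberated mRNA redistributes to the
#' alternate factor by `alpha` (eIF3-site disruption) or `beta` (IRP-site
#' disruption), with `0 <= alpha + beta <= 1`.
#'
#' Under the normalization used throughout (wild-type readout defined as
#' 1), the reduced predictions eliminate `x3` via
#' `x3 = 1 - y1*x1 - y2*x2`, so `x1`/`x2` are interpreted in rescaled
#' units and may exceed a simplex when mutant readouts greatly exceed 1.
#' The simplex constraint `x1 + x2 + x3 = 1` is therefore enforced only
#' when `x3` is supplied explicitly.
#'
#' @param x1,x2 Fractions bound solely by IRP and solely by eIF3
#'   (non-negative).
#' @param x3 Fraction unbound. Optional; required by [predict_raw()]. When
#'   supplied, `x1 + x2 + x3` must equal 1.
#' @param y1,y2 Translational efficiencies of the IRP-bound and
#'   eIF3-bound states, each in `[0, 1]`.
#' @param alpha,beta Redistributed fractions on eIF3-site and IRP-site
#'   disruption; non-negative with `alpha + beta <= 1`.
#' @return An object of class `"occupancy_params"`.
#' @seealso [predict_raw()], [predict_reduced()], [test_exclusivity()]
#' @examples
#' p <- occupancy_params(x1 = 0.4, x2 = 0.4, x3 = 0.2, y1 = 0, y2 = 0)
#' predict_raw(p)
#' @export
occupancy_params <- function(x1, x2, x3 = NULL, y1, y2, alpha = 0, beta = 0) {
  p <- list(x1 = x1, x2 = x2, x3 = x3, y1 = y1, y2 = y2,
            alpha = alpha, beta = beta)
  validate_occupancy_params(p)
  structure(p, class = "occupancy_params")
}

validate_occupancy_params <- function(p) {
  chk <- function(ok, constraint) {
    if (!isTRUE(ok)) {
      stop("occupancy constraint violated: ", constraint, call. = FALSE)
    }
  }
  num1 <- function(v, nm) {
    chk(is.numeric(v) && length(v) == 1L && is.finite(v),
        paste0(nm, " must be a finite scalar"))
  }
  for (nm in c("x1", "x2", "y1", "y2", "alpha", "beta")) num1(p[[nm]], nm)
  chk(p$x1 >= 0, "x1 >= 0")
  chk(p$x2 >= 0, "x2 >= 0")
  chk(p$y1 >= 0 && p$y1 <= 1, "0 <= y1 <= 1")
  chk(p$y2 >= 0 && p$y2 <= 1, "0 <= y2 <= 1")
  chk(p$alpha >= 0, "alpha >= 0")
  chk(p$beta >= 0, "beta >= 0")
  chk(p$alpha + p$beta <= 1 + 1e-12, "alpha + beta <= 1")
  if (!is.null(p$x3)) {
    num1(p$x3, "x3")
    chk(p$x3 >= 0, "x3 >= 0")
    chk(abs(p$x1 + p$x2 + p$x3 - 1) <= 1e-9, "x1 + x2 + x3 = 1")
  }
  invisible(p)
}

#' @export
print.occupancy_params <- function(x, ...) {
  cat("Three-state occupancy parameters\n")
  cat(sprintf("  x1 (IRP-bound)  = %g\n", x$x1))
  cat(sprintf("  x2 (eIF3-bound) = %g\n", x$x2))
  if (!is.null(x$x3)) cat(sprintf("  x3 (unbound)    = %g\n", x$x3))
  cat(sprintf("  y1, y2 = %g, %g;  alpha, beta = %g, %g\n",
              x$y1, x$y2, x$alpha, x$beta))
  invisible(x)
}

#' Predict raw reporter outputs from the exclusive-binding model
#'
#' Forward model for the four luciferase reporter constructs:
#' wild type (`FTL`), the eIF3 repressive-element deletion (`D3RE`), the
#' IRE apical-loop mutant that abolishes IRP binding (`LOOP`), and the
#' combination (`DOUBLE`):
#' \deqn{FTL = y_1 x_1 + y_2 x_2 + x_3}
#' \deqn{\Delta 3RE = y_1 (x_1 + \alpha) + x_2 - \alpha + x_3}
#' \deqn{Loop = x_1 - \beta + y_2 (x_2 + \beta) + x_3}
#' \deqn{Double = x_1 + x_2 + x_3}
#'
#' @param params An [occupancy_params()] object with `x3` supplied.
#' @return Named numeric vector with elements `FTL`, `D3RE`, `LOOP`,
#'   `DOUBLE`.
#' @export
predict_raw <- function(params) {
  validate_occupancy_params(params)
  if (is.null(params$x3)) {
    stop("predict_raw() requires x3; use predict_reduced() for the ",
         "normalized three-equation form", call. = FALSE)
  }
  with(params, c(
    FTL    = y1 * x1 + y2 * x2 + x3,
    D3RE   = y1 * (x1 + alpha) + x2 - alpha + x3,
    LOOP   = x1 - beta + y2 * (x2 + beta) + x3,
    DOUBLE = x1 + x2 + x3
  ))
}

#' Predict normalized reporter outputs with the unbound fraction eliminated
#'
#' Uses the wild-type normalization `FTL = 1` to eliminate `x3`
#' (`x3 = 1 - y1*x1 - y2*x2`), giving
#' \deqn{\Delta 3RE = 1 + y_1\alpha - \alpha + (1 - y_2) x_2}
#' \deqn{Loop = 1 + y_2\beta - \beta + (1 - y_1) x_1}
#' \deqn{Double = 1 + (1 - y_1) x_1 + (1 - y_2) x_2}
#'
#' @inheritParams predict_raw
#' @return Named numeric vector with elements `D3RE`, `LOOP`, `DOUBLE`.
#' @export
predict_reduced <- function(params) {
  validate_occupancy_params(params)
  with(params, c(
    D3RE   = 1 + y1 * alpha - alpha + (1 - y2) * x2,
    LOOP   = 1 + y2 * beta - beta + (1 - y1) * x1,
    DOUBLE = 1 + (1 - y1) * x1 + (1 - y2) * x2
  ))
}

#' Bracket term of the exclusivity identity
#'
#' The exclusive-binding model implies
#' `Double = Loop + D3RE + (alpha + beta - y1*alpha - y2*beta - 1)`.
#' The bracketed term is bounded in `[-1, 0]` over the constraint box, so
#' the model can never predict `Double > Loop + D3RE`.
#'
#' @param y1,y2 Translational efficiencies in `[0, 1]`.
#' @param alpha,beta Redistribution fractions, `alpha + beta <= 1`.
#' @return Scalar value of `alpha + beta - y1*alpha - y2*beta - 1`.
#' @export
bracket_term <- function(y1, y2, alpha, beta) {
  validate_occupancy_params(list(x1 = 0, x2 = 0, x3 = NULL,
                                 y1 = y1, y2 = y2,
                                 alpha = alpha, beta = beta))
  alpha + beta - y1 * alpha - y2 * beta - 1
}

#' Feasible range of the exclusivity right-hand side
#'
#' Given measured `Loop` and `D3RE` means, the exclusive model constrains
#' the predicted `Double` readout to
#' `[Loop + D3RE - 1, Loop + D3RE]` because the bracket term lies in
#' `[-1, 0]`.
#'
#' @param loop_mean,d3re_mean Positive normalized reporter means.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' rhs_bounds(12.5, 4.4)  # upper bound 16.9
#' @export
rhs_bounds <- function(loop_mean, d3re_mean) {
  if (!is.numeric(loop_mean) || !is.numeric(d3re_mean) ||
      length(loop_mean) != 1L || length(d3re_mean) != 1L ||
      !is.finite(loop_mean) || !is.finite(d3re_mean) ||
      loop_mean <= 0 || d3re_mean <= 0) {
    stop("loop_mean and d3re_mean must be positive finite scalars",
         call. = FALSE)
  }
  s <- loop_mean + d3re_mean
  c(lower = s - 1, upper = s)
}

#' Per-construct reporter readouts
#'
#' Validates a table of normalized luciferase readouts, one row per
#' construct with columns `construct`, `mean`, `sd`, `n`. Construct names
#' are canonicalized case-insensitively; `Δ3RE`/`∆3RE`/`DELTA3RE` map to
#' `D3RE` and `ΔPAR`/`DELTAPAR` to `DPAR`.
#'
#' @param x A data frame with columns `construct`, `mean`, `sd`, `n`.
#' @return The validated data frame with class `"construct_readouts"`.
#' @export
construct_readouts <- function(x) {
  x <- as.data.frame(x)
  need <- c("construct", "mean", "sd", "n")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  x$construct <- canonical_construct(x$construct)
  if (anyDuplicated(x$construct)) {
    stop("duplicated construct entries: ",
         paste(unique(x$construct[duplicated(x$construct)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(x$mean) || any(!is.finite(x$mean)) || any(x$mean <= 0)) {
    stop("construct means must be positive and finite", call. = FALSE)
  }
  if (!is.numeric(x$sd) || any(!is.finite(x$sd)) || any(x$sd < 0)) {
    stop("construct sds must be non-negative and finite", call. = FALSE)
  }
  if (any(x$n < 1)) stop("replicate counts n must be >= 1", call. = FALSE)
  class(x) <- c("construct_readouts", "data.frame")
  x
}

canonical_construct <- function(nm) {
  nm <- toupper(trimws(as.character(nm)))
  nm <- gsub("Δ|∆", "DELTA", nm)   # Greek/Unicode deltas
  nm[nm %in% c("DELTA3RE", "D3RE", "3RE")] <- "D3RE"
  nm[nm %in% c("DELTAPAR", "DPAR", "PAR")] <- "DPAR"
  nm[nm %in% c("WT", "WILDTYPE", "WILD-TYPE")] <- "FTL"
  nm
}

readout_row <- function(readouts, construct) {
  i <- match(construct, readouts$construct)
  if (is.na(i)) {
    stop("readouts are missing the ", construct, " construct", call. = FALSE)
  }
  readouts[i, , drop = FALSE]
}

#' Test whether readouts are consistent with mutually exclusive binding
#'
#' Point test: the exclusive model is feasible only if
#' `Double <= Loop + D3RE` (see [rhs_bounds()]). Probabilistic test:
#' each construct mean is resampled from a normal with its reported SD,
#' truncated at zero by resampling, and `p_consistent` is the fraction of
#' draws satisfying the inequality. A standardized exceedance
#' `z = (Double - Loop - D3RE) / sqrt(sd_D^2 + sd_L^2 + sd_R^2)` is also
#' reported.
#'
#' @param readouts A [construct_readouts()] table (or coercible data
#'   frame) containing `D3RE`, `LOOP` and `DOUBLE` rows.
#' @param n_draws Number of Monte-Carlo draws (default 100000). Values
#'   below 1000 trigger a warning but are still computed.
#' @param seed Integer seed; the verdict is reproducible bit-for-bit.
#' @return An object of class `"exclusivity_verdict"`: a list with
#'   `rhs_lower`, `rhs_upper`, `point_consistent`, `p_consistent`,
#'   `z_score`, `n_draws`, `seed`, and the construct means used.
#' @examples
#' paper <- construct_readouts(data.frame(
#'   construct = c("D3RE", "LOOP", "DOUBLE"),
#'   mean = c(4.4, 12.5, 41.8), sd = c(0.4, 2.9, 6.5), n = 6))
#' test_exclusivity(paper, n_draws = 10000)
#' @export
test_exclusivity <- function(readouts, n_draws = 100000L, seed = 2019L) {
  readouts <- construct_readouts(readouts)
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  if (n_draws < 1000) {
    warning("n_draws < 1000: Monte-Carlo error on p_consistent may exceed 2%",
            call. = FALSE)
  }
  d3 <- readout_row(readouts, "D3RE")
  lo <- readout_row(readouts, "LOOP")
  db <- readout_row(readouts, "DOUBLE")
  if (any(!is.finite(c(d3$sd, lo$sd, db$sd)))) {
    stop("finite sds are required for error propagation", call. = FALSE)
  }
  bounds <- rhs_bounds(lo$mean, d3$mean)
  z <- (db$mean - lo$mean - d3$mean) /
    sqrt(db$sd^2 + lo$sd^2 + d3$sd^2)
  p <- withr::with_seed(as.integer(seed), {
    draw <- function(m, s) rnorm_trunc0(n_draws, m, s)
    mean(draw(db$mean, db$sd) <= draw(lo$mean, lo$sd) + draw(d3$mean, d3$sd))
  })
  structure(list(
    rhs_lower = unname(bounds["lower"]),
    rhs_upper = unname(bounds["upper"]),
    point_consistent = db$mean <= bounds[["upper"]],
    p_consistent = p,
    z_score = z,
    n_draws = as.integer(n_draws),
    seed = as.integer(seed),
    means = c(D3RE = d3$mean, LOOP = lo$mean, DOUBLE = db$mean),
    sds = c(D3RE = d3$sd, LOOP = lo$sd, DOUBLE = db$sd)
  ), class = "exclusivity_verdict")
}

# Zero-truncated normal draws by resampling negative values, so the
# distribution matches "resample on negative draws" exactly.
rnorm_trunc0 <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(neg <- x < 0)) x[neg] <- rnorm(sum(neg), mean, sd)
  x
}

#' @export
print.exclusivity_verdict <- function(x, ...) {
  cat("Exclusive-binding consistency test\n")
  cat(sprintf("  Double = %.3g vs feasible RHS [%.3g, %.3g]\n",
              x$means[["DOUBLE"]], x$rhs_lower, x$rhs_upper))
  cat(sprintf("  point_consistent = %s\n", x$point_consistent))
  cat(sprintf("  p_consistent = %.4g  (n_draws = %d, seed = %d)\n",
              x$p_consistent, x$n_draws, x$seed))
  cat(sprintf("  z_score = %.3f\n", x$z_score))
  if (!x$point_consistent) {
    cat("  -> exclusive binding is inconsistent with the readouts;\n")
    cat("     IRP and eIF3 likely act in cis on the same mRNA\n")
  }
  invisible(x)
}

#' Constrained least-squares feasibility fit of the exclusive model
#'
#' Inverts the reduced predictions ([predict_reduced()]) by minimizing the
#' SD-weighted squared residual against the measured `D3RE`, `LOOP` and
#' `DOUBLE` means over the constrained box (`x1, x2 >= 0`,
#' `y1, y2 in [0,1]`, `alpha, beta >= 0`, `alpha + beta <= 1`), using a
#' multi-start bounded local search on a Latin-hypercube of starting
#' points. The map from parameters to predictions is not injective, so the
#' contract is on the recovered predictions, not the parameters.
#'
#' @inheritParams test_exclusivity
#' @param n_starts Number of Latin-hypercube starting points (default 32).
#' @param x_max Upper bound of the search box for `x1`, `x2`. Defaults to
#'   twice the largest observed mean (rescaled units; see
#'   [occupancy_params()]).
#' @param seed Integer seed for the start design.
#' @return A list of class `"exclusive_fit"`: best-fit `params`
#'   (an [occupancy_params()] without `x3`), `fitted` predictions,
#'   `chisq`, `feasible` (`chisq` below the 95th percentile of a
#'   chi-square with 3 d.o.f.), and `converged`.
#' @export
fit_exclusive <- function(readouts, n_starts = 32L, x_max = NULL, seed = 1L) {
  readouts <- construct_readouts(readouts)
  d3 <- readout_row(readouts, "D3RE")
  lo <- readout_row(readouts, "LOOP")
  db <- readout_row(readouts, "DOUBLE")
  target <- c(D3RE = d3$mean, LOOP = lo$mean, DOUBLE = db$mean)
  w <- 1 / pmax(c(d3$sd, lo$sd, db$sd), 1e-6)^2
  if (is.null(x_max)) x_max <- max(2 * max(target), 1)

  # theta = (x1, x2, y1, y2, alpha, s) with beta = s * (1 - alpha),
  # which maps the unit box onto {alpha + beta <= 1} smoothly.
  unpack <- function(th) {
    list(x1 = th[1], x2 = th[2], x3 = NULL, y1 = th[3], y2 = th[4],
         alpha = th[5], beta = th[6] * (1 - th[5]))
  }
  obj <- function(th) {
    p <- unpack(th)
    pred <- c(
      1 + p$y1 * p$alpha - p$alpha + (1 - p$y2) * p$x2,
      1 + p$y2 * p$beta - p$beta + (1 - p$y1) * p$x1,
      1 + (1 - p$y1) * p$x1 + (1 - p$y2) * p$x2
    )
    sum(w * (pred - target)^2)
  }
  lower <- rep(0, 6)
  upper <- c(x_max, x_max, 1, 1, 1, 1)
  starts <- withr::with_seed(as.integer(seed),
                             latin_hypercube(n_starts, lower, upper))
  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], obj, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(fit)) next
    any_conv <- any_conv || fit$convergence == 0
    if (is.null(best) ||
        fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 &&
         lexicographically_less(fit$par, best$par))) {
      best <- fit
    }
  }
  if (is.null(best)) stop("fit_exclusive: all optimizer starts failed",
                          call. = FALSE)
  p <- unpack(best$par)
  params <- structure(p, class = "occupancy_params")
  structure(list(
    params = params,
    fitted = predict_reduced(params),
    target = target,
    chisq = best$value,
    feasible = best$value <= qchisq(0.95, df = 3),
    converged = any_conv,
    n_starts = as.integer(n_starts)
  ), class = "exclusive_fit")
}

lexicographically_less <- function(a, b) {
  d <- a - b
  i <- which(abs(d) > 1e-12)[1]
  !is.na(i) && d[i] < 0
}

# Maximin-free Latin hypercube: one stratified uniform draw per dimension,
# rows randomly permuted per column.
latin_hypercube <- function(n, lower, upper) {
  d <- length(lower)
  u <- vapply(seq_len(d), function(j) (sample.int(n) - runif(n)) / n,
              numeric(n))
  u <- matrix(u, nrow = n)
  sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
}

#' @export
print.exclusive_fit <- function(x, ...) {
  cat("Exclusive-model feasibility fit\n")
  cat(sprintf("  chi-square = %.4g (95%% cut-off %.3f, 3 d.o.f.)\n",
              x$chisq, qchisq(0.95, 3)))
  cat(sprintf("  feasible = %s, converged = %s\n", x$feasible, x$converged))
  cat("  fitted vs target:\n")
  for (nm in names(x$fitted)) {
    cat(sprintf("    %-6s %.4g  (measured %.4g)\n",
                nm, x$fitted[[nm]], x$target[[nm]]))
  }
  invisible(x)
}
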