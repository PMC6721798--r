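#' Parameters for synthetic reporter-table generation
#'
#' Three generative modes:
#' * `"exclusive"` — construct means come from [predict_raw()] under the
#'   three-state exclusive-binding model, then are normalized to the
#'   wild-type mean.
#' * `"cobinding"` — a fourth state (`x4`, bound by both factors
#'   simultaneously) is added. The doubly-bound state translates at
#'   `y1 * y2` (independent repression, the default) or `min(y1, y2)`.
#'   Site disruption fully liberates the corresponding factor from both
#'   the singly- and doubly-bound states; this co-binding rule is a
#'   stated assumption of the generator, not a measured mechanism.
#' * fold-override — `fold_targets` names per-construct mean folds
#'   directly (e.g. `c(DPAR = 38, D3RE = 6)`, the published effect
#'   sizes), bypassing the occupancy model.
#'
#' Replicate noise is multiplicative log-normal with coefficient of
#' variation `cv` (luminescence is strictly positive and spans a
#' ~40-fold range, so additive noise would be unrealistic).
#'
#' @param mode `"exclusive"` or `"cobinding"`; ignored when
#'   `fold_targets` is supplied.
#' @param occupancy An [occupancy_params()] with `x3` supplied (the
#'   generator works on the raw simplex scale).
#' @param x4 Co-binding mode only: fraction bound by both factors;
#'   `x1 + x2 + x3 + x4` must equal 1.
#' @param cobind_rule `"product"` (`y1*y2`) or `"min"` (`min(y1, y2)`).
#' @param fold_targets Optional named vector of per-construct fold
#'   means relative to wild type; a `FTL` entry of 1 is implied.
#' @param n Replicates per construct (default 3, the biological
#'   replicate count of the reporter assays; the consistency analyses
#'   use n = 100).
#' @param cv Noise coefficient of variation (default 0.10).
#' @param seed Integer seed; generation is a pure function of
#'   (parameters, seed).
#' @return An object of class `"reporter_gen_params"`.
#' @export
reporter_gen_params <- function(mode = c("exclusive", "cobinding"),
                                occupancy = NULL, x4 = 0,
                                cobind_rule = c("product", "min"),
                                fold_targets = NULL,
                                n = 3L, cv = 0.10, seed = 1L) {
  mode <- match.arg(mode)
  cobind_rule <- match.arg(cobind_rule)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (is.null(fold_targets)) {
    if (is.null(occupancy)) {
      stop("either occupancy parameters or fold_targets must be given",
           call. = FALSE)
    }
    validate_occupancy_params(occupancy)
    if (mode == "exclusive" && is.null(occupancy$x3)) {
      stop("exclusive mode needs occupancy with x3 on the simplex",
           call. = FALSE)
    }
    if (mode == "cobinding") {
      # x3 is the four-state remainder 1 - x1 - x2 - x4; a supplied x3
      # would impose the three-state simplex, which cannot hold with x4
      if (!is.null(occupancy$x3)) {
        stop("co-binding mode derives x3 from the four-state simplex; ",
             "supply occupancy without x3", call. = FALSE)
      }
      if (x4 < 0) stop("x4 must be >= 0", call. = FALSE)
      if (occupancy$x1 + occupancy$x2 + x4 > 1 + 1e-9) {
        stop("fractions including x4 must sum to <= 1", call. = FALSE)
      }
    }
  } else {
    if (is.null(names(fold_targets)) || any(fold_targets <= 0)) {
      stop("fold_targets must be a named vector of positive folds",
           call. = FALSE)
    }
  }
  structure(list(mode = mode, occupancy = occupancy, x4 = x4,
                 cobind_rule = cobind_rule, fold_targets = fold_targets,
                 n = as.integer(n), cv = cv, seed = as.integer(seed)),
            class = "reporter_gen_params")
}

cobinding_means <- function(p) {
  o <- p$occupancy
  x4 <- p$x4
  x3 <- 1 - o$x1 - o$x2 - x4
  y12 <- if (p$cobind_rule == "product") o$y1 * o$y2 else min(o$y1, o$y2)
  c(FTL    = o$y1 * o$x1 + o$y2 * o$x2 + x3 + y12 * x4,
    D3RE   = o$y1 * o$x1 + o$x2 + x3 + o$y1 * x4,
    LOOP   = o$x1 + o$y2 * o$x2 + x3 + o$y2 * x4,
    DOUBLE = o$x1 + o$x2 + x3 + x4)
}

#' Generate a synthetic reporter table
#'
#' Construct means are computed per the generative mode of
#' [reporter_gen_params()]; each replicate is the mean times a
#' mean-one log-normal factor with the requested CV; finally the whole
#' table is renormalized so the generated wild-type mean is exactly 1,
#' mimicking assay-level normalization.
#'
#' @param params A [reporter_gen_params()].
#' @return A data frame of class `"reporter_table"` with columns
#'   `construct`, `replicate`, `value`.
#' @examples
#' p <- reporter_gen_params(fold_targets = c(DPAR = 38, D3RE = 6),
#'                          n = 10, cv = 0.1, seed = 7)
#' estimate_folds(gen_reporter(p))
#' @export
gen_reporter <- function(params) {
  stopifnot(inherits(params, "reporter_gen_params"))
  means <- if (!is.null(params$fold_targets)) {
    ft <- params$fold_targets
    names(ft) <- canonical_construct(names(ft))
    if (!"FTL" %in% names(ft)) ft <- c(FTL = 1, ft)
    ft
  } else if (params$mode == "exclusive") {
    raw <- predict_raw(params$occupancy)
    raw / raw[["FTL"]]
  } else {
    raw <- cobinding_means(params)
    raw / raw[["FTL"]]
  }
  if (any(means <= 0)) {
    stop("generative construct means must be positive; got ",
         paste(signif(means, 3), collapse = ", "), call. = FALSE)
  }
  sdlog <- sqrt(log1p(params$cv^2))
  tbl <- withr::with_seed(params$seed, {
    do.call(rbind, lapply(names(means), function(cn) {
      noise <- exp(rnorm(params$n, -sdlog^2 / 2, sdlog))  # mean-one
      data.frame(construct = cn, replicate = seq_len(params$n),
                 value = means[[cn]] * noise)
    }))
  })
  wt <- mean(tbl$value[tbl$construct == "FTL"])
  tbl$value <- tbl$value / wt
  structure(tbl, class = c("reporter_table", "data.frame"))
}

#' Summaries of a reporter table
#'
#' `estimate_folds()` returns per-construct mean folds relative to the
#' wild-type mean; `summarize_reporter()` condenses a replicate-level
#' table into a [construct_readouts()] summary (mean, SD, n), normalized
#' so the wild-type mean is 1 — the analysis stage that feeds
#' [test_exclusivity()].
#'
#' @param tbl A reporter table with columns `construct`, `value`.
#' @return `estimate_folds()`: named numeric vector.
#'   `summarize_reporter()`: a [construct_readouts()] data frame.
#' @export
estimate_folds <- function(tbl) {
  tbl <- as.data.frame(tbl)
  stopifnot(all(c("construct", "value") %in% names(tbl)))
  tbl$construct <- canonical_construct(tbl$construct)
  m <- tapply(tbl$value, tbl$construct, mean)
  if (!"FTL" %in% names(m)) {
    stop("reporter table has no FTL (wild-type) rows", call. = FALSE)
  }
  folds <- setNames(as.numeric(m) / m[["FTL"]], names(m))
  folds[order(match(names(folds), c("FTL", "DPAR", "D3RE", "LOOP",
                                    "DOUBLE")))]
}

#' @rdname estimate_folds
#' @export
summarize_reporter <- function(tbl) {
  tbl <- as.data.frame(tbl)
  stopifnot(all(c("construct", "value") %in% names(tbl)))
  tbl$construct <- canonical_construct(tbl$construct)
  wt <- mean(tbl$value[tbl$construct == "FTL"])
  if (!is.finite(wt) || wt <= 0) {
    stop("reporter table has no usable FTL (wild-type) rows", call. = FALSE)
  }
  agg <- do.call(rbind, lapply(split(tbl, tbl$construct), function(d) {
    data.frame(construct = d$construct[1],
               mean = mean(d$value) / wt,
               sd = if (nrow(d) > 1) sd(d$value) / wt else 0,
               n = nrow(d))
  }))
  rownames(agg) <- NULL
  construct_readouts(agg)
}

#' Generate a noisy EMSA time course
#'
#' Runs [simulate_competition()] once and overlays additive Gaussian
#' noise (clipped to `[0, 1]`) per replicate; gel-derived bound
#' fractions are background-subtracted, so additive noise is the
#' appropriate layer.
#'
#' @param reaction A [binding_reaction()].
#' @param noise_sd Additive noise SD on the bound fraction
#'   (default 0.02, ~2% of full scale).
#' @param n_points Number of equally spaced sample times over
#'   `[0, duration]`.
#' @param seed Integer seed.
#' @param n_rep Number of noise replicates sharing the one simulated
#'   trajectory.
#' @return A data frame of class `"time_course"` with columns
#'   `time_min`, `bound_fraction`, `replicate`.
#' @export
gen_timecourse <- function(reaction, noise_sd = 0.02, n_points = 50L,
                           seed = 1L, n_rep = 1L) {
  stopifnot(noise_sd >= 0, n_points >= 2, n_rep >= 1)
  times <- seq(0, reaction$duration, length.out = n_points)
  base <- simulate_competition(reaction, times)
  out <- withr::with_seed(as.integer(seed), {
    do.call(rbind, lapply(seq_len(n_rep), function(r) {
      bf <- base$bound_fraction + rnorm(n_points, 0, noise_sd)
      data.frame(time_min = base$time_min,
                 bound_fraction = pmin(pmax(bf, 0), 1),
                 replicate = r)
    }))
  })
  structure(out, class = c("time_course", "data.frame"),
            reaction = reaction,
            competitor_added = reaction$preincubation)
}

#' Generate a noisy competition dose-response table
#'
#' Simulates the competition reaction at each fold excess, reads the
#' labeled bound fraction at `read_time` (default: end of the
#' incubation), and overlays additive Gaussian noise clipped to
#' `[0, 1]`.
#'
#' @param reaction Template [binding_reaction()]; its `competitor_fold`
#'   is replaced by each entry of `folds`.
#' @param folds Vector of competitor fold excesses (> 0).
#' @param noise_sd Additive noise SD (default 0.02).
#' @param seed Integer seed.
#' @param n_rep Replicates per fold.
#' @param read_time Minutes at which the gel is read (default
#'   `reaction$duration`).
#' @return A data frame of class `"dose_response"` with columns
#'   `fold_excess`, `response`, `replicate`.
#' @export
gen_dose_response <- function(reaction, folds, noise_sd = 0.02,
                              seed = 1L, n_rep = 1L,
                              read_time = reaction$duration) {
  stopifnot(all(folds > 0), noise_sd >= 0, n_rep >= 1)
  clean <- vapply(folds, function(f) {
    r <- reaction
    r$competitor_fold <- f
    tc <- simulate_competition(r, c(0, read_time))
    tc$bound_fraction[2]
  }, numeric(1))
  out <- withr::with_seed(as.integer(seed), {
    do.call(rbind, lapply(seq_len(n_rep), function(rep) {
      resp <- clean + rnorm(length(folds), 0, noise_sd)
      data.frame(fold_excess = folds,
                 response = pmin(pmax(resp, 0), 1),
                 replicate = rep)
    }))
  })
  structure(out, class = c("dose_response", "data.frame"),
            reaction = reaction, read_time = read_time)
}
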