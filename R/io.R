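#' Read a reporter readout table from CSV
#'
#' Expects a header `construct,mean,sd,n`. Extra columns are ignored
#' with a warning; malformed numeric cells and unknown construct names
#' are reported with their line numbers. Construct names are matched
#' case-insensitively against the canonical set (`FTL`, `D3RE`, `LOOP`,
#' `DOUBLE`, `DPAR`, plus Greek-delta spellings).
#'
#' @param path Path to a CSV file.
#' @param allowed Canonical construct names accepted; `NULL` accepts
#'   anything.
#' @return A [construct_readouts()] data frame.
#' @export
load_readouts <- function(path,
                          allowed = c("FTL", "D3RE", "LOOP", "DOUBLE",
                                      "DPAR")) {
  raw <- read_table_checked(path, required = c("construct", "mean",
                                               "sd", "n"))
  for (col in c("mean", "sd", "n")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) {
      stop("non-numeric ", col, " in ", path, " at line(s) ",
           paste(bad + 1L, collapse = ", "), call. = FALSE)
    }
    raw[[col]] <- v
  }
  raw$construct <- canonical_construct(raw$construct)
  if (!is.null(allowed)) {
    bad <- which(!raw$construct %in% allowed)
    if (length(bad)) {
      stop("unknown construct name(s) in ", path, " at line(s) ",
           paste(bad + 1L, collapse = ", "), ": ",
           paste(unique(raw$construct[bad]), collapse = ", "),
           call. = FALSE)
    }
  }
  construct_readouts(raw[, c("construct", "mean", "sd", "n")])
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    check.names = FALSE),
    error = function(e) {
      stop("could not parse ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  if (nrow(raw) == 0L) stop(path, " contains no data rows", call. = FALSE)
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    stop(path, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(raw), c(required, "replicate"))
  if (length(extra)) {
    warning("ignoring unused column(s) in ", path, ": ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  raw
}

#' Read an EMSA time course from CSV
#'
#' Schema: `time_min,bound_fraction[,replicate]`.
#'
#' @param path Path to a CSV file.
#' @return A `"time_course"` data frame sorted by time.
#' @export
load_timecourse <- function(path) {
  raw <- read_table_checked(path, c("time_min", "bound_fraction"))
  for (col in c("time_min", "bound_fraction")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("non-numeric ", col, " in ", path, " at line(s) ",
           paste(bad + 1L, collapse = ", "), call. = FALSE)
    }
    raw[[col]] <- v
  }
  if (any(raw$bound_fraction < 0 | raw$bound_fraction > 1)) {
    stop("bound_fraction values in ", path, " must lie in [0, 1]",
         call. = FALSE)
  }
  keep <- intersect(c("time_min", "bound_fraction", "replicate"),
                    names(raw))
  out <- raw[order(raw$time_min), keep, drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("time_course", "data.frame"))
}

#' Read a competition dose-response table from CSV
#'
#' Schema: `fold_excess,response[,replicate]`.
#'
#' @param path Path to a CSV file.
#' @return A `"dose_response"` data frame.
#' @export
load_doseresponse <- function(path) {
  raw <- read_table_checked(path, c("fold_excess", "response"))
  for (col in c("fold_excess", "response")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("non-numeric ", col, " in ", path, " at line(s) ",
           paste(bad + 1L, collapse = ", "), call. = FALSE)
    }
    raw[[col]] <- v
  }
  if (any(raw$fold_excess <= 0)) {
    stop("fold_excess values in ", path, " must be > 0", call. = FALSE)
  }
  keep <- intersect(c("fold_excess", "response", "replicate"), names(raw))
  out <- raw[, keep, drop = FALSE]
  structure(out, class = c("dose_response", "data.frame"))
}

#' Read 5'-UTR sequences from FASTA
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of sequences over A/C/G/U/T.
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  bad <- which(!grepl("^[ACGUTacgut]+$", seqs))
  if (length(bad)) {
    stop("sequence(s) ", paste(names(seqs)[bad], collapse = ", "),
         " in ", path, " contain characters outside A/C/G/U/T",
         call. = FALSE)
  }
  seqs
}

#' Read an element map from YAML or JSON
#'
#' Recognised keys (all optional, defaults from [element_map()]):
#' `par`, `re3`, `ire` (two-element start/end), `loop_positions`,
#' `bulge`, `cap_distance` (named), `steric_threshold`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [element_map()].
#' @export
load_element_map <- function(path) {
  cfg <- load_config(path)
  args <- list()
  if (!is.null(cfg$par)) args$par <- unlist(cfg$par)
  if (!is.null(cfg$re3)) args$re3 <- unlist(cfg$re3)
  if (!is.null(cfg$ire)) args$ire <- unlist(cfg$ire)
  if (!is.null(cfg$loop_positions)) {
    args$loop_positions <- unlist(cfg$loop_positions)
  }
  if (!is.null(cfg$bulge)) args$bulge <- cfg$bulge
  if (!is.null(cfg$cap_distance)) {
    args$cap_distance <- unlist(cfg$cap_distance)
  }
  if (!is.null(cfg$steric_threshold)) {
    args$steric_threshold <- cfg$steric_threshold
  }
  do.call(element_map, args)
}

load_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json: ", path, call. = FALSE)
  }
}

# Stable JSON output: 12 significant digits, scalars unboxed.
write_json_stable <- function(x, path) {
  round12 <- function(v) {
    if (is.numeric(v)) signif(v, 12) else if (is.list(v)) {
      lapply(v, round12)
    } else v
  }
  jsonlite::write_json(round12(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write an exclusivity verdict to JSON
#'
#' Serializes the verdict fields plus provenance (input path, seed,
#' draw count, package version) with 12-significant-digit floats so
#' reruns are byte-identical.
#'
#' @param verdict An `"exclusivity_verdict"` from [test_exclusivity()].
#' @param path Output JSON path.
#' @param input Optional input path recorded as provenance.
#' @return The path, invisibly.
#' @export
write_verdict <- function(verdict, path, input = NA_character_) {
  stopifnot(inherits(verdict, "exclusivity_verdict"))
  doc <- list(
    rhs_lower = verdict$rhs_lower,
    rhs_upper = verdict$rhs_upper,
    point_consistent = verdict$point_consistent,
    p_consistent = verdict$p_consistent,
    z_score = verdict$z_score,
    n_draws = verdict$n_draws,
    seed = verdict$seed,
    means = as.list(verdict$means),
    sds = as.list(verdict$sds),
    provenance = list(
      input = input,
      package = "ftlreg",
      version = as.character(utils::packageVersion("ftlreg"))
    )
  )
  write_json_stable(doc, path)
}

#' Run the full generate-analyze-report pipeline
#'
#' Executes, in order: reporter-table generation (or loading),
#' exclusive-binding consistency testing, EMSA time-course simulation
#' and k_off fitting, dose-response simulation and IC50 fitting, and
#' variant annotation; then writes a report bundle (readouts CSV,
#' verdict/fit JSONs, variant table, plain-text summary) into the
#' output directory. Any stage failure aborts with the stage name;
#' outputs of completed stages are preserved. Outputs carry seeds and
#' the package version and contain no timestamps, so reruns with the
#' same config are byte-identical.
#'
#' @param config A list, or path to a YAML/JSON file, with (all
#'   optional) entries: `seed`, `n_draws`, `out_dir`,
#'   `readouts` (path to a readout CSV; otherwise a table is
#'   generated), `reporter` (list passed to [reporter_gen_params()]:
#'   `fold_targets`, `n`, `cv`), `kinetics` (list: `koff`, `kon`,
#'   `competitor_fold`, `duration`, `folds`, `noise_sd`, `n_points`),
#'   `variants` (character vector of labels).
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisible list with the in-memory results (`readouts`,
#'   `verdict`, `koff_fit`, `ic50_fit`, `variants`, `paths`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- load_config(config)
  }
  stopifnot(is.list(config))
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("an output directory is required",
                             call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 2019L)
  n_draws <- as.integer(config$n_draws %||% 100000L)
  paths <- new.env(parent = emptyenv())  # stages add entries by reference
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           "\n(outputs of earlier stages are preserved in ", out_dir, ")",
           call. = FALSE)
    })
  }

  # -- reporter stage ----------------------------------------------------
  readouts <- stage("reporter", {
    if (!is.null(config$readouts)) {
      load_readouts(config$readouts)
    } else {
      rep_cfg <- config$reporter %||% list()
      ft <- unlist(rep_cfg$fold_targets %||%
                     c(DPAR = 38, D3RE = 4.4, LOOP = 12.5, DOUBLE = 41.8))
      gp <- reporter_gen_params(
        fold_targets = ft,
        n = as.integer(rep_cfg$n %||% 100L),
        cv = as.numeric(rep_cfg$cv %||% 0.10),
        seed = seed)
      tbl <- gen_reporter(gp)
      paths$reporter_table <- file.path(out_dir, "reporter_table.csv")
      utils::write.csv(tbl, paths$reporter_table, row.names = FALSE)
      summarize_reporter(tbl)
    }
  })
  paths$readouts <- file.path(out_dir, "readouts.csv")
  utils::write.csv(as.data.frame(readouts), paths$readouts,
                   row.names = FALSE)

  verdict <- stage("exclusivity", {
    test_exclusivity(readouts, n_draws = n_draws, seed = seed)
  })
  paths$verdict <- file.path(out_dir, "verdict.json")
  write_verdict(verdict, paths$verdict,
                input = config$readouts %||% "generated")

  # -- kinetics stage ----------------------------------------------------
  kin <- config$kinetics %||% list()
  reaction <- stage("kinetics", {
    binding_reaction(
      competitor_fold = as.numeric(kin$competitor_fold %||% 1e5),
      kon = as.numeric(kin$kon %||% 1e6),
      koff = as.numeric(kin$koff %||% 0.006),
      duration = as.numeric(kin$duration %||% 510))
  })
  koff_fit <- stage("kinetics", {
    tc <- gen_timecourse(reaction,
                         noise_sd = as.numeric(kin$noise_sd %||% 0.02),
                         n_points = as.integer(kin$n_points %||% 40L),
                         seed = seed)
    paths$timecourse <- file.path(out_dir, "timecourse.csv")
    utils::write.csv(as.data.frame(tc), paths$timecourse,
                     row.names = FALSE)
    fit_koff(tc)
  })
  paths$koff <- file.path(out_dir, "koff_fit.json")
  write_json_stable(list(koff = koff_fit$koff, se = koff_fit$se,
                         f0 = koff_fit$f0, finf = koff_fit$finf,
                         converged = koff_fit$converged,
                         seed = seed), paths$koff)

  ic50_fit <- stage("dose-response", {
    folds <- as.numeric(unlist(kin$folds %||%
                                 10^seq(log10(1000), log10(1e5),
                                        length.out = 6)))
    dr <- gen_dose_response(reaction, folds,
                            noise_sd = as.numeric(kin$noise_sd %||% 0.02),
                            seed = seed)
    paths$doseresponse <- file.path(out_dir, "doseresponse.csv")
    utils::write.csv(as.data.frame(dr), paths$doseresponse,
                     row.names = FALSE)
    fit_dose_response(dr, response_limits = c(0, 1))  # bound fractions
  })
  paths$ic50 <- file.path(out_dir, "ic50_fit.json")
  write_json_stable(list(ic50 = ic50_fit$ic50, hill = ic50_fit$hill,
                         top = ic50_fit$top, bottom = ic50_fit$bottom,
                         determinable = ic50_fit$determinable,
                         reason = ic50_fit$reason, seed = seed),
                    paths$ic50)

  # -- variant stage -----------------------------------------------------
  variants <- stage("variants", {
    labels <- unlist(config$variants %||% c("G51C", "G52C", "A15G"))
    map <- if (!is.null(config$element_map)) {
      load_element_map(config$element_map)
    } else {
      element_map()
    }
    do.call(rbind, lapply(labels, function(lb) {
      a <- annotate_variant(lb, map)
      data.frame(variant = a$label, position = a$position,
                 overlaps = paste(a$overlaps, collapse = ";"),
                 nearest = a$nearest %||% NA,
                 distance_nt = a$distance_nt %||% NA,
                 direction = a$direction %||% NA,
                 steric = a$steric)
    }))
  })
  paths$variants <- file.path(out_dir, "variants.csv")
  utils::write.csv(variants, paths$variants, row.names = FALSE)

  # -- summary -----------------------------------------------------------
  paths$summary <- file.path(out_dir, "summary.txt")
  lines <- c(
    "ftlreg pipeline summary",
    sprintf("package version: %s",
            as.character(utils::packageVersion("ftlreg"))),
    sprintf("seed: %d; exclusivity draws: %d", seed, n_draws),
    "",
    sprintf("exclusive-binding model: point_consistent = %s, p = %.4g, z = %.3f",
            verdict$point_consistent, verdict$p_consistent,
            verdict$z_score),
    sprintf("koff fit: %s",
            if (koff_fit$converged) {
              sprintf("%.4g /min (SE %.2g)", koff_fit$koff, koff_fit$se)
            } else "failed"),
    sprintf("IC50 fit: %s",
            if (ic50_fit$determinable) {
              sprintf("%.4g-fold excess", ic50_fit$ic50)
            } else paste("not determinable:", ic50_fit$reason)),
    sprintf("variants annotated: %s",
            paste(variants$variant, collapse = ", "))
  )
  writeLines(lines, paths$summary)

  invisible(list(readouts = readouts, verdict = verdict,
                 koff_fit = koff_fit, ic50_fit = ic50_fit,
                 variants = variants, paths = as.list(paths)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
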