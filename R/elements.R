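#' Regulatory-element map of the FTL 5'-UTR
#'
#' Coordinates are 1-based inclusive on the mature 5'-UTR, with +1 at the
#' annotated transcription start. Defaults carry the published
#' annotation: the eIF3 PAR-CLIP site at nt 53-76, the eIF3 repressive
#' element (3RE) at nt 58-90, IRP-contact apical-loop positions
#' {15, 16, 17}, the characteristic C bulge at nt 18, and the
#' cap-to-C-bulge distances of the reporter constructs (native 32 nt,
#' extended 70 nt) with the 60-nt steric threshold beyond which bound IRP
#' can no longer fully block 43S loading. The IRE start is not annotated
#' and defaults to `NA` (its end, 57, follows from the PAR site
#' overlapping the last five IRE nucleotides); supply `ire` explicitly to
#' use IRE interval queries.
#'
#' Cap distances are stored as construct metadata rather than derived
#' from the C-bulge UTR coordinate, because reporter constructs carry
#' vector-derived 5' sequence of unstated length.
#'
#' @param par,re3,ire Integer vectors `c(start, end)` for the PAR-CLIP
#'   site, the 3RE and the IRE.
#' @param loop_positions IRP-contact positions in the apical loop.
#' @param bulge Position of the characteristic C bulge.
#' @param cap_distance Named vector of cap-to-C-bulge distances (nt) per
#'   construct.
#' @param steric_threshold Cap distance (nt) beyond which IRP blocking
#'   becomes partial (strict inequality).
#' @return An object of class `"element_map"`.
#' @examples
#' m <- element_map()
#' element_length(m, "PAR")  # 24
#' @export
element_map <- function(par = c(53L, 76L), re3 = c(58L, 90L),
                        ire = c(NA_integer_, 57L),
                        loop_positions = c(15L, 16L, 17L),
                        bulge = 18L,
                        cap_distance = c(native = 32L, extended = 70L),
                        steric_threshold = 60L) {
  iv <- function(v, nm) {
    if (length(v) != 2L) stop(nm, " must be c(start, end)", call. = FALSE)
    if (!anyNA(v) && v[1] > v[2]) {
      stop(nm, ": start must not exceed end", call. = FALSE)
    }
    as.integer(v)
  }
  m <- list(
    intervals = list(PAR = iv(par, "par"), `3RE` = iv(re3, "re3"),
                     IRE = iv(ire, "ire")),
    loop_positions = as.integer(loop_positions),
    bulge = as.integer(bulge),
    cap_distance = cap_distance,
    steric_threshold = as.integer(steric_threshold)
  )
  if (is.null(names(m$cap_distance))) {
    stop("cap_distance must be a named vector", call. = FALSE)
  }
  structure(m, class = "element_map")
}

#' @export
print.element_map <- function(x, ...) {
  cat("FTL 5'-UTR element map (1-based inclusive)\n")
  for (nm in names(x$intervals)) {
    cat(sprintf("  %-4s [%s, %s]\n", nm, x$intervals[[nm]][1],
                x$intervals[[nm]][2]))
  }
  cat("  IRP loop contacts:", paste(x$loop_positions, collapse = ", "),
      "; C bulge:", x$bulge, "\n")
  cat("  cap distances:",
      paste(names(x$cap_distance), x$cap_distance, sep = "=",
            collapse = ", "),
      "nt; steric threshold", x$steric_threshold, "nt\n")
  invisible(x)
}

#' Length of a mapped element
#'
#' @param map An [element_map()].
#' @param name Element name (`"PAR"`, `"3RE"`, `"IRE"`).
#' @return Integer length in nucleotides, `end - start + 1`.
#' @export
element_length <- function(map, name) {
  stopifnot(inherits(map, "element_map"))
  if (!name %in% names(map$intervals)) {
    stop("unknown element '", name, "'; available: ",
         paste(names(map$intervals), collapse = ", "), call. = FALSE)
  }
  v <- map$intervals[[name]]
  if (anyNA(v)) {
    stop("element '", name, "' has unset coordinates in this map",
         call. = FALSE)
  }
  v[2] - v[1] + 1L
}

parse_variant <- function(label) {
  m <- regmatches(label, regexec("^([ACGUT])([0-9]+)([ACGUT])$",
                                 toupper(trimws(label))))[[1]]
  if (length(m) != 4L) {
    stop("malformed variant label '", label,
         "'; expected <ref><position><alt>, e.g. G51C or A15G",
         call. = FALSE)
  }
  list(label = toupper(trimws(label)), ref = m[2],
       position = as.integer(m[3]), alt = m[4])
}

#' Annotate a 5'-UTR point variant against the element map
#'
#' Reports every element whose interval (or contact-position set)
#' contains the variant position; when no element overlaps, reports the
#' nearest element and the distance to its closest boundary, with the
#' direction (`upstream` of the element start or `downstream` of its
#' end). Also classifies the carrying construct by the cap-distance
#' steric rule.
#'
#' @param variant Variant label such as `"G51C"` or `"A15G"`
#'   (`<ref><1-based position><alt>`).
#' @param map An [element_map()].
#' @param construct Construct context for the steric classification
#'   (default `"native"`).
#' @return An object of class `"variant_annotation"`: `label`,
#'   `position`, `ref`, `alt`, `overlaps` (character vector),
#'   `nearest`, `distance_nt`, `direction`, `steric`.
#' @examples
#' annotate_variant("G52C", element_map())  # 1 nt upstream of the PAR site
#' @export
annotate_variant <- function(variant, map, construct = "native") {
  stopifnot(inherits(map, "element_map"))
  v <- parse_variant(variant)
  if (v$position < 1L) stop("variant position must be >= 1", call. = FALSE)
  pos <- v$position

  hits <- character(0)
  gaps <- data.frame(element = character(0), distance = numeric(0),
                     direction = character(0))
  for (nm in names(map$intervals)) {
    b <- map$intervals[[nm]]
    if (anyNA(b)) next
    if (pos >= b[1] && pos <= b[2]) {
      hits <- c(hits, nm)
    } else if (pos < b[1]) {
      gaps <- rbind(gaps, data.frame(element = nm, distance = b[1] - pos,
                                     direction = "upstream"))
    } else {
      gaps <- rbind(gaps, data.frame(element = nm, distance = pos - b[2],
                                     direction = "downstream"))
    }
  }
  if (pos %in% map$loop_positions) hits <- c(hits, "IRP-contact loop")
  if (pos == map$bulge) hits <- c(hits, "C bulge")

  nearest <- distance <- direction <- NA
  if (!length(hits) && nrow(gaps)) {
    i <- which.min(gaps$distance)
    nearest <- gaps$element[i]
    distance <- gaps$distance[i]
    direction <- gaps$direction[i]
  }
  structure(list(
    label = v$label, position = pos, ref = v$ref, alt = v$alt,
    overlaps = hits, nearest = nearest, distance_nt = distance,
    direction = direction,
    steric = steric_class(cap_distance(map, construct), map)
  ), class = "variant_annotation")
}

#' @export
print.variant_annotation <- function(x, ...) {
  cat(sprintf("%s (position %d, %s>%s)\n", x$label, x$position,
              x$ref, x$alt))
  if (length(x$overlaps)) {
    cat("  inside:", paste(x$overlaps, collapse = ", "), "\n")
  } else if (!is.na(x$nearest)) {
    cat(sprintf("  no element overlap; %d nt %s of %s\n",
                x$distance_nt, x$direction, x$nearest))
  }
  cat("  construct steric class:", x$steric, "\n")
  invisible(x)
}

#' Cap-to-IRE distance of a construct and its steric class
#'
#' `cap_distance()` returns the configured distance (nt) between the
#' 5'-cap and the characteristic C bulge for a named construct.
#' `steric_class()` applies the steric rule: IRP fully blocks 43S
#' loading only when the IRE sits within the threshold of the cap, so
#' distances strictly greater than the threshold are `"partial-block"`.
#'
#' @param map An [element_map()].
#' @param construct Construct key, e.g. `"native"` or `"extended"`.
#' @param distance Distance in nt.
#' @return `cap_distance()`: integer nt. `steric_class()`:
#'   `"full-block"` or `"partial-block"`.
#' @examples
#' m <- element_map()
#' cap_distance(m, "extended") - cap_distance(m, "native")  # 38
#' steric_class(70, m)
#' @export
cap_distance <- function(map, construct) {
  stopifnot(inherits(map, "element_map"))
  if (!construct %in% names(map$cap_distance)) {
    stop("unknown construct '", construct, "'; available: ",
         paste(names(map$cap_distance), collapse = ", "), call. = FALSE)
  }
  as.integer(map$cap_distance[[construct]])
}

#' @rdname cap_distance
#' @export
steric_class <- function(distance, map) {
  stopifnot(inherits(map, "element_map"))
  if (distance > map$steric_threshold) "partial-block" else "full-block"
}

# --- construct building -------------------------------------------------

#' Sequence edits for reporter constructs
#'
#' `edit_deletion()`, `edit_substitution()` and `edit_insertion5()`
#' describe single edits in original (pre-edit) 1-based coordinates;
#' `construct_spec()` bundles non-overlapping edits under a construct
#' name. Substitution reference bases are checked against the sequence
#' when applied; U and T are treated as equivalent.
#'
#' @param start,end Deletion interval, 1-based inclusive.
#' @param position Substitution position.
#' @param ref,alt Reference and substituted base.
#' @param sequence Sequence inserted directly after the 5' cap (i.e.
#'   prepended to the UTR).
#' @param name Construct name.
#' @param edits List of edits.
#' @return `construct_spec()` returns an object of class
#'   `"construct_spec"`.
#' @examples
#' d3re <- construct_spec("D3RE", list(edit_deletion(58, 90)))
#' @export
construct_spec <- function(name, edits = list()) {
  for (e in edits) {
    if (!inherits(e, "utr_edit")) {
      stop("edits must be built with edit_deletion()/edit_substitution()/",
           "edit_insertion5()", call. = FALSE)
    }
  }
  spans <- lapply(edits, function(e) {
    switch(e$type,
           deletion = c(e$start, e$end),
           substitution = c(e$position, e$position),
           insertion5 = NULL)
  })
  spans <- do.call(rbind, spans)
  if (!is.null(spans) && nrow(spans) > 1L) {
    o <- order(spans[, 1])
    spans <- spans[o, , drop = FALSE]
    if (any(spans[-1, 1] <= spans[-nrow(spans), 2])) {
      stop("construct '", name, "' has overlapping edits", call. = FALSE)
    }
  }
  if (sum(vapply(edits, function(e) e$type == "insertion5", TRUE)) > 1L) {
    stop("at most one 5' insertion per construct", call. = FALSE)
  }
  structure(list(name = name, edits = edits), class = "construct_spec")
}

#' @rdname construct_spec
#' @export
edit_deletion <- function(start, end) {
  stopifnot(start >= 1, end >= start)
  structure(list(type = "deletion", start = as.integer(start),
                 end = as.integer(end)), class = "utr_edit")
}

#' @rdname construct_spec
#' @export
edit_substitution <- function(position, ref, alt) {
  stopifnot(position >= 1, nchar(ref) == 1L, nchar(alt) == 1L)
  structure(list(type = "substitution", position = as.integer(position),
                 ref = toupper(ref), alt = toupper(alt)),
            class = "utr_edit")
}

#' @rdname construct_spec
#' @export
edit_insertion5 <- function(sequence) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGUT]+$", sequence)) {
    stop("insertion sequence must be over A/C/G/U/T", call. = FALSE)
  }
  structure(list(type = "insertion5", sequence = sequence,
                 length = nchar(sequence)), class = "utr_edit")
}

base_eq <- function(a, b) {
  norm <- function(x) chartr("T", "U", toupper(x))
  norm(a) == norm(b)
}

#' Apply a construct spec to a 5'-UTR sequence
#'
#' Applies the edits 5' to 3' in a single pass over the original
#' coordinates: deletions remove their interval, substitutions replace
#' one base after checking the reference, and a 5' insertion is
#' prepended (directly after the cap). Returns the edited sequence plus
#' a lift-over table mapping every original position to its new
#' coordinate (`NA` for deleted positions). RNA and DNA alphabets are
#' both accepted; the output follows the input alphabet.
#'
#' @param sequence A single character string over A/C/G/U/T (either
#'   case).
#' @param spec A [construct_spec()].
#' @return A list of class `"edited_construct"`: `name`, `sequence`,
#'   and `liftover` (data frame with columns `old`, `new`).
#' @examples
#' utr <- synthetic_ftl_utr()
#' nchar(utr) - nchar(apply_construct(utr, construct_spec(
#'   "DPAR", list(edit_deletion(53, 76))))$sequence)  # 24
#' @export
apply_construct <- function(sequence, spec) {
  stopifnot(inherits(spec, "construct_spec"))
  if (!is.character(sequence) || length(sequence) != 1L ||
      nchar(sequence) == 0L) {
    stop("sequence must be one non-empty string", call. = FALSE)
  }
  if (!grepl("^[ACGUTacgut]+$", sequence)) {
    stop("sequence must be over the A/C/G/U/T alphabet", call. = FALSE)
  }
  is_rna <- grepl("[Uu]", sequence) || !grepl("[Tt]", sequence)
  bases <- strsplit(sequence, "")[[1]]
  L <- length(bases)
  keep <- rep(TRUE, L)
  prefix <- character(0)

  for (e in spec$edits) {
    switch(e$type,
      deletion = {
        if (e$end > L) {
          stop("deletion ", e$start, "-", e$end,
               " extends past the sequence (length ", L, ")",
               call. = FALSE)
        }
        keep[e$start:e$end] <- FALSE
      },
      substitution = {
        if (e$position > L) {
          stop("substitution position ", e$position,
               " is past the sequence (length ", L, ")", call. = FALSE)
        }
        found <- bases[e$position]
        if (!base_eq(found, e$ref)) {
          stop("reference mismatch at position ", e$position,
               ": expected ", e$ref, ", found ", toupper(found),
               call. = FALSE)
        }
        bases[e$position] <- e$alt
      },
      insertion5 = {
        prefix <- strsplit(e$sequence, "")[[1]]
      }
    )
  }
  match_alphabet <- function(b) {
    if (is_rna) chartr("Tt", "Uu", b) else chartr("Uu", "Tt", b)
  }
  out_bases <- match_alphabet(c(prefix, bases[keep]))
  new_pos <- rep(NA_integer_, L)
  new_pos[keep] <- length(prefix) + seq_len(sum(keep))
  structure(list(
    name = spec$name,
    sequence = paste(out_bases, collapse = ""),
    liftover = data.frame(old = seq_len(L), new = new_pos)
  ), class = "edited_construct")
}

#' @export
print.edited_construct <- function(x, ...) {
  cat(sprintf("Construct %s: %d nt\n", x$name, nchar(x$sequence)))
  cat(" ", substr(x$sequence, 1, 60),
      if (nchar(x$sequence) > 60) "..." else "", "\n")
  invisible(x)
}

#' Reporter construct recipes used in the study design
#'
#' Returns the named edit recipes for the standard constructs: the
#' PAR-CLIP site deletion (`DPAR`, nt 53-76), the eIF3 repressive
#' element deletion (`D3RE`, nt 58-90), the IRP-binding apical-loop
#' double mutant (`LOOP`, A15G/G16C), the combined `DOUBLE` construct,
#' the hyperferritinemia SNP constructs `G51C` and `G52C`, and the
#' extended-spacer construct (`EXT`, a 38-nt random 5' insertion moving
#' the IRE past the 60-nt steric threshold).
#'
#' @param spacer 38-nt insertion sequence for `EXT`; defaults to a
#'   seeded random sequence via [spacer_sequence()].
#' @return Named list of [construct_spec()] objects.
#' @export
ftl_construct_specs <- function(spacer = spacer_sequence()) {
  loop_edits <- list(edit_substitution(15, "A", "G"),
                     edit_substitution(16, "G", "C"))
  list(
    DPAR   = construct_spec("DPAR", list(edit_deletion(53, 76))),
    D3RE   = construct_spec("D3RE", list(edit_deletion(58, 90))),
    LOOP   = construct_spec("LOOP", loop_edits),
    DOUBLE = construct_spec("DOUBLE", c(loop_edits,
                                        list(edit_deletion(58, 90)))),
    G51C   = construct_spec("G51C", list(edit_substitution(51, "G", "C"))),
    G52C   = construct_spec("G52C", list(edit_substitution(52, "G", "C"))),
    EXT    = construct_spec("EXT", list(edit_insertion5(spacer)))
  )
}

#' Random spacer sequence for the extended cap-distance construct
#'
#' @param length Spacer length in nt (default 38, the extension that
#'   moves the C bulge from 32 to 70 nt from the cap).
#' @param seed Integer seed.
#' @return A character string over A/C/G/U.
#' @export
spacer_sequence <- function(length = 38L, seed = 101L) {
  withr::with_seed(as.integer(seed), {
    paste(sample(c("A", "C", "G", "U"), length, replace = TRUE),
          collapse = "")
  })
}

#' Synthetic stand-in FTL 5'-UTR sequence
#'
#' The study's UTR sequence is not reprinted and no accession is
#' deposited, so this generates a SYNTHETIC 200-nt stand-in whose bases
#' at all annotated positions match the reference annotation (A15, G16,
#' U17, C18, G51, G52), letting every construct recipe validate. It is
#' not the real FTL 5'-UTR and must not be used for structure or
#' sequence analysis.
#'
#' @param length Total UTR length (default 200 nt; must be >= 90 to
#'   cover the 3RE).
#' @param seed Integer seed.
#' @return A character string over A/C/G/U.
#' @export
synthetic_ftl_utr <- function(length = 200L, seed = 42L) {
  stopifnot(length >= 90L)
  bases <- withr::with_seed(as.integer(seed), {
    sample(c("A", "C", "G", "U"), length, replace = TRUE)
  })
  anchors <- c(`15` = "A", `16` = "G", `17` = "U", `18` = "C",
               `51` = "G", `52` = "G")
  bases[as.integer(names(anchors))] <- anchors
  paste(bases, collapse = "")
}
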