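#' Construct a deregulation set for one experimental condition
#'
#' The unit of overlap arithmetic: a named set of deregulated features
#' (miRNAs or proteins) for one combination of exposure modality, dose
#' and sampling time, with the direction of change per member.
#'
#' @param members Character vector of feature identifiers, no
#'   duplicates. Gene-symbol style identifiers are matched
#'   case-insensitively in [venn()].
#' @param direction Optional `"up"`/`"down"` per member.
#' @param modality Exposure modality (`"PBI"`, `"WBI"` or `"SI"`).
#' @param dose_gy Dose in Gy (e.g. 0.1 or 2.0).
#' @param time Sampling time label (e.g. `"15d"`, `"6mo"`).
#' @param layer Omics layer (`"miRNA"`, `"protein"`, ...).
#' @return An object of class `deregulation_set`.
#' @export
deregulation_set <- function(members, direction = NULL, modality = NA,
                             dose_gy = NA, time = NA, layer = NA) {
  members <- as.character(members)
  if (anyDuplicated(members)) stop("duplicate members in deregulation set")
  if (!is.null(direction)) {
    direction <- rep_len(as.character(direction), length(members))
  }
  structure(
    list(members = members, direction = direction,
         condition = list(modality = modality, dose_gy = dose_gy,
                          time = time, layer = layer)),
    class = "deregulation_set"
  )
}

#' @export
print.deregulation_set <- function(x, ...) {
  cond <- x$condition
  cat(sprintf("Deregulation set (%s, %s Gy, %s, %s): %d members\n",
              cond$modality, cond$dose_gy, cond$time, cond$layer,
              length(x$members)))
  invisible(x)
}

#' @export
length.deregulation_set <- function(x) length(x$members)

set_members <- function(x, ignore_case = TRUE) {
  m <- if (inherits(x, "deregulation_set")) x$members else as.character(x)
  if (ignore_case) tolower(m) else m
}

#' Venn summary of 2 to 4 deregulation sets
#'
#' Exact region cardinalities by set algebra, with membership lists
#' retained and shared-fraction percentages computed relative to each
#' set. Region counts satisfy inclusion-exclusion: exclusive regions sum
#' to the union size.
#'
#' @param sets Named list of 2-4 `deregulation_set` objects or character
#'   vectors.
#' @param ignore_case Match feature ids case-insensitively (default
#'   TRUE; gene-symbol capitalization varies across sources).
#' @return An object of class `venn_summary`: list with `set_sizes`,
#'   `regions` (exclusive region counts, names like `"A&B"`),
#'   `region_members`, `intersections` (all non-trivial subset
#'   intersections), `union_size` and `shared_percent` (pairwise shared
#'   fraction relative to each set, for >= 2 sets).
#' @export
venn <- function(sets, ignore_case = TRUE) {
  k <- length(sets)
  if (k < 2L || k > 4L) stop("venn supports 2 to 4 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- LETTERS[seq_len(k)]
  }
  mem <- lapply(sets, set_members, ignore_case = ignore_case)
  univ <- unique(unlist(mem))
  inset <- vapply(mem, function(m) univ %in% m, logical(length(univ)))
  if (length(univ) == 1L) {
    inset <- matrix(inset, nrow = 1L, dimnames = list(NULL, names(sets)))
  }
  # exclusive regions: every nonempty membership pattern
  patterns <- apply(inset, 1, function(r) {
    paste(names(sets)[r], collapse = "&")
  })
  regions <- table(factor(patterns))
  region_members <- split(univ, patterns)
  # subset intersections (non-exclusive)
  combos <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(names(sets), m, simplify = FALSE)
  }), recursive = FALSE)
  intersections <- vapply(combos, function(cc) {
    sum(rowSums(inset[, cc, drop = FALSE]) == length(cc))
  }, numeric(1))
  names(intersections) <- vapply(combos, paste, "", collapse = "&")
  structure(
    list(
      set_sizes = vapply(mem, length, integer(1)),
      regions = as.integer(regions) |> setNames(names(regions)),
      region_members = region_members,
      intersections = intersections,
      union_size = length(univ)
    ),
    class = "venn_summary"
  )
}

#' @export
print.venn_summary <- function(x, ...) {
  cat("Venn summary of", length(x$set_sizes), "sets (union",
      x$union_size, "features)\n")
  for (nm in names(x$regions)) {
    cat(sprintf("  %-20s %d\n", nm, x$regions[[nm]]))
  }
  invisible(x)
}

#' Shared fraction of a set, as a percentage
#'
#' `100 * intersection / size`, rounded to the configured number of
#' digits so that printed percentages reproduce exactly.
#'
#' @param intersection Intersection cardinality (<= `size`).
#' @param size Set cardinality (> 0).
#' @param digits Rounding digits (0 = integer percent, 1 = one decimal).
#' @return The rounded percentage.
#' @export
shared_fraction <- function(intersection, size, digits = 0) {
  if (any(size <= 0)) stop("set size must be > 0")
  if (any(intersection > size)) {
    stop("intersection cannot exceed the set size")
  }
  round(100 * intersection / size, digits)
}

#' Signed percent change between two counts
#'
#' `100 * (later - earlier) / earlier`; negative values are decreases.
#'
#' @param later,earlier Counts at the later and earlier time (earlier
#'   > 0).
#' @param digits Rounding digits (default 0).
#' @return Signed percent change.
#' @export
count_change <- function(later, earlier, digits = 0) {
  if (any(earlier <= 0)) stop("`earlier` must be > 0")
  round(100 * (later - earlier) / earlier, digits)
}

#' Dose to a shielded region
#'
#' The out-of-field dose as total dose times shield transmission,
#' reported in mGy (e.g. 2.0 Gy x 0.2% transmission = 4 mGy to the
#' shielded brain).
#'
#' @param total_dose_gy Delivered dose in Gy, >= 0.
#' @param transmission Transmission fraction through the shield, in
#'   [0, 1].
#' @return Shielded dose in mGy.
#' @export
shielded_dose <- function(total_dose_gy, transmission) {
  if (any(total_dose_gy < 0)) stop("dose must be >= 0")
  if (any(transmission < 0 | transmission > 1)) {
    stop("`transmission` must be in [0, 1]")
  }
  1000 * total_dose_gy * transmission
}

#' Consolidated multi-stage report
#'
#' Collects per-stage outputs into one structured, serializable report.
#' Absent stages are reported explicitly; condition keys, when supplied
#' on deregulation sets, are checked for consistency across stages.
#'
#' @param mirna Optional miRNA DE output (data frame from [mirna_de()]).
#' @param proteomics Optional proteomics output (from [protein_de()]).
#' @param raman Optional list of CLS/PCA summaries.
#' @param neurogenesis Optional output of [neurogenesis_summary()].
#' @param overlaps Optional named list of `venn_summary` objects and/or
#'   shared-fraction values.
#' @param config Optional configuration list, echoed (and hashed) into
#'   the report for traceability.
#' @return An object of class `omics_report` (a named list).
#' @export
build_report <- function(mirna = NULL, proteomics = NULL, raman = NULL,
                         neurogenesis = NULL, overlaps = NULL,
                         config = NULL) {
  stages <- list(mirna = mirna, proteomics = proteomics, raman = raman,
                 neurogenesis = neurogenesis, overlaps = overlaps)
  if (all(vapply(stages, is.null, logical(1)))) {
    stop("at least one stage output is required")
  }
  conds <- Filter(Negate(is.null), lapply(stages, attr, "condition"))
  if (length(conds) > 1L) {
    for (i in seq_along(conds)[-1]) {
      if (!identical(conds[[i]], conds[[1]])) {
        stop("inconsistent condition keys across stage inputs: ",
             names(conds)[1], " declares ",
             paste(unlist(conds[[1]]), collapse = "/"), " but ",
             names(conds)[i], " declares ",
             paste(unlist(conds[[i]]), collapse = "/"))
      }
    }
  }
  sections <- lapply(stages, function(x) {
    if (is.null(x)) "absent" else x
  })
  cfg <- config %||% list()
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 10)
  structure(
    c(sections,
      list(config = cfg,
           config_hash = sprintf("%08x", sum(utf8ToInt(cfg_json) *
                                               seq_along(utf8ToInt(cfg_json))) %% 4294967291))),
    class = "omics_report"
  )
}

#' Serialize a report to JSON and Markdown
#'
#' Floating point values are serialized at 10 significant digits so that
#' reruns of a seeded pipeline yield byte-identical files.
#'
#' @param report An `omics_report`.
#' @param json_path,md_path Output paths (either may be `NULL`).
#' @return Invisibly, a list with the JSON string and Markdown lines.
#' @export
write_report <- function(report, json_path = NULL, md_path = NULL) {
  if (!inherits(report, "omics_report")) stop("expected an `omics_report`")
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                           digits = 10, pretty = TRUE, force = TRUE)
  md <- c("# Multi-omics out-of-field radiation report", "")
  for (nm in setdiff(names(report), c("config", "config_hash"))) {
    md <- c(md, paste0("## ", nm), "")
    sec <- report[[nm]]
    if (identical(sec, "absent")) {
      md <- c(md, "_absent_", "")
    } else if (is.data.frame(sec)) {
      md <- c(md, paste(names(sec), collapse = " | "),
              paste(rep("---", ncol(sec)), collapse = " | "),
              apply(sec, 1, function(r) paste(format(r, digits = 10),
                                              collapse = " | ")),
              "")
    } else {
      md <- c(md, paste0("```", collapse = ""),
              utils::capture.output(utils::str(sec, digits.d = 10)),
              "```", "")
    }
  }
  md <- c(md, paste0("config hash: ", report$config_hash))
  if (!is.null(json_path)) writeLines(json, json_path)
  if (!is.null(md_path)) writeLines(md, md_path)
  invisible(list(json = json, markdown = md))
}
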