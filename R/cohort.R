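#' Construct a two-phase cohort object
#'
#' A `cohort` holds one phase-one record per subject of a two-phase
#' case-control study: disease status, the phase-two sampling stratum,
#' the phase-two sampling indicator, and marker values for sampled
#' subjects. Case strata and control strata are separate namespaces:
#' equality of labels across the two arms carries no meaning, and the
#' number of strata may differ between arms.
#'
#' @param data data.frame with columns `id`, `disease` (0 = control,
#'   1 = case), `stratum` (sampling-stratum label, coerced to character),
#'   `sampled` (0/1 phase-two indicator), `x` and optionally `y`
#'   (marker values, `NA` unless `sampled == 1`). An optional `p_true`
#'   column holds known design sampling probabilities.
#' @param n_markers 1 or 2; defaults to 2 when a `y` column is present.
#' @param validate run the full invariant checks (default). The
#'   simulator skips them for cohorts whose validity is guaranteed by
#'   construction.
#' @return An object of class `cohort`: the validated data.frame with
#'   count attributes (`N`, `N_case`, `N_control`, per-arm stratum tables).
#' @seealso [read_cohort()], [validate_cohort()], [stratum_table()]
#' @export
cohort_data <- function(data, n_markers = if ("y" %in% names(data)) 2L else 1L,
                        validate = TRUE) {
  required <- c("id", "disease", "stratum", "sampled", "x")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n_markers <- as.integer(n_markers)
  if (!n_markers %in% c(1L, 2L)) stop("n_markers must be 1 or 2", call. = FALSE)
  if (n_markers == 2L && !"y" %in% names(data)) {
    stop("n_markers = 2 but no 'y' column present", call. = FALSE)
  }
  if (!is.character(data$stratum)) data$stratum <- as.character(data$stratum)
  data$disease <- as.numeric(data$disease)
  data$sampled <- as.numeric(data$sampled)

  if (validate) {
    findings <- .cohort_findings(data, n_markers, warnings = FALSE)
    errs <- findings[vapply(findings, function(f) f$severity == "error",
                            logical(1))]
    if (length(errs) > 0L) {
      stop("invalid cohort:\n",
           paste(vapply(errs, `[[`, character(1), "message"),
                 collapse = "\n"), call. = FALSE)
    }
  }

  obj <- structure(data,
                   n_markers = n_markers,
                   class = c("cohort", "data.frame"))
  attr(obj, "counts") <- .cohort_counts(obj)
  obj
}

# Counts N, N_D, N_Dbar and per-arm stratum tables.
.cohort_counts <- function(c) {
  is_case <- c$disease == 1
  list(N = nrow(c),
       N_case = sum(is_case),
       N_control = sum(!is_case),
       case = .stratum_tally(c$stratum[is_case], c$sampled[is_case]),
       control = .stratum_tally(c$stratum[!is_case], c$sampled[!is_case]))
}

.stratum_tally <- function(stratum, sampled) {
  if (length(stratum) == 0L) {
    return(data.frame(stratum = character(), N_k = integer(), n_k = integer(),
                      stringsAsFactors = FALSE))
  }
  f <- factor(stratum)
  data.frame(stratum = levels(f),
             N_k = tabulate(f, nbins = nlevels(f)),
             n_k = tabulate(f[sampled == 1], nbins = nlevels(f)),
             stringsAsFactors = FALSE)
}

# Shared rule list used by the constructor (errors only) and
# validate_cohort() (errors and warnings).
.cohort_findings <- function(data, n_markers, warnings = TRUE) {
  findings <- list()
  add <- function(severity, invariant, message, ids = NULL) {
    findings[[length(findings) + 1L]] <<-
      list(severity = severity, invariant = invariant,
           message = message, ids = ids)
  }
  bad_d <- !data$disease %in% c(0, 1) | is.na(data$disease)
  if (any(bad_d)) {
    add("error", "disease binary",
        paste0("non-binary disease for id(s): ",
               paste(utils::head(data$id[bad_d], 10L), collapse = ", ")),
        data$id[bad_d])
  }
  bad_s <- !data$sampled %in% c(0, 1) | is.na(data$sampled)
  if (any(bad_s)) {
    add("error", "sampled binary",
        paste0("non-binary sampled indicator for id(s): ",
               paste(utils::head(data$id[bad_s], 10L), collapse = ", ")),
        data$id[bad_s])
  }
  if (any(bad_d) || any(bad_s)) return(findings)

  markers <- c("x", if (n_markers == 2L) "y")
  for (m in markers) {
    miss <- is.na(data[[m]]) & data$sampled == 1
    if (any(miss)) {
      add("error", "marker present iff sampled",
          paste0("sampled subject(s) with missing ", m, ": ",
                 paste(utils::head(data$id[miss], 10L), collapse = ", ")),
          data$id[miss])
    }
    extra <- !is.na(data[[m]]) & data$sampled == 0
    if (any(extra)) {
      add("error", "marker present iff sampled",
          paste0("unsampled subject(s) with non-missing ", m, ": ",
                 paste(utils::head(data$id[extra], 10L), collapse = ", ")),
          data$id[extra])
    }
  }
  if (sum(data$disease == 1) < 1L || sum(data$disease == 0) < 1L) {
    add("error", "both arms non-empty",
        "cohort must contain at least one case and one control")
  }
  if (!warnings) return(findings)
  for (arm in c("case", "control")) {
    sel <- data$disease == (arm == "case")
    tab <- .stratum_tally(data$stratum[sel], data$sampled[sel])
    for (k in seq_len(nrow(tab))) {
      if (tab$n_k[k] == 0L) {
        add("warning", "stratum sampled",
            sprintf("no phase-two subjects in %s stratum '%s' (N_k = %d)",
                    arm, tab$stratum[k], tab$N_k[k]))
      } else if (tab$n_k[k] == tab$N_k[k]) {
        add("warning", "sampling fraction 1",
            sprintf(paste0("%s stratum '%s' has sampling fraction 1; ",
                           "weight-estimation correction vanishes"),
                    arm, tab$stratum[k]))
      }
    }
  }
  findings
}

#' Report invariant violations and design warnings for a cohort
#'
#' Returns an empty list when every invariant holds. Strata with no
#' sampled subjects or with sampling fraction exactly 1 are reported as
#' warnings, not errors: the former cannot be weighted (see
#' [fit_stratum_weights()]), the latter contribute no weight-estimation
#' correction.
#'
#' @param c a `cohort` or plain data.frame in the cohort layout.
#' @return list of findings, each with `severity`, `invariant`,
#'   `message` and involved subject `ids`.
#' @export
validate_cohort <- function(c) {
  n_markers <- attr(c, "n_markers")
  if (is.null(n_markers)) n_markers <- if ("y" %in% names(c)) 2L else 1L
  .cohort_findings(as.data.frame(c), n_markers)
}

#' Read a two-phase cohort from a delimited text file
#'
#' @param path CSV (or TSV, by extension) file with a header row.
#' @param schema named list/character mapping canonical names
#'   (`id`, `disease`, `stratum`, `sampled`, `x`, `y`, `p_true`) to the
#'   file's column names; unmapped names default to themselves.
#' @param n_markers 1 or 2; default guesses from the mapped `y` column.
#' @return a validated [cohort_data()] object.
#' @details Missing markers may be written as empty fields or `NA`;
#'   both are read as `NA`.
#' @export
read_cohort <- function(path, schema = NULL, n_markers = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = c("NA", ""), stringsAsFactors = FALSE,
                           colClasses = NA, check.names = FALSE)
  map <- c(id = "id", disease = "disease", stratum = "stratum",
           sampled = "sampled", x = "x", y = "y", p_true = "p_true")
  if (!is.null(schema)) {
    schema <- unlist(schema)
    bad <- setdiff(names(schema), names(map))
    if (length(bad) > 0L) stop("unknown schema key(s): ",
                               paste(bad, collapse = ", "), call. = FALSE)
    map[names(schema)] <- schema
  }
  need <- c("id", "disease", "stratum", "sampled", "x")
  absent <- need[!map[need] %in% names(raw)]
  if (length(absent) > 0L) {
    stop("file lacks required column(s): ",
         paste(map[absent], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(id = raw[[map["id"]]],
                    disease = raw[[map["disease"]]],
                    stratum = raw[[map["stratum"]]],
                    sampled = raw[[map["sampled"]]],
                    x = as.numeric(raw[[map["x"]]]),
                    stringsAsFactors = FALSE)
  if (map["y"] %in% names(raw)) out$y <- as.numeric(raw[[map["y"]]])
  if (map["p_true"] %in% names(raw)) out$p_true <- as.numeric(raw[[map["p_true"]]])
  if (is.null(n_markers)) n_markers <- if ("y" %in% names(out)) 2L else 1L
  cohort_data(out, n_markers = n_markers)
}

#' Write a cohort to a delimited text file
#'
#' Missing markers are written as empty fields, so that a write/read
#' round trip reproduces the cohort exactly.
#'
#' @param c a `cohort`.
#' @param path output path; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(c, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(c), path, sep = sep, na = "",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-stratum phase-one and phase-two counts for one arm
#'
#' @param c a `cohort`.
#' @param arm `"case"` or `"control"`.
#' @return data.frame with columns `stratum`, `N_k` (phase-one count),
#'   `n_k` (phase-two sampled count).
#' @export
stratum_table <- function(c, arm = c("case", "control")) {
  arm <- match.arg(arm)
  attr(c, "counts")[[arm]]
}

#' @export
print.cohort <- function(x, ...) {
  ct <- attr(x, "counts")
  cat(sprintf("Two-phase cohort: N = %d (%d cases, %d controls), %d marker%s\n",
              ct$N, ct$N_case, ct$N_control, attr(x, "n_markers"),
              if (attr(x, "n_markers") > 1L) "s" else ""))
  cat(sprintf("Phase two: %d cases, %d controls sampled\n",
              sum(ct$case$n_k), sum(ct$control$n_k)))
  cat("Case strata:    ", paste(sprintf("%s %d/%d", ct$case$stratum,
                                        ct$case$n_k, ct$case$N_k),
                                collapse = ", "), "\n")
  cat("Control strata: ", paste(sprintf("%s %d/%d", ct$control$stratum,
                                        ct$control$n_k, ct$control$N_k),
                                collapse = ", "), "\n")
  invisible(x)
}

# Internal: split a cohort into per-arm plain lists used by the
# estimation kernels (no data.frame overhead downstream).
.arm_view <- function(c, arm) {
  is_case <- c$disease == 1
  rows <- if (arm == "case") which(is_case) else which(!is_case)
  list(id = c$id[rows],
       stratum = c$stratum[rows],
       sampled = c$sampled[rows] == 1,
       x = c$x[rows],
       y = if (!is.null(c$y)) c$y[rows] else NULL,
       p_true = if (!is.null(c$p_true)) c$p_true[rows] else NULL)
}
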