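#' Construct a typed interaction set
#'
#' A candidate regulator-to-target edge list with evidence provenance.
#' Allowed edge classes are TF->gene, TF->TF, TF->miRNA, miRNA->gene and
#' miRNA->TF; miRNA->miRNA regulation and self-loops are not representable.
#'
#' @param records Data frame with columns `regulator`, `regulator_class`
#'   (`"TF"`/`"miRNA"`), `target`, `target_class` (`"gene"`/`"TF"`/`"miRNA"`),
#'   logical `predicted` and `experimental`, and optional `source`.
#' @return A data frame of class `interaction_set`, deduplicated on
#'   (regulator, target).
#' @export
interaction_set <- function(records) {
  req <- c("regulator", "regulator_class", "target", "target_class",
           "predicted", "experimental")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    stop("records need columns ", paste(req, collapse = ", "))
  }
  records <- as.data.frame(records)
  if (is.null(records$source)) records$source <- NA_character_
  records <- records[c(req, "source")]
  bad_reg <- !records$regulator_class %in% c("TF", "miRNA")
  bad_tgt <- !records$target_class %in% c("gene", "TF", "miRNA")
  if (any(bad_reg) || any(bad_tgt)) {
    stop("unknown class token in rows: ",
         paste(head(which(bad_reg | bad_tgt), 5), collapse = ", "))
  }
  loops <- records$regulator == records$target
  if (any(loops)) {
    message("dropping ", sum(loops), " self-loop(s)")
    records <- records[!loops, , drop = FALSE]
  }
  mm <- records$regulator_class == "miRNA" & records$target_class == "miRNA"
  if (any(mm)) {
    warning("dropping ", sum(mm), " miRNA->miRNA record(s) (not a valid edge class)")
    records <- records[!mm, , drop = FALSE]
  }
  key <- paste(records$regulator, records$target)
  if (anyDuplicated(key)) {
    records <- collapse_records(records, key)
  }
  rownames(records) <- NULL
  structure(records, class = c("interaction_set", "data.frame"))
}

# Collapse duplicate (regulator, target) rows: evidence flags are OR-ed,
# sources concatenated. Errors if the duplicates disagree on entity classes.
collapse_records <- function(records, key) {
  parts <- split(seq_len(nrow(records)), factor(key, levels = unique(key)))
  rows <- lapply(parts, function(i) {
    r <- records[i, , drop = FALSE]
    if (length(unique(r$regulator_class)) > 1 || length(unique(r$target_class)) > 1) {
      stop("conflicting entity classes for pair ", r$regulator[1], " -> ", r$target[1])
    }
    out <- r[1, , drop = FALSE]
    out$predicted <- any(r$predicted)
    out$experimental <- any(r$experimental)
    src <- unique(r$source[!is.na(r$source)])
    out$source <- if (length(src)) paste(src, collapse = ";") else NA_character_
    out
  })
  do.call(rbind, rows)
}

#' Read an interaction adjacency list from TSV
#'
#' Expects a tab-separated file with header columns `regulator`,
#' `regulator_class`, `target`, `target_class`, and optionally `evidence`
#' (semicolon-joined flags, as written by [write_interactions()]). When the
#' `evidence` column is absent every record gets the `evidence_label`
#' supplied by the caller — "predicted" for sequence-based target
#' predictions, "experimental" for curated/validated regulations.
#'
#' @param path Path to the TSV file.
#' @param evidence_label `"predicted"` or `"experimental"`.
#' @param source Provenance string recorded per row; defaults to the
#'   file name.
#' @return An [interaction_set()].
#' @export
load_interactions <- function(path, evidence_label = c("predicted", "experimental"),
                              source = basename(path)) {
  evidence_label <- match.arg(evidence_label)
  raw <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    warning("empty interaction file: ", path)
    raw <- data.frame(regulator = character(), regulator_class = character(),
                      target = character(), target_class = character(),
                      stringsAsFactors = FALSE)
  }
  req <- c("regulator", "regulator_class", "target", "target_class")
  if (!all(req %in% names(raw))) {
    stop("interaction file ", path, " needs columns ", paste(req, collapse = ", "))
  }
  bad <- !raw$regulator_class %in% c("TF", "miRNA") |
    !raw$target_class %in% c("gene", "TF", "miRNA")
  if (any(bad)) {
    stop("unknown class token in ", path, " at line(s) ",
         paste(head(which(bad) + 1L, 5), collapse = ", "))
  }
  if (!is.null(raw$evidence)) {
    flags <- strsplit(as.character(raw$evidence), ";", fixed = TRUE)
    raw$predicted <- vapply(flags, function(f) "predicted" %in% f, logical(1))
    raw$experimental <- vapply(flags, function(f) "experimental" %in% f, logical(1))
  } else {
    raw$predicted <- rep(evidence_label == "predicted", nrow(raw))
    raw$experimental <- rep(evidence_label == "experimental", nrow(raw))
  }
  raw$source <- rep(source, nrow(raw))
  interaction_set(raw)
}

#' Write an interaction set as a TSV adjacency list
#'
#' The output dialect (`regulator`, `regulator_class`, `target`,
#' `target_class`, `evidence` with semicolon-joined flags) is the same one
#' [load_interactions()] reads, and is also used for the final network edge
#' lists.
#'
#' @param set An [interaction_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(set, path) {
  stopifnot(inherits(set, "interaction_set"))
  ev <- character(nrow(set))
  for (i in seq_len(nrow(set))) {
    flags <- c(if (set$predicted[i]) "predicted", if (set$experimental[i]) "experimental")
    ev[i] <- paste(flags, collapse = ";")
  }
  out <- data.frame(regulator = set$regulator, regulator_class = set$regulator_class,
                    target = set$target, target_class = set$target_class,
                    evidence = ev, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge predicted and experimentally supported interaction sets
#'
#' Union on (regulator, target); evidence flags are OR-combined so a pair
#' present in both sets carries both flags. Conflicting entity classes for
#' the same pair across files are an error.
#'
#' @param predicted,experimental Two [interaction_set()] objects (naming is
#'   conventional; any two sets merge the same way).
#' @return The merged [interaction_set()].
#' @export
merge_sets <- function(predicted, experimental) {
  stopifnot(inherits(predicted, "interaction_set"),
            inherits(experimental, "interaction_set"))
  interaction_set(rbind(as.data.frame(predicted), as.data.frame(experimental)))
}

#' Restrict an interaction set to measured entities
#'
#' Keeps only records whose regulator and target were both measured on the
#' expression panel; everything else is dropped with a logged count.
#'
#' @param set An [interaction_set()].
#' @param entity_ids Character vector of measured entity ids.
#' @return The restricted [interaction_set()].
#' @export
restrict_to_measured <- function(set, entity_ids) {
  stopifnot(inherits(set, "interaction_set"))
  keep <- set$regulator %in% entity_ids & set$target %in% entity_ids
  if (any(!keep)) {
    message("dropping ", sum(!keep), " record(s) with unmeasured endpoints")
  }
  out <- set[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
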