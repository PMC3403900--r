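#' Paired tumor / adjacent non-tumor expression panel
#'
#' Bundles the two intensity matrices of a paired design (same probes, same
#' patients, identical ordering) with the probe-to-entity map. Intensities
#' are assumed already normalized (e.g. RMA) and must be strictly positive.
#'
#' @param tu Numeric matrix, probes x patients, tumor intensities.
#' @param an Numeric matrix of identical dimensions and dimnames, adjacent
#'   non-tumor intensities.
#' @param probe_map Data frame with columns `probe_id`, `entity_id`,
#'   `entity_class` (one of `"gene"`, `"TF"`, `"miRNA"`). Every row of
#'   `tu`/`an` must appear exactly once in `probe_id`.
#' @return An object of class `expression_panel`.
#' @export
expression_panel <- function(tu, an, probe_map) {
  if (!is.matrix(tu) || !is.matrix(an)) {
    stop("`tu` and `an` must be matrices (probes x patients)")
  }
  if (!identical(dim(tu), dim(an))) {
    stop("`tu` and `an` must have identical dimensions")
  }
  if (!identical(rownames(tu), rownames(an)) ||
      !identical(colnames(tu), colnames(an))) {
    stop("`tu` and `an` must share row and column names in the same order")
  }
  if (is.null(rownames(tu))) stop("intensity matrices must have probe rownames")
  if (anyNA(tu) || anyNA(an) || any(tu <= 0) || any(an <= 0)) {
    stop("intensities must be finite and strictly positive")
  }
  probe_map <- validate_probe_map(probe_map)
  missing <- setdiff(rownames(tu), probe_map$probe_id)
  if (length(missing) > 0) {
    stop("probes without an entity mapping: ", paste(head(missing, 5), collapse = ", "))
  }
  structure(list(tu = tu, an = an, probe_map = probe_map),
            class = "expression_panel")
}

validate_probe_map <- function(probe_map) {
  req <- c("probe_id", "entity_id", "entity_class")
  if (!is.data.frame(probe_map) || !all(req %in% names(probe_map))) {
    stop("`probe_map` needs columns probe_id, entity_id, entity_class")
  }
  probe_map <- as.data.frame(probe_map)[req]
  bad <- !probe_map$entity_class %in% c("gene", "TF", "miRNA")
  if (any(bad)) {
    stop("unknown entity_class: ", paste(unique(probe_map$entity_class[bad]), collapse = ", "))
  }
  if (anyDuplicated(probe_map$probe_id)) {
    stop("probe_map maps some probes more than once")
  }
  probe_map
}

#' @export
print.expression_panel <- function(x, ...) {
  cat("expression_panel:", nrow(x$tu), "probes x", ncol(x$tu), "patients;",
      length(unique(x$probe_map$entity_id)), "entities\n")
  invisible(x)
}

#' Penalty term for tumor/normal ratios
#'
#' The penalty added to both the numerator and denominator of the
#' tumor/normal intensity ratio, to keep ratios of small intensities from
#' exploding. It is the mean of the 25% intensity quantiles of the whole
#' tumor matrix and the whole adjacent non-tumor matrix,
#' `(q0.25(TU) + q0.25(AN)) / 2`, each quantile pooled over every entry of
#' its matrix. Quantiles use the usual linear-interpolation rule
#' (`type = 7`).
#'
#' @param panel An [expression_panel()].
#' @return A single positive number.
#' @seealso [compute_ratios()]
#' @export
compute_alpha <- function(panel) {
  stopifnot(inherits(panel, "expression_panel"))
  if (length(panel$tu) == 0) stop("empty intensity matrix")
  q_tu <- quantile(as.vector(panel$tu), 0.25, names = FALSE, type = 7)
  q_an <- quantile(as.vector(panel$an), 0.25, names = FALSE, type = 7)
  (q_tu + q_an) / 2
}

#' Penalized log2 tumor/normal ratio matrix
#'
#' Computes `log2((TU + alpha) / (AN + alpha))` entrywise at probe level.
#'
#' @param panel An [expression_panel()].
#' @param alpha Positive penalty; defaults to [compute_alpha()] of `panel`.
#' @return A `ratio_matrix`: list with `values` (probes x patients matrix of
#'   log2 ratios), `alpha`, and `level = "probe"`.
#' @export
compute_ratios <- function(panel, alpha = compute_alpha(panel)) {
  stopifnot(inherits(panel, "expression_panel"))
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) || alpha <= 0) {
    stop("`alpha` must be a single positive number")
  }
  values <- log2((panel$tu + alpha) / (panel$an + alpha))
  if (!all(is.finite(values))) stop("non-finite ratios produced")
  ratio_matrix(values, alpha, level = "probe")
}

ratio_matrix <- function(values, alpha, level = c("probe", "entity")) {
  structure(list(values = values, alpha = alpha, level = match.arg(level)),
            class = "ratio_matrix")
}

#' Assemble a ratio matrix from its components
#'
#' Rebuilds a `ratio_matrix` from a values matrix and the penalty it was
#' computed with -- e.g. after reading a stage artifact back from TSV with
#' [read_expression_matrix()].
#'
#' @param values Numeric matrix of log2 ratios with row names.
#' @param alpha The positive penalty used to compute the ratios.
#' @param level `"entity"` (default) or `"probe"`.
#' @return A `ratio_matrix`.
#' @export
as_ratio_matrix <- function(values, alpha, level = "entity") {
  stopifnot(is.matrix(values), !is.null(rownames(values)), alpha > 0)
  ratio_matrix(values, alpha, level)
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat("ratio_matrix (", x$level, " level): ", nrow(x$values), " x ",
      ncol(x$values), ", alpha = ", format(x$alpha), "\n", sep = "")
  invisible(x)
}

#' Merge probe-level ratios to entity level
#'
#' Entities measured by several probes get the arithmetic mean of their
#' probes' ratio rows, patient by patient. Merging happens after the ratio
#' computation, so the entity ratio is the mean of probe ratios, not the
#' ratio of mean intensities.
#'
#' @param ratios A probe-level `ratio_matrix` from [compute_ratios()].
#' @param probe_map Probe-to-entity map (see [expression_panel()]).
#' @return An entity-level `ratio_matrix` whose rows are entity ids, with an
#'   `entity_class` attribute (named character vector) carried along.
#' @export
merge_probes <- function(ratios, probe_map) {
  stopifnot(inherits(ratios, "ratio_matrix"), ratios$level == "probe")
  probe_map <- validate_probe_map(probe_map)
  idx <- match(rownames(ratios$values), probe_map$probe_id)
  if (anyNA(idx)) {
    stop("probe without an entity mapping: ",
         rownames(ratios$values)[which(is.na(idx))[1]])
  }
  entity <- probe_map$entity_id[idx]
  sums <- rowsum(ratios$values, group = entity)
  counts <- as.vector(table(entity)[rownames(sums)])
  merged <- sums / counts
  out <- ratio_matrix(merged, ratios$alpha, level = "entity")
  cls <- probe_map$entity_class[idx]
  attr(out, "entity_class") <- setNames(cls, entity)[rownames(merged)]
  out
}

#' Per-entity differential statistics on log-ratios
#'
#' One-sample two-sided t-test of each entity's log2 ratios against zero.
#' Positive t means up-regulation in tumor, negative t down-regulation.
#' Rows with zero variance (or fewer than 3 finite values) get `NA` rather
#' than an error.
#'
#' @param ratios A `ratio_matrix` (any level).
#' @return Data frame with columns `entity`, `t`, `p`.
#' @export
differential_stats <- function(ratios) {
  stopifnot(inherits(ratios, "ratio_matrix"))
  v <- ratios$values
  if (ncol(v) < 3) stop("need at least 3 patients for a t-test")
  n <- ncol(v)
  m <- rowMeans(v)
  s <- sqrt(rowSums((v - m)^2) / (n - 1))
  t_stat <- ifelse(s > 0, m / (s / sqrt(n)), NA_real_)
  p <- 2 * pt(-abs(t_stat), df = n - 1)
  bad <- sum(!is.finite(t_stat))
  if (bad > 0) message(bad, " zero-variance rows reported as NA")
  data.frame(entity = rownames(v), t = t_stat, p = p, row.names = NULL,
             stringsAsFactors = FALSE)
}
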