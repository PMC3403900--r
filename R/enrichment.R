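#' Annotation collection for over-representation analysis
#'
#' Term-to-member sets over an explicit background universe. Term members
#' outside the background are trimmed (the test conditions on the
#' background, so ids not in it cannot contribute to any overlap).
#'
#' @param terms Named list of character vectors (term -> member ids).
#' @param background Character vector, the id universe; defaults to the
#'   union of all term members.
#' @return An `annotation_collection`.
#' @export
annotation_collection <- function(terms, background = NULL) {
  stopifnot(is.list(terms), !is.null(names(terms)), all(nzchar(names(terms))))
  if (is.null(background)) background <- unique(unlist(terms))
  background <- unique(as.character(background))
  trimmed <- lapply(terms, function(m) intersect(unique(as.character(m)), background))
  n_lost <- sum(lengths(terms) - lengths(trimmed))
  if (n_lost > 0) message("trimmed ", n_lost, " term member(s) outside the background")
  structure(list(terms = trimmed, background = background),
            class = "annotation_collection")
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect (term, description, then members, tab-separated),
#' parsed with `fgsea::gmtPathways()`.
#'
#' @param path Path to the GMT file.
#' @param background Optional id universe; defaults to the union of all
#'   sets in the file.
#' @return An [annotation_collection()].
#' @export
read_gmt <- function(path, background = NULL) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    stop("reading GMT files requires the fgsea package")
  }
  annotation_collection(fgsea::gmtPathways(path), background)
}

#' Hypergeometric over-representation of a query set
#'
#' One-sided hypergeometric upper-tail test per term: the p-value is the
#' probability of an overlap at least as large as observed when `|query|`
#' ids are drawn from the background without replacement. FDRs are
#' Benjamini-Hochberg adjusted across terms ([bh_fdr()]).
#'
#' @param query Character vector of ids; ids outside the background are
#'   dropped with a warning.
#' @param annotations An [annotation_collection()].
#' @return Data frame sorted by p-value (ties by term name): `term`,
#'   `overlap`, `query_size`, `term_size`, `background_size`, `p_value`,
#'   `fdr`. Empty (with a warning) for an empty query.
#' @export
hypergeom_enrich <- function(query, annotations) {
  stopifnot(inherits(annotations, "annotation_collection"))
  query <- unique(as.character(query))
  outside <- setdiff(query, annotations$background)
  if (length(outside) > 0) {
    warning("dropping ", length(outside), " query id(s) outside the background")
    query <- setdiff(query, outside)
  }
  empty <- data.frame(term = character(), overlap = integer(),
                      query_size = integer(), term_size = integer(),
                      background_size = integer(), p_value = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE)
  if (length(query) == 0) {
    warning("empty query; no enrichment computed")
    return(empty)
  }
  n_bg <- length(annotations$background)
  n_q <- length(query)
  rows <- lapply(names(annotations$terms), function(term) {
    members <- annotations$terms[[term]]
    k <- length(intersect(query, members))
    m <- length(members)
    p <- phyper(k - 1, m, n_bg - m, n_q, lower.tail = FALSE)
    data.frame(term = term, overlap = k, query_size = n_q, term_size = m,
               background_size = n_bg, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out$fdr <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjustment with monotonicity enforcement, as implemented by
#' `p.adjust(method = "BH")`; inputs are validated to lie in `[0, 1]`.
#'
#' @param p_values Numeric vector of p-values.
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop("p-values must be numbers in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}
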