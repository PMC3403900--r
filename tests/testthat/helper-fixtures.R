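# Small in-code fixtures shared across test files.

# A panel with explicit intensities: probes x patients matrices.
make_panel <- function(tu, an, classes = NULL) {
  probes <- rownames(tu)
  if (is.null(classes)) classes <- rep("gene", length(probes))
  expression_panel(tu, an, data.frame(
    probe_id = probes, entity_id = sub("^p_", "", probes),
    entity_class = classes, stringsAsFactors = FALSE))
}

const_panel <- function(tu_value, an_value, n_probes = 2, n_patients = 4) {
  tu <- matrix(tu_value, n_probes, n_patients,
               dimnames = list(paste0("p_", seq_len(n_probes)),
                               paste0("s", seq_len(n_patients))))
  an <- matrix(an_value, n_probes, n_patients, dimnames = dimnames(tu))
  make_panel(tu, an)
}

# Candidate interaction data frame -> interaction_set, with defaults.
make_interactions <- function(regulator, regulator_class, target, target_class,
                              predicted = TRUE, experimental = FALSE) {
  interaction_set(data.frame(
    regulator = regulator, regulator_class = regulator_class,
    target = target, target_class = target_class,
    predicted = predicted, experimental = experimental,
    stringsAsFactors = FALSE))
}

# Entity-level ratio matrix straight from a values matrix.
make_ratios <- function(values, alpha = 1) {
  coregrn:::ratio_matrix(values, alpha, level = "entity")
}

# A grn object from an accepted-edge data frame (adds missing columns).
make_grn <- function(edges, cutoffs = c(TF = 0, miRNA = 0)) {
  if (is.null(edges$r)) edges$r <- 0.9
  if (is.null(edges$n_used)) edges$n_used <- 96L
  if (is.null(edges$predicted)) edges$predicted <- TRUE
  if (is.null(edges$experimental)) edges$experimental <- FALSE
  coregrn:::grn_from_edges(edges, cutoffs)
}

# Edge data frame for simple TF->gene chains/paths given an edge list.
edges_df <- function(from, to, from_class = "TF", to_class = "gene") {
  data.frame(regulator = from, regulator_class = from_class,
             target = to, target_class = to_class, stringsAsFactors = FALSE)
}
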