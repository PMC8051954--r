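# shared fixtures, all built in code

fix_counts <- function(values, features, barcodes) {
  count_matrix(matrix(values, nrow = length(features), byrow = TRUE),
               features, barcodes)
}

# a minimal hand-built experiment: 2 markers, 4 cells + 4 empties with
# known counts, partition preassigned via metadata
fix_experiment <- function(adt_cells, adt_empty, markers = c("mkA", "mkB"),
                           cell_types = NULL) {
  n_cell <- ncol(adt_cells)
  n_empty <- ncol(adt_empty)
  bc <- sprintf("bc%02d", seq_len(n_cell + n_empty))
  adt <- count_matrix(cbind(adt_cells, adt_empty), markers, bc)
  meta <- data.frame(barcode = bc,
                     droplet_class = rep(c("cell", "empty"), c(n_cell, n_empty)),
                     cell_type = c(if (is.null(cell_types)) rep("T", n_cell)
                                   else cell_types,
                                   rep(NA_character_, n_empty)),
                     stringsAsFactors = FALSE)
  panel <- antibody_panel(markers, list(DF1 = rep(1, length(markers))))
  suppressMessages(build_experiment(adt, panel,
                                    staining_condition("DF1", 1, 50, 1e6),
                                    metadata = meta))
}

fix_conditions <- function() {
  list(DF1 = staining_condition("DF1", 1, 50, 1e6),
       DF4 = staining_condition("DF4", 4, 50, 1e6))
}

# small archetype lane for pipeline-level tests
fix_lane <- function(seed = 1, n_cells = 500, n_empty = 5000, ...) {
  simulate_lane(archetype_panel(),
                sim_config(n_cells = n_cells, n_empty = n_empty, seed = seed, ...),
                fix_conditions())
}
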