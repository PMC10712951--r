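# Representational similarity analysis of hidden-layer responses.

#' Capture hidden-layer responses to a probe set
#'
#' Probes each item and records the settled activation patterns of the
#' requested layers.  `mode = "settled"` is the fully settled response
#' including big-loop recurrence (EC_out feeding back into EC_in);
#' `mode = "initial"` severs that loop structurally (the EC_out->EC_in
#' gate is held at 0 during settling), capturing the spread of activity
#' through the circuit before output recirculates — so the subfields'
#' own representational contributions can be assessed.  Weights are
#' never changed.
#'
#' @param network an `hnet`.
#' @param inputs probe matrix (items x input units).
#' @param mode `"settled"` or `"initial"`.
#' @param layers layer names to record (default the three subfields).
#' @inheritParams settle
#' @return named list of response matrices (items x units), with the
#'   mode stored in attribute `"mode"`.
#' @export
capture_responses <- function(network, inputs,
                              mode = c("settled", "initial"),
                              layers = c("DG", "CA3", "CA1"),
                              engine = "cpp") {
  mode <- match.arg(mode)
  override <- if (mode == "initial") list("EC_out->EC_in" = 0) else NULL
  snaps <- lapply(layers, function(l)
    matrix(NA_real_, nrow(inputs), network$layers[[l]]$size,
           dimnames = list(rownames(inputs), NULL)))
  names(snaps) <- layers
  for (i in seq_len(nrow(inputs))) {
    st <- probe(network, inputs[i, ], gate_override = override,
                full_state = TRUE, engine = engine)
    for (l in layers) snaps[[l]][i, ] <- st$act[[l]]
  }
  for (l in layers) attr(snaps[[l]], "mode") <- mode
  snaps
}

#' Item-by-item Pearson similarity matrix
#'
#' Pearson correlations between the activation patterns evoked by pairs
#' of items.  The matrix is symmetric with unit diagonal.  Pairs
#' involving a constant (zero-variance) pattern have no defined
#' correlation and are set to 0 with a warning.
#'
#' @param responses items x units response matrix (one layer, one mode,
#'   e.g. from [capture_responses()]).
#' @return items x items correlation matrix.
#' @export
similarity_matrix <- function(responses) {
  stopifnot(nrow(responses) >= 2)
  sds <- apply(responses, 1, sd)
  m <- suppressWarnings(cor(t(responses)))
  if (any(sds == 0)) {
    warning("constant response pattern(s); correlations set to 0")
    m[sds == 0, ] <- 0
    m[, sds == 0] <- 0
  }
  diag(m) <- 1
  dimnames(m) <- list(rownames(responses), rownames(responses))
  m
}

#' Within- and between-category mean similarity
#'
#' Means of the off-diagonal similarity-matrix cells for same-category
#' and different-category item pairs, after dropping any excluded items
#' (e.g. the weather task's equiprobable card combinations).
#'
#' @param matrix similarity matrix from [similarity_matrix()].
#' @param labels category label per item.
#' @param excluded_items indices or names of items to drop.
#' @return list with `within` and `between` means (a category with a
#'   single item contributes no within pairs).
#' @export
within_between_summary <- function(matrix, labels, excluded_items = NULL) {
  stopifnot(nrow(matrix) == length(labels))
  keep <- seq_len(nrow(matrix))
  if (!is.null(excluded_items)) {
    if (is.character(excluded_items))
      excluded_items <- match(excluded_items, rownames(matrix))
    keep <- setdiff(keep, excluded_items)
  }
  m <- matrix[keep, keep, drop = FALSE]
  lab <- labels[keep]
  same <- outer(lab, lab, `==`)
  off <- !diag(TRUE, nrow(m))
  list(within = mean(m[same & off]), between = mean(m[!same]))
}

#' Write similarity matrices as labelled delimited tables
#'
#' One tab-separated file per layer x mode, named
#' `rsa_<layer>_<mode>.tsv`, mirroring source-data CSV conventions.
#'
#' @param matrices named list of similarity matrices.
#' @param dir output directory (created if needed).
#' @param mode mode tag used in the file names.
#' @return the written paths, invisibly.
#' @export
write_similarity <- function(matrices, dir, mode = "settled") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (l in names(matrices)) {
    p <- file.path(dir, paste0("rsa_", l, "_", mode, ".tsv"))
    write.table(round(matrices[[l]], 6), p, sep = "\t", quote = FALSE,
                col.names = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
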