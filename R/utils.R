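# Internal helpers shared across the pipeline stages.

# Topological order of a directed edge set, or NULL (with the offending cycle
# attached) when the graph is cyclic. Kahn's algorithm; deterministic because
# ties are broken by the order of `nodes`.
topo_sort <- function(nodes, edges) {
  indeg <- setNames(integer(length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) indeg[[edges$to[i]]] <- indeg[[edges$to[i]]] + 1L
  order <- character(0)
  avail <- nodes[indeg[nodes] == 0L]
  while (length(avail) > 0) {
    v <- avail[1]
    order <- c(order, v)
    out <- edges$to[edges$from == v]
    indeg[out] <- indeg[out] - 1L
    avail <- c(avail[-1], out[indeg[out] == 0L & !(out %in% avail[-1])])
    avail <- intersect(nodes, avail) # keep the declared ordering
  }
  if (length(order) < length(nodes)) {
    list(order = NULL, cycle = setdiff(nodes, order))
  } else {
    list(order = order, cycle = NULL)
  }
}

stopifnot_scalar_prob <- function(x, name, open_left = TRUE, open_right = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (open_left) x > 0 else x >= 0) &&
    (if (open_right) x < 1 else x <= 1)
  if (!ok) abort(sprintf("`%s` must be a single number in %s0,1%s, got %s",
                         name, if (open_left) "(" else "[",
                         if (open_right) ")" else "]",
                         deparse(x)))
  invisible(x)
}

# Symmetric matrix from a long (var1, var2, value) specification with unit
# diagonal; used to build labelled correlation matrices.
build_corr_matrix <- function(labels, pairs) {
  m <- diag(length(labels))
  dimnames(m) <- list(labels, labels)
  for (i in seq_len(nrow(pairs))) {
    m[pairs$var1[i], pairs$var2[i]] <- pairs$value[i]
    m[pairs$var2[i], pairs$var1[i]] <- pairs$value[i]
  }
  m
}

check_square_named <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    abort(sprintf("`%s` must be a square matrix", what))
  if (is.null(rownames(m)) || is.null(colnames(m)))
    abort(sprintf("`%s` must have row and column names", what))
  if (max(abs(m - t(m))) > 1e-8)
    abort(sprintf("`%s` must be symmetric", what))
  invisible(m)
}

is_psd <- function(m, tol = 1e-8) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > -tol * max(abs(ev))
}

# Significance stars following the reporting convention used for effect
# tables: * p<.10, ** p<.05, *** p<.01.
effect_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.01 ~ "***",
    p < 0.05 ~ "**",
    p < 0.10 ~ "*",
    TRUE ~ ""
  )
}
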