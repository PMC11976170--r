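# Flattened tree structures of a fitted ranger probability forest, with
# covers (in-bag weighted sample counts) and per-class leaf values. Shared by
# the impurity-importance and Shapley-attribution computations.

extract_tree <- function(model, t) {
  ti <- ranger::treeInfo(model$fit, t)
  leaf <- is.na(ti$leftChild)
  predcols <- paste0("pred.", MUSCLES)
  leafval <- as.matrix(ti[, predcols, drop = FALSE])
  leafval[is.na(leafval)] <- 0
  colnames(leafval) <- MUSCLES
  list(childL = ifelse(leaf, -1L, ti$leftChild),
       childR = ifelse(leaf, -1L, ti$rightChild),
       splitvar = ifelse(leaf, 0L, ti$splitvarID),
       splitval = ifelse(leaf, 0, ti$splitval),
       leafval = leafval)
}

# All trees with covers and per-class in-bag counts attached.
forest_structure <- function(model) {
  stopifnot(inherits(model, "mep_rf"))
  if (!is.null(model$cache$forest)) return(model$cache$forest)
  if (is.null(model$fit$inbag.counts)) {
    abort_param("forest was fitted without keep.inbag; cannot attach covers")
  }
  X <- model$X_train
  y0 <- as.integer(model$y_train) - 1L
  ntree <- model$fit$num.trees
  trees <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    tr <- extract_tree(model, t)
    w <- model$fit$inbag.counts[[t]]
    route <- cpp_tree_route(tr$childL, tr$childR, tr$splitvar, tr$splitval,
                            X, as.numeric(w), y0, length(MUSCLES))
    tr$cover <- route$cover
    tr$counts <- route$counts
    trees[[t]] <- tr
  }
  model$cache$forest <- trees
  trees
}
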