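# Fast per-row evaluation of a fitted randomForest regression ensemble.
#
# predict.randomForest re-marshals the whole forest into C on every call,
# which dominates run time when the recursive projection needs one row at a
# time. Here the trees are unpacked once into flat arrays and each row is
# evaluated by walking all trees simultaneously with vectorized indexing.
# Terminal-node predictions are randomForest's own node means, so per-tree
# outputs are identical to predict(..., predict.all = TRUE)$individual.

pack_forest <- function(rf) {
  ntree <- rf$ntree
  trees <- lapply(seq_len(ntree), function(k)
    randomForest::getTree(rf, k, labelVar = FALSE))
  sizes <- vapply(trees, nrow, integer(1))
  offset <- c(0L, cumsum(sizes))[seq_len(ntree)]
  all <- do.call(rbind, trees)
  list(
    ntree = ntree,
    offset = offset,
    left = as.integer(all[, "left daughter"]),
    right = as.integer(all[, "right daughter"]),
    splitvar = as.integer(all[, "split var"]),
    splitpt = as.numeric(all[, "split point"]),
    terminal = all[, "status"] == -1,
    pred = as.numeric(all[, "prediction"])
  )
}

# x: numeric vector in the training feature order; returns ntree per-tree
# predictions
predict_packed_row <- function(pf, x) {
  node <- rep.int(1L, pf$ntree)
  repeat {
    idx <- pf$offset + node
    live <- !pf$terminal[idx]
    if (!any(live)) break
    il <- idx[live]
    goleft <- x[pf$splitvar[il]] <= pf$splitpt[il]
    node[live] <- ifelse(goleft, pf$left[il], pf$right[il])
  }
  pf$pred[pf$offset + node]
}
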