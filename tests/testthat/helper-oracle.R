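# Independent brute-force reference implementation of the persistence sweep.
# Deliberately naive: components are kept as explicit voxel-coordinate sets and
# rescanned from scratch at every filtration step; no union-find, no shared
# code with the package's C++ path.

oracle_lex_order <- function(x) {
  d <- dim(x)
  coords <- arrayInd(seq_along(x), d)
  keys <- c(list(-as.numeric(x)), lapply(seq_len(ncol(coords)),
                                         function(k) coords[, k]))
  do.call(order, keys)
}

oracle_neighbors <- function(coord, d, full) {
  nd <- length(d)
  deltas <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  keep <- rowSums(deltas != 0) >= 1
  if (!full) keep <- keep & rowSums(deltas != 0) == 1
  deltas <- deltas[keep, , drop = FALSE]
  nb <- sweep(deltas, 2, coord, "+")
  ok <- rep(TRUE, nrow(nb))
  for (k in seq_len(nd)) ok <- ok & nb[, k] >= 1 & nb[, k] <= d[k]
  nb[ok, , drop = FALSE]
}

oracle_segment <- function(x, tau, full = TRUE) {
  d <- dim(x)
  ord <- oracle_lex_order(x)
  coords <- arrayInd(ord, d)
  # components: list(root_coord, root_int, voxels = matrix of coords)
  comps <- list()
  lex_less <- function(a, b) {
    for (k in seq_along(a)) {
      if (a[k] != b[k]) return(a[k] < b[k])
    }
    FALSE
  }
  for (s in seq_len(nrow(coords))) {
    v <- coords[s, ]
    Iv <- x[matrix(v, 1)]
    nb <- oracle_neighbors(v, d, full)
    owners <- integer(0)
    for (ci in seq_along(comps)) {
      vox <- comps[[ci]]$voxels
      for (r in seq_len(nrow(nb))) {
        if (any(colSums(abs(t(vox) - nb[r, ])) == 0)) {
          owners <- c(owners, ci)
          break
        }
      }
    }
    owners <- unique(owners)
    if (length(owners) == 0) {
      comps[[length(comps) + 1]] <- list(root = v, root_int = Iv,
                                         voxels = matrix(v, 1))
      next
    }
    best <- owners[1]
    for (ci in owners[-1]) {
      if (comps[[ci]]$root_int > comps[[best]]$root_int ||
          (comps[[ci]]$root_int == comps[[best]]$root_int &&
             lex_less(comps[[ci]]$root, comps[[best]]$root)))
        best <- ci
    }
    if (comps[[best]]$root_int - Iv <= tau) {
      comps[[best]]$voxels <- rbind(comps[[best]]$voxels, v)
      absorbed <- integer(0)
      for (ci in owners) {
        if (ci == best) next
        if (abs(comps[[best]]$root_int - comps[[ci]]$root_int) <= tau) {
          comps[[best]]$voxels <- rbind(comps[[best]]$voxels,
                                        comps[[ci]]$voxels)
          absorbed <- c(absorbed, ci)
        }
      }
      if (length(absorbed)) comps <- comps[-absorbed]
    }
    # else: background, nothing happens
  }
  comps <- Filter(function(cc) cc$root_int >= tau, comps)
  if (length(comps) > 1) {
    key <- order(-vapply(comps, function(cc) cc$root_int, 0))
    # stable refine by lexicographic root among equal intensities
    ints <- vapply(comps, function(cc) cc$root_int, 0)
    lexs <- vapply(comps, function(cc)
      sum(cc$root * (max(d) + 1)^rev(seq_along(d) - 1)), 0)
    key <- order(-ints, lexs)
    comps <- comps[key]
  }
  labels <- array(0L, dim = d)
  for (ci in seq_along(comps)) {
    labels[comps[[ci]]$voxels] <- ci
  }
  labels
}

rand_stack <- function(seed, dims, levels = NULL) {
  set.seed(seed)
  x <- if (is.null(levels)) stats::runif(prod(dims))
       else sample(levels, prod(dims), replace = TRUE)
  array(x, dim = dims)
}
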