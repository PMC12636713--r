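# Connected-component utilities.
#
# Objects are 8-connected, background 4-connected (package-wide constant).
# EBImage::bwlabel is 4-connected, so diagonally touching components are
# merged afterwards with a union-find pass.

# iterative union-find with path halving
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_merge_pairs <- function(n, pairs) {
  # pairs: 2-column matrix of ids to union; returns root id per element
  parent <- uf_new(n)
  if (!is.null(pairs) && nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ra <- uf_find(parent, pairs[k, 1L])
      rb <- uf_find(parent, pairs[k, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
}

# label pairs of positive, differing labels across the two diagonal
# directions of a label matrix
diagonal_label_pairs <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr < 2L || nc < 2L) return(NULL)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]      # \ direction
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]     # / direction
  a <- c(a1, a2); b <- c(b1, b2)
  sel <- a > 0L & b > 0L & a != b
  if (!any(sel)) return(NULL)
  unique(cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel])))
}

# 4-adjacent pairs of positive, differing labels (used when merging grown
# objects that touch)
adjacent_label_pairs <- function(lab, diagonal = TRUE) {
  nr <- nrow(lab); nc <- ncol(lab)
  a <- c(if (nr > 1L) lab[-nr, ] else NULL, if (nc > 1L) lab[, -nc] else NULL)
  b <- c(if (nr > 1L) lab[-1, ] else NULL, if (nc > 1L) lab[, -1] else NULL)
  if (diagonal) {
    dp <- diagonal_label_pairs(lab)
    sel <- a > 0L & b > 0L & a != b
    pairs <- cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel]))
    return(unique(rbind(pairs, dp)))
  }
  sel <- a > 0L & b > 0L & a != b
  if (!any(sel)) return(NULL)
  unique(cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel])))
}

# 8-connected labeling of a binary mask; returns an integer matrix with
# contiguous labels 1..n
label8 <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  n <- max(lab)
  if (n < 2L) return(lab)
  pairs <- diagonal_label_pairs(lab)
  if (is.null(pairs)) return(lab)
  root <- uf_merge_pairs(n, pairs)
  # contiguous relabel of roots
  u <- sort(unique(root))
  remap <- integer(n); remap[u] <- seq_along(u)
  newlab <- remap[root]
  pos <- lab > 0L
  lab[pos] <- newlab[lab[pos]]
  lab
}

# apply an old-label -> new-label integer map to a raster
apply_label_map <- function(lab, map) {
  pos <- lab > 0L
  lab[pos] <- map[lab[pos]]
  lab
}
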