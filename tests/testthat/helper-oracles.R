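# Independent brute-force oracles, deliberately written with explicit loops
# and raw arithmetic, sharing no code with the package internals.

# moving average: enumerate every 1%-step window [s, s+w) and average by hand
brute_moving_average <- function(std, w) {
  xs <- c(); Ls <- c(); Bs <- c(); As <- c(); Rs <- c()
  for (s in 0:(100 - w)) {
    sx <- sl <- sb <- sa <- sr <- 0; cnt <- 0
    for (i in seq_len(nrow(std))) {
      if (std$p[i] >= s && std$p[i] < s + w) {
        sx <- sx + std$p[i]; sl <- sl + std$l[i]; sb <- sb + std$b[i]
        sa <- sa + std$a[i]; sr <- sr + std$r[i]; cnt <- cnt + 1
      }
    }
    if (cnt > 0) {
      xs <- c(xs, sx / cnt); Ls <- c(Ls, sl / cnt); Bs <- c(Bs, sb / cnt)
      As <- c(As, sa / cnt); Rs <- c(Rs, sr / cnt)
    }
  }
  pts <- data.frame(x = xs, L = Ls, B = Bs, A = As, R = Rs)
  pts <- unique(pts)
  # merge any residual equal-x points by plain averaging
  out <- do.call(rbind, lapply(split(pts, pts$x), function(g) {
    data.frame(x = g$x[1], L = mean(g$L), B = mean(g$B),
               A = mean(g$A), R = mean(g$R))
  }))
  out <- out[order(out$x), ]
  rownames(out) <- NULL
  out
}

# UPGMA cophenetic matrix by naive agglomeration: cluster distance is the
# plain mean over all leaf pairs, recomputed from the original matrix at
# every step (no recurrence); ties by smallest leaf-label pair.
brute_upgma_cophenetic <- function(dm, labels) {
  n <- nrow(dm)
  dimnames(dm) <- list(labels, labels)
  clusters <- as.list(labels)
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        pairs <- expand.grid(a = clusters[[i]], b = clusters[[j]],
                             stringsAsFactors = FALSE)
        dij <- mean(mapply(function(a, b) dm[a, b], pairs$a, pairs$b))
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 &&
             (key[1] < best$k1 || (key[1] == best$k1 && key[2] < best$k2)))) {
          best <- list(d = dij, i = i, j = j, k1 = key[1], k2 = key[2])
        }
      }
    }
    for (a in clusters[[best$i]]) for (b in clusters[[best$j]]) {
      coph[a, b] <- coph[b, a] <- best$d
    }
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  coph
}

# rooted-topology comparison: the set of tip-label clades below each node
clade_sets <- function(tree) {
  n <- length(tree$tip.label)
  sets <- lapply((n + 1):(n + tree$Nnode), function(node) {
    tips <- ape::extract.clade(tree, node)$tip.label
    paste(sort(tips), collapse = "|")
  })
  sort(unlist(sets))
}

same_rooted_topology <- function(t1, t2) {
  identical(clade_sets(t1), clade_sets(t2))
}

# cophenetic matrix of an ultrametric phylo, ordered by label
tree_cophenetic <- function(tree, labels) {
  co <- ape::cophenetic.phylo(tree)
  co[labels, labels]
}
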