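# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is read from disk unless a test exercises file I/O.

# a tiny two-cell world with environmental values 0 and 1 (closed-form maxent)
two_cell_features <- function() {
  st <- env_stack(list(raster_grid(matrix(c(0, 1), 1, 2), name = "e")))
  build_features(st, n_presences = 4, mode = "explicit", classes = "linear")
}

# small continuous stack of any size (deterministic)
toy_stack <- function(n = 10, layers = 3, seed = 99) {
  set.seed(seed)
  env_stack(lapply(seq_len(layers), function(i)
    raster_grid(matrix(stats::runif(n * n), n, n),
                name = sprintf("env%02d", i))))
}

# hand-built alignment exercising every site class and the indel rules:
# - taxa B and C share an internal gap at columns 4-6
# - taxon D has a longer overlapping gap at columns 3-7
# - taxa A and E are gap-free
toy_alignment <- function() {
  as_alignment(rbind(
    taxonA = strsplit("ACGTACGTACGTACGTACGT", "")[[1]],
    taxonB = strsplit("ACG---GTACGTACGTACGA", "")[[1]],
    taxonC = strsplit("ACG---GTACGTACGTACGA", "")[[1]],
    taxonD = strsplit("AC-----TACGTACGTACGT", "")[[1]],
    taxonE = strsplit("ACGTACGTACGTACGAACGT", "")[[1]]))
}

# independent brute-force oracles -------------------------------------------

# AUC by looping over all presence-background pairs
auc_brute <- function(pres, bg) {
  tot <- 0
  for (a in pres) for (b in bg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pres) * length(bg))
}

# patristic distance by walking both root paths and subtracting the shared
# prefix twice (independent of ape::dist.nodes)
patristic_brute <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent <- function(node) tree$edge[tree$edge[, 2] == node, 1]
  elen <- function(node) tree$edge.length[tree$edge[, 2] == node]
  path_to_root <- function(tip) {
    nodes <- tip; d <- 0
    while (nodes[length(nodes)] != root) {
      d <- c(d, d[length(d)] + elen(nodes[length(nodes)]))
      nodes <- c(nodes, parent(nodes[length(nodes)]))
    }
    list(nodes = nodes, dist = d)
  }
  paths <- lapply(seq_len(ntip), path_to_root)
  D <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1)) for (j in (i + 1):ntip) {
    shared <- intersect(paths[[i]]$nodes, paths[[j]]$nodes)
    # deepest shared node = first shared along either path
    anc <- shared[which.min(match(shared, paths[[i]]$nodes))]
    di <- paths[[i]]$dist[match(anc, paths[[i]]$nodes)]
    dj <- paths[[j]]$dist[match(anc, paths[[j]]$nodes)]
    D[i, j] <- D[j, i] <- di + dj
  }
  D
}

# Pearson r from the raw covariance formula
pearson_brute <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
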